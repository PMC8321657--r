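random_pfm <- function(L, seed) {
  set.seed(seed)
  m <- matrix(sample(0:20, L * 4, replace = TRUE), L, 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_len(L), sample.int(4, L, replace = TRUE))] <- 60
  m
}

test_that("scan equals exhaustive both-strand enumeration with exact p-values", {
  set.seed(5)
  genome <- tiny_genome(chr1 = paste(sample(c("A", "C", "G", "T"), 400,
                                            replace = TRUE), collapse = ""))
  for (L in 4:6) {
    pfm <- random_pfm(L, seed = L)
    hits <- scan_motifs(genome, list(TFX = pfm), p_threshold = 1e-2)
    brute <- brute_scan(genome, pfm)
    brute$pval <- brute_pval(pfm, brute_int_score(genome, pfm, brute))
    brute <- brute[brute$pval <= 1e-2, ]
    key <- function(d) paste(d$start, d$strand)
    expect_setequal(key(hits), key(brute))
    m <- match(key(hits), key(brute))
    expect_equal(hits$score, brute$score[m], tolerance = 1e-9)
    expect_equal(hits$pval, brute$pval[m], tolerance = 1e-12)
  }
})

test_that("a uniform PPM scores zero everywhere and never passes the gate", {
  pfm <- matrix(25, 6, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  genome <- tiny_genome(chr1 = strrep("ACGT", 50))
  hits <- scan_motifs(genome, list(U = pfm), p_threshold = 1e-4)
  expect_equal(nrow(hits), 0)
})

test_that("palindromic motifs yield one hit per strand at the same locus", {
  # ACGT consensus is its own reverse complement
  pfm <- consensus <- matrix(1, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  pfm[] <- 1
  pfm[cbind(1:4, match(c("A", "C", "G", "T"), c("A", "C", "G", "T")))] <- 97
  genome <- tiny_genome(chr1 = paste0(strrep("T", 30), "ACGT", strrep("T", 30)))
  hits <- scan_motifs(genome, list(P = pfm), p_threshold = 1e-2)
  at_locus <- hits[hits$start == 30, ]
  expect_equal(nrow(at_locus), 2)
  expect_setequal(at_locus$strand, c("+", "-"))
  expect_equal(at_locus$score[1], at_locus$score[2], tolerance = 1e-9)
})

test_that("Z-score filter uses the population sd and a strict inequality", {
  inst <- tibble::tibble(tf = "A", chrom = "chr1", start = 1:5 * 10L,
                         end = 1:5 * 10L + 6L, strand = "+",
                         score = c(10, 8, 6, 4, 2), pval = 1e-5)
  kept <- zscore_filter(inst)
  expect_equal(kept$score, 10)  # mean 6, population sd sqrt(8)

  two <- inst[1:2, ]
  two$score <- c(5, 1)
  expect_equal(zscore_filter(two)$score, 5)  # mean 3, sd 2

  flat <- inst
  flat$score <- rep(3, 5)
  expect_equal(nrow(zscore_filter(flat)), 0)

  single <- inst[1, ]
  expect_message(kept1 <- zscore_filter(single), "single instance")
  expect_equal(nrow(kept1), 1)
})

test_that("motif score change follows the PPM column and the strand rules", {
  ppm <- matrix(c(0.90, 0.03, 0.03, 0.04,
                  0.25, 0.25, 0.25, 0.25,
                  0.10, 0.20, 0.30, 0.40), 3, 4, byrow = TRUE,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_equal(motif_score_change(ppm, 1, "A", "T"), 0.86)
  expect_equal(motif_score_change(ppm, 2, "A", "G"), 0)
  # minus strand: complement alleles, mirror the offset
  expect_equal(motif_score_change(ppm, 1, "A", "T", strand = "-"),
               motif_score_change(ppm, 3, "T", "A", strand = "+"))
  expect_error(motif_score_change(ppm, 1, "A", "A"), "differ")
  expect_error(motif_score_change(ppm, 4, "A", "T"), "outside")
})

test_that("score change is ref/alt-symmetric and strand-flip invariant", {
  set.seed(9)
  ppm <- pfm_to_ppm(random_pfm(8, 9))
  bases <- c("A", "C", "G", "T")
  for (i in 1:50) {
    off <- sample.int(8, 1)
    al <- sample(bases, 2)
    d1 <- motif_score_change(ppm, off, al[1], al[2])
    expect_equal(motif_score_change(ppm, off, al[2], al[1]), d1)
    expect_gte(d1, 0)
    expect_lte(d1, 1)
    d2 <- motif_score_change(ppm, 8 + 1 - off,
                             chartr("ACGT", "TGCA", al[1]),
                             chartr("ACGT", "TGCA", al[2]), strand = "-")
    expect_equal(d2, d1)
  }
})

test_that("feature imputation follows the mode/mean rule with a 4-cell floor", {
  expect_equal(impute_feature(c("Enh", "Enh", "Tss", "Enh", "Quies")), "Enh")
  expect_equal(impute_feature(c(1, 2, 3, 4)), 2.5)
  expect_true(is.na(impute_feature(c("Enh", "Enh", "Tss"))))
  expect_true(is.na(impute_feature(c(1, 2, 3, NA))))
})

test_that("logistic weight fitting recovers planted effects and drops others", {
  set.seed(21)
  n <- 3000
  X <- data.frame(peak = rbinom(n, 1, 0.4), dhs = rbinom(n, 1, 0.4),
                  noise = rbinom(n, 1, 0.5))
  eta <- -1 + 2.0 * X$peak + 1.0 * X$dhs + 0 * X$noise
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  w <- fit_annotation_weights(X, y)
  full <- attr(w, "all_coefficients")
  expect_true(all(c("peak", "dhs") %in% names(w)))
  expect_lt(abs(full["peak"] - 2.0), 0.4)
  expect_lt(abs(full["dhs"] - 1.0), 0.4)
  expect_lt(abs(full["noise"]), 0.3)
  td <- tidy(w)
  expect_true(all(td$retained == (td$feature %in% names(w))))

  # a feature pushing the wrong way is excluded
  eta2 <- 1 - 2 * X$peak
  y2 <- rbinom(n, 1, 1 / (1 + exp(-eta2)))
  expect_warning(w2 <- fit_annotation_weights(X["peak"], y2), "positive")
  expect_length(w2, 0)

  expect_error(fit_annotation_weights(X, rep(1, n)), "classes")
})

test_that("separated data falls back to a ridge fit with finite weights", {
  X <- data.frame(peak = c(rep(1, 20), rep(0, 20)))
  y <- c(rep(1, 20), rep(0, 20))
  expect_message(w <- fit_annotation_weights(X, y), "ridge|Separation")
  expect_true(is.finite(w[["peak"]]))
  expect_gt(w[["peak"]], 0)
})
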