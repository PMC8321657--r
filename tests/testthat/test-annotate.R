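toy_bundle <- function(peak_cells = "cell1", dhs_cells = "cell1",
                       tpm = 5, cancer = "Liver", cell = "cell1") {
  annotation_bundle(
    peaks = tibble::tibble(cell_type = peak_cells, tf = "TF1",
                           chrom = "chr1", start = 90L, end = 130L),
    dhs = tibble::tibble(cell_type = dhs_cells, chrom = "chr1",
                         start = 80L, end = 140L),
    states = tibble::tibble(cell_type = cell, chrom = "chr1",
                            start = c(0L, 150L), end = c(150L, 400L),
                            state = c("Enh", "Quies")),
    cage = tibble::tibble(cell_type = character(), chrom = character(),
                          start = integer(), end = integer()),
    repdomains = tibble::tibble(cell_type = cell, chrom = "chr1",
                                start = 0L, end = 400L, domain = "early"),
    tf_expr = tibble::tibble(cell_type = cell, tf = "TF1", tpm = tpm),
    cell_map = tibble::tibble(cancer_type = cancer, cell_type = cell)
  )
}

toy_instance <- function(strand = "+") {
  tibble::tibble(tf = "TF1", chrom = "chr1", start = 100L, end = 110L,
                 strand = strand, score = 12, pval = 1e-5)
}

toy_pfm <- function() {
  m <- matrix(2, 10, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[, "A"] <- 90  # strong A at every position; A>T is maximally disruptive
  list(TF1 = m)
}

test_that("scoring joins mutations to motifs with features and weighted sum", {
  mut <- mut_row("chr1", 104, "A", "T")
  w <- c(matching_peak = 2, in_dhs = 1, delta = 1)
  sc <- score_mutated_motifs(mut, toy_instance(), toy_pfm(), toy_bundle(), w)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$motif_position, 5L)
  ppm <- pfm_to_ppm(toy_pfm()$TF1)
  expect_equal(sc$delta, unname(abs(ppm[5, "A"] - ppm[5, "T"])))
  expect_true(sc$matching_peak)
  expect_true(sc$in_dhs)
  expect_true(sc$state_Enh)
  expect_true(sc$tf_expressed)
  expect_equal(sc$regulatory_score, 2 + 1 + sc$delta)

  # weighted-sum example: peak=1, dhs=0, delta=0.5 -> 2.5
  row <- sc
  row$in_dhs <- FALSE
  row$delta <- 0.5
  expect_equal(regulatory_score(row, w), 2.5)
  row$matching_peak <- FALSE
  row$delta <- 0
  expect_equal(regulatory_score(row, w), 0)
})

test_that("mutations outside every motif produce no pairs", {
  mut <- mut_row("chr1", 250, "A", "T")
  sc <- score_mutated_motifs(mut, toy_instance(), toy_pfm(), toy_bundle(),
                             default_annotation_weights())
  expect_equal(nrow(sc), 0)
})

test_that("minus-strand instances mirror the motif position", {
  mut <- mut_row("chr1", 104, "A", "T")
  sc <- score_mutated_motifs(mut, toy_instance(strand = "-"), toy_pfm(),
                             toy_bundle(), c(delta = 1))
  expect_equal(sc$motif_position, 10L - 4L)  # L + 1 - offset, offset = 5
})

test_that("indels overlapping a motif get the maximal score change", {
  del <- mut_row("chr1", 104, "AAA", "A")
  sc <- score_mutated_motifs(del, toy_instance(), toy_pfm(), toy_bundle(),
                             c(delta = 1))
  expect_equal(sc$delta, 1.0)
})

test_that("regulatory score is monotone in every positively weighted feature", {
  set.seed(13)
  w <- c(matching_peak = 2, in_dhs = 1.5, state_Enh = 0.5, delta = 1)
  for (i in 1:100) {
    base <- tibble::tibble(matching_peak = FALSE, in_dhs = runif(1) < 0.5,
                           state_Enh = runif(1) < 0.5, delta = runif(1))
    s0 <- regulatory_score(base, w)
    expect_gte(s0, 0)
    f <- sample(names(w)[1:3], 1)
    bumped <- base
    bumped[[f]] <- TRUE
    expect_gte(regulatory_score(bumped, w), s0)
  }
})

test_that("TF expression filter keeps expressed TFs and warns on missing", {
  mut <- mut_row("chr1", 104, "A", "T")
  sc_expr <- score_mutated_motifs(mut, toy_instance(), toy_pfm(),
                                  toy_bundle(tpm = 5), c(delta = 1))
  expect_equal(nrow(filter_expressed_tfs(sc_expr)), 1)

  sc_zero <- score_mutated_motifs(mut, toy_instance(), toy_pfm(),
                                  toy_bundle(tpm = 0), c(delta = 1))
  expect_equal(nrow(filter_expressed_tfs(sc_zero)), 0)

  b <- toy_bundle()
  b$tf_expr <- b$tf_expr[0, ]
  sc_na <- score_mutated_motifs(mut, toy_instance(), toy_pfm(), b, c(delta = 1))
  expect_warning(out <- filter_expressed_tfs(sc_na), "no expression")
  expect_equal(nrow(out), 0)
})

test_that("unmatched cancer types impute features across four-plus cell lines", {
  cells <- paste0("cell", 1:5)
  b <- annotation_bundle(
    peaks = tibble::tibble(cell_type = cells[1:4], tf = "TF1", chrom = "chr1",
                           start = 90L, end = 130L),
    dhs = tibble::tibble(cell_type = "cell1", chrom = "chr1",
                         start = 80L, end = 140L),
    states = tibble::tibble(cell_type = rep(cells, each = 1), chrom = "chr1",
                            start = 0L, end = 400L,
                            state = c("Enh", "Enh", "Tss", "Enh", "Quies")),
    cage = tibble::tibble(cell_type = character(), chrom = character(),
                          start = integer(), end = integer()),
    repdomains = tibble::tibble(cell_type = character(), chrom = character(),
                                start = integer(), end = integer(),
                                domain = character()),
    tf_expr = tibble::tibble(cell_type = cells[1:4], tf = "TF1",
                             tpm = c(1, 2, 3, 4)),
    cell_map = tibble::tibble(cancer_type = "Matched", cell_type = "cell1")
  )
  mut <- mut_row("chr1", 104, "A", "T", cancer = "Unmatched")
  sc <- score_mutated_motifs(mut, toy_instance(), toy_pfm(), b, c(delta = 1))
  expect_true(sc$matching_peak)        # peak in 4/5 cells, modal TRUE
  expect_false(sc$in_dhs)              # DHS known in 1 cell only: left absent
  expect_true(sc$state_Enh)            # modal label over 5 cells
  expect_equal(sc$tf_tpm, 2.5)         # mean over the 4 cells with data
})

test_that("the regulatory definition needs a large change plus peak or DHS", {
  cfg <- regmut_config()
  sc <- fake_scored(100, 110, 3, delta = 0.4, matching_peak = TRUE,
                    in_dhs = FALSE)
  expect_true(is_regulatory(sc, cfg))
  expect_true(is_regulatory(dplyr::mutate(sc, matching_peak = FALSE,
                                          in_dhs = TRUE), cfg))
  expect_false(is_regulatory(dplyr::mutate(sc, delta = 0.2), cfg))
  expect_false(is_regulatory(dplyr::mutate(sc, matching_peak = FALSE,
                                           in_dhs = FALSE), cfg))
  # boundary: strict for the observed arm, inclusive for the simulated arm
  at <- dplyr::mutate(sc, delta = 0.3)
  expect_false(is_regulatory(at, cfg, strict = TRUE))
  expect_true(is_regulatory(at, cfg, strict = FALSE))
})
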