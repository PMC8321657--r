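test_that("context96 collapses strand presentations onto pyrimidine bins", {
  expect_equal(context96("C", "T", "ACG"), "A[C>T]G")
  expect_equal(context96("G", "A", "CGT"), "A[C>T]G")  # purine: revcomp
  expect_equal(context96("A", "T", "TAG"), "C[T>A]A")
  expect_true(is.na(context96("C", "T", "NCG")))
  expect_error(context96("C", "T", "AAG"), "middle base")
})

test_that("all 192 raw presentations collapse exhaustively onto the 96 bins", {
  bases <- c("A", "C", "G", "T")
  raw <- tidyr::expand_grid(l = bases, ref = bases, r = bases, alt = bases) |>
    dplyr::filter(ref != alt)
  got <- context96(raw$ref, raw$alt, paste0(raw$l, raw$ref, raw$r))
  expect_equal(length(got), 192)
  expect_setequal(unique(got), context96_labels())
  expect_equal(as.vector(table(factor(got, context96_labels()))), rep(2, 96))
  # each pair maps with its reverse complement to the same bin
  rc <- context96(chartr("ACGT", "TGCA", raw$ref), chartr("ACGT", "TGCA", raw$alt),
                  revcomp(paste0(raw$l, raw$ref, raw$r)))
  expect_identical(rc, got)
})

test_that("profiles count SNVs into the right bins", {
  g <- tiny_genome(chr1 = "AACGTT")
  muts <- dplyr::bind_rows(purrr::map(1:10, ~ mut_row("chr1", 2, "C", "T")))
  prof <- mutation_profile96(muts, g)
  expect_equal(unname(prof["A[C>T]G"]), 10)
  expect_equal(sum(prof), 10)
  empty <- mutation_profile96(muts[0, ], g)
  expect_equal(sum(empty), 0)
  expect_error(mutation_profile96(muts[0, ], g, normalize = TRUE), "empty")
  expect_s3_class(plot_96_profile(prof), "ggplot")
})

test_that("cosine similarity matches hand values and is scale invariant", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2))
  a <- runif(96)
  b <- runif(96)
  expect_equal(cosine_similarity(a, 7.3 * b), cosine_similarity(a, b),
               tolerance = 1e-12)
  expect_error(cosine_similarity(a, numeric(96) * 0), "zero vector")
  expect_error(cosine_similarity(a, b[1:10]), "equal length")
})

test_that("DBS features use the lexicographically smaller strand presentation", {
  expect_equal(dbs_feature("AC", "GT"), min("AC>GT", "GT>AC"))
  expect_equal(dbs_feature("CC", "TT"), dbs_feature("GG", "AA"))
})

test_that("signature contribution comparison detects a planted shift", {
  set.seed(17)
  g <- tiny_genome(chr1 = strrep("ACG", 400))
  n <- 300
  mk <- function(ids) {
    dplyr::bind_rows(purrr::map(ids, function(i) {
      mut_row("chr1", 3 * (i %% 350) + 1, "C", "T",
              sample = paste0("P", i))
    }))
  }
  reg <- mk(1:n)
  oth <- mk((n + 1):(2 * n))
  contrib <- tibble::tibble(
    sample_id = c(paste0("P", 1:n), paste0("P", (n + 1):(2 * n))),
    category = "SBS", feature_type = "A[C>T]G",
    signature = "SBS1",
    contribution = c(pmin(runif(n) + 0.2, 1), runif(n)))
  res <- compare_contributions(reg, oth, contrib, g)
  expect_equal(res$signature, "SBS1")
  expect_gt(res$direction, 0)
  expect_lt(res$ks_p, 0.01)

  # identical arms: zero D, p = 1
  contrib2 <- dplyr::mutate(contrib, contribution = 0.5)
  res2 <- compare_contributions(reg, oth, contrib2, g)
  expect_equal(res2$direction, 0)
  expect_equal(res2$ks_p, 1)
})

test_that("KS p-values are calibrated under the null", {
  set.seed(23)
  ps <- vapply(1:400, function(i) {
    suppressWarnings(stats::ks.test(runif(200), runif(200))$p.value)
  }, numeric(1))
  # two-sample KS p-values are mildly discrete; check rejection-rate
  # calibration at the usual thresholds instead of exact uniformity
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.1)
})

test_that("profiles drawn from one catalog signature are called at 0.7", {
  synth <- simulate_scenario(synthetic_scenario(
    genome_length = 50000L, n_samples_per_cancer_type = c(Liver = 5L),
    background_mutation_rate = 0, rng_seed = 2L))
  catalog <- synth$catalog
  # draw 2000 mutations from signature SBS_A's 96-distribution
  set.seed(2)
  labs <- context96_labels()
  spec <- setNames(catalog[, "SBS_A"], labs)
  synth2 <- simulate_scenario(synthetic_scenario(
    genome_length = 100000L, n_samples_per_cancer_type = c(Liver = 10L),
    spectrum = spec / sum(spec), background_mutation_rate = 1e-3,
    rng_seed = 3L))
  prof <- mutation_profile96(synth2$mutations, synth2$genome)
  sim <- similarity_matrix(prof, catalog, threshold = 0.7)
  expect_gt(sim$cosine[sim$signature == "SBS_A"], 0.95)
  expect_true(sim$called[sim$signature == "SBS_A"])
  expect_equal(sim$signature[which.max(sim$cosine)], "SBS_A")
  # a profile equal to a catalog column scores exactly 1
  exact <- similarity_matrix(catalog[, "SBS_B"], catalog, threshold = 0.7)
  expect_equal(max(exact$cosine), 1)
  # sub-threshold cosine is not called
  below <- similarity_matrix(c(1, rep(0, 95)),
                             matrix(c(0.69, sqrt(1 - 0.69^2), rep(0, 94)),
                                    ncol = 1,
                                    dimnames = list(NULL, "S")), 0.7)
  expect_false(below$called)
})
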