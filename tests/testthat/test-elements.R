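test_that("element merging follows the 200-bp single-linkage rule", {
  near <- fake_scored(c(100, 250), c(110, 260), c(2, 3))
  el <- merge_elements(near, gap = 200)
  expect_equal(nrow(el), 1)
  expect_equal(el$start, 100L)
  expect_equal(el$end, 260L)
  expect_equal(el$element_score, 2.5)

  far <- fake_scored(c(100, 400), c(110, 410), c(2, 3))
  expect_equal(nrow(merge_elements(far, gap = 200)), 2)

  # chromosomes never merge across
  two_chrom <- dplyr::bind_rows(fake_scored(100, 110, 1),
                                fake_scored(120, 130, 1, chrom = "chr2"))
  expect_equal(nrow(merge_elements(two_chrom, gap = 200)), 2)
})

test_that("merging equals a brute-force single-linkage clustering oracle", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(2:60, 1)
    starts <- sort(sample.int(5000, n))
    ends <- starts + sample(5:30, n, replace = TRUE)
    gap <- sample(c(0, 50, 200), 1)
    sc <- fake_scored(starts, ends, runif(n))
    el <- merge_elements(sc, gap = gap)
    truth <- brute_single_linkage(starts, ends, gap)
    expect_equal(nrow(el), length(unique(truth)))
    # members grouped identically
    got <- integer(n)
    for (i in seq_len(nrow(el))) got[el$motif_rows[[i]]] <- i
    expect_equal(length(unique(paste(got, truth))), length(unique(truth)))
  }
})

test_that("element empirical p follows the max(k,1)/n convention", {
  el <- merge_elements(fake_scored(1000, 1010, score = 10))
  sim_el <- function(n, scores) {
    merge_elements(fake_scored(seq(2000, by = 400, length.out = n),
                               seq(2010, by = 400, length.out = n),
                               scores))
  }
  # k = 0 among 103 simulated elements -> the floor 1/103
  out <- element_empirical_p(el, sim_el(103, rep(1, 103)), window = 1e6)
  expect_equal(round(out$empirical_p, 4), 0.0097)
  # all simulated scores at least as high -> p = 1
  out2 <- element_empirical_p(el, sim_el(100, rep(20, 100)), window = 1e6)
  expect_equal(out2$empirical_p, 1)
  # k = 5 of 100 -> 0.05
  out3 <- element_empirical_p(el, sim_el(100, c(rep(20, 5), rep(1, 95))),
                              window = 1e6)
  expect_equal(out3$empirical_p, 0.05)
  # no simulated background at all -> NA with warning
  expect_warning(
    out4 <- suppressMessages(
      element_empirical_p(el, sim_el(5, rep(1, 5))[0, ], window = 1e6)),
    "no simulated background")
  expect_true(is.na(out4$empirical_p))
})

test_that("empirical p is super-uniform under the null", {
  set.seed(77)
  n_sim <- 103
  alphas <- c(0.01, 0.05, 0.1, 0.25, 0.5)
  hits <- matrix(0, 400, length(alphas))
  for (r in 1:400) {
    scores <- rnorm(n_sim + 1)
    el <- merge_elements(fake_scored(1000, 1010, score = scores[1]))
    sims <- merge_elements(fake_scored(seq(2000, by = 50, length.out = n_sim),
                                       seq(2010, by = 50, length.out = n_sim),
                                       scores[-1], set_id = 1:n_sim))
    p <- element_empirical_p(el, sims, window = 1e6)$empirical_p
    hits[r, ] <- p <= alphas
  }
  rate <- colMeans(hits)
  # P(p <= a) <= a + 1/n plus Monte Carlo slack
  expect_true(all(rate <= alphas + 1 / n_sim + 3 * sqrt(alphas / 400)))
})

test_that("the inflation factor is 1 for identical samples and behaves directionally", {
  p <- runif(500, 0.01, 1)
  expect_equal(compute_lambda(p, p), 1)
  set.seed(8)
  u1 <- runif(10000)
  u2 <- runif(10000)
  expect_lt(abs(compute_lambda(u1, u2) - 1), 0.1)
  expect_gt(compute_lambda(u1 / 50, u2), 1)
  qc <- qc_report("test", u1, u2)
  expect_s3_class(autoplot(qc), "ggplot")
})

test_that("burden test: no element mutations implies no enrichment", {
  set.seed(3)
  g <- tiny_genome(chr1 = paste(sample(c("A", "C", "G", "T"), 20000,
                                       replace = TRUE), collapse = ""))
  bg <- purrr::map(1:60, ~ mut_row("chr1", sample(c(1000:8000, 12000:19000), 1),
                                   "N", "T", sample = paste0("S", .x %% 10)))
  bg <- dplyr::bind_rows(bg)
  bg$ref <- unname(substr(g["chr1"], bg$start + 1, bg$start + 1))
  bg <- bg[bg$ref != bg$alt & bg$ref != "N", ]
  el <- tibble::tibble(chrom = "chr1", start = 9000L, end = 9200L)
  res <- burden_test(el, bg, g, window = 10000L, rate_max = 1e6)
  expect_gte(res$p, 0.5)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$n_element, 0)
})

test_that("burden test flags a strongly enriched element", {
  set.seed(4)
  g <- tiny_genome(chr1 = paste(sample(c("A", "C", "G", "T"), 20000,
                                       replace = TRUE), collapse = ""))
  pos <- c(sample(1000:19000, 50), rep(9050:9080, 1))  # pile-up inside element
  muts <- purrr::map(seq_along(pos), ~ mut_row("chr1", pos[.x], "N", "T",
                                               sample = paste0("S", .x %% 10)))
  muts <- dplyr::bind_rows(muts)
  muts$ref <- unname(substr(g["chr1"], muts$start + 1, muts$start + 1))
  muts$alt <- ifelse(muts$ref == "T", "A", "T")
  muts <- muts[muts$ref != "N", ]
  el <- tibble::tibble(chrom = "chr1", start = 9000L, end = 9100L)
  res <- burden_test(el, muts, g, window = 10000L, rate_max = 1e6)
  expect_lt(res$p, 0.01)
  expect_gt(res$estimate, 0)
})

test_that("burden test excludes hypermutated samples first", {
  set.seed(6)
  g <- tiny_genome(chr1 = paste(sample(c("A", "C", "G", "T"), 100000,
                                       replace = TRUE), collapse = ""))
  # hyper: 10 mutations on a 0.1 Mb genome = 100/Mb > 30/Mb
  hyper <- dplyr::bind_rows(purrr::map(1:10, ~ mut_row("chr1", 9000 + .x * 5,
                                                       "N", "T", sample = "HM")))
  ok <- dplyr::bind_rows(purrr::map(1:2, ~ mut_row("chr1", 5000 + .x * 100,
                                                   "N", "T", sample = paste0("S", .x))))
  muts <- dplyr::bind_rows(hyper, ok)
  muts$ref <- unname(substr(g["chr1"], muts$start + 1, muts$start + 1))
  muts$alt <- ifelse(muts$ref == "T", "A", "T")
  el <- tibble::tibble(chrom = "chr1", start = 9000L, end = 9100L)
  res <- burden_test(el, muts, g, window = 10000L, rate_max = 30)
  expect_equal(res$n_samples, 2)   # HM removed
  expect_equal(res$n_element, 0)
})

test_that("final filters honor regulatory mutations, CDS overlap and recurrence", {
  cfg <- regmut_config(min_recurrent_samples = 3L)
  scored <- dplyr::bind_rows(
    fake_scored(1000, 1010, 5, sample = "S1", regulatory = TRUE),
    fake_scored(1005, 1015, 5, sample = "S2", regulatory = FALSE),
    fake_scored(1008, 1018, 5, sample = "S3", regulatory = FALSE))
  el <- merge_elements(scored, gap = 200)
  el$empirical_p <- 0.01
  el$burden_p <- 0.001
  muts <- dplyr::bind_rows(mut_row("chr1", 1002, "C", "T", sample = "S1"),
                           mut_row("chr1", 1007, "C", "T", sample = "S2"),
                           mut_row("chr1", 1012, "C", "T", sample = "S3"))
  out <- finalize_elements(el, scored, muts, cds = NULL, config = cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_samples, 3)
  expect_gte(out$end - out$start, 200)  # extended to the element size floor

  # an element with zero regulatory mutations is dropped regardless of recurrence
  scored0 <- dplyr::mutate(scored, regulatory = FALSE)
  expect_equal(nrow(finalize_elements(el, scored0, muts, config = cfg)), 0)

  # a CDS overlap kills the element
  cds <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1100L)
  expect_equal(nrow(finalize_elements(el, scored, muts, cds = cds,
                                      config = cfg)), 0)

  # recurrence below three samples fails
  muts2 <- muts[1:2, ]
  expect_equal(nrow(finalize_elements(el, scored, muts2, config = cfg)), 0)

  # failing the empirical test is terminal
  el2 <- dplyr::mutate(el, empirical_p = 0.2)
  expect_equal(nrow(finalize_elements(el2, scored, muts, config = cfg)), 0)
})

test_that("Benjamini-Hochberg matches the textbook step-up on a fixed vector", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216,
         0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569, 0.594, 0.696)
  m <- length(p)
  stepup <- rev(cummin(rev(sort(p) * m / seq_len(m))))[order(order(p))]
  expect_equal(p.adjust(p, "BH"), pmin(stepup, 1))
})

test_that("pan-cancer merging unions loci and excludes flagged cohorts", {
  cohorts <- dplyr::bind_rows(
    cohort_spec("Liver", "Liver"),
    cohort_spec("Eso", "Eso"),
    cohort_spec("Lymph", "Lymph", is_lymphoma_group = TRUE))
  els <- tibble::tibble(
    chrom = "chr1", start = c(100L, 150L, 5000L, 100L),
    end = c(200L, 250L, 5100L, 220L),
    element_score = c(3, 4, 5, 6),
    samples = list(c("A", "B"), c("B", "C"), c("D", "E", "F"), c("L1", "L2", "L3")),
    n_samples = c(2L, 2L, 3L, 3L),
    cohort_id = c("Liver", "Eso", "Liver", "Lymph"))
  out <- merge_pan_cancer(els, cohorts, min_samples = 3L)
  expect_equal(nrow(out), 2)
  shared <- out[out$start == 100, ]
  expect_setequal(shared$samples[[1]], c("A", "B", "C"))
  expect_setequal(shared$cohort_ids[[1]], c("Liver", "Eso"))
  expect_false(any(purrr::map_lgl(out$cohort_ids, ~ "Lymph" %in% .x)))
  # disjoint elements pass through unchanged
  expect_true(any(out$start == 5000))
})
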