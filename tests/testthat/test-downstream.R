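toy_models <- function() {
  genes <- tibble::tibble(
    gene_id = c("G1", "G2"), gene_name = c("G1", "G2"), chrom = "chr1",
    start = c(1000L, 20000L), end = c(4000L, 23000L), strand = c("+", "+"),
    tss = c(1000L, 20000L), biotype = "protein_coding")
  cds <- tibble::tibble(gene_id = "G1", chrom = "chr1",
                        start = 1200L, end = 3000L)
  utr <- tibble::tibble(gene_id = c("G1", "G1"), chrom = "chr1",
                        start = c(1000L, 3700L), end = c(1200L, 4000L),
                        utr_side = c("5'UTR", "3'UTR"))
  list(genes = genes, cds = cds, utr = utr)
}

test_that("gene assignment applies overlap, promoter and nearest-flank rules", {
  gm <- toy_models()
  # extension overlaps the gene and sits within 2 kb upstream of the TSS
  prom <- assign_genes(tibble::tibble(chrom = "chr1", start = 500L, end = 700L), gm)
  expect_equal(prom$genes[[1]], "G1")
  expect_equal(prom$feature_type, "promoter")

  # inside the gene body but outside CDS/UTR -> intronic
  intr <- assign_genes(tibble::tibble(chrom = "chr1", start = 3100L, end = 3200L), gm)
  expect_equal(intr$feature_type, "intronic")
  expect_equal(intr$genes[[1]], "G1")

  # far from both genes: both flanks assigned, intergenic
  mid <- assign_genes(tibble::tibble(chrom = "chr1", start = 10000L, end = 10100L), gm)
  expect_setequal(mid$genes[[1]], c("G1", "G2"))
  expect_equal(mid$feature_type, "intergenic")

  # UTR overlap labels the element
  u <- assign_genes(tibble::tibble(chrom = "chr1", start = 3750L, end = 3800L), gm)
  expect_equal(u$feature_type, "3'UTR")

  # no gene on the chromosome
  expect_warning(
    un <- assign_genes(tibble::tibble(chrom = "chr9", start = 1L, end = 10L), gm),
    "No gene")
  expect_equal(un$feature_type, "intergenic")
  expect_length(un$genes[[1]], 0)
})

test_that("CNV exclusion requires three stars, a peak hit and locus coverage", {
  el <- tibble::tibble(chrom = "chr1", start = 5000L, end = 5200L)
  peaks <- tibble::tibble(chrom = "chr1", start = 4000L, end = 6000L)
  seg <- function(sample, stars, s = 4500L, e = 5500L) {
    tibble::tibble(sample_id = sample, chrom = "chr1", start = s, end = e,
                   call = "amp", stars = stars)
  }
  expect_equal(cnv_exclude(el, c("A", "B"), seg("A", 3), peaks), "B")
  expect_setequal(cnv_exclude(el, c("A", "B"), seg("A", 2), peaks), c("A", "B"))
  # 3-star segment outside every peak
  far_peaks <- tibble::tibble(chrom = "chr1", start = 100000L, end = 101000L)
  expect_setequal(cnv_exclude(el, c("A", "B"), seg("A", 3), far_peaks),
                  c("A", "B"))
  # segment not covering the element
  expect_setequal(cnv_exclude(el, c("A", "B"), seg("A", 3, 4000L, 5100L), peaks),
                  c("A", "B"))
})

test_that("permutation t-test handles shifts, degeneracy and matches theory", {
  set.seed(41)
  shifted <- expression_permutation_test(rnorm(10, 2), rnorm(40, 0), B = 10000)
  expect_lt(shifted$p, 0.05)
  expect_gt(shifted$t, 0)

  flat <- expression_permutation_test(rep(3, 5), rep(3, 10), B = 100)
  expect_equal(flat$p, 1)

  # converges to the classical pooled t-test p on normal data
  set.seed(42)
  x <- rnorm(15, 0.7)
  y <- rnorm(15, 0)
  perm <- expression_permutation_test(x, y, B = 100000)
  classical <- stats::t.test(x, y, var.equal = TRUE)$p.value
  expect_lt(abs(perm$p - classical), 0.01)

  expect_error(expression_permutation_test(1, rnorm(5)), "two samples")
})

test_that("paired motif-expression test detects shifts and degenerates to 1", {
  set.seed(43)
  expr <- matrix(rnorm(40, 5), nrow = 1,
                 dimnames = list("G1", paste0("S", 1:40)))
  mut <- paste0("S", 1:15)
  expr["G1", mut] <- expr["G1", mut] + 2
  res <- paired_expression_test(expr, "G1", mut)
  expect_equal(res$n_pairs, 15)
  expect_lt(res$p, 0.02)

  const <- matrix(5, nrow = 1, ncol = 20,
                  dimnames = list("G1", paste0("S", 1:20)))
  expect_equal(paired_expression_test(const, "G1", paste0("S", 1:8))$p, 1)

  expect_warning(skip <- paired_expression_test(expr, "G1", paste0("S", 1:3)),
                 "skipped")
  expect_true(is.na(skip$p))
  expect_error(paired_expression_test(expr, "G9", mut), "not in matrix")
})

test_that("methylation Fisher test builds the oriented 2x2 from CpG status", {
  # 3 CpGs inside (1 mutated), 3 outside (2 mutated), all methylated in P1
  inside <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 30L))
  outside <- tibble::tibble(chrom = "chr1", pos = c(110L, 120L, 130L))
  meth <- tibble::tibble(chrom = "chr1",
                         pos = c(10L, 20L, 30L, 110L, 120L, 130L),
                         P1 = 0.8, P2 = 0.05)
  muts <- dplyr::bind_rows(
    mut_row("chr1", 10, "C", "T", sample = "P1"),
    mut_row("chr1", 110, "C", "T", sample = "P1"),
    mut_row("chr1", 120, "C", "T", sample = "P1"),
    mut_row("chr1", 130, "C", "T", sample = "P2"))  # P2 unmethylated: no count
  res <- methylation_fisher(inside, outside, muts, meth)
  expect_equal(res$inside_mutated, 1)
  expect_equal(res$outside_mutated, 2)
  expect_equal(res$odds_ratio, (2 * 2) / (1 * 1))
  ft <- stats::fisher.test(matrix(c(1, 2, 2, 1), 2))$p.value
  expect_equal(res$fisher_p, ft)

  # OR equals the closed-form cross-ratio a=3,b=97,c=12,d=88 orientation
  expect_equal((12 * 97) / (3 * 88), 4.4091, tolerance = 1e-4)

  expect_error(methylation_fisher(inside[0, ], outside, muts, meth),
               "Insufficient")
})

test_that("active motifs separate from inactive ones by methylation level", {
  set.seed(44)
  n <- 100
  motifs <- tibble::tibble(chrom = "chr1",
                           start = seq(100L, by = 50L, length.out = 2 * n))
  motifs$end <- motifs$start + 10L
  motifs$strand <- "+"
  peaks <- tibble::tibble(cell_type = "HepG2", chrom = "chr1",
                          start = motifs$start[1:n] - 5L,
                          end = motifs$end[1:n] + 5L)
  meth <- tibble::tibble(chrom = "chr1", pos = motifs$start + 4L,
                         beta = c(rbeta(n, 1, 9), rbeta(n, 9, 1)))
  res <- active_inactive_methylation(motifs, peaks, meth, position = 5L)
  expect_equal(res$n_active, n)
  expect_lt(res$p, 0.01)
  expect_lt(res$mean_active, res$mean_inactive)

  empty_peaks <- tibble::tibble(cell_type = "K562", chrom = "chr1",
                                start = 1000000L, end = 1000100L)
  expect_error(active_inactive_methylation(motifs, empty_peaks, meth), "empty")
})

test_that("hypergeometric enrichment equals the exact tail sum", {
  universe <- paste0("g", 1:20)
  pw <- tibble::tibble(pathway = "p1", description = "d",
                       genes = list(universe[1:5]))
  cand <- c(universe[1:4], universe[10:15])  # overlap 4, draws 10
  res <- pathway_enrichment(cand, pw, universe)
  exact <- sum(vapply(4:5, function(k) {
    choose(5, k) * choose(15, 10 - k) / choose(20, 10)
  }, numeric(1)))
  expect_equal(res$p, exact)

  # overlap 0 with a small draw: p near 1
  res0 <- pathway_enrichment(universe[6:8], pw, universe)
  expect_gt(res0$p, 0.5)

  # pathway == candidates == universe: the certain event
  res1 <- pathway_enrichment(universe, tibble::tibble(
    pathway = "all", description = "d", genes = list(universe)), universe)
  expect_equal(res1$p, 1)

  expect_error(pathway_enrichment(c("nope"), pw, universe), "outside")
})

test_that("hypergeometric p matches brute-force enumeration on small universes", {
  set.seed(45)
  for (i in 1:10) {
    N <- sample(8:25, 1)
    universe <- paste0("g", seq_len(N))
    K <- sample(2:(N - 2), 1)
    nd <- sample(2:(N - 2), 1)
    pw <- tibble::tibble(pathway = "p", description = "d",
                         genes = list(sample(universe, K)))
    cand <- sample(universe, nd)
    k_obs <- length(intersect(cand, pw$genes[[1]]))
    # enumerate all draws of size nd by their overlap distribution
    p_brute <- sum(vapply(k_obs:min(K, nd), function(k) {
      choose(K, k) * choose(N - K, nd - k) / choose(N, nd)
    }, numeric(1)))
    expect_equal(pathway_enrichment(cand, pw, universe)$p, p_brute,
                 tolerance = 1e-12)
  }
})
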