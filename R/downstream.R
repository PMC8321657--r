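#' Assign mutated elements to genes and feature types
#'
#' Each element is extended by `window` bp; genes overlapping the extension
#' are assigned.  When none overlaps, the nearest upstream and nearest
#' downstream genes on the chromosome are both assigned.  The feature type is
#' promoter (within `window` bp upstream of a TSS, strand-aware), 5'/3' UTR
#' (overlapping a UTR), intronic (overlapping a gene's noncoding body) or
#' intergenic; when several apply, the type containing the most element
#' mutations wins (ties broken promoter > 5'UTR > 3'UTR > intronic).
#'
#' @param elements element tibble (`chrom`, `start`, `end`).
#' @param gene_models list from [read_gene_models()].
#' @param mutations optional mutation tibble used for conflict resolution.
#' @param window extension/promoter window in bp (default 2000).
#' @return `elements` with list-column `genes` and column `feature_type`.
#' @export
assign_genes <- function(elements, gene_models, mutations = NULL,
                         window = 2000L) {
  genes <- gene_models$genes
  utr <- gene_models$utr %||% tibble(gene_id = character(), chrom = character(),
                                     start = integer(), end = integer(),
                                     utr_side = character())
  cds <- gene_models$cds %||% tibble(chrom = character(), start = integer(),
                                     end = integer())
  promoters <- tibble(
    chrom = genes$chrom,
    start = as.integer(ifelse(genes$strand == "-", genes$tss + 1L,
                              pmax(genes$tss - window, 0L))),
    end = as.integer(ifelse(genes$strand == "-", genes$tss + window + 1L,
                            genes$tss))
  )
  out <- as_tibble(elements)
  out$genes <- vector("list", nrow(out))
  out$feature_type <- NA_character_

  for (i in seq_len(nrow(out))) {
    el <- out[i, ]
    gch <- genes[genes$chrom == el$chrom, ]
    if (nrow(gch) == 0) {
      warn(sprintf("No gene on %s; element %d:%d unassigned",
                   el$chrom, el$start, el$end))
      out$genes[[i]] <- character(0)
      out$feature_type[i] <- "intergenic"
      next
    }
    ext_start <- max(el$start - window, 0L)
    ext_end <- el$end + window
    hit <- gch$start < ext_end & gch$end > ext_start
    assigned <- if (any(hit)) {
      gch$gene_name[hit]
    } else {
      up <- gch[gch$end <= el$start, ]
      down <- gch[gch$start >= el$end, ]
      c(if (nrow(up) > 0) up$gene_name[which.max(up$end)],
        if (nrow(down) > 0) down$gene_name[which.min(down$start)])
    }
    out$genes[[i]] <- unique(assigned)
    out$feature_type[i] <- element_feature_type(el, genes, promoters, utr, cds,
                                                mutations)
  }
  out
}

element_feature_type <- function(el, genes, promoters, utr, cds, mutations) {
  el_iv <- el[, c("chrom", "start", "end")]
  regions <- list(
    promoter = promoters,
    `5'UTR` = utr[utr$utr_side == "5'UTR", c("chrom", "start", "end")],
    `3'UTR` = utr[utr$utr_side == "3'UTR", c("chrom", "start", "end")],
    intronic = noncoding_gene_body(genes, cds, utr)
  )
  applies <- names(regions)[vapply(regions, function(r) {
    isTRUE(overlap_any(el_iv, r))
  }, logical(1))]
  if (length(applies) == 0) return("intergenic")
  if (length(applies) == 1 || is.null(mutations)) return(applies[1])
  el_muts <- mutations[mutations$chrom == el$chrom &
                         mutations$start >= el$start &
                         mutations$start < el$end, ]
  if (nrow(el_muts) == 0) return(applies[1])
  counts <- vapply(applies, function(ft) {
    sum(overlap_any(el_muts, regions[[ft]]))
  }, numeric(1))
  applies[which.max(counts)]
}

# gene bodies minus coding sequence and UTRs (the "noncoding gene region")
noncoding_gene_body <- function(genes, cds, utr) {
  if (nrow(genes) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  body <- as_granges(genes)
  excl_list <- list()
  if (nrow(cds) > 0) excl_list <- c(excl_list, list(as_granges(cds)))
  if (nrow(utr) > 0) excl_list <- c(excl_list, list(as_granges(utr)))
  if (length(excl_list) > 0) {
    body <- GenomicRanges::setdiff(body, do.call(c, excl_list))
  }
  tibble(chrom = as.character(GenomicRanges::seqnames(body)),
         start = GenomicRanges::start(body) - 1L,
         end = GenomicRanges::end(body))
}

#' Exclude samples whose element mutations sit in confident CNVs
#'
#' A mutated sample is removed when it carries a 3-star (highest-confidence)
#' CNV segment that both intersects a GISTIC amplification/deletion peak and
#' contains the element locus.
#'
#' @param element one-row element tibble.
#' @param samples character vector of mutated samples at the element.
#' @param cnv_segments tibble from [read_cnv_segments()].
#' @param gistic_peaks tibble `chrom`, `start`, `end`.
#' @return Retained sample vector.
#' @export
cnv_exclude <- function(element, samples, cnv_segments, gistic_peaks) {
  seg <- cnv_segments[cnv_segments$stars == 3 &
                        cnv_segments$sample_id %in% samples, ]
  if (nrow(seg) == 0) return(samples)
  in_peak <- overlap_any(seg, gistic_peaks)
  covers <- seg$chrom == element$chrom & seg$start <= element$start &
    seg$end >= element$end
  drop <- unique(seg$sample_id[in_peak & covers])
  setdiff(samples, drop)
}

pooled_t_stat <- function(s1, ss1, n1, s2, ss2, n2) {
  m1 <- s1 / n1
  m2 <- s2 / n2
  v1 <- (ss1 - n1 * m1^2) / (n1 - 1)
  v2 <- (ss2 - n2 * m2^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  ifelse(se > 0, (m1 - m2) / se, 0)
}

#' Permutation t-test of expression between mutated and non-mutated samples
#'
#' Computes the pooled-variance two-sample t statistic and evaluates it
#' against `B` random relabelings of the samples.  The two-sided empirical
#' p-value uses the add-one convention `(k + 1)/(B + 1)`.  Degenerate input
#' (zero pooled variance) returns p = 1.
#'
#' @param expr_mut expression values of mutated samples (>= 2).
#' @param expr_non expression values of non-mutated samples (>= 2).
#' @param B number of permutations (default 100000).
#' @return One-row tibble `t`, `p`, `n_mut`, `n_non`.
#' @export
expression_permutation_test <- function(expr_mut, expr_non, B = 100000L) {
  n1 <- length(expr_mut)
  n2 <- length(expr_non)
  if (n1 < 2 || n2 < 2) abort("Need at least two samples per group")
  x <- c(expr_mut, expr_non)
  n <- n1 + n2
  if (stats::var(x) == 0) {
    return(tibble(t = 0, p = 1, n_mut = n1, n_non = n2))
  }
  t_obs <- pooled_t_stat(sum(expr_mut), sum(expr_mut^2), n1,
                         sum(expr_non), sum(expr_non^2), n2)
  # indicator matrix of group-1 membership for each permutation
  M <- vapply(seq_len(B), function(b) {
    v <- numeric(n)
    v[sample.int(n, n1)] <- 1
    v
  }, numeric(n))
  s1 <- drop(x %*% M)
  ss1 <- drop((x^2) %*% M)
  tot <- sum(x)
  tot2 <- sum(x^2)
  t_perm <- pooled_t_stat(s1, ss1, n1, tot - s1, tot2 - ss1, n2)
  p <- (sum(abs(t_perm) >= abs(t_obs)) + 1) / (B + 1)
  tibble(t = t_obs, p = p, n_mut = n1, n_non = n2)
}

#' Paired Wilcoxon test of expression at mutated motif loci
#'
#' For each mutated sample with expression data, a random non-mutated sample
#' is drawn as its pair, and the target gene's expression differences are
#' tested with a signed-rank test.  Fewer than `min_pairs` pairs skips the
#' test (returns `NA` with a warning); all-zero differences give p = 1.
#'
#' @param expr expression matrix (genes x samples).
#' @param gene_id target gene (row of `expr`).
#' @param mutated_samples samples mutated at the motif locus.
#' @param min_pairs minimum pairs (default 5).
#' @return One-row tibble `gene_id`, `n_pairs`, `p`.
#' @export
paired_expression_test <- function(expr, gene_id, mutated_samples,
                                   min_pairs = 5L) {
  if (!gene_id %in% rownames(expr)) abort(paste0("Gene not in matrix: ", gene_id))
  mut <- intersect(mutated_samples, colnames(expr))
  non <- setdiff(colnames(expr), mutated_samples)
  n_pairs <- length(mut)
  if (n_pairs < min_pairs || length(non) < n_pairs) {
    warn(sprintf("Only %d pair(s) for %s; test skipped", n_pairs, gene_id))
    return(tibble(gene_id = gene_id, n_pairs = n_pairs, p = NA_real_))
  }
  ctrl <- sample(non, n_pairs)
  d <- expr[gene_id, mut] - expr[gene_id, ctrl]
  if (all(d == 0)) {
    return(tibble(gene_id = gene_id, n_pairs = n_pairs, p = 1))
  }
  p <- suppressWarnings(wilcox.test(expr[gene_id, mut], expr[gene_id, ctrl],
                                    paired = TRUE)$p.value)
  tibble(gene_id = gene_id, n_pairs = n_pairs, p = p)
}

#' Fisher test of mutation rates at methylated CpGs inside vs outside motifs
#'
#' A CpG enters the test when methylated (beta > `beta_min`) in at least one
#' patient; it counts as mutated when a C>T mutation at its position occurs
#' in a patient in whom it is methylated.  The odds ratio is oriented so that
#' OR > 1 means the outside CpGs are more mutated; the caller supplies
#' motif-annotated mutations for the inside arm.
#'
#' @param cpg_inside,cpg_outside tibbles `chrom`, `pos` (0-based cytosine).
#' @param mutations mutation tibble (C>T records are considered).
#' @param methylation tibble from [read_methylation()]: `chrom`, `pos`, one
#'   beta column per patient; patient names must match `sample_id`s.
#' @param beta_min methylated-CpG threshold (default 0.2).
#' @return One-row tibble with the 2x2 counts, `odds_ratio` and `fisher_p`.
#' @export
methylation_fisher <- function(cpg_inside, cpg_outside, mutations,
                               methylation, beta_min = 0.2) {
  status <- function(cpgs) {
    if (nrow(cpgs) == 0) return(logical(0))
    vapply(seq_len(nrow(cpgs)), function(i) {
      row <- methylation[methylation$chrom == cpgs$chrom[i] &
                           methylation$pos == cpgs$pos[i], ]
      if (nrow(row) == 0) return(NA)
      betas <- unlist(row[1, setdiff(names(row), c("chrom", "pos"))])
      meth_patients <- names(betas)[!is.na(betas) & betas > beta_min]
      if (length(meth_patients) == 0) return(NA)  # never methylated: excluded
      any(mutations$chrom == cpgs$chrom[i] &
            mutations$start == cpgs$pos[i] &
            mutations$ref == "C" & mutations$alt == "T" &
            mutations$sample_id %in% meth_patients)
    }, logical(1))
  }
  s_in <- status(cpg_inside)
  s_out <- status(cpg_outside)
  s_in <- s_in[!is.na(s_in)]
  s_out <- s_out[!is.na(s_out)]
  if (length(s_in) == 0 || length(s_out) == 0) {
    abort("Insufficient data: an arm has no methylated CpG")
  }
  a <- sum(s_in); b <- length(s_in) - a     # inside: mutated / not
  c_ <- sum(s_out); d <- length(s_out) - c_ # outside: mutated / not
  or <- (c_ * b) / (a * d)                  # >1: outside more mutated
  p <- fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE))$p.value
  tibble(inside_mutated = a, inside_unmutated = b,
         outside_mutated = c_, outside_unmutated = d,
         odds_ratio = or, fisher_p = p)
}

#' Methylation of active versus inactive motifs
#'
#' Active motifs overlap a ChIP peak of the motif's TF in the cell line;
#' inactive motifs do not.  Per cell line, a two-sided Mann-Whitney test
#' compares methylation levels at the designated motif position.
#'
#' @param motifs motif-instance tibble (`chrom`, `start`, `end`, `strand`).
#' @param peaks tibble `cell_type`, `chrom`, `start`, `end`.
#' @param methylation tibble `chrom`, `pos` plus beta column(s); per-position
#'   level is the mean over beta columns.
#' @param position 1-based motif position carrying the CpG (default 5).
#' @return Tibble per cell line: `cell_type`, `n_active`, `n_inactive`,
#'   `mean_active`, `mean_inactive`, `p`.
#' @export
active_inactive_methylation <- function(motifs, peaks, methylation,
                                        position = 5L) {
  L <- motifs$end - motifs$start
  cpg_pos <- ifelse(motifs$strand == "-", motifs$end - position,
                    motifs$start + position - 1L)
  beta_cols <- setdiff(names(methylation), c("chrom", "pos"))
  level <- rowMeans(methylation[, beta_cols, drop = FALSE], na.rm = TRUE)
  beta_at <- vapply(seq_len(nrow(motifs)), function(i) {
    j <- which(methylation$chrom == motifs$chrom[i] &
                 methylation$pos == cpg_pos[i])
    if (length(j) == 0) NA_real_ else level[j[1]]
  }, numeric(1))
  purrr::map(unique(peaks$cell_type), function(ct) {
    active <- overlap_any(motifs, peaks[peaks$cell_type == ct, ])
    b_act <- beta_at[active & !is.na(beta_at)]
    b_ina <- beta_at[!active & !is.na(beta_at)]
    if (length(b_act) == 0 || length(b_ina) == 0) {
      abort(sprintf("Cell line %s: empty active or inactive class", ct))
    }
    p <- suppressWarnings(wilcox.test(b_act, b_ina)$p.value)
    tibble(cell_type = ct, n_active = length(b_act),
           n_inactive = length(b_ina), mean_active = mean(b_act),
           mean_inactive = mean(b_ina), p = p)
  }) |> purrr::list_rbind()
}

#' Hypergeometric pathway enrichment
#'
#' Upper-tail hypergeometric test of candidate-gene overlap per pathway
#' (population = universe, successes = pathway genes in the universe, draws =
#' candidates), with Benjamini-Hochberg adjustment across pathways.
#'
#' @param candidates character vector of candidate genes (subset of the
#'   universe).
#' @param pathways tibble from [read_gmt()].
#' @param universe gene universe; defaults to the union of all pathway genes.
#' @return Tibble `pathway`, `overlap`, `pathway_size`, `universe_size`,
#'   `p`, `fdr`, ordered by p.
#' @export
pathway_enrichment <- function(candidates, pathways, universe = NULL) {
  if (is.null(universe)) universe <- unique(unlist(pathways$genes))
  candidates <- unique(candidates)
  extra <- setdiff(candidates, universe)
  if (length(extra) > 0) {
    abort(paste0("Candidate gene(s) outside the universe: ",
                 paste(head(extra, 5), collapse = ", ")))
  }
  N <- length(universe)
  n_draw <- length(candidates)
  out <- purrr::map(seq_len(nrow(pathways)), function(i) {
    pw <- intersect(pathways$genes[[i]], universe)
    K <- length(pw)
    k <- length(intersect(pw, candidates))
    p <- phyper(k - 1, K, N - K, n_draw, lower.tail = FALSE)
    tibble(pathway = pathways$pathway[i], overlap = k, pathway_size = K,
           universe_size = N, p = p)
  }) |> purrr::list_rbind()
  out$fdr <- p.adjust(out$p, method = "BH")
  dplyr::arrange(out, .data$p)
}
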