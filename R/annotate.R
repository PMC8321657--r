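CHROMATIN_STATES <- c("Tss", "Enh", "Tx", "Repr", "Quies")
REPLICATION_DOMAINS <- c("early", "late")

as_granges <- function(tab) {
  GenomicRanges::GRanges(tab$chrom,
                         IRanges::IRanges(tab$start + 1L, pmax(tab$end, tab$start + 1L)))
}

# index pairs (a, b) of overlapping intervals between two 0-based half-open tables
overlap_pairs <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(tibble(a = integer(), b = integer()))
  h <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b))
  tibble(a = S4Vectors::queryHits(h), b = S4Vectors::subjectHits(h))
}

overlap_any <- function(a, b) {
  if (nrow(a) == 0) return(logical(0))
  if (is.null(b) || nrow(b) == 0) return(rep(FALSE, nrow(a)))
  GenomicRanges::countOverlaps(as_granges(a), as_granges(b)) > 0
}

#' Assemble a cell-type-resolved annotation bundle
#'
#' Holds every functional track used to build mutated-motif feature vectors,
#' each resolved per cell type, plus the cancer-type to cell-type matching.
#'
#' @param peaks TF ChIP peaks: tibble `cell_type`, `tf`, `chrom`, `start`, `end`.
#' @param dhs DNaseI hypersensitive sites: `cell_type`, `chrom`, `start`, `end`.
#' @param states chromatin states: `cell_type`, `chrom`, `start`, `end`,
#'   `state` (labels in Tss/Enh/Tx/Repr/Quies).
#' @param cage CAGE peaks: `cell_type`, `chrom`, `start`, `end`.
#' @param repdomains replication domains: `cell_type`, `chrom`, `start`,
#'   `end`, `domain` (early/late).
#' @param tf_expr TF expression: `cell_type`, `tf`, `tpm`.
#' @param cell_map cancer-type matching: `cancer_type`, `cell_type`.
#' @return List of class `annotation_bundle`.
#' @export
annotation_bundle <- function(peaks, dhs, states, cage, repdomains,
                              tf_expr, cell_map) {
  bad_states <- setdiff(unique(states$state), CHROMATIN_STATES)
  if (length(bad_states) > 0) {
    abort(paste0("Unknown chromatin state label(s): ",
                 paste(bad_states, collapse = ", ")))
  }
  structure(list(peaks = as_tibble(peaks), dhs = as_tibble(dhs),
                 states = as_tibble(states), cage = as_tibble(cage),
                 repdomains = as_tibble(repdomains),
                 tf_expr = as_tibble(tf_expr), cell_map = as_tibble(cell_map)),
            class = "annotation_bundle")
}

#' Cell types matched to a cancer type
#' @param bundle [annotation_bundle()].
#' @param cancer_type cancer-type label.
#' @return Character vector of matched cell types (may be empty: unmatched).
#' @export
matched_cell_types <- function(bundle, cancer_type) {
  bundle$cell_map$cell_type[bundle$cell_map$cancer_type == cancer_type]
}

all_cell_types <- function(bundle) {
  unique(c(bundle$cell_map$cell_type, bundle$peaks$cell_type,
           bundle$dhs$cell_type, bundle$states$cell_type,
           bundle$tf_expr$cell_type))
}

# modal label with deterministic (alphabetical) tie-break
modal_label <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_character_)
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1]
}

# binary feature per query interval, matched cells; imputation across all
# cells (>= min_cells non-missing, modal label) when `cells` is empty
binary_feature <- function(query, track, cells, all_cells, min_cells = 4L) {
  if (length(cells) > 0) {
    return(overlap_any(query, track[track$cell_type %in% cells, ]))
  }
  per_cell <- vapply(all_cells, function(ct) {
    overlap_any(query, track[track$cell_type == ct, ])
  }, logical(nrow(query)))
  if (nrow(query) == 1) per_cell <- matrix(per_cell, nrow = 1)
  apply(per_cell, 1, function(v) {
    lab <- impute_feature(as.character(v), min_cells = min_cells)
    !is.na(lab) && lab == "TRUE"
  })
}

label_at <- function(points, track, label_col, cells, all_cells, min_cells = 4L) {
  pick <- function(ct_track) {
    ov <- overlap_pairs(points, ct_track)
    out <- rep(NA_character_, nrow(points))
    if (nrow(ov) > 0) {
      first <- ov[!duplicated(ov$a), ]
      out[first$a] <- ct_track[[label_col]][first$b]
    }
    out
  }
  if (length(cells) > 0) {
    labs <- vapply(cells, function(ct) pick(track[track$cell_type == ct, ]),
                   character(nrow(points)))
    if (nrow(points) == 1) labs <- matrix(labs, nrow = 1)
    return(apply(labs, 1, modal_label))
  }
  labs <- vapply(all_cells, function(ct) pick(track[track$cell_type == ct, ]),
                 character(nrow(points)))
  if (nrow(points) == 1) labs <- matrix(labs, nrow = 1)
  apply(labs, 1, function(v) impute_feature(v, min_cells = min_cells))
}

#' Score mutations overlapping motif instances
#'
#' Joins mutations to motif instances (a pair exists when at least one
#' mutated base falls inside the motif), computes the motif matching-score
#' change, builds the cell-type-matched annotation feature vector and the
#' weighted regulatory score.  For cancer types with no matched cell type,
#' features are imputed across the other cell types when at least four carry
#' the annotation.
#'
#' @param mutations mutation tibble.
#' @param instances motif-instance tibble from [scan_motifs()] (after
#'   [zscore_filter()]).
#' @param pfms named list of PFMs covering every TF in `instances`.
#' @param bundle [annotation_bundle()].
#' @param weights [fit_annotation_weights()] result or named numeric vector
#'   (positive weights; the motif-score change enters as feature `delta`).
#' @param background,pseudocount passed to [pfm_to_ppm()].
#' @return Tibble with one row per (mutation, motif) pair: mutation columns,
#'   `tf`, `motif_start`, `motif_end`, `strand`, `motif_position` (1-based,
#'   5' end of the motif strand), `delta`, the binary features
#'   (`matching_peak`, `in_dhs`, `state_*`, `in_cage`, `repdomain_*`,
#'   `tf_expressed`), `tf_tpm` and `regulatory_score`.
#' @export
score_mutated_motifs <- function(mutations, instances, pfms, bundle, weights,
                                 background = rep(0.25, 4), pseudocount = 0.8) {
  ov <- overlap_pairs(mutations, instances)
  empty <- scored_motif_prototype()
  if (nrow(ov) == 0) return(empty)

  mut <- as_tibble(mutations)[ov$a, ]
  ins <- as_tibble(instances)[ov$b, ]
  sc <- dplyr::bind_cols(
    mut,
    tibble(tf = ins$tf, motif_start = ins$start, motif_end = ins$end,
           strand = ins$strand, motif_score = ins$score)
  )
  L <- ins$end - ins$start
  first_base <- pmax(sc$start, sc$motif_start)  # first mutated base in motif
  offset_plus <- first_base - sc$motif_start + 1L
  sc$motif_position <- ifelse(sc$strand == "-", L + 1L - offset_plus, offset_plus)

  ppms <- lapply(pfms, pfm_to_ppm, background = background,
                 pseudocount = pseudocount)
  sc$delta <- vapply(seq_len(nrow(sc)), function(i) {
    mutation_delta(sc[i, ], ppms[[sc$tf[i]]], offset_plus[i])
  }, numeric(1))

  sc <- add_annotation_features(sc, bundle)
  sc$regulatory_score <- regulatory_score(sc, weights)
  sc
}

scored_motif_prototype <- function() {
  feat <- c("matching_peak", "in_dhs", paste0("state_", CHROMATIN_STATES),
            "in_cage", paste0("repdomain_", REPLICATION_DOMAINS), "tf_expressed")
  out <- tibble(chrom = character(), start = integer(), end = integer(),
                ref = character(), alt = character(), mut_class = character(),
                sample_id = character(), cancer_type = character(),
                tf = character(), motif_start = integer(), motif_end = integer(),
                strand = character(), motif_score = numeric(),
                motif_position = integer(), delta = numeric())
  for (f in feat) out[[f]] <- logical()
  out$tf_tpm <- numeric()
  out$regulatory_score <- numeric()
  out
}

# score change for one (mutation, motif) pair; SNVs use the PPM column
# difference, longer same-length substitutions the max per-base difference
# over overlapped positions, indels the maximal disruption 1.0 (convention)
mutation_delta <- function(row, ppm, offset_plus) {
  if (row$mut_class == "SNV") {
    return(motif_score_change(ppm, offset_plus, row$ref, row$alt, row$strand))
  }
  if (row$mut_class %in% c("DNP", "TNP", "ONP")) {
    L <- nrow(ppm)
    deltas <- vapply(seq_len(nchar(row$ref)), function(k) {
      pos <- row$start + k - 1L
      off <- pos - row$motif_start + 1L
      if (off < 1 || off > L) return(NA_real_)
      r <- substr(row$ref, k, k)
      a <- substr(row$alt, k, k)
      if (r == a) return(NA_real_)
      motif_score_change(ppm, off, r, a, row$strand)
    }, numeric(1))
    deltas <- deltas[!is.na(deltas)]
    return(if (length(deltas) > 0) max(deltas) else 0)
  }
  1.0  # indel overlapping a motif: maximal disruption
}

add_annotation_features <- function(sc, bundle) {
  all_cells <- all_cell_types(bundle)
  motif_iv <- tibble(chrom = sc$chrom, start = sc$motif_start, end = sc$motif_end)
  point_iv <- tibble(chrom = sc$chrom, start = sc$start,
                     end = pmax(sc$start + 1L, sc$end))

  for (f in c("matching_peak", "in_dhs", "in_cage", "tf_expressed")) sc[[f]] <- FALSE
  for (s in CHROMATIN_STATES) sc[[paste0("state_", s)]] <- FALSE
  for (d in REPLICATION_DOMAINS) sc[[paste0("repdomain_", d)]] <- FALSE
  sc$tf_tpm <- NA_real_

  for (ct in unique(sc$cancer_type)) {
    rows <- which(sc$cancer_type == ct)
    cells <- matched_cell_types(bundle, ct)
    miv <- motif_iv[rows, ]
    piv <- point_iv[rows, ]
    # matching TF peak: the instance overlaps a same-TF peak in a matched cell
    for (tf in unique(sc$tf[rows])) {
      trows <- rows[sc$tf[rows] == tf]
      peaks_tf <- bundle$peaks[bundle$peaks$tf == tf, ]
      sc$matching_peak[trows] <- binary_feature(motif_iv[trows, ], peaks_tf,
                                                cells, all_cells)
      expr <- bundle$tf_expr[bundle$tf_expr$tf == tf, ]
      tpm <- if (length(cells) > 0) {
        vals <- expr$tpm[expr$cell_type %in% cells]
        if (length(vals) > 0) max(vals) else NA_real_
      } else {
        impute_feature(expr$tpm[match(all_cells, expr$cell_type)])
      }
      sc$tf_tpm[trows] <- tpm
      sc$tf_expressed[trows] <- !is.na(tpm) & tpm > 0
    }
    sc$in_dhs[rows] <- binary_feature(miv, bundle$dhs, cells, all_cells)
    sc$in_cage[rows] <- binary_feature(miv, bundle$cage, cells, all_cells)
    st <- label_at(piv, bundle$states, "state", cells, all_cells)
    for (s in CHROMATIN_STATES) {
      sc[[paste0("state_", s)]][rows] <- !is.na(st) & st == s
    }
    dom <- label_at(piv, bundle$repdomains, "domain", cells, all_cells)
    for (d in REPLICATION_DOMAINS) {
      sc[[paste0("repdomain_", d)]][rows] <- !is.na(dom) & dom == d
    }
  }
  sc
}

#' Weighted regulatory score of scored motifs
#'
#' Non-negative weighted sum of the binary annotation features plus the
#' motif-score change `delta` as one weighted feature.  Features absent from
#' the weight vector contribute nothing.
#'
#' @param scored tibble from [score_mutated_motifs()] (feature columns).
#' @param weights named non-negative numeric vector (e.g. from
#'   [fit_annotation_weights()]).
#' @return Numeric vector of scores, one per row.
#' @export
regulatory_score <- function(scored, weights) {
  w <- unclass(weights)
  score <- numeric(nrow(scored))
  for (f in names(w)) {
    if (!f %in% names(scored)) next
    x <- as.numeric(scored[[f]])
    x[is.na(x)] <- 0
    score <- score + w[[f]] * x
  }
  score
}

#' Drop mutated motifs of TFs not expressed in matched cell types
#'
#' @param scored tibble from [score_mutated_motifs()].
#' @param tpm_min expression threshold (strict, default 0).
#' @return Filtered tibble; TFs with no expression record are dropped with a
#'   warning.
#' @export
filter_expressed_tfs <- function(scored, tpm_min = 0) {
  missing <- unique(scored$tf[is.na(scored$tf_tpm)])
  if (length(missing) > 0) {
    warn(paste0("TF(s) with no expression record treated as not expressed: ",
                paste(missing, collapse = ", ")))
  }
  scored[!is.na(scored$tf_tpm) & scored$tf_tpm > tpm_min, ]
}

#' Classify scored mutations as regulatory
#'
#' A mutation is regulatory when it changes the motif matching score by more
#' than `score_change_min` (0.3 by default, contrasting the uniform 0.25
#' background) and overlaps a matching TF peak or DHS from the matched
#' tissue.  Inclusive-threshold mode (`strict = FALSE`) is used for the
#' simulated arm of the TF burden test.
#'
#' @param scored tibble from [score_mutated_motifs()].
#' @param config [regmut_config()].
#' @param strict strict (`>`, observed arm) or inclusive (`>=`, simulated
#'   arm) comparison against `score_change_min`.
#' @return Logical vector.
#' @export
is_regulatory <- function(scored, config = regmut_config(), strict = TRUE) {
  passes <- if (strict) scored$delta > config$score_change_min
            else scored$delta >= config$score_change_min
  passes & (scored$matching_peak | scored$in_dhs)
}
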