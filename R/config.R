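#' Pipeline configuration
#'
#' Builds the run configuration with every tunable threshold of the pipeline.
#' Defaults are the values used throughout the analysis: motifs are retained at
#' scan p < 1e-4 and a per-TF Z-score > 1; simulated mutations are placed
#' within a 50 kb window but at least 50 bp from their source; 103 simulated
#' sets give the empirical p-value floor of 1/103; mutated motifs within
#' 200 bp merge into elements which, when significant, are extended to 200 bp;
#' a motif-matching-score change above 0.3 (contrasting the uniform 0.25
#' per-nucleotide background) plus a matching peak/DHS defines a regulatory
#' mutation; recurrent elements need at least three mutated samples.
#'
#' @param ... named overrides of any default listed below.
#'
#' @return A named list of class `regmut_config`:
#' \describe{
#'   \item{motif_scan_p_threshold}{scan p-value cutoff (1e-4)}
#'   \item{motif_zscore_min}{per-TF instance Z-score cutoff (1)}
#'   \item{shuffle_window}{max distance, bp, for simulated positions (50000)}
#'   \item{shuffle_min_dist}{min distance, bp, from the source (50)}
#'   \item{n_sim_sets}{number of simulated mutation sets (103)}
#'   \item{merge_gap}{max gap, bp, merging mutated motifs into elements (200)}
#'   \item{element_extension}{final element size floor, bp (200)}
#'   \item{element_p_max}{empirical p cutoff for elements (0.05)}
#'   \item{burden_fdr_max}{burden-test FDR cutoff (0.05)}
#'   \item{score_change_min}{motif matching-score change cutoff (0.3)}
#'   \item{background_nt_freq}{uniform per-nucleotide background (0.25)}
#'   \item{min_recurrent_samples}{min distinct mutated samples (3)}
#'   \item{hypermut_sample_max}{per-sample mutation cap; samples strictly above
#'     are removed (100000)}
#'   \item{burden_hypermut_rate_max}{mutations/Mb cap inside the burden test (30)}
#'   \item{gene_window}{element-to-gene window, bp (2000)}
#'   \item{meth_beta_min}{methylated-CpG beta cutoff (0.2)}
#'   \item{cosine_sim_threshold}{signature-call cosine cutoff (0.7)}
#'   \item{n_expr_permutations}{expression-test permutations (100000)}
#'   \item{rng_seed}{base seed for every stochastic step (1)}
#' }
#' @examples
#' cfg <- regmut_config(n_sim_sets = 20)
#' cfg$background_nt_freq
#' @export
regmut_config <- function(...) {
  cfg <- list(
    motif_scan_p_threshold = 1e-4,
    motif_zscore_min = 1,
    shuffle_window = 50000L,
    shuffle_min_dist = 50L,
    n_sim_sets = 103L,
    merge_gap = 200L,
    element_extension = 200L,
    element_p_max = 0.05,
    burden_fdr_max = 0.05,
    score_change_min = 0.3,
    background_nt_freq = 1 / length(DNA_BASES),
    min_recurrent_samples = 3L,
    hypermut_sample_max = 100000L,
    burden_hypermut_rate_max = 30,
    gene_window = 2000L,
    meth_beta_min = 0.2,
    cosine_sim_threshold = 0.7,
    n_expr_permutations = 100000L,
    rng_seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0) {
    abort(paste0("Unknown config field(s): ", paste(bad, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "regmut_config")
}

validate_config <- function(cfg) {
  probs <- c("motif_scan_p_threshold", "element_p_max", "burden_fdr_max",
             "score_change_min", "background_nt_freq", "meth_beta_min")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      abort(paste0(p, " must lie in [0, 1], got ", cfg[[p]]))
    }
  }
  counts <- c("shuffle_window", "shuffle_min_dist", "n_sim_sets", "merge_gap",
              "element_extension", "min_recurrent_samples",
              "hypermut_sample_max", "gene_window", "n_expr_permutations")
  for (p in counts) {
    if (cfg[[p]] < 1 || cfg[[p]] != round(cfg[[p]])) {
      abort(paste0(p, " must be a positive integer, got ", cfg[[p]]))
    }
  }
  invisible(cfg)
}

#' Read a configuration from YAML
#'
#' Unspecified fields keep their [regmut_config()] defaults; unknown fields
#' are an error.
#'
#' @param path YAML file with a flat mapping of config fields.
#' @return A `regmut_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(regmut_config, vals)
}

#' @export
print.regmut_config <- function(x, ...) {
  cat("<regmut_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
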