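#' Default annotation weights
#'
#' Positive log-odds-scale weights applied when no training data for
#' [fit_annotation_weights()] is supplied.  Matching TF peaks and DHSs carry
#' the largest weights (they are the strongest predictors of functional
#' motifs), promoter/enhancer states and CAGE contribute moderately, and the
#' motif-score change enters as the weighted feature `delta`.
#'
#' @return Named numeric vector of class `annotation_weights`.
#' @export
default_annotation_weights <- function() {
  w <- c(matching_peak = 2.0, in_dhs = 1.5, state_Tss = 0.5, state_Enh = 0.5,
         in_cage = 0.25, repdomain_early = 0.1, tf_expressed = 0.25,
         delta = 1.0)
  structure(w, class = "annotation_weights", all_coefficients = w,
            separated = FALSE)
}

#' Run the per-cohort analysis end to end
#'
#' Executes preparation (hypermutation filter, MNV collapsing), simulated-set
#' generation, motif scanning, annotation scoring, element calling with the
#' local empirical test and the burden GLM, final element filters, per-TF and
#' per-position enrichment, and (when contribution tables are supplied) the
#' signature comparison, for one cohort.
#'
#' @param inputs list with components `genome`, `pfms`, `mutations`,
#'   `bundle`, `cohorts`, optionally `gene_models`, `contributions`,
#'   `catalog`, `weights`; a [simulate_scenario()] bundle works directly.
#' @param cohort_id cohort to analyse.
#' @param config [regmut_config()].
#' @param sim_sets optional precomputed [make_simulated_sets()] result for
#'   the full catalog (shared across cohorts); generated when missing.
#' @param instances optional precomputed, Z-filtered [scan_motifs()] result.
#' @return List of class `cohort_run` with `cohort_id`, `stage_counts`,
#'   `elements` (significant recurrent elements), `regulatory_mutations`,
#'   `qc` ([qc_report()]), `tf_burden`, `position_burden`,
#'   `signature_comparison` and `cosine` (both `NULL` without contribution
#'   inputs).
#' @export
run_cohort <- function(inputs, cohort_id, config = regmut_config(),
                       sim_sets = NULL, instances = NULL) {
  genome <- inputs$genome
  weights <- inputs$weights %||% default_annotation_weights()
  bg <- rep(config$background_nt_freq, 4)

  prep <- filter_hypermutated(inputs$mutations, config$hypermut_sample_max)
  muts <- collapse_mnps(prep$mutations)
  muts <- assign_cohorts(muts, inputs$cohorts)
  cmuts <- cohort_mutations(muts, cohort_id)

  if (is.null(sim_sets)) {
    sim_sets <- make_simulated_sets(muts, genome,
                                    n_sets = config$n_sim_sets,
                                    base_seed = config$rng_seed,
                                    window = config$shuffle_window,
                                    min_dist = config$shuffle_min_dist)
    sim_sets <- assign_cohorts(sim_sets, inputs$cohorts)
  }
  csim <- cohort_mutations(sim_sets, cohort_id)

  if (is.null(instances)) {
    instances <- scan_motifs(genome, inputs$pfms, background = bg,
                             p_threshold = config$motif_scan_p_threshold)
    instances <- zscore_filter(instances, config$motif_zscore_min)
  }

  scored <- score_mutated_motifs(cmuts, instances, inputs$pfms,
                                 inputs$bundle, weights, background = bg)
  scored <- filter_expressed_tfs(scored)
  scored$regulatory <- is_regulatory(scored, config)

  sim_scored <- score_mutated_motifs(csim, instances, inputs$pfms,
                                     inputs$bundle, weights, background = bg)
  sim_scored <- filter_expressed_tfs(sim_scored)

  elements <- merge_elements(scored, gap = config$merge_gap)
  sim_elements <- if (nrow(sim_scored) > 0) {
    split(sim_scored, sim_scored$set_id) |>
      purrr::map(merge_elements, gap = config$merge_gap) |>
      purrr::list_rbind()
  } else {
    merge_elements(sim_scored)
  }

  elements <- element_empirical_p(elements, sim_elements,
                                  window = config$shuffle_window)
  elements <- burden_test_elements(elements, cmuts, genome,
                                   window = config$shuffle_window,
                                   rate_max = config$burden_hypermut_rate_max)

  set.seed(config$rng_seed)
  p_theo <- theoretical_background(elements, sim_elements,
                                   window = config$shuffle_window)
  qc <- if (nrow(elements) > 0 && length(p_theo) > 0) {
    qc_report(cohort_id, elements$empirical_p[!is.na(elements$empirical_p)],
              p_theo)
  } else NULL

  cds <- if (!is.null(inputs$gene_models)) inputs$gene_models$cds else NULL
  final <- finalize_elements(elements, scored, cmuts, cds = cds,
                             config = config)
  if (!is.null(inputs$gene_models) && nrow(final) > 0) {
    final <- assign_genes(final, inputs$gene_models, mutations = cmuts,
                          window = config$gene_window)
  }

  reg_rows <- sort(unique(unlist(final$motif_rows)))
  reg_mutations <- scored[intersect(reg_rows, which(scored$regulatory)), ]

  obs_arm <- scored[scored$regulatory, ]
  sim_arm <- filter_simulated_functional(sim_scored, obs_arm, config)
  tf_burden <- if (nrow(obs_arm) > 0) {
    tf_enrichment(obs_arm, sim_arm, n_sets = config$n_sim_sets)
  } else NULL
  position_burden <- if (nrow(obs_arm) > 0) {
    position_enrichment(obs_arm, sim_arm, inputs$pfms,
                        n_sets = config$n_sim_sets)
  } else NULL

  signature_comparison <- cosine <- NULL
  if (!is.null(inputs$contributions) && nrow(reg_mutations) > 0) {
    others <- dplyr::anti_join(
      cmuts, reg_mutations,
      by = c("chrom", "start", "sample_id"))
    signature_comparison <- compare_contributions(
      reg_mutations, others, inputs$contributions, genome)
  }
  if (!is.null(inputs$catalog) && nrow(reg_mutations) > 0) {
    prof <- mutation_profile96(reg_mutations, genome)
    if (sum(prof) > 0) {
      cosine <- similarity_matrix(prof, inputs$catalog,
                                  threshold = config$cosine_sim_threshold)
    }
  }

  stage_counts <- c(
    mutations = nrow(cmuts),
    mutations_in_motifs = dplyr::n_distinct(scored[c("chrom", "start", "sample_id")]),
    scored_motifs = nrow(scored),
    elements = nrow(elements),
    significant_elements = nrow(final),
    regulatory_mutations = nrow(reg_mutations)
  )

  structure(list(cohort_id = cohort_id, stage_counts = stage_counts,
                 elements = final, all_elements = elements,
                 scored = scored, regulatory_mutations = reg_mutations,
                 qc = qc, tf_burden = tf_burden,
                 position_burden = position_burden,
                 signature_comparison = signature_comparison,
                 cosine = cosine),
            class = "cohort_run")
}

#' @export
print.cohort_run <- function(x, ...) {
  cat("<cohort_run>", x$cohort_id, "\n")
  for (nm in names(x$stage_counts)) {
    cat(sprintf("  %-24s %d\n", nm, x$stage_counts[[nm]]))
  }
  invisible(x)
}

#' Run every cohort and merge the pan-cancer element set
#'
#' Simulated sets and motif instances are generated once and shared across
#' cohorts; per-cohort significant elements from cohorts not flagged as
#' lymphoma or melanoma groups are merged into the pan-cancer set.
#'
#' @inheritParams run_cohort
#' @return List with `cohorts` (named list of [run_cohort()] results) and
#'   `pan_cancer` (merged element tibble).
#' @export
run_all <- function(inputs, config = regmut_config()) {
  genome <- inputs$genome
  bg <- rep(config$background_nt_freq, 4)
  prep <- filter_hypermutated(inputs$mutations, config$hypermut_sample_max)
  muts <- assign_cohorts(collapse_mnps(prep$mutations), inputs$cohorts)
  sim_sets <- make_simulated_sets(muts, genome, n_sets = config$n_sim_sets,
                                  base_seed = config$rng_seed,
                                  window = config$shuffle_window,
                                  min_dist = config$shuffle_min_dist)
  sim_sets <- assign_cohorts(sim_sets, inputs$cohorts)
  instances <- zscore_filter(
    scan_motifs(genome, inputs$pfms, background = bg,
                p_threshold = config$motif_scan_p_threshold),
    config$motif_zscore_min)

  runs <- lapply(inputs$cohorts$cohort_id, function(cid) {
    run_cohort(inputs, cid, config, sim_sets = sim_sets, instances = instances)
  })
  names(runs) <- inputs$cohorts$cohort_id

  per_cohort <- purrr::imap(runs, function(r, cid) {
    if (nrow(r$elements) == 0) return(NULL)
    dplyr::mutate(r$elements, cohort_id = cid)
  })
  per_cohort <- purrr::list_rbind(purrr::compact(per_cohort))
  pan <- if (!is.null(per_cohort) && nrow(per_cohort) > 0) {
    merge_pan_cancer(per_cohort, inputs$cohorts,
                     min_samples = config$min_recurrent_samples)
  } else {
    tibble(chrom = character(), start = integer(), end = integer(),
           element_score = numeric(), n_samples = integer(),
           samples = list(), cohort_ids = list())
  }
  list(cohorts = runs, pan_cancer = pan)
}

#' Write the per-cohort result tables
#'
#' Emits `elements_<cohort>.tsv` (coordinates 0-based half-open, score,
#' empirical p, burden FDR, sample recurrence, genes, feature type),
#' `regulatory_mutations_<cohort>.tsv`, `tf_burden_<cohort>.tsv`,
#' `position_burden_<cohort>.tsv` and `qc_<cohort>.tsv`.
#'
#' @param run [run_cohort()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_results <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cid <- run$cohort_id
  el <- run$elements
  if (nrow(el) > 0) {
    out <- tibble(chrom = el$chrom, start = el$start, end = el$end,
                  element_score = el$element_score,
                  empirical_p = el$empirical_p, burden_fdr = el$burden_fdr,
                  n_samples = el$n_samples,
                  n_regulatory = el$n_regulatory,
                  genes = purrr::map_chr(el$genes %||% list(),
                                         ~ paste(.x, collapse = ",")) |>
                    (\(x) if (length(x) == 0) NA_character_ else x)(),
                  feature_type = el$feature_type %||% NA_character_)
  } else {
    out <- tibble()
  }
  readr::write_tsv(out, file.path(dir, sprintf("elements_%s.tsv", cid)),
                   progress = FALSE)
  readr::write_tsv(
    dplyr::select(run$regulatory_mutations, !dplyr::where(is.list)),
    file.path(dir, sprintf("regulatory_mutations_%s.tsv", cid)),
    progress = FALSE)
  if (!is.null(run$tf_burden)) {
    readr::write_tsv(run$tf_burden,
                     file.path(dir, sprintf("tf_burden_%s.tsv", cid)),
                     progress = FALSE)
  }
  if (!is.null(run$position_burden)) {
    readr::write_tsv(run$position_burden,
                     file.path(dir, sprintf("position_burden_%s.tsv", cid)),
                     progress = FALSE)
  }
  if (!is.null(run$qc)) {
    readr::write_tsv(tibble(cohort_id = cid, lambda = run$qc$lambda),
                     file.path(dir, sprintf("qc_%s.tsv", cid)),
                     progress = FALSE)
  }
  invisible(dir)
}
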