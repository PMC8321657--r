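#' Rank-based empirical p-value against simulated set counts
#'
#' `p = max(k, 1)/n` with `k` the number of simulated sets whose count
#' reaches the observed count; with the 103 sets used throughout, an
#' observation exceeding every set receives the floor 1/103 = 0.0097.
#'
#' @param observed observed count (scalar).
#' @param sim_counts numeric vector of per-set counts (one per simulated
#'   set; include zeros for sets without any count).
#' @return Empirical p-value in `[1/n, 1]`.
#' @export
empirical_p_counts <- function(observed, sim_counts) {
  n <- length(sim_counts)
  if (n == 0) abort("No simulated sets")
  max(sum(sim_counts >= observed), 1) / n
}

#' Filter simulated mutated motifs to the functional arm
#'
#' Mirrors the observed regulatory definition on the simulated sets: a
#' simulated mutated motif is kept when its motif-score change is at least
#' `score_change_min` (inclusive on this arm), it overlaps a matching TF peak
#' or DHS, and its regulatory score is no more than one (population) standard
#' deviation below the mean score of the observed regulatory mutations of
#' the same TF.  TFs absent from the observed arm skip the score filter.
#'
#' @param sim_scored scored simulated mutated motifs (with `set_id`).
#' @param obs_scored observed scored motifs restricted to regulatory
#'   mutations.
#' @param config [regmut_config()].
#' @return Filtered `sim_scored`.
#' @export
filter_simulated_functional <- function(sim_scored, obs_scored,
                                        config = regmut_config()) {
  keep <- is_regulatory(sim_scored, config, strict = FALSE)
  stats <- obs_scored |>
    dplyr::group_by(.data$tf) |>
    dplyr::summarise(
      mean_score = mean(.data$regulatory_score),
      sd_score = sqrt(mean((.data$regulatory_score - mean(.data$regulatory_score))^2)),
      .groups = "drop"
    )
  m <- match(sim_scored$tf, stats$tf)
  has_stats <- !is.na(m)
  if (any(!has_stats & keep)) {
    message("TF(s) absent from the observed arm skip the score filter: ",
            paste(unique(sim_scored$tf[!has_stats & keep]), collapse = ", "))
  }
  floor_score <- stats$mean_score[m] - stats$sd_score[m]
  score_ok <- !has_stats | sim_scored$regulatory_score >= floor_score
  sim_scored[keep & score_ok, ]
}

#' Per-TF mutation-burden enrichment against the simulated sets
#'
#' Counts regulatory-mutated motifs per TF in the observed arm and per TF per
#' set in the (functionally filtered) simulated arm, then computes the
#' empirical p-value and fold enrichment over the simulated mean.
#'
#' @param obs_scored observed scored motifs restricted to regulatory
#'   mutations.
#' @param sim_scored simulated scored motifs after
#'   [filter_simulated_functional()], carrying `set_id`.
#' @param n_sets total number of simulated sets (103 by default; sets with
#'   zero counts still count).
#' @return Tibble `tf`, `observed_count`, `sim_mean`, `fold_enrichment`
#'   (`Inf` flagged via `fold_undefined` when the simulated mean is 0),
#'   `empirical_p`, ordered by p then fold.
#' @export
tf_enrichment <- function(obs_scored, sim_scored, n_sets = 103L) {
  obs_counts <- dplyr::count(obs_scored, .data$tf, name = "observed_count")
  sim_counts <- dplyr::count(sim_scored, .data$tf, .data$set_id, name = "n")
  purrr::map(seq_len(nrow(obs_counts)), function(i) {
    tf <- obs_counts$tf[i]
    per_set <- numeric(n_sets)
    rows <- sim_counts[sim_counts$tf == tf, ]
    per_set[rows$set_id] <- rows$n
    mu <- mean(per_set)
    tibble(
      tf = tf,
      observed_count = obs_counts$observed_count[i],
      sim_mean = mu,
      fold_enrichment = if (mu > 0) obs_counts$observed_count[i] / mu else Inf,
      fold_undefined = mu == 0,
      empirical_p = empirical_p_counts(obs_counts$observed_count[i], per_set)
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$empirical_p, dplyr::desc(.data$fold_enrichment))
}

#' Per-motif-position mutation enrichment
#'
#' Aligns all mutated motifs of each TF on the motif (position 1 is the 5'
#' end of the motif strand) and compares per-position observed counts to the
#' simulated sets with the same empirical p-value convention.
#'
#' @inheritParams tf_enrichment
#' @param pfms named PFM list, used for motif lengths (positions with zero
#'   observed mutations are still reported, with p = 1).
#' @return Tibble `tf`, `motif_position`, `observed_count`, `sim_mean`,
#'   `empirical_p`.
#' @export
position_enrichment <- function(obs_scored, sim_scored, pfms, n_sets = 103L) {
  tfs <- unique(obs_scored$tf)
  purrr::map(tfs, function(tf) {
    L <- nrow(pfms[[tf]])
    obs_tf <- obs_scored[obs_scored$tf == tf, ]
    sim_tf <- sim_scored[sim_scored$tf == tf, ]
    purrr::map(seq_len(L), function(pos) {
      obs_n <- sum(obs_tf$motif_position == pos)
      per_set <- numeric(n_sets)
      rows <- dplyr::count(sim_tf[sim_tf$motif_position == pos, ], .data$set_id)
      per_set[rows$set_id] <- rows$n
      tibble(tf = tf, motif_position = pos, observed_count = obs_n,
             sim_mean = mean(per_set),
             empirical_p = if (obs_n == 0) 1
                           else empirical_p_counts(obs_n, per_set))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

#' Plot per-position mutation enrichment for one TF
#' @param position_results tibble from [position_enrichment()].
#' @param tf TF to plot.
#' @return A ggplot object: observed counts per motif position with the
#'   simulated mean as a reference line.
#' @export
plot_position_enrichment <- function(position_results, tf) {
  tab <- position_results[position_results$tf == tf, ]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$motif_position)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed_count,
                                   fill = .data$empirical_p < 0.05)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_mean), color = "red") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "steelblue"),
                               name = "p < 0.05") +
    ggplot2::labs(x = "motif position", y = "mutated motifs", title = tf) +
    ggplot2::theme_minimal()
}
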