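#' Merge mutated motifs into mutated elements
#'
#' Single-linkage clustering: scored mutated motifs whose motif intervals lie
#' within `gap` bp of each other (on the same chromosome) join one element.
#' The element spans min start to max end of its members and carries the
#' arithmetic mean of the member regulatory scores.
#'
#' @param scored tibble from [score_mutated_motifs()].
#' @param gap maximum gap in bp (default 200).
#' @return Tibble with one row per element: `element_id`, `chrom`, `start`,
#'   `end`, `element_score`, `n_motifs`, `n_samples`, list-columns `samples`
#'   and `motif_rows` (row indices into `scored`).
#' @export
merge_elements <- function(scored, gap = 200L) {
  empty <- tibble(element_id = integer(), chrom = character(),
                  start = integer(), end = integer(), element_score = numeric(),
                  n_motifs = integer(), n_samples = integer(),
                  samples = list(), motif_rows = list())
  if (nrow(scored) == 0) return(empty)
  ord <- order(scored$chrom, scored$motif_start, scored$motif_end)
  s <- scored[ord, ]
  n <- nrow(s)
  cluster <- integer(n)
  cluster[1] <- 1L
  max_end <- s$motif_end[1]
  for (i in seq_len(n)[-1]) {
    same <- s$chrom[i] == s$chrom[i - 1]
    if (same && s$motif_start[i] - max_end <= gap) {
      cluster[i] <- cluster[i - 1]
      max_end <- max(max_end, s$motif_end[i])
    } else {
      cluster[i] <- cluster[i - 1] + 1L
      max_end <- s$motif_end[i]
    }
  }
  rows_orig <- ord
  purrr::map(unique(cluster), function(cl) {
    idx <- which(cluster == cl)
    tibble(
      element_id = cl,
      chrom = s$chrom[idx[1]],
      start = min(s$motif_start[idx]),
      end = max(s$motif_end[idx]),
      element_score = mean(s$regulatory_score[idx]),
      n_motifs = length(idx),
      n_samples = dplyr::n_distinct(s$sample_id[idx]),
      samples = list(unique(s$sample_id[idx])),
      motif_rows = list(rows_orig[idx])
    )
  }) |> purrr::list_rbind()
}

# simulated elements in the +/- window around an element (interval distance)
sim_in_window <- function(element, sim_elements, window) {
  same <- sim_elements$chrom == element$chrom
  near <- sim_elements$start < element$end + window &
    sim_elements$end > element$start - window
  sim_elements[same & near, ]
}

#' Empirical p-value of element regulatory scores
#'
#' Compares each observed element's score to the scores of simulated elements
#' (the simulated sets pushed through the same merge/score path) within a
#' +/- `window` neighborhood.  With `k` simulated elements scoring at least
#' the observed value among `n` in the window, `p = max(k, 1)/n`; when fewer
#' than 10 simulated elements fall in the window, the background widens to
#' the chromosome.  Elements with no simulated background anywhere get `NA`.
#'
#' @param elements tibble from [merge_elements()].
#' @param sim_elements simulated-element tibble (same columns; typically
#'   [merge_elements()] applied per simulated set, rows pooled).
#' @param window background window in bp (default 50000, matching the
#'   shuffle distance so the background is local).
#' @return `elements` with an `empirical_p` column.
#' @export
element_empirical_p <- function(elements, sim_elements, window = 50000L) {
  widened <- 0L
  p <- vapply(seq_len(nrow(elements)), function(i) {
    el <- elements[i, ]
    sims <- sim_in_window(el, sim_elements, window)
    if (nrow(sims) < 10) {
      sims <- sim_elements[sim_elements$chrom == el$chrom, ]
      widened <<- widened + 1L
    }
    n <- nrow(sims)
    if (n == 0) return(NA_real_)
    k <- sum(sims$element_score >= el$element_score)
    max(k, 1) / n
  }, numeric(1))
  if (widened > 0) {
    message(widened, " element(s) used a chromosome-wide simulated background")
  }
  if (anyNA(p)) {
    warn(paste0(sum(is.na(p)), " element(s) have no simulated background; ",
                "empirical p undefined"))
  }
  out <- as_tibble(elements)
  out$empirical_p <- p
  out
}

#' Theoretical p-value background from simulated elements
#'
#' For each observed element's window, one simulated element is drawn at
#' random and ranked against the other simulated elements in the window,
#' yielding the p-value distribution expected under the null; used for the
#' QQ comparison and the genomic inflation factor.
#'
#' @param elements observed elements (define the windows).
#' @param sim_elements simulated elements.
#' @param window bp (default 50000).
#' @return Numeric vector of theoretical p-values (windows with fewer than 2
#'   simulated elements are skipped).
#' @export
theoretical_background <- function(elements, sim_elements, window = 50000L) {
  p <- vapply(seq_len(nrow(elements)), function(i) {
    sims <- sim_in_window(elements[i, ], sim_elements, window)
    n <- nrow(sims)
    if (n < 2) return(NA_real_)
    j <- sample.int(n, 1L)
    k <- sum(sims$element_score[-j] >= sims$element_score[j])
    max(k, 1) / (n - 1)
  }, numeric(1))
  p[!is.na(p)]
}

#' Genomic inflation factor
#'
#' Ratio of the median observed to median theoretical chi-square(1) quantile
#' of the two p-value samples; approximately 1 for a calibrated statistic.
#'
#' @param p_observed,p_theoretical p-value vectors.
#' @return Scalar lambda.
#' @export
compute_lambda <- function(p_observed, p_theoretical) {
  chi_obs <- qchisq(1 - p_observed, df = 1)
  chi_theo <- qchisq(1 - p_theoretical, df = 1)
  median(chi_obs) / median(chi_theo)
}

#' QC report for a cohort's element p-values
#' @param cohort_id cohort label.
#' @param p_observed,p_theoretical p-value vectors.
#' @return Object of class `regmut_qc` with `lambda` and both sorted arrays.
#' @export
qc_report <- function(cohort_id, p_observed, p_theoretical) {
  structure(list(cohort_id = cohort_id,
                 lambda = compute_lambda(p_observed, p_theoretical),
                 p_observed = sort(p_observed),
                 p_theoretical = sort(p_theoretical)),
            class = "regmut_qc")
}

#' @export
print.regmut_qc <- function(x, ...) {
  cat(sprintf("<regmut_qc> cohort %s: lambda = %.3f (%d observed, %d theoretical p-values)\n",
              x$cohort_id, x$lambda, length(x$p_observed), length(x$p_theoretical)))
  invisible(x)
}

#' QQ plot of observed versus theoretical element p-values
#' @param object `regmut_qc` object.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot regmut_qc
#' @export
autoplot.regmut_qc <- function(object, ...) {
  n <- length(object$p_observed)
  expected <- -log10(ppoints(n))
  theo_q <- -log10(stats::quantile(object$p_theoretical, probs = ppoints(n),
                                   type = 1, names = FALSE))
  tab <- tibble(expected = sort(theo_q),
                observed = sort(-log10(object$p_observed)),
                significant = sort(object$p_observed, decreasing = TRUE) < 0.05)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$expected, y = .data$observed,
                                    color = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "black", `TRUE` = "blue")) +
    ggplot2::labs(
      x = expression(-log[10] ~ "theoretical p"),
      y = expression(-log[10] ~ "observed p"),
      title = sprintf("Cohort %s, lambda = %.2f", object$cohort_id, object$lambda)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# pyrimidine-collapsed trinucleotide labels (32) used as burden cofactors
collapsed_context_labels <- function() {
  out <- character(0)
  for (c in c("C", "T")) for (l in DNA_BASES) for (r in DNA_BASES) {
    out <- c(out, paste0(l, c, r))
  }
  out
}

collapse_context <- function(ctx) {
  mid <- substr(ctx, 2, 2)
  flip <- mid %in% c("A", "G")
  ctx[flip] <- revcomp(ctx[flip])
  ctx
}

# counts of collapsed trinucleotide contexts over a genomic region
region_context_counts <- function(genome, chrom, start, end) {
  labs <- collapsed_context_labels()
  counts <- setNames(numeric(32), labs)
  len <- chrom_lengths(genome)[[chrom]]
  lo <- max(start, 1L)
  hi <- min(end - 1L, len - 2L)
  if (hi < lo) return(counts)
  seq <- substr(genome[[chrom]], lo, hi + 2L)
  codes <- dna_codes(seq)
  n <- length(codes)
  id <- 16L * codes[1:(n - 2)] + 4L * codes[2:(n - 1)] + codes[3:n]
  ok <- !is.na(id)
  ctx <- collapse_context(trimer_name(id[ok]))
  tab <- table(factor(ctx, levels = labs))
  counts[names(tab)] <- as.numeric(tab)
  counts
}

#' Mutation-burden test for one element
#'
#' Fits a Poisson generalized linear model of mutation counts on a
#' trinucleotide-context stratification of the +/- `window` neighborhood,
#' with log-opportunity offsets (context positions times retained samples),
#' and tests enrichment of the in-element indicator by a one-sided
#' likelihood-ratio test.  Samples exceeding `rate_max` mutations per
#' megabase genome-wide are excluded first.  SNVs stratify by their collapsed
#' trinucleotide context; indels and multi-nucleotide substitutions count in
#' a single extra stratum.
#'
#' @param element one-row tibble with `chrom`, `start`, `end`.
#' @param mutations all annotated mutations of the cohort.
#' @param genome [read_genome()] result.
#' @param window background window in bp (default 50000).
#' @param rate_max hypermutation exclusion, mutations/Mb (default 30).
#' @return Object of class `regmut_burden`: list with `p` (one-sided),
#'   `estimate` (log rate ratio), `method` (`"glm"` or `"poisson_tail"`),
#'   `n_element`, `n_background`, `n_samples`.
#' @export
burden_test <- function(element, mutations, genome, window = 50000L,
                        rate_max = 30) {
  genome_mb <- sum(chrom_lengths(genome)) / 1e6
  per_sample <- dplyr::count(mutations, .data$sample_id)
  keep_samples <- per_sample$sample_id[per_sample$n / genome_mb <= rate_max]
  muts <- mutations[mutations$sample_id %in% keep_samples, ]
  n_samples <- length(keep_samples)

  w_lo <- max(0L, element$start - window)
  w_hi <- min(chrom_lengths(genome)[[element$chrom]], element$end + window)
  in_win <- muts$chrom == element$chrom & muts$start >= w_lo & muts$start < w_hi
  muts <- muts[in_win, ]
  if (nrow(muts) == 0) abort("No mutations in the burden window")
  in_el <- muts$start >= element$start & muts$start < element$end

  ctx_labels <- c(collapsed_context_labels(), "indel")
  mut_ctx <- rep("indel", nrow(muts))
  snv <- muts$mut_class == "SNV"
  if (any(snv)) {
    raw <- trinuc_context(genome, muts$chrom[snv], muts$start[snv])
    cc <- ifelse(is.na(raw), NA_character_, collapse_context(raw))
    mut_ctx[snv] <- ifelse(is.na(cc), "indel", cc)
  }

  opp_el <- region_context_counts(genome, element$chrom, element$start, element$end)
  opp_all <- region_context_counts(genome, element$chrom, w_lo, w_hi)
  opp_bg <- pmax(opp_all - opp_el, 0)
  # indel opportunity: region width
  opp_el <- c(opp_el, indel = element$end - element$start)
  opp_bg <- c(opp_bg, indel = (w_hi - w_lo) - (element$end - element$start))

  count_in <- table(factor(mut_ctx[in_el], levels = ctx_labels))
  count_bg <- table(factor(mut_ctx[!in_el], levels = ctx_labels))
  dat <- tibble(
    stratum = rep(ctx_labels, 2),
    in_element = rep(c(1, 0), each = length(ctx_labels)),
    count = c(as.numeric(count_in), as.numeric(count_bg)),
    opportunity = c(as.numeric(opp_el[ctx_labels]),
                    as.numeric(opp_bg[ctx_labels])) * max(n_samples, 1)
  )
  dat <- dat[dat$opportunity > 0, ]
  used <- unique(dat$stratum[dat$count > 0])
  dat <- dat[dat$stratum %in% used, ]

  fit0 <- fit1 <- NULL
  ok <- tryCatch({
    fit1 <- glm(count ~ stratum + in_element + offset(log(opportunity)),
                family = poisson(), data = dat)
    fit0 <- glm(count ~ stratum + offset(log(opportunity)),
                family = poisson(), data = dat)
    fit1$converged && fit0$converged
  }, error = function(e) FALSE)

  n_el_mut <- sum(in_el)
  n_bg_mut <- sum(!in_el)
  if (isTRUE(ok) && "in_element" %in% names(coef(fit1))) {
    est <- unname(coef(fit1)["in_element"])
    dev <- fit0$deviance - fit1$deviance
    p_two <- pchisq(max(dev, 0), df = 1, lower.tail = FALSE)
    p <- if (est > 0) p_two / 2 else 1 - p_two / 2
    method <- "glm"
  } else {
    # exact Poisson tail on pooled counts at the background rate
    opp_e <- sum(dat$opportunity[dat$in_element == 1])
    opp_b <- sum(dat$opportunity[dat$in_element == 0])
    rate <- if (opp_b > 0) n_bg_mut / opp_b else 0
    p <- stats::ppois(n_el_mut - 1, lambda = rate * opp_e, lower.tail = FALSE)
    est <- if (rate > 0 && opp_e > 0) log((n_el_mut / opp_e) / rate) else NA_real_
    method <- "poisson_tail"
    message("Burden GLM did not converge; exact Poisson tail fallback used")
  }
  structure(list(p = p, estimate = est, method = method,
                 n_element = n_el_mut, n_background = n_bg_mut,
                 n_samples = n_samples),
            class = "regmut_burden")
}

#' @export
print.regmut_burden <- function(x, ...) {
  cat(sprintf("<regmut_burden> p = %.4g (%s), %d element / %d background mutations, %d samples\n",
              x$p, x$method, x$n_element, x$n_background, x$n_samples))
  invisible(x)
}

#' Tidy a burden-test fit
#' @param x `regmut_burden` object.
#' @param ... unused.
#' @return One-row tibble `term`, `estimate`, `p.value`, `method`.
#' @method tidy regmut_burden
#' @export
tidy.regmut_burden <- function(x, ...) {
  tibble(term = "in_element", estimate = x$estimate, p.value = x$p,
         method = x$method)
}

#' Glance at a burden-test fit
#' @param x `regmut_burden` object.
#' @param ... unused.
#' @return One-row tibble with counts and the p-value.
#' @method glance regmut_burden
#' @export
glance.regmut_burden <- function(x, ...) {
  tibble(p.value = x$p, n_element = x$n_element,
         n_background = x$n_background, n_samples = x$n_samples,
         method = x$method)
}

#' Burden test across a table of elements
#' @param elements element tibble.
#' @param mutations cohort mutation tibble.
#' @param genome [read_genome()] result.
#' @param window,rate_max see [burden_test()].
#' @return `elements` with a `burden_p` column (`NA` where the window held no
#'   mutation).
#' @export
burden_test_elements <- function(elements, mutations, genome,
                                 window = 50000L, rate_max = 30) {
  out <- as_tibble(elements)
  out$burden_p <- vapply(seq_len(nrow(out)), function(i) {
    tryCatch(burden_test(out[i, ], mutations, genome, window, rate_max)$p,
             error = function(e) NA_real_)
  }, numeric(1))
  out
}

#' Final element filters
#'
#' Applies, in order: empirical p < `element_p_max`; Benjamini-Hochberg FDR
#' on the burden p across the cohort's tested elements < `burden_fdr_max`;
#' at least one regulatory mutation; symmetric extension of short elements to
#' `element_extension` bp and re-intersection with the full mutation catalog
#' (recovering mutations that lacked motif overlap); removal of elements
#' overlapping coding sequence; recurrence in at least
#' `min_recurrent_samples` distinct samples.
#'
#' @param elements tibble with `empirical_p` and `burden_p` columns.
#' @param scored scored-motif tibble the elements were built from, with a
#'   logical `regulatory` column ([is_regulatory()]).
#' @param mutations the cohort's full mutation catalog.
#' @param cds coding-sequence intervals (`chrom`, `start`, `end`), or `NULL`.
#' @param config [regmut_config()].
#' @return Tibble of significant recurrent elements with updated spans,
#'   sample lists, `n_mutations`, `n_regulatory` and `burden_fdr`.
#' @export
finalize_elements <- function(elements, scored, mutations, cds = NULL,
                              config = regmut_config()) {
  el <- as_tibble(elements)
  el <- el[!is.na(el$empirical_p) & el$empirical_p < config$element_p_max, ]
  el <- el[!is.na(el$burden_p), ]
  if (nrow(el) == 0) return(dplyr::mutate(el, burden_fdr = numeric(0),
                                          n_regulatory = integer(0),
                                          n_mutations = integer(0)))
  el$burden_fdr <- p.adjust(el$burden_p, method = "BH")
  el <- el[el$burden_fdr < config$burden_fdr_max, ]

  el$n_regulatory <- vapply(el$motif_rows, function(rows) {
    sum(scored$regulatory[rows])
  }, integer(1))
  el <- el[el$n_regulatory >= 1, ]
  if (nrow(el) == 0) return(el)

  # extend short elements symmetrically to the typical regulatory size
  width <- el$end - el$start
  short <- width < config$element_extension
  pad <- pmax(ceiling((config$element_extension - width) / 2), 0)
  el$start <- as.integer(ifelse(short, pmax(el$start - pad, 0L), el$start))
  el$end <- as.integer(ifelse(short, el$end + pad, el$end))

  # re-intersect with the entire mutation catalog
  ov <- overlap_pairs(el, mutations)
  by_el <- split(ov$b, ov$a)
  el$samples <- lapply(seq_len(nrow(el)), function(i) {
    rows <- by_el[[as.character(i)]]
    if (is.null(rows)) el$samples[[i]]
    else unique(mutations$sample_id[rows])
  })
  el$n_mutations <- vapply(seq_len(nrow(el)), function(i) {
    length(by_el[[as.character(i)]] %||% integer(0))
  }, integer(1))
  el$n_samples <- lengths(el$samples)

  if (!is.null(cds) && nrow(cds) > 0) {
    el <- el[!overlap_any(el, cds), ]
  }
  el[el$n_samples >= config$min_recurrent_samples, ]
}

#' Merge per-cohort significant elements into a pan-cancer set
#'
#' Overlapping elements from non-excluded cohorts are unioned (span and
#' sample sets) and the recurrence filter re-applied.
#'
#' @param element_sets tibble of significant elements carrying `cohort_id`;
#'   typically a row-bind over cohorts.
#' @param cohorts cohort spec tibble; lymphoma/melanoma-flagged cohorts are
#'   excluded from the merge.
#' @param min_samples recurrence threshold after merging (default 3).
#' @return Merged element tibble with `cohort_ids` list-column.
#' @export
merge_pan_cancer <- function(element_sets, cohorts, min_samples = 3L) {
  excluded <- cohorts$cohort_id[cohorts$is_lymphoma_group | cohorts$is_melanoma_group]
  el <- element_sets[!element_sets$cohort_id %in% excluded, ]
  if (nrow(el) == 0) {
    return(dplyr::mutate(el, cohort_ids = list()))
  }
  el <- dplyr::arrange(el, .data$chrom, .data$start)
  cluster <- integer(nrow(el))
  cluster[1] <- 1L
  max_end <- el$end[1]
  for (i in seq_len(nrow(el))[-1]) {
    if (el$chrom[i] == el$chrom[i - 1] && el$start[i] < max_end) {
      cluster[i] <- cluster[i - 1]
      max_end <- max(max_end, el$end[i])
    } else {
      cluster[i] <- cluster[i - 1] + 1L
      max_end <- el$end[i]
    }
  }
  merged <- purrr::map(unique(cluster), function(cl) {
    idx <- which(cluster == cl)
    samples <- unique(unlist(el$samples[idx]))
    tibble(chrom = el$chrom[idx[1]],
           start = min(el$start[idx]), end = max(el$end[idx]),
           element_score = mean(el$element_score[idx]),
           n_samples = length(samples), samples = list(samples),
           cohort_ids = list(unique(el$cohort_id[idx])))
  }) |> purrr::list_rbind()
  merged[merged$n_samples >= min_samples, ]
}
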