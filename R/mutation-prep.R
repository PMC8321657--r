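#' Remove hypermutated samples
#'
#' Samples with strictly more than `max_per_sample` mutations are removed
#' from the catalog.
#'
#' @param mutations mutation tibble.
#' @param max_per_sample per-sample cap (default 100000; "more than" is
#'   strict, so a sample at exactly the cap is retained).
#' @return List with `mutations` (retained rows) and `removed_samples`
#'   (tibble `sample_id`, `n_mutations`).
#' @export
filter_hypermutated <- function(mutations, max_per_sample = 100000L) {
  counts <- dplyr::count(mutations, .data$sample_id, name = "n_mutations")
  removed <- dplyr::filter(counts, .data$n_mutations > max_per_sample)
  if (nrow(removed) > 0) {
    message("Removed ", nrow(removed), " hypermutated sample(s): ",
            paste(removed$sample_id, collapse = ", "))
  }
  list(
    mutations = dplyr::filter(mutations,
                              !.data$sample_id %in% removed$sample_id),
    removed_samples = removed
  )
}

#' Collapse adjacent same-sample SNVs into multi-nucleotide variants
#'
#' Runs of SNVs at strictly consecutive positions in the same sample become a
#' single DNP/TNP/ONP with concatenated alleles.  Non-adjacent SNVs and
#' non-SNV records pass through unchanged.  The operation preserves the total
#' number of mutated bases and is idempotent.
#'
#' @param mutations mutation tibble.
#' @return Mutation tibble with runs collapsed.
#' @export
collapse_mnps <- function(mutations) {
  if (nrow(mutations) == 0) return(as_tibble(mutations))
  snv <- dplyr::filter(mutations, .data$mut_class == "SNV") |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$start)
  rest <- dplyr::filter(mutations, .data$mut_class != "SNV")
  if (nrow(snv) == 0) return(dplyr::bind_rows(snv, rest))

  new_run <- c(TRUE, !(snv$sample_id[-1] == snv$sample_id[-nrow(snv)] &
                         snv$chrom[-1] == snv$chrom[-nrow(snv)] &
                         snv$start[-1] == snv$start[-nrow(snv)] + 1L))
  run_id <- cumsum(new_run)
  collapsed <- snv |>
    dplyr::mutate(.run = run_id) |>
    dplyr::group_by(.data$.run) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      ref = paste(.data$ref, collapse = ""),
      alt = paste(.data$alt, collapse = ""),
      sample_id = dplyr::first(.data$sample_id),
      cancer_type = dplyr::first(.data$cancer_type),
      .groups = "drop"
    ) |>
    dplyr::mutate(mut_class = mutation_class(.data$ref, .data$alt)) |>
    dplyr::select(-".run") |>
    dplyr::relocate("chrom", "start", "end", "ref", "alt", "mut_class",
                    "sample_id", "cancer_type")
  dplyr::bind_rows(collapsed, rest) |>
    dplyr::arrange(.data$chrom, .data$start, .data$sample_id)
}

#' Define analysis cohorts
#'
#' A cohort is a named set of cancer types, optionally flagged as the
#' lymphoma group, the melanoma group, or a meta-cohort.  Meta-cohorts in the
#' spirit of ATELM ("all tumors except lymphoma and melanoma") simply list
#' the cancer types they include.
#'
#' @param cohort_id cohort name.
#' @param cancer_types character vector of member cancer types.
#' @param is_lymphoma_group,is_melanoma_group,is_meta logical flags.
#' @return One-row tibble with a `cancer_types` list-column.
#' @export
cohort_spec <- function(cohort_id, cancer_types, is_lymphoma_group = FALSE,
                        is_melanoma_group = FALSE, is_meta = FALSE) {
  tibble(cohort_id = cohort_id, cancer_types = list(cancer_types),
         is_lymphoma_group = is_lymphoma_group,
         is_melanoma_group = is_melanoma_group, is_meta = is_meta)
}

#' Read cohort definitions from YAML
#'
#' The YAML maps each cohort id to a mapping with `cancer_types` (list) and
#' optional flags `is_lymphoma_group`, `is_melanoma_group`, `is_meta`.
#'
#' @param path YAML file.
#' @return Tibble of cohort specs (one row per cohort).
#' @export
read_cohorts <- function(path) {
  spec <- yaml::read_yaml(path)
  purrr::imap(spec, function(x, id) {
    cohort_spec(id, unlist(x$cancer_types),
                isTRUE(x$is_lymphoma_group), isTRUE(x$is_melanoma_group),
                isTRUE(x$is_meta))
  }) |> purrr::list_rbind()
}

#' Assign mutations to cohorts
#'
#' A mutation belongs to every cohort whose cancer-type set contains its
#' cancer type.  Every cancer type present in the catalog must appear in at
#' least one cohort.
#'
#' @param mutations mutation tibble.
#' @param cohorts tibble of [cohort_spec()] rows.
#' @return `mutations` with an added `cohort_ids` list-column.
#' @export
assign_cohorts <- function(mutations, cohorts) {
  if (nrow(cohorts) == 0) abort("Empty cohort specification")
  type_to_cohorts <- cohorts |>
    dplyr::select("cohort_id", "cancer_types") |>
    tidyr::unnest("cancer_types") |>
    dplyr::rename(cancer_type = "cancer_types")
  orphan <- setdiff(unique(mutations$cancer_type), type_to_cohorts$cancer_type)
  if (length(orphan) > 0) {
    abort(paste0("Cancer type(s) in no cohort: ", paste(orphan, collapse = ", ")))
  }
  lut <- split(type_to_cohorts$cohort_id, type_to_cohorts$cancer_type)
  out <- as_tibble(mutations)
  out$cohort_ids <- unname(lut[out$cancer_type])
  out
}

#' Restrict a mutation catalog to one cohort
#' @param mutations tibble from [assign_cohorts()].
#' @param cohort_id cohort to keep.
#' @return Mutation tibble containing only that cohort's records.
#' @export
cohort_mutations <- function(mutations, cohort_id) {
  keep <- purrr::map_lgl(mutations$cohort_ids, ~ cohort_id %in% .x)
  mutations[keep, ]
}
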