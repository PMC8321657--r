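#' The 96 pyrimidine-centered trinucleotide context labels
#'
#' Six substitution classes (C>A, C>G, C>T, T>A, T>C, T>G) crossed with the 16
#' flanking-base combinations, in the conventional order (substitution-major,
#' flanks alphabetical), e.g. `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
context96_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(DNA_BASES, DNA_BASES, function(l, r) {
      paste0(l, "[", s, "]", r)
    })))
  }))
}

#' Map an SNV to its 96-context category
#'
#' When the reference base is a purine the mutation is presented on the
#' opposite strand (flanks and alleles reverse-complemented) so that the
#' reference is always a pyrimidine.
#'
#' @param ref,alt single-base alleles (vectors allowed).
#' @param context 3-mer genomic context centered on the mutated base.
#' @return Character vector of labels like `"A[C>T]G"`; `NA` where the context
#'   contains N.
#' @examples
#' context96("C", "T", "ACG")
#' context96("G", "A", "CGT")  # collapses to the same bin
#' @export
context96 <- function(ref, alt, context) {
  stopifnot(length(ref) == length(alt), length(ref) == length(context))
  out <- rep(NA_character_, length(ref))
  ok <- !grepl("N", context, fixed = TRUE) & nchar(context) == 3 &
    substr(context, 2, 2) == ref
  if (any(substr(context, 2, 2) != ref & !grepl("N", context, fixed = TRUE))) {
    abort("context middle base must equal the reference allele")
  }
  purine <- ref %in% c("A", "G")
  r <- ref
  a <- alt
  ctx <- context
  flip <- ok & purine
  if (any(flip)) {
    ctx[flip] <- revcomp(context[flip])
    r[flip] <- complement_base(ref[flip])
    a[flip] <- complement_base(alt[flip])
  }
  out[ok] <- paste0(substr(ctx[ok], 1, 1), "[", r[ok], ">", a[ok], "]",
                    substr(ctx[ok], 3, 3))
  out
}

#' Build a 96-context mutation profile
#'
#' Counts SNVs into the 96 pyrimidine-centered trinucleotide categories.
#' Non-SNV records and SNVs with undefined context (chromosome edge, N) are
#' ignored.
#'
#' @param mutations mutation tibble (see [read_mutations()]).
#' @param genome [read_genome()] result.
#' @param normalize return probabilities instead of counts.
#' @return Named numeric vector of length 96 in [context96_labels()] order.
#' @export
mutation_profile96 <- function(mutations, genome, normalize = FALSE) {
  labs <- context96_labels()
  counts <- setNames(numeric(96), labs)
  snv <- mutations[mutations$mut_class == "SNV", ]
  if (nrow(snv) > 0) {
    ctx <- trinuc_context(genome, snv$chrom, snv$start)
    cat96 <- context96(snv$ref, snv$alt, ifelse(is.na(ctx), "NNN", ctx))
    tab <- table(factor(cat96, levels = labs))
    counts[names(tab)] <- as.numeric(tab)
  }
  if (normalize) {
    s <- sum(counts)
    if (s == 0) abort("Cannot normalize an empty profile")
    counts <- counts / s
  }
  counts
}

#' Canonical double-base substitution feature
#'
#' A DNP has two strand presentations; the lexicographically smaller
#' `"REF>ALT"` string of the two is the canonical feature.
#'
#' @param ref,alt two-base alleles.
#' @return Character vector like `"CC>TT"`.
#' @export
dbs_feature <- function(ref, alt) {
  fwd <- paste0(ref, ">", alt)
  rev <- paste0(revcomp(ref), ">", revcomp(alt))
  pmin(fwd, rev)
}

#' Per-mutation signature feature type
#'
#' SNVs map to their 96-context label; DNPs to the canonical dinucleotide
#' substitution; other classes get `NA` (no signature stratum).
#'
#' @param mutations mutation tibble.
#' @param genome [read_genome()] result.
#' @return Tibble `mutations` plus columns `category` (`"SBS"`/`"DBS"`/`NA`)
#'   and `feature_type`.
#' @export
signature_features <- function(mutations, genome) {
  out <- as_tibble(mutations)
  out$category <- dplyr::case_when(
    out$mut_class == "SNV" ~ "SBS",
    out$mut_class == "DNP" ~ "DBS",
    TRUE ~ NA_character_
  )
  ft <- rep(NA_character_, nrow(out))
  is_snv <- which(out$mut_class == "SNV")
  if (length(is_snv) > 0) {
    ctx <- trinuc_context(genome, out$chrom[is_snv], out$start[is_snv])
    ft[is_snv] <- context96(out$ref[is_snv], out$alt[is_snv],
                            ifelse(is.na(ctx), "NNN", ctx))
  }
  is_dnp <- which(out$mut_class == "DNP")
  if (length(is_dnp) > 0) {
    ft[is_dnp] <- dbs_feature(out$ref[is_dnp], out$alt[is_dnp])
  }
  out$feature_type <- ft
  out
}

#' Cosine similarity of two non-negative profiles
#' @param a,b numeric vectors of equal length; neither may be all-zero.
#' @return Scalar in `[0, 1]` for non-negative inputs.
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 0))  # 1/sqrt(2)
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) abort("Profiles must have equal length")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("Cosine similarity is undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Compare signature contributions between regulatory and other mutations
#'
#' Joins every mutation to its per-sample, per-feature-type signature
#' contributions and, for each signature, runs a two-sample two-sided
#' Kolmogorov-Smirnov test between the regulatory arm and the rest.
#'
#' @param regulatory mutation tibble of regulatory mutations (after
#'   [signature_features()] or raw; features are recomputed if absent).
#' @param others mutation tibble of the remaining mutations.
#' @param contributions table from [read_signature_contributions()].
#' @param genome [read_genome()] result.
#' @return Tibble with one row per signature: `signature`, `category`,
#'   `n_regulatory`, `n_others`, `direction`
#'   (mean(regulatory) - mean(others)), `ks_p`.
#' @export
compare_contributions <- function(regulatory, others, contributions, genome) {
  join_arm <- function(muts) {
    if (!"feature_type" %in% names(muts)) muts <- signature_features(muts, genome)
    muts |>
      dplyr::filter(!is.na(.data$feature_type)) |>
      dplyr::inner_join(contributions,
                        by = c("sample_id", "category", "feature_type"),
                        relationship = "many-to-many")
  }
  reg <- join_arm(regulatory)
  oth <- join_arm(others)
  sigs <- union(unique(reg$signature), unique(oth$signature))
  if (length(sigs) == 0) {
    return(tibble(signature = character(), category = character(),
                  n_regulatory = integer(), n_others = integer(),
                  direction = numeric(), ks_p = numeric()))
  }
  purrr::map(sigs, function(s) {
    x <- reg$contribution[reg$signature == s]
    y <- oth$contribution[oth$signature == s]
    if (length(x) == 0 || length(y) == 0) {
      return(tibble(signature = s,
                    category = (reg$category[reg$signature == s] %||%
                                  oth$category[oth$signature == s])[1],
                    n_regulatory = length(x), n_others = length(y),
                    direction = NA_real_, ks_p = NA_real_))
    }
    ks <- suppressWarnings(ks.test(x, y, alternative = "two.sided"))
    tibble(
      signature = s,
      category = c(reg$category[reg$signature == s],
                   oth$category[oth$signature == s])[1],
      n_regulatory = length(x), n_others = length(y),
      direction = mean(x) - mean(y),
      ks_p = ks$p.value
    )
  }) |> purrr::list_rbind() |> dplyr::arrange(.data$ks_p)
}

#' Cosine-similarity matrix against a signature catalog
#'
#' @param profiles numeric matrix, 96 rows (contexts) by one column per
#'   profile (e.g. per cancer type), or a single 96-vector.
#' @param catalog 96 x S signature matrix from [read_signature_catalog()].
#' @param threshold cosine above which a signature is "called" for a profile.
#' @return Tibble with `profile`, `signature`, `cosine`, `called`.
#' @export
similarity_matrix <- function(profiles, catalog, threshold = 0.7) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, ncol = 1,
                                                 dimnames = list(NULL, "profile"))
  if (nrow(profiles) != nrow(catalog)) {
    abort("profiles and catalog must share the 96-context rows")
  }
  grid <- tidyr::expand_grid(profile = colnames(profiles),
                             signature = colnames(catalog))
  grid$cosine <- purrr::map2_dbl(grid$profile, grid$signature, function(p, s) {
    cosine_similarity(profiles[, p], catalog[, s])
  })
  grid$called <- grid$cosine >= threshold
  grid
}

#' Plot a 96-context profile
#' @param profile named 96-vector from [mutation_profile96()].
#' @return A ggplot object: relative contribution per context, faceted by
#'   substitution class.
#' @export
plot_96_profile <- function(profile) {
  labs <- context96_labels()
  tab <- tibble(
    context = factor(labs, levels = labs),
    substitution = sub(".*\\[(.*)\\].*", "\\1", labs),
    flanks = sub("\\[.*\\]", ".", labs),
    count = as.numeric(profile[labs])
  )
  tot <- sum(tab$count)
  tab$relative <- if (tot > 0) tab$count / tot else 0
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$flanks, y = .data$relative,
                                    fill = .data$substitution)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(. ~ substitution, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "relative contribution") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 5))
}
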