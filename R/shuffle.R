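#' Trinucleotide context at a genomic position
#'
#' @param genome [read_genome()] result.
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @return 3-mer `genome[pos-1 .. pos+2)`; `NA` (undefined) at chromosome
#'   edges or when the 3-mer contains N.
#' @examples
#' g <- structure(c(chr1 = "AACGT"), class = "regmut_genome")
#' trinuc_context(g, "chr1", 2)  # "ACG"
#' @export
trinuc_context <- function(genome, chrom, pos) {
  lens <- chrom_lengths(genome)
  out <- rep(NA_character_, length(pos))
  ok <- pos >= 1 & pos <= lens[chrom] - 2
  if (any(ok, na.rm = TRUE)) {
    idx <- which(ok)
    out[idx] <- substr(genome[chrom[idx]], pos[idx], pos[idx] + 2L)
  }
  out[grepl("N", out, fixed = TRUE)] <- NA_character_
  out
}

#' Precompute a per-chromosome position index keyed by 3-mer
#'
#' Maps every defined trinucleotide to the sorted 0-based positions of its
#' central base, giving O(log k) candidate lookup during shuffling instead of
#' a 50-kb scan per mutation.
#'
#' @param genome [read_genome()] result.
#' @return Named list (chromosome) of named lists (3-mer -> sorted integer
#'   positions), with class `trinuc_index`.
#' @export
build_trinuc_index <- function(genome) {
  idx <- lapply(unclass(genome), function(seq) {
    codes <- dna_codes(seq)
    n <- length(codes)
    if (n < 3) return(list())
    # trimer id of the 3-mer centered at 0-based position p (p = 1..n-2)
    id <- 16L * codes[1:(n - 2)] + 4L * codes[2:(n - 1)] + codes[3:n]
    centers <- 1:(n - 2)
    ok <- !is.na(id)
    split(centers[ok], trimer_name(id[ok]))
  })
  structure(idx, class = "trinuc_index")
}

trimer_name <- function(id) {
  # id = 16*a + 4*b + c with codes 1..4
  rest <- id - 21L  # shift so AAA -> 0
  a <- rest %/% 16L
  b <- (rest %% 16L) %/% 4L
  c <- rest %% 4L
  paste0(DNA_BASES[a + 1L], DNA_BASES[b + 1L], DNA_BASES[c + 1L])
}

#' Candidate positions sharing a context near a source position
#' @noRd
eligible_positions <- function(index, chrom, context, pos, window, min_dist) {
  positions <- index[[chrom]][[context]]
  if (is.null(positions)) return(integer())
  lo <- findInterval(pos - window - 0.5, positions) + 1L
  hi <- findInterval(pos + window + 0.5, positions)
  if (hi < lo) return(integer())
  cand <- positions[lo:hi]
  cand[abs(cand - pos) >= min_dist]
}

#' Shuffle one mutation set preserving trinucleotide context
#'
#' Every SNV is moved to a position drawn uniformly among positions on the
#' same chromosome with an identical trinucleotide context, at distance
#' between `min_dist` and `window` from the source.  If no candidate exists
#' the window is doubled once; if still none the mutation is dropped.  Indels
#' (and multi-nucleotide substitutions) are relocated uniformly within the
#' same distance bounds without context matching, and their reference allele
#' is rewritten from the genome at the landing site.
#'
#' @param mutations mutation tibble.
#' @param genome [read_genome()] result.
#' @param index [build_trinuc_index()] of the same genome.
#' @param window,min_dist distance bounds in bp.
#' @return Tibble like `mutations` with shuffled coordinates plus columns
#'   `source_start` and `context_matched`; dropped mutations are absent and
#'   their count reported via a message.
#' @export
shuffle_mutations <- function(mutations, genome, index,
                              window = 50000L, min_dist = 50L) {
  n <- nrow(mutations)
  if (n == 0) {
    out <- as_tibble(mutations)
    out$source_start <- integer()
    out$context_matched <- logical()
    return(out)
  }
  lens <- chrom_lengths(genome)
  is_snv <- mutations$mut_class == "SNV"
  ctx <- rep(NA_character_, n)
  ctx[is_snv] <- trinuc_context(genome, mutations$chrom[is_snv],
                                mutations$start[is_snv])

  new_start <- rep(NA_integer_, n)
  matched <- rep(NA, n)
  for (i in seq_len(n)) {
    chrom <- mutations$chrom[i]
    pos <- mutations$start[i]
    if (is_snv[i]) {
      if (is.na(ctx[i])) next  # undefined context: drop
      cand <- eligible_positions(index, chrom, ctx[i], pos, window, min_dist)
      if (length(cand) == 0) {
        cand <- eligible_positions(index, chrom, ctx[i], pos, 2L * window, min_dist)
      }
      if (length(cand) == 0) next
      new_start[i] <- cand[sample.int(length(cand), 1L)]
      matched[i] <- TRUE
    } else {
      len <- mutations$end[i] - mutations$start[i]
      lo <- max(0L, pos - window)
      hi <- min(lens[[chrom]] - max(len, 1L), pos + window)
      cand <- setdiff(lo:hi, (pos - min_dist + 1L):(pos + min_dist - 1L))
      if (length(cand) == 0) next
      new_start[i] <- cand[sample.int(length(cand), 1L)]
      matched[i] <- FALSE
    }
  }
  keep <- !is.na(new_start)
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(dropped, " mutation(s) dropped during shuffling (no eligible position)")
  }
  out <- as_tibble(mutations[keep, ])
  out$source_start <- out$start
  width <- out$end - out$start
  out$start <- new_start[keep]
  out$end <- out$start + pmax(width, 1L)
  # rewrite ref for relocated non-context-matched records from the genome
  non_ctx <- which(!matched[keep])
  if (length(non_ctx) > 0) {
    out$ref[non_ctx] <- vapply(non_ctx, function(j) {
      substr(genome[[out$chrom[j]]], out$start[j] + 1L, out$end[j])
    }, character(1))
  }
  out$context_matched <- matched[keep]
  out
}

#' Generate the simulated mutation sets
#'
#' Produces `n_sets` context-preserving shuffles of the observed catalog; the
#' k-th set is generated under seed `base_seed + k` so sets are independently
#' reproducible.
#'
#' @param mutations observed mutation tibble.
#' @param genome [read_genome()] result.
#' @param n_sets number of simulated sets (103 by default, the value that
#'   fixes the empirical p-value floor at 1/103).
#' @param base_seed integer seed base.
#' @param window,min_dist distance bounds in bp.
#' @param index optional precomputed [build_trinuc_index()].
#' @return Tibble of all simulated mutations with a `set_id` column in
#'   `1:n_sets`.
#' @export
make_simulated_sets <- function(mutations, genome, n_sets = 103L,
                                base_seed = 1L, window = 50000L,
                                min_dist = 50L, index = NULL) {
  stopifnot(n_sets >= 1)
  if (is.null(index)) index <- build_trinuc_index(genome)
  sets <- lapply(seq_len(n_sets), function(k) {
    set.seed(base_seed + k)
    out <- shuffle_mutations(mutations, genome, index,
                             window = window, min_dist = min_dist)
    out$set_id <- k
    out
  })
  purrr::list_rbind(sets)
}

#' Write simulated sets, one TSV per set
#' @param sim_sets tibble from [make_simulated_sets()].
#' @param dir output directory (`sim_<k>.tsv`).
#' @return The directory, invisibly.
#' @export
write_simulated_sets <- function(sim_sets, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (k in unique(sim_sets$set_id)) {
    write_mutations(sim_sets[sim_sets$set_id == k, ],
                    file.path(dir, sprintf("sim_%d.tsv", k)))
  }
  invisible(dir)
}
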