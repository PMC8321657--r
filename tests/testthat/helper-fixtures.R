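# shared toy fixtures and independent brute-force oracles

tiny_genome <- function(...) {
  seqs <- c(...)
  structure(toupper(seqs), class = "regmut_genome")
}

mut_row <- function(chrom, pos, ref, alt, sample = "S1", cancer = "Liver") {
  tibble::tibble(chrom = chrom, start = as.integer(pos),
                 end = as.integer(pos + nchar(ref)),
                 ref = ref, alt = alt, mut_class = mutation_class(ref, alt),
                 sample_id = sample, cancer_type = cancer)
}

# brute-force both-strand PWM scan: score every window directly
brute_scan <- function(genome, pfm, background = rep(0.25, 4),
                       pseudocount = 0.8) {
  pwm <- pfm_to_pwm(pfm, background, pseudocount)
  L <- nrow(pwm)
  revcomp_chr <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  out <- list()
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    n <- nchar(seq)
    if (n < L) next
    for (s in 0:(n - L)) {
      kmer <- substr(seq, s + 1, s + L)
      if (grepl("N", kmer)) next
      for (strand in c("+", "-")) {
        word <- if (strand == "+") kmer else revcomp_chr(kmer)
        letters <- strsplit(word, "")[[1]]
        score <- sum(vapply(seq_len(L), function(j) pwm[j, letters[j]],
                            numeric(1)))
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = chrom, start = s, end = s + L, strand = strand,
          score = score)
      }
    }
  }
  dplyr::bind_rows(out)
}

# exact null tail by enumerating all 4^L words under the background; the
# statistic is the per-position 1/1000-bit discretized log-odds score (the
# same quantity the scanner's dynamic program computes)
brute_pval <- function(pfm, score_bits, background = rep(0.25, 4),
                       pseudocount = 0.8) {
  pwm <- pfm_to_pwm(pfm, background, pseudocount)
  int_pwm <- round(pwm * 1000)
  L <- nrow(pwm)
  grid <- expand.grid(rep(list(1:4), L))
  probs <- apply(grid, 1, function(ix) prod(background[ix]))
  ints <- apply(grid, 1, function(ix) sum(int_pwm[cbind(seq_len(L), ix)]))
  vapply(score_bits, function(s) sum(probs[ints >= s]), numeric(1))
}

# discretized window score for a hit table produced by brute_scan
brute_int_score <- function(genome, pfm, hits, background = rep(0.25, 4),
                            pseudocount = 0.8) {
  int_pwm <- round(pfm_to_pwm(pfm, background, pseudocount) * 1000)
  L <- nrow(int_pwm)
  revcomp_chr <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  vapply(seq_len(nrow(hits)), function(i) {
    kmer <- substr(genome[[hits$chrom[i]]], hits$start[i] + 1,
                   hits$start[i] + L)
    word <- if (hits$strand[i] == "+") kmer else revcomp_chr(kmer)
    letters <- strsplit(word, "")[[1]]
    sum(int_pwm[cbind(seq_len(L), match(letters, c("A", "C", "G", "T")))])
  }, numeric(1))
}

# brute-force single-linkage interval clustering with gap threshold:
# relabel until no pair of clusters is linked by any interval pair
brute_single_linkage <- function(starts, ends, gap) {
  n <- length(starts)
  labels <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (labels[i] == labels[j]) next
      d <- max(starts[i], starts[j]) - min(ends[i], ends[j])
      if (d <= gap) {
        m <- min(labels[i], labels[j])
        labels[labels %in% c(labels[i], labels[j])] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  labels
}

# minimal one-TF scored-motif table for element tests
fake_scored <- function(motif_start, motif_end, score, sample = "S1",
                        chrom = "chr1", tf = "TF1", regulatory = TRUE,
                        delta = 0.5, matching_peak = TRUE, in_dhs = TRUE,
                        motif_position = 1L, set_id = NULL) {
  n <- length(motif_start)
  rec <- function(x) rep_len(x, n)
  out <- tibble::tibble(
    chrom = rec(chrom), start = as.integer(motif_start),
    end = as.integer(motif_start) + 1L,
    ref = "C", alt = "T", mut_class = "SNV",
    sample_id = rec(sample), cancer_type = "Liver", tf = rec(tf),
    motif_start = as.integer(motif_start), motif_end = as.integer(motif_end),
    strand = "+", motif_score = 10, motif_position = rec(as.integer(motif_position)),
    delta = rec(delta), matching_peak = rec(matching_peak), in_dhs = rec(in_dhs),
    tf_tpm = 5, regulatory_score = score, regulatory = rec(regulatory))
  if (!is.null(set_id)) out$set_id <- rec(set_id)
  out
}

# small scenario with one strongly mutated hotspot, used by several suites
hotspot_scenario <- function(seed = 11L, has_peak = TRUE, has_dhs = TRUE,
                             n_mutated = 10L, rate = 5e-5,
                             genome_length = 120000L, n_samples = 20L) {
  synthetic_scenario(
    genome_length = genome_length, n_chromosomes = 1L,
    motif_lengths = c(10L), n_instances_per_tf = 50L,
    n_samples_per_cancer_type = c(Liver = n_samples),
    background_mutation_rate = rate,
    planted_hotspots = tibble::tibble(
      tf = "TF1", n_mutated_samples = n_mutated, motif_position = 3L,
      has_peak = has_peak, has_dhs = has_dhs),
    rng_seed = seed)
}
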