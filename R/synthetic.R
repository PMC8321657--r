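#' Define a synthetic study scenario
#'
#' Describes a toy-scale study with known planted truth: a random genome with
#' planted motif instances, per-sample somatic mutations drawn from a
#' 96-context spectrum plus planted recurrent hotspots, cell-type-resolved
#' annotation tracks with controlled overlap, expression with planted cis
#' effects, CNVs, methylation and pathway sets.
#'
#' @param genome_length total bp per chromosome (default 200000).
#' @param n_chromosomes number of chromosomes (default 1).
#' @param gc_fraction genome GC content (default 0.41, human-like).
#' @param motif_lengths integer vector, one motif length per TF (default
#'   c(10, 12); TF names are TF1, TF2, ...).
#' @param n_instances_per_tf planted (decoy) motif instances per TF
#'   (default 40).
#' @param weak_instance_fraction fraction of planted instances carrying one
#'   mismatched base (default 0.7).  Real genome scans yield a broad
#'   matching-score distribution; the mismatched copies reproduce that spread
#'   so the per-TF Z-score filter retains the strong tail rather than a
#'   degenerate single-score set.  Hotspot instances are always full-strength.
#' @param n_cell_types annotation cell types (default 2).
#' @param n_samples_per_cancer_type named integer vector, samples per cancer
#'   type (default c(Liver = 20)).
#' @param spectrum 96-probability vector (or one row per cancer type as a
#'   matrix) over [context96_labels()]; default uniform.
#' @param background_mutation_rate mutations/bp/sample (default 1e-4).
#' @param planted_hotspots tibble with columns `tf`, `n_mutated_samples`,
#'   `motif_position` (1-based), `has_peak`, `has_dhs`; each hotspot occupies
#'   one planted instance of its TF.
#' @param planted_cis_effect additive log2 expression shift in mutated
#'   samples for the gene nearest each hotspot (default 1).
#' @param n_genes genes per chromosome, placed in a gene-dense tail region
#'   (default 4).
#' @param rng_seed integer seed (default 1).
#' @return List of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(genome_length = 200000L, n_chromosomes = 1L,
                               gc_fraction = 0.41,
                               motif_lengths = c(10L, 12L),
                               n_instances_per_tf = 40L,
                               weak_instance_fraction = 0.7,
                               n_cell_types = 2L,
                               n_samples_per_cancer_type = c(Liver = 20L),
                               spectrum = NULL,
                               background_mutation_rate = 1e-4,
                               planted_hotspots = NULL,
                               planted_cis_effect = 1,
                               n_genes = 4L,
                               rng_seed = 1L) {
  labs <- context96_labels()
  if (is.null(spectrum)) spectrum <- setNames(rep(1 / 96, 96), labs)
  if (is.null(dim(spectrum))) {
    spectrum <- matrix(spectrum, nrow = length(n_samples_per_cancer_type),
                       ncol = 96, byrow = TRUE,
                       dimnames = list(names(n_samples_per_cancer_type), labs))
  }
  if (any(abs(rowSums(spectrum) - 1) > 1e-9)) {
    abort("Each spectrum must sum to 1")
  }
  if (background_mutation_rate < 0) abort("Mutation rate must be >= 0")
  if (is.null(planted_hotspots)) {
    planted_hotspots <- tibble(tf = character(), n_mutated_samples = integer(),
                               motif_position = integer(), has_peak = logical(),
                               has_dhs = logical())
  }
  planted_hotspots <- as_tibble(planted_hotspots)
  tf_names <- paste0("TF", seq_along(motif_lengths))
  if (nrow(planted_hotspots) > 0) {
    if (!all(planted_hotspots$tf %in% tf_names)) {
      abort("Hotspot TFs must be among the scenario's TFs")
    }
    L <- setNames(motif_lengths, tf_names)
    if (any(planted_hotspots$motif_position < 1 |
            planted_hotspots$motif_position > L[planted_hotspots$tf])) {
      abort("Hotspot motif_position outside the motif")
    }
    if (any(planted_hotspots$n_mutated_samples > sum(n_samples_per_cancer_type))) {
      abort("Hotspot recurrence exceeds the number of samples")
    }
  }
  structure(list(
    genome_length = as.integer(genome_length),
    n_chromosomes = as.integer(n_chromosomes),
    gc_fraction = gc_fraction,
    motif_lengths = as.integer(motif_lengths),
    tf_names = tf_names,
    n_instances_per_tf = as.integer(n_instances_per_tf),
    weak_instance_fraction = weak_instance_fraction,
    n_cell_types = as.integer(n_cell_types),
    n_samples_per_cancer_type = n_samples_per_cancer_type,
    spectrum = spectrum,
    background_mutation_rate = background_mutation_rate,
    planted_hotspots = planted_hotspots,
    planted_cis_effect = planted_cis_effect,
    n_genes = as.integer(n_genes),
    rng_seed = as.integer(rng_seed)
  ), class = "synthetic_scenario")
}

random_genome <- function(n_chromosomes, genome_length, gc_fraction) {
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- vapply(seq_len(n_chromosomes), function(i) {
    paste(sample(DNA_BASES, genome_length, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
  structure(setNames(seqs, paste0("chr", seq_len(n_chromosomes))),
            class = "regmut_genome")
}

# strong-consensus PFM: 85 counts on the consensus base, 5 elsewhere
consensus_pfm <- function(consensus) {
  L <- nchar(consensus)
  m <- matrix(5, L, 4, dimnames = list(NULL, DNA_BASES))
  for (j in seq_len(L)) m[j, substr(consensus, j, j)] <- 85
  m
}

splice_into <- function(seq, start0, replacement) {
  paste0(substr(seq, 1, start0), replacement,
         substr(seq, start0 + nchar(replacement) + 1L, nchar(seq)))
}

#' Generate the full synthetic input bundle
#'
#' Deterministic given the scenario's `rng_seed`.  Background mutations are
#' drawn per the 96-context spectrum (a context category is sampled, then a
#' genomic position carrying that context on either strand); hotspot
#' mutations hit the planted motif instance at the planted position with the
#' most disruptive alternate allele; hotspot instances get matching peak/DHS
#' intervals in the matched cell type when flagged.
#'
#' @param scenario [synthetic_scenario()].
#' @return List of class `synthetic_bundle` with components `genome`, `pfms`,
#'   `instances` (planted motif instances), `mutations`, `bundle`
#'   ([annotation_bundle()]), `gene_models`, `expression`, `methylation`,
#'   `cnv_segments`, `gistic_peaks`, `pathways`, `contributions`, `catalog`,
#'   `cohorts`, `sample_map`, `config` and `truth` (planted ground truth).
#' @export
simulate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$rng_seed)
  sc <- scenario
  cancer_types <- names(sc$n_samples_per_cancer_type)
  samples <- purrr::imap(sc$n_samples_per_cancer_type, function(n, ct) {
    tibble(sample_id = sprintf("%s_S%02d", ct, seq_len(n)), cancer_type = ct)
  }) |> purrr::list_rbind()

  genome <- random_genome(sc$n_chromosomes, sc$genome_length, sc$gc_fraction)

  # motifs: a random consensus per TF, instances planted in the first 70% of
  # each chromosome (the tail is reserved for genes so hotspot elements stay
  # noncoding)
  consensi <- vapply(sc$motif_lengths, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))
  names(consensi) <- sc$tf_names
  pfms <- lapply(consensi, consensus_pfm)

  instances <- list()
  occupied <- integer(0)
  n_strong <- pmax(ceiling(sc$n_instances_per_tf *
                             (1 - sc$weak_instance_fraction)), 1L)
  for (tf in sc$tf_names) {
    L <- nchar(consensi[tf])
    placed <- 0L
    tries <- 0L
    while (placed < sc$n_instances_per_tf && tries < sc$n_instances_per_tf * 50L) {
      tries <- tries + 1L
      chrom <- sample(names(genome), 1L)
      lim <- floor(0.7 * chrom_lengths(genome)[[chrom]])
      start0 <- sample.int(lim - L - 200L, 1L) + 100L
      slots <- start0:(start0 + L - 1L)
      if (any(slots %in% occupied)) next
      occupied <- c(occupied, (start0 - 5L):(start0 + L + 4L))
      placed <- placed + 1L
      word <- consensi[tf]
      strong <- placed <= n_strong  # hotspots occupy the leading instances
      if (!strong) {
        # roughly one mismatch per 10 bp keeps weak copies clearly separated
        # from the consensus score yet still above the scan p-value gate
        for (j in sample.int(L, max(1L, round(L / 10)))) {
          word <- paste0(substr(word, 1, j - 1L),
                         sample(setdiff(DNA_BASES, substr(word, j, j)), 1L),
                         substr(word, j + 1L, L))
        }
      }
      genome[[chrom]] <- splice_into(genome[[chrom]], start0, word)
      instances[[length(instances) + 1L]] <-
        tibble(tf = tf, chrom = chrom, start = start0, end = start0 + L,
               strand = "+", strong = strong)
    }
  }
  instances <- purrr::list_rbind(instances)

  # hotspots occupy the first instances of their TF, in order
  hot <- sc$planted_hotspots
  hot_rows <- integer(nrow(hot))
  used <- integer(0)
  for (h in seq_len(nrow(hot))) {
    cand <- setdiff(which(instances$tf == hot$tf[h]), used)
    if (length(cand) == 0) abort("Not enough planted instances for hotspots")
    hot_rows[h] <- cand[1]
    used <- c(used, cand[1])
  }

  hotspot_muts <- if (nrow(hot) == 0) {
    new_mutation_tbl(character(), integer(), integer(), character(),
                     character(), character(), character())
  } else purrr::map(seq_len(nrow(hot)), function(h) {
    inst <- instances[hot_rows[h], ]
    pos <- inst$start + hot$motif_position[h] - 1L
    ref <- substr(genome[[inst$chrom]], pos + 1L, pos + 1L)
    ppm <- pfm_to_ppm(pfms[[inst$tf]])
    col <- ppm[hot$motif_position[h], ]
    alt <- names(which.min(col[setdiff(DNA_BASES, ref)]))
    mut_samples <- sample(samples$sample_id, hot$n_mutated_samples[h])
    new_mutation_tbl(inst$chrom, pos, pos + 1L, ref, alt, mut_samples,
                     samples$cancer_type[match(mut_samples, samples$sample_id)])
  }) |> purrr::list_rbind()

  background_muts <- draw_background_mutations(sc, genome, samples)
  mutations <- dplyr::bind_rows(hotspot_muts, background_muts) |>
    dplyr::arrange(.data$chrom, .data$start, .data$sample_id)

  # annotation tracks: matched cell per cancer type, hotspot-controlled overlap
  cells <- paste0("cell", seq_len(sc$n_cell_types))
  cell_map <- tibble(cancer_type = cancer_types,
                     cell_type = cells[((seq_along(cancer_types) - 1L) %%
                                          sc$n_cell_types) + 1L])
  peaks <- dhs <- cage <- list()
  for (h in seq_len(nrow(hot))) {
    inst <- instances[hot_rows[h], ]
    h_samples <- hotspot_muts$sample_id[hotspot_muts$start >= inst$start &
                                          hotspot_muts$start < inst$end &
                                          hotspot_muts$chrom == inst$chrom]
    cts <- unique(samples$cancer_type[samples$sample_id %in% h_samples])
    mcells <- unique(cell_map$cell_type[cell_map$cancer_type %in% cts])
    if (isTRUE(hot$has_peak[h])) {
      peaks[[length(peaks) + 1L]] <-
        tibble(cell_type = mcells, tf = inst$tf, chrom = inst$chrom,
               start = pmax(inst$start - 50L, 0L), end = inst$end + 50L)
    }
    if (isTRUE(hot$has_dhs[h])) {
      dhs[[length(dhs) + 1L]] <-
        tibble(cell_type = mcells, chrom = inst$chrom,
               start = pmax(inst$start - 100L, 0L), end = inst$end + 100L)
    }
  }
  peaks <- if (length(peaks)) purrr::list_rbind(peaks) else
    tibble(cell_type = character(), tf = character(), chrom = character(),
           start = integer(), end = integer())
  dhs <- if (length(dhs)) purrr::list_rbind(dhs) else
    tibble(cell_type = character(), chrom = character(),
           start = integer(), end = integer())

  # chromatin states: enhancer blocks over planted instances, quiescent rest
  states <- purrr::map(cells, function(cell) {
    purrr::map(names(genome), function(chrom) {
      len <- chrom_lengths(genome)[[chrom]]
      inst_c <- instances[instances$chrom == chrom, ]
      enh <- tibble(cell_type = cell, chrom = chrom,
                    start = pmax(inst_c$start - 20L, 0L),
                    end = pmin(inst_c$end + 20L, len), state = "Enh")
      enh <- enh[order(enh$start), ]
      # collapse overlapping enhancer blocks, fill gaps with Quies
      if (nrow(enh) > 0) {
        keep <- !duplicated(cummax(enh$end))
        gaps_start <- c(0L, enh$end)
        gaps_end <- c(enh$start, len)
      } else {
        gaps_start <- 0L
        gaps_end <- len
      }
      quies <- tibble(cell_type = cell, chrom = chrom, start = gaps_start,
                      end = gaps_end, state = "Quies")
      dplyr::bind_rows(enh, quies[quies$end > quies$start, ]) |>
        dplyr::arrange(.data$start)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  repdomains <- purrr::map(cells, function(cell) {
    purrr::map(names(genome), function(chrom) {
      len <- chrom_lengths(genome)[[chrom]]
      half <- len %/% 2L
      tibble(cell_type = cell, chrom = chrom,
             start = c(0L, half), end = c(half, len),
             domain = c("early", "late"))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  tf_expr <- tidyr::expand_grid(cell_type = cells, tf = sc$tf_names) |>
    dplyr::mutate(tpm = round(rlnorm(dplyr::n(), meanlog = 2, sdlog = 0.5), 2))

  # genes in the reserved 70-95% stretch of each chromosome
  gene_models <- synth_gene_models(genome, sc$n_genes)
  cage <- tibble(cell_type = rep(cells, each = nrow(gene_models$genes)),
                 chrom = rep(gene_models$genes$chrom, length(cells)),
                 start = rep(pmax(gene_models$genes$tss - 50L, 0L), length(cells)),
                 end = rep(gene_models$genes$tss + 50L, length(cells)))

  bundle <- annotation_bundle(peaks, dhs, states, cage, repdomains,
                              tf_expr, cell_map)

  # expression: log-normal with additive cis effect for hotspot-mutated samples
  genes <- gene_models$genes
  log_expr <- matrix(rnorm(nrow(genes) * nrow(samples), mean = 5, sd = 1),
                     nrow = nrow(genes),
                     dimnames = list(genes$gene_name, samples$sample_id))
  cis_genes <- character(0)
  for (h in seq_len(nrow(hot))) {
    inst <- instances[hot_rows[h], ]
    gch <- genes[genes$chrom == inst$chrom, ]
    if (nrow(gch) == 0) next
    nearest <- gch$gene_name[which.min(pmin(abs(gch$start - inst$end),
                                            abs(inst$start - gch$end)))]
    h_samples <- hotspot_muts$sample_id[hotspot_muts$chrom == inst$chrom &
                                          hotspot_muts$start >= inst$start &
                                          hotspot_muts$start < inst$end]
    log_expr[nearest, h_samples] <- log_expr[nearest, h_samples] +
      sc$planted_cis_effect
    cis_genes <- c(cis_genes, nearest)
  }
  expression <- round(2^log_expr, 3)

  methylation <- synth_methylation(genome, samples$sample_id)
  cnv <- synth_cnv(genome, samples$sample_id)
  pathways <- synth_pathways(genes$gene_name, cis_genes)
  sig <- synth_signatures(samples)

  cohorts <- dplyr::bind_rows(
    purrr::map(cancer_types, function(ct) {
      cohort_spec(ct, ct,
                  is_lymphoma_group = grepl("Lymph", ct),
                  is_melanoma_group = grepl("Melanoma|Skin", ct))
    }) |> purrr::list_rbind(),
    cohort_spec("ATELM",
                cancer_types[!grepl("Lymph|Melanoma|Skin", cancer_types)],
                is_meta = TRUE)
  )
  cohorts <- cohorts[lengths(cohorts$cancer_types) > 0, ]

  truth <- list(
    hotspots = dplyr::bind_cols(hot, instances[hot_rows, c("chrom", "start", "end")]),
    hotspot_samples = split(hotspot_muts$sample_id,
                            paste0(hotspot_muts$chrom, ":", hotspot_muts$start)),
    enriched_tfs = unique(hot$tf),
    cis_genes = unique(cis_genes),
    spectra = sc$spectrum,
    consensi = consensi
  )

  structure(list(genome = genome, pfms = pfms, instances = instances,
                 mutations = mutations, bundle = bundle,
                 gene_models = gene_models, expression = expression,
                 methylation = methylation, cnv_segments = cnv$segments,
                 gistic_peaks = cnv$peaks, pathways = pathways,
                 contributions = sig$contributions, catalog = sig$catalog,
                 cohorts = cohorts,
                 sample_map = samples, truth = truth),
            class = "synthetic_bundle")
}

# background SNVs: per sample Poisson(rate * genome size) mutations, each
# drawn by sampling a 96-category then a genomic position carrying that
# context on either strand; falls back to a uniform position (own context)
# when the requested context is absent from the genome
draw_background_mutations <- function(sc, genome, samples) {
  labs <- context96_labels()
  index <- build_trinuc_index(genome)
  genome_size <- sum(chrom_lengths(genome))
  chrom_names <- names(genome)
  out <- list()
  for (i in seq_len(nrow(samples))) {
    n_mut <- rpois(1, sc$background_mutation_rate * genome_size)
    if (n_mut == 0) next
    spectrum <- sc$spectrum[samples$cancer_type[i], ]
    cats <- sample(labs, n_mut, replace = TRUE, prob = spectrum)
    ctx <- paste0(substr(cats, 1, 1), substr(cats, 3, 3), substr(cats, 7, 7))
    ref_pyr <- substr(cats, 3, 3)
    alt_pyr <- substr(cats, 5, 5)
    rc_ctx <- revcomp(ctx)
    recs <- purrr::map(seq_len(n_mut), function(j) {
      pos_f <- unlist(lapply(chrom_names, function(ch) {
        p <- index[[ch]][[ctx[j]]]
        if (is.null(p)) return(NULL)
        setNames(p, rep(ch, length(p)))
      }))
      pos_r <- unlist(lapply(chrom_names, function(ch) {
        p <- index[[ch]][[rc_ctx[j]]]
        if (is.null(p)) return(NULL)
        setNames(p, rep(ch, length(p)))
      }))
      n_f <- length(pos_f)
      n_r <- length(pos_r)
      if (n_f + n_r == 0) {
        # fallback: uniform position, keep its own context
        ch <- sample(chrom_names, 1)
        p <- sample.int(chrom_lengths(genome)[[ch]] - 2L, 1L)
        ref <- substr(genome[[ch]], p + 1L, p + 1L)
        alt <- sample(setdiff(DNA_BASES, ref), 1)
        return(tibble(chrom = ch, pos = p, ref = ref, alt = alt))
      }
      k <- sample.int(n_f + n_r, 1L)
      if (k <= n_f) {
        tibble(chrom = names(pos_f)[k], pos = unname(pos_f[k]),
               ref = ref_pyr[j], alt = alt_pyr[j])
      } else {
        tibble(chrom = names(pos_r)[k - n_f], pos = unname(pos_r[k - n_f]),
               ref = complement_base(ref_pyr[j]),
               alt = complement_base(alt_pyr[j]))
      }
    }) |> purrr::list_rbind()
    out[[i]] <- new_mutation_tbl(recs$chrom, recs$pos, recs$pos + 1L,
                                 recs$ref, recs$alt, samples$sample_id[i],
                                 samples$cancer_type[i])
  }
  if (length(out) == 0) {
    return(new_mutation_tbl(character(), integer(), integer(), character(),
                            character(), character(), character()))
  }
  purrr::list_rbind(out)
}

synth_gene_models <- function(genome, n_genes) {
  genes <- cds <- utr <- list()
  for (chrom in names(genome)) {
    len <- chrom_lengths(genome)[[chrom]]
    region_start <- floor(0.72 * len)
    span <- floor(0.23 * len)
    if (n_genes == 0) next
    pitch <- span %/% max(n_genes, 1L)
    for (g in seq_len(n_genes)) {
      gs <- as.integer(region_start + (g - 1L) * pitch)
      glen <- min(3000L, pitch - 100L)
      ge <- gs + glen
      strand <- if (g %% 2 == 0) "-" else "+"
      id <- sprintf("G%s_%d", sub("chr", "", chrom), g)
      genes[[length(genes) + 1L]] <-
        tibble(gene_id = id, gene_name = id, chrom = chrom, start = gs,
               end = ge, strand = strand,
               tss = if (strand == "-") ge - 1L else gs,
               biotype = "protein_coding")
      u5 <- 200L; clen <- min(2000L, glen - 600L); u3 <- 300L
      if (strand == "+") {
        utr[[length(utr) + 1L]] <- tibble(gene_id = id, chrom = chrom,
                                          start = gs, end = gs + u5,
                                          utr_side = "5'UTR")
        cds[[length(cds) + 1L]] <- tibble(gene_id = id, chrom = chrom,
                                          start = gs + u5, end = gs + u5 + clen)
        utr[[length(utr) + 1L]] <- tibble(gene_id = id, chrom = chrom,
                                          start = ge - u3, end = ge,
                                          utr_side = "3'UTR")
      } else {
        utr[[length(utr) + 1L]] <- tibble(gene_id = id, chrom = chrom,
                                          start = ge - u5, end = ge,
                                          utr_side = "5'UTR")
        cds[[length(cds) + 1L]] <- tibble(gene_id = id, chrom = chrom,
                                          start = ge - u5 - clen, end = ge - u5)
        utr[[length(utr) + 1L]] <- tibble(gene_id = id, chrom = chrom,
                                          start = gs, end = gs + u3,
                                          utr_side = "3'UTR")
      }
    }
  }
  list(genes = purrr::list_rbind(genes), cds = purrr::list_rbind(cds),
       utr = purrr::list_rbind(utr))
}

# beta values from a two-component mixture: mostly unmethylated Beta(1, 9),
# a methylated Beta(9, 1) component, so the beta > 0.2 filter separates them
synth_methylation <- function(genome, sample_ids, max_cpgs = 200L) {
  cpgs <- purrr::map(names(genome), function(chrom) {
    hits <- stringr::str_locate_all(genome[[chrom]], "CG")[[1]][, 1]
    if (length(hits) > max_cpgs) hits <- sort(sample(hits, max_cpgs))
    tibble(chrom = chrom, pos = as.integer(hits - 1L))
  }) |> purrr::list_rbind()
  betas <- matrix(
    ifelse(runif(nrow(cpgs) * length(sample_ids)) < 0.3,
           rbeta(nrow(cpgs) * length(sample_ids), 9, 1),
           rbeta(nrow(cpgs) * length(sample_ids), 1, 9)),
    nrow = nrow(cpgs), dimnames = list(NULL, sample_ids))
  dplyr::bind_cols(cpgs, as_tibble(round(betas, 3)))
}

synth_cnv <- function(genome, sample_ids, n_segments = 10L) {
  lens <- chrom_lengths(genome)
  segs <- purrr::map(seq_len(n_segments), function(i) {
    chrom <- sample(names(genome), 1)
    w <- sample(2000:20000, 1)
    s <- sample.int(lens[[chrom]] - w, 1)
    tibble(sample_id = sample(sample_ids, 1), chrom = chrom,
           start = s, end = s + w,
           call = sample(c("amp", "del"), 1),
           stars = sample(1:3, 1))
  }) |> purrr::list_rbind()
  peaks <- purrr::map(names(genome), function(chrom) {
    tibble(chrom = chrom, start = floor(lens[[chrom]] * 0.4),
           end = floor(lens[[chrom]] * 0.45))
  }) |> purrr::list_rbind()
  list(segments = segs, peaks = peaks)
}

synth_pathways <- function(gene_names, cis_genes) {
  half <- ceiling(length(gene_names) / 2)
  tibble(
    pathway = c("pw_cancer", "pw_other"),
    description = c("synthetic cancer pathway", "synthetic control pathway"),
    genes = list(unique(c(cis_genes, gene_names[seq_len(half)])),
                 gene_names[(half + 1):length(gene_names)])
  )
}

# three synthetic SBS-like signatures and per-sample contribution tables
synth_signatures <- function(samples) {
  labs <- context96_labels()
  sig1 <- setNames(rep(1e-3, 96), labs)
  sig1[grepl("\\[C>T\\]", labs)] <- 0.05   # deamination-like
  sig2 <- setNames(rep(1e-3, 96), labs)
  sig2[grepl("\\[T>A\\]", labs)] <- 0.05
  sig3 <- setNames(rep(1 / 96, 96), labs)  # flat clock-like
  catalog <- cbind(SBS_A = sig1 / sum(sig1), SBS_B = sig2 / sum(sig2),
                   SBS_C = sig3 / sum(sig3))
  rownames(catalog) <- labs
  w <- matrix(stats::runif(nrow(samples) * 3, 0.1, 1), ncol = 3)
  w <- w / rowSums(w)
  contributions <- purrr::map(seq_len(nrow(samples)), function(i) {
    num <- sweep(catalog, 2, w[i, ], "*")
    prob <- num / pmax(rowSums(num), 1e-12)
    tibble(sample_id = samples$sample_id[i], category = "SBS",
           feature_type = rep(labs, 3),
           signature = rep(colnames(catalog), each = 96),
           contribution = as.vector(prob))
  }) |> purrr::list_rbind()
  list(catalog = catalog, contributions = contributions)
}

#' Write a synthetic bundle to disk in the package's input formats
#'
#' Emits exactly the formats the readers accept: FASTA genome, JASPAR PFMs,
#' mutation TSV, per-cell-type BED tracks, TF-expression TSV, GTF gene
#' models, expression/methylation/CNV/contribution TSVs, GISTIC BED, GMT
#' pathways, signature-catalog TSV and a cohort YAML.
#'
#' @param synth [simulate_scenario()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(synth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_genome(synth$genome, fp("genome.fa"))
  write_pfms(synth$pfms, fp("motifs.jaspar"))
  write_mutations(synth$mutations, fp("mutations.tsv"))
  b <- synth$bundle
  for (ct in unique(c(b$peaks$cell_type, b$dhs$cell_type, b$states$cell_type))) {
    if (any(b$peaks$cell_type == ct)) {
      write_track(b$peaks[b$peaks$cell_type == ct, ], fp(paste0("peaks_", ct, ".bed")))
    }
    if (any(b$dhs$cell_type == ct)) {
      write_track(dplyr::mutate(b$dhs[b$dhs$cell_type == ct, ], name = "DHS"),
                  fp(paste0("dhs_", ct, ".bed")))
    }
    write_track(b$states[b$states$cell_type == ct, ], fp(paste0("states_", ct, ".bed")))
    write_track(b$repdomains[b$repdomains$cell_type == ct, ],
                fp(paste0("repdomains_", ct, ".bed")))
  }
  readr::write_tsv(b$tf_expr, fp("tf_expression.tsv"), progress = FALSE)
  write_gtf(synth$gene_models, fp("genes.gtf"))
  write_expression(synth$expression, fp("expression.tsv"))
  readr::write_tsv(synth$methylation, fp("methylation.tsv"), progress = FALSE)
  readr::write_tsv(synth$cnv_segments, fp("cnv_segments.tsv"), progress = FALSE)
  write_track(dplyr::mutate(synth$gistic_peaks, name = "peak"), fp("gistic.bed"))
  write_gmt(synth$pathways, fp("pathways.gmt"))
  readr::write_tsv(synth$contributions, fp("signature_contributions.tsv"),
                   progress = FALSE)
  cat_tab <- dplyr::bind_cols(tibble(context = rownames(synth$catalog)),
                              as_tibble(synth$catalog))
  readr::write_tsv(cat_tab, fp("signature_catalog.tsv"), progress = FALSE)
  cohort_list <- setNames(lapply(seq_len(nrow(synth$cohorts)), function(i) {
    list(cancer_types = as.list(synth$cohorts$cancer_types[[i]]),
         is_lymphoma_group = synth$cohorts$is_lymphoma_group[i],
         is_melanoma_group = synth$cohorts$is_melanoma_group[i],
         is_meta = synth$cohorts$is_meta[i])
  }), synth$cohorts$cohort_id)
  yaml::write_yaml(cohort_list, fp("cohorts.yaml"))
  invisible(dir)
}

write_gtf <- function(gene_models, path) {
  fmt <- function(tab, type, extra = "") {
    sprintf('%s\tsynth\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s"; gene_biotype "%s";',
            tab$chrom, type, tab$start + 1L, tab$end, tab$strand, tab$gene_id,
            tab$gene_name, tab$biotype)
  }
  g <- gene_models$genes
  lines <- fmt(g, "gene")
  join_attrs <- function(tab) {
    m <- match(tab$gene_id, g$gene_id)
    tibble(chrom = tab$chrom, start = tab$start, end = tab$end,
           strand = g$strand[m], gene_id = tab$gene_id,
           gene_name = g$gene_name[m], biotype = g$biotype[m])
  }
  if (nrow(gene_models$cds) > 0) {
    lines <- c(lines, fmt(join_attrs(gene_models$cds), "CDS"))
  }
  if (nrow(gene_models$utr) > 0) {
    u <- join_attrs(gene_models$utr)
    type <- ifelse(gene_models$utr$utr_side == "5'UTR",
                   "five_prime_utr", "three_prime_utr")
    lines <- c(lines, sprintf('%s\tsynth\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                              u$chrom, type, u$start + 1L, u$end, u$strand,
                              u$gene_id, u$gene_name, u$biotype))
  }
  writeLines(lines, path)
  invisible(path)
}
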