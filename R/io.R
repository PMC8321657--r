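#' Read a reference genome from FASTA
#'
#' Sequences are uppercased; the alphabet is restricted to A/C/G/T/N.
#'
#' @param path FASTA file.
#' @return Named character vector, one uppercase sequence per chromosome,
#'   with class `regmut_genome`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' read_genome(fa)
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("No such FASTA file: ", path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) abort(paste0("Empty FASTA: ", path))
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(out))
  bad <- stringr::str_locate(out, "[^ACGTN]")[, 1]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    ch <- substr(out[i], bad[i], bad[i])
    abort(sprintf("Non-IUPAC character '%s' in sequence '%s' at position %d",
                  ch, names(out)[i], bad[i]))
  }
  structure(out, class = "regmut_genome")
}

#' Write a genome to FASTA
#' @param genome named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @export
print.regmut_genome <- function(x, ...) {
  cat(sprintf("<regmut_genome> %d sequence(s), %s bp total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  invisible(x)
}

chrom_lengths <- function(genome) nchar(unclass(genome))

#' Classify a variant by allele lengths
#'
#' @param ref,alt character vectors of reference/alternate alleles.
#' @return factor-like character vector in SNV/DNP/TNP/ONP/INS/DEL.
#' @export
mutation_class <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  dplyr::case_when(
    nr == na & nr == 1 ~ "SNV",
    nr == na & nr == 2 ~ "DNP",
    nr == na & nr == 3 ~ "TNP",
    nr == na ~ "ONP",
    na > nr ~ "INS",
    TRUE ~ "DEL"
  )
}

new_mutation_tbl <- function(chrom, start, end, ref, alt, sample_id, cancer_type) {
  tibble(
    chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
    mut_class = mutation_class(toupper(ref), toupper(alt)),
    sample_id = as.character(sample_id),
    cancer_type = as.character(cancer_type)
  )
}

#' Read somatic mutations from VCF or a 6-column TSV
#'
#' Accepts either a VCF (sample taken from the `SAMPLE` INFO key, or from a
#' supplied `sample_map` when records carry genotype columns) or a minimal TSV
#' with header `chrom, pos, ref, alt, sample_id, cancer_type` (1-based `pos`).
#' Coordinates are converted to the package's internal 0-based half-open
#' convention.  Indels of 100 bp or longer are rejected, with the removed
#' count reported.
#'
#' @param path input file; format chosen by extension unless `format` given.
#' @param sample_map data frame with columns `sample_id`, `cancer_type`.
#'   Required for VCF input and for TSV input lacking a `cancer_type` column.
#' @param genome optional [read_genome()] result; when given, reference
#'   alleles are validated against it and mismatches are an error.
#' @param format `"auto"`, `"vcf"` or `"tsv"`.
#' @return Tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `ref`, `alt`, `mut_class`, `sample_id`, `cancer_type`.
#' @export
read_mutations <- function(path, sample_map = NULL, genome = NULL,
                           format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  muts <- if (format == "vcf") read_mutations_vcf(path) else read_mutations_tsv(path)

  if (!"cancer_type" %in% names(muts) || all(is.na(muts$cancer_type))) {
    if (is.null(sample_map)) {
      abort("sample_map with sample_id/cancer_type is required for this input")
    }
    muts$cancer_type <- NULL
    missing <- setdiff(unique(muts$sample_id), sample_map$sample_id)
    if (length(missing) > 0) {
      abort(paste0("Sample(s) absent from sample_map: ",
                   paste(missing, collapse = ", ")))
    }
    muts <- dplyr::left_join(muts, as_tibble(sample_map), by = "sample_id")
  }

  indel_len <- pmax(nchar(muts$ref), nchar(muts$alt))
  long <- muts$mut_class %in% c("INS", "DEL") & indel_len >= 100
  if (any(long)) {
    message(sum(long), " indel(s) of length >= 100 bp rejected")
    muts <- muts[!long, ]
  }
  if (!is.null(genome)) validate_ref_alleles(muts, genome)
  muts[c("chrom", "start", "end", "ref", "alt", "mut_class",
         "sample_id", "cancer_type")]
}

read_mutations_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "sample_id")
  if (!all(need %in% names(tab))) {
    abort(paste0("Mutation TSV must carry columns ",
                 paste(need, collapse = ", ")))
  }
  if (!"cancer_type" %in% names(tab)) tab$cancer_type <- NA_character_
  new_mutation_tbl(tab$chrom, tab$pos - 1L, tab$pos - 1L + nchar(tab$ref),
                   tab$ref, tab$alt, tab$sample_id, tab$cancer_type)
}

read_mutations_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(new_mutation_tbl(character(), integer(), integer(),
                            character(), character(), character(), character()))
  }
  sample_id <- vcfR::extract.info(v, "SAMPLE")
  if (all(is.na(sample_id))) {
    abort("VCF records must carry a SAMPLE INFO key identifying the tumor")
  }
  pos <- as.integer(fix$POS)
  new_mutation_tbl(fix$CHROM, pos - 1L, pos - 1L + nchar(fix$REF),
                   fix$REF, fix$ALT, sample_id, NA_character_)
}

validate_ref_alleles <- function(muts, genome) {
  obs <- vapply(seq_len(nrow(muts)), function(i) {
    substr(genome[[muts$chrom[i]]], muts$start[i] + 1L, muts$end[i])
  }, character(1))
  bad <- which(obs != muts$ref)
  if (length(bad) > 0) {
    abort(paste0(
      "Reference allele mismatch at: ",
      paste(sprintf("%s:%d %s!=%s", muts$chrom[bad], muts$start[bad] + 1L,
                    muts$ref[bad], obs[bad])[seq_len(min(5, length(bad)))],
            collapse = "; "),
      if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else ""))
  }
  invisible(muts)
}

#' Write mutations as a 6-column TSV
#'
#' Positions are written 1-based in a column named `pos` (the internal
#' representation is 0-based half-open).
#' @param mutations mutation tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(mutations, path) {
  out <- tibble(chrom = mutations$chrom, pos = mutations$start + 1L,
                ref = mutations$ref, alt = mutations$alt,
                sample_id = mutations$sample_id,
                cancer_type = mutations$cancer_type)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR text layout: a `>identifier name` header followed by four
#' rows (A, C, G, T) of non-negative counts, with or without brackets.
#'
#' @param path JASPAR text file.
#' @return Named list of L x 4 numeric matrices (rows = motif positions,
#'   columns = A, C, G, T), names taken from the header's TF name.
#' @export
read_pfms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) abort(paste0("No JASPAR headers ('>') in ", path))
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i]
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    block <- lines[(from + 1):to]
    if (length(block) != 4) {
      abort(sprintf("Motif block %d in %s has %d rows; expected 4 (A,C,G,T)",
                    i, path, length(block)))
    }
    header <- sub("^>\\s*", "", lines[from])
    parts <- strsplit(header, "\\s+")[[1]]
    name <- if (length(parts) >= 2) parts[2] else parts[1]
    rows <- lapply(block, function(l) {
      l <- sub("^\\s*[ACGTacgt]\\s*", "", l)
      l <- gsub("\\[|\\]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    len <- unique(lengths(rows))
    if (length(len) != 1) {
      abort(sprintf("Motif '%s': rows of unequal length (%s)",
                    name, paste(lengths(rows), collapse = ",")))
    }
    m <- t(do.call(rbind, rows))
    colnames(m) <- DNA_BASES
    if (any(is.na(m)) || any(m < 0)) {
      abort(sprintf("Motif '%s': counts must be non-negative numbers", name))
    }
    out[[name]] <- m
  }
  out
}

#' Write PFMs in JASPAR text format
#' @param pfms named list of L x 4 count matrices.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pfms <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(pfms)) {
    m <- pfms[[nm]]
    writeLines(paste0(">", nm, " ", nm), con)
    for (b in DNA_BASES) {
      writeLines(sprintf("%s [ %s ]", b, paste(m[, b], collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read an annotation track (BED or bedGraph)
#'
#' BED input is 0-based half-open and stays so internally.  The `kind`
#' controls the name column's meaning: `peak` tracks label intervals with the
#' bound TF, `state` tracks with a chromatin-state label, `repdomain` with a
#' replication-domain class; `dhs` and `cage` need no label.
#'
#' @param path BED4/BED6 or bedGraph file.
#' @param kind one of `"peak"`, `"dhs"`, `"state"`, `"cage"`, `"repdomain"`,
#'   `"signal"` (bedGraph).
#' @return Tibble `chrom`, `start`, `end` plus `tf` (peak), `state`,
#'   `domain` (repdomain) or `value` (signal) as appropriate.
#' @export
read_track <- function(path, kind = c("peak", "dhs", "state", "cage",
                                      "repdomain", "signal")) {
  kind <- match.arg(kind)
  fmt <- if (kind == "signal") "bedGraph" else "bed"
  gr <- rtracklayer::import(path, format = fmt)
  tab <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  if (kind == "signal") {
    tab$value <- gr$score
  } else if (!is.null(gr$name)) {
    label <- as.character(gr$name)
    if (kind == "peak") tab$tf <- label
    if (kind == "state") tab$state <- label
    if (kind == "repdomain") tab$domain <- label
  } else if (kind %in% c("peak", "state", "repdomain")) {
    abort(sprintf("'%s' track %s needs a BED name column", kind, path))
  }
  if (kind == "state") check_state_conflicts(tab)
  tab
}

check_state_conflicts <- function(tab) {
  tab <- dplyr::arrange(tab, .data$chrom, .data$start)
  by_chrom <- split(tab, tab$chrom)
  for (ct in by_chrom) {
    if (nrow(ct) < 2) next
    ov <- ct$start[-1] < ct$end[-nrow(ct)]
    conflict <- ov & ct$state[-1] != ct$state[-nrow(ct)]
    if (any(conflict)) {
      i <- which(conflict)[1] + 1
      abort(sprintf(
        "Conflicting chromatin-state labels overlap at %s:%d ('%s' vs '%s')",
        ct$chrom[i], ct$start[i], ct$state[i - 1], ct$state[i]))
    }
  }
  invisible(tab)
}

#' Write an interval table as BED (0-based half-open)
#' @param tab tibble with `chrom`, `start`, `end` and optionally a label
#'   column (`tf`, `state`, `domain` or `name`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_track <- function(tab, path) {
  label_col <- intersect(c("tf", "state", "domain", "name"), names(tab))[1]
  name <- if (!is.na(label_col)) tab[[label_col]] else rep(".", nrow(tab))
  bed <- tibble(chrom = tab$chrom, start = tab$start, end = tab$end, name = name)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param path GMT file (`id <tab> description <tab> gene1 <tab> ...`).
#' @return Tibble with columns `pathway`, `description` and list-column `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    pathway = map_chr(parts, 1),
    description = map_chr(parts, 2),
    genes = map(parts, ~ .x[-(1:2)])
  )
}

#' Write gene sets as GMT
#' @param pathways tibble from [read_gmt()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(seq_len(nrow(pathways)), function(i) {
    paste(c(pathways$pathway[i], pathways$description[i],
            pathways$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GTF/GFF
#'
#' Extracts genes, CDS and UTR features into interval tables.  `gene`
#' features need `gene_id` (and optionally `gene_name`, `gene_biotype` /
#' `gene_type`) attributes.
#'
#' @param path GTF or GFF3 file.
#' @return List of tibbles: `genes` (`gene_id`, `gene_name`, `chrom`, `start`,
#'   `end`, `strand`, `tss`, `biotype`), `cds` and `utr` (`gene_id`, `chrom`,
#'   `start`, `end`, `utr_side` for utr).  All coordinates 0-based half-open.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  tab <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = as.character(gr$gene_id)
  )
  tab$gene_name <- if (!is.null(gr$gene_name)) as.character(gr$gene_name) else tab$gene_id
  bt <- gr$gene_biotype %||% gr$gene_type
  tab$biotype <- if (!is.null(bt)) as.character(bt) else "protein_coding"

  genes <- tab |>
    dplyr::filter(.data$type == "gene") |>
    dplyr::mutate(tss = ifelse(.data$strand == "-", .data$end - 1L, .data$start)) |>
    dplyr::select("gene_id", "gene_name", "chrom", "start", "end",
                  "strand", "tss", "biotype")
  cds <- tab |>
    dplyr::filter(.data$type == "CDS") |>
    dplyr::select("gene_id", "chrom", "start", "end")
  utr <- tab |>
    dplyr::filter(.data$type %in% c("five_prime_utr", "three_prime_utr",
                                    "five_prime_UTR", "three_prime_UTR", "UTR")) |>
    dplyr::mutate(utr_side = ifelse(grepl("five", .data$type, ignore.case = TRUE),
                                    "5'UTR", "3'UTR")) |>
    dplyr::select("gene_id", "chrom", "start", "end", "utr_side")
  list(genes = genes, cds = cds, utr = utr)
}

#' Read an expression matrix (genes x samples TSV)
#' @param path TSV whose first column is `gene_id`, remaining columns samples.
#' @return Numeric matrix, rownames = genes, colnames = samples.
#' @export
read_expression <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' Write an expression matrix as TSV
#' @param expr numeric matrix with gene rownames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  tab <- dplyr::bind_cols(tibble(gene_id = rownames(expr)),
                          as_tibble(expr))
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a methylation beta-value table
#' @param path TSV with `chrom`, `pos` (0-based CpG cytosine position) and one
#'   beta column per patient.
#' @return Tibble as in the file.
#' @export
read_methylation <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read CNV segments (SEG-like TSV)
#' @param path TSV with `sample_id`, `chrom`, `start`, `end`, `call`
#'   (amp/del), `stars` (confidence 1-3).
#' @return Tibble as in the file, coordinates 0-based half-open.
#' @export
read_cnv_segments <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a per-sample signature-contribution table
#' @param path TSV with columns `sample_id`, `category` (SBS/DBS),
#'   `feature_type` (96-context label or dinucleotide substitution),
#'   `signature`, `contribution`.
#' @return Tibble as in the file.
#' @export
read_signature_contributions <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (any(tab$contribution < 0)) abort("Signature contributions must be >= 0")
  tab
}

#' Read a 96-context signature catalog
#' @param path TSV whose first column (`context`) holds the 96 labels
#'   (e.g. `A[C>T]G`) and remaining columns one signature each.
#' @return Numeric 96 x S matrix with context rownames.
#' @export
read_signature_catalog <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m[context96_labels(), , drop = FALSE]
}
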