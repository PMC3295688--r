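#' Read a genome from a FASTA file
#'
#' Sequences are uppercased on read and must contain only A, C, G, T or N.
#' Record names must be unique and sequences non-empty.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A [Biostrings::DNAStringSet], one element per chromosome.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "cistromer_io_error")
  }
  # read as raw strings first: the DNA reader silently drops letters
  # outside the alphabet, which must be a validation error instead
  g <- Biostrings::readBStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  validate_genome(stats::setNames(as.character(g), names(g)))
}

#' Write a genome to a FASTA file
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  genome <- validate_genome(genome)
  con <- file(path, "w")
  on.exit(close(con))
  chars <- genome_chars(genome)
  for (nm in names(chars)) {
    writeLines(paste0(">", nm), con)
    s <- chars[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

validate_genome <- function(genome) {
  chars <- if (is.character(genome)) genome else
    stats::setNames(as.character(genome), names(genome))
  if (length(chars) == 0 || any(nchar(chars) == 0)) {
    abort("genome records must be non-empty", class = "cistromer_io_error")
  }
  if (is.null(names(chars)) || anyDuplicated(names(chars))) {
    abort("chromosome names must be present and unique",
          class = "cistromer_io_error")
  }
  chars <- toupper(chars)
  if (any(grepl("[^ACGTN]", chars))) {
    abort("genome contains characters outside {A,C,G,T,N}",
          class = "cistromer_io_error")
  }
  stats::setNames(Biostrings::DNAStringSet(chars), names(chars))
}

#' Read intervals, tags, or peaks from a BED file
#'
#' Coordinates are 0-based half-open, as in the BED standard, and the input
#' row order is preserved. `kind = "tag"` requires a 6-column BED with a
#' strand column; `kind = "peak"` reads, when present, column 5 as the peak
#' score (-log10 enrichment p), column 7 as the summit offset from `start`,
#' column 8 as fold enrichment and column 9 as the FDR.
#'
#' @param path Path to a BED file (whitespace separated, no header).
#' @param kind One of `"interval"`, `"tag"`, `"peak"`.
#' @param genome Optional genome; when supplied, coordinates are checked
#'   against chromosome bounds.
#' @return A tibble of intervals, tags, or peaks.
#' @export
read_bed <- function(path, kind = c("interval", "tag", "peak"),
                     genome = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "cistromer_io_error")
  }
  raw <- readr::read_table(path, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (nrow(raw) == 0) {
    return(empty_bed(kind))
  }
  if (ncol(raw) < 3) {
    abort("BED lines need at least 3 columns", class = "cistromer_io_error")
  }
  x <- tibble(
    chrom = raw[[1]],
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]])
  )
  if (any(is.na(x$start)) || any(is.na(x$end))) {
    abort("non-numeric BED coordinates", class = "cistromer_io_error")
  }
  if (any(x$start >= x$end)) {
    abort("BED intervals must satisfy start < end",
          class = "cistromer_io_error")
  }
  if (ncol(raw) >= 4) x$name <- raw[[4]]
  if (kind == "tag") {
    if (ncol(raw) < 6) {
      abort("tag BED requires a strand column (6 columns)",
            class = "cistromer_io_error")
    }
    x$strand <- raw[[6]]
    if (!all(x$strand %in% c("+", "-"))) {
      abort("tag strand must be '+' or '-'", class = "cistromer_io_error")
    }
  }
  if (kind == "peak") {
    x$score <- if (ncol(raw) >= 5) as.numeric(raw[[5]]) else NA_real_
    offset <- if (ncol(raw) >= 7) as.integer(raw[[7]]) else
      (x$end - x$start) %/% 2L
    x$summit <- x$start + offset
    x$fold_enrichment <- if (ncol(raw) >= 8) as.numeric(raw[[8]]) else NA_real_
    x$fdr <- if (ncol(raw) >= 9) as.numeric(raw[[9]]) else NA_real_
    if (!"name" %in% names(x)) x$name <- paste0("peak_", seq_len(nrow(x)))
    x <- x[, c("chrom", "start", "end", "name", "score", "summit",
               "fold_enrichment", "fdr")]
    check_peaks(x)
  }
  if (!is.null(genome)) check_bounds(x, genome)
  x
}

empty_bed <- function(kind) {
  base <- tibble(chrom = character(), start = integer(), end = integer())
  switch(kind,
    interval = base,
    tag = mutate(base, name = character(), strand = character()),
    peak = mutate(base, name = character(), score = numeric(),
                  summit = integer(), fold_enrichment = numeric(),
                  fdr = numeric())
  )
}

#' Write intervals, tags, or peaks to a BED file
#'
#' Tags are written as BED6 (`name`, score 0, strand); peaks as BED6 plus
#' summit offset, fold enrichment and FDR columns (summit serialized as an
#' offset from `start`); plain intervals as BED3/BED4.
#'
#' @param x A tibble of intervals, tags, or peaks.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (nrow(x) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  nm <- if ("name" %in% names(x)) x$name else paste0("iv_", seq_len(nrow(x)))
  out <- if ("summit" %in% names(x)) {
    check_peaks(x)
    data.frame(x$chrom, x$start, x$end, nm,
               round(if (is.null(x$score)) 0 else x$score, 4), ".",
               x$summit - x$start,
               round(x$fold_enrichment %||% NA_real_, 4),
               signif(x$fdr %||% NA_real_, 4))
  } else if ("strand" %in% names(x)) {
    data.frame(x$chrom, x$start, x$end, nm, 0L, x$strand)
  } else {
    data.frame(x$chrom, x$start, x$end, nm)
  }
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Convert a per-base coverage vector to a run-length track
#'
#' @param values Numeric vector of per-base coverage starting at position 0.
#' @param chrom Chromosome name for the resulting records.
#' @return A tibble with columns `chrom`, `start`, `end`, `value` in which
#'   consecutive equal values are merged into single records.
#' @export
as_coverage_track <- function(values, chrom = "chr1") {
  if (length(values) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  value = numeric()))
  }
  r <- rle(values)
  ends <- cumsum(r$lengths)
  tibble(chrom = chrom, start = as.integer(ends - r$lengths),
         end = as.integer(ends), value = as.numeric(r$values))
}

#' Write a coverage track in bedGraph format
#'
#' Zero-valued runs are omitted and adjacent equal-valued records merged,
#' so the file is the minimal run-length encoding of the track.
#'
#' @param track Tibble with columns `chrom`, `start`, `end`, `value`;
#'   records must be sorted by start within chromosome and non-overlapping.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  need <- c("chrom", "start", "end", "value")
  if (!all(need %in% names(track))) {
    abort("track must have columns chrom, start, end, value",
          class = "cistromer_io_error")
  }
  if (any(!is.finite(track$value)) || any(track$value < 0)) {
    abort("coverage values must be finite and non-negative",
          class = "cistromer_io_error")
  }
  for (ch in unique(track$chrom)) {
    s <- track[track$chrom == ch, ]
    if (is.unsorted(s$start) || any(s$start[-1] < s$end[-nrow(s)])) {
      abort("track records must be sorted and non-overlapping",
            class = "cistromer_io_error")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in unique(track$chrom)) {
    s <- track[track$chrom == ch & track$value != 0, ]
    if (nrow(s) == 0) next
    # merge touching runs with equal value
    keep_start <- c(TRUE, !(s$start[-1] == s$end[-nrow(s)] &
                              s$value[-1] == s$value[-nrow(s)]))
    grp <- cumsum(keep_start)
    m <- s |>
      mutate(grp = grp) |>
      group_by(grp) |>
      summarise(start = min(.data$start), end = max(.data$end),
                value = .data$value[1], .groups = "drop")
    writeLines(paste(ch, m$start, m$end,
                     format(m$value, trim = TRUE, scientific = FALSE)), con)
  }
  invisible(path)
}

#' Read and write gene models (refFlat-like TSV)
#'
#' The table has one row per gene model with columns `gene_id`, `chrom`,
#' `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end`, `exon_starts`,
#' `exon_ends`; exon coordinates are comma-separated lists, 0-based
#' half-open, one entry per exon.
#'
#' @param path Path to the TSV file.
#' @return A tibble with list-columns `exon_starts` and `exon_ends`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "cistromer_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), chrom = readr::col_character(),
    strand = readr::col_character(), tx_start = readr::col_integer(),
    tx_end = readr::col_integer(), cds_start = readr::col_integer(),
    cds_end = readr::col_integer(), exon_starts = readr::col_character(),
    exon_ends = readr::col_character()
  ), progress = FALSE)
  raw$exon_starts <- lapply(strsplit(raw$exon_starts, ","), as.integer)
  raw$exon_ends <- lapply(strsplit(raw$exon_ends, ","), as.integer)
  check_gene_models(raw)
  raw
}

#' @rdname read_gene_models
#' @param genes Gene-model tibble.
#' @export
write_gene_models <- function(genes, path) {
  check_gene_models(genes)
  out <- genes
  out$exon_starts <- vapply(genes$exon_starts, paste, "", collapse = ",")
  out$exon_ends <- vapply(genes$exon_ends, paste, "", collapse = ",")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write expression tables
#'
#' Two-column TSV (`gene_id`, `fold_change`); the rank column (1 = largest
#' fold change under the chosen ordering) is recomputed on read.
#'
#' @param path Path to the TSV file.
#' @return Tibble with `gene_id`, `fold_change`, `rank`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "cistromer_io_error")
  }
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    fold_change = readr::col_double()
  ), progress = FALSE)
  if (anyDuplicated(x$gene_id)) {
    abort("duplicate gene ids in expression table",
          class = "cistromer_io_error")
  }
  x$rank <- rank_expression(x$fold_change)
  arrange(x, .data$rank)
}

#' @rdname read_expression
#' @param expression Expression tibble (`gene_id`, `fold_change`).
#' @export
write_expression <- function(expression, path) {
  readr::write_tsv(expression[, c("gene_id", "fold_change")], path,
                   progress = FALSE)
  invisible(path)
}

# Ranks: 1 = largest value; ties broken by original order (stable).
rank_expression <- function(values) {
  ord <- order(-values)
  r <- integer(length(values))
  r[ord] <- seq_along(values)
  r
}
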