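# Internal helpers shared across modules.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Derive a reproducible stage seed from a global seed
#'
#' Hashes a stage label together with a global seed so that pipeline stages
#' draw from independent, individually reproducible RNG streams. The result
#' is always a positive integer below 2^31.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "simulate")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.double(seed) %% m
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  as.integer(h %% (m - 1) + 1)
}

chrom_lengths_of <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

# Genome as named character vector (uppercase strings).
genome_chars <- function(genome) {
  stats::setNames(as.character(genome), names(genome))
}

# Map a DNA string to integer codes A=1 C=2 G=3 T=4, anything else NA.
BASE_CODE <- local({
  v <- rep(NA_integer_, 127)
  v[utf8ToInt("A")] <- 1L
  v[utf8ToInt("C")] <- 2L
  v[utf8ToInt("G")] <- 3L
  v[utf8ToInt("T")] <- 4L
  v
})

seq_to_int <- function(s) BASE_CODE[utf8ToInt(s)]

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Validate a tag tibble; optionally against a genome's chromosome bounds.
check_tags <- function(tags, genome = NULL) {
  need <- c("chrom", "start", "end", "strand")
  if (!all(need %in% names(tags))) {
    abort("tags must have columns chrom, start, end, strand",
          class = "cistromer_bad_input")
  }
  if (any(tags$start >= tags$end)) {
    abort("tag intervals must satisfy start < end (0-based half-open)",
          class = "cistromer_bad_input")
  }
  if (!all(tags$strand %in% c("+", "-"))) {
    abort("tag strand must be '+' or '-'", class = "cistromer_bad_input")
  }
  if (!is.null(genome)) check_bounds(tags, genome)
  invisible(tags)
}

check_peaks <- function(peaks, genome = NULL) {
  need <- c("chrom", "start", "end", "summit")
  if (!all(need %in% names(peaks))) {
    abort("peaks must have columns chrom, start, end, summit",
          class = "cistromer_bad_input")
  }
  bad <- peaks$summit < peaks$start | peaks$summit >= peaks$end
  if (any(bad)) {
    abort("every peak summit must lie inside [start, end)",
          class = "cistromer_bad_input")
  }
  if (!is.null(genome)) check_bounds(peaks, genome)
  invisible(peaks)
}

check_bounds <- function(x, genome) {
  lens <- chrom_lengths_of(genome)
  unknown <- setdiff(unique(x$chrom), names(lens))
  if (length(unknown)) {
    abort(paste0("chromosome(s) not in genome: ",
                 paste(unknown, collapse = ", ")),
          class = "cistromer_bad_input")
  }
  if (any(x$start < 0) || any(x$end > lens[x$chrom])) {
    abort("interval outside chromosome bounds", class = "cistromer_bad_input")
  }
  invisible(x)
}

check_gene_models <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
            "cds_start", "cds_end", "exon_starts", "exon_ends")
  if (!all(need %in% names(genes))) {
    abort("gene models lack required columns", class = "cistromer_bad_input")
  }
  with(genes, {
    if (any(tx_start >= tx_end)) {
      abort("gene models must satisfy tx_start < tx_end",
            class = "cistromer_bad_input")
    }
    if (any(cds_start < tx_start | cds_end > tx_end | cds_start > cds_end)) {
      abort("CDS must lie within the transcript and be non-inverted",
            class = "cistromer_bad_input")
    }
  })
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_starts[[i]]
    ee <- genes$exon_ends[[i]]
    if (length(es) == 0 || length(es) != length(ee) ||
        any(es >= ee) || is.unsorted(es, strictly = TRUE) ||
        any(es < genes$tx_start[i]) || any(ee > genes$tx_end[i]) ||
        (length(es) > 1 && any(es[-1] < ee[-length(ee)]))) {
      abort(paste0("invalid exon structure for gene ", genes$gene_id[i]),
            class = "cistromer_bad_input")
    }
  }
  invisible(genes)
}

#' Transcription start sites of gene models
#'
#' The TSS is the first transcribed base: `tx_start` for a plus-strand
#' gene and `tx_end - 1` for a minus-strand gene (0-based coordinates).
#'
#' @param genes Gene-model tibble (see [read_gene_models()]).
#' @return Integer vector of TSS positions, one per gene.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
}

# Extract sequences for intervals from a genome; strand-aware when a
# `strand` column is present (minus-strand intervals are reverse-complemented).
extract_sequences <- function(genome, intervals) {
  check_bounds(intervals, genome)
  chars <- genome_chars(genome)
  out <- substring(chars[intervals$chrom], intervals$start + 1, intervals$end)
  if ("strand" %in% names(intervals)) {
    neg <- intervals$strand == "-"
    if (any(neg)) out[neg] <- revcomp_chr(out[neg])
  }
  unname(out)
}
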