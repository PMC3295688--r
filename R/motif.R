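#' Exhaustive enriched k-mer discovery
#'
#' A deterministic stand-in for probabilistic motif discovery: every k-mer
#' occurring in the peak sequences is counted in canonical form (the
#' lexicographically smaller of the k-mer and its reverse complement) and
#' scored by the ratio of its observed frequency to its expected frequency
#' under a base-composition (0-order) model of the background sequences
#' (raw background counts of any single k-mer are too sparse at useful k
#' to divide by). The top-ratio canonical k-mer is reported, along with
#' every occurrence and its strand.
#'
#' @param peak_sequences Character vector of peak DNA sequences (>= 10).
#' @param k Motif width (>= 4).
#' @param background_sequences Character vector of background DNA
#'   sequences (e.g. size-matched random genomic segments).
#' @param min_count Minimum occurrence count for a k-mer to be considered.
#' @return A `kmer_result` list: `consensus` (canonical form), `ratio`,
#'   `n_occurrences`, and `occurrences` — a tibble with `seq_index`,
#'   `start` (0-based offset within the sequence), `strand` (orientation
#'   of the consensus at that position) and `site` (the oriented k-mer).
#' @export
find_enriched_kmer <- function(peak_sequences, k = 9L,
                               background_sequences, min_count = 3L) {
  k <- as.integer(k)
  if (k < 4) abort("k must be >= 4", class = "cistromer_bad_input")
  if (length(peak_sequences) < 10) {
    abort("need at least 10 peak sequences", class = "cistromer_bad_input")
  }
  if (any(nchar(peak_sequences) < k)) {
    abort("all peak sequences must be at least k long",
          class = "cistromer_bad_input")
  }
  obs <- canonical_kmer_counts(peak_sequences, k)
  if (sum(obs$counts) == 0) {
    abort("no scoreable k-mer windows in peak sequences",
          class = "cistromer_bad_input")
  }
  obs_total <- sum(obs$counts)
  obs$counts <- obs$counts[obs$counts >= min_count]
  if (length(obs$counts) == 0) {
    abort("no k-mer reaches min_count", class = "cistromer_bad_input")
  }
  # expected canonical frequency from the background base composition
  # (0-order model): smooth where raw counts of any one k-mer are sparse
  base_freq <- background_base_freq(background_sequences)
  expected <- vapply(names(obs$counts), function(km) {
    p <- prod(base_freq[strsplit(km, "")[[1]]])
    rc <- revcomp_chr(km)
    if (rc != km) p <- p + prod(base_freq[strsplit(rc, "")[[1]]])
    p
  }, numeric(1))
  ratio <- (obs$counts / obs_total) / expected
  best <- names(obs$counts)[which.max(ratio)]
  occ <- kmer_occurrences(peak_sequences, best, k)
  structure(list(consensus = best, k = k, ratio = max(ratio),
                 n_occurrences = nrow(occ), occurrences = occ),
            class = "kmer_result")
}

#' Nucleotide-shuffle sequences
#'
#' Independently permutes the letters of each sequence, preserving its
#' exact base composition while destroying positional structure — the
#' standard null for motif discovery backgrounds.
#'
#' @param seqs Character vector of DNA sequences.
#' @param seed Integer seed.
#' @return Character vector of shuffled sequences.
#' @export
shuffle_sequences <- function(seqs, seed = 1L) {
  with_seed(seed, {
    vapply(seqs, function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, "", USE.NAMES = FALSE)
  })
}

# Single-base composition of the background sequences (A/C/G/T, sums to 1).
background_base_freq <- function(seqs) {
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(seqs))[, c("A", "C", "G", "T"), drop = FALSE])
  if (sum(counts) == 0) {
    abort("background sequences contain no A/C/G/T bases",
          class = "cistromer_bad_input")
  }
  counts / sum(counts)
}

canonical_form <- function(kmers) {
  rc <- revcomp_chr(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

all_kmers_of <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

canonical_kmer_counts <- function(seqs, k) {
  km <- unlist(lapply(seqs, all_kmers_of, k = k), use.names = FALSE)
  km <- km[!grepl("N", km, fixed = TRUE)]
  counts <- table(canonical_form(km))
  list(counts = c(counts))
}

kmer_occurrences <- function(seqs, consensus, k) {
  rc <- revcomp_chr(consensus)
  rows <- lapply(seq_along(seqs), function(i) {
    km <- all_kmers_of(seqs[i], k)
    fwd <- which(km == consensus)
    rev <- which(km == rc & km != consensus)
    tibble(seq_index = i,
           start = as.integer(c(fwd, rev) - 1L),
           strand = rep(c("+", "-"), c(length(fwd), length(rev))),
           site = consensus)
  })
  arrange(bind_rows(rows), .data$seq_index, .data$start)
}

#' Build a position weight matrix from aligned occurrences
#'
#' @param occurrences Character vector of equal-length aligned site
#'   sequences (oriented), or the `occurrences` tibble of a
#'   [find_enriched_kmer()] result.
#' @param pseudocount Pseudocount added per letter and position.
#' @return A `pwm` object: `width`, `probs` (4 x width matrix, rows
#'   A/C/G/T, columns summing to 1), `pseudocount`, `consensus`
#'   (per-position argmax).
#' @export
build_pwm <- function(occurrences, pseudocount = 0.5) {
  if (is.data.frame(occurrences)) occurrences <- occurrences$site
  if (length(occurrences) == 0) {
    abort("no occurrences to build a PWM from", class = "cistromer_bad_input")
  }
  w <- unique(nchar(occurrences))
  if (length(w) != 1) {
    abort("occurrences must all have the same length",
          class = "cistromer_bad_input")
  }
  mat <- matrix(0, nrow = 4, ncol = w, dimnames = list(c("A", "C", "G", "T")))
  codes <- vapply(occurrences, seq_to_int, integer(w))
  codes <- matrix(codes, nrow = w)
  for (j in seq_len(w)) {
    tab <- tabulate(codes[j, ], nbins = 4)
    mat[, j] <- tab
  }
  probs <- sweep(mat + pseudocount, 2,
                 colSums(mat) + 4 * pseudocount, "/")
  consensus <- paste(rownames(probs)[apply(probs, 2, which.max)],
                     collapse = "")
  structure(list(width = w, probs = probs, pseudocount = pseudocount,
                 consensus = consensus), class = "pwm")
}

# log2 likelihood-ratio scoring matrix against a uniform 0.25 background.
pwm_log_odds <- function(pwm) log2(pwm$probs / 0.25)

# Scores of all windows of a coded sequence under a log-odds matrix.
# Returns NA where the window touches an N.
score_all_windows <- function(codes, lo) {
  w <- ncol(lo)
  npos <- length(codes) - w + 1
  if (npos < 1) return(numeric(0))
  s <- numeric(npos)
  for (j in seq_len(w)) {
    s <- s + unname(lo[, j][codes[j:(j + npos - 1)]])
  }
  s
}

# Log-odds matrix scoring the minus strand at the same left coordinate:
# column j reads the complement of position w+1-j.
reverse_complement_lo <- function(lo) {
  lo[c(4, 3, 2, 1), rev(seq_len(ncol(lo))), drop = FALSE]
}

#' Genome-wide PWM score baseline
#'
#' Scores every window on both strands of the genome (excluding windows
#' that touch an N or overlap an excluded region, typically coding
#' intervals) and returns the mean and standard deviation of the scores —
#' the normalization constants that turn a raw PWM score into a z-score.
#' Scores are `sum(log2(p[i, base] / 0.25))` over positions.
#'
#' @param pwm A `pwm` object.
#' @param genome Genome.
#' @param excluded_regions Optional interval tibble (`chrom`, `start`,
#'   `end`) of regions whose windows are excluded.
#' @return A `baseline_stats` object: `mean_score`, `sd_score`,
#'   `n_positions` (scored windows, both strands), `excluded_bp`.
#' @export
genome_baseline <- function(pwm, genome, excluded_regions = NULL) {
  lo <- pwm_log_odds(pwm)
  lens <- chrom_lengths_of(genome)
  chars <- genome_chars(genome)
  lo_rc <- reverse_complement_lo(lo)
  w <- pwm$width
  scores <- list()
  excluded_bp <- 0L
  for (ch in names(lens)) {
    codes <- seq_to_int(chars[[ch]])
    fwd <- score_all_windows(codes, lo)
    rev <- score_all_windows(codes, lo_rc)
    keep <- !is.na(fwd)
    if (!is.null(excluded_regions)) {
      ex <- excluded_regions[excluded_regions$chrom == ch, , drop = FALSE]
      if (nrow(ex) > 0) {
        excluded_bp <- excluded_bp + excluded_span(ex, lens[[ch]])
        starts <- seq_len(length(fwd)) - 1L
        hit <- IRanges::findOverlaps(
          IRanges::IRanges(starts + 1L, width = w),
          IRanges::IRanges(ex$start + 1L, ex$end)
        )
        keep[unique(S4Vectors::queryHits(hit))] <- FALSE
      }
    }
    scores[[ch]] <- c(fwd[keep], rev[keep])
  }
  all_scores <- unlist(scores, use.names = FALSE)
  if (length(all_scores) < 1) {
    abort("no scoreable positions left after exclusions",
          class = "cistromer_degenerate")
  }
  sdv <- sd(all_scores)
  if (!is.finite(sdv) || sdv == 0) {
    abort("degenerate baseline: score standard deviation is zero",
          class = "cistromer_degenerate")
  }
  structure(list(mean_score = mean(all_scores), sd_score = sdv,
                 n_positions = length(all_scores),
                 excluded_bp = as.integer(excluded_bp)),
            class = "baseline_stats")
}

excluded_span <- function(ex, len) {
  ir <- IRanges::reduce(IRanges::IRanges(pmax(ex$start, 0L) + 1L,
                                         pmin(ex$end, len)))
  sum(IRanges::width(ir))
}

#' Scan parameters for motif-site calling
#'
#' @param z_cutoff Minimum baseline z-score for a hit (default 4.29).
#' @param both_strands Scan both strands?
#' @return A `scan_config` list.
#' @export
scan_config <- function(z_cutoff = 4.29, both_strands = TRUE) {
  if (!is.finite(z_cutoff)) {
    abort("z_cutoff must be finite", class = "cistromer_bad_input")
  }
  structure(list(z_cutoff = z_cutoff, both_strands = both_strands),
            class = "scan_config")
}

#' Scan peaks for motif instances by baseline z-score
#'
#' Every window inside each peak is scored on both strands; windows with
#' `z = (score - mean) / sd >= z_cutoff` are hits. Overlapping hits on the
#' same strand within a peak are greedily resolved to the higher z. The
#' one-sided p is the standard-normal upper tail of z.
#'
#' @param peaks Peak tibble.
#' @param genome Genome.
#' @param pwm A `pwm` object.
#' @param baseline A `baseline_stats` object.
#' @param config A [scan_config()].
#' @return A `motif_scan` list: `hits` (tibble: `name`, `chrom`, `start`,
#'   `end`, `strand`, `score`, `z`, `p`), `per_peak` (tibble: `name`,
#'   `n_hits`, `best_z`), `fraction_with_hit`, and the configuration.
#' @export
scan_peaks <- function(peaks, genome, pwm, baseline,
                       config = scan_config()) {
  check_peaks(peaks, genome)
  chars <- genome_chars(genome)
  lo <- pwm_log_odds(pwm)
  lo_rc <- reverse_complement_lo(lo)
  w <- pwm$width
  nm <- if ("name" %in% names(peaks)) peaks$name else
    paste0("peak_", seq_len(nrow(peaks)))
  hit_rows <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    s <- substring(chars[[peaks$chrom[i]]], peaks$start[i] + 1, peaks$end[i])
    codes <- seq_to_int(s)
    fwd <- score_all_windows(codes, lo)
    if (length(fwd) == 0) next
    cand <- tibble(
      offset = rep(seq_along(fwd) - 1L, if (config$both_strands) 2 else 1),
      strand = rep(if (config$both_strands) c("+", "-") else "+",
                   each = length(fwd)),
      score = if (config$both_strands) c(fwd, score_all_windows(codes, lo_rc))
              else fwd
    )
    cand <- cand[!is.na(cand$score), , drop = FALSE]
    cand$z <- (cand$score - baseline$mean_score) / baseline$sd_score
    cand <- cand[cand$z >= config$z_cutoff, , drop = FALSE]
    if (nrow(cand) == 0) next
    # greedy: best z first; drop same-strand overlaps
    cand <- cand[order(-cand$z, cand$offset), , drop = FALSE]
    kept <- integer(0)
    for (j in seq_len(nrow(cand))) {
      ov <- kept[cand$strand[kept] == cand$strand[j]]
      if (length(ov) == 0 ||
          all(abs(cand$offset[ov] - cand$offset[j]) >= w)) {
        kept <- c(kept, j)
      }
    }
    cand <- cand[kept, , drop = FALSE]
    hit_rows[[i]] <- tibble(
      name = nm[i], chrom = peaks$chrom[i],
      start = peaks$start[i] + cand$offset,
      end = peaks$start[i] + cand$offset + w,
      strand = cand$strand, score = cand$score, z = cand$z,
      p = pnorm(cand$z, lower.tail = FALSE))
  }
  hits <- bind_rows(hit_rows)
  if (nrow(hits) == 0) {
    hits <- tibble(name = character(), chrom = character(),
                   start = integer(), end = integer(), strand = character(),
                   score = numeric(), z = numeric(), p = numeric())
  }
  hits <- arrange(hits, match(.data$name, nm), .data$start)
  per_peak <- tibble(name = nm) |>
    left_join(hits |> group_by(.data$name) |>
                summarise(n_hits = n(), best_z = max(.data$z),
                          .groups = "drop"),
              by = "name") |>
    mutate(n_hits = ifelse(is.na(.data$n_hits), 0L, .data$n_hits),
           best_z = ifelse(is.infinite(.data$best_z), NA_real_,
                           .data$best_z))
  structure(list(hits = hits, per_peak = per_peak,
                 fraction_with_hit = mean(per_peak$n_hits > 0),
                 z_cutoff = config$z_cutoff),
            class = "motif_scan")
}

#' Distance from the best motif hit to each peak summit
#'
#' For every peak with at least one hit, the distance from the best
#' (highest-z) hit to the summit: 0 when the summit lies inside the site,
#' otherwise the distance to the nearer site edge. A background distance
#' is computed the same way for one uniformly placed site of the same
#' length within each such peak.
#'
#' @param scan A `motif_scan` from [scan_peaks()] (or its `hits` tibble).
#' @param peaks Peak tibble the scan was run on.
#' @param seed Seed for the background placements.
#' @return Tibble with `name`, `distance`, `background_distance`.
#' @export
summit_site_distances <- function(scan, peaks, seed = 1L) {
  hits <- if (inherits(scan, "motif_scan")) scan$hits else scan
  check_peaks(peaks)
  nm <- if ("name" %in% names(peaks)) peaks$name else
    paste0("peak_", seq_len(nrow(peaks)))
  if (nrow(hits) == 0) {
    return(tibble(name = character(), distance = integer(),
                  background_distance = integer()))
  }
  if (!all(hits$name %in% nm)) {
    abort("hits refer to unknown peaks", class = "cistromer_bad_input")
  }
  best <- hits |> group_by(.data$name) |>
    summarise(start = .data$start[which.max(.data$z)],
              end = .data$end[which.max(.data$z)], .groups = "drop")
  idx <- match(best$name, nm)
  summit <- peaks$summit[idx]
  w <- best$end - best$start
  dist <- site_summit_distance(best$start, best$end, summit)
  with_seed(seed, {
    span <- peaks$end[idx] - peaks$start[idx] - w
    bg_start <- peaks$start[idx] +
      as.integer(floor(runif(length(idx)) * pmax(span + 1, 1)))
  })
  bg_dist <- site_summit_distance(bg_start, bg_start + w, summit)
  tibble(name = best$name, distance = dist, background_distance = bg_dist)
}

site_summit_distance <- function(start, end, summit) {
  inside <- summit >= start & summit < end
  as.integer(ifelse(inside, 0L,
                    pmin(abs(summit - start), abs(summit - (end - 1L)))))
}

#' Write a PWM as a letter-probability matrix text file
#'
#' Four columns (A, C, G, T), one row per motif position, preceded by a
#' minimal MEME-style header.
#'
#' @param pwm A `pwm` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               sprintf("MOTIF %s", pwm$consensus),
               sprintf("letter-probability matrix: alength= 4 w= %d",
                       pwm$width)), con)
  writeLines(apply(t(pwm$probs), 1, function(r) {
    paste(sprintf("%.6f", r), collapse = " ")
  }), con)
  invisible(path)
}

#' Coding (CDS-overlapping exon) intervals of gene models
#'
#' The default exclusion set for [genome_baseline()].
#'
#' @param genes Gene-model tibble.
#' @return Interval tibble (`chrom`, `start`, `end`).
#' @export
coding_intervals <- function(genes) {
  if (nrow(genes) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  bind_rows(lapply(seq_len(nrow(genes)), function(i) {
    iv <- clip_intervals(genes$exon_starts[[i]], genes$exon_ends[[i]],
                         genes$cds_start[i], genes$cds_end[i])
    mutate(iv, chrom = genes$chrom[i])
  }))[, c("chrom", "start", "end")]
}
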