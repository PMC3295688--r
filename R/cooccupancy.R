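#' Intersect two peak sets
#'
#' An A peak counts as overlapping when its interval, extended by
#' `slop_bp` on each side, intersects any B interval by at least 1 bp
#' (half-open convention: adjacent intervals do not overlap at slop 0).
#' Symmetric statistics with the roles swapped are computed as well.
#'
#' @param set_a,set_b Peak or interval tibbles on the same genome.
#' @param slop_bp Extension applied to each side of every A (and, for the
#'   swapped statistics, B) interval before testing.
#' @return An `overlap_result`: set sizes, pair count, `n_a_with_b`,
#'   `fraction_a`, the swapped `n_b_with_a`/`fraction_b`, and the pair
#'   table.
#' @export
intersect_peaksets <- function(set_a, set_b, slop_bp = 0L) {
  pairs <- overlap_pairs(set_a, set_b, slop_bp)
  structure(list(
    n_a = nrow(set_a), n_b = nrow(set_b),
    n_overlap_pairs = nrow(pairs),
    n_a_with_b = length(unique(pairs$a)),
    fraction_a = if (nrow(set_a)) length(unique(pairs$a)) / nrow(set_a)
                 else NA_real_,
    n_b_with_a = length(unique(pairs$b)),
    fraction_b = if (nrow(set_b)) length(unique(pairs$b)) / nrow(set_b)
                 else NA_real_,
    slop_bp = slop_bp, pairs = pairs,
    empirical_p = NA_real_, n_resamples = 0L
  ), class = "overlap_result")
}

overlap_pairs <- function(set_a, set_b, slop_bp) {
  if (nrow(set_a) == 0 || nrow(set_b) == 0) {
    return(tibble(a = integer(), b = integer()))
  }
  rows <- lapply(intersect(unique(set_a$chrom), unique(set_b$chrom)),
                 function(ch) {
    ai <- which(set_a$chrom == ch)
    bi <- which(set_b$chrom == ch)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(set_a$start[ai] + 1L - slop_bp,
                       set_a$end[ai] + slop_bp),
      IRanges::IRanges(set_b$start[bi] + 1L, set_b$end[bi]),
      minoverlap = 1L
    )
    tibble(a = ai[S4Vectors::queryHits(hits)],
           b = bi[S4Vectors::subjectHits(hits)])
  })
  arrange(bind_rows(rows), .data$a, .data$b)
}

#' Co-occupancy significance by size-matched resampling
#'
#' Places `n_resamples` random peak sets with the same length multiset as
#' `set_a` (see [random_background_peaks()]) and compares each resample's
#' overlap count with B to the observed count. The empirical p-value uses
#' the add-one rule, `(1 + #{resamples >= observed}) / (n_resamples + 1)`,
#' so it is never zero.
#'
#' @inheritParams intersect_peaksets
#' @param genome Genome used for the random placements.
#' @param n_resamples Number of random sets (>= 19).
#' @param seed Integer seed.
#' @return An `overlap_result` with `empirical_p`, `n_resamples` and the
#'   resampled `null_counts` filled in.
#' @export
overlap_significance <- function(set_a, set_b, genome, n_resamples = 999L,
                                 slop_bp = 0L, seed = 1L) {
  if (n_resamples < 19) {
    abort("n_resamples must be >= 19", class = "cistromer_bad_input")
  }
  check_bounds(set_a, genome)
  check_bounds(set_b, genome)
  res <- intersect_peaksets(set_a, set_b, slop_bp)
  sizes <- set_a$end - set_a$start
  rand <- random_background_peaks(genome, sizes, n_sets = n_resamples,
                                  seed = seed)
  null_counts <- vapply(seq_len(n_resamples), function(s) {
    rs <- rand[rand$set == s, , drop = FALSE]
    length(unique(overlap_pairs(rs, set_b, slop_bp)$a))
  }, integer(1))
  res$empirical_p <- (1 + sum(null_counts >= res$n_a_with_b)) /
    (n_resamples + 1)
  res$n_resamples <- as.integer(n_resamples)
  res$null_counts <- null_counts
  res
}
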