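# broom-style tidiers and compact print methods for the result objects.

#' @export
glance.peak_model <- function(x, ...) {
  tibble(fragment_shift_d = x$fragment_shift_d,
         n_model_regions = x$n_model_regions)
}

#' @export
print.peak_model <- function(x, ...) {
  cat("Peak model: fragment shift d =", x$fragment_shift_d,
      "bp from", x$n_model_regions, "model regions\n")
  invisible(x)
}

#' @export
tidy.annotation_summary <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
tidy.ks_result <- function(x, ...) x$running

#' @export
glance.ks_result <- function(x, ...) {
  tibble(n_total = x$n_total, n_hits = x$n_hits, es = x$es,
         es_rank = x$es_rank, p_perm = x$p_perm,
         n_permutations = x$n_permutations, p_ks_asymp = x$p_ks_asymp,
         exhaustive = x$exhaustive, rank_by = x$rank_by)
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf(
    "Running-sum enrichment: %d hits in %d genes, ES = %.3f at rank %d\n",
    x$n_hits, x$n_total, x$es, x$es_rank))
  cat(sprintf("  permutation p = %.4g (%s, %d placements); asymptotic KS p = %.4g\n",
              x$p_perm, if (x$exhaustive) "exhaustive" else "Monte Carlo",
              x$n_permutations, x$p_ks_asymp))
  invisible(x)
}

#' @export
tidy.overlap_result <- function(x, ...) x$pairs

#' @export
glance.overlap_result <- function(x, ...) {
  tibble(n_a = x$n_a, n_b = x$n_b, n_overlap_pairs = x$n_overlap_pairs,
         n_a_with_b = x$n_a_with_b, fraction_a = x$fraction_a,
         n_b_with_a = x$n_b_with_a, fraction_b = x$fraction_b,
         slop_bp = x$slop_bp, empirical_p = x$empirical_p,
         n_resamples = x$n_resamples)
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Peak-set overlap: %d/%d A peaks (%.1f%%) overlap B (slop %d bp)\n",
              x$n_a_with_b, x$n_a, 100 * x$fraction_a, x$slop_bp))
  if (!is.na(x$empirical_p)) {
    cat(sprintf("  empirical p = %.4g (%d size-matched resamples)\n",
                x$empirical_p, x$n_resamples))
  }
  invisible(x)
}

#' @export
glance.baseline_stats <- function(x, ...) {
  tibble(mean_score = x$mean_score, sd_score = x$sd_score,
         n_positions = x$n_positions, excluded_bp = x$excluded_bp)
}

#' @export
glance.geneset_overlap <- function(x, ...) {
  tibble(universe_size = x$universe_size, set1_size = x$set1_size,
         set2_size = x$set2_size, overlap = x$overlap,
         p_hyper = x$p_hyper)
}

#' @export
print.geneset_overlap <- function(x, ...) {
  cat(sprintf(
    "Gene-set overlap: %d/%d vs %d in a universe of %d; hypergeometric p = %.3g\n",
    x$overlap, x$set1_size, x$set2_size, x$universe_size, x$p_hyper))
  invisible(x)
}

#' @export
tidy.motif_scan <- function(x, ...) x$hits

#' @export
glance.motif_scan <- function(x, ...) {
  tibble(n_peaks = nrow(x$per_peak), n_hits = nrow(x$hits),
         fraction_with_hit = x$fraction_with_hit, z_cutoff = x$z_cutoff)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (width %d, pseudocount %g)\n", x$consensus, x$width,
              x$pseudocount))
  print(round(x$probs, 3))
  invisible(x)
}

#' @export
print.run_report <- function(x, ...) {
  r <- x$report
  cat("Pipeline run (seed ", r$seed, ")\n", sep = "")
  cat("  d = ", r$fragment_shift_d, " bp; ", r$n_peaks, " peaks\n", sep = "")
  cat(sprintf("  promoter fraction %.3f; motif %s in %.1f%% of peaks\n",
              r$feature_fractions$promoter, r$motif$consensus,
              100 * r$motif$fraction_with_hit))
  cat(sprintf("  co-occupancy %.1f%% (p = %.3g)",
              100 * r$cooccupancy$fraction_a, r$cooccupancy$empirical_p))
  if (!is.null(r$ks)) {
    cat(sprintf("; KS ES = %.3f (p = %.3g)", r$ks$es, r$ks$p_perm))
  }
  cat("\n")
  invisible(x)
}
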