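# ggplot2 graphics for the result objects.

#' @export
autoplot.ks_result <- function(object, ...) {
  df <- object$running
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$es_curve)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_rug(data = df[df$is_hit, ], sides = "b",
                      colour = "#b2182b", alpha = 0.6) +
    ggplot2::labs(x = "Rank in expression list",
                  y = "Running enrichment score",
                  title = sprintf("ES = %.3f, permutation p = %.3g",
                                  object$es, object$p_perm)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.annotation_summary <- function(object, ...) {
  df <- as_tibble(unclass(object))
  df$feature_class <- factor(df$feature_class, levels = FEATURE_CLASSES)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature_class,
                                   y = .data$fraction)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = NULL, y = "Fraction of peaks",
                  title = "Peak distribution over genomic features") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.motif_scan <- function(object, ...) {
  df <- object$per_peak |>
    group_by(.data$n_hits) |>
    summarise(n = n(), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n_hits), y = .data$n)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "Motif instances per peak", y = "Peaks",
                  title = sprintf("%.1f%% of peaks contain a motif (z >= %.2f)",
                                  100 * object$fraction_with_hit,
                                  object$z_cutoff)) +
    ggplot2::theme_minimal()
}

#' Histogram of summit-to-TSS distances against a background
#'
#' @param distances Output of [summit_to_tss_distances()] for real peaks.
#' @param background Optional equivalent tibble for random peaks.
#' @param binwidth Histogram bin width in bp.
#' @param xlim Distance range shown.
#' @return A ggplot object.
#' @export
plot_tss_distances <- function(distances, background = NULL,
                               binwidth = 500, xlim = c(-10000, 10000)) {
  df <- mutate(distances, set = "peaks")
  if (!is.null(background)) {
    df <- bind_rows(df, mutate(background, set = "random"))
  }
  df <- df[!is.na(df$tss_distance), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tss_distance,
                                   fill = .data$set)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6, boundary = 0) +
    ggplot2::coord_cartesian(xlim = xlim) +
    ggplot2::scale_fill_manual(values = c(peaks = "#2166ac",
                                          random = "grey60")) +
    ggplot2::labs(x = "Summit - TSS distance (bp)", y = "Peaks",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of summit-to-motif distances against the background
#'
#' @param distances Output of [summit_site_distances()].
#' @param binwidth Histogram bin width in bp.
#' @return A ggplot object.
#' @export
plot_site_distances <- function(distances, binwidth = 25) {
  df <- tidyr::pivot_longer(distances, c("distance", "background_distance"),
                            names_to = "set", values_to = "bp")
  df$set <- ifelse(df$set == "distance", "best motif", "random site")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bp, fill = .data$set)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6, boundary = 0) +
    ggplot2::scale_fill_manual(values = c(`best motif` = "#2166ac",
                                          `random site` = "grey60")) +
    ggplot2::labs(x = "Distance to summit (bp)", y = "Peaks", fill = NULL) +
    ggplot2::theme_minimal()
}
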