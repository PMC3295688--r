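#' Peak-calling parameters
#'
#' Defaults mirror a stringent model-based ChIP-seq analysis: windows of
#' twice the 300 bp bandwidth, candidate model regions at least 32-fold
#' enriched over the background rate, Poisson p cutoff 1e-10 and
#' sample-swap FDR cutoff 1%.
#'
#' @param mfold Minimum enrichment multiple over background for a window
#'   to enter strand-shift model estimation.
#' @param bandwidth Half the scan window width, in bp.
#' @param p_cutoff Poisson enrichment p-value cutoff.
#' @param fdr_cutoff Sample-swap FDR cutoff.
#' @return A `peak_calling_config` list.
#' @export
peak_calling_config <- function(mfold = 32, bandwidth = 300L,
                                p_cutoff = 1e-10, fdr_cutoff = 0.01) {
  if (mfold <= 1) abort("mfold must be > 1", class = "cistromer_bad_input")
  if (bandwidth <= 0) {
    abort("bandwidth must be positive", class = "cistromer_bad_input")
  }
  if (p_cutoff <= 0 || p_cutoff >= 1 || fdr_cutoff <= 0 || fdr_cutoff >= 1) {
    abort("cutoffs must be in (0, 1)", class = "cistromer_bad_input")
  }
  structure(list(mfold = mfold, bandwidth = as.integer(bandwidth),
                 p_cutoff = p_cutoff, fdr_cutoff = fdr_cutoff),
            class = "peak_calling_config")
}

# 5' position of each tag (start on +, end - 1 on -).
tag_5p <- function(tags) {
  as.integer(ifelse(tags$strand == "+", tags$start, tags$end - 1L))
}

# Count points falling in [ws, ws + width) for sorted positions.
count_in_windows <- function(pos_sorted, ws, width) {
  if (length(pos_sorted) == 0) return(rep(0L, length(ws)))
  findInterval(ws + width - 0.5, pos_sorted) -
    findInterval(ws - 0.5, pos_sorted)
}

window_starts <- function(len, width, step) {
  if (len <= width) return(0L)
  as.integer(seq(0L, len - width, by = step))
}

# Smoothed positional mode: tabulate positions, moving-average smooth,
# return the leftmost argmax.
smoothed_mode <- function(pos, half_width = 10L) {
  rng <- range(pos)
  counts <- tabulate(pos - rng[1] + 1L, nbins = rng[2] - rng[1] + 1L)
  k <- 2L * half_width + 1L
  sm <- if (length(counts) <= k) counts else
    as.numeric(stats::filter(counts, rep(1, k), sides = 2))
  sm[is.na(sm)] <- 0
  rng[1] + which.max(sm) - 1L
}

#' Estimate the fragment shift d from strand-separated tag pileups
#'
#' Scans sliding windows of twice the bandwidth; windows whose tag count
#' exceeds `mfold` times the expected background count (background rate
#' estimated robustly as the mean count over the lower 80% of windows, so
#' that enriched windows do not inflate it) become model regions. Within
#' each region the smoothed mode of the minus-strand 5' positions minus
#' the smoothed mode of the plus-strand 5' positions gives one shift
#' estimate; `d` is the median over regions.
#'
#' @param treatment Tag tibble.
#' @param genome Genome (chromosome bounds).
#' @param config A [peak_calling_config()].
#' @return A `peak_model` list with `fragment_shift_d` and
#'   `n_model_regions`.
#' @export
estimate_fragment_shift <- function(treatment, genome,
                                    config = peak_calling_config()) {
  check_tags(treatment, genome)
  if (nrow(treatment) == 0) {
    abort("treatment is empty", class = "cistromer_bad_input")
  }
  width <- 2L * config$bandwidth
  step <- max(1L, config$bandwidth %/% 3L)
  lens <- chrom_lengths_of(genome)
  p5 <- tag_5p(treatment)

  # background rate from the lower 80% of window counts
  all_counts <- unlist(lapply(names(lens), function(ch) {
    pos <- sort(p5[treatment$chrom == ch])
    count_in_windows(pos, window_starts(lens[[ch]], width, step), width)
  }))
  bg_count <- mean(all_counts[all_counts <= stats::quantile(all_counts, 0.8)])

  shifts <- numeric(0)
  for (ch in names(lens)) {
    sel <- treatment$chrom == ch
    pos <- p5[sel]
    str <- treatment$strand[sel]
    ord <- order(pos)
    pos_s <- pos[ord]
    ws <- window_starts(lens[[ch]], width, step)
    cnt <- count_in_windows(pos_s, ws, width)
    cand <- which(cnt >= config$mfold * bg_count & cnt > 0)
    if (length(cand) == 0) next
    # keep non-overlapping candidates, strongest first
    cand <- cand[order(-cnt[cand])]
    kept <- integer(0)
    for (i in cand) {
      if (all(abs(ws[i] - ws[kept]) >= width)) kept <- c(kept, i)
    }
    for (i in kept) {
      inw <- pos >= ws[i] & pos < ws[i] + width
      fw <- pos[inw & str == "+"]
      rv <- pos[inw & str == "-"]
      if (length(fw) < 5 || length(rv) < 5) next
      s <- smoothed_mode(rv) - smoothed_mode(fw)
      if (s > 0) shifts <- c(shifts, s)
    }
  }
  if (length(shifts) == 0) {
    abort("no window passed the mfold model filter (NoModel)",
          class = "cistromer_no_model")
  }
  structure(list(fragment_shift_d = as.integer(round(stats::median(shifts))),
                 n_model_regions = length(shifts)),
            class = "peak_model")
}

#' Poisson enrichment p-value
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Poisson(lambda)` — the
#' window enrichment statistic.
#'
#' @param k Observed count.
#' @param lambda Expected count.
#' @return p-value vector.
#' @export
poisson_enrichment_pvalue <- function(k, lambda) {
  ppois(k - 1, lambda, lower.tail = FALSE)
}

# log10 of the upper-tail Poisson p, stable for extreme counts.
log10_poisson_tail <- function(k, lambda) {
  ppois(k - 1, lambda, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Call enriched peaks against a control
#'
#' Tags are shifted by `d/2` toward their 3' direction; sliding windows of
#' twice the bandwidth are scored with the Poisson upper tail of the
#' treatment count against `lambda = max(depth-scaled control count,
#' genome-wide treatment rate x window)`. Overlapping significant windows
#' merge into peaks, which are re-scored over their full extent. The
#' summit is the leftmost position of maximum pileup of tags extended to
#' `d` bp. FDR is the sample-swap estimate: the number of control-over-
#' treatment peaks at least as significant, divided by the number of
#' treatment peaks at least as significant.
#'
#' @param treatment,control Tag tibbles (control may have zero rows, in
#'   which case the uniform genome-wide rate is the background).
#' @param model A `peak_model` from [estimate_fragment_shift()], or a
#'   list with `fragment_shift_d`.
#' @param config A [peak_calling_config()].
#' @param genome Genome (chromosome bounds).
#' @return Peak tibble: `chrom`, `start`, `end`, `name`, `score`
#'   (-log10 p), `summit`, `fold_enrichment`, `fdr`, sorted by position.
#' @export
call_peaks <- function(treatment, control, model,
                       config = peak_calling_config(), genome) {
  if (is.null(model$fragment_shift_d)) {
    abort("model with fragment_shift_d required", class = "cistromer_bad_input")
  }
  check_tags(treatment, genome)
  if (nrow(treatment) == 0) {
    abort("treatment is empty", class = "cistromer_bad_input")
  }
  if (nrow(control) > 0) check_tags(control, genome)
  d <- model$fragment_shift_d
  lens <- chrom_lengths_of(genome)

  t_pos <- shifted_positions(treatment, d, lens)
  c_pos <- shifted_positions(control, d, lens)
  regions <- score_enriched_regions(t_pos, c_pos, lens, config)
  if (nrow(regions) == 0) return(empty_peaks())

  # sample-swap FDR: call with the roles exchanged at the same threshold
  swap <- if (length(c_pos$pos) > 0) {
    score_enriched_regions(c_pos, t_pos, lens, config)
  } else {
    tibble(log10p = numeric(0))
  }
  swap_sorted <- sort(swap$log10p)
  treat_sorted <- sort(regions$log10p)
  regions$fdr <- pmin(1, findInterval(regions$log10p, swap_sorted) /
                           findInterval(regions$log10p, treat_sorted))

  regions <- regions[regions$log10p <= log10(config$p_cutoff) &
                       regions$fdr <= config$fdr_cutoff, , drop = FALSE]
  if (nrow(regions) == 0) return(empty_peaks())

  regions$summit <- peak_summits(regions, treatment, d, lens)
  regions <- arrange(regions, .data$chrom, .data$start)
  tibble(chrom = regions$chrom, start = regions$start, end = regions$end,
         name = paste0("peak_", seq_len(nrow(regions))),
         score = -regions$log10p, summit = regions$summit,
         fold_enrichment = regions$fold_enrichment, fdr = regions$fdr)
}

empty_peaks <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         name = character(), score = numeric(), summit = integer(),
         fold_enrichment = numeric(), fdr = numeric())
}

# Shift each tag's 5' position d/2 toward its 3' end; clamp to bounds.
shifted_positions <- function(tags, d, lens) {
  if (nrow(tags) == 0) {
    return(list(chrom = character(), pos = integer(), total = 0L))
  }
  half <- d %/% 2L
  p5 <- tag_5p(tags)
  pos <- ifelse(tags$strand == "+", p5 + half, p5 - half)
  pos <- pmin(pmax(pos, 0L), lens[tags$chrom] - 1L)
  list(chrom = tags$chrom, pos = as.integer(pos), total = nrow(tags))
}

score_enriched_regions <- function(t_pos, c_pos, lens, config) {
  width <- 2L * config$bandwidth
  step <- max(1L, config$bandwidth %/% 3L)
  genome_len <- sum(lens)
  rate_t <- t_pos$total / genome_len
  ratio <- if (c_pos$total > 0) t_pos$total / c_pos$total else NA_real_
  log_cut <- log10(config$p_cutoff)

  out <- vector("list", length(lens))
  for (j in seq_along(lens)) {
    ch <- names(lens)[j]
    tp <- sort(t_pos$pos[t_pos$chrom == ch])
    cp <- sort(c_pos$pos[c_pos$chrom == ch])
    ws <- window_starts(lens[[j]], width, step)
    kt <- count_in_windows(tp, ws, width)
    kc <- count_in_windows(cp, ws, width)
    lam <- pmax(if (is.na(ratio)) 0 else kc * ratio, rate_t * width)
    lp <- log10_poisson_tail(kt, lam)
    sig <- which(lp <= log_cut & kt > 0)
    if (length(sig) == 0) next
    # merge overlapping/touching significant windows into regions
    s <- ws[sig]
    e <- s + width
    newgrp <- c(TRUE, s[-1] > cummax(e[-length(e)]))
    grp <- cumsum(newgrp)
    rs <- as.integer(tapply(s, grp, min))
    re <- as.integer(tapply(e, grp, max))
    re <- pmin(re, lens[[j]])
    # re-score each merged region over its full extent
    k_t <- count_in_windows(tp, rs, re - rs)
    k_c <- count_in_windows(cp, rs, re - rs)
    lam_r <- pmax(if (is.na(ratio)) 0 else k_c * ratio, rate_t * (re - rs))
    out[[j]] <- tibble(chrom = ch, start = rs, end = re,
                       log10p = log10_poisson_tail(k_t, lam_r),
                       fold_enrichment = k_t / lam_r)
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(chrom = character(), start = integer(), end = integer(),
                  log10p = numeric(), fold_enrichment = numeric())
  }
  res
}

# Summit: leftmost maximum of the pileup of tags extended to d bp.
peak_summits <- function(regions, tags, d, lens) {
  p5 <- tag_5p(tags)
  ext_start <- as.integer(ifelse(tags$strand == "+", p5, p5 - d + 1L))
  ext_end <- ext_start + as.integer(d)
  vapply(seq_len(nrow(regions)), function(i) {
    ch <- regions$chrom[i]
    rs <- regions$start[i]
    re <- regions$end[i]
    sel <- tags$chrom == ch & ext_end > rs & ext_start < re
    if (!any(sel)) return(as.integer(rs + (re - rs) %/% 2L))
    n <- re - rs
    delta <- numeric(n + 1)
    s_off <- pmax(ext_start[sel] - rs, 0L) + 1L
    e_off <- pmin(ext_end[sel] - rs, n) + 1L
    for (k in seq_along(s_off)) {
      delta[s_off[k]] <- delta[s_off[k]] + 1
      delta[e_off[k]] <- delta[e_off[k]] - 1
    }
    cov <- cumsum(delta[seq_len(n)])
    as.integer(rs + which.max(cov) - 1L)
  }, integer(1))
}

#' Pileup track of d-extended tags
#'
#' Extends every tag from its 5' end to length `d` in its 3' direction and
#' returns the per-base coverage as a run-length track suitable for
#' [write_bedgraph()].
#'
#' @param tags Tag tibble.
#' @param genome Genome.
#' @param d Extension length in bp (the fragment shift estimate).
#' @return Run-length coverage tibble (`chrom`, `start`, `end`, `value`).
#' @export
pileup_track <- function(tags, genome, d) {
  check_tags(tags, genome)
  lens <- chrom_lengths_of(genome)
  p5 <- tag_5p(tags)
  ext_start <- pmax(as.integer(ifelse(tags$strand == "+", p5, p5 - d + 1L)),
                    0L)
  ext_end <- pmin(ext_start + as.integer(d), lens[tags$chrom])
  bind_rows(lapply(names(lens), function(ch) {
    sel <- tags$chrom == ch
    n <- lens[[ch]]
    delta <- numeric(n + 1)
    for (k in which(sel)) {
      delta[ext_start[k] + 1L] <- delta[ext_start[k] + 1L] + 1
      delta[ext_end[k] + 1L] <- delta[ext_end[k] + 1L] - 1
    }
    as_coverage_track(cumsum(delta[seq_len(n)]), ch)
  }))
}
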