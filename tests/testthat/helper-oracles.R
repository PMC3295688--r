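# Independent oracles, deliberately naive: direct loops and summations,
# no shared code with the implementation paths they check.

# Poisson upper tail P(X >= k) by direct term summation.
poisson_tail_oracle <- function(k, lambda) {
  if (k <= 0) return(1)
  upper <- max(k + 60, ceiling(lambda + 12 * sqrt(lambda) + 60))
  sum(dpois(k:upper, lambda))
}

# PWM log2-odds score of a single window string (uniform 0.25 background).
window_score_oracle <- function(s, pwm) {
  bases <- strsplit(s, "")[[1]]
  if (any(!bases %in% c("A", "C", "G", "T"))) return(NA_real_)
  total <- 0
  for (i in seq_along(bases)) {
    total <- total + log2(pwm$probs[bases[i], i] / 0.25)
  }
  total
}

rc_oracle <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# All-window scan of one peak sequence on both strands with the same
# cutoff and greedy same-strand overlap rule, written independently.
scan_oracle <- function(seq, pwm, baseline, z_cutoff) {
  w <- pwm$width
  n <- nchar(seq)
  rows <- list()
  for (off in 0:(n - w)) {
    win <- substr(seq, off + 1, off + w)
    for (strand in c("+", "-")) {
      s <- window_score_oracle(if (strand == "+") win else rc_oracle(win),
                               pwm)
      if (is.na(s)) next
      z <- (s - baseline$mean_score) / baseline$sd_score
      if (z >= z_cutoff) {
        rows[[length(rows) + 1]] <-
          data.frame(offset = off, strand = strand, score = s, z = z)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric(), z = numeric()))
  }
  cand <- do.call(rbind, rows)
  cand <- cand[order(-cand$z, cand$offset), ]
  kept <- list()
  for (i in seq_len(nrow(cand))) {
    clash <- FALSE
    for (k in kept) {
      if (k$strand == cand$strand[i] &&
          abs(k$offset - cand$offset[i]) < w) {
        clash <- TRUE
        break
      }
    }
    if (!clash) kept[[length(kept) + 1]] <- cand[i, ]
  }
  out <- do.call(rbind, kept)
  out[order(out$offset, out$strand), ]
}

# Quadratic all-pairs interval overlap with slop (half-open convention).
overlap_oracle <- function(a, b, slop = 0L) {
  pairs <- 0L
  a_hit <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] - slop < b$end[j] &&
          b$start[j] < a$end[i] + slop) {
        pairs <- pairs + 1L
        a_hit[i] <- TRUE
      }
    }
  }
  list(pairs = pairs, n_a_with_b = sum(a_hit))
}

# Running-sum enrichment score for hit positions, independent loop form.
ks_es_oracle <- function(hit_pos, n) {
  nh <- length(hit_pos)
  cur <- 0
  best <- 0
  for (i in seq_len(n)) {
    cur <- cur + if (i %in% hit_pos) 1 / nh else -1 / (n - nh)
    if (abs(cur) > abs(best)) best <- cur
  }
  best
}

# Hypergeometric upper tail by explicit combinatorial summation.
hyper_oracle <- function(N, K, n, ov) {
  tot <- 0
  for (i in ov:min(K, n)) {
    tot <- tot + choose(K, i) * choose(N - K, n - i)
  }
  tot / choose(N, n)
}
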