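random_seqs <- function(n, len, seed) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    }, "")
  })
}

test_that("k-mer discovery recovers a planted half-site on either strand", {
  base <- random_seqs(30, 100, seed = 51)
  plant <- function(seqs, motif) {
    withr::with_seed(52, {
      vapply(seqs, function(s) {
        pos <- sample.int(nchar(s) - nchar(motif) + 1, 1)
        paste0(substr(s, 1, pos - 1), motif,
               substr(s, pos + nchar(motif), nchar(s)))
      }, "", USE.NAMES = FALSE)
    })
  }
  fwd <- plant(base, "CCAAGGTCA")
  res <- find_enriched_kmer(fwd, k = 9,
                            background_sequences = shuffle_sequences(fwd, 1))
  expect_identical(res$consensus, "CCAAGGTCA")
  expect_gte(res$n_occurrences, 30)
  expect_true(all(res$occurrences$strand == "+"))

  # planted only as the reverse complement: same canonical consensus
  rev <- plant(base, "TGACCTTGG")
  res_rc <- find_enriched_kmer(rev, k = 9,
                               background_sequences =
                                 shuffle_sequences(rev, 1))
  expect_identical(res_rc$consensus, "CCAAGGTCA")
  expect_true(all(res_rc$occurrences$strand == "-"))
})

test_that("pure random sequences give no outlying enrichment ratio", {
  seqs <- random_seqs(30, 200, seed = 61)
  obs <- find_enriched_kmer(seqs, k = 9, min_count = 2,
                            background_sequences =
                              shuffle_sequences(seqs, 1))$ratio
  null_tops <- vapply(1:99, function(b) {
    reshuffled <- shuffle_sequences(seqs, seed = 1000 + b)
    find_enriched_kmer(reshuffled, k = 9, min_count = 2,
                       background_sequences =
                         shuffle_sequences(reshuffled, 1))$ratio
  }, numeric(1))
  p_emp <- (1 + sum(null_tops >= obs)) / 100
  expect_gt(p_emp, 0.01)
})

test_that("PWM construction follows the pseudocount arithmetic", {
  pwm <- build_pwm(rep("CCAAGGTCA", 10), pseudocount = 0.5)
  expect_identical(pwm$width, 9L)
  expect_identical(pwm$consensus, "CCAAGGTCA")
  # consensus letter probability = (10 + 0.5) / (10 + 4 * 0.5)
  expect_equal(unname(pwm$probs["C", 1]), 10.5 / 12)
  expect_equal(unname(colSums(pwm$probs)), rep(1, 9), tolerance = 1e-9)

  expect_error(build_pwm(character(0)), class = "cistromer_bad_input")
  expect_error(build_pwm(c("ACGT", "ACGTA")), class = "cistromer_bad_input")
})

test_that("genome baseline equals an exhaustive per-window rescan", {
  pwm <- build_pwm(c(rep("CCAAGGTCA", 8), "CCAAGTTCA", "CCATGGTCA"))
  genome <- Biostrings::DNAStringSet(
    c(chrA = random_seqs(1, 6000, seed = 71),
      chrB = random_seqs(1, 4000, seed = 72)))
  got <- genome_baseline(pwm, genome)

  scores <- unlist(lapply(as.character(genome), function(s) {
    vapply(0:(nchar(s) - 9), function(off) {
      win <- substr(s, off + 1, off + 9)
      c(window_score_oracle(win, pwm),
        window_score_oracle(rc_oracle(win), pwm))
    }, numeric(2))
  }))
  expect_equal(got$mean_score, mean(scores), tolerance = 1e-9)
  expect_equal(got$sd_score, sd(scores), tolerance = 1e-9)
  expect_identical(got$n_positions, length(scores))
})

test_that("uniform PWMs and empty scans are rejected as degenerate", {
  flat <- build_pwm(c("ACGT", "CGTA", "GTAC", "TACG",
                      "ACGT", "CGTA", "GTAC", "TACG"), pseudocount = 1e6)
  genome <- Biostrings::DNAStringSet(c(chr1 = random_seqs(1, 2000, 73)))
  expect_error(genome_baseline(flat, genome),
               class = "cistromer_degenerate")
})

test_that("baseline bookkeeping counts both strands after exclusions", {
  pwm <- build_pwm(c(rep("CCAAGGTCA", 9), "ACGTACGTA"))
  genome <- Biostrings::DNAStringSet(c(chr1 = random_seqs(1, 1000, 74)))
  # windows starting at 0..499 stay; everything overlapping [508,1000) goes
  excl <- tibble::tibble(chrom = "chr1", start = 508L, end = 1000L)
  got <- genome_baseline(pwm, genome, excl)
  expect_identical(got$n_positions, 500L * 2L)
  expect_identical(got$excluded_bp, 492L)
})

test_that("peak scanning equals the brute-force window oracle", {
  motif <- default_motif()
  w <- default_world()
  genome <- w$genome
  set.seed(81)
  lens <- setNames(Biostrings::width(genome), names(genome))
  starts <- sample.int(lens[["chr1"]] - 2000L, 10)
  peaks <- tibble::tibble(chrom = "chr1", start = starts,
                          end = starts + sample(seq(200L, 2000L, 100L), 10,
                                                TRUE))
  peaks$end <- pmin(peaks$end, lens[["chr1"]])
  peaks$summit <- peaks$start + (peaks$end - peaks$start) %/% 2L
  peaks$name <- paste0("rp_", 1:10)
  scan <- scan_peaks(peaks, genome, motif$pwm, motif$baseline,
                     scan_config(z_cutoff = 2.5))
  seqs <- extract_sequences_for_test(genome, peaks)
  for (i in 1:10) {
    want <- scan_oracle(seqs[i], motif$pwm, motif$baseline, 2.5)
    got <- scan$hits[scan$hits$name == peaks$name[i], ]
    got <- got[order(got$start, got$strand), ]
    expect_identical(got$start - peaks$start[i], want$offset)
    expect_identical(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("z-to-p conversion is the standard normal upper tail", {
  # the z = 4.29 operating point
  expect_equal(pnorm(4.29, lower.tail = FALSE), 8.95e-6, tolerance = 0.002)
  motif <- default_motif()
  hits <- motif$scan$hits
  expect_equal(hits$p, pnorm(hits$z, lower.tail = FALSE))
  expect_equal(hits$z,
               (hits$score - motif$baseline$mean_score) /
                 motif$baseline$sd_score)
  # p strictly decreasing in z
  ord <- order(hits$z)
  expect_true(all(diff(hits$p[ord]) <= 0))
})

test_that("hit sets mirror under genome reverse complementation", {
  motif <- default_motif()
  genome <- Biostrings::DNAStringSet(
    c(chrM = random_seqs(1, 3000, seed = 91)))
  s <- as.character(genome)[[1]]
  s <- paste0(substr(s, 1, 1200), "CCAAGGTCA", substr(s, 1210, 3000))
  genome <- Biostrings::DNAStringSet(c(chrM = s))
  rc_genome <- Biostrings::DNAStringSet(
    c(chrM = rc_oracle(as.character(genome)[[1]])))
  n <- nchar(s)
  peaks <- tibble::tibble(chrom = "chrM", start = 1000L, end = 1500L,
                          summit = 1250L, name = "p")
  mirrored <- tibble::tibble(chrom = "chrM", start = n - 1500L,
                             end = n - 1000L, summit = n - 1251L,
                             name = "p")
  a <- scan_peaks(peaks, genome, motif$pwm, motif$baseline)$hits
  b <- scan_peaks(mirrored, rc_genome, motif$pwm, motif$baseline)$hits
  expect_identical(nrow(a), nrow(b))
  expect_identical(sort(n - a$end), sort(b$start))
  expect_setequal(a$z, b$z)
  expect_identical(table(a$strand)[["+"]], table(b$strand)[["-"]])
})

test_that("summit-to-site distance follows the overlap-zero rule", {
  peaks <- tibble::tibble(chrom = "chr1", start = 0L, end = 400L,
                          summit = 105L, name = "p1")
  hits <- tibble::tibble(name = "p1", chrom = "chr1", start = 100L,
                         end = 109L, strand = "+", score = 10, z = 5,
                         p = 1e-7)
  d <- summit_site_distances(hits, peaks, seed = 1)
  expect_identical(d$distance, 0L)

  peaks$summit <- 120L
  d <- summit_site_distances(hits, peaks, seed = 1)
  expect_identical(d$distance, 12L)
})

test_that("real summit-site distances beat the random-site background", {
  w <- default_world()
  peaks <- default_peaks()
  motif <- default_motif()
  d <- summit_site_distances(motif$scan, peaks, seed = 5)
  expect_lt(median(d$distance), median(d$background_distance))
})
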