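test_that("peak-to-gene assignment respects the distance window", {
  genes <- toy_genes()
  # gA spans [10000, 20000) on chr1: a peak 15 kb away is excluded at 10 kb
  far <- tibble::tibble(chrom = "chr1", start = 35200L, end = 35400L)
  expect_identical(nrow(peaks_to_genes(far, genes[1, ], 10000L)), 0L)
  # a peak overlapping the transcript body is included at window 0
  onbody <- tibble::tibble(chrom = "chr1", start = 15000L, end = 15200L)
  expect_identical(peaks_to_genes(onbody, genes, 0L)$gene_id, "gA")

  # random instances against the quadratic distance oracle
  set.seed(47)
  for (rep in 1:10) {
    n <- sample(3:15, 1)
    start <- sample.int(90000L, n)
    peaks <- tibble::tibble(chrom = sample(c("chr1", "chr2"), n, TRUE),
                            start = start, end = start + 300L)
    wbp <- sample(c(0L, 2000L, 10000L), 1)
    got <- peaks_to_genes(peaks, genes, wbp)$gene_id
    want <- as.character(sort(unique(unlist(lapply(seq_len(nrow(genes)),
                                                   function(g) {
      for (i in seq_len(n)) {
        if (peaks$chrom[i] == genes$chrom[g] &&
            peaks$start[i] < genes$tx_end[g] + wbp &&
            genes$tx_start[g] - wbp < peaks$end[i]) {
          return(genes$gene_id[g])
        }
      }
      NULL
    })))))
    expect_identical(got, want)
  }
})

test_that("nearest-gene mode breaks ties toward the lower coordinate", {
  genes <- toy_genes()
  # equidistant between gA (ends 20000) and gB (starts 40000)
  mid <- tibble::tibble(chrom = "chr1", start = 29900L, end = 30100L)
  got <- peaks_to_genes(mid, genes, window_bp = 10000L, mode = "nearest")
  expect_identical(got$gene_id, "gA")
})

test_that("the 4-gene running sum is exact: curve, ES, enumeration p", {
  expr <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
                         fold_change = c(4, 3, 2, 1))
  res <- ks_running_enrichment(expr, c("g1", "g2"))
  expect_true(res$exhaustive)
  expect_equal(res$running$es_curve, c(0.5, 1.0, 0.5, 0))
  expect_equal(res$es, 1.0)
  expect_equal(res$p_perm, 1 / 6)
  expect_equal(res$running$es_curve[res$n_total], 0)

  expect_error(ks_running_enrichment(expr, character(0)),
               class = "cistromer_bad_input")
  expect_error(ks_running_enrichment(expr, expr$gene_id),
               class = "cistromer_bad_input")
})

test_that("the running sum always returns to zero and ignores labels", {
  set.seed(53)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    nh <- sample(2:(n - 2), 1)
    expr <- tibble::tibble(gene_id = paste0("g", 1:n),
                           fold_change = rnorm(n))
    hits <- sample(expr$gene_id, nh)
    res <- ks_running_enrichment(expr, hits, n_permutations = 19,
                                 seed = rep)
    expect_lt(abs(res$running$es_curve[n]), 1e-12)
    expect_lte(abs(res$es), 1)
    # es equals the independent oracle on the hit positions
    pos <- which(res$running$is_hit)
    expect_equal(res$es, ks_es_oracle(pos, n))

    # relabeling gene ids leaves es unchanged
    relabeled <- expr
    relabeled$gene_id <- paste0("x", 1:n)
    ord <- order(-relabeled$fold_change)
    new_hits <- relabeled$gene_id[ord][pos]
    res2 <- ks_running_enrichment(relabeled, new_hits,
                                  n_permutations = 19, seed = rep)
    expect_equal(res2$es, res$es)
  }
})

test_that("Monte-Carlo permutation p agrees with exhaustive enumeration", {
  expr <- tibble::tibble(gene_id = paste0("g", 1:10),
                         fold_change = 10:1)
  hits <- c("g1", "g3", "g4")
  exact <- ks_running_enrichment(expr, hits)
  expect_true(exact$exhaustive)
  mc <- ks_running_enrichment(expr, hits, n_permutations = 2000,
                              seed = 5, exhaustive = FALSE)
  mc_sd <- sqrt(exact$p_perm * (1 - exact$p_perm) / 2000)
  expect_lt(abs(mc$p_perm - exact$p_perm), 3 * mc_sd + 1 / 2001)
})

test_that("ranking by absolute fold change is supported", {
  expr <- tibble::tibble(gene_id = paste0("g", 1:6),
                         fold_change = c(-5, 4, -3, 2, 1, -0.5))
  res <- ks_running_enrichment(expr, c("g1", "g3"),
                               rank_by = "abs_fold_change")
  expect_identical(res$running$gene_id[1:2], c("g1", "g2"))
  expect_true(res$running$is_hit[1])
})

test_that("planted expression signal is detected in the right direction", {
  w <- default_world()
  res <- ks_running_enrichment(w$expression, w$truth$bound_genes,
                               n_permutations = 999, seed = 9)
  expect_gt(res$es, 0)
  expect_lte(res$p_perm, 0.05)
})

test_that("hypergeometric overlap matches combinatorial enumeration", {
  got <- hypergeometric_overlap(10, set1 = 5, set2 = 4, overlap = 4)
  expect_equal(got$p_hyper, 5 / 210, tolerance = 1e-12)

  expect_equal(hypergeometric_overlap(30, 10, 8, overlap = 0)$p_hyper, 1)

  # most-extreme overlap equals the single most-extreme term
  ext <- hypergeometric_overlap(20, 4, 3, overlap = 3)
  expect_equal(ext$p_hyper, choose(4, 3) / choose(20, 3) *
                 choose(16, 0), tolerance = 1e-12)

  set.seed(59)
  for (rep in 1:25) {
    N <- sample(5:20, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    ovs <- max(0, K + n - N):min(K, n)
    ov <- ovs[sample.int(length(ovs), 1)]
    got <- hypergeometric_overlap(N, K, n, overlap = ov)$p_hyper
    expect_equal(got, hyper_oracle(N, K, n, ov), tolerance = 1e-12)
  }

  # id-vector interface
  u <- paste0("g", 1:10)
  r <- hypergeometric_overlap(10, u[1:5], u[c(1:4, 8)])
  expect_identical(r$overlap, 4L)
  expect_error(hypergeometric_overlap(10, 12, 4, overlap = 2),
               class = "cistromer_bad_input")
})
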