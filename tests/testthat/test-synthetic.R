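small_cfg <- function(...) {
  args <- list(seed = 11L, chrom_lengths = c(chr1 = 100000L),
               n_genes = 10L, n_sites = 30L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

test_that("genome generation honours composition and determinism", {
  cfg <- small_cfg(gc_content = 1.0, n_genes = 0L, n_sites = 0L)
  g <- simulate_genome(cfg)
  expect_false(grepl("[AT]", as.character(g)[[1]]))

  cfg <- sim_config(seed = 3L, chrom_lengths = c(chr1 = 100000L),
                    gc_content = 0.42)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1), as.character(g2))

  # observed GC within 3 binomial SDs of 0.42 at n = 100 kb
  chars <- strsplit(as.character(g1)[[1]], "")[[1]]
  gc <- mean(chars %in% c("G", "C"))
  expect_lt(abs(gc - 0.42), 3 * sqrt(0.42 * 0.58 / 100000))

  expect_error(sim_config(gc_content = 1.4), class = "cistromer_bad_input")
})

test_that("gene models are non-overlapping, validated, strand-balanced", {
  expect_identical(nrow(simulate_gene_models(
    simulate_genome(small_cfg(n_genes = 0L)), small_cfg(n_genes = 0L))), 0L)

  cfg <- sim_config(seed = 8L, chrom_lengths = c(chr1 = 1000000L),
                    n_genes = 50L)
  genome <- simulate_genome(cfg)
  genes <- simulate_gene_models(genome, cfg)
  expect_identical(nrow(genes), 50L)
  # pairwise transcript overlap is zero
  ord <- order(genes$chrom, genes$tx_start)
  s <- genes[ord, ]
  same <- s$chrom[-1] == s$chrom[-nrow(s)]
  expect_true(all(s$tx_start[-1][same] >= s$tx_end[-nrow(s)][same]))
  # validator passes (check_gene_models runs inside the generator; verify
  # invariants visibly too)
  expect_true(all(s$cds_start >= s$tx_start & s$cds_end <= s$tx_end))
  # strand counts within 3 SDs of 25/25
  expect_lt(abs(sum(genes$strand == "+") - 25), 3 * sqrt(50 * 0.25) + 1e-9)
})

test_that("motif planting writes the consensus and hits its promoter quota", {
  cfg <- small_cfg(n_sites = 0L)
  genome <- simulate_genome(cfg)
  genes <- simulate_gene_models(genome, cfg)
  out <- plant_motif_sites(genome, genes, cfg)
  expect_identical(as.character(out$genome), as.character(genome))
  expect_identical(nrow(out$truth$sites), 0L)

  cfg <- sim_config(seed = 5L, chrom_lengths = c(chr1 = 1000000L),
                    n_genes = 60L, n_sites = 200L,
                    promoter_site_fraction = 0.24)
  genome <- simulate_genome(cfg)
  genes <- simulate_gene_models(genome, cfg)
  out <- plant_motif_sites(genome, genes, cfg)
  sites <- out$truth$sites
  expect_identical(nrow(sites), 200L)
  chars <- as.character(out$genome)
  written <- substring(chars[sites$chrom], sites$start + 1, sites$end)
  expect_true(all(written[sites$strand == "+"] == cfg$consensus))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(cfg$consensus)))
  expect_true(all(written[sites$strand == "-"] == rc))
  # promoter-proximal fraction within 3 binomial SDs of 0.24
  expect_lt(abs(mean(sites$promoter_placed) - 0.24),
            3 * sqrt(0.24 * 0.76 / 200))
  # bound genes are a subset of the gene ids
  expect_true(all(out$truth$bound_genes %in% genes$gene_id))
})

test_that("tag simulation reproduces the bimodal strand shift", {
  # no background, no sites: zero tags
  cfg <- small_cfg(n_sites = 0L, background_tag_rate = 0)
  genome <- simulate_genome(cfg)
  empty_truth <- plant_motif_sites(genome, toy_genes()[0, ], cfg)$truth
  tags <- simulate_tags(genome, empty_truth, cfg)
  expect_identical(nrow(tags$treatment), 0L)
  expect_identical(nrow(tags$control), 0L)

  # one site with ~500 tags per strand: strand mode separation = d +- 10
  cfg <- sim_config(seed = 21L, chrom_lengths = c(chr1 = 50000L),
                    n_sites = 1L, n_genes = 0L, tags_per_site_mean = 500,
                    background_tag_rate = 0, fragment_shift_d = 152L)
  genome <- simulate_genome(cfg)
  planted <- plant_motif_sites(genome, toy_genes()[0, ], cfg)
  tags <- simulate_tags(planted$genome, planted$truth, cfg)$treatment
  p5 <- ifelse(tags$strand == "+", tags$start, tags$end - 1L)
  # kernel width of order jitter SD/1.5 keeps the mode estimate stable
  dens_f <- density(p5[tags$strand == "+"], bw = 25)
  dens_r <- density(p5[tags$strand == "-"], bw = 25)
  sep <- dens_r$x[which.max(dens_r$y)] - dens_f$x[which.max(dens_f$y)]
  expect_lt(abs(sep - 152), 10)

  # total treatment tag count near n_sites * 2 * mean + background mass
  cfg <- sim_config(seed = 9L, chrom_lengths = c(chr1 = 500000L),
                    n_genes = 20L, n_sites = 100L, tags_per_site_mean = 30,
                    background_tag_rate = 0.001)
  genome <- simulate_genome(cfg)
  genes <- simulate_gene_models(genome, cfg)
  planted <- plant_motif_sites(genome, genes, cfg)
  tags <- simulate_tags(planted$genome, planted$truth, cfg)
  expected <- 100 * 2 * 30 + 0.001 * 500000
  expect_lt(abs(nrow(tags$treatment) - expected), 3 * sqrt(expected))
})

test_that("expression simulation shifts bound genes and is deterministic", {
  cfg <- sim_config(seed = 14L, chrom_lengths = c(chr1 = 1000000L),
                    n_genes = 60L, n_sites = 100L)
  genome <- simulate_genome(cfg)
  genes <- simulate_gene_models(genome, cfg)
  truth <- plant_motif_sites(genome, genes, cfg)$truth

  # null effect: bound-gene ranks not systematically shifted
  cfg0 <- cfg
  cfg0$expression_effect <- 0
  e0 <- simulate_expression(genes, truth, cfg0)
  pv <- wilcox.test(e0$rank[e0$gene_id %in% truth$bound_genes],
                    e0$rank[!e0$gene_id %in% truth$bound_genes])$p.value
  expect_gt(pv, 0.01)

  # effect 2: bound genes rank higher (smaller rank number)
  e2 <- simulate_expression(genes, truth, cfg)
  expect_lt(mean(e2$rank[e2$gene_id %in% truth$bound_genes]),
            mean(e2$rank[!e2$gene_id %in% truth$bound_genes]))

  expect_identical(simulate_expression(genes, truth, cfg), e2)
})

test_that("fixture set re-reads to the same world", {
  cfg <- small_cfg()
  world <- simulate_world(cfg)
  dir <- withr::local_tempdir()
  files <- write_fixture_set(world, dir)
  expect_length(files, 7)
  expect_true(all(file.exists(files)))

  genome <- read_fasta(files[["genome"]])
  expect_identical(as.character(genome), as.character(world$genome))
  # ground-truth loci recoverable from the emitted FASTA
  sites <- world$truth$sites
  plus <- sites[sites$strand == "+", ]
  got <- substring(as.character(genome)[plus$chrom], plus$start + 1,
                   plus$end)
  expect_true(all(got == cfg$consensus))

  genes <- read_gene_models(files[["genes"]])
  expect_identical(genes$tx_start, world$genes$tx_start)
  treatment <- read_bed(files[["treatment"]], kind = "tag")
  expect_identical(nrow(treatment), nrow(world$treatment))
  expect_identical(treatment$start, world$treatment$start)
})

test_that("different seeds give different tag collections", {
  w1 <- simulate_world(small_cfg())
  cfg2 <- small_cfg()
  cfg2$seed <- 12L
  w2 <- simulate_world(cfg2)
  expect_false(identical(w1$treatment$start, w2$treatment$start))
})
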