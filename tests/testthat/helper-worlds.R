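# Shared fixtures, computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# The default synthetic study world, plus the peak calls and motif scan
# derived from it. One fixed seed for the whole suite.
WORLD_SEED <- 101L

default_world <- function() {
  cached("world", simulate_world(sim_config(seed = WORLD_SEED)))
}

default_model <- function() {
  cached("model", {
    w <- default_world()
    estimate_fragment_shift(w$treatment, w$genome)
  })
}

default_peaks <- function() {
  cached("peaks", {
    w <- default_world()
    call_peaks(w$treatment, w$control, default_model(),
               peak_calling_config(), w$genome)
  })
}

default_motif <- function() {
  cached("motif", {
    w <- default_world()
    peaks <- default_peaks()
    seqs <- extract_sequences_for_test(w$genome, peaks)
    bg <- shuffle_sequences(seqs, seed = 7L)
    kmer <- find_enriched_kmer(seqs, k = 9L, background_sequences = bg)
    pwm <- build_pwm(kmer$occurrences)
    baseline <- genome_baseline(pwm, w$genome, coding_intervals(w$genes))
    scan <- scan_peaks(peaks, w$genome, pwm, baseline, scan_config())
    list(kmer = kmer, pwm = pwm, baseline = baseline, scan = scan)
  })
}

# Sequence extraction for tests without reaching into internals.
extract_sequences_for_test <- function(genome, intervals) {
  chars <- as.character(genome)
  unname(substring(chars[intervals$chrom], intervals$start + 1,
                   intervals$end))
}

# A tiny hand-built world: two chromosomes, five genes with known
# structure, used for exact annotation checks.
toy_genes <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC", "gD", "gE"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    strand = c("+", "-", "+", "-", "+"),
    tx_start = c(10000L, 40000L, 70000L, 10000L, 50000L),
    tx_end = c(20000L, 50000L, 74000L, 18000L, 56000L),
    cds_start = c(10300L, 40500L, 70400L, 10200L, 50100L),
    cds_end = c(19500L, 49600L, 73800L, 17600L, 55900L),
    exon_starts = list(c(10000L, 15000L), c(40000L, 46000L),
                       70000L, c(10000L, 13000L, 16000L), 50000L),
    exon_ends = list(c(12000L, 20000L), c(42000L, 50000L),
                     74000L, c(11000L, 14000L, 18000L), 56000L)
  )
}

toy_genome <- function() {
  cached("toy_genome", {
    set.seed(99)
    s <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
    Biostrings::DNAStringSet(c(chr1 = s(100000), chr2 = s(80000)))
  })
}

# Hand-derived expectations for the five-gene toy world.
toy_summits <- function() {
  tibble::tribble(
    ~chrom, ~summit, ~class, ~gene, ~tss_dist,
    "chr1",  9500L, "promoter",   "gA",   -500L,
    "chr1", 10100L, "utr5",       "gA",    100L,
    "chr1", 11000L, "exon",       "gA",   1000L,
    "chr1", 13000L, "intron",     "gA",   3000L,
    "chr1", 19700L, "utr3",       "gA",   9700L,
    "chr1", 20500L, "downstream", "gA",  10500L,
    "chr1", 25000L, "intergenic", "gA",  15000L,
    "chr1", 51000L, "promoter",   "gB",  -1001L,
    "chr1", 49800L, "utr5",       "gB",    199L,
    "chr1", 41000L, "exon",       "gB",   8999L,
    "chr1", 43000L, "intron",     "gB",   6999L,
    "chr1", 40200L, "utr3",       "gB",   9799L,
    "chr1", 39000L, "downstream", "gB",  10999L,
    "chr1", 69000L, "promoter",   "gC",  -1000L,
    "chr1", 70200L, "utr5",       "gC",    200L,
    "chr2", 19000L, "promoter",   "gD",  -1001L,
    "chr2", 17800L, "utr5",       "gD",    199L,
    "chr2", 12000L, "intron",     "gD",   5999L,
    "chr2", 49000L, "promoter",   "gE",  -1000L,
    "chr2", 55950L, "utr3",       "gE",   5950L
  )
}

make_peaks <- function(chrom, summit, half_width = 150L) {
  tibble::tibble(chrom = chrom, start = summit - half_width,
                 end = summit + half_width, summit = summit,
                 name = paste0("peak_", seq_along(summit)))
}

make_tags <- function(chrom, start, strand, read_length = 39L) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(start + read_length),
                 name = paste0("t", seq_along(start)), strand = strand)
}
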