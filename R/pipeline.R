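#' Pipeline configuration
#'
#' One object driving the full analysis chain: simulate (or load) inputs,
#' call peaks, annotate, scan motifs, test co-occupancy, and run the
#' ranked-list enrichment. A single global `seed` deterministically
#' derives every stage seed (see [derive_seed()]), so identical
#' configurations yield byte-identical reports.
#'
#' @param seed Global integer seed.
#' @param outdir Output directory, or `NULL` to skip writing files.
#' @param sim A [sim_config()]; defaults to one seeded from `seed`.
#' @param peak A [peak_calling_config()].
#' @param annotation An [annotation_config()].
#' @param scan A [scan_config()].
#' @param motif List: `k` (motif width) and `pseudocount`.
#' @param cooccupancy List: `slop_bp` and `n_resamples`. The comparison
#'   set B defaults to the ground-truth planted sites; supply `peaks_b`
#'   (a peak tibble or BED path) to compare against another cistrome.
#' @param ks List: `n_permutations`, `rank_by`, `window_bp` (peak-to-gene
#'   window).
#' @param peaks_b Optional second peak set for co-occupancy.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, outdir = NULL,
                            sim = NULL,
                            peak = peak_calling_config(),
                            annotation = annotation_config(),
                            scan = scan_config(),
                            motif = list(k = 9L, pseudocount = 0.5),
                            cooccupancy = list(slop_bp = 0L,
                                               n_resamples = 99L),
                            ks = list(n_permutations = 999L,
                                      rank_by = "fold_change",
                                      window_bp = 10000L),
                            peaks_b = NULL) {
  if (is.null(sim)) sim <- sim_config(seed = derive_seed(seed, "simulate"))
  structure(list(seed = as.integer(seed), outdir = outdir, sim = sim,
                 peak = peak, annotation = annotation, scan = scan,
                 motif = motif, cooccupancy = cooccupancy, ks = ks,
                 peaks_b = peaks_b),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — synthetic world, fragment-shift model,
#' peak calling, feature annotation, motif discovery/baseline/scan,
#' co-occupancy resampling, and running-sum enrichment — and returns (and
#' optionally writes) a machine-readable report. When ground truth is
#' available, site recovery and peak precision are reported too.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list; when `config$outdir` is set, all stage
#'   outputs plus `report.json` are written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  world <- simulate_world(config$sim)
  genome <- world$genome
  genes <- world$genes

  model <- estimate_fragment_shift(world$treatment, genome, config$peak)
  peaks <- call_peaks(world$treatment, world$control, model, config$peak,
                      genome)

  classified <- classify_peaks(peaks, genes, config$annotation)
  summary <- annotation_summary(classified)
  tss <- summit_to_tss_distances(peaks, genes)

  motif_res <- run_motif_stage(peaks, genome, genes, config)
  scan <- motif_res$scan

  set_b <- resolve_peaks_b(world, config)
  co <- overlap_significance(peaks, set_b, genome,
                             n_resamples = config$cooccupancy$n_resamples,
                             slop_bp = config$cooccupancy$slop_bp,
                             seed = derive_seed(config$seed, "cooccupancy"))

  hit_genes <- peaks_to_genes(peaks, genes,
                              window_bp = config$ks$window_bp)
  if (nrow(hit_genes) >= nrow(world$expression)) {
    # dense worlds saturate the 10 kb window (every gene is near a peak);
    # fall back to the TSS-proximal gene set so the statistic is defined
    hit_genes <- tibble(gene_id = sort(unique(stats::na.omit(
      classified$feature_gene[classified$feature_class %in%
                                c("promoter", "utr5")]))))
  }
  ks <- if (nrow(hit_genes) > 0 &&
            nrow(hit_genes) < nrow(world$expression)) {
    ks_running_enrichment(world$expression, hit_genes,
                          n_permutations = config$ks$n_permutations,
                          seed = derive_seed(config$seed, "ks"),
                          rank_by = config$ks$rank_by)
  }

  recovery <- truth_recovery(peaks, world$truth)
  report <- list(
    seed = config$seed,
    parameters = list(
      mfold = config$peak$mfold, bandwidth = config$peak$bandwidth,
      p_cutoff = config$peak$p_cutoff, fdr_cutoff = config$peak$fdr_cutoff,
      z_cutoff = config$scan$z_cutoff, motif_k = config$motif$k,
      n_resamples = config$cooccupancy$n_resamples,
      ks_permutations = config$ks$n_permutations
    ),
    fragment_shift_d = model$fragment_shift_d,
    n_model_regions = model$n_model_regions,
    n_peaks = nrow(peaks),
    feature_fractions = as.list(stats::setNames(summary$fraction,
                                                summary$feature_class)),
    motif = list(consensus = motif_res$kmer$consensus,
                 fraction_with_hit = scan$fraction_with_hit,
                 baseline_mean = motif_res$baseline$mean_score,
                 baseline_sd = motif_res$baseline$sd_score),
    cooccupancy = list(fraction_a = co$fraction_a,
                       n_a_with_b = co$n_a_with_b,
                       empirical_p = co$empirical_p),
    ks = if (!is.null(ks)) list(es = ks$es, p_perm = ks$p_perm,
                                n_hits = ks$n_hits) else NULL,
    recovery = recovery
  )
  if (!is.null(config$outdir)) {
    write_pipeline_outputs(config$outdir, world, model, peaks, classified,
                           tss, motif_res, ks, report)
  }
  structure(list(report = report, world = world, model = model,
                 peaks = peaks, classified = classified, summary = summary,
                 tss_distances = tss, kmer = motif_res$kmer,
                 pwm = motif_res$pwm, baseline = motif_res$baseline,
                 scan = scan, cooccupancy = co, ks = ks),
            class = "run_report")
}

run_motif_stage <- function(peaks, genome, genes, config) {
  seqs <- extract_sequences(genome, peaks)
  bg_seqs <- shuffle_sequences(seqs,
                               seed = derive_seed(config$seed,
                                                  "motif_background"))
  kmer <- find_enriched_kmer(seqs, k = config$motif$k,
                             background_sequences = bg_seqs)
  pwm <- build_pwm(kmer$occurrences,
                   pseudocount = config$motif$pseudocount)
  baseline <- genome_baseline(pwm, genome, coding_intervals(genes))
  scan <- scan_peaks(peaks, genome, pwm, baseline, config$scan)
  distances <- summit_site_distances(scan, peaks,
                                     seed = derive_seed(config$seed,
                                                        "site_distances"))
  list(kmer = kmer, pwm = pwm, baseline = baseline, scan = scan,
       distances = distances)
}

resolve_peaks_b <- function(world, config) {
  if (is.null(config$peaks_b)) {
    sites <- world$truth$sites
    tibble(chrom = sites$chrom, start = sites$start, end = sites$end,
           summit = sites$start + (sites$end - sites$start) %/% 2L,
           name = paste0("site_", seq_len(nrow(sites))))
  } else if (is.character(config$peaks_b)) {
    read_bed(config$peaks_b, kind = "peak", genome = world$genome)
  } else {
    config$peaks_b
  }
}

# Fraction of planted sites inside a called peak, and of peaks holding one.
truth_recovery <- function(peaks, truth) {
  sites <- truth$sites
  if (nrow(sites) == 0 || nrow(peaks) == 0) {
    return(list(site_sensitivity = NA_real_, peak_precision = NA_real_))
  }
  pairs <- overlap_pairs(sites, peaks, 0L)
  list(site_sensitivity = length(unique(pairs$a)) / nrow(sites),
       peak_precision = length(unique(pairs$b)) / nrow(peaks))
}

write_pipeline_outputs <- function(outdir, world, model, peaks, classified,
                                   tss, motif_res, ks, report) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fixture_set(world, file.path(outdir, "fixtures"))
  write_bed(peaks, file.path(outdir, "peaks.bed"))
  write_bedgraph(pileup_track(world$treatment, world$genome,
                              model$fragment_shift_d),
                 file.path(outdir, "pileup.bedGraph"))
  ann <- classified
  ann$feature_class <- as.character(ann$feature_class)
  readr::write_tsv(left_join(ann, tss, by = "name"),
                   file.path(outdir, "annotation.tsv"), progress = FALSE)
  write_pwm(motif_res$pwm, file.path(outdir, "pwm.txt"))
  hits <- motif_res$scan$hits
  if (nrow(hits) > 0) {
    write_bed(tibble(chrom = hits$chrom, start = hits$start,
                     end = hits$end, name = hits$name,
                     strand = hits$strand),
              file.path(outdir, "motif_hits.bed"))
  }
  if (!is.null(ks)) {
    readr::write_tsv(ks$running, file.path(outdir, "ks_curve.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(outdir)
}
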