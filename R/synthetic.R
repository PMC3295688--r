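#' Configuration for the synthetic ChIP-seq world
#'
#' Bundles every parameter of the synthetic-data generator. Defaults
#' describe the study conditions the pipeline is validated under: a 1 Mb
#' two-chromosome genome at mouse-like GC content, 200 planted
#' nuclear-receptor half-sites of which 24.1% sit within 2 kb upstream of
#' a TSS, tags of 39 bp with a fragment shift d = 152 bp, and an
#' expression table in which site-proximal ("bound") genes carry an
#' elevated fold change.
#'
#' @param seed Integer seed; one seed fully determines the whole world.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param gc_content Genome G+C fraction in `[0, 1]`.
#' @param n_genes Number of non-overlapping gene models to place.
#' @param n_sites Number of motif instances to plant.
#' @param promoter_site_fraction Probability that a planted site falls
#'   within 2 kb upstream of a TSS (the remainder are placed uniformly
#'   outside all promoter windows).
#' @param fragment_shift_d Distance (bp) between forward- and
#'   reverse-strand tag modes flanking a site.
#' @param tags_per_site_mean Poisson mean tag count per site and strand.
#' @param background_tag_rate Uniform background tag rate (tags per bp),
#'   applied to both the treatment and the control collection.
#' @param read_length Tag length in bp.
#' @param expression_effect Additive mean fold-change shift for bound genes.
#' @param consensus Half-site consensus planted into the genome.
#' @param promoter_bp Width of the upstream window used both for promoter
#'   placement and for the bound-gene definition.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 600000L, chr2 = 400000L),
                       gc_content = 0.42,
                       n_genes = 60L,
                       n_sites = 200L,
                       promoter_site_fraction = 0.241,
                       fragment_shift_d = 152L,
                       tags_per_site_mean = 30,
                       background_tag_rate = 0.001,
                       read_length = 39L,
                       expression_effect = 2,
                       consensus = "CCAAGGTCA",
                       promoter_bp = 2000L) {
  cfg <- list(seed = as.integer(seed),
              chrom_lengths = chrom_lengths,
              gc_content = gc_content,
              n_genes = as.integer(n_genes),
              n_sites = as.integer(n_sites),
              promoter_site_fraction = promoter_site_fraction,
              fragment_shift_d = as.integer(fragment_shift_d),
              tags_per_site_mean = tags_per_site_mean,
              background_tag_rate = background_tag_rate,
              read_length = as.integer(read_length),
              expression_effect = expression_effect,
              consensus = toupper(consensus),
              promoter_bp = as.integer(promoter_bp))
  if (length(cfg$chrom_lengths) == 0 || any(cfg$chrom_lengths <= 0)) {
    abort("chrom_lengths must be positive", class = "cistromer_bad_input")
  }
  if (is.null(names(cfg$chrom_lengths))) {
    names(cfg$chrom_lengths) <- paste0("chr", seq_along(cfg$chrom_lengths))
  }
  if (cfg$gc_content < 0 || cfg$gc_content > 1) {
    abort("gc_content must be in [0, 1]", class = "cistromer_bad_input")
  }
  if (cfg$promoter_site_fraction < 0 || cfg$promoter_site_fraction > 1) {
    abort("promoter_site_fraction must be in [0, 1]",
          class = "cistromer_bad_input")
  }
  if (cfg$fragment_shift_d <= 0) {
    abort("fragment_shift_d must be positive", class = "cistromer_bad_input")
  }
  if (cfg$n_sites < 0 || cfg$n_genes < 0 || cfg$tags_per_site_mean < 0 ||
      cfg$background_tag_rate < 0 || cfg$expression_effect < 0) {
    abort("counts, rates and effects must be non-negative",
          class = "cistromer_bad_input")
  }
  if (grepl("[^ACGT]", cfg$consensus)) {
    abort("consensus must be over {A,C,G,T}", class = "cistromer_bad_input")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a random genome
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = gc_content` (split equally
#' within each pair). Identical seeds give byte-identical genomes.
#'
#' @param config A [sim_config()].
#' @return A [Biostrings::DNAStringSet].
#' @export
simulate_genome <- function(config) {
  gc <- config$gc_content
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(derive_seed(config$seed, "genome"), {
    seqs <- vapply(config$chrom_lengths, function(len) {
      paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
    }, "")
  })
  stats::setNames(Biostrings::DNAStringSet(seqs), names(config$chrom_lengths))
}

#' Generate non-overlapping gene models
#'
#' Transcripts (2-8 kb) are placed uniformly without overlap, strands
#' assigned at random; each model gets 1-4 exons separated by introns, a
#' 5'UTR, a CDS and a 3'UTR, and satisfies all gene-model invariants.
#'
#' @param genome Genome the models are placed on.
#' @param config A [sim_config()].
#' @return A gene-model tibble (see [read_gene_models()]).
#' @export
simulate_gene_models <- function(genome, config) {
  n <- config$n_genes
  if (n == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), tx_start = integer(),
                  tx_end = integer(), cds_start = integer(),
                  cds_end = integer(),
                  exon_starts = list(), exon_ends = list()))
  }
  lens <- chrom_lengths_of(genome)
  with_seed(derive_seed(config$seed, "genes"), {
    placed <- lapply(names(lens), function(ch) cbind(start = integer(),
                                                     end = integer()))
    names(placed) <- names(lens)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(500)) {
        L <- sample(2000:8000, 1)
        valid <- names(lens)[lens > L + 2]
        if (length(valid) == 0) next
        ch <- sample(valid, 1, prob = lens[valid])
        s <- sample.int(lens[ch] - L, 1)
        e <- s + L
        prev <- placed[[ch]]
        if (nrow(prev) == 0 || all(e <= prev[, 1] | s >= prev[, 2])) {
          placed[[ch]] <- rbind(prev, c(s, e))
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort("could not place requested genes without overlap",
              class = "cistromer_placement_error")
      }
      n_ex <- sample(1:4, 1)
      # partition transcript into exons (>=150 bp) and introns (>=100 bp)
      mins <- c(rep(150, n_ex), rep(100, n_ex - 1))
      extra <- L - sum(mins)
      w <- runif(2 * n_ex - 1)
      lens_i <- mins + floor(extra * w / sum(w))
      lens_i[1] <- lens_i[1] + (L - sum(lens_i))
      bounds <- s + cumsum(c(0, lens_i))
      ex_idx <- seq(1, 2 * n_ex - 1, by = 2)
      es <- as.integer(bounds[ex_idx])
      ee <- as.integer(bounds[ex_idx + 1])
      u5 <- sample(30:min(120L, ee[1] - es[1] - 30L), 1)
      u3 <- sample(30:min(120L, ee[n_ex] - es[n_ex] - 30L), 1)
      rows[[i]] <- tibble(
        gene_id = sprintf("gene_%03d", i), chrom = ch,
        strand = sample(c("+", "-"), 1),
        tx_start = as.integer(s), tx_end = as.integer(e),
        cds_start = as.integer(s + u5), cds_end = as.integer(e - u3),
        exon_starts = list(es), exon_ends = list(ee))
    }
    genes <- bind_rows(rows)
  })
  check_gene_models(genes)
  genes
}

# Strand-aware promoter windows [start, end) upstream of each TSS.
promoter_windows <- function(genes, promoter_bp) {
  tibble(
    chrom = genes$chrom,
    start = ifelse(genes$strand == "+",
                   pmax(genes$tx_start - promoter_bp, 0L),
                   genes$tx_end),
    end = ifelse(genes$strand == "+", genes$tx_start,
                 genes$tx_end + promoter_bp),
    gene_id = genes$gene_id
  )
}

#' Plant motif instances into a genome
#'
#' Overwrites the genome with the consensus (or its reverse complement for
#' minus-strand placements) at each chosen locus. A `promoter_site_fraction`
#' Bernoulli draw decides, per site, whether it is placed inside a 2 kb
#' upstream promoter window of a random gene or uniformly outside all
#' promoter windows. Sites never overlap each other.
#'
#' @param genome Genome to modify.
#' @param genes Gene models (used for promoter windows; may be empty, in
#'   which case all sites are placed uniformly).
#' @param config A [sim_config()].
#' @return A list with elements `genome` (modified) and `truth`, the
#'   ground-truth ledger: `sites` (tibble with chrom, start, end, strand,
#'   promoter_placed) and `bound_genes` (gene ids with a site within the
#'   promoter window distance of their TSS).
#' @export
plant_motif_sites <- function(genome, genes, config) {
  w <- nchar(config$consensus)
  lens <- chrom_lengths_of(genome)
  if (w > min(lens)) {
    abort("consensus longer than the smallest chromosome",
          class = "cistromer_bad_input")
  }
  if (config$n_sites == 0) {
    truth <- list(sites = tibble(chrom = character(), start = integer(),
                                 end = integer(), strand = character(),
                                 promoter_placed = logical()),
                  bound_genes = character())
    return(list(genome = genome, truth = truth))
  }
  prom <- promoter_windows(genes, config$promoter_bp)
  # clamp to the chromosome so sites can never extend past the end
  prom$start <- pmax(prom$start, 0L)
  prom$end <- pmin(prom$end, unname(lens[prom$chrom]))
  prom <- prom[prom$end - prom$start >= w, , drop = FALSE]
  with_seed(derive_seed(config$seed, "sites"), {
    in_prom <- runif(config$n_sites) < config$promoter_site_fraction
    if (nrow(prom) == 0) in_prom[] <- FALSE
    sites <- vector("list", config$n_sites)
    taken <- lapply(names(lens), function(ch) cbind(integer(), integer()))
    names(taken) <- names(lens)
    for (i in seq_len(config$n_sites)) {
      ok <- FALSE
      for (try in seq_len(1000)) {
        if (in_prom[i]) {
          j <- sample.int(nrow(prom), 1)
          ch <- prom$chrom[j]
          s <- prom$start[j] + sample.int(prom$end[j] - prom$start[j] - w + 1,
                                          1) - 1L
        } else {
          ch <- sample(names(lens), 1, prob = lens)
          s <- sample.int(lens[ch] - w + 1, 1) - 1L
          pc <- prom[prom$chrom == ch, , drop = FALSE]
          if (nrow(pc) && any(s < pc$end & s + w > pc$start)) next
        }
        tk <- taken[[ch]]
        if (nrow(tk) == 0 || all(s + w <= tk[, 1] | s >= tk[, 2])) {
          taken[[ch]] <- rbind(tk, c(s, s + w))
          sites[[i]] <- tibble(chrom = ch, start = as.integer(s),
                               end = as.integer(s + w),
                               strand = sample(c("+", "-"), 1),
                               promoter_placed = in_prom[i])
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort("could not place requested motif sites without overlap",
              class = "cistromer_placement_error")
      }
    }
    sites <- bind_rows(sites)
  })
  chars <- genome_chars(genome)
  for (i in seq_len(nrow(sites))) {
    ins <- if (sites$strand[i] == "+") config$consensus else
      revcomp_chr(config$consensus)
    substr(chars[[sites$chrom[i]]], sites$start[i] + 1, sites$end[i]) <- ins
  }
  genome <- stats::setNames(Biostrings::DNAStringSet(chars), names(chars))
  bound <- bound_gene_ids(sites, genes, config$promoter_bp)
  list(genome = genome,
       truth = list(sites = sites, bound_genes = bound))
}

bound_gene_ids <- function(sites, genes, window_bp) {
  if (nrow(genes) == 0 || nrow(sites) == 0) return(character())
  tss <- gene_tss(genes)
  bound <- vapply(seq_len(nrow(genes)), function(i) {
    same <- sites$chrom == genes$chrom[i]
    if (!any(same)) return(FALSE)
    d <- pmax(sites$start[same] - tss[i], tss[i] - (sites$end[same] - 1L), 0L)
    any(d <= window_bp)
  }, logical(1))
  genes$gene_id[bound]
}

#' Simulate treatment and control tag collections
#'
#' For each ground-truth site, `Poisson(tags_per_site_mean)` forward tags
#' have their 5' ends near `center - d/2` and an equal-rate set of reverse
#' tags have their 5' ends near `center + d/2`; positions are jittered with
#' a discretized normal of SD `d/4`. Uniform background tags at
#' `background_tag_rate` per bp are added to both collections; the control
#' contains background only.
#'
#' @param genome Genome (for chromosome bounds).
#' @param truth Ground truth from [plant_motif_sites()].
#' @param config A [sim_config()].
#' @return List with `treatment` and `control` tag tibbles and
#'   `site_tags`, the per-site forward/reverse tag counts.
#' @export
simulate_tags <- function(genome, truth, config) {
  lens <- chrom_lengths_of(genome)
  d <- config$fragment_shift_d
  L <- config$read_length
  sites <- truth$sites
  with_seed(derive_seed(config$seed, "tags"), {
    sig <- NULL
    site_tags <- tibble(site = integer(), n_fwd = integer(),
                        n_rev = integer())
    if (nrow(sites) > 0) {
      nf <- rpois(nrow(sites), config$tags_per_site_mean)
      nr <- rpois(nrow(sites), config$tags_per_site_mean)
      site_tags <- tibble(site = seq_len(nrow(sites)), n_fwd = nf,
                          n_rev = nr)
      center <- (sites$start + sites$end) %/% 2L
      fwd <- tibble(
        chrom = rep(sites$chrom, nf),
        p5 = round(rep(center, nf) - d / 2 + rnorm(sum(nf), 0, d / 4)),
        strand = "+")
      rev <- tibble(
        chrom = rep(sites$chrom, nr),
        p5 = round(rep(center, nr) + d / 2 + rnorm(sum(nr), 0, d / 4)),
        strand = "-")
      sig <- bind_rows(fwd, rev)
    }
    bg_t <- uniform_tags(lens, config$background_tag_rate)
    bg_c <- uniform_tags(lens, config$background_tag_rate)
  })
  treatment <- tags_from_5p(bind_rows(sig, bg_t), lens, L)
  control <- tags_from_5p(bg_c, lens, L)
  list(treatment = treatment, control = control, site_tags = site_tags)
}

uniform_tags <- function(lens, rate) {
  n <- rpois(1, rate * sum(lens))
  if (n == 0) {
    return(tibble(chrom = character(), p5 = integer(), strand = character()))
  }
  ch <- sample(names(lens), n, replace = TRUE, prob = lens)
  tibble(chrom = ch,
         p5 = floor(runif(n) * lens[ch]),
         strand = sample(c("+", "-"), n, replace = TRUE))
}

# Build [start,end) tag intervals from 5' positions, truncating to bounds.
tags_from_5p <- function(x, lens, read_length) {
  if (is.null(x) || nrow(x) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), strand = character()))
  }
  maxlen <- lens[x$chrom]
  p5 <- ifelse(x$strand == "+",
               pmin(pmax(x$p5, 0), maxlen - read_length),
               pmin(pmax(x$p5, read_length - 1), maxlen - 1))
  start <- as.integer(ifelse(x$strand == "+", p5, p5 - read_length + 1))
  tibble(chrom = x$chrom, start = start,
         end = start + as.integer(read_length),
         name = paste0("tag_", seq_len(nrow(x))),
         strand = x$strand)
}

#' Simulate an expression table with planted signal
#'
#' Fold changes are standard normal; genes bound in the ground truth are
#' shifted upward by `expression_effect`. Ranks order genes by descending
#' fold change.
#'
#' @param genes Gene models.
#' @param truth Ground truth from [plant_motif_sites()].
#' @param config A [sim_config()].
#' @return Expression tibble (`gene_id`, `fold_change`, `rank`), sorted by
#'   rank.
#' @export
simulate_expression <- function(genes, truth, config) {
  with_seed(derive_seed(config$seed, "expression"), {
    fc <- rnorm(nrow(genes))
  })
  fc[genes$gene_id %in% truth$bound_genes] <-
    fc[genes$gene_id %in% truth$bound_genes] + config$expression_effect
  out <- tibble(gene_id = genes$gene_id, fold_change = fc)
  out$rank <- rank_expression(out$fold_change)
  arrange(out, .data$rank)
}

#' Build a complete synthetic world
#'
#' Runs all generators in order and returns every object the downstream
#' pipeline needs, fully determined by `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `genome`, `genes`, `truth`, `treatment`, `control`,
#'   `site_tags`, `expression`, and the `config` echo.
#' @export
simulate_world <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  genes <- simulate_gene_models(genome, config)
  planted <- plant_motif_sites(genome, genes, config)
  tags <- simulate_tags(planted$genome, planted$truth, config)
  expr <- simulate_expression(genes, planted$truth, config)
  list(genome = planted$genome, genes = genes, truth = planted$truth,
       treatment = tags$treatment, control = tags$control,
       site_tags = tags$site_tags, expression = expr, config = config)
}

#' Write the complete fixture set for a synthetic world
#'
#' Emits genome FASTA, gene-model TSV, ground-truth site BED, treatment
#' and control tag BED, expression TSV, and a YAML echo of the
#' configuration (7 files).
#'
#' @param world Output of [simulate_world()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixture_set <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.tsv"),
    truth = file.path(dir, "truth_sites.bed"),
    treatment = file.path(dir, "treatment.bed"),
    control = file.path(dir, "control.bed"),
    expression = file.path(dir, "expression.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write_fasta(world$genome, files["genome"])
  write_gene_models(world$genes, files["genes"])
  sites <- world$truth$sites
  sites$name <- paste0("site_", seq_len(nrow(sites)))
  write_bed(sites[, c("chrom", "start", "end", "name", "strand")],
            files["truth"])
  write_bed(world$treatment, files["treatment"])
  write_bed(world$control, files["control"])
  write_expression(world$expression, files["expression"])
  cfg <- unclass(world$config)
  cfg$chrom_lengths <- as.list(cfg$chrom_lengths)
  yaml::write_yaml(cfg, files["config"])
  invisible(files)
}
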