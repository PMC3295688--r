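#' Annotation parameters
#'
#' @param promoter_bp Promoter width: bp upstream (5') of the TSS.
#' @param downstream_bp Downstream width: bp past the 3' transcript end.
#' @param gene_window_bp Window for peak-to-gene assignment.
#' @return An `annotation_config` list.
#' @export
annotation_config <- function(promoter_bp = 2000L, downstream_bp = 2000L,
                              gene_window_bp = 10000L) {
  if (promoter_bp <= 0 || downstream_bp <= 0 || gene_window_bp <= 0) {
    abort("annotation widths must be positive", class = "cistromer_bad_input")
  }
  structure(list(promoter_bp = as.integer(promoter_bp),
                 downstream_bp = as.integer(downstream_bp),
                 gene_window_bp = as.integer(gene_window_bp)),
            class = "annotation_config")
}

FEATURE_CLASSES <- c("promoter", "utr5", "exon", "intron", "utr3",
                     "downstream", "intergenic")

# Feature intervals for one gene, strand-aware, 0-based half-open.
# utr5 = exon parts 5' of the CDS, utr3 = exon parts 3' of it (swapped on
# the minus strand); "exon" is the CDS-overlapping exon remainder.
gene_feature_intervals <- function(gene, config) {
  es <- gene$exon_starts[[1]]
  ee <- gene$exon_ends[[1]]
  plus <- gene$strand == "+"
  left_utr <- clip_intervals(es, ee, gene$tx_start, gene$cds_start)
  right_utr <- clip_intervals(es, ee, gene$cds_end, gene$tx_end)
  cds_exon <- clip_intervals(es, ee, gene$cds_start, gene$cds_end)
  introns <- if (length(es) > 1) {
    tibble(start = ee[-length(ee)], end = es[-1])
  } else {
    tibble(start = integer(), end = integer())
  }
  promoter <- if (plus) {
    tibble(start = gene$tx_start - config$promoter_bp, end = gene$tx_start)
  } else {
    tibble(start = gene$tx_end, end = gene$tx_end + config$promoter_bp)
  }
  downstream <- if (plus) {
    tibble(start = gene$tx_end, end = gene$tx_end + config$downstream_bp)
  } else {
    tibble(start = gene$tx_start - config$downstream_bp,
           end = gene$tx_start)
  }
  feats <- bind_rows(
    mutate(promoter, class = "promoter"),
    mutate(if (plus) left_utr else right_utr, class = "utr5"),
    mutate(cds_exon, class = "exon"),
    mutate(introns, class = "intron"),
    mutate(if (plus) right_utr else left_utr, class = "utr3"),
    mutate(downstream, class = "downstream")
  )
  feats$chrom <- gene$chrom
  feats$gene_id <- gene$gene_id
  feats[feats$end > feats$start, , drop = FALSE]
}

clip_intervals <- function(starts, ends, lo, hi) {
  s <- pmax(starts, lo)
  e <- pmin(ends, hi)
  keep <- s < e
  tibble(start = s[keep], end = e[keep])
}

#' Classify peaks onto gene features by summit position
#'
#' Each peak is assigned exactly one feature class from its summit: when
#' the summit hits features of several genes, precedence is promoter >
#' 5'UTR > exon > intron > 3'UTR > downstream; anything else is
#' intergenic. Flanks are strand-aware (the promoter is 5' of the TSS, the
#' downstream window 3' of the transcript end).
#'
#' @param peaks Peak tibble with summits.
#' @param genes Gene-model tibble.
#' @param config An [annotation_config()].
#' @return The peak tibble with `feature_class` and `feature_gene` columns
#'   appended.
#' @export
classify_peaks <- function(peaks, genes, config = annotation_config()) {
  check_peaks(peaks)
  check_gene_models(genes)
  if (nrow(peaks) == 0) {
    return(mutate(peaks, feature_class = character(),
                  feature_gene = character()))
  }
  feats <- if (nrow(genes) == 0) {
    tibble(chrom = character(), start = integer(), end = integer(),
           class = character(), gene_id = character())
  } else {
    bind_rows(lapply(seq_len(nrow(genes)), function(i) {
      gene_feature_intervals(genes[i, ], config)
    }))
  }
  cls <- rep("intergenic", nrow(peaks))
  gid <- rep(NA_character_, nrow(peaks))
  if (nrow(feats) > 0) {
    prec <- match(feats$class, FEATURE_CLASSES)
    for (ch in unique(peaks$chrom)) {
      pi <- which(peaks$chrom == ch)
      fi <- which(feats$chrom == ch)
      if (length(fi) == 0) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(peaks$summit[pi] + 1L, width = 1L),
        IRanges::IRanges(feats$start[fi] + 1L, feats$end[fi])
      )
      if (length(hits) == 0) next
      h <- tibble(p = pi[S4Vectors::queryHits(hits)],
                  f = fi[S4Vectors::subjectHits(hits)])
      h$prec <- prec[h$f]
      best <- h |> group_by(.data$p) |>
        summarise(f = .data$f[which.min(.data$prec)], .groups = "drop")
      cls[best$p] <- feats$class[best$f]
      gid[best$p] <- feats$gene_id[best$f]
    }
  }
  mutate(peaks, feature_class = factor(cls, levels = FEATURE_CLASSES),
         feature_gene = gid)
}

#' Summarise a peak classification
#'
#' @param classified Output of [classify_peaks()].
#' @return An `annotation_summary` tibble: one row per feature class with
#'   `n` and `fraction` (fractions sum to 1).
#' @export
annotation_summary <- function(classified) {
  counts <- table(factor(classified$feature_class, levels = FEATURE_CLASSES))
  out <- tibble(feature_class = names(counts), n = as.integer(counts),
                fraction = as.integer(counts) / max(1L, nrow(classified)))
  structure(out, class = c("annotation_summary", class(out)),
            n_peaks = nrow(classified))
}

#' Signed distance from each peak summit to the nearest TSS
#'
#' Distance is `summit - TSS` with the sign flipped for minus-strand genes
#' so that negative always means upstream of the gene. The nearest TSS is
#' chosen by absolute distance among same-chromosome genes, ties to the
#' lower-coordinate gene; peaks on chromosomes without genes are flagged
#' missing (`NA`).
#'
#' @param peaks Peak tibble with summits.
#' @param genes Gene-model tibble (at least one row).
#' @return Tibble with `name`, `nearest_gene`, `tss_distance`.
#' @export
summit_to_tss_distances <- function(peaks, genes) {
  check_peaks(peaks)
  if (nrow(genes) == 0) {
    abort("at least one gene model required", class = "cistromer_bad_input")
  }
  check_gene_models(genes)
  tss <- gene_tss(genes)
  nm <- if ("name" %in% names(peaks)) peaks$name else
    paste0("peak_", seq_len(nrow(peaks)))
  res <- lapply(seq_len(nrow(peaks)), function(i) {
    j <- which(genes$chrom == peaks$chrom[i])
    if (length(j) == 0) {
      return(tibble(name = nm[i], nearest_gene = NA_character_,
                    tss_distance = NA_integer_))
    }
    raw <- peaks$summit[i] - tss[j]
    ord <- order(abs(raw), tss[j])
    k <- j[ord[1]]
    dist <- peaks$summit[i] - tss[match(k, seq_len(nrow(genes)))]
    if (genes$strand[k] == "-") dist <- -dist
    tibble(name = nm[i], nearest_gene = genes$gene_id[k],
           tss_distance = as.integer(dist))
  })
  bind_rows(res)
}

#' Randomly placed background peak sets
#'
#' Places peaks of the given length multiset uniformly on the genome:
#' chromosomes are chosen proportional to length (among chromosomes long
#' enough for the peak), starts uniform over valid placements, summit at
#' the interval midpoint. Each set preserves the input length multiset.
#' Placements may overlap each other and any real peaks.
#'
#' @param genome Genome.
#' @param sizes Integer vector: the peak length multiset to reproduce.
#' @param n_sets Number of independent random sets.
#' @param seed Integer seed.
#' @return Peak tibble with a `set` column (1..n_sets).
#' @export
random_background_peaks <- function(genome, sizes, n_sets = 1L, seed = 1L) {
  lens <- chrom_lengths_of(genome)
  sizes <- as.integer(sizes)
  if (any(sizes <= 0)) {
    abort("peak sizes must be positive", class = "cistromer_bad_input")
  }
  if (any(sizes > max(lens))) {
    abort("a peak size exceeds every chromosome",
          class = "cistromer_bad_input")
  }
  n <- length(sizes)
  with_seed(seed, {
    out <- lapply(seq_len(n_sets), function(s) {
      ch <- character(n)
      for (i in seq_len(n)) {
        valid <- names(lens)[lens >= sizes[i]]
        ch[i] <- if (length(valid) == 1) valid else
          sample(valid, 1, prob = lens[valid])
      }
      start <- as.integer(floor(runif(n) * (lens[ch] - sizes + 1)))
      tibble(set = s, chrom = ch, start = start,
             end = start + sizes,
             summit = start + sizes %/% 2L,
             name = paste0("rand_", s, "_", seq_len(n)))
    })
  })
  bind_rows(out)
}
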