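#' Assign peaks to nearby genes
#'
#' In `"window"` mode (the default) a gene is included when its transcript
#' interval extended by `window_bp` on both sides contains any part of a
#' peak. In `"nearest"` mode each peak is assigned only to its nearest
#' gene (by distance between the peak interval and the transcript, 0 when
#' overlapping; ties to the lower-coordinate gene), and that gene is
#' included when the distance is at most `window_bp`.
#'
#' @param peaks Peak or interval tibble.
#' @param genes Gene-model tibble.
#' @param window_bp Assignment window in bp (default 10 kb).
#' @param mode `"window"` or `"nearest"`.
#' @return Tibble with `gene_id` and `n_peaks` (peaks supporting the
#'   gene), one row per included gene, sorted by `gene_id`.
#' @export
peaks_to_genes <- function(peaks, genes, window_bp = 10000L,
                           mode = c("window", "nearest")) {
  mode <- match.arg(mode)
  if (window_bp < 0) {
    abort("window_bp must be >= 0", class = "cistromer_bad_input")
  }
  check_gene_models(genes)
  if (nrow(peaks) == 0 || nrow(genes) == 0) {
    return(tibble(gene_id = character(), n_peaks = integer()))
  }
  if (mode == "window") {
    ext <- tibble(chrom = genes$chrom,
                  start = pmax(genes$tx_start - window_bp, 0L),
                  end = genes$tx_end + window_bp)
    pairs <- overlap_pairs(ext, peaks, 0L)
    if (nrow(pairs) == 0) {
      return(tibble(gene_id = character(), n_peaks = integer()))
    }
    out <- tibble(gene_id = genes$gene_id[pairs$a]) |>
      group_by(.data$gene_id) |>
      summarise(n_peaks = n(), .groups = "drop")
  } else {
    assigned <- vapply(seq_len(nrow(peaks)), function(i) {
      j <- which(genes$chrom == peaks$chrom[i])
      if (length(j) == 0) return(NA_character_)
      gap <- pmax(genes$tx_start[j] - peaks$end[i],
                  peaks$start[i] - genes$tx_end[j], 0L)
      ord <- order(gap, genes$tx_start[j])
      if (gap[ord[1]] > window_bp) return(NA_character_)
      genes$gene_id[j[ord[1]]]
    }, character(1))
    assigned <- assigned[!is.na(assigned)]
    if (length(assigned) == 0) {
      return(tibble(gene_id = character(), n_peaks = integer()))
    }
    out <- tibble(gene_id = assigned) |>
      group_by(.data$gene_id) |>
      summarise(n_peaks = n(), .groups = "drop")
  }
  arrange(out, .data$gene_id)
}

#' Running-sum (KS) enrichment of a gene set in a ranked list
#'
#' Walks the expression list in rank order, stepping the running sum up by
#' `1/n_hits` at each gene in the hit set and down by
#' `1/(n_total - n_hits)` otherwise; the enrichment score `es` is the
#' deviation of maximum absolute value (sign retained, first occurrence on
#' ties). Significance is assessed by permutation of hit positions:
#' one-sided in the direction of the observed `es`, exhaustively over all
#' `choose(n_total, n_hits)` placements when that is small, otherwise by
#' Monte Carlo with the add-one rule. A two-sample asymptotic KS p-value
#' comparing hit against non-hit ranks is reported alongside.
#'
#' @param expression Expression tibble (`gene_id`, `fold_change`); gene
#'   ids must be unique.
#' @param hit_genes Character vector of gene ids (the ChIP-derived set),
#'   or a tibble with a `gene_id` column.
#' @param n_permutations Monte-Carlo permutation count.
#' @param seed Integer seed for the permutations.
#' @param rank_by Rank genes by descending `"fold_change"` or descending
#'   `"abs_fold_change"`.
#' @param exhaustive Force (`TRUE`) or forbid (`FALSE`) exhaustive
#'   enumeration; `NULL` (default) enumerates when
#'   `choose(n_total, n_hits) <= 5000`.
#' @return A `ks_result`: `n_total`, `n_hits`, `running` (tibble with
#'   `rank`, `gene_id`, `is_hit`, `es_curve`), `es`, `es_rank`, `p_perm`,
#'   `n_permutations`, `p_ks_asymp`, `exhaustive`.
#' @export
ks_running_enrichment <- function(expression, hit_genes,
                                  n_permutations = 999L, seed = 1L,
                                  rank_by = c("fold_change",
                                              "abs_fold_change"),
                                  exhaustive = NULL) {
  rank_by <- match.arg(rank_by)
  if (is.data.frame(hit_genes)) hit_genes <- hit_genes$gene_id
  if (anyDuplicated(expression$gene_id)) {
    abort("expression gene ids must be unique", class = "cistromer_bad_input")
  }
  key <- if (rank_by == "fold_change") expression$fold_change else
    abs(expression$fold_change)
  ord <- order(-key)
  ranked <- expression[ord, , drop = FALSE]
  is_hit <- ranked$gene_id %in% hit_genes
  n <- nrow(ranked)
  nh <- sum(is_hit)
  if (nh == 0 || nh == n) {
    abort("hit set must be a non-empty proper subset of the ranked list",
          class = "cistromer_bad_input")
  }
  curve <- ks_curve(which(is_hit), n)
  i_max <- which.max(abs(curve))
  es <- curve[i_max]

  do_exhaustive <- if (is.null(exhaustive)) choose(n, nh) <= 5000 else
    exhaustive
  if (do_exhaustive) {
    combos <- utils::combn(n, nh)
    es_all <- apply(combos, 2, function(pos) {
      cv <- ks_curve(pos, n)
      cv[which.max(abs(cv))]
    })
    p_perm <- if (es >= 0) mean(es_all >= es) else mean(es_all <= es)
    n_perm_used <- ncol(combos)
  } else {
    with_seed(seed, {
      es_all <- vapply(seq_len(n_permutations), function(b) {
        cv <- ks_curve(sample.int(n, nh), n)
        cv[which.max(abs(cv))]
      }, numeric(1))
    })
    hitcount <- if (es >= 0) sum(es_all >= es) else sum(es_all <= es)
    p_perm <- (1 + hitcount) / (n_permutations + 1)
    n_perm_used <- n_permutations
  }
  hit_ranks <- which(is_hit)
  p_asymp <- suppressWarnings(
    ks.test(hit_ranks, setdiff(seq_len(n), hit_ranks), exact = FALSE)$p.value
  )
  structure(list(
    n_total = n, n_hits = nh,
    running = tibble(rank = seq_len(n), gene_id = ranked$gene_id,
                     is_hit = is_hit, es_curve = curve),
    es = es, es_rank = i_max, p_perm = p_perm,
    n_permutations = as.integer(n_perm_used),
    p_ks_asymp = p_asymp, exhaustive = do_exhaustive,
    rank_by = rank_by
  ), class = "ks_result")
}

# Running-sum curve for hit positions within 1..n; length n, ends at 0.
ks_curve <- function(hit_pos, n) {
  nh <- length(hit_pos)
  step <- rep(-1 / (n - nh), n)
  step[hit_pos] <- 1 / nh
  cumsum(step)
}

#' Hypergeometric gene-list overlap test
#'
#' Upper-tail probability of observing at least the given overlap between
#' two gene sets drawn from a common universe:
#' `p = sum_{i >= overlap} C(K, i) C(N - K, n - i) / C(N, n)`.
#'
#' @param universe_size Size `N` of the gene universe (explicit, never
#'   inferred).
#' @param set1,set2 Character vectors of gene ids (subsets of the
#'   universe), or integer sizes together with `overlap`.
#' @param overlap Overlap count; required when sizes are given instead of
#'   id vectors.
#' @return A `geneset_overlap`: `universe_size`, `set1_size`, `set2_size`,
#'   `overlap`, `p_hyper`.
#' @export
hypergeometric_overlap <- function(universe_size, set1, set2,
                                   overlap = NULL) {
  if (is.character(set1) && is.character(set2)) {
    k1 <- length(unique(set1))
    k2 <- length(unique(set2))
    ov <- length(intersect(unique(set1), unique(set2)))
  } else {
    if (is.null(overlap)) {
      abort("overlap must be given with numeric set sizes",
            class = "cistromer_bad_input")
    }
    k1 <- set1
    k2 <- set2
    ov <- overlap
  }
  if (k1 > universe_size || k2 > universe_size) {
    abort("sets cannot exceed the universe", class = "cistromer_bad_input")
  }
  if (ov > min(k1, k2)) {
    abort("overlap exceeds a set size", class = "cistromer_bad_input")
  }
  p <- phyper(ov - 1, k1, universe_size - k1, k2, lower.tail = FALSE)
  structure(list(universe_size = universe_size, set1_size = k1,
                 set2_size = k2, overlap = ov, p_hyper = p),
            class = "geneset_overlap")
}
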