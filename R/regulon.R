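#' Predict transcription units (operons) from a gene table
#'
#' Two-rule distance/linkage heuristic: adjacent genes on the same contig and
#' strand are joined into one transcription unit when their intergenic
#' distance is at most `max_igd` nt, or when the distance is at most
#' `4 * max_igd` and the pair's functional-link score reaches
#' `link_threshold`. Overlapping genes count as distance 0. Gene order within
#' a unit is transcription order (leader first).
#'
#' @param gene_table data.frame with genome_id, gene_id, contig, start, end,
#'   strand (1-based inclusive; need not be sorted).
#' @param max_igd maximum intergenic distance (nt) for unconditional joining.
#' @param link_scores optional data.frame (gene1, gene2, score) of
#'   functional-link scores for adjacent pairs.
#' @param link_threshold minimum link score for distance-relaxed joining.
#' @return data.frame with one row per gene: tu_id, genome_id, contig,
#'   strand, gene_id, tu_order (1 = leader), n_genes.
#' @export
predict_operons <- function(gene_table, max_igd = 45L, link_scores = NULL,
                            link_threshold = 0.7) {
  gt <- gene_table[order(gene_table$contig, gene_table$start), , drop = FALSE]
  link_of <- function(a, b) {
    if (is.null(link_scores)) return(-Inf)
    hit <- link_scores$score[(link_scores$gene1 == a & link_scores$gene2 == b) |
                             (link_scores$gene1 == b & link_scores$gene2 == a)]
    if (length(hit)) max(hit) else -Inf
  }
  out <- vector("list", 0)
  tu_counter <- 0L
  for (contig in unique(gt$contig)) {
    sub <- gt[gt$contig == contig, , drop = FALSE]
    n <- nrow(sub)
    new_tu <- rep(TRUE, n)
    if (n > 1) {
      for (i in 2:n) {
        same <- sub$strand[i] == sub$strand[i - 1]
        d <- max(sub$start[i] - sub$end[i - 1] - 1L, 0L)   # overlap -> 0
        joined <- same && (d <= max_igd ||
                           (d <= 4 * max_igd &&
                            link_of(sub$gene_id[i - 1], sub$gene_id[i]) >= link_threshold))
        new_tu[i] <- !joined
      }
    }
    block <- cumsum(new_tu)
    for (b in unique(block)) {
      idx <- which(block == b)
      tu_counter <- tu_counter + 1L
      strand <- sub$strand[idx[1]]
      ord <- if (strand == "+") idx else rev(idx)   # leader = 3'-most on minus
      out[[length(out) + 1L]] <- data.frame(
        tu_id = sprintf("tu%05d", tu_counter),
        genome_id = sub$genome_id[idx[1]], contig = contig, strand = strand,
        gene_id = sub$gene_id[ord], tu_order = seq_along(idx),
        n_genes = length(idx), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Expand promoter hits to operon-level regulated gene sets
#'
#' A sigma-54 promoter drives the whole transcription unit, so every gene of
#' a hit unit is called regulated, not only the leader.
#'
#' @param hits hit table with a `tu_id` column ([scan_regions()] output).
#' @param tus transcription units ([predict_operons()] output).
#' @return character vector of regulated gene ids.
#' @export
expand_regulon <- function(hits, tus) {
  if (nrow(hits) == 0) return(character(0))
  orphan <- setdiff(hits$tu_id, tus$tu_id)
  if (length(orphan)) stopf("hit references unknown transcription unit: %s", orphan[1])
  unique(tus$gene_id[tus$tu_id %in% hits$tu_id])
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability that at least
#' `k` of `n` regulated genes fall in a COG of `K` members drawn from a pool
#' of `N`. Computed in log space via [stats::phyper()].
#'
#' @param N population gene count.
#' @param K genes annotated to the COG.
#' @param n regulated genes.
#' @param k regulated genes annotated to the COG.
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (!(is_count(N) && is_count(K) && is_count(n) && is_count(k)))
    stopf("N, K, n, k must be nonnegative integers")
  if (K > N || n > N) stopf("K and n must not exceed N")
  if (k > min(K, n)) stopf("k must not exceed min(K, n)")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Per-class hypergeometric COG enrichment of the sigma-54 regulon
#'
#' For every (class, COG) pair, tests whether regulated genes are enriched in
#' the COG: N = genes in the class (or the global pool), K = class genes in
#' the COG, n = regulated genes, k = regulated genes in the COG. Genes with
#' no COG label contribute to N but to no K; k counts genes
#' (operon-expanded), not operons. Benjamini-Hochberg adjustment is applied
#' within class.
#'
#' @param gene_table gene table with `gene_id`, `class`, `COG` columns.
#' @param regulated named list: class label -> character vector of regulated
#'   gene ids.
#' @param population `"within_class"` (default: N and K per class) or
#'   `"global"` (N and K from the pooled gene set).
#' @param keep_all keep pairs with k = 0 as well (useful for null
#'   calibration); default emits only K > 0 and k > 0 pairs.
#' @return data.frame sorted by ascending p: class, cog, N, K, n, k,
#'   p_value, p_bh, neg_log10_p.
#' @export
enrich_classes <- function(gene_table, regulated,
                           population = c("within_class", "global"),
                           keep_all = FALSE) {
  population <- match.arg(population)
  rows <- list()
  for (cl in unique(gene_table$class)) {
    sub <- gene_table[gene_table$class == cl, , drop = FALSE]
    reg <- intersect(regulated[[cl]], sub$gene_id)
    if (length(reg) == 0) next   # class without a regulon: skipped
    pool <- if (population == "global") gene_table else sub
    N <- nrow(pool)
    n <- length(reg)
    cog_counts <- table(pool$COG[!is.na(pool$COG)])
    reg_cogs <- sub$COG[sub$gene_id %in% reg & !is.na(sub$COG)]
    k_counts <- table(reg_cogs)
    for (cog in names(cog_counts)) {
      K <- as.integer(cog_counts[[cog]])
      k <- if (cog %in% names(k_counts)) as.integer(k_counts[[cog]]) else 0L
      if (!keep_all && k == 0) next
      p <- hypergeom_upper_tail(N, K, n, min(k, min(K, n)))
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, cog = cog, N = N, K = K, n = n, k = k, p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(class = character(0), cog = character(0), N = integer(0),
                      K = integer(0), n = integer(0), k = integer(0),
                      p_value = numeric(0), p_bh = numeric(0),
                      neg_log10_p = numeric(0)))
  res <- do.call(rbind, rows)
  res$p_bh <- NA_real_
  for (cl in unique(res$class)) {
    sel <- res$class == cl
    res$p_bh[sel] <- stats::p.adjust(res$p_value[sel], method = "BH")
  }
  res$neg_log10_p <- -log10(pmax(res$p_value, .Machine$double.xmin))
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  res
}
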