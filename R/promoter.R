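#' Extract upstream regions of transcription-unit leaders
#'
#' One region per transcription unit, ending immediately before the leader's
#' translation start and truncated at contig edges. Minus-strand regions are
#' reverse-complemented so every region reads 5'->3' relative to its leader;
#' scanning therefore never needs the reverse strand.
#'
#' @param gene_table data.frame with columns genome_id, gene_id, contig,
#'   start, end, strand (1-based inclusive coordinates).
#' @param genomes named character vector of contig sequences.
#' @param tus transcription units as returned by [predict_operons()] (one row
#'   per gene: tu_id, gene_id, tu_order, ...).
#' @param window_len upstream window length in nt.
#' @return data.frame of regions: region_id, tu_id, genome_id, contig,
#'   genomic_start, genomic_end, strand, sequence.
#' @export
extract_upstream <- function(gene_table, genomes, tus, window_len = 350L) {
  leaders <- tus[tus$tu_order == 1, , drop = FALSE]
  rows <- vector("list", nrow(leaders))
  for (i in seq_len(nrow(leaders))) {
    g <- gene_table[gene_table$gene_id == leaders$gene_id[i], , drop = FALSE]
    if (nrow(g) != 1) {
      warning(sprintf("leader gene %s not resolvable; skipped", leaders$gene_id[i]))
      next
    }
    contig_seq <- genomes[[g$contig]]
    if (is.null(contig_seq) || is.na(contig_seq)) {
      warning(sprintf("leader gene %s off-contig; skipped", g$gene_id))
      next
    }
    L <- nchar(contig_seq)
    if (g$strand == "+") {
      e <- g$start - 1L
      s <- max(1L, g$start - window_len)
      if (e < s) next
      seqstr <- substr(contig_seq, s, e)
    } else {
      s <- g$end + 1L
      e <- min(L, g$end + window_len)
      if (e < s) next
      seqstr <- revcomp(substr(contig_seq, s, e))
    }
    rows[[i]] <- data.frame(region_id = leaders$tu_id[i], tu_id = leaders$tu_id[i],
                            genome_id = g$genome_id, contig = g$contig,
                            genomic_start = s, genomic_end = e,
                            strand = g$strand, sequence = seqstr,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

#' Scan upstream regions with a PWM under an E-value threshold
#'
#' Scores every window of every region (strand-faithful: regions are already
#' oriented), keeps the best-scoring scorable window per region, converts
#' scores to exact p-values, and to E-values as p-value times the total
#' number of scorable windows in the scanned set (per-scan Bonferroni). Hits
#' with E-value <= `e_cutoff` are returned sorted by ascending E-value.
#'
#' @param pwm the scanning PWM.
#' @param regions region table from [extract_upstream()] (or any data.frame
#'   with region_id, tu_id, sequence).
#' @param e_cutoff E-value threshold.
#' @param granularity p-value grid (bins per bit).
#' @return data.frame of hits: region_id, tu_id, offset (1-based), site,
#'   score, p_value, e_value.
#' @export
scan_regions <- function(pwm, regions, e_cutoff = 5, granularity = 100L) {
  if (nrow(regions) == 0) stopf("scan_regions needs at least one region")
  lut <- encoder_for(pwm$alphabet)
  dist <- pwm_score_distribution(pwm, granularity)
  w <- pwm$width
  best <- vector("list", nrow(regions))
  total_windows <- 0
  for (i in seq_len(nrow(regions))) {
    s <- regions$sequence[i]
    if (nchar(s) < w) next     # region shorter than the motif: skipped
    codes <- encode_seq(s, lut)
    scores <- score_all_windows(pwm$log_odds, codes)
    total_windows <- total_windows + sum(!is.na(scores))
    if (all(is.na(scores))) next
    j <- which.max(scores)
    best[[i]] <- data.frame(region_id = regions$region_id[i],
                            tu_id = regions$tu_id[i],
                            offset = j, site = substr(s, j, j + w - 1L),
                            score = scores[j], stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, Filter(Negate(is.null), best))
  if (is.null(hits)) hits <- data.frame(region_id = character(0), tu_id = character(0),
                                        offset = integer(0), site = character(0),
                                        score = numeric(0))
  hits$p_value <- pvalue_lookup(dist, hits$score)
  hits$e_value <- hits$p_value * total_windows
  hits <- hits[!is.na(hits$e_value) & hits$e_value <= e_cutoff, , drop = FALSE]
  hits <- hits[order(hits$e_value), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "total_windows") <- total_windows
  hits
}

# Of several discovered motifs, keep the one whose consensus scores highest
# against the reference (seed) PWM -- guards the cycle against drifting to a
# co-occurring non-sigma-54 motif.
closest_to_seed <- function(motifs, seed_pwm) {
  if (length(motifs) == 1) return(motifs[[1]])
  sc <- vapply(motifs, function(m) {
    cons <- as.character(consensus(m))
    if (nchar(cons) != seed_pwm$width) return(-Inf)
    score_window(seed_pwm, cons, 1L)
  }, numeric(1))
  motifs[[which.max(sc)]]
}

#' Iterative pattern-finding / pattern-discovery cycles
#'
#' Cycle 1 scans the regions with the seed PWM; each later cycle re-estimates
#' the PWM by EM motif discovery on the previous cycle's hit windows and
#' rescans. Stops early (keeping the previous trace) when a cycle yields
#' fewer than `min_hits` hits.
#'
#' @param seed_pwm the seed matrix (cycle 1 scanner).
#' @param regions region table from [extract_upstream()].
#' @param n_cycles number of cycles (default 5).
#' @param e_cutoff E-value threshold for every scan.
#' @param min_hits minimum hits needed to re-estimate the PWM.
#' @param n_motifs motifs extracted per discovery step; the one closest to
#'   the seed is kept.
#' @param seed RNG seed forwarded to [discover_motif_em()].
#' @return list of cycle traces (cycle_index, pwm, hits, n_hits) with
#'   attribute `early_stop`.
#' @export
run_cycles <- function(seed_pwm, regions, n_cycles = 5L, e_cutoff = 5,
                       min_hits = 10L, n_motifs = 2L, seed = 1L) {
  if (n_cycles < 1) stopf("n_cycles must be >= 1")
  if (!identical(sort(seed_pwm$alphabet), sort(DNA_ALPHABET)))
    stopf("seed PWM must be over the DNA alphabet")
  traces <- list()
  pwm <- seed_pwm
  early <- FALSE
  for (cyc in seq_len(n_cycles)) {
    hits <- scan_regions(pwm, regions, e_cutoff = e_cutoff)
    traces[[cyc]] <- list(cycle_index = cyc, pwm = pwm, hits = hits,
                          n_hits = nrow(hits))
    if (nrow(hits) < min_hits) { early <- TRUE; break }
    if (cyc == n_cycles) break
    motifs <- discover_motif_em(hits$site, width = pwm$width,
                                n_motifs = n_motifs, seed = seed + cyc,
                                background = pwm$background)
    pwm <- closest_to_seed(motifs, seed_pwm)
  }
  structure(traces, early_stop = early, class = "cycle_trace")
}

#' Confusion matrix and Matthews correlation coefficient
#'
#' Compares a predicted gene set with a truth set over a universe.
#' MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)), defined as 0
#' when any denominator factor is 0.
#'
#' @param predicted,truth,universe character vectors of gene ids;
#'   `predicted` and `truth` must be subsets of `universe`.
#' @return list with `confusion` (tp, fp, fn, tn), `mcc`, `precision`,
#'   `sensitivity`, `specificity` (proportions in \[0, 1\]).
#' @export
confusion_and_mcc <- function(predicted, truth, universe) {
  predicted <- unique(predicted); truth <- unique(truth); universe <- unique(universe)
  if (!all(predicted %in% universe)) stopf("predicted set is not within the universe")
  if (!all(truth %in% universe)) stopf("truth set is not within the universe")
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  tn <- length(universe) - tp - fp - fn
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  list(confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
       mcc = mcc,
       precision = if (tp + fp == 0) 0 else tp / (tp + fp),
       sensitivity = if (tp + fn == 0) 0 else tp / (tp + fn),
       specificity = if (tn + fp == 0) 0 else tn / (tn + fp))
}

#' Calibrate the E-value cutoff by Matthews correlation
#'
#' Runs the full pattern-finding/pattern-discovery cycle at each candidate
#' cutoff, expands hits to operon-level gene sets, scores them against the
#' truth regulon at gene level, and selects the cutoff maximising MCC (ties
#' broken toward the smaller cutoff).
#'
#' @param seed_pwm seed matrix.
#' @param regions region table from [extract_upstream()].
#' @param tus transcription units ([predict_operons()] output).
#' @param truth character vector: true regulated genes.
#' @param universe character vector: all genes of the benchmark set.
#' @param cutoffs ascending E-value cutoffs to evaluate.
#' @param n_cycles cycles per cutoff (default 5).
#' @param seed RNG seed forwarded to [run_cycles()].
#' @param ... further arguments forwarded to [run_cycles()].
#' @return list with `per_cutoff` (data.frame: cutoff, n_hits, tp, fp, fn,
#'   tn, mcc, precision, sensitivity, specificity), `selected_cutoff`,
#'   `traces`, and `flag` (`"no_predictions"` when every cutoff was empty).
#' @export
calibrate_cutoff <- function(seed_pwm, regions, tus, truth, universe,
                             cutoffs = c(0.625, 1.25, 2.5, 5),
                             n_cycles = 5L, seed = 1L, ...) {
  stats_rows <- vector("list", length(cutoffs))
  traces <- vector("list", length(cutoffs))
  for (ci in seq_along(cutoffs)) {
    tr <- run_cycles(seed_pwm, regions, e_cutoff = cutoffs[ci],
                     n_cycles = n_cycles, seed = seed, ...)
    traces[[ci]] <- tr
    hits <- tr[[length(tr)]]$hits
    predicted <- expand_regulon(hits, tus)
    m <- confusion_and_mcc(predicted, truth, universe)
    stats_rows[[ci]] <- data.frame(cutoff = cutoffs[ci], n_hits = nrow(hits),
                                   tp = m$confusion["tp"], fp = m$confusion["fp"],
                                   fn = m$confusion["fn"], tn = m$confusion["tn"],
                                   mcc = m$mcc, precision = m$precision,
                                   sensitivity = m$sensitivity,
                                   specificity = m$specificity,
                                   stringsAsFactors = FALSE)
  }
  per_cutoff <- do.call(rbind, stats_rows)
  rownames(per_cutoff) <- NULL
  flag <- NULL
  if (all(per_cutoff$n_hits == 0)) {
    selected <- min(cutoffs)
    flag <- "no_predictions"
  } else {
    best <- which(per_cutoff$mcc == max(per_cutoff$mcc))
    selected <- min(per_cutoff$cutoff[best])   # tie-break: smaller cutoff
  }
  list(per_cutoff = per_cutoff, selected_cutoff = selected,
       traces = traces, flag = flag)
}
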