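# Pfam accessions of the three RpoN functional domains.
RPON_DOMAINS <- c(AID = "PF00309", DBD = "PF04552", CBD = "PF04963")

#' Default per-domain E-value thresholds for RpoN domain calls
#'
#' AID (PF00309) 1.6e-14, DBD (PF04552) 2.8e-50, CBD (PF04963) 2.3e-70 —
#' calibrated on bona fide RpoN sequences.
#' @export
rpon_domain_thresholds <- function() {
  c(PF00309 = 1.6e-14, PF04552 = 2.8e-50, PF04963 = 2.3e-70)
}

architecture_label <- function(domains_present) {
  d <- sort(domains_present)
  if (setequal(d, c("AID", "CBD", "DBD"))) "AID-DBD-CBD"
  else if (setequal(d, c("AID", "CBD"))) "AID-CBD"
  else if (setequal(d, c("AID", "DBD"))) "AID-DBD"
  else if (setequal(d, c("CBD", "DBD"))) "CBD-DBD"
  else if (length(d) == 0) "none"
  else "partial-other"
}

#' Classify RpoN proteins by functional-domain architecture
#'
#' A domain (AID = PF00309, DBD = PF04552, CBD = PF04963) is present when the
#' protein has at least one hit at or below that domain's E-value threshold.
#' The architecture label follows the present subset; unknown domain ids in
#' the table are ignored.
#'
#' @param hits domain-hit table ([read_domtbl()] output), possibly covering
#'   many proteins.
#' @param thresholds named E-value thresholds per Pfam accession (default
#'   [rpon_domain_thresholds()]).
#' @return data.frame: protein_id, AID, DBD, CBD (logical), architecture.
#' @export
classify_rpon <- function(hits, thresholds = rpon_domain_thresholds()) {
  if (!all(RPON_DOMAINS %in% names(thresholds)))
    stopf("thresholds must cover PF00309, PF04552 and PF04963")
  ids <- unique(hits$protein_id)
  res <- data.frame(protein_id = ids, AID = FALSE, DBD = FALSE, CBD = FALSE,
                    architecture = "none", stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    sub <- hits[hits$protein_id == ids[i], , drop = FALSE]
    present <- character(0)
    for (dom in names(RPON_DOMAINS)) {
      acc <- RPON_DOMAINS[[dom]]
      if (any(sub$domain_id == acc & sub$e_value <= thresholds[[acc]]))
        present <- c(present, dom)
    }
    res$AID[i] <- "AID" %in% present
    res$DBD[i] <- "DBD" %in% present
    res$CBD[i] <- "CBD" %in% present
    res$architecture[i] <- architecture_label(present)
  }
  res
}

#' RpoN census over an organism roster
#'
#' Per-class and global statistics of RpoN carriage: percentage of organisms
#' with at least one RpoN call, the copy-number histogram, the fraction of
#' multi-copy organisms (reported against both the full roster and the
#' RpoN-positive subset), and the domain-architecture histogram. Percentages
#' are rounded to one decimal.
#'
#' @param calls data.frame with `protein_id`, `genome_id` and optionally
#'   `architecture` (one row per RpoN protein call).
#' @param roster data.frame with `genome_id` and `class_label` (one row per
#'   organism studied).
#' @return list: `per_class` data.frame (class_label, n_organisms,
#'   n_with_rpon, pct_with_rpon), `global` list (n_organisms, n_with_rpon,
#'   pct_with_rpon, copy_histogram, multi_copy_pct_all,
#'   multi_copy_pct_positive, architecture_histogram).
#' @export
rpon_census <- function(calls, roster) {
  if (anyDuplicated(roster$genome_id)) stopf("roster genome ids must be unique")
  if (nrow(calls) && !all(calls$genome_id %in% roster$genome_id))
    stopf("call references genome absent from the roster: %s",
          setdiff(calls$genome_id, roster$genome_id)[1])
  copies <- table(factor(calls$genome_id, levels = roster$genome_id))
  copy_hist <- table(as.integer(copies))
  n_org <- nrow(roster)
  n_pos <- sum(copies >= 1)
  n_multi <- sum(copies > 1)
  per_class <- do.call(rbind, lapply(split(roster, roster$class_label), function(r) {
    pos <- sum(copies[r$genome_id] >= 1)
    data.frame(class_label = r$class_label[1], n_organisms = nrow(r),
               n_with_rpon = pos,
               pct_with_rpon = round(100 * pos / nrow(r), 1),
               stringsAsFactors = FALSE)
  }))
  rownames(per_class) <- NULL
  arch_hist <- if ("architecture" %in% names(calls) && nrow(calls))
    table(calls$architecture) else table(character(0))
  list(per_class = per_class,
       global = list(
         n_organisms = n_org, n_with_rpon = n_pos,
         pct_with_rpon = round(100 * n_pos / n_org, 1),
         copy_histogram = copy_hist,
         multi_copy_pct_all = round(100 * n_multi / n_org, 1),
         multi_copy_pct_positive = if (n_pos > 0) round(100 * n_multi / n_pos, 1) else NA_real_,
         architecture_histogram = arch_hist))
}
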