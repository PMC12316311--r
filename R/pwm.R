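#' Build a position weight matrix from aligned sites
#'
#' Tallies per-column letter counts from equal-length sites, smooths with a
#' pseudocount, and derives per-column probabilities and log2-odds against the
#' background stationary distribution. Works identically for DNA and protein
#' alphabets.
#'
#' @param sites character vector of equal-length sequences.
#' @param pseudocount nonnegative scalar added to each count, or a named
#'   per-letter vector (e.g. `0.01 * background` for proteins).
#' @param background a [background_model()]; its stationary distribution sets
#'   the log-odds denominator. Defaults to uniform over the detected alphabet.
#' @param alphabet letter set; guessed from the sites when `NULL`.
#' @return an object of class `pwm` with fields `alphabet`, `width`, `counts`,
#'   `probs`, `log_odds` (letters x columns matrices), `background`,
#'   `pseudocount`, `nsites`.
#' @examples
#' build_pwm(c("TGGCA", "TGGCA"), pseudocount = 0)
#' @export
build_pwm <- function(sites, pseudocount = NULL, background = NULL, alphabet = NULL) {
  if (length(sites) < 1) stopf("build_pwm needs at least one site")
  lens <- nchar(sites)
  if (length(unique(lens)) != 1)
    stopf("all sites must have equal length (saw lengths %s)",
          paste(sort(unique(lens)), collapse = ", "))
  w <- lens[1]
  if (w < 1) stopf("PWM width must be >= 1")
  if (is.null(alphabet)) alphabet <- guess_alphabet(sites)
  a <- length(alphabet)
  lut <- encoder_for(alphabet)
  codes <- vapply(sites, encode_seq, integer(w), lut = lut)
  codes <- matrix(codes, nrow = w)            # w x n
  if (anyNA(codes)) {
    bad <- which(colSums(is.na(codes)) > 0)[1]
    stopf("site %d ('%s') contains letters outside the alphabet", bad, sites[bad])
  }
  counts <- vapply(seq_len(w), function(col) tabulate(codes[col, ], nbins = a),
                   integer(a))                # a x w
  dimnames(counts) <- list(alphabet, NULL)
  if (is.null(background))
    background <- background_model(stationary = stats::setNames(rep(1 / a, a), alphabet))
  if (!identical(names(background$stationary), alphabet))
    background$stationary <- background$stationary[alphabet]
  if (is.null(pseudocount))
    pseudocount <- if (a == 4) 0.25 else 0.01 * background$stationary
  pc <- if (length(pseudocount) == 1) rep(pseudocount, a) else pseudocount[alphabet]
  if (any(pc < 0)) stopf("pseudocount must be nonnegative")
  n <- length(sites)
  probs <- (counts + pc) / (n + sum(pc))
  log_odds <- log2(probs / background$stationary)
  structure(list(alphabet = alphabet, width = w, counts = counts, probs = probs,
                 log_odds = log_odds, background = background,
                 pseudocount = pc, nsites = n),
            class = "pwm")
}

#' Construct a PWM directly from a probability matrix
#' @param probs letters x columns matrix of probabilities (rows named by
#'   letter, each column summing to 1).
#' @inheritParams build_pwm
#' @export
pwm_from_probs <- function(probs, background = NULL) {
  alphabet <- rownames(probs)
  if (is.null(alphabet)) stopf("probability matrix must have letter rownames")
  if (any(abs(colSums(probs) - 1) > 1e-9)) stopf("each column must sum to 1")
  a <- length(alphabet)
  if (is.null(background))
    background <- background_model(stationary = stats::setNames(rep(1 / a, a), alphabet))
  structure(list(alphabet = alphabet, width = ncol(probs),
                 counts = probs * NA, probs = probs,
                 log_odds = log2(probs / background$stationary),
                 background = background, pseudocount = rep(0, a), nsites = NA),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cons <- consensus(x)
  cat(sprintf("PWM: width %d, |alphabet| %d, consensus %s\n",
              x$width, length(x$alphabet), cons))
  invisible(x)
}

#' Consensus string of a PWM
#'
#' Per-column argmax letter; ties are broken by alphabet order and flagged in
#' the `"tied"` attribute of the returned string.
#' @param pwm a [build_pwm()] object.
#' @return consensus string with a logical attribute `tied` (one flag per
#'   column).
#' @export
consensus <- function(pwm) {
  idx <- apply(pwm$probs, 2, which.max)
  mx <- pwm$probs[cbind(idx, seq_len(pwm$width))]
  tied <- vapply(seq_len(pwm$width),
                 function(j) sum(abs(pwm$probs[, j] - mx[j]) < 1e-12) > 1, logical(1))
  structure(paste(pwm$alphabet[idx], collapse = ""), tied = tied)
}

#' Information content per column (bits)
#' @param pwm a PWM.
#' @return data.frame with one row per column: per-letter probabilities and
#'   the column information content relative to the background.
#' @export
pwm_ic_table <- function(pwm) {
  p <- pwm$probs
  b <- pwm$background$stationary
  ic <- colSums(ifelse(p > 0, p * log2(p / b), 0))
  out <- data.frame(position = seq_len(pwm$width), t(p), ic = ic)
  names(out)[2:(1 + length(pwm$alphabet))] <- pwm$alphabet
  rownames(out) <- NULL
  out
}

#' Log-odds score of one window (bits)
#'
#' Sum of per-column log2-odds of the window starting at `offset` (1-based).
#' Windows containing letters outside the alphabet score `NA` (non-scorable).
#' @param pwm a PWM.
#' @param sequence a sequence string.
#' @param offset 1-based window start.
#' @export
score_window <- function(pwm, sequence, offset = 1L) {
  if (offset < 1 || offset + pwm$width - 1 > nchar(sequence))
    stopf("window [%d, %d] outside sequence of length %d",
          offset, offset + pwm$width - 1, nchar(sequence))
  lut <- encoder_for(pwm$alphabet)
  codes <- encode_seq(substr(sequence, offset, offset + pwm$width - 1), lut)
  if (anyNA(codes)) return(NA_real_)
  sum(pwm$log_odds[cbind(codes, seq_len(pwm$width))])
}

# Scores of every window of one encoded sequence; NA where non-scorable.
score_all_windows <- function(log_odds, codes) {
  w <- ncol(log_odds)
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  scores <- numeric(n)
  na_mask <- rep(FALSE, n)
  for (col in seq_len(w)) {
    v <- log_odds[, col][codes[col:(col + n - 1L)]]
    na_mask <- na_mask | is.na(v)
    v[is.na(v)] <- 0
    scores <- scores + v
  }
  scores[na_mask] <- NA_real_
  scores
}

#' Exact score distribution of a PWM under the background
#'
#' Dynamic-programming convolution of the per-column log-odds distributions
#' under the order-0 stationary background, on a score grid of `granularity`
#' bins per bit. Returns the tail function used for p-values.
#' @param pwm a PWM.
#' @param granularity bins per bit (>= 100).
#' @return list with `breaks` (bin scores), `tail` (P(score >= bin)), and the
#'   probability mass on non-finite scores.
#' @keywords internal
pwm_score_distribution <- function(pwm, granularity = 100L) {
  if (granularity < 100) stopf("granularity must be >= 100")
  lo <- pwm$log_odds
  bg <- pwm$background$stationary
  finite <- is.finite(lo)
  bins <- round(lo * granularity)
  # offset so bins are nonnegative indices
  min_col <- apply(ifelse(finite, bins, Inf), 2, min)
  max_col <- apply(ifelse(finite, bins, -Inf), 2, max)
  total_min <- sum(min_col)
  total_range <- sum(max_col - min_col)
  dist <- numeric(total_range + 1); dist[1] <- 1
  p_neg_inf <- 0
  cur_len <- 1L
  for (col in seq_len(pwm$width)) {
    probs_col <- numeric(max_col[col] - min_col[col] + 1)
    p_inf_col <- 0
    for (l in seq_along(pwm$alphabet)) {
      if (finite[l, col]) {
        k <- bins[l, col] - min_col[col] + 1
        probs_col[k] <- probs_col[k] + bg[l]
      } else p_inf_col <- p_inf_col + bg[l]
    }
    p_neg_inf <- p_neg_inf + (1 - p_neg_inf) * p_inf_col
    new_len <- cur_len + length(probs_col) - 1L
    acc <- numeric(new_len)
    for (k in seq_along(probs_col)) {
      if (probs_col[k] > 0)
        acc[k:(k + cur_len - 1L)] <- acc[k:(k + cur_len - 1L)] + probs_col[k] * dist[1:cur_len]
    }
    dist[1:new_len] <- acc
    cur_len <- new_len
  }
  dist <- dist[1:cur_len] / max(sum(dist[1:cur_len]) + p_neg_inf, .Machine$double.eps)
  tail <- rev(cumsum(rev(dist)))
  list(granularity = granularity, min_bin = total_min,
       tail = tail, p_neg_inf = p_neg_inf)
}

# Vectorised p-value lookup against a pwm_score_distribution. Used for scores
# of real windows, which are achievable by construction: scores that round
# past the top of the grid (per-column rounding drift) clamp to the smallest
# positive tail rather than 0.
pvalue_lookup <- function(dist, scores) {
  out <- rep(NA_real_, length(scores))
  fin <- is.finite(scores)
  n <- length(dist$tail)
  b <- pmin(pmax(round(scores[fin] * dist$granularity) - dist$min_bin + 1L, 1L), n)
  out[fin] <- dist$tail[b]
  out[!fin & !is.na(scores)] <- 1   # -Inf: every window scores at least -Inf
  out
}

#' Exact p-value of a PWM score
#'
#' P(a random background window scores >= `score`), computed by
#' dynamic-programming convolution of discretised per-column score
#' distributions under the order-0 stationary background. Exact up to the
#' score grid (`granularity` bins per bit).
#' @param pwm a PWM.
#' @param score score in bits.
#' @param granularity bins per bit (>= 100).
#' @export
score_pvalue <- function(pwm, score, granularity = 100L) {
  dist <- pwm_score_distribution(pwm, granularity)
  if (!is.finite(score)) {
    if (score == -Inf) return(1)
    return(0)
  }
  max_fin <- dist$min_bin + length(dist$tail) - 1L
  b <- round(score * granularity) - dist$min_bin + 1L
  if (b <= 1L) return(1)                   # at or below the minimum achievable
  if (b > length(dist$tail)) return(0)     # above the maximum achievable
  dist$tail[b]
}
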