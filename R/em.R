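# ZOOPS (zero-or-one occurrence per sequence) expectation-maximisation motif
# discovery. The E-step computes per-window occupancy posteriors from the
# current PWM, background and occurrence prior lambda; the M-step re-estimates
# the PWM (with pseudocount) and lambda. Starts are derived from
# over-represented anchor words aligned at every in-window offset, screened by
# one-iteration likelihood; full EM runs from the best screened starts and the
# best run by log likelihood is kept. Additional motifs are found after
# MEME-style probabilistic erasure of earlier occurrences.
#
# Internally all sequences are concatenated (padded with NA codes) so that
# every E/M step is a handful of vectorised operations over one long array.

em_pack <- function(sequences, width, lut) {
  n_seq <- length(sequences)
  lens <- nchar(sequences)
  pad <- width                       # NA padding keeps windows within one sequence
  starts <- cumsum(c(1L, lens[-n_seq] + pad))
  total <- starts[n_seq] + lens[n_seq] - 1L
  codes <- rep(NA_integer_, total)
  for (i in seq_len(n_seq))
    codes[starts[i]:(starts[i] + lens[i] - 1L)] <- encode_seq(sequences[i], lut)
  m <- pmax(lens - width + 1L, 0L)
  win_start <- unlist(lapply(seq_len(n_seq), function(i)
    if (m[i] > 0) starts[i] + 0:(m[i] - 1L) else integer(0)), use.names = FALSE)
  win_seq <- rep(seq_len(n_seq), m)
  list(codes = codes, n_seq = n_seq, m = m, win_start = win_start,
       win_seq = win_seq, seq_starts = starts, lens = lens)
}

# scores of every window (concatenated); NA where non-scorable
em_scores <- function(pack, log_odds) {
  w <- ncol(log_odds)
  sc <- numeric(length(pack$win_start))
  na_mask <- rep(FALSE, length(sc))
  for (col in seq_len(w)) {
    v <- log_odds[, col][pack$codes[pack$win_start + col - 1L]]
    na_mask <- na_mask | is.na(v)
    v[is.na(v)] <- 0
    sc <- sc + v
  }
  sc[na_mask] <- NA_real_
  sc
}

em_step <- function(pack, probs, bg, lambda, pc, erase, width) {
  log_odds <- log2(pmax(probs, 1e-300) / bg)
  r <- 2^em_scores(pack, log_odds)
  r[is.na(r)] <- 0
  if (!is.null(erase)) r <- r * erase
  m_of <- pack$m[pack$win_seq]
  prior <- lambda / m_of
  sum_r <- rowsum(prior * r, pack$win_seq, reorder = TRUE)[, 1]
  seq_with_windows <- sort(unique(pack$win_seq))
  denom_all <- rep(1 - lambda, pack$n_seq)
  denom_all[seq_with_windows] <- denom_all[seq_with_windows] + sum_r
  ll <- sum(log(denom_all))
  z <- (prior * r) / denom_all[pack$win_seq]
  counts <- matrix(0, nrow(probs), width, dimnames = dimnames(probs))
  pos <- which(z > 0)
  for (col in seq_len(width)) {
    v <- pack$codes[pack$win_start[pos] + col - 1L]
    ok <- !is.na(v)
    if (any(ok)) {
      tal <- rowsum(z[pos][ok], v[ok])
      idx <- as.integer(rownames(tal))
      counts[idx, col] <- counts[idx, col] + tal[, 1]
    }
  }
  new_probs <- sweep(counts + pc, 2, colSums(counts) + sum(pc), "/")
  list(ll = ll, z = z, probs = new_probs,
       lambda = min(max(sum(z) / pack$n_seq, 1e-6), 1 - 1e-6))
}

em_run <- function(pack, start_probs, bg, pc, erase, width, max_iter, tol) {
  probs <- start_probs
  lambda <- 0.5
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  st <- NULL
  for (iter in seq_len(max_iter)) {
    st <- em_step(pack, probs, bg, lambda, pc, erase, width)
    ll_trace <- c(ll_trace, st$ll)
    probs <- st$probs
    lambda <- st$lambda
    if (is.finite(ll_old) && abs(st$ll - ll_old) <= tol * max(1, abs(ll_old))) {
      converged <- TRUE
      break
    }
    ll_old <- st$ll
  }
  list(probs = probs, lambda = lambda, ll = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, converged = converged, z = st$z)
}

# Candidate starts: top anchor words, aligned at every admissible in-window
# offset; each candidate PWM is built from the windows carrying the word at
# that offset.
em_candidate_starts <- function(sequences, pack, width, n_words, alphabet,
                                background, erase, k = NULL) {
  if (is.null(k)) k <- if (length(alphabet) == 4) min(6L, width) else min(4L, width)
  word_list <- lapply(seq_along(sequences), function(i) {
    L <- pack$lens[i]
    if (L < k) return(character(0))
    substring(sequences[i], 1:(L - k + 1L), k:L)
  })
  all_words <- unlist(word_list, use.names = FALSE)
  wt <- if (is.null(erase)) rep(1, length(all_words)) else {
    # weight each word occurrence by the erase weight of windows touching it;
    # approximate with the weight of the window starting at the word when valid
    unlist(lapply(seq_along(sequences), function(i) {
      L <- pack$lens[i]
      if (L < k) return(numeric(0))
      n_sub <- L - k + 1L
      w_i <- rep(1, n_sub)
      if (pack$m[i] > 0) {
        ei <- erase[pack$win_seq == i]
        w_i[seq_len(min(n_sub, length(ei)))] <- ei[seq_len(min(n_sub, length(ei)))]
      }
      w_i
    }), use.names = FALSE)
  }
  keep <- !grepl("[^A-Z]", all_words)
  tab <- sort(tapply(wt[keep], all_words[keep], sum), decreasing = TRUE)
  words <- names(tab)[seq_len(min(n_words, length(tab)))]
  starts <- list()
  for (word in words) {
    occ_by_seq <- lapply(sequences, function(s) {
      p <- gregexpr(word, s, fixed = TRUE)[[1]]
      p[p > 0]
    })
    for (anchor in seq_len(width - k + 1L)) {
      wins <- character(0)
      for (i in seq_along(sequences)) {
        for (p in occ_by_seq[[i]]) {
          s0 <- p - anchor + 1L
          if (s0 >= 1L && s0 + width - 1L <= pack$lens[i])
            wins <- c(wins, substr(sequences[i], s0, s0 + width - 1L))
        }
      }
      wins <- wins[!grepl("[^A-Z]", wins)]
      if (length(wins) == 0) next
      starts[[length(starts) + 1L]] <-
        build_pwm(wins, background = background, alphabet = alphabet)$probs
    }
  }
  starts
}

#' EM motif discovery (ZOOPS model)
#'
#' Discovers up to `n_motifs` ungapped motifs of fixed `width` in a sequence
#' set under the zero-or-one-occurrence-per-sequence model. Candidate starts
#' are over-represented anchor words aligned at every in-window offset,
#' screened by one-iteration likelihood; EM runs to convergence from the best
#' screened starts and the best run by log likelihood is kept. Occurrences
#' are then probabilistically erased and the next motif sought. A motif whose
#' likelihood gain over the motif-free model fails a BIC-style significance
#' bound is reported with occurrence prior 0 and `significant = FALSE`.
#'
#' @param sequences character vector (>= 2 sequences, each at least `width`
#'   long).
#' @param width motif width in letters.
#' @param n_motifs maximum number of motifs.
#' @param n_starts anchor words screened per motif (full EM runs from the
#'   best few screened starts).
#' @param seed integer RNG seed (tie-breaks only; the algorithm is otherwise
#'   deterministic).
#' @param background a [background_model()]; estimated from the data when
#'   `NULL`.
#' @param pseudocount per-letter smoothing (defaults as in [build_pwm()]).
#' @param max_iter,tol EM stopping rule: relative log-likelihood change below
#'   `tol` or `max_iter` iterations (non-convergence is flagged, the best
#'   iterate returned).
#' @return list of `pwm` objects ranked by log-likelihood ratio, each with
#'   attributes `lambda` (occurrence prior), `llr`, `ll_trace`, `converged`,
#'   `significant`.
#' @export
discover_motif_em <- function(sequences, width, n_motifs = 1L, n_starts = 10L,
                              seed = 1L, background = NULL, pseudocount = NULL,
                              max_iter = 200L, tol = 1e-6) {
  if (length(sequences) < 2) stopf("motif discovery needs at least 2 sequences")
  if (any(nchar(sequences) < width))
    stopf("every sequence must be at least as long as the motif width (%d)", width)
  alphabet <- guess_alphabet(sequences)
  a <- length(alphabet)
  if (is.null(background)) background <- estimate_background(sequences, alphabet)
  bg <- background$stationary[alphabet]
  if (is.null(pseudocount))
    pseudocount <- if (a == 4) 0.25 else 0.01 * bg
  pc <- if (length(pseudocount) == 1) rep(pseudocount, a) else pseudocount
  lut <- encoder_for(alphabet)
  pack <- em_pack(sequences, width, lut)
  total_windows <- sum(pack$m)
  bic_penalty <- ((a - 1) * width + 1) / 2 * log(max(total_windows, 2))
  erase <- rep(1, length(pack$win_start))
  motifs <- list()
  with_seed(seed, {
    for (mi in seq_len(n_motifs)) {
      cand <- em_candidate_starts(sequences, pack, width, n_starts, alphabet,
                                  background, if (mi > 1) erase else NULL)
      if (length(cand) == 0) break
      # one-iteration screen
      screen_ll <- vapply(cand, function(pr)
        em_step(pack, pr, bg, 0.5, pc, if (mi > 1) erase else NULL, width)$ll,
        numeric(1))
      top <- order(screen_ll, decreasing = TRUE)[seq_len(min(3L, length(cand)))]
      best <- NULL
      for (ci in top) {
        fit <- em_run(pack, cand[[ci]], bg, pc, if (mi > 1) erase else NULL,
                      width, max_iter, tol)
        if (is.null(best) || fit$ll > best$ll) best <- fit
      }
      significant <- best$ll >= bic_penalty   # gain over the lambda = 0 model
      pwm <- pwm_from_probs(best$probs, background = background)
      pwm$nsites <- round(best$lambda * length(sequences))
      attr(pwm, "lambda") <- if (significant) best$lambda else 0
      attr(pwm, "llr") <- best$ll
      attr(pwm, "ll_trace") <- best$ll_trace
      attr(pwm, "converged") <- best$converged
      attr(pwm, "significant") <- significant
      motifs[[length(motifs) + 1L]] <- pwm
      if (mi < n_motifs) {
        # MEME-style erasure: positions covered by occurrences are discounted
        u <- rep(1, length(pack$codes))
        nz <- which(best$z > 1e-6)
        for (j in nz) {
          span <- pack$win_start[j]:(pack$win_start[j] + width - 1L)
          u[span] <- u[span] * (1 - best$z[j])
        }
        lu <- log(pmax(u, 1e-300))
        cs <- c(0, cumsum(lu))
        wlog <- cs[pack$win_start + width] - cs[pack$win_start]
        erase <- erase * exp(wlog)
      }
    }
  })
  ord <- order(vapply(motifs, function(p) attr(p, "llr"), numeric(1)),
               decreasing = TRUE)
  motifs[ord]
}
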