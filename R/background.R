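#' Background sequence models
#'
#' A background model is either an order-0 letter distribution or an order-1
#' Markov chain (stationary distribution plus a letter-by-letter transition
#' table). Scanning and motif discovery use the stationary distribution for
#' log-odds and exact score p-values; order-1 models are available for
#' background sequence emission (the generator's `markov_order` switch).
#'
#' @param order Markov order, 0 or 1.
#' @param stationary named letter distribution (must sum to 1).
#' @param transitions square letter-by-letter matrix of conditional
#'   probabilities; rows must sum to 1. Required when `order = 1`.
#' @return an object of class `background_model`.
#' @examples
#' background_model(stationary = c(A = .3, C = .2, G = .2, T = .3))
#' @export
background_model <- function(order = 0L,
                             stationary = stats::setNames(rep(0.25, 4), c("A", "C", "G", "T")),
                             transitions = NULL) {
  if (!order %in% c(0L, 1L)) stopf("background order must be 0 or 1")
  if (is.null(names(stationary))) stopf("stationary distribution must be named")
  if (abs(sum(stationary) - 1) > 1e-9) stopf("stationary distribution must sum to 1")
  if (any(stationary < 0)) stopf("stationary probabilities must be nonnegative")
  if (order == 1L) {
    if (is.null(transitions)) stopf("order-1 background requires a transition table")
    if (!all(abs(rowSums(transitions) - 1) < 1e-9))
      stopf("transition rows must sum to 1")
  }
  structure(list(order = as.integer(order), stationary = stationary,
                 transitions = transitions),
            class = "background_model")
}

#' GC-parameterised DNA background
#'
#' Convenience constructor: an order-0 or order-1 DNA background with
#' stationary GC content `gc`. The order-1 chain mixes the stationary
#' distribution with a self-transition excess `rho` (mild local
#' autocorrelation), keeping the stationary distribution at `gc`.
#'
#' @param gc stationary GC fraction in \[0, 1\].
#' @param order Markov order, 0 or 1.
#' @param rho order-1 self-transition excess in \[0, 1).
#' @export
dna_background <- function(gc = 0.5, order = 0L, rho = 0.1) {
  if (gc < 0 || gc > 1) stopf("gc must lie in [0, 1]")
  stat <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  trans <- NULL
  if (order == 1L) {
    trans <- matrix(rep(stat, each = 4), 4, 4, dimnames = list(names(stat), names(stat)))
    trans <- (1 - rho) * trans + rho * diag(4)
    dimnames(trans) <- list(names(stat), names(stat))
  }
  background_model(order = order, stationary = stat, transitions = trans)
}

#' Uniform protein background over the 20 standard residues (or the packaged
#' average bacterial composition).
#' @param composition `"average"` (default) or `"uniform"`.
#' @export
protein_background <- function(composition = c("average", "uniform")) {
  composition <- match.arg(composition)
  stat <- if (composition == "average") AA_BACKGROUND
          else stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  background_model(order = 0L, stationary = stat)
}

#' Sample a background sequence
#'
#' @param n sequence length (letters).
#' @param background a [background_model()].
#' @param rng_seed optional integer seed (local to this call).
#' @return a single character string.
#' @export
sample_background <- function(n, background = dna_background(), rng_seed = NULL) {
  with_seed(rng_seed, {
    letters <- names(background$stationary)
    if (background$order == 0L || n == 1L) {
      paste(sample(letters, n, replace = TRUE, prob = background$stationary),
            collapse = "")
    } else {
      out <- integer(n)
      out[1] <- sample.int(length(letters), 1, prob = background$stationary)
      tr <- background$transitions
      for (i in 2:n) out[i] <- sample.int(length(letters), 1, prob = tr[out[i - 1], ])
      paste(letters[out], collapse = "")
    }
  })
}

#' Estimate an order-0 background from sequences
#' @param seqs character vector of sequences.
#' @param alphabet letter set (defaults to a DNA/protein guess).
#' @export
estimate_background <- function(seqs, alphabet = NULL) {
  if (is.null(alphabet)) alphabet <- guess_alphabet(seqs)
  lut <- encoder_for(alphabet)
  codes <- unlist(lapply(seqs, encode_seq, lut = lut), use.names = FALSE)
  tab <- tabulate(codes[!is.na(codes)], nbins = length(alphabet))
  background_model(stationary = stats::setNames((tab + 1) / sum(tab + 1), alphabet))
}
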