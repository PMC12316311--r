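#' @keywords internal
"_PACKAGE"

DNA_ALPHABET <- c("A", "C", "G", "T")
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Average amino-acid frequencies of bacterial proteomes (Swiss-Prot-like),
# renormalised over the 20 standard residues. Used as the default protein
# background and as the decoy-generator composition.
AA_BACKGROUND <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0581, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
  S = 0.0660, T = 0.0535, V = 0.0687, W = 0.0110, Y = 0.0292)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generator calls do not
#' disturb the caller's RNG stream. `seed = NULL` runs `expr` unseeded.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# letter -> integer code lookup over the 256 single-byte values
encoder_for <- function(alphabet) {
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt(paste(alphabet, collapse = ""))] <- seq_along(alphabet)
  lut
}

# Encode one sequence string as integer codes (NA for letters outside the
# alphabet, e.g. N).
encode_seq <- function(x, lut) lut[utf8ToInt(x)]

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Guess the alphabet of a set of sequences.
guess_alphabet <- function(seqs) {
  letters_seen <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  if (all(letters_seen %in% c(DNA_ALPHABET, "N"))) DNA_ALPHABET else AA_ALPHABET
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x == round(x)
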