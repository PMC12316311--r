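#' Read a FASTA file
#'
#' Wrapping-agnostic reader (via Biostrings); sequences are case-folded to
#' upper case. Duplicate ids are an error; an empty file returns an empty
#' vector with a warning.
#'
#' @param path FASTA file.
#' @param type `"auto"` (default), `"dna"` or `"protein"`.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("auto", "dna", "protein")) {
  type <- match.arg(type)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    warning(sprintf("empty FASTA file: %s", path))
    return(stats::setNames(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stopf("duplicate FASTA ids: %s", paste(dup, collapse = ", "))
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

GENE_TABLE_COLS <- c("genome_id", "gene_id", "contig", "start", "end",
                     "strand", "COG", "class")

#' Read a gene table
#'
#' Tab-separated with header; columns genome_id, gene_id, contig, start, end,
#' strand, COG, class (1-based inclusive coordinates). Coordinates are
#' validated (start <= end) and strand must be `+` or `-`; the COG column may
#' be empty.
#'
#' @param path file path.
#' @return data.frame of gene records.
#' @export
read_gene_table <- function(path) {
  gt <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing_cols <- setdiff(setdiff(GENE_TABLE_COLS, c("COG", "class")), names(gt))
  if (length(missing_cols))
    stopf("gene table missing columns: %s", paste(missing_cols, collapse = ", "))
  bad <- which(!(gt$start <= gt$end))
  if (length(bad))
    stopf("start > end at line %d of %s", bad[1] + 1L, path)
  badstrand <- which(!gt$strand %in% c("+", "-"))
  if (length(badstrand))
    stopf("invalid strand at line %d of %s", badstrand[1] + 1L, path)
  if (!"COG" %in% names(gt)) gt$COG <- NA_character_
  if (!"class" %in% names(gt)) gt$class <- NA_character_
  gt
}

#' Write a gene table
#' @param gene_table gene records.
#' @param path output path.
#' @export
write_gene_table <- function(gene_table, path) {
  utils::write.table(gene_table[, intersect(GENE_TABLE_COLS, names(gene_table))],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a promoter site collection
#'
#' Accepts FASTA or plain one-sequence-per-line text (the distribution format
#' of curated seed promoter sets). Returns unique upper-cased sequences.
#'
#' @param path file path.
#' @return character vector of unique site sequences.
#' @export
read_promoter_sites <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && startsWith(first, ">")) {
    unique(unname(read_fasta(path)))
  } else {
    lines <- toupper(trimws(readLines(path, warn = FALSE)))
    unique(lines[nzchar(lines)])
  }
}

#' Write PWMs in MEME motif text format
#'
#' Minimal MEME version-4 text: alphabet line, background frequencies, and a
#' letter-probability matrix per motif.
#'
#' @param pwms list of PWMs (or a single PWM).
#' @param path output path.
#' @param names motif names.
#' @export
write_meme <- function(pwms, path, names = NULL) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (is.null(names)) names <- sprintf("MOTIF_%d", seq_along(pwms))
  alphabet <- pwms[[1]]$alphabet
  bg <- pwms[[1]]$background$stationary
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "",
               paste0("ALPHABET= ", paste(alphabet, collapse = "")), "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", alphabet, bg), collapse = " "), ""), con)
  for (i in seq_along(pwms)) {
    p <- pwms[[i]]
    nsites <- if (is.na(p$nsites)) 20L else p$nsites
    writeLines(sprintf("MOTIF %s", names[i]), con)
    writeLines(sprintf("letter-probability matrix: alength= %d w= %d nsites= %d E= 0",
                       length(alphabet), p$width, nsites), con)
    for (j in seq_len(p$width))
      writeLines(paste(sprintf("%.6f", p$probs[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read PWMs from MEME motif text format
#' @param path MEME motif file.
#' @return named list of PWMs.
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  al_line <- grep("^ALPHABET=", lines, value = TRUE)
  if (!length(al_line)) stopf("no ALPHABET line in %s", path)
  alphabet <- strsplit(sub("^ALPHABET=\\s*", "", al_line[1]), "")[[1]]
  bg <- stats::setNames(rep(1 / length(alphabet), length(alphabet)), alphabet)
  bg_idx <- grep("^Background letter frequencies", lines)
  if (length(bg_idx)) {
    f <- strsplit(trimws(lines[bg_idx[1] + 1L]), "\\s+")[[1]]
    bg <- stats::setNames(as.numeric(f[seq(2, length(f), 2)]), f[seq(1, length(f), 2)])
    bg <- bg[alphabet] / sum(bg[alphabet])
  }
  background <- background_model(stationary = bg)
  motif_idx <- grep("^MOTIF\\s", lines)
  pwms <- list()
  for (mi in motif_idx) {
    name <- strsplit(trimws(lines[mi]), "\\s+")[[1]][2]
    hdr <- mi + which(grepl("^letter-probability matrix:", lines[(mi + 1):length(lines)]))[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- vapply(lines[(hdr + 1):(hdr + w)],
                   function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                   numeric(length(alphabet)))
    probs <- matrix(rows, nrow = length(alphabet), dimnames = list(alphabet, NULL))
    probs <- sweep(probs, 2, colSums(probs), "/")
    pwms[[name]] <- pwm_from_probs(probs, background = background)
  }
  pwms
}

#' Write a promoter hit table (TSV)
#' @param hits [scan_regions()] output.
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
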