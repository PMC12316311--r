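#' Ground-truth sigma-54 promoter PWM
#'
#' The bipartite -24/-12 promoter model used to plant sites: consensus
#' `TGGCACG` + N spacer + `TTGCT`, i.e. the -24 box `TGGCAC` and -12 box `TGC`
#' with their conserved flanking letters, separated so that the distance
#' between `TGGCAC` and `TGC` equals `spacer` (default 6 nt, range 5-7).
#' Conserved columns carry `conservation` probability on the consensus letter
#' (remainder split evenly); spacer columns are uniform.
#'
#' @param spacer nucleotides between the `TGGCAC` and `TGC` boxes (5-7).
#' @param conservation consensus-letter probability of conserved columns.
#' @param gc background GC content used for the log-odds reference.
#' @return a `pwm` object of width `spacer + 9`.
#' @export
default_promoter_pwm <- function(spacer = 6L, conservation = 0.95, gc = 0.5) {
  if (spacer < 3) stopf("spacer must be at least 3 nt")
  inner <- spacer - 3L                     # Ns between TGGCACG and TTGCT
  cons <- c(strsplit("TGGCACG", "")[[1]], rep(NA, inner), strsplit("TTGCT", "")[[1]])
  w <- length(cons)
  probs <- matrix(1 / 4, 4, w, dimnames = list(DNA_ALPHABET, NULL))
  for (j in seq_len(w)) {
    if (!is.na(cons[j])) {
      probs[, j] <- (1 - conservation) / 3
      probs[cons[j], j] <- conservation
    }
  }
  pwm_from_probs(probs, background = dna_background(gc))
}

#' Sample one promoter site from a truth PWM
#'
#' Draws a site column-wise from the PWM probabilities. When `spacer_range`
#' is given, a spacer length is drawn uniformly from it and the bipartite
#' default truth of that spacer is sampled (`pwm_truth` is then ignored).
#'
#' @param pwm_truth PWM to sample from (default [default_promoter_pwm()]).
#' @param spacer_range optional integer pair: uniform range of spacer lengths
#'   (nucleotides between the `TGGCAC` and `TGC` boxes).
#' @param rng_seed optional integer seed (local to this call).
#' @return a nucleotide string, with attribute `spacer` when drawn variably.
#' @export
sample_promoter <- function(pwm_truth = default_promoter_pwm(),
                            spacer_range = NULL, rng_seed = NULL) {
  with_seed(rng_seed, {
    sp <- NA_integer_
    if (!is.null(spacer_range)) {
      if (length(spacer_range) == 0) stopf("spacer_range must not be empty")
      rng <- seq(min(spacer_range), max(spacer_range))
      sp <- if (length(rng) == 1) rng else sample(rng, 1)
      pwm_truth <- default_promoter_pwm(spacer = sp)
    }
    letters <- pwm_truth$alphabet
    site <- vapply(seq_len(pwm_truth$width), function(j) {
      p <- pwm_truth$probs[, j]
      if (max(p) >= 1 - 1e-12) letters[which.max(p)]
      else sample(letters, 1, prob = p)
    }, character(1))
    structure(paste(site, collapse = ""), spacer = sp)
  })
}

#' Specification of one synthetic genome batch
#'
#' Bundles the parameters of the genome generator: number of genomes, genes
#' per genome, taxonomic class label, background GC and Markov order, operon
#' geometry (operon-size distribution, within-operon and between-unit
#' intergenic distances in nt), the fraction of transcription units led by a
#' planted sigma-54 promoter, the upstream window the truth labels refer to,
#' and the RNG seed.
#'
#' @param n_genomes,genes_per_genome counts.
#' @param class_label taxonomic class name.
#' @param gc_content stationary GC fraction in \[0, 1\].
#' @param markov_order background Markov order (0 or 1).
#' @param operon_geometry list with `sizes`, `size_probs`, `igd_within`
#'   (min/max nt), `igd_between` (min/max nt).
#' @param promoter_rate fraction of transcription units with a planted
#'   promoter, in \[0, 1\].
#' @param upstream_len upstream window length the planted offsets refer to.
#' @param spacer_range `NULL` for the fixed default spacer (6 nt) or an
#'   integer pair for variable 5-7 nt spacers.
#' @param pwm_truth truth PWM to plant (default [default_promoter_pwm()]).
#' @param rng_seed integer seed.
#' @export
genome_spec <- function(n_genomes = 2L, genes_per_genome = 60L,
                        class_label = "classA", gc_content = 0.5,
                        markov_order = 0L,
                        operon_geometry = list(sizes = 1:4,
                                               size_probs = c(0.45, 0.25, 0.18, 0.12),
                                               igd_within = c(0, 40),
                                               igd_between = c(130, 400)),
                        promoter_rate = 0.3, upstream_len = 350L,
                        spacer_range = NULL, pwm_truth = NULL,
                        rng_seed = 1L) {
  if (gc_content < 0 || gc_content > 1) stopf("gc_content must lie in [0, 1]")
  if (promoter_rate < 0 || promoter_rate > 1) stopf("promoter_rate must lie in [0, 1]")
  if (!markov_order %in% c(0L, 1L)) stopf("markov_order must be 0 or 1")
  if (is.null(pwm_truth)) pwm_truth <- default_promoter_pwm(gc = gc_content)
  if (upstream_len < pwm_truth$width)
    stopf("upstream_len (%d) must be >= the planted motif width (%d)",
          upstream_len, pwm_truth$width)
  structure(list(n_genomes = n_genomes, genes_per_genome = genes_per_genome,
                 class_label = class_label, gc_content = gc_content,
                 markov_order = markov_order, operon_geometry = operon_geometry,
                 promoter_rate = promoter_rate, upstream_len = upstream_len,
                 spacer_range = spacer_range, pwm_truth = pwm_truth,
                 rng_seed = as.integer(rng_seed)),
            class = "genome_spec")
}

# Lay out one genome: operon partition, coordinates, strands, planted sites.
generate_one_genome <- function(spec, genome_id) {
  geom <- spec$operon_geometry
  n_genes <- spec$genes_per_genome
  sizes <- integer(0)
  while (sum(sizes) < n_genes) {
    s <- sample(geom$sizes, 1, prob = geom$size_probs)
    sizes <- c(sizes, s)
  }
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n_genes)
  sizes <- sizes[sizes > 0]
  contig <- paste0(genome_id, "_c1")
  motif_w <- spec$pwm_truth$width
  gene_rows <- list(); tu_rows <- list(); prom_rows <- list()
  cursor <- 0L
  gi <- 0L
  for (ti in seq_along(sizes)) {
    gap_before <- sample(geom$igd_between[1]:geom$igd_between[2], 1)
    cursor <- cursor + gap_before
    strand <- sample(c("+", "-"), 1)
    tu_id <- sprintf("%s_tu%03d", genome_id, ti)
    starts <- integer(sizes[ti]); ends <- integer(sizes[ti])
    for (k in seq_len(sizes[ti])) {
      if (k > 1) cursor <- cursor + sample(geom$igd_within[1]:geom$igd_within[2], 1)
      len <- sample(300:1200, 1)
      starts[k] <- cursor + 1L
      ends[k] <- cursor + len
      cursor <- cursor + len
    }
    gene_ids <- sprintf("%s_g%04d", genome_id, gi + seq_len(sizes[ti]))
    gi <- gi + sizes[ti]
    # transcription order: left-to-right on +, right-to-left on -
    order_tx <- if (strand == "+") seq_len(sizes[ti]) else rev(seq_len(sizes[ti]))
    gene_rows[[ti]] <- data.frame(
      genome_id = genome_id, gene_id = gene_ids, contig = contig,
      start = starts, end = ends, strand = strand,
      COG = NA_character_, class = spec$class_label,
      stringsAsFactors = FALSE)
    tu_rows[[ti]] <- data.frame(
      tu_id = tu_id, genome_id = genome_id, contig = contig, strand = strand,
      gene_id = gene_ids[order_tx], tu_order = seq_len(sizes[ti]),
      stringsAsFactors = FALSE)
    planted <- stats::runif(1) < spec$promoter_rate
    if (planted) {
      site <- sample_promoter(spec$pwm_truth, spacer_range = spec$spacer_range)
      w <- nchar(site)
      gap_avail <- if (strand == "+") gap_before else NA   # minus strand gap known later
      prom_rows[[ti]] <- data.frame(
        tu_id = tu_id, genome_id = genome_id, contig = contig, strand = strand,
        site = as.character(site), width = w,
        leader_start = if (strand == "+") starts[1] else NA_integer_,
        leader_end = if (strand == "-") ends[sizes[ti]] else NA_integer_,
        dist = NA_integer_, gap_avail = gap_avail,
        stringsAsFactors = FALSE)
    }
  }
  trailing <- sample(geom$igd_between[1]:geom$igd_between[2], 1)
  total_len <- cursor + trailing
  genes <- do.call(rbind, gene_rows)
  tus <- do.call(rbind, tu_rows)
  proms <- if (length(prom_rows)) do.call(rbind, prom_rows[!vapply(prom_rows, is.null, logical(1))]) else NULL
  # resolve minus-strand upstream gaps (distance to next gene or contig end)
  if (!is.null(proms) && nrow(proms)) {
    for (r in seq_len(nrow(proms))) {
      if (proms$strand[r] == "-") {
        le <- proms$leader_end[r]
        nxt <- suppressWarnings(min(genes$start[genes$start > le]))
        proms$gap_avail[r] <- (if (is.finite(nxt)) nxt - 1L else total_len) - le
      }
      w <- proms$width[r]
      dmax <- min(proms$gap_avail[r], spec$upstream_len)
      lo <- w + 8L
      hi <- max(lo, min(w + 45L, dmax))
      proms$dist[r] <- if (hi <= lo) min(lo, dmax) else sample(lo:hi, 1)
    }
  }
  # emit background and overwrite planted sites
  seq_chars <- strsplit(sample_background(total_len,
      dna_background(spec$gc_content, order = spec$markov_order)), "")[[1]]
  if (!is.null(proms) && nrow(proms)) {
    for (r in seq_len(nrow(proms))) {
      w <- proms$width[r]; d <- proms$dist[r]
      if (proms$strand[r] == "+") {
        s0 <- proms$leader_start[r] - d
        seq_chars[s0:(s0 + w - 1L)] <- strsplit(proms$site[r], "")[[1]]
      } else {
        e0 <- proms$leader_end[r] + d
        seq_chars[(e0 - w + 1L):e0] <- strsplit(revcomp(proms$site[r]), "")[[1]]
      }
    }
  }
  list(sequence = stats::setNames(paste(seq_chars, collapse = ""), contig),
       gene_table = genes, tus = tus, promoters = proms)
}

#' Generate synthetic genomes with planted sigma-54 promoters
#'
#' Emits background sequence from the specified Markov model, places genes on
#' both strands with the requested operon geometry, and plants one sampled
#' promoter site upstream of the leader gene of a `promoter_rate` fraction of
#' transcription units. All planted structure is returned as truth labels.
#'
#' @param spec a [genome_spec()].
#' @return list with `sequences` (named contig strings), `gene_table`
#'   (genome_id, gene_id, contig, start, end, strand, COG, class), and `truth`
#'   (`regulated_genes`, `promoter_positions`, `tus`, `cog_assignment`,
#'   `enriched_cogs`).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$rng_seed, {
    out <- lapply(seq_len(spec$n_genomes), function(i)
      generate_one_genome(spec, sprintf("%s_g%02d", spec$class_label, i)))
    sequences <- unlist(lapply(out, `[[`, "sequence"))
    gene_table <- do.call(rbind, lapply(out, `[[`, "gene_table"))
    tus <- do.call(rbind, lapply(out, `[[`, "tus"))
    proms <- do.call(rbind, Filter(Negate(is.null), lapply(out, `[[`, "promoters")))
    regulated <- character(0)
    if (!is.null(proms) && nrow(proms))
      regulated <- tus$gene_id[tus$tu_id %in% proms$tu_id]
    rownames(gene_table) <- NULL
    truth <- list(regulated_genes = regulated,
                  promoter_positions = proms,
                  tus = tus,
                  cog_assignment = NULL,
                  enriched_cogs = NULL)
    list(sequences = sequences, gene_table = gene_table, truth = truth)
  })
}

#' Generate a multi-class collection with planted COG enrichment
#'
#' Generates genomes for each class spec, then assigns COG labels so that the
#' classes named in `enrichment_plan` have their planted COGs preferentially
#' carried by sigma-54-regulated genes (the true enrichment signal downstream
#' analysis should recover).
#'
#' @param specs list of [genome_spec()] objects (one per class).
#' @param enrichment_plan named list: class label -> character vector of COG
#'   ids planted as enriched. Empty list plants no dependence.
#' @param cog_vocab shared COG vocabulary.
#' @param cog_assign_rate fraction of genes receiving a COG label.
#' @param enrich_prob probability that a regulated gene of an enriched class
#'   carries a planted COG instead of a baseline draw.
#' @return list with `sequences`, `gene_table`, `truth`, and `classes`.
#' @export
generate_class_collection <- function(specs, enrichment_plan = list(),
                                      cog_vocab = sprintf("COG%04d", 1:40),
                                      cog_assign_rate = 0.85,
                                      enrich_prob = 0.3) {
  if (length(specs) < 1) stopf("at least one class spec is required")
  labels <- vapply(specs, `[[`, character(1), "class_label")
  if (anyDuplicated(labels)) stopf("class labels must be unique")
  if (any(vapply(specs, function(s) as.numeric(s$n_genomes), numeric(1)) < 1))
    stopf("every class needs at least one genome")
  unknown <- setdiff(names(enrichment_plan), labels)
  if (length(unknown)) stopf("enrichment_plan names unknown class: %s", unknown[1])
  gens <- lapply(specs, generate_genome)
  sequences <- unlist(lapply(gens, `[[`, "sequences"))
  gene_table <- do.call(rbind, lapply(gens, `[[`, "gene_table"))
  tus <- do.call(rbind, lapply(gens, function(g) g$truth$tus))
  proms <- do.call(rbind, Filter(Negate(is.null),
                                 lapply(gens, function(g) g$truth$promoter_positions)))
  regulated <- unlist(lapply(gens, function(g) g$truth$regulated_genes))
  rownames(gene_table) <- NULL
  cog_seed <- specs[[1]]$rng_seed + 104729L   # offset stream for label assignment
  gene_table$COG <- with_seed(cog_seed, {
    cogs <- ifelse(stats::runif(nrow(gene_table)) < cog_assign_rate,
                   sample(cog_vocab, nrow(gene_table), replace = TRUE),
                   NA_character_)
    for (cl in names(enrichment_plan)) {
      planted <- enrichment_plan[[cl]]
      idx <- which(gene_table$class == cl & gene_table$gene_id %in% regulated)
      hit <- idx[stats::runif(length(idx)) < enrich_prob]
      if (length(hit))
        cogs[hit] <- sample(planted, length(hit), replace = TRUE)
    }
    cogs
  })
  enriched <- if (length(enrichment_plan))
    do.call(rbind, lapply(names(enrichment_plan), function(cl)
      data.frame(class = cl, cog = enrichment_plan[[cl]], stringsAsFactors = FALSE)))
  else NULL
  truth <- list(regulated_genes = regulated, promoter_positions = proms,
                tus = tus,
                cog_assignment = stats::setNames(gene_table$COG, gene_table$gene_id),
                enriched_cogs = enriched)
  list(sequences = sequences, gene_table = gene_table, truth = truth,
       classes = labels)
}

#' Specification of a synthetic EBP proteome
#'
#' Positives are built from 10 ordered motif instances (containing the
#' invariant GAFTGA hexapeptide) joined by random linkers; decoys are random
#' sequences with GAFTGA occurrences rejected and resampled.
#'
#' @param n_positives,n_decoys counts.
#' @param motif_truth list of 10 protein PWMs of width 12 (default
#'   [default_ebp_motifs()]).
#' @param linker_len_range,decoy_len_range length ranges in amino acids.
#' @param rng_seed integer seed.
#' @export
proteome_spec <- function(n_positives = 60L, n_decoys = 120L,
                          motif_truth = default_ebp_motifs(),
                          linker_len_range = c(5, 40),
                          decoy_len_range = c(200, 1000),
                          rng_seed = 1L) {
  if (length(motif_truth) != 10) stopf("motif_truth must contain 10 motifs")
  structure(list(n_positives = n_positives, n_decoys = n_decoys,
                 motif_truth = motif_truth,
                 linker_len_range = linker_len_range,
                 decoy_len_range = decoy_len_range,
                 rng_seed = as.integer(rng_seed)),
            class = "proteome_spec")
}

#' Ground-truth EBP motif set
#'
#' Ten protein PWMs of width 12 at `conservation` consensus probability;
#' motif 2 (the first along the protein in the conserved architecture) embeds
#' the invariant `GAFTGA` hexapeptide with probability 1.
#' @param conservation consensus-letter probability of non-invariant columns.
#' @export
default_ebp_motifs <- function(conservation = 0.9) {
  consensi <- c("LRDVIESNMRVL",   # 1
                "MAGAFTGAEDKR",   # 2: carries GAFTGA
                "WKQHVDTEFPNS",   # 3
                "DYETIKVHMWSA",   # 4
                "QLNPRSGAYWCK",   # 5
                "FHTMEKDQVLYG",   # 6
                "SPVKAYLHNTWE",   # 7
                "CGRWFDMKAQIT",   # 8
                "ENSLHQPVYKFD",   # 9
                "TKFYGWALRMEP")   # 10
  bg <- protein_background()
  lapply(seq_along(consensi), function(i) {
    cons <- strsplit(consensi[i], "")[[1]]
    probs <- matrix((1 - conservation) / 19, 20, 12,
                    dimnames = list(AA_ALPHABET, NULL))
    for (j in 1:12) probs[cons[j], j] <- conservation
    if (i == 2) {
      # keep GAFTGA invariant (positions 3-8 of the consensus MAGAFTGAEDKR)
      for (j in 3:8) { probs[, j] <- 0; probs[cons[j], j] <- 1 }
    }
    pwm_from_probs(probs, background = bg)
  })
}

#' Architecture order of the planted EBP motifs along the protein
#'
#' The conserved left-to-right order of the 10 motifs in sigma-54-specific
#' enhancer-binding proteins, in truth-motif numbering.
#' @export
sigma54_ebp_motif_order <- c(2L, 10L, 6L, 3L, 4L, 9L, 7L, 5L, 8L, 1L)

sample_protein_letters <- function(n) {
  sample(AA_ALPHABET, n, replace = TRUE, prob = AA_BACKGROUND)
}

sample_motif_instance <- function(pwm) {
  paste(vapply(seq_len(pwm$width), function(j) {
    p <- pwm$probs[, j]
    if (max(p) >= 1 - 1e-12) pwm$alphabet[which.max(p)]
    else sample(pwm$alphabet, 1, prob = p)
  }, character(1)), collapse = "")
}

#' Generate a synthetic EBP proteome with truth labels
#'
#' @param spec a [proteome_spec()].
#' @param architecture_order left-to-right motif order used to build
#'   positives (default [sigma54_ebp_motif_order]).
#' @return list with `proteins` (named character vector) and `truth`
#'   (`ebp_proteins`: ids of the planted positives).
#' @export
generate_proteome <- function(spec, architecture_order = sigma54_ebp_motif_order) {
  stopifnot(inherits(spec, "proteome_spec"))
  with_seed(spec$rng_seed, {
    lr <- spec$linker_len_range
    positives <- character(spec$n_positives)
    for (i in seq_len(max(spec$n_positives, 0))) {
      parts <- character(0)
      for (mi in architecture_order) {
        linker <- paste(sample_protein_letters(sample(lr[1]:lr[2], 1)), collapse = "")
        parts <- c(parts, linker, sample_motif_instance(spec$motif_truth[[mi]]))
      }
      tail_linker <- paste(sample_protein_letters(sample(lr[1]:lr[2], 1)), collapse = "")
      positives[i] <- paste(c(parts, tail_linker), collapse = "")
    }
    dr <- spec$decoy_len_range
    decoys <- character(spec$n_decoys)
    for (i in seq_len(max(spec$n_decoys, 0))) {
      repeat {
        s <- paste(sample_protein_letters(sample(dr[1]:dr[2], 1)), collapse = "")
        if (!grepl("GAFTGA", s, fixed = TRUE)) break
      }
      decoys[i] <- s
    }
    names(positives) <- sprintf("ebp%04d", seq_len(max(spec$n_positives, 0)))[seq_along(positives)]
    names(decoys) <- sprintf("decoy%05d", seq_len(max(spec$n_decoys, 0)))[seq_along(decoys)]
    proteins <- c(positives, decoys)
    list(proteins = proteins,
         truth = list(ebp_proteins = names(positives)))
  })
}
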