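#' Pipeline configuration
#'
#' Builds (and validates) the configuration consumed by [run_pipeline()].
#' Inputs are either paths to on-disk files (genome FASTA, gene table, seed
#' promoter sites, proteome FASTA, domain-hit tables) or `synthetic = TRUE`,
#' in which case the generator supplies everything with planted ground truth.
#'
#' @param out_dir output directory.
#' @param rng_seed master seed; every stochastic stage derives its seed from
#'   it.
#' @param synthetic generate inputs with the synthetic-data module.
#' @param genome_fasta,gene_table,seed_sites,proteome_fasta,domain_hits
#'   optional input paths (checked at load time).
#' @param window_len upstream window (nt).
#' @param n_cycles pattern-finding/pattern-discovery cycles.
#' @param cutoffs E-value cutoffs for calibration.
#' @param pseudocount PWM smoothing.
#' @param max_igd,link_threshold operon-prediction thresholds.
#' @param ebp_domain_evalue,cluster_identity,ebp_motif_width,ebp_nmotifs,ebp_scan_evalue
#'   EBP pipeline parameters.
#' @param rpon_thresholds RpoN domain E-value thresholds.
#' @param synthetic_specs list of [genome_spec()] for synthetic mode.
#' @param enrichment_plan planted enrichment for synthetic mode.
#' @export
pipeline_config <- function(out_dir, rng_seed = 1L, synthetic = TRUE,
                            genome_fasta = NULL, gene_table = NULL,
                            seed_sites = NULL, proteome_fasta = NULL,
                            domain_hits = NULL,
                            window_len = 350L, n_cycles = 5L,
                            cutoffs = c(0.625, 1.25, 2.5, 5),
                            pseudocount = 0.25,
                            max_igd = 45L, link_threshold = 0.7,
                            ebp_domain_evalue = 1e-51, cluster_identity = 0.6,
                            ebp_motif_width = 12L, ebp_nmotifs = 10L,
                            ebp_scan_evalue = 0.1,
                            rpon_thresholds = rpon_domain_thresholds(),
                            synthetic_specs = NULL,
                            enrichment_plan = list()) {
  paths <- Filter(Negate(is.null),
                  list(genome_fasta = genome_fasta, gene_table = gene_table,
                       seed_sites = seed_sites, proteome_fasta = proteome_fasta,
                       domain_hits = domain_hits))
  for (nm in names(paths))
    if (!file.exists(paths[[nm]])) stopf("input path does not exist: %s", paths[[nm]])
  if (window_len < 1 || n_cycles < 1 || any(cutoffs <= 0))
    stopf("invalid pipeline parameters")
  structure(c(list(out_dir = out_dir, rng_seed = as.integer(rng_seed),
                   synthetic = synthetic,
                   window_len = window_len, n_cycles = n_cycles,
                   cutoffs = cutoffs, pseudocount = pseudocount,
                   max_igd = max_igd, link_threshold = link_threshold,
                   ebp_domain_evalue = ebp_domain_evalue,
                   cluster_identity = cluster_identity,
                   ebp_motif_width = ebp_motif_width,
                   ebp_nmotifs = ebp_nmotifs,
                   ebp_scan_evalue = ebp_scan_evalue,
                   rpon_thresholds = rpon_thresholds,
                   synthetic_specs = synthetic_specs,
                   enrichment_plan = enrichment_plan),
              paths),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file with keys matching [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' A small self-contained demo configuration
#' @param out_dir output directory.
#' @param rng_seed master seed.
#' @export
demo_config <- function(out_dir = tempfile("rponscan_demo_"), rng_seed = 1L) {
  specs <- list(
    genome_spec(n_genomes = 2, genes_per_genome = 40, class_label = "classA",
                promoter_rate = 0.3, rng_seed = rng_seed),
    genome_spec(n_genomes = 2, genes_per_genome = 40, class_label = "classB",
                promoter_rate = 0.3, rng_seed = rng_seed + 1L))
  pipeline_config(out_dir = out_dir, rng_seed = rng_seed, synthetic = TRUE,
                  synthetic_specs = specs,
                  enrichment_plan = list(classA = "COG0174"))
}

#' Run the full regulon-inference pipeline
#'
#' Executes the three phases in order — seed PWM construction, per-class
#' pattern-finding/pattern-discovery cycles with cutoff calibration, operon
#' prediction and operon-expanded COG enrichment — plus the EBP-detection
#' and RpoN-census branches when their inputs are available, and writes all
#' result tables and a run manifest under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list of results: `seed_pwm`, `calibration`, `hits`,
#'   `tus`, `regulated`, `enrichment`, `ebp`, `census`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  results <- list()

  # --- inputs --------------------------------------------------------------
  if (isTRUE(config$synthetic)) {
    specs <- config$synthetic_specs
    if (is.null(specs))
      specs <- list(genome_spec(class_label = "classA",
                                rng_seed = config$rng_seed))
    collection <- generate_class_collection(specs, config$enrichment_plan)
    genomes <- collection$sequences
    gene_table <- collection$gene_table
    truth <- collection$truth
    seed_sites <- with_seed(config$rng_seed + 7L,
      vapply(1:200, function(i) as.character(sample_promoter()), character(1)))
    log_stage("inputs", "synthetic collection: %d genomes, %d genes",
              length(genomes), nrow(gene_table))
  } else {
    genomes <- read_fasta(config$genome_fasta)
    gene_table <- read_gene_table(config$gene_table)
    truth <- NULL
    seed_sites <- read_promoter_sites(config$seed_sites)
    log_stage("inputs", "%d contigs, %d genes, %d seed sites",
              length(genomes), nrow(gene_table), length(seed_sites))
  }

  # --- phase 1: seed matrix ------------------------------------------------
  seed_pwm <- build_pwm(seed_sites, pseudocount = config$pseudocount)
  write_meme(seed_pwm, file.path(config$out_dir, "seed_pwm.meme"), names = "seed")
  utils::write.csv(pwm_ic_table(seed_pwm),
                   file.path(config$out_dir, "seed_pwm_ic.csv"), row.names = FALSE)
  results$seed_pwm <- seed_pwm
  log_stage("seed", "seed PWM width %d from %d sites", seed_pwm$width,
            length(seed_sites))

  # --- operons -------------------------------------------------------------
  tus <- predict_operons(gene_table, max_igd = config$max_igd,
                         link_threshold = config$link_threshold)
  results$tus <- tus
  log_stage("operons", "%d transcription units", length(unique(tus$tu_id)))

  # --- phase 2: per-class cycles ------------------------------------------
  hits_all <- list(); regulated <- list(); calib <- list()
  for (cl in unique(gene_table$class)) {
    gsub_ <- gene_table[gene_table$class == cl, , drop = FALSE]
    tsub <- tus[tus$gene_id %in% gsub_$gene_id, , drop = FALSE]
    regions <- extract_upstream(gsub_, genomes, tsub,
                                window_len = config$window_len)
    if (!is.null(truth)) {
      cl_truth <- intersect(truth$regulated_genes, gsub_$gene_id)
      cal <- calibrate_cutoff(seed_pwm, regions, tsub, cl_truth, gsub_$gene_id,
                              cutoffs = config$cutoffs,
                              n_cycles = config$n_cycles,
                              seed = config$rng_seed)
      calib[[cl]] <- cal
      tr <- cal$traces[[match(cal$selected_cutoff, config$cutoffs)]]
      hits <- tr[[length(tr)]]$hits
    } else {
      tr <- run_cycles(seed_pwm, regions, n_cycles = config$n_cycles,
                       e_cutoff = max(config$cutoffs), seed = config$rng_seed)
      hits <- tr[[length(tr)]]$hits
    }
    hits_all[[cl]] <- hits
    regulated[[cl]] <- expand_regulon(hits, tsub)
    write_hits(hits, file.path(config$out_dir, sprintf("hits_%s.tsv", cl)))
    log_stage("cycles", "class %s: %d hits, %d regulated genes", cl,
              nrow(hits), length(regulated[[cl]]))
  }
  results$calibration <- calib
  results$hits <- hits_all
  results$regulated <- regulated

  # --- phase 3: enrichment -------------------------------------------------
  enr <- enrich_classes(gene_table, regulated)
  utils::write.csv(enr, file.path(config$out_dir, "enrichment.csv"),
                   row.names = FALSE)
  results$enrichment <- enr
  log_stage("enrichment", "%d (class, COG) results", nrow(enr))

  # --- EBP branch ----------------------------------------------------------
  if (isTRUE(config$synthetic)) {
    pspec <- proteome_spec(n_positives = 30, n_decoys = 60,
                           rng_seed = config$rng_seed + 11L)
    prot <- generate_proteome(pspec)
    ebp <- run_ebp_pipeline(prot$proteins[prot$truth$ebp_proteins],
                            reference_positives = prot$proteins[prot$truth$ebp_proteins],
                            seed = config$rng_seed)
    # classify the whole proteome with the trained motif set
    prep <- prepare_motif_scan(ebp$motifs)
    verdicts <- vapply(names(prot$proteins), function(id) {
      sc <- scan_protein_prepared(prep, prot$proteins[[id]], config$ebp_scan_evalue)
      classify_ebp(sc, prot$proteins[[id]], ebp$expected_order)$verdict
    }, character(1))
    ebp$proteome_verdicts <- data.frame(protein_id = names(verdicts),
                                        verdict = unname(verdicts),
                                        stringsAsFactors = FALSE)
    utils::write.csv(ebp$proteome_verdicts,
                     file.path(config$out_dir, "ebp_verdicts.csv"),
                     row.names = FALSE)
    results$ebp <- ebp
    log_stage("ebp", "%d bona fide of %d proteins",
              sum(verdicts == "bona_fide"), length(verdicts))
  } else if (!is.null(config$proteome_fasta)) {
    proteins <- read_fasta(config$proteome_fasta, type = "protein")
    dh <- if (!is.null(config$domain_hits)) read_domtbl(config$domain_hits) else NULL
    ebp <- run_ebp_pipeline(proteins, domain_hits = dh,
                            domain_threshold = config$ebp_domain_evalue,
                            identity_threshold = config$cluster_identity,
                            width = config$ebp_motif_width,
                            n_motifs = config$ebp_nmotifs,
                            e_cutoff = config$ebp_scan_evalue,
                            seed = config$rng_seed)
    utils::write.csv(ebp$verdicts, file.path(config$out_dir, "ebp_verdicts.csv"),
                     row.names = FALSE)
    results$ebp <- ebp
  }

  # --- RpoN census branch --------------------------------------------------
  if (!is.null(config$domain_hits) || isTRUE(config$synthetic)) {
    roster <- unique(gene_table[, c("genome_id", "class")])
    names(roster) <- c("genome_id", "class_label")
    if (isTRUE(config$synthetic)) {
      # plant one full-architecture RpoN per genome except the last
      pos <- roster$genome_id[-nrow(roster)]
      calls <- data.frame(protein_id = paste0(pos, "_rpon"), genome_id = pos,
                          architecture = "AID-DBD-CBD", stringsAsFactors = FALSE)
    } else {
      rcalls <- classify_rpon(read_domtbl(config$domain_hits),
                              thresholds = config$rpon_thresholds)
      rcalls <- rcalls[rcalls$architecture != "none", , drop = FALSE]
      calls <- data.frame(protein_id = rcalls$protein_id,
                          genome_id = sub("_.*$", "", rcalls$protein_id),
                          architecture = rcalls$architecture,
                          stringsAsFactors = FALSE)
    }
    cens <- rpon_census(calls, roster)
    utils::write.csv(cens$per_class, file.path(config$out_dir, "census.csv"),
                     row.names = FALSE)
    results$census <- cens
    log_stage("census", "%.1f%% of organisms carry rpoN",
              cens$global$pct_with_rpon)
  }

  # --- manifest ------------------------------------------------------------
  outputs <- list.files(config$out_dir, full.names = FALSE)
  checksums <- vapply(file.path(config$out_dir, outputs), function(f)
    as.character(sum(utf8ToInt(paste(readLines(f, warn = FALSE), collapse = "\n")))),
    character(1))
  manifest <- list(package_version = as.character(utils::packageVersion("rponscan")),
                   rng_seed = config$rng_seed,
                   parameters = config[c("window_len", "n_cycles", "cutoffs",
                                         "pseudocount", "max_igd",
                                         "ebp_scan_evalue")],
                   outputs = stats::setNames(as.list(unname(checksums)), outputs))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
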