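# Shared fixtures, built in code and memoised per test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) assign(key, expr, envir = fixture_env)
  get(key, envir = fixture_env)
}

# seed sites drawn from the ground-truth promoter model
truth_seed_sites <- function(n = 200, seed0 = 5000) {
  memo(sprintf("sites_%d_%d", n, seed0),
       vapply(seq_len(n), function(i)
         as.character(sample_promoter(rng_seed = seed0 + i)), character(1)))
}

truth_seed_pwm <- function() memo("seed_pwm", build_pwm(truth_seed_sites()))

# a small planted genome shared across pipeline tests
small_genome <- function() {
  memo("small_genome", {
    spec <- genome_spec(n_genomes = 2, genes_per_genome = 50,
                        promoter_rate = 0.3, rng_seed = 7)
    generate_genome(spec)
  })
}

# a synthetic EBP proteome and the motif set trained on its positives
ebp_fixture <- function() {
  memo("ebp_fixture", {
    pspec <- proteome_spec(n_positives = 60, n_decoys = 200, rng_seed = 3)
    prot <- generate_proteome(pspec)
    pos <- prot$proteins[prot$truth$ebp_proteins]
    pipe <- run_ebp_pipeline(pos, reference_positives = pos, seed = 2)
    list(proteome = prot, positives = pos,
         decoys = prot$proteins[setdiff(names(prot$proteins),
                                        prot$truth$ebp_proteins)],
         motifs = pipe$motifs, expected_order = pipe$expected_order,
         verdicts = pipe$verdicts)
  })
}

# build a protein from truth-motif consensus instances in a given order
make_architecture_protein <- function(order = sigma54_ebp_motif_order,
                                      drop = integer(0), seed = 17) {
  motifs <- default_ebp_motifs()
  with_seed(seed, {
    parts <- character(0)
    for (mi in order) {
      linker <- paste(sample(rponscan:::AA_ALPHABET, 12, replace = TRUE,
                             prob = rponscan:::AA_BACKGROUND), collapse = "")
      inst <- if (mi %in% drop) "" else as.character(consensus(motifs[[mi]]))
      parts <- c(parts, linker, inst)
    }
    paste(parts, collapse = "")
  })
}
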