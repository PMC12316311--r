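toy_genome <- function() {
  # one 1000-nt contig, two genes mirrored across strands
  set.seed(5)
  seq1 <- sample_background(1000, rng_seed = 5)
  genes <- data.frame(
    genome_id = "g1", gene_id = c("gA", "gB"), contig = "c1",
    start = c(401, 1000 - 500 + 1), end = c(500, 1000 - 401 + 1),
    strand = c("+", "-"), COG = NA_character_, class = "t",
    stringsAsFactors = FALSE)
  # mirror the sequence so the minus-strand upstream is the revcomp mirror
  list(sequences = c(c1 = seq1), genes = genes)
}

test_that("extract_upstream truncates at contig edges and resolves strand", {
  g <- toy_genome()
  genes <- g$genes[1, ]
  genes$start <- 11; genes$end <- 110
  tus <- data.frame(tu_id = "t1", gene_id = "gA", tu_order = 1)
  reg <- extract_upstream(genes, g$sequences, tus, window_len = 300)
  expect_equal(nchar(reg$sequence), 10)   # only 10 nt available
  expect_equal(reg$genomic_start, 1)

  # plus and minus strand genes at mirrored coordinates give
  # reverse-complement-identical regions
  s <- g$sequences["c1"]
  mirrored <- c(c1 = paste0(s, revcomp(s)))
  L <- nchar(s)
  genes2 <- data.frame(
    genome_id = "g1", gene_id = c("fw", "rc"), contig = "c1",
    start = c(401, 2 * L - 500 + 1), end = c(500, 2 * L - 401 + 1),
    strand = c("+", "-"), COG = NA_character_, class = "t",
    stringsAsFactors = FALSE)
  tus2 <- data.frame(tu_id = c("t1", "t2"), gene_id = c("fw", "rc"),
                     tu_order = c(1, 1))
  regs <- extract_upstream(genes2, mirrored, tus2, window_len = 100)
  expect_identical(regs$sequence[1], regs$sequence[2])
})

test_that("scanning recovers planted sites and respects the E-value contract", {
  g <- small_genome()
  regions <- extract_upstream(g$gene_table, g$sequences, g$truth$tus, 350)
  pwm <- truth_seed_pwm()
  hits <- scan_regions(pwm, regions, e_cutoff = 5)
  planted <- g$truth$promoter_positions$tu_id
  expect_gte(sum(planted %in% hits$tu_id), length(planted) - 1)
  expect_true(all(diff(hits$e_value) >= 0))
  expect_true(all(hits$e_value <= 5))
  # cutoff 0: no E-value can satisfy it
  expect_equal(nrow(scan_regions(pwm, regions, e_cutoff = 0)), 0)
  # raising the cutoff never removes a hit
  hits2 <- scan_regions(pwm, regions, e_cutoff = 10)
  expect_true(all(hits$region_id %in% hits2$region_id))
})

test_that("doubling the region set with non-matching sequence doubles E-values", {
  g <- small_genome()
  regions <- extract_upstream(g$gene_table, g$sequences, g$truth$tus, 350)
  pwm <- truth_seed_pwm()
  decoy <- regions
  decoy$region_id <- paste0(decoy$region_id, "_d")
  decoy$tu_id <- paste0(decoy$tu_id, "_d")
  decoy$sequence <- vapply(seq_len(nrow(decoy)), function(i)
    sample_background(nchar(decoy$sequence[i]), rng_seed = 777 + i), character(1))
  h1 <- scan_regions(pwm, regions, e_cutoff = 5)
  h2 <- scan_regions(pwm, rbind(regions, decoy), e_cutoff = 10)
  common <- intersect(h1$region_id, h2$region_id)
  expect_gt(length(common), 0)
  e1 <- h1$e_value[match(common, h1$region_id)]
  e2 <- h2$e_value[match(common, h2$region_id)]
  expect_equal(e2, 2 * e1, tolerance = 1e-9)
  expect_equal(h2$p_value[match(common, h2$region_id)],
               h1$p_value[match(common, h1$region_id)])
})

test_that("run_cycles stops early without matches and reduces to scan_regions at one cycle", {
  pwm <- truth_seed_pwm()
  null_regions <- data.frame(
    region_id = paste0("r", 1:20), tu_id = paste0("t", 1:20),
    sequence = vapply(1:20, function(i) sample_background(300, rng_seed = i),
                      character(1)),
    stringsAsFactors = FALSE)
  tr <- run_cycles(pwm, null_regions, n_cycles = 5, e_cutoff = 0.625)
  expect_length(tr, 1)
  expect_true(attr(tr, "early_stop"))
  expect_identical(tr[[1]]$pwm, pwm)   # final PWM is still the seed

  g <- small_genome()
  regions <- extract_upstream(g$gene_table, g$sequences, g$truth$tus, 350)
  tr1 <- run_cycles(pwm, regions, n_cycles = 1, e_cutoff = 5)
  direct <- scan_regions(pwm, regions, e_cutoff = 5)
  expect_equal(tr1[[1]]$hits$region_id, direct$region_id)
  expect_error(run_cycles(build_pwm("ACD"), regions), "DNA")
})

test_that("cycles refine a corrupted seed toward the planted truth", {
  truth <- default_promoter_pwm()
  # corrupt: blend 10% noise into every column
  noisy <- truth$probs * 0.9 + 0.1 / 4
  seed_pwm <- pwm_from_probs(noisy, background = truth$background)
  spec <- genome_spec(n_genomes = 2, genes_per_genome = 150,
                      promoter_rate = 0.35, rng_seed = 55)
  g <- generate_genome(spec)
  regions <- extract_upstream(g$gene_table, g$sequences, g$truth$tus, 350)
  tr <- run_cycles(seed_pwm, regions, n_cycles = 5, e_cutoff = 5, seed = 4)
  tvd <- function(p) mean(colSums(abs(p$probs - truth$probs)) / 2)
  expect_lt(tvd(tr[[length(tr)]]$pwm), tvd(seed_pwm))
})

test_that("confusion_and_mcc implements the standard definitions and conventions", {
  u <- sprintf("g%02d", 1:10)
  m <- confusion_and_mcc(u[1:3], u[1:3], u)
  expect_equal(m$mcc, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)

  # tp=2 fp=1 fn=1 tn=6
  m2 <- confusion_and_mcc(u[1:3], u[c(1, 2, 4)], u)
  expect_equal(unname(m2$confusion), c(2, 1, 1, 6))
  expect_equal(m2$mcc, 11 / 21)

  m3 <- confusion_and_mcc(character(0), u[1:3], u)
  expect_equal(m3$mcc, 0)
  expect_equal(m3$sensitivity, 0)
  expect_error(confusion_and_mcc(c("zz"), u[1], u), "universe")
})

test_that("calibrate_cutoff ties break small and single cutoffs are unconditional", {
  g <- small_genome()
  tus <- g$truth$tus
  regions <- extract_upstream(g$gene_table, g$sequences, tus, 350)
  pwm <- truth_seed_pwm()
  cal <- calibrate_cutoff(pwm, regions, tus, g$truth$regulated_genes,
                          g$gene_table$gene_id, cutoffs = 2.5, n_cycles = 2,
                          seed = 1)
  expect_equal(cal$selected_cutoff, 2.5)
  # force a tie by duplicating the cutoff list
  cal2 <- calibrate_cutoff(pwm, regions, tus, g$truth$regulated_genes,
                           g$gene_table$gene_id, cutoffs = c(2.5, 2.5),
                           n_cycles = 1, seed = 1)
  expect_equal(cal2$selected_cutoff, 2.5)
  expect_equal(cal2$per_cutoff$mcc[1], cal2$per_cutoff$mcc[2])
})

test_that("non-canonical spacers lower sensitivity against a fixed-spacer seed", {
  seed_pwm <- truth_seed_pwm()          # trained on 6-nt-spacer sites
  mk <- function(spacer_range, seed) {
    spec <- genome_spec(n_genomes = 2, genes_per_genome = 120,
                        promoter_rate = 0.5, spacer_range = spacer_range,
                        rng_seed = seed)
    g <- generate_genome(spec)
    regions <- extract_upstream(g$gene_table, g$sequences, g$truth$tus, 350)
    hits <- scan_regions(seed_pwm, regions, e_cutoff = 5)
    planted <- g$truth$promoter_positions$tu_id
    mean(planted %in% hits$tu_id)
  }
  sens_canonical <- mk(NULL, 61)          # fixed 6-nt spacer
  sens_shifted <- mk(c(5, 5), 62)         # all 5-nt spacers
  expect_gt(sens_canonical, sens_shifted)
})
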