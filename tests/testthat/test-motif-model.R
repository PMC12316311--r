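test_that("build_pwm tallies counts and applies the pseudocount formula", {
  p <- build_pwm(c("TGGCA", "TGGCA"), pseudocount = 0)
  expect_equal(unname(p$probs["T", 1]), 1)
  expect_equal(as.character(consensus(p)), "TGGCA")

  p2 <- build_pwm(c("AA", "CC"), pseudocount = 0.25)
  expect_equal(unname(p2$probs["A", 1]), 1.25 / 3)
  expect_equal(unname(p2$probs["G", 2]), 0.25 / 3)

  expect_error(build_pwm(c("AA", "AAA")), "equal length")
  expect_error(build_pwm(c("AA", "AX")), "site 2")
})

test_that("PWM built from planted sites recovers the promoter boxes", {
  p <- build_pwm(truth_seed_sites(500, seed0 = 9000))
  cons <- as.character(consensus(p))
  expect_match(cons, "^TGGCACG")
  expect_match(cons, "TTGCT$")
})

test_that("consensus flags ties and resolves them by alphabet order", {
  uni <- pwm_from_probs(matrix(0.25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL)))
  cons <- consensus(uni)
  expect_equal(as.character(cons), "AAA")
  expect_true(all(attr(cons, "tied")))
  det <- build_pwm("TGC", pseudocount = 0)
  expect_equal(as.character(consensus(det)), "TGC")
  expect_false(any(attr(consensus(det), "tied")))
})

test_that("score_window sums per-column log-odds and flags non-scorable windows", {
  probs <- matrix(c(0.5, 0.2, 0.2, 0.1,
                    0.1, 0.4, 0.3, 0.2), 4, 2,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- pwm_from_probs(probs)
  expect_equal(score_window(p, "AC"), log2(0.5 / 0.25) + log2(0.4 / 0.25))
  expect_true(is.na(score_window(p, "AN")))
  # probs equal to background: identically zero scores
  uni <- pwm_from_probs(matrix(0.25, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_equal(score_window(uni, "ACGT"), 0)
  # deterministic PWM on its own consensus attains the column-maxima sum
  det <- build_pwm("TGGC", pseudocount = 0)
  expect_equal(score_window(det, "TGGC"),
               sum(apply(det$log_odds, 2, max, na.rm = TRUE)))
})

test_that("score_pvalue matches exhaustive window enumeration (DNA and protein)", {
  dna <- c("A", "C", "G", "T")
  set.seed(42)
  # brackets allow for the per-column score-grid rounding (w/2 + 1 bins)
  check_bracket <- function(p, sc, w) {
    eps <- (w / 2 + 1) / 100
    for (s in unique(sc)) {
      pv <- score_pvalue(p, s)
      expect_lte(pv, mean(sc >= s - eps) + 1e-9)
      expect_gte(pv, mean(sc >= s + eps) - 1e-9)
    }
  }
  for (w in c(2L, 4L, 6L)) {
    sites <- replicate(25, paste(sample(dna, w, replace = TRUE), collapse = ""))
    p <- build_pwm(sites)
    wins <- apply(expand.grid(rep(list(dna), w)), 1, paste, collapse = "")
    sc <- vapply(wins, function(x) score_window(p, x), numeric(1))
    check_bracket(p, sc, w)
  }
  # identical code path over the 20-letter alphabet
  aa <- rponscan:::AA_ALPHABET
  set.seed(7)
  sites <- replicate(15, paste(sample(aa, 2, replace = TRUE), collapse = ""))
  p <- build_pwm(sites, background = protein_background("uniform"))
  wins <- apply(expand.grid(aa, aa), 1, paste0, collapse = "")
  sc <- vapply(wins, function(x) score_window(p, x), numeric(1))
  check_bracket(p, sc, 2L)
})

test_that("score_pvalue honours its bounds and monotonicity", {
  p <- truth_seed_pwm()
  max_s <- sum(apply(p$log_odds, 2, max))
  min_s <- sum(apply(p$log_odds, 2, min))
  expect_equal(score_pvalue(p, min_s - 1), 1)
  expect_equal(score_pvalue(p, max_s + 1), 0)
  ss <- seq(min_s, max_s, length.out = 50)
  pv <- vapply(ss, function(s) score_pvalue(p, s), numeric(1))
  expect_true(all(diff(pv) <= 1e-12))
})

test_that("EM converges on identical sequences and its likelihood never decreases", {
  seqs <- rep("TGGCACGAATTGCT", 5)
  m <- discover_motif_em(seqs, width = 14, seed = 1)
  expect_equal(as.character(consensus(m[[1]])), "TGGCACGAATTGCT")
  expect_gte(attr(m[[1]], "lambda"), 0.95)
  tr <- attr(m[[1]], "ll_trace")
  expect_true(all(diff(tr) >= -1e-6 * pmax(1, abs(tr[-length(tr)]))))
  expect_error(discover_motif_em("ACGT", width = 2), "at least 2")
})

test_that("EM recovers a planted motif from unaligned regions", {
  spec <- genome_spec(n_genomes = 2, genes_per_genome = 60,
                      promoter_rate = 1.0, rng_seed = 21)
  g <- generate_genome(spec)
  regions <- extract_upstream(g$gene_table, g$sequences, g$truth$tus, 350)
  m <- discover_motif_em(regions$sequence, width = 15, seed = 5)
  expect_match(as.character(consensus(m[[1]])), "TGGCACG")
  tr <- attr(m[[1]], "ll_trace")
  expect_true(all(diff(tr) >= -1e-6 * pmax(1, abs(tr[-length(tr)]))))
  tvd <- mean(colSums(abs(m[[1]]$probs - default_promoter_pwm()$probs)) / 2)
  expect_lt(tvd, 0.12)
})

test_that("EM occurrence prior collapses to zero on pure background", {
  lams <- vapply(1:20, function(s) {
    seqs <- vapply(1:25, function(i) sample_background(150, rng_seed = s * 1000 + i),
                   character(1))
    m <- discover_motif_em(seqs, width = 15, seed = s)
    attr(m[[1]], "lambda")
  }, numeric(1))
  expect_true(all(lams < 0.05))
})

test_that("MEME motif text round-trips PWMs", {
  p <- truth_seed_pwm()
  tmp <- tempfile(fileext = ".meme")
  on.exit(unlink(tmp))
  write_meme(list(p), tmp, names = "seed")
  back <- read_meme(tmp)
  expect_equal(names(back), "seed")
  expect_equal(back$seed$probs, p$probs, tolerance = 1e-5)
  expect_equal(back$seed$background$stationary, p$background$stationary,
               tolerance = 1e-5)
})
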