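test_that("domain pre-filter applies the E-value threshold inclusively", {
  hits <- data.frame(protein_id = sprintf("p%d", 1:5),
                     domain_id = "PF00158",
                     e_value = c(1e-60, 1e-52, 1e-51, 1e-50, 2e-51),
                     score = 100, env_from = 1, env_to = 200,
                     stringsAsFactors = FALSE)
  kept <- filter_by_domain(hits)
  expect_setequal(kept, c("p1", "p2", "p3"))
  expect_length(filter_by_domain(hits, threshold = 1e-61), 0)
  # other domains are ignored
  hits$domain_id[1] <- "PF99999"
  expect_setequal(filter_by_domain(hits), c("p2", "p3"))
})

test_that("greedy clustering follows the best-offset identity definition", {
  s <- c(a = "AAAAAAAAAA", b = "AAAAAGGGGG")
  expect_length(greedy_cluster(s)$representatives, 2)   # identity 0.5
  s2 <- c(a = "AAAAAAAAAA", b = "AAAAAAAGGG")
  expect_length(greedy_cluster(s2)$representatives, 1)  # identity 0.7
  ident <- rep(c(x = "MKLVWATGAD"), 5)
  names(ident) <- sprintf("s%d", 1:5)
  cl <- greedy_cluster(ident)
  expect_length(cl$representatives, 1)
  expect_length(cl$membership, 5)
  # zero shared 3-mers: two clusters without alignment
  s3 <- c(a = "AAAAAAAA", b = "WWWWWWWW")
  expect_length(greedy_cluster(s3)$representatives, 2)
  expect_error(greedy_cluster(c(a = "")), "empty")
  # representative count is non-increasing in the identity threshold
  set.seed(8)
  pool <- vapply(1:12, function(i)
    paste(sample(rponscan:::AA_ALPHABET, 30, TRUE), collapse = ""), character(1))
  names(pool) <- sprintf("q%d", 1:12)
  n_reps <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th)
    length(greedy_cluster(pool, identity_threshold = th)$representatives),
    numeric(1))
  expect_true(all(diff(n_reps) >= 0))
})

test_that("discovered motifs recover the planted EBP motif set", {
  fix <- ebp_fixture()
  truth_cons <- vapply(default_ebp_motifs(), function(m)
    as.character(consensus(m)), character(1))
  found_cons <- vapply(fix$motifs, function(m)
    as.character(consensus(m)), character(1))
  hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  best <- vapply(truth_cons, function(tc)
    min(vapply(found_cons, hamming, numeric(1), a = tc)), numeric(1))
  expect_true(all(best <= 2))
  expect_true(any(grepl("GAFTGA", found_cons, fixed = TRUE)))
})

test_that("scan_protein finds concatenated consensi in increasing positions", {
  motifs <- default_ebp_motifs()
  protein <- paste(vapply(motifs, function(m) as.character(consensus(m)),
                          character(1)), collapse = "")
  sc <- scan_protein(motifs, protein, e_cutoff = 0.1)
  expect_true(all(sc$present))
  expect_true(all(diff(sc$position) > 0))
  expect_equal(sc$position, seq(1, by = 12, length.out = 10))
  # e_cutoff 0 marks everything absent
  sc0 <- scan_protein(motifs, protein, e_cutoff = 0)
  expect_false(any(sc0$present))
  # short protein: all motifs absent
  scs <- scan_protein(motifs, "MKLV", e_cutoff = 0.1)
  expect_false(any(scs$present))
})

test_that("random decoys rarely present all ten motifs", {
  fix <- ebp_fixture()
  prep <- rponscan:::prepare_motif_scan(fix$motifs)
  n_present <- vapply(fix$decoys[1:100], function(p)
    sum(rponscan:::scan_protein_prepared(prep, p, 0.1)$present), numeric(1))
  expect_gte(mean(n_present < 10), 0.95)
})

test_that("classifier verdicts follow the GAFTGA and order rules", {
  motifs <- default_ebp_motifs()
  good <- make_architecture_protein()
  v <- classify_ebp(scan_protein(motifs, good), good)
  expect_equal(v$verdict, "bona_fide")

  # swapping the first two motifs of the architecture breaks the order
  swapped_order <- sigma54_ebp_motif_order
  swapped_order[1:2] <- swapped_order[2:1]
  bad <- make_architecture_protein(order = swapped_order)
  v2 <- classify_ebp(scan_protein(motifs, bad), bad)
  expect_equal(v2$verdict, "rejected")
  expect_equal(v2$reason, "order")

  # mutating GAFTGA -> GAFSGA rejects even with all motifs in order
  mut <- sub("GAFTGA", "GAFSGA", good, fixed = TRUE)
  v3 <- classify_ebp(scan_protein(motifs, mut), mut)
  expect_equal(v3$verdict, "rejected")
  expect_equal(v3$reason, "gaftga")
})

test_that("every synthetic positive classifies bona fide end to end", {
  fix <- ebp_fixture()
  expect_true(all(fix$verdicts$verdict == "bona_fide"))
})

test_that("specificity bookkeeping is exact in degenerate cases", {
  fix <- ebp_fixture()
  one <- evaluate_specificity(fix$motifs, fix$decoys[1],
                              expected_order = fix$expected_order)
  expect_equal(one$specificity_pct, 100)
  # positives mislabelled as decoys: specificity 0
  mis <- evaluate_specificity(fix$motifs, fix$positives,
                              expected_order = fix$expected_order)
  expect_equal(mis$specificity_pct, 0)
  expect_error(evaluate_specificity(fix$motifs, character(0)), "empty")
})

test_that("removing any single motif flips a bona fide verdict", {
  motifs <- default_ebp_motifs()
  for (drop in 1:10) {
    p <- make_architecture_protein(drop = drop)
    v <- classify_ebp(scan_protein(motifs, p), p)
    if (drop == 2) {
      # motif 2 carries GAFTGA: dropping it also removes the hexapeptide
      expect_equal(v$verdict, "rejected")
    } else {
      expect_equal(v$verdict, "rejected")
      expect_true(v$reason %in% c("missing_motif", "order"))
    }
  }
})

test_that("domain hit tables round-trip and report malformed rows", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  hits <- data.frame(protein_id = c("p1", "p2"), domain_id = "PF00158",
                     e_value = c(1e-60, 1e-10), score = c(200, 50),
                     env_from = c(1, 5), env_to = c(180, 120),
                     stringsAsFactors = FALSE)
  write_domtbl(hits, tmp)
  back <- read_domtbl(tmp)
  expect_equal(back$protein_id, hits$protein_id)
  expect_equal(back$e_value, hits$e_value)
  cat("broken row without numbers\n", file = tmp, append = TRUE)
  back2 <- read_domtbl(tmp)
  expect_equal(nrow(back2), 2)
  expect_equal(attr(back2, "parse_report")$n_skipped, 1)
})
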