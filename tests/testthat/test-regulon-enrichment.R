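toy_gene_table <- function(starts, ends, strands) {
  data.frame(genome_id = "g1", gene_id = sprintf("g%02d", seq_along(starts)),
             contig = "c1", start = starts, end = ends, strand = strands,
             COG = NA_character_, class = "t", stringsAsFactors = FALSE)
}

test_that("predict_operons applies the distance and linkage rules", {
  # A-B gap 20 (joined), B-C gap 400 (split)
  gt <- toy_gene_table(c(1, 121, 621), c(100, 200, 800), c("+", "+", "+"))
  tus <- predict_operons(gt)
  expect_equal(length(unique(tus$tu_id)), 2)
  expect_setequal(tus$gene_id[tus$tu_id == tus$tu_id[1]], c("g01", "g02"))

  # opposite strands never join
  gt2 <- toy_gene_table(c(1, 121), c(100, 200), c("+", "-"))
  expect_equal(length(unique(predict_operons(gt2)$tu_id)), 2)

  # linkage rescues a 100-nt gap (<= 4 * 45) when the pair score passes
  gt3 <- toy_gene_table(c(1, 201), c(100, 300), c("+", "+"))
  links <- data.frame(gene1 = "g01", gene2 = "g02", score = 0.9)
  expect_equal(length(unique(predict_operons(gt3, link_scores = links)$tu_id)), 1)
  expect_equal(length(unique(predict_operons(gt3)$tu_id)), 2)

  # overlapping genes count as distance 0
  gt4 <- toy_gene_table(c(1, 90), c(100, 200), c("+", "+"))
  expect_equal(length(unique(predict_operons(gt4)$tu_id)), 1)
})

test_that("predicted operons reproduce the generator's planted partition", {
  g <- small_genome()
  pred <- predict_operons(g$gene_table)
  part <- function(t) sort(vapply(split(t$gene_id, t$tu_id),
                                  function(x) paste(sort(x), collapse = ","),
                                  character(1)))
  expect_identical(unname(part(pred)), unname(part(g$truth$tus)))
  # leaders agree too
  leaders <- function(t) sort(t$gene_id[t$tu_order == 1])
  expect_identical(leaders(pred), leaders(g$truth$tus))
})

test_that("expand_regulon unions operon members and validates tu ids", {
  tus <- data.frame(tu_id = c("t1", "t1", "t1", "t2"),
                    gene_id = c("a", "b", "c", "d"), tu_order = c(1, 2, 3, 1))
  hits <- data.frame(tu_id = "t1")
  expect_setequal(expand_regulon(hits, tus), c("a", "b", "c"))
  expect_length(expand_regulon(hits[0, , drop = FALSE], tus), 0)
  expect_error(expand_regulon(data.frame(tu_id = "zz"), tus), "zz")
})

test_that("hypergeom_upper_tail matches combinatorial enumeration", {
  # printed example: N=10, K=4, n=5, k=3
  expect_equal(hypergeom_upper_tail(10, 4, 5, 3), 66 / 252)
  expect_equal(hypergeom_upper_tail(10, 4, 5, 0), 1)
  expect_equal(hypergeom_upper_tail(8, 8, 8, 8), 1)
  expect_error(hypergeom_upper_tail(10, 11, 5, 3), "exceed")
  expect_error(hypergeom_upper_tail(10, 4, 5, 5), "exceed")
  # swap-duality
  expect_equal(hypergeom_upper_tail(30, 7, 12, 4), hypergeom_upper_tail(30, 12, 7, 4))
})

test_that("enrichment ranks planted (class, COG) pairs first", {
  mkspecs <- function(seed) list(
    genome_spec(n_genomes = 2, genes_per_genome = 100, class_label = "classA",
                promoter_rate = 0.3, rng_seed = seed),
    genome_spec(n_genomes = 2, genes_per_genome = 100, class_label = "classB",
                promoter_rate = 0.3, rng_seed = seed + 1))
  col <- generate_class_collection(mkspecs(70), list(classA = "COG0007"))
  reg <- split(col$truth$regulated_genes,
               col$gene_table$class[match(col$truth$regulated_genes,
                                          col$gene_table$gene_id)])
  enr <- enrich_classes(col$gene_table, reg)
  expect_equal(enr$class[1], "classA")
  expect_equal(enr$cog[1], "COG0007")
  expect_true(all(enr$p_bh >= enr$p_value - 1e-15))
  # class with no regulated genes is skipped
  reg0 <- list(classA = reg$classA, classB = character(0))
  enr0 <- enrich_classes(col$gene_table, reg0)
  expect_false("classB" %in% enr0$class)
})

test_that("null enrichment p-values are uniform after randomised PIT", {
  specs <- list(
    genome_spec(n_genomes = 2, genes_per_genome = 120, class_label = "cA",
                promoter_rate = 0.3, rng_seed = 201),
    genome_spec(n_genomes = 2, genes_per_genome = 120, class_label = "cB",
                promoter_rate = 0.3, rng_seed = 202))
  pits <- c()
  for (rep in 1:3) {
    sp <- lapply(specs, function(s) { s$rng_seed <- s$rng_seed + rep * 10L; s })
    col <- generate_class_collection(sp, list())
    reg <- split(col$truth$regulated_genes,
                 col$gene_table$class[match(col$truth$regulated_genes,
                                            col$gene_table$gene_id)])
    enr <- enrich_classes(col$gene_table, reg, keep_all = TRUE)
    p_next <- mapply(function(N, K, n, k)
      if (k + 1 > min(K, n)) 0 else hypergeom_upper_tail(N, K, n, k + 1),
      enr$N, enr$K, enr$n, enr$k)
    set.seed(300 + rep)
    pits <- c(pits, p_next + stats::runif(nrow(enr)) * (enr$p_value - p_next))
  }
  expect_gt(stats::ks.test(pits, "punif")$p.value, 0.01)
})
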