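toy_genes <- function() {
  data.frame(chrom = c("1", "1", "2"),
             start = c(1000L, 30000L, 500L),
             end = c(2000L, 40000L, 600L),
             strand = c("+", "-", "+"),
             gene_id = c("g1", "g2", "g3"),
             symbol = c("ALPHA", "BETA", "GAMMA"),
             stringsAsFactors = FALSE)
}

test_that("nearest-gene mapping handles containment, ties and absence", {
  genes <- toy_genes()
  snps <- data.frame(rsid = c("in_body", "tie", "far_chrom"),
                     chrom = c("1", "1", "7"),
                     pos = c(1500L, 12000L, 100L), stringsAsFactors = FALSE)
  expect_warning(out <- nearest_gene(snps, genes), "without genes")
  expect_equal(out$gene[1], "ALPHA")
  expect_equal(out$distance[1], 0)
  # pos 12000: 10 kb from ALPHA's end and 18 kb from BETA's start
  expect_equal(out$gene[2], "ALPHA")
  expect_equal(out$distance[2], 10000)
  expect_true(is.na(out$gene[3]))

  # exact equidistance resolves by distance-to-start, then symbol
  g2 <- genes
  g2$start <- c(1000L, 22000L, 500L)
  g2$end <- c(2000L, 40000L, 600L)
  snp_tie <- data.frame(rsid = "t", chrom = "1", pos = 12000L)
  out_tie1 <- nearest_gene(snp_tie, g2)
  out_tie2 <- nearest_gene(snp_tie, g2)
  expect_identical(out_tie1, out_tie2)
  # both genes are 10 kb away; BETA's start (22000) is 10 kb from the SNP,
  # ALPHA's start (1000) is 11 kb, so BETA wins the start tie-break
  expect_equal(out_tie1$gene, "BETA")
})

test_that("nearest-gene matches the exhaustive-scan oracle", {
  cfg <- simulation_config(seed = 41, n_genes = 50, chrom_length = 1e7,
                           n_snps = 50, n_blocks = 5)
  genes <- simulate_gene_annotation(cfg)
  set.seed(17)
  snps <- data.frame(rsid = sprintf("s%02d", 1:50), chrom = "1",
                     pos = sample.int(1e7, 50), stringsAsFactors = FALSE)
  got <- nearest_gene(snps, genes)
  want <- vapply(seq_len(50), function(i)
    brute_nearest(snps$pos[i], snps$chrom[i], genes), character(1))
  expect_equal(got$gene, want)
})

test_that("immune overlap flags exactly the listed genes", {
  genes <- toy_genes()
  snps <- data.frame(rsid = c("a", "b"), chrom = "1",
                     pos = c(1500L, 35000L), stringsAsFactors = FALSE)
  near <- nearest_gene(snps, genes)
  none <- immune_overlap(near, gene_set("empty", members = character()))
  expect_false(any(none$immune))
  all_in <- immune_overlap(near, gene_set("all", members = c("alpha", "beta")))
  expect_true(all(all_in$immune)) # case-insensitive join
  some <- immune_overlap(near, gene_set("some", members = "BETA"))
  expect_equal(some$immune, c(FALSE, TRUE))
})

test_that("hypergeometric enrichment is exact", {
  sets <- list(gene_set("perfect", members = paste0("Q", 1:5),
                        database = "db"))
  res <- hypergeom_enrich(paste0("Q", 1:5), sets, universe_size = 20)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$k, 5)
  expect_equal(res$driver_genes, "Q1,Q2,Q3,Q4,Q5")

  # k = 0 and K = 0 give p = 1
  res0 <- hypergeom_enrich("Q1", list(gene_set("empty", members = character(),
                                               database = "db")),
                           universe_size = 20)
  expect_equal(res0$p, 1)

  # tail summation vs the complement-CDF oracle on random instances
  set.seed(23)
  for (i in 1:100) {
    N <- sample(20:200, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    k <- sample(0:min(K, n), 1)
    got <- pleioscan:::hyper_tail(k, K, n, N)
    want <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(got, want, tolerance = 1e-12)
  }

  # p non-increasing in k; full tail sums to 1
  ps <- vapply(0:5, pleioscan:::hyper_tail, numeric(1), K = 5, n = 10, N = 30)
  expect_true(all(diff(ps) <= 1e-15))
  expect_equal(sum(dhyper(0:5, 5, 25, 10)), 1, tolerance = 1e-12)

  expect_error(pleioscan:::hyper_tail(6, 5, 10, 30), "exceeds")
  expect_error(hypergeom_enrich(character(), sets, 20), "empty query")
})

test_that("BH adjustment and ranking order the result table", {
  sets <- list(gene_set("s1", members = paste0("Q", 1:5), database = "d1"),
               gene_set("s2", members = c("Q1", paste0("X", 1:9)),
                        database = "d1"),
               gene_set("s3", members = paste0("X", 10:14), database = "d2"))
  res <- hypergeom_enrich(paste0("Q", 1:5), sets, universe_size = 50)
  expect_equal(res$set_name[1], "s1")
  expect_true(all(diff(res$p) >= 0))
  expect_equal(res$p_adj, p.adjust(res$p, "BH")[order(res$p)],
               tolerance = 1e-12)
})

test_that("immune-pathway selection unions driver genes of keyword hits", {
  res <- data.frame(
    set_name = c("T-cell receptor signaling", "Lipid metabolism",
                 "Interferon response", "DNA repair"),
    database = c("d1", "d1", "d2", "d2"),
    k = 2, K = 10, n = 5, N = 100,
    p = c(1e-5, 1e-4, 1e-3, 1e-2),
    p_adj = NA_real_,
    driver_genes = c("G1,G2", "G3", "G2,G4", "G5"),
    stringsAsFactors = FALSE)
  got <- select_immune_pathway_genes(res)
  expect_equal(got, c("G1", "G2", "G4"))

  # no keyword hits -> empty
  none <- select_immune_pathway_genes(res, keywords = "zzz")
  expect_equal(none, character(0))

  # top_n cuts before keyword matching
  cut <- select_immune_pathway_genes(res, top_n = 1)
  expect_equal(cut, c("G1", "G2", "G4"))

  res$database <- NA_character_
  expect_error(select_immune_pathway_genes(res), "database")
})

test_that("GMT files round-trip and validate", {
  sets <- list(gene_set("a", "descr", c("G1", "G2"), database = "db"),
               gene_set("b", "x", "G3", database = "db"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f, database = "db")
  expect_equal(back, sets)
  writeLines("name_only\tdesc", f)
  expect_error(read_gmt(f), "malformed")
})

test_that("synthetic gene sets feed the enrichment end to end", {
  cfg <- simulation_config(seed = 44, n_genes = 120)
  genes <- simulate_gene_annotation(cfg)
  driven <- genes$symbol[1:5]
  gs <- simulate_gene_sets(genes, immune_genes = driven,
                           driven_genes = driven, seed = 44)
  res <- hypergeom_enrich(driven, gs$pathways, universe = genes$symbol)
  picked <- select_immune_pathway_genes(res)
  expect_true(all(driven %in% picked))
})
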