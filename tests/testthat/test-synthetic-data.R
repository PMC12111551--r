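test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_snps = 0), "positive")
  expect_error(simulation_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulation_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(simulation_config(block_rho = 1), "block_rho")
  expect_error(simulation_config(infiltration_loading = 1.2),
               "infiltration_loading")
  expect_error(planted_effect(1, "opposite", 0.1, 0.1), "inconsistent")
  expect_error(planted_effect(1, "null", 0.1, 0), "inconsistent")
  expect_error(planted_effect(1, "concordant", 0.1, -0.1), "inconsistent")
  expect_error(
    simulation_config(n_snps = 10, n_blocks = 2,
                      planted_effects = list(planted_effect(11, "null"))),
    "out of range")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 3, n_snps = 60, n_blocks = 6,
                           planted_effects = list(
                             planted_effect(5, "opposite", 0.1, -0.1)))
  g1 <- simulate_ld_genotypes(cfg, n_individuals = 200)
  g2 <- simulate_ld_genotypes(cfg, n_individuals = 200)
  expect_identical(g1, g2)
  s1 <- simulate_pair_sumstats(g1$genotypes, g1$snp_map, cfg)
  s2 <- simulate_pair_sumstats(g2$genotypes, g2$snp_map, cfg)
  expect_identical(s1, s2)
  e1 <- simulate_expression(cfg, "G001", "G002")
  e2 <- simulate_expression(cfg, "G001", "G002")
  expect_identical(e1, e2)
  expect_identical(simulate_snp_map(cfg), g1$snp_map)
})

test_that("genotypes respect the configured LD structure", {
  # independence case: block_rho = 0
  cfg0 <- simulation_config(seed = 2, n_snps = 20, n_blocks = 2,
                            block_rho = 0)
  g0 <- simulate_ld_genotypes(cfg0, n_individuals = 2000)
  r0 <- cor(g0$genotypes)
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.1)

  # adjacent-pair correlation matches block_rho^2 at large n
  cfg <- simulation_config(seed = 2, n_snps = 6, n_blocks = 1,
                           block_rho = 0.9, maf_range = c(0.3, 0.3))
  g <- simulate_ld_genotypes(cfg, n_individuals = 1e5)
  r2_adj <- cor(g$genotypes[, 1], g$genotypes[, 2])^2
  expect_equal(r2_adj, 0.81, tolerance = 0.02)
  # decay: distance-2 correlation ~ rho^2
  r2_d2 <- cor(g$genotypes[, 1], g$genotypes[, 3])^2
  expect_equal(r2_d2, 0.9^4, tolerance = 0.03)

  # cross-block independence
  cfg2 <- simulation_config(seed = 4, n_snps = 20, n_blocks = 2,
                            block_rho = 0.9)
  g2 <- simulate_ld_genotypes(cfg2, n_individuals = 5000)
  cross <- cor(g2$genotypes[, 1:10], g2$genotypes[, 11:20])
  expect_lt(max(abs(cross)), 0.08)

  expect_true(all(g$genotypes %in% 0:2))
  expect_true(all(diff(g$snp_map$pos) > 0))
})

test_that("empirical allele frequencies track the configured MAFs", {
  cfg <- simulation_config(seed = 6, n_snps = 100, n_blocks = 10)
  n <- 5000
  g <- simulate_ld_genotypes(cfg, n_individuals = n)
  freq <- colMeans(g$genotypes) / 2
  sd3 <- 3 * sqrt(g$snp_map$maf * (1 - g$snp_map$maf) / (2 * n))
  # a ~0.3% exceedance rate is expected for a 3-SD band
  expect_gt(mean(abs(freq - g$snp_map$maf) <= sd3), 0.98)
})

test_that("analytic mode reproduces the stated standard-error formula", {
  cfg <- simulation_config(seed = 8, n_snps = 50, n_blocks = 5,
                           n_cases_a = 30000, n_controls_a = 70000)
  g <- simulate_ld_genotypes(cfg, n_individuals = 500)
  ss <- simulate_pair_sumstats(g$genotypes, g$snp_map, cfg)
  neff <- 4 / (1 / 30000 + 1 / 70000)
  expect_equal(ss$a$se, 1 / sqrt(2 * neff * ss$a$eaf * (1 - ss$a$eaf)),
               tolerance = 1e-12)
})

test_that("null SNPs show nominal type-I error and planted opposite SNPs
          are powered at the per-trait threshold", {
  cfg <- simulation_config(seed = 9, n_snps = 2000, n_blocks = 2000)
  sm <- simulate_snp_map(cfg)
  ss <- simulate_pair_sumstats(NULL, sm, cfg)
  expect_lt(abs(mean(ss$a$p < 0.05) - 0.05), 0.02)
  expect_lt(abs(mean(ss$b$p < 0.05) - 0.05), 0.02)

  pe <- lapply(1:200, function(i) planted_effect(i, "opposite", 0.15, -0.15))
  cfgp <- simulation_config(seed = 10, n_snps = 200, n_blocks = 200,
                            planted_effects = pe)
  smp <- simulate_snp_map(cfgp)
  ssp <- simulate_pair_sumstats(NULL, smp, cfgp)
  expect_gt(mean(ssp$a$p < 1e-3 & ssp$b$p < 1e-3), 0.95)
})

test_that("phenotype-simulation mode recovers a planted effect", {
  cfg <- simulation_config(seed = 12, n_snps = 30, n_blocks = 30,
                           n_cases_a = 2500, n_controls_a = 2500,
                           n_cases_b = 2500, n_controls_b = 2500,
                           planted_effects = list(
                             planted_effect(1, "opposite", 0.6, -0.6)))
  g <- simulate_ld_genotypes(cfg, n_individuals = 5000)
  ss <- simulate_pair_sumstats(g$genotypes, g$snp_map, cfg,
                               mode = "phenotype")
  expect_lt(ss$a$p[1], 1e-4)
  expect_lt(ss$b$p[1], 1e-4)
  expect_gt(ss$a$beta[1], 0)
  expect_lt(ss$b$beta[1], 0)
  # null SNPs stay unremarkable
  expect_gt(min(ss$a$p[-1]), 1e-5)
})

test_that("a planted effect on a monomorphic SNP is a generation error", {
  cfg <- simulation_config(seed = 13, n_snps = 10, n_blocks = 1,
                           planted_effects = list(
                             planted_effect(3, "a_only", 0.2, 0)))
  g <- simulate_ld_genotypes(cfg, n_individuals = 100)
  g$genotypes[, 3] <- 0L
  expect_error(simulate_pair_sumstats(g$genotypes, g$snp_map, cfg),
               "monomorphic")
})

test_that("expression rows are Z-scored and driven by the latent factor", {
  cfg <- simulation_config(seed = 14, n_genes = 40, n_samples_expr = 300,
                           n_cohorts = 2, infiltration_loading = 0.9)
  ex <- simulate_expression(cfg, driven_genes = "G001",
                            marker_genes = "G002")
  for (m in ex) {
    expect_equal(unname(rowMeans(m)), rep(0, nrow(m)), tolerance = 1e-9)
    expect_equal(unname(apply(m, 1, sd)), rep(1, nrow(m)), tolerance = 1e-9)
    expect_gt(spearman_rho(m["G001", ], m["G002", ]), 0.5)
  }

  cfg0 <- simulation_config(seed = 14, n_genes = 40, n_samples_expr = 300,
                            n_cohorts = 2, infiltration_loading = 0)
  ex0 <- simulate_expression(cfg0, driven_genes = "G001",
                             marker_genes = "G002")
  rhos <- vapply(ex0, function(m) spearman_rho(m["G001", ], m["G002", ]),
                 numeric(1))
  expect_lt(max(abs(rhos)), 0.3)
  cells <- correlation_matrix("G001", "G002", ex0)
  expect_false(any(prioritize_genes(cells)$prioritized))

  expect_error(simulate_expression(cfg, "not_a_gene", "G002"), "universe")
})
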