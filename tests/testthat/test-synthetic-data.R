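test_that("genotype simulation is seed-deterministic and respects the LD layout", {
  cfg <- sim_config(seed = 9, scenario = "H1", n_exposure = 2000,
                    n_outcome = 2000, n_blocks = 2, block_size = 10)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$exposure, s2$exposure)
  expect_identical(s1$outcome, s2$outcome)
  expect_identical(s1$ld, s2$ld)

  set.seed(1)
  g0 <- simulate_genotypes(5000, 1, 30, rho = 0)
  off <- g0$ld[upper.tri(g0$ld)]
  expect_lt(mean(abs(off)), 0.05)

  set.seed(2)
  g9 <- simulate_genotypes(5000, 1, 30, rho = 0.9)
  # adjacent r^2 decays with SNP distance (monotone trend on average)
  mean_r2_at <- vapply(1:6, function(d) {
    i <- seq_len(30 - d)
    mean(g9$ld[cbind(i, i + d)]^2)
  }, numeric(1))
  expect_true(all(diff(mean_r2_at) < 0))
  expect_error(simulate_genotypes(100, 2, 1, rho = 0), "block_size")
})

test_that("null GWAS p-values are uniform and a strong causal SNP is powered", {
  set.seed(3)
  g <- simulate_genotypes(2000, 250, 40, rho = 0)     # 10000 SNPs
  stats0 <- simulate_trait_gwas(g, numeric(10000))
  expect_gt(mean(stats0$pvalue < 0.05), 0.04)
  expect_lt(mean(stats0$pvalue < 0.05), 0.06)

  # single causal SNP at 1% variance explained, n = 50000
  hits <- vapply(1:60, function(i) {
    set.seed(100 + i)
    g <- simulate_genotypes(50000, 1, 2, rho = 0)
    eff <- c(pwmr:::effect_for_ve(0.01, g$mafs[1]), 0)
    simulate_trait_gwas(g, eff)$pvalue[1] < 5e-8
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the marginal beta at a causal SNP is unbiased for its true effect", {
  set.seed(4)
  betas <- replicate(80, {
    g <- simulate_genotypes(8000, 1, 2, rho = 0)
    eff <- c(pwmr:::effect_for_ve(0.01, g$mafs[1]), 0)
    simulate_trait_gwas(g, eff)$beta[1] / eff[1]
  })
  expect_equal(mean(betas), 1, tolerance = 0.05)
  expect_error(
    simulate_trait_gwas(simulate_genotypes(500, 1, 2, rho = 0), c(10, 0)),
    "heritability")
})

test_that("scenario ground truth is consistent and round-trips through files", {
  cfg <- sim_config(seed = 11, scenario = "H4", n_exposure = 3000,
                    n_outcome = 3000, n_blocks = 1, block_size = 20)
  sim <- simulate_scenario(cfg)
  expect_identical(sim$truth$causal_snps$exposure, sim$truth$causal_snps$outcome)
  expect_equal(sim$truth$true_causal_effect, 0.5)

  med <- simulate_scenario(sim_config(
    seed = 12, scenario = "mediation_chain", n_exposure = 3000,
    n_outcome = 3000, n_riskfactor = 3000, n_blocks = 11, block_size = 8,
    true_effects = list(rf_instruments = 10)))
  expect_equal(med$truth$true_c_prime, 0.2)
  expect_equal(med$truth$true_proportion, 0.3)
  expect_equal(nrow(med$riskfactor), 88L)

  dir <- tempfile("scenario")
  write_scenario(sim, dir)
  back <- load_scenario(dir)
  expect_equal(back$exposure, sim$exposure)
  expect_equal(back$outcome, sim$outcome)
  expect_equal(back$ld, sim$ld, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "truth", "truth.json")))
})

test_that("analysis loaders refuse to read from a truth directory", {
  sim <- simulate_scenario(sim_config(seed = 13, scenario = "H0",
                                      n_exposure = 500, n_outcome = 500,
                                      n_blocks = 1, block_size = 5))
  dir <- tempfile("scenario")
  write_scenario(sim, dir)
  expect_error(load_scenario(file.path(dir, "truth")), "truth")
})

test_that("H3 places distinct causal variants and null_mr has no outcome signal", {
  h3 <- simulate_scenario(sim_config(seed = 14, scenario = "H3",
                                     n_exposure = 2000, n_outcome = 2000,
                                     n_blocks = 1, block_size = 20))
  expect_false(h3$truth$causal_snps$exposure == h3$truth$causal_snps$outcome)

  nm <- simulate_scenario(sim_config(seed = 15, scenario = "null_mr",
                                     n_exposure = 2000, n_outcome = 2000,
                                     n_blocks = 5, block_size = 4))
  expect_equal(nm$truth$true_causal_effect, 0)
  expect_equal(length(nm$truth$causal_snps$exposure), 5L)
  expect_equal(sum(nm$truth$per_snp_effects$outcome), 0)
})
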