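test_that("SMR statistic combines the two z-scores as expected", {
  # z_gx = z_gy = 2: T = 2, p = upper chi-square(1) tail at 2
  pr <- make_pairs(beta_gx = 0.2, beta_gy = 0.1, se_gx = 0.1, se_gy = 0.05)
  res <- smr_test(pr)
  expect_equal(res$b_smr, 0.5)
  expect_equal(res$p_smr, 0.15729920705028513, tolerance = 1e-10)
  expect_equal(res$se_smr, 0.5 / sqrt(2))

  # strong-instrument limit: T -> z_gy^2
  strong <- make_pairs(beta_gx = 1, beta_gy = 0.06, se_gx = 1e-6, se_gy = 0.02)
  expect_equal(smr_test(strong)$p_smr, pchisq(3^2, 1, lower.tail = FALSE),
               tolerance = 1e-6)

  # null outcome: T = 0, p = 1
  null <- make_pairs(beta_gx = 0.2, beta_gy = 0, se_gx = 0.02, se_gy = 0.02)
  expect_equal(smr_test(null)$p_smr, 1)
  expect_error(smr_test(make_pairs(beta_gx = 0, beta_gy = 0.1)), "beta_gx")
})

test_that("SMR p-value never beats the weaker marginal association", {
  set.seed(31)
  for (i in 1:20) {
    pr <- make_pairs(beta_gx = runif(1, 0.05, 0.3), beta_gy = rnorm(1, 0, 0.05),
                     se_gx = runif(1, 0.005, 0.05), se_gy = runif(1, 0.005, 0.05))
    res <- smr_test(pr)
    p_gx <- pchisq((pr$beta_gx / pr$se_gx)^2, 1, lower.tail = FALSE)
    p_gy <- pchisq((pr$beta_gy / pr$se_gy)^2, 1, lower.tail = FALSE)
    expect_gte(res$p_smr + 1e-12, max(p_gx, p_gy))
  }
})

test_that("chi-square mixture tail matches the plain chi-square for equal weights", {
  for (q in c(0.5, 2, 5, 12)) {
    expect_equal(pchisq_mixture(q, rep(1, 6)),
                 pchisq(q, 6, lower.tail = FALSE), tolerance = 1e-6)
  }
  # Monte-Carlo oracle for genuinely unequal weights
  set.seed(32)
  lambda <- c(2.5, 1.2, 0.6, 0.1)
  draws <- colSums(lambda * matrix(rchisq(4 * 2e5, df = 1), 4))
  for (q in c(2, 6, 12)) {
    expect_lt(abs(pchisq_mixture(q, lambda) - mean(draws > q)), 5e-3)
  }
})

test_that("HEIDI returns NA with fewer than three eligible SNPs", {
  pr <- make_pairs(beta_gx = c(0.3, 0.25), beta_gy = c(0.09, 0.075),
                   se_gx = 0.01, se_gy = 0.01, snp_id = c("top", "s2"))
  pr$chrom <- "1"; pr$pos <- c(100L, 200L)
  ld <- make_ld(c("top", "s2"), data.frame(i = "top", j = "s2", r = 0.6))
  res <- heidi_test(pr, ld, "top")
  expect_true(is.na(res$heidi_p))
  expect_lt(res$n_used, 3)
  expect_error(heidi_test(pr, ld, "absent"), "top_snp")
})

test_that("HEIDI is invariant to the ordering of non-top SNPs", {
  set.seed(33)
  sim <- simulate_scenario(sim_config(seed = 5, scenario = "H4",
                                      n_exposure = 8000, n_outcome = 8000,
                                      n_blocks = 1, block_size = 30,
                                      true_effects = list(ve_exposure = 0.05)))
  pr <- harmonize(sim$exposure, sim$outcome)
  top <- pr$snp_id[which.min(pr$pvalue_gx)]
  a <- heidi_test(pr, sim$ld, top)
  idx <- c(which(pr$snp_id == top), sample(which(pr$snp_id != top)))
  b <- heidi_test(pr[idx, ], sim$ld, top)
  expect_equal(a$heidi_p, b$heidi_p, tolerance = 1e-12)
  expect_setequal(a$snp_ids, b$snp_ids)
})
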