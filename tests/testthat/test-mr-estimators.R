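test_that("Wald ratio arithmetic, null case and sign symmetry", {
  p <- make_pairs(beta_gx = 0.2, beta_gy = 0.1, se_gy = 0.05)
  w <- wald_ratio(p)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.25)
  expect_equal(w$ci_low, 0.5 - qnorm(0.975) * 0.25)

  p0 <- make_pairs(beta_gx = 0.2, beta_gy = 0)
  w0 <- wald_ratio(p0)
  expect_equal(w0$beta, 0)
  expect_equal(w0$pvalue, 1)

  pneg <- p; pneg$beta_gx <- -p$beta_gx
  wneg <- wald_ratio(pneg)
  expect_equal(wneg$beta, -w$beta)
  expect_equal(wneg$se, w$se)

  expect_error(wald_ratio(make_pairs(beta_gx = 0, beta_gy = 0.1)), "beta_gx")
})

test_that("IVW with one instrument equals the Wald ratio to machine precision", {
  p <- make_pairs(beta_gx = 0.13, beta_gy = 0.04, se_gy = 0.018)
  for (m in c("fixed", "random")) {
    est <- ivw(p, model = m)
    w <- wald_ratio(p)
    expect_identical(est$beta, w$beta)
    expect_identical(est$se, w$se)
    expect_identical(est$pvalue, w$pvalue)
  }
  expect_error(ivw(make_pairs(0.1, 0.1)[0, ]), "no instruments")
})

test_that("IVW pools duplicated evidence and matches the WLS-through-origin oracle", {
  p1 <- make_pairs(beta_gx = 0.2, beta_gy = 0.08, se_gy = 0.02)
  p2 <- rbind(p1, p1)
  e1 <- ivw(p1, model = "fixed")
  e2 <- ivw(p2, model = "fixed")
  expect_equal(e2$beta, e1$beta)
  expect_equal(e2$se, e1$se / sqrt(2))

  set.seed(11)
  pr <- make_pairs(beta_gx = runif(5, 0.05, 0.3),
                   beta_gy = rnorm(5, 0.05, 0.03),
                   se_gy = runif(5, 0.01, 0.05))
  est <- ivw(pr, model = "fixed")
  fit <- lm(beta_gy ~ 0 + beta_gx, data = pr, weights = 1 / pr$se_gy^2)
  expect_equal(est$beta, unname(coef(fit)["beta_gx"]), tolerance = 1e-12)
})

test_that("multiplicative random-effects IVW never shrinks the standard error", {
  set.seed(12)
  for (i in 1:10) {
    pr <- make_pairs(beta_gx = runif(6, 0.05, 0.3),
                     beta_gy = rnorm(6, 0.02, 0.05),
                     se_gy = runif(6, 0.01, 0.05))
    f <- ivw(pr, model = "fixed")
    r <- ivw(pr, model = "random")
    expect_equal(r$beta, f$beta)
    expect_gte(r$se, f$se)
    q <- cochran_q(pr)
    if (q$q_stat <= nrow(pr) - 1) expect_equal(r$se, f$se)
  }
})

test_that("Cochran's Q matches hand computation, is permutation-invariant, zero when homogeneous", {
  pr <- make_pairs(beta_gx = c(1, 1), beta_gy = c(0.1, 0.3), se_gy = c(0.1, 0.1))
  q <- cochran_q(pr)
  w <- 1 / 0.1^2
  bhat <- (w * 0.1 + w * 0.3) / (2 * w)
  expect_equal(q$q_stat, w * (0.1 - bhat)^2 + w * (0.3 - bhat)^2)
  expect_equal(q$q_pvalue, pchisq(q$q_stat, 1, lower.tail = FALSE))

  set.seed(13)
  pr2 <- make_pairs(beta_gx = runif(7, 0.1, 0.3), beta_gy = rnorm(7, 0, 0.05),
                    se_gy = runif(7, 0.01, 0.05))
  expect_equal(cochran_q(pr2)$q_stat, cochran_q(pr2[sample(7), ])$q_stat)

  prh <- make_pairs(beta_gx = c(0.1, 0.2, 0.4), beta_gy = c(0.05, 0.1, 0.2),
                    se_gy = c(0.02, 0.03, 0.01))
  expect_lt(cochran_q(prh)$q_stat, 1e-9)
  expect_error(cochran_q(pr[1, ]), "at least 2")
})

test_that("Egger: exact line through origin gives zero intercept; planted pleiotropy recovered", {
  pr <- make_pairs(beta_gx = c(0.1, 0.2, 0.3, 0.4),
                   beta_gy = 0.5 * c(0.1, 0.2, 0.3, 0.4),
                   se_gy = 0.02)
  eg <- suppressWarnings(mr_egger(pr))   # exact fit: lm warns about summaries
  expect_equal(eg$intercept, 0, tolerance = 1e-12)
  expect_equal(eg$slope$beta, 0.5, tolerance = 1e-12)
  expect_error(mr_egger(pr[1:2, ]), "at least 3")

  # constant directional pleiotropy delta shifts the intercept estimate to delta
  set.seed(14)
  delta <- 0.04
  ints <- replicate(200, {
    a <- runif(25, 0.05, 0.3)
    se <- runif(25, 0.01, 0.03)
    pr <- make_pairs(beta_gx = a, beta_gy = delta + 0.3 * a + rnorm(25, 0, se),
                     se_gy = se)
    mr_egger(pr)$intercept
  })
  expect_equal(mean(ints), delta, tolerance = 0.005)
})

test_that("MR-PRESSO is seed-deterministic and flags a grossly displaced instrument", {
  set.seed(15)
  a <- runif(20, 0.05, 0.3)
  se <- rep(0.02, 20)
  pr <- make_pairs(beta_gx = a, beta_gy = 0.3 * a + rnorm(20, 0, se), se_gy = se)
  r1 <- mr_presso(pr, n_sim = 300, seed = 77)
  r2 <- mr_presso(pr, n_sim = 300, seed = 77)
  expect_identical(r1, r2)
  expect_gt(r1$global_pvalue, 0.05)

  bad <- pr
  bad$beta_gy[7] <- bad$beta_gy[7] + 10 * bad$se_gy[7]
  r3 <- mr_presso(bad, n_sim = 500, seed = 78)
  expect_true("rs7" %in% r3$outlier_ids)
  expect_lt(r3$global_pvalue, 0.05)
  expect_error(mr_presso(pr[1:3, ], seed = 1), "at least 4")
  expect_error(mr_presso(pr), "seed")
})

test_that("Steiger: symmetric case, strong asymmetry, antisymmetry under trait exchange", {
  # equal variance explained on both sides: z = 0, tie is not 'correct'
  pr <- make_pairs(beta_gx = 0.1, beta_gy = 0.1, eaf = 0.3)
  s <- steiger(pr, n_gx = 10000, n_gy = 10000)
  expect_equal(s$z, 0)
  expect_equal(s$steiger_pvalue, 1)
  expect_false(s$correct_direction)

  # r_x = 0.1 vs r_y = 0.01 at n = 100000: decisive
  mk <- function(rx, ry) {
    b_x <- sqrt(rx^2 / (2 * 0.3 * 0.7))
    b_y <- sqrt(ry^2 / (2 * 0.3 * 0.7))
    make_pairs(beta_gx = b_x, beta_gy = b_y, eaf = 0.3,
               n_gx = 100000, n_gy = 100000)
  }
  s2 <- steiger(mk(0.1, 0.01))
  expect_true(s2$correct_direction)
  expect_lt(s2$steiger_pvalue, 1e-10)
  expect_equal(s2$r_x, 0.1, tolerance = 1e-12)

  # exchanging exposure and outcome negates z exactly
  pr3 <- mk(0.08, 0.03)
  sw <- pr3
  sw[, c("beta_gx", "beta_gy")] <- sw[, c("beta_gy", "beta_gx")]
  sw[, c("se_gx", "se_gy")] <- sw[, c("se_gy", "se_gx")]
  expect_equal(steiger(sw)$z, -steiger(pr3)$z)

  expect_error(steiger(make_pairs(beta_gx = 1.5, beta_gy = 0.1, eaf = 0.5)),
               "standardized")
})

test_that("BH adjustment matches examples and never lowers a p-value", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")

  set.seed(16)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
})
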