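test_that("log ABF matches the closed form and its limits", {
  # independent hand computation of the shrinkage form
  beta <- 0.1; se <- 0.02; sd0 <- 0.15
  r <- sd0^2 / (sd0^2 + se^2)
  expect_equal(log_abf(beta, se, sd0), 0.5 * (log(1 - r) + r * (beta / se)^2))

  # z = 0: strictly negative
  expect_lt(log_abf(0, 0.02, 0.15), 0)
  # no-information limit: se -> Inf gives log ABF -> 0
  expect_equal(log_abf(0.1, 1e6, 0.15), 0, tolerance = 1e-8)
  expect_error(log_abf(0.1, 0), "positive")
})

test_that("posteriors sum to one, are permutation-invariant, and monotone in p12", {
  set.seed(21)
  d1 <- make_ss(n = 40, snp_id = sprintf("v%d", 1:40),
                beta = rnorm(40, 0, 0.05), se = runif(40, 0.01, 0.03))
  d2 <- make_ss(n = 40, snp_id = sprintf("v%d", 1:40),
                beta = rnorm(40, 0, 0.05), se = runif(40, 0.01, 0.03))
  res <- coloc_abf(d1, d2)
  expect_equal(res$pph0 + res$pph1 + res$pph2 + res$pph3 + res$pph4, 1,
               tolerance = 1e-10)

  perm <- sample(40)
  res_p <- coloc_abf(d1[perm, ], d2[rev(perm), ])
  for (h in c("pph0", "pph1", "pph2", "pph3", "pph4")) {
    expect_equal(res_p[[h]], res[[h]], tolerance = 1e-12)
  }

  p12_grid <- c(1e-7, 1e-6, 1e-5, 1e-4, 1e-3)
  pph4 <- vapply(p12_grid, function(p12)
    coloc_abf(d1, d2, p12 = p12)$pph4, numeric(1))
  expect_true(all(diff(pph4) >= 0))

  expect_error(coloc_abf(d1[1:3, ], d2[10:12, ]), "shared")
})

test_that("log-space posteriors agree with a direct-probability oracle on small loci", {
  direct_oracle <- function(d1, d2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                            sd1 = 0.15, sd2 = 0.15) {
    abf <- function(beta, se, sd0) {
      r <- sd0^2 / (sd0^2 + se^2)
      sqrt(1 - r) * exp(r * (beta / se)^2 / 2)
    }
    b1 <- abf(d1$beta, d1$se, sd1)
    b2 <- abf(d2$beta, d2$se, sd2)
    s1 <- sum(b1); s2 <- sum(b2); s4 <- sum(b1 * b2)
    ev <- c(1, p1 * s1, p2 * s2, p1 * p2 * (s1 * s2 - s4), p12 * s4)
    ev / sum(ev)
  }
  set.seed(22)
  for (rep in 1:10) {
    k <- sample(3:20, 1)
    d1 <- make_ss(n = k, snp_id = sprintf("v%d", 1:k),
                  beta = rnorm(k, 0, 0.08), se = runif(k, 0.01, 0.05))
    d2 <- make_ss(n = k, snp_id = sprintf("v%d", 1:k),
                  beta = rnorm(k, 0, 0.08), se = runif(k, 0.01, 0.05))
    got <- coloc_abf(d1, d2)
    want <- direct_oracle(d1, d2)
    expect_equal(c(got$pph0, got$pph1, got$pph2, got$pph3, got$pph4),
                 want, tolerance = 1e-8)
  }
})

test_that("a locus with no association on either trait is assigned to H0", {
  set.seed(23)
  d1 <- make_ss(n = 100, snp_id = sprintf("v%d", 1:100), beta = 0, se = 0.02)
  d2 <- make_ss(n = 100, snp_id = sprintf("v%d", 1:100), beta = 0, se = 0.02)
  expect_gt(coloc_abf(d1, d2)$pph0, 0.99)
})
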