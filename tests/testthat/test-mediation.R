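mk_est <- function(beta, se, id = "x", out = "y") {
  pwmr:::new_mr_estimate(id, out, "ivw_random", 5L, beta, se,
                         2 * pnorm(-abs(beta / se)))
}

test_that("mediation decomposition arithmetic and degenerate cases", {
  res <- mediate(mk_est(0.2, 0.02, "rf", "med"),
                 mk_est(0.5, 0.05, "med", "out"),
                 mk_est(0.4, 0.03, "rf", "out"))
  expect_equal(res$mediated, 0.1)
  expect_equal(res$proportion, 0.25)
  expect_equal(res$se_mediated, sqrt(0.5^2 * 0.02^2 + 0.2^2 * 0.05^2))
  expect_lt(res$sobel_p, 0.05)

  # no path through the mediator
  res0 <- mediate(mk_est(0, 0.02), mk_est(0.5, 0.05), mk_est(0.4, 0.03))
  expect_equal(res0$mediated, 0)
  expect_equal(res0$sobel_p, 1)
  expect_equal(res0$proportion, 0)
  expect_false(res0$reliable)

  expect_error(mediate(mk_est(0.2, 0.02), mk_est(0.5, 0.05), mk_est(0, 0.03)),
               "total effect")
})

test_that("Sobel p is symmetric in the two legs; se_mediated vanishes only without noise", {
  a <- mediate(mk_est(0.2, 0.04), mk_est(0.7, 0.01), mk_est(0.3, 0.05))
  b <- mediate(mk_est(0.7, 0.01), mk_est(0.2, 0.04), mk_est(0.3, 0.05))
  expect_equal(a$sobel_p, b$sobel_p)
  expect_equal(a$se_mediated, b$se_mediated)

  z <- mediate(mk_est(0.2, 0), mk_est(0.5, 0), mk_est(0.4, 0.01))
  expect_equal(z$se_mediated, 0)
  nz <- mediate(mk_est(0.2, 1e-4), mk_est(0.5, 0), mk_est(0.4, 0.01))
  expect_gt(nz$se_mediated, 0)
})

test_that("the reliability gate excludes pleiotropic totals regardless of Sobel p", {
  s1 <- mk_est(0.2, 0.02); s2 <- mk_est(0.5, 0.05); tot <- mk_est(0.4, 0.03)
  clean <- mediate(s1, s2, tot, total_pleiotropy_p = 0.4)
  expect_true(clean$reliable)
  pleio <- mediate(s1, s2, tot, total_pleiotropy_p = 0.02)
  expect_false(pleio$reliable)
  expect_equal(pleio$sobel_p, clean$sobel_p)   # gate does not alter the test
  # untestable pleiotropy (NA) counts as a pass
  expect_true(mediate(s1, s2, tot, total_pleiotropy_p = NA)$reliable)
  # direction mismatch between mediated and total effects fails the gate
  flip <- mediate(mk_est(-0.2, 0.02), s2, tot, total_pleiotropy_p = 0.4)
  expect_false(flip$reliable)
})

test_that("two-term and three-term proportion variances are ordered", {
  three <- mediate(mk_est(0.2, 0.02), mk_est(0.5, 0.05), mk_est(0.4, 0.03),
                   prop_var = "three")
  two <- mediate(mk_est(0.2, 0.02), mk_est(0.5, 0.05), mk_est(0.4, 0.03),
                 prop_var = "two")
  expect_lt(two$se_proportion, three$se_proportion)
  expect_equal(two$proportion, three$proportion)
})
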