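# Two-sample MR estimators and instrument diagnostics: Wald ratio, IVW
# (fixed / multiplicative random effects), Cochran's Q, the Egger intercept
# test, an MR-PRESSO-style global/outlier test, Steiger directionality, and
# Benjamini-Hochberg FDR.

Z975 <- stats::qnorm(0.975)

# One-row MR-estimate record; rbind-able across exposures/outcomes/methods.
new_mr_estimate <- function(exposure_id, outcome_id, method, n_snps,
                            beta, se, pvalue) {
  data.frame(
    exposure_id = exposure_id, outcome_id = outcome_id, method = method,
    n_snps = as.integer(n_snps), beta = beta, se = se,
    ci_low = beta - Z975 * se, ci_high = beta + Z975 * se,
    pvalue = max(min(pvalue, 1), .Machine$double.xmin),
    odds_ratio_scale = FALSE,
    stringsAsFactors = FALSE
  )
}

# Per-SNP Wald ratios and first-order weights shared by the estimators.
.ratios <- function(pairs) {
  if (any(pairs$beta_gx == 0)) stop("beta_gx = 0: Wald ratio undefined", call. = FALSE)
  b <- pairs$beta_gy / pairs$beta_gx
  se <- pairs$se_gy / abs(pairs$beta_gx)
  list(b = b, se = se, w = 1 / se^2)
}

#' Wald ratio causal estimate from a single instrument
#'
#' `beta = beta_gy / beta_gx` with first-order standard error
#' `se_gy / |beta_gx|` and a two-sided normal p-value.
#'
#' @param pair One harmonized exposure/outcome pair (one-row data frame from
#'   [harmonize()]).
#' @param exposure_id,outcome_id Labels carried into the result.
#' @return One-row MR-estimate data frame (`method = "wald_ratio"`).
#' @export
wald_ratio <- function(pair, exposure_id = "exposure", outcome_id = "outcome") {
  pair <- pair[1L, , drop = FALSE]
  r <- .ratios(pair)
  p <- 2 * stats::pnorm(-abs(r$b / r$se))
  new_mr_estimate(exposure_id, outcome_id, "wald_ratio", 1L, r$b, r$se, p)
}

#' Inverse-variance weighted causal estimate
#'
#' Meta-analysis of per-SNP Wald ratios with first-order weights
#' `1/se_j^2`. The fixed-effect estimate is the weighted mean with
#' `se = 1/sqrt(sum(w))`; the multiplicative random-effects variant scales
#' that standard error by `sqrt(Q/(k-1))` when Cochran's Q exceeds its
#' degrees of freedom, and is otherwise identical to the fixed-effect fit.
#' With a single instrument both reduce exactly to the Wald ratio.
#'
#' @param pairs Harmonized pairs (data frame from [harmonize()]).
#' @param model `"fixed"` or `"random"`.
#' @param exposure_id,outcome_id Labels carried into the result.
#' @return One-row MR-estimate data frame.
#' @export
ivw <- function(pairs, model = c("fixed", "random"),
                exposure_id = "exposure", outcome_id = "outcome") {
  model <- match.arg(model)
  k <- nrow(pairs)
  if (is.null(k) || k == 0L) stop("no instruments supplied to ivw", call. = FALSE)
  r <- .ratios(pairs)
  beta <- sum(r$w * r$b) / sum(r$w)
  se <- 1 / sqrt(sum(r$w))
  if (model == "random" && k >= 2L) {
    q <- sum(r$w * (r$b - beta)^2)
    se <- se * max(1, sqrt(q / (k - 1)))
  }
  p <- 2 * stats::pnorm(-abs(beta / se))
  method <- if (model == "fixed") "ivw_fixed" else "ivw_random"
  new_mr_estimate(exposure_id, outcome_id, method, k, beta, se, p)
}

#' Cochran's Q heterogeneity test across instruments
#'
#' `Q = sum w_j (b_j - b_ivw)^2` against the fixed-effect IVW estimate, with
#' a chi-square reference on `k - 1` degrees of freedom.
#'
#' @param pairs Harmonized pairs; at least two instruments.
#' @return List with `q_stat`, `q_pvalue`, `df`.
#' @export
cochran_q <- function(pairs) {
  k <- nrow(pairs)
  if (k < 2L) stop("Cochran's Q requires at least 2 instruments", call. = FALSE)
  r <- .ratios(pairs)
  beta <- sum(r$w * r$b) / sum(r$w)
  q <- sum(r$w * (r$b - beta)^2)
  list(q_stat = q, q_pvalue = stats::pchisq(q, df = k - 1, lower.tail = FALSE),
       df = k - 1L)
}

#' Egger regression: directional pleiotropy intercept test and causal slope
#'
#' Weighted linear regression of outcome effects on exposure effects with a
#' free intercept (weights `1/se_gy^2`), after orienting all exposure
#' effects non-negative. A non-zero intercept indicates directional
#' pleiotropy; its p-value comes from a t-test on `k - 2` degrees of
#' freedom.
#'
#' @param pairs Harmonized pairs; at least three instruments.
#' @param exposure_id,outcome_id Labels carried into the slope estimate.
#' @return List with `slope` (one-row MR-estimate data frame, method
#'   `"egger"`), `intercept`, `intercept_se`, `intercept_pvalue`.
#' @export
mr_egger <- function(pairs, exposure_id = "exposure", outcome_id = "outcome") {
  k <- nrow(pairs)
  if (k < 3L) stop("Egger regression requires at least 3 instruments", call. = FALSE)
  s <- sign(pairs$beta_gx)
  s[s == 0] <- 1
  x <- pairs$beta_gx * s
  y <- pairs$beta_gy * s
  w <- 1 / pairs$se_gy^2
  fit <- stats::lm(y ~ x, weights = w)
  cf <- summary(fit)$coefficients
  slope_p <- 2 * stats::pt(-abs(cf["x", "t value"]), df = k - 2)
  list(
    slope = new_mr_estimate(exposure_id, outcome_id, "egger", k,
                            cf["x", "Estimate"], cf["x", "Std. Error"], slope_p),
    intercept = cf["(Intercept)", "Estimate"],
    intercept_se = cf["(Intercept)", "Std. Error"],
    intercept_pvalue = cf["(Intercept)", "Pr(>|t|)"]
  )
}

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' MR-PRESSO-style residual-sum global pleiotropy test with outlier search
#'
#' The observed statistic is the variance-weighted sum over instruments of
#' squared leave-one-out residuals `beta_gy_j - bhat^(-j) * beta_gx_j`,
#' where `bhat^(-j)` is the fixed-effect IVW slope excluding instrument j.
#' Its null distribution is built by parametric simulation: each draw
#' resamples `beta_gx_j ~ N(beta_gx_j, se_gx_j)` and
#' `beta_gy_j ~ N(bhat^(-j) beta_gx_j, se_gy_j)` and recomputes the
#' statistic. Per-instrument outlier p-values use the same draws term by
#' term, flagged at a Bonferroni-corrected `outlier_alpha / k`.
#'
#' Monte-Carlo p-values use the add-one estimator `(1 + #{sim >= obs}) /
#' (1 + n_sim)` so they are never exactly zero.
#'
#' @param pairs Harmonized pairs; at least four instruments.
#' @param n_sim Number of parametric draws (default 1000).
#' @param seed Mandatory RNG seed; the same seed gives bit-identical
#'   p-values.
#' @param outlier_alpha Family-wise outlier significance level before
#'   Bonferroni division by the number of instruments (default 0.05).
#' @return List with `global_pvalue`, `outlier_ids`, `outlier_pvalues`
#'   (named, one per instrument), `rss_obs`.
#' @export
mr_presso <- function(pairs, n_sim = 1000, seed, outlier_alpha = 0.05) {
  k <- nrow(pairs)
  if (k < 4L) stop("MR-PRESSO requires at least 4 instruments", call. = FALSE)
  if (missing(seed)) stop("mr_presso requires an explicit seed", call. = FALSE)
  a <- pairs$beta_gx; b <- pairs$beta_gy
  sx <- pairs$se_gx; sy <- pairs$se_gy
  w <- 1 / sy^2

  loo_slope <- function(a, b) {
    s1 <- sum(w * a * b); s2 <- sum(w * a^2)
    (s1 - w * a * b) / (s2 - w * a^2)
  }
  bhat_loo <- loo_slope(a, b)
  terms_obs <- w * (b - bhat_loo * a)^2
  rss_obs <- sum(terms_obs)

  sims <- with_seed(seed, {
    A <- matrix(stats::rnorm(k * n_sim, mean = a, sd = sx), k, n_sim)
    B <- matrix(stats::rnorm(k * n_sim, mean = bhat_loo * a, sd = sy), k, n_sim)
    s1 <- colSums(w * A * B)
    s2 <- colSums(w * A^2)
    bl <- (rep(s1, each = k) - w * A * B) / (rep(s2, each = k) - w * A^2)
    w * (B - bl * A)^2
  })
  rss_sim <- colSums(sims)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (1 + n_sim)
  outlier_p <- (1 + rowSums(sims >= terms_obs)) / (1 + n_sim)
  ids <- if (!is.null(pairs$snp_id)) pairs$snp_id else as.character(seq_len(k))
  names(outlier_p) <- ids
  list(
    global_pvalue = global_p,
    outlier_ids = ids[outlier_p < outlier_alpha / k],
    outlier_pvalues = outlier_p,
    rss_obs = rss_obs
  )
}

#' Steiger test of causal direction
#'
#' Compares the instrument set's aggregate correlation with the exposure
#' (`r_x = sqrt(sum of per-SNP variance explained)`) against its correlation
#' with the outcome, via Fisher z-transforms:
#' `z = (atanh(r_x) - atanh(r_y)) / sqrt(1/(n_gx-3) + 1/(n_gy-3))`.
#' Instruments should act on the exposure first, so `r_x > r_y` supports the
#' assumed direction; ties are conservatively counted as not-correct.
#'
#' @param pairs Harmonized pairs (betas on standardized trait scales).
#' @param n_gx,n_gy Sample sizes; default to the per-SNP medians in `pairs`.
#' @return List with `steiger_pvalue`, `correct_direction`, `r_x`, `r_y`,
#'   `z`.
#' @export
steiger <- function(pairs, n_gx = NULL, n_gy = NULL) {
  if (nrow(pairs) < 1L) stop("steiger requires at least one instrument", call. = FALSE)
  if (is.null(n_gx)) n_gx <- stats::median(pairs$n_gx)
  if (is.null(n_gy)) n_gy <- stats::median(pairs$n_gy)
  if (min(n_gx, n_gy) < 4) stop("steiger requires sample sizes >= 4", call. = FALSE)
  eaf_y <- if (!is.null(pairs$eaf_gy)) pairs$eaf_gy else pairs$eaf
  r2x <- sum(2 * pairs$eaf * (1 - pairs$eaf) * pairs$beta_gx^2)
  r2y <- sum(2 * eaf_y * (1 - eaf_y) * pairs$beta_gy^2)
  if (r2x >= 1 || r2y >= 1) {
    stop("summed variance explained >= 1; betas not on a standardized scale",
         call. = FALSE)
  }
  r_x <- sqrt(r2x); r_y <- sqrt(r2y)
  z <- (atanh(r_x) - atanh(r_y)) / sqrt(1 / (n_gx - 3) + 1 / (n_gy - 3))
  list(
    steiger_pvalue = 2 * stats::pnorm(-abs(z)),
    correct_direction = r_x > r_y,
    r_x = r_x, r_y = r_y, z = z
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; output order matches input order.
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @return Vector of adjusted p-values (q-values).
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}
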