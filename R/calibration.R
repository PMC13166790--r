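# Simulation-based calibration suite: type-I error, parameter recovery and
# scenario discrimination for the pipeline's estimators, run on the
# synthetic generator. For repeated replicates the genotype panels (and
# hence LD) are drawn once per calibration and held fixed while phenotypic
# noise is redrawn, so each replicate's summary statistics are an
# independent draw conditional on one representative genotype realization;
# this keeps thousands of replicates tractable on one CPU without changing
# the sampling distribution being calibrated.

# Fixed-panel two-cohort MR replicate machinery: k independent instrument
# blocks, exposure x = G a + e in cohort 1, outcome y = theta * x + e in
# cohort 2 (theta = 0 gives the null). Returns per-replicate IVW p and beta.
.mr_replicates <- function(n_reps, n, k, theta, seed, ve = 0.005,
                           model = "random", p_sel = 5e-8) {
  set.seed(seed)
  m <- 2L * k
  mafs <- stats::runif(m, 0.05, 0.45)
  gx <- simulate_genotypes(n, k, 2L, rho = 0, mafs = mafs)
  gy <- simulate_genotypes(n, k, 2L, rho = 0, mafs = mafs)
  idx <- seq(1L, m, by = 2L)      # first SNP of each block = the causal one
  a <- effect_for_ve(ve, mafs[idx])
  Gx <- gx$G[, idx, drop = FALSE]
  Gy <- gy$G[, idx, drop = FALSE]
  info <- gx$info[idx, , drop = FALSE]
  gcx <- drop(Gx %*% a)
  gcy <- drop(Gy %*% a)
  vgx <- stats::var(gcx)

  pvals <- betas <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    x <- gcx + stats::rnorm(n, 0, sqrt(1 - vgx))
    ex <- .marginal_gwas(Gx, x, info)[[1L]]
    if (theta == 0) {
      y <- stats::rnorm(n)
    } else {
      x_oc <- gcy + stats::rnorm(n, 0, sqrt(1 - stats::var(gcy)))
      y <- theta * x_oc + stats::rnorm(n, 0, sqrt(1 - theta^2))
    }
    oy <- .marginal_gwas(Gy, y, info)[[1L]]
    sel <- ex$pvalue < p_sel
    if (!any(sel)) {
      pvals[r] <- NA_real_
      betas[r] <- NA_real_
      next
    }
    pr <- data.frame(
      snp_id = ex$snp_id[sel],
      beta_gx = ex$beta[sel], se_gx = ex$se[sel],
      beta_gy = oy$beta[sel], se_gy = oy$se[sel],
      eaf = ex$eaf[sel], eaf_gy = oy$eaf[sel],
      n_gx = n, n_gy = n, stringsAsFactors = FALSE
    )
    est <- ivw(pr, model = model)
    pvals[r] <- est$pvalue
    betas[r] <- est$beta
  }
  list(pvalue = pvals, beta = betas)
}

#' Type-I error of the IVW test under the null
#'
#' Replicates a two-sample design with independent instruments and no
#' causal effect, and reports the fraction of IVW p-values below `alpha`.
#'
#' @param n_reps Number of replicates (default 2000).
#' @param n Per-cohort GWAS sample size (default 50000).
#' @param k Number of instruments (default 10).
#' @param alpha Nominal level (default 0.05).
#' @param seed RNG seed.
#' @param model IVW model (default the pipeline's `"random"`).
#' @return List with `rejection_rate`, `n_reps`.
#' @export
calib_ivw_type1 <- function(n_reps = 2000, n = 50000, k = 10, alpha = 0.05,
                            seed = 1, model = "random") {
  sim <- .mr_replicates(n_reps, n, k, theta = 0, seed = seed, model = model)
  list(rejection_rate = mean(sim$pvalue < alpha), n_reps = n_reps)
}

#' Recovery of a true causal effect by IVW
#'
#' @param n_reps Number of replicates (default 500).
#' @param theta True causal effect per SD (default 0.15).
#' @inheritParams calib_ivw_type1
#' @return List with `median_beta`, `median_bias`, `theta`, `n_reps`.
#' @export
calib_ivw_recovery <- function(n_reps = 500, n = 50000, k = 10, theta = 0.15,
                               seed = 1, model = "random") {
  sim <- .mr_replicates(n_reps, n, k, theta = theta, seed = seed, model = model)
  med <- stats::median(sim$beta)
  list(median_beta = med, median_bias = med - theta, theta = theta,
       n_reps = n_reps)
}

#' Size of the Egger intercept test under a pleiotropy-free null
#'
#' Summary-level replicates: fixed true instrument effects, noisy exposure
#' and outcome estimates generated from a pure causal model (every
#' instrument acts only through the exposure), intercept tested at `alpha`.
#'
#' @param n_reps Number of replicates (default 2000).
#' @param k Number of instruments (default 30).
#' @param theta Causal slope (default 0.1).
#' @param alpha Nominal level (default 0.05).
#' @param seed RNG seed.
#' @return List with `rejection_rate`, `n_reps`.
#' @export
calib_egger_null <- function(n_reps = 2000, k = 30, theta = 0.1, alpha = 0.05,
                             seed = 1) {
  set.seed(seed)
  a <- stats::runif(k, 0.05, 0.15)
  se_gx <- rep(0.005, k)
  se_gy <- stats::runif(k, 0.008, 0.02)
  rej <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    pr <- data.frame(
      beta_gx = stats::rnorm(k, a, se_gx), se_gx = se_gx,
      beta_gy = stats::rnorm(k, theta * a, se_gy), se_gy = se_gy
    )
    rej[r] <- mr_egger(pr)$intercept_pvalue < alpha
  }
  list(rejection_rate = mean(rej), n_reps = n_reps)
}

# Fixed-panel locus replicates for HEIDI / coloc: one LD block per cohort,
# causal variant(s) at known positions, phenotypes redrawn per replicate.
.locus_replicates <- function(n_reps, n, n_snps, rho, causal_x, causal_y_gap,
                              theta, ve, seed, fun) {
  set.seed(seed)
  mafs <- stats::runif(n_snps, 0.05, 0.45)
  gx <- simulate_genotypes(n, 1L, n_snps, rho, mafs = mafs)
  gy <- simulate_genotypes(n, 1L, n_snps, rho, mafs = mafs)
  info <- gx$info
  c1 <- causal_x
  a_x <- numeric(n_snps); a_x[c1] <- effect_for_ve(ve, mafs[c1])
  gcx <- drop(gx$G %*% a_x)
  vx <- stats::var(gcx)
  shared <- is.null(causal_y_gap)
  if (shared) {
    gcy <- drop(gy$G %*% a_x)
  } else {
    c2 <- c1 + causal_y_gap
    a_y <- numeric(n_snps); a_y[c2] <- effect_for_ve(ve, mafs[c2])
    gcy <- drop(gy$G %*% a_y)
  }
  vy_g <- stats::var(gcy)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    x <- gcx + stats::rnorm(n, 0, sqrt(1 - vx))
    ex <- .marginal_gwas(gx$G, x, info)[[1L]]
    if (shared) {
      x_oc <- gcy + stats::rnorm(n, 0, sqrt(1 - vy_g))
      y <- theta * x_oc + stats::rnorm(n, 0, sqrt(1 - theta^2))
    } else {
      y <- gcy + stats::rnorm(n, 0, sqrt(1 - vy_g))
    }
    oy <- .marginal_gwas(gy$G, y, info)[[1L]]
    out[[r]] <- fun(ex, oy, gx$ld)
  }
  out
}

.pairs_from_stats <- function(ex, oy, n) {
  data.frame(
    snp_id = ex$snp_id, chrom = ex$chrom, pos = ex$pos,
    beta_gx = ex$beta, se_gx = ex$se, pvalue_gx = ex$pvalue,
    beta_gy = oy$beta, se_gy = oy$se, pvalue_gy = oy$pvalue,
    eaf = ex$eaf, eaf_gy = oy$eaf, n_gx = n, n_gy = n,
    stringsAsFactors = FALSE
  )
}

#' HEIDI calibration under a shared causal variant, and power under linkage
#'
#' Under a single shared causal variant (the SMR/HEIDI null) the HEIDI
#' p-value should be uniform; under two distinct variants in LD it should
#' reject. Reports the rejection rate at `alpha`.
#'
#' @param n_reps Number of replicates (default 1000).
#' @param scenario `"shared"` (null) or `"linked"` (distinct causal
#'   variants `gap` SNPs apart).
#' @param n GWAS sample size per cohort (default 20000).
#' @param n_snps Locus size (default 60).
#' @param rho AR(1) LD (default 0.8).
#' @param theta Causal effect under the shared scenario (default 0.5).
#' @param ve Variance explained by the causal variant (default 0.02).
#' @param gap SNP distance between the two causal variants under
#'   `"linked"` (default 2, r^2 around 0.4 at `rho = 0.8`).
#' @param alpha Rejection threshold (0.05 for size, 0.01 for the pass rule).
#' @param seed RNG seed.
#' @return List with `rejection_rate`, `n_informative` (replicates with a
#'   reportable HEIDI p), `n_reps`.
#' @export
calib_heidi <- function(n_reps = 1000, scenario = c("shared", "linked"),
                        n = 20000, n_snps = 60, rho = 0.8, theta = 0.5,
                        ve = 0.02, gap = 2, alpha = 0.05, seed = 1) {
  scenario <- match.arg(scenario)
  c1 <- ceiling(n_snps / 2)
  res <- .locus_replicates(
    n_reps, n, n_snps, rho, causal_x = c1,
    causal_y_gap = if (scenario == "shared") NULL else gap,
    theta = theta, ve = ve, seed = seed,
    fun = function(ex, oy, ld) {
      pr <- .pairs_from_stats(ex, oy, n)
      top <- pr$snp_id[which.min(pr$pvalue_gx)]
      heidi_test(pr, ld, top)$heidi_p
    }
  )
  p <- unlist(res)
  list(rejection_rate = mean(p < alpha, na.rm = TRUE),
       n_informative = sum(!is.na(p)), n_reps = n_reps)
}

#' Colocalization discrimination across causal-variant scenarios
#'
#' Shared-variant replicates ("H4") should give PPH4 above the strong
#' threshold; distinct-variant replicates ("H3") should make H3 the modal
#' hypothesis; null replicates PPH0.
#'
#' @param n_reps Number of replicates (default 100).
#' @param scenario `"H4"`, `"H3"` or `"H0"`.
#' @param n GWAS sample size (default 50000).
#' @param n_snps Locus size (default 200).
#' @param theta Causal effect under H4 (default 0.5).
#' @param ve Variance explained by the causal variant (default 0.01).
#' @param gap SNP distance between distinct causal variants under H3
#'   (default 10; essentially unlinked at the default LD decay).
#' @param rho,seed As elsewhere.
#' @return List with `pph4_above_0.8` (fraction), `modal_counts` (table of
#'   modal hypotheses across replicates), `mean_posteriors`, `n_reps`.
#' @export
calib_coloc <- function(n_reps = 100, scenario = c("H4", "H3", "H0"),
                        n = 50000, n_snps = 200, theta = 0.5, ve = 0.01,
                        gap = 10, rho = 0.8, seed = 1) {
  scenario <- match.arg(scenario)
  c1 <- ceiling(n_snps / 2)
  res <- .locus_replicates(
    n_reps, n, n_snps, rho, causal_x = c1,
    causal_y_gap = switch(scenario, H4 = NULL, H3 = gap, H0 = NULL),
    theta = if (scenario == "H4") theta else 0,
    ve = if (scenario == "H0") 1e-12 else ve, seed = seed,
    fun = function(ex, oy, ld) {
      coloc_abf(ex, oy, locus_id = scenario)
    }
  )
  post <- do.call(rbind, res)[, c("pph0", "pph1", "pph2", "pph3", "pph4")]
  modal <- table(factor(c("pph0", "pph1", "pph2", "pph3", "pph4")[
    max.col(as.matrix(post))], levels = colnames(post)))
  list(pph4_above_0.8 = mean(post$pph4 > 0.8),
       modal_counts = modal,
       mean_posteriors = colMeans(post), n_reps = n_reps)
}

#' Steiger orientation under forward- and reverse-causal simulations
#'
#' Forward: instruments act on the exposure, which causes the outcome; the
#' per-instrument Steiger check should pass. Reverse: the instruments'
#' primary trait is the outcome and the exposure is downstream; the check
#' should fail.
#'
#' @param n_reps Number of replicates (default 100).
#' @param direction `"forward"` or `"reverse"`.
#' @param n GWAS sample size (default 50000).
#' @param k Number of instruments (default 10).
#' @param theta Causal effect along the chain (default 0.5).
#' @param ve Variance explained per instrument on its primary trait
#'   (default 0.005).
#' @param seed RNG seed.
#' @return List with `pass_rate` (fraction of replicates where every
#'   instrument passes the Steiger filter in the assumed direction),
#'   `n_reps`.
#' @export
calib_steiger <- function(n_reps = 100, direction = c("forward", "reverse"),
                          n = 50000, k = 10, theta = 0.5, ve = 0.005,
                          seed = 1) {
  direction <- match.arg(direction)
  set.seed(seed)
  m <- 2L * k
  mafs <- stats::runif(m, 0.05, 0.45)
  gx <- simulate_genotypes(n, k, 2L, rho = 0, mafs = mafs)
  gy <- simulate_genotypes(n, k, 2L, rho = 0, mafs = mafs)
  idx <- seq(1L, m, by = 2L)
  a <- numeric(m); a[idx] <- effect_for_ve(ve, mafs[idx])
  info <- gx$info
  gc1 <- drop(gx$G %*% a)   # primary-trait genetic component, cohort 1
  gc2 <- drop(gy$G %*% a)
  v1 <- stats::var(gc1); v2 <- stats::var(gc2)
  pass <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    if (direction == "forward") {
      x1 <- gc1 + stats::rnorm(n, 0, sqrt(1 - v1))          # exposure, cohort 1
      y2 <- theta * (gc2 + stats::rnorm(n, 0, sqrt(1 - v2))) +
        stats::rnorm(n, 0, sqrt(1 - theta^2))               # outcome, cohort 2
      ex <- .marginal_gwas(gx$G[, idx], x1, info[idx, ])[[1L]]
      oy <- .marginal_gwas(gy$G[, idx], y2, info[idx, ])[[1L]]
    } else {
      # instruments act on the outcome trait; "exposure" is downstream
      o1 <- gc1 + stats::rnorm(n, 0, sqrt(1 - v1))
      x1 <- theta * o1 + stats::rnorm(n, 0, sqrt(1 - theta^2))
      o2 <- gc2 + stats::rnorm(n, 0, sqrt(1 - v2))
      ex <- .marginal_gwas(gx$G[, idx], x1, info[idx, ])[[1L]]   # exposure GWAS
      oy <- .marginal_gwas(gy$G[, idx], o2, info[idx, ])[[1L]]   # outcome GWAS
    }
    pr <- .pairs_from_stats(ex, oy, n)
    ok <- vapply(seq_len(nrow(pr)), function(i) {
      s <- steiger(pr[i, , drop = FALSE])
      s$correct_direction && s$steiger_pvalue < 0.05
    }, logical(1))
    pass[r] <- all(ok)
  }
  list(pass_rate = mean(pass), n_reps = n_reps)
}

#' Detection of a planted MR-PRESSO outlier
#'
#' Summary-level replicates: `k` clean instruments following a causal model
#' plus one instrument displaced by `shift` outcome standard errors.
#' Reports how often the displaced instrument is flagged.
#'
#' @param n_reps Number of replicates (default 100).
#' @param k Number of clean instruments (default 20).
#' @param theta Causal slope (default 0.1).
#' @param shift Displacement in units of the outcome SE (default 10).
#' @param n_sim Parametric draws per MR-PRESSO call (default 1000).
#' @param seed RNG seed.
#' @return List with `outlier_detection_rate`, `global_rejection_rate`,
#'   `n_reps`.
#' @export
calib_presso_outlier <- function(n_reps = 100, k = 20, theta = 0.1,
                                 shift = 10, n_sim = 1000, seed = 1) {
  set.seed(seed)
  a <- stats::runif(k + 1L, 0.05, 0.2)
  se_gx <- rep(0.005, k + 1L)
  se_gy <- stats::runif(k + 1L, 0.008, 0.02)
  seeds <- sample.int(.Machine$integer.max, n_reps)
  hit <- glob <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seeds[r])
    bgy <- stats::rnorm(k + 1L, theta * a, se_gy)
    bgy[k + 1L] <- bgy[k + 1L] + shift * se_gy[k + 1L]
    pr <- data.frame(
      snp_id = c(sprintf("clean%02d", seq_len(k)), "planted"),
      beta_gx = stats::rnorm(k + 1L, a, se_gx), se_gx = se_gx,
      beta_gy = bgy, se_gy = se_gy, stringsAsFactors = FALSE
    )
    out <- mr_presso(pr, n_sim = n_sim, seed = seeds[r])
    hit[r] <- "planted" %in% out$outlier_ids
    glob[r] <- out$global_pvalue < 0.05
  }
  list(outlier_detection_rate = mean(hit), global_rejection_rate = mean(glob),
       n_reps = n_reps)
}

#' Coverage of the mediation proportion's delta-method interval
#'
#' Fixed-panel replicates of the full risk factor -> mediator -> outcome
#' chain across three independent cohorts; each replicate estimates the
#' three MR legs, runs [mediate()], and checks whether the true proportion
#' mediated falls inside the reported 95% interval.
#'
#' @param n_reps Number of replicates (default 200).
#' @param n Per-cohort sample size (default 50000).
#' @param beta1,beta2,direct Chain effects (defaults 0.2, 0.3, 0.14: true
#'   proportion mediated 30%).
#' @param rf_instruments Risk-factor instruments (default 10).
#' @param seed RNG seed.
#' @return List with `coverage`, `median_proportion`, `true_proportion`,
#'   `n_reps`.
#' @export
calib_mediation <- function(n_reps = 200, n = 50000, beta1 = 0.2,
                            beta2 = 0.3, direct = 0.14,
                            rf_instruments = 10, seed = 1) {
  set.seed(seed)
  n_blocks <- rf_instruments + 1L
  block_size <- 8L
  m <- n_blocks * block_size
  mafs <- stats::runif(m, 0.05, 0.45)
  g <- lapply(1:3, function(i)
    simulate_genotypes(n, n_blocks, block_size, rho = 0.8, mafs = mafs))
  info <- g[[1L]]$info
  center <- function(b) which(info$block == b)[ceiling(block_size / 2)]
  rf_idx <- vapply(seq_len(rf_instruments), center, integer(1))
  med_idx <- center(n_blocks) + c(0L, 2L)
  a_rf <- numeric(m); a_rf[rf_idx] <- effect_for_ve(0.005, mafs[rf_idx])
  a_med <- numeric(m); a_med[med_idx] <- effect_for_ve(0.02, mafs[med_idx])
  gc_rf <- lapply(g, function(gg) drop(gg$G %*% a_rf))
  gc_med <- lapply(g, function(gg) drop(gg$G %*% a_med))
  v_rf <- vapply(gc_rf, stats::var, numeric(1))

  true_prop <- beta1 * beta2 / (beta1 * beta2 + direct)
  cover <- logical(n_reps)
  props <- numeric(n_reps)
  chain <- function(i) {
    rf <- gc_rf[[i]] + stats::rnorm(n, 0, sqrt(1 - v_rf[i]))
    sig_m <- gc_med[[i]] + beta1 * rf
    mediator <- sig_m + stats::rnorm(n, 0, sqrt(1 - stats::var(sig_m)))
    sig_y <- beta2 * mediator + direct * rf
    y <- sig_y + stats::rnorm(n, 0, sqrt(1 - stats::var(sig_y)))
    list(rf = rf, mediator = mediator, y = y)
  }
  for (r in seq_len(n_reps)) {
    c1 <- chain(1L); c2 <- chain(2L); c3 <- chain(3L)
    rf_stats <- .marginal_gwas(g[[1L]]$G[, rf_idx], c1$rf, info[rf_idx, ])[[1L]]
    med_rf <- .marginal_gwas(g[[2L]]$G[, rf_idx], c2$mediator, info[rf_idx, ])[[1L]]
    med_cis <- .marginal_gwas(g[[2L]]$G[, med_idx[1L], drop = FALSE],
                              c2$mediator, info[med_idx[1L], ])[[1L]]
    out_cis <- .marginal_gwas(g[[3L]]$G[, med_idx[1L], drop = FALSE],
                              c3$y, info[med_idx[1L], ])[[1L]]
    out_rf <- .marginal_gwas(g[[3L]]$G[, rf_idx], c3$y, info[rf_idx, ])[[1L]]

    step1 <- ivw(.pairs_from_stats(rf_stats, med_rf, n), model = "random",
                 exposure_id = "RF", outcome_id = "MED")
    step2 <- wald_ratio(.pairs_from_stats(med_cis, out_cis, n),
                        exposure_id = "MED", outcome_id = "Y")
    total <- ivw(.pairs_from_stats(rf_stats, out_rf, n), model = "random",
                 exposure_id = "RF", outcome_id = "Y")
    md <- mediate(step1, step2, total)
    props[r] <- md$proportion
    cover[r] <- md$prop_ci_low <= true_prop && true_prop <= md$prop_ci_high
  }
  list(coverage = mean(cover), median_proportion = stats::median(props),
       true_proportion = true_prop, n_reps = n_reps)
}
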