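# Summary-data-based MR at the top cis-QTL and the HEIDI test that separates
# a single shared causal variant from LD-linked distinct variants.

#' Summary-data-based MR test at the top QTL
#'
#' `b_smr = beta_gy / beta_gx`; the test statistic combines the two z-scores
#' as `T = z_gx^2 * z_gy^2 / (z_gx^2 + z_gy^2)` with a chi-square(1)
#' reference, and `se_smr = |b_smr| / sqrt(T)`. T is bounded by the smaller
#' of the two squared z-scores, so the SMR p-value can never beat the weaker
#' of the two marginal associations.
#'
#' @param top One harmonized pair (one-row data frame) for the top QTL.
#' @param probe_id Label carried into the result.
#' @return One-row data frame: `probe_id`, `top_snp`, `b_smr`, `se_smr`,
#'   `p_smr` (plus `heidi_p = NA`, `n_heidi_snps = 0` placeholders filled by
#'   [heidi_test()] callers).
#' @export
smr_test <- function(top, probe_id = "probe") {
  top <- top[1L, , drop = FALSE]
  if (top$beta_gx == 0) stop("beta_gx = 0: SMR effect undefined", call. = FALSE)
  zx2 <- (top$beta_gx / top$se_gx)^2
  zy2 <- (top$beta_gy / top$se_gy)^2
  t_smr <- if (zx2 + zy2 == 0) 0 else zx2 * zy2 / (zx2 + zy2)
  b_smr <- top$beta_gy / top$beta_gx
  data.frame(
    probe_id = probe_id,
    top_snp = if (!is.null(top$snp_id)) top$snp_id else NA_character_,
    b_smr = b_smr,
    se_smr = if (t_smr > 0) abs(b_smr) / sqrt(t_smr) else Inf,
    p_smr = stats::pchisq(t_smr, df = 1, lower.tail = FALSE),
    heidi_p = NA_real_,
    n_heidi_snps = 0L,
    stringsAsFactors = FALSE
  )
}

#' Tail probability of a weighted sum of independent chi-square(1) variables
#'
#' Computes `P(sum lambda_i X_i > q)` with `X_i ~ chi-square(1)` via Imhof's
#' integral representation (numerical integration). When all weights are
#' equal the exact scaled chi-square is used; if integration fails, a
#' Satterthwaite moment-matched chi-square approximation is the fallback.
#'
#' @param q Observed statistic.
#' @param lambda Non-negative eigenvalue weights.
#' @return Upper-tail probability in `[0, 1]`.
#' @export
pchisq_mixture <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-10]
  m <- length(lambda)
  if (m == 0L) return(1)
  if (max(lambda) - min(lambda) < 1e-7 * max(lambda)) {
    return(stats::pchisq(q / mean(lambda), df = m, lower.tail = FALSE))
  }
  satterthwaite <- function() {
    sc <- sum(lambda^2) / sum(lambda)
    df <- sum(lambda)^2 / sum(lambda^2)
    stats::pchisq(q / sc, df = df, lower.tail = FALSE)
  }
  imhof <- function(u) {
    theta <- 0.5 * colSums(atan(lambda %o% u)) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p((lambda %o% u)^2)))
    out <- sin(theta) / (u * rho)
    # u -> 0 limit: theta'(0) = (sum(lambda) - q) / 2
    small <- u < 1e-12
    out[small] <- 0.5 * (sum(lambda) - q)
    out
  }
  # integrate chunkwise over a couple of oscillation periods at a time; the
  # envelope decays like u^-(m/2+1), so once a chunk is negligible the
  # remainder is too
  p <- tryCatch({
    chunk <- 4 * pi / max(q, 1)
    total <- 0
    u0 <- 0
    for (kk in seq_len(500L)) {
      part <- stats::integrate(imhof, u0, u0 + chunk, rel.tol = 1e-10,
                               abs.tol = 1e-13, subdivisions = 200L)$value
      total <- total + part
      u0 <- u0 + chunk
      if (kk > 5L && abs(part) < 1e-13) break
    }
    0.5 + total / pi
  }, error = function(e) satterthwaite())
  min(max(p, 0), 1)
}

#' HEIDI test: heterogeneity in dependent instruments at a cis locus
#'
#' Tests whether the SMR effect is driven by one shared causal variant (null)
#' or by distinct variants in LD (alternative). SNPs in intermediate LD with
#' the top QTL (`r2_min < r^2 < r2_max`) and with exposure p-value below
#' `p_exposure_max` are compared to the top SNP: `d_i = b_i - b_top` of
#' per-SNP ratio estimates, with a first-order delta covariance that
#' propagates both exposure and outcome sampling error and the LD-induced
#' correlation of z-scores across SNPs. The statistic
#' `T = sum (d_i / sd(d_i))^2` is referred to an eigenvalue-weighted
#' chi-square mixture (see [pchisq_mixture()]). Fewer than `min_snps`
#' eligible SNPs yields `heidi_p = NA` with the count recorded.
#'
#' @param locus Harmonized pairs across the locus (must contain `top_snp`).
#' @param ld Signed LD matrix covering the locus SNPs.
#' @param top_snp SNP id of the top QTL.
#' @param r2_min,r2_max LD-eligibility window around the top SNP (defaults
#'   0.05 and 0.9).
#' @param max_snps Maximum number of comparison SNPs, strongest exposure
#'   associations first (default 20).
#' @param p_exposure_max Exposure inclusion threshold (default 1.57e-3).
#' @param min_snps Minimum comparison SNPs needed to report a p-value
#'   (default 3).
#' @return List with `heidi_p` (`NA` when not performable), `n_used`, and
#'   the comparison SNP ids.
#' @export
heidi_test <- function(locus, ld, top_snp, r2_min = 0.05, r2_max = 0.9,
                       max_snps = 20, p_exposure_max = 1.57e-3,
                       min_snps = 3) {
  if (!(top_snp %in% locus$snp_id)) stop("top_snp not in locus", call. = FALSE)
  if (!(top_snp %in% rownames(ld))) stop("top_snp not in LD matrix", call. = FALSE)
  locus <- locus[locus$snp_id %in% rownames(ld), , drop = FALSE]

  top <- locus[locus$snp_id == top_snp, , drop = FALSE]
  rest <- locus[locus$snp_id != top_snp, , drop = FALSE]
  p_exp <- if (!is.null(rest$pvalue_gx)) rest$pvalue_gx else
    2 * stats::pnorm(-abs(rest$beta_gx / rest$se_gx))
  r2_top <- ld[top_snp, rest$snp_id]^2
  eligible <- r2_top > r2_min & r2_top < r2_max & p_exp < p_exposure_max
  rest <- rest[eligible, , drop = FALSE]
  p_exp <- p_exp[eligible]
  if (nrow(rest) > max_snps) {
    keep <- order(p_exp, rest$snp_id)[seq_len(max_snps)]
    rest <- rest[keep, , drop = FALSE]
  }
  m <- nrow(rest)
  if (m < min_snps) {
    return(list(heidi_p = NA_real_, n_used = m, snp_ids = rest$snp_id))
  }

  sel <- rbind(top, rest)       # index 1 = top
  a <- sel$beta_gx; sx <- sel$se_gx
  b <- sel$beta_gy; sy <- sel$se_gy
  bw <- b / a                   # per-SNP Wald ratios
  r <- ld[sel$snp_id, sel$snp_id]

  # cov(bw_i, bw_j) by first-order delta, with corr(z_i, z_j) = r_ij on each
  # trait and the two GWAS samples independent of each other.
  cov_b <- r * (outer(sy, sy) + outer(bw, bw) * outer(sx, sx)) / outer(a, a)
  idx <- 2:(m + 1)
  v <- cov_b[idx, idx, drop = FALSE] -
    outer(cov_b[idx, 1], rep(1, m)) -
    outer(rep(1, m), cov_b[1, idx]) +
    cov_b[1, 1]
  d <- bw[idx] - bw[1]
  sd_d <- sqrt(diag(v))
  if (any(!is.finite(sd_d)) || any(sd_d <= 0)) {
    return(list(heidi_p = NA_real_, n_used = m, snp_ids = rest$snp_id))
  }
  t_stat <- sum((d / sd_d)^2)
  corr_d <- v / outer(sd_d, sd_d)
  ev <- eigen((corr_d + t(corr_d)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  list(heidi_p = pchisq_mixture(t_stat, ev), n_used = m, snp_ids = rest$snp_id)
}
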