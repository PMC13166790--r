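# Bayesian colocalization of two association signals at a locus under the
# single-causal-variant-per-trait assumption, using Wakefield-style
# approximate Bayes factors and log-space hypothesis sums.

#' Log approximate Bayes factor for one variant
#'
#' With `z = beta/se` and shrinkage `r = prior_sd^2 / (prior_sd^2 + se^2)`,
#' the log approximate Bayes factor against the null is
#' `0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param beta,se Marginal effect and standard error (vectorized).
#' @param prior_sd Prior standard deviation of the true effect (0.15 is the
#'   usual choice for quantitative traits, 0.2 for binary).
#' @return Numeric vector of log ABFs.
#' @export
log_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0)) stop("standard errors must be positive", call. = FALSE)
  z <- beta / se
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  0.5 * (log1p(-r) + r * z^2)
}

logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable when a ~ b.
logdiffexp <- function(a, b) {
  if (b - a > -1e-12) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Bayesian colocalization over five hypotheses (PPH0-PPH4)
#'
#' Assumes at most one causal variant per trait at the locus. Per-variant
#' log ABFs are combined in log space into the evidence for: H0 no
#' association with either trait; H1/H2 association with one trait only;
#' H3 both traits associated through distinct causal variants; H4 both
#' traits share one causal variant. Posteriors are proportional to
#' `{1, p1*S1, p2*S2, p1*p2*S3, p12*S4}`, where the cross-variant H3 sum is
#' computed stably as the log-space difference between the full product of
#' the two single-trait sums and the shared-variant sum.
#'
#' @param trait1,trait2 Variant data frames sharing `snp_id`, each with
#'   `beta` and `se` columns (e.g. `sumstats` data slots restricted to the
#'   locus). Only variants present in both are used; alignment of effect
#'   alleles is irrelevant because the ABF depends on `z^2`.
#' @param p1,p2 Prior probabilities that a variant is causal for trait 1
#'   (resp. 2) only (default `1e-4`).
#' @param p12 Prior probability that a variant is causal for both traits
#'   (default `1e-5`).
#' @param prior_sd1,prior_sd2 Effect-prior standard deviations per trait.
#' @param locus_id Label carried into the result.
#' @return One-row data frame: `locus_id`, `n_variants`, `pph0`..`pph4`,
#'   `pph3_plus_pph4`, priors, and `lead_shared_snp` (the variant with the
#'   largest single-SNP H4 contribution).
#' @export
coloc_abf <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd1 = 0.15, prior_sd2 = 0.15,
                      locus_id = "locus") {
  d1 <- ss_data(trait1)
  d2 <- ss_data(trait2)
  shared <- intersect(d1$snp_id, d2$snp_id)
  if (length(shared) == 0L) {
    stop("no shared variants between traits at locus '", locus_id, "'",
         call. = FALSE)
  }
  d1 <- d1[match(shared, d1$snp_id), , drop = FALSE]
  d2 <- d2[match(shared, d2$snp_id), , drop = FALSE]
  l1 <- log_abf(d1$beta, d1$se, prior_sd1)
  l2 <- log_abf(d2$beta, d2$se, prior_sd2)

  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls4 <- logsumexp(l1 + l2)
  lh <- c(
    h0 = 0,
    h1 = log(p1) + ls1,
    h2 = log(p2) + ls2,
    h3 = log(p1) + log(p2) + logdiffexp(ls1 + ls2, ls4),
    h4 = log(p12) + ls4
  )
  post <- exp(lh - logsumexp(lh))
  post <- post / sum(post)
  data.frame(
    locus_id = locus_id, n_variants = length(shared),
    pph0 = post[["h0"]], pph1 = post[["h1"]], pph2 = post[["h2"]],
    pph3 = post[["h3"]], pph4 = post[["h4"]],
    pph3_plus_pph4 = post[["h3"]] + post[["h4"]],
    p1 = p1, p2 = p2, p12 = p12,
    lead_shared_snp = shared[which.max(l1 + l2)],
    stringsAsFactors = FALSE
  )
}
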