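# Whole-study generator: a discovery pQTL panel over many proteins, a
# smaller replication pQTL panel covering only part of the proteome, an
# outcome GWAS, risk-factor GWAS for the mediation screen, and a bank of
# extra outcomes for phenome-wide MR -- all with known ground truth.

#' Simulate a full proteome-wide MR study
#'
#' Each protein owns one cis LD block holding `pqtl_per_protein` causal cis
#' variants; `n_causal` proteins causally affect the outcome with effect
#' `theta` per SD. Each risk factor owns `rf_instruments` independent
#' single-variant blocks; risk factor 1 acts on the first causal protein
#' (`beta1`) and directly on the outcome, giving a ground-truth mediation
#' chain with proportion mediated `beta1 * theta / (beta1 * theta +
#' direct1)`. The replication panel re-measures only the first
#' `ceiling(replication_coverage * n_proteins)` proteins in an independent
#' (much smaller) cohort, mirroring a replication resource that lacks many
#' proteins; causal proteins are split between covered and uncovered
#' indices so both replicated and unreplicated true positives exist.
#' Phenome-wide outcomes are null traits (plus `phewas_planted` true
#' effects of the first causal protein) carrying case counts for the
#' more-than-500-cases filter.
#'
#' @param seed Integer RNG seed.
#' @param n_proteins,n_causal Protein panel size and number of causal
#'   proteins (default 20 and 5).
#' @param theta Causal effect of each causal protein on the outcome per SD
#'   (default 0.2).
#' @param n_exposure,n_outcome,n_replication,n_riskfactor Cohort sizes
#'   (defaults 20000, 20000, 619, 20000).
#' @param pqtl_per_protein Causal cis variants per protein (default 3).
#' @param ve_cis Variance in protein level explained per causal cis variant
#'   (default 0.05; cis effects on plasma proteins are large).
#' @param n_riskfactors,rf_instruments,ve_rf Risk-factor layout (defaults
#'   2 risk factors, 10 instruments each, 0.8% variance per instrument --
#'   the complex behavioural and anthropometric risk factors this emulates
#'   are polygenic with many independent genome-wide-significant loci).
#' @param beta1,direct1 Mediation chain: effect of risk factor 1 on the
#'   first causal protein and its direct outcome effect (defaults 0.3 and
#'   0.14, so the true proportion mediated is 30%).
#' @param direct2 Direct outcome effect of risk factor 2 (no mediation;
#'   default 0.15).
#' @param replication_coverage Fraction of proteins present in the
#'   replication panel (default 0.6).
#' @param n_phewas,phewas_planted Number of null phenome-wide outcomes and
#'   of planted true-effect outcomes (defaults 12 and 1).
#' @param block_size,rho,maf_range LD layout per block (defaults 25 SNPs,
#'   0.8, 0.05-0.45).
#' @return List of class `"pwmr_study"`: `proteins` and `replication`
#'   (named lists of summary-statistic data frames), `outcome`,
#'   `riskfactors`, `phewas` (list of `list(data, meta)`), `genes`, `ld`,
#'   `truth`.
#' @export
simulate_study <- function(seed, n_proteins = 20, n_causal = 5, theta = 0.2,
                           n_exposure = 20000, n_outcome = 20000,
                           n_replication = 619, n_riskfactor = 20000,
                           pqtl_per_protein = 3, ve_cis = 0.05,
                           n_riskfactors = 2, rf_instruments = 10,
                           ve_rf = 0.008,
                           beta1 = 0.3, direct1 = 0.14, direct2 = 0.15,
                           replication_coverage = 0.6,
                           n_phewas = 12, phewas_planted = 1,
                           block_size = 25, rho = 0.8,
                           maf_range = c(0.05, 0.45)) {
  stopifnot(n_causal <= n_proteins, n_riskfactors >= 1)
  set.seed(as.integer(seed))
  n_rf_blocks <- n_riskfactors * rf_instruments
  n_blocks <- n_proteins + n_rf_blocks
  m <- n_blocks * block_size
  mafs <- stats::runif(m, maf_range[1], maf_range[2])

  gen <- function(n) {
    simulate_genotypes(n, n_blocks, block_size, rho, maf_range, mafs = mafs)
  }
  panel <- gen(n_exposure)
  info <- panel$info
  center <- function(b) which(info$block == b)[ceiling(block_size / 2)]

  protein_ids <- sprintf("PROT%02d", seq_len(n_proteins))
  rf_ids <- sprintf("RF%d", seq_len(n_riskfactors))
  # causal proteins: split across replication-covered and uncovered indices
  n_cov <- ceiling(replication_coverage * n_proteins)
  k1 <- min(ceiling(n_causal * 0.6), n_cov)
  causal_idx <- c(seq_len(k1),
                  if (n_causal > k1) n_proteins - seq_len(n_causal - k1) + 1L)
  theta_p <- stats::setNames(numeric(n_proteins), protein_ids)
  theta_p[causal_idx] <- theta

  # per-protein cis effect vectors (pqtl_per_protein spaced causal SNPs)
  spacing <- max(1L, (block_size %/% 2L) %/% max(1L, pqtl_per_protein))
  cis_idx <- lapply(seq_len(n_proteins), function(p) {
    i <- center(p) + spacing * (seq_len(pqtl_per_protein) - 1L)
    i[i <= max(which(info$block == p))]
  })
  a_prot <- lapply(cis_idx, function(i) {
    a <- numeric(m); a[i] <- effect_for_ve(ve_cis, mafs[i]); a
  })
  # risk-factor instrument effect vectors
  a_rf <- lapply(seq_len(n_riskfactors), function(r) {
    blocks <- n_proteins + (r - 1L) * rf_instruments + seq_len(rf_instruments)
    i <- vapply(blocks, center, integer(1))
    a <- numeric(m); a[i] <- effect_for_ve(ve_rf, mafs[i]); a
  })
  beta1_rp <- matrix(0, n_riskfactors, n_proteins)
  beta1_rp[1L, causal_idx[1L]] <- beta1
  direct_r <- c(direct1, direct2, rep(0, max(0, n_riskfactors - 2L)))[seq_len(n_riskfactors)]

  # structural model evaluated in one cohort; returns trait matrix
  build <- function(geno) {
    n <- nrow(geno$G)
    RF <- vapply(seq_len(n_riskfactors),
                 function(r) .structural_trait(geno, a_rf[[r]]), numeric(n))
    X <- vapply(seq_len(n_proteins), function(p) {
      .structural_trait(geno, a_prot[[p]],
                        extra = drop(RF %*% beta1_rp[, p]))
    }, numeric(n))
    sig_y <- drop(X %*% theta_p) + drop(RF %*% direct_r)
    vy <- stats::var(sig_y)
    if (vy >= 1) stop("heritability >= 1", call. = FALSE)
    Y <- sig_y + stats::rnorm(n, 0, sqrt(1 - vy))
    list(RF = RF, X = X, Y = Y)
  }

  tr <- build(panel)
  proteins <- .marginal_gwas(panel$G, tr$X, info)
  names(proteins) <- protein_ids

  rep_ids <- protein_ids[seq_len(n_cov)]
  grep_ <- gen(n_replication)
  trr <- build(grep_)
  replication <- .marginal_gwas(grep_$G, trr$X[, seq_len(n_cov), drop = FALSE], info)
  names(replication) <- rep_ids

  gout <- gen(n_outcome)
  tro <- build(gout)
  outcome <- .marginal_gwas(gout$G, tro$Y, info)[[1L]]

  # phenome-wide outcomes measured in the outcome cohort: nulls plus
  # planted effects of the first causal protein
  n_ph <- n_phewas + phewas_planted
  PH <- matrix(stats::rnorm(n_outcome * n_ph), n_outcome, n_ph)
  if (phewas_planted > 0) {
    for (t in seq_len(phewas_planted)) {
      PH[, t] <- 0.3 * tro$X[, causal_idx[1L]] + stats::rnorm(n_outcome, 0, sqrt(1 - 0.09))
    }
  }
  ph_stats <- .marginal_gwas(gout$G, PH, info)
  ph_ids <- c(sprintf("PHEWAS_EFFECT%d", seq_len(phewas_planted)),
              sprintf("PHEWAS_NULL%02d", seq_len(n_phewas)))
  # deterministic case counts straddling the >500 filter; planted-effect
  # outcomes get the largest counts so they remain testable
  ph_cases <- round(seq(5000, 120, length.out = n_ph))
  phewas <- lapply(seq_len(n_ph), function(t) {
    list(data = ph_stats[[t]],
         meta = list(trait_id = ph_ids[t], trait_type = "binary",
                     n_cases = ph_cases[t], n_total = n_outcome))
  })
  names(phewas) <- ph_ids

  grf <- gen(n_riskfactor)
  trf <- build(grf)
  riskfactors <- .marginal_gwas(grf$G, trf$RF, info)
  names(riskfactors) <- rf_ids

  centers <- vapply(seq_len(n_proteins), center, integer(1))
  genes <- data.frame(
    gene_id = protein_ids, chrom = info$chrom[centers],
    tss = info$pos[centers],
    stringsAsFactors = FALSE
  )
  truth <- list(
    causal_proteins = protein_ids[sort(causal_idx)],
    theta = theta_p,
    replicated_panel = rep_ids,
    causal_snps = stats::setNames(
      lapply(cis_idx, function(i) info$snp_id[i]), protein_ids),
    riskfactor_instruments = stats::setNames(
      lapply(a_rf, function(a) info$snp_id[a != 0]), rf_ids),
    mediation = list(
      risk_factor = rf_ids[1L], mediator = protein_ids[causal_idx[1L]],
      beta1 = beta1, beta2 = theta, direct = direct1,
      c_prime = beta1 * theta + direct1,
      proportion = beta1 * theta / (beta1 * theta + direct1)
    ),
    phewas_effect = ph_ids[seq_len(phewas_planted)]
  )
  structure(list(
    proteins = proteins, replication = replication, outcome = outcome,
    riskfactors = riskfactors, phewas = phewas,
    genes = genes, ld = panel$ld, truth = truth,
    meta = list(seed = as.integer(seed), n_exposure = n_exposure,
                n_outcome = n_outcome, n_replication = n_replication,
                n_riskfactor = n_riskfactor)
  ), class = "pwmr_study")
}
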