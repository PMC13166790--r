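# Synthetic GWAS summary-statistics generator with known ground truth.
# Emulates the statistical structure of the study design: marginal per-SNP
# linear-regression summary statistics over AR(1) LD blocks, a quantitative
# pain-site-count outcome, large cis effects near a transcription start
# site, shared vs distinct causal variants at a locus, and risk factor ->
# protein -> outcome mediation chains. Every draw is reproducible under the
# mandatory seed.

#' Simulation configuration
#'
#' Validates and completes a scenario configuration. Unset effect-size
#' entries in `true_effects` are filled with scenario defaults:
#' `ve_exposure`/`ve_outcome` 0.01 (variance explained by a locus causal
#' variant), `ve_instrument` 0.005 (per instrument in multi-instrument MR
#' scenarios), `theta` (causal effect of exposure on outcome per SD) 0.5 for
#' H4, 0.15 for `effect_mr`, 0 otherwise; `h3_gap` 2 (SNP spacing between
#' the two distinct causal variants under H3); mediation chain `beta1` 0.2,
#' `beta2` 0.3, `direct` 0.14 (so the total effect is 0.2 and the true
#' proportion mediated 30%), with `rf_instruments` 10 and `med_cis_snps` 3.
#'
#' @param seed Integer RNG seed (mandatory).
#' @param scenario One of `H0, H1, H2, H3, H4, mediation_chain, null_mr,
#'   effect_mr`.
#' @param n_exposure,n_outcome,n_riskfactor GWAS sample sizes (defaults
#'   50000).
#' @param n_blocks,block_size LD layout (defaults 20 blocks of 50 SNPs).
#' @param rho Adjacent-SNP AR(1) latent correlation within a block
#'   (default 0.8; `|rho| < 1`).
#' @param maf_range Minor-allele-frequency range, inside `(0, 0.5)`.
#' @param true_effects Named list overriding scenario effect defaults.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       scenario = c("H0", "H1", "H2", "H3", "H4",
                                    "mediation_chain", "null_mr", "effect_mr"),
                       n_exposure = 50000, n_outcome = 50000,
                       n_riskfactor = 50000,
                       n_blocks = 20, block_size = 50, rho = 0.8,
                       maf_range = c(0.05, 0.45), true_effects = list()) {
  scenario <- match.arg(scenario)
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory", call. = FALSE)
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (!(maf_range[1] > 0 && maf_range[1] <= maf_range[2] && maf_range[2] < 0.5)) {
    stop("maf_range must satisfy 0 < low <= high < 0.5", call. = FALSE)
  }
  if (block_size < 2) stop("block_size must be >= 2", call. = FALSE)
  defaults <- list(
    ve_exposure = 0.01, ve_outcome = 0.01, ve_instrument = 0.005,
    theta = switch(scenario, H4 = 0.5, effect_mr = 0.15, 0),
    h3_gap = 2,
    beta1 = 0.2, beta2 = 0.3, direct = 0.14,
    rf_instruments = 10, med_cis_snps = 3,
    ve_rf = 0.005, ve_med_cis = 0.01
  )
  eff <- utils::modifyList(defaults, true_effects)
  if (scenario == "mediation_chain" &&
      n_blocks < eff$rf_instruments + 1) {
    stop("mediation_chain needs n_blocks >= rf_instruments + 1", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), scenario = scenario,
    n_exposure = n_exposure, n_outcome = n_outcome,
    n_riskfactor = n_riskfactor,
    n_blocks = n_blocks, block_size = block_size, rho = rho,
    maf_range = maf_range, true_effects = eff
  ), class = "sim_config")
}

# Non-palindromic allele pairs cycled over SNP index.
.ALLELE_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G",
                          "T", "C", "G", "A", "C", "T"),
                        ncol = 2, byrow = TRUE)

#' Simulate a genotype panel over AR(1) LD blocks
#'
#' Per block, a latent Gaussian AR(1) vector (adjacent correlation `rho`) is
#' drawn per individual and thresholded into 0/1/2 dosages at Hardy-Weinberg
#' genotype frequencies for the SNP's minor-allele frequency. Blocks are
#' mutually independent; the returned LD matrix is the empirical
#' within-block dosage correlation (block-diagonal, cross-block entries
#' exactly zero by construction).
#'
#' @param n Number of individuals.
#' @param n_blocks,block_size LD layout; `block_size >= 2`.
#' @param rho Adjacent-SNP latent correlation, `|rho| < 1`.
#' @param maf_range Range to draw per-SNP minor-allele frequencies from.
#' @param mafs Optional pre-drawn frequencies (length `n_blocks *
#'   block_size`), e.g. to share allele frequencies across cohorts.
#' @return List with `G` (n x m dosage matrix, columns named by SNP id),
#'   `info` (SNP table: id, chrom, pos, block, maf, alleles), `ld`
#'   (empirical signed LD matrix), `mafs`.
#' @export
simulate_genotypes <- function(n, n_blocks, block_size, rho,
                               maf_range = c(0.05, 0.45), mafs = NULL) {
  if (block_size < 2) stop("block_size must be >= 2", call. = FALSE)
  m <- n_blocks * block_size
  if (is.null(mafs)) {
    mafs <- stats::runif(m, maf_range[1], maf_range[2])
  } else if (length(mafs) != m) {
    stop("mafs must have length n_blocks * block_size", call. = FALSE)
  }
  block <- rep(seq_len(n_blocks), each = block_size)
  within <- rep(seq_len(block_size), times = n_blocks)
  # blocks cycle over the autosomes (chromosome 6 skipped so synthetic loci
  # never collide with the MHC exclusion), 25 Mb apart within a chromosome
  chrom_pool <- as.character(setdiff(1:22, 6))
  info <- data.frame(
    snp_id = sprintf("snp_%d_%d", block, within),
    chrom = chrom_pool[(block - 1L) %% 21L + 1L],
    pos = ((block - 1L) %/% 21L) * 25000000L + 1000000L +
      (within - 1L) * 5000L,
    block = block,
    maf = mafs,
    ea = .ALLELE_PAIRS[(seq_len(m) - 1L) %% nrow(.ALLELE_PAIRS) + 1L, 1L],
    oa = .ALLELE_PAIRS[(seq_len(m) - 1L) %% nrow(.ALLELE_PAIRS) + 1L, 2L],
    stringsAsFactors = FALSE
  )

  G <- matrix(0, n, m)
  ld <- matrix(0, m, m)
  sq <- sqrt(1 - rho^2)
  for (b in seq_len(n_blocks)) {
    cols <- which(block == b)
    Z <- matrix(stats::rnorm(n * block_size), n, block_size)
    if (rho != 0) {
      for (j in 2:block_size) Z[, j] <- rho * Z[, j - 1] + sq * Z[, j]
    }
    p <- mafs[cols]
    q0 <- stats::qnorm((1 - p)^2)       # below: 0 copies of effect allele
    q1 <- stats::qnorm(1 - p^2)         # above: 2 copies
    Gb <- sweep(Z, 2, q0, ">") + sweep(Z, 2, q1, ">")
    G[, cols] <- Gb
    ld[cols, cols] <- stats::cor(Gb)
  }
  colnames(G) <- info$snp_id
  dimnames(ld) <- list(info$snp_id, info$snp_id)
  diag(ld) <- 1
  list(G = G, info = info, ld = ld, mafs = mafs)
}

# Per-allele effect giving variance explained `ve` at frequency `maf` on a
# unit-variance trait.
effect_for_ve <- function(ve, maf) sqrt(ve / (2 * maf * (1 - maf)))

# Marginal simple-regression GWAS of one or more standardized traits on
# every dosage column. Y: n x T matrix (or vector). Returns a list of
# summary-statistic data frames, one per trait column.
.marginal_gwas <- function(G, Y, info) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Y <- scale(Y)                       # mean 0, sd 1 (n-1 denominator)
  gm <- colMeans(G)
  sxx <- colSums(G * G) - n * gm^2
  SXY <- crossprod(G, Y)              # m x T; Y centered
  lapply(seq_len(ncol(Y)), function(t) {
    beta <- unname(SXY[, t]) / unname(sxx)
    rss <- pmax((n - 1) - beta * SXY[, t], 1e-12)
    se <- sqrt(rss / ((n - 2) * sxx))
    pv <- pmax(2 * stats::pt(-abs(beta / se), df = n - 2), 1e-300)
    out <- data.frame(
      snp_id = info$snp_id, chrom = info$chrom, pos = info$pos,
      ea = info$ea, oa = info$oa, eaf = unname(gm) / 2,
      beta = beta, se = se, pvalue = pv, n = n,
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
  })
}

#' Marginal GWAS of a simulated quantitative trait
#'
#' Builds the trait `y = G %*% effects + noise`, with the noise variance
#' chosen so the trait has unit variance (error if the genetic variance is
#' 1 or more), standardizes it, and emits per-SNP simple-regression summary
#' statistics (beta, SE, p, EAF, n). Standardization makes the
#' `R2 = 2*EAF*(1-EAF)*beta^2` variance-explained formula applicable
#' downstream.
#'
#' @param geno Genotype panel from [simulate_genotypes()].
#' @param effects Per-allele effect vector (length = number of SNPs, or a
#'   named vector over SNP ids; missing ids get 0).
#' @return Summary-statistics data frame (see [read_sumstats()] `data`).
#' @export
simulate_trait_gwas <- function(geno, effects) {
  m <- ncol(geno$G)
  if (!is.null(names(effects))) {
    full <- stats::setNames(numeric(m), colnames(geno$G))
    full[names(effects)] <- effects
    effects <- full
  }
  if (length(effects) != m) stop("effects must cover every SNP", call. = FALSE)
  y <- .structural_trait(geno, effects)
  .marginal_gwas(geno$G, y, geno$info)[[1L]]
}

# Genetic component + scaled noise; errors when genetic variance >= 1.
.structural_trait <- function(geno, effects, extra = 0) {
  sig <- drop(geno$G %*% effects) + extra
  v <- stats::var(sig)
  if (v >= 1) stop("heritability >= 1: genetic variance exceeds trait variance",
                   call. = FALSE)
  sig + stats::rnorm(nrow(geno$G), 0, sqrt(1 - v))
}

#' Simulate a complete two-trait (or mediation) GWAS scenario
#'
#' Draws allele frequencies once, simulates an independent genotype cohort
#' per trait (two-sample design), builds the scenario's structural model and
#' returns marginal summary statistics with a ground-truth record:
#'
#' * `H0` no causal variant for either trait; `H1`/`H2` one causal variant
#'   for the exposure (resp. outcome) only; `H3` distinct causal variants
#'   `h3_gap` SNPs apart in the same block; `H4` one shared causal variant,
#'   the outcome inheriting `theta` times the exposure effect.
#' * `null_mr`/`effect_mr`: one causal exposure variant per block (mutually
#'   independent instruments) and outcome `theta * exposure + noise`.
#' * `mediation_chain`: risk factor with `rf_instruments` single-SNP blocks,
#'   a mediator protein with a cis locus in the next block, and outcome
#'   `beta2 * mediator + direct * risk factor + noise`, so the total effect
#'   is `beta1 * beta2 + direct`.
#'
#' @param config A [sim_config()] object.
#' @return List of class `"pwmr_scenario"` with `exposure`, `outcome`,
#'   optional `riskfactor` summary-statistic data frames, `ld`, `genes`
#'   (annotation usable by [select_cis_instruments()]), `truth`
#'   (ground-truth record) and `config`.
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  eff <- config$true_effects
  set.seed(config$seed)

  m <- config$n_blocks * config$block_size
  mafs <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  gen <- function(n) {
    simulate_genotypes(n, config$n_blocks, config$block_size, config$rho,
                       config$maf_range, mafs = mafs)
  }
  gx <- gen(config$n_exposure)
  info <- gx$info
  center <- function(b) which(info$block == b)[ceiling(config$block_size / 2)]
  zero <- numeric(m)
  a_for <- function(idx, ve) {
    a <- zero
    a[idx] <- effect_for_ve(ve, mafs[idx])
    a
  }
  sc <- config$scenario
  riskfactor <- NULL
  truth <- list(scenario = sc)

  if (sc %in% c("H0", "H1", "H2", "H3", "H4")) {
    c1 <- center(1L)
    a_x <- if (sc %in% c("H1", "H3", "H4")) a_for(c1, eff$ve_exposure) else zero
    x <- .structural_trait(gx, a_x)
    exposure <- .marginal_gwas(gx$G, x, info)[[1L]]

    gy <- gen(config$n_outcome)
    if (sc == "H4") {
      x_oc <- .structural_trait(gy, a_x)        # exposure realized in outcome cohort
      vy <- eff$theta^2 * stats::var(x_oc)
      if (vy >= 1) stop("heritability >= 1", call. = FALSE)
      y <- eff$theta * x_oc + stats::rnorm(config$n_outcome, 0, sqrt(1 - vy))
      a_y_marginal <- eff$theta * a_x
      causal_y <- info$snp_id[c1]
    } else if (sc %in% c("H2", "H3")) {
      c2 <- if (sc == "H2") c1 else c1 + eff$h3_gap
      if (c2 > max(which(info$block == 1L))) stop("h3_gap outside block", call. = FALSE)
      a_y <- a_for(c2, eff$ve_outcome)
      y <- .structural_trait(gy, a_y)
      a_y_marginal <- a_y
      causal_y <- info$snp_id[c2]
    } else {
      y <- .structural_trait(gy, zero)
      a_y_marginal <- zero
      causal_y <- character(0)
    }
    outcome <- .marginal_gwas(gy$G, y, info)[[1L]]
    truth$causal_snps <- list(
      exposure = if (sc %in% c("H1", "H3", "H4")) info$snp_id[c1] else character(0),
      outcome = causal_y
    )
    truth$true_causal_effect <- if (sc == "H4") eff$theta else 0
    truth$per_snp_effects <- list(
      exposure = stats::setNames(a_x, info$snp_id),
      outcome = stats::setNames(a_y_marginal, info$snp_id)
    )
  } else if (sc %in% c("null_mr", "effect_mr")) {
    cc <- vapply(seq_len(config$n_blocks), center, integer(1))
    a_x <- a_for(cc, eff$ve_instrument)
    x <- .structural_trait(gx, a_x)
    exposure <- .marginal_gwas(gx$G, x, info)[[1L]]

    gy <- gen(config$n_outcome)
    x_oc <- .structural_trait(gy, a_x)
    if (eff$theta == 0) {
      y <- stats::rnorm(config$n_outcome)
    } else {
      vy <- eff$theta^2 * stats::var(x_oc)
      if (vy >= 1) stop("heritability >= 1", call. = FALSE)
      y <- eff$theta * x_oc + stats::rnorm(config$n_outcome, 0, sqrt(1 - vy))
    }
    outcome <- .marginal_gwas(gy$G, y, info)[[1L]]
    truth$causal_snps <- list(exposure = info$snp_id[cc],
                              outcome = character(0))
    truth$true_causal_effect <- eff$theta
    truth$per_snp_effects <- list(
      exposure = stats::setNames(a_x, info$snp_id),
      outcome = stats::setNames(eff$theta * a_x, info$snp_id)
    )
  } else { # mediation_chain
    rf_idx <- vapply(seq_len(eff$rf_instruments), center, integer(1))
    med_block <- eff$rf_instruments + 1L
    med_start <- center(med_block)
    spacing <- max(1L, (config$block_size %/% 2L) %/% max(1L, eff$med_cis_snps))
    med_idx <- med_start + spacing * (seq_len(eff$med_cis_snps) - 1L)
    med_idx <- med_idx[med_idx <= max(which(info$block == med_block))]
    a_rf <- a_for(rf_idx, eff$ve_rf)
    a_med <- a_for(med_idx, eff$ve_med_cis)

    chain <- function(geno) {
      rf <- .structural_trait(geno, a_rf)
      mediator <- .structural_trait(geno, a_med, extra = eff$beta1 * rf)
      sig_y <- eff$beta2 * mediator + eff$direct * rf
      vy <- stats::var(sig_y)
      if (vy >= 1) stop("heritability >= 1", call. = FALSE)
      y <- sig_y + stats::rnorm(nrow(geno$G), 0, sqrt(1 - vy))
      list(rf = rf, mediator = mediator, y = y)
    }
    grf <- gen(config$n_riskfactor)
    riskfactor <- .marginal_gwas(grf$G, chain(grf)$rf, info)[[1L]]
    exposure <- .marginal_gwas(gx$G, chain(gx)$mediator, info)[[1L]]
    gy <- gen(config$n_outcome)
    outcome <- .marginal_gwas(gy$G, chain(gy)$y, info)[[1L]]

    truth$causal_snps <- list(
      riskfactor = info$snp_id[rf_idx],
      exposure = info$snp_id[med_idx],
      outcome = character(0)
    )
    truth$true_beta1 <- eff$beta1
    truth$true_beta2 <- eff$beta2
    truth$true_direct <- eff$direct
    truth$true_c_prime <- eff$beta1 * eff$beta2 + eff$direct
    truth$true_proportion <- eff$beta1 * eff$beta2 / truth$true_c_prime
  }

  cis_block <- if (sc == "mediation_chain") eff$rf_instruments + 1L else 1L
  genes <- data.frame(
    gene_id = c("EXPOSURE_GENE",
                if (sc == "mediation_chain") "MEDIATOR_GENE"),
    chrom = info$chrom[center(cis_block)],
    tss = info$pos[center(cis_block)],
    stringsAsFactors = FALSE
  )
  structure(list(
    exposure = exposure, outcome = outcome, riskfactor = riskfactor,
    ld = gx$ld, genes = genes, truth = truth, config = config
  ), class = "pwmr_scenario")
}

#' Write a simulated scenario to a directory
#'
#' Writes `exposure.tsv`, `outcome.tsv` (and `riskfactor.tsv` when present),
#' `ld.tsv`, `genes.tsv` and `meta.json` under `dir`, and the ground-truth
#' record under `dir/truth/truth.json` so that analysis inputs and truth
#' never share a directory.
#'
#' @param sim A `pwmr_scenario` from [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  stopifnot(inherits(sim, "pwmr_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_sumstats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(sim$outcome, file.path(dir, "outcome.tsv"))
  if (!is.null(sim$riskfactor)) {
    write_sumstats(sim$riskfactor, file.path(dir, "riskfactor.tsv"))
  }
  write_ld_matrix(sim$ld, file.path(dir, "ld.tsv"))
  utils::write.table(sim$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(scenario = sim$config$scenario, seed = sim$config$seed,
               n_exposure = sim$config$n_exposure,
               n_outcome = sim$config$n_outcome)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth", "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load scenario analysis inputs from a directory
#'
#' Reads back what [write_scenario()] wrote, except the ground truth: any
#' attempt to point this loader at a truth directory is refused, so truth
#' can never leak into analysis inputs.
#'
#' @param dir Scenario directory.
#' @return List with `exposure`, `outcome`, optional `riskfactor`, `ld`,
#'   `genes`.
#' @export
load_scenario <- function(dir) {
  parts <- strsplit(normalizePath(dir, mustWork = TRUE), "/")[[1L]]
  if ("truth" %in% parts) {
    stop("refusing to read analysis inputs from a truth directory", call. = FALSE)
  }
  out <- list(
    exposure = read_sumstats(file.path(dir, "exposure.tsv"),
                             trait_id = "exposure")$data,
    outcome = read_sumstats(file.path(dir, "outcome.tsv"),
                            trait_id = "outcome")$data,
    ld = read_ld_matrix(file.path(dir, "ld.tsv")),
    genes = utils::read.delim(file.path(dir, "genes.tsv"),
                              colClasses = c("character", "character", "integer"))
  )
  rf <- file.path(dir, "riskfactor.tsv")
  if (file.exists(rf)) {
    out$riskfactor <- read_sumstats(rf, trait_id = "riskfactor")$data
  }
  out
}
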