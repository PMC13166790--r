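# Study orchestration: discovery MR across the protein panel, replication,
# reverse MR with Steiger filtering, SMR/HEIDI, colocalization, evidence
# tiers, the mediation screen and phenome-wide MR, with TSV reports and a
# run log echoing every threshold.

#' Pipeline run configuration
#'
#' Bundles every threshold used by the pipeline stages. All fields must be
#' non-NULL; [run_all()] refuses to run otherwise, naming the missing
#' field. Defaults follow the study conventions: genome-wide significance
#' `5e-8`; clumping `r^2 < 0.001` in a 10,000 kb window; cis window 1 Mb
#' around the transcription start site; MHC exclusion chr6 26-34 Mb;
#' instrument `F > 10`; discovery FDR 0.05; replication nominal p < 0.05
#' with direction consistency; coloc priors `1e-4, 1e-4, 1e-5` with
#' PPH4 > 0.8 as strong evidence and a configurable tier-passing threshold
#' of 0.6; HEIDI pass at p >= 0.01; phenome-wide outcomes require more than
#' 500 cases.
#'
#' @param ... Overrides for any configuration field (see the function
#'   definition for the full list).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(
    p_threshold = 5e-8,
    cis_kb = 1000,
    mhc = list(chrom = "6", start = 26e6, end = 34e6),
    f_min = 10,
    clump_r2 = 0.001,
    clump_window_kb = 10000,
    palindrome_eaf_window = 0.08,
    standardized_betas = TRUE,
    ivw_model = "random",
    fdr_alpha = 0.05,
    replication_alpha = 0.05,
    presso_n_sim = 1000,
    coloc_p1 = 1e-4,
    coloc_p2 = 1e-4,
    coloc_p12 = 1e-5,
    coloc_window_kb = 500,
    prior_sd_quantitative = 0.15,
    prior_sd_binary = 0.2,
    pph4_strong = 0.8,
    coloc_pass_threshold = 0.6,
    smr_p_threshold = 5e-8,
    heidi_r2_min = 0.05,
    heidi_r2_max = 0.9,
    heidi_max_snps = 20,
    heidi_p_exposure = 1.57e-3,
    heidi_pass_p = 0.01,
    phewas_min_cases = 500,
    seed = 1L
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(override)] <- override
  structure(cfg, class = "run_config")
}

check_config <- function(config) {
  if (!inherits(config, "run_config")) stop("config must come from run_config()",
                                            call. = FALSE)
  required <- names(unclass(run_config()))
  bad <- union(setdiff(required, names(config)),
               names(config)[vapply(config, is.null, logical(1))])
  if (length(bad) > 0L) {
    stop("configuration field missing: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(config)
}

# instruments for a non-protein trait: genome-wide threshold + clump + F,
# with no cis restriction (and no MHC exclusion).
select_trait_instruments <- function(sumstats, ld, config) {
  d <- ss_data(sumstats)
  d <- d[d$pvalue < config$p_threshold, , drop = FALSE]
  d <- ld_clump(d, ld = ld, r2_max = config$clump_r2,
                window_kb = config$clump_window_kb)
  if (nrow(d) > 0L) {
    st <- compute_strength(d)
    d$r2 <- st$r2
    d$f_stat <- st$f_stat
    d <- d[d$f_stat > config$f_min, , drop = FALSE]
  }
  rownames(d) <- NULL
  d
}

# MR of a harmonized pair set: Wald when 1 instrument, IVW otherwise,
# with diagnostics where the instrument count permits.
mr_with_diagnostics <- function(pairs, exposure_id, outcome_id, config) {
  k <- nrow(pairs)
  est <- if (k == 1L) {
    wald_ratio(pairs, exposure_id, outcome_id)
  } else {
    ivw(pairs, model = config$ivw_model, exposure_id, outcome_id)
  }
  est$q_stat <- est$q_pvalue <- NA_real_
  est$egger_intercept <- est$egger_intercept_pvalue <- NA_real_
  est$presso_global_pvalue <- NA_real_
  est$presso_n_outliers <- NA_integer_
  if (k >= 2L) {
    q <- cochran_q(pairs)
    est$q_stat <- q$q_stat
    est$q_pvalue <- q$q_pvalue
  }
  if (k >= 3L) {
    eg <- mr_egger(pairs, exposure_id, outcome_id)
    est$egger_intercept <- eg$intercept
    est$egger_intercept_pvalue <- eg$intercept_pvalue
  }
  if (k >= 4L) {
    pr <- mr_presso(pairs, n_sim = config$presso_n_sim, seed = config$seed)
    est$presso_global_pvalue <- pr$global_pvalue
    est$presso_n_outliers <- length(pr$outlier_ids)
  }
  st <- steiger(pairs)
  est$steiger_pvalue <- st$steiger_pvalue
  est$steiger_correct_direction <- st$correct_direction
  est
}

#' Proteome-wide discovery MR
#'
#' Selects cis-pQTL instruments per protein, estimates the causal effect on
#' the outcome (Wald ratio with one instrument, IVW otherwise), attaches
#' heterogeneity / pleiotropy / MR-PRESSO / Steiger diagnostics where the
#' instrument count permits, and applies Benjamini-Hochberg FDR across all
#' tested proteins. Proteins with no surviving instruments are reported as
#' untestable, not as null results.
#'
#' @param proteins Named list of per-protein summary-statistic data frames.
#' @param outcome Outcome summary statistics.
#' @param genes Gene annotation data frame (`gene_id` = protein id,
#'   `chrom`, `tss`).
#' @param ld Signed LD matrix or `NULL`.
#' @param config [run_config()] object.
#' @return List with `results` (one row per tested protein, `qvalue` and
#'   `significant` columns), `untestable`, and `pairs` (named list of
#'   harmonized instrument sets).
#' @export
run_discovery <- function(proteins, outcome, genes, ld, config = run_config()) {
  check_config(config)
  if (is.null(outcome)) stop("outcome summary statistics missing", call. = FALSE)
  if (!isTRUE(config$standardized_betas)) {
    stop("F-statistic filtering requires betas on a standardized trait scale ",
         "(standardized_betas = TRUE)", call. = FALSE)
  }
  ids <- sort(names(proteins))
  rows <- list()
  pairs_list <- list()
  untestable <- data.frame(protein_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  for (id in ids) {
    gene <- genes[genes$gene_id == id, , drop = FALSE]
    if (nrow(gene) == 0L) stop("missing gene annotation for protein ", id,
                               call. = FALSE)
    inst <- select_cis_instruments(
      proteins[[id]], gene[1L, ], ld = ld,
      p_threshold = config$p_threshold, cis_kb = config$cis_kb,
      mhc = config$mhc, f_min = config$f_min,
      r2_max = config$clump_r2, window_kb = config$clump_window_kb
    )
    if (nrow(inst) == 0L) {
      untestable <- rbind(untestable, data.frame(
        protein_id = id, reason = "no surviving cis instruments",
        stringsAsFactors = FALSE))
      next
    }
    pr <- harmonize(inst, outcome,
                    palindrome_eaf_window = config$palindrome_eaf_window)
    if (nrow(pr) == 0L) {
      untestable <- rbind(untestable, data.frame(
        protein_id = id, reason = "no instruments shared with outcome",
        stringsAsFactors = FALSE))
      next
    }
    pairs_list[[id]] <- pr
    rows[[id]] <- mr_with_diagnostics(pr, id, "outcome", config)
  }
  results <- do.call(rbind, rows)
  if (!is.null(results)) {
    results$qvalue <- bh_fdr(results$pvalue)
    results$significant <- results$qvalue < config$fdr_alpha
    rownames(results) <- NULL
  }
  list(results = results, untestable = untestable, pairs = pairs_list)
}

#' Replication MR in an independent pQTL panel
#'
#' Re-estimates the protein -> outcome effect with instruments selected from
#' the replication panel. A protein replicates when the replication p-value
#' is below `replication_alpha` and the effect direction agrees with the
#' discovery estimate; proteins absent from the replication panel (or with
#' no surviving instruments there) get `replicated = NA` ("unavailable").
#'
#' @param discovery Result of [run_discovery()].
#' @param replication Named list of replication summary statistics (may
#'   cover only part of the protein panel).
#' @param outcome,genes,ld,config As in [run_discovery()].
#' @param protein_ids Proteins to attempt (default: discovery-significant).
#' @return Data frame: protein, replication beta/p, `replicated` flag.
#' @export
run_replication <- function(discovery, replication, outcome, genes, ld,
                            config = run_config(), protein_ids = NULL) {
  check_config(config)
  res <- discovery$results
  if (is.null(protein_ids)) {
    protein_ids <- res$exposure_id[res$significant]
  }
  out <- lapply(protein_ids, function(id) {
    row <- data.frame(protein_id = id, rep_beta = NA_real_, rep_se = NA_real_,
                      rep_pvalue = NA_real_, rep_n_snps = NA_integer_,
                      replicated = NA, stringsAsFactors = FALSE)
    if (!(id %in% names(replication))) return(row)
    gene <- genes[genes$gene_id == id, , drop = FALSE]
    inst <- select_cis_instruments(
      replication[[id]], gene[1L, ], ld = ld,
      p_threshold = config$p_threshold, cis_kb = config$cis_kb,
      mhc = config$mhc, f_min = config$f_min,
      r2_max = config$clump_r2, window_kb = config$clump_window_kb
    )
    if (nrow(inst) == 0L) return(row)
    pr <- harmonize(inst, outcome,
                    palindrome_eaf_window = config$palindrome_eaf_window)
    if (nrow(pr) == 0L) return(row)
    est <- if (nrow(pr) == 1L) wald_ratio(pr, id, "outcome") else
      ivw(pr, model = config$ivw_model, id, "outcome")
    disc_beta <- res$beta[res$exposure_id == id]
    row$rep_beta <- est$beta
    row$rep_se <- est$se
    row$rep_pvalue <- est$pvalue
    row$rep_n_snps <- est$n_snps
    row$replicated <- est$pvalue < config$replication_alpha &&
      sign(est$beta) == sign(disc_beta)
    row
  })
  do.call(rbind, out)
}

#' Reverse MR and per-instrument Steiger filtering
#'
#' Selects instruments for the outcome (genome-wide significance, clumping
#' and F-filter; no cis restriction) and estimates outcome -> protein
#' effects. `reverse_null` is `TRUE` when the reverse IVW p-value is at
#' least 0.05. `steiger_pass` requires every forward instrument to have a
#' significantly stronger association with the protein than with the
#' outcome (per-instrument Steiger p < 0.05 with the correct direction).
#'
#' @param outcome Outcome summary statistics (used as exposure here).
#' @param proteins Named list of protein summary statistics.
#' @param forward_pairs Named list of harmonized forward instrument sets
#'   (from [run_discovery()]).
#' @param ld,config As elsewhere.
#' @param protein_ids Proteins to test (default: names of `forward_pairs`).
#' @return Data frame: protein, reverse estimate and p, `reverse_null`,
#'   `steiger_pass`, `n_reverse_snps`.
#' @export
run_reverse <- function(outcome, proteins, forward_pairs, ld,
                        config = run_config(), protein_ids = NULL) {
  check_config(config)
  if (is.null(protein_ids)) protein_ids <- names(forward_pairs)
  rev_inst <- select_trait_instruments(outcome, ld, config)
  out <- lapply(protein_ids, function(id) {
    fp <- forward_pairs[[id]]
    st_each <- lapply(seq_len(nrow(fp)), function(i) steiger(fp[i, , drop = FALSE]))
    steiger_pass <- all(vapply(st_each, function(s)
      s$correct_direction && s$steiger_pvalue < 0.05, logical(1)))
    row <- data.frame(protein_id = id, rev_beta = NA_real_, rev_se = NA_real_,
                      rev_pvalue = NA_real_, n_reverse_snps = nrow(rev_inst),
                      reverse_null = NA, steiger_pass = steiger_pass,
                      stringsAsFactors = FALSE)
    if (nrow(rev_inst) == 0L) return(row)   # untestable, flagged by NA
    pr <- harmonize(rev_inst, proteins[[id]],
                    palindrome_eaf_window = config$palindrome_eaf_window)
    if (nrow(pr) == 0L) return(row)
    est <- if (nrow(pr) == 1L) wald_ratio(pr, "outcome", id) else
      ivw(pr, model = config$ivw_model, "outcome", id)
    row$rev_beta <- est$beta
    row$rev_se <- est$se
    row$rev_pvalue <- est$pvalue
    row$reverse_null <- est$pvalue >= 0.05
    row
  })
  do.call(rbind, out)
}

#' SMR test at the top cis-QTL plus the HEIDI linkage test, per protein
#'
#' The top QTL is the harmonized instrument with the smallest exposure
#' p-value (it must pass `smr_p_threshold`). HEIDI compares cis-region SNPs
#' in intermediate LD with the top QTL; fewer than three eligible SNPs
#' yields a missing HEIDI p-value, reported as NA and not counted as a
#' failure.
#'
#' @param proteins Named list of protein summary statistics (full cis
#'   region, not just instruments).
#' @param outcome,genes,ld,config As elsewhere.
#' @param protein_ids Proteins to test.
#' @return Data frame mirroring the usual reporting: probe, top SNP,
#'   `b_smr`, `p_smr`, `heidi_p` (or NA), `n_heidi_snps`, pass flags.
#' @export
run_smr_heidi <- function(proteins, outcome, genes, ld,
                          config = run_config(), protein_ids) {
  check_config(config)
  out <- lapply(protein_ids, function(id) {
    gene <- genes[genes$gene_id == id, , drop = FALSE][1L, ]
    d <- ss_data(proteins[[id]])
    cis <- d[d$chrom == gene$chrom &
               abs(d$pos - gene$tss) <= config$cis_kb * 1000, , drop = FALSE]
    pr <- harmonize(cis, outcome,
                    palindrome_eaf_window = config$palindrome_eaf_window)
    pr_sig <- pr[pr$pvalue_gx < config$smr_p_threshold, , drop = FALSE]
    if (nrow(pr_sig) == 0L) {
      return(data.frame(probe_id = id, top_snp = NA_character_,
                        b_smr = NA_real_, se_smr = NA_real_, p_smr = NA_real_,
                        heidi_p = NA_real_, n_heidi_snps = 0L,
                        smr_pass = NA, heidi_pass = NA,
                        stringsAsFactors = FALSE))
    }
    top <- pr_sig[which.min(pr_sig$pvalue_gx), , drop = FALSE]
    res <- smr_test(top, probe_id = id)
    hd <- heidi_test(pr, ld, top$snp_id,
                     r2_min = config$heidi_r2_min, r2_max = config$heidi_r2_max,
                     max_snps = config$heidi_max_snps,
                     p_exposure_max = config$heidi_p_exposure)
    res$heidi_p <- hd$heidi_p
    res$n_heidi_snps <- hd$n_used
    res$smr_pass <- res$p_smr < 0.05
    res$heidi_pass <- if (is.na(hd$heidi_p)) NA else hd$heidi_p >= config$heidi_pass_p
    res
  })
  do.call(rbind, out)
}

#' Bayesian colocalization at each protein's cis locus
#'
#' The locus is the set of SNPs within `coloc_window_kb` of the lead
#' instrument shared by both traits. Reports the five posterior hypothesis
#' probabilities, the combined PPH3+PPH4 column, and two pass flags: strong
#' evidence (`pph4 > pph4_strong`) and the tier-rule pass
#' (`pph4 > coloc_pass_threshold`).
#'
#' @param proteins,outcome,config As elsewhere.
#' @param pairs Named list of harmonized instrument sets (lead SNP source).
#' @param outcome_type `"quantitative"` or `"binary"` (effect-prior SD
#'   switch).
#' @param protein_ids Proteins to test.
#' @return Data frame, one row per locus.
#' @export
run_coloc <- function(proteins, outcome, pairs, config = run_config(),
                      protein_ids = names(pairs),
                      outcome_type = "quantitative") {
  check_config(config)
  prior_sd_out <- if (outcome_type == "binary") config$prior_sd_binary else
    config$prior_sd_quantitative
  out <- lapply(protein_ids, function(id) {
    pp <- pairs[[id]]
    lead <- pp[which.min(pp$pvalue_gx), , drop = FALSE]
    d1 <- ss_data(proteins[[id]])
    d1 <- d1[d1$chrom == lead$chrom &
               abs(d1$pos - lead$pos) <= config$coloc_window_kb * 1000, , drop = FALSE]
    res <- coloc_abf(d1, outcome,
                     p1 = config$coloc_p1, p2 = config$coloc_p2,
                     p12 = config$coloc_p12,
                     prior_sd1 = config$prior_sd_quantitative,
                     prior_sd2 = prior_sd_out, locus_id = id)
    res$coloc_strong <- res$pph4 > config$pph4_strong
    res$coloc_pass <- res$pph4 > config$coloc_pass_threshold
    res
  })
  do.call(rbind, out)
}

#' Evidence tier for one protein from its validation flags
#'
#' Deterministic rule: proteins without a successful, direction-consistent
#' replication (flag `NA` for unavailable, or `FALSE`) are Tier 3;
#' replicated proteins failing any validation (SMR, HEIDI, colocalization,
#' reverse-MR null, Steiger) are Tier 2; replicated proteins passing all of
#' them are Tier 1. An untestable HEIDI (`NA`) is not counted as a failure.
#'
#' @param replicated `TRUE`/`FALSE`/`NA` (NA = replication unavailable).
#' @param smr_pass,coloc_pass,reverse_null,steiger_pass Logical flags.
#' @param heidi_pass Logical or `NA` (untestable).
#' @return Integer tier (1, 2 or 3).
#' @export
classify_tier <- function(replicated, smr_pass, heidi_pass, coloc_pass,
                          reverse_null, steiger_pass) {
  if (is.na(replicated) || !replicated) return(3L)
  if (is.na(smr_pass)) stop("replicated protein with missing SMR flag: pipeline bug",
                            call. = FALSE)
  heidi_ok <- is.na(heidi_pass) || heidi_pass
  all_pass <- smr_pass && heidi_ok && coloc_pass &&
    isTRUE(reverse_null) && isTRUE(steiger_pass)
  if (all_pass) 1L else 2L
}

#' Phenome-wide MR of one protein's instruments across many outcomes
#'
#' Binary outcomes with 500 or fewer cases are excluded before testing
#' (strictly more than `phewas_min_cases` cases required). Remaining
#' outcomes get a Wald/IVW estimate and Benjamini-Hochberg FDR across the
#' retained set.
#'
#' @param instruments Instrument summary statistics for the protein (e.g.
#'   from [select_cis_instruments()]).
#' @param outcomes Named list of `list(data = sumstats data frame, meta =
#'   trait metadata)` entries.
#' @param config As elsewhere.
#' @param exposure_id Label for the exposure protein.
#' @return List with `results` (tested outcomes, q-values, `significant`)
#'   and `excluded` (case-count exclusions).
#' @export
run_phewas <- function(instruments, outcomes, config = run_config(),
                       exposure_id = "protein") {
  check_config(config)
  n_cases <- vapply(outcomes, function(o) {
    nc <- o$meta$n_cases
    if (is.null(nc)) NA_real_ else as.numeric(nc)
  }, numeric(1))
  is_binary <- vapply(outcomes, function(o)
    identical(o$meta$trait_type, "binary"), logical(1))
  drop <- is_binary & (is.na(n_cases) | n_cases <= config$phewas_min_cases)
  excluded <- data.frame(outcome_id = names(outcomes)[drop],
                         n_cases = n_cases[drop],
                         reason = "n_cases <= minimum",
                         stringsAsFactors = FALSE)
  kept <- names(outcomes)[!drop]
  rows <- lapply(kept, function(id) {
    pr <- harmonize(instruments, outcomes[[id]]$data,
                    palindrome_eaf_window = config$palindrome_eaf_window)
    if (nrow(pr) == 0L) return(NULL)
    est <- if (nrow(pr) == 1L) wald_ratio(pr, exposure_id, id) else
      ivw(pr, model = config$ivw_model, exposure_id, id)
    est$n_cases <- n_cases[[id]]
    est
  })
  results <- do.call(rbind, rows)
  if (!is.null(results)) {
    results$qvalue <- bh_fdr(results$pvalue)
    results$significant <- results$qvalue < config$fdr_alpha
    rownames(results) <- NULL
  }
  list(results = results, excluded = excluded)
}

#' Mediation screen: risk factors -> proteins -> outcome
#'
#' Three MR legs with FDR control at each: total effects of risk factors on
#' the outcome (`c_prime`, with an Egger pleiotropy check when at least
#' three instruments), risk-factor effects on each candidate protein
#' (`beta1`), and the discovery protein -> outcome estimates (`beta2`,
#' already FDR-controlled). Combinations significant on all three legs are
#' decomposed with [mediate()]; the reliability gate requires a Sobel
#' p < 0.05, direction agreement between mediated and total effects, and no
#' pleiotropy in the total-effect analysis.
#'
#' @param riskfactors Named list of risk-factor summary statistics.
#' @param proteins Named list of protein summary statistics.
#' @param outcome Outcome summary statistics.
#' @param discovery Result of [run_discovery()] (supplies `beta2`).
#' @param ld,config As elsewhere.
#' @param protein_ids Candidate mediators (default: discovery-significant).
#' @return List with `mediation` (one row per screened combination),
#'   `total` and `beta1` leg tables.
#' @export
run_mediation <- function(riskfactors, proteins, outcome, discovery, ld,
                          config = run_config(), protein_ids = NULL) {
  check_config(config)
  res <- discovery$results
  if (is.null(protein_ids)) protein_ids <- res$exposure_id[res$significant]
  rf_ids <- sort(names(riskfactors))

  rf_inst <- lapply(riskfactors[rf_ids], select_trait_instruments, ld = ld,
                    config = config)
  total <- do.call(rbind, lapply(rf_ids, function(r) {
    pr <- harmonize(rf_inst[[r]], outcome,
                    palindrome_eaf_window = config$palindrome_eaf_window)
    if (nrow(pr) == 0L) return(NULL)
    est <- mr_with_diagnostics(pr, r, "outcome", config)
    est
  }))
  if (is.null(total) || nrow(total) == 0L) {
    return(list(mediation = NULL, total = NULL, beta1 = NULL))
  }
  total$qvalue <- bh_fdr(total$pvalue)
  total$significant <- total$qvalue < config$fdr_alpha

  beta1 <- do.call(rbind, lapply(rf_ids, function(r) {
    do.call(rbind, lapply(protein_ids, function(p) {
      pr <- harmonize(rf_inst[[r]], proteins[[p]],
                      palindrome_eaf_window = config$palindrome_eaf_window)
      if (nrow(pr) == 0L) return(NULL)
      if (nrow(pr) == 1L) wald_ratio(pr, r, p) else
        ivw(pr, model = config$ivw_model, r, p)
    }))
  }))
  if (!is.null(beta1) && nrow(beta1) > 0L) {
    beta1$qvalue <- bh_fdr(beta1$pvalue)
    beta1$significant <- beta1$qvalue < config$fdr_alpha
  }

  combos <- list()
  for (r in rf_ids) {
    t_row <- total[total$exposure_id == r, , drop = FALSE]
    if (nrow(t_row) == 0L || !t_row$significant) next
    for (p in protein_ids) {
      b1 <- beta1[beta1$exposure_id == r & beta1$outcome_id == p, , drop = FALSE]
      b2 <- res[res$exposure_id == p, , drop = FALSE]
      if (nrow(b1) == 0L || !b1$significant) next
      if (nrow(b2) == 0L || !b2$significant) next
      combos[[paste(r, p, sep = ".")]] <-
        mediate(b1, b2, t_row,
                total_pleiotropy_p = t_row$egger_intercept_pvalue)
    }
  }
  list(mediation = if (length(combos)) do.call(rbind, combos) else NULL,
       total = total, beta1 = beta1)
}

write_report <- function(df, path) {
  if (is.null(df)) df <- data.frame(note = "no rows")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full study workflow and write all reports
#'
#' Discovery -> replication -> reverse MR / Steiger -> SMR/HEIDI ->
#' colocalization -> evidence tiers -> mediation screen -> phenome-wide MR,
#' on a simulated (or equivalently structured) study bundle. Writes
#' `discovery.tsv`, `replication.tsv`, `reverse.tsv`, `smr_heidi.tsv`,
#' `coloc.tsv`, `tiers.tsv`, `mediation.tsv`, `phewas.tsv`, a
#' `truth_comparison.tsv` when ground truth is present, and `run_log.txt`
#' echoing every threshold and seed. Reruns with the same inputs and
#' configuration are byte-identical.
#'
#' @param study A `pwmr_study` bundle (see [simulate_study()]) or a list
#'   with the same fields.
#' @param config [run_config()] object.
#' @param out_dir Report directory (created if needed).
#' @return List with every stage's tables, invisibly.
#' @export
run_all <- function(study, config = run_config(), out_dir) {
  check_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  discovery <- run_discovery(study$proteins, study$outcome, study$genes,
                             study$ld, config)
  if (is.null(discovery$results)) {
    stop("stage discovery: no testable protein", call. = FALSE)
  }
  sig <- discovery$results$exposure_id[discovery$results$significant]

  replication <- run_replication(discovery, study$replication, study$outcome,
                                 study$genes, study$ld, config)
  reverse <- run_reverse(study$outcome, study$proteins, discovery$pairs,
                         study$ld, config, protein_ids = sig)
  smr <- run_smr_heidi(study$proteins, study$outcome, study$genes, study$ld,
                       config, protein_ids = sig)
  coloc <- if (length(sig) > 0L) {
    run_coloc(study$proteins, study$outcome, discovery$pairs, config,
              protein_ids = sig)
  } else NULL

  tiers <- if (length(sig) > 0L) {
    flags <- data.frame(
      protein_id = sig,
      replicated = replication$replicated[match(sig, replication$protein_id)],
      smr_pass = smr$smr_pass[match(sig, smr$probe_id)],
      heidi_pass = smr$heidi_pass[match(sig, smr$probe_id)],
      coloc_pass = coloc$coloc_pass[match(sig, coloc$locus_id)],
      reverse_null = reverse$reverse_null[match(sig, reverse$protein_id)],
      steiger_pass = reverse$steiger_pass[match(sig, reverse$protein_id)],
      stringsAsFactors = FALSE
    )
    flags$tier <- vapply(seq_len(nrow(flags)), function(i) {
      classify_tier(flags$replicated[i], flags$smr_pass[i],
                    flags$heidi_pass[i], flags$coloc_pass[i],
                    flags$reverse_null[i], flags$steiger_pass[i])
    }, integer(1))
    flags
  } else NULL

  mediation <- run_mediation(study$riskfactors, study$proteins, study$outcome,
                             discovery, study$ld, config)
  phewas <- if (length(sig) > 0L && length(study$phewas) > 0L) {
    lead <- sig[1L]
    fp <- discovery$pairs[[lead]]
    inst <- data.frame(
      snp_id = fp$snp_id, chrom = fp$chrom, pos = fp$pos,
      ea = fp$ea, oa = fp$oa, eaf = fp$eaf,
      beta = fp$beta_gx, se = fp$se_gx, pvalue = fp$pvalue_gx, n = fp$n_gx,
      stringsAsFactors = FALSE
    )
    run_phewas(inst, study$phewas, config, exposure_id = lead)
  } else NULL

  write_report(discovery$results, file.path(out_dir, "discovery.tsv"))
  write_report(discovery$untestable, file.path(out_dir, "untestable.tsv"))
  write_report(replication, file.path(out_dir, "replication.tsv"))
  write_report(reverse, file.path(out_dir, "reverse.tsv"))
  write_report(smr, file.path(out_dir, "smr_heidi.tsv"))
  write_report(coloc, file.path(out_dir, "coloc.tsv"))
  write_report(tiers, file.path(out_dir, "tiers.tsv"))
  write_report(mediation$mediation, file.path(out_dir, "mediation.tsv"))
  write_report(if (is.null(phewas)) NULL else phewas$results,
               file.path(out_dir, "phewas.tsv"))

  if (!is.null(study$truth)) {
    truth_cmp <- data.frame(
      protein_id = names(study$truth$theta),
      true_effect = as.numeric(study$truth$theta),
      detected = names(study$truth$theta) %in% sig,
      stringsAsFactors = FALSE
    )
    write_report(truth_cmp, file.path(out_dir, "truth_comparison.tsv"))
  }

  log_lines <- c(
    "pwmr run log",
    paste0("seed=", config$seed),
    vapply(setdiff(names(config), "mhc"), function(nm)
      paste0(nm, "=", paste(format(config[[nm]]), collapse = ",")),
      character(1)),
    paste0("mhc=", config$mhc$chrom, ":", format(config$mhc$start),
           "-", format(config$mhc$end))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(discovery = discovery, replication = replication,
                 reverse = reverse, smr_heidi = smr, coloc = coloc,
                 tiers = tiers, mediation = mediation, phewas = phewas))
}
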