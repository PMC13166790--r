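# cis-pQTL instrument selection: per-variant strength (R2, F), greedy LD
# clumping, and the full cis filter chain (significance, cis window, MHC
# exclusion, clumping, F threshold).

#' Variance explained and F-statistic of a genetic instrument
#'
#' For a variant with effect-allele frequency `eaf`, per-allele effect `beta`
#' on a variance-standardized trait and sample size `n`, the variance
#' explained is `R2 = 2 * eaf * (1 - eaf) * beta^2` and the instrument
#' strength `F = R2 * (n - 2) / (1 - R2)`. `R2` is only a variance fraction
#' when the trait is standardized; callers are responsible for that scale.
#'
#' @param v Data frame of variants with columns `eaf`, `beta`, `n` (e.g. a
#'   `sumstats` data slot), or a `sumstats` object.
#' @return Data frame with columns `r2` and `f_stat`, one row per variant.
#' @export
compute_strength <- function(v) {
  d <- ss_data(v)
  r2 <- 2 * d$eaf * (1 - d$eaf) * d$beta^2
  if (any(r2 >= 1)) {
    stop("variance explained >= 1; betas are not on a standardized-trait scale",
         call. = FALSE)
  }
  data.frame(r2 = r2, f_stat = r2 * (d$n - 2) / (1 - r2))
}

#' Greedy LD clumping of association signals
#'
#' Sorts candidates by ascending p-value (ties broken by chromosome,
#' position, then SNP id), accepts the best remaining signal, and discards
#' every candidate on the same chromosome within `window_kb` of an accepted
#' SNP whose squared LD correlation with it is at least `r2_max`. SNPs absent
#' from the LD matrix are treated as unlinked and recorded in the
#' `"not_in_ld"` attribute.
#'
#' @param candidates Variant data frame (columns `snp_id, chrom, pos, pvalue`).
#' @param ld Signed LD matrix (see [read_ld_matrix()]), or `NULL` to treat
#'   all pairs as unlinked.
#' @param r2_max Squared-correlation threshold (default 0.001).
#' @param window_kb Clump window in kb, center-to-center (default 10000,
#'   i.e. +/- 10 Mb).
#' @return The retained subset of `candidates`, in acceptance order.
#' @export
ld_clump <- function(candidates, ld = NULL, r2_max = 0.001, window_kb = 10000) {
  d <- ss_data(candidates)
  if (nrow(d) == 0L) return(d)
  ord <- order(d$pvalue, d$chrom, d$pos, d$snp_id)
  d <- d[ord, , drop = FALSE]
  in_ld <- if (is.null(ld)) rep(FALSE, nrow(d)) else d$snp_id %in% rownames(ld)
  window_bp <- window_kb * 1000

  active <- rep(TRUE, nrow(d))
  take <- integer(0)
  for (i in seq_len(nrow(d))) {
    if (!active[i]) next
    take <- c(take, i)
    active[i] <- FALSE
    j <- which(active & d$chrom == d$chrom[i] &
                 abs(d$pos - d$pos[i]) <= window_bp)
    if (length(j) > 0L && in_ld[i]) {
      jl <- j[in_ld[j]]
      if (length(jl) > 0L) {
        r2 <- ld[d$snp_id[i], d$snp_id[jl]]^2
        active[jl[r2 >= r2_max]] <- FALSE
      }
    }
  }
  out <- d[take, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "not_in_ld") <- d$snp_id[!in_ld]
  out
}

#' Select cis-pQTL instruments for one protein
#'
#' Applies, in order: genome-wide significance (`pvalue < p_threshold`); the
#' cis window (`|pos - tss| <= cis_kb * 1000` on the gene's chromosome); MHC
#' exclusion (closed interval, default chr6 26-34 Mb); greedy LD clumping;
#' and the instrument-strength filter `F > f_min`. Attrition counts per
#' filter are attached as attribute `"attrition"`.
#'
#' @param sumstats Per-protein summary statistics (`sumstats` object or data
#'   frame); betas must be on a standardized protein scale for the F filter
#'   to be meaningful.
#' @param gene List or one-row data frame with `gene_id`, `chrom`, `tss`.
#' @param ld Signed LD matrix or `NULL`.
#' @param p_threshold Significance threshold (default `5e-8`).
#' @param cis_kb Half-width of the cis window around the transcription start
#'   site in kb (default 1000, i.e. 1 Mb).
#' @param mhc List with `chrom`, `start`, `end` delimiting the major
#'   histocompatibility complex region to exclude.
#' @param f_min Minimum F-statistic, exclusive (default 10).
#' @param r2_max,window_kb Clumping parameters passed to [ld_clump()].
#' @return Instrument data frame: the retained variants with `r2`, `f_stat`
#'   and `is_cis` columns appended.
#' @export
select_cis_instruments <- function(sumstats, gene, ld = NULL,
                                   p_threshold = 5e-8, cis_kb = 1000,
                                   mhc = list(chrom = "6", start = 26e6, end = 34e6),
                                   f_min = 10, r2_max = 0.001,
                                   window_kb = 10000) {
  d <- ss_data(sumstats)
  if (is.null(gene) || is.na(gene[["gene_id"]]) || is.na(gene[["tss"]])) {
    stop("missing gene annotation for protein", call. = FALSE)
  }
  gene <- as.list(gene)
  att <- c(input = nrow(d))

  d <- d[d$pvalue < p_threshold, , drop = FALSE]
  att["significant"] <- nrow(d)

  cis <- d$chrom == gene$chrom & abs(d$pos - gene$tss) <= cis_kb * 1000
  d <- d[cis, , drop = FALSE]
  att["cis"] <- nrow(d)

  in_mhc <- d$chrom == mhc$chrom & d$pos >= mhc$start & d$pos <= mhc$end
  d <- d[!in_mhc, , drop = FALSE]
  att["non_mhc"] <- nrow(d)

  d <- ld_clump(d, ld = ld, r2_max = r2_max, window_kb = window_kb)
  not_in_ld <- attr(d, "not_in_ld")
  att["clumped"] <- nrow(d)

  if (nrow(d) > 0L) {
    st <- compute_strength(d)
    d$r2 <- st$r2
    d$f_stat <- st$f_stat
    d <- d[d$f_stat > f_min, , drop = FALSE]
  } else {
    d$r2 <- numeric(0)
    d$f_stat <- numeric(0)
  }
  att["strong"] <- nrow(d)
  d$is_cis <- rep(TRUE, nrow(d))
  rownames(d) <- NULL
  attr(d, "attrition") <- att
  attr(d, "not_in_ld") <- not_in_ld
  d
}
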