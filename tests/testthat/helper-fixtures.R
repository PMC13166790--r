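# Small in-code fixtures shared across the suite.

# A valid summary-statistics data frame; fields overridable per column.
make_ss <- function(n = 4, snp_id = sprintf("rs%d", seq_len(n)),
                    chrom = "1", pos = seq_len(n) * 1000L,
                    ea = "A", oa = "G", eaf = 0.3, beta = 0.1, se = 0.02,
                    pvalue = 1e-9, n_samp = 10000) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos, ea = ea, oa = oa,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n_samp,
             stringsAsFactors = FALSE)
}

write_ss_file <- function(df, path = tempfile(fileext = ".tsv")) {
  pwmr::write_sumstats(df, path)
  path
}

# Harmonized-pair set straight from numbers.
make_pairs <- function(beta_gx, beta_gy, se_gx = 0.02, se_gy = 0.02,
                       eaf = 0.3, n_gx = 50000, n_gy = 50000,
                       snp_id = sprintf("rs%d", seq_along(beta_gx))) {
  data.frame(snp_id = snp_id,
             beta_gx = beta_gx, se_gx = se_gx,
             beta_gy = beta_gy, se_gy = se_gy,
             eaf = eaf, eaf_gy = eaf, n_gx = n_gx, n_gy = n_gy,
             pvalue_gx = 2 * stats::pnorm(-abs(beta_gx / se_gx)),
             pvalue_gy = 2 * stats::pnorm(-abs(beta_gy / se_gy)),
             stringsAsFactors = FALSE)
}

# LD matrix with given ids and pairwise entries.
make_ld <- function(ids, r = NULL) {
  m <- diag(length(ids))
  dimnames(m) <- list(ids, ids)
  if (!is.null(r)) {
    for (k in seq_len(nrow(r))) {
      i <- as.character(r[k, 1]); j <- as.character(r[k, 2])
      m[i, j] <- m[j, i] <- as.numeric(r[k, 3])
    }
  }
  m
}
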