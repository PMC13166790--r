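test_that("instrument strength matches the R2 and F closed forms", {
  st <- compute_strength(data.frame(eaf = 0.5, beta = 0.1, n = 10000))
  expect_equal(st$r2, 0.005)
  expect_equal(st$f_stat, 0.005 * 9998 / 0.995, tolerance = 1e-12)

  expect_equal(compute_strength(data.frame(eaf = 0.4, beta = 0, n = 100))$f_stat, 0)

  # r2 -> 0 monotonically as eaf -> 0 at fixed beta
  r2 <- compute_strength(data.frame(eaf = c(0.4, 0.1, 0.01, 0.001),
                                    beta = 0.3, n = 1000))$r2
  expect_true(all(diff(r2) < 0))

  # f_stat strictly increases with n at fixed r2
  f <- compute_strength(data.frame(eaf = 0.3, beta = 0.1,
                                   n = c(1000, 5000, 50000)))$f_stat
  expect_true(all(diff(f) > 0))

  expect_error(compute_strength(data.frame(eaf = 0.5, beta = 2, n = 10)),
               "standardized")
})

test_that("ld_clump discards dominated neighbors and keeps independent ones", {
  cand <- make_ss(n = 2, snp_id = c("a", "b"), pos = c(1000L, 6000L),
                  pvalue = c(1e-12, 1e-9))
  ld <- make_ld(c("a", "b"), data.frame(i = "a", j = "b", r = sqrt(0.5)))
  expect_equal(ld_clump(cand, ld, r2_max = 0.001)$snp_id, "a")

  ld2 <- make_ld(c("a", "b"), data.frame(i = "a", j = "b", r = sqrt(0.0005)))
  expect_setequal(ld_clump(cand, ld2, r2_max = 0.001)$snp_id, c("a", "b"))

  # outside the window: retained regardless of LD
  cand$pos <- c(1000L, 20000000L)
  expect_setequal(ld_clump(cand, ld, r2_max = 0.001, window_kb = 10000)$snp_id,
                  c("a", "b"))
})

test_that("ld_clump equals a brute-force application of the greedy rule", {
  greedy_oracle <- function(d, ld, r2_max, window_bp) {
    d <- d[order(d$pvalue, d$chrom, d$pos, d$snp_id), ]
    kept <- character(0)
    for (i in seq_len(nrow(d))) {
      ok <- TRUE
      for (k in kept) {
        same_chr <- d$chrom[i] == d$chrom[d$snp_id == k]
        near <- abs(d$pos[i] - d$pos[d$snp_id == k]) <= window_bp
        r2 <- if (d$snp_id[i] %in% rownames(ld) && k %in% rownames(ld))
          ld[d$snp_id[i], k]^2 else 0
        if (same_chr && near && r2 >= r2_max) ok <- FALSE
      }
      if (ok) kept <- c(kept, d$snp_id[i])
    }
    kept
  }
  set.seed(99)
  for (rep in 1:20) {
    n <- 6
    ids <- sprintf("s%d", 1:n)
    d <- make_ss(n = n, snp_id = ids, pos = sort(sample.int(50000, n)),
                 pvalue = runif(n, 1e-12, 1e-4))
    A <- matrix(rnorm(n * 3), n)
    r <- stats::cov2cor(tcrossprod(A) + diag(n) * 0.5)
    dimnames(r) <- list(ids, ids)
    got <- ld_clump(d, r, r2_max = 0.1, window_kb = 20)$snp_id
    want <- greedy_oracle(d, r, r2_max = 0.1, window_bp = 20000)
    expect_equal(got, want)
  }
})

test_that("cis selection applies significance, window, MHC and F filters", {
  gene <- list(gene_id = "G1", chrom = "2", tss = 5000000L)
  base <- make_ss(n = 1, snp_id = "edge", chrom = "2",
                  pos = gene$tss + 999999L, pvalue = 1e-10,
                  eaf = 0.3, beta = 0.12, n_samp = 20000)
  got <- select_cis_instruments(base, gene)
  expect_equal(got$snp_id, "edge")           # closed-boundary cis window
  expect_true(got$f_stat > 10)

  # 1 bp beyond the window: excluded
  far <- base; far$pos <- gene$tss + 1000001L
  expect_equal(nrow(select_cis_instruments(far, gene)), 0L)

  # inside the MHC: excluded even if cis
  gene6 <- list(gene_id = "G6", chrom = "6", tss = 29500000L)
  mhc_snp <- make_ss(n = 1, snp_id = "mhc", chrom = "6", pos = 30000000L,
                     pvalue = 1e-10, beta = 0.12, n_samp = 20000)
  sel <- select_cis_instruments(mhc_snp, gene6)
  expect_equal(nrow(sel), 0L)
  expect_equal(unname(attr(sel, "attrition")["non_mhc"]), 0L)

  # sub-threshold significance: excluded
  weak <- base; weak$pvalue <- 1e-7
  expect_equal(nrow(select_cis_instruments(weak, gene)), 0L)

  expect_error(select_cis_instruments(base, list(gene_id = NA, chrom = "2",
                                                 tss = NA)), "gene annotation")
})

test_that("cis selection is order-invariant and output is pairwise unlinked", {
  gene <- list(gene_id = "G1", chrom = "1", tss = 1000000L)
  set.seed(7)
  n <- 8
  ids <- sprintf("s%d", 1:n)
  d <- make_ss(n = n, snp_id = ids, chrom = "1",
               pos = gene$tss + as.integer(seq(-400000, 400000, length.out = n)),
               pvalue = runif(n, 1e-30, 1e-9), beta = runif(n, 0.05, 0.2),
               n_samp = 50000)
  A <- matrix(rnorm(n * 4), n)
  ld <- stats::cov2cor(tcrossprod(A) + diag(n))
  dimnames(ld) <- list(ids, ids)

  a <- select_cis_instruments(d, gene, ld, r2_max = 0.01)
  b <- select_cis_instruments(d[sample(n), ], gene, ld, r2_max = 0.01)
  expect_equal(a$snp_id, b$snp_id)

  if (nrow(a) > 1L) {
    sub <- ld[a$snp_id, a$snp_id]
    expect_true(max(sub[upper.tri(sub)]^2) < 0.01)
  }
})
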