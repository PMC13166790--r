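test_that("invalid rows are dropped and logged, valid rows kept", {
  df <- make_ss(n = 4)
  df$eaf[2] <- 1.2              # outside (0,1)
  df$se[4] <- -0.01             # not positive
  p <- write_ss_file(df)
  ss <- read_sumstats(p, trait_id = "t")
  expect_equal(nrow(ss$data), 2L)
  expect_equal(nrow(ss$rejections), 2L)
  expect_setequal(ss$rejections$snp_id, c("rs2", "rs4"))
  expect_true(any(grepl("eaf", ss$rejections$reason)))
})

test_that("column_map aliases parse identically to the canonical header", {
  df <- make_ss(n = 3)
  p1 <- write_ss_file(df)
  raw <- utils::read.delim(p1, check.names = FALSE)
  names(raw)[names(raw) == "EA"] <- "A1"
  names(raw)[names(raw) == "OA"] <- "A2"
  p2 <- tempfile(fileext = ".tsv")
  utils::write.table(raw, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  a <- read_sumstats(p1, trait_id = "t")
  b <- read_sumstats(p2, column_map = c(A1 = "EA", A2 = "OA"), trait_id = "t")
  expect_equal(a$data, b$data)
})

test_that("missing columns and empty files are hard errors naming the problem", {
  df <- make_ss(n = 2)
  raw <- utils::read.delim(write_ss_file(df), check.names = FALSE)
  raw$BETA <- NULL
  p <- tempfile(fileext = ".tsv")
  utils::write.table(raw, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(p), "BETA")
  p0 <- tempfile(fileext = ".tsv")
  writeLines("SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN", p0)
  expect_error(read_sumstats(p0), "empty")
})

test_that("write then read round-trips records exactly", {
  df <- make_ss(n = 5, beta = rnorm(5), se = runif(5, 0.01, 0.05),
                pvalue = runif(5, 1e-12, 1), eaf = runif(5, 0.05, 0.95))
  ss <- read_sumstats(write_ss_file(df), trait_id = "t")
  expect_equal(ss$data, df)
})

test_that("harmonize flips swapped alleles: beta negated, eaf complemented", {
  ex <- make_ss(n = 1, ea = "A", oa = "G", beta = 0.2)
  oy <- make_ss(n = 1, ea = "G", oa = "A", beta = 0.1, eaf = 0.3)
  h <- harmonize(ex, oy)
  expect_equal(h$beta_gy, -0.1)
  expect_equal(h$eaf_gy, 0.7)
  expect_true(h$flipped)
})

test_that("palindromic SNPs near eaf 0.5 are dropped, others frequency-aligned", {
  ex <- make_ss(n = 1, ea = "A", oa = "T", eaf = 0.30, beta = 0.2)
  oy <- make_ss(n = 1, ea = "A", oa = "T", eaf = 0.50, beta = 0.1)
  h <- harmonize(ex, oy, palindrome_eaf_window = 0.08)
  expect_equal(nrow(h), 0L)
  expect_equal(attr(h, "drops")$reason, "palindromic_ambiguous")

  # unambiguous palindrome on opposite frequency sides: strand-flip inferred
  oy2 <- make_ss(n = 1, ea = "A", oa = "T", eaf = 0.70, beta = 0.1)
  h2 <- harmonize(ex, oy2, palindrome_eaf_window = 0.08)
  expect_equal(nrow(h2), 1L)
  expect_true(h2$flipped)
  expect_equal(h2$beta_gy, -0.1)

  # multi-base alleles are never treated as palindromic
  ex3 <- make_ss(n = 1, ea = "AT", oa = "A", eaf = 0.5)
  oy3 <- make_ss(n = 1, ea = "AT", oa = "A", eaf = 0.5, beta = 0.3)
  h3 <- harmonize(ex3, oy3)
  expect_equal(h3$beta_gy, 0.3)
})

test_that("incompatible allele pairs are dropped", {
  ex <- make_ss(n = 1, ea = "A", oa = "G")
  oy <- make_ss(n = 1, ea = "A", oa = "C")
  h <- harmonize(ex, oy)
  expect_equal(nrow(h), 0L)
  expect_equal(attr(h, "drops")$reason, "incompatible_alleles")
})

test_that("duplicate snp ids are a hard error", {
  ex <- make_ss(n = 2, snp_id = c("rs1", "rs1"))
  oy <- make_ss(n = 2)
  expect_error(harmonize(ex, oy), "duplicate")
})

test_that("harmonize is idempotent and a double allele swap restores beta", {
  set.seed(4)
  ex <- make_ss(n = 6, ea = c("A", "T", "G", "C", "A", "T"),
                oa = c("G", "C", "A", "A", "C", "G"),
                beta = rnorm(6), eaf = runif(6, 0.1, 0.45))
  oy <- ex
  oy$beta <- rnorm(6)
  h1 <- harmonize(ex, oy)
  expect_equal(nrow(h1), 6L)
  expect_false(any(h1$flipped))

  # re-feed aligned output as new outcome: nothing changes
  oy_aligned <- oy
  oy_aligned$beta <- h1$beta_gy
  h2 <- harmonize(ex, oy_aligned)
  expect_equal(h2, h1)

  # swap outcome alleles twice -> original beta restored exactly
  swap <- function(d) {
    tmp <- d$ea; d$ea <- d$oa; d$oa <- tmp
    d$beta <- -d$beta; d$eaf <- 1 - d$eaf
    d
  }
  expect_equal(harmonize(ex, swap(swap(oy)))$beta_gy, h1$beta_gy)

  # output count never exceeds either input count
  expect_lte(nrow(h1), min(nrow(ex), nrow(oy)))
})

test_that("LD matrix validation and round trip", {
  m <- make_ld(c("a", "b"), data.frame(i = "a", j = "b", r = 0.5))
  p <- tempfile(fileext = ".tsv")
  write_ld_matrix(m, p)
  expect_equal(read_ld_matrix(p), m, tolerance = 1e-12)

  bad <- m
  bad["a", "b"] <- 0.9
  bad["b", "a"] <- 0.2
  expect_error(validate_ld_matrix(bad), "asymmetric")
  bad2 <- m
  diag(bad2) <- c(1, 0.9)
  expect_error(validate_ld_matrix(bad2), "diagonal")
  expect_error(validate_ld_matrix(m[, 1, drop = FALSE]), "square")
  bad3 <- m
  bad3["a", "b"] <- bad3["b", "a"] <- 1.5
  expect_error(validate_ld_matrix(bad3), "exceed")
})
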