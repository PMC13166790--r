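# Reading, validation and allele harmonization of GWAS summary statistics,
# plus signed LD correlation matrices. All coordinates are 1-based; chromosome
# labels are plain strings ("6", not "chr6").

# canonical file header -> internal column name
.SS_HEADER <- c(
  SNP = "snp_id", CHR = "chrom", POS = "pos", EA = "ea", OA = "oa",
  EAF = "eaf", BETA = "beta", SE = "se", P = "pvalue", N = "n"
)

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab-separated table with the canonical header
#' `SNP CHR POS EA OA EAF BETA SE P N` (any order; extra columns ignored).
#' Rows violating the per-variant invariants (alleles must be non-empty
#' uppercase DNA strings and differ; `0 < EAF < 1`; `SE > 0`; `0 < P <= 1`;
#' `POS >= 1`; `N >= 2`; finite `BETA`) are dropped and logged rather than
#' failing the whole file.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param column_map Optional named character vector renaming file columns to
#'   canonical ones, e.g. `c(A1 = "EA", A2 = "OA")` maps the file's `A1`
#'   column onto the canonical effect-allele column.
#' @param trait_id Trait identifier; defaults to the file name without
#'   extension.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param n_cases Number of cases (binary traits only); must not exceed the
#'   total sample size.
#' @return An object of class `"sumstats"`: a list with `data` (data frame
#'   with columns `snp_id, chrom, pos, ea, oa, eaf, beta, se, pvalue, n`),
#'   `meta` (trait metadata), and `rejections` (data frame of dropped rows
#'   with reasons).
#' @export
read_sumstats <- function(path, column_map = NULL,
                          trait_id = sub("\\.[^.]*$", "", basename(path)),
                          trait_type = c("quantitative", "binary"),
                          n_cases = NULL) {
  trait_type <- match.arg(trait_type)
  raw <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character"),
    error = function(e) stop("cannot read summary statistics from '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  if (nrow(raw) == 0L) stop("empty summary-statistics file: ", path, call. = FALSE)

  if (!is.null(column_map)) {
    hit <- names(column_map)[names(column_map) %in% names(raw)]
    names(raw)[match(hit, names(raw))] <- unname(column_map[hit])
  }
  missing_cols <- setdiff(names(.SS_HEADER), names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  df <- data.frame(
    snp_id = as.character(raw$SNP),
    chrom  = as.character(raw$CHR),
    pos    = suppressWarnings(as.integer(raw$POS)),
    ea     = toupper(as.character(raw$EA)),
    oa     = toupper(as.character(raw$OA)),
    eaf    = suppressWarnings(as.numeric(raw$EAF)),
    beta   = suppressWarnings(as.numeric(raw$BETA)),
    se     = suppressWarnings(as.numeric(raw$SE)),
    pvalue = suppressWarnings(as.numeric(raw$P)),
    n      = suppressWarnings(as.numeric(raw$N)),
    stringsAsFactors = FALSE
  )

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    reason[is.na(reason) & bad] <<- why
  }
  dna <- function(a) !is.na(a) & grepl("^[ACGT]+$", a)
  flag(is.na(df$snp_id) | df$snp_id == "", "missing snp_id")
  flag(!dna(df$ea) | !dna(df$oa), "allele not a DNA string")
  flag(df$ea == df$oa, "identical alleles")
  flag(!(df$eaf > 0 & df$eaf < 1), "eaf outside (0,1)")
  flag(!is.finite(df$beta), "non-finite beta")
  flag(!(df$se > 0) | !is.finite(df$se), "se not positive")
  flag(!(df$pvalue > 0 & df$pvalue <= 1), "pvalue outside (0,1]")
  flag(is.na(df$pos) | df$pos < 1L, "position < 1")
  flag(is.na(df$n) | df$n < 2, "n < 2")

  keep <- is.na(reason)
  rejections <- data.frame(
    row = which(!keep),
    snp_id = df$snp_id[!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL

  n_total <- if (nrow(df) > 0L) as.integer(max(df$n)) else NA_integer_
  if (!is.null(n_cases) && !is.na(n_total) && n_cases > n_total) {
    stop("n_cases exceeds total sample size", call. = FALSE)
  }
  structure(list(
    data = df,
    meta = list(trait_id = trait_id, trait_type = trait_type,
                n_cases = n_cases, n_total = n_total),
    rejections = rejections
  ), class = "sumstats")
}

#' @export
print.sumstats <- function(x, ...) {
  cat("GWAS summary statistics for trait '", x$meta$trait_id, "' (",
      x$meta$trait_type, ")\n", sep = "")
  cat("  variants: ", nrow(x$data), "; rejected rows: ", nrow(x$rejections),
      "; n_total: ", x$meta$n_total, "\n", sep = "")
  invisible(x)
}

# Accept either a `sumstats` object or its bare data frame.
ss_data <- function(x) {
  if (inherits(x, "sumstats")) x$data else as.data.frame(x)
}

#' Write summary statistics as canonical tab-separated text
#'
#' Inverse of [read_sumstats()]: writes the canonical header
#' `SNP CHR POS EA OA EAF BETA SE P N`.
#'
#' @param x A `sumstats` object or bare summary-statistics data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  df <- ss_data(x)
  out <- data.frame(
    SNP = df$snp_id, CHR = df$chrom, POS = df$pos, EA = df$ea, OA = df$oa,
    EAF = df$eaf, BETA = df$beta, SE = df$se, P = df$pvalue, N = df$n,
    stringsAsFactors = FALSE
  )
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.is_palindromic <- function(ea, oa) {
  # Single-base strand-ambiguous pairs only; indels are never palindromic.
  nchar(ea) == 1L & nchar(oa) == 1L &
    ((ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
     (ea == "C" & oa == "G") | (ea == "G" & oa == "C"))
}

#' Align exposure and outcome summary statistics on shared effect alleles
#'
#' Joins two summary-statistics sets on `snp_id` and orients every outcome
#' record onto the exposure's effect allele. Outcome records whose alleles are
#' swapped relative to the exposure have their beta negated and frequency
#' complemented (`flipped = TRUE`). Palindromic SNPs (A/T or C/G) are dropped
#' when the effect-allele frequency is within `palindrome_eaf_window` of 0.5
#' on either trait (strand cannot be inferred); otherwise strand is inferred
#' by comparing which side of 0.5 the two frequencies fall on. Allele pairs
#' matching neither directly nor after swap are dropped as incompatible.
#'
#' @param exposure,outcome `sumstats` objects or bare data frames.
#' @param palindrome_eaf_window Half-width of the frequency window around 0.5
#'   inside which palindromic SNPs are considered strand-ambiguous and
#'   dropped (default 0.08).
#' @return Data frame of harmonized pairs with columns `snp_id, chrom, pos,
#'   ea, oa, beta_gx, se_gx, pvalue_gx, eaf, n_gx, beta_gy, se_gy, pvalue_gy,
#'   eaf_gy, n_gy, flipped, palindromic_dropped`; dropped SNPs and their
#'   reasons are attached as attribute `"drops"`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  ex <- ss_data(exposure)
  oy <- ss_data(outcome)
  for (nm in c("exposure", "outcome")) {
    d <- if (nm == "exposure") ex else oy
    if (anyDuplicated(d$snp_id)) {
      stop("duplicate snp_id in ", nm, " summary statistics: ",
           d$snp_id[duplicated(d$snp_id)][1L], call. = FALSE)
    }
  }
  idx <- match(ex$snp_id, oy$snp_id)
  keep <- !is.na(idx)
  ex <- ex[keep, , drop = FALSE]
  oy <- oy[idx[keep], , drop = FALSE]

  aligned <- oy$ea == ex$ea & oy$oa == ex$oa
  swapped <- oy$ea == ex$oa & oy$oa == ex$ea
  pal <- .is_palindromic(ex$ea, ex$oa) & (aligned | swapped)
  ambiguous <- pal & (abs(ex$eaf - 0.5) < palindrome_eaf_window |
                      abs(oy$eaf - 0.5) < palindrome_eaf_window)

  # For unambiguous palindromes the written orientation is uninformative
  # (strand flips mimic allele swaps): orient by allele frequency instead.
  flip <- swapped & !pal
  flip[pal] <- (ex$eaf[pal] - 0.5) * (oy$eaf[pal] - 0.5) < 0

  status <- ifelse(ambiguous, "palindromic_ambiguous",
            ifelse(aligned | swapped, "ok", "incompatible_alleles"))
  ok <- status == "ok"

  out <- data.frame(
    snp_id = ex$snp_id[ok], chrom = ex$chrom[ok], pos = ex$pos[ok],
    ea = ex$ea[ok], oa = ex$oa[ok],
    beta_gx = ex$beta[ok], se_gx = ex$se[ok], pvalue_gx = ex$pvalue[ok],
    eaf = ex$eaf[ok], n_gx = ex$n[ok],
    beta_gy = ifelse(flip[ok], -oy$beta[ok], oy$beta[ok]),
    se_gy = oy$se[ok], pvalue_gy = oy$pvalue[ok],
    eaf_gy = ifelse(flip[ok], 1 - oy$eaf[ok], oy$eaf[ok]),
    n_gy = oy$n[ok],
    flipped = flip[ok],
    palindromic_dropped = rep(FALSE, sum(ok)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "drops") <- data.frame(
    snp_id = ex$snp_id[!ok], reason = status[!ok], stringsAsFactors = FALSE
  )
  out
}

#' Validate a signed LD correlation matrix
#'
#' @param r Square numeric matrix with identical SNP-id row and column names.
#' @param tol Tolerance for symmetry, unit diagonal and the `|r| <= 1` bound.
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_ld_matrix <- function(r, tol = 1e-8) {
  if (!is.matrix(r) || !is.numeric(r)) stop("LD matrix must be numeric", call. = FALSE)
  if (nrow(r) != ncol(r)) stop("LD matrix is not square", call. = FALSE)
  ids <- rownames(r)
  if (is.null(ids) || is.null(colnames(r)) || !identical(ids, colnames(r))) {
    stop("LD matrix must carry identical SNP-id row and column names", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate SNP ids in LD matrix", call. = FALSE)
  if (any(!is.finite(r))) stop("non-finite entries in LD matrix", call. = FALSE)
  if (max(abs(r - t(r))) > tol) stop("LD matrix asymmetric beyond tolerance", call. = FALSE)
  if (max(abs(r)) > 1 + tol) stop("LD correlations exceed 1 in magnitude", call. = FALSE)
  if (max(abs(diag(r) - 1)) > tol) stop("LD matrix diagonal is not 1", call. = FALSE)
  invisible(r)
}

#' Read a signed LD matrix from tab-separated text
#'
#' Expects a square matrix whose first row and first column carry SNP ids.
#'
#' @param path Input file path.
#' @return Validated numeric matrix with SNP-id dimnames.
#' @export
read_ld_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, sep = "\t", row.names = 1,
                                   check.names = FALSE))
  storage.mode(m) <- "double"
  validate_ld_matrix(m)
  m
}

#' Write an LD matrix as tab-separated text
#'
#' @param r Numeric LD matrix with SNP-id dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(r, path) {
  validate_ld_matrix(r)
  utils::write.table(format(r, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
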