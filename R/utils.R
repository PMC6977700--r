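`%||%` <- function(a, b) if (is.null(a)) b else a

# p-value floor applied before any -log10 so downstream scores stay finite
P_FLOOR <- 1e-300

.floor_p <- function(p) pmax(p, P_FLOOR)

#' Detect the field delimiter of a delimited text file
#'
#' Counts tabs and commas on the header line; ties are broken toward tab
#' (GEO-style matrices are tab-delimited).
#'
#' @param path Path to a delimited text file.
#' @return `"\t"` or `","`.
#' @keywords internal
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE)))
  n_com <- lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))
  if (n_com > n_tab) "," else "\t"
}

# Center and scale rows to unit variance (denominator n - 1).
# Rows with zero variance yield NaN; callers decide whether that is an error.
.standardize_rows <- function(mat) {
  mu <- rowMeans(mat)
  ctr <- mat - mu
  sdv <- sqrt(rowSums(ctr^2) / (ncol(mat) - 1L))
  ctr / sdv
}

# Pearson r for paired rows of two row-standardized matrices
.pair_cor <- function(za, zb, ia, ib) {
  n <- ncol(za)
  r <- rowSums(za[ia, , drop = FALSE] * zb[ib, , drop = FALSE]) / (n - 1L)
  pmin(pmax(r, -1), 1)
}

# Two-sided p-value for a Pearson correlation via the t-transform, df = n - 2
.cor_pval <- function(r, n) {
  r2 <- pmin(r^2, 1)
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.xmin))
  2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
}

.assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  }
}
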