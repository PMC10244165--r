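#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test with the probability-mass rule: the two-sided
#' p-value sums, over all tables with the observed margins, the
#' probabilities not exceeding that of the observed table (within a 1e-7
#' relative tolerance for floating-point safety). Degenerate margins give
#' p = 1 with a flag.
#'
#' @param a,b,c,d Non-negative integer counts: rows are groups, columns are
#'   outcome yes/no. Alternatively `a` may be a 2x2 matrix.
#' @return p-value in (0, 1], with attributes `odds_ratio` (sample odds
#'   ratio ad/bc) and `degenerate`.
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    b <- a[1L, 2L]; c <- a[2L, 1L]; d <- a[2L, 2L]; a <- a[1L, 1L]
  }
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("table error: counts must be non-negative integers")
  }
  if (sum(counts) < 1) stop("table error: empty table")
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0L || n == 0L || k == 0L || (b + d) == 0L) {
    return(structure(1, odds_ratio = NA_real_, degenerate = TRUE))
  }
  xs <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  if (p > 1 - 1e-12) p <- 1
  or <- (a * d) / (b * c)
  structure(p, odds_ratio = or, degenerate = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the
#' input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the same order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0L))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  o <- order(pvalues)
  q_sorted <- rev(cummin(rev(pvalues[o] * m / seq_len(m))))
  pmin(1, q_sorted)[order(o)]
}

#' Batch Fisher tests with FDR correction
#'
#' @param tables `data.frame` (or matrix) with columns `a`, `b`, `c`, `d`.
#' @return The input with `p`, `odds_ratio` and `q` columns appended.
#' @export
fisher_batch <- function(tables) {
  tables <- as.data.frame(tables)
  stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
  res <- lapply(seq_len(nrow(tables)), function(i) {
    fisher_exact_two_sided(tables$a[i], tables$b[i], tables$c[i],
                           tables$d[i])
  })
  tables$p <- vapply(res, as.numeric, numeric(1L))
  tables$odds_ratio <- vapply(res, attr, numeric(1L), "odds_ratio")
  tables$q <- benjamini_hochberg(tables$p)
  tables
}
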