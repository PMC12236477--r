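# Internal numerical helpers shared across modules.

#' Column-standardize a matrix for correlation
#'
#' Centers each column and scales it to unit sum of squares, so that
#' `crossprod()` of two standardized matrices is a matrix of Pearson
#' correlations.
#'
#' @param x numeric matrix (rows = voxels).
#' @param what label used in the zero-variance error message.
#' @return matrix of the same shape.
#' @noRd
standardize_cols <- function(x, what = "pattern") {
  n <- nrow(x)
  x <- x - rep(colMeans(x), each = n)
  ss <- sqrt(colSums(x^2))
  if (any(ss == 0) || any(!is.finite(ss))) {
    bad <- which(ss == 0 | !is.finite(ss))
    abort(sprintf(
      "zero-variance or non-finite %s (column%s %s)",
      what, if (length(bad) > 1) "s" else "", paste(bad, collapse = ", ")
    ))
  }
  x / rep(ss, each = n)
}

#' All-pairs Pearson correlation between columns of two matrices
#'
#' @param x,y matrices with the same number of rows (voxels).
#' @return `ncol(x)` by `ncol(y)` correlation matrix.
#' @noRd
cross_cor <- function(x, y, what_x = "pattern", what_y = "pattern") {
  crossprod(standardize_cols(x, what_x), standardize_cols(y, what_y))
}

#' Column-matched Pearson correlation
#'
#' Correlates column i of `x` with column i of `y`.
#' @noRd
colwise_cor <- function(x, y, what_x = "pattern", what_y = "pattern") {
  colSums(standardize_cols(x, what_x) * standardize_cols(y, what_y))
}

#' Column means and standard deviations without apply()
#' @noRd
col_sds <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  sqrt(pmax(colSums(x^2) - n * m^2, 0) / (n - 1))
}

#' One-sample / paired t statistic with degenerate-variance flagging
#'
#' `stats::t.test()` refuses constant data; the subsequent-memory analyses
#' must instead flag such parcels. All-zero differences are a well-defined
#' t = 0 (p = 0.5 one-tailed); non-zero constant differences are flagged
#' degenerate.
#'
#' @param d numeric vector of paired differences.
#' @param tail `"greater"` (one-tailed), or `"two.sided"`.
#' @return list with `t`, `p`, `df`, `n`, `degenerate`.
#' @noRd
t_one_sample <- function(d, tail = c("greater", "two.sided")) {
  tail <- match.arg(tail)
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 3) abort("need at least 3 complete pairs for a t-test")
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = if (tail == "greater") 0.5 else 1,
                  df = n - 1, n = n, degenerate = FALSE))
    }
    return(list(t = sign(mean(d)) * Inf, p = NA_real_,
                df = n - 1, n = n, degenerate = TRUE))
  }
  tval <- mean(d) / (s / sqrt(n))
  p <- if (tail == "greater") {
    pt(tval, df = n - 1, lower.tail = FALSE)
  } else {
    2 * pt(abs(tval), df = n - 1, lower.tail = FALSE)
  }
  list(t = tval, p = p, df = n - 1, n = n, degenerate = FALSE)
}

#' Two-sample pooled-variance t statistic (one-tailed x > y)
#' @noRd
t_two_sample <- function(x, y, tail = c("greater", "two.sided")) {
  tail <- match.arg(tail)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 3 || n2 < 3) abort("need at least 3 observations per group")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  if (sp2 == 0) {
    return(list(t = 0, p = if (tail == "greater") 0.5 else 1,
                df = df, n = n1 + n2, degenerate = mean(x) != mean(y)))
  }
  tval <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- if (tail == "greater") {
    pt(tval, df = df, lower.tail = FALSE)
  } else {
    2 * pt(abs(tval), df = df, lower.tail = FALSE)
  }
  list(t = tval, p = p, df = df, n = n1 + n2, degenerate = FALSE)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0", name))
  invisible(x)
}
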