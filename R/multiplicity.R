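#' @title Multiple-testing machinery
#'
#' @description
#' Storey-style q-values (false discovery rates) and the
#' observed-versus-expected P-value bin table used to diagnose whether a
#' family of association P-values departs from the uniform distribution
#' expected when no SNP has an effect. Bins are finer at small P-values,
#' where an excess of real effects would show first.
#'
#' @name multiplicity
NULL

#' Default P-value bin edges
#'
#' Ascending break points `0, 0.001, 0.01, 0.05, 0.1, 1` defining the five
#' bins `[0, 0.001]`, `(0.001, 0.01]`, `(0.01, 0.05]`, `(0.05, 0.1]`,
#' `(0.1, 1]`: lower-open, upper-closed, with the lowest bin closed at 0 so
#' the bins tile `[0, 1]` exactly.
#'
#' @return Numeric vector of break points.
#' @export
default_bin_edges <- function() c(0, 0.001, 0.01, 0.05, 0.1, 1)

validate_edges <- function(bin_edges) {
  if (length(bin_edges) < 2L || is.unsorted(bin_edges, strictly = TRUE) ||
      bin_edges[1L] != 0 || bin_edges[length(bin_edges)] != 1) {
    abort_validation(
      "bin edges must increase strictly from 0 to 1 (a partition of [0, 1])")
  }
  bin_edges
}

bin_labels <- function(bin_edges) {
  k <- length(bin_edges) - 1L
  lab <- sprintf("(%g,%g]", bin_edges[-length(bin_edges)], bin_edges[-1L])
  lab[1L] <- sprintf("[%g,%g]", bin_edges[1L], bin_edges[2L])
  lab
}

#' Expected P-value counts per bin under the uniform null
#'
#' Under the null every P-value is uniform on \[0, 1\], so the expected
#' count in a bin is `m` times the bin width. Returned unrounded; display
#' rounding is done by [render_expected()].
#'
#' @param m Number of tests (>= 0).
#' @param bin_edges Ascending break points partitioning \[0, 1\];
#'   default [default_bin_edges()].
#' @return Numeric vector of expected counts, one per bin, in ascending
#'   bin order; sums exactly to `m`.
#' @export
#' @examples
#' expected_bin_counts(49)  # 0.049 0.441 1.96 2.45 44.1
expected_bin_counts <- function(m, bin_edges = default_bin_edges()) {
  if (!is_count(m)) abort_validation("m must be a non-negative integer")
  validate_edges(bin_edges)
  m * diff(bin_edges)
}

#' Render an expected count the way summary tables print it
#'
#' Round half away from zero: to the nearest integer for values >= 10, one
#' decimal for values in \[1, 10), two decimals below 1.
#'
#' @param x Numeric vector of expected counts.
#' @return Numeric vector, rounded for display.
#' @export
#' @examples
#' render_expected(expected_bin_counts(49))  # 0.05 0.44 2.0 2.5 44
render_expected <- function(x) {
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    out[i] <- if (is.na(x[i])) NA_real_
    else if (x[i] >= 10) round_half_up(x[i], 0)
    else if (x[i] >= 1) round_half_up(x[i], 1)
    else round_half_up(x[i], 2)
  }
  out
}

#' Observed-versus-expected P-value bin table
#'
#' Counts observed P-values per bin (lower-open, upper-closed; the lowest
#' bin closed at 0, so a P-value exactly on an edge falls in the lower
#' bin), sets the expected counts from [expected_bin_counts()], and, when
#' q-values are supplied, records the (min, max) q-value among the
#' P-values in each bin.
#'
#' @param p_values Numeric vector of P-values in \[0, 1\].
#' @param bin_edges Ascending break points; default [default_bin_edges()].
#' @param q_values Optional q-value vector parallel to `p_values`.
#' @return A data frame of class `pvalue_bin_table` with columns `bin`
#'   (label, descending order as conventionally printed), `lower`,
#'   `upper`, `observed`, `expected` and, if q-values were given, `q_min`,
#'   `q_max` (NA for empty bins); attribute `m` holds the test count.
#' @export
pvalue_bin_table <- function(p_values, bin_edges = default_bin_edges(),
                             q_values = NULL) {
  validate_edges(bin_edges)
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort_validation("all p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  k <- length(bin_edges) - 1L
  idx <- if (m > 0) {
    as.integer(cut(p_values, bin_edges, right = TRUE, include.lowest = TRUE))
  } else integer()
  observed <- tabulate(idx, nbins = k)
  out <- data.frame(bin = bin_labels(bin_edges),
                    lower = bin_edges[-length(bin_edges)],
                    upper = bin_edges[-1L],
                    observed = observed,
                    expected = expected_bin_counts(m, bin_edges),
                    stringsAsFactors = FALSE)
  if (!is.null(q_values)) {
    stopifnot(length(q_values) == m)
    out$q_min <- vapply(seq_len(k), function(b) {
      qs <- q_values[idx == b]
      if (length(qs)) min(qs) else NA_real_
    }, numeric(1))
    out$q_max <- vapply(seq_len(k), function(b) {
      qs <- q_values[idx == b]
      if (length(qs)) max(qs) else NA_real_
    }, numeric(1))
  }
  out <- out[rev(seq_len(k)), , drop = FALSE]  # print large-p bin first
  rownames(out) <- NULL
  attr(out, "m") <- m
  class(out) <- c("pvalue_bin_table", class(out))
  out
}

#' Estimate the null proportion pi0 from a P-value distribution
#'
#' `pi0(lambda) = #\{p > lambda\} / (m * (1 - lambda))`. The `"spline"`
#' method fits a cubic smoothing spline to `pi0(lambda)` over the grid and
#' takes its value at the largest lambda (the Storey 2002 recipe); the
#' `"fixed"` method evaluates at a single `lambda_fixed`. The estimate is
#' clipped to (0, 1]; a raw estimate of 0 (every p below every lambda) is
#' floored at `1/m`.
#'
#' @param p_values Numeric vector of P-values in \[0, 1\], non-empty.
#' @param lambda_grid Grid of thresholds inside (0, 1); default
#'   `seq(0.05, 0.90, by = 0.05)`.
#' @param method `"spline"` (default) or `"fixed"`.
#' @param lambda_fixed Threshold used by the fixed method; default 0.5.
#' @return The pi0 estimate, a scalar in (0, 1].
#' @export
pi0_estimate <- function(p_values, lambda_grid = seq(0.05, 0.90, by = 0.05),
                         method = c("spline", "fixed"), lambda_fixed = 0.5) {
  method <- match.arg(method)
  if (length(p_values) == 0L) abort_validation("need at least one p-value")
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort_validation("all p-values must lie in [0, 1]")
  }
  if (any(lambda_grid <= 0 | lambda_grid >= 1)) {
    abort_validation("lambda grid must lie strictly inside (0, 1)")
  }
  m <- length(p_values)
  pi0_at <- function(l) sum(p_values > l) / (m * (1 - l))
  raw <- if (method == "fixed") {
    pi0_at(lambda_fixed)
  } else {
    grid <- sort(lambda_grid)
    pi0_l <- vapply(grid, pi0_at, numeric(1))
    if (length(grid) >= 4L) {
      fit <- stats::smooth.spline(grid, pi0_l, df = 3)
      stats::predict(fit, x = max(grid))$y
    } else {
      pi0_l[length(pi0_l)]  # too few grid points to smooth
    }
  }
  min(1, max(raw, 1 / m))
}

#' Storey q-values from P-values and a pi0 estimate
#'
#' With the P-values sorted ascending, `q(i) = min over j >= i of
#' pi0 * m * p(j) / j`; the original input order is restored. With
#' `pi0 = 1` this is exactly the Benjamini-Hochberg adjusted P-value.
#'
#' @param p_values Numeric vector of P-values in \[0, 1\].
#' @param pi0 Null-proportion estimate in (0, 1]; default estimated by
#'   [pi0_estimate()] with the spline method.
#' @return A list of class `qvalue_set` with `p_values`, `q_values`
#'   (parallel to the input), `pi0` and `lambda_grid` (NULL when pi0 was
#'   supplied directly).
#' @export
#' @examples
#' qvalues(c(0.001, 0.01, 0.1), pi0 = 1)$q_values  # 0.003 0.015 0.100
qvalues <- function(p_values, pi0 = NULL) {
  if (length(p_values) == 0L) abort_validation("need at least one p-value")
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort_validation("all p-values must lie in [0, 1]")
  }
  lambda_grid <- NULL
  if (is.null(pi0)) {
    lambda_grid <- seq(0.05, 0.90, by = 0.05)
    pi0 <- pi0_estimate(p_values, lambda_grid)
  }
  if (pi0 <= 0 || pi0 > 1) abort_validation("pi0 must lie in (0, 1]")
  m <- length(p_values)
  ord <- order(p_values)
  p_sorted <- p_values[ord]
  q_sorted <- rev(cummin(rev(pi0 * m * p_sorted / seq_len(m))))
  q <- numeric(m)
  q[ord] <- q_sorted
  structure(list(p_values = p_values, q_values = q, pi0 = pi0,
                 lambda_grid = lambda_grid),
            class = "qvalue_set")
}

#' @export
print.qvalue_set <- function(x, ...) {
  cat(sprintf("q-value set: m = %d, pi0 = %.4g, min q = %.4g\n",
              length(x$p_values), x$pi0, min(x$q_values)))
  invisible(x)
}
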