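#' Paired t-test on per-subject values
#'
#' Classical paired t on the differences `x - y`, two-sided p from the t
#' distribution with n - 1 degrees of freedom (via [stats::t.test()]).
#' Degenerate zero-variance differences are flagged: all-zero differences
#' return t = 0, p = 1; constant nonzero differences return an infinite t
#' with p = NA.
#'
#' @param x,y Numeric vectors of equal length (>= 3), paired by subject.
#' @param label Test label carried into reports.
#' @return List of class `test_result`: `label`, `family` (`"paired_t"`),
#'   `statistic`, `df`, `p`, `n`, `flag`.
#' @export
paired_t <- function(x, y, label = "paired_t") {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(structure(list(label = label, family = "paired_t",
                            statistic = 0, df = length(d) - 1L, p = 1,
                            n = length(d), flag = "zero_variance"),
                       class = "test_result"))
    }
    return(structure(list(label = label, family = "paired_t",
                          statistic = sign(mean(d)) * Inf,
                          df = length(d) - 1L, p = NA_real_,
                          n = length(d), flag = "zero_variance"),
                     class = "test_result"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  structure(list(label = label, family = "paired_t",
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, n = length(d), flag = ""),
            class = "test_result")
}

#' Pearson correlation test
#'
#' Sample correlation with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom (via
#' [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length (>= 3) with nonzero variance.
#' @param label Test label.
#' @return List of class `test_result` with `family = "pearson"`; the
#'   `statistic` is r, `df = n - 2`.
#' @export
pearson_r <- function(x, y, label = "pearson") {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in correlation input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(label = label, family = "pearson",
                 statistic = unname(ct$estimate), df = unname(ct$parameter),
                 p = ct$p.value, n = length(x), flag = ""),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, df = %d, p = %.4g%s\n", x$label,
              if (x$family == "pearson") "r" else "t",
              x$statistic, x$df, x$p,
              if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Signed percent modulation of a test amplitude against a reference
#'
#' `100 * (a_test - a_ref) / |a_ref|`.  The sign carries direction on the
#' signed-amplitude scale: a negative-going response that grows more
#' negative yields a negative modulation ("reduced"), one that shrinks
#' toward zero a positive modulation; magnitudes beyond 100% are legal
#' (the reference may be small).
#'
#' @param a_test,a_ref Amplitudes in the same (signed) units; `a_ref != 0`.
#' @return Percent modulation.
#' @export
#' @examples
#' percent_modulation(1.4541, 1.0) # +45.41
percent_modulation <- function(a_test, a_ref) {
  if (any(a_ref == 0)) stop("reference amplitude is zero")
  100 * (a_test - a_ref) / abs(a_ref)
}

#' Holm-Bonferroni step-down correction
#'
#' The ordered p-values are compared to `alpha / (m - k + 1)` (k the 1-based
#' rank); rejection proceeds while `p_(k)` is below its threshold and stops
#' at the first failure, so the rejection set is always a prefix of the
#' sorted order.  For 10 tests at alpha = 0.05 the first two cutoffs are
#' 0.005 and 0.00555....
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @param alpha Familywise error level (default 0.05).
#' @param labels Optional labels, recycled into the result.
#' @return Data frame in step-down (ascending p) order: `label`, `p`,
#'   `rank`, `threshold`, `significant`.
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05,
                            labels = paste0("test", seq_along(pvals))) {
  if (!length(pvals)) stop("no p-values")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  ord <- order(pvals)
  thr <- alpha / (m - seq_len(m) + 1)
  sig <- pvals[ord] < thr
  if (any(!sig)) sig[seq(which.min(sig), m)] <- FALSE # prefix property
  data.frame(label = labels[ord], p = pvals[ord], rank = seq_len(m),
             threshold = thr, significant = sig,
             stringsAsFactors = FALSE)
}
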