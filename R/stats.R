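#' Microhomology usage counts for one sample
#'
#' @param sample Sample label.
#' @param n_plus_mh Unique events with homology >= 5 bp.
#' @param n_minus_mh Unique events with homology < 5 bp.
#' @param coverage Mean fold-coverage in genome copies (> 0).
#' @return Object of class `mh_counts` with per-genome rates.
#' @export
mh_counts <- function(sample, n_plus_mh, n_minus_mh, coverage) {
  cov <- coverage_value(coverage)
  if (cov <= 0) stop("coverage must be > 0")
  if (n_plus_mh < 0 || n_minus_mh < 0) stop("counts must be >= 0")
  structure(list(sample = sample,
                 n_plus_mh = n_plus_mh, n_minus_mh = n_minus_mh,
                 coverage = cov,
                 rate_plus = n_plus_mh / cov,
                 rate_minus = n_minus_mh / cov),
            class = "mh_counts")
}

#' @export
print.mh_counts <- function(x, ...) {
  cat(sprintf("%s: +MH %d (%.3g/genome), -MH %d (%.3g/genome) at %.1fx\n",
              x$sample, x$n_plus_mh, x$rate_plus, x$n_minus_mh,
              x$rate_minus, x$coverage))
  invisible(x)
}

#' Chi-squared comparison of microhomology usage between two samples
#'
#' Pearson chi-squared test (df = 1, no continuity correction by default) on
#' the 2x2 table of raw +MH / -MH event counts of two samples. Raw counts
#' are used rather than coverage-normalized rates, which would invalidate
#' the test's sampling model.
#'
#' @param a,b `mh_counts` objects.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return List of class `chi2_result`: `statistic`, `df`, `p_value`,
#'   `table`.
#' @export
mh_chi2 <- function(a, b, correct = FALSE) {
  stopifnot(inherits(a, "mh_counts"), inherits(b, "mh_counts"))
  tab <- matrix(c(a$n_plus_mh, a$n_minus_mh, b$n_plus_mh, b$n_minus_mh),
                nrow = 2, byrow = TRUE,
                dimnames = list(c(a$sample, b$sample), c("+MH", "-MH")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-squared test undefined: a row or column of the 2x2 table is zero")
  }
  ct <- stats::chisq.test(tab, correct = correct)
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value), table = tab),
            class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("chi-squared = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Fold change between two coverage-normalized rates
#'
#' @param a,b Rates (events per genome); `b` must be positive.
#' @return `a / b`.
#' @export
fold_change <- function(a, b) {
  if (b <= 0) stop("reference rate must be > 0")
  a / b
}
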