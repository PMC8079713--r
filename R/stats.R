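#' Percentile-bootstrap confidence interval of the median
#'
#' Estimation-statistics summary in the DABEST style: the point estimate is
#' the sample median and the 95% interval is the 2.5/97.5 percentile range
#' of `n_boot` bootstrap medians. Deterministic for a fixed seed.
#'
#' @param sample numeric vector (>= 2 values).
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return list of class `bootstrap_estimate`: `point`, `ci_low`,
#'   `ci_high`, `n_boot`, `seed`, `n`.
#' @export
bootstrap_median_ci <- function(sample, n_boot = 10000L, seed = 1L,
                                conf = 0.95) {
  if (length(sample) < 2L) stop_param("need at least 2 values")
  n <- length(sample)
  meds <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    apply(matrix(sample[idx], n_boot, n), 1L, median)
  })
  qs <- quantile(meds, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  structure(list(point = median(sample), ci_low = qs[1], ci_high = qs[2],
                 n_boot = n_boot, seed = seed, n = n),
            class = "bootstrap_estimate")
}

#' Bootstrap median difference between two conditions
#'
#' Point estimate `median(b) - median(a)` with a percentile-bootstrap 95%
#' interval from independent resampling of both samples — the effect size
#' plotted in a DABEST comparison.
#'
#' @param a,b numeric vectors (>= 2 values each); `b` is the test
#'   condition.
#' @inheritParams bootstrap_median_ci
#' @return a `bootstrap_estimate`.
#' @export
median_difference <- function(a, b, n_boot = 10000L, seed = 1L,
                              conf = 0.95) {
  if (length(a) < 2L || length(b) < 2L) stop_param("need >= 2 values per sample")
  na <- length(a); nb <- length(b)
  diffs <- with_seed(seed, {
    ia <- matrix(sample.int(na, na * n_boot, replace = TRUE), n_boot, na)
    ib <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), n_boot, nb)
    apply(matrix(b[ib], n_boot, nb), 1L, median) -
      apply(matrix(a[ia], n_boot, na), 1L, median)
  })
  qs <- quantile(diffs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  structure(list(point = median(b) - median(a), ci_low = qs[1],
                 ci_high = qs[2], n_boot = n_boot, seed = seed,
                 n = c(na, nb)),
            class = "bootstrap_estimate")
}

#' Bootstrap fold change (ratio of medians)
#'
#' `median(b) / median(a)` with a percentile-bootstrap 95% interval, the
#' form in which relative changes between conditions are reported.
#'
#' @inheritParams median_difference
#' @return a `bootstrap_estimate`.
#' @export
median_ratio <- function(a, b, n_boot = 10000L, seed = 1L, conf = 0.95) {
  if (length(a) < 2L || length(b) < 2L) stop_param("need >= 2 values per sample")
  na <- length(a); nb <- length(b)
  ratios <- with_seed(seed, {
    ia <- matrix(sample.int(na, na * n_boot, replace = TRUE), n_boot, na)
    ib <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), n_boot, nb)
    apply(matrix(b[ib], n_boot, nb), 1L, median) /
      apply(matrix(a[ia], n_boot, na), 1L, median)
  })
  qs <- quantile(ratios, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  structure(list(point = median(b) / median(a), ci_low = qs[1],
                 ci_high = qs[2], n_boot = n_boot, seed = seed,
                 n = c(na, nb)),
            class = "bootstrap_estimate")
}

#' @export
print.bootstrap_estimate <- function(x, ...) {
  cat(sprintf("%.4g, 95%% CI [%.4g, %.4g] (n_boot %d)\n",
              x$point, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' Violin-plot summary of a sample
#'
#' Median, quartiles (linear-interpolation convention, R type 7), and
#' adjacent values: the extreme data values still within 1.5 interquartile
#' ranges of the quartiles. Adjacent values are always members of the
#' sample.
#'
#' @param sample numeric vector (>= 4 values).
#' @return list of class `violin_summary`: `median`, `q1`, `q3`,
#'   `adjacent_low`, `adjacent_high`, `n`.
#' @export
violin_summary <- function(sample) {
  if (length(sample) < 4L) stop_param("need at least 4 values")
  q <- quantile(sample, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- min(sample[sample >= q[1] - 1.5 * iqr])
  hi <- max(sample[sample <= q[3] + 1.5 * iqr])
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 adjacent_low = lo, adjacent_high = hi,
                 n = length(sample)),
            class = "violin_summary")
}

#' @export
print.violin_summary <- function(x, ...) {
  cat(sprintf(
    "median %.4g, IQR [%.4g, %.4g], adjacent [%.4g, %.4g], n = %d\n",
    x$median, x$q1, x$q3, x$adjacent_low, x$adjacent_high, x$n))
  invisible(x)
}
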