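#' Constant-synthesis septal constriction model
#'
#' Diameter of the septal leading edge under outside-in synthesis of a flat
#' plate at constant total synthesis rate: `d = d0` before the constriction
#' start `t0`, then `d = sqrt(d0^2 - (4k/pi) (t - t0))`, clamped at zero
#' beyond the completion time `t0 + pi d0^2 / (4k)`. `k` is the rate at
#' which area is added to the septal plate (nm^2/s).
#'
#' @param t times, s.
#' @param d0 initial diameter, nm.
#' @param t0 constriction start, s.
#' @param k area addition rate, nm^2/s.
#' @return diameters, nm.
#' @export
eval_constriction_model <- function(t, d0, t0, k) {
  check_positive(d0, "d0"); check_positive(k, "k")
  arg <- d0^2 - (4 * k / pi) * (t - t0)
  ifelse(t < t0, d0, sqrt(pmax(arg, 0)))
}

#' Fit the constriction model to a diameter trajectory
#'
#' Least squares over `(d0, t0, k)` by Levenberg-Marquardt. `t0` is
#' initialised at the first time the median-smoothed trajectory falls below
#' 95% of its maximum, `k` from a two-point slope of the squared diameter,
#' `d0` from the pre-start mean. In `post_treatment` mode only samples with
#' `t >= t_treat` enter the fit (the mode used for drug-arrest
#' trajectories); `exclude_after` drops trailing samples, mirroring the
#' removal of residual signal after the completion-intensity drop.
#'
#' @param trajectory data frame with columns `t_s` and `diameter_nm`.
#' @param mode `"full"` or `"post_treatment"`.
#' @param t_treat treatment time, s (required for post-treatment mode).
#' @param exclude_after optional index; samples after it are excluded.
#' @return list of class `constriction_fit`: `d0`, `t0`, `k`,
#'   `t_eff` (effective constriction time, s), `rss`, `converged`, `mode`.
#' @export
fit_constriction <- function(trajectory, mode = c("full", "post_treatment"),
                             t_treat = NULL, exclude_after = NULL) {
  mode <- match.arg(mode)
  t <- trajectory$t_s; d <- trajectory$diameter_nm
  if (!is.null(exclude_after)) {
    keep <- seq_len(min(exclude_after, length(t)))
    t <- t[keep]; d <- d[keep]
  }
  if (mode == "post_treatment") {
    if (is.null(t_treat)) stop_param("post-treatment mode requires `t_treat`")
    keep <- t >= t_treat
    t <- t[keep]; d <- d[keep]
  }
  ok <- is.finite(t) & is.finite(d)
  t <- t[ok]; d <- d[ok]
  if (length(t) < 6L) stop_param("need at least 6 usable diameter samples")
  dmax <- max(d)
  flat <- sd(d) < 1e-9 * max(dmax, 1)
  sm <- if (length(d) >= 5) runmed(d, 5) else d
  below <- which(sm < 0.95 * dmax)
  t0_init <- if (length(below) > 0) t[below[1]] else t[ceiling(length(t) / 2)]
  pre <- d[t < t0_init]
  d0_init <- if (length(pre) > 0) mean(pre) else dmax
  d0_init <- max(d0_init, 1e-6)
  post <- which(t >= t0_init)
  k_init <- if (length(post) >= 2) {
    i1 <- post[1]; i2 <- post[length(post)]
    max(-pi / 4 * (d[i2]^2 - d[i1]^2) / (t[i2] - t[i1]), 1e-9)
  } else 1e-9
  if (k_init <= 1e-9) k_init <- d0_init^2 / (4 * diff(range(t)) + 1)
  resid <- function(v) d - eval_constriction_model(t, v[1], v[2], v[3])
  span <- diff(range(t))
  fit <- minpack.lm::nls.lm(
    par = c(d0 = d0_init, t0 = t0_init, k = k_init), fn = resid,
    lower = c(1e-9, min(t) - 2 * span, 1e-12),
    upper = c(4 * dmax + 1, max(t), Inf),
    control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-14,
                                         ptol = 1e-14))
  v <- fit$par
  converged <- fit$info %in% 1:4 && !flat
  structure(list(d0 = v[[1]], t0 = v[[2]], k = v[[3]],
                 t_eff = effective_constriction_time(v[[1]], v[[3]]),
                 rss = sum(fit$fvec^2), converged = converged,
                 mode = mode),
            class = "constriction_fit")
}

#' @export
print.constriction_fit <- function(x, ...) {
  cat(sprintf(
    "constriction fit (%s): d0 %.0f nm, t0 %.1f s, k %.1f nm^2/s, t_eff %.1f min%s\n",
    x$mode, x$d0, x$t0, x$k, x$t_eff / 60,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Effective constriction time
#'
#' The conventional summary `t_eff = 2 pi d0^2 / k`: the reported effective
#' time for an unconstricted septum of diameter `d0` to constrict at area
#' addition rate `k`. Note this conventional quantity is 8 times the
#' model's geometric completion time `pi d0^2 / (4k)` (see
#' [constriction_completion_time()]); both are exposed, comparisons between
#' conditions are ratio-based and therefore unaffected by the convention.
#'
#' @param d0 initial diameter, nm (1100 nm is the physiological
#'   unconstricted default).
#' @param k area addition rate, nm^2/s.
#' @return time, s.
#' @export
effective_constriction_time <- function(d0, k) {
  check_positive(d0, "d0"); check_positive(k, "k")
  2 * pi * d0^2 / k
}

#' Geometric completion time of the constriction model
#'
#' First time at which the modelled diameter reaches zero, measured from
#' the constriction start: `pi d0^2 / (4k)`.
#'
#' @inheritParams effective_constriction_time
#' @return time, s.
#' @export
constriction_completion_time <- function(d0, k) {
  check_positive(d0, "d0"); check_positive(k, "k")
  pi * d0^2 / (4 * k)
}

#' Septal plate area implied by a leading-edge diameter
#'
#' Area of the annular plate built inward from the initial diameter:
#' `pi/4 (d0^2 - d^2)`; under the model it grows linearly at rate `k` after
#' the constriction start.
#'
#' @param d current diameter, nm.
#' @param d0 initial diameter, nm.
#' @return area, nm^2.
#' @export
septal_plate_area <- function(d, d0) {
  pi / 4 * (d0^2 - d^2)
}
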