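#' Classify Z-ring division state
#'
#' Nascent: axial thickness > 400 nm. Mature: thickness < 400 nm and
#' relative diameter > 0.9. Constricting: thickness < 400 nm and relative
#' diameter < 0.9. Boundary conventions (equalities are undefined by strict
#' inequalities): thickness exactly 400 nm takes the non-nascent branch and
#' relative diameter exactly 0.9 is mature, so every input receives exactly
#' one label.
#'
#' @param thickness axial thickness, nm (> 0); vectorised.
#' @param rel_diameter diameter divided by the unconstricted reference
#'   diameter (> 0); vectorised.
#' @return character vector: `"nascent"`, `"mature"` or `"constricting"`.
#' @export
classify_state <- function(thickness, rel_diameter) {
  if (any(thickness <= 0) || any(rel_diameter <= 0))
    stop_param("thickness and rel_diameter must be positive")
  ifelse(thickness > 400, "nascent",
         ifelse(rel_diameter >= 0.9, "mature", "constricting"))
}

# two-segment variance-change cost: sum over segments of n * log(sd),
# population sd, floored to keep degenerate segments finite
segment_cost <- function(n, sumx, sumx2) {
  v <- pmax(sumx2 / n - (sumx / n)^2, 0)
  n * 0.5 * log(pmax(v, 1e-16))
}

#' Detect a condensation step in an axial-thickness series
#'
#' Global single change-point detection driven by changes in the standard
#' deviation of the series: for every admissible split the cost
#' `n1*log(sd1) + n2*log(sd2)` (the Gaussian variance-change likelihood) is
#' evaluated and the global minimiser taken. The two-state result is
#' accepted only when the two segment means differ by at least
#' `min_step` (50 nm); otherwise a single state is reported.
#'
#' @param thickness_series numeric vector, nm (>= 10 points).
#' @param min_step minimum mean difference for a real state change, nm.
#' @param min_seg minimum segment length (points).
#' @return list of class `state_segmentation`: `n_states` (1 or 2),
#'   `change_index` (last index of the first segment; `NA` if one state),
#'   `means`, `sds` (per segment, nm), `cost`.
#' @export
detect_condensation_step <- function(thickness_series, min_step = 50,
                                     min_seg = 2L) {
  x <- as.numeric(thickness_series)
  n <- length(x)
  if (n < 10L) stop_param("need at least 10 points for state detection")
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  j <- seq(min_seg, n - min_seg)       # split after index j
  n1 <- j; n2 <- n - j
  s1 <- cs[j]; s2 <- cs[n] - cs[j]
  q1 <- cs2[j]; q2 <- cs2[n] - cs2[j]
  cost2 <- segment_cost(n1, s1, q1) + segment_cost(n2, s2, q2)
  best <- which.min(cost2)
  jb <- j[best]
  m1 <- s1[best] / n1[best]; m2 <- s2[best] / n2[best]
  if (abs(m1 - m2) >= min_step) {
    structure(list(
      n_states = 2L, change_index = jb,
      means = c(m1, m2),
      sds = c(sqrt(max(q1[best] / n1[best] - m1^2, 0)),
              sqrt(max(q2[best] / n2[best] - m2^2, 0))),
      cost = cost2[best]), class = "state_segmentation")
  } else {
    m <- mean(x)
    structure(list(
      n_states = 1L, change_index = NA_integer_,
      means = m, sds = sqrt(max(mean(x^2) - m^2, 0)),
      cost = segment_cost(n, cs[n], cs2[n])),
      class = "state_segmentation")
  }
}

#' Low-thickness rule for partially condensed (GTPase-mutant) rings
#'
#' Rings expressing GTPase-deficient FtsZ lack the clean two-state
#' condensation step, so they are scored as "low thickness before
#' constriction" when the axial thickness drops below a threshold for at
#' least one frame before constriction starts. The default threshold,
#' 356 nm, is one standard deviation above the mean thickness of condensed
#' wild-type rings.
#'
#' @param thickness_series nm.
#' @param t constriction start, expressed as the index of the first
#'   constricting sample.
#' @param threshold nm.
#' @return logical.
#' @export
d213a_low_thickness <- function(thickness_series, t, threshold = 356) {
  n <- length(thickness_series)
  if (t < 1 || t > n) stop_param("constriction start must lie within the series")
  pre <- thickness_series[seq_len(t - 1)]
  length(pre) > 0 && any(pre < threshold)
}

#' Align ring trajectories to the start of constriction
#'
#' Shifts each trajectory's time axis so its constriction start maps to
#' zero; no resampling, inter-sample intervals are preserved exactly.
#' Trajectories with a missing start time are dropped with a warning.
#'
#' @param trajectories list of data frames, each with a `t_s` column.
#' @param t0s numeric vector of per-trajectory constriction start times
#'   (same units as `t_s`; `NA` to skip).
#' @return list of aligned trajectories.
#' @export
align_to_constriction <- function(trajectories, t0s) {
  if (length(trajectories) != length(t0s))
    stop_param("need one constriction start per trajectory")
  out <- vector("list", length(trajectories))
  keep <- logical(length(trajectories))
  for (i in seq_along(trajectories)) {
    if (is.na(t0s[i])) {
      warning("trajectory ", i, " has no constriction start; skipped")
      next
    }
    tr <- trajectories[[i]]
    tr$t_s <- tr$t_s - t0s[i]
    out[[i]] <- tr
    keep[i] <- TRUE
  }
  out[keep]
}

#' Classify septal synthase (PBP2B) level
#'
#' Septal transpeptidase signal, normalised to \[0, 1\], thresholded at 0.5;
#' exactly 0.5 counts as high (documented convention).
#'
#' @param normalised_intensity numeric in \[0, 1\]; vectorised.
#' @return character vector `"low"` / `"high"`.
#' @export
classify_pbp2b_level <- function(normalised_intensity) {
  if (any(normalised_intensity < 0))
    stop_param("normalised intensity must be non-negative")
  ifelse(normalised_intensity < 0.5, "low", "high")
}

#' Relative diameter of a trajectory
#'
#' Diameter divided by the trajectory's own unconstricted reference: the
#' median diameter over the pre-constriction portion, falling back to
#' 1100 nm (the physiological unconstricted septum) when no pre-constriction
#' samples exist.
#'
#' @param diameter_nm vector of diameters, nm.
#' @param t0_index index of the first constricting sample (`NA` = all
#'   pre-constriction).
#' @return vector of relative diameters.
#' @export
relative_diameter <- function(diameter_nm, t0_index = NA) {
  ref <- if (!is.na(t0_index) && t0_index > 1)
    median(diameter_nm[seq_len(t0_index - 1)])
  else if (is.na(t0_index)) median(diameter_nm)
  else NA_real_
  if (is.na(ref) || ref <= 0) ref <- 1100
  diameter_nm / ref
}
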