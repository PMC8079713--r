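#' Hessian ridge filter for kymographs
#'
#' Gaussian blur at the feature scale (default 2 px, 130 nm at 65 nm/px)
#' followed, per pixel, by the major eigenvalue of the Hessian matrix of the
#' blurred image — the eigenvalue of largest absolute value, computed from
#' central finite differences. Bright ridges (treadmilling filaments) have
#' dominant negative curvature across the ridge and so yield strongly
#' negative values along their centrelines, independent of absolute
#' intensity. The angular axis is treated as periodic, the time axis as
#' replicated.
#'
#' @param kymo a [kymograph()] or plain matrix (rows = time, columns =
#'   angle).
#' @param sigma_px blur standard deviation, px.
#' @param bright_ridges negate the output so bright ridges become positive
#'   (display convenience).
#' @return filtered matrix, same dimensions.
#' @export
ridge_filter <- function(kymo, sigma_px = 2, bright_ridges = FALSE) {
  m <- if (inherits(kymo, "vercini_kymograph")) kymo$values else kymo
  if (nrow(m) < 3L || ncol(m) < 3L)
    stop_param("kymograph must be at least 3 x 3")
  check_positive(sigma_px, "sigma_px")
  sm <- gaussian_blur(m, sigma_px,
                      boundary_rows = "replicate",   # time
                      boundary_cols = "periodic")    # angle
  br <- "replicate"; bc <- "periodic"
  sh <- function(dr, dc) shift_mat(sm, dr, dc, br, bc)
  hrr <- sh(1, 0) - 2 * sm + sh(-1, 0)
  hcc <- sh(0, 1) - 2 * sm + sh(0, -1)
  hrc <- (sh(1, 1) - sh(1, -1) - sh(-1, 1) + sh(-1, -1)) / 4
  tr2 <- (hrr + hcc) / 2
  disc <- sqrt(((hrr - hcc) / 2)^2 + hrc^2)
  l1 <- tr2 + disc
  l2 <- tr2 - disc
  major <- ifelse(abs(l1) >= abs(l2), l1, l2)
  if (bright_ridges) -major else major
}

#' Filament trace container
#'
#' An annotated filament trajectory on a kymograph: ordered (time, angle)
#' points plus the ring radius used to convert angular displacement to arc
#' length.
#'
#' @param t_s times, s (strictly increasing, length >= 2).
#' @param angle_deg angular positions, degrees (any real; wrapping is
#'   handled by unwrapping at analysis time).
#' @param radius_nm ring radius, nm.
#' @export
filament_trace <- function(t_s, angle_deg, radius_nm) {
  if (length(t_s) < 2L || length(t_s) != length(angle_deg))
    stop_param("a trace needs >= 2 (time, angle) points")
  if (any(diff(t_s) <= 0)) stop_param("trace times must be strictly increasing")
  check_positive(radius_nm, "radius_nm")
  structure(list(t_s = as.numeric(t_s), angle_deg = as.numeric(angle_deg),
                 radius_nm = radius_nm),
            class = "filament_trace")
}

# minimal-step unwrapping of consecutive angular differences
unwrap_steps <- function(angle_deg) {
  d <- diff(angle_deg)
  ((d + 180) %% 360) - 180
}

#' Treadmilling speed of a filament trace
#'
#' Speed is the absolute total unwrapped angular displacement (each
#' consecutive step taken as the minimal consistent angular difference)
#' converted to arc length at the ring radius, divided by the trace
#' lifetime.
#'
#' @param trace a [filament_trace()].
#' @return speed, nm/s.
#' @export
trace_to_speed <- function(trace) {
  trace_metrics(trace)$speed_nm_s
}

#' Immobile-filament classification
#'
#' A filament is immobile when its speed is below 10 nm/s (strict
#' inequality; 10 nm/s itself counts as mobile).
#'
#' @param speed nm/s (>= 0).
#' @return logical.
#' @export
classify_immobile <- function(speed) {
  if (any(speed < 0)) stop_param("speeds must be non-negative")
  speed < 10
}

#' Summary metrics of a filament trace
#'
#' @param trace a [filament_trace()].
#' @return one-row data frame: `speed_nm_s`, `lifetime_s`, `distance_nm`
#'   (arc length of the total unwrapped displacement), `immobile`.
#' @export
trace_metrics <- function(trace) {
  lifetime <- trace$t_s[length(trace$t_s)] - trace$t_s[1]
  if (lifetime <= 0) stop_param("trace lifetime must be positive")
  total_deg <- sum(unwrap_steps(trace$angle_deg))
  distance <- abs(total_deg) * pi / 180 * trace$radius_nm
  speed <- distance / lifetime
  data.frame(speed_nm_s = speed, lifetime_s = lifetime,
             distance_nm = distance, immobile = classify_immobile(speed))
}

#' Metrics for a table of traces
#'
#' @param traces data frame in long format with columns `trace_id`, `t_s`,
#'   `angle_deg`.
#' @param radius_nm ring radius, nm.
#' @return data frame, one row per trace id, with the [trace_metrics()]
#'   columns.
#' @export
trace_metrics_table <- function(traces, radius_nm) {
  ids <- unique(traces$trace_id)
  out <- lapply(ids, function(id) {
    tr <- traces[traces$trace_id == id, , drop = FALSE]
    tr <- tr[order(tr$t_s), , drop = FALSE]
    cbind(trace_id = id,
          trace_metrics(filament_trace(tr$t_s, tr$angle_deg, radius_nm)))
  })
  do.call(rbind, out)
}

#' Ground-truth-guided trace measurement on a kymograph
#'
#' Automated filament tracking is deliberately not implemented (at cellular
#' filament densities such trackers fragment trajectories and miss immobile
#' filaments); traces normally enter as manual annotations. For simulated
#' movies this function plays the annotator: for each ground-truth filament
#' alive for at least `min_frames` frames, the filament's angular position
#' in each frame is measured as the intensity-weighted centroid of the
#' kymograph row within a window around the (known) ground-truth angle, and
#' the measured positions form the trace. Speeds derived from these traces
#' test the whole imaging-plus-extraction pipeline, with the fitted ring
#' radius used for the arc conversion.
#'
#' @param kymo a (non-doubled) [kymograph()].
#' @param truth ground-truth filament table from [simulate_filaments()].
#' @param ring_diameter_nm ground-truth ring diameter used to propagate the
#'   true angles, nm.
#' @param window_deg half-width of the measurement window, degrees.
#' @param min_frames minimum frames a filament must be visible.
#' @return list of [filament_trace()] objects, named by filament id, with
#'   the matching rows of `truth` as attribute `"truth"`.
#' @export
guided_traces <- function(kymo, truth, ring_diameter_nm,
                          window_deg = 12, min_frames = 5L) {
  dt <- kymo$frame_interval
  nf <- nrow(kymo$values)
  nang <- ncol(kymo$values)
  step <- 360 / nang
  radius_true <- ring_diameter_nm / 2
  traces <- list(); keep <- integer(0)
  hw <- max(1L, round(window_deg / step))
  for (i in seq_len(nrow(truth))) {
    f <- truth[i, ]
    ft <- (seq_len(nf) - 1) * dt
    frames <- which(ft >= f$birth_s & ft < f$death_s)
    if (length(frames) < min_frames) next
    ang_meas <- numeric(length(frames))
    ok <- logical(length(frames))
    for (kidx in seq_along(frames)) {
      j <- frames[kidx]
      t <- (j - 1) * dt
      a_true <- filament_angle_at(f, t, radius_true)
      centre_col <- round(a_true / step) + 1L
      cols <- ((centre_col - hw - 1L):(centre_col + hw - 1L)) %% nang + 1L
      row <- kymo$values[j, cols]
      if (anyNA(row)) next
      w <- pmax(row, 0)
      if (sum(w) <= 0) { ang_meas[kidx] <- a_true; ok[kidx] <- TRUE; next }
      # intensity-weighted centroid about the window centre
      offs <- seq(-hw, hw) * step
      ang_meas[kidx] <- (centre_col - 1L) * step + sum(w * offs) / sum(w)
      ok[kidx] <- TRUE
    }
    if (sum(ok) < min_frames) next
    tt <- (frames[ok] - 1) * dt
    tr <- filament_trace(tt, ang_meas[ok] %% 360, kymo$radius_nm)
    attr(tr, "truth") <- f
    traces[[length(traces) + 1L]] <- tr
    keep <- c(keep, f$filament_id)
  }
  names(traces) <- as.character(keep)
  traces
}
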