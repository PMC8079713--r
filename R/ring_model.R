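#' Septal ring image-model parameters
#'
#' Joint model of a vertically imaged septal ring: the signal is a
#' twelve-sector annulus, radially Gaussian about radius `R0` with one
#' amplitude per 30-degree sector, evaluated in polar coordinates about the
#' sub-pixel centre `(x0, y0)`; the cytoplasmic background is a central
#' Gaussian plus a Cauchy (Lorentzian) term plus a constant.
#'
#' Coordinate convention: pixel centres at integer coordinates, origin
#' top-left, x rightward, y downward; the polar angle is measured
#' counterclockwise (as displayed) from +x, and sector i covers
#' \[30(i-1), 30i) degrees.
#'
#' @param x0,y0 ring centre, px.
#' @param R0 ring radius, px.
#' @param sigma annulus radial width, px.
#' @param A numeric vector of 12 sector amplitudes (ADU).
#' @param a Gaussian background amplitude (ADU).
#' @param sigma_bg1 Gaussian background width (px).
#' @param b Cauchy background amplitude (ADU).
#' @param sigma_bg2 Cauchy background scale (px).
#' @param c_ constant background offset (ADU).
#' @return object of class `ring_model_params`.
#' @export
ring_model_params <- function(x0, y0, R0, sigma, A, a, sigma_bg1, b,
                              sigma_bg2, c_) {
  check_positive(R0, "R0"); check_positive(sigma, "sigma")
  check_positive(sigma_bg1, "sigma_bg1"); check_positive(sigma_bg2, "sigma_bg2")
  if (length(A) != 12L || any(A < 0))
    stop_param("`A` must be 12 non-negative sector amplitudes")
  check_nonneg(a, "a"); check_nonneg(b, "b"); check_nonneg(c_, "c_")
  structure(list(x0 = x0, y0 = y0, R0 = R0, sigma = sigma, A = as.numeric(A),
                 a = a, sigma_bg1 = sigma_bg1, b = b, sigma_bg2 = sigma_bg2,
                 c = c_),
            class = "ring_model_params")
}

#' @export
print.ring_model_params <- function(x, ...) {
  cat(sprintf("ring model: centre (%.2f, %.2f) px, R0 %.2f px, sigma %.2f px\n",
              x$x0, x$y0, x$R0, x$sigma))
  cat(sprintf("  sector amplitudes: %s\n",
              paste(sprintf("%.3g", x$A), collapse = " ")))
  cat(sprintf("  background: a %.3g (s %.3g px), b %.3g (s %.3g px), c %.3g\n",
              x$a, x$sigma_bg1, x$b, x$sigma_bg2, x$c))
  invisible(x)
}

# polar angle (degrees, [0,360)) of pixels about (x0, y0); counterclockwise
# as displayed (y axis points down).
polar_angle_deg <- function(x, y, x0, y0) {
  (atan2(y0 - y, x - x0) * 180 / pi) %% 360
}

eval_background <- function(p, x, y) {
  r2 <- (x - p$x0)^2 + (y - p$y0)^2
  p$a * exp(-r2 / (2 * p$sigma_bg1^2)) +
    p$b * p$sigma_bg2^2 / (r2 + p$sigma_bg2^2) + p$c
}

#' Evaluate the septal ring model on a pixel grid
#'
#' @param params a [ring_model_params()].
#' @param ny,nx grid size (rows, columns).
#' @return `ny` x `nx` intensity matrix (ADU).
#' @export
evaluate_ring_model <- function(params, ny, nx = ny) {
  x <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  y <- matrix(seq_len(ny), ny, nx)
  r <- sqrt((x - params$x0)^2 + (y - params$y0)^2)
  th <- polar_angle_deg(x, y, params$x0, params$y0)
  sector <- pmin(floor(th / 30) + 1L, 12L)
  amp <- matrix(params$A[sector], ny, nx)
  amp * exp(-(r - params$R0)^2 / (2 * params$sigma^2)) +
    eval_background(params, x, y)
}

pack_params <- function(p) {
  c(p$x0, p$y0, p$R0, p$sigma, p$A, p$a, p$sigma_bg1, p$b, p$sigma_bg2, p$c)
}

unpack_params <- function(v) {
  structure(list(x0 = v[1], y0 = v[2], R0 = v[3], sigma = v[4],
                 A = v[5:16], a = v[17], sigma_bg1 = v[18], b = v[19],
                 sigma_bg2 = v[20], c = v[21]),
            class = "ring_model_params")
}

# radial mean profile in 1-px bins around (x0, y0)
radial_profile <- function(frame, x0, y0) {
  ny <- nrow(frame); nx <- ncol(frame)
  x <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  y <- matrix(seq_len(ny), ny, nx)
  r <- sqrt((x - x0)^2 + (y - y0)^2)
  bin <- round(r)
  means <- tapply(as.vector(frame), as.vector(bin), mean)
  list(r = as.numeric(names(means)), value = as.numeric(means))
}

init_ring_params <- function(frame) {
  ny <- nrow(frame); nx <- ncol(frame)
  x <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  y <- matrix(seq_len(ny), ny, nx)
  w <- frame - min(frame)
  tot <- sum(w)
  if (tot <= 0) { x0 <- (nx + 1) / 2; y0 <- (ny + 1) / 2 }
  else { x0 <- sum(w * x) / tot; y0 <- sum(w * y) / tot }
  c0 <- as.numeric(quantile(frame, 0.05))
  a0 <- max(mean(frame[abs(y - y0) < 2 & abs(x - x0) < 2]) - c0, 1e-3)
  bg0 <- list(x0 = x0, y0 = y0, a = a0 / 2, sigma_bg1 = max(nx, ny) / 6,
              b = a0 / 2, sigma_bg2 = max(nx, ny) / 4, c = c0)
  # background-only pre-fit (7 parameters) so the ring shows up in the
  # residual radial profile
  resid_bg <- function(v) {
    p <- list(x0 = v[1], y0 = v[2], a = v[3], sigma_bg1 = v[4], b = v[5],
              sigma_bg2 = v[6], c = v[7])
    as.vector(frame - eval_background(p, x, y))
  }
  v0 <- c(x0, y0, bg0$a, bg0$sigma_bg1, bg0$b, bg0$sigma_bg2, bg0$c)
  bgfit <- try(minpack.lm::nls.lm(
    par = v0, fn = resid_bg,
    lower = c(1, 1, 0, 0.5, 0, 0.5, 0),
    upper = c(nx, ny, Inf, 4 * max(nx, ny), Inf, 4 * max(nx, ny), Inf),
    control = minpack.lm::nls.lm.control(maxiter = 60)), silent = TRUE)
  if (!inherits(bgfit, "try-error")) {
    v <- bgfit$par
    bgp <- list(x0 = v[1], y0 = v[2], a = v[3], sigma_bg1 = v[4], b = v[5],
                sigma_bg2 = v[6], c = v[7])
  } else bgp <- bg0
  res <- frame - eval_background(bgp, x, y)
  prof <- radial_profile(res, bgp$x0, bgp$y0)
  rmax <- min(nx, ny) / 2 - 1
  sel <- which(prof$r >= 2 & prof$r <= rmax)
  # candidate radii: strong local maxima of the residual radial profile;
  # a weak annulus can be rivalled by a residual central bump, so all
  # comparable peaks are tried and the best-RSS fit wins
  cand <- numeric(0)
  if (length(sel) >= 3) {
    v <- prof$value[sel]
    pk <- sel[which(diff(sign(diff(c(-Inf, v, -Inf)))) < 0)]
    pk <- pk[prof$value[pk] >= 0.4 * max(v)]
    cand <- prof$r[pk]
  }
  if (length(cand) == 0) cand <- max(rmax / 2, 2)
  cand <- utils::head(cand[order(-prof$value[match(cand, prof$r)])], 3L)
  A0 <- max(prof$value[sel], 1e-3)
  lapply(cand, function(R0)
    ring_model_params(bgp$x0, bgp$y0, max(R0, 1.5), 2, rep(A0, 12),
                      max(bgp$a, 0), max(bgp$sigma_bg1, 0.5),
                      max(bgp$b, 0), max(bgp$sigma_bg2, 0.5),
                      max(bgp$c, 0)))
}

#' Fit the septal ring model to one frame
#'
#' Nonlinear least squares (Levenberg-Marquardt with box bounds) of the
#' twelve-sector annulus plus Gaussian-Cauchy background model against a
#' single image frame. When no initial parameters are supplied, the fit
#' self-initialises: the centre from the intensity centroid, the background
#' from a background-only pre-fit, and the ring radius from the argmax of
#' the background-subtracted radial mean profile.
#'
#' @param frame image matrix (ADU), at least ~4 ring radii wide.
#' @param init optional [ring_model_params()] warm start (e.g. the previous
#'   frame's fit).
#' @param fix_sigma optional fixed annulus width (px); by default the width
#'   is fitted.
#' @return a [ring_model_params()] with diagnostic fields `rss`,
#'   `converged`, `noise_sd` attached as attributes.
#' @section No-ring detection: if the fitted sector amplitudes are
#'   indistinguishable from the residual noise floor, an error of class
#'   `vercini_no_ring_error` is raised.
#' @export
fit_ring_model <- function(frame, init = NULL, fix_sigma = NULL) {
  ny <- nrow(frame); nx <- ncol(frame)
  inits <- if (is.null(init)) init_ring_params(frame) else list(init)
  x <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  y <- matrix(seq_len(ny), ny, nx)
  th_cache <- NULL
  model_of <- function(v) {
    p <- unpack_params(v)
    r <- sqrt((x - p$x0)^2 + (y - p$y0)^2)
    th <- polar_angle_deg(x, y, p$x0, p$y0)
    sector <- pmin(floor(th / 30) + 1L, 12L)
    matrix(p$A[sector], ny, nx) * exp(-(r - p$R0)^2 / (2 * p$sigma^2)) +
      eval_background(p, x, y)
  }
  sig_fixed <- !is.null(fix_sigma)
  resid_fn <- function(v) {
    if (sig_fixed) v[4] <- fix_sigma
    as.vector(frame - model_of(v))
  }
  lower <- c(1, 1, 1, 0.4, rep(0, 12), 0, 0.5, 0, 0.5, 0)
  upper <- c(nx, ny, max(nx, ny) / 2, max(nx, ny) / 2, rep(Inf, 12),
             Inf, 4 * max(nx, ny), Inf, 4 * max(nx, ny), Inf)
  fit <- NULL
  for (ini in inits) {
    if (sig_fixed) ini$sigma <- fix_sigma
    v0 <- pmin(pmax(pack_params(ini), lower), upper)
    cand <- minpack.lm::nls.lm(
      par = v0, fn = resid_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        maxiter = 300, ftol = 1e-12, ptol = 1e-12))
    if (is.null(fit) || sum(cand$fvec^2) < sum(fit$fvec^2)) fit <- cand
  }
  v <- fit$par
  if (sig_fixed) v[4] <- fix_sigma
  p <- unpack_params(v)
  res <- resid_fn(v)
  noise_sd <- sd(res)
  if (max(p$A) < 2 * noise_sd + 1e-8 * (abs(p$c) + 1))
    stop(errorCondition(
      "no ring detected: annulus amplitude below the noise floor",
      class = c("vercini_no_ring_error", "error")))
  attr(p, "rss") <- sum(res^2)
  attr(p, "converged") <- fit$info %in% 1:4
  attr(p, "noise_sd") <- noise_sd
  p
}

#' Time-averaged frame of a movie
#'
#' Treadmilling spreads filament signal around the circumference over time,
#' so the temporal mean shows the full annulus even when single frames
#' contain only a couple of filaments; the geometry (centre, radius) is
#' therefore best initialised on the average frame.
#'
#' @param movie a [movie_stack()].
#' @return matrix, the pixel-wise mean over frames.
#' @export
average_frame <- function(movie) {
  Reduce(`+`, movie$frames) / length(movie$frames)
}

#' Fit the ring model to every frame of a movie
#'
#' Frames are fitted independently, each warm-started from the previous
#' frame's result; the first fit is warm-started from a fit of the
#' time-averaged frame (see [average_frame()]) unless `init` is given.
#' A frame where the optimiser fails to converge is flagged (not an error);
#' a frame with no detectable ring inherits the latest usable fit (the ring
#' geometry does not move between frames; only its occupancy fluctuates),
#' or `NULL` if none exists yet.
#'
#' @param movie a [movie_stack()].
#' @param init optional warm start for the first frame.
#' @param every fit every `every`-th frame and reuse the latest fit in
#'   between (the ring is stationary on the second timescale of these
#'   movies); default 1 fits all frames.
#' @param max_r0_dev per-frame fits whose radius deviates from the
#'   time-average geometry by more than this relative amount are treated as
#'   failed and replaced by the latest usable fit. Single frames with very
#'   few filaments do not constrain the annulus geometry; a large radius
#'   excursion on a stationary ring signals a collapsed fit, not motion.
#' @return list of per-frame [ring_model_params()] (or `NULL`).
#' @export
fit_ring_movie <- function(movie, init = NULL, every = 1L,
                           max_r0_dev = 0.25) {
  nf <- n_frames(movie)
  fits <- vector("list", nf)
  if (is.null(init))
    init <- tryCatch(fit_ring_model(average_frame(movie)),
                     vercini_no_ring_error = function(e) NULL)
  prev <- init
  for (j in seq_len(nf)) {
    if (j == 1L || (j - 1L) %% every == 0L) {
      f <- tryCatch(fit_ring_model(movie$frames[[j]], init = prev),
                    vercini_no_ring_error = function(e) NULL)
      if (!is.null(f) && !is.null(init) &&
          abs(f$R0 - init$R0) / init$R0 > max_r0_dev)
        f <- NULL
      if (!is.null(f)) prev <- f
      fits[[j]] <- if (!is.null(f)) f else prev
    } else {
      fits[[j]] <- fits[[j - 1L]]
    }
  }
  fits
}

#' Circumferential kymograph container
#'
#' @param values matrix, rows = frames, columns = angular samples, of
#'   background-subtracted intensity.
#' @param angles angular sample positions, degrees.
#' @param radius_nm ring radius used for sampling, nm.
#' @param frame_interval s.
#' @param doubled whether columns span two revolutions (0-720 degrees).
#' @export
kymograph <- function(values, angles, radius_nm, frame_interval,
                      doubled = FALSE) {
  structure(list(values = values, angles = angles, radius_nm = radius_nm,
                 frame_interval = frame_interval, doubled = doubled),
            class = "vercini_kymograph")
}

#' @export
print.vercini_kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d frames x %d angles%s, radius %.0f nm, %g s/frame\n",
              nrow(x$values), ncol(x$values),
              if (x$doubled) " (doubled, 0-720 deg)" else "",
              x$radius_nm, x$frame_interval))
  invisible(x)
}

#' Extract the circumferential kymograph of a septal movie
#'
#' For each frame, the fitted background is subtracted on the pixel grid and
#' the residual is sampled by bilinear interpolation along the circular line
#' profile at the fitted radius, producing one kymograph row per frame.
#' Frames whose fit is missing or non-converged yield rows of `NA`.
#'
#' @param movie a [movie_stack()].
#' @param fits one [ring_model_params()] (reused for all frames) or a list
#'   with one element per frame, as from [fit_ring_movie()].
#' @param angular_step degrees per column (default 1).
#' @param doubled duplicate the columns over a second revolution (0-720
#'   degrees side by side), the display convention that keeps filament
#'   trajectories crossing the 0/360 boundary readable.
#' @return a [kymograph()].
#' @export
extract_kymograph <- function(movie, fits, angular_step = 1,
                              doubled = FALSE) {
  check_positive(angular_step, "angular_step")
  nf <- n_frames(movie)
  if (inherits(fits, "ring_model_params")) fits <- rep(list(fits), nf)
  if (length(fits) != nf)
    stop_param("need one fit per frame (or a single fit to reuse)")
  angles <- seq(0, 360 - angular_step, by = angular_step)
  ny <- nrow(movie$frames[[1]]); nx <- ncol(movie$frames[[1]])
  x <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  y <- matrix(seq_len(ny), ny, nx)
  vals <- matrix(NA_real_, nf, length(angles))
  bg_cache_key <- NULL; bg_img <- NULL
  used_r0 <- rep(NA_real_, nf)
  for (j in seq_len(nf)) {
    p <- fits[[j]]
    if (is.null(p)) next
    conv <- attr(p, "converged")
    if (!is.null(conv) && !conv) next
    key <- pack_params(p)
    if (is.null(bg_cache_key) || !identical(key, bg_cache_key)) {
      bg_img <- eval_background(p, x, y)
      bg_cache_key <- key
    }
    sub <- movie$frames[[j]] - bg_img
    ar <- angles * pi / 180
    sx <- p$x0 + p$R0 * cos(ar)
    sy <- p$y0 - p$R0 * sin(ar)
    vals[j, ] <- bilinear_sample(sub, sx, sy)
    used_r0[j] <- p$R0
  }
  if (all(is.na(used_r0)))
    stop_param("no usable ring fit in any frame")
  # robust radius summary across frames for the arc-length conversion
  radius_px <- median(used_r0, na.rm = TRUE)
  k <- kymograph(vals, angles, radius_px * movie$pixel_size,
                 movie$frame_interval, doubled = FALSE)
  if (doubled) double_kymograph(k) else k
}

#' Duplicate a kymograph over a second revolution (0-720 degrees)
#'
#' @param kymo a [kymograph()].
#' @return doubled kymograph; the second half of the columns repeats the
#'   first.
#' @export
double_kymograph <- function(kymo) {
  if (kymo$doubled) return(kymo)
  kymograph(cbind(kymo$values, kymo$values),
            c(kymo$angles, kymo$angles + 360),
            kymo$radius_nm, kymo$frame_interval, doubled = TRUE)
}

#' Median septal intensity of a kymograph
#'
#' Median over all pixels of the (non-doubled) kymograph's first 60 frames
#' (or all frames if fewer), the per-ring intensity summary used to compare
#' septal protein levels between rings.
#'
#' @param kymo a [kymograph()].
#' @return median background-subtracted intensity.
#' @export
median_septal_intensity <- function(kymo) {
  v <- kymo$values
  if (kymo$doubled) v <- v[, seq_len(ncol(v) / 2), drop = FALSE]
  if (nrow(v) == 0L || ncol(v) == 0L) stop_param("empty kymograph")
  median(v[seq_len(min(60L, nrow(v))), ], na.rm = TRUE)
}

#' Ring diameter in nanometres
#'
#' @param params a [ring_model_params()].
#' @param pixel_size nm/px (65 nm/px on the reference instrument).
#' @return diameter, nm.
#' @export
ring_diameter_nm <- function(params, pixel_size = 65) {
  check_positive(pixel_size, "pixel_size")
  2 * params$R0 * pixel_size
}

#' Per-frame ring-fit table
#'
#' @param fits list from [fit_ring_movie()].
#' @return data frame with one row per frame: centre, radius, width, sector
#'   amplitudes, background parameters, residual sum of squares and
#'   convergence flag (`NA` rows for frames with no detectable ring).
#' @export
ring_fit_table <- function(fits) {
  rows <- lapply(seq_along(fits), function(j) {
    p <- fits[[j]]
    if (is.null(p)) {
      as.data.frame(c(list(frame = j), stats::setNames(
        as.list(rep(NA_real_, 21)), fit_table_cols()),
        list(rss = NA_real_, converged = FALSE)))
    } else {
      v <- as.list(pack_params(p))
      names(v) <- fit_table_cols()
      as.data.frame(c(list(frame = j), v,
                      list(rss = attr(p, "rss"),
                           converged = isTRUE(attr(p, "converged")))))
    }
  })
  do.call(rbind, rows)
}

fit_table_cols <- function() {
  c("x0", "y0", "R0", "sigma", paste0("A_", 0:11),
    "a", "sigma_bg1", "b", "sigma_bg2", "c")
}
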