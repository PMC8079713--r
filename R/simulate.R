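#' Speed samplers for simulated treadmilling filaments
#'
#' Treadmilling speeds of mobile filaments are drawn either from a lognormal
#' distribution parameterised by its median and interquartile range (the
#' field reports speed distributions by median and IQR), from a constant, or
#' by bootstrap resampling of an empirical table of measured speeds.
#'
#' @param median,iqr target median and interquartile range, nm/s.
#' @param value constant speed, nm/s.
#' @param values numeric vector of measured speeds (nm/s) to resample.
#' @return a speed-sampler object used by [sim_config()].
#' @examples
#' s <- speed_lognormal(28, 16)
#' @export
speed_lognormal <- function(median, iqr) {
  check_positive(median, "median"); check_positive(iqr, "iqr")
  # IQR = 2 * median * sinh(z75 * sdlog) for a lognormal
  sdlog <- asinh(iqr / (2 * median)) / qnorm(0.75)
  structure(list(type = "lognormal", meanlog = log(median), sdlog = sdlog,
                 median = median, iqr = iqr),
            class = "vercini_speed_sampler")
}

#' @rdname speed_lognormal
#' @export
speed_constant <- function(value) {
  check_nonneg(value, "value")
  structure(list(type = "constant", value = value),
            class = "vercini_speed_sampler")
}

#' @rdname speed_lognormal
#' @export
speed_empirical <- function(values) {
  if (length(values) == 0L || !is.numeric(values) || anyNA(values))
    stop_param("empirical speed table must be a non-empty numeric vector")
  structure(list(type = "empirical", values = as.numeric(values)),
            class = "vercini_speed_sampler")
}

draw_speeds <- function(sampler, n) {
  if (n == 0L) return(numeric(0))
  switch(sampler$type,
    lognormal = rlnorm(n, sampler$meanlog, sampler$sdlog),
    constant  = rep(sampler$value, n),
    empirical = sample(sampler$values, n, replace = TRUE),
    stop_param("unknown speed sampler type")
  )
}

#' Median of the configured filament speed distribution
#'
#' Median of the mixture of immobile (uniform on \[0, 10) nm/s) and mobile
#' (speed-sampler) filaments, used as the reference value when validating
#' pipeline speed recovery on simulated data.
#'
#' @param config a [sim_config()].
#' @return median speed, nm/s.
#' @export
config_speed_median <- function(config) {
  p <- config$immobile_fraction
  mob_q <- function(q) switch(config$speed_sampler$type,
    lognormal = exp(config$speed_sampler$meanlog +
                    config$speed_sampler$sdlog * qnorm(q)),
    constant  = config$speed_sampler$value,
    empirical = unname(quantile(config$speed_sampler$values, q)))
  if (p >= 1) return(5)
  # immobile component lives entirely below 10 nm/s
  if (p <= 0.5 && mob_q((0.5 - p) / (1 - p)) >= 10)
    mob_q((0.5 - p) / (1 - p))
  else {
    # fall back to numeric quantile of the mixture
    f <- function(m) {
      p * pmin(pmax(m / 10, 0), 1) +
        (1 - p) * switch(config$speed_sampler$type,
          lognormal = stats::plnorm(m, config$speed_sampler$meanlog,
                                    config$speed_sampler$sdlog),
          constant  = as.numeric(m >= config$speed_sampler$value),
          empirical = stats::ecdf(config$speed_sampler$values)(m)) - 0.5
    }
    stats::uniroot(f, c(0, 1e4))$root
  }
}

#' Simulation configuration for vertical-cell septal movies
#'
#' Defaults emulate a nascent Z-ring imaged end-on: a 1100 nm diameter ring
#' sampled at 65 nm/px and 1 frame/s, mean 1.3 filaments per ring per frame,
#' 35% immobile filaments, mobile treadmilling speeds lognormal with median
#' 28 nm/s and IQR 16 nm/s, 30 s mean filament lifetime, and a diffuse
#' Gaussian-plus-Cauchy cytoplasmic background under shot noise, camera gain
#' and read noise.
#'
#' @param ring_diameter ring diameter, nm.
#' @param pixel_size image pixel size, nm/px.
#' @param frame_interval time between frames, s.
#' @param n_frames number of frames.
#' @param filament_density mean filaments per ring per frame.
#' @param mean_lifetime mean filament lifetime, s.
#' @param immobile_fraction probability a filament is immobile (speed drawn
#'   uniformly below the 10 nm/s mobility threshold).
#' @param speed_sampler a sampler from [speed_lognormal()],
#'   [speed_constant()] or [speed_empirical()].
#' @param filament_photons photons emitted per filament per frame.
#' @param psf_sigma point-spread-function standard deviation, nm.
#' @param background_params named vector `c(a, sigma_bg1, b, sigma_bg2, c)`:
#'   Gaussian amplitude (photons), Gaussian width (nm), Cauchy amplitude
#'   (photons), Cauchy scale (nm), constant offset (photons).
#' @param camera_gain camera gain, ADU/photon.
#' @param read_noise read noise, ADU rms.
#' @param offset camera offset, ADU.
#' @param field_px image width/height in pixels; default covers ~2.4 ring
#'   radii on each side.
#' @param seed integer RNG seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(ring_diameter = 1100, pixel_size = 65,
                       frame_interval = 1, n_frames = 120,
                       filament_density = 1.3, mean_lifetime = 30,
                       immobile_fraction = 0.35,
                       speed_sampler = speed_lognormal(28, 16),
                       filament_photons = 400, psf_sigma = 130,
                       background_params = c(a = 30, sigma_bg1 = 400,
                                             b = 20, sigma_bg2 = 650, c = 5),
                       camera_gain = 2, read_noise = 3, offset = 100,
                       field_px = NULL, seed = 1L) {
  check_positive(ring_diameter, "ring_diameter")
  check_positive(pixel_size, "pixel_size")
  check_positive(frame_interval, "frame_interval")
  check_positive(n_frames, "n_frames")
  check_nonneg(filament_density, "filament_density")
  check_positive(mean_lifetime, "mean_lifetime")
  if (immobile_fraction < 0 || immobile_fraction > 1)
    stop_param("`immobile_fraction` must lie in [0, 1]")
  if (!inherits(speed_sampler, "vercini_speed_sampler"))
    stop_param("`speed_sampler` must come from speed_lognormal()/speed_constant()/speed_empirical()")
  check_positive(filament_photons, "filament_photons")
  check_positive(psf_sigma, "psf_sigma")
  bg <- background_params
  need <- c("a", "sigma_bg1", "b", "sigma_bg2", "c")
  if (!all(need %in% names(bg)))
    stop_param("`background_params` must be named c(a, sigma_bg1, b, sigma_bg2, c)")
  if (any(bg[c("a", "b", "c")] < 0) || any(bg[c("sigma_bg1", "sigma_bg2")] <= 0))
    stop_param("background amplitudes must be >= 0 and widths > 0")
  check_positive(camera_gain, "camera_gain")
  check_nonneg(read_noise, "read_noise")
  check_nonneg(offset, "offset")
  r_px <- ring_diameter / 2 / pixel_size
  if (is.null(field_px)) field_px <- 2L * ceiling(2.4 * r_px) + 1L
  structure(list(
    ring_diameter = ring_diameter, pixel_size = pixel_size,
    frame_interval = frame_interval, n_frames = as.integer(n_frames),
    filament_density = filament_density, mean_lifetime = mean_lifetime,
    immobile_fraction = immobile_fraction, speed_sampler = speed_sampler,
    filament_photons = filament_photons, psf_sigma = psf_sigma,
    background_params = bg[need], camera_gain = camera_gain,
    read_noise = read_noise, offset = offset,
    field_px = as.integer(field_px), seed = as.integer(seed)),
    class = "sim_config")
}

#' Draw per-frame filament counts
#'
#' Counts of filaments per ring per frame are Poisson with the configured
#' mean density.
#'
#' @param density mean filaments per ring per frame (>= 0).
#' @param n number of draws.
#' @return integer vector of counts.
#' @export
sample_filament_count <- function(density, n = 1L) {
  check_nonneg(density, "density")
  rpois(n, density)
}

#' Simulate a birth-death population of filaments on the ring
#'
#' Continuous-time birth-death process: births are Poisson with rate
#' `filament_density / mean_lifetime`, lifetimes exponential with the
#' configured mean, so the steady-state expected filament count equals the
#' configured density. The population is initialised in its stationary state
#' (Poisson-distributed initial count, exponential residual lifetimes).
#' Each filament gets a uniform initial angle, a treadmilling direction of
#' +1 or -1 with equal probability, and is immobile with the configured
#' probability (immobile speeds uniform on \[0, 10) nm/s; mobile speeds from
#' the configured sampler).
#'
#' @param config a [sim_config()].
#' @param duration simulated time span, s; defaults to the movie length.
#' @return data frame with columns `filament_id`, `birth_s`, `death_s`,
#'   `angle0_deg`, `speed_nm_s`, `direction`, `immobile`.
#' @export
simulate_filaments <- function(config, duration = NULL) {
  if (is.null(duration)) duration <- config$n_frames * config$frame_interval
  tau <- config$mean_lifetime
  n0 <- rpois(1L, config$filament_density)
  birth <- rep(0, n0)
  death <- rexp(n0, 1 / tau)          # residual lifetime (memoryless)
  beta <- config$filament_density / tau
  nb <- rpois(1L, beta * duration)
  tb <- sort(runif(nb, 0, duration))
  birth <- c(birth, tb)
  death <- c(death, tb + rexp(nb, 1 / tau))
  n <- length(birth)
  immobile <- runif(n) < config$immobile_fraction
  speed <- numeric(n)
  speed[immobile] <- runif(sum(immobile), 0, 10)
  speed[!immobile] <- draw_speeds(config$speed_sampler, sum(!immobile))
  data.frame(
    filament_id = seq_len(n),
    birth_s = birth, death_s = death,
    angle0_deg = runif(n, 0, 360),
    speed_nm_s = speed,
    direction = ifelse(runif(n) < 0.5, -1, 1),
    immobile = immobile)
}

#' Ground-truth angular position of a filament at a time point
#'
#' @param filament one row of the [simulate_filaments()] table.
#' @param t time, s.
#' @param radius_nm ring radius, nm.
#' @return angle in degrees, wrapped to \[0, 360).
#' @export
filament_angle_at <- function(filament, t, radius_nm) {
  ang <- filament$angle0_deg + filament$direction * filament$speed_nm_s /
    radius_nm * (t - filament$birth_s) * 180 / pi
  ang %% 360
}

#' Render a noiseless photon-expectation frame
#'
#' Evaluates the Gaussian-plus-Cauchy cytoplasmic background at every pixel
#' and adds one isotropic 2-D Gaussian of total integral `filament_photons`
#' per filament, centred at the filament's position on the ring. Filaments
#' beyond the pixel grid simply contribute their in-field tail (off-field
#' light is clipped).
#'
#' @param field_px image size (pixels, square).
#' @param centre ring centre `c(x0, y0)` in pixels.
#' @param filament_xy 2-column matrix of filament positions (px); may have
#'   zero rows.
#' @param filament_photons photons per filament.
#' @param psf_sigma_px PSF standard deviation, px.
#' @param bg background parameters `c(a, sigma_bg1, b, sigma_bg2, c)` with
#'   widths in px and amplitudes in photons.
#' @return `field_px` x `field_px` matrix of expected photons.
#' @export
render_frame <- function(field_px, centre, filament_xy, filament_photons,
                         psf_sigma_px, bg) {
  check_positive(psf_sigma_px, "psf_sigma_px")
  x <- matrix(seq_len(field_px), field_px, field_px, byrow = TRUE)
  y <- matrix(seq_len(field_px), field_px, field_px)
  r2 <- (x - centre[1])^2 + (y - centre[2])^2
  img <- bg[["a"]] * exp(-r2 / (2 * bg[["sigma_bg1"]]^2)) +
    bg[["b"]] * bg[["sigma_bg2"]]^2 / (r2 + bg[["sigma_bg2"]]^2) +
    bg[["c"]]
  if (!is.null(filament_xy) && nrow(filament_xy) > 0) {
    amp <- filament_photons / (2 * pi * psf_sigma_px^2)
    for (i in seq_len(nrow(filament_xy))) {
      d2 <- (x - filament_xy[i, 1])^2 + (y - filament_xy[i, 2])^2
      img <- img + amp * exp(-d2 / (2 * psf_sigma_px^2))
    }
  }
  img
}

#' Apply the camera noise model
#'
#' Per pixel: Poisson shot noise on the photon expectation, multiplied by
#' the camera gain, plus Gaussian read noise and a constant offset,
#' quantised to integer ADU and floored at zero.
#'
#' @param photon_image matrix of expected photons (>= 0).
#' @param gain ADU per photon.
#' @param read_noise ADU rms.
#' @param offset ADU.
#' @return integer-valued ADU matrix.
#' @export
add_camera_noise <- function(photon_image, gain, read_noise, offset) {
  check_positive(gain, "gain")
  check_nonneg(read_noise, "read_noise")
  check_nonneg(offset, "offset")
  if (any(photon_image < 0))
    stop_param("photon expectations must be non-negative")
  n <- length(photon_image)
  adu <- rpois(n, as.vector(photon_image)) * gain + offset
  if (read_noise > 0) adu <- adu + rnorm(n, 0, read_noise)
  matrix(pmax(round(adu), 0), nrow(photon_image), ncol(photon_image))
}

#' Simulate a vertical-cell septal ring movie
#'
#' Composes [simulate_filaments()], [render_frame()] and
#' [add_camera_noise()]: a stationary birth-death filament population
#' treadmills around a fixed ring centred in the field; each frame is
#' rendered as background plus filament PSFs and passed through the camera
#' noise model. Fully reproducible from the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `movie` (a [movie_stack()]) and `truth` (the
#'   ground-truth filament table).
#' @export
simulate_ring_movie <- function(config) {
  with_seed(config$seed, {
    radius_nm <- config$ring_diameter / 2
    r_px <- radius_nm / config$pixel_size
    centre <- rep((config$field_px + 1) / 2, 2)
    fil <- simulate_filaments(config)
    bg <- config$background_params
    bg_px <- c(a = unname(bg[["a"]]),
               sigma_bg1 = unname(bg[["sigma_bg1"]]) / config$pixel_size,
               b = unname(bg[["b"]]),
               sigma_bg2 = unname(bg[["sigma_bg2"]]) / config$pixel_size,
               c = unname(bg[["c"]]))
    psf_px <- config$psf_sigma / config$pixel_size
    frames <- vector("list", config$n_frames)
    for (j in seq_len(config$n_frames)) {
      t <- (j - 1) * config$frame_interval
      live <- fil[fil$birth_s <= t & fil$death_s > t, , drop = FALSE]
      if (nrow(live) > 0) {
        ang <- filament_angle_at(live, t, radius_nm) * pi / 180
        xy <- cbind(centre[1] + r_px * cos(ang),
                    centre[2] - r_px * sin(ang))
      } else xy <- matrix(numeric(0), 0, 2)
      exp_img <- render_frame(config$field_px, centre, xy,
                              config$filament_photons, psf_px, bg_px)
      frames[[j]] <- add_camera_noise(exp_img, config$camera_gain,
                                      config$read_noise, config$offset)
    }
    list(movie = movie_stack(frames, config$pixel_size,
                             config$frame_interval),
         truth = fil)
  })
}

#' Simulate a septal constriction trajectory
#'
#' Diameters follow the constant-synthesis constriction model (constant
#' total peptidoglycan synthesis rate around the septal leading edge of a
#' flat plate) plus i.i.d. Gaussian noise, truncated at zero. A smooth
#' synthase-arrival intensity column (logistic rise around the constriction
#' start, normalised to \[0, 1\], same noise model scaled to 0.05) is emitted
#' alongside for two-colour workflows.
#'
#' @param d0 initial diameter, nm.
#' @param t0 constriction start time, s.
#' @param k septal-plate area addition rate, nm^2/s.
#' @param noise_sd diameter noise, nm.
#' @param dt frame interval, s.
#' @param n number of frames.
#' @param seed optional RNG seed.
#' @return data frame `t_s`, `diameter_nm`, `intensity`, with the
#'   ground-truth parameters in `attr(, "truth")`.
#' @export
simulate_constriction_trace <- function(d0, t0, k, noise_sd = 0, dt = 15,
                                        n = 100, seed = NULL) {
  check_positive(d0, "d0"); check_positive(k, "k"); check_positive(dt, "dt")
  check_nonneg(noise_sd, "noise_sd")
  with_seed(seed, {
    t <- (seq_len(n) - 1) * dt
    d <- eval_constriction_model(t, d0, t0, k)
    if (noise_sd > 0) d <- d + rnorm(n, 0, noise_sd)
    d <- pmax(d, 0)
    intensity <- 1 / (1 + exp(-(t - t0) / max(t0 / 4, dt)))
    if (noise_sd > 0) intensity <- intensity + rnorm(n, 0, 0.05)
    out <- data.frame(t_s = t, diameter_nm = d,
                      intensity = pmin(pmax(intensity, 0), 1))
    attr(out, "truth") <- list(d0 = d0, t0 = t0, k = k)
    out
  })
}

#' Simulate an axial-thickness time series with one condensation step
#'
#' Two Gaussian segments with the stated means and standard deviations; a
#' step index equal to `n` (or 0) yields a single-state series. Emulates the
#' condensation of a diffuse nascent Z-ring into a thin mature ring as a
#' step decrease in axial thickness.
#'
#' @param mean_pre,sd_pre pre-step mean and SD, nm.
#' @param mean_post,sd_post post-step mean and SD, nm.
#' @param step_index number of pre-step samples (0..n).
#' @param n series length.
#' @param seed optional RNG seed.
#' @return numeric vector of thicknesses (nm).
#' @export
simulate_thickness_trace <- function(mean_pre, sd_pre, mean_post, sd_post,
                                     step_index, n, seed = NULL) {
  check_nonneg(sd_pre, "sd_pre"); check_nonneg(sd_post, "sd_post")
  if (step_index < 0 || step_index > n)
    stop_param("`step_index` must lie in [0, n]")
  with_seed(seed, {
    n1 <- step_index; n2 <- n - step_index
    c(rnorm(n1, mean_pre, sd_pre), rnorm(n2, mean_post, sd_post))
  })
}

#' Multi-frame image stack container
#'
#' @param frames list of equal-shape numeric matrices (ADU).
#' @param pixel_size nm/px.
#' @param frame_interval s.
#' @return object of class `movie_stack`.
#' @export
movie_stack <- function(frames, pixel_size, frame_interval) {
  if (length(frames) == 0L) stop_param("movie must contain at least one frame")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_param("all frames must have the same shape")
  check_positive(pixel_size, "pixel_size")
  check_positive(frame_interval, "frame_interval")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("movie_stack: %d frames of %d x %d px, %g nm/px, %g s/frame\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie a [movie_stack()].
#' @export
n_frames <- function(movie) length(movie$frames)
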