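test_that("ring model evaluation matches its closed form", {
  mk <- make_ring_frame(R0 = 8, A = rep(0, 12), a = 0, b = 0, cc = 7)
  expect_true(all(mk$frame == 7))
  mk2 <- make_ring_frame(R0 = 8)
  p <- mk2$params
  ctr_val <- evaluate_ring_model(p, 41, 41)[round(p$y0), round(p$x0)]
  # at the centre the annulus term is tiny and Bg = a + b + c
  expect_equal(ctr_val, p$a + p$b + p$c + p$A[1] * exp(-p$R0^2 / (2 * p$sigma^2)),
               tolerance = 1e-12)
  # on the circle at a mid-sector angle the signal equals that sector's A
  th <- 45 * pi / 180
  x <- p$x0 + p$R0 * cos(th); y <- p$y0 - p$R0 * sin(th)
  r2 <- (x - p$x0)^2 + (y - p$y0)^2
  bgv <- p$a * exp(-r2 / (2 * p$sigma_bg1^2)) +
    p$b * p$sigma_bg2^2 / (r2 + p$sigma_bg2^2) + p$c
  # direct evaluation of the model formula at an off-grid point
  sig <- p$A[2] * exp(0)
  grid <- evaluate_ring_model(p, 41, 41)
  expect_equal(vercini:::bilinear_sample(grid, x, y), sig + bgv,
               tolerance = 0.02 * (sig + bgv))
})

test_that("round-trip fit recovers parameters on noiseless frames", {
  set.seed(31)
  for (R0 in c(5.4, 8.5, 11.2)) {
    A <- runif(12, 60, 140)
    mk <- make_ring_frame(R0 = R0, A = A, dx = 0.3, dy = -0.2)
    f <- fit_ring_model(mk$frame)
    expect_lt(abs(f$R0 - R0), 0.01 * R0)
    expect_lt(abs(f$x0 - mk$params$x0), 0.05)
    expect_lt(abs(f$y0 - mk$params$y0), 0.05)
    expect_lt(max(abs(f$A - A) / A), 0.01)
    expect_lt(abs(f$sigma - 2) / 2, 0.01)
  }
})

test_that("pure-background frames raise a no-ring error", {
  mk <- make_ring_frame(R0 = 8, A = rep(0, 12))
  expect_error(fit_ring_model(mk$frame), class = "vercini_no_ring_error")
  set.seed(32)
  noisy <- mk$frame + rnorm(length(mk$frame), 0, 2)
  expect_error(fit_ring_model(matrix(noisy, nrow(mk$frame))),
               class = "vercini_no_ring_error")
})

test_that("kymograph extraction follows the fitted circle", {
  # single immobile filament at a fixed angle, built frame by frame
  cfg <- sim_config(filament_density = 0, n_frames = 30, seed = 33L)
  r_px <- cfg$ring_diameter / 2 / cfg$pixel_size
  ctr <- (cfg$field_px + 1) / 2
  psf_px <- cfg$psf_sigma / cfg$pixel_size
  bgp <- cfg$background_params
  bg_px <- c(a = bgp[["a"]], sigma_bg1 = bgp[["sigma_bg1"]] / 65,
             b = bgp[["b"]], sigma_bg2 = bgp[["sigma_bg2"]] / 65,
             c = bgp[["c"]])
  # noiseless frames: argmax constancy is then exact by construction
  frames <- lapply(seq_len(30), function(j) {
    ang <- 77 * pi / 180
    xy <- matrix(c(ctr + r_px * cos(ang), ctr - r_px * sin(ang)), 1, 2)
    render_frame(cfg$field_px, c(ctr, ctr), xy, 400, psf_px, bg_px) *
      cfg$camera_gain + cfg$offset
  })
  movie <- movie_stack(frames, cfg$pixel_size, cfg$frame_interval)
  p_known <- ring_model_params(ctr, ctr, r_px, psf_px, rep(60, 12),
                               bg_px[["a"]] * cfg$camera_gain,
                               bg_px[["sigma_bg1"]],
                               bg_px[["b"]] * cfg$camera_gain,
                               bg_px[["sigma_bg2"]],
                               bg_px[["c"]] * cfg$camera_gain + cfg$offset)
  kymo <- extract_kymograph(movie, p_known)
  peaks <- apply(kymo$values, 1, which.max)
  # immobile filament: argmax column constant across frames, at its angle
  expect_lte(max(peaks) - min(peaks), 2)
  expect_lte(abs(median(peaks) - (77 + 1)), 1)
  # doubling duplicates the columns exactly
  dbl <- double_kymograph(kymo)
  expect_identical(ncol(dbl$values), 2L * ncol(kymo$values))
  expect_identical(dbl$values[, 1:360], kymo$values)
  expect_identical(dbl$values[, 361:720], kymo$values)
})

test_that("kymograph sampling is periodic and background-subtracted", {
  mk <- make_ring_frame(R0 = 8.5)
  movie <- movie_stack(list(mk$frame), 65, 1)
  # column 0 and a would-be column at 360 degrees sample the same position
  k1 <- extract_kymograph(movie, mk$params, angular_step = 0.5)
  expect_equal(k1$values[1, 1],
               vercini:::bilinear_sample(
                 mk$frame - vercini:::eval_background(
                   mk$params,
                   matrix(seq_len(ncol(mk$frame)), nrow(mk$frame),
                          ncol(mk$frame), byrow = TRUE),
                   matrix(seq_len(nrow(mk$frame)), nrow(mk$frame),
                          ncol(mk$frame))),
                 mk$params$x0 + mk$params$R0, mk$params$y0),
               tolerance = 1e-12)
  # background-only movie: extracted kymograph mean is ~0
  cfg <- sim_config(filament_density = 0, n_frames = 25, seed = 35L)
  sim <- simulate_ring_movie(cfg)
  bgp <- cfg$background_params
  ctr <- (cfg$field_px + 1) / 2
  p <- ring_model_params(ctr, ctr, 550 / 65, 2, rep(1e-9, 12),
                         bgp[["a"]] * cfg$camera_gain,
                         bgp[["sigma_bg1"]] / 65,
                         bgp[["b"]] * cfg$camera_gain,
                         bgp[["sigma_bg2"]] / 65,
                         bgp[["c"]] * cfg$camera_gain + cfg$offset)
  kymo <- extract_kymograph(sim$movie, p)
  expect_lt(abs(mean(kymo$values)), 0.5 * cfg$read_noise)
})

test_that("median septal intensity uses the first 60 frames only", {
  mkk <- function(vals) kymograph(vals, 0:359, 550, 1)
  expect_equal(median_septal_intensity(mkk(matrix(5, 10, 360))), 5)
  two_block <- rbind(matrix(0, 60, 360), matrix(100, 60, 360))
  expect_equal(median_septal_intensity(mkk(two_block)), 0)
  alt <- matrix(rep(c(0, 10), length.out = 60 * 360), 60, 360)
  expect_equal(median_septal_intensity(mkk(alt)), 5)
  # linear in uniform amplitude scaling
  set.seed(36)
  v <- matrix(rexp(30 * 360), 30, 360)
  expect_equal(median_septal_intensity(mkk(3 * v)),
               3 * median_septal_intensity(mkk(v)))
})

test_that("ring diameter conversion is exact", {
  p <- make_ring_frame(R0 = 8.5)$params
  expect_equal(ring_diameter_nm(p, 65), 1105)
  p2 <- make_ring_frame(R0 = 5)$params
  expect_equal(ring_diameter_nm(p2, 106), 1060)
})
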