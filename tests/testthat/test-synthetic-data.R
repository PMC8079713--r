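test_that("filament counts are Poisson with the configured density", {
  expect_identical(sample_filament_count(0, 100L), rep(0L, 100))
  set.seed(11)
  n <- 1e5L
  x13 <- sample_filament_count(1.3, n)
  expect_lt(abs(mean(x13) - 1.3), 3 * sqrt(1.3 / n))
  x33 <- sample_filament_count(3.3, n)
  expect_gt(var(x33) / mean(x33), 0.95)
  expect_lt(var(x33) / mean(x33), 1.05)
  expect_error(sample_filament_count(-1), class = "vercini_param_error")
})

test_that("birth-death filament population is stationary at the density", {
  cfg <- sim_config(filament_density = 3.3, mean_lifetime = 30)
  set.seed(21)
  dur <- 1e5
  fil <- simulate_filaments(cfg, duration = dur)
  expect_true(all(fil$death_s > fil$birth_s))
  # exact time-average of the population count over the run
  avg <- sum(pmin(fil$death_s, dur) - pmax(fil$birth_s, 0)) / dur
  expect_lt(abs(avg - 3.3) / 3.3, 0.05)
})

test_that("immobile flags and speed samplers behave as configured", {
  cfg <- sim_config(immobile_fraction = 1)
  set.seed(3)
  fil <- simulate_filaments(cfg, duration = 500)
  expect_true(all(fil$immobile))
  expect_true(all(fil$speed_nm_s < 10))

  cfg2 <- sim_config(immobile_fraction = 0,
                     speed_sampler = speed_constant(30))
  set.seed(4)
  fil2 <- simulate_filaments(cfg2, duration = 500)
  expect_true(all(fil2$speed_nm_s == 30))
  expect_true(all(fil2$direction %in% c(-1, 1)))

  expect_error(speed_empirical(numeric(0)), class = "vercini_param_error")
  # lognormal sampler hits its target median and IQR
  s <- speed_lognormal(28, 16)
  set.seed(5)
  draws <- vercini:::draw_speeds(s, 2e5)
  expect_lt(abs(median(draws) - 28) / 28, 0.02)
  expect_lt(abs(IQR(draws) - 16) / 16, 0.05)
})

test_that("rendered frames follow the background model and conserve photons", {
  bg <- c(a = 50, sigma_bg1 = 6, b = 30, sigma_bg2 = 10, c = 10)
  img <- render_frame(41, c(21, 21), matrix(numeric(0), 0, 2), 400, 2, bg)
  expect_equal(img[21, 21], 50 + 30 + 10)
  # far from the centre only the constant remains
  bg_far <- c(a = 50, sigma_bg1 = 6, b = 10, sigma_bg2 = 10, c = 20)
  r10 <- render_frame(201, c(101, 101), matrix(numeric(0), 0, 2), 400, 2,
                      bg_far)
  expect_lt(abs(r10[101, 201] - bg_far[["c"]]) / bg_far[["c"]], 0.01)
  # photon conservation of the PSF
  zero_bg <- c(a = 0, sigma_bg1 = 6, b = 0, sigma_bg2 = 10, c = 0)
  one <- render_frame(41, c(21, 21), matrix(c(21, 21), 1, 2), 400, 2, zero_bg)
  expect_lt(abs(sum(one) - 400) / 400, 0.001)
  two <- render_frame(61, c(31, 31),
                      rbind(c(25, 31), c(37, 28)), 400, 2, zero_bg)
  expect_lt(abs(sum(two) - 800) / 800, 0.001)
})

test_that("camera noise has gain^2 * mean + read_noise^2 variance", {
  set.seed(6)
  flat <- add_camera_noise(matrix(0, 10, 10), 2, 0, 100)
  expect_true(all(flat == 100))
  img <- matrix(100, 320, 320)
  adu <- add_camera_noise(img, 2, 3, 100)
  expect_lt(abs(var(as.vector(adu)) - 409) / 409, 0.05)
  adu2 <- add_camera_noise(img, 1, 0, 50)
  se <- sqrt(100 / length(img))
  expect_lt(abs(mean(adu2) - 150), 3 * se)
  expect_error(add_camera_noise(matrix(-1, 2, 2), 2, 3, 100),
               class = "vercini_param_error")
})

test_that("movies are reproducible bit-exactly from the seed", {
  cfg <- test_sim_config(n_frames = 10)
  a <- simulate_ring_movie(cfg)
  b <- simulate_ring_movie(cfg)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$truth, b$truth)
  cfg2 <- test_sim_config(n_frames = 10, seed = 43L)
  c2 <- simulate_ring_movie(cfg2)
  expect_false(identical(a$movie$frames, c2$movie$frames))
})

test_that("background-only movies produce ridge-free kymographs", {
  cfg <- sim_config(filament_density = 0, n_frames = 20, seed = 9L)
  sim <- simulate_ring_movie(cfg)
  expect_identical(nrow(sim$truth), 0L)
  # no model fit possible without a ring; sample at the known geometry
  ctr <- (cfg$field_px + 1) / 2
  p <- ring_model_params(ctr, ctr, 550 / 65, 2, rep(1e-9, 12),
                         cfg$background_params[["a"]] * cfg$camera_gain,
                         cfg$background_params[["sigma_bg1"]] / 65,
                         cfg$background_params[["b"]] * cfg$camera_gain,
                         cfg$background_params[["sigma_bg2"]] / 65,
                         cfg$background_params[["c"]] * cfg$camera_gain +
                           cfg$offset)
  kymo <- extract_kymograph(sim$movie, p)
  rf <- ridge_filter(kymo)
  noise_floor <- sd(kymo$values)
  expect_lt(max(abs(rf)), 3 * noise_floor)
})

test_that("constriction traces follow the kinetic model", {
  d0 <- 1100; t0 <- 300; k <- 1000
  tr <- simulate_constriction_trace(d0, t0, k, noise_sd = 0, dt = 5,
                                    n = 400)
  pre <- tr$diameter_nm[tr$t_s < t0]
  expect_true(all(pre == d0))
  t_half_area <- t0 + pi * d0^2 / (8 * k)
  d_at <- eval_constriction_model(t_half_area, d0, t0, k)
  expect_equal(d_at, d0 / sqrt(2), tolerance = 1e-12)
  t_zero <- t0 + pi * d0^2 / (4 * k)
  first_zero <- tr$t_s[which(tr$diameter_nm == 0)[1]]
  expect_lte(abs(first_zero - t_zero), 5)
})

test_that("thickness traces have the configured segment structure", {
  x <- simulate_thickness_trace(600, 80, 330, 30, 120, 120, seed = 12)
  expect_length(x, 120)
  expect_lt(abs(mean(x) - 600), 3 * 80 / sqrt(120))
  y <- simulate_thickness_trace(600, 80, 330, 30, 60, 120, seed = 12)
  s <- detect_condensation_step(y)
  expect_identical(s$n_states, 2L)
  # sub-threshold step (20 nm, SDs differ): split is found but rejected
  z <- simulate_thickness_trace(600, 15, 580, 45, 60, 120, seed = 12)
  expect_identical(detect_condensation_step(z)$n_states, 1L)
  expect_error(simulate_thickness_trace(600, 80, 330, 30, 200, 120),
               class = "vercini_param_error")
})
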