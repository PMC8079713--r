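test_that("septal profile extraction reproduces axis-aligned structures", {
  img <- matrix(1, 41, 41)
  img[, 19:23] <- 50   # vertical bar, width 5 px
  pr <- extract_septal_profiles(img, c(21, 21), 0, pixel_size = 65)
  expect_lt(abs(max(pr$lateral$intensities) - 50) / 50, 0.01)
  # rotation by 0 degrees is the identity: direct band means
  expect_equal(pr$lateral$intensities, colMeans(img[19:23, ]))
  expect_equal(pr$axial$intensities, rowMeans(img[, 19:23]))
  expect_length(pr$lateral$intensities, 41)
  # the averaging band is exactly 5 rows
  img2 <- matrix(0, 41, 41)
  img2[c(18, 24), ] <- 100  # just outside the +/- 2 px band
  pr2 <- extract_septal_profiles(img2, c(21, 21), 0)
  expect_true(all(pr2$lateral$intensities == 0))
  img2[19, ] <- 100
  pr3 <- extract_septal_profiles(img2, c(21, 21), 0)
  expect_true(all(pr3$lateral$intensities == 20))
  expect_error(extract_septal_profiles(img, c(2, 2), 0),
               class = "vercini_param_error")
})

test_that("profile extraction after rotation recovers a tilted bar", {
  # bar along a 30-degree axis through the centre
  n <- 61; ctr <- 31
  x <- matrix(seq_len(n), n, n, byrow = TRUE)
  y <- matrix(seq_len(n), n, n)
  alpha <- 30 * pi / 180
  # perpendicular distance from the line through the centre at angle alpha
  # (y axis points down, so the displayed axis direction is (cos, -sin))
  d_perp <- abs(-(x - ctr) * sin(alpha) - (y - ctr) * cos(alpha))
  img <- 10 + 90 * exp(-d_perp^2 / (2 * 2^2))
  pr <- extract_septal_profiles(img, c(ctr, ctr), 30)
  # along the axis the profile is flat at the 5-row band average of the bar
  band_mean <- 10 + 90 * mean(exp(-(-2:2)^2 / (2 * 2^2)))
  mid <- (ctr - 8):(ctr + 8)
  expect_lt(diff(range(pr$lateral$intensities[mid])), 2)
  expect_lt(abs(mean(pr$lateral$intensities[mid]) - band_mean), 2)
  # across the axis it falls off like the Gaussian bar
  expect_lt(abs(max(pr$axial$intensities) - 100) / 100, 0.02)
})

test_that("tilted-circle projection conserves intensity and fits recover d", {
  x <- seq(-1500, 1500, by = 25)
  for (d in c(700, 1100)) {
    m <- tilted_circle_model(x, d, 120, total = 1000)
    expect_lt(abs(sum(m) * 25 - 1000) / 1000, 0.001)
  }
  y <- 200 + tilted_circle_model(x, 1100, 120, total = 5e4)
  fit <- fit_tilted_circle(line_profile(x, y, "lateral"))
  expect_lt(abs(fit$d - 1100) / 1100, 0.01)
  expect_true(fit$converged)
  # narrow PSF: the two profile maxima approach +/- d/2
  y2 <- tilted_circle_model(x, 1100, 8, total = 1)
  ord <- order(-y2)
  pk <- sort(x[ord[1:2]])
  expect_lte(abs(diff(pk) - 1100), 25)
})

test_that("super-Gaussian fits match the closed-form FWHM", {
  expect_equal(super_gaussian_fwhm(100, 1), 2 * sqrt(2 * log(2)) * 100,
               tolerance = 1e-12)
  expect_equal(super_gaussian_fwhm(100, 1), 235.4820, tolerance = 1e-4)
  xs <- seq(-1000, 1000, by = 25)
  ys <- 10 + 500 * exp(-(((xs - 30)^2) / (2 * 150^2))^2)
  fit <- fit_super_gaussian(line_profile(xs, ys, "axial"))
  expect_lt(abs(fit$fwhm - super_gaussian_fwhm(150, 2)) /
              super_gaussian_fwhm(150, 2), 0.005)
  # constrained P = 1 reduces to a plain Gaussian fit
  yg <- 5 + 200 * exp(-((xs + 40)^2) / (2 * 180^2))
  fg <- fit_super_gaussian(line_profile(xs, yg, "axial"), fix_P = 1)
  expect_equal(fg$P, 1)
  expect_lt(abs(fg$fwhm - 2.3548 * 180) / (2.3548 * 180), 0.001)
  # FWHM monotone in sigma at fixed P
  expect_true(all(diff(super_gaussian_fwhm(c(50, 100, 200, 400), 2)) > 0))
})

test_that("septal density is intensity over circumference", {
  expect_equal(septal_density(0, 1100), 0)
  expect_equal(septal_density(pi * 1100, 1100), 1)
  expect_equal(septal_density(3455.8, 1100), 1, tolerance = 1e-4)
})

test_that("full frame quantification recovers diameter and thickness", {
  # separable side-on ring: tilted-circle projection laterally (x), a
  # super-Gaussian axially (y), on a constant baseline
  nx <- 61; ny <- 61; px <- 65
  xs <- (seq_len(nx) - 31) * px
  ys <- (seq_len(ny) - 31) * px
  lat <- tilted_circle_model(xs, 1100, 120, total = 1)
  axi <- exp(-((ys^2) / (2 * 200^2))^1.5)
  img <- 20 + 4e5 * outer(axi, lat / max(lat))
  q <- quantify_ring_frame(img, c(31, 31), 0, pixel_size = px)
  expect_lt(abs(q$diameter_nm - 1100) / 1100, 0.03)
  want_fwhm <- super_gaussian_fwhm(200, 1.5)
  expect_lt(abs(q$thickness_fwhm_nm - want_fwhm) / want_fwhm, 0.03)
  expect_equal(q$septal_density, q$total_intensity / (pi * q$diameter_nm))
})

test_that("profile extraction is linear in image intensity", {
  set.seed(51)
  img <- matrix(rexp(41 * 41, 1 / 50), 41, 41)
  a <- extract_septal_profiles(img, c(21, 21), 20)
  b <- extract_septal_profiles(3 * img, c(21, 21), 20)
  expect_equal(b$lateral$intensities, 3 * a$lateral$intensities,
               tolerance = 1e-12)
  expect_equal(b$axial$intensities, 3 * a$axial$intensities,
               tolerance = 1e-12)
})
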