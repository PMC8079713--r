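test_that("division-state thresholds partition the plane", {
  expect_identical(classify_state(500, 1.0), "nascent")
  expect_identical(classify_state(300, 0.95), "mature")
  expect_identical(classify_state(300, 0.5), "constricting")
  # boundary conventions: 400 nm is non-nascent, 0.9 is mature
  expect_identical(classify_state(400, 1.0), "mature")
  expect_identical(classify_state(400, 0.9), "mature")
  expect_identical(classify_state(399, 0.89), "constricting")
  set.seed(61)
  th <- runif(200, 100, 800); rd <- runif(200, 0.1, 1.2)
  labs <- classify_state(th, rd)
  expect_true(all(labs %in% c("nascent", "mature", "constricting")))
  expect_length(labs, 200)
})

test_that("condensation step detection matches the exhaustive oracle", {
  expect_identical(detect_condensation_step(rep(500, 20))$n_states, 1L)
  set.seed(62)
  for (i in 1:60) {
    n <- sample(10:200, 1)
    if (i %% 2 == 0) {
      cp <- sample(3:(n - 3), 1)
      x <- c(rnorm(cp, 600, 80), rnorm(n - cp, 330, 30))
    } else {
      x <- rnorm(n, 500, runif(1, 10, 100))
    }
    got <- detect_condensation_step(x)
    want <- bf_changepoint(x)
    expect_identical(got$n_states, want$n_states)
    expect_identical(got$change_index, want$change_index)
  }
})

test_that("steps below 50 nm are rejected; invariance to offsets", {
  set.seed(63)
  x <- c(rnorm(60, 600, 10), rnorm(60, 570, 40))  # 30 nm step, SD change
  s <- detect_condensation_step(x)
  expect_identical(s$n_states, 1L)
  y <- c(rnorm(60, 600, 80), rnorm(60, 330, 30))
  sy <- detect_condensation_step(y)
  expect_identical(sy$n_states, 2L)
  expect_lte(abs(sy$change_index - 60), 2)
  # adding a constant shifts means but not the segmentation
  sy2 <- detect_condensation_step(y + 1000)
  expect_identical(sy2$change_index, sy$change_index)
  expect_error(detect_condensation_step(rnorm(5)),
               class = "vercini_param_error")
})

test_that("the low-thickness rule scores pre-constriction drops", {
  x <- rep(450, 30)
  expect_false(d213a_low_thickness(x, 20))
  x[10] <- 350
  expect_true(d213a_low_thickness(x, 20))
  expect_false(d213a_low_thickness(x, 5))   # drop is after the start
  # default threshold is 356 nm: 356 itself does not count
  y <- rep(356, 30)
  expect_false(d213a_low_thickness(y, 15))
  y[3] <- 355.9
  expect_true(d213a_low_thickness(y, 15))
  expect_error(d213a_low_thickness(x, 40), class = "vercini_param_error")
})

test_that("alignment shifts constriction start to zero, preserving spacing", {
  tr1 <- data.frame(t_s = seq(0, 50, 10), diameter_nm = 1100 - seq(0, 50, 10))
  tr2 <- data.frame(t_s = seq(5, 45, 5), diameter_nm = 900 - seq(5, 45, 5))
  al <- suppressWarnings(align_to_constriction(list(tr1, tr2), c(10, NA)))
  expect_length(al, 1)
  expect_equal(al[[1]]$t_s, seq(-10, 40, 10))
  expect_equal(diff(al[[1]]$t_s), diff(tr1$t_s))
  expect_warning(align_to_constriction(list(tr1), NA), "skipped")
})

test_that("state labels along a noise-free trajectory never revert", {
  t <- 0:100
  thick <- c(rep(550, 30), rep(330, 71))
  diam <- c(rep(1100, 60), 1100 * sqrt(pmax(1 - (t[61:101] - 60) / 41, 0.05)))
  rel <- relative_diameter(diam, t0_index = 61)
  labs <- classify_state(thick, rel)
  ord <- c(nascent = 1, mature = 2, constricting = 3)
  expect_true(all(diff(ord[labs]) >= 0))
})

test_that("synthase-level classification thresholds at 0.5", {
  expect_identical(classify_pbp2b_level(0.3), "low")
  expect_identical(classify_pbp2b_level(0.7), "high")
  expect_identical(classify_pbp2b_level(0.5), "high")
  expect_identical(classify_pbp2b_level(c(0, 1)), c("low", "high"))
})
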