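test_that("constriction model analytics hold to 1e-9 relative", {
  d0 <- 1100; t0 <- 300; k <- 1000
  expect_identical(eval_constriction_model(t0 - 1e-9, d0, t0, k), d0)
  expect_identical(eval_constriction_model(0, d0, t0, k), d0)
  t_half <- t0 + pi * d0^2 / (8 * k)
  expect_equal(eval_constriction_model(t_half, d0, t0, k), d0 / sqrt(2),
               tolerance = 1e-9)
  t_done <- t0 + pi * d0^2 / (4 * k)
  expect_equal(eval_constriction_model(t_done, d0, t0, k), 0,
               tolerance = 1e-9)
  expect_identical(eval_constriction_model(t_done + 100, d0, t0, k), 0)
  # septal plate area grows linearly with slope k after t0
  t <- seq(t0, t_done - 1, length.out = 200)
  area <- septal_plate_area(eval_constriction_model(t, d0, t0, k), d0)
  slopes <- diff(area) / diff(t)
  expect_lt(max(abs(slopes - k)) / k, 1e-9)
})

test_that("noiseless trajectories are recovered exactly", {
  tr <- simulate_constriction_trace(1100, 300, 1000, 0, 15, 100)
  fit <- fit_constriction(tr)
  expect_lt(abs(fit$d0 - 1100) / 1100, 1e-6)
  expect_lt(abs(fit$t0 - 300) / 300, 1e-6)
  expect_lt(abs(fit$k - 1000) / 1000, 1e-6)
  expect_true(fit$converged)
  # flat trajectory: start time unidentifiable, flagged
  flat <- data.frame(t_s = seq(0, 900, 15), diameter_nm = rep(1100, 61))
  ff <- fit_constriction(flat)
  expect_false(ff$converged)
  expect_error(fit_constriction(data.frame(t_s = 1:3, diameter_nm = 1:3)),
               class = "vercini_param_error")
})

test_that("noisy recovery: d0 within 2% and k within 5% in the median", {
  errs <- t(vapply(1:40, function(i) {
    tr <- simulate_constriction_trace(1100, 300, 1000, 30, 15, 100,
                                      seed = 7000 + i)
    f <- fit_constriction(tr)
    c(abs(f$d0 - 1100) / 1100, abs(f$k - 1000) / 1000)
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.02)
  expect_lt(median(errs[, 2]), 0.05)
})

test_that("post-treatment mode ignores pre-treatment samples entirely", {
  tr <- simulate_constriction_trace(1100, 300, 1000, 10, 15, 100,
                                    seed = 71)
  corrupted <- tr
  corrupted$diameter_nm[corrupted$t_s < 450] <-
    runif(sum(corrupted$t_s < 450), 0, 5000)
  f1 <- fit_constriction(tr, mode = "post_treatment", t_treat = 450)
  f2 <- fit_constriction(corrupted, mode = "post_treatment", t_treat = 450)
  expect_equal(f1$d0, f2$d0)
  expect_equal(f1$t0, f2$t0)
  expect_equal(f1$k, f2$k)
  expect_error(fit_constriction(tr, mode = "post_treatment"),
               class = "vercini_param_error")
  # exclusion index drops trailing samples
  tr2 <- tr
  tr2$diameter_nm[90:100] <- 3000
  f3 <- fit_constriction(tr2, exclude_after = 89)
  f4 <- fit_constriction(tr[1:89, ])
  expect_equal(f3$k, f4$k)
})

test_that("effective constriction time follows its conventions", {
  expect_equal(effective_constriction_time(1, 2 * pi), 1)
  # the conventional t_eff is 8x the geometric completion time
  for (d0 in c(900, 1100)) for (k in c(500, 2000)) {
    expect_equal(effective_constriction_time(d0, k) /
                   constriction_completion_time(d0, k), 8)
  }
  # invariant under d0 -> a*d0, k -> a^2*k
  expect_equal(effective_constriction_time(1100, 1000),
               effective_constriction_time(2.5 * 1100, 2.5^2 * 1000))
})

test_that("fit error shrinks with trajectory length", {
  med_err <- vapply(c(25, 100, 400), function(n) {
    errs <- vapply(1:15, function(i) {
      dt <- 1500 / n
      tr <- simulate_constriction_trace(1100, 300, 1000, 30, dt, n,
                                        seed = 9000 + 17 * n + i)
      abs(fit_constriction(tr)$k - 1000) / 1000
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_lt(med_err[3], med_err[1])
})
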