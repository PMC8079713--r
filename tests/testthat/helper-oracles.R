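# Independent oracles used across tests.

# Exhaustive change-point search with the variance-change cost, written as
# a plain loop over all admissible splits (independent of the package's
# cumulative-sum implementation).
bf_changepoint <- function(x, min_step = 50, min_seg = 2L) {
  n <- length(x)
  best_cost <- Inf; best_j <- NA_integer_
  for (j in min_seg:(n - min_seg)) {
    x1 <- x[1:j]; x2 <- x[(j + 1):n]
    v1 <- mean(x1^2) - mean(x1)^2
    v2 <- mean(x2^2) - mean(x2)^2
    cost <- j * 0.5 * log(max(v1, 1e-16)) +
      (n - j) * 0.5 * log(max(v2, 1e-16))
    if (cost < best_cost) { best_cost <- cost; best_j <- j }
  }
  if (abs(mean(x[1:best_j]) - mean(x[(best_j + 1):n])) >= min_step)
    list(n_states = 2L, change_index = best_j)
  else
    list(n_states = 1L, change_index = NA_integer_)
}

# Noiseless synthetic septal frame from known ring-model parameters.
make_ring_frame <- function(R0 = 8.5, field = NULL, A = rep(100, 12),
                            sigma = 2, a = 50, sbg1 = 6, b = 30, sbg2 = 10,
                            cc = 10, dx = 0, dy = 0) {
  if (is.null(field)) field <- 2L * ceiling(2.2 * R0) + 5L
  ctr <- (field + 1) / 2
  p <- ring_model_params(ctr + dx, ctr + dy, R0, sigma, A, a, sbg1, b,
                         sbg2, cc)
  list(frame = evaluate_ring_model(p, field, field), params = p)
}

# Small, fast simulation config for pipeline tests.
test_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_frames = 60, filament_density = 1.3, seed = 42L), list(...))
  do.call(sim_config, args)
}
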