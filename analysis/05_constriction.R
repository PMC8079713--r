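#!/usr/bin/env Rscript
# Fit the constant-synthesis constriction model to every simulated
# trajectory, report parameter recovery, effective constriction times, and
# a two-condition comparison (control vs slowed synthesis) analysed with
# bootstrap estimation statistics.
# Requires: analysis/01_simulate.R. Outputs under results/constriction/.

suppressPackageStartupMessages(library(vercini))

out <- "results/constriction"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cons <- read.csv("results/data/constriction_traces.csv")
fits <- do.call(rbind, lapply(split(cons, cons$cell_id), function(d) {
  f <- fit_constriction(d[, c("t_s", "diameter_nm")])
  data.frame(cell_id = d$cell_id[1], d0_nm = f$d0, t0_s = f$t0,
             k_nm2_s = f$k, t_eff_min = f$t_eff / 60,
             completion_min = constriction_completion_time(f$d0, f$k) / 60,
             rss = f$rss, converged = f$converged,
             d0_true = d$d0_true[1], k_true = d$k_true[1])
}))
write.csv(fits, file.path(out, "constriction_fits.csv"), row.names = FALSE)
cat(sprintf("fitted %d trajectories: median |d0 err| %.2f%%, median |k err| %.2f%%\n",
            nrow(fits),
            100 * median(abs(fits$d0_nm - fits$d0_true) / fits$d0_true),
            100 * median(abs(fits$k_nm2_s - fits$k_true) / fits$k_true)))
cat(sprintf("median completion time %.1f min (d0 ~1100 nm, k ~1000 nm^2/s)\n",
            median(fits$completion_min)))

# two-condition comparison: the same cells with synthesis slowed 1.5-fold,
# fitted in post-treatment mode from the treatment time
set.seed(61)
arrest <- do.call(rbind, lapply(seq_len(40), function(i) {
  d0 <- rnorm(1, 1100, 100)
  tr <- simulate_constriction_trace(d0, runif(1, 200, 400),
                                    rlnorm(1, log(1000 / 1.5), 0.2),
                                    30, 15, 100, seed = 700L + i)
  f <- fit_constriction(tr, mode = "post_treatment", t_treat = 150)
  data.frame(cell_id = i, completion_min =
               constriction_completion_time(f$d0, f$k) / 60)
}))
r <- median_ratio(fits$completion_min, arrest$completion_min,
                  n_boot = 10000, seed = 12)
cat(sprintf("slowed/control completion-time fold change: %.2f, 95%% CI [%.2f, %.2f]\n",
            r$point, r$ci_low, r$ci_high))
write.csv(data.frame(comparison = "slowed_vs_control",
                     fold_change = r$point, ci_low = r$ci_low,
                     ci_high = r$ci_high),
          file.path(out, "fold_change.csv"), row.names = FALSE)
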