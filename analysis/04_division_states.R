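#!/usr/bin/env Rscript
# Condensation step detection on the thickness series, division-state
# classification, and the low-thickness rule for partially condensed
# (GTPase-mutant-like) rings.
# Requires: analysis/01_simulate.R. Outputs under results/states/.

suppressPackageStartupMessages(library(vercini))

th <- read.csv("results/data/thickness_series.csv")
out <- "results/states"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

res <- do.call(rbind, lapply(split(th, th$cell_id), function(d) {
  s <- detect_condensation_step(d$thickness_nm)
  data.frame(cell_id = d$cell_id[1], group = d$group[1],
             n_states = s$n_states,
             change_index = if (s$n_states == 2) s$change_index else NA,
             step_true = d$step_true[1],
             low_pre_constriction = d213a_low_thickness(
               d$thickness_nm, t = nrow(d)))
}))
write.csv(res, file.path(out, "segmentation.csv"), row.names = FALSE)

wt <- res[res$group == "wildtype", ]
mut <- res[res$group == "mutant", ]
cat(sprintf("wild-type-like: %d/%d detected as two-state; change point within 2 frames of truth in %d/%d\n",
            sum(wt$n_states == 2), nrow(wt),
            sum(abs(wt$change_index - wt$step_true) <= 2, na.rm = TRUE),
            sum(wt$n_states == 2)))
cat(sprintf("mutant-like:    %d/%d detected as single-state; %d/%d flagged low thickness (<356 nm) pre-constriction\n",
            sum(mut$n_states == 1), nrow(mut),
            sum(mut$low_pre_constriction), nrow(mut)))

# state labels along an idealised full-division trajectory
traj <- data.frame(t_s = 60 * (0:99))
traj$thickness_nm <- c(rep(550, 25), rep(330, 75))
traj$diameter_nm <- c(rep(1100, 60),
                      eval_constriction_model(traj$t_s[61:100],
                                              1100, traj$t_s[61], 1000))
traj$diameter_nm <- pmax(traj$diameter_nm, 1)
traj$rel_diameter <- relative_diameter(traj$diameter_nm, t0_index = 61)
traj$state <- classify_state(traj$thickness_nm, traj$rel_diameter)
write.csv(traj, file.path(out, "example_trajectory.csv"), row.names = FALSE)
cat("example trajectory states:",
    paste(rle(traj$state)$values, collapse = " -> "), "\n")
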