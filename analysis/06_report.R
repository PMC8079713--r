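#!/usr/bin/env Rscript
# Collate the stage outputs into a single results/summary.csv.
# Requires: analysis/01..05.

rows <- list()
add <- function(metric, value) rows[[length(rows) + 1L]] <<-
  data.frame(metric = metric, value = value)

g <- read.csv("results/rings/geometry_summary.csv")
for (i in seq_len(nrow(g)))
  add(paste0("diameter_error_pct_", g$preset[i]), g$diameter_error_pct[i])

m <- read.csv("results/speeds/trace_metrics.csv")
for (p in unique(m$preset)) {
  sel <- m[m$preset == p, ]
  add(paste0("median_speed_nm_s_", p), median(sel$speed_nm_s))
  add(paste0("immobile_pct_", p), 100 * mean(sel$immobile))
}

s <- read.csv("results/states/segmentation.csv")
add("wildtype_two_state_pct",
    100 * mean(s$n_states[s$group == "wildtype"] == 2))
add("mutant_single_state_pct",
    100 * mean(s$n_states[s$group == "mutant"] == 1))

f <- read.csv("results/constriction/constriction_fits.csv")
add("constriction_median_completion_min", median(f$completion_min))
fc <- read.csv("results/constriction/fold_change.csv")
add("completion_time_fold_change", fc$fold_change)

summary <- do.call(rbind, rows)
write.csv(summary, "results/summary.csv", row.names = FALSE)
print(summary, row.names = FALSE)
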