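#!/usr/bin/env Rscript
# Generate the synthetic study data: vertical-cell septal movies at the four
# filament-density presets (nascent, mature, 2x mature, 12x mature), plus
# constriction trajectories and axial-thickness series used downstream.
# Outputs land under results/data/.

suppressPackageStartupMessages(library(vercini))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

densities <- c(nascent = 1.3, mature = 3.3, mature_2x = 6.5,
               mature_12x = 37.5)
# mature and constricting rings have fewer immobile filaments
immobile <- c(nascent = 0.35, mature = 0.15, mature_2x = 0.15,
              mature_12x = 0.13)

for (nm in names(densities)) {
  cfg <- sim_config(filament_density = densities[[nm]],
                    immobile_fraction = immobile[[nm]],
                    n_frames = 300, seed = 100L + match(nm, names(densities)))
  sim <- simulate_ring_movie(cfg)
  write_movie(sim$movie, file.path(out, paste0("movie_", nm, ".tif")))
  write_truth_csv(sim$truth, file.path(out, paste0("truth_", nm, ".csv")))
  cat(sprintf("%-10s density %5.1f: %3d ground-truth filaments\n",
              nm, densities[[nm]], nrow(sim$truth)))
}

# constriction trajectories: 40 cells, physiological d0 ~ 1100 +/- 100 nm,
# area-addition rates around 1000 nm^2/s, 30 nm measurement noise
set.seed(201)
cons <- lapply(seq_len(40), function(i) {
  d0 <- rnorm(1, 1100, 100)
  k <- rlnorm(1, log(1000), 0.2)
  tr <- simulate_constriction_trace(d0, runif(1, 200, 400), k, 30, 15, 100,
                                    seed = 300L + i)
  tr$cell_id <- i
  attr_truth <- attr(tr, "truth")
  tr$d0_true <- attr_truth$d0; tr$k_true <- attr_truth$k
  tr$t0_true <- attr_truth$t0
  tr
})
write.csv(do.call(rbind, cons), file.path(out, "constriction_traces.csv"),
          row.names = FALSE)
cat("wrote 40 constriction trajectories\n")

# axial-thickness series: condensing wild-type-like rings (600 -> 330 nm
# step) and partially condensed mutant-like rings (single ~430 nm state)
set.seed(202)
wt <- lapply(seq_len(30), function(i) {
  cp <- sample(30:90, 1)
  data.frame(cell_id = i, frame = 1:120, group = "wildtype",
             step_true = cp,
             thickness_nm = simulate_thickness_trace(600, 80, 330, 30, cp,
                                                     120, seed = 400L + i))
})
mut <- lapply(seq_len(30), function(i) {
  data.frame(cell_id = 100 + i, frame = 1:120, group = "mutant",
             step_true = NA,
             thickness_nm = simulate_thickness_trace(430, 45, 0, 0, 120,
                                                     120, seed = 500L + i))
})
write.csv(rbind(do.call(rbind, wt), do.call(rbind, mut)),
          file.path(out, "thickness_series.csv"), row.names = FALSE)
cat("wrote 60 thickness series (30 condensing, 30 partially condensed)\n")
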