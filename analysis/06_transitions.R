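#!/usr/bin/env Rscript
# Running-window diffusion features along single two-state trajectories and
# HMM segmentation of confined vs normal episodes.

suppressMessages(library(condensateSPT))

nd <- data.frame(x_um = c(1.5, 2.5), y_um = c(2.0, 2.0),
                 radius_um = 0.15, escape_prob = 0.02)
sc <- scene(center = c(2, 2), radius = 1.6, nanodomains = nd)
p <- sim_params(frame_interval = 0.02, n_tracks = 30, D_free = 0.1,
                D_confined = 0.02, p_switching = 1, switching = TRUE,
                mean_track_len = 150, min_track_len = 100, seed = 601)
tr <- simulate_trajectories(sc, p)
parts <- split_trajectories(tr)
states <- split(tr$true_state, tr$trajectory_id)

n_ok <- 0; rows <- list()
for (id in names(parts)) {
  xy <- parts[[id]]
  if (nrow(xy) < 41) next
  rw <- running_window_profile(xy, 0.02)
  seg <- hmm_segment(rw, seed = 602)
  true_sw <- which(diff(states[[id]] == "confined") != 0)
  rows[[id]] <- data.frame(trajectory_id = id, n_windows = nrow(rw),
                           n_true_switches = length(true_sw),
                           n_detected = length(seg$transition_frames))
  n_ok <- n_ok + 1
}
summ <- do.call(rbind, rows)
utils::write.csv(summ, "results/transition_summary.csv", row.names = FALSE)
cat(sprintf("segmented %d trajectories; mean true switches %.1f, mean detected %.1f\n",
            n_ok, mean(summ$n_true_switches), mean(summ$n_detected)))
cat("(window-level smoothing merges rapid flickers; see methods vignette)\n")
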