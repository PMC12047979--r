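#' Random-walk control for the trajectory classifier
#'
#' Simulates pure Brownian trajectories with no confinement — the negative
#' control for the three-way classifier — and classifies them with the
#' standard thresholds. The control runs at the intra-condensate step
#' scale: mean frame step about 40 nm (`D = 0.025` µm²/s at a 20-ms frame
#' interval), i.e. roughly 2.5 times the 16-nm localization error, with
#' geometric trajectory lengths (mean 20 frames, minimum 5 localizations).
#' Any confined-labeled fraction here is classifier false positives driven
#' by localization noise and finite trajectory length.
#'
#' @param n_tracks Number of trajectories (>= 1000 recommended).
#' @param seed Integer seed.
#' @param D Diffusion coefficient (µm²/s).
#' @param frame_interval Frame interval (s).
#' @param loc_error_sd Localization error (µm).
#' @param mean_track_len,min_track_len Geometric length distribution.
#' @return List: `fractions` (over the three retained categories),
#'   `fractions_with_excluded`, `classification` table.
#' @export
random_walk_control <- function(n_tracks = 2000, seed = 1L, D = 0.025,
                                frame_interval = 0.02,
                                loc_error_sd = 0.016,
                                mean_track_len = 20, min_track_len = 5) {
  p <- sim_params(frame_interval = frame_interval, n_tracks = n_tracks,
                  D_free = D, loc_error_sd = loc_error_sd,
                  mean_track_len = mean_track_len,
                  min_track_len = min_track_len, seed = seed)
  # large arena so the condensate boundary never interferes
  sc <- scene(center = c(0, 0), radius = 1000)
  tr <- simulate_trajectories(sc, p)
  cls <- classify_trajectories(tr, frame_interval)
  list(fractions = category_fractions(cls),
       fractions_with_excluded = category_fractions(cls,
                                                    drop_excluded = FALSE),
       classification = cls)
}
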