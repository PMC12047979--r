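#' Define a condensate scene for simulation
#'
#' A scene is a disk-shaped condensate, optionally containing nanodomains:
#' small disks in which diffusion is confined. Nanodomains must lie fully
#' inside the condensate.
#'
#' @param center Numeric length-2, condensate center (µm).
#' @param radius Condensate radius (µm), > 0.
#' @param nanodomains `data.frame` with columns `x_um`, `y_um`, `radius_um`
#'   and `escape_prob` (per-frame probability that a trapped molecule
#'   escapes, in \[0, 1\]). May be empty or `NULL`.
#' @return An object of class `"spt_scene"`.
#' @export
scene <- function(center = c(0, 0), radius = 2, nanodomains = NULL) {
  stopifnot(length(center) == 2, is.finite(center), radius > 0)
  if (is.null(nanodomains)) {
    nanodomains <- data.frame(x_um = numeric(0), y_um = numeric(0),
                              radius_um = numeric(0), escape_prob = numeric(0))
  }
  stopifnot(all(c("x_um", "y_um", "radius_um", "escape_prob") %in%
                  names(nanodomains)))
  if (nrow(nanodomains)) {
    if (any(nanodomains$radius_um <= 0))
      stop("nanodomain radii must be > 0")
    if (any(nanodomains$escape_prob < 0 | nanodomains$escape_prob > 1))
      stop("escape_prob must be in [0, 1]")
    d <- sqrt((nanodomains$x_um - center[1])^2 +
                (nanodomains$y_um - center[2])^2)
    if (any(d + nanodomains$radius_um > radius + 1e-12))
      stop("nanodomains must lie fully inside the condensate disk")
  }
  structure(list(center = as.numeric(center), radius = radius,
                 nanodomains = nanodomains), class = "spt_scene")
}

#' Simulation parameters for trajectory generation
#'
#' Defaults reflect the imaging conditions the analysis assumes: 117-nm
#' pixels, a 20-ms frame interval, and a 16-nm static localization error.
#' Trajectory lengths are geometric (photobleaching-like) with a configurable
#' mean, truncated so every trajectory has at least `min_track_len`
#' localizations.
#'
#' @param frame_interval Frame interval (s), > 0.
#' @param n_tracks Number of trajectories to simulate.
#' @param D_free Free (normal) diffusion coefficient (µm²/s), >= 0.
#' @param D_confined Diffusion coefficient inside nanodomains (µm²/s), >= 0.
#' @param loc_error_sd Localization error s.d. per axis (µm); default
#'   0.016 µm (the 16-nm static localization error).
#' @param p_immobile,p_confined,p_switching Fractions of immobile, confined
#'   and two-state switching molecules; the remainder diffuses normally.
#' @param switching Logical; enable the switching class.
#' @param subframe_steps Sub-steps per frame used to emulate continuous
#'   (full-frame) exposure; 1 disables motion blur.
#' @param mean_track_len Mean of the geometric length distribution (frames).
#' @param min_track_len Minimum localizations per trajectory.
#' @param confinement Either `"reflect"` (hard wall at the nanodomain
#'   boundary) or `"spring"` (Ornstein--Uhlenbeck pull toward the domain
#'   center with relaxation length equal to the domain radius).
#' @param seed Integer seed; every simulation is reproducible given it.
#' @return An object of class `"spt_params"`.
#' @export
sim_params <- function(frame_interval = 0.02, n_tracks = 100,
                       D_free = 0.025, D_confined = 0.005,
                       loc_error_sd = 0.016,
                       p_immobile = 0, p_confined = 0, p_switching = 0,
                       switching = FALSE, subframe_steps = 1,
                       mean_track_len = 20, min_track_len = 5,
                       confinement = c("reflect", "spring"),
                       seed = 1L) {
  confinement <- match.arg(confinement)
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  stopifnot(D_free >= 0, D_confined >= 0, loc_error_sd >= 0,
            subframe_steps >= 1, mean_track_len >= 1,
            min_track_len >= 2, n_tracks >= 1)
  p <- c(p_immobile, p_confined, p_switching)
  if (any(p < 0) || sum(p) > 1)
    stop("class fractions must be in [0, 1] and sum to <= 1")
  if (!switching && p_switching > 0)
    stop("p_switching > 0 requires switching = TRUE")
  structure(list(frame_interval = frame_interval, n_tracks = n_tracks,
                 D_free = D_free, D_confined = D_confined,
                 loc_error_sd = loc_error_sd, p_immobile = p_immobile,
                 p_confined = p_confined, p_switching = p_switching,
                 switching = switching,
                 subframe_steps = as.integer(subframe_steps),
                 mean_track_len = mean_track_len,
                 min_track_len = as.integer(min_track_len),
                 confinement = confinement, seed = as.integer(seed)),
            class = "spt_params")
}

# geometric track lengths (localizations), truncated at >= min_len
sample_track_lengths <- function(n, mean_len, min_len) {
  out <- integer(0)
  while (length(out) < n) {
    l <- stats::rgeom(2L * n, prob = 1 / mean_len) + 1L
    out <- c(out, l[l >= min_len])
  }
  out[seq_len(n)]
}

# reflect points that left a disk back across its boundary
reflect_into_disk <- function(xy, center, radius) {
  for (it in 1:50) {
    dx <- xy[, 1] - center[1]; dy <- xy[, 2] - center[2]
    d <- sqrt(dx^2 + dy^2)
    out <- d > radius
    if (!any(out)) break
    f <- (2 * radius - d[out]) / d[out]
    f[f < 0] <- 0   # pathological overshoot: clamp to boundary-opposite
    xy[out, 1] <- center[1] + dx[out] * f
    xy[out, 2] <- center[2] + dy[out] * f
  }
  xy
}

#' Simulate labeled single-molecule trajectories inside a condensate
#'
#' Generates Brownian (normal), immobile, nanodomain-confined and optionally
#' two-state switching trajectories. Brownian steps have per-axis variance
#' `2 * D * dt`; confined molecules reflect at their nanodomain boundary
#' (or feel a spring, see [sim_params()]); all molecules reflect at the
#' condensate boundary; localization noise is added independently per frame.
#' With `subframe_steps > 1` the recorded position is the average of the
#' sub-frame positions, emulating full-frame (continuous) camera exposure.
#'
#' @param scene A [scene()].
#' @param params A [sim_params()].
#' @return A `data.frame` with columns `trajectory_id`, `frame`, `x_um`,
#'   `y_um`, `true_state` (per-frame state), carrying attributes `labels`
#'   (per-trajectory true class), `params`, `scene`, and — when motion blur
#'   is on — `subpositions` (the sub-frame positions used for rendering).
#' @export
simulate_trajectories <- function(scene, params) {
  stopifnot(inherits(scene, "spt_scene"), inherits(params, "spt_params"))
  set.seed(params$seed)
  nd <- scene$nanodomains
  classes <- c("immobile", "confined", "normal", "switching")
  probs <- c(params$p_immobile, params$p_confined, params$p_switching)
  probs <- c(probs[1], probs[2], 1 - sum(probs), probs[3])
  cls <- sample(classes, params$n_tracks, replace = TRUE, prob = probs)
  if (nrow(nd) == 0 && any(cls %in% c("confined", "switching")))
    stop("scene has no nanodomains but confined/switching molecules requested")
  lens <- sample_track_lengths(params$n_tracks, params$mean_track_len,
                               params$min_track_len)
  dt <- params$frame_interval
  sub <- params$subframe_steps
  sdt <- dt / sub
  keep_sub <- sub > 1
  out <- vector("list", params$n_tracks)
  subpos <- if (keep_sub) vector("list", params$n_tracks) else NULL

  draw_start <- function() {
    repeat {
      p <- scene$center + stats::runif(2, -scene$radius, scene$radius)
      if (sum((p - scene$center)^2) <= scene$radius^2) return(p)
    }
  }

  for (i in seq_len(params$n_tracks)) {
    L <- lens[i]
    ci <- cls[i]
    if (ci == "immobile") {
      anchor <- draw_start()
      xy <- matrix(anchor, L, 2, byrow = TRUE)
      st <- rep("immobile", L)
      sp <- if (keep_sub) xy[rep(seq_len(L), each = sub), , drop = FALSE]
    } else if (ci == "normal") {
      # vectorized free walk; falls back to stepwise reflection only if the
      # walk actually leaves the condensate disk
      n_sub <- L * sub
      p0 <- draw_start()
      stp <- matrix(stats::rnorm(2L * (n_sub - 1L), 0,
                                 sqrt(2 * params$D_free * sdt)),
                    n_sub - 1L, 2)
      pos <- rbind(p0, sweep(apply(stp, 2, cumsum), 2, p0, "+"))
      dimnames(pos) <- NULL
      r2max <- max((pos[, 1] - scene$center[1])^2 +
                     (pos[, 2] - scene$center[2])^2)
      if (r2max > scene$radius^2) {
        # re-walk the same increments with reflection at the boundary
        for (k in 2:n_sub) {
          p <- pos[k - 1L, ] + stp[k - 1L, ]
          pos[k, ] <- reflect_into_disk(matrix(p, 1), scene$center,
                                        scene$radius)[1, ]
        }
      }
      if (keep_sub) {
        xy <- cbind(colMeans(matrix(pos[, 1], nrow = sub)),
                    colMeans(matrix(pos[, 2], nrow = sub)))
        sp <- pos
      } else xy <- pos[seq(1L, n_sub, by = sub), , drop = FALSE]
      st <- rep("normal", L)
    } else {
      n_sub <- L * sub
      pos <- matrix(0, n_sub, 2)
      dom <- 0L          # 0 = free, >0 = nanodomain index
      if (ci %in% c("confined", "switching")) {
        dom <- sample.int(nrow(nd), 1L)
        repeat {
          p0 <- c(nd$x_um[dom], nd$y_um[dom]) +
            stats::runif(2, -nd$radius_um[dom], nd$radius_um[dom])
          if (sum((p0 - c(nd$x_um[dom], nd$y_um[dom]))^2) <=
                nd$radius_um[dom]^2) break
        }
      } else p0 <- draw_start()
      pos[1, ] <- p0
      state_frame <- character(L)
      for (fr in seq_len(L)) {
        state_frame[fr] <- if (dom > 0L) "confined" else "normal"
        k0 <- (fr - 1L) * sub + 1L
        nstep <- if (fr < L) sub else sub - 1L
        if (nstep > 0) for (k in (k0 + 1L):(k0 + nstep)) {
          in_dom <- dom > 0L
          D <- if (in_dom) params$D_confined else params$D_free
          p <- pos[k - 1L, ] + stats::rnorm(2, 0, sqrt(2 * D * sdt))
          if (in_dom) {
            dc <- c(nd$x_um[dom], nd$y_um[dom]); rr <- nd$radius_um[dom]
            if (params$confinement == "reflect") {
              p <- reflect_into_disk(matrix(p, 1), dc, rr)[1, ]
            } else {
              p <- p + (dc - p) * min(1, sum((p - dc)^2) / rr^2)
            }
          }
          p <- reflect_into_disk(matrix(p, 1), scene$center, scene$radius)[1, ]
          pos[k, ] <- p
        }
        # state switching assessed once per full frame
        if (ci == "switching") {
          p <- pos[min(k0 + nstep, n_sub), ]
          if (dom > 0L) {
            if (stats::runif(1) < nd$escape_prob[dom]) dom <- 0L
          } else if (nrow(nd)) {
            d2 <- (p[1] - nd$x_um)^2 + (p[2] - nd$y_um)^2
            hit <- which(d2 <= nd$radius_um^2)
            if (length(hit)) dom <- hit[1L]
          }
        }
      }
      if (keep_sub) {
        # full-frame exposure: recorded position = mean of the sub positions
        xy <- cbind(colMeans(matrix(pos[, 1], nrow = sub)),
                    colMeans(matrix(pos[, 2], nrow = sub)))
        sp <- pos
      } else xy <- pos[seq(1L, n_sub, by = sub), , drop = FALSE]
      st <- state_frame
    }
    noise <- matrix(stats::rnorm(2L * L, 0, params$loc_error_sd), L, 2)
    obs <- xy + noise
    out[[i]] <- data.frame(trajectory_id = i, frame = seq_len(L),
                           x_um = obs[, 1], y_um = obs[, 2],
                           true_state = st)
    if (keep_sub) {
      nsp <- nrow(sp)
      subpos[[i]] <- data.frame(trajectory_id = i,
                                frame = (seq_len(nsp) - 1L) %/% sub + 1L,
                                x_um = sp[, 1], y_um = sp[, 2])
    }
  }
  df <- do.call(rbind, out)
  attr(df, "labels") <- data.frame(trajectory_id = seq_len(params$n_tracks),
                                   true_class = cls, n_frames = lens)
  attr(df, "params") <- params
  attr(df, "scene") <- scene
  if (keep_sub) attr(df, "subpositions") <- do.call(rbind, subpos)
  df
}

#' Simulate an optical-tweezers force trace with a fusion event
#'
#' The post-onset force follows `F(t) = a + b * exp(-(t - onset)/tau) +
#' c * (t - onset)`; before the onset the trace sits at the baseline
#' `a + b` (plus the linear drift), so the exponential relaxation starts at
#' the onset. Gaussian measurement noise is added throughout.
#'
#' @param tau Characteristic fusion time (s), > 0.
#' @param a,b,c Model constants: baseline offset, fusion amplitude, and
#'   linear drift from trap-trap interference.
#' @param noise_sd Gaussian noise s.d. (pN).
#' @param rate_hz Sampling rate; default 50 kHz.
#' @param duration_s Trace duration (s).
#' @param onset_s Fusion onset time (s).
#' @param seed Integer seed.
#' @return A `data.frame` (`time_s`, `force_pN`) of class `"force_trace"`
#'   with attributes `rate_hz` and `truth`.
#' @export
simulate_force_trace <- function(tau, a = 10, b = 5, c = 0.5,
                                 noise_sd = 0.1, rate_hz = 50000,
                                 duration_s = 6, onset_s = 3, seed = 1L) {
  if (tau <= 0) stop("tau must be > 0")
  stopifnot(rate_hz > 0, duration_s > 0, onset_s >= 0, onset_s < duration_s)
  set.seed(as.integer(seed))
  t <- seq(0, duration_s, by = 1 / rate_hz)
  f <- a + c * pmax(t - onset_s, 0) +
    ifelse(t < onset_s, b, b * exp(-(t - onset_s) / tau))
  f <- f + stats::rnorm(length(t), 0, noise_sd)
  out <- data.frame(time_s = t, force_pN = f)
  class(out) <- c("force_trace", "data.frame")
  attr(out, "rate_hz") <- rate_hz
  attr(out, "truth") <- list(tau = tau, a = a, b = b, c = c,
                             onset_s = onset_s, seed = seed)
  out
}

#' Write trajectories to CSV
#'
#' Columns: `trajectory_id`, `frame`, `x_um`, `y_um` and, when present,
#' `true_state`. The simulation seed (if known) is embedded as a header
#' comment line.
#'
#' @param trajectories Trajectory `data.frame`.
#' @param path Output file.
#' @export
write_trajectories <- function(trajectories, path) {
  p <- attr(trajectories, "params")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(p)) writeLines(sprintf("# seed=%d", p$seed), con)
  cols <- intersect(c("trajectory_id", "frame", "x_um", "y_um", "true_state"),
                    names(trajectories))
  utils::write.csv(trajectories[, cols], con, row.names = FALSE)
  invisible(path)
}

#' Read trajectories from CSV
#'
#' Accepts the native layout (`trajectory_id`, `frame`, `x_um`, `y_um`) and
#' the column layout exported by common Fiji tracking plugins
#' (`TRACK_ID`, `FRAME`, `POSITION_X`, `POSITION_Y`).
#'
#' @param path CSV file.
#' @return Trajectory `data.frame` in the native layout.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (all(c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y") %in% names(df))) {
    df <- data.frame(trajectory_id = df$TRACK_ID, frame = df$FRAME,
                     x_um = df$POSITION_X, y_um = df$POSITION_Y)
  }
  stopifnot(all(c("trajectory_id", "frame", "x_um", "y_um") %in% names(df)))
  df[order(df$trajectory_id, df$frame), , drop = FALSE]
}

#' Split a trajectory table into per-trajectory coordinate matrices
#'
#' @param trajectories Trajectory `data.frame`.
#' @return Named list of two-column matrices (`x_um`, `y_um`), frame-ordered.
#' @export
split_trajectories <- function(trajectories) {
  ord <- order(trajectories$trajectory_id, trajectories$frame)
  trajectories <- trajectories[ord, , drop = FALSE]
  lapply(split(seq_len(nrow(trajectories)), trajectories$trajectory_id),
         function(ix) cbind(x_um = trajectories$x_um[ix],
                            y_um = trajectories$y_um[ix]))
}
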