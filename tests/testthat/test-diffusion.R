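test_that("mean step size is the arithmetic mean of Euclidean steps", {
  xy <- rbind(c(0, 0), c(3, 4) * 0.117, c(3 * 0.117, 4 * 0.117 + 0.05))
  expect_equal(mean_step_size(xy), mean(c(5 * 0.117, 0.05)))
  expect_equal(mean_step_size(rbind(c(1, 1), c(1, 1), c(1, 1))), 0)
  expect_error(mean_step_size(rbind(c(0, 0))), "2 localizations")
})

test_that("mean Brownian step approaches the Rayleigh mean", {
  set.seed(1)
  D <- 1; dt <- 0.01
  xy <- cbind(cumsum(c(0, stats::rnorm(1e4, 0, sqrt(2 * D * dt)))),
              cumsum(c(0, stats::rnorm(1e4, 0, sqrt(2 * D * dt)))))
  expect_equal(mean_step_size(xy), sqrt(pi * D * dt), tolerance = 0.02)
})

test_that("MSD obeys closed forms and the half-length lag rule", {
  static <- matrix(1, 10, 2)
  m <- compute_msd(static, 0.02)
  expect_true(all(m$msd == 0))
  expect_equal(nrow(m), 5)                      # floor(10/2)
  v <- 0.3; dt <- 0.02
  ball <- cbind(v * dt * (0:19), 0)
  mb <- compute_msd(ball, dt)
  expect_equal(mb$msd, (v * mb$lag * dt)^2, tolerance = 1e-12)
  expect_equal(nrow(compute_msd(matrix(stats::rnorm(16), 8, 2), dt)), 4)
  expect_equal(nrow(compute_msd(matrix(stats::rnorm(10), 5, 2), dt)), 4)
  expect_error(compute_msd(matrix(0, 4, 2), dt), "5 localizations")
})

test_that("alpha fit recovers ballistic and Brownian exponents exactly", {
  dt <- 0.02
  lags <- 1:10
  ball <- data.frame(lag = lags, tau_s = lags * dt,
                     msd = (0.5 * lags * dt)^2, n_pairs = 20)
  fb <- fit_alpha(ball)
  expect_equal(fb$alpha, 2, tolerance = 1e-6)
  brown <- data.frame(lag = lags, tau_s = lags * dt,
                      msd = 4 * 0.3 * lags * dt, n_pairs = 20)
  fr <- fit_alpha(brown)
  expect_equal(fr$alpha, 1, tolerance = 1e-9)
  expect_equal(fr$intercept, log(4 * 0.3), tolerance = 1e-9)
  expect_equal(fr$r2, 1, tolerance = 1e-9)
})

test_that("hard confinement drives alpha below the 0.7 threshold", {
  nd <- data.frame(x_um = 0, y_um = 0, radius_um = 0.1, escape_prob = 0)
  p <- sim_params(n_tracks = 40, D_confined = 0.05, frame_interval = 0.02,
                  loc_error_sd = 0, p_confined = 1, mean_track_len = 60,
                  min_track_len = 30, seed = 2)
  tr <- simulate_trajectories(scene(radius = 2, nanodomains = nd), p)
  alphas <- vapply(split_trajectories(tr), function(xy)
    fit_alpha(compute_msd(xy, 0.02))$alpha, 0)
  expect_lt(mean(alphas, na.rm = TRUE), 0.7)
})

test_that("classifier applies the printed thresholds", {
  # immobile: noise-only track well under the 30 nm mean step threshold
  set.seed(3)
  imm <- matrix(stats::rnorm(60, 0, 0.008), 30, 2)
  expect_equal(classify_trajectory(imm, 0.02)$category, "immobile")
  # normal: clean Brownian with a decent length
  nrm <- cbind(cumsum(c(0, stats::rnorm(99, 0, sqrt(2 * 0.5 * 0.02)))),
               cumsum(c(0, stats::rnorm(99, 0, sqrt(2 * 0.5 * 0.02)))))
  cn <- classify_trajectory(nrm, 0.02)
  expect_equal(cn$category, "normal")
  expect_true(is.finite(cn$d_app))
  # too-short mobile track cannot support an alpha fit
  short <- rbind(c(0, 0), c(0.2, 0.2), c(0.1, 0.4))
  expect_equal(classify_trajectory(short, 0.02)$category, "excluded")
})

test_that("classification fractions sum to one with and without exclusions", {
  p <- sim_params(n_tracks = 150, D_free = 0.025, seed = 4)
  tr <- simulate_trajectories(scene(radius = 2), p)
  cls <- classify_trajectories(tr, 0.02)
  expect_equal(sum(category_fractions(cls)), 1)
  expect_equal(sum(category_fractions(cls, drop_excluded = FALSE)), 1)
  expect_equal(nrow(cls), 150)
})

test_that("classifier recall is at least 80% per class on a labeled mixture", {
  nd <- data.frame(x_um = c(-1, 0.8, 0, -0.6, 0.9),
                   y_um = c(-0.8, -0.7, 0.9, 0.6, 0.5),
                   radius_um = 0.12, escape_prob = 0)
  sc <- scene(radius = 6, nanodomains = nd)
  p <- sim_params(n_tracks = 300, D_free = 0.5, D_confined = 0.05,
                  frame_interval = 0.02, p_immobile = 1 / 3,
                  p_confined = 1 / 3, mean_track_len = 120,
                  min_track_len = 60, seed = 1)
  tr <- simulate_trajectories(sc, p)
  cls <- classify_trajectories(tr, 0.02)
  m <- merge(cls, attr(tr, "labels"), by = "trajectory_id")
  ret <- m[m$category != "excluded", ]
  for (tc in c("immobile", "confined", "normal")) {
    s <- ret[ret$true_class == tc, ]
    expect_gte(mean(s$category == tc), 0.8)
  }
})

test_that("alpha estimator centers near 1 on Brownian tracks, with its known small negative bias", {
  # the unweighted log-log fit over half the trajectory carries a small
  # negative bias (log of noisy long-lag MSD values); it must stay small
  # and shrink when the fit is restricted to short lags
  p <- sim_params(n_tracks = 1000, D_free = 0.5, frame_interval = 0.02,
                  loc_error_sd = 0, mean_track_len = 80,
                  min_track_len = 50, seed = 5)
  tr <- simulate_trajectories(scene(radius = 50), p)
  parts <- split_trajectories(tr)
  alphas <- vapply(parts, function(xy)
    fit_alpha(compute_msd(xy, 0.02))$alpha, 0)
  expect_gt(mean(alphas), 0.88)
  expect_lt(mean(alphas), 1.05)
  short_lag <- vapply(parts, function(xy) {
    m <- compute_msd(xy, 0.02)
    fit_alpha(m[seq_len(max(4, floor(nrow(m) / 4))), ])$alpha
  }, 0)
  expect_gt(mean(short_lag), mean(alphas))
})

test_that("D/sigma fit is exact on noiseless Brownian MSD and flags blur mismatch", {
  dt <- 0.02; lags <- 1:8
  exact <- data.frame(lag = lags, tau_s = lags * dt,
                      msd = 4 * 0.7 * lags * dt, n_pairs = 50)
  fd <- fit_d_sigma(exact, dt, R = 0)
  expect_equal(fd$d_app, 0.7, tolerance = 1e-12)
  expect_lt(fd$sigma, 1e-6)
  expect_false(fd$clipped)
  # blurred simulation: R = 1/6 restores a physical (non-negative)
  # noise intercept, R = 0 forces clipping
  p <- sim_params(n_tracks = 400, D_free = 1, frame_interval = dt,
                  loc_error_sd = 0.016, subframe_steps = 30,
                  mean_track_len = 40, min_track_len = 20, seed = 6)
  tr <- simulate_trajectories(scene(radius = 50), p)
  m <- pooled_msd(tr, dt, max_lag = 6)
  f_blur <- fit_d_sigma(m, dt, R = 1 / 6)
  f_none <- fit_d_sigma(m, dt, R = 0)
  expect_equal(f_blur$d_app, 1, tolerance = 0.05)
  expect_false(f_blur$clipped)
  expect_true(f_none$clipped)
})

test_that("step angles fold to [0, 180] with the right limits", {
  line <- cbind(0:5, 0)
  expect_equal(step_angles(line), rep(0, 4))
  zig <- cbind(c(0, 1, 0, 1, 0), 0)
  expect_equal(step_angles(zig), rep(180, 3))
  set.seed(7)
  p <- sim_params(n_tracks = 200, D_free = 0.5, frame_interval = 0.02,
                  loc_error_sd = 0, mean_track_len = 40, seed = 8)
  tr <- simulate_trajectories(scene(radius = 50), p)
  ang <- unlist(lapply(split_trajectories(tr), step_angles))
  expect_equal(mean(ang), 90, tolerance = 2)
  # confined walks turn back on themselves: mean angle above 90
  nd <- data.frame(x_um = 0, y_um = 0, radius_um = 0.08, escape_prob = 0)
  pc <- sim_params(n_tracks = 100, D_confined = 0.05, frame_interval = 0.02,
                   loc_error_sd = 0, p_confined = 1, mean_track_len = 40,
                   seed = 9)
  trc <- simulate_trajectories(scene(radius = 2, nanodomains = nd), pc)
  angc <- unlist(lapply(split_trajectories(trc), step_angles))
  expect_gt(mean(angc), 95)
})

test_that("state array finds single-state and two-state structure", {
  p <- sim_params(n_tracks = 250, D_free = 0.8, frame_interval = 0.02,
                  loc_error_sd = 0.016, mean_track_len = 20, seed = 10)
  tr <- simulate_trajectories(scene(radius = 30), p)
  sa <- state_array_spectrum(tr, 0.02)
  expect_equal(sum(sa$occupation), 1, tolerance = 1e-9)
  expect_true(all(sa$occupation >= 0))
  expect_equal(sa$d[which.max(sa$occupation)], 0.8, tolerance = 0.25)
  # two-state mixture resolves with roughly equal mass
  p1 <- sim_params(n_tracks = 150, D_free = 0.1, frame_interval = 0.02,
                   mean_track_len = 20, seed = 11)
  p2 <- sim_params(n_tracks = 150, D_free = 10, frame_interval = 0.02,
                   mean_track_len = 20, seed = 12)
  t1 <- simulate_trajectories(scene(radius = 30), p1)
  t2 <- simulate_trajectories(scene(radius = 60), p2)
  t2$trajectory_id <- t2$trajectory_id + 10000
  both <- rbind(t1, t2)
  sa2 <- state_array_spectrum(both, 0.02)
  low <- sum(sa2$occupation[sa2$d < 1])
  expect_equal(low, 0.5, tolerance = 0.1)
  # spectrum invariant to trajectory order
  rev_ids <- both[order(-both$trajectory_id, both$frame), ]
  sa3 <- state_array_spectrum(rev_ids, 0.02)
  expect_equal(sa2$occupation, sa3$occupation, tolerance = 1e-8)
})
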