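test_that("in-mask annulus area matches analytic and Monte-Carlo oracles", {
  px <- 0.117
  big <- matrix(TRUE, 80, 80)
  a <- ring_area_in_mask(c(4.5, 4.5), 0.3, 0.1, big, pixel_size = px)
  expect_equal(a, pi * (0.4^2 - 0.3^2), tolerance = 0.02)
  # center on the straight edge of a half-plane: half the ring
  hp <- matrix(FALSE, 80, 80); hp[, 1:40] <- TRUE
  ah <- ring_area_in_mask(c(40 * px, 40 * px), 0.3, 0.1, hp,
                          pixel_size = px)
  expect_equal(ah, pi * (0.4^2 - 0.3^2) / 2, tolerance = 0.02)
  expect_error(ring_area_in_mask(c(1, 1), -0.1, 0.1, big, pixel_size = px),
               ">= 0")
  # arbitrary mask vs 1e6-sample Monte-Carlo
  set.seed(1)
  blob <- disk_mask(60, c(25, 30), 18) | disk_mask(60, c(40, 28), 10)
  ctr <- c(28 * px, 29 * px)
  for (r0 in c(0.8, 1.6)) {
    got <- ring_area_in_mask(ctr, r0, 0.1, blob, pixel_size = px)
    mc <- mc_ring_area(ctr, r0, 0.1, blob, px, n = 1e6)
    expect_equal(got, mc, tolerance = 0.01)
  }
})

test_that("G(r) is flat at 1 for uniform points and explodes for a tight cluster", {
  set.seed(2)
  px <- 0.117
  R <- 4; ctr <- c(40 * px, 40 * px)
  mask <- disk_mask(80, c(40, 40), R / px)
  pts <- disk_points(4000, ctr, R)
  pc <- pair_correlation(pts, roi = mask, mode = "auto", pixel_size = px)
  expect_lt(abs(mean(pc$g) - 1), 0.05)
  expect_true(all(abs(pc$g - 1) < 0.2))
  # one tight cluster plus sparse background
  cl <- cbind(stats::rnorm(150, ctr[1], 0.05), stats::rnorm(150, ctr[2], 0.05))
  bg <- disk_points(150, ctr, R)
  pcl <- pair_correlation(rbind(cl, bg), roi = mask, mode = "auto",
                          pixel_size = px)
  expect_gt(pcl$g[1], 5)
  expect_gt(pcl$g[1], pcl$g[nrow(pcl)])
})

test_that("edge correction removes the boundary fall-off of uncorrected G(r)", {
  set.seed(3)
  px <- 0.117
  R <- 2; ctr <- c(20 * px, 20 * px)
  mask <- disk_mask(40, c(20, 20), R / px)
  pts <- disk_points(3000, ctr, R)
  pc <- pair_correlation(pts, roi = mask, mode = "auto", pixel_size = px)
  # uncorrected version: analytic ring areas for every reference point
  n <- nrow(pts)
  edges <- seq(0, 1, by = 0.02)
  cnt <- numeric(length(edges) - 1)
  for (i in seq_len(n)) {
    d <- sqrt((pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2)[-i]
    cnt <- cnt + tabulate(findInterval(d[d < 1], edges), length(edges) - 1)
  }
  rho <- n / (pi * R^2)
  r_lo <- edges[1:46]
  g_unc <- vapply(1:46, function(j) {
    sum(cnt[j:(j + 4)]) / (n * rho * pi * ((r_lo[j] + 0.1)^2 - r_lo[j]^2))
  }, 0)
  slope_unc <- stats::coef(stats::lm(g_unc ~ r_lo))[2]
  slope_cor <- stats::coef(stats::lm(pc$g ~ pc$r))[2]
  expect_lt(slope_unc, -0.15)         # systematic drop with distance
  expect_lt(abs(slope_cor), 0.1)      # corrected curve stays flat
  expect_lt(slope_unc, slope_cor - 0.15)
})

test_that("G(r) matches a brute-force double loop with Monte-Carlo edge areas", {
  set.seed(4)
  px <- 0.117
  R <- 1.5; ctr <- c(15 * px, 15 * px)
  mask <- disk_mask(30, c(15, 15), R / px)
  pts <- disk_points(30, ctr, R)
  pc <- pair_correlation(pts, roi = mask, mode = "auto", pixel_size = px)
  oracle <- brute_pcf(pts, mask, px)
  ok <- is.finite(pc$g) & is.finite(oracle$g) & oracle$g > 0
  rel <- abs(pc$g[ok] - oracle$g[ok]) / pmax(oracle$g[ok], 1)
  expect_lt(stats::median(rel), 0.02)
  expect_lt(max(rel), 0.06)
})

test_that("cross-correlation is symmetric for equal-density sets", {
  set.seed(5)
  px <- 0.117
  R <- 2; ctr <- c(20 * px, 20 * px)
  mask <- disk_mask(40, c(20, 20), R / px)
  a <- disk_points(400, ctr, R)
  b <- disk_points(400, ctr, R)
  g1 <- pair_correlation(a, b, roi = mask, mode = "cross", pixel_size = px)
  g2 <- pair_correlation(b, a, roi = mask, mode = "cross", pixel_size = px)
  expect_equal(g1$g, g2$g, tolerance = 0.1)
})

test_that("exponential fit recovers generator parameters", {
  r <- seq(0.05, 0.95, by = 0.02)
  curve <- data.frame(r = r, g = 1 + 1.0 * exp(-r / 0.289))
  f <- fit_exponential(curve)
  expect_true(f$converged)
  expect_equal(f$A, 1.0, tolerance = 0.01)
  expect_equal(f$R, 0.289, tolerance = 0.01)
  flat <- data.frame(r = r, g = rep(1, length(r)))
  ff <- fit_exponential(flat)
  expect_equal(ff$A, 0, tolerance = 1e-6)
  expect_error(fit_exponential(data.frame(r = 1:3 / 10, g = c(2, 1.5, 1.2))),
               "5 valid bins")
})

test_that("curve pooling and bootstrap behave on degenerate and equal-weight input", {
  r <- seq(0.05, 0.95, by = 0.02)
  mk <- function(g) {
    out <- data.frame(r = r, g = g)
    class(out) <- c("pcf_curve", "data.frame")
    attr(out, "n_interest") <- 100
    out
  }
  same <- mk(1 + 0.8 * exp(-r / 0.3))
  agg <- aggregate_and_bootstrap(list(same, same, same), n_boot = 50,
                                 seed = 1)
  expect_equal(agg$pooled$g, same$g, tolerance = 1e-12)
  expect_equal(unname(diff(agg$ci[, "A"])), 0, tolerance = 1e-9)
  # equal weights pool to the arithmetic mean
  c1 <- mk(1 + 0.5 * exp(-r / 0.2)); c2 <- mk(1 + 1.5 * exp(-r / 0.4))
  agg2 <- aggregate_and_bootstrap(list(c1, c2), weights = c(1, 1),
                                  n_boot = 20, seed = 2)
  expect_equal(agg2$pooled$g, (c1$g + c2$g) / 2, tolerance = 1e-12)
  expect_error(aggregate_and_bootstrap(list(same)), "at least 2")
})

test_that("bootstrap intervals cover the generating parameters in most replicate experiments", {
  set.seed(6)
  r <- seq(0.05, 0.95, by = 0.02)
  covers <- vapply(1:10, function(rep) {
    curves <- lapply(1:12, function(i) {
      g <- 1 + 1.0 * exp(-r / 0.289) + stats::rnorm(length(r), 0, 0.08)
      out <- data.frame(r = r, g = g)
      class(out) <- c("pcf_curve", "data.frame")
      attr(out, "n_interest") <- 100
      out
    })
    agg <- aggregate_and_bootstrap(curves, n_boot = 300, seed = rep)
    (agg$ci[1, "A"] <= 1.0 && 1.0 <= agg$ci[2, "A"]) &&
      (agg$ci[1, "R"] <= 0.289 && 0.289 <= agg$ci[2, "R"])
  }, TRUE)
  expect_gte(sum(covers), 8)
})

test_that("nanodomain centers agree between puncta detection and confined centroids", {
  px <- 0.117
  true_px <- rbind(c(12, 10), c(25, 22), c(10, 26))   # (x, y) pixels
  cnts <- matrix(0L, 36, 36)
  for (i in 1:3) {
    for (dy in -1:1) for (dx in -1:1)
      cnts[true_px[i, 2] + dy, true_px[i, 1] + dx] <-
        ifelse(dy == 0 && dx == 0, 40L, 15L)
  }
  dm <- structure(list(counts = cnts, pixel_size = px),
                  class = "density_map")
  got <- nanodomain_centers(dm, method = "puncta", quality_threshold = 1)
  expect_equal(nrow(got), 3)
  for (i in 1:3) {
    truth <- (true_px[i, ] - 0.5) * px
    expect_lt(min(sqrt((got[, 1] - truth[1])^2 + (got[, 2] - truth[2])^2)),
              px)
  }
  # no confined trajectories -> empty set
  empty <- nanodomain_centers(
    data.frame(trajectory_id = integer(0), frame = integer(0),
               x_um = numeric(0), y_um = numeric(0)),
    method = "confined-centroid")
  expect_equal(nrow(empty), 0)
  # strong-trap simulation: both methods find the same domains
  nd <- data.frame(x_um = c(1.2, 2.8), y_um = c(1.4, 2.6),
                   radius_um = 0.12, escape_prob = 0)
  p <- sim_params(n_tracks = 60, D_confined = 0.05, frame_interval = 0.02,
                  loc_error_sd = 0.016, p_confined = 1,
                  mean_track_len = 30, seed = 7)
  tr <- simulate_trajectories(scene(center = c(2, 2), radius = 1.99,
                                    nanodomains = nd), p)
  cents <- nanodomain_centers(tr, method = "confined-centroid")
  for (i in 1:2) {
    d <- sqrt((cents[, 1] - nd$x_um[i])^2 + (cents[, 2] - nd$y_um[i])^2)
    expect_lt(min(d), 2 * px)
  }
})

test_that("radial profile is flat for uniform points and peaks where points sit", {
  set.seed(8)
  px <- 0.117
  mask <- disk_mask(80, c(40, 40), 30)
  ctr <- c(40 * px, 40 * px)
  R <- sqrt(sum(mask) / pi) * px
  pts <- disk_points(10000, ctr, R)
  rp <- radial_profile(pts, mask, pixel_size = px)
  inner <- rp$r_mid > 0.1 & rp$r_mid < 0.9
  expect_lt(max(abs(rp$p_norm[inner] - 1)), 0.15)
  expect_lt(abs(mean(rp$p_norm[inner]) - 1), 0.03)
  # peripheral points produce one dominant bin
  th <- stats::runif(300, 0, 2 * pi)
  per <- cbind(ctr[1] + 0.9 * R * cos(th), ctr[2] + 0.9 * R * sin(th))
  rpp <- radial_profile(per, mask, pixel_size = px)
  expect_equal(rpp$r_mid[which.max(rpp$p_norm)], 0.925, tolerance = 0.08)
  # annular process matches the analytic ring density
  rin <- 0.5 * R; rout <- 0.7 * R
  u <- stats::runif(20000)
  rad <- sqrt(rin^2 + u * (rout^2 - rin^2))
  th2 <- stats::runif(20000, 0, 2 * pi)
  ann <- cbind(ctr[1] + rad * cos(th2), ctr[2] + rad * sin(th2))
  rpa <- radial_profile(ann, mask, pixel_size = px)
  sel <- rpa$r_mid > 0.525 & rpa$r_mid < 0.675
  expected <- 1 / (0.7^2 - 0.5^2)   # uniform within the annulus
  expect_lt(max(abs(rpa$p_norm[sel] - expected) / expected), 0.05)
})

test_that("radial bootstrap collapses for identical profiles and averages distinct ones", {
  r <- seq(0.025, 1.175, by = 0.05)
  mk <- function(v) {
    out <- data.frame(r_mid = r, p_norm = v, n = 10)
    class(out) <- c("radial_profile", "data.frame")
    out
  }
  same <- mk(rep(1, length(r)))
  bb <- bootstrap_radial(list(same, same, same), n_boot = 100, seed = 1)
  expect_equal(bb$hi - bb$lo, rep(0, length(r)), tolerance = 1e-12)
  two <- bootstrap_radial(list(mk(rep(0.5, length(r))),
                               mk(rep(1.5, length(r)))),
                          n_boot = 100, seed = 2)
  expect_true(all(two$mean > 0.5 - 1e-9 & two$mean < 1.5 + 1e-9))
  expect_equal(two$mean, rep(1, length(r)), tolerance = 1e-9)
})

test_that("bootstrap outputs are reproducible under a fixed seed", {
  r <- seq(0.05, 0.95, by = 0.02)
  curves <- lapply(1:5, function(i) {
    out <- data.frame(r = r, g = 1 + 0.8 * exp(-r / 0.3) +
                        stats::rnorm(length(r), 0, 0.05))
    class(out) <- c("pcf_curve", "data.frame")
    attr(out, "n_interest") <- 50
    out
  })
  a1 <- aggregate_and_bootstrap(curves, n_boot = 50, seed = 11)
  a2 <- aggregate_and_bootstrap(curves, n_boot = 50, seed = 11)
  expect_identical(a1$boot, a2$boot)
})
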