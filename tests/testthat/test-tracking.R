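test_that("DoG filter removes DC and matches explicit kernel convolution", {
  expect_equal(max(abs(dog_filter(matrix(7, 25, 25)))), 0, tolerance = 1e-12)
  fr <- matrix(0, 31, 31); fr[16, 16] <- 50
  d <- dog_filter(fr)
  expect_gt(d[16, 16], 0)
  expect_lt(d[16, 20], 0)
  # oracle: direct 2D convolution with the (G1 - G3) difference kernel
  set.seed(1)
  img <- matrix(stats::runif(41 * 41), 41, 41)
  g1 <- function(s, rad) {   # normalized over its own 4-sigma support,
    x <- -ceiling(4 * s):ceiling(4 * s)      # then zero-padded
    k <- exp(-x^2 / (2 * s^2)); k <- k / sum(k)
    pad <- rad - ceiling(4 * s)
    c(rep(0, pad), k, rep(0, pad))
  }
  rad <- 12
  k2 <- outer(g1(1, rad), g1(1, rad)) - outer(g1(3, rad), g1(3, rad))
  r <- (nrow(k2) - 1) / 2
  got <- dog_filter(img)
  for (pix in list(c(21, 21), c(18, 25), c(25, 14))) {
    y <- pix[1]; x <- pix[2]
    patch <- img[y + (-r:r), x + (-r:r)]
    expect_lt(abs(got[y, x] - sum(patch * k2[nrow(k2):1, ncol(k2):1])),
              1e-6)
  }
})

test_that("LoG detector recovers rendered emitters with subpixel accuracy", {
  set.seed(2)
  px <- 0.117
  # 20 well-separated static emitters on a grid with subpixel offsets
  gx <- rep(seq(8, 58, by = 12), 4)[1:20] + stats::runif(20, -0.4, 0.4)
  gy <- rep(seq(8, 44, by = 12), each = 5)[1:20] + stats::runif(20, -0.4, 0.4)
  tr <- data.frame(trajectory_id = 1:20, frame = 1,
                   x_um = gx * px, y_um = gy * px)
  st <- render_video(tr, optics = list(psf_sd_px = 1.3, photons = 3000,
                                       background = 5, camera_noise_sd = 1),
                     dims = c(52, 66), noise = TRUE, seed = 3)
  det <- detect_spots(dog_filter(st[, , 1]), quality_threshold = 5)
  expect_equal(nrow(det), 20)
  # match detections to ground truth
  err <- vapply(seq_len(20), function(i) {
    min(sqrt((det$x_px - gx[i])^2 + (det$y_px - gy[i])^2))
  }, 0)
  expect_lt(sqrt(mean(err^2)), 0.5)
})

test_that("pure noise with a high threshold yields zero detections", {
  set.seed(4)
  fr <- matrix(stats::rnorm(40 * 40, 10, 1), 40, 40)
  det <- detect_spots(fr, quality_threshold = 50)
  expect_equal(nrow(det), 0)
})

test_that("two emitters 10 px apart are both detected", {
  tr <- data.frame(trajectory_id = 1:2, frame = 1,
                   x_um = c(10, 20) * 0.117, y_um = c(15, 15) * 0.117)
  st <- render_video(tr, optics = list(psf_sd_px = 1.3, photons = 3000,
                                       background = 0, camera_noise_sd = 0),
                     dims = c(30, 30), noise = FALSE)
  det <- detect_spots(st[, , 1], quality_threshold = 5)
  expect_equal(nrow(det), 2)
})

test_that("auto quality threshold separates a bimodal mixture and falls back when unimodal", {
  set.seed(5)
  q <- c(stats::rnorm(3000, 2, 0.5), stats::rnorm(1000, 20, 3))
  th <- auto_quality_threshold(q)
  expect_gt(th, 4); expect_lt(th, 16)
  q1 <- stats::rnorm(2000, 8, 1)
  expect_equal(auto_quality_threshold(q1), 5)
  expect_error(auto_quality_threshold(numeric(0)), "100")
  expect_error(auto_quality_threshold(rep(3, 500)), "degenerate")
})

test_that("a single slow emitter links into one full-length trajectory", {
  set.seed(6)
  det <- data.frame(frame = 1:30, x_px = 10 + cumsum(stats::rnorm(30, 0, 0.5)),
                    y_px = 10 + cumsum(stats::rnorm(30, 0, 0.5)), quality = 9)
  det$x_um <- det$x_px * 0.117; det$y_um <- det$y_px * 0.117
  tr <- link_trajectories(det, max_link_px = 5)
  expect_equal(length(unique(tr$trajectory_id)), 1)
  expect_equal(nrow(tr), 30)
})

test_that("a step beyond the cap terminates the trajectory and starts a new one", {
  det <- data.frame(frame = 1:4, x_px = c(0, 1, 7, 8), y_px = 0,
                    x_um = c(0, 1, 7, 8) * 0.117, y_um = 0, quality = 1)
  tr <- link_trajectories(det, max_link_px = 5)
  expect_equal(length(unique(tr$trajectory_id)), 2)
  # and with the dilute-phase cap the same data stay linked
  tr15 <- link_trajectories(det, max_link_px = 15)
  expect_equal(length(unique(tr15$trajectory_id)), 1)
})

test_that("frame-to-frame assignment matches brute-force optimal matching", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    prev <- cbind(stats::runif(n, 0, 20), stats::runif(n, 0, 20))
    cur <- prev + matrix(stats::rnorm(2 * n, 0, 1), n, 2)
    cost <- outer(prev[, 1], cur[, 1], "-")^2 +
      outer(prev[, 2], cur[, 2], "-")^2
    oracle <- brute_assignment(cost)
    links <- condensateSPT:::match_frame(prev, cur, cap = 50, method = "lap")
    got <- sum(cost[cbind(links$prev, links$cur)])
    expect_equal(got, oracle$cost, tolerance = 1e-9)
  }
})

test_that("no linked step ever exceeds the cap and linking is deterministic", {
  set.seed(8)
  det <- do.call(rbind, lapply(1:15, function(f)
    data.frame(frame = f, x_px = stats::runif(12, 0, 40),
               y_px = stats::runif(12, 0, 40), quality = 1)))
  det$x_um <- det$x_px * 0.117; det$y_um <- det$y_px * 0.117
  tr1 <- link_trajectories(det, max_link_px = 5)
  tr2 <- link_trajectories(det, max_link_px = 5)
  expect_identical(tr1, tr2)
  steps <- unlist(lapply(split(tr1, tr1$trajectory_id), function(s)
    sqrt(diff(s$x_px)^2 + diff(s$y_px)^2)))
  expect_true(all(steps <= 5 + 1e-9))
})

test_that("tracking a rendered video recovers at least 95% of true steps", {
  set.seed(9)
  px <- 0.117
  # well-separated emitters: starts on a 15-px grid, slow diffusion
  p <- sim_params(n_tracks = 9, D_free = 0.02, frame_interval = 0.02,
                  loc_error_sd = 0, mean_track_len = 30,
                  min_track_len = 10, seed = 10)
  sc <- scene(center = c(3.5, 3.5), radius = 2.7)
  tr <- simulate_trajectories(sc, p)
  grid <- expand.grid(x = c(12, 27, 42) * px, y = c(12, 27, 42) * px)
  for (i in unique(tr$trajectory_id)) {
    sel <- tr$trajectory_id == i
    tr$x_um[sel] <- tr$x_um[sel] - tr$x_um[sel][1] + grid$x[i]
    tr$y_um[sel] <- tr$y_um[sel] - tr$y_um[sel][1] + grid$y[i]
  }
  st <- render_video(tr, optics = list(psf_sd_px = 1.3, photons = 4000,
                                       background = 5, camera_noise_sd = 1),
                     dims = c(56, 56), noise = TRUE, seed = 11)
  det <- detect_spots(dog_filter(st), quality_threshold = 5)
  out <- link_trajectories(det, max_link_px = 5)
  # count true steps recovered: both endpoints detected in consecutive
  # frames within 1 px of truth and linked into the same output track
  truth <- split(tr, tr$trajectory_id)
  recovered <- 0; total <- 0
  for (s in truth) {
    for (k in seq_len(nrow(s) - 1)) {
      total <- total + 1
      f1 <- s$frame[k]; f2 <- s$frame[k + 1]
      d1 <- out[out$frame == f1, ]
      d2 <- out[out$frame == f2, ]
      i1 <- which(sqrt((d1$x_um - s$x_um[k])^2 +
                         (d1$y_um - s$y_um[k])^2) < px)
      i2 <- which(sqrt((d2$x_um - s$x_um[k + 1])^2 +
                         (d2$y_um - s$y_um[k + 1])^2) < px)
      if (length(i1) && length(i2) &&
          any(outer(d1$trajectory_id[i1], d2$trajectory_id[i2], "==")))
        recovered <- recovered + 1
    }
  }
  expect_gte(recovered / total, 0.95)
})
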