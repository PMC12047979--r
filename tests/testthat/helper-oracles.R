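# independent oracles and small fixture builders used across test files

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

# brute-force optimal assignment by permutation enumeration
brute_assignment <- function(cost) {
  n <- nrow(cost)
  pm <- perms(n)
  vals <- apply(pm, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
  list(cost = min(vals), assignment = pm[which.min(vals), ])
}

# Monte-Carlo annulus-in-mask area: sample uniformly in the annulus itself
mc_ring_area <- function(center, r, dr, mask, pixel_size, n = 1e6,
                         seed = 42) {
  set.seed(seed)
  u <- stats::runif(n)
  rad <- sqrt(r^2 + u * ((r + dr)^2 - r^2))
  th <- stats::runif(n, 0, 2 * pi)
  x <- center[1] + rad * cos(th); y <- center[2] + rad * sin(th)
  ic <- floor(x / pixel_size) + 1L; ir <- floor(y / pixel_size) + 1L
  ok <- ic >= 1 & ic <= ncol(mask) & ir >= 1 & ir <= nrow(mask)
  inside <- logical(n)
  inside[ok] <- mask[cbind(ir[ok], ic[ok])]
  pi * ((r + dr)^2 - r^2) * mean(inside)
}

# brute-force edge-corrected G(r): literal double loop over reference
# points and sliding bins, Monte-Carlo in-mask annulus areas near edges
brute_pcf <- function(pts, mask, pixel_size, dr = 0.1, r_step = 0.02,
                      r_max = 1, mc_n = 2e5, seed = 99) {
  n <- nrow(pts)
  area <- sum(mask) * pixel_size^2
  rho <- n / area
  r_lo <- seq(0, r_max - dr, by = r_step)
  gsum <- numeric(length(r_lo)); gcnt <- numeric(length(r_lo))
  for (i in seq_len(n)) {
    d <- sqrt((pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2)[-i]
    for (j in seq_along(r_lo)) {
      a <- mc_ring_area(pts[i, ], r_lo[j], dr, mask, pixel_size,
                        n = mc_n, seed = seed + i * 1000 + j)
      if (a <= 0) next
      cnt <- sum(d >= r_lo[j] & d < r_lo[j] + dr)
      gsum[j] <- gsum[j] + cnt / a
      gcnt[j] <- gcnt[j] + 1
    }
  }
  data.frame(r = r_lo + dr / 2, g = gsum / (rho * pmax(gcnt, 1)))
}

# disk mask on a pixel grid (mask pixel centers inside the disk)
disk_mask <- function(n_px, center_px, radius_px) {
  outer(seq_len(n_px), seq_len(n_px), function(r, c)
    (c - 0.5 - center_px[1])^2 + (r - 0.5 - center_px[2])^2 <= radius_px^2)
}

# uniform points inside a disk (µm)
disk_points <- function(n, center, radius) {
  th <- stats::runif(n, 0, 2 * pi)
  rad <- radius * sqrt(stats::runif(n))
  cbind(center[1] + rad * cos(th), center[2] + rad * sin(th))
}

# windowed-series fixture for HMM tests
make_series <- function(alpha, d_app) {
  s <- data.frame(center_frame = seq_along(alpha) + 10,
                  start_frame = seq_along(alpha),
                  alpha = alpha, d_app = d_app)
  class(s) <- c("windowed_series", "data.frame")
  attr(s, "window") <- 20
  s
}

# trajectory data.frame from a coordinate matrix
traj_df <- function(xy, id = 1L) {
  data.frame(trajectory_id = id, frame = seq_len(nrow(xy)),
             x_um = xy[, 1], y_um = xy[, 2])
}
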