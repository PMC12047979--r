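gaussian_kernel_1d <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- -radius:radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with replicate padding (columns then rows)
conv_sep <- function(M, k) {
  r <- (length(k) - 1) / 2
  pad_conv <- function(A) {
    Ap <- A[c(rep(1, r), seq_len(nrow(A)), rep(nrow(A), r)), , drop = FALSE]
    out <- apply(Ap, 2, function(col)
      as.numeric(stats::filter(col, k, sides = 2)))
    out[(r + 1):(r + nrow(A)), , drop = FALSE]
  }
  t(pad_conv(t(pad_conv(M))))
}

gaussian_blur <- function(M, sigma) conv_sep(M, gaussian_kernel_1d(sigma))

#' Difference-of-Gaussians band-pass filter
#'
#' Per-frame band-pass: the difference between a narrow (in-focus spot
#' scale) and a wide (slightly defocused / background scale) Gaussian blur.
#' A constant frame maps to zero.
#'
#' The blur uses an explicitly sampled, normalized Gaussian kernel (radius
#' `ceiling(4 * sigma)`) applied separably with replicate boundary padding,
#' so the result equals direct convolution with the difference kernel
#' `G(sigma_low) - G(sigma_high)`.
#'
#' @param stack Image stack array `(ny, nx, t)` or a single matrix.
#' @param sigma_low_px,sigma_high_px Gaussian sigmas in pixels;
#'   `sigma_low_px < sigma_high_px`.
#' @return Filtered stack of the same shape and class.
#' @export
dog_filter <- function(stack, sigma_low_px = 1, sigma_high_px = 3) {
  if (sigma_low_px >= sigma_high_px)
    stop("sigma_low_px must be < sigma_high_px")
  one <- is.matrix(stack)
  if (one) stack <- array(stack, dim = c(dim(stack), 1))
  out <- stack
  for (t in seq_len(dim(stack)[3])) {
    fr <- stack[, , t]
    out[, , t] <- gaussian_blur(fr, sigma_low_px) -
      gaussian_blur(fr, sigma_high_px)
  }
  if (one) out <- out[, , 1]
  out
}

# scale-normalized LoG response of one frame (positive for bright blobs)
log_response <- function(frame, sigma) {
  sm <- gaussian_blur(frame, sigma)
  ny <- nrow(sm); nx <- ncol(sm)
  up <- sm[c(1, seq_len(ny - 1)), ]
  dn <- sm[c(seq_len(ny - 1) + 1, ny), ]
  lf <- sm[, c(1, seq_len(nx - 1))]
  rt <- sm[, c(seq_len(nx - 1) + 1, nx)]
  -sigma^2 * (up + dn + lf + rt - 4 * sm)
}

# 1D quadratic (parabolic) sub-pixel offset from three samples
qinterp <- function(fm, f0, fp) {
  den <- fm - 2 * f0 + fp
  if (!is.finite(den) || den == 0) return(0)
  d <- 0.5 * (fm - fp) / den
  max(-0.5, min(0.5, d))
}

#' Detect spots with a Laplacian-of-Gaussian blob detector
#'
#' Blobs are detected at the scale implied by the estimated object diameter
#' (`sigma = diameter / (2 * sqrt(2))`), as local maxima of the
#' scale-normalized LoG response, refined to sub-pixel positions by 3x3
#' quadratic peak interpolation. The quality score of a spot is the LoG
#' response at its maximum; only spots with `quality >= quality_threshold`
#' are returned.
#'
#' @param stack Image stack `(ny, nx, t)` or single matrix (filtered or raw).
#' @param diameter_px Estimated object diameter in pixels (default 5).
#' @param quality_threshold Minimum quality (default 5).
#' @param pixel_size Pixel size in µm for the µm coordinates.
#' @return `data.frame` with `frame`, `x_px`, `y_px` (0-based pixel-center
#'   coordinates), `x_um`, `y_um`, `quality`. Zero rows when nothing passes.
#' @export
detect_spots <- function(stack, diameter_px = 5, quality_threshold = 5,
                         pixel_size = 0.117) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  sigma <- diameter_px / (2 * sqrt(2))
  res <- vector("list", dim(stack)[3])
  for (t in seq_len(dim(stack)[3])) {
    r <- log_response(stack[, , t], sigma)
    ny <- nrow(r); nx <- ncol(r)
    if (ny < 3 || nx < 3) next
    core <- r[2:(ny - 1), 2:(nx - 1)]
    ismax <- core >= quality_threshold
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      ismax <- ismax & core >= r[2:(ny - 1) + dy, 2:(nx - 1) + dx]
    }
    idx <- which(ismax, arr.ind = TRUE)
    if (!nrow(idx)) next
    iy <- idx[, 1] + 1L; ix <- idx[, 2] + 1L
    sy <- mapply(function(y, x) qinterp(r[y - 1, x], r[y, x], r[y + 1, x]),
                 iy, ix)
    sx <- mapply(function(y, x) qinterp(r[y, x - 1], r[y, x], r[y, x + 1]),
                 iy, ix)
    res[[t]] <- data.frame(frame = t, x_px = ix - 1 + sx, y_px = iy - 1 + sy,
                           quality = r[cbind(iy, ix)])
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(frame = integer(0), x_px = numeric(0),
                      y_px = numeric(0), quality = numeric(0))
  out$x_um <- out$x_px * pixel_size
  out$y_um <- out$y_px * pixel_size
  out[, c("frame", "x_px", "y_px", "x_um", "y_um", "quality")]
}

#' Choose a spot-quality threshold from the quality distribution
#'
#' False positives dominate the low-quality mode of the quality histogram;
#' the threshold is placed at the first valley above that mode. When the
#' histogram shows no such valley (unimodal), the fixed default of 5 is
#' returned.
#'
#' @param qualities Numeric vector of spot quality values (>= 100 values).
#' @param n_bins Histogram bins (default 64).
#' @param fallback Threshold when no bimodality is found (default 5).
#' @return Numeric threshold.
#' @export
auto_quality_threshold <- function(qualities, n_bins = 64, fallback = 5) {
  if (length(qualities) < 100)
    stop("need at least 100 quality values")
  if (diff(range(qualities)) == 0)
    stop("degenerate quality distribution (all values equal)")
  h <- graphics::hist(qualities, breaks = n_bins, plot = FALSE)
  cnt <- stats::filter(h$counts, rep(1 / 3, 3), sides = 2)
  cnt[is.na(cnt)] <- h$counts[is.na(cnt)]
  cnt <- as.numeric(cnt)
  mode_i <- which.max(cnt)
  n <- length(cnt)
  if (mode_i >= n - 1) return(fallback)
  # first local minimum above the dominant mode followed by a real rebound
  for (i in (mode_i + 1):(n - 1)) {
    if (cnt[i] <= cnt[i - 1] && cnt[i] <= cnt[i + 1] &&
        max(cnt[(i + 1):n]) >= 2 * max(cnt[i], 1e-9) &&
        max(cnt[(i + 1):n]) >= 0.05 * cnt[mode_i]) {
      return(h$mids[i])
    }
  }
  fallback
}

# Shortest-augmenting-path solver for the square linear assignment problem.
# Returns, for each row, the assigned column. O(n^3).
solve_lap <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  BIG <- max(cost[is.finite(cost)], 0) * n + 1e9
  cost[!is.finite(cost)] <- BIG
  u <- numeric(n); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)   # index 1 <-> virtual column
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 1L
    minv <- rep(Inf, n + 1); used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in which(!used[-1]) + 1L) {
        cur <- cost[i0, j - 1L] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) assign[p[j]] <- j - 1L
  assign
}

# one frame-to-frame assignment with births/deaths (LAP-tracker block form)
match_frame <- function(prev_xy, cur_xy, cap, method) {
  n <- nrow(prev_xy); m <- nrow(cur_xy)
  if (n == 0 || m == 0)
    return(data.frame(prev = integer(0), cur = integer(0)))
  d2 <- outer(prev_xy[, 1], cur_xy[, 1], "-")^2 +
    outer(prev_xy[, 2], cur_xy[, 2], "-")^2
  cap2 <- cap^2
  d2[d2 > cap2] <- Inf
  if (method == "greedy") {
    links <- data.frame(prev = integer(0), cur = integer(0))
    repeat {
      if (all(!is.finite(d2))) break
      ij <- which(d2 == min(d2), arr.ind = TRUE)[1, , drop = TRUE]
      links <- rbind(links, data.frame(prev = ij[1], cur = ij[2]))
      d2[ij[1], ] <- Inf; d2[, ij[2]] <- Inf
    }
    return(links)
  }
  alt <- 1.05 * cap2   # birth/death cost: any allowed link is preferred
  N <- n + m
  cost <- matrix(Inf, N, N)
  cost[seq_len(n), seq_len(m)] <- d2               # link block
  cost[cbind(seq_len(n), m + seq_len(n))] <- alt   # track death (diagonal)
  cost[cbind(n + seq_len(m), seq_len(m))] <- alt   # detection birth (diag)
  cost[n + seq_len(m), m + seq_len(n)] <- 0        # completion block
  a <- solve_lap(cost)
  keep <- which(a[seq_len(n)] <= m)
  keep <- keep[is.finite(d2[cbind(keep, a[keep])])]
  data.frame(prev = keep, cur = a[keep])
}

#' Link detections into trajectories (gap-free nearest assignment)
#'
#' Frame-to-frame linking by optimal bipartite assignment on squared
#' distance, subject to a maximum linking distance; unmatched detections
#' terminate or start trajectories. No gap closing: a trajectory ends the
#' first frame it is not matched.
#'
#' @param detections `data.frame` from [detect_spots()] (needs `frame`,
#'   `x_px`, `y_px`; µm columns are carried through).
#' @param max_link_px Maximum linking distance in pixels (5 for
#'   intra-condensate tracking, 15 for dilute-phase tracking).
#' @param pixel_size Pixel size (µm).
#' @param min_len Minimum localizations per returned trajectory (default 2).
#' @param method `"lap"` (optimal assignment, default) or `"greedy"`.
#' @return Trajectory `data.frame` (`trajectory_id`, `frame`, `x_um`,
#'   `y_um`, `quality`).
#' @export
link_trajectories <- function(detections, max_link_px = 5,
                              pixel_size = 0.117, min_len = 2,
                              method = c("lap", "greedy")) {
  method <- match.arg(method)
  if (!nrow(detections))
    return(data.frame(trajectory_id = integer(0), frame = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      quality = numeric(0)))
  detections <- detections[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(detections$frame))
  by_frame <- split(detections, detections$frame)
  next_id <- 1L
  # active tracks: id + row of last detection
  track_of <- vector("list", length(frames))
  prev <- by_frame[[as.character(frames[1])]]
  prev_ids <- seq_len(nrow(prev)); next_id <- nrow(prev) + 1L
  track_of[[1]] <- prev_ids
  for (fi in seq_along(frames)[-1]) {
    cur <- by_frame[[as.character(frames[fi])]]
    contiguous <- frames[fi] == frames[fi - 1] + 1
    if (contiguous && nrow(prev)) {
      links <- match_frame(cbind(prev$x_px, prev$y_px),
                           cbind(cur$x_px, cur$y_px), max_link_px, method)
    } else links <- data.frame(prev = integer(0), cur = integer(0))
    ids <- integer(nrow(cur))
    ids[links$cur] <- prev_ids[links$prev]
    nb <- sum(ids == 0L)
    ids[ids == 0L] <- next_id + seq_len(nb) - 1L
    next_id <- next_id + nb
    track_of[[fi]] <- ids
    prev <- cur; prev_ids <- ids
  }
  detections$trajectory_id <- unlist(track_of)
  keep_cols <- intersect(c("trajectory_id", "frame", "x_px", "y_px",
                           "x_um", "y_um", "quality"), names(detections))
  out <- detections[, keep_cols]
  len <- table(out$trajectory_id)
  out <- out[out$trajectory_id %in%
               as.integer(names(len)[len >= min_len]), , drop = FALSE]
  # renumber in order of first appearance
  out <- out[order(out$trajectory_id, out$frame), , drop = FALSE]
  out$trajectory_id <- match(out$trajectory_id, unique(out$trajectory_id))
  rownames(out) <- NULL
  out
}
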