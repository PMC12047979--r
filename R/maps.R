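#' Oversampling-suppressed localization pool
#'
#' To keep a single long trajectory from printing artificial puncta into a
#' density map, any trajectory longer than 10 steps contributes exactly 10
#' randomly chosen localizations (without replacement); shorter trajectories
#' contribute all of theirs.
#'
#' @param trajectories Trajectory `data.frame`.
#' @param seed Integer seed making the subsampling deterministic.
#' @param max_points Localizations kept per long trajectory (default 10).
#' @return `data.frame` (`trajectory_id`, `x_um`, `y_um`) with attribute
#'   `seed`.
#' @export
subsample_pool <- function(trajectories, seed = 1L, max_points = 10L) {
  if (!nrow(trajectories)) {
    out <- data.frame(trajectory_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0))
    attr(out, "seed") <- seed
    return(out)
  }
  set.seed(as.integer(seed))
  idx <- split(seq_len(nrow(trajectories)), trajectories$trajectory_id)
  take <- lapply(idx, function(ix) {
    n_steps <- length(ix) - 1L
    if (n_steps > max_points) sort(sample(ix, max_points)) else ix
  })
  out <- trajectories[unlist(take, use.names = FALSE),
                      c("trajectory_id", "x_um", "y_um")]
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

#' Localization density map on the camera pixel grid
#'
#' 2D histogram of localizations with half-open pixel bins
#' `[i * px, (i + 1) * px)`: a point exactly on a bin edge belongs to the
#' higher bin. The grid origin is at (0, 0) µm.
#'
#' @param pool Localization pool (`x_um`, `y_um`), e.g. [subsample_pool()].
#' @param pixel_size Pixel size (µm, default 0.117).
#' @param dims Optional `c(ny, nx)`; computed from the data when `NULL`.
#' @return List of class `"density_map"`: `counts` (ny x nx integer
#'   matrix), `pixel_size`.
#' @export
density_map <- function(pool, pixel_size = 0.117, dims = NULL) {
  if (!nrow(pool)) stop("empty localization pool")
  ix <- floor(pool$x_um / pixel_size) + 1L
  iy <- floor(pool$y_um / pixel_size) + 1L
  if (is.null(dims)) dims <- c(max(iy), max(ix))
  keep <- ix >= 1 & iy >= 1 & ix <= dims[2] & iy <= dims[1]
  counts <- matrix(0L, dims[1], dims[2])
  tab <- table(factor(iy[keep], levels = seq_len(dims[1])),
               factor(ix[keep], levels = seq_len(dims[2])))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, pixel_size = pixel_size),
            class = "density_map")
}

#' Step-size heatmap
#'
#' Per-pixel arithmetic mean of the step lengths whose step center (the
#' midpoint of the two endpoint positions) falls inside the pixel. Pixels
#' without steps are `NA`; per-pixel step counts are kept as weights.
#'
#' @param trajectories Trajectory `data.frame`.
#' @param pixel_size Pixel size (µm).
#' @param dims Optional `c(ny, nx)`.
#' @return List of class `"stepsize_heatmap"`: `mean_step` (µm, `NA` where
#'   empty), `n_steps`, `pixel_size`.
#' @export
stepsize_heatmap <- function(trajectories, pixel_size = 0.117, dims = NULL) {
  parts <- split_trajectories(trajectories)
  segs <- do.call(rbind, lapply(parts, function(xy) {
    if (nrow(xy) < 2) return(NULL)
    a <- xy[-nrow(xy), , drop = FALSE]; b <- xy[-1, , drop = FALSE]
    cbind(mx = (a[, 1] + b[, 1]) / 2, my = (a[, 2] + b[, 2]) / 2,
          len = sqrt(rowSums((b - a)^2)))
  }))
  if (is.null(segs) || !nrow(segs)) stop("need at least one step")
  ix <- floor(segs[, "mx"] / pixel_size) + 1L
  iy <- floor(segs[, "my"] / pixel_size) + 1L
  if (is.null(dims)) dims <- c(max(iy), max(ix))
  keep <- ix >= 1 & iy >= 1 & ix <= dims[2] & iy <= dims[1]
  ix <- ix[keep]; iy <- iy[keep]; len <- segs[keep, "len"]
  key <- (ix - 1L) * dims[1] + iy
  sums <- tapply(len, key, sum)
  cnts <- tapply(len, key, length)
  mean_step <- matrix(NA_real_, dims[1], dims[2])
  n_steps <- matrix(0L, dims[1], dims[2])
  pos <- as.integer(names(sums))
  mean_step[pos] <- sums / cnts
  n_steps[pos] <- cnts
  structure(list(mean_step = mean_step, n_steps = n_steps,
                 pixel_size = pixel_size), class = "stepsize_heatmap")
}

#' Segment and qualify condensates from a whole-FOV density map
#'
#' The counts image is smoothed with a sigma = 1 px Gaussian, thresholded
#' at 10 localizations per pixel, and connected components smaller than
#' 200 px are discarded; each surviving condensate is cropped with a 3-px
#' padding box.
#'
#' @param dmap A `"density_map"`.
#' @param smooth_sigma Gaussian sigma in px (default 1).
#' @param threshold Localizations-per-pixel threshold (default 10).
#' @param min_area_px Minimum component area (default 200).
#' @param pad_px Crop padding (default 3).
#' @return List of `"condensate_roi"` objects: `mask` (cropped logical
#'   matrix), `offset` (`c(row, col)` of the crop origin, 0-based),
#'   `area_px`, `centroid_um`, `equiv_radius_um`, `pixel_size`.
#' @export
segment_condensates <- function(dmap, smooth_sigma = 1, threshold = 10,
                                min_area_px = 200, pad_px = 3) {
  counts <- dmap$counts
  sm <- gaussian_blur(counts, smooth_sigma)
  mask <- sm >= threshold
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  n <- max(lab)
  out <- list()
  for (k in seq_len(n)) {
    sel <- lab == k
    area <- sum(sel)
    if (area < min_area_px) next
    rows <- range(which(rowSums(sel) > 0))
    cols <- range(which(colSums(sel) > 0))
    r0 <- max(1, rows[1] - pad_px); r1 <- min(nrow(sel), rows[2] + pad_px)
    c0 <- max(1, cols[1] - pad_px); c1 <- min(ncol(sel), cols[2] + pad_px)
    m <- sel[r0:r1, c0:c1, drop = FALSE]
    idx <- which(m, arr.ind = TRUE)
    # pixel-center coordinates in µm, relative to the full FOV grid
    cy <- mean(idx[, 1] + r0 - 1 - 0.5) * dmap$pixel_size
    cx <- mean(idx[, 2] + c0 - 1 - 0.5) * dmap$pixel_size
    roi <- structure(list(mask = m, offset = c(r0 - 1L, c0 - 1L),
                          area_px = area, centroid_um = c(cx, cy),
                          equiv_radius_um =
                            sqrt(area / pi) * dmap$pixel_size,
                          pixel_size = dmap$pixel_size),
                     class = "condensate_roi")
    out[[length(out) + 1]] <- roi
  }
  out
}

#' Weighted pixel-wise Pearson correlation coefficient
#'
#' Pearson correlation of two images with per-pixel reliability weights,
#' using weighted means:
#' `sum(w (x - xw)(y - yw)) / sqrt(sum(w (x - xw)^2) sum(w (y - yw)^2))`.
#' The conventional weight is the squared per-pixel localization count.
#' `NA` pixels (in either image or the weights) are excluded.
#'
#' @param image_x,image_y Numeric matrices of identical shape.
#' @param weights Non-negative matrix of the same shape; at least 2 pixels
#'   with positive weight.
#' @return Correlation in `[-1, 1]`.
#' @export
weighted_pcc <- function(image_x, image_y, weights) {
  stopifnot(all(dim(image_x) == dim(image_y)),
            all(dim(image_x) == dim(weights)))
  ok <- is.finite(image_x) & is.finite(image_y) & is.finite(weights) &
    weights > 0
  if (sum(ok) < 2) stop("need at least 2 pixels with positive weight")
  x <- image_x[ok]; y <- image_y[ok]; w <- weights[ok]
  if (sum(w) <= 0) stop("total weight must be positive")
  xw <- sum(w * x) / sum(w); yw <- sum(w * y) / sum(w)
  num <- sum(w * (x - xw) * (y - yw))
  den <- sqrt(sum(w * (x - xw)^2) * sum(w * (y - yw)^2))
  if (den == 0) stop("zero variance under the given weights")
  num / den
}

#' Weight matrix for the weighted PCC of two localization images
#'
#' The per-pixel weight is the squared number of localizations; for a
#' two-channel comparison the default combines both channels' counts before
#' squaring (`mode = "joint"`); `mode = "x"` / `"y"` use one channel only.
#'
#' @param counts_x,counts_y Per-pixel localization count matrices.
#' @param mode `"joint"`, `"x"`, or `"y"`.
#' @return Weight matrix.
#' @export
pcc_weights <- function(counts_x, counts_y = NULL,
                        mode = c("joint", "x", "y")) {
  mode <- match.arg(mode)
  w <- switch(mode,
              joint = if (is.null(counts_y)) counts_x else
                counts_x + counts_y,
              x = counts_x,
              y = counts_y)
  w^2
}

# ordered marching-squares-style boundary polygon of a mask, lightly
# smoothed to suppress pixelation bias in perimeter estimates
boundary_polygon <- function(mask, smooth_k = 5) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (!length(oc)) stop("mask has no boundary")
  poly <- oc[[which.max(vapply(oc, nrow, 0L))]]  # (x, y), 0-based
  n <- nrow(poly)
  if (n >= smooth_k && smooth_k > 1) {
    k <- smooth_k
    sm <- poly
    half <- (k - 1) / 2
    for (j in 1:2) {
      ext <- c(poly[(n - half + 1):n, j], poly[, j], poly[1:half, j])
      sm[, j] <- stats::filter(ext, rep(1 / k, k), sides = 2)[
        (half + 1):(half + n)]
    }
    poly <- sm
  }
  poly
}

#' Circularity of a condensate mask
#'
#' `4 pi Area / Perimeter^2`, with the perimeter measured on the traced
#' boundary polygon after light contour smoothing (to remove the
#' staircase bias of pixelated boundaries); 1 for an ideal disk, smaller
#' for elongated shapes.
#'
#' @param mask Logical (or 0/1) matrix, one connected component.
#' @return Circularity in `(0, 1]` (values slightly above 1 are clipped).
#' @export
circularity <- function(mask) {
  mask <- mask > 0
  if (!sum(mask)) stop("empty mask")
  touches <- any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
  poly <- boundary_polygon(mask)
  if (nrow(poly) < 3) {
    val <- 0
    attr(val, "touches_border") <- touches
    return(val)
  }
  nxt <- c(2:nrow(poly), 1)
  per <- sum(sqrt(rowSums((poly - poly[nxt, ])^2)))
  # shoelace area of the same polygon, so area and perimeter are consistent
  area <- abs(sum(poly[, 1] * poly[nxt, 2] - poly[nxt, 1] * poly[, 2])) / 2
  val <- min(4 * pi * area / per^2, 1)
  attr(val, "touches_border") <- touches
  val
}
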