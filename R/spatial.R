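# mask helpers ---------------------------------------------------------------

# a "mask geometry" is a logical matrix plus pixel size and a 0-based
# (row, col) offset locating it in the full-FOV µm coordinate frame
as_mask_geom <- function(roi, pixel_size = NULL) {
  if (inherits(roi, "condensate_roi"))
    return(list(mask = roi$mask, pixel_size = roi$pixel_size,
                offset = roi$offset))
  if (is.matrix(roi)) {
    if (is.null(pixel_size)) stop("pixel_size required for a bare mask")
    return(list(mask = roi > 0, pixel_size = pixel_size, offset = c(0L, 0L)))
  }
  stop("roi must be a condensate_roi or a logical matrix")
}

mask_area_um2 <- function(g) sum(g$mask) * g$pixel_size^2

mask_centroid_um <- function(g) {
  idx <- which(g$mask, arr.ind = TRUE)
  cx <- mean(idx[, 2] + g$offset[2] - 0.5) * g$pixel_size
  cy <- mean(idx[, 1] + g$offset[1] - 0.5) * g$pixel_size
  c(cx, cy)
}

# subpixel-center coordinates (µm) of all in-mask subpixels
mask_subpixels <- function(g, subdiv) {
  idx <- which(g$mask, arr.ind = TRUE)
  h <- g$pixel_size / subdiv
  off <- (seq_len(subdiv) - 0.5) / subdiv   # within-pixel fractions
  px <- (idx[, 2] + g$offset[2] - 1) * g$pixel_size
  py <- (idx[, 1] + g$offset[1] - 1) * g$pixel_size
  list(x = rep(px, each = subdiv^2) +
         rep(rep(off * g$pixel_size, each = subdiv), length(px)),
       y = rep(py, each = subdiv^2) +
         rep(rep(off * g$pixel_size, times = subdiv), length(py)),
       sub_area = h^2)
}

#' Annulus area inside a condensate mask
#'
#' Area of the annulus `[r, r + dr)` around `center` intersected with the
#' mask, computed numerically on a subdivided pixel grid. Far from the
#' boundary this reproduces the analytic ring area `pi ((r+dr)^2 - r^2)`.
#'
#' @param center Length-2 point (µm).
#' @param r Inner radius (µm), >= 0.
#' @param dr Ring width (µm).
#' @param roi `"condensate_roi"` or logical mask matrix.
#' @param pixel_size Pixel size (µm) when `roi` is a bare matrix.
#' @param subdiv Subdivision per pixel axis (default 8).
#' @return Area in µm².
#' @export
ring_area_in_mask <- function(center, r, dr, roi, pixel_size = NULL,
                              subdiv = 8L) {
  if (r < 0) stop("r must be >= 0")
  g <- as_mask_geom(roi, pixel_size)
  ring_areas_in_mask(center, c(r, r + dr), g, subdiv)[1]
}

# areas of consecutive annuli given by edges, restricted to the mask;
# vectorized over all annuli via one histogram of subpixel distances
ring_areas_in_mask <- function(center, edges, g, subdiv = 8L) {
  rmax <- max(edges)
  # crop mask to the bounding box of the outer circle to bound work
  nr <- nrow(g$mask); nc <- ncol(g$mask)
  col_lo <- max(1L, floor((center[1] - rmax) / g$pixel_size) - g$offset[2])
  col_hi <- min(nc, ceiling((center[1] + rmax) / g$pixel_size) -
                  g$offset[2] + 1L)
  row_lo <- max(1L, floor((center[2] - rmax) / g$pixel_size) - g$offset[1])
  row_hi <- min(nr, ceiling((center[2] + rmax) / g$pixel_size) -
                  g$offset[1] + 1L)
  if (col_lo > col_hi || row_lo > row_hi)
    return(numeric(length(edges) - 1L))
  sub <- list(mask = g$mask[row_lo:row_hi, col_lo:col_hi, drop = FALSE],
              pixel_size = g$pixel_size,
              offset = c(g$offset[1] + row_lo - 1L,
                         g$offset[2] + col_lo - 1L))
  sp <- mask_subpixels(sub, subdiv)
  if (!length(sp$x)) return(numeric(length(edges) - 1L))
  d <- sqrt((sp$x - center[1])^2 + (sp$y - center[2])^2)
  counts <- graphics::hist(d[d >= edges[1] & d < rmax],
                           breaks = edges, plot = FALSE)$counts
  counts * sp$sub_area
}

# pair correlation ------------------------------------------------------------

#' Edge-corrected pair-correlation function within a condensate
#'
#' `G(r)` is the density of interest particles at distance `r` from a
#' reference particle relative to complete spatial randomness. Overlapping
#' distance bins of width `dr` slide in steps of `r_step`. For reference
#' particles closer to the condensate boundary than `r + dr`, the in-mask
#' annulus area replaces the analytic ring area; annuli fully outside the
#' mask are skipped for that reference. In `auto` mode self-pairs are
#' excluded.
#'
#' @param ref_points,interest_points Two-column matrices / data.frames of
#'   µm coordinates (`x_um`, `y_um` columns or columns 1:2). For `auto`
#'   mode pass the same set twice (or omit `interest_points`).
#' @param roi `"condensate_roi"` or logical mask (+ `pixel_size`).
#' @param mode `"auto"` or `"cross"`.
#' @param dr Bin width (µm, default 0.1).
#' @param r_step Sliding step (µm, default 0.02); `dr` must be a multiple.
#' @param r_max Maximum outer radius (µm, default 1).
#' @param pixel_size For bare-matrix `roi`.
#' @param subdiv Subpixel subdivision for edge areas.
#' @return `data.frame` of class `"pcf_curve"`: `r` (bin midpoint, µm),
#'   `r_lo`, `g`, `n_ref_used`; attributes `n_ref`, `n_interest`,
#'   `rho_interest`.
#' @export
pair_correlation <- function(ref_points, interest_points = NULL, roi,
                             mode = c("auto", "cross"), dr = 0.1,
                             r_step = 0.02, r_max = 1,
                             pixel_size = NULL, subdiv = 8L) {
  mode <- match.arg(mode)
  pts_mat <- function(p) {
    if (is.data.frame(p)) {
      if (all(c("x_um", "y_um") %in% names(p))) cbind(p$x_um, p$y_um)
      else as.matrix(p[, 1:2])
    } else as.matrix(p)
  }
  ref <- pts_mat(ref_points)
  interest <- if (is.null(interest_points)) ref else pts_mat(interest_points)
  if (mode == "auto" && is.null(interest_points)) interest <- ref
  if (nrow(ref) < 2) stop("need at least 2 reference points")
  if (!nrow(interest)) stop("empty interest set")
  k <- round(dr / r_step)
  if (abs(k * r_step - dr) > 1e-9) stop("dr must be a multiple of r_step")
  g <- as_mask_geom(roi, pixel_size)
  area <- mask_area_um2(g)
  rho <- nrow(interest) / area
  edges <- seq(0, r_max, by = r_step)
  ne <- length(edges) - 1L          # elementary bins
  nb <- ne - k + 1L                 # reported sliding bins
  r_lo <- edges[seq_len(nb)]
  # distance of each ref to the mask boundary, from the distance transform
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(g$mask * 1)))
  rcol <- floor(ref[, 1] / g$pixel_size) - g$offset[2] + 1L
  rrow <- floor(ref[, 2] / g$pixel_size) - g$offset[1] + 1L
  inside <- rcol >= 1 & rcol <= ncol(dm) & rrow >= 1 & rrow <= nrow(dm)
  bdist <- rep(0, nrow(ref))
  bdist[inside] <- (dm[cbind(rrow[inside], rcol[inside])] - 1) * g$pixel_size
  interior <- bdist >= r_max + r_step   # margin: analytic area valid
  self_exclude <- mode == "auto" && nrow(ref) == nrow(interest)

  hist_counts <- function(i) {
    d <- sqrt((interest[, 1] - ref[i, 1])^2 + (interest[, 2] - ref[i, 2])^2)
    if (self_exclude) d <- d[-i]
    d <- d[d < r_max]
    if (!length(d)) return(integer(ne))
    tabulate(findInterval(d, edges, left.open = FALSE,
                          rightmost.closed = FALSE), nbins = ne)
  }
  elem_analytic <- pi * (edges[-1]^2 - edges[-length(edges)]^2)
  # accumulate per-bin sum of c_i / a_i over usable refs, and usable count
  sum_ratio <- numeric(ne); n_used <- numeric(ne)
  int_ix <- which(interior)
  if (length(int_ix)) {
    cint <- integer(ne)
    for (i in int_ix) cint <- cint + hist_counts(i)
    sum_ratio <- sum_ratio + cint / elem_analytic
    n_used <- n_used + length(int_ix)
  }
  for (i in which(!interior)) {
    a <- ring_areas_in_mask(ref[i, ], edges, g, subdiv)
    ci <- hist_counts(i)
    pos <- a > 0
    sum_ratio[pos] <- sum_ratio[pos] + ci[pos] / a[pos]
    n_used <- n_used + as.numeric(pos)
  }
  # aggregate elementary bins into sliding windows of width dr
  agg <- function(v) vapply(seq_len(nb), function(j) sum(v[j:(j + k - 1)]), 0)
  # G over a sliding bin: ratio of pooled counts to pooled expected counts,
  # computed per elementary bin then combined area-weighted
  g_elem <- ifelse(n_used > 0, sum_ratio / (rho * n_used), NA_real_)
  # combine: weight each elementary bin by its analytic area share
  gval <- vapply(seq_len(nb), function(j) {
    w <- elem_analytic[j:(j + k - 1)]
    v <- g_elem[j:(j + k - 1)]
    ok <- is.finite(v)
    if (!any(ok)) return(NA_real_)
    sum(w[ok] * v[ok]) / sum(w[ok])
  }, 0)
  out <- data.frame(r = r_lo + dr / 2, r_lo = r_lo, g = gval,
                    n_ref_used = agg(n_used) / k)
  class(out) <- c("pcf_curve", "data.frame")
  attr(out, "n_ref") <- nrow(ref)
  attr(out, "n_interest") <- nrow(interest)
  attr(out, "rho_interest") <- rho
  out
}

#' Exponential clustering fit of a pair-correlation curve
#'
#' Nonlinear least squares of `G(r) = 1 + A exp(-r / R)`, initialized at
#' `A0 = G(first bin) - 1`, `R0 = 0.2` µm.
#'
#' @param curve `"pcf_curve"` (needs `r`, `g`) with >= 5 valid bins.
#' @return List: `A`, `R` (µm), `converged`, `cov` (2x2), `r2`,
#'   `message` (diagnostics on failure).
#' @export
fit_exponential <- function(curve) {
  ok <- is.finite(curve$g)
  if (sum(ok) < 5) stop("need at least 5 valid bins")
  df <- data.frame(r = curve$r[ok], g = curve$g[ok])
  a0 <- df$g[1] - 1
  fit <- NULL
  for (st in list(c(a0, 0.2), c(sign(a0 + 1e-12) * max(abs(a0), 0.05), 0.1),
                  c(0.1, 0.3))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(g ~ 1 + A * exp(-r / R), data = df,
                        start = list(A = st[1], R = st[2]),
                        lower = c(A = -Inf, R = 1e-4),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error")) {
    if (stats::sd(df$g) < 1e-8)   # flat curve: no clustering, R undefined
      return(list(A = 0, R = NA_real_, converged = TRUE,
                  cov = matrix(NA_real_, 2, 2), r2 = NA_real_,
                  message = "flat curve; R unidentifiable"))
    return(list(A = NA_real_, R = NA_real_, converged = FALSE,
                cov = matrix(NA_real_, 2, 2), r2 = NA_real_,
                message = conditionMessage(fit)))
  }
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  r2 <- 1 - sum(res^2) / sum((df$g - mean(df$g))^2)
  list(A = unname(cf["A"]), R = unname(cf["R"]), converged = TRUE,
       cov = stats::vcov(fit), r2 = r2, message = "")
}

#' Pool per-condensate G(r) curves and bootstrap the exponential fit
#'
#' The pooled curve is the weighted mean of the individual-condensate
#' curves (weights: per-condensate particle counts). `n_boot` bootstrap
#' rounds resample condensates with replacement, re-pool and refit,
#' yielding distributions and percentile intervals for `A` and `R`.
#'
#' @param curves List of `"pcf_curve"`s on a common r grid.
#' @param weights Numeric weights, one per curve (default: each curve's
#'   `n_interest` attribute, else equal).
#' @param n_boot Bootstrap rounds (default 5000).
#' @param seed Integer seed.
#' @return List: `pooled` (curve), `fit`, `boot` (`data.frame` of A, R per
#'   round), `ci` (2.5/97.5 percentiles), `n_failed`.
#' @export
aggregate_and_bootstrap <- function(curves, weights = NULL, n_boot = 5000,
                                    seed = 1L) {
  if (length(curves) < 2) stop("need at least 2 curves")
  r <- curves[[1]]$r
  for (cu in curves) stopifnot(isTRUE(all.equal(cu$r, r)))
  G <- vapply(curves, function(cu) cu$g, numeric(length(r)))
  if (is.null(weights)) {
    weights <- vapply(curves, function(cu) {
      w <- attr(cu, "n_interest"); if (is.null(w)) 1 else w
    }, 0)
  }
  # NA-aware pooling: weights renormalized over non-missing curves per bin
  Gz <- G; Gz[is.na(Gz)] <- 0
  pool <- function(ix) {
    w <- weights[ix]
    num <- Gz[, ix, drop = FALSE] %*% w
    den <- (!is.na(G[, ix, drop = FALSE])) %*% w
    out <- as.numeric(num) / as.numeric(den)
    out[as.numeric(den) == 0] <- NA
    out
  }
  mk <- function(gv) {
    out <- data.frame(r = r, g = gv)
    class(out) <- c("pcf_curve", "data.frame")
    out
  }
  pooled <- mk(pool(seq_along(curves)))
  fit <- fit_exponential(pooled)
  set.seed(as.integer(seed))
  ab <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    ix <- sample(length(curves), replace = TRUE)
    fb <- tryCatch(fit_exponential(mk(pool(ix))), error = function(e) NULL)
    if (!is.null(fb) && isTRUE(fb$converged)) ab[b, ] <- c(fb$A, fb$R)
  }
  boot <- data.frame(A = ab[, 1], R = ab[, 2])
  okb <- stats::complete.cases(boot)
  ci <- apply(boot[okb, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975))
  list(pooled = pooled, fit = fit, boot = boot,
       ci = ci, n_failed = sum(!okb))
}

# nanodomains -----------------------------------------------------------------

#' Nanodomain center estimates within one condensate
#'
#' Either LoG blob detection (`"puncta"`) on the condensate's localization
#' density map, or the centroid of each confined-classified trajectory
#' (`"confined-centroid"`).
#'
#' @param x For `"puncta"`: a `"density_map"` (or counts matrix) of the
#'   condensate crop. For `"confined-centroid"`: the trajectory
#'   `data.frame` restricted to confined trajectories.
#' @param method `"puncta"` or `"confined-centroid"`.
#' @param pixel_size Pixel size (µm) for `"puncta"` on a bare matrix.
#' @param diameter_px LoG diameter for `"puncta"` (default 5).
#' @param quality_threshold LoG quality cut for `"puncta"` (default 1).
#' @param offset_um `c(x, y)` µm offset of the map origin (default 0, 0).
#' @return Two-column matrix (`x_um`, `y_um`); possibly zero rows.
#' @export
nanodomain_centers <- function(x, method = c("puncta", "confined-centroid"),
                               pixel_size = 0.117, diameter_px = 5,
                               quality_threshold = 1,
                               offset_um = c(0, 0)) {
  method <- match.arg(method)
  if (method == "puncta") {
    counts <- if (inherits(x, "density_map")) x$counts else x
    if (inherits(x, "density_map")) pixel_size <- x$pixel_size
    det <- detect_spots(counts, diameter_px = diameter_px,
                        quality_threshold = quality_threshold,
                        pixel_size = pixel_size)
    if (!nrow(det))
      return(cbind(x_um = numeric(0), y_um = numeric(0)))
    # histogram-grid convention: pixel i spans [(i-1) px, i px)
    return(cbind(x_um = (det$x_px + 0.5) * pixel_size + offset_um[1],
                 y_um = (det$y_px + 0.5) * pixel_size + offset_um[2]))
  }
  parts <- split_trajectories(x)
  if (!length(parts)) return(cbind(x_um = numeric(0), y_um = numeric(0)))
  ct <- t(vapply(parts, colMeans, numeric(2)))
  colnames(ct) <- c("x_um", "y_um")
  ct
}

#' Ring-area-normalized radial profile of points in a condensate
#'
#' Distances from the condensate center are normalized by the condensate's
#' equivalent radius (from its area, assuming a circle), binned, and each
#' bin is divided by its expected fraction under spatial uniformity (ring
#' area over disk area), so uniform points give a flat profile at 1.
#'
#' @param points Two-column matrix / data.frame of µm coordinates.
#' @param roi `"condensate_roi"` or logical mask (+ `pixel_size`).
#' @param bin_width Bin width in normalized radius (default 0.05).
#' @param r_range Normalized radius range (default `c(0, 1.2)`).
#' @param pixel_size For bare-matrix `roi`.
#' @return `data.frame` of class `"radial_profile"`: `r_mid`, `p_norm`,
#'   `n`; attributes `n_points`, `n_outside_mask`, `radius_um`.
#' @export
radial_profile <- function(points, roi, bin_width = 0.05,
                           r_range = c(0, 1.2), pixel_size = NULL) {
  p <- if (is.data.frame(points)) {
    if (all(c("x_um", "y_um") %in% names(points)))
      cbind(points$x_um, points$y_um) else as.matrix(points[, 1:2])
  } else as.matrix(points)
  if (!nrow(p)) stop("need at least 1 point")
  g <- as_mask_geom(roi, pixel_size)
  center <- mask_centroid_um(g)
  R <- sqrt(mask_area_um2(g) / pi)
  dn <- sqrt((p[, 1] - center[1])^2 + (p[, 2] - center[2])^2) / R
  # flag points outside the mask
  pc <- floor(p[, 1] / g$pixel_size) - g$offset[2] + 1L
  pr <- floor(p[, 2] / g$pixel_size) - g$offset[1] + 1L
  ok <- pc >= 1 & pc <= ncol(g$mask) & pr >= 1 & pr <= nrow(g$mask)
  ok[ok] <- g$mask[cbind(pr[ok], pc[ok])]
  edges <- seq(r_range[1], r_range[2], by = bin_width)
  cnt <- graphics::hist(dn[dn >= r_range[1] & dn < r_range[2]],
                        breaks = edges, plot = FALSE)$counts
  lo <- edges[-length(edges)]; hi <- edges[-1]
  expected <- pmax(pmin(hi, 1)^2 - pmin(lo, 1)^2, 0)
  p_norm <- ifelse(expected > 0, (cnt / length(dn)) / expected, NA_real_)
  out <- data.frame(r_mid = (lo + hi) / 2, p_norm = p_norm, n = cnt)
  class(out) <- c("radial_profile", "data.frame")
  attr(out, "n_points") <- nrow(p)
  attr(out, "n_outside_mask") <- sum(!ok)
  attr(out, "radius_um") <- R
  out
}

#' Bootstrap the mean radial profile over condensates
#'
#' @param profiles List of `"radial_profile"`s on a common bin grid.
#' @param n_boot Bootstrap rounds (default 5000).
#' @param seed Integer seed.
#' @return `data.frame`: `r_mid`, `mean`, `lo` and `hi` (2.5/97.5
#'   percentile band of the bootstrap mean).
#' @export
bootstrap_radial <- function(profiles, n_boot = 5000, seed = 1L) {
  if (length(profiles) < 2) stop("need at least 2 profiles")
  r <- profiles[[1]]$r_mid
  P <- vapply(profiles, function(p) p$p_norm, numeric(length(r)))
  set.seed(as.integer(seed))
  bm <- matrix(NA_real_, n_boot, length(r))
  for (b in seq_len(n_boot)) {
    ix <- sample(ncol(P), replace = TRUE)
    bm[b, ] <- rowMeans(P[, ix, drop = FALSE], na.rm = TRUE)
  }
  data.frame(r_mid = r,
             mean = rowMeans(P, na.rm = TRUE),
             lo = apply(bm, 2, stats::quantile, 0.025, na.rm = TRUE),
             hi = apply(bm, 2, stats::quantile, 0.975, na.rm = TRUE))
}
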