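as_xy <- function(traj) {
  if (is.data.frame(traj)) {
    stopifnot(all(c("x_um", "y_um") %in% names(traj)))
    if ("frame" %in% names(traj)) traj <- traj[order(traj$frame), ]
    return(cbind(traj$x_um, traj$y_um))
  }
  stopifnot(is.matrix(traj), ncol(traj) == 2)
  traj
}

#' Mean step size of a trajectory
#'
#' Arithmetic mean of the Euclidean frame-to-frame step lengths.
#'
#' @param traj Two-column coordinate matrix (µm) or a trajectory
#'   `data.frame` with `x_um`, `y_um` (and optionally `frame`).
#' @return Mean step length in µm.
#' @export
mean_step_size <- function(traj) {
  xy <- as_xy(traj)
  if (nrow(xy) < 2) stop("trajectory needs at least 2 localizations")
  d <- diff(xy)
  mean(sqrt(rowSums(d^2)))
}

#' Time-averaged mean squared displacement
#'
#' Overlapping time-averaged MSD. The lag range follows the half-length
#' rule: lags `1..max(floor(N/2), 4)` for a trajectory of `N`
#' localizations — half the trajectory for well-sampled tracks, with at
#' least 4 MSD points guaranteed for short ones (never more than `N - 1`).
#'
#' @param traj Coordinates as in [mean_step_size()]; >= 5 localizations.
#' @param frame_interval Frame interval (s).
#' @return `data.frame` of class `"msd_curve"`: `lag`, `tau_s`, `msd`
#'   (µm²), `n_pairs`.
#' @export
compute_msd <- function(traj, frame_interval) {
  xy <- as_xy(traj)
  N <- nrow(xy)
  if (N < 5) stop("trajectory needs at least 5 localizations")
  max_lag <- min(max(floor(N / 2), 4L), N - 1L)
  msd <- numeric(max_lag); npairs <- integer(max_lag)
  for (k in seq_len(max_lag)) {
    d <- xy[(1 + k):N, , drop = FALSE] - xy[1:(N - k), , drop = FALSE]
    msd[k] <- mean(rowSums(d^2))
    npairs[k] <- N - k
  }
  out <- data.frame(lag = seq_len(max_lag),
                    tau_s = seq_len(max_lag) * frame_interval,
                    msd = msd, n_pairs = npairs)
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Ensemble-pooled MSD over many trajectories
#'
#' Averages the time-averaged MSD curves of all trajectories at each lag,
#' weighting by the number of displacement pairs, up to `max_lag`. Pooling
#' before fitting avoids the selection and clipping biases of averaging
#' per-trajectory fit results.
#'
#' @param trajectories Trajectory `data.frame`.
#' @param frame_interval Frame interval (s).
#' @param max_lag Largest lag (frames, default 10).
#' @return `"msd_curve"` with pooled `msd` and total `n_pairs` per lag.
#' @export
pooled_msd <- function(trajectories, frame_interval, max_lag = 10) {
  parts <- split_trajectories(trajectories)
  ssum <- numeric(max_lag); npair <- numeric(max_lag)
  for (xy in parts) {
    N <- nrow(xy)
    if (N < 2) next
    for (k in seq_len(min(max_lag, N - 1))) {
      d <- xy[(1 + k):N, , drop = FALSE] - xy[1:(N - k), , drop = FALSE]
      ssum[k] <- ssum[k] + sum(rowSums(d^2))
      npair[k] <- npair[k] + (N - k)
    }
  }
  keep <- npair > 0
  out <- data.frame(lag = seq_len(max_lag)[keep],
                    tau_s = (seq_len(max_lag) * frame_interval)[keep],
                    msd = (ssum / pmax(npair, 1))[keep],
                    n_pairs = npair[keep])
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Anomalous-exponent fit on log-log axes
#'
#' Unweighted least squares of `log(MSD)` on `log(tau)`:
#' `log(MSD) = alpha * log(tau) + log(2 n D)` with `n = 2` dimensions.
#' Non-positive MSD points are dropped; fewer than 4 remaining points make
#' the trajectory ineligible (`NA` result).
#'
#' @param msd An `"msd_curve"` from [compute_msd()].
#' @return List: `alpha`, `intercept` (`log(2 n D)`), `r2`, `n_points`.
#' @export
fit_alpha <- function(msd) {
  ok <- is.finite(msd$msd) & msd$msd > 0
  if (sum(ok) < 4)
    return(list(alpha = NA_real_, intercept = NA_real_, r2 = NA_real_,
                n_points = sum(ok)))
  x <- log(msd$tau_s[ok]); y <- log(msd$msd[ok])
  fit <- stats::lm.fit(cbind(1, x), y)
  ybar <- mean(y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - ybar)^2)
  list(alpha = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r2 = r2, n_points = sum(ok))
}

#' Apparent diffusion coefficient and localization error from MSD
#'
#' Linear least squares of the camera-corrected 2D MSD model
#' `MSD(tau) = 4 D tau + 4 sigma^2 - 8 D R dt`, where `R` is the motion
#' blur coefficient (`1/6` for continuous full-frame exposure, `0` for
#' instantaneous exposure) and `dt` the frame interval. Negative estimates
#' of `D` or `sigma^2` are clipped at zero and flagged.
#'
#' @param msd An `"msd_curve"`.
#' @param frame_interval Frame interval (s).
#' @param R Motion blur coefficient (default 1/6).
#' @return List: `d_app` (µm²/s), `sigma` (µm), `clipped` (logical),
#'   `r2` of the linear fit.
#' @export
fit_d_sigma <- function(msd, frame_interval, R = 1 / 6) {
  ok <- is.finite(msd$msd)
  if (sum(ok) < 2) stop("need at least 2 MSD points")
  x <- msd$tau_s[ok]; y <- msd$msd[ok]
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  icpt <- unname(fit$coefficients[1])
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  d <- slope / 4
  clipped <- FALSE
  if (d < 0) { d <- 0; clipped <- TRUE }
  sig2 <- (icpt + 8 * d * R * frame_interval) / 4
  if (sig2 < 0) { sig2 <- 0; clipped <- TRUE }
  list(d_app = d, sigma = sqrt(sig2), clipped = clipped, r2 = r2)
}

#' Angles between consecutive steps
#'
#' The angle between every pair of consecutive displacement vectors, folded
#' to `[0, 180]` degrees regardless of turn direction: 0° means no change
#' of direction, 180° a complete reversal. Zero-length steps are skipped.
#'
#' @param traj Coordinates as in [mean_step_size()]; >= 3 localizations.
#' @return Numeric vector of angles in degrees.
#' @export
step_angles <- function(traj) {
  xy <- as_xy(traj)
  if (nrow(xy) < 3) stop("trajectory needs at least 3 localizations")
  v <- diff(xy)
  len <- sqrt(rowSums(v^2))
  keep <- len > 0
  v <- v[keep, , drop = FALSE]; len <- len[keep]
  if (nrow(v) < 2) return(numeric(0))
  a <- v[-nrow(v), , drop = FALSE]; b <- v[-1, , drop = FALSE]
  cosang <- rowSums(a * b) / (len[-length(len)] * len[-1])
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Classify one trajectory as immobile, confined, normal, or excluded
#'
#' Decision rule: immobile if the mean step size is below 30 nm; otherwise
#' fit the anomalous exponent on log-log MSD; excluded if the fit's
#' R-squared is below 0.7 (or too few usable MSD points); confined if
#' `alpha < alpha_threshold`; normal otherwise (the boundary value goes to
#' normal). For normal trajectories `d_app` and the localization error are
#' also fitted with the motion-blur model.
#'
#' @param traj Coordinates or trajectory `data.frame`.
#' @param frame_interval Frame interval (s).
#' @param immobile_um Immobile mean-step threshold (µm, default 0.030).
#' @param alpha_threshold Confinement threshold on alpha (default 0.7).
#' @param r2_min Minimum R-squared of the alpha fit (default 0.7).
#' @param blur_R Motion blur coefficient for the D/sigma fit (default 1/6).
#' @return List: `category`, `mean_step`, `alpha`, `alpha_r2`, `d_app`,
#'   `loc_error_sigma` (the last two `NA` unless normal).
#' @export
classify_trajectory <- function(traj, frame_interval,
                                immobile_um = 0.030, alpha_threshold = 0.7,
                                r2_min = 0.7, blur_R = 1 / 6) {
  xy <- as_xy(traj)
  ms <- mean_step_size(xy)
  res <- list(category = NA_character_, mean_step = ms, alpha = NA_real_,
              alpha_r2 = NA_real_, d_app = NA_real_,
              loc_error_sigma = NA_real_)
  if (ms < immobile_um) { res$category <- "immobile"; return(res) }
  if (nrow(xy) < 5) { res$category <- "excluded"; return(res) }
  m <- compute_msd(xy, frame_interval)
  fa <- fit_alpha(m)
  res$alpha <- fa$alpha; res$alpha_r2 <- fa$r2
  if (!is.finite(fa$alpha) || !is.finite(fa$r2) || fa$r2 < r2_min) {
    res$category <- "excluded"; return(res)
  }
  if (fa$alpha < alpha_threshold) { res$category <- "confined"; return(res) }
  res$category <- "normal"
  fd <- fit_d_sigma(m, frame_interval, R = blur_R)
  res$d_app <- fd$d_app; res$loc_error_sigma <- fd$sigma
  res
}

#' Classify every trajectory in a table
#'
#' Applies [classify_trajectory()] per trajectory and returns one row each.
#'
#' @inheritParams classify_trajectory
#' @param trajectories Trajectory `data.frame`.
#' @param ... Passed to [classify_trajectory()].
#' @return `data.frame`: `trajectory_id`, `n_frames`, `category`,
#'   `mean_step`, `alpha`, `alpha_r2`, `d_app`, `loc_error_sigma`.
#' @export
classify_trajectories <- function(trajectories, frame_interval, ...) {
  parts <- split_trajectories(trajectories)
  rows <- lapply(names(parts), function(id) {
    r <- classify_trajectory(parts[[id]], frame_interval, ...)
    data.frame(trajectory_id = id, n_frames = nrow(parts[[id]]),
               category = r$category, mean_step = r$mean_step,
               alpha = r$alpha, alpha_r2 = r$alpha_r2, d_app = r$d_app,
               loc_error_sigma = r$loc_error_sigma)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Category fractions of a classified set
#'
#' @param classified Output of [classify_trajectories()].
#' @param drop_excluded If `TRUE` (default), fractions are over the three
#'   retained categories (immobile, confined, normal), matching how
#'   category fractions are conventionally reported after the R-squared
#'   exclusion; if `FALSE`, excluded counts in the denominator.
#' @return Named numeric vector of fractions summing to 1.
#' @export
category_fractions <- function(classified, drop_excluded = TRUE) {
  lv <- c("immobile", "confined", "normal", "excluded")
  tab <- table(factor(classified$category, levels = lv))
  if (drop_excluded) tab <- tab[1:3]
  as.numeric(tab) / sum(tab) -> fr
  stats::setNames(fr, names(tab))
}

#' State-array spectrum of apparent diffusion coefficients
#'
#' Grid-likelihood estimate of the distribution of D over mobile
#' trajectories. For each trajectory the sum of squared 2D displacements is
#' gamma-distributed with shape = number of steps and scale
#' `4 (D dt + sigma^2 - 2 D R dt)`; mixture occupations over a log-spaced
#' D grid are estimated by expectation-maximization with a weak symmetric
#' Dirichlet prior. This is a simplified state-array estimator (grid
#' likelihood + EM), not a variational treatment.
#'
#' @param trajectories Trajectory `data.frame` (mobile trajectories).
#' @param frame_interval Frame interval (s).
#' @param d_grid Log-spaced grid of D values (µm²/s); default 64 points
#'   from 0.01 to 100.
#' @param loc_error Localization error sigma (µm, default 0.016).
#' @param blur_R Motion blur coefficient entering the per-step variance
#'   (default 0).
#' @param dirichlet_alpha Symmetric Dirichlet concentration (default 1.01).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return `data.frame` of class `"state_array"`: `d` (µm²/s),
#'   `occupation` (non-negative, sums to 1).
#' @export
state_array_spectrum <- function(trajectories, frame_interval,
                                 d_grid = 10^seq(log10(0.01), log10(100),
                                                 length.out = 64),
                                 loc_error = 0.016, blur_R = 0,
                                 dirichlet_alpha = 1.01,
                                 max_iter = 500, tol = 1e-8) {
  parts <- split_trajectories(trajectories)
  parts <- parts[vapply(parts, nrow, 0L) >= 2]
  if (!length(parts)) stop("no usable trajectories")
  S <- vapply(parts, function(xy) sum(diff(xy[, 1])^2 + diff(xy[, 2])^2), 0)
  M <- vapply(parts, function(xy) nrow(xy) - 1L, 0L)
  keep <- S > 0
  S <- S[keep]; M <- M[keep]
  scale_j <- 4 * (d_grid * frame_interval + loc_error^2 -
                    2 * d_grid * blur_R * frame_interval)
  if (any(scale_j <= 0))
    stop("per-step variance non-positive on part of the D grid")
  K <- length(d_grid); N <- length(S)
  ll <- matrix(0, N, K)
  for (j in seq_len(K))
    ll[, j] <- stats::dgamma(S, shape = M, scale = scale_j[j], log = TRUE)
  w <- rep(1 / K, K)
  last <- -Inf
  for (it in seq_len(max_iter)) {
    lw <- sweep(ll, 2, log(w), "+")
    mx <- apply(lw, 1, max)
    pr <- exp(lw - mx)
    rs <- rowSums(pr)
    loglik <- sum(mx + log(rs))
    resp <- pr / rs
    nk <- colSums(resp) + (dirichlet_alpha - 1)
    nk[nk < 0] <- 0
    w <- nk / sum(nk)
    if (is.finite(last) && abs(loglik - last) < tol * abs(loglik)) break
    last <- loglik
  }
  out <- data.frame(d = d_grid, occupation = w)
  class(out) <- c("state_array", "data.frame")
  attr(out, "loglik") <- last
  out
}
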