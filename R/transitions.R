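#' Running-window diffusion profile along one trajectory
#'
#' Slides a window of `window` steps (stride 1) along the trajectory and
#' computes the anomalous exponent and apparent diffusion coefficient of
#' each window with the same MSD fitters used for whole-trajectory
#' classification.
#'
#' @param traj Coordinates or trajectory `data.frame`; length must exceed
#'   the window.
#' @param frame_interval Frame interval (s).
#' @param window Window size in steps (default 20).
#' @param blur_R Motion blur coefficient for the window D fit (default 1/6).
#' @return `data.frame` of class `"windowed_series"`: `center_frame`
#'   (window center, frames, 1-based), `start_frame`, `alpha`, `d_app`.
#' @export
running_window_profile <- function(traj, frame_interval, window = 20,
                                   blur_R = 1 / 6) {
  xy <- as_xy(traj)
  N <- nrow(xy)
  if (N < window + 1) stop("trajectory shorter than the window")
  n_win <- N - window
  alpha <- d_app <- numeric(n_win)
  for (i in seq_len(n_win)) {
    w <- xy[i:(i + window), , drop = FALSE]
    m <- compute_msd(w, frame_interval)
    fa <- fit_alpha(m)
    fd <- fit_d_sigma(m, frame_interval, R = blur_R)
    alpha[i] <- fa$alpha
    d_app[i] <- fd$d_app
  }
  out <- data.frame(center_frame = seq_len(n_win) + window / 2,
                    start_frame = seq_len(n_win), alpha = alpha,
                    d_app = d_app)
  class(out) <- c("windowed_series", "data.frame")
  attr(out, "window") <- window
  out
}

# --- minimal diagonal-Gaussian HMM (Baum-Welch + Viterbi) -------------------

hmm_loglik_obs <- function(X, mu, sd) {
  # X: T x d; returns T x K log emission densities
  K <- nrow(mu)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K))
    out[, k] <- rowSums(vapply(seq_len(ncol(X)), function(j)
      stats::dnorm(X[, j], mu[k, j], sd[k, j], log = TRUE),
      numeric(nrow(X))))
  out
}

hmm_fit_once <- function(X, K, mu0, sd0, max_iter = 100, tol = 1e-4) {
  Tn <- nrow(X)
  mu <- mu0; sd <- sd0
  A <- matrix(1 / K, K, K); diag(A) <- diag(A) + 0.8
  A <- A / rowSums(A)
  pi0 <- rep(1 / K, K)
  last <- -Inf
  for (it in seq_len(max_iter)) {
    lb <- hmm_loglik_obs(X, mu, sd)
    # scaled forward-backward
    alpha <- matrix(0, Tn, K); beta <- matrix(0, Tn, K); cscale <- numeric(Tn)
    a <- pi0 * exp(lb[1, ] - max(lb[1, ]))
    cscale[1] <- sum(a); alpha[1, ] <- a / cscale[1]
    lmax <- apply(lb, 1, max)
    B <- exp(lb - lmax)
    for (t in 2:Tn) {
      a <- (alpha[t - 1, ] %*% A) * B[t, ]
      cscale[t] <- sum(a)
      alpha[t, ] <- a / cscale[t]
    }
    loglik <- sum(log(cscale)) + sum(lmax)
    beta[Tn, ] <- 1
    for (t in (Tn - 1):1)
      beta[t, ] <- as.numeric(A %*% (B[t + 1, ] * beta[t + 1, ])) / cscale[t + 1]
    gamma <- alpha * beta
    gamma <- gamma / rowSums(gamma)
    xi <- matrix(0, K, K)
    for (t in 1:(Tn - 1)) {
      m <- (alpha[t, ] %o% (B[t + 1, ] * beta[t + 1, ])) * A
      xi <- xi + m / sum(m)
    }
    pi0 <- gamma[1, ]
    A <- xi / pmax(rowSums(xi), .Machine$double.eps)
    for (k in seq_len(K)) {
      wk <- gamma[, k] / sum(gamma[, k])
      mu[k, ] <- colSums(X * wk)
      sd[k, ] <- sqrt(pmax(colSums((X - matrix(mu[k, ], Tn, ncol(X),
                                               byrow = TRUE))^2 * wk),
                           1e-8))
    }
    if (is.finite(last) && abs(loglik - last) < tol) break
    last <- loglik
  }
  list(mu = mu, sd = sd, A = A, pi0 = pi0, loglik = loglik)
}

hmm_viterbi <- function(X, fit) {
  K <- nrow(fit$mu); Tn <- nrow(X)
  lb <- hmm_loglik_obs(X, fit$mu, fit$sd)
  lA <- log(pmax(fit$A, 1e-300))
  delta <- matrix(-Inf, Tn, K); psi <- matrix(0L, Tn, K)
  delta[1, ] <- log(pmax(fit$pi0, 1e-300)) + lb[1, ]
  for (t in 2:Tn) for (k in seq_len(K)) {
    v <- delta[t - 1, ] + lA[, k]
    psi[t, k] <- which.max(v)
    delta[t, k] <- max(v) + lb[t, k]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Two-state segmentation of a running-window diffusion series
#'
#' Fits a two-state Gaussian-emission hidden Markov model to the windowed
#' features (by default both the anomalous exponent and `log10(D_app)`),
#' decodes the most likely state path, and reports transitions. States are
#' canonicalized by mean alpha: the state with the lower mean alpha is
#' `"confined"`, the other `"normal"`. A near-constant series yields a
#' single state and no transitions.
#'
#' @param series `"windowed_series"` from [running_window_profile()].
#' @param features Character subset of `c("alpha", "d_app")` (default both;
#'   `d_app` enters as `log10`).
#' @param restarts Independent EM restarts with perturbed k-means
#'   initializations; best likelihood wins (default 10).
#' @param tol EM log-likelihood tolerance (default 1e-4).
#' @param seed Integer seed for initialization.
#' @return List: `states` (per-window labels), `transition_frames` (first
#'   frame of the first window in each new state), `fit`, `series`.
#' @export
hmm_segment <- function(series, features = c("alpha", "d_app"),
                        restarts = 10, tol = 1e-4, seed = 1L) {
  stopifnot(nrow(series) >= 2)
  features <- match.arg(features, c("alpha", "d_app"), several.ok = TRUE)
  cols <- list()
  if ("alpha" %in% features) cols$alpha <- series$alpha
  if ("d_app" %in% features)
    cols$log_dapp <- log10(pmax(series$d_app, 1e-6))
  X <- do.call(cbind, cols)
  ok <- stats::complete.cases(X)
  Xo <- X[ok, , drop = FALSE]
  if (nrow(Xo) < 4 || all(apply(Xo, 2, stats::sd) < 1e-10)) {
    states <- rep("confined", nrow(series))
    if (mean(series$alpha, na.rm = TRUE) >= 0.7) states[] <- "normal"
    return(list(states = states, transition_frames = integer(0),
                fit = NULL, series = series))
  }
  # standardize features for fitting
  mu_f <- colMeans(Xo); sd_f <- apply(Xo, 2, stats::sd)
  sd_f[sd_f < 1e-10] <- 1
  Z <- sweep(sweep(Xo, 2, mu_f), 2, sd_f, "/")
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(restarts)) {
    km <- tryCatch(stats::kmeans(Z, centers = 2, nstart = 1),
                   error = function(e) NULL)
    if (is.null(km)) next
    mu0 <- km$centers + matrix(stats::rnorm(4, 0, if (r == 1) 0 else 0.2),
                               2, ncol(Z))
    sd0 <- matrix(1, 2, ncol(Z))
    f <- tryCatch(hmm_fit_once(Z, 2, mu0, sd0, tol = tol),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$loglik > best$loglik)) best <- f
  }
  if (is.null(best))
    stop("HMM fitting failed on all restarts")
  path <- hmm_viterbi(Z, best)
  # canonical labels: lower mean alpha (first feature if alpha present)
  if ("alpha" %in% features) {
    amean <- vapply(1:2, function(k) mean(Xo[path == k, 1]), 0)
  } else {
    amean <- vapply(1:2, function(k) mean(Xo[path == k, 1]), 0)
  }
  lab <- c("confined", "normal")
  ord <- order(amean)            # lower alpha (or log D) -> confined
  labels <- character(2); labels[ord] <- lab
  states_ok <- labels[path]
  states <- rep(NA_character_, nrow(series))
  states[ok] <- states_ok
  sf <- series$start_frame[ok]
  chg <- which(diff(path) != 0)
  transition_frames <- sf[chg + 1]
  list(states = states, transition_frames = transition_frames,
       fit = best, series = series)
}
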