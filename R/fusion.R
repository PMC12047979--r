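#' Read a force trace from CSV
#'
#' Expects columns `time_s`, `force_pN`; the sampling rate is inferred from
#' the time grid.
#'
#' @param path CSV file.
#' @return `"force_trace"` `data.frame`.
#' @export
read_force_trace <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("time_s", "force_pN") %in% names(df)))
  out <- df[order(df$time_s), c("time_s", "force_pN")]
  class(out) <- c("force_trace", "data.frame")
  attr(out, "rate_hz") <- 1 / stats::median(diff(out$time_s))
  out
}

#' Write a force trace to CSV
#' @param trace `"force_trace"`.
#' @param path Output file.
#' @export
write_force_trace <- function(trace, path) {
  tr <- attr(trace, "truth")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(tr)) writeLines(sprintf("# seed=%d", tr$seed), con)
  utils::write.csv(as.data.frame(trace)[, c("time_s", "force_pN")], con,
                   row.names = FALSE)
  invisible(path)
}

#' Detect the fusion onset in a force trace
#'
#' Block-averages the trace down to `down_hz` (default 5 Hz), takes the
#' discrete gradient, and places the onset at the largest absolute gradient
#' peak. If that peak does not exceed `threshold_factor` times the median
#' absolute gradient, no event is flagged.
#'
#' @param trace `"force_trace"` (>= 2 s long).
#' @param down_hz Downsampled rate (default 5).
#' @param threshold_factor No-event threshold as a multiple of the median
#'   absolute gradient (default 5).
#' @return List: `onset_index` (index into the full-rate trace, `NA` if no
#'   event), `onset_time_s`, `event` (logical), `gradient` (downsampled).
#' @export
detect_fusion_onset <- function(trace, down_hz = 5, threshold_factor = 5) {
  rate <- attr(trace, "rate_hz")
  if (is.null(rate)) rate <- 1 / stats::median(diff(trace$time_s))
  if (max(trace$time_s) - min(trace$time_s) < 2)
    stop("trace must span at least 2 s")
  block <- max(1L, round(rate / down_hz))
  n_blk <- floor(nrow(trace) / block)
  f <- trace$force_pN[seq_len(n_blk * block)]
  fb <- colMeans(matrix(f, nrow = block))
  grad <- diff(fb)
  peak <- which.max(abs(grad))
  med <- stats::median(abs(grad))
  event <- abs(grad[peak]) > threshold_factor * max(med, 1e-12)
  if (!event)
    return(list(onset_index = NA_integer_, onset_time_s = NA_real_,
                event = FALSE, gradient = grad))
  # refine within +/- one block at a finer gradient resolution
  lo <- max(1L, (peak - 1L) * block + 1L)
  hi <- min(nrow(trace), (peak + 1L) * block)
  fine_block <- max(1L, round(rate / 500))
  nfb <- floor((hi - lo + 1L) / fine_block)
  onset_index <- (peak - 1L) * block + 1L
  if (nfb >= 3) {
    ff <- colMeans(matrix(trace$force_pN[lo:(lo + nfb * fine_block - 1L)],
                          nrow = fine_block))
    fg <- diff(ff)
    onset_index <- lo + (which.max(abs(fg)) - 1L) * fine_block
  }
  list(onset_index = onset_index,
       onset_time_s = trace$time_s[onset_index], event = TRUE,
       gradient = grad)
}

#' Fit the characteristic fusion time to a force trace
#'
#' Nonlinear least squares of `F(t) = a + b exp(-t / tau) + c t` on the
#' full-rate data over a window after the onset (`t` measured from the
#' onset). `tau` is initialized from the 1/e decay time of the
#' downsampled post-onset force.
#'
#' @param trace `"force_trace"`.
#' @param onset Full-rate onset index (e.g. from [detect_fusion_onset()]).
#' @param window_s Fit window length after onset (s, default 1).
#' @return List of class `"fusion_fit"`: `tau`, `a`, `b`, `c`, `r2`,
#'   `cov`, `converged`, `onset_index`, `message`.
#' @export
fit_fusion <- function(trace, onset, window_s = 1) {
  rate <- attr(trace, "rate_hz")
  if (is.null(rate)) rate <- 1 / stats::median(diff(trace$time_s))
  stopifnot(is.finite(onset), onset >= 1, onset <= nrow(trace))
  n <- min(nrow(trace), onset + round(window_s * rate))
  seg <- trace[onset:n, ]
  t <- seg$time_s - seg$time_s[1]
  f <- seg$force_pN
  # tau0 from the 1/e decay time of the block-averaged segment
  block <- max(1L, round(rate / 50))
  nb <- floor(length(f) / block)
  fb <- colMeans(matrix(f[seq_len(nb * block)], nrow = block))
  tb <- (seq_len(nb) - 0.5) * block / rate
  a0 <- mean(fb[max(1, nb - 4):nb])
  b0 <- fb[1] - a0
  if (abs(b0) < 1e-12)
    return(structure(list(tau = NA_real_, a = a0, b = 0, c = 0,
                          r2 = NA_real_, cov = NULL, converged = FALSE,
                          onset_index = onset,
                          message = "no decay amplitude at onset"),
                     class = "fusion_fit"))
  dec <- which(abs(fb - a0) <= abs(b0) / exp(1))
  tau0 <- if (length(dec)) min(max(tb[dec[1]], 1e-3), window_s) else
    window_s / 5
  fit <- NULL
  for (t0 in unique(c(tau0, 0.02 * window_s, 0.1 * window_s,
                      0.5 * window_s))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(f ~ a + b * exp(-t / tau) + c * t,
                        data = data.frame(t = t, f = f),
                        start = list(a = a0, b = b0, c = 0, tau = t0),
                        lower = c(a = -Inf, b = -Inf, c = -Inf, tau = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error"))
    return(structure(list(tau = NA_real_, a = NA_real_, b = NA_real_,
                          c = NA_real_, r2 = NA_real_, cov = NULL,
                          converged = FALSE, onset_index = onset,
                          message = conditionMessage(fit)),
                     class = "fusion_fit"))
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  r2 <- 1 - sum(res^2) / sum((f - mean(f))^2)
  structure(list(tau = unname(cf["tau"]), a = unname(cf["a"]),
                 b = unname(cf["b"]), c = unname(cf["c"]), r2 = r2,
                 cov = stats::vcov(fit), converged = TRUE,
                 onset_index = onset, message = ""),
            class = "fusion_fit")
}

#' Condensate area from a confocal frame by Otsu thresholding
#'
#' Global Otsu threshold on intensity; the area of the largest connected
#' foreground component, in µm². Flags frames without usable bimodality.
#'
#' @param frame Single-channel intensity matrix.
#' @param pixel_size Pixel size (µm).
#' @return List: `area_um2`, `n_pixels`, `threshold`, `flagged` (logical),
#'   `mask` of the largest component.
#' @export
otsu_area <- function(frame, pixel_size) {
  rng <- range(frame)
  if (diff(rng) <= 0)
    return(list(area_um2 = NA_real_, n_pixels = 0L, threshold = NA_real_,
                flagged = TRUE, mask = NULL))
  norm <- (frame - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > th
  frac <- mean(mask)
  flagged <- frac < 0.001 || frac > 0.999
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  if (max(lab) == 0)
    return(list(area_um2 = NA_real_, n_pixels = 0L,
                threshold = th * diff(rng) + rng[1], flagged = TRUE,
                mask = NULL))
  sizes <- tabulate(lab[lab > 0])
  k <- which.max(sizes)
  list(area_um2 = sizes[k] * pixel_size^2, n_pixels = sizes[k],
       threshold = th * diff(rng) + rng[1], flagged = flagged,
       mask = lab == k)
}
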