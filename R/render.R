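#' Render trajectories into a synthetic image stack
#'
#' Each localization is rendered as an isotropic 2D Gaussian spot of
#' integrated intensity `photons`. When the trajectories carry sub-frame
#' positions (simulated with `subframe_steps > 1`), motion blur is emulated
#' by averaging the renderings of the sub-positions within each frame.
#' Poisson photon noise and Gaussian read noise are added unless disabled.
#'
#' @param trajectories Trajectory `data.frame` (µm coordinates).
#' @param optics List with `psf_sd_px` (Gaussian PSF s.d., pixels),
#'   `photons` (> 0), `background` (photons/pixel) and `camera_noise_sd`
#'   (read-noise s.d.).
#' @param pixel_size Pixel size in µm (default 0.117).
#' @param dims `c(ny, nx)` image size in pixels; computed from the data
#'   extent when `NULL`.
#' @param n_frames Number of frames; defaults to the maximum frame index.
#' @param noise Logical; add Poisson + Gaussian noise (default `TRUE`).
#' @param seed Integer seed for the noise.
#' @return Numeric array `(ny, nx, n_frames)` of class `"image_stack"` with
#'   attributes `pixel_size` and `frame_interval` (when known). Pixel
#'   centers sit at integer coordinates: a point at `x_um` falls on pixel
#'   column `round(x_um / pixel_size) + 1`.
#' @export
render_video <- function(trajectories,
                         optics = list(psf_sd_px = 1.3, photons = 500,
                                       background = 10, camera_noise_sd = 2),
                         pixel_size = 0.117, dims = NULL, n_frames = NULL,
                         noise = TRUE, seed = 1L) {
  if (optics$photons <= 0) stop("photons must be > 0")
  pts <- attr(trajectories, "subpositions")
  if (is.null(pts)) pts <- trajectories[, c("trajectory_id", "frame",
                                            "x_um", "y_um")]
  xp <- pts$x_um / pixel_size
  yp <- pts$y_um / pixel_size
  if (is.null(n_frames))
    n_frames <- max(trajectories$frame)
  if (is.null(dims)) {
    dims <- c(ceiling(max(yp, 0)) + 4L, ceiling(max(xp, 0)) + 4L)
  }
  ny <- dims[1]; nx <- dims[2]
  # per-frame weight: sub-positions share the frame's photon budget
  nsub <- table(paste(pts$trajectory_id, pts$frame))
  w <- optics$photons / as.numeric(nsub[paste(pts$trajectory_id, pts$frame)])
  sd <- optics$psf_sd_px
  half <- ceiling(4 * sd)
  stack <- array(optics$background, dim = c(ny, nx, n_frames))
  for (i in seq_len(nrow(pts))) {
    f <- pts$frame[i]
    if (f < 1 || f > n_frames) next
    cx <- xp[i] + 1; cy <- yp[i] + 1      # pixel-center convention
    xs <- max(1, floor(cx - half)):min(nx, ceiling(cx + half))
    ys <- max(1, floor(cy - half)):min(ny, ceiling(cy + half))
    if (!length(xs) || !length(ys)) next
    gx <- exp(-(xs - cx)^2 / (2 * sd^2))
    gy <- exp(-(ys - cy)^2 / (2 * sd^2))
    spot <- (w[i] / (2 * pi * sd^2)) * outer(gy, gx)
    stack[ys, xs, f] <- stack[ys, xs, f] + spot
  }
  if (noise) {
    set.seed(as.integer(seed))
    n <- length(stack)
    stack[] <- stats::rpois(n, stack) +
      stats::rnorm(n, 0, optics$camera_noise_sd)
  }
  structure(stack, class = "image_stack", pixel_size = pixel_size)
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Intensities are clipped to `[0, 65535]` and stored as 16-bit.
#'
#' @param stack Numeric array `(ny, nx, t)`.
#' @param path Output file.
#' @export
write_image_stack <- function(stack, path) {
  frames <- lapply(seq_len(dim(stack)[3]), function(t) {
    m <- stack[, , t]
    pmin(pmax(m, 0), 65535) / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' @param path TIFF file.
#' @param pixel_size Pixel size in µm to attach (default 0.117).
#' @return Numeric array `(ny, nx, t)` of class `"image_stack"`, rescaled
#'   back to 16-bit counts.
#' @export
read_image_stack <- function(path, pixel_size = 0.117) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  stack <- array(0, dim = c(dim(frames[[1]])[1], dim(frames[[1]])[2],
                            length(frames)))
  for (t in seq_along(frames)) stack[, , t] <- frames[[t]] * 65535
  structure(stack, class = "image_stack", pixel_size = pixel_size)
}
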