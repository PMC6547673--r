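#' Render a fluorescence time-lapse stack from trajectories
#'
#' Draws each spheroid as a 2D Gaussian blob whose full width at half
#' maximum equals its diameter (so the half-maximum footprint of the
#' rendered spot recovers the physical size), adds Poisson photon noise on
#' top of a constant background, and returns a 16-bit count stack. One
#' field of view per call.
#'
#' @param trajectories Trajectory table (shared schema) for a single field.
#' @param fov_x_um,fov_y_um Field extents (um).
#' @param n_frames Number of frames to render (frames `0:(n_frames-1)`).
#' @param pixel_size_um Pixel size (um per pixel). Default 3.25 um
#'   (a 4x objective with 2x2 camera binning), putting a 70 um spheroid at
#'   ~22 px across.
#' @param blob_peak Peak signal counts of a spheroid above background.
#' @param background Mean background counts per pixel.
#' @param seed Seed for the photon noise.
#' @return Integer array `[ny, nx, n_frames]` of class `image_stack` with
#'   attributes `pixel_size_um` and `frame_interval_s` (1 s).
#' @export
render_image_stack <- function(trajectories, fov_x_um = 3300,
                               fov_y_um = 2500, n_frames = 30,
                               pixel_size_um = 3.25,
                               blob_peak = 20000, background = 200,
                               seed = 1) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive",
                               call. = FALSE)
  if (nrow(trajectories) > 0 &&
      any(trajectories$diameter_um / pixel_size_um < 2))
    stop("spheroid smaller than 2 px at this pixel size; ",
         "rendering resolution too coarse", call. = FALSE)
  nx <- as.integer(ceiling(fov_x_um / pixel_size_um))
  ny <- as.integer(ceiling(fov_y_um / pixel_size_um))
  withr::with_seed(seed, {
    stack <- array(0L, dim = c(ny, nx, n_frames))
    for (f in seq_len(n_frames)) {
      frame0 <- f - 1L
      signal <- matrix(0, ny, nx)
      rows <- trajectories[trajectories$frame == frame0, , drop = FALSE]
      if (nrow(rows) > 0) {
        for (i in seq_len(nrow(rows))) {
          cx <- rows$x_um[i] / pixel_size_um + 0.5
          cy <- rows$y_um[i] / pixel_size_um + 0.5
          sigma <- rows$diameter_um[i] / (2 * sqrt(2 * log(2))) /
            pixel_size_um
          r <- ceiling(3.5 * sigma)
          xi <- max(1, floor(cx - r)):min(nx, ceiling(cx + r))
          yi <- max(1, floor(cy - r)):min(ny, ceiling(cy + r))
          if (length(xi) == 0 || length(yi) == 0) next
          gx <- exp(-(xi - cx)^2 / (2 * sigma^2))
          gy <- exp(-(yi - cy)^2 / (2 * sigma^2))
          signal[yi, xi] <- signal[yi, xi] + blob_peak * outer(gy, gx)
        }
      }
      counts <- stats::rpois(ny * nx, lambda = as.vector(background + signal))
      counts[counts > 65535] <- 65535L
      stack[, , f] <- as.integer(counts)
    }
    structure(stack, pixel_size_um = pixel_size_um, frame_interval_s = 1,
              class = "image_stack")
  })
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' A JSON sidecar (`<path>.json`) records the pixel size and frame
#' interval so the stack is self-describing on re-ingestion.
#'
#' @param stack An `image_stack` (or plain `[ny, nx, n_frames]` array of
#'   counts in 0..65535).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path) {
  n_frames <- dim(stack)[3]
  pages <- lapply(seq_len(n_frames),
                  function(f) unclass(stack)[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16,
                  compression = "none")
  meta <- list(pixel_size_um = attr(stack, "pixel_size_um"),
               frame_interval_s = attr(stack, "frame_interval_s"),
               n_frames = n_frames)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a multi-page TIFF stack written by [write_tiff_stack()]
#'
#' @param path TIFF path; pixel size and frame interval are taken from the
#'   JSON sidecar if present, else from the arguments.
#' @param pixel_size_um,frame_interval_s Calibration fallbacks when no
#'   sidecar exists; an error is raised if the pixel size is unknown.
#' @return An `image_stack` array of counts.
#' @export
read_tiff_stack <- function(path, pixel_size_um = NULL,
                            frame_interval_s = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
    if (is.null(frame_interval_s)) frame_interval_s <- meta$frame_interval_s
  }
  if (is.null(pixel_size_um))
    stop("pixel size calibration missing (no sidecar and no argument)",
         call. = FALSE)
  if (is.null(frame_interval_s)) frame_interval_s <- 1
  stack <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                             length(pages)))
  for (f in seq_along(pages))
    stack[, , f] <- as.integer(round(pages[[f]] * 65535))
  structure(stack, pixel_size_um = pixel_size_um,
            frame_interval_s = frame_interval_s, class = "image_stack")
}
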