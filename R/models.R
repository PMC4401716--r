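#' Optical model of the point-spread function
#'
#' Describes the microscope PSF as a circular 2D Gaussian whose standard
#' deviation grows with defocus following the Gaussian-beam law
#' \eqn{\sigma(z) = \sigma_0 \sqrt{1 + (z/z_R)^2}}. The in-focus width
#' `sigma0` defaults to 175 nm, typical of green-emitting beads on a
#' high-NA oil objective; `z_r` sets how fast the PSF blurs with defocus.
#'
#' @param sigma0 In-focus PSF standard deviation, nm. Must be positive.
#' @param z_r Defocus depth scale, nm. Must be positive.
#' @param wavelength_tag Free-text label of the emission band; carried as
#'   metadata only, never used in computation.
#' @return An object of class `optics_model`.
#' @examples
#' op <- optics_model()
#' psf_sigma_at_z(c(-400, 0, 400), op)
#' @export
optics_model <- function(sigma0 = 175, z_r = 400, wavelength_tag = "505nm") {
  stopifnot(is.numeric(sigma0), length(sigma0) == 1L, is.finite(sigma0), sigma0 > 0,
            is.numeric(z_r), length(z_r) == 1L, is.finite(z_r), z_r > 0)
  structure(list(sigma0 = sigma0, z_r = z_r, wavelength_tag = wavelength_tag),
            class = "optics_model")
}

#' Camera model
#'
#' Pixel geometry and noise properties of the detector. Conversion gain is
#' expressed in photons per camera count (ADU); the EM excess factor models
#' the variance doubling of electron-multiplying cameras (1 = none, 2 =
#' typical EMCCD).
#'
#' @param pixel_size Pixel size in the sample plane, nm.
#' @param photons_per_count Conversion gain, photons/ADU.
#' @param read_noise Gaussian read noise, counts rms.
#' @param baseline Camera offset added to every pixel, counts.
#' @param em_excess_factor Multiplicative excess-noise variance factor,
#'   >= 1.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(pixel_size = 100, photons_per_count = 1,
                         read_noise = 1, baseline = 100,
                         em_excess_factor = 2) {
  stopifnot(pixel_size > 0, photons_per_count > 0, read_noise >= 0,
            baseline >= 0, em_excess_factor >= 1)
  structure(list(pixel_size = pixel_size,
                 photons_per_count = photons_per_count,
                 read_noise = read_noise, baseline = baseline,
                 em_excess_factor = em_excess_factor),
            class = "camera_model")
}

#' PSF width at a given defocus
#'
#' @param z Axial position(s) relative to the focal plane, nm.
#' @param optics An [optics_model()].
#' @return PSF standard deviation(s) in nm; `sigma0` at `z = 0`, even in
#'   `z` and strictly increasing in `|z|`.
#' @export
psf_sigma_at_z <- function(z, optics = optics_model()) {
  stopifnot(inherits(optics, "optics_model"))
  optics$sigma0 * sqrt(1 + (z / optics$z_r)^2)
}

#' Image stack container
#'
#' A list of equally-shaped 2D frames (camera counts) plus the camera model
#' and, for calibration z-stacks, the stage position of every frame and the
#' ground-truth emitter table produced by the simulator.
#'
#' @param frames List of numeric matrices, all of the same dimensions.
#' @param camera A [camera_model()].
#' @param z_per_frame Optional numeric vector of stage z positions (nm),
#'   one per frame.
#' @param truth Optional ground-truth emitter `data.frame`
#'   (columns `id, x_nm, y_nm, z_nm, photons`, optionally `on_frames`).
#' @param optics Optional [optics_model()] recorded as provenance.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, camera, z_per_frame = NULL, truth = NULL,
                        optics = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L,
            inherits(camera, "camera_model"))
  dims <- dim(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), dims),
               logical(1))
  if (!all(ok)) stop("all frames must be matrices of identical dimensions")
  if (!is.null(z_per_frame) && length(z_per_frame) != length(frames))
    stop("z_per_frame must have one entry per frame")
  structure(list(frames = frames, camera = camera,
                 z_per_frame = z_per_frame, truth = truth, optics = optics),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %d x %d px (%g nm/px)\n",
              length(x$frames), d[1], d[2], x$camera$pixel_size))
  if (!is.null(x$z_per_frame))
    cat(sprintf("  calibration stack, z in [%g, %g] nm\n",
                min(x$z_per_frame), max(x$z_per_frame)))
  if (!is.null(x$truth))
    cat(sprintf("  ground truth: %d emitters\n", nrow(x$truth)))
  invisible(x)
}

# photon-unit view of a counts frame
frame_to_photons <- function(frame, camera) {
  (frame - camera$baseline) * camera$photons_per_count
}
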