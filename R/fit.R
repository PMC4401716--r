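# Spot detection and five-parameter 2D Gaussian fitting.
#
# Amplitude unit convention: the fitted peak height above offset, in
# photons/pixel, divided by the pixel area in um^2, giving photons/um^2.
# Thresholds quoted in the field (order 1,500-2,200 photons/um^2 at 100 nm
# pixels) are in exactly these units. The offset is excluded from the peak.

# separable Gaussian blur via banded Toeplitz multiplication
smooth_kernel_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, 0, sigma)
  M <- matrix(0, n, n)
  idx <- seq_len(n)
  for (d in -r:r) {
    ok <- idx + d >= 1 & idx + d <= n
    M[cbind(idx[ok], (idx + d)[ok])] <- k[d + r + 1]
  }
  M / rowSums(M)
}

gaussian_smooth <- function(img, sigma = 1) {
  Ky <- smooth_kernel_matrix(nrow(img), sigma)
  Kx <- smooth_kernel_matrix(ncol(img), sigma)
  Ky %*% img %*% t(Kx)
}

local_maxima <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  p <- matrix(-Inf, ny + 2, nx + 2)
  p[2:(ny + 1), 2:(nx + 1)] <- m
  res <- matrix(TRUE, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    res <- res & (m >= p[(2:(ny + 1)) + dy, (2:(nx + 1)) + dx])
  }
  res
}

#' Detect candidate emitters in a frame
#'
#' Local maxima of a Gaussian-smoothed frame exceeding the robust
#' background (median) by `min_snr` robust noise standard deviations
#' (MAD), thinned so that no two candidates are closer than
#' `min_separation_px` (greedy, brightest first). Deterministic given the
#' frame.
#'
#' @param frame Numeric matrix of camera counts.
#' @param camera A [camera_model()].
#' @param min_snr Detection threshold in smoothed-noise sigmas. The
#'   default of 4 keeps the expected number of false maxima per frame well
#'   below one.
#' @param min_separation_px Minimum candidate separation, pixels.
#' @param smooth_sigma_px Smoothing kernel sigma, pixels.
#' @return `data.frame` with integer `row`, `col` and the smoothed `value`;
#'   zero rows when nothing is found.
#' @export
detect_spots <- function(frame, camera = camera_model(), min_snr = 4,
                         min_separation_px = 5, smooth_sigma_px = 1) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  img <- frame_to_photons(frame, camera)
  sm <- gaussian_smooth(img, smooth_sigma_px)
  bg <- stats::median(sm)
  nsd <- stats::mad(sm)
  thr <- bg + min_snr * nsd
  cand <- which(local_maxima(sm) & sm > thr, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(row = integer(0), col = integer(0), value = numeric(0)))
  vals <- sm[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    sel <- which(keep)
    d2 <- (cand[sel, 1] - cand[i, 1])^2 + (cand[sel, 2] - cand[i, 2])^2
    if (all(d2 >= min_separation_px^2)) keep[i] <- TRUE
  }
  data.frame(row = as.integer(cand[keep, 1]), col = as.integer(cand[keep, 2]),
             value = vals[keep])
}

empty_localizations <- function() {
  data.frame(frame = integer(0), x_nm = numeric(0), y_nm = numeric(0),
             sigma_nm = numeric(0), amplitude_photons_um2 = numeric(0),
             offset_photons = numeric(0), intensity_photons = numeric(0),
             precision_nm = numeric(0), fit_ok = logical(0))
}

#' Fit a five-parameter 2D Gaussian to one candidate spot
#'
#' Least-squares fit of
#' \eqn{f(px,py) = A \exp(-((px-x_0)^2 + (py-y_0)^2)/(2 s^2)) + B}
#' over a square region of interest around the candidate, in photon units.
#' Returns the localization in calibrated units: centre in nm (pixel
#' `(0,0)` spans `[0, pixel)^2`), width = the Gaussian standard deviation
#' in nm, amplitude as peak photon surface density (photons/um^2,
#' offset-excluded), integrated intensity \eqn{2\pi A s^2} photons, and the
#' theoretical localization precision (see [localization_precision()],
#' with the fitted offset as the background variance).
#'
#' `fit_ok` is `FALSE` when the optimizer fails, the fitted peak is not
#' positive, the fitted width leaves `(0.5, 10) * expected_sigma_px`
#' (no single emitter can appear narrower than half the in-focus PSF), or
#' the centre leaves the region of interest. A region that touches the
#' frame edge is shrunk to fit. When no explicit `roi_halfwidth_px` is
#' given and the fitted width approaches the region half-width, the fit
#' is repeated with a larger region so that defocused PSFs are not
#' clipped into degenerate width/offset estimates.
#'
#' @param frame Numeric matrix of camera counts.
#' @param candidate List or one-row `data.frame` with `row`, `col` (integer
#'   pixel position from [detect_spots()]).
#' @param camera A [camera_model()].
#' @param roi_halfwidth_px Half-width of the fit region; default
#'   `ceiling(3 * expected_sigma_px)`.
#' @param expected_sigma_px Expected in-focus PSF sigma in pixels (used for
#'   the start value and the width sanity band).
#' @param frame_index Value stored in the `frame` column.
#' @return One-row localization `data.frame`.
#' @export
fit_gaussian2d <- function(frame, candidate, camera = camera_model(),
                           roi_halfwidth_px = NULL,
                           expected_sigma_px = 1.75, frame_index = NA_integer_) {
  adaptive <- is.null(roi_halfwidth_px)
  if (adaptive) roi_halfwidth_px <- ceiling(3 * expected_sigma_px)
  h <- as.integer(roi_halfwidth_px)
  h_max <- 3L * h
  repeat {
    out <- fit_gaussian2d_once(frame, candidate, camera, h,
                               expected_sigma_px, frame_index)
    s_px <- out$sigma_nm / camera$pixel_size
    # a width comparable to the region half-width means the region clipped
    # the PSF and the width/offset estimates are degenerate: refit larger
    if (!adaptive || !isTRUE(out$fit_ok) || is.na(s_px) ||
        s_px <= 0.55 * h || h >= h_max) return(out)
    h <- min(h_max, as.integer(ceiling(3.5 * s_px)))
  }
}

fit_gaussian2d_once <- function(frame, candidate, camera, h,
                                expected_sigma_px, frame_index) {
  r0 <- max(1L, candidate$row - h); r1 <- min(nrow(frame), candidate$row + h)
  c0 <- max(1L, candidate$col - h); c1 <- min(ncol(frame), candidate$col + h)
  roi <- frame_to_photons(frame[r0:r1, c0:c1, drop = FALSE], camera)
  bad <- function() {
    out <- empty_localizations()[0, ]
    out[1, ] <- list(frame_index, NA_real_, NA_real_, NA_real_, NA_real_,
                     NA_real_, NA_real_, NA_real_, FALSE)
    out
  }
  if (stats::var(as.vector(roi)) == 0) return(bad())
  dd <- data.frame(px = rep(c0:c1, each = nrow(roi)),
                   py = rep(r0:r1, times = ncol(roi)),
                   z = as.vector(roi))
  border <- roi[c(1, nrow(roi)), , drop = FALSE]
  B0 <- stats::median(c(border, roi[, c(1, ncol(roi))]))
  A0 <- max(roi) - B0
  if (A0 <= 0) A0 <- max(1e-3, max(roi) - min(roi))
  fit <- suppressWarnings(try(minpack.lm::nlsLM(
    z ~ A * exp(-((px - x0)^2 + (py - y0)^2) / (2 * s^2)) + B,
    data = dd,
    start = list(A = A0, x0 = candidate$col, y0 = candidate$row,
                 s = expected_sigma_px, B = B0),
    control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE))
  if (inherits(fit, "try-error")) return(bad())
  cf <- stats::coef(fit)
  A <- cf[["A"]]; x0 <- cf[["x0"]]; y0 <- cf[["y0"]]
  s <- abs(cf[["s"]]); B <- cf[["B"]]
  converged <- !isFALSE(fit$convInfo$isConv)
  # lower width bound 0.5x the diffraction-limited width: no single
  # emitter can fit narrower; such fits are noise spikes on a pedestal
  ok <- converged && is.finite(A) && is.finite(s) && A > 0 &&
    s > 0.5 * expected_sigma_px && s < 10 * expected_sigma_px &&
    x0 >= c0 - 1 && x0 <= c1 + 1 && y0 >= r0 - 1 && y0 <= r1 + 1
  px_nm <- camera$pixel_size
  intensity <- A * 2 * pi * s^2
  prec <- if (ok && intensity > 0)
    localization_precision(s * px_nm, intensity, max(B, 0), px_nm)
  else NA_real_
  out <- empty_localizations()[0, ]
  out[1, ] <- list(frame_index, (x0 - 0.5) * px_nm, (y0 - 0.5) * px_nm,
                   s * px_nm, amplitude_to_photon_density(A, px_nm),
                   B, intensity, prec, ok)
  out
}

#' Detect and fit all spots of one frame
#'
#' After fitting, converged localizations whose centres fall within
#' `min_separation_px` pixels of a brighter one are dropped: a strongly
#' defocused PSF can seed several detection maxima whose fits collapse
#' onto the same emitter, and such duplicates would inflate counts.
#'
#' @inheritParams detect_spots
#' @inheritParams fit_gaussian2d
#' @return Localization `data.frame`, one row per retained candidate.
#' @export
fit_frame <- function(frame, camera = camera_model(), min_snr = 4,
                      min_separation_px = 5, roi_halfwidth_px = NULL,
                      expected_sigma_px = 1.75, frame_index = NA_integer_) {
  cand <- detect_spots(frame, camera, min_snr, min_separation_px)
  if (nrow(cand) == 0) return(empty_localizations())
  out <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
    fit_gaussian2d(frame, cand[i, ], camera, roi_halfwidth_px,
                   expected_sigma_px, frame_index)))
  ok <- which(out$fit_ok & is.finite(out$x_nm) & is.finite(out$y_nm))
  if (length(ok) > 1) {
    min_sep_nm <- min_separation_px * camera$pixel_size
    ord <- ok[order(-out$intensity_photons[ok])]
    keep <- logical(0)
    drop <- integer(0)
    for (i in ord) {
      if (length(keep)) {
        # merge radius grows with the brighter fit's width: a defocused
        # PSF cannot host two resolvable emitters within ~1.5 sigma
        rad <- pmax(min_sep_nm, 1.5 * out$sigma_nm[keep])
        if (any((out$x_nm[keep] - out$x_nm[i])^2 +
                  (out$y_nm[keep] - out$y_nm[i])^2 < rad^2)) {
          drop <- c(drop, i)
          next
        }
      }
      keep <- c(keep, i)
    }
    if (length(drop)) out <- out[-drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Fit every frame of a stack
#'
#' Runs [detect_spots()] and [fit_gaussian2d()] on all frames and
#' concatenates the results. For calibration stacks with `z_per_frame` the
#' ground-truth axial position of every localization (the stage position
#' of its frame) is attached as `true_z_nm`.
#'
#' @param stack A [frame_stack()].
#' @inheritParams fit_frame
#' @return Localization `data.frame`.
#' @export
fit_stack <- function(stack, min_snr = 4, min_separation_px = 5,
                      roi_halfwidth_px = NULL, expected_sigma_px = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(expected_sigma_px)) {
    expected_sigma_px <- if (!is.null(stack$optics))
      stack$optics$sigma0 / stack$camera$pixel_size else 1.75
  }
  tabs <- lapply(seq_along(stack$frames), function(f)
    fit_frame(stack$frames[[f]], stack$camera, min_snr, min_separation_px,
              roi_halfwidth_px, expected_sigma_px, frame_index = f))
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  if (!is.null(stack$z_per_frame) && nrow(out) > 0)
    out$true_z_nm <- stack$z_per_frame[out$frame]
  out
}

#' Theoretical localization precision (least-squares Gaussian fitting)
#'
#' Standard error of a fitted emitter position for a pixelated detector
#' with Gaussian-distributed background, after Mortensen and colleagues'
#' least-squares result: with \eqn{\sigma_a^2 = \sigma^2 + a^2/12},
#' \deqn{\mathrm{var}(x) = \frac{\sigma_a^2}{N}\left(\frac{16}{9} +
#'   \frac{8\pi\sigma_a^2 b^2}{N a^2}\right),}
#' where \eqn{N} is the photon count, \eqn{a} the pixel size and
#' \eqn{b^2} the background variance per pixel in photons.
#'
#' @param width_nm Fitted PSF standard deviation, nm (> 0).
#' @param photons Detected photons (> 0).
#' @param background_var_photons Background variance per pixel, photons^2
#'   (for Poisson background equal to its mean level).
#' @param pixel_size_nm Pixel size, nm.
#' @return Precision in nm (vectorized); strictly decreasing in `photons`.
#' @examples
#' localization_precision(175, 1000, 0, 100) # ~7.48 nm
#' @export
localization_precision <- function(width_nm, photons,
                                   background_var_photons = 0,
                                   pixel_size_nm = 100) {
  if (any(!is.finite(photons)) || any(photons <= 0))
    stop("photons must be positive")
  stopifnot(all(width_nm > 0), pixel_size_nm > 0,
            all(background_var_photons >= 0))
  sa2 <- width_nm^2 + pixel_size_nm^2 / 12
  v <- (sa2 / photons) *
    (16 / 9 + 8 * pi * sa2 * background_var_photons /
       (photons * pixel_size_nm^2))
  sqrt(v)
}

#' Convert a fitted peak height to photon surface density
#'
#' @param peak_amplitude_photons_per_pixel Peak height above offset,
#'   photons/pixel.
#' @param pixel_size_nm Pixel size, nm (> 0).
#' @return Peak surface density in photons/um^2
#'   (`peak / (pixel_size_um)^2`).
#' @examples
#' amplitude_to_photon_density(15, 100) # 1500
#' @export
amplitude_to_photon_density <- function(peak_amplitude_photons_per_pixel,
                                        pixel_size_nm) {
  stopifnot(pixel_size_nm > 0)
  peak_amplitude_photons_per_pixel / (pixel_size_nm / 1000)^2
}
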