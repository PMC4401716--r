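# Calibration of the virtual light-sheet: from a labeled bead z-stack to
# width and amplitude thresholds with known confidence and recall.

#' Link per-frame localizations into bead traces
#'
#' Reconstructs per-bead axial traces from the localizations of a
#' calibration stack: a localization joins the trace whose running mean
#' lateral position lies within `link_radius_nm`; localizations at each z
#' step are averaged per bead. Traces covering fewer than
#' `min_coverage` of the z steps are discarded. If two traces ever come
#' within `link_radius_nm` of each other (or a localization matches more
#' than one trace) both are discarded with a warning, as their
#' memberships are ambiguous.
#'
#' When the originating `stack` is supplied, the background-subtracted
#' integrated intensity of a fixed box centred on the bead (half-width
#' `box_halfwidth_px`) is computed for every z step, averaged over the
#' frames of the step; this is the signal used to locate the focal plane.
#'
#' @param localizations Localization `data.frame` (only `fit_ok` rows are
#'   used) with a `frame` column.
#' @param z_per_frame Stage z position per frame, nm.
#' @param link_radius_nm Linking radius, nm.
#' @param stack Optional [frame_stack()] for boxed intensities.
#' @param box_halfwidth_px Integration box half-width in pixels; default
#'   `ceiling(1.5 * sigma0 / pixel)` (box side about 3 in-focus sigmas),
#'   a box matched to the PSF core so that defocus moves photons out of it.
#' @param min_coverage Minimum fraction of z steps a trace must cover.
#' @return List of `bead_trace` objects, each with `bead_id`, `x_nm`,
#'   `y_nm` (mean position) and a `steps` `data.frame` (per-z mean fitted
#'   parameters, localization count and `boxed_intensity`).
#' @export
link_beads <- function(localizations, z_per_frame, link_radius_nm = 500,
                       stack = NULL, box_halfwidth_px = NULL,
                       min_coverage = 0.5) {
  stopifnot(!is.null(z_per_frame))
  locs <- localizations[localizations$fit_ok &
                          is.finite(localizations$x_nm) &
                          is.finite(localizations$y_nm), , drop = FALSE]
  z_steps <- unique(z_per_frame)
  step_of_frame <- match(z_per_frame, z_steps)
  n_tr <- 0L
  mx <- numeric(0); my <- numeric(0); cnt <- integer(0)
  ambiguous <- logical(0)
  member <- integer(nrow(locs))
  for (f in sort(unique(locs$frame))) {
    rows <- which(locs$frame == f)
    claimed <- integer(0)
    for (i in rows) {
      if (n_tr > 0) {
        d2 <- (mx / cnt - locs$x_nm[i])^2 + (my / cnt - locs$y_nm[i])^2
        hits <- which(d2 <= link_radius_nm^2)
      } else hits <- integer(0)
      if (length(hits) >= 2) ambiguous[hits] <- TRUE
      if (length(hits) >= 1) {
        t <- hits[which.min(d2[hits])]
        if (t %in% claimed) ambiguous[t] <- TRUE
        claimed <- c(claimed, t)
        mx[t] <- mx[t] + locs$x_nm[i]; my[t] <- my[t] + locs$y_nm[i]
        cnt[t] <- cnt[t] + 1L
        member[i] <- t
      } else {
        n_tr <- n_tr + 1L
        mx <- c(mx, locs$x_nm[i]); my <- c(my, locs$y_nm[i])
        cnt <- c(cnt, 1L); ambiguous <- c(ambiguous, FALSE)
        member[i] <- n_tr
      }
    }
  }
  if (n_tr == 0) return(list())
  # final proximity check between trace means; only traces with real
  # coverage count as beads (one-off spurious detections are not beads)
  cx <- mx / cnt; cy <- my / cnt
  n_steps_covered <- vapply(seq_len(n_tr), function(t)
    length(unique(step_of_frame[locs$frame[member == t]])), integer(1))
  is_bead <- n_steps_covered >= min_coverage * length(z_steps)
  beads <- which(is_bead)
  if (length(beads) >= 2) {
    for (ai in seq_len(length(beads) - 1)) for (bi in (ai + 1):length(beads)) {
      a <- beads[ai]; b <- beads[bi]
      if ((cx[a] - cx[b])^2 + (cy[a] - cy[b])^2 <= link_radius_nm^2)
        ambiguous[c(a, b)] <- TRUE
    }
  }
  if (any(ambiguous))
    warning(sprintf("%d trace(s) discarded as ambiguous (beads closer than the link radius)",
                    sum(ambiguous)))
  param_cols <- intersect(c("x_nm", "y_nm", "sigma_nm",
                            "amplitude_photons_um2", "offset_photons",
                            "intensity_photons", "precision_nm"),
                          names(locs))
  if (is.null(box_halfwidth_px)) {
    s0_px <- if (!is.null(stack) && !is.null(stack$optics))
      stack$optics$sigma0 / stack$camera$pixel_size else 1.75
    box_halfwidth_px <- ceiling(1.5 * s0_px)
  }
  traces <- list()
  for (t in seq_len(n_tr)) {
    if (ambiguous[t]) next
    rows <- which(member == t)
    steps_here <- step_of_frame[locs$frame[rows]]
    if (length(unique(steps_here)) < min_coverage * length(z_steps)) next
    agg <- data.frame(z = z_steps)
    for (cc in param_cols)
      agg[[cc]] <- vapply(seq_along(z_steps), function(s) {
        v <- locs[[cc]][rows[steps_here == s]]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
    agg$n_locs <- vapply(seq_along(z_steps), function(s)
      sum(steps_here == s), integer(1))
    if (!is.null(stack)) {
      agg$boxed_intensity <- boxed_intensity_profile(
        stack, cx[t], cy[t], box_halfwidth_px, step_of_frame,
        length(z_steps))
    }
    traces[[length(traces) + 1]] <-
      structure(list(bead_id = length(traces) + 1L, x_nm = cx[t],
                     y_nm = cy[t], steps = agg), class = "bead_trace")
  }
  traces
}

# per-step mean of background-subtracted box sums around (x, y)
boxed_intensity_profile <- function(stack, x_nm, y_nm, h, step_of_frame,
                                    n_steps) {
  cam <- stack$camera
  col0 <- round(x_nm / cam$pixel_size + 0.5)
  row0 <- round(y_nm / cam$pixel_size + 0.5)
  vals <- vapply(seq_along(stack$frames), function(f) {
    fr <- frame_to_photons(stack$frames[[f]], cam)
    r <- max(1, row0 - h):min(nrow(fr), row0 + h)
    cc <- max(1, col0 - h):min(ncol(fr), col0 + h)
    sum(fr[r, cc]) - length(r) * length(cc) * stats::median(fr)
  }, numeric(1))
  vapply(seq_len(n_steps), function(s) mean(vals[step_of_frame == s]),
         numeric(1))
}

#' Locate the focal plane of one bead trace
#'
#' The focal plane is the z step at which the boxed integrated intensity
#' of the PSF is highest. Ties are broken toward the median step index.
#'
#' @param trace A `bead_trace` from [link_beads()] (needs
#'   `boxed_intensity`).
#' @return Integer index into `trace$steps`.
#' @export
find_focal_plane <- function(trace) {
  bi <- trace$steps$boxed_intensity
  if (is.null(bi)) stop("trace has no boxed_intensity (link with stack =)")
  if (diff(range(bi)) == 0) stop("no focus found: boxed intensity is constant")
  idx <- which(bi == max(bi))
  med <- (length(bi) + 1) / 2
  idx[which.min(abs(idx - med))]
}

#' Fit the axial intensity profile with a Gaussian
#'
#' Per-bead boxed-intensity profiles are normalized to unit peak, averaged
#' across beads, and fitted with a 1D Gaussian plus baseline by
#' least squares. The fitted centre defines the focal plane position
#' `z0`; the full width at half maximum is `2 sqrt(2 ln 2) * sigma_ax`
#' exactly.
#'
#' @param traces List of `bead_trace` objects sharing a z grid, or a
#'   `data.frame` with columns `z` and `intensity` (a single ready-made
#'   profile).
#' @return An `axial_profile` object: `z_centers`, `mean_value`,
#'   `sd_value`, fit parameters (`z0`, `sigma_ax`, `amplitude`,
#'   `baseline`) and `fwhm`.
#' @export
fit_axial_profile <- function(traces) {
  if (is.data.frame(traces)) {
    z <- traces$z
    M <- matrix(traces$intensity, nrow = 1)
  } else {
    stopifnot(length(traces) >= 1)
    z <- traces[[1]]$steps$z
    for (tr in traces)
      if (!isTRUE(all.equal(tr$steps$z, z)))
        stop("traces do not share a common z grid")
    M <- do.call(rbind, lapply(traces, function(tr) tr$steps$boxed_intensity))
  }
  M <- M / apply(M, 1, max, na.rm = TRUE)
  mean_value <- colMeans(M, na.rm = TRUE)
  sd_value <- apply(M, 2, function(v) if (sum(is.finite(v)) > 1) stats::sd(v, na.rm = TRUE) else 0)
  dd <- data.frame(z = z, y = mean_value)
  rng <- diff(range(z))
  # moment-based starts; sigma is bounded above because a profile flatter
  # than the scanned range carries no width information (the fit would
  # otherwise degenerate into an amplitude/baseline trade-off)
  w0 <- pmax(dd$y - stats::quantile(dd$y, 0.1), 0)
  z0_start <- if (sum(w0) > 0) sum(w0 * z) / sum(w0) else z[which.max(dd$y)]
  s_lo <- min(diff(sort(unique(z)))) / 2
  s_hi <- 2 * rng
  s_start <- min(max(sqrt(sum(w0 * (z - z0_start)^2) / max(sum(w0), 1e-12)),
                     s_lo), s_hi)
  par0 <- c(a = max(dd$y) - min(dd$y), z0 = z0_start, s = s_start,
            b = min(dd$y))
  resid_fn <- function(p) p[1] * exp(-(z - p[2])^2 / (2 * p[3]^2)) +
    p[4] - dd$y
  fit <- try(minpack.lm::nls.lm(
    par = par0, fn = resid_fn,
    lower = c(0, min(z) - rng, s_lo, -Inf),
    upper = c(Inf, max(z) + rng, s_hi, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error") || !(fit$info %in% 1:4)) {
    cond <- simpleError("axial profile Gaussian fit did not converge")
    cond$profile <- dd
    stop(cond)
  }
  cf <- fit$par
  names(cf) <- names(par0)
  s_ax <- abs(cf[["s"]])
  structure(list(z_centers = z, mean_value = mean_value,
                 sd_value = sd_value, z0 = cf[["z0"]], sigma_ax = s_ax,
                 amplitude = cf[["a"]], baseline = cf[["b"]],
                 fwhm = 2 * sqrt(2 * log(2)) * s_ax),
            class = "axial_profile")
}

#' @export
print.axial_profile <- function(x, ...) {
  cat(sprintf("<axial_profile> z0 = %.1f nm, sigma = %.1f nm, FWHM = %.1f nm (%d steps)\n",
              x$z0, x$sigma_ax, x$fwhm, length(x$z_centers)))
  invisible(x)
}

#' Define the virtual light-sheet bounds
#'
#' The acceptance volume is a slab centred on the fitted focal plane
#' `z0`. Its thickness is either the FWHM of the axial intensity profile
#' (`thickness_mode = "fwhm"`) or an explicit value in nm (the field's
#' usual convention is ~600 nm for high-NA objectives). Bounds are
#' inclusive on both ends.
#'
#' @param profile An `axial_profile`.
#' @param thickness_mode `"fwhm"` or `"explicit"`.
#' @param explicit_thickness_nm Slab thickness when
#'   `thickness_mode = "explicit"`.
#' @return A `vls_bounds` object: `z0`, `half_thickness`,
#'   `thickness_mode`.
#' @export
define_vls <- function(profile, thickness_mode = c("fwhm", "explicit"),
                       explicit_thickness_nm = NULL) {
  thickness_mode <- match.arg(thickness_mode)
  thickness <- if (thickness_mode == "fwhm") profile$fwhm
  else {
    if (is.null(explicit_thickness_nm))
      stop("explicit_thickness_nm required for thickness_mode = 'explicit'")
    explicit_thickness_nm
  }
  if (!is.finite(thickness) || thickness <= 0)
    stop("virtual light-sheet thickness must be positive")
  structure(list(z0 = profile$z0, half_thickness = thickness / 2,
                 thickness_mode = thickness_mode),
            class = "vls_bounds")
}

#' @export
print.vls_bounds <- function(x, ...) {
  cat(sprintf("<vls_bounds> z0 = %.1f nm +/- %.1f nm (%s)\n", x$z0,
              x$half_thickness, x$thickness_mode))
  invisible(x)
}

#' Label localizations by true axial position
#'
#' Tags every localization as inside or outside the virtual light-sheet
#' using its known z position (boundary inclusive). This is the data
#' behind the width-versus-amplitude "parameter plot".
#'
#' @param localizations Localization `data.frame` with a `true_z_nm`
#'   column (no missing values).
#' @param vls A `vls_bounds` object.
#' @return The table with a logical `in_vls` column added.
#' @export
label_localizations <- function(localizations, vls) {
  z <- localizations$true_z_nm
  if (is.null(z) || anyNA(z))
    stop("every localization needs a true_z_nm value")
  localizations$in_vls <- abs(z - vls$z0) <= vls$half_thickness
  localizations
}

#' Confidence and recall along a threshold scan
#'
#' For each threshold the retained set is `width <= threshold` (width
#' scans) or `amplitude >= threshold` (amplitude scans), intersected with
#' an optional prior filter (e.g. an already-fixed width cut). Counting
#' against the `in_vls` labels: TP = kept and inside, FP = kept and
#' outside, FN = inside but removed by either stage. Confidence is
#' TP/(TP+FP) — undefined (NA), not zero, when nothing is kept — and
#' recall is TP/(TP+FN).
#'
#' @param labeled Output of [label_localizations()].
#' @param parameter `"width"` or `"amplitude"`.
#' @param thresholds Numeric thresholds (sorted internally).
#' @param prior_keep Optional logical vector: rows already retained by a
#'   previous stage.
#' @return `data.frame` with `threshold`, `tp`, `fp`, `fn`, `confidence`,
#'   `recall`; attribute `parameter`.
#' @export
confidence_recall_curve <- function(labeled,
                                    parameter = c("width", "amplitude"),
                                    thresholds, prior_keep = NULL) {
  parameter <- match.arg(parameter)
  if (nrow(labeled) == 0) stop("empty labeled localization set")
  if (is.null(labeled$in_vls)) stop("labeled set needs an in_vls column")
  thresholds <- sort(unique(thresholds))
  vals <- if (parameter == "width") labeled$sigma_nm
  else labeled$amplitude_photons_um2
  if (is.null(prior_keep)) prior_keep <- rep(TRUE, nrow(labeled))
  kept <- if (parameter == "width") outer(vals, thresholds, `<=`)
  else outer(vals, thresholds, `>=`)
  kept[is.na(kept)] <- FALSE
  kept <- kept & prior_keep
  inv <- labeled$in_vls
  total_in <- sum(inv)
  if (total_in == 0) stop("labeled set contains no in-vls localizations")
  tp <- colSums(kept & inv)
  fp <- colSums(kept & !inv)
  fn <- total_in - tp
  confidence <- ifelse(tp + fp == 0, NA_real_, tp / (tp + fp))
  out <- data.frame(threshold = thresholds, tp = tp, fp = fp, fn = fn,
                    confidence = confidence, recall = tp / total_in)
  attr(out, "parameter") <- parameter
  out
}

#' Select the width threshold for an imaging mode
#'
#' Structural mode: the threshold at which the confidence and recall
#' curves intersect, refined by linear interpolation between the two
#' bracketing scan points; when several crossings exist the one at the
#' largest threshold (highest recall) is used. Confidence mode: the
#' threshold maximizing confidence, ties broken toward the larger
#' threshold so that more localizations are retained. Undefined
#' confidence values are excluded, never treated as 0 or 1.
#'
#' @param curve A width [confidence_recall_curve()] with >= 2 thresholds.
#' @param mode `"structural"` or `"confidence"`.
#' @return Width threshold in nm.
#' @export
select_width_threshold <- function(curve,
                                   mode = c("structural", "confidence")) {
  mode <- match.arg(mode)
  stopifnot(nrow(curve) >= 2)
  t <- curve$threshold
  if (all(is.na(curve$confidence)))
    stop("confidence is undefined over the whole scan")
  if (mode == "confidence") {
    best <- max(curve$confidence, na.rm = TRUE)
    return(max(t[!is.na(curve$confidence) & curve$confidence == best]))
  }
  d <- curve$confidence - curve$recall
  cross <- c()
  for (i in seq_len(length(t) - 1)) {
    if (is.na(d[i]) || is.na(d[i + 1])) next
    if (d[i] == 0) cross <- c(cross, t[i])
    if (d[i] * d[i + 1] < 0)
      cross <- c(cross, t[i] + (t[i + 1] - t[i]) * d[i] / (d[i] - d[i + 1]))
  }
  if (!is.na(d[length(t)]) && d[length(t)] == 0) cross <- c(cross, t[length(t)])
  if (length(cross) == 0)
    stop("confidence and recall curves do not cross; widen the width scan")
  max(cross)
}

#' Select the amplitude threshold for a target confidence
#'
#' With the width cut already applied, scans every observed amplitude of
#' the surviving localizations as a candidate threshold and returns the
#' smallest one whose confidence reaches `target_confidence` — i.e. the
#' choice maximizing recall subject to the confidence floor.
#'
#' @param labeled Output of [label_localizations()].
#' @param width_max Width cut (nm) applied as the prior stage.
#' @param target_confidence Required confidence, in (0, 1).
#' @return Amplitude threshold (photons/um^2) with attributes
#'   `achieved_confidence`, `achieved_recall` and the scan `curve`.
#' @export
select_amplitude_threshold <- function(labeled, width_max,
                                       target_confidence = 0.9) {
  stopifnot(target_confidence > 0, target_confidence < 1)
  prior <- !is.na(labeled$sigma_nm) & labeled$sigma_nm <= width_max
  cands <- sort(unique(labeled$amplitude_photons_um2[
    prior & is.finite(labeled$amplitude_photons_um2)]))
  if (length(cands) == 0) stop("no localizations survive the width cut")
  curve <- confidence_recall_curve(labeled, "amplitude", cands,
                                   prior_keep = prior)
  ok <- which(!is.na(curve$confidence) &
                curve$confidence >= target_confidence)
  if (length(ok) == 0)
    stop(sprintf(
      "target confidence %.3f unreachable; maximum achievable is %.3f",
      target_confidence, max(curve$confidence, na.rm = TRUE)))
  i <- min(ok)
  structure(curve$threshold[i],
            achieved_confidence = curve$confidence[i],
            achieved_recall = curve$recall[i], curve = curve)
}

#' Evaluate a width/amplitude threshold pair on a labeled set
#'
#' @param labeled Output of [label_localizations()].
#' @param width_max,amplitude_min Thresholds (keep iff
#'   `width <= width_max` and `amplitude >= amplitude_min`).
#' @return List with `confidence`, `recall`, `tp`, `fp`, `fn`, `n_kept`.
#' @export
evaluate_thresholds <- function(labeled, width_max, amplitude_min) {
  keep <- !is.na(labeled$sigma_nm) & !is.na(labeled$amplitude_photons_um2) &
    labeled$sigma_nm <= width_max &
    labeled$amplitude_photons_um2 >= amplitude_min
  inv <- labeled$in_vls
  tp <- sum(keep & inv); fp <- sum(keep & !inv); fn <- sum(!keep & inv)
  list(confidence = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
       recall = tp / (tp + fn), tp = tp, fp = fp, fn = fn,
       n_kept = sum(keep))
}

#' Default calibration configuration
#'
#' @param mode Which imaging modes to calibrate: `"both"`,
#'   `"structural"` or `"confidence"`.
#' @param width_scan_nm Width-threshold scan grid, nm.
#' @param thickness_mode,thickness_nm Virtual light-sheet thickness rule
#'   passed to [define_vls()]; the default is the field's ~600 nm
#'   convention.
#' @param target_structural,target_confidence Amplitude-stage confidence
#'   targets of the two modes.
#' @param link_radius_nm,box_halfwidth_px,min_snr,min_separation_px
#'   Stage parameters passed through to linking and fitting.
#' @return Named list of configuration values.
#' @export
calibration_config <- function(mode = "both",
                               width_scan_nm = seq(100, 500, by = 1),
                               thickness_mode = "explicit",
                               thickness_nm = 600,
                               target_structural = 0.90,
                               target_confidence = 0.95,
                               link_radius_nm = 500,
                               box_halfwidth_px = NULL,
                               min_snr = 4, min_separation_px = 5) {
  list(mode = mode, width_scan_nm = width_scan_nm,
       thickness_mode = thickness_mode, thickness_nm = thickness_nm,
       target_structural = target_structural,
       target_confidence = target_confidence,
       link_radius_nm = link_radius_nm,
       box_halfwidth_px = box_halfwidth_px, min_snr = min_snr,
       min_separation_px = min_separation_px)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Calibrate the virtual light-sheet from a bead z-stack
#'
#' Full pipeline: fit every frame, link the localizations into bead
#' traces, fit the axial boxed-intensity profile, define the acceptance
#' slab, label all localizations by their known z, scan width thresholds
#' (confidence/recall curves), select the width threshold per imaging
#' mode, then select the amplitude threshold reaching the mode's
#' confidence target. Stage failures are re-raised tagged with the stage
#' name.
#'
#' @param stack A calibration [frame_stack()] with `z_per_frame`.
#' @param config A [calibration_config()] (or a partial list overriding
#'   its defaults).
#' @return A `vls_calibration_set`: shared `profile`, `vls`, `labeled`
#'   table and `width_curve`, plus one `vls_calibration` per requested
#'   mode under `$modes` (each holding `width_max_nm`,
#'   `amplitude_min_photons_um2`, achieved confidence/recall and both
#'   curves).
#' @export
calibrate <- function(stack, config = calibration_config()) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(stack$z_per_frame))
    stop("[input] calibration stack must carry z_per_frame")
  config <- utils::modifyList(calibration_config(), config)
  locs <- stage("fit", fit_stack(stack, min_snr = config$min_snr,
                                 min_separation_px = config$min_separation_px))
  locs <- locs[locs$fit_ok, , drop = FALSE]
  if (nrow(locs) == 0) stop("[fit] no successful fits in the stack")
  traces <- stage("link", link_beads(locs, stack$z_per_frame,
                                     config$link_radius_nm, stack = stack,
                                     box_halfwidth_px = config$box_halfwidth_px))
  if (length(traces) == 0) stop("[link] no bead traces recovered")
  profile <- stage("profile", fit_axial_profile(traces))
  vls <- stage("vls", define_vls(profile, config$thickness_mode,
                                 config$thickness_nm))
  labeled <- stage("label", label_localizations(locs, vls))
  wcurve <- stage("width_curve",
                  confidence_recall_curve(labeled, "width",
                                          config$width_scan_nm))
  modes <- if (config$mode == "both") c("structural", "confidence")
  else config$mode
  targets <- c(structural = config$target_structural,
               confidence = config$target_confidence)
  fits <- lapply(modes, function(m) {
    wmax <- stage(paste0("width_select_", m),
                  select_width_threshold(wcurve, m))
    amp <- stage(paste0("amplitude_select_", m),
                 select_amplitude_threshold(labeled, wmax, targets[[m]]))
    ach <- evaluate_thresholds(labeled, wmax, as.numeric(amp))
    structure(list(mode = m, z0 = vls$z0,
                   half_thickness = vls$half_thickness,
                   width_max_nm = wmax,
                   amplitude_min_photons_um2 = as.numeric(amp),
                   target_confidence = targets[[m]],
                   achieved_confidence = ach$confidence,
                   achieved_recall = ach$recall,
                   width_curve = wcurve,
                   amplitude_curve = attr(amp, "curve"),
                   n_localizations = nrow(labeled)),
              class = "vls_calibration")
  })
  names(fits) <- modes
  structure(list(profile = profile, vls = vls, labeled = labeled,
                 width_curve = wcurve, traces = traces, modes = fits),
            class = "vls_calibration_set")
}

#' @export
print.vls_calibration <- function(x, ...) {
  cat(sprintf(
    "<vls_calibration> %s mode: width <= %.1f nm, amplitude >= %.0f photons/um^2\n",
    x$mode, x$width_max_nm, x$amplitude_min_photons_um2))
  cat(sprintf("  vls: z0 = %.1f nm +/- %.1f nm\n", x$z0, x$half_thickness))
  cat(sprintf("  achieved confidence %.3f, recall %.3f (n = %d)\n",
              x$achieved_confidence, x$achieved_recall, x$n_localizations))
  invisible(x)
}

#' @export
print.vls_calibration_set <- function(x, ...) {
  cat(sprintf("<vls_calibration_set> %d localizations, %d bead traces\n",
              nrow(x$labeled), length(x$traces)))
  for (m in x$modes) print(m)
  invisible(x)
}

#' Per-parameter axial profiles across beads
#'
#' For each fitted parameter (width, amplitude, integrated intensity,
#' precision, offset): its per-z mean and standard deviation across bead
#' traces, as plottable tables with +/- 1 sd bands.
#'
#' @param traces List of `bead_trace` objects from [link_beads()].
#' @return Named list of `data.frame`s (`z`, `mean`, `sd`, `n`).
#' @export
export_parameter_profiles <- function(traces) {
  stopifnot(length(traces) >= 1)
  z <- traces[[1]]$steps$z
  params <- c(width = "sigma_nm", amplitude = "amplitude_photons_um2",
              intensity = "intensity_photons", precision = "precision_nm",
              offset = "offset_photons")
  out <- lapply(params, function(cc) {
    M <- do.call(rbind, lapply(traces, function(tr) tr$steps[[cc]]))
    data.frame(z = z,
               mean = colMeans(M, na.rm = TRUE),
               sd = apply(M, 2, function(v)
                 if (sum(is.finite(v)) > 1) stats::sd(v, na.rm = TRUE) else 0),
               n = colSums(is.finite(M)))
  })
  names(out) <- names(params)
  out
}

#' Calibration-transfer validation on independent replicates
#'
#' Generates two independent synthetic bead z-stacks, calibrates on the
#' first and evaluates the selected threshold pair(s) on the
#' ground-truth-labeled localizations of the second — the confidence a
#' user would actually obtain when applying the calibration to new data.
#' The default stack protocol is a reduced scan (41 steps of 25 nm,
#' 5 frames per step, 20 beads, 500-1,500 photons/frame).
#'
#' @param seed_calibration,seed_evaluation Seeds of the two stacks.
#' @param stack_args List of overrides for [simulate_bead_zstack()].
#' @param config Calibration configuration (see [calibration_config()]).
#' @return `data.frame` with one row per mode: thresholds, achieved
#'   confidence/recall on the independent replicate, and evaluated counts.
#' @export
crossval_confidence <- function(seed_calibration, seed_evaluation,
                                stack_args = list(),
                                config = calibration_config()) {
  defaults <- list(n_beads = 20, z_min = -500, z_max = 500, z_step = 25,
                   frames_per_step = 5, photons_range = c(500, 1500))
  args <- utils::modifyList(defaults, stack_args)
  stack_a <- do.call(simulate_bead_zstack,
                     c(args, list(seed = seed_calibration)))
  stack_b <- do.call(simulate_bead_zstack,
                     c(args, list(seed = seed_evaluation)))
  calset <- calibrate(stack_a, config)
  locs_b <- fit_stack(stack_b)
  locs_b <- locs_b[locs_b$fit_ok, , drop = FALSE]
  labeled_b <- label_localizations(locs_b, calset$vls)
  rows <- lapply(calset$modes, function(cal) {
    ev <- evaluate_thresholds(labeled_b, cal$width_max_nm,
                              cal$amplitude_min_photons_um2)
    data.frame(mode = cal$mode, width_max_nm = cal$width_max_nm,
               amplitude_min_photons_um2 = cal$amplitude_min_photons_um2,
               confidence = ev$confidence, recall = ev$recall,
               tp = ev$tp, fp = ev$fp, fn = ev$fn,
               n_evaluated = nrow(labeled_b))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "calibration") <- calset
  out
}
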