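# Shared fixtures. Expensive objects (a small calibrated z-stack, the
# two-replicate cross-validation runs) are computed once per test run and
# cached for every file that needs them.

quiet_camera <- function(...) {
  camera_model(read_noise = 0, baseline = 100, em_excess_factor = 1, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small but complete calibration over the full axial working range:
# 10 beads, 41 steps of 50 nm, 2 frames/step
demo_calibration <- function() {
  cached_fixture("demo_cal", {
    st <- simulate_bead_zstack(n_beads = 10, z_min = -1000, z_max = 1000,
                               z_step = 50, frames_per_step = 2, seed = 3)
    suppressWarnings(calibrate(st))
  })
}

# reduced-protocol calibration-transfer runs: 5 independent seed pairs
crossval_results <- function() {
  cached_fixture("crossval", {
    lapply(1:5, function(i)
      suppressWarnings(crossval_confidence(1000 + 2 * i - 1, 1000 + 2 * i)))
  })
}

# canonical localization rows from raw vectors, for table-level tests
make_locs <- function(x, y, sigma = 175, amplitude = 2000, frame = 1,
                      true_z = NULL, fit_ok = TRUE) {
  n <- max(length(x), length(y), length(sigma), length(amplitude),
           length(frame), length(true_z))
  out <- data.frame(frame = rep_len(frame, n), x_nm = rep_len(x, n),
                    y_nm = rep_len(y, n), sigma_nm = rep_len(sigma, n),
                    amplitude_photons_um2 = rep_len(amplitude, n),
                    offset_photons = 5, intensity_photons = 1000,
                    precision_nm = 8, fit_ok = rep_len(fit_ok, n))
  if (!is.null(true_z)) out$true_z_nm <- rep_len(true_z, n)
  out
}

bead_trace_stub <- function(z, boxed_intensity) {
  structure(list(bead_id = 1L, x_nm = 0, y_nm = 0,
                 steps = data.frame(z = z, boxed_intensity = boxed_intensity)),
            class = "bead_trace")
}
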