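# Bead linking, axial profile, slab definition, confidence/recall
# statistics and threshold selection.

test_that("bead linking reconstructs traces and rejects ambiguous pairs", {
  set.seed(1)
  z_steps <- seq(-500, 500, 100)
  zpf <- z_steps  # one frame per step
  one <- make_locs(x = 1000 + stats::rnorm(11, 0, 5),
                   y = 1000 + stats::rnorm(11, 0, 5), frame = 1:11)
  tr <- link_beads(one, zpf)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$steps$n_locs, rep(1L, 11))

  two <- rbind(make_locs(x = 1000, y = 1000, frame = 1:11),
               make_locs(x = 6000, y = 6000, frame = 1:11))
  tr2 <- link_beads(two, zpf)
  expect_length(tr2, 2)
  xs <- sort(vapply(tr2, `[[`, numeric(1), "x_nm"))
  expect_equal(xs, c(1000, 6000), tolerance = 1e-6)

  close_pair <- rbind(make_locs(x = 1000, y = 1000, frame = 1:11),
                      make_locs(x = 1100, y = 1000, frame = 1:11))
  expect_warning(tr3 <- link_beads(close_pair, zpf), "ambiguous")
  expect_length(tr3, 0)
})

test_that("focal plane is the boxed-intensity argmax with median tie-break", {
  prof <- stats::dnorm(seq(-500, 500, 50), 0, 280)
  prof[17] <- max(prof) * 2
  tr <- bead_trace_stub(seq(-500, 500, 50), prof)
  expect_equal(find_focal_plane(tr), 17)
  expect_equal(which.max(prof), 17)  # brute-force argmax agrees

  bi <- rep(1, 15); bi[c(10, 12)] <- 5
  expect_equal(find_focal_plane(bead_trace_stub(1:15, bi)), 10)

  expect_error(find_focal_plane(bead_trace_stub(1:9, rep(1, 9))),
               "no focus")
})

test_that("axial profile fit recovers an injected Gaussian and its FWHM", {
  z <- seq(-1000, 1000, 10)
  prof <- data.frame(z = z,
                     intensity = exp(-(z - 37)^2 / (2 * 283^2)) + 0.05)
  pr <- fit_axial_profile(prof)
  expect_equal(pr$fwhm, 2 * sqrt(2 * log(2)) * 283, tolerance = 5e-4)
  expect_lt(abs(pr$fwhm - 666), 1)
  expect_equal(pr$z0, 37, tolerance = 0.05)
  expect_equal(pr$fwhm / pr$sigma_ax, 2 * sqrt(2 * log(2)))

  # mirrored profile: same width, negated centre
  mir <- data.frame(z = z, intensity = rev(prof$intensity))
  pm <- fit_axial_profile(mir)
  expect_equal(pm$sigma_ax, pr$sigma_ax, tolerance = 1e-3)
  expect_equal(pm$z0, -pr$z0, tolerance = 0.1)

  # recovery under noise: bias below 2% over 20 replicates
  set.seed(8)
  est <- replicate(20, {
    noisy <- data.frame(z = z, intensity = prof$intensity +
                          stats::rnorm(length(z), 0, 0.02))
    fit_axial_profile(noisy)$sigma_ax
  })
  expect_lt(abs(mean(est) / 283 - 1), 0.02)
})

test_that("slab bounds follow the requested thickness rule", {
  z <- seq(-1000, 1000, 10)
  pr <- fit_axial_profile(data.frame(z = z,
                                     intensity = exp(-z^2 / (2 * 283^2))))
  v1 <- define_vls(pr, "fwhm")
  expect_equal(v1$half_thickness, pr$fwhm / 2)
  v2 <- define_vls(pr, "explicit", 600)
  expect_equal(v2$half_thickness, 300)
  expect_error(define_vls(pr, "explicit", 0), "positive")
})

test_that("labelling is boundary-inclusive and matches a recount", {
  vls <- structure(list(z0 = 10, half_thickness = 300,
                        thickness_mode = "explicit"), class = "vls_bounds")
  locs <- make_locs(x = 1:5 * 100, y = 0,
                    true_z = c(10, 310, 311, -290, -291))
  lab <- label_localizations(locs, vls)
  expect_equal(lab$in_vls, c(TRUE, TRUE, FALSE, TRUE, FALSE))

  set.seed(21)
  rand <- make_locs(x = stats::runif(300, 0, 1e4), y = 0,
                    true_z = stats::runif(300, -800, 800))
  labr <- label_localizations(rand, vls)
  brute <- vapply(rand$true_z_nm, function(z) abs(z - 10) <= 300, logical(1))
  expect_identical(labr$in_vls, brute)

  expect_error(label_localizations(make_locs(x = 1, y = 1), vls), "true_z")
})

test_that("confidence/recall counting equals a per-point recount", {
  # hand-built set: at threshold 200, TP = 9, FP = 1, FN = 1
  lab <- make_locs(x = 1:11 * 100, y = 0,
                   sigma = c(rep(150, 9), 180, 250),
                   true_z = c(rep(0, 9), 500, 100))
  vls <- structure(list(z0 = 0, half_thickness = 300,
                        thickness_mode = "explicit"), class = "vls_bounds")
  lab <- label_localizations(lab, vls)
  cur <- confidence_recall_curve(lab, "width", 200)
  expect_equal(cur$tp, 9); expect_equal(cur$fp, 1); expect_equal(cur$fn, 1)
  expect_equal(cur$confidence, 0.9)
  expect_equal(cur$recall, 0.9)

  # loosest threshold keeps everything: recall 1, confidence = in fraction
  loose <- confidence_recall_curve(lab, "width", max(lab$sigma_nm))
  expect_equal(loose$recall, 1)
  expect_equal(loose$confidence, mean(lab$in_vls))

  # 200-point random set: every (TP, FP, FN) equals an exhaustive recount
  set.seed(31)
  rand <- make_locs(x = stats::runif(200, 0, 1e4), y = 0,
                    sigma = stats::runif(200, 120, 400),
                    amplitude = stats::runif(200, 300, 4000),
                    true_z = stats::runif(200, -700, 700))
  rand <- label_localizations(rand, vls)
  thr <- seq(100, 500, 20)
  cur2 <- confidence_recall_curve(rand, "width", thr)
  for (i in seq_along(thr)) {
    keep <- rand$sigma_nm <= thr[i]
    expect_equal(cur2$tp[i], sum(keep & rand$in_vls))
    expect_equal(cur2$fp[i], sum(keep & !rand$in_vls))
    expect_equal(cur2$fn[i], sum(!keep & rand$in_vls))
  }
  # monotonicity: tightening the width cut never increases recall or FP
  expect_true(all(diff(cur2$recall) >= 0))   # ascending thresholds
  expect_true(all(diff(cur2$fp) >= 0))
  # undefined confidence below the smallest width, never 0 or 1
  none <- confidence_recall_curve(rand, "width", 50)
  expect_true(is.na(none$confidence))
  expect_equal(none$recall, 0)
})

test_that("width selection interpolates the crossing and breaks ties upward", {
  grid <- seq(200, 250, 5)
  conf <- 0.7 - 0.002 * (grid - 223)
  recall <- 0.7 + 0.003 * (grid - 223)
  cur <- data.frame(threshold = grid, confidence = conf, recall = recall)
  expect_equal(select_width_threshold(cur, "structural"), 223)

  # crossing exactly on a sampled threshold
  cur2 <- data.frame(threshold = c(210, 220, 230),
                     confidence = c(0.9, 0.8, 0.7),
                     recall = c(0.7, 0.8, 0.9))
  expect_equal(select_width_threshold(cur2, "structural"), 220)

  # plateau maximum: the largest threshold wins
  cur3 <- data.frame(threshold = seq(190, 220, 10),
                     confidence = c(0.8, 0.95, 0.95, 0.9),
                     recall = c(0.2, 0.4, 0.6, 0.8))
  expect_equal(select_width_threshold(cur3, "confidence"), 210)

  # no sign change: actionable error
  cur4 <- data.frame(threshold = c(200, 300), confidence = c(0.4, 0.3),
                     recall = c(0.9, 1))
  expect_error(select_width_threshold(cur4, "structural"), "widen")
})

test_that("amplitude selection returns the smallest qualifying threshold", {
  vls <- structure(list(z0 = 0, half_thickness = 300,
                        thickness_mode = "explicit"), class = "vls_bounds")
  # separable: all in-slab amplitudes above all out-of-slab ones
  sep <- make_locs(x = 1:20 * 100, y = 0, sigma = 180,
                   amplitude = c(seq(2000, 2900, 100), seq(600, 1500, 100)),
                   true_z = c(rep(0, 10), rep(500, 10)))
  sep <- label_localizations(sep, vls)
  thr <- select_amplitude_threshold(sep, width_max = 500,
                                    target_confidence = 0.95)
  expect_equal(as.numeric(thr), 2000)
  expect_equal(attr(thr, "achieved_confidence"), 1)

  # 50-point random set against the exhaustive oracle
  set.seed(41)
  rnd <- make_locs(x = 1:50 * 100, y = 0, sigma = 180,
                   amplitude = stats::runif(50, 500, 3000),
                   true_z = sample(c(0, 500), 50, replace = TRUE))
  rnd <- label_localizations(rnd, vls)
  got <- select_amplitude_threshold(rnd, 500, 0.8)
  cands <- sort(unique(rnd$amplitude_photons_um2))
  oracle <- Inf
  for (tt in cands) {
    keep <- rnd$amplitude_photons_um2 >= tt
    conf <- sum(keep & rnd$in_vls) / sum(keep)
    if (is.finite(conf) && conf >= 0.8) { oracle <- tt; break }
  }
  expect_equal(as.numeric(got), oracle)

  # unreachable target reports the maximum achievable
  inter <- make_locs(x = 1:40 * 100, y = 0, sigma = 180,
                     amplitude = rep(seq(600, 2500, 100), 2),
                     true_z = rep(c(0, 500), each = 20))
  inter <- label_localizations(inter, vls)
  expect_error(select_amplitude_threshold(inter, 500, 0.999),
               "maximum achievable")
})

test_that("end-to-end calibration reaches both mode targets on its own data", {
  cs <- demo_calibration()
  expect_s3_class(cs, "vls_calibration_set")
  expect_gte(cs$modes$structural$achieved_confidence, 0.90)
  expect_gte(cs$modes$confidence$achieved_confidence, 0.95)
  expect_gte(cs$modes$structural$achieved_recall,
             cs$modes$confidence$achieved_recall)
  expect_lt(abs(cs$vls$z0), 100)  # true focal plane is z = 0
  # stage tagging on invalid input
  st <- simulate_bead_zstack(n_beads = 1, z_min = -100, z_max = 100,
                             z_step = 100, frames_per_step = 1,
                             shape = c(48, 48), seed = 6)
  st$z_per_frame <- NULL
  expect_error(calibrate(st), "z_per_frame")
})

test_that("per-parameter axial profiles peak where the physics says", {
  # exact traces built from the defocus law: width minimal and amplitude
  # maximal at the focal plane
  z <- seq(-500, 500, 100)
  mk <- function(jit) {
    s <- psf_sigma_at_z(z, optics_model())
    structure(list(bead_id = 1L, x_nm = 0, y_nm = 0,
                   steps = data.frame(z = z, sigma_nm = s + jit,
                                      amplitude_photons_um2 = 1000 / (s + jit)^2 * 1e6,
                                      offset_photons = 5,
                                      intensity_photons = 1000,
                                      precision_nm = 8,
                                      n_locs = 1L,
                                      boxed_intensity = 1)),
              class = "bead_trace")
  }
  traces <- list(mk(0), mk(1), mk(-1))
  prof <- export_parameter_profiles(traces)
  expect_equal(z[which.min(prof$width$mean)], 0)
  expect_equal(z[which.max(prof$amplitude$mean)], 0)
  # sd bands equal a direct recomputation and are non-negative
  direct <- apply(rbind(traces[[1]]$steps$sigma_nm,
                        traces[[2]]$steps$sigma_nm,
                        traces[[3]]$steps$sigma_nm), 2, stats::sd)
  expect_equal(prof$width$sd, direct)
  expect_true(all(prof$width$sd >= 0))
})
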