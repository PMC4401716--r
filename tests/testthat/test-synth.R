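# Synthetic microscope: defocus law, image formation, acquisition protocols.

test_that("defocus law is exact at focus, even in z and monotone in |z|", {
  op <- optics_model(sigma0 = 175, z_r = 400)
  expect_identical(psf_sigma_at_z(0, op), 175)
  expect_equal(psf_sigma_at_z(400, op), 175 * sqrt(2))
  set.seed(42)
  z <- stats::runif(100, -1500, 1500)
  expect_equal(psf_sigma_at_z(z, op), psf_sigma_at_z(-z, op))
  expect_true(all(psf_sigma_at_z(z, op) >= 175))
  az <- sort(abs(z))
  expect_true(all(diff(psf_sigma_at_z(az, op)) > 0))
})

test_that("rendered frames conserve photons and honour the noise model", {
  cam <- quiet_camera()
  # no emitters, no background, no read noise: constant baseline frame
  f0 <- render_frame(NULL, c(32, 32), camera = cam,
                     background_photons_per_pixel = 0, noise = TRUE, seed = 1)
  expect_true(all(f0 == 100))
  # photon conservation without noise (truncation only)
  em <- data.frame(x_nm = 1600, y_nm = 1600, z_nm = 0, photons = 1000)
  fr <- render_frame(em, c(32, 32), camera = cam, noise = FALSE)
  expect_equal(sum(fr - 100), 1000, tolerance = 0.01)
  # identical seed, identical frame
  a <- render_frame(em, c(32, 32), camera = camera_model(),
                    background_photons_per_pixel = 3, seed = 7)
  b <- render_frame(em, c(32, 32), camera = camera_model(),
                    background_photons_per_pixel = 3, seed = 7)
  expect_identical(a, b)
  # off-field emitter clipped silently, only its tail contributes
  em2 <- data.frame(x_nm = -500, y_nm = 1600, z_nm = 0, photons = 1000)
  fr2 <- render_frame(em2, c(32, 32), camera = cam, noise = FALSE)
  expect_gte(sum(fr2 - 100), 0)
  expect_lt(sum(fr2 - 100), 600)
})

test_that("bead z-stacks follow the scan protocol with well-separated beads", {
  st <- simulate_bead_zstack(n_beads = 1, z_min = -500, z_max = 500,
                             z_step = 500, frames_per_step = 1,
                             shape = c(48, 48), seed = 2)
  expect_length(st$frames, 3)
  expect_equal(st$z_per_frame, c(-500, 0, 500))

  st2 <- simulate_bead_zstack(n_beads = 5, z_min = -100, z_max = 100,
                              z_step = 10, frames_per_step = 2, seed = 4)
  expect_length(st2$frames, 21 * 2)
  expect_true(all(st2$photons_per_frame >= 500 & st2$photons_per_frame <= 1500))
  d <- as.matrix(stats::dist(st2$truth[, c("x_nm", "y_nm")]))
  diag(d) <- Inf
  expect_true(all(d >= 8 * 175))

  st3 <- simulate_bead_zstack(n_beads = 5, z_min = -100, z_max = 100,
                              z_step = 10, frames_per_step = 2, seed = 4)
  expect_identical(st2$frames, st3$frames)

  expect_error(
    simulate_bead_zstack(n_beads = 10, z_min = -100, z_max = 100,
                         z_step = 100, frames_per_step = 1,
                         shape = c(32, 32), seed = 1),
    "field too small")
})

test_that("blinking movies record ground truth consistent with the frames", {
  em <- data.frame(id = 1, x_nm = 1600, y_nm = 1600, z_nm = 0)
  mv <- simulate_smlm_movie(em, n_frames = 10, mean_on_frames = 1,
                            activation_prob = 0.5,
                            photons_range = c(800, 1000), shape = c(32, 32),
                            camera = quiet_camera(),
                            background_photons_per_pixel = 0, noise = FALSE,
                            seed = 5)
  on <- mv$truth$on_frames[[1]]
  expect_gte(length(on), 1)
  sums <- vapply(mv$frames, function(f) sum(f - 100), numeric(1))
  expect_true(all(sums[on] > 500))
  off <- setdiff(1:10, on)
  if (length(off)) expect_true(all(abs(sums[off]) < 1e-6))

  mv2 <- simulate_smlm_movie(em, n_frames = 10, mean_on_frames = 1,
                             activation_prob = 0.5,
                             photons_range = c(800, 1000), shape = c(32, 32),
                             camera = quiet_camera(),
                             background_photons_per_pixel = 0, noise = FALSE,
                             seed = 5)
  expect_identical(mv$frames, mv2$frames)
  expect_identical(mv$truth$on_frames, mv2$truth$on_frames)
})

test_that("shell layouts exclude voids; cluster layouts honour geometry", {
  voids <- data.frame(cx = 2500, cy = 2500, cz = 0, rx = 700, ry = 700,
                      rz = 250)
  sh <- layout_vacuole_shell(300, c(0, 5000, 0, 5000), c(-600, 600),
                             voids, seed = 9)
  expect_equal(nrow(sh), 300)
  d <- ((sh$x_nm - 2500) / 700)^2 + ((sh$y_nm - 2500) / 700)^2 +
    (sh$z_nm / 250)^2
  expect_true(all(d > 1))

  cl <- layout_clusters(data.frame(x_nm = c(0, 5000), y_nm = c(0, 5000),
                                   z_nm = c(0, 800)),
                        n_per_cluster = 15, seed = 9)
  expect_equal(nrow(cl), 30)
  expect_equal(as.integer(table(cl$cluster)), c(15L, 15L))
  expect_lt(max(abs(cl$z_nm[cl$cluster == 1])), 200)
})
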