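#' Render one camera frame of point emitters
#'
#' Image formation: every emitter contributes a circular 2D Gaussian with
#' peak `photons / (2 pi (sigma(z)/pixel)^2)` photons per pixel at its
#' `(x, y)` position, on top of a uniform background. Noise, when enabled,
#' is Poisson shot noise (variance inflated by the camera's EM excess
#' factor), then Gaussian read noise, then the baseline offset and integer
#' quantization. With `noise = FALSE` the expected image is returned
#' unquantized (plus baseline), which is what the exact-recovery tests use.
#'
#' Emitters outside the field contribute only their in-field tail and are
#' otherwise clipped silently.
#'
#' @param emitters_on `data.frame` with columns `x_nm`, `y_nm`, `z_nm`,
#'   `photons` (expected detected photons this frame); may be empty.
#' @param shape Frame dimensions `c(rows, cols)` in pixels.
#' @param optics An [optics_model()].
#' @param camera A [camera_model()].
#' @param background_photons_per_pixel Uniform background level, photons.
#' @param noise Logical; apply the camera noise model.
#' @param seed Optional integer; when given the frame is a pure function of
#'   the arguments.
#' @return Numeric matrix of camera counts.
#' @export
render_frame <- function(emitters_on, shape, optics = optics_model(),
                         camera = camera_model(),
                         background_photons_per_pixel = 0,
                         noise = TRUE, seed = NULL) {
  stopifnot(length(shape) == 2L, all(shape >= 1),
            background_photons_per_pixel >= 0)
  if (!is.null(seed)) set.seed(seed)
  ny <- as.integer(shape[1]); nx <- as.integer(shape[2])
  img <- matrix(background_photons_per_pixel, ny, nx)
  if (!is.null(emitters_on) && nrow(emitters_on) > 0) {
    px <- camera$pixel_size
    for (k in seq_len(nrow(emitters_on))) {
      s_px <- psf_sigma_at_z(emitters_on$z_nm[k], optics) / px
      u <- emitters_on$x_nm[k] / px + 0.5  # continuous column coordinate
      v <- emitters_on$y_nm[k] / px + 0.5  # continuous row coordinate
      w <- ceiling(6 * s_px) + 1
      cmin <- max(1L, floor(u - w)); cmax <- min(nx, ceiling(u + w))
      rmin <- max(1L, floor(v - w)); rmax <- min(ny, ceiling(v + w))
      if (cmin > cmax || rmin > rmax) next
      peak <- emitters_on$photons[k] / (2 * pi * s_px^2)
      gx <- exp(-((cmin:cmax) - u)^2 / (2 * s_px^2))
      gy <- exp(-((rmin:rmax) - v)^2 / (2 * s_px^2))
      img[rmin:rmax, cmin:cmax] <- img[rmin:rmax, cmin:cmax] +
        peak * (gy %o% gx)
    }
  }
  if (noise) {
    f <- camera$em_excess_factor
    img <- if (f > 1) {
      f * matrix(stats::rpois(length(img), img / f), ny, nx)
    } else {
      matrix(stats::rpois(length(img), img), ny, nx)
    }
  }
  counts <- img / camera$photons_per_count
  if (noise && camera$read_noise > 0)
    counts <- counts + matrix(stats::rnorm(length(counts), 0, camera$read_noise), ny, nx)
  counts <- counts + camera$baseline
  if (noise) counts <- pmin(pmax(round(counts), 0), 65535)
  counts
}

# random well-separated lateral positions inside the field (nm)
place_emitters <- function(n, shape, camera, min_separation_nm, margin_nm) {
  xmax <- shape[2] * camera$pixel_size
  ymax <- shape[1] * camera$pixel_size
  if (xmax - 2 * margin_nm <= 0 || ymax - 2 * margin_nm <= 0)
    stop("field too small for the requested margin")
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > 50000L)
      stop(sprintf(
        "field too small to place %d emitters at >= %g nm separation", n,
        min_separation_nm))
    x <- stats::runif(1, margin_nm, xmax - margin_nm)
    y <- stats::runif(1, margin_nm, ymax - margin_nm)
    if (length(xs) == 0 ||
        all((xs - x)^2 + (ys - y)^2 >= min_separation_nm^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  data.frame(x_nm = xs, y_nm = ys)
}

#' Simulate a bead calibration z-stack
#'
#' Emulates the standard calibration acquisition: immobile sub-diffraction
#' beads are imaged while the stage steps through focus. The defaults
#' reproduce the reference protocol of 201 steps of 10 nm with 10 frames
#' per step and 500-1,500 detected photons per bead and frame. Beads are
#' placed at random lateral positions at least `8 * sigma0` apart and stay
#' fixed for the whole stack; the stage position of every frame is recorded
#' in `z_per_frame`.
#'
#' @param n_beads Number of beads (>= 1).
#' @param z_min,z_max,z_step Stage scan range and step, nm (`z_step > 0`).
#' @param frames_per_step Frames acquired at each z position.
#' @param photons_range Per-bead per-frame expected photons are drawn
#'   uniformly from this range.
#' @param optics,camera Imaging models.
#' @param shape Frame shape `c(rows, cols)` in pixels; by default sized to
#'   hold `n_beads` at the required separation.
#' @param background_photons_per_pixel Uniform background, photons.
#' @param seed Integer seed; the stack is a pure function of the arguments.
#' @return A [frame_stack()] with `z_per_frame`, a `truth` table (one row
#'   per bead; `z_nm = 0` is the bead's position relative to the focal
#'   plane at stage zero; `photons` is the per-frame mean), and the
#'   per-frame photon draws in `$photons_per_frame` (frames x beads).
#' @export
simulate_bead_zstack <- function(n_beads = 28, z_min = -1000, z_max = 1000,
                                 z_step = 10, frames_per_step = 10,
                                 photons_range = c(500, 1500),
                                 optics = optics_model(),
                                 camera = camera_model(), shape = NULL,
                                 background_photons_per_pixel = 5,
                                 seed = 1) {
  stopifnot(z_step > 0, z_min < z_max, n_beads >= 1, frames_per_step >= 1,
            length(photons_range) == 2L, photons_range[1] > 0,
            photons_range[2] >= photons_range[1])
  set.seed(seed)
  min_sep <- 8 * optics$sigma0
  margin <- 8 * optics$sigma0
  if (is.null(shape)) {
    side_nm <- ceiling(sqrt(n_beads)) * min_sep * 1.6 + 2 * margin
    side <- ceiling(side_nm / camera$pixel_size)
    shape <- c(side, side)
  }
  pos <- place_emitters(n_beads, shape, camera, min_sep, margin)
  z_steps <- seq(z_min, z_max, by = z_step)
  z_per_frame <- rep(z_steps, each = frames_per_step)
  n_frames <- length(z_per_frame)
  phot <- matrix(stats::runif(n_frames * n_beads, photons_range[1],
                              photons_range[2]),
                 n_frames, n_beads)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    em <- data.frame(x_nm = pos$x_nm, y_nm = pos$y_nm,
                     z_nm = z_per_frame[f], photons = phot[f, ])
    frames[[f]] <- render_frame(em, shape, optics, camera,
                                background_photons_per_pixel, noise = TRUE)
  }
  truth <- data.frame(id = seq_len(n_beads), x_nm = pos$x_nm,
                      y_nm = pos$y_nm, z_nm = 0,
                      photons = colMeans(phot))
  st <- frame_stack(frames, camera, z_per_frame = z_per_frame, truth = truth,
                    optics = optics)
  st$photons_per_frame <- phot
  st
}

#' Simulate a blinking SMLM movie
#'
#' Each emitter of the layout switches on stochastically and stays on for a
#' geometrically distributed number of frames (mean `mean_on_frames`); the
#' number of simultaneously active emitters can be capped to keep frames
#' sparse. Emitters have fixed 3D positions; their axial position only
#' affects the rendered PSF width and peak (total detected photons per
#' frame are drawn independently of z). The blinking model is a two-state
#' stand-in for photo-activation; no bleaching or dark-state kinetics.
#'
#' @param emitters `data.frame` with columns `x_nm`, `y_nm`, `z_nm` and
#'   optionally `id` (see [layout_clusters()], [layout_vacuole_shell()]).
#' @param n_frames Number of movie frames (>= 1).
#' @param mean_on_frames Mean burst duration in frames (>= 1).
#' @param activation_prob Per-frame probability that an idle emitter
#'   switches on.
#' @param max_on_per_frame Cap on simultaneously active emitters.
#' @param photons_range Uniform range of expected photons per on-frame.
#' @param optics,camera Imaging models.
#' @param shape Frame shape in pixels; defaults to the bounding box of the
#'   layout plus a margin.
#' @param background_photons_per_pixel Uniform background, photons.
#' @param noise Logical; apply the camera noise model.
#' @param seed Integer seed.
#' @return A [frame_stack()] whose `truth` table carries one row per
#'   emitter with its fixed `z_nm` and an `on_frames` list-column of frame
#'   indices.
#' @export
simulate_smlm_movie <- function(emitters, n_frames, mean_on_frames = 2,
                                activation_prob = 0.01,
                                max_on_per_frame = Inf,
                                photons_range = c(500, 1500),
                                optics = optics_model(),
                                camera = camera_model(), shape = NULL,
                                background_photons_per_pixel = 5,
                                noise = TRUE, seed = 1) {
  stopifnot(n_frames >= 1, mean_on_frames >= 1, activation_prob >= 0,
            activation_prob <= 1, nrow(emitters) >= 1)
  set.seed(seed)
  n <- nrow(emitters)
  if (is.null(shape)) {
    margin <- 8 * optics$sigma0
    shape <- rep(ceiling((max(emitters$x_nm, emitters$y_nm) + margin) /
                           camera$pixel_size), 2)
  }
  q_stay <- 1 - 1 / mean_on_frames
  on <- rep(FALSE, n)
  on_frames <- vector("list", n)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    on[on] <- stats::runif(sum(on)) < q_stay
    idle <- which(!on)
    newly <- idle[stats::runif(length(idle)) < activation_prob]
    room <- max_on_per_frame - sum(on)
    if (length(newly) > room)
      newly <- newly[seq_len(max(0, floor(room)))]
    on[newly] <- TRUE
    active <- which(on)
    for (i in active) on_frames[[i]] <- c(on_frames[[i]], f)
    em <- if (length(active)) {
      data.frame(x_nm = emitters$x_nm[active], y_nm = emitters$y_nm[active],
                 z_nm = emitters$z_nm[active],
                 photons = stats::runif(length(active), photons_range[1],
                                        photons_range[2]))
    } else {
      data.frame(x_nm = numeric(0), y_nm = numeric(0), z_nm = numeric(0),
                 photons = numeric(0))
    }
    frames[[f]] <- render_frame(em, shape, optics, camera,
                                background_photons_per_pixel, noise = noise)
  }
  truth <- data.frame(id = if (!is.null(emitters$id)) emitters$id else seq_len(n),
                      x_nm = emitters$x_nm, y_nm = emitters$y_nm,
                      z_nm = emitters$z_nm,
                      photons = mean(photons_range))
  truth$on_frames <- on_frames
  if (!is.null(emitters$cluster)) truth$cluster <- emitters$cluster
  frame_stack(frames, camera, truth = truth, optics = optics)
}

#' Emitter layout: tight 3D clusters
#'
#' Builds a ground-truth layout of several compact emitter groups at
#' distinct axial positions, emulating protein foci imaged at different
#' depths.
#'
#' @param centers `data.frame` with columns `x_nm`, `y_nm`, `z_nm`, one row
#'   per cluster.
#' @param n_per_cluster Emitters per cluster.
#' @param sd_lateral_nm,sd_axial_nm Gaussian spread of emitters around the
#'   cluster centre.
#' @param seed Optional integer seed.
#' @return `data.frame` with `id`, `cluster`, `x_nm`, `y_nm`, `z_nm`.
#' @export
layout_clusters <- function(centers, n_per_cluster = 10, sd_lateral_nm = 40,
                            sd_axial_nm = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sdl <- rep_len(sd_lateral_nm, nrow(centers))
  sda <- rep_len(sd_axial_nm, nrow(centers))
  out <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    data.frame(cluster = k,
               x_nm = stats::rnorm(n_per_cluster, centers$x_nm[k], sdl[k]),
               y_nm = stats::rnorm(n_per_cluster, centers$y_nm[k], sdl[k]),
               z_nm = stats::rnorm(n_per_cluster, centers$z_nm[k], sda[k]))
  }))
  out$id <- seq_len(nrow(out))
  out[, c("id", "cluster", "x_nm", "y_nm", "z_nm")]
}

#' Emitter layout: uniform volume with ellipsoidal voids
#'
#' Emulates a cytosolic label excluded from organelles: emitters are drawn
#' uniformly in a 3D slab and rejected inside any of the given ellipsoidal
#' voids. Because the slab is thicker than the voids, out-of-focus emitters
#' above and below a void project laterally into it, which is exactly the
#' background that axial filtering is meant to remove.
#'
#' @param n Number of emitters.
#' @param field_nm Lateral bounds `c(xmin, xmax, ymin, ymax)`, nm.
#' @param z_range_nm Axial bounds `c(zmin, zmax)`, nm.
#' @param voids `data.frame` with columns `cx`, `cy`, `cz`, `rx`, `ry`,
#'   `rz` (ellipsoid centres and semi-axes, nm).
#' @param seed Optional integer seed.
#' @return `data.frame` with `id`, `x_nm`, `y_nm`, `z_nm`.
#' @export
layout_vacuole_shell <- function(n, field_nm, z_range_nm = c(-600, 600),
                                 voids = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xs <- numeric(0); ys <- numeric(0); zs <- numeric(0)
  while (length(xs) < n) {
    m <- 2 * (n - length(xs)) + 10
    x <- stats::runif(m, field_nm[1], field_nm[2])
    y <- stats::runif(m, field_nm[3], field_nm[4])
    z <- stats::runif(m, z_range_nm[1], z_range_nm[2])
    keep <- rep(TRUE, m)
    if (!is.null(voids) && nrow(voids) > 0) {
      for (k in seq_len(nrow(voids))) {
        d <- ((x - voids$cx[k]) / voids$rx[k])^2 +
          ((y - voids$cy[k]) / voids$ry[k])^2 +
          ((z - voids$cz[k]) / voids$rz[k])^2
        keep <- keep & d > 1
      }
    }
    xs <- c(xs, x[keep]); ys <- c(ys, y[keep]); zs <- c(zs, z[keep])
  }
  data.frame(id = seq_len(n), x_nm = xs[seq_len(n)], y_nm = ys[seq_len(n)],
             z_nm = zs[seq_len(n)])
}
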