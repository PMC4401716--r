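# Applying a calibration to localization tables and classifying clusters.

threshold_pair <- function(calibration) {
  if (inherits(calibration, "vls_calibration"))
    return(list(width_max = calibration$width_max_nm,
                amplitude_min = calibration$amplitude_min_photons_um2))
  if (is.list(calibration) && !is.null(calibration$width_max))
    return(list(width_max = calibration$width_max,
                amplitude_min = calibration$amplitude_min))
  stop("calibration must be a vls_calibration or list(width_max, amplitude_min)")
}

threshold_keep_flags <- function(localizations, width_max, amplitude_min) {
  w <- localizations$sigma_nm
  a <- localizations$amplitude_photons_um2
  valid <- is.finite(w) & is.finite(a)
  if (!is.null(localizations$fit_ok)) valid <- valid & localizations$fit_ok
  list(valid = valid,
       keep = valid & w <= width_max & a >= amplitude_min,
       rej_width = valid & w > width_max,
       rej_amplitude = valid & w <= width_max & a < amplitude_min)
}

#' Filter a localization table with calibrated thresholds
#'
#' Keeps exactly the rows with `width <= width_max` and
#' `amplitude >= amplitude_min`, in their original order. Rows with a
#' failed fit or missing width/amplitude are rejected before
#' thresholding and counted separately. A row failing both cuts is
#' counted under the width stage, matching the two-step calibration
#' order.
#'
#' @param localizations Localization `data.frame` with `sigma_nm` and
#'   `amplitude_photons_um2` columns.
#' @param calibration A `vls_calibration` (one imaging mode) or a
#'   `list(width_max =, amplitude_min =)`.
#' @return List with the `localizations` kept and a `report` (class
#'   `vls_filter_report`): `n_input`, `n_kept`, `n_rejected_width`,
#'   `n_rejected_amplitude`, `n_rejected_invalid` and the thresholds
#'   used.
#' @export
apply_thresholds <- function(localizations, calibration) {
  thr <- threshold_pair(calibration)
  fl <- threshold_keep_flags(localizations, thr$width_max, thr$amplitude_min)
  report <- structure(list(
    n_input = nrow(localizations), n_kept = sum(fl$keep),
    n_rejected_width = sum(fl$rej_width),
    n_rejected_amplitude = sum(fl$rej_amplitude),
    n_rejected_invalid = sum(!fl$valid),
    width_max_nm = thr$width_max,
    amplitude_min_photons_um2 = thr$amplitude_min),
    class = "vls_filter_report")
  list(localizations = localizations[fl$keep, , drop = FALSE],
       report = report)
}

#' @export
print.vls_filter_report <- function(x, ...) {
  cat(sprintf(
    "<vls_filter_report> kept %d / %d (width > %.1f nm: %d; amplitude < %.0f: %d; invalid: %d)\n",
    x$n_kept, x$n_input, x$width_max_nm, x$n_rejected_width,
    x$amplitude_min_photons_um2, x$n_rejected_amplitude,
    x$n_rejected_invalid))
  invisible(x)
}

#' Density-connected lateral clustering
#'
#' Simple single-linkage grouping: localizations within `radius_nm` of
#' each other (lateral distance) are connected; connected components with
#' at least `min_points` members become clusters, numbered by first
#' occurrence. Everything else gets the reserved noise id 0. This is a
#' deterministic stand-in for whatever cluster definition an experiment
#' uses; any external assignment can be passed to [classify_clusters()]
#' instead.
#'
#' @param localizations Localization `data.frame` with `x_nm`, `y_nm`.
#' @param radius_nm Linking radius (> 0), nm.
#' @param min_points Minimum component size to count as a cluster.
#' @return Integer vector of cluster ids (0 = noise), one per row.
#' @export
group_clusters <- function(localizations, radius_nm, min_points = 10) {
  stopifnot(radius_nm > 0)
  x <- localizations$x_nm; y <- localizations$y_nm
  n <- length(x)
  if (n == 0) return(integer(0))
  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  cellx <- floor(x / radius_nm); celly <- floor(y / radius_nm)
  key <- paste(cellx, celly, sep = ",")
  cell_of <- split(seq_len(n), key)
  for (i in seq_len(n)) {
    for (dx in -1:1) for (dy in -1:1) {
      js <- cell_of[[paste(cellx[i] + dx, celly[i] + dy, sep = ",")]]
      js <- js[js > i]
      if (!length(js)) next
      close <- js[(x[js] - x[i])^2 + (y[js] - y[i])^2 <= radius_nm^2]
      for (j in close) {
        ri <- find_root(i); rj <- find_root(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find_root, integer(1))
  sizes <- table(root)
  big <- as.integer(names(sizes)[sizes >= min_points])
  ids <- integer(n)
  next_id <- 0L
  assigned <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    if (!(root[i] %in% big)) next
    kk <- as.character(root[i])
    if (is.null(assigned[[kk]])) {
      next_id <- next_id + 1L
      assigned[[kk]] <- next_id
    }
    ids[i] <- assigned[[kk]]
  }
  ids
}

#' Classify clusters by virtual-light-sheet membership
#'
#' Counts, per cluster, the localizations kept versus rejected by the
#' calibrated thresholds and assigns the three observed categories:
#' `fully-in` (no rejected member), `fully-out` (no kept member) and
#' `partial` (a cluster straddling the slab boundary). Out-of-focus
#' clusters are expected to show fewer detected localizations per emitter
#' — selecting `fully-in` clusters before counting prevents that
#' under-counting bias.
#'
#' @param localizations Localization `data.frame`.
#' @param cluster_assignment Integer vector of cluster ids per row
#'   (0 = noise), e.g. from [group_clusters()].
#' @param calibration Thresholds as in [apply_thresholds()].
#' @return `data.frame` with `cluster_id`, `n_in_vls`, `n_out`,
#'   `category` (noise rows summarized under id 0, flagged `is_noise`).
#' @export
classify_clusters <- function(localizations, cluster_assignment,
                              calibration) {
  stopifnot(length(cluster_assignment) == nrow(localizations))
  thr <- threshold_pair(calibration)
  fl <- threshold_keep_flags(localizations, thr$width_max,
                             thr$amplitude_min)
  ids <- sort(unique(cluster_assignment))
  out <- do.call(rbind, lapply(ids, function(cid) {
    sel <- cluster_assignment == cid
    n_in <- sum(fl$keep & sel)
    n_out <- sum(!fl$keep & sel)
    category <- if (n_in > 0 && n_out == 0) "fully-in"
    else if (n_in == 0) "fully-out"
    else "partial"
    data.frame(cluster_id = cid, n_in_vls = n_in, n_out = n_out,
               category = category, is_noise = cid == 0L)
  }))
  rownames(out) <- NULL
  out
}
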