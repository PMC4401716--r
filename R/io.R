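# File formats: localization tables (delimited text), image stacks
# (multi-page 16-bit TIFF with plain-text sidecars), calibration files
# (JSON) and configuration (YAML/JSON).
#
# Canonical units are fixed at nm and photons/um^2 so that calibration
# files are portable between fitting engines.

canonical_columns <- c("frame", "x_nm", "y_nm", "sigma_nm",
                       "amplitude_photons_um2", "offset_photons",
                       "intensity_photons", "precision_nm", "fit_ok",
                       "true_z_nm")

mandatory_columns <- c("x_nm", "y_nm", "sigma_nm", "amplitude_photons_um2")

#' Column mapping for importing foreign localization tables
#'
#' Maps canonical column names to the column names of another fitter's
#' output, with optional pure linear unit converters
#' (`value * scale + offset`) per column, e.g. widths in pixels converted
#' to nm by `scale = pixel_size_nm`.
#'
#' @param columns Named character vector: canonical name -> source column
#'   name. Mappings for `x_nm`, `y_nm`, `sigma_nm` and
#'   `amplitude_photons_um2` are mandatory for filtering.
#' @param converters Named list (by canonical name) of
#'   `list(scale =, offset =)`.
#' @return A `localization_schema` object.
#' @export
localization_schema <- function(columns = stats::setNames(canonical_columns,
                                                          canonical_columns),
                                converters = list()) {
  stopifnot(is.character(columns), !is.null(names(columns)))
  unknown <- setdiff(names(columns), canonical_columns)
  if (length(unknown))
    stop("unknown canonical columns: ", paste(unknown, collapse = ", "))
  structure(list(columns = columns, converters = converters),
            class = "localization_schema")
}

detect_delimiter <- function(path) {
  first <- readLines(path, n = 1)
  if (lengths(regmatches(first, gregexpr("\t", first))) >
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

#' Read a localization table
#'
#' Reads a delimited text file (comma or tab, auto-detected, header row
#' required) and maps it onto the canonical table via a
#' [localization_schema()]. Rows whose mandatory values fail numeric
#' conversion are kept but flagged `fit_ok = FALSE`; their count is
#' attached as attribute `n_flagged`.
#'
#' @param path File path.
#' @param schema A [localization_schema()]; by default the canonical
#'   column names are expected verbatim.
#' @return Canonical localization `data.frame` (nm / photons/um^2 units).
#' @export
read_localizations <- function(path, schema = localization_schema()) {
  stopifnot(inherits(schema, "localization_schema"))
  raw <- utils::read.table(path, header = TRUE, sep = detect_delimiter(path),
                           stringsAsFactors = FALSE, check.names = FALSE)
  cols <- schema$columns
  missing_src <- cols[!(cols %in% names(raw)) &
                        names(cols) %in% mandatory_columns]
  if (length(missing_src))
    stop("missing mandatory columns: ",
         paste(names(missing_src), collapse = ", "))
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (cn in canonical_columns) {
    src <- cols[cn]
    if (is.na(src) || !(src %in% names(raw))) next
    v <- raw[[src]]
    if (cn == "fit_ok") {
      out[[cn]] <- as.logical(v)
      next
    }
    v <- suppressWarnings(as.numeric(v))
    conv <- schema$converters[[cn]]
    if (!is.null(conv))
      v <- v * (if (is.null(conv$scale)) 1 else conv$scale) +
        (if (is.null(conv$offset)) 0 else conv$offset)
    out[[cn]] <- v
  }
  flagged <- rep(FALSE, nrow(out))
  for (cn in intersect(mandatory_columns, names(out)))
    flagged <- flagged | !is.finite(out[[cn]])
  if (is.null(out$fit_ok)) out$fit_ok <- TRUE
  out$fit_ok[flagged] <- FALSE
  attr(out, "n_flagged") <- sum(flagged)
  out
}

#' Write a localization table
#'
#' Comma-delimited, canonical header, full double precision, stable
#' column order; byte-identical output for identical input.
#'
#' @param table Canonical localization `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  ord <- c(intersect(canonical_columns, names(table)),
           setdiff(names(table), canonical_columns))
  tab <- table[, ord, drop = FALSE]
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) formatC(v, digits = 17,
                                                   format = "g"))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

stack_sidecars <- function(path) {
  stem <- sub("\\.tiff?$", "", path, ignore.case = TRUE)
  list(z = paste0(stem, ".z.csv"), truth = paste0(stem, ".truth.csv"))
}

#' Write an image stack as multi-page TIFF with sidecars
#'
#' Frames are written as 16-bit unsigned grayscale. For calibration
#' stacks the per-frame z table goes to `<stem>.z.csv`; the ground-truth
#' emitter table, when present, to `<stem>.truth.csv` (with `on_frames`
#' flattened to a `;`-separated string).
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  pages <- lapply(stack$frames, function(f)
    pmin(pmax(round(f), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  sc <- stack_sidecars(path)
  if (!is.null(stack$z_per_frame))
    utils::write.csv(data.frame(frame = seq_along(stack$z_per_frame),
                                z_nm = stack$z_per_frame),
                     sc$z, row.names = FALSE)
  if (!is.null(stack$truth)) {
    tr <- stack$truth
    if (!is.null(tr$on_frames))
      tr$on_frames <- vapply(tr$on_frames, paste, character(1),
                             collapse = ";")
    utils::write.csv(tr, sc$truth, row.names = FALSE)
  }
  invisible(path)
}

#' Read an image stack from multi-page TIFF
#'
#' Sidecar z and truth tables are discovered by naming convention
#' (`<stem>.z.csv`, `<stem>.truth.csv`) and attached when present.
#'
#' @param path TIFF path.
#' @param camera A [camera_model()] describing the acquisition (TIFF
#'   carries no calibrated metadata).
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, camera = camera_model()) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) stop("TIFF contains no pages")
  if (any(vapply(pages, function(p) length(dim(p)) != 2, logical(1))))
    stop("only single-channel grayscale TIFF stacks are supported")
  frames <- lapply(pages, function(p) matrix(as.numeric(p), nrow(p), ncol(p)))
  sc <- stack_sidecars(path)
  z <- NULL; truth <- NULL
  if (file.exists(sc$z)) {
    zt <- utils::read.csv(sc$z)
    if (nrow(zt) != length(frames))
      stop("z sidecar length does not match the frame count")
    z <- zt$z_nm
  }
  if (file.exists(sc$truth)) {
    truth <- utils::read.csv(sc$truth, stringsAsFactors = FALSE)
    if (!is.null(truth$on_frames))
      truth$on_frames <- lapply(strsplit(as.character(truth$on_frames), ";"),
                                as.integer)
  }
  frame_stack(frames, camera, z_per_frame = z, truth = truth)
}

#' Persist a calibration as JSON
#'
#' @param calibration A `vls_calibration_set` or single `vls_calibration`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calibration, path) {
  modes <- if (inherits(calibration, "vls_calibration_set"))
    calibration$modes
  else list(calibration)
  payload <- list(
    format = "vls-calibration",
    format_version = 1L,
    vls = list(z0_nm = modes[[1]]$z0,
               half_thickness_nm = modes[[1]]$half_thickness),
    modes = lapply(modes, function(m)
      list(mode = m$mode, width_max_nm = m$width_max_nm,
           amplitude_min_photons_um2 = m$amplitude_min_photons_um2,
           target_confidence = m$target_confidence,
           achieved_confidence = m$achieved_confidence,
           achieved_recall = m$achieved_recall,
           n_localizations = m$n_localizations)))
  names(payload$modes) <- vapply(modes, `[[`, character(1), "mode")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a calibration JSON file
#'
#' @param path Path written by [write_calibration()].
#' @return List with `vls` bounds and one `vls_calibration` per mode.
#' @export
read_calibration <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "vls-calibration")
    stop("not a vls calibration file")
  modes <- lapply(p$modes, function(m) {
    structure(list(mode = m$mode, z0 = p$vls$z0_nm,
                   half_thickness = p$vls$half_thickness_nm,
                   width_max_nm = m$width_max_nm,
                   amplitude_min_photons_um2 = m$amplitude_min_photons_um2,
                   target_confidence = m$target_confidence,
                   achieved_confidence = m$achieved_confidence,
                   achieved_recall = m$achieved_recall,
                   n_localizations = m$n_localizations),
              class = "vls_calibration")
  })
  list(vls = p$vls, modes = modes, format_version = p$format_version)
}

#' Read a configuration file
#'
#' YAML or JSON, by extension. Command-line flags are expected to
#' override configuration keys (flag > config > default).
#'
#' @param path Config path (`.yaml`/`.yml`/`.json`).
#' @return Named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}
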