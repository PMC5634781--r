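#' Read and validate a cell table
#'
#' Cell tables are comma-separated with a single header row and columns
#' `cell_id`, `clone_id`, `zone`, `t_h`, `x_um`, `y_um`,
#' `minor_axis_dx`, `minor_axis_dy` (`t_h` may be empty for static
#' tissue). Coordinates are micrometres in the tissue frame (PD = +y).
#'
#' @param path file path.
#' @return Validated data.frame.
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cell_id", "clone_id", "zone", "t_h", "x_um", "y_um",
           "minor_axis_dx", "minor_axis_dy")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("cell table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c("x_um", "y_um", "minor_axis_dx", "minor_axis_dy")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad)) {
      stop("cell table ", path, ": non-finite `", col, "` at row ", bad[1],
           call. = FALSE)
    }
  }
  nrm <- sqrt(df$minor_axis_dx^2 + df$minor_axis_dy^2)
  bad <- which(nrm < .Machine$double.eps)
  if (length(bad)) {
    stop("cell table ", path, ": zero-length minor axis at row ", bad[1],
         call. = FALSE)
  }
  df
}

#' Write a cell table
#' @param cells cell table data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a sister-track table
#'
#' Track tables are comma-separated with columns `pair_id`, `t_h`,
#' `x1_um`, `y1_um`, `x2_um`, `y2_um`; within each pair, `t_h` must be
#' strictly increasing (duplicated time points are rejected).
#'
#' @param path file path.
#' @return List of single-pair track data.frames, named by `pair_id`.
#' @export
read_track_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("pair_id", "t_h", "x1_um", "y1_um", "x2_um", "y2_um")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("track table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in req[-1]) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad)) {
      stop("track table ", path, ": non-finite `", col, "` at row ", bad[1],
           call. = FALSE)
    }
  }
  tracks <- split(df, df$pair_id)
  lapply(tracks, function(tr) {
    tr <- tr[order(tr$t_h), , drop = FALSE]
    if (any(diff(tr$t_h) <= 0)) {
      stop("track table ", path, ": non-increasing or duplicated t_h for pair ",
           tr$pair_id[1], call. = FALSE)
    }
    rownames(tr) <- NULL
    tr
  })
}

#' Write a set of sister tracks as one table
#' @param tracks list of track data.frames or a single track.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(tracks, path) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, function(tr) {
    tr[, c("pair_id", "t_h", "x1_um", "y1_um", "x2_um", "y2_um")]
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a multi-page TIFF image stack
#'
#' Stacks are stored as 32-bit float TIFF, one page per time point;
#' intensities must lie in \[0, 1\] for writing (the renderer's default
#' levels do).
#'
#' @param path file path.
#' @return `read_stack`: list of numeric matrices.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p
  })
}

#' @rdname read_stack
#' @param frames list of numeric matrices (or a `"frame_stack"`).
#' @export
write_stack <- function(frames, path) {
  mx <- max(vapply(frames, max, numeric(1)))
  if (mx > 1) {
    stop("intensities exceed 1; rescale before writing a float TIFF",
         call. = FALSE)
  }
  tiff::writeTIFF(unclass(frames), path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a polygonal ROI file
#'
#' ROIs are JSON: either one polygon (`[[x, y], ...]`) or a named list of
#' polygons, in image pixel coordinates.
#'
#' @param path file path.
#' @return A single m x 2 matrix, or a named list of such matrices.
#' @export
read_roi <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_poly <- function(p) {
    m <- as.matrix(p)
    if (ncol(m) != 2L) stop("ROI polygons must be m x 2", call. = FALSE)
    storage.mode(m) <- "double"
    m
  }
  if (is.list(obj) && !is.data.frame(obj)) lapply(obj, as_poly) else as_poly(obj)
}

#' Analysis run configuration
#'
#' Centralizes the classification constants and geometry parameters of a
#' pipeline run. Round-trips losslessly through JSON
#' ([write_config()] / [read_config()]).
#'
#' @param phi_sd_threshold_deg stacked-vs-arbitrary SD threshold (degrees).
#' @param theta_sd_threshold_deg single-vs-multi SD threshold (degrees).
#' @param dip_threshold contact-call dip threshold.
#' @param complete_range,partial_range pivot classification bands (degrees).
#' @param cell_radius_um polygon expansion / rendering radius.
#' @param pixel_size_um physical pixel size for image frames.
#' @param seed integer master seed.
#' @param output_dir optional output directory.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(phi_sd_threshold_deg = 12, theta_sd_threshold_deg = 12,
                       dip_threshold = 0.5, complete_range = c(70, 100),
                       partial_range = c(30, 70), cell_radius_um = 5,
                       pixel_size_um = 0.5, seed = 1L, output_dir = NULL) {
  for (nm in c("phi_sd_threshold_deg", "theta_sd_threshold_deg",
               "dip_threshold", "cell_radius_um", "pixel_size_um")) {
    stopifnot_scalar(get(nm), nm, positive = TRUE)
  }
  structure(list(phi_sd_threshold_deg = phi_sd_threshold_deg,
                 theta_sd_threshold_deg = theta_sd_threshold_deg,
                 dip_threshold = dip_threshold,
                 complete_range = complete_range,
                 partial_range = partial_range,
                 cell_radius_um = cell_radius_um,
                 pixel_size_um = pixel_size_um,
                 seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `"run_config"`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$seed <- as.integer(obj$seed)
  do.call(run_config, obj)
}
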