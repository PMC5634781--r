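#' Minor-axis orientation angle Phi of a cell
#'
#' Computes the angle Phi between a cell's minor axis and the tissue
#' proximodistal (PD) axis. Both axes are undirected, so the result is the
#' acute angle, folded to \[0, 90\] degrees; `Phi(v) == Phi(-v)`.
#'
#' In columnar proliferative-zone chondrocytes the minor axis of the
#' flattened cell body points along the direction of stacking, so a tight
#' clustering of Phi near 0 is the signature of a proximodistally stacked
#' clone, while resting-zone clones show near-uniform Phi.
#'
#' @param minor_axis numeric length-2 vector: the cell's minor axis in the
#'   tissue plane (need not be normalized; zero length is an error).
#' @param pd_axis numeric length-2 vector: the proximodistal axis
#'   (default `c(0, 1)`, the package convention).
#' @return Angle in degrees in \[0, 90\].
#' @examples
#' measure_phi(c(0, 1))           # parallel to PD axis -> 0
#' measure_phi(c(1, 0))           # mediolateral -> 90
#' measure_phi(c(1, 1) / sqrt(2)) # 45
#' @export
measure_phi <- function(minor_axis, pd_axis = c(0, 1)) {
  axial_angle_deg(minor_axis, pd_axis)
}

#' Classify a clone as stacked or arbitrarily arranged
#'
#' The standard deviation of the per-cell minor-axis angles Phi within one
#' clone separates stacked clones (cells aligned in rows, low SD) from
#' arbitrarily arranged clones (high SD). The default threshold is 12
#' degrees; SD exactly at the threshold counts as stacked.
#'
#' @param cells data.frame of the cells of one clone with columns
#'   `x_um`, `y_um`, `minor_axis_dx`, `minor_axis_dy` (see
#'   [read_cell_table()] for the full table schema), or a numeric vector of
#'   precomputed Phi angles in degrees.
#' @param threshold_deg classification threshold on the sample SD of Phi
#'   (degrees, default 12).
#' @param pd_axis proximodistal axis, default `c(0, 1)`.
#' @return A list of class `"clone_arrangement"` with elements `phi_deg`
#'   (per-cell angles), `phi_sd_deg`, `arrangement` (`"stacked"` or
#'   `"arbitrary"`), and `threshold_deg`.
#' @details The clone must have more than two cells: an SD over one or two
#'   angles carries no information about arrangement. Sample SD uses the
#'   n - 1 denominator.
#' @export
classify_clone_arrangement <- function(cells, threshold_deg = 12,
                                       pd_axis = c(0, 1)) {
  stopifnot_scalar(threshold_deg, "threshold_deg", positive = TRUE)
  if (is.numeric(cells)) {
    phi <- as.numeric(cells)
  } else {
    phi <- vapply(seq_len(nrow(cells)), function(i) {
      measure_phi(c(cells$minor_axis_dx[i], cells$minor_axis_dy[i]), pd_axis)
    }, numeric(1))
  }
  if (length(phi) <= 2L) {
    stop("clone arrangement requires more than two cells (got ",
         length(phi), ")", call. = FALSE)
  }
  if (any(!is.finite(phi))) stop("non-finite Phi angle", call. = FALSE)
  s <- stats::sd(phi)
  structure(
    list(phi_deg = phi, phi_sd_deg = s,
         arrangement = if (s <= threshold_deg) "stacked" else "arbitrary",
         threshold_deg = threshold_deg),
    class = "clone_arrangement"
  )
}

#' @noRd
#' Index of the topmost cell: maximal PD coordinate; ties broken by smaller
#' ML coordinate, then by cell_id for determinism.
topmost_index <- function(xy, pd_axis = c(0, 1), cell_id = NULL) {
  pd_axis <- pd_axis / sqrt(sum(pd_axis^2))
  ml_axis <- c(pd_axis[2], -pd_axis[1])
  pd_coord <- xy %*% pd_axis
  ml_coord <- xy %*% ml_axis
  if (is.null(cell_id)) cell_id <- seq_len(nrow(xy))
  ord <- order(-pd_coord, ml_coord, cell_id)
  ord[1L]
}

#' Topmost-cell orientation angles theta of a stacked clone
#'
#' For a stacked clone, theta_i is the axial angle between the segment from
#' the topmost cell (largest proximodistal coordinate) to cell i and the
#' proximodistal axis, folded to \[0, 90\] degrees. A low within-clone SD of
#' theta means all cells sit below one another (a single column); lateral
#' neighbours push theta toward 90 and inflate the SD (a multi-column).
#'
#' @param cells data.frame with `x_um`, `y_um` (and optionally `cell_id`
#'   used for deterministic tie-breaks), or an n x 2 coordinate matrix.
#' @param pd_axis proximodistal axis, default `c(0, 1)`.
#' @return Numeric vector of n - 1 angles in degrees in \[0, 90\], one per
#'   non-topmost cell, in the input order of those cells. Attribute
#'   `"topmost"` carries the row index of the topmost cell.
#' @export
measure_theta <- function(cells, pd_axis = c(0, 1)) {
  if (is.data.frame(cells)) {
    xy <- cbind(cells$x_um, cells$y_um)
    id <- if (!is.null(cells$cell_id)) cells$cell_id else NULL
  } else {
    xy <- as.matrix(cells)
    id <- NULL
  }
  if (nrow(xy) < 2L) stop("theta requires at least two cells", call. = FALSE)
  top <- topmost_index(xy, pd_axis, id)
  others <- setdiff(seq_len(nrow(xy)), top)
  theta <- vapply(others, function(i) {
    seg <- xy[i, ] - xy[top, ]
    if (all(seg == 0)) {
      stop("coincident centroids: theta undefined", call. = FALSE)
    }
    axial_angle_deg(seg, pd_axis)
  }, numeric(1))
  attr(theta, "topmost") <- top
  theta
}

#' Classify a stacked clone as a single or multi-width column
#'
#' Applies the SD-of-theta rule: if the sample SD of the topmost-cell
#' angles theta is at or below `threshold_deg` (default 12) the clone is a
#' `"single"` column, otherwise `"multi"`.
#'
#' @param theta_deg numeric vector of theta angles (degrees), as returned
#'   by [measure_theta()].
#' @param threshold_deg SD threshold in degrees (default 12).
#' @return List with `width_class` (`"single"`/`"multi"`), `theta_sd_deg`,
#'   and `low_confidence` (`TRUE` when only one theta is available, i.e. a
#'   two-cell clone, where the SD is undefined and `"single"` is assigned
#'   by convention).
#' @export
classify_column_width <- function(theta_deg, threshold_deg = 12) {
  stopifnot_scalar(threshold_deg, "threshold_deg", positive = TRUE)
  if (length(theta_deg) < 1L) {
    stop("no theta angles supplied", call. = FALSE)
  }
  if (length(theta_deg) == 1L) {
    return(list(width_class = "single", theta_sd_deg = NA_real_,
                low_confidence = TRUE))
  }
  s <- stats::sd(theta_deg)
  list(width_class = if (s <= threshold_deg) "single" else "multi",
       theta_sd_deg = s, low_confidence = FALSE)
}

#' Border polygon of a clone
#'
#' Approximates the manually drawn column border as the convex hull of the
#' cell centroids expanded by the cell radius: each centroid contributes a
#' circle of boundary points and the hull of all of them is returned. Two
#' cells yield (a polygonal approximation of) a stadium; collinear clones
#' degrade gracefully because the radius gives the hull finite width.
#'
#' @param cells data.frame with `x_um`, `y_um`, or an n x 2 matrix of
#'   centroids (micrometres).
#' @param cell_radius_um expansion radius in micrometres (default 5).
#' @param n_circle number of boundary samples per circle (default 64).
#' @return An m x 2 matrix of polygon vertices (columns `x_um`, `y_um`),
#'   counter-clockwise, not closed (first vertex not repeated), of class
#'   `"column_polygon"`.
#' @export
column_polygon <- function(cells, cell_radius_um = 5, n_circle = 64L) {
  stopifnot_scalar(cell_radius_um, "cell_radius_um", positive = TRUE)
  xy <- if (is.data.frame(cells)) cbind(cells$x_um, cells$y_um) else as.matrix(cells)
  if (nrow(xy) < 2L) stop("polygon requires at least two cells", call. = FALSE)
  if (all(abs(sweep(xy, 2, xy[1, ])) < 1e-12)) {
    stop("all centroids coincident: column polygon undefined", call. = FALSE)
  }
  ang <- seq(0, 2 * pi, length.out = n_circle + 1L)[-(n_circle + 1L)]
  circ <- cbind(cos(ang), sin(ang)) * cell_radius_um
  pts <- do.call(rbind, lapply(seq_len(nrow(xy)), function(i) {
    sweep(circ, 2, xy[i, ], `+`)
  }))
  h <- grDevices::chull(pts)          # clockwise; reverse for CCW
  poly <- pts[rev(h), , drop = FALSE]
  colnames(poly) <- c("x_um", "y_um")
  class(poly) <- c("column_polygon", class(poly))
  poly
}

#' @noRd
#' Area and second central moments of a simple polygon (shoelace /
#' Green's-theorem formulas). Vertices as n x 2 matrix, not closed.
polygon_moments <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  if (abs(A) < .Machine$double.eps) {
    stop("degenerate polygon with zero area", call. = FALSE)
  }
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  # raw second moments about the origin
  Ixx <- sum((x^2 + x * xn + xn^2) * cr) / 12
  Iyy <- sum((y^2 + y * yn + yn^2) * cr) / 12
  Ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  # central moments (positive for CCW orientation; normalize by sign of A)
  s <- sign(A)
  list(area = abs(A), centroid = c(cx, cy),
       mu_xx = s * Ixx - abs(A) * cx^2,
       mu_yy = s * Iyy - abs(A) * cy^2,
       mu_xy = s * Ixy - abs(A) * cx * cy)
}

#' Orientation of a column polygon relative to the proximodistal axis
#'
#' The major axis of the polygon is the principal axis of its area (from
#' the second central area moments); the returned orientation is the acute
#' angle between that axis and the proximodistal axis, in \[0, 90\]
#' degrees. Columns lying along the growth direction score near 0.
#'
#' @param poly polygon vertex matrix as returned by [column_polygon()].
#' @param pd_axis proximodistal axis, default `c(0, 1)`.
#' @param iso_tol relative tolerance below which the two principal moments
#'   are considered equal (isotropic shape, e.g. a circle), in which case
#'   the orientation is undefined: 0 is returned with attribute
#'   `"undefined" = TRUE`.
#' @return Angle in degrees in \[0, 90\], with attribute `"undefined"`.
#' @export
column_orientation <- function(poly, pd_axis = c(0, 1), iso_tol = 1e-6) {
  m <- polygon_moments(poly)
  num <- 2 * m$mu_xy
  den <- m$mu_xx - m$mu_yy
  scale <- m$mu_xx + m$mu_yy   # > 0 for a non-degenerate area
  if (sqrt(num^2 + den^2) <= iso_tol * scale) {
    out <- 0
    attr(out, "undefined") <- TRUE
    return(out)
  }
  # principal (major) axis angle from +x, in degrees
  major <- rad2deg(0.5 * atan2(num, den))
  out <- fold_quarter_turn(major - rad2deg(atan2(pd_axis[2], pd_axis[1])))
  attr(out, "undefined") <- FALSE
  out
}

#' Per-clone morphology summary of a cell table
#'
#' Runs the full clone-morphology quantification over a cell table: per
#' clone, the SD of Phi and the stacked/arbitrary call; for stacked clones,
#' the SD of theta and the single/multi width call, and the orientation of
#' the radius-expanded border polygon. Clones with two or fewer cells are
#' reported with `arrangement = NA` (too few cells to classify).
#'
#' @param cells cell table as returned by [generate_tissue()] or
#'   [read_cell_table()].
#' @param phi_threshold_deg SD-of-Phi threshold (degrees, default 12).
#' @param theta_threshold_deg SD-of-theta threshold (degrees, default 12).
#' @param cell_radius_um polygon expansion radius (micrometres, default 5).
#' @param pd_axis proximodistal axis, default `c(0, 1)`.
#' @return data.frame with one row per clone: `clone_id`, `n_cells`,
#'   `phi_sd_deg`, `arrangement`, `theta_sd_deg`, `width_class`,
#'   `orientation_deg`, `orientation_undefined`.
#' @export
summarize_clones <- function(cells, phi_threshold_deg = 12,
                             theta_threshold_deg = 12, cell_radius_um = 5,
                             pd_axis = c(0, 1)) {
  ids <- unique(cells$clone_id)
  if (length(ids) == 0L) {
    warning("empty cell table: returning empty clone summary", call. = FALSE)
    return(data.frame(clone_id = character(0), n_cells = integer(0),
                      phi_sd_deg = numeric(0), arrangement = character(0),
                      theta_sd_deg = numeric(0), width_class = character(0),
                      orientation_deg = numeric(0),
                      orientation_undefined = logical(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(ids, function(cl) {
    cc <- cells[cells$clone_id == cl, , drop = FALSE]
    n <- nrow(cc)
    out <- data.frame(clone_id = cl, n_cells = n, phi_sd_deg = NA_real_,
                      arrangement = NA_character_, theta_sd_deg = NA_real_,
                      width_class = NA_character_,
                      orientation_deg = NA_real_,
                      orientation_undefined = NA,
                      stringsAsFactors = FALSE)
    if (n <= 2L) return(out)
    arr <- classify_clone_arrangement(cc, phi_threshold_deg, pd_axis)
    out$phi_sd_deg <- arr$phi_sd_deg
    out$arrangement <- arr$arrangement
    if (arr$arrangement == "stacked") {
      th <- measure_theta(cc, pd_axis)
      wd <- classify_column_width(th, theta_threshold_deg)
      out$theta_sd_deg <- wd$theta_sd_deg
      out$width_class <- wd$width_class
      poly <- column_polygon(cc, cell_radius_um)
      o <- column_orientation(poly, pd_axis)
      out$orientation_deg <- as.numeric(o)
      out$orientation_undefined <- isTRUE(attr(o, "undefined"))
    }
    out
  })
  do.call(rbind, rows)
}

#' Zone-level Phi summary
#'
#' The zone mean of Phi can be taken either over all cells pooled or by
#' first averaging within clones; the two differ when clone sizes vary, and
#' both are reported.
#'
#' @param cells cell table with `zone` and `clone_id` columns.
#' @param pd_axis proximodistal axis, default `c(0, 1)`.
#' @return data.frame with one row per zone: `zone`, `n_cells`, `n_clones`,
#'   `phi_mean_pooled_deg`, `phi_mean_of_clone_means_deg`, `phi_sd_pooled_deg`.
#' @export
summarize_phi_by_zone <- function(cells, pd_axis = c(0, 1)) {
  phi <- vapply(seq_len(nrow(cells)), function(i) {
    measure_phi(c(cells$minor_axis_dx[i], cells$minor_axis_dy[i]), pd_axis)
  }, numeric(1))
  zones <- unique(cells$zone)
  do.call(rbind, lapply(zones, function(z) {
    sel <- cells$zone == z
    cm <- tapply(phi[sel], cells$clone_id[sel], mean)
    data.frame(zone = z, n_cells = sum(sel), n_clones = length(cm),
               phi_mean_pooled_deg = mean(phi[sel]),
               phi_mean_of_clone_means_deg = mean(cm),
               phi_sd_pooled_deg = stats::sd(phi[sel]),
               stringsAsFactors = FALSE)
  }))
}
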