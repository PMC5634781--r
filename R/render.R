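#' Specification of rendered sister-pair frames
#'
#' Describes how [render_pair_frames()] turns a sister track into an image
#' stack: two uniform disks ("cell bodies") on a background, an interior
#' cytoplasmic bridge filling the capsule between the bodies while the
#' pair is in contact, and an optional thin junctional band at the
#' interface midline. Bodies are disks, not ellipses: shape anisotropy
#' only matters for orientation measurements, which the analysis takes
#' from the cell table, so the intensity operations can be tested on a
#' geometry whose integrals are available in closed form.
#'
#' Image frame convention: origin top-left, x rightward (columns),
#' y downward (rows), pixel units; the tissue micrometre frame (y up) maps
#' onto it via `pixel_size_um` with y negated and the tissue origin at the
#' image centre (see [um_to_px()]).
#'
#' @param image_size_px integer `c(width, height)` in pixels.
#' @param pixel_size_um physical pixel size (micrometres).
#' @param cell_radius_um body radius (micrometres).
#' @param background_level,cell_level,bridge_level,junction_level
#'   intensities (arbitrary units, >= 0). `junction_level = 0` disables
#'   the band.
#' @param bridge_halfwidth_um half-width of the interior bridge capsule
#'   (micrometres).
#' @param junction_halfwidth_um half-thickness of the junction band along
#'   the sister axis (micrometres).
#' @param contact_gap_um maximal surface gap (distance minus two radii)
#'   at which the pair still counts as in contact.
#' @param noise_sd SD of additive Gaussian noise (intensity units;
#'   negative values are clipped to 0).
#' @return An object of class `"frame_spec"`.
#' @export
frame_spec <- function(image_size_px = c(96L, 96L), pixel_size_um = 0.5,
                       cell_radius_um = 4, background_level = 0.05,
                       cell_level = 0.6, bridge_level = 0.55,
                       junction_level = 0, bridge_halfwidth_um = 2.5,
                       junction_halfwidth_um = 1, contact_gap_um = 0.5,
                       noise_sd = 0.01) {
  if (length(image_size_px) == 1L) image_size_px <- rep(image_size_px, 2)
  if (any(image_size_px < 8)) stop("image_size_px too small", call. = FALSE)
  for (nm in c("background_level", "cell_level", "bridge_level",
               "junction_level", "noise_sd")) {
    stopifnot_scalar(get(nm), nm, nonneg = TRUE)
  }
  stopifnot_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  stopifnot_scalar(cell_radius_um, "cell_radius_um", positive = TRUE)
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um,
                 cell_radius_um = cell_radius_um,
                 background_level = background_level,
                 cell_level = cell_level, bridge_level = bridge_level,
                 junction_level = junction_level,
                 bridge_halfwidth_um = bridge_halfwidth_um,
                 junction_halfwidth_um = junction_halfwidth_um,
                 contact_gap_um = contact_gap_um,
                 noise_sd = noise_sd),
            class = "frame_spec")
}

#' Convert tissue coordinates (micrometres, y up) to image pixel
#' coordinates (x = column, y = row, origin top-left)
#'
#' @param xy_um n x 2 matrix or length-2 vector of tissue coordinates.
#' @param spec a `"frame_spec"`.
#' @return Matrix (or vector) of pixel coordinates in the image frame.
#' @export
um_to_px <- function(xy_um, spec) {
  v <- is.null(dim(xy_um))
  xy <- if (v) matrix(xy_um, ncol = 2) else as.matrix(xy_um)
  W <- spec$image_size_px[1]; H <- spec$image_size_px[2]
  px <- cbind(xy[, 1] / spec$pixel_size_um + W / 2,
              H / 2 - xy[, 2] / spec$pixel_size_um)
  if (v) as.numeric(px) else px
}

#' Render a sister track as an image stack
#'
#' One frame per track sample: two disks at the cell positions; while the
#' pair is in contact (surface gap <= `contact_gap_um`) the capsule
#' between the bodies is filled at `bridge_level` and, if
#' `junction_level > 0`, a thin band at the interface midline is set to
#' the junction level. When separated, the space between the bodies is
#' background. `junction_level` may be a vector with one value per frame
#' (e.g. a decaying junctional signal).
#'
#' @param track single-pair track data.frame (micrometre tissue frame).
#' @param spec a `"frame_spec"`.
#' @param seed integer seed for the additive noise (ignored when
#'   `noise_sd = 0`).
#' @return List of class `"frame_stack"`: numeric matrices
#'   (rows = image y, cols = image x), one per time point, with
#'   attributes `"t_h"` and `"in_contact"` (geometric ground truth).
#' @export
render_pair_frames <- function(track, spec, seed = 1L) {
  validate_track(track)
  n <- nrow(track)
  W <- spec$image_size_px[1]; H <- spec$image_size_px[2]
  jl <- rep_len(spec$junction_level, n)
  r_px <- spec$cell_radius_um / spec$pixel_size_um
  # pixel-centre coordinates in the image frame
  cx <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  cy <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)
  frames <- withr_seed(seed, lapply(seq_len(n), function(k) {
    p1 <- um_to_px(c(track$x1_um[k], track$y1_um[k]), spec)
    p2 <- um_to_px(c(track$x2_um[k], track$y2_um[k]), spec)
    if (any(c(p1, p2) < r_px) || any(c(p1[1], p2[1]) > W - r_px) ||
        any(c(p1[2], p2[2]) > H - r_px)) {
      stop("track coordinates (plus cell radius) fall outside the frame",
           call. = FALSE)
    }
    d1 <- sqrt((cx - p1[1])^2 + (cy - p1[2])^2)
    d2 <- sqrt((cx - p2[1])^2 + (cy - p2[2])^2)
    img <- matrix(spec$background_level, H, W)
    seg <- p2 - p1
    L <- sqrt(sum(seg^2))
    gap_um <- (L * spec$pixel_size_um) - 2 * spec$cell_radius_um
    contact <- gap_um <= spec$contact_gap_um
    if (contact && L > 0) {
      u <- seg / L
      # signed coordinate along the sister axis and distance from it
      s <- (cx - p1[1]) * u[1] + (cy - p1[2]) * u[2]
      perp <- abs((cx - p1[1]) * -u[2] + (cy - p1[2]) * u[1])
      bw <- spec$bridge_halfwidth_um / spec$pixel_size_um
      img[s >= 0 & s <= L & perp <= bw] <- spec$bridge_level
    }
    body <- d1 <= r_px | d2 <= r_px
    img[body] <- spec$cell_level
    if (contact && L > 0 && jl[k] > 0) {
      u <- seg / L
      s <- (cx - p1[1]) * u[1] + (cy - p1[2]) * u[2]
      perp <- abs((cx - p1[1]) * -u[2] + (cy - p1[2]) * u[1])
      jw <- spec$junction_halfwidth_um / spec$pixel_size_um
      # the junctional (membrane) band overlays the interface, bodies included
      img[abs(s - L / 2) <= jw & perp <= r_px] <- jl[k]
    }
    if (spec$noise_sd > 0) {
      img <- pmax(img + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W), 0)
    }
    img
  }))
  truth <- attr(track, "truth")
  attr(frames, "t_h") <- track$t_h
  attr(frames, "in_contact") <- vapply(seq_len(n), function(k) {
    d <- sqrt((track$x2_um[k] - track$x1_um[k])^2 +
              (track$y2_um[k] - track$y1_um[k])^2)
    (d - 2 * spec$cell_radius_um) <= spec$contact_gap_um
  }, logical(1))
  attr(frames, "spec") <- spec
  class(frames) <- "frame_stack"
  frames
}
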