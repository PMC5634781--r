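#' Intensity profile along a polyline
#'
#' Samples an image along a polyline at sub-pixel steps (default half a
#' pixel) with bilinear interpolation, averaging across a perpendicular
#' band of `width_px` pixels, and normalizes by the maximum along the
#' line (F/Fmax). This is the kymograph primitive used to follow the
#' cytoplasmic signal between two sister-cell nuclei.
#'
#' @param frame numeric matrix (rows = image y, cols = image x).
#' @param waypoints m x 2 matrix of polyline vertices in image pixel
#'   coordinates (x = column, y = row), m >= 2, inside the frame.
#' @param width_px width of the averaging band in pixels (odd values
#'   centre the band on the path).
#' @param step_px sampling step along the path (default 0.5 pixel).
#' @return An object of class `"line_profile"`: data.frame with
#'   `position_um` unavailable here, so `position_px` (arc length along
#'   the path), `intensity` (band-averaged), `f_over_fmax`. Attribute
#'   `"flat_zero"` flags an all-zero line (F/Fmax undefined, set to `NA`).
#' @export
polyline_profile <- function(frame, waypoints, width_px = 3L, step_px = 0.5) {
  wp <- as.matrix(waypoints)
  if (nrow(wp) < 2L) stop("polyline needs at least two waypoints", call. = FALSE)
  H <- nrow(frame); W <- ncol(frame)
  if (any(wp[, 1] < 0.5) || any(wp[, 1] > W - 0.5) ||
      any(wp[, 2] < 0.5) || any(wp[, 2] > H - 0.5)) {
    stop("waypoints outside the frame", call. = FALSE)
  }
  seglen <- sqrt(rowSums((wp[-1, , drop = FALSE] -
                          wp[-nrow(wp), , drop = FALSE])^2))
  if (any(seglen == 0)) stop("zero-length polyline segment", call. = FALSE)
  total <- sum(seglen)
  pos <- seq(0, total, by = step_px)
  if (pos[length(pos)] < total) pos <- c(pos, total)
  cum <- c(0, cumsum(seglen))
  # point and unit tangent at each arc-length position
  idx <- pmin(findInterval(pos, cum, rightmost.closed = TRUE),
              length(seglen))
  frac <- (pos - cum[idx]) / seglen[idx]
  pts <- wp[idx, , drop = FALSE] +
    (wp[idx + 1L, , drop = FALSE] - wp[idx, , drop = FALSE]) * frac
  tang <- (wp[idx + 1L, , drop = FALSE] - wp[idx, , drop = FALSE]) / seglen[idx]
  normal <- cbind(-tang[, 2], tang[, 1])
  offsets <- seq_len(width_px) - (width_px + 1) / 2
  acc <- numeric(length(pos))
  for (o in offsets) {
    acc <- acc + bilinear_sample(frame, pts + o * normal)
  }
  intensity <- acc / length(offsets)
  mx <- max(intensity)
  flat_zero <- mx <= 0
  prof <- data.frame(position_px = pos, intensity = intensity,
                     f_over_fmax = if (flat_zero) NA_real_ else intensity / mx)
  attr(prof, "flat_zero") <- flat_zero
  class(prof) <- c("line_profile", class(prof))
  prof
}

#' @noRd
#' Bilinear interpolation of `frame` at pixel coordinates `pts`
#' (x = column, y = row; pixel centres at half-integers). Coordinates are
#' clamped to the valid interpolation domain.
bilinear_sample <- function(frame, pts) {
  H <- nrow(frame); W <- ncol(frame)
  x <- pmin(pmax(pts[, 1], 0.5), W - 0.5) - 0.5
  y <- pmin(pmax(pts[, 2], 0.5), H - 0.5) - 0.5
  x0 <- pmin(floor(x), W - 2L); y0 <- pmin(floor(y), H - 2L)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1L, x0 + 1L)
  v00 <- frame[i00]
  v10 <- frame[cbind(y0 + 1L, x0 + 2L)]
  v01 <- frame[cbind(y0 + 2L, x0 + 1L)]
  v11 <- frame[cbind(y0 + 2L, x0 + 2L)]
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}

#' Contact statistic of a sister-pair line profile
#'
#' Operationalizes the flat-vs-inverted-bell criterion: over the central
#' `interior_fraction` of the path (excluding the nuclear endpoints) the
#' dip is `1 - min(F/Fmax)`. A flat profile gives dip 0; a profile falling
#' to background in the middle gives a dip near 1. The pair is called in
#' contact when the dip does not exceed `dip_threshold`.
#'
#' @param profile a `"line_profile"` from [polyline_profile()].
#' @param interior_fraction central fraction of the path examined
#'   (default 0.5).
#' @param dip_threshold maximal dip still called contact (default 0.5).
#' @param t_h optional time stamp carried into the result.
#' @return List of class `"contact_call"`: `t_h`, `dip`, `in_contact`.
#' @export
contact_statistic <- function(profile, interior_fraction = 0.5,
                              dip_threshold = 0.5, t_h = NA_real_) {
  if (isTRUE(attr(profile, "flat_zero"))) {
    stop("all-zero profile: F/Fmax undefined", call. = FALSE)
  }
  pos <- profile$position_px
  total <- pos[length(pos)]
  lo <- total * (1 - interior_fraction) / 2
  hi <- total - lo
  sel <- pos >= lo & pos <= hi
  if (sum(sel) < 2L) stop("interior of the profile has too few samples",
                          call. = FALSE)
  dip <- 1 - min(profile$f_over_fmax[sel])
  structure(list(t_h = t_h, dip = dip, in_contact = dip <= dip_threshold),
            class = "contact_call")
}

#' Contact calls along a frame stack
#'
#' Runs [polyline_profile()] + [contact_statistic()] on every frame of a
#' rendered stack, profiling the straight line between the two cell
#' centres of the accompanying track.
#'
#' @param frames a `"frame_stack"` from [render_pair_frames()].
#' @param track the single-pair track the frames were rendered from.
#' @param width_px,interior_fraction,dip_threshold see
#'   [polyline_profile()] and [contact_statistic()].
#' @return data.frame: `t_h`, `dip`, `in_contact`.
#' @export
contact_timecourse <- function(frames, track, width_px = 3L,
                               interior_fraction = 0.5, dip_threshold = 0.5) {
  spec <- attr(frames, "spec")
  do.call(rbind, lapply(seq_along(frames), function(k) {
    wp <- um_to_px(rbind(c(track$x1_um[k], track$y1_um[k]),
                         c(track$x2_um[k], track$y2_um[k])), spec)
    cc <- contact_statistic(polyline_profile(frames[[k]], wp, width_px),
                            interior_fraction, dip_threshold,
                            t_h = track$t_h[k])
    data.frame(t_h = cc$t_h, dip = cc$dip, in_contact = cc$in_contact)
  }))
}

#' @noRd
#' Logical mask of pixels whose centres lie inside a polygon given in
#' image pixel coordinates (m x 2, x = column, y = row).
polygon_mask <- function(dim_hw, poly) {
  H <- dim_hw[1]; W <- dim_hw[2]
  cx <- rep(seq_len(W) - 0.5, each = H)
  cy <- rep(seq_len(H) - 0.5, times = W)
  m <- pracma::inpolygon(cx, cy, poly[, 1], poly[, 2], boundary = TRUE)
  matrix(m, H, W)
}

#' Junctional / total intensity ratio of a sister pair
#'
#' Background-subtracted ratio of the summed intensity inside the
#' junction region to the summed intensity over the whole sister-pair
#' region. The background is the median intensity outside the pair
#' region. This is the per-image normalization used to compare junctional
#' N-cadherin enrichment across conditions.
#'
#' @param frame numeric image matrix.
#' @param junction_region polygon (m x 2, image pixel coordinates) of the
#'   junctional band; must lie within `pair_region`.
#' @param pair_region polygon covering both sister cells.
#' @param t_h optional time stamp.
#' @return List of class `"junction_measure"`: `t_h`,
#'   `junctional_intensity`, `total_intensity` (both background
#'   subtracted), `ratio` (clipped to \[0, 1\]; `NA` and `undefined = TRUE`
#'   when the total is not positive), `background`.
#' @export
junctional_fraction <- function(frame, junction_region, pair_region,
                                t_h = NA_real_) {
  dimhw <- dim(frame)
  jm <- polygon_mask(dimhw, as.matrix(junction_region))
  pm <- polygon_mask(dimhw, as.matrix(pair_region))
  if (any(jm & !pm)) {
    stop("junction_region must lie inside pair_region", call. = FALSE)
  }
  bg <- stats::median(frame[!pm])
  jsum <- sum(frame[jm] - bg)
  tsum <- sum(frame[pm] - bg)
  undef <- tsum <= 0
  structure(list(t_h = t_h, junctional_intensity = jsum,
                 total_intensity = tsum,
                 ratio = if (undef) NA_real_ else min(1, max(0, jsum / tsum)),
                 background = bg, undefined = undef),
            class = "junction_measure")
}

#' Junctional intensity time course (F/Fmax)
#'
#' Sums the background-subtracted intensity inside a (possibly per-time)
#' junction region for every frame and normalizes by the maximum over the
#' time course (F/Fmax). The cumulative running sum of F/Fmax is emitted
#' as a secondary series.
#'
#' @param frames a `"frame_stack"` or plain list of image matrices.
#' @param junction_regions one polygon, or a list of polygons (one per
#'   frame), in image pixel coordinates.
#' @param pair_regions optional polygon(s) defining the background
#'   exclusion zone; defaults to the junction region(s).
#' @param t_h optional numeric vector of time stamps (defaults to the
#'   stack's `"t_h"` attribute or `seq_along(frames) - 1`).
#' @return data.frame: `t_h`, `junctional_intensity`, `f_over_fmax`,
#'   `cumulative_f_over_fmax`. Attribute `"undefined"` flags a
#'   non-positive maximum (all F/Fmax `NA`).
#' @export
junction_timecourse <- function(frames, junction_regions,
                                pair_regions = NULL, t_h = NULL) {
  n <- length(frames)
  if (n < 2L) stop("time course needs at least two frames", call. = FALSE)
  if (is.null(t_h)) {
    t_h <- attr(frames, "t_h")
    if (is.null(t_h)) t_h <- seq_len(n) - 1
  }
  jr <- if (is.matrix(junction_regions) || is.data.frame(junction_regions))
    rep(list(as.matrix(junction_regions)), n) else junction_regions
  pr <- if (is.null(pair_regions)) jr else
    if (is.matrix(pair_regions) || is.data.frame(pair_regions))
      rep(list(as.matrix(pair_regions)), n) else pair_regions
  raw <- vapply(seq_len(n), function(k) {
    jm <- polygon_mask(dim(frames[[k]]), as.matrix(jr[[k]]))
    pm <- polygon_mask(dim(frames[[k]]), as.matrix(pr[[k]]))
    bg <- stats::median(frames[[k]][!pm])
    sum(frames[[k]][jm] - bg)
  }, numeric(1))
  mx <- max(raw)
  undef <- mx <= 0
  f <- if (undef) rep(NA_real_, n) else pmax(0, raw) / mx
  out <- data.frame(t_h = t_h, junctional_intensity = raw, f_over_fmax = f,
                    cumulative_f_over_fmax = cumsum(ifelse(is.na(f), 0, f)))
  attr(out, "undefined") <- undef
  out
}

#' Pearson colocalization coefficient
#'
#' Product-moment correlation of two intensity channels over the masked
#' pixels: 1 is perfect colocalization, -1 perfect anti-correlation.
#'
#' @param ch1,ch2 numeric vectors or matrices of identical size.
#' @param mask optional logical vector/matrix selecting the pixels to
#'   include (default: all).
#' @return List of class `"coloc_result"`: `r`, `n_px`, `undefined`
#'   (`TRUE`, with `r = NA`, when either channel is constant over the
#'   mask).
#' @export
pearson_colocalization <- function(ch1, ch2, mask = NULL) {
  a <- as.numeric(ch1); b <- as.numeric(ch2)
  if (length(a) != length(b)) stop("channel lengths differ", call. = FALSE)
  if (!is.null(mask)) {
    m <- as.logical(mask)
    a <- a[m]; b <- b[m]
  }
  if (length(a) < 3L) stop("need at least 3 masked pixels", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(structure(list(r = NA_real_, n_px = length(a), undefined = TRUE),
                     class = "coloc_result"))
  }
  structure(list(r = stats::cor(a, b), n_px = length(a), undefined = FALSE),
            class = "coloc_result")
}
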