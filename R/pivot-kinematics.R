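#' Raw pivot angle of a sister-cell pair
#'
#' The pivot angle omega is the angle of the undirected axis through the
#' two sister cells relative to the mediolateral (+x) direction, computed
#' as the two-argument arctangent of (dy, dx) and folded to a half turn,
#' \[0, 180) degrees. 0 means the sisters lie side by side along the
#' mediolateral axis; 90 means they are stacked proximodistally.
#'
#' @param p1,p2 numeric length-2 coordinates (micrometres) of the two
#'   cells; they must not coincide.
#' @return Angle in degrees in \[0, 180).
#' @export
raw_pivot_angle <- function(p1, p2) {
  d <- c(p2[1] - p1[1], p2[2] - p1[2])
  if (all(d == 0)) stop("coincident sister cells: pivot angle undefined",
                        call. = FALSE)
  fold_half_turn(rad2deg(atan2(d[2], d[1])))
}

#' @noRd
#' Unwrap a sequence of half-turn-folded angles (degrees in [0,180)) into a
#' continuous trajectory: each step is chosen within (-90, 90] of the
#' previous unwrapped value. A step of exactly 90 is directionally
#' ambiguous; it is resolved toward the smaller absolute cumulative value
#' and flagged.
unwrap_half_turn <- function(raw) {
  n <- length(raw)
  out <- numeric(n)
  out[1] <- raw[1]
  ambiguous <- FALSE
  for (k in seq_len(n - 1L) + 1L) {
    delta <- (raw[k] - out[k - 1L]) %% 180
    if (delta > 90) delta <- delta - 180
    if (abs(abs(delta) - 90) < 1e-12) {
      # exactly a quarter turn: direction ambiguous; take the one with the
      # smaller absolute cumulative value
      ambiguous <- TRUE
      delta <- if (abs(out[k - 1L] + 90) <= abs(out[k - 1L] - 90)) 90 else -90
    }
    out[k] <- out[k - 1L] + delta
  }
  attr(out, "ambiguous_step") <- ambiguous
  out
}

#' Pivot-angle time series of a sister track
#'
#' Computes the raw pivot angle at every time point of a track, unwraps the
#' half-turn-folded values into a continuous trajectory (successive steps
#' within +/-90 degrees, so cumulative pivots past 90 and up to 180 degrees
#' and beyond are preserved), and normalizes by subtracting the first
#' unwrapped value, so the series starts at exactly 0.
#'
#' @param track a `sister_track`: data.frame with columns `pair_id`, `t_h`,
#'   `x1_um`, `y1_um`, `x2_um`, `y2_um` for a single pair, strictly
#'   increasing `t_h`, at least two samples (see [read_track_table()]).
#' @return An object of class `"pivot_series"`: list with `pair_id`, `t_h`,
#'   `omega_raw_deg` (unwrapped), `omega_deg` (normalized to 0 at the first
#'   sample), `final_omega_deg` (plateau estimate: mean of the last quartile
#'   of samples; the last sample, flagged low-confidence, when fewer than 4
#'   samples), `distance_um` (inter-cell distance per sample), and flags.
#' @export
pivot_angle_series <- function(track) {
  validate_track(track)
  n <- nrow(track)
  raw_folded <- vapply(seq_len(n), function(k) {
    raw_pivot_angle(c(track$x1_um[k], track$y1_um[k]),
                    c(track$x2_um[k], track$y2_um[k]))
  }, numeric(1))
  raw <- unwrap_half_turn(raw_folded)
  omega <- raw - raw[1]
  if (n >= 4L) {
    q <- ceiling(n / 4)
    final <- mean(omega[(n - q + 1L):n])
    lowconf <- FALSE
  } else {
    final <- omega[n]
    lowconf <- TRUE
  }
  structure(
    list(pair_id = track$pair_id[1], t_h = track$t_h,
         omega_raw_deg = as.numeric(raw), omega_deg = as.numeric(omega),
         final_omega_deg = final,
         distance_um = sqrt((track$x2_um - track$x1_um)^2 +
                            (track$y2_um - track$y1_um)^2),
         low_confidence = lowconf,
         ambiguous_step = isTRUE(attr(raw, "ambiguous_step"))),
    class = "pivot_series"
  )
}

#' Classify the pivot outcome of a series
#'
#' Sister pairs that rotate into a proximodistal stack reach a pivot of
#' roughly a quarter turn; the outcome is classified on the magnitude of
#' the plateau estimate `final_omega_deg`: `"complete"` within
#' `complete_range` (default 70-100 degrees, closed), `"partial"` within
#' `partial_range` (default \[30, 70), closed-open), `"none"` otherwise.
#'
#' @param series a `"pivot_series"` from [pivot_angle_series()].
#' @param complete_range length-2 numeric, closed interval (degrees).
#' @param partial_range length-2 numeric, interval closed below and open
#'   above (degrees).
#' @return Character scalar: `"complete"`, `"partial"` or `"none"`.
#' @export
classify_pivot <- function(series, complete_range = c(70, 100),
                           partial_range = c(30, 70)) {
  a <- abs(series$final_omega_deg)
  if (a >= complete_range[1] && a <= complete_range[2]) return("complete")
  if (a >= partial_range[1] && a < partial_range[2]) return("partial")
  "none"
}

#' Division orientation of a sister track
#'
#' Axial angle of the inter-cell axis at the first observed time point
#' relative to the mediolateral direction, folded to \[0, 90\] degrees: 0
#' is a mediolateral division (sisters side by side), 90 a proximodistal
#' one.
#'
#' @param track a single-pair track (see [pivot_angle_series()]).
#' @return Angle in degrees in \[0, 90\].
#' @export
division_orientation <- function(track) {
  fold_quarter_turn(raw_pivot_angle(c(track$x1_um[1], track$y1_um[1]),
                                    c(track$x2_um[1], track$y2_um[1])))
}

#' Pivot summary over a list of tracks
#'
#' @param tracks list of single-pair track data.frames, or one data.frame
#'   with several `pair_id` values (split internally).
#' @param complete_range,partial_range classification bands, see
#'   [classify_pivot()].
#' @return data.frame with one row per pair: `pair_id`, `n_samples`,
#'   `division_orientation_deg`, `final_omega_deg`, `pivot_class`,
#'   `final_distance_um`, `low_confidence`.
#' @export
summarize_pivots <- function(tracks, complete_range = c(70, 100),
                             partial_range = c(30, 70)) {
  if (is.data.frame(tracks)) {
    tracks <- split(tracks, tracks$pair_id)
  }
  do.call(rbind, lapply(tracks, function(tr) {
    tr <- tr[order(tr$t_h), , drop = FALSE]
    s <- pivot_angle_series(tr)
    data.frame(pair_id = s$pair_id, n_samples = length(s$t_h),
               division_orientation_deg = division_orientation(tr),
               final_omega_deg = s$final_omega_deg,
               pivot_class = classify_pivot(s, complete_range, partial_range),
               final_distance_um = s$distance_um[length(s$distance_um)],
               low_confidence = s$low_confidence,
               stringsAsFactors = FALSE)
  }))
}

#' Long-format omega series table for a set of tracks
#'
#' @inheritParams summarize_pivots
#' @return data.frame with columns `pair_id`, `t_h`, `omega_deg`.
#' @export
pivot_series_table <- function(tracks) {
  if (is.data.frame(tracks)) tracks <- split(tracks, tracks$pair_id)
  do.call(rbind, lapply(tracks, function(tr) {
    tr <- tr[order(tr$t_h), , drop = FALSE]
    s <- pivot_angle_series(tr)
    data.frame(pair_id = s$pair_id, t_h = s$t_h, omega_deg = s$omega_deg,
               stringsAsFactors = FALSE)
  }))
}

#' @noRd
validate_track <- function(track) {
  req <- c("pair_id", "t_h", "x1_um", "y1_um", "x2_um", "y2_um")
  miss <- setdiff(req, names(track))
  if (length(miss)) {
    stop("track is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(track) < 2L) stop("track needs at least two samples", call. = FALSE)
  if (length(unique(track$pair_id)) != 1L) {
    stop("track must contain a single pair_id; use summarize_pivots() for sets",
         call. = FALSE)
  }
  if (any(diff(track$t_h) <= 0)) {
    stop("track time must be strictly increasing", call. = FALSE)
  }
  coords <- as.matrix(track[, c("x1_um", "y1_um", "x2_um", "y2_um")])
  if (any(!is.finite(coords))) stop("non-finite track coordinates", call. = FALSE)
  invisible(track)
}
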