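# Internal angle helpers. Convention throughout the package: the tissue
# proximodistal (PD) axis is +y and the mediolateral (ML) axis is +x of the
# coordinate frame; interface angles are degrees, internals use degrees too
# (folding arithmetic is exact in degrees).

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' @noRd
#' Fold an angle (degrees) to [0, 180): the undirected-axis representative.
fold_half_turn <- function(a) {
  a <- a %% 180
  a[a < 0] <- a[a < 0] + 180
  a
}

#' @noRd
#' Fold an angle (degrees) to [0, 90]: the acute angle between two
#' undirected axes.
fold_quarter_turn <- function(a) {
  a <- fold_half_turn(a)
  ifelse(a > 90, 180 - a, a)
}

#' @noRd
#' Acute angle in degrees between two undirected axes given as vectors.
axial_angle_deg <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 < .Machine$double.eps || n2 < .Machine$double.eps) {
    stop("axial angle undefined for a zero-length vector", call. = FALSE)
  }
  c_ <- abs(sum(v1 * v2)) / (n1 * n2)
  rad2deg(acos(min(1, c_)))
}

#' @noRd
#' Rotate 2D points (n x 2 matrix or length-2 vector) by `deg` degrees CCW.
rotate2d <- function(p, deg) {
  th <- deg2rad(deg)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  if (is.matrix(p)) p %*% t(R) else as.numeric(R %*% p)
}

#' @noRd
#' Unit vector at `deg` degrees from the +x (mediolateral) axis.
unit_from_deg <- function(deg) c(cos(deg2rad(deg)), sin(deg2rad(deg)))

#' @noRd
stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be non-negative", name), call. = FALSE)
  }
  invisible(x)
}
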