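# Independent oracle implementations used to cross-check the package's
# angle and moment machinery. Each deliberately takes a different route
# than the implementation it checks.

# acute angle between undirected axes via atan2 of cross/dot (the package
# uses acos of |dot|)
oracle_axial_angle <- function(v1, v2) {
  cr <- v1[1] * v2[2] - v1[2] * v2[1]
  dt <- v1[1] * v2[1] + v1[2] * v2[2]
  a <- abs(atan2(cr, dt)) * 180 / pi
  if (a > 90) a <- 180 - a
  a
}

# theta from the topmost cell via the arctangent of |dML| / |dPD|
oracle_theta <- function(xy) {
  top <- which(xy[, 2] == max(xy[, 2]))
  if (length(top) > 1) top <- top[which.min(xy[top, 1])]
  sapply(setdiff(seq_len(nrow(xy)), top), function(i) {
    atan2(abs(xy[i, 1] - xy[top, 1]), abs(xy[i, 2] - xy[top, 2])) * 180 / pi
  })
}

# unwrapped, normalized pivot trajectory via complex arguments of the
# squared inter-cell vector ratio (axial angle doubling), instead of the
# package's fold-and-adjust unwrapping
oracle_omega <- function(track) {
  z <- complex(real = track$x2_um - track$x1_um,
               imaginary = track$y2_um - track$y1_um)
  step <- Arg((z[-1] / z[-length(z)])^2) / 2 * 180 / pi
  c(0, cumsum(step))
}

# polygon second central moments by fan triangulation from the first
# vertex (signed triangle moments), then the major-axis angle from the
# leading eigenvector of the moment matrix
oracle_polygon_orientation <- function(poly, pd_axis = c(0, 1)) {
  n <- nrow(poly)
  A <- 0; Sx <- 0; Sy <- 0; Sxx <- 0; Syy <- 0; Sxy <- 0
  for (i in 2:(n - 1)) {
    x <- c(poly[1, 1], poly[i, 1], poly[i + 1, 1])
    y <- c(poly[1, 2], poly[i, 2], poly[i + 1, 2])
    a <- ((x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])) / 2
    A <- A + a
    Sx <- Sx + a * mean(x)
    Sy <- Sy + a * mean(y)
    Sxx <- Sxx + a / 6 * (x[1]^2 + x[2]^2 + x[3]^2 +
                          x[1] * x[2] + x[1] * x[3] + x[2] * x[3])
    Syy <- Syy + a / 6 * (y[1]^2 + y[2]^2 + y[3]^2 +
                          y[1] * y[2] + y[1] * y[3] + y[2] * y[3])
    Sxy <- Sxy + a / 12 * (2 * sum(x * y) + x[1] * y[2] + x[2] * y[1] +
                           x[1] * y[3] + x[3] * y[1] +
                           x[2] * y[3] + x[3] * y[2])
  }
  cx <- Sx / A; cy <- Sy / A
  M <- matrix(c(Sxx - A * cx^2, Sxy - A * cx * cy,
                Sxy - A * cx * cy, Syy - A * cy^2), 2, 2) / A
  ev <- eigen(M)
  major <- ev$vectors[, which.max(ev$values)]
  oracle_axial_angle(major, pd_axis)
}

# two-sample Watson U^2 via stats::ecdf at the pooled points
oracle_u2 <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- sort(c(x, y))
  d <- stats::ecdf(x)(pooled) - stats::ecdf(y)(pooled)
  n1 * n2 / N^2 * sum((d - mean(d))^2)
}

# exact permutation p-value by explicit enumeration of all splits
oracle_u2_exact_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  pooled <- c(x, y)
  obs <- oracle_u2(x, y)
  splits <- utils::combn(N, n1)
  vals <- apply(splits, 2, function(ix) oracle_u2(pooled[ix], pooled[-ix]))
  mean(vals >= obs - 1e-12)
}

# random simple clone for oracle comparisons
random_clone_xy <- function(n) {
  cbind(stats::runif(n, -20, 20), stats::runif(n, -20, 20))
}
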