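#' Construct an angle sample for circular testing
#'
#' Axial data (orientations with period 180 degrees, such as minor-axis or
#' column-orientation angles) are doubled to circular data (period 360)
#' before testing, the standard treatment for axial observations; circular
#' data are used as given modulo 360.
#'
#' @param values_deg numeric vector of angles in degrees.
#' @param kind `"axial"` (period 180) or `"circular"` (period 360).
#' @return Object of class `"angle_sample"`.
#' @export
angle_sample <- function(values_deg, kind = c("axial", "circular")) {
  kind <- match.arg(kind)
  v <- as.numeric(values_deg)
  if (any(!is.finite(v))) stop("non-finite angles", call. = FALSE)
  structure(list(values_deg = v, kind = kind), class = "angle_sample")
}

#' @noRd
#' Angles on the circle (degrees in [0,360)) ready for testing.
circularized <- function(s) {
  if (inherits(s, "angle_sample")) {
    v <- s$values_deg
    if (s$kind == "axial") v <- 2 * v
  } else {
    v <- as.numeric(s)
  }
  v %% 360
}

#' @noRd
#' Two-sample Watson U^2 statistic from pooled sorted positions.
#' `lab_sorted`: logical, TRUE where the pooled order statistic comes from
#' sample 1. Ties (equal pooled values) use the midrank convention: the
#' cumulative-difference value is averaged within each tied block.
#' `tie_group`: integer block index per sorted position.
u2_from_labels <- function(lab_sorted, n1, n2, tie_group = NULL) {
  N <- n1 + n2
  d <- cumsum(lab_sorted) / n1 - cumsum(!lab_sorted) / n2
  if (!is.null(tie_group)) d <- stats::ave(d, tie_group)
  n1 * n2 / N^2 * sum((d - mean(d))^2)
}

#' Two-sample Watson's U-squared test for circular data
#'
#' Nonparametric comparison of two samples of directions or orientations
#' on the circle, based on the squared discrepancy between the two
#' empirical cumulative fractions accumulated around the pooled ordering:
#' `U^2 = n1*n2/N^2 * sum_k (d_k - mean(d))^2`, with `d_k` the difference
#' of empirical cumulative fractions at the k-th pooled point. The
#' centering on `mean(d)` makes the statistic invariant to the choice of
#' origin on the circle. Axial samples are doubled to circular internally
#' (see [angle_sample()]).
#'
#' The null distribution is obtained by permutation of the pooled sample:
#' exhaustively over all `choose(N, n1)` assignments when that count does
#' not exceed `enumeration_cap` (the p-value is then exact), otherwise by
#' `n_permutations` random assignments with the add-one estimator
#' `(1 + #{U^2_perm >= U^2_obs}) / (n_permutations + 1)`.
#'
#' @param a,b `"angle_sample"` objects, or numeric vectors in degrees
#'   (treated as `kind`).
#' @param n_permutations number of random permutations (default 9999).
#' @param seed integer seed for the permutation draw (mandatory for
#'   reproducibility).
#' @param kind interpretation of bare numeric inputs (default axial).
#' @param enumeration_cap largest number of label assignments still
#'   enumerated exhaustively (default 5000).
#' @return List of class `"cc_test"`: `statistic` (U^2), `p_value`,
#'   `method`, `n1`, `n2`, `n_permutations` (`NA` for exhaustive),
#'   `seed`, `ties` (`TRUE` when midranks were used).
#' @export
watson_u2 <- function(a, b, n_permutations = 9999, seed = 1L,
                      kind = c("axial", "circular"),
                      enumeration_cap = 5000) {
  kind <- match.arg(kind)
  if (!inherits(a, "angle_sample")) a <- angle_sample(a, kind)
  if (!inherits(b, "angle_sample")) b <- angle_sample(b, kind)
  x <- circularized(a); y <- circularized(b)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 4L || n2 < 4L) {
    stop("Watson's U2 needs at least 4 observations per sample", call. = FALSE)
  }
  pooled <- c(x, y)
  ord <- order(pooled)
  sorted <- pooled[ord]
  ties <- anyDuplicated(sorted) > 0L
  tie_group <- if (ties) cumsum(c(TRUE, diff(sorted) > 0)) else NULL
  lab <- c(rep(TRUE, n1), rep(FALSE, n2))[ord]
  obs <- u2_from_labels(lab, n1, n2, tie_group)
  N <- n1 + n2
  n_comb <- choose(N, n1)
  eps <- 1e-12
  if (n_comb <= enumeration_cap) {
    combs <- utils::combn(N, n1)
    null_u2 <- apply(combs, 2, function(ix) {
      l <- logical(N); l[ix] <- TRUE
      u2_from_labels(l, n1, n2, tie_group)
    })
    p <- mean(null_u2 >= obs - eps)
    method <- "watson_u2_exhaustive"
    nperm <- NA_integer_
  } else {
    null_u2 <- withr_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        u2_from_labels(sample(lab), n1, n2, tie_group)
      }, numeric(1))
    })
    p <- (1 + sum(null_u2 >= obs - eps)) / (n_permutations + 1)
    method <- "watson_u2_permutation"
    nperm <- as.integer(n_permutations)
  }
  structure(list(statistic = obs, p_value = p, method = method,
                 n1 = n1, n2 = n2, n_permutations = nperm,
                 seed = as.integer(seed), ties = ties),
            class = "cc_test")
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two independent samples, with
#' midranks for ties: exact p-value for small tie-free samples, normal
#' approximation with tie correction otherwise (the standard behaviour of
#' [stats::wilcox.test()], which backs this interface).
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @return `"cc_test"` list: `statistic` (rank-sum W), `p_value`,
#'   `method`, `n1`, `n2`, `degenerate` (`TRUE`, `p = 1`, when all values
#'   of both samples are identical).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 observations per sample", call. = FALSE)
  }
  if (length(unique(c(x, y))) == 1L) {
    return(structure(list(statistic = length(x) * length(y) / 2, p_value = 1,
                          method = "wilcoxon_rank_sum", n1 = length(x),
                          n2 = length(y), degenerate = TRUE),
                     class = "cc_test"))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = "wilcoxon_rank_sum", n1 = length(x),
                 n2 = length(y), degenerate = FALSE),
            class = "cc_test")
}

#' One-sample Kolmogorov-Smirnov normality screen
#'
#' Tests the sample against a normal law with the sample's own mean and
#' SD and recommends the nonparametric path (rank-based tests) when
#' normality is rejected. Because the reference parameters are estimated
#' from the same data, the test is conservative (the Lilliefors caveat);
#' the result is flagged rather than corrected.
#'
#' @param x numeric vector (n >= 5).
#' @param alpha rejection level for the recommendation (default 0.05).
#' @return `"cc_test"` list: `statistic` (D), `p_value`, `method`, `n1`,
#'   `normal` (logical), `recommend` (`"parametric"`/`"nonparametric"`),
#'   `parameters_estimated = TRUE`, `zero_variance`.
#' @export
ks_normality <- function(x, alpha = 0.05) {
  if (length(x) < 5L) stop("normality screen needs n >= 5", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(structure(list(statistic = NA_real_, p_value = 0,
                          method = "ks_normality", n1 = length(x),
                          normal = FALSE, recommend = "nonparametric",
                          parameters_estimated = TRUE, zero_variance = TRUE),
                     class = "cc_test"))
  }
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  normal <- kt$p.value >= alpha
  structure(list(statistic = unname(kt$statistic), p_value = kt$p.value,
                 method = "ks_normality", n1 = length(x), normal = normal,
                 recommend = if (normal) "parametric" else "nonparametric",
                 parameters_estimated = TRUE, zero_variance = FALSE),
            class = "cc_test")
}

#' @export
print.cc_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic =", format(x$statistic, digits = 6),
      " p =", format(x$p_value, digits = 4), "\n")
  ns <- c(x$n1, x$n2)
  cat("  n =", paste(ns[!is.na(ns)], collapse = ", "), "\n")
  invisible(x)
}
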