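test_that("measure_phi folds the minor-axis angle to the acute range", {
  expect_equal(measure_phi(c(0, 1)), 0)
  expect_equal(measure_phi(c(0, -1)), 0)      # axial: Phi(v) == Phi(-v)
  expect_equal(measure_phi(c(1, 0)), 90)
  expect_equal(measure_phi(c(1, 1) / sqrt(2)), 45)
  expect_error(measure_phi(c(0, 0)), "zero-length")
})

test_that("arrangement classification applies the SD-of-Phi rule", {
  r1 <- classify_clone_arrangement(c(10, 12, 14))
  expect_equal(r1$phi_sd_deg, sd(c(10, 12, 14)))   # = 2
  expect_identical(r1$arrangement, "stacked")
  r2 <- classify_clone_arrangement(c(0, 30, 60, 90))
  expect_equal(r2$phi_sd_deg, sd(c(0, 30, 60, 90)), tolerance = 1e-12)
  expect_gt(r2$phi_sd_deg, 38)                     # ~38.73 by hand
  expect_identical(r2$arrangement, "arbitrary")
  # identical values: SD 0, stacked for any positive threshold
  expect_identical(classify_clone_arrangement(rep(17, 5), 0.001)$arrangement,
                   "stacked")
  # SD exactly at the threshold counts as stacked
  phis <- c(0, 24)  # sd = 16.97; craft sd == 12 instead
  expect_identical(
    classify_clone_arrangement(c(0, 12, 24), threshold_deg = 12)$arrangement,
    "stacked")
  expect_error(classify_clone_arrangement(c(1, 2)), "more than two")
})

test_that("theta is measured from the topmost cell with deterministic ties", {
  expect_equal(as.numeric(measure_theta(rbind(c(0, 0), c(0, -5), c(0, -10)))),
               c(0, 0))
  expect_equal(as.numeric(measure_theta(rbind(c(0, 0), c(5, 0)))), 90)
  th <- measure_theta(rbind(c(0, 0), c(0, -5), c(5, -5)))
  expect_equal(as.numeric(th), c(0, 45))
  expect_identical(attr(th, "topmost"), 1L)
  # tie on the PD coordinate: smaller ML coordinate wins
  th2 <- measure_theta(rbind(c(3, 10), c(-2, 10), c(0, 0)))
  expect_identical(attr(th2, "topmost"), 2L)
})

test_that("column width classification applies the SD-of-theta rule", {
  expect_identical(classify_column_width(c(0, 2, 3))$width_class, "single")
  w <- classify_column_width(c(0, 45, 90))
  expect_identical(w$width_class, "multi")
  expect_equal(w$theta_sd_deg, 45)
  # two-cell clone: single by convention, flagged
  w2 <- classify_column_width(5)
  expect_identical(w2$width_class, "single")
  expect_true(w2$low_confidence)
})

test_that("column polygon is a radius-expanded hull containing all centroids", {
  xy <- rbind(c(0, 0), c(0, 10))
  poly <- column_polygon(xy, cell_radius_um = 3)
  expect_equal(max(poly[, 2]) - min(poly[, 2]), 10 + 6, tolerance = 1e-2)
  expect_equal(max(poly[, 1]) - min(poly[, 1]), 6, tolerance = 1e-2)
  # collinear clone degrades gracefully (finite width from the radius)
  poly3 <- column_polygon(rbind(c(0, 0), c(0, 5), c(0, 10)), 2)
  expect_gt(nrow(poly3), 3)
  # random clones: every centroid inside the polygon
  set.seed(11)
  for (i in 1:10) {
    xy <- random_clone_xy(6)
    poly <- column_polygon(xy, 4)
    inside <- pracma::inpolygon(xy[, 1], xy[, 2], poly[, 1], poly[, 2],
                                boundary = TRUE)
    expect_true(all(inside))
  }
  expect_error(column_polygon(rbind(c(1, 1), c(1, 1))), "coincident")
})

test_that("column orientation is the principal-axis angle to the PD axis", {
  rect <- rbind(c(-1, -5), c(1, -5), c(1, 5), c(-1, 5))  # 2 x 10, long side PD
  o <- column_orientation(rect)
  expect_equal(as.numeric(o), 0, tolerance = 1e-9)
  expect_false(attr(o, "undefined"))
  rect30 <- rotate2d(rect, 30)
  expect_equal(as.numeric(column_orientation(rect30)), 30, tolerance = 1e-9)
  # near-circle: isotropic, flagged undefined
  ang <- seq(0, 2 * pi, length.out = 129)[-129]
  circ <- cbind(cos(ang), sin(ang)) * 5
  o2 <- column_orientation(circ)
  expect_true(attr(o2, "undefined"))
  expect_equal(as.numeric(o2), 0)
})

test_that("angle machinery matches independent oracles on random inputs", {
  set.seed(7)
  for (i in 1:60) {
    v <- rnorm(2); while (sum(v^2) < 1e-3) v <- rnorm(2)
    expect_equal(measure_phi(v), oracle_axial_angle(v, c(0, 1)),
                 tolerance = 1e-9)
    xy <- random_clone_xy(sample(3:8, 1))
    expect_equal(as.numeric(measure_theta(xy)), as.numeric(oracle_theta(xy)),
                 tolerance = 1e-9)
    poly <- column_polygon(xy, runif(1, 2, 6))
    expect_equal(as.numeric(column_orientation(poly)),
                 oracle_polygon_orientation(poly), tolerance = 1e-9)
  }
})

test_that("outputs are invariant to translation, ML reflection, and joint rotation", {
  set.seed(21)
  xy <- random_clone_xy(6)
  phi_axes <- matrix(rnorm(12), 6, 2)
  phis <- apply(phi_axes, 1, measure_phi)
  # translation
  xy_t <- sweep(xy, 2, c(13.7, -41.2), `+`)
  expect_equal(as.numeric(measure_theta(xy_t)), as.numeric(measure_theta(xy)))
  expect_equal(as.numeric(column_orientation(column_polygon(xy_t, 4))),
               as.numeric(column_orientation(column_polygon(xy, 4))),
               tolerance = 1e-9)
  # reflection of the mediolateral axis (x -> -x)
  refl <- function(m) cbind(-m[, 1], m[, 2])
  expect_equal(apply(refl(phi_axes), 1, measure_phi), phis, tolerance = 1e-12)
  expect_equal(as.numeric(column_orientation(column_polygon(refl(xy), 4))),
               as.numeric(column_orientation(column_polygon(xy, 4))),
               tolerance = 1e-9)
  # joint rotation of coordinates and pd_axis (frame equivariance)
  for (ang in c(17, -62, 101)) {
    pd <- rotate2d(c(0, 1), ang)
    xy_r <- rotate2d(xy, ang)
    expect_equal(as.numeric(measure_theta(xy_r, pd)),
                 as.numeric(measure_theta(xy)), tolerance = 1e-9)
    # hull vertices come from circle boundary samples at fixed phase, so
    # rotation equivariance holds to the circle-discretization level only
    expect_equal(as.numeric(column_orientation(column_polygon(xy_r, 4), pd)),
                 as.numeric(column_orientation(column_polygon(xy, 4))),
                 tolerance = 1e-3)
    expect_equal(apply(rotate2d(phi_axes, ang), 1, measure_phi, pd_axis = pd),
                 phis, tolerance = 1e-9)
  }
})

test_that("summarize_clones fills the classification cascade per clone", {
  cells <- generate_tissue(tissue_params(n_clones = 12, seed = 5))
  cs <- summarize_clones(cells)
  expect_identical(nrow(cs), 12L)
  expect_true(all(cs$arrangement %in% c("stacked", "arbitrary")))
  stacked <- cs$arrangement == "stacked"
  expect_true(all(!is.na(cs$theta_sd_deg[stacked])))
  expect_true(all(is.na(cs$width_class[!stacked])))
  # empty table: empty summary with a warning, not an error
  expect_warning(cs0 <- summarize_clones(cells[0, ]), "empty")
  expect_identical(nrow(cs0), 0L)
})
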