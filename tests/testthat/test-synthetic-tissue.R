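test_that("generation is deterministic for a fixed seed and validates inputs", {
  p <- tissue_params(n_clones = 10, seed = 42)
  a <- generate_tissue(p)
  b <- generate_tissue(p)
  expect_identical(a, b)
  c2 <- generate_tissue(tissue_params(n_clones = 10, seed = 43))
  expect_false(identical(a$x_um, c2$x_um))
  expect_error(tissue_params(n_clones = 0), "positive")
  expect_error(tissue_params(cells_per_clone = c(0, 4)), "lower bound")
  expect_error(tissue_params(orientation_spread_deg = -1), "non-negative")
})

test_that("zero spread with a fixed stack axis gives exactly constant Phi", {
  p <- tissue_params(n_clones = 5, orientation_spread_deg = 0,
                     column_width = 1, stack_tilt_deg = 0,
                     stack_tilt_sd_deg = 0, seed = 3)
  cells <- generate_tissue(p)
  phi <- apply(cells[, c("minor_axis_dx", "minor_axis_dy")], 1, measure_phi)
  expect_equal(phi, rep(0, nrow(cells)), tolerance = 1e-12)
})

test_that("proliferative tight-spread clones classify stacked, resting arbitrary", {
  cells <- generate_tissue(tissue_params(n_clones = 60,
                                         orientation_spread_deg = 3, seed = 9))
  cs <- summarize_clones(cells)
  expect_gte(mean(cs$arrangement == "stacked"), 0.95)
  rest <- generate_tissue(tissue_params(n_clones = 60, zone = "resting",
                                        seed = 10))
  rs <- summarize_clones(rest)
  expect_gt(mean(rs$phi_sd_deg > 12), 0.8)  # most resting clones exceed 12
})

test_that("clones never overlap and multi-width clones classify multi", {
  p <- tissue_params(n_clones = 40, column_width = 2, seed = 12)
  cells <- generate_tissue(p)
  # no two cells of different clones closer than one cell diameter
  sp <- split(cells, cells$clone_id)
  centers <- t(vapply(sp, function(cc) c(mean(cc$x_um), mean(cc$y_um)),
                      numeric(2)))
  expect_gt(min(dist(centers)), 2 * p$cell_spacing_um)
  cs <- summarize_clones(cells)
  stacked <- cs[cs$arrangement == "stacked", ]
  expect_gte(mean(stacked$width_class == "multi"), 0.9)
})

test_that("pooled Phi SD recovers the orientation spread away from the folds", {
  for (spread in c(5, 10, 20)) {
    cells <- generate_tissue(tissue_params(
      n_clones = 30, orientation_spread_deg = spread, stack_tilt_deg = 45,
      stack_tilt_sd_deg = 0, seed = 100 + spread))
    expect_gt(nrow(cells), 200)
    got <- summarize_phi_by_zone(cells)$phi_sd_pooled_deg
    expect_lt(abs(got - spread) / spread, 0.2)
  }
})

test_that("arbitrary-call fraction is monotone in the orientation spread", {
  frac <- vapply(c(2, 10, 25, 60), function(spread) {
    calls <- unlist(lapply(1:5, function(s) {
      cs <- summarize_clones(generate_tissue(tissue_params(
        n_clones = 20, orientation_spread_deg = spread, seed = s)))
      cs$arrangement == "arbitrary"
    }))
    mean(calls)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
})

test_that("noise-free pivot tracks round-trip through the angle series", {
  tr <- simulate_pivot_track(pivot_scenario(division_angle_deg = 10,
                                            final_pivot_deg = 85,
                                            noise_sd_deg = 0, seed = 1))
  s <- pivot_angle_series(tr)
  expect_equal(s$omega_deg[1], 0)
  expect_equal(s$final_omega_deg, 85, tolerance = 1e-9)
  expect_equal(max(s$omega_deg), 85, tolerance = 1e-9)
  # inter-cell distance constant without separation
  expect_equal(s$distance_um, rep(8, length(s$t_h)), tolerance = 1e-9)
})

test_that("noisy pivots are recovered near the programmed excursion", {
  finals <- vapply(1:20, function(s) {
    tr <- simulate_pivot_track(pivot_scenario(final_pivot_deg = 50,
                                              noise_sd_deg = 3, seed = s))
    pivot_angle_series(tr)$final_omega_deg
  }, numeric(1))
  expect_lt(abs(mean(finals) - 50), 5)
})

test_that("separation grows the inter-cell distance after the set time", {
  tr <- simulate_pivot_track(pivot_scenario(separates = TRUE,
                                            separation_time_h = 3,
                                            noise_sd_deg = 0, seed = 2))
  d <- sqrt((tr$x2_um - tr$x1_um)^2 + (tr$y2_um - tr$y1_um)^2)
  expect_equal(d[tr$t_h <= 3], rep(8, sum(tr$t_h <= 3)), tolerance = 1e-9)
  expect_true(all(diff(d[tr$t_h >= 3]) > 0))
})

test_that("coloc pairs hit exact and statistical correlation targets", {
  p1 <- generate_coloc_pair(1, 500, seed = 4)
  expect_equal(pearson_colocalization(p1$ch1, p1$ch2)$r, 1, tolerance = 1e-12)
  pm <- generate_coloc_pair(-1, 500, seed = 5)
  expect_equal(pearson_colocalization(pm$ch1, pm$ch2)$r, -1, tolerance = 1e-12)
  ph <- generate_coloc_pair(0.5, 1e5, seed = 6)
  expect_lt(abs(pearson_colocalization(ph$ch1, ph$ch2)$r - 0.5), 0.02)
})

test_that("scenario presets encode the four phenotypes and reject unknowns", {
  wt <- scenario_preset("wild_type", seed = 1)
  expect_s3_class(wt$tissue, "tissue_params")
  expect_s3_class(wt$pivot, "pivot_scenario")
  expect_false(wt$pivot$separates)
  expect_true(scenario_preset("pcp_gain", 1)$pivot$separates)
  expect_true(is.na(scenario_preset("pcp_loss", 1)$pivot$division_angle_deg))
  expect_true(scenario_preset("ncad_block", 1)$pivot$separates)
  expect_equal(scenario_preset("pcp_gain", 1)$junction_half_time_h, 5)
  expect_error(scenario_preset("mystery", 1), "unknown")
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_tissue(tissue_params(n_clones = 3, seed = 7)))
  invisible(simulate_pivot_track(pivot_scenario(seed = 8)))
  invisible(generate_coloc_pair(0.3, 100, seed = 9))
  expect_identical(.Random.seed, before)
})
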