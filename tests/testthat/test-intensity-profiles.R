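flat_frame <- function(level = 0.4, n = 40) matrix(level, n, n)

test_that("uniform images give flat profiles with F/Fmax of one", {
  prof <- polyline_profile(flat_frame(), rbind(c(5, 20), c(35, 20)))
  expect_true(all(prof$f_over_fmax == 1))
  expect_equal(prof$intensity, rep(0.4, nrow(prof)), tolerance = 1e-12)
  cc <- contact_statistic(prof)
  expect_equal(cc$dip, 0)
  expect_true(cc$in_contact)
})

test_that("a polyline equals the concatenation of its collinear segments", {
  set.seed(41)
  img <- matrix(runif(60 * 60), 60, 60)
  one <- polyline_profile(img, rbind(c(10, 30), c(50, 30)))
  two <- polyline_profile(img, rbind(c(10, 30), c(30, 30), c(50, 30)))
  expect_equal(two$intensity, one$intensity, tolerance = 1e-12)
  expect_equal(two$position_px, one$position_px, tolerance = 1e-12)
})

test_that("profiles reject bad waypoints and all-zero lines are flagged", {
  expect_error(polyline_profile(flat_frame(), rbind(c(5, 20))), "at least two")
  expect_error(polyline_profile(flat_frame(), rbind(c(-3, 20), c(30, 20))),
               "outside")
  prof0 <- polyline_profile(flat_frame(0), rbind(c(5, 20), c(35, 20)))
  expect_true(attr(prof0, "flat_zero"))
  expect_error(contact_statistic(prof0), "all-zero")
})

test_that("the dip statistic separates rendered contact from separation", {
  fs <- frame_spec(noise_sd = 0)
  # in contact: bridge at near-cell level, shallow dip
  tr <- simulate_pivot_track(pivot_scenario(noise_sd_deg = 0, seed = 1))
  fr <- render_pair_frames(tr, fs)
  ct <- contact_timecourse(fr, tr)
  expect_true(all(ct$in_contact))
  expect_true(all(ct$dip < 0.2))
  # bridge at cell level: essentially no dip at all
  fs_flat <- frame_spec(bridge_level = 0.6, noise_sd = 0)
  fr2 <- render_pair_frames(tr[1:2, ], fs_flat)
  ct2 <- contact_timecourse(fr2, tr[1:2, ])
  expect_lt(max(ct2$dip), 0.05)
  # separated pair: interior falls to background -> dip = 1 - bg/cell
  tr_sep <- tr[1:2, ]
  tr_sep$x1_um <- c(-10, -10); tr_sep$x2_um <- c(10, 10)
  tr_sep$y1_um <- 0; tr_sep$y2_um <- 0
  fr3 <- render_pair_frames(tr_sep, fs)
  ct3 <- contact_timecourse(fr3, tr_sep)
  expect_false(any(ct3$in_contact))
  expect_equal(ct3$dip, rep(1 - fs$background_level / fs$cell_level, 2),
               tolerance = 0.01)
})

test_that("dip deepens monotonically with a deeper interior minimum", {
  base <- c(1, 1, 1, 0.9, 1, 1, 1)
  dips <- vapply(seq(0.9, 0.1, by = -0.2), function(m) {
    v <- base; v[4] <- m
    prof <- data.frame(position_px = seq(0, 30, length.out = 7),
                       intensity = v, f_over_fmax = v / max(v))
    attr(prof, "flat_zero") <- FALSE
    contact_statistic(prof, interior_fraction = 0.6)$dip
  }, numeric(1))
  expect_true(all(diff(dips) > 0))
  expect_true(all(dips >= 0 & dips <= 1))
})

test_that("junctional fraction is the background-subtracted region ratio", {
  # hand-built frame: 30x30, background 0.1, pair square with known sums
  img <- matrix(0.1, 30, 30)
  img[11:20, 11:20] <- 0.5              # pair region: 100 px
  img[14:17, 14:17] <- 0.9              # junctional core: 16 px
  # pixel centres sit at half-integers: the polygon (10,10)-(20,20) covers
  # exactly rows/cols 11:20
  pairp <- rbind(c(10, 10), c(20, 10), c(20, 20), c(10, 20))
  junp <- rbind(c(13, 13), c(17, 13), c(17, 17), c(13, 17))
  jm <- junctional_fraction(img, junp, pairp)
  jsum <- 16 * (0.9 - 0.1)
  tsum <- 84 * (0.5 - 0.1) + 16 * (0.9 - 0.1)
  expect_equal(jm$ratio, jsum / tsum, tolerance = 1e-12)
  expect_false(jm$undefined)
  # all signal inside the junction region -> ratio 1
  img2 <- matrix(0.1, 30, 30)
  img2[14:17, 14:17] <- 0.9
  expect_equal(junctional_fraction(img2, junp, pairp)$ratio, 1,
               tolerance = 1e-12)
  # junction region must be nested
  expect_error(junctional_fraction(img, pairp, junp), "inside")
  # zero-signal pair flagged undefined
  img3 <- matrix(0.1, 30, 30)
  expect_true(junctional_fraction(img3, junp, pairp)$undefined)
})

test_that("a junctional band raises the junctional fraction over no-band frames", {
  tr <- simulate_pivot_track(pivot_scenario(noise_sd_deg = 0, seed = 3))[1:2, ]
  fs_band <- frame_spec(junction_level = 1, noise_sd = 0)
  fs_none <- frame_spec(junction_level = 0, noise_sd = 0)
  jr <- junction_roi(tr, fs_band, 1)
  pr <- pair_roi(tr, fs_band, 1)
  with_band <- junctional_fraction(render_pair_frames(tr, fs_band)[[1]], jr, pr)
  without <- junctional_fraction(render_pair_frames(tr, fs_none)[[1]], jr, pr)
  expect_gt(with_band$ratio, without$ratio)
})

test_that("junction time courses normalize by the course maximum", {
  tr <- simulate_pivot_track(pivot_scenario(noise_sd_deg = 0, seed = 4))
  fs <- frame_spec(junction_level = 0.9, noise_sd = 0)
  fr <- render_pair_frames(tr, fs)
  jrois <- lapply(seq_len(nrow(tr)), function(k) junction_roi(tr, fs, k))
  prois <- lapply(seq_len(nrow(tr)), function(k) pair_roi(tr, fs, k))
  jc <- junction_timecourse(fr, jrois, prois, t_h = tr$t_h)
  expect_equal(max(jc$f_over_fmax), 1)
  # constant band; the 1-px-wide band rasterizes differently as the pair
  # rotates, so allow pixelation wobble
  expect_true(all(jc$f_over_fmax > 0.75))
  expect_equal(jc$cumulative_f_over_fmax, cumsum(jc$f_over_fmax))
  # decaying band: half-time visible in F/Fmax
  fs_dec <- fs
  fs_dec$junction_level <- 0.9 * 0.5^(tr$t_h / 5)
  frd <- render_pair_frames(tr, fs_dec)
  jcd <- junction_timecourse(frd, jrois, prois, t_h = tr$t_h)
  expect_lt(abs(jcd$f_over_fmax[jcd$t_h == 5] - 0.5), 0.15)
  expect_lt(jcd$f_over_fmax[length(jcd$f_over_fmax)], 0.5)
})

test_that("pearson colocalization is affine-invariant and flags degeneracy", {
  set.seed(51)
  ch1 <- runif(200)
  expect_equal(pearson_colocalization(ch1, 3 * ch1 + 7)$r, 1,
               tolerance = 1e-12)
  expect_equal(pearson_colocalization(ch1, -ch1)$r, -1, tolerance = 1e-12)
  # matches the textbook product-moment formula on random vectors
  ch2 <- runif(200)
  r_direct <- sum((ch1 - mean(ch1)) * (ch2 - mean(ch2))) /
    sqrt(sum((ch1 - mean(ch1))^2) * sum((ch2 - mean(ch2))^2))
  expect_equal(pearson_colocalization(ch1, ch2)$r, r_direct,
               tolerance = 1e-12)
  # mask restricts the computation
  m <- rep(c(TRUE, FALSE), 100)
  expect_equal(pearson_colocalization(ch1, ch2, m)$n_px, 100L)
  expect_true(pearson_colocalization(ch1, rep(1, 200))$undefined)
  expect_error(pearson_colocalization(ch1, ch2[1:10]), "lengths differ")
})

test_that("intensity statistics are invariant to a positive gain", {
  set.seed(61)
  img <- matrix(runif(40 * 40, 0.1, 0.9), 40, 40)
  wp <- rbind(c(5, 20), c(35, 20))
  p1 <- polyline_profile(img, wp)
  p2 <- polyline_profile(img * 3.7, wp)
  expect_equal(p1$f_over_fmax, p2$f_over_fmax, tolerance = 1e-12)
  expect_equal(contact_statistic(p1)$dip, contact_statistic(p2)$dip,
               tolerance = 1e-12)
  ch1 <- runif(100); ch2 <- runif(100)
  expect_equal(pearson_colocalization(ch1 * 5, ch2)$r,
               pearson_colocalization(ch1, ch2)$r, tolerance = 1e-12)
})

test_that("rendered total intensity matches the analytic composition", {
  fs <- frame_spec(noise_sd = 0)
  # separated pair: background + two full disks, no bridge
  tr <- data.frame(pair_id = "p", t_h = 0:1, x1_um = -10, y1_um = 0,
                   x2_um = 10, y2_um = 0)
  img <- render_pair_frames(tr, fs)[[1]]
  r_px <- fs$cell_radius_um / fs$pixel_size_um
  npx <- prod(fs$image_size_px)
  disk_area <- pi * r_px^2
  analytic <- fs$background_level * (npx - 2 * disk_area) +
    fs$cell_level * 2 * disk_area
  expect_lt(abs(sum(img) - analytic) / analytic, 0.02)
  # in contact: bridge capsule minus the disk overlaps, in closed form
  tr2 <- data.frame(pair_id = "p", t_h = 0:1, x1_um = -4, y1_um = 0,
                    x2_um = 4, y2_um = 0)
  img2 <- render_pair_frames(tr2, fs)[[1]]
  L <- 16; bw <- fs$bridge_halfwidth_um / fs$pixel_size_um
  strip_in_disk <- bw * sqrt(r_px^2 - bw^2) + r_px^2 * asin(bw / r_px)
  bridge_area <- L * 2 * bw - 2 * strip_in_disk
  analytic2 <- fs$background_level *
    (npx - 2 * disk_area - bridge_area) +
    fs$cell_level * 2 * disk_area + fs$bridge_level * bridge_area
  expect_lt(abs(sum(img2) - analytic2) / analytic2, 0.02)
})

test_that("rendering rejects coordinates that leave the frame", {
  fs <- frame_spec()
  tr <- data.frame(pair_id = "p", t_h = 0:1, x1_um = -40, y1_um = 0,
                   x2_um = 10, y2_um = 0)
  expect_error(render_pair_frames(tr, fs), "outside the frame")
})
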