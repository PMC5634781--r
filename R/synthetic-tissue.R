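#' Parameters for the synthetic tissue generator
#'
#' Bundles and validates the parameters of [generate_tissue()]. The
#' generator emulates clonal patches of growth-plate cartilage in the 2D
#' section plane: proximodistal (PD) axis = +y, mediolateral (ML) = +x.
#'
#' Proliferative-zone clones are stacks: cells are placed in
#' `column_width` lateral sub-columns at `cell_spacing_um` pitch, the whole
#' stack tilted by a per-clone angle drawn from
#' `N(stack_tilt_deg, stack_tilt_sd_deg)`, and each cell's minor axis is
#' the stack axis plus wrapped-normal noise with SD
#' `orientation_spread_deg` (axial, folded to \[0, 180)). The default
#' between-clone tilt SD of 15 degrees reproduces a zone-level mean
#' minor-axis angle of about 12 degrees when the within-clone spread is
#' small. Resting-zone clones are loose isotropic cell clusters with
#' near-uniform minor-axis orientation.
#'
#' @param n_clones number of clones (>= 1).
#' @param cells_per_clone integer range `c(lo, hi)` of cells per clone
#'   (default 8-16, i.e. clones after three to four division rounds).
#' @param zone `"proliferative"` or `"resting"`.
#' @param orientation_spread_deg within-clone SD of the minor-axis angle
#'   about the clone's stack axis (degrees; proliferative zone only).
#' @param column_width number of lateral sub-columns per clone (1 =
#'   single column).
#' @param cell_spacing_um centre-to-centre cell spacing (micrometres).
#' @param stack_tilt_deg mean stack-axis tilt from the PD axis (degrees).
#' @param stack_tilt_sd_deg SD of the per-clone stack-axis tilt (degrees).
#' @param jitter_um SD of isotropic positional jitter added to each
#'   centroid (micrometres).
#' @param seed integer random seed (mandatory; the generator never touches
#'   global RNG state outside its own evaluation).
#' @return An object of class `"tissue_params"` (a validated list).
#' @export
tissue_params <- function(n_clones = 100, cells_per_clone = c(8L, 16L),
                          zone = c("proliferative", "resting"),
                          orientation_spread_deg = 3, column_width = 1L,
                          cell_spacing_um = 8, stack_tilt_deg = 0,
                          stack_tilt_sd_deg = 15, jitter_um = 0.5,
                          seed = 1L) {
  zone <- match.arg(zone)
  stopifnot_scalar(n_clones, "n_clones", positive = TRUE)
  stopifnot_scalar(orientation_spread_deg, "orientation_spread_deg",
                   nonneg = TRUE)
  stopifnot_scalar(column_width, "column_width", positive = TRUE)
  stopifnot_scalar(cell_spacing_um, "cell_spacing_um", positive = TRUE)
  stopifnot_scalar(jitter_um, "jitter_um", nonneg = TRUE)
  stopifnot_scalar(seed, "seed")
  if (length(cells_per_clone) == 1L) cells_per_clone <- rep(cells_per_clone, 2)
  if (cells_per_clone[1] < 1 || cells_per_clone[2] < cells_per_clone[1]) {
    stop("`cells_per_clone` must be an increasing range with lower bound >= 1",
         call. = FALSE)
  }
  structure(list(n_clones = as.integer(n_clones),
                 cells_per_clone = as.integer(cells_per_clone),
                 zone = zone,
                 orientation_spread_deg = orientation_spread_deg,
                 column_width = as.integer(column_width),
                 cell_spacing_um = cell_spacing_um,
                 stack_tilt_deg = stack_tilt_deg,
                 stack_tilt_sd_deg = stack_tilt_sd_deg,
                 jitter_um = jitter_um,
                 seed = as.integer(seed)),
            class = "tissue_params")
}

#' Generate a synthetic cell table
#'
#' Draws a clone ensemble under a [tissue_params()] specification and
#' returns a cell table in the package's standard schema. Output is
#' deterministic for a fixed seed. Clones are laid out on a grid with
#' pitch large enough that no two clones can overlap for any tilt.
#'
#' @param params a `"tissue_params"` object.
#' @return data.frame with columns `cell_id`, `clone_id`, `zone`, `t_h`
#'   (all `NA` for static tissue), `x_um`, `y_um`, `minor_axis_dx`,
#'   `minor_axis_dy`. Attribute `"truth"` carries the per-clone ground
#'   truth (tilt, n_cells).
#' @export
generate_tissue <- function(params) {
  if (!inherits(params, "tissue_params")) params <- do.call(tissue_params, params)
  p <- params
  rows <- withr_seed(p$seed, {
    n_cells <- sample(seq(p$cells_per_clone[1], p$cells_per_clone[2]),
                      p$n_clones, replace = TRUE)
    max_rows <- ceiling(max(n_cells) / p$column_width)
    extent <- sqrt((max_rows * p$cell_spacing_um)^2 +
                   (p$column_width * p$cell_spacing_um)^2) +
              2 * p$cell_spacing_um * sqrt(max(n_cells))
    pitch <- extent + 4 * p$cell_spacing_um + 6 * p$jitter_um
    n_side <- ceiling(sqrt(p$n_clones))
    out <- vector("list", p$n_clones)
    truth <- vector("list", p$n_clones)
    for (cl in seq_len(p$n_clones)) {
      base <- c(((cl - 1) %% n_side) * pitch,
                ((cl - 1) %/% n_side) * pitch)
      n <- n_cells[cl]
      if (p$zone == "proliferative") {
        tilt <- stats::rnorm(1, p$stack_tilt_deg, p$stack_tilt_sd_deg)
        k <- seq_len(n) - 1L
        colx <- (k %% p$column_width) - (p$column_width - 1) / 2
        rowy <- k %/% p$column_width
        local <- cbind(colx * p$cell_spacing_um, -rowy * p$cell_spacing_um)
        # tilt the whole stack about its top cell
        local <- rotate2d(local, tilt)
        xy <- sweep(local, 2, base, `+`) +
          matrix(stats::rnorm(2 * n, 0, p$jitter_um), ncol = 2)
        ang <- tilt + stats::rnorm(n, 0, p$orientation_spread_deg)
      } else {
        tilt <- NA_real_
        R <- p$cell_spacing_um * sqrt(n)
        xy <- matrix(NA_real_, n, 2)
        for (i in seq_len(n)) {
          for (try in 1:50) {
            cand <- base + R * stats::runif(2, -1, 1)
            ok <- i == 1L ||
              min(sqrt(rowSums(sweep(xy[seq_len(i - 1L), , drop = FALSE],
                                     2, cand)^2))) > 0.9 * p$cell_spacing_um
            if (ok) break
          }
          xy[i, ] <- cand
        }
        ang <- stats::runif(n, 0, 180)
      }
      ang <- fold_half_turn(ang)
      # minor axis = PD axis (+y) rotated by the signed angle
      axes <- cbind(-sin(deg2rad(ang)), cos(deg2rad(ang)))
      out[[cl]] <- data.frame(
        cell_id = sprintf("c%04d_%02d", cl, seq_len(n)),
        clone_id = sprintf("clone%04d", cl),
        zone = p$zone, t_h = NA_real_,
        x_um = xy[, 1], y_um = xy[, 2],
        minor_axis_dx = axes[, 1], minor_axis_dy = axes[, 2],
        stringsAsFactors = FALSE)
      truth[[cl]] <- data.frame(clone_id = sprintf("clone%04d", cl),
                                n_cells = n, tilt_deg = tilt,
                                stringsAsFactors = FALSE)
    }
    list(cells = do.call(rbind, out), truth = do.call(rbind, truth))
  })
  cells <- rows$cells
  attr(cells, "truth") <- rows$truth
  attr(cells, "params") <- p
  cells
}

#' @noRd
#' Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
#' RNG state is untouched. Seeds are mandatory, never global.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Scenario for a simulated sister-cell pivot track
#'
#' Parameterizes [simulate_pivot_track()]. The simulated pair keeps a
#' constant inter-cell distance while the sister axis rotates from
#' `division_angle_deg` (relative to the mediolateral axis) by
#' `final_pivot_deg`, following a smoothstep ramp that completes at 75% of
#' the track duration and plateaus thereafter, with additive per-sample
#' Gaussian angular noise. If `separates` is set, the pair loses contact
#' at `separation_time_h`: the distance then grows at
#' `separation_rate_um_h` and the pivot freezes at its value at
#' separation (rearrangement requires cell-cell contact).
#'
#' @param division_angle_deg initial sister-axis angle from the ML axis
#'   (degrees); `NA` draws it uniformly from \[0, 90) (misoriented
#'   division).
#' @param final_pivot_deg total pivot excursion (degrees).
#' @param duration_h track duration (hours, > 0).
#' @param sample_interval_h sampling interval (hours, > 0).
#' @param noise_sd_deg SD of per-sample angular noise (degrees).
#' @param separates logical: does the pair lose contact?
#' @param separation_time_h time of contact loss (hours; used only when
#'   `separates`).
#' @param pair_distance_um inter-cell centre distance while in contact
#'   (micrometres; default 8, two touching 4-micrometre-radius cells).
#' @param separation_rate_um_h distance growth rate after separation.
#' @param seed integer random seed.
#' @return An object of class `"pivot_scenario"`.
#' @export
pivot_scenario <- function(division_angle_deg = 0, final_pivot_deg = 85,
                           duration_h = 10, sample_interval_h = 1,
                           noise_sd_deg = 3, separates = FALSE,
                           separation_time_h = 3, pair_distance_um = 8,
                           separation_rate_um_h = 1.5, seed = 1L) {
  stopifnot_scalar(duration_h, "duration_h", positive = TRUE)
  stopifnot_scalar(sample_interval_h, "sample_interval_h", positive = TRUE)
  stopifnot_scalar(noise_sd_deg, "noise_sd_deg", nonneg = TRUE)
  stopifnot_scalar(pair_distance_um, "pair_distance_um", positive = TRUE)
  if (separates) stopifnot_scalar(separation_time_h, "separation_time_h",
                                  nonneg = TRUE)
  structure(list(division_angle_deg = division_angle_deg,
                 final_pivot_deg = final_pivot_deg,
                 duration_h = duration_h,
                 sample_interval_h = sample_interval_h,
                 noise_sd_deg = noise_sd_deg,
                 separates = isTRUE(separates),
                 separation_time_h = separation_time_h,
                 pair_distance_um = pair_distance_um,
                 separation_rate_um_h = separation_rate_um_h,
                 seed = as.integer(seed)),
            class = "pivot_scenario")
}

#' @noRd
#' Smoothstep ramp completing at `frac` of the duration.
pivot_ramp <- function(t, duration, frac = 0.75) {
  x <- pmin(1, pmax(0, t / (frac * duration)))
  3 * x^2 - 2 * x^3
}

#' Simulate a sister-cell pivot track
#'
#' @param scenario a `"pivot_scenario"` object.
#' @param pair_id identifier for the output track (default `"pair1"`).
#' @param center_um centre of the pair in the tissue frame (micrometres).
#' @return A single-pair track data.frame (`pair_id`, `t_h`, `x1_um`,
#'   `y1_um`, `x2_um`, `y2_um`) with attribute `"truth"`: list with the
#'   realized division angle, the noise-free angle series, the per-sample
#'   contact flag and the scenario.
#' @export
simulate_pivot_track <- function(scenario, pair_id = "pair1",
                                 center_um = c(0, 0)) {
  s <- scenario
  if (!inherits(s, "pivot_scenario")) stop("need a pivot_scenario", call. = FALSE)
  t <- seq(0, s$duration_h, by = s$sample_interval_h)
  track <- withr_seed(s$seed, {
    div <- if (is.na(s$division_angle_deg)) stats::runif(1, 0, 90) else
      s$division_angle_deg
    t_eff <- if (s$separates) pmin(t, s$separation_time_h) else t
    alpha_true <- div + s$final_pivot_deg * pivot_ramp(t_eff, s$duration_h)
    alpha <- alpha_true + stats::rnorm(length(t), 0, s$noise_sd_deg)
    d <- rep(s$pair_distance_um, length(t))
    in_contact <- rep(TRUE, length(t))
    if (s$separates) {
      after <- t > s$separation_time_h
      d[after] <- d[after] +
        s$separation_rate_um_h * (t[after] - s$separation_time_h)
      in_contact[after] <- FALSE
    }
    u <- cbind(cos(deg2rad(alpha)), sin(deg2rad(alpha)))
    p1 <- sweep(-u * d / 2, 2, center_um, `+`)
    p2 <- sweep(u * d / 2, 2, center_um, `+`)
    tr <- data.frame(pair_id = pair_id, t_h = t,
                     x1_um = p1[, 1], y1_um = p1[, 2],
                     x2_um = p2[, 1], y2_um = p2[, 2],
                     stringsAsFactors = FALSE)
    attr(tr, "truth") <- list(division_angle_deg = div,
                              alpha_true_deg = alpha_true,
                              in_contact = in_contact,
                              scenario = s)
    tr
  })
  track
}

#' Synthetic intensity pair with a target correlation
#'
#' Generates two non-negative intensity vectors whose sample Pearson
#' correlation converges to `r_target` as `n_px` grows (bivariate-normal
#' construction, affinely mapped to intensity-like levels). At
#' `r_target` +/-1 the second channel is an exact affine image of the
#' first, so the sample correlation is exactly +/-1.
#'
#' @param r_target target correlation in \[-1, 1\].
#' @param n_px number of pixels (>= 3).
#' @param seed integer random seed.
#' @return List with numeric vectors `ch1`, `ch2`.
#' @export
generate_coloc_pair <- function(r_target, n_px = 1e4, seed = 1L) {
  stopifnot_scalar(r_target, "r_target")
  if (abs(r_target) > 1) stop("|r_target| must be <= 1", call. = FALSE)
  withr_seed(seed, {
    z1 <- stats::rnorm(n_px)
    z2 <- if (abs(r_target) == 1) sign(r_target) * z1 else
      r_target * z1 + sqrt(1 - r_target^2) * stats::rnorm(n_px)
    list(ch1 = 100 + 20 * z1, ch2 = 80 + 15 * z2)
  })
}

#' Phenotype scenario presets
#'
#' Bundles of generator parameters encoding the four qualitative
#' phenotypes the analysis is designed to distinguish:
#'
#' * `wild_type` — mediolateral division, full pivot into a single
#'   proximodistal column, persistent sister-cell contact and junctional
#'   band; tightly stacked single-width clones.
#' * `pcp_loss` — (reduced planar-cell-polarity signalling) misoriented
#'   divisions drawn uniformly, but contact, pivot and stacking are
#'   intact; stacks form with arbitrary orientation (large stack tilt).
#' * `pcp_gain` — (overactive planar-cell-polarity signalling)
#'   misoriented divisions, sister separation shortly after cytokinesis,
#'   junctional band decaying with a 5 h half-time; clones arbitrarily
#'   arranged.
#' * `ncad_block` — (N-cadherin loss of function) divisions still
#'   mediolateral but sisters separate and no complete pivot occurs.
#'
#' @param name one of `"wild_type"`, `"pcp_loss"`, `"pcp_gain"`,
#'   `"ncad_block"`.
#' @param seed integer seed propagated into all component parameter sets.
#' @return List of class `"scenario_preset"` with elements `name`,
#'   `tissue` ([tissue_params()]), `pivot` ([pivot_scenario()]), `frame`
#'   ([frame_spec()]), and `junction_half_time_h` (`NA` = persistent
#'   junction).
#' @export
scenario_preset <- function(name, seed = 1L) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("wild_type", "pcp_loss", "pcp_gain", "ncad_block")) {
    stop("unknown scenario preset: ",
         if (is.character(name)) name else "<non-character>", call. = FALSE)
  }
  seed <- as.integer(seed)
  tissue <- switch(name,
    wild_type = tissue_params(n_clones = 50, orientation_spread_deg = 3,
                              column_width = 1L, stack_tilt_sd_deg = 15,
                              seed = seed),
    pcp_loss  = tissue_params(n_clones = 50, orientation_spread_deg = 3,
                              column_width = 1L, stack_tilt_sd_deg = 40,
                              seed = seed),
    pcp_gain  = tissue_params(n_clones = 50, orientation_spread_deg = 30,
                              column_width = 1L, stack_tilt_sd_deg = 15,
                              seed = seed),
    ncad_block = tissue_params(n_clones = 50, orientation_spread_deg = 3,
                               column_width = 1L, stack_tilt_sd_deg = 15,
                               seed = seed))
  pivot <- switch(name,
    wild_type = pivot_scenario(division_angle_deg = 0, final_pivot_deg = 85,
                               separates = FALSE, seed = seed),
    pcp_loss  = pivot_scenario(division_angle_deg = NA, final_pivot_deg = 85,
                               separates = FALSE, seed = seed),
    pcp_gain  = pivot_scenario(division_angle_deg = NA, final_pivot_deg = 85,
                               separates = TRUE, separation_time_h = 3,
                               seed = seed),
    ncad_block = pivot_scenario(division_angle_deg = 0, final_pivot_deg = 85,
                                separates = TRUE, separation_time_h = 2,
                                seed = seed))
  structure(list(name = name, tissue = tissue, pivot = pivot,
                 frame = frame_spec(),
                 junction_half_time_h = if (name == "pcp_gain") 5 else NA_real_),
            class = "scenario_preset")
}
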