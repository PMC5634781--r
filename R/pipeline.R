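#' Rectangular ROI around the sister-cell interface at one time point
#'
#' Builds an axis-aligned-with-the-pair polygon (in image pixel
#' coordinates) covering the junctional band at the interface midline:
#' centred on the midpoint of the two cells, extending
#' `junction_halfwidth_um + margin_um` along the sister axis and the cell
#' radius perpendicular to it.
#'
#' @param track single-pair track data.frame.
#' @param spec a `"frame_spec"`.
#' @param k time index (row of the track).
#' @param margin_um extra along-axis margin (micrometres).
#' @return 4 x 2 polygon matrix (image pixel coordinates).
#' @export
junction_roi <- function(track, spec, k = 1L, margin_um = 0.25) {
  p1 <- c(track$x1_um[k], track$y1_um[k])
  p2 <- c(track$x2_um[k], track$y2_um[k])
  u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  nvec <- c(-u[2], u[1])
  mid <- (p1 + p2) / 2
  a <- spec$junction_halfwidth_um + margin_um
  b <- spec$cell_radius_um
  corners_um <- rbind(mid + a * u + b * nvec, mid + a * u - b * nvec,
                      mid - a * u - b * nvec, mid - a * u + b * nvec)
  um_to_px(corners_um, spec)
}

#' Rectangular ROI covering both sister cells
#' @inheritParams junction_roi
#' @param margin_um margin beyond the cell outlines (micrometres).
#' @return 4 x 2 polygon matrix (image pixel coordinates).
#' @export
pair_roi <- function(track, spec, k = 1L, margin_um = 1) {
  p1 <- c(track$x1_um[k], track$y1_um[k])
  p2 <- c(track$x2_um[k], track$y2_um[k])
  u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  nvec <- c(-u[2], u[1])
  r <- spec$cell_radius_um + margin_um
  corners_um <- rbind(p2 + r * u + r * nvec, p2 + r * u - r * nvec,
                      p1 - r * u - r * nvec, p1 - r * u + r * nvec)
  um_to_px(corners_um, spec)
}

#' Run the full analysis pipeline on one phenotype preset
#'
#' Generates a clone ensemble, an ensemble of sister-pair pivot tracks,
#' and the corresponding rendered image stacks for one scenario preset,
#' then runs all three analysis tracks: clonal architecture (Phi / theta
#' / column orientation classification), pivot kinematics (omega series
#' and outcome classification), and intensity dynamics (contact dips and
#' junctional F/Fmax time course).
#'
#' The cytoplasmic channel used for contact detection is rendered without
#' a junctional band; the junction channel is rendered on the paired,
#' non-separating interface geometry with a band whose level decays with
#' the preset's junction half-time (junctional protein loss precedes
#' physical separation, so the band position stays defined over the
#' course).
#'
#' @param preset preset name (see [scenario_preset()]) or a
#'   `"scenario_preset"` object.
#' @param config a [run_config()]; its `seed` drives every random draw.
#' @param n_pairs number of sister tracks to simulate (default 12).
#' @return List of class `"cc_report"`: `preset`, `clone_summary`,
#'   `phi_by_zone`, `pivot_summary`, `contact`, `junction`, `fractions`
#'   (named numeric: stacked, single-column, complete-pivot, final
#'   contact), and `manifest`. If `config$output_dir` is set, tables are
#'   written there as CSV plus a JSON manifest.
#' @export
run_pipeline <- function(preset, config = run_config(), n_pairs = 12L) {
  if (is.character(preset)) preset <- scenario_preset(preset, config$seed)
  stopifnot(inherits(preset, "scenario_preset"))
  seed <- config$seed

  # --- clonal architecture -------------------------------------------------
  tissue <- preset$tissue
  tissue$seed <- seed
  cells <- generate_tissue(tissue)
  clone_summary <- summarize_clones(
    cells, phi_threshold_deg = config$phi_sd_threshold_deg,
    theta_threshold_deg = config$theta_sd_threshold_deg,
    cell_radius_um = config$cell_radius_um)
  phi_by_zone <- summarize_phi_by_zone(cells)

  # --- pivot kinematics ----------------------------------------------------
  tracks <- lapply(seq_len(n_pairs), function(i) {
    sc <- preset$pivot
    sc$seed <- seed + 101L * i
    simulate_pivot_track(sc, pair_id = sprintf("pair%03d", i))
  })
  pivot_summary <- summarize_pivots(tracks, config$complete_range,
                                    config$partial_range)

  # --- intensity dynamics --------------------------------------------------
  fs <- preset$frame
  fs$pixel_size_um <- config$pixel_size_um
  contact <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    fr <- render_pair_frames(tracks[[i]], fs, seed = seed + 211L * i)
    cbind(pair_id = tracks[[i]]$pair_id[1],
          contact_timecourse(fr, tracks[[i]],
                             dip_threshold = config$dip_threshold))
  }))
  # junction channel on the non-separating twin of the first track
  jsc <- preset$pivot
  jsc$seed <- seed + 101L
  jsc$separates <- FALSE
  jtrack <- simulate_pivot_track(jsc, pair_id = "junction_pair")
  jlevel <- 0.9
  if (!is.na(preset$junction_half_time_h)) {
    jlevel <- 0.9 * 0.5^(jtrack$t_h / preset$junction_half_time_h)
  }
  jspec <- fs
  jspec$junction_level <- jlevel
  jframes <- render_pair_frames(jtrack, jspec, seed = seed + 331L)
  jrois <- lapply(seq_len(nrow(jtrack)), function(k)
    junction_roi(jtrack, jspec, k))
  prois <- lapply(seq_len(nrow(jtrack)), function(k)
    pair_roi(jtrack, jspec, k))
  junction <- junction_timecourse(jframes, jrois, prois, t_h = jtrack$t_h)

  stacked <- clone_summary$arrangement == "stacked"
  fractions <- c(
    stacked = mean(stacked, na.rm = TRUE),
    single_column = mean(clone_summary$width_class[which(stacked)] == "single"),
    complete_pivot = mean(pivot_summary$pivot_class == "complete"),
    final_contact = mean(contact$in_contact[contact$t_h == max(contact$t_h)]))

  manifest <- list(preset = preset$name, seed = seed, n_pairs = n_pairs,
                   config = unclass(config),
                   package_version = as.character(
                     utils::packageVersion("chondrocolumn")))
  report <- structure(list(preset = preset$name, cells = cells,
                           clone_summary = clone_summary,
                           phi_by_zone = phi_by_zone,
                           pivot_summary = pivot_summary, contact = contact,
                           junction = junction, fractions = fractions,
                           manifest = manifest),
                      class = "cc_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Write a pipeline report bundle to a directory
#' @param report a `"cc_report"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$clone_summary,
                   file.path(dir, "clone_summary.csv"), row.names = FALSE)
  utils::write.csv(report$pivot_summary,
                   file.path(dir, "pivot_summary.csv"), row.names = FALSE)
  utils::write.csv(report$contact, file.path(dir, "contact.csv"),
                   row.names = FALSE)
  utils::write.csv(report$junction, file.path(dir, "junction.csv"),
                   row.names = FALSE)
  jsonlite::write_json(c(report$manifest,
                         list(fractions = as.list(report$fractions))),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Compare two pipeline reports
#'
#' Statistical comparison of two conditions: Watson's U-squared on the
#' stacked-clone column orientations (axial), Wilcoxon rank-sum on the
#' per-clone SD of Phi, and the difference of headline fractions.
#'
#' @param report_a,report_b `"cc_report"` objects.
#' @param seed integer seed for the permutation test.
#' @return List: `orientation_test` (`cc_test` or `NULL` when either
#'   condition has fewer than 4 stacked clones), `phi_sd_test`,
#'   `fraction_diff` (a - b).
#' @export
compare_conditions <- function(report_a, report_b, seed = 1L) {
  ori_a <- report_a$clone_summary$orientation_deg
  ori_a <- ori_a[!is.na(ori_a)]
  ori_b <- report_b$clone_summary$orientation_deg
  ori_b <- ori_b[!is.na(ori_b)]
  ot <- if (length(ori_a) >= 4 && length(ori_b) >= 4) {
    watson_u2(angle_sample(ori_a, "axial"), angle_sample(ori_b, "axial"),
              seed = seed)
  }
  pt <- wilcoxon_rank_sum(stats::na.omit(report_a$clone_summary$phi_sd_deg),
                          stats::na.omit(report_b$clone_summary$phi_sd_deg))
  list(orientation_test = ot, phi_sd_test = pt,
       fraction_diff = report_a$fractions - report_b$fractions)
}

#' @export
print.cc_report <- function(x, ...) {
  cat("chondrocolumn report -- preset:", x$preset, "\n")
  cat(sprintf("  clones: %d (stacked %.0f%%, of which single-column %.0f%%)\n",
              nrow(x$clone_summary), 100 * x$fractions[["stacked"]],
              100 * x$fractions[["single_column"]]))
  cat(sprintf("  pairs: %d (complete pivot %.0f%%, in contact at end %.0f%%)\n",
              nrow(x$pivot_summary), 100 * x$fractions[["complete_pivot"]],
              100 * x$fractions[["final_contact"]]))
  jf <- x$junction$f_over_fmax
  cat(sprintf("  junction F/Fmax at final hour: %.2f\n", jf[length(jf)]))
  invisible(x)
}
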