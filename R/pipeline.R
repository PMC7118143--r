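#' Pipeline configuration
#'
#' Bundles every stage's settings with defaults matching the published
#' protocol: 244-px crops, 0.7 solidity threshold, 5-point positional
#' smoothing, first-half window 42–47.75 h, latter-half window 48–54 h,
#' 20-degree KDE bandwidth, +/-15-degree accordance band, 10,000 /
#' 1,000 resampling trials.
#'
#' @param scenario_a a [sim_scenario()] for group A (required for
#'   synthetic runs).
#' @param scenario_b optional second group; enables group comparisons.
#' @param render render frame pairs and run detection + segmentation
#'   (FALSE runs the track-level pipeline on ground-truth positions and
#'   orientations).
#' @param image_shape rendered frame shape `c(nrow, ncol)`.
#' @param noise_sd rendering noise SD (gray levels).
#' @param segmentation a [segmentation_config()].
#' @param tracking a [tracking_config()].
#' @param first_half_h,latter_half_h analysis windows in hours; must be
#'   ordered and non-overlapping.
#' @param bandwidth_deg KDE bandwidth.
#' @param half_width_deg accordance band half width.
#' @param peak_trials,accordance_trials resampling trial counts.
#' @param rng_seed master seed for the resampling tests.
#' @param out_dir output directory (`NULL` = no files written).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(scenario_a, scenario_b = NULL, render = FALSE,
                            image_shape = c(480, 480), noise_sd = 3,
                            segmentation = segmentation_config(),
                            tracking = tracking_config(),
                            first_half_h = c(42, 47.75),
                            latter_half_h = c(48, 54),
                            bandwidth_deg = 20, half_width_deg = 15,
                            peak_trials = 10000, accordance_trials = 1000,
                            rng_seed = 1L, out_dir = NULL) {
  if (!(first_half_h[1] < first_half_h[2] &&
        first_half_h[2] < latter_half_h[1] &&
        latter_half_h[1] < latter_half_h[2]))
    stop("analysis windows must be ordered and non-overlapping: ",
         "first half ", first_half_h[1], "-", first_half_h[2],
         ", latter half ", latter_half_h[1], "-", latter_half_h[2])
  structure(list(scenario_a = scenario_a, scenario_b = scenario_b,
                 render = render, image_shape = image_shape,
                 noise_sd = noise_sd, segmentation = segmentation,
                 tracking = tracking, first_half_h = first_half_h,
                 latter_half_h = latter_half_h,
                 bandwidth_deg = bandwidth_deg,
                 half_width_deg = half_width_deg,
                 peak_trials = peak_trials,
                 accordance_trials = accordance_trials,
                 rng_seed = as.integer(rng_seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Track-level angle analysis of a group
#'
#' For each cell: smooth positions, derive movement vectors, fit the
#' robust projected path on the first-half window, and compute latter-half
#' angle records against the per-frame axis orientations.
#'
#' @param positions data.frame `cell_id, frame, time_h, x, y`.
#' @param orientations data.frame `cell_id, frame, orientation_deg` and
#'   optionally `excluded`.
#' @param smooth_window positional smoothing window (odd; default 5).
#' @param first_half_h,latter_half_h analysis windows (hours).
#' @return list with `records` (all cells' angle records) and `paths`
#'   (named list of `projected_path` objects). Cells with fewer than 5
#'   first-half points are skipped with a warning.
#' @export
analyze_tracks <- function(positions, orientations, smooth_window = 5,
                           first_half_h = c(42, 47.75),
                           latter_half_h = c(48, 54)) {
  cells <- unique(positions$cell_id)
  recs <- list(); paths <- list()
  for (cid in cells) {
    p <- positions[positions$cell_id == cid, , drop = FALSE]
    p <- p[order(p$frame), , drop = FALSE]
    tr <- make_trajectory(cid, p$frame, cbind(p$x, p$y),
                          tracking_config(smooth_window = smooth_window,
                                          min_track_frames = 1),
                          t0_h = p$time_h[1] - 0.25 * p$frame[1])
    fh <- tr$times_h >= first_half_h[1] & tr$times_h <= first_half_h[2]
    if (sum(fh) < 5) {
      warning("cell ", cid, ": fewer than 5 first-half points; skipped")
      next
    }
    path <- fit_projected_path(tr$smooth_xy[fh, , drop = FALSE])
    ori <- orientations[orientations$cell_id == cid,
                        setdiff(names(orientations), "cell_id"),
                        drop = FALSE]
    recs[[as.character(cid)]] <-
      compute_angle_records(tr, ori, path, latter_half_h)
    paths[[as.character(cid)]] <- path
  }
  list(records = do.call(rbind, recs), paths = paths)
}

# shape table derived from ground truth (track-level pipeline, no imaging)
truth_shapes <- function(truth) {
  data.frame(cell_id = truth$cell_id, frame = truth$frame,
             time_h = truth$time_h,
             centroid_x = truth$x, centroid_y = truth$y,
             area_px = pi * truth$major_px * truth$minor_px / 4,
             major_px = truth$major_px, minor_px = truth$minor_px,
             orientation_deg = truth$orientation_deg,
             eccentricity = eccentricity_of(truth$minor_px,
                                            truth$major_px),
             solidity = 1, excluded = FALSE, reason = "",
             stringsAsFactors = FALSE)
}

run_group <- function(scenario, config, label) {
  truth <- simulate_tracks(scenario)
  if (config$render) {
    frames <- render_frames(truth, config$image_shape, config$noise_sd,
                            rng_seed = scenario$rng_seed + 7L)
    dets <- lapply(frames, function(f)
      detect_nuclei(f$gfp, config$tracking$gfp_threshold_method,
                    config$tracking$min_blob_px))
    tracks <- link_tracks(dets, config$tracking$max_link_px,
                          config$tracking$min_track_frames)
    shapes <- segment_cells(frames, tracks, config$segmentation)
  } else {
    tracks <- truth[, c("cell_id", "frame", "x", "y")]
    shapes <- truth_shapes(truth)
  }
  positions <- merge(tracks,
                     data.frame(frame = sort(unique(truth$frame)),
                                time_h = sort(unique(truth$time_h))),
                     by = "frame")
  positions <- positions[order(positions$cell_id, positions$frame),
                         c("cell_id", "frame", "time_h", "x", "y")]
  ana <- analyze_tracks(positions, shapes,
                        config$tracking$smooth_window,
                        config$first_half_h, config$latter_half_h)
  list(label = label, truth = truth, tracks = positions, shapes = shapes,
       records = ana$records, paths = ana$paths)
}

#' Run the full two-step pipeline
#'
#' Executes the configured stages — simulate, (optionally render +
#' detect + link + segment), angle analysis, and group statistics — and,
#' when `out_dir` is set, writes each stage's CSV/JSON artifacts plus a
#' manifest (package version, config hash, seed, file checksums).
#' Rerunning with the same configuration and seed reproduces
#' byte-identical CSV outputs.
#'
#' @param config a [pipeline_config()].
#' @return list with per-group results (`group_a`, `group_b`), `summary`
#'   (accordance rates, peak densities, shape comparison and resampling
#'   tests when two groups are configured), and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  groups <- list(group_a = run_group(config$scenario_a, config, "A"))
  if (!is.null(config$scenario_b))
    groups$group_b <- run_group(config$scenario_b, config, "B")

  summarise_group <- function(g) {
    recs <- g$records[g$records$valid, , drop = FALSE]
    surf <- bivariate_density(recs, bandwidth_deg = config$bandwidth_deg)
    list(n_records = nrow(recs),
         accordance_rate = accordance_rate(recs, config$half_width_deg),
         peak_density = peak_density(surf),
         exclusions = exclusion_report(g$shapes, g$records))
  }
  summary <- lapply(groups, summarise_group)

  if (length(groups) == 2) {
    summary$shape_comparison <- compare_shape_metrics(
      groups$group_a$shapes, groups$group_b$shapes,
      labels = c(config$scenario_a$name,
                 config$scenario_b$name %||% "B"))
    summary$peak_test <- peak_density_resample_test(
      groups$group_a$records, summary$group_b$peak_density,
      n_trials = config$peak_trials,
      resample_size = summary$group_b$n_records,
      rng_seed = config$rng_seed)
    summary$accordance_test <- accordance_resample_test(
      groups$group_a$records, summary$group_b$accordance_rate,
      n_trials = config$accordance_trials,
      resample_size = summary$group_b$n_records,
      rng_seed = config$rng_seed + 1L)
  }

  manifest <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (nm in names(groups)) {
      g <- groups[[nm]]
      for (what in c("tracks", "shapes", "records")) {
        path <- file.path(config$out_dir, paste0(nm, "_", what, ".csv"))
        write.csv(g[[what]], path, row.names = FALSE)
        files <- c(files, path)
      }
    }
    spath <- file.path(config$out_dir, "summary.json")
    jsonlite::write_json(summary_for_json(summary), spath,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, spath)
    manifest <- list(
      package = "shapepath",
      version = as.character(utils::packageVersion("shapepath")),
      rng_seed = config$rng_seed,
      config_hash = config_hash(config),
      files = data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  c(groups, list(summary = summary, manifest = manifest))
}

# JSON-friendly view of the summary (resample results as plain lists)
summary_for_json <- function(summary) {
  lapply(summary, function(s) {
    if (inherits(s, "resample_result")) unclass(s)
    else if (is.list(s) && !is.data.frame(s))
      lapply(s, function(x) if (is.data.frame(x)) x else x)
    else s
  })
}

config_hash <- function(config) {
  cfg <- config[setdiff(names(config), "out_dir")]  # paths don't alter results
  flat <- unlist(lapply(cfg, function(x)
    if (is.list(x)) unlist(x, use.names = TRUE) else x))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(flat), vapply(flat, format, ""), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

#' Per-reason exclusion summary
#'
#' Counts frames excluded by each deterministic rule (low-solidity,
#' no-object, degenerate, manual) plus, when angle records are supplied,
#' frames dropped from angular statistics for zero movement. Every
#' excluded frame lands in exactly one bucket.
#'
#' @param fits data.frame of ellipse fits (with `excluded`, `reason`).
#' @param records optional angle records (for the zero-movement bucket:
#'   in-window frames invalid despite a retained shape fit).
#' @return list with `n_total`, `n_excluded`, `percent`, a `by_reason`
#'   table, and a formatted `label` like `"60/1639 (3.7%)"`.
#' @export
exclusion_report <- function(fits, records = NULL) {
  reasons <- c("low-solidity", "no-object", "degenerate", "manual",
               "zero-movement")
  counts <- vapply(reasons, function(r) sum(fits$reason == r, na.rm = TRUE),
                   numeric(1))
  if (!is.null(records) && nrow(records) > 0) {
    key_fit <- paste(fits$cell_id, fits$frame)
    bad <- records[!records$valid, , drop = FALSE]
    if (nrow(bad) > 0) {
      shape_ok <- !fits$excluded[match(paste(bad$cell_id, bad$frame),
                                       key_fit)]
      shape_ok[is.na(shape_ok)] <- TRUE
      counts["zero-movement"] <- sum(shape_ok)
    }
  }
  n_total <- nrow(fits)
  n_excl <- sum(fits$excluded) + counts["zero-movement"]
  list(n_total = n_total, n_excluded = unname(n_excl),
       percent = unname(round(100 * n_excl / n_total, 1)),
       by_reason = counts,
       label = format_exclusion(unname(n_excl), n_total))
}

#' Format an exclusion count as "n/total (p%)"
#'
#' @param n_excluded,n_total counts.
#' @return character scalar, e.g. `"60/1639 (3.7%)"`.
#' @export
format_exclusion <- function(n_excluded, n_total) {
  sprintf("%d/%d (%.1f%%)", n_excluded, n_total,
          round(100 * n_excluded / n_total, 1))
}
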