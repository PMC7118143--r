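test_that("crops are centered, clamped at borders, and sized correctly", {
  frame <- matrix(0, 760, 1088)   # rows = y, cols = x
  cr <- crop_around_nucleus(frame, c(544, 380), 244)
  expect_equal(dim(cr$crop), c(244, 244))
  expect_equal(unname(cr$offset), c(422, 258))  # columns 422..665 inclusive

  cr2 <- crop_around_nucleus(frame, c(10, 10), 244)
  expect_equal(unname(cr2$offset), c(0, 0))

  expect_error(crop_around_nucleus(matrix(0, 100, 100), c(50, 50), 244),
               "larger than frame")
  expect_error(crop_around_nucleus(frame, c(2000, 380), 244),
               "outside frame")
})

test_that("edge detection marks steps and returns nothing on flat input", {
  expect_false(any(detect_edges(matrix(128, 50, 50))))

  step <- matrix(80, 40, 40); step[, 21:40] <- 180
  mask <- detect_edges(step)
  cols <- unique(which(mask, arr.ind = TRUE)[, 2])
  expect_true(all(cols %in% 19:22))
  expect_true(any(mask))
})

test_that("edges of a rendered ellipse trace the true boundary", {
  gt <- data.frame(cell_id = 1, frame = 0, time_h = 42, x = 40, y = 39,
                   major_px = 16, minor_px = 10, orientation_deg = 25,
                   heading_deg = 0)
  fr <- render_frames(gt, c(80, 80), noise_sd = 0)
  mask <- detect_edges(fr[[1]]$phase)
  edge_xy <- which(mask, arr.ind = TRUE)
  oracle <- mask_boundary(rasterize_ellipse(40, 39, 8, 5, 25, c(80, 80)))
  near <- apply(oracle, 1, function(p) {
    min(sqrt((edge_xy[, 2] - 1 - p["x"])^2 + (edge_xy[, 1] - 1 - p["y"])^2))
  })
  expect_gte(mean(near <= 2), 0.9)
})

test_that("closing fills a thin ring into the equivalent disk", {
  ring <- make_ring(20, 20, 8, 1, c(41, 41))
  filled <- close_object(ring, closing_radius_px = 2)
  disk <- rasterize_disk(20, 20, 8.5, c(41, 41))  # ring outer edge
  expect_lt(abs(sum(filled) - sum(disk)) / sum(disk), 0.10)

  expect_false(any(close_object(matrix(FALSE, 20, 20))))

  two <- make_ring(15, 15, 6, 1, c(60, 60)) |
         make_ring(15, 45, 6, 1, c(60, 60))
  lab <- EBImage::bwlabel(EBImage::Image(t(close_object(two, 2) * 1)))
  expect_equal(max(lab), 2)
})

test_that("cell-body selection follows nucleus containment then proximity", {
  small <- rasterize_disk(15, 15, 4, c(60, 60))
  big <- rasterize_disk(42, 42, 10, c(60, 60))
  both <- small | big
  sel <- select_cell_body(both, c(15, 15), min_area_px = 10)
  expect_equal(sum(sel), sum(small))   # nucleus wins over size

  lone <- rasterize_disk(30, 30, 6, c(60, 60))
  sel2 <- select_cell_body(lone, c(30, 41), min_area_px = 10, gate_px = 10)
  expect_equal(sum(sel2), sum(lone))   # 5 px outside, within the gate

  sel3 <- select_cell_body(lone, c(30, 50), min_area_px = 10, gate_px = 10)
  expect_null(sel3)                    # beyond the gate

  tiny <- rasterize_disk(10, 10, 1, c(30, 30))  # ~5 px
  expect_null(select_cell_body(tiny, c(10, 10), min_area_px = 10))
})

test_that("moment ellipse agrees with the brute-force oracle to 1e-6", {
  set.seed(11)
  for (k in 1:25) {
    a <- runif(1, 4, 14); b <- runif(1, 2, a)
    th <- runif(1, -90, 90)
    cx <- 30 + runif(1, -0.5, 0.5); cy <- 30 + runif(1, -0.5, 0.5)
    mask <- rasterize_ellipse(cx, cy, a, b, th, c(60, 60))
    fit <- fit_ellipse(mask)
    oracle <- brute_moments(mask)
    expect_equal(fit$major_px, oracle$major, tolerance = 1e-6)
    expect_equal(fit$minor_px, oracle$minor, tolerance = 1e-6)
    expect_equal(fit$area_px, oracle$n)
    if (oracle$major / oracle$minor > 1.05) {
      dor <- abs(fold_axis_angle(fit$orientation_deg - oracle$orientation))
      expect_lt(dor, 1e-6)
    }
  }
})

test_that("moment ellipse recovers crafted shapes", {
  disk <- rasterize_disk(30, 30, 10, c(61, 61))
  f <- fit_ellipse(disk)
  expect_equal(f$major_px, 20, tolerance = 0.03)
  expect_equal(f$minor_px, 20, tolerance = 0.03)
  expect_lt(f$eccentricity, 0.1)
  expect_gt(f$solidity, 0.95)

  ell <- rasterize_ellipse(30, 30, 12, 6, 0, c(61, 61))
  f2 <- fit_ellipse(ell)
  expect_equal(f2$major_px, 24, tolerance = 0.03)
  expect_equal(f2$minor_px, 12, tolerance = 0.03)
  expect_lt(abs(fold_axis_angle(f2$orientation_deg)), 3)

  row5 <- matrix(FALSE, 20, 20); row5[10, 5:9] <- TRUE
  f3 <- fit_ellipse(row5)
  expect_equal(f3$minor_px, 0)
  expect_true(f3$excluded)
  expect_equal(f3$reason, "degenerate")

  expect_error(fit_ellipse(matrix(FALSE, 5, 5)), "empty mask")
})

test_that("EBImage moment features cross-check the ellipse fit", {
  mask <- rasterize_ellipse(32.2, 31.8, 11, 5.5, 35, c(64, 64))
  f <- fit_ellipse(mask)
  cf <- EBImage::computeFeatures.moment(EBImage::Image(t(mask * 1)))
  expect_equal(f$major_px, unname(cf[, "m.majoraxis"]), tolerance = 1e-6)
  expect_equal(f$eccentricity, unname(cf[, "m.eccentricity"]),
               tolerance = 1e-6)
  # EBImage measures theta in its y-down frame: sign flips
  expect_equal(f$orientation_deg, -unname(cf[, "m.theta"]) * 180 / pi,
               tolerance = 1e-6)
})

test_that("eccentricity follows the focal-distance definition", {
  expect_equal(eccentricity_of(6, 10), 0.8)
  expect_equal(eccentricity_of(10, 10), 0)
  # Table-style mean axes give a different value than a mean of per-cell
  # eccentricities would
  expect_equal(eccentricity_of(7.22, 11.2), 0.7644839, tolerance = 1e-6)
  expect_error(eccentricity_of(11, 10), "exceeds")
})

test_that("retained fits satisfy the eccentricity identity", {
  set.seed(3)
  for (k in 1:10) {
    a <- runif(1, 5, 12); b <- runif(1, 2.5, a)
    mask <- rasterize_ellipse(30, 30, a, b, runif(1, -90, 90), c(60, 60))
    f <- fit_ellipse(mask)
    if (!f$excluded)
      expect_equal(f$eccentricity,
                   eccentricity_of(f$minor_px, f$major_px),
                   tolerance = 1e-9)
  }
})

test_that("solidity QC excludes crescents and keeps convex bodies", {
  crescent <- rasterize_disk(20, 20, 12, c(50, 50)) &
    !rasterize_disk(26, 20, 10, c(50, 50))
  f <- qc_filter(fit_ellipse(crescent), 0.7)
  expect_lt(f$solidity, 0.7)
  expect_true(f$excluded)
  expect_equal(f$reason, "low-solidity")

  ell <- rasterize_ellipse(25, 25, 11, 6, 40, c(50, 50))
  f2 <- qc_filter(fit_ellipse(ell), 0.7)
  expect_false(f2$excluded)
  expect_gt(f2$solidity, 0.9)

  # boundary convention: exactly at threshold is retained
  f3 <- f2; f3$solidity <- 0.7
  expect_false(qc_filter(f3, 0.7)$excluded)
})

test_that("segmentation recovers area and orientation on rendered cells", {
  scene <- render_test_scene(rng_seed = 2)
  tr <- scene$truth
  cfg <- segmentation_config(crop_size = 96)
  frame_idx <- vapply(scene$frames, function(f) f$frame_index, numeric(1))
  rel_err <- c(); orient_err <- c()
  for (r in seq_len(nrow(tr))) {
    cc <- tr[r, ]
    fit <- segment_frame(scene$frames[[match(cc$frame, frame_idx)]]$phase,
                         c(cc$x, cc$y), cfg, cc$frame)
    expect_false(fit$excluded)
    true_area <- pi * cc$major_px * cc$minor_px / 4
    rel_err <- c(rel_err, (fit$area_px - true_area) / true_area)
    ecc_true <- sqrt(1 - (cc$minor_px / cc$major_px)^2)
    if (ecc_true > 0.3)
      orient_err <- c(orient_err,
                      abs(fold_axis_angle(fit$orientation_deg -
                                            cc$orientation_deg)))
  }
  expect_lt(abs(mean(rel_err)), 0.05)
  expect_lt(mean(orient_err), 5)
})

test_that("automated segmentation matches the annotated reference masks", {
  ext <- system.file("extdata", package = "shapepath")
  params <- read.csv(file.path(ext, "synthetic_annotation_params.csv"))
  masks <- read.csv(file.path(ext, "synthetic_annotation_masks.csv"))
  for (k in seq_len(nrow(params))) {
    p <- params[k, ]
    gt <- data.frame(cell_id = p$cell_id, frame = 0, time_h = 42,
                     x = p$x, y = p$y, major_px = p$major_px,
                     minor_px = p$minor_px,
                     orientation_deg = p$orientation_deg, heading_deg = 0)
    fr <- render_frames(gt, c(96, 96), noise_sd = 0)
    fit <- segment_frame(fr[[1]]$phase, c(p$x, p$y),
                         segmentation_config(crop_size = 96), 0)
    annotated <- sum(masks$cell_id == p$cell_id)
    expect_lt(abs(fit$area_px - annotated) / annotated, 0.10)
  }
})
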