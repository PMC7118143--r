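test_that("projected path is exact on collinear data", {
  x <- 0:9
  xy <- cbind(x, -(2 * x + 1))          # y = 2x + 1 in math coordinates
  p <- fit_projected_path(xy)
  expect_equal(p$direction, c(1, 2) / sqrt(5), tolerance = 1e-9)
  expect_equal(p$path_angle_deg, atan2(2, 1) * 180 / pi, tolerance = 1e-9)

  # reversed traversal flips the sign with the net displacement
  p2 <- fit_projected_path(xy[10:1, ])
  expect_equal(p2$direction, -c(1, 2) / sqrt(5), tolerance = 1e-9)
})

test_that("bisquare weighting rejects a gross outlier", {
  x <- 0:9
  ym <- 2 * x + 1
  ym[4] <- ym[4] + 80                    # gross positional outlier
  p <- fit_projected_path(cbind(x, -ym))
  # oracle: ordinary least squares on the clean subset is exact
  clean_angle <- atan2(2, 1) * 180 / pi
  expect_lt(abs(p$path_angle_deg - clean_angle), 1)
})

test_that("vertical motion does not degenerate the fit", {
  xy <- cbind(rep(3, 8), -(seq(0, 14, by = 2)))
  p <- fit_projected_path(xy)
  expect_equal(abs(p$direction), c(0, 1), tolerance = 1e-9)
  expect_equal(p$direction[2], 1)        # moving +y in math coordinates
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_projected_path(matrix(1, 8, 2)), "degenerate-path")
  expect_error(fit_projected_path(cbind(1:4, 1:4)), "fewer than 5")
})

test_that("robust path agrees with MASS::rlm on noisy data", {
  skip_if_not_installed("MASS")
  set.seed(21)
  x <- seq(0, 20, length.out = 24)
  ym <- 0.8 * x + 2 + rnorm(24, 0, 0.4)
  ym[c(5, 17)] <- ym[c(5, 17)] + 25
  p <- fit_projected_path(cbind(x, -ym))
  rf <- MASS::rlm(ym ~ x, psi = MASS::psi.bisquare, maxit = 50)
  ang_rlm <- atan2(unname(coef(rf)[2]), 1) * 180 / pi
  expect_lt(abs(p$path_angle_deg - ang_rlm), 0.5)
})

test_that("angle operations match hand-worked cases", {
  expect_equal(axis_rotation(30, 30), 0)
  expect_equal(axis_rotation(100, 0), -80)
  expect_equal(axis_rotation(-90, 85), 5)

  path <- 0
  expect_equal(turning_angle(cbind(1, 0), path), 0)
  expect_equal(turning_angle(cbind(-1, 0), path), 180)
  expect_equal(turning_angle(cbind(1, -1), path), 45)  # image y down
  expect_true(is.na(turning_angle(cbind(0, 0), path)))

  expect_equal(accordance_angle(cbind(cos(10 * pi / 180),
                                      -sin(10 * pi / 180)), 10),
               0, tolerance = 1e-9)
  expect_equal(abs(accordance_angle(cbind(1, 0), 90)), 90)
  mv170 <- cbind(cos(170 * pi / 180), -sin(170 * pi / 180))
  expect_equal(accordance_angle(mv170, 0), -10, tolerance = 1e-9)
  expect_true(is.na(accordance_angle(cbind(0, 0), 10)))
})

test_that("angle range contracts hold over a million random inputs", {
  set.seed(31)
  n <- 1e6
  ori <- runif(n, -720, 720)
  pth <- runif(n, -720, 720)
  rot <- axis_rotation(ori, pth)
  expect_true(all(rot >= -90 & rot < 90))

  mv <- cbind(rnorm(n), rnorm(n))
  turn <- turning_angle(mv, 0) - runif(1, 0, 0)  # vectorised path = 0
  turn <- turning_angle(mv, pth[1])
  expect_true(all(turn > -180 & turn <= 180, na.rm = TRUE))

  acc <- accordance_angle(mv, ori)
  expect_true(all(acc >= -90 & acc < 90, na.rm = TRUE))

  # folding picks the representative closest to zero difference
  expect_equal(fold_axis_angle(ori + 180), fold_axis_angle(ori))
})

test_that("bivariate KDE matches closed-form peaks and integrates to 1", {
  # all records at the origin: the kernel's own height
  d0 <- bivariate_density(rep(0, 25), rep(0, 25))
  expect_equal(peak_density(d0), 1 / (2 * pi * 400), tolerance = 0.02)
  expect_equal(shapepath:::trapz2(d0$density, 1, 1), 1, tolerance = 1e-9)

  # truncation before renormalisation is tiny for central data
  d0r <- bivariate_density(rep(0, 25), rep(0, 25), renormalize = FALSE)
  expect_equal(shapepath:::trapz2(d0r$density, 1, 1), 1, tolerance = 0.01)

  # independent Gaussians: convolution peak 1/(2*pi*(sigma^2 + h^2))
  set.seed(5)
  s <- 37
  rot <- fold_axis_angle(rnorm(1e5, 0, s))
  turn <- wrap_angle_180(rnorm(1e5, 0, s))
  dg <- bivariate_density(rot, turn)
  expect_equal(peak_density(dg), 1 / (2 * pi * (s^2 + 400)),
               tolerance = 0.05)
  expect_equal(shapepath:::trapz2(dg$density, 1, 1), 1, tolerance = 1e-9)

  expect_error(bivariate_density(rep(0, 5), rep(0, 5)), "at least 10")
})

test_that("KDE is symmetric for sign-symmetric records", {
  r <- c(10, -10, 40, -40, 0, 25, -25, 60, -60, 5, -5, 0)
  t <- c(30, -30, -80, 80, 0, 100, -100, 15, -15, 170, -170, 0)
  d <- bivariate_density(r, t)
  flipped <- d$density[rev(seq_along(d$grid_rotation)),
                       rev(seq_along(d$grid_turning))]
  expect_lt(max(abs(d$density - flipped)), 1e-12)
})

test_that("peak density behaves like a density maximum", {
  set.seed(9)
  rot <- runif(50000, -90, 90)
  turn <- runif(50000, -180, 180)
  du <- bivariate_density(rot, turn)
  expect_equal(peak_density(du), 1 / (180 * 360), tolerance = 0.12)
  expect_gte(peak_density(du), mean(du$density))

  # invariant to record order and duplication
  r <- rnorm(40, 0, 30); t <- rnorm(40, 0, 50)
  p1 <- peak_density(bivariate_density(r, t))
  perm <- sample(40)
  p2 <- peak_density(bivariate_density(r[perm], t[perm]))
  p3 <- peak_density(bivariate_density(rep(r, 2), rep(t, 2)))
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(p1, p3, tolerance = 1e-12)
})

test_that("accordance rate counts the strict central band", {
  expect_equal(accordance_rate(rep(0, 50)), 1)
  set.seed(3)
  u <- runif(1e5, -90, 90)
  expect_equal(accordance_rate(u), 30 / 180, tolerance = 0.01)
  # boundary is strict: exactly 15 degrees is outside
  expect_equal(accordance_rate(c(0, 15, -15, 14.999)), 0.5)
})

test_that("calibrated accordance sample recovers the target rate", {
  sigma <- calibrate_coupling(0.396, 15)
  set.seed(17)
  ang <- fold_axis_angle(rnorm(10000, 0, sigma))
  expect_equal(accordance_rate(ang), 0.396, tolerance = 0.015 / 0.396)
})

test_that("latter-half statistics use only latter-half frames", {
  sc <- sim_scenario("HC-like", n_cells = 2, rng_seed = 13)
  gt <- simulate_tracks(sc)
  res <- analyze_tracks(gt[, c("cell_id", "frame", "time_h", "x", "y")],
                        gt[, c("cell_id", "frame", "orientation_deg")])
  expect_true(all(res$records$time_h >= 48))
  expect_true(all(res$records$time_h <= 54))
  # the window is exposed and honoured when changed
  res2 <- analyze_tracks(gt[, c("cell_id", "frame", "time_h", "x", "y")],
                         gt[, c("cell_id", "frame", "orientation_deg")],
                         latter_half_h = c(50, 52))
  expect_true(all(res2$records$time_h >= 50 & res2$records$time_h <= 52))
})

test_that("zero-noise tracks yield identically zero angles", {
  sc <- sim_scenario("HC-like", n_cells = 4, sigma_turn_deg = 0,
                     sigma_couple_deg = 0, sigma_rot_deg = 0,
                     rng_seed = 19)
  gt <- simulate_tracks(sc)
  res <- analyze_tracks(gt[, c("cell_id", "frame", "time_h", "x", "y")],
                        gt[, c("cell_id", "frame", "orientation_deg")])
  recs <- res$records[res$records$valid, ]
  expect_gt(nrow(recs), 50)
  expect_lt(max(abs(recs$rotation_deg)), 1e-6)
  expect_lt(max(abs(recs$turning_deg)), 1e-6)
  expect_lt(max(abs(recs$accordance_deg)), 1e-6)
})
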