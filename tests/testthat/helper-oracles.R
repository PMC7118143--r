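# Independent oracles used across the suite. Deliberately written as
# plain loops / closed forms so they share no code path with the package.

# brute-force moment-equivalent ellipse: explicit sums and the closed-form
# eigenvalues of the 2x2 central moment matrix (no eigen())
brute_moments <- function(mask) {
  sx <- 0; sy <- 0; n <- 0
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j]) { sx <- sx + (j - 1); sy <- sy + -(i - 1); n <- n + 1 }
  }
  cx <- sx / n; cy <- sy / n
  mxx <- 0; myy <- 0; mxy <- 0
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j]) {
      dx <- (j - 1) - cx; dy <- -(i - 1) - cy
      mxx <- mxx + dx * dx; myy <- myy + dy * dy; mxy <- mxy + dx * dy
    }
  }
  mxx <- mxx / n; myy <- myy / n; mxy <- mxy / n
  tr <- mxx + myy
  det2 <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  l1 <- tr / 2 + det2; l2 <- tr / 2 - det2
  theta <- 0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi
  list(major = 4 * sqrt(max(l1, 0)), minor = 4 * sqrt(max(l2, 0)),
       orientation = ((theta + 90) %% 180) - 90, n = n)
}

# loop rasterizers (pixel-centre inequality)
rasterize_ellipse <- function(cx, cy, a_semi, b_semi, theta_deg, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  th <- theta_deg * pi / 180
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) {
    dx <- (j - 1) - cx
    dy <- -((i - 1) - cy)
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    if ((u / a_semi)^2 + (v / b_semi)^2 <= 1) m[i, j] <- TRUE
  }
  m
}

rasterize_disk <- function(cx, cy, r, shape) {
  rasterize_ellipse(cx, cy, r, r, 0, shape)
}

make_ring <- function(cx, cy, r, thickness, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) {
    d <- sqrt(((j - 1) - cx)^2 + ((i - 1) - cy)^2)
    if (d >= r - thickness / 2 && d <= r + thickness / 2) m[i, j] <- TRUE
  }
  m
}

# boundary pixels of a mask (object pixels with a 4-neighbour outside)
mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    nb <- c(if (i > 1) mask[i - 1, j] else FALSE,
            if (i < nr) mask[i + 1, j] else FALSE,
            if (j > 1) mask[i, j - 1] else FALSE,
            if (j < nc) mask[i, j + 1] else FALSE)
    if (!all(nb)) out <- rbind(out, c(x = j - 1, y = i - 1))
  }
  out
}

# small helper for tests that need a quick HC-like rendered scene
render_test_scene <- function(scen = "HC-like", n_cells = 6, n_frames = 6,
                              rng_seed = 2, noise_sd = 3) {
  sc <- sim_scenario(scen, n_cells = n_cells, n_frames = n_frames,
                     rng_seed = rng_seed, aggregate_xy = c(250, 250),
                     start_radius_px = 80, start_band_px = 100)
  gt <- simulate_tracks(sc)
  fr <- render_frames(gt, c(500, 500), noise_sd = noise_sd,
                      rng_seed = rng_seed + 100)
  list(scenario = sc, truth = attr(fr, "truth_rendered"), frames = fr)
}
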