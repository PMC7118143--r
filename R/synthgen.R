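#' Define a simulation scenario
#'
#' A scenario bundles every knob of the synthetic-track generator. The two
#' named presets emulate the healthy-control ("HC-like") and RELN-deletion
#' ("RELN-del-like") migration phenotypes: cell-body area and eccentricity
#' are drawn from the published group means/SDs, the movement-vs-axis
#' coupling dispersion is calibrated so that the expected within-±15°
#' accordance rate equals the published group rate (39.6% / 32.8%), and the
#' turning dispersion is seeded from the published bivariate peak density
#' (8.9e-5 / 5.2e-5 per degree squared) through the closed-form kernel
#' relation.
#'
#' @param name `"HC-like"`, `"RELN-del-like"`, or any custom label (custom
#'   labels take all defaults from the HC-like preset unless overridden).
#' @param n_cells number of cells to simulate. Default 24.
#' @param n_frames frames per cell; default 49 (a 42–54 h window at 15-min
#'   intervals).
#' @param dt_h hours per frame (default 0.25).
#' @param speed_px_per_frame mean step length in pixels per frame.
#' @param area_mean,area_sd cell-body area distribution (pixel^2).
#' @param ecc_mean,ecc_sd eccentricity distribution (dimensionless; samples
#'   are clipped to `[0, 0.99]`).
#' @param sigma_turn_deg SD of the per-frame turning noise about the
#'   outward base heading (degrees).
#' @param sigma_rot_deg SD of additional independent axis jitter (degrees);
#'   default 0 (the axis dispersion about the path then emerges from
#'   turning + coupling noise).
#' @param sigma_couple_deg SD of the movement-vs-axis coupling noise
#'   (degrees).
#' @param rng_seed integer seed making the scenario reproducible.
#' @param start_radius_px,start_band_px cells start on a ring
#'   `start_radius_px + U(0, start_band_px)` around `aggregate_xy`,
#'   heading outward (emulating migration away from a neurosphere edge).
#'   `start_radius_px = NULL` (default) picks a ring circumference large
#'   enough for `n_cells` at the minimum spacing.
#' @param aggregate_xy centre of the virtual aggregate (pixels).
#' @param min_spacing_px minimum distance allowed between any two cells at
#'   any common frame; offending cells are re-placed.
#' @param smooth_window window (odd) of the local movement average the
#'   axis couples to; matches the pipeline's positional smoothing.
#' @param shape_jitter_sd optional per-frame SD of multiplicative shape
#'   jitter (default 0: shape constant within a cell).
#'
#' @return a list of class `"sim_scenario"`.
#' @export
#' @examples
#' sc <- sim_scenario("HC-like", n_cells = 4, n_frames = 12)
#' sc$area_mean
sim_scenario <- function(name = c("HC-like", "RELN-del-like"),
                         n_cells = 24, n_frames = 49, dt_h = 0.25,
                         speed_px_per_frame = 2,
                         area_mean = NULL, area_sd = NULL,
                         ecc_mean = NULL, ecc_sd = NULL,
                         sigma_turn_deg = NULL, sigma_rot_deg = 0,
                         sigma_couple_deg = NULL,
                         rng_seed = 1L,
                         start_radius_px = NULL, start_band_px = 40,
                         aggregate_xy = c(0, 0),
                         min_spacing_px = 25,
                         smooth_window = 5,
                         shape_jitter_sd = 0) {
  name <- if (length(name) > 1) match.arg(name) else as.character(name)
  reln <- identical(name, "RELN-del-like")

  # published group statistics the presets are calibrated to
  if (is.null(area_mean)) area_mean <- if (reln) 44.1 else 60.6
  if (is.null(area_sd))   area_sd   <- if (reln) 15.6 else 16.8
  if (is.null(ecc_mean))  ecc_mean  <- if (reln) 0.767 else 0.719
  if (is.null(ecc_sd))    ecc_sd    <- if (reln) 0.145 else 0.143
  if (is.null(sigma_couple_deg))
    sigma_couple_deg <- calibrate_coupling(if (reln) 0.328 else 0.396, 15)
  if (is.null(sigma_turn_deg)) {
    peak <- if (reln) 5.2e-5 else 8.9e-5
    sigma_turn_deg <- sqrt(1 / (2 * pi * peak) - 20^2)  # closed-form seed
  }

  # default ring large enough that n_cells fit at the minimum spacing
  if (is.null(start_radius_px))
    start_radius_px <- max(120, 1.3 * n_cells * min_spacing_px / (2 * pi))

  stopifnot(n_frames >= 2, n_cells >= 1, dt_h > 0,
            area_sd >= 0, ecc_sd >= 0,
            sigma_turn_deg >= 0, sigma_rot_deg >= 0, sigma_couple_deg >= 0,
            smooth_window >= 1, smooth_window %% 2 == 1)

  structure(list(
    name = name, n_cells = as.integer(n_cells),
    n_frames = as.integer(n_frames), dt_h = dt_h,
    speed_px_per_frame = speed_px_per_frame,
    area_mean = area_mean, area_sd = area_sd,
    ecc_mean = ecc_mean, ecc_sd = ecc_sd,
    sigma_turn_deg = sigma_turn_deg, sigma_rot_deg = sigma_rot_deg,
    sigma_couple_deg = sigma_couple_deg,
    rng_seed = as.integer(rng_seed),
    start_radius_px = start_radius_px, start_band_px = start_band_px,
    aggregate_xy = aggregate_xy, min_spacing_px = min_spacing_px,
    smooth_window = as.integer(smooth_window),
    shape_jitter_sd = shape_jitter_sd
  ), class = "sim_scenario")
}

#' Calibrate the coupling dispersion to a target central angular mass
#'
#' Finds the standard deviation `sigma` of a zero-mean wrapped normal such
#' that, after folding to the axial range `[-90, 90)`, the probability of
#' falling strictly inside `(-half_width_deg, half_width_deg)` equals
#' `target_central_mass`. Solved by root finding on the wrapped-normal CDF;
#' the result is monotone decreasing in the target mass.
#'
#' @param target_central_mass probability in (0, 1).
#' @param half_width_deg positive half width in degrees (15 for the
#'   accordance-rate convention).
#' @return `sigma` in degrees.
#' @export
#' @examples
#' calibrate_coupling(0.396, 15)  # ~28.9 degrees
calibrate_coupling <- function(target_central_mass, half_width_deg) {
  stopifnot(target_central_mass > 0, target_central_mass < 1,
            half_width_deg > 0)
  central_mass <- function(sigma) {
    k <- -5:5
    sum(pnorm((half_width_deg + 180 * k) / sigma) -
        pnorm((-half_width_deg + 180 * k) / sigma))
  }
  f <- function(sigma) central_mass(sigma) - target_central_mass
  lo <- 0.1; hi <- 180
  if (f(lo) <= 0 || f(hi) >= 0)
    stop("calibration failure: no dispersion in (0.1, 180) degrees attains ",
         "a central mass of ", target_central_mass)
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Calibrate angular dispersions to a target bivariate KDE peak
#'
#' Returns equal dispersions `sigma` for the axis-rotation and turning
#' coordinates such that the large-sample peak of the pipeline's bivariate
#' kernel density (Gaussian product kernel, given bandwidth, 1-degree grid,
#' renormalised) over independent zero-mean Gaussian pairs equals
#' `target_peak`. Seeded by the closed-form Gaussian convolution peak
#' `1 / (2*pi*(sigma^2 + h^2))`, then refined by simulation through the
#' package's own KDE (which accounts for axial folding and grid-edge
#' renormalisation).
#'
#' @param target_peak target peak density in per degree squared.
#' @param bandwidth_deg kernel bandwidth (SD) in degrees; default 20.
#' @param refine refine the closed-form seed by simulation (default TRUE).
#' @param n_sim pairs per refinement simulation.
#' @param n_refine refinement iterations.
#' @param sim_seed internal RNG seed for the refinement simulations (the
#'   caller's RNG state is restored afterwards).
#' @return named numeric vector `c(sigma_rot_deg=, sigma_turn_deg=)`.
#' @export
#' @examples
#' calibrate_peak_density(8.9e-5, 20, refine = FALSE)
calibrate_peak_density <- function(target_peak, bandwidth_deg = 20,
                                   refine = TRUE, n_sim = 1e5,
                                   n_refine = 2, sim_seed = 1203L) {
  stopifnot(target_peak > 0, bandwidth_deg > 0)
  h2 <- bandwidth_deg^2
  max_peak <- 1 / (2 * pi * h2)  # all mass at the origin
  if (target_peak >= max_peak * 0.999)
    stop("target peak ", target_peak, " is at or above the maximum ",
         "attainable peak ", signif(max_peak, 4), " for bandwidth ",
         bandwidth_deg, " degrees")
  sigma <- sqrt(1 / (2 * pi * target_peak) - h2)
  if (refine) {
    sigma <- with_seed(sim_seed, {
      s <- sigma
      for (i in seq_len(n_refine)) {
        rot <- fold_axis_angle(rnorm(n_sim, 0, s))
        turn <- wrap_angle_180(rnorm(n_sim, 0, s))
        pk <- peak_density(bivariate_density(rot, turn,
                                             bandwidth_deg = bandwidth_deg))
        cf <- pk * 2 * pi * (s^2 + h2)  # deviation from the closed form
        s <- sqrt(max(cf / (2 * pi * target_peak) - h2, 1e-2))
      }
      s
    })
  }
  c(sigma_rot_deg = sigma, sigma_turn_deg = sigma)
}

#' Simulate ground-truth tracks for a scenario
#'
#' Each cell starts on a ring around the virtual aggregate and receives an
#' outward base heading. Per step the instantaneous heading is the base
#' heading plus wrapped-normal turning noise; the step length is positive
#' with the scenario's mean speed. The major-axis orientation couples to
#' the locally averaged movement direction (same window as the pipeline's
#' positional smoothing) plus wrapped-normal coupling noise, folded to the
#' axial range. Cell shape (area, eccentricity) is drawn once per cell and
#' converted to full axis lengths via `area = pi*major*minor/4` and
#' `minor/major = sqrt(1 - ecc^2)`. Cells whose paths come closer than
#' `min_spacing_px` to an already placed cell are re-placed.
#'
#' @param scenario a [sim_scenario()] object.
#' @return a `data.frame` (class `"ground_truth"`) with columns
#'   `cell_id, frame, time_h, x, y, major_px, minor_px, orientation_deg,
#'   heading_deg`. Frames are 0-based; times are `42 + 0.25*frame` hours
#'   under the defaults; positions are image pixel coordinates (x right,
#'   y down); angles are degrees in standard math convention (CCW from +x
#'   after flipping the image y-axis), orientations folded to `[-90, 90)`.
#' @export
#' @examples
#' gt <- simulate_tracks(sim_scenario("HC-like", n_cells = 3, n_frames = 10))
#' head(gt)
simulate_tracks <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  with_seed(sc$rng_seed, {
    n <- sc$n_frames
    placed <- list()  # accepted per-cell position matrices
    out <- vector("list", sc$n_cells)
    base_angles <- 360 * (seq_len(sc$n_cells) - 1) / sc$n_cells

    for (i in seq_len(sc$n_cells)) {
      ok <- FALSE
      for (try in 1:200) {
        phi <- if (try == 1) base_angles[i] + runif(1, -3, 3)
               else runif(1, 0, 360)
        r0 <- sc$start_radius_px + runif(1, 0, sc$start_band_px)
        start <- sc$aggregate_xy +
          r0 * c(cos(phi * pi / 180), -sin(phi * pi / 180))
        tau <- rnorm(n - 1, 0, sc$sigma_turn_deg)
        len <- pmax(rnorm(n - 1, sc$speed_px_per_frame,
                          0.25 * sc$speed_px_per_frame),
                    0.05 * sc$speed_px_per_frame)
        head_deg <- wrap_angle_180(phi + tau)
        steps <- cbind(len * cos(head_deg * pi / 180),
                       -len * sin(head_deg * pi / 180))
        cum <- apply(steps, 2, cumsum)
        if (!is.matrix(cum)) cum <- matrix(cum, nrow = 1)
        pos <- rbind(start, sweep(cum, 2, start, `+`))
        dimnames(pos) <- NULL

        clash <- FALSE
        for (p in placed) {
          if (min(sqrt(rowSums((pos - p)^2))) < sc$min_spacing_px) {
            clash <- TRUE; break
          }
        }
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not place cell ", i, " with min_spacing_px = ",
             sc$min_spacing_px, " after 200 attempts")
      placed[[length(placed) + 1]] <- pos

      # shape drawn once per cell
      area <- rnorm(1, sc$area_mean, sc$area_sd)
      while (area <= 10) area <- rnorm(1, sc$area_mean, sc$area_sd)
      ecc <- min(max(rnorm(1, sc$ecc_mean, sc$ecc_sd), 0), 0.99)
      ratio <- sqrt(1 - ecc^2)                  # minor / major
      major <- sqrt(4 * area / (pi * ratio))
      minor <- major * ratio
      jit <- if (sc$shape_jitter_sd > 0)
        pmax(1 + rnorm(n, 0, sc$shape_jitter_sd), 0.2) else rep(1, n)

      # axis couples to the locally averaged movement direction
      w <- min(sc$smooth_window, if (n %% 2 == 1) n else n - 1)
      sm <- moving_average(pos, w)
      svec <- diff(sm)
      ref_head <- heading_of(svec)
      ref_head <- c(ref_head, ref_head[n - 1])
      ref_head[is.na(ref_head)] <- phi  # stationary stretch: base heading
      delta <- rnorm(n, 0, sc$sigma_couple_deg)
      rho <- if (sc$sigma_rot_deg > 0) rnorm(n, 0, sc$sigma_rot_deg)
             else numeric(n)
      orient <- fold_axis_angle(ref_head + delta + rho)

      out[[i]] <- data.frame(
        cell_id = i, frame = 0:(n - 1), time_h = 42 + sc$dt_h * (0:(n - 1)),
        x = pos[, 1], y = pos[, 2],
        major_px = major * jit, minor_px = minor * jit,
        orientation_deg = orient,
        heading_deg = c(head_deg, head_deg[n - 1])
      )
    }
    gt <- do.call(rbind, out)
    rownames(gt) <- NULL
    class(gt) <- c("ground_truth", "data.frame")
    gt
  })
}

#' Rendering configuration for synthetic frame pairs
#'
#' Intensity dialect: the phase channel is a mid-gray background with a
#' brighter elliptical interior and a darker rim just inside the
#' boundary, with band-limited (smoothly interpolated) edges emulating
#' diffraction-limited optics — chosen so a sobel-magnitude threshold
#' closes into a single object whose gradient ring is symmetric about
#' the true boundary. The nuclear channel is a small bright Gaussian
#' blob at each centroid on a dark background. All values are 8-bit
#' gray levels.
#'
#' @param background,interior,rim phase-channel gray levels.
#' @param rim_center_px,rim_sigma_px position (pixels inside the
#'   boundary) and width of the dark rim band.
#' @param edge_softness_px length scale of the boundary intensity
#'   transition (pixels).
#' @param gfp_background,gfp_amplitude,gfp_sigma_px nuclear-channel
#'   background, blob amplitude and Gaussian SD (pixels).
#' @param min_spacing_px minimum centre distance between rendered cells in
#'   any frame; closer pairs are a generator contract violation.
#' @return a list of class `"render_config"`.
#' @export
render_config <- function(background = 110, interior = 172, rim = 52,
                          rim_center_px = 0.9, rim_sigma_px = 0.8,
                          edge_softness_px = 0.7,
                          gfp_background = 8, gfp_amplitude = 210,
                          gfp_sigma_px = 2.2, min_spacing_px = 25) {
  structure(list(background = background, interior = interior, rim = rim,
                 rim_center_px = rim_center_px,
                 rim_sigma_px = rim_sigma_px,
                 edge_softness_px = edge_softness_px,
                 gfp_background = gfp_background,
                 gfp_amplitude = gfp_amplitude, gfp_sigma_px = gfp_sigma_px,
                 min_spacing_px = min_spacing_px),
            class = "render_config")
}

#' Rasterise the ground-truth mask of one ellipse
#'
#' A pixel (0-based, pixel-centre convention) belongs to the mask when its
#' centre satisfies the ellipse inequality. This is the reference object
#' used by segmentation recovery tests.
#'
#' @param x,y centre in pixels (0-based).
#' @param major_px,minor_px full axis lengths in pixels.
#' @param orientation_deg major-axis orientation, math convention.
#' @param image_shape `c(nrow, ncol)` of the target image.
#' @return logical matrix `image_shape[1] x image_shape[2]`.
#' @export
true_ellipse_mask <- function(x, y, major_px, minor_px, orientation_deg,
                              image_shape) {
  nr <- image_shape[1]; nc <- image_shape[2]
  px <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  py <- matrix(rep(0:(nr - 1), nc), nr, nc)
  th <- orientation_deg * pi / 180
  dx <- px - x
  dy <- -(py - y)                       # math convention (y up)
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / (major_px / 2))^2 + (v / (minor_px / 2))^2 <= 1
}

#' Render synthetic phase/nuclear frame pairs from ground-truth tracks
#'
#' @param truth a `ground_truth` data frame from [simulate_tracks()].
#' @param image_shape `c(nrow, ncol)` in pixels.
#' @param noise_sd SD of additive Gaussian noise (gray levels) applied to
#'   both channels before 8-bit quantisation.
#' @param config a [render_config()].
#' @param rng_seed seed for the rendering noise.
#' @return list of frame pairs; each element is a list with `phase` and
#'   `gfp` integer matrices in `[0, 255]`, `frame_index`, and `time_h`.
#'   Attribute `"truth_rendered"` holds the subset of `truth` actually
#'   drawn (cells whose ellipse leaves the field in a frame are truncated
#'   from ground truth for that frame).
#' @export
render_frames <- function(truth, image_shape = c(320, 320), noise_sd = 3,
                          config = render_config(), rng_seed = 1L) {
  stopifnot(is.data.frame(truth), noise_sd >= 0)
  nr <- image_shape[1]; nc <- image_shape[2]
  frames <- sort(unique(truth$frame))
  with_seed(rng_seed, {
    out <- vector("list", length(frames))
    kept <- vector("list", length(frames))
    for (fi in seq_along(frames)) {
      f <- frames[fi]
      sub <- truth[truth$frame == f, , drop = FALSE]
      # truncate cells whose ellipse (plus margin) leaves the field
      marg <- sub$major_px / 2 + 6
      inb <- sub$x - marg >= 0 & sub$x + marg <= nc - 1 &
             sub$y - marg >= 0 & sub$y + marg <= nr - 1
      sub <- sub[inb, , drop = FALSE]
      if (nrow(sub) > 1) {
        d <- as.matrix(dist(sub[, c("x", "y")]))
        diag(d) <- Inf
        if (min(d) < config$min_spacing_px)
          stop("cells closer than min_spacing_px = ", config$min_spacing_px,
               " in frame ", f, "; regenerate tracks with a larger ",
               "min_spacing_px")
      }
      phase <- matrix(config$background, nr, nc)
      gfp <- matrix(config$gfp_background, nr, nc)
      for (ci in seq_len(nrow(sub))) {
        cc <- sub[ci, ]
        a <- cc$major_px / 2; b <- cc$minor_px / 2
        th <- cc$orientation_deg * pi / 180
        x0 <- floor(cc$x - a - 6); x1 <- ceiling(cc$x + a + 6)
        y0 <- floor(cc$y - a - 6); y1 <- ceiling(cc$y + a + 6)
        xs <- x0:x1; ys <- y0:y1
        px <- matrix(rep(xs, each = length(ys)), length(ys))
        py <- matrix(rep(ys, length(xs)), length(ys))
        dx <- px - cc$x; dy <- -(py - cc$y)
        u <- dx * cos(th) + dy * sin(th)
        v <- -dx * sin(th) + dy * cos(th)
        r <- sqrt((u / a)^2 + (v / b)^2)
        g <- (1 - r) * sqrt(a * b)      # approx. px distance to boundary
        w <- 1 / (1 + exp(-g / config$edge_softness_px))
        profile <- (config$interior - config$background) * w -
          (config$interior - config$rim) *
            exp(-(g - config$rim_center_px)^2 / (2 * config$rim_sigma_px^2))
        phase[ys + 1, xs + 1] <- phase[ys + 1, xs + 1] + profile

        # nuclear blob
        g0 <- floor(cc$x - 4 * config$gfp_sigma_px)
        g1 <- ceiling(cc$x + 4 * config$gfp_sigma_px)
        h0 <- floor(cc$y - 4 * config$gfp_sigma_px)
        h1 <- ceiling(cc$y + 4 * config$gfp_sigma_px)
        gx <- g0:g1; gy <- h0:h1
        bx <- matrix(rep(gx, each = length(gy)), length(gy))
        by <- matrix(rep(gy, length(gx)), length(gy))
        blob <- config$gfp_amplitude *
          exp(-((bx - cc$x)^2 + (by - cc$y)^2) / (2 * config$gfp_sigma_px^2))
        gfp[gy + 1, gx + 1] <- gfp[gy + 1, gx + 1] + blob
      }
      if (noise_sd > 0) {
        phase <- phase + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
        gfp <- gfp + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
      }
      out[[fi]] <- list(
        phase = matrix(pmin(pmax(round(phase), 0), 255), nr, nc),
        gfp = matrix(pmin(pmax(round(gfp), 0), 255), nr, nc),
        frame_index = f,
        time_h = sub$time_h[1] %||% unique(truth$time_h[truth$frame == f])[1]
      )
      kept[[fi]] <- sub
    }
    truth_rendered <- do.call(rbind, kept)
    attr(out, "truth_rendered") <- truth_rendered
    out
  })
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a
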