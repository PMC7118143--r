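#' Fit the projected path to first-half positions
#'
#' Fits a reference line to the smoothed positions of a cell's first-half
#' window by iteratively reweighted least squares with Tukey bisquare
#' weights (tuning constant 4.685, scale = 1.4826 * MAD of the residuals,
#' at most 50 iterations, convergence tolerance 1e-8 on the
#' coefficients). The coordinate with the larger variance is used as the
#' regressor so near-vertical paths do not degenerate. The direction sign
#' is chosen so the unit direction points along the net first-half
#' displacement.
#'
#' @param first_half_xy n x 2 matrix of positions in image coordinates
#'   (x right, y down); at least 5 points.
#' @return list of class `"projected_path"` with fields `direction`
#'   (unit vector, math convention: y up), `path_angle_deg` (heading of
#'   the line in degrees), `anchor` (a point on the line, image
#'   coordinates), `n_points_used`, `robust_scale`, `iterations`.
#' @export
#' @examples
#' xy <- cbind(0:9, -(2 * (0:9) + 1))   # y = 2x + 1 in math coordinates
#' fit_projected_path(xy)$path_angle_deg
fit_projected_path <- function(first_half_xy) {
  xy <- as.matrix(first_half_xy)
  if (nrow(xy) < 5) stop("fewer than 5 points in the fit window")
  x <- xy[, 1]; ym <- -xy[, 2]          # math convention
  if (var(x) < 1e-24 && var(ym) < 1e-24) stop("degenerate-path: all points identical")

  swap <- var(ym) > var(x)              # regress the steadier coordinate
  u <- if (swap) ym else x              # regressor
  v <- if (swap) x else ym              # response
  X <- cbind(1, u)
  beta <- theil_sen(u, v)               # leverage-robust initialisation
  cc <- 4.685
  s <- NA_real_
  iter <- 0L
  for (it in 1:50) {
    iter <- it
    r <- v - X %*% beta
    s <- mad(r, center = 0)             # 1.4826 * median(|r|)
    if (s < 1e-12) break                 # exact fit
    w <- (1 - pmin(abs(r / (cc * s)), 1)^2)^2
    if (sum(w > 0) < 2) break
    beta_new <- qr.coef(qr(X * sqrt(as.vector(w))), v * sqrt(as.vector(w)))
    if (max(abs(beta_new - beta)) < 1e-8 * max(1, max(abs(beta)))) {
      beta <- beta_new; break
    }
    beta <- beta_new
  }
  slope <- unname(beta[2])
  dir <- if (swap) c(slope, 1) else c(1, slope)
  dir <- dir / sqrt(sum(dir^2))
  net <- c(x[length(x)] - x[1], ym[length(ym)] - ym[1])
  if (sum(dir * net) < 0) dir <- -dir
  structure(list(direction = dir,
                 path_angle_deg = atan2(dir[2], dir[1]) * 180 / pi,
                 anchor = c(mean(x), mean(-ym)),
                 n_points_used = nrow(xy),
                 robust_scale = s, iterations = iter),
            class = "projected_path")
}

# median of pairwise slopes + matching intercept; robust to leverage
# points that would corrupt an ordinary least-squares initialisation
theil_sen <- function(u, v) {
  n <- length(u)
  ij <- combn(n, 2)
  du <- u[ij[2, ]] - u[ij[1, ]]
  dv <- v[ij[2, ]] - v[ij[1, ]]
  ok <- abs(du) > 1e-12
  slope <- if (any(ok)) median(dv[ok] / du[ok]) else 0
  c(median(v - slope * u), slope)
}

path_angle <- function(path) {
  if (inherits(path, "projected_path")) path$path_angle_deg
  else as.numeric(path)
}

#' Axis rotation relative to the projected path
#'
#' Signed difference between the (headless) major-axis orientation and the
#' path heading, folded modulo 180 degrees into `[-90, 90)`.
#'
#' @param orientation_deg major-axis orientation(s) in degrees.
#' @param path a `projected_path` or a numeric path heading in degrees.
#' @return rotation angle(s) in degrees.
#' @export
#' @examples
#' axis_rotation(100, 0)   # -80
axis_rotation <- function(orientation_deg, path) {
  fold_axis_angle(orientation_deg - path_angle(path))
}

#' Turning angle of the movement vector relative to the projected path
#'
#' Signed angle from the path direction to the movement vector, wrapped to
#' `(-180, 180]`. Zero movement vectors have no heading and yield `NA`.
#'
#' @param movement_vec n x 2 matrix of displacement vectors in image
#'   coordinates (y down).
#' @param path a `projected_path` or numeric heading in degrees.
#' @return turning angle(s) in degrees (`NA` for zero vectors).
#' @export
turning_angle <- function(movement_vec, path) {
  wrap_angle_180(heading_of(movement_vec) - path_angle(path))
}

#' Accordance angle between movement vector and major axis
#'
#' Headless difference between the movement heading and the major-axis
#' orientation, folded to `[-90, 90)`. Zero movement vectors yield `NA`.
#'
#' @param movement_vec n x 2 matrix of displacement vectors (image
#'   coordinates).
#' @param orientation_deg major-axis orientation(s) in degrees.
#' @return accordance angle(s) in degrees.
#' @export
accordance_angle <- function(movement_vec, orientation_deg) {
  fold_axis_angle(heading_of(movement_vec) - orientation_deg)
}

#' Per-frame angle records for one cell
#'
#' Joins a trajectory with its per-frame axis orientations, fits nothing:
#' the projected path must be supplied. The movement vector at frame `k`
#' is `smooth_xy[k+1] - smooth_xy[k]`. Only frames whose time lies inside
#' `window_h` enter the result; records are invalid when the movement
#' vector is zero, the orientation is missing, or the frame was excluded
#' by shape quality control.
#'
#' @param trajectory a [make_trajectory()] object.
#' @param orientations data.frame with columns `frame, orientation_deg`
#'   and optionally `excluded`.
#' @param path a `projected_path`.
#' @param window_h `c(min, max)` time window in hours (default the latter
#'   half, 48–54 h).
#' @return data.frame `cell_id, frame, time_h, rotation_deg, turning_deg,
#'   accordance_deg, valid`.
#' @export
compute_angle_records <- function(trajectory, orientations, path,
                                  window_h = c(48, 54)) {
  tr <- trajectory
  nv <- nrow(tr$movement_vec)
  frames <- tr$frames[seq_len(nv)]
  times <- tr$times_h[seq_len(nv)]
  keep <- times >= window_h[1] & times <= window_h[2]
  mv <- tr$movement_vec[keep, , drop = FALSE]
  ori <- orientations$orientation_deg[match(frames[keep],
                                            orientations$frame)]
  excl <- if ("excluded" %in% names(orientations))
    orientations$excluded[match(frames[keep], orientations$frame)]
  else rep(FALSE, sum(keep))
  excl[is.na(excl)] <- TRUE
  turn <- turning_angle(mv, path)
  rot <- axis_rotation(ori, path)
  acc <- accordance_angle(mv, ori)
  valid <- !is.na(turn) & !is.na(ori) & !excl
  data.frame(cell_id = tr$cell_id, frame = frames[keep],
             time_h = times[keep],
             rotation_deg = ifelse(valid, rot, NA_real_),
             turning_deg = ifelse(valid, turn, NA_real_),
             accordance_deg = ifelse(valid, acc, NA_real_),
             valid = valid)
}

# trapezoid integral of a surface sampled on regular grids
trapz2 <- function(density, step_r, step_t) {
  wr <- rep(1, nrow(density)); wr[c(1, length(wr))] <- 0.5
  wt <- rep(1, ncol(density)); wt[c(1, length(wt))] <- 0.5
  as.numeric(wr %*% density %*% wt) * step_r * step_t
}

# Gaussian kernel matrix between grid points and data values
kernel_matrix <- function(grid, values, bw) {
  exp(-(outer(grid, values, "-"))^2 / (2 * bw^2)) / (bw * sqrt(2 * pi))
}

#' Bivariate kernel density of (axis rotation, turning angle)
#'
#' Product-Gaussian kernel density over the (rotation, turning) plane on
#' regular degree grids (rotation over `[-90, 90]`, turning over
#' `[-180, 180]`), bandwidth = kernel SD per dimension (default 20
#' degrees). No periodic wrapping is applied (a plain planar kernel
#' smoother); mass smoothed past the grid edges is compensated by
#' renormalising so the trapezoidal grid integral is 1.
#'
#' @param rotation_deg,turning_deg numeric vectors (paired), or a
#'   data.frame with columns `rotation_deg, turning_deg` and optionally
#'   `valid` as the first argument.
#' @param bandwidth_deg kernel SD in degrees.
#' @param grid_step grid spacing in degrees (default 1).
#' @param renormalize renormalise the grid integral to 1 (default TRUE).
#' @return list of class `"density_surface"` with fields `grid_rotation`,
#'   `grid_turning`, `density` (per degree squared), `bandwidth_deg`, `n`.
#' @export
bivariate_density <- function(rotation_deg, turning_deg = NULL,
                              bandwidth_deg = 20, grid_step = 1,
                              renormalize = TRUE) {
  if (is.data.frame(rotation_deg)) {
    df <- rotation_deg
    if ("valid" %in% names(df)) df <- df[df$valid, , drop = FALSE]
    rotation_deg <- df$rotation_deg
    turning_deg <- df$turning_deg
  }
  ok <- !is.na(rotation_deg) & !is.na(turning_deg)
  rotation_deg <- rotation_deg[ok]; turning_deg <- turning_deg[ok]
  n <- length(rotation_deg)
  if (n < 10) stop("need at least 10 valid records, got ", n)
  gr <- seq(-90, 90, by = grid_step)
  gt <- seq(-180, 180, by = grid_step)
  dens <- matrix(0, length(gr), length(gt))
  chunk <- 20000L
  for (st in seq(1, n, by = chunk)) {
    en <- min(st + chunk - 1L, n)
    Kr <- kernel_matrix(gr, rotation_deg[st:en], bandwidth_deg)
    Kt <- kernel_matrix(gt, turning_deg[st:en], bandwidth_deg)
    dens <- dens + Kr %*% t(Kt)
  }
  dens <- dens / n
  if (renormalize) dens <- dens / trapz2(dens, grid_step, grid_step)
  structure(list(grid_rotation = gr, grid_turning = gt, density = dens,
                 bandwidth_deg = bandwidth_deg, n = n),
            class = "density_surface")
}

#' Peak of a bivariate density surface
#'
#' @param surface a `density_surface` from [bivariate_density()].
#' @return maximum grid density in per degree squared.
#' @export
peak_density <- function(surface) {
  stopifnot(inherits(surface, "density_surface"))
  max(surface$density)
}

#' Accordance rate within a +/- half-width band
#'
#' Fraction of valid records whose movement-vs-axis angular difference
#' lies strictly inside `(-half_width_deg, half_width_deg)`; the
#' denominator counts valid records only.
#'
#' @param records numeric vector of accordance angles, or a data.frame
#'   with columns `accordance_deg` and optionally `valid`.
#' @param half_width_deg band half width (default 15 degrees).
#' @return proportion in `[0, 1]`.
#' @export
accordance_rate <- function(records, half_width_deg = 15) {
  if (is.data.frame(records)) {
    if ("valid" %in% names(records))
      records <- records[records$valid, , drop = FALSE]
    records <- records$accordance_deg
  }
  records <- records[!is.na(records)]
  if (length(records) < 1) stop("no valid records")
  mean(abs(records) < half_width_deg)
}
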