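#' Wrap angles to the half-open interval (-180, 180]
#'
#' Directional (headed) angles such as movement headings and turning angles
#' live on the full circle; the canonical representative is taken in
#' (-180, 180], so a reversal maps to 180 rather than -180.
#'
#' @param deg numeric vector of angles in degrees.
#' @return numeric vector of the same length in (-180, 180].
#' @export
#' @examples
#' wrap_angle_180(c(190, -180, 360, 180))
wrap_angle_180 <- function(deg) {
  w <- ((deg + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Fold axial angles to [-90, 90)
#'
#' An ellipse major axis is headless (180-degree periodic); its canonical
#' representative is taken in [-90, 90).
#'
#' @param deg numeric vector of angles in degrees.
#' @return numeric vector of the same length in [-90, 90).
#' @export
#' @examples
#' fold_axis_angle(c(100, -95, 90))
fold_axis_angle <- function(deg) {
  ((deg + 90) %% 180) - 90
}

# heading of displacement vectors given in image coordinates (y down);
# returns degrees in standard math convention (CCW from +x), NA for zero rows
heading_of <- function(v) {
  v <- matrix(v, ncol = 2)
  zero <- v[, 1] == 0 & v[, 2] == 0
  h <- atan2(-v[, 2], v[, 1]) * 180 / pi
  h[zero] <- NA_real_
  h
}

# evaluate an expression with a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
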