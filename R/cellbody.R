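# conversions between row/col matrices (rows = y, cols = x) and EBImage
# Image objects (indexed x, y)
as_ebi <- function(m) EBImage::Image(t(m))
from_ebi <- function(img) t(EBImage::imageData(img))

#' Segmentation configuration
#'
#' @param crop_size side of the square cutout around the tracked nucleus
#'   (default 244 pixels).
#' @param gradient_threshold `"otsu"` (automatic threshold on the sobel
#'   gradient magnitude) or a numeric threshold on the 0–255 gradient
#'   scale.
#' @param closing_radius_px disk radius of the morphological closing
#'   applied to the edge mask.
#' @param halo_erode_px inward boundary shift (pixels, may be
#'   fractional) compensating the sub-pixel outward halo a thresholded
#'   gradient ring leaves around a step boundary (0 disables).
#' @param solidity_threshold objects whose solidity (pixels over
#'   convex-hull pixels) falls strictly below this are excluded as
#'   crescent-shaped misidentifications (default 0.7; exactly 0.7 is
#'   retained).
#' @param min_area_px connected components below this size are ignored.
#' @param nucleus_gate_px when no component contains the nucleus, the
#'   nearest component within this boundary distance is selected.
#' @return list of class `"segmentation_config"`.
#' @export
segmentation_config <- function(crop_size = 244,
                                gradient_threshold = "otsu",
                                closing_radius_px = 2,
                                halo_erode_px = 0.55,
                                solidity_threshold = 0.7,
                                min_area_px = 10,
                                nucleus_gate_px = 10) {
  stopifnot(solidity_threshold > 0, solidity_threshold < 1, crop_size >= 16)
  structure(list(crop_size = as.integer(crop_size),
                 gradient_threshold = gradient_threshold,
                 closing_radius_px = closing_radius_px,
                 halo_erode_px = halo_erode_px,
                 solidity_threshold = solidity_threshold,
                 min_area_px = min_area_px,
                 nucleus_gate_px = nucleus_gate_px),
            class = "segmentation_config")
}

#' Cut a square crop centered on the tracked nucleus
#'
#' @param phase_frame numeric matrix (rows = y, cols = x).
#' @param nucleus_xy `c(x, y)` 0-based position inside the frame.
#' @param crop_size side length in pixels.
#' @return list with `crop` (matrix) and `offset` (`c(x0, y0)`, 0-based
#'   position of the crop's top-left pixel in frame coordinates, recorded
#'   so crop coordinates map back to frame space).
#' @export
crop_around_nucleus <- function(phase_frame, nucleus_xy, crop_size = 244) {
  nr <- nrow(phase_frame); nc <- ncol(phase_frame)
  x <- nucleus_xy[1]; y <- nucleus_xy[2]
  if (x < 0 || x > nc - 1 || y < 0 || y > nr - 1)
    stop("nucleus position (", x, ", ", y, ") outside frame")
  if (crop_size > nc || crop_size > nr)
    stop("crop_size ", crop_size, " larger than frame ", nc, "x", nr)
  half <- floor(crop_size / 2)
  x0 <- max(0, min(round(x) - half, nc - crop_size))
  y0 <- max(0, min(round(y) - half, nr - crop_size))
  list(crop = phase_frame[(y0 + 1):(y0 + crop_size),
                          (x0 + 1):(x0 + crop_size)],
       offset = c(x0 = x0, y0 = y0))
}

# 3x3 sobel gradient magnitude with replicate border padding; exact
# (shift-based) so constant images give exactly zero everywhere
sobel_magnitude <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- m[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  ii <- 2:(nr + 1); jj <- 2:(nc + 1)
  gx <- (p[ii - 1, jj + 1] + 2 * p[ii, jj + 1] + p[ii + 1, jj + 1]) -
        (p[ii - 1, jj - 1] + 2 * p[ii, jj - 1] + p[ii + 1, jj - 1])
  gy <- (p[ii + 1, jj - 1] + 2 * p[ii + 1, jj] + p[ii + 1, jj + 1]) -
        (p[ii - 1, jj - 1] + 2 * p[ii - 1, jj] + p[ii - 1, jj + 1])
  sqrt(gx^2 + gy^2)
}

#' Detect cell-outline edges with a sobel filter
#'
#' Computes the sobel gradient magnitude and thresholds it (Otsu on the
#' gradient by default). Deterministic given the crop and configuration.
#'
#' @param crop numeric matrix (grayscale crop).
#' @param threshold `"otsu"` or a numeric gradient-magnitude threshold.
#' @return logical edge mask of the same shape (empty for a constant
#'   image).
#' @export
detect_edges <- function(crop, threshold = "otsu") {
  gm <- sobel_magnitude(crop)
  mx <- max(gm)
  if (mx < 1e-8) return(matrix(FALSE, nrow(crop), ncol(crop)))
  if (is.numeric(threshold)) return(gm > threshold)
  thr <- EBImage::otsu(as_ebi(gm / mx), range = c(0, 1))
  gm > thr * mx
}

#' Close cell outlines into filled candidate objects
#'
#' Morphological closing (dilation then erosion with a disk element)
#' followed by hole filling; optionally the boundary is then shifted
#' inward by `halo_erode_px` pixels to compensate the outward halo a
#' thresholded gradient ring leaves around a step boundary. The shift is
#' fractional: the binary object is averaged with a disk kernel and
#' re-thresholded at the level that moves a straight boundary inward by
#' the requested amount — sub-pixel corrections a binary erosion cannot
#' express.
#'
#' @param edge_mask logical matrix from [detect_edges()].
#' @param closing_radius_px disk radius for the closing.
#' @param halo_erode_px inward boundary shift in pixels (default 0:
#'   none; may be fractional).
#' @return logical object mask.
#' @export
close_object <- function(edge_mask, closing_radius_px = 2,
                         halo_erode_px = 0) {
  if (!any(edge_mask)) return(edge_mask)
  img <- as_ebi(edge_mask * 1)
  brush <- EBImage::makeBrush(2 * closing_radius_px + 1, "disc")
  img <- EBImage::closing(img, brush)
  img <- EBImage::fillHull(img)
  obj <- from_ebi(img) > 0
  if (halo_erode_px > 0) {
    R <- max(2, ceiling(halo_erode_px))
    k <- EBImage::makeBrush(2 * R + 1, "disc")
    k <- k / sum(k)
    sm <- from_ebi(EBImage::filter2(as_ebi(obj * 1), k,
                                    boundary = "replicate"))
    t <- min(halo_erode_px / R, 0.999)
    level <- 0.5 + (asin(t) + t * sqrt(1 - t^2)) / pi
    shifted <- sm > level
    if (any(shifted)) obj <- shifted    # tiny objects: keep unshifted
  }
  obj
}

#' Select the connected component belonging to the tracked cell
#'
#' Returns the component containing the nucleus position; if none does,
#' the component whose boundary is nearest to the nucleus within
#' `gate_px`. Components smaller than `min_area_px` are ignored.
#'
#' @param object_mask logical matrix from [close_object()].
#' @param nucleus_xy `c(x, y)` 0-based, in crop coordinates.
#' @param min_area_px minimal component size.
#' @param gate_px distance gate for the nearest-component fallback.
#' @return logical mask of the selected component, or `NULL` when no
#'   component qualifies (the frame is then excluded with reason
#'   `"no-object"`).
#' @export
select_cell_body <- function(object_mask, nucleus_xy, min_area_px = 10,
                             gate_px = 10) {
  lab <- from_ebi(EBImage::bwlabel(as_ebi(object_mask * 1)))
  sizes <- table(lab[lab > 0])
  ids <- as.integer(names(sizes)[sizes >= min_area_px])
  if (length(ids) == 0) return(NULL)
  ix <- round(nucleus_xy[1]) + 1; iy <- round(nucleus_xy[2]) + 1
  hit <- 0L
  if (ix >= 1 && ix <= ncol(lab) && iy >= 1 && iy <= nrow(lab))
    hit <- lab[iy, ix]
  if (!(hit %in% ids)) {
    dmin <- vapply(ids, function(id) {
      idx <- which(lab == id, arr.ind = TRUE)
      min(sqrt((idx[, 2] - 1 - nucleus_xy[1])^2 +
               (idx[, 1] - 1 - nucleus_xy[2])^2))
    }, numeric(1))
    if (min(dmin) > gate_px) return(NULL)
    hit <- ids[which.min(dmin)]
  }
  lab == hit
}

#' Fit the moment-equivalent ellipse of a binary object
#'
#' The object is summarised by the ellipse with the same normalized second
#' central moments: centroid = pixel-coordinate mean, full axis lengths =
#' `4 * sqrt(eigenvalue)` of the 2x2 central second-moment matrix of the
#' pixel centres, orientation = major eigenvector direction (degrees,
#' counterclockwise from +x after flipping the image y-axis, folded to
#' `[-90, 90)`), eccentricity = inter-focal distance over major axis
#' length, area = pixel count, solidity = pixel count over convex-hull
#' pixel count. A mask whose pixels are collinear is flagged excluded with
#' reason `"degenerate"` (minor axis 0).
#'
#' @param object_mask logical matrix (rows = y, cols = x).
#' @param frame_index optional frame index stored in the result.
#' @return one-row data.frame with columns `frame, centroid_x, centroid_y,
#'   area_px, major_px, minor_px, orientation_deg, eccentricity, solidity,
#'   excluded, reason`. Centroids are 0-based crop coordinates (x right,
#'   y down).
#' @export
fit_ellipse <- function(object_mask, frame_index = NA_integer_) {
  idx <- which(object_mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  x <- idx[, 2] - 1
  y <- idx[, 1] - 1
  ym <- -y                               # math convention for angles
  n <- nrow(idx)
  cx <- mean(x); cy <- mean(y); cym <- mean(ym)
  mxx <- mean((x - cx)^2)
  myy <- mean((ym - cym)^2)
  mxy <- mean((x - cx) * (ym - cym))
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2), symmetric = TRUE)
  l1 <- max(ev$values[1], 0); l2 <- max(ev$values[2], 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  orient <- fold_axis_angle(atan2(ev$vectors[2, 1], ev$vectors[1, 1]) *
                              180 / pi)
  degen <- minor < 1e-9
  ecc <- if (degen) NA_real_ else sqrt(1 - (minor / major)^2)
  sol <- if (degen) NA_real_ else solidity_of(x, y, object_mask)
  data.frame(frame = frame_index,
             centroid_x = cx, centroid_y = cy,
             area_px = n, major_px = major, minor_px = minor,
             orientation_deg = orient, eccentricity = ecc, solidity = sol,
             excluded = degen,
             reason = if (degen) "degenerate" else "",
             stringsAsFactors = FALSE)
}

# object pixels over convex-hull pixels; hull pixels counted as pixel
# centres inside the hull polygon of the object's pixel centres, unioned
# with the object itself so solidity is always <= 1
solidity_of <- function(x, y, object_mask) {
  n <- length(x)
  h <- chull(x, y)
  if (length(h) < 3) return(NA_real_)
  poly <- cbind(x[h], y[h])
  poly <- rbind(poly, poly[1, ])
  xs <- min(x):max(x); ys <- min(y):max(y)
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, length(xs))
  inside <- mgcv::in.out(poly, cbind(gx, gy))
  is_obj <- object_mask[cbind(gy + 1, gx + 1)]
  hull_px <- sum(inside | is_obj)
  n / max(hull_px, n)
}

#' Eccentricity from full axis lengths
#'
#' The ratio of the inter-focal distance to the major axis length:
#' `sqrt(1 - (minor/major)^2)`; 0 for a perfect circle, approaching 1 for
#' a line segment.
#'
#' @param minor_px,major_px full axis lengths, `0 < minor_px <= major_px`.
#' @return eccentricity in `[0, 1)`.
#' @export
#' @examples
#' eccentricity_of(6, 10)  # 0.8
eccentricity_of <- function(minor_px, major_px) {
  stopifnot(all(minor_px > 0))
  if (any(minor_px > major_px)) stop("minor axis exceeds major axis")
  sqrt(1 - (minor_px / major_px)^2)
}

#' Apply the solidity quality-control filter
#'
#' Flags fits whose solidity is strictly below the threshold as excluded
#' with reason `"low-solidity"` (a solidity exactly at the threshold is
#' retained); fits already excluded for another reason are unchanged.
#'
#' @param fit data.frame of ellipse fits (one or more rows).
#' @param solidity_threshold default 0.7.
#' @return the data.frame with `excluded`/`reason` updated.
#' @export
qc_filter <- function(fit, solidity_threshold = 0.7) {
  low <- !fit$excluded & !is.na(fit$solidity) &
    fit$solidity < solidity_threshold
  fit$excluded[low] <- TRUE
  fit$reason[low] <- "low-solidity"
  fit
}

# excluded-fit placeholder row
excluded_fit_row <- function(frame_index, reason) {
  data.frame(frame = frame_index, centroid_x = NA_real_,
             centroid_y = NA_real_, area_px = NA_integer_,
             major_px = NA_real_, minor_px = NA_real_,
             orientation_deg = NA_real_, eccentricity = NA_real_,
             solidity = NA_real_, excluded = TRUE, reason = reason,
             stringsAsFactors = FALSE)
}

#' Segment and profile one cell in one phase-contrast frame
#'
#' Runs the full shape-profiling chain: crop around the tracked nucleus,
#' sobel edge detection, morphological closing and hole filling, selection
#' of the component belonging to the tracked cell, moment-equivalent
#' ellipse fit, and the solidity quality-control filter. Centroids are
#' mapped back to frame coordinates.
#'
#' @param phase_frame numeric matrix (full frame).
#' @param nucleus_xy `c(x, y)` 0-based nucleus position in frame
#'   coordinates.
#' @param config a [segmentation_config()].
#' @param frame_index stored in the result.
#' @return one-row data.frame as in [fit_ellipse()].
#' @export
segment_frame <- function(phase_frame, nucleus_xy,
                          config = segmentation_config(),
                          frame_index = NA_integer_) {
  cr <- crop_around_nucleus(phase_frame, nucleus_xy, config$crop_size)
  edges <- detect_edges(cr$crop, config$gradient_threshold)
  obj <- close_object(edges, config$closing_radius_px, config$halo_erode_px)
  nuc_crop <- nucleus_xy - cr$offset
  sel <- select_cell_body(obj, nuc_crop, config$min_area_px,
                          config$nucleus_gate_px)
  if (is.null(sel))
    return(excluded_fit_row(frame_index, "no-object"))
  fit <- fit_ellipse(sel, frame_index)
  fit$centroid_x <- fit$centroid_x + cr$offset[1]
  fit$centroid_y <- fit$centroid_y + cr$offset[2]
  qc_filter(fit, config$solidity_threshold)
}

#' Segment a tracked cell across all frames
#'
#' @param frames list of frame pairs from [render_frames()] (or any list
#'   whose elements have `phase` and `frame_index`).
#' @param tracks data.frame with columns `cell_id, frame, x, y` (nucleus
#'   positions in frame coordinates).
#' @param config a [segmentation_config()].
#' @param manual_exclusions optional data.frame `cell_id, frame` of frames
#'   to exclude by hand (reason `"manual"`), mirroring a by-eye exclusion
#'   pass.
#' @param t0_h,dt_h time of frame 0 and frame interval (hours).
#' @return data.frame with one row per (cell, frame):
#'   `cell_id, frame, time_h` plus the [fit_ellipse()] columns.
#' @export
segment_cells <- function(frames, tracks, config = segmentation_config(),
                          manual_exclusions = NULL, t0_h = 42, dt_h = 0.25) {
  frame_idx <- vapply(frames, function(f) f$frame_index, numeric(1))
  rows <- vector("list", nrow(tracks))
  for (r in seq_len(nrow(tracks))) {
    tr <- tracks[r, ]
    manual <- !is.null(manual_exclusions) &&
      any(manual_exclusions$cell_id == tr$cell_id &
            manual_exclusions$frame == tr$frame)
    if (manual) {
      fit <- excluded_fit_row(tr$frame, "manual")
    } else {
      fr <- frames[[match(tr$frame, frame_idx)]]
      fit <- segment_frame(fr$phase, c(tr$x, tr$y), config, tr$frame)
    }
    fit <- cbind(data.frame(cell_id = tr$cell_id), fit)
    fit$time_h <- t0_h + dt_h * tr$frame
    rows[[r]] <- fit
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("cell_id", "frame", "time_h", "centroid_x", "centroid_y",
          "area_px", "major_px", "minor_px", "orientation_deg",
          "eccentricity", "solidity", "excluded", "reason")]
}
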