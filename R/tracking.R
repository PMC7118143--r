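# centered moving average with symmetrically shrinking windows at the ends
# (track length preserved; first/last points use progressively smaller
# symmetric windows). xy: n x 2 matrix.
moving_average <- function(xy, window) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  stopifnot(window %% 2 == 1, window >= 1)
  if (window > n) stop("smoothing window (", window, ") exceeds track length (",
                       n, ")")
  half <- (window - 1) / 2
  out <- xy
  if (half > 0) {
    cs <- rbind(0, apply(xy, 2, cumsum))
    for (i in seq_len(n)) {
      h <- min(half, i - 1, n - i)
      out[i, ] <- (cs[i + h + 1, ] - cs[i - h, ]) / (2 * h + 1)
    }
  }
  out
}

#' Tracking configuration
#'
#' @param gfp_threshold_method thresholding method for nuclear detection
#'   (only `"otsu"` implemented).
#' @param max_link_px frame-to-frame linking gate in pixels.
#' @param smooth_window odd window of the positional moving average
#'   (default 5, the five-time-point smoothing of the published protocol).
#' @param min_track_frames tracks shorter than this are discarded.
#' @param min_blob_px minimal nuclear blob size in pixels.
#' @param distance_band_px optional `c(min, max)` distance band from the
#'   aggregate centre for track inclusion (`NULL` = no filter).
#' @param aggregate_xy aggregate centre used by `distance_band_px`.
#' @return list of class `"tracking_config"`.
#' @export
tracking_config <- function(gfp_threshold_method = "otsu",
                            max_link_px = 15, smooth_window = 5,
                            min_track_frames = 40, min_blob_px = 4,
                            distance_band_px = NULL,
                            aggregate_xy = c(0, 0)) {
  stopifnot(smooth_window %% 2 == 1, smooth_window >= 1, max_link_px > 0)
  structure(list(gfp_threshold_method = gfp_threshold_method,
                 max_link_px = max_link_px,
                 smooth_window = as.integer(smooth_window),
                 min_track_frames = as.integer(min_track_frames),
                 min_blob_px = min_blob_px,
                 distance_band_px = distance_band_px,
                 aggregate_xy = aggregate_xy),
            class = "tracking_config")
}

#' Detect nuclei in a nuclear-fluorescence frame
#'
#' Thresholds the frame (Otsu), labels connected components, drops blobs
#' below `min_blob_px` pixels, and returns background-corrected
#' intensity-weighted centroids.
#'
#' @param gfp_frame numeric matrix (rows = y, cols = x), 8-bit gray levels.
#' @param threshold_method `"otsu"` (default) or a numeric threshold on
#'   the 0–255 scale.
#' @param min_blob_px minimal blob size in pixels.
#' @return data.frame with columns `x, y` (0-based pixel-centre
#'   coordinates), possibly zero rows.
#' @export
detect_nuclei <- function(gfp_frame, threshold_method = "otsu",
                          min_blob_px = 4) {
  g <- gfp_frame / 255
  if (max(g) - min(g) < 1e-8)
    return(data.frame(x = numeric(0), y = numeric(0)))
  thr <- if (is.numeric(threshold_method)) threshold_method / 255
         else EBImage::otsu(EBImage::Image(t(g)), range = c(0, 1))
  mask <- g > thr
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask)))))
  ids <- setdiff(unique(as.vector(lab)), 0)
  cent <- lapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < min_blob_px) return(NULL)
    w <- g[idx] - thr
    data.frame(x = sum((idx[, 2] - 1) * w) / sum(w),
               y = sum((idx[, 1] - 1) * w) / sum(w))
  })
  cent <- do.call(rbind, cent)
  if (is.null(cent)) data.frame(x = numeric(0), y = numeric(0)) else cent
}

#' Link per-frame detections into single-cell trajectories
#'
#' Gated mutual-nearest-neighbour linking between consecutive frames:
#' a detection pair is linked when each is the other's nearest neighbour
#' and their distance is within `max_link_px`. Unmatched detections start
#' new tracks; there is no gap closing, so a missed detection splits a
#' track. Tracks shorter than `min_track_frames` are discarded.
#'
#' @param detections list of per-frame data frames with columns `x, y`
#'   (one element per frame, in frame order), or a data.frame with columns
#'   `frame, x, y`.
#' @param max_link_px linking gate (pixels).
#' @param min_track_frames minimal retained track length (frames).
#' @param frame_offset frame index of the first list element (default 0).
#' @return data.frame with columns `cell_id, frame, x, y`.
#' @export
link_tracks <- function(detections, max_link_px = 15, min_track_frames = 40,
                        frame_offset = 0L) {
  if (is.data.frame(detections)) {
    frames <- sort(unique(detections$frame))
    detections <- lapply(frames, function(f)
      detections[detections$frame == f, c("x", "y"), drop = FALSE])
    frame_offset <- frames[1]
    stopifnot(all(diff(frames) == 1))
  }
  nf <- length(detections)
  stopifnot(nf >= 2)
  tracks <- list()          # each: list(frames=, x=, y=)
  active <- integer(0)      # track index per detection row of previous frame
  prev <- NULL
  for (f in seq_len(nf)) {
    cur <- as.data.frame(detections[[f]])
    ncur <- nrow(cur)
    assigned <- rep(NA_integer_, ncur)
    if (!is.null(prev) && nrow(prev) > 0 && ncur > 0) {
      d <- sqrt(outer(prev$x, cur$x, "-")^2 + outer(prev$y, cur$y, "-")^2)
      nn_prev <- apply(d, 1, which.min)   # nearest current for each prev
      nn_cur <- apply(d, 2, which.min)    # nearest prev for each current
      for (i in seq_len(nrow(prev))) {
        j <- nn_prev[i]
        if (nn_cur[j] == i && d[i, j] <= max_link_px)
          assigned[j] <- active[i]
      }
    }
    new_active <- integer(ncur)
    for (j in seq_len(ncur)) {
      if (is.na(assigned[j])) {
        tracks[[length(tracks) + 1]] <-
          list(frames = integer(0), x = numeric(0), y = numeric(0))
        assigned[j] <- length(tracks)
      }
      t <- tracks[[assigned[j]]]
      t$frames <- c(t$frames, f - 1L + frame_offset)
      t$x <- c(t$x, cur$x[j]); t$y <- c(t$y, cur$y[j])
      tracks[[assigned[j]]] <- t
      new_active[j] <- assigned[j]
    }
    active <- new_active
    prev <- cur
  }
  keep <- which(vapply(tracks, function(t) length(t$frames), 1L) >=
                  min_track_frames)
  out <- lapply(seq_along(keep), function(k) {
    t <- tracks[[keep[k]]]
    data.frame(cell_id = k, frame = t$frames, x = t$x, y = t$y)
  })
  if (length(out) == 0)
    return(data.frame(cell_id = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0)))
  do.call(rbind, out)
}

#' Smooth raw positions with a centered moving average
#'
#' Interior points use the full window; the first and last points use
#' symmetrically shrinking windows so track length is preserved (this
#' affects the first and last `(window-1)/2` movement vectors).
#'
#' @param raw_xy n x 2 matrix (or data.frame) of positions.
#' @param smooth_window odd window length, at most the track length.
#' @return n x 2 matrix of smoothed positions.
#' @export
smooth_positions <- function(raw_xy, smooth_window = 5) {
  moving_average(raw_xy, smooth_window)
}

#' Per-frame movement vectors by forward differencing
#'
#' @param smooth_xy n x 2 matrix of (smoothed) positions.
#' @return (n-1) x 2 matrix of displacement vectors; attribute
#'   `"zero"` flags frames with a zero displacement (stationary).
#' @export
movement_vectors <- function(smooth_xy) {
  smooth_xy <- as.matrix(smooth_xy)
  stopifnot(nrow(smooth_xy) >= 2)
  v <- diff(smooth_xy)
  attr(v, "zero") <- v[, 1] == 0 & v[, 2] == 0
  v
}

#' Assemble a trajectory from raw per-frame positions
#'
#' @param cell_id identifier.
#' @param frames 0-based frame indices (consecutive).
#' @param raw_xy n x 2 positions (pixels).
#' @param config a [tracking_config()].
#' @param t0_h acquisition start time in hours (default 42).
#' @param dt_h hours per frame (default 0.25).
#' @return list of class `"trajectory"` with fields `cell_id, frames,
#'   times_h, raw_xy, smooth_xy, movement_vec`.
#' @export
make_trajectory <- function(cell_id, frames, raw_xy,
                            config = tracking_config(),
                            t0_h = 42, dt_h = 0.25) {
  raw_xy <- as.matrix(raw_xy)
  stopifnot(length(frames) == nrow(raw_xy), all(diff(frames) == 1))
  sm <- smooth_positions(raw_xy, config$smooth_window)
  structure(list(cell_id = cell_id, frames = as.integer(frames),
                 times_h = t0_h + dt_h * as.numeric(frames),
                 raw_xy = raw_xy, smooth_xy = sm,
                 movement_vec = movement_vectors(sm)),
            class = "trajectory")
}
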