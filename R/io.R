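#' Write rendered frame pairs as multi-page TIFF stacks
#'
#' Writes one 8-bit stack per channel (`phase.tif`, `gfp.tif`) into
#' `dir`. Requires the `tiff` package.
#'
#' @param frames list of frame pairs from [render_frames()].
#' @param dir output directory (created if missing).
#' @return invisibly, the two file paths.
#' @export
write_frames_tiff <- function(frames, dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF stacks")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(phase = file.path(dir, "phase.tif"),
             gfp = file.path(dir, "gfp.tif"))
  tiff::writeTIFF(lapply(frames, function(f) f$phase / 255),
                  paths["phase"], bits.per.sample = 8)
  tiff::writeTIFF(lapply(frames, function(f) f$gfp / 255),
                  paths["gfp"], bits.per.sample = 8)
  invisible(paths)
}

#' Read an 8-bit grayscale TIFF stack into a list of matrices
#'
#' @param path TIFF file.
#' @param frame_offset frame index of the first page (default 0).
#' @param t0_h,dt_h acquisition start and frame interval (hours).
#' @return list of single-channel elements with `phase` = NULL semantics
#'   left to the caller: each element holds `image` (matrix, 0–255),
#'   `frame_index`, `time_h`.
#' @export
read_stack_tiff <- function(path, frame_offset = 0L, t0_h = 42,
                            dt_h = 0.25) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF stacks")
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(seq_along(pages), function(i) {
    m <- pages[[i]]
    if (length(dim(m)) == 3) m <- m[, , 1]
    list(image = round(m * 255),
         frame_index = frame_offset + i - 1L,
         time_h = t0_h + dt_h * (frame_offset + i - 1))
  })
}

#' Write ground-truth tracks to CSV
#'
#' Header: `cell_id,frame,time_h,x,y,major_px,minor_px,orientation_deg,
#' heading_deg`.
#'
#' @param truth a `ground_truth` data frame.
#' @param path output CSV path.
#' @export
write_ground_truth_csv <- function(truth, path) {
  write.csv(as.data.frame(truth), path, row.names = FALSE)
  invisible(path)
}

#' Read positions CSV (bypassing detection)
#'
#' Expects at least columns `cell_id, frame, x, y`; `time_h` is derived
#' from the frame index when absent.
#'
#' @param path CSV path.
#' @param t0_h,dt_h acquisition start and frame interval (hours).
#' @return data.frame `cell_id, frame, time_h, x, y`.
#' @export
read_positions_csv <- function(path, t0_h = 42, dt_h = 0.25) {
  df <- read.csv(path)
  stopifnot(all(c("cell_id", "frame", "x", "y") %in% names(df)))
  if (!"time_h" %in% names(df)) df$time_h <- t0_h + dt_h * df$frame
  df[, c("cell_id", "frame", "time_h", "x", "y")]
}
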