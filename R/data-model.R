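#' @keywords internal
"_PACKAGE"

# Typed condition helper: every user-facing failure carries a
# "smartline_<class>" condition class so callers can handle it.
stop_smartline <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("smartline_", class), "smartline_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop_smartline("nonfinite", "%s contains NaN/Inf or missing values", what)
  invisible(x)
}

#' Acquisition metadata
#'
#' Spatial and temporal resolution of an acquisition: pixel size
#' (micrometres per pixel), single-frame imaging period (s), single-line
#' imaging period (s) and pixel dwell time (microseconds).
#'
#' @param pixel_size Pixel size, um/pixel.
#' @param frame_period Frame period, s.
#' @param line_period Line period, s.
#' @param dwell_time Pixel dwell time, us.
#' @return An `acquisition_metadata` object.
#' @export
acquisition_metadata <- function(pixel_size, frame_period, line_period, dwell_time) {
  v <- c(pixel_size = pixel_size, frame_period = frame_period,
         line_period = line_period, dwell_time = dwell_time)
  assert_finite(v, "acquisition metadata")
  if (any(v <= 0))
    stop_smartline("bad_metadata", "metadata field '%s' must be strictly positive",
                   names(v)[which(v <= 0)[1]])
  structure(as.list(v), class = "acquisition_metadata")
}

#' Raster movie
#'
#' A time-ordered stack of 2D frames with acquisition metadata. Frames are
#' stored as a `[T, H, W]` array of non-negative fluorescence values.
#'
#' @param frames Numeric array `[T, H, W]` (a single `[H, W]` matrix is
#'   promoted to `T = 1`).
#' @param meta An [acquisition_metadata()] object.
#' @return A `raster_movie` object with fields `frames` and `meta`.
#' @export
raster_movie <- function(frames, meta) {
  if (is.matrix(frames)) frames <- array(frames, c(1L, dim(frames)))
  if (length(dim(frames)) != 3L)
    stop_smartline("bad_movie", "frames must be a [T, H, W] array")
  assert_finite(frames, "movie frames")
  if (!inherits(meta, "acquisition_metadata"))
    stop_smartline("bad_metadata", "meta must be an acquisition_metadata object")
  structure(list(frames = frames, meta = meta), class = "raster_movie")
}

n_frames <- function(movie) dim(movie$frames)[1]
fov_shape <- function(movie) dim(movie$frames)[2:3]

#' @export
print.raster_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("raster_movie: %d frames of %d x %d px (%.3g s/frame)\n",
              d[1], d[2], d[3], x$meta$frame_period))
  invisible(x)
}

#' Region of interest
#'
#' A weighted pixel footprint on the field-of-view grid. Coordinates are
#' 0-based `(row, col)` pairs with the origin at the top-left pixel.
#'
#' @param id Integer identifier (unique within a segmentation).
#' @param pixels Integer matrix `[n, 2]` of 0-based (row, col) coordinates.
#' @param weights Non-negative per-pixel weights (default all 1).
#' @return An `roi` object; `centroid` is the weight-mean of coordinates.
#' @export
roi <- function(id, pixels, weights = NULL) {
  pixels <- matrix(as.numeric(pixels), ncol = 2)
  if (nrow(pixels) == 0) stop_smartline("empty_roi", "ROI %s has no pixels", id)
  if (is.null(weights)) weights <- rep(1, nrow(pixels))
  assert_finite(pixels, "ROI pixels"); assert_finite(weights, "ROI weights")
  if (any(weights < 0)) stop_smartline("negative_weight", "negative weight in ROI %s", id)
  if (length(weights) != nrow(pixels))
    stop_smartline("bad_roi", "weights length != number of pixels in ROI %s", id)
  w <- weights / sum(weights)
  structure(list(id = as.integer(id), pixels = pixels, weights = weights,
                 centroid = c(sum(pixels[, 1] * w), sum(pixels[, 2] * w))),
            class = "roi")
}

#' Segmentation
#'
#' An ordered list of ROIs on a common field of view, with optional
#' surround footprints (see [add_surround()]).
#'
#' @param fov_shape Integer `(H, W)`.
#' @param rois List of [roi()] objects with unique ids.
#' @param surround_width Surround radius in pixels (0 = no surrounds).
#' @param surrounds Optional list (parallel to `rois`) of 0-based pixel
#'   matrices; normally filled in by [add_surround()].
#' @return A `segmentation` object.
#' @export
segmentation <- function(fov_shape, rois, surround_width = 0L, surrounds = NULL) {
  fov_shape <- as.integer(fov_shape)
  ids <- vapply(rois, function(r) r$id, integer(1))
  if (anyDuplicated(ids)) stop_smartline("duplicate_roi_id", "ROI ids must be unique")
  for (r in rois) {
    p <- r$pixels
    if (any(p < 0) || any(p[, 1] >= fov_shape[1]) || any(p[, 2] >= fov_shape[2]))
      stop_smartline("roi_out_of_bounds", "ROI %d has pixels outside the FOV", r$id)
  }
  if (surround_width == 0 && !is.null(surrounds))
    stop_smartline("bad_segmentation", "surround footprints present with surround_width = 0")
  structure(list(fov_shape = fov_shape, rois = rois,
                 surround_width = as.integer(surround_width),
                 surrounds = surrounds),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation: %d ROIs on a %d x %d FOV (surround width %d px)\n",
              length(x$rois), x$fov_shape[1], x$fov_shape[2], x$surround_width))
  invisible(x)
}

#' Smart line scanning trajectory
#'
#' An ordered sequence of 0-based FOV pixel coordinates with per-pixel
#' provenance labels (`"roi <k>"`, `"surround <k>"` or `"refbox"`), an
#' optional reference-box rectangle and the line period.
#'
#' @param coords Integer matrix `[n, 2]` of 0-based (row, col) pixels.
#' @param labels Character vector of per-pixel source labels.
#' @param refbox Optional `(row0, col0, height, width)` rectangle whose
#'   pixels are the trailing block of `coords`, in row-major order.
#' @param line_period Time to scan the whole trajectory once, s (NA if
#'   not yet known).
#' @return An `sls_trajectory` object.
#' @export
sls_trajectory <- function(coords, labels, refbox = NULL, line_period = NA_real_) {
  coords <- matrix(as.integer(round(coords)), ncol = 2)
  if (length(labels) != nrow(coords))
    stop_smartline("bad_trajectory", "labels length != number of coordinates")
  if (!is.null(refbox)) {
    refbox <- as.integer(refbox)
    nref <- refbox[3] * refbox[4]
    n <- nrow(coords)
    exp_coords <- cbind(rep(refbox[1] + seq_len(refbox[3]) - 1L, each = refbox[4]),
                        rep(refbox[2] + seq_len(refbox[4]) - 1L, times = refbox[3]))
    if (n < nref || !identical(coords[(n - nref + 1):n, , drop = FALSE], exp_coords))
      stop_smartline("bad_trajectory",
                     "refbox pixels must be the trailing coords in row-major order")
  }
  structure(list(coords = coords, labels = as.character(labels),
                 refbox = refbox, line_period = as.numeric(line_period)),
            class = "sls_trajectory")
}

#' @export
print.sls_trajectory <- function(x, ...) {
  cat(sprintf("sls_trajectory: %d pixels (%d refbox)%s\n", nrow(x$coords),
              if (is.null(x$refbox)) 0L else x$refbox[3] * x$refbox[4],
              if (is.na(x$line_period)) "" else
                sprintf(", line period %.4g s", x$line_period)))
  invisible(x)
}

#' Smart line scanning recording
#'
#' A `[n_lines, n_pixels]` fluorescence array: one row per trajectory
#' pass, one column per trajectory pixel, plus strictly increasing line
#' timestamps spaced by the trajectory's line period.
#'
#' @param lines Numeric matrix `[n_lines, n_pixels]`.
#' @param timestamps Line timestamps, s. Defaults to
#'   `(0:(n_lines-1)) * line_period`.
#' @param trajectory An [sls_trajectory()] with `nrow(coords) == n_pixels`.
#' @param crop_index Optional first discarded line (1-based) after
#'   large-artefact detection.
#' @return An `sls_recording` object.
#' @export
sls_recording <- function(lines, trajectory, timestamps = NULL, crop_index = NULL) {
  lines <- as.matrix(lines)
  assert_finite(lines, "recording lines")
  if (ncol(lines) != nrow(trajectory$coords))
    stop_smartline("bad_recording", "lines have %d pixels but trajectory has %d",
                   ncol(lines), nrow(trajectory$coords))
  if (is.null(timestamps)) {
    lp <- trajectory$line_period
    if (is.na(lp)) stop_smartline("bad_recording",
                                  "timestamps required when trajectory has no line period")
    timestamps <- (seq_len(nrow(lines)) - 1) * lp
  }
  if (length(timestamps) != nrow(lines) || any(diff(timestamps) <= 0))
    stop_smartline("bad_recording", "timestamps must be strictly increasing, one per line")
  structure(list(lines = lines, timestamps = as.numeric(timestamps),
                 trajectory = trajectory, crop_index = crop_index),
            class = "sls_recording")
}

#' @export
print.sls_recording <- function(x, ...) {
  cat(sprintf("sls_recording: %d lines x %d pixels (%.4g s)\n",
              nrow(x$lines), ncol(x$lines), diff(range(x$timestamps))))
  invisible(x)
}

# line period of a recording, from trajectory or timestamps
rec_line_period <- function(rec) {
  lp <- rec$trajectory$line_period
  if (is.finite(lp)) lp else stats::median(diff(rec$timestamps))
}
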