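#' Load a raster movie from TIFF
#'
#' Reads either a single multi-page TIFF or a sequence of page-per-frame
#' TIFF files (sorted lexicographically by file name). Values are taken
#' as stored, with no rescaling.
#'
#' @param path A single TIFF path, a character vector of per-frame TIFF
#'   paths, or a directory containing `.tif`/`.tiff` files.
#' @param meta An [acquisition_metadata()] object.
#' @return A [raster_movie()].
#' @export
load_raster_movie <- function(path, meta) {
  if (length(path) == 1 && dir.exists(path))
    path <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                       full.names = TRUE)
  path <- sort(path)
  if (length(path) == 0) stop_smartline("unreadable", "no TIFF files to read")
  pages <- list()
  for (p in path) {
    if (!file.exists(p)) stop_smartline("unreadable", "cannot read '%s'", p)
    info <- as.data.frame(tiff::readTIFF(p, payload = FALSE))[1, ]
    # 8/16-bit samples are integer counts; 32-bit is IEEE float (the
    # microscopy convention, and what writeTIFF emits at 32 bits)
    is_float <- isTRUE(info$bits.per.sample >= 32)
    pg <- tiff::readTIFF(p, all = TRUE, as.is = !is_float)
    if (!is.list(pg)) pg <- list(pg)
    pages <- c(pages, lapply(pg, function(m) {
      if (length(dim(m)) == 3L) m <- m[, , 1]  # drop extra channels
      m
    }))
  }
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(m) identical(dim(m), shp), logical(1))))
    stop_smartline("inconsistent_pages", "TIFF pages differ in shape")
  frames <- array(0, c(length(pages), shp))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]]
  assert_finite(frames, "movie frames")
  raster_movie(frames, meta)
}

#' Write a raster movie to a multi-page TIFF
#'
#' Integer-valued movies in `[0, 65535]` are stored losslessly as 16-bit
#' integer samples; any other movie is stored as 32-bit float after
#' division by a power-of-two scale (recorded in a JSON sidecar), which
#' is exact up to float32 precision.
#'
#' @param movie A [raster_movie()].
#' @param path Output TIFF path. A `<path>.json` sidecar stores the
#'   acquisition metadata and the scale.
#' @return `path`, invisibly.
#' @export
write_raster_movie <- function(movie, path) {
  fr <- movie$frames
  Tn <- dim(fr)[1]
  is_int <- all(fr == round(fr)) && min(fr) >= 0 && max(fr) <= 65535
  scale <- if (is_int) 65535 else 2^ceiling(log2(max(max(fr), 1)))
  pages <- lapply(seq_len(Tn), function(t) fr[t, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = if (is_int) 16L else 32L)
  jsonlite::write_json(
    list(meta = unclass(movie$meta), scale = scale, integer_samples = is_int),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a movie written by [write_raster_movie()]
#' @param path TIFF path with its `<path>.json` sidecar.
#' @return A [raster_movie()].
#' @export
read_raster_movie <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta <- do.call(acquisition_metadata, as.list(side$meta))
  m <- load_raster_movie(path, meta)
  m$frames <- if (isTRUE(side$integer_samples)) m$frames else
    m$frames * side$scale
  m
}

#' Load a segmentation from a pixel-by-ROI matrix
#'
#' Reads a `[H*W, n_rois]` non-negative matrix (CSV or whitespace-
#' separated text, no header): one column per ROI, with positive values
#' in the rows corresponding to the ROI's pixels, which become the pixel
#' weights.
#'
#' @param path CSV/TXT file path (or a numeric matrix, used directly).
#' @param fov_shape Integer `(H, W)`.
#' @param order Vectorisation order of the pixel rows: `"row"` (default;
#'   row index `r*W + c`) or `"col"` (Matlab heritage, `c*H + r`).
#' @return A [segmentation()].
#' @export
load_segmentation_matrix <- function(path, fov_shape, order = c("row", "col")) {
  order <- match.arg(order)
  H <- fov_shape[1]; W <- fov_shape[2]
  m <- if (is.matrix(path)) path else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
    as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  }
  storage.mode(m) <- "double"
  assert_finite(m, "segmentation matrix")
  if (nrow(m) != H * W)
    stop_smartline("bad_matrix", "matrix has %d rows; expected H*W = %d", nrow(m), H * W)
  if (any(m < 0)) stop_smartline("negative_weight", "negative weight in segmentation matrix")
  rois <- vector("list", ncol(m))
  for (k in seq_len(ncol(m))) {
    idx <- which(m[, k] > 0) - 1L  # 0-based pixel ids
    if (length(idx) == 0) stop_smartline("empty_roi", "column %d is all-zero", k)
    px <- if (order == "row") cbind(idx %/% W, idx %% W) else cbind(idx %% H, idx %/% H)
    rois[[k]] <- roi(k, px, m[idx + 1L, k])
  }
  segmentation(fov_shape, rois)
}

#' Write a segmentation as a pixel-by-ROI matrix
#' @param seg A [segmentation()].
#' @param path Output CSV path; a `<path>.json` sidecar records the FOV
#'   shape and vectorisation order.
#' @param order `"row"` or `"col"` vectorisation of pixel rows.
#' @return `path`, invisibly.
#' @export
write_segmentation_matrix <- function(seg, path, order = c("row", "col")) {
  order <- match.arg(order)
  H <- seg$fov_shape[1]; W <- seg$fov_shape[2]
  m <- matrix(0, H * W, length(seg$rois))
  for (k in seq_along(seg$rois)) {
    r <- seg$rois[[k]]
    idx <- if (order == "row") r$pixels[, 1] * W + r$pixels[, 2] else
      r$pixels[, 2] * H + r$pixels[, 1]
    m[idx + 1, k] <- r$weights
  }
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(fov_shape = seg$fov_shape, order = order),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a segmentation from an integer label mask
#'
#' Nonzero mask values are ROI ids; weights are all 1.
#'
#' @param path 16-bit integer TIFF path, or an integer matrix.
#' @return A [segmentation()].
#' @export
load_label_mask <- function(path) {
  m <- if (is.matrix(path)) path else tiff::readTIFF(path, as.is = TRUE)
  assert_finite(m, "label mask")
  ids <- sort(unique(m[m > 0]))
  if (length(ids) == 0) stop_smartline("empty_roi", "label mask has no nonzero labels")
  rois <- lapply(ids, function(k) {
    w <- which(m == k, arr.ind = TRUE)
    roi(k, w - 1L)
  })
  segmentation(dim(m), rois)
}

#' Write a segmentation as a 16-bit label mask TIFF
#'
#' Overlapping ROI pixels keep the lowest ROI id.
#' @param seg A [segmentation()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(seg, path) {
  m <- matrix(0L, seg$fov_shape[1], seg$fov_shape[2])
  for (r in rev(seg$rois)) m[r$pixels + 1] <- r$id
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Trajectory JSON round trip
#'
#' The schema is a list of `[row, col, label]` triplets plus the refbox
#' rectangle and the line period.
#' @param traj An [sls_trajectory()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_trajectory_json <- function(traj, path) {
  pix <- lapply(seq_len(nrow(traj$coords)), function(i)
    list(traj$coords[i, 1], traj$coords[i, 2], traj$labels[i]))
  jsonlite::write_json(
    list(pixels = pix,
         refbox = if (is.null(traj$refbox)) NULL else as.integer(traj$refbox),
         line_period = traj$line_period),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory_json
#' @export
read_trajectory_json <- function(path) {
  j <- jsonlite::read_json(path)
  coords <- t(vapply(j$pixels, function(p) c(p[[1]], p[[2]]), numeric(2)))
  labels <- vapply(j$pixels, function(p) p[[3]], character(1))
  refbox <- if (is.null(j$refbox)) NULL else unlist(j$refbox)
  lp <- if (is.null(j$line_period)) NA_real_ else j$line_period
  sls_trajectory(coords, labels, refbox, lp)
}

#' SLS recording round trip (plain-text container)
#'
#' The lines matrix is stored as a headerless CSV and a `<path>.json`
#' sidecar holds the timestamps and the trajectory.
#' @param rec An [sls_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sls_recording <- function(rec, path) {
  utils::write.table(rec$lines, path, sep = ",", row.names = FALSE, col.names = FALSE)
  write_trajectory_json(rec$trajectory, paste0(path, ".traj.json"))
  jsonlite::write_json(list(timestamps = rec$timestamps, crop_index = rec$crop_index),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_sls_recording
#' @export
read_sls_recording <- function(path) {
  lines <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(lines) <- NULL
  traj <- read_trajectory_json(paste0(path, ".traj.json"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sls_recording(lines, traj, timestamps = side$timestamps,
                crop_index = side$crop_index)
}

#' Embed an SLS recording as a raster movie
#'
#' Each line becomes one FOV-sized frame: trajectory pixels carry the
#' recorded values and all other pixels are filled with i.i.d. Gaussian
#' noise whose mean and standard deviation are estimated from the whole
#' recording (negative draws clipped to zero).
#'
#' @param rec An [sls_recording()].
#' @param fov_shape Integer `(H, W)` containing all trajectory coords.
#' @param seed RNG seed for the Gaussian fill (explicit for
#'   reproducibility).
#' @param max_lines Cap on the number of embedded lines (default all).
#' @return A [raster_movie()] with `frame_period = line_period`.
#' @export
sls_to_raster <- function(rec, fov_shape, seed, max_lines = nrow(rec$lines)) {
  co <- rec$trajectory$coords
  H <- fov_shape[1]; W <- fov_shape[2]
  if (any(co < 0) || any(co[, 1] >= H) || any(co[, 2] >= W))
    stop_smartline("roi_out_of_bounds", "trajectory coordinates outside the FOV")
  nl <- min(max_lines, nrow(rec$lines))
  mu <- mean(rec$lines); sd0 <- stats::sd(as.vector(rec$lines))
  if (!is.finite(sd0)) sd0 <- 0
  set.seed(seed)
  frames <- array(pmax(0, stats::rnorm(nl * H * W, mu, sd0)), c(nl, H, W))
  lin <- co[, 1] + co[, 2] * H + 1L  # column-major index into an H x W frame
  for (t in seq_len(nl)) {
    f <- frames[t, , ]
    f[lin] <- rec$lines[t, ]
    frames[t, , ] <- f
  }
  lp <- rec_line_period(rec)
  raster_movie(frames, acquisition_metadata(1, lp, lp,
                                            lp / ncol(rec$lines) * 1e6))
}
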