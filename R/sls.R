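#' Classify trajectory pixels against a reference segmentation
#'
#' For every trajectory pixel the minimal Euclidean distance `d` to each
#' ROI's pixel set is computed (pixel centres). Distance intervals map
#' to classes per ROI: `d` in `[0, 1]` = ROI, `(1, 2]` = outer ring,
#' `(2, 4]` = surround. A pixel with a class for exactly one ROI gets
#' that class; a pixel claimed by two or more ROIs is `discarded`; a
#' pixel farther than 4 px from every ROI is `background`.
#'
#' @param traj An [sls_trajectory()].
#' @param ref_seg The reference [segmentation()] used to build the
#'   trajectory.
#' @return A `pixel_classification`: per-pixel `class`, `roi_id` (NA for
#'   background/discarded) and `distance` to the assigned ROI.
#' @export
classify_pixels <- function(traj, ref_seg) {
  if (length(ref_seg$rois) == 0) stop_smartline("empty_roi", "empty segmentation")
  n <- nrow(traj$coords)
  K <- length(ref_seg$rois)
  dmat <- vapply(ref_seg$rois, function(r) min_dist_to_set(traj$coords, r$pixels),
                 numeric(n))
  dmat <- matrix(dmat, n, K)
  cls <- rep("background", n); rid <- rep(NA_integer_, n); dist <- rep(NA_real_, n)
  in_any <- dmat <= 4
  n_claims <- rowSums(in_any)
  ids <- vapply(ref_seg$rois, function(r) r$id, integer(1))
  one <- which(n_claims == 1)
  if (length(one)) {
    k <- max.col(-dmat[one, , drop = FALSE], ties.method = "first")
    d <- dmat[cbind(one, k)]
    cls[one] <- ifelse(d <= 1, "roi", ifelse(d <= 2, "outer_ring", "surround"))
    rid[one] <- ids[k]; dist[one] <- d
  }
  cls[n_claims >= 2] <- "discarded"
  structure(list(class = cls, roi_id = rid, distance = dist,
                 roi_ids = ids, fov_shape = ref_seg$fov_shape,
                 ref_counts = stats::setNames(
                   vapply(ref_seg$rois, function(r) nrow(r$pixels), integer(1)),
                   ids)),
            class = "pixel_classification")
}

# trajectory-pixel indices of a ROI's pool (roi + outer ring + surround)
cls_pool <- function(cls, id,
                     classes = c("roi", "outer_ring", "surround")) {
  which(cls$class %in% classes & cls$roi_id == id)
}

#' Per-line pixel assignment
#'
#' Holds, for every line and ROI, the trajectory-pixel indices counted
#' as that ROI, plus the neuropil pixels used for decontamination.
#' `assigned[[k]]` (and `neuropil[[k]]`) is either a single integer
#' vector (constant over lines) or a list with one vector per line.
#'
#' @param roi_ids Integer ROI ids.
#' @param assigned,neuropil Lists as described above, one entry per ROI.
#' @param n_lines Number of recording lines covered.
#' @return A `line_assignment` object.
#' @export
line_assignment <- function(roi_ids, assigned, neuropil, n_lines) {
  structure(list(roi_ids = roi_ids, assigned = assigned,
                 neuropil = neuropil, n_lines = as.integer(n_lines)),
            class = "line_assignment")
}

asg_get <- function(slot, t) if (is.list(slot)) slot[[t]] else slot

#' Static assignment from a pixel classification
#'
#' ROI pixels are the trajectory pixels classified as that ROI; neuropil
#' pixels are its surround-class pixels.
#'
#' @param cls A [classify_pixels()] result.
#' @param n_lines Number of lines the assignment covers.
#' @return A [line_assignment()].
#' @export
assignment_from_classification <- function(cls, n_lines) {
  assigned <- lapply(cls$roi_ids, function(id) cls_pool(cls, id, "roi"))
  neuropil <- lapply(cls$roi_ids, function(id) cls_pool(cls, id, "surround"))
  line_assignment(cls$roi_ids, assigned, neuropil, n_lines)
}

#' Detect large motion artefacts
#'
#' Pixel traces are mean-centred and reduced by PCA; the first principal
#' component's score vector is fitted with a second-order autoregressive
#' model (ordinary least squares on the two lagged scores). Calcium
#' dynamics are well described by such a model, so the Pearson
#' correlation between the scores and their one-step AR(2) prediction,
#' computed in a trailing window, stays high while the recording is
#' physiological; the first line where it drops below `threshold` marks
#' a large artefact, and that line and everything after it is flagged
#' for discard.
#'
#' @param rec An [sls_recording()].
#' @param window_s Sliding-window width, s (default 10).
#' @param threshold Correlation threshold (default 0.3).
#' @return An `artifact_report`: `pc1_scores`, `ar2_fit`, `sliding_corr`
#'   (NA before the first full window), `crop_index` (first discarded
#'   line, or NULL), `threshold`, `window_s`, `ar_coeffs`.
#' @export
detect_large_artifact <- function(rec, window_s = 10, threshold = 0.3) {
  lp <- rec_line_period(rec)
  L <- max(3L, as.integer(round(window_s / lp)))
  n <- nrow(rec$lines)
  if (n <= 3 * L)
    stop_smartline("too_short", "need more than 3 windows of lines (%d <= %d)",
                   n, 3 * L)
  X <- sweep(rec$lines, 2, colMeans(rec$lines))
  sv <- svd(X, nu = 1, nv = 1)
  v1 <- sv$v[, 1]
  if (mean(v1) < 0) v1 <- -v1
  s <- as.numeric(X %*% v1)
  y <- s[3:n]; x1 <- s[2:(n - 1)]; x2 <- s[1:(n - 2)]
  XtX <- matrix(c(sum(x1^2), sum(x1 * x2), sum(x1 * x2), sum(x2^2)), 2)
  coefs <- tryCatch(as.numeric(solve(XtX, c(sum(x1 * y), sum(x2 * y)))),
                    error = function(e) c(0, 0))
  fit <- rep(NA_real_, n)
  fit[3:n] <- coefs[1] * x1 + coefs[2] * x2
  # trailing-window correlation between scores and fit; the window
  # ending at t covers lines (t-L+1):t and needs fitted values, so the
  # first evaluated line is t = L + 2
  sc <- rep(NA_real_, n)
  sv_ <- s[3:n]; fv <- fit[3:n]
  c1 <- cumsum(sv_); c2 <- cumsum(fv); c11 <- cumsum(sv_^2)
  c22 <- cumsum(fv^2); c12 <- cumsum(sv_ * fv)
  at <- function(cs, i) ifelse(i >= 1, cs[pmax(i, 1)], 0)
  ts <- (L + 2):n
  hi <- ts - 2; lo <- hi - L
  Sx <- at(c1, hi) - at(c1, lo); Sy <- at(c2, hi) - at(c2, lo)
  Sxx <- at(c11, hi) - at(c11, lo); Syy <- at(c22, hi) - at(c22, lo)
  Sxy <- at(c12, hi) - at(c12, lo)
  den <- (L * Sxx - Sx^2) * (L * Syy - Sy^2)
  r <- ifelse(den > 0, (L * Sxy - Sx * Sy) / sqrt(pmax(den, 0)), 0)
  sc[ts] <- pmin(1, pmax(-1, r))
  cross <- which(!is.na(sc) & sc < threshold)
  structure(list(pc1_scores = s, ar2_fit = fit, sliding_corr = sc,
                 crop_index = if (length(cross)) cross[1] else NULL,
                 threshold = threshold, window_s = window_s,
                 ar_coeffs = coefs),
            class = "artifact_report")
}

#' Crop a recording at a detected artefact
#' @param rec An [sls_recording()].
#' @param report A [detect_large_artifact()] result.
#' @return The recording truncated before `crop_index` (unchanged if no
#'   artefact was detected).
#' @export
crop_recording <- function(rec, report) {
  ci <- report$crop_index
  if (is.null(ci)) return(rec)
  keep <- seq_len(ci - 1)
  sls_recording(rec$lines[keep, , drop = FALSE], rec$trajectory,
                timestamps = rec$timestamps[keep], crop_index = ci)
}

# rank-1 PCA reconstruction of a [time x series] matrix (per-series
# mean-centred; means re-added; PC sign fixed so the mean loading >= 0)
rank1_reconstruction <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 1, nv = 1)
  u <- sv$u[, 1]; v <- sv$v[, 1]
  if (mean(v) < 0) { u <- -u; v <- -v }
  sweep(sv$d[1] * u %*% t(v), 2, mu, "+")
}

#' Subtract global background activity
#'
#' A rank-1 PCA representation of the background-pixel activity is
#' averaged across background pixels into a background series `b(t)`,
#' scaled by the contamination `ratio` and subtracted from every
#' trajectory pixel; negative values are clipped to zero.
#'
#' @param rec An [sls_recording()].
#' @param cls A [classify_pixels()] result with >= 2 background pixels.
#' @param ratio Contamination ratio (default 0.7).
#' @return The background-subtracted [sls_recording()], with the
#'   estimated series in `attr(, "background")`.
#' @export
subtract_background <- function(rec, cls, ratio = 0.7) {
  bg <- which(cls$class == "background")
  if (length(bg) < 2)
    stop_smartline("no_background",
                   "background subtraction needs >= 2 background pixels; %s",
                   "scan background pixels or skip this step")
  b <- rowMeans(rank1_reconstruction(rec$lines[, bg, drop = FALSE]))
  out <- sls_recording(pmax(rec$lines - ratio * b, 0), rec$trajectory,
                       timestamps = rec$timestamps, crop_index = rec$crop_index)
  attr(out, "background") <- b
  out
}

# column-wise Eq.-1 SNR of a [window x pixels] matrix; NA if degenerate
col_snr25 <- function(M) {
  n <- nrow(M)
  if (n < 2) return(rep(NA_real_, ncol(M)))
  S <- apply(M, 2, sort)
  h <- (n - 1) * 0.25 + 1
  lo <- floor(h)
  q <- S[lo, ] + (h - lo) * (S[min(lo + 1, n), ] - S[lo, ])
  k <- colSums(S < rep(q, each = n))
  cs <- apply(S, 2, cumsum); cs2 <- apply(S^2, 2, cumsum)
  out <- rep(NA_real_, ncol(M))
  ok <- k > 0
  if (any(ok)) {
    m <- cs[cbind(k[ok], which(ok))] / k[ok]
    v <- cs2[cbind(k[ok], which(ok))] / k[ok] - m^2
    sd <- sqrt(pmax(v, 0))
    mx <- S[n, ok]
    good <- sd > 0
    out[which(ok)[good]] <- (mx[good] - m[good]) / sd[good]
  }
  out
}

#' SNR-based line-by-line motion correction
#'
#' For each ROI the pool of trajectory pixels labelled ROI, outer ring
#' or surround is considered. At every line the single-pixel SNR over
#' the subsequent `window_s` window is computed for each pool pixel,
#' pixels are sorted by descending SNR (ties by (row, col) ascending),
#' and the top `n` pixels, `n` being the reference ROI pixel count, are
#' assigned to the ROI for that line. Unassigned pool pixels become the
#' line's neuropil pixels.
#'
#' @param rec An [sls_recording()].
#' @param cls A [classify_pixels()] result.
#' @param ref_seg The reference [segmentation()].
#' @param window_s Forward SNR window, s (default 10; truncated at the
#'   recording end).
#' @return A [line_assignment()].
#' @export
correct_motion_snr <- function(rec, cls, ref_seg, window_s = 10) {
  lp <- rec_line_period(rec)
  L <- max(2L, as.integer(round(window_s / lp)))
  n <- nrow(rec$lines)
  co <- rec$trajectory$coords
  ids <- cls$roi_ids
  assigned <- vector("list", length(ids)); neuropil <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    pool <- cls_pool(cls, ids[k])
    n_ref <- cls$ref_counts[[as.character(ids[k])]]
    if (length(pool) < n_ref)
      stop_smartline("pool_too_small",
                     "ROI %d pool (%d px) smaller than its reference count (%d)",
                     ids[k], length(pool), n_ref)
    ord_tie <- order(co[pool, 1], co[pool, 2])
    a_k <- vector("list", n); np_k <- vector("list", n)
    prev_win <- NULL
    for (t in seq_len(n)) {
      win <- t:min(t + L - 1, n)
      s <- col_snr25(rec$lines[win, pool, drop = FALSE])
      s[is.na(s)] <- -Inf
      r <- order(-s[ord_tie])  # stable sort: ties fall back to (row, col)
      sel <- pool[ord_tie][r[seq_len(n_ref)]]
      a_k[[t]] <- sel
      np_k[[t]] <- setdiff(pool, sel)
    }
    assigned[[k]] <- a_k; neuropil[[k]] <- np_k
  }
  line_assignment(ids, assigned, neuropil, n)
}

# partial-window centred rolling mean of each column of X, width L
rolling_mean_cols <- function(X, L) {
  n <- nrow(X)
  half_lo <- (L - 1) %/% 2; half_hi <- L - 1 - half_lo
  cs <- apply(rbind(0, X), 2, cumsum)
  lo <- pmax(seq_len(n) - half_lo, 1); hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

#' Reference-box line-by-line motion correction
#'
#' The reference-box pixels of every line are reshaped into a small
#' image and the image sequence is registered rigidly to its
#' first-frames template ([register_raster()]), after optional temporal
#' smoothing (and decimation) over `smooth_window_s`. The per-line
#' planar displacement is the negated registration correction; each
#' ROI's reference footprint, shifted by the rounded displacement, is
#' mapped onto its pool pixels (shifted pixels off the trajectory are
#' dropped from that line's assignment).
#'
#' @param rec An [sls_recording()] whose trajectory has a refbox of at
#'   least 4 x 4 pixels.
#' @param cls A [classify_pixels()] result.
#' @param ref_seg The reference [segmentation()].
#' @param smooth_window_s Temporal smoothing window, s (0, 1 or 10 are
#'   typical; 0 = none).
#' @param downsample If TRUE, decimate to one frame per window (shifts
#'   are mapped back to lines by nearest assignment).
#' @param n_template Leading (smoothed) frames averaged into the
#'   registration template.
#' @return A list with `shifts` (`[n_lines, 2]` estimated displacement)
#'   and `assignment` (a [line_assignment()]).
#' @export
correct_motion_refbox <- function(rec, cls, ref_seg, smooth_window_s = 0,
                                  downsample = FALSE, n_template = 10L) {
  rb <- rec$trajectory$refbox
  if (is.null(rb)) stop_smartline("no_refbox", "trajectory has no reference box")
  h <- rb[3]; w <- rb[4]
  if (h < 4 || w < 4) stop_smartline("bad_refbox", "reference box smaller than 4 x 4")
  n <- nrow(rec$lines)
  lp <- rec_line_period(rec)
  npix <- ncol(rec$lines)
  rb_cols <- (npix - h * w + 1):npix
  R <- rec$lines[, rb_cols, drop = FALSE]  # row-major refbox values per line
  L <- if (smooth_window_s > 0) max(1L, as.integer(round(smooth_window_s / lp))) else 1L
  if (L > 1 && downsample) {
    nb <- n %/% L
    grp <- rep(seq_len(nb), each = L)
    Rs <- rowsum(R[seq_len(nb * L), , drop = FALSE], grp) / L
    line2frame <- pmin(pmax(ceiling((seq_len(n) - L / 2) / L), 1), nb)
  } else if (L > 1) {
    Rs <- rolling_mean_cols(R, L)
    line2frame <- seq_len(n)
  } else {
    Rs <- R
    line2frame <- seq_len(n)
  }
  frames <- array(0, c(nrow(Rs), h, w))
  for (t in seq_len(nrow(Rs)))
    frames[t, , ] <- matrix(Rs[t, ], h, w, byrow = TRUE)
  mov <- raster_movie(frames, acquisition_metadata(1, lp * max(L, 1), lp, 1))
  reg <- register_raster(mov, "rigid", n_template = min(n_template, nrow(Rs)),
                         max_shift = max(1L, floor(min(h, w) / 2) - 1L))
  disp_frames <- -reg$shifts  # displacement of the tissue, per frame
  shifts <- disp_frames[line2frame, , drop = FALSE]
  # map shifted reference footprints onto the trajectory pool
  W <- ref_seg$fov_shape[2]
  co <- rec$trajectory$coords
  ids <- cls$roi_ids
  ushift <- unique(round(shifts))
  assigned <- vector("list", length(ids)); neuropil <- vector("list", length(ids))
  shift_key <- paste(round(shifts[, 1]), round(shifts[, 2]))
  ukey <- paste(ushift[, 1], ushift[, 2])
  line_u <- match(shift_key, ukey)
  for (k in seq_along(ids)) {
    pool <- cls_pool(cls, ids[k])
    pool_key <- co[pool, 1] * W + co[pool, 2]
    rpx <- ref_seg$rois[[k]]$pixels
    per_shift <- lapply(seq_len(nrow(ushift)), function(u) {
      sh <- ushift[u, ]
      key <- (rpx[, 1] + sh[1]) * W + (rpx[, 2] + sh[2])
      pool[pool_key %in% key]
    })
    per_shift_np <- lapply(per_shift, function(a) setdiff(pool, a))
    assigned[[k]] <- lapply(line_u, function(u) per_shift[[u]])
    neuropil[[k]] <- lapply(line_u, function(u) per_shift_np[[u]])
  }
  list(shifts = shifts,
       assignment = line_assignment(ids, assigned, neuropil, n))
}

#' ROI trace set
#'
#' @param traces `[n_lines, n_rois]` matrix of per-line trace values.
#' @param roi_ids Integer ROI ids (column order).
#' @param rate Sampling rate (lines/s).
#' @param provenance Character vector of applied processing steps.
#' @return A `trace_set` object.
#' @export
trace_set <- function(traces, roi_ids, rate, provenance = character(0)) {
  traces <- as.matrix(traces)
  colnames(traces) <- paste0("roi_", roi_ids)
  structure(list(traces = traces, roi_ids = roi_ids, rate = rate,
                 provenance = provenance),
            class = "trace_set")
}

# per-line mean of one ROI's assigned pixels
roi_line_means <- function(lines, slot) {
  if (!is.list(slot)) {
    if (length(slot) == 0)
      stop_smartline("empty_assignment", "ROI has no assigned pixels")
    return(rowMeans(lines[, slot, drop = FALSE]))
  }
  vapply(seq_len(nrow(lines)), function(t) {
    idx <- slot[[t]]
    if (length(idx) == 0)
      stop_smartline("empty_assignment", "empty assignment at line %d", t)
    mean(lines[t, idx])
  }, numeric(1))
}

#' Extract per-ROI fluorescence traces
#'
#' @param rec An [sls_recording()].
#' @param assignment A [line_assignment()] (e.g. from
#'   [assignment_from_classification()] or a motion-correction step).
#' @return A [trace_set()] at the line rate.
#' @export
extract_traces <- function(rec, assignment) {
  tr <- vapply(seq_along(assignment$roi_ids), function(k)
    roi_line_means(rec$lines, assignment$assigned[[k]]), numeric(nrow(rec$lines)))
  trace_set(tr, assignment$roi_ids, 1 / rec_line_period(rec), "extract")
}

#' Local neuropil decontamination
#'
#' Per ROI and line: mean over assigned ROI pixels minus `ratio` times
#' the mean over its neuropil pixels (surround pixels, or the per-line
#' unassigned pool after motion correction); negatives clipped to zero.
#' A ROI with no neuropil pixels passes through unchanged and is flagged
#' in the provenance.
#'
#' @param rec An [sls_recording()].
#' @param assignment A [line_assignment()].
#' @param ratio Contamination ratio (default 0.7).
#' @return A [trace_set()].
#' @export
subtract_neuropil_local <- function(rec, assignment, ratio = 0.7) {
  n <- nrow(rec$lines)
  prov <- "neuropil_local"
  tr <- matrix(0, n, length(assignment$roi_ids))
  for (k in seq_along(assignment$roi_ids)) {
    soma <- roi_line_means(rec$lines, assignment$assigned[[k]])
    np_slot <- assignment$neuropil[[k]]
    empty <- if (is.list(np_slot)) all(lengths(np_slot) == 0) else length(np_slot) == 0
    if (empty) {
      tr[, k] <- soma
      prov <- c(prov, sprintf("roi %d: no neuropil pixels, passed through",
                              assignment$roi_ids[k]))
    } else {
      np <- roi_line_means(rec$lines, np_slot)
      tr[, k] <- pmax(0, soma - ratio * np)
    }
  }
  trace_set(tr, assignment$roi_ids, 1 / rec_line_period(rec), prov)
}

#' Global neuropil decontamination
#'
#' Per ROI a signal is extracted as the mean over its assigned and
#' neuropil (surround) pixels; a rank-1 PCA representation of these
#' signals, interpretable as a global neuropil signal, is subtracted
#' from each ROI's plain ROI-pixel trace; negatives clipped to zero.
#'
#' @param rec An [sls_recording()].
#' @param assignment A [line_assignment()] with >= 2 ROIs.
#' @return A [trace_set()].
#' @export
subtract_neuropil_global <- function(rec, assignment) {
  K <- length(assignment$roi_ids)
  if (K < 2) stop_smartline("too_few_rois", "global neuropil needs >= 2 ROIs")
  n <- nrow(rec$lines)
  sig <- matrix(0, n, K); soma <- matrix(0, n, K)
  for (k in seq_len(K)) {
    a <- assignment$assigned[[k]]; np <- assignment$neuropil[[k]]
    both <- if (is.list(a) || is.list(np))
      lapply(seq_len(n), function(t) union(asg_get(a, t), asg_get(np, t)))
    else union(a, np)
    sig[, k] <- roi_line_means(rec$lines, both)
    soma[, k] <- roi_line_means(rec$lines, a)
  }
  recon <- rank1_reconstruction(sig)
  trace_set(pmax(soma - recon, 0), assignment$roi_ids,
            1 / rec_line_period(rec), "neuropil_global")
}

#' Deconvolve a trace set
#'
#' Each ROI trace is dF/F0-normalised and deconvolved with an AR model
#' of order 2 (order 1 if the line rate is below 2 Hz).
#'
#' @param ts A [trace_set()] of fluorescence traces.
#' @return A list with `activity` and `denoised` [trace_set()]s and
#'   `ar_coeffs` (per-ROI list).
#' @export
deconvolve_sls <- function(ts) {
  p <- if (ts$rate < 2) 1L else 2L
  act <- ts$traces; den <- ts$traces
  ar <- vector("list", ncol(ts$traces))
  for (k in seq_len(ncol(ts$traces))) {
    d <- deconvolve(dff(ts$traces[, k]), rate = ts$rate, order = p)
    act[, k] <- d$activity$values; den[, k] <- d$denoised$values
    ar[[k]] <- d$ar_coeffs
  }
  list(activity = trace_set(act, ts$roi_ids, ts$rate,
                            c(ts$provenance, "deconvolve")),
       denoised = trace_set(den, ts$roi_ids, ts$rate,
                            c(ts$provenance, "deconvolve")),
       ar_coeffs = ar)
}

mean_pairwise_correlation <- function(traces) {
  K <- ncol(traces)
  if (K < 2) return(NA_real_)
  cm <- suppressWarnings(stats::cor(traces))
  cm[!is.finite(cm)] <- 0
  mean(cm[upper.tri(cm)])
}

#' Processing quality metrics
#'
#' Average per-ROI SNR and average pairwise Pearson correlation of the
#' traces, and their change from `before` to `after`.
#'
#' @param before,after [trace_set()]s over the same ROIs and lines.
#' @return A list with `delta_snr`, `delta_corr`, and the raw
#'   `snr_before/after`, `corr_before/after` (Δcorr is NA with < 2 ROIs).
#' @export
quality_metrics <- function(before, after) {
  if (!identical(dim(before$traces), dim(after$traces)))
    stop_smartline("bad_traces", "trace sets differ in shape")
  snr_of <- function(ts) mean(apply(ts$traces, 2, snr_or_na), na.rm = TRUE)
  sb <- snr_of(before); sa <- snr_of(after)
  cb <- mean_pairwise_correlation(before$traces)
  ca <- mean_pairwise_correlation(after$traces)
  list(delta_snr = sa - sb, delta_corr = ca - cb,
       snr_before = sb, snr_after = sa, corr_before = cb, corr_after = ca)
}

#' Run an SLS processing pipeline
#'
#' Applies the requested steps in the given order. Available steps:
#' `crop_large_artifacts`, `subtract_background`, `correct_motion_snr`
#' or `correct_motion_refbox` (not both), `subtract_neuropil_local` or
#' `subtract_neuropil_global` (not both). Trajectory pixels are
#' classified against the reference segmentation first; metrics compare
#' the final traces with raw traces extracted over the same lines.
#'
#' @param rec An [sls_recording()].
#' @param ref_seg The reference [segmentation()].
#' @param steps Character vector of step names (possibly empty).
#' @param params List of parameters: `window_s` (10), `threshold` (0.3),
#'   `ratio` (0.7), `smooth_window_s` (0), `downsample` (FALSE).
#' @return A list with `traces` (final [trace_set()]), `raw_traces`,
#'   `artifact_report` (or NULL), `metrics`, `classification`,
#'   `assignment` and `shifts` (refbox motion only).
#' @export
run_pipeline <- function(rec, ref_seg, steps = character(0), params = list()) {
  all_steps <- c("crop_large_artifacts", "subtract_background",
                 "correct_motion_snr", "correct_motion_refbox",
                 "subtract_neuropil_local", "subtract_neuropil_global")
  bad <- setdiff(steps, all_steps)
  if (length(bad)) stop_smartline("bad_step", "unknown step '%s'", bad[1])
  if (all(c("correct_motion_snr", "correct_motion_refbox") %in% steps))
    stop_smartline("bad_step", "choose one motion-correction method, not both")
  if (all(c("subtract_neuropil_local", "subtract_neuropil_global") %in% steps))
    stop_smartline("bad_step", "choose one neuropil method, not both")
  p <- utils::modifyList(list(window_s = 10, threshold = 0.3, ratio = 0.7,
                              smooth_window_s = 0, downsample = FALSE), params)
  if ("correct_motion_refbox" %in% steps && is.null(rec$trajectory$refbox))
    stop_smartline("no_refbox",
                   "step correct_motion_refbox needs a trajectory reference box")
  cls <- classify_pixels(rec$trajectory, ref_seg)
  if ("subtract_background" %in% steps && sum(cls$class == "background") < 2)
    stop_smartline("no_background",
                   "step subtract_background needs background trajectory pixels")
  report <- NULL; shifts <- NULL
  cur <- rec
  assignment <- NULL
  prov <- character(0)
  for (st in steps) {
    if (st == "crop_large_artifacts") {
      report <- detect_large_artifact(cur, p$window_s, p$threshold)
      cur <- crop_recording(cur, report)
      assignment <- NULL  # line count may have changed
    } else if (st == "subtract_background") {
      cur <- subtract_background(cur, cls, p$ratio)
    } else if (st == "correct_motion_snr") {
      assignment <- correct_motion_snr(cur, cls, ref_seg, p$window_s)
    } else if (st == "correct_motion_refbox") {
      mc <- correct_motion_refbox(cur, cls, ref_seg, p$smooth_window_s,
                                  p$downsample)
      assignment <- mc$assignment; shifts <- mc$shifts
    }
    prov <- c(prov, st)
  }
  if (is.null(assignment))
    assignment <- assignment_from_classification(cls, nrow(cur$lines))
  final <- if ("subtract_neuropil_local" %in% steps)
    subtract_neuropil_local(cur, assignment, p$ratio)
  else if ("subtract_neuropil_global" %in% steps)
    subtract_neuropil_global(cur, assignment)
  else extract_traces(cur, assignment)
  final$provenance <- c(prov, final$provenance)
  raw <- extract_traces(
    sls_recording(rec$lines[seq_len(nrow(cur$lines)), , drop = FALSE],
                  rec$trajectory,
                  timestamps = rec$timestamps[seq_len(nrow(cur$lines))]),
    assignment_from_classification(cls, nrow(cur$lines)))
  list(traces = final, raw_traces = raw, artifact_report = report,
       metrics = quality_metrics(raw, final), classification = cls,
       assignment = assignment, shifts = shifts)
}
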