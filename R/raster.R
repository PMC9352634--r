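#' Fluorescence trace
#'
#' @param values Numeric fluorescence samples.
#' @param rate Sampling rate, samples/s.
#' @return A `trace` object.
#' @export
trace <- function(values, rate) {
  assert_finite(values, "trace values")
  if (length(values) < 2) stop_smartline("bad_trace", "a trace needs >= 2 samples")
  if (!is.finite(rate) || rate <= 0) stop_smartline("bad_trace", "rate must be positive")
  structure(list(values = as.numeric(values), rate = as.numeric(rate)),
            class = "trace")
}

trace_values <- function(x) if (inherits(x, "trace")) x$values else as.numeric(x)

# population standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Trace signal-to-noise ratio
#'
#' `SNR = (max f - mean(f25)) / sd(f25)` where `f25` are all values
#' strictly below the 25th percentile of the trace (linear-interpolation
#' percentile) and `sd` is the population standard deviation. The
#' sub-percentile tail estimates the noise floor, so the ratio measures
#' peak transient amplitude in noise units.
#'
#' @param x A [trace()] or numeric vector.
#' @return A single number.
#' @export
snr <- function(x) {
  f <- trace_values(x)
  assert_finite(f, "trace")
  q <- stats::quantile(f, 0.25, names = FALSE, type = 7)
  f25 <- f[f < q]
  if (length(f25) == 0)
    stop_smartline("degenerate_trace", "no values strictly below the 25th percentile")
  s <- pop_sd(f25)
  if (s == 0)
    stop_smartline("degenerate_trace", "sub-percentile values are constant")
  (max(f) - mean(f25)) / s
}

#' Normalised fluorescence dF/F0
#'
#' `dF/F0(t) = (f(t) - F0) / F0` with `F0 = mean(f50)`, the mean of all
#' values strictly below the median of the trace.
#'
#' @param x A [trace()] or numeric vector.
#' @return Same type as the input.
#' @export
dff <- function(x) {
  f <- trace_values(x)
  assert_finite(f, "trace")
  q <- stats::quantile(f, 0.5, names = FALSE, type = 7)
  f50 <- f[f < q]
  if (length(f50) == 0)
    stop_smartline("degenerate_trace", "no values strictly below the median")
  f0 <- mean(f50)
  if (f0 <= 0)
    stop_smartline("degenerate_trace", "baseline F0 = %.3g is not positive", f0)
  out <- (f - f0) / f0
  if (inherits(x, "trace")) trace(out, x$rate) else out
}

#' Temporal projections of a raster movie
#'
#' @param movie A [raster_movie()] with at least two frames.
#' @return A list with `average` (per-pixel temporal mean), `max_min`
#'   (per-pixel max - min) and `correlation` (per-pixel mean Pearson
#'   correlation of the pixel trace with its 8-connected neighbours;
#'   pairs involving a constant pixel contribute 0).
#' @export
compute_projections <- function(movie) {
  fr <- movie$frames
  Tn <- dim(fr)[1]; H <- dim(fr)[2]; W <- dim(fr)[3]
  if (Tn < 2) stop_smartline("bad_movie", "projections need at least 2 frames")
  avg <- apply(fr, c(2, 3), mean)
  mm <- apply(fr, c(2, 3), max) - apply(fr, c(2, 3), min)
  # z-score each pixel trace (population sd); constant pixels stay zero
  mu <- aperm(array(avg, c(H, W, Tn)), c(3, 1, 2))
  ctr <- fr - mu
  sd2 <- apply(ctr^2, c(2, 3), mean)
  sdv <- sqrt(sd2)
  z <- ctr / aperm(array(pmax(sdv, .Machine$double.xmin), c(H, W, Tn)), c(3, 1, 2))
  corr_sum <- matrix(0, H, W); n_nb <- matrix(0, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ys <- max(1, 1 + dy):min(H, H + dy); xs <- max(1, 1 + dx):min(W, W + dx)
    # corr(pixel, neighbour at offset (dy,dx)) = mean_t z * z_shift
    pr <- apply(z[, ys, xs, drop = FALSE] * z[, ys - dy, xs - dx, drop = FALSE],
                c(2, 3), mean)
    corr_sum[ys, xs] <- corr_sum[ys, xs] + pr
    n_nb[ys, xs] <- n_nb[ys, xs] + 1
  }
  list(average = avg, max_min = mm, correlation = corr_sum / n_nb)
}

# bilinear sampling of matrix img at 0-based real coords (ys, xs); zero outside
bilinear_sample <- function(img, ys, xs) {
  H <- nrow(img); W <- ncol(img)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  val <- function(yy, xx) {
    ok <- yy >= 0 & yy <= H - 1 & xx >= 0 & xx <= W - 1
    v <- numeric(length(yy))
    v[ok] <- img[cbind(yy[ok] + 1, xx[ok] + 1)]
    v
  }
  val(y0, x0) * (1 - fy) * (1 - fx) + val(y0 + 1, x0) * fy * (1 - fx) +
    val(y0, x0 + 1) * (1 - fy) * fx + val(y0 + 1, x0 + 1) * fy * fx
}

# shift a matrix by real (dy, dx) with bilinear resampling, zero fill:
# out(y, x) = img(y - dy, x - dx)
shift_image <- function(img, dy, dx) {
  H <- nrow(img); W <- ncol(img)
  g <- expand.grid(y = 0:(H - 1), x = 0:(W - 1))
  matrix(bilinear_sample(img, g$y - dy, g$x - dx), H, W)
}

# integer + quadratic-subpixel cross-correlation shift of frame against
# template (both demeaned); returns the correction (dy, dx) to apply to
# the frame, capped at max_shift
cc_shift <- function(frame, template, max_shift) {
  H <- nrow(frame); W <- ncol(frame)
  A <- frame - mean(frame); B <- template - mean(template)
  C <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE))
  wrap <- function(k, n) ((k %% n) + n) %% n + 1
  us <- -max_shift:max_shift
  sub <- C[wrap(us, H), wrap(us, W), drop = FALSE]
  pk <- arrayInd(which.max(sub), dim(sub))
  u0 <- us[pk[1]]; v0 <- us[pk[2]]
  refine <- function(cm, c0, cp) {
    d <- cm - 2 * c0 + cp
    if (!is.finite(d) || d >= 0) return(0)
    off <- max(-0.5, min(0.5, 0.5 * (cm - cp) / d))
    if (abs(off) < 1e-6) 0 else off  # snap float-epsilon asymmetry to zero
  }
  du <- refine(C[wrap(u0 - 1, H), wrap(v0, W)], C[wrap(u0, H), wrap(v0, W)],
               C[wrap(u0 + 1, H), wrap(v0, W)])
  dv <- refine(C[wrap(u0, H), wrap(v0 - 1, W)], C[wrap(u0, H), wrap(v0, W)],
               C[wrap(u0, H), wrap(v0 + 1, W)])
  pmin(pmax(c(u0 + du, v0 + dv), -max_shift), max_shift)
}

#' Register a raster movie to a first-frames template
#'
#' The template is the temporal mean of the first `n_template` frames of
#' the raw movie. In `rigid` mode each frame gets one cross-correlation
#' shift (integer grid, refined to subpixel by quadratic peak
#' interpolation, capped at `max_shift`). In `patch` mode the FOV is
#' split into an overlapping grid of patches, each registered rigidly,
#' and a per-pixel shift field is obtained by bilinear blending of the
#' patch shifts. Registered frames are resampled with zero fill at the
#' borders.
#'
#' @param movie A [raster_movie()].
#' @param mode `"rigid"` or `"patch"`.
#' @param n_template Number of leading frames averaged into the template.
#' @param max_shift Maximum correction per axis, pixels (must be below
#'   half the smaller FOV dimension).
#' @param patch_grid Patches per axis in `patch` mode (50% overlap).
#' @return A list with `shifts` (`[T, 2]` matrix of (dy, dx) corrections;
#'   in patch mode the patch-average), `registered` ([raster_movie()]),
#'   `template`, and in patch mode `patch_shifts`.
#' @export
register_raster <- function(movie, mode = c("rigid", "patch"), n_template = 10L,
                            max_shift = 10L, patch_grid = 4L) {
  mode <- match.arg(mode)
  fr <- movie$frames
  Tn <- dim(fr)[1]; H <- dim(fr)[2]; W <- dim(fr)[3]
  n_template <- min(n_template, Tn)
  if (max_shift >= min(H, W) / 2)
    stop_smartline("bad_shift", "max_shift must be < min(H, W)/2")
  template <- apply(fr[seq_len(n_template), , , drop = FALSE], c(2, 3), mean)
  shifts <- matrix(0, Tn, 2)
  reg <- fr
  if (mode == "rigid") {
    for (t in seq_len(Tn)) {
      s <- cc_shift(fr[t, , ], template, max_shift)
      shifts[t, ] <- s
      reg[t, , ] <- if (all(s == 0)) fr[t, , ] else shift_image(fr[t, , ], s[1], s[2])
    }
    return(list(shifts = shifts, registered = raster_movie(reg, movie$meta),
                template = template))
  }
  # patch mode: patch_grid x patch_grid patches with 50% overlap
  g <- patch_grid
  py <- ceiling(2 * H / (g + 1)); px <- ceiling(2 * W / (g + 1))
  y0 <- round(seq(0, H - py, length.out = g)); x0 <- round(seq(0, W - px, length.out = g))
  cy <- y0 + (py - 1) / 2; cx <- x0 + (px - 1) / 2
  patch_shifts <- array(0, c(Tn, g, g, 2))
  grid <- expand.grid(y = 0:(H - 1), x = 0:(W - 1))
  # blending weights: bilinear interpolation of the patch-centre shift values
  interp1 <- function(centers, pos) {
    # returns for each pos: indices (i, i+1) and weight of i
    i <- findInterval(pos, centers, all.inside = TRUE)
    i <- pmin(pmax(i, 1), length(centers) - 1)
    w <- (centers[i + 1] - pos) / (centers[i + 1] - centers[i])
    list(i = i, w = pmin(pmax(w, 0), 1))
  }
  iy <- interp1(cy, grid$y); ix <- interp1(cx, grid$x)
  mxs <- min(max_shift, floor(min(py, px) / 2 - 1))
  for (t in seq_len(Tn)) {
    for (a in seq_len(g)) for (b in seq_len(g)) {
      ys <- y0[a] + seq_len(py); xs <- x0[b] + seq_len(px)
      patch_shifts[t, a, b, ] <- cc_shift(fr[t, ys, xs], template[ys, xs], mxs)
    }
    for (k in 1:2) {
      S <- patch_shifts[t, , , k]
      f <- S[cbind(iy$i, ix$i)] * iy$w * ix$w +
        S[cbind(iy$i + 1, ix$i)] * (1 - iy$w) * ix$w +
        S[cbind(iy$i, ix$i + 1)] * iy$w * (1 - ix$w) +
        S[cbind(iy$i + 1, ix$i + 1)] * (1 - iy$w) * (1 - ix$w)
      if (k == 1) dy_field <- f else dx_field <- f
    }
    reg[t, , ] <- matrix(bilinear_sample(fr[t, , ], grid$y - dy_field,
                                         grid$x - dx_field), H, W)
    shifts[t, ] <- c(mean(patch_shifts[t, , , 1]), mean(patch_shifts[t, , , 2]))
  }
  list(shifts = shifts, registered = raster_movie(reg, movie$meta),
       template = template, patch_shifts = patch_shifts)
}

# traces of a set of 0-based pixels from a movie: [T, n] matrix
pixel_traces <- function(movie, pixels) {
  fr <- movie$frames
  Tn <- dim(fr)[1]; H <- dim(fr)[2]
  m <- matrix(fr, Tn, H * dim(fr)[3])  # column-major over (H, W)
  m[, pixels[, 1] + pixels[, 2] * H + 1, drop = FALSE]
}

snr_or_na <- function(f) tryCatch(snr(f), smartline_degenerate_trace = function(e) NA_real_)

#' SNR-maximising pixel selection for a ROI
#'
#' Candidate pixels are sorted by decreasing single-pixel SNR (ties
#' broken by (row, col) ascending; degenerate pixels are dropped). The
#' SNR of the k-pixel mean trace is then evaluated for every prefix
#' k = 1..N and the prefix achieving the maximum is returned (ties go to
#' the smaller prefix).
#'
#' @param movie A [raster_movie()].
#' @param candidate_pixels Integer matrix `[n, 2]` of 0-based (row, col).
#' @return A list with `pixels` (the chosen prefix, in SNR order),
#'   `snr` (the pooled SNR attained), `order` (all ranked candidates)
#'   and `prefix_snr` (pooled SNR per prefix size).
#' @export
snr_maximize_pixels <- function(movie, candidate_pixels) {
  candidate_pixels <- matrix(as.integer(candidate_pixels), ncol = 2)
  tr <- pixel_traces(movie, candidate_pixels)
  s <- apply(tr, 2, snr_or_na)
  keep <- which(!is.na(s))
  if (length(keep) == 0)
    stop_smartline("degenerate_trace", "all candidate pixels have degenerate traces")
  ord <- keep[order(-s[keep], candidate_pixels[keep, 1], candidate_pixels[keep, 2])]
  cum <- apply(tr[, ord, drop = FALSE], 1, cumsum)
  cum <- if (is.matrix(cum)) t(cum) else matrix(cum, ncol = 1)
  prefix_snr <- vapply(seq_along(ord), function(k)
    snr_or_na(cum[, k] / k), numeric(1))
  prefix_snr[is.na(prefix_snr)] <- -Inf
  k_best <- which.max(prefix_snr)  # which.max takes the first maximum
  list(pixels = candidate_pixels[ord[seq_len(k_best)], , drop = FALSE],
       snr = prefix_snr[k_best],
       order = candidate_pixels[ord, , drop = FALSE],
       prefix_snr = prefix_snr)
}

#' Candidate pixels from a drawn contour or bounding box
#'
#' A least-squares ellipse (conic) is fitted to the contour points and
#' pixels whose centres fall inside (or on) the ellipse are returned.
#' With a bounding box, all box pixels are returned. Results are clipped
#' to the FOV.
#'
#' @param contour Numeric matrix `[n >= 5, 2]` of (row, col) points.
#' @param bbox Integer `(row0, col0, height, width)`, 0-based.
#' @param fov_shape Integer `(H, W)`.
#' @return Integer matrix `[m, 2]` of 0-based candidate pixels.
#' @export
ellipse_candidates <- function(contour = NULL, bbox = NULL, fov_shape) {
  H <- fov_shape[1]; W <- fov_shape[2]
  if (!is.null(bbox)) {
    bbox <- as.integer(bbox)
    rs <- bbox[1] + seq_len(bbox[3]) - 1L; cs <- bbox[2] + seq_len(bbox[4]) - 1L
    rs <- rs[rs >= 0 & rs < H]; cs <- cs[cs >= 0 & cs < W]
    return(cbind(rep(rs, each = length(cs)), rep(cs, times = length(rs))))
  }
  p <- matrix(as.numeric(contour), ncol = 2)
  if (nrow(p) < 5) stop_smartline("bad_contour", "ellipse fit needs >= 5 points")
  r <- p[, 1]; c <- p[, 2]
  D <- cbind(r^2, r * c, c^2, r, c, 1)
  th <- svd(D)$v[, 6]  # least-squares conic, ||theta|| = 1
  a <- th[1]; b <- th[2]; cc <- th[3]; d <- th[4]; e <- th[5]; f <- th[6]
  disc <- b^2 - 4 * a * cc
  if (!is.finite(disc) || disc >= -1e-12 * (a^2 + b^2 + cc^2))
    stop_smartline("degenerate_contour", "contour points do not define an ellipse")
  ctr <- solve(matrix(c(2 * a, b, b, 2 * cc), 2), -c(d, e))
  Q <- function(y, x) a * y^2 + b * y * x + cc * x^2 + d * y + e * x + f
  q0 <- Q(ctr[1], ctr[2])
  g <- expand.grid(y = 0:(H - 1), x = 0:(W - 1))
  inside <- Q(g$y, g$x) / q0 >= -1e-9
  cbind(g$y[inside], g$x[inside])
}

# rotate a matrix about the FOV centre by angle (degrees), bilinear, zero fill
rotate_image <- function(img, angle) {
  if (angle == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  th <- angle * pi / 180
  ctr <- c((H - 1) / 2, (W - 1) / 2)
  g <- expand.grid(y = 0:(H - 1), x = 0:(W - 1))
  yy <- g$y - ctr[1]; xx <- g$x - ctr[2]
  # inverse map: sample the source at R(-theta) p
  ys <- cos(th) * yy + sin(th) * xx + ctr[1]
  xs <- -sin(th) * yy + cos(th) * xx + ctr[2]
  matrix(bilinear_sample(img, ys, xs), H, W)
}

#' Align a segmentation across sessions
#'
#' Grid search over integer shifts and rotations (about the FOV centre)
#' minimising the mean square error between the transformed source
#' projection and the target projection (zero fill outside). The winning
#' transform is applied to all ROI pixels with nearest-pixel rounding;
#' pixels leaving the FOV are dropped.
#'
#' @param seg [segmentation()] drawn on the source session.
#' @param source_projection,target_projection Same-shape matrices
#'   (typically correlation projections of the two sessions).
#' @param shift_range Integer shifts searched per axis (default -20:20).
#' @param angle_range Angles searched, degrees (default +/-10 by 0.5).
#' @return The transformed [segmentation()], with attributes `shift`,
#'   `angle` and `mse` describing the chosen transform.
#' @export
align_segmentation <- function(seg, source_projection, target_projection,
                               shift_range = -20:20,
                               angle_range = seq(-10, 10, by = 0.5)) {
  A0 <- source_projection; B <- target_projection
  if (!identical(dim(A0), dim(B)))
    stop_smartline("bad_projection", "projections must share shape")
  if (length(shift_range) == 0 || length(angle_range) == 0)
    stop_smartline("bad_search", "empty search range")
  H <- nrow(B); W <- ncol(B)
  S <- max(abs(shift_range))
  Hp <- H + 2 * S + 1; Wp <- W + 2 * S + 1
  Bp <- matrix(0, Hp, Wp); Bp[1:H, 1:W] <- B
  fftB <- stats::fft(Bp)
  sum_B2 <- sum(B^2)
  best <- list(mse = Inf)
  for (ang in angle_range) {
    A <- rotate_image(A0, ang)
    # sum over shifted-in region of A^2 via an integral image
    csum <- matrix(0, H + 1, W + 1)
    csum[2:(H + 1), 2:(W + 1)] <- apply(apply(A^2, 2, cumsum), 1, cumsum)
    rect_sum <- function(y1, y2, x1, x2) { # 1-based inclusive, empty -> 0
      if (y2 < y1 || x2 < x1) return(0)
      csum[y2 + 1, x2 + 1] - csum[y1, x2 + 1] - csum[y2 + 1, x1] + csum[y1, x1]
    }
    Ap <- matrix(0, Hp, Wp); Ap[1:H, 1:W] <- A
    C <- Re(stats::fft(Conj(stats::fft(Ap)) * fftB, inverse = TRUE)) / (Hp * Wp)
    wrap <- function(k, n) ((k %% n) + n) %% n + 1
    for (dy in shift_range) for (dx in shift_range) {
      a2 <- rect_sum(max(1, 1 - dy), min(H, H - dy), max(1, 1 - dx), min(W, W - dx))
      mse <- (sum_B2 + a2 - 2 * C[wrap(dy, Hp), wrap(dx, Wp)]) / (H * W)
      if (mse < best$mse - 1e-12)
        best <- list(mse = mse, shift = c(dy, dx), angle = ang)
    }
  }
  th <- best$angle * pi / 180
  ctr <- c((H - 1) / 2, (W - 1) / 2)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)  # forward rotation
  new_rois <- list()
  for (r in seg$rois) {
    q <- t(R %*% t(sweep(r$pixels, 2, ctr))) + rep(ctr, each = nrow(r$pixels))
    q <- round(sweep(q, 2, best$shift, "+"))
    keep <- q[, 1] >= 0 & q[, 1] < H & q[, 2] >= 0 & q[, 2] < W
    dup <- duplicated(q)
    keep <- keep & !dup
    if (any(keep))
      new_rois[[length(new_rois) + 1]] <-
        roi(r$id, q[keep, , drop = FALSE], r$weights[keep])
  }
  out <- segmentation(c(H, W), new_rois, seg$surround_width, seg$surrounds)
  attr(out, "shift") <- best$shift; attr(out, "angle") <- best$angle
  attr(out, "mse") <- best$mse
  out
}

#' Autoregressive deconvolution of a calcium trace
#'
#' The dF/F0 trace is modelled as an AR(p) process whose kernel captures
#' the calcium indicator decay: order p = 1 for sampling rates below
#' 2 Hz, p = 2 otherwise. Coefficients are estimated from the trace
#' autocovariance (Yule-Walker); the inferred activity is the rectified
#' innovation `max(0, f(t) - sum_i g_i f(t-i))` and the denoised trace is
#' the activity re-convolved with the AR kernel.
#'
#' @param x A [trace()] (dF/F0), or a numeric vector with `rate` given.
#' @param rate Sampling rate, Hz (taken from the trace if omitted).
#' @param order Force the AR order instead of the rate rule.
#' @return A list with `denoised`, `activity` (both [trace()]s),
#'   `ar_coeffs` and `order`.
#' @export
deconvolve <- function(x, rate = NULL, order = NULL) {
  if (inherits(x, "trace")) { rate <- x$rate; f <- x$values } else f <- as.numeric(x)
  if (is.null(rate) || rate <= 0) stop_smartline("bad_trace", "positive rate required")
  p <- if (!is.null(order)) as.integer(order) else if (rate < 2) 1L else 2L
  if (length(f) < 3 * p)
    stop_smartline("bad_trace", "trace shorter than 3p = %d samples", 3 * p)
  ac <- stats::acf(f, lag.max = p, type = "covariance", plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  gamma <- if (ac[1] <= .Machine$double.eps * max(1, mean(f^2))) rep(0, p) else {
    Rm <- stats::toeplitz(ac[seq_len(p)])
    as.numeric(solve(Rm, ac[2:(p + 1)]))
  }
  n <- length(f)
  pred <- rep(0, n)
  for (i in seq_len(p))
    pred[(i + 1):n] <- pred[(i + 1):n] + gamma[i] * f[1:(n - i)]
  activity <- pmax(0, f - pred)
  denoised <- as.numeric(stats::filter(activity, gamma, method = "recursive"))
  list(denoised = trace(denoised, rate), activity = trace(activity, rate),
       ar_coeffs = gamma, order = p)
}
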