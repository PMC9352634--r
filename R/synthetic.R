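#' Synthetic scene configuration
#'
#' Parameters of the simulated imaging session: disk-shaped somata with
#' GCaMP-like AR(2) transients, a shared slowly fluctuating background,
#' per-ROI neuropil fields, Gaussian shot-like noise and a photon
#' offset. All stages are deterministic given `seed`.
#'
#' @param fov_shape FOV `(H, W)` in pixels.
#' @param n_rois Number of somata.
#' @param roi_radius Soma radius, pixels.
#' @param spike_rate Poisson spike rate per soma, Hz.
#' @param kernel AR(2) calcium-kernel coefficients `(g1, g2)` (roots
#'   must lie inside the unit circle).
#' @param spike_amplitude Peak dF/F of a single-spike transient (the
#'   kernel impulse response is normalised to this peak).
#' @param soma_baseline Baseline soma brightness, counts.
#' @param background_amplitude Amplitude of the shared background
#'   series, counts.
#' @param neuropil_amplitude Amplitude of the neuropil fields, counts.
#' @param noise_sd Gaussian noise standard deviation, counts.
#' @param photon_offset Constant detector offset, counts.
#' @param seed RNG seed for all stages.
#' @return A `scene_config` object.
#' @export
scene_config <- function(fov_shape = c(48L, 48L), n_rois = 6L, roi_radius = 3L,
                         spike_rate = 0.4, kernel = c(1.6, -0.64),
                         spike_amplitude = 1.5, soma_baseline = 100,
                         background_amplitude = 25, neuropil_amplitude = 40,
                         noise_sd = 2, photon_offset = 100, seed = 1L) {
  rt <- polyroot(c(-kernel[2], -kernel[1], 1))  # z^2 - g1 z - g2
  if (any(Mod(rt) >= 1))
    stop_smartline("bad_config", "AR kernel roots must lie inside the unit circle")
  if (any(c(spike_rate, spike_amplitude, soma_baseline, background_amplitude,
            neuropil_amplitude, noise_sd, photon_offset) < 0))
    stop_smartline("bad_config", "amplitudes, rates and noise sd must be >= 0")
  structure(list(fov_shape = as.integer(fov_shape), n_rois = as.integer(n_rois),
                 roi_radius = roi_radius, spike_rate = spike_rate,
                 kernel = kernel, spike_amplitude = spike_amplitude,
                 soma_baseline = soma_baseline,
                 background_amplitude = background_amplitude,
                 neuropil_amplitude = neuropil_amplitude, noise_sd = noise_sd,
                 photon_offset = photon_offset, seed = as.integer(seed)),
            class = "scene_config")
}

#' Rigid planar motion configuration
#'
#' @param drift_sd Random-walk step sd, px per line/frame (slow drift).
#' @param large_shift Optional `list(t0 = <line index>, shift = c(dy, dx))`
#'   abrupt displacement applied from `t0` onward.
#' @return A `motion_config` object.
#' @export
motion_config <- function(drift_sd = 0, large_shift = NULL) {
  if (drift_sd < 0) stop_smartline("bad_config", "drift_sd must be >= 0")
  structure(list(drift_sd = drift_sd, large_shift = large_shift),
            class = "motion_config")
}

# smooth a white-noise series to a slow unit-sd fluctuation
slow_series <- function(n, width) {
  z <- stats::rnorm(n + 2 * width)
  k <- rep(1 / width, width)
  s <- stats::filter(z, k, sides = 2)
  s <- s[(width + 1):(width + n)]
  s <- s - mean(s)
  sd0 <- pop_sd(s)
  if (sd0 > 0) s / sd0 else s
}

#' Build a synthetic static scene
#'
#' Places `n_rois` disk somata (rejection-sampled, non-overlapping) with
#' a smooth per-pixel gain, a spatially smoothed neuropil field and a
#' per-pixel neuropil-region map (pixels near a soma follow that ROI's
#' neuropil series; the rest follow the shared series).
#'
#' @param cfg A [scene_config()].
#' @return A ground-truth skeleton: `config`, `segmentation`,
#'   `centers`, `gain_img` (per-ROI soma gain image, sparse in a list),
#'   `npil_field`, `npil_region` and `scene_image` (baseline scene at
#'   zero activity, without offset or noise).
#' @export
make_scene <- function(cfg) {
  set.seed(cfg$seed)
  H <- cfg$fov_shape[1]; W <- cfg$fov_shape[2]
  r <- cfg$roi_radius
  margin <- r + 3
  min_sep <- 2 * r + 5
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(centers) < cfg$n_rois) {
    tries <- tries + 1
    if (tries > 5000)
      stop_smartline("placement_failed", "cannot place %d ROIs in a %d x %d FOV",
                     cfg$n_rois, H, W)
    cand <- c(stats::runif(1, margin, H - 1 - margin),
              stats::runif(1, margin, W - 1 - margin))
    if (nrow(centers) == 0 ||
        min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= min_sep)
      centers <- rbind(centers, cand)
  }
  centers <- round(centers)
  rois <- list(); gains <- list()
  render_px <- list(); render_gain <- list()
  skirt <- 1.5  # PSF skirt: blur carries attenuated somatic signal past the rim
  for (k in seq_len(max(cfg$n_rois, 0))) {
    rr <- ceiling(r + skirt)
    rs <- (centers[k, 1] - rr):(centers[k, 1] + rr)
    cs <- (centers[k, 2] - rr):(centers[k, 2] + rr)
    cand <- cbind(rep(rs, each = length(cs)), rep(cs, times = length(rs)))
    d <- sqrt((cand[, 1] - centers[k, 1])^2 + (cand[, 2] - centers[k, 2])^2)
    bright <- stats::runif(1, 0.8, 1.2)
    core <- d <= r + 1e-9
    g_core <- (0.6 + 0.4 * (1 - (d[core] / (r + 1))^2)) * bright
    rois[[k]] <- roi(k, cand[core, , drop = FALSE], g_core)
    gains[[k]] <- g_core
    ext <- d <= r + skirt + 1e-9
    g_ext <- numeric(sum(ext))
    dd <- d[ext]
    g_ext[dd <= r + 1e-9] <- g_core
    out <- dd > r + 1e-9
    g_ext[out] <- 0.6 * bright * (1 - (dd[out] - r) / skirt)
    keep <- cand[ext, 1] >= 0 & cand[ext, 1] < H & cand[ext, 2] >= 0 & cand[ext, 2] < W
    render_px[[k]] <- cand[ext, , drop = FALSE][keep, , drop = FALSE]
    render_gain[[k]] <- g_ext[keep]
  }
  seg <- segmentation(c(H, W), rois)
  z <- matrix(stats::rnorm(H * W), H, W)
  k7 <- rep(1 / 7, 7)
  for (i in 1:2) {
    z <- apply(z, 2, function(col) {
      s <- stats::filter(col, k7, sides = 2, circular = TRUE); as.numeric(s) })
    z <- t(apply(z, 1, function(rw) {
      s <- stats::filter(rw, k7, sides = 2, circular = TRUE); as.numeric(s) }))
  }
  z <- (z - mean(z)) / pop_sd(z)
  npil_field <- pmax(1 + 0.3 * z, 0.2)
  g <- expand.grid(y = 0:(H - 1), x = 0:(W - 1))
  if (cfg$n_rois > 0) {
    d2 <- vapply(seq_len(cfg$n_rois), function(k)
      (g$y - centers[k, 1])^2 + (g$x - centers[k, 2])^2, numeric(H * W))
    d2 <- matrix(d2, H * W)
    nearest <- max.col(-d2, ties.method = "first")
    region <- ifelse(sqrt(d2[cbind(seq_len(H * W), nearest)]) <= r + 4, nearest, 0L)
  } else region <- rep(0L, H * W)
  npil_region <- matrix(region, H, W)
  scene_image <- matrix(0, H, W)
  for (k in seq_along(rois))
    scene_image[render_px[[k]] + 1] <- scene_image[render_px[[k]] + 1] +
      render_gain[[k]] * cfg$soma_baseline
  scene_image <- scene_image + npil_field * cfg$neuropil_amplitude
  structure(list(config = cfg, segmentation = seg, centers = centers,
                 gains = gains, render_px = render_px,
                 render_gain = render_gain, npil_field = npil_field,
                 npil_region = npil_region, scene_image = scene_image),
            class = "ground_truth")
}

#' Simulate ground-truth temporal dynamics
#'
#' Poisson spike trains filtered by the AR(2) calcium kernel give
#' per-ROI somatic dF traces; the background and neuropil series are
#' slow smoothed Gaussian fluctuations scaled by their amplitudes
#' (linear in the amplitudes by construction).
#'
#' @param gt A [make_scene()] result.
#' @param duration_s Simulated duration, s.
#' @param rate_hz Sampling rate (frames or lines per second).
#' @return `gt` extended with `spikes`, `somatic_dff`, `background`,
#'   `neuropil` (`[n, n_rois + 1]`, column 1 the shared series), `rate`
#'   and `n_samples`.
#' @export
simulate_traces <- function(gt, duration_s, rate_hz) {
  cfg <- gt$config
  set.seed(cfg$seed + 1L)
  n <- as.integer(round(duration_s * rate_hz))
  K <- cfg$n_rois
  p <- min(1, cfg$spike_rate / rate_hz)
  spikes <- matrix(stats::rbinom(n * max(K, 1), 1L, p), n)[, seq_len(K), drop = FALSE]
  # normalise the kernel impulse response so one spike peaks at spike_amplitude
  h_peak <- max(stats::filter(c(1, rep(0, 199)), cfg$kernel, method = "recursive"))
  somatic <- vapply(seq_len(K), function(k)
    as.numeric(stats::filter(spikes[, k] * cfg$spike_amplitude / h_peak,
                             cfg$kernel, method = "recursive")),
    numeric(n))
  somatic <- matrix(somatic, n)
  slow_w <- max(3L, as.integer(round(2 * rate_hz)))
  bg <- cfg$background_amplitude * (1 + 0.5 * slow_series(n, slow_w))
  zp <- slow_series(n, slow_w)
  npil <- matrix(0, n, K + 1)
  npil[, 1] <- 1 + 0.4 * zp
  for (k in seq_len(K))
    npil[, k + 1] <- 1 + 0.4 * (0.8 * zp + 0.2 * slow_series(n, slow_w))
  gt$spikes <- spikes; gt$somatic_dff <- somatic
  gt$background <- bg; gt$neuropil <- npil
  gt$rate <- rate_hz; gt$n_samples <- n
  gt
}

#' Rigid motion series
#'
#' @param motion A [motion_config()].
#' @param n Number of frames/lines.
#' @param seed RNG seed for the drift random walk.
#' @return `[n, 2]` matrix of (dy, dx) displacements.
#' @export
motion_series <- function(motion, n, seed) {
  set.seed(seed)
  m <- matrix(0, n, 2)
  if (motion$drift_sd > 0) {
    m[, 1] <- cumsum(stats::rnorm(n, 0, motion$drift_sd))
    m[, 2] <- cumsum(stats::rnorm(n, 0, motion$drift_sd))
  }
  ls <- motion$large_shift
  if (!is.null(ls) && ls$t0 <= n) {
    idx <- ls$t0:n
    m[idx, 1] <- m[idx, 1] + ls$shift[1]
    m[idx, 2] <- m[idx, 2] + ls$shift[2]
  }
  m
}

# spatial scene at sample t (no offset, no uniform background, no noise)
scene_at <- function(gt, t) {
  cfg <- gt$config
  S <- gt$npil_field * cfg$neuropil_amplitude *
    matrix(gt$neuropil[t, gt$npil_region + 1], nrow(gt$npil_field))
  for (k in seq_len(cfg$n_rois)) {
    px <- gt$render_px[[k]] + 1
    S[px] <- S[px] + gt$render_gain[[k]] * cfg$soma_baseline *
      (1 + gt$somatic_dff[t, k])
  }
  S
}

# shift scene content by (dy, dx): out(x) = S(x - dy, x - dx), zero fill;
# exact integer roll when the shift is integer, bilinear otherwise
shift_scene <- function(S, dy, dx) {
  if (dy == 0 && dx == 0) return(S)
  H <- nrow(S); W <- ncol(S)
  if (dy == round(dy) && dx == round(dx)) {
    out <- matrix(0, H, W)
    ys <- max(1, 1 + dy):min(H, H + dy); xs <- max(1, 1 + dx):min(W, W + dx)
    if (length(ys) > 0 && length(xs) > 0)
      out[ys, xs] <- S[ys - dy, xs - dx]
    return(out)
  }
  shift_image(S, dy, dx)
}

#' Render a raster movie from ground truth
#'
#' Per frame the static scene components are shifted by the motion
#' series, the uniform background series and photon offset added,
#' Gaussian noise applied, and negatives clipped to zero.
#'
#' @param gt A [simulate_traces()] result.
#' @param motion A [motion_config()].
#' @param n_frames Number of frames (at most `gt$n_samples`).
#' @return A [raster_movie()]; the motion series used is attached as
#'   `attr(, "motion")`.
#' @export
render_raster <- function(gt, motion = motion_config(), n_frames = gt$n_samples) {
  cfg <- gt$config
  if (n_frames > gt$n_samples)
    stop_smartline("bad_config", "n_frames exceeds simulated samples")
  H <- cfg$fov_shape[1]; W <- cfg$fov_shape[2]
  m <- motion_series(motion, n_frames, cfg$seed + 2L)
  set.seed(cfg$seed + 3L)
  frames <- array(0, c(n_frames, H, W))
  for (t in seq_len(n_frames)) {
    S <- shift_scene(scene_at(gt, t), m[t, 1], m[t, 2])
    noise <- cfg$noise_sd * stats::rnorm(H * W)
    frames[t, , ] <- pmax(cfg$photon_offset + gt$background[t] + S +
                            matrix(noise, H, W), 0)
  }
  lp <- 1 / (gt$rate * H)
  mov <- raster_movie(frames, acquisition_metadata(1, 1 / gt$rate, lp,
                                                   lp / W * 1e6))
  attr(mov, "motion") <- m
  mov
}

#' Render an SLS recording from ground truth
#'
#' Each line samples the motion-shifted scene at the trajectory
#' coordinates at that line's time, with the same additive model (and
#' the same RNG draw order) as [render_raster()], so the two renderers
#' agree exactly on trajectory coordinates under identical motion and
#' seeds.
#'
#' @param gt A [simulate_traces()] result.
#' @param traj An [sls_trajectory()] on the same FOV.
#' @param motion A [motion_config()].
#' @param n_lines Number of lines (at most `gt$n_samples`).
#' @return An [sls_recording()] at line rate `gt$rate`; the motion
#'   series is attached as `attr(, "motion")`.
#' @export
render_sls <- function(gt, traj, motion = motion_config(), n_lines = gt$n_samples) {
  cfg <- gt$config
  if (n_lines > gt$n_samples)
    stop_smartline("bad_config", "n_lines exceeds simulated samples")
  H <- cfg$fov_shape[1]; W <- cfg$fov_shape[2]
  co <- traj$coords
  if (any(co < 0) || any(co[, 1] >= H) || any(co[, 2] >= W))
    stop_smartline("roi_out_of_bounds", "trajectory outside the scene FOV")
  idx <- co[, 1] + co[, 2] * H + 1L
  m <- motion_series(motion, n_lines, cfg$seed + 2L)
  set.seed(cfg$seed + 3L)
  lines <- matrix(0, n_lines, nrow(co))
  for (t in seq_len(n_lines)) {
    S <- shift_scene(scene_at(gt, t), m[t, 1], m[t, 2])
    noise <- cfg$noise_sd * stats::rnorm(H * W)
    lines[t, ] <- pmax(0, cfg$photon_offset + gt$background[t] + S[idx] +
                         noise[idx])
  }
  if (is.na(traj$line_period)) traj$line_period <- 1 / gt$rate
  rec <- sls_recording(lines, traj,
                       timestamps = (seq_len(n_lines) - 1) / gt$rate)
  attr(rec, "motion") <- m
  rec
}
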