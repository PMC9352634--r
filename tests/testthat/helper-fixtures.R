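# Shared fixtures and independent oracles, built in code at test time.

test_meta <- function(frame_period = 0.1)
  acquisition_metadata(1, frame_period, frame_period / 32, 1)

# a small movie with two bright blobs over noise
test_scene_matrix <- function(H = 32, W = 32) {
  sc <- matrix(0, H, W)
  sc[8:12, 10:15] <- 100
  sc[20:25, 20:22] <- 60
  sc
}

static_movie <- function(n = 10, H = 32, W = 32, noise_sd = 0, seed = 1) {
  set.seed(seed)
  sc <- test_scene_matrix(H, W)
  fr <- array(stats::rnorm(n * H * W, 0, noise_sd), c(n, H, W))
  for (t in seq_len(n)) fr[t, , ] <- pmax(fr[t, , ] + sc, 0)
  raster_movie(fr, test_meta())
}

# integer zero-fill roll of a matrix (oracle for shift_scene/registration)
roll_zero <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  ys <- max(1, 1 + dy):min(H, H + dy); xs <- max(1, 1 + dx):min(W, W + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# independent Eq.-1 SNR oracle (deliberately plain)
oracle_snr <- function(f) {
  q <- as.numeric(stats::quantile(f, 0.25, type = 7))
  f25 <- f[f < q]
  (max(f) - mean(f25)) / sqrt(mean((f25 - mean(f25))^2))
}

# exhaustive prefix oracle for SNR-maximising pixel selection
oracle_prefix_selection <- function(traces, pixels) {
  s <- apply(traces, 2, function(f)
    tryCatch(oracle_snr(f), error = function(e) NA_real_))
  keep <- which(!is.na(s) & is.finite(s))
  ord <- keep[order(-s[keep], pixels[keep, 1], pixels[keep, 2])]
  best_k <- 1; best <- -Inf
  for (k in seq_along(ord)) {
    m <- rowMeans(traces[, ord[seq_len(k)], drop = FALSE])
    v <- tryCatch(oracle_snr(m), error = function(e) -Inf)
    if (!is.finite(v)) v <- -Inf
    if (v > best) { best <- v; best_k <- k }
  }
  pixels[ord[seq_len(best_k)], , drop = FALSE]
}

# brute-force pixel classification oracle (per-pixel, per-ROI loops)
oracle_classify <- function(coords, seg) {
  n <- nrow(coords)
  out <- data.frame(class = rep("background", n), roi_id = NA_integer_)
  for (i in seq_len(n)) {
    claims <- character(0); claim_id <- integer(0)
    for (r in seg$rois) {
      d <- min(sqrt((r$pixels[, 1] - coords[i, 1])^2 +
                      (r$pixels[, 2] - coords[i, 2])^2))
      cl <- if (d <= 1) "roi" else if (d <= 2) "outer_ring" else
        if (d <= 4) "surround" else NA
      if (!is.na(cl)) { claims <- c(claims, cl); claim_id <- c(claim_id, r$id) }
    }
    if (length(claims) == 1) {
      out$class[i] <- claims; out$roi_id[i] <- claim_id
    } else if (length(claims) >= 2) out$class[i] <- "discarded"
  }
  out
}

# independent nearest-neighbour chain (oracle for greedy_intra_roi_path)
oracle_greedy <- function(px, entry) {
  px <- matrix(as.numeric(px), ncol = 2)
  out <- matrix(0, 0, 2)
  cur <- entry
  while (nrow(px) > 0) {
    d <- sqrt((px[, 1] - cur[1])^2 + (px[, 2] - cur[2])^2)
    i <- order(d, px[, 1], px[, 2])[1]
    out <- rbind(out, px[i, ])
    cur <- px[i, ]
    px <- px[-i, , drop = FALSE]
  }
  out
}

# small synthetic SLS session shared by several test files
demo_session <- function(seed = 7, n_lines = 300, rate = 20,
                         surround_width = 3, refbox = c(30, 30, 8, 8),
                         motion = motion_config(), n_rois = 4, ...) {
  sc <- scene_config(fov_shape = c(40, 40), n_rois = n_rois, seed = seed, ...)
  gt <- simulate_traces(make_scene(sc), n_lines / rate + 1, rate)
  traj <- build_trajectory(gt$segmentation, ga_config(100, 60, seed = seed),
                           surround_width = surround_width, refbox = refbox)
  rec <- render_sls(gt, traj, motion, n_lines)
  list(gt = gt, traj = traj, rec = rec, seg = gt$segmentation)
}

# md5 map of a directory's files, keyed by relative name
dir_md5 <- function(d) {
  f <- sort(list.files(d, recursive = TRUE, full.names = TRUE))
  # config/provenance embed absolute paths; numeric outputs must match
  f <- f[!basename(f) %in% c("config.json", "provenance.json")]
  stats::setNames(unname(tools::md5sum(f)), basename(f))
}

sim_config <- function(out, seed = 3)
  list(out = out, seed = seed,
       scene = list(fov_shape = c(36, 36), n_rois = 3, noise_sd = 2),
       motion = list(drift_sd = 0),
       duration_s = 8, rate_hz = 10, n_frames = 20,
       n_generations = 40,
       design = list(surround_width = 2, refbox = c(26, 26, 6, 6)))


# a session whose refbox shows a high-contrast pattern, with an optional
# injected integer displacement of the whole scene from line t0 on
refbox_session <- function(n = 120, t0 = NULL, shift = c(0, 0), noise_sd = 0,
                           seed = 1) {
  set.seed(seed)
  seg <- segmentation(c(30, 30), list(roi(1, as.matrix(expand.grid(10:12, 10:12)))))
  segs <- add_surround(seg, 2)
  roi_path <- greedy_intra_roi_path(segs$rois[[1]]$pixels, c(10, 10))
  sur_path <- greedy_intra_roi_path(segs$surrounds[[1]], roi_path[nrow(roi_path), ])
  rb <- c(18, 18, 8, 8)
  rb_px <- cbind(rep(18:25, each = 8), rep(18:25, times = 8))
  co <- rbind(roi_path, sur_path, rb_px)
  labels <- c(rep("roi 1", nrow(roi_path)), rep("surround 1", nrow(sur_path)),
              rep("refbox", 64))
  traj <- sls_trajectory(co, labels, refbox = rb, line_period = 0.05)
  # scene: bright soma patch + checkered refbox pattern on a flat field
  scene <- matrix(20, 30, 30)
  scene[11:13, 11:13] <- 100  # 1-based block = ROI pixels
  pat <- matrix(runif(64, 10, 130), 8, 8)  # aperiodic, sharp autocorrelation
  scene[19:26, 19:26] <- pat
  lines <- matrix(0, n, nrow(co))
  for (t in seq_len(n)) {
    sc <- scene
    if (!is.null(t0) && t >= t0) sc <- roll_zero(scene, shift[1], shift[2])
    lines[t, ] <- sc[cbind(co[, 1] + 1, co[, 2] + 1)] + rnorm(nrow(co), 0, noise_sd)
  }
  rec <- sls_recording(pmax(lines, 0), traj)
  list(rec = rec, seg = seg, cls = classify_pixels(traj, seg))
}

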