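test_that("pixel classification follows the distance-interval rules", {
  seg <- segmentation(c(30, 30), list(roi(1, rbind(c(10, 10))),
                                      roi(2, rbind(c(10, 20)))))
  co <- rbind(c(10, 10),      # d = 0 -> roi 1
              c(10, 11.0) + c(0, 0.5) * 0,  # placeholder (integer coords only)
              c(12, 10),      # d = 2 -> outer ring 1
              c(13, 10),      # d = 3 -> surround 1
              c(15, 10),      # d = 5 -> background
              c(10, 14))      # d = 4 from roi 1 AND d = 6 from roi 2 -> surround 1
  co[2, ] <- c(10, 12)        # d = 2 -> outer ring 1
  traj <- sls_trajectory(co, rep("x", nrow(co)))
  cls <- classify_pixels(traj, seg)
  expect_equal(cls$class, c("roi", "outer_ring", "outer_ring", "surround",
                            "background", "surround"))
  expect_equal(cls$roi_id[1], 1L)
  # a pixel claimed by both ROIs is discarded
  seg2 <- segmentation(c(30, 30), list(roi(1, rbind(c(10, 10))),
                                       roi(2, rbind(c(10, 16)))))
  co2 <- rbind(c(10, 13), c(10, 14))  # d = (3, 3) and (4, 2): both claim
  cls2 <- classify_pixels(sls_trajectory(co2, c("x", "x")), seg2)
  expect_equal(cls2$class, c("discarded", "discarded"))
  expect_error(classify_pixels(traj, segmentation(c(30, 30), list())),
               class = "smartline_empty_roi")
})

test_that("pixel classification equals the brute-force distance oracle", {
  set.seed(20)
  for (case in 1:12) {
    K <- sample(2:4, 1)
    rois <- lapply(seq_len(K), function(k)
      roi(k, unique(cbind(sample(0:17, 4, TRUE), sample(0:17, 4, TRUE)))))
    seg <- segmentation(c(18, 18), rois)
    co <- unique(cbind(sample(0:17, 40, TRUE), sample(0:17, 40, TRUE)))
    cls <- classify_pixels(sls_trajectory(co, rep("x", nrow(co))), seg)
    orc <- oracle_classify(co, seg)
    expect_equal(cls$class, orc$class)
    expect_equal(cls$roi_id, orc$roi_id)
    # classes partition the trajectory pixels
    expect_true(all(cls$class %in% c("roi", "outer_ring", "surround",
                                     "background", "discarded")))
  }
})

# rank-1 recording: pixel j = loading_j * s_t (+ optional noise)
rank1_recording <- function(s, loadings, coords, noise_sd = 0, line_period = 0.05,
                            seed = 1) {
  set.seed(seed)
  n <- length(s)
  lines <- outer(s, loadings) + matrix(rnorm(n * length(loadings), 0, noise_sd), n)
  sls_recording(lines - min(lines), sls_trajectory(coords, rep("x", nrow(coords)),
                                                   line_period = line_period))
}

test_that("artefact detection stays quiet on AR(2)-consistent dynamics", {
  set.seed(21)
  n <- 400
  s <- as.numeric(stats::filter(rnorm(n), c(1.6, -0.64), method = "recursive"))
  co <- cbind(0, 0:9)
  rec <- rank1_recording(s, runif(10, 0.5, 1.5), co, noise_sd = 0.05)
  rep <- detect_large_artifact(rec, window_s = 5, threshold = 0.3)
  expect_null(rep$crop_index)
  expect_gt(min(rep$sliding_corr, na.rm = TRUE), 0.8)
  expect_lt(max(abs(rep$ar_coeffs - c(1.6, -0.64))), 0.15)
  # degenerate threshold above 1 fires at the first evaluated window
  rep2 <- detect_large_artifact(rec, window_s = 5, threshold = 1.01)
  L <- round(5 / 0.05)
  expect_equal(rep2$crop_index, L + 2)
  expect_error(detect_large_artifact(
    sls_recording(rec$lines[1:100, ], rec$trajectory,
                  timestamps = rec$timestamps[1:100]), window_s = 5),
    class = "smartline_too_short")
})

test_that("artefact detection fires within a window of a decorrelating shift", {
  n <- 400; t0 <- 250; L <- round(5 / 0.05)
  hits <- 0
  for (s_i in 1:10) {
    set.seed(30 + s_i)
    s <- as.numeric(stats::filter(rnorm(n), c(1.6, -0.64), method = "recursive"))
    lines <- outer(s, runif(12, 0.5, 1.5)) + matrix(rnorm(n * 12, 0, 0.05), n)
    # from t0 on: pixels decouple into independent white noise
    lines[t0:n, ] <- matrix(rnorm((n - t0 + 1) * 12, 0, sd(s)), n - t0 + 1)
    rec <- sls_recording(lines - min(lines),
                         sls_trajectory(cbind(0, 0:11), rep("x", 12),
                                        line_period = 0.05))
    rep <- detect_large_artifact(rec, window_s = 5, threshold = 0.3)
    if (!is.null(rep$crop_index) && abs(rep$crop_index - t0) <= L) hits <- hits + 1
  }
  expect_gte(hits, 9)
  # cropping keeps only the leading lines
  expect_lt(nrow(crop_recording(rec, rep)$lines), n)
})

test_that("background subtraction removes a shared rank-1 signal", {
  seg <- segmentation(c(20, 20), list(roi(1, rbind(c(5, 5), c(5, 6)))))
  co <- rbind(c(5, 5), c(5, 6), c(15, 15), c(15, 16), c(16, 15))
  b <- 10 + 5 * sin(seq(0, 6 * pi, length.out = 200))
  lines <- matrix(b, 200, 5)
  rec <- sls_recording(lines, sls_trajectory(co, rep("x", 5), line_period = 0.05))
  cls <- classify_pixels(rec$trajectory, seg)
  out <- subtract_background(rec, cls, ratio = 0.7)
  # identical traces: rank-1 is exact, so every pixel keeps 0.3 b(t)
  expect_equal(out$lines, matrix(0.3 * b, 200, 5), tolerance = 1e-9)
  expect_equal(attr(out, "background"), b, tolerance = 1e-9)
  # a zero-valued pixel is clipped at zero, not driven negative
  lines2 <- lines; lines2[, 1] <- 0
  out2 <- subtract_background(
    sls_recording(lines2, rec$trajectory), cls, 0.7)
  expect_true(all(out2$lines[, 1] == 0))
  expect_true(all(out2$lines >= 0))
  # fewer than two background pixels is a typed error
  seg_far <- segmentation(c(20, 20), list(roi(1, rbind(c(5, 5), c(15, 15)))))
  expect_error(subtract_background(rec, classify_pixels(rec$trajectory, seg_far)),
               class = "smartline_no_background")
})

test_that("SNR-based reassignment equals a per-window brute-force ranking", {
  set.seed(22)
  seg <- segmentation(c(20, 20), list(roi(1, rbind(c(5, 5), c(5, 6)))))
  co <- rbind(c(5, 5), c(5, 6), c(6, 5), c(6, 6), c(5, 7), c(4, 5))
  n <- 80
  lines <- matrix(rexp(n * 6, 1), n) + 5
  lines[, 2] <- lines[, 2] + c(rep(0, 30), 20 * 0.8^(0:19), rep(0, 30))
  rec <- sls_recording(lines, sls_trajectory(co, rep("x", 6), line_period = 0.1))
  cls <- classify_pixels(rec$trajectory, seg)
  asg <- correct_motion_snr(rec, cls, seg, window_s = 2)
  L <- 20
  pool <- which(cls$class %in% c("roi", "outer_ring", "surround"))
  for (t in c(1, 15, 40, n - 5, n)) {
    win <- t:min(t + L - 1, n)
    s <- sapply(pool, function(j)
      tryCatch(oracle_snr(lines[win, j]), error = function(e) -Inf))
    ord <- pool[order(-s, co[pool, 1], co[pool, 2])]
    expect_equal(sort(asg$assigned[[1]][[t]]), sort(ord[1:2]))
    expect_setequal(asg$neuropil[[1]][[t]], setdiff(pool, ord[1:2]))
  }
  # a pool smaller than the reference count is rejected
  seg_big <- segmentation(c(20, 20), list(roi(1, cbind(5, 0:12))))
  co_small <- rbind(c(5, 0), c(5, 1))
  rec_s <- sls_recording(lines[, 1:2],
                         sls_trajectory(co_small, c("x", "x"), line_period = 0.1))
  expect_error(correct_motion_snr(rec_s, classify_pixels(rec_s$trajectory, seg_big),
                                  seg_big, 2),
               class = "smartline_pool_too_small")
})

test_that("refbox motion correction recovers injected displacements", {
  ses <- refbox_session()
  mc <- correct_motion_refbox(ses$rec, ses$cls, ses$seg)
  expect_true(all(mc$shifts == 0))
  # with zero motion the assignment is exactly the reference footprint
  co0 <- ses$rec$trajectory$coords
  rpx0 <- ses$seg$rois[[1]]$pixels
  ref_idx <- which((co0[, 1] * 30 + co0[, 2]) %in% (rpx0[, 1] * 30 + rpx0[, 2]))
  expect_setequal(mc$assignment$assigned[[1]][[5]], ref_idx)
  # injected step (2, -1) from line 60
  ses2 <- refbox_session(t0 = 60, shift = c(2, -1), noise_sd = 1, seed = 2)
  mc2 <- correct_motion_refbox(ses2$rec, ses2$cls, ses2$seg)
  late <- 70:120
  expect_gte(mean(abs(mc2$shifts[late, 1] - 2) < 0.5 &
                    abs(mc2$shifts[late, 2] + 1) < 0.5), 0.95)
  expect_true(all(abs(mc2$shifts[1:55, ]) < 0.5))
  # assigned pixels after the shift sit at the displaced footprint
  a <- mc2$assignment$assigned[[1]][[100]]
  co <- ses2$rec$trajectory$coords
  rpx <- ses2$seg$rois[[1]]$pixels
  shifted_keys <- (rpx[, 1] + 2) * 30 + (rpx[, 2] - 1)
  expect_true(all((co[a, 1] * 30 + co[a, 2]) %in% shifted_keys))
  expect_gte(length(a), 5)
  # smoothing reduces the variance of the shift series on a static scene
  ses3 <- refbox_session(noise_sd = 25, seed = 3)
  m_raw <- correct_motion_refbox(ses3$rec, ses3$cls, ses3$seg, smooth_window_s = 0)
  m_sm <- correct_motion_refbox(ses3$rec, ses3$cls, ses3$seg, smooth_window_s = 2)
  expect_lte(var(m_sm$shifts[, 1]) + var(m_sm$shifts[, 2]),
             var(m_raw$shifts[, 1]) + var(m_raw$shifts[, 2]))
  # errors: no refbox / tiny refbox
  tr <- sls_trajectory(rbind(c(0, 0), c(0, 1)), c("x", "x"), line_period = 0.05)
  rec0 <- sls_recording(matrix(1:10, 5, 2), tr)
  expect_error(correct_motion_refbox(rec0, ses$cls, ses$seg),
               class = "smartline_no_refbox")
})

test_that("local neuropil subtraction inverts constructed contamination", {
  seg <- segmentation(c(20, 20), list(roi(1, rbind(c(5, 5), c(5, 6)))))
  co <- rbind(c(5, 5), c(5, 6), c(5, 9), c(8, 5))  # roi x2, surround x2
  n <- 100
  s <- c(rep(0, 40), 8 * 0.85^(0:19), rep(0, 40))
  np <- 3 + sin(seq(0, 4 * pi, length.out = n))
  lines <- cbind(s + 0.7 * np, s + 0.7 * np, np, np)
  rec <- sls_recording(lines, sls_trajectory(co, rep("x", 4), line_period = 0.05))
  cls <- classify_pixels(rec$trajectory, seg)
  asg <- assignment_from_classification(cls, n)
  out <- subtract_neuropil_local(rec, asg, ratio = 0.7)
  expect_equal(out$traces[, 1], s, tolerance = 1e-12)
  # ROI pixels identical to surround pixels: output = 0.3 x common trace
  rec2 <- sls_recording(cbind(np, np, np, np), rec$trajectory)
  out2 <- subtract_neuropil_local(rec2, asg, 0.7)
  expect_equal(out2$traces[, 1], 0.3 * np, tolerance = 1e-12)
  # clipping: 0.5 n - 0.7 n < 0 everywhere -> all zero
  rec3 <- sls_recording(cbind(0.5 * np, 0.5 * np, np, np), rec$trajectory)
  expect_true(all(subtract_neuropil_local(rec3, asg, 0.7)$traces[, 1] == 0))
  # ROI without neuropil pixels passes through and is flagged
  seg_iso <- segmentation(c(20, 20), list(roi(1, rbind(c(5, 5), c(5, 6)))))
  co_iso <- rbind(c(5, 5), c(5, 6))
  rec_iso <- sls_recording(lines[, 1:2],
                           sls_trajectory(co_iso, c("x", "x"), line_period = 0.05))
  asg_iso <- assignment_from_classification(
    classify_pixels(rec_iso$trajectory, seg_iso), n)
  out_iso <- subtract_neuropil_local(rec_iso, asg_iso)
  expect_equal(out_iso$traces[, 1], s + 0.7 * np)
  expect_true(any(grepl("passed through", out_iso$provenance)))
})

test_that("global neuropil subtraction zeroes identical ROI signals", {
  seg <- segmentation(c(30, 30), list(roi(1, rbind(c(5, 5), c(5, 6))),
                                      roi(2, rbind(c(20, 20), c(20, 21)))))
  co <- rbind(c(5, 5), c(5, 6), c(5, 9),
              c(20, 20), c(20, 21), c(20, 24))
  n <- 120
  b <- 5 + 2 * cos(seq(0, 3 * pi, length.out = n))
  lines <- matrix(b, n, 6)
  rec <- sls_recording(lines, sls_trajectory(co, rep("x", 6), line_period = 0.05))
  asg <- assignment_from_classification(classify_pixels(rec$trajectory, seg), n)
  out <- subtract_neuropil_global(rec, asg)
  expect_equal(max(abs(out$traces)), 0, tolerance = 1e-9)
  # independent transients on top of the shared signal decorrelate
  set.seed(23)
  t1 <- pmax(0, as.numeric(stats::filter(rbinom(n, 1, 0.05) * 5,
                                         c(1.3, -0.42), method = "recursive")))
  t2 <- pmax(0, as.numeric(stats::filter(rbinom(n, 1, 0.05) * 5,
                                         c(1.3, -0.42), method = "recursive")))
  lines2 <- cbind(b + t1, b + t1, b, b + t2, b + t2, b)
  rec2 <- sls_recording(lines2, rec$trajectory)
  out2 <- subtract_neuropil_global(rec2, asg)
  raw <- extract_traces(rec2, asg)
  expect_lt(cor(out2$traces)[1, 2], cor(raw$traces)[1, 2])
  expect_error(subtract_neuropil_global(
    rec, line_assignment(1L, list(1:2), list(3L), n)),
    class = "smartline_too_few_rois")
})

test_that("trace extraction averages the assigned pixels per line", {
  co <- rbind(c(1, 1), c(1, 2), c(2, 1))
  traj <- sls_trajectory(co, rep("x", 3), line_period = 0.1)
  lines <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12), 4, 3)
  rec <- sls_recording(lines, traj)
  # single-pixel ROI: the trace is that pixel's column
  a1 <- line_assignment(1L, list(2L), list(integer(0)), 4)
  expect_equal(extract_traces(rec, a1)$traces[, 1], lines[, 2])
  expect_equal(extract_traces(rec, a1)$rate, 10)
  # time-varying assignment equals a per-line brute-force average
  slots <- list(c(1L, 2L), 3L, c(1L, 3L), c(1L, 2L, 3L))
  a2 <- line_assignment(1L, list(slots), list(integer(0)), 4)
  want <- sapply(1:4, function(t) mean(lines[t, slots[[t]]]))
  expect_equal(extract_traces(rec, a2)$traces[, 1], want)
  a3 <- line_assignment(1L, list(list(1L, integer(0), 1L, 1L)),
                        list(integer(0)), 4)
  expect_error(extract_traces(rec, a3), class = "smartline_empty_assignment")
})

test_that("trace-set deconvolution applies the AR-order rule", {
  n <- 200
  set.seed(24)
  f <- 10 + pmax(0, as.numeric(stats::filter(rbinom(n, 1, 0.04) * 3,
                                             c(1.6, -0.64), method = "recursive"))) +
    rnorm(n, 0, 0.05)
  ts20 <- trace_set(cbind(f, rev(f)), 1:2, rate = 20)
  d <- deconvolve_sls(ts20)
  expect_length(d$ar_coeffs[[1]], 2)  # AR(2) at 20 Hz
  expect_true(all(d$activity$traces >= 0))
  ts1 <- trace_set(cbind(f, rev(f)), 1:2, rate = 1)
  expect_length(deconvolve_sls(ts1)$ar_coeffs[[1]], 1)  # AR(1) below 2 Hz
  # zero traces give zero activities
  z <- trace_set(matrix(10, 50, 2) + 0, 1:2, 20)
  expect_error(deconvolve_sls(z), class = "smartline_degenerate_trace")
})

test_that("quality metrics compare SNR and pairwise correlations", {
  set.seed(25)
  n <- 150
  base <- sapply(1:3, function(k)
    10 + pmax(0, as.numeric(stats::filter(rbinom(n, 1, 0.05) * 4,
                                          c(1.3, -0.42), method = "recursive"))) +
      rnorm(n, 0, 0.1))
  ts <- trace_set(base, 1:3, 20)
  m0 <- quality_metrics(ts, ts)
  expect_equal(m0$delta_snr, 0)
  expect_equal(m0$delta_corr, 0)
  # adding independent noise decorrelates
  shared <- base + 3 * sin(seq(0, 6 * pi, length.out = n))
  noisy <- shared + matrix(rnorm(n * 3, 0, 3), n)
  expect_lt(quality_metrics(trace_set(shared, 1:3, 20),
                            trace_set(noisy, 1:3, 20))$delta_corr, 0)
  # identical pair has correlation 1; a single ROI has undefined delta corr
  two <- trace_set(cbind(base[, 1], base[, 1]), 1:2, 20)
  expect_equal(quality_metrics(two, two)$corr_before, 1)
  one <- trace_set(base[, 1, drop = FALSE], 1L, 20)
  expect_true(is.na(quality_metrics(one, one)$delta_corr))
})

test_that("run_pipeline validates steps and reports neutral metrics when empty", {
  ses <- demo_session(seed = 9, n_lines = 150)
  res <- run_pipeline(ses$rec, ses$seg, character(0))
  expect_equal(res$metrics$delta_snr, 0)
  expect_equal(res$metrics$delta_corr, 0)
  expect_equal(res$traces$traces, res$raw_traces$traces)
  expect_error(run_pipeline(ses$rec, ses$seg,
                            c("correct_motion_snr", "correct_motion_refbox")),
               class = "smartline_bad_step")
  expect_error(run_pipeline(ses$rec, ses$seg,
                            c("subtract_neuropil_local", "subtract_neuropil_global")),
               class = "smartline_bad_step")
  expect_error(run_pipeline(ses$rec, ses$seg, "unknown_step"),
               class = "smartline_bad_step")
  # pre-flight: refbox-dependent step on a refbox-less trajectory
  ses2 <- demo_session(seed = 9, n_lines = 60, refbox = NULL)
  expect_error(run_pipeline(ses2$rec, ses2$seg, "correct_motion_refbox"),
               class = "smartline_no_refbox")
})

test_that("subtraction pipelines reduce correlations; motion-only does not", {
  ses <- demo_session(seed = 2, n_lines = 600)
  res_bg <- run_pipeline(ses$rec, ses$seg,
                         c("subtract_background", "subtract_neuropil_local"))
  expect_lt(res_bg$metrics$delta_corr, 0)
  expect_true(all(res_bg$traces$traces >= 0))
  res_mo <- run_pipeline(ses$rec, ses$seg, "correct_motion_snr")
  expect_gte(res_mo$metrics$delta_corr, -0.1)
})
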