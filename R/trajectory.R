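#' Genetic-algorithm configuration for the ROI-ordering TSP
#'
#' @param population_size Individuals per generation (divisible by 4;
#'   selection works on random groups of 4).
#' @param n_generations Number of generations.
#' @param seed RNG seed; the whole search is reproducible from it.
#' @return A `ga_config` object.
#' @export
ga_config <- function(population_size = 100L, n_generations = 1000L, seed = 1L) {
  if (population_size <= 0 || n_generations <= 0)
    stop_smartline("bad_config", "population size and generations must be positive")
  if (population_size %% 4 != 0)
    stop_smartline("bad_config", "population size must be divisible by 4")
  structure(list(population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 seed = as.integer(seed)),
            class = "ga_config")
}

closed_tour_length <- function(D, order) {
  nxt <- c(order[-1], order[1])
  sum(D[cbind(order, nxt)])
}

#' Solve the ROI visiting order by a genetic algorithm
#'
#' Approximate solution of the travelling-salesman problem over ROI
#' centroids (closed tour, Euclidean distances in pixels). Each
#' generation the population is scored, the global best retained, and
#' the population randomly split into groups of 4; the best individual
#' of each group spawns four children: itself, a flip (reversal of a
#' random subsegment), a swap (exchange of two random positions) and a
#' slide (one-step rotation of the subsegment), all sharing the same
#' random cut points.
#'
#' @param centroids Numeric matrix `[n, 2]` of (row, col) centroids.
#' @param config A [ga_config()].
#' @return A list with `order` (1-based permutation of centroid
#'   indices), `tour_length` (pixels) and `history` (best length per
#'   generation, non-increasing).
#' @export
solve_roi_order_ga <- function(centroids, config = ga_config()) {
  centroids <- matrix(as.numeric(centroids), ncol = 2)
  n <- nrow(centroids)
  if (n == 0) stop_smartline("bad_config", "no centroids")
  D <- as.matrix(stats::dist(centroids))
  if (n <= 3) {  # every closed tour has the same length
    ord <- seq_len(n)
    len <- if (n == 1) 0 else closed_tour_length(D, ord)
    return(list(order = ord, tour_length = len,
                history = rep(len, config$n_generations)))
  }
  set.seed(config$seed)
  P <- config$population_size
  pop <- t(vapply(seq_len(P), function(i) sample.int(n), integer(n)))
  lengths_of <- function(m)
    rowSums(matrix(D[cbind(as.vector(m), as.vector(m[, c(2:n, 1)]))], nrow(m)))
  L <- lengths_of(pop)
  best_i <- which.min(L)
  best_len <- L[best_i]; best_ord <- pop[best_i, ]
  history <- numeric(config$n_generations)
  for (gen in seq_len(config$n_generations)) {
    L <- lengths_of(pop)
    i <- which.min(L)
    if (L[i] < best_len) { best_len <- L[i]; best_ord <- pop[i, ] }
    history[gen] <- best_len
    groups <- matrix(sample.int(P), nrow = 4L)
    newpop <- pop
    for (g in seq_len(P %/% 4L)) {
      members <- groups[, g]
      base <- pop[members[which.min(L[members])], ]
      ij <- sort(sample.int(n, 2L))
      i1 <- ij[1]; j1 <- ij[2]
      flip <- base; flip[i1:j1] <- base[j1:i1]
      swp <- base; swp[c(i1, j1)] <- base[c(j1, i1)]
      sld <- base; sld[i1:j1] <- base[c(j1, i1:(j1 - 1))]
      newpop[members, ] <- rbind(base, flip, swp, sld)
    }
    pop <- newpop
  }
  list(order = best_ord, tour_length = best_len, history = history)
}

#' Exact TSP solution by exhaustive enumeration
#'
#' Enumerates the `(n-1)!/2` distinct closed tours (first node fixed,
#' reversal symmetry halved). Intended as an oracle for small instances.
#'
#' @param centroids Numeric matrix `[n <= 10, 2]`.
#' @return As [solve_roi_order_ga()] (with a single-entry `history`).
#' @export
brute_force_tsp <- function(centroids) {
  centroids <- matrix(as.numeric(centroids), ncol = 2)
  n <- nrow(centroids)
  if (n > 10) stop_smartline("bad_config", "brute force limited to n <= 10")
  D <- as.matrix(stats::dist(centroids))
  if (n <= 3) {
    ord <- seq_len(n)
    len <- if (n == 1) 0 else closed_tour_length(D, ord)
    return(list(order = ord, tour_length = len, history = len))
  }
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perms(v[-i]))))
  }
  p <- perms(2:n)
  p <- p[p[, 1] < p[, n - 1], , drop = FALSE]  # halve by reversal symmetry
  tours <- cbind(1L, p)
  lens <- rowSums(matrix(D[cbind(as.vector(tours),
                                 as.vector(tours[, c(2:n, 1)]))], nrow(tours)))
  i <- which.min(lens)
  list(order = as.integer(tours[i, ]), tour_length = lens[i], history = lens[i])
}

#' Greedy nearest-neighbour path through a ROI's pixels
#'
#' Starts at the pixel closest to `entry` and repeatedly appends the
#' unvisited pixel nearest (Euclidean) to the current one; all ties are
#' broken by (row, col) ascending.
#'
#' @param pixels Integer matrix `[n, 2]` of 0-based (row, col).
#' @param entry Numeric (row, col) entry point.
#' @return The pixels reordered into the visiting chain.
#' @export
greedy_intra_roi_path <- function(pixels, entry) {
  px <- matrix(as.numeric(pixels), ncol = 2)
  n <- nrow(px)
  if (n == 0) stop_smartline("empty_roi", "no pixels to order")
  left <- seq_len(n)
  pick <- function(from) {
    d <- sqrt((px[left, 1] - from[1])^2 + (px[left, 2] - from[2])^2)
    left[order(d, px[left, 1], px[left, 2])[1]]
  }
  path <- integer(n)
  cur <- pick(entry)
  for (i in seq_len(n)) {
    path[i] <- cur
    left <- left[left != cur]
    if (length(left)) cur <- pick(px[cur, ])
  }
  matrix(as.integer(px[path, ]), ncol = 2)
}

# min distance from each query pixel to a pixel set (both [k,2] matrices)
min_dist_to_set <- function(query, set) {
  d2 <- outer(query[, 1], set[, 1], "-")^2 + outer(query[, 2], set[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' Add surround footprints to a segmentation
#'
#' Each ROI gains a surround: the Euclidean dilation of its pixel set by
#' radius `width`, minus the pixels of every ROI, clipped to the FOV.
#' A pixel reached by two ROIs' dilations is assigned to the nearer ROI
#' (ties to the lower ROI id).
#'
#' @param seg A [segmentation()].
#' @param width Dilation radius in pixels (0 returns `seg` unchanged).
#' @return The segmentation with `surrounds` filled in.
#' @export
add_surround <- function(seg, width) {
  if (width < 0) stop_smartline("bad_config", "surround width must be >= 0")
  if (width == 0) return(seg)
  H <- seg$fov_shape[1]; W <- seg$fov_shape[2]
  all_roi <- do.call(rbind, lapply(seg$rois, function(r) r$pixels))
  roi_key <- all_roi[, 1] * W + all_roi[, 2]
  wd <- ceiling(width)
  claim_key <- integer(0); claim_id <- integer(0); claim_d <- numeric(0)
  for (r in seg$rois) {
    rs <- max(0, min(r$pixels[, 1]) - wd):min(H - 1, max(r$pixels[, 1]) + wd)
    cs <- max(0, min(r$pixels[, 2]) - wd):min(W - 1, max(r$pixels[, 2]) + wd)
    cand <- cbind(rep(rs, each = length(cs)), rep(cs, times = length(rs)))
    cand <- cand[!(cand[, 1] * W + cand[, 2]) %in% roi_key, , drop = FALSE]
    if (nrow(cand) == 0) next
    d <- min_dist_to_set(cand, r$pixels)
    sel <- d <= width + 1e-9
    claim_key <- c(claim_key, cand[sel, 1] * W + cand[sel, 2])
    claim_id <- c(claim_id, rep(r$id, sum(sel)))
    claim_d <- c(claim_d, d[sel])
  }
  surrounds <- stats::setNames(vector("list", length(seg$rois)),
                               vapply(seg$rois, function(r) r$id, integer(1)))
  if (length(claim_key)) {
    o <- order(claim_key, claim_d, claim_id)  # per pixel: nearest, then lower id
    first <- !duplicated(claim_key[o])
    win_key <- claim_key[o][first]; win_id <- claim_id[o][first]
    for (k in seq_along(seg$rois)) {
      id <- seg$rois[[k]]$id
      kk <- win_key[win_id == id]
      surrounds[[k]] <- cbind(kk %/% W, kk %% W)
    }
  }
  segmentation(seg$fov_shape, seg$rois, as.integer(ceiling(width)), surrounds)
}

#' Build a smart line scanning trajectory
#'
#' ROI visiting order comes from [solve_roi_order_ga()] on the ROI
#' centroids. Within each ROI, the ROI pixels and then, contiguously,
#' its surround pixels are ordered by [greedy_intra_roi_path()] with the
#' entry point set to the last pixel of the previous ROI (the first ROI
#' enters at its own centroid). Reference-box pixels are appended last
#' in row-major order.
#'
#' @param seg A [segmentation()] (surrounds added here if
#'   `surround_width > 0` and not already present).
#' @param config A [ga_config()].
#' @param surround_width Surround radius, pixels.
#' @param refbox Optional `(row0, col0, height, width)` inside the FOV.
#' @param dwell_time Optional pixel dwell time (us) used to derive the
#'   trajectory line period.
#' @param flyback_s Per-line flyback overhead, s.
#' @return An [sls_trajectory()].
#' @export
build_trajectory <- function(seg, config = ga_config(), surround_width = 0L,
                             refbox = NULL, dwell_time = NULL, flyback_s = 0) {
  if (length(seg$rois) == 0) stop_smartline("empty_roi", "segmentation has no ROIs")
  H <- seg$fov_shape[1]; W <- seg$fov_shape[2]
  all_roi <- do.call(rbind, lapply(seg$rois, function(r) r$pixels))
  if (anyDuplicated(all_roi[, 1] * W + all_roi[, 2]))
    stop_smartline("overlapping_rois",
                   "ROI pixel sets overlap; de-duplicate the segmentation first")
  if (surround_width > 0 && is.null(seg$surrounds))
    seg <- add_surround(seg, surround_width)
  if (!is.null(refbox)) {
    refbox <- as.integer(refbox)
    if (refbox[1] < 0 || refbox[2] < 0 || refbox[1] + refbox[3] > H ||
        refbox[2] + refbox[4] > W)
      stop_smartline("bad_refbox", "reference box outside the FOV")
  }
  cents <- t(vapply(seg$rois, function(r) r$centroid, numeric(2)))
  sol <- solve_roi_order_ga(cents, config)
  coords <- matrix(integer(0), 0, 2); labels <- character(0)
  entry <- cents[sol$order[1], ]
  for (k in sol$order) {
    r <- seg$rois[[k]]
    path <- greedy_intra_roi_path(r$pixels, entry)
    coords <- rbind(coords, path)
    labels <- c(labels, rep(sprintf("roi %d", r$id), nrow(path)))
    entry <- path[nrow(path), ]
    sur <- if (is.null(seg$surrounds)) NULL else seg$surrounds[[k]]
    if (!is.null(sur) && nrow(sur) > 0) {
      spath <- greedy_intra_roi_path(sur, entry)
      coords <- rbind(coords, spath)
      labels <- c(labels, rep(sprintf("surround %d", r$id), nrow(spath)))
      entry <- spath[nrow(spath), ]
    }
  }
  if (!is.null(refbox)) {
    rb <- cbind(rep(refbox[1] + seq_len(refbox[3]) - 1L, each = refbox[4]),
                rep(refbox[2] + seq_len(refbox[4]) - 1L, times = refbox[3]))
    coords <- rbind(coords, rb)
    labels <- c(labels, rep("refbox", nrow(rb)))
  }
  lp <- if (is.null(dwell_time)) NA_real_ else
    nrow(coords) * dwell_time * 1e-6 + flyback_s
  traj <- sls_trajectory(coords, labels, refbox, lp)
  attr(traj, "tour") <- sol
  traj
}

#' Effective line sampling rate of a trajectory
#'
#' @param traj An [sls_trajectory()].
#' @param dwell_time Pixel dwell time, us.
#' @param flyback_s Per-line flyback overhead, s (0 = ideal galvo).
#' @return Lines per second, Hz.
#' @export
effective_line_rate <- function(traj, dwell_time, flyback_s = 0) {
  if (dwell_time <= 0) stop_smartline("bad_config", "dwell time must be positive")
  1 / (nrow(traj$coords) * dwell_time * 1e-6 + flyback_s)
}
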