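# Medial centerline extraction from a binary tube mask.
#
# The centerline is defined as the curve through the mask that stays
# equidistant from the boundary in each orthogonal cross-section. It is
# recovered as the medially-weighted shortest voxel path between the two
# geodesic extremes of the mask, then smoothed and resampled at a fixed
# arc-length spacing.

# Exact anisotropic squared Euclidean distance transform via separable
# 1D min-convolution along each axis (brute-force offset scan; exact because
# the squared EDT is separable).
minconv_axis1 <- function(M, step) {
  n <- nrow(M)
  R <- M
  cap <- suppressWarnings(max(M[is.finite(M)]))
  has_inf <- any(!is.finite(M))
  for (o in seq_len(n - 1)) {
    c2 <- (o * step)^2
    if (!has_inf && c2 >= cap) break
    R[(o + 1):n, ] <- pmin(R[(o + 1):n, ], M[1:(n - o), ] + c2)
    R[1:(n - o), ] <- pmin(R[1:(n - o), ], M[(o + 1):n, ] + c2)
  }
  R
}

minconv_pass <- function(A, axis, step) {
  d <- dim(A)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  B <- aperm(A, perm)
  db <- dim(B)
  B <- minconv_axis1(matrix(B, db[1]), step)
  dim(B) <- db
  aperm(B, order(perm))
}

#' Euclidean distance-to-background transform in millimetres
#'
#' For each foreground voxel, the Euclidean distance (in mm, honouring
#' anisotropic spacing) from its center to the nearest background voxel
#' center. Background voxels map to 0.
#'
#' @param mask a [seg_mask()].
#' @return numeric array of distances in mm, same shape as the mask.
#' @export
edt_mm <- function(mask) {
  A <- array(ifelse(mask$values != 0, Inf, 0), dim = dim(mask$values))
  for (axis in 1:3) A <- minconv_pass(A, axis, mask$spacing_mm[axis])
  sqrt(A)
}

# 26-connected neighbour offsets with lexicographically positive direction
offsets26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  g[keep, , drop = FALSE]
}

# Edge list over foreground voxels for a set of offsets. Returns linear voxel
# indices (from, to) and the physical step length of each edge.
mask_edges <- function(arr, spacing, offs) {
  d <- dim(arr)
  from <- integer(0); to <- integer(0); len <- numeric(0)
  lin <- array(seq_along(arr), dim = d)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    sx <- seq(max(1, 1 - o[1]), min(d[1], d[1] - o[1]))
    sy <- seq(max(1, 1 - o[2]), min(d[2], d[2] - o[2]))
    sz <- seq(max(1, 1 - o[3]), min(d[3], d[3] - o[3]))
    a <- arr[sx, sy, sz, drop = FALSE]
    b <- arr[sx + o[1], sy + o[2], sz + o[3], drop = FALSE]
    hit <- which(a != 0 & b != 0)
    if (!length(hit)) next
    la <- lin[sx, sy, sz, drop = FALSE][hit]
    lb <- lin[sx + o[1], sy + o[2], sz + o[3], drop = FALSE][hit]
    from <- c(from, la); to <- c(to, lb)
    len <- c(len, rep(sqrt(sum((o * spacing)^2)), length(hit)))
  }
  list(from = from, to = to, len = len)
}

largest_component <- function(arr, spacing) {
  fg <- which(arr != 0)
  ed <- mask_edges(arr, spacing, offsets26())
  vid <- match(seq_along(arr), fg)  # linear index -> vertex id
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(ed$from))
    g <- igraph::add_edges(g, rbind(vid[ed$from], vid[ed$to]))
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    keepc <- which.max(comp$csize)
    drop_lin <- fg[comp$membership != keepc]
    arr[drop_lin] <- 0L
    warning(sprintf("mask has %d connected components; keeping the largest", comp$no))
  }
  arr
}

# Detect internal cavities: background 6-connected components inside the
# foreground bounding box that do not reach the box faces.
has_cavity <- function(arr) {
  d <- dim(arr)
  fg <- which(arr != 0, arr.ind = TRUE)
  lo <- pmax(apply(fg, 2, min) - 1L, 1L)
  hi <- pmin(apply(fg, 2, max) + 1L, d)
  sub <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  bg <- array(sub == 0, dim = dim(sub))
  # flood the border-reachable background by repeated 6-neighbour dilation
  reach <- array(FALSE, dim = dim(bg))
  reach[1, , ] <- bg[1, , ]; reach[dim(bg)[1], , ] <- bg[dim(bg)[1], , ]
  reach[, 1, ] <- reach[, 1, ] | bg[, 1, ]; reach[, dim(bg)[2], ] <- reach[, dim(bg)[2], ] | bg[, dim(bg)[2], ]
  reach[, , 1] <- reach[, , 1] | bg[, , 1]; reach[, , dim(bg)[3]] <- reach[, , dim(bg)[3]] | bg[, , dim(bg)[3]]
  repeat {
    grown <- reach
    n <- dim(reach)
    grown[-1, , ] <- grown[-1, , ] | reach[-n[1], , ]
    grown[-n[1], , ] <- grown[-n[1], , ] | reach[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | reach[, -n[2], ]
    grown[, -n[2], ] <- grown[, -n[2], ] | reach[, -1, ]
    grown[, , -1] <- grown[, , -1] | reach[, , -n[3]]
    grown[, , -n[3]] <- grown[, , -n[3]] | reach[, , -1]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  any(bg & !reach)
}

moving_average_path <- function(P, window = 5L) {
  n <- nrow(P)
  if (n <= 2L || window <= 1L) return(P)
  h <- window %/% 2L
  out <- P
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i, ] <- colMeans(P[lo:hi, , drop = FALSE])
  }
  out
}

resample_path <- function(P, spacing_mm) {
  seg <- sqrt(rowSums(diff(P)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  n_out <- max(2L, round(L / spacing_mm) + 1L)
  s_new <- seq(0, L, length.out = n_out)
  out <- sapply(1:3, function(a) stats::approx(s, P[, a], xout = s_new)$y)
  list(points = out, arc_length = L)
}

path_tangents <- function(P, half_width = 3L) {
  # central differences over a +/- half_width sample baseline (clamped at the
  # ends); a wider baseline suppresses residual voxel-path wiggle that would
  # tilt the orthogonal measurement plane
  n <- nrow(P)
  T <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    a <- max(1L, i - half_width)
    b <- min(n, i + half_width)
    T[i, ] <- P[b, ] - P[a, ]
  }
  T / sqrt(rowSums(T^2))
}

#' Extract the medial centerline of a tubular segmentation mask
#'
#' The largest 26-connected foreground component is retained; the Euclidean
#' distance transform (mm) supplies a medialness weight; the two endpoints are
#' found by a two-pass farthest-point geodesic search (ties near the extreme
#' broken toward the most medial voxel); the centerline is the shortest path
#' on the 26-connected foreground voxel graph with edge weight
#' `step_length / (boundary_distance + 0.1)^2`, smoothed by a moving average
#' and resampled at a fixed arc-length spacing.
#'
#' @param mask a [seg_mask()] containing a single tubular component with at
#'   least 100 foreground voxels.
#' @param sample_spacing_mm arc-length spacing of the returned samples (mm).
#' @param smooth_window moving-average window (samples) applied to the raw
#'   voxel path before resampling.
#' @return an object of class `centerline` with fields `points_mm` (n x 3),
#'   `tangents` (n x 3 unit rows), `arc_length_mm`, `sample_spacing_mm`.
#' @export
extract_centerline <- function(mask, sample_spacing_mm = 1.0, smooth_window = 5L) {
  arr <- mask$values
  if (sum(arr) < 100L)
    stop("degenerate input: fewer than 100 foreground voxels")
  arr <- largest_component(arr, mask$spacing_mm)
  if (has_cavity(arr))
    stop("topology error: mask contains an internal cavity")
  dist_mm <- edt_mm(seg_mask(arr, mask$spacing_mm, mask$origin_mm))
  if (max(dist_mm) < min(mask$spacing_mm))
    stop("degenerate input: mask thinner than 2 voxels everywhere")

  fg <- which(arr != 0)
  vid <- match(seq_along(arr), fg)
  ed <- mask_edges(arr, mask$spacing_mm, offsets26())
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  g <- igraph::add_edges(g, rbind(vid[ed$from], vid[ed$to]))
  dmid <- (dist_mm[ed$from] + dist_mm[ed$to]) / 2
  w_medial <- ed$len / (dmid + 0.1)^2

  d <- dim(arr)
  fg_ind <- cbind((fg - 1) %% d[1] + 1,
                  ((fg - 1) %/% d[1]) %% d[2] + 1,
                  (fg - 1) %/% (d[1] * d[2]) + 1)
  fg_mm <- world_from_index(fg_ind, mask$spacing_mm, mask$origin_mm)
  # The geodesic extreme of a tube is an end-face rim voxel; the centroid of
  # the extreme region, snapped to the nearest foreground voxel, recovers the
  # medial end-face center instead.
  pick_far <- function(from_v) {
    dg <- as.numeric(igraph::distances(g, v = from_v, weights = ed$len))
    band <- sqrt(sum(mask$spacing_mm^2))  # one diagonal voxel step
    cand <- which(is.finite(dg) & dg >= max(dg[is.finite(dg)]) - band)
    ctr <- colMeans(fg_mm[cand, , drop = FALSE])
    which.min(colSums((t(fg_mm) - ctr)^2))
  }
  v0 <- which.max(dist_mm[fg])  # most interior voxel as the search seed
  e1 <- pick_far(v0)
  e2 <- pick_far(e1)

  vpath <- igraph::shortest_paths(g, from = e1, to = e2, weights = w_medial,
                                  output = "vpath")$vpath[[1]]
  P <- fg_mm[as.integer(vpath), , drop = FALSE]
  P <- moving_average_path(P, smooth_window)
  rs <- resample_path(P, sample_spacing_mm)
  structure(list(points_mm = rs$points,
                 tangents = path_tangents(rs$points),
                 arc_length_mm = rs$arc_length,
                 sample_spacing_mm = sample_spacing_mm),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d samples, arc length %.1f mm, spacing %.2f mm\n",
              nrow(x$points_mm), x$arc_length_mm, x$sample_spacing_mm))
  invisible(x)
}
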