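# CT-like aortic tube phantoms with exact geometric ground truth.
#
# The phantom is a tube of (possibly linearly varying) lumen radius swept
# along an analytic space curve: a straight cylinder, a half-torus arc, or a
# "candy cane" (straight ascending limb + half-torus arch + straight
# descending limb) that mimics the thoracic aorta. Wall calcifications are
# spherical blobs centered on the lumen surface. Ground truth (centerline,
# maximum diameter, volume, calcium) is computed from the analytic
# specification, never from the rasterized grid.

#' Specify an aortic tube phantom
#'
#' @param shape_mode `"straight_cylinder"`, `"torus_arc"` or `"candy_cane"`.
#' @param lumen_radius_mm lumen radius in mm; either a scalar or a pair
#'   `(r_start, r_end)` for a linear taper along the arc.
#' @param segment_length_mm straight-segment length in mm (cylinder length,
#'   or the length of each straight limb of the candy cane).
#' @param bend_radius_mm bend radius of the torus arc in mm (torus and candy
#'   cane only); must exceed the lumen radius.
#' @param lumen_hu,background_hu attenuation inside/outside the tube (HU).
#' @param calcifications list of blobs, each a list/vector with elements
#'   `position` (arc-position fraction in `[0, 1]`), `radius_mm`, and `hu`
#'   (> 130).
#' @param noise_sd_hu standard deviation of the iid Gaussian HU noise.
#' @param voxel_spacing_mm voxel spacing triple (default 1.5, 1.5, 3 mm).
#' @param grid_shape integer triple; `NULL` (default) sizes the grid to
#'   contain the tube with at least a 2-voxel margin.
#' @param seed integer seed for the noise generator.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(shape_mode = c("straight_cylinder", "torus_arc", "candy_cane"),
                         lumen_radius_mm = 18, segment_length_mm = 100,
                         bend_radius_mm = 120, lumen_hu = 40,
                         background_hu = -950, calcifications = list(),
                         noise_sd_hu = 0, voxel_spacing_mm = c(1.5, 1.5, 3.0),
                         grid_shape = NULL, seed = 1L) {
  shape_mode <- match.arg(shape_mode)
  r <- as.numeric(lumen_radius_mm)
  if (!length(r) %in% 1:2 || any(r <= 0)) stop("lumen radius must be positive")
  if (shape_mode != "straight_cylinder" && max(r) >= bend_radius_mm)
    stop("lumen radius must be smaller than the bend radius")
  calcifications <- lapply(calcifications, function(b) {
    b <- as.list(b)
    stopifnot(b$position >= 0, b$position <= 1, b$radius_mm > 0)
    if (b$hu <= 130) stop("calcification blobs must exceed 130 HU")
    b
  })
  structure(list(shape_mode = shape_mode, lumen_radius_mm = r,
                 segment_length_mm = segment_length_mm,
                 bend_radius_mm = bend_radius_mm, lumen_hu = lumen_hu,
                 background_hu = background_hu,
                 calcifications = calcifications, noise_sd_hu = noise_sd_hu,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 grid_shape = grid_shape, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Analytic curve sampled at ds mm: points, unit tangents, total arc length.
phantom_curve <- function(spec, ds = 0.5) {
  L <- spec$segment_length_mm
  R <- spec$bend_radius_mm
  total <- switch(spec$shape_mode,
                  straight_cylinder = L,
                  torus_arc = pi * R,
                  candy_cane = 2 * L + pi * R)
  s <- seq(0, total, by = ds)
  if (s[length(s)] < total) s <- c(s, total)
  pt <- matrix(0, length(s), 3)
  tg <- matrix(0, length(s), 3)
  if (spec$shape_mode == "straight_cylinder") {
    pt[, 3] <- s
    tg[, 3] <- 1
  } else if (spec$shape_mode == "torus_arc") {
    phi <- s / R
    pt[, 1] <- R * (1 - cos(phi)); pt[, 3] <- R * sin(phi)
    tg[, 1] <- sin(phi); tg[, 3] <- cos(phi)
  } else {
    for (i in seq_along(s)) {
      si <- s[i]
      if (si <= L) {
        pt[i, ] <- c(0, 0, si); tg[i, ] <- c(0, 0, 1)
      } else if (si <= L + pi * R) {
        phi <- (si - L) / R
        pt[i, ] <- c(R * (1 - cos(phi)), 0, L + R * sin(phi))
        tg[i, ] <- c(sin(phi), 0, cos(phi))
      } else {
        pt[i, ] <- c(2 * R, 0, L - (si - L - pi * R))
        tg[i, ] <- c(0, 0, -1)
      }
    }
  }
  list(s = s, points = pt, tangents = tg, arc_length = total)
}

phantom_radius_at <- function(spec, s, total) {
  r <- spec$lumen_radius_mm
  if (length(r) == 1L) rep(r, length(s)) else r[1] + (r[2] - r[1]) * s / total
}

# Analytic tube volume: pi * integral r(s)^2 ds (closed form for a linear
# taper), valid for bends with bend_radius > lumen radius (Pappus).
phantom_true_volume_ml <- function(spec, total) {
  r <- spec$lumen_radius_mm
  if (length(r) == 1L) {
    v <- pi * r^2 * total
  } else {
    v <- pi * total * (r[1]^2 + r[1] * r[2] + r[2]^2) / 3
  }
  v / 1000
}

#' Generate a phantom volume, mask and ground truth
#'
#' The mask contains every voxel whose center lies within the local lumen
#' radius of the analytic centerline (flat end caps). The image is
#' `background_hu` outside the mask and `lumen_hu` inside, with calcification
#' blobs painted at their specified HU where the blob sphere intersects the
#' mask, plus seeded iid Gaussian noise.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([image_volume()]), `mask` ([seg_mask()]), and
#'   `truth`: `centerline_points_mm`, `arc_length_mm`, `true_max_diameter_cm`,
#'   `true_volume_ml`, `true_calcium_mm3`.
#' @export
generate_phantom <- function(spec) {
  sp <- spec$voxel_spacing_mm
  cv <- phantom_curve(spec, ds = min(sp) / 3)
  rad <- phantom_radius_at(spec, cv$s, cv$arc_length)
  rmax <- max(rad)

  margin <- 2 * sp + sp  # >= 2-voxel margin plus one voxel of slack
  # half-voxel offset keeps the tube at a generic sub-voxel position, away
  # from the degenerate case of boundary voxel centers exactly at radius r
  lo <- apply(cv$points, 2, min) - rmax - margin - sp / 2
  hi <- apply(cv$points, 2, max) + rmax + margin
  if (is.null(spec$grid_shape)) {
    gshape <- as.integer(ceiling((hi - lo) / sp)) + 1L
    origin <- lo
  } else {
    gshape <- as.integer(spec$grid_shape)
    origin <- lo
    if (any((gshape - 1) * sp < hi - lo))
      stop("geometry error: tube does not fit the requested grid with a 2-voxel margin")
  }

  ax <- lapply(1:3, function(a) origin[a] + (seq_len(gshape[a]) - 1) * sp[a])
  mask_arr <- array(FALSE, dim = gshape)
  ds <- cv$s[2] - cv$s[1]
  half_slab <- 0.75 * ds  # slight overlap so bent sections leave no gaps
  for (i in seq_along(cv$s)) {
    c0 <- cv$points[i, ]; t0 <- cv$tangents[i, ]; r0 <- rad[i]
    reach <- r0 + ds
    ix <- which(abs(ax[[1]] - c0[1]) <= reach)
    iy <- which(abs(ax[[2]] - c0[2]) <= reach)
    iz <- which(abs(ax[[3]] - c0[3]) <= reach)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx <- ax[[1]][ix] - c0[1]; dy <- ax[[2]][iy] - c0[2]; dz <- ax[[3]][iz] - c0[3]
    g <- expand.grid(dx = dx, dy = dy, dz = dz)
    proj <- g$dx * t0[1] + g$dy * t0[2] + g$dz * t0[3]
    perp2 <- g$dx^2 + g$dy^2 + g$dz^2 - proj^2
    # flat end caps: the first/last slab does not extend past the curve ends
    pl <- if (i == 1L) 0 else -half_slab
    pu <- if (i == length(cv$s)) 0 else half_slab
    inside <- proj >= pl & proj <= pu & perp2 <= r0^2
    if (any(inside)) {
      sub <- mask_arr[ix, iy, iz, drop = FALSE]
      sub[inside] <- TRUE
      mask_arr[ix, iy, iz] <- sub
    }
  }

  img <- array(spec$background_hu, dim = gshape)
  img[mask_arr] <- spec$lumen_hu

  true_calcium <- 0
  normal <- c(0, 1, 0)  # perpendicular to every tangent (curves lie in x-z)
  for (b in spec$calcifications) {
    s_b <- b$position * cv$arc_length
    i_b <- which.min(abs(cv$s - s_b))
    ctr <- cv$points[i_b, ] + phantom_radius_at(spec, s_b, cv$arc_length) * normal
    a_mm <- b$radius_mm
    ix <- which(abs(ax[[1]] - ctr[1]) <= a_mm)
    iy <- which(abs(ax[[2]] - ctr[2]) <= a_mm)
    iz <- which(abs(ax[[3]] - ctr[3]) <= a_mm)
    if (length(ix) && length(iy) && length(iz)) {
      g <- expand.grid(dx = ax[[1]][ix] - ctr[1], dy = ax[[2]][iy] - ctr[2],
                       dz = ax[[3]][iz] - ctr[3])
      inblob <- g$dx^2 + g$dy^2 + g$dz^2 <= a_mm^2
      sub_m <- mask_arr[ix, iy, iz, drop = FALSE]
      sub_i <- img[ix, iy, iz, drop = FALSE]
      sub_i[inblob & sub_m] <- b$hu  # clipped to the segmentation mask
      img[ix, iy, iz] <- sub_i
    }
    # analytic in-mask half-volume of a surface-centered blob
    true_calcium <- true_calcium + 0.5 * 4 / 3 * pi * a_mm^3
  }

  if (spec$noise_sd_hu > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
            add = TRUE)
    set.seed(spec$seed)
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd_hu), dim = gshape)
  }

  cl_pts <- phantom_curve(spec, ds = 1)$points

  list(volume = image_volume(img, sp, origin),
       mask = seg_mask(mask_arr, sp, origin),
       truth = list(centerline_points_mm = cl_pts,
                    arc_length_mm = cv$arc_length,
                    true_max_diameter_cm = 2 * rmax / 10,
                    true_volume_ml = phantom_true_volume_ml(spec, cv$arc_length),
                    true_calcium_mm3 = true_calcium))
}

#' Write a phantom to disk
#'
#' Writes `<prefix>_image.nii.gz`, `<prefix>_mask.nii.gz` and
#' `<prefix>_truth.json`.
#'
#' @param phantom a [generate_phantom()] result.
#' @param prefix output path prefix.
#' @return character vector of the three paths, invisibly.
#' @export
write_phantom <- function(phantom, prefix) {
  p1 <- paste0(prefix, "_image.nii.gz")
  p2 <- paste0(prefix, "_mask.nii.gz")
  p3 <- paste0(prefix, "_truth.json")
  write_volume_nifti(phantom$volume, p1)
  write_volume_nifti(phantom$mask, p2)
  tr <- phantom$truth
  tr$centerline_points_mm <- unname(apply(tr$centerline_points_mm, 1, c,
                                          simplify = FALSE))
  jsonlite::write_json(tr, p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
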