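# Feature quantification on a segmented thoracic aorta: maximum orthogonal
# diameter, mask volume, calcification burden, and plausibility QC.

orthonormal_basis <- function(t) {
  a <- c(1, 0, 0)
  if (abs(sum(t * a)) > 0.9) a <- c(0, 1, 0)
  u <- c(t[2] * a[3] - t[3] * a[2],
         t[3] * a[1] - t[1] * a[3],
         t[1] * a[2] - t[2] * a[1])
  u <- u / sqrt(sum(u^2))
  v <- c(t[2] * u[3] - t[3] * u[2],
         t[3] * u[1] - t[1] * u[3],
         t[1] * u[2] - t[2] * u[1])
  list(u = u, v = v)
}

# In-mask extent (mm) from a point along each of a set of directions, by
# marching in `step_mm` increments through the trilinearly interpolated mask
# (inside iff value >= 0.5), with linear sub-step refinement of the crossing.
ray_extent <- function(mask_arr, spacing, origin, center, dirs, step_mm, max_mm) {
  s <- seq(step_mm, max_mm, by = step_mm)
  nd <- nrow(dirs); ns <- length(s)
  pts <- matrix(0, nd * ns, 3)
  for (a in 1:3)
    pts[, a] <- rep(dirs[, a], each = ns) * rep(s, nd) + center[a]
  idx <- index_from_world(pts, spacing, origin)
  val <- matrix(trilinear_interp(mask_arr, idx, fill = 0), ns, nd)
  ext <- numeric(nd)
  for (j in seq_len(nd)) {
    out <- which(val[, j] < 0.5)
    if (!length(out)) { ext[j] <- max_mm; next }
    k <- out[1]
    v_out <- val[k, j]
    if (k == 1L) {
      # boundary within the first step: interpolate from the (inside) center,
      # taking the mask value there as 1
      ext[j] <- step_mm * 0.5 / max(1 - v_out, 0.5)
    } else {
      v_in <- val[k - 1L, j]
      frac <- (v_in - 0.5) / max(v_in - v_out, 1e-9)
      ext[j] <- s[k - 1L] + step_mm * frac
    }
  }
  ext
}

#' Maximum orthogonal diameter along a centerline
#'
#' For each centerline sample (with `end_trim_mm` trimmed from both ends to
#' avoid oblique end-cap chords), chords are cast through the sample point in
#' the plane orthogonal to the local tangent, at `angular_step_deg` increments
#' over 180 degrees. Each chord length is the in-mask extent through the
#' point, found by marching the trilinearly interpolated mask in 0.25 mm
#' steps (inside iff interpolated value >= 0.5). The per-point diameter is
#' the longest chord; the global maximum is reported in cm.
#'
#' @param mask a [seg_mask()].
#' @param cl a [extract_centerline()] result for the same mask.
#' @param end_trim_mm arc length removed from each end before measuring.
#' @param angular_step_deg angular resolution of the chord search.
#' @param step_mm marching step along each ray.
#' @return list with `max_diameter_cm` and `diameter_profile`, a data.frame
#'   of (`arc_position_mm`, `diameter_cm`).
#' @export
measure_max_diameter <- function(mask, cl, end_trim_mm = 10.0,
                                 angular_step_deg = 1.0, step_mm = 0.25) {
  if (cl$arc_length_mm <= 2 * end_trim_mm)
    stop("degenerate input: centerline shorter than twice the end trim")
  n <- nrow(cl$points_mm)
  s <- seq(0, cl$arc_length_mm, length.out = n)
  keep <- which(s >= end_trim_mm & s <= cl$arc_length_mm - end_trim_mm)
  if (!length(keep))
    stop("degenerate input: no centerline samples after end trimming")
  max_mm <- sqrt(sum((dim(mask$values) * mask$spacing_mm)^2)) / 2 + 1
  theta <- seq(0, 180 - angular_step_deg, by = angular_step_deg) * pi / 180
  diam <- numeric(length(keep))
  for (i in seq_along(keep)) {
    k <- keep[i]
    b <- orthonormal_basis(cl$tangents[k, ])
    dirs <- cos(theta) %o% b$u + sin(theta) %o% b$v
    fwd <- ray_extent(mask$values, mask$spacing_mm, mask$origin_mm,
                      cl$points_mm[k, ], dirs, step_mm, max_mm)
    bwd <- ray_extent(mask$values, mask$spacing_mm, mask$origin_mm,
                      cl$points_mm[k, ], -dirs, step_mm, max_mm)
    diam[i] <- max(fwd + bwd)
  }
  profile <- data.frame(arc_position_mm = s[keep], diameter_cm = diam / 10)
  list(max_diameter_cm = max(profile$diameter_cm), diameter_profile = profile)
}

#' Segmentation volume in millilitres
#'
#' Foreground voxel count times the voxel volume.
#'
#' @param mask a non-empty [seg_mask()].
#' @return volume in ml.
#' @export
compute_volume <- function(mask) {
  n <- sum(mask$values)
  if (n == 0L) stop("mask is empty")
  n * voxel_volume_mm3(mask) / 1000
}

# Separable Gaussian smoothing with sigma given in mm, converted per axis to
# voxel units. Truncated at 4 sigma; rows renormalized (edge replication).
gaussian_smooth_mm <- function(values, spacing_mm, sigma_mm) {
  A <- values
  for (axis in 1:3) {
    sv <- sigma_mm / spacing_mm[axis]
    h <- max(1L, ceiling(4 * sv))
    k <- exp(-(seq(-h, h))^2 / (2 * sv^2))
    n <- dim(A)[axis]
    K <- matrix(0, n, n)
    for (o in seq(-h, h)) {
      j <- seq_len(n) + o
      ok <- j >= 1 & j <= n
      K[cbind(which(ok), j[ok])] <- k[o + h + 1]
    }
    K <- K / rowSums(K)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    B <- aperm(A, perm)
    db <- dim(B)
    B <- K %*% matrix(B, db[1])
    dim(B) <- db
    A <- aperm(B, order(perm))
  }
  A
}

#' Aortic calcification burden
#'
#' The full HU volume is smoothed with an isotropic-in-mm Gaussian kernel of
#' the given full width at half maximum (to suppress noise-driven
#' threshold crossings), then voxels inside the mask with smoothed
#' attenuation at or above `threshold_hu` are counted and converted to mm^3.
#'
#' @param vol an [image_volume()] in HU.
#' @param mask the aligned [seg_mask()].
#' @param fwhm_mm Gaussian full width at half maximum in mm (default 3).
#' @param threshold_hu calcification threshold in HU (default 130,
#'   inclusive).
#' @return calcified volume in mm^3.
#' @export
quantify_calcium <- function(vol, mask, fwhm_mm = 3.0, threshold_hu = 130) {
  check_aligned(vol, mask)
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0)
    stop("`fwhm_mm` must be a positive scalar")
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  sm <- gaussian_smooth_mm(vol$values, vol$spacing_mm, sigma_mm)
  sum(sm >= threshold_hu & mask$values != 0) * voxel_volume_mm3(vol)
}

#' Assemble the aortic feature set for one subject
#'
#' Runs centerline extraction, diameter measurement, volume and calcium
#' quantification on an aligned volume/mask pair, then applies the
#' plausibility filter.
#'
#' @param vol an [image_volume()].
#' @param mask the aligned [seg_mask()].
#' @param resample resample the pair to `target_spacing_mm` first.
#' @param target_spacing_mm working resolution (default 1.5 x 1.5 x 3 mm).
#' @param fwhm_mm,threshold_hu passed to [quantify_calcium()].
#' @param end_trim_mm,angular_step_deg passed to [measure_max_diameter()].
#' @return an `aortic_features` object: `max_diameter_cm`, `volume_ml`,
#'   `calcium_mm3`, `diameter_profile`, `qc_pass`, `qc_reasons`.
#' @export
measure_aorta <- function(vol, mask, resample = TRUE,
                          target_spacing_mm = c(1.5, 1.5, 3.0),
                          fwhm_mm = 3.0, threshold_hu = 130,
                          end_trim_mm = 10.0, angular_step_deg = 1.0) {
  if (resample) {
    rs <- resample_volume(vol, mask, target_spacing_mm)
    vol <- rs$volume; mask <- rs$mask
  }
  cl <- extract_centerline(mask)
  dm <- measure_max_diameter(mask, cl, end_trim_mm = end_trim_mm,
                             angular_step_deg = angular_step_deg)
  feats <- structure(list(max_diameter_cm = dm$max_diameter_cm,
                          volume_ml = compute_volume(mask),
                          calcium_mm3 = quantify_calcium(vol, mask, fwhm_mm,
                                                         threshold_hu),
                          diameter_profile = dm$diameter_profile,
                          qc_pass = NA, qc_reasons = character(0)),
                     class = "aortic_features")
  qc_plausibility(feats)
}

#' Plausibility quality control of aortic features
#'
#' Measurements with a maximum diameter below 2.0 cm or a volume below 70 ml
#' are flagged as implausible (strict `<` comparisons); non-finite features
#' also fail.
#'
#' @param features an `aortic_features` object, or any list with
#'   `max_diameter_cm` and `volume_ml`.
#' @param diameter_min_cm,volume_min_ml exclusion thresholds.
#' @return the feature set with `qc_pass` and `qc_reasons` set.
#' @export
qc_plausibility <- function(features, diameter_min_cm = 2.0, volume_min_ml = 70) {
  reasons <- character(0)
  d <- features$max_diameter_cm; v <- features$volume_ml
  if (!is.finite(d) || !is.finite(v)) {
    reasons <- c(reasons, "non_finite")
  } else {
    if (d < diameter_min_cm) reasons <- c(reasons, "diameter_below_minimum")
    if (v < volume_min_ml) reasons <- c(reasons, "volume_below_minimum")
  }
  features$qc_pass <- length(reasons) == 0L
  features$qc_reasons <- reasons
  features
}

#' @export
print.aortic_features <- function(x, ...) {
  cat(sprintf(paste0("<aortic_features> max diameter %.2f cm, volume %.1f ml, ",
                     "calcium %.0f mm^3, QC %s\n"),
              x$max_diameter_cm, x$volume_ml, x$calcium_mm3,
              if (isTRUE(x$qc_pass)) "pass" else
                paste("fail:", paste(x$qc_reasons, collapse = ","))))
  invisible(x)
}

#' Serialize an aortic feature set to JSON
#' @param features an `aortic_features` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_features_json <- function(features, path) {
  out <- unclass(features)
  out$diameter_profile <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
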