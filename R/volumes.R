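#' Construct an image volume
#'
#' A 3D scalar grid of CT attenuation values (Hounsfield units) with per-axis
#' voxel spacing in millimetres. Voxel centers follow the voxel-center
#' convention: the physical position of voxel index `(i, j, k)` (1-based) is
#' `origin_mm + (c(i, j, k) - 1) * spacing_mm`. Axis-aligned orientation is
#' assumed.
#'
#' @param values numeric 3D array of HU values.
#' @param spacing_mm positive numeric triple, voxel edge lengths in mm.
#' @param origin_mm numeric triple, physical position of the first voxel
#'   center in mm.
#' @return an object of class `image_volume` with fields `values`,
#'   `spacing_mm`, `origin_mm`.
#' @export
image_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be a strictly positive triple")
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L) stop("`origin_mm` must be a triple")
  structure(list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "image_volume")
}

#' Construct a segmentation mask
#'
#' A binary grid aligned voxel-for-voxel with an [image_volume()]. Values are
#' stored as integer 0/1.
#'
#' @param values 3D array coercible to 0/1 (logical or numeric).
#' @inheritParams image_volume
#' @return an object of class `seg_mask`.
#' @export
seg_mask <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  v <- array(as.integer(values != 0), dim = dim(values))
  obj <- image_volume(v, spacing_mm, origin_mm)
  class(obj) <- "seg_mask"
  obj
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %s voxels, spacing %s mm, %d foreground\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              sum(x$values)))
  invisible(x)
}

#' Voxel volume in cubic millimetres
#' @param x an `image_volume` or `seg_mask`.
#' @return scalar, product of the spacings.
#' @export
voxel_volume_mm3 <- function(x) prod(x$spacing_mm)

check_aligned <- function(vol, mask) {
  if (!identical(dim(vol$values), dim(mask$values)))
    stop("volume and mask shapes differ")
  if (max(abs(vol$spacing_mm - mask$spacing_mm)) > 1e-6)
    stop("volume and mask spacings differ")
  if (max(abs(vol$origin_mm - mask$origin_mm)) > 1e-6)
    stop("volume and mask origins differ")
  invisible(TRUE)
}

world_from_index <- function(idx, spacing_mm, origin_mm) {
  sweep(sweep(idx - 1, 2, spacing_mm, "*"), 2, origin_mm, "+")
}

index_from_world <- function(pts, spacing_mm, origin_mm) {
  sweep(sweep(pts, 2, origin_mm, "-"), 2, spacing_mm, "/") + 1
}

#' Read a NIfTI volume as an image_volume
#'
#' Spacing is taken from the NIfTI pixdim; the origin is set to zero (the
#' pipeline only requires internally consistent coordinates for aligned
#' volume/mask pairs).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param mask if `TRUE`, binarize at 0.5 and return a [seg_mask()].
#' @return an `image_volume` or `seg_mask`.
#' @export
read_volume_nifti <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  arr <- array(as.numeric(img), dim = dim(img)[seq_len(3)])
  if (mask) seg_mask(arr >= 0.5, sp) else image_volume(arr, sp)
}

#' Write an image_volume or seg_mask to NIfTI
#'
#' @param x an `image_volume` or `seg_mask`.
#' @param path output path (`.nii.gz` recommended).
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(x, path) {
  img <- RNifti::asNifti(x$values)
  RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Trilinear interpolation on a 3D array
#'
#' @param arr numeric 3D array.
#' @param idx n x 3 matrix of fractional 1-based voxel indices.
#' @param fill value for sample points outside the grid; use `"clamp"` to
#'   replicate edge values instead.
#' @return numeric vector of length `nrow(idx)`.
#' @keywords internal
trilinear_interp <- function(arr, idx, fill = 0) {
  d <- dim(arr)
  n <- nrow(idx)
  clamp_mode <- identical(fill, "clamp")
  if (clamp_mode) {
    for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 1), d[a])
    keep <- rep(TRUE, n)
    out <- numeric(n)
  } else {
    keep <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
            idx[, 2] >= 1 & idx[, 2] <= d[2] &
            idx[, 3] >= 1 & idx[, 3] <= d[3]
    out <- rep(as.numeric(fill), n)
  }
  if (!any(keep)) return(out)
  ii <- idx[keep, , drop = FALSE]
  i0 <- floor(ii)
  for (a in 1:3) i0[, a] <- pmin(i0[, a], d[a] - 1)  # upper-edge samples
  fr <- ii - i0
  x0 <- i0[, 1]; y0 <- i0[, 2]; z0 <- i0[, 3]
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  g <- function(dx, dy, dz) arr[cbind(x0 + dx, y0 + dy, z0 + dz)]
  v <- g(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
       g(1, 0, 0) * fx       * (1 - fy) * (1 - fz) +
       g(0, 1, 0) * (1 - fx) * fy       * (1 - fz) +
       g(1, 1, 0) * fx       * fy       * (1 - fz) +
       g(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
       g(1, 0, 1) * fx       * (1 - fy) * fz +
       g(0, 1, 1) * (1 - fx) * fy       * fz +
       g(1, 1, 1) * fx       * fy       * fz
  out[keep] <- v
  out
}

#' Resample a volume/mask pair to a target voxel spacing
#'
#' HU values are resampled with trilinear interpolation; the mask is resampled
#' by trilinear interpolation of its 0/1 values followed by thresholding at
#' 0.5. The default target matches the working resolution used for all
#' downstream feature measurements (1.5 x 1.5 x 3 mm).
#'
#' @param vol an [image_volume()].
#' @param mask the aligned [seg_mask()].
#' @param target_spacing_mm numeric triple, output spacing in mm.
#' @return list with elements `volume` and `mask` at the target spacing.
#' @export
resample_volume <- function(vol, mask, target_spacing_mm = c(1.5, 1.5, 3.0)) {
  check_aligned(vol, mask)
  target_spacing_mm <- as.numeric(target_spacing_mm)
  if (length(target_spacing_mm) != 3L || any(target_spacing_mm <= 0))
    stop("`target_spacing_mm` must be a positive triple")
  if (max(abs(vol$spacing_mm - target_spacing_mm)) < 1e-9)
    return(list(volume = vol, mask = mask))
  d_in <- dim(vol$values)
  d_out <- pmax(2L, as.integer(ceiling(d_in * vol$spacing_mm / target_spacing_mm)))
  grid <- as.matrix(expand.grid(x = seq_len(d_out[1]), y = seq_len(d_out[2]),
                                z = seq_len(d_out[3])))
  pts <- world_from_index(grid, target_spacing_mm, vol$origin_mm)
  idx <- index_from_world(pts, vol$spacing_mm, vol$origin_mm)
  hu <- trilinear_interp(vol$values, idx, fill = "clamp")
  mk <- trilinear_interp(mask$values + 0, idx, fill = 0)
  vol_out <- image_volume(array(hu, d_out), target_spacing_mm, vol$origin_mm)
  mask_out <- seg_mask(array(mk >= 0.5, d_out), target_spacing_mm, vol$origin_mm)
  if (sum(mask_out$values) == 0L)
    stop("degenerate input: mask is empty after resampling")
  list(volume = vol_out, mask = mask_out)
}
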