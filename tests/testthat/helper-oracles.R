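# Shared fixtures and independent oracles used across the suite.

# Small default phantoms (kept small so the suite stays fast).
small_cylinder <- function(r = 12, L = 60, spacing = c(1.5, 1.5, 3),
                           calcifications = list(), noise = 0, seed = 1L) {
  generate_phantom(phantom_spec("straight_cylinder", lumen_radius_mm = r,
                                segment_length_mm = L,
                                voxel_spacing_mm = spacing,
                                calcifications = calcifications,
                                noise_sd_hu = noise, seed = seed))
}

# O(n^2) brute-force Harrell c-index for continuous (tie-free) times.
brute_force_cindex <- function(time, status, score) {
  n <- length(time)
  conc <- 0; tied <- 0; usable <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) next
    a <- if (time[i] < time[j]) i else j
    b <- if (time[i] < time[j]) j else i
    if (status[a] != 1) next          # ordering not determinable
    usable <- usable + 1
    if (score[a] > score[b]) conc <- conc + 1
    else if (score[a] == score[b]) tied <- tied + 1
  }
  (conc + 0.5 * tied) / usable
}

# Independent fine-grid Gaussian smoothing oracle: separable direct
# convolution with stats::filter (edge replication), axis by axis.
filter_smooth_oracle <- function(arr, spacing, fwhm_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    sv <- sigma / spacing[ax]
    h <- ceiling(4 * sv)
    k <- stats::dnorm(seq(-h, h), sd = sv)
    k <- k / sum(k)
    A <- aperm(arr, c(ax, setdiff(1:3, ax)))
    da <- dim(A)
    M <- matrix(A, da[1])
    Mp <- rbind(matrix(rep(M[1, ], each = h), h), M,
                matrix(rep(M[nrow(M), ], each = h), h))
    Fm <- stats::filter(Mp, k, sides = 2)[(h + 1):(h + da[1]), , drop = FALSE]
    A <- array(Fm, da)
    arr <- aperm(A, order(c(ax, setdiff(1:3, ax))))
  }
  arr
}

# Symmetric Hausdorff distance between two point sets (rows).
hausdorff_mm <- function(A, B) {
  d2 <- function(P, Q) max(apply(P, 1, function(p)
    min(sqrt(colSums((t(Q) - p)^2)))))
  max(d2(A, B), d2(B, A))
}
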