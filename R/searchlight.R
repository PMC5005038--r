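# Volumetric searchlight mapping of condition contrasts.

#' Searchlight sphere specification
#'
#' @param diameter Sphere diameter in voxels (odd; default 7).
#' @param min_voxels Minimum gray-matter voxels a sphere must contain to be
#'   analyzed; the default 31 implements "more than 30".
#' @return A `sphere_spec` list.
#' @export
sphere_spec <- function(diameter = 7L, min_voxels = 31L) {
  diameter <- as.integer(diameter)
  if (diameter < 1L || diameter %% 2L == 0L) {
    abort("`diameter` must be a positive odd integer.")
  }
  if (min_voxels < 2L) abort("`min_voxels` must be >= 2.")
  list(diameter = diameter, min_voxels = as.integer(min_voxels))
}

#' Integer voxel offsets of a searchlight sphere
#'
#' All integer offsets with Euclidean norm at most `(diameter - 1) / 2`,
#' including the centre: 1 for diameter 1, 7 for diameter 3, 123 for the
#' default diameter 7.
#'
#' @param spec A [sphere_spec()].
#' @return An integer matrix with one offset per row (columns x, y, z).
#' @export
sphere_offsets <- function(spec = sphere_spec()) {
  r <- (spec$diameter - 1L) / 2
  g <- seq(-r, r)
  off <- as.matrix(expand.grid(x = g, y = g, z = g))
  off[rowSums(off^2) <= r^2 + 1e-9, , drop = FALSE]
}

#' Run a searchlight contrast map
#'
#' Slides a sphere over every voxel of the volume; for each centre, the
#' sphere is restricted to gray-matter voxels and skipped unless it contains
#' more than `min_voxels - 1` of them; otherwise the condition contrast is
#' computed from the pairwise pattern correlations across the sphere's voxels
#' and written to the map. Undefined voxels hold `NA`.
#'
#' @param pattern_volume 4-D array (x, y, z, trial) of per-trial patterns.
#' @param graymask Logical 3-D gray-matter mask with matching geometry.
#' @param labels Pair labels from [label_pairs()] for the trial dimension.
#' @param scheme,exclude Contrast scheme and pair exclusions.
#' @param sphere A [sphere_spec()].
#' @return A `searchlight_map`: the 3-D contrast array plus the parameters.
#' @export
run_searchlight <- function(pattern_volume, graymask, labels,
                            scheme = "mod60", exclude = character(),
                            sphere = sphere_spec()) {
  d <- dim(pattern_volume)
  if (length(d) != 4L) abort("`pattern_volume` must be 4-D (x, y, z, trial).")
  if (!identical(dim(graymask), d[1:3])) {
    abort("geometry mismatch between `pattern_volume` and `graymask`.")
  }
  nt <- d[4]
  if (max(labels$j) != nt) abort("`labels` do not match the trial dimension.")
  mem <- condition_membership(labels, scheme)
  keep <- filter_pairs(labels, exclude)
  pair_lin <- labels$i + (labels$j - 1L) * nt # upper-tri linear indices
  a_idx <- pair_lin[mem$a & keep]
  b_idx <- pair_lin[mem$b & keep]
  off <- sphere_offsets(sphere)
  P <- matrix(pattern_volume, prod(d[1:3]), nt)
  gray_lin <- array(FALSE, d[1:3]); gray_lin[graymask] <- TRUE
  out <- array(NA_real_, d[1:3])
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  for (cz in seq_len(nz)) {
    for (cy in seq_len(ny)) {
      for (cx in seq_len(nx)) {
        vx <- cx + off[, 1]; vy <- cy + off[, 2]; vz <- cz + off[, 3]
        ok <- vx >= 1 & vx <= nx & vy >= 1 & vy <= ny & vz >= 1 & vz <= nz
        lin <- vx[ok] + (vy[ok] - 1L) * nx + (vz[ok] - 1L) * nx * ny
        lin <- lin[gray_lin[lin]]
        if (length(lin) < sphere$min_voxels) next
        cmat <- suppressWarnings(cor(P[lin, , drop = FALSE]))
        z <- fisher_z(cmat)
        za <- z[a_idx]; zb <- z[b_idx]
        za <- za[!is.na(za)]; zb <- zb[!is.na(zb)]
        if (!length(za) || !length(zb)) next
        out[cx, cy, cz] <- mean(za) - mean(zb)
      }
    }
  }
  structure(list(map = out, scheme = scheme, exclude = exclude,
                 sphere = sphere),
            class = "searchlight_map")
}

#' @export
print.searchlight_map <- function(x, ...) {
  cat(sprintf("<searchlight_map> %s, %d defined voxels of %d\n",
              x$scheme, sum(!is.na(x$map)), length(x$map)))
  invisible(x)
}

# 1-D Gaussian kernel for a given sigma in voxels.
gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Convolve a 3-D array along one dimension with zero padding.
conv_dim <- function(arr, kernel, dim_idx) {
  perm <- switch(dim_idx, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- matrix(a, d[1], d[2] * d[3])
  r <- (length(kernel) - 1L) / 2
  padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
  sm <- apply(padded, 2L, function(col) {
    stats::convolve(col, rev(kernel), type = "open")[(2 * r + 1):(2 * r + d[1])]
  })
  aperm(array(sm, d), order(perm))
}

#' Smooth a searchlight map
#'
#' Gaussian smoothing with `sigma = fwhm / (2 * sqrt(2 * log(2)))` (in mm,
#' converted to voxels), as normalized convolution: undefined (`NA`) voxels
#' are excluded from every kernel and the weights renormalized, so defined
#' values are never diluted by missing neighbours. `fwhm_mm = 0` is the
#' identity.
#'
#' @param x A `searchlight_map` or 3-D array.
#' @param fwhm_mm Full width at half maximum in mm (default 4).
#' @param voxel_mm Isotropic voxel size in mm (default 2).
#' @return The smoothed object, same class and shape as the input.
#' @export
smooth_map <- function(x, fwhm_mm = 4, voxel_mm = 2) {
  if (fwhm_mm < 0) abort("`fwhm_mm` must be non-negative.")
  arr <- if (inherits(x, "searchlight_map")) x$map else x
  if (fwhm_mm > 0) {
    sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
    k <- gauss_kernel(sigma_vox)
    valid <- !is.na(arr)
    filled <- ifelse(valid, arr, 0)
    w <- valid * 1
    for (dd in 1:3) {
      filled <- conv_dim(filled, k, dd)
      w <- conv_dim(w, k, dd)
    }
    sm <- filled / w
    sm[!valid] <- NA_real_
    arr <- sm
  }
  if (inherits(x, "searchlight_map")) {
    x$map <- arr
    x
  } else {
    arr
  }
}
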