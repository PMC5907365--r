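#' Dendritic density profile of a group of co-registered morphologies
#'
#' Discretizes space into voxels aligned with the origin-centered
#' convention used for registration, marks for each morphology every voxel
#' containing at least one of its points (after resampling edges to at
#' most `resample_spacing`), optionally smooths each binary volume with a
#' unity-sum 3-D discrete Gaussian kernel (sigma `kernel_std` um,
#' truncated at 3 sigma and renormalized to sum exactly 1), and averages
#' the per-morphology volumes. Voxel values are therefore the (smoothed)
#' fraction of morphologies occupying each voxel and lie in [0, 1].
#'
#' @param morphologies list of [morphology()] objects.
#' @param voxel_size voxel edge length in um (default 0.25).
#' @param resample_spacing maximum distance between connected samples in
#'   um (default 0.1).
#' @param kernel_std Gaussian smoothing sigma in um; 0 disables smoothing.
#'   Chosen per group of morphologies.
#' @return A `density_profile`: list with `values` (3-D array), `origin`
#'   (um coordinates of the voxel center at array index [1,1,1]),
#'   `voxel_size`, `kernel_std`.
#' @export
density_profile <- function(morphologies, voxel_size = 0.25,
                            resample_spacing = 0.1, kernel_std = 0) {
  if (!is.list(morphologies) || length(morphologies) == 0 ||
      !all(vapply(morphologies, inherits, logical(1), "morphology")))
    stop("density_profile: need a non-empty list of morphologies")
  stopifnot(voxel_size > 0, resample_spacing > 0, kernel_std >= 0)

  idx_list <- lapply(morphologies, function(m) {
    pts <- morph_point_cloud(m, resample_spacing)
    unique(voxel_index(pts, voxel_size))
  })
  all_idx <- do.call(rbind, idx_list)
  pad <- ceiling(3 * kernel_std / voxel_size)
  lo <- apply(all_idx, 2, min) - pad
  hi <- apply(all_idx, 2, max) + pad
  dims <- hi - lo + 1

  kern <- gaussian_kernel_1d(kernel_std / voxel_size)
  acc <- array(0, dims)
  for (idx in idx_list) {
    vol <- array(0, dims)
    vol[cbind(idx[, 1] - lo[1] + 1, idx[, 2] - lo[2] + 1,
              idx[, 3] - lo[3] + 1)] <- 1
    acc <- acc + smooth_volume(vol, kern)
  }
  structure(list(values = acc / length(idx_list),
                 origin = lo * voxel_size,
                 voxel_size = voxel_size,
                 kernel_std = kernel_std),
            class = "density_profile")
}

# unity-sum 1-D Gaussian kernel with sigma in voxels, truncated at 3 sigma
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- ceiling(3 * sigma_vox)
  w <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  w / sum(w)
}

# separable 3-D convolution with zero boundary; each 1-D kernel sums to 1,
# so the product kernel has unity sum and interior mass is conserved
smooth_volume <- function(vol, kern) {
  if (length(kern) == 1) return(vol)
  conv_axis <- function(a, axis) {
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    mat <- matrix(ap, nrow = d[axis])
    n <- nrow(mat)
    r <- (length(kern) - 1) / 2
    out <- matrix(0, n, ncol(mat))
    for (k in seq_along(kern)) {
      off <- k - r - 1
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + kern[k] * mat[src[ok], , drop = FALSE]
    }
    aperm(array(out, d[perm]), order(perm))
  }
  conv_axis(conv_axis(conv_axis(vol, 1), 2), 3)
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density_profile: %s voxels of %.3g um, kernel sigma %.3g um\n",
              paste(dim(x$values), collapse = " x "),
              x$voxel_size, x$kernel_std))
  invisible(x)
}

#' Maximal projection of a density profile
#'
#' Elementwise maximum of the density values along one axis, giving a 2-D
#' image of the strongest occupancy seen along that direction.
#'
#' @param profile a [density_profile()].
#' @param axis axis to project along: 1 (x), 2 (y) or 3 (z).
#' @return A 2-D matrix of values in [0, 1].
#' @export
max_projection <- function(profile, axis) {
  stopifnot(inherits(profile, "density_profile"))
  if (!axis %in% 1:3) stop("max_projection: axis must be 1, 2 or 3")
  apply(profile$values, setdiff(1:3, axis), max)
}
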