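#' Voxel volume representations and spatial dissimilarity measures
#'
#' Space is discretized into cubic voxels of edge length `voxel_size` with
#' one voxel centered at the origin: voxel index i along an axis covers the
#' half-open interval [i*v - v/2, i*v + v/2). A morphology's volume is the
#' set of voxels containing at least one point of the morphology, where
#' "points" are the SWC nodes plus edge samples spaced at most
#' `voxel_size / 2` apart (so straight cable occupies every traversed
#' voxel). Radii are ignored: this is a centerline volume model.
#'
#' @name voxel_set
NULL

# round-half-up voxel index
voxel_index <- function(coord, voxel_size) {
  floor(coord / voxel_size + 0.5)
}

# encode integer index triples as one double each; exact for |idx| < 2^15
.VKEY_B <- 32768
.VKEY_M <- 65537
voxel_keys <- function(idx) {
  if (any(abs(idx) >= .VKEY_B)) stop("voxel index out of encodable range")
  (idx[, 1] + .VKEY_B) + .VKEY_M * ((idx[, 2] + .VKEY_B) +
                                    .VKEY_M * (idx[, 3] + .VKEY_B))
}

voxel_unkey <- function(keys) {
  k1 <- keys %% .VKEY_M
  r <- (keys - k1) / .VKEY_M
  k2 <- r %% .VKEY_M
  k3 <- (r - k2) / .VKEY_M
  cbind(k1 - .VKEY_B, k2 - .VKEY_B, k3 - .VKEY_B)
}

new_voxel_set <- function(keys, voxel_size) {
  structure(list(voxel_size = voxel_size, keys = keys),
            class = "voxel_set")
}

# fast internal path: unique voxel keys of an Nx3 coordinate matrix
points_to_keys <- function(xyz, voxel_size) {
  unique(voxel_keys(voxel_index(xyz, voxel_size)))
}

#' Voxelize a morphology
#'
#' @param m a [morphology()].
#' @param voxel_size voxel edge length in um (> 0).
#' @return A `voxel_set`: the set of integer voxel indices occupied by the
#'   morphology, with its voxel size.
#' @export
voxelize <- function(m, voxel_size) {
  stopifnot(inherits(m, "morphology"))
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("voxelize: voxel_size must be a positive number")
  pts <- morph_point_cloud(m, voxel_size / 2)
  new_voxel_set(points_to_keys(pts, voxel_size), voxel_size)
}

#' Indices of a voxel set
#'
#' @param vs a `voxel_set`.
#' @return Integer matrix with one (i, j, k) row per occupied voxel.
#' @export
voxel_indices <- function(vs) {
  stopifnot(inherits(vs, "voxel_set"))
  idx <- voxel_unkey(vs$keys)
  colnames(idx) <- c("i", "j", "k")
  idx
}

#' @export
print.voxel_set <- function(x, ...) {
  cat(sprintf("voxel_set: %d voxels of edge %.6g um\n",
              length(x$keys), x$voxel_size))
  invisible(x)
}

#' @export
length.voxel_set <- function(x) length(x$keys)

# centroid of occupied voxel centers, in um
voxel_set_centroid <- function(vs) {
  colMeans(voxel_unkey(vs$keys)) * vs$voxel_size
}

# intersection / union counts for two key vectors (already unique)
.overlap_counts <- function(ka, kb) {
  ninter <- sum(!is.na(match(ka, kb)))
  c(inter = ninter, union = length(ka) + length(kb) - ninter)
}

#' Pairwise spatial dissimilarity of two voxel sets
#'
#' `D = 1 - n(A intersect B) / n(A union B)`, i.e. one minus the Jaccard
#' overlap of the two voxel sets. This is the "non-centric" measure, used
#' when estimating translation and rotation differences.
#'
#' @param a,b `voxel_set` objects with equal voxel sizes.
#' @return A number in [0, 1]; 0 iff the sets are equal, 1 iff disjoint.
#' @export
dissimilarity <- function(a, b) {
  stopifnot(inherits(a, "voxel_set"), inherits(b, "voxel_set"))
  if (!isTRUE(all.equal(a$voxel_size, b$voxel_size)))
    stop("dissimilarity: voxel sizes differ")
  if (length(a$keys) + length(b$keys) == 0)
    stop("dissimilarity: both voxel sets are empty")
  cnt <- .overlap_counts(a$keys, b$keys)
  1 - cnt[["inter"]] / cnt[["union"]]
}

#' Centric spatial dissimilarity
#'
#' Translates the test morphology (in continuous space) so that the
#' centroid of its occupied voxel centers coincides with that of the
#' reference voxel set, re-voxelizes, and computes [dissimilarity()].
#' Because the translation removal happens first, this measure is
#' insensitive to pure translation differences; it is used when estimating
#' scaling differences.
#'
#' @param test a [morphology()].
#' @param reference a `voxel_set`.
#' @param voxel_size voxel edge length in um; must equal the reference's.
#' @return A number in [0, 1].
#' @export
centric_dissimilarity <- function(test, reference, voxel_size = reference$voxel_size) {
  stopifnot(inherits(test, "morphology"), inherits(reference, "voxel_set"))
  if (!isTRUE(all.equal(voxel_size, reference$voxel_size)))
    stop("centric_dissimilarity: voxel sizes differ")
  tv <- voxelize(test, voxel_size)
  shift <- voxel_set_centroid(reference) - voxel_set_centroid(tv)
  pts <- morph_point_cloud(test, voxel_size / 2)
  pts <- sweep(pts, 2, shift, "+")
  shifted <- new_voxel_set(points_to_keys(pts, voxel_size), voxel_size)
  dissimilarity(shifted, reference)
}

#' Occupancy histogram of a group of voxel sets
#'
#' The occupancy of a voxel is the number of group members occupying it.
#' The histogram counts voxels per occupancy value k in 1..N (zero
#' occupancy excluded); the weighted histogram multiplies each count by k;
#' the normalized histogram divides the weighted histogram by its sum.
#'
#' @param sets a list of `voxel_set` objects with equal voxel sizes.
#' @return An `occupancy_histogram`: data.frame with columns `occupancy`,
#'   `count`, `weighted`, `normalized` and attribute `group_size`.
#' @export
occupancy_histogram <- function(sets) {
  if (!is.list(sets) || length(sets) == 0 ||
      !all(vapply(sets, inherits, logical(1), "voxel_set")))
    stop("occupancy_histogram: need a non-empty list of voxel_set objects")
  vsz <- vapply(sets, function(s) s$voxel_size, numeric(1))
  if (diff(range(vsz)) > 1e-12 * vsz[1])
    stop("occupancy_histogram: voxel sizes differ")
  n <- length(sets)
  occ <- table(unlist(lapply(sets, function(s) s$keys)))
  tab <- table(factor(as.integer(occ), levels = seq_len(n)))
  counts <- as.integer(tab)
  k <- seq_len(n)
  weighted <- counts * k
  total <- sum(weighted)
  normalized <- if (total > 0) weighted / total else weighted
  out <- data.frame(occupancy = k, count = counts, weighted = weighted,
                    normalized = normalized)
  attr(out, "group_size") <- n
  class(out) <- c("occupancy_histogram", "data.frame")
  out
}

#' Group spatial dissimilarity (Earth-Mover-Distance)
#'
#' The distance between the group's normalized occupancy histogram and the
#' histogram of perfect overlap (all mass at occupancy N), quantified by
#' the 1-D Earth-Mover-Distance with ground distance |i - j| between
#' occupancy values. In closed form this is `sum_k p_k * (N - k)`. A
#' perfectly co-registered group scores 0.
#'
#' @param hist an [occupancy_histogram()].
#' @param normalized if `TRUE`, divide by `N - 1` so the score of fully
#'   disjoint sets is 1 regardless of group size (default `FALSE`: raw
#'   occupancy units).
#' @return A non-negative number.
#' @export
group_dissimilarity <- function(hist, normalized = FALSE) {
  stopifnot(inherits(hist, "occupancy_histogram"))
  n <- attr(hist, "group_size")
  emd <- sum(hist$normalized * (n - hist$occupancy))
  if (normalized && n > 1) emd <- emd / (n - 1)
  emd
}

#' Export a voxel set as a CSV of indices
#'
#' Writes the sorted (i, j, k) integer indices, one voxel per row.
#'
#' @param vs a `voxel_set`.
#' @param path output CSV path.
#' @export
write_voxel_csv <- function(vs, path) {
  idx <- voxel_indices(vs)
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
  utils::write.csv(as.data.frame(idx), path, row.names = FALSE)
  invisible(path)
}

#' Export an occupancy histogram as CSV
#'
#' @param hist an [occupancy_histogram()].
#' @param path output CSV path.
#' @export
write_histogram_csv <- function(hist, path) {
  utils::write.csv(as.data.frame(hist), path, row.names = FALSE)
  invisible(path)
}
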