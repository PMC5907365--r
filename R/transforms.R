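#' Affine transforms for morphology registration
#'
#' An `affine_transform` is parameterized by per-axis rotation angles
#' (degrees, applied extrinsically about x, then y, then z, i.e.
#' `R = Rz %*% Ry %*% Rx`), strictly positive per-axis scale factors,
#' a translation (um) and a center (um). Points are mapped as
#' `x' = R (S (x - center)) + center + translation`.
#'
#' Reflections are excluded by construction: scales are positive, so the
#' linear part always has positive determinant.
#'
#' @param angles_deg numeric(3), rotation about x, y, z in degrees.
#' @param scales numeric(3), per-axis scale factors, all > 0.
#' @param translation numeric(3), translation in um.
#' @param center numeric(3), fixed point about which rotation and scaling
#'   are applied, in um.
#' @return An object of class `affine_transform`.
#' @examples
#' t1 <- affine_transform(angles_deg = c(0, 0, 90), translation = c(1, 0, 0))
#' as.matrix(t1)
#' @export
affine_transform <- function(angles_deg = c(0, 0, 0), scales = c(1, 1, 1),
                             translation = c(0, 0, 0), center = c(0, 0, 0)) {
  angles_deg <- as.numeric(angles_deg)
  scales <- as.numeric(scales)
  translation <- as.numeric(translation)
  center <- as.numeric(center)
  stopifnot(length(angles_deg) == 3, length(scales) == 3,
            length(translation) == 3, length(center) == 3)
  if (!all(is.finite(c(angles_deg, scales, translation, center))))
    stop("affine_transform: all parameters must be finite")
  if (any(scales <= 0))
    stop("affine_transform: scales must be strictly positive (no reflections)")
  structure(list(angles_deg = angles_deg, scales = scales,
                 translation = translation, center = center),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("affine_transform\n")
  cat("  rotation (deg, about x,y,z):", format(x$angles_deg, digits = 6), "\n")
  cat("  scales               :", format(x$scales, digits = 6), "\n")
  cat("  translation (um)     :", format(x$translation, digits = 6), "\n")
  cat("  center (um)          :", format(x$center, digits = 6), "\n")
  invisible(x)
}

# 3x3 rotation matrix from extrinsic x,y,z angles in degrees: R = Rz Ry Rx
rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rz %*% ry %*% rx
}

#' Convert an affine transform to a 4x4 homogeneous matrix
#'
#' @param x an `affine_transform`.
#' @param ... unused.
#' @return A 4x4 homogeneous matrix `M` such that applying `x` to a point
#'   `p` equals `(M %*% c(p, 1))[1:3]`.
#' @export
as.matrix.affine_transform <- function(x, ...) {
  r <- rotation_matrix(x$angles_deg)
  a <- r %*% diag(x$scales)              # linear part R S
  # x' = A (p - c) + c + t  =  A p + (c + t - A c)
  offset <- x$center + x$translation - a %*% x$center
  m <- diag(4)
  m[1:3, 1:3] <- a
  m[1:3, 4] <- offset
  m
}

# coerce affine_transform or 4x4 matrix to 4x4 matrix
transform_matrix <- function(t) {
  if (inherits(t, "affine_transform")) return(as.matrix(t))
  if (is.matrix(t) && all(dim(t) == c(4, 4))) return(t)
  stop("expected an affine_transform or a 4x4 homogeneous matrix")
}

#' Compose two transforms
#'
#' Returns the 4x4 homogeneous matrix of the map "apply `inner`, then
#' `outer`". Arguments may be `affine_transform` objects or 4x4 matrices.
#'
#' @param outer,inner transforms (objects or 4x4 matrices).
#' @return 4x4 homogeneous matrix.
#' @export
compose_transforms <- function(outer, inner) {
  transform_matrix(outer) %*% transform_matrix(inner)
}

#' Invert a transform
#'
#' @param t an `affine_transform` or 4x4 homogeneous matrix.
#' @return 4x4 homogeneous matrix of the inverse map.
#' @export
invert_transform <- function(t) {
  m <- transform_matrix(t)
  if (abs(det(m[1:3, 1:3])) < .Machine$double.eps)
    stop("invert_transform: singular linear part")
  solve(m)
}

# apply a 4x4 (or affine_transform) to a 3xN or Nx3 coordinate matrix;
# coords given as Nx3, returned Nx3
apply_matrix_to_points <- function(t, xyz) {
  m <- transform_matrix(t)
  p <- t(xyz %*% t(m[1:3, 1:3]))
  t(p + m[1:3, 4])
}

#' Transform parameter ranges for random test transforms
#'
#' Holds per-axis intervals for translation (um), rotation (degrees) and
#' scale (dimensionless). Defaults are the randomized-test ranges used
#' throughout the synthetic protocol: translation U[-20, 20] um, rotation
#' U[-30, 30] degrees, scale U[0.5, 2] (i.e. [0.5, 1/0.5]) per axis,
#' uniform in linear scale.
#'
#' @param translation numeric(2) interval in um.
#' @param rotation numeric(2) interval in degrees.
#' @param scale numeric(2) interval, within (0, Inf).
#' @return An object of class `transform_ranges`.
#' @export
transform_ranges <- function(translation = c(-20, 20), rotation = c(-30, 30),
                             scale = c(0.5, 2)) {
  chk <- function(iv, nm, pos = FALSE) {
    iv <- as.numeric(iv)
    if (length(iv) != 2 || !all(is.finite(iv)) || iv[1] > iv[2])
      stop("transform_ranges: invalid ", nm, " interval")
    if (pos && iv[1] <= 0) stop("transform_ranges: scale interval must be > 0")
    iv
  }
  structure(list(translation = chk(translation, "translation"),
                 rotation = chk(rotation, "rotation"),
                 scale = chk(scale, "scale", pos = TRUE)),
            class = "transform_ranges")
}

#' Draw a random affine transform
#'
#' Each parameter is drawn independently and uniformly (in linear scale)
#' from its interval. Uses the current RNG state; call [set.seed()] for
#' reproducibility.
#'
#' @param ranges a [transform_ranges()] object.
#' @param center numeric(3), the fixed point of the drawn transform.
#' @return An `affine_transform`.
#' @export
random_transform <- function(ranges = transform_ranges(), center = c(0, 0, 0)) {
  stopifnot(inherits(ranges, "transform_ranges"))
  ru <- function(iv, n = 3) stats::runif(n, iv[1], iv[2])
  affine_transform(angles_deg = ru(ranges$rotation),
                   scales = ru(ranges$scale),
                   translation = ru(ranges$translation),
                   center = center)
}

#' Measure of Anisotropic Scaling (MAS)
#'
#' Quantifies how different the per-axis scale factors of an affine
#' difference are. With the scales sorted ascending as s1 <= s2 <= s3,
#' `MAS = 1 - (s1/s2 + s1/s3 + s2/s3) / 3`. MAS is 0 when all three scales
#' are equal and grows towards 1 as they diverge; it is invariant to
#' permutation of the axes and to multiplying all scales by a constant.
#'
#' @param scales numeric(3) of strictly positive per-axis scale factors.
#' @return A number in [0, 1).
#' @examples
#' mas(c(1, 1, 1))   # 0: isotropic
#' mas(c(1, 1, 2))   # 1/3
#' @export
mas <- function(scales) {
  scales <- as.numeric(scales)
  stopifnot(length(scales) == 3)
  if (!all(is.finite(scales)) || any(scales <= 0))
    stop("mas: scales must be finite and strictly positive")
  s <- sort(scales)
  1 - (s[1] / s[2] + s[1] / s[3] + s[2] / s[3]) / 3
}

#' Serialize / deserialize a transform as JSON
#'
#' The JSON object has fields `angles_deg`, `scales`, `translation_um`,
#' `center_um`; [transform_from_json()] reverses [transform_to_json()].
#'
#' @param t an `affine_transform`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
transform_to_json <- function(t, path = NULL) {
  stopifnot(inherits(t, "affine_transform"))
  obj <- list(angles_deg = t$angles_deg, scales = t$scales,
              translation_um = t$translation, center_um = t$center)
  js <- jsonlite::toJSON(obj, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname transform_to_json
#' @param json JSON string or file path to read from.
#' @export
transform_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  affine_transform(angles_deg = obj$angles_deg, scales = obj$scales,
                   translation = obj$translation_um, center = obj$center_um)
}
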