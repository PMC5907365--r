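#' Neuron morphologies as SWC node tables
#'
#' A `morphology` is a data.frame with one row per SWC node and columns
#' `id`, `type`, `x`, `y`, `z`, `radius`, `parent` (coordinates and radii
#' in um; `parent == -1` marks a root). Node ids must be unique, every
#' non-root parent must exist, and the parent links must form a forest
#' (no cycles). Structure type codes are carried through untouched.
#'
#' @param nodes data.frame with the seven SWC columns.
#' @return An object of class `morphology` (also a data.frame).
#' @export
morphology <- function(nodes) {
  nodes <- as.data.frame(nodes)
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(required %in% names(nodes)))
    stop("morphology: nodes must have columns ", paste(required, collapse = ", "))
  nodes <- nodes[required]
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  for (cc in c("x", "y", "z", "radius")) nodes[[cc]] <- as.numeric(nodes[[cc]])
  validate_morphology(nodes)
  rownames(nodes) <- NULL
  class(nodes) <- c("morphology", "data.frame")
  nodes
}

validate_morphology <- function(nodes) {
  if (nrow(nodes) < 1) stop("morphology: must contain at least one node")
  if (anyDuplicated(nodes$id)) {
    d <- nodes$id[duplicated(nodes$id)][1]
    stop("morphology: duplicate node id ", d)
  }
  if (!all(is.finite(nodes$x) & is.finite(nodes$y) & is.finite(nodes$z)))
    stop("morphology: non-finite coordinates")
  if (!all(is.finite(nodes$radius)) || any(nodes$radius < 0))
    stop("morphology: radii must be finite and >= 0")
  nonroot <- nodes$parent != -1L
  idx <- match(nodes$parent[nonroot], nodes$id)
  if (anyNA(idx)) {
    bad <- nodes$parent[nonroot][is.na(idx)][1]
    stop("morphology: dangling parent id ", bad)
  }
  # acyclicity: follow parent pointers with memoization (O(n) total); a
  # cycle is a chain that revisits an in-progress node before any root
  parent_idx <- rep(NA_integer_, nrow(nodes))
  parent_idx[nonroot] <- idx
  state <- integer(nrow(nodes))  # 0 unknown, 1 in progress, 2 reaches a root
  for (i in seq_len(nrow(nodes))) {
    if (state[i] != 0L) next
    chain <- integer(0)
    j <- i
    while (TRUE) {
      if (is.na(parent_idx[j]) || state[j] == 2L) break
      if (state[j] == 1L) stop("morphology: cycle detected in parent links")
      state[j] <- 1L
      chain <- c(chain, j)
      j <- parent_idx[j]
    }
    state[chain] <- 2L
  }
  invisible(nodes)
}

#' @export
print.morphology <- function(x, ...) {
  nroot <- sum(x$parent == -1L)
  cat(sprintf("morphology: %d nodes, %d root(s), extent %s um\n",
              nrow(x), nroot,
              paste(sprintf("%.1f", apply(x[, c("x", "y", "z")], 2,
                                          function(v) diff(range(v)))),
                    collapse = " x ")))
  invisible(x)
}

#' Read a morphology from an SWC file
#'
#' Accepts any whitespace separation, blank lines and `#` comment lines;
#' multiple roots (a forest) are allowed. Malformed lines, duplicate ids
#' and dangling parents raise an error naming the offending line.
#'
#' @param path path to an SWC text file.
#' @return A [morphology()].
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("read_swc: file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  lines <- trimws(raw[keep])
  if (length(lines) == 0) stop("read_swc: no data lines in ", path)
  fields <- strsplit(lines, "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7)) {
    bad <- which(nf != 7)[1]
    stop("read_swc: line ", lineno[bad], ": expected 7 columns, found ", nf[bad])
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    stop("read_swc: line ", lineno[bad], ": non-numeric field")
  }
  nodes <- data.frame(id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4],
                      z = m[, 5], radius = m[, 6], parent = m[, 7])
  res <- tryCatch(morphology(nodes), error = function(e) e)
  if (inherits(res, "error")) {
    msg <- conditionMessage(res)
    if (grepl("duplicate node id", msg)) {
      d <- as.integer(sub(".*duplicate node id ", "", msg))
      bad <- which(nodes$id == d)[2]
      stop("read_swc: line ", lineno[bad], ": ", msg)
    }
    if (grepl("dangling parent", msg)) {
      d <- as.integer(sub(".*dangling parent id ", "", msg))
      bad <- which(nodes$parent == d)[1]
      stop("read_swc: line ", lineno[bad], ": ", msg)
    }
    stop("read_swc: ", msg)
  }
  res
}

#' Write a morphology to an SWC file
#'
#' Coordinates and radii are written with enough digits that a read/write
#' round-trip reproduces them to at least 6 significant digits.
#'
#' @param m a [morphology()].
#' @param path output file path.
#' @export
write_swc <- function(m, path) {
  stopifnot(inherits(m, "morphology"))
  lines <- sprintf("%d %d %.10g %.10g %.10g %.10g %d",
                   m$id, m$type, m$x, m$y, m$z, m$radius, m$parent)
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("write_swc: cannot write to ", path)
  invisible(path)
}

#' Centroid of a morphology
#'
#' Unweighted arithmetic mean of the node coordinates, in um.
#'
#' @param m a [morphology()].
#' @return numeric(3).
#' @export
centroid <- function(m) {
  stopifnot(inherits(m, "morphology"))
  c(mean(m$x), mean(m$y), mean(m$z))
}

morph_coords <- function(m) {
  cbind(m$x, m$y, m$z)
}

#' Resample a morphology to bound edge lengths
#'
#' Inserts evenly spaced nodes on every parent-child edge longer than
#' `max_spacing`, so that after resampling no connected pair of nodes is
#' further apart than `max_spacing`. Inserted nodes lie exactly on the
#' original segment with linearly interpolated radii; they receive fresh
#' ids above the current maximum, so original ids are preserved.
#'
#' @param m a [morphology()].
#' @param max_spacing maximum allowed edge length in um (> 0).
#' @return A [morphology()].
#' @export
resample_morphology <- function(m, max_spacing) {
  stopifnot(inherits(m, "morphology"))
  if (!is.numeric(max_spacing) || length(max_spacing) != 1 || max_spacing <= 0)
    stop("resample_morphology: max_spacing must be a positive number")
  nonroot <- which(m$parent != -1L)
  pidx <- match(m$parent[nonroot], m$id)
  dx <- m$x[nonroot] - m$x[pidx]
  dy <- m$y[nonroot] - m$y[pidx]
  dz <- m$z[nonroot] - m$z[pidx]
  len <- sqrt(dx^2 + dy^2 + dz^2)
  nseg <- pmax(1L, ceiling(len / max_spacing))
  todo <- which(nseg > 1L)
  if (length(todo) == 0) return(m)

  next_id <- max(m$id) + 1L
  new_rows <- vector("list", length(todo))
  child_new_parent <- integer(length(todo))
  for (k in seq_along(todo)) {
    e <- todo[k]
    ci <- nonroot[e]; pi <- pidx[e]; ns <- nseg[e]
    f <- seq_len(ns - 1L) / ns
    ids <- seq.int(next_id, length.out = ns - 1L)
    next_id <- next_id + ns - 1L
    new_rows[[k]] <- data.frame(
      id = ids,
      type = m$type[ci],
      x = m$x[pi] + f * (m$x[ci] - m$x[pi]),
      y = m$y[pi] + f * (m$y[ci] - m$y[pi]),
      z = m$z[pi] + f * (m$z[ci] - m$z[pi]),
      radius = m$radius[pi] + f * (m$radius[ci] - m$radius[pi]),
      parent = c(m$id[pi], ids[-length(ids)][seq_len(max(0L, ns - 2L))]))
    child_new_parent[k] <- ids[length(ids)]
  }
  out <- as.data.frame(m)
  out$parent[nonroot[todo]] <- child_new_parent
  out <- rbind(out, do.call(rbind, new_rows))
  morphology(out)
}

#' Apply an affine transform to a morphology
#'
#' Node coordinates are mapped by the transform; ids, topology and
#' structure types are preserved. Radii are multiplied by the cube root of
#' the determinant of the linear part (the geometric mean of the per-axis
#' scale factors), so isotropic rescaling scales radii accordingly while
#' rigid motions leave them untouched.
#'
#' @param m a [morphology()].
#' @param t an `affine_transform` or 4x4 homogeneous matrix.
#' @return A [morphology()].
#' @export
apply_transform <- function(m, t) {
  stopifnot(inherits(m, "morphology"))
  mat <- transform_matrix(t)
  xyz <- apply_matrix_to_points(mat, morph_coords(m))
  d <- det(mat[1:3, 1:3])
  if (d <= 0) stop("apply_transform: transform must be orientation-preserving")
  out <- as.data.frame(m)
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  out$radius <- out$radius * d^(1 / 3)
  morphology(out)
}

#' Total cable length of a morphology
#'
#' Sum of all parent-child edge lengths in um.
#'
#' @param m a [morphology()].
#' @return numeric(1).
#' @export
cable_length <- function(m) {
  stopifnot(inherits(m, "morphology"))
  nonroot <- which(m$parent != -1L)
  if (length(nonroot) == 0) return(0)
  pidx <- match(m$parent[nonroot], m$id)
  sum(sqrt((m$x[nonroot] - m$x[pidx])^2 +
           (m$y[nonroot] - m$y[pidx])^2 +
           (m$z[nonroot] - m$z[pidx])^2))
}

# Core of edge resampling on raw coordinate matrices: points on the tree
# sampled so consecutive connected samples are <= spacing apart. `nonroot`
# and `pidx` index child and parent rows of the edges.
point_cloud_core <- function(xyz, nonroot, pidx, spacing) {
  if (length(nonroot) == 0) return(xyz)
  d <- xyz[nonroot, , drop = FALSE] - xyz[pidx, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  nseg <- pmax(1, ceiling(len / spacing))
  todo <- which(nseg > 1)
  if (length(todo) == 0) return(xyz)
  reps <- nseg[todo] - 1
  ei <- rep(todo, reps)                       # edge index per interpolated pt
  f <- unlist(lapply(reps, function(r) seq_len(r) / (r + 1)), use.names = FALSE)
  # fraction measured from parent along the edge; r interior points at k/(r+1)
  base <- xyz[pidx[ei], , drop = FALSE]
  extra <- base + d[ei, , drop = FALSE] * f
  rbind(xyz, extra)
}

# Fast path used by voxelization and density profiles; returns an Nx3
# matrix (original nodes plus interpolated edge points) without building
# a morphology object.
morph_point_cloud <- function(m, spacing) {
  xyz <- morph_coords(m)
  nonroot <- which(m$parent != -1L)
  pidx <- match(m$parent[nonroot], m$id)
  point_cloud_core(xyz, nonroot, pidx, spacing)
}
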