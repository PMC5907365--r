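#' Average volume of a group of morphologies
#'
#' The union of the voxel sets of all members. The union (rather than a
#' majority vote) is the conservative choice: every part of every
#' morphology remains represented in the reference, so parts that have not
#' yet overlapped still attract registration in later iterations.
#'
#' @param members a list of [morphology()] objects.
#' @param voxel_size voxel edge length in um.
#' @return A `voxel_set`.
#' @export
average_volume <- function(members, voxel_size) {
  if (!is.list(members) || length(members) == 0 ||
      !all(vapply(members, inherits, logical(1), "morphology")))
    stop("average_volume: need a non-empty list of morphologies")
  keys <- unique(unlist(lapply(members, function(m) voxelize(m, voxel_size)$keys)))
  new_voxel_set(keys, voxel_size)
}

#' Acceptance rule for a pairwise registration within a group
#'
#' A registration to an average volume is accepted only if it improves
#' spatial dissimilarity lexicographically from the coarsest scale down:
#' if dissimilarity at the largest voxel size decreased, accept; if it is
#' unchanged, consider the next voxel size, and so on. If all entries are
#' equal the registration is rejected. This guards against over-fitting
#' fine-scale overlap to an average that is not a real morphology at the
#' price of coarse-scale alignment.
#'
#' @param before,after numeric vectors of dissimilarities ordered from the
#'   largest to the smallest voxel size.
#' @return `TRUE` to accept, `FALSE` to reject.
#' @export
accept_registration <- function(before, after) {
  if (length(before) != length(after) || length(before) < 1)
    stop("accept_registration: before/after must have equal positive length")
  for (i in seq_along(before)) {
    if (after[i] < before[i]) return(TRUE)
    if (after[i] > before[i]) return(FALSE)
  }
  FALSE
}

#' Restrict the scale search interval by cumulative applied scaling
#'
#' Group registration repeatedly rescales morphologies towards the
#' average volume; left unconstrained, repeated stretching would grow
#' members without bound. The allowed per-step interval for a morphology
#' whose cumulative applied scale is `cum` is
#' `[global_min / cum, global_max / cum]` intersected with the per-step
#' default bounds, and always contains 1 (if `cum` has escaped the global
#' bounds, the interval clamps to {1}: no further scaling that direction).
#'
#' @param cum cumulative per-axis scale(s) already applied; scalar or
#'   numeric(3).
#' @param global_bounds numeric(2) global bounds on cumulative scaling.
#' @param step_bounds numeric(2) default per-step search bounds.
#' @return numeric(2) interval if `cum` is scalar, otherwise a 2 x 3
#'   matrix of per-axis intervals.
#' @export
restrict_scaling <- function(cum, global_bounds = c(0.5, 2),
                             step_bounds = global_bounds) {
  stopifnot(all(cum > 0), length(global_bounds) == 2,
            all(global_bounds > 0), global_bounds[1] <= global_bounds[2],
            length(step_bounds) == 2)
  one <- function(cm) {
    lo <- max(global_bounds[1] / cm, step_bounds[1])
    hi <- min(global_bounds[2] / cm, step_bounds[2])
    lo <- min(lo, 1); hi <- max(hi, 1)  # the interval always contains 1
    c(lo, hi)
  }
  if (length(cum) == 1) return(one(cum))
  vapply(cum, one, numeric(2))
}

#' Map final registered morphologies back to the initial reference frame
#'
#' Applies the inverse of the initial reference morphology's accumulated
#' transform to every member, so that the reference returns to its
#' original coordinates and all members become directly comparable to it.
#'
#' @param morphologies list of [morphology()] objects.
#' @param reference_total 4x4 homogeneous matrix accumulated on the
#'   initial reference morphology.
#' @return List of transformed morphologies.
#' @export
normalize_finals <- function(morphologies, reference_total) {
  inv <- invert_transform(reference_total)
  lapply(morphologies, apply_transform, t = inv)
}

#' Reg-MaxS-N: group co-registration by iterative averaging
#'
#' Co-registers two or more morphologies without external references.
#' Iteration 0 translates every morphology so its centroid coincides with
#' the initial reference morphology's. Each following iteration registers
#' every morphology (in index order) to the current reference volume with
#' [reg_maxs()] — the initial reference's own volume in iteration 1, the
#' union average volume of the previous iteration's members afterwards.
#' Each pairwise result is gated by [accept_registration()] on the
#' dissimilarity vectors over all voxel sizes (coarsest first); a rejected
#' morphology is carried unchanged. Per-morphology cumulative scaling is
#' tracked and restricted to `global_scale_bounds` via
#' [restrict_scaling()]. Iterations stop when every registration of an
#' iteration is rejected, or after `max_iters`. The solution is the
#' iteration (including iteration 0) minimizing the occupancy-based group
#' dissimilarity at the smallest voxel size; finally all members are
#' mapped by the inverse of the initial reference's accumulated transform
#' so results live in its original frame.
#'
#' @param group list of [morphology()] objects (length >= 2).
#' @param initial_ref_index index of the initial reference morphology.
#' @param schedule a [search_schedule()].
#' @param global_scale_bounds numeric(2) bounds on cumulative per-axis
#'   scaling of any member.
#' @param max_iters maximum number of averaging iterations.
#' @param max_outer passed to [reg_maxs()].
#' @param verbose print per-iteration group dissimilarities.
#' @return A `reg_maxs_n_result` list: `final_morphologies` (normalized),
#'   `solution_iteration` (0-based), `group_dissimilarity` (per recorded
#'   iteration, at the smallest voxel size), `acceptance` (list of logical
#'   vectors per iteration), `total_transforms` (per-member 4x4 at the
#'   solution), `normalization_transform`, `cum_scales` (per-member, at
#'   the solution), `voxel_sizes`.
#' @export
reg_maxs_n <- function(group, initial_ref_index = 1,
                       schedule = search_schedule(),
                       global_scale_bounds = c(0.5, 2),
                       max_iters = 20, max_outer = 30, verbose = FALSE) {
  if (!is.list(group) || length(group) < 2 ||
      !all(vapply(group, inherits, logical(1), "morphology")))
    stop("reg_maxs_n: need a list of at least two morphologies")
  n <- length(group)
  if (initial_ref_index < 1 || initial_ref_index > n)
    stop("reg_maxs_n: invalid initial_ref_index")
  # one clipped schedule for the whole group, from the reference's extent
  schedule <- clip_schedule(schedule, group[[initial_ref_index]])
  vs <- schedule$voxel_sizes
  v_min <- vs[length(vs)]

  ref_cent <- centroid(group[[initial_ref_index]])
  totals <- vector("list", n)        # accumulated 4x4 per member
  members <- vector("list", n)       # current state per member
  cum_scales <- rep(list(c(1, 1, 1)), n)
  for (i in seq_len(n)) {
    shift <- ref_cent - centroid(group[[i]])
    tr <- affine_transform(translation = shift)
    totals[[i]] <- as.matrix(tr)
    members[[i]] <- apply_transform(group[[i]], tr)
  }

  group_d <- function(ms) {
    group_dissimilarity(occupancy_histogram(lapply(ms, voxelize, voxel_size = v_min)))
  }

  history <- list(list(members = members, totals = totals,
                       cum_scales = cum_scales, d = group_d(members),
                       accepted = rep(NA, n)))
  if (verbose)
    message(sprintf("iteration 0: group dissimilarity %.4f", history[[1]]$d))

  for (iter in seq_len(max_iters)) {
    reference <- if (iter == 1) {
      make_reference_provider(members[[initial_ref_index]])
    } else {
      make_reference_provider(members)
    }
    accepted <- logical(n)
    new_members <- members
    for (i in seq_len(n)) {
      before <- canonical_d_vector(members[[i]], reference, vs)
      res <- reg_maxs(members[[i]], reference, schedule = schedule,
                      global_scale_bounds = global_scale_bounds,
                      cum_scales_init = cum_scales[[i]],
                      max_outer = max_outer, centroid_align = FALSE)
      after <- canonical_d_vector(res$registered, reference, vs)
      if (accept_registration(before, after)) {
        accepted[i] <- TRUE
        new_members[[i]] <- res$registered
        totals[[i]] <- compose_transforms(res$total_transform, totals[[i]])
        cum_scales[[i]] <- res$cum_scales
      }
    }
    members <- new_members
    history[[iter + 1L]] <- list(members = members, totals = totals,
                                 cum_scales = cum_scales,
                                 d = group_d(members), accepted = accepted)
    if (verbose)
      message(sprintf("iteration %d: group dissimilarity %.4f, %d/%d accepted",
                      iter, history[[iter + 1L]]$d, sum(accepted), n))
    if (!any(accepted)) break
  }

  ds <- vapply(history, function(h) h$d, numeric(1))
  sol <- which.min(ds)               # earliest minimum
  sol_state <- history[[sol]]
  norm_t <- sol_state$totals[[initial_ref_index]]
  finals <- normalize_finals(sol_state$members, norm_t)

  structure(list(
    final_morphologies = finals,
    solution_iteration = sol - 1L,
    group_dissimilarity = ds,
    acceptance = lapply(history, function(h) h$accepted),
    total_transforms = sol_state$totals,
    normalization_transform = norm_t,
    cum_scales = sol_state$cum_scales,
    voxel_sizes = vs), class = "reg_maxs_n_result")
}

#' @export
print.reg_maxs_n_result <- function(x, ...) {
  cat("reg_maxs_n_result\n")
  cat("  members            :", length(x$final_morphologies), "\n")
  cat("  iterations recorded:", length(x$group_dissimilarity), "\n")
  cat("  solution iteration :", x$solution_iteration, "\n")
  cat("  group dissimilarity:",
      paste(sprintf("%.4f", x$group_dissimilarity), collapse = ", "), "\n")
  invisible(x)
}
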