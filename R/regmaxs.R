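#' Multi-scale search schedule
#'
#' Registration refines transform estimates over a strictly descending
#' sequence of voxel sizes. At the coarsest level the full plausible
#' region is searched (rotation +-30 deg per axis with 7 samples,
#' translation +-2v per axis with 9 samples where v is the coarsest voxel
#' size, scale log-spaced over the allowed bounds with 7 samples per
#' axis). Each finer level searches the region of uncertainty of the
#' previous estimate: the parameter span of all candidates whose
#' dissimilarity tied exactly with the optimum, widened by one grid step
#' — so an informative level shrinks the window for refinement while a
#' level too coarse to discriminate leaves it wide — sampled with the
#' same per-kind counts.
#'
#' @param voxel_sizes strictly descending voxel edge lengths in um.
#' @param n_initial_scale_samples odd number of log-spaced scale samples
#'   per axis.
#' @param n_refine_samples retained for configurability of window
#'   sampling; must be odd.
#' @return An object of class `search_schedule`.
#' @export
search_schedule <- function(voxel_sizes = c(160, 80, 40, 20, 10),
                            n_initial_scale_samples = 7,
                            n_refine_samples = 5) {
  voxel_sizes <- as.numeric(voxel_sizes)
  if (length(voxel_sizes) < 1 || any(voxel_sizes <= 0) ||
      any(diff(voxel_sizes) >= 0))
    stop("search_schedule: voxel_sizes must be positive and strictly descending")
  if (n_initial_scale_samples %% 2 != 1 || n_refine_samples %% 2 != 1)
    stop("search_schedule: sample counts must be odd")
  structure(list(voxel_sizes = voxel_sizes,
                 n_initial_scale_samples = as.integer(n_initial_scale_samples),
                 n_refine_samples = as.integer(n_refine_samples)),
            class = "search_schedule")
}

# drop leading (coarsest) levels whose voxel exceeds half the bounding-box
# diagonal of the morphology; the finest level is always kept
clip_schedule <- function(schedule, m) {
  bb <- apply(morph_coords(m), 2, range)
  half_diag <- sqrt(sum((bb[2, ] - bb[1, ])^2)) / 2
  vs <- schedule$voxel_sizes
  keep <- vs <= half_diag
  keep[length(vs)] <- TRUE
  schedule$voxel_sizes <- vs[keep]
  schedule
}

# ---- objective machinery -------------------------------------------------

# memoised provider of reference voxel sets per voxel size; `ref` is a
# morphology or a list of morphologies (group average volume = union)
make_reference_provider <- function(ref) {
  if (inherits(ref, "morphology")) ref <- list(ref)
  stopifnot(is.list(ref), length(ref) >= 1,
            all(vapply(ref, inherits, logical(1), "morphology")))
  cache <- new.env(parent = emptyenv())
  function(v) {
    key <- format(v, digits = 15)
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    keys <- unique(unlist(lapply(ref, function(m) voxelize(m, v)$keys)))
    vs <- new_voxel_set(keys, v)
    assign(key, vs, envir = cache)
    vs
  }
}

# exact comparison of two dissimilarities given as (inter, union) counts:
# TRUE iff D(a) < D(b); D = 1 - i/u changes only in rational steps, so
# comparison is by integer cross-multiplication, never by float tolerance
counts_less <- function(a, b) {
  a[["inter"]] * b[["union"]] > b[["inter"]] * a[["union"]]
}

counts_equal <- function(a, b) {
  a[["inter"]] * b[["union"]] == b[["inter"]] * a[["union"]]
}

# evaluate a batch of candidate parameter triples against a reference
# voxel set. `cand` is an n x 3 matrix: um offsets (translation), degrees
# (rotation) or log-scales (scale). `geom` carries the test morphology's
# node coordinates and edge indexing plus a point cloud pre-resampled at
# v/2. Rigid candidates (translation, rotation) preserve edge lengths, so
# transforming the pre-resampled cloud is exactly equivalent to the
# canonical resample-after-transform; scale candidates change edge
# lengths, so the nodes are scaled first and edges resampled afterwards —
# otherwise the sampling density (and with it the voxel set) would differ
# from the canonical voxelization the search is later judged by.
# Returns matrix with columns inter, union.
evaluate_candidates <- function(kind, cand, geom, center, v, ref_set) {
  ref_keys <- ref_set$keys
  nref <- length(ref_keys)
  ref_cent <- if (kind == "scale") voxel_set_centroid(ref_set) else NULL
  out <- matrix(0, nrow(cand), 2, dimnames = list(NULL, c("inter", "union")))
  pts0 <- if (kind == "rotation") sweep(geom$pts, 2, center) else NULL
  xyz0 <- if (kind == "scale") sweep(geom$xyz, 2, center) else NULL
  for (ci in seq_len(nrow(cand))) {
    p <- cand[ci, ]
    q <- switch(kind,
      translation = sweep(geom$pts, 2, p, "+"),
      rotation = sweep(pts0 %*% t(rotation_matrix(p)), 2, center, "+"),
      scale = {
        nodes <- sweep(sweep(xyz0, 2, exp(p), "*"), 2, center, "+")
        point_cloud_core(nodes, geom$nonroot, geom$pidx, v / 2)
      })
    keys <- points_to_keys(q, v)
    if (kind == "scale") {
      # centric measure: align occupied-voxel centroids before comparing
      cent <- colMeans(voxel_unkey(keys)) * v
      q <- sweep(q, 2, ref_cent - cent, "+")
      keys <- points_to_keys(q, v)
    }
    ninter <- sum(!is.na(match(keys, ref_keys)))
    out[ci, ] <- c(ninter, length(keys) + nref - ninter)
  }
  out
}

# pick the best row: minimal D, ties by smallest parameter norm (log-scale
# norm for scale), then by candidate order; also returns the full tie set,
# whose parameter span measures the uncertainty of the estimate
pick_best <- function(cand, counts, kind) {
  d <- 1 - counts[, "inter"] / counts[, "union"]
  dmin <- min(d)
  tie <- which(d <= dmin + 1e-12)
  best <- tie
  if (length(best) > 1) {
    norms <- sqrt(rowSums(cand[best, , drop = FALSE]^2))
    best <- best[norms <= min(norms) + 1e-12]
  }
  list(index = best[1], ties = tie)
}

#' Exhaustive search over a finite candidate set
#'
#' Evaluates every candidate with the objective and returns the minimizer.
#' Ties are broken deterministically: first by the smallest parameter norm
#' (L2 norm of the candidate row, after applying `norm_fun` if given),
#' then by candidate order.
#'
#' @param candidates numeric matrix, one candidate parameter tuple per row
#'   (a vector is treated as a one-column matrix).
#' @param objective function mapping a candidate row to a numeric score to
#'   be minimized.
#' @param norm_fun function mapping a candidate row to its tie-break norm;
#'   defaults to the Euclidean norm.
#' @return A list with `parameters` (best row), `value` (best objective),
#'   `index` (row index of the winner).
#' @export
exhaustive_search <- function(candidates, objective,
                              norm_fun = function(p) sqrt(sum(p^2))) {
  if (is.null(dim(candidates))) candidates <- matrix(candidates, ncol = 1)
  if (nrow(candidates) < 1) stop("exhaustive_search: no candidates")
  vals <- apply(candidates, 1, objective)
  vmin <- min(vals)
  tie <- which(vals <= vmin + 1e-12)
  if (length(tie) > 1) {
    norms <- vapply(tie, function(i) norm_fun(candidates[i, ]), numeric(1))
    tie <- tie[norms <= min(norms) + 1e-12]
  }
  idx <- tie[1]
  list(parameters = candidates[idx, ], value = vals[idx], index = idx)
}

# number of grid samples per axis for one search level
level_samples <- function(kind, schedule) {
  switch(kind,
    translation = 9L,
    rotation = 7L,
    scale = schedule$n_initial_scale_samples)
}

#' Multi-scale estimation of one transform difference
#'
#' Estimates the translation, rotation or scaling difference between a
#' test morphology and a reference volume by running exhaustive searches
#' over progressively finer voxel sizes; each level searches a window of
#' previous-estimate +- previous-grid-step. The objective is the
#' non-centric dissimilarity for translation and rotation and the centric
#' dissimilarity for scale.
#'
#' @param kind one of "translation", "rotation", "scale".
#' @param test a [morphology()].
#' @param reference a [morphology()], a list of morphologies, or a
#'   reference provider function `function(voxel_size) -> voxel_set`.
#' @param schedule a [search_schedule()].
#' @param scale_bounds for `kind = "scale"`: either numeric(2) applied to
#'   every axis or a 2 x 3 matrix of per-axis (lower, upper) bounds.
#' @param center center for rotation/scaling; defaults to the test's
#'   centroid.
#' @return numeric(3): um offsets, degrees, or per-axis scale factors.
#' @export
multiscale_estimate <- function(kind, test, reference, schedule = search_schedule(),
                                scale_bounds = c(0.5, 2),
                                center = centroid(test)) {
  kind <- match.arg(kind, c("translation", "rotation", "scale"))
  stopifnot(inherits(test, "morphology"), inherits(schedule, "search_schedule"))
  refprov <- if (is.function(reference)) reference else make_reference_provider(reference)
  log_bounds <- NULL
  if (kind == "scale") {
    if (is.null(dim(scale_bounds)))
      scale_bounds <- matrix(scale_bounds, 2, 3)
    stopifnot(all(dim(scale_bounds) == c(2, 3)), all(scale_bounds > 0),
              all(scale_bounds[1, ] <= scale_bounds[2, ]))
    log_bounds <- log(scale_bounds)
  }
  vs <- schedule$voxel_sizes
  # per-axis search window, initialized to the full plausible region at
  # the coarsest level; subsequent levels search the region of
  # uncertainty of the previous estimate: the span of all candidates that
  # tied with the optimum, widened by one grid step. A level that cannot
  # discriminate (few occupied voxels, massive ties) therefore leaves the
  # window wide, while an informative level shrinks it for refinement.
  window <- switch(kind,
    translation = matrix(rep(c(-2, 2) * vs[1], 3), 2, 3),
    rotation = matrix(rep(c(-30, 30), 3), 2, 3),
    scale = log_bounds)
  nsamp <- level_samples(kind, schedule)
  est <- NULL
  for (level in seq_along(vs)) {
    v <- vs[level]
    # the identity (0 in search coordinates) and the previous level's
    # estimate are always candidates: windows can become asymmetric, and
    # the refined grid must never lose the identity or the carried
    # optimum to floating-point sampling
    grids <- lapply(1:3, function(ax) {
      g <- seq(window[1, ax], window[2, ax], length.out = nsamp)
      extra <- c(0, if (!is.null(est)) est[ax])
      extra <- extra[extra >= window[1, ax] - 1e-12 &
                     extra <= window[2, ax] + 1e-12]
      unique(sort(c(g, extra)))
    })
    cand <- as.matrix(expand.grid(grids[[1]], grids[[2]], grids[[3]],
                                  KEEP.OUT.ATTRS = FALSE))
    dimnames(cand) <- NULL
    nonroot <- which(test$parent != -1L)
    geom <- list(xyz = morph_coords(test),
                 nonroot = nonroot,
                 pidx = match(test$parent[nonroot], test$id),
                 pts = morph_point_cloud(test, v / 2))
    counts <- evaluate_candidates(kind, cand, geom, center, v, refprov(v))
    best <- pick_best(cand, counts, kind)
    est <- cand[best$index, ]
    # window step of the regular grid (inserted identity/estimate
    # candidates do not count towards the sampling resolution)
    step <- (window[2, ] - window[1, ]) / (nsamp - 1)
    tie_par <- cand[best$ties, , drop = FALSE]
    for (ax in 1:3) {
      lo <- max(window[1, ax], min(tie_par[, ax]) - step[ax])
      hi <- min(window[2, ax], max(tie_par[, ax]) + step[ax])
      window[, ax] <- c(lo, hi)
    }
  }
  if (kind == "scale") exp(est) else est
}

# canonical (inter, union) counts of test vs reference at one voxel size
canonical_counts <- function(m, refprov, v) {
  keys <- voxelize(m, v)$keys
  ref_keys <- refprov(v)$keys
  ninter <- sum(!is.na(match(keys, ref_keys)))
  c(inter = ninter, union = length(keys) + length(ref_keys) - ninter)
}

canonical_d_vector <- function(m, refprov, voxel_sizes) {
  vapply(voxel_sizes, function(v) {
    cnt <- canonical_counts(m, refprov, v)
    1 - cnt[["inter"]] / cnt[["union"]]
  }, numeric(1))
}

# counts at every voxel size: 2 x n matrix, rows inter/union, columns
# ordered like voxel_sizes (largest first)
canonical_counts_vector <- function(m, refprov, voxel_sizes) {
  vapply(voxel_sizes, function(v) canonical_counts(m, refprov, v),
         numeric(2))
}

# lexicographic comparison of per-level dissimilarities from the coarsest
# level down, on exact counts: -1 if a < b, 0 if equal, +1 if a > b
lex_compare_counts <- function(a, b) {
  for (j in seq_len(ncol(a))) {
    # D = 1 - i/u, so D(a) < D(b) iff i_a * u_b > i_b * u_a
    left <- a[1, j] * b[2, j]
    right <- b[1, j] * a[2, j]
    if (left > right) return(-1L)
    if (left < right) return(1L)
  }
  0L
}

#' Reg-MaxS: pairwise registration by maximizing volume overlap
#'
#' Registers `test` to `reference` by iteratively estimating and removing
#' transform differences with multi-scale exhaustive search. The
#' procedure: (i) optional centroid alignment; (ii) an inner loop
#' alternating translation and rotation estimation, applying an estimate
#' iff it does not worsen the dissimilarity at the smallest voxel size;
#' (iii) one scale estimation (centric measure) applied about the current
#' centroid, within the scale bounds, iff it improves the per-level
#' dissimilarity vector lexicographically from the coarsest level down or
#' does not worsen the finest level; (ii) and (iii) repeat until a full
#' outer pass makes no progress against the best state seen, or
#' `max_outer` passes are reached. All comparisons are exact on voxel
#' counts. The returned solution is the trace state with minimal
#' smallest-voxel-size dissimilarity (earliest on ties), which guarantees
#' the result is never worse than the initial alignment. The search is
#' fully deterministic. Reflections are not handled and must be removed
#' beforehand.
#'
#' @param test a [morphology()] to be registered.
#' @param reference a [morphology()], list of morphologies (registered to
#'   their union volume), or a provider `function(voxel_size) -> voxel_set`.
#' @param schedule a [search_schedule()]; coarse levels larger than half
#'   the test's bounding-box diagonal are dropped.
#' @param scale_bounds numeric(2) or 2 x 3 matrix of per-axis bounds on
#'   each applied scale step.
#' @param global_scale_bounds optional numeric(2); when given, the
#'   cumulative per-axis scaling applied during this call (times
#'   `cum_scales_init`) is kept inside these bounds by shrinking the
#'   per-step search interval (see [restrict_scaling()]).
#' @param cum_scales_init numeric(3) cumulative per-axis scaling already
#'   applied to `test` before this call (used by group registration).
#' @param max_outer maximum number of outer translation/rotation + scale
#'   passes.
#' @param centroid_align if `TRUE` (default), start by translating `test`
#'   so its node centroid coincides with the reference centroid (the
#'   occupied-voxel centroid at the smallest voxel size when the reference
#'   is a volume).
#' @param ref_centroid optional numeric(3) overriding the reference
#'   centroid used for the initial alignment.
#' @return A `reg_maxs_result` list: `total_transform` (4x4 matrix up to
#'   the chosen solution), `registered` (test mapped by it), `trace`
#'   (data.frame of steps with dissimilarity at every voxel size),
#'   `solution_index`, `dissimilarity` (solution's per-voxel-size vector),
#'   `cum_scales` (cumulative per-axis scales at the solution),
#'   `voxel_sizes`.
#' @export
reg_maxs <- function(test, reference, schedule = search_schedule(),
                     scale_bounds = c(0.5, 2), global_scale_bounds = NULL,
                     cum_scales_init = c(1, 1, 1), max_outer = 30,
                     centroid_align = TRUE, ref_centroid = NULL) {
  stopifnot(inherits(test, "morphology"))
  schedule <- clip_schedule(schedule, test)
  vs <- schedule$voxel_sizes
  v_min <- vs[length(vs)]
  refprov <- if (is.function(reference)) reference else make_reference_provider(reference)
  if (is.null(dim(scale_bounds))) scale_bounds <- matrix(scale_bounds, 2, 3)

  if (is.null(ref_centroid)) {
    ref_centroid <- if (inherits(reference, "morphology")) centroid(reference)
                    else voxel_set_centroid(refprov(v_min))
  }

  m_cur <- test
  total <- diag(4)
  cum <- as.numeric(cum_scales_init)
  trace <- list()

  if (centroid_align) {
    shift <- ref_centroid - centroid(m_cur)
    tr <- affine_transform(translation = shift)
    m_cur <- apply_transform(m_cur, tr)
    total <- compose_transforms(tr, total)
  }

  record <- function(step, kind, params) {
    trace[[length(trace) + 1L]] <<- list(
      step = step, kind = kind, params = params,
      d = canonical_d_vector(m_cur, refprov, vs),
      counts_min = canonical_counts(m_cur, refprov, v_min),
      total = total, cum_scales = cum)
  }
  record("initial", if (centroid_align) "centroid_alignment" else "none",
         c(0, 0, 0))
  cnts_cur <- canonical_counts_vector(m_cur, refprov, vs)
  best_min <- trace[[1]]$counts_min
  best_lex <- cnts_cur

  # Acceptance of an estimated step depends on its kind. Translation and
  # rotation steps are applied iff they do not worsen the finest-level
  # dissimilarity (ties allowed, so plateaus can be traversed; coarse
  # levels hold too few voxels for their fluctuations to be allowed to
  # override the fine alignment). A scale step is applied iff it improves
  # the per-level dissimilarity vector lexicographically from the
  # coarsest level down — the same coarse-first logic as the group
  # acceptance rule — because escaping a large scale difference
  # legitimately repairs the large-scale picture at a transient
  # fine-scale price. All comparisons are exact on the voxel counts.
  # Returns TRUE iff the step was applied and progressed (improved the
  # best fine-level state seen so far, or was an accepted scale step,
  # which later passes must be given the chance to exploit); the
  # trace-minimum solution rule makes exploratory steps safe.
  apply_step <- function(kind, params) {
    ctr <- centroid(m_cur)
    tr <- switch(kind,
      translation = affine_transform(translation = params),
      rotation = affine_transform(angles_deg = params, center = ctr),
      scale = affine_transform(scales = params, center = ctr))
    if (kind == "scale") {
      # the scale estimate was scored with the centric measure; apply the
      # same voxel-centroid alignment translation together with the scale
      m_scaled <- apply_transform(m_cur, tr)
      shift <- voxel_set_centroid(refprov(v_min)) -
        voxel_set_centroid(voxelize(m_scaled, v_min))
      tr <- compose_transforms(affine_transform(translation = shift), tr)
    }
    m_new <- apply_transform(m_cur, tr)
    cnts_new <- canonical_counts_vector(m_new, refprov, vs)
    cnt_new_min <- c(inter = unname(cnts_new[1, length(vs)]),
                     union = unname(cnts_new[2, length(vs)]))
    cnt_cur_min <- c(inter = unname(cnts_cur[1, length(vs)]),
                     union = unname(cnts_cur[2, length(vs)]))
    lex_better <- lex_compare_counts(cnts_new, cnts_cur) < 0
    fine_not_worse <- !counts_less(cnt_cur_min, cnt_new_min)
    accepted <- if (kind == "scale") lex_better || fine_not_worse
                else fine_not_worse
    if (!accepted) return(FALSE)
    m_cur <<- m_new
    total <<- compose_transforms(tr, total)
    if (kind == "scale") cum <<- cum * params
    cnts_cur <<- cnts_new
    record("applied", kind, params)
    progressed <- kind == "scale" && lex_better
    if (counts_less(cnt_new_min, best_min)) {
      best_min <<- cnt_new_min
      progressed <- TRUE
    }
    if (lex_compare_counts(cnts_new, best_lex) < 0)
      best_lex <<- cnts_new
    progressed
  }

  for (outer in seq_len(max_outer)) {
    pass_improved <- FALSE
    for (inner in seq_len(max_outer)) {
      cycle_improved <- FALSE
      for (kind in c("translation", "rotation")) {
        par <- multiscale_estimate(kind, m_cur, refprov, schedule,
                                   center = centroid(m_cur))
        if (any(par != 0) && apply_step(kind, par)) cycle_improved <- TRUE
      }
      if (!cycle_improved) break
      pass_improved <- TRUE
    }
    bounds <- scale_bounds
    if (!is.null(global_scale_bounds)) {
      for (ax in 1:3) {
        iv <- restrict_scaling(cum[ax], global_scale_bounds,
                               step_bounds = scale_bounds[, ax])
        bounds[, ax] <- iv
      }
    }
    par <- multiscale_estimate("scale", m_cur, refprov, schedule,
                               scale_bounds = bounds, center = centroid(m_cur))
    if (any(par != 1) && apply_step("scale", par)) pass_improved <- TRUE
    if (!pass_improved) break
  }

  d_min_all <- vapply(trace, function(e) {
    1 - e$counts_min[["inter"]] / e$counts_min[["union"]]
  }, numeric(1))
  # exact earliest-minimum selection on the rational counts
  sol <- 1L
  for (i in seq_along(trace)[-1]) {
    if (counts_less(trace[[i]]$counts_min, trace[[sol]]$counts_min)) sol <- i
  }
  sol_entry <- trace[[sol]]
  trace_df <- data.frame(
    step = vapply(trace, function(e) e$step, character(1)),
    kind = vapply(trace, function(e) e$kind, character(1)),
    params = vapply(trace, function(e)
      paste(format(e$params, digits = 6), collapse = " "), character(1)))
  dmat <- do.call(rbind, lapply(trace, function(e) e$d))
  colnames(dmat) <- paste0("D_v", format(vs, trim = TRUE))
  trace_df <- cbind(trace_df, as.data.frame(dmat))

  structure(list(
    total_transform = sol_entry$total,
    registered = apply_transform(test, sol_entry$total),
    trace = trace_df,
    solution_index = sol,
    dissimilarity = sol_entry$d,
    cum_scales = sol_entry$cum_scales,
    voxel_sizes = vs), class = "reg_maxs_result")
}

#' @export
print.reg_maxs_result <- function(x, ...) {
  cat("reg_maxs_result\n")
  cat("  steps recorded :", nrow(x$trace), "\n")
  cat("  solution index :", x$solution_index, "\n")
  cat("  voxel sizes    :", paste(x$voxel_sizes, collapse = ", "), "um\n")
  cat("  dissimilarity  :", paste(sprintf("%.4f", x$dissimilarity),
                                  collapse = ", "), "\n")
  invisible(x)
}
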