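#' Corresponding point pairs between two morphologies
#'
#' In `"known"` mode nodes are paired by id (available for synthetic test
#' cases, where the transformed morphology keeps the ids of the
#' original). In `"nearest"` mode every reference node is paired with its
#' Euclidean-nearest test node (ties resolved to the lowest test id),
#' which is the fallback when no true correspondence exists.
#'
#' @param reference,test [morphology()] objects.
#' @param mode `"known"` or `"nearest"`.
#' @return data.frame with columns `ref_id`, `test_id`, `distance` (um),
#'   one row per reference node.
#' @export
correspondences <- function(reference, test, mode = c("known", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(reference, "morphology"), inherits(test, "morphology"))
  rp <- morph_coords(reference)
  tp <- morph_coords(test)
  if (mode == "known") {
    idx <- match(reference$id, test$id)
    if (anyNA(idx))
      stop("correspondences: known mode requires matching node ids")
    d <- sqrt(rowSums((rp - tp[idx, , drop = FALSE])^2))
    data.frame(ref_id = reference$id, test_id = test$id[idx], distance = d)
  } else {
    ord <- order(test$id)           # lowest-id wins on exact distance ties
    tp <- tp[ord, , drop = FALSE]
    tid <- test$id[ord]
    # squared distance matrix reference x test, computed blockwise
    t2 <- rowSums(tp^2)
    nearest <- integer(nrow(rp))
    dist <- numeric(nrow(rp))
    block <- 2048L
    for (s in seq(1, nrow(rp), by = block)) {
      e <- min(s + block - 1L, nrow(rp))
      rb <- rp[s:e, , drop = FALSE]
      d2 <- outer(rowSums(rb^2), t2, "+") - 2 * rb %*% t(tp)
      j <- max.col(-d2, ties.method = "first")
      nearest[s:e] <- j
      dist[s:e] <- sqrt(pmax(d2[cbind(seq_len(e - s + 1L), j)], 0))
    }
    data.frame(ref_id = reference$id, test_id = tid[nearest], distance = dist)
  }
}

#' Exact one-sided sign test on corresponding-point distances
#'
#' Tests whether distances are significantly below a threshold. With
#' `k = count(d < threshold)` successes out of `n` distances (ties at the
#' threshold count as failures, which is conservative), the p-value is the
#' exact binomial tail `P(Binomial(n, 1/2) >= k)`; the result is
#' significant when `p < alpha`. A Wilcoxon signed-rank variant (of the
#' differences `d - threshold`) is available for sensitivity analysis.
#'
#' @param distances numeric vector of non-negative distances (um).
#' @param threshold success threshold in um (typically the smallest voxel
#'   size used for registration).
#' @param alpha significance level (default 0.01).
#' @param method `"sign"` (exact binomial, default) or `"wilcoxon"`.
#' @return List with `p_value`, `significant`, `k`, `n`.
#' @export
sign_test <- function(distances, threshold, alpha = 0.01,
                      method = c("sign", "wilcoxon")) {
  method <- match.arg(method)
  distances <- as.numeric(distances)
  if (length(distances) < 1) stop("sign_test: no distances")
  n <- length(distances)
  k <- sum(distances < threshold)
  p <- if (method == "sign") {
    stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  } else {
    suppressWarnings(
      stats::wilcox.test(distances, mu = threshold,
                         alternative = "less", exact = FALSE)$p.value)
  }
  list(p_value = p, significant = p < alpha, k = k, n = n)
}

#' Suite-level registration performance percentages
#'
#' Given the m x n table of corresponding-point distances (rows: the m
#' reference points, columns: the n tests), applies the sign test two
#' ways: per test across reference points (columns), and per reference
#' point across tests (rows). Reports the percentage of tests and of
#' points whose distances are significantly below the threshold.
#'
#' @param distances numeric m x n matrix.
#' @param threshold success threshold in um.
#' @param alpha significance level.
#' @return List with `percent_tests`, `percent_points`, and the logical
#'   vectors `test_significant`, `point_significant`.
#' @export
performance_summary <- function(distances, threshold, alpha = 0.01) {
  distances <- as.matrix(distances)
  if (anyNA(distances)) stop("performance_summary: distance table incomplete")
  per_test <- apply(distances, 2, function(d)
    sign_test(d, threshold, alpha)$significant)
  per_point <- apply(distances, 1, function(d)
    sign_test(d, threshold, alpha)$significant)
  list(percent_tests = 100 * mean(per_test),
       percent_points = 100 * mean(per_point),
       test_significant = per_test,
       point_significant = per_point)
}

#' PCA-based baseline registration
#'
#' A simple registration assuming the two morphologies have similar
#' density profiles and similar orientation in space: it aligns centroids,
#' rotates the test so its principal axes coincide with the reference's
#' (axis signs chosen to give a proper rotation of maximal trace, i.e.
#' the rotation closest to the identity consistent with the axes), and
#' scales each principal axis by the ratio of coordinate standard
#' deviations along the corresponding axes. When two principal variance
#' ratios are within 1% of each other in either morphology the axis
#' assignment is ambiguous; a warning is issued and the rotation is left
#' at identity.
#'
#' @param test,reference [morphology()] objects with at least 4
#'   non-collinear nodes each.
#' @return A 4x4 homogeneous transform matrix mapping test coordinates
#'   into the reference frame; apply with [apply_transform()].
#' @export
pca_register <- function(test, reference) {
  stopifnot(inherits(test, "morphology"), inherits(reference, "morphology"))
  tp <- morph_coords(test)
  rp <- morph_coords(reference)
  if (nrow(tp) < 4 || nrow(rp) < 4)
    stop("pca_register: need at least 4 nodes per morphology")
  ct <- colMeans(tp); cr <- colMeans(rp)
  et <- eigen(stats::cov(sweep(tp, 2, ct)), symmetric = TRUE)
  er <- eigen(stats::cov(sweep(rp, 2, cr)), symmetric = TRUE)
  if (et$values[3] <= 0 || er$values[3] <= 0)
    stop("pca_register: degenerate (collinear/coplanar) morphology")

  ambiguous <- function(vals) any(vals[-3] / vals[-1] < 1.01)
  rot_ok <- TRUE
  if (ambiguous(et$values) || ambiguous(er$values)) {
    warning("pca_register: principal variances nearly equal; ",
            "axis correspondence ambiguous, leaving rotation at identity")
    rot_ok <- FALSE
  }

  scales <- sqrt(er$values / et$values)
  if (rot_ok) {
    vt <- et$vectors; vr <- er$vectors
    # choose axis signs s in {-1,1}^3 with det(vr diag(s) vt') = +1,
    # maximizing the trace (the proper rotation closest to identity);
    # the full map is then x' = Vr diag(scales * s) Vt' (x - ct) + cr
    best_s <- NULL; best_tr <- -Inf
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      s <- c(s1, s2, s3)
      rr <- vr %*% diag(s) %*% t(vt)
      if (det(rr) < 0) next
      if (sum(diag(rr)) > best_tr) { best_tr <- sum(diag(rr)); best_s <- s }
    }
    r <- vr %*% diag(best_s) %*% t(vt)
    lin <- vr %*% diag(scales * best_s) %*% t(vt)
  } else {
    r <- diag(3)
    lin <- diag(3)                 # no axis correspondence: rigid shift only
    scales <- c(1, 1, 1)
  }
  m <- diag(4)
  m[1:3, 1:3] <- lin
  m[1:3, 4] <- cr - lin %*% ct
  attr(m, "scales") <- scales
  attr(m, "rotation") <- r
  m
}
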