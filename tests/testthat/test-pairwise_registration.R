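test_that("search schedules validate their invariants", {
  s <- search_schedule()
  expect_equal(s$voxel_sizes, c(160, 80, 40, 20, 10))
  expect_error(search_schedule(c(10, 20)), "descending")
  expect_error(search_schedule(numeric(0)), "descending|positive")
  expect_error(search_schedule(c(40, 20), n_refine_samples = 4), "odd")
  # coarse levels above half the bounding-box diagonal are dropped
  small <- line_morphology(5, spacing = 10)   # diagonal 40, half 20
  clipped <- regmaxs:::clip_schedule(search_schedule(), small)
  expect_equal(clipped$voxel_sizes, c(20, 10))
})

test_that("exhaustive search minimizes with deterministic tie-breaking", {
  cand <- matrix(c(0, 10, 20), ncol = 1)
  res <- exhaustive_search(cand, function(p) abs(p - 10))
  expect_equal(res$parameters, 10)
  expect_equal(res$value, 0)

  # symmetric objective, 0 not a candidate: smallest-norm rule can't
  # separate -10 from +10, so candidate order decides
  cand <- matrix(c(-10, 10), ncol = 1)
  res <- exhaustive_search(cand, function(p) p^2 - 100)
  expect_equal(res$index, 1)

  # smallest parameter norm wins among equal objectives
  cand <- matrix(c(30, 0, -20), ncol = 1)
  res <- exhaustive_search(cand, function(p) 0)
  expect_equal(res$parameters, 0)
  expect_error(exhaustive_search(matrix(0, 0, 1), identity), "no candidates")

  # recovering a planted rotation on a voxelized line by brute force
  line <- line_morphology(20, spacing = 5)
  rot17 <- apply_transform(line, affine_transform(angles_deg = c(0, 0, 17),
                                                  center = centroid(line)))
  ref <- voxelize(rot17, 10)
  cand <- matrix(seq(0, 30, by = 1), ncol = 1)
  res <- exhaustive_search(cand, function(p) {
    m <- apply_transform(line, affine_transform(angles_deg = c(0, 0, p),
                                                center = centroid(line)))
    dissimilarity(voxelize(m, 10), ref)
  })
  expect_equal(res$parameters, 17)
})

test_that("multiscale estimation recovers planted single-kind differences", {
  base <- generate_tree(tree_gen_params(n_nodes = 150, seed = 20))
  sched <- search_schedule(c(80, 40, 20, 10))

  expect_equal(multiscale_estimate("translation", base, base, sched),
               c(0, 0, 0))
  expect_equal(multiscale_estimate("rotation", base, base, sched), c(0, 0, 0))
  expect_equal(multiscale_estimate("scale", base, base, sched), c(1, 1, 1))

  shift <- c(12, -7, 3)
  moved <- apply_transform(base, affine_transform(translation = shift))
  est <- multiscale_estimate("translation", moved, base, sched)
  expect_lt(max(abs(est + shift)), 5)        # within the finest grid step

  rot <- apply_transform(base, affine_transform(angles_deg = c(0, 0, 15),
                                                center = centroid(base)))
  est <- multiscale_estimate("rotation", rot, base, sched,
                             center = centroid(rot))
  back <- rotation_matrix <- regmaxs:::rotation_matrix
  # the estimated rotation composed with the planted one is near identity
  resid <- rotation_matrix(est) %*% rotation_matrix(c(0, 0, 15))
  expect_lt(acos(min((sum(diag(resid)) - 1) / 2, 1)) * 180 / pi, 6)
})

test_that("registering a morphology to itself returns identity", {
  m <- generate_tree(tree_gen_params(n_nodes = 150, seed = 22))
  res <- reg_maxs(m, m, schedule = search_schedule(c(40, 20, 10)))
  expect_equal(tail(res$dissimilarity, 1), 0)
  expect_true(all(res$dissimilarity == 0))
  expect_equal(res$total_transform, diag(4), tolerance = 1e-9)
  expect_morph_equal(res$registered, m, tol = 1e-9)
})

test_that("planted pure translations are recovered across seeds", {
  base <- generate_tree(tree_gen_params(n_nodes = 120, seed = 30))
  sched <- search_schedule(c(80, 40, 20, 10))
  set.seed(99)
  for (i in 1:20) {
    shift <- runif(3, -20, 20)
    moved <- apply_transform(base, affine_transform(translation = shift))
    res <- reg_maxs(moved, base, sched)
    back <- res$registered
    err <- sqrt(sum((centroid(back) - centroid(base))^2))
    expect_lt(err, 10 / 2)                   # within the finest level step
    expect_lt(max(abs(back$x - base$x)), 10)
  }
})

test_that("solutions never fall behind the initial centroid alignment", {
  base <- generate_tree(tree_gen_params(n_nodes = 120, seed = 31))
  suite <- make_suite(base, 4, 0, seed = 5)
  sched <- search_schedule(c(80, 40, 20, 10))
  for (tc in suite) {
    res <- reg_maxs(tc$transformed, base, sched)
    d_init <- res$trace[1, ncol(res$trace)]
    expect_lte(tail(res$dissimilarity, 1), d_init)
    # every applied scale obeyed the bounds
    expect_true(all(res$cum_scales >= 0.5 - 1e-9 &
                    res$cum_scales <= 2 + 1e-9))
  }
})

test_that("registration is deterministic", {
  base <- generate_tree(tree_gen_params(n_nodes = 100, seed = 33))
  tc <- make_suite(base, 1, 0, seed = 7)[[1]]
  sched <- search_schedule(c(80, 40, 20, 10))
  r1 <- reg_maxs(tc$transformed, base, sched)
  r2 <- reg_maxs(tc$transformed, base, sched)
  expect_identical(r1$total_transform, r2$total_transform)
  expect_identical(r1$trace, r2$trace)
})

test_that("anisotropically scaled cases never worsen beyond initialization", {
  base <- generate_tree(tree_gen_params(n_nodes = 120, seed = 35))
  hard <- apply_transform(base, affine_transform(
    scales = c(1.12, 0.61, 1.27), angles_deg = c(10, -5, 20),
    translation = c(8, -12, 4), center = centroid(base)))
  res <- reg_maxs(hard, base, search_schedule(c(80, 40, 20, 10)))
  expect_lte(tail(res$dissimilarity, 1),
             res$trace[1, ncol(res$trace)])
})
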