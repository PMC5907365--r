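test_that("correspondences pair by id or by nearest neighbor", {
  m <- toy_morphology()
  for (mode in c("known", "nearest"))
    expect_equal(correspondences(m, m, mode)$distance, rep(0, 3))

  ref <- morphology(data.frame(id = 1:2, type = 3, x = c(0, 10), y = 0,
                               z = 0, radius = 1, parent = c(-1, 1)))
  test <- morphology(data.frame(id = 1:2, type = 3, x = c(1, 20), y = 0,
                                z = 0, radius = 1, parent = c(-1, 1)))
  nn <- correspondences(ref, test, "nearest")
  # ref node at x=10 is nearer to the test node at x=1 (9 um) than x=20
  expect_equal(nn$distance, c(1, 9))
  expect_equal(nn$test_id, c(1, 1))

  relabeled <- test
  relabeled$id <- c(5L, 6L)
  relabeled$parent <- c(-1L, 5L)
  expect_error(correspondences(ref, relabeled, "known"), "matching node ids")
})

test_that("nearest-neighbor distances never exceed known-correspondence ones", {
  base <- generate_tree(tree_gen_params(n_nodes = 200, seed = 12))
  moved <- add_noise(base, 3, seed = 1)
  known <- correspondences(base, moved, "known")$distance
  nn <- correspondences(base, moved, "nearest")$distance
  expect_true(all(nn <= known + 1e-6))
})

test_that("sign test matches the exact binomial tail", {
  r <- sign_test(rep(1, 10), threshold = 5)
  expect_equal(r$p_value, 0.5^10)
  expect_true(r$significant)
  expect_equal(r$k, 10)

  r <- sign_test(c(rep(1, 50), rep(9, 50)), threshold = 5)
  expect_false(r$significant)
  expect_gt(r$p_value, 0.4)

  r <- sign_test(rep(10, 5), threshold = 5)
  expect_equal(r$p_value, 1)
  expect_false(r$significant)

  # ties at the threshold count as failures
  expect_equal(sign_test(rep(5, 8), threshold = 5)$k, 0)
  expect_error(sign_test(numeric(0), 5), "no distances")
})

test_that("sign test equals exhaustive enumeration for all n <= 12", {
  # oracle: P(X >= k) for X ~ Binomial(n, 1/2) by summing the pmf
  for (n in 1:12) {
    for (k in 0:n) {
      d <- c(rep(0, k), rep(2, n - k))     # k below threshold 1
      p_oracle <- sum(choose(n, k:n)) / 2^n
      expect_equal(sign_test(d, threshold = 1)$p_value, p_oracle,
                   tolerance = 1e-12)
    }
  }
})

test_that("wilcoxon variant is available for sensitivity analysis", {
  set.seed(2)
  d <- abs(rnorm(40, 2, 1))
  r <- sign_test(d, threshold = 8, method = "wilcoxon")
  expect_true(r$p_value < 0.01)
})

test_that("performance summary regroups distances per test and per point", {
  all_zero <- matrix(0, 10, 8)
  s <- performance_summary(all_zero, threshold = 10)
  expect_equal(s$percent_tests, 100)
  expect_equal(s$percent_points, 100)

  all_far <- matrix(100, 10, 8)
  s <- performance_summary(all_far, threshold = 10)
  expect_equal(s$percent_tests, 0)
  expect_equal(s$percent_points, 0)

  # 3 tests of 10 points: two all-below, one all-above; per point only 3
  # observations, so no point can reach p < 0.01
  d <- cbind(rep(0, 10), rep(0, 10), rep(99, 10))
  s <- performance_summary(d, threshold = 10)
  expect_equal(s$percent_tests, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(s$percent_points, 0)
})

test_that("pca registration recovers rotations and principal-axis scaling", {
  set.seed(33)
  # anisotropic point blob with clearly distinct variances
  pts <- cbind(rnorm(400, 0, 30), rnorm(400, 0, 12), rnorm(400, 0, 4))
  ref <- morphology(data.frame(id = 1:400, type = 3, x = pts[, 1],
                               y = pts[, 2], z = pts[, 3], radius = 1,
                               parent = c(-1, seq_len(399))))
  expect_equal(pca_register(ref, ref)[1:3, 1:3], diag(3), tolerance = 1e-6)

  rot20 <- affine_transform(angles_deg = c(0, 0, 20))
  test <- apply_transform(ref, rot20)
  m <- pca_register(test, ref)
  # recovered rotation should undo the 20 degree turn
  expect_equal(m[1:3, 1:3] %*% as.matrix(rot20)[1:3, 1:3], diag(3),
               tolerance = 1e-3)

  sc <- apply_transform(ref, affine_transform(scales = c(1.5, 1, 1)))
  m <- pca_register(sc, ref)
  expect_equal(sort(attr(m, "scales")), c(1 / 1.5, 1, 1), tolerance = 1e-3)
  # sample principal axes deviate slightly from the world axes, so the
  # undo is approximate at the scale of that deviation
  back <- apply_transform(sc, m)
  expect_lt(max(abs(back$x - ref$x)), 1)
})

test_that("pca registration is invariant to node order and pre-translation", {
  set.seed(44)
  pts <- cbind(rnorm(200, 0, 25), rnorm(200, 0, 10), rnorm(200, 0, 3))
  ref <- morphology(data.frame(id = 1:200, type = 3, x = pts[, 1],
                               y = pts[, 2], z = pts[, 3], radius = 1,
                               parent = c(-1, seq_len(199))))
  test <- apply_transform(ref, affine_transform(angles_deg = c(5, -8, 12),
                                                translation = c(40, -10, 5)))
  m1 <- pca_register(test, ref)
  perm <- sample(200)
  shuffled <- morphology(as.data.frame(test)[perm, ])
  m2 <- pca_register(shuffled, ref)
  expect_equal(m1, m2, tolerance = 1e-9, ignore_attr = TRUE)
  moved <- apply_transform(test, affine_transform(translation = c(-7, 3, 9)))
  m3 <- pca_register(moved, ref)
  expect_equal(m1[1:3, 1:3], m3[1:3, 1:3], tolerance = 1e-9)
  # registration error stays tiny in all variants
  reg <- apply_transform(test, m1)
  expect_lt(max(abs(reg$x - ref$x), abs(reg$y - ref$y)), 1e-6)
})

test_that("pca registration warns on ambiguous principal variances", {
  # points on a circle have exactly equal variance along x and y
  ang <- 2 * pi * (0:99) / 100
  iso <- morphology(data.frame(id = 1:100, type = 3,
                               x = 10 * cos(ang), y = 10 * sin(ang),
                               z = 0.1 * rep(c(-1, 1), 50), radius = 1,
                               parent = c(-1, seq_len(99))))
  expect_warning(pca_register(iso, iso), "ambiguous")
})
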