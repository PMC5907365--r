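test_that("voxelization uses origin-centered round-half-up indexing", {
  node_at <- function(x, y = 0, z = 0)
    morphology(data.frame(id = 1, type = 1, x = x, y = y, z = z,
                          radius = 1, parent = -1))
  expect_equal(unname(voxel_indices(voxelize(node_at(0), 10))[1, ]),
               c(0, 0, 0))
  # voxel 0 covers [-5, 5): 5.1 spills over, 4.9 does not
  expect_equal(unname(voxel_indices(voxelize(node_at(5.1), 10))[1, ]),
               c(1, 0, 0))
  expect_equal(unname(voxel_indices(voxelize(node_at(4.9), 10))[1, ]),
               c(0, 0, 0))
  expect_error(voxelize(node_at(0), 0), "positive")
})

test_that("long edges are filled by resampling before voxelization", {
  two <- morphology(data.frame(id = 1:2, type = 3, x = c(0, 100), y = 0,
                               z = 0, radius = 1, parent = c(-1, 1)))
  vs <- voxelize(two, 10)
  idx <- voxel_indices(vs)
  expect_equal(length(vs), 11)
  expect_setequal(idx[, 1], 0:10)
  expect_true(all(idx[, 2] == 0) && all(idx[, 3] == 0))
})

test_that("voxelization is equivariant under whole-voxel translations", {
  m <- generate_tree(tree_gen_params(n_nodes = 120, seed = 8))
  v <- 10
  base_idx <- voxel_indices(voxelize(m, v))
  shifted <- apply_transform(m, affine_transform(translation = c(3, -2, 1) * v))
  shift_idx <- voxel_indices(voxelize(shifted, v))
  reorder <- function(ix) ix[order(ix[, 1], ix[, 2], ix[, 3]), ]
  expect_equal(reorder(shift_idx),
               reorder(sweep(base_idx, 2, c(3, -2, 1), "+")))
})

test_that("pairwise dissimilarity is the Jaccard complement", {
  a <- make_voxel_set(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 10)
  b <- make_voxel_set(rbind(c(2, 0, 0), c(3, 0, 0)), 10)
  expect_equal(dissimilarity(a, b), 0.75)  # |inter| 1, |union| 4
  expect_equal(dissimilarity(a, a), 0)
  disj <- make_voxel_set(rbind(c(9, 9, 9)), 10)
  expect_equal(dissimilarity(a, disj), 1)
  expect_error(dissimilarity(a, make_voxel_set(rbind(c(0, 0, 0)), 5)),
               "voxel sizes")
})

test_that("dissimilarity properties hold on random voxel-set pairs", {
  set.seed(42)
  for (i in 1:200) {
    na <- sample(1:30, 1); nb <- sample(1:30, 1)
    a_idx <- unique(matrix(sample(-3:3, 3 * na, replace = TRUE), ncol = 3))
    b_idx <- unique(matrix(sample(-3:3, 3 * nb, replace = TRUE), ncol = 3))
    a <- make_voxel_set(a_idx, 10)
    b <- make_voxel_set(b_idx, 10)
    d <- dissimilarity(a, b)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, dissimilarity(b, a))
    akeys <- sort(a$keys); bkeys <- sort(b$keys)
    if (identical(akeys, bkeys)) expect_equal(d, 0) else expect_gt(d, 0)
    if (length(intersect(akeys, bkeys)) == 0) expect_equal(d, 1)
    # hand formula on the raw sets
    inter <- length(intersect(akeys, bkeys))
    expect_equal(d, 1 - inter / (length(akeys) + length(bkeys) - inter))
  }
})

test_that("centric dissimilarity removes pure translation differences", {
  m <- generate_tree(tree_gen_params(n_nodes = 100, seed = 2))
  ref <- voxelize(m, 10)
  moved <- apply_transform(m, affine_transform(translation = c(50, 0, 0)))
  expect_equal(centric_dissimilarity(moved, ref, 10), 0)
  expect_equal(centric_dissimilarity(m, ref, 10), 0)
})

test_that("centric dissimilarity of a scaled line matches hand enumeration", {
  line <- line_morphology(3, spacing = 10)      # voxels (0,1,2) at v=10
  ref <- voxelize(line, 10)
  doubled <- apply_transform(line, affine_transform(scales = c(2, 2, 2),
                                                    center = centroid(line)))
  # doubled spans x in [-10, 30]: voxels -1..3 (5 voxels), same voxel
  # centroid (x=10) as the reference; overlap is voxels 0..2
  expect_equal(centric_dissimilarity(doubled, ref, 10), 1 - 3 / 5)
})

test_that("occupancy histograms count, weight and normalize as defined", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  a <- make_voxel_set(sq, 10)
  h_same <- occupancy_histogram(list(a, a))
  expect_equal(h_same$count, c(0, 4))
  expect_equal(h_same$normalized, c(0, 1))

  b <- make_voxel_set(sq + 5, 10)               # disjoint copy
  h_disj <- occupancy_histogram(list(a, b))
  expect_equal(h_disj$count, c(8, 0))
  expect_equal(h_disj$normalized, c(1, 0))

  # 4 shared + 2 unique each
  c1 <- make_voxel_set(rbind(sq, c(5, 5, 5), c(6, 5, 5)), 10)
  c2 <- make_voxel_set(rbind(sq, c(-5, -5, -5), c(-6, -5, -5)), 10)
  h <- occupancy_histogram(list(c1, c2))
  expect_equal(h$count, c(4, 4))
  expect_equal(h$weighted, c(4, 8))
  expect_equal(h$normalized, c(1 / 3, 2 / 3))
  expect_equal(sum(h$normalized), 1)
  expect_error(occupancy_histogram(list()), "non-empty")
})

test_that("k identical sets put all occupancy mass at k", {
  a <- make_voxel_set(rbind(c(0, 0, 0), c(2, 1, 0), c(0, 1, 1)), 5)
  for (k in c(2, 3, 5)) {
    h <- occupancy_histogram(rep(list(a), k))
    expect_equal(h$normalized[k], 1)
    expect_equal(group_dissimilarity(h), 0)
  }
})

test_that("group dissimilarity equals the EMD closed form and oracle", {
  h <- occupancy_histogram(list(
    make_voxel_set(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                         c(5, 5, 5), c(6, 5, 5)), 10),
    make_voxel_set(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                         c(-5, -5, -5), c(-6, -5, -5)), 10)))
  expect_equal(group_dissimilarity(h), 1 / 3)

  disj <- occupancy_histogram(list(make_voxel_set(rbind(c(0, 0, 0)), 10),
                                   make_voxel_set(rbind(c(1, 1, 1)), 10)))
  expect_equal(group_dissimilarity(disj), 1)
  expect_equal(group_dissimilarity(disj, normalized = TRUE), 1)

  # closed form vs independent CDF-based oracle on random histograms
  set.seed(17)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    sets <- lapply(seq_len(n), function(j)
      make_voxel_set(unique(matrix(sample(-1:1, 3 * sample(1:20, 1),
                                          replace = TRUE), ncol = 3)), 10))
    h <- occupancy_histogram(sets)
    expect_equal(group_dissimilarity(h),
                 emd_cdf_oracle(h$normalized, n), tolerance = 1e-9)
  }
})

test_that("voxel set and histogram CSV exports round-trip", {
  a <- make_voxel_set(rbind(c(1, 2, 3), c(0, 0, 0), c(-1, 5, 2)), 10)
  path <- tempfile(fileext = ".csv")
  write_voxel_csv(a, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$i, sort(back$i))
  h <- occupancy_histogram(list(a, a))
  write_histogram_csv(h, path)
  hb <- utils::read.csv(path)
  expect_equal(hb$normalized, h$normalized)
})
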