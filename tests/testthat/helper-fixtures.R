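# Small fixtures shared across test files; everything built in code.

# three-node toy morphology: root at origin, two further nodes
toy_morphology <- function() {
  morphology(data.frame(
    id = 1:3, type = c(1L, 3L, 3L),
    x = c(0, 10, 10), y = c(0, 0, 10), z = c(0, 0, 0),
    radius = 1, parent = c(-1L, 1L, 2L)))
}

toy_swc_lines <- c("1 1 0 0 0 1 -1",
                   "2 3 10 0 0 1 1",
                   "3 3 10 10 0 1 2")

write_toy_swc <- function(lines = toy_swc_lines) {
  path <- tempfile(fileext = ".swc")
  writeLines(lines, path)
  path
}

# build a voxel_set directly from an integer index matrix (test back door)
make_voxel_set <- function(idx, voxel_size) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  regmaxs:::new_voxel_set(unique(regmaxs:::voxel_keys(idx)), voxel_size)
}

# independent EMD oracle: sum of absolute CDF differences between the
# normalized histogram and the point mass at occupancy N
emd_cdf_oracle <- function(normalized, n) {
  target <- c(rep(0, n - 1), 1)
  sum(abs(cumsum(normalized) - cumsum(target)))
}

# straight-line morphology along x with given node spacing
line_morphology <- function(n, spacing = 10, y = 0, z = 0) {
  morphology(data.frame(
    id = seq_len(n), type = 3L,
    x = (seq_len(n) - 1) * spacing, y = y, z = z,
    radius = 0.5, parent = c(-1L, seq_len(n - 1))))
}

expect_morph_equal <- function(a, b, tol = 1e-6) {
  expect_equal(a$id, b$id)
  expect_equal(a$parent, b$parent)
  expect_equal(a$type, b$type)
  expect_equal(a$x, b$x, tolerance = tol)
  expect_equal(a$y, b$y, tolerance = tol)
  expect_equal(a$z, b$z, tolerance = tol)
  expect_equal(a$radius, b$radius, tolerance = tol)
}
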