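#' Parameters for the synthetic tree generator
#'
#' The generator grows a connected tree by a seeded stochastic branching
#' walk, emulating the gross layout of a dendritic arbor: mostly
#' direction-persistent neurite segments of roughly constant step length,
#' occasional branch points, and a bounded spatial extent (default
#' half-widths 150 x 150 x 50 um, a moderately flattened arbor). It does
#' not attempt biophysically realistic dendrite synthesis.
#'
#' @param n_nodes number of nodes (>= 1).
#' @param spatial_extent numeric(3), half-widths of the allowed box around
#'   the origin in um; the walk is reflected back at the faces.
#' @param branch_probability probability per grown node of opening a new
#'   branch at that node.
#' @param step_length_mean,step_length_sd mean and sd of segment step
#'   lengths in um.
#' @param seed integer seed; the same parameters always generate the same
#'   tree.
#' @return An object of class `tree_gen_params`.
#' @export
tree_gen_params <- function(n_nodes = 300, spatial_extent = c(150, 150, 50),
                            branch_probability = 0.12,
                            step_length_mean = 10, step_length_sd = 2,
                            seed = 1L) {
  stopifnot(n_nodes >= 1, all(spatial_extent > 0),
            branch_probability >= 0, branch_probability <= 1,
            step_length_mean > 0, step_length_sd >= 0)
  structure(list(n_nodes = as.integer(n_nodes),
                 spatial_extent = as.numeric(spatial_extent),
                 branch_probability = branch_probability,
                 step_length_mean = step_length_mean,
                 step_length_sd = step_length_sd,
                 seed = as.integer(seed)),
            class = "tree_gen_params")
}

# run code with a private RNG state, leaving the caller's stream untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic tree morphology
#'
#' Grows a connected tree with exactly `n_nodes` nodes by a stochastic
#' branching walk (see [tree_gen_params()]). All coordinates stay within
#' `spatial_extent` of the origin. Deterministic given the seed.
#'
#' @param params a [tree_gen_params()] object.
#' @return A [morphology()] with `n_nodes` nodes and `n_nodes - 1` edges.
#' @export
generate_tree <- function(params = tree_gen_params()) {
  stopifnot(inherits(params, "tree_gen_params"))
  n <- params$n_nodes
  ext <- params$spatial_extent
  with_seed(params$seed, {
    xyz <- matrix(0, n, 3)
    dir <- matrix(0, n, 3)        # growth direction carried by each tip
    parent <- integer(n)
    parent[1] <- -1L
    dir[1, ] <- c(1, 0, 0)
    tips <- 1L                    # indices of extendable tips
    i <- 1L
    while (i < n) {
      tip <- tips[sample.int(length(tips), 1L)]
      step <- abs(stats::rnorm(1, params$step_length_mean, params$step_length_sd))
      # direction persistence with angular jitter
      d <- dir[tip, ] + stats::rnorm(3, 0, 0.4)
      d <- d / sqrt(sum(d^2))
      p <- xyz[tip, ] + step * d
      # reflect at the box faces to stay inside the extent
      for (ax in 1:3) {
        if (p[ax] > ext[ax]) { p[ax] <- 2 * ext[ax] - p[ax]; d[ax] <- -d[ax] }
        if (p[ax] < -ext[ax]) { p[ax] <- -2 * ext[ax] - p[ax]; d[ax] <- -d[ax] }
        p[ax] <- min(max(p[ax], -ext[ax]), ext[ax])
      }
      i <- i + 1L
      xyz[i, ] <- p
      dir[i, ] <- d
      parent[i] <- tip
      # the new node replaces its parent as a tip; branching keeps the
      # parent extendable so a second daughter can sprout there later
      if (stats::runif(1) < params$branch_probability) {
        tips <- c(tips, i)
      } else {
        tips[tips == tip] <- i
      }
    }
    morphology(data.frame(id = seq_len(n), type = 3L,
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          radius = 0.5, parent = parent))
  })
}

#' Add Gaussian positional noise to a morphology
#'
#' Adds independent zero-mean Gaussian noise of standard deviation `std`
#' to every coordinate of every node. Topology, ids and radii are
#' unchanged. This emulates the biological variability in fine dendrite
#' placement between specimens of a stereotypic neuron type.
#'
#' @param m a [morphology()].
#' @param std noise standard deviation in um (>= 0).
#' @param seed optional integer seed for reproducibility.
#' @return A [morphology()].
#' @export
add_noise <- function(m, std, seed = NULL) {
  stopifnot(inherits(m, "morphology"))
  if (!is.numeric(std) || length(std) != 1 || std < 0)
    stop("add_noise: std must be a non-negative number")
  if (std == 0) return(m)
  run <- function() {
    out <- as.data.frame(m)
    n <- nrow(out)
    out$x <- out$x + stats::rnorm(n, 0, std)
    out$y <- out$y + stats::rnorm(n, 0, std)
    out$z <- out$z + stats::rnorm(n, 0, std)
    morphology(out)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Build a randomized-transform test suite
#'
#' For every noise standard deviation and every random transform draw,
#' emits a test case holding the base morphology `M`, its noisy version
#' `N(M)`, the transformed noisy version `TN(M) = T(N(M))` and the true
#' transform `T`. Node ids are identical across the three morphologies, so
#' point correspondence is known by construction. Transforms are drawn
#' from `ranges` (defaults: translation U[-20, 20] um, rotation
#' U[-30, 30] deg, scale U[0.5, 2] per axis) and applied about the noisy
#' morphology's centroid.
#'
#' @param base a [morphology()].
#' @param n_transforms number of random transforms per noise level.
#' @param noise_stds numeric vector of noise standard deviations in um
#'   (0 = noiseless protocol).
#' @param ranges a [transform_ranges()] object.
#' @param seed integer seed.
#' @param max_mas optional upper bound on the [mas()] of drawn transforms;
#'   draws are rejected and redrawn until the bound holds (used to
#'   stratify suites at low anisotropic scaling).
#' @return A list of `test_case` objects with fields `base`, `noisy`,
#'   `transformed`, `true_transform`, `noise_std`, `mas`.
#' @export
make_suite <- function(base, n_transforms, noise_stds = 0,
                       ranges = transform_ranges(), seed = 1L,
                       max_mas = NULL) {
  stopifnot(inherits(base, "morphology"), n_transforms >= 1)
  with_seed(seed, {
    cases <- list()
    for (std in noise_stds) {
      for (k in seq_len(n_transforms)) {
        noisy <- if (std == 0) base else {
          out <- as.data.frame(base)
          n <- nrow(out)
          out$x <- out$x + stats::rnorm(n, 0, std)
          out$y <- out$y + stats::rnorm(n, 0, std)
          out$z <- out$z + stats::rnorm(n, 0, std)
          morphology(out)
        }
        repeat {
          tr <- random_transform(ranges, center = centroid(noisy))
          if (is.null(max_mas) || mas(tr$scales) < max_mas) break
        }
        cases[[length(cases) + 1L]] <- structure(
          list(base = base, noisy = noisy,
               transformed = apply_transform(noisy, tr),
               true_transform = tr, noise_std = std,
               mas = mas(tr$scales)),
          class = "test_case")
      }
    }
    cases
  })
}
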