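small_nerve <- function(...) {
  nerve_params(image_size_px = c(128, 128), n_planes = 8, curvature_tilt = 2,
               ...)
}

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(small_nerve(break_rate = 1.2), "probabilities")
  expect_error(nerve_params(image_size_px = c(32, 128)), ">= 64")
  expect_error(nerve_params(curvature_tilt = 20, n_planes = 20), "smaller")
  expect_error(small_nerve(n_fibers = -1), "n_fibers")
  expect_error(small_nerve(swirl_turns = 0), "positive")
})

test_that("empty parameterizations give empty truth", {
  g <- generate_nerve_stack(small_nerve(n_fibers = 0, terminal_density = 0,
                                        seed = 3))
  expect_equal(g$truth$true_fragment_count, 0L)
  expect_false(any(g$truth$true_coverage_mask))
  # stack is pure noise, bounded by a few noise SDs
  expect_lt(max(g$stack$voxels), 6 * 0.02)
})

test_that("generation is a pure function of parameters and seed", {
  p <- small_nerve(n_fibers = 5, terminal_density = 0.5, break_rate = 0.3,
                   seed = 7)
  g1 <- generate_nerve_stack(p)
  g2 <- generate_nerve_stack(p)
  expect_identical(g1$stack$voxels, g2$stack$voxels)
  expect_identical(g1$truth$true_coverage_mask, g2$truth$true_coverage_mask)
  g3 <- generate_nerve_stack(small_nerve(n_fibers = 5, terminal_density = 0.5,
                                         break_rate = 0.3, seed = 8))
  expect_false(identical(g1$stack$voxels, g3$stack$voxels))
  # generator does not disturb the caller's RNG stream
  withr::with_seed(99, {
    before <- runif(1)
  })
  withr::with_seed(99, {
    invisible(generate_nerve_stack(p))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("non-touching layouts plant exactly the requested fragment count", {
  for (seed in 1:5) {
    p <- small_nerve(n_fibers = 5, terminal_density = 0, break_rate = 0,
                     coverage_loss = 0, seed = seed, non_touching = TRUE)
    g <- generate_nerve_stack(p)
    expect_equal(g$truth$planted_pieces, 5L)
    expect_equal(g$truth$true_fragment_count, 5L)
    expect_equal(oracle_fragment_count(g$truth$true_coverage_mask, 8L), 5L)
  }
})

test_that("recorded truth equals the BFS oracle on the planted mask", {
  cases <- list(
    small_nerve(n_fibers = 6, break_rate = 0.4, seed = 11),
    small_nerve(n_fibers = 3, terminal_density = 1, seed = 12),
    small_nerve(n_fibers = 8, coverage_loss = 0.4, break_rate = 0.2,
                seed = 13),
    small_nerve(n_fibers = 4, seed = 14, connectivity = 4L)
  )
  for (p in cases) {
    g <- generate_nerve_stack(p)
    expect_equal(g$truth$true_fragment_count,
                 oracle_fragment_count(g$truth$true_coverage_mask,
                                       p$connectivity))
  }
})

test_that("fibers land in the sub-basal band, terminals higher, with tilt", {
  p <- nerve_params(image_size_px = c(96, 96), n_planes = 12, n_fibers = 4,
                    terminal_density = 1, curvature_tilt = 4, noise_sd = 0,
                    seed = 5)
  g <- generate_nerve_stack(p)
  v <- g$stack$voxels
  fib_z <- apply(v * array(rep(g$truth$sub_basal_mask, 12), dim = dim(v)),
                 3, sum)
  ter_z <- apply(v * array(rep(g$truth$terminal_mask &
                                 !g$truth$sub_basal_mask, 12), dim = dim(v)),
                 3, sum)
  expect_lt(which.max(fib_z), which.max(ter_z))
  # corner drift: brightest plane under the far corner is deeper than
  # under the near corner
  near <- v[1:20, 1:20, ]; far <- v[77:96, 77:96, ]
  nz <- which.max(apply(near, 3, sum)); fz <- which.max(apply(far, 3, sum))
  expect_gt(fz, nz)
})

test_that("mean degradation is monotone over seeds", {
  seeds <- 1:8
  stats_at <- function(br, cl) {
    vals <- vapply(seeds, function(s) {
      p <- small_nerve(n_fibers = 8, terminal_density = 0, break_rate = br,
                       coverage_loss = cl, noise_sd = 0, seed = s)
      tr <- generate_nerve_stack(p)$truth
      c(k = tr$true_fragment_count, cov = sum(tr$true_coverage_mask))
    }, numeric(2))
    rowMeans(vals)
  }
  by_break <- sapply(c(0, 0.3, 0.6), stats_at, cl = 0)
  expect_true(all(diff(by_break["k", ]) > 0))
  by_loss <- sapply(c(0, 0.4, 0.8), function(cl) stats_at(0, cl))
  expect_true(all(diff(by_loss["cov", ]) < 0))
})
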