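test_that("tile grid partitions the image with near-equal tiles, larger first", {
  g <- tile_grid(c(800, 800))
  expect_equal(nrow(g$tiles), 9L)
  hs <- g$tiles$y1 - g$tiles$y0 + 1L
  ws <- g$tiles$x1 - g$tiles$x0 + 1L
  expect_true(all(hs %in% c(266L, 267L)))
  expect_true(all(ws %in% c(266L, 267L)))
  expect_equal(sum(unique(g$tiles[, c("grid_row", "y0", "y1")])$y1 -
                     unique(g$tiles[, c("grid_row", "y0", "y1")])$y0 + 1L), 800L)

  g9 <- tile_grid(c(9, 9))
  expect_true(all(g9$tiles$y1 - g9$tiles$y0 + 1L == 3L))

  g10 <- tile_grid(c(10, 10))
  sizes <- (g10$tiles$y1 - g10$tiles$y0 + 1L)[g10$tiles$grid_col == 1L]
  expect_equal(sizes, c(4L, 3L, 3L))

  # partition property: every pixel covered exactly once
  for (dims in list(c(10, 10), c(64, 97), c(800, 800))) {
    g <- tile_grid(dims)
    cover <- matrix(0L, dims[1], dims[2])
    for (i in seq_len(nrow(g$tiles))) {
      tl <- g$tiles[i, ]
      cover[tl$y0:tl$y1, tl$x0:tl$x1] <- cover[tl$y0:tl$y1, tl$x0:tl$x1] + 1L
    }
    expect_true(all(cover == 1L))
  }

  expect_error(tile_grid(c(2, 10), rows = 3), "empty")
})

test_that("split then stitch is the identity on masks", {
  for (seed in 1:5) {
    m <- random_mask(73, 91, 0.4, seed)
    g <- tile_grid(dim(m))
    tiles <- split_tiles(m, g)
    expect_equal(length(tiles), 9L)
    back <- stitch_tiles(tiles, g)
    expect_equal(unclass(back), m, ignore_attr = TRUE)
  }
  # all-empty tiles give an empty full mask
  g <- tile_grid(c(30, 30))
  empt <- stitch_tiles(split_tiles(matrix(FALSE, 30, 30), g), g)
  expect_false(any(empt))
  # missing tile is an error
  expect_error(stitch_tiles(split_tiles(matrix(TRUE, 30, 30), g)[-1], g),
               "expected 9 tiles")
})

test_that("standard-deviation projection follows the population formula", {
  s <- array(c(0, 10), dim = c(1, 1, 2))
  expect_equal(as.numeric(sd_project(s)), 5)
  s3 <- array(c(2, 4, 9), dim = c(1, 1, 3))
  expect_equal(as.numeric(sd_project(s3)), sqrt(26 / 3))

  const <- array(3, dim = c(4, 5, 6))
  expect_true(all(sd_project(const) == 0))

  expect_warning(p1 <- sd_project(const, 2, 2), "single-plane")
  expect_true(all(p1 == 0))

  for (seed in 1:10) {
    st <- withr::with_seed(seed, array(runif(6 * 7 * 5), dim = c(6, 7, 5)))
    expect_lt(max(abs(sd_project(st) - oracle_sd_project(st, 1, 5))), 1e-9)
    expect_lt(max(abs(sd_project(st, 2, 4) - oracle_sd_project(st, 2, 4))),
              1e-9)
  }
  expect_error(sd_project(const, 3, 9), "invalid plane interval")
})

test_that("binarization thresholds as specified, Otsu splits bimodal images", {
  img <- matrix(c(0, 10), 20, 20)
  m <- binarize(img, "manual", threshold = 5)
  expect_equal(unclass(m), img == 10, ignore_attr = TRUE)
  expect_false(any(binarize(img, "manual", threshold = 10)))
  expect_error(binarize(img, "manual"), "requires a threshold")

  bim <- withr::with_seed(1, matrix(sample(c(rnorm(500, 20, 3),
                                             rnorm(500, 200, 3))), 40, 25))
  bm <- binarize(bim, "otsu")
  thr <- attr(bm, "threshold_used")
  expect_gt(thr, 30)
  expect_lt(thr, 190)
  expect_equal(unclass(bm), bim > thr, ignore_attr = TRUE)

  expect_warning(empty <- binarize(matrix(0, 8, 8), "otsu"), "constant")
  expect_false(any(empty))
})

test_that("auto plane bounds find the brightest window", {
  vox <- array(0.01, dim = c(16, 16, 12))
  vox[, , 5:7] <- 0.8
  expect_equal(unname(auto_zbounds(vox, width = 3)), c(5L, 7L))
  expect_equal(unname(auto_zbounds(vox, width = 3, z_range = c(8, 12))[1]), 8L)
})

test_that("a fiber crossing tile boundaries stitches without seam fragments", {
  for (seed in 1:20) {
    m <- matrix(FALSE, 60, 60)
    # random diagonal-ish polyline spanning the whole image
    y <- 1; x <- 1
    withr::with_seed(seed, {
      while (y < 60 && x < 60) {
        m[y, x] <- TRUE
        step <- sample(1:3, 1)
        if (step == 1) y <- y + 1 else if (step == 2) x <- x + 1 else {
          y <- y + 1; x <- x + 1
        }
      }
    })
    g <- tile_grid(dim(m))
    back <- stitch_tiles(split_tiles(m, g), g)
    expect_equal(label_fragments(back)$n_fragments,
                 oracle_fragment_count(m, 8L))
    expect_equal(label_fragments(back)$n_fragments, 1L)
  }
})

test_that("project_stack recovers planted structure from a tilted stack", {
  p <- nerve_params(image_size_px = c(128, 128), n_planes = 10, n_fibers = 4,
                    terminal_density = 0.4, curvature_tilt = 3, seed = 21)
  g <- generate_nerve_stack(p)
  pr <- project_stack(g$stack, layer = "sub_basal")
  expect_equal(dim(pr$mask), c(128L, 128L))
  # recovered sub-basal foreground should mostly agree with the planted mask
  truth <- g$truth$sub_basal_mask
  inter <- sum(pr$mask & truth)
  expect_gt(inter / sum(truth), 0.7)
  expect_gt(inter / max(sum(pr$mask), 1L), 0.7)
  pe <- project_stack(g$stack, layer = "epithelial")
  expect_gt(sum(pe$mask & g$truth$terminal_mask) /
              max(sum(g$truth$terminal_mask), 1L), 0.6)
  expect_equal(nrow(pr$provenance$zbounds), 9L)
})
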