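test_that("preprocessing rescales to 8-bit and smoothing is optional", {
  expect_true(all(preprocess_dapi(matrix(7, 16, 16)) == 0))
  two <- matrix(c(10, 20), 16, 16)
  out <- preprocess_dapi(two, sigma = 0)
  expect_equal(sort(unique(as.vector(out))), c(0, 255))
  img <- withr::with_seed(1, matrix(runif(900), 30, 30))
  expect_equal(preprocess_dapi(img, sigma = 0),
               round(255 * (img - min(img)) / diff(range(img))))
})

test_that("profile extraction uses interior evenly spaced coordinates", {
  img <- matrix(runif(600 * 600), 600, 600)
  ps <- extract_profiles(img)
  expect_equal(ps$n_profiles, 10L)
  coords <- vapply(ps$profiles, `[[`, numeric(1), "coord")
  axes <- vapply(ps$profiles, `[[`, character(1), "axis")
  expect_equal(coords[axes == "column"], c(100, 200, 300, 400, 500))
  expect_equal(coords[axes == "row"], c(100, 200, 300, 400, 500))
  expect_equal(ps$profiles[[1]]$values, img[, 100])

  # transposition swaps the row and column profile sets
  pt <- extract_profiles(t(img))
  cols <- function(p) lapply(p$profiles[vapply(p$profiles, `[[`,
                                               character(1), "axis")
                                        == "column"], `[[`, "values")
  rows <- function(p) lapply(p$profiles[vapply(p$profiles, `[[`,
                                               character(1), "axis")
                                        == "row"], `[[`, "values")
  expect_equal(cols(pt), rows(ps))
  expect_equal(rows(pt), cols(ps))

  expect_error(extract_profiles(matrix(0, 4, 100)), "too small")
})

test_that("first derivative is exact on ramps and converges on sines", {
  expect_true(all(first_derivative(rep(5, 10)) == 0))
  expect_equal(first_derivative(c(0, 1, 2, 3)), c(1, 1, 1, 1))
  expect_error(first_derivative(c(1, 2)), "at least 3")

  amp_err <- vapply(c(50, 200, 1000), function(T) {
    x <- 0:(3 * T)
    d <- first_derivative(2 * sin(2 * pi * x / T))
    abs(max(d) - 2 * pi * 2 / T) / (2 * pi * 2 / T)
  }, numeric(1))
  expect_true(all(diff(amp_err) < 0))
  expect_lt(amp_err[3], 1e-4)
})

test_that("transition detection finds nuclei and enforces alternation", {
  expect_equal(detect_transitions(rep(0, 50))$n_transitions, 0L)

  # one clean nucleus: rise then fall
  x <- seq(0, 1, length.out = 101)
  bump <- exp(-((x - 0.5) / 0.12)^2)
  tr <- detect_transitions(first_derivative(bump))
  expect_equal(tr$n_peaks, 1L)
  expect_equal(tr$n_troughs, 1L)
  expect_lt(tr$peaks$index, tr$troughs$index)

  # K equally spaced nuclei give K peaks and K troughs
  for (K in c(3, 7)) {
    prof <- c(rep(c(rep(0, 10), rep(8, 10)), K), rep(0, 10))
    tr <- detect_transitions(first_derivative(prof))
    expect_equal(tr$n_peaks, K)
    expect_equal(tr$n_troughs, K)
    idx <- sort(c(tr$peaks$index, tr$troughs$index))
    kinds <- ifelse(idx %in% tr$peaks$index, "p", "t")
    expect_true(all(kinds == rep(c("p", "t"), K)))
  }

  # plateaus resolve to their leftmost index
  d <- c(0, 2, 2, 2, 0, -2, -2, 0)
  tr <- detect_transitions(d, min_prominence = 1)
  expect_equal(tr$peaks$index, 2L)
  expect_equal(tr$troughs$index, 6L)

  # same-sign consecutive extrema: the lesser one is dropped
  d2 <- c(0, 3, 0.5, 5, 0, -4, 0)
  tr2 <- detect_transitions(d2, min_prominence = 0.1)
  expect_equal(tr2$n_peaks, 1L)
  expect_equal(tr2$peaks$value, 5)
})

test_that("derivative metrics match closed forms and internal identities", {
  flat <- epithelial_metrics(as_line_profile_set(rep(3, 60)))
  expect_equal(flat$transition_delta, 0)
  expect_equal(flat$auc, 0)
  expect_true(flat$no_transitions)

  # triangular wave of slope +/- s: derivative is a square wave, so each
  # peak-trough pair has delta exactly 2 s
  for (s in c(2, 5)) {
    tri <- rep(c(seq(0, 10 * s, by = s), seq(9 * s, s, by = -s)), 6)
    met <- epithelial_metrics(as_line_profile_set(tri))
    expect_equal(met$transition_delta, 2 * s)
    expect_equal(met$auc, met$auc_per_transition * met$n_transitions)
  }

  # identity auc = auc_per_transition * n_transitions on realistic images
  g <- generate_epithelium_image(epithelium_params(seed = 31,
                                                   blur_sigma_px = 1))
  met <- analyze_epithelium(g$image)
  expect_equal(met$auc, met$auc_per_transition * met$n_transitions)
  expect_gt(met$n_transitions, 0)
})

test_that("metrics are invariant to intensity offset and transposition", {
  g <- generate_epithelium_image(epithelium_params(seed = 12))
  m1 <- analyze_epithelium(g$image)
  m2 <- analyze_epithelium(g$image + 100)
  expect_equal(m1, m2, ignore_attr = TRUE)
  m3 <- analyze_epithelium(t(g$image))
  expect_equal(m1$auc, m3$auc)
  expect_equal(m1$transition_delta, m3$transition_delta)
  expect_equal(m1$n_transitions, m3$n_transitions)
})

test_that("per-profile pooling is available and reports per-profile rows", {
  g <- generate_epithelium_image(epithelium_params(seed = 13))
  met <- analyze_epithelium(g$image, pool = "profile")
  per <- attr(met, "per_profile")
  expect_equal(nrow(per), 10L)
  expect_equal(sum(per$auc), met$auc)
  expect_equal(sum(per$n_peaks) + sum(per$n_troughs), met$n_transitions)
})
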