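#' Parameters for the synthetic DAPI epithelium generator
#'
#' Describes a field of bright nuclei on dark background: nuclei on a jittered
#' square lattice, rendered as smooth discs, then degraded in a fixed order
#' (dropout, blur, contrast flattening, noise). Defaults emulate the healthy
#' central corneal epithelium: a clearly periodic field of densely packed
#' nuclei (nucleus diameter comparable to the lattice pitch, as in epithelial
#' sheets) with per-nucleus brightness variation.
#'
#' @param image_size_px integer pair (rows, cols).
#' @param nucleus_spacing_px lattice pitch in pixels.
#' @param nucleus_radius_px nucleus radius in pixels.
#' @param position_jitter_px uniform jitter applied to each center, per axis.
#' @param dropout probability in \[0, 1\] that a nucleus is removed.
#' @param blur_sigma_px Gaussian blur applied after rendering.
#' @param intensity_flattening fraction in \[0, 1\] by which nucleus/background
#'   contrast is reduced (0 = none, 1 = fully flat).
#' @param noise_sd additive Gaussian noise on the \[0, 1\] intensity scale.
#' @param seed integer seed.
#' @return a validated `epithelium_params` list.
#' @export
epithelium_params <- function(image_size_px = c(512L, 512L),
                              nucleus_spacing_px = 24,
                              nucleus_radius_px = 9,
                              position_jitter_px = 2,
                              dropout = 0, blur_sigma_px = 0,
                              intensity_flattening = 0,
                              noise_sd = 0.02, seed = 1L) {
  p <- list(image_size_px = as.integer(image_size_px[1:2]),
            nucleus_spacing_px = nucleus_spacing_px,
            nucleus_radius_px = nucleus_radius_px,
            position_jitter_px = position_jitter_px,
            dropout = dropout, blur_sigma_px = blur_sigma_px,
            intensity_flattening = intensity_flattening,
            noise_sd = noise_sd, seed = as.integer(seed))
  if (any(p$image_size_px < 8L)) stop("image dimensions too small")
  if (p$nucleus_spacing_px <= 0 || p$nucleus_radius_px <= 0) {
    stop("spacing and radius must be positive")
  }
  if (p$position_jitter_px < 0 || p$blur_sigma_px < 0 || p$noise_sd < 0) {
    stop("jitter, blur and noise must be non-negative")
  }
  probs <- c(p$dropout, p$intensity_flattening)
  if (any(probs < 0 | probs > 1)) {
    stop("dropout and intensity_flattening must lie in [0, 1]")
  }
  if (p$nucleus_spacing_px <= 2 * p$position_jitter_px) {
    stop("nucleus_spacing_px must exceed twice the jitter")
  }
  # guaranteed overlap is an error; merely possible overlap is a warning
  if (2 * p$nucleus_radius_px > p$nucleus_spacing_px + 2 * p$position_jitter_px) {
    stop("nuclei would always overlap: radius too large for this spacing/jitter")
  }
  if (2 * p$nucleus_radius_px > p$nucleus_spacing_px - 2 * p$position_jitter_px) {
    warning("nuclei may overlap for some jitter draws")
  }
  structure(p, class = "epithelium_params")
}

#' Generate a synthetic DAPI epithelium image with planted nucleus centers
#'
#' Centers are placed on a square lattice at pitch `nucleus_spacing_px`
#' (first row/column at half a pitch from the border), jittered, thinned by
#' `dropout`, and rendered as smooth flat-topped bright discs over a dim
#' background. Degradation then proceeds blur -> contrast flattening ->
#' additive noise, in that fixed order. Truth lists the surviving
#' (post-dropout, pre-degradation) centers.
#'
#' @param params an [epithelium_params()] object.
#' @return list with `image` (numeric matrix in \[0, 1\]) and `truth`
#'   (`nucleus_centers`: n x 2 matrix of (y, x); `n_nuclei`).
#' @examples
#' p <- epithelium_params(image_size_px = c(200, 200), nucleus_spacing_px = 20,
#'                        nucleus_radius_px = 5, position_jitter_px = 0)
#' nrow(generate_epithelium_image(p)$truth$nucleus_centers) # 100
#' @export
generate_epithelium_image <- function(params) {
  stopifnot(inherits(params, "epithelium_params"))
  p <- params
  h <- p$image_size_px[1L]; w <- p$image_size_px[2L]
  s <- p$nucleus_spacing_px

  withr::with_seed(p$seed, {
    ys <- seq(s / 2, by = s, length.out = floor(h / s))
    xs <- seq(s / 2, by = s, length.out = floor(w / s))
    centers <- as.matrix(expand.grid(y = ys, x = xs))
    n <- nrow(centers)
    if (n > 0L && p$position_jitter_px > 0) {
      centers[, 1L] <- centers[, 1L] +
        runif(n, -p$position_jitter_px, p$position_jitter_px)
      centers[, 2L] <- centers[, 2L] +
        runif(n, -p$position_jitter_px, p$position_jitter_px)
    }
    # per-nucleus brightness varies with chromatin state in real DAPI fields;
    # this low-frequency structure also anchors the image's dynamic range
    amplitude <- runif(n, 0.55, 0.95)
    if (n > 0L && p$dropout > 0) {
      keep <- runif(n) >= p$dropout
      centers <- centers[keep, , drop = FALSE]
      amplitude <- amplitude[keep]
    }

    background <- 0.08
    img <- matrix(background, h, w)
    r <- p$nucleus_radius_px
    win <- ceiling(2 * r)
    for (i in seq_len(nrow(centers))) {
      cy <- centers[i, 1L]; cx <- centers[i, 2L]
      yy <- max(1L, floor(cy - win)):min(h, ceiling(cy + win))
      xx <- max(1L, floor(cx - win)):min(w, ceiling(cx + win))
      d2 <- outer((yy - cy)^2, (xx - cx)^2, `+`)
      # flat-topped profile: near-constant core, smooth shoulder at d ~ r
      img[yy, xx] <- pmin(1, img[yy, xx] +
                            amplitude[i] * exp(-0.5 * (d2 / (0.6 * r)^2)^2))
    }

    img <- gaussian_blur(img, p$blur_sigma_px)
    if (p$intensity_flattening > 0) {
      mu <- mean(img)
      img <- mu + (img - mu) * (1 - p$intensity_flattening)
    }
    if (p$noise_sd > 0) {
      img <- img + rnorm(length(img), 0, p$noise_sd)
    }
    img <- clamp01(img)

    truth <- structure(
      list(nucleus_centers = centers, n_nuclei = nrow(centers)),
      class = "synthetic_truth"
    )
    list(image = img, truth = truth, params = p)
  })
}
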