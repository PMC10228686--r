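`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Gaussian smoothing of a 2D image
#'
#' Thin wrapper around [EBImage::gblur()] that treats `sigma = 0` as the
#' identity and shrinks the filter support when the image is smaller than the
#' default kernel (EBImage requires the kernel to fit inside the image).
#'
#' @param img numeric matrix.
#' @param sigma standard deviation of the Gaussian kernel in pixels; `0`
#'   returns `img` unchanged.
#' @return numeric matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (sigma == 0) {
    return(img)
  }
  radius <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  fit <- min(dim(img))
  if (radius > fit) {
    radius <- if (fit %% 2L == 1L) fit else fit - 1L
  }
  out <- EBImage::gblur(img, sigma = sigma, radius = radius)
  matrix(as.numeric(out), nrow = nrow(img), ncol = ncol(img))
}

# trapezoidal integral of y over unit-spaced samples
trapz_unit <- function(y) {
  n <- length(y)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2)
}

# split n pixels into k runs whose sizes differ by at most 1, larger runs first
split_sizes <- function(n, k) {
  base <- n %/% k
  rem <- n %% k
  c(rep(base + 1L, rem), rep(base, k - rem))
}
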