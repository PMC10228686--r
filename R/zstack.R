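#' Construct an image stack
#'
#' Container for a 3D fluorescence volume. Planes are stored along the third
#' array dimension, so `voxels[, , k]` is the k-th z-plane (a y-by-x matrix).
#' All intensities must be finite and non-negative.
#'
#' @param voxels 3D numeric array, dimensions (y, x, z); a matrix is accepted
#'   and treated as a single plane.
#' @param pixel_size_um optional lateral pixel size in micrometres.
#' @return an `image_stack` object.
#' @export
image_stack <- function(voxels, pixel_size_um = NULL) {
  if (is.matrix(voxels)) {
    voxels <- array(voxels, dim = c(dim(voxels), 1L))
  }
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (!all(is.finite(voxels)) || any(voxels < 0)) {
    stop("stack intensities must be finite and non-negative")
  }
  if (!is.null(pixel_size_um)) {
    stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1L,
              pixel_size_um > 0)
  }
  structure(
    list(voxels = voxels, pixel_size_um = pixel_size_um,
         plane_count = dim(voxels)[3L]),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d px, %d plane(s)%s\n", d[1], d[2], d[3],
              if (is.null(x$pixel_size_um)) "" else
                sprintf(", %.3g um/px", x$pixel_size_um)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Build a tile grid partitioning an image
#'
#' Splits a (y, x) extent into `rows` x `cols` rectangular tiles with no gaps
#' and no overlaps. Tile edge lengths along each axis differ by at most one
#' pixel; the larger tiles come first. Tiles are ordered row-major (all tiles
#' of the first row of the grid, left to right, then the second row).
#' Rectangles use 1-based closed intervals `[y0, y1] x [x0, x1]`, the
#' convention used throughout the package.
#'
#' @param dim_yx integer pair, image extent (rows, cols) in pixels.
#' @param rows,cols grid dimensions; the default 3 x 3 gives the nine tiles
#'   used for full-cornea stacks.
#' @return a `tile_grid` object with a `tiles` data frame
#'   (tile, grid_row, grid_col, y0, y1, x0, x1).
#' @examples
#' g <- tile_grid(c(800, 800))
#' nrow(g$tiles) # 9
#' @export
tile_grid <- function(dim_yx, rows = 3L, cols = 3L) {
  stopifnot(length(dim_yx) >= 2L, rows >= 1L, cols >= 1L)
  h <- as.integer(dim_yx[1L]); w <- as.integer(dim_yx[2L])
  if (h < rows || w < cols) {
    stop("image extent smaller than the tile grid: some tiles would be empty")
  }
  hs <- split_sizes(h, rows)
  ws <- split_sizes(w, cols)
  y1 <- cumsum(hs); y0 <- y1 - hs + 1L
  x1 <- cumsum(ws); x0 <- x1 - ws + 1L
  idx <- expand.grid(grid_col = seq_len(cols), grid_row = seq_len(rows))
  tiles <- data.frame(
    tile = seq_len(rows * cols),
    grid_row = idx$grid_row, grid_col = idx$grid_col,
    y0 = y0[idx$grid_row], y1 = y1[idx$grid_row],
    x0 = x0[idx$grid_col], x1 = x1[idx$grid_col]
  )
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 dim_yx = c(h, w), tiles = tiles),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d x %d tiles over %d x %d px\n",
              x$rows, x$cols, x$dim_yx[1], x$dim_yx[2]))
  invisible(x)
}

#' Split a stack (or 2D image) into tile sub-stacks
#'
#' @param stack an [image_stack()], 3D array, or 2D matrix.
#' @param grid a [tile_grid()]; defaults to 3 x 3 over the stack extent.
#' @return list of sub-stacks (same type as the input), one per tile in
#'   row-major order, each carrying its tile rectangle as attribute `"tile"`.
#' @export
split_tiles <- function(stack, grid = NULL) {
  v <- if (inherits(stack, "image_stack")) stack$voxels else stack
  two_d <- is.matrix(v)
  if (two_d) v <- array(v, dim = c(dim(v), 1L))
  grid <- grid %||% tile_grid(dim(v)[1:2])
  if (!identical(as.integer(grid$dim_yx), as.integer(dim(v)[1:2]))) {
    stop("grid extent does not match image extent")
  }
  lapply(seq_len(nrow(grid$tiles)), function(i) {
    tl <- grid$tiles[i, ]
    sub <- v[tl$y0:tl$y1, tl$x0:tl$x1, , drop = FALSE]
    out <- if (two_d) sub[, , 1L] else if (inherits(stack, "image_stack")) {
      image_stack(sub, pixel_size_um = stack$pixel_size_um)
    } else sub
    attr(out, "tile") <- tl
    out
  })
}

#' Standard-deviation z-projection
#'
#' Flattens a sub-stack over an inclusive plane interval: each output pixel is
#' the standard deviation of that pixel's intensities across planes
#' `z_lo..z_hi`. The population convention (divide by the number of planes, not
#' n - 1) is used, matching the ImageJ "Standard Deviation" projection. A
#' single-plane interval is permitted and yields an all-zero projection with a
#' warning.
#'
#' @param substack an [image_stack()] or 3D array.
#' @param z_lo,z_hi inclusive 1-based plane bounds; defaults cover all planes.
#' @return numeric matrix (the projected image) with attribute `"z_bounds"`.
#' @examples
#' s <- array(c(0, 10), dim = c(1, 1, 2))
#' sd_project(s) # 5
#' @export
sd_project <- function(substack, z_lo = 1L, z_hi = NULL) {
  v <- if (inherits(substack, "image_stack")) substack$voxels else substack
  stopifnot(is.array(v), length(dim(v)) == 3L)
  nz <- dim(v)[3L]
  z_hi <- z_hi %||% nz
  if (z_lo < 1L || z_hi > nz || z_lo > z_hi) {
    stop(sprintf("invalid plane interval [%d, %d] for a %d-plane stack",
                 z_lo, z_hi, nz))
  }
  if (z_lo == z_hi) {
    warning("single-plane interval: standard-deviation projection is all zero")
  }
  a <- v[, , z_lo:z_hi, drop = FALSE]
  mu <- rowMeans(a, dims = 2L)
  mu2 <- rowMeans(a * a, dims = 2L)
  out <- sqrt(pmax(mu2 - mu * mu, 0))
  attr(out, "z_bounds") <- c(z_lo = as.integer(z_lo), z_hi = as.integer(z_hi))
  out
}

#' Automatic plane bounds for one tile
#'
#' Chooses the contiguous window of `width` planes (within an optional
#' candidate range) maximizing total intensity. This is the unattended stand-in
#' for the manual per-tile plane selection of the interactive workflow.
#'
#' @param substack an [image_stack()] or 3D array.
#' @param width window width in planes.
#' @param z_range optional inclusive candidate range `c(lo, hi)`.
#' @return integer vector `c(z_lo, z_hi)`.
#' @export
auto_zbounds <- function(substack, width = 3L, z_range = NULL) {
  v <- if (inherits(substack, "image_stack")) substack$voxels else substack
  nz <- dim(v)[3L]
  z_range <- as.integer(z_range %||% c(1L, nz))
  stopifnot(z_range[1] >= 1L, z_range[2] <= nz, z_range[1] <= z_range[2])
  width <- min(as.integer(width), z_range[2] - z_range[1] + 1L)
  totals <- apply(v, 3L, sum)[z_range[1]:z_range[2]]
  n <- length(totals)
  cs <- cumsum(c(0, totals))
  win <- cs[(width + 1L):(n + 1L)] - cs[seq_len(n - width + 1L)]
  # leftmost maximum, robust to cumsum round-off on ties
  lo <- z_range[1] + which(win >= max(win) - 1e-9 * (1 + max(win)))[1L] - 1L
  c(z_lo = lo, z_hi = lo + width - 1L)
}

# per-tile two-band heuristic: the brightest window is the sub-basal band
# when fibers are present; the epithelial band is searched strictly above it
# (skipping one bleed-through plane). A bright band already high in the stack
# means a single-band tile and is used as-is.
auto_layer_zbounds <- function(substack, layer, width = 3L) {
  v <- if (inherits(substack, "image_stack")) substack$voxels else substack
  nz <- dim(v)[3L]
  w_main <- auto_zbounds(substack, width = width)
  if (layer == "sub_basal") {
    return(w_main)
  }
  lo <- w_main[2L] + 2L
  if (lo > nz || w_main[1L] > ceiling(0.6 * nz)) {
    return(w_main)
  }
  auto_zbounds(substack, width = width, z_range = c(lo, nz))
}

#' Binarize a projected image
#'
#' @param img numeric matrix (e.g. from [sd_project()]).
#' @param method `"otsu"` computes the threshold from the image histogram
#'   ([EBImage::otsu()]); `"manual"` and `"fixed"` use the supplied threshold.
#' @param threshold numeric threshold, required for manual/fixed.
#' @return a `binary_mask`: logical matrix with attributes `threshold_used`
#'   and `method`. Pixels strictly above the threshold are foreground.
#' @export
binarize <- function(img, method = c("otsu", "manual", "fixed"),
                     threshold = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(img), all(is.finite(img)))
  if (method %in% c("manual", "fixed")) {
    if (is.null(threshold)) stop("method '", method, "' requires a threshold")
  } else {
    rng <- range(img)
    if (rng[1] == rng[2]) {
      warning("constant image: Otsu undefined, returning an empty mask")
      threshold <- rng[2]
    } else {
      threshold <- EBImage::otsu(img, range = rng)
    }
  }
  structure(img > threshold, threshold_used = as.numeric(threshold),
            method = method, class = c("binary_mask", "matrix", "array"))
}

#' Re-stitch per-tile binary masks
#'
#' Inverse of [split_tiles()] for masks: copies each tile's pixels back into a
#' full-extent mask with no blending, so `stitch_tiles(split_tiles(m, g), g)`
#' is the identity.
#'
#' @param tiles list of logical matrices, one per tile, row-major order.
#' @param grid the [tile_grid()] that produced them.
#' @return logical matrix of the grid's full extent (class `binary_mask`).
#' @export
stitch_tiles <- function(tiles, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  if (length(tiles) != nrow(grid$tiles)) {
    stop(sprintf("expected %d tiles, got %d", nrow(grid$tiles), length(tiles)))
  }
  out <- matrix(FALSE, grid$dim_yx[1], grid$dim_yx[2])
  for (i in seq_along(tiles)) {
    tl <- grid$tiles[i, ]
    m <- tiles[[i]]
    if (!all(dim(m) == c(tl$y1 - tl$y0 + 1L, tl$x1 - tl$x0 + 1L))) {
      stop(sprintf("tile %d extent does not match its grid rectangle", i))
    }
    out[tl$y0:tl$y1, tl$x0:tl$x1] <- as.logical(m)
  }
  structure(out, class = c("binary_mask", "matrix", "array"))
}

#' Tiled projection of a curved-cornea stack into a flat binary image
#'
#' Full z-stack pipeline for one layer: split the stack into tiles, choose (or
#' accept) per-tile plane bounds, flatten each tile by standard-deviation
#' projection, binarize, and re-stitch into a single full-extent mask.
#'
#' Plane bounds: supply a `n_tiles x 2` matrix per the grid's tile order, or
#' `"auto"` to pick bounds per tile. Auto mode finds the tile's brightest
#' `window`-plane interval, which is the sub-basal band whenever fibers are
#' present (the plexus dominates total intensity); for the epithelial layer it
#' then searches strictly above that band (skipping one bleed-through plane),
#' falling back to the bright band itself when that band already sits in the
#' upper planes (single-band stack). This is the unattended stand-in for the
#' per-tile manual bounds of the interactive workflow; `z_range` overrides the
#' candidate range entirely.
#'
#' Thresholding: `threshold_scope = "global"` (default) computes one threshold
#' from the stitched projection and applies it to every tile, which is robust
#' when some tiles contain no structure; `"tile"` thresholds each tile from its
#' own histogram, mirroring the interactive per-tile workflow.
#'
#' @param stack an [image_stack()] or 3D array.
#' @param layer `"sub_basal"` or `"epithelial"`; only used to pick the default
#'   auto-bounds candidate range.
#' @param grid a [tile_grid()]; default 3 x 3.
#' @param zbounds `"auto"` or a `n_tiles x 2` integer matrix of inclusive
#'   plane bounds.
#' @param window auto-bounds window width in planes.
#' @param z_range optional explicit candidate range for auto bounds,
#'   overriding the layer default.
#' @param threshold_method,threshold passed to [binarize()].
#' @param threshold_scope `"global"` or `"tile"`, see Details.
#' @return list with elements `mask` (stitched `binary_mask`), `projection`
#'   (stitched real-valued projection) and `provenance` (tile rectangles,
#'   per-tile plane bounds and thresholds, method, layer).
#' @export
project_stack <- function(stack, layer = c("sub_basal", "epithelial"),
                          grid = NULL, zbounds = "auto", window = 3L,
                          z_range = NULL,
                          threshold_method = c("otsu", "manual", "fixed"),
                          threshold = NULL,
                          threshold_scope = c("global", "tile")) {
  layer <- match.arg(layer)
  threshold_method <- match.arg(threshold_method)
  threshold_scope <- match.arg(threshold_scope)
  v <- if (inherits(stack, "image_stack")) stack$voxels else stack
  nz <- dim(v)[3L]
  grid <- grid %||% tile_grid(dim(v)[1:2])
  subs <- split_tiles(stack, grid)
  n_tiles <- length(subs)

  if (identical(zbounds, "auto")) {
    zb <- t(vapply(subs, function(s) {
      if (!is.null(z_range)) {
        auto_zbounds(s, width = window, z_range = z_range)
      } else {
        auto_layer_zbounds(s, layer = layer, width = window)
      }
    }, integer(2L)))
  } else {
    zb <- as.matrix(zbounds)
    if (nrow(zb) != n_tiles || ncol(zb) != 2L) {
      stop("zbounds must be 'auto' or an n_tiles x 2 matrix")
    }
  }

  projs <- lapply(seq_len(n_tiles), function(i) {
    sd_project(subs[[i]], zb[i, 1L], zb[i, 2L])
  })
  proj_full <- matrix(0, grid$dim_yx[1], grid$dim_yx[2])
  for (i in seq_len(n_tiles)) {
    tl <- grid$tiles[i, ]
    proj_full[tl$y0:tl$y1, tl$x0:tl$x1] <- projs[[i]]
  }

  if (threshold_scope == "global" && threshold_method == "otsu") {
    rng <- range(proj_full)
    thr <- if (rng[1] == rng[2]) {
      warning("constant projection: Otsu undefined, returning an empty mask")
      rng[2]
    } else EBImage::otsu(proj_full, range = rng)
    masks <- lapply(projs, binarize, method = "fixed", threshold = thr)
  } else {
    masks <- lapply(projs, binarize, method = threshold_method,
                    threshold = threshold)
  }
  thr_used <- vapply(masks, function(m) attr(m, "threshold_used"), numeric(1))

  list(
    mask = stitch_tiles(masks, grid),
    projection = proj_full,
    provenance = list(
      layer = layer, grid = grid$tiles, zbounds = zb,
      sd_convention = "population",
      threshold_method = threshold_method, threshold_scope = threshold_scope,
      thresholds = thr_used
    )
  )
}
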