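#' Parameters for the synthetic corneal nerve stack generator
#'
#' Describes a synthetic central-cornea confocal stack: sub-basal nerve fibers
#' drawn as streamlines of a logarithmic-spiral field (the central whorl),
#' punctate epithelial terminals in a higher plane band, both drifting across
#' z with corneal curvature, plus a controllable degeneration process (fiber
#' breakage, terminal dropout, whole-fiber coverage loss).
#'
#' @param image_size_px integer pair (rows, cols), each >= 64; the default
#'   800 x 800 matches full-cornea acquisition.
#' @param n_planes number of z-planes (>= 1).
#' @param n_fibers number of sub-basal fibers (>= 0).
#' @param swirl_turns spiral winding of the whorl, in revolutions.
#' @param fiber_width_px rendered fiber width in pixels.
#' @param terminal_density epithelial terminals per 1000 px^2.
#' @param break_rate probability in \[0, 1\] that a fiber is severed at each of
#'   its candidate break points (candidates are spaced along arc length).
#' @param terminal_dropout probability in \[0, 1\] that a terminal is removed.
#' @param coverage_loss probability in \[0, 1\] that a fiber is removed whole.
#' @param curvature_tilt z-planes of band drift between opposite image
#'   corners (emulates the flattened cornea's residual curvature); must be
#'   `< n_planes`.
#' @param noise_sd additive Gaussian noise, intensity units on \[0, 1\].
#' @param seed integer seed; generation is a pure function of (params, seed).
#' @param connectivity connectivity (8 or 4) under which the planted fragment
#'   count is recorded.
#' @param non_touching if `TRUE`, fibers are laid out as short spiral-aligned
#'   arcs in disjoint image cells with guard margins, so planted fragments are
#'   guaranteed not to touch and the planted count is exact by construction.
#' @return a validated `nerve_params` list.
#' @export
nerve_params <- function(image_size_px = c(800L, 800L), n_planes = 20L,
                         n_fibers = 24L, swirl_turns = 1.5,
                         fiber_width_px = 2, terminal_density = 0.5,
                         break_rate = 0, terminal_dropout = 0,
                         coverage_loss = 0, curvature_tilt = 4L,
                         noise_sd = 0.02, seed = 1L, connectivity = 8L,
                         non_touching = FALSE) {
  p <- list(image_size_px = as.integer(image_size_px[1:2]),
            n_planes = as.integer(n_planes), n_fibers = as.integer(n_fibers),
            swirl_turns = swirl_turns, fiber_width_px = fiber_width_px,
            terminal_density = terminal_density, break_rate = break_rate,
            terminal_dropout = terminal_dropout, coverage_loss = coverage_loss,
            curvature_tilt = as.integer(curvature_tilt), noise_sd = noise_sd,
            seed = as.integer(seed), connectivity = as.integer(connectivity),
            non_touching = isTRUE(non_touching))
  probs <- c(p$break_rate, p$terminal_dropout, p$coverage_loss)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(p$image_size_px < 64L)) stop("image dimensions must be >= 64 px")
  if (p$n_planes < 1L) stop("n_planes must be >= 1")
  if (p$n_fibers < 0L) stop("n_fibers must be >= 0")
  if (p$curvature_tilt >= p$n_planes) {
    stop("curvature_tilt must be smaller than n_planes")
  }
  if (p$swirl_turns <= 0 || p$fiber_width_px <= 0) {
    stop("swirl_turns and fiber_width_px must be positive")
  }
  if (p$terminal_density < 0 || p$noise_sd < 0) {
    stop("terminal_density and noise_sd must be non-negative")
  }
  if (!p$connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(p, class = "nerve_params")
}

# disc stamp offsets for a fiber of the given width
disc_offsets <- function(width_px) {
  r <- max(width_px / 2, 0)
  ri <- as.integer(floor(r))
  off <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  off[off$dy^2 + off$dx^2 <= r^2, , drop = FALSE]
}

# rasterize float polyline points (y, x) into pixel indices with thickness
stamp_points <- function(pts, offsets, h, w) {
  if (nrow(pts) == 0L) return(integer(0))
  py <- round(pts[, 1L]); px <- round(pts[, 2L])
  yy <- outer(py, offsets$dy, `+`)
  xx <- outer(px, offsets$dx, `+`)
  ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
  unique((xx[ok] - 1) * h + yy[ok])
}

# trace one whorl streamline: log spiral r = r_in * exp(b * theta)
trace_spiral_fiber <- function(theta0, h, w, swirl_turns, wobble_amp,
                               wobble_freq, wobble_phase) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  r_in <- 4
  r_out <- 0.48 * min(h, w)
  theta_max <- 2 * pi * swirl_turns
  b <- log(r_out / r_in) / theta_max
  theta <- 0
  out <- matrix(0, nrow = ceiling(4 * r_out * (1 + theta_max)), ncol = 3L)
  n <- 0L
  arc <- 0
  step <- 0.7
  while (theta <= theta_max) {
    r <- r_in * exp(b * theta) *
      (1 + wobble_amp * sin(wobble_freq * theta + wobble_phase))
    y <- cy + r * sin(theta + theta0)
    x <- cx + r * cos(theta + theta0)
    n <- n + 1L
    out[n, ] <- c(y, x, arc)
    dtheta <- step / max(r * sqrt(1 + b^2), 1)
    theta <- theta + dtheta
    arc <- arc + step
  }
  out[seq_len(n), , drop = FALSE]
}

# short spiral-aligned arc through a given center (non-touching layout)
trace_cell_arc <- function(center_yx, half_len, h, w) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  dy <- center_yx[1] - cy; dx <- center_yx[2] - cx
  theta <- atan2(dy, dx)
  b <- 0.35 # nominal pitch of the whorl field
  # tangent of r = exp(b*theta) streamline through this polar angle
  tx <- b * cos(theta) - sin(theta)
  ty <- b * sin(theta) + cos(theta)
  nrm <- sqrt(tx^2 + ty^2)
  tx <- tx / nrm; ty <- ty / nrm
  t <- seq(-half_len, half_len, by = 0.5)
  bend <- 0.15 * t^2 / max(half_len, 1)
  cbind(center_yx[1] + t * ty + bend * tx,
        center_yx[2] + t * tx - bend * ty,
        t + half_len)
}

# cut a traced fiber at Bernoulli(break_rate) candidate positions, removing a
# gap of >= 3 fiber widths so binarization cannot re-bridge the cut;
# returns the list of surviving pieces (point matrices)
apply_breaks <- function(pts, break_rate, fiber_width_px) {
  total <- pts[nrow(pts), 3L]
  gap <- 3 * fiber_width_px + 2
  spacing <- max(25, 2 * gap + 6)
  if (total < 2 * gap) return(list(pts))
  cand <- seq(gap, total - gap, by = spacing)
  if (length(cand) == 0L || break_rate == 0) return(list(pts))
  cut <- cand[runif(length(cand)) < break_rate]
  if (length(cut) == 0L) return(list(pts))
  drop <- rep(FALSE, nrow(pts))
  for (pos in cut) {
    drop <- drop | (pts[, 3L] >= pos - gap / 2 & pts[, 3L] <= pos + gap / 2)
  }
  keep <- !drop
  if (!any(keep)) return(list())
  piece_id <- cumsum(c(TRUE, diff(which(keep)) > 1L))
  pts_kept <- pts[keep, , drop = FALSE]
  lapply(split(seq_len(nrow(pts_kept)), piece_id),
         function(i) pts_kept[i, , drop = FALSE])
}

#' Generate a synthetic corneal nerve stack with planted ground truth
#'
#' Renders sub-basal fibers into a low-z plane band and epithelial terminal
#' puncta (2 x 2 px) into a higher band; both bands drift linearly by
#' `curvature_tilt` planes between opposite image corners. Degeneration is
#' applied to the noiseless geometry in a fixed order: whole-fiber coverage
#' loss, then fiber breakage, then terminal dropout; Gaussian noise is added
#' to the rendered stack last. The returned truth records the noiseless
#' 2D coverage mask and its exact connected-component count under
#' `params$connectivity` (verified against the planted piece count for
#' non-touching layouts).
#'
#' @param params a [nerve_params()] object.
#' @return list with `stack` (an [image_stack()]) and `truth`, a
#'   `synthetic_truth` list: `true_fragment_count`, `true_coverage_mask`,
#'   `sub_basal_mask`, `terminal_mask`, `planted_pieces`, `n_terminals`.
#' @examples
#' p <- nerve_params(image_size_px = c(128, 128), n_planes = 8, n_fibers = 3,
#'                   terminal_density = 0, curvature_tilt = 2, seed = 7)
#' g <- generate_nerve_stack(p)
#' g$truth$true_fragment_count
#' @export
generate_nerve_stack <- function(params) {
  stopifnot(inherits(params, "nerve_params"))
  p <- params
  h <- p$image_size_px[1L]; w <- p$image_size_px[2L]

  withr::with_seed(p$seed, {
    offsets <- disc_offsets(p$fiber_width_px)
    fiber_mask <- matrix(FALSE, h, w)
    planted_pieces <- 0L

    n_term_target <- round(p$terminal_density * h * w / 1000)

    if (p$non_touching) {
      n_cells_needed <- p$n_fibers + n_term_target
      side <- max(1L, ceiling(sqrt(max(n_cells_needed, 1L) * 1.6)))
      cs_y <- h %/% side; cs_x <- w %/% side
      margin <- ceiling(1.5 * p$fiber_width_px) + 2
      usable <- min(cs_y, cs_x) - 2 * margin
      if (side^2 < n_cells_needed || usable < 4) {
        stop("too many fibers/terminals for a non-touching layout at this image size")
      }
      cells <- sample.int(side^2, n_cells_needed)
      fiber_cells <- cells[seq_len(p$n_fibers)]
      term_cells <- cells[setdiff(seq_len(n_cells_needed),
                                  seq_len(p$n_fibers))]
      keep_fiber <- runif(p$n_fibers) >= p$coverage_loss
      pieces <- list()
      for (i in seq_len(p$n_fibers)) {
        ci <- fiber_cells[i]
        cyx <- c(((ci - 1) %/% side) * cs_y + cs_y / 2,
                 ((ci - 1) %% side) * cs_x + cs_x / 2)
        pts <- trace_cell_arc(cyx, usable / 2, h, w)
        if (!keep_fiber[i]) next
        pieces <- c(pieces, apply_breaks(pts, p$break_rate, p$fiber_width_px))
      }
      term_pos <- if (length(term_cells)) cbind(
        ((term_cells - 1) %/% side) * cs_y + cs_y / 2,
        ((term_cells - 1) %% side) * cs_x + cs_x / 2
      ) else matrix(0, 0L, 2L)
    } else {
      theta0 <- runif(p$n_fibers, 0, 2 * pi)
      wob_amp <- runif(p$n_fibers, 0, 0.03)
      wob_freq <- sample(3:7, p$n_fibers, replace = TRUE)
      wob_phase <- runif(p$n_fibers, 0, 2 * pi)
      keep_fiber <- runif(p$n_fibers) >= p$coverage_loss
      pieces <- list()
      for (i in seq_len(p$n_fibers)) {
        pts <- trace_spiral_fiber(theta0[i], h, w, p$swirl_turns,
                                  wob_amp[i], wob_freq[i], wob_phase[i])
        if (!keep_fiber[i]) next
        pieces <- c(pieces, apply_breaks(pts, p$break_rate, p$fiber_width_px))
      }
      term_pos <- if (n_term_target > 0L) cbind(
        runif(n_term_target, 3, h - 3), runif(n_term_target, 3, w - 3)
      ) else matrix(0, 0L, 2L)
    }

    planted_pieces <- length(pieces)
    for (pc in pieces) {
      fiber_mask[stamp_points(pc, offsets, h, w)] <- TRUE
    }

    # terminal dropout, then render surviving puncta as 2 x 2 px squares
    if (nrow(term_pos) > 0L && p$terminal_dropout > 0) {
      term_pos <- term_pos[runif(nrow(term_pos)) >= p$terminal_dropout, ,
                           drop = FALSE]
    }
    term_mask <- matrix(FALSE, h, w)
    if (nrow(term_pos) > 0L) {
      py <- pmin(pmax(round(term_pos[, 1L]), 1L), h - 1L)
      px <- pmin(pmax(round(term_pos[, 2L]), 1L), w - 1L)
      for (d in list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))) {
        term_mask[cbind(py + d[1L], px + d[2L])] <- TRUE
      }
    }

    coverage_mask <- fiber_mask | term_mask
    true_k <- label_fragments(coverage_mask, p$connectivity)$n_fragments

    # render: linear plane-band drift from corner (1,1) to corner (h,w)
    drift <- round(p$curvature_tilt *
                     (outer(seq_len(h) - 1L, seq_len(w) - 1L, `+`)) /
                     (h + w - 2L))
    z_sub <- max(1L, round(p$n_planes * 0.3))
    z_epi <- min(p$n_planes, round(p$n_planes * 0.75))
    vox <- array(0, dim = c(h, w, p$n_planes))
    paint <- function(mask, z_base, amp) {
      idx2 <- which(mask)
      if (length(idx2) == 0L) return()
      z <- pmin(pmax(z_base + drift[idx2], 1L), p$n_planes)
      for (dz in -1L:1L) {
        zz <- pmin(pmax(z + dz, 1L), p$n_planes)
        lin <- idx2 + (zz - 1L) * (h * w)
        val <- if (dz == 0L) amp else 0.35 * amp
        vox[lin] <<- pmax(vox[lin], val)
      }
    }
    paint(fiber_mask, z_sub, 0.85)
    paint(term_mask, z_epi, 0.9)

    if (p$noise_sd > 0) {
      vox <- vox + rnorm(length(vox), 0, p$noise_sd)
    }
    vox <- clamp01(vox)

    truth <- structure(
      list(true_fragment_count = true_k,
           true_coverage_mask = coverage_mask,
           sub_basal_mask = fiber_mask,
           terminal_mask = term_mask,
           planted_pieces = planted_pieces,
           n_terminals = nrow(term_pos),
           connectivity = p$connectivity),
      class = "synthetic_truth"
    )
    list(stack = image_stack(vox), truth = truth, params = p)
  })
}
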