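# Independent oracles used across the suite. These deliberately take
# different algorithmic routes from the package implementations.

# breadth-first-search connected-component count (package uses a
# depth-first explicit stack in C++)
oracle_fragment_count <- function(mask, connectivity = 8L) {
  d <- dim(mask)
  mask <- as.logical(mask)
  dim(mask) <- d
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 4L) {
    dy <- c(-1L, 1L, 0L, 0L); dx <- c(0L, 0L, -1L, 1L)
  } else {
    dy <- rep(-1:1, times = 3)[-5L]; dx <- rep(-1:1, each = 3)[-5L]
  }
  count <- 0L
  fg <- which(mask)
  if (length(fg) == 0L) return(0L)
  queue <- integer(length(fg))
  for (start in fg) {
    if (lab[start]) next
    count <- count + 1L
    lab[start] <- count
    queue[1L] <- start; qhead <- 1L; qtail <- 1L
    while (qhead <= qtail) {
      cur <- queue[qhead]; qhead <- qhead + 1L
      cy <- ((cur - 1L) %% nr) + 1L
      cx <- ((cur - 1L) %/% nr) + 1L
      ny <- cy + dy; nx <- cx + dx
      ok <- ny >= 1L & ny <= nr & nx >= 1L & nx <= nc
      for (k in which(ok)) {
        id <- (nx[k] - 1L) * nr + ny[k]
        if (mask[id] && lab[id] == 0L) {
          lab[id] <- count
          qtail <- qtail + 1L
          queue[qtail] <- id
        }
      }
    }
  }
  count
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-pixel closed-form population SD, plain loops
oracle_sd_project <- function(substack, z_lo, z_hi) {
  d <- dim(substack)
  out <- matrix(0, d[1L], d[2L])
  for (i in seq_len(d[1L])) {
    for (j in seq_len(d[2L])) {
      v <- substack[i, j, z_lo:z_hi]
      out[i, j] <- sqrt(sum((v - mean(v))^2) / length(v))
    }
  }
  out
}

# descending scan formulation of the blink threshold rule: walk the tested
# lengths from longest to shortest and stop at the first positive response
oracle_threshold <- function(lengths_mm, positives) {
  ord <- order(lengths_mm, decreasing = TRUE)
  for (k in ord) {
    if (positives[k] >= 3) return(lengths_mm[k])
  }
  0
}

# random binary mask at a given foreground density
random_mask <- function(nr, nc, density, seed) {
  withr::with_seed(seed, matrix(runif(nr * nc) < density, nr, nc))
}
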