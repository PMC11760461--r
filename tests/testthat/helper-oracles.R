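# Independent oracles and fixture builders used across the suite.

# Naive Otsu oracle: exhaustive minimization of the within-class variance
# over all 256 histogram bin cuts (no cumulative-moment shortcut).
oracle_otsu <- function(values, levels = 256L) {
  v <- as.vector(values)
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = levels + 1L)
  mids <- (edges[-1L] + edges[-(levels + 1L)]) / 2
  h <- tabulate(pmin(pmax(findInterval(v, edges, all.inside = TRUE), 1L), levels),
                nbins = levels)
  best <- Inf; best_t <- NA_integer_
  for (t in seq_len(levels - 1L)) {
    i0 <- seq_len(t); i1 <- (t + 1L):levels
    w0 <- sum(h[i0]); w1 <- sum(h[i1])
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[i0] * mids[i0]) / w0
    m1 <- sum(h[i1] * mids[i1]) / w1
    icv <- (sum(h[i0] * (mids[i0] - m0)^2) + sum(h[i1] * (mids[i1] - m1)^2)) /
      (w0 + w1)
    if (icv < best - 1e-15) { best <- icv; best_t <- t }
  }
  edges[best_t + 1L]
}

# Stack-based 8-connected flood fill; returns a label matrix.
oracle_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] > 0 && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      stack <- list(c(i, j)); lab[i, j] <- nxt
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              mask[ii, jj] > 0 && lab[ii, jj] == 0L) {
            lab[ii, jj] <- nxt
            stack[[length(stack) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# keep the `keep` largest components by brute force on an oracle labeling
oracle_largest <- function(mask, keep = 1L) {
  lab <- oracle_label(mask)
  n <- max(lab)
  if (n == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  rowmajor <- (row(lab) - 1L) * ncol(lab) + col(lab)
  anchor <- vapply(seq_len(n), function(l) min(rowmajor[lab == l]), numeric(1))
  kept <- order(-sizes, anchor)[seq_len(min(keep, n))]
  matrix(as.integer(lab %in% kept & lab > 0L), nrow(mask), ncol(mask))
}

# dark bar of a given orientation on a bright background (capsule raster)
make_bar_frame <- function(size, theta_deg, width = 3, len = 40,
                           bg = 0.8, fg = 0.3) {
  c0 <- (size + 1) / 2
  a <- theta_deg * pi / 180
  px <- matrix(rep(seq_len(size), each = size), size, size)
  py <- matrix(rep(seq_len(size), times = size), size, size)
  dx <- cos(a) * len / 2; dy <- sin(a) * len / 2
  x0 <- c0 - dx; y0 <- c0 - dy; ddx <- 2 * dx; ddy <- 2 * dy
  tt <- pmin(pmax(((px - x0) * ddx + (py - y0) * ddy) / (ddx^2 + ddy^2), 0), 1)
  d <- sqrt((px - (x0 + tt * ddx))^2 + (py - (y0 + tt * ddy))^2)
  f <- matrix(bg, size, size); f[d <= width / 2] <- fg
  f
}

# sinusoidal grating whose stripes are oriented at theta (degrees)
make_grating <- function(size, wavelength, theta_deg, amp = 0.4) {
  a <- theta_deg * pi / 180
  px <- matrix(rep(seq_len(size), each = size), size, size)
  py <- matrix(rep(seq_len(size), times = size), size, size)
  0.5 + amp * cos(2 * pi / wavelength * (-px * sin(a) + py * cos(a)))
}
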