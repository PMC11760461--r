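#' Validate a grayscale frame
#'
#' A frame is a plain numeric matrix of intensities on \code{[0,1]},
#' rows indexing image lines top to bottom (origin top-left).
#'
#' @param frame Numeric matrix.
#' @param min_dim Smallest admissible linear dimension.
#' @return The frame, invisibly, after validation.
#' @keywords internal
check_frame <- function(frame, min_dim = 16L) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    stop("frame must be a numeric matrix", call. = FALSE)
  }
  if (nrow(frame) < min_dim || ncol(frame) < min_dim) {
    stop(sprintf("frame must be at least %dx%d pixels", min_dim, min_dim),
         call. = FALSE)
  }
  if (any(!is.finite(frame))) stop("frame contains non-finite values", call. = FALSE)
  if (min(frame) < 0 || max(frame) > 1) {
    stop("frame intensities must lie in [0,1]", call. = FALSE)
  }
  invisible(frame)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Mirror-reflect indices onto 1..n
#'
#' Symmetric (edge-duplicating) reflection with period 2n, defined for any
#' integer offset, so padding wider than the image is still well-formed.
#' @keywords internal
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * n)
  ifelse(p < n, p + 1L, 2L * n - p)
}

#' Pad a matrix by mirror reflection
#' @keywords internal
pad_reflect <- function(x, pr, pc) {
  ri <- reflect_index(seq.int(1L - pr, nrow(x) + pr), nrow(x))
  ci <- reflect_index(seq.int(1L - pc, ncol(x) + pc), ncol(x))
  x[ri, ci, drop = FALSE]
}

#' 2-D cross-correlation with reflective borders, "same" output
#'
#' Correlates \code{img} with an odd-sized \code{kernel}. Implemented by
#' mirror-padding the image by the kernel half-width and running EBImage's
#' FFT filter (which convolves, hence the kernel flip) on the padded copy.
#'
#' @param img Numeric matrix.
#' @param kernel Odd-dimensioned numeric matrix.
#' @return Matrix of the same size as \code{img}.
#' @keywords internal
xcorr2 <- function(img, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  if (kh %% 2L == 0L || kw %% 2L == 0L) stop("kernel dimensions must be odd", call. = FALSE)
  pr <- (kh - 1L) %/% 2L
  pc <- (kw - 1L) %/% 2L
  if (pr == 0L && pc == 0L) return(img * kernel[1L, 1L])
  flipped <- kernel[rev(seq_len(kh)), rev(seq_len(kw)), drop = FALSE]
  padded <- pad_reflect(img, pr, pc)
  out <- EBImage::filter2(padded, flipped, boundary = "circular")
  out[(pr + 1L):(pr + nrow(img)), (pc + 1L):(pc + ncol(img)), drop = FALSE]
}

#' Isotropic Gaussian smoothing kernel
#' @keywords internal
gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  o <- seq.int(-radius, radius)
  g <- exp(-o^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

lanczos_tap <- function(t, a = 3) {
  out <- rep(0, length(t))
  inside <- abs(t) < a
  tt <- t[inside]
  out[inside] <- ifelse(tt == 0, 1,
                        a * sin(pi * tt) * sin(pi * tt / a) / (pi^2 * tt^2))
  out
}

#' One-dimensional Lanczos resampling weight matrix
#'
#' Rows are output samples, columns input samples. Downsampling widens the
#' kernel by the scale factor (anti-aliasing); edges are handled by clamping
#' source indices. Rows are normalized to unit sum so constants are preserved.
#'
#' @param n_in,n_out Input/output lengths.
#' @param a Lanczos order (default 3).
#' @keywords internal
lanczos_weights <- function(n_in, n_out, a = 3) {
  if (n_in == n_out) return(diag(n_in))
  s <- n_in / n_out
  fs <- max(s, 1)
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    x <- (i - 0.5) * s - 0.5          # 0-based source coordinate
    lo <- ceiling(x - a * fs)
    hi <- floor(x + a * fs)
    idx <- lo:hi
    w <- lanczos_tap((idx - x) / fs, a)
    src <- pmin(pmax(idx, 0L), n_in - 1L) + 1L   # clamp to the edge
    for (k in seq_along(idx)) W[i, src[k]] <- W[i, src[k]] + w[k]
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W
}

#' Resize a matrix by separable Lanczos-3 resampling
#'
#' @param img Numeric matrix.
#' @param out_h,out_w Target dimensions.
#' @param a Lanczos order.
#' @return \code{out_h} by \code{out_w} matrix.
#' @export
lanczos_resize <- function(img, out_h, out_w, a = 3) {
  stopifnot(is.matrix(img), out_h >= 1, out_w >= 1)
  Wr <- lanczos_weights(nrow(img), out_h, a)
  Wc <- lanczos_weights(ncol(img), out_w, a)
  Wr %*% img %*% t(Wc)
}
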