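#' Build an oriented Gabor filter bank
#'
#' Kernels follow a cosine-phase Gabor: an isotropic Gaussian envelope of
#' standard deviation \code{sigma} multiplying a carrier of wavelength
#' \code{lambda}. The bank angle is the *preferred bar orientation* (the
#' carrier runs perpendicular to it), with 0 degrees meaning a horizontal
#' bar, so a kernel at angle theta responds maximally to edges oriented at
#' theta. A cosine-phase kernel is 180-degree periodic, hence angles are
#' evenly spaced on \[0, 180). Each kernel is DC-corrected (mean subtracted)
#' and scaled to unit L2 norm so responses are comparable across
#' orientations.
#'
#' @param sigma Envelope standard deviation in pixels (default 8).
#' @param wavelength Carrier period in pixels (default 12).
#' @param n_orientations Number of evenly spaced orientations (default 8).
#' @param support Odd kernel side length in pixels; defaults to
#'   \code{4*sigma + 1}.
#' @return Object of class \code{gabor_bank}: list with \code{kernels}
#'   (one matrix per orientation), \code{orientations} (degrees),
#'   \code{sigma}, \code{wavelength}, \code{support}.
#' @examples
#' bank <- build_gabor_bank(sigma = 4, wavelength = 6, n_orientations = 8,
#'                          support = 17)
#' sapply(bank$kernels, mean)   # all ~0
#' @export
build_gabor_bank <- function(sigma = 8, wavelength = 12, n_orientations = 8,
                             support = NULL) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (!is.numeric(wavelength) || wavelength <= 0) {
    stop("wavelength must be positive", call. = FALSE)
  }
  if (n_orientations < 2) stop("n_orientations must be at least 2", call. = FALSE)
  if (is.null(support)) support <- 2L * ceiling(2 * sigma) + 1L
  support <- as.integer(support)
  if (support %% 2L == 0L) stop("support must be odd", call. = FALSE)

  half <- (support - 1L) %/% 2L
  off <- seq.int(-half, half)
  X <- matrix(rep(off, each = support), support, support)   # column offset
  Y <- matrix(rep(off, times = support), support, support)  # row offset
  env <- exp(-(X^2 + Y^2) / sigma^2)

  angles <- seq(0, 180, length.out = n_orientations + 1L)[seq_len(n_orientations)]
  kernels <- lapply(angles, function(th) {
    a <- th * pi / 180
    u <- -X * sin(a) + Y * cos(a)      # axis perpendicular to the bar
    k <- env * cos(2 * pi * u / wavelength)
    k <- k - mean(k)                   # kill the DC response
    k / sqrt(sum(k^2))
  })
  structure(list(kernels = kernels, orientations = angles, sigma = sigma,
                 wavelength = wavelength, support = support),
            class = "gabor_bank")
}

#' Build a Gaussian image pyramid
#'
#' Level 1 is the input; every further level is Gaussian pre-smoothed
#' (anti-aliasing, sigma = 1 px) and Lanczos-downsampled by a factor of two
#' (ceiling dimensions), then clipped back to \[0,1]. If the requested depth
#' would drop the coarsest level below 8x8, the depth is reduced with a
#' warning.
#'
#' @param frame Numeric matrix in \[0,1], at least 16x16.
#' @param n_scales Requested number of levels (default 8).
#' @return Object of class \code{pyramid}: list with \code{levels} (list of
#'   matrices, fine to coarse) and \code{n_scales}.
#' @export
build_pyramid <- function(frame, n_scales = 8L) {
  check_frame(frame)
  if (n_scales < 1) stop("n_scales must be at least 1", call. = FALSE)
  n_scales <- as.integer(n_scales)
  # deepest usable level: halving (ceiling) must stay >= 8 px
  d <- min(dim(frame)); feasible <- 1L
  while (feasible < n_scales && ceiling(d / 2) >= 8) {
    d <- ceiling(d / 2); feasible <- feasible + 1L
  }
  if (feasible < n_scales) {
    warning(sprintf("n_scales reduced from %d to %d to keep the coarsest level >= 8 px",
                    n_scales, feasible), call. = FALSE)
    n_scales <- feasible
  }
  levels <- vector("list", n_scales)
  levels[[1L]] <- frame
  if (n_scales > 1L) {
    gk <- gaussian_kernel(1)
    for (j in 2:n_scales) {
      prev <- levels[[j - 1L]]
      sm <- xcorr2(prev, gk)
      levels[[j]] <- clip01(lanczos_resize(sm, ceiling(nrow(prev) / 2),
                                           ceiling(ncol(prev) / 2)))
    }
  }
  structure(list(levels = levels, n_scales = n_scales), class = "pyramid")
}

#' Oriented Gabor responses over a pyramid
#'
#' Cross-correlates every pyramid level with every bank kernel ("same"-size
#' output, reflective borders). Levels smaller than 8 px on a side are
#' skipped with a warning; because the kernel size is fixed across scales
#' it may exceed coarse levels, which the periodic mirror padding handles.
#'
#' @param pyramid A \code{pyramid}.
#' @param bank A \code{gabor_bank}.
#' @return List, one element per retained scale, each a 3-D array
#'   \code{[row, col, orientation]}, with attribute \code{scales} giving the
#'   pyramid indices kept.
#' @export
oriented_responses <- function(pyramid, bank) {
  stopifnot(inherits(pyramid, "pyramid"), inherits(bank, "gabor_bank"))
  keep <- vapply(pyramid$levels, function(L) min(dim(L)) >= 8L, logical(1))
  if (!all(keep)) {
    warning(sprintf("skipping %d pyramid level(s) smaller than 8 px",
                    sum(!keep)), call. = FALSE)
  }
  raw <- lapply(pyramid$levels[keep], function(L) {
    arr <- array(0, dim = c(nrow(L), ncol(L), length(bank$kernels)))
    for (t in seq_along(bank$kernels)) arr[, , t] <- xcorr2(L, bank$kernels[[t]])
    # snap FFT roundoff to exact zero so flat inputs stay exact fixpoints
    arr[abs(arr) < 1e-12] <- 0
    arr
  })
  attr(raw, "scales") <- which(keep)
  raw
}

#' Per-pixel optimal orientation
#'
#' Selects, per pixel, the orientation whose response has the largest
#' magnitude, keeping the signed response. Ties go to the lowest
#' orientation index.
#'
#' @param raw 3-D response array \code{[row, col, orientation]}.
#' @return List with \code{signed} (matrix of winning signed responses) and
#'   \code{angle_index} (integer matrix of winning orientation indices).
#' @export
optimal_orientation <- function(raw) {
  d <- dim(raw)
  m <- matrix(raw, d[1] * d[2], d[3])
  idx <- max.col(abs(m), ties.method = "first")
  signed <- m[cbind(seq_len(nrow(m)), idx)]
  list(signed = matrix(signed, d[1], d[2]),
       angle_index = matrix(as.integer(idx), d[1], d[2]))
}

#' Split a signed response into polarity channels
#'
#' @param signed Numeric matrix.
#' @return List with nonnegative \code{pos = max(S, 0)} and
#'   \code{neg = max(-S, 0)}; \code{pos - neg} reconstructs the input exactly.
#' @export
split_polarity <- function(signed) {
  list(pos = pmax(signed, 0), neg = pmax(-signed, 0))
}

#' Suppress the response noise floor
#'
#' Computes the threshold as the \code{percentile} type-1 quantile of the
#' nonzero magnitudes of \code{c_map} (or, with \code{mode = "max_fraction"},
#' as \code{max * (1 - percentile)}) and hard-gates entries strictly below
#' it to zero; surviving entries are untouched.
#'
#' @param c_map Nonnegative matrix (one polarity channel at one scale).
#' @param percentile Fraction in (0,1); default 0.05.
#' @param mode \code{"percentile"} (default) or \code{"max_fraction"}.
#' @return List with \code{clean} (gated matrix) and \code{thr} (scalar;
#'   0 for an all-zero input, which is returned unchanged).
#' @export
noise_floor <- function(c_map, percentile = 0.05, mode = c("percentile", "max_fraction")) {
  mode <- match.arg(mode)
  if (percentile <= 0 || percentile >= 1) {
    stop("percentile must be in (0,1)", call. = FALSE)
  }
  nz <- c_map[c_map > 0]
  if (length(nz) == 0L) return(list(clean = c_map, thr = 0))
  thr <- if (mode == "percentile") {
    unname(stats::quantile(nz, percentile, type = 1))
  } else {
    max(nz) * (1 - percentile)
  }
  clean <- c_map
  clean[clean < thr] <- 0
  list(clean = clean, thr = thr)
}

#' Naka-Rushton contrast gain control
#'
#' \code{R = c^n / (c^n + sigma_nr^n)}, the saturating contrast-response
#' curve of early visual neurons; \code{R(sigma_nr) = 0.5} exactly.
#'
#' @param c_clean Nonnegative matrix or vector.
#' @param n Exponent, >= 1 (default 2).
#' @param sigma_nr Semi-saturation constant (default 0.1). If
#'   \code{sigma_is_power} is TRUE, \code{sigma_nr} is interpreted as the
#'   already-raised value \code{sigma^n}.
#' @param sigma_is_power Alternative parameter reading (default FALSE).
#' @return Values in \[0, 1).
#' @export
naka_rushton <- function(c_clean, n = 2, sigma_nr = 0.1, sigma_is_power = FALSE) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (sigma_nr <= 0) stop("sigma_nr must be positive", call. = FALSE)
  if (any(c_clean < 0)) stop("c_clean must be nonnegative", call. = FALSE)
  sp <- if (sigma_is_power) sigma_nr else sigma_nr^n
  cn <- c_clean^n
  cn / (cn + sp)
}

#' Multiscale oriented edge decomposition
#'
#' Runs the full first stage on a pyramid: oriented Gabor responses, optimal
#' orientation selection, polarity split, noise-floor gating (per scale, per
#' polarity) and Naka-Rushton gain control.
#'
#' @param pyramid A \code{pyramid}.
#' @param bank A \code{gabor_bank}.
#' @param config Pipeline configuration (see [default_config()]).
#' @return Object of class \code{edge_stack}: per scale a list with
#'   \code{raw}, \code{signed}, \code{angle_index}, \code{pos}, \code{neg}
#'   (noise-gated polarity channels), \code{thr} (named noise thresholds)
#'   and \code{nr} (list \code{pos}/\code{neg} of Naka-Rushton responses);
#'   plus \code{orientations} and \code{scales}.
#' @export
edge_decompose <- function(pyramid, bank, config = default_config()) {
  raw_list <- oriented_responses(pyramid, bank)
  per_scale <- lapply(raw_list, function(raw) {
    opt <- optimal_orientation(raw)
    pol <- split_polarity(opt$signed)
    nfp <- noise_floor(pol$pos, config$noise$percentile, config$noise$mode)
    nfn <- noise_floor(pol$neg, config$noise$percentile, config$noise$mode)
    nr <- lapply(list(pos = nfp$clean, neg = nfn$clean), naka_rushton,
                 n = config$nr$n, sigma_nr = config$nr$sigma,
                 sigma_is_power = config$nr$sigma_is_power)
    list(raw = raw, signed = opt$signed, angle_index = opt$angle_index,
         pos = nfp$clean, neg = nfn$clean,
         thr = c(pos = nfp$thr, neg = nfn$thr), nr = nr)
  })
  structure(list(per_scale = per_scale, orientations = bank$orientations,
                 scales = attr(raw_list, "scales")),
            class = "edge_stack")
}
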