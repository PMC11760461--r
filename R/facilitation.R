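#' Oriented additive-signal mask
#'
#' The sub-threshold "educated guess" a responding receptive field projects
#' along its preferred orientation: an anisotropic Gaussian in rotated
#' coordinates (x' along the bar orientation \code{theta}, y' across it)
#' with the classical-RF disk (distance <= \code{rf_radius}) zeroed so a
#' response cannot facilitate itself. The mask is normalized to unit sum
#' over its nonzero support.
#'
#' @param theta Orientation in degrees (bar direction; 0 = horizontal).
#' @param sigma_x Collinear decay, in pixels.
#' @param sigma_y Orthogonal decay, in pixels.
#' @param rf_radius Classical receptive-field radius in pixels.
#' @param support Odd mask side length; defaults to cover 3 sigma.
#' @return Odd-sized nonnegative matrix summing to 1 (or all zero, with a
#'   warning, when the RF disk covers the whole support).
#' @export
additive_mask <- function(theta, sigma_x, sigma_y, rf_radius = 0,
                          support = NULL) {
  stopifnot(sigma_x > 0, sigma_y > 0, rf_radius >= 0)
  if (is.null(support)) {
    support <- 2L * max(ceiling(3 * max(sigma_x, sigma_y)), ceiling(rf_radius) + 1L) + 1L
  }
  support <- as.integer(support)
  if (support %% 2L == 0L) stop("support must be odd", call. = FALSE)
  half <- (support - 1L) %/% 2L
  off <- seq.int(-half, half)
  X <- matrix(rep(off, each = support), support, support)
  Y <- matrix(rep(off, times = support), support, support)
  a <- theta * pi / 180
  xp <- X * cos(a) + Y * sin(a)
  yp <- Y * cos(a) - X * sin(a)
  m <- exp(-0.5 * ((xp / sigma_x)^2 + (yp / sigma_y)^2))
  m[X^2 + Y^2 <= rf_radius^2] <- 0
  s <- sum(m)
  if (s == 0) {
    warning("additive mask is empty: rf_radius covers the whole support",
            call. = FALSE)
    return(m)
  }
  m / s
}

# masks for every bank orientation at one scale
additive_masks_for_scale <- function(orientations, sigma_x, sigma_y, rf_radius,
                                     support = NULL) {
  lapply(orientations, additive_mask, sigma_x = sigma_x, sigma_y = sigma_y,
         rf_radius = rf_radius, support = support)
}

#' Induced additive fields
#'
#' For each orientation, the gain-controlled responses whose optimal
#' orientation matches are scaled by the facilitation strength \code{a} and
#' spread through the oriented additive mask (dense correlation realizes the
#' superposition over all neighboring inducers of that orientation).
#'
#' @param nr_response Nonnegative response matrix (one polarity, one scale).
#' @param angle_index Integer matrix of winning orientation indices.
#' @param masks List of additive masks, one per orientation.
#' @param a Facilitation strength.
#' @return List, per orientation, of \code{list(own, induced)}: the
#'   orientation-restricted response and its induced additive field.
#' @export
induce_additive <- function(nr_response, angle_index, masks, a = 1) {
  lapply(seq_along(masks), function(t) {
    own <- nr_response * (angle_index == t)
    induced <- if (a == 0 || !any(own > 0)) {
      matrix(0, nrow(own), ncol(own))
    } else {
      xcorr2(a * own, masks[[t]])
    }
    list(own = own, induced = induced)
  })
}

#' Collinear lateral-facilitation sum
#'
#' The lateral-facilitation field of one orientation channel: the classical
#' (own) response plus the summed additive fields induced by same-oriented
#' neighbors. Overlapping additive signals from collinear flankers add up,
#' which is what lifts sub-threshold gap responses above threshold.
#'
#' @param fields Output of [induce_additive()].
#' @return 3-D array \code{[row, col, orientation]}.
#' @export
collinear_sum <- function(fields) {
  h <- nrow(fields[[1]]$own); w <- ncol(fields[[1]]$own)
  arr <- array(0, dim = c(h, w, length(fields)))
  for (t in seq_along(fields)) arr[, , t] <- fields[[t]]$own + fields[[t]]$induced
  arr
}

#' Percentile soft threshold
#'
#' The gate level \code{thr} is the \code{gamma_j}-th percentile (type-1
#' quantile) of the *nonzero* facilitation values of the scale image — the
#' same convention as the edge-stage noise floor; taken over all pixels the
#' threshold collapses to zero whenever fewer than \code{100 - gamma_j}
#' percent of pixels respond, leaving the stage inert (see the methods
#' vignette). Values below the gate are set exactly to zero; values at or
#' above it are scaled by a logistic soft step \code{H(LF - thr)} of
#' steepness \code{k} (default \code{10/thr}), so \code{H(0) = 0.5} and the
#' hard threshold is recovered as \code{k -> Inf}. A pixel is said to be
#' *activated* when its gate factor exceeds 0.5, i.e. \code{LF > thr}.
#'
#' @param lf Numeric matrix or array (one orientation channel or a stack).
#' @param gamma_j Percentile in (0,100).
#' @param steepness Logistic steepness; NA (default) uses \code{10/thr}.
#' @return List with \code{lf_thr} (same shape, nonnegative where input is
#'   nonnegative), \code{thr}, and \code{steepness} actually used.
#' @export
percentile_soft_threshold <- function(lf, gamma_j, steepness = NA_real_) {
  if (gamma_j <= 0 || gamma_j >= 100) stop("gamma_j must be in (0,100)", call. = FALSE)
  nz <- lf[lf > 0]
  thr <- if (length(nz)) unname(stats::quantile(nz, gamma_j / 100, type = 1)) else 0
  if (length(unique(as.vector(lf))) == 1L && lf[1] != 0) {
    message("constant lateral-facilitation field: threshold equals the field value")
  }
  k <- if (is.na(steepness)) { if (thr > 0) 10 / thr else Inf } else steepness
  out <- lf
  below <- lf < thr
  out[below] <- 0
  if (is.finite(k)) {
    out[!below] <- lf[!below] * stats::plogis(k * (lf[!below] - thr))
  }  # k = Inf: hard gate, survivors kept at full value
  list(lf_thr = out, thr = thr, steepness = k)
}

#' Recombine polarity channels
#'
#' @param lf_thr_pos,lf_thr_neg Thresholded facilitation fields (matrices or
#'   arrays of identical shape).
#' @return \code{lf_thr_pos - lf_thr_neg}, elementwise.
#' @export
recombine_polarities <- function(lf_thr_pos, lf_thr_neg) {
  stopifnot(identical(dim(lf_thr_pos), dim(lf_thr_neg)))
  lf_thr_pos - lf_thr_neg
}

signed_power <- function(x, p) sign(x) * abs(x)^p

#' Collapse orientation channels
#'
#' Sums signed orientation responses raised (in magnitude) to the integer
#' power \code{m1} — emphasizing strong, consistent responses over weak
#' noise — then applies the inverse root so the result stays on the original
#' intensity scale.
#'
#' @param signed_combined 3-D array \code{[row, col, orientation]}.
#' @param m1 Integer >= 1 (default 1: a plain sum).
#' @return Matrix \code{T_j'} for the scale.
#' @export
recombine_orientations <- function(signed_combined, m1 = 1L) {
  if (m1 < 1) stop("m1 must be >= 1", call. = FALSE)
  d <- dim(signed_combined)
  tj <- matrix(0, d[1], d[2])
  for (t in seq_len(d[3])) tj <- tj + signed_power(signed_combined[, , t], m1)
  signed_power(tj, 1 / m1)
}

#' Collapse scales into the compound texture image
#'
#' Each per-scale map is Lanczos-upsampled to the target shape, the
#' tau-weighted signed \code{m2}-power sum is taken, and the normalization
#' \code{gamma_norm} with the inverse \code{1/m2} root restores the
#' intensity range (set \code{literal_power = TRUE} to skip the root).
#'
#' @param t_per_scale List of per-scale matrices \code{T_j'}, fine to coarse.
#' @param target_shape Integer vector \code{c(rows, cols)}.
#' @param tau Per-scale weights (recycled from the last entry).
#' @param m2 Integer >= 1 (default 2).
#' @param gamma_norm Normalization constant (default 1/8).
#' @param literal_power Apply the raw \code{m2} power without the root.
#' @return List with \code{texture} (the compound texture image TE),
#'   \code{compound} (pre-normalization sum) and \code{t_resized}.
#' @export
recombine_scales <- function(t_per_scale, target_shape, tau = 1, m2 = 2L,
                             gamma_norm = 1 / 8, literal_power = FALSE) {
  if (m2 < 1) stop("m2 must be >= 1", call. = FALSE)
  t_resized <- lapply(t_per_scale, function(tj) {
    if (all(dim(tj) == target_shape)) tj else
      lanczos_resize(tj, target_shape[1], target_shape[2])
  })
  acc <- matrix(0, target_shape[1], target_shape[2])
  for (j in seq_along(t_resized)) {
    acc <- acc + signed_power(t_resized[[j]], m2) / param_at(tau, j)
  }
  te <- if (literal_power) gamma_norm * acc else gamma_norm * signed_power(acc, 1 / m2)
  list(texture = te, compound = acc, t_resized = t_resized)
}

#' Lateral-facilitation line completion stage
#'
#' Runs, per scale and polarity: oriented additive-signal induction,
#' collinear summation, percentile soft thresholding, then recombination
#' over polarity, orientation and scale into the compound texture image.
#' Relative decay constants are converted to pixels by the scale image
#' width (\code{lf.pixel_scale_mode = "width"}) or taken literally.
#'
#' @param edges An \code{edge_stack} from [edge_decompose()].
#' @param target_shape Full-resolution shape \code{c(rows, cols)}.
#' @param config Pipeline configuration.
#' @return Object of class \code{lf_stack}: \code{per_scale} (each with
#'   \code{lf}, \code{lf_thr} pos/neg arrays, \code{thr} matrix
#'   \code{[orientation, polarity]}, \code{signed}, \code{t_prime}),
#'   \code{texture} (TE), \code{compound}, \code{t_resized}.
#' @export
lateral_facilitation <- function(edges, target_shape, config = default_config()) {
  stopifnot(inherits(edges, "edge_stack"))
  lfc <- config$lf
  per_scale <- vector("list", length(edges$per_scale))
  for (j in seq_along(edges$per_scale)) {
    es <- edges$per_scale[[j]]
    width <- ncol(es$angle_index)
    px <- if (lfc$pixel_scale_mode == "width") width else 1
    sx <- max(param_at(lfc$sigma_x, j) * px, 0.25)
    sy <- max(param_at(lfc$sigma_y, j) * px, 0.25)
    masks <- additive_masks_for_scale(edges$orientations, sx, sy, lfc$rf_radius)
    gam <- param_at(lfc$gamma_percentile, j)
    pol <- lapply(es$nr, function(nr_map) {
      lf <- collinear_sum(induce_additive(nr_map, es$angle_index, masks, lfc$a))
      thr <- numeric(dim(lf)[3])
      lf_thr <- array(0, dim = dim(lf))
      for (t in seq_len(dim(lf)[3])) {
        st <- percentile_soft_threshold(lf[, , t], gam, lfc$soft_step_steepness)
        lf_thr[, , t] <- st$lf_thr
        thr[t] <- st$thr
      }
      list(lf = lf, lf_thr = lf_thr, thr = thr)
    })
    signed <- recombine_polarities(pol$pos$lf_thr, pol$neg$lf_thr)
    per_scale[[j]] <- list(
      lf = list(pos = pol$pos$lf, neg = pol$neg$lf),
      lf_thr = list(pos = pol$pos$lf_thr, neg = pol$neg$lf_thr),
      thr = cbind(pos = pol$pos$thr, neg = pol$neg$thr),
      signed = signed,
      t_prime = recombine_orientations(signed, lfc$m1))
  }
  rec <- recombine_scales(lapply(per_scale, `[[`, "t_prime"), target_shape,
                          tau = lfc$tau, m2 = lfc$m2,
                          gamma_norm = lfc$gamma_norm,
                          literal_power = lfc$literal_scale_power)
  structure(list(per_scale = per_scale, texture = rec$texture,
                 compound = rec$compound, t_resized = rec$t_resized),
            class = "lf_stack")
}
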