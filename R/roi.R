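#' Otsu threshold of a value set
#'
#' Bins the values into a 256-bin histogram and returns the bin edge that
#' minimizes the within-class intensity variance (equivalently, maximizes
#' the between-class variance; the efficient cumulative form is used here).
#' Ties go to the lowest cut.
#'
#' @param values Numeric vector or matrix with at least two distinct values.
#' @param levels Number of histogram bins (default 256).
#' @return Scalar threshold; pixels strictly above it form the foreground.
#' @export
otsu_threshold <- function(values, levels = 256L) {
  v <- as.vector(values)
  rng <- range(v)
  if (rng[1] == rng[2]) {
    stop("otsu_threshold: input is constant", call. = FALSE)
  }
  edges <- seq(rng[1], rng[2], length.out = levels + 1L)
  mids <- (edges[-1L] + edges[-(levels + 1L)]) / 2
  h <- tabulate(pmin(pmax(findInterval(v, edges, all.inside = TRUE), 1L), levels),
                nbins = levels)
  w0 <- cumsum(h)[-levels]
  w1 <- sum(h) - w0
  m0 <- cumsum(h * mids)[-levels]
  mu_t <- sum(h * mids)
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, levels - 1L)
  between[valid] <- (mu_t * w0[valid] - sum(h) * m0[valid])^2 /
    (w0[valid] * w1[valid])
  edges[which.max(between) + 1L]   # upper edge of the background class
}

#' Binarize a per-scale compound map by Otsu's threshold
#'
#' @param t_prime_j Per-scale compound map (signed values admitted).
#' @param use_magnitude Threshold \code{abs(t_prime_j)} instead.
#' @return List with binary \code{mask} (1 strictly above the threshold)
#'   and \code{threshold} (NA, with a warning and an empty mask, for a
#'   constant input).
#' @export
binarize_scale <- function(t_prime_j, use_magnitude = FALSE) {
  vals <- if (use_magnitude) abs(t_prime_j) else t_prime_j
  if (length(unique(as.vector(vals))) < 2L) {
    warning("constant compound map: returning an empty scale mask", call. = FALSE)
    return(list(mask = matrix(0L, nrow(t_prime_j), ncol(t_prime_j)),
                threshold = NA_real_))
  }
  mu <- otsu_threshold(vals)
  mask <- matrix(0L, nrow(vals), ncol(vals))
  mask[vals > mu] <- 1L
  list(mask = mask, threshold = mu)
}

#' Morphological closing with a disk
#'
#' Dilation then erosion by the same disk structuring element; fills gaps
#' and holes narrower than the disk. Radius 0 is the identity.
#'
#' @param mask Binary matrix (0/1).
#' @param radius Disk radius in pixels.
#' @return Binary matrix; always a superset of the input foreground.
#' @export
morph_close <- function(mask, radius) {
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  if (radius == 0 || !any(mask > 0)) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(ceiling(radius)) + 1L, shape = "disc")
  m <- matrix(as.double(mask > 0), nrow(mask), ncol(mask))
  closed <- EBImage::erode(EBImage::dilate(m, brush), brush)
  # closing is extensive; the union guards against border erosion artifacts
  matrix(as.integer(closed > 0.5 | m > 0), nrow(mask), ncol(mask))
}

#' 8-connected component labels
#'
#' EBImage's fast 4-connected labeling, followed by merging labels that
#' touch diagonally (via graph components), yields 8-connectivity.
#'
#' @param mask Binary matrix.
#' @return Integer matrix of labels (0 = background), renumbered 1..n.
#' @export
label_components <- function(mask) {
  m <- matrix(as.double(mask > 0), nrow(mask), ncol(mask))
  lab <- matrix(as.integer(EBImage::bwlabel(m)), nrow(m), ncol(m))
  n <- max(lab)
  if (n <= 1L) return(lab)
  # diagonal adjacencies between distinct 4-connected labels
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- NULL
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    r1 <- seq_len(nr - 1L); c1 <- if (sh[2] == 1L) seq_len(nc - 1L) else 2:nc
    a <- lab[r1, c1, drop = FALSE]
    b <- lab[r1 + 1L, c1 + sh[2], drop = FALSE]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  if (is.null(pairs)) return(lab)
  g <- igraph::graph_from_edgelist(unique(pairs), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(n)]
  out <- lab
  out[lab > 0L] <- comp[lab[lab > 0L]]
  out
}

#' Keep the largest connected components
#'
#' Components are 8-connected; sizes are pixel counts, ties broken by the
#' earliest anchor pixel in row-major (top-left first) order.
#'
#' @param mask Binary matrix.
#' @param keep Number of components to retain (default 1).
#' @return Binary matrix containing only the retained components.
#' @export
largest_components <- function(mask, keep = 1L) {
  if (keep < 1) stop("keep must be >= 1", call. = FALSE)
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  # row-major anchor: first pixel reading left-to-right, top-to-bottom
  rowmajor <- (row(lab) - 1L) * ncol(lab) + col(lab)
  anchor <- vapply(seq_len(n), function(l) min(rowmajor[lab == l]), numeric(1))
  ord <- order(-sizes, anchor)
  kept <- ord[seq_len(min(keep, n))]
  matrix(as.integer(lab %in% kept & lab > 0L), nrow(mask), ncol(mask))
}

#' Sliding-median fusion of scale masks
#'
#' Width-\code{L} stride-1 windows over the ordered (fine to coarse) stack
#' of co-registered binary masks; per pixel the median of the L binary
#' values (majority vote for odd L, the even-L convention averaging the two
#' central order statistics).
#'
#' @param masks List of N full-size binary matrices.
#' @param L Window width, \code{1 <= L <= N}.
#' @return List of \code{N - L + 1} binary matrices.
#' @export
median_scale_windows <- function(masks, L = 3L) {
  n <- length(masks)
  if (L > n) stop("median width L exceeds the number of scale masks", call. = FALSE)
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  need <- if (L %% 2L == 1L) (L + 1L) / 2 else L / 2  # even L: 0.5 rounds up
  lapply(seq_len(n - L + 1L), function(i) {
    acc <- Reduce(`+`, masks[i:(i + L - 1L)])
    matrix(as.integer(acc >= need), nrow(masks[[1]]), ncol(masks[[1]]))
  })
}

#' Vote-combine median masks into the final ROI
#'
#' @param median_masks List of binary matrices.
#' @param tau Vote threshold; the ROI keeps pixels with vote count strictly
#'   above \code{tau} (default 0: the union).
#' @return List with integer \code{vote_image} and binary \code{roi}.
#' @export
combine_scale_masks <- function(median_masks, tau = 0) {
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  vote <- Reduce(`+`, median_masks)
  list(vote_image = vote,
       roi = matrix(as.integer(vote > tau), nrow(vote), ncol(vote)))
}

#' Multiscale blood-vessel ROI extraction
#'
#' Per scale: Otsu binarization of the compound map (of its magnitude by
#' default — see the methods vignette), disk closing with the radius capped
#' at 1/8 of the level size, largest 8-connected component(s); each mask is
#' then Lanczos-upsampled to full resolution and re-binarized at 0.5 so the
#' sliding-median fusion and vote threshold operate on a common grid.
#'
#' @param lf An \code{lf_stack} from [lateral_facilitation()], or a plain
#'   list of per-scale compound maps.
#' @param target_shape Full-resolution shape \code{c(rows, cols)}.
#' @param config Pipeline configuration.
#' @return Object of class \code{roi_masks}: \code{otsu_masks},
#'   \code{otsu_thresholds}, \code{closed_masks}, \code{cc_masks},
#'   \code{resized_masks}, \code{median_masks}, \code{vote_image},
#'   \code{roi}.
#' @export
extract_roi <- function(lf, target_shape, config = default_config()) {
  t_prime <- if (inherits(lf, "lf_stack")) {
    lapply(lf$per_scale, `[[`, "t_prime")
  } else lf
  rc <- config$roi
  otsu_masks <- list(); thresholds <- numeric(length(t_prime))
  closed <- list(); cc <- list(); resized <- list()
  for (j in seq_along(t_prime)) {
    b <- binarize_scale(t_prime[[j]], rc$use_magnitude)
    otsu_masks[[j]] <- b$mask
    thresholds[j] <- b$threshold
    # cap the disk so closing cannot erase a small level's structure
    radius <- min(param_at(rc$disk_radius, j), min(dim(b$mask)) %/% 8L)
    closed[[j]] <- morph_close(b$mask, radius)
    cc[[j]] <- largest_components(closed[[j]], rc$keep_components)
    resized[[j]] <- if (all(dim(cc[[j]]) == target_shape)) cc[[j]] else {
      matrix(as.integer(lanczos_resize(cc[[j]] + 0, target_shape[1],
                                       target_shape[2]) > 0.5),
             target_shape[1], target_shape[2])
    }
  }
  L <- min(rc$median_width, length(resized))
  med <- median_scale_windows(resized, L)
  comb <- combine_scale_masks(med, rc$vote_threshold)
  structure(list(otsu_masks = otsu_masks, otsu_thresholds = thresholds,
                 closed_masks = closed, cc_masks = cc, resized_masks = resized,
                 median_masks = med, vote_image = comb$vote_image,
                 roi = comb$roi),
            class = "roi_masks")
}
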