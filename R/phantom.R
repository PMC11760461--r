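#' Specification for a synthetic angiogram phantom
#'
#' Describes the frame the generator renders: a dark branching vessel tree
#' (contrast agent absorbs X-rays) on a brighter background, modulated by a
#' smooth non-uniform illumination field, broad low-contrast bony blobs,
#' optional tool-like curves (a thin wire with stent-marker dots), and
#' photon-counting (Poisson) quantum noise. The seed fully determines the
#' output.
#'
#' @param size Frame side length in pixels (default 256).
#' @param background_level Background intensity (default 0.65).
#' @param vessel_contrast Peak fractional X-ray absorption of the vessel
#'   tube profile (default 0.25).
#' @param root_caliber Root vessel caliber (diameter) in pixels (default 6).
#' @param min_caliber Smallest rendered caliber in pixels (default 1.2).
#' @param depth Branching depth of the tree (default 4).
#' @param branch_angle Range, degrees, of the half-angle between daughter
#'   branches (default c(20, 45)).
#' @param illumination_amplitude Relative amplitude of the smooth
#'   multiplicative illumination field (default 0.15).
#' @param bone_count,bone_contrast Number and absorption contrast of broad
#'   low-frequency bony structures (defaults 2 and 0.08).
#' @param wire Render a thin tool-like wire with marker dots (default TRUE).
#' @param tool_contrast Absorption contrast of the tools (default 0.35).
#' @param photon_scale Mean photon count at unit intensity; lower means
#'   lower radiation dose (default 2000; \code{Inf} disables noise).
#' @param contrast_dilution Multiplier on the vessel contrast emulating dye
#'   clearance (default 1).
#' @param seed Integer RNG seed (default 1).
#' @return List of class \code{phantom_spec}.
#' @export
phantom_spec <- function(size = 256L, background_level = 0.65,
                         vessel_contrast = 0.25, root_caliber = 6,
                         min_caliber = 1.2, depth = 4L,
                         branch_angle = c(20, 45),
                         illumination_amplitude = 0.15,
                         bone_count = 2L, bone_contrast = 0.08,
                         wire = TRUE, tool_contrast = 0.35,
                         photon_scale = 2000, contrast_dilution = 1,
                         seed = 1L) {
  if (root_caliber < 1 || min_caliber < 1) {
    stop("vessel calibers below 1 px cannot be rendered", call. = FALSE)
  }
  if (size < 32) stop("phantom size must be at least 32 px", call. = FALSE)
  structure(as.list(environment()), class = "phantom_spec")
}

# stamp a Gaussian tube profile sample onto the attenuation canvas
stamp_tube <- function(canvas, mask, cx, cy, r) {
  n <- nrow(canvas)
  sp <- r / 1.6                       # profile sd from the tube radius
  w <- ceiling(2.5 * sp) + 1L
  rows <- max(1L, floor(cy - w)):min(n, ceiling(cy + w))
  cols <- max(1L, floor(cx - w)):min(ncol(canvas), ceiling(cx + w))
  if (!length(rows) || !length(cols)) return(list(canvas = canvas, mask = mask))
  d2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
  canvas[rows, cols] <- pmax(canvas[rows, cols], exp(-d2 / (2 * sp^2)))
  mask[rows, cols] <- mask[rows, cols] | (d2 <= r^2)
  list(canvas = canvas, mask = mask)
}

# grow a wiggly branching centerline and render it as dark tubes
render_tree <- function(size, root_caliber, min_caliber, depth, branch_angle) {
  canvas <- matrix(0, size, size)
  mask <- matrix(FALSE, size, size)
  ds <- 1.5
  queue <- list(list(x = 2, y = size * stats::runif(1, 0.3, 0.7),
                     heading = stats::runif(1, -0.3, 0.3),
                     r = root_caliber / 2, depth = depth,
                     until_split = stats::runif(1, 25, 50)))
  while (length(queue) > 0) {
    b <- queue[[1]]; queue <- queue[-1]
    repeat {
      b$x <- b$x + ds * cos(b$heading)
      b$y <- b$y + ds * sin(b$heading)
      if (b$x < 1 || b$x > size || b$y < 1 || b$y > size) break
      b$heading <- b$heading + stats::rnorm(1, 0, 0.06)
      b$r <- b$r * 0.9985
      if (2 * b$r < min_caliber) break
      st <- stamp_tube(canvas, mask, b$x, b$y, b$r)
      canvas <- st$canvas; mask <- st$mask
      b$until_split <- b$until_split - ds
      if (b$until_split <= 0) {
        if (b$depth > 1L) {
          half <- stats::runif(1, branch_angle[1], branch_angle[2]) * pi / 180
          for (s in c(-1, 1)) {
            queue[[length(queue) + 1L]] <- list(
              x = b$x, y = b$y, heading = b$heading + s * half,
              r = b$r * stats::runif(1, 0.65, 0.8), depth = b$depth - 1L,
              until_split = stats::runif(1, 25, 50))
          }
        }
        break
      }
    }
  }
  list(attenuation = canvas, mask = mask)
}

render_wire <- function(size, n_markers = 2L) {
  canvas <- matrix(0, size, size)
  mask <- matrix(FALSE, size, size)
  x <- 2; y <- size * stats::runif(1, 0.15, 0.85)
  heading <- stats::runif(1, -0.2, 0.2)
  pts <- NULL
  while (x >= 1 && x <= size && y >= 1 && y <= size) {
    st <- stamp_tube(canvas, mask, x, y, 0.8)
    canvas <- st$canvas; mask <- st$mask
    pts <- rbind(pts, c(x, y))
    x <- x + 1.2 * cos(heading); y <- y + 1.2 * sin(heading)
    heading <- heading + stats::rnorm(1, 0, 0.03)
  }
  if (n_markers > 0 && nrow(pts) > 10) {
    at <- pts[round(seq(0.35, 0.75, length.out = n_markers) * nrow(pts)), ,
              drop = FALSE]
    for (i in seq_len(nrow(at))) {
      st <- stamp_tube(canvas, mask, at[i, 1], at[i, 2], 2)
      canvas <- st$canvas; mask <- st$mask
    }
  }
  list(attenuation = canvas, mask = mask)
}

smooth_field <- function(size, grid = 4L) {
  g <- matrix(stats::rnorm(grid^2), grid, grid)
  f <- lanczos_resize(g, size, size)
  f <- f - mean(f)
  m <- max(abs(f))
  if (m > 0) f / m else f
}

#' Generate a synthetic angiogram phantom with ground truth
#'
#' Renders the scene described by a [phantom_spec()]: the noise-free frame
#' composes multiplicative absorption layers
#' \code{background * illumination * (1 - bones) * (1 - vessels) * (1 - tools)},
#' then quantum noise is applied as
#' \code{Poisson(photon_scale * I) / photon_scale}.
#'
#' @param spec A \code{phantom_spec}.
#' @return List of class \code{phantom} with \code{frame} (noisy),
#'   \code{clean} (noise-free render), and \code{ground_truth}: binary
#'   \code{vessel_mask}, \code{tool_mask}, \code{background_sample_region}
#'   (pixels at least 8 px from any vessel/tool and outside bone cores),
#'   plus the \code{spec}.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  n <- spec$size
  tree <- render_tree(n, spec$root_caliber, spec$min_caliber, spec$depth,
                      spec$branch_angle)
  tool <- if (spec$wire) render_wire(n) else
    list(attenuation = matrix(0, n, n), mask = matrix(FALSE, n, n))
  bone <- matrix(0, n, n)
  for (b in seq_len(spec$bone_count)) {
    cx <- stats::runif(1, 0.2, 0.8) * n; cy <- stats::runif(1, 0.2, 0.8) * n
    sx <- stats::runif(1, 0.12, 0.28) * n; sy <- stats::runif(1, 0.12, 0.28) * n
    d <- outer((seq_len(n) - cy)^2 / (2 * sy^2), (seq_len(n) - cx)^2 / (2 * sx^2), `+`)
    bone <- pmax(bone, spec$bone_contrast * exp(-d))
  }
  illum <- 1 + spec$illumination_amplitude * smooth_field(n)
  clean <- spec$background_level * illum *
    (1 - bone) *
    (1 - spec$contrast_dilution * spec$vessel_contrast * tree$attenuation) *
    (1 - spec$tool_contrast * tool$attenuation)
  clean <- clip01(clean)
  frame <- if (is.finite(spec$photon_scale)) {
    clip01(matrix(stats::rpois(n * n, spec$photon_scale * clean), n, n) /
             spec$photon_scale)
  } else clean
  # background sample region: >= 8 px from vessels/tools, outside bone cores
  occupied <- matrix(as.double(tree$mask | tool$mask), n, n)
  far <- EBImage::dilate(occupied, EBImage::makeBrush(17L, shape = "disc")) < 0.5
  bg <- far & (bone < 0.25 * spec$bone_contrast)
  structure(list(frame = frame, clean = clean,
                 ground_truth = list(
                   vessel_mask = matrix(as.integer(tree$mask), n, n),
                   tool_mask = matrix(as.integer(tool$mask), n, n),
                   background_sample_region = matrix(as.integer(bg), n, n)),
                 spec = spec),
            class = "phantom")
}

#' Contrast-to-noise ratio of a vessel against its background
#'
#' \code{CNR = |mean(background) - mean(vessel)| / sd(background)}, the
#' common angiography visibility convention. Note the literature reports
#' CNR improvements without a single agreed definition; this one is
#' documented so results are comparable only within this convention.
#'
#' @param frame Frame in \[0,1].
#' @param ground_truth List with binary \code{vessel_mask} and
#'   \code{background_sample_region}.
#' @return Scalar CNR.
#' @export
cnr <- function(frame, ground_truth) {
  vm <- ground_truth$vessel_mask > 0
  bg <- ground_truth$background_sample_region > 0
  if (!any(vm) || !any(bg)) stop("cnr: empty mask", call. = FALSE)
  s <- stats::sd(frame[bg])
  if (s == 0) stop("cnr: constant background region", call. = FALSE)
  abs(mean(frame[bg]) - mean(frame[vm])) / s
}

#' Percent CNR improvement between two renderings of the same scene
#'
#' @param frame_before,frame_after Frames sharing the ground truth.
#' @param ground_truth As in [cnr()].
#' @return \code{100 * (CNR_after - CNR_before) / CNR_before}.
#' @export
cnr_improvement <- function(frame_before, frame_after, ground_truth) {
  before <- cnr(frame_before, ground_truth)
  if (before == 0) stop("cnr_improvement: baseline CNR is zero", call. = FALSE)
  100 * (cnr(frame_after, ground_truth) - before) / before
}

#' Two-bar fixture for collinear line-completion checks
#'
#' Two dark bars of width \code{bar_width} separated by \code{gap} pixels on
#' a bright background. With \code{angle_between = 0} the bars are
#' collinear; otherwise the second bar is rotated about the far side of the
#' gap. Returns the frame and the exact gap region between the facing bar
#' ends for assertions.
#'
#' @param bar_length,bar_width,gap Geometry in pixels.
#' @param angle_between Rotation of the second bar in degrees (0 or 90 are
#'   the canonical cases).
#' @param size Frame side length (default 256).
#' @param background,bar_level Intensities (defaults 0.8 and 0.3).
#' @return List with \code{frame}, binary \code{gap_region}, and binary
#'   \code{bar_mask}.
#' @export
gap_fixture <- function(bar_length = 24, bar_width = 3, gap = 4,
                        angle_between = 0, size = 256L,
                        background = 0.8, bar_level = 0.3) {
  # column center on the half-grid so a gap of g opens exactly g columns;
  # row center placed so an odd bar_width rasterizes to exactly that many rows
  cc <- size / 2 + 0.5
  cy <- if (bar_width %% 2 == 1) size %/% 2 else size / 2 + 0.5
  hw <- bar_width / 2
  # capsule pixels: distance to a segment <= half-width
  seg_dist <- function(px, py, x0, y0, x1, y1) {
    dx <- x1 - x0; dy <- y1 - y0
    tt <- ((px - x0) * dx + (py - y0) * dy) / (dx^2 + dy^2)
    tt <- pmin(pmax(tt, 0), 1)
    sqrt((px - (x0 + tt * dx))^2 + (py - (y0 + tt * dy))^2)
  }
  px <- matrix(rep(seq_len(size), each = size), size, size)   # column = x
  py <- matrix(rep(seq_len(size), times = size), size, size)  # row = y
  # bar 1: horizontal, its right face at the gap's left edge
  b1 <- seg_dist(px, py, cc - gap / 2 - bar_length + hw, cy,
                 cc - gap / 2 - hw, cy) <= hw
  a <- angle_between * pi / 180
  if (angle_between %% 180 == 0) {
    b2 <- seg_dist(px, py, cc + gap / 2 + hw, cy,
                   cc + gap / 2 + bar_length - hw, cy) <= hw
  } else {
    # rotated bar centered beyond the gap's right edge
    mx <- cc + gap / 2 + hw
    dx <- cos(a) * (bar_length / 2 - hw); dy <- sin(a) * (bar_length / 2 - hw)
    b2 <- seg_dist(px, py, mx - dx, cy - dy, mx + dx, cy + dy) <= hw
  }
  bars <- b1 | b2
  frame <- matrix(background, size, size)
  frame[bars] <- bar_level
  gap_region <- px > cc - gap / 2 & px < cc + gap / 2 & abs(py - cy) <= hw
  list(frame = frame,
       gap_region = matrix(as.integer(gap_region & !bars), size, size),
       bar_mask = matrix(as.integer(bars), size, size))
}

#' Gap activation fraction of the lateral-facilitation field
#'
#' Runs the edge decomposition and lateral facilitation at the finest scale
#' on a fixture frame and reports the fraction of the gap region where the
#' post-threshold facilitation field *at the first bar's orientation* (in
#' either polarity) is nonzero — the operational measure of whether the
#' line is completed across the gap. Measuring at the line's own
#' orientation is what makes the perpendicular control meaningful: a
#' crossing bar excites its own orientation channels in the gap regardless
#' of any facilitation.
#'
#' @param fixture Output of [gap_fixture()].
#' @param config Pipeline configuration.
#' @param orientation Orientation (degrees) of the line whose completion is
#'   probed; default 0, the first bar of [gap_fixture()].
#' @return Fraction in \[0,1].
#' @export
gap_activation_fraction <- function(fixture, config = default_config(),
                                    orientation = 0) {
  pyr <- build_pyramid(fixture$frame, 1L)
  bank <- build_gabor_bank(config$gabor$sigma, config$gabor$lambda,
                           config$gabor$n_orientations, config$gabor$support)
  edges <- edge_decompose(pyr, bank, config)
  lf <- lateral_facilitation(edges, dim(fixture$frame), config)
  t <- which.min(abs(edges$orientations - orientation))
  act <- lf$per_scale[[1]]$lf_thr$pos[, , t] > 0 |
    lf$per_scale[[1]]$lf_thr$neg[, , t] > 0
  mean(act[fixture$gap_region > 0])
}
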