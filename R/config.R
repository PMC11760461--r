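#' Default pipeline configuration
#'
#' Per-scale vectors (lateral-facilitation decay constants, threshold
#' percentiles, closing radii) follow the published per-scale parameter
#' table for an 8-scale decomposition; when a pyramid ends up with fewer
#' scales the leading entries are used, and deeper requests recycle the last
#' entry.
#'
#' Groups and keys:
#' \describe{
#'   \item{gabor}{\code{sigma} (8 px), \code{lambda} (12 px),
#'     \code{n_orientations} (8), \code{support} (33 px, odd).}
#'   \item{pyramid}{\code{n_scales} (8).}
#'   \item{noise}{\code{percentile} (0.05), \code{mode}
#'     ("percentile" or "max_fraction").}
#'   \item{nr}{\code{n} (2), \code{sigma} (0.1), \code{sigma_is_power}
#'     (FALSE: \code{sigma} is the semi-saturation itself).}
#'   \item{lf}{\code{sigma_x}, \code{sigma_y} (per-scale collinear /
#'     orthogonal decay, relative units), \code{gamma_percentile} (per-scale
#'     threshold percentile), \code{a} (facilitation strength, 1),
#'     \code{rf_radius} (classical-RF radius, 8 px),
#'     \code{m1} (1), \code{m2} (2), \code{gamma_norm} (1/8), \code{tau}
#'     (per-scale weights, all 1), \code{soft_step_steepness} (NA = auto
#'     10/thr), \code{pixel_scale_mode} ("width": relative sigmas scale with
#'     the level width; "pixels": taken literally),
#'     \code{literal_scale_power} (FALSE: apply the 1/m2 root).}
#'   \item{roi}{\code{disk_radius} (per-scale closing radii 0,2,3,4,5,5,5,6),
#'     \code{median_width} (3), \code{vote_threshold} (0),
#'     \code{keep_components} (1), \code{use_magnitude} (FALSE).}
#'   \item{integrate}{\code{alpha} (0.4), \code{beta} (4),
#'     \code{clip} (TRUE).}
#' }
#'
#' @return Nested named list of class \code{pipeline_config}.
#' @export
default_config <- function() {
  structure(list(
    gabor = list(sigma = 8, lambda = 12, n_orientations = 8L, support = 33L),
    pyramid = list(n_scales = 8L),
    noise = list(percentile = 0.05, mode = "percentile"),
    nr = list(n = 2, sigma = 0.1, sigma_is_power = FALSE),
    lf = list(
      sigma_x = c(0.05, 0.05, 0.06, 0.07, 0.07, 0.07, 0.1, 0.1),
      sigma_y = c(0.05, 0.05, 0.06, 0.07, 0.07, 0.07, 0.1, 0.1),
      gamma_percentile = c(99, 80, 97, 97, 96, 96, 96, 96),
      a = 1, rf_radius = 8, m1 = 1L, m2 = 2L, gamma_norm = 1 / 8,
      tau = rep(1, 8), soft_step_steepness = NA_real_,
      pixel_scale_mode = "width", literal_scale_power = FALSE),
    roi = list(disk_radius = c(0, 2, 3, 4, 5, 5, 5, 6), median_width = 3L,
               vote_threshold = 0, keep_components = 1L, use_magnitude = TRUE),
    integrate = list(alpha = 0.4, beta = 4, clip = TRUE)
  ), class = "pipeline_config")
}

# index a per-scale parameter vector, recycling the last entry
param_at <- function(vec, j) vec[min(j, length(vec))]

#' Load a pipeline configuration from a YAML file
#'
#' Values in the file override the defaults; unknown keys are rejected with
#' the offending key named, and basic type/range checks are applied.
#'
#' @param path Path to a YAML file, or NULL for pure defaults.
#' @return A \code{pipeline_config}.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (!is.list(user)) stop("config file must contain a mapping", call. = FALSE)
  for (grp in names(user)) {
    if (!grp %in% names(cfg)) {
      stop("unknown config group: '", grp, "'", call. = FALSE)
    }
    for (key in names(user[[grp]])) {
      if (!key %in% names(cfg[[grp]])) {
        stop("unknown config key: '", grp, ".", key, "'", call. = FALSE)
      }
      cfg[[grp]][[key]] <- user[[grp]][[key]]
    }
  }
  validate_config(cfg)
}

#' Write a configuration to YAML
#' @param config A \code{pipeline_config}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(cfg) {
  pos <- function(x, nm) if (!is.numeric(x) || any(x <= 0)) {
    stop("config ", nm, " must be positive", call. = FALSE)
  }
  pos(cfg$gabor$sigma, "gabor.sigma"); pos(cfg$gabor$lambda, "gabor.lambda")
  if (cfg$gabor$n_orientations < 2) stop("gabor.n_orientations must be >= 2", call. = FALSE)
  if (cfg$gabor$support %% 2 == 0) stop("gabor.support must be odd", call. = FALSE)
  if (cfg$pyramid$n_scales < 1) stop("pyramid.n_scales must be >= 1", call. = FALSE)
  if (cfg$noise$percentile <= 0 || cfg$noise$percentile >= 1) {
    stop("noise.percentile must be in (0,1)", call. = FALSE)
  }
  if (!cfg$noise$mode %in% c("percentile", "max_fraction")) {
    stop("noise.mode must be 'percentile' or 'max_fraction'", call. = FALSE)
  }
  if (cfg$nr$n < 1) stop("nr.n must be >= 1", call. = FALSE)
  pos(cfg$nr$sigma, "nr.sigma")
  pos(cfg$lf$sigma_x, "lf.sigma_x"); pos(cfg$lf$sigma_y, "lf.sigma_y")
  if (any(cfg$lf$gamma_percentile <= 0 | cfg$lf$gamma_percentile >= 100)) {
    stop("lf.gamma_percentile entries must be in (0,100)", call. = FALSE)
  }
  if (cfg$lf$rf_radius < 0) stop("lf.rf_radius must be >= 0", call. = FALSE)
  if (cfg$lf$m1 < 1 || cfg$lf$m2 < 1) stop("lf.m1 and lf.m2 must be >= 1", call. = FALSE)
  pos(cfg$lf$tau, "lf.tau")
  if (!cfg$lf$pixel_scale_mode %in% c("width", "pixels")) {
    stop("lf.pixel_scale_mode must be 'width' or 'pixels'", call. = FALSE)
  }
  if (any(cfg$roi$disk_radius < 0)) stop("roi.disk_radius must be >= 0", call. = FALSE)
  if (cfg$roi$median_width < 1) stop("roi.median_width must be >= 1", call. = FALSE)
  if (cfg$roi$vote_threshold < 0) stop("roi.vote_threshold must be >= 0", call. = FALSE)
  if (cfg$roi$keep_components < 1) stop("roi.keep_components must be >= 1", call. = FALSE)
  if (cfg$integrate$alpha < 0 || cfg$integrate$beta < 0) {
    stop("integrate.alpha and integrate.beta must be >= 0", call. = FALSE)
  }
  cfg
}
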