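#' Read a grayscale frame from PNG or TIFF
#'
#' Intensities are mapped linearly to \[0,1] from the source bit depth
#' (handled by the format readers). RGB input is converted to luma
#' (Rec. 709 weights) with a warning.
#'
#' @param path Path to an 8- or 16-bit PNG or TIFF file.
#' @return Numeric matrix in \[0,1]; multi-directory TIFFs return a list of
#'   matrices.
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) stop("cannot read frame: no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path, all = TRUE),
    stop("unsupported image format '", ext, "' (use png or tiff): ", path,
         call. = FALSE))
  to_gray <- function(x) {
    if (length(dim(x)) == 3L) {
      warning("color input converted to luma: ", path, call. = FALSE)
      x <- if (dim(x)[3] >= 3L) {
        0.2126 * x[, , 1] + 0.7152 * x[, , 2] + 0.0722 * x[, , 3]
      } else x[, , 1]
    }
    clip01(matrix(as.numeric(x), nrow(x), ncol(x)))
  }
  if (is.list(img)) {
    frames <- lapply(img, to_gray)
    if (length(frames) == 1L) frames[[1]] else frames
  } else to_gray(img)
}

#' Write a frame to PNG or TIFF
#'
#' Quantizes \[0,1] intensities to the requested depth; both formats are
#' lossless. The PNG writer emits 8 bits; use TIFF for 16- or 32-bit output.
#'
#' @param frame Numeric matrix in \[0,1].
#' @param path Output path ending in .png, .tif or .tiff.
#' @param bit_depth Target bit depth (default 16; PNG forces 8).
#' @return \code{path}, invisibly.
#' @export
write_frame <- function(frame, path, bit_depth = 16L) {
  if (!is.matrix(frame) || any(!is.finite(frame)) ||
      min(frame) < 0 || max(frame) > 1) {
    stop("frame must be a finite numeric matrix in [0,1]", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = {
      if (bit_depth != 8L) {
        stop("png output is 8-bit; use tiff for ", bit_depth, "-bit frames",
             call. = FALSE)
      }
      png::writePNG(round(frame * 255) / 255, path)
    },
    tif = , tiff = {
      if (!bit_depth %in% c(8L, 16L, 32L)) {
        stop("tiff supports 8, 16 or 32 bits", call. = FALSE)
      }
      tiff::writeTIFF(frame, path, bits.per.sample = as.integer(bit_depth))
    },
    stop("unsupported image format '", ext, "' (use png or tiff)", call. = FALSE))
  invisible(path)
}
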