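#' Flat structuring element
#'
#' Full square structuring element of odd size with its center set;
#' \code{flatSE(3)} is the default 3x3 square used throughout.
#'
#' @param size odd integer side length.
#' @return A logical matrix.
#' @export
flatSE <- function(size = 3L) {
  size <- as.integer(size)
  if (length(size) != 1L || size < 1L || size %% 2L == 0L)
    stop("structuring element size must be a positive odd integer",
         call. = FALSE)
  matrix(TRUE, size, size)
}

.checkSE <- function(se) {
  if (!is.matrix(se) || !is.logical(se))
    stop("structuring element must be a logical matrix", call. = FALSE)
  if (nrow(se) %% 2L == 0L || ncol(se) %% 2L == 0L)
    stop("structuring element dimensions must be odd", call. = FALSE)
  if (!se[(nrow(se) + 1L) %/% 2L, (ncol(se) + 1L) %/% 2L])
    stop("structuring element center must be set", call. = FALSE)
  invisible(se)
}

#' Grayscale dilation and erosion
#'
#' Window maximum (dilation) or minimum (erosion) over the structuring
#' element footprint, truncated at the image borders (only in-image
#' neighbors participate).  A 1x1 structuring element returns the input
#' unchanged.
#'
#' @param img numeric matrix.
#' @param se logical structuring element with odd dimensions and its
#'   center set; default the full 3x3 square.
#' @return Matrix of the same shape.
#' @export
grayDilate <- function(img, se = flatSE(3L)) {
  .checkImage(img); .checkSE(se)
  gray_dilate_cpp(img, se)
}

#' @rdname grayDilate
#' @export
grayErode <- function(img, se = flatSE(3L)) {
  .checkImage(img); .checkSE(se)
  gray_erode_cpp(img, se)
}

.reconstruct <- function(mask, marker, se, dilation, tol = 1e-12,
                         maxIter = 10000L) {
  .checkImage(mask); .checkImage(marker); .checkSE(se)
  if (!identical(dim(mask), dim(marker)))
    stop("'mask' and 'marker' must have the same shape", call. = FALSE)
  d <- if (dilation) marker - mask else mask - marker
  if (max(d) > 0)
    stop(sprintf(
      "marker must be %s the mask everywhere (max violation %.6g)",
      if (dilation) "<=" else ">=", max(d)), call. = FALSE)
  geodesic_reconstruct_cpp(marker, mask, se, dilation, tol, maxIter)$image
}

#' Morphological reconstruction by dilation or erosion
#'
#' Geodesic reconstruction: starting from the marker g, iterate
#' \code{g <- pmin(dilate(g), mask)} (dilation form; requires
#' \code{marker <= mask}) or \code{g <- pmax(erode(g), mask)} (erosion
#' form; requires \code{marker >= mask}) until the fixed point.  The
#' result is sandwiched between marker and mask.
#'
#' @param mask constraining image f.
#' @param marker seed image g.
#' @param se structuring element (default 3x3 square).
#' @return The reconstructed image.
#' @export
reconstructDilation <- function(mask, marker, se = flatSE(3L)) {
  .reconstruct(mask, marker, se, dilation = TRUE)
}

#' @rdname reconstructDilation
#' @export
reconstructErosion <- function(mask, marker, se = flatSE(3L)) {
  .reconstruct(mask, marker, se, dilation = FALSE)
}

# opening-by-reconstruction: suppress bright structures smaller than the SE
.openRec <- function(f, se) reconstructDilation(f, grayErode(f, se), se)
# closing-by-reconstruction: suppress dark structures smaller than the SE
.closeRec <- function(f, se) reconstructErosion(f, grayDilate(f, se), se)

#' Opening and closing reconstruction
#'
#' Compound reconstruction operators.  \code{openingReconstruction} is the
#' opening-by-reconstruction applied to the closing-by-reconstruction of
#' the input; \code{closingReconstruction} is the dual composition
#' (closing-by-reconstruction of the opening-by-reconstruction).  Both
#' remove bright and dark structures smaller than the structuring element
#' while preserving object contours, which re-concentrates the histogram
#' of a noisy piecewise-constant image near its class intensities.
#' \code{reconstructImage} is the denoising operator applied to an image
#' before clustering: the closing reconstruction of the raw noisy image.
#'
#' @param f input image (the raw noisy image is the mask; markers are its
#'   erosion/dilation by \code{se}).
#' @param se structuring element (default 3x3 square).
#' @return The reconstructed image; values stay within \code{range(f)}.
#' @export
openingReconstruction <- function(f, se = flatSE(3L)) {
  .openRec(.closeRec(f, se), se)
}

#' @rdname openingReconstruction
#' @export
closingReconstruction <- function(f, se = flatSE(3L)) {
  .closeRec(.openRec(f, se), se)
}

#' @rdname openingReconstruction
#' @export
reconstructImage <- function(f, se = flatSE(3L)) {
  closingReconstruction(f, se)
}
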