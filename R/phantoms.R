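#' Synthetic segmentation phantoms with ground truth
#'
#' Builds one of two fixed 256 x 256 test images.  \code{"ST"} has three
#' classes with 8-bit intensities 0, 85 and 170; \code{"SF"} has four
#' classes with intensities 0, 85, 170 and 255.  The geometric layout is a
#' fixed, versioned convention of this package: ST is three equal-width
#' vertical bands with an inscribed disk and an inscribed square that cross
#' band boundaries (flat regions plus curved and straight edges); SF is a
#' 2 x 2 quadrant layout with an inscribed central disk.  The generator is
#' deterministic and also returns the pixel-aligned ground-truth label map.
#'
#' @param name phantom name, \code{"ST"} or \code{"SF"}.
#' @return A list with elements \code{image} (numeric matrix on the 8-bit
#'   0..255 scale), \code{labels} (integer matrix of class labels in
#'   1..n_classes), \code{intensities} (8-bit intensity of each class),
#'   \code{n_classes} and \code{name}.
#' @examples
#' ph <- makePhantom("ST")
#' table(ph$image)
#' @export
makePhantom <- function(name = c("ST", "SF")) {
  if (!is.character(name) || length(name) != 1L || !name %in% c("ST", "SF"))
    stop("unknown phantom name; valid options are \"ST\" and \"SF\"",
         call. = FALSE)
  n <- 256L
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  if (name == "ST") {
    intensities <- c(0, 85, 170)
    lab <- matrix(1L, n, n)
    lab[col >= 86L & col <= 170L] <- 2L
    lab[col >= 171L] <- 3L
    # disk of class 3 straddling the boundary between bands 1 and 2
    lab[(row - 78)^2 + (col - 86)^2 <= 40^2] <- 3L
    # square of class 1 straddling the boundary between bands 2 and 3
    lab[row >= 150L & row <= 213L & col >= 139L & col <= 202L] <- 1L
  } else {
    intensities <- c(0, 85, 170, 255)
    lab <- matrix(1L, n, n)
    lab[row <= 128L & col >= 129L] <- 2L
    lab[row >= 129L & col <= 128L] <- 3L
    lab[row >= 129L & col >= 129L] <- 4L
    # central disk of class 4 crossing all quadrant boundaries
    lab[(row - 128.5)^2 + (col - 128.5)^2 <= 48^2] <- 4L
  }
  list(image = matrix(intensities[lab], n, n), labels = lab,
       intensities = intensities, n_classes = length(intensities),
       name = name)
}

#' Rescale an 8-bit image to the canonical [0,1] intensity scale
#'
#' @param img numeric matrix.
#' @param maxval intensity mapped to 1 (default 255).
#' @return The rescaled matrix.
#' @export
normalizeImage <- function(img, maxval = 255) {
  .checkImage(img)
  img / maxval
}
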