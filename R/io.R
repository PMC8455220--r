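#' Read and write grayscale images and label maps as PNG
#'
#' \code{readGrayImage} reads a PNG into a numeric matrix on [0,1]
#' (multi-channel images are averaged over the first three channels).
#' \code{writeGrayImage} writes a [0,1] matrix as grayscale PNG (values
#' clipped into range).  Label maps use the convention
#' gray level = (label - 1)/255, supporting up to 256 classes.
#'
#' @param path file path.
#' @param img numeric matrix on [0,1].
#' @param labels integer matrix of labels in 1..n_classes.
#' @return \code{readGrayImage}: a numeric matrix on [0,1];
#'   \code{readLabelMap}: an integer matrix of 1-based labels; the writers
#'   return the path invisibly.
#' @export
readGrayImage <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L)
    x <- apply(x[, , seq_len(min(3L, dim(x)[3L])), drop = FALSE],
               c(1L, 2L), mean)
  x
}

#' @rdname readGrayImage
#' @export
writeGrayImage <- function(img, path) {
  .checkImage(img)
  img[img < 0] <- 0
  img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname readGrayImage
#' @export
writeLabelMap <- function(labels, path) {
  if (min(labels) < 1L || max(labels) > 256L)
    stop("labels must lie in 1..256", call. = FALSE)
  png::writePNG((labels - 1L) / 255, path)
  invisible(path)
}

#' @rdname readGrayImage
#' @export
readLabelMap <- function(path) {
  img <- readGrayImage(path)
  matrix(as.integer(round(img * 255)) + 1L, nrow(img), ncol(img))
}
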