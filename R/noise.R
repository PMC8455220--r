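#' Corrupt an image with parameterized noise
#'
#' Adds one of three noise models to an image on the [0,1] scale,
#' reproducibly from a seed; the caller's RNG state is left untouched.
#'
#' \describe{
#'   \item{gaussian}{adds zero-mean Gaussian noise with \emph{variance}
#'     \code{level} on the [0,1] scale ("5\% Gaussian noise" means variance
#'     0.05, the \code{imnoise} convention).}
#'   \item{salt_pepper}{replaces a fraction \code{level} of the pixels,
#'     chosen uniformly without replacement; half become salt (1) and half
#'     pepper (0).  The corrupted count is exactly
#'     \code{round(level * N)}; an odd count gets the extra pixel as salt.}
#'   \item{rician}{replaces each pixel v by
#'     \code{sqrt((v + n1)^2 + n2^2)} with n1, n2 independent zero-mean
#'     Gaussians of standard deviation \code{level * reference} (the
#'     magnitude-MRI noise model; \code{reference} defaults to the
#'     brightest intensity present, the BrainWeb convention).}
#' }
#' The result is clipped back to [0,1].
#'
#' @param img numeric matrix with values in [0,1].
#' @param kind noise model: \code{"gaussian"}, \code{"salt_pepper"} or
#'   \code{"rician"}.
#' @param level noise level as a fraction (e.g. 0.05 for "5\%"); for
#'   \code{salt_pepper} it must lie in (0, 1].
#' @param seed RNG seed; equal (img, kind, level, seed) give bitwise-equal
#'   output.  \code{NULL} uses the current RNG stream.
#' @param reference reference intensity for the Rician sigma
#'   (default \code{max(img)}).
#' @return The corrupted matrix, same shape, values in [0,1].
#' @examples
#' ph <- makePhantom("ST")
#' noisy <- addNoise(normalizeImage(ph$image), "gaussian", 0.03, seed = 1)
#' @export
addNoise <- function(img, kind = c("gaussian", "salt_pepper", "rician"),
                     level, seed = NULL, reference = NULL) {
  kind <- match.arg(kind)
  .checkImage(img)
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9)
    stop("'img' must be normalized to [0,1] before adding noise",
         call. = FALSE)
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0)
    stop("'level' must be a single positive number", call. = FALSE)
  if (kind == "salt_pepper" && level > 1)
    stop("salt_pepper 'level' must lie in (0, 1]", call. = FALSE)
  N <- length(img)
  .withSeed(seed, {
    out <- switch(kind,
      gaussian = img + rnorm(N, mean = 0, sd = sqrt(level)),
      salt_pepper = {
        k <- round(level * N)
        pos <- sample.int(N, k)
        out <- img
        nsalt <- ceiling(k / 2)
        out[pos[seq_len(nsalt)]] <- 1
        if (k > nsalt) out[pos[(nsalt + 1L):k]] <- 0
        out
      },
      rician = {
        ref <- if (is.null(reference)) max(img) else reference
        sigma <- level * ref
        n1 <- rnorm(N, 0, sigma)
        n2 <- rnorm(N, 0, sigma)
        sqrt((img + n1)^2 + n2^2)
      })
    out[out < 0] <- 0
    out[out > 1] <- 1
    dim(out) <- dim(img)
    out
  })
}
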