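#' Window mean and window median filters
#'
#' \code{boxMean} replaces each pixel by the arithmetic mean of the
#' (2*radius+1)^2 window intersected with the image (the divisor is the
#' actual in-image window size; no padding).  \code{windowMedian} is the
#' corresponding window median with identical border semantics; for even
#' in-window counts at borders it returns the average of the two middle
#' order statistics.
#'
#' @param img numeric matrix with finite entries.
#' @param radius window half-width, integer >= 1 (3x3 window = radius 1).
#' @return Filtered matrix of the same shape.
#' @examples
#' boxMean(matrix(1:9, 3, 3), 1)[2, 2]  # mean of 1..9 = 5
#' @export
boxMean <- function(img, radius = 1L) {
  .checkImage(img)
  radius <- as.integer(radius)
  if (length(radius) != 1L || radius < 1L)
    stop("'radius' must be an integer >= 1", call. = FALSE)
  box_mean_cpp(img, radius)
}

#' @rdname boxMean
#' @export
windowMedian <- function(img, radius = 1L) {
  .checkImage(img)
  radius <- as.integer(radius)
  if (length(radius) != 1L || radius < 1L)
    stop("'radius' must be an integer >= 1", call. = FALSE)
  window_median_cpp(img, radius)
}

# Window statistics of the (rho-scaled) guidance image; computed once per
# guidance, reused across filter calls (the per-iteration membership maps
# change, the guidance does not).
.gfPrecompute <- function(I, params) {
  Ig <- params@rho * I
  r <- params@radius
  mu <- box_mean_cpp(Ig, r)
  varI <- box_mean_cpp(Ig * Ig, r) - mu * mu
  varI[varI < 0] <- 0  # guard against negative rounding error
  list(Ig = Ig, mu = mu, varI = varI, r = r, eps = params@epsilon)
}

.gfApply <- function(p, pre) {
  r <- pre$r
  mean_p <- box_mean_cpp(p, r)
  cov_Ip <- box_mean_cpp(pre$Ig * p, r) - pre$mu * mean_p
  denom <- pre$varI + pre$eps
  a <- ifelse(denom > 0, cov_Ip / denom, 0)
  b <- mean_p - a * pre$mu
  box_mean_cpp(a, r) * pre$Ig + box_mean_cpp(b, r)
}

#' Guided image filter
#'
#' Edge-preserving filter that fits, in every window \eqn{\omega_k}, a
#' ridge-regularized linear model of the input \code{p} on the guidance
#' image: \eqn{a_k = (\overline{Ip} - \mu_k \bar p_k)/(\sigma_k^2 +
#' \epsilon)}, \eqn{b_k = \bar p_k - a_k \mu_k}, and returns
#' \eqn{q_i = \bar a_i I_i + \bar b_i} where the bars are window means over
#' all windows containing pixel i.  The guidance actually used is
#' \code{rho * I}; scaling the guidance by \eqn{\rho} is algebraically
#' identical to filtering the unscaled guidance with regularizer
#' \eqn{\epsilon/\rho^2}.  Window statistics use truncated border windows
#' (see \code{\link{boxMean}}); the output range is not clipped.  On
#' windows where the guidance is constant and \code{epsilon} is 0 the
#' degenerate fit is resolved as \eqn{a_k = 0}, \eqn{b_k = \bar p_k} (the
#' minimal-norm solution).
#'
#' @param p input image (e.g. a membership map), numeric matrix.
#' @param I guidance image, same shape as \code{p}.
#' @param params a \code{\link{GuidedFilterParams}} object.
#' @return The filtered image q, same shape as \code{p}.
#' @examples
#' set.seed(1)
#' I <- matrix(runif(64), 8, 8)
#' q <- guidedFilter(I, I, GuidedFilterParams(epsilon = 0))  # identity
#' max(abs(q - I)) < 1e-10
#' @export
guidedFilter <- function(p, I, params = GuidedFilterParams()) {
  .checkImage(p)
  .checkImage(I)
  if (!identical(dim(p), dim(I)))
    stop("'p' and 'I' must have the same shape", call. = FALSE)
  validObject(params)
  .gfApply(p, .gfPrecompute(I, params))
}
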