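#' Guided-filter parameters
#'
#' Parameter container for \code{\link{guidedFilter}}: the window half-width
#' \code{radius} (a 3x3 window is radius 1), the ridge regularizer
#' \code{epsilon} of the per-window linear fit, and the influence factor
#' \code{rho} that multiplies the guidance image.  Scaling the guidance by
#' \code{rho} is mathematically equivalent to filtering the unscaled
#' guidance with regularizer \code{epsilon / rho^2}.
#'
#' @slot radius integer window half-width, >= 1.
#' @slot epsilon non-negative regularizer of the local linear fit.
#' @slot rho positive scale factor applied to the guidance image.
#' @export
setClass("GuidedFilterParams",
         representation(radius = "integer", epsilon = "numeric",
                        rho = "numeric"),
         prototype(radius = 1L, epsilon = 1e-4, rho = 1))

setValidity("GuidedFilterParams", function(object) {
  msg <- character(0)
  if (length(object@radius) != 1L || object@radius < 1L)
    msg <- c(msg, "radius must be a single integer >= 1")
  if (length(object@epsilon) != 1L || !is.finite(object@epsilon) ||
      object@epsilon < 0)
    msg <- c(msg, "epsilon must be a single finite value >= 0")
  if (length(object@rho) != 1L || !is.finite(object@rho) || object@rho <= 0)
    msg <- c(msg, "rho must be a single finite value > 0")
  if (length(msg)) msg else TRUE
})

#' @param radius integer window half-width (>= 1).
#' @param epsilon non-negative regularizer.
#' @param rho positive influence factor for the guidance image.
#' @return A \code{GuidedFilterParams} object.
#' @examples
#' GuidedFilterParams(radius = 1, epsilon = 1e-4, rho = 0.014)
#' @rdname GuidedFilterParams-class
#' @export
GuidedFilterParams <- function(radius = 1L, epsilon = 1e-4, rho = 1) {
  new("GuidedFilterParams", radius = as.integer(radius),
      epsilon = as.numeric(epsilon), rho = as.numeric(rho))
}

setMethod("show", "GuidedFilterParams", function(object) {
  cat(sprintf(
    "GuidedFilterParams: radius=%d (window %dx%d), epsilon=%g, rho=%g\n",
    object@radius, 2L * object@radius + 1L, 2L * object@radius + 1L,
    object@epsilon, object@rho))
  cat(sprintf("  effective epsilon (rho-scaled guidance): %g\n",
              object@epsilon / object@rho^2))
})

#' Fuzzy segmentation result
#'
#' Holds the output of one run of any clustering variant: the hard label
#' map (argmax over memberships), the fuzzy membership matrix U (one row
#' per cluster, one column per pixel, columns summing to 1), the cluster
#' center intensities, the objective-function trace and convergence state.
#'
#' @slot method character, the algorithm that produced the result.
#' @slot labels integer matrix of hard labels in 1..C, same shape as the
#'   segmented image.
#' @slot membership C x N numeric matrix of memberships, columns sum to 1.
#' @slot centers numeric vector of C cluster center intensities on [0,1].
#' @slot objectiveTrace numeric vector, objective J after each iteration.
#' @slot nIter integer, iterations performed.
#' @slot converged logical, whether |dJ| fell below the threshold before
#'   the iteration cap.
#' @export
setClass("FuzzySegResult",
         representation(method = "character", labels = "matrix",
                        membership = "matrix", centers = "numeric",
                        objectiveTrace = "numeric", nIter = "integer",
                        converged = "logical"))

setValidity("FuzzySegResult", function(object) {
  msg <- character(0)
  U <- object@membership
  C <- length(object@centers)
  if (nrow(U) != C)
    msg <- c(msg, "membership must have one row per cluster center")
  if (ncol(U) != length(object@labels))
    msg <- c(msg, "membership must have one column per pixel")
  if (any(U < -1e-9) || any(U > 1 + 1e-9))
    msg <- c(msg, "memberships must lie in [0,1]")
  if (ncol(U) && max(abs(colSums(U) - 1)) > 1e-6)
    msg <- c(msg, "membership columns must sum to 1")
  if (ncol(U)) {
    am <- max.col(t(U), ties.method = "first")
    if (!identical(as.integer(am), as.integer(object@labels)))
      msg <- c(msg, "labels must equal the argmax of the memberships")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "FuzzySegResult", function(object) {
  cat(sprintf("FuzzySegResult (%s): %d x %d image, C=%d clusters\n",
              object@method, nrow(object@labels), ncol(object@labels),
              length(object@centers)))
  cat("  centers:", paste(sprintf("%.4f", object@centers), collapse = ", "),
      "\n")
  cat(sprintf("  %d iterations, converged: %s, final J = %.6g\n",
              object@nIter, object@converged,
              utils::tail(object@objectiveTrace, 1)))
})

#' @export
setGeneric("segLabels", function(object) standardGeneric("segLabels"))
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))
#' @export
setGeneric("centers", function(object) standardGeneric("centers"))
#' @export
setGeneric("objectiveTrace",
           function(object) standardGeneric("objectiveTrace"))
#' @export
setGeneric("nIterations", function(object) standardGeneric("nIterations"))
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' Accessors for FuzzySegResult
#'
#' \code{segLabels} returns the hard label map (integer matrix, labels in
#' 1..C); \code{membership} the C x N membership matrix; \code{centers} the
#' cluster center intensities; \code{objectiveTrace} the per-iteration
#' objective values; \code{nIterations} and \code{isConverged} the
#' iteration count and convergence flag.
#'
#' @param object a \code{\linkS4class{FuzzySegResult}}.
#' @return See description.
#' @rdname FuzzySegResult-accessors
#' @aliases segLabels membership centers objectiveTrace nIterations
#'   isConverged
#' @export
setMethod("segLabels", "FuzzySegResult", function(object) object@labels)
#' @rdname FuzzySegResult-accessors
#' @export
setMethod("membership", "FuzzySegResult", function(object) object@membership)
#' @rdname FuzzySegResult-accessors
#' @export
setMethod("centers", "FuzzySegResult", function(object) object@centers)
#' @rdname FuzzySegResult-accessors
#' @export
setMethod("objectiveTrace", "FuzzySegResult",
          function(object) object@objectiveTrace)
#' @rdname FuzzySegResult-accessors
#' @export
setMethod("nIterations", "FuzzySegResult", function(object) object@nIter)
#' @rdname FuzzySegResult-accessors
#' @export
setMethod("isConverged", "FuzzySegResult", function(object) object@converged)
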