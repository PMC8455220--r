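# Fuzzy c-means engine shared by the whole algorithm family.
#
# All variants alternate (Picard iteration):
#   U-step  u_cn = 1 / sum_j (d_cn / d_jn)^(1/(m-1))   with d the squared
#           distance term of the variant's objective,
#   optional membership filtering (guided filter, per cluster map),
#   V-step  v_c = weighted mean of the clustered intensities,
# and stop when the objective J changes by less than xi.

# memberships from the N x C matrix of (possibly augmented) squared
# distances; zero distances give crisp memberships (ties split equally).
.membershipFromDist <- function(dd, em) {
  w <- dd^(-em)
  bad <- !is.finite(w)
  if (any(bad)) {
    rz <- rowSums(bad) > 0L
    sub <- matrix(0, sum(rz), ncol(dd))
    sub[bad[rz, , drop = FALSE]] <- 1
    w[rz, ] <- sub
  }
  w / rowSums(w)
}

# Initial centers: seeded kmeans++-style draw on the pixel intensities.
# The first center is a uniformly drawn pixel; each further center is a
# pixel drawn with probability proportional to its squared distance to the
# nearest center already chosen.  This keeps the initialization random (so
# averaged accuracy integrates over it) while spreading the centers across
# the intensity range, which matters on near-piecewise-constant images
# where independent uniform draws frequently seed two centers inside the
# same class.
.initCenters <- function(x, C) {
  v <- numeric(C)
  v[1L] <- x[sample.int(length(x), 1L)]
  d2 <- (x - v[1L])^2
  for (c in seq_len(C)[-1L]) {
    if (all(d2 == 0))
      stop(sprintf("image has fewer than C=%d distinct intensities", C),
           call. = FALSE)
    v[c] <- x[sample.int(length(x), 1L, prob = d2)]
    d2 <- pmin(d2, (x - v[c])^2)
  }
  v
}

# x:       vector the objective clusters (raw image, or beta for the
#          reconstruction variant)
# xbar:    neighbor-term vector for the spatially constrained variants
# filterU: optional function applied to the N x C membership matrix
#          between the U-step and the V-step
.fcmCore <- function(x, C, m, xi, maxIter, v, alpha = 0, xbar = NULL,
                     filterU = NULL) {
  em <- 1 / (m - 1)
  N <- length(x)
  trace <- numeric(maxIter)
  Jprev <- Inf
  converged <- FALSE
  U <- NULL
  for (it in seq_len(maxIter)) {
    d2 <- outer(x, v, function(a, b) (a - b)^2)
    dd <- if (is.null(xbar)) d2 else
      d2 + alpha * outer(xbar, v, function(a, b) (a - b)^2)
    U <- .membershipFromDist(dd, em)
    if (!is.null(filterU)) U <- filterU(U)
    Um <- if (m == 2) U * U else U^m
    mass <- colSums(Um)
    if (any(mass == 0)) {
      # empty cluster: re-seed its center from a random pixel
      for (c in which(mass == 0)) {
        v[c] <- x[sample.int(N, 1L)]
        message(sprintf("re-seeded empty cluster %d", c))
      }
      mass[mass == 0] <- .Machine$double.xmin
    }
    v <- if (is.null(xbar))
      colSums(Um * x) / mass
    else
      colSums(Um * (x + alpha * xbar)) / ((1 + alpha) * mass)
    d2 <- outer(x, v, function(a, b) (a - b)^2)
    J <- if (is.null(xbar)) sum(Um * d2) else
      sum(Um * (d2 + alpha * outer(xbar, v, function(a, b) (a - b)^2)))
    trace[it] <- J
    if (abs(J - Jprev) < xi) { converged <- TRUE; break }
    Jprev <- J
  }
  list(U = U, v = v, trace = trace[seq_len(it)], nIter = it,
       converged = converged)
}

# guided-filter regularization of the membership maps: filter each cluster
# map with the (rho-scaled) guidance, clip negatives, renormalize columns;
# pixels whose filtered memberships sum to zero keep their pre-filter values
.makeMembershipFilter <- function(I, params) {
  pre <- .gfPrecompute(I, params)
  nr <- nrow(I); nc <- ncol(I)
  function(U) {
    V <- U
    for (c in seq_len(ncol(U)))
      V[, c] <- .gfApply(matrix(U[, c], nr, nc), pre)
    V[V < 0] <- 0
    s <- rowSums(V)
    zero <- s == 0
    if (any(zero)) {
      V[zero, ] <- U[zero, , drop = FALSE]
      s[zero] <- 1
    }
    V / s
  }
}

.finishResult <- function(method, img, core) {
  labels <- matrix(max.col(core$U, ties.method = "first"),
                   nrow(img), ncol(img))
  new("FuzzySegResult", method = method, labels = labels,
      membership = t(core$U), centers = as.numeric(core$v),
      objectiveTrace = core$trace, nIter = as.integer(core$nIter),
      converged = core$converged)
}

.checkClusterArgs <- function(C, m, xi, maxIter) {
  if (length(C) != 1L || C < 2L) stop("'C' must be >= 2", call. = FALSE)
  if (m <= 1) stop("fuzzifier 'm' must be > 1", call. = FALSE)
  if (xi <= 0) stop("'xi' must be > 0", call. = FALSE)
  if (maxIter < 1L) stop("'maxIter' must be >= 1", call. = FALSE)
}

#' Fuzzy c-means segmentation of a grayscale image
#'
#' Minimizes \eqn{J(U,V) = \sum_c \sum_n u_{cn}^m (x_n - v_c)^2} subject to
#' columns of U summing to 1, by Picard iteration of the closed-form
#' membership and center updates.  Iteration stops when the objective
#' changes by less than \code{xi} or after \code{maxIter} iterations (the
#' result is then flagged as not converged).
#'
#' @param img numeric matrix on the [0,1] scale.
#' @param C number of clusters (>= 2).
#' @param m fuzzifier (> 1), default 2.
#' @param xi convergence threshold on |dJ|, default 1e-8.
#' @param maxIter iteration cap, default 200.
#' @param seed RNG seed for the random center initialization; the caller's
#'   RNG state is preserved.  \code{NULL} uses the current stream.
#' @param centers optional numeric vector of C initial centers (overrides
#'   the random initialization).
#' @return A \code{\linkS4class{FuzzySegResult}}.
#' @examples
#' ph <- makePhantom("ST")
#' res <- fcm(normalizeImage(ph$image), C = 3, seed = 1)
#' sort(centers(res)) * 255
#' @export
fcm <- function(img, C, m = 2, xi = 1e-8, maxIter = 200L, seed = NULL,
                centers = NULL) {
  .checkImage(img); .checkClusterArgs(C, m, xi, maxIter)
  x <- as.vector(img)
  .withSeed(seed, {
    v0 <- if (is.null(centers)) .initCenters(x, C) else as.numeric(centers)
    .finishResult("fcm", img, .fcmCore(x, C, m, xi, maxIter, v0))
  })
}

#' Spatially constrained FCM (mean- or median-filter neighbor term)
#'
#' Adds the neighbor term \eqn{\alpha (\bar x_n - v_c)^2} to the FCM
#' objective, where \eqn{\bar x} is the window mean (variant
#' \code{"S1"}) or window median (variant \code{"S2"}) of the image,
#' precomputed once.  Updates: memberships proportional to
#' \eqn{((x_n - v_c)^2 + \alpha(\bar x_n - v_c)^2)^{-1/(m-1)}} normalized
#' per pixel, and centers
#' \eqn{v_c = \sum u^m (x_n + \alpha \bar x_n) / ((1+\alpha) \sum u^m)}.
#' With \code{alpha = 0} the trajectory is identical to \code{\link{fcm}}.
#'
#' @inheritParams fcm
#' @param variant \code{"S1"} (mean filter) or \code{"S2"} (median filter).
#' @param alpha weight of the neighbor term, default 3.8.
#' @param radius neighbor window half-width, default 1 (3x3).
#' @return A \code{\linkS4class{FuzzySegResult}}.
#' @export
fcmS <- function(img, C, variant = c("S1", "S2"), alpha = 3.8, radius = 1L,
                 m = 2, xi = 1e-8, maxIter = 200L, seed = NULL,
                 centers = NULL) {
  variant <- match.arg(variant)
  .checkImage(img); .checkClusterArgs(C, m, xi, maxIter)
  if (alpha < 0) stop("'alpha' must be >= 0", call. = FALSE)
  xbar <- if (variant == "S1") boxMean(img, radius) else
    windowMedian(img, radius)
  x <- as.vector(img)
  .withSeed(seed, {
    v0 <- if (is.null(centers)) .initCenters(x, C) else as.numeric(centers)
    .finishResult(paste0("fcm_", tolower(variant)), img,
                  .fcmCore(x, C, m, xi, maxIter, v0, alpha = alpha,
                           xbar = as.vector(xbar)))
  })
}

#' FCM with guided-filter membership regularization
#'
#' \code{fcmGF} runs FCM on the raw noisy image and, in every iteration,
#' filters each cluster's membership map with the guided filter using the
#' raw image itself as guidance (influence factor fixed at 1), then clips
#' and renormalizes the columns of U before the center update.
#' \code{ifcmGF} is identical except that the guidance image is scaled by
#' the influence factor \code{rho}; by the guided-filter scaling identity
#' this equals \code{fcmGF} with regularizer \code{epsilon / rho^2}.
#'
#' @inheritParams fcm
#' @param epsilon guided-filter regularizer, default 1e-4.
#' @param radius guided-filter window half-width, default 1 (3x3).
#' @param rho influence factor multiplying the guidance image (> 0).
#' @return A \code{\linkS4class{FuzzySegResult}}.
#' @export
fcmGF <- function(img, C, epsilon = 1e-4, radius = 1L, m = 2, xi = 1e-8,
                  maxIter = 200L, seed = NULL, centers = NULL) {
  ifcmGF(img, C, rho = 1, epsilon = epsilon, radius = radius, m = m,
         xi = xi, maxIter = maxIter, seed = seed, centers = centers,
         .method = "fcm_gf")
}

#' @rdname fcmGF
#' @param .method internal result tag.
#' @export
ifcmGF <- function(img, C, rho, epsilon = 1e-4, radius = 1L, m = 2,
                   xi = 1e-8, maxIter = 200L, seed = NULL, centers = NULL,
                   .method = "ifcm_gf") {
  .checkImage(img); .checkClusterArgs(C, m, xi, maxIter)
  gf <- GuidedFilterParams(radius = radius, epsilon = epsilon, rho = rho)
  filt <- .makeMembershipFilter(img, gf)
  x <- as.vector(img)
  .withSeed(seed, {
    v0 <- if (is.null(centers)) .initCenters(x, C) else as.numeric(centers)
    .finishResult(.method, img,
                  .fcmCore(x, C, m, xi, maxIter, v0, filterU = filt))
  })
}

#' Morphological-reconstruction FCM with guided-filter regularization
#'
#' Computes once the closing reconstruction \eqn{\beta} of the raw noisy
#' image (\code{\link{reconstructImage}}), then clusters \eqn{\beta}:
#' memberships and centers are updated on \eqn{\beta}, while in every
#' iteration each membership map is guided-filtered with the guidance
#' \code{rho * img} (the \emph{raw} noisy image, not \eqn{\beta}) and the
#' columns renormalized.  The returned labels cover the original image's
#' pixels.
#'
#' @inheritParams ifcmGF
#' @param se structuring element for the reconstruction (default 3x3).
#' @return A \code{\linkS4class{FuzzySegResult}}.
#' @export
mrifcmGF <- function(img, C, rho, epsilon = 1e-4, radius = 1L,
                     se = flatSE(3L), m = 2, xi = 1e-8, maxIter = 200L,
                     seed = NULL, centers = NULL) {
  .checkImage(img); .checkClusterArgs(C, m, xi, maxIter)
  beta <- reconstructImage(img, se)
  gf <- GuidedFilterParams(radius = radius, epsilon = epsilon, rho = rho)
  filt <- .makeMembershipFilter(img, gf)
  x <- as.vector(beta)
  .withSeed(seed, {
    v0 <- if (is.null(centers)) .initCenters(x, C) else as.numeric(centers)
    .finishResult("mrifcm_gf", img,
                  .fcmCore(x, C, m, xi, maxIter, v0, filterU = filt))
  })
}

#' Segment an image with any algorithm of the family
#'
#' Dispatcher over \code{\link{fcm}}, \code{\link{fcmS}},
#' \code{\link{fcmGF}}, \code{\link{ifcmGF}} and \code{\link{mrifcmGF}};
#' used by the command-line interface and the evaluation harness.
#'
#' @inheritParams fcm
#' @param method one of \code{"fcm"}, \code{"fcm_s1"}, \code{"fcm_s2"},
#'   \code{"fcm_gf"}, \code{"ifcm_gf"}, \code{"mrifcm_gf"}.
#' @param ... further arguments passed to the method function
#'   (\code{rho}, \code{epsilon}, \code{alpha}, \code{se}, ...).
#' @return A \code{\linkS4class{FuzzySegResult}}.
#' @export
segmentImage <- function(img, method = c("fcm", "fcm_s1", "fcm_s2",
                                         "fcm_gf", "ifcm_gf", "mrifcm_gf"),
                         C, seed = NULL, ...) {
  method <- match.arg(method)
  switch(method,
         fcm = fcm(img, C, seed = seed, ...),
         fcm_s1 = fcmS(img, C, variant = "S1", seed = seed, ...),
         fcm_s2 = fcmS(img, C, variant = "S2", seed = seed, ...),
         fcm_gf = fcmGF(img, C, seed = seed, ...),
         ifcm_gf = ifcmGF(img, C, seed = seed, ...),
         mrifcm_gf = mrifcmGF(img, C, seed = seed, ...))
}
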