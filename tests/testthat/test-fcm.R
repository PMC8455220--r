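test_that("membership update matches the closed form, including degenerate distances", {
  X <- c(0, 0.2, 1.0); V <- c(0.1, 0.9); m <- 2
  dd <- outer(X, V, function(a, b) (a - b)^2)
  U <- fuzzyseg:::.membershipFromDist(dd, 1 / (m - 1))
  for (n in seq_along(X))
    expect_equal(U[n, ], naive_membership(X[n], V, m), tolerance = 1e-12)
  expect_equal(rowSums(U), rep(1, 3))
  # pixel exactly at a center: crisp membership
  U2 <- fuzzyseg:::.membershipFromDist(
    outer(c(0.1, 0.5), V, function(a, b) (a - b)^2), 1)
  expect_equal(U2[1, ], c(1, 0))
  # equidistant from two centers: (0.5, 0.5)
  U3 <- fuzzyseg:::.membershipFromDist(
    outer(0.5, V, function(a, b) (a - b)^2), 1)
  expect_equal(U3[1, ], c(0.5, 0.5))
  # coincident with two centers: tie split equally
  U4 <- fuzzyseg:::.membershipFromDist(matrix(c(0, 0, 1), 1), 1)
  expect_equal(U4[1, ], c(0.5, 0.5, 0))
})

test_that("center update is the u^m-weighted mean", {
  set.seed(31)
  x <- runif(5)
  U <- matrix(runif(10), 5, 2); U <- U / rowSums(U)
  m <- 2
  got <- colSums(U^m * x) / colSums(U^m)
  for (c in 1:2)
    expect_equal(got[c], sum(U[, c]^m * x) / sum(U[, c]^m))
  # crisp memberships give per-class arithmetic means
  Uc <- cbind(c(1, 1, 0, 0, 0), c(0, 0, 1, 1, 1))
  expect_equal(colSums(Uc^m * x) / colSums(Uc^m),
               c(mean(x[1:2]), mean(x[3:5])))
  # uniform memberships give the global mean for every center
  Uu <- matrix(0.5, 5, 2)
  expect_equal(colSums(Uu^m * x) / colSums(Uu^m), rep(mean(x), 2))
})

test_that("fcm on separable toy data converges to crisp clusters and a non-increasing objective", {
  img <- matrix(c(0, 0, 1, 1), 2, 2)
  res <- fcm(img, 2, centers = c(0.3, 0.7))
  expect_true(isConverged(res))
  expect_equal(sort(centers(res)), c(0, 1), tolerance = 1e-4)
  expect_true(all(membership(res) > 0.999 | membership(res) < 0.001))
  # objective trace non-increasing on a realistic noisy image
  ph <- makePhantom("ST")
  noisy <- addNoise(normalizeImage(ph$image), "gaussian", 0.05, seed = 4)
  res2 <- fcm(noisy[1:64, 1:64], 3, seed = 9)
  expect_true(all(diff(objectiveTrace(res2)) <= 1e-10))
  expect_lte(nIterations(res2), 200L)
})

test_that("fcm agrees with an independent fuzzy c-means implementation", {
  skip_if_not_installed("e1071")
  set.seed(77)
  x <- c(rnorm(150, 0.2, 0.03), rnorm(150, 0.8, 0.03))
  x[x < 0] <- 0; x[x > 1] <- 1
  img <- matrix(x, 20, 15)
  ours <- fcm(img, 2, centers = c(0.1, 0.9), xi = 1e-12)
  ref <- e1071::cmeans(matrix(x, ncol = 1), centers = matrix(c(0.1, 0.9)),
                       m = 2, iter.max = 500)
  expect_equal(sort(centers(ours)), sort(as.numeric(ref$centers)),
               tolerance = 1e-4)
  expect_equal(as.integer(segLabels(ours)), as.integer(ref$cluster))
})

test_that("memberships stay column-stochastic through the guided-filter step", {
  ph <- makePhantom("ST")
  noisy <- addNoise(normalizeImage(ph$image), "salt_pepper", 0.2, seed = 6)
  crop <- noisy[110:157, 62:109]  # spans all three classes (disk edge)
  filt <- fuzzyseg:::.makeMembershipFilter(
    crop, GuidedFilterParams(radius = 1, epsilon = 1e-4, rho = 0.01))
  set.seed(15)
  U <- matrix(runif(48 * 48 * 3), ncol = 3); U <- U / rowSums(U)
  V <- filt(U)
  expect_true(all(V >= 0) && all(V <= 1 + 1e-12))
  expect_equal(rowSums(V), rep(1, nrow(V)), tolerance = 1e-9)
  # and through full runs of every variant
  for (res in list(ifcmGF(crop, 3, rho = 0.01, seed = 2),
                   mrifcmGF(crop, 3, rho = 0.01, seed = 2),
                   fcmS(crop, 3, "S2", seed = 2))) {
    expect_equal(colSums(membership(res)), rep(1, 48 * 48),
                 tolerance = 1e-9)
    expect_true(all(membership(res) >= 0))
  }
})

test_that("fcmS with alpha = 0 reproduces the plain fcm trajectory", {
  ph <- makePhantom("ST")
  noisy <- addNoise(normalizeImage(ph$image), "gaussian", 0.05, seed = 3)
  crop <- noisy[1:40, 1:40]
  a <- fcm(crop, 3, seed = 21)
  b <- fcmS(crop, 3, "S1", alpha = 0, seed = 21)
  expect_equal(centers(a), centers(b), tolerance = 1e-12)
  expect_identical(segLabels(a), segLabels(b))
  expect_equal(objectiveTrace(a), objectiveTrace(b), tolerance = 1e-12)
})

test_that("one fcmS update step matches hand-evaluated formulas on a 5-pixel toy", {
  x <- c(0.0, 0.1, 0.5, 0.9, 1.0)
  img <- matrix(x, 1, 5)
  alpha <- 2; m <- 2; v <- c(0.2, 0.8)
  xbar <- as.vector(windowMedian(img, 1))
  d2 <- outer(x, v, function(a, b) (a - b)^2) +
    alpha * outer(xbar, v, function(a, b) (a - b)^2)
  w <- 1 / d2
  U <- w / rowSums(w)
  vexp <- colSums(U^m * (x + alpha * xbar)) / ((1 + alpha) * colSums(U^m))
  res <- fcmS(img, 2, "S2", alpha = alpha, centers = v, maxIter = 1)
  expect_equal(centers(res), as.numeric(vexp), tolerance = 1e-12)
})

test_that("rho = 1 makes ifcmGF identical to fcmGF, and alpha-scaled guidance equals rescaled epsilon", {
  ph <- makePhantom("ST")
  noisy <- addNoise(normalizeImage(ph$image), "gaussian", 0.05, seed = 13)
  crop <- noisy[33:96, 33:96]
  a <- fcmGF(crop, 3, seed = 8)
  b <- ifcmGF(crop, 3, rho = 1, seed = 8)
  expect_identical(segLabels(a), segLabels(b))
  expect_equal(centers(a), centers(b))
  # (epsilon, rho) equivalent to (epsilon / rho^2, 1), same seed
  for (rho in c(0.5, 2)) {
    u <- ifcmGF(crop, 3, rho = rho, epsilon = 1e-4, seed = 8)
    w <- ifcmGF(crop, 3, rho = 1, epsilon = 1e-4 / rho^2, seed = 8)
    expect_identical(segLabels(u), segLabels(w))
    expect_equal(centers(u), centers(w), tolerance = 1e-8)
  }
})

test_that("results are seed-deterministic and invariant to center relabeling", {
  ph <- makePhantom("ST")
  noisy <- addNoise(normalizeImage(ph$image), "gaussian", 0.03, seed = 17)
  crop <- noisy[1:64, 1:64]
  r1 <- ifcmGF(crop, 3, rho = 0.05, seed = 99)
  r2 <- ifcmGF(crop, 3, rho = 0.05, seed = 99)
  expect_identical(segLabels(r1), segLabels(r2))
  expect_identical(centers(r1), centers(r2))
  # permuting the initial centers permutes the output clusters only
  v0 <- c(0.1, 0.4, 0.7)
  truth <- ph$labels[1:64, 1:64]
  p1 <- fcm(crop, 3, centers = v0)
  p2 <- fcm(crop, 3, centers = rev(v0))
  expect_equal(sort(centers(p1)), sort(centers(p2)), tolerance = 1e-9)
  expect_equal(segmentationAccuracy(segLabels(p1), truth)$sa,
               segmentationAccuracy(segLabels(p2), truth)$sa)
  expect_equal(segmentationAccuracy(segLabels(p1), segLabels(p2))$sa, 1.0)
})

test_that("reaching the iteration cap flags non-convergence instead of erroring", {
  ph <- makePhantom("ST")
  noisy <- addNoise(normalizeImage(ph$image), "gaussian", 0.1, seed = 1)
  res <- fcm(noisy[1:32, 1:32], 3, seed = 1, maxIter = 2L)
  expect_false(isConverged(res))
  expect_identical(nIterations(res), 2L)
})

test_that("invalid clustering configurations are rejected", {
  img <- matrix(runif(16), 4, 4)
  expect_error(fcm(img, 1), "C")
  expect_error(fcm(img, 2, m = 1), "m")
  expect_error(fcm(img, 2, xi = 0), "xi")
  expect_error(ifcmGF(img, 2, rho = 0), "rho")
})
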