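test_that("dilation and erosion match the window max/min oracle and the 1x1 identity", {
  set.seed(606)
  x <- rand_img(6, 6)
  expect_equal(grayDilate(x), naive_morph(x, flatSE(3), TRUE))
  expect_equal(grayErode(x), naive_morph(x, flatSE(3), FALSE))
  se5 <- flatSE(5)
  expect_equal(grayDilate(x, se5), naive_morph(x, se5, TRUE))
  # cross-shaped structuring element
  cross <- matrix(c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE,
                    FALSE, TRUE, FALSE), 3, 3)
  expect_equal(grayErode(x, cross), naive_morph(x, cross, FALSE))
  expect_identical(grayDilate(x, flatSE(1)), x)
  expect_identical(grayErode(x, flatSE(1)), x)
  cst <- matrix(0.4, 5, 5)
  expect_equal(grayDilate(cst), cst)
  expect_equal(grayErode(cst), cst)
  expect_error(flatSE(4), "odd")
  expect_error(grayDilate(x, matrix(TRUE, 2, 3)), "odd")
})

test_that("geodesic reconstruction matches the literal iterative definition", {
  set.seed(707)
  se <- flatSE(3)
  for (k in 1:4) {
    f <- rand_img(8, 8)
    g <- pmin(f, rand_img(8, 8))   # marker <= mask
    got <- reconstructDilation(f, g, se)
    expect_equal(got, naive_reconstruct(f, g, se, TRUE), tolerance = 1e-12)
    ge <- pmax(f, rand_img(8, 8))  # marker >= mask
    expect_equal(reconstructErosion(f, ge, se),
                 naive_reconstruct(f, ge, se, FALSE), tolerance = 1e-12)
  }
})

test_that("reconstruction obeys sandwich bounds, fixed point, and marker preconditions", {
  set.seed(808)
  f <- rand_img(12, 12)
  se <- flatSE(3)
  # marker = mask is already the fixed point
  expect_equal(reconstructDilation(f, f, se), f)
  expect_equal(reconstructErosion(f, f, se), f)
  # marker = erosion: erode(f) <= result <= f, and one more geodesic step
  # leaves the result unchanged
  g <- grayErode(f, se)
  rec <- reconstructDilation(f, g, se)
  expect_true(all(rec >= g - 1e-12) && all(rec <= f + 1e-12))
  expect_equal(pmin(grayDilate(rec, se), f), rec, tolerance = 1e-12)
  # dual side
  gd <- grayDilate(f, se)
  recE <- reconstructErosion(f, gd, se)
  expect_true(all(recE <= gd + 1e-12) && all(recE >= f - 1e-12))
  expect_equal(pmax(grayErode(recE, se), f), recE, tolerance = 1e-12)
  # violated precondition errors name the violation
  expect_error(reconstructDilation(f, f + 0.1, se), "violation")
  expect_error(reconstructErosion(f, f - 0.1, se), "violation")
})

test_that("erosion reconstruction is the complement-dual of dilation reconstruction", {
  set.seed(909)
  for (k in 1:3) {
    f <- rand_img(8, 8)
    g <- pmax(f, rand_img(8, 8))
    expect_equal(reconstructErosion(f, g),
                 1 - reconstructDilation(1 - f, 1 - g), tolerance = 1e-12)
  }
})

test_that("a connected flat marker suppresses regional maxima not touching it", {
  # plateau image: background 0.2, two bumps 0.8 and 0.5
  f <- matrix(0.2, 9, 9)
  f[2:3, 2:3] <- 0.8
  f[7:8, 7:8] <- 0.5
  g <- matrix(min(f), 9, 9)
  rec <- reconstructDilation(f, g, flatSE(3))
  # marker everywhere at global min: all maxima above the background level
  # are flattened to the surrounding level
  expect_equal(rec, matrix(0.2, 9, 9))
  expect_equal(rec, naive_reconstruct(f, g, flatSE(3), TRUE))
})

test_that("opening/closing reconstruction: identities, range bounds and idempotence", {
  set.seed(111)
  cst <- matrix(0.6, 8, 8)
  expect_equal(closingReconstruction(cst), cst)
  expect_equal(openingReconstruction(cst), cst)
  f <- rand_img(10, 10)
  expect_identical(closingReconstruction(f, flatSE(1)), f)
  beta <- closingReconstruction(f)
  expect_gte(min(beta), min(f))
  expect_lte(max(beta), max(f))
  # reconstruction-by-composition operators are idempotent
  expect_equal(closingReconstruction(beta), beta, tolerance = 1e-12)
  op <- openingReconstruction(f)
  expect_equal(openingReconstruction(op), op, tolerance = 1e-12)
  # reconstructImage is the closing reconstruction
  expect_identical(reconstructImage(f), beta)
})

test_that("closing reconstruction re-concentrates a salt-and-pepper phantom at its class intensities", {
  ph <- makePhantom("ST")
  img <- normalizeImage(ph$image)
  noisy <- addNoise(img, "salt_pepper", 0.2, seed = 20)
  beta <- reconstructImage(noisy)
  near <- outer(as.vector(beta), c(0, 85, 170) / 255,
                function(a, b) abs(a - b)) <= 10 / 255
  frac <- mean(rowSums(near) > 0)
  expect_gte(frac, 0.99)
  # the reconstruction preserves a clean phantom's clustering
  res_clean <- fcm(img, 3, seed = 5)
  res_beta <- fcm(reconstructImage(img), 3, seed = 5)
  expect_equal(segmentationAccuracy(segLabels(res_beta), ph$labels)$sa,
               segmentationAccuracy(segLabels(res_clean), ph$labels)$sa)
})
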