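# Brute-force reference implementations used as independent oracles.
# All operate with the same border convention as the package (window
# intersected with the image) but are written as literal per-pixel /
# per-window loops, independent of the production code paths.

naive_box_mean <- function(x, r) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- max(1, i - r):min(nr, i + r)
    rj <- max(1, j - r):min(nc, j + r)
    out[i, j] <- mean(x[ri, rj])
  }
  out
}

naive_window_median <- function(x, r) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- max(1, i - r):min(nr, i + r)
    rj <- max(1, j - r):min(nc, j + r)
    out[i, j] <- median(x[ri, rj])
  }
  out
}

naive_morph <- function(x, se, dilate) {
  nr <- nrow(x); nc <- ncol(x)
  ci <- (nrow(se) + 1L) %/% 2L; cj <- (ncol(se) + 1L) %/% 2L
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (si in seq_len(nrow(se))) for (sj in seq_len(ncol(se))) {
      if (!se[si, sj]) next
      ii <- i + si - ci; jj <- j + sj - cj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        vals <- c(vals, x[ii, jj])
    }
    out[i, j] <- if (dilate) max(vals) else min(vals)
  }
  out
}

# literal iterative geodesic reconstruction using the naive operators
naive_reconstruct <- function(mask, marker, se, dilation) {
  g <- marker
  repeat {
    h <- if (dilation) pmin(naive_morph(g, se, TRUE), mask)
         else pmax(naive_morph(g, se, FALSE), mask)
    if (identical(h, g)) return(g)
    g <- h
  }
}

# Guided filter oracle: per window, solve the 2x2 normal equations of the
# window-normalized ridge regression of p on the (rho-scaled) guidance
# (a linear solve, not the production closed form), then average the
# coefficients of all windows containing each pixel.
naive_guided_filter <- function(p, I, r, eps, rho = 1) {
  Ig <- rho * I
  nr <- nrow(p); nc <- ncol(p)
  a <- matrix(0, nr, nc); b <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- max(1, i - r):min(nr, i + r)
    rj <- max(1, j - r):min(nc, j + r)
    Iw <- as.vector(Ig[ri, rj]); pw <- as.vector(p[ri, rj])
    A <- rbind(c(mean(Iw^2) + eps, mean(Iw)), c(mean(Iw), 1))
    rhs <- c(mean(Iw * pw), mean(pw))
    if (abs(det(A)) < 1e-300) {    # constant window, eps = 0
      a[i, j] <- 0; b[i, j] <- mean(pw)
    } else {
      ab <- solve(A, rhs)
      a[i, j] <- ab[1]; b[i, j] <- ab[2]
    }
  }
  q <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- max(1, i - r):min(nr, i + r)
    rj <- max(1, j - r):min(nc, j + r)
    q[i, j] <- mean(a[ri, rj]) * Ig[i, j] + mean(b[ri, rj])
  }
  q
}

# direct evaluation of the membership closed form for a single pixel
naive_membership <- function(x, v, m) {
  d <- abs(x - v)
  if (any(d == 0)) return(as.numeric(d == 0) / sum(d == 0))
  u <- vapply(seq_along(v), function(c)
    1 / sum((d[c] / d)^(2 / (m - 1))), numeric(1))
  u
}

rand_img <- function(nr, nc) matrix(runif(nr * nc), nr, nc)
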