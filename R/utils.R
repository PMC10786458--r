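# Shared numeric helpers (interpolation, fft correlation plumbing).

clampIndex <- function(i, n) pmin.int(pmax.int(i, 1L), n)

#' Bilinear image sampling with edge clamping
#'
#' Samples `img` at fractional positions; `x` indexes columns and `y` rows,
#' both 1-based at pixel centres. Queries outside the image are clamped to
#' the border value.
#'
#' @param img numeric matrix.
#' @param x,y numeric vectors of equal length.
#' @return numeric vector of sampled intensities.
#' @export
interpBilinear <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  x <- pmin(pmax(x, 1), W); y <- pmin(pmax(y, 1), H)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x1 <- clampIndex(x0 + 1, W); y1 <- clampIndex(y0 + 1, H)
  img[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    img[cbind(y0, x1)] * (1 - fy) * fx +
    img[cbind(y1, x0)] * fy * (1 - fx) +
    img[cbind(y1, x1)] * fy * fx
}

#' Bicubic (Catmull-Rom) image sampling with edge clamping
#'
#' Keys cubic-convolution kernel (a = -0.5). Same indexing conventions as
#' [interpBilinear()].
#'
#' @inheritParams interpBilinear
#' @return numeric vector of sampled intensities.
#' @export
interpBicubic <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  x <- pmin(pmax(x, 1), W); y <- pmin(pmax(y, 1), H)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  cubw <- function(s) {
    s <- abs(s)
    w <- numeric(length(s))
    i1 <- s <= 1
    w[i1] <- 1.5 * s[i1]^3 - 2.5 * s[i1]^2 + 1
    i2 <- s > 1 & s < 2
    w[i2] <- -0.5 * s[i2]^3 + 2.5 * s[i2]^2 - 4 * s[i2] + 2
    w
  }
  out <- numeric(length(x))
  for (j in -1:2) {
    wy <- cubw(fy - j)
    rows <- clampIndex(y0 + j, H)
    for (i in -1:2) {
      wx <- cubw(fx - i)
      cols <- clampIndex(x0 + i, W)
      out <- out + img[cbind(rows, cols)] * wy * wx
    }
  }
  out
}

# Circular cross-correlation of two equal, mean-subtracted matrices via FFT.
# Entry [1,1] corresponds to zero shift; positive shifts wrap.
crossCorrFFT <- function(a, b) {
  Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) / length(a)
}

# 2D summed-area lookup: total of `m` over rows r0..r1, cols c0..c1 for
# vectors of equal length. `S` is the padded cumulative sum of m.
summedArea <- function(m) {
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed by apply
  S <- matrix(0, nrow(m) + 1, ncol(m) + 1)
  S[-1, -1] <- t(cs)
  S
}

boxSum <- function(S, r0, r1, c0, c1) {
  S[cbind(r1 + 1, c1 + 1)] - S[cbind(r0, c1 + 1)] -
    S[cbind(r1 + 1, c0)] + S[cbind(r0, c0)]
}

# Centroid (x = col, y = row) of a logical mask, optionally weighted.
maskCentroid <- function(mask, weights = NULL) {
  idx <- which(mask, arr.ind = TRUE)
  w <- if (is.null(weights)) rep(1, nrow(idx)) else weights[mask]
  if (sum(w) <= 0) w <- rep(1, nrow(idx))
  c(x = sum(idx[, 2] * w) / sum(w), y = sum(idx[, 1] * w) / sum(w))
}

# Analytic disc mask on the pixel grid (radius in px, centre in px coords).
discMask <- function(shape, center, radius) {
  H <- shape[1]; W <- shape[2]
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  rr <- matrix(seq_len(H), H, W)
  (cc - center[1])^2 + (rr - center[2])^2 <= radius^2
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
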