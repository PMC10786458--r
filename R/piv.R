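# Multi-pass windowed cross-correlation PIV against the undeformed t=0
# reference frame, with global/local outlier filtering and sub-pixel peak
# refinement (3-point Gaussian, parabolic fallback).

#' PIV configuration
#'
#' Defaults reconcile the printed acquisition parameters: a 32 px
#' interrogation window at 75 % overlap with a second pass at 16 px yields
#' the 4 x 4 px final vector grid.
#'
#' @param passWindows integer vector of window sizes per pass (px),
#'   powers of two, decreasing.
#' @param overlap overlap fraction in [0, 1).
#' @param subpixel sub-pixel estimator ("gaussian3").
#' @param globalK global outlier threshold (standard deviations).
#' @param localThreshold local outlier threshold (multiples of the 3x3
#'   neighborhood median absolute deviation).
#' @param minSNR minimum peak-to-second-peak ratio.
#' @return a [PIVConfig-class].
#' @export
pivConfig <- function(passWindows = c(32L, 16L), overlap = 0.75,
                      subpixel = "gaussian3", globalK = 3,
                      localThreshold = 2.5, minSNR = 1.3) {
  new("PIVConfig", passWindows = as.integer(passWindows), overlap = overlap,
      subpixel = subpixel, globalK = globalK,
      localThreshold = localThreshold, minSNR = minSNR)
}

# Core correlation of two equal patches; returns NA displacement for a
# (near-)constant target. Zero-padded (linear, not circular) correlation
# normalised by the overlap area removes both wrap-around aliasing and the
# triangular bias; the peak search is restricted to |shift| <= maxShift.
.correlatePair <- function(ref, tgt, maxShift = nrow(ref) %/% 4) {
  n <- nrow(ref)
  ref0 <- ref - mean(ref)
  tgt0 <- tgt - mean(tgt)
  sr <- sqrt(sum(ref0^2)); st <- sqrt(sum(tgt0^2))
  if (sr < 1e-12 * n) {
    stop(errorCondition("reference patch is constant; correlation undefined",
                        class = "undefinedCorrelation"))
  }
  if (st < 1e-12 * n) {
    return(list(du = NA_real_, dv = NA_real_, snr = 0))
  }
  N <- 2L * n
  R <- matrix(0, N, N); Tm <- matrix(0, N, N)
  R[1:n, 1:n] <- ref0; Tm[1:n, 1:n] <- tgt0
  C <- Re(stats::fft(Conj(stats::fft(R)) * stats::fft(Tm),
                     inverse = TRUE)) / (N * N)
  m1 <- min(maxShift + 1L, n - 1L)        # one guard ring for sub-pixel fit
  shifts <- -m1:m1
  overlap <- outer(n - abs(shifts), n - abs(shifts))
  sub <- C[(shifts %% N) + 1L, (shifts %% N) + 1L] *
    (n * n) / (overlap * sr * st)         # rows: dy, cols: dx
  inner <- 2:(length(shifts) - 1)
  pkv <- max(sub[inner, inner])
  pk <- which(sub == pkv, arr.ind = TRUE)
  pk <- pk[pk[, 1] %in% inner & pk[, 2] %in% inner, , drop = FALSE][1, ]
  c0 <- sub[pk[1], pk[2]]
  refine <- function(cm, cc, cp) {
    if (cm > 0 && cc > 0 && cp > 0 &&
        (log(cm) - 2 * log(cc) + log(cp)) < 0) {
      0.5 * (log(cm) - log(cp)) / (log(cm) - 2 * log(cc) + log(cp))
    } else if ((cm - 2 * cc + cp) < 0) {
      0.5 * (cm - cp) / (cm - 2 * cc + cp)
    } else {
      0
    }
  }
  du <- shifts[pk[2]] + refine(sub[pk[1], pk[2] - 1], c0, sub[pk[1], pk[2] + 1])
  dv <- shifts[pk[1]] + refine(sub[pk[1] - 1, pk[2]], c0, sub[pk[1] + 1, pk[2]])
  # second peak: highest value outside the 3x3 around the main peak
  excl <- sub
  excl[pk[1] + (-1:1), pk[2] + (-1:1)] <- -Inf
  second <- max(excl[inner, inner])
  snr <- if (second > 1e-12) c0 / second else 100
  list(du = du, dv = dv, snr = min(snr, 100))
}

#' Correlate a single interrogation-window pair
#'
#' Normalised circular cross-correlation of two equal square patches; the
#' integer peak is refined independently in x and y by a 3-point Gaussian
#' fit (parabolic fallback when a log is undefined). The signal-to-noise
#' ratio is the peak divided by the highest non-adjacent secondary peak.
#'
#' @param ref,tgt equal square numeric matrices with even side length.
#' @return list with `du`, `dv` (px, displacement of `tgt` relative to
#'   `ref`) and `snr`.
#' @export
correlateWindow <- function(ref, tgt) {
  if (!all(dim(ref) == dim(tgt)) || nrow(ref) != ncol(ref))
    stop("patches must be square and of equal size")
  if (nrow(ref) %% 2 != 0) stop("patch size must be even")
  .correlatePair(ref, tgt)
}

# Build the interrogation grid for a window size: patch start offsets and
# node (centre) coordinates in px.
.pivGrid <- function(H, W, w, step) {
  ax <- seq(1L, W - w + 1L, by = step)
  ay <- seq(1L, H - w + 1L, by = step)
  list(ax = ax, ay = ay, cx = ax + (w - 1) / 2, cy = ay + (w - 1) / 2)
}

# Sample a field matrix (on grid gx, gy) at query coordinates, bilinear
# with clamping; NA nodes contribute 0.
.sampleField <- function(m, gx, gy, qx, qy) {
  m[is.na(m)] <- 0
  ix <- pmin(pmax((qx - gx[1]) / (gx[2] - gx[1]) + 1, 1), length(gx))
  iy <- pmin(pmax((qy - gy[1]) / (gy[2] - gy[1]) + 1, 1), length(gy))
  qm <- matrix(0, length(qy), length(qx))
  grid <- expand.grid(y = iy, x = ix)
  qm[] <- interpBilinear(m, grid$x, grid$y)
  qm
}

#' Multi-pass PIV between two frames
#'
#' The coarse pass estimates integer window offsets; each finer pass
#' re-interrogates with the target window pre-shifted by the previous
#' (filtered and interpolated) field. The final grid spacing is
#' final_window * (1 - overlap) — 4 px for the default configuration.
#' [filterOutliers()] runs after every pass.
#'
#' @param frame0 reference (t = 0) frame, numeric matrix.
#' @param frameT target frame of the same size.
#' @param config a [PIVConfig-class].
#' @return a [DisplacementField-class].
#' @export
multipassPIV <- function(frame0, frameT, config = pivConfig()) {
  if (!all(dim(frame0) == dim(frameT)))
    stop("frames must have identical dimensions")
  H <- nrow(frame0); W <- ncol(frame0)
  if (min(H, W) < max(config@passWindows))
    stop("frame smaller than the interrogation window")
  prev <- NULL
  field <- NULL
  for (w in config@passWindows) {
    step <- max(1L, as.integer(round(w * (1 - config@overlap))))
    g <- .pivGrid(H, W, w, step)
    nx <- length(g$ax); ny <- length(g$ay)
    offx <- offy <- matrix(0L, ny, nx)
    if (!is.null(prev)) {
      offx[] <- as.integer(round(.sampleField(prev@u, prev@gridX, prev@gridY,
                                              g$cx, g$cy)))
      offy[] <- as.integer(round(.sampleField(prev@v, prev@gridX, prev@gridY,
                                              g$cx, g$cy)))
    }
    u <- v <- snr <- matrix(NA_real_, ny, nx)
    for (iy in seq_len(ny)) {
      b <- g$ay[iy]
      for (ix in seq_len(nx)) {
        a <- g$ax[ix]
        ta <- clampIndex(a + offx[iy, ix], W - w + 1L)
        tb <- clampIndex(b + offy[iy, ix], H - w + 1L)
        res <- tryCatch(
          .correlatePair(frame0[b:(b + w - 1L), a:(a + w - 1L)],
                         frameT[tb:(tb + w - 1L), ta:(ta + w - 1L)]),
          undefinedCorrelation = function(e)
            list(du = NA_real_, dv = NA_real_, snr = 0))
        u[iy, ix] <- (ta - a) + res$du
        v[iy, ix] <- (tb - b) + res$dv
        snr[iy, ix] <- res$snr
      }
    }
    field <- new("DisplacementField", gridX = g$cx, gridY = g$cy,
                 u = u, v = v, snr = snr,
                 valid = is.finite(u) & is.finite(v),
                 reference = 0L, target = 1L, pixelSize = NA_real_)
    field <- filterOutliers(field, config)
    prev <- field
  }
  field
}

# Stack the 8 neighbours of every node into an (ny, nx, 8) array (NA pad).
.neighborStack <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  out <- array(NA_real_, c(ny, nx, 8))
  k <- 0
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    k <- k + 1
    ys <- seq_len(ny) + dy; xs <- seq_len(nx) + dx
    okY <- ys >= 1 & ys <= ny; okX <- xs >= 1 & xs <= nx
    out[okY, okX, k] <- m[ys[okY], xs[okX]]
  }
  out
}

.neighborMedian <- function(m) {
  apply(.neighborStack(m), c(1, 2), stats::median, na.rm = TRUE)
}

#' Filter spurious displacement vectors
#'
#' Applies, in order: an SNR cut (`snr < minSNR`), a global filter
#' (component deviates from the global mean by more than `globalK`
#' standard deviations) and a local filter (component deviates from the
#' 3x3 neighborhood median by more than `localThreshold` times the
#' neighborhood median absolute deviation, floored at 0.1 px).
#' Invalidated vectors are replaced by the neighborhood median, iterated
#' until all interior gaps are filled; replaced vectors stay flagged
#' `valid = FALSE`.
#'
#' @param field a [DisplacementField-class].
#' @param config a [PIVConfig-class].
#' @return the filtered [DisplacementField-class].
#' @export
filterOutliers <- function(field, config = pivConfig()) {
  u <- field@u; v <- field@v
  valid <- field@valid & is.finite(u) & is.finite(v)
  valid <- valid & (field@snr >= config@minSNR)
  # global filter
  for (comp in list(u, v)) {
    mu <- mean(comp[valid]); sdv <- stats::sd(comp[valid])
    if (is.finite(sdv) && sdv > 1e-9) {
      valid <- valid & !(abs(comp - mu) > config@globalK * sdv &
                           is.finite(comp))
    }
  }
  # local filter (median absolute neighborhood deviation, floored)
  uu <- u; uu[!valid] <- NA
  vv <- v; vv[!valid] <- NA
  for (comp in list(u = uu, v = vv)) {
    nb <- .neighborStack(comp)
    med <- apply(nb, c(1, 2), stats::median, na.rm = TRUE)
    madn <- apply(abs(nb - rep(med, 8)), c(1, 2), stats::median, na.rm = TRUE)
    dev <- abs(comp - med)
    bad <- is.finite(dev) & is.finite(madn) &
      dev > config@localThreshold * (madn + 0.1)
    valid <- valid & !bad
  }
  # replacement: iterated neighborhood median over surviving + filled values
  fu <- u; fu[!valid] <- NA
  fv <- v; fv[!valid] <- NA
  for (it in seq_len(prod(dim(u)))) {
    nas <- which(is.na(fu) | is.na(fv))
    if (!length(nas)) break
    mu <- .neighborMedian(fu); mv <- .neighborMedian(fv)
    fill <- nas[is.finite(mu[nas]) & is.finite(mv[nas])]
    if (!length(fill)) break
    fu[fill] <- mu[fill]
    fv[fill] <- mv[fill]
  }
  methods::initialize(field, u = fu, v = fv, valid = valid)
}

#' Displacement fields for a whole stack
#'
#' One field per frame t >= 2, each computed against frame 1 (cumulative
#' reference at t = 0, not frame-to-frame chaining). Vectors whose
#' interrogation window covers the nucleus mask by less than half are
#' marked invalid and set to NA.
#'
#' @param stack an [ImageStack-class] with >= 2 frames.
#' @param config a [PIVConfig-class].
#' @param mask optional logical matrix restricting vectors to the nucleus.
#' @return list of [DisplacementField-class], one per target frame.
#' @export
displacementSequence <- function(stack, config = pivConfig(), mask = NULL) {
  nT <- nFrames(stack)
  if (nT < 2) stop("at least two frames required")
  if (!is.null(mask) && !any(mask)) stop("mask is empty")
  f0 <- getFrame(stack, 1)
  cover <- NULL
  fields <- vector("list", nT - 1)
  for (t in 2:nT) {
    fld <- multipassPIV(f0, getFrame(stack, t), config)
    fld@target <- t - 1L
    fld@pixelSize <- pixelSize(stack)
    if (!is.null(mask)) {
      if (is.null(cover)) {
        w <- config@passWindows[length(config@passWindows)]
        S <- summedArea(mask * 1)
        a0 <- pmax(round(fld@gridX - w / 2 + 0.5), 1)
        b0 <- pmax(round(fld@gridY - w / 2 + 0.5), 1)
        a1 <- pmin(a0 + w - 1, ncol(mask)); b1 <- pmin(b0 + w - 1, nrow(mask))
        gr <- expand.grid(y = seq_along(fld@gridY), x = seq_along(fld@gridX))
        frac <- boxSum(S, b0[gr$y], b1[gr$y], a0[gr$x], a1[gr$x]) /
          ((b1[gr$y] - b0[gr$y] + 1) * (a1[gr$x] - a0[gr$x] + 1))
        cover <- matrix(frac >= 0.5, length(fld@gridY), length(fld@gridX))
      }
      fld@u[!cover] <- NA_real_
      fld@v[!cover] <- NA_real_
      fld@valid <- fld@valid & cover
    }
    fields[[t - 1]] <- fld
  }
  fields
}
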