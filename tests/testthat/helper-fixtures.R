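# Shared fixtures. Expensive phantoms and their PIV fields are computed once
# per test run and cached; every fixture is seeded and deterministic.

PX <- 0.1233

fixtureCache <- new.env(parent = emptyenv())
withFixture <- function(key, expr) {
  if (!exists(key, envir = fixtureCache))
    assign(key, expr, envir = fixtureCache)
  get(key, envir = fixtureCache)
}

# Band-limited sub-pixel shift of a periodic image via Fourier phase ramp.
fftShiftImage <- function(img, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  fy <- c(0:(H %/% 2), -((H - H %/% 2 - 1):1)) / H
  fx <- c(0:(W %/% 2), -((W - W %/% 2 - 1):1)) / W
  ph <- exp(-2i * pi * (outer(fy * dy, rep(1, W)) +
                          outer(rep(1, H), fx * dx)))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (H * W)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Periodic band-limited noise texture (no nucleus envelope): seamless under
# circular rolls and Fourier shifts.
periodicTexture <- function(n, sigf = 1, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * n), n, n)
  fr <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  Kf <- exp(-2 * pi^2 * sigf^2 * outer(fr^2, fr^2, `+`))
  zf <- Re(stats::fft(stats::fft(z) * Kf, inverse = TRUE)) / (n * n)
  100 + 20 * zf / sd(zf)
}

# Logical node matrix: TRUE where the (rounded) grid node lies inside mask.
nodesInMask <- function(field, mask) {
  gx <- round(field@gridX); gy <- round(field@gridY)
  matrix(mask[cbind(rep(gy, length(gx)), rep(gx, each = length(gy)))],
         length(gy))
}

# Ground-truth displacement at the field's grid nodes, in px.
truthAtNodes <- function(truth, field, t, px = PX) {
  gr <- expand.grid(y = field@gridY, x = field@gridX)
  gt <- truth@displacementFn((gr$x - 1) * px, (gr$y - 1) * px, t) / px
  list(u = matrix(gt[, 1], length(field@gridY)),
       v = matrix(gt[, 2], length(field@gridY)))
}

# Build a DisplacementField directly from matrices (for filter/strain tests).
makeField <- function(u, v, gridX = NULL, gridY = NULL, spacing = 4,
                      snr = 10) {
  if (is.null(gridX)) gridX <- seq_len(ncol(u)) * spacing
  if (is.null(gridY)) gridY <- seq_len(nrow(u)) * spacing
  new("DisplacementField", gridX = gridX, gridY = gridY, u = u, v = v,
      snr = matrix(snr, nrow(u), ncol(u)),
      valid = is.finite(u) & is.finite(v),
      reference = 0L, target = 1L, pixelSize = PX)
}

# Two-frame phantom at peak deformation (t = 0 and t = 29.9 s), A = 1 um.
pivPhantomFixture <- function() withFixture("pivPhantom", {
  spec <- phantomSpec(imageShape = c(128L, 128L), nFrames = 2L,
                      frameInterval = 29.9, amplitude = 1, noiseSigma = 0,
                      nucleusRadius = 6.5, seed = 11L)
  rs <- suppressWarnings(renderSequence(spec))
  masks <- phantomMasks(spec)
  field <- displacementSequence(rs$stack, pivConfig(), masks$nucleus)[[1]]
  list(spec = spec, stack = rs$stack, truth = rs$truth, masks = masks,
       field = field, tPeak = 29.9)
})

# 25-frame phantom sampling the full creep/recovery protocol (dt = 2.5 s).
temporalPhantomFixture <- function() withFixture("temporalPhantom", {
  spec <- phantomSpec(imageShape = c(96L, 96L), nFrames = 25L,
                      frameInterval = 2.5, amplitude = 0.6, noiseSigma = 0,
                      nucleusRadius = 5, seed = 5L)
  rs <- suppressWarnings(renderSequence(spec))
  masks <- phantomMasks(spec)
  fields <- displacementSequence(rs$stack, pivConfig(), masks$nucleus)
  list(spec = spec, stack = rs$stack, truth = rs$truth, masks = masks,
       fields = fields)
})

# Immobile / mobile nucleolus phantoms at peak deformation. The immobile
# nucleolus sits on the far side of the stimulus, where the local far
# field stays below the nuclear average, so the perinucleolar gradient
# terminates below NUC; the mobile one sits at the nucleus centre, where
# the local displacement matches the nuclear average.
nucleolusPhantomFixture <- function(mobile) {
  key <- if (mobile) "nllMobile" else "nllImmobile"
  withFixture(key, {
    spec <- phantomSpec(
      imageShape = c(128L, 128L), nFrames = 2L, frameInterval = 29.9,
      amplitude = 1, noiseSigma = 0, nucleusRadius = 6.5,
      nucleolus = list(center = c(7.83, if (mobile) 7.83 else 5.83),
                       radius = 2, mobile = mobile, rampLength = 2),
      seed = 7L)
    rs <- suppressWarnings(renderSequence(spec))
    masks <- phantomMasks(spec)
    # restrict vectors to windows clear of the static lamina edge: a half
    # window (8 px) inside the nuclear border
    pivMask <- interiorMask(masks$nucleus, 8)
    field <- displacementSequence(rs$stack, pivConfig(), pivMask)[[1]]
    interior <- interiorMask(masks$nucleus, 6)
    shells <- perinucleolarShells(masks$nucleolus, interior, 4, 3)
    labels <- new("CompartmentLabels", nucleusMask = masks$nucleus,
                  interiorMask = interior,
                  densityLabels = matrix(0L, 128, 128),
                  nucleolusMask = masks$nucleolus, shellLabels = shells,
                  chcMask = matrix(FALSE, 128, 128), borderCutoff = 6,
                  shellThickness = 4, pixelSize = PX)
    dispMap <- displacementMagnitudeMap(field, c(128L, 128L),
                                        mask = interior)
    list(spec = spec, truth = rs$truth, masks = masks, field = field,
         labels = labels, dispMap = dispMap, tPeak = 29.9)
  })
}

# Rigid CHC phantom: bright condensed disc translating 0.8 um at peak,
# sampled at 1 frame/s over the whole protocol.
chcPhantomFixture <- function() withFixture("chcPhantom", {
  spec <- phantomSpec(
    imageShape = c(128L, 128L), nFrames = 61L, frameInterval = 1,
    amplitude = 1, noiseSigma = 0, nucleusRadius = 6.5,
    chc = list(center = c(7.83, 7.83), radius = 2.5, amplitude = 0.8),
    seed = 9L)
  rs <- suppressWarnings(renderSequence(spec))
  masks <- phantomMasks(spec)
  list(spec = spec, stack = rs$stack, truth = rs$truth, masks = masks)
})

# Parameter-recovery sweep: noisy Kelvin-Voigt traces refitted at 4 fps.
kvSweepFixture <- function() withFixture("kvSweep", {
  taus <- c(0.2, 0.5, 1, 2, 5)
  set.seed(42)
  t <- seq(0, 60, by = 0.25)
  res <- lapply(taus, function(tau) {
    errC <- errR <- numeric(100)
    plateau <- 1 - exp(-10 / tau)
    for (i in 1:100) {
      y <- kelvinVoigtResponse(t, tau, tau) +
        rnorm(length(t), sd = 0.05 * plateau)
      kv <- fitKelvinVoigt(timeSeries(t, y))
      errC[i] <- abs(kv@tauC - tau) / tau
      errR[i] <- abs(kv@tauR - tau) / tau
    }
    c(medianCreep = median(errC), medianRelax = median(errR))
  })
  do.call(rbind, res)
})

# Sub-pixel accuracy sweep: uniform Fourier shifts of a noise-free texture.
subpixelSweepFixture <- function() withFixture("subpixelSweep", {
  spec <- phantomSpec(imageShape = c(128L, 128L), nucleusRadius = 7.5,
                      amplitude = 0, noiseSigma = 0, seed = 3L)
  tex <- getFrame(makeTexture(spec), 1)
  shifts <- c(-1, -0.7, -0.5, -0.3, -0.1, 0.1, 0.25, 0.5, 0.75, 1)
  biases <- c(); rmses <- c()
  for (s in shifts) {
    tgt <- fftShiftImage(tex, s, -s / 2)
    f <- multipassPIV(tex, tgt)
    ny <- length(f@gridY); nx <- length(f@gridX)
    sel <- f@valid
    sel[c(1:4, (ny - 3):ny), ] <- FALSE
    sel[, c(1:4, (nx - 3):nx)] <- FALSE
    eu <- f@u[sel] - s; ev <- f@v[sel] + s / 2
    biases <- c(biases, mean(eu), mean(ev))
    rmses <- c(rmses, sqrt(mean(eu^2 + ev^2)))
  }
  list(maxBias = max(abs(biases)), maxRMSE = max(rmses))
})
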