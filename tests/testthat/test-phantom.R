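# Synthetic phantom generator: texture statistics, analytic displacement
# model, rendering consistency and the noise model.

test_that("texture is deterministic per seed and handles a degenerate nucleus", {
  spec <- phantomSpec(imageShape = c(64L, 64L), nucleusRadius = 3, seed = 7L)
  t1 <- getFrame(makeTexture(spec), 1)
  t2 <- getFrame(makeTexture(spec), 1)
  expect_identical(t1, t2)
  other <- getFrame(makeTexture(phantomSpec(imageShape = c(64L, 64L),
                                            nucleusRadius = 3, seed = 8L)), 1)
  expect_false(identical(t1, other))

  bare <- phantomSpec(imageShape = c(64L, 64L), nucleusRadius = 0)
  frame <- getFrame(makeTexture(bare), 1)
  expect_true(all(frame == frame[1, 1]))          # all background
  expect_false(any(phantomMasks(bare)$nucleus))
  expect_error(phantomSpec(imageShape = c(64L, 64L), nucleusRadius = 10),
               "fit")
})

test_that("texture autocorrelation FWHM matches the requested grain", {
  # oracle: direct autocorrelation of the unmasked interior
  for (grain in c(0.3, 0.5)) {
    spec <- phantomSpec(imageShape = c(256L, 256L), nucleusRadius = 15,
                        textureGrain = grain, seed = 2L)
    tex <- getFrame(makeTexture(spec), 1)
    crop <- tex[65:192, 65:192]                    # fully inside the nucleus
    crop <- crop - mean(crop)
    ac <- Re(stats::fft(Mod(stats::fft(crop))^2, inverse = TRUE))
    ac <- ac / ac[1, 1]
    prof <- ac[1, 1:20]                            # lag profile along x
    below <- which(prof < 0.5)[1]
    fwhm <- 2 * (below - 2 + (prof[below - 1] - 0.5) /
                   (prof[below - 1] - prof[below]))
    expect_lt(abs(fwhm - grain / PX) / (grain / PX), 0.2)
  }
})

test_that("displacement model obeys timing, amplitude and compartment rules", {
  spec <- phantomSpec()
  x <- runif(50, 0, 30); y <- runif(50, 0, 30)
  expect_true(all(displacementModel(x, y, 0, spec) == 0))    # pre-stimulus
  expect_true(all(displacementModel(x, y, 19.9, spec) == 0))

  # at the stimulus line, late in a long stimulation, |u| approaches A = 2 um
  longStim <- phantomSpec(amplitude = 2, tOn = 20, tOff = 1e6)
  p0 <- longStim@stimulusLine[1:2]
  d <- displacementModel(p0[1] + 1e-9, p0[2] + 1e-9, 1e5, longStim)
  expect_equal(sqrt(sum(d^2)), 2, tolerance = 1e-6)

  # rigid CHC: zero displacement spread over the disc at every frame
  chc <- chcPhantomFixture()
  cen <- chc$spec@chc$center
  th <- runif(200, 0, 2 * pi); rr <- sqrt(runif(200)) * chc$spec@chc$radius
  xs <- cen[1] + rr * cos(th); ys <- cen[2] + rr * sin(th)
  for (t in c(22, 25, 30, 31, 35)) {
    d <- displacementModel(xs, ys, t, chc$spec)
    expect_lt(sd(d[, 1]), 1e-3)
    expect_lt(sd(d[, 2]), 1e-3)
  }

  # immobile nucleolus nulls the field inside the disc
  nll <- nucleolusPhantomFixture(mobile = FALSE)
  cenN <- nll$spec@nucleolus$center
  dN <- displacementModel(cenN[1] + c(0, 0.5), cenN[2] + c(0, -0.5), 29,
                          nll$spec)
  expect_true(all(abs(dN) < 1e-12))
})

test_that("temporal profile at a fixed point is the Kelvin-Voigt curve", {
  spec <- phantomSpec(amplitude = 1)
  ts <- seq(0, 60, by = 0.25)
  pt <- spec@nucleusCenter
  mag <- vapply(ts, function(t)
    sqrt(sum(displacementModel(pt[1], pt[2], t, spec)^2)), numeric(1))
  geo <- sqrt(sum(displacementModel(pt[1], pt[2], 1e9,
    phantomSpec(amplitude = 1, tOff = 1e18))^2))   # spatial factor alone
  expect_equal(mag, geo * kelvinVoigtResponse(ts, spec@tauC, spec@tauR),
               tolerance = 1e-9)
})

test_that("analytic strain matches finite differences of the displacement model", {
  set.seed(1)
  nll <- nucleolusPhantomFixture(mobile = FALSE)
  specs <- list(phantomSpec(), nll$spec)
  h <- 1e-3
  for (spec in specs) {
    gt <- groundTruth(spec)
    cen <- spec@nucleusCenter
    th <- runif(100, 0, 2 * pi)
    rr <- sqrt(runif(100)) * (spec@nucleusRadius - 0.1)
    xs <- cen[1] + rr * cos(th); ys <- cen[2] + rr * sin(th)
    for (t in c(25, 40)) {
      dudx <- (gt@displacementFn(xs + h, ys, t)[, 1] -
                 gt@displacementFn(xs - h, ys, t)[, 1]) / (2 * h)
      dudy <- (gt@displacementFn(xs, ys + h, t)[, 1] -
                 gt@displacementFn(xs, ys - h, t)[, 1]) / (2 * h)
      dvdx <- (gt@displacementFn(xs + h, ys, t)[, 2] -
                 gt@displacementFn(xs - h, ys, t)[, 2]) / (2 * h)
      dvdy <- (gt@displacementFn(xs, ys + h, t)[, 2] -
                 gt@displacementFn(xs, ys - h, t)[, 2]) / (2 * h)
      s <- gt@strainFn(xs, ys, t)
      expect_lt(max(abs(s[, "hydro"] - (dudx + dvdy) / 2)), 1e-3)
      expect_lt(max(abs(s[, "shear"] - (dudy + dvdx))), 1e-3)
    }
  }
})

test_that("rendering: null deformation and integer shifts are exact", {
  null <- phantomSpec(imageShape = c(64L, 64L), nucleusRadius = 3,
                      amplitude = 0, noiseSigma = 0, nFrames = 3L,
                      frameInterval = 15)
  rs <- renderSequence(null)
  expect_identical(getFrame(rs$stack, 1), getFrame(rs$stack, 2))
  expect_identical(getFrame(rs$stack, 1), getFrame(rs$stack, 3))

  # uniform 3 px shift: rendered frame equals the integer-rolled frame 0
  shift <- phantomSpec(imageShape = c(96L, 96L), nucleusRadius = 5.5,
                       amplitude = 3 * PX, decayLength = Inf,
                       stimulusLine = c(0, -2, 0), tauC = 0.01,
                       noiseSigma = 0, nFrames = 2L, frameInterval = 29.9)
  rs <- suppressWarnings(renderSequence(shift))
  f0 <- getFrame(rs$stack, 1); f1 <- getFrame(rs$stack, 2)
  interior <- 30:70
  # texture moved +3 px in y (away from a line far above the image)
  expect_equal(f1[interior + 3, interior], f0[interior, interior],
               tolerance = 1e-9)
})

test_that("noise model is seeded, unbiased and optional", {
  quiet <- phantomSpec(imageShape = c(64L, 64L), nucleusRadius = 3,
                       noiseSigma = 0)
  stack <- makeTexture(quiet)
  expect_identical(addNoise(stack, quiet)@frames, stack@frames)

  noisy <- phantomSpec(imageShape = c(1000L, 1000L), nucleusRadius = 3,
                       noiseSigma = 5)
  base <- new("ImageStack",
              frames = array(1000, c(1000L, 1000L, 1L)),
              timestamps = 0, pixelSize = PX, channel = "chromatin")
  out <- addNoise(base, noisy)
  resid <- out@frames - base@frames
  expect_lt(abs(sd(resid) - 5) / 5, 0.02)          # moment check, 1e6 px
  expect_lt(abs(mean(resid)), 0.05)
  out2 <- addNoise(base, noisy)
  expect_identical(out@frames, out2@frames)        # same seed, same noise
  expect_error(phantomSpec(noiseSigma = -1), "noiseSigma")
})
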