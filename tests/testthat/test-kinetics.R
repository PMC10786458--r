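# Temporal dynamics: image differences, Kelvin-Voigt fitting, feature and
# CHC tracking, kymographs, border rigidity and fiber strain.

staticStack <- function(frame, n, dt = 0.25) {
  new("ImageStack", frames = array(frame, c(dim(frame), n)),
      timestamps = (seq_len(n) - 1) * dt, pixelSize = PX,
      channel = "chromatin")
}

test_that("image differences are zero for static stacks and exact for patches", {
  frame <- matrix(50, 40, 40)
  s <- staticStack(frame, 5)
  mask <- matrix(TRUE, 40, 40)
  ts <- imageDifferenceSeries(s, mask)
  expect_true(all(ts@value == 0))

  fr2 <- frame; fr2[3:7, 3:6] <- frame[3:7, 3:6] + 12   # 20 px changed by 12
  arr <- array(frame, c(40, 40, 2)); arr[, , 2] <- fr2
  s2 <- new("ImageStack", frames = arr, timestamps = c(0, 0.25),
            pixelSize = PX, channel = "chromatin")
  ts2 <- imageDifferenceSeries(s2, mask)
  expect_equal(ts2@value[2], 20 * 12 / sum(mask))        # direct-sum oracle
  expect_error(imageDifferenceSeries(s, matrix(FALSE, 40, 40)), "mask")
})

test_that("phantom image difference rises under stimulation and reverts after", {
  tp <- temporalPhantomFixture()
  ts <- imageDifferenceSeries(tp$stack, tp$masks$nucleus)
  peak <- max(ts@value[ts@t <= 30])
  final <- ts@value[length(ts@value)]
  expect_gt(peak, 0)
  expect_lt(final, 0.2 * peak)                  # partially reversible
  expect_true(all(ts@value[ts@t < 20] == 0))    # quiet baseline (no noise)
})

test_that("Kelvin-Voigt fitting recovers the printed CHC time constants to 1%", {
  t <- seq(0, 60, by = 0.25)
  y <- kelvinVoigtResponse(t, 0.74, 0.92)       # E = 1
  kv <- fitKelvinVoigt(timeSeries(t, y))
  expect_lt(abs(kv@tauC - 0.74) / 0.74, 0.01)
  expect_lt(abs(kv@tauR - 0.92) / 0.92, 0.01)
  expect_equal(kv@E, 1, tolerance = 0.01)
  expect_equal(kv@etaCreep, kv@E * kv@tauC)     # tau = eta / E

  flat <- fitKelvinVoigt(timeSeries(t, rep(0, length(t))))
  expect_true(flat@flat)
})

test_that("Kelvin-Voigt fitting is the identity on its own forward model", {
  for (tau in c(0.1, 0.5, 2, 10)) {
    for (E in c(0.1, 1, 10)) {
      t <- seq(0, 60, by = 0.25)
      y <- kelvinVoigtResponse(t, tau, tau, amplitude = 1 / E)
      kv <- fitKelvinVoigt(timeSeries(t, y))
      expect_lt(abs(kv@tauC - tau) / tau, 0.01)
      expect_lt(abs(kv@tauR - tau) / tau, 0.01)
      expect_lt(abs(kv@E - E) / E, 0.01)
    }
  }
})

test_that("noisy parameter recovery approaches the Cramer-Rao information limit", {
  # independent oracle: the achievable precision for tau under iid noise,
  # from the Fisher information of each phase's model (numerical Jacobian)
  crlbMedian <- function(tau, sigma, phase) {
    ts <- seq(0.25, if (phase == "creep") 10 else 30, by = 0.25)
    dtau <- 1e-6
    if (phase == "creep") {
      f <- function(p) (1 - exp(-ts / p))           # amplitude free
      J <- cbind(f(tau), ((f(tau + dtau) - f(tau - dtau)) / (2 * dtau)))
      V <- sigma^2 * solve(crossprod(J))[2, 2]
    } else {
      b <- 1 - exp(-10 / tau)                       # amplitude fixed
      f <- function(p) b * exp(-ts / p)
      g <- (f(tau + dtau) - f(tau - dtau)) / (2 * dtau)
      V <- sigma^2 / sum(g^2)
    }
    stats::qnorm(0.75) * sqrt(V) / tau              # median |err| / tau
  }
  sweep <- kvSweepFixture()
  taus <- c(0.2, 0.5, 1, 2, 5)
  for (i in seq_along(taus)) {
    sigma <- 0.05 * (1 - exp(-10 / taus[i]))
    expect_lt(sweep[i, "medianCreep"],
              max(0.05, 1.6 * crlbMedian(taus[i], sigma, "creep")))
    expect_lt(sweep[i, "medianRelax"],
              max(0.05, 1.6 * crlbMedian(taus[i], sigma, "relax")))
  }
})

test_that("feature tracking follows static and translating blobs", {
  blob <- function(cx, cy) {
    outer(1:64, 1:64, function(y, x)
      100 * exp(-((x - cx)^2 + (y - cy)^2) / 18) + 10)
  }
  mask <- matrix(TRUE, 64, 64)
  s <- staticStack(blob(32, 32), 6)
  tr <- trackFeatures(s, "bright", mask, quantileCut = 0.05)
  expect_equal(length(unique(tr$featureId)), 1)
  expect_lt(max(abs(tr$x - tr$x[1])), 1e-6)
  expect_lt(diff(range(tr$area)) / mean(tr$area), 1e-9)

  # 0.05 um/frame translation
  step <- 0.05 / PX
  arr <- array(0, c(64, 64, 10))
  for (k in 1:10) arr[, , k] <- blob(20 + (k - 1) * step, 32)
  s2 <- new("ImageStack", frames = arr,
            timestamps = (0:9) * 0.25, pixelSize = PX,
            channel = "chromatin")
  tr2 <- trackFeatures(s2, "bright", mask, quantileCut = 0.05)
  expect_equal(length(unique(tr2$featureId)), 1)
  vel <- diff(tr2$x) / diff(tr2$t)                 # um/s
  expect_lt(max(abs(vel - 0.05 / 0.25)) / (0.05 / 0.25), 0.1)
})

test_that("the rigid CHC tracks the Kelvin-Voigt profile with constant shape", {
  chc <- chcPhantomFixture()
  tr <- trackFeatures(chc$stack, "bright", chc$masks$nucleus,
                      quantileCut = 0.15, minArea = 50)
  main <- names(which.max(table(tr$featureId)))
  tr <- tr[tr$featureId == as.integer(main), ]
  expect_equal(nrow(tr), 61)
  disp <- sqrt((tr$x - tr$x[1])^2 + (tr$y - tr$y[1])^2)
  want <- 0.8 * kelvinVoigtResponse(tr$t, chc$spec@tauC, chc$spec@tauR)
  expect_lt(max(abs(disp - want)), 0.05 * 0.8)     # 5% of peak translation
  expect_lt(diff(range(tr$area)) / mean(tr$area), 0.02)
  expect_lt(diff(range(tr$major)) / mean(tr$major), 0.02)
  expect_lt(diff(range(tr$minor)) / mean(tr$minor), 0.02)

  # cross-module consistency: tracking equals mean PIV displacement (peak)
  f <- multipassPIV(getFrame(chc$stack, 1), getFrame(chc$stack, 31))
  sel <- nodesInMask(f, interiorMask(chc$masks$chc, 9)) & is.finite(f@u)
  pivDisp <- c(mean(f@u[sel]), mean(f@v[sel]))
  trackDisp <- c(tr$x[31] - tr$x[1], tr$y[31] - tr$y[1]) / PX
  expect_lt(sqrt(sum((pivDisp - trackDisp)^2)), 0.2)
})

test_that("kymographs show static columns and unit-slope moving edges", {
  frame <- matrix(rep(seq(10, 100, length.out = 48), each = 48), 48, 48)
  s <- staticStack(frame, 4)
  ky <- kymograph(s, c(5, 24), c(44, 24))
  expect_true(all(ky == ky[, 1]))
  expect_error(kymograph(s, c(5, 24), c(5, 24)), "zero-length")

  # edge advancing 1 px/frame along x
  arr <- array(10, c(48, 48, 6))
  for (k in 1:6) arr[, (20 + k):48, k] <- 100
  s2 <- new("ImageStack", frames = arr, timestamps = (0:5) * 0.25,
            pixelSize = PX, channel = "chromatin")
  ky2 <- kymograph(s2, c(1, 24), c(48, 24), nSamples = 48)
  edge <- apply(ky2, 2, function(col) which(col >= 55)[1])
  expect_equal(unname(diff(edge)), rep(1, 5))

  # phantom streaks return toward the initial position after recovery
  tp <- temporalPhantomFixture()
  cen <- tp$spec@nucleusCenter / PX + 1
  ky3 <- kymograph(tp$stack, c(cen[1], cen[2] - 25), c(cen[1], cen[2] + 25))
  first <- ky3[, 1]; peak <- ky3[, 13]; last <- ky3[, 25]
  expect_gt(mean(abs(peak - first)), 3 * mean(abs(last - first)))
})

test_that("border profiles detect translations and certify phantom border rigidity", {
  disc <- matrix(FALSE, 64, 64)
  disc[(col(disc) - 32)^2 + (row(disc) - 32)^2 <= 20^2] <- TRUE
  bp <- borderProfile(list(disc, disc, disc), pixelSize = PX)
  expect_equal(borderDeviation(bp), 0, tolerance = 1e-9)

  shifted <- matrix(FALSE, 64, 64)
  shifted[(col(shifted) - 33)^2 + (row(shifted) - 32)^2 <= 20^2] <- TRUE
  bp2 <- borderProfile(list(disc, shifted), pixelSize = PX)
  expect_equal(borderDeviation(bp2), 1 * PX, tolerance = 0.15)

  # internal deformation leaves the rendered nuclear border static (<200 nm)
  tp <- temporalPhantomFixture()
  masks <- lapply(c(1, 9, 12, 13, 25), function(k)
    segmentNucleus(getFrame(tp$stack, k)))
  bp3 <- borderProfile(masks, pixelSize = PX)
  expect_lt(borderDeviation(bp3), 0.2)
})

test_that("fiber strain is the scaled centroid displacement", {
  track <- data.frame(featureId = 1L, frame = 1:5,
                      t = c(10, 20, 22, 25, 30),
                      x = c(5, 5, 5.2, 5.35, 5.45),
                      y = c(4, 4, 4, 4, 4),
                      area = 1, major = 1, minor = 1)
  fs <- fiberStrain(track, L0 = 3, tOn = 20)
  expect_equal(fs$strain[1:2], c(0, 0))
  expect_equal(fs$strain[5], 0.15)             # dL = 0.45 um, L0 = 3 um
  expect_equal(fs$strain, fs$deltaL / 3)
  expect_error(fiberStrain(track, L0 = 0), "L0")
})
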