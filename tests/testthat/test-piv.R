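# Multi-pass PIV: correlation core, grid geometry, outlier filtering and
# ground-truth recovery on rendered phantoms.

test_that("window correlation recovers zero, integer and half-pixel shifts", {
  spec <- phantomSpec(imageShape = c(64L, 64L), nucleusRadius = 3.8,
                      amplitude = 0, seed = 4L)
  tex <- getFrame(makeTexture(spec), 1)
  patch <- tex[17:48, 17:48]
  same <- correlateWindow(patch, patch)
  expect_equal(c(same$du, same$dv), c(0, 0))
  expect_gt(same$snr, 1)

  shifted <- tex[17:48 + 2, 17:48 - 3]             # content moved (+3, -2)
  res <- correlateWindow(patch, shifted)
  expect_equal(round(c(res$du, res$dv)), c(3, -2))

  sub <- fftShiftImage(tex, 0.5, 0)[17:48, 17:48]  # band-limited 0.5 px
  res <- correlateWindow(patch, sub)
  expect_lt(abs(res$du - 0.5), 0.1)
  expect_lt(abs(res$dv), 0.1)

  expect_error(correlateWindow(matrix(1, 32, 32), patch),
               class = "undefinedCorrelation")
  expect_error(correlateWindow(patch[1:16, 1:32], patch), "square")
})

test_that("default multi-pass config yields a 4 px grid and zero field on static frames", {
  spec <- phantomSpec(nucleusRadius = 14, amplitude = 0, seed = 6L)
  tex <- getFrame(makeTexture(spec), 1)              # 256 x 256
  f <- multipassPIV(tex, tex)
  expect_equal(gridSpacing(f), 4)
  expect_true(all(abs(f@u[f@valid]) < 1e-9))
  expect_true(all(abs(f@v[f@valid]) < 1e-9))
  expect_error(multipassPIV(tex[1:16, 1:16], tex[1:16, 1:16]), "window")
})

test_that("sub-pixel accuracy: |bias| < 0.05 px and RMSE < 0.15 px", {
  sw <- subpixelSweepFixture()
  expect_lt(sw$maxBias, 0.05)
  expect_lt(sw$maxRMSE, 0.15)
})

test_that("PIV is translation-equivariant and antisymmetric under frame swap", {
  # periodic texture: circular rolls are seamless, so interior windows see
  # byte-identical content at index-shifted nodes
  tex <- periodicTexture(128, seed = 12)
  tgt <- fftShiftImage(tex, 0.2, -0.3)
  roll <- function(m, dy, dx) {
    m[((seq_len(nrow(m)) - 1 - dy) %% nrow(m)) + 1,
      ((seq_len(ncol(m)) - 1 - dx) %% ncol(m)) + 1]
  }
  f1 <- multipassPIV(tex, tgt)
  f2 <- multipassPIV(roll(tex, 8, 8), roll(tgt, 8, 8))
  ny <- length(f1@gridY); nx <- length(f1@gridX)
  iy <- 5:(ny - 4); ix <- 5:(nx - 4)
  sel <- f1@valid[iy - 2, ix - 2] & f2@valid[iy, ix]
  expect_lt(max(abs((f2@u[iy, ix] - f1@u[iy - 2, ix - 2])[sel])), 1e-9)
  expect_lt(max(abs((f2@v[iy, ix] - f1@v[iy - 2, ix - 2])[sel])), 1e-9)

  fRev <- multipassPIV(tgt, tex)
  int <- function(m) m[iy, ix]
  sel <- int(f1@valid) & int(fRev@valid)
  # forward and reverse errors are independent, so the per-vector sum is
  # bounded in the mean, not the extreme
  expect_lt(mean(abs((int(f1@u) + int(fRev@u))[sel])), 0.1)
  expect_lt(mean(abs((int(f1@v) + int(fRev@v))[sel])), 0.1)
})

test_that("outlier filters keep uniform fields, catch spikes and planted outliers", {
  u <- matrix(0.3, 15, 15); v <- matrix(-0.2, 15, 15)
  f <- filterOutliers(makeField(u, v))
  expect_true(all(f@valid))                         # nothing invalidated
  expect_equal(f@u, u)

  u2 <- u; u2[8, 8] <- 10.3
  f2 <- filterOutliers(makeField(u2, v))
  expect_false(f2@valid[8, 8])
  expect_equal(sum(!f2@valid), 1)                   # exactly the spike
  expect_equal(f2@u[8, 8], 0.3)                     # neighbor median fill

  # smooth field + 5% planted large outliers
  set.seed(13)
  gx <- seq(4, 120, by = 4); gy <- seq(4, 120, by = 4)
  base <- outer(gy, gx, function(y, x) sin(x / 40) + cos(y / 50))
  u3 <- base; v3 <- -base / 2
  n <- length(u3)
  planted <- sample(n, round(0.05 * n))
  sgn <- sample(c(-1, 1), length(planted), TRUE)
  u3[planted] <- u3[planted] + sgn * runif(length(planted), 5, 8)
  f3 <- filterOutliers(makeField(u3, v3, gridX = gx, gridY = gy))
  caught <- !f3@valid
  expect_gte(mean(caught[planted]), 0.95)
  expect_lt(mean(caught[-planted]), 0.02)           # false positives
})

test_that("PIV recovers phantom ground truth (RMSE < 0.15 px noise-free)", {
  pf <- pivPhantomFixture()
  f <- pf$field
  inner <- interiorMask(pf$masks$nucleus, 9)        # windows fully on texture
  sel <- nodesInMask(f, inner) & is.finite(f@u)
  gt <- truthAtNodes(pf$truth, f, pf$tPeak)
  err <- sqrt(mean((gt$u[sel] - f@u[sel])^2 + (gt$v[sel] - f@v[sel])^2))
  expect_lt(err, 0.15)
  expect_gt(max(abs(gt$v[sel])), 3)                 # deformation was real
})

test_that("static stacks give zero fields and sequences follow the Kelvin-Voigt time course", {
  spec <- phantomSpec(imageShape = c(64L, 64L), nucleusRadius = 3,
                      amplitude = 0, noiseSigma = 0, nFrames = 3L,
                      frameInterval = 20)
  rs <- renderSequence(spec)
  flds <- displacementSequence(rs$stack, pivConfig(),
                               phantomMasks(spec)$nucleus)
  for (f in flds) {
    expect_true(all(abs(f@u[f@valid]) < 1e-9))
  }
  expect_error(displacementSequence(rs$stack, pivConfig(),
                                    matrix(FALSE, 64, 64)), "mask")

  tp <- temporalPhantomFixture()
  # pick a well-displaced interior node and follow its magnitude over time
  inner <- interiorMask(tp$masks$nucleus, 9)
  f1 <- tp$fields[[12]]                              # t = 30 s, creep peak
  sel <- nodesInMask(f1, inner)
  gt <- truthAtNodes(tp$truth, f1, 30)
  node <- which(sel & abs(gt$v) > 3, arr.ind = TRUE)[1, ]
  ts <- timestamps(tp$stack)[-1]
  meas <- vapply(tp$fields, function(f)
    sqrt(f@u[node[1], node[2]]^2 + f@v[node[1], node[2]]^2), numeric(1))
  spatial <- sqrt(sum(displacementModel(
    (f1@gridX[node[2]] - 1) * PX, (f1@gridY[node[1]] - 1) * PX, 1e9,
    phantomSpec(imageShape = c(96L, 96L), nucleusRadius = 5,
                amplitude = 0.6, tOff = 1e18))^2)) / PX
  expected <- spatial * kelvinVoigtResponse(ts, tp$spec@tauC, tp$spec@tauR)
  expect_lt(max(abs(meas - expected)), 0.05 * spatial)  # 5% of plateau
})

test_that("vectors inside an immobile nucleolus are static while chromatin flows", {
  nll <- nucleolusPhantomFixture(mobile = FALSE)
  f <- nll$field
  cen <- nll$spec@nucleolus$center / PX + 1
  # nodes whose whole final window lies inside the nucleolus disc
  rIn <- nll$spec@nucleolus$radius / PX - 8
  dd <- sqrt(outer(f@gridY - cen[2], rep(1, length(f@gridX)))^2 +
               outer(rep(1, length(f@gridY)), f@gridX - cen[1])^2)
  selIn <- dd <= rIn & is.finite(f@u)
  expect_gt(sum(selIn), 5)
  expect_lt(mean(sqrt(f@u^2 + f@v^2)[selIn]), 0.1)
  # while the far field moves by several px
  far <- nodesInMask(f, interiorMask(nll$masks$nucleus, 9)) &
    dd > (nll$spec@nucleolus$radius + 2.2) / PX & is.finite(f@u)
  expect_gt(mean(sqrt(f@u^2 + f@v^2)[far]), 1)
})
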