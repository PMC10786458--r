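# Synthetic nucleus phantoms: band-limited chromatin texture warped by an
# analytic displacement field with Kelvin-Voigt time dependence. Every
# rendered sequence comes with exact ground truth for PIV, strain, tracking
# and viscoelastic-fit validation.

#' Construct a phantom specification
#'
#' Defaults reproduce the acquisition conditions the analysis is designed
#' for: 4 frames/s for 60 s (20 s baseline, 10 s stimulation, 30 s
#' recovery), 0.1233 um/px, a nucleus of 20 um diameter, peak displacement
#' of 2 um at the stimulus line and Kelvin-Voigt times tauC = 0.74 s /
#' tauR = 0.92 s. The stimulus line defaults to a horizontal line 2 um
#' below the nucleus edge.
#'
#' @param imageShape integer(2) (height, width) px.
#' @param pixelSize um/px.
#' @param frameInterval s.
#' @param nFrames number of frames.
#' @param nucleusRadius um.
#' @param nucleusCenter (x, y) um; default image centre.
#' @param textureGrain um, autocorrelation FWHM of the chromatin texture.
#' @param amplitude um, peak displacement at the stimulus line.
#' @param decayLength um, exponential decay length of displacement.
#' @param stimulusLine numeric(3) (x0, y0, theta_deg); default horizontal
#'   line 2 um below the nucleus.
#' @param tauC,tauR s, Kelvin-Voigt creep and relaxation times.
#' @param tOn,tOff s, stimulation window.
#' @param nucleolus optional list(center, radius, mobile, rampLength).
#' @param chc optional list(center, radius, amplitude).
#' @param noiseSigma Gaussian read noise sd (intensity a.u.).
#' @param poissonGain Poisson noise gain, 0 = off.
#' @param seed RNG seed.
#' @return a [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(imageShape = c(128, 128), nFrames = 8)
#' spec
#' @export
phantomSpec <- function(imageShape = c(256L, 256L), pixelSize = 0.1233,
                        frameInterval = 0.25, nFrames = 240L,
                        nucleusRadius = 10, nucleusCenter = NULL,
                        textureGrain = 0.4, amplitude = 2,
                        decayLength = 10, stimulusLine = NULL,
                        tauC = 0.74, tauR = 0.92, tOn = 20, tOff = 30,
                        nucleolus = list(), chc = list(),
                        noiseSigma = 2, poissonGain = 0, seed = 1L) {
  imageShape <- as.integer(imageShape)
  if (is.null(nucleusCenter))
    nucleusCenter <- (rev(imageShape) - 1) / 2 * pixelSize
  if (is.null(stimulusLine))
    stimulusLine <- c(nucleusCenter[1],
                      nucleusCenter[2] + nucleusRadius + 2, 0)
  if (length(nucleolus)) {
    nucleolus <- utils::modifyList(
      list(mobile = FALSE, rampLength = 1), nucleolus)
  }
  if (length(chc)) {
    chc <- utils::modifyList(list(amplitude = NA_real_, rampLength = 1), chc)
  }
  new("PhantomSpec", imageShape = imageShape, pixelSize = pixelSize,
      frameInterval = frameInterval, nFrames = as.integer(nFrames),
      nucleusRadius = nucleusRadius, nucleusCenter = nucleusCenter,
      textureGrain = textureGrain, amplitude = amplitude,
      decayLength = decayLength, stimulusLine = stimulusLine,
      tauC = tauC, tauR = tauR, tOn = tOn, tOff = tOff,
      nucleolus = nucleolus, chc = chc,
      noiseSigma = noiseSigma, poissonGain = poissonGain,
      seed = as.integer(seed))
}

#' Kelvin-Voigt creep/recovery response
#'
#' Normalised temporal response g(t): 0 before stimulation onset,
#' 1 - exp(-(t - tOn)/tauC) during stimulation, and exponential recovery
#' g(tOff) * exp(-(t - tOff)/tauR) afterwards.
#'
#' @param t time(s), s.
#' @param tauC,tauR creep and relaxation times, s.
#' @param tOn,tOff stimulation window, s.
#' @param amplitude plateau scaling (default 1).
#' @return numeric vector, same length as `t`.
#' @export
kelvinVoigtResponse <- function(t, tauC, tauR, tOn = 20, tOff = 30,
                                amplitude = 1) {
  g <- numeric(length(t))
  creep <- t >= tOn & t <= tOff
  g[creep] <- 1 - exp(-(t[creep] - tOn) / tauC)
  post <- t > tOff
  gOff <- 1 - exp(-(tOff - tOn) / tauC)
  g[post] <- gOff * exp(-(t[post] - tOff) / tauR)
  amplitude * g
}

# Signed distance of points (um) to the stimulus line and its unit normal.
.lineGeometry <- function(x, y, spec) {
  p0 <- spec@stimulusLine[1:2]
  th <- spec@stimulusLine[3] * pi / 180
  nrm <- c(-sin(th), cos(th))
  list(delta = (x - p0[1]) * nrm[1] + (y - p0[2]) * nrm[2], normal = nrm)
}

#' Analytic phantom displacement field
#'
#' Forward (Lagrangian) displacement of the material point at t=0 position
#' (x, y): magnitude A * exp(-d/lambda) * g(t), directed away from the
#' stimulus line, where d is the distance to the line and g is the
#' Kelvin-Voigt response. Inside an immobile nucleolus the field is zero,
#' ramping linearly to the far-field value over the coupling ramp length;
#' inside a rigid CHC disc the field is a spatially constant translation,
#' blended into the surrounding field over the CHC ramp length so the
#' total field stays continuous.
#'
#' @param x,y positions, um (equal-length vectors).
#' @param t time, s (scalar).
#' @param spec a [PhantomSpec-class].
#' @return matrix with columns `u`, `v` (um).
#' @export
displacementModel <- function(x, y, t, spec) {
  stopifnot(length(t) == 1L)
  geo <- .lineGeometry(x, y, spec)
  g <- kelvinVoigtResponse(t, spec@tauC, spec@tauR, spec@tOn, spec@tOff)
  mag <- spec@amplitude * exp(-abs(geo$delta) / spec@decayLength) * g
  s <- sign(geo$delta)
  u <- mag * s * geo$normal[1]
  v <- mag * s * geo$normal[2]
  nll <- spec@nucleolus
  if (length(nll) && !isTRUE(nll$mobile)) {
    rho <- sqrt((x - nll$center[1])^2 + (y - nll$center[2])^2)
    w <- pmin(pmax((rho - nll$radius) / nll$rampLength, 0), 1)
    u <- u * w
    v <- v * w
  }
  ch <- spec@chc
  if (length(ch)) {
    # rigid body translation inside; blend to the far field over the ramp
    rc <- sqrt((x - ch$center[1])^2 + (y - ch$center[2])^2)
    w <- pmin(pmax((rc - ch$radius) / ch$rampLength, 0), 1)
    tr <- .chcTranslation(t, spec)
    u <- w * u + (1 - w) * tr[1]
    v <- w * v + (1 - w) * tr[2]
  }
  cbind(u = u, v = v)
}

# Rigid-body translation of the CHC disc at time t (um).
.chcTranslation <- function(t, spec) {
  ch <- spec@chc
  geo <- .lineGeometry(ch$center[1], ch$center[2], spec)
  g <- kelvinVoigtResponse(t, spec@tauC, spec@tauR, spec@tOn, spec@tOff)
  amp <- if (is.na(ch$amplitude)) {
    spec@amplitude * exp(-abs(geo$delta) / spec@decayLength)
  } else {
    ch$amplitude
  }
  amp * g * sign(geo$delta) * geo$normal
}

# Analytic spatial strain of the phantom displacement field: hydrostatic
# (du/dx + dv/dy)/2 and engineering shear du/dy + dv/dx, by product rule
# over the exponential line field and the nucleolar coupling ramp. Zero
# inside a rigid CHC disc (rigid body).
.phantomStrain <- function(x, y, t, spec) {
  geo <- .lineGeometry(x, y, spec)
  g <- kelvinVoigtResponse(t, spec@tauC, spec@tauR, spec@tOn, spec@tOff)
  nx <- geo$normal[1]; ny <- geo$normal[2]
  f <- spec@amplitude * g * sign(geo$delta) *
    exp(-abs(geo$delta) / spec@decayLength)
  fp <- -(spec@amplitude * g / spec@decayLength) *
    exp(-abs(geo$delta) / spec@decayLength)
  # base gradient: d u_i / d x_j = f'(delta) n_i n_j
  dudx <- fp * nx * nx; dudy <- fp * nx * ny
  dvdx <- fp * ny * nx; dvdy <- fp * ny * ny
  uf <- f * nx; vf <- f * ny                      # current field components
  nll <- spec@nucleolus
  if (length(nll) && !isTRUE(nll$mobile)) {
    dx <- x - nll$center[1]; dy <- y - nll$center[2]
    rho <- sqrt(dx^2 + dy^2)
    w <- pmin(pmax((rho - nll$radius) / nll$rampLength, 0), 1)
    wp <- ifelse(rho > nll$radius & rho < nll$radius + nll$rampLength,
                 1 / nll$rampLength, 0)
    rho[rho == 0] <- 1
    dwdx <- wp * dx / rho; dwdy <- wp * dy / rho
    dudx <- w * dudx + uf * dwdx; dudy <- w * dudy + uf * dwdy
    dvdx <- w * dvdx + vf * dwdx; dvdy <- w * dvdy + vf * dwdy
    uf <- w * uf; vf <- w * vf
  }
  ch <- spec@chc
  if (length(ch)) {
    # u = w*u_f + (1-w)*u_c with constant u_c: gradient w*grad(u_f) +
    # (u_f - u_c) (x) grad(w)
    dx <- x - ch$center[1]; dy <- y - ch$center[2]
    rc <- sqrt(dx^2 + dy^2)
    w <- pmin(pmax((rc - ch$radius) / ch$rampLength, 0), 1)
    wp <- ifelse(rc > ch$radius & rc < ch$radius + ch$rampLength,
                 1 / ch$rampLength, 0)
    rc[rc == 0] <- 1
    dwdx <- wp * dx / rc; dwdy <- wp * dy / rc
    tr <- .chcTranslation(t, spec)
    dudx <- w * dudx + (uf - tr[1]) * dwdx
    dudy <- w * dudy + (uf - tr[1]) * dwdy
    dvdx <- w * dvdx + (vf - tr[2]) * dwdx
    dvdy <- w * dvdy + (vf - tr[2]) * dwdy
  }
  hydro <- (dudx + dvdy) / 2
  shr <- dudy + dvdx
  cbind(hydro = hydro, shear = shr)
}

#' Ground truth closures for a phantom
#'
#' @param spec a [PhantomSpec-class].
#' @return a [GroundTruth-class] whose `displacementFn(x, y, t)` and
#'   `strainFn(x, y, t)` evaluate the analytic field and its strain.
#' @export
groundTruth <- function(spec) {
  new("GroundTruth",
      displacementFn = function(x, y, t) displacementModel(x, y, t, spec),
      strainFn = function(x, y, t) .phantomStrain(x, y, t, spec),
      spec = spec)
}

#' Ground-truth masks of a phantom
#'
#' Hard pixel masks of the nucleus, nucleolus and CHC discs at t = 0.
#'
#' @param spec a [PhantomSpec-class].
#' @return list of logical matrices `nucleus`, `nucleolus`, `chc`.
#' @export
phantomMasks <- function(spec) {
  px <- spec@pixelSize
  toPx <- function(center, radius)
    discMask(spec@imageShape, center / px + 1, radius / px)
  nuc <- if (spec@nucleusRadius > 0) {
    toPx(spec@nucleusCenter, spec@nucleusRadius)
  } else {
    matrix(FALSE, spec@imageShape[1], spec@imageShape[2])
  }
  nll <- if (length(spec@nucleolus)) {
    toPx(spec@nucleolus$center, spec@nucleolus$radius)
  } else {
    matrix(FALSE, spec@imageShape[1], spec@imageShape[2])
  }
  ch <- if (length(spec@chc)) {
    toPx(spec@chc$center, spec@chc$radius)
  } else {
    matrix(FALSE, spec@imageShape[1], spec@imageShape[2])
  }
  list(nucleus = nuc, nucleolus = nll, chc = ch)
}

# Full-field chromatin texture (with nucleolar/CHC pockets painted in)
# and the static nucleus envelope. The envelope is applied AFTER warping:
# the stiff nuclear lamina keeps the border static while chromatin moves
# beneath it, which is also why downstream analysis cuts 6 px off the
# border.
.phantomScene <- function(spec) {
  H <- spec@imageShape[1]; W <- spec@imageShape[2]
  px <- spec@pixelSize
  grainPx <- max(spec@textureGrain / px, 1e-6)
  # filtering white noise with a Gaussian of sd sigf gives an
  # autocorrelation FWHM of 2*sqrt(2*log(2)) * sigf * sqrt(2)
  sigf <- grainPx / (2 * sqrt(2 * log(2)) * sqrt(2))
  z <- withSeed(spec@seed, matrix(stats::rnorm(H * W), H, W))
  fy <- c(0:(H %/% 2), -((H - H %/% 2 - 1):1)) / H
  fx <- c(0:(W %/% 2), -((W - W %/% 2 - 1):1)) / W
  Kf <- exp(-2 * pi^2 * sigf^2 *
              (outer(fy^2, rep(1, W)) + outer(rep(1, H), fx^2)))
  zf <- Re(stats::fft(stats::fft(z) * Kf, inverse = TRUE)) / (H * W)
  tex <- 100 + 20 * zf / stats::sd(zf)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  rr <- matrix(seq_len(H), H, W)
  softDisc <- function(center, radius) {
    d <- sqrt((cc - (center[1] / px + 1))^2 + (rr - (center[2] / px + 1))^2)
    pmin(pmax(radius / px - d + 0.5, 0), 1)   # 1 px soft edge
  }
  if (length(spec@nucleolus)) {
    tex <- tex * (1 - 0.8 * softDisc(spec@nucleolus$center,
                                     spec@nucleolus$radius))
  }
  if (length(spec@chc)) {
    tex <- tex + 150 * softDisc(spec@chc$center, spec@chc$radius)
  }
  envelope <- if (spec@nucleusRadius > 0) {
    softDisc(spec@nucleusCenter, spec@nucleusRadius)
  } else {
    matrix(0, H, W)
  }
  list(tex = tex, envelope = envelope, background = 5)
}

#' Render the undeformed phantom texture
#'
#' White noise low-pass filtered to the requested grain (autocorrelation
#' FWHM = `textureGrain`), normalised to mean 100 / sd 20, masked to the
#' nucleus disc over a dim background. The nucleolus appears as a dark
#' chromatin-void pocket and the CHC as a bright condensed disc.
#' Deterministic for a given seed.
#'
#' @param spec a [PhantomSpec-class].
#' @return single-frame [ImageStack-class] (channel "chromatin").
#' @export
makeTexture <- function(spec) {
  sc <- .phantomScene(spec)
  img <- pmax(sc$background + (sc$tex - sc$background) * sc$envelope, 0)
  new("ImageStack",
      frames = array(img, c(spec@imageShape[1], spec@imageShape[2], 1L)),
      timestamps = 0, pixelSize = spec@pixelSize, channel = "chromatin")
}

#' Render a deformed phantom sequence with ground truth
#'
#' Each frame warps the t = 0 full-field texture by the phantom
#' displacement field: for every pixel the forward map X -> X + u(X, t)
#' is inverted by fixed-point iteration and the reference texture is
#' sampled there by backward mapping (bicubic by default), so that the
#' texture at position X + u(X, t) in frame t is the texture at X in
#' frame 0. The nucleus envelope is applied after warping — the stiff
#' lamina keeps the nuclear border static while chromatin moves beneath
#' it. Camera noise is added last via [addNoise()].
#'
#' @param spec a [PhantomSpec-class].
#' @param interpolation "bicubic" (default) or "bilinear".
#' @return list with elements `stack` ([ImageStack-class]) and `truth`
#'   ([GroundTruth-class]).
#' @export
renderSequence <- function(spec, interpolation = c("bicubic", "bilinear")) {
  interpolation <- match.arg(interpolation)
  sample2 <- if (interpolation == "bicubic") interpBicubic else interpBilinear
  sc <- .phantomScene(spec)
  H <- spec@imageShape[1]; W <- spec@imageShape[2]
  px <- spec@pixelSize
  frame0 <- pmax(sc$background + (sc$tex - sc$background) * sc$envelope, 0)
  ts <- (seq_len(spec@nFrames) - 1) * spec@frameInterval
  X <- as.vector(matrix((seq_len(W) - 1) * px, H, W, byrow = TRUE))
  Y <- as.vector(matrix((seq_len(H) - 1) * px, H, W))
  out <- array(0, c(H, W, spec@nFrames))
  warned <- FALSE
  for (k in seq_along(ts)) {
    t <- ts[k]
    g <- kelvinVoigtResponse(t, spec@tauC, spec@tauR, spec@tOn, spec@tOff)
    if (g == 0 || spec@amplitude == 0) {
      out[, , k] <- frame0
      next
    }
    # invert X + u(X) = x by fixed-point iteration (|grad u| << 1)
    Xs <- X; Ys <- Y
    for (it in 1:8) {
      d <- displacementModel(Xs, Ys, t, spec)
      Xs <- X - d[, 1]
      Ys <- Y - d[, 2]
    }
    if (!warned && (any(Xs < 0) || any(Xs > (W - 1) * px) ||
                    any(Ys < 0) || any(Ys > (H - 1) * px))) {
      warning("displacement exceeds image bounds; sampling edge-clamped")
      warned <- TRUE
    }
    warped <- matrix(sample2(sc$tex, Xs / px + 1, Ys / px + 1), H, W)
    out[, , k] <- pmax(sc$background +
                         (warped - sc$background) * sc$envelope, 0)
  }
  stack <- new("ImageStack", frames = out, timestamps = ts,
               pixelSize = px, channel = "chromatin")
  stack <- addNoise(stack, spec)
  list(stack = stack, truth = groundTruth(spec))
}

#' Add camera noise to a stack
#'
#' Optional Poisson shot noise (gain `poissonGain` counts/photon) followed
#' by i.i.d. Gaussian read noise of sd `noiseSigma`, clipped at zero.
#' Seeded from `spec@seed`; repeated calls with the same spec are
#' identical. With `noiseSigma = 0` and `poissonGain = 0` the stack is
#' returned untouched.
#'
#' @param stack an [ImageStack-class].
#' @param spec a [PhantomSpec-class] carrying the noise model and seed.
#' @return a noised [ImageStack-class].
#' @export
addNoise <- function(stack, spec) {
  if (spec@noiseSigma < 0) stop("noiseSigma must be >= 0")
  if (spec@noiseSigma == 0 && spec@poissonGain == 0) return(stack)
  fr <- stack@frames
  fr <- withSeed(spec@seed + 1L, {
    if (spec@poissonGain > 0) {
      fr[] <- stats::rpois(length(fr), fr / spec@poissonGain) *
        spec@poissonGain
    }
    if (spec@noiseSigma > 0) {
      fr <- fr + stats::rnorm(length(fr), sd = spec@noiseSigma)
    }
    fr
  })
  fr[fr < 0] <- 0
  methods::initialize(stack, frames = fr)
}
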