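# Temporal dynamics: image-difference series, Kelvin-Voigt creep/relaxation
# fitting, intra-nuclear feature tracking, kymographs, border-rigidity
# profiles and fiber-strain estimates.

#' Construct a time series
#'
#' @param t s, strictly increasing.
#' @param value metric values.
#' @param tOn,tOff s, stimulation window (defaults 20 / 30).
#' @return a [TimeSeries-class].
#' @export
timeSeries <- function(t, value, tOn = 20, tOff = 30) {
  new("TimeSeries", t = t, value = value, tOn = tOn, tOff = tOff)
}

#' Mean absolute image difference over time
#'
#' For every frame t, the mean over the mask of |I_t - I_0| against the
#' first frame; frame 0 gives 0 by construction. Rearrangement of
#' chromatin away from its initial configuration raises the series,
#' recovery lowers it.
#'
#' @param stack an [ImageStack-class] with >= 2 frames.
#' @param mask logical matrix (e.g. the nucleus); must be non-empty.
#' @param tOn,tOff stimulation window (s) recorded on the series.
#' @return a [TimeSeries-class].
#' @export
imageDifferenceSeries <- function(stack, mask, tOn = 20, tOff = 30) {
  if (nFrames(stack) < 2) stop("at least two frames required")
  if (!any(mask)) stop("mask is empty")
  f0 <- getFrame(stack, 1)
  vals <- vapply(seq_len(nFrames(stack)), function(i) {
    mean(abs(getFrame(stack, i) - f0)[mask])
  }, numeric(1))
  timeSeries(timestamps(stack), vals, tOn, tOff)
}

.nlsMultiStart <- function(formulaStr, data, starts, lower) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(stats::as.formula(formulaStr), data = data,
                        start = st, lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  best
}

#' Fit a Kelvin-Voigt model to a creep/recovery series
#'
#' The baseline (mean of the pre-stimulus samples) is subtracted. The
#' creep segment (tOn <= t <= tOff, time origin tOn) is fitted to
#' amplitude * (1 - exp(-t'/tauC)) with amplitude = 1/E; the relaxation
#' segment (t > tOff, origin tOff) to epsAtOff * exp(-t'/tauR), where the
#' amplitude epsAtOff is fixed at the creep endpoint implied by the creep
#' fit, so only tauR is free in the second phase. Both fits are
#' nonlinear least squares with multi-start over tau in {0.1, 1, 10} s.
#' The two phases are fitted independently, so distinct creep and
#' relaxation times can be reported.
#'
#' @param series a [TimeSeries-class] covering both phases.
#' @return a [KelvinVoigtParams-class]; `flat = TRUE` flags series whose
#'   response is indistinguishable from baseline noise.
#' @export
fitKelvinVoigt <- function(series) {
  t <- series@t; y <- series@value
  tOn <- series@tOn; tOff <- series@tOff
  pre <- t < tOn
  baseline <- if (any(pre)) mean(y[pre]) else 0
  noise <- if (sum(pre) > 2) stats::sd(y[pre]) else 0
  y <- y - baseline
  creepSel <- t >= tOn & t <= tOff
  relaxSel <- t > tOff
  if (sum(creepSel) < 3 || sum(relaxSel) < 3)
    stop("series must cover both the stimulation and the recovery phase")
  dC <- data.frame(ts = t[creepSel] - tOn, y = y[creepSel])
  a0 <- max(abs(dC$y))
  if (a0 < .Machine$double.eps^0.5 || a0 <= 3 * noise) {
    return(new("KelvinVoigtParams", E = NA_real_, tauC = NA_real_,
               tauR = NA_real_, etaCreep = NA_real_, etaRelax = NA_real_,
               amplitude = 0, epsAtOff = 0, fitRMSE = 0,
               tOn = tOn, tOff = tOff, flat = TRUE))
  }
  starts <- lapply(c(0.1, 1, 10), function(tau) list(a = a0, tau = tau))
  creep <- .nlsMultiStart("y ~ a * (1 - exp(-ts / tau))", dC, starts,
                          lower = c(a = 0, tau = 1e-4))
  if (is.null(creep))
    stop("Kelvin-Voigt creep fit failed to converge (all starts)")
  cc <- stats::coef(creep$fit)
  epsOff <- unname(cc["a"] * (1 - exp(-(tOff - tOn) / cc["tau"])))
  dR <- data.frame(ts = t[relaxSel] - tOff, y = y[relaxSel],
                   b = max(epsOff, 1e-12))
  startsR <- lapply(c(0.1, 1, 10), function(tau) list(tau = tau))
  relax <- .nlsMultiStart("y ~ b * exp(-ts / tau)", dR, startsR,
                          lower = c(tau = 1e-4))
  if (is.null(relax))
    stop("Kelvin-Voigt relaxation fit failed to converge (all starts)")
  cr <- stats::coef(relax$fit)
  rmse <- sqrt((creep$rss + relax$rss) / (nrow(dC) + nrow(dR)))
  E <- unname(1 / cc["a"])
  new("KelvinVoigtParams", E = E, tauC = unname(cc["tau"]),
      tauR = unname(cr["tau"]), etaCreep = E * unname(cc["tau"]),
      etaRelax = E * unname(cr["tau"]), amplitude = unname(cc["a"]),
      epsAtOff = epsOff, fitRMSE = rmse,
      tOn = tOn, tOff = tOff, flat = FALSE)
}

# Detect features in one frame: dark (chromatin-void, below the low
# intensity quantile) or bright (condensed, above the high quantile)
# connected components inside the mask.
.detectFeatures <- function(frame, polarity, mask, quantileCut, minAreaPx) {
  vals <- frame[mask]
  fm <- if (polarity == "dark") {
    thr <- stats::quantile(vals, quantileCut, names = FALSE)
    frame < thr & mask
  } else {
    thr <- stats::quantile(vals, 1 - quantileCut, names = FALSE)
    frame > thr & mask
  }
  lab <- .ebMatrix(EBImage::bwlabel(fm))
  ids <- seq_len(max(lab))
  out <- list()
  for (id in ids) {
    sel <- lab == id
    npx <- sum(sel)
    if (npx < minAreaPx) next
    idx <- which(sel, arr.ind = TRUE)
    w <- if (polarity == "dark") max(frame[sel]) + 1 - frame[sel] else
      frame[sel] - min(frame[sel]) + 1
    W <- sum(w)
    cx <- sum(idx[, 2] * w) / W
    cy <- sum(idx[, 1] * w) / W
    mxx <- sum(w * (idx[, 2] - cx)^2) / W
    myy <- sum(w * (idx[, 1] - cy)^2) / W
    mxy <- sum(w * (idx[, 2] - cx) * (idx[, 1] - cy)) / W
    ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2), symmetric = TRUE)$values
    out[[length(out) + 1]] <- list(x = cx, y = cy, area = npx,
                                   major = 4 * sqrt(max(ev[1], 0)),
                                   minor = 4 * sqrt(max(ev[2], 0)))
  }
  out
}

#' Track intra-nuclear features over time
#'
#' Per frame, features are detected by intensity quantile thresholding
#' (dark = chromatin-void pockets such as nucleoli; bright = condensed
#' clusters such as the CHC), measured by intensity-weighted centroids and
#' second-moment ellipse axes, and linked frame-to-frame by nearest
#' neighbor within a maximum step. When a link is ambiguous (two
#' candidates within the gate) the track is split with a warning.
#'
#' @param stack an [ImageStack-class].
#' @param polarity "dark" or "bright".
#' @param mask logical matrix restricting detection (e.g. the nucleus).
#' @param quantileCut intensity quantile defining the feature (default
#'   0.15: below the 15th percentile for dark, above the 85th for bright).
#' @param minArea minimum feature area in px (default 5).
#' @param maxStep maximum frame-to-frame centroid step, um (default 1).
#' @return data.frame with columns featureId, frame, t, x, y (um),
#'   area (um^2), major, minor (um).
#' @export
trackFeatures <- function(stack, polarity = c("dark", "bright"), mask,
                          quantileCut = 0.15, minArea = 5, maxStep = 1) {
  polarity <- match.arg(polarity)
  px <- pixelSize(stack)
  ts <- timestamps(stack)
  rows <- list()
  active <- list()   # featureId -> last (x, y) px
  nextId <- 1L
  for (k in seq_len(nFrames(stack))) {
    dets <- .detectFeatures(getFrame(stack, k), polarity, mask,
                            quantileCut, minArea)
    assigned <- rep(FALSE, length(dets))
    newActive <- list()
    for (fid in names(active)) {
      last <- active[[fid]]
      if (!length(dets)) next
      dist <- vapply(dets, function(d)
        sqrt((d$x - last[1])^2 + (d$y - last[2])^2) * px, numeric(1))
      inGate <- which(dist <= maxStep & !assigned)
      if (length(inGate) >= 2) {
        warning(sprintf(
          "ambiguous link for feature %s at frame %d; track split", fid, k))
        next
      }
      if (length(inGate) == 1) {
        j <- inGate
        assigned[j] <- TRUE
        d <- dets[[j]]
        rows[[length(rows) + 1]] <- data.frame(
          featureId = as.integer(fid), frame = k, t = ts[k],
          x = (d$x - 1) * px, y = (d$y - 1) * px,
          area = d$area * px^2, major = d$major * px, minor = d$minor * px)
        newActive[[fid]] <- c(d$x, d$y)
      }
    }
    for (j in seq_along(dets)) {
      if (assigned[j]) next
      d <- dets[[j]]
      fid <- as.character(nextId)
      rows[[length(rows) + 1]] <- data.frame(
        featureId = nextId, frame = k, t = ts[k],
        x = (d$x - 1) * px, y = (d$y - 1) * px,
        area = d$area * px^2, major = d$major * px, minor = d$minor * px)
      newActive[[fid]] <- c(d$x, d$y)
      nextId <- nextId + 1L
    }
    active <- newActive
  }
  if (!length(rows)) {
    return(data.frame(featureId = integer(), frame = integer(),
                      t = numeric(), x = numeric(), y = numeric(),
                      area = numeric(), major = numeric(),
                      minor = numeric()))
  }
  do.call(rbind, rows)
}

#' Kymograph along a line
#'
#' Bilinear intensity sampling along the segment from `from` to `to`
#' (pixel coordinates, (x, y)) in every frame, stacked into a position x
#' time matrix.
#'
#' @param stack an [ImageStack-class].
#' @param from,to numeric(2) endpoints (x, y) in px.
#' @param nSamples number of positions (default: one per pixel of length).
#' @return numeric matrix [position, frame].
#' @export
kymograph <- function(stack, from, to, nSamples = NULL) {
  len <- sqrt(sum((to - from)^2))
  if (len <= 0) stop("zero-length line")
  if (is.null(nSamples)) nSamples <- ceiling(len) + 1
  s <- seq(0, 1, length.out = nSamples)
  xs <- from[1] + s * (to[1] - from[1])
  ys <- from[2] + s * (to[2] - from[2])
  vapply(seq_len(nFrames(stack)), function(k)
    interpBilinear(getFrame(stack, k), xs, ys), numeric(nSamples))
}

#' Radial border profile over time
#'
#' For each angle, a ray is cast from the t = 0 nuclear centroid and the
#' outermost crossing of the mask boundary is located with sub-pixel
#' linear interpolation. Deviations of r(theta, t) from r(theta, 0)
#' quantify distortion of the nuclear shape.
#'
#' @param masks list of logical matrices (one per frame) or a logical
#'   (H, W, T) array.
#' @param pixelSize um/px.
#' @param centroidRef (x, y) px of the reference centroid (default: the
#'   centroid of the first mask).
#' @param nAngles number of angular samples over 360 degrees.
#' @return a [BorderProfile-class]; radii in um.
#' @export
borderProfile <- function(masks, pixelSize = 0.1233, centroidRef = NULL,
                          nAngles = 360L) {
  if (is.array(masks) && length(dim(masks)) == 3) {
    masks <- lapply(seq_len(dim(masks)[3]), function(i) masks[, , i])
  }
  if (!length(masks) || !any(masks[[1]])) stop("masks must be non-empty")
  if (is.null(centroidRef)) centroidRef <- maskCentroid(masks[[1]])
  H <- nrow(masks[[1]]); W <- ncol(masks[[1]])
  angles <- seq(0, 360, length.out = nAngles + 1)[-(nAngles + 1)]
  th <- angles * pi / 180
  rmax <- sqrt(max((c(1, W) - centroidRef[1])^2) +
                 max((c(1, H) - centroidRef[2])^2))
  rs <- seq(0, rmax, by = 0.25)
  qx <- centroidRef[1] + outer(rs, cos(th))   # [radius, angle]
  qy <- centroidRef[2] + outer(rs, sin(th))
  r <- matrix(NA_real_, nAngles, length(masks))
  for (k in seq_along(masks)) {
    vals <- matrix(interpBilinear(masks[[k]] * 1, as.vector(qx),
                                  as.vector(qy)),
                   length(rs), nAngles)
    for (a in seq_len(nAngles)) {
      inside <- which(vals[, a] >= 0.5)
      if (!length(inside)) next
      i <- max(inside)
      if (i >= length(rs)) { r[a, k] <- rs[i]; next }
      v0 <- vals[i, a]; v1 <- vals[i + 1, a]
      frac <- if (v0 > v1) (v0 - 0.5) / (v0 - v1) else 0
      r[a, k] <- rs[i] + frac * 0.25
    }
  }
  new("BorderProfile", angles = angles, r = r * pixelSize,
      centroid = unname(centroidRef), pixelSize = pixelSize)
}

#' Maximum radial border deviation
#'
#' max over angles and frames of |r(theta, t) - r(theta, 0)|, in um.
#'
#' @param profile a [BorderProfile-class].
#' @return numeric scalar (um).
#' @export
borderDeviation <- function(profile) {
  max(abs(profile@r - profile@r[, 1]), na.rm = TRUE)
}

#' Chromatin fiber strain from a feature track
#'
#' Assumes the tracked centroid displacement since stimulation onset
#' equals the extension dL of fibers of rest length L0 (~3 um), so
#' strain(t) = |centroid(t) - centroid(tOn)| / L0.
#'
#' @param track data.frame from [trackFeatures()] (single feature).
#' @param L0 fiber rest length, um (default 3).
#' @param tOn stimulation onset, s (default 20); the reference centroid is
#'   the last sample at t <= tOn.
#' @return data.frame with columns t, deltaL (um), strain.
#' @export
fiberStrain <- function(track, L0 = 3, tOn = 20) {
  if (L0 <= 0) stop("L0 must be > 0")
  if (length(unique(track$featureId)) > 1)
    stop("fiberStrain expects a single feature track")
  ref <- track[track$t <= tOn, , drop = FALSE]
  ref <- if (nrow(ref)) ref[nrow(ref), ] else track[1, ]
  dL <- sqrt((track$x - ref$x)^2 + (track$y - ref$y)^2)
  data.frame(t = track$t, deltaL = dL, strain = dL / L0)
}
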