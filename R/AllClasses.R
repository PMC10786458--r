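#' @import methods
#' @importFrom stats median quantile sd rnorm rpois coef lm nls fft aov TukeyHSD t.test integrate smooth.spline predict ptukey setNames
NULL

# Central data containers. All image-like slots are base matrices indexed
# [row, col] with row = y (increasing downward) and col = x; pixel (r, c) is
# centred at physical coordinates ((c-1)*pixelSize, (r-1)*pixelSize) in um.

#' Time-lapse fluorescence image stack
#'
#' Holds a single-channel image sequence with uniform frame timing and a
#' physical pixel size. Frames are stored as an (H, W, T) array.
#'
#' @slot frames numeric array, dim (height, width, n_frames); non-negative.
#' @slot timestamps numeric, acquisition time of each frame in seconds,
#'   strictly increasing.
#' @slot pixelSize numeric, physical pixel size in um/pixel.
#' @slot channel character label (e.g. "chromatin", "stain").
#' @exportClass ImageStack
setClass("ImageStack",
  representation(frames = "array", timestamps = "numeric",
                 pixelSize = "numeric", channel = "character"))

setValidity("ImageStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a 3D array (H, W, T)")
  if (length(object@timestamps) != d[3]) return("one timestamp per frame required")
  if (d[3] > 1 && any(diff(object@timestamps) <= 0))
    return("timestamps must be strictly increasing")
  if (!all(is.finite(object@frames))) return("intensities must be finite")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("pixelSize must be a positive scalar")
  TRUE
})

#' Synthetic phantom specification
#'
#' Parameters of a synthetic nucleus sequence: a band-limited chromatin-like
#' texture deformed by an analytic displacement field with Kelvin-Voigt time
#' dependence. Lengths are um, times are seconds. The stimulus line is given
#' as (x0, y0, theta_deg): a line through (x0, y0) um at angle theta to the
#' x axis; displacement points away from it on both sides.
#'
#' @slot imageShape integer(2), (height, width) in pixels.
#' @slot pixelSize um/pixel.
#' @slot frameInterval s between frames.
#' @slot nFrames number of frames.
#' @slot nucleusRadius um.
#' @slot nucleusCenter numeric(2), (x, y) um.
#' @slot textureGrain um, correlation length (autocorrelation FWHM) of the
#'   chromatin texture.
#' @slot amplitude um, peak displacement at the stimulus line.
#' @slot decayLength um, exponential decay length of displacement away from
#'   the line.
#' @slot stimulusLine numeric(3), (x0, y0, theta_deg).
#' @slot tauC,tauR s, Kelvin-Voigt creep and relaxation times.
#' @slot tOn,tOff s, stimulation window.
#' @slot nucleolus list() or list(center=c(x,y), radius, mobile=FALSE,
#'   rampLength): optional nucleolar disc; immobile discs null the field
#'   inside with a linear coupling ramp of the given length outside.
#' @slot chc list() or list(center=c(x,y), radius, amplitude=NA,
#'   rampLength=1): optional rigid central-heterochromatin disc translating
#'   as a solid body, blended into the surrounding field over rampLength um.
#' @slot noiseSigma Gaussian read-noise standard deviation (intensity a.u.).
#' @slot poissonGain photons-per-count gain for optional Poisson noise
#'   (0 disables).
#' @slot seed integer RNG seed; identical specs render bit-identically.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(imageShape = "integer", pixelSize = "numeric",
                 frameInterval = "numeric", nFrames = "integer",
                 nucleusRadius = "numeric", nucleusCenter = "numeric",
                 textureGrain = "numeric", amplitude = "numeric",
                 decayLength = "numeric", stimulusLine = "numeric",
                 tauC = "numeric", tauR = "numeric",
                 tOn = "numeric", tOff = "numeric",
                 nucleolus = "list", chc = "list",
                 noiseSigma = "numeric", poissonGain = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  s <- object
  fov <- (rev(s@imageShape) - 1) * s@pixelSize   # (x extent, y extent) um
  if (s@amplitude < 0) return("amplitude must be >= 0")
  if (s@decayLength <= 0) return("decayLength must be > 0")
  if (s@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (s@tauC <= 0 || s@tauR <= 0) return("tauC, tauR must be > 0")
  if (s@tOff <= s@tOn) return("tOff must exceed tOn")
  if (2 * s@nucleusRadius > min(fov))
    return("nucleus does not fit inside the image")
  inNucleus <- function(disc) {
    sqrt(sum((disc$center - s@nucleusCenter)^2)) + disc$radius <=
      s@nucleusRadius + 1e-9
  }
  if (length(s@nucleolus) && !inNucleus(s@nucleolus))
    return("nucleolus disc must lie inside the nucleus")
  if (length(s@chc) && !inNucleus(s@chc))
    return("chc disc must lie inside the nucleus")
  TRUE
})

#' Analytic ground truth for a phantom sequence
#'
#' Closures over a [PhantomSpec-class]: `displacementFn(x, y, t)` returns the
#' forward displacement (u, v) in um of the material point at t=0 position
#' (x, y) um; `strainFn(x, y, t)` returns its analytic hydrostatic and shear
#' strain.
#'
#' @slot displacementFn function(x, y, t) -> matrix with columns u, v (um).
#' @slot strainFn function(x, y, t) -> matrix with columns hydro, shear.
#' @slot spec the generating [PhantomSpec-class].
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(displacementFn = "function", strainFn = "function",
                 spec = "PhantomSpec"))

#' Multi-pass PIV configuration
#'
#' @slot passWindows integer vector of interrogation-window sizes per pass
#'   (pixels), powers of two, decreasing.
#' @slot overlap window overlap fraction in [0, 1).
#' @slot subpixel sub-pixel peak estimator tag ("gaussian3").
#' @slot globalK global filter threshold in standard deviations.
#' @slot localThreshold local filter threshold in multiples of the
#'   neighborhood median absolute deviation.
#' @slot minSNR minimum peak-to-second-peak ratio.
#' @exportClass PIVConfig
setClass("PIVConfig",
  representation(passWindows = "integer", overlap = "numeric",
                 subpixel = "character", globalK = "numeric",
                 localThreshold = "numeric", minSNR = "numeric"))

setValidity("PIVConfig", function(object) {
  w <- object@passWindows
  if (!length(w)) return("at least one pass window required")
  if (any(bitwAnd(w, w - 1L) != 0L)) return("windows must be powers of two")
  if (length(w) > 1 && any(diff(w) >= 0)) return("windows must be decreasing")
  if (object@overlap < 0 || object@overlap >= 1)
    return("overlap must be in [0, 1)")
  TRUE
})

#' Gridded displacement field
#'
#' Displacement of the target frame relative to the undeformed reference
#' frame on a regular grid of interrogation-window centres. Units are pixels.
#'
#' @slot gridX,gridY pixel coordinates (column / row) of grid nodes.
#' @slot u,v displacement components (px), matrices [gridY, gridX].
#' @slot snr correlation peak-to-second-peak ratio per node.
#' @slot valid logical matrix; FALSE where a vector was filtered and replaced
#'   (or masked out, in which case u, v are NA).
#' @slot reference,target frame indices (reference is frame 1, i.e. t = 0).
#' @slot pixelSize um/pixel (NA when unknown).
#' @exportClass DisplacementField
setClass("DisplacementField",
  representation(gridX = "numeric", gridY = "numeric",
                 u = "matrix", v = "matrix", snr = "matrix",
                 valid = "matrix", reference = "integer", target = "integer",
                 pixelSize = "numeric"))

setValidity("DisplacementField", function(object) {
  d <- c(length(object@gridY), length(object@gridX))
  for (s in c("u", "v", "snr", "valid"))
    if (!identical(dim(slot(object, s)), as.integer(d)))
      return(sprintf("slot %s has wrong dimensions", s))
  if (any(!is.finite(object@u[object@valid])))
    return("u must be finite where valid")
  if (any(!is.finite(object@v[object@valid])))
    return("v must be finite where valid")
  TRUE
})

#' Hydrostatic and shear strain field
#'
#' Dimensionless strain per displacement-grid node (1 = 100 %):
#' hydrostatic = (du/dx + dv/dy)/2, shear = du/dy + dv/dx, with derivatives
#' normalised by the node spacing `Lchar` (the characteristic initial
#' length).
#'
#' @slot hydro,shear strain matrices [gridY, gridX].
#' @slot gridX,gridY grid node coordinates (px).
#' @slot Lchar node spacing, same units as the displacement components.
#' @exportClass StrainField
setClass("StrainField",
  representation(hydro = "matrix", shear = "matrix",
                 gridX = "numeric", gridY = "numeric", Lchar = "numeric"))

#' Nuclear compartment label maps
#'
#' Pixel-wise segmentation products: the nucleus and its lamina-excluded
#' interior, seven equi-volumetric chromatin-density classes C1 (dimmest) to
#' C7 (brightest), the nucleolus, perinucleolar shells PC1..PCn, and the
#' optional central heterochromatin cluster.
#'
#' @slot nucleusMask,interiorMask,nucleolusMask,chcMask logical matrices.
#' @slot densityLabels integer matrix, 0 outside, 1..nBins inside.
#' @slot shellLabels integer matrix, 0 outside, k for shell PCk.
#' @slot borderCutoff px eroded off the nuclear border.
#' @slot shellThickness px per perinucleolar shell.
#' @slot pixelSize um/pixel.
#' @exportClass CompartmentLabels
setClass("CompartmentLabels",
  representation(nucleusMask = "matrix", interiorMask = "matrix",
                 densityLabels = "matrix", nucleolusMask = "matrix",
                 shellLabels = "matrix", chcMask = "matrix",
                 borderCutoff = "numeric", shellThickness = "numeric",
                 pixelSize = "numeric"))

#' Kelvin-Voigt viscoelastic fit
#'
#' Creep (stimulation) and relaxation (recovery) phases are fitted
#' independently: creep amplitude*(1 - exp(-t'/tauC)) with amplitude = 1/E,
#' relaxation epsAtOff*exp(-t'/tauR), with time origins tOn and tOff.
#' eta = E * tau by the Kelvin-Voigt definition tau = eta/E.
#'
#' @slot E relative elastic constant (1/creep amplitude).
#' @slot tauC,tauR s, creep (retardation) and relaxation times.
#' @slot etaCreep,etaRelax viscosity equivalents E*tauC and E*tauR.
#' @slot amplitude fitted creep plateau (= 1/E).
#' @slot epsAtOff fitted deformation at stimulus end.
#' @slot fitRMSE root-mean-square residual over both phases.
#' @slot tOn,tOff s, stimulus timing.
#' @slot flat TRUE when the response amplitude is indistinguishable from
#'   baseline noise (fit values then carry no meaning).
#' @exportClass KelvinVoigtParams
setClass("KelvinVoigtParams",
  representation(E = "numeric", tauC = "numeric", tauR = "numeric",
                 etaCreep = "numeric", etaRelax = "numeric",
                 amplitude = "numeric", epsAtOff = "numeric",
                 fitRMSE = "numeric", tOn = "numeric", tOff = "numeric",
                 flat = "logical"))

setValidity("KelvinVoigtParams", function(object) {
  if (!object@flat && (object@tauC <= 0 || object@tauR <= 0))
    return("tauC and tauR must be positive")
  TRUE
})

#' Temperature-sensitive dye calibration
#'
#' Linear model of relative intensity versus temperature change:
#' I/I_ref = 1 - slope * dT, optionally after a multiplicative
#' thermophoretic correction of the raw intensity.
#'
#' @slot referenceTemperature degC at which I_ref was taken.
#' @slot slope fractional intensity decrease per degC (mCherry ~0.013).
#' @slot correction multiplicative thermophoretic correction factor.
#' @slot thermosensitive FALSE when the calibration data show no
#'   temperature dependence.
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  representation(referenceTemperature = "numeric", slope = "numeric",
                 correction = "numeric", thermosensitive = "logical"))

setValidity("CalibrationCurve", function(object) {
  if (object@correction <= 0) return("correction must be > 0")
  if (object@slope < 0) return("slope must be >= 0")
  TRUE
})

#' Fitted spatial temperature profile
#'
#' Smooth model of temperature versus distance perpendicular to the heating
#' scan line; the gradient is the analytic derivative of the fitted model,
#' never of the raw samples.
#'
#' @slot positions um, strictly increasing sample positions.
#' @slot temperature degC raw samples.
#' @slot fittedParams named list of model parameters.
#' @slot predictFn function(x) -> fitted temperature.
#' @slot gradientFn function(x) -> dT/dx (degC/um) of the fitted model.
#' @slot gradient degC/um at each sample position.
#' @slot model "exp2" (two-sided exponential) or "spline".
#' @exportClass TemperatureProfile
setClass("TemperatureProfile",
  representation(positions = "numeric", temperature = "numeric",
                 fittedParams = "list", predictFn = "function",
                 gradientFn = "function", gradient = "numeric",
                 model = "character"))

#' Scalar time series with stimulus timing
#'
#' @slot t s, uniformly spaced timestamps.
#' @slot value metric values (image-difference a.u., displacement um, ...).
#' @slot tOn,tOff s, stimulation window.
#' @exportClass TimeSeries
setClass("TimeSeries",
  representation(t = "numeric", value = "numeric",
                 tOn = "numeric", tOff = "numeric"))

setValidity("TimeSeries", function(object) {
  if (length(object@t) != length(object@value))
    return("t and value must have equal length")
  if (length(object@t) > 1 && any(diff(object@t) <= 0))
    return("t must be strictly increasing")
  TRUE
})

#' Radial nuclear-border profile
#'
#' Distance from the t=0 nuclear centroid to the border, per angle and
#' frame, used to quantify shape distortion during stimulation.
#'
#' @slot angles degrees, regular sampling over 360.
#' @slot r um, matrix [angle, frame]; NA where a ray found no border.
#' @slot centroid (x, y) px of the t=0 centroid.
#' @slot pixelSize um/pixel.
#' @exportClass BorderProfile
setClass("BorderProfile",
  representation(angles = "numeric", r = "matrix",
                 centroid = "numeric", pixelSize = "numeric"))

setValidity("BorderProfile", function(object) {
  if (nrow(object@r) != length(object@angles))
    return("one row of r per angle required")
  if (any(object@r[is.finite(object@r)] <= 0)) return("radii must be > 0")
  TRUE
})
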