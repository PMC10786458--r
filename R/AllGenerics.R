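# Accessor generics and show methods.

#' @describeIn ImageStack-class frame array accessor
#' @param object an object
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @export
setMethod("frames", "ImageStack", function(object) object@frames)

#' Number of frames
#' @param object an [ImageStack-class]
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @export
setMethod("nFrames", "ImageStack", function(object) dim(object@frames)[3])

#' @describeIn ImageStack-class timestamps accessor (seconds)
#' @export
setGeneric("timestamps", function(object) standardGeneric("timestamps"))
#' @export
setMethod("timestamps", "ImageStack", function(object) object@timestamps)

#' Physical pixel size (um/pixel)
#' @param object an object carrying a pixel size
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @export
setMethod("pixelSize", "ImageStack", function(object) object@pixelSize)
#' @export
setMethod("pixelSize", "DisplacementField", function(object) object@pixelSize)
#' @export
setMethod("pixelSize", "CompartmentLabels", function(object) object@pixelSize)

#' Extract one frame of a stack as a matrix
#' @param object an [ImageStack-class]
#' @param i frame index (1-based)
#' @export
setGeneric("getFrame", function(object, i) standardGeneric("getFrame"))
#' @export
setMethod("getFrame", "ImageStack", function(object, i) {
  object@frames[, , i, drop = TRUE]
})

#' Displacement components and grid accessors
#' @param object a [DisplacementField-class]
#' @export
setGeneric("uComponent", function(object) standardGeneric("uComponent"))
#' @export
setMethod("uComponent", "DisplacementField", function(object) object@u)
#' @rdname uComponent
#' @export
setGeneric("vComponent", function(object) standardGeneric("vComponent"))
#' @export
setMethod("vComponent", "DisplacementField", function(object) object@v)
#' @rdname uComponent
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @export
setMethod("validMask", "DisplacementField", function(object) object@valid)

#' Grid node spacing (px)
#' @param object a [DisplacementField-class] or [StrainField-class]
#' @export
setGeneric("gridSpacing", function(object) standardGeneric("gridSpacing"))
#' @export
setMethod("gridSpacing", "DisplacementField", function(object) {
  unique(c(diff(object@gridX), diff(object@gridY)))
})
#' @export
setMethod("gridSpacing", "StrainField", function(object) object@Lchar)

#' Strain component accessors
#' @param object a [StrainField-class]
#' @export
setGeneric("hydrostatic", function(object) standardGeneric("hydrostatic"))
#' @export
setMethod("hydrostatic", "StrainField", function(object) object@hydro)
#' @rdname hydrostatic
#' @export
setGeneric("shear", function(object) standardGeneric("shear"))
#' @export
setMethod("shear", "StrainField", function(object) object@shear)

#' Compartment accessors
#' @param object a [CompartmentLabels-class]
#' @export
setGeneric("nucleusMask", function(object) standardGeneric("nucleusMask"))
#' @export
setMethod("nucleusMask", "CompartmentLabels", function(object) object@nucleusMask)
#' @rdname nucleusMask
#' @export
setGeneric("interiorOf", function(object) standardGeneric("interiorOf"))
#' @export
setMethod("interiorOf", "CompartmentLabels", function(object) object@interiorMask)
#' @rdname nucleusMask
#' @export
setGeneric("densityLabels", function(object) standardGeneric("densityLabels"))
#' @export
setMethod("densityLabels", "CompartmentLabels", function(object) object@densityLabels)
#' @rdname nucleusMask
#' @export
setGeneric("nucleolusMask", function(object) standardGeneric("nucleolusMask"))
#' @export
setMethod("nucleolusMask", "CompartmentLabels", function(object) object@nucleolusMask)
#' @rdname nucleusMask
#' @export
setGeneric("shellLabels", function(object) standardGeneric("shellLabels"))
#' @export
setMethod("shellLabels", "CompartmentLabels", function(object) object@shellLabels)
#' @rdname nucleusMask
#' @export
setGeneric("chcMask", function(object) standardGeneric("chcMask"))
#' @export
setMethod("chcMask", "CompartmentLabels", function(object) object@chcMask)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ImageStack '%s': %d x %d px, %d frames, %.4g um/px\n",
              object@channel, d[1], d[2], d[3], object@pixelSize))
  if (d[3] > 1)
    cat(sprintf("  t = %.3g .. %.3g s (dt = %.3g s)\n",
                object@timestamps[1], object@timestamps[d[3]],
                object@timestamps[2] - object@timestamps[1]))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d px @ %.4g um/px, %d frames @ %.3g s\n",
              object@imageShape[1], object@imageShape[2], object@pixelSize,
              object@nFrames, object@frameInterval))
  cat(sprintf("  nucleus r = %.3g um; A = %.3g um, lambda = %.3g um\n",
              object@nucleusRadius, object@amplitude, object@decayLength))
  cat(sprintf("  Kelvin-Voigt tauC = %.3g s, tauR = %.3g s, stim %g-%g s\n",
              object@tauC, object@tauR, object@tOn, object@tOff))
  cat(sprintf("  nucleolus: %s; chc: %s; noise sigma = %.3g; seed = %d\n",
              if (length(object@nucleolus)) "yes" else "no",
              if (length(object@chc)) "yes" else "no",
              object@noiseSigma, object@seed))
})

setMethod("show", "DisplacementField", function(object) {
  cat(sprintf("DisplacementField: %d x %d nodes, spacing %s px, frames %d -> %d\n",
              length(object@gridY), length(object@gridX),
              paste(format(gridSpacing(object)), collapse = "/"),
              object@reference, object@target))
  cat(sprintf("  valid %.1f%%; |d| max %.3g px\n",
              100 * mean(object@valid),
              suppressWarnings(max(sqrt(object@u^2 + object@v^2), na.rm = TRUE))))
})

setMethod("show", "StrainField", function(object) {
  cat(sprintf("StrainField: %d x %d nodes, Lchar = %.3g\n",
              length(object@gridY), length(object@gridX), object@Lchar))
  cat(sprintf("  hydro in [%.3g, %.3g]; shear in [%.3g, %.3g]\n",
              min(object@hydro, na.rm = TRUE), max(object@hydro, na.rm = TRUE),
              min(object@shear, na.rm = TRUE), max(object@shear, na.rm = TRUE)))
})

setMethod("show", "CompartmentLabels", function(object) {
  cat(sprintf(paste0("CompartmentLabels: nucleus %d px, interior %d px ",
                     "(cutoff %g px)\n"),
              sum(object@nucleusMask), sum(object@interiorMask),
              object@borderCutoff))
  cat(sprintf("  density bins: %d; nucleolus %d px; shells: %d; CHC %d px\n",
              max(object@densityLabels), sum(object@nucleolusMask),
              max(object@shellLabels), sum(object@chcMask)))
})

setMethod("show", "KelvinVoigtParams", function(object) {
  if (object@flat) {
    cat("KelvinVoigtParams: flat response (no deformation detected)\n")
  } else {
    cat(sprintf("KelvinVoigtParams: tauC = %.4g s, tauR = %.4g s, E = %.4g\n",
                object@tauC, object@tauR, object@E))
    cat(sprintf("  amplitude = %.4g, eps(tOff) = %.4g, RMSE = %.3g\n",
                object@amplitude, object@epsAtOff, object@fitRMSE))
  }
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(paste0("CalibrationCurve: slope = %.4g /degC (ref %.3g degC,",
                     " correction %.3g)%s\n"),
              object@slope, object@referenceTemperature, object@correction,
              if (object@thermosensitive) "" else " [non-thermosensitive]"))
})

setMethod("show", "TemperatureProfile", function(object) {
  cat(sprintf("TemperatureProfile (%s): %d samples, x in [%.3g, %.3g] um\n",
              object@model, length(object@positions),
              min(object@positions), max(object@positions)))
  cat(sprintf("  max |dT/dx| = %.3g degC/um\n", max(abs(object@gradient))))
})

setMethod("show", "TimeSeries", function(object) {
  cat(sprintf("TimeSeries: %d samples, t in [%.3g, %.3g] s, stim %g-%g s\n",
              length(object@t), min(object@t), max(object@t),
              object@tOn, object@tOff))
})

setMethod("show", "BorderProfile", function(object) {
  cat(sprintf("BorderProfile: %d angles x %d frames, r in [%.3g, %.3g] um\n",
              nrow(object@r), ncol(object@r),
              min(object@r, na.rm = TRUE), max(object@r, na.rm = TRUE)))
})
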