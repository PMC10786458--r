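# Nuclear compartment segmentation: nucleus mask, lamina-excluded interior,
# equi-volumetric chromatin-density bins, nucleolus, perinucleolar shells
# and the central heterochromatin cluster. Morphology and thresholds are
# delegated to EBImage; distances use the Euclidean distance transform.

.ebMatrix <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

.discBrush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

#' Segment the nucleus from a chromatin frame
#'
#' Otsu threshold on the normalised intensity, morphological closing, hole
#' filling, then retention of the largest connected component.
#'
#' @param frame single-channel numeric matrix.
#' @param closingRadius radius (px) of the closing structuring element;
#'   0 disables.
#' @return logical nucleus mask.
#' @export
segmentNucleus <- function(frame, closingRadius = 2) {
  rng <- range(frame)
  if (diff(rng) <= 0) stop("segmentation failure: constant frame")
  v <- (frame - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(v))
  fg <- v > thr
  if (!any(fg)) stop("segmentation failure: empty foreground")
  if (closingRadius > 0)
    fg <- .ebMatrix(EBImage::closing(fg, .discBrush(closingRadius))) > 0
  fg <- .ebMatrix(EBImage::fillHull(fg)) > 0
  lab <- .ebMatrix(EBImage::bwlabel(fg))
  if (max(lab) == 0) stop("segmentation failure: empty foreground")
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Lamina-excluded nuclear interior
#'
#' Erodes the nucleus mask by a Euclidean disc of radius `borderCutoff`
#' pixels (default 6 px, ~0.74 um) to exclude the low displacements next
#' to the nuclear lamina.
#'
#' @param mask logical nucleus mask.
#' @param borderCutoff erosion radius in px; 0 returns the mask unchanged.
#' @return logical interior mask.
#' @export
interiorMask <- function(mask, borderCutoff = 6) {
  if (!any(mask)) stop("empty nucleus mask")
  if (borderCutoff == 0) return(mask)
  out <- .ebMatrix(EBImage::erode(mask * 1, .discBrush(borderCutoff))) > 0
  if (!any(out)) stop("border cutoff erases the whole nucleus")
  out
}

#' Equi-volumetric chromatin-density bins
#'
#' Ranks the pixels of a region by intensity (ties broken by stable pixel
#' order) and splits the rank range into `nBins` contiguous classes of
#' equal pixel count (within 1 px). Label 1 is the dimmest (lightest
#' chromatin), `nBins` the brightest (densest).
#'
#' @param intensity numeric matrix.
#' @param regionMask logical matrix selecting the region to bin.
#' @param nBins number of density classes (default 7).
#' @return integer matrix of labels, 0 outside the region.
#' @export
equivolumetricBins <- function(intensity, regionMask, nBins = 7L) {
  idx <- which(regionMask)
  n <- length(idx)
  if (n < nBins) stop("region has fewer pixels than bins")
  vals <- intensity[idx]
  if (length(unique(vals)) == 1)
    warning("constant intensity in region; binning is degenerate (tie order)")
  r <- rank(vals, ties.method = "first")
  lab <- as.integer(((r - 1) * nBins) %/% n) + 1L
  out <- matrix(0L, nrow(intensity), ncol(intensity))
  out[idx] <- lab
  out
}

#' Segment nucleoli from a nucleolar-stain frame
#'
#' Otsu threshold computed over the intensities inside the nucleus;
#' components smaller than `minArea` are discarded. Multiple nucleoli are
#' allowed.
#'
#' @param stainFrame numeric matrix (nucleolar stain channel).
#' @param nucleusMask logical matrix.
#' @param minArea minimum component area in um^2 (default 0.5).
#' @param pixelSize um/px used to convert `minArea`.
#' @return logical nucleolus mask (empty with a warning when no nucleolus
#'   is found).
#' @export
segmentNucleolus <- function(stainFrame, nucleusMask, minArea = 0.5,
                             pixelSize = 0.1233) {
  empty <- matrix(FALSE, nrow(stainFrame), ncol(stainFrame))
  vals <- stainFrame[nucleusMask]
  if (!length(vals) || diff(range(vals)) <= 0) {
    warning("no nucleolus found: stain channel carries no signal")
    return(empty)
  }
  v <- (vals - min(vals)) / diff(range(vals))
  thr <- EBImage::otsu(EBImage::Image(matrix(v, 1)))
  mask <- nucleusMask &
    (stainFrame - min(vals)) / diff(range(vals)) > thr
  lab <- .ebMatrix(EBImage::bwlabel(mask))
  minPx <- max(1L, as.integer(round(minArea / pixelSize^2)))
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts >= minPx)
  out <- matrix(lab %in% keep, nrow(stainFrame))
  if (!any(out)) warning("no nucleolus found above the minimum area")
  out
}

#' Perinucleolar chromatin shells
#'
#' Concentric annuli of `thickness` px around the nucleolus boundary,
#' computed from the Euclidean distance transform: shell k holds pixels at
#' distance ((k-1)*thickness, k*thickness] from the nucleolus border,
#' intersected with the nuclear interior and excluding the nucleolus
#' itself. The transform measures to the nearest nucleolus pixel centre,
#' which for a smooth boundary lies on average a quarter pixel inside the
#' true border; shell edges are therefore offset by 0.25 px. With the
#' default 4 px at 0.1233 um/px each shell spans ~0.5 um (PC1: 0-0.5 um,
#' PC2: 0.5-1 um, PC3: 1-1.5 um).
#'
#' @param nucleolusMask logical matrix (non-empty).
#' @param interior logical matrix, lamina-excluded nuclear interior.
#' @param thickness shell thickness in px (default 4).
#' @param nShells number of shells (default 3).
#' @return integer matrix: 0 outside, k for shell PCk.
#' @export
perinucleolarShells <- function(nucleolusMask, interior, thickness = 4,
                                nShells = 3L) {
  if (!any(nucleolusMask)) stop("empty nucleolus mask")
  d <- .ebMatrix(EBImage::distmap(1 - nucleolusMask)) - 0.25
  out <- matrix(0L, nrow(nucleolusMask), ncol(nucleolusMask))
  for (k in seq_len(nShells)) {
    sel <- d > (k - 1) * thickness & d <= k * thickness &
      interior & !nucleolusMask
    out[sel] <- k
  }
  out
}

#' Segment the central heterochromatin cluster
#'
#' Thresholds at a high intensity quantile inside the nucleus (default the
#' 85th percentile), keeps the largest connected component and fills its
#' holes.
#'
#' @param frame chromatin-channel numeric matrix.
#' @param nucleusMask logical matrix.
#' @param quantileThreshold intensity quantile defining "condensed"
#'   (default 0.85).
#' @return logical CHC mask (empty with a warning when nothing exceeds
#'   the threshold).
#' @export
segmentCHC <- function(frame, nucleusMask, quantileThreshold = 0.85) {
  vals <- frame[nucleusMask]
  thr <- stats::quantile(vals, quantileThreshold, names = FALSE)
  mask <- frame > thr & nucleusMask
  if (!any(mask) || diff(range(vals)) <= 0) {
    warning("no CHC component above threshold")
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  lab <- .ebMatrix(EBImage::bwlabel(mask))
  counts <- tabulate(lab[lab > 0])
  out <- lab == which.max(counts)
  .ebMatrix(EBImage::fillHull(out)) > 0
}

#' Full compartment label object
#'
#' Convenience constructor running the whole segmentation stack on one
#' chromatin frame (plus optional stain frame): nucleus, interior,
#' equi-volumetric density bins (nucleolus excluded), nucleolus, shells
#' and optionally the CHC.
#'
#' @param frame chromatin frame (numeric matrix).
#' @param stainFrame optional nucleolar-stain frame.
#' @param pixelSize um/px.
#' @param borderCutoff px eroded off the border (default 6).
#' @param nBins density classes (default 7).
#' @param shellThickness px per perinucleolar shell (default 4).
#' @param nShells number of shells (default 3).
#' @param detectCHC also segment the central heterochromatin cluster.
#' @param nucleusMaskOverride optional precomputed nucleus mask.
#' @return a [CompartmentLabels-class].
#' @export
compartmentLabels <- function(frame, stainFrame = NULL, pixelSize = 0.1233,
                              borderCutoff = 6, nBins = 7L,
                              shellThickness = 4, nShells = 3L,
                              detectCHC = FALSE,
                              nucleusMaskOverride = NULL) {
  nuc <- if (is.null(nucleusMaskOverride)) segmentNucleus(frame) else
    nucleusMaskOverride
  interior <- interiorMask(nuc, borderCutoff)
  nll <- if (is.null(stainFrame)) {
    matrix(FALSE, nrow(frame), ncol(frame))
  } else {
    segmentNucleolus(stainFrame, nuc, pixelSize = pixelSize)
  }
  bins <- equivolumetricBins(frame, interior & !nll, nBins)
  shells <- if (any(nll)) {
    perinucleolarShells(nll, interior, shellThickness, nShells)
  } else {
    matrix(0L, nrow(frame), ncol(frame))
  }
  chc <- if (detectCHC) segmentCHC(frame, nuc) else
    matrix(FALSE, nrow(frame), ncol(frame))
  new("CompartmentLabels", nucleusMask = nuc, interiorMask = interior,
      densityLabels = bins, nucleolusMask = nll, shellLabels = shells,
      chcMask = chc, borderCutoff = borderCutoff,
      shellThickness = shellThickness, pixelSize = pixelSize)
}
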