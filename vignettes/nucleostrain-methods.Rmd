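---
title: "Methods: chromatin displacement, strain and viscoelasticity from time-lapse stacks"
author: "nucleostrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin displacement, strain and viscoelasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleostrain)
```

# The measurement problem

A line-scanned infrared laser creates a steep, localized temperature
gradient next to a cell nucleus. The gradient displaces chromatin by
hundreds of nanometers to a few microns while the stiff nuclear lamina
keeps the nuclear outline essentially fixed (border distortions stay
below ~200 nm). Because the deformation is gentle, reversible and
spatially graded, tracking it quantifies the mechanics of nuclear
sub-compartments without injecting probe particles. The recording
protocol is 4 frames/s for 60 s: 20 s baseline, 10 s stimulation,
30 s recovery; the default pixel size is 0.1233 µm/px, inferred from the
stated 6 px ≈ 0.74 µm border cutoff (the alternative 0.125 µm/px implied
by 4 px ≈ 0.5 µm shells differs by 1.4 % and is configurable everywhere).

This vignette describes the models implemented in the package, the
parameters that matter, the synthetic phantom used to validate every
stage, and the numerical and design choices that were genuinely open.

# Thermometry

Temperature-sensitive dyes lose quantum efficiency with heat; for
mCherry the relative intensity falls ~1.3 % per °C. `calibrateDye()` fits
I/I_ref = 1 − slope·ΔT by ordinary least squares (reference = the lowest
calibration temperature); a span below 0.5 °C is rejected as
ill-conditioned. Rhodamine chamber measurements additionally suffer
thermophoresis (concentration depletion, not quantum yield), handled as a
single multiplicative correction supplied with the calibration — its
magnitude is experiment-specific and the package deliberately ships no
default other than 1.

Spatial profiles T(x) perpendicular to the scan line are fitted with a
two-sided exponential T₀ + B·e^(−|x−x₀|/ℓ) about the known line position
x₀ (the scan-line position is part of the experiment geometry, so it is a
fixed argument, not a free parameter — with one-sided data a free x₀ is
scale-degenerate). A smoothing spline replaces the exponential whenever
it achieves a lower RSS-based AIC (n·log(RSS/n) + 2k with k = 3 for the
exponential and the spline's effective degrees of freedom otherwise).
Gradients are always the analytic derivative of the fitted model, never
finite differences of raw data — that is what makes ~1 °C/µm gradients
recoverable from noisy samples. `windowAverage()` integrates the fitted
model over a 20 µm window, the typical nuclear length, so chamber and
intra-nuclear thermometry can be compared directly.

The thermal-expansion bound contextualises all of this:
with water's volumetric expansion coefficient 3.5×10⁻⁴/°C and the ~2 °C
average nuclear heating, passive expansion is at most 0.07 % — far below
the measured chromatin strains, which therefore cannot be a trivial
volumetric artifact (`thermalExpansionBound()`).

# Displacement by multi-pass PIV

`multipassPIV()` correlates interrogation windows of the reference
(t = 0) frame with the corresponding windows of each later frame —
cumulative referencing, not frame-to-frame chaining, so errors do not
accumulate along the sequence. The printed acquisition parameters are a
32 px window at 75 % overlap with a final 4×4 px vector grid; a 4 px grid
at 75 % overlap is only attainable with a 16 px final window, so the
default pass schedule is [32, 16] px — the second pass re-interrogates
with integer window offsets taken from the (filtered, interpolated) first
pass.

Numerical choices in the correlation core:

- patches are mean-subtracted and correlated by zero-padded FFT (linear,
  not circular, correlation) and the plane is normalised by the overlap
  area of each shift. Circular correlation is cheaper but its wrap-around
  aliases bias the sub-pixel estimate by ~0.1 px on textures whose grain
  approaches the window size; the zero-padded form keeps the bias below
  0.03 px (the suite's sub-pixel sweep asserts |bias| < 0.05 px and
  RMSE < 0.15 px on noise-free shifts in [−1, 1] px);
- the peak search is restricted to |shift| ≤ window/4; the integer peak
  is refined independently in x and y by the 3-point Gaussian estimator,
  with a parabolic fallback when a neighbour is non-positive;
- the signal-to-noise ratio is peak over the highest non-adjacent
  secondary peak; vectors with SNR < 1.3 are discarded;
- a constant reference patch has no correlation structure; such vectors
  are marked invalid rather than guessed.

Outlier handling (`filterOutliers()`) applies a global filter (component
further than 3 SD from the field mean), then a local filter (deviation
from the 3×3 neighbourhood median beyond 2.5× the neighbourhood median
absolute deviation, floored at 0.1 px so that perfectly uniform fields are
not flagged). Invalidated vectors are replaced by the iterated
neighbourhood median but stay flagged, so downstream statistics can
distinguish measured from interpolated vectors. The filter thresholds are
conventions — the source analysis names "local and global filters"
without parameters — and are exposed in `pivConfig()`.

Coordinates follow image convention: origin top-left, x = column (u),
y = row (v), y increasing downward; grid nodes sit at window centres.
Windows covering the nucleus mask by less than half are masked out in
`displacementSequence()`. Windows that straddle the nuclear border mix
moving chromatin with the static lamina edge and bias toward zero — the
same reason the compartment analysis erodes 6 px off the border before
averaging anything.

# Strain

With u, v on a regular grid of spacing L_char (the characteristic initial
length before deformation), `strainFromDisplacement()` forms central
differences across adjacent nodes (one-sided at edges), normalised by
L_char, and combines them as

- hydrostatic strain ε_hydro = (∂u/∂x + ∂v/∂y)/2 — the mean normal
  strain, local volume change (positive = extension);
- shear strain ε_shear = ∂u/∂y + ∂v/∂x — the engineering (unhalved)
  shear.

The printed expressions are dimensionally consistent exactly when the raw
node-to-node displacement differences are divided by L_char, which equals
standard infinitesimal strain with physical-unit derivatives; the /2
belongs to the hydrostatic sum only. Whether the source intended the
tensor convention (an extra ½ on shear) cannot be determined from the
printed formula; the literal engineering reading is implemented and the
factor is trivial to apply downstream if desired. Strains are
dimensionless (1 = 100 %). No smoothing is applied — none is described —
and central differences are preferred over one-sided ones for
second-order accuracy. `upsampleToImage()` interpolates node values
bilinearly to pixel resolution with nearest-value extrapolation inside
the mask beyond the grid hull, so label masks can be applied per pixel.

Two invariants anchor the implementation: strains vanish identically for
rigid translations, and a divergence-free field (u = ∂ψ/∂y, v = −∂ψ/∂x)
has mean total hydrostatic strain < 10⁻³ across the grid — the discrete
analogue of volume conservation, mirroring the near-zero whole-nucleus
total observed experimentally.

# Compartments

`segmentNucleus()` is Otsu thresholding with morphological closing, hole
filling and retention of the largest connected component.
`interiorMask()` erodes by a Euclidean disc of 6 px (~0.74 µm) to exclude
lamina-proximal pixels. `equivolumetricBins()` ranks interior pixels by
chromatin intensity and cuts the rank range into seven equal-count
classes; ties are broken by stable pixel order, which makes binning
deterministic without a seed. Nucleoli (detected by Otsu inside the
nucleus on the live-stain channel, minimum area 0.5 µm²) are excluded
from the density classes before binning — nucleoli are chromatin-void, so
letting their dark pixels occupy C1 would dilute the lightest chromatin
class; whether the source binned before or after exclusion is unstated,
and exclusion-first is the implemented reading.

Perinucleolar shells PC1–PC3 are 4 px (~0.5 µm) annuli from the Euclidean
distance transform around the nucleolus. The transform measures to the
nearest nucleolus pixel centre, which for a smooth boundary lies on
average a quarter pixel inside the true border, so shell edges are offset
by 0.25 px; on a disc of radius 20 px this reproduces the analytic
annulus area to a fraction of a percent instead of 7 %. The CHC of
inverted nuclei is segmented at the 85th intensity percentile within the
nucleus (the threshold is a convention; none is printed), largest
component, holes filled.

# Kinetics and the Kelvin-Voigt model

The mean absolute image difference |I_t − I₀| over the nucleus
(`imageDifferenceSeries()`) rises when chromatin leaves its initial
configuration and falls as it returns. The absolute value is deliberate:
a signed mean would cancel bidirectional intensity changes and contradict
the positive, creep-shaped curves the measurement produces.

`fitKelvinVoigt()` fits the two phases independently after subtracting
the 20 s pre-stimulus baseline:

- creep (t_on ≤ t ≤ t_off, origin t_on): ε(t) = (1/E)(1 − e^(−t/τ_c));
- relaxation (t > t_off, origin t_off): ε(t) = ε(t₁)·e^(−t/τ_r), with the
  amplitude fixed at the creep endpoint ε(t₁) implied by the creep fit —
  the model's own prediction, which also removes an amplitude/τ
  degeneracy at small τ.

Fits are nonlinear least squares (Levenberg–Marquardt) with multi-start
over τ ∈ {0.1, 1, 10} s. Independent phase fits are essential: creep and
relaxation times genuinely differ (0.74 s vs 0.92 s for the CHC), so a
single-τ constraint is not imposed. A response whose creep amplitude does
not exceed three baseline noise SDs is flagged `flat` rather than fitted.

How well can τ be recovered at 4 frames/s? The Cramér–Rao bound for the
creep fit with 5 % noise gives a median relative error of ~8 % at
τ = 0.2 s (the response saturates within a few samples) and ~6 % at
τ = 5 s (the 10 s window truncates the plateau, so amplitude and τ become
degenerate), but well under 5 % for τ ∈ [0.5, 2] s — comfortably covering
the observed ~1 s time scale. The test suite asserts that the estimator
stays within 1.6× of this information limit across τ ∈ [0.2, 5] s; no
estimator can do fundamentally better under the same sampling and noise.

Feature tracking (`trackFeatures()`) thresholds dark (chromatin-void,
e.g. nucleoli) or bright (condensed, e.g. CHC) features by intensity
quantile, measures intensity-weighted centroids and second-moment ellipse
axes, and links detections by nearest neighbour within a 1 µm gate —
feature density is low, so no probabilistic tracker is warranted;
ambiguous links split the track with a warning. `kymograph()` samples
intensity bilinearly along a fixed line per frame. `borderProfile()`
casts rays from the t = 0 centroid and records the outermost sub-pixel
mask crossing per angle, giving the border-rigidity statistic
max|r(θ,t) − r(θ,0)|. `fiberStrain()` converts CHC centroid displacement
since stimulus onset into fiber strain ΔL/L₀ with L₀ = 3 µm, the measured
rest length of the radial fibers; displacement is referenced to the onset
frame (not frame 0 — the pre-stimulus baseline contains no extension).

# Compartment statistics

`compartmentStrainStats()` averages a per-pixel strain map over each
density class and the nucleolus, at peak deformation (the last
stimulation frame, t_on + 10 s). The absolute mode averages |ε| —
extension and compression add up; the total mode averages signed ε — they
cancel. |total| ≤ absolute holds per compartment by the triangle
inequality, and the pixel-count-weighted mean of compartment totals
equals the whole-region total exactly. `shellDisplacementStats()` reports
mean displacement magnitude for NLL, PC1–PC3 and NUC (the whole
interior). `groupTests()` runs one-way ANOVA with Tukey HSD
(Tukey–Kramer for unequal n, p-values from the studentized-range
distribution), a two-tailed unpaired t-test for binned contrasts (e.g.
light C1–C3 vs dense C4–C7), and boxplot summaries (25–75 percentile,
whiskers over the full range after excluding |x − mean| > 3 SD).
Observations are intended to be nucleus-level means — one value per
nucleus and compartment — matching how n is reported in the source
analyses; pixel-level ANOVA would pseudo-replicate.

# The synthetic phantom

`phantomSpec()` / `renderSequence()` generate the ground-truth test bed.
The texture is white noise low-pass filtered to a 0.4 µm autocorrelation
FWHM (chromatin-scale speckle), normalised to mean 100 / SD 20 over a dim
background. The displacement field is

u(X, t) = A · e^(−d/λ) · g(t) · n̂,

pointing away from the stimulus line (d = distance to the line), with
Kelvin-Voigt time course g(t) (τ_c = 0.74 s, τ_r = 0.92 s by default) and
defaults A = 2 µm (the observed upper displacement scale) and λ = 10 µm
(the nuclear length scale; the source reports only that displacement
decreases away from the stimulus, so the exponential is the simplest
monotone choice that keeps strain analytic). Optional inclusions:

- an **immobile nucleolus** nulls the field inside its disc with a linear
  coupling ramp to the far field (adhesion of perinucleolar chromatin to
  the nucleolar interface);
- a **mobile nucleolus** simply advects with the field;
- a **rigid CHC** translates as a solid body, blended into the
  surrounding field over a 1 µm ramp — a hard discontinuity at the disc
  edge would be unphysical and renders a garbled edge under backward
  warping.

The displacement convention is forward/Lagrangian: u(X, t) is the motion
of the material point at t = 0 position X. Rendering inverts
X + u(X) = x per pixel by fixed-point iteration (the field gradients are
≪ 1, so a handful of iterations converge) and samples the t = 0 texture
by backward mapping with Catmull–Rom bicubic interpolation — forward
splatting would leave holes. The nucleus envelope is applied *after*
warping: the lamina is static, chromatin slides beneath it, which renders
a static border (< 200 nm deviation in the suite) and reproduces the
motivation for the 6 px border cutoff. Camera noise (Gaussian read noise,
optional Poisson shot noise; Gaussian-only by default since the camera
statistics are unreported) is added last, seeded, so identical specs
render bit-identically.

`groundTruth()` closes over the same spec and returns the displacement
and its analytic strain (product rule across the line field and both
coupling ramps), verified against central finite differences at random
points to 10⁻³.

What the phantom does **not** emulate: the optical PSF, photobleaching,
3-D sectioning, intensity-dependent noise correlations, and any actual
thermophysics of the temperature field. Passing the suite therefore
certifies the *analysis chain* — PIV accuracy, strain algebra,
segmentation geometry, fit consistency, statistical ordering — on imagery
with known truth, not the biological conclusions drawn from real
recordings.

# Problem sizes and fixtures

The test fixtures are scaled for exactness, not realism of size: 128 px
phantoms (≈ 16 µm field) with 2–61 frames, chosen so that each property
is sharp — e.g. the PIV ground-truth comparison uses a two-frame phantom
at peak deformation with vectors restricted to windows a half-window
clear of the static border; the pipeline round trip uses a 25-frame,
2.5 s-interval phantom with slow generator time constants (τ_c = 5 s)
matched to that sampling and a small amplitude (0.02 µm) that keeps the
image-difference response in its linear regime, because mean |ΔI| is
proportional to displacement only to first order. The immobile-nucleolus
fixture places the nucleolus on the far side of the stimulus so the
perinucleolar displacement gradient terminates below the nuclear average,
and the mobile-nucleolus fixture centres it where the local field matches
that average. The acceptance script re-runs the grid-geometry check at
the full 256×256 frame size.

# Known limitations

- PIV vectors within half a window of the nuclear border mix static and
  moving content; they are flagged by mask coverage, but quantitative
  work should erode at least the 6 px rim, as the compartment statistics
  do.
- The equi-volumetric bins assume the chromatin reporter intensity is a
  monotone proxy of density; no attempt is made to calibrate absolute
  density.
- Kelvin-Voigt is the minimal viscoelastic model consistent with the
  creep/recovery shape; power-law or generalized Maxwell rheology is out
  of scope, as are MSD-based passive microrheology and 3-D strain.
- τ estimates at the edges of the practical range (≲ 0.3 s or ≳ 5 s at
  4 frames/s and 10 s stimulation) carry the irreducible uncertainty
  quantified by the Cramér–Rao analysis above.
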