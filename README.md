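# nucleostrain

Probe-free mapping of chromatin deformation inside living cell nuclei from
fluorescence time-lapse microscopy.

Highly localized temperature gradients (an IR laser scanned along a line
next to the nucleus) displace chromatin by hundreds of nanometers to a few
microns without deforming the stiff nuclear lamina. Recording a
fluorescent chromatin reporter (H2b) at 4 frames/s through a
20 s baseline / 10 s stimulation / 30 s recovery protocol turns every
nucleus into a rheology experiment: where chromatin moves, how much it is
compressed or sheared, and how fast it creeps and recovers report the
material properties of its compartments. `nucleostrain` implements the
complete analysis chain:

- **thermometry** — temperature-sensitive dye calibration
  (mCherry quantum efficiency falls ~1.3 %/°C), intensity-to-temperature
  conversion, smooth spatial profile fits with analytic, noise-robust
  gradients, and 20 µm window averages over the nuclear length scale;
- **piv** — dense intra-nuclear displacement fields by multi-pass windowed
  cross-correlation against the undeformed t = 0 frame (32 px windows,
  75 % overlap, final 4×4 px vector grid), with sub-pixel 3-point Gaussian
  peak refinement and global/local outlier filters;
- **strain** — hydrostatic and shear strain maps from the vector grid:
  ε_hydro = (∂u/∂x + ∂v/∂y)/2, ε_shear = ∂u/∂y + ∂v/∂x, derivatives
  normalised by the characteristic initial length L_char (the node
  spacing), upsampled to pixel resolution;
- **compartments** — nucleus segmentation, exclusion of a 6 px (~0.74 µm)
  lamina-proximal rim, seven equi-volumetric chromatin-density classes
  C1 (lightest) … C7 (densest) by intensity rank, nucleolus detection from
  a live-stain channel, perinucleolar shells PC1–PC3 of 4 px (~0.5 µm)
  each, and the central heterochromatin cluster (CHC) of genetically
  inverted nuclei;
- **kinetics** — image-difference time series, Kelvin-Voigt viscoelastic
  fits (creep ε(t) = (1/E)(1 − e^(−t/τ_c)), recovery
  ε(t) = ε(t₁)·e^(−t/τ_r), τ = η/E), feature and CHC tracking, kymographs,
  radial border-rigidity profiles, and fiber-strain estimates
  ΔL/L₀ with L₀ ≈ 3 µm;
- **stats** — per-compartment strain statistics (absolute |ε| versus
  signed totals), shell displacement tables (NLL, PC1–PC3, NUC), one-way
  ANOVA with Tukey HSD, binned two-tailed t-tests, and boxplot summaries
  with a 3×SD outlier rule;
- **phantom** — a synthetic nucleus generator with chromatin-like
  band-limited texture warped by an analytic displacement field
  (exponential decay from the stimulus line, Kelvin-Voigt time course,
  optional immobile/mobile nucleoli, a rigid CHC, a static nuclear border,
  camera noise) that provides exact ground truth — displacement and
  analytic strain closures — for every stage.

## Worked example

Render a synthetic nucleus undergoing the stimulation protocol and run the
full pipeline on it:

```r
library(nucleostrain)

spec <- phantomSpec(imageShape = c(96L, 96L), nFrames = 25L,
                    frameInterval = 2.5, amplitude = 0.6,
                    nucleusRadius = 5, noiseSigma = 2, seed = 5)
spec
#> PhantomSpec: 96 x 96 px @ 0.1233 um/px, 25 frames @ 2.5 s
#>   nucleus r = 5 um; A = 0.6 um, lambda = 10 um
#>   Kelvin-Voigt tauC = 0.74 s, tauR = 0.92 s, stim 20-30 s
#>   nucleolus: no; chc: no; noise sigma = 2; seed = 5

phantom <- renderSequence(spec)
res <- runPipeline(runConfig(stack = phantom$stack, frameInterval = 2.5))

res$fields[[12]]             # displacement field at peak deformation (t = 30 s)
#> DisplacementField: 21 x 21 nodes, spacing 4 px, frames 0 -> 12
#>   valid 51.5%; |d| max 3.69 px

res$compartmentAbsolute      # mean |hydrostatic strain| per density class
#>   compartment      value nPixels     mode
#> 1          C1 0.01674613     525 absolute
#> 2          C2 0.01654871     525 absolute
#> ...
#> 7          C7 0.01552972     524 absolute
```

The vector grid has the expected 4 px spacing; the peak displacement of
3.7 px ≈ 0.45 µm reflects the 0.6 µm stimulus amplitude attenuated by the
exponential decay across the nucleus, and each density class holds the
same number of pixels (equi-volumetric binning). Absolute hydrostatic
strains of ~1.6 % are typical for this gentle phantom.

Viscoelastic parameters are recovered exactly from clean creep/recovery
traces sampled at the acquisition rate (4 frames/s):

```r
t <- seq(0, 60, by = 0.25)
trace <- kelvinVoigtResponse(t, tauC = 0.74, tauR = 0.92)
fitKelvinVoigt(timeSeries(t, trace))
#> KelvinVoigtParams: tauC = 0.74 s, tauR = 0.92 s, E = 1
#>   amplitude = 1, eps(tOff) = 1, RMSE = 0
```

In the pipeline example above the fitted times (0.59 s / 0.81 s) are
biased low: the image-difference response is only approximately linear in
the displacement at this large amplitude, and 2.5 s frames undersample
sub-second kinetics — quantitative τ estimates require the full 4 frames/s
protocol. See the methods vignette (`vignettes/nucleostrain-methods.Rmd`)
for the model, parameter and calibration details.

A thin command-line wrapper is installed with the package
(`inst/scripts/nucleostrain`): `nucleostrain run --config run.yaml`
executes the pipeline on a TIFF stack, `nucleostrain phantom --out dir`
renders the default phantom with its ground truth.

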