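---
title: "Optimising inline phase-contrast microtomography on simulated soft tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimising inline phase-contrast microtomography on simulated soft tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(phasetomo)
```

## The problem

Synchrotron X-ray microtomography of soft tissue is a chain of coupled
choices: how many projections to record, how far to place the detector
behind the sample (the propagation distance, PD, which controls inline
phase contrast), how aggressively to phase-retrieve, and which acquisition
artefacts to correct before reconstruction. Each choice trades image
quality against dose, scan time or quantitative fidelity, and on a real
beamline they can only be screened with precious sample and beam time.

`phasetomo` rebuilds that whole decision chain on the desk. A digital
phantom of an iodine-stained spinal cord in paraffin wax is imaged by a
physical forward model (parallel-beam projection, Fresnel propagation,
photon statistics, injectable artefacts), pushed through the standard
correction and reconstruction chain, and scored with the same image-quality
metrics used at the beamline. Because the phantom is ground truth, every
correction and every parameter choice can be validated against what the
sample actually contains.

## Physical model

The sample is described by per-voxel complex refractive index
$n = 1 - \delta + i\beta$: phase shift scales with $\delta$, absorption
with $\beta$ (attenuation coefficient $\mu = 4\pi\beta/\lambda$). A
monochromatic 25 keV beam is assumed ($\lambda = hc/E$ with
$hc = 1.239842\times10^{-9}$ keV·m); the real pink beam this emulates has
its peak there, and all closed-form planning in the field is done at the
peak energy anyway.

For each projection angle the thin-object exit wave is
$\psi_0(u) = e^{-(2\pi/\lambda)B(u)}\,e^{-i(2\pi/\lambda)D(u)}$, with $B$
and $D$ the line integrals of $\beta$ and $\delta$. Free-space propagation
over distance $z$ applies the 1-D angular-spectrum kernel
$e^{-i\pi\lambda z f^2}$ (edge-replicated padding to twice the width
suppresses wrap-around); the detector records
$|\psi_z|^2$ scaled to counts, Poisson-sampled, and clipped at a 16-bit
full well. Flat fields sit at 85 % of the full well, mirroring the usual
exposure choice.

Three artefact generators are available, each with recorded ground truth:

* **zingers** — short bright streaks from stray X-rays, injected at a
  configurable rate per tomographic slice (default 20);
* **ring seeds** — fixed-pattern pixel-gain errors multiplied into the
  sample frames but *not* into the recorded flats. This detail matters: a
  gain defect present identically in flats and frames cancels exactly
  under flat/dark normalisation and can never produce rings, so the
  generator emulates defects the flats fail to capture (the situation that
  actually produces rings);
* **radial lens distortion** — $r' = r(1 + k_1 r^2 + k_2 r^4)$ about a
  configurable centre, applied by resampling.

## Planning rules

The planner collects the closed forms a scan is designed with:

```{r plan}
beam <- beam_spec(25)
max_propagation_distance(3.2, beam)    # Fresnel bound a^2 / lambda, mm
min_resolvable_feature(160, beam)      # its inverse, um
nyquist_projection_count(2560)         # width * pi/2, angular sampling
plan_tiled_scan(100, 3.5, 0.02)        # scans to tile a 10 cm sample
```

The Fresnel-regime bound $PD \le a^2/\lambda$ gives the largest propagation
distance at which edge fringes still enhance, rather than obscure, features
of diameter $a$. The angular rule rounds $\text{width}\times\pi/2$ to the
nearest integer, matching how the counts are quoted in practice (4021 for
2560 px). The tiled-scan estimate interprets the overlap as a fraction of
the field of view lost at each junction and rounds partial tiles up.

## The phantom

`make_cord_phantom()` builds a 2-D slice: an embedding cylinder (wax by
default) out to 0.49 of the grid, a white-matter disc of radius 0.30 of the
grid, a mirror-symmetric grey-matter butterfly whose $\beta$ exceeds white
matter by the `stain_contrast` factor (default 2, emulating Lugol's-iodine
uptake), dark vessels of 2–8 px diameter, and brighter ~15 px somata
confined to grey matter. The 0.30/0.49 proportions keep the embedding
sleeve at least 3/8 of the grid radius thick, so the beam never crosses an
embedding/air interface inside the field of view (the same reason real
samples are centred in 3 mm of medium). `make_wire_phantom()` builds the
wire-standard object (seven copper pieces in insulation) used for
embedding-medium comparisons.

Material $(\delta, \beta)$ defaults are plausible 25 keV soft-tissue and
embedding values, constrained by two observables rather than taken from
tables: the absorption ordering air < wax ≤ epoxy < agar < tissue <
stained tissue, and ~30 % absorption through 3 mm of wax. They live in
`material_table()` and are overridable; nothing in the physics code
hard-codes them. Structure edges are rasterised with area-weighted
coverage, so a "2 px vessel" is meaningful even off the pixel grid;
the corollary is that boundary voxels blend two materials and only
interior voxels carry a material's constants exactly.

Everything random is seeded, and a phantom is a pure function of its
arguments: identical calls give byte-identical maps.

## Corrections

The pre-reconstruction chain runs in the fixed order zingers → flat/dark →
undistort → ring suppression, and records what it did:

* **Zingers** are detected per frame against a 3×3 median with a robust
  (MAD-based) noise scale and an 8σ default threshold, and replaced by the
  local median. Only bright excursions are touched.
* **Flat/dark** is the exact algebraic normalisation
  $T = (F - d)/(f - d)$, floored at $10^{-6}$ so logarithms stay finite.
* **Undistortion** inverts the radial model by fixed-point iteration to
  $10^{-3}$ px. The distortion *centre* (which shifts whenever the
  microscope turret rotates) is estimated computationally: the 180°
  check projection is mirrored, aligned once by integer cross-correlation,
  and candidate centres are screened coarse-to-fine for the one whose
  correction minimises the 0°/180° mean squared difference. Two details
  proved essential and are worth recording. First, the alignment must be
  estimated once, from the initial-guess correction — re-aligning per
  candidate absorbs most of the centre signal into the shift. Second, both
  frames are Gaussian pre-smoothed (σ = 2 px) before scoring, because the
  double-resampling interpolation error of sharp edges otherwise biases
  the score landscape by more than the centre signal itself.
* **Ring suppression** estimates the angle-invariant column bias as the
  column mean over angles minus a *running-median* smoothing of that
  profile, and subtracts it from every row. The median reference passes
  monotone structure (sample edges, tangent kinks) through unchanged while
  removing narrow static stripes. Known limitation: any feature that is
  genuinely static in detector coordinates — e.g. the quasi-static tangent
  bumps that small vessels leave in the angular mean, or phase-contrast
  fringes of a perfectly centred object — is partially treated as a ring.
  This is inherent to all column-bias ring removal, not to this
  implementation.

## Retrieval and reconstruction

Paganin single-distance retrieval divides the transmission spectrum by
$1 + \frac{\lambda z (\delta/\beta)}{4\pi}|k|^2$ ($|k|$ in rad/m) and takes
$-\log$; ratio 0 reduces exactly to the absorption logarithm. The output is
left proportional to thickness times attenuation — only ratios matter for
the screening studies. The retrieval pixel size defaults to 1.6125 µm and
the geometric pixel to 1.625 µm; both appear in beamline practice and both
are configuration-visible.

FBP uses the band-limited (Ram-Lak) ramp built in the spatial domain (so
the finite DC term is handled correctly), optional Hann apodisation,
power-of-two zero padding, linear-interpolation backprojection, and the
$\pi/(2 n_\text{angles})$ scaling that returns a line-integral sinogram to
the map's own units. On a noiseless absorption scan the reconstruction
recovers $4\pi\beta/\lambda$ within 5 % RMSE in compartment interiors; on
an analytic disc the interior mean is recovered to 0.03 %.

Projection subsets for the downsampling study are strict evenly-spaced
divisors of the full count, so subset angle sets remain equally spaced; a
non-divisor request is rejected naming the nearest valid sizes. The 180°
check frame is never used in reconstruction.

## The screening studies and what they show

The reference study conditions are a 512×512 cord phantom (1.625 µm
voxels), 160 mm PD, 1440 projections, Poisson noise at the 85 % flat
level, no injected artefacts. The sizes are a deliberate desk-scale
reduction of beamline practice (2560-wide detectors, 24 000-projection
scans): they preserve the governing ratios — the largest subset sits just
below the angular Nyquist count (804 for 512 px), as 24 000-projection
studies put their useful subsets around theirs — while keeping the full
acceptance suite inside a few CPU-minutes.

* **Projection number.** The study reconstructs the full scan as the
  reference and each subset {720, 360, 180, 90, 45} against it. PSNR (in its
  summed-squared-error form, see below) increases monotonically with
  subset size by several dB per doubling. RMS contrast, computed on each
  individually min-max-normalised slice cropped to the ROI, rises and
  saturates early: the final 360→720 step moves it by only a few percent
  of the curve's range. The downsampling reconstructions use the optimised
  protocol — Paganin retrieval at the ratio the δ/β screen selects —
  matching how the full-pipeline projection study is actually run once
  retrieval is tuned. Without retrieval, edge-fringe streaks keep
  evolving right up to the Nyquist count and the saturation is much
  weaker; with over-strong retrieval (ratio ≥ 300) noise is crushed so
  hard that contrast keeps creeping instead. Under mild noise the
  normalised RMS approaches its plateau from above (noise inflates the
  ROI standard deviation more than the slice range); heavily
  under-sampled beamline data approach it from below because streak
  extremes inflate the normalisation range. The invariant checked is the
  saturation itself — the vanishing last step — not the approach
  direction.
* **δ/β ratio.** Screening the standard grid {1 … 3000} at fixed PD shows
  an interior maximum of normalised RMS contrast (at 100 under the default
  materials, whose true tissue δ/β is ~400 for white matter and ~130 for
  stained grey matter): under-filtering leaves fringe and noise extremes
  that stretch the normalisation range, over-filtering blurs structure
  away. Retrieval also splits the grey-level histogram into clean
  background and sample modes, which `histogram_peaks()` locates — with a
  Poisson-significance test on the inter-mode dip so that flat histograms
  are flagged unimodal rather than guessed at.
* **Propagation distance.** Simulating the same phantom at
  {20, 40, 80, 160, 320} mm with a common seed shows RMS contrast and the
  edge-overshoot score (mean excursion of reconstructed values beyond the
  ROI's true attenuation range) both increasing monotonically with PD —
  the fringe-enhancement/fidelity trade-off that makes the Fresnel bound
  the right planning tool. The PD sweep evaluates RMS on the raw
  (unnormalised) reconstructions: all five share one attenuation scale,
  and normalising each slice would fold the growing overshoot into the
  denominator and conflate the two effects. Screening runs at 720
  projections, mirroring the reduced-projection screening scans used in
  practice.

## Metric definitions

PSNR is implemented in its summed-squared-error form,
$10\log_{10}\!\left[\max(t)^2 / \sum (t-n)^2\right]$, deliberately *not*
normalising by pixel count: this reproduces the form the screening
methodology defines, and absolute dB values are therefore offset by
$10\log_{10} N$ from the textbook MSE form (available behind
`normalise = "mse"`). Only curve shapes and differences are interpreted.
RMS contrast is the sample standard deviation over the ROI (the $n-1$
denominator as defined). Slice normalisation for the contrast studies is
min-max over the whole slice, then ROI cropping — the slice-wide range is
anchored by the stable air/tissue span, so the statistic is not dominated
by whatever extremes the crop happens to contain. `saturation_fraction()`
reports a curve's position as a fraction of its observed dynamic range,
baselined at the smallest parameter value, because "percent saturation"
is otherwise undefined for curves that diverge at their own reference
point.

## Segmentation check

Vasculature is segmented by grey-level thresholding inside the cord mask
of a retrieved reconstruction (δ/β = 5 — mild retrieval preserving
2–3 px features, inside the 1–10 band where fine detail survives), with
the cutoff at the midpoint of the reconstructed vessel and white-matter
means. Against the phantom truth this recovers ≥ 80 % of vessel pixels of
diameter ≥ 3 px with Dice ≥ 0.7; 2 px vessels sit at the resolution limit
and are excluded from the recovery target, exactly as sub-2-pixel
capillaries are not expected to segment at the beamline.

## What passing these tests does and does not show

The simulation reproduces the *mechanisms* behind the optimisation
methodology: angular undersampling, photon statistics, Fresnel edge
enhancement, retrieval blur, fixed-pattern rings, zingers and lens
distortion. It deliberately omits partial coherence and source-size blur,
scintillator point spread, beam polychromaticity, sample drift and
deformation, stain-diffusion chemistry and tissue shrinkage. Passing the
property suite therefore shows the pipeline's internal consistency and
its agreement with the physics it models — not that any particular
parameter value (an optimal δ/β of 100, say) transfers to a given real
sample, whose material contrasts set their own optimum. That is, indeed,
the point of the methodology: the screening procedures, not their
numerical outcomes, are the reusable artefact.

## Numerical choices

* Rotation axis at the centre-pixel convention $(n-1)/2$, 0-based; angles
  in degrees externally, radians internally; 0° rays run along grid rows.
* Fresnel propagation and 1-D Paganin pad by edge replication to the next
  power of two ≥ twice the width.
* Transmission floor $10^{-6}$; Paganin output floor $10^{-12}$ before the
  logarithm.
* Fixed-point undistortion tolerance $10^{-3}$ px, 50-iteration cap.
* Centre search: coarse-to-fine steps {8, 4, 2, 1} px over a ±24 px
  window, ties broken toward the frame centre (the documented behaviour
  for distortion-free scans).
* Histogram smoothing: moving average, window ≈ bins/32; modes accepted
  only if the inter-mode dip clears 5 Poisson standard errors.
* Per-frame Poisson seeds derive from the master seed plus the frame
  index, so any projection subset is reproducible in isolation.

## Reproducing the study figures

```{r study, eval = FALSE}
ph <- make_cord_phantom(grid_px = 512, seed = 11)
geom <- scan_geometry(beam_spec(25), detector_spec(512, 1, 1.625),
                      propagation_distance_mm = 160, n_projections = 1440)
pset <- simulate_scan(ph, geom, seed = 5)
r <- roi(156, 356, 156, 356)

curve <- downsampling_study(pset, c(720, 360, 180, 90, 45),
                            params = retrieval_params(100, pd_mm = 160),
                            study_roi = r)
db <- sweep_delta_beta(pset, c(1, 3, 10, 30, 100, 300, 1000, 3000),
                       study_roi = r, n_subset = 720)
pd <- sweep_propagation_distance(ph, geom, c(20, 40, 80, 160, 320), r,
                                 seed = 5)
```

`scripts/acceptance.R` runs exactly these computations from scratch at the
512 px scale and writes the headline numbers as JSON; the test suite
asserts the qualitative properties at the tolerances given above.
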