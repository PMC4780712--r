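---
title: "Scatter in dental cone-beam CT: simulation and projection-domain correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scatter in dental cone-beam CT: simulation and projection-domain correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbctscatter)
```

## The problem

Dental cone-beam CT (CBCT) irradiates a large axial volume with a single
circular orbit of a flat-panel detector. Unlike fan-beam CT, where source
collimation admits scatter only from a thin slice, the cone admits
scattered photons from the whole illuminated volume; scatter-to-primary
ratios (SPR) in CBCT can reach 0.4-2.0, versus about 0.01 for single-ray
geometries. Scatter depresses reconstructed attenuation values towards
the object center (cupping), destabilizes CT numbers and reduces
contrast-to-noise ratio (CNR).

This package implements, end to end and at desk scale, a study of that
problem for a dental CBCT geometry (source-axis distance 49.54 cm,
source-detector distance 71.4 cm, 384 x 480 detector at 0.5 mm pitch,
301 views over 360 degrees, 120 kVp):

1. a Monte Carlo photon-transport engine that labels every Compton and
   Rayleigh interaction per photon, so detected signal separates exactly
   into primary and scatter channels;
2. a characterization of ROI intensity and SPR versus the axial
   collimating-slit opening (0.5, 1, 2, 5, 10, 20 mm and uncollimated)
   for water cylinders of 10, 15 and 20 cm diameter with
   tissue-equivalent rod inserts;
3. the projection-domain correction built on that characterization: the
   intensity of each detector pixel is modelled as
   $y = a\,\ln x + b$ in the slit size $x$, fitted per pixel from two
   acquisitions with different axial fields of view (FOV, 4 cm and
   13 cm), extrapolated towards a narrow slit, low-pass filtered, and
   subtracted;
4. Feldkamp-Davis-Kress (FDK) filtered backprojection and evaluation
   (CNR, cupping index, line profiles).

## Physics model and its assumptions

**Cross sections.** Linear attenuation coefficients are generated from a
parametric per-element model: free-electron Klein-Nishina for incoherent
scattering, and power-law photoelectric
($\sigma_{pe} \propto Z^{4.38} E^{-3.07}$) and coherent
($\sigma_{coh} \propto Z^{2.5} E^{-2}$) terms whose constants are
calibrated against published NIST mass-attenuation values for water and
aluminium over 15-150 keV. Totals agree with the reference values within
about 1.4% across that range (water at 60 keV: 0.2063/cm vs 0.2059).
Tables are tabulated at 2-keV resolution over 10-150 keV and queried by
log-log interpolation. Known trade-offs: electron binding (incoherent
suppression at low energy) is folded into the calibrated split rather
than modelled; K-edges are absent, so heavy elements (the CsI
scintillator) carry larger component errors — acceptable here because
the scintillator only sets a smooth detection efficiency.

**Transport.** Photon histories are tracked with Woodcock (delta)
tracking inside the phantom's bounding cylinder; interaction type is
sampled proportionally to the local photoelectric/Compton/Rayleigh
components. Compton scattering samples the free-electron Klein-Nishina
energy-angle law (no Doppler broadening); Rayleigh scattering uses the
Thomson angular law (no atomic form factors) and no energy change;
photoelectric absorption terminates the history. The air gap is treated
as vacuum. The detector is either an ideal photon counter or a 0.6-mm
CsI slab with simplified one-dimensional depth transport whose Compton
and Rayleigh interactions are counted in the per-photon labels. A photon
is classified *primary* iff it left the phantom without any Compton or
Rayleigh interaction (a flag extends the classification to detector
interactions); `total = primary + scatter` holds exactly per pixel.
Histories are tallied as photon counts by default (energy weighting
optional). Random streams are derived per view from a master seed
(splitmix-seeded Mersenne Twister with explicit bit-stable uniform
conversion), so a fixed seed reproduces a stack bit for bit.

**Emission model.** Photons are aimed uniformly at the illuminated
detector band, so the expected open-field image is uniform per pixel up
to detection efficiency; acquisitions at different collimations are
compared after flat-field normalization, and multi-FOV scans use photon
budgets proportional to the band area so that per-pixel fluence matches
a constant-output tube.

**Spectrum.** The polychromatic model is Kramers bremsstrahlung
($\phi(E) \propto (kVp-E)/E$) filtered by the stated 10 mm aluminium
equivalent, plus tungsten K lines at 59.3/67.2 keV carrying 6%/3% of the
continuum. The spectrum shape is a modelling choice (only the tube
voltage and filtration are specified for the scanner); a monoenergetic
60 keV mode supports fast, analytically checkable runs and is the desk
default, which also keeps scatter effects separate from beam hardening.

## Geometry, collimation, and an unavoidable inconsistency

The collimator is modelled as a thin slit at distance $d_c$ from the
source; similar triangles map a slit of $s$ mm to an illuminated band of
$s \cdot \mathrm{SDD}/d_c$ on the detector and an axial FOV of
$s \cdot \mathrm{SAD}/d_c$ at the isocenter. $d_c$ is not printed for
the scanner; the package calibrates it once so that a 4-cm FOV
corresponds to a 14-mm slit ($d_c = 17.34$ cm), the anchor we consider
most reliable. Under that anchor the 13-cm FOV maps to 45.5 mm rather
than the film-measured 42 mm; the two film points are mutually
inconsistent with any single thin-slit geometry, and we keep the 4-cm
anchor throughout.

A second inconsistency matters for the slit sweep: with slits spanning
0.5 mm to fully open, the beam height at the detector spans a ~93x
range, while the detector is only ~9x taller than the 11x11-pixel
central ROI. No collimator distance can keep the narrowest beam covering
the ROI *and* the widest settings distinct. Under the 4-cm anchor, slits
below ~5 mm illuminate less than the ROI; the ROI-mean intensity is then
exactly linear (not logarithmic) in the slit opening over those
settings. The sweep therefore reports an *exposure-normalized* tally —
ROI mean of counts divided by the expected fully-illuminated-pixel
flat-field value — which preserves the constant-tube-output reading:
intensity rises with slit size through both band coverage and scatter
growth. Natural-log fit quality of that curve is high for the larger
phantoms, whose scatter growth dominates the upper slits, and lower for
the 10-cm phantom, where the coverage ramp dominates; this is a
geometric consequence of the anchor and is reported as measured.

## The two-FOV correction

For acquisitions at slits $x_1 < x_2$ (defaults: the 4-cm and 13-cm FOV
scans), each pixel's flat-field-normalized intensities $(y_1, y_2)$
determine the two-point model $a = (y_2-y_1)/\ln(x_2/x_1)$,
$b = y_1 - a \ln x_1$, which reproduces both observations exactly.
Pixels outside the overlap band of the narrower FOV, or with
non-positive intensity, are masked; pixels where $y_2 \le y_1$ (noise
implies a non-positive slope) fall back to a flat model $a = 0$, so
their scatter estimate is driven by neighbours through the subsequent
low-pass. The model is extrapolated to a target slit; the residual
(raw minus extrapolated) is smoothed per view with a truncated,
renormalized 11x11 Gaussian kernel of sigma 5 pixels (reflective
borders, exact DC preservation), clamped at zero, rescaled to counts,
and subtracted; corrected counts are floored at 1 so the downstream log
transform stays defined.

**Choice of the extrapolation target.** The published description never
states the target slit. Its printed two-FOV example (ROI means 7095 at
14 mm and 8167 at 42 mm, extrapolated value 5497) is inconsistent with
extrapolating to the narrowest characterized slit — the fitted model
gives 3843 at 0.5 mm — but is reproduced exactly at a target of 2.73 mm.
The package therefore defaults to `target_slit_mm = 2.7` and leaves the
target a required, logged parameter. The trade-off is explicit: a
smaller target removes more scatter but multiplies the fitted slope by
$\ln(x_1/x_t)$, amplifying noise, and over-subtracts whenever the true
slit response is flatter than logarithmic below $x_1$ (which is what the
Monte Carlo characterization shows under the film-anchored geometry).

## FDK reconstruction

Cosine pre-weighting $\mathrm{SDD}/\sqrt{\mathrm{SDD}^2+u^2+v^2}$,
row-wise discrete Ram-Lak ramp filtering (projections rebinned to the
virtual detector through the isocenter, zero-padded to the next power of
two; no apodization by default, honouring the study's choice of no
additional filtering, with Hamming optional), then voxel-driven,
distance-weighted backprojection with uniform $\pi/n_{views}$ weighting
of the full 360-degree orbit. The implementation is linear in the
projections and deterministic; on a scatter-free monoenergetic water
cylinder it recovers the water attenuation coefficient within a fraction
of a percent at 64 views and a 128x128 grid. CT numbers are calibrated
as $HU = 1000(\mu - \mu_w)/\mu_w$ with $\mu_w$ *measured* from a
dedicated water-only calibration reconstruction rather than computed
from the spectrum, which makes the calibration robust to beam hardening.

## Evaluation

`roi_stats` uses arithmetic means and sample (n-1) standard deviations
(the published protocol does not specify population vs sample).
`compute_spr` is the ratio of scatter to primary ROI means on the first
view (gantry angle 0), the convention used for all tally reporting. The
uncollimated sweep point is mapped to the slit size that exactly covers
the detector height so the log fit has a finite abscissa. `compute_cnr`
implements $CNR = |CT\# - CT\#_w| / SD_w$ per insert ROI (0.9-cm circle,
placed in the core for cored bone inserts) against a water background
ROI at the insert-ring radius, at an angle verified to be insert-free
(the protocol does not state its background location); a pooled annulus
background is available because a 0.9-cm ROI contains only ~30 voxels at
desk-scale voxel sizes and its SD estimate carries ~14% sampling error,
which would otherwise dominate CNR comparisons. `cupping_index` is the
mean HU in an edge annulus (70-90% of the body radius) minus the mean in
a central disc (30%, grown if a central insert excludes it), insert
voxels masked with a 3-mm margin: ~0 for artifact-free water, positive
under cupping.

## The analytic projector as fixture generator and oracle

The analytic forward model computes exact Beer-Lambert line integrals
through the nested cylinders (spectral summation, optional scintillator
efficiency) and adds a parametric scatter field: a smooth spatial
profile times a slit response $g(s)$, with $g(s) = \ln(1+s/s_0)$ by
default — precisely the regime the estimator assumes — and a saturating
exponential alternative for robustness probes. Poisson noise is optional
and channel conservation holds in expectation. This module is the
primary-channel oracle for the Monte Carlo engine (agreement within
Poisson error on downsampled grids) and generates the correction's
ground-truth fixtures. What passing fixture-based tests show is that the
estimator recovers primary signal *when the scatter truly follows the
log law and the two scans differ only by collimation*; they do not show
that real scatter follows that law, and the Monte Carlo end-to-end runs
show the method's behaviour when it does not (over-subtraction bias
controlled by the target-slit choice).

## Desk-scale problem sizes

The full-resolution study (84 scans of 301 views at 384x480) is far
beyond a single desk run; the package's defaults scale it down while
keeping every algorithmic step identical. Choices used by the test
suite, stated once here: detector downsampled 4x (96x120 at 2 mm) or 8x
for reconstruction studies; 24-64 views; monoenergetic 60 keV; $\ge$
2x10^5 photon histories per sweep setting (1x10^6 for the log-fit
characterization); end-to-end correction runs at ~2-4x10^3 expected
photons per illuminated pixel per view, reconstructed on 96x96x12 grids
at 1.5 mm. Monte Carlo standard errors are propagated into every
comparison (3-sigma bands for oracles, 2x standard error for SPR
monotonicity).

## Known limitations

- No electron transport, fluorescence escape, dose scoring, heel effect,
  bow-tie filtration, or detector lag/glare; air-gap scatter ignored.
- Power-law photoelectric/coherent model without K-edges; Thomson
  Rayleigh angles overestimate large-angle coherent scatter.
- The desk-scale Monte Carlo is Poisson-limited: comparisons that on a
  clinical scanner are dominated by systematic artifact structure (e.g.
  CNR orderings between acquisitions whose scatter differs by a few
  percent of signal) are marginal at these budgets, and the test suite
  says so explicitly where it applies.
- The thin-slit collimator model cannot reconcile all printed
  collimation measurements (see above); the 4-cm anchor is used
  throughout.
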