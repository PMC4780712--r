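# cbctscatter

Scatter is the dominant artifact source in dental cone-beam CT (CBCT):
because a wide cone irradiates the whole axial volume at once,
scatter-to-primary ratios (SPR) can reach 0.4–2.0 (versus ~0.01 for
single-ray geometries), depressing CT numbers toward the object center
(cupping) and destroying contrast-to-noise ratio (CNR). `cbctscatter`
implements a complete desk-scale study of this problem for a dental CBCT
geometry, for medical-physics researchers and students who want every
step — photon transport, collimation physics, correction and
reconstruction — inspectable and reproducible in R.

The package provides:

- a **Monte Carlo photon-transport engine** (compiled, seeded,
  bit-reproducible) for cylindrical water phantoms with
  tissue-equivalent rod inserts, labelling every Compton and Rayleigh
  interaction per photon so each detected count is classified *primary*
  or *scatter* exactly (`simulate_view()`, `simulate_scan()`,
  `run_slit_sweep()`);
- an **analytic Beer–Lambert projector** with a parametric
  low-frequency scatter field, used as fixture generator and oracle
  (`project_primary()`, `add_scatter_and_noise()`);
- the **two-FOV projection-domain scatter correction**: per detector
  pixel, intensity versus collimating-slit size is modelled as
  *y = a·ln x + b*, fitted from acquisitions at two axial
  fields of view (4 cm and 13 cm), extrapolated toward a narrow slit,
  the residual low-pass filtered with an 11×11 Gaussian (σ = 5 px)
  and subtracted (`fit_log_model()`, `extrapolate_projection()`,
  `estimate_scatter()`, `correct_projection()`, `correct_fov_scan()`);
- **FDK filtered backprojection** (cosine weighting, Ram-Lak ramp,
  distance-weighted backprojection) with measured-water HU calibration
  (`fdk_reconstruct()`, `hu_calibrate()`);
- **evaluation tools**: ROI statistics, SPR, CNR
  (|CT# − CT#_water| / SD_water), cupping index, line profiles, with
  tibble outputs and `autoplot()`/`plot_*()` displays.

The default geometry is the nominal dental scanner: SAD 49.54 cm,
SDD 71.4 cm, 384×480 detector at 0.5 mm pitch, 301 views over 360°,
120 kVp with 10 mm Al-equivalent filtration. See the vignette
(`vignettes/cbct-scatter-correction.Rmd`) for the physics model, the
collimator calibration (4-cm FOV ↔ 14-mm slit) and every numerical
choice.

## Worked example

Characterize SPR versus axial collimation for a 20-cm five-tissue
phantom (one view per slit setting, 10⁶ photons each, 4×-downsampled
detector):

```r
library(cbctscatter)
sw <- run_slit_sweep(diameters_cm = 20, layouts = "five_tissue",
                     n_photons = 1e6, master_seed = 1)
sw[, c("slit_label", "slit_x_mm", "mean_total_norm", "spr", "se_spr")]
#>   slit_label slit_x_mm mean_total_norm    spr  se_spr
#> 1        0.5       0.5         0.00271 0.0824 0.00616
#> 2          1       1.0         0.00543 0.0879 0.00639
#> 3          2       2.0         0.01099 0.0840 0.00618
#> 4          5       5.0         0.02670 0.0796 0.00608
#> 5         10      10.0         0.03078 0.1680 0.01259
#> 6         20      20.0         0.03508 0.3553 0.02814
#> 7       open      46.6         0.04119 0.5370 0.05529
fit_diagnostics(sw$slit_x_mm, sw$mean_total_norm)
#>         a       b    r2 degenerate
#> 1 0.00921 0.00769 0.971 FALSE
```

The exposure-normalized central-ROI intensity rises with the slit
opening and follows the natural-log model (R² = 0.971 here); the SPR
climbs from ~0.08 under tight collimation to 0.54 uncollimated, inside
the 0.4–2.0 range reported for CBCT. `autoplot(sw)` draws both panels.

Run the full pipeline — two Monte Carlo scans (4-cm and 13-cm FOV),
correction, FDK reconstruction, evaluation — at a medium desk scale
(36 views, 8×-downsampled detector, ~10³ photons per pixel per view;
about 40 s on one core):

```r
cfg <- run_config(n_views = 36L, photons_per_view = 8.4e5, downsample = 8L,
                  recon = list(nx = 96L, ny = 96L, nz = 12L, voxel_mm = 1.5),
                  seed = 5L)
art <- run_pipeline(cfg)
round(tapply(art$cnr$ct_water_mean, art$cnr$acquisition, mean), 1)
#>       alt corrected       raw
#>     -41.5       0.1     -44.2
round(art$cupping, 1)
#>       raw       alt corrected
#>       8.6      25.0     -26.2
```

Scatter biases the water background to −44 HU in the raw 4-cm scan and
−42 HU in the 13-cm scan (which also shows the stronger cupping,
25 HU); after correction the water background sits at 0.1 HU. At this
photon budget the CNR comparison between acquisitions is
noise-dominated; the test suite runs it at larger budgets and the
vignette discusses what is and is not resolvable at desk scale.

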