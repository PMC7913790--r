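# iffmap

Interstitial fluid flow (IFF) — the slow convective movement of fluid
through the extracellular space of tissue — shapes how drugs distribute
within and around brain tumors, yet it is rarely measured in patients.
`iffmap` estimates IFF velocity vector fields and isotropic diffusion
coefficient maps from standard dynamic contrast-enhanced MRI (DCE-MRI)
series, for imaging scientists and tumor-microenvironment researchers who
want pixel-wise transport parameters, region and cohort statistics, and
flow-pattern graphics from data that most clinical protocols already
acquire.

## The model

Treating MR signal intensity as proportional to the local contrast-agent
concentration φ(**x**, t), transport on a 2D slice follows the
diffusion–advection equation

    ∂φ/∂t = ∇·(D ∇φ) − ∇·(φ u)

with per-pixel isotropic diffusion coefficient D(**x**) and velocity
**u**(**x**) = (ux, uy). From one background-subtracted image stack (≥ 1
pre-contrast + ≥ 4 post-contrast frames), `estimate_transport()` builds
one forward-time, central-space finite-difference row per frame interval
and pixel,

    (φ[k+1] − φ[k])/Δτ[k] = D·Lφ[k] − ux·Gxφ[k] − uy·Gyφ[k],

and solves the three unknowns (D, ux, uy) per pixel by corrected-score
least squares — a noise-aware variant that subtracts the exactly known
finite-difference noise moments from the normal equations, removing the
errors-in-variables bias that plain least squares suffers at realistic
noise. Pixels that are flat, ill-conditioned or on the border are flagged
invalid (`NA`), never silent zeros. A forward simulator with known ground
truth (`simulate_phantom()`), region tools (polygon rasterization,
parenchymal rings), cohort statistics and deterministic raster graphics
(heat maps, quiver/streamline overlays, rose histograms) complete the
pipeline; see the vignette `vignettes/transport-estimation.Rmd` for the
numerical details and design rationale.

## Worked example

Simulate a tumor-ring phantom — a disk with one transport regime (D = 0.2
px²/frame, radially outward flow at 0.05 px/frame) inside an annulus with
another (D = 0.1, 0.15 px/frame) — then recover the fields and summarize
both regions:

```r
library(iffmap)

spec <- phantom_spec("tumor_ring", shape = c(48, 48), D = 0.2, D_out = 0.1,
                     ring_speed_in = 0.05, ring_speed_out = 0.15, seed = 7)
ph  <- simulate_phantom(spec, frame_times = 0:4, pre_contrast_count = 1,
                        micro_dt = 1, advection = "gradient")
sub <- subtract_background(ph$stack)
roi <- region_mask(ph$tumor_mask$mask | ph$ring_mask$mask, "roi")
fit <- estimate_transport(sub, roi)
summary(fit)
#> Pixel-wise diffusion-advection fit (px_frame units)
#>   pixel status: ok=728, degenerate=0, ill_conditioned=44, border=0, outside_mask=1532
#>   clipped negative D: 0
#>   D quartiles:     0.1 / 0.1 / 0.2
#>   speed quartiles: 0.05 / 0.15 / 0.15
#>   noise sd used by correction: 0

rbind(summarize_region(fit, ph$tumor_mask, "P01", "s1"),
      summarize_region(fit, ph$ring_mask,  "P01", "s1"))
#>   patient_id slice_id     region mean_speed median_speed mean_D median_D n_valid    units
#> 1        P01       s1      tumor       0.05         0.05    0.2      0.2     256 px_frame
#> 2        P01       s1 parenchyma       0.15         0.15    0.1      0.1     472 px_frame
```

Both regions recover their true regimes exactly (the simulation is
noiseless and matched to the inverse stencil; the 44 ill-conditioned
pixels sit where the radial flow gives the per-pixel system no leverage
and are excluded rather than guessed). Unit conversion is a metadata
rescale: with 0.9 mm pixels and 40 s between frames,
`to_physical_units(fit, 0.9, 40)` reports the tumor median speed as
0.001125 mm/s ≈ 1.1 µm/s, a typical interstitial flow magnitude.

Directional structure comes from the same fit:

```r
rose_histogram(fit, ph$tumor_mask)
#> <rose_histogram> 16 direction bins x 5 magnitude bins; 256 pixels (0 static)
streamlines <- compute_streamlines(fit, streamline_seeds(ph$tumor_mask))
render_quiver_streamlines(fit, streamlines = streamlines,
                          out_path = "flow.png")
```

`run_slice()` chains the whole analysis (load or simulate → frame
selection → background subtraction → estimation → summaries → figures)
from a YAML config and writes a manifest with MD5 hashes of every
artifact; `run_cohort()` aggregates slices to patients, joins clinical
covariates and emits the cohort statistics report (tumor vs. parenchyma,
correlations with age/weight/survival, group tests, pre/post-resection).

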