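# pfmmd

Desk-scale simulator and processing pipeline for **planar frequency-mixing
magnetic detection (p-FMMD)** imaging of brain infarcts.

p-FMMD is a nonlinear AC susceptometry: superparamagnetic iron oxide
nanoparticles (SPIONs) bound to a tissue section are driven by a two-tone
magnetic field (high frequency *f₁*, low frequency *f₂*). Because the
equilibrium magnetization of a superparamagnetic ensemble follows the
Langevin function

L(ξ) = coth ξ − 1/ξ,  ξ = m·H/kT (dimensionless field),

the response contains intermodulation products at *m·f₁ ± n·f₂* that only a
nonlinear material can generate. The lowest odd-order product *f₁ + 2f₂* has
small-signal amplitude ξ₁ξ₂²/60 per unit particle amount (the cubic Taylor
coefficient of L is −1/45), so its lock-in amplitude directly quantifies the
amount of SPIONs under the scan head. Raster-scanning a brain section whose
activated microglia carry antibody-conjugated SPIONs therefore yields a 2D
map of the inflamed (infarcted) region.

The package implements the full chain on synthetic phantoms, for researchers
who want to prototype, test or teach this imaging workflow without an
instrument or animal data:

1. **fmmd core** — Langevin response to two-tone excitation, leakage-free
   extraction of mixing components, amount calibration
   (`langevin()`, `response_series()`, `mixing_spectrum()`,
   `quantify_amount()`).
2. **scan simulation** — the 5×5 slide grid (3 cm × 2.4 cm, 0.6 cm ×
   0.48 cm cells), four fiducial SPION droplets, Gaussian coil point-spread
   function, raster trajectory (10 lines, 0.3 cm steps)
   (`grid_layout()`, `acquire()`, `add_fiducial_droplets()`).
3. **phantoms** — coronal brain-slice silhouettes with a one-sided infarct
   of exact area fraction, edema swelling, SPION binding maps, TTC-style
   optical renderings, and z-stacks of 40 µm sections sampled every 15th
   section (`make_slice()`, `make_stack()`, `render_optical()`).
4. **registration** — fiducial detection with subpixel centroids, exact
   four-point homography, bilinear warping, colour overlay
   (`detect_fiducials()`, `fit_homography()`, `warp()`, `merge_overlay()`).
5. **segmentation** — BT.601 YCbCr conversion, colour-box thresholding,
   brain outer-border extraction, hemisphere splitting
   (`rgb_to_ycbcr()`, `threshold_signal()`, `brain_outline()`,
   `split_hemispheres()`).
6. **volumetry** — edema-corrected infarct percentage
   V\_infarct(%) = (A\_contra − (A\_ipsi − A\_infarct)) / A\_contra × 100,
   per slice and stack-aggregated, with mean ± SEM replicate summaries
   (`infarct_percent()`, `stack_report()`, `summarize_replicates()`).
7. **3D reconstruction** — voxel volumes from mask stacks, isosurface
   extraction (marching tetrahedra), boundary caps, gradient normals,
   PLY/OBJ/STL export, and a Dice coincidence score between modality
   volumes (`build_volume()`, `isosurface()`, `isocaps()`, `isonormals()`,
   `coincidence_ratio()`, `export_mesh()`).
8. **pipeline** — a configuration-driven driver running all stages on a
   run directory, each stage also callable standalone on files, plus the
   `exec/fmmd-imager` command-line script (`run_pipeline()`,
   `stage_phantom()` … `stage_mesh()`, `fmmd_imager_main()`).

## Worked example

```r
library(pfmmd)

# mixing physics: f1 = 1000 Hz, f2 = 50 Hz, xi1 = xi2 = 0.3
e <- excitation_config()
p <- langevin_particle(moment_scale = 0.3)
a12 <- mixing_amplitude(mixing_spectrum(response_series(p, e)))
c(amplitude = a12, analytic = a12_small_signal(0.3, 0.3), ratio = a12 / a12_small_signal(0.3, 0.3))
#>    amplitude     analytic        ratio
#> 0.0004344433 0.0004500000 0.9654295

# end-to-end run: 15-slice phantom stack, scan, register, segment,
# quantify, mesh (about 10 s)
res <- run_pipeline(default_run_config(), dir = "run1")
res$summary$pfmmd$V_infarct_pct   # 48.23565  signal-derived estimate
res$summary$truth$V_infarct_pct   # 49.99792  ground-truth masks
res$dice                          # 0.9821095 3D overlap, signal vs truth
```

The mixing amplitude sits 3.5 % below the cubic small-signal law at
ξ = 0.3 (higher-order Langevin terms), and converges to it within 0.4 % at
ξ = 0.1. The pipeline recovers the phantom's requested 50 % edema-corrected
infarct within ~2 percentage points through the full simulated measurement
chain; when the SPION map deliberately under-covers the infarct
(`phantom$spion_coverage < 1`), the signal-derived estimate drops strictly
below the truth-mask estimate — the same direction of bias seen when
microglial activation does not span the whole infarct.

The command line mirrors the same stages:

```sh
fmmd-imager simulate-spectrum --xi1 0.3 --xi2 0.3
fmmd-imager run --config run.yaml --out rundir
fmmd-imager compare --a rundir/masks --b other/masks
```

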