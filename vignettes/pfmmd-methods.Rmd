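---
title: "Simulating and quantifying p-FMMD infarct imaging: models and design choices"
author: "pfmmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying p-FMMD infarct imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfmmd)
options(pfmmd.verbose = FALSE)
```

This vignette explains the models behind each stage of the package, the
parameters that matter, and the design decisions taken where the published
workflow leaves choices open.

## 1. Mixing physics

A SPION ensemble in thermal equilibrium magnetizes along the Langevin
function $L(\xi) = \coth\xi - 1/\xi$, with $\xi$ the dimensionless ratio
of magnetic to thermal energy. We model magnetization as instantaneous
(equilibrium) — no Néel/Brownian relaxation, no hysteresis — because the
particles are superparamagnetic and the excitation frequencies are far
below relaxation rates. `langevin()` switches to the Taylor series
$\xi/3 - \xi^3/45 + 2\xi^5/945$ below $|\xi| < 0.02$, where the closed
form loses precision to cancellation; the first omitted term is below
$10^{-18}$ at the switch point.

Under a two-tone drive $H(t) = H_1\sin 2\pi f_1 t + H_2\sin 2\pi f_2 t$,
the odd nonlinearity generates components at $m f_1 \pm n f_2$ with
$m + n$ odd only. The cubic term $-\xi^3/45$ gives the leading amplitude
of the quantification line $f_1 + 2 f_2$:
$|{-\tfrac{1}{45}}| \cdot \tfrac{3}{4}\, \xi_1 \xi_2^2 = \xi_1\xi_2^2/60$
per unit amount (`a12_small_signal()`). At $\xi = 0.3$ the full
simulation sits about 3.5 % below this cubic law (quintic corrections);
at $\xi \le 0.1$ it agrees within 1 %. Proportionality to particle
*amount* is exact at any drive, which is what calibration relies on.

**Excitation defaults.** The instrument's actual frequencies and
amplitudes are not part of the published description, so the package
chooses $f_1 = 1000$ Hz, $f_2 = 50$ Hz, $\xi_1 = \xi_2 = 0.3$: the 20:1
rational ratio gives a short common period (20 ms), all mixing lines of
order $\le 5$ are distinct multiples of 50 Hz, and $\xi = 0.3$ is small
enough for near-linear quantification yet large enough for a healthy
signal. These are stand-ins, not instrument values.

**Demodulation.** Amplitudes are obtained by projection onto
sine/cosine at the exact line frequency over an integer number of common
periods. On such series the projection equals the windowless DFT bin
(verified to $10^{-9}$ in the tests), so spectral leakage never enters
any tolerance. Series that do not span integer periods are rejected
rather than windowed. Additive measurement noise is available
(`noise_sd`, seeded) and off by default so tests are deterministic.

## 2. Scan-image formation

The slide carries a 5×5 grid, 3 cm × 2.4 cm (0.6 cm × 0.48 cm cells);
four fiducial SPION droplets sit on the midpoints between cell pairs
(1,2), (4,5), (21,22), (24,25); the head scans 10 vertical lines at
0.3 cm lateral steps, right to left, centred on the grid.

The coil sensitivity footprint is modelled as an isotropic Gaussian PSF
(default FWHM 0.15 cm, truncated at 3σ, unit sum). No kernel is published
for the 2 mm scanning gap; a single-parameter symmetric kernel is the
simplest model consistent with a planar coil pair. Image formation is

$$\text{signal}(x) = \text{cal} \cdot (\text{PSF} \ast \text{amount})(x),$$

the small-signal $f_1+2f_2$ amplitude for the PSF-weighted local particle
amount. Two numerical points matter:

* **Blur before sampling.** The pipeline evaluates the convolution at
  the fine phantom pitch (0.01 cm) in the slide frame and only then
  samples the smooth field at scanner pixel centres through the
  geometric distortion. Sampling a sharp concentration map at the 0.05 cm
  scan pitch first would alias droplet positions by up to half a scan
  pixel and ruin subpixel registration.
* **Amplitude maps are sampled pointwise; density maps are warped with
  the Jacobian.** `warp()` multiplies by the local inverse-Jacobian
  determinant only when `preserve_mass = TRUE` (appropriate for
  concentration/density images); amplitude readings are pointwise
  physical values and use `preserve_mass = FALSE`.

An optional `line_sampled` mode keeps only the 10 scan-line columns and
rebuilds the raster by linear interpolation, emulating the instrument's
coarse lateral sampling; it is off by default because the native lateral
resolution of the real scanner is not documented.

**Coordinates.** One convention everywhere: origin at the slide's
top-left corner, x rightward, y downward, cm units, pixel centres at
$(i-\tfrac12)\cdot\text{pitch}$.

## 3. Phantom generator

`make_slice()` builds a coronal-section stand-in: a superellipse
(exponent 2.5) split at a vertical midline into mirrored hemisphere
lobes. This is deliberately schematic — smooth, hemisphere-separable,
one-line mathematics — not an anatomical atlas. What it *does* emulate,
because the quantification formula exists to handle them:

* **Edema**: the ipsilateral (right) lobe is scaled isotropically by
  `edema_factor`, so its area grows by the factor squared.
* **One-sided infarct of exact size**: the infarct grows from a
  mid-lateral seed point inside the ipsilateral lobe; selecting the
  $k = \lfloor \text{fraction} \times A_{ipsi}\rfloor$ nearest pixels
  (under a seeded, direction-dependent metric for boundary roughness)
  pins $A_{infarct}/A_{ipsi}$ to one-pixel granularity.
* **Mirror-symmetric boundary roughness**: the lobe outline is perturbed
  by seeded harmonics even under x-reflection, so at `edema_factor = 1`
  the hemispheres are *exactly* equal — a property several tests use.
* **SPION binding** (`bind_spions()`): uniform density on the infarct,
  optional multiplicative texture, and a `coverage < 1` mode that
  restricts binding to the inner part of the infarct — the mechanism by
  which microglial activation can under-represent the infarct.

`make_stack()` emulates 629 serial 40 µm sections with every 15th
section between indices 135 and 345 scanned (15 slices, z-spacing
15 × 40 µm = 0.06 cm). The published description mentions both this
sampling and "22 slices" (which corresponds to a 10-section step over
the same range); the step is therefore an explicit parameter rather than
a guess. Silhouette size follows an ellipsoidal axial profile peaking
mid-stack. Ground truth (areas, fractions, the edema-corrected
percentage) is recorded exactly from pixel counts; pipeline closure is
always checked against this bookkeeping, not against re-derived values.

What the phantom does **not** emulate: cytoarchitecture, curved
interhemispheric fissures, partial-volume staining gradients, specimen
preparation artefacts. Passing tests show the processing chain is
correct and internally consistent, not that it meets any particular
accuracy on real tissue.

## 4. Registration

The scanner and camera frames differ by an unknown planar projective
transform. Four fiducial droplets exactly determine a homography
(8 degrees of freedom), fitted by direct linear transform
(`fit_homography()`); a projective rather than affine model is used
because perspective "distortion correction" is part of the workflow and
four correspondences determine it exactly. Degenerate (collinear)
configurations are rejected naming the offending triple.

The fiducial layout is symmetric under 180° rotation of the grid, so
positions alone cannot establish correspondence. The simulator therefore
defaults to four *distinct* droplet amounts (1.0, 0.8, 0.6, 0.4) and
`detect_fiducials()` assigns labels by ranking integrated intensities;
explicit pairings can be configured instead.

Droplet centres are localised as the intensity-weighted centroid of the
above-half-maximum region, evaluated on a bilinearly upsampled window
with an iteratively re-centred circular aperture. The aperture fixes a
subtle bias: a rectangular window that is asymmetric about the true
centre truncates the blob's tails asymmetrically and biases a plain
centroid by a substantial fraction of a pixel; the re-centred circular
aperture removes this, giving centres good to ~0.02 scan pixels on
noise-free phantoms and end-to-end fiducial misalignment well below one
optical pixel (0.01 cm) under the default 2° rotation + perspective
distortion.

Warping uses inverse-mapping bilinear interpolation: continuous,
monotone, no overshoot for non-negative signal. Out-of-domain pixels are
zero.

## 5. Segmentation

Colour thresholding is done in YCbCr using the ITU-R BT.601 full-range
transform — the common image-editing convention, with the achromatic
fixed point at (128, 128, 128) and red mapping to (76, 85, 255). The
signal mask is a six-bound box in (Y, Cb, Cr) followed by a radius-1
morphological opening to drop isolated pixels.

The default box is *derived*, not tuned: alpha blending is channel-wise
linear and BT.601 is affine, so every possible blend of the overlay
colour with any underlying image lies inside the YCbCr bounding box of
the blends with the eight RGB-cube corners
(`default_signal_thresholds()`, plus a 2-count margin for PNG rounding).
Overlay pixels are therefore segmented exactly, whatever the optical
image underneath.

The brain outer border is found on luma with a **three-class Otsu**
threshold (exhaustive two-threshold search), keeping the lower
threshold: a TTC-style photograph is trimodal (dark background, red
viable tissue, white infarct), and a standard two-class Otsu settles
between red and white, discarding the viable tissue. The largest
8-connected component above the threshold is kept and its holes filled,
yielding one simply-connected mask. The hemisphere split is a straight
vertical cut (default: mask x-centroid; the pipeline uses the phantom's
known midline), matching the area bookkeeping granularity of the
quantification formula.

The pipeline thresholds the registered signal at half its maximum: for a
PSF-blurred uniform source this recovers the support boundary almost
exactly, and it makes the segmented extent independent of the overall
calibration scale. The registered signal is first cropped to the central
3×3 grid cells where the specimen sits — the fiducial droplets are
adjustment points, not sample signal, and would otherwise dominate the
maximum.

## 6. Volumetry

The edema-corrected infarct percentage

$$V_{infarct}(\%) = \frac{A_{contra} - (A_{ipsi} - A_{infarct})}{A_{contra}} \times 100$$

subtracts the surviving ipsilateral tissue from the contralateral area,
so swelling of the injured hemisphere does not inflate the estimate;
with no edema it reduces to $100\,A_{infarct}/A_{contra}$. Stack
aggregation sums areas across slices *before* applying the formula
(equivalent to volume ratios, since z-spacing is constant), rather than
averaging per-slice percentages — a volume-consistent choice the
published workflow leaves open. Signal masks are clipped to the
ipsilateral hemisphere so $A_{infarct} \le A_{ipsi}$ always holds.
Replicate summaries report mean ± SEM; significance testing is out of
scope.

## 7. 3D reconstruction

Mask stacks become (z, y, x) voxel volumes with physical voxel sizes
(dz = 0.06 cm for default stacks, dy = dx = the mask pitch); anisotropy
is carried in vertex coordinates, not resampled away, unless inter-slice
linear interpolation is requested (`interp = "linear"`, inserting k
planes per gap).

Isosurfaces are extracted by **marching tetrahedra** on the Kuhn
(6-tetrahedra) subdivision of each grid cell rather than the classic
15-case marching-cubes table. The tetrahedral cases are unambiguous (no
face-saddle disambiguation), the subdivision tiles space compatibly
(neighbouring cells split shared faces along the same diagonal), and the
resulting surface is crack-free and watertight wherever the object does
not touch the volume boundary — properties the tests audit directly
(every edge shared by exactly two faces). Accuracy is equivalent for the
purpose: a voxelized radius-10 sphere yields an enclosed volume within
1 % of $\tfrac43\pi r^3$.

`isocaps()` closes boundary intersections with planar triangulations of
the above-level regions on the six boundary faces, using the same cell
diagonals and edge interpolation as the isosurface so that the union is
watertight. Caps sit on the boundary *sample plane* (the outermost voxel
centres), so a boundary-touching object loses a half-voxel layer in the
capped direction — the same semantics as the MATLAB-style
isosurface/isocaps pair this mirrors. `isonormals()` attaches outward
per-vertex normals from the trilinearly interpolated gradient of a
Gaussian-presmoothed field (σ = 1 voxel), falling back to averaged face
normals at vanishing gradients.

The "ratio of coincidence" between two modality volumes is not formally
defined in the published workflow; the package adopts the **Dice
coefficient** $2|A\cap B|/(|A|+|B|)$ on binarized voxel volumes
(symmetric, standard), reporting intersection-over-union alongside.

## 8. Pipeline, problem sizes, determinism

`run_pipeline()` executes phantom → scan → register → segment →
quantify → mesh on a run directory; every stage is also a standalone
file-based function, and the monolithic run literally calls the same
stage sequence, so stage-wise and monolithic execution are identical by
construction. The resolved configuration, a manifest (path, stage,
config hash) and a timing log are always written.

Default sizes were chosen so a full run takes seconds on one CPU:
optical pitch 0.01 cm (300 × 240 slice images), scan pitch 0.05 cm,
15-slice stacks, meshing on 2× downsampled masks. The acceptance script
additionally exercises a 0.005 cm-pitch truth-mask stack. All
randomness (phantom shapes, textures, noise) derives from the single
config seed, and repeated runs agree to well below $10^{-10}$ in every
reported percentage (PNG/TIFF round trips are bit-deterministic).

A simulated scanner distortion (2° rotation, small translation, mild
perspective) is applied between the slide and scanner frames so that
registration is genuinely exercised; its parameters live in the config
(`distortion`) and registration never sees them.

## Known limitations

* The excitation parameters are plausible stand-ins; absolute signal
  units are arbitrary and only ratios/linearity are meaningful.
* The PSF is a single isotropic Gaussian; lift-off, coil geometry and
  sample-thickness effects are not modelled.
* Phantoms are geometric stand-ins; no claim of anatomical realism, and
  no attempt to reproduce animal-derived percentages.
* Boundary caps clip objects at the outermost sample plane (half-voxel
  deficit per capped face).
* The midline is a straight vertical line; curved fissures would need a
  different hemisphere model.
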