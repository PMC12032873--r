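---
title: "Simulating cine DENSE cardiac MR with ground-truth strain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cine DENSE cardiac MR with ground-truth strain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Cine DENSE (displacement encoding with stimulated echoes) stores the
displacement of myocardial tissue since end-diastole in the image phase:
a displacement $u$ along the encoding direction produces a phase
$2\pi k_e u$, wrapping every $1/k_e$ mm. Because regional strain cannot be
measured non-invasively with certainty in vivo, validating a DENSE strain
analysis chain requires synthetic images whose underlying deformation —
and therefore the exact Green–Lagrange strain — is known. `densesim`
generates such images end-to-end and quantifies the bias/variance behavior
of a regularized strain analysis against the analytic ground truth.

This vignette records the model choices, their defaults and units, the
numerical decisions, and what the built-in synthetic cohort does and does
not represent.

## Anatomy

The end-diastolic anatomy is a label map (background 0, myocardium 1,
blood pool 2) on an $N_1 \times N_1$ raster with physical pixel size
(default 240 pixels at 0.8 mm, configurable). Two sources are supported:

* a parametric annulus (`generate_annulus()`), with endocardial and
  epicardial diameters in pixels;
* an imported binary myocardial mask (`upsample_and_dilate_mask()`),
  which is Gaussian-smoothed ($\sigma$ = 1 input pixel, enough to suppress
  staircase edges), cubic-spline interpolated to the target raster,
  thresholded at 0.5, and optionally dilated by up to 6 pixels —
  mirroring the observation that manual DENSE segmentations run thin.
  The blood pool is inferred by hole-filling the annulus, a convention
  chosen because imported masks carry only myocardium.

Pixel centers sit at $(i + 0.5)\,\mathrm{px}$ for 0-based index $i$, with
the raster center at the physical origin; one fixed convention is used by
every module so that anatomy, motion, k-space and reconstruction agree to
sub-pixel precision.

`polar_geometry()` derives the LV center (centroid of myocardium plus
blood pool), per-pixel radial/circumferential unit vectors along the
outward ray, and a normalized transmural coordinate from the ratio of
Euclidean distance transforms to the endocardial and epicardial borders
(0 and 1 on the respective border pixel centers).

## Motion

Deformation is analytic and polar about the LV center:

$$ r'(r, t) = r - a(t)\, f(r), \qquad
   \theta'(r, t) = \theta + a(t)\, \rho\, g(r), $$

with $a(t)$ the temporal activation, $\rho$ the peak rotation (2D twist)
and $f$ a polynomial of order 2 in the transmural offset. $f$ is
parameterized directly by interpretable strain targets:

* `peak_ecc_scale` — endocardial circumferential Green strain at
  end-systole (default −0.18, cohort range −0.22 to −0.14);
* `peak_err_scale` — endocardial radial Green strain at end-systole
  (default 0.35, cohort range 0.25 to 0.45);
* `transmural_err_gradient` — 0 gives transmurally constant radial
  strain; positive values weight it toward the endocardium approximately
  linearly, the pattern expected from incompressible rings (cohort range
  0 to 0.8).

An exact incompressible variant $r'^2 = r^2 - c(t)$ (unit Jacobian) is
available and doubles as the closed-form oracle used by the test suite:
for an endocardial radius contracting from 30 to 24 mm it yields
$E_{cc} = -0.18$ and $E_{rr} = 0.28125$ at the endocardium.

The activation $a(t)$ is a raised cosine in the skewed phase
$(t/t_{ES})^{q}$ with $q = 0.8$, rising from 0 at end-diastole to 1 at
end-systole (`es_fraction`, default 0.35 of the R-R interval) and
relaxing over diastole. The skew makes the early-systolic strain rate
exceed the late-systolic rate, as seen in vivo. Prospective triggering is
represented by the imaging schedule starting at `t_start` rather than 0.
Ground-truth displacements are evaluated analytically at exact sample
times; no temporal interpolation is involved.

Folding is excluded by checking the analytic Jacobian
($\lambda_r \lambda_c > 0$) at every frame. Ground-truth strain is
computed by central differences of the deformed pixel positions
(one-sided at wall edges), $E = (F^\top F - I)/2$, projected on the
radial/circumferential directions at the end-diastolic pixel. On the
incompressible oracle the discretization error decreases monotonically
with raster resolution and is below 1% of the endocardial value at 4
times the DENSE phase-grid resolution, which motivates the default
4:1 ratio between the ground-truth raster and the gridding matrix.

## DENSE acquisition

Each tissue pixel is a spin isochromat with T1/T2/M0 from an editable 3T
table (myocardium 1200/50 ms, blood 1900/250 ms, relative M0 1.0/1.2).
The transverse signal at an imaging pulse is the sum of two terms:

* the stimulated echo, amplitude
  $\tfrac12 M_0 \sin\alpha_n \prod_{m<n}\cos\alpha_m\, e^{-t/T_1}$,
  phase $2\pi k_e\,(x(t)-x_0)\cdot\hat e$ plus the phase-cycling offset.
  Blood additionally decays with a washout time constant (25 ms),
  modelling dark blood: its stimulated echo at frame 5 is below 1% of
  frame 1.
* the T1-recovery echo, amplitude $M_0 (1 - e^{-t/T_1})\sin\alpha_n$,
  phase $2\pi k_e\, x(t)\cdot\hat e$ (it experiences only the second
  encoding gradient). n-point phase cycling (default 2) offsets the
  stimulated echo by $2\pi(c-1)/n$ per cycle; the cycle-weighted complex
  sum retains the stimulated echo and cancels the T1 echo exactly in this
  two-term model.

Variable flip angles follow the standard constant-signal backward
recursion $\tan\alpha_n = \sin\alpha_{n+1} e^{-\Delta t/T_1}$ ending at
15°.

Isochromat signals at deformed (sub-pixel) positions are gridded onto an
$N_2 \times N_2$ Cartesian matrix ($N_2 = 60 < N_1$) by non-uniform
Fourier interpolation, which sums sub-voxel isochromats coherently and
thereby simulates intravoxel dephasing. The image is then multiplied by a
radially symmetric Hamming-shaped window with value 0.5 at a diameter of
0.6 times the image width, approximating the reduced-FOV excitation
profile of the two encoding pulses.

Spiral sampling uses four uniform-density Archimedean interleaves rotated
by 90°, acquired over two cardiac cycles: interleaf $l \in \{1,2\}$ of
cycle $c$ images frame $i$ at
$t = t_\mathrm{start} + \epsilon_c + \Delta t\,(l-1)/2 + \Delta t\, i$
(defaults 15 ms and 30 ms, i.e. 15/45/75 ms and 30/60/90 ms), with
$\epsilon_c$ a per-cycle ECG trigger jitter uniform within ±5 ms. The two
cardiac cycles of an encoding are shared by its phase cycles. Combined
frames carry the nominal times 22.5 + 30 i ms; optional frame
interpolation shares interleaves between adjacent frames to double the
temporal resolution (additional frames at 37.5 + 30 i ms). Ground-truth
motion is sampled at the *jittered* interleaf times, so interleaves of
one frame see slightly inconsistent motion — the source of the
characteristic swirl artifacts.

Numerical choices for the spiral: the readout lasts 11 ms with samples
uniform in spiral angle; each sample is weighted by $e^{-\tau/T_2^*}$
($T_2^* = 40$ ms) over the readout; density compensation uses the
analytic $|k|\,dk$ area elements of the combined interleaf set.
Reconstruction is the density-compensated adjoint non-uniform Fourier
transform onto $N_f \times N_f$. The spiral reaches
$k_{max} = \min(N_f, N_2)/(2\,\mathrm{FOV})$: the gridded object spectrum
is periodic beyond the $N_2$ Nyquist radius, so sampling there would read
spectral replicas rather than signal. On a static phantom the noiseless
spiral reconstruction agrees with the Cartesian reference to within 5%
NRMSE inside the excitation window (the residual is the circular-passband
truncation plus T2* apodization).

Complex white noise is added per spiral sample before phase-cycle
combination. The calibration targets the **noise-referenced** myocardial
SNR at end-systole — mean noiseless myocardial magnitude over the
standard deviation of the magnitude noise residual — because the plain
in-region mean/std ratio also contains the deterministic excitation-window
shading and partial-volume edges, which cap it (at roughly 9–18 depending
on the annulus size) below the highest SNR stratum. Both numbers are
reported per series (`snr_noise_es` and `snr`); `measure_snr()` implements
the plain mean/std definition. Calibration is two-pass: an analytic sigma
from the image-domain gain of one unit-noise reconstruction, then a
multiplicative refinement against measured realizations that absorbs the
Rician magnitude compression at low SNR.

Final images: magnitude is the average of the x- and y-encoded
magnitudes; phases are referenced to the 0-encoded acquisition and
wrapped to $(-\pi, \pi]$.

## Strain evaluation

The analysis mask is the known simulated myocardial contour (its Eulerian
footprint per frame); contour detection is out of scope. Pixels whose
magnitude falls below 30% of the in-mask median are excluded from the
displacement fit — their phase is noise.

1. **Phase to displacement**: $u = \phi/(2\pi k_e)$, wrapped every
   $1/k_e$ (10 mm at the default encoding).
2. **Unwrapping**: the first frame (lowest motion) is unwrapped spatially
   by quality-guided region growing and anchored to the smallest
   congruent solution; later frames unwrap per pixel against their
   temporal predecessor, which is well posed because inter-frame
   increments stay below half a period. A final pass snaps isolated
   outliers to the period multiple nearest their neighborhood median.
3. **Regularized fit** (per frame and component):
   $\arg\min_L \lVert A L - E\rVert^2 + \lambda \lVert \nabla^2 L\rVert^2$
   on the raster node grid (bounding box of the masks plus margin), with
   $A$ selecting node values at the sample pixels and $\nabla^2$ the
   5-point Laplacian. The smoothness knob $k \in [0,1]$ maps to
   $\lambda = \texttt{lambda\_scale}\; k/(1-k)$. The relative
   normalization inside the original grid-fitting tool is not published;
   `lambda_scale` defaults to 0.1, calibrated once so that the $k$ range
   reproduces the documented regime — noise suppression growing with $k$
   and progressive radial-strain underestimation near the endocardium at
   high $k$ — and it is exposed in the configuration as the principal
   fidelity risk when comparing error magnitudes with published tables.
   A tiny ridge ($10^{-10}$ of the diagonal) keeps the normal matrix
   definite against free-boundary biharmonic null modes; $k = 0$ with
   unconstrained nodes falls back to that ridge with a warning. Away from
   the data the solution is clamped to the observed displacement range:
   the free biharmonic extension inside the blood pool carries no
   information and can oscillate by orders of magnitude.
4. **Lagrangian tracking**: material points are the image-resolution
   pixels inside the end-diastolic myocardium. Each frame solves
   $x = X + u(x)$ by fixed-point iteration (bilinear sampling, at most 5
   iterations, tolerance 0.01 pixel) warm-started from the previous
   frame. Points whose fixed point does not close, or whose displacement
   exceeds 1.3 times the largest observed displacement, drifted out of
   the data support; their frame value is marked missing.
5. **Temporal fit**: an order-10 least-squares polynomial per point and
   component over the frame times (reduced with a warning when frames are
   scarce). Missing frames are infilled by the per-point fit when at
   least $2(\mathrm{order}+1)$ frames support it; chronically lost points
   stay missing. Trajectories are fitted, then differentiated — whether
   the published analysis fits before or after strain is not stated; we
   fit first.
6. **Strain**: the same central-difference Green-strain operator as the
   ground truth, on the estimated trajectories. Estimated strain
   magnitudes beyond $|E| = 2$ (far outside the physiological range) flag
   mis-tracked pixels and are invalidated rather than reported.

For error statistics the estimate is compared at the ground-truth
end-systolic frame (the frame time closest to
`es_fraction` × R-R); ground-truth rasters are bilinearly resampled at
the estimated material positions. Signed errors are truth minus estimate,
so positive radial-strain errors mean underestimation. Global peak strain
is the per-frame spatial mean over the myocardium followed by the
extremum over frames (maximum for radial, minimum for circumferential) —
the usual convention; transmural segments are tertiles of the normalized
transmural coordinate.

## The virtual cohort

`cohort_config()` defaults encode the study conditions at a reduced
problem size chosen to keep a full stratified experiment tractable on a
single CPU: 24 annulus-only cases, ground-truth raster $N_1 = 120$ at
1.6 mm (the published full-scale settings are 240 at 0.8 mm over the same
192 mm field of view), gridding $N_2 = 60$, reconstruction $N_f = 64$,
epicardial diameters 0.4–0.6 of the matrix with endo/epi ratios 0.5–0.8,
R-R intervals 825–1200 ms, peak rotation uniform in ±0.5 rad, and three
end-systolic SNR strata ([3.9, 6.1], [8.3, 11.5], [13.9, 17.7]) with
equal counts. Each case derives a child seed from the master seed, so the
full report is reproducible bit for bit.

What the generator does **not** emulate: torso background tissues, coil
sensitivities and B0 inhomogeneity (so image shading is limited to the
excitation window), through-plane and long-axis motion, right-ventricular
deformation, diastolic untwisting asymmetry, and anatomy variability
beyond annuli (imported masks excepted). Passing cohort-level checks
therefore demonstrates the fidelity of the encoding/reconstruction/
analysis chain under controlled geometry, not performance on patient
anatomy.

At the reduced $N_f$, the thinnest cohort walls span only ~3
reconstruction pixels, which makes radial strain intrinsically harder to
recover than at the published 90–128 matrices; the quantitative error
statistics are therefore expected to land in the published ranges rather
than on the printed decimals.

## Reproducing the headline numbers

`scripts/acceptance.R --seed S --out results/acceptance.json` rebuilds
the nominal spiral frame times and runs the full 24-case cohort at
$k \in \{0.1, 0.3, 0.9\}$, writing the pooled end-systolic signed-error
means and the Bland–Altman biases of global peak strain. The test suite
additionally verifies the closed-form oracles (incompressible annulus,
phase-cycling cancellation, spiral timing), the noise calibration, the
solver against a dense reference, and the qualitative bias–variance
trade-off across the regularization grid.
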