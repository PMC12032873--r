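# densesim

Synthetic cine DENSE cardiac MR with sub-voxel ground-truth strain, in R.

Cine DENSE (displacement encoding with stimulated echoes) encodes the
displacement of myocardial tissue since end-diastole in the image phase: a
displacement *u* along the encoding direction appears as a phase
2π·k\_e·u, wrapping every 1/k\_e mm (10 mm at the usual k\_e = 0.1
cycles/mm). DENSE is among the most accurate ways to measure regional
myocardial strain, but validating a strain *analysis* chain requires data
whose true deformation is known — which in-vivo imaging cannot provide.

`densesim` is for researchers developing or tuning DENSE strain analysis:
it simulates the whole imaging experiment from a known analytic
deformation, so every derived quantity can be compared against an exact
reference. The pipeline has five modules, each usable on its own:

1. **Anatomy** — end-diastolic label maps from a parametric annulus or an
   imported binary mask (PNG/NIfTI), with per-pixel polar geometry and a
   normalized transmural coordinate.
2. **Motion** — smooth contractile deformations in polar form,
   r′ = r − a(t)·f(r), θ′ = θ + a(t)·ρ·g(r), parameterized by peak
   endocardial radial/circumferential Green strain, a transmural
   radial-strain gradient, 2D twist and a systole-weighted activation;
   ground-truth Green–Lagrange strain E = (FᵀF − I)/2 by central
   differences of the deformed pixel positions.
3. **Acquisition** — a Bloch-style stimulated-echo signal model
   (stimulated echo + T1-recovery echo, variable flip angles, dark
   blood), non-uniform Fourier gridding with intravoxel dephasing,
   reduced-FOV excitation windowing, four interleaved Archimedean spirals
   over two cardiac cycles with ECG trigger jitter and T2* readout decay,
   calibrated complex k-space noise, density-compensated adjoint
   reconstruction, n-point phase cycling, and x/y/reference encoding
   combination.
4. **Strain evaluation** — phase→displacement conversion, spatiotemporal
   unwrapping, the Laplacian-regularized grid fit
   argmin ‖AL − E‖² + λ(k)‖∇²L‖² with smoothness k ∈ [0, 1], Lagrangian
   tracking, order-10 temporal polynomial fitting, and the same Green
   strain operator as the ground truth.
5. **Cohort metrics** — seeded stratified virtual cohorts and the error
   report: pixel signed errors (mean ± std, truth − estimate) by
   regularization, SNR stratum and transmural tertile, plus Bland–Altman
   bias and limits of agreement of global peak strain.

## Worked example

Simulate one mid-ventricular short-axis slice at the full study scale
(240×240 ground truth at 0.8 mm, gridding 60, reconstruction 90) with a
target myocardial SNR of 10, then analyze it at typical regularization:

```r
library(densesim)

lm  <- generate_annulus(240, 0.8, endo_diameter = 88, epi_diameter = 132)
geo <- polar_geometry(lm)
mp  <- motion_params(rr_interval = 1000, peak_rotation = 0.3)
acq <- acq_params(target_snr = 10, Nf = 90)
ser <- simulate_dense_series(lm, geo, mp, acq, seed = 42)
ser
#> <dense_series> 33 frames 90 x 90, ES frame 12 (352.5 ms), SNR 5.2

truth <- green_strain(
  generate_displacement_field(lm, geo, mp, ser$frame_times),
  geometry = geo)
est <- evaluate_strain(ser, lm, geo, k = 0.9)
pixel_signed_errors(truth, est, ser$es_index, ser$es_index)
#>   component segment      ase    std    n
#> 1       err subendo  0.04674 0.0494  272
#> 2       err     mid -0.00208 0.0227  352
#> 3       err  subepi -0.00922 0.0896  388
#> 4       err  global  0.00830 0.0668 1012
#> 5       ecc subendo -0.00217 0.0087  272
#> 6       ecc     mid -0.00039 0.0092  352
#> 7       ecc  subepi -0.00180 0.0469  388
#> 8       ecc  global -0.00141 0.0299 1012
```

Reading the table: errors are ground truth minus estimate at end-systole,
pooled over myocardial pixels. At k = 0.9 the subendocardial radial strain
is underestimated by ≈ 0.047 Green-strain units (the hallmark of
over-regularization, strongest where the true strain peaks), while
circumferential strain is essentially unbiased (−0.001 globally). The
global peak radial strain comes out at 0.243 versus the true 0.255.
The printed per-frame `SNR` is the plain in-region mean/std of the
magnitude, which also contains the excitation-window shading; the noise
calibration targets the noise-referenced SNR (`ser$snr_noise_es`, here
≈ 10).

A 24-case stratified cohort with the full error report:

```r
coh <- generate_cohort(cohort_config(master_seed = 1))
rep <- evaluation_table(coh)
rep          # pooled ASE ± std per component and k
write_error_report(rep, "results/")
```

A thin command-line wrapper is included at `inst/cli/dense-sim.R`
(`simulate`, `evaluate`, `cohort` subcommands; YAML configs, NIfTI/CSV
outputs).

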