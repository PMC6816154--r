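# csaaa

Simulation and analysis toolkit for **compressed-sensing (CS) black-blood
MRI of abdominal aortic aneurysms (AAA)**, written for imaging scientists
who want to test whether an accelerated acquisition preserves the
measurements that drive aneurysm surveillance — without needing patient
data.

AAA management rests on the maximal outer diameter (intervention above
5.5 cm or growth > 1 cm/year) and, increasingly, on the composition of the
intraluminal thrombus (ILT). 3D black-blood MRI shows wall and thrombus but
is slow; CS accelerates it by undersampling k-space. `csaaa` simulates the
whole chain on seeded digital phantoms with analytic ground truth:

1. **Phantoms** — a fusiform aneurysm (Gaussian bulge, 2 mm wall, ILT layer
   of one of four signal types, psoas-muscle reference, spine) rasterised
   at 1.3 mm isotropic with partial-volume averaging, plus smooth
   RSS-normalised complex coil sensitivities and a multi-coil k-space
   forward model with complex Gaussian noise.
2. **Undersampling** — variable-density Poisson-disc masks with elliptical
   coverage and a fully sampled calibration centre, calibrated by bisection
   to the target acceleration (R = 5 samples 20% of the elliptical
   k-space).
3. **Reconstruction** — the combined CS / parallel-imaging objective

   $$\hat{x} = \arg\min_x \tfrac12 \sum_{n=1}^{N}
   \lVert y_n - F_u(\mathrm{CSM}_n \odot x)\rVert_2^2
   + \lambda \lVert W x \rVert_1,$$

   minimised by accelerated proximal gradient with a monotone safeguard;
   $W$ is an orthogonal Daubechies-4 wavelet transform, coil maps
   $\mathrm{CSM}_n$ are estimated from the calibration region, and the
   default operating point is $\lambda = 0.002$ (on data normalised so the
   zero-filled image peaks at 1) with 10 iterations.
4. **Morphometry** — sub-voxel cross-section contours, maximal (Feret)
   diameter, lumen and ILT/wall areas, ILT-to-muscle and ILT-to-lumen
   ratios, four-type ILT classification (bright threshold 1.2), 20%–80%
   boundary sharpness in mm⁻¹, and endpoint growth rates in mm/year.
5. **Agreement statistics** — Bland-Altman bias with 95% limits of
   agreement, within-subject coefficient of variation, ICC (two-way,
   absolute agreement), and Cohen's kappa.

`run_experiment()` ties these into a synthetic method-comparison study
(fully sampled reference arm vs CS arm over a cohort of phantoms) and
`longitudinal_series()` into a growth-rate surveillance simulation.

## Worked example

```r
library(csaaa)

# a 4.85 cm aneurysm with mixed bright/iso thrombus, imaged at R = 5
spec <- aaa_phantom_spec(outer_diameter_cm = 4.85, ilt_type = 2, seed = 1)
ph   <- build_phantom(spec)
maps <- coil_sensitivities(dim(ph$intensity), n_coils = 4, seed = 2)
mask <- poisson_disc_mask(64, 64, target_accel = 5, seed = 3)
acq  <- simulate_acquisition(ph, maps, mask, seed = 4)
rec  <- reconstruct_cs(acq, estimate_sensitivities(acq), recon_config())
rec
#> <recon_result> 48 x 64 x 64, lambda = 0.002, 10 iterations; cost 119.7 -> 67.82

muscle <- ph$labels == 5
measure_volume(Mod(rec$image), ph$voxel_size, muscle)
#> <aneurysm_measures> D = 4.86 cm (slice 25); lumen 6.36 cm^2, ILT/wall 11.91 cm^2;
#>   ILT/muscle 1.35, type 2; sharpness 0.46 mm^-1
ph$truth$max_outer_diameter_cm
#> [1] 4.85
```

The CS volume recovers the analytic maximal diameter within a hundredth of
a centimetre (truth 4.85 cm, lumen area truth 6.38 cm²), classifies the
mixed thrombus correctly, and the cost trace in `rec$cost_trace` is
non-increasing. The ILT-to-muscle ratio (construction value 1.25) drifts to
1.35 on this noisy accelerated reconstruction — exactly the kind of effect
the agreement tables of `run_experiment()` quantify cohort-wide.

A full synthetic study:

```r
rep <- run_experiment(experiment_config(n_phantoms = 20, seed = 2024))
rep$agreement   # one row per metric: bias, limits of agreement, ICC, CV
```

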