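---
title: "Simulating accelerated black-blood MRI of aortic aneurysms: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating accelerated black-blood MRI of aortic aneurysms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csaaa)
```

## The problem this package addresses

Abdominal aortic aneurysms (AAA) are managed by surveillance of the maximal
outer diameter; intervention is considered above 5.5 cm or for rapid growth.
3D black-blood MRI visualises the vessel wall and the intraluminal thrombus
(ILT), but a fully sampled high-resolution acquisition is slow. Compressed
sensing (CS) accelerates it by undersampling k-space and reconstructing with
a sparsity prior. The clinically relevant question is not pixelwise image
fidelity but whether the *measurements* that drive management — maximal
diameter, lumen and thrombus areas, thrombus signal ratios and type,
boundary sharpness, growth rates — survive the acceleration.

`csaaa` makes that question testable without patient data. It simulates the
whole chain on digital phantoms with analytic ground truth: phantom →
multi-coil k-space → undersampling → reconstruction → morphometry →
method-agreement statistics.

## The reconstruction model

The acquisition of coil $n$ is modelled as
$$ y_n = F_u(\mathrm{CSM}_n \odot x) + \varepsilon_n, $$
where $x$ is the image, $\mathrm{CSM}_n$ the coil sensitivity map, $F_u$ the
mask-restricted centred *unitary* Fourier transform, and $\varepsilon_n$
i.i.d. complex Gaussian noise. The reconstruction solves

$$ \hat{x} \;=\; \arg\min_x \; \tfrac12 \sum_{n=1}^{N}
   \bigl\lVert y_n - F_u(\mathrm{CSM}_n \odot x) \bigr\rVert_2^2
   \;+\; \lambda \lVert W x \rVert_1 , $$

a combined parallel-imaging / compressed-sensing formulation: the first term
enforces consistency with the acquired k-space samples, the second promotes
sparsity of the solution in a wavelet basis $W$.

Choices the cost function itself does not fix:

* **Solver.** Accelerated proximal gradient (FISTA-type) with a monotone
  safeguard: whenever the extrapolated step would increase the cost, a plain
  proximal step from the current iterate (guaranteed non-increasing for a
  step below the inverse Lipschitz constant) is taken instead, and the
  momentum restarts. The recorded cost trace is therefore non-increasing.
* **Step size.** With unitary FFTs, RSS-normalised maps and a projection
  mask, the normal operator satisfies $\|A^HA\| \le 1$ exactly, so the
  default step is 1. A power-iteration estimate is available
  (`step_rule = "power"`) for non-normalised inputs; the default avoids
  spending iterations re-deriving a bound that holds by construction.
* **Wavelet.** Orthogonal Daubechies-4 (8-tap), periodised, up to 3 levels
  per axis, applied separably along each array dimension. Orthogonality
  makes the $\ell_1$ proximal step exact (plain soft-thresholding) and
  preserves energy; both properties are tested. Axes whose length cannot be
  halved get fewer levels. The transform is implemented as cached orthogonal
  matrices per axis length — exact, simple, and fast at these volume sizes.
* **Scale of $\lambda$.** A regularisation weight quoted by a scanner
  implementation is meaningless without a data scale. The package
  normalises each dataset so the zero-filled adjoint image has maximum
  magnitude 1 and then applies $\lambda$ (default 0.002, with 10 iterations
  — the protocol's operating point) on that scale, making the value
  transferable across inputs. This convention is declared, not inferred.
* **Initialisation.** The zero-filled adjoint image; the complex image is
  kept throughout and magnitude is taken only at measurement time.

Coil sensitivities are estimated from the fully sampled k-space centre:
the calibration region is apodised with a Hann window over its extent,
inverse-transformed, divided by the root-sum-of-squares, and phase-aligned
to the first coil; the support is where the low-resolution RSS exceeds 5%
of its maximum. The reference arm — a stand-in for the conventional
(non-CS) protocol — is a fully sampled acquisition reconstructed by direct
coil combination $\sum_n \overline{\mathrm{CSM}_n}\,F^{-1}y_n / \sum_n
|\mathrm{CSM}_n|^2$.

## The undersampling mask

The phase-encode plane (the two undersampled dimensions; the readout is
always fully sampled) is covered by a variable-density Poisson-disc pattern
with elliptical support and a fully sampled central calibration ellipse
(default 4% of the in-ellipse area; the protocol states that the centre is
fully sampled but not its size). The minimum-distance radius grows linearly
with normalised elliptical radius, $r(\rho) = r_0(1 + \alpha\rho)$ with
$\alpha = 2$ by default — the density law is a standard choice; only
"variable density" is prescribed. $r_0$ is calibrated by bisection until
the sampled fraction of the ellipse is within 0.005 of $1/R$; at the
protocol acceleration $R = 5$ the mask samples 20% of the elliptical
k-space. The acceleration is interpreted *relative to the elliptical
region*, since both protocol arms use elliptical scanning; a rectangular
interpretation would differ by the ellipse fill factor ($\pi/4$).
Generation is greedy dart throwing over a seeded random permutation of the
candidate grid with a background-grid neighbour search (implemented in
C++); two accepted points at radii $\rho_1, \rho_2$ are never closer than
$\min(r(\rho_1), r(\rho_2))$. `mask_diagnostics()` verifies the distance
law per annulus and the point-spread-function incoherence claim directly.

## The digital phantom

A straight, axially aligned aorta (AAAs are largely immobilised by the
spine; tortuosity is out of scope) with a Gaussian fusiform bulge:
$r_\text{out}(z) = r_\text{neck} + (D/2 - r_\text{neck})
e^{-z^2/2\sigma^2}$, a constant 2 mm wall, and an ILT layer concentrated at
the bulge. Tissue intensities (arbitrary units): background 0.2, suppressed
lumen 0.3, iso-intense ILT 1.0, bright ILT 1.5, wall 0.9, psoas muscle 1.0,
spine 1.1 — chosen so the 1.2 ILT-to-muscle "bright" threshold and a
thrombus-to-lumen contrast ratio in the clinically reported range are
exercised. The four ILT types are constructed as: type 1 all bright, type 2
a contiguous angular sector (default half) bright, type 3 all iso-intense,
type 4 no ILT. Defaults: 48 × 64 × 64 voxels at 1.3 mm isotropic — a field
of view cropped around the aorta rather than the full abdomen, which keeps
simulations light without changing any contract — 4 receive coils (the
clinical body array has more elements; only smoothness and RSS
normalisation matter to the reconstruction), complex noise SD 0.03 per
component on unit-scale tissue (SNR ≈ 30), maximal diameter 4.85 cm (a
typical surveillance-cohort mean), bulge $\sigma$ 12 mm, apex ILT thickness
8 mm.

Labels are assigned by voxel-centre membership; intensities are averaged
over 2× supersampled sub-voxels, giving a partial-volume edge profile.
The truth record (maximal outer diameter and slice, areas at that slice,
construction ILT-to-muscle ratio, type) is computed from the radius
profiles analytically, never by re-measuring the raster. Coil maps are
smooth complex Gaussian bumps on a ring around the FOV, RSS-normalised and
phase-aligned to coil 1. What the phantom deliberately does *not* emulate:
pulse-sequence physics (relaxation, flow suppression), respiratory or
cardiac motion, ILT spatial texture (homogeneous classes plus noise), and
vessel tortuosity. Passing tests therefore certify the computational chain
under these conditions, not clinical performance.

## Morphometry

Cross-sections are taken per slice along the vessel axis. From the lumen
centre, 64 radial rays sample the intensity profile at quarter-voxel
spacing on a 2× Fourier-upsampled slice (magnitude MR images are
band-limited, so sinc interpolation is the natural sub-voxel interpolant;
a light Gaussian low-pass, σ = 0.35 voxel, is applied in the same pass).

* **Inner boundary** (lumen–thrombus): the innermost rising gradient peak
  reaching half the ray's strongest rising gradient, refined to sub-sample
  precision by the gradient-peak centroid.
* **Outer boundary** (outer wall surface): at 1.3 mm resolution the 2 mm
  wall flanked by bright thrombus is only marginally resolved, so competing
  gradient peaks make a max-gradient detector bistable. Instead the outer
  boundary is the first *sustained* fall of the profile below a fixed level
  between wall and background (35% of the robust intensity range above the
  low quantile), located by linear interpolation of the level crossing —
  a quantity that moves continuously with sub-voxel geometry in both the
  resolved and merged regimes. The search is limited to 14 mm beyond the
  inner boundary, which keeps muscle and spine out of reach.
* Failed rays are interpolated circularly from neighbours; a slice with
  more than 25% failures is flagged invalid. Per-angle radii are low-pass
  filtered to 6 angular Fourier harmonics (real cross-sections are smooth
  ovals; this suppresses voxel-phase oscillation of the contour). Areas are
  polygon integrals; the per-slice diameter is the maximal Feret width of
  the outer contour.
* **Maximal diameter**: per-slice diameters are screened against a running
  5-slice median, required to be unimodal walking outward from an apex
  located by a windowed minimum (a short run of corrupted slices cannot
  inflate it), and the reported maximum comes from a local quadratic fit of
  the diameter profile around the apex — the numerical analogue of finding
  the true maximum on multi-planar reformats. One consequence of the fit is
  that the reported maximum can sit marginally below the noisiest single
  slice; that slice is noise, not anatomy.
* **Signal regions**: the thrombus annulus lies between the inner contour
  and the outer contour shrunk by a 2 mm wall margin, with half-voxel edge
  margins; the lumen region is inside the inner contour; the muscle ROI is
  the eroded muscle label (or a user mask). The ILT-to-muscle and
  ILT-to-lumen ratios are mean-intensity ratios; whether the clinical
  "contrast ratio" is a mean ratio or a CNR-style expression is ambiguous,
  and the mean ratio is implemented.
* **ILT typing**: voxelwise ratio to the muscle mean over the thrombus
  annulus at the maximal slice; bright if > 1.2. Type 4 if the annulus area
  is below 0.5 cm²; else type 1 if the bright fraction ≥ 0.7, type 2 if
  ≥ 0.3, type 3 otherwise. The 0.7/0.3 cutoffs and the area floor
  operationalise the qualitative labels "dominantly bright" / "mixture";
  they are exposed as arguments.
* **Sharpness**: 1 / (20%–80% transition distance) in mm⁻¹, measured along
  the two orthogonal in-plane directions (both senses) through the section
  centre, for the inner and outer interfaces; plateau medians flanking the
  widest monotone segment define the edge amplitude. Closed forms used as
  oracles: a linear ramp of width $w$ gives $0.6w$; a Gaussian-blurred step
  of SD $\sigma$ gives $2\,\Phi^{-1}(0.8)\,\sigma = 1.683\sigma$.
* **Growth rate**: endpoint formula, (latest − baseline) diameter in mm
  over the follow-up in 365.25-day years; intermediate time points are
  ignored by definition.

All measurements are invariant under positive intensity scaling — every
threshold is relative.

### Known measurement limitations

The wall-only ring of a type-4 phantom (2 mm at 1.3 mm voxels) is below the
resolution at which a ±5% *area* claim is meaningful: a ±5% band on a
2.9 cm² ring corresponds to ±0.1 mm of radial localisation. Diameters,
lumen areas and thrombus-bearing ring areas meet their tolerances; the
type-4 ring area is reported but carries a systematic +10–20% width bias.
Sub-voxel diameter localisation is accurate to roughly ±0.05 mm after
contour and axial averaging, which bounds the accuracy of recovered growth
rates at about ±0.1 mm/year per subject for annual follow-up.

## Agreement statistics

Bland-Altman bias with 95% limits of agreement $\text{bias} \pm 1.96\,SD$
of the paired differences (sample SD); within-subject coefficient of
variation (root mean per-subject variance over the grand mean, ×100 — the
convention is ambiguous, so the SD-of-differences form is reported
alongside); intraclass correlation from the two-way mean-squares
decomposition, absolute-agreement single-measures ICC(A,1) by default
(appropriate for method comparison) with the consistency form selectable;
and Cohen's kappa for the four ILT types. These four are implemented from
their defining formulas and validated in the tests against independent
routes (`stats::aov` mean squares, contingency-table hand computations,
null simulations).

## The synthetic study

`run_experiment()` mirrors the surveillance comparison: a cohort of
phantoms with diameters uniform on 3–5.5 cm and ILT types cycling 1–4 is
imaged with both arms — fully sampled reference versus Poisson-disc $R=5$
plus CS reconstruction — measured, and tabulated as one agreement row per
metric plus a kappa for ILT typing. `longitudinal_series()` grows each
subject's diameter linearly at a subject-specific rate (mean 3.3, SD
3.1 mm/year, truncated to keep geometry feasible), measures every time
point with both arms, and recovers growth rates. `run_sweep()` evaluates
the λ × iterations grid (0.0005–0.004 × 10–40) against ground truth as
mean ± SD NRMSE (RMSE over the reference intensity range).

Problem sizes used by the test suite — 48 × 64 × 64 default phantoms, a
36 × 36 in-plane grid for unit fixtures, cohorts of 20 and 9 — were chosen
as the smallest sizes at which every geometric feature (wall, thrombus,
muscle, calibration region) spans enough voxels to be meaningful.

Master seeds derive per-phantom seeds, so every run is bit-reproducible;
all randomness flows through R's RNG (the C++ dart-throwing consumes a
pre-shuffled candidate order).

## Numerical edge cases

Degenerate inputs are defined rather than left to chance: ICC of exactly
identical columns is 1 (zero variance otherwise errors); kappa under
degenerate margins is 1 for perfect agreement and an error otherwise;
soft-thresholding at zero magnitude returns zero; acceleration 1 samples
the whole ellipse and short-circuits the radius calibration; a calibration
region exceeding the sampling budget, a geometry exceeding the grid (with
the offending slice named), an empty muscle ROI, non-increasing dates and
non-finite k-space all raise informative errors. The sharpness transition
distance is floored at the sample spacing.
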