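---
title: "Methods: Z-spectrum simulation, five-pool decomposition, and MRS quality control"
author: "cestr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Z-spectrum simulation, five-pool decomposition, and MRS quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cestr)
```

## The measurement and the model

Chemical exchange saturation transfer (CEST) MRI saturates exchangeable
solute protons with a frequency-selective RF pulse; exchange carries the
saturation to bulk water and reduces the water signal in proportion to
solute concentration and exchange rate. The Z-spectrum is the normalized
water signal $S/S_0$ as a function of the saturation offset $\Delta$ (ppm
relative to water at 0 ppm). `cestr` analyzes Z-spectra acquired (or
simulated) under 2&nbsp;µT, 1&nbsp;s continuous-wave saturation at
300.41&nbsp;MHz on a non-uniform grid: 0.2&nbsp;ppm steps on
$[-5,-4]\cup[4,5]$ ppm and 0.1&nbsp;ppm steps on $[-4,4]$ ppm
(91 offsets; `build_offset_grid()`).

The signal drop is decomposed into five Lorentzian lines,

$$1 - S/S_0(\Delta) \;=\; \sum_{i=1}^{5}
A_i \frac{(W_i/2)^2}{(W_i/2)^2 + (\Delta - c_i)^2},$$

one per proton pool: direct water saturation (0 ppm), semi-solid
magnetization transfer contrast (MTC, $-1.5$ ppm), relayed NOE
($-3.5$ ppm), creatine (2 ppm), and the combined amide/amine pool
(mobile proteins/peptides and glutamate, 3.5 ppm). $A_i$ is the peak
fractional drop, $W_i$ the full width at half maximum in ppm. We fit the
drop $1 - S/S_0$ rather than $S/S_0$ so all amplitudes are non-negative;
because the drop is an affine transform of the signal, the coefficient of
determination is identical on either scale. The per-pool "fitted integral"
reported by the pipeline is the area of the isolated fitted line over the
acquired window $[-5, 5]$ ppm, evaluated in closed form
($\int L = A \tfrac{W}{2}[\arctan\tfrac{b-c}{W/2} -
\arctan\tfrac{a-c}{W/2}]$). The window is configurable; the full acquired
window is the default because it is robust and needs no extra convention
for partially overlapping lines.

### Parameterization choices

The exact Lorentzian parameterization (FWHM vs. half-width, fraction vs.
percent) is a convention choice; `cestr` uses the standard FWHM form with
amplitudes as fractions of $S_0$. Pool positions are nominally fixed and
allowed to move only within small windows so the pools stay identifiable
on a ±5 ppm acquisition window:

| pool | center (ppm) | center bound | width bounds (ppm) | amplitude |
|------|-------------:|-------------:|-------------------:|----------:|
| water | 0 | ±0.2 | (0.5, 4) | (0, 1) |
| MTC | −1.5 | ±0.3 | (2, 10) | (0, 1) |
| rNOE | −3.5 | ±0.3 | (0.3, 3) | (0, 1) |
| creatine | 2 | ±0.3 | (0.3, 3) | (0, 1) |
| amide/amine | 3.5 | ±0.3 | (0.3, 3) | (0, 1) |

The MTC line is really a broad semi-Lorentzian background; bounding its
width in (2, 10) ppm keeps it from absorbing the narrow solute dips.

### Optimization

`fit_five_pool()` runs bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) with an analytic Jacobian and tight tolerances
(`ftol = ptol = 1e-15`). The start is a single deterministic, data-driven
point: each amplitude begins at a fixed fraction of the observed drop at
its nominal center (0.9 for water, 0.3–0.5 for the others), centers at
nominal, widths at pool-typical values (1.8/5/1.2/0.8/1.2 ppm). This start
recovers noiseless in-bounds models to ≈1e−13 across randomized
ground truths while keeping results exactly reproducible; an optional
randomized multistart (`fit_config(multistart = )`) exists for atypical
spectra but is off by default. A constant input returns the all-zero
model with $R^2 = 0$ by convention; non-convergence is reported through
the `converged` flag, never as an error. Missing samples (e.g. edge
points dropped by B0 correction) are removed from the objective, not
imputed.

## B0 correction (WASSR)

Static-field inhomogeneity shifts the apparent water frequency voxel by
voxel, which would misassign pool amplitudes. A low-power water
saturation shift referencing (WASSR) acquisition samples the direct-water
line on its own narrow grid; WASSR sweep settings vary between protocols,
so the package defaults — ±1 ppm sweep, 0.05 ppm steps, 0.3 ppm line
FWHM, 0.95 saturation depth — are package choices typical of small-animal
WASSR acquisitions, and all are configurable.

`wassr_center_frequency()` estimates the line center as the point of
maximal left–right symmetry: it minimizes
$\sum_\delta [S(c+\delta) - S(c-\delta)]^2$ over cubic-spline-interpolated
samples, scanned at 0.001 ppm resolution around the sampled minimum. The
symmetry objective is insensitive to the line depth and degrades
gracefully with noise (mean error ≈0.003 ppm at noise SD 0.01 on the
default line). A minimum at the sweep edge raises an error, since the
shift is then outside the measurable range. `b0_correct()` resamples the
Z-spectrum at `offsets + shift` by cubic spline; samples that would need
extrapolation are marked missing.

## The physical oracle

Alongside the phenomenological Lorentzian-sum generator, the package
integrates the coupled Bloch–McConnell equations
(`simulate_zspectrum_bm()`): three magnetization components per pool,
two-site exchange of each solute with water under detailed balance, and
constant-amplitude irradiation. Under continuous-wave saturation the
system is linear, $\dot y = Ay + b$, so the constant matrix $A$ is also
the exact Jacobian handed to the implicit (BDF) integrator at relative
tolerance 1e−8. This simulator shares no code with the Lorentzian model
and serves as the physical cross-check: for a dilute, slowly exchanging
solute both models place the solute signal-drop minimum at the same
offset (tested at 1 µT, where the direct-water shoulder does not swamp
the dip).

## The digital phantom

`default_phantom_spec()` emulates a single-slice small-animal
embryo-imaging session at desk scale: a
single 2D slice with ten elliptical "embryo brain" ROIs of ~51 voxels
each (five control, five exposed; about 510 foreground voxels total), a
smooth left–right linear B0 ramp spanning ±0.2 ppm, and Gaussian noise of
SD 0.005 on the normalized signal. Exposure multiplies the true amide
amplitude by 1.3 and the rNOE amplitude by 1.2 — the direction and rough
size of the drug-exposure hyperintensities the pipeline is designed to
detect. Gaussian noise on the normalized signal is the default noise
model because at the SNR of normalized Z-spectra (≫3) a Rician magnitude
model coincides with it (a Rician option is provided).
Background voxels carry `NA` spectra and a zero mask label, never zeros,
so fits cannot silently run on air. Every stochastic operation takes an
explicit integer seed and restores the global RNG state; identical
specifications and seeds give bit-identical phantoms.

What the phantom does **not** emulate: within-group biological
variability between ROIs (all control ROIs share one ground truth),
motion/ghosting/Gibbs artifacts (screened manually in practice),
partial-volume mixing at ROI edges, and spatially correlated noise.
Passing tests therefore demonstrate correctness of the estimation chain
under the stated noise model, not robustness to every in-vivo
confound.

## Image pipeline and quality control

`fit_image()` runs per voxel: WASSR center → B0 correction → five-pool
fit; a WASSR failure flags the voxel and the pipeline continues.
`make_contrast_map()` produces pixel-by-pixel fitted-integral maps whose
QC mask requires convergence and $R^2 \ge 0.8$ (the exclusion rule,
applied at voxel level; the threshold is inclusive, so $R^2 = 0.80$
passes). `apply_qc()` reports exclusions and flags a whole dataset when
fewer than half its foreground voxels pass (floor configurable).
`roi_aggregate()` averages map values over QC-passing voxels; an ROI with
no passing voxel is reported missing, never as zero.

Whether group quantitation should come from per-pixel fits or from
ROI-averaged spectra is a protocol choice, so both paths exist.
Group-level simulations
(`simulate_group_study()`, `power_two_group()`) default to the
ROI-averaged mode — one fit on the mean B0-corrected spectrum per ROI —
which raises spectral SNR by roughly the square root of the ROI size and
keeps repeated power simulations cheap; the per-voxel mode drives the
contrast maps and the QC analyses. At the phantom's conditions (effect
1.3 at 3.5 ppm, n = 5 ROIs per group, noise SD 0.005) the two-tailed
pooled t test on ROI amide integrals rejects at α = 0.05 in essentially
every seeded replicate, and at effect 1.0 the rejection rate sits at the
nominal α.

## MRS preprocessing and quality gates

The ¹H-MRS chain mirrors a 2048-point, 3005 Hz acquisition whose first 68
samples are digital-filter dead time: `truncate_and_zerofill()` drops the
leading 68 points and appends 68 zeros (length contract 2048);
`apodize()` multiplies by $e^{-\pi \cdot LB \cdot t}$ with LB = 5 Hz —
the convention in which LB is the added Lorentzian FWHM in Hz, stated
explicitly because conventions differ by a factor of $\pi$;
`fid_to_spectrum()` is a centred FFT with the ppm axis referenced to the
carrier; `phase_correct()` applies
$e^{-i(\varphi_0 + 2\pi f t_{fo})}$ with a default first-order time of
−0.22 ms, and when no zero-order phase is supplied it is estimated by
maximizing the real integral over the metabolite window, a standard
automatic criterion. `frequency_align()` centers the dominant peak near
the N-acetyl aspartate methyl resonance (2.01 ppm) with parabolic sub-bin
refinement, and flags spectra with no detectable peak rather than
shifting them.

Quality gates apply the inclusion rules with inclusive bounds:
SNR ≥ 12 and water linewidth ≤ 0.1 ppm for spectra; for metabolites, a
group-mean Cramér–Rao lower bound ≤ 30% for inclusion in statistics and
an individual CRLB ≤ 20% for per-measurement reliability. SNR is the
baseline-subtracted real peak height over the real-part SD of a
signal-free region; with apodization the frequency-domain noise is
correlated between bins, so a wide noise window gives a much more stable
SD estimate — the tests use 3 ppm windows for this reason. Full basis-set
quantitation is deliberately **not** re-implemented: `lc_quantify()` is a
simplified stand-in (non-negative least squares of single-peak synthetic
lineshapes, CRLBs from the linearized covariance
$\sigma^2 (X^\top X)^{-1}$) that exists so the CRLB rules are executable
and testable; its institutional units are self-consistent within the
synthetic world only, and any correspondence to a real metabolite panel
(NAA, creatine, glutamate, ...) is name-level only.

## Statistics

Two-group comparisons use the classical pooled-variance two-tailed t test
("Student's t" taken at face value; Welch's correction is a flag).
Three or more groups use one-way ANOVA followed by Tukey's HSD
(studentized-range adjusted p-values); a generic two-crossed-factor
ANOVA with type-II sums of squares is included and exercised only by
synthetic tests. No multiple-testing correction is applied across
measures beyond Tukey within a comparison — the usual practice in
exploratory preclinical comparisons of this kind. Degenerate inputs use fixed conventions: zero pooled
variance gives p = 1 (equal means) or p = 0 (unequal); an all-constant
ANOVA reports p = 1. Significance labels follow the ladder
`****` < 0.0001, `***` < 0.001, `**` < 0.01, `*` < 0.05, `#` < 0.1
(strict inequalities), `ns` otherwise.

## Summary arithmetic

`tissue_ratio()` and `phenotype_summary()` derive summary tables from raw
counts and group means, rounding half-even at the displayed precision.
Ratios are ratios of group means, since per-animal pairing is not part of
the tabulated inputs; a ratio computed per animal and then averaged can
differ slightly (for the shipped table, embryo-brain:plasma is 0.08 from
the means). The package always computes the arithmetic from the inputs
rather than accepting externally quoted figures, so any inconsistency in
a source table (e.g. a per-litter count that does not match its totals)
stays visible in the output.

## Problem sizes and numerical conventions

The test suite and the acceptance script use: 50 randomized models for
exact recovery (tolerance 1e−6 on all 15 parameters; $R^2 \ge 1 -
10^{-10}$); 100 random pools for the closed-form-vs-trapezoid integral
oracle (relative 1e−6, 0.001 ppm trapezoid); 100 seeds for noisy WASSR
recovery (mean error < 0.02 ppm at noise SD 0.01); 100 seeded phantom
replicates per effect level for power and size; a 510-voxel phantom with
10 corrupted voxels for the QC gate; 2000 replicates for ANOVA type-I
error; and 500 replicates for quantitation unbiasedness (within 2
standard errors). These sizes keep each property statistically
informative while the whole suite completes in a few minutes on one CPU.
Floating-point conventions: offset grids are snapped to exact multiples
of the fine step; B0 correction treats source offsets within 1e−9 ppm of
the acquired range as interior; all JSON output is written at full
precision.
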