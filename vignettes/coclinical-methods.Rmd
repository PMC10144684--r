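---
title: "Quantitative MRI and imaging-omics methods in coclin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MRI and imaging-omics methods in coclin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coclin)
```

# Scope

`coclin` implements the analysis core of a co-clinical treatment-response
study: a cohort of patients and a matched cohort of patient-derived
xenografts (PDX) imaged with diffusion-weighted (DW) and dynamic
contrast-enhanced (DCE) MRI before (T0) and during (T1) therapy, with bulk
expression profiling alongside. The package covers the quantitative maps,
the lesion biomarkers, the response tables and waterfall orderings, an
on-treatment expression simulator, and the rank-based imaging-omics
association — plus a digital phantom generator that provides analytic
ground truth for all of it. Pharmacokinetic DCE modelling
(K^trans^, v~e~, k~ep~, v~p~), RECIST/mRECIST category assignment, and
upstream RNA-seq quantification are deliberately out of scope.

# Parameter maps

## Apparent diffusion coefficient

DW-MRI signal at diffusion weighting $b$ (s/mm^2^) is modelled as the
monoexponential decay

$$S(b) = S_0 \, e^{-\mathrm{ADC}\cdot b},$$

and `fit_adc_map()` estimates ADC per voxel by least squares. The fit is
initialised at the closed-form log-linear solution (ordinary regression of
$\log S$ on $b$) and refined by a damped Gauss-Newton iteration in
$(S_0, \mathrm{ADC})$ with ADC bounded to $[0, 0.01]$ mm^2^/s — wide
enough for free water at body temperature with margin. On noiseless data
the log-linear start is already the global optimum, so the refinement
changes nothing and the fit reproduces a generating ADC to floating-point
precision; the refinement matters only under noise, where minimising
residuals in signal space rather than log space avoids the variance
distortion of the log transform. Voxels containing any nonpositive signal
are reported as `NaN` rather than clipped: the log-linear start is
undefined there and clipping would bias low-signal voxels systematically.
Default b-sets follow the two acquisition settings the package emulates:
0/150/700 s/mm^2^ preclinically and 0/100/600/800 s/mm^2^ clinically.

## Signal enhancement ratio

The DCE analysis is semi-quantitative. Per voxel,

$$\mathrm{SER} = \frac{S_\mathrm{early} - S_\mathrm{baseline}}
                      {S_\mathrm{late} - S_\mathrm{baseline}},$$

with $S_\mathrm{baseline}$ the mean of the first 10 frames,
$S_\mathrm{early}$ the post-baseline peak, and $S_\mathrm{late}$ the
signal at the frame nearest the voxel's peak time plus 6 minutes
(`late_offset = 360` s). Three conventions needed fixing:

* **Peak definition.** A whole-ROI reading defines one peak for the
  lesion; a voxel-wise map needs a per-voxel peak so that the ROI
  mean/median of the map is meaningful. The voxel-wise definition is the
  default; `peak = "roi"` switches to the ROI-aggregate peak time. On a
  lesion with a spatially uniform curve the two coincide, which is how the
  option is tested.
* **Peak search window.** The search starts at the first post-baseline
  frame: pre-contrast frames cannot enhance, and a noise spike in the
  baseline must not be declared the peak. Ties go to the earliest frame so
  output is deterministic.
* **Late frame beyond the acquisition.** The nearest-frame rule clamps to
  the final frame; affected voxels are flagged in the map's `clamped`
  attribute instead of being dropped or erroring.

Non-enhancing voxels make the denominator vanish; any voxel with
$|S_\mathrm{late} - S_\mathrm{baseline}|$ below `epsilon` is `NaN`. The
default epsilon is $10^{-6}$ times the series maximum — scale-free, since
MRI signal units are arbitrary. SER itself is invariant under affine
rescaling of the series, which the suite checks directly.

# Lesion features

`extract_lesion_features()` reduces a mask plus maps to the biomarker set
used downstream: longest diameter, volume, and mean/median ADC and SER.
The diameter is measured in-plane per axial slice (the third array axis),
matching the RECIST-style clinical reading; a full-3D variant sits behind
`full_3d = TRUE`. Distances run between voxel centres, a deterministic
convention that underestimates a continuous diameter by up to one voxel —
the tests carry exactly that tolerance. The implementation prunes each
slice to its convex hull before the pairwise scan and is checked for
exact equality against a brute-force all-pairs oracle. Volume is voxel
count times voxel volume; median uses midpoint averaging on even counts.
`caliper_volume()` implements the bench formula
$\ell \times w^2 \times 0.5$ used to size PDX tumors for randomization
(175 mm^3^ at $\ell = 14$, $w = 5$).

# Response assessment

The response rate of a feature is its percent change from baseline,
$100\,(x_{T1} - x_{T0})/x_{T0}$; percent was chosen over a raw fraction
because waterfall axes conventionally read in percent.
`build_response_table()` pairs T0 with T1 per subject and lesion and
reports subjects missing a timepoint in an explicit exclusion table.
`waterfall_order()` sorts ascending (best response first) with
lexicographic subject-id tie-breaks, ordering the patient and PDX cohorts
independently for side-by-side display. Response *categories* (RECIST 1.1,
mRECIST, RCB) are intentionally absent.

# On-treatment expression simulation

Where real on-treatment transcriptomics is unavailable, `coclin` simulates
it from baseline: per sample, four multiplicative factors are drawn
uniformly from $[0.5, 1.5]$ and fixed for that sample; each gene is
multiplied by one of the four, chosen uniformly. Uniform draws are the
least-informative reading of "picked at random" for both choices. The full
factor vector and per-gene assignment are returned for audit, and the
per-sample squared correlation between baseline and simulated counts is
attached as a diagnostic. On moderately dispersed real count data that
r^2^ lands around 0.5-0.8; on synthetic data it is a property of the count
distribution's dispersion (heavier-tailed baselines give higher r^2^), so
the simulator reports and optionally warns, but never fails, outside that
band.

Seeding uses one child stream per sample, derived as a deterministic
sequence from the master seed: appending samples to a cohort extends the
sequence without rewriting earlier samples' simulations, which the suite
verifies bit-for-bit. Patient (normalized) and PDX (raw count) tables pass
through the identical operation; no normalization is inserted.
`harmonize_gene_sets()` restricts both cohorts to their shared symbols in
lexicographic order before any cross-cohort step, erroring (not silently
emptying) on disjoint sets.

# Imaging-omics association

`spearman_associate()` correlates each gene with a per-sample feature —
typically the baseline-relative change of an imaging biomarker via
`delta_feature()` — using Spearman's rank correlation with average-rank
ties. Genes split by correlation sign into a top (positive) and bottom
(negative) list, ranked by $|\rho|$ then p-value then symbol, truncated at
500 by default and always at the sign boundary: "top" means positively
associated even when fewer than 500 genes qualify.

p-values use the t-approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ for $n > 9$. PDX arms are tiny (three
animals per arm is typical), so for $n \le 9$ the exact permutation null
of Spearman's statistic is used instead, computed by full enumeration of
the $n!$ rank permutations and cached per $n$. The exact distribution
presumes untied data; a tied gene at small $n$ falls back to the
t-approximation, mirroring the behaviour of standard references. BH
q-values are added across all tested genes — a conventional addition for
ranked association output — with raw p always reported alongside.
`cohort_overlap()` produces the Venn partition of the selected lists, and
`volcano_data()`/`plot_volcano()` the $(\rho, -\log_{10} p)$ table and
plot. Delta-vs-delta analyses default to absolute expression differences;
a log-ratio is a caller-side transform of the inputs.

# Digital phantoms and the synthetic cohort

`make_dwi_phantom()` and `make_dce_phantom()` build ellipsoidal lesions on
regular grids with exact digitisation at voxel centres. The DWI phantom
evaluates the forward diffusion model with the truth ADC inside the lesion
and a distinct background ADC outside; the DCE phantom builds a
piecewise-linear curve — flat 10-frame baseline, linear rise, monotone
washout — whose level at the frame nearest peak + 6 min is chosen to
invert the SER formula exactly, so a noiseless phantom recovers the truth
to $10^{-9}$ relative error. Curves with SER < 1 (persistent late
enhancement) would put their true maximum after the nominal peak and are
excluded by construction. Noise is additive Gaussian, seeded.

`make_cohort()` assembles the full study: 21 patients and 9 PDX by
default (the prototyping scale of the co-clinical setting emulated — three
animals per treatment arm), each with T0/T1 studies, responders drawn at
`responder_fraction` with volume changes from the `effect` ranges
(responders $[-70\%, -40\%]$, non-responders $[-5\%, +25\%]$ — a clear
separation chosen so response classes are unambiguous at phantom
resolution), ADC rising and SER falling under response as cellularity
drops. Baseline expression is log-normal (log-SD 1.5, a typical bulk
RNA-seq dispersion); 50 planted genes couple log-linearly to the
standardized volume change with slope 1.2 against residual log-SD 0.4 —
the generator's reference effect size, strong enough that recovery into
the default lists is expected in essentially every seeded replicate, which
is what the recovery suite measures. A `imaging = "none"` switch generates
truth and expression without voxel data for association-scale replication;
`"full"` phantoms use a 24 x 24 x 12 grid (1.25 x 1.25 x 2.5 mm
clinically, 0.45 x 0.45 x 0.9 mm preclinically) — small enough that the
end-to-end pipeline with 60 studies runs in seconds while leaving lesion
digitisation errors within the tolerances stated above.

What the generator does *not* emulate: rician MRI noise, motion and
partial-volume effects, non-ellipsoidal or infiltrative lesion geometry,
batch structure or library-size variation in counts, and any real
biological coupling between imaging response and expression beyond the
planted monotone signal. Passing tests therefore demonstrate correctness
of the computations and of signal recovery under the stated generative
model, not clinical performance.

# Determinism and I/O

Everything stochastic takes an explicit seed; the pipeline
(`run_pipeline()`) writes only plain-text outputs (CSV/TSV/JSON) with no
timestamps, and a rerun under the same cohort and seed is byte-identical —
checked by hashing every output file. Imaging interchange is NIfTI-1 with
a JSON sidecar carrying `b_values` or `frame_times`; expression tables are
TSV with a `gene_symbol` first column, validated on read with the
offending line reported. A thin command-line front end
(`inst/scripts/coclin.R`) exposes the map fitting, simulation, and
pipeline stages for shell use.
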