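---
title: "Worst-case robustness evaluation of IMPT plans: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Worst-case robustness evaluation of IMPT plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imptrobust)
```

## The evaluation problem

Proton dose distributions deform, rather than translate, under setup and
range errors, so the photon-era PTV margin concept does not transfer to
intensity-modulated proton therapy (IMPT). The accepted clinical surrogate
is scenario-based worst-case evaluation: the treatment planning system
recalculates the dose under a small set of systematic perturbations, and
the plan is judged on the resulting family of distributions.

This package operates on exactly that input: a nominal dose grid $D_0$ and
twelve scenario grids $D_1,\dots,D_{12}$ on one common voxel lattice, each
scenario combining one signed setup shift along one anatomical axis (L/R,
A/P, S/I) with one sign of the range uncertainty. `build_scenario_table()`
enumerates the frozen ordering (U1 = $(+s,0,0,+r)$, U2 = $(+s,0,0,-r)$, …,
U12 = $(0,0,-s,-r)$); scenario ids are load-bearing because reports name
the worst scenario per metric. The magnitudes follow clinical practice:
$s$ = 5 mm (prostate) or 3 mm (head and neck), $r$ = 3.5%.

Grid alignment is a hard precondition, never a repair step: all 13 grids
and every ROI mask must share shape, spacing and origin (within $10^{-6}$
mm), because every quantity below is defined voxel-by-voxel across
scenarios. Resampling is deliberately out of scope; a mismatch raises an
error.

## The five methods

With $i = 0$ the nominal scenario:

* error-bar dose distribution
  $\mathrm{ebDD}(v) = \max_{i=0..12} D_i(v) - \min_{i=0..12} D_i(v)$;
* root-mean-square error dose
  $\mathrm{RMSED}(v) = \bigl[\tfrac{1}{12}\sum_{i=1}^{12}
  (D_0(v)-D_i(v))^2\bigr]^{1/2}$ (nominal excluded from the sum, as it is
  the reference);
* voxel-wise extrema $\min_i D_i(v)$, $\max_i D_i(v)$ over $i = 0..12$ —
  generally not physically realizable, since different voxels may take
  their extremum in different scenarios;
* the physical-scenario worst case: each DVH metric evaluated on all 13
  distributions, reporting the worst single-scenario value
  (`band_metric_summary()`);
* the DVH band: the 13 cumulative DVHs on shared dose edges with their
  pointwise envelope (`compute_dvh_band()`), its width summarized by the
  per-metric bandwidth (max − min of the 13 values).

Two identities anchor the implementation and its tests:
$\mathrm{ebDD} \equiv \max - \min$ holds bit-for-bit because both sides are
computed from the same reductions, and the DVH of the voxel-wise minimum
lies at or below every scenario DVH pointwise (likewise the maximum above),
so voxel-wise worst-case metrics are always at least as conservative as the
physical-scenario worst case — for every ROI, metric, and seed. The test
suite checks both against naive per-voxel loop oracles.

On the RMSED divisor: the method's name implies a *mean* square, so the sum
is divided by 12 before the root. The alternative root-sum-square reading
differs by the constant $\sqrt{12}$, which cannot change any correlation or
ranking; `compute_rmsed(mean = FALSE)` provides it.

## DVH metrics: estimator choices

Headline metrics are computed from exact sorted voxel doses, never from a
binned curve, so they carry no bin-width sensitivity:

* $D_{p\%}$ = the $\lceil pN/100 \rceil$-th largest in-ROI voxel dose
  (equivalently, the largest dose received by at least $p\%$ of the
  volume);
* $D_{v\,\mathrm{cc}}$ = the $\lceil v/\text{voxel volume} \rceil$-th
  hottest voxel — a conservative ceiling rule with no sub-voxel
  interpolation, erring toward reporting hotter doses;
* $D_\mathrm{mean}$ = the arithmetic in-ROI mean;
* $V_{x\%}$ = percent of ROI volume at or above $x\%$ of the prescription
  (prescription-relative, as clinical prostate criteria are stated).

Curves exist for banding and export only. Two consistency properties bound
the discretization: the curve-inverted $D_{p\%}$ agrees with the exact one
within one bin width, and the mean reconstructed from the differential
histogram agrees within half a bin. Default dose bin: 0.05 Gy.

Worst-direction bookkeeping is explicit in `metric_spec()`: target coverage
(CTV D95%) is `lower_is_worse`; all OAR metrics are `higher_is_worse`. The
worst scenario per metric is reported with ties broken toward the lowest
scenario index (nominal counting as index 0).

## EVH / RVH and their AUC

`compute_vvh()` histograms the in-ROI ebDD or RMSED values with the same
cumulative-descending construction as a DVH. The AUC integrates volume as a
fraction (0–1), so its unit is Gy and it is comparable across ROIs of
different volume; by the survival-function identity it equals the ROI-mean
variation, and the implementation is required (and tested) to agree with
the direct mean within half a bin. A percent-volume axis (AUC × 100) is
available as an option; a global axis convention cannot affect any
correlation result.

Two numerical conventions matter here. First, the error axis stops exactly
at the maximum in-ROI variation, so a uniform variation $c$ integrates to
exactly $c$ and a zero map to exactly 0. Second, the default error bin is
0.01 Gy — finer than the DVH dose bin — because per-voxel variations inside
a robustly optimized target are an order of magnitude smaller than doses;
with a coarser bin the AUC of a robust CTV would be dominated by
discretization rather than signal.

## The synthetic cohort: what it emulates, and what it does not

The generator replaces the TPS planning-and-recalculation loop with an
analytic model chosen for closed-form oracles over physical realism:

$$D(x) = R_x \cdot S(d(x)) \cdot M(x) + \varepsilon(x), \qquad
S(d) = \frac{1}{1 + e^{d/\sigma}}$$

where $d$ is a scaled-radius signed distance from the CTV surface expanded
by the robust margin (negative inside), $\sigma$ is the penumbra scale,
$M$ is a small linear dose tilt along the beam axis, and $\varepsilon$ is
Gaussian calculation noise.

Scenario doses are *recomputed* from this model, not resampled from the
nominal grid: a setup shift evaluates the model at $x - \text{shift}$
(masks stay put — evaluation is in the planning anatomy), and the range
error displaces the distal falloff along one beam axis by
$r/100 \times$ depth-to-edge. Because everything is analytic there is no
interpolation anywhere; at integer-voxel shifts the scenario grid equals
the translated nominal grid exactly, which the tests exploit as an oracle.
The noise field is drawn once per plan and shared by all 13 scenarios
(deterministic recalculation texture), which also makes zero-magnitude
scenarios bitwise equal to nominal — the degenerate-collapse tests depend
on that.

Default parameters, with reasoning:

| parameter | default | why |
|---|---|---|
| grid | $50^3$ voxels at 3 mm | covers a 15 cm anatomy at clinical dose-grid resolution while keeping a 20-plan cohort evaluable in seconds |
| penumbra $\sigma$ | 3 mm | an 80–20 falloff of $\approx$ 8 mm, typical of combined distal/lateral proton penumbra |
| robust margin | 18 mm (prostate), 15 mm (head and neck) | setup magnitude + range excursion + $\approx 3\sigma$, so every *single* scenario keeps CTV D95 within a few percent of nominal, as robust optimization achieves |
| plateau tilt | 2–5% per 100 mm, per plan | real IMPT target doses are heterogeneous at the percent level; a perfectly flat plateau would make in-target variation pure numerical noise |
| noise | 0.02 Gy SD | sub-0.1%-of-Rx calculation texture |
| prescriptions | 36.25–70 Gy (prostate), 54–70 Gy (head and neck) | spans the clinical range so %Rx normalization is exercised |

Each plan carries an abutting OAR straddling the falloff (high-dose
regime), a mid-dose structure, and distant low-dose structures, so the
<50% Rx / ≥50% Rx grouping is populated; OAR centers are skewed off the
pure shift axes so that different scenarios dominate different OAR
subregions — with strictly axis-aligned placement a single scenario
dominates every voxel and the voxel-wise and physical-scenario worst cases
coincide identically, which is degenerate (though the near-unity
correlation between the two is expected regardless and survives on this
geometry).

This geometry also reproduces the qualitative structure the methods were
designed to reveal: variation concentrates in the 5–15 mm peri-target
gradient shell rather than inside the CTV; the CTV's DVH band is far
narrower than the abutting OAR's; and because each scenario erodes a
*different* cap of the target surface while the voxel-wise minimum pools
all of them, the voxel-wise D95 is strictly more conservative than the
physical-scenario worst case (by a fraction of a percent of Rx on these
phantoms).

What the phantom does **not** emulate: CT images and Hounsfield-unit
scaling (range errors act geometrically along a single beam axis),
multi-field dose composition, anatomical deformation, fractionation of
random errors, and any specific optimizer's trade-offs. Consequently,
passing tests demonstrate the correctness and internal consistency of the
*evaluation* layer and the direction of its clinical findings, not the
absolute magnitudes a clinical cohort would produce — correlation floors in
the acceptance suite (r > 0.9) are deliberately set below clinically
reported values, and conservativeness gaps are smaller than clinical ones
because analytic plans are cleaner than real ones.

## Cohort comparison layer

`build_method_table()` emits one row per (plan, ROI, metric) joining the
five methods; dose-valued entries are normalized to %Rx (volume-valued
$V_{x\%}$ entries are already percentages and enter as such — Pearson r is
invariant to per-column affine rescaling, so the mixture is harmless). Each
OAR row is assigned to the low-/high-dose group from its nominal value;
for volume-valued metrics the ROI's nominal mean dose stands in, since a
volume percentage is not commensurable with 50% of Rx. The nominal scenario
defines the grouping because it is the plan of record.

`pearson_matrix()` reports all 10 method pairs per stratum (CTV rows, OAR
rows) with two-sided p-values from the t-distribution with $n-2$ df,
unadjusted (as is conventional for descriptive method-comparison tables),
plus a clearly separate Holm-adjusted column. A constant column yields a
flagged row rather than a silent NaN. `summarize_conservativeness()`
reports box-plot quartiles of the paired difference (band-worst − voxel-wise
worst for coverage, reversed for OARs), paired on identical
(plan, ROI, metric) keys, in %Rx.

## Degenerate inputs and numerical edges

* Zero uncertainty magnitudes are legal throughout and collapse everything:
  ebDD = RMSED = 0, bandwidth = 0, both worst cases equal the nominal
  metric. This is a tested contract, not an accident.
* Empty ROIs, non-finite doses, negative spacings, lattice mismatches,
  missing scenarios, and requests for more absolute volume than the ROI
  holds all raise distinct classed errors (`impt_error_*`); the CLI maps
  validation errors to exit code 2 and internal-consistency violations
  (e.g. a broken map identity) to 3.
* `compute_maps()` re-verifies its own invariants
  ($\min \le D_0 \le \max$, ebDD $\equiv$ max − min, non-negativity)
  before returning.
* All randomness is seed-derived (per-plan seed =
  $(10007 \cdot \text{seed} + \text{plan index}) \bmod (2^{31}-1)$, so
  nearby root seeds do not share plans) and RNG state is restored after every internal draw, so package calls
  never perturb the caller's random stream and reruns are bit-identical.

## Problem sizes

The shipped test suite and the acceptance script evaluate a 20-plan mixed
cohort (10 prostate + 10 head and neck, $50^3$ grids, 13 scenario doses
per plan, 110 ROIs, 110 DVH points) in well under a minute on one CPU;
formula oracles run on $16^3$ random scenario sets against brute-force
loops. These sizes were chosen as the smallest that exercise every code
path and populate both dose groups and both strata convincingly.

## Known limitations

* Distance to an ellipsoid is approximated by a scaled-radius formula
  (exact along the shortest semi-axis, an underestimate elsewhere); for
  the moderate anisotropies the generator samples this only perturbs the
  geometry knobs, never the evaluation layer.
* DICOM support is import-only RT Dose (uncompressed little endian, axial
  orientation); RTSTRUCT contour rasterization is a separable problem and
  masks must arrive as label volumes.
* The 12-scenario grid is fixed; 21-scenario or probabilistic sampling is
  out of scope by design.
* D$_{p\%}$/D$_{cc}$ interpolation conventions differ between commercial
  systems; the exact-sorted-voxel estimators here are deterministic and
  documented, and the curve-consistency properties bound the effect of the
  choice.
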