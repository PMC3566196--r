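---
title: "Methods: flow quantification, compliance estimation and cohort statistics"
author: "cranioflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flow quantification, compliance estimation and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cranioflow)
```

# Overview

`cranioflow` implements an MRI-based analysis of intracranial hemodynamics and
hydrodynamics. Its inputs are two retrospectively gated velocity-encoded cine
phase-contrast series covering one cardiac cycle in 32 phases: a high-VENC
series (70--90 cm/s) for the fast arterial and jugular flows and a low-VENC
series (7--9 cm/s) for the slow secondary veins and the craniospinal CSF. From
these it derives, per subject:

* volumetric flow waveforms of the four cervical arteries (RICA, LICA, RVA,
  LVA), both internal jugular veins (RIJV, LIJV), the three secondary venous
  channels (vertebral, epidural and deep cervical veins) and the CSF space;
* the drainage summary: total cerebral blood flow (tCBF, sum of the four
  arterial cycle means), total jugular venous flow and the secondary venous
  fractions, expressed in percent of tCBF;
* the cervical CSF stroke volume;
* the intracranial volume-change waveform (ICVC), the CSF pressure gradient
  (PTP-PG), the intracranial compliance index and an MR-based estimate of
  intracranial pressure (MRICP);
* matched-cohort statistics (rank-transform mixed-effects comparison,
  Mann-Whitney U, Spearman correlation).

No scanner data ship with the package. A phantom generator produces synthetic
cine series with analytic ground truth, and per-subject values of a published
30-subject matched cohort are packaged as plain-text tables so that the group
summaries and the statistical battery can be reproduced end to end.

# The phantom: Womersley flow as analytic ground truth

Each lumen is modelled as a rigid circular tube carrying fully developed
laminar pulsatile flow driven by an axially uniform pressure gradient with at
most 8 Fourier harmonics (band-limited, so 32-phase sampling is alias-free).
For a driving gradient $G_n e^{i\omega_n t}$ (we use $G = -\partial p /
\partial z$, in dyn/cm$^3$) the axial velocity is the Womersley solution

$$
\hat u_n(r) \;=\; \frac{G_n}{i\rho\omega_n}\left(1 -
  \frac{J_0(i^{3/2}\alpha_n\, r/R)}{J_0(i^{3/2}\alpha_n)}\right),
\qquad \alpha_n = R\sqrt{\omega_n \rho / \mu},
$$

with the steady term giving the Poiseuille parabola $G_0 (R^2 - r^2)/(4\mu)$
and no-slip at the wall. $J_0$ and $J_1$ of complex argument are evaluated by
power series (accurate to about $10^{-10}$ relative over the $\alpha \le 10$
range used; no installed package provides complex-argument Bessel functions).
The cross-sectional flow has the closed form
$Q_n = (G_n \pi R^2 / i\rho\omega_n)\,
(1 - 2 J_1(\zeta)/(\zeta J_0(\zeta)))$ with $\zeta = i^{3/2}\alpha_n$, so
every phantom carries exact flow and pressure-gradient waveforms alongside the
images. The solution is validated in the test suite against an independent
finite-difference boundary-value solve of the radial momentum ODE.

Velocity maps to image phase as $\varphi = \pi v / \mathrm{VENC}$, wrapped
into $(-\pi, \pi]$; Gaussian noise of configurable SD is added in the phase
domain (not complex-Rician - adequate at the SNRs simulated and with simpler
variance bookkeeping). Pixels sample the analytic profile at their centres,
with no subpixel integration: this keeps the discretised flow oracle exact on
the same grid the quantification uses, at the cost of a small partial-volume
rim error (the integrated phantom flow agrees with the analytic waveform to
better than 2% relative RMS at 8 or more pixels per radius). The CSF channel
is modelled as a circular tube rather than an annulus, preserving the exact
oracle. Cardiac period defaults to 1.0 s (not reported per subject in the
source cohort) and is configurable.

What the phantom does **not** emulate: k-space acquisition, eddy-current or
Maxwell-term phase offsets, vessel wall motion, through-plane motion and
non-circular lumina. Passing tests on phantoms therefore demonstrate the
correctness of the numerics and the internal consistency of the pipeline, not
robustness to all artefacts of real scanner data.

A cohort generator complements the image phantom: it draws per-subject
drainage and hydrodynamic quantities from truncated normal distributions at
configurable group means and SDs (defaults: the packaged cohort's group
rows). Truncation is mean-preserving - the underlying location is solved
numerically so the truncated mean equals the configured mean - because plain
truncation at [0, 100] would bias a 60.9 +/- 21 percent fraction by about
-1.4. The per-subject constraint jugular% + secondary% <= 100 is enforced by
truncating the secondary fraction to the remaining headroom.

# Pulsatility-based segmentation

Lumen pixels are identified from the full velocity time series: the operator
(or test harness) supplies one seed pixel per lumen, the seed's series is
mean-centred and normalised into a reference waveform, every pixel is scored
by the Pearson correlation of its series with the reference, pixels at or
above the threshold are kept, and the 4-connected component containing the
seed is returned. Static background has undefined correlation and never
passes. Regions smaller than `min_region_px` (default 2) are rejected.

The correlation threshold is not published for the original method. We
default to **0.6**, not higher, for a physical reason: at the Womersley
numbers of jugular and CSF lumina ($\alpha \approx 5$--$9$) the velocity
waveform of the viscous boundary layer genuinely leads the core in phase, so
even noiseless lumina decorrelate radially. At a 0.85 threshold the rim of a
jugular phantom is cut off (about -14% flow) and the median Dice coefficient
against truth at lumen SNR 10 falls below 0.9; at 0.6 the noiseless phantom
is recovered exactly, median Dice at SNR 10 is about 0.96, and background
rejection is still comfortable (correlation noise SD of a static pixel over
32 phases is about 0.18). Anticorrelated pixels are excluded by default so
that adjacent arteries and veins sharing a waveform shape do not merge; for
the CSF channel, whose flow direction alternates within the cycle, the
pipeline enables the `polarity` option. Pixels exactly at the threshold are
included. Aliased pixels are not specially handled during segmentation;
wrapping is assumed resolved upstream (an optional single-wrap correction,
`correct_single_wrap()`, is provided and off by default). The cord region is
treated as background.

# Flow quantification

Flow is the sum of pixel velocities over the mask times the pixel area,
converted to ml/min, per cardiac phase. All cycle statistics use the
trapezoidal rule with periodic closure, which on a uniform 32-phase grid
reduces to the sample mean; spectral accuracy is unnecessary and periodicity
is physical (retrospective gating). Percentages are computed from cycle-mean
flows and reported to one decimal. Venous waveforms are stored
outflow-positive; the through-plane axis is taken positive toward the
cranium, so the pipeline negates venous and CSF waveforms measured on it.

The CSF stroke volume - the volume shuttled back and forth between cranium
and spinal canal per cycle - is the time integral of the positive lobe of the
**mean-subtracted** CSF waveform by default (the back-and-forth displacement
is the oscillatory component; a raw-positive-lobe mode is available).

# Intracranial volume change, pressure gradient, compliance and MRICP

In steady state the intracranial volume is constant on average over the
cycle, so cycle-mean venous outflow must equal arterial inflow. Since the
measured channels miss part of the outflow, the measured venous sum is scaled
by mean(arterial)/mean(venous) - a multiplicative correction modelling the
unmeasured channels as proportional parallel pathways (an additive offset
mode is available). The net transcranial rate $A(t) - V'(t) -
\mathrm{CSF}(t)$ (CSF positive toward the spine) is then integrated
cumulatively around the cycle; ICVC is the peak-to-peak excursion of the
resulting volume waveform. We apply the steady-state constraint to the full
net rate (its residual cycle mean - the net CSF mean, physiologically
negligible - is removed before integration), which makes the cycle closure
of the volume waveform exactly zero on every input, not just on phantoms.

The CSF pressure gradient is recovered from the velocity field through the
axial Navier-Stokes momentum balance
$-\partial p/\partial z = \rho\,\partial v/\partial t - \mu \nabla^2 v$,
evaluated per interior mask pixel with a 5-point Laplacian and centred cyclic
temporal differences, aggregated per phase by the **median** over interior
pixels (robust to rim partial-volume pixels; a mean mode exists) and
converted with 1 mmHg = 1333.22 dyn/cm$^2$. On noiseless Womersley phantoms
at 12 pixels per radius the recovered waveform matches the prescribed
gradient to better than 0.5% relative RMS across $\alpha \in \{2, 5, 10\}$;
the steady Poiseuille case inverts exactly (the 5-point Laplacian is exact on
a parabola). The main discretisation error is the centred temporal
difference, which attenuates harmonic $n$ by $\mathrm{sinc}(2\pi n/32)$ -
0.6% at the fundamental.

The compliance index is $\mathrm{ICVC} / (\mathrm{PTP\text{-}PG} \cdot d)$
and the pressure estimate follows the inverse law $\mathrm{MRICP} = a /
\mathrm{compliance} + b$. The constants $d$ (effective gradient-to-pressure
distance, default 1.8 cm), $a$ (default 73 mmHg) and $b$ (default 0) live in
proprietary prior work and are **not** identifiable from published group
means alone (mean-of-ratios vs ratio-of-means leaves about 8% slack); the
defaults are chosen to be consistent with typical adult group means of the
compliance index (about 6-8) and MRICP (about 9-12 mmHg), they are exposed in
`calibration_config()` and echoed into every output file, and no validation
quantity depends on them. The inverse law holds exactly for every subject by
construction, and MRICP is capped (with a warning) as compliance tends to
zero. ICVC is defined as max - min of the volume waveform (rather than the
excursion from the cycle-start baseline).

# Cohort statistics

The matched two-group comparison is a two-step rank procedure suited to small
samples: pooled midranks of both groups first (per-group ranking would
destroy the group contrast), then a linear mixed model on the ranks with a
fixed group effect and a random intercept per matched pair, fitted by REML
with variance components constrained non-negative (`lme4`). The group effect
is tested by a two-sided Wald t-test with (complete pairs - 1) degrees of
freedom - in the balanced paired design this coincides with the paired
t-test on within-pair rank differences, which is also the fallback when the
fit fails. When no pair shows any within-pair rank difference the exact null
(p = 1) is returned directly. Empirically the test holds its level: 5.5%
rejections at nominal 5% over 1000 null cohorts of 15 + 15, and median
p < 0.02 at the packaged cohort's jugular-fraction effect size.

The ordinal venogram grade (1-6) is compared by the Mann-Whitney U test with
midrank ties. For pooled samples of at most 12 the p-value is exact: via the
standard Wilcoxon distribution when tie-free and via the exact conditional
distribution of the tie-adjusted rank sum (a count recursion over doubled
midrank scores) when ties are present - the tie-corrected normal
approximation errs by up to 0.08 in this regime, which is why the exact path
covers it. Larger samples use the normal approximation with tie and
continuity corrections. Subjects with a missing grade are excluded pairwise
(no imputation). Spearman correlation uses Pearson on midranks with the
t approximation (n - 2 df). All tests are two-sided at alpha = 0.05 with no
multiplicity correction.

Which variables get the mixed model vs the U test is ambiguous in the source
description; the package applies the mixed model to all continuous variables
and the U test to the ordinal grade.

# Reproduction of the packaged tables

`reproduce_tables()` recomputes every printed group mean/median from the
packaged per-subject values and reports per-cell discrepancies. The tolerance
is the rounding-propagation bound: half a unit of the per-subject printed
precision plus half a unit of the summary's own printed precision (the
per-subject values are themselves rounded, so a summary recomputed from them
can differ from one computed on unrounded data by up to half an input unit).
One cell needs this bound rather than exact agreement: the control-group mean
MRICP prints 8.77 while the mean of the printed per-subject values is 8.747,
evidence that the published summary was computed before rounding. The
packaged fixtures store the printed values verbatim, including the original
row-order quirk (CTR_13 listed before CTR_12), and are checksum-verified on
load. The published mixed-model p-values are *not* reproduction targets:
they depend on unpublished software details (REML implementation, tie
handling); the package reproduces the procedure and the group summaries, and
its own battery reproduces the direction and significance pattern of the
published comparisons.

# Problem sizes and numerical choices

Default grids keep everything comfortably fast on one CPU: the full
ten-lumen subject phantom uses a 192 x 192 grid at 0.02 cm pixels (7-20
pixels per radius depending on the vessel) and 32 phases; oracle studies use
48 x 48 or 64 x 64 single-lumen grids; segmentation accuracy is summarised
over 50 noise replicates; type-I error over 1000 null cohorts and power over
500. Ties at the segmentation threshold are included; vessel discs must not
overlap and must lie fully inside the grid (geometry errors otherwise);
degenerate inputs (zero-variance seed, empty mask, non-positive tCBF or
venous mean, zero PTP-PG) raise typed errors rather than propagating NaN.

# Known limitations

* Rigid circular tubes: no vessel compliance, annular CSF geometry or
  non-axial flow; the pressure-gradient inversion assumes fully developed
  axial flow.
* Calibration constants of the compliance-to-ICP law are conventions, not
  measurements; MRICP values should be compared within-study only.
* No eddy-current/background-phase correction and no DICOM ingestion; real
  scanner data must arrive as NIfTI + JSON sidecar in the documented layout.
* The segmentation is single-slice and seed-driven; there is no automatic
  vessel detection or multi-slice propagation.
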