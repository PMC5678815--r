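---
title: "Modelling radiation-induced lung fibrosis with the fibrosis index"
author: "rilfi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling radiation-induced lung fibrosis with the fibrosis index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rilfi)
```

## The problem

Normal lung tissue is the dose-limiting organ for thoracic radiotherapy: the
late endpoint of concern is radiation-induced lung fibrosis (RILF), which in
mouse models develops over roughly six months after whole-thorax irradiation.
Two CT-visible signatures track it — the mean lung density rises (collagen
deposition, hyper-cellularity) and the aerated lung volume shrinks
(restrictive disease). `rilfi` implements a complete quantitative chain from
CT-like volumes to radiobiological parameters:

1. segment the lung and measure volume and mean density (`segment_lung()`,
   `lung_metrics()`),
2. condense both into a scalar severity score, the fibrosis index
   (`fibrosis_index()`),
3. fit FI against dose per fractionation arm (`fit_fi_model()`),
4. estimate the fractionation sensitivity $\alpha/\beta$ three ways
   (`alpha_beta_profile()`, `fe_plot()`, `fit_lq()`),
5. model FI against biologically effective dose and extract threshold
   landmarks (`fit_bed_logistic()`, `extract_landmarks()`),
6. pool $\alpha/\beta$ estimates across studies (`pool_fixed()`).

A synthetic-data layer (`simulate_cohort()`, `simulate_phantom()`,
`make_reference_cohort()`) emulates the two-arm C57BL/6 study design the
package models, so every stage is exercised and tested without animal data.

## The fibrosis index

With a treated scan's mean density $\overline{HU}_t$ and volume $V_t$, and an
age-matched reference cohort's means $\overline{HU}_r$, $V_r$:

$$ FI = \sqrt{\Delta \overline{HU}\uparrow \times \Delta \overline{V}\downarrow } $$

the geometric mean of the relative density increase and relative volume
decrease. Both deltas must be positive for a fibrotic pattern; if either is
non-positive (emphysema and pleural effusion push density and volume in
other directions) FI is clamped to 0 and flagged. The peak position of the
smoothed lung-HU histogram (`ppsh()`) is the differential diagnostic for
those confounders: emphysema drags the mode toward air, effusion toward
fluid.

The absolute normalization that makes FI saturate at a particular ceiling is
an empirical convention established outside this package (the deltas can be
scaled before the geometric mean). `fibrosis_index()` therefore exposes a
`convention` argument — `"relative"` computes dimensionless fractional
deltas with a configurable `scale`; `"direct"` accepts externally normalized
deltas — and every downstream model operates on FI values regardless of how
they were normalized.

## The FI dose-response model

Mean FI as a function of total dose $D$ follows a probit-type sigmoid:

$$ FI(D) = \tfrac{1}{2} A \left\{ 1 - \operatorname{erf}\!\left(\sqrt{\pi}\,
\gamma \left(1 - \frac{D}{ED_{50}}\right)\right) \right\} $$

* $A$ — saturation constant, the maximal attainable FI (default 7.20, the
  empirical ceiling corresponding to 100% fibrosis). $A$ is *fixed* by
  default during fitting, because it is measured, not estimated; freeing it
  is available via `fix_a = NULL`.
* $ED_{50}$ (Gy) — dose of half-maximal fibrosis. This is a deterministic
  reading: the dose at which the population's *mean* FI reaches $A/2$, not
  an incidence probability.
* $\gamma$ — the maximum normalized dose-response gradient
  (dimensionless steepness).

The model is strictly increasing, bounded in $(0, A)$, passes through
$A/2$ at $ED_{50}$ exactly, and inverts in closed form
(`inverse_dose()`):

$$ D(FI) = ED_{50}\left[1 - \frac{\operatorname{erf}^{-1}(1 - 2FI/A)}
{\sqrt{\pi}\,\gamma}\right]. $$

```{r}
fit1 <- fi_model(A = 7.20, ed50 = 14.55, gamma = 1.64)  # single fraction
fit5 <- fi_model(A = 7.20, ed50 = 27.7,  gamma = 1.41)  # five fractions
predict_fi(fit1, c(0, 14.55, 20))
inverse_dose(fit1, 3.60)
```

Fitting (`fit_fi_model()`) is Levenberg–Marquardt least squares over
$(ED_{50}, \gamma)$. Initialization is deterministic — $ED_{50,0}$ by linear
interpolation of where group-mean FI crosses $A/2$ (median nonzero dose as
fallback), $\gamma_0 = 1$ — with bounds $ED_{50} \in (0, 10 D_{max}]$,
$\gamma \in (0, 20]$. Per-animal rows are fitted unweighted by default;
`group_means = TRUE` collapses to dose-level means first (both are common
in practice and agree exactly on balanced noise-free data). Goodness of fit
is the adjusted $R^2$ under the residual-versus-total convention — stated
explicitly because nonlinear-fit $R^2$ has no single standard.

## Three routes to alpha/beta

Fractionation sensitivity is parameterized by $\alpha/\beta$ (Gy) of the
linear-quadratic (LQ) model; equal biologically effective doses

$$ BED = D\left(1 + \frac{d}{\alpha/\beta}\right) $$

define isoeffective schedules of total dose $D$ at dose per fraction $d$.

**Isoeffect pairing.** For any FI level, the inverse FI-model of each arm
gives isoeffective doses $D_1, D_2$; equating BEDs yields
$\alpha/\beta = (D_2 d_2 - D_1 d_1)/(D_1 - D_2)$
(`alpha_beta_from_pair()`). `alpha_beta_profile()` sweeps this over a grid
of FI levels — default 0.05 to 7.15 in steps of 0.05, reported per level
with the grid mean ± SD, so any sub-range can be recomputed rather than
relying on an unstated "effective range". The profile declines as fibrosis
severity rises; `fit_exp_decay()` summarizes that relaxation.

**Fe plot.** Under the LQ model, reciprocal total isoeffect dose is exactly
linear in dose per fraction, and $\alpha/\beta$ is the intercept/slope ratio
of the least-squares line (`fe_plot()`). On two schedules this reduces
algebraically to the pairing formula; on LQ-exact points the line fits with
zero residual — both identities are pinned in the test suite.

**LQ regression.** `fit_lq()` fits $y = c - (\alpha D + \beta d D)$ with a
free intercept to a transformed response, by default $y = -\log_{10}(FI)$
with FI floored at 0.05 (the lower edge of the usable FI range; the floor
keeps the log finite for sham-level responses). The linkage between the FI
transform and the LQ effect is a convention, so the transform is a
pluggable function; the base of the log rescales $(\alpha, \beta, c)$
jointly and leaves $\alpha/\beta$ invariant, which is the contract-level
output. A design with a single dose per fraction cannot separate $\alpha$
from $\beta$ and is rejected.

One structural point the synthetic experiments make visible: data generated
from the probit-type FI-model do not follow the per-arm LQ shape — over the
study's dose range $-\log_{10}$ of a sigmoid is concave in $D$, so a
single-arm LQ fit can return $\beta \le 0$. The two-arm joint fit is
identified through the fractionation contrast and behaves well. The
estimator's own contract (exact recovery on data generated from the LQ
model) holds to numerical precision regardless.

`isoeffect_curve()` completes the toolkit: given $\alpha/\beta$ and a
reference schedule it solves the BED-equality quadratic for the positive
root of $d$ at each fraction number (complex or negative roots are domain
errors, not clipped), reproducing the classic sparing pattern — dose per
fraction falls and total dose rises with $n$.

## The BED response and its landmarks

Pooling both arms on the BED axis, FI follows a four-parameter log-logistic
(`fit_bed_logistic()`):

$$ FI(BED) = A_2 + \frac{A_1 - A_2}{1 + (BED/k)^p} $$

with lower/upper asymptotes $A_1, A_2$ (either can be fixed, e.g.
$A_1 = 0$, $A_2 = 7.2$), midpoint $k$ (Gy) and shape $p$. Three landmarks
are derived (`extract_landmarks()`):

* **cut-off** — the maximum-slope point; closed form
  $k\left(\frac{p-1}{p+1}\right)^{1/p}$ for $p > 1$ ($p \le 1$ has no
  interior slope maximum and is flagged rather than reported);
* **BED~Tr~**, the fibrosis-initiation threshold — the maximum of the
  geometric (arc-length) curvature $\kappa = f''/(1+f'^2)^{3/2}$ on the
  rising toe below the cut-off, found by a 4096-point grid scan bracketing
  a golden-section refinement to $10^{-6}$ Gy;
* **BED~ED50~** — the BED of half-maximal FI; equal to $k$ when $A_1 = 0$,
  otherwise $k\left(\frac{A_2 - 2A_1}{A_2}\right)^{1/p}$.

Curvature is not invariant to axis scaling, and no canonical normalization
exists for a (Gy, FI) plane. The default computes curvature in raw units;
`normalize_axes = TRUE` rescales both axes to $[0,1]$ over the search range
first. The two conventions give different thresholds (the maximum-slope and
midpoint landmarks are unaffected), so the choice is an explicit argument
and both values are reported by the analysis scripts. The ordering
$BED_{Tr} < \text{cut-off} < BED_{ED50}$ holds for every rising fit with
$A_1 = 0$, $p > 1$.

## Imaging stage

`segment_lung()` grows the 6-connected region (26-connectivity optional)
containing a seed voxel within the HU window $[-900, -100]$ — the range
spanning aerated through consolidated lung. The manual resection of trachea
and main bronchi that an operator would perform is replaced by an optional
exclusion mask subtracted after growth, making that step reproducible.
`lung_metrics()` is deliberately elementary: volume = voxel count ×
voxel volume, density = arithmetic mean HU in the mask.

`ppsh()` bins masked HU (default 10 HU bins), smooths with a centred moving
average (default 50 HU window) and reports the peak bin centre; partial
windows at the histogram edges average over the bins actually present, which
makes the peak invariant to adding a constant count to every bin, and ties
break toward lower HU. All defaults are explicit, configurable conventions.
Volumes are axis-aligned with no orientation or affine resampling; NIfTI-1
is the interchange format (spacing from the header).

## What the synthetic generator does and does not emulate

`simulate_cohort()` draws each animal's true FI from the arm's FI-model at
its total dose and adds Gaussian noise truncated at 0. Defaults are the
study conditions the package models: the two-arm design (single fractions
0, 10.5, 12.5, 14.5, 17.5, 20 Gy; five daily fractions of 0, 2, 4, 6, 7,
8.5 Gy), 12 animals per dose group, endpoint 24 weeks.

The noise scale is a synthetic convention, not an empirical estimate: no
per-animal FI variance is published for this design. The default
`fi_sd = 0.2` FI units was chosen once as a realistic scale — roughly 3% of
the saturation ceiling, small against the ~7-FI dynamic range but large
enough that group means at 12 animals carry visible error. Likewise the
reference conventions (volume 400 mm³, density −550 HU, SD 5% of each mean)
are plausible healthy-mouse-lung values used only as anchors for the
back-filled columns.

Volume and HU columns are back-filled from observed FI by the symmetric
split $\Delta HU = \Delta V = FI$, then inverting the relative-delta
convention, so `fibrosis_index()` recomputes the stored FI exactly; they are
bookkeeping that keeps the imaging-free and imaging-full paths mutually
consistent, not physical scans (for $FI > 1$ the implied volume is not
physiological). Phantoms (`simulate_phantom()`) are quasi-spherical
single-component regions with exactly known voxel counts, volume and mean
HU — ideal for exactness testing, anatomically unrealistic by design.

Consequences for interpretation: passing parameter-recovery tests shows the
estimation chain is unbiased and precise *under the stated noise model*
(additive, homoscedastic, truncated); it does not validate the noise model
against real mice, nor the segmentation against real anatomy (motion,
partial-volume effects, operator variability are all absent). Longitudinal
imaging is not simulated — the analysis is endpoint-only.

## Numerical choices

* erf/erfinv from `pracma`; nonlinear least squares via `minpack.lm`
  (Levenberg–Marquardt, bounded).
* The BED logistic is driven through `nls.lm` directly: when a parameter
  legitimately converges to 0 (typically $A_1$), finite-difference steps
  proportional to the parameter underflow and a post-hoc model rebuild
  falsely reports a singular gradient; standard errors come from the
  Levenberg–Marquardt Jacobian instead.
* The sigmoid saturates to exactly $0$ or $A$ in double precision a few
  $\gamma$-widths beyond the midpoint; strict monotonicity is therefore
  guaranteed (and tested) on the numerically responsive range.
* Degenerate inputs fail loudly: all-zero FI, constant FI, single-schedule
  LQ designs, empty segmentations, $FI \notin (0, A)$ inversions and
  $D_1 = D_2$ isoeffect pairs are errors, not silent values.
* Determinism: every generator takes an explicit seed; identical
  configurations reproduce identical outputs.

## Problem sizes

The replication experiments in the tests and the acceptance script use 200
synthetic cohorts per arm (12 animals × 6 dose levels each), which puts the
Monte-Carlo error of mean recovered $ED_{50}$ near 0.05% — comfortably
below the 1% bias the recovery claims are stated at — while the whole
experiment fits in well under a minute. Phantom fixtures use 16³–64³
volumes; segmentation exactness is independent of scale.

## Limitations

* FI condenses two mechanisms into one scalar; mixed pathologies (fibrosis
  with emphysema) need the PPSH diagnostic and may still be ambiguous.
* The deterministic FI-model describes mean severity, not incidence; no
  event-count probit/logit machinery is provided on purpose.
* No repopulation/time-factor or incomplete-repair corrections: fractions
  are treated as fully repaired daily exposures.
* Fixed-effect pooling only; between-study heterogeneity is reported via
  the co-printed unweighted SD, not modelled (no random-effects estimator).
* The BED-threshold landmarks depend on the curvature axis convention, as
  surfaced by the `normalize_axes` argument; report which convention you
  used.
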