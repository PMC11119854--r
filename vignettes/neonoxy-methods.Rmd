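---
title: "Models and methods behind neonoxy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neonoxy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neonoxy)
```

`neonoxy` implements the physiological computation stack of a neonatal
acute-lung-injury (ALI) oximetry experiment: a piglet cohort ventilated
through a stepwise inspired-oxygen (FiO2) reduction from 50% to room air,
with arterial and regional venous blood gases, multi-site near-infrared
spectroscopy (NIRS), hemodynamics, ventilator waveforms and lung ultrasound
collected at each step. This vignette explains each model, its assumptions,
the tunable parameters, and the choices made where the underlying methods
literature leaves the design open.

## Oxygen transport and the shunt forward model

The gas-exchange layer is standard clinical physiology. Alveolar oxygen
tension uses the simplified alveolar gas equation

$$P_AO_2 = F_iO_2 (P_b - P_{H_2O}) - P_aCO_2 / RQ$$

with barometric pressure 760 mmHg, water vapour 47 mmHg and respiratory
quotient 0.8 by default (`physio_constants()`); the alveolar–arterial
difference and PaO2:FiO2 ratio follow directly. The oxyhemoglobin
dissociation curve is the Severinghaus single-equation fit,

$$S(P) = \left(1 + \frac{23400}{P^3 + 150P}\right)^{-1},$$

chosen because it is accurate across the clinical range, strictly monotone,
and analytically invertible: `hb_po2()` solves the associated depressed cubic
exactly (Cardano), and the pair round-trips to better than $10^{-6}$
relative. Temperature and pH corrections are deliberately not applied; the
constants object is the hook for recalibration.

Arterial saturation as a function of FiO2 is predicted by a two-parameter
defect model (`predict_sao2()`): a right-to-left shunt fraction $Q_s/Q_t$
and a rightward displacement of the FiO2–SaO2 curve (in mmHg of effective
alveolar PO2) standing in for reduced ventilation–perfusion ratio.
End-capillary blood equilibrates at the displaced alveolar tension; arterial
content is the shunt-weighted mixture

$$C_a = (1 - Q_s/Q_t)\,C_{c'} + (Q_s/Q_t)\,C_v, \qquad C_v = C_a - \mathrm{avDO_2},$$

with a fixed arteriovenous content difference (default 2.3 mL O2/dL)
closing the venous side, as is conventional when cardiac output and oxygen
consumption are not measured separately. The circular dependence on $C_a$ is
resolved by a damped fixed-point iteration (damping 0.5, tolerance
$10^{-8}$ mL/dL, at most 100 steps); saturation is then read back off the
dissociation curve by a vectorised, safeguarded Newton inversion of the
monotone content function. The model is monotone increasing in FiO2 and
monotone decreasing in both defect parameters, which the test suite checks
on a parameter grid, and it agrees with an independent closed-form oracle
(the fixed point solves algebraically to $C_a = C_{c'} - q\,\mathrm{avDO_2}/(1-q)$)
to better than $10^{-8}$.

`fit_shunt_vq()` inverts the forward model on observed FiO2 steps by
exhaustive grid search ($Q_s/Q_t$ 0–0.6 by 0.01; displacement 0–200 mmHg by
2) followed by Nelder–Mead refinement from the grid optimum. The search is
fully deterministic — a smooth two-dimensional landscape needs no random
restarts — and the refinement is bounded at $Q_s/Q_t \le 0.65$, just beyond
the grid, where the damped iteration is still guaranteed to converge within
its iteration budget. Four steps identify two parameters comfortably when
saturations leave the ceiling; when every observed SaO2 sits at 1.0 the
shunt is unidentifiable and the fit returns zero with a warning rather than
an arbitrary interior value.

## Regional oxygen extraction and risk flags

Fractional oxygen extraction is
$\mathrm{FOE} = (S_aO_2 - rSO_2)/S_aO_2$, computed identically from NIRS
regional saturations (`foe_from_nirs()`) and from co-oximetry venous
saturations (`foe_from_gases()`); the two differ by the NIRS device's
arterial/venous weighting, which shifts the level but not the response to
FiO2. All saturations are normalised to fractions at ingest — a column
entirely above 1 is treated as percent, a mixture is rejected as a scale
violation — and extraction is reported as a fraction, formatted as percent
only for display.

Risk flagging uses two published neonatal thresholds: an absolute regional
cerebral saturation below 45%, and a drop of more than 20% from the animal's
own baseline. Both are strict inequalities (a reading of exactly 45%, or
exactly a 20% drop, is not flagged), matching how the thresholds are
stated. Baseline-referenced analysis (`delta_from_baseline()`) exists
because inter-individual variability of baseline regional saturation is
large in neonates, making each animal its own control more informative than
group means.

The saturation-range table (`bin_by_sao2()`) groups post-injury
cerebral-NIRS observations by arterial saturation into 95–100, 90–95, 85–90
and <85 percent. Bins are half-open $[\ell, u)$ with the top bin closed at
100, so a reading of exactly 95 falls in 95–100; this convention, and the
four-row scheme, reproduce the published table layout (a fifth 80–85 row is
sometimes named in prose but never tabulated, so the package defaults to
four). Percentages of flagged readings are rounded half-up to integers to
match printed values such as "7 (64%)".

## Cerebral autoregulation classification

The classifier scores each observation against a nomogram of expected
cerebral saturation under intact regulation,

$$\widehat{rcSO_2} = rcSO_2^{base} \cdot f_{BP}(mBP) \cdot f_{CO_2}(P_aCO_2) \cdot f_{O_2}(P_aO_2),$$

multiplicative around the animal's own baseline: $f_{BP}$ is 1 across the
autoregulatory plateau (default 40–90 mmHg) and declines linearly below it
(default 1%/mmHg); $f_{CO_2} = 1 + 0.03\,(P_aCO_2 - 40)$ captures CO2
vascular reactivity; $f_{O_2} = 1 + 0.012\,\max(0, 50 - P_aO_2)$ encodes the
flow augmentation an intact circulation mounts under hypoxemia. Published
neonatal nomograms differ in form and units and none is reproduced verbatim
here, so every parameter is exposed in `autoreg_nomogram()` and every
quantitative claim made for the classifier is established by parameter
recovery on synthetic data or by closed-form identity — never by the
specific default numbers.

An observation is *impaired* when measured rcSO2 falls more than 20% below
the expected value (`deviation_cut`); desaturation only — readings above
expectation are logged as intact, since the clinical concern is cerebral
desaturation. Two genuinely open choices are implemented behind switches,
with these defaults:

* the deviation denominator is the nomogram **expected** value (switchable
  to baseline): deviation from the trendline reads most naturally as
  relative to the trendline itself;
* hypoxemia attribution is driven by **PaO2** (switchable to SaO2): the
  nomogram's oxygen term is a tension effect, and tension is the measured
  quantity least confounded by the dissociation curve's ceiling.

Impairment is attributed to the factor with the largest standardized
excursion: BP (the larger of plateau shortfall and relative drop from
baseline mBP), O2 (shortfall below the hypoxemia threshold), CO2 (relative
deviation from 40 mmHg). Ties break hypoxemia > pressure > CO2, the order of
physiological potency at the extremes, and the order is configurable. An
impaired observation with no measurable excursion is labelled
`impaired_unattributed` with a warning rather than silently assigned.
Group-level outputs (`attribute_cohort()`) are contingency counts per group
and FiO2 step, compared by Pearson chi-squared without continuity
correction (`compare_groups_chi2()`), the conventional test for r×c count
tables of this size.

## Respiratory mechanics

`fit_single_compartment()` fits the linear single-compartment equation of
motion $P_{aw}(t) = V(t)/C + R\,\dot V(t) + P_0$ by ordinary least squares
on the design $[V, \dot V, 1]$. A least-squares fit over the whole breath
was preferred over loop-geometry constructions because it uses every sample,
has a closed-form solution, and recovers noiseless parameters to machine
precision — which the tests require across a grid of (C, R, P0). Quasi-static
compliance (`static_compliance()`, tidal volume over plateau-minus-PEEP) is
provided alongside, and on a passive breath with zero flow at the
measurement instant the two definitions coincide exactly. Rank-deficient
designs (constant flow or volume) raise identifiability errors instead of
returning arbitrary coefficients. The package fits one breath at a time;
segmentation of continuous multi-breath recordings is left to the caller.

## Lung ultrasound

Aeration scoring is per-zone: three anterior zones and one posterolateral
zone per lung, each graded 0 (A-lines only), 1 (≥3 separated B-lines), 2
(crowded B-lines or subpleural consolidation) or 3 (extended consolidation).
`composite_score()` sums the eight zones, giving 0–24 per animal; image
interpretation itself is out of scope — the scores are inputs.

## The synthetic cohort generator

`generate_cohort()` emulates the study design: 6 control and 7 oleic-acid
(OA) injured animals by default, five measurement periods (baseline and
1 h post injury at FiO2 50%, then 40, 30, 21%), PaCO2 held near-constant by
ventilation. Observable data are forward-composed from the package's own
models so that every estimator can be tested as an inverse problem:
saturations from `predict_sao2()` under per-period shunt/V:Q truth, arterial
PO2 from the dissociation curve, cerebral NIRS from the nomogram expectation
minus an injected autoregulation deficit, gut/kidney NIRS from regional
baselines with a configured decline, venous saturations equal to the
noiseless regional values (so NIRS- and gas-derived extraction share
slopes), and airway waveforms from the equation of motion. Independent
Gaussian noise is added to SaO2 (SD 0.01), regional saturations (SD 2
percentage points) and airway pressure (SD 0.2 cmH2O); dispersion was
sanity-checked against the between-animal standard errors of the printed
summary tables, which is the only dispersion information available.

Default physiology follows the study's printed group summaries: OA animals
step from a 5% baseline shunt to 30–35% with compliance falling from 2.2 to
~1.1 mL/cmH2O and resistance rising from 50 to ~85 cmH2O·s/L; blood
pressures track the group means by period; control cerebral deficits reach
18% of baseline only at room air while OA deficits reach 45%. Every
parameter is a per-animal, per-period configuration field, and the generator
exports its ground truth (including the injected impairment cause, derived
from which excursion the configuration actually creates) for recovery
testing. Per-animal seeds derive from the master seed by a fixed
linear-congruential mix, so cohorts regenerate identically from
`(configs, master_seed)` on any platform.

What the generator does **not** emulate: within-period time dynamics (each
period is one record), pharmacology of oleic acid or anesthesia,
device-specific NIRS calibration, inter-variable correlation beyond what the
forward models induce, and non-Gaussian artifacts such as ambient-light
dropouts. Passing recovery tests therefore demonstrate that the estimators
invert the stated physiological models at realistic noise — not that they
are robust to every failure mode of real recordings.

## Problem sizes and numerical choices

The test suite and acceptance checks run in minutes on one core: the
forward-model/oracle grid is 5×5×3, noiseless inversion checks use 4-step
curves, Monte-Carlo recovery uses 100 replicates at the stated noise, and
synthetic cohorts of 4–13 animals exercise the full pipeline. Noisy-recovery
criteria are assessed on the mean estimate across replicates, since with
four observations per curve the per-replicate sampling error of the shunt
fraction is of the same order as the tolerance. Other numerical tie-breaks:
the fixed point is damped at 0.5 and errors out (rather than returning a
stale value) if unconverged; the Newton content inversion is clamped to
[0, 1500] mmHg; negative alveolar tensions clamp to zero with a warning;
binning assigns boundary saturations to the upper-open convention described
above; chi-squared drops classes unobserved in both groups so degrees of
freedom reflect observed classes.

## Known limitations

The two-parameter shunt model compresses a continuous V:Q distribution into
one displacement; severe inhomogeneity will alias into both parameters. The
assumed arteriovenous content difference makes the venous side a constant
offset, which is wrong during large swings of cardiac output or
consumption. The nomogram is a local linearisation — outside neonatal
ranges of pressure and tension its multiplicative factors are not validated.
Classification attributes impairment to a single dominant factor even when
excursions co-occur, by design. None of the estimators model measurement
drift within a period.
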