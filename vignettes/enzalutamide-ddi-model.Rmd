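---
title: "Modeling enzalutamide's CYP3A and P-gp drug-drug interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling enzalutamide's CYP3A and P-gp drug-drug interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzddi)
```

## The problem

Enzalutamide induces CYP3A4 strongly and inhibits P-glycoprotein (P-gp);
its circulating N-desmethyl metabolite (M2) does both as well. For victim
drugs that are dual CYP3A/P-gp substrates the two mechanisms pull in
opposite directions: induction lowers exposure, efflux inhibition raises
it. `enzddi` chains together the in vitro assay analysis, the in vitro-in
vivo extrapolation (IVIVE), and a dynamic perpetrator-victim PBPK model
so the net effect can be simulated mechanism by mechanism.

## In vitro models and fitting

**Induction.** Hepatocyte mRNA fold increases are fit with
$\mathrm{fold} = 1 + (\mathrm{Ind}_{max}-1)\,C/(\mathrm{IndC}_{50}+C)$
by unweighted least squares on the per-concentration means. Lot-level
replicates are not available, so weighting by lot is not attempted; the
package therefore quotes a ±15% band when comparing against fits made
with unknown weighting. The highest tested concentration (100 µmol/L,
two lots only, visibly depressed by cytotoxicity) is included by default
because excluding it leaves a two-point, exactly-interpolating fit; the
`exclude` argument makes the sensitivity easy to check. Optimization is
a fixed grid of Levenberg-Marquardt starts (log-spaced IndC50 crossed
with a range of amplitudes) — deterministic, and verified in tests
against a dense grid-search oracle to within 1% of the residual sum.

**Calibration.** In vitro amplitudes under-predict clinical CYP3A4
induction, so the amplitude is rescaled by the rifampicin positive
control measured in the same assay:
$\mathrm{Ind}_{cal} = 1 + (\mathrm{Ind}-1)\,
(\mathrm{Ind}_{ref}-1)/(\mathrm{Ind}_{rif}-1)$.
The in vivo reference for rifampicin defaults to 16, a standard hepatic
CYP3A4 value, and rifampicin's single-concentration fold increase (8.05
at 10 µmol/L) stands in for its in vitro `Ind_max` since only one
concentration was tested. This maps enzalutamide's 5.9 to 11.43 and M2's
5.1 to 9.72.

**P-gp inhibition.** Bidirectional transwell data are reduced to
corrected efflux ratios (MDR1 ratio over control-cell ratio) and percent
of control, then fit with a three-parameter Hill model
($I_{max}$, $IC_{50}$, Hill factor all free, since the assay's fixed
parameters are not stated). Published assay tables round each
directional ratio to one decimal before forming the corrected ratio;
`summarize_efflux(ratio_digits = 1)` reproduces that reporting pathway
exactly, while the default carries full precision. The fitted IC50 is
used downstream as the competitive $K_i$ (probe concentration far below
its $K_m$).

## IVIVE

Enzalutamide is a low-extraction drug, so the retrograde calculation
inverts $CL_{po} = f_u\,CL_{int,u}$ directly (the full well-stirred
inversion is available via `well_stirred = TRUE`). The unbound intrinsic
clearance is scaled through liver mass (1650 g) × MPPGL (40 mg/g),
split across pathways (87% CYP2C8 / 13% CYP3A4), and divided by
microsomal abundances (CYP2C8 24, CYP3A4 137 pmol/mg). These system
constants are standard population values; they reproduce the published
per-pmol clearances within 2% and are all overridable in
`system_model()`. Metabolite routing keeps the overall parent→M2
conversion at 63%: 67% of CYP2C8 flux and 39% of CYP3A4 flux form M2,
and M2's own elimination is 9% CYP3A4 (the rest is unassigned microsomal
clearance), which is what lets enzalutamide autoinduction raise M2
clearance modestly while raising M2 formation too.

## The PBPK engine

Per compound the state is: gut-lumen amount, enterocyte amount, central
and peripheral amounts, plus cumulative elimination by route (for exact
mass-balance audits). Design choices, each of which was genuinely open:

* **Absorption** is first-order (`ka`) from the lumen through a single
  well-mixed enterocyte compartment rather than a multi-segment
  dissolution-absorption model: the interaction magnitudes of interest
  are set by gut/liver extraction, not by dissolution detail.
  Incomplete absorption is a first-order lumen loss sized so the
  no-efflux absorbed fraction equals `fa`. Enzalutamide's `ka` (1.4/h)
  was chosen once to give the observed 1-2 h time-to-peak and frozen.
* **Distribution** is one central + one peripheral compartment
  parameterized from Vss (fraction `vc_frac` central); the full-organ
  model is deliberately collapsed.
* **Hepatic elimination** uses the well-stirred model applied to the
  portal inlet, so first-pass and systemic extraction respond together
  to enzyme-pool changes. The per-enzyme intrinsic clearances are scaled
  by the dynamic CYP3A4 pool and the competitive inhibition factor.
* **Driver concentrations**: liver interactions use the unbound hepatic
  inlet concentration; gut interactions use the unbound enterocyte
  concentration (`fu_gut`, set equal to plasma `fu` for the
  perpetrators, as in their published parameterization). With these
  drivers the perpetrator [I]u/Ki in the enterocyte is of order 0.5-2 —
  the regime in which baseline P-gp inhibition raises digoxin exposure
  while a 3.5-fold expression increase overturns it, matching the
  clinical verification pattern.
* **P-gp induction** is a static fold increase (FI) on intestinal P-gp
  expression, off by default (FI = 1), because transporter turnover data
  to drive a dynamic model do not exist and the no-induction setting
  reproduces the observed digoxin interaction direction. FI = 2 and 3.5
  are scenario switches.
* **Renal P-gp** inhibition is not modeled.
* **Numerics**: lsoda with absolute tolerance 1e-10 µmol/L and relative
  1e-8, 0.1 h output grid, doses as bolus events into the lumen.
  Negative concentrations are bounded by the absolute tolerance and
  clipped only inside interaction terms. Tests pin mass balance to
  1e-6 relative, closed-form single-dose AUC and enzyme-turnover limits
  to 0.1%, and grid/tolerance refinement to 0.01%.

## DDI study designs

The default scenario is 160 mg enzalutamide once daily for 50 days, a
single victim dose co-administered at the start of day 51 (dosing times
relative to the perpetrator's last dose are not published; simultaneous
co-dosing at steady state is the declared default), and a 120 h victim
window. Victim regimens: digoxin 0.25 mg, midazolam 2 mg, apixaban
10 mg, rivaroxaban 20 mg, all single doses. The population is a single
cohort (default 100 subjects) of paired arms with log-normal
between-subject multipliers on hepatic CL_int (CV 35%), Vss (20%) and ka
(30%) — declared assumptions, seedable and bit-reproducible. Sensitivity
grids run a deterministic representative subject (all multipliers 1).
Predicted ratios are judged against the Guest et al. observation-scaled
interval with variability term 1.25, which reproduces all four published
acceptance intervals for midazolam and digoxin.

The victim parameter files are minimal approximations assembled from
public PK constants plus the stated CYP3A fractions (apixaban 0.42,
rivaroxaban 0.61) and default intestinal P-gp RAF/REF (25 and 0.15):
they are not the proprietary library models, so simulated apixaban and
rivaroxaban ratios are qualitative — the tests assert direction and
ordering (rivaroxaban reduction ≥ apixaban; apixaban ratio strictly
increasing in RAF/REF; rivaroxaban insensitive to RAF/REF; OAT3
Models 1 and 2 within 10%), not the published numbers. Rivaroxaban
Model 1 routes half its renal clearance through inhibitable OAT3;
Model 2 none.

## Synthetic data and what passing tests show

`gen_induction_dataset()` draws lot-level folds as the Emax curve times
log-normal noise (CV 0.33, the scale of the assay's reported SD/mean);
`gen_transwell_dataset()` builds four directional permeability series
whose corrected ratio follows the Hill curve with truncated-normal
measurement noise (CV 0.06, truncated at 3 SD to keep P_app positive);
`gen_victim_compound()` draws valid victims for property tests. At the
real assay design (3 concentrations × 3 lots) the 200-seed recovery
medians are within 25% (Ind_max) and 30% (IC50) — which shows the
fitting machinery is unbiased at the design's information content, not
that three concentrations are a generous design. The generators emulate
between-lot and replicate noise only; they do not emulate cytotoxic
fall-off at high concentrations, radiocounting statistics, or clinical
concentration data.

## Problem sizes

The packaged examples and tests use representative-subject simulations
(one deterministic subject) for scenario and sensitivity work and small
cohorts for population properties; the default cohort size for study
use is 100 subjects. Simulated durations are 50 days of perpetrator
loading plus a 120 h victim window at a 0.1 h output grid.

## Known limitations

* Victim models are approximations; absolute DOAC ratios should not be
  read quantitatively.
* P-gp induction is static; the FI scenarios bracket, rather than
  resolve, the inhibition/induction balance.
* The metabolite enters systemically (hepatically formed M2 is not
  subject to its own first pass), a small simplification given M2's low
  extraction.
* Calibration rests on a single positive control (rifampicin) and a
  configurable in vivo reference.
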