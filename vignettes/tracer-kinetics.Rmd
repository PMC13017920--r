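---
title: "Models and methods: postprandial tracer kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: postprandial tracer kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mealkinetics)
```

This vignette documents the models implemented in `mealkinetics`, their
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## Study design and data model

The package targets meal studies with a primed-continuous infusion of
D8-phenylalanine (prime 3 µmol/kg lean mass, 0.07 µmol/kg LM/min) and
D2-tyrosine (prime 2.3, 0.04), started 150 min before a liquid mixed meal
whose casein is intrinsically labelled with ring-D5-phenylalanine. Blood
is drawn simultaneously from a radial artery, the femoral vein and a
superficial epigastric vein at −60, −30 and 10–360 min; the −150 min
sample precedes the prime and measures background enrichment. Muscle
biopsies are taken at −30 and 360 min. All fluxes are normalised to
DXA-measured lean mass.

Data are long tibbles: concentrations `(site, time, analyte,
concentration)` and enrichments `(site, time, analyte, isotopologue,
ttr)`. Because D8-phenylalanine transaminates to D7-phenylalanine, and
their hydroxylation products are D7-/D6-tyrosine, all calculations use the
pooled channels D8+D7 (phe), D7+D6 (tyr); the meal label D5 and the
infused D2-tyrosine are their own channels, and the FSR precursor pools
D5+D7+D8 (`pooled_ttr()`).

**Background correction.** `correct_background()` subtracts the −150 min
enrichment from all later TTRs. The reference is matched per
subject-visit (not per site): there is only one pre-infusion sample, drawn
from the antecubital catheter, and natural abundance does not differ
between sampling sites. Matching can be tightened to site level via `by`.
If data arrive already corrected the step is simply skipped
(`background_correct = FALSE` in the pipeline).

## Whole-body kinetics

The single-pool non-steady-state estimator treats plasma (plus rapidly
exchanging fluid) as one well-mixed pool of effective volume
`pV = 0.125 L/kg body weight`. Over a sample pair $(t_1, t_2)$:

$$R_a = \frac{F - pV\,\bar C\,\frac{E_2-E_1}{t_2-t_1}}{\bar E},
\qquad R_d = R_a - pV\,\frac{C_2-C_1}{t_2-t_1},$$

with $\bar C$, $\bar E$ pair means, attached to the midpoint
$(t_1+t_2)/2$. Two unit conventions collide here: `pV` is defined per kg
body weight while fluxes are per kg lean mass. The package rescales the
pool once, `pV_eff = pV × BW/LM` (`effective_pool_volume()`), so every
term of the equation shares per-kg-lean-mass units.

**Pairing convention.** Estimates are computed on *consecutive* sample
pairs of whatever samples survive validation, so a missing 90-min sample
simply yields a (60, 120) pair at midpoint 90. On the full design the
fasting pair (−60, −30) gives the baseline midpoint −45 and the
postprandial midpoints 15, 25, 35, 45, 55, 75, 105, 150, 210, 270, 330;
the (−30, 10) pair straddling the meal is kept but labelled
`"transition"`. No smoothing is applied to `C(t)` or `E(t)` before
differencing — the estimator sees the measured points.

**Oral appearance.** The D5 meal label identifies meal-derived
phenylalanine:

$$R_{a,oral} = \frac{R_{a,total}\,\bar E_{D5} +
pV_{eff}\,\bar C\,\frac{E_{D5,2}-E_{D5,1}}{t_2-t_1}}{r},$$

where `r` is the D5:tracee ratio of the meal protein. The default
(`mode = "corrected"`) includes the concentration factor $\bar C$ in the
pool-derivative term; without it the term has units of 1/min rather than
µmol/L/min and cannot be added to a flux. A `mode = "printed"` variant
evaluating the pool term as `pV·dE/dt` alone is retained for comparison
with analyses that used that literal form. Endogenous appearance defaults
to `Ra_total − Ra_oral` (`mode = "simple"`); a `subtract_tracer` mode also
removes the infusion rate for conventions that count the infusate in
total appearance. Which variant a given published analysis used cannot
always be determined from its typeset equations; the defaults here are
the dimensionally consistent forms, and both variants are exported so the
choice is explicit and testable.

**Hydroxylation, synthesis, net gain.** Phenylalanine leaves the free
pool only into protein synthesis or hydroxylation to tyrosine, so

$$Hydrox = R_{a,D2tyr}\,\frac{E_{D7D6,tyr}}{\bar E_{D8D7,phe}}, \qquad
Synthesis = R_{d,total} - Hydrox,$$

degradation equals endogenous appearance, and both convert to grams of
mixed protein via 273 µmol phenylalanine/g and 1440 min/day
(`to_grams_per_day()`). Net gain is synthesis − degradation. The
hydroxylation transfer assumes the D2-tyrosine Steele estimate reflects
total tyrosine turnover and that the product enrichment is near
quasi-steady state within a pair; early postprandial midpoints, where the
product pool is still filling, carry the largest bias (visible in the
simulator recovery, below).

**Splanchnic appearance.** `splanchnic_appearance()` integrates oral
appearance over 0–360 min (trapezoid) and reports it as a percentage of
ingested phenylalanine, plus the complement as the first-pass extraction
estimate. Both labels are reported because the literature attaches both
names to this quantity. If the supplied series starts after 0 min a zero
is prepended (no meal label is circulating at ingestion); a series ending
early is extended by its last value rather than extrapolated.

**Degenerate inputs.** Non-positive mean enrichments, non-increasing
times and non-positive labelling ratios are errors. Negative oral or
endogenous estimates — possible under measurement noise near the end of
absorption — are clipped to zero *with a warning*, never silently;
negative synthesis (hydroxylation exceeding disposal) is kept and flagged,
since clipping it would hide an inconsistency the user should see.

## Tissue arteriovenous balance

The two-pool model uses arterial and venous concentrations, enrichments
and arterial blood flow:

$$NB = (C_a - C_v)\,\frac{flow}{LM},\quad
FE = \frac{C_aE_a - C_vE_v}{C_aE_a},\quad
Uptake = FE\,C_a\,\frac{flow}{LM},\quad
Release = Uptake - NB.$$

For phenylalanine, uptake estimates tissue protein synthesis and release
estimates degradation. The identity `uptake − net balance − release = 0`
holds exactly by construction at every timepoint. Leg balances are
reported in µmol/min/kg LM — the only unit consistent with
`(Ca−Cv)×flow` — regardless of axis-label conventions elsewhere. Flow is
linearly interpolated to blood-sample times with constant extension at the
ends (flow is not measured at the baseline draw); the supplied flow is
used as-is, with no haematocrit (whole-blood vs plasma) correction. The
adipose bed, catheterised without a flow measurement, uses
`mode = "difference"`: concentration gradients in µmol/L only, with
uptake/release left `NA` rather than guessed. No three-pool
(intracellular) extension is attempted.

## Fractional synthesis rates

The precursor-product model is
$FSR = 100\,(E_{p,2}-E_{p,1}) / (\bar E_{prec}\,\Delta t)$, %/h for
muscle (biopsies at −30 and 360 min, the literal biopsy times — the
pre-meal biopsy follows tracer start, so the window deliberately spans
fasting and fed states) and %/day for plasma proteins. "Weighted average"
precursor enrichment is implemented as the time-weighted trapezoid mean
over the window (`precursor_average()`), since sampling is non-uniform; a
plain arithmetic mean is available by flag for sensitivity checks.

The muscle precursor is the biopsy free-pool pooled phenylalanine TTR
when present — two points, at the biopsy times. A two-point mean cannot
see the postprandial enrichment excursion between the biopsies, and on
simulated data this overestimates FSR by roughly 10% relative to the
dense-precursor truth; that is a property of the sampling design, not of
the estimator, and it is why the recovery guarantees below are stated for
constant or slowly varying precursors. Plasma-protein FSR windows all
start at meal ingestion (t = 0) and end at 60/120/240/360 min, for both
the infused-label and the meal-label (D5) channels; the meal-label
variant is reported separately because orally delivered label reaches the
liver at higher enrichment.

## Insulin indices and AUC conventions

`homa_ir()` is `G·I/(22.5 × 7.18)` (glucose mmol/L, insulin pmol/L);
`matsuda()` is `10000 / sqrt(G_f·18 · I_f/7.18 · Ḡ·18 · Ī/7.18)` with
post-meal means over 0–120 min. The constants 18 and 7.18 are the unit
conversions to mg/dL and µU/mL; the means default to trapezoid
(time-weighted) because sampling is non-uniform, with an arithmetic
option. `auc_trapezoid()` linearly imputes *interior* missing values
(via `zoo`) and refuses to extrapolate leading/trailing gaps; incremental
AUC subtracts a baseline defined by `baseline_summary()`: mean of −60 and
−30 min for concentrations, the −45 midpoint for kinetics, −30 min for
hormones.

## The forward simulator

`simulate_subject()` integrates, on a dense grid, a single well-mixed
phenylalanine pool

$$V\frac{dC}{dt} = R_{a,endo}(t) + R_{a,oral}(t) - k\,V\,C,$$

with $V = pV_{eff}$ and $k$ set by the fasting steady state
($k = R_{a,basal}/(V C_{basal})$), plus tracer channels (D8+D7 from the
infusion with the prime as the initial pool, D5 injected at
$r·R_{a,oral}$, D2-tyrosine from its infusion, D7+D6-tyrosine produced at
the hydroxylation flux scaled by the phe tracer enrichment) all cleared
at the same rate constant, and a tyrosine pool fed by its own
proteolysis, meal tyrosine and the hydroxylation product.

The generator's defaults are the study conditions it emulates:

* cohort: 12 subjects per group; body weight 75.4 ± 5.4 / 111.8 ± 12.1 kg
  and lean mass 58.1 ± 5.2 / 68.0 ± 8.7 kg (healthy weight / obesity);
* fasting fluxes: endogenous phenylalanine appearance 0.75 µmol/kg LM/min
  (CV 8%), tyrosine 0.40, fasting concentrations 55 / 50 µmol/L — typical
  adult whole-body values;
* meal: 26 g labelled casein, 7 900 µmol phenylalanine, label ratio
  r = 0.08, systemic appearance fraction 0.35, absorption a gamma density
  (shape 3, scale 20 min) peaking near 40 min, matching the early oral
  appearance peak of such meals;
* meal response: proteolysis suppressed by a smooth single-peak curve
  (depth 0.25, CV 15%, peak at 75 min, mostly resolved by 6 h);
  hydroxylation is a fraction 0.08 (CV 10%) of disposal scaled by
  `(C/C_basal)^α` with α = 1, encoding that amino acid oxidation rises
  with availability;
* tissue bed: femoral flow 0.45 L/min rising 20% postprandially, leg
  fractional extraction 0.45 at baseline, fasting net balance
  −0.05 µmol/min/kg LM, uptake rising 40% and release suppressed in
  proportion to the proteolysis curve; adipose gradients of a few µmol/L;
* protein pools: muscle FSR 0.08 %/h, plasma-protein FSR 10 %/day
  (CV 10%), incorporated from the running precursor enrichment;
* measurement: background TTR 2×10⁻⁴ added to all channels, lognormal
  noise with CV 2% (enrichment), 3% (concentration), 5% (flow).

A group effect is injected solely through
`suppression_group_multiplier` — e.g. 0.8 for 20% blunted postprandial
proteolysis suppression in one group; visit effects are plain parameter
shifts and no interleukin biology is modelled.

**What it does not emulate.** The simulator is exactly the one-pool model
the Steele estimator assumes, so whole-body recovery tests verify the
calculus and the sampling design, *not* robustness to multi-compartment
kinetics, recycling of label from protein breakdown, intracellular
dilution across tissue beds (a two-pool AV truth is generated directly),
splanchnic tracer dilution of the meal label, or assay-specific error
structure. Passing recovery tests therefore certifies the implementation
against its own stated model; on real data the known biases of these
methods (e.g. underestimated oral appearance from splanchnic dilution,
two-pool underestimation of degradation) apply unchanged.

**Numerics.** The pools are linear ODEs with smooth forcings, so the
integrator uses the exact exponential integrating factor with
piecewise-linear inflow over a fixed step (default 0.05 min; valid up to
the 0.1 min used for large replicate studies). This is exact for the
interpolated inflow and O(h²) overall, conserves tracer mass to better
than 10⁻⁷ relative (verified against the cumulative-balance ledger each
channel carries), and matches `deSolve::lsoda` at tolerance 10⁻¹⁰ in the
cross-check test, while being fast enough for hundred-replicate power
studies. The prime is an instantaneous bolus at −150 min (initial pool
`prime/V`). The −150 min sample is drawn *before* the prime and carries
only background enrichment. All randomness flows from one integer seed;
subject biology and visit-level noise use separate derived streams so the
same person can be re-measured across visits. Noise is mean-preserving
lognormal. Instabilities (non-positive pools, extraction reaching 1,
hydroxylation fraction reaching 1) abort with the offending parameter
named.

**Verification scales.** The recovery suite uses: one noise-free subject
at 1-min sampling (whole-body error < 2% of the true peak at every
midpoint) and three at the study grid (< 10% between midpoints 15 and
270); exact arteriovenous recovery (≤ 10⁻⁹, the relations are algebraic);
FSR closed forms (10⁻¹⁰ with constant precursor, < 1% under ±10% drift);
and 100 replicates of the 12-per-group blunted-suppression scenario at a
0.1-min step, where the group contrast — postprandial endogenous
appearance relative to the −45 min baseline, and baseline-relative net
protein gain AUC, the study's own within-subject conventions — must have
the injected sign in at least 95 replicates. These sizes keep the full
suite within a few minutes on one core while leaving each check
well-powered.

## Serialisation

`write_study_bundle()` stores a cohort as long CSVs plus a JSON manifest;
times are integer minutes relative to the meal and numeric values are
written at 6 significant digits, which is the precision at which
identical seeds are guaranteed byte-identical output.
`read_study_bundle()` validates schema version, file presence, site
labels, per-series time monotonicity and value signs before returning
tibbles.

## Known limitations

* Single-pool whole-body model: no multi-compartment or Bayesian/ODE-fit
  estimators; early postprandial hydroxylation carries the product-pool
  filling bias described above.
* Two-pool tissue balance only; transmembrane transport kinetics and
  three-pool models are out of scope.
* The two-biopsy free-pool precursor convention cannot track postprandial
  precursor excursions (≈10% FSR overestimate on simulated data).
* Group-comparison statistics (mixed models, post-hoc contrasts) are
  deliberately not reimplemented; standard tools apply directly to the
  tidy outputs.
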