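---
title: "Methods: probabilistic QIVIVE for bisphenol A"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic QIVIVE for bisphenol A}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qivive)
```

`qivive` implements a probabilistic quantitative in vitro to in vivo
extrapolation (QIVIVE) workflow for bisphenol A (BPA) and its glucuronide
(BPAG) and sulphate (BPAS) conjugates.  The pipeline runs in six stages:
a virtual population over the physiological priors; hierarchical Bayesian
calibration of a physiologically based kinetic (PBK) model against
multi-individual plasma time courses; two-phase global sensitivity analysis
(Morris screening, then eFAST); estimation of the free in vitro
concentration from the nominal assay concentration; two-phase approximate
Bayesian computation (ABC) reverse dosimetry reconstructing the oral dose
(`PORALDOSE`) that matches a target tissue concentration; and model-averaged
benchmark-dose (BMD) estimation with chemical-specific adjustment factor
(CSAF) and human-equivalent-dose arithmetic.

This vignette records the modelling assumptions, the defaults and their
rationale, the numerical choices, and the design decisions taken where the
underlying methodology left the implementation open.

## The PBK model

The model is flow-limited (venous equilibration): each tissue exchanges with
blood at its regional flow, with the exchanging concentration equal to the
tissue concentration divided by the tissue:blood partition coefficient.
Compartments are stomach, gut, liver, kidney, fat, slowly and rapidly
perfused tissue, and blood, for each of the three analytes, plus a lymph
pathway for parent BPA.  The differential system is solved in compiled code
through `deSolve`'s delay-differential interface, because two transport
processes are genuine delays:

* **enterohepatic recirculation** — first-order uptake from liver into bile
  (`K1_*_LIVER`), with the transported mass reappearing in the small
  intestine after a fixed biliary transit delay (default 4 h), where it
  competes between reabsorption (`GIPERM`) and faecal loss (`K1_*_GUT`);
* **lymphatic uptake** — a fraction `FracDOSELymph` of the dose is absorbed
  into lymph (`BELLYPERMLymph`, `GIPERMLymph`), leaves the lymph pool at
  rate `K1Lymph`, and arrives in venous blood only after the transit delay
  `Lymphlag`, bypassing first-pass metabolism.  This component produces the
  characteristic second plasma-BPA peak: `count_peaks()` on a simulated
  profile with `FracDOSELymph = 0.04, Lymphlag = 1.1` detects two maxima,
  and exactly one when `FracDOSELymph = 0`.

Both delay terms are implemented conservatively: the outflow of a transit
pool at time $t$ equals the inflow at $t - \tau$, with the in-between mass
held explicitly, so delayed transport cannot create or destroy mass and no
state can integrate negative.

**Oral uptake.** Ingestion is a zero-order infusion into the stomach over
`DRINKTIME` (default 0.1 h — the few minutes it takes to eat the dosed
cookie; the parameter appears in the model glossary but carries no prior, so
it is a fixed design constant).  The dose is split at intake into a hepatic
fraction (`FracDOSEHep`), a lymphatic fraction (`FracDOSELymph`), and an
unabsorbed remainder eliminated in faeces.

**Stomach emptying.** Only maximum and minimum emptying rates (`KEMAX`,
`KEMIN`) are tabulated, with no functional form.  We use a first-order
emptying rate that decays from `KEMAX` towards `KEMIN` as the meal clears,
$k(t) = KEMIN + (KEMAX - KEMIN)\,e^{-t/DRINKTIME}$.  This is a documented
assumption, configurable through the parameter set.

**Metabolism.** BPA is conjugated to BPAG and BPAS in gut tissue (before
portal transfer, i.e. true first pass) and in liver, by Michaelis–Menten
kinetics.  In vitro maximum rates (pmol/min/mg microsomal protein) are
scaled to the whole organ by `scale_vmax()`:
`Vmax_organ = Vmax_invitro * MPY * organ_mass * 60 * MW * 1e-9` mg/h.
Metabolite masses are tracked in their own mg; mass-balance checks convert
to BPA equivalents with the molecular-weight ratios (BPA 228.291, BPAG
404.418, BPAS 308.355 g/mol).

**Plasma binding.** Each analyte has bound and unbound blood pools.  A
fraction `FB_x` of all venous inflow enters the bound pool; bound material
returns to the unbound pool at first order (`K1_x_REMOVED_PLASMA`); only the
unbound pool perfuses tissues and is eliminated.  This realises "bound and
unbound in equilibrium such that the bound fraction is gradually removed".

**Elimination.** Urinary elimination is first order on the kidney tissue
amount (`K1_*_Urine`); faecal elimination collects the unabsorbed transit
pool and the non-reabsorbed fraction of biliary recirculation.

**Mass-balance re-parameterisation.** `build_parameter_set()` enforces the
logical constraints: fractional blood flows are renormalised to sum to
exactly one (preserving ratios), and fractional tissue volumes must leave
residual carcass mass.  When parameters are drawn *independently* (virtual
population, GSA, ABC), box ranges can jointly exceed the anatomical budget;
those callers use `on_volume_overflow = "rescale"`, which shrinks all
volume fractions proportionally to a 0.95 total.  With the tabulated
volume-fraction distributions this rescaling triggers for an appreciable
share of draws and biases volume means downward by up to ~2%; the
population tests account for that.

**Numerics.** Default output grid 0.01 h over 24 h; solver `lsoda` through
`dede` with `rtol = 1e-7`; total BPA-equivalent mass is conserved to
~1e-6 of the dose across 100 random parameter sets (the acceptance suite
asserts 0.1%), and halving the step changes the 0–3 h liver AUC by far less
than 0.1%.  A state more negative than 1e-4 of the dose raises an integrity
error.

**Dosimetry outputs.** `CVli` and `CVki` are the venous-equilibrium liver
and kidney BPA concentrations (mg/L).  The QIVIVE tissue-dose window is
0–3 h (which captures the maximum AUC); the sensitivity-analysis window is
0–5 h (the period of maximum output variance); both are arguments, not
constants.

## Priors and packaged posterior summaries

The packaged prior table (`bpa_priors()`) carries, per parameter, the
distribution family (normal, lognormal for body weight on the log scale,
or uniform), moments, truncation bounds, and a scope tag: eleven parameters
(uptake fractions, lymph lag, hepatic microsomal yield and six
physiological quantities) are individual-specific; the rest are global.
Where the source tables print conflicting blocks, the block consistent with
the printed prior quantile summaries was adopted; the handful of obvious
misprints corrected in transcription are listed in the package sources.

The calibrated posterior summaries for the fourteen volunteers of the
original study are packaged (`bpa_posterior_global()`,
`bpa_posterior_individual()`, `bpa_posterior_sigma()`) because later stages
consume them as inputs: GSA ranges (`posterior_ranges()` takes the 95%
interval for global parameters and the min/max interval endpoints over the
fourteen volunteers for individual-specific ones) and the CSAF.

## Calibration

`run_mcmc()` is a component-wise adaptive random-walk Metropolis sampler
over the hierarchical vector: global parameters, per-individual parameters
(independent truncated priors per individual — no hyper-distribution,
matching the structure of the published per-individual summaries), and
per-analyte error SDs with uniform priors over the published prior spans.
The Gaussian error model operates on the natural concentration scale
(consistent with the magnitude of the published error SDs); a log-scale
option exists but is off by default.  Proposal scales adapt during burn-in
towards the 0.23–0.44 acceptance window.  Updating an individual-specific
component re-simulates only that individual; predictions are cached.
Convergence is monitored with the Gelman–Rubin statistic across chains.

The exact posterior values of the original calibration are not reproducible
— they require the unpublished volunteer plasma data — so the package
substitutes parameter-recovery evidence: calibrating on synthetic plasma
data generated at known parameters, the 95% credible intervals cover the
generating values in well over 90% of replicate-parameter combinations
(twenty replicates in the acceptance suite, at reduced iteration counts:
two virtual individuals, two chains, 120 retained iterations, simulation
step 0.2 h).

## Global sensitivity analysis

`morris_rank()` implements elementary-effects screening with one-at-a-time
trajectories (defaults: 50 trajectories, 8 levels — unstated in the source
methodology, so configurable), repeated six times with the final rank taken
as the mode of per-repeat ranks.  `efast()` implements the extended FAST
estimator: driving frequency `floor((N-1)/2M)` with interference factor
`M = 4`, first-order indices from the driver harmonics and total-order
indices from the complement band below half the driving frequency.  Two
implementation details matter:

* complement frequencies are **spread** across the admissible band rather
  than cycled `1, 2, ...`; with few complementary parameters the cycled
  assignment puts them on closed low-order Lissajous curves that sample the
  complementary space poorly and noticeably bias the indices;
* the spectral variance components are pooled across random-phase
  resampling curves before forming ratios.

With 1025 points per curve and two resamples the estimator reproduces the
closed-form Ishigami decomposition to within 0.05 on every index, which the
test suite asserts.

Screened-out parameters are held at their defaults (prior means, or range
midpoints for uniforms).  The top-10 set feeds eFAST and the top-8 set
feeds ABC, both configurable.  The Lowry display (`lowry_bounds()`,
`plot_lowry()`) stacks main effects and interactions per parameter, with
the interaction ribbon bounded below by the cumulative main effects and
above by the cumulative total effects capped at one.

On this model the three top-ranked parameters for liver tissue dose —
hepatic microsomal yield and the liver Vmax/KM for glucuronidation — are
co-dominant, jointly multiplicative in the intrinsic clearance, and their
summed total effects exceed 100% of variance (total-order indices overlap).
This differs markedly from the published ~61%; see *Known limitations*.

## Free in vitro concentration

`partition()` allocates the nominal mass over five well compartments at
equilibrium — aqueous medium, serum constituents, well plastic, headspace,
cells — with affinities expressed as log-Kow regressions (coefficients in
`vcba_regression()`), Henry's-law headspace partitioning at 37 °C, and a
deliberately negligible default cell sink (~3 pL per cell).  The
fate-model constants of the original in vitro distribution algorithm are
not recoverable from the published account; the shipped serum-regression
intercept is therefore an explicit **calibration**: it reproduces the
published free:nominal ratio of ≈0.499 for BPA at 5% serum in a 24-well
plate, and the same constants then predict ≈0.498 for the 384-well
geometry, matching the published "48–49% of nominal" across all four
assays.  Because all sinks are linear, the ratio is concentration
independent (asserted to within 1% across the tested range), and free
concentration is `nominal x fraction_free_medium`, matching the published
tables' convention.  First-order abiotic degradation over the exposure
duration is computed (`degradation_factor`) but not folded into the free
concentration column by default, again matching the published tables; at
BPA's degradation rates the factor is ~0.98 over 24 h.

## ABC reverse dosimetry

For each target free concentration the workflow reconstructs the oral dose
distribution in two phases (`rejection_phase()`, `abc_mcmc()`), with the
published design constants as defaults: 5000 uniform draws of the top-8
sensitive parameters plus dose, retention within ±7.5% of the target,
then four ABC-MCMC chains of 50,000 iterations with multivariate Gaussian
proposals scaled from the phase-1 covariance (`2.38^2/d`), accepting moves
whose summary falls within ±5%.  Choices the source left open:

* the **matched summary** is the peak tissue concentration over the
  simulation window (default), with a time-averaged 0–3 h AUC one flag
  away; the choice is recorded in the result's configuration;
* the dose proposal range is auto-bracketed by a 20-point logarithmic dose
  scan before phase 1;
* non-sensitive parameters are fixed at central values during ABC;
* chains start at phase-1 points that already satisfy the phase-2
  tolerance, so every pooled sample is in-band by construction and no
  burn-in is discarded;
* a target of zero is rejected (relative tolerance undefined), and a chain
  whose acceptance falls below 1% shrinks its proposal scale and warns.

On a toy linear kinetic model the pooled two-phase dose posterior matches a
brute-force grid conditional to Kolmogorov–Smirnov distance < 0.05, and
phase-1-only and two-phase means agree within Monte-Carlo error.  On the
PBK model the posterior mean dose is strictly increasing in the target
concentration, mirroring the ordering of the published dose table.

## Benchmark dose

`fit_model_family()` fits the four continuous families of the regulatory
default set — exponential and Hill, 3- and 5-parameter, with lognormal
response (Gaussian ML on the log scale) — and `bmd_at_bmr()` solves each
family's BMD as the dose producing a 10% change in median response over the
modelled background, averaging across families with Akaike weights (equal
weights reduce to the arithmetic mean of family BMDs).  A family whose
fitted plateau lies below the benchmark response yields no finite BMD and
is excluded with its weight renormalised; a flat response is flagged with
no BMD.  `bootstrap_bmdl()` runs a parametric bootstrap under the averaged
fit (each replicate draws a family by weight, regenerates lognormal
responses, refits everything) and reports BMDL/BMDU as the 5%/95% quantiles
of replicate BMDs — the one-sided 95% limits of the 90% interval — with
1000 replicates by default.  Responses are treated as individual continuous
observations; replicate rows are not collapsed.

The reconstructed dose-response sets pair the posterior mean (and 2.5%,
97.5%) doses with the natural-scale responses: log2 fold inductions are
exponentiated; percentage activities have negatives and the explicitly
flagged low-concentration anomalies set to zero and a constant of one added
(the lognormal fit requires positive responses).  The anomaly rule is an
explicit per-assay exclusion list, not an automatic filter.

**Dose units.** The published BMDL10 table is labelled µg/kg BW/day, but
the abstract of the source study states the BMDL10 values were calculated
in ng/kg BW/day, and only the ng scale is arithmetically consistent with
the printed dose-response tables (a 10% response change occurs near 1 µg/kg
= 1000 ng/kg for the pregnane-X-receptor assay, matching the printed 1300).
The acceptance script therefore converts the tabulated doses to ng/kg
before BMD analysis, reporting values on the scale the tables print.

## The synthetic-data generators

`sample_population()` draws body weight, fractional volumes and flows from
their prior families (independent truncated draws — the organ-mass
covariance of a real virtual-population generator is not reproduced) and
re-parameterises every row.  `generate_hbm()` emulates the biomonitoring
design the calibration expects: by default fourteen virtual volunteers, a
single 100 µg/kg oral dose, three analytes sampled on a 0–24 h grid
densified over the absorption phase (the original volunteer schedule is not
published), and independent zero-truncated Gaussian noise with per-analyte
SDs defaulting to the published posterior error-SD magnitudes (0.6, 199,
23 µg/L).  The generating parameters are returned for recovery tests, and
an individual whose simulation fails is re-drawn (at most five times, with
a message).  `generate_assay()` produces Hill-curve concentration-response
tables in the dashboard layout, in either response encoding.  All
generators are pure functions of their specification and seed.

What passing tests on these generators do *not* show: real plasma data have
correlated physiology, non-Gaussian error, and model misspecification, none
of which the generator emulates; parameter-recovery results demonstrate
internal consistency of the sampler, not fidelity of the PBK model to human
kinetics.

## Problem sizes in the shipped tests

The acceptance suite runs reduced but honest configurations chosen to keep
a full check of the pipeline practical on one core: eFAST at 513 points
per parameter (the published-scale check) and 1025 for the analytic
validation; 1000 bootstrap replicates for BMDL; twenty recovery replicates
with two virtual individuals, two chains and 120 retained iterations; ABC
with 4 × 4000 iterations on the toy model and 2 × 250 on the PBK model.
These sizes are the package's test design, stated here so results are
interpretable; production analyses should use the published-scale defaults
(`abc_config()`, `bootstrap_bmdl(replicates = 1000)` or more).

## Known limitations

* **Absolute dose scale of reverse dosimetry.**  With the tabulated
  metabolic constants, scaled to the whole liver, hepatic intrinsic
  clearance is so high that liver tissue BPA concentrations per unit dose
  are two orders of magnitude below what the published dose table implies.
  The published PORALDOSE values are not desk-reproducible (they depend on
  the unpublished calibration data and engine internals), and the package
  therefore validates reverse dosimetry by oracle equivalence and
  monotonicity rather than by absolute dose comparison.
* **Sensitivity-share discrepancy.**  The summed top-3 total effects for
  the tissue-dose outputs exceed 100% here, against the published ~61/55%:
  in this implementation the three clearance-controlling parameters (MPY,
  liver Vmax and KM) are jointly multiplicative and co-dominant with heavy
  interaction shares.  The discrepancy is reported, not tuned away.
* **BMDL for the most potent assay.**  The model-averaged BMDL10 for the
  estrogen-receptor assay comes out ~3x above the published value while the
  pregnane-X-receptor assay reproduces within ~7%; the published lower
  limit implies bootstrap curves rising 10% at ~30x below the lowest
  tested dose, which this implementation's fits do not produce.  Both
  numbers are computed and reported as-is.
* The cell-partitioning, growth and cytotoxicity sub-models of a full
  dynamic in vitro fate simulation are out of scope, as are inhalation and
  dermal routes, repeated-dose regimens and gestational sub-models.
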