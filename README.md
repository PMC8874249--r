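# qivive

Probabilistic quantitative in vitro to in vivo extrapolation (QIVIVE) for
bisphenol A (BPA) and its glucuronide (BPAG) and sulphate (BPAS)
conjugates.

High-throughput screening assays report concentration–response in vitro;
risk assessment needs dose–response in vivo.  `qivive` bridges the two with
a reproducible, uncertainty-aware pipeline for toxicologists and
kinetic modellers:

1. **PBK model** — a physiologically based kinetic model of oral BPA uptake
   with lymphatic bypass, first-pass gut and liver conjugation,
   bound/unbound plasma pools and enterohepatic recirculation, solved as a
   delay differential system (biliary transit and lymphatic lags) in
   compiled code.
2. **Hierarchical calibration** — Metropolis-within-Gibbs MCMC of global
   and per-individual parameters against plasma BPA/BPAG/BPAS time courses
   under a Gaussian error model.
3. **Global sensitivity analysis** — Morris elementary-effects screening
   followed by eFAST variance decomposition (main effects S\_M and total
   effects S\_T), with Lowry-plot output.
4. **Free in vitro concentration** — an equilibrium mass-balance model of
   the assay well (medium, serum, plastic, headspace, cells) converting
   nominal to bioavailable concentrations.
5. **ABC reverse dosimetry** — two-phase approximate Bayesian computation
   (rejection within ±7.5%, then ABC-MCMC within ±5%) reconstructing the
   distribution of oral dose whose liver/kidney tissue concentration
   matches each free in vitro concentration.
6. **Benchmark dose** — model-averaged BMD/BMDL₁₀/BMDU₁₀ at a 10% benchmark
   response from four continuous families (exponential and Hill, 3- and
   5-parameter, lognormal response) with Akaike weights and a parametric
   bootstrap, plus chemical-specific adjustment factor (CSAF = posterior
   97.5% quantile / median) and human-equivalent-dose arithmetic.

Synthetic-data generators emulate the biomonitoring study design (14
volunteers, single 100 µg/kg oral dose, three analytes, double-peak
kinetics from lymphatic lag) and ToxCast-style assay tables, so the whole
pipeline is testable end to end without external downloads.  The four
published assay datasets, prior tables, posterior summaries and
physicochemical constants ship as plain-CSV package data.

## Worked example

```r
library(qivive)

## forward PBK simulation at the study dose
params <- build_parameter_set(default_parameters())
sim <- simulate_pbk(params, dose_event(100), duration = 24)
max(sim$series$plasma_BPA)    # 2.98 ug/L peak plasma BPA
pbk_auc(sim, "CVli", c(0, 3)) # 0.00177 mg*h/L liver tissue AUC

## free in vitro concentration for the lowest tested concentration
pr <- partition(um_to_mgl(0.01, 228.291), bpa_physchem(),
                assay_setup("24-well", serum_fraction = 0.05))
pr$fraction_free_medium       # 0.499: half the nominal is bioavailable

## CSAF from the calibrated posterior of the plasma-binding fraction
fb <- subset(bpa_posterior_global(), parameter == "FB_BPA")
csaf(median = fb$median, q97.5 = fb$q97.5)  # 2.52

## model-averaged BMDL10 for the pregnane X receptor assay, pairing the
## reconstructed mean doses (ng/kg BW/day) with natural-scale responses
pd <- subset(bpa_poraldose(), assay == "ATG_PXR_TRANS_up")
resp <- preprocess_response(
  subset(bpa_assays(), assay == "ATG_PXR_TRANS_up")$response,
  "log2_fold_induction")
res <- bootstrap_bmdl(dose_response_set(pd$dose_mean * 1000, resp),
                      replicates = 1000, seed = 1)
res
#> <bmd_result> BMR 10%: BMD 1936, BMDL 1213, BMDU 3998 (1000 bootstrap replicates)
apply_csaf(res$bmdl10, 2.52)  # 481 ng/kg BW/day after the CSAF
hed_and_tdi(8960, 0.068, 150) # HED 609, t_TDI 4.06 ug/kg BW/day
```

The BMD result says: along the reconstructed in vivo dose axis, a 10%
increase in pregnane-X-receptor fold induction over background is reached
at ~1.9 µg/kg-day equivalent (1936 ng/kg BW/day), with a lower 95%
confidence limit of ~1.2 µg/kg-day; dividing by the CSAF of 2.52 adjusts
for inter-individual kinetic variability.

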