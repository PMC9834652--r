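---
title: "Net energy evaluation by indirect calorimetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Net energy evaluation by indirect calorimetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swineNE)
```

## The problem

Feed is the dominant cost in pig production, and high-fiber milling
by-products such as wheat bran substitute for corn and soybean meal only if
their *available* energy is known. Gross energy (GE) overstates that
availability badly for fibrous feeds: part of GE leaves in feces (the
digestible-energy step, DE), part in urine and methane (metabolizable
energy, ME), and part is dissipated as the heat increment of digestion and
nutrient deposition. Net energy (NE) subtracts all three and is the scale on
which protein- and fiber-rich ingredients are penalised and starch- and
fat-rich ones favoured. This package implements the full measurement chain
by which NE is determined in respiration chambers and the statistical layer
by which NE is then predicted from routine chemistry.

## The energy partition model

For one pig over one collection period, with intakes and outputs on a daily
basis:

* **Digestibility.** For energy or any nutrient,
  ATTD = 100 (Fi − Ff)/Fi, with Fi the intake and Ff the fecal output.
  DE (MJ/kg DM) = (GE intake − fecal GE)/DM intake.
* **Metabolizability.** ME = DE − (urinary energy + methane energy)/DM
  intake, with methane valued at 39.5 kJ/L.
* **Heat production.** From chamber gas exchange by the Brouwer equation,
  HP (kJ) = 16.18 O₂ + 5.02 CO₂ − 2.17 CH₄ − 5.99 urinary N
  (litres and grams per window). Fed-state HP is computed per chamber-day
  from cumulative daily gas volumes and averaged over days; fasting heat
  production (FHP) is measured over an 8-h overnight window at the end of
  the stay and extrapolated by ×(24/8) to the daily basis.
* **Retention.** RE = ME intake − HP; its protein component is
  REP = N retention × 6.25 × 23.86 kJ/g, and the lipid component is the
  remainder (negative REL — lipid mobilisation — is flagged, not rejected).
* **Net energy.** NE (MJ/kg DM) = (RE + FHP)/DM intake, i.e. retained
  energy plus the maintenance expenditure that FHP proxies.

Energy flows are scaled by metabolic body weight BW^0.60 when compared
across pigs; all internal arithmetic is in kJ, with MJ/kg DM only at report
boundaries. Because HP rises with intake, diet comparisons adjust total HP
to a reference ME intake (default 2,254 kJ/kg BW^0.60/d) by a
within-period covariance: a single straight line THP = a + b·MEI is pooled
across the pigs of one period and each pig is moved along the slope,
`adjust_thp_for_mei()`. Pooling one slope per period (rather than per diet)
is the only identifiable choice at 6–8 pigs per period; a per-diet slope
would consume most of the degrees of freedom.

Per-pig-first aggregation is the default throughout: DE/ME/NE and ratios
are computed for each pig and then averaged per diet. Ratios of diet means
differ slightly (this is visible when checking utilization ratios computed
from rounded diet means) and are not what chamber studies report.

## Ingredient values by the difference method

A test ingredient cannot be fed alone, so it is fed at 30% of a basal
corn–soybean-meal diet. The basal mixture's energy is the basal diet's
value divided by the mixture's share (default 0.97; minerals, vitamins and
carrier are treated as energy-free). The ingredient's calculated values
are then

E_ingredient = (E_test_diet − f_mix · E_mixture)/f_test,

applied to GE, DE, ME and NE alike. Because both diets contribute sampling
error, the chain is re-anchored to the ingredient's bomb-calorimetry GE
(GEm): DE = GEm·DEc/GEc, ME = DE·MEc/DEc, NE = ME·NEc/MEc, which collapses
algebraically to NE = GEm·NEc/GEc — the package asserts the chained and
collapsed forms agree to 1e-12.

**Inclusion-fraction basis.** Formulations are as-fed but energies are per
kg DM. The default converts as-fed inclusions to DM fractions using the
test ingredient's DM and the analyzed diet DM, inferring the non-test
portion's DM from their difference (corn and soybean meal DM are not
observed separately); `basis = "as-fed"` is available for sensitivity
checks. On the packaged reference data the two bases differ by well under
1%, far less than the propagation error of the method itself: note that
ingredient values inherit roughly 1/f_test ≈ 3.3 times the diet-level
error, which is why ingredient tables derived from per-animal records
cannot be regenerated exactly from rounded diet means.

## Prediction equations and their validation

Two Noblet-type equations predict NE from DE or ME plus proximate
chemistry (`noblet_ne1()`, `noblet_ne2()`); a determined NE is validated by
its relative error against the mean of the two predictions. The screening
layer is a Pearson correlation matrix with t-transform p-values, and
prediction equations are built by `ols_fit()` (least squares with
R² , RMSE = √(SSE/(n−p−1)), and Gaussian-likelihood AIC = n ln(SSE/n) + 2k,
BIC = n ln(SSE/n) + k ln(n), k counting the intercept) and
`stepwise_select()` — forward selection on partial-F p-values with a
backward check and a variance-inflation cap (default VIF ≤ 10).

**Entry/stay levels.** The defaults are 0.15/0.15, the conventional
stepwise levels for small feed-evaluation datasets. This is a deliberate
choice: with n = 6 samples the partial-F p-value of a useful second
predictor is typically ≈0.14, so a 0.05 entry level would terminate every
search at one variable and the well-known two-predictor equations
(GE + CP, GE + ME) could never be selected. Both levels are arguments, and
the 0.05 behaviour is exercised in the tests.

**Information criteria.** Published AIC/BIC values for such equations
follow software-specific likelihood constants and are not comparable across
implementations; the package documents its convention and uses R² and RMSE
for ranking.

## The chamber simulator

`simulate_experiment()` generates complete experiments with known ground
truth so that every stage is testable without animal data. Per pig it draws
body weight and DM intake, derives true intakes from diet chemistry, sets
fecal outputs from target digestibilities, urinary and methane energy as
fixed fractions of DE, fixes retained energy from the diet's target NE via
RE = NE·DMI − FHP·BW^0.60, and then *inverts* the Brouwer equation at the
configured respiratory quotient (O₂ = (HP + 2.17 CH₄ + 5.99 N)/(16.18 +
5.02 RQ), CO₂ = RQ·O₂) so the generated gas volumes reproduce the intended
heat production identically. Urinary N closes the nitrogen balance at a
configured protein share of RE; the fasting window is an 8-h Brouwer
inversion at the fasted RQ with urinary N prorated by time.

Default conditions mirror a growing-pig chamber study with 30% wheat-bran
diets: 6 pigs per diet of 41 ± 2 kg, DMI 0.156 kg/d per kg BW^0.60 (ME
intake ≈ 2,250 kJ/kg BW^0.60/d), GE digestibility 0.80, urinary and
methane losses 3.1% and 0.4% of DE, RQ 1.08 fed / 0.82 fasted, FHP
800 kJ/kg BW^0.60/d, NE/ME 0.80 and a protein share of RE of 0.42.
Measurement noise is multiplicative log-normal (mean 1) with a 3%
coefficient of variation, applied *after* construction and only to measured
outputs and gas volumes — so energy is conserved in truth but not in the
measurements, as in real chambers. Intakes are left exact (weighed feed);
the noise CV is a single knob rather than per-instrument error models.

What the simulator does **not** emulate: within-day gas kinetics and
circadian activity, analyzer drift and chamber washout, diet refusals,
growth across periods, and between-pig variation in true digestibility
(noise enters measurements, not biology). Passing recovery tests therefore
demonstrates that the analysis chain is algebraically correct and unbiased
under calibrated noise — not that it is robust to structured errors real
chambers can produce.

## Numerical and design choices

* **CV convention** in composition summaries: population denominator (n) by
  default, matching how reference composition tables are typically printed;
  a `sample` switch is provided. Printed CVs in survey tables often follow
  no single convention across analytes — the package reports computed
  values and does not force agreement.
* **Degenerate inputs:** zero intake, nonpositive GE, IDF > TDF and
  fraction violations are errors; fecal output exceeding intake (negative
  digestibility), negative ME after losses, negative REL and negative
  difference-method energies are flagged with warnings but returned, since
  they occur in real noisy data.
* **Missing analytes** stay `NA` rather than 0, so a missing value can
  never silently bias a regression; SDF and CP are derived (TDF − IDF,
  6.25 N) only when absent, and checked for consistency (±0.02 and ±0.05
  % DM, absorbing two-decimal rounding) when present.
* **Ties in stepwise ranking** break by fewer parameters, then alphabetical
  predictor names, making selection fully deterministic.
* **Calibration checks** ("diet mean within 3 SE of truth") use the SE of
  the diet mean estimated across simulation replicates; a per-replicate SE
  from 6 pigs has t-tails (5 df) and would cap the achievable coverage near
  97% regardless of the estimator's quality.
* **Problem sizes** used by the test-suite recovery studies: 8 diets × 6
  pigs with 5 fed days each per replicate, 20–25 replicates for the noisy
  calibration — sizes chosen to match the design being emulated while
  keeping a full run in seconds.

## Worked example

```{r example}
study <- wheat_bran_study()
sim <- simulate_experiment(simulation_config(seed = 7, noise_cv = 0),
                           study$diets)
res <- run_energy_analysis(study$ingredients, study$diets,
                           sim$chamber_records, sim$balance_records)
res$diet_balance[, c("diet_id", "DE", "ME", "NE", "NE_over_ME")]
```

With zero noise the recovered diet values equal the simulator's ground
truth to machine precision; `validate_reference_tables()` runs the same
machinery over the packaged reference dataset and reports every derivable
printed cell.

## Known limitations

* n = 6 ingredient samples supports at most two-predictor equations and no
  out-of-sample validation; the regression layer reports, it does not
  cross-validate.
* Mixed-model inference with random period/chamber effects and multiple-
  comparison letters is out of scope; `aggregate_by_diet()` reports simple
  means.
* The difference method assumes energy additivity and an energy-free
  mineral carrier; ingredients interacting with the basal mixture (e.g.
  strong hindgut fermentation shifts) violate the assumption and the method
  inherits that bias.
* One basal diet per analysis: designs with several reference diets need
  to be split into separate runs.
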