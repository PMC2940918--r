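---
title: "A prevalence-based burden model for metabolic syndrome in hypertension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A prevalence-based burden model for metabolic syndrome in hypertension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsburden)
```

## The model in one paragraph

`metsburden` estimates the annual health-service burden of metabolic
syndrome (MetS) among hypertensive adults with a prevalence-based approach:
a snapshot of the prevalent population in one year, not a lifetime
simulation of incident cases. Hypertensive persons in each age-band × sex
stratum are distributed over risk groups defined by the number
$k \in \{0,\dots,4\}$ of additional MetS components present (MetS
$\Leftrightarrow k \ge 2$ under the modified ATP III "three of five"
rule). Cardiovascular events, attributable mortality and type 2 diabetes
are attributed to the groups through relative-risk gradients anchored to
sourced overall rates, and four cost components — antihypertensive drugs,
physician follow-up, acute cardiovascular events, diabetes management —
are aggregated in euro millions per year, projected to a horizon year with
compound annual growth rates (CAGRs), and optionally discounted.

## Component classification

The modified ATP III thresholds (`atp3_thresholds()`) use the 140/90 mm Hg
treatment threshold for blood pressure rather than the original 135/85;
the unmodified profile is available by argument. Inequality directions are
part of the definition and are pinned by boundary tests: waist strictly
`>`, HDL strictly `<`, triglycerides, glucose and either blood pressure
inclusive `>=`; known diabetes satisfies the glucose criterion at any
measured value.

Two classification decisions were genuinely open:

* **Treated-but-controlled hypertensives.** A subject whose measured
  pressure is below threshold but who carries an antihypertensive-treatment
  flag counts as hypertensive — the modelled population is defined by the
  condition, not by momentary control. The flag is optional, so
  classification on raw pressure alone is equally available.
* **Out-of-model subjects.** `assign_risk_category()` refuses
  non-hypertensive input rather than silently dropping it; filtering is an
  explicit upstream step. Silent drops in attribution code are a classic
  source of untraceable population leaks.

## Synthetic microdata: what it emulates and what it does not

The conditional-structure stage needs survey-style microdata; the package
generates its own (`simulate_microdata()`), emulating a public-use health
survey: age-band × sex strata with population shares, survey weights, and
five binary component indicators with controllable marginals and
dependence. Dependence is a **Gaussian copula**: indicators are a latent
multivariate-normal draw thresholded at the Gaussian quantiles of the
stratum marginals. The latent correlation matrix spans
independence-to-strong-clustering with a single parameter block, which is
exactly what the downstream tests need to vary; no claim is made that real
risk-factor clustering is Gaussian. The generator deliberately does *not*
simulate raw continuous measurements (waist, lipids) or survey design
effects (clusters, PSUs, post-stratification), so passing tests say
nothing about measurement error or design-based variance in real surveys —
they validate the estimation and calibration arithmetic under a known
dependence structure.

Defaults: seed 20080101; age bands 20–29 … 70–79, 80+ (the open-ended band
samples ages 80–89); equal or log-normal weights. A fixed spec yields a
bit-identical record stream and leaves the caller's RNG state untouched.

## Conditional structure and IPF calibration

`estimate_conditional_matrix()` tabulates, per stratum, the weighted
relative frequency of the $2^4 = 16$ subsets of the non-BP components
among hypertensive records (canonical order: binary counting, obesity most
significant). Strata with no hypertensive records are an error listing the
offending strata — pooling across strata silently would change the
age structure of the reference.

Transferring the reference structure to a country with different component
levels is done by **iterative proportional fitting** on each 16-cell table
with the four single-component marginals as fitting margins. IPF preserves
every odds ratio of the reference while matching the targets, which is the
natural formalisation of "apply the reference's clustering structure to
local prevalence data". Numerical choices:

* zero reference cells are lifted to $10^{-9}$ before fitting so any
  margin strictly inside $(0,1)$ stays reachable;
* targets are clipped to $[10^{-6}, 1 - 10^{-6}]$;
* convergence at worst marginal discrepancy $< 10^{-8}$, at most 10,000
  iterations, with the per-iteration discrepancy history retained — the
  tests check it is monotonically non-increasing;
* non-convergence is an error reporting the worst discrepancy, never a
  silent partial fit.

The suite validates IPF against a closed-form oracle: a 2×2 table with
margins 0.5/0.5 and odds ratio 4 has cells (1/3, 1/6, 1/6, 1/3); embedding
it in the 16-cell space with two independent components, the fitted cells
agree to $10^{-6}$. A parameter-recovery test generates $10^5$ subjects
under a block-diagonal latent correlation (two correlated pairs), where
the true 16-cell structure factorises into two bivariate-normal orthant
tables computed by 1-D numerical integration, and checks estimate →
calibrate recovers every cell within 3 standard errors.

`decompose_population()` then converts per-stratum hypertensive counts
into group counts; conservation (groups sum to the input count) is exact
up to floating point and is tested at $10^{-9}$ relative.

## Consequences and costs

For each outcome the parameter pack carries an overall rate per 1,000
hypertensives and a gradient $rr_k$ with $rr_0 = 1$, non-decreasing in $k$
(pack validation enforces both). `calibrate_group_rates()` returns
$b \cdot rr_k$ with $b = \text{overall} / \sum_k w_k rr_k$, so the pooled
rate reproduces the sourced overall rate exactly — the calibration
identity the acceptance suite asserts.

Design decisions in the cost layer:

* **Even distribution of management costs.** Drug and physician costs are
  spread evenly over the five risk groups (same treated proportion and
  unit costs per group). Real prescribing is skewed toward high-$k$
  patients, so the MetS share of drug costs is, if anything,
  underestimated.
* **Death outcomes.** Cardiovascular death is an event with an acute cost;
  attributable all-cause mortality is a separate outcome with no
  downstream cost. Modelling them as distinct configurable outcomes avoids
  double-counting management costs for decedents.
* **Continuation (adherence).** The continuation rate scales dispensed
  drug cost and treatment-dependent new-onset diabetes, but not physician
  visits — patients who discontinue therapy still attend follow-up. This
  makes continuation a weak lever on totals, which matches the behaviour
  of the one-at-a-time analysis.
* **Static annual snapshot.** Event rates are first-event rates on a
  population initially free of cardiovascular disease; no within-year
  competing-mortality adjustment, no event history.
* **Rounding.** All internal arithmetic is unrounded; reports round euro
  millions to the nearest million and percentages to integers, half away
  from zero, at serialisation only. `total = drug + physician + cvd + t2d`
  holds exactly before rounding for every slice.

## Projection and discounting

Component marginals among hypertensives and hypertension prevalence each
compound with their own CAGR, $\min(1, p_0 (1+g)^y)$; demographic change
enters only through horizon-year stratum populations. Factorising the two
drivers ("aging population" vs "rising component prevalence") makes each
independently testable: zero CAGRs with unchanged demography reproduce the
base year exactly, and doubling the horizon population doubles counts and
costs exactly. Horizon costs stay at base-year prices.

Discounting uses the single-snapshot convention: the horizon-year annual
cost is discounted back over the whole base-to-horizon interval,
$\text{amount}/(1+r)^{12}$ for 2008→2020 at the conventional 3 %. This is
the convention uniquely consistent with all three published discounted
2020 country totals, which the acceptance suite recomputes to the million.

## Sensitivity analysis

Scenarios are univariate by construction: one constructor per perturbation
(±20 % on a unit-cost family, continuation scaling capped at 1, treated
share, incident-only diabetes, discount rate), and `apply_scenario()`
returns a pack in which everything except the targeted factor is
bit-identical to baseline (tested with `identical()` after undoing the
one change). Because each cost component is linear in its unit-cost
family, scaling a family by $1+\delta$ moves exactly that component by
$1+\delta$ — `scale_cost_component()` applies the same identity directly
to a published cost breakdown, which is how the acceptance suite checks
the ±20 % sensitivity cells. The incident-only diabetes scenario costs
incident cases plus treatment-attributable new-onset cases instead of the
prevalence pool; pack validation requires incidence ≤ prevalence, so this
always lowers the diabetes component.

## The illustrative parameter pack

The sourced national inputs behind the original analyses (surveys, sales
data, country cost studies) are not redistributable, so `demo_pack()`
builds a fully in-code illustrative pack for a fictional high-burden
country. Choices, made once at design time:

* demography: ~68 m adults 20+, age shares declining from 16 % to 8 % per
  decade band, mild aging by 2020; hypertension prevalence rising from
  12 % (20–29) to 88 % (80+);
* component marginals among hypertensives with linear age gradients
  (obesity 45→70 %, triglycerides 40→55 %, impaired glucose 25→55 %, low
  HDL 28→32 %), giving a MetS share of hypertensives near 60 %;
* treatment: 60 % treated, six drug classes with plausible 2008-era euro
  costs, continuation 0.46–0.65, new-onset-diabetes relative risks above 1
  only for diuretics, beta-blockers and combinations;
* rates per 1,000 hypertensives: cardiovascular events totalling 22,
  mortality 2.4, diabetes prevalence 169, incidence 12;
* relative-risk gradients: events/mortality (1, 1.5, 2.1, 2.9, 3.8) and
  diabetes (1, 2.2, 6.5, 12.5, 20). The gradients were chosen so that,
  combined with the pack's own risk-group mix, the MetS/non-MetS rate
  ratios land near the field's headline figures — about twofold for events
  and mortality and about sixfold for diabetes prevalence — which the
  acceptance script recomputes at run time rather than asserting as
  constants.

CAGRs (hypertension 1 %, obesity 2.2 %, glucose 2.5 %, triglycerides 1 %,
HDL 0.4 %) produce a substantial horizon-year rise without capping any
prevalence.

## Problem sizes and reproducibility

The default test suite runs the generator at $10^4$–$10^5$ subjects
(marginal-recovery and parameter-recovery checks use $10^5$ with 3-SE
tolerances; pipeline tests use 15,000–20,000, where IPF across 14 strata
converges in well under a second). `run_pipeline()` is fully deterministic
given its configuration: the reference simulation is seeded, reruns are
byte-identical, and the report carries a provenance block (configuration
hash, seed, package and R versions) whose hash changes with any
configuration field.

## Known limitations

* Healthcare-payer perspective only: no productivity or other indirect
  costs, no costs for survivors of established cardiovascular disease —
  both omissions bias totals downward.
* The conditional structure is transferred between populations assuming
  the clustering (odds-ratio) pattern is portable; only the margins adapt.
* Treated and untreated patients share event rates; treatment affects
  costs and new-onset diabetes only.
* The projection ignores policy interventions and multi-year cost streams
  between base and horizon; the horizon is a single snapshot.
* Uncertainty is explored one factor at a time; no probabilistic
  sensitivity analysis.
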