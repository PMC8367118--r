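---
title: "Comparing acute hospital spending with need-weighted populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing acute hospital spending with need-weighted populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weightedspend)
```

## The problem

Commissioner spending on acute hospital care varies enormously across
general practices, but most of that variation reflects *who is
registered* rather than how the practice works. A practice dominated by
adults aged 20–59 generates far fewer admissions per head than one with
many patients over 80. Any fair comparison — for example, asking whether
a digital-first practice's population costs the hospital system less —
must first standardise the populations for need.

`weightedspend` implements that standardisation the way NHS allocation
formulas do: indirect standardisation by capitation weighting. Each
registered person is multiplied by a relative-need coefficient for their
age-sex band, the practice total is adjusted by local factors, and
spending is then expressed **per weighted patient**. If one population
is expected to incur twice the costs of another, it has twice the
weighted patients; differences that survive weighting are differences
for reasons other than need.

## The model

### Quarterly averaging

Registered lists change within a financial year (1 April – 31 March),
so each practice's population is the arithmetic mean of its quarterly
snapshots, taken band by band (`average_registered_population()`).
Fractional persons are retained throughout; rounding happens only in
report formatting (half-up, 2 decimals for band shares, 1 elsewhere,
whole pounds for per-patient costs, 3 significant figures for
millions). Practices with fewer than four snapshots — typically opened
or closed mid-year — are averaged over the snapshots they have and
flagged `partial_year`; we deliberately do not impute missing quarters,
since any imputation model would add assumptions the data cannot check.
Snapshots dated outside the requested financial year are an error, not
silently dropped.

### Weighting schemes

All three engines are strictly coefficient-table-driven
(`coefficient_table()`), with the same composition:

$$W \;=\; \Big(\sum_b n_b\, w_b\Big) \times \prod_j f_j$$

* **Core services**: per-band need is the component-weight-summed
  multiplier over five service components (general & acute, mental
  health, maternity, community, prescribing); the local factors are
  utilisation, supply, price, unmet need (a premature-mortality proxy,
  taken exactly as the table supplies it — no internal SMR
  computation), deprivation, and unavoidable smallness.
* **Core services adapted**: only the general & acute and maternity
  components are priced, reweighted to sum to one — appropriate when
  the spending extract being divided contains no mental health,
  community or prescribing costs. The practice's *actual* averaged
  profile is always used (never a prior-year estimate, which can be
  badly wrong for a fast-growing practice), and the local factors are
  averaged over the areas the practice's patients actually live in,
  weighted by the residence mix. With a single-area mix and the same
  components this reduces exactly to the core engine, which the tests
  assert.
* **Carr-Hill**: a single consultation-workload age-sex curve, scaled
  by premature mortality, market forces and rurality, with a premium
  per registered nursing-home patient:
  $W = (\sum_b n_b w_b)\, m \cdot mf \cdot r \cdot (1 + \pi \cdot
  \text{nh rate})$. The rurality factor is retained as a table entry
  defaulting to 1, reflecting its phased-out status.

Two composition choices were genuinely open. Published descriptions of
the commissioner formula list local factors without stating how they
combine; we compose them **multiplicatively**, the standard capitation
convention, and state that here rather than asserting it as the
formula's published intent. Likewise, how "unavoidable smallness" should
apply to a very large practice is unstated; the smallness factor is a
table entry defaulting to 1, so it is neutral unless a user's table says
otherwise.

Every table is schema-checked on load: strictly positive finite
multipliers, component weights summing to 1 within 1e-9, and a
normalisation identity — a uniform population (equal persons per band,
neutral local factors) must evaluate to the table's declared
`reference_mean` within 1e-6. Violations are reported with their path
(`core_services/local_factors/A03/deprivation: ...`). Bands present in
a profile but missing from a table are an error; there is no silent
default coefficient.

### Focal-practice adjustments

The adjustment chain is fixed, so runs are reproducible bit-for-bit:

1. **Site-cohort removal** — patients registered at a site outside the
   spending extract's geographic coverage are removed from the
   population, band-wise, *before* weighting. Spending is left
   untouched: the extract holds no costs for them, so a reciprocal
   spend adjustment would be invention. The removal operates on the
   averaged profile, which is the level at which all downstream
   arithmetic happens.
2. **Weighting** (each scheme).
3. **Reference-cohort removal** — a legacy cohort whose spending
   cannot be separated out is removed at the *reference area's* average
   cost per patient and average need index: spend −= size × ref cost,
   registered −= size, weighted −= size × ref index. Removing a cohort
   at the practice's own averages provably leaves the cost per weighted
   patient unchanged (mean-preserving deletion), which the tests check.
4. **Cost per weighted patient** = spend / weighted.
5. **Expected-cost correction** — where an external review reports
   that joiners used hospital services less than a matched population
   *before* joining, the focal cost is conservatively inflated. The
   factor is computed from per-band attendance rates, unit costs and
   prior-use modifiers: evaluate expected cost with and without the
   modifiers; the factor is the relative shortfall, and the focal cost
   per weighted patient is multiplied by (1 + factor). It is applied to
   the *ratio*, never to total spend. By default the factor is
   recomputed from the year's own profile — the faithful
   generalisation when modifiers are available per year — with a
   `pinned` mode (e.g. 0.12) for reproducing a previously published
   factor whose inputs are not available. The correction is invariant
   to uniform scaling of unit costs and of the population, so only the
   *relative* modifier structure matters.
6. **Inflation** (cross-year comparisons only) — GDP-deflator
   restatement, `cost × deflator_target / deflator_source`; chaining
   through an intermediate year equals the direct conversion to 1e-12.

Every step appends to an `AdjustmentLedger`; `ledger_replay()`
recomputes the chain from the initial row and demands exact equality.

### Comparison

Cost per weighted patient is computed per practice and per primary care
network, always summing spend and weighted counts **before** dividing —
the mean of member ratios is a different quantity and the tests include
the counterexample. The reference cost is total reference spend over
total reference weighted, with the focal practice excluded. The focal
value is compared with the distribution of reference network values
(the focal practice's own network excluded) by a one-sided simple *z*:
$(x_f - \bar x)/s$, lower-tail normal *p*. We use the $n-1$ standard
deviation by default ("simple z test" does not pin this down; a switch
selects $n$). Practice-level distributions are heavy-tailed, so the *z*
comparison is gated on a normality screen — Shapiro–Wilk *and*
Kolmogorov–Smirnov (with estimated parameters) both non-rejecting at
α = 0.05 — which network aggregates typically pass and practice-level
values fail; the result object always carries *z* and *p* plus the
screen verdict, so the gating is a reporting rule, not a computational
one. The percentile rank among practices uses
$\lceil 100 \cdot \#\{v \le x_f\}/(n+1)\rceil$ clamped to [1, 100],
ties counted as ≤, so near-minimal values report low single-digit
percentiles. Total savings are the focal weighted population times the
(reference − focal) gap.

## The synthetic region generator

Because practice-level spending extracts of this kind are released ad
hoc rather than deposited, the package's validation runs entirely on
synthetic regions with known ground truth (`region_config()`,
`generate_region()`). The generator emulates:

* ~357 reference practices (lognormal list sizes, mean ~6,900, sdlog
  0.5) in 48 near-equal networks of ~50,000 patients;
* a working-age-heavy urban age-sex mixture, with practice-level
  Dirichlet heterogeneity and a deprivation-linked local-factor
  gradient (one area per network);
* one focal practice in its own network: quarterly list growing ~10%
  per quarter to an average near 60,000, ~86% of patients aged 20–39,
  and a configurable true spend multiplier (default 0.65, i.e. a
  genuinely 35%-cheaper population);
* true spend = weighted population under the *generating*
  core-services table × £715 per weighted patient × multiplier ×
  mean-1 gamma noise.

The gamma shape is `spend_noise` (default 50) **scaled proportionally
to list size**: per-patient cost shocks aggregate, so a practice twice
the size has half the per-patient variance. Without this, the ~60,000
patient focal practice would be far noisier than the ~50,000-patient
network aggregates it is compared against and the z comparison would
have no interpretable calibration; with it, network aggregates are
approximately normal (passing the screen, as intended) and the focal
value is exchangeable with network values under the null. Setting
`spend_noise = Inf` gives the noise-free limit used to verify recovery
bias.

The generated coefficient tables (`generate_coefficients()`) are
explicitly **synthetic, non-official**: plausible U-shaped age-cost
curves, maternity concentrated in women aged 20–39, a flatter
consultation-workload curve for the global-sum scheme, ±5% lognormal
jitter per seed, and band needs scaled so the regional
population-weighted need index lands near 0.95 with the declared
`reference_mean` consistent by construction. By default analysis and
generation share the same tables (the well-specified case); passing
perturbed tables to the pipeline studies misspecification.

What the generator does **not** emulate: disease mix, seasonality,
patient-level events, list churn within quarters, correlated shocks
between neighbouring practices. Passing tests therefore demonstrate
that the pipeline's arithmetic and statistics are correct and that the
method recovers a known ground truth under realistic dispersion — not
that any particular real-world difference is causal, and not that the
synthetic coefficient shapes match official allocation coefficients.

## Validation problem sizes

The test suite exercises: hand-checkable toys for every operation;
nested-loop oracle equivalence for all three engines (random tables of
2–5 bands, 1–3 areas, 1e-9 relative); trapezoidal-integration oracle
for the z-test *p* (1e-6 over z ∈ [−6, 2]); a 20-region recovery study
(60 practices / 8 networks, multiplier 0.65) whose mean reported
percentage difference must sit within ±5 points of −35; and a 200-region
null calibration at a reduced size chosen for exchangeability (48
networks × 3 practices, focal sized like a network), whose rejection
rate at α = 0.05 must stay inside a 99% binomial band. Sampling theory
puts the true size of this z comparison near
$P\{t_{n-1} < -1.645/\sqrt{1+1/n}\} \approx 0.055$ at $n = 48$
reference networks — slightly liberal, as any plug-in z against a
finite sample is; with only 8 reference networks it is nearer 0.08,
which is why headline inference should be read at network counts of
this order or above.

## Known limitations

* Indirect standardisation can only adjust for what the coefficient
  tables encode; self-selection on unmeasured traits passes straight
  through. The expected-cost correction mitigates, not eliminates,
  this.
* With a single focal observation, the z test treats the reference
  network values as the null distribution; it is mildly anti-
  conservative at small network counts (above).
* Percentile ranks at practice level are reported without a p-value by
  design — practice-level distributions fail the normality screen.
* The deflator restates whole-economy prices; health-specific input
  price inflation may differ.
* Official allocation coefficients, where available to a user, should
  replace the synthetic tables; results under synthetic tables
  validate the machinery, not any official allocation.
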