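---
title: "Measuring effective coverage of hypertension screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring effective coverage of hypertension screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htcascade)
```

## The problem and the metric

Crude coverage — the share of a target population that received a service —
says nothing about whether the service did any good. A province can screen
most of its adults for hypertension while leaving the majority of elevated
readings unconfirmed and untreated. *Effective coverage* (EC) closes that
gap: it is the fraction of potential health gain actually delivered, and at
the individual level it is the product

$$EC_{ij} = Q_{ij}\,U_{ij} \mid N_{ij} = 1,$$

where, for person $i$ under programme $j$:

* $N \in \{0,1\}$ is **need** — membership in the screening target group;
* $U \in \{0,1\}$ is **utilization** — the person received at least one
  blood-pressure screening during the observation year;
* $Q \in [0,1]$ is **quality/effectiveness** — whether the care that should
  follow the person's screening result was actually delivered. Under the
  default binary scoring $Q \in \{0,1\}$.

Aggregated EC over any stratum is the mean of $Q \cdot U$ over its need
population, so EC never exceeds crude coverage, and under binary scoring
`ec = coverage * effectiveness` holds exactly per stratum.

`htcascade` implements this metric for hypertension screening from
individual-level administrative records (claims-like data), together with a
synthetic cohort generator, because the national outpatient database the
design emulates is access-restricted: every pipeline stage is exercised
against generated data whose ground truth is known by construction.

## Need, subgroups and the quality criteria

**Need.** The target population is everyone aged 15 or older (completed
years at the window start — the usual administrative convention; a birthday
during the year does not change status), resident in one of the 76 included
provinces, registered in the civil registration system, and *not* already
diagnosed with hypertension before the window start (ICD-10 I10–I15 or a
hypertension registry entry). A diagnosis made during the window keeps the
person in the target: they become the "newly diagnosed" branch of the
cascade. The observation window defaults to calendar year 2013; a fiscal
year can be configured via `study_config()`.

**Subgroups.** Each screened person is classified at their *initial*
screening — the earliest in-window screening record, with same-day ties
broken by the higher systolic then diastolic reading (the more
clinically conservative choice; the source data dictionary gives no tie
rule):

| category        | rule (mmHg)                        |
|-----------------|------------------------------------|
| normotension    | SBP < 120 **and** DBP < 80         |
| pre-HT          | SBP 120–139 **and/or** DBP 80–89   |
| suspected HT    | SBP ≥ 140 **and/or** DBP ≥ 90      |

The "and/or" wording is implemented as precedence suspected > pre-HT >
normotension: crossing either threshold suffices, whatever the other
reading. `classify_bp()` is total over the physiologic grid (SBP 50–300,
DBP 30–200, DBP < SBP) and partitions it into exactly these three classes.

**Quality (Q) per subgroup.**

* *Normotension* — at least one BP measurement in the year. A screened
  normotensive person satisfies this by construction, so $Q = 1$.
* *Pre-HT* — a hypertension & CVD risk-assessment service on or after the
  initial screening, inside the window.
* *Suspected HT* — a repeat BP measurement (later screening record or
  follow-up BP event) within `confirmation_window_days` of the initial
  screening. The default is 60 days, exclusive of day 0 and inclusive of
  day 60: a same-day repeat is not an independent confirmation.

**The diagnosed cascade.** Suspected-HT persons with an in-window HT
diagnosis on/after their screening enter four further indicators: timely
treatment start (within `treatment_window_days = 183` of the *diagnosis*
date — treatment follows diagnosis in the care pathway, and the six-month
window is anchored there rather than at screening); CVD risk assessment (a
lipid panel with total cholesterol, LDL and HDL, on/after diagnosis); BP
control (the latest post-diagnosis follow-up reading under 140/90, or
strictly below the initial reading on both components); and CVD risk
reduction (the latest qualifying panel improves on the first: total
cholesterol and LDL both not greater, at least one strictly lower).

**What goes into the headline Q.** Under the default
`q_scoring = "binary_subgroup"`, Q is the person's own subgroup criterion
and the diagnosed indicators are reported as cascade rows only. This is the
scoring under which the implied national EC
($0.546 \times (0.651 + 0.289 \times 0.826 + 0.060 \times 0.380) \approx 0.498$)
is consistent with the published provincial average of 49.9%; folding the
diagnosed criteria into Q cannot reach that figure, so the subgroup rule is
taken as the intended one. A `"strict"` mode that additionally requires
every diagnosed-cascade criterion of diagnosed persons is available behind
the config flag.

The three diagnosed-service proportions and both outcome proportions are
all reported over the *diagnosed* denominator. The published prose is
ambiguous between "diagnosed" and "the preceding subgroup" for the CVD
assessment / BP control / risk reduction figures; fixing all denominators
to the diagnosed group is the one choice that keeps the cascade a coherent
set of conditional proportions, and it is applied uniformly.

## The synthetic cohort generator

`generate_cohort()` emulates the six-file claims extract (persons,
screenings, services, diagnoses, registry, follow-ups) at any scale. A
`cohort_preset()` fixes the marginal cascade: screening probability,
subgroup shares, and each conditional criterion probability.
`thailand2013_preset()` carries the 2013 national margins (54.6% screened;
65.1/28.9/6.0 subgroup shares; 82.6% pre-HT assessment; 38.0% confirmation;
9.2% diagnosis; 36.5/21.8/50.8/0.7% diagnosed indicators).

Choices that matter, and why:

* **Exact-quota mode** assigns deterministic branch counts — round-half-up
  of parent × p, with largest-remainder correction on the three-way
  subgroup split so children always sum to their parent. Recovery of the
  cascade by the pipeline is then *exact*, which is the module's core
  contract and the package's primary acceptance surface. **Stochastic
  mode** draws each branch independently per person, for
  sampling-variability tests.
* Branches are **independent** (e.g. confirmation and diagnosis among
  suspected persons): only marginal proportions are published, so the
  joint structure is a modelling choice, made once and documented here.
  Risk reduction is the exception — it is nested within risk assessment,
  because the criterion logically requires two lipid panels.
* **BP readings** are drawn uniformly over integer grids inside the
  assigned category's region (suspected capped at 220/120), with both the
  systolic-driven and the diastolic-driven arm of each "and/or" region
  generated, so the pipeline must genuinely re-derive the category from
  raw values. The pipeline uses only thresholds, so realism beyond region
  membership would add nothing to what the tests can show.
* **Event dates**: initial screenings are uniform over the first nine
  months of the window so confirmation and treatment windows can close
  inside it; satisfied criteria get in-window offsets, unsatisfied ones
  are split roughly half "no event at all" and half "a non-qualifying
  event" (too late, or before the anchoring date), so both failure paths
  of every criterion occur in every sizeable cohort.
* Follow-up BP events emitted for the BP-control criterion are dated
  *after* the confirmation window (and control events for
  unconfirmed-but-controlled persons suppress the late-confirmation
  variant), because any later BP measurement counts toward confirmation —
  without this the control events would corrupt the confirmation margin.
* Ages are drawn within bands (38% aged 15–34, then 42% / 20% in the
  35–59 and 60+ bands — the first figure matches the reported population
  structure, the split of the remainder is this package's choice), with
  birth dates placed exactly so that completed age at the reference date
  equals the drawn age. Sexes are balanced.
* The `province_varying_preset()` applies seeded logit-normal province
  effects to the screening probability (sd 1.0) and, attenuated by half,
  to the quality criteria — producing a provincial coverage spread
  comparable to the published 6.9–80.5% range, for qualitative testing of
  provincial summaries only. Effects are applied on the logit scale (not
  as raw multipliers) so no clamping artefacts arise near 0 and 1.

What the generator does **not** emulate: demographically realistic
population structure, BP measurement error, within-year migration,
correlation between cascade branches, or the real 21-file national data
layout. Passing recovery tests therefore shows the pipeline computes the
metric correctly from records with this structure — it says nothing about
coding quality or linkage error in real claims data.

## Aggregation and reporting

`build_cascade()` tallies every node with its documented denominator and
reports empty-denominator proportions as undefined (`NA`), never 0.
`summarize_provinces()` emits per-province coverage, effectiveness and EC
(provinces with no eligible persons are omitted with a warning);
`national_summary()` adds the pooled cascade, the unweighted provincial
mean EC *and* the population-weighted pooled EC (the published report does
not say which averaging was used, so both are emitted), the coverage−EC
gap statistics, and the Pearson correlation between provincial coverage
and EC with a two-sided t-based p-value via `stats::cor.test()`. The
correlation is reported as undefined with fewer than 3 provinces or zero
variance. Report files round percentages to one decimal, matching the
published precision; full precision is kept internally.

## A worked run

```{r replicate, eval = FALSE}
cmp <- replicate_thailand2013(n = 1e6, seed = 1)
cmp
```

generates the exact-quota replication cohort, runs the full pipeline, and
returns the recovered cascade side by side with the preset targets; at
n = 1,000,000 every node agrees to within one quota-rounding unit
(≤ 0.004 percentage points). The test suite runs the same contract at
n = 1,000,000 once, stochastic recovery at n = 100,000 over 20 seeds, and
the invariant suites on small random presets (n = 500–3,000), sizes chosen
so the whole suite stays in the order of a minute while the full-scale
surface is still exercised.

## Numerical and degenerate-input choices

* All date comparisons are day-granular; windows are integer day counts.
* Quota arithmetic uses round-half-up (not banker's rounding) so counts
  are platform-stable, and largest-remainder correction at multi-way
  splits so conservation (`subgroups sum to screened`) holds exactly.
* An eligible person with no screening has $U = 0$, $Q$ undefined, and
  contributes 0 to EC — quality is conditional on utilization.
* Persons with missing birth dates are fatal by default; permissive runs
  exclude them with an explicit `missing_birth_date` reason (a deliberate
  extension of the exclusion-reason set, so the exclusion is visible
  rather than folded into `under_age`).
* Orphan events (person absent from the persons table) are validation
  errors, never silently joined; permissive reading drops and counts them.

## Known limitations

* Q is binary; the framework admits fractional quality weights and
  `compute_individual_ec()` accepts them, but no criterion here produces
  one.
* The pre-HT criterion recognises the risk-assessment service only as a
  coded event; its clinical content (history, anthropometry) is not
  itemised.
* Eligibility uses the province of record at the window start; migration
  within the year is out of scope.
* The generator's independence assumption means joint statistics across
  cascade branches (e.g. confirmation × diagnosis) are not calibrated to
  any empirical target.
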