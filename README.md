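# htcascade

Effective coverage of population hypertension (HT) screening from
individual-level administrative health records.

Crude service coverage — the share of the target population screened at
least once — overstates what a screening programme delivers when elevated
readings are not confirmed, diagnosed and treated. **Effective coverage**
(EC) corrects for this. For person *i*:

```
EC_i = Q_i * U_i | N_i = 1
```

* **N** (need): aged ≥ 15 in completed years, resident in an included
  province, civil-registered, no hypertension diagnosis (ICD-10 I10–I15 or
  registry entry) before the observation year;
* **U** (utilization): ≥ 1 blood-pressure screening during the year;
* **Q** (quality/effectiveness): binary, by the screened person's BP
  subgroup at the *initial* (earliest in-window) screening —
  normotension (SBP < 120 and DBP < 80): the screening itself suffices;
  pre-HT (120–139 and/or 80–89): an HT & CVD risk-assessment service
  on/after screening; suspected HT (≥ 140 and/or ≥ 90): a repeat BP
  measurement within 60 days.

Aggregates (cascade tables, provincial and national summaries) are means
of `Q*U` over the need population, so `EC ≤ coverage` everywhere and
`EC = coverage × effectiveness` per stratum under binary scoring. Newly
diagnosed persons are followed through four further cascade indicators
(timely treatment within 183 days of diagnosis, lipid-panel CVD risk
assessment, BP control, lipid improvement), reported over the diagnosed
denominator.

Because the national claims database this schema emulates is
access-restricted, the package ships a **synthetic cohort generator**
(`generate_cohort()`): six CSV record files (persons, screenings,
services, diagnoses, registry, follow-ups) with a configurable cascade
structure, in an *exact-quota* mode (deterministic branch counts, so the
pipeline must recover the cascade exactly) and a *stochastic* mode. The
`thailand2013_preset()` carries the 2013 Thai national cascade margins.

## Worked example

```r
library(htcascade)

cmp <- replicate_thailand2013(n = 1e6, seed = 1, quiet = TRUE)
print(as.data.frame(cmp), row.names = FALSE)
#>                     node  target_pct recovered_pct diff_pp
#>                 eligible 100.0000000   100.0000000       0
#>                 screened  54.6000000    54.6000000       0
#>             normotension  65.1000000    65.1000000       0
#>                   pre_ht  28.9000000    28.9000000       0
#>             suspected_ht   6.0000000     6.0000000       0
#>     pre_ht_risk_assessed  82.6000989    82.6000989       0
#>  suspected_confirmed_60d  38.0006105    38.0006105       0
#>                diagnosed   9.2002442     9.2002442       0
#>           treated_timely  36.4963504    36.4963504       0
#>        cvd_risk_assessed  21.7982747    21.7982747       0
#>            bp_controlled  50.7962840    50.7962840       0
#>         cvd_risk_reduced   0.6967485     0.6967485       0
```

Reading: of one million persons in need, 54.6% were screened; among the
screened, 28.9% were pre-hypertensive and 6.0% suspected hypertensive;
82.6% of the pre-HT group got risk assessment, 38.0% of suspected cases a
60-day confirmation, 9.2% a diagnosis; of the diagnosed, 36.5% started
treatment within six months, 21.8% got a lipid-panel risk assessment,
50.8% reached BP control and 0.7% reduced their lipid-measured CVD risk.
The `recovered` column is what the full pipeline (eligibility →
classification → criteria → aggregation) re-derives from the raw generated
records; `target` is the generator's ground truth. The implied national EC
is `mean(Q*U) ≈ 49.8%`.

Lower-level surface: `read_bundle()` / `write_bundle()` /
`validate_bundle()`, `determine_eligibility()`, `classify_bp()` /
`assign_subgroups()`, `q_pre_ht()` / `q_suspected()` /
`diagnosed_cascade()`, `assess_cohort()`, `build_cascade()`,
`summarize_provinces()`, `national_summary()`, `run_pipeline()`. A thin
CLI wrapper lives at `inst/cli/htcascade` (subcommands `generate`,
`assess`, `replicate`). The methods vignette
(`vignettes/effective-coverage.Rmd`) documents the model, criteria windows,
generator design and limitations.

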