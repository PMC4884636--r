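# rsinflect

Relative-survival modelling and inflection-point stratification for
lymph-node-positive (LN+) cancer registry cohorts.

Registry cohorts rarely carry reliable cause-of-death information, so the
disease-specific burden is measured by **relative survival** — observed
all-cause survival divided by the expected survival of a demographically
matched general population (Ederer II). `rsinflect` models a cohort's
relative-survival curve with **inverse Gompertzian kinetics**

```
RS(t) = 1 - b1 * exp(-b2 * exp(-b3 * t)),        t in years
```

and computes the curve's **inflection point (IP)** — the time at which
`dRS/dt = -b1*b2*b3*exp(-b2*exp(-b3*t))*exp(-b3*t)` is most negative,
`ln(b2)/b3` in closed form for `b2 > 1`. The IP is interpreted as the time
beyond which reproducible cure is unlikely under the era's treatments.
Cohorts are stratified by the fraction of positive lymph nodes (%LN+ =
positive / examined), the stratification boundaries being chosen from an
IP-versus-%LN+ **cutoff scan**. The package is aimed at biostatisticians
and outcomes researchers working with SEER-style patient-level extracts
and population life tables.

What is inside:

* `life_table()` / `read_life_table()` / `ederer2_expected()` — life-table
  handling and Ederer II matched expected survival on a monthly grid;
* `km_estimate()`, `relative_survival()`, `rs_z_test()`, `logrank_test()` —
  Kaplan–Meier observed survival with Greenwood errors, relative survival
  with the registry correction rules (cap at 100%, then carry the previous
  value back over any increase), and group tests;
* `inverse_gompertz_rs()`, `rs_derivative()`, `inflection_point()`,
  `fit_inverse_gompertz()` — the model, its derivative, numeric IP, and a
  seeded two-stage least-squares fit (differential evolution +
  Levenberg–Marquardt);
* `percent_ln_positive()`, `filter_cohort()`, `cutoff_scan()`,
  `stratify_groups()`, `stratify_by_ln_count()` — %LN+ stratification;
* `stratum_spec()` / `cohort_spec()` / `generate_cohort()` /
  `synthetic_life_table()` — a seeded synthetic registry-cohort generator
  with known relative-survival truth, used to validate the pipeline;
* `run_config()` / `run_pipeline()` — an end-to-end, byte-reproducible
  report bundle, also runnable from a shell via
  `inst/scripts/rsinflect-pipeline.R`.

## Worked example

Published-scale parameters straight into the closed chain — the highest
%LN+ group of a radical-prostatectomy cohort is typically fit by
`(b1, b2, b3) = (0.469, 4.51, 0.222)`:

```r
library(rsinflect)
round(as.numeric(inflection_point(b2 = 4.51, b3 = 0.222)), 2)
#> [1] 6.79                    # years: the IP for that group, "about 7 years"
round(100 * inverse_gompertz_rs(10, 0.469, 4.51, 0.222), 1)
#> [1] 71.3                    # 10-year relative survival, percent
```

A full synthetic round trip — generate a cohort whose truth is known, then
recover it through Ederer II -> KM -> relative survival -> fit:

```r
lt <- synthetic_life_table()
drop <- monthly_dropout_rate(0.2, 300)          # 20% lost over 25 years
spec <- cohort_spec(list(
  stratum_spec("low",  c(1e-6, 0.10), 2000, b1 = 0.513, b2 = 5.22,
               b3 = log(5.22) / 14, censoring_rate = drop),   # true IP 14 y
  stratum_spec("high", c(0.40, 1.00), 2000, b1 = 0.616, b2 = 4.00,
               b3 = log(4.00) / 7,  censoring_rate = drop)),  # true IP  7 y
  seed = 101)
cohort <- generate_cohort(spec, lt)
res <- stratify_groups(cohort, lt, boundaries = c(0.10, 0.40), seed = 101)
res$groups[, c("label", "n", "b1", "b2", "b3", "r_squared", "ip_years")]
#>    label    n    b1   b2    b3 r_squared ip_years
#> 1   <10% 2000 0.415 5.30 0.146     0.999    11.45
#> 2 10-40%    0    NA   NA    NA        NA       NA
#> 3  >=40% 2000 0.639 3.72 0.189     0.999     6.96
subset(res$z_tests, month == 120)
#>   group_a group_b month  rs_a  rs_b    z        p
#> 2    <10%   >=40%   120 0.877 0.641 13.2 8.33e-40
```

The fast-declining group's IP (truth 7 y) is recovered almost exactly; the
slow group's (truth 14 y) is noisier because its inflection lies deep in
the follow-up tail — the methods vignette
(`vignettes/relative-survival-inflection.Rmd`) quantifies this
identifiability limit. The 10-year relative survival drops from 88% to 64%
across the groups, with a strongly significant Z-test.

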