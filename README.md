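# slklink

Record linkage with the statistical linkage key **SLK-581**, and honest
measurement of what that costs.

Many Australian administrative health collections (notably aged-care
minimum data sets) carry no full personal identifiers — only the SLK-581,
a privacy-preserving 14-character key built from letters 2, 3 and 5 of the
surname, letters 2 and 3 of the given name, the date of birth as
`DDMMYYYY`, and a one-character sex code (`1` male, `2` female, `9`
otherwise), with dummy characters (`2` padding, `9`/`0` for missing
components) keeping the length fixed:

```
TAYLOR / LEE / 1946-09-05 / male  ->  AYO EE 05091946 1  =  "AYOEE050919461"
```

Linking such collections to fully identified data (hospital admissions,
death registrations) by exact SLK equality is cheap and deterministic —
but every record with a missing name, an invalid date of birth (January-1
sentinel birthdays, ages over 110), or invalid sex gets a dummy-filled key
that can never match a complete one, so links are silently lost and
health-service utilisation is underestimated. `slklink` implements the
five linkage strategies used to quantify this in a whole-of-population
hospital/death-registration setting, and the evaluation machinery to
compare them:

1. **full_probabilistic** — follow a supplied master linkage key (MLK), a
   person-level grouping maintained by a linkage unit with probabilistic
   methods; the reference standard.
2. **basic_slk** — exact 14-character SLK match, nothing else.
3. **most_recent_slk** — each MLK person is represented by the SLK of
   their most recent hospital separation (preferring complete keys);
   deaths match representative keys and inherit the person's whole record
   set.
4. **most_frequent_slk** — as above with the modal complete SLK,
   frequency ties broken by recency.
5. **any_match_slk** — two stages: exact SLK match, then expansion of
   every hit to its full MLK person group.

For each strategy versus the reference, the package computes per-person
missed-link and false-positive-link rates (a person can have both), their
trends by financial year of admission, the percentage of decedents
hospitalised and the mean/median hospitalisations per decedent over
windows of 1–9 financial years before death, and condition-specific
hospitalisation rates with rate ratios.

Because the underlying population data are confidential, the package
includes a first-class synthetic generator (`synth_config()`,
`simulate_study()`) that emulates the structure of the NSW study setting:
65.1/34.9 public/private sector mix, missing-both-names rates of 10.9%
(public) and 71.1% (private, declining from ~80% to ~62% across the study
window), 0.6% incomplete death registrations (via date of birth only),
~12.8 admissions per decedent over nine years, duplicate death
registrations, skewed name-frequency pools, identity drift, and an
error-injected MLK honouring the 5/1000 missed and 3/1000 false-positive
per-record quality bounds — with hidden ground truth for every record.

## Worked example

```r
library(slklink)

cfg <- synth_config(n_persons = 1000, seed = 7)
sim <- simulate_study(cfg)
ret <- dedupe_deaths(sim$deaths, sim$mlk, seed = cfg$seed)
res <- run_strategies(ret, sim$admissions, sim$mlk)
do.call(rbind, lapply(res, summary))
#>            strategy deaths_retained deaths_linked deaths_unlinked pct_unlinked records_linked ambiguous_deaths
#>  full_probabilistic             490           475              15          3.1           6110                0
#>           basic_slk             490           461              29          5.9           4092                0
#>     most_recent_slk             490           458              32          6.5           5968                3
#>   most_frequent_slk             490           461              29          5.9           6029                3
#>       any_match_slk             490           461              29          5.9           6031                4
```

Each row counts the retained (deduplicated) death records, how many
linked to at least one admission under that strategy, and how many
admission records were drawn in. The basic SLK strategy links almost as
many *persons* as the reference but far fewer *records* — exactly the
failure mode of interest: records with dummy-filled keys stay invisible.

```r
cmp <- compare_links(res$basic_slk, res$full_probabilistic)
round(100 * c(missed = cmp$missed_rate, false_positive = cmp$fp_rate), 2)
#>         missed false_positive
#>          89.70           0.84
```

Over the nine-year window, 89.7% of linked decedents lost at least one
admission record under the basic SLK strategy, while false positives stay
under 1% — missingness breaks links, but exact matching almost never
fabricates them. The downstream bias:

```r
hospitalisation_stats(res$full_probabilistic, ret, sim$admissions, fy_window(9))$mean
#> [1] 12.5
hospitalisation_stats(res$basic_slk, ret, sim$admissions, fy_window(9))$mean
#> [1] 8.4
```

The whole simulate → link → evaluate pipeline, with every table and
figure series written as headed CSV, is also available as
`run_pipeline(cfg, out_dir)` or from the shell via
`Rscript inst/cli/slklink.R all --out-dir out --seed 7`.

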