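---
title: "Deterministic linkage with the SLK-581: strategies, evaluation, and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic linkage with the SLK-581}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slklink)
```

## The problem

Privacy-preserving collections often replace full personal identifiers
with the SLK-581, a 14-character statistical linkage key: letters 2, 3
and 5 of the surname, letters 2 and 3 of the given name, the date of
birth as `DDMMYYYY`, and a one-character sex code. Linking such a
collection to identified data can then only be done deterministically —
two records link when their keys are byte-identical. This vignette
documents how `slklink` builds and classifies the key, the five linkage
strategies it implements, how strategies are scored against a reference
probabilistic person grouping, and what the synthetic data generator
does and does not emulate.

## Key construction

`build_slk()` composes four components, each with an explicit convention
for degenerate input:

* **Names** are normalised first (`normalize_name()`): uppercased,
  diacritics folded to ASCII where a transliteration exists, all
  non-alphabetic characters dropped. An empty or whitespace-only name is
  missing. Positional extraction then takes letters 2/3/5 (surname) and
  2/3 (given name); positions beyond a short name's end yield the pad
  character `2`, and a wholly missing name fills its field with `9`s.
  A short-but-present name is *complete* — padding is not missingness.
* **Date of birth** renders literally as `DDMMYYYY`; missing renders
  `00000000`. Validity is a separate judgement (`validate_dob()`): a
  date is invalid if missing, if it falls on January 1 of *any* year
  (the sentinel convention used in data entry), or if the implied age at
  the record's event date exceeds 110 completed years. The event date —
  hospital separation date or death date — is the reference point for
  the age check because it is the only date guaranteed present on every
  record. Age uses completed years (birthday arithmetic), so exactly 110
  is valid and 111 is not. A January-1 birthday that is also over-age
  classifies as over-age.
* **Sex** codes male `1`, female `2`, and anything else `9` with an
  invalid flag.

A key is *incomplete* when any of six reasons applies: age over 110,
missing/invalid date of birth, missing both names, missing surname only,
missing given name only, missing/invalid sex. The three name reasons are
mutually exclusive; reasons from different component groups may co-occur
(a record can simultaneously lack names and carry an invalid sex).
`quality_report()` tabulates counts and percentages of each reason by
data source and hospital sector, with percentages against the group's
record count; a record with several reasons still counts once toward the
total incomplete.

Incomplete keys are not quarantined: they carry their dummy characters
into matching and can link — but only to an identically dummy-filled
key. This is what confines the damage of missingness to *missed* links
rather than false ones: a dummy-filled key essentially never equals a
complete one.

## The five strategies

All strategies operate on the same retained death records: where a
person (by MLK group) has duplicate death registrations,
`dedupe_deaths()` keeps one uniformly at random, deterministically given
its seed.

1. **Full probabilistic** (`link_full_probabilistic()`): each death
   links to exactly the admission records sharing its MLK person key.
   The MLK — the person-level grouping maintained by a linkage unit — is
   an *input*, not something the package infers; the strategy follows it
   even where it is wrong.
2. **Basic SLK** (`link_basic_slk()`): exact equality of the full
   14-character key, dummy characters included; no blocking, no partial
   match, no use of the MLK.
3. **Most recent SLK** (`person_slk_most_recent()` +
   `link_via_person_slk()`): every MLK person with admissions gets a
   representative key — the key of their most recent separation among
   records with a complete key, falling back to the most recent
   incomplete key for persons with no complete one. Deaths match
   representative keys and inherit the person's entire admission set.
4. **Most frequent SLK** (`person_slk_most_frequent()`): as 3 but with
   the modal complete key; frequency ties go to the tied key borne by
   the most recent separation.
5. **Any match SLK** (`link_any_match()`): stage one is the basic exact
   match; stage two expands every stage-one hit to its whole MLK person
   group. By construction each death's any-match set contains its
   basic-SLK set, and the set of deaths linked at stage one equals the
   set linked by the basic strategy.

Two deterministic tie-breaks are fixed for reproducibility: "most
recent" resolves equal separation dates by largest record id, and a
death whose key matches more than one MLK person links to the *union* of
the matched groups and is flagged `ambiguous` (non-unique keys are rare;
the union maximises sensitivity and the flag preserves auditability).

## Evaluation

`compare_links()` scores a strategy against the reference per retained
death: with reference set $R$ and strategy set $S$, the person has a
missed link iff $R \setminus S \neq \emptyset$ and a false positive iff
$S \setminus R \neq \emptyset$; both can hold at once. Person-level
rates divide by the retained deaths with at least one reference link — a
person the reference never linked can have no missed link.

`error_trend_by_year()` localises errors to the financial year (1 July –
30 June) of the admission record: all deaths fall in the final year, so
earlier financial years correspond to more years before death.
Utilisation statistics (`percent_hospitalised()`,
`hospitalisation_stats()`, `condition_rates()`) count linked admissions
whose separation date falls in a window of financial years ending at the
death year; the denominator is *all* retained deaths including unlinked
ones (this convention reproduces the published worked identities
exactly). The 95% CI on the mean is the normal approximation
$\bar{x} \pm 1.96\, s/\sqrt{n}$ — the simplest defensible default, kept
swappable; quartiles use the inverse-ECDF quantile (type 1) so integer
counts give integer quartiles. Report rounding follows the conventional
table formats: percentages and means to 1 decimal, rate ratios to 2.
Condition windows default to the full nine years, the maximal and most
informative choice.

## The synthetic study

`synth_config()` defaults encode the structure of a nine-financial-year
admission window (July 2000 – June 2009) with all deaths in the final
year:

| parameter | default | why |
|---|---|---|
| `p_public` | 0.651 | public/private admission mix |
| `missing_name_rate_public` | 0.109 | missing-both-names, public, flat over time |
| `missing_name_rate_private` | 0.711 | time-average, private |
| `private_missing_trend` | 0.18 | linear decline ~80% → ~62% across the window |
| `invalid_dob_rate` | 0.005 | blanked or January-1 sentinel, equiprobable |
| `invalid_sex_rate` | 1e-4 | rare |
| `death_incomplete_rate` | 0.006 | deaths: invalid DOB only, names never missing |
| `admissions_mean`, `admissions_dispersion` | 12.8, 1.5 | negative-binomial per decedent over nine years |
| `mlk_missed_rate`, `mlk_fp_rate` | 0.005, 0.003 | per-record MLK error injection |
| `name_variant_rate` | 0.02 | mean identity-drift rate |
| `duplicate_death_rate` | 0.02 | duplicate registrations |

Under the sector mix, the independent component rates imply an overall
incomplete-key fraction of about 32.3% among admissions — the
calibration the acceptance script re-measures. Counts per decedent are
negative-binomial because means alone do not pin down a distribution
and over-dispersion matches the long upper quartiles seen in
utilisation data; the dispersion is configurable. Non-decedents also
accrue admissions (background mean 1.0) so key collisions with living
persons can produce false positives.

Three generator choices deserve emphasis:

* **Canonical identities are fully valid.** No person is born on
  January 1 or aged over 110; all invalidity is injected by
  `apply_missingness()`. Otherwise ~0.27% of natural birthdays would
  land on the sentinel date and contaminate the calibration.
* **Identity drift accumulates backwards in time.** The name-variant
  probability per record is `name_variant_rate * 2 * (1 - f)` where `f`
  is the record's position in the study window, so records far before
  death (whose identity was fixed at registration) are more likely to
  carry a variant spelling. Together with the declining private
  missing-name rate this is the mechanism behind the rising
  missed-link trend with years before death. The mean rate across the
  window equals `name_variant_rate`.
* **MLK errors concentrate in poorly identified records.**
  `perturb_mlk()` splits a record into a fresh singleton with the missed
  rate, else reassigns it to another group with the false-positive rate;
  optional weights tilt where errors land while preserving the overall
  per-record rates. `simulate_study()` weights incomplete-SLK records
  20:1. This reflects how probabilistic linkage actually fails — on
  records with poor identifying information — and it is required for
  internal consistency: if MLK errors were independent of identifier
  quality, deterministic SLK matching would "rediscover" the split-out
  complete records and the false-positive person rate would sit far
  above the sub-1% scale that motivates using the key at all.

Realized MLK error rates are *measured*, not assumed:
`mlk_error_rates()` compares the perturbed and true partitions with a
plurality rule. A record is a false positive when its true person is
not the plurality true person of its perturbed group; a non-FP record
is missed when its true group (two or more records) has a plurality
perturbed key different from its own, the plurality being taken over
non-FP members. Ties prefer the label-matching owner of a group (group
labels persist from the true grouping), then lexicographic order. These
conventions attribute each disrupted record exactly once.

Determinism is end-to-end: one master seed, with an independent derived
substream per generation stage, so changing one stage's parameters never
shifts another stage's draws; the pipeline writes byte-identical files
on re-run, and every output CSV carries a header with the package
version, seed and configuration hash.

## What the generator does not emulate

Condition labels are abstract (a prevalence and a private-sector
relative risk per label) — there is no clinical coding, comorbidity
structure, or repeat-admission correlation beyond person-level counts.
There is no geography, no migration, and no within-person clustering of
missingness (each record draws independently given sector and date),
which makes per-year missed-link levels higher than a clustered process
would give; the package's qualitative checks therefore assert
*directions and scales* (missed links rising with years before death,
false positives under 1%, private-affine conditions underestimated
most), never the published levels, which depend on confidential data.
Passing tests show the machinery is faithful and the calibrated margins
are reproduced; they do not show that real linkage errors behave like
the injected ones.

## Problem sizes

The test suite fuzzes 10^5 identities for key well-formedness, measures
generator calibrations on batches of 20 000–100 000 records (three
binomial standard errors as tolerance), verifies the hash-join matcher
against a brute-force all-pairs oracle on instances of a few hundred
records, and runs the qualitative error-pattern checks on the default
configuration of 2 000 persons (~1 000 decedents, ~14 000 records) —
sizes chosen so the full suite and the acceptance script each complete
in well under a minute on one CPU while keeping Monte-Carlo tolerances
tight.

## Limitations

The reference strategy is only as good as the supplied MLK; the package
deliberately does not implement probabilistic linkage itself (blocking,
scoring, clerical review), nor SLK variants, phonetic encodings, or
stepwise deterministic algorithms that add geography or event dates. The
exact dummy-character conventions follow the national standard's
published form; sites using local variants can still use every strategy,
since matching is string equality on whatever key `build_slk()`
produces.
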