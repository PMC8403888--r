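# insdcmeta

Audit the completeness of spatiotemporal metadata in INSDC-style sequence
archives.

Archived genomic reads are only reusable for genetic-diversity monitoring if
each sequenced individual carries the minimal context of *where* and *when*
it was sampled — a latitude/longitude and a collection year. Those live in
free-text BioSample attributes that submitters omit, fill with placeholder
tokens, or misfile under the wrong key. `insdcmeta` is a tested pipeline for
measuring that gap on exported archive records (and on synthetic corpora with
known ground truth):

- **Record model & I/O** — corpora of samples (BioSample-like), attributes,
  and dataset (BioProject-like) memberships; readers/writers for a
  BioSample-style XML dialect and a flat TSV.
- **Field parsers** — total, categorized parsing of coordinate dialects
  (hemisphere letters, signed decimal, DMS, split fields), collection dates
  (ISO 8601, month names, embedded years, ranges), location tiers
  (`coordinates > place_name > country > none`) against a packaged country
  gazetteer, and recovery of values misfiled under non-canonical keys.
- **Wildness classification** — configurable taxon-list and keyword rules
  separating wild, domesticated, and captive material.
- **Audit summaries** — four-cell status (`both` / `coords_only` /
  `year_only` / `neither`) at sample and dataset level, `all`/`any`/
  `proportion` rollup rules, taxon-group and deposition-year cross-tabs,
  priority selection of datasets with more than four wild members,
  augmentation with externally recovered metadata, and a cost-of-loss
  estimate at $50 per sequenced individual.
- **Validation** — random subsampling of wild-classified datasets, filter
  precision against truth labels, and percentile (or BCa) bootstrap
  confidence intervals with a fixed, reproducible quantile convention.
- **Synthetic corpora** — a seeded generator with per-record ground truth;
  the joint presence law is `P(both) = p_coords·p_year + excess`, and
  wild-filter precision is calibrated through a per-dataset ambiguity rate.

## Worked example

The `analysis/` scripts run the whole audit on a simulated, study-scale
corpus (seed via `AUDIT_SEED`, default 1):

```sh
Rscript analysis/01_simulate_corpus.R     # ~3,000 datasets, ground truth
Rscript analysis/02_parse_and_classify.R  # parse + wildness calls
Rscript analysis/03_audit.R               # summaries, priority, cost
Rscript analysis/04_validate_filter.R     # subsample + bootstrap CIs
```

Output of the run at seed 1:

```
simulated 26799 samples in 3000 datasets (seed 1)
parsed 26799 samples: 17.1% coordinates, 40.8% year, 14.1% both
misfiled recoveries promoted: 211 coordinates, 551 years
wildness calls: captive 1660, domesticated 3836, wild 21303
dataset-level (all members):  coords 1.8%, year 7.5%, both 1.5%
dataset-level (any member):   coords 64.5%, year 86.3%, both 59.4%
priority wild datasets: 1460
lost investment: $1,151,100 (23,022 samples x $50; basis not_both)
wild pool: 2371 datasets; subsampled 200 (seed 11)
filter precision: 70.0%
complete metadata among sampled datasets: 2.0% (bootstrapped 95% CI: 0.5 to 4.0%)
```

Reading this: the generator planted coordinates on 17% of samples, years on
41%, both on 14% — the audit recovers those proportions from the rendered
free text alone, including the ~5% of values deliberately misfiled under
keys like `isolation_source`. The keyword filter calls 2,371 of 3,000
datasets wild; on a 200-dataset validation subsample, 70% of those calls are
correct (matching the calibrated generative precision). Samples outside the
`both` cell represent $1.15M of sequencing investment that cannot be reused
for diversity monitoring. The spread between the `all` and `any` dataset
rollups is expected under per-sample independence and is reported side by
side precisely because the rollup rule is a modelling choice.

Equivalent calls from R:

```r
library(insdcmeta)
scenario <- scenario_paper_mimic(seed = 1)
corpus   <- classify_corpus_wildness(parse_corpus(scenario$corpus))
summary  <- summarize_corpus(corpus)
print(summary)
#> <audit_summary> 26799 samples in 3000 datasets (21303 putatively wild samples)
#>   coordinates: 17.1%   year: 40.8%   both: 14.1%
estimate_lost_investment(summary)
#> lost investment: $1,151,100 (23,022 samples x $50; basis not_both)
```

## Methods

See `vignettes/metadata-audit.Rmd` for the full account: parsing dialects
and rejection categories, the tier and rollup semantics, the bootstrap
conventions, the generator's joint law and precision calibration, and known
limitations.
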