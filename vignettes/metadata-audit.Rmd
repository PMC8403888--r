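---
title: "Auditing spatiotemporal metadata in sequence archives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing spatiotemporal metadata in sequence archives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Raw genomic reads archived in the INSDC (DDBJ, ENA/EBI, NCBI) are, in
principle, time-stamped records of genetic diversity: re-usable baselines for
monitoring wild populations. In practice their reuse hinges on two free-text
sample attributes -- a latitude/longitude and a collection date -- that
submitters frequently omit, fill with placeholder tokens ("missing", "not
collected"), or deposit under the wrong attribute key. `insdcmeta` implements
an auditable pipeline for quantifying this metadata gap: it parses the text
dialects submitters actually use, classifies each sample's provenance (wild,
domesticated, captive), rolls per-sample status up to datasets, validates the
provenance filter by subsampling with bootstrap confidence intervals, merges
externally recovered metadata, and prices what the gap costs.

Everything runs offline. The package ships a synthetic-corpus generator with
per-record ground truth, so every stage -- down to the bootstrap quantile
convention -- is verified against known answers rather than against a moving
archive snapshot.

## Record model

A corpus holds three tables: `samples` (one row per sequenced individual,
BioSample style, with taxon and deposition year), `attributes` (one row per
key--value pair, duplicates retained, values verbatim), and `memberships`
(sample-to-dataset links, BioProject style; a sample may belong to several
datasets and samples without any link are parked in flagged "unlinked"
singletons, included in sample-level but excluded from dataset-level
statistics). Attribute keys are harmonized by lower-casing and collapsing
spaces/hyphens to underscores, because `"Lat Lon"`, `"lat-lon"` and
`"lat_lon"` are the same field in the wild; the original spelling is kept for
reporting. Two serializations are supported -- a BioSample-style XML dialect
and a flat TSV with one row per attribute -- and parse to identical corpora.

## Parsing model

**Coordinates.** Three combined dialects are recognized in priority order:
hemisphere-letter pairs (`36.21 N 121.77 W`, letter before or after the
number), signed decimal pairs (latitude first -- the dominant archive
convention; without letters the order is genuinely unrecoverable, so a
convention must be fixed), and degrees-minutes-seconds. Separate
`latitude`/`longitude` fields form a fourth, split-field dialect. Values are
WGS84 decimal degrees by assumption; no datum handling, since the audit needs
presence and validity, not geodesy. Parsing is total: no input raises, and
every failure carries exactly one category (`placeholder`, `unparseable`,
`out_of_range`). A parsed (0, 0) is valid but flagged: it is a common
placeholder location, and under the default audit policy it does not count as
"has coordinates" (configurable via `audit_policy(count_zero_zero = TRUE)`).

**Dates.** The audit keeps the collection *year* plus a precision label. ISO
8601 forms, English month-name forms, bare years embedded in free text, and
year ranges are recognized; a range `2008/2010` contributes its earliest year
(a conservative single timestamp) and keeps `precision = "range"` so
sensitivity analyses can find such records. The plausibility window is
[1800, current year]: wide enough for museum material, narrow enough to
reject `0` and other typos.

**Location tiers.** Evidence is ordered `coordinates > place_name > country >
none`. Geographic-name fields follow the `"country: region: locality"`
convention; tokens are matched against a packaged, editable country gazetteer
(with synonyms), the last non-country token is taken as the locality, and the
country is recorded even when the tier is finer. No geocoding -- the
gazetteer keeps the pipeline deterministic and offline.

**Misfiled recovery.** Every value under a non-canonical key is also tried as
a coordinate, then as a date. Recoveries never overwrite a canonical parse;
if a canonical slot is empty, the *first* recovery in attribute order is
promoted and flagged with origin `"misfiled"`. Attribute order is the only
defensible prior for choosing among multiple recoveries, and the flag keeps
archive-native and rescued metadata separable in every summary.

## Wildness classification

Archives carry no "wild" flag, so provenance is inferred:

1. a taxon on the domesticated-species list forces `domesticated`
   (species-level exclusion, overriding per-sample evidence);
2. otherwise any domestication keyword (cultivar, breed, variety, farm,
   hatchery, aquaculture, ...) in attribute keys or values -- word-boundary,
   case-insensitive -- gives `domesticated`;
3. otherwise any captivity keyword (captive, zoo, laboratory, aquarium, ...)
   gives `captive`;
4. otherwise the sample is *putatively wild* -- a default branch, not
   positive evidence, which is exactly why the filter's precision must be
   estimated by validation.

`"strain"` alone never triggers: it saturates model-organism records. It only
adds evidence when a core domestication keyword co-occurs. Captive is kept
distinct from domesticated (both are excluded from "wild") because the two
error modes differ and separate labels aid error analysis. All lists ship as
editable configuration (`scope_rules()`); they are a documented
reconstruction of the kind of filter such audits use, not a claim about any
particular study's exact lists.

## Audit summaries

Each sample falls in one of four cells -- `both`, `coords_only`,
`year_only`, `neither` -- which partition every grouping (overall, per taxon
group, per deposition year, per dataset); the suite asserts this conservation
on randomized corpora. Dataset rollups are a genuine modelling choice: does a
dataset "have coordinates" when *all* members do, when *any* does, or when a
proportion does? The phrase "individuals in X% of datasets had..." does not
disambiguate, so the rule is a first-class knob (`all` is the default;
summaries report `all` and `any` side by side, and `any >= proportion >= all`
holds field-wise by construction). Note that under within-dataset independence
of metadata presence the `all` reading collapses toward zero as datasets grow,
while real archives -- where completeness is largely a per-study habit -- sit
far from that floor; the gap between the two readings is itself diagnostic.

Conservation-priority datasets are those with **more than four** putatively
wild members (a dataset with exactly four is excluded -- the threshold is
strict). Externally recovered metadata enters through an augmentation table;
recovered values fill empty slots only, are tagged with origin
`"augmentation"`, and conflicts with archive-derived values are logged, never
applied -- so before/after comparisons cleanly separate what the archive held
from what labor recovered, and coverage can only increase.

The lost-investment estimate is `n_missing x cost`, with cost defaulting to
USD 50 per sequenced individual and `n_missing` defaulting to samples outside
the `both` cell ("missing spatiotemporal metadata"); a stricter `neither`
basis is available.

## Filter validation and the bootstrap

The validation design mirrors how such filters are checked in practice:
subsample `n` datasets uniformly without replacement from those the filter
calls wild, obtain truth labels (here: generator ground truth; in a real
audit: reading the associated publications), and report the precision plus a
bootstrap CI for any per-dataset proportion of interest. Choices fixed here,
and recorded in each result object for auditability:

* **percentile bootstrap** by default (the simplest defensible variant; BCa
  is available as an option);
* **type-7 quantiles** (linear interpolation between order statistics), so an
  independent implementation can agree bit-for-bit;
* the resampling index matrix is drawn in a *single*
  `sample.int(n, n * n_reps, replace = TRUE)` call, making the entire
  procedure reproducible from the seed alone -- the test suite exploits this
  to check the implementation against an independently coded oracle exactly;
* datasets, not individuals, are the resampling unit, because datasets were
  the sampling unit of the validation subsample;
* the CI is reported on two bases -- all sampled datasets, and the
  truly-wild subset -- since a validation interval can reasonably be computed
  over either.

The suite also checks calibration directly: over 500 simulated worlds with a
true proportion of 0.13 at n = 140 (1,000 resamples each), the empirical
coverage of the nominal 95% interval must lie in [0.90, 0.98].

## The synthetic generator

The generator draws what the audit assumes: datasets with zero-truncated
negative-binomial sizes, exponential deposition growth, per-dataset taxa and
library strategies, and per-sample metadata presence under an explicit joint
law: `P(both) = p_coords * p_year + p_both_excess`. One excess parameter
(rather than a copula) suffices because the phenomenon to emulate is simple
strong positive dependence -- submitters who record where usually record
when; marginals of 17%/41% with 14% joint imply roughly twice the
independence expectation (~7%). Present values are rendered in a mixture of
all four coordinate dialects and all supported date formats; masking replaces
present values with placeholder tokens at rate `p_placeholder`; misfiling
moves present values under non-canonical keys at rate `p_misfiled`; absent
fields still emit placeholder tokens half the time, as real records do.

Wildness and ambiguity are assigned per *dataset*: a submission is one study,
its samples share provenance, and validation operates at dataset level. A
nonwild dataset plants keyword signals in its samples unless it is ambiguous
(probability `p_ambiguous_provenance`), in which case the filter will wrongly
call it wild. For a wild fraction w and target precision q, setting
`p_ambiguous = w (1/q - 1) / (1 - w)` gives expected precision q; the
demonstration scenario uses w = 0.55 and q = 0.70, hence ~0.524. Had
ambiguity been drawn per sample instead, any dataset of nontrivial size would
almost surely contain a keyword and precision would collapse to ~1, leaving
nothing to validate.

The generator uses one seeded substream per concern (structure, values,
masking, provenance), with all decision variables drawn unconditionally, so
toggling one rate leaves every other draw unchanged -- this is what makes the
invariant tests sharp (e.g. "raising the misfiled rate changes *only* the
misfiled flags").

**What the generator does not emulate:** within-dataset correlation of
metadata presence (real completeness is largely a per-study habit; here
presence is iid given the joint law), realistic species naming, accession
formats beyond syntactic plausibility, sequence data, and free-text noise
beyond the planted dialects and placeholders. Passing tests therefore
demonstrate correctness of the *pipeline mechanics* -- parsing, promotion,
partitioning, rollup algebra, resampling -- not that any particular archive
snapshot has any particular coverage.

## Problem sizes and numerical choices

The demonstration scenario (`scenario_paper_mimic()`) uses 3,000 datasets
with mean size ~8 (about 25,000-27,000 samples): large enough that the
configured proportions are recovered within 3 binomial standard errors and a
200-dataset validation subsample fits comfortably inside the
programmatically-wild pool, small enough that the whole pipeline audits in
seconds. Archive datasets have strongly right-skewed sizes; the
zero-truncated negative binomial with dispersion 1 captures that shape at a
simulation-friendly scale. Coordinate values are rounded to 6 decimals
(~0.1 m, beyond any field GPS); DMS rendering keeps 0.1" of arc, bounding
round-trip error by ~3e-5 degrees against the stated 1e-4 tolerance.
Degenerate inputs are handled by contract: empty corpora report undefined
(`NA`) proportions rather than zeros, empty datasets are constructor errors,
and empty indicator lists are bootstrap errors.

## Known limitations

* The canonical key lists, placeholder lexicon, keyword lists and gazetteer
  are curated defaults, exposed as configuration; a production audit of a
  real snapshot would extend them.
* Signed coordinate pairs are assumed latitude-first; a lon-lat submission
  without hemisphere letters is silently transposed (detectable only when
  |value| > 90 forces `out_of_range`).
* The embedded-year rule will happily "recover" a year from any stray
  4-digit number in a scanned free-text field; misfiled recoveries are
  flagged precisely so such promotions remain auditable.
* Live archive querying is out of scope by design; the pipeline consumes
  exported records.
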