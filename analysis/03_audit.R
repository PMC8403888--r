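#!/usr/bin/env Rscript
# Step 3: the completeness audit.
#
# Rolls sample status up to datasets (reporting both the strict "all
# members" and the lenient "any member" readings), cross-tabulates status
# by taxon group and deposition year, selects the conservation-priority
# datasets (>4 putatively wild members), and prices the metadata gap at
# $50 per sequenced individual.

suppressPackageStartupMessages(library(insdcmeta))

corpus <- read_flat_table("results/corpus.tsv")
corpus <- classify_corpus_wildness(parse_corpus(corpus))

summary <- summarize_corpus(corpus)
growth <- summarize_growth(corpus)
paths <- write_audit_tables(summary, "results/audit", growth = growth)

priority <- select_priority_datasets(corpus)
readr::write_tsv(priority, "results/priority_datasets.tsv")
lost <- estimate_lost_investment(summary)

print(summary)
cat(sprintf("dataset-level (all members):  coords %.1f%%, year %.1f%%, both %.1f%%\n",
            100 * summary$dataset_props$all$prop_coords,
            100 * summary$dataset_props$all$prop_year,
            100 * summary$dataset_props$all$prop_both))
cat(sprintf("dataset-level (any member):   coords %.1f%%, year %.1f%%, both %.1f%%\n",
            100 * summary$dataset_props$any$prop_coords,
            100 * summary$dataset_props$any$prop_year,
            100 * summary$dataset_props$any$prop_both))
cat(sprintf("priority wild datasets: %d\n", nrow(priority)))
print(lost)
cat("wrote", length(paths), "audit tables under results/audit/\n")
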