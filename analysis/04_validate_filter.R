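#!/usr/bin/env Rscript
# Step 4: validate the wild filter by subsampling, with bootstrap CIs.
#
# Subsamples 200 datasets from those the keyword filter calls wild,
# compares the calls with the generator's ground truth (standing in for
# the literature reading a human validator would do), and bootstraps the
# proportion of sampled datasets whose members all carry complete
# spatiotemporal metadata -- on both the all-sampled and truly-wild bases.

suppressPackageStartupMessages(library(insdcmeta))

seed <- as.integer(Sys.getenv("AUDIT_SEED", "1"))

corpus <- read_flat_table("results/corpus.tsv")
corpus <- classify_corpus_wildness(parse_corpus(corpus))
truth <- readr::read_tsv("results/ground_truth_datasets.tsv",
                         show_col_types = FALSE)

rollup <- rollup_datasets(corpus, rule = "all")
indicator <- tibble::tibble(dataset_accession = rollup$dataset_accession,
                            indicator = rollup$dataset_has_both)

report <- validate_wild_filter(corpus, truth, indicator,
                               n = 200, seed = seed + 10L, n_reps = 10000)

out <- list(
  n_subsampled = report$sample$n,
  wild_pool_size = report$sample$pool_size,
  filter_precision = report$precision,
  metadata_complete_all_sampled = list(
    point = report$bootstrap_all$point_estimate,
    ci_low = report$bootstrap_all$ci_low,
    ci_high = report$bootstrap_all$ci_high),
  metadata_complete_truly_wild = list(
    point = report$bootstrap_truly_wild$point_estimate,
    ci_low = report$bootstrap_truly_wild$ci_low,
    ci_high = report$bootstrap_truly_wild$ci_high),
  method = report$bootstrap_all$method)
jsonlite::write_json(out, "results/validation_report.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("wild pool: %d datasets; subsampled %d (seed %d)\n",
            report$sample$pool_size, report$sample$n, seed + 10L))
cat(sprintf("filter precision: %.1f%%\n", 100 * report$precision))
cat("complete metadata among sampled datasets: ")
print(report$bootstrap_all)
cat("  ... restricted to truly wild datasets: ")
print(report$bootstrap_truly_wild)
cat("wrote results/validation_report.json\n")
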