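#!/usr/bin/env Rscript
# Run the full clone-detection pipeline on the synthetic survey and score the
# clone assignment against the generator's truth labels.

library(clonekit)

dir <- "results/synthetic_survey"
if (!file.exists(file.path(dir, "genotypes.gen")))
  stop("run analysis/01_simulate_survey.R first")

report <- run_pipeline(pipeline_config(
  genotypes = file.path(dir, "genotypes.gen"),
  depth = file.path(dir, "depth.tsv"),
  metadata = file.path(dir, "metadata.csv"),
  out_dir = "results/pipeline"))

print(report)

truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                             simplifyVector = TRUE)
m <- clone_metrics(report$assignment, truth)
message(sprintf("clone precision %.3f, recall %.3f (predicted %d co-clonal pairs, true %d)",
                m$precision, m$recall, m$n_pairs_pred, m$n_pairs_true))
message(sprintf("clones detected: %d (true: %d)",
                length(unique(report$assignment$clone_id)),
                length(unique(truth$clone_id))))
write.csv(report$taxa, "results/pipeline/taxon_summary.csv", row.names = FALSE)
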