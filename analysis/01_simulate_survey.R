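#!/usr/bin/env Rscript
# Generate a synthetic island-wide survey with the shape of the real one:
# ten taxa, eighteen true clones, mixed ploidies (2x-5x), one sexually
# reproducing diploid taxon, duplicate libraries for threshold calibration.
# Everything downstream (02-04) runs off the files written here.

library(clonekit)

out <- "results/synthetic_survey"

taxa <- list(
  taxon_spec("anthelminthica", ploidy = 4, n_clones = 2, ramets_per_clone = 2,
             n_localities = 2, habit = "stoloniferous", native = FALSE,
             males_recorded = NA),
  taxon_spec("corneri", ploidy = 2, n_clones = 1, ramets_per_clone = 1,
             n_localities = 1, native = FALSE, males_recorded = NA),
  taxon_spec("fraseriana", ploidy = 3, n_clones = 1, ramets_per_clone = 1,
             n_localities = 1, native = FALSE, males_recorded = NA),
  taxon_spec("neglecta", ploidy = 5, n_clones = 1, ramets_per_clone = 23,
             n_localities = 11),
  taxon_spec("nitens", ploidy = 2, n_clones = 8, ramets_per_clone = 1,
             n_localities = 1, habit = "stoloniferous",
             reproduce = "sexual_diploid", males_recorded = TRUE),
  taxon_spec("podzolicola", ploidy = 3, n_clones = 1, ramets_per_clone = 8,
             n_localities = 5),
  taxon_spec("rubinea", ploidy = 3, n_clones = 1, ramets_per_clone = 75,
             n_localities = 47),
  taxon_spec("triangulata", ploidy = 3, n_clones = 1, ramets_per_clone = 9,
             n_localities = 8),
  taxon_spec("sp_macritchie", ploidy = 3, n_clones = 1, ramets_per_clone = 2,
             n_localities = 2),
  taxon_spec("sp_mandai", ploidy = 3, n_clones = 1, ramets_per_clone = 1,
             n_localities = 1)
)

cfg <- sim_config(taxa, seed = 20200924)
ds <- simulate_dataset(cfg)
write_simulated_dataset(ds, out)

n_clones_true <- length(unique(ds$truth$clones$clone_id))
message(sprintf("wrote %s: %d libraries (%d duplicates), %d loci, %d true clones",
                out, nrow(ds$metadata),
                sum(!is.na(ds$metadata$duplicate_group)) -
                  length(unique(stats::na.omit(ds$metadata$duplicate_group))),
                n_loci(ds$genotypes), n_clones_true))
message(sprintf("heterozygous loci per library: %d-%d",
                min(rowSums(is_het(ds$genotypes))),
                max(rowSums(is_het(ds$genotypes)))))
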