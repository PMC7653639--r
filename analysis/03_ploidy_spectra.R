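#!/usr/bin/env Rscript
# Allele-balance ploidy evidence: per-taxon minor-allele fraction spectra,
# peak tables, and the library-merging stability check on the largest clone.

library(clonekit)

dir <- "results/synthetic_survey"
depth <- read_depth_table(file.path(dir, "depth.tsv"))
meta <- read_sample_metadata(file.path(dir, "metadata.csv"))
dir.create("results/ploidy", recursive = TRUE, showWarnings = FALSE)

rows <- lapply(split(meta$sample_id, meta$taxon_label), function(ids) {
  s <- build_spectrum(depth, samples = ids)
  pk <- detect_peaks(s)
  call <- infer_ploidy(pk)
  data.frame(taxon = meta$taxon_label[match(ids[1], meta$sample_id)],
             n_loci = s$n_loci,
             peaks = paste(sprintf("%.1f%%", 100 * pk$position),
                           collapse = " + "),
             ploidy = call$ploidy, consistent = call$consistent)
})
calls <- do.call(rbind, rows)
rownames(calls) <- NULL
print(calls, row.names = FALSE)
write.csv(calls, "results/ploidy/taxon_ploidy.csv", row.names = FALSE)

# merging libraries of one clone must not move the peaks
rub <- meta$sample_id[meta$taxon_label == "rubinea"][1:3]
st <- merge_stability(depth, as.list(rub))
message(sprintf("merge stability over %d rubinea libraries: %s (union peaks at %s, %d loci)",
                length(rub), if (st$stable) "stable" else "UNSTABLE",
                paste(sprintf("%.1f%%", 100 * st$union_peaks$position),
                      collapse = " + "),
                st$union_n_loci))
write.csv(st$comparison, "results/ploidy/merge_stability.csv",
          row.names = FALSE)
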