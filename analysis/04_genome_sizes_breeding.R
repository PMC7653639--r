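#!/usr/bin/env Rscript
# Genome-size arithmetic and breeding-system classification on the published
# survey table, plus replicate QC on the bundled synthetic flow-cytometry
# measurements.

library(clonekit)

dir.create("results/genome_size", recursive = TRUE, showWarnings = FALSE)
tab <- hanguana_survey()

# 2C -> 1Cx conversion reproduces the printed monoploid sizes
tab$cx1_recomputed <- monoploid_size(tab$c2_pg, tab$ploidy)
stopifnot(identical(tab$cx1_recomputed, tab$cx1_pg))
message(sprintf("1Cx check: all %d printed values reproduced from 2C / ploidy",
                nrow(tab)))

fold <- max(tab$c2_pg) / min(tab$c2_pg)
message(sprintf("2C range: %.3f-%.3f pg, a %.2f-fold difference",
                min(tab$c2_pg), max(tab$c2_pg), fold))

published_neglecta <- 3.29  # earlier literature value for the pentaploid
ours <- tab$c2_pg[tab$taxon == "Hanguana neglecta"]
message(sprintf("neglecta 2C %.3f pg is %.0f%% above the published %.2f pg",
                ours, 100 * (ours - published_neglecta) / published_neglecta,
                published_neglecta))

# theoretical 2C windows from the two measured diploid anchors
anchors <- tab$cx1_pg[tab$ploidy == 2]
ranges <- do.call(rbind, lapply(2:5, function(p) {
  r <- theoretical_2c_range(p, anchors)
  inside <- tab$c2_pg[tab$ploidy == p] >= r["low"] &
    tab$c2_pg[tab$ploidy == p] <= r["high"]
  data.frame(ploidy = p, low = r[["low"]], high = r[["high"]],
             n_taxa = sum(tab$ploidy == p), n_inside = sum(inside))
}))
print(ranges, row.names = FALSE)
write.csv(ranges, "results/genome_size/theoretical_ranges.csv",
          row.names = FALSE)
if (ranges$n_inside[ranges$ploidy == 4] == 0)
  message("tetraploid 2C below its window: genome downsizing flagged")

# replicate QC on the synthetic flow-cytometry series
fcm <- read_fcm_replicates(system.file("extdata", "fcm_replicates_synthetic.csv",
                                       package = "clonekit"))
qc <- do.call(rbind, lapply(split(fcm$c2_pg, fcm$sample_id), function(v) {
  r <- qc_fcm_replicates(v)
  data.frame(n = length(v), mean_2c = round(r$mean_2c, 3),
             max_min = round(r$max_min_ratio, 4),
             sem_frac = round(r$sem_frac, 4), decision = r$decision)
}))
qc$sample_id <- rownames(qc)
rownames(qc) <- NULL
print(qc[, c(6, 1:5)], row.names = FALSE)
write.csv(qc[, c(6, 1:5)], "results/genome_size/fcm_qc.csv", row.names = FALSE)

# classification from the printed evidence columns
cls <- classify_sexual_system(tab)
stopifnot(identical(cls$call, tab$system),
          identical(cls$inferred, tab$system_inferred))
message(sprintf("sexual-system calls reproduced for all %d taxa (%d apomictic, %d sexual)",
                nrow(cls), sum(cls$call == "apomictic"),
                sum(cls$call == "sexual")))
write.csv(cls, "results/genome_size/system_calls.csv", row.names = FALSE)
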