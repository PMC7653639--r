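test_that("founder dosages follow the binomial dosage model and are reproducible", {
  set.seed(1)
  expect_true(all(simulate_founder(3, 100, q = rep(0, 100)) == 0))
  d <- simulate_founder(3, 20000, q = rep(0.5, 20000))
  expect_lt(abs(mean(d) - 1.5), 0.05)
  set.seed(99); d1 <- simulate_founder(4, 500)
  set.seed(99); d2 <- simulate_founder(4, 500)
  expect_identical(d1, d2)
})

test_that("library simulation targets the dosage fraction and is error-free at zero rates", {
  cfg <- sim_config(list(taxon_spec("t")), seed = 1, seq_error_rate = 0,
                    genotype_error_rate = 0, depth_mean = 5000,
                    depth_dispersion = 0)
  set.seed(2)
  lib <- simulate_library(rep(1L, 400), 3L, cfg)
  mf <- minor_fraction_table(lib$depth)
  expect_lt(abs(mean(mf$minor_frac, na.rm = TRUE) - 1 / 3), 0.01)
  # dosage between 0 and p emits a heterozygous diploidized call
  expect_true(all(lib$a1 == 1L & lib$a2 == 2L))
  # depth far below the emission floor yields missing calls downstream
  cfg_low <- sim_config(list(taxon_spec("t")), seed = 1, depth_mean = 10,
                        depth_dispersion = 0)
  set.seed(3)
  lib_low <- simulate_library(rep(1L, 200), 2L, cfg_low)
  expect_gt(mean(is.na(lib_low$a1)), 0.95)
})

test_that("sexual families are Mendelian: sibs share ~50% of het genotypes", {
  # both parents het at every locus: P(offspring het) = 1/2, so a sib matches
  # a given het locus with probability 1/2 (brute-force over the 16 gamete
  # combinations of two independent offspring)
  set.seed(41)
  n <- 4000
  off <- simulate_sexual_family(rep(1L, n), rep(1L, n), 2)
  het1 <- off[[1]] == 1L
  match_rate <- mean(off[[2]][het1] == 1L)
  expect_lt(abs(match_rate - 0.5), 0.05)
  # identical homozygous founders: all offspring identical
  off2 <- simulate_sexual_family(rep(2L, 50), rep(2L, 50), 3)
  expect_true(all(vapply(off2, identical, TRUE, off2[[1]])))
  expect_true(all(off2[[1]] == 2L))
  expect_error(simulate_sexual_family(rep(3L, 5), rep(1L, 5), 2), "parent")
})

test_that("simulated datasets are reproducible, truth-consistent, and parse cleanly", {
  cfg <- two_taxon_config(7)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$genotypes$a1, ds2$genotypes$a1)
  expect_identical(ds1$depth, ds2$depth)

  # truth consistent with metadata
  expect_equal(ds1$truth$clones$sample_id, ds1$metadata$sample_id)
  expect_equal(ds1$truth$clones$taxon_label, ds1$metadata$taxon_label)
  # duplicate libraries share the biological clone
  dup <- duplicate_pairs(ds1$metadata)
  tr <- ds1$truth$clones
  expect_gt(nrow(dup), 0)
  expect_equal(tr$clone_id[match(dup$sample_a, tr$sample_id)],
               tr$clone_id[match(dup$sample_b, tr$sample_id)])

  # study conditions: >= 500 heterozygous loci per sample
  expect_true(all(rowSums(is_het(ds1$genotypes)) >= 500))

  # round-trips through the io layer without warnings
  dir <- withr::local_tempdir()
  expect_no_warning(write_simulated_dataset(ds1, dir))
  m2 <- read_genepop(file.path(dir, "genotypes.gen"))
  expect_equal(m2$a1, ds1$genotypes$a1)
  d2 <- read_depth_table(file.path(dir, "depth.tsv"))
  expect_equal(nrow(d2), nrow(ds1$depth))
  meta2 <- read_sample_metadata(file.path(dir, "metadata.csv"))
  expect_equal(meta2$sample_id, ds1$metadata$sample_id)
})

test_that("duplicate libraries are genotype-identical at zero error rates", {
  cfg <- sim_config(list(
    taxon_spec("t", ploidy = 3, n_clones = 2, ramets_per_clone = 3,
               n_localities = 3)),
    n_loci = 800, seed = 11, seq_error_rate = 0, genotype_error_rate = 0,
    depth_mean = 400, depth_dispersion = 0, duplicate_library_rate = 0.4)
  ds <- simulate_dataset(cfg)
  dup <- duplicate_pairs(ds$metadata)
  expect_gt(nrow(dup), 0)
  for (k in seq_len(nrow(dup))) {
    r <- het_similarity(dup$sample_a[k], dup$sample_b[k], ds$genotypes)
    expect_equal(r$sim_percent, 100)
  }
})

test_that("a simulated polyploid's spectrum peaks at the theoretical fractions", {
  cfg <- sim_config(list(taxon_spec("t5", ploidy = 5, ramets_per_clone = 1)),
                    n_loci = 5000, seed = 19, depth_mean = 120,
                    duplicate_library_rate = 0)
  ds <- simulate_dataset(cfg)
  sid <- ds$metadata$sample_id[1]
  pk <- detect_peaks(build_spectrum(ds$depth, samples = sid))
  call <- infer_ploidy(pk)
  expect_equal(call$ploidy, 5L)
  expect_true(call$consistent)
})
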