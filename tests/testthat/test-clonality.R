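test_that("het similarity is 100% against self and averages both directions", {
  m <- gt(c("1/2", "1/2", "1/2", "1/2", "3/3"),
          c("1/2", "1/2", "1/2", "1/3", "3/3"))
  self <- het_similarity("S1", "S1", m)
  expect_equal(self$sim_percent, 100)

  # A het at 4 loci, B matches 3 of them; B het at the same 4, matching 3
  r <- het_similarity("S1", "S2", m)
  expect_equal(r$pct_ab, 75)
  expect_equal(r$pct_ba, 75)
  expect_equal(r$sim_percent, 75)
  expect_equal(r$n_het_compared, 8L)
  expect_false(r$reliable)  # below the 20-locus overlap floor
})

test_that("asymmetric het sets give directional percentages that average", {
  # A het at L1,L2; B het only at L1 plus a hom mismatch at L2
  m <- gt(c("1/2", "1/2", "1/1"),
          c("1/2", "1/1", "1/1"))
  r <- het_similarity("S1", "S2", m)
  expect_equal(r$pct_ab, 50)    # A->B: L1 match, L2 mismatch
  expect_equal(r$pct_ba, 100)   # B->A: only L1 is het in B
  expect_equal(r$sim_percent, 75)
})

test_that("a sample without heterozygous loci is incomparable one way, undefined both ways", {
  m <- gt(c("1/1", "2/2"),
          c("1/1", "2/2"),
          c("1/2", "2/2"))
  r12 <- het_similarity("S1", "S2", m)
  expect_true(is.na(r12$sim_percent))
  r13 <- het_similarity("S1", "S3", m)   # only S3->S1 direction defined
  expect_true(is.na(r13$pct_ab))
  expect_equal(r13$sim_percent, r13$pct_ba)
})

test_that("allele-sharing match mode is at least as permissive as genotype identity", {
  set.seed(9)
  m <- random_gt(6, 50, n_alleles = 3)
  for (pair in list(c(1, 2), c(3, 4), c(5, 6))) {
    a <- sample_ids(m)[pair[1]]
    b <- sample_ids(m)[pair[2]]
    g <- het_similarity(a, b, m, match = "genotype")$sim_percent
    s <- het_similarity(a, b, m, match = "allele")$sim_percent
    if (!is.na(g) && !is.na(s)) expect_gte(s, g)
  }
})

test_that("duplicate libraries with 1% dropout at ~500 het loci sit near 99%", {
  set.seed(21)
  n <- 1500
  a1 <- matrix(1L, 2, n)
  a2 <- matrix(2L, 2, n)                       # 1500 shared het loci
  drop <- runif(n) < 0.01                      # library 2 allelic dropout
  a2[2, drop] <- 1L
  m <- genotype_matrix(a1, a2, sample_ids = c("lib1", "lib2"),
                       locus_ids = sprintf("L%d", 1:n))
  r <- het_similarity("lib1", "lib2", m)
  expect_gt(r$sim_percent, 97)
  expect_lt(r$sim_percent, 100)
})

test_that("pairwise table covers all pairs and is order-invariant", {
  set.seed(4)
  m <- random_gt(6, 40)
  tab <- pairwise_het_similarities(m)
  expect_equal(nrow(tab), choose(6, 2))
  perm <- sample(6)
  tab2 <- pairwise_het_similarities(m[perm, ])
  key <- function(t) {
    o <- order(t$sample_a, t$sample_b)
    t[o, c("sample_a", "sample_b", "sim_percent", "n_het_compared")]
  }
  expect_equal(key(tab2), key(tab), ignore_attr = TRUE)
  # three identical samples: all pairs at 100
  m3 <- gt(c("1/2", "3/4"), c("1/2", "3/4"), c("1/2", "3/4"))
  expect_equal(pairwise_het_similarities(m3)$sim_percent, rep(100, 3))
})

test_that("threshold calibration finds the widest gap under the duplicates", {
  tab <- data.frame(
    sample_a = sprintf("a%d", 1:6), sample_b = sprintf("b%d", 1:6),
    sim_percent = c(10, 12, 15, 96, 98, 100),
    n_het_compared = 100L, pct_ab = NA, pct_ba = NA, reliable = TRUE)
  dups <- data.frame(sample_a = c("a5", "a6"), sample_b = c("b5", "b6"))
  cal <- calibrate_threshold(tab, dups)
  expect_equal(unname(cal$gap), c(15, 96))
  expect_equal(cal$threshold_percent, 55.5)
  expect_true(cal$calibrated)
  expect_equal(cal$duplicate_range, c(98, 100))
})

test_that("calibration falls back to 85 without a wide-enough gap, and fails on low duplicates", {
  tab <- data.frame(
    sample_a = sprintf("a%d", 1:5), sample_b = sprintf("b%d", 1:5),
    sim_percent = c(80, 82, 84, 86, 88),
    n_het_compared = 100L, pct_ab = NA, pct_ba = NA, reliable = TRUE)
  expect_warning(cal <- calibrate_threshold(tab, NULL), "falling back")
  expect_equal(cal$threshold_percent, 85)
  expect_false(cal$calibrated)

  # contaminated duplicate at 40% under the default 85% threshold
  tab2 <- data.frame(
    sample_a = c(sprintf("a%d", 1:5), "d1"),
    sample_b = c(sprintf("b%d", 1:5), "d2"),
    sim_percent = c(80, 82, 84, 86, 88, 40),
    n_het_compared = 100L, pct_ab = NA, pct_ba = NA, reliable = TRUE)
  dups <- data.frame(sample_a = "d1", sample_b = "d2")
  expect_error(suppressWarnings(calibrate_threshold(tab2, dups)),
               "contamination")
})

test_that("clone components match a union-find oracle; raising the threshold never merges", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 10
    ids <- sprintf("S%02d", 1:n)
    cmb <- combn(n, 2)
    tab <- data.frame(sample_a = ids[cmb[1, ]], sample_b = ids[cmb[2, ]],
                      sim_percent = runif(ncol(cmb), 0, 100),
                      n_het_compared = 50L, pct_ab = NA, pct_ba = NA,
                      reliable = TRUE)
    attr(tab, "sample_ids") <- ids
    prev <- 0L
    for (thr in c(30, 60, 85)) {
      ca <- assign_clones(tab, thr)
      hit <- tab$sim_percent >= thr
      want <- oracle_components(ids, tab$sample_a[hit], tab$sample_b[hit])
      got <- split(ca$assignment$sample_id, ca$assignment$clone_id)
      expect_equal(canon_partition(got), canon_partition(want))
      expect_gte(length(ca$clones), prev)
      prev <- length(ca$clones)
    }
  }
})

test_that("uniform high similarity yields one clone; uniform low, all singletons", {
  ids <- sprintf("S%02d", 1:12)
  cmb <- combn(12, 2)
  high <- data.frame(sample_a = ids[cmb[1, ]], sample_b = ids[cmb[2, ]],
                     sim_percent = 99.5, n_het_compared = 400L,
                     pct_ab = NA, pct_ba = NA, reliable = TRUE)
  attr(high, "sample_ids") <- ids
  ca <- assign_clones(high, 85)
  expect_equal(length(ca$clones), 1L)
  expect_equal(nrow(ca$transitivity_violations), 0L)
  low <- high
  low$sim_percent <- 40
  attr(low, "sample_ids") <- ids
  expect_equal(length(assign_clones(low, 85)$clones), 12L)
})

test_that("below-threshold pairs inside a clone are reported as transitivity violations", {
  ids <- c("A", "B", "C")
  tab <- data.frame(sample_a = c("A", "A", "B"), sample_b = c("B", "C", "C"),
                    sim_percent = c(90, 90, 60), n_het_compared = 100L,
                    pct_ab = NA, pct_ba = NA, reliable = TRUE)
  attr(tab, "sample_ids") <- ids
  ca <- assign_clones(tab, 85)
  expect_equal(length(ca$clones), 1L)
  expect_equal(nrow(ca$transitivity_violations), 1L)
  expect_equal(ca$transitivity_violations$sample_a, "B")
})

test_that("sexual sibs sit far below duplicates, with the gap in between", {
  set.seed(31)
  cfg <- two_taxon_config(31, duplicate_library_rate = 0.3)
  ds <- simulate_dataset(cfg)
  sib_ids <- ds$metadata$sample_id[ds$metadata$taxon_label == "taxB"]
  msib <- ds$genotypes[sib_ids, ]
  tab <- pairwise_het_similarities(msib)
  dups <- duplicate_pairs(ds$metadata)
  dups <- dups[dups$sample_a %in% sib_ids, , drop = FALSE]
  truth <- ds$truth$clones
  same_clone <- truth$clone_id[match(tab$sample_a, truth$sample_id)] ==
    truth$clone_id[match(tab$sample_b, truth$sample_id)]
  expect_gt(nrow(dups), 0)   # the seeded duplicate draw hits taxB
  cal <- calibrate_threshold(tab, dups)
  sib_mean <- mean(tab$sim_percent[!same_clone], na.rm = TRUE)
  expect_lt(sib_mean, cal$gap[["low"]])
  expect_lt(cal$gap[["high"]], min(tab$sim_percent[same_clone], na.rm = TRUE) + 1e-9)
  expect_true(abs(sib_mean - 50) < 15)  # Mendelian expectation ~50%
})
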