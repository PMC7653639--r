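test_that("missingness filter keeps loci at or below the threshold", {
  set.seed(2)
  m <- random_gt(10, 30, p_missing = 0)
  # plant controlled missingness: locus 1 -> 3/10 missing, locus 2 -> 4/10
  m$a1[1:3, 1] <- m$a2[1:3, 1] <- NA_integer_
  m$a1[1:4, 2] <- m$a2[1:4, 2] <- NA_integer_
  kept <- locus_ids(filter_loci_by_missingness(m, 0.30))
  expect_true("L001" %in% kept)
  expect_false("L002" %in% kept)
  complete <- filter_loci_by_missingness(m, 0)
  expect_true(all(colSums(is_missing(complete)) == 0))
})

test_that("p-distance counts allele-dosage differences over shared loci", {
  # identical matrices: all off-diagonal zero
  m <- gt(c("1/1", "1/2", "2/2"), c("1/1", "1/2", "2/2"))
  expect_equal(p_distance_matrix(m)$d[1, 2], 0)

  # 10 shared loci, one hom/het difference -> 1/20
  row_a <- c("1/1", rep("3/3", 9))
  row_b <- c("1/2", rep("3/3", 9))
  dm <- p_distance_matrix(gt(row_a, row_b))
  expect_equal(dm$d[1, 2], 0.05)
  expect_equal(dm$n_compared[1, 2], 10L)

  # no shared allele at a locus counts 2 differences
  dm2 <- p_distance_matrix(gt(c("1/1", "3/3"), c("2/2", "3/3")))
  expect_equal(dm2$d[1, 2], 2 / 4)

  # pair sharing no loci: undefined, not zero
  dm3 <- p_distance_matrix(gt(c("1/1", NA), c(NA, "2/2")))
  expect_true(is.na(dm3$d[1, 2]))
  expect_equal(dm3$n_compared[1, 2], 0L)
})

test_that("p-distance agrees with the exhaustive per-locus oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- random_gt(5, 20)
    dm <- p_distance_matrix(m)
    want <- oracle_p_distance(m)
    expect_equal(unname(dm$d), want)
    expect_equal(dm$d, t(dm$d))
    expect_equal(unname(diag(dm$d)), rep(0, 5))
  }
})

test_that("partition groups are single-linkage components of the threshold graph", {
  ids <- c("a", "b", "c", "d", "e")
  d <- matrix(0.05, 5, 5, dimnames = list(ids, ids))
  diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 0.001
  d["c", "d"] <- d["d", "c"] <- 0.001
  dm <- structure(list(d = d, n_compared = matrix(10L, 5, 5),
                       sample_ids = ids), class = "p_distance")
  groups <- partition_samples(dm, 0.9978)
  expect_equal(canon_partition(groups),
               canon_partition(list(c("a", "b"), c("c", "d"), "e")))
  # chaining: a-b and b-c close, a-c not -> still one group of 3
  d2 <- matrix(0.05, 3, 3, dimnames = list(ids[1:3], ids[1:3]))
  diag(d2) <- 0
  d2["a", "b"] <- d2["b", "a"] <- 0.001
  d2["b", "c"] <- d2["c", "b"] <- 0.001
  d2["a", "c"] <- d2["c", "a"] <- 0.004
  dm2 <- structure(list(d = d2, n_compared = matrix(10L, 3, 3),
                        sample_ids = ids[1:3]), class = "p_distance")
  expect_equal(partition_samples(dm2, 0.9978), list(c("a", "b", "c")))
  # complete linkage splits the chain
  expect_equal(length(partition_samples(dm2, 0.9978, linkage = "complete")), 2L)
  # cutoff 0: everything within distance 1
  expect_equal(partition_samples(dm, 0), list(ids))
})

test_that("partition matches a union-find oracle and is monotone in the cutoff", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 8
    ids <- sprintf("S%d", 1:n)
    d <- matrix(runif(n * n, 0, 0.01), n, n, dimnames = list(ids, ids))
    d <- (d + t(d)) / 2
    diag(d) <- 0
    dm <- structure(list(d = d, n_compared = matrix(5L, n, n),
                         sample_ids = ids), class = "p_distance")
    for (cutoff in c(0.995, 0.9978, 0.999)) {
      thr <- 1 - cutoff
      pairs <- which(upper.tri(d) & d <= thr, arr.ind = TRUE)
      want <- oracle_components(ids, ids[pairs[, 1]], ids[pairs[, 2]])
      got <- partition_samples(dm, cutoff)
      expect_equal(canon_partition(got), canon_partition(want))
      expect_equal(sort(unlist(got)), sort(ids))  # partition covers, disjoint
    }
    n_groups <- vapply(c(0.99, 0.995, 0.999, 0.9999),
                       function(s) length(partition_samples(dm, s)), 0L)
    expect_true(all(diff(n_groups) >= 0))
  }
})

test_that("parsimony-informative counting requires two alleles in two samples", {
  # all identical: uninformative
  expect_equal(count_parsimony_informative(gt("1/1", "1/1", "1/1")), 0L)
  # allele 1 in 3 samples, allele 2 in 2 samples: informative
  expect_equal(count_parsimony_informative(
    gt(c("1/1"), c("1/2"), c("1/2"))), 1L)
  # singleton variant: not informative
  expect_equal(count_parsimony_informative(gt("1/1", "1/1", "1/2")), 0L)
  # het carriers count once per sample, any dosage
  expect_equal(count_parsimony_informative(gt("1/2", "1/2", "1/1")), 1L)
  # brute-force check on random matrices
  set.seed(3)
  m <- random_gt(6, 40, n_alleles = 3)
  brute <- sum(vapply(seq_len(n_loci(m)), function(l) {
    carriers <- list()
    for (s in seq_len(6)) {
      if (is.na(m$a1[s, l])) next
      for (a in unique(c(m$a1[s, l], m$a2[s, l])))
        carriers[[as.character(a)]] <- c(carriers[[as.character(a)]], s)
    }
    sum(lengths(lapply(carriers, unique)) >= 2) >= 2
  }, logical(1)))
  expect_equal(count_parsimony_informative(m), brute)
})
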