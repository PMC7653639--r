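test_that("spectrum pools minor fractions and respects the coverage filter", {
  # exact 2:1 depth everywhere: one occupied bin at 0.33
  counts <- cbind(A = rep(80L, 50), C = rep(40L, 50))
  s <- build_spectrum(depth_from_counts(counts))
  expect_equal(s$n_loci, 50L)
  occupied <- which(s$counts > 0)
  expect_length(occupied, 1L)
  expect_lt(abs(s$mids[occupied] - 1 / 3), 0.01)

  # monomorphic loci only: empty-spectrum error
  mono <- depth_from_counts(cbind(A = rep(60L, 10)))
  expect_error(build_spectrum(mono), "empty spectrum")

  # pushing every locus below the coverage floor empties the spectrum
  low <- depth_from_counts(cbind(A = rep(8L, 50), C = rep(4L, 50)))
  expect_error(build_spectrum(low), "empty spectrum")

  # per-sample pooling: unknown sample is an error
  expect_error(build_spectrum(depth_from_counts(counts), samples = "nope"),
               "not in depth table")
})

test_that("peak detection finds unimodal and bimodal structure and rejects flat noise", {
  mk <- function(fracs) {
    n <- length(fracs)
    tot <- rep(1000L, n)
    minor <- as.integer(round(tot * fracs))
    depth_from_counts(cbind(A = tot - minor, C = minor))
  }
  # unimodal pile at 0.50
  s <- build_spectrum(mk(rep(0.5, 200)))
  pk <- detect_peaks(s)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$position - 0.5), 0.011)

  # bimodal 0.20 / 0.40 with 60:40 mass
  s2 <- build_spectrum(mk(c(rep(0.2, 120), rep(0.4, 80))))
  pk2 <- detect_peaks(s2)
  expect_equal(nrow(pk2), 2L)
  expect_lt(abs(pk2$position[1] - 0.2), 0.011)
  expect_lt(abs(pk2$position[2] - 0.4), 0.011)
  expect_gt(pk2$mass[1], pk2$mass[2])

  # uniform 2% mass per bin: no window holds more than 10% of total
  flat <- mk(seq(0.005, 0.495, by = 0.01))
  s3 <- build_spectrum(flat, min_frac = 0.001)
  expect_equal(sum(s3$counts > 0), 50L)
  expect_error(detect_peaks(s3, min_mass_frac = 0.10), "no peak")
})

test_that("ploidy inference maps peak sets to the smallest consistent ploidy", {
  expect_equal(infer_ploidy(0.50)$ploidy, 2L)
  expect_equal(infer_ploidy(0.33)$ploidy, 3L)
  expect_equal(infer_ploidy(c(0.20, 0.40))$ploidy, 5L)
  expect_equal(infer_ploidy(0.25)$ploidy, 4L)            # parsimony, not 8x
  expect_equal(infer_ploidy(c(0.25, 0.50))$ploidy, 4L)   # 0.50 allowed as 2 of 4
  expect_true(all(vapply(list(0.5, 0.33, c(0.2, 0.4), c(0.25, 0.5)),
                         function(p) infer_ploidy(p)$consistent, TRUE)))
  # inconsistent peaks: best effort with the flag down
  odd <- infer_ploidy(c(0.15, 0.47))
  expect_false(odd$consistent)
  # every consistent call satisfies the allowed-set predicate exactly
  for (p in 2:6) {
    peaks <- allowed_peaks(p)
    call <- infer_ploidy(peaks)
    expect_true(call$consistent)
    expect_true(all(vapply(call$peak_positions, function(x)
      min(abs(x - allowed_peaks(call$ploidy))) <= 0.03, TRUE)))
  }
})

test_that("allowed peak sets follow min(d, p-d)/p", {
  expect_equal(allowed_peaks(2), 0.5)
  expect_equal(allowed_peaks(3), 1 / 3)
  expect_equal(allowed_peaks(4), c(0.25, 0.5))
  expect_equal(allowed_peaks(5), c(0.2, 0.4))
})

test_that("simulated dosage peaks land within 0.02 of min(d, p-d)/p at high coverage", {
  set.seed(17)
  cases <- list(c(2, 1), c(3, 1), c(4, 1), c(5, 2))
  for (cs in cases) {
    p <- cs[1]; d <- cs[2]
    dt <- simulate_ploidy_depths(3000, p, dosage = d, depth_mean = 150,
                                 depth_dispersion = 0.15)
    pk <- detect_peaks(build_spectrum(dt))
    main <- pk$position[which.max(pk$mass)]
    expect_lt(abs(main - min(d, p - d) / p), 0.02)
  }
})

test_that("ploidy recovery from mixed-dosage simulations is reliable for 2x-5x", {
  set.seed(23)
  for (p in 2:5) {
    dt <- simulate_ploidy_depths(2000, p, dosage = NULL, depth_mean = 100)
    call <- infer_ploidy(detect_peaks(build_spectrum(dt)))
    expect_equal(call$ploidy, p)
    expect_true(call$consistent)
  }
})

test_that("merging clonal libraries leaves peaks in place; mixing ploidies does not", {
  set.seed(29)
  lib <- function(id, p, dos) {
    dt <- simulate_ploidy_depths(2500, p, dosage = dos, sample_id = id)
    dt
  }
  d1 <- lib("t1", 3, 1)
  d2 <- lib("t2", 3, 1)
  both <- rbind(d1, d2)
  st <- merge_stability(both, list("t1", "t2"))
  expect_true(st$stable)
  expect_gte(st$union_n_loci, max(st$comparison$n_loci))
  expect_lt(abs(st$union_peaks$position[1] - 1 / 3), 0.02)

  # diploid + triploid libraries: shifted/double peaks fail the check
  d3 <- lib("t3", 2, 1)
  mix <- rbind(d1, d3)
  st2 <- merge_stability(mix, list("t1", "t3"))
  expect_false(st2$stable)
})
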