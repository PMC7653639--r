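# Independent brute-force oracles and tiny fixture builders.

# random genotype matrix: alleles 1..n_alleles, hom/het/missing cells
random_gt <- function(n_samples, n_loci, n_alleles = 4, p_missing = 0.15) {
  a1 <- matrix(sample(seq_len(n_alleles), n_samples * n_loci, TRUE),
               n_samples, n_loci)
  a2 <- matrix(sample(seq_len(n_alleles), n_samples * n_loci, TRUE),
               n_samples, n_loci)
  miss <- matrix(runif(n_samples * n_loci) < p_missing, n_samples, n_loci)
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  genotype_matrix(a1, a2,
                  sample_ids = sprintf("S%02d", seq_len(n_samples)),
                  locus_ids = sprintf("L%03d", seq_len(n_loci)))
}

# genotype matrix from a character matrix of "a/b" / NA, with default ids
gt <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("S%d", seq_len(nrow(m)))
  colnames(m) <- sprintf("L%d", seq_len(ncol(m)))
  genotype_matrix_from_strings(m)
}

# per-locus, per-pair exhaustive p-distance
oracle_p_distance <- function(m) {
  n <- n_samples(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    diffs <- 0L
    L <- 0L
    for (l in seq_len(n_loci(m))) {
      x <- c(m$a1[i, l], m$a2[i, l])
      y <- c(m$a1[j, l], m$a2[j, l])
      if (any(is.na(x)) || any(is.na(y))) next
      L <- L + 1L
      if (identical(sort(x), sort(y))) {
        # 0 differences
      } else if (length(intersect(x, y)) > 0L) {
        diffs <- diffs + 1L
      } else {
        diffs <- diffs + 2L
      }
    }
    d[i, j] <- if (L == 0L) NA_real_ else diffs / (2 * L)
  }
  d
}

# union-find connected components over an edge list
oracle_components <- function(ids, edges_a, edges_b) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k])
    rb <- find(edges_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(ids, find, "")
  split(ids, roots)
}

# canonical form of a partition for comparison
canon_partition <- function(groups) {
  groups <- lapply(groups, function(g) sort(unname(g)))
  unname(groups[order(vapply(groups, `[`, "", 1L))])
}

# depth table from a matrix of counts: rows = loci, cols = alleles
depth_from_counts <- function(counts, sample_id = "S1") {
  loci <- sprintf("L%04d", seq_len(nrow(counts)))
  alleles <- colnames(counts)
  if (is.null(alleles)) alleles <- as.character(seq_len(ncol(counts)))
  df <- data.frame(
    sample_id = sample_id,
    locus_id = rep(loci, times = ncol(counts)),
    allele = rep(alleles, each = nrow(counts)),
    count = as.vector(counts))
  df[df$count > 0, , drop = FALSE]
}

two_taxon_config <- function(seed, ...) {
  sim_config(list(
    taxon_spec("taxA", ploidy = 3, n_clones = 1, ramets_per_clone = 10,
               n_localities = 6, habit = "solitary"),
    taxon_spec("taxB", ploidy = 2, n_clones = 5, ramets_per_clone = 1,
               n_localities = 1, habit = "stoloniferous",
               reproduce = "sexual_diploid", males_recorded = TRUE)
  ), seed = seed, ...)
}
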