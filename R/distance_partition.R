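#' Filter loci by missing-data fraction
#'
#' Keeps loci whose fraction of missing calls across samples is at most
#' `max_missing_frac` (boundary inclusive). `max_missing_frac = 0` keeps only
#' loci called in every sample.
#'
#' @param m a [genotype_matrix()].
#' @param max_missing_frac allowed missing fraction per locus, in \[0, 1\].
#' @return A [genotype_matrix()] with the surviving loci, order preserved.
#' @export
filter_loci_by_missingness <- function(m, max_missing_frac = 0.30) {
  if (max_missing_frac < 0 || max_missing_frac > 1)
    stop("max_missing_frac must be in [0, 1]")
  keep <- colMeans(is_missing(m)) <= max_missing_frac
  m[, keep]
}

#' Pairwise p-distance matrix with pairwise deletion
#'
#' For each sample pair, over the loci where both calls are present, each
#' locus contributes 0, 1 or 2 allele differences (identical unordered pair,
#' one shared allele, no shared allele) and the distance is the difference
#' count divided by twice the number of shared loci. Pairs sharing no loci
#' get `NA` (undefined, never silently zero).
#'
#' @param m a [genotype_matrix()] with at least two samples.
#' @return A list of class `p_distance` with `d` (symmetric distance matrix,
#'   zero diagonal), `n_compared` (loci used per pair) and `sample_ids`.
#' @export
p_distance_matrix <- function(m) {
  n <- n_samples(m)
  if (n < 2L) stop("need at least two samples")
  ids <- sample_ids(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  ncmp <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(ncmp) <- as.integer(colSums(!is.na(t(m$a1))))
  a1 <- m$a1
  a2 <- m$a2
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      both <- !is.na(a1[i, ]) & !is.na(a1[j, ])
      L <- sum(both)
      ncmp[i, j] <- ncmp[j, i] <- L
      if (L == 0L) {
        d[i, j] <- d[j, i] <- NA_real_
        next
      }
      x1 <- a1[i, both]; x2 <- a2[i, both]
      y1 <- a1[j, both]; y2 <- a2[j, both]
      eq <- x1 == y1 & x2 == y2
      share <- x1 == y1 | x1 == y2 | x2 == y1 | x2 == y2
      diffs <- sum(ifelse(eq, 0L, ifelse(share, 1L, 2L)))
      d[i, j] <- d[j, i] <- diffs / (2 * L)
    }
  }
  structure(list(d = d, n_compared = ncmp, sample_ids = ids),
            class = "p_distance")
}

#' Partition samples into similarity groups
#'
#' Groups samples whose p-distance is at most `1 - similarity_cutoff`.
#' Single linkage (connected components of the threshold graph) is the
#' default; complete linkage is available. Undefined distances are treated as
#' above threshold (non-edges). Groups are returned largest first, ties
#' broken by smallest member id.
#'
#' @param dm a [p_distance_matrix()] result.
#' @param similarity_cutoff similarity threshold in (0, 1\]; e.g. 0.9978
#'   groups samples at least 99.78 % similar.
#' @param linkage `"single"` (default) or `"complete"`.
#' @return A list of character vectors of sample ids (each sorted).
#' @export
partition_samples <- function(dm, similarity_cutoff = 0.9978,
                              linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (similarity_cutoff < 0 || similarity_cutoff > 1)
    stop("similarity_cutoff must be in [0, 1]")
  thr <- 1 - similarity_cutoff
  d <- dm$d
  ids <- dm$sample_ids
  adj <- !is.na(d) & d <= thr
  diag(adj) <- TRUE
  if (linkage == "single") {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    memb <- igraph::components(g)$membership
  } else {
    d2 <- d
    d2[is.na(d2)] <- 2           # beyond any possible p-distance
    hc <- stats::hclust(stats::as.dist(d2), method = "complete")
    memb <- stats::cutree(hc, h = thr)
  }
  groups <- split(ids, memb)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups), vapply(groups, `[`, "", 1L))
  unname(groups[ord])
}

#' Count parsimony-informative loci
#'
#' A locus is parsimony-informative when at least two distinct alleles are
#' each present (in any dosage) in at least two samples.
#'
#' @param m a [genotype_matrix()].
#' @return Integer count of informative loci.
#' @export
count_parsimony_informative <- function(m) {
  informative <- vapply(seq_len(n_loci(m)), function(j) {
    x1 <- m$a1[, j]
    x2 <- m$a2[, j]
    ok <- !is.na(x1)
    if (!any(ok)) return(FALSE)
    # samples carrying each allele (presence, not dosage)
    carriers <- table(unique(data.frame(
      s = rep(which(ok), 2L), a = c(x1[ok], x2[ok])))$a)
    sum(carriers >= 2L) >= 2L
  }, logical(1L))
  sum(informative)
}
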