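#' Heterozygous-locus similarity between two samples
#'
#' The clone-detection statistic: each heterozygous locus of one sample is
#' compared to the call at the same locus in the other sample, and the
#' percentage of identical matches is recorded. Both directions are computed
#' (A's het loci against B, and B's against A) and averaged; the raw
#' directional percentages are kept for audit. A direction is undefined when
#' the focal sample has no heterozygous locus that is called in the partner;
#' if both directions are undefined the pair is incomparable (`NA`).
#'
#' @param a,b sample ids.
#' @param m a [genotype_matrix()].
#' @param min_overlap minimum total compared het loci before the value is
#'   considered reliable (default 20); smaller pairs are flagged, not dropped.
#' @param match `"genotype"` (default): a match is an identical unordered
#'   allele pair. `"allele"`: a match is any shared allele.
#' @return A list with `sim_percent`, `n_het_compared` (loci entering either
#'   direction), `pct_ab`, `pct_ba`, `n_ab`, `n_ba` and `reliable`.
#' @export
het_similarity <- function(a, b, m, min_overlap = 20L,
                           match = c("genotype", "allele")) {
  match <- match.arg(match)
  ia <- base::match(a, sample_ids(m))
  ib <- base::match(b, sample_ids(m))
  if (is.na(ia) || is.na(ib)) stop("sample not in matrix: ",
                                   if (is.na(ia)) a else b)
  het <- is_het(m)
  called <- !is_missing(m)
  res <- het_similarity_idx(ia, ib, m$a1, m$a2, het, called, match)
  res$reliable <- !is.na(res$sim_percent) && res$n_het_compared >= min_overlap
  res
}

# directional comparison on row indices; het/called are precomputed matrices
het_similarity_idx <- function(ia, ib, a1, a2, het, called, match) {
  direction <- function(i, j) {
    idx <- het[i, ] & called[j, ]
    n <- sum(idx)
    if (n == 0L) return(c(NA_real_, 0))
    if (match == "genotype") {
      hits <- sum(a1[i, idx] == a1[j, idx] & a2[i, idx] == a2[j, idx])
    } else {
      hits <- sum(a1[i, idx] == a1[j, idx] | a1[i, idx] == a2[j, idx] |
                    a2[i, idx] == a1[j, idx] | a2[i, idx] == a2[j, idx])
    }
    c(100 * hits / n, n)
  }
  ab <- direction(ia, ib)
  ba <- direction(ib, ia)
  sims <- c(ab[1L], ba[1L])
  sim <- if (all(is.na(sims))) NA_real_ else mean(sims, na.rm = TRUE)
  list(sim_percent = sim, n_het_compared = as.integer(ab[2L] + ba[2L]),
       pct_ab = ab[1L], pct_ba = ba[1L],
       n_ab = as.integer(ab[2L]), n_ba = as.integer(ba[2L]))
}

#' All pairwise heterozygous-locus similarities
#'
#' Computes [het_similarity()] for every unordered sample pair. Sorting the
#' `sim_percent` column low-to-high reproduces the classic clone-detection
#' curve: a dense low block (distinct clones), an empty gap, and a high block
#' (within-clone pairs and technical duplicates).
#'
#' @param m a [genotype_matrix()] with at least two samples.
#' @inheritParams het_similarity
#' @return A `data.frame` of class `similarity_table`: one row per unordered
#'   pair with `sample_a`, `sample_b` (a < b), `sim_percent`,
#'   `n_het_compared`, `pct_ab`, `pct_ba`, `reliable`.
#' @export
pairwise_het_similarities <- function(m, min_overlap = 20L,
                                      match = c("genotype", "allele")) {
  match <- match.arg(match)
  n <- n_samples(m)
  if (n < 2L) stop("need at least two samples")
  ids <- sample_ids(m)
  het <- is_het(m)
  called <- !is_missing(m)
  pairs <- utils::combn(n, 2L)
  np <- ncol(pairs)
  out <- data.frame(sample_a = character(np), sample_b = character(np),
                    sim_percent = numeric(np), n_het_compared = integer(np),
                    pct_ab = numeric(np), pct_ba = numeric(np),
                    stringsAsFactors = FALSE)
  for (k in seq_len(np)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    lo <- if (ids[i] <= ids[j]) i else j
    hi <- if (ids[i] <= ids[j]) j else i
    r <- het_similarity_idx(lo, hi, m$a1, m$a2, het, called, match)
    out$sample_a[k] <- ids[lo]
    out$sample_b[k] <- ids[hi]
    out$sim_percent[k] <- r$sim_percent
    out$n_het_compared[k] <- r$n_het_compared
    out$pct_ab[k] <- r$pct_ab
    out$pct_ba[k] <- r$pct_ba
  }
  out$reliable <- !is.na(out$sim_percent) & out$n_het_compared >= min_overlap
  class(out) <- c("similarity_table", "data.frame")
  attr(out, "sample_ids") <- ids
  out
}

# canonical unordered-pair key
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Calibrate the clone similarity threshold from duplicate libraries
#'
#' Looks for the widest empty interval (gap) among the pairwise similarity
#' values lying below the minimum duplicate-library similarity, and places
#' the threshold at its midpoint. If no duplicates are supplied, the gap is
#' searched over all values. When the widest gap is narrower than
#' `min_gap_width` the calibration falls back to `default_percent` with a
#' warning. Every duplicate pair must exceed the returned threshold —
#' a duplicate below it indicates contamination and is an error.
#'
#' @param tab a [pairwise_het_similarities()] table.
#' @param duplicates `data.frame` with columns `sample_a`, `sample_b` listing
#'   known duplicate-library pairs, or `NULL`.
#' @param default_percent fallback threshold (default 85).
#' @param min_gap_width minimum acceptable gap width in percentage points
#'   (default 5).
#' @return A list with `threshold_percent`, `gap` (`c(low, high)` or `NULL`
#'   when falling back), `calibrated` (logical) and `duplicate_range`.
#' @export
calibrate_threshold <- function(tab, duplicates = NULL, default_percent = 85,
                                min_gap_width = 5) {
  sims <- tab$sim_percent[!is.na(tab$sim_percent)]
  if (length(sims) == 0L) stop("similarity table has no comparable pairs")
  dup_sims <- numeric(0)
  if (!is.null(duplicates) && nrow(duplicates) > 0L) {
    key <- pair_key(tab$sample_a, tab$sample_b)
    dkey <- pair_key(duplicates$sample_a, duplicates$sample_b)
    hit <- key %in% dkey
    dup_sims <- tab$sim_percent[hit & !is.na(tab$sim_percent)]
  }
  ceiling_val <- if (length(dup_sims)) min(dup_sims) else Inf
  below <- sort(unique(sims[sims < ceiling_val]))
  cand <- if (is.finite(ceiling_val)) c(below, ceiling_val) else below
  gap <- NULL
  if (length(cand) >= 2L) {
    w <- diff(cand)
    k <- which.max(w)
    if (w[k] >= min_gap_width) gap <- c(low = cand[k], high = cand[k + 1L])
  }
  if (is.null(gap)) {
    warning("no similarity gap of at least ", min_gap_width,
            " points; falling back to default threshold ", default_percent, "%")
    threshold <- default_percent
    calibrated <- FALSE
  } else {
    threshold <- mean(gap)
    calibrated <- TRUE
  }
  if (length(dup_sims) && any(dup_sims < threshold)) {
    key <- pair_key(tab$sample_a, tab$sample_b)
    dkey <- pair_key(duplicates$sample_a, duplicates$sample_b)
    bad <- tab[key %in% dkey & !is.na(tab$sim_percent) &
                 tab$sim_percent < threshold, , drop = FALSE]
    stop("calibration failure: duplicate pair below threshold (possible ",
         "contamination): ",
         paste(bad$sample_a, bad$sample_b, round(bad$sim_percent, 2),
               collapse = "; "))
  }
  list(threshold_percent = threshold, gap = gap, calibrated = calibrated,
       duplicate_range = if (length(dup_sims)) range(dup_sims) else NULL)
}

#' Assign samples to clones
#'
#' Clones are the connected components of the graph whose edges join sample
#' pairs with similarity at or above the threshold. Incomparable pairs are
#' non-edges. A component containing an internal pair below the threshold is
#' kept intact but recorded as a transitivity violation. Clone ids are the
#' lexicographically smallest member of each clone.
#'
#' @param tab a [pairwise_het_similarities()] table.
#' @param threshold_percent similarity threshold in (0, 100).
#' @return A list of class `clone_assignment` with `assignment` (data.frame
#'   `sample_id`, `clone_id`), `threshold_percent`, `clones` (list of member
#'   vectors, largest first) and `transitivity_violations` (data.frame of
#'   offending within-clone pairs).
#' @export
assign_clones <- function(tab, threshold_percent = 85) {
  if (threshold_percent <= 0 || threshold_percent >= 100)
    stop("threshold_percent must be in (0, 100)")
  ids <- attr(tab, "sample_ids")
  if (is.null(ids)) ids <- sort(unique(c(tab$sample_a, tab$sample_b)))
  edge <- !is.na(tab$sim_percent) & tab$sim_percent >= threshold_percent
  g <- igraph::graph_from_data_frame(
    tab[edge, c("sample_a", "sample_b"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = ids))
  memb <- igraph::components(g)$membership[ids]
  clones <- split(ids, memb)
  clone_id <- vapply(clones, function(v) min(v), "")
  assignment <- data.frame(
    sample_id = ids,
    clone_id = clone_id[as.character(memb)],
    stringsAsFactors = FALSE, row.names = NULL)
  # within-clone pairs observed below threshold
  same <- assignment$clone_id[base::match(tab$sample_a, assignment$sample_id)] ==
    assignment$clone_id[base::match(tab$sample_b, assignment$sample_id)]
  viol <- tab[same & !edge & !is.na(tab$sim_percent),
              c("sample_a", "sample_b", "sim_percent"), drop = FALSE]
  rownames(viol) <- NULL
  clones <- lapply(clones, sort)
  names(clones) <- clone_id
  ord <- order(-lengths(clones), names(clones))
  structure(list(assignment = assignment,
                 threshold_percent = threshold_percent,
                 clones = clones[ord],
                 transitivity_violations = viol),
            class = "clone_assignment")
}

#' @export
print.clone_assignment <- function(x, ...) {
  cat(sprintf("clone_assignment: %d samples in %d clones (threshold %.2f%%)\n",
              nrow(x$assignment), length(x$clones), x$threshold_percent))
  if (nrow(x$transitivity_violations))
    cat("  ", nrow(x$transitivity_violations), "transitivity violation(s)\n")
  invisible(x)
}

#' Compare a clone assignment against simulation truth
#'
#' Pairwise precision and recall over co-clonal sample pairs: a pair is a
#' positive when both members carry the same label. Duplicate libraries must
#' be labelled with their biological clone in `truth`.
#'
#' @param assignment data.frame with `sample_id`, `clone_id` (e.g. from
#'   [assign_clones()]).
#' @param truth data.frame with `sample_id`, `clone_id` giving true labels.
#' @return A list with `precision`, `recall`, `n_pairs_pred`, `n_pairs_true`.
#' @export
clone_metrics <- function(assignment, truth) {
  ids <- assignment$sample_id
  pred <- assignment$clone_id
  tru <- truth$clone_id[base::match(ids, truth$sample_id)]
  if (any(is.na(tru))) stop("truth missing for some samples")
  cmb <- utils::combn(length(ids), 2L)
  p_same <- pred[cmb[1L, ]] == pred[cmb[2L, ]]
  t_same <- tru[cmb[1L, ]] == tru[cmb[2L, ]]
  list(precision = if (any(p_same)) mean(t_same[p_same]) else NA_real_,
       recall = if (any(t_same)) mean(p_same[t_same]) else NA_real_,
       n_pairs_pred = sum(p_same), n_pairs_true = sum(t_same))
}
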