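#' Construct a diploidized genotype matrix
#'
#' The central container of the pipeline: an unordered allele-pair call per
#' (sample, locus) cell. Calls are diploidized in the Stacks sense — a
#' polyploid heterozygote is still stored as a two-allele pair, so true allele
#' dosage is only visible through read depths, never through the matrix.
#'
#' @param a1,a2 integer matrices (samples x loci) holding the two alleles of
#'   each call. Pairs are unordered: the constructor sorts each cell so that
#'   `a1 <= a2`. A missing call has `NA` in both matrices.
#' @param sample_ids,locus_ids character vectors naming rows and columns;
#'   default to the dimnames of `a1`.
#'
#' @return An object of class `genotype_matrix`: a list with integer matrices
#'   `a1`, `a2` carrying sample/locus dimnames.
#' @export
genotype_matrix <- function(a1, a2,
                            sample_ids = rownames(a1),
                            locus_ids = colnames(a1)) {
  if (!is.matrix(a1) || !is.matrix(a2) || !all(dim(a1) == dim(a2)))
    stop("a1 and a2 must be matrices of identical dimensions")
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(a1)))
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(ncol(a1)))
  sample_ids <- as.character(sample_ids)
  locus_ids <- as.character(locus_ids)
  if (length(sample_ids) != nrow(a1) || length(locus_ids) != ncol(a1))
    stop("id vectors inconsistent with matrix dimensions")
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  if (any(is.na(a1) != is.na(a2)))
    stop("half-missing calls are not allowed: both alleles or neither")
  # enforce unordered storage
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(sample_ids, locus_ids)
  structure(list(a1 = a1, a2 = a2), class = "genotype_matrix")
}

#' Build a genotype matrix from "a/b" call strings
#'
#' @param calls character matrix with entries like `"1/2"` (allele pair) or
#'   `NA` for missing.
#' @return A [genotype_matrix()].
#' @export
genotype_matrix_from_strings <- function(calls) {
  if (!is.matrix(calls)) stop("calls must be a character matrix")
  split2 <- function(part) {
    out <- matrix(NA_integer_, nrow(calls), ncol(calls))
    ok <- !is.na(calls)
    pieces <- strsplit(calls[ok], "/", fixed = TRUE)
    if (any(lengths(pieces) != 2L)) stop("calls must look like 'a/b'")
    out[ok] <- as.integer(vapply(pieces, `[`, "", part))
    out
  }
  genotype_matrix(split2(1L), split2(2L),
                  sample_ids = rownames(calls), locus_ids = colnames(calls))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d loci (%.1f%% missing, %.1f%% heterozygous of called)\n",
    n_samples(x), n_loci(x),
    100 * mean(is_missing(x)),
    100 * mean(is_het(x)[!is_missing(x)])
  ))
  invisible(x)
}

#' Genotype matrix accessors
#'
#' @param m a [genotype_matrix()].
#' @return `sample_ids()`/`locus_ids()` return character vectors;
#'   `n_samples()`/`n_loci()` integers; `is_het()`/`is_missing()` logical
#'   matrices; `genotype_strings()` a character matrix of `"a/b"` calls.
#' @name genotype-accessors
NULL

#' @rdname genotype-accessors
#' @export
sample_ids <- function(m) rownames(m$a1)

#' @rdname genotype-accessors
#' @export
locus_ids <- function(m) colnames(m$a1)

#' @rdname genotype-accessors
#' @export
n_samples <- function(m) nrow(m$a1)

#' @rdname genotype-accessors
#' @export
n_loci <- function(m) ncol(m$a1)

#' @rdname genotype-accessors
#' @export
is_missing <- function(m) is.na(m$a1)

#' @rdname genotype-accessors
#' @export
is_het <- function(m) !is.na(m$a1) & m$a1 != m$a2

#' @rdname genotype-accessors
#' @export
genotype_strings <- function(m) {
  out <- matrix(NA_character_, n_samples(m), n_loci(m),
                dimnames = dimnames(m$a1))
  ok <- !is.na(m$a1)
  out[ok] <- paste0(m$a1[ok], "/", m$a2[ok])
  out
}

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i,j sample and locus indices (any form base matrices accept).
#' @param ... ignored.
#' @return A [genotype_matrix()] over the selected samples and loci.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_loci(x))
  genotype_matrix(x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE])
}
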