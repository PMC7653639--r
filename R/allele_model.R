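#' Genotype-calling parameters
#'
#' Depth and minor-allele-frequency rules used to turn per-allele read counts
#' into diploidized genotype calls. Defaults follow the standard ddRAD
#' filtering scheme: a locus needs at least 30 reads; a minor allele present
#' in more than 10 % of reads is called (heterozygote); a locus whose minor
#' allele sits in the ambiguous 5-10 % band is discarded; below 5 % the minor
#' reads are treated as sequencing error and the locus is called homozygous.
#'
#' @param min_depth minimum total reads per locus (default 30).
#' @param het_min_frac minor fraction above which a heterozygote is called
#'   (default 0.10; exclusive bound).
#' @param error_max_frac minor fraction at or below which minor reads are
#'   treated as error (default 0.05; inclusive bound). The discard band is
#'   `(error_max_frac, het_min_frac]`.
#' @return A list of class `call_params`.
#' @export
call_params <- function(min_depth = 30L, het_min_frac = 0.10,
                        error_max_frac = 0.05) {
  if (min_depth < 1L) stop("min_depth must be >= 1")
  if (!(error_max_frac >= 0 && error_max_frac <= het_min_frac && het_min_frac < 1))
    stop("need 0 <= error_max_frac <= het_min_frac < 1")
  structure(list(min_depth = as.integer(min_depth),
                 het_min_frac = het_min_frac,
                 error_max_frac = error_max_frac),
            class = "call_params")
}

#' Call one locus from allele read depths
#'
#' Band convention (boundaries included downward): minor fraction
#' `<= error_max_frac` is homozygous, in `(error_max_frac, het_min_frac]` the
#' locus is discarded, `> het_min_frac` is heterozygous. A locus with more
#' than two alleles above `het_min_frac` is discarded as paranormal. Total
#' depth below `min_depth` (including all-zero depths) yields no call.
#'
#' @param depths named numeric vector of read counts per allele.
#' @param params a [call_params()] object.
#' @return A list of class `locus_call` with `state` (one of `"HOM"`,
#'   `"HET"`, `"DISCARDED"`, `"NO_CALL"`), `alleles` (sorted pair of allele
#'   names for HOM/HET, else `NULL`), `total_depth` and `minor_frac`
#'   (`NA` when no call).
#' @export
call_locus <- function(depths, params = call_params()) {
  if (length(depths) == 0L) stop("depths must be non-empty")
  if (any(depths < 0)) stop("depths must be non-negative")
  if (is.null(names(depths))) names(depths) <- as.character(seq_along(depths))
  total <- sum(depths)
  res <- function(state, alleles = NULL, minor = NA_real_) {
    structure(list(state = state, alleles = alleles,
                   total_depth = as.integer(total), minor_frac = minor),
              class = "locus_call")
  }
  if (total < params$min_depth) return(res("NO_CALL"))
  o <- order(-depths, names(depths))          # depth desc, allele name tiebreak
  d <- depths[o]
  minor <- (total - d[[1L]]) / total          # exact at band boundaries
  if (sum(d / total > params$het_min_frac) > 2L)
    return(res("DISCARDED", minor = minor))
  if (minor <= params$error_max_frac)
    return(res("HOM", alleles = rep(names(d)[1L], 2L), minor = minor))
  if (minor <= params$het_min_frac)
    return(res("DISCARDED", minor = minor))
  res("HET", alleles = sort(names(d)[1:2]), minor = minor)
}

# Vectorized group statistics over a depth table: one row per (sample, locus)
# with total depth, top-two allele names/counts and the count of alleles whose
# frequency exceeds `het_min_frac`.
depth_group_stats <- function(df, het_min_frac = 0.10) {
  key <- paste(df$sample_id, df$locus_id, sep = "\r")
  o <- order(key, -df$count, df$allele, method = "radix")
  key <- key[o]
  cnt <- df$count[o]
  al <- df$allele[o]
  first <- !duplicated(key)
  gidx <- cumsum(first)                       # group index per row
  ng <- gidx[length(gidx)]
  total <- as.vector(rowsum(cnt, gidx))
  top1_cnt <- cnt[first]
  top1_al <- al[first]
  # second occurrence of each key, if any
  rest <- which(!first)
  second <- rest[!duplicated(gidx[rest])]
  top2_cnt <- rep(0L, ng)
  top2_al <- rep(NA_character_, ng)
  top2_cnt[gidx[second]] <- cnt[second]
  top2_al[gidx[second]] <- al[second]
  above <- as.vector(rowsum(as.integer(cnt > het_min_frac * total[gidx]), gidx))
  data.frame(sample_id = df$sample_id[o][first],
             locus_id = df$locus_id[o][first],
             total = total, top1_al = top1_al, top1_cnt = top1_cnt,
             top2_al = top2_al, top2_cnt = top2_cnt, n_above = above,
             stringsAsFactors = FALSE)
}

#' Build a genotype matrix from a depth table
#'
#' Applies [call_locus()] to every (sample, locus) cell. `DISCARDED` and
#' `NO_CALL` states both become missing cells; allele names are mapped to
#' integer codes by sorted order of the allele alphabet observed in the table.
#'
#' @param df a depth table (see [read_depth_table()]).
#' @param params a [call_params()] object.
#' @return A [genotype_matrix()] with a `call_states` attribute: a per-sample
#'   table of call-state tallies for logging.
#' @export
build_genotype_matrix <- function(df, params = call_params()) {
  df <- validate_depth_table(df)
  if (nrow(df) == 0L) stop("depth table is empty")
  st <- depth_group_stats(df, params$het_min_frac)
  minor <- (st$total - st$top1_cnt) / st$total
  state <- rep("HET", nrow(st))
  state[minor <= params$het_min_frac] <- "DISCARDED"
  state[minor <= params$error_max_frac] <- "HOM"
  state[st$n_above > 2L] <- "DISCARDED"
  state[st$total < params$min_depth] <- "NO_CALL"

  alphabet <- sort(unique(df$allele))
  code <- function(a) match(a, alphabet)
  samples <- unique(df$sample_id)
  loci <- unique(df$locus_id)
  a1 <- matrix(NA_integer_, length(samples), length(loci),
               dimnames = list(samples, loci))
  a2 <- a1
  idx <- cbind(match(st$sample_id, samples), match(st$locus_id, loci))
  hom <- state == "HOM"
  het <- state == "HET"
  a1[idx[hom, , drop = FALSE]] <- code(st$top1_al[hom])
  a2[idx[hom, , drop = FALSE]] <- code(st$top1_al[hom])
  a1[idx[het, , drop = FALSE]] <- code(st$top1_al[het])
  a2[idx[het, , drop = FALSE]] <- code(st$top2_al[het])
  m <- genotype_matrix(a1, a2)
  tallies <- table(sample_id = st$sample_id,
                   state = factor(state, c("HOM", "HET", "DISCARDED", "NO_CALL")))
  attr(m, "call_states") <- tallies
  attr(m, "allele_alphabet") <- alphabet
  m
}

#' Minor-allele depth fraction of a locus
#'
#' The allele-balance statistic behind the ploidy spectrum: with exactly two
#' alleles passing the calling cut-off, the fraction of reads carried by the
#' minor allele relative to the top-two allele depth. `NA` when total
#' coverage is below `min_total`, when no second allele reaches `min_frac`,
#' or when more than two alleles do.
#'
#' @param depths named numeric vector of read counts per allele.
#' @param min_total minimum total coverage (default 20).
#' @param min_frac lower cut-off for calling an allele (default 0.05).
#' @param denominator `"top_two"` (default, mirrors kmer-pair normalization)
#'   or `"total"`.
#' @return A fraction in (0, 0.5], or `NA_real_`.
#' @export
minor_fraction <- function(depths, min_total = 20L, min_frac = 0.05,
                           denominator = c("top_two", "total")) {
  denominator <- match.arg(denominator)
  if (any(depths < 0)) stop("depths must be non-negative")
  total <- sum(depths)
  if (total < min_total) return(NA_real_)
  pass <- depths[depths / total >= min_frac]
  if (length(pass) != 2L) return(NA_real_)
  pass <- sort(pass, decreasing = TRUE)
  den <- if (denominator == "top_two") sum(pass) else total
  unname(pass[2L] / den)
}

#' Minor-allele depth fractions for every (sample, locus) in a depth table
#'
#' Vectorized [minor_fraction()] over a depth table.
#'
#' @inheritParams build_genotype_matrix
#' @inheritParams minor_fraction
#' @return A `data.frame` with `sample_id`, `locus_id`, `minor_frac` (`NA`
#'   where the locus fails the filters).
#' @export
minor_fraction_table <- function(df, min_total = 20L, min_frac = 0.05,
                                 denominator = c("top_two", "total")) {
  denominator <- match.arg(denominator)
  df <- validate_depth_table(df)
  if (nrow(df) == 0L)
    return(data.frame(sample_id = character(0), locus_id = character(0),
                      minor_frac = numeric(0)))
  key <- paste(df$sample_id, df$locus_id, sep = "\r")
  o <- order(key, -df$count, df$allele, method = "radix")
  key <- key[o]
  cnt <- df$count[o]
  first <- !duplicated(key)
  gidx <- cumsum(first)
  ng <- gidx[length(gidx)]
  total <- as.vector(rowsum(cnt, gidx))
  top1 <- cnt[first]
  rest <- which(!first)
  second <- rest[!duplicated(gidx[rest])]
  top2 <- rep(NA_real_, ng)
  top2[gidx[second]] <- cnt[second]
  n_pass <- as.vector(rowsum(as.integer(cnt >= min_frac * total[gidx]), gidx))
  frac <- rep(NA_real_, ng)
  ok <- total >= min_total & n_pass == 2L & !is.na(top2)
  den <- if (denominator == "top_two") top1 + top2 else total
  frac[ok] <- top2[ok] / den[ok]
  data.frame(sample_id = df$sample_id[o][first],
             locus_id = df$locus_id[o][first],
             minor_frac = frac, stringsAsFactors = FALSE)
}
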