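#' Read a genepop genotype file
#'
#' Parses the classic genepop layout emitted by Stacks: a title line, locus
#' names (one per line or a single comma-separated line), then one or more
#' `Pop` blocks of `sample_id , 0101 0202 ...` rows. Allele code 0 (`00` or
#' `000`) marks a missing call; a genotype containing a 0 allele is treated as
#' wholly missing.
#'
#' @param path file path.
#' @param allele_digits 2 or 3, or `NULL` (default) to auto-detect from the
#'   width of the first genotype string.
#' @return A [genotype_matrix()], samples in file order.
#' @export
read_genepop <- function(path, allele_digits = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("genepop file too short: ", path)
  body <- lines[-1L]                       # drop title
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop("genepop format error: no 'Pop' line in ", path)
  locus_lines <- body[seq_len(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",", fixed = TRUE)))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop("genepop format error: no locus names in ", path)
  rows <- body[seq.int(first_pop, length(body))]
  rows <- rows[!grepl("^\\s*pop\\s*$", rows, ignore.case = TRUE)]
  if (length(rows) == 0L) stop("genepop format error: no sample rows in ", path)

  ids <- character(length(rows))
  gts <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    parts <- strsplit(rows[k], ",", fixed = TRUE)[[1L]]
    if (length(parts) < 2L)
      stop("genepop format error at sample row ", k, ": no comma separator")
    ids[k] <- trimws(parts[1L])
    g <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "\\s+")[[1L]]
    gts[[k]] <- g[nzchar(g)]
  }
  widths <- unique(nchar(unlist(gts)))
  if (is.null(allele_digits)) {
    if (length(widths) != 1L || !widths %in% c(4L, 6L))
      stop("genepop dialect error: cannot auto-detect allele-code width (genotype widths: ",
           paste(widths, collapse = ", "), ")")
    allele_digits <- widths / 2L
  }
  if (!allele_digits %in% c(2L, 3L))
    stop("genepop dialect error: allele_digits must be 2 or 3")
  if (any(widths != 2L * allele_digits))
    stop("genepop format error: genotype strings not ", 2L * allele_digits,
         " characters wide")
  bad <- which(lengths(gts) != length(loci))
  if (length(bad))
    stop("genepop format error: sample row ", bad[1L], " ('", ids[bad[1L]],
         "') has ", lengths(gts)[bad[1L]], " genotypes, expected ", length(loci))

  gmat <- matrix(unlist(gts), nrow = length(rows), byrow = TRUE)
  a1 <- matrix(as.integer(substr(gmat, 1L, allele_digits)),
               nrow = nrow(gmat))
  a2 <- matrix(as.integer(substr(gmat, allele_digits + 1L, 2L * allele_digits)),
               nrow = nrow(gmat))
  miss <- a1 == 0L | a2 == 0L
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  genotype_matrix(a1, a2, sample_ids = ids, locus_ids = loci)
}

#' Write a genotype matrix as genepop
#'
#' @param m a [genotype_matrix()].
#' @param path output file path.
#' @param title title line (first line of the file).
#' @param allele_digits 2 (default) or 3.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(m, path, title = "clonekit export", allele_digits = 2L) {
  if (!allele_digits %in% c(2L, 3L))
    stop("allele_digits must be 2 or 3")
  amax <- suppressWarnings(max(m$a2, na.rm = TRUE))
  if (is.finite(amax) && amax >= 10L^allele_digits)
    stop("allele codes too large for ", allele_digits, "-digit genepop")
  fmt <- paste0("%0", allele_digits, "d")
  code <- function(a) {
    out <- sprintf(fmt, ifelse(is.na(a), 0L, a))
    matrix(out, n_samples(m), n_loci(m))
  }
  g <- matrix(paste0(code(m$a1), code(m$a2)), n_samples(m), n_loci(m))
  rows <- paste(sample_ids(m), ",", apply(g, 1L, paste, collapse = " "))
  writeLines(c(title, locus_ids(m), "Pop", rows), path)
  invisible(path)
}

#' Read a per-allele read-depth table
#'
#' Tab-separated with header `sample_id, locus_id, allele, count`; one row per
#' observed allele at a (sample, locus).
#'
#' @param path file path.
#' @return A `data.frame` with those four columns (`count` integer).
#' @export
read_depth_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "character", "numeric"))
  validate_depth_table(df)
}

#' Validate a depth table
#'
#' @param df data.frame with columns `sample_id`, `locus_id`, `allele`,
#'   `count`.
#' @return The validated data.frame (count coerced to integer).
#' @export
validate_depth_table <- function(df) {
  need <- c("sample_id", "locus_id", "allele", "count")
  if (!all(need %in% names(df)))
    stop("depth table must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  if (nrow(df) == 0L) {
    df$count <- integer(0)
    return(df)
  }
  if (any(is.na(df$count)) || any(df$count < 0) || any(df$count != round(df$count)))
    stop("depth table validation error: counts must be non-negative integers")
  key <- paste(df$sample_id, df$locus_id, df$allele, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop("depth table validation error: duplicated (sample, locus, allele) key: ",
         paste(df$sample_id[dup][1L], df$locus_id[dup][1L], df$allele[dup][1L],
               sep = " / "))
  df$count <- as.integer(df$count)
  df$allele <- as.character(df$allele)
  rownames(df) <- NULL
  df
}

#' Write a depth table as TSV
#'
#' @param df a depth table (see [read_depth_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' CSV with columns `sample_id`, `taxon_label`, `locality_id`,
#' `duplicate_group` (empty when the library is the only one from its
#' biological sample), `habit` (`solitary` or `stoloniferous`), `native`
#' and `males_recorded` (logical; `males_recorded` may be NA where the taxon
#' was not surveyed).
#'
#' @param path file path.
#' @return A validated `data.frame`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_sample_metadata(df)
}

#' Validate sample metadata
#'
#' @param df data.frame of sample metadata (see [read_sample_metadata()]).
#' @return The validated data.frame.
#' @export
validate_sample_metadata <- function(df) {
  need <- c("sample_id", "taxon_label", "locality_id", "duplicate_group",
            "habit", "native", "males_recorded")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("metadata validation error: duplicated sample_id: ",
         df$sample_id[duplicated(df$sample_id)][1L])
  bad_habit <- setdiff(unique(df$habit), c("solitary", "stoloniferous"))
  if (length(bad_habit))
    stop("metadata validation error: unknown habit value: ",
         paste(bad_habit, collapse = ", "))
  df$native <- as.logical(df$native)
  df$males_recorded <- as.logical(df$males_recorded)
  grp <- df$duplicate_group[!is.na(df$duplicate_group)]
  for (g in unique(grp)) {
    taxa <- unique(df$taxon_label[!is.na(df$duplicate_group) &
                                    df$duplicate_group == g])
    if (length(taxa) > 1L)
      stop("metadata validation error: duplicate_group '", g,
           "' spans multiple taxa: ", paste(taxa, collapse = ", "))
  }
  df
}

#' Read flow-cytometry 2C replicate measurements
#'
#' CSV with columns `sample_id`, `day` (integer day index) and `c2_pg`
#' (holoploid 2C genome size in picograms). Each plant is expected to be
#' measured on at least three different days.
#'
#' @param path file path.
#' @return A `data.frame` with those columns.
#' @export
read_fcm_replicates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "day", "c2_pg")
  if (!all(need %in% names(df)))
    stop("FCM replicate table must have columns: ", paste(need, collapse = ", "))
  if (any(is.na(df$c2_pg)) || any(df$c2_pg <= 0))
    stop("FCM validation error: 2C values must be positive")
  df[need]
}

#' Extract duplicate-library pairs from metadata
#'
#' Every pair of libraries sharing a `duplicate_group` is a known technical
#' duplicate: two sequencing libraries of one biological sample. These pairs
#' calibrate the error floor of the heterozygous-locus similarity statistic.
#'
#' @param meta sample metadata (see [read_sample_metadata()]).
#' @return A `data.frame` with columns `sample_a`, `sample_b`.
#' @export
duplicate_pairs <- function(meta) {
  out <- list()
  grp <- meta$duplicate_group
  for (g in unique(grp[!is.na(grp)])) {
    ids <- sort(meta$sample_id[!is.na(grp) & grp == g])
    if (length(ids) >= 2L) {
      cmb <- utils::combn(ids, 2L)
      out[[g]] <- data.frame(sample_a = cmb[1L, ], sample_b = cmb[2L, ],
                             stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(sample_a = character(0), sample_b = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
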