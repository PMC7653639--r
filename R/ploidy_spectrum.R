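#' Build a minor-allele depth-fraction spectrum
#'
#' Pools [minor_fraction()] values for the requested samples into a histogram
#' over (0, 0.5]. Modal positions indicate ploidy: diploid heterozygous loci
#' pile at 1/2, triploid at 1/3, tetraploid at 1/4 (and 1/2), pentaploid at
#' 1/5 and 2/5. Only the fraction axis carries signal with ddRAD data — the
#' raw count axis reflects the skewed coverage distribution.
#'
#' @param df a depth table (see [read_depth_table()]).
#' @param samples sample ids to pool, or `NULL` for all samples in the table.
#' @param min_total minimum total locus coverage (default 20).
#' @param min_frac lower cut-off for calling an allele (default 0.05).
#' @param bin_width histogram bin width on the fraction axis (default 0.01).
#' @param denominator passed to [minor_fraction_table()].
#' @return A list of class `allele_spectrum` with `breaks`, `mids`, `counts`,
#'   `n_loci` (fractions used), `n_excluded` and `params`.
#' @export
build_spectrum <- function(df, samples = NULL, min_total = 20L,
                           min_frac = 0.05, bin_width = 0.01,
                           denominator = c("top_two", "total")) {
  denominator <- match.arg(denominator)
  if (!is.null(samples)) {
    missing_samples <- setdiff(samples, unique(df$sample_id))
    if (length(missing_samples))
      stop("samples not in depth table: ",
           paste(missing_samples, collapse = ", "))
    df <- df[df$sample_id %in% samples, , drop = FALSE]
  }
  mf <- minor_fraction_table(df, min_total = min_total, min_frac = min_frac,
                             denominator = denominator)
  fracs <- mf$minor_frac[!is.na(mf$minor_frac)]
  if (length(fracs) == 0L)
    stop("empty spectrum: no locus passed the coverage/allele filters")
  breaks <- seq(0, 0.5, by = bin_width)
  if (breaks[length(breaks)] < 0.5) breaks <- c(breaks, 0.5)
  # fractions are in (0, 0.5]; right-closed bins match
  counts <- as.vector(table(cut(fracs, breaks, right = TRUE,
                                include.lowest = FALSE)))
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = counts, n_loci = length(fracs),
                 n_excluded = sum(is.na(mf$minor_frac)),
                 params = list(min_total = min_total, min_frac = min_frac,
                               bin_width = bin_width,
                               denominator = denominator)),
            class = "allele_spectrum")
}

#' @export
print.allele_spectrum <- function(x, ...) {
  cat(sprintf("allele_spectrum: %d loci in %d bins of width %.3g (%d excluded)\n",
              x$n_loci, length(x$counts), x$params$bin_width, x$n_excluded))
  invisible(x)
}

#' Plot a minor-allele fraction spectrum
#'
#' @param x an [build_spectrum()] result.
#' @param peaks optional [detect_peaks()] result to mark.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.allele_spectrum <- function(x, peaks = NULL, ...) {
  graphics::plot(x$mids, x$counts, type = "h", lwd = 3, lend = 1,
                 xlab = "minor-allele depth fraction", ylab = "loci",
                 xlim = c(0, 0.5), ...)
  if (!is.null(peaks))
    graphics::abline(v = peaks$position, col = "red", lty = 2)
  invisible(x)
}

# centered moving average, partial at the edges
smooth_counts <- function(counts, window) {
  if (window <= 1L) return(as.numeric(counts))
  half <- (window - 1L) %/% 2L
  n <- length(counts)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(counts[lo:hi])
  }, numeric(1L))
}

#' Detect peaks in an allele-balance spectrum
#'
#' Local maxima of the smoothed histogram are retained when the raw mass
#' within two bins of the maximum holds more than `min_mass_frac` of the
#' total spectrum mass (strictly more: a uniform spectrum concentrates
#' exactly `5 * bin_width / 0.5` of its mass in any window and must yield no
#' peak). Peak positions are the mass-weighted centroid of the bins
#' in that window, which is robust to the read-depth dispersion of real data.
#'
#' @param s an [build_spectrum()] result.
#' @param min_mass_frac minimum fraction of total mass within +/-2 bins of a
#'   maximum (default 0.10).
#' @param smooth_window moving-average window in bins (default 3).
#' @param min_separation suppression radius in bins: of two local maxima
#'   closer than this, only the stronger is kept. Default 8: genuine
#'   allele-balance positions are never closer than 12 bins at the default
#'   bin width for ploidy up to 8, while dispersion shoulders fall within a
#'   few bins of their smudge, so one smudge is never split in two.
#' @return A `data.frame` with `position`, `mass`, `mass_frac` and `bin`
#'   (index of the maximum), sorted by position.
#' @export
detect_peaks <- function(s, min_mass_frac = 0.10, smooth_window = 3L,
                         min_separation = 8L) {
  counts <- s$counts
  n <- length(counts)
  if (sum(counts) == 0L) stop("no peak: spectrum is empty")
  sm <- smooth_counts(counts, smooth_window)
  left <- c(-Inf, sm[-n])
  right <- c(sm[-1L], -Inf)
  cand <- which(sm >= left & sm >= right & sm > 0)
  # collapse plateau runs to their centre bin
  if (length(cand)) {
    runs <- split(cand, cumsum(c(1L, diff(cand) != 1L)))
    cand <- vapply(runs, function(r) r[ceiling(length(r) / 2)], integer(1L))
  }
  # greedy suppression: keep the strongest candidate in any min_separation radius
  cand <- cand[order(-sm[cand], cand)]
  kept <- integer(0)
  for (b in cand) {
    if (all(abs(b - kept) >= min_separation)) kept <- c(kept, b)
  }
  total <- sum(counts)
  rows <- lapply(kept, function(b) {
    win <- max(1L, b - 2L):min(n, b + 2L)
    mass <- sum(counts[win])
    data.frame(position = sum(s$mids[win] * counts[win]) / mass,
               mass = mass, mass_frac = mass / total, bin = b)
  })
  out <- do.call(rbind, rows)
  out <- out[out$mass_frac > min_mass_frac, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no peak: no local maximum holds more than ", min_mass_frac,
         " of the spectrum mass")
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Allowed allele-balance peak positions for a ploidy level
#'
#' At ploidy `p` a heterozygous locus with `d` copies of the minor allele
#' contributes reads at fraction `min(d, p - d) / p`.
#'
#' @param ploidy integer >= 2.
#' @return Sorted unique vector of allowed fractions.
#' @export
allowed_peaks <- function(ploidy) {
  d <- seq_len(ploidy - 1L)
  sort(unique(pmin(d, ploidy - d) / ploidy))
}

#' Infer ploidy from allele-balance peaks
#'
#' Chooses the smallest ploidy `p` in `2..max_ploidy` such that every peak
#' lies within `tolerance` of the allowed set for `p` and the lowest peak
#' matches `1/p`. The parsimony (smallest-p) rule arbitrates degenerate
#' cases, e.g. a lone 0.25 peak is called tetraploid, not octoploid. When no
#' ploidy fits, the closest one is returned with `consistent = FALSE`.
#'
#' @param peaks numeric vector of peak positions, or a [detect_peaks()]
#'   data.frame.
#' @param tolerance maximum distance from an allowed position (default 0.03,
#'   small enough to separate 1/3 from 1/4 and 2/5).
#' @param max_ploidy highest ploidy considered (default 8).
#' @return A list of class `ploidy_call` with `ploidy`, `peak_positions`,
#'   `peak_masses` (when available) and `consistent`.
#' @export
infer_ploidy <- function(peaks, tolerance = 0.03, max_ploidy = 8L) {
  masses <- NULL
  if (is.data.frame(peaks)) {
    masses <- peaks$mass
    peaks <- peaks$position
  }
  if (length(peaks) == 0L) stop("need at least one peak")
  fits <- function(p) {
    allowed <- allowed_peaks(p)
    all(vapply(peaks, function(x) min(abs(x - allowed)) <= tolerance,
               logical(1L))) &&
      abs(min(peaks) - 1 / p) <= tolerance
  }
  score <- function(p) {
    allowed <- allowed_peaks(p)
    sum(vapply(peaks, function(x) min(abs(x - allowed)), numeric(1L))) +
      abs(min(peaks) - 1 / p)
  }
  candidates <- 2L:max_ploidy
  ok <- vapply(candidates, fits, logical(1L))
  if (any(ok)) {
    p <- candidates[which(ok)[1L]]
    consistent <- TRUE
  } else {
    p <- candidates[which.min(vapply(candidates, score, numeric(1L)))]
    consistent <- FALSE
  }
  structure(list(ploidy = p, peak_positions = peaks, peak_masses = masses,
                 consistent = consistent),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat(sprintf("ploidy_call: %dx (peaks at %s)%s\n", x$ploidy,
              paste(sprintf("%.3f", x$peak_positions), collapse = ", "),
              if (x$consistent) "" else " [inconsistent: best effort]"))
  invisible(x)
}

#' Library-merging stability check
#'
#' If several libraries are truly clonal, pooling their depth tables must not
#' move the allele-balance peaks — the signal only sharpens with more data.
#' Builds a spectrum per library set and for the union. The check fails when
#' a set disagrees with the union on the number of detected peaks, when the
#' union loses loci, or when any set's mass centroid inside a union peak's
#' window sits more than one bin width from the union peak (libraries likely
#' not clonal). Centroids are compared inside the union's windows so that the
#' verdict reflects genuine allele-balance shifts, not the bin-level jitter
#' of independently placed windows.
#'
#' @param df a depth table.
#' @param library_sets list (length >= 2) of character vectors of sample ids.
#' @param ... passed to [build_spectrum()] and [detect_peaks()] via
#'   `min_total`, `min_frac`, `bin_width`, `min_mass_frac`.
#' @param min_total,min_frac,bin_width spectrum parameters.
#' @param min_mass_frac peak mass filter.
#' @return A list with `stable` (logical), `comparison` (per-set peak
#'   positions and shifts) and `union_peaks`.
#' @export
merge_stability <- function(df, library_sets, min_total = 20L,
                            min_frac = 0.05, bin_width = 0.01,
                            min_mass_frac = 0.10) {
  if (length(library_sets) < 2L) stop("need at least two library sets")
  spectra <- lapply(library_sets, function(s)
    build_spectrum(df, samples = s, min_total = min_total,
                   min_frac = min_frac, bin_width = bin_width))
  union_set <- unique(unlist(library_sets))
  s_union <- build_spectrum(df, samples = union_set, min_total = min_total,
                            min_frac = min_frac, bin_width = bin_width)
  p_union <- detect_peaks(s_union, min_mass_frac = min_mass_frac)
  nb <- length(s_union$counts)
  rows <- list()
  stable <- s_union$n_loci >= max(vapply(spectra, `[[`, 0L, "n_loci"))
  for (k in seq_along(spectra)) {
    sp <- spectra[[k]]
    pk <- detect_peaks(sp, min_mass_frac = min_mass_frac)
    if (nrow(pk) != nrow(p_union)) stable <- FALSE
    # set centroid inside each union peak's window
    position <- shift <- rep(NA_real_, nrow(p_union))
    for (u in seq_len(nrow(p_union))) {
      win <- max(1L, p_union$bin[u] - 2L):min(nb, p_union$bin[u] + 2L)
      mass <- sum(sp$counts[win])
      if (mass == 0L) {
        stable <- FALSE
        next
      }
      position[u] <- sum(sp$mids[win] * sp$counts[win]) / mass
      shift[u] <- abs(position[u] - p_union$position[u])
      if (shift[u] > bin_width) stable <- FALSE
    }
    rows[[k]] <- data.frame(set = k, position = position, shift = shift,
                            n_loci = sp$n_loci)
  }
  list(stable = stable, comparison = do.call(rbind, rows),
       union_peaks = p_union, union_n_loci = s_union$n_loci)
}
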