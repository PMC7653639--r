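#' Half-up rounding
#'
#' Rounds halves away from zero, matching the convention used for printed
#' picogram values (base `round()` rounds halves to even, which would give
#' 2.290/4 = 0.572 instead of the conventional 0.573).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Quality control for flow-cytometry 2C replicates
#'
#' Replicate acceptance rule: at least `min_reps` measurements on different
#' days; accepted outright when day-to-day variation (max/min ratio) stays
#' within `daily_ratio_max`; when it exceeds that, the series is accepted
#' only once the standard error of the mean falls below `sem_max_frac` of the
#' mean, otherwise another measurement is needed.
#'
#' @param values numeric vector of 2C measurements in pg.
#' @param daily_ratio_max maximum accepted max/min ratio (default 1.02, i.e.
#'   2 % day-to-day variation).
#' @param sem_max_frac maximum SEM as a fraction of the mean (default 0.01).
#' @param min_reps minimum number of replicates (default 3).
#' @return A list with `decision` (`"accepted"`, `"needs_more_measurements"`
#'   or `"rejected"`), `mean_2c`, `max_min_ratio` and `sem_frac`.
#' @export
qc_fcm_replicates <- function(values, daily_ratio_max = 1.02,
                              sem_max_frac = 0.01, min_reps = 3L) {
  if (length(values) < 1L) stop("need at least one measurement")
  if (any(is.na(values)) || any(values <= 0))
    return(list(decision = "rejected", mean_2c = NA_real_,
                max_min_ratio = NA_real_, sem_frac = NA_real_))
  ratio <- max(values) / min(values)
  sem_frac <- if (length(values) >= 2L)
    stats::sd(values) / sqrt(length(values)) / mean(values) else NA_real_
  decision <- if (length(values) < min_reps) {
    "needs_more_measurements"
  } else if (ratio <= daily_ratio_max) {
    "accepted"
  } else if (!is.na(sem_frac) && sem_frac < sem_max_frac) {
    "accepted"
  } else {
    "needs_more_measurements"
  }
  list(decision = decision, mean_2c = mean(values), max_min_ratio = ratio,
       sem_frac = sem_frac)
}

#' Monoploid (1Cx) genome size from a 2C value
#'
#' @param twoC holoploid 2C genome size in pg (> 0).
#' @param ploidy integer ploidy level (>= 1).
#' @param decimals decimal places for half-up rounding (default 3, the
#'   conventional pg precision).
#' @return 1Cx value in pg.
#' @export
monoploid_size <- function(twoC, ploidy, decimals = 3L) {
  if (any(twoC <= 0)) stop("twoC must be positive")
  if (any(ploidy < 1L)) stop("ploidy must be >= 1")
  round_half_up(twoC / ploidy, decimals)
}

#' Theoretical 2C range for a ploidy level from diploid 1Cx anchors
#'
#' Multiplies the smallest and largest monoploid anchor by the ploidy: the
#' interval a taxon's 2C value should occupy in the absence of genome
#' up/downsizing. A measured 2C below the interval flags genome downsizing.
#'
#' @param ploidy integer ploidy level.
#' @param cx_anchors numeric vector of monoploid (1Cx) sizes in pg, usually
#'   from measured diploids.
#' @return Named numeric `c(low, high)`.
#' @export
theoretical_2c_range <- function(ploidy, cx_anchors) {
  if (length(cx_anchors) == 0L) stop("need at least one anchor")
  c(low = ploidy * min(cx_anchors), high = ploidy * max(cx_anchors))
}

#' Intraspecific genome-size variation
#'
#' Percent excess of the largest over the smallest measured value.
#'
#' @param values numeric vector (length >= 2) of 2C values in pg.
#' @return Percentage, `100 * (max - min) / min`.
#' @export
intraspecific_variation <- function(values) {
  if (length(values) < 2L) stop("need at least two values")
  100 * (max(values) - min(values)) / min(values)
}
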