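#' Published survey summary for Singapore *Hanguana*
#'
#' The per-taxon evidence table from the ddRAD survey of the dioecious forest
#' herb genus *Hanguana* (Hanguanaceae) in Singapore: sample and locality
#' counts, growth habit, detected clone counts, male sightings, ploidy and
#' genome sizes, plus the published sexual-system call. `n_localities` is
#' `NA` for the non-native taxa, which were not field-surveyed;
#' `males_recorded` is likewise `NA` for them. `system_inferred` marks taxa
#' whose clonality could not be tested, so the call rests on ploidy or male
#' records alone.
#'
#' @return A `data.frame` with one row per taxon.
#' @export
hanguana_survey <- function() {
  data.frame(
    taxon = c("Hanguana anthelminthica", "Hanguana corneri",
              "Hanguana fraseriana", "Hanguana neglecta", "Hanguana nitens",
              "Hanguana podzolicola", "Hanguana rubinea",
              "Hanguana triangulata", "Hanguana sp. 'MacRitchie'",
              "Hanguana sp. 'Mandai'"),
    n_samples = c(5L, 1L, 1L, 23L, 12L, 8L, 75L, 9L, 2L, 1L),
    n_duplicates = c(0L, 0L, 0L, 7L, 3L, 1L, 4L, 3L, 1L, 1L),
    n_localities = c(NA, NA, NA, 11L, 1L, 5L, 47L, 8L, 2L, 1L),
    native = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    habit = c("stoloniferous", "solitary", "solitary", "solitary",
              "stoloniferous", "solitary", "solitary", "solitary",
              "solitary", "solitary"),
    n_clones = c(2L, 1L, 1L, 1L, 8L, 1L, 1L, 1L, 1L, 1L),
    males_recorded = c(NA, NA, NA, FALSE, TRUE, FALSE, FALSE, FALSE,
                       FALSE, FALSE),
    ploidy = c(4L, 2L, 3L, 5L, 2L, 3L, 3L, 3L, 3L, 3L),
    c2_pg = c(2.290, 1.493, 2.099, 3.561, 1.276, 2.050, 2.027, 2.001,
              1.990, 1.995),
    cx1_pg = c(0.573, 0.747, 0.700, 0.712, 0.638, 0.683, 0.676, 0.667,
               0.663, 0.665),
    system = c("sexual", "sexual", "apomictic", "apomictic", "sexual",
               "apomictic", "apomictic", "apomictic", "apomictic",
               "apomictic"),
    system_inferred = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                        FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Classify a taxon's sexual system from survey evidence
#'
#' Codifies the inference chain linking clone counts, localities, growth
#' habit, male records and ploidy to a sexual/apomictic call, in a dioecious
#' plant where gametophytic apomixis predicts odd ploidy:
#'
#' 1. Males recorded implies sexual reproduction (a male cannot be apomictic).
#' 2. Where clonality is testable (at least two samples from at least two
#'    known localities), multiple clones imply sexual reproduction.
#' 3. A single clone spread over several localities in a solitary
#'    (non-stoloniferous) taxon implies apomixis — vegetative spread cannot
#'    explain the distribution. In a stoloniferous taxon the same pattern is
#'    called apomictic but flagged inconclusive, since runners confound it.
#' 4. Where clonality is untestable (a single sample, or localities unknown),
#'    the call is inferred from ploidy parity: odd ploidy (3x, 5x) implies
#'    apomixis, even ploidy defaults to sexual.
#'
#' `inferred` is `TRUE` exactly when rule 4 carried the call.
#'
#' @param evidence a `data.frame` with columns `n_samples`, `n_localities`,
#'   `habit`, `n_clones`, `males_recorded`, `ploidy` (one row per taxon; see
#'   [hanguana_survey()]).
#' @return A `data.frame` with `call` (`"sexual"`/`"apomictic"`), `inferred`,
#'   `flagged` (stoloniferous uniclonal ambiguity) and `rationale`
#'   (semicolon-joined fired rules), one row per input row.
#' @export
classify_sexual_system <- function(evidence) {
  if (any(evidence$n_clones > evidence$n_samples, na.rm = TRUE))
    stop("n_clones cannot exceed n_samples")
  one <- function(e) {
    rules <- character(0)
    if (isTRUE(e$males_recorded)) {
      return(list(call = "sexual", inferred = FALSE, flagged = FALSE,
                  rationale = "males recorded: sexual"))
    }
    testable <- !is.na(e$n_localities) && e$n_samples >= 2L &&
      e$n_localities >= 2L
    if (testable) {
      if (e$n_clones >= 2L)
        return(list(call = "sexual", inferred = FALSE, flagged = FALSE,
                    rationale = "multiple clones among sampled localities: sexual"))
      if (e$habit == "solitary")
        return(list(call = "apomictic", inferred = FALSE, flagged = FALSE,
                    rationale = paste0("single clone across ", e$n_localities,
                                       " localities, solitary habit: apomictic")))
      return(list(call = "apomictic", inferred = FALSE, flagged = TRUE,
                  rationale = "single clone but stoloniferous: vegetative spread confounds; flagged"))
    }
    if (is.na(e$ploidy))
      stop("inconclusive: clonality untestable and ploidy unknown for row")
    if (e$ploidy %% 2L == 1L)
      return(list(call = "apomictic", inferred = TRUE, flagged = FALSE,
                  rationale = sprintf("clonality untestable; odd ploidy (%dx): apomictic (inferred)",
                                      e$ploidy)))
    list(call = "sexual", inferred = TRUE, flagged = FALSE,
         rationale = sprintf("clonality untestable; even ploidy (%dx): sexual (inferred)",
                             e$ploidy))
  }
  rows <- lapply(seq_len(nrow(evidence)), function(i) {
    r <- one(as.list(evidence[i, , drop = FALSE]))
    data.frame(call = r$call, inferred = r$inferred, flagged = r$flagged,
               rationale = r$rationale, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(evidence$taxon)) out <- cbind(taxon = evidence$taxon, out)
  rownames(out) <- NULL
  out
}
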