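#' Pipeline configuration
#'
#' Collects inputs and stage parameters for [run_pipeline()]. Inputs may be
#' in-memory objects or file paths (genepop for genotypes, TSV for depths,
#' CSV for metadata). A YAML file with these fields is accepted via
#' [read_pipeline_config()].
#'
#' @param genotypes a [genotype_matrix()] or genepop path; `NULL` to build
#'   calls from the depth table.
#' @param depth a depth table data.frame or TSV path; `NULL` for
#'   clonality-only mode (the ploidy stage is skipped with a warning).
#' @param metadata metadata data.frame or CSV path (optional; enables
#'   duplicate calibration and taxon-level classification).
#' @param call_params a [call_params()] object for depth-based calling.
#' @param partition_similarity similarity cutoff for the sample partition
#'   (default 0.9978).
#' @param partition_max_missing per-locus missingness allowed at the
#'   partition stage (default 0.30).
#' @param group_max_missing per-locus missingness allowed within a partition
#'   group before clonality (default 0: no missing data for any sample).
#' @param clone_default_threshold fallback similarity threshold in percent
#'   (default 85).
#' @param min_overlap minimum compared het loci per pair (default 20).
#' @param min_gap_width minimum calibration gap width in points (default 5).
#' @param ploidy_min_total,ploidy_min_frac,ploidy_bin_width spectrum
#'   parameters (defaults 20, 0.05, 0.01).
#' @param ploidy_min_mass_frac peak mass filter (default 0.10).
#' @param ploidy_tolerance peak-to-allowed-position tolerance (default 0.03).
#' @param out_dir directory for intermediate tables, or `NULL`.
#' @param seed RNG seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes = NULL, depth = NULL, metadata = NULL,
                            call_params = clonekit::call_params(),
                            partition_similarity = 0.9978,
                            partition_max_missing = 0.30,
                            group_max_missing = 0,
                            clone_default_threshold = 85,
                            min_overlap = 20L, min_gap_width = 5,
                            ploidy_min_total = 20L, ploidy_min_frac = 0.05,
                            ploidy_bin_width = 0.01,
                            ploidy_min_mass_frac = 0.10,
                            ploidy_tolerance = 0.03,
                            out_dir = NULL, seed = 1L) {
  if (is.null(genotypes) && is.null(depth))
    stop("need genotypes (genepop) or a depth table")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments;
#' `genotypes`, `depth` and `metadata` are file paths.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (f in c("genotypes", "depth", "metadata"))
    if (!is.null(y[[f]]) && !file.exists(y[[f]]))
      stop("configured path does not exist: ", y[[f]])
  cp <- do.call(call_params, y$call_params %||% list())
  y$call_params <- cp
  do.call(pipeline_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the clone-detection and ploidy pipeline
#'
#' Stages, in order: (1) genotype acquisition (genepop, or depth-based
#' calling); (2) locus filtering at `partition_max_missing` and p-distance
#' partition at `partition_similarity`; (3) per partition group, loci are
#' refiltered to `group_max_missing`, pairwise heterozygous-locus
#' similarities computed, the clone threshold calibrated against duplicate
#' libraries (falling back to `clone_default_threshold`), and clones
#' assigned; (4) per-sample allele-balance ploidy calls when depths are
#' available; (5) per-taxon sexual-system classification when metadata is
#' available. Deterministic: identical inputs give an identical report.
#'
#' @param cfg a [pipeline_config()].
#' @return A list of class `clone_report`; see its printed summary for the
#'   main per-taxon table.
#' @export
run_pipeline <- function(cfg) {
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  # -- stage 1: genotypes -----------------------------------------------
  m <- cfg$genotypes
  if (is.character(m)) m <- read_genepop(m)
  if (is.null(m)) {
    depth <- cfg$depth
    if (is.character(depth)) depth <- read_depth_table(depth)
    m <- build_genotype_matrix(depth, cfg$call_params)
    cfg$depth <- depth
  }
  depth <- cfg$depth
  if (is.character(depth)) depth <- read_depth_table(depth)
  meta <- cfg$metadata
  if (is.character(meta)) meta <- read_sample_metadata(meta)
  say("stage genotypes: %d samples x %d loci", n_samples(m), n_loci(m))

  # -- stage 2: partition ------------------------------------------------
  m_part <- filter_loci_by_missingness(m, cfg$partition_max_missing)
  say("stage partition: %d loci pass missingness <= %.2f",
      n_loci(m_part), cfg$partition_max_missing)
  if (n_loci(m_part) == 0L)
    stop("stage partition failed: no locus passes the missingness filter")
  dm <- p_distance_matrix(m_part)
  groups <- partition_samples(dm, cfg$partition_similarity)
  say("stage partition: %d group(s) at %.4f similarity",
      length(groups), cfg$partition_similarity)

  dup_all <- if (!is.null(meta)) duplicate_pairs(meta) else
    data.frame(sample_a = character(0), sample_b = character(0))

  # -- stage 3: clonality per group --------------------------------------
  group_results <- vector("list", length(groups))
  assignment <- list()
  for (gi in seq_along(groups)) {
    gs <- groups[[gi]]
    if (length(gs) < 2L) {
      assignment[[gi]] <- data.frame(sample_id = gs, clone_id = gs,
                                     stringsAsFactors = FALSE)
      group_results[[gi]] <- list(samples = gs, n_loci = NA_integer_,
                                  singleton = TRUE)
      next
    }
    mg <- filter_loci_by_missingness(m[gs, ], cfg$group_max_missing)
    say("group %d (%d samples): %d loci at missingness <= %.2f, %d parsimony-informative",
        gi, length(gs), n_loci(mg), cfg$group_max_missing,
        count_parsimony_informative(mg))
    if (n_loci(mg) == 0L)
      stop("stage clonality failed in group ", gi,
           ": no locus passes the within-group missingness filter (samples: ",
           paste(gs, collapse = ", "), ")")
    tab <- pairwise_het_similarities(mg, min_overlap = cfg$min_overlap)
    dup_g <- dup_all[dup_all$sample_a %in% gs & dup_all$sample_b %in% gs, ,
                     drop = FALSE]
    cal <- withCallingHandlers(
      calibrate_threshold(tab, duplicates = dup_g,
                          default_percent = cfg$clone_default_threshold,
                          min_gap_width = cfg$min_gap_width),
      warning = function(w) {
        say("group %d: %s", gi, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    ca <- assign_clones(tab, cal$threshold_percent)
    if (nrow(ca$transitivity_violations))
      say("group %d: %d transitivity violation(s)", gi,
          nrow(ca$transitivity_violations))
    assignment[[gi]] <- ca$assignment
    group_results[[gi]] <- list(samples = gs, n_loci = n_loci(mg),
                                similarities = tab, calibration = cal,
                                clones = ca, singleton = FALSE)
  }
  assignment <- do.call(rbind, assignment)
  say("stage clonality: %d clone(s) among %d samples",
      length(unique(assignment$clone_id)), nrow(assignment))

  # -- stage 4: ploidy ---------------------------------------------------
  ploidy_calls <- NULL
  if (is.null(depth)) {
    warning("no depth table configured: ploidy stage skipped")
    say("stage ploidy: skipped (no depth table)")
  } else {
    ids <- intersect(sample_ids(m), unique(depth$sample_id))
    rows <- lapply(ids, function(sid) {
      call <- tryCatch({
        s <- build_spectrum(depth, samples = sid,
                            min_total = cfg$ploidy_min_total,
                            min_frac = cfg$ploidy_min_frac,
                            bin_width = cfg$ploidy_bin_width)
        pk <- detect_peaks(s, min_mass_frac = cfg$ploidy_min_mass_frac)
        infer_ploidy(pk, tolerance = cfg$ploidy_tolerance)
      }, error = function(e) NULL)
      if (is.null(call))
        return(data.frame(sample_id = sid, ploidy = NA_integer_,
                          consistent = FALSE, peaks = NA_character_,
                          stringsAsFactors = FALSE))
      data.frame(sample_id = sid, ploidy = call$ploidy,
                 consistent = call$consistent,
                 peaks = paste(sprintf("%.3f", call$peak_positions),
                               collapse = ","),
                 stringsAsFactors = FALSE)
    })
    ploidy_calls <- do.call(rbind, rows)
    say("stage ploidy: %d consistent call(s) of %d samples",
        sum(ploidy_calls$consistent), nrow(ploidy_calls))
  }

  # -- stage 5: per-taxon summary and classification ---------------------
  taxa <- NULL
  if (!is.null(meta)) {
    meta2 <- meta[meta$sample_id %in% assignment$sample_id, , drop = FALSE]
    meta2$clone_id <- assignment$clone_id[match(meta2$sample_id,
                                                assignment$sample_id)]
    if (!is.null(ploidy_calls))
      meta2$ploidy <- ploidy_calls$ploidy[match(meta2$sample_id,
                                                ploidy_calls$sample_id)]
    rows <- lapply(split(meta2, meta2$taxon_label), function(d) {
      # count biological samples: duplicate libraries collapse onto one
      bio <- ifelse(is.na(d$duplicate_group), d$sample_id, d$duplicate_group)
      pl <- if (!is.null(d$ploidy)) {
        p <- d$ploidy[!is.na(d$ploidy)]
        if (length(p)) as.integer(stats::median(p)) else NA_integer_
      } else NA_integer_
      data.frame(taxon = d$taxon_label[1L],
                 n_samples = length(unique(bio)),
                 n_localities = length(unique(d$locality_id)),
                 habit = d$habit[1L],
                 n_clones = length(unique(d$clone_id)),
                 males_recorded = d$males_recorded[1L],
                 ploidy = pl, stringsAsFactors = FALSE)
    })
    taxa <- do.call(rbind, rows)
    rownames(taxa) <- NULL
    cls <- classify_sexual_system(taxa)
    taxa$system <- cls$call
    taxa$system_inferred <- cls$inferred
    taxa$system_flagged <- cls$flagged
    say("stage classification: %d taxa (%d apomictic, %d sexual)",
        nrow(taxa), sum(taxa$system == "apomictic"),
        sum(taxa$system == "sexual"))
  }

  report <- structure(list(groups = groups, group_results = group_results,
                           assignment = assignment,
                           ploidy_calls = ploidy_calls, taxa = taxa,
                           distance = dm, log = log_lines, config = cfg),
                      class = "clone_report")
  if (!is.null(cfg$out_dir)) write_clone_report(report, cfg$out_dir)
  report
}

#' @export
print.clone_report <- function(x, ...) {
  cat(sprintf("clone_report: %d samples, %d partition group(s), %d clone(s)\n",
              nrow(x$assignment), length(x$groups),
              length(unique(x$assignment$clone_id))))
  if (!is.null(x$taxa)) {
    cat("\nPer-taxon summary:\n")
    print(x$taxa, row.names = FALSE)
  }
  invisible(x)
}

#' Write the report's tables under a directory
#'
#' Emits `clones.csv`, `similarities.tsv` (all groups pooled, sorted low to
#' high — the clone-detection curve), `ploidy.csv`, `taxa.csv`,
#' `distance.tsv` and `log.txt`.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_clone_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$assignment, file.path(dir, "clones.csv"),
                   row.names = FALSE)
  sims <- do.call(rbind, lapply(seq_along(report$group_results), function(i) {
    gr <- report$group_results[[i]]
    if (isTRUE(gr$singleton)) return(NULL)
    cbind(group = i, gr$similarities)
  }))
  if (!is.null(sims)) {
    sims <- sims[order(sims$sim_percent), , drop = FALSE]
    utils::write.table(sims, file.path(dir, "similarities.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$ploidy_calls))
    utils::write.csv(report$ploidy_calls, file.path(dir, "ploidy.csv"),
                     row.names = FALSE)
  if (!is.null(report$taxa))
    utils::write.csv(report$taxa, file.path(dir, "taxa.csv"),
                     row.names = FALSE)
  utils::write.table(report$distance$d, file.path(dir, "distance.tsv"),
                     sep = "\t", quote = FALSE)
  writeLines(report$log, file.path(dir, "log.txt"))
  invisible(dir)
}
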