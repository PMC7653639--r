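#' Describe one simulated taxon
#'
#' @param name taxon label.
#' @param ploidy 2-5.
#' @param n_clones number of genetically distinct clones (for
#'   `reproduce = "sexual_diploid"` these are full sibs from one cross).
#' @param ramets_per_clone libraries sampled per clone.
#' @param n_localities distinct field localities the ramets cycle through.
#' @param habit `"solitary"` or `"stoloniferous"`.
#' @param reproduce `"clonal"` (each clone an independent founder) or
#'   `"sexual_diploid"` (clones are Mendelian offspring of two diploid
#'   parents; requires `ploidy = 2`).
#' @param males_recorded logical male-sighting flag carried into metadata.
#' @param native logical.
#' @return A list of class `taxon_spec`.
#' @export
taxon_spec <- function(name, ploidy = 2L, n_clones = 1L, ramets_per_clone = 1L,
                       n_localities = 1L, habit = "solitary",
                       reproduce = c("clonal", "sexual_diploid"),
                       males_recorded = FALSE, native = TRUE) {
  reproduce <- match.arg(reproduce)
  if (!ploidy %in% 2:5) stop("ploidy must be 2, 3, 4 or 5")
  if (reproduce == "sexual_diploid" && ploidy != 2L)
    stop("sexual_diploid taxa must be diploid")
  if (!habit %in% c("solitary", "stoloniferous")) stop("unknown habit")
  structure(list(name = name, ploidy = as.integer(ploidy),
                 n_clones = as.integer(n_clones),
                 ramets_per_clone = as.integer(ramets_per_clone),
                 n_localities = as.integer(n_localities), habit = habit,
                 reproduce = reproduce, males_recorded = males_recorded,
                 native = native),
            class = "taxon_spec")
}

#' Simulation configuration
#'
#' Defaults emulate a deep ddRAD survey: 6000 SNP loci of which 30 % segregate
#' within each taxon (giving roughly 500-750 heterozygous loci per sample,
#' depending on ploidy), negative-binomially dispersed locus coverage with
#' mean 100x and dispersion 0.3 (a per-locus depth factor is shared across
#' libraries, so low-coverage loci drop out consistently, as restriction-site
#' variation does in real data), 0.1 % per-read substitution error, 1 %
#' per-library heterozygote dropout, and a duplicate-library rate of 0.15
#' (about one library in seven re-sequenced, as in the survey design).
#'
#' @param taxa list of [taxon_spec()] objects.
#' @param n_loci total SNP loci in the catalog.
#' @param segregating_frac fraction of loci polymorphic within a taxon.
#' @param allele_freq_beta Beta(a, b) prior for per-locus allele frequency.
#' @param depth_mean,depth_dispersion negative-binomial locus coverage:
#'   mean and dispersion (variance = mu + dispersion * mu^2).
#' @param seq_error_rate per-read substitution error.
#' @param genotype_error_rate per-library heterozygote-to-homozygote dropout.
#' @param duplicate_library_rate fraction of samples given a second library.
#' @param min_emit_depth loci under this total depth are emitted as missing
#'   calls (default 30, the genotype caller's depth floor).
#' @param seed mandatory RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(taxa, n_loci = 6000L, segregating_frac = 0.30,
                       allele_freq_beta = c(1, 1), depth_mean = 100,
                       depth_dispersion = 0.3, seq_error_rate = 0.001,
                       genotype_error_rate = 0.01,
                       duplicate_library_rate = 0.15, min_emit_depth = 30L,
                       seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  if (inherits(taxa, "taxon_spec")) taxa <- list(taxa)
  stopifnot(all(vapply(taxa, inherits, TRUE, "taxon_spec")))
  probs <- c(segregating_frac, seq_error_rate, genotype_error_rate,
             duplicate_library_rate)
  if (any(probs < 0 | probs > 1)) stop("rates must be in [0, 1]")
  structure(list(taxa = taxa, n_loci = as.integer(n_loci),
                 segregating_frac = segregating_frac,
                 allele_freq_beta = allele_freq_beta,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 seq_error_rate = seq_error_rate,
                 genotype_error_rate = genotype_error_rate,
                 duplicate_library_rate = duplicate_library_rate,
                 min_emit_depth = as.integer(min_emit_depth),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a founder genotype as allele dosages
#'
#' Per locus, the minor-allele frequency `q` is drawn from the Beta prior and
#' the dosage `d` (copies of allele 2 out of `ploidy`) from Binomial(p, q).
#' Loci with `d` of 0 or `p` are homozygous.
#'
#' @param ploidy integer >= 2.
#' @param n_loci number of loci.
#' @param allele_freq_beta Beta prior parameters.
#' @param q optional fixed per-locus allele frequencies (overrides the prior).
#' @return Integer dosage vector of length `n_loci`.
#' @export
simulate_founder <- function(ploidy, n_loci, allele_freq_beta = c(1, 1),
                             q = NULL) {
  if (ploidy < 2L) stop("ploidy must be >= 2")
  if (is.null(q))
    q <- stats::rbeta(n_loci, allele_freq_beta[1], allele_freq_beta[2])
  stats::rbinom(n_loci, ploidy, q)
}

#' Simulate one sequencing library from a founder genotype
#'
#' Locus coverage is negative binomial (optionally via a supplied per-locus
#' depth factor so that libraries of one data set share locus dropout);
#' allele-2 reads are binomial at the dosage fraction `d/p`, then each read
#' flips allele with the substitution-error rate. The emitted diploidized
#' call is heterozygous for any dosage strictly between 0 and `p`, subject to
#' heterozygote dropout (the call collapses to the deeper allele's
#' homozygote), and missing when total depth falls under `min_emit_depth`.
#'
#' @param dosages integer dosage vector (copies of allele 2).
#' @param ploidy integer ploidy.
#' @param cfg a [sim_config()] (depth/error fields are used).
#' @param sample_id library name used in the depth rows.
#' @param locus_ids locus names (default `L0001`...).
#' @param depth_factor optional per-locus multiplier on `depth_mean`; when
#'   `NULL`, gamma factors are drawn fresh (marginally negative-binomial
#'   depth).
#' @return A list with `depth` (data.frame rows: sample_id, locus_id, allele,
#'   count; zero-count alleles omitted), `a1`, `a2` (the diploidized call,
#'   `NA` = missing) and `total_depth`.
#' @export
simulate_library <- function(dosages, ploidy, cfg, sample_id = "S1",
                             locus_ids = NULL, depth_factor = NULL) {
  n <- length(dosages)
  if (is.null(locus_ids)) locus_ids <- sprintf("L%04d", seq_len(n))
  if (is.null(depth_factor)) {
    depth_factor <- if (cfg$depth_dispersion > 0)
      stats::rgamma(n, shape = 1 / cfg$depth_dispersion,
                    scale = cfg$depth_dispersion)
    else rep(1, n)
  }
  total <- stats::rpois(n, cfg$depth_mean * depth_factor)
  a2_true <- stats::rbinom(n, total, dosages / ploidy)
  e <- cfg$seq_error_rate
  a2 <- stats::rbinom(n, a2_true, 1 - e) + stats::rbinom(n, total - a2_true, e)
  a1_cnt <- total - a2

  call1 <- ifelse(dosages == 0L, 1L, ifelse(dosages == ploidy, 2L, 1L))
  call2 <- ifelse(dosages == 0L, 1L, ifelse(dosages == ploidy, 2L, 2L))
  het <- dosages > 0L & dosages < ploidy
  drop <- het & stats::runif(n) < cfg$genotype_error_rate
  if (any(drop)) {
    keep2 <- a2[drop] >= a1_cnt[drop]   # dropout keeps the deeper allele
    call1[drop] <- ifelse(keep2, 2L, 1L)
    call2[drop] <- call1[drop]
  }
  miss <- total < cfg$min_emit_depth
  call1[miss] <- NA_integer_
  call2[miss] <- NA_integer_

  keep1 <- a1_cnt > 0L
  keep2r <- a2 > 0L
  depth <- data.frame(
    sample_id = sample_id,
    locus_id = c(locus_ids[keep1], locus_ids[keep2r]),
    allele = c(rep("1", sum(keep1)), rep("2", sum(keep2r))),
    count = c(a1_cnt[keep1], a2[keep2r]),
    stringsAsFactors = FALSE)
  list(depth = depth, a1 = call1, a2 = call2, total_depth = total)
}

#' Simulate a sexual full-sib family from two diploid parents
#'
#' Offspring dosages are the union of one Mendelian gamete per parent per
#' locus (selfing excluded by construction: gametes come from the two
#' distinct founders).
#'
#' @param parent1,parent2 diploid dosage vectors (values 0, 1, 2).
#' @param n_offspring number of sibs.
#' @return A list of integer dosage vectors, one per offspring.
#' @export
simulate_sexual_family <- function(parent1, parent2, n_offspring) {
  stopifnot(length(parent1) == length(parent2),
            all(parent1 %in% 0:2), all(parent2 %in% 0:2))
  n <- length(parent1)
  lapply(seq_len(n_offspring), function(i) {
    stats::rbinom(n, 1L, parent1 / 2) + stats::rbinom(n, 1L, parent2 / 2)
  })
}

#' Simulate a complete survey data set with ground truth
#'
#' Builds per-taxon genotypes (a homozygous taxon backbone plus loci
#' segregating within the taxon), clones and ramets, duplicate libraries
#' (same biological genotype, independent depth and error draws), the pooled
#' depth table, the diploidized genotype matrix, sample metadata and a truth
#' set.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_dataset` with `depth` (depth table),
#'   `genotypes` ([genotype_matrix()]), `metadata`, `truth` (list with
#'   `clones` data.frame mapping sample to true clone and ploidy, and
#'   `founder_dosages`) and `config`.
#' @export
simulate_dataset <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_loci
  locus_ids <- sprintf("L%05d", seq_len(n))
  depth_factor <- if (cfg$depth_dispersion > 0)
    stats::rgamma(n, shape = 1 / cfg$depth_dispersion,
                  scale = cfg$depth_dispersion)
  else rep(1, n)
  q_global <- stats::rbeta(n, cfg$allele_freq_beta[1], cfg$allele_freq_beta[2])

  libs <- list()
  meta <- list()
  truth <- list()
  founders <- list()
  for (tx in cfg$taxa) {
    seg <- stats::runif(n) < cfg$segregating_frac
    # homozygous taxon backbone at non-segregating loci
    backbone <- ifelse(stats::runif(n) < q_global, tx$ploidy, 0L)
    clone_dosages <- if (tx$reproduce == "sexual_diploid") {
      make_parent <- function() {
        d <- simulate_founder(2L, n, q = q_global)
        ifelse(seg, d, backbone)
      }
      simulate_sexual_family(make_parent(), make_parent(), tx$n_clones)
    } else {
      lapply(seq_len(tx$n_clones), function(c) {
        d <- simulate_founder(tx$ploidy, n, q = q_global)
        as.integer(ifelse(seg, d, backbone))
      })
    }
    for (ci in seq_len(tx$n_clones)) {
      clone_label <- sprintf("%s_clone%02d", tx$name, ci)
      founders[[clone_label]] <- clone_dosages[[ci]]
      for (ri in seq_len(tx$ramets_per_clone)) {
        sid <- sprintf("%s_c%02d_r%02d", tx$name, ci, ri)
        loc <- sprintf("%s_loc%02d",
                       tx$name,
                       ((ci - 1L) * tx$ramets_per_clone + ri - 1L) %%
                         tx$n_localities + 1L)
        lib <- simulate_library(clone_dosages[[ci]], tx$ploidy, cfg,
                                sample_id = sid, locus_ids = locus_ids,
                                depth_factor = depth_factor)
        libs[[sid]] <- lib
        meta[[sid]] <- data.frame(
          sample_id = sid, taxon_label = tx$name, locality_id = loc,
          duplicate_group = NA_character_, habit = tx$habit,
          native = tx$native, males_recorded = tx$males_recorded,
          stringsAsFactors = FALSE)
        truth[[sid]] <- data.frame(sample_id = sid, clone_id = clone_label,
                                   ploidy = tx$ploidy,
                                   taxon_label = tx$name,
                                   stringsAsFactors = FALSE)
      }
    }
  }

  # duplicate libraries: an independent re-sequencing of the same genotype
  ids <- names(libs)
  n_dup <- round(cfg$duplicate_library_rate * length(ids))
  dup_of <- if (n_dup > 0) sample(ids, n_dup) else character(0)
  for (sid in dup_of) {
    tr <- truth[[sid]]
    tx <- Filter(function(t) t$name == tr$taxon_label, cfg$taxa)[[1L]]
    did <- paste0(sid, "_dup")
    lib <- simulate_library(founders[[tr$clone_id]], tx$ploidy, cfg,
                            sample_id = did, locus_ids = locus_ids,
                            depth_factor = depth_factor)
    libs[[did]] <- lib
    md <- meta[[sid]]
    meta[[sid]]$duplicate_group <- sid
    md$sample_id <- did
    md$duplicate_group <- sid
    meta[[did]] <- md
    truth[[did]] <- data.frame(sample_id = did, clone_id = tr$clone_id,
                               ploidy = tr$ploidy,
                               taxon_label = tr$taxon_label,
                               stringsAsFactors = FALSE)
  }

  ids <- names(libs)
  a1 <- do.call(rbind, lapply(libs, `[[`, "a1"))
  a2 <- do.call(rbind, lapply(libs, `[[`, "a2"))
  rownames(a1) <- rownames(a2) <- ids
  colnames(a1) <- colnames(a2) <- locus_ids
  depth <- do.call(rbind, lapply(libs, `[[`, "depth"))
  rownames(depth) <- NULL
  metadata <- do.call(rbind, meta[ids])
  rownames(metadata) <- NULL
  truth_df <- do.call(rbind, truth[ids])
  rownames(truth_df) <- NULL
  structure(list(depth = depth,
                 genotypes = genotype_matrix(a1, a2),
                 metadata = metadata,
                 truth = list(clones = truth_df, founder_dosages = founders),
                 config = cfg),
            class = "sim_dataset")
}

#' Write a simulated data set to disk
#'
#' Emits `genotypes.gen` (genepop), `depth.tsv`, `metadata.csv` and
#' `truth.json` under `dir`.
#'
#' @param ds a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genepop(ds$genotypes, file.path(dir, "genotypes.gen"),
                title = "simulated survey")
  write_depth_table(ds$depth, file.path(dir, "depth.tsv"))
  utils::write.csv(ds$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(ds$truth$clones, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Simulate a depth table of heterozygous loci at fixed ploidy
#'
#' Convenience generator for allele-balance spectra: `n_loci` heterozygous
#' loci at the given ploidy and minor-allele dosage(s), negative-binomial
#' total depth and binomial allelic sampling.
#'
#' @param n_loci number of loci.
#' @param ploidy integer ploidy.
#' @param dosage minor-allele dosage per locus: a scalar, a vector recycled
#'   over loci, or `NULL` to draw uniformly from `1..(ploidy - 1)`.
#' @param depth_mean,depth_dispersion negative-binomial coverage parameters.
#' @param seq_error_rate per-read substitution error.
#' @param sample_id sample name in the emitted rows.
#' @return A depth table `data.frame`.
#' @export
simulate_ploidy_depths <- function(n_loci, ploidy, dosage = NULL,
                                   depth_mean = 100, depth_dispersion = 0.3,
                                   seq_error_rate = 0, sample_id = "S1") {
  dos <- if (is.null(dosage))
    sample(seq_len(ploidy - 1L), n_loci, replace = TRUE)
  else rep_len(as.integer(dosage), n_loci)
  if (any(dos < 1L) || any(dos >= ploidy))
    stop("dosage must be in 1..(ploidy - 1)")
  cfg0 <- list(depth_mean = depth_mean, depth_dispersion = depth_dispersion,
               seq_error_rate = seq_error_rate, genotype_error_rate = 0,
               min_emit_depth = 0L)
  lib <- simulate_library(dos, ploidy, cfg0, sample_id = sample_id)
  validate_depth_table(lib$depth)
}
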