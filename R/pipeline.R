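#' Pipeline configuration
#'
#' Collects every threshold used across the pipeline, with defaults at the
#' study's stated values: MAF filter 0.05; informative-subset window on
#' marker informativeness; 99% neutral envelope; Fst cut-offs 0.20
#' (envelope and hierarchical scans) and 0.15 (Bayesian scan); Bayesian run
#' lengths of 20 x 50,000 pilot iterations then 100,000 iterations with
#' 5,000 retained samples at thinning 10; 10,000 AMOVA permutations;
#' 100,000 simulated loci for the hierarchical null; block building with
#' `r2_min = 0.7`, `max_gap_cM = 5`; FDR 5%; reversal margin 0.10.
#'
#' `profile = "ci"` shrinks the stochastic workloads (10,000 simulated
#' loci, 1,000 permutations, pilot runs 10 x 500 and 20,000 main
#' iterations with 2,000 retained samples) so an end-to-end run completes
#' in minutes; every threshold keeps its default value.
#'
#' @param profile `"paper"` or `"ci"`.
#' @param maf MAF filter threshold.
#' @param pic_lo,pic_hi informative-subset window.
#' @param pic_measure `"pic"` or `"he"`.
#' @param envelope_quantile neutral-envelope quantile.
#' @param fst_cutoff_envelope Fst cut-off for the envelope/hierarchical
#'   scans.
#' @param fst_cutoff_bayes Fst cut-off for the Bayesian scan.
#' @param n_sim_fdist,n_sim_hier simulated neutral loci per scan.
#' @param bayes a [bayes_config()]; `NULL` builds one from the profile.
#' @param r2_min,max_gap_cM haplotype-block building parameters.
#' @param fdr association FDR level.
#' @param reversal_margin temporal reversal margin.
#' @param n_perm AMOVA permutations.
#' @param min_cohort_n minimum cohort size for diversity/trajectories.
#' @param impute_strategy,impute_k imputation settings.
#' @param K_range candidate cluster counts for DAPC.
#' @param stages named logical list toggling `prep`, `popstruct`,
#'   `selscan`, `hapassoc`, `temporal`.
#' @param selected_markers marker ids to use when `selscan` is disabled.
#' @param seed global seed; every stage derives its own stream from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(profile = c("paper", "ci"), maf = 0.05,
                            pic_lo = 0.30, pic_hi = 0.375,
                            pic_measure = "pic", envelope_quantile = 0.99,
                            fst_cutoff_envelope = 0.20, fst_cutoff_bayes = 0.15,
                            n_sim_fdist = NULL, n_sim_hier = NULL, bayes = NULL,
                            r2_min = 0.7, max_gap_cM = 5, fdr = 0.05,
                            reversal_margin = 0.10, n_perm = NULL,
                            min_cohort_n = 10, impute_strategy = "knn",
                            impute_k = 10, K_range = 1:8, stages = list(),
                            selected_markers = NULL, seed = 1) {
  profile <- match.arg(profile)
  ci <- profile == "ci"
  if (is.null(n_sim_fdist)) n_sim_fdist <- if (ci) 10000 else 50000
  if (is.null(n_sim_hier)) n_sim_hier <- if (ci) 10000 else 100000
  if (is.null(n_perm)) n_perm <- if (ci) 1000 else 10000
  if (is.null(bayes)) {
    bayes <- if (ci) {
      bayes_config(n_pilot = 10, pilot_len = 500, n_iter = 20000,
                   sample_size = 2000, thinning = 10,
                   fst_cutoff = fst_cutoff_bayes, seed = derive_seed(seed, 43))
    } else {
      bayes_config(fst_cutoff = fst_cutoff_bayes, seed = derive_seed(seed, 43))
    }
  }
  st <- list(prep = TRUE, popstruct = TRUE, selscan = TRUE, hapassoc = TRUE,
             temporal = TRUE)
  st[names(stages)] <- stages
  cfg <- list(profile = profile, maf = maf, pic_lo = pic_lo, pic_hi = pic_hi,
              pic_measure = pic_measure, envelope_quantile = envelope_quantile,
              fst_cutoff_envelope = fst_cutoff_envelope,
              fst_cutoff_bayes = fst_cutoff_bayes, n_sim_fdist = n_sim_fdist,
              n_sim_hier = n_sim_hier, bayes = bayes, r2_min = r2_min,
              max_gap_cM = max_gap_cM, fdr = fdr,
              reversal_margin = reversal_margin, n_perm = n_perm,
              min_cohort_n = min_cohort_n, impute_strategy = impute_strategy,
              impute_k = impute_k, K_range = K_range, stages = st,
              selected_markers = selected_markers, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error (exit early rather than silently ignore a typo).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes prep, population structure, the three-method selection scan,
#' haplotype-locus association, and temporal trajectory analysis in order,
#' logging input/output record counts per stage. All randomness descends
#' from `config$seed` via per-stage derived seeds, so a rerun with the same
#' config and inputs is bit-identical. If `out_dir` is given, result TSVs,
#' a JSON report and a markdown report are written there.
#'
#' @param panel a `geno_panel` (or path to a matrix TSV).
#' @param map marker map tibble (or path).
#' @param config a [pipeline_config()].
#' @param traits optional trait tibble (or path); required for the
#'   association stage.
#' @param cohorts optional cohort tibble (or path); required for the
#'   temporal stage.
#' @param out_dir optional output directory.
#' @return A `bs_pipeline` list: per-stage results plus `report` (named
#'   list of counts and settings).
#' @export
run_pipeline <- function(panel, map, config = pipeline_config(),
                         traits = NULL, cohorts = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(panel)) panel <- read_genotypes(panel)
  if (is.character(map)) map <- read_map(map)
  if (is.character(traits)) traits <- read_traits(traits)
  if (is.character(cohorts)) cohorts <- read_cohorts(cohorts)
  seed <- config$seed
  report <- list(config = config[setdiff(names(config), "bayes")],
                 counts = list(), lambda_gc = list())
  res <- list()
  report$counts$markers_input <- length(marker_ids(panel))
  report$counts$lines_input <- nrow(panel)

  # ---- prep ----
  if (config$stages$prep) {
    panel_qc <- remove_duplicates(panel, map)
    report$counts$markers_after_dedup <- length(marker_ids(panel_qc))
    panel_qc <- impute_missing(panel_qc, strategy = config$impute_strategy,
                               k = config$impute_k, seed = derive_seed(seed, 11))
    panel_qc <- maf_filter(panel_qc, config$maf)
    report$counts$markers_after_maf <- length(marker_ids(panel_qc))
    info <- pic_subset(panel_qc, config$pic_lo, config$pic_hi,
                       measure = config$pic_measure)
    panel_info <- info$panel
    res$marker_stats <- info$stats
    report$counts$markers_informative <- length(marker_ids(panel_info))
  } else {
    panel_qc <- panel_info <- panel
  }
  res$panel_qc <- panel_qc
  res$panel_info <- panel_info

  # ---- population structure ----
  if (config$stages$popstruct) {
    res$structure <- dapc_cluster(panel_info, K_range = config$K_range,
                                  seed = derive_seed(seed, 21))
    assignment <- res$structure$assignment
    if (res$structure$K >= 2) {
      res$fst <- pairwise_fst(panel_info, assignment)
      res$amova <- amova(panel_info, assignment, n_perm = config$n_perm,
                         seed = derive_seed(seed, 22))
    }
    if (!is.null(cohorts)) {
      res$diversity <- diversity_by_cohort(panel_info, cohorts,
                                           min_n = config$min_cohort_n,
                                           seed = derive_seed(seed, 23))
    }
    report$counts$K <- res$structure$K
  } else {
    assignment <- NULL
  }

  # ---- selection scan ----
  if (config$stages$selscan) {
    if (is.null(assignment)) stop("selscan stage requires the popstruct stage")
    if (res$structure$K < 2) stop("selscan needs K >= 2 subpopulations")
    res$fdist <- fdist_scan(panel_info, assignment,
                            n_sim_loci = config$n_sim_fdist,
                            quantile = config$envelope_quantile,
                            fst_cutoff = config$fst_cutoff_envelope,
                            seed = derive_seed(seed, 31))
    res$hier <- tryCatch(
      hier_scan(panel_info, assignment, n_sim = config$n_sim_hier,
                quantile = config$envelope_quantile,
                fst_cutoff = config$fst_cutoff_envelope,
                seed = derive_seed(seed, 32)),
      error = function(e) {
        message("hierarchical scan skipped: ", conditionMessage(e))
        NULL
      }
    )
    bc <- config$bayes
    res$bayes <- bayes_scan(panel_info, assignment, bc)
    scans <- list(fdist = res$fdist, bayes = res$bayes)
    if (!is.null(res$hier)) scans$hier <- res$hier
    res$consensus <- consensus_outliers(scans)
    selected <- res$consensus$marker_id
    report$counts$outliers <- length(selected)
    report$venn <- attr(res$consensus, "venn")
  } else {
    if (is.null(config$selected_markers)) {
      stop("selscan disabled: supply selected_markers in the config")
    }
    selected <- config$selected_markers
    report$counts$outliers <- length(selected)
  }
  res$selected_markers <- selected

  # ---- haplotype loci & association ----
  if (config$stages$hapassoc && length(selected) > 0) {
    loci <- build_haplotype_loci(selected, panel_qc, map,
                                 r2_min = config$r2_min,
                                 max_gap_cM = config$max_gap_cM)
    loci <- call_haplotypes(loci, panel_qc)
    res$loci <- loci
    report$counts$haplotype_loci <- nrow(loci)
    if (!is.null(traits)) {
      K <- kinship_matrix(panel_qc)
      res$kinship <- K
      res$assoc <- mlm_scan(loci, traits, K, fdr_level = config$fdr)
      sig <- dplyr::filter(res$assoc, .data$significant)
      report$counts$associated_locus_trait_pairs <- nrow(sig)
      report$counts$associated_loci <- length(unique(sig$locus_id))
      report$lambda_gc <- as.list(stats::setNames(
        unique(res$assoc[c("trait", "lambda_gc")])$lambda_gc,
        unique(res$assoc[c("trait", "lambda_gc")])$trait
      ))
    }
  }

  # ---- temporal trajectories ----
  if (config$stages$temporal && !is.null(cohorts) && length(selected) > 0) {
    traj <- cohort_frequencies(panel_qc, cohorts,
                               markers = intersect(selected, marker_ids(panel_qc)),
                               min_n = config$min_cohort_n)
    res$trajectories <- traj
    res$reversals <- detect_reversal(traj, margin = config$reversal_margin)
    report$counts$reversals <- sum(res$reversals$reversal, na.rm = TRUE)
    report$counts$fixed <- sum(
      res$reversals$fixed & res$reversals$reversal, na.rm = TRUE
    )
    if (!is.null(res$loci)) {
      res$locus_reversal <- haplotype_reversal_summary(res$loci, res$reversals)
    }
  }

  res$report <- report
  class(res) <- "bs_pipeline"
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir, config)
  res
}

write_pipeline_outputs <- function(res, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  settings <- list(seed = config$seed, profile = config$profile,
                   fdr = config$fdr, maf = config$maf,
                   envelope_quantile = config$envelope_quantile,
                   fst_cutoffs = c(config$fst_cutoff_envelope,
                                   config$fst_cutoff_bayes))
  if (!is.null(res$marker_stats)) {
    write_results(res$marker_stats, file.path(out_dir, "marker_stats.tsv"), settings)
  }
  if (!is.null(res$fdist)) {
    write_results(res$fdist, file.path(out_dir, "scan_fdist.tsv"), settings)
  }
  if (!is.null(res$hier)) {
    write_results(res$hier, file.path(out_dir, "scan_hier.tsv"), settings)
  }
  if (!is.null(res$bayes)) {
    write_results(res$bayes, file.path(out_dir, "scan_bayes.tsv"), settings)
  }
  if (!is.null(res$consensus)) {
    write_results(res$consensus, file.path(out_dir, "outliers_consensus.tsv"),
                  settings)
  }
  if (!is.null(res$loci)) {
    flat <- dplyr::mutate(
      dplyr::select(res$loci, -dplyr::any_of(c("calls", "allele_freq"))),
      members = purrr::map_chr(.data$members, paste, collapse = ",")
    )
    write_results(flat, file.path(out_dir, "haplotype_loci.tsv"), settings)
  }
  if (!is.null(res$assoc)) {
    write_results(dplyr::select(res$assoc, -"effects"),
                  file.path(out_dir, "association.tsv"), settings)
    write_results(allelic_effects_table(res$assoc),
                  file.path(out_dir, "allelic_effects.tsv"), settings)
  }
  if (!is.null(res$reversals)) {
    write_results(res$reversals, file.path(out_dir, "reversals.tsv"), settings)
  }
  if (!is.null(res$diversity)) {
    write_results(res$diversity, file.path(out_dir, "diversity.tsv"), settings)
  }
  jsonlite::write_json(res$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  md <- c(
    "# Pipeline report", "",
    sprintf("- profile: %s, seed: %d", config$profile, config$seed),
    sprintf("- %s: %s", names(res$report$counts),
            unlist(res$report$counts))
  )
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' @export
print.bs_pipeline <- function(x, ...) {
  cat("<bs_pipeline>\n")
  for (nm in names(x$report$counts)) {
    cat(sprintf("  %s: %s\n", nm, x$report$counts[[nm]]))
  }
  invisible(x)
}
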