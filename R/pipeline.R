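#' Configure a full pipeline run
#'
#' Collects every knob of the end-to-end analysis in one validated list.
#' Exactly one of `manifest` (path to a cohort manifest on disk) or
#' `spec` (a [cohort_spec()] to simulate) must be given.
#'
#' @param spec a [cohort_spec()] to simulate, or `NULL`.
#' @param manifest path to a manifest TSV, or `NULL`.
#' @param fd_threshold_mm FD threshold defining a corrupted frame
#'   (default 0.2 mm).
#' @param cap_percent motion cap for the reliability subset (default 20).
#' @param sweep_caps cap grid for the motion sweep
#'   (default `seq(10, 40, 0.5)`).
#' @param zscore,path_weighted,weighted_synchrony feature/synchrony flags.
#' @param threshold_method,threshold_level synchrony thresholding rule
#'   (default BH-FDR at q = 0.05).
#' @param seed integer seed governing simulation (and any downstream
#'   randomness; the analysis stages are deterministic).
#' @return an object of class `vg_run_config`.
#' @export
run_config <- function(spec = NULL, manifest = NULL,
                       fd_threshold_mm = 0.2, cap_percent = 20,
                       sweep_caps = seq(10, 40, by = 0.5),
                       zscore = TRUE, path_weighted = FALSE,
                       weighted_synchrony = FALSE,
                       threshold_method = "fdr", threshold_level = 0.05,
                       seed = 1L) {
  if (is.null(spec) == is.null(manifest)) {
    abort("give exactly one of 'spec' or 'manifest'",
          class = "vgfc_error_validation")
  }
  check_scalar(fd_threshold_mm, "fd_threshold_mm", lower = 0,
               strict_lower = TRUE)
  check_scalar(cap_percent, "cap_percent", lower = 0, strict_lower = TRUE,
               upper = 100)
  if (length(sweep_caps) < 1 || any(sweep_caps <= 0 | sweep_caps > 100)) {
    abort("invalid field 'sweep_caps': bounds must lie in (0, 100]",
          class = "vgfc_error_validation")
  }
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(spec = spec, manifest = manifest,
                 fd_threshold_mm = fd_threshold_mm,
                 cap_percent = cap_percent, sweep_caps = sweep_caps,
                 zscore = zscore, path_weighted = path_weighted,
                 weighted_synchrony = weighted_synchrony,
                 threshold_method = threshold_method,
                 threshold_level = threshold_level,
                 seed = as.integer(seed)),
        class = "vg_run_config")
}

config_hash <- function(config) {
  rlang::hash(lapply(unclass(config), unclass))
}

write_stage_table <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(paste0("# config_hash: ", hash), con)
  close(con)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the whole analysis pipeline
#'
#' Executes, in order: cohort simulation (or manifest ingest) →
#' motion summaries → per-region visibility-graph feature tables for both
#' sessions → degree-synchrony matrices per scan and group means per
#' session → motion-impact correlation and cap sweep → test-retest
#' reliability report. Every table is written as TSV with a leading
#' `# config_hash:` comment; a `run_manifest.json` records the config,
#' seed, package version and per-stage row counts. Rerunning with the same
#' config (and seed) reproduces every output byte-for-byte.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created; reused if existing).
#' @return the output directory path, invisibly. Side effects: files
#'   `motion.tsv`, `features_ses1.tsv`, `features_ses2.tsv`,
#'   `synchrony_mean_ses1.tsv`, `synchrony_mean_ses2.tsv`,
#'   `synchrony_edges_ses1.tsv`, `synchrony_edges_ses2.tsv`,
#'   `motion_impact.tsv`, `motion_sweep.tsv`, `reliability.tsv`,
#'   `run_manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "vg_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "vgfc_error_pipeline")
    })
  }

  cohort <- stage("input", {
    if (!is.null(config$spec)) {
      spec <- config$spec
      spec$seed <- config$seed
      generate_cohort(spec)
    } else {
      manifest_to_cohort(read_manifest(config$manifest))
    }
  })

  motion <- stage("motion", cohort_motion(cohort, config$fd_threshold_mm))
  feats <- stage("features",
                 cohort_features(cohort, zscore = config$zscore,
                                 path_weighted = config$path_weighted))

  syn_means <- stage("synchrony", {
    lapply(1:2, function(ses) {
      # group maps come from the low-motion subset, like the study's maps
      ms <- filter(motion, .data$session == ses)
      keep <- ms$subject[ms$pct_corrupted < config$cap_percent]
      if (length(keep) < 3) keep <- ms$subject
      mats <- lapply(keep, function(s)
        synchrony_matrix(cohort$series[[s]][[ses]],
                         weighted = config$weighted_synchrony))
      gm <- group_mean_synchrony(mats, pvalues = "t")
      threshold_synchrony(gm, method = config$threshold_method,
                          level = config$threshold_level)
    })
  })

  impact <- stage("motion-impact", {
    f1 <- filter(feats, .data$session == 1)
    m1 <- filter(motion, .data$session == 1)
    per_region <- motion_feature_correlation(f1, m1)
    sweep <- motion_sweep(f1, m1, caps = config$sweep_caps)
    list(per_region = per_region, sweep = sweep)
  })

  reliability <- stage("reliability",
    reliability_report(filter(feats, .data$session == 1),
                       filter(feats, .data$session == 2),
                       motion_pct = motion,
                       cap_percent = config$cap_percent))

  stage("write", {
    write_stage_table(motion, file.path(out_dir, "motion.tsv"), hash)
    for (ses in 1:2) {
      write_stage_table(filter(feats, .data$session == ses),
                        file.path(out_dir, sprintf("features_ses%d.tsv", ses)),
                        hash)
      gm <- syn_means[[ses]]
      df <- as_tibble(gm$r, .name_repair = "minimal")
      names(df) <- gm$region_labels
      write_stage_table(mutate(df, region = gm$region_labels, .before = 1),
                        file.path(out_dir,
                                  sprintf("synchrony_mean_ses%d.tsv", ses)),
                        hash)
      write_stage_table(tidy(gm),
                        file.path(out_dir,
                                  sprintf("synchrony_edges_ses%d.tsv", ses)),
                        hash)
    }
    write_stage_table(impact$per_region,
                      file.path(out_dir, "motion_impact.tsv"), hash)
    write_stage_table(as_tibble(impact$sweep),
                      file.path(out_dir, "motion_sweep.tsv"), hash)
    write_stage_table(reliability, file.path(out_dir, "reliability.tsv"),
                      hash)
    manifest <- list(
      package = "vgfc",
      version = as.character(utils::packageVersion("vgfc")),
      config = lapply(unclass(config), function(v)
        if (inherits(v, "cohort_spec")) unclass(v) else v),
      config_hash = hash,
      seed = config$seed,
      rows = list(motion = nrow(motion), features = nrow(feats),
                  motion_impact = nrow(impact$per_region),
                  motion_sweep = nrow(impact$sweep),
                  reliability = nrow(reliability)))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  invisible(out_dir)
}

# Load an on-disk cohort (manifest rows) into the in-memory vg_cohort shape.
manifest_to_cohort <- function(manifest) {
  subjects <- sort(unique(manifest$subject_id))
  series <- list(); motion <- list()
  for (s in subjects) {
    series[[s]] <- list(); motion[[s]] <- list()
    for (ses in 1:2) {
      row <- filter(manifest, .data$subject_id == s, .data$session == ses)
      if (nrow(row) != 1) {
        abort(sprintf("manifest must have exactly one row for subject %d session %d",
                      s, ses), class = "vgfc_error_validation")
      }
      series[[s]][[ses]] <- read_timeseries(row$series_path)
      motion[[s]][[ses]] <- read_fd(row$motion_path)
    }
  }
  first <- series[[subjects[1]]][[1]]
  spec <- cohort_spec(n_subjects = length(subjects),
                      n_regions = ncol(first), n_frames = nrow(first))
  structure(list(spec = spec, series = series, motion = motion,
                 truth = NULL,
                 communities = tibble(region = colnames(first),
                                      community = NA_integer_)),
            class = "vg_cohort")
}

#' Read a pipeline output table
#'
#' Reads any TSV written by [run_pipeline()], skipping the config-hash
#' comment line.
#'
#' @param path file path.
#' @return a tibble.
#' @export
read_stage_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
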