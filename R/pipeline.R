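## End-to-end orchestration: synthetic study (or CSV study) -> preprocessing
## with exclusion logic -> IBS feature table + permuted-dyad levels ->
## behavioral features -> mixed-model reports, with a run record capturing
## configuration, seeds, exclusions and output hashes.

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults matching the study protocol (band [0.01, 0.08] Hz, split at
#' 600 s, 7.81 / 10 Hz sampling, RQA lmin 40 / Theiler 1 / m 1) and rejects
#' unknown keys or contradictory settings.
#'
#' @param config named list of overrides, or the path of a YAML file holding
#'   them.
#' @return normalized configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) config_error(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
    for (nm in c("band", "features"))
      if (!is.null(config[[nm]])) config[[nm]] <- unlist(config[[nm]])
  }
  defaults <- list(
    band = c(0.01, 0.08),
    split_time = 600,
    task_duration = 1200,
    fs_nirs = 7.81,
    fs_behavior = 10,
    chromophore = "o2hb",
    rqa_lmin = 40L,
    rqa_theiler = 1L,
    rqa_m = 1L,
    rqa_target_rr = 0.10,
    pca_variance_fraction = 0.80,
    pca_mode = "remove",
    permuted_per_guide = NULL,   # NULL = all non-interacting combinations
    features = c("level", "slope", "pct_det"),
    reml = FALSE
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    config_error(sprintf("unknown configuration key(s): %s (accepted: %s)",
                         paste(unknown, collapse = ", "),
                         paste(names(defaults), collapse = ", ")))
  cfg <- utils::modifyList(defaults, config)
  if (length(cfg$band) != 2L || cfg$band[1] <= 0 || cfg$band[1] >= cfg$band[2])
    config_error("band must be an increasing positive interval [f_lo, f_hi]")
  if (cfg$split_time <= 0 || cfg$split_time >= cfg$task_duration)
    config_error("split_time must lie strictly inside the task duration")
  if (cfg$fs_nirs <= 2 * cfg$band[2])
    config_error("fs_nirs must exceed twice the band upper edge")
  if (!cfg$chromophore %in% c("o2hb", "hhb"))
    config_error("chromophore must be 'o2hb' or 'hhb'")
  if (!all(cfg$features %in% c("level", "slope", "pct_det")))
    config_error("features must be a subset of level, slope, pct_det")
  cfg
}

#' Run the full analysis pipeline on a study
#'
#' Preprocesses every participant, applies the exclusion logic (bad channels
#' -> discarded ROIs -> excluded participants -> excluded dyads), computes
#' the IBS feature table and the permuted-dyad pre-period levels, the
#' behavioral features, and the complete inferential program (control
#' analyses, Time x Group disruption tests, moderation models).
#'
#' @param study `ibs_study` from [simulate_study()] (or [read_study()]).
#' @param config configuration list, see [validate_config()].
#' @param out_dir optional directory; when given, the feature and behavior
#'   tables are written as CSV, the statistical results as JSON, and the run
#'   record includes their md5 hashes.
#' @param preproc optional `preprocess_params`.
#' @return list: features, permuted_levels, behavior, difficulty,
#'   exclusions, stats (control/hypothesis/moderation reports), run_record.
#' @export
run_pipeline <- function(study, config = list(), out_dir = NULL,
                         preproc = preprocess_params()) {
  cfg <- validate_config(config)
  warn <- character(0)

  ## --- preprocessing + exclusion logic -------------------------------------
  prep <- list(); excl <- list()
  for (d in study$dyads) {
    rec <- d$recording
    if (is.null(rec$guide)) data_error("study has no channel-level recordings")
    pg <- preprocess_participant(rec$guide, preproc)
    pd <- preprocess_participant(rec$drawer, preproc)
    excl[[rec$dyad_id]] <- data.frame(
      dyad_id = rec$dyad_id,
      role = c("guide", "drawer"),
      n_bad_channels = c(sum(pg$quality$verdict == "bad"),
                         sum(pd$quality$verdict == "bad")),
      n_missing_rois = c(pg$roi$n_missing, pd$roi$n_missing),
      excluded = c(pg$roi$excluded, pd$roi$excluded))
    if (pg$roi$excluded || pd$roi$excluded) {
      warn <- c(warn, sprintf("%s excluded: participant with >1 missing ROI", rec$dyad_id))
      next
    }
    prep[[rec$dyad_id]] <- list(dyad_id = rec$dyad_id, group = rec$group,
                                guide = pg$roi, drawer = pd$roi,
                                markers = rec$markers)
  }
  exclusions <- do.call(rbind, excl)
  rownames(exclusions) <- NULL
  if (length(prep) < 2L) data_error("fewer than 2 dyads retained after exclusion")

  ## --- IBS features --------------------------------------------------------
  features <- feature_table(prep, band = cfg$band, chromophore = cfg$chromophore,
                            features = cfg$features,
                            rqa = rqa_params(cfg$rqa_m, cfg$rqa_target_rr,
                                             cfg$rqa_lmin, cfg$rqa_theiler))

  ## --- permuted-dyad pre-period levels -------------------------------------
  slot <- cfg$chromophore
  mk <- prep[[1]]$markers
  series <- list()
  for (p in prep) {
    ok <- intersect(names(which(p$guide$status == "ok")),
                    names(which(p$drawer$status == "ok")))
    series[[paste0(p$dyad_id, "_guide")]] <- p$guide[[slot]][ok, , drop = FALSE]
    series[[paste0(p$dyad_id, "_drawer")]] <- p$drawer[[slot]][ok, , drop = FALSE]
  }
  cohort <- data.frame(dyad_id = names(prep),
                       guide_id = paste0(names(prep), "_guide"),
                       drawer_id = paste0(names(prep), "_drawer"),
                       stringsAsFactors = FALSE)
  permuted <- build_permuted_dyads(cohort)
  if (!is.null(cfg$permuted_per_guide)) {
    keep <- unlist(lapply(split(seq_len(nrow(permuted)), permuted$guide_dyad),
                          function(ix) utils::head(ix, cfg$permuted_per_guide)))
    permuted <- permuted[sort(keep), , drop = FALSE]
  }
  pairs <- rbind(data.frame(kind = "real", guide_id = cohort$guide_id,
                            drawer_id = cohort$drawer_id,
                            guide_dyad = cohort$dyad_id,
                            drawer_dyad = cohort$dyad_id,
                            stringsAsFactors = FALSE),
                 permuted)
  pre_window <- c(mk$task_start, mk$disruption)
  permuted_levels <- batch_ibs_levels(series, pairs, cfg$fs_nirs, cfg$band,
                                      window = pre_window,
                                      periods = list(pre = pre_window))

  ## --- behavioral features -------------------------------------------------
  retained <- names(prep)
  beh <- behavior_table(study)
  beh <- beh[beh$dyad_id %in% retained, ]
  diff_tab <- difficulty_table(study)
  diff_tab <- diff_tab[diff_tab$dyad_id %in% retained, ]

  ## --- statistics ----------------------------------------------------------
  lvl_pre <- permuted_levels[permuted_levels$period == "pre",
                             c("kind", "guide_dyad", "roi", "level")]
  soft <- function(expr, stage) tryCatch(expr, nirsync_error = function(e) {
    warn <<- c(warn, sprintf("%s skipped: %s", stage, conditionMessage(e)))
    NULL
  })
  control <- soft(run_control_analyses(lvl_pre, beh, diff_tab, reml = cfg$reml),
                  "control analyses")
  hypothesis <- if ("level" %in% cfg$features && length(unique(features$period)) > 1L)
    soft(run_ibs_hypothesis_tests(features, reml = cfg$reml), "hypothesis tests") else NULL
  deltas <- do.call(rbind, lapply(split(beh, beh$dyad_id), function(b) {
    data.frame(dyad_id = b$dyad_id[1],
               delta = b$speech_ratio[b$period == "post"] -
                 b$speech_ratio[b$period == "pre"])
  }))
  deltas <- deltas[is.finite(deltas$delta), ]
  moderation <- tryCatch(run_moderation(features, deltas, reml = cfg$reml),
                         nirsync_error = function(e) {
                           warn <<- c(warn, paste("moderation skipped:", conditionMessage(e)))
                           NULL
                         })

  ## --- outputs + run record ------------------------------------------------
  hashes <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(out_dir, "features.csv")
    f2 <- file.path(out_dir, "behavior.csv")
    f3 <- file.path(out_dir, "permuted_levels.csv")
    f4 <- file.path(out_dir, "results.json")
    data.table::fwrite(features, f1)
    data.table::fwrite(beh, f2)
    data.table::fwrite(permuted_levels, f3)
    jsonlite::write_json(summarize_stats(control, hypothesis, moderation),
                         f4, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    hashes <- tools::md5sum(c(f1, f2, f3, f4))
  }
  run_record <- list(config = cfg,
                     package_version = as.character(utils::packageVersion("nirsync")),
                     seed = study$params$rng_seed %||% NA,
                     n_dyads_in = length(study$dyads),
                     n_dyads_retained = length(prep),
                     warnings = warn,
                     hashes = as.list(hashes))
  list(features = features, permuted_levels = permuted_levels,
       behavior = beh, difficulty = diff_tab, exclusions = exclusions,
       stats = list(control = control, hypothesis = hypothesis,
                    moderation = moderation),
       run_record = run_record)
}

## Flatten the statistical reports into plain lists for JSON export.
summarize_stats <- function(control, hypothesis, moderation) {
  lrt_row <- function(cmp) {
    if (is.null(cmp) || isTRUE(cmp$degenerate)) return(NULL)
    out <- list(chi_sq = cmp$lrt$chi_sq, df = cmp$lrt$df,
                p_value = cmp$lrt$p_value,
                aic_full = cmp$full$aic, aic_reduced = cmp$reduced$aic,
                logLik_full = cmp$full$logLik,
                logLik_reduced = cmp$reduced$logLik,
                fallback = cmp$fallback)
    if (!is.null(cmp$effect))
      out <- c(out, list(beta_std = cmp$effect$beta_std,
                         beta_ci = c(cmp$effect$ci_lo, cmp$effect$ci_hi),
                         marginal_r2 = cmp$effect$marginal_r2,
                         partial_r2 = cmp$effect$partial_r2))
    out
  }
  list(control = lapply(control, lrt_row),
       hypothesis = if (!is.null(hypothesis)) lapply(hypothesis, lrt_row),
       moderation = if (!is.null(moderation)) lapply(moderation, lrt_row))
}
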