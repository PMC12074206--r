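## End-to-end orchestration: simulate -> condition -> segment -> extract ->
## asymmetry -> rank, as reproducible functions over the module surface.
## All tables are long/tidy delimited text; wide matrices appear only in
## reports.

#' Default run configuration
#'
#' A fully serialisable list of every tunable parameter of a pipeline run:
#' protocol timing, the six movement runs, filter bands, feature thresholds,
#' cohort composition and seeds. A run archived with its configuration and
#' seed is exactly reproducible.
#'
#' @return Nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    protocol = list(n_trials = 20L, move_s = 3, rest_s = 4, fs_hz = 2000),
    movements = list(
      list(movement = "smile", intensity = "strong"),
      list(movement = "smile", intensity = "light"),
      list(movement = "eyes", intensity = "strong"),
      list(movement = "eyes", intensity = "light"),
      list(movement = "forehead", intensity = "strong"),
      list(movement = "forehead", intensity = "light")),
    filters = list(
      bandpass = list(order = 4L, low_hz = 10, high_hz = 250),
      bandstop = list(order = 4L, low_hz = 48.5, high_hz = 51.5)),
    thresholds = list(zc_thresh = 5, ssc_thresh = 5, wamp_thresh = 10,
                      myop_thresh = 16, vorder_v = 3),
    cohort = list(n_per_group = 10L, groups = 0:4,
                  burst_amplitude = 50, baseline_noise_sd = 2,
                  mains_amplitude = 10,
                  burst_jitter_sdlog = 0.3, noise_jitter_sdlog = 0.2),
    analysis = list(control_lesioned = "left", ai_magnitude = TRUE,
                    ranking_condition = "MOVE", fs_threshold = 0.2),
    seed = 1L,
    format = "csv")
}

.protocolsFromConfig <- function(config) {
  p <- config$protocol
  lapply(config$movements, function(mv)
    ProtocolSpec(n_trials = p$n_trials, move_s = p$move_s,
                 rest_s = p$rest_s, fs_hz = p$fs_hz,
                 movement = mv$movement, intensity = mv$intensity))
}

.filtersFromConfig <- function(config) {
  f <- config$filters
  list(bandpass = FilterSpec("bandpass", f$bandpass$order,
                             f$bandpass$low_hz, f$bandpass$high_hz),
       bandstop = FilterSpec("bandstop", f$bandstop$order,
                             f$bandstop$low_hz, f$bandstop$high_hz))
}

.thresholdsFromConfig <- function(config) {
  do.call(ThresholdSpec, config$thresholds)
}

#' Analyse one recording run of one subject
#'
#' Conditions the recording, segments it by the protocol clock, extracts
#' the twenty features per interval on the movement-relevant channels, and
#' returns both the per-trial table and the trial-aggregated means.
#'
#' @param rec an [EmgRecording-class] (raw; conditioning is applied here).
#' @param protocol the run's [ProtocolSpec-class].
#' @param th a [ThresholdSpec-class].
#' @param filters list with `bandpass` and `bandstop` [FilterSpec-class]
#'   entries.
#' @return List with `trials` (per-trial wide table) and `aggregated`
#'   (long per-(side, condition, feature) means and SDs).
#' @export
analyzeRecording <- function(rec, protocol, th = ThresholdSpec(),
                             filters = list(
                               bandpass = FilterSpec("bandpass", 4, 10, 250),
                               bandstop = FilterSpec("bandstop", 4, 48.5, 51.5))) {
  cond <- applyConditioning(rec, bandpass = filters$bandpass,
                            bandstop = filters$bandstop)
  trials <- extractFeatureTable(cond, protocol, th = th)
  list(trials = trials, aggregated = aggregateTrials(trials))
}

#' Run the full analysis on an in-memory synthetic cohort
#'
#' Generates each subject's recordings run by run (streaming, so cohort
#' size is not memory-bound), analyses them, and assembles the asymmetry,
#' ranking and contrast tables.
#'
#' @param n_per_group subjects per HB group.
#' @param groups ordinal HB group codes (default all five).
#' @param protocols list of [ProtocolSpec-class] runs per subject.
#' @param master_seed integer seed controlling the whole cohort.
#' @param config configuration list ([defaultRunConfig()]) supplying
#'   thresholds, filters and analysis options.
#' @return List: `manifest`, `features` (per-trial long),
#'   `subject_features` (aggregated long), `asymmetry`, `ranking`,
#'   `contrasts`.
#' @export
runSyntheticAnalysis <- function(n_per_group = 10L, groups = 0:4,
                                 protocols = list(ProtocolSpec()),
                                 master_seed = 1L,
                                 config = defaultRunConfig()) {
  co <- config$cohort
  cohort <- generateCohort(
    n_per_group = n_per_group, groups = groups, protocols = protocols,
    master_seed = master_seed,
    burst_amplitude = co$burst_amplitude,
    baseline_noise_sd = co$baseline_noise_sd,
    mains_amplitude = co$mains_amplitude,
    burst_jitter_sdlog = co$burst_jitter_sdlog,
    noise_jitter_sdlog = co$noise_jitter_sdlog,
    return_recordings = FALSE)
  th <- .thresholdsFromConfig(config)
  filters <- .filtersFromConfig(config)

  trial_tabs <- list(); agg_tabs <- list()
  for (prof in cohort$profiles) {
    for (pr in protocols) {
      rec <- generateRecording(prof, pr)
      res <- analyzeRecording(rec, pr, th = th, filters = filters)
      res$trials <- cbind(subject_id = prof@subject_id, res$trials)
      res$aggregated <- cbind(subject_id = prof@subject_id, res$aggregated)
      key <- paste(prof@subject_id, pr@movement, pr@intensity)
      trial_tabs[[key]] <- res$trials
      agg_tabs[[key]] <- res$aggregated
    }
  }
  subject_features <- do.call(rbind, agg_tabs)
  rownames(subject_features) <- NULL
  features_long <- featureTableLong(do.call(rbind, trial_tabs))
  rownames(features_long) <- NULL

  ai <- buildAsymmetryTable(
    subject_features, cohort$manifest,
    control_lesioned = config$analysis$control_lesioned,
    magnitude = isTRUE(config$analysis$ai_magnitude))
  ranking <- featureRankingTable(
    ai, condition = config$analysis$ranking_condition)
  contrasts <- motionContrastTable(subject_features)

  list(manifest = cohort$manifest, features = features_long,
       subject_features = subject_features, asymmetry = ai,
       ranking = ranking, contrasts = contrasts)
}

#' Simulate a synthetic cohort to disk
#'
#' Writes one recording file per subject and run, a cohort manifest, and an
#' archived copy of the configuration, so the run can be re-analysed from
#' the directory alone.
#'
#' @param config configuration list (see [defaultRunConfig()]) or a path to
#'   a JSON/YAML configuration file.
#' @param out_dir output directory (created if absent; must be writable).
#' @return The manifest data.frame, invisibly. Files written:
#'   `<subject>_<movement>_<intensity>.<format>`, `manifest.csv`,
#'   `config.json`.
#' @export
simulateCohort <- function(config = defaultRunConfig(), out_dir) {
  if (missing(out_dir) || is.null(out_dir) || !nzchar(out_dir))
    stop("an output directory is required")
  if (is.character(config) && length(config) == 1L && file.exists(config))
    config <- readRunConfig(config)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)

  protocols <- .protocolsFromConfig(config)
  co <- config$cohort
  cohort <- generateCohort(
    n_per_group = co$n_per_group, groups = co$groups,
    protocols = protocols, master_seed = config$seed,
    burst_amplitude = co$burst_amplitude,
    baseline_noise_sd = co$baseline_noise_sd,
    mains_amplitude = co$mains_amplitude,
    burst_jitter_sdlog = co$burst_jitter_sdlog,
    noise_jitter_sdlog = co$noise_jitter_sdlog,
    return_recordings = FALSE)

  ext <- if (identical(config$format, "edf")) "edf" else "csv"
  rows <- list()
  for (prof in cohort$profiles) {
    for (pr in protocols) {
      rec <- generateRecording(prof, pr)
      fname <- sprintf("%s_%s_%s.%s", prof@subject_id, pr@movement,
                       pr@intensity, ext)
      writeRecording(rec, file.path(out_dir, fname))
      md <- cohort$manifest[cohort$manifest$subject_id == prof@subject_id, ]
      rows[[fname]] <- data.frame(
        md, movement = pr@movement, intensity = pr@intensity,
        path = fname, etiology = "synthetic", row.names = NULL,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  data.table::fwrite(manifest, file.path(out_dir, "manifest.csv"))
  writeRunConfig(config, file.path(out_dir, "config.json"))
  invisible(manifest)
}

#' Analyse a simulated (or imported) cohort from disk
#'
#' Reads each manifest entry, runs [analyzeRecording()], and writes the
#' per-trial feature table, the per-subject aggregated table, the asymmetry
#' table, the feature ranking, the MOVE/REST contrasts, an error summary
#' for any failed recordings, and a parameter log. Per-subject failures are
#' isolated: the run continues and failures are reported.
#'
#' @param manifest manifest data.frame or path to `manifest.csv`; relative
#'   recording paths are resolved against the manifest's directory.
#' @param config configuration list or path (defaults to the archived
#'   `config.json` next to the manifest, if present).
#' @param out_dir directory for the output tables (created if absent).
#' @return List of the assembled tables (also written as CSV), invisibly.
#' @export
analyzeCohort <- function(manifest, config = NULL, out_dir) {
  if (missing(out_dir)) stop("an output directory is required")
  base_dir <- "."
  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- data.table::setDF(data.table::fread(manifest))
  }
  if (is.null(config)) {
    cand <- file.path(base_dir, "config.json")
    config <- if (file.exists(cand)) readRunConfig(cand)
              else defaultRunConfig()
  } else if (is.character(config)) {
    config <- readRunConfig(config)
  }
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)

  p <- config$protocol
  th <- .thresholdsFromConfig(config)
  filters <- .filtersFromConfig(config)

  trial_tabs <- list(); agg_tabs <- list(); errors <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    path <- row$path
    if (!file.exists(path)) path <- file.path(base_dir, row$path)
    key <- paste(row$subject_id, row$movement, row$intensity)
    res <- tryCatch({
      rec <- readRecording(path)
      protocol <- ProtocolSpec(n_trials = p$n_trials, move_s = p$move_s,
                               rest_s = p$rest_s, fs_hz = p$fs_hz,
                               movement = row$movement,
                               intensity = row$intensity)
      analyzeRecording(rec, protocol, th = th, filters = filters)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[key]] <- data.frame(subject_id = row$subject_id,
                                  path = row$path,
                                  error = conditionMessage(res),
                                  stringsAsFactors = FALSE)
      next
    }
    trial_tabs[[key]] <- cbind(subject_id = row$subject_id, res$trials)
    agg_tabs[[key]] <- cbind(subject_id = row$subject_id, res$aggregated)
  }
  if (length(trial_tabs) == 0L)
    stop("no recording could be analysed; first error: ",
         if (length(errors)) errors[[1]]$error else "none")

  subject_features <- do.call(rbind, agg_tabs)
  rownames(subject_features) <- NULL
  features_long <- featureTableLong(do.call(rbind, trial_tabs))

  md <- unique(manifest[c("subject_id", "hb_grade", "hb_group",
                          "is_control", "lesioned_side")])
  ok <- unique(subject_features$subject_id)
  ai <- buildAsymmetryTable(
    subject_features, md[md$subject_id %in% ok, ],
    control_lesioned = config$analysis$control_lesioned,
    magnitude = isTRUE(config$analysis$ai_magnitude))
  ranking <- featureRankingTable(
    ai, condition = config$analysis$ranking_condition)
  contrasts <- tryCatch(motionContrastTable(subject_features),
                        error = function(e) NULL)

  err_tab <- if (length(errors)) do.call(rbind, errors) else
    data.frame(subject_id = character(), path = character(),
               error = character())
  if (nrow(err_tab))
    warning(nrow(err_tab), " recording(s) failed; see errors.csv")

  fwrite0 <- function(x, f) data.table::fwrite(x, file.path(out_dir, f))
  fwrite0(features_long, "features.csv")
  fwrite0(subject_features, "subject_features.csv")
  fwrite0(ai, "asymmetry.csv")
  fwrite0(ranking, "ranking.csv")
  if (!is.null(contrasts)) fwrite0(contrasts, "contrasts.csv")
  fwrite0(err_tab, "errors.csv")
  writeLines(c(
    sprintf("facialEMG analysis log"),
    sprintf("recordings analysed: %d; failed: %d",
            length(trial_tabs), nrow(err_tab)),
    sprintf("segments (feature rows): %d", nrow(features_long)),
    sprintf("asymmetry records: %d", nrow(ai)),
    sprintf("protocol: %d trials, %g s MOVE + %g s REST @ %g Hz",
            p$n_trials, p$move_s, p$rest_s, p$fs_hz),
    sprintf("bandpass: %g-%g Hz order %d; bandstop: %g-%g Hz order %d",
            config$filters$bandpass$low_hz, config$filters$bandpass$high_hz,
            config$filters$bandpass$order,
            config$filters$bandstop$low_hz, config$filters$bandstop$high_hz,
            config$filters$bandstop$order),
    sprintf("thresholds: zc=%g ssc=%g wamp=%g myop=%g vorder_v=%g",
            config$thresholds$zc_thresh, config$thresholds$ssc_thresh,
            config$thresholds$wamp_thresh, config$thresholds$myop_thresh,
            config$thresholds$vorder_v),
    sprintf("AI: magnitude=%s, control pseudo-lesioned side=%s, ranked on %s",
            isTRUE(config$analysis$ai_magnitude),
            config$analysis$control_lesioned,
            config$analysis$ranking_condition)),
    file.path(out_dir, "log.txt"))

  invisible(list(features = features_long,
                 subject_features = subject_features, asymmetry = ai,
                 ranking = ranking, contrasts = contrasts,
                 errors = err_tab))
}

.wideMatrix <- function(df, value) {
  runs <- unique(df[c("movement", "intensity")])
  run_names <- paste(runs$movement, runs$intensity)
  feats <- sort(unique(df$feature))
  m <- matrix(NA_real_, length(feats), nrow(runs),
              dimnames = list(feats, run_names))
  for (k in seq_len(nrow(df))) {
    rn <- paste(df$movement[k], df$intensity[k])
    m[df$feature[k], rn] <- df[[value]][k]
  }
  m
}

#' Render a plain-text summary report of an analysed cohort
#'
#' Builds heatmap-style wide matrices (features x movement runs) of the
#' Fisher scores, Spearman correlations and p-values, lists the features
#' whose Fisher score exceeds the highlight threshold per run, and
#' summarises the MOVE/REST contrasts. Missing tables are skipped with a
#' warning.
#'
#' @param in_dir directory written by [analyzeCohort()], or a list of
#'   tables with elements `ranking` and optionally `contrasts`.
#' @param out_file optional path for the rendered text report.
#' @param fs_threshold Fisher-score highlight threshold (default 0.2).
#' @return Character vector of report lines, invisibly when written.
#' @export
reportCohort <- function(in_dir, out_file = NULL, fs_threshold = 0.2) {
  if (is.character(in_dir)) {
    rk_path <- file.path(in_dir, "ranking.csv")
    if (!file.exists(rk_path)) stop("no ranking table found in ", in_dir)
    ranking <- data.table::setDF(data.table::fread(rk_path))
    ct_path <- file.path(in_dir, "contrasts.csv")
    contrasts <- if (file.exists(ct_path))
      data.table::setDF(data.table::fread(ct_path)) else NULL
  } else {
    ranking <- in_dir$ranking
    contrasts <- in_dir$contrasts
    if (is.null(ranking) || nrow(ranking) == 0L)
      stop("a non-empty ranking table is required")
  }
  if (nrow(ranking) == 0L) stop("ranking table is empty")

  fmt_mat <- function(m) {
    utils::capture.output(print(round(m, 3)))
  }
  lines <- c("facialEMG cohort report",
             strrep("=", 40), "",
             "Fisher scores (AI of features vs HB groups):",
             fmt_mat(.wideMatrix(ranking, "fisher_score")), "",
             "Spearman rho (AI vs ordinal HB group):",
             fmt_mat(.wideMatrix(ranking, "spearman_rho")), "",
             "Spearman p-values (two-tailed, unadjusted):",
             fmt_mat(.wideMatrix(ranking, "spearman_p")), "")
  runs <- unique(ranking[c("movement", "intensity")])
  lines <- c(lines, sprintf("Features with Fisher score > %g:", fs_threshold))
  for (k in seq_len(nrow(runs))) {
    rk <- rankFeatures(ranking, movement = runs$movement[k],
                       intensity = runs$intensity[k],
                       threshold = fs_threshold)
    top <- rk$feature[rk$flagged]
    lines <- c(lines, sprintf("  %s %s: %s", runs$movement[k],
                              runs$intensity[k],
                              if (length(top)) paste(top, collapse = ", ")
                              else "(none)"))
  }
  if (is.null(contrasts)) {
    warning("contrast table missing: report omits MOVE/REST contrasts")
    lines <- c(lines, "", "MOVE/REST contrasts: not available")
  } else {
    sig <- contrasts[!is.na(contrasts$p_value) & contrasts$p_value < 0.001, ]
    lines <- c(lines, "",
               sprintf("MOVE/REST contrasts: %d cells, %d with p < 0.001",
                       nrow(contrasts), nrow(sig)))
  }
  if (!is.null(out_file)) {
    writeLines(lines, out_file)
    return(invisible(lines))
  }
  lines
}
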