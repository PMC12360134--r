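#' Pipeline run configuration
#'
#' Assembles (and validates) the configuration of an end-to-end run:
#' synthetic mode generates a cohort from a [cohort_design()]; files mode
#' reads trial bundles written by [write_trial()].  The global seed fixes
#' all stochastic behaviour.  Configurations round-trip through YAML via
#' [read_run_config()] / [write_run_config()].
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param design a [cohort_design()] (synthetic mode); built from `seed`
#'   with defaults when `NULL`.
#' @param trial_dirs character vector of bundle directories (files mode).
#' @param out_dir output directory for artifacts.
#' @param seed global integer seed.
#' @param curvature_window,curvature_order,fit_region kinematics tunables,
#'   see [summarize_trial()].
#' @param alpha significance level for the statistical report.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"), design = NULL,
                       trial_dirs = NULL, out_dir = "undulokin_out",
                       seed = 1L, curvature_window = 15L,
                       curvature_order = 3L, fit_region = c(0.50, 0.95),
                       alpha = 0.05) {
  mode <- match.arg(mode)
  if (mode == "synthetic" && is.null(design))
    design <- cohort_design(seed = as.integer(seed))
  if (mode == "files" && (is.null(trial_dirs) || !length(trial_dirs)))
    abort_field("trial_dirs", "files mode needs at least one trial bundle")
  structure(
    list(mode = mode, design = design, trial_dirs = trial_dirs,
         out_dir = out_dir, seed = as.integer(seed),
         curvature_window = curvature_window,
         curvature_order = curvature_order, fit_region = fit_region,
         alpha = alpha),
    class = "run_config"
  )
}

#' Write / read a run configuration as YAML
#'
#' Only plain-value fields are serialized; a synthetic design is stored
#' as its scalar parameters (custom trend functions are not serializable
#' and revert to the defaults on read).
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` (write) or a [run_config()] (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  d <- config$design
  lst <- list(
    mode = config$mode, out_dir = config$out_dir, seed = config$seed,
    curvature_window = config$curvature_window,
    curvature_order = config$curvature_order,
    fit_region = config$fit_region, alpha = config$alpha,
    trial_dirs = config$trial_dirs,
    design = if (is.null(d)) NULL else list(
      n_individuals = d$n_individuals, speeds = d$speeds,
      missing_individual = d$missing$individual,
      missing_speed = d$missing$speed_bl,
      noise_sd = d$noise_sd, fps = d$fps,
      envelope_power = d$envelope_power, seed = d$seed,
      body_lengths = d$body_lengths))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  design <- NULL
  if (!is.null(lst$design)) {
    d <- lst$design
    design <- cohort_design(
      n_individuals = d$n_individuals, speeds = unlist(d$speeds),
      missing = if (is.null(d$missing_individual)) NULL else
        data.frame(individual = unlist(d$missing_individual),
                   speed_bl = unlist(d$missing_speed)),
      noise_sd = d$noise_sd, fps = d$fps,
      envelope_power = d$envelope_power,
      body_lengths = unlist(d$body_lengths), seed = d$seed)
  }
  run_config(mode = lst$mode, design = design,
             trial_dirs = unlist(lst$trial_dirs),
             out_dir = lst$out_dir, seed = lst$seed,
             curvature_window = lst$curvature_window,
             curvature_order = lst$curvature_order,
             fit_region = unlist(lst$fit_region), alpha = lst$alpha)
}

#' Validate pipeline inputs
#'
#' Report-only schema and consistency checks: file existence, row
#' parseability, frame-rate consistency between metadata and frame
#' spacing.  Nothing is fatal; every finding is one report row.
#'
#' @param config a [run_config()].
#' @return Data frame with columns `item`, `level` (`"ok"`, `"warning"`,
#'   `"error"`), `message`; zero "warning"/"error" rows means a clean
#'   configuration.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rows <- list()
  add <- function(item, level, message)
    rows[[length(rows) + 1L]] <<- data.frame(item = item, level = level,
                                             message = message)
  if (config$mode == "synthetic") {
    nd <- tryCatch(n_trials(config$design), error = function(e) NA_integer_)
    if (is.na(nd)) add("design", "error", "invalid cohort design")
  } else {
    for (d in config$trial_dirs) {
      for (f in c("midlines.csv", "landmarks_lateral.csv",
                  "landmarks_dorsal.csv", "meta.json")) {
        if (!file.exists(file.path(d, f)))
          add(d, "error", paste("missing file:", f))
      }
      mj <- file.path(d, "meta.json")
      if (file.exists(mj)) {
        meta <- tryCatch(jsonlite::read_json(mj, simplifyVector = TRUE),
                         error = function(e) NULL)
        if (is.null(meta)) {
          add(d, "error", "unreadable meta.json")
        } else if (is.null(meta$fps) || !is.finite(meta$fps) ||
                   meta$fps <= 0) {
          add(d, "error", "meta.json lacks a positive fps")
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(item = character(), level = character(),
                      message = character()))
  do.call(rbind, rows)
}

#' Run the full pipeline
#'
#' End-to-end orchestration: obtain the trials (synthetic generation or
#' bundle reading), summarize each trial's kinematics, run the
#' cross-speed statistical report and the PCA, and write the artifact
#' set — `summaries.csv`, `stats_tests.csv`, `letters.csv`,
#' `summary_table.csv`, `pca_variance.csv`, `pca_contributions.csv`,
#' `pca_scores.csv`, `st_re.csv`, `run_meta.json` and `log.txt` — into
#' `config$out_dir`.  Deterministic given the seed (only `log.txt` and
#' `run_meta.json` carry timestamps).  Individual trial failures are
#' logged and skipped; the run fails only if every trial fails.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `summaries`, `report`, `pca`, `st_re`,
#'   `truth` (synthetic mode) and `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }

  truth <- NULL
  if (config$mode == "synthetic") {
    logf("generating synthetic cohort (seed %d)", config$seed)
    cohort <- generate_cohort(config$design)
    trials <- cohort$trials
    truth <- cohort$truth
  } else {
    logf("reading %d trial bundles", length(config$trial_dirs))
    trials <- lapply(config$trial_dirs, function(d)
      tryCatch(read_trial(d), error = function(e) {
        logf("trial %s failed to load: %s", d, conditionMessage(e))
        NULL
      }))
    trials <- Filter(Negate(is.null), trials)
  }

  summaries <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    summaries[[i]] <- tryCatch(
      withCallingHandlers(
        summarize_trial(tr$midlines, tr$landmarks, tr$meta,
                        curvature_window = config$curvature_window,
                        curvature_order = config$curvature_order,
                        fit_region = config$fit_region),
        warning = function(w) {
          logf("trial %s: %s", tr$midlines$trial_id, conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) {
        logf("trial %s skipped: %s", tr$midlines$trial_id,
             conditionMessage(e))
        NULL
      })
  }
  summaries <- do.call(rbind, Filter(Negate(is.null), summaries))
  if (is.null(summaries) || !nrow(summaries))
    stop("all trials failed; see the run log", call. = FALSE)
  logf("%d trial summaries computed", nrow(summaries))

  report <- withCallingHandlers(
    stats_report(summaries, alpha = config$alpha),
    warning = function(w) {
      logf("stats: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  pca <- pca_contributions(summaries)
  if (length(pca$dropped_rows))
    logf("PCA dropped rows: %s", paste(pca$dropped_rows, collapse = ", "))
  stre <- st_re_table(summaries)
  tbl1 <- summary_table(summaries, report = report)

  wcsv <- function(df, name)
    utils::write.csv(df, file.path(config$out_dir, name), row.names = FALSE)
  wcsv(summaries, "summaries.csv")
  wcsv(report$tests, "stats_tests.csv")
  wcsv(report$letters, "letters.csv")
  wcsv(tbl1, "summary_table.csv")
  wcsv(data.frame(axis = seq_along(pca$percent_variance),
                  percent_variance = pca$percent_variance),
       "pca_variance.csv")
  wcsv(data.frame(variable = rownames(pca$contributions),
                  pca$contributions, check.names = FALSE),
       "pca_contributions.csv")
  wcsv(data.frame(pca$scores), "pca_scores.csv")
  wcsv(stre, "st_re.csv")
  if (!is.null(truth)) wcsv(truth, "ground_truth.csv")

  jsonlite::write_json(
    list(mode = config$mode, seed = config$seed,
         n_trials = nrow(summaries),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(config$out_dir, "run_meta.json"), auto_unbox = TRUE)
  writeLines(log_lines, file.path(config$out_dir, "log.txt"))

  invisible(list(summaries = summaries, report = report, pca = pca,
                 st_re = stre, summary_table = tbl1, truth = truth,
                 log = log_lines))
}
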