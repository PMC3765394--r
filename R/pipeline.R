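# One-shot orchestration: cohort builder -> matcher -> analytics, plus the
# simulate / run / report entry points mirrored by the inst/cli/ratext
# script.

#' Run the full analysis pipeline in memory
#'
#' Identifies the incident cohort, windows the events, matches codes (in the
#' analysis window) and keywords (in the extended search window), collapses
#' hits to patient flags, and produces the five result tables.
#'
#' @param patients,events Data.frames ([read_patients()], [read_events()]).
#' @param codelists,keywords Spec lists ([read_codelists()],
#'   [read_keywords()]); default to the shipped lists.
#' @param study_start,study_end Study period bounds.
#' @param prevalence_window `"with_tail"` counts hits up to 14 days after the
#'   index code toward prevalence (the analysis window); `"year_before"`
#'   drops the post-index tail. Interval statistics always use first
#'   occurrences on or before the index date.
#' @param family_size Bonferroni multiplier for the 10 group comparisons.
#' @return List: `cohort`, `exclusions`, `flags`, `code_hits`,
#'   `keyword_hits`, and `tables` (prevalence, intervals, code_ranks,
#'   crosstab, combinations, keyword_multiplicity).
#' @export
run_pipeline <- function(patients, events, codelists = NULL, keywords = NULL,
                         study_start = as.Date("2005-01-01"),
                         study_end = as.Date("2008-12-31"),
                         prevalence_window = c("with_tail", "year_before"),
                         family_size = 10) {
  prevalence_window <- match.arg(prevalence_window)
  if (is.null(codelists)) codelists <- read_codelists(default_codelist_dir())
  if (is.null(keywords)) keywords <- read_keywords(default_keyword_dir())

  cohort <- identify_cases(patients, events, codelists$ra_diagnosis,
                           study_start, study_end)
  if (nrow(cohort) == 0L) warning("no eligible cases identified")
  marker_codes <- c(codelists$inflammatory_arthritis_dx$codes,
                    codelists$synovitis$codes)
  win <- window_events(cohort, events, codelists$dmard, marker_codes)

  indicator_specs <- codelists[intersect(indicator_groups(),
                                         names(codelists))]
  code_hits <- match_events(win$analysis, indicator_specs,
                            keywords[0])$code_hits
  keyword_hits <- match_events(win$search, list(), keywords)$keyword_hits

  if (prevalence_window == "year_before") {
    idx <- win$cohort$index_date
    ci <- idx[match(code_hits$patient_id, win$cohort$patient_id)]
    code_hits_flag <- code_hits[code_hits$effective_date <= ci, , drop = FALSE]
    ki <- idx[match(keyword_hits$patient_id, win$cohort$patient_id)]
    keyword_hits_flag <-
      keyword_hits[keyword_hits$effective_date <= ki, , drop = FALSE]
  } else {
    code_hits_flag <- code_hits
    keyword_hits_flag <- keyword_hits
  }

  flags <- collapse_to_patient(code_hits_flag, keyword_hits_flag, win$cohort)
  tables <- list(
    prevalence = prevalence_table(flags, family_size = family_size),
    intervals = interval_table(flags, family_size = family_size),
    code_ranks = rank_codes(keyword_hits_flag),
    crosstab = crosstab_table(flags),
    combinations = combination_table(flags),
    keyword_multiplicity = keyword_multiplicity(flags))
  list(cohort = win$cohort, exclusions = attr(cohort, "exclusions"),
       flags = flags, code_hits = code_hits, keyword_hits = keyword_hits,
       tables = tables)
}

#' Read a simulation config from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; absent keys keep their
#' defaults. `occurrence` and `assoc_code_weights` are flat named maps;
#' `intervals` maps group name to `[median, q1, q3]`.
#'
#' @param path YAML file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- formals(sim_config)
  unknown <- setdiff(names(raw), names(args))
  if (length(unknown)) {
    stop("unknown simulation config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- sim_config()
  for (key in c("occurrence", "assoc_code_weights")) {
    if (!is.null(raw[[key]])) raw[[key]] <- unlist(raw[[key]])
  }
  if (!is.null(raw$occurrence)) {
    raw$occurrence <- utils::modifyList(as.list(defaults$occurrence),
                                        as.list(raw$occurrence))
    raw$occurrence <- unlist(raw$occurrence)
  }
  if (!is.null(raw$intervals)) {
    raw$intervals <- utils::modifyList(defaults$intervals,
                                       lapply(raw$intervals, as.numeric))
  }
  if (!is.null(raw$age_quartiles)) {
    raw$age_quartiles <- lapply(raw$age_quartiles, as.numeric)
  }
  for (key in c("study_start", "study_end")) {
    if (!is.null(raw[[key]])) raw[[key]] <- as.Date(raw[[key]])
  }
  do.call(sim_config, raw)
}

#' Simulate a dataset and write it to disk
#'
#' Writes `patients.csv`, `events.csv`, `groundtruth.csv`,
#' `groundtruth_events.csv` and a `manifest.json` echoing the configuration,
#' into `out_dir`.
#'
#' @param config A [sim_config()] or path to a YAML config file.
#' @param seed Optional seed overriding the config's.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the simulated dataset (as from [simulate_cohort()]).
#' @export
cmd_simulate <- function(config = sim_config(), seed = NULL, out_dir) {
  if (is.character(config)) config <- read_sim_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config)
  write_patients(sim$patients, file.path(out_dir, "patients.csv"))
  write_events(sim$events, file.path(out_dir, "events.csv"))
  utils::write.csv(sim$truth, file.path(out_dir, "groundtruth.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(sim$truth_events,
                   file.path(out_dir, "groundtruth_events.csv"),
                   row.names = FALSE, na = "")
  manifest <- config
  manifest$study_start <- format(manifest$study_start)
  manifest$study_end <- format(manifest$study_end)
  class(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(sim)
}

#' Configuration for a pipeline run
#'
#' @param patients,events Paths to the input CSV files.
#' @param codelist_dir,keyword_dir Directories of group files; default to the
#'   shipped lists.
#' @param study_start,study_end Study period bounds.
#' @param prevalence_window See [run_pipeline()].
#' @param family_size Bonferroni multiplier.
#' @param out_dir Output directory for tables and the run log.
#' @return Classed list of settings.
#' @export
run_config <- function(patients, events, codelist_dir = NULL,
                       keyword_dir = NULL,
                       study_start = "2005-01-01", study_end = "2008-12-31",
                       prevalence_window = "with_tail", family_size = 10,
                       out_dir = ".") {
  structure(list(patients = patients, events = events,
                 codelist_dir = codelist_dir, keyword_dir = keyword_dir,
                 study_start = as.Date(study_start),
                 study_end = as.Date(study_end),
                 prevalence_window = prevalence_window,
                 family_size = family_size, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with keys mirroring the [run_config()] arguments.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(formals(run_config)))
  if (length(unknown)) {
    stop("unknown run config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

table_files <- c(prevalence = "table2_prevalence.csv",
                 intervals = "table2_intervals.csv",
                 code_ranks = "table3_code_ranks.csv",
                 crosstab = "table4_crosstab.csv",
                 combinations = "table5_combinations.csv",
                 keyword_multiplicity = "keyword_multiplicity.csv")

#' Run the pipeline from files and write all outputs
#'
#' Validates all input paths up front, executes
#' cohort builder -> matcher -> analytics, and writes the five result tables
#' plus `keyword_multiplicity.csv`, `cohort.csv`, `exclusions.csv`,
#' `flags.csv`, `hits.csv` and a `run.log` with cohort size, exclusion
#' counts and per-stage timings. A failure aborts naming the stage.
#'
#' @param config A [run_config()] or path to a YAML run config.
#' @return Invisibly, the [run_pipeline()] result.
#' @export
cmd_run <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$patients, config$events, config$codelist_dir,
              config$keyword_dir)) {
    if (!is.null(p) && !file.exists(p)) stop("input path not found: ", p)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  log_msg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log_msg(sprintf("stage %-10s %6.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }

  inputs <- stage("read", {
    list(patients = read_patients(config$patients),
         events = read_events(config$events),
         codelists = read_codelists(config$codelist_dir %||%
                                      default_codelist_dir()),
         keywords = read_keywords(config$keyword_dir %||%
                                    default_keyword_dir()))
  })
  res <- stage("analyse", {
    run_pipeline(inputs$patients, inputs$events, inputs$codelists,
                 inputs$keywords, config$study_start, config$study_end,
                 config$prevalence_window, config$family_size)
  })
  stage("write", {
    for (nm in names(table_files)) {
      utils::write.csv(res$tables[[nm]],
                       file.path(config$out_dir, table_files[[nm]]),
                       row.names = FALSE, na = "")
    }
    write_date_csv(res$cohort, file.path(config$out_dir, "cohort.csv"))
    utils::write.csv(res$exclusions,
                     file.path(config$out_dir, "exclusions.csv"),
                     row.names = FALSE, na = "")
    write_date_csv(res$flags, file.path(config$out_dir, "flags.csv"))
    mk_hits <- function(df, channel, detail_col) {
      out <- df[c("patient_id", "event_id", "group_name", "effective_date")]
      out$channel <- rep(channel, nrow(df))
      out$read_code <- df[[detail_col]]
      out
    }
    hits <- rbind(mk_hits(res$code_hits, "code", "read_code"),
                  mk_hits(res$keyword_hits, "keyword",
                          "associated_read_code"))
    write_date_csv(hits, file.path(config$out_dir, "hits.csv"))
  })
  log_msg("cohort size ", nrow(res$cohort))
  excl <- table(res$exclusions$reason)
  for (r in names(excl)) log_msg("excluded ", r, ": ", excl[[r]])
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_date_csv <- function(df, path) {
  for (col in names(df)) {
    if (inherits(df[[col]], "Date")) {
      df[[col]] <- ifelse(is.na(df[[col]]), "", format(df[[col]], "%Y-%m-%d"))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Render a plain-markdown summary of a completed run
#'
#' Reads the table CSVs written by [cmd_run()] from `out_dir` and renders a
#' five-section report (prevalence, intervals, associated-code ranking,
#' code-vs-keyword crosstab, combinations) with percentages to 1 d.p.
#' Regeneration is idempotent.
#'
#' @param out_dir Directory holding the result tables.
#' @param file Output file name within `out_dir`.
#' @return Invisibly, the report text (character vector of lines).
#' @export
cmd_report <- function(out_dir, file = "report.md") {
  paths <- file.path(out_dir, table_files)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing table file(s): ",
                            paste(basename(missing), collapse = ", "))
  tabs <- lapply(paths, utils::read.csv, check.names = FALSE)
  names(tabs) <- names(table_files)

  fmt_tab <- function(df) {
    df[] <- lapply(df, function(x) {
      if (is.numeric(x)) ifelse(is.na(x), "", format(x, digits = 4)) else x
    })
    header <- paste(names(df), collapse = " | ")
    sep <- paste(rep("---", ncol(df)), collapse = " | ")
    body <- apply(df, 1, paste, collapse = " | ")
    c(paste("|", header, "|"), paste("|", sep, "|"),
      if (nrow(df)) paste("|", body, "|"))
  }
  section <- function(title, df) c(paste("##", title), "", fmt_tab(df), "")
  lines <- c(
    "# Indicator-code and keyword analysis",
    "",
    section("Prevalence by gender", tabs$prevalence),
    section("Interval to index RA code (days)", tabs$intervals),
    section("Codes associated with keyword-bearing text", tabs$code_ranks),
    section("Coded vs textual evidence", tabs$crosstab),
    section("Marker combinations", tabs$combinations),
    section("Keyword multiplicity", tabs$keyword_multiplicity))
  writeLines(lines, file.path(out_dir, file))
  invisible(lines)
}
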