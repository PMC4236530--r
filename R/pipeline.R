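#' Read and write pipeline CSV files
#'
#' Every file the pipeline writes is UTF-8 CSV with ISO dates, preceded by
#' `#` comment lines recording the package version, master seed and a hash
#' of the generating configuration, so any output can be traced to its run.
#' `read_pipeline_csv()` skips those comment lines and restores `Date`
#' columns.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @param seed master seed to record.
#' @param config_hash configuration hash to record (see [config_hash()]).
#' @return `read_pipeline_csv()` returns a data.frame; the writer returns
#'   `path` invisibly.
#' @export
write_pipeline_csv <- function(df, path, seed = NA, config_hash = NA) {
  hdr <- c(
    paste0("# slklink ", as.character(utils::packageVersion("slklink"))),
    paste0("# seed: ", seed),
    paste0("# config_hash: ", config_hash))
  con <- file(path, open = "wb")
  writeLines(hdr, con)
  close(con)
  for (cl in names(df))
    if (inherits(df[[cl]], "Date")) df[[cl]] <- format(df[[cl]], "%Y-%m-%d")
  data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_csv
#' @param date_cols columns to coerce to `Date` when present.
#' @export
read_pipeline_csv <- function(path, date_cols = c("birth_date",
                                                  "separation_date",
                                                  "death_date")) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  df <- data.frame(data.table::fread(text = lines, colClasses = "character",
                                     na.strings = c("", "NA")),
                   stringsAsFactors = FALSE)
  for (cl in intersect(date_cols, names(df))) df[[cl]] <- as.Date(df[[cl]])
  for (cl in intersect(c("slk_complete", "ambiguous_flag"), names(df)))
    df[[cl]] <- as.logical(df[[cl]])
  for (cl in grep("^(n_|count$|pct$|rate|mean$|ci_|median$|q25$|q75$|fy_end$|window_years$|percent|missed|fp_)",
                  names(df), value = TRUE))
    suppressWarnings(df[[cl]] <- as.numeric(df[[cl]]))
  df
}

#' Hash of a run configuration
#'
#' MD5 of the JSON-serialised configuration; recorded in every output file
#' header so results can be matched to the exact parameter set.
#'
#' @param config a [synth_config()] or any serialisable list.
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Save or load a generator configuration as YAML
#'
#' @param config a [synth_config()].
#' @param path YAML file path.
#' @return `load_config()` returns a validated [synth_config()].
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  for (cl in c("study_start", "study_end", "death_window_start",
               "death_window_end"))
    x[[cl]] <- format(x[[cl]], "%Y-%m-%d")
  x$condition_prevalences <- as.list(x$condition_prevalences)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$condition_prevalences))
    x$condition_prevalences <- as.data.frame(x$condition_prevalences,
                                             stringsAsFactors = FALSE)
  do.call(synth_config, x)
}

#' Simulate a synthetic linkage study and write its files
#'
#' Generates persons, admissions, deaths, the true MLK and the
#' error-injected MLK, and writes `persons.csv` (ground truth, kept
#' separate), `admissions.csv`, `deaths.csv`, `mlk.csv` and a
#' `manifest.yaml` echoing the seed and every parameter.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list from [simulate_study()] with `$paths`.
#' @export
run_simulate <- function(config = synth_config(), out_dir) {
  validate_synth_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_study(config)
  h <- config_hash(config)
  paths <- list(
    persons = file.path(out_dir, "persons.csv"),
    admissions = file.path(out_dir, "admissions.csv"),
    deaths = file.path(out_dir, "deaths.csv"),
    mlk = file.path(out_dir, "mlk.csv"),
    mlk_true = file.path(out_dir, "mlk_true.csv"),
    manifest = file.path(out_dir, "manifest.yaml"))
  write_pipeline_csv(sim$persons, paths$persons, config$seed, h)
  write_pipeline_csv(sim$admissions, paths$admissions, config$seed, h)
  write_pipeline_csv(sim$deaths, paths$deaths, config$seed, h)
  write_pipeline_csv(sim$mlk, paths$mlk, config$seed, h)
  write_pipeline_csv(sim$mlk_true, paths$mlk_true, config$seed, h)
  save_config(config, file.path(out_dir, "config.yaml"))
  yaml::write_yaml(list(seed = config$seed, config_hash = h,
                        n_persons = nrow(sim$persons),
                        n_admissions = nrow(sim$admissions),
                        n_deaths = nrow(sim$deaths)),
                   paths$manifest)
  sim$paths <- paths
  invisible(sim)
}

#' Link deaths to admissions under the selected strategies
#'
#' Reads the dataset files written by [run_simulate()] (or user-supplied
#' files in the same schema), deduplicates death records (one per MLK
#' person, randomly retained), runs the selected strategies, and writes one
#' `links_<strategy>.csv` per strategy (columns `death_record_id`,
#' `admission_record_id`, `strategy`, `ambiguous_flag`), the retained
#' deaths, and a `linkage_summary.csv` of per-strategy counts.
#'
#' @param data_dir directory holding `admissions.csv`, `deaths.csv`,
#'   `mlk.csv`.
#' @param out_dir output directory (defaults to `data_dir`).
#' @param strategies strategies to run (see [run_strategies()]).
#' @param seed seed for the duplicate-death selection.
#' @return invisibly, the named list of [linkage_result]s.
#' @export
run_link <- function(data_dir, out_dir = data_dir,
                     strategies = c("full_probabilistic", "basic_slk",
                                    "most_recent_slk", "most_frequent_slk",
                                    "any_match_slk"),
                     seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  admissions <- read_records(file.path(data_dir, "admissions.csv"),
                             c("record_id", "separation_date"))
  deaths <- read_records(file.path(data_dir, "deaths.csv"),
                         c("record_id", "death_date"))
  mlk <- read_records(file.path(data_dir, "mlk.csv"),
                      c("record_id", "person_key"))
  retained <- dedupe_deaths(deaths, mlk, seed = derive_seed(seed, "dedupe"))
  results <- run_strategies(retained, admissions, mlk, strategies)
  write_pipeline_csv(retained, file.path(out_dir, "retained_deaths.csv"),
                     seed)
  for (nm in names(results)) {
    res <- results[[nm]]
    links <- data.frame(
      death_record_id = res$links$death_id,
      admission_record_id = res$links$admission_id,
      strategy = nm,
      ambiguous_flag = res$links$death_id %in% res$ambiguous,
      stringsAsFactors = FALSE)
    write_pipeline_csv(links, file.path(out_dir,
                                        paste0("links_", nm, ".csv")), seed)
  }
  smry <- do.call(rbind, lapply(results, summary))
  rownames(smry) <- NULL
  write_pipeline_csv(smry, file.path(out_dir, "linkage_summary.csv"), seed)
  invisible(results)
}

read_records <- function(path, required_cols) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- read_pipeline_csv(path)
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols))
    stop("file ", basename(path), " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  df
}

rebuild_result <- function(path, retained, strategy) {
  df <- read_pipeline_csv(path)
  new_linkage_result(
    strategy,
    data.frame(death_id = df$death_record_id,
               admission_id = df$admission_record_id,
               stringsAsFactors = FALSE),
    retained$record_id,
    unique(df$death_record_id[df$ambiguous_flag]))
}

#' Evaluate linked files and write the report tables
#'
#' Reads the link files written by [run_link()] and produces the report
#' set: a key-quality table by source/sector, percentage hospitalised and
#' mean/median hospitalisations per decedent by window and strategy,
#' condition-specific rates and rate ratios, and the two yearly error-trend
#' series (missed and false-positive person rates by financial year of
#' admission). The full probabilistic strategy is the reference and must be
#' present.
#'
#' @param data_dir directory holding the dataset and link files.
#' @param out_dir where to write the report CSVs (defaults to `data_dir`).
#' @param windows integer vector of window lengths in financial years
#'   (default 1 through 9, all ending at the final study year).
#' @param final_fy financial-year-end of the death window (default 2009).
#' @param verbose print a console summary.
#' @return invisibly, a named list of the report data.frames.
#' @export
run_evaluate <- function(data_dir, out_dir = data_dir, windows = 1:9,
                         final_fy = 2009L, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  admissions <- read_records(file.path(data_dir, "admissions.csv"),
                             c("record_id", "separation_date"))
  deaths <- read_records(file.path(data_dir, "deaths.csv"),
                         c("record_id", "death_date"))
  retained <- read_records(file.path(data_dir, "retained_deaths.csv"),
                           "record_id")
  link_files <- list.files(data_dir, pattern = "^links_.*\\.csv$",
                           full.names = TRUE)
  strategies <- sub("^links_(.*)\\.csv$", "\\1", basename(link_files))
  if (!"full_probabilistic" %in% strategies)
    stop("run_evaluate: reference strategy 'full_probabilistic' links not ",
         "found; evaluation requires the full probabilistic result")
  results <- setNames(
    lapply(seq_along(link_files),
           function(i) rebuild_result(link_files[i], retained,
                                      strategies[i])),
    strategies)
  reference <- results$full_probabilistic

  admissions$source <- "admissions"
  deaths$source <- "deaths"
  qr_adm <- quality_report(admissions, "separation_date",
                           by = c("source", "sector"))
  qr_dth <- quality_report(deaths, "death_date", by = "source")
  table1 <- rbind(qr_adm, qr_dth)

  t2 <- list(); t3 <- list()
  for (w in windows) {
    win <- fy_window(w, final_fy)
    for (nm in names(results)) {
      st <- hospitalisation_stats(results[[nm]], retained, admissions, win)
      st$strategy <- nm
      t3[[paste(w, nm)]] <- st
      t2[[paste(w, nm)]] <- data.frame(
        window_years = w, strategy = nm,
        percent_hospitalised = st$percent_hospitalised,
        stringsAsFactors = FALSE)
    }
  }
  table2 <- do.call(rbind, t2); rownames(table2) <- NULL
  table3 <- do.call(rbind, t3); rownames(table3) <- NULL

  full_window <- fy_window(max(windows), final_fy)
  table5 <- condition_rates(results, retained, admissions, full_window)

  trends <- lapply(names(results), function(nm) {
    tr <- error_trend_by_year(results[[nm]], reference, admissions)
    tr$strategy <- nm
    tr
  })
  trend <- do.call(rbind, trends)
  figure1 <- trend[, c("fy_end", "fy", "strategy", "n_deaths",
                       "missed_rate")]
  figure2 <- trend[, c("fy_end", "fy", "strategy", "n_deaths", "fp_rate")]

  reports <- list(table1_quality = table1,
                  table2_percent_hospitalised = table2,
                  table3_mean_hospitalisations = table3,
                  table4_median_hospitalisations =
                    table3[, c("window_years", "strategy", "n_deaths",
                               "median", "q25", "q75")],
                  table5_condition_rates = table5,
                  figure1_missed_by_year = figure1,
                  figure2_false_positive_by_year = figure2)
  for (nm in names(reports))
    write_pipeline_csv(reports[[nm]], file.path(out_dir,
                                                paste0(nm, ".csv")))
  if (verbose) {
    cat("Strategies evaluated:", paste(names(results), collapse = ", "),
        "\n")
    cat("Retained deaths:", nrow(retained), "\n")
    full <- table3[table3$window_years == max(windows), ]
    for (i in seq_len(nrow(full)))
      cat(sprintf("  %-20s %%hosp %.1f  mean %.1f (%.1f-%.1f)\n",
                  full$strategy[i], full$percent_hospitalised[i],
                  full$mean[i], full$ci_lo[i], full$ci_hi[i]))
  }
  invisible(reports)
}

#' Run the full simulate - link - evaluate pipeline
#'
#' @param config a [synth_config()].
#' @param out_dir output directory.
#' @param strategies strategies to run.
#' @param windows evaluation window lengths in financial years.
#' @param verbose print a console summary.
#' @return invisibly, the list of report data.frames.
#' @export
run_pipeline <- function(config = synth_config(), out_dir,
                         strategies = c("full_probabilistic", "basic_slk",
                                        "most_recent_slk",
                                        "most_frequent_slk",
                                        "any_match_slk"),
                         windows = 1:9, verbose = FALSE) {
  run_simulate(config, out_dir)
  run_link(out_dir, out_dir, strategies, seed = config$seed)
  run_evaluate(out_dir, out_dir, windows,
               final_fy = fy_end(config$death_window_end),
               verbose = verbose)
}
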