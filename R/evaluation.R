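#' Financial-year helpers
#'
#' The study's time unit is the Australian financial year, 1 July to
#' 30 June. `fy_end()` maps a date to the calendar year in which its
#' financial year ends (2008-09 has `fy_end` 2009); `fy_label()` renders
#' the conventional label; `fy_window()` builds the span of financial
#' years ending in `final` and reaching back `n_years`.
#'
#' @param date a `Date` vector.
#' @param fy_end_year,final integer financial-year-end calendar years.
#' @param n_years window length in financial years.
#' @return integers, labels, or an integer vector of year-ends.
#' @export
fy_end <- function(date) {
  d <- as.Date(date)
  as.integer(format(d, "%Y")) + as.integer(format(d, "%m") >= "07")
}

#' @rdname fy_end
#' @export
fy_label <- function(fy_end_year) {
  sprintf("%d-%02d", fy_end_year - 1L, fy_end_year %% 100L)
}

#' @rdname fy_end
#' @export
fy_window <- function(n_years, final = 2009L) {
  stopifnot(n_years >= 1L)
  seq.int(final - n_years + 1L, final)
}

# links joined to admission separation financial year (and conditions)
links_with_admissions <- function(result, admissions,
                                  cols = "separation_date") {
  l <- data.table::as.data.table(result$links)
  a <- data.table::as.data.table(
    admissions[, c("record_id", cols), drop = FALSE])
  data.table::setnames(a, "record_id", "admission_id")
  merge(l, a, by = "admission_id")
}

#' Compare a linkage strategy to the reference strategy
#'
#' For each retained death with reference link set R and strategy link set
#' S, the death has a missed link when `R \ S` is non-empty and a false
#' positive link when `S \ R` is non-empty (both can hold simultaneously).
#' Person-level rates are proportions over retained deaths that have at
#' least one reference link.
#'
#' @param result strategy [linkage_result].
#' @param reference reference [linkage_result] (full probabilistic), over
#'   the same retained deaths.
#' @return list of class `link_comparison`: `per_death` data.frame
#'   (`death_id`, `missed_any`, `false_any`, `n_ref`, `n_strategy`),
#'   `missed_rate`, `fp_rate`, `n_eval` (denominator), `strategy`.
#' @export
compare_links <- function(result, reference) {
  if (!identical(result$deaths, reference$deaths))
    stop("compare_links: the two results cover different retained deaths")
  r <- data.table::as.data.table(reference$links)
  s <- data.table::as.data.table(result$links)
  missed <- r[!s, on = c("death_id", "admission_id")]
  false <- s[!r, on = c("death_id", "admission_id")]
  per <- data.table::data.table(death_id = reference$deaths)
  nref <- r[, .N, by = "death_id"]
  nstr <- s[, .N, by = "death_id"]
  per <- merge(per, nref, by = "death_id", all.x = TRUE)
  data.table::setnames(per, "N", "n_ref")
  per <- merge(per, nstr, by = "death_id", all.x = TRUE)
  data.table::setnames(per, "N", "n_strategy")
  per$n_ref[is.na(per$n_ref)] <- 0L
  per$n_strategy[is.na(per$n_strategy)] <- 0L
  per[, "missed_any" := death_id %in% missed$death_id]
  per[, "false_any" := death_id %in% false$death_id]
  denom <- per[n_ref > 0L]
  structure(list(
    per_death = data.frame(per, stringsAsFactors = FALSE),
    missed_rate = if (nrow(denom)) mean(denom$missed_any) else 0,
    fp_rate = if (nrow(denom)) mean(denom$false_any) else 0,
    n_eval = nrow(denom), strategy = result$strategy),
    class = "link_comparison")
}

#' Missed- and false-positive-link rates by financial year
#'
#' For each financial year of admission, the proportion of decedents with
#' at least one missed (resp. false positive) link among their reference
#' (resp. strategy) records separated in that year; the denominator is the
#' decedents with at least one reference record in the year. Because all
#' deaths fall in the final year, earlier financial years correspond to
#' more years before death.
#'
#' @param result,reference [linkage_result]s over the same retained deaths.
#' @param admissions admission records with `separation_date`.
#' @return data.frame: `fy_end`, `fy`, `n_deaths`, `missed_rate`,
#'   `fp_rate`.
#' @export
error_trend_by_year <- function(result, reference, admissions) {
  if (!identical(result$deaths, reference$deaths))
    stop("error_trend_by_year: results cover different retained deaths")
  r <- links_with_admissions(reference, admissions)
  s <- links_with_admissions(result, admissions)
  r[, "fy_end" := fy_end(separation_date)]
  s[, "fy_end" := fy_end(separation_date)]
  rl <- data.table::as.data.table(reference$links)
  sl <- data.table::as.data.table(result$links)
  missed <- r[!sl, on = c("death_id", "admission_id")]
  false <- s[!rl, on = c("death_id", "admission_id")]
  denom <- unique(r[, c("fy_end", "death_id")])[, .N, by = "fy_end"]
  nmiss <- unique(missed[, c("fy_end", "death_id")])[, .N, by = "fy_end"]
  nfalse <- unique(false[, c("fy_end", "death_id")])[, .N, by = "fy_end"]
  out <- merge(denom, nmiss, by = "fy_end", all.x = TRUE,
               suffixes = c("", "_miss"))
  data.table::setnames(out, c("N", "N_miss"), c("n_deaths", "n_missed"))
  out <- merge(out, nfalse, by = "fy_end", all.x = TRUE)
  data.table::setnames(out, "N", "n_false")
  out$n_missed[is.na(out$n_missed)] <- 0L
  out$n_false[is.na(out$n_false)] <- 0L
  out[, "missed_rate" := n_missed / n_deaths]
  out[, "fp_rate" := n_false / n_deaths]
  out[, "fy" := fy_label(fy_end)]
  data.table::setorder(out, fy_end)
  data.frame(out[, c("fy_end", "fy", "n_deaths", "missed_rate", "fp_rate")],
             stringsAsFactors = FALSE)
}

# per retained death, the number of linked admissions separated within the
# financial-year window (zero for unlinked deaths)
window_counts <- function(result, retained_deaths, admissions, window) {
  l <- links_with_admissions(result, admissions)
  l <- l[fy_end(separation_date) %in% window]
  cnt <- l[, .N, by = "death_id"]
  out <- data.table::data.table(death_id = retained_deaths$record_id)
  out <- merge(out, cnt, by = "death_id", all.x = TRUE)
  out$N[is.na(out$N)] <- 0L
  data.table::setnames(out, "N", "n_admissions")
  out
}

#' Percentage of decedents hospitalised within a window
#'
#' 100 times the share of retained deaths with at least one linked
#' admission separated in the financial-year window; the denominator is
#' all retained deaths, including those that did not link at all.
#'
#' @param result a [linkage_result].
#' @param retained_deaths the deduplicated death records.
#' @param admissions admission records with `separation_date`.
#' @param window integer vector of financial-year-ends (see
#'   [fy_window()]).
#' @return a single percentage.
#' @export
percent_hospitalised <- function(result, retained_deaths, admissions,
                                 window) {
  if (nrow(retained_deaths) == 0L) return(0)
  cnt <- window_counts(result, retained_deaths, admissions, window)
  100 * mean(cnt$n_admissions > 0L)
}

#' Hospitalisations per decedent within a window
#'
#' Mean (with a normal-approximation 95% confidence interval,
#' mean +/- 1.96 sd/sqrt(n)), median and quartiles of the number of linked
#' admissions per retained death in the window. Counts include zeros for
#' unlinked decedents; quartiles use the inverse-ECDF quantile so integer
#' counts yield integer quartiles.
#'
#' @inheritParams percent_hospitalised
#' @return data.frame with `window_years`, `n_deaths`, `percent_hospitalised`,
#'   `mean`, `ci_lo`, `ci_hi`, `median`, `q25`, `q75`.
#' @export
hospitalisation_stats <- function(result, retained_deaths, admissions,
                                  window) {
  cnt <- window_counts(result, retained_deaths, admissions, window)
  x <- cnt$n_admissions
  n <- length(x)
  m <- mean(x)
  half <- if (n > 1L) 1.96 * sd(x) / sqrt(n) else 0
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 1, names = FALSE)
  data.frame(
    window_years = length(window), n_deaths = n,
    percent_hospitalised = 100 * mean(x > 0L),
    mean = m, ci_lo = m - half, ci_hi = m + half,
    median = q[2], q25 = q[1], q75 = q[3], stringsAsFactors = FALSE)
}

#' Condition-specific hospitalisation rates and rate ratios
#'
#' For each condition label and strategy: the percentage of retained deaths
#' with at least one linked in-window admission carrying the label, and the
#' ratio of that rate to the reference (full probabilistic) strategy's
#' rate, rounded to two decimals (reference ratio is 1.00 by construction).
#'
#' @param results named list of [linkage_result]s, including the reference.
#' @param reference name of the reference element (default
#'   `"full_probabilistic"`).
#' @param retained_deaths the deduplicated death records.
#' @param admissions admission records with `separation_date` and
#'   `conditions` (semicolon-separated labels).
#' @param window integer vector of financial-year-ends.
#' @param conditions labels to tabulate; default all labels observed in
#'   `admissions`. An unknown label is an error.
#' @return data.frame: `condition`, `strategy`, `rate`, `rate_ratio`.
#' @export
condition_rates <- function(results, retained_deaths, admissions, window,
                            reference = "full_probabilistic",
                            conditions = NULL) {
  if (!reference %in% names(results))
    stop("condition_rates: reference strategy '", reference,
         "' not among results")
  observed <- unique(unlist(strsplit(admissions$conditions[
    !is.na(admissions$conditions) & admissions$conditions != ""], ";",
    fixed = TRUE)))
  if (is.null(conditions)) conditions <- sort(observed)
  unknown <- setdiff(conditions, observed)
  if (length(unknown))
    stop("condition_rates: unknown condition label(s): ",
         paste(unknown, collapse = ", "))
  n <- nrow(retained_deaths)
  rate_one <- function(result) {
    l <- links_with_admissions(result, admissions,
                               cols = c("separation_date", "conditions"))
    l <- l[fy_end(separation_date) %in% window]
    vapply(conditions, function(cc) {
      hit <- l[grepl(paste0("(^|;)", cc, "($|;)"), conditions)]
      100 * length(unique(hit$death_id)) / max(1L, n)
    }, numeric(1))
  }
  rates <- lapply(results, rate_one)
  ref_rate <- rates[[reference]]
  out <- do.call(rbind, lapply(names(results), function(snm) {
    data.frame(condition = conditions, strategy = snm,
               rate = rates[[snm]],
               rate_ratio = round(ifelse(ref_rate > 0,
                                         rates[[snm]] / ref_rate, NA_real_),
                                  2),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
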