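#' Tabulate SLK-581 quality by data source
#'
#' Counts and percentages of each incompleteness reason, and of total
#' incomplete keys, per source/sector group — the layout used to audit key
#' quality in admitted-patient versus death-registration data. Percentages
#' are computed against the group's record count. Reason counts within the
#' name group are mutually exclusive; a record contributes to "total
#' incomplete" once however many reasons it carries.
#'
#' @param records data.frame with identity columns (`surname`, `given_name`,
#'   `birth_date`, `sex`), an event-date column, and grouping columns.
#' @param event_col name of the event-date column (default
#'   `"event_date"`; falls back to `"separation_date"`/`"death_date"` if
#'   present).
#' @param by character vector of grouping column names (default uses
#'   `source` and `sector` where present; otherwise one overall group).
#' @return data.frame in long form: one row per group x reason (plus a
#'   `total_incomplete` row per group) with columns `group`, `reason`,
#'   `count`, `pct`, `n_records`.
#' @examples
#' recs <- data.frame(surname = c("TAYLOR", NA), given_name = c("LEE", NA),
#'                    birth_date = as.Date(c("1946-09-05", "1950-03-02")),
#'                    sex = c("male", "female"),
#'                    event_date = as.Date("2008-09-01"))
#' quality_report(recs)
#' @export
quality_report <- function(records, event_col = NULL, by = NULL) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("quality_report: no records supplied")
  if (is.null(event_col)) {
    event_col <- intersect(c("event_date", "separation_date", "death_date"),
                           names(records))[1]
    if (is.na(event_col)) stop("quality_report: no event-date column found")
  }
  if (is.null(by)) by <- intersect(c("source", "sector"), names(records))

  rm <- classify_incompleteness(records$surname, records$given_name,
                                as.Date(records$birth_date), records$sex,
                                as.Date(records[[event_col]]))
  dt <- data.table::as.data.table(rm)
  dt$total_incomplete <- rowSums(rm) > 0
  if (length(by) > 0L) {
    dt$group <- do.call(paste, c(lapply(by, function(b) records[[b]]),
                                 sep = "/"))
  } else {
    dt$group <- "all"
  }
  long <- dt[, c(lapply(.SD, sum), list(n_records = .N)),
             by = "group", .SDcols = c(SLK_REASONS, "total_incomplete")]
  out <- data.table::melt(
    long, id.vars = c("group", "n_records"),
    measure.vars = c(SLK_REASONS, "total_incomplete"),
    variable.name = "reason", value.name = "count",
    variable.factor = FALSE)
  out[, "pct" := 100 * count / n_records]
  data.table::setcolorder(out, c("group", "reason", "count", "pct",
                                 "n_records"))
  data.table::setorder(out, group)
  data.frame(out, stringsAsFactors = FALSE)
}

#' Pivot a quality report to the reason-by-source table layout
#'
#' Reshapes the long output of [quality_report()] to one row per reason and
#' a count and percentage column per group, the familiar audit-table shape.
#'
#' @param report output of [quality_report()].
#' @return data.frame, rows ordered as [SLK_REASONS] then total incomplete.
#' @export
quality_report_wide <- function(report) {
  dt <- data.table::as.data.table(report)
  dt[, "pct" := round(pct, 1)]
  w <- data.table::dcast(dt, reason ~ group, value.var = c("count", "pct"))
  ord <- match(c(SLK_REASONS, "total_incomplete"), w$reason)
  data.frame(w[ord[!is.na(ord)], ], stringsAsFactors = FALSE)
}
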