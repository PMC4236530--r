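#' @name linkage_result
#' @title Linkage result container
#' @description All five strategies return a `linkage_result`: the strategy
#'   label, a `links` table (`death_id`, `admission_id`), the retained death
#'   record ids (`deaths`, so deaths with no links are represented), and the
#'   ids of deaths whose SLK matched more than one MLK person (`ambiguous`;
#'   such deaths link to the union of the matched groups).
NULL

new_linkage_result <- function(strategy, links, deaths, ambiguous = character(0)) {
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (nrow(links) == 0L)
    links <- data.frame(death_id = character(0), admission_id = character(0),
                        stringsAsFactors = FALSE)
  names(links) <- c("death_id", "admission_id")
  links <- links[order(links$death_id, links$admission_id), , drop = FALSE]
  rownames(links) <- NULL
  structure(
    list(strategy = strategy, links = links,
         deaths = sort(unique(deaths)), ambiguous = sort(unique(ambiguous))),
    class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  n_linked <- length(unique(x$links$death_id))
  cat("<linkage_result> strategy:", x$strategy, "\n",
      " deaths:", length(x$deaths),
      "| linked:", n_linked,
      "| unlinked:", length(x$deaths) - n_linked,
      "| admission links:", nrow(x$links),
      "| ambiguous:", length(x$ambiguous), "\n")
  invisible(x)
}

#' Summarise a linkage result in the counts-reporting shape
#'
#' @param object a `linkage_result`.
#' @param ... unused.
#' @return data.frame with strategy, deaths retained/linked/unlinked,
#'   percent unlinked, admission records linked, ambiguous deaths.
#' @export
summary.linkage_result <- function(object, ...) {
  n <- length(object$deaths)
  linked <- length(unique(object$links$death_id))
  data.frame(
    strategy = object$strategy, deaths_retained = n, deaths_linked = linked,
    deaths_unlinked = n - linked,
    pct_unlinked = round(100 * (n - linked) / max(1, n), 1),
    records_linked = nrow(object$links),
    ambiguous_deaths = length(object$ambiguous), stringsAsFactors = FALSE)
}

mlk_lookup <- function(mlk, ids, what) {
  key <- mlk$person_key[match(ids, mlk$record_id)]
  if (anyNA(key)) {
    missing_ids <- ids[is.na(key)]
    stop("record id(s) absent from the MLK: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "),
         if (length(missing_ids) > 5L) " ..." else "",
         " (", what, ")")
  }
  key
}

ensure_slk <- function(records, event_col) {
  if (!all(c("slk", "slk_complete") %in% names(records)))
    records <- add_slk(records, event_col)
  records
}

#' Retain one death record per MLK person
#'
#' Where a person has duplicate death registrations, one record is selected
#' uniformly at random and retained; the same retained set is then used by
#' every linkage strategy. Deterministic given `seed`.
#'
#' @param deaths death record data.frame with `record_id`.
#' @param mlk MLK covering the death record ids.
#' @param seed integer seed for the random selection.
#' @return the retained subset of `deaths`.
#' @export
dedupe_deaths <- function(deaths, mlk, seed = 1L) {
  if (nrow(deaths) == 0L) return(deaths)
  key <- mlk_lookup(mlk, deaths$record_id, "deaths")
  set.seed(as.integer(seed))
  u <- runif(nrow(deaths))
  keep <- unlist(lapply(split(seq_len(nrow(deaths)), key),
                        function(ix) ix[which.min(u[ix])]),
                 use.names = FALSE)
  out <- deaths[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strategy 1: link via the supplied probabilistic person grouping
#'
#' Each death links to exactly the admission records sharing its MLK person
#' key. This is the reference ("full probabilistic") strategy: the MLK is
#' taken as given, the product of an external probabilistic linkage.
#'
#' @param deaths retained death records.
#' @param admissions admission records.
#' @param mlk MLK covering all record ids (error, naming the id, if not).
#' @return a [linkage_result].
#' @export
link_full_probabilistic <- function(deaths, admissions, mlk) {
  dkey <- mlk_lookup(mlk, deaths$record_id, "deaths")
  akey <- if (nrow(admissions)) {
    mlk_lookup(mlk, admissions$record_id, "admissions")
  } else character(0)
  d <- data.table::data.table(death_id = deaths$record_id, person_key = dkey)
  a <- data.table::data.table(admission_id = admissions$record_id,
                              person_key = akey)
  links <- merge(d, a, by = "person_key", allow.cartesian = TRUE)
  new_linkage_result("full_probabilistic",
                     links[, c("death_id", "admission_id")],
                     deaths$record_id)
}

#' Strategy 2: basic SLK-581 linkage
#'
#' A death links to every admission whose 14-character SLK-581 equals its
#' own exactly, dummy characters included; the MLK plays no part. SLK
#' columns are computed on the fly if absent.
#'
#' @param deaths retained death records.
#' @param admissions admission records.
#' @return a [linkage_result].
#' @export
link_basic_slk <- function(deaths, admissions) {
  deaths <- ensure_slk(deaths, "death_date")
  admissions <- ensure_slk(admissions, "separation_date")
  d <- data.table::data.table(death_id = deaths$record_id, slk = deaths$slk)
  a <- data.table::data.table(admission_id = admissions$record_id,
                              slk = admissions$slk)
  links <- merge(d, a, by = "slk", allow.cartesian = TRUE)
  new_linkage_result("basic_slk", links[, c("death_id", "admission_id")],
                     deaths$record_id)
}

# per-person choice of a representative SLK; `how` is "recent" or "frequent"
person_slk_table <- function(admissions, mlk, how) {
  admissions <- ensure_slk(admissions, "separation_date")
  if (nrow(admissions) == 0L)
    return(data.frame(person_key = character(0), slk = character(0),
                      stringsAsFactors = FALSE))
  dt <- data.table::data.table(
    person_key = mlk_lookup(mlk, admissions$record_id, "admissions"),
    slk = admissions$slk, complete = admissions$slk_complete,
    separation_date = as.Date(admissions$separation_date),
    record_id = admissions$record_id)
  # complete keys take precedence over everything for persons who have any
  dt[, "has_complete" := any(complete), by = "person_key"]
  dt <- dt[complete | !has_complete]
  if (how == "recent") {
    data.table::setorderv(dt, c("person_key", "separation_date", "record_id"),
                          order = c(1L, -1L, -1L))
    rep_slk <- dt[, list(slk = slk[1L]), by = "person_key"]
  } else {
    agg <- dt[, list(n = .N, last_date = max(separation_date),
                     last_id = max(record_id)),
              by = c("person_key", "slk")]
    data.table::setorderv(agg, c("person_key", "n", "last_date", "last_id"),
                          order = c(1L, -1L, -1L, -1L))
    rep_slk <- agg[, list(slk = slk[1L]), by = "person_key"]
  }
  data.frame(rep_slk, stringsAsFactors = FALSE)
}

#' Strategy 3 representative keys: most recent SLK-581 per person
#'
#' Each MLK person with admissions is assigned the SLK-581 of their most
#' recent hospital separation among records with a complete key; a person
#' with no complete key gets the most recent incomplete one. Exact date
#' ties break by largest record id.
#'
#' @param admissions admission records (SLK computed if absent).
#' @param mlk MLK covering the admission record ids.
#' @return data.frame `person_key`, `slk`.
#' @export
person_slk_most_recent <- function(admissions, mlk) {
  person_slk_table(admissions, mlk, "recent")
}

#' Strategy 4 representative keys: most frequent SLK-581 per person
#'
#' Each MLK person with admissions is assigned their modal complete
#' SLK-581; frequency ties break in favour of the tied key borne by the
#' most recent separation (then largest record id). A person with no
#' complete key gets the modal incomplete key under the same tie rules.
#'
#' @inheritParams person_slk_most_recent
#' @return data.frame `person_key`, `slk`.
#' @export
person_slk_most_frequent <- function(admissions, mlk) {
  person_slk_table(admissions, mlk, "frequent")
}

#' Link deaths to persons through representative SLK-581 keys
#'
#' A death matches every MLK person whose representative key equals the
#' death's SLK-581 exactly; it links to the union of all admission records
#' of the matched persons. Deaths matching more than one person are flagged
#' ambiguous.
#'
#' @param deaths retained death records.
#' @param slk_map person-to-representative-key table
#'   ([person_slk_most_recent()] or [person_slk_most_frequent()]).
#' @param admissions admission records.
#' @param mlk the MLK the map was built from.
#' @param strategy label to carry on the result.
#' @return a [linkage_result].
#' @export
link_via_person_slk <- function(deaths, slk_map, admissions, mlk,
                                strategy = "person_slk") {
  deaths <- ensure_slk(deaths, "death_date")
  d <- data.table::data.table(death_id = deaths$record_id, slk = deaths$slk)
  pmap <- data.table::as.data.table(slk_map)
  hits <- merge(d, pmap, by = "slk", allow.cartesian = TRUE)
  amb <- hits[, .N, by = "death_id"][N > 1L]$death_id
  a <- data.table::data.table(
    admission_id = admissions$record_id,
    person_key = if (nrow(admissions))
      mlk_lookup(mlk, admissions$record_id, "admissions") else character(0))
  links <- merge(hits[, c("death_id", "person_key")], a, by = "person_key",
                 allow.cartesian = TRUE)
  links <- unique(links[, c("death_id", "admission_id")])
  new_linkage_result(strategy, links, deaths$record_id, amb)
}

#' Strategy 5: any-match SLK-581 linkage
#'
#' Two stages: first each death is linked to admissions by exact SLK-581
#' match (as in the basic strategy); second, every stage-1 admission
#' record's whole MLK person group (restricted to admissions) is pulled in.
#' The result is therefore always a per-death superset of the basic-SLK
#' result. Deaths whose stage-1 matches span more than one MLK person are
#' flagged ambiguous and link to the union of the groups.
#'
#' @param deaths retained death records.
#' @param admissions admission records.
#' @param mlk MLK covering the admission record ids.
#' @return a [linkage_result].
#' @export
link_any_match <- function(deaths, admissions, mlk) {
  stage1 <- link_basic_slk(deaths, admissions)
  if (nrow(stage1$links) == 0L)
    return(new_linkage_result("any_match_slk", stage1$links,
                              deaths$record_id))
  a <- data.table::data.table(
    admission_id = admissions$record_id,
    person_key = mlk_lookup(mlk, admissions$record_id, "admissions"))
  s1 <- data.table::as.data.table(stage1$links)
  s1 <- merge(s1, a, by = "admission_id")
  amb <- unique(s1[, c("death_id", "person_key")])[, .N, by = "death_id"]
  amb <- amb[N > 1L]$death_id
  expanded <- merge(unique(s1[, c("death_id", "person_key")]), a,
                    by = "person_key", allow.cartesian = TRUE)
  links <- unique(expanded[, c("death_id", "admission_id")])
  new_linkage_result("any_match_slk", links, deaths$record_id, amb)
}

#' Run a set of linkage strategies
#'
#' Dispatches the five strategies over one prepared dataset (SLKs are
#' attached once), returning a named list of [linkage_result]s.
#'
#' @param deaths retained (deduplicated) death records.
#' @param admissions admission records.
#' @param mlk MLK covering all record ids.
#' @param strategies subset of `c("full_probabilistic", "basic_slk",
#'   "most_recent_slk", "most_frequent_slk", "any_match_slk")`.
#' @return named list of [linkage_result]s.
#' @export
run_strategies <- function(deaths, admissions, mlk,
                           strategies = c("full_probabilistic", "basic_slk",
                                          "most_recent_slk",
                                          "most_frequent_slk",
                                          "any_match_slk")) {
  known <- c("full_probabilistic", "basic_slk", "most_recent_slk",
             "most_frequent_slk", "any_match_slk")
  bad <- setdiff(strategies, known)
  if (length(bad))
    stop("unknown strategy name(s): ", paste(bad, collapse = ", "))
  deaths <- ensure_slk(deaths, "death_date")
  admissions <- ensure_slk(admissions, "separation_date")
  out <- list()
  for (s in strategies) {
    out[[s]] <- switch(
      s,
      full_probabilistic = link_full_probabilistic(deaths, admissions, mlk),
      basic_slk = link_basic_slk(deaths, admissions),
      most_recent_slk = link_via_person_slk(
        deaths, person_slk_most_recent(admissions, mlk), admissions, mlk,
        strategy = "most_recent_slk"),
      most_frequent_slk = link_via_person_slk(
        deaths, person_slk_most_frequent(admissions, mlk), admissions, mlk,
        strategy = "most_frequent_slk"),
      any_match_slk = link_any_match(deaths, admissions, mlk))
  }
  out
}
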