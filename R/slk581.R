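#' slklink: SLK-581 record linkage and evaluation
#'
#' Construction and quality assessment of the 14-character statistical
#' linkage key SLK-581, five linkage strategies joining death registrations
#' to hospital admission records, evaluation of each strategy against a
#' reference probabilistic person grouping, and a calibrated synthetic data
#' generator with hidden ground truth.
#'
#' @import data.table
#' @importFrom stats quantile rbinom rnbinom runif sd setNames
#' @importFrom utils modifyList
#' @keywords internal
"_PACKAGE"

#' @name slk_reasons
#' @title Incompleteness reason categories
#' @description The six mutually-tracked reasons a SLK-581 is classified
#'   incomplete: age over 110 years at the event date, missing or invalid
#'   date of birth (including January-1 birthdays), missing both names,
#'   missing surname only, missing given name only, and missing or invalid
#'   sex. Within the name group at most one reason applies; reasons from
#'   different component groups (names, date of birth, sex) may co-occur.
#' @export
SLK_REASONS <- c(
  "age_over_110", "missing_invalid_dob",
  "missing_both_names", "missing_surname_only", "missing_given_only",
  "missing_invalid_sex"
)

#' Normalise a raw name to a canonical letter sequence
#'
#' Uppercases, folds diacritics to ASCII where a transliteration exists, and
#' keeps alphabetic characters only (spaces, hyphens, apostrophes dropped).
#' Empty or whitespace-only input becomes `NA`, as does input with no
#' alphabetic content.
#'
#' @param raw character vector of names as recorded; may contain `NA`.
#' @return character vector of the same length: uppercase A-Z strings or `NA`.
#' @examples
#' normalize_name(c("O'Brien", "van der Berg", "", NA))
#' @export
normalize_name <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  x <- as.character(raw)
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & !grepl("^\\s*$", x)
  if (any(ok)) {
    y <- x[ok]
    # fold diacritics where a mapping exists; unmapped bytes become "?" and
    # are dropped with the other non-letters below
    y2 <- iconv(y, from = "UTF-8", to = "ASCII//TRANSLIT")
    y2[is.na(y2)] <- y[is.na(y2)]
    y2 <- toupper(y2)
    y2 <- gsub("[^A-Z]", "", y2)
    y2[y2 == ""] <- NA_character_
    out[ok] <- y2
  }
  out
}

#' Extract letters at fixed ordinal positions from a normalised name
#'
#' Positions beyond the end of a short-but-present name yield the padding
#' character `"2"`; a missing name yields `"9"` at every position. This is
#' the positional rule behind the SLK-581 name components (surname letters
#' 2, 3, 5; given-name letters 2, 3).
#'
#' @param name character vector of normalised names (see [normalize_name()]),
#'   `NA` for missing.
#' @param positions integer vector of 1-based letter ordinals.
#' @return character vector, each element of width `length(positions)`.
#' @examples
#' extract_letters(c("TAYLOR", "NG", NA), c(2, 3, 5))
#' @export
extract_letters <- function(name, positions) {
  stopifnot(length(positions) >= 1L, all(positions >= 1L))
  n <- length(name)
  if (n == 0L) return(character(0))
  mat <- vapply(positions, function(p) {
    ch <- substr(name, p, p)
    ch[!is.na(name) & ch == ""] <- "2"
    ch[is.na(name)] <- "9"
    ch
  }, character(n))
  if (n == 1L) mat <- matrix(mat, nrow = 1L)
  apply(mat, 1L, paste0, collapse = "")
}

#' Encode a birth date as the 8-character DDMMYYYY component
#'
#' Missing dates render as `"00000000"`. Present dates render literally,
#' zero-padded; validity with respect to the event (January-1 birthdays,
#' age over 110) is assessed separately by [validate_dob()] and affects the
#' completeness flag, not the rendered value.
#'
#' @param birth_date a `Date` vector (or coercible), `NA` for missing.
#' @return character vector of 8-character strings.
#' @export
encode_dob <- function(birth_date) {
  d <- as.Date(birth_date)
  out <- format(d, "%d%m%Y")
  out[is.na(d)] <- "00000000"
  out
}

#' Validate a date of birth against an event date
#'
#' A date of birth is invalid if it is missing, if it falls on January 1 of
#' any year, or if the implied age at the event date exceeds 110 years.
#' Missing and January-1 dates are classified `missing_invalid_dob`;
#' over-age dates are classified `age_over_110` (which takes precedence in
#' the rare case a January-1 birthday is also over-age).
#'
#' @param birth_date `Date` vector, `NA` for missing.
#' @param event_date `Date` vector (recycled), the per-record reference date
#'   (hospital separation date or death date).
#' @return data.frame with columns `valid` (logical) and `reason`
#'   (`NA`, `"missing_invalid_dob"`, or `"age_over_110"`).
#' @export
validate_dob <- function(birth_date, event_date) {
  bd <- as.Date(birth_date)
  ed <- as.Date(event_date)
  if (any(is.na(ed))) stop("event_date must be present for every record")
  n <- max(length(bd), length(ed))
  bd <- rep_len(bd, n); ed <- rep_len(ed, n)
  jan1 <- !is.na(bd) & format(bd, "%m%d") == "0101"
  over110 <- !is.na(bd) & age_at(bd, ed) > 110
  reason <- rep(NA_character_, n)
  reason[is.na(bd) | jan1] <- "missing_invalid_dob"
  reason[over110] <- "age_over_110"
  data.frame(valid = is.na(reason), reason = reason,
             stringsAsFactors = FALSE)
}

# completed years of age at an event date (birthday arithmetic, not /365.25)
age_at <- function(birth_date, event_date) {
  by <- as.integer(format(birth_date, "%Y"))
  ey <- as.integer(format(event_date, "%Y"))
  had_birthday <- format(event_date, "%m%d") >= format(birth_date, "%m%d")
  ey - by - ifelse(had_birthday, 0L, 1L)
}

#' Encode sex as the 1-character SLK-581 component
#'
#' Male codes `"1"`, female `"2"`; anything else (missing or other values)
#' codes `"9"` and is flagged invalid.
#'
#' @param sex character vector; `"male"`/`"female"` are valid (case
#'   insensitive), everything else invalid.
#' @return data.frame with columns `code` (character) and `valid` (logical).
#' @export
encode_sex <- function(sex) {
  s <- tolower(as.character(sex))
  code <- rep("9", length(s))
  code[!is.na(s) & s == "male"] <- "1"
  code[!is.na(s) & s == "female"] <- "2"
  data.frame(code = code, valid = code != "9", stringsAsFactors = FALSE)
}

#' Classify the incompleteness reasons of an identity
#'
#' Returns, per record, which of the six reason categories apply. Within the
#' name group exactly one of missing-both / missing-surname-only /
#' missing-given-only applies (or none); the date-of-birth group contributes
#' at most one of age-over-110 / missing-invalid-DOB; the sex group
#' contributes missing-invalid-sex. Reasons across groups may co-occur.
#'
#' @param surname,given_name raw name vectors (normalised internally).
#' @param birth_date,sex identity components.
#' @param event_date per-record reference date for the age check.
#' @return logical matrix with one row per record and one column per
#'   category in [SLK_REASONS].
#' @export
classify_incompleteness <- function(surname, given_name, birth_date, sex,
                                    event_date) {
  sn <- normalize_name(surname)
  gn <- normalize_name(given_name)
  dv <- validate_dob(birth_date, event_date)
  sv <- encode_sex(sex)
  n <- length(sn)
  m <- matrix(FALSE, nrow = n, ncol = length(SLK_REASONS),
              dimnames = list(NULL, SLK_REASONS))
  m[, "missing_both_names"] <- is.na(sn) & is.na(gn)
  m[, "missing_surname_only"] <- is.na(sn) & !is.na(gn)
  m[, "missing_given_only"] <- !is.na(sn) & is.na(gn)
  m[, "age_over_110"] <- !is.na(dv$reason) & dv$reason == "age_over_110"
  m[, "missing_invalid_dob"] <- !is.na(dv$reason) & dv$reason == "missing_invalid_dob"
  m[, "missing_invalid_sex"] <- !sv$valid
  m
}

#' Build SLK-581 keys from personal identifiers
#'
#' Concatenates letters 2, 3 and 5 of the surname, letters 2 and 3 of the
#' given name, the date of birth as DDMMYYYY and a one-character sex code
#' into a key of exactly 14 characters, with dummy characters for short or
#' missing components. A key is complete iff no incompleteness reason
#' applies; short-but-present names are complete (padding is not
#' missingness).
#'
#' @param surname,given_name character vectors, names as recorded.
#' @param birth_date `Date` vector, `NA` allowed.
#' @param sex character vector (`"male"`/`"female"`/other).
#' @param event_date `Date` vector (recycled), reference date for the age
#'   validity check.
#' @return data.frame with columns `slk` (14-character key), `complete`
#'   (logical), and `reasons` (semicolon-separated reason labels, `""` when
#'   complete).
#' @examples
#' build_slk("TAYLOR", "LEE", as.Date("1946-09-05"), "male",
#'           as.Date("2008-09-01"))
#' @export
build_slk <- function(surname, given_name, birth_date, sex, event_date) {
  sn <- normalize_name(surname)
  gn <- normalize_name(given_name)
  value <- paste0(
    extract_letters(sn, c(2L, 3L, 5L)),
    extract_letters(gn, c(2L, 3L)),
    encode_dob(birth_date),
    encode_sex(sex)$code
  )
  rm <- classify_incompleteness(surname, given_name, birth_date, sex,
                                event_date)
  reasons <- apply(rm, 1L, function(r) paste(SLK_REASONS[r], collapse = ";"))
  data.frame(slk = value, complete = reasons == "", reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Attach SLK-581 columns to a record table
#'
#' Convenience wrapper: computes [build_slk()] over a data.frame carrying
#' identity columns (`surname`, `given_name`, `birth_date`, `sex`) and a
#' per-record event-date column, and binds `slk`, `slk_complete`,
#' `slk_reasons` columns.
#'
#' @param records data.frame of records.
#' @param event_col name of the event-date column (e.g. `"separation_date"`
#'   or `"death_date"`).
#' @return `records` with the three SLK columns appended.
#' @export
add_slk <- function(records, event_col) {
  stopifnot(is.data.frame(records), event_col %in% names(records))
  if (nrow(records) == 0L) {
    records$slk <- character(0)
    records$slk_complete <- logical(0)
    records$slk_reasons <- character(0)
    return(records)
  }
  k <- build_slk(records$surname, records$given_name,
                 as.Date(records$birth_date), records$sex,
                 as.Date(records[[event_col]]))
  records$slk <- k$slk
  records$slk_complete <- k$complete
  records$slk_reasons <- k$reasons
  records
}
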