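#' Configuration for the synthetic linkage study generator
#'
#' Assembles and validates the parameter set controlling the synthetic
#' population of persons, hospital admission records, death registrations,
#' and the error-injected master linkage key (MLK). Defaults emulate the
#' structure of a large Australian admitted-patient / death-registration
#' linkage study: a 65.1/34.9 public/private sector mix; missing-both-names
#' rates of 10.9% (public, flat over time) and 71.1% (private, declining
#' linearly from ~80% to ~62% across the study window); rare invalid dates
#' of birth and sex; death records whose identifiers are incomplete for
#' 0.6% of records, via the date of birth only; a mean of 12.8 admissions
#' per decedent over the nine-year window; and MLK error rates of 5/1000
#' missed and 3/1000 false-positive links.
#'
#' @param n_persons number of persons to simulate.
#' @param p_decedent fraction of persons who die in the death window; the
#'   rest are background population who may still accrue admissions.
#' @param study_start,study_end study window (admission separation dates).
#' @param death_window_start,death_window_end window containing all deaths.
#' @param p_public probability an admission is in the public sector.
#' @param missing_name_rate_public,missing_name_rate_private probability
#'   both names are blanked on an admission record, by sector (private rate
#'   is the time-average).
#' @param private_missing_trend total linear decline of the private
#'   missing-name rate across the study window (start = mean + trend/2,
#'   end = mean - trend/2); 0 disables the trend.
#' @param invalid_dob_rate probability a record's date of birth is
#'   invalidated (blanked, or set to January 1).
#' @param invalid_sex_rate probability a record's sex is invalidated.
#' @param death_incomplete_rate probability a death record's identifiers are
#'   incomplete (drawn as an invalid date of birth; names are never missing
#'   on death records).
#' @param admissions_mean,admissions_dispersion negative-binomial mean and
#'   size (dispersion) of admissions per decedent over the study window.
#' @param background_admissions_mean mean admissions per non-decedent.
#' @param mlk_missed_rate,mlk_fp_rate per-record error-injection rates for
#'   the perturbed MLK.
#' @param mlk_error_weight_incomplete relative weight with which MLK error
#'   injection concentrates on records whose SLK-581 is incomplete
#'   (probabilistic linkage errors cluster in records with poor
#'   identifiers); 1 makes the injection uniform. The overall per-record
#'   rates are preserved either way.
#' @param name_variant_rate probability a record's surname or given name is
#'   replaced by a spelling variant (one perturbed letter).
#' @param duplicate_death_rate probability a decedent has a duplicate death
#'   registration record.
#' @param condition_prevalences data.frame with columns `condition`,
#'   `prevalence` (per-admission probability in the public sector) and
#'   `private_rr` (relative risk in the private sector); labels are
#'   abstract condition names.
#' @param name_pool_size,name_skew size of the surname/given-name pools and
#'   the Zipf exponent of their frequency distribution (larger = more
#'   sharing of common names, hence more SLK collisions).
#' @param age_at_death_range ages (completed years) at death, uniform.
#' @param seed master seed; every generation stage derives an independent
#'   substream from it.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_persons = 2000,
                         p_decedent = 0.5,
                         study_start = as.Date("2000-07-01"),
                         study_end = as.Date("2009-06-30"),
                         death_window_start = as.Date("2008-07-01"),
                         death_window_end = as.Date("2009-06-30"),
                         p_public = 0.651,
                         missing_name_rate_public = 0.109,
                         missing_name_rate_private = 0.711,
                         private_missing_trend = 0.18,
                         invalid_dob_rate = 0.005,
                         invalid_sex_rate = 1e-4,
                         death_incomplete_rate = 0.006,
                         admissions_mean = 12.8,
                         admissions_dispersion = 1.5,
                         background_admissions_mean = 1.0,
                         mlk_missed_rate = 0.005,
                         mlk_fp_rate = 0.003,
                         mlk_error_weight_incomplete = 20,
                         name_variant_rate = 0.02,
                         duplicate_death_rate = 0.02,
                         condition_prevalences = default_conditions(),
                         name_pool_size = 500,
                         name_skew = 1.0,
                         age_at_death_range = c(50, 100),
                         seed = 1L) {
  cfg <- list(
    n_persons = as.integer(n_persons), p_decedent = p_decedent,
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    death_window_start = as.Date(death_window_start),
    death_window_end = as.Date(death_window_end),
    p_public = p_public,
    missing_name_rate_public = missing_name_rate_public,
    missing_name_rate_private = missing_name_rate_private,
    private_missing_trend = private_missing_trend,
    invalid_dob_rate = invalid_dob_rate,
    invalid_sex_rate = invalid_sex_rate,
    death_incomplete_rate = death_incomplete_rate,
    admissions_mean = admissions_mean,
    admissions_dispersion = admissions_dispersion,
    background_admissions_mean = background_admissions_mean,
    mlk_missed_rate = mlk_missed_rate, mlk_fp_rate = mlk_fp_rate,
    mlk_error_weight_incomplete = mlk_error_weight_incomplete,
    name_variant_rate = name_variant_rate,
    duplicate_death_rate = duplicate_death_rate,
    condition_prevalences = as.data.frame(condition_prevalences),
    name_pool_size = as.integer(name_pool_size), name_skew = name_skew,
    age_at_death_range = age_at_death_range,
    seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

default_conditions <- function() {
  data.frame(
    condition = c("cancer", "cardiovascular", "diabetes", "arthritis"),
    prevalence = c(0.10, 0.25, 0.12, 0.05),
    private_rr = c(1.0, 0.9, 0.6, 3.0),
    stringsAsFactors = FALSE)
}

#' Validate a generator configuration
#'
#' Checks proportions, window ordering and the condition table; errors with
#' a message naming the offending field.
#'
#' @param cfg a [synth_config()].
#' @return the configuration, invisibly, if valid.
#' @export
validate_synth_config <- function(cfg) {
  props <- c("p_decedent", "p_public", "missing_name_rate_public",
             "missing_name_rate_private", "invalid_dob_rate",
             "invalid_sex_rate", "death_incomplete_rate", "mlk_missed_rate",
             "mlk_fp_rate", "name_variant_rate", "duplicate_death_rate")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("synth_config: ", p, " must be a proportion in [0, 1]")
  }
  if (cfg$n_persons < 0) stop("synth_config: n_persons must be >= 0")
  if (cfg$study_start > cfg$study_end)
    stop("synth_config: study window dates out of order")
  if (cfg$death_window_start > cfg$death_window_end)
    stop("synth_config: death window dates out of order")
  if (cfg$death_window_end > cfg$study_end ||
      cfg$death_window_start < cfg$study_start)
    stop("synth_config: death window must lie within the study window")
  if (cfg$admissions_mean < 0 || cfg$background_admissions_mean < 0 ||
      cfg$admissions_dispersion <= 0)
    stop("synth_config: admission count parameters must be positive")
  cp <- cfg$condition_prevalences
  if (!all(c("condition", "prevalence", "private_rr") %in% names(cp)))
    stop("synth_config: condition_prevalences needs columns condition, ",
         "prevalence, private_rr")
  invisible(cfg)
}

# independent substream per generation stage (D-style seed derivation):
# a change to one stage's parameters must not shift another stage's draws
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

zipf_weights <- function(n, skew) (1 / seq_len(n)^skew)

random_name_pool <- function(n, min_len = 4L, max_len = 8L) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(l)
    paste0(sample(LETTERS, l, replace = TRUE), collapse = ""), character(1))
}

# canonical dates of birth are always valid: never January 1 (reserved as
# the injected sentinel) and never implying age > 110
sample_birth_dates <- function(ref_dates, ages) {
  offs <- sample.int(364L, length(ref_dates), replace = TRUE)  # 1..364 days
  bd <- as.Date(paste0(as.integer(format(ref_dates, "%Y")) - ages - 1L,
                       "-12-31")) + offs
  jan1 <- format(bd, "%m%d") == "0101"
  bd[jan1] <- bd[jan1] + 1L
  bd
}

#' Generate the synthetic person population
#'
#' Persons carry a unique hidden `true_id`, a canonical (fully valid)
#' identity, and for decedents a death date uniform in the death window.
#' Names are drawn from skewed frequency pools so a small fraction of
#' persons share an SLK-581, which is what makes purely deterministic
#' linkage fallible even with complete data.
#'
#' @param config a [synth_config()].
#' @return data.frame: `true_id`, `surname`, `given_name`, `birth_date`,
#'   `sex`, `death_date` (`NA` for survivors).
#' @export
generate_population <- function(config) {
  validate_synth_config(config)
  n <- config$n_persons
  if (n == 0L) {
    return(data.frame(true_id = character(0), surname = character(0),
                      given_name = character(0),
                      birth_date = as.Date(character(0)),
                      sex = character(0),
                      death_date = as.Date(character(0)),
                      stringsAsFactors = FALSE))
  }
  set.seed(derive_seed(config$seed, "population"))
  sur_pool <- random_name_pool(config$name_pool_size)
  giv_pool <- random_name_pool(config$name_pool_size, 3L, 7L)
  w <- zipf_weights(config$name_pool_size, config$name_skew)
  surname <- sample(sur_pool, n, replace = TRUE, prob = w)
  given <- sample(giv_pool, n, replace = TRUE, prob = w)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  dies <- runif(n) < config$p_decedent
  span <- as.integer(config$death_window_end - config$death_window_start)
  death_date <- as.Date(rep(NA, n))
  death_date[dies] <- config$death_window_start +
    sample.int(span + 1L, sum(dies), replace = TRUE) - 1L
  ref <- death_date
  ref[!dies] <- config$study_end
  ages <- sample(config$age_at_death_range[1]:config$age_at_death_range[2],
                 n, replace = TRUE)
  birth_date <- sample_birth_dates(ref, ages)
  data.frame(
    true_id = sprintf("P%06d", seq_len(n)),
    surname = surname, given_name = given, birth_date = birth_date,
    sex = sex, death_date = death_date, stringsAsFactors = FALSE)
}

#' Degrade a recorded identity with sector-specific missingness
#'
#' Blanks both names at the sector's missing-name rate (the private-sector
#' rate declines linearly over the study window when
#' `private_missing_trend > 0`), invalidates the date of birth (blank or
#' January 1, equiprobable) at `invalid_dob_rate`, and invalidates sex at
#' `invalid_sex_rate`. Events are independent. Must be called inside a
#' seeded RNG stream.
#'
#' @param identity data.frame with `surname`, `given_name`, `birth_date`,
#'   `sex` (one row per record).
#' @param sector character vector `"public"`/`"private"` per record.
#' @param event_date per-record date used to position the record on the
#'   private-sector quality trend.
#' @param config a [synth_config()].
#' @return the identity data.frame with missingness applied.
#' @export
apply_missingness <- function(identity, sector, event_date, config) {
  n <- nrow(identity)
  if (n == 0L) return(identity)
  frac <- as.numeric(as.Date(event_date) - config$study_start) /
    max(1, as.numeric(config$study_end - config$study_start))
  frac <- pmin(pmax(frac, 0), 1)
  rate_priv <- config$missing_name_rate_private +
    config$private_missing_trend * (0.5 - frac)
  rate_priv <- pmin(pmax(rate_priv, 0), 1)
  rate <- ifelse(sector == "private", rate_priv,
                 config$missing_name_rate_public)
  blank <- runif(n) < rate
  identity$surname[blank] <- NA_character_
  identity$given_name[blank] <- NA_character_
  bad_dob <- runif(n) < config$invalid_dob_rate
  if (any(bad_dob)) {
    to_jan1 <- bad_dob & runif(n) < 0.5
    to_na <- bad_dob & !to_jan1
    bd <- as.Date(identity$birth_date)
    if (any(to_jan1))
      bd[to_jan1] <- as.Date(paste0(format(bd[to_jan1], "%Y"), "-01-01"))
    bd[to_na] <- NA
    identity$birth_date <- bd
  }
  bad_sex <- runif(n) < config$invalid_sex_rate
  identity$sex[bad_sex] <- NA_character_
  identity
}

# replace one letter of the surname or given name (even chance) with a
# random different letter; this is what makes a person's recorded SLK drift.
# `rate` may be a per-record vector (identity drift grows with time before
# the identity was fixed at death)
perturb_names <- function(identity, rate) {
  n <- nrow(identity)
  hit <- runif(n) < rate
  if (!any(hit)) return(identity)
  which_col <- ifelse(runif(n) < 0.5, "surname", "given_name")
  for (i in which(hit)) {
    nm <- identity[[which_col[i]]][i]
    if (is.na(nm) || nchar(nm) == 0L) next
    pos <- sample.int(nchar(nm), 1L)
    repl <- sample(setdiff(LETTERS, substr(nm, pos, pos)), 1L)
    substr(nm, pos, pos) <- repl
    identity[[which_col[i]]][i] <- nm
  }
  identity
}

#' Generate synthetic hospital admission records
#'
#' Per-decedent admission counts are negative-binomial with the configured
#' mean and dispersion; non-decedents draw from the background mean.
#' Separation dates are uniform over the person's at-risk span (study start
#' to death or study end). Sector is public with probability `p_public`.
#' The recorded identity is the canonical identity passed through the
#' name-variant process and [apply_missingness()]; condition labels attach
#' per admission with sector-dependent probabilities.
#'
#' @param persons output of [generate_population()].
#' @param config a [synth_config()].
#' @return data.frame of admission records: `record_id`, `true_id`,
#'   identity columns as recorded, `separation_date`, `sector`,
#'   `conditions` (semicolon-separated labels, possibly empty).
#' @export
generate_admissions <- function(persons, config) {
  validate_synth_config(config)
  empty <- data.frame(
    record_id = character(0), true_id = character(0),
    surname = character(0), given_name = character(0),
    birth_date = as.Date(character(0)), sex = character(0),
    separation_date = as.Date(character(0)), sector = character(0),
    conditions = character(0), stringsAsFactors = FALSE)
  if (nrow(persons) == 0L) return(empty)
  set.seed(derive_seed(config$seed, "admissions"))
  dec <- !is.na(persons$death_date)
  mu <- ifelse(dec, config$admissions_mean, config$background_admissions_mean)
  counts <- rnbinom(nrow(persons), size = config$admissions_dispersion,
                    mu = mu)
  if (sum(counts) == 0L) return(empty)
  idx <- rep(seq_len(nrow(persons)), counts)
  m <- length(idx)
  end <- persons$death_date[idx]
  end[is.na(end)] <- config$study_end
  span <- pmax(0, as.numeric(end - config$study_start))
  sep_date <- config$study_start + floor(runif(m) * (span + 1))
  sector <- ifelse(runif(m) < config$p_public, "public", "private")
  identity <- persons[idx, c("surname", "given_name", "birth_date", "sex")]
  rownames(identity) <- NULL
  # identity drift: recorded names diverge from the identity fixed at
  # death the further back the separation lies (mean rate preserved)
  frac <- as.numeric(sep_date - config$study_start) /
    max(1, as.numeric(config$study_end - config$study_start))
  identity <- perturb_names(identity,
                            config$name_variant_rate * 2 * (1 - frac))
  identity <- apply_missingness(identity, sector, sep_date, config)
  cp <- config$condition_prevalences
  cond_mat <- vapply(seq_len(nrow(cp)), function(j) {
    p <- ifelse(sector == "private",
                pmin(1, cp$prevalence[j] * cp$private_rr[j]),
                cp$prevalence[j])
    runif(m) < p
  }, logical(m))
  if (m == 1L) cond_mat <- matrix(cond_mat, nrow = 1L)
  conditions <- apply(cond_mat, 1L,
                      function(r) paste(cp$condition[r], collapse = ";"))
  data.frame(
    record_id = sprintf("A%08d", seq_len(m)),
    true_id = persons$true_id[idx],
    surname = identity$surname, given_name = identity$given_name,
    birth_date = identity$birth_date, sex = identity$sex,
    separation_date = sep_date, sector = sector,
    conditions = conditions, stringsAsFactors = FALSE)
}

#' Generate synthetic death registration records
#'
#' One record per decedent, plus duplicate registrations at
#' `duplicate_death_rate`. Identifier incompleteness occurs at
#' `death_incomplete_rate` and is drawn exclusively as an invalid date of
#' birth (blank or January 1): names are never missing on death records,
#' mirroring the composition observed in registry data.
#'
#' @param persons output of [generate_population()].
#' @param config a [synth_config()].
#' @return data.frame: `record_id`, `true_id`, recorded identity columns,
#'   `death_date`.
#' @export
generate_deaths <- function(persons, config) {
  validate_synth_config(config)
  dec <- persons[!is.na(persons$death_date), , drop = FALSE]
  if (nrow(dec) == 0L) {
    return(data.frame(record_id = character(0), true_id = character(0),
                      surname = character(0), given_name = character(0),
                      birth_date = as.Date(character(0)),
                      sex = character(0),
                      death_date = as.Date(character(0)),
                      stringsAsFactors = FALSE))
  }
  set.seed(derive_seed(config$seed, "deaths"))
  dup <- runif(nrow(dec)) < config$duplicate_death_rate
  idx <- c(seq_len(nrow(dec)), which(dup))
  m <- length(idx)
  bd <- as.Date(dec$birth_date[idx])
  bad <- runif(m) < config$death_incomplete_rate
  if (any(bad)) {
    to_jan1 <- bad & runif(m) < 0.5
    if (any(to_jan1))
      bd[to_jan1] <- as.Date(paste0(format(bd[to_jan1], "%Y"), "-01-01"))
    bd[bad & !to_jan1] <- NA
  }
  data.frame(
    record_id = sprintf("D%06d", seq_len(m)),
    true_id = dec$true_id[idx],
    surname = dec$surname[idx], given_name = dec$given_name[idx],
    birth_date = bd, sex = dec$sex[idx],
    death_date = dec$death_date[idx], stringsAsFactors = FALSE)
}

#' Run the full synthetic generation pipeline
#'
#' Population, admissions, deaths, ground-truth MLK and the error-injected
#' MLK, all from one master seed with independent per-stage substreams.
#'
#' @param config a [synth_config()].
#' @return list with elements `persons`, `admissions`, `deaths`,
#'   `mlk_true`, `mlk`, `config`.
#' @export
simulate_study <- function(config = synth_config()) {
  persons <- generate_population(config)
  admissions <- generate_admissions(persons, config)
  deaths <- generate_deaths(persons, config)
  mlk_true <- build_true_mlk(admissions, deaths)
  complete <- c(add_slk(admissions, "separation_date")$slk_complete,
                add_slk(deaths, "death_date")$slk_complete)
  w <- ifelse(complete, 1, config$mlk_error_weight_incomplete)
  mlk <- perturb_mlk(mlk_true, config$mlk_missed_rate, config$mlk_fp_rate,
                     seed = derive_seed(config$seed, "mlk"),
                     weights = if (length(w)) w else NULL)
  list(persons = persons, admissions = admissions, deaths = deaths,
       mlk_true = mlk_true, mlk = mlk, config = config)
}
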