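#' Build the ground-truth master linkage key
#'
#' The true MLK groups every admission and death record by its hidden
#' `true_id`; it is the error-free person grouping a probabilistic linkage
#' unit would produce if it never erred.
#'
#' @param admissions,deaths record data.frames carrying `record_id` and
#'   `true_id`.
#' @return data.frame with columns `record_id`, `person_key`, one row per
#'   record.
#' @export
build_true_mlk <- function(admissions, deaths) {
  data.frame(
    record_id = c(admissions$record_id, deaths$record_id),
    person_key = c(admissions$true_id, deaths$true_id),
    stringsAsFactors = FALSE)
}

#' Inject linkage errors into a master linkage key
#'
#' Emulates the quality bounds reported by probabilistic linkage units:
#' with probability `missed_rate` a record is split out of its group into a
#' fresh singleton key (a missed link); otherwise, with probability
#' `fp_rate`, it is reassigned into another, uniformly chosen, person group
#' (a false-positive link). The two injections are exclusive per record.
#' Optional per-record `weights` tilt where the errors land (probabilistic
#' linkage errors concentrate in records with poor identifying
#' information) while preserving the overall per-record rates: record `i`
#' is perturbed with probability `rate * weights[i] / mean(weights)`.
#' Deterministic given `seed`.
#'
#' @param mlk data.frame `record_id`/`person_key` (see [build_true_mlk()]).
#' @param missed_rate,fp_rate per-record injection probabilities in
#'   \[0, 1\].
#' @param seed integer seed for the injection draws.
#' @param weights optional non-negative per-record weights (recycled rates
#'   stay unweighted when `NULL`).
#' @return a data.frame of the same shape with perturbed `person_key`.
#' @export
perturb_mlk <- function(mlk, missed_rate, fp_rate, seed = 1L,
                        weights = NULL) {
  stopifnot(missed_rate >= 0, missed_rate <= 1, fp_rate >= 0, fp_rate <= 1)
  n <- nrow(mlk)
  if (n == 0L) return(mlk)
  if (is.null(weights)) {
    w <- rep(1, n)
  } else {
    stopifnot(length(weights) == n, all(weights >= 0), any(weights > 0))
    w <- weights / mean(weights)
  }
  p_miss <- pmin(1, missed_rate * w)
  p_fp <- pmin(1, fp_rate * w)
  set.seed(as.integer(seed))
  u <- runif(n)
  split <- u < p_miss
  reassign <- !split & u < p_miss + p_fp
  key <- mlk$person_key
  key[split] <- paste0("MISS_", mlk$record_id[split])
  if (any(reassign)) {
    pool <- unique(mlk$person_key)
    for (i in which(reassign)) {
      others <- pool[pool != mlk$person_key[i]]
      if (length(others) > 0L) key[i] <- sample(others, 1L)
    }
  }
  data.frame(record_id = mlk$record_id, person_key = key,
             stringsAsFactors = FALSE)
}

#' Measure realized MLK error rates against the ground truth
#'
#' Compares a perturbed person grouping to the true grouping using a
#' plurality rule, so the rates are measurable from the two partitions
#' alone. A record is a *false positive* if its true person is not the
#' plurality true person of its perturbed group (it sits in somebody
#' else's group). A record that is not a false positive is *missed* if its
#' true group has at least two records and the record's perturbed key
#' differs from the plurality perturbed key of its true group (it has been
#' separated from its true co-members). The true-group plurality is taken
#' over the group's non-false-positive records so that a record reassigned
#' elsewhere is attributed once, as a false positive, rather than also
#' flagging the co-members it left behind. Ties break deterministically by
#' key order.
#'
#' @param mlk_true,mlk_perturbed `record_id`/`person_key` data.frames over
#'   the same record ids.
#' @return list with `missed_per_record`, `fp_per_record` (proportions),
#'   `n_records`, and per-record logical vectors `missed`, `fp` aligned to
#'   `mlk_true$record_id`.
#' @export
mlk_error_rates <- function(mlk_true, mlk_perturbed) {
  dt <- data.table::data.table(
    record_id = mlk_true$record_id, true = mlk_true$person_key)
  pert <- data.table::data.table(
    record_id = mlk_perturbed$record_id, pert = mlk_perturbed$person_key)
  dt <- merge(dt, pert, by = "record_id", all.x = TRUE, sort = FALSE)
  if (anyNA(dt$pert)) stop("mlk_error_rates: record ids do not match")

  # plurality true person of each perturbed group; ties prefer the true id
  # matching the group's own key (group labels persist under perturbation,
  # so label agreement marks the group's rightful owner)
  cnt <- dt[, .N, by = c("pert", "true")]
  cnt[, "owner" := as.integer(true == pert)]
  data.table::setorderv(cnt, c("pert", "N", "owner", "true"),
                        order = c(1L, -1L, -1L, 1L))
  plur_true <- cnt[, list(plur_true = true[1L]), by = "pert"]
  dt <- merge(dt, plur_true, by = "pert", sort = FALSE)
  dt[, "fp" := true != plur_true]

  # plurality perturbed key of each true group, over non-FP members; ties
  # again prefer the label-matching (original) key
  cnt2 <- dt[fp == FALSE, .N, by = c("true", "pert")]
  cnt2[, "owner" := as.integer(pert == true)]
  data.table::setorderv(cnt2, c("true", "N", "owner", "pert"),
                        order = c(1L, -1L, -1L, 1L))
  plur_pert <- cnt2[, list(plur_pert = pert[1L]), by = "true"]
  gsize <- dt[, list(gsize = .N), by = "true"]
  dt <- merge(dt, plur_pert, by = "true", sort = FALSE, all.x = TRUE)
  dt <- merge(dt, gsize, by = "true", sort = FALSE)
  dt[, "missed" := !fp & gsize >= 2L & !is.na(plur_pert) &
       pert != plur_pert]

  data.table::setkey(dt, NULL)
  ord <- match(mlk_true$record_id, dt$record_id)
  list(missed_per_record = mean(dt$missed),
       fp_per_record = mean(dt$fp),
       n_records = nrow(dt),
       missed = dt$missed[ord], fp = dt$fp[ord])
}
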