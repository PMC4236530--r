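# fixture builders and independent oracles used across test files

make_identity <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    surname = replicate(n, paste0(sample(LETTERS, sample(2:9, 1),
                                         replace = TRUE), collapse = "")),
    given_name = replicate(n, paste0(sample(LETTERS, sample(2:8, 1),
                                            replace = TRUE), collapse = "")),
    birth_date = as.Date("1920-01-02") + sample.int(30000, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# identity corpus with injected missingness/invalidity for fuzzing
fuzz_identities <- function(n, seed = 1) {
  df <- make_identity(n, seed)
  set.seed(seed + 1)
  df$surname[runif(n) < 0.15] <- NA
  df$given_name[runif(n) < 0.15] <- NA
  df$surname[runif(n) < 0.05] <- ""
  df$birth_date[runif(n) < 0.1] <- NA
  jan1 <- runif(n) < 0.05
  df$birth_date[jan1] <- as.Date(paste0(
    sample(1900:2000, sum(jan1), replace = TRUE), "-01-01"))
  df$sex[runif(n) < 0.05] <- NA
  df$sex[runif(n) < 0.03] <- "unknown"
  df
}

# tiny hand-held linkage fixture: 2 persons, known SLKs
tiny_dataset <- function() {
  adm <- data.frame(
    record_id = c("A1", "A2", "A3", "A4"),
    true_id = c("P1", "P1", "P2", "P2"),
    surname = c("TAYLOR", "TAYLOR", "NGUYEN", NA),
    given_name = c("LEE", "LEE", "KIM", NA),
    birth_date = as.Date(c("1946-09-05", "1946-09-05", "1950-03-02",
                           "1950-03-02")),
    sex = c("male", "male", "female", "female"),
    separation_date = as.Date(c("2003-05-01", "2008-02-01", "2006-07-15",
                                "2009-01-10")),
    sector = c("public", "public", "private", "private"),
    conditions = c("cancer", "", "arthritis", "arthritis;diabetes"),
    stringsAsFactors = FALSE)
  dth <- data.frame(
    record_id = c("D1", "D2"),
    true_id = c("P1", "P2"),
    surname = c("TAYLOR", "NGUYEN"),
    given_name = c("LEE", "KIM"),
    birth_date = as.Date(c("1946-09-05", "1950-03-02")),
    sex = c("male", "female"),
    death_date = as.Date(c("2008-09-01", "2009-03-01")),
    stringsAsFactors = FALSE)
  mlk <- build_true_mlk(adm, dth)
  list(admissions = adm, deaths = dth, mlk = mlk)
}

# brute-force all-pairs SLK matcher: the independent oracle for the
# hash-join implementation of basic SLK linkage
brute_force_basic <- function(deaths, admissions) {
  deaths <- add_slk(deaths, "death_date")
  admissions <- add_slk(admissions, "separation_date")
  out <- list()
  for (i in seq_len(nrow(deaths))) {
    for (j in seq_len(nrow(admissions))) {
      if (identical(deaths$slk[i], admissions$slk[j]))
        out[[length(out) + 1L]] <- data.frame(
          death_id = deaths$record_id[i],
          admission_id = admissions$record_id[j],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(death_id = character(0), admission_id = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$death_id, res$admission_id), ]
  rownames(res) <- NULL
  res
}

# noise-free generator configuration: unique identities survive intact so
# all strategies must agree
noiseless_config <- function(n = 300, seed = 11) {
  synth_config(
    n_persons = n, p_decedent = 0.5, seed = seed,
    missing_name_rate_public = 0, missing_name_rate_private = 0,
    private_missing_trend = 0, invalid_dob_rate = 0, invalid_sex_rate = 0,
    death_incomplete_rate = 0, mlk_missed_rate = 0, mlk_fp_rate = 0,
    name_variant_rate = 0, duplicate_death_rate = 0,
    name_pool_size = 5000, name_skew = 0)
}

links_of <- function(result) {
  l <- result$links[order(result$links$death_id, result$links$admission_id), ]
  rownames(l) <- NULL
  l
}
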