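test_that("duplicate deaths collapse to one random retained record per person", {
  tiny <- tiny_dataset()
  expect_identical(dedupe_deaths(tiny$deaths, tiny$mlk, seed = 3),
                   tiny$deaths)
  dup <- rbind(tiny$deaths,
               transform(tiny$deaths[1, ], record_id = "D3"))
  mlk <- build_true_mlk(tiny$admissions, dup)
  kept <- dedupe_deaths(dup, mlk, seed = 3)
  expect_equal(nrow(kept), 2L)
  expect_equal(sum(kept$true_id == "P1"), 1L)
  expect_identical(kept, dedupe_deaths(dup, mlk, seed = 3))
  # across many seeds both duplicates get picked sometimes
  picks <- vapply(1:40, function(s)
    dedupe_deaths(dup, mlk, seed = s)$record_id[
      dedupe_deaths(dup, mlk, seed = s)$true_id == "P1"], character(1))
  expect_true(all(c("D1", "D3") %in% picks))
})

test_that("the probabilistic strategy follows the supplied grouping exactly", {
  tiny <- tiny_dataset()
  res <- link_full_probabilistic(tiny$deaths, tiny$admissions, tiny$mlk)
  expect_equal(links_of(res),
               data.frame(death_id = c("D1", "D1", "D2", "D2"),
                          admission_id = c("A1", "A2", "A3", "A4"),
                          stringsAsFactors = FALSE))
  # a perturbed grouping is followed, not second-guessed
  mlk2 <- tiny$mlk
  mlk2$person_key[mlk2$record_id == "A1"] <- "SPLIT"
  res2 <- link_full_probabilistic(tiny$deaths, tiny$admissions, mlk2)
  expect_equal(links_of(res2)$admission_id[links_of(res2)$death_id == "D1"],
               "A2")
  # deaths whose person has no admissions link to the empty set
  lone <- data.frame(record_id = "D9", true_id = "P9", surname = "ZZ",
                     given_name = "QQ", birth_date = as.Date("1940-02-02"),
                     sex = "male", death_date = as.Date("2008-10-01"),
                     stringsAsFactors = FALSE)
  mlk3 <- rbind(tiny$mlk, data.frame(record_id = "D9", person_key = "P9"))
  res3 <- link_full_probabilistic(rbind(tiny$deaths, lone),
                                  tiny$admissions, mlk3)
  expect_false("D9" %in% res3$links$death_id)
  expect_true("D9" %in% res3$deaths)
  expect_error(link_full_probabilistic(rbind(tiny$deaths, lone),
                                       tiny$admissions, tiny$mlk), "D9")
})

test_that("basic SLK linkage is exact 14-character equality, dummies included", {
  tiny <- tiny_dataset()
  res <- link_basic_slk(tiny$deaths, tiny$admissions)
  l <- links_of(res)
  # D1 matches A1 and A2 (same complete key); D2 matches A3 only: A4 has
  # missing names so its dummy-filled key cannot equal D2's key
  expect_equal(l$admission_id[l$death_id == "D1"], c("A1", "A2"))
  expect_equal(l$admission_id[l$death_id == "D2"], "A3")
  # two records that are dummy-incomplete in the same way do match
  d_missing <- tiny$deaths
  d_missing$surname[2] <- NA
  d_missing$given_name[2] <- NA
  res2 <- link_basic_slk(d_missing, tiny$admissions)
  l2 <- links_of(res2)
  expect_equal(l2$admission_id[l2$death_id == "D2"], "A4")
})

test_that("most-recent representative keys prefer complete then recency", {
  ev <- as.Date("2008-09-01")
  k1 <- build_slk("TAYLOR", "LEE", as.Date("1946-09-05"), "male", ev)$slk
  k2 <- build_slk("TAYLOR", "LEO", as.Date("1946-09-05"), "male", ev)$slk
  mk <- function(slks, dates, complete_names) {
    data.frame(
      record_id = paste0("A", seq_along(slks)), true_id = "P1",
      surname = ifelse(complete_names, "TAYLOR", NA),
      given_name = ifelse(complete_names,
                          c("LEE", "LEO")[match(slks, c(k1, k2))], NA),
      birth_date = as.Date("1946-09-05"), sex = "male",
      separation_date = as.Date(dates), sector = "public",
      conditions = "", stringsAsFactors = FALSE)
  }
  mlk_for <- function(adm) data.frame(record_id = adm$record_id,
                                      person_key = "P1")
  # two complete keys: latest wins
  adm <- mk(c(k1, k2), c("2005-01-01", "2008-01-01"), c(TRUE, TRUE))
  expect_equal(person_slk_most_recent(adm, mlk_for(adm))$slk, k2)
  # complete beats a more recent incomplete
  adm <- mk(c(k1, k2), c("2005-01-01", "2008-01-01"), c(TRUE, FALSE))
  expect_equal(person_slk_most_recent(adm, mlk_for(adm))$slk, k1)
  # no complete keys: the latest incomplete wins
  adm <- mk(c(k1, k2), c("2005-01-01", "2008-01-01"), c(FALSE, FALSE))
  got <- person_slk_most_recent(adm, mlk_for(adm))$slk
  expect_equal(got, add_slk(adm, "separation_date")$slk[2])
})

test_that("most-frequent representative keys use mode then recency", {
  base <- tiny_dataset()$admissions[rep(1, 3), ]
  base$record_id <- c("A1", "A2", "A3")
  base$separation_date <- as.Date(c("2005-01-01", "2006-01-01",
                                    "2008-01-01"))
  base$given_name[3] <- "LEO"  # minority key on the most recent record
  mlk <- data.frame(record_id = base$record_id, person_key = "P1")
  got <- person_slk_most_frequent(base, mlk)
  expect_equal(got$slk, add_slk(base, "separation_date")$slk[1])
  # frequency tie: the key on the most recent separation wins
  tie <- base[1:2, ]
  tie$given_name <- c("LEE", "LEO")
  tie$separation_date <- as.Date(c("2008-06-01", "2005-01-01"))
  got_tie <- person_slk_most_frequent(tie, mlk[1:2, ])
  expect_equal(got_tie$slk, add_slk(tie, "separation_date")$slk[1])
})

test_that("representative-key linkage unions groups and flags ambiguity", {
  tiny <- tiny_dataset()
  slk_map <- person_slk_most_recent(tiny$admissions, tiny$mlk)
  res <- link_via_person_slk(tiny$deaths, slk_map, tiny$admissions,
                             tiny$mlk, strategy = "most_recent_slk")
  l <- links_of(res)
  expect_equal(l$admission_id[l$death_id == "D1"], c("A1", "A2"))
  expect_equal(res$ambiguous, character(0))
  # a death whose SLK matches two persons links both groups, flagged
  twin <- tiny$admissions
  twin$record_id <- c("B1", "B2", "B3", "B4")
  twin$true_id <- "P3"
  twin[, c("surname", "given_name", "birth_date", "sex")] <-
    tiny$admissions[1, c("surname", "given_name", "birth_date", "sex")]
  adm2 <- rbind(tiny$admissions, twin)
  mlk2 <- build_true_mlk(adm2, tiny$deaths)
  map2 <- person_slk_most_recent(adm2, mlk2)
  res2 <- link_via_person_slk(tiny$deaths, map2, adm2, mlk2)
  l2 <- links_of(res2)
  expect_setequal(l2$admission_id[l2$death_id == "D1"],
                  c("A1", "A2", "B1", "B2", "B3", "B4"))
  expect_equal(res2$ambiguous, "D1")
})

test_that("any-match expands stage-1 SLK hits to whole MLK groups", {
  tiny <- tiny_dataset()
  # A4 (missing names) shares P2's group with A3; stage 1 finds A3 only,
  # stage 2 pulls in A4
  res <- link_any_match(tiny$deaths, tiny$admissions, tiny$mlk)
  l <- links_of(res)
  expect_setequal(l$admission_id[l$death_id == "D2"], c("A3", "A4"))
  basic <- link_basic_slk(tiny$deaths, tiny$admissions)
  expect_true(all(paste(basic$links$death_id, basic$links$admission_id)
                  %in% paste(l$death_id, l$admission_id)))
  # stage 1 empty leaves the death unlinked
  stranger <- tiny$deaths[1, ]
  stranger$surname <- "QWXYZK"
  res2 <- link_any_match(stranger, tiny$admissions, tiny$mlk)
  expect_equal(nrow(res2$links), 0L)
})

test_that("hash-join SLK matching equals brute-force all-pairs comparison", {
  for (seed in c(101, 202)) {
    sim <- simulate_study(synth_config(n_persons = 60, seed = seed))
    adm <- head(sim$admissions, 450)
    ret <- dedupe_deaths(sim$deaths, sim$mlk, seed = seed)
    got <- links_of(link_basic_slk(ret, adm))
    want <- brute_force_basic(ret, adm)
    expect_equal(got, want)
  }
})

test_that("with no noise and the true MLK all five strategies coincide", {
  cfg <- noiseless_config()
  sim <- simulate_study(cfg)
  ret <- dedupe_deaths(sim$deaths, sim$mlk, seed = 1)
  res <- run_strategies(ret, sim$admissions, sim$mlk)
  ref <- links_of(res$full_probabilistic)
  for (nm in names(res)[-1]) {
    expect_equal(links_of(res[[nm]]), ref, info = nm)
    cmp <- compare_links(res[[nm]], res$full_probabilistic)
    expect_equal(cmp$missed_rate, 0, info = nm)
    expect_equal(cmp$fp_rate, 0, info = nm)
  }
})

test_that("per death, any-match is a superset of basic SLK", {
  sim <- simulate_study(synth_config(n_persons = 800, seed = 303))
  ret <- dedupe_deaths(sim$deaths, sim$mlk, seed = 303)
  basic <- link_basic_slk(ret, sim$admissions)
  anym <- link_any_match(ret, sim$admissions, sim$mlk)
  b <- paste(basic$links$death_id, basic$links$admission_id)
  a <- paste(anym$links$death_id, anym$links$admission_id)
  expect_true(all(b %in% a))
  # counting consistency: deaths with stage-1 links = deaths linked by basic
  expect_setequal(unique(basic$links$death_id),
                  intersect(unique(anym$links$death_id),
                            unique(basic$links$death_id)))
})

test_that("with the true MLK, any-match misses a subset of basic's misses", {
  sim <- simulate_study(synth_config(n_persons = 800, seed = 404))
  ret <- dedupe_deaths(sim$deaths, sim$mlk_true, seed = 404)
  ref <- link_full_probabilistic(ret, sim$admissions, sim$mlk_true)
  basic <- compare_links(link_basic_slk(ret, sim$admissions), ref)
  anym <- compare_links(link_any_match(ret, sim$admissions, sim$mlk_true),
                        ref)
  miss_b <- basic$per_death$death_id[basic$per_death$missed_any]
  miss_a <- anym$per_death$death_id[anym$per_death$missed_any]
  expect_true(all(miss_a %in% miss_b))
  expect_lte(anym$missed_rate, basic$missed_rate)
})

test_that("unknown strategy names are rejected", {
  tiny <- tiny_dataset()
  expect_error(run_strategies(tiny$deaths, tiny$admissions, tiny$mlk,
                              strategies = "fellegi_sunter"),
               "unknown strategy")
})
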