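# hand-held comparison fixture: one reference and one strategy result over
# three deaths with known set differences
cmp_fixture <- function() {
  deaths <- c("D1", "D2", "D3")
  ref <- slklink:::new_linkage_result(
    "full_probabilistic",
    data.frame(death_id = c("D1", "D1", "D1", "D2"),
               admission_id = c("a", "b", "c", "x")),
    deaths)
  strat <- slklink:::new_linkage_result(
    "basic_slk",
    data.frame(death_id = c("D1", "D1", "D1", "D2"),
               admission_id = c("a", "b", "d", "x")),
    deaths)
  list(ref = ref, strat = strat, deaths = deaths)
}

test_that("missed and false flags come from per-death set differences", {
  fx <- cmp_fixture()
  cmp <- compare_links(fx$strat, fx$ref)
  pd <- cmp$per_death
  # D1: R={a,b,c}, S={a,b,d} -> both missed and false simultaneously
  expect_true(pd$missed_any[pd$death_id == "D1"])
  expect_true(pd$false_any[pd$death_id == "D1"])
  # D2: identical sets -> neither
  expect_false(pd$missed_any[pd$death_id == "D2"])
  expect_false(pd$false_any[pd$death_id == "D2"])
  # rates over deaths with >= 1 reference link (D3 has none)
  expect_equal(cmp$n_eval, 2L)
  expect_equal(cmp$missed_rate, 0.5)
  expect_equal(cmp$fp_rate, 0.5)
  # reference against itself is exactly (0, 0)
  self <- compare_links(fx$ref, fx$ref)
  expect_equal(self$missed_rate, 0)
  expect_equal(self$fp_rate, 0)
  # mismatched retained-death sets are an error
  other <- slklink:::new_linkage_result("basic_slk", fx$ref$links,
                                        c("D1", "D2"))
  expect_error(compare_links(other, fx$ref), "different retained deaths")
})

test_that("missed sets shrink to R minus S and false to S minus R", {
  fx <- cmp_fixture()
  cmp <- compare_links(fx$strat, fx$ref)
  pd <- cmp$per_death
  expect_equal(pd$n_ref[pd$death_id == "D1"], 3)
  expect_equal(pd$n_strategy[pd$death_id == "D1"], 3)
  # a pure subset strategy has misses but no false positives
  sub <- slklink:::new_linkage_result(
    "basic_slk",
    data.frame(death_id = c("D1", "D1"), admission_id = c("a", "b")),
    fx$deaths)
  cmp2 <- compare_links(sub, fx$ref)
  expect_equal(cmp2$missed_rate, 1)  # both D1 and D2 lost links
  expect_equal(cmp2$fp_rate, 0)
})

test_that("yearly error trend localises errors to the admission year", {
  adm <- data.frame(
    record_id = c("a", "b", "x"),
    separation_date = as.Date(c("2003-10-01", "2008-10-01", "2005-03-01")),
    stringsAsFactors = FALSE)
  deaths <- c("D1", "D2")
  ref <- slklink:::new_linkage_result(
    "full_probabilistic",
    data.frame(death_id = c("D1", "D1", "D2"),
               admission_id = c("a", "b", "x")), deaths)
  # strategy misses only the 2003-04 record
  strat <- slklink:::new_linkage_result(
    "basic_slk",
    data.frame(death_id = c("D1", "D2"), admission_id = c("b", "x")),
    deaths)
  tr <- error_trend_by_year(strat, ref, adm)
  expect_equal(tr$missed_rate[tr$fy_end == 2004], 1)
  expect_equal(sum(tr$missed_rate > 0), 1L)
  expect_true(all(tr$fp_rate == 0))
  # a perfect strategy yields an all-zero series
  tr0 <- error_trend_by_year(ref, ref, adm)
  expect_true(all(tr0$missed_rate == 0) && all(tr0$fp_rate == 0))
})

test_that("percent hospitalised counts linked deaths over all retained deaths", {
  retained <- data.frame(record_id = c("D1", "D2", "D3", "D4"),
                         stringsAsFactors = FALSE)
  adm <- data.frame(
    record_id = c("a", "b"),
    separation_date = as.Date(c("2008-10-01", "2002-01-01")),
    stringsAsFactors = FALSE)
  res <- slklink:::new_linkage_result(
    "basic_slk",
    data.frame(death_id = c("D1", "D2"), admission_id = c("a", "b")),
    retained$record_id)
  expect_equal(percent_hospitalised(res, retained, adm, fy_window(9)), 50)
  # the one-year window sees only the 2008-09 record
  expect_equal(percent_hospitalised(res, retained, adm, fy_window(1)), 25)
  empty <- slklink:::new_linkage_result("basic_slk",
                                        res$links[0, ],
                                        retained$record_id)
  expect_equal(percent_hospitalised(empty, retained, adm, fy_window(9)), 0)
})

test_that("hospitalisation stats match direct computation on known counts", {
  retained <- data.frame(record_id = sprintf("D%d", 1:4),
                         stringsAsFactors = FALSE)
  adm <- data.frame(
    record_id = sprintf("a%d", 1:6),
    separation_date = as.Date("2008-10-01"),
    stringsAsFactors = FALSE)
  # counts per death: 3, 2, 1, 0
  res <- slklink:::new_linkage_result(
    "basic_slk",
    data.frame(death_id = c("D1", "D1", "D1", "D2", "D2", "D3"),
               admission_id = sprintf("a%d", 1:6)),
    retained$record_id)
  st <- hospitalisation_stats(res, retained, adm, fy_window(1))
  x <- c(3, 2, 1, 0)
  expect_equal(st$mean, mean(x))
  expect_equal(st$ci_lo, mean(x) - 1.96 * sd(x) / 2)
  expect_equal(st$ci_hi, mean(x) + 1.96 * sd(x) / 2)
  expect_equal(st$median, quantile(x, 0.5, type = 1, names = FALSE))
  expect_equal(st$q25, quantile(x, 0.25, type = 1, names = FALSE))
  expect_equal(st$q75, quantile(x, 0.75, type = 1, names = FALSE))
  expect_equal(st$percent_hospitalised, 75)
  # all-zero counts degrade gracefully
  none <- slklink:::new_linkage_result("basic_slk", res$links[0, ],
                                       retained$record_id)
  st0 <- hospitalisation_stats(none, retained, adm, fy_window(1))
  expect_equal(st0$mean, 0)
  expect_equal(st0$median, 0)
  expect_equal(c(st0$q25, st0$q75), c(0, 0))
})

test_that("percent and mean never decrease as the window lengthens", {
  sim <- simulate_study(synth_config(n_persons = 400, seed = 77))
  ret <- dedupe_deaths(sim$deaths, sim$mlk, seed = 77)
  res <- link_full_probabilistic(ret, sim$admissions, sim$mlk)
  pcts <- vapply(1:9, function(w)
    percent_hospitalised(res, ret, sim$admissions, fy_window(w)),
    numeric(1))
  means <- vapply(1:9, function(w)
    hospitalisation_stats(res, ret, sim$admissions, fy_window(w))$mean,
    numeric(1))
  expect_true(all(diff(pcts) >= 0))
  expect_true(all(diff(means) >= 0))
})

test_that("condition rates ratio strategies against the reference", {
  adm <- data.frame(
    record_id = sprintf("a%d", 1:10),
    separation_date = as.Date("2008-10-01"),
    conditions = rep(c("cancer", "cancer;diabetes"), 5),
    stringsAsFactors = FALSE)
  retained <- data.frame(record_id = sprintf("D%d", 1:10),
                         stringsAsFactors = FALSE)
  ref <- slklink:::new_linkage_result(
    "full_probabilistic",
    data.frame(death_id = sprintf("D%d", 1:10),
               admission_id = sprintf("a%d", 1:10)),
    retained$record_id)
  # strategy keeps 6 of 10 persons' links: 3 with diabetes, 6 with cancer
  strat <- slklink:::new_linkage_result(
    "basic_slk",
    data.frame(death_id = sprintf("D%d", 1:6),
               admission_id = sprintf("a%d", 1:6)),
    retained$record_id)
  cr <- condition_rates(list(full_probabilistic = ref, basic_slk = strat),
                        retained, adm, fy_window(9))
  ref_rows <- cr[cr$strategy == "full_probabilistic", ]
  expect_true(all(ref_rows$rate_ratio == 1))
  expect_equal(cr$rate[cr$strategy == "basic_slk" &
                         cr$condition == "cancer"], 60)
  expect_equal(cr$rate_ratio[cr$strategy == "basic_slk" &
                               cr$condition == "diabetes"],
               round(30 / 50, 2))
  expect_error(
    condition_rates(list(full_probabilistic = ref), retained, adm,
                    fy_window(9), conditions = "asthma"),
    "unknown condition")
  expect_error(
    condition_rates(list(basic_slk = strat), retained, adm, fy_window(9)),
    "reference")
})

test_that("financial-year helpers split years at 1 July", {
  expect_equal(fy_end(as.Date(c("2008-06-30", "2008-07-01"))),
               c(2008L, 2009L))
  expect_equal(fy_label(2009L), "2008-09")
  expect_equal(fy_label(2001L), "2000-01")
  expect_equal(fy_window(2), c(2008L, 2009L))
  expect_equal(fy_window(9), 2001:2009)
})
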