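test_that("person-time matches a hand day-count oracle and its bounds", {
  win <- follow_up_window("2008-01-01", "2010-01-01")  # 731 days

  res <- toy_residents()[1:4, ]
  res$entry_date <- c("2007-06-01", "2008-01-01", "2008-01-01", "2009-06-01")
  res$death_date <- c("", "2008-01-01", "2009-01-01", "")
  co <- read_toy_cohort(res = res, ev = toy_events()[0, ])
  pt <- person_time(co$residents, win)

  # hand day counts: full window; death at window start; one year; late entry
  expect_equal(pt, c(731, 0, 366, 214) / 365.25)
  expect_true(all(pt >= 0 & pt <= win$years))

  # an exit_date column censors a resident who moves away
  res$exit_date <- c("2008-07-01", "", "", "")
  co2 <- read_toy_cohort(res = res, ev = toy_events()[0, ])
  expect_equal(person_time(co2$residents, win)[1], 182 / 365.25)
})

test_that("mean survival is the care-level mean of censored person-time", {
  win <- follow_up_window("2008-01-01", "2010-01-01")
  res <- toy_residents()[1:3, ]
  res$care_level <- "low"
  res$entry_date <- "2008-01-01"
  # survive 365.25-ish and 730.5-ish days: use exact day counts as oracle
  res$death_date <- c("2008-12-31", "2009-12-31", "")
  co <- read_toy_cohort(res = res, ev = toy_events()[0, ])
  expect_warning(tab <- estimate_mean_survival(co$residents, win),
                 "high|dementia|psychogeriatric")
  expect_equal(unclass(tab)[["low"]], mean(c(365, 730, 731) / 365.25))

  # all residents censored at window end: mean equals the window length
  res$death_date <- ""
  co2 <- read_toy_cohort(res = res, ev = toy_events()[0, ])
  tab2 <- suppressWarnings(estimate_mean_survival(co2$residents, win))
  expect_equal(unclass(tab2)[["low"]], win$years)

  # a single-resident level contributes its own time
  res$care_level <- c("low", "low", "dementia")
  co3 <- read_toy_cohort(res = res, ev = toy_events()[0, ])
  tab3 <- suppressWarnings(estimate_mean_survival(co3$residents, win))
  expect_equal(unclass(tab3)[["dementia"]], win$years)
})

test_that("approximate person-time is a capped, linear product of counts", {
  win <- follow_up_window("2008-01-01", "2010-01-01")
  tab <- structure(c(low = 1.2, high = 3.0), class = "mean_survival_table")
  expect_equal(approximate_facility_person_time(c(low = 10), tab, win), 12.0)
  # mean survival above the window length is capped at the window
  expect_equal(approximate_facility_person_time(c(high = 10), tab, win),
               10 * win$years)
  expect_equal(approximate_facility_person_time(integer(0), tab, win), 0)
  expect_error(
    approximate_facility_person_time(c(psychogeriatric = 3), tab, win),
    "psychogeriatric")
  # linear in care-level counts
  a <- approximate_facility_person_time(c(low = 3, high = 2), tab, win)
  b <- approximate_facility_person_time(c(low = 6, high = 4), tab, win)
  expect_equal(b, 2 * a)
})

test_that("facility aggregates carry counts, proportions and exact exposure", {
  co <- read_toy_cohort()
  win <- toy_window()
  cnt <- count_pah_events(co$events, co$residents, load_code_list(), win)
  agg <- aggregate_facilities(co, cnt, win)

  expect_s3_class(agg, "facility_aggregates")
  expect_equal(agg$facility_id, co$facilities$facility_id)
  expect_equal(sum(agg$pah_count), sum(cnt$pah_count))
  # exact person-years conserve the per-resident sum
  expect_equal(sum(agg$person_years), sum(person_time(co$residents, win)))
  # proportions: F2 has 4 residents, 2 with gp_urgent_2wk
  expect_equal(agg$gp_urgent_2wk[agg$facility_id == "F2"], 0.5)
  expect_true(all(agg[, CORE4] >= 0 & agg[, CORE4] <= 1))
  # care-level headcounts
  expect_equal(agg$care_low[agg$facility_id == "F3"], 2L)
  expect_equal(agg$care_high[agg$facility_id == "F3"], 1L)
})

test_that("approximate exposure equals exact when survival is homogeneous", {
  win <- follow_up_window("2008-01-01", "2010-01-01")
  res <- toy_residents()
  res$care_level <- "low"
  res$entry_date <- "2008-01-01"
  res$death_date <- "2009-01-01"  # everyone survives exactly the level mean
  co <- read_toy_cohort(res = res, ev = toy_events()[0, ])
  cnt <- count_pah_events(co$events, co$residents, load_code_list(), win)
  exact <- suppressWarnings(aggregate_facilities(co, cnt, win, mode = "exact"))
  approx <- suppressWarnings(aggregate_facilities(co, cnt, win, mode = "approximate"))
  expect_equal(approx$person_years, exact$person_years)

  # heterogeneous survival: the two modes disagree per facility
  res$death_date <- rep(c("2008-04-01", ""), 5)
  co2 <- read_toy_cohort(res = res, ev = toy_events()[0, ])
  cnt2 <- count_pah_events(co2$events, co2$residents, load_code_list(), win)
  exact2 <- suppressWarnings(aggregate_facilities(co2, cnt2, win, mode = "exact"))
  approx2 <- suppressWarnings(aggregate_facilities(co2, cnt2, win, mode = "approximate"))
  expect_false(isTRUE(all.equal(approx2$person_years, exact2$person_years)))
  # but both conserve the cohort total (approximation redistributes time)
  expect_equal(sum(approx2$person_years), sum(exact2$person_years))
})

test_that("a facility with no residents is flagged with zeroed aggregates", {
  res <- toy_residents()
  res <- res[res$facility_id != "F2", ]
  ev <- toy_events()
  ev <- ev[ev$resident_id %in% res$resident_id, ]
  co <- read_toy_cohort(res = res, ev = ev)
  cnt <- count_pah_events(co$events, co$residents, load_code_list(), toy_window())
  expect_warning(agg <- aggregate_facilities(co, cnt, toy_window()),
                 "zero residents")
  f2 <- agg[agg$facility_id == "F2", ]
  expect_true(f2$flag_zero_residents)
  expect_equal(f2$n_residents, 0L)
  expect_equal(f2$pah_count, 0L)
  expect_equal(f2$person_years, 0)
})
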