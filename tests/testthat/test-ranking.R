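toy_aggregates <- function(pah = c(12L, 6L, 0L, 9L, 3L),
                           res = c(30L, 20L, 10L, 30L, 12L),
                           py = c(50, 25, 12, 20, 30)) {
  data.frame(facility_id = sprintf("F%d", seq_along(pah)),
             stratum = rep(c("DHB1", "DHB2"), length.out = length(pah)),
             n_residents = res, n_beds = res + 10L,
             pah_count = pah, person_years = py,
             stringsAsFactors = FALSE)
}

test_that("method values implement their stated ratios and flags", {
  agg <- toy_aggregates()
  expect_equal(unname(method1_values(agg)), c(0.4, 0.3, 0, 0.3, 0.25))
  expect_equal(unname(method1_values(agg, denominator = "beds"))[1], 12 / 40)
  expect_equal(unname(method2_values(agg)),
               c(0.24, 0.24, 0, 0.45, 0.1))
  # 17 events over 50 person-years is 34 per 100 person-years
  agg2 <- toy_aggregates(pah = c(17L, 1L), res = c(20L, 5L), py = c(50, 10))
  expect_equal(unname(method2_values(agg2))[1] * 100, 34)
  # halving person-years doubles the rate
  agg3 <- agg2; agg3$person_years <- agg3$person_years / 2
  expect_equal(method2_values(agg3), 2 * method2_values(agg2))
  # zero denominators are flagged as NA with a warning
  agg4 <- toy_aggregates(pah = c(1L, 2L), res = c(0L, 5L), py = c(0, 5))
  expect_warning(v <- method1_values(agg4), "zero denominator")
  expect_true(is.na(v[1]))
})

test_that("ranks are ascending with a deterministic facility-id tie-break", {
  expect_equal(unname(rank_values(c(A = 0.1, B = 0.3, C = 0.2))), c(1L, 3L, 2L))
  # all-equal values fall back to id order
  expect_equal(unname(rank_values(c(B = 1, A = 1, C = 1),
                                  ids = c("B", "A", "C"))), c(2L, 1L, 3L))
  expect_error(rank_values(c(A = 1, B = Inf)), "B")
  # NA (flagged) values keep their slot but are excluded from the permutation
  r <- rank_values(c(A = 0.5, B = NA, C = 0.1))
  expect_equal(unname(r), c(2L, NA, 1L))
})

test_that("adding events to one facility never lowers its observed-rate rank", {
  agg <- toy_aggregates()
  base_rank <- rank_values(method2_values(agg))[["F2"]]
  agg$pah_count[agg$facility_id == "F2"] <- agg$pah_count[2] + 10L
  expect_gte(rank_values(method2_values(agg))[["F2"]], base_rank)
})

test_that("rank change is observed minus predicted and detects set mismatch", {
  r2 <- c(A = 3L, B = 1L, C = 2L)
  r3 <- c(A = 1L, B = 2L, C = 3L)
  chg <- method4_values(r2, r3)
  expect_equal(unname(chg), c(2L, -1L, -1L))
  # the facility observed highest but predicted mid-rank tops Method 4
  expect_equal(names(which.max(rank_values(chg))), "A")
  expect_equal(sum(chg), 0L)
  expect_error(method4_values(r2, r3[c("A", "B")]), "C")
  r3_bad <- c(A = 1L, B = 2L, D = 3L)
  expect_error(method4_values(r2, r3_bad), "[CD]")
})

test_that("residuals subtract predictions, with a Pearson variant", {
  expect_equal(residual_values(20, 12), 8)
  expect_equal(residual_values(c(5, 7), c(5, 7)), c(0, 0))
  expect_equal(residual_values(20, 12, type = "pearson", k = Inf), 8 / sqrt(12))
  expect_equal(residual_values(20, 12, type = "pearson", k = 2),
               8 / sqrt(12 + 144 / 2))
  expect_error(residual_values(1, -2), "negative predicted")
})

test_that("rank tables hold strict permutations for every method", {
  withr::local_seed(BASE_SEED + 10)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    agg <- data.frame(facility_id = sprintf("F%02d", 1:n),
                      stratum = sample(c("DHB1", "DHB2", "DHB3"), n, TRUE),
                      n_residents = sample(5:50, n, TRUE),
                      n_beds = sample(10:60, n, TRUE),
                      pah_count = as.integer(stats::rnbinom(n, mu = 10, size = 2)),
                      person_years = stats::runif(n, 5, 80),
                      gp_urgent_2wk = stats::runif(n),
                      stringsAsFactors = FALSE)
    model <- structure(list(beta = c(`(Intercept)` = -1, gp_urgent_2wk = 0.8),
                            covariates = "gp_urgent_2wk",
                            offset_mode = "log_person_time", k = 2),
                       class = "nbmm")
    rt <- rank_facilities(agg, model)
    for (m in c("method1", "method2", "method3", "method4", "residual")) {
      expect_equal(sort(rt[[paste0("rank_", m)]]), seq_len(n))
    }
    # rank change sums to zero on tie-free inputs
    expect_equal(sum(rt$value_method4), 0L)
    # rankings are invariant to row permutation of the input
    perm <- sample(n)
    rt_p <- rank_facilities(agg[perm, , drop = FALSE], model)
    expect_equal(rt_p[order(rt_p$facility_id), ], rt[order(rt$facility_id), ],
                 ignore_attr = "row.names")
  }
})

test_that("uniform person-time makes Methods 1 and 2 agree exactly", {
  withr::local_seed(BASE_SEED + 11)
  n <- 25
  agg <- toy_aggregates(pah = as.integer(stats::rnbinom(n, mu = 8, size = 2)),
                        res = sample(5:40, n, TRUE),
                        py = 0)  # overwritten below
  agg$person_years <- agg$n_residents * 1.83  # equal follow-up per resident
  rt <- rank_facilities(agg)
  expect_equal(rt$rank_method1, rt$rank_method2)
})

test_that("top-N selection works overall and within strata", {
  withr::local_seed(BASE_SEED + 12)
  n <- 36
  agg <- data.frame(facility_id = sprintf("F%02d", 1:n),
                    stratum = rep(c("DHB1", "DHB2", "DHB3"), each = 12),
                    n_residents = sample(20:40, n, TRUE),
                    n_beds = sample(20:50, n, TRUE),
                    pah_count = as.integer(stats::rpois(n, 10)),
                    person_years = stats::runif(n, 20, 60),
                    stringsAsFactors = FALSE)
  rt <- rank_facilities(agg)

  top10 <- select_top(rt, "method2", 10)
  expect_equal(nrow(top10), 10)
  # the selected facilities are exactly the 10 highest rates
  expect_equal(sort(top10$value, decreasing = TRUE),
               sort(rt$value_method2, decreasing = TRUE)[1:10])
  expect_equal(top10$rank[1], n)

  strat <- select_top(rt, "method2", 12, strata = TRUE)
  expect_equal(nrow(strat), 36)
  expect_equal(as.integer(table(strat$stratum)), rep(12L, 3))

  expect_warning(big <- select_top(rt, "method2", 50), "only 36")
  expect_equal(nrow(big), n)
  expect_error(select_top(rt, "method7", 5), "not computed")
})

test_that("method comparison reports overlap and Spearman agreement", {
  agg <- toy_aggregates()
  rt <- rank_facilities(agg)
  cmp <- compare_methods(rt, "method1", "method1", top_n = 3)
  expect_equal(cmp$overlap, 3)
  expect_equal(cmp$spearman, 1)

  # construct exactly reversed rankings
  rt2 <- rt
  rt2$rank_method2 <- nrow(rt2) + 1L - rt2$rank_method1
  rt2$value_method2 <- -rt2$value_method1
  cmp2 <- compare_methods(rt2, "method1", "method2")
  expect_equal(cmp2$spearman, -1)

  # equal follow-up: method1 and method2 top sets coincide
  agg$person_years <- agg$n_residents * 2
  rt3 <- rank_facilities(agg)
  cmp3 <- compare_methods(rt3, "method1", "method2", top_n = 3)
  expect_equal(cmp3$overlap, 3)
})
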