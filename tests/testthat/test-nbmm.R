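# simulate a simple clustered NB/Poisson dataset directly (independent of
# the cohort generator) for the model unit tests
sim_units <- function(n_fac, n_per, beta, sigma_b, k, seed,
                      exposure_range = c(0.5, 2)) {
  withr::local_seed(seed)
  n <- n_fac * n_per
  fac <- rep(sprintf("F%03d", 1:n_fac), each = n_per)
  x1 <- stats::rbinom(n, 1, 0.3)
  x2 <- stats::rnorm(n)
  t <- stats::runif(n, exposure_range[1], exposure_range[2])
  b <- stats::rnorm(n_fac, 0, sigma_b)
  mu <- t * exp(beta[1] + beta[2] * x1 + beta[3] * x2 + rep(b, each = n_per))
  y <- if (is.finite(k)) stats::rnbinom(n, mu = mu, size = k) else stats::rpois(n, mu)
  data.frame(facility_id = fac, x1 = x1, x2 = x2, person_time = t,
             pah_count = y, stringsAsFactors = FALSE)
}

test_that("the NB2 log mass matches its gamma form, limits and normalisation", {
  # Poisson limit: P(0 | mu=1) -> exp(-1)
  expect_equal(nb_log_pmf(0, 1, 1e12), -1, tolerance = 1e-6)
  # geometric-type case against an independent evaluation of the gamma form
  expect_equal(nb_log_pmf(2, 2, 1), stats::dnbinom(2, size = 1, mu = 2, log = TRUE))
  expect_equal(nb_log_pmf(7, 3.2, 2.5),
               stats::dnbinom(7, size = 2.5, mu = 3.2, log = TRUE))
  # normalisation
  expect_equal(sum(exp(nb_log_pmf(0:400, 2.5, 1.3))), 1, tolerance = 1e-10)
  # domain errors
  expect_error(nb_log_pmf(1, -1, 2), "mu")
  expect_error(nb_log_pmf(1, 1, 0), "k")
  expect_error(nb_log_pmf(1.5, 1, 1), "integer")
})

test_that("the marginal likelihood collapses to independent NB at sigma_b = 0", {
  d <- sim_units(3, 5, c(-0.5, 0.7, 0.2), 0.4, 2, seed = BASE_SEED)
  X <- cbind(1, d$x1, d$x2)
  beta <- c(-0.5, 0.7, 0.2)
  ll0 <- nbmm_loglik(d$pah_count, X, d$facility_id, beta, 0, 2,
                     offset = log(d$person_time))
  expect_equal(ll0, sum(nb_log_pmf(d$pah_count,
                                   exp(drop(X %*% beta) + log(d$person_time)), 2)))
  # an all-zero covariate with a zero coefficient changes nothing
  ll <- nbmm_loglik(d$pah_count, X, d$facility_id, beta, 0.4, 2,
                    offset = log(d$person_time))
  ll_aug <- nbmm_loglik(d$pah_count, cbind(X, 0), d$facility_id, c(beta, 0),
                        0.4, 2, offset = log(d$person_time))
  expect_equal(ll_aug, ll)
})

test_that("adaptive quadrature agrees with brute-force integration and improves with nodes", {
  d <- sim_units(3, 5, c(-0.5, 0.7, 0.2), 0.4, 2, seed = BASE_SEED + 1)
  X <- cbind(1, d$x1, d$x2)
  beta <- c(-0.4, 0.6, 0.1)
  eta <- drop(X %*% beta) + log(d$person_time)
  oracle <- brute_loglik(d$pah_count, eta, d$facility_id, 0.4, 2)
  errs <- vapply(c(1, 3, 7, 15), function(Q) {
    abs(nbmm_loglik(d$pah_count, X, d$facility_id, beta, 0.4, 2,
                    offset = log(d$person_time), quadrature_points = Q) - oracle)
  }, numeric(1))
  expect_lt(errs[4] / abs(oracle), 1e-6)
  # errors shrink towards the brute-force value as nodes are added
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("the fit recovers a Poisson GLM when the random effect and dispersion vanish", {
  d <- sim_units(20, 10, c(-0.3, 0.6, 0.25), 0, Inf, seed = BASE_SEED + 2)
  fit <- nbmm_fit(d, covariates = c("x1", "x2"), fix_sigma_b = 0, fix_k = 1e8)
  oracle <- stats::glm(pah_count ~ x1 + x2 + offset(log(person_time)),
                       family = stats::poisson(), data = d)
  expect_equal(unname(fit$beta), unname(stats::coef(oracle)), tolerance = 1e-4)
  expect_true(fit$converged)
  expect_equal(unname(fit$se), unname(sqrt(diag(stats::vcov(oracle)))),
               tolerance = 1e-3)
})

test_that("a constant covariate triggers the singular-information path", {
  d <- sim_units(5, 8, c(-0.3, 0.5, 0.2), 0.2, 3, seed = BASE_SEED + 3)
  d$flat <- 1
  expect_warning(
    fit <- nbmm_fit(d, covariates = "flat", fix_sigma_b = 0.2, fix_k = 3),
    "singular")
  expect_true(all(is.na(fit$se)))
})

test_that("non-finite linear predictors are reported with their facility", {
  d <- sim_units(3, 4, c(-0.3, 0.5, 0.2), 0.2, 3, seed = BASE_SEED + 4)
  X <- cbind(1, d$x1)
  expect_error(nbmm_loglik(d$pah_count, X, d$facility_id, c(1e400, 0), 0.2, 3),
               "non-finite linear predictor")
})

test_that("backward elimination honours alpha, fixed points and listing order", {
  d <- sim_units(40, 25, c(-0.5, 0.8, 0.4), 0.2, 2, seed = BASE_SEED + 5)
  withr::local_seed(BASE_SEED + 6)
  d$noise1 <- stats::rbinom(nrow(d), 1, 0.3)
  d$noise2 <- stats::rnorm(nrow(d))

  # alpha = 1 retains everything
  out1 <- backward_eliminate(d, c("x1", "x2", "noise1", "noise2"), alpha = 1)
  expect_equal(nrow(out1$trace), 0)
  expect_setequal(out1$retained, c("x1", "x2", "noise1", "noise2"))

  # strong true effects only: no eliminations at alpha = 0.05
  out2 <- backward_eliminate(d, c("x1", "x2"), alpha = 0.05)
  expect_equal(nrow(out2$trace), 0)

  # retained set does not depend on the order covariates are listed
  outA <- backward_eliminate(d, c("x1", "x2", "noise1", "noise2"), alpha = 0.05)
  outB <- backward_eliminate(d, c("noise2", "noise1", "x2", "x1"), alpha = 0.05)
  expect_equal(outA$retained, outB$retained)
  expect_equal(outA$trace$removed, outB$trace$removed)
  expect_true(all(c("x1", "x2") %in% outA$retained))
})

test_that("facility predictions scale with exposure and check covariates", {
  model <- structure(list(beta = c(`(Intercept)` = log(0.34)),
                          covariates = character(),
                          offset_mode = "log_person_time", k = 2),
                     class = "nbmm")
  agg <- data.frame(facility_id = c("A", "B", "C"),
                    person_years = c(100, 0, 200), stringsAsFactors = FALSE)
  pred <- predict_facility_counts(model, agg)
  # a facility rate of 0.34 per person-year over 100 person-years
  expect_equal(unname(pred), c(34, 0, 68))

  model2 <- structure(list(beta = c(`(Intercept)` = 0, frailty = 1),
                           covariates = "frailty",
                           offset_mode = "log_person_time", k = 2),
                      class = "nbmm")
  expect_error(predict_facility_counts(model2, agg), "frailty")
})

test_that("parameters are recovered within reported uncertainty at modest scale", {
  d <- sim_units(150, 40, c(-1.0, 0.8, 0.5), 0.3, 2, seed = BASE_SEED + 7)
  fit <- nbmm_fit(d, covariates = c("x1", "x2"))
  truth <- c(-1.0, 0.8, 0.5)
  expect_true(all(abs(fit$beta - truth) < 3 * fit$se))
  expect_lt(abs(fit$sigma_b - 0.3), 0.12)
  expect_lt(abs(fit$k - 2), 0.5)
})
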