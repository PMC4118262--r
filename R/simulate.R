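#' Define a simulation scenario
#'
#' A scenario holds every parameter of the synthetic cohort generator: the
#' facility/resident structure, the true model parameters (used by the
#' parameter-recovery tests), care-level-dependent survival, and how events
#' are coded. See [scenario_presets()] for ready-made scenarios.
#'
#' @param n_facilities number of facilities (>= 1).
#' @param residents_mean,residents_dispersion mean and NB dispersion (size)
#'   of residents per facility; facilities are guaranteed at least one
#'   resident.
#' @param care_level_mix named probabilities over
#'   low/high/dementia/psychogeriatric summing to 1, drawn independently per
#'   resident.
#' @param covariate_prevalence named Bernoulli prevalences for the binary
#'   resident covariates (defaults: the four core predictors).
#' @param beta_true named true log-rate effects for the covariates in
#'   `covariate_prevalence`; `intercept` is the log baseline PAH rate per
#'   person-year.
#' @param sigma_b_true facility random-intercept SD (>= 0).
#' @param dispersion_k_true NB2 size parameter of resident event counts.
#' @param survival_rates named per-year exponential death rates by care
#'   level.
#' @param pah_fraction_of_events fraction of generated events given
#'   PAH-matching diagnosis codes (the rest get codes from a disjoint
#'   non-matching prefix space, so the fraction is exact by construction).
#' @param window a [follow_up_window()].
#' @param seed master integer seed; per-table streams are derived from it so
#'   e.g. facility draws do not change when resident settings change.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_facilities,
                                residents_mean,
                                residents_dispersion = 8,
                                care_level_mix = c(low = 0.55, high = 0.30,
                                                   dementia = 0.10,
                                                   psychogeriatric = 0.05),
                                covariate_prevalence = c(
                                  gp_urgent_2wk = 0.10,
                                  ed_visit_prior_window = 0.15,
                                  prior_diabetes_admission = 0.10,
                                  prior_dementia_admission = 0.20),
                                beta_true = c(intercept = log(0.34),
                                              gp_urgent_2wk = 0.8,
                                              ed_visit_prior_window = 0.5,
                                              prior_diabetes_admission = 0.4,
                                              prior_dementia_admission = 0.3),
                                sigma_b_true = 0.3,
                                dispersion_k_true = 2,
                                survival_rates = c(low = 0.35, high = 0.55,
                                                   dementia = 0.45,
                                                   psychogeriatric = 0.40),
                                pah_fraction_of_events = 1,
                                window = follow_up_window("2008-09-01",
                                                          "2010-07-01"),
                                seed = 20080901) {
  if (n_facilities < 1) stop("scenario requires at least one facility", call. = FALSE)
  if (abs(sum(care_level_mix) - 1) > 1e-8) {
    stop("care_level_mix probabilities must sum to 1", call. = FALSE)
  }
  if (any(!names(care_level_mix) %in% CARE_LEVELS)) {
    stop("unknown care level in care_level_mix", call. = FALSE)
  }
  stopifnot(residents_mean > 0, sigma_b_true >= 0, dispersion_k_true > 0,
            all(survival_rates > 0),
            pah_fraction_of_events >= 0, pah_fraction_of_events <= 1,
            inherits(window, "follow_up_window"))
  if (!"intercept" %in% names(beta_true)) {
    stop("beta_true must include an 'intercept' element", call. = FALSE)
  }
  covs <- setdiff(names(beta_true), "intercept")
  if (!setequal(covs, names(covariate_prevalence))) {
    stop("beta_true covariates must match covariate_prevalence names",
         call. = FALSE)
  }
  structure(list(n_facilities = as.integer(n_facilities),
                 residents_mean = residents_mean,
                 residents_dispersion = residents_dispersion,
                 care_level_mix = care_level_mix,
                 covariate_prevalence = covariate_prevalence,
                 beta_true = beta_true,
                 sigma_b_true = sigma_b_true,
                 dispersion_k_true = dispersion_k_true,
                 survival_rates = survival_rates,
                 pah_fraction_of_events = pah_fraction_of_events,
                 window = window, seed = as.integer(seed)),
            class = "simulation_scenario")
}

#' Named scenario presets
#'
#' * `"opal_like"` emulates the scale of a census-type regional survey:
#'   149 facilities of mean 42 residents (about 6.3 thousand residents),
#'   a 22-month follow-up window, and a baseline calibrated so the overall
#'   PAH rate is near 0.34 events per person-year.
#' * `"tiny"` is a 5-facility, ~10-residents-each cohort that runs the whole
#'   pipeline in seconds, used for oracle and smoke tests.
#'
#' @param name preset name; omit to list available presets.
#' @param seed master seed applied to the returned scenario.
#' @return A [simulation_scenario()] (or the preset names if `name` is
#'   missing).
#' @export
scenario_presets <- function(name, seed = 20080901) {
  presets <- list(
    opal_like = function() {
      sc <- simulation_scenario(n_facilities = 149, residents_mean = 42,
                                seed = seed)
      # calibrate the baseline so the marginal rate is 0.34 per person-year:
      # E[rate] = exp(b0) * prod_j(1 - p_j + p_j e^{beta_j}) * e^{sigma^2/2}
      covs <- setdiff(names(sc$beta_true), "intercept")
      p <- sc$covariate_prevalence[covs]
      bump <- sum(log(1 - p + p * exp(sc$beta_true[covs]))) +
        sc$sigma_b_true^2 / 2
      sc$beta_true["intercept"] <- log(0.34) - bump
      sc
    },
    tiny = function() {
      simulation_scenario(n_facilities = 5, residents_mean = 10,
                          residents_dispersion = 100, seed = seed)
    })
  if (missing(name)) return(names(presets))
  if (!name %in% names(presets)) {
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  }
  presets[[name]]()
}

#' Simulate a synthetic long-term care cohort
#'
#' Generates facilities, residents and coded hospital events with the
#' statistical structure the facility-profiling model assumes: facility
#' random intercepts `b_i ~ N(0, sigma_b^2)`; independent Bernoulli resident
#' covariates; exponential survival by care level censored at the window
#' end; per-resident event counts drawn NB2 with mean
#' `person_time x exp(beta0 + beta'x + b_i)` and size `k`; admission dates
#' uniform within each resident's exposure; and diagnosis codes drawn so
#' that exactly a `pah_fraction_of_events` share of events match the bundled
#' PAH code list (non-matching events use a disjoint `Z99`-style prefix
#' space). Fully reproducible given the scenario seed.
#'
#' @param scenario a [simulation_scenario()] or preset name.
#' @return A `pah_cohort` (see [read_cohort()]) whose attribute `"truth"`
#'   records the generating parameters and per-facility random intercepts.
#' @export
simulate_cohort <- function(scenario) {
  if (is.character(scenario)) scenario <- scenario_presets(scenario)
  stopifnot(inherits(scenario, "simulation_scenario"))
  sc <- scenario
  win <- sc$window

  # facility table stream
  set.seed(derive_seed(sc$seed, 1))
  G <- sc$n_facilities
  fac_id <- sprintf("F%03d", seq_len(G))
  n_res <- pmax(1L, stats::rnbinom(G, mu = sc$residents_mean,
                                   size = sc$residents_dispersion))
  strata <- paste0("DHB", 1 + (seq_len(G) - 1) %% 3)
  ownership <- sample(c("for_profit", "not_for_profit", "public"), G,
                      replace = TRUE, prob = c(0.6, 0.3, 0.1))
  chain <- stats::runif(G) < 0.4
  dist_km <- round(stats::rexp(G, rate = 1 / 6), 2)
  b_i <- stats::rnorm(G, 0, sc$sigma_b_true)

  # resident stream
  set.seed(derive_seed(sc$seed, 2))
  N <- sum(n_res)
  res_fac <- rep(fac_id, n_res)
  res_id <- sprintf("R%05d", seq_len(N))
  care <- sample(names(sc$care_level_mix), N, replace = TRUE,
                 prob = sc$care_level_mix)
  age <- round(pmin(pmax(stats::rnorm(N, 84, 7), 65), 105), 1)
  sex <- sample(c("female", "male"), N, replace = TRUE, prob = c(0.71, 0.29))
  covs <- names(sc$covariate_prevalence)
  xmat <- sapply(covs, function(cv) {
    as.integer(stats::runif(N) < sc$covariate_prevalence[[cv]])
  })
  xmat <- matrix(xmat, nrow = N, dimnames = list(NULL, covs))

  # survival stream: exponential by care level, censored at window end
  set.seed(derive_seed(sc$seed, 3))
  surv_years <- stats::rexp(N, rate = sc$survival_rates[care])
  died <- surv_years < win$years
  death_date <- rep(as.Date(NA), N)
  death_date[died] <- win$start + round(surv_years[died] * DAYS_PER_YEAR)
  death_date[died & death_date > win$end] <- NA  # rounding pushed past end
  entry_date <- rep(win$start, N)

  residents <- data.frame(resident_id = res_id, facility_id = res_fac,
                          care_level = care, age_years = age, sex = sex,
                          entry_date = entry_date, death_date = death_date,
                          stringsAsFactors = FALSE)
  for (cv in covs) residents[[cv]] <- xmat[, cv]
  pt <- person_time(residents, win)

  # event stream: NB2 counts with person-time x exp(eta) mean
  set.seed(derive_seed(sc$seed, 4))
  beta <- sc$beta_true
  eta <- beta[["intercept"]] + drop(xmat %*% beta[covs]) +
    b_i[match(res_fac, fac_id)]
  mu <- pt * exp(eta)
  n_ev <- integer(N)
  pos <- mu > 0
  n_ev[pos] <- stats::rnbinom(sum(pos), mu = mu[pos],
                              size = sc$dispersion_k_true)
  M <- sum(n_ev)
  ev_res <- rep(res_id, n_ev)
  ridx <- rep(seq_len(N), n_ev)
  # admission uniform within the resident's exposure
  adm_frac <- stats::runif(M)
  adm_date <- win$start + floor(adm_frac * pt[ridx] * DAYS_PER_YEAR)

  # diagnosis-code stream
  set.seed(derive_seed(sc$seed, 5))
  is_pah_event <- stats::runif(M) < sc$pah_fraction_of_events
  events <- data.frame(event_id = sprintf("E%06d", seq_len(max(M, 0))),
                       resident_id = ev_res,
                       admission_date = adm_date,
                       acute = rep(TRUE, M),
                       dx1 = character(M), dx2 = character(M),
                       dx3 = character(M),
                       stringsAsFactors = FALSE)
  if (M > 0) {
    dx1 <- draw_filler_codes(M)
    if (any(is_pah_event)) dx1[is_pah_event] <- draw_pah_codes(sum(is_pah_event))
    events$dx1 <- dx1
    # secondary diagnoses always from the disjoint non-PAH space
    events$dx2 <- draw_filler_codes(M)
    events$dx3 <- ifelse(stats::runif(M) < 0.5, draw_filler_codes(M), "")
  }

  fac <- data.frame(facility_id = fac_id,
                    care_levels = vapply(split(care, factor(res_fac, levels = fac_id)),
                                         function(x) paste(sort(unique(x)), collapse = ";"),
                                         character(1)),
                    n_beds = as.integer(ceiling(n_res * stats::runif(G, 1.0, 1.15))),
                    ownership = ownership,
                    chain_member = chain,
                    distance_to_hospital_km = dist_km,
                    stratum = strata,
                    stringsAsFactors = FALSE)

  cohort <- build_cohort(to_character_df(fac), to_character_df(residents),
                         to_character_df(events))
  attr(cohort, "truth") <- list(scenario = sc, b = stats::setNames(b_i, fac_id),
                                person_time = stats::setNames(pt, res_id),
                                n_events = stats::setNames(n_ev, res_id))
  pah_log("simulate", facilities = G, residents = N, events = M,
          seed = sc$seed)
  cohort
}

# PAH-matching codes: a prefix from the bundled list plus a numeric suffix.
draw_pah_codes <- function(n_pah) {
  prefixes <- load_code_list()$entries$code_prefix
  pick <- sample(prefixes, n_pah, replace = TRUE)
  suffix <- ifelse(grepl(".", pick, fixed = TRUE), "",
                   sprintf(".%d", sample(0:9, n_pah, replace = TRUE)))
  paste0(pick, suffix)
}

# Disjoint dummy prefix space, never matched by the bundled list.
draw_filler_codes <- function(M) {
  sprintf("Z99.%d", sample(0:9, M, replace = TRUE))
}

to_character_df <- function(df) {
  for (nm in names(df)) {
    if (inherits(df[[nm]], "Date")) {
      v <- format(df[[nm]], "%Y-%m-%d")
      v[is.na(v)] <- ""
      df[[nm]] <- v
    } else {
      df[[nm]] <- as.character(df[[nm]])
    }
  }
  df
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario: %d facilities, ~%g residents each, seed %d\n",
              x$n_facilities, x$residents_mean, x$seed))
  cat(sprintf("  window: %s to %s (%.2f y); sigma_b %.2f, k %.2f, PAH fraction %.2f\n",
              format(x$window$start), format(x$window$end), x$window$years,
              x$sigma_b_true, x$dispersion_k_true, x$pah_fraction_of_events))
  invisible(x)
}
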