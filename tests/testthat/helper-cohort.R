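# Fixture builders shared across tests. Everything is generated in code;
# CSV fixtures are written to tempfiles on demand.

options(pahrank.verbose = FALSE)

BASE_SEED <- 20080901  # fixed stream for all simulation-backed tests

toy_facilities <- function() {
  data.frame(
    facility_id = c("F1", "F2", "F3"),
    care_levels = c("low", "high", "low;high"),
    n_beds = c(20L, 30L, 25L),
    ownership = c("for_profit", "public", "not_for_profit"),
    chain_member = c(TRUE, FALSE, FALSE),
    distance_to_hospital_km = c(2.5, 10, 0),
    stratum = c("DHB1", "DHB1", "DHB2"),
    stringsAsFactors = FALSE)
}

toy_residents <- function() {
  data.frame(
    resident_id = sprintf("R%02d", 1:10),
    facility_id = c("F1", "F1", "F1", "F2", "F2", "F2", "F2", "F3", "F3", "F3"),
    care_level = c("low", "low", "low", "high", "high", "high", "high",
                   "low", "high", "low"),
    age_years = seq(70, 97, 3),
    sex = rep(c("female", "male"), 5),
    entry_date = "2008-01-01",
    death_date = c("", "", "2008-06-30", "", "2008-03-01", "", "", "", "", ""),
    gp_urgent_2wk = c(1, 0, 0, 1, 1, 0, 0, 0, 1, 0),
    ed_visit_prior_window = c(0, 0, 1, 0, 1, 0, 1, 0, 0, 0),
    prior_diabetes_admission = c(0, 1, 0, 0, 0, 0, 0, 1, 0, 0),
    prior_dementia_admission = c(0, 0, 0, 1, 0, 0, 0, 0, 0, 1),
    stringsAsFactors = FALSE)
}

toy_events <- function() {
  data.frame(
    event_id = sprintf("E%02d", 1:12),
    resident_id = c("R01", "R01", "R02", "R03", "R04", "R04", "R05", "R06",
                    "R08", "R08", "R09", "R10"),
    admission_date = c("2008-02-01", "2008-05-01", "2008-03-15", "2008-04-01",
                       "2008-02-20", "2008-07-01", "2008-02-25", "2008-08-01",
                       "2008-03-01", "2008-09-15", "2008-04-10", "2008-06-05"),
    acute = TRUE,
    dx1 = c("J18.9", "Z51.1", "I50.0", "N39.0", "Z51.1", "J44.1", "E86",
            "Z51.1", "L03.1", "Z51.1", "R55", "S72.0"),
    dx2 = c("", "J18.9", "", "", "I50.0", "", "", "", "", "", "", ""),
    dx3 = c("", "", "", "", "", "", "", "Z51.1", "", "J18.9", "", ""),
    stringsAsFactors = FALSE)
}

# Write a (facilities, residents, events) triple to CSVs and read it back
# through the public reader.
write_toy_csvs <- function(fac = toy_facilities(), res = toy_residents(),
                           ev = toy_events(), dir = withr::local_tempdir(
                             .local_envir = parent.frame())) {
  paths <- file.path(dir, c("facilities.csv", "residents.csv", "events.csv"))
  utils::write.csv(fac, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(res, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(ev, paths[3], row.names = FALSE, quote = FALSE)
  paths
}

read_toy_cohort <- function(fac = toy_facilities(), res = toy_residents(),
                            ev = toy_events()) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- write_toy_csvs(fac, res, ev, dir)
  read_cohort(paths[1], paths[2], paths[3])
}

toy_window <- function() follow_up_window("2008-01-01", "2009-01-01")

# Independent brute-force marginal log-likelihood: per-facility trapezoid
# integration of the NB x normal integrand on a wide grid, built on
# stats::dnbinom / stats::dnorm rather than any package internals.
brute_loglik <- function(y, eta, facility, sigma_b, k,
                         npts = 10001, half_width = 10) {
  f <- as.factor(facility)
  total <- 0
  grid <- seq(-half_width * sigma_b, half_width * sigma_b, length.out = npts)
  h <- grid[2] - grid[1]
  for (g in levels(f)) {
    idx <- f == g
    lf <- vapply(grid, function(b) {
      sum(stats::dnbinom(y[idx], size = k, mu = exp(eta[idx] + b), log = TRUE)) +
        stats::dnorm(b, 0, sigma_b, log = TRUE)
    }, numeric(1))
    m <- max(lf)
    w <- exp(lf - m)
    total <- total + m + log(h * (sum(w) - (w[1] + w[npts]) / 2))
  }
  total
}

# Per-resident model frame (count, exposure, covariates) for a cohort.
model_frame_for <- function(cohort, window, code_list = load_code_list()) {
  cnt <- count_pah_events(cohort$events, cohort$residents, code_list, window)
  df <- cohort$residents
  df$pah_count <- cnt$pah_count[match(df$resident_id, cnt$resident_id)]
  df$person_time <- person_time(df, window)
  df
}

CORE4 <- c("gp_urgent_2wk", "ed_visit_prior_window",
           "prior_diabetes_admission", "prior_dementia_admission")
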