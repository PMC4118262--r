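#' Read a cohort of facilities, residents and hospital events from CSV
#'
#' Reads and validates the three tables that describe a long-term care cohort:
#' facilities (one row per facility), residents (one row per resident, nested
#' in a facility) and hospital discharge events (one row per admission, with
#' ordered diagnosis code columns `dx1`, `dx2`, ...). Dates must be ISO-8601
#' (`YYYY-MM-DD`). All foreign keys are checked; unknown resident columns are
#' preserved as additional covariates.
#'
#' @param facility_path,resident_path,event_path paths to the three CSV files.
#' @return A list of class `pah_cohort` with elements `facilities`,
#'   `residents` and `events` (data frames with parsed dates), plus
#'   `covariate_cols`, the names of all resident covariate columns (the four
#'   core predictors and any extra columns found in the file).
#' @details Required columns:
#' * facilities: `facility_id`, `care_levels` (semicolon-joined subset of
#'   low/high/dementia/psychogeriatric), `n_beds`, `ownership`, `chain_member`,
#'   `distance_to_hospital_km`, `stratum`.
#' * residents: `resident_id`, `facility_id`, `care_level`, `age_years`,
#'   `sex`, `entry_date`, `death_date` (blank if alive), and the four core
#'   covariates `gp_urgent_2wk`, `ed_visit_prior_window`,
#'   `prior_diabetes_admission`, `prior_dementia_admission` (missing core
#'   covariate columns are created as 0). An optional `exit_date` column
#'   censors residents who leave the facility alive.
#' * events: `event_id`, `resident_id`, `admission_date`, `acute`, and one or
#'   more `dx<k>` columns holding ordered diagnosis codes (position 1 =
#'   primary diagnosis; blanks allowed).
#' @seealso [apply_filter()], [simulate_cohort()], [write_cohort()]
#' @export
read_cohort <- function(facility_path, resident_path, event_path) {
  facilities <- read_table_checked(facility_path, "facilities",
    c("facility_id", "care_levels", "n_beds", "ownership", "chain_member",
      "distance_to_hospital_km", "stratum"))
  residents <- read_table_checked(resident_path, "residents",
    c("resident_id", "facility_id", "care_level", "age_years", "sex",
      "entry_date", "death_date"))
  events <- read_table_checked(event_path, "events",
    c("event_id", "resident_id", "admission_date", "acute"))

  cohort <- build_cohort(facilities, residents, events)
  pah_log("read_cohort",
          facilities = nrow(cohort$facilities),
          residents = nrow(cohort$residents),
          events = nrow(cohort$events))
  cohort
}

read_table_checked <- function(path, what, required) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

CARE_LEVELS <- c("low", "high", "dementia", "psychogeriatric")
CORE_COVARIATES <- c("gp_urgent_2wk", "ed_visit_prior_window",
                     "prior_diabetes_admission", "prior_dementia_admission")

# Assemble and validate a cohort from raw (character) tables. Used both by
# read_cohort() and by the simulator round-trip tests.
build_cohort <- function(facilities, residents, events) {
  facilities$n_beds <- as.integer(facilities$n_beds)
  facilities$chain_member <- parse_logical(facilities$chain_member, "facilities$chain_member")
  facilities$distance_to_hospital_km <- as.numeric(facilities$distance_to_hospital_km)

  if (anyDuplicated(facilities$facility_id)) {
    stop("facilities: duplicated facility_id: ",
         paste(unique(facilities$facility_id[duplicated(facilities$facility_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(is.na(facilities$n_beds) | facilities$n_beds < 1)) {
    stop("facilities: n_beds must be a positive integer", call. = FALSE)
  }
  lv <- strsplit(facilities$care_levels, ";", fixed = TRUE)
  bad <- vapply(lv, function(x) length(x) == 0 || any(!x %in% CARE_LEVELS), logical(1))
  if (any(bad)) {
    stop("facilities: care_levels must be a nonempty ';'-joined subset of ",
         paste(CARE_LEVELS, collapse = "/"), " (offending: ",
         paste(facilities$facility_id[bad], collapse = ", "), ")", call. = FALSE)
  }

  residents$age_years <- as.numeric(residents$age_years)
  residents$entry_date <- parse_iso_date(residents$entry_date, "residents$entry_date")
  residents$death_date <- parse_iso_date(residents$death_date, "residents$death_date")
  if ("exit_date" %in% names(residents)) {
    residents$exit_date <- parse_iso_date(residents$exit_date, "residents$exit_date")
  }
  if (anyDuplicated(residents$resident_id)) {
    stop("residents: duplicated resident_id", call. = FALSE)
  }
  dangling <- setdiff(residents$facility_id, facilities$facility_id)
  if (length(dangling)) {
    stop("residents reference unknown facility_id: ",
         paste(sort(unique(dangling)), collapse = ", "), call. = FALSE)
  }
  if (any(!residents$care_level %in% CARE_LEVELS)) {
    stop("residents: care_level must be one of ",
         paste(CARE_LEVELS, collapse = "/"), call. = FALSE)
  }
  died <- !is.na(residents$death_date)
  if (any(died & residents$death_date < residents$entry_date)) {
    stop("residents: death_date precedes entry_date for ",
         paste(residents$resident_id[died & residents$death_date <
               residents$entry_date], collapse = ", "), call. = FALSE)
  }
  # Core model covariates always present (default 0); extra columns kept as
  # covariates, numeric where they sniff numeric (open 146-variable schema).
  for (cc in CORE_COVARIATES) {
    if (!cc %in% names(residents)) residents[[cc]] <- 0
  }
  fixed <- c("resident_id", "facility_id", "care_level", "age_years", "sex",
             "entry_date", "death_date", "exit_date")
  covariate_cols <- setdiff(names(residents), fixed)
  for (cc in covariate_cols) {
    v <- residents[[cc]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      if (!anyNA(num[nzchar(trimws(v))])) residents[[cc]] <- num
    }
  }
  for (cc in CORE_COVARIATES) {
    residents[[cc]][is.na(residents[[cc]])] <- 0
  }

  events$admission_date <- parse_iso_date(events$admission_date, "events$admission_date")
  events$acute <- parse_logical(events$acute, "events$acute")
  dangling_ev <- setdiff(events$resident_id, residents$resident_id)
  if (length(dangling_ev)) {
    stop("events reference unknown resident_id: ",
         paste(sort(unique(dangling_ev)), collapse = ", "), call. = FALSE)
  }
  dx_cols <- grep("^dx[0-9]+$", names(events), value = TRUE)
  dx_cols <- dx_cols[order(as.integer(sub("^dx", "", dx_cols)))]
  if (nrow(events) > 0 && length(dx_cols) == 0) {
    stop("events: no diagnosis columns (dx1, dx2, ...) found", call. = FALSE)
  }

  structure(list(facilities = facilities, residents = residents,
                 events = events, covariate_cols = covariate_cols,
                 dx_cols = dx_cols),
            class = "pah_cohort")
}

parse_logical <- function(x, what) {
  if (is.logical(x)) return(x)
  x <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
  if (anyNA(out)) stop(sprintf("%s: unparseable logical value(s)", what), call. = FALSE)
  out
}

#' @export
print.pah_cohort <- function(x, ...) {
  cat("Long-term care cohort\n")
  cat(sprintf("  facilities: %d\n  residents:  %d\n  events:     %d\n",
              nrow(x$facilities), nrow(x$residents), nrow(x$events)))
  cat(sprintf("  resident covariates: %s\n",
              paste(x$covariate_cols, collapse = ", ")))
  invisible(x)
}

#' Write a cohort back to CSV files
#'
#' Inverse of [read_cohort()]: writes `facilities.csv`, `residents.csv` and
#' `events.csv` under `dir` in the documented schemas (ISO-8601 dates, blank
#' for missing death dates).
#'
#' @param cohort a `pah_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pah_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("facilities.csv", "residents.csv", "events.csv"))
  fmt <- function(df) {
    for (nm in names(df)) {
      if (inherits(df[[nm]], "Date")) {
        v <- format(df[[nm]], "%Y-%m-%d")
        v[is.na(v)] <- ""
        df[[nm]] <- v
      }
    }
    df
  }
  utils::write.csv(fmt(cohort$facilities), paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(cohort$residents), paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(cohort$events), paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Follow-up window
#'
#' A half-open observation window `[start, end)`. Event membership is decided
#' on the admission date; person-time accrues from `max(entry, start)` to
#' `min(death-or-exit, end)`.
#'
#' @param start,end ISO-8601 strings or `Date`s; `end` must be after `start`.
#' @return An object of class `follow_up_window` with elements `start`, `end`
#'   and `years` (window length in years of 365.25 days).
#' @export
follow_up_window <- function(start, end) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("window dates must parse as ISO-8601", call. = FALSE)
  if (end <= start) stop("window end_date must be after start_date", call. = FALSE)
  structure(list(start = start, end = end,
                 years = as.numeric(end - start) / DAYS_PER_YEAR),
            class = "follow_up_window")
}

#' Cohort filter
#'
#' Conjunctive, idempotent cohort exclusion rules applied before ranking.
#'
#' @param exclude_care_levels care levels to exclude (character). With
#'   `whole_facility = TRUE` (the default, matching the exclusion of all
#'   high-level-care facilities from selection), any facility offering an
#'   excluded care level is dropped with all its residents; with `FALSE`, only
#'   residents in excluded levels are dropped, and a mixed facility is kept if
#'   at least `min_residents` residents remain.
#' @param min_residents minimum residents a facility must retain.
#' @param strata_include optional set of strata (DHB analogues) to keep.
#' @param whole_facility see `exclude_care_levels`.
#' @return An object of class `cohort_filter`.
#' @export
cohort_filter <- function(exclude_care_levels = character(),
                          min_residents = 0L,
                          strata_include = NULL,
                          whole_facility = TRUE) {
  exclude_care_levels <- as.character(exclude_care_levels)
  if (length(exclude_care_levels) && any(!exclude_care_levels %in% CARE_LEVELS)) {
    stop("unknown care level(s): ",
         paste(setdiff(exclude_care_levels, CARE_LEVELS), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(min_residents >= 0)
  structure(list(exclude_care_levels = exclude_care_levels,
                 min_residents = as.integer(min_residents),
                 strata_include = strata_include,
                 whole_facility = isTRUE(whole_facility)),
            class = "cohort_filter")
}

#' Apply a cohort filter
#'
#' Drops facilities and residents according to a [cohort_filter()]. Events of
#' dropped residents are removed too, so the result is again a consistent
#' `pah_cohort`. Filtering is idempotent and never adds rows.
#'
#' @param cohort a `pah_cohort`.
#' @param filter a `cohort_filter`.
#' @return The filtered `pah_cohort`.
#' @export
apply_filter <- function(cohort, filter) {
  stopifnot(inherits(cohort, "pah_cohort"), inherits(filter, "cohort_filter"))
  fac <- cohort$facilities
  res <- cohort$residents
  ev <- cohort$events
  n_res_in <- nrow(res)

  if (!is.null(filter$strata_include)) {
    fac <- fac[fac$stratum %in% filter$strata_include, , drop = FALSE]
  }
  if (length(filter$exclude_care_levels)) {
    if (filter$whole_facility) {
      offers_excluded <- vapply(strsplit(fac$care_levels, ";", fixed = TRUE),
                                function(x) any(x %in% filter$exclude_care_levels),
                                logical(1))
      fac <- fac[!offers_excluded, , drop = FALSE]
      res <- res[res$facility_id %in% fac$facility_id, , drop = FALSE]
    } else {
      res <- res[!res$care_level %in% filter$exclude_care_levels, , drop = FALSE]
    }
  }
  res <- res[res$facility_id %in% fac$facility_id, , drop = FALSE]
  if (filter$min_residents > 0) {
    keep <- names(which(table(factor(res$facility_id, levels = fac$facility_id)) >=
                        filter$min_residents))
    fac <- fac[fac$facility_id %in% keep, , drop = FALSE]
    res <- res[res$facility_id %in% fac$facility_id, , drop = FALSE]
  }
  if (nrow(fac) == 0) {
    stop("cohort filter excludes every facility", call. = FALSE)
  }
  ev <- ev[ev$resident_id %in% res$resident_id, , drop = FALSE]
  pah_log("apply_filter",
          facilities_kept = nrow(fac), residents_kept = nrow(res),
          residents_excluded = n_res_in - nrow(res), events_kept = nrow(ev))
  out <- cohort
  out$facilities <- fac
  out$residents <- res
  out$events <- ev
  out
}
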