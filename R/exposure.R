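#' Person-time at risk within a follow-up window
#'
#' Years at risk for each resident: from the later of entry and window start
#' to the earliest of death, exit (if an `exit_date` column is present) and
#' window end, floored at zero. A year is 365.25 days.
#'
#' @param residents resident data frame (parsed dates, see [read_cohort()]).
#' @param window a [follow_up_window()].
#' @return Numeric vector of years, one per resident row, each in
#'   `[0, window$years]`.
#' @export
person_time <- function(residents, window) {
  stopifnot(inherits(window, "follow_up_window"))
  start <- pmax(residents$entry_date, window$start)
  end <- residents$death_date
  end[is.na(end)] <- window$end
  if ("exit_date" %in% names(residents)) {
    exit <- residents$exit_date
    use <- !is.na(exit)
    end[use] <- pmin(end[use], exit[use])
  }
  end <- pmin(end, window$end)
  pmax(as.numeric(end - start), 0) / DAYS_PER_YEAR
}

#' Mean survival time by care level
#'
#' Observed mean person-time over the window per resident care level,
#' censored at the window end (no extrapolation beyond follow-up). This is
#' the survey-to-death construction behind the approximate person-time
#' denominator: where individual follow-up is unavailable, current resident
#' counts by care level are multiplied by these means.
#'
#' @inheritParams person_time
#' @return An object of class `mean_survival_table`: a named numeric vector
#'   of mean years, one entry per care level observed in `residents`.
#' @export
estimate_mean_survival <- function(residents, window) {
  pt <- person_time(residents, window)
  means <- tapply(pt, factor(residents$care_level, levels = CARE_LEVELS), mean)
  absent <- names(means)[is.na(means)]
  if (length(absent)) {
    warning("no residents in care level(s): ", paste(absent, collapse = ", "),
            "; omitted from mean-survival table", call. = FALSE)
  }
  structure(means[!is.na(means)], class = "mean_survival_table")
}

#' Approximate facility person-time from care-level counts
#'
#' `sum over care levels of count x min(mean survival, window length)`:
#' the denominator used when only current resident headcounts by care level
#' are known, not individual entry/death dates.
#'
#' @param care_level_counts named integer vector (names are care levels).
#' @param table a [mean_survival_table][estimate_mean_survival].
#' @param window a [follow_up_window()]; mean survival is capped at its
#'   length so no resident can contribute more exposure than the window holds.
#' @return Person-years (scalar).
#' @export
approximate_facility_person_time <- function(care_level_counts, table, window) {
  stopifnot(inherits(table, "mean_survival_table"),
            inherits(window, "follow_up_window"))
  care_level_counts <- care_level_counts[care_level_counts > 0]
  if (!length(care_level_counts)) return(0)
  missing <- setdiff(names(care_level_counts), names(table))
  if (length(missing)) {
    stop("no mean-survival entry for care level(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sum(care_level_counts * pmin(unclass(table)[names(care_level_counts)], window$years))
}

#' Aggregate residents, exposure and PAH counts to facility level
#'
#' Builds one row per facility holding resident count, PAH count,
#' person-years (exact sum of resident person-time, or the care-level
#' mean-survival approximation), care-level headcounts, and facility-level
#' covariate means/proportions for every resident covariate column.
#'
#' @param cohort a `pah_cohort` (possibly filtered).
#' @param pah_counts per-resident counts from [count_pah_events()].
#' @param window a [follow_up_window()].
#' @param mode `"exact"` (default) sums individual person-time;
#'   `"approximate"` multiplies care-level headcounts by mean survival.
#' @param survival_table optional [mean_survival_table][estimate_mean_survival]
#'   for `mode = "approximate"`; estimated from the cohort itself if omitted.
#' @return A data frame of class `facility_aggregates`: `facility_id`,
#'   `n_residents`, `n_beds`, `stratum`, `pah_count`, `person_years`,
#'   `care_<level>` headcounts, one column per covariate proportion/mean, and
#'   `flag_zero_residents`.
#' @export
aggregate_facilities <- function(cohort, pah_counts, window,
                                 mode = c("exact", "approximate"),
                                 survival_table = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "pah_cohort"), inherits(window, "follow_up_window"))
  fac <- cohort$facilities
  res <- cohort$residents
  fid <- factor(res$facility_id, levels = fac$facility_id)

  counts <- pah_counts$pah_count[match(res$resident_id, pah_counts$resident_id)]
  if (anyNA(counts)) {
    stop("pah_counts missing resident(s): ",
         paste(utils::head(res$resident_id[is.na(counts)], 5), collapse = ", "),
         call. = FALSE)
  }

  agg <- data.frame(facility_id = fac$facility_id,
                    n_residents = as.integer(table(fid)),
                    n_beds = fac$n_beds,
                    stratum = fac$stratum,
                    pah_count = as.integer(rowsum_by(counts, fid)),
                    stringsAsFactors = FALSE)

  lvl_counts <- table(fid, factor(res$care_level, levels = CARE_LEVELS))
  for (lv in CARE_LEVELS) agg[[paste0("care_", lv)]] <- as.integer(lvl_counts[, lv])

  if (mode == "exact") {
    agg$person_years <- as.numeric(rowsum_by(person_time(res, window), fid))
  } else {
    if (is.null(survival_table)) survival_table <- estimate_mean_survival(res, window)
    agg$person_years <- vapply(seq_len(nrow(agg)), function(i) {
      cc <- unlist(agg[i, paste0("care_", CARE_LEVELS)])
      names(cc) <- CARE_LEVELS
      approximate_facility_person_time(cc, survival_table, window)
    }, numeric(1))
  }

  for (cv in cohort$covariate_cols) {
    v <- res[[cv]]
    if (!is.numeric(v)) next
    m <- rowsum_by(v, fid) / pmax(agg$n_residents, 1)
    agg[[cv]] <- as.numeric(m)
  }

  agg$flag_zero_residents <- agg$n_residents == 0
  if (any(agg$flag_zero_residents)) {
    warning("facility with zero residents: ",
            paste(agg$facility_id[agg$flag_zero_residents], collapse = ", "),
            call. = FALSE)
  }
  pah_log("aggregate", facilities = nrow(agg),
          pah_total = sum(agg$pah_count),
          person_years = round(sum(agg$person_years), 2), mode = mode)
  class(agg) <- c("facility_aggregates", "data.frame")
  agg
}

# group sums with zero (not NA) for empty groups, keeping factor level order
rowsum_by <- function(x, f) {
  out <- numeric(nlevels(f))
  s <- rowsum(x, f)
  out[match(rownames(s), levels(f))] <- s[, 1]
  out
}
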