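#' Classify diagnosis codes as potentially avoidable
#'
#' `is_pah()` decides for one event whether any diagnosis at position
#' `1..max_diagnosis_position` matches the code list; a match at a deeper
#' position (e.g. the fourth diagnosis) does not count. `classify_events()`
#' is the vectorised version over an event table.
#'
#' @param diagnosis_codes character vector of ordered diagnosis codes for one
#'   event (position 1 = primary); blanks/NA ignored. May be empty.
#' @param code_list a [pah_code_list][load_code_list].
#' @return `is_pah()`: a single logical. `classify_events()`: a logical
#'   vector, one element per event row.
#' @export
is_pah <- function(diagnosis_codes, code_list) {
  stopifnot(inherits(code_list, "pah_code_list"))
  k <- code_list$max_diagnosis_position
  codes <- as.character(diagnosis_codes)
  codes <- codes[seq_len(min(length(codes), k))]
  codes <- codes[!is.na(codes) & nzchar(trimws(codes))]
  if (!length(codes)) return(FALSE)
  any(matches_any_prefix(normalize_code(codes), code_list$entries$prefix_norm))
}

matches_any_prefix <- function(codes_norm, prefixes_norm) {
  out <- rep(FALSE, length(codes_norm))
  for (p in prefixes_norm) {
    out <- out | startsWith(codes_norm, p)
  }
  out
}

#' @param events event data frame with ordered `dx1`, `dx2`, ... columns.
#' @rdname is_pah
#' @export
classify_events <- function(events, code_list) {
  stopifnot(inherits(code_list, "pah_code_list"))
  dx_cols <- grep("^dx[0-9]+$", names(events), value = TRUE)
  dx_cols <- dx_cols[order(as.integer(sub("^dx", "", dx_cols)))]
  dx_cols <- utils::head(dx_cols, code_list$max_diagnosis_position)
  out <- rep(FALSE, nrow(events))
  for (col in dx_cols) {
    v <- as.character(events[[col]])
    ok <- !is.na(v) & nzchar(trimws(v))
    if (any(ok)) {
      out[ok] <- out[ok] |
        matches_any_prefix(normalize_code(v[ok]), code_list$entries$prefix_norm)
    }
  }
  out
}

#' Count PAH events per resident within a follow-up window
#'
#' Counts, for every resident, the hospital events classified as potentially
#' avoidable whose admission date falls in the half-open window
#' `[start, end)`. Residents without any qualifying event get a count of 0.
#'
#' @param events event data frame (see [read_cohort()]).
#' @param residents resident data frame; every event's `resident_id` must
#'   appear here.
#' @param code_list a [pah_code_list][load_code_list].
#' @param window a [follow_up_window()].
#' @param acute_only if `TRUE` (default) only acute admissions are counted,
#'   matching a definition restricted to acute unplanned admissions.
#' @return A data frame `resident_id`, `facility_id`, `pah_count`, one row
#'   per resident, in the residents' row order.
#' @export
count_pah_events <- function(events, residents, code_list, window,
                             acute_only = TRUE) {
  stopifnot(inherits(window, "follow_up_window"))
  unknown <- setdiff(events$resident_id, residents$resident_id)
  if (length(unknown)) {
    stop("events reference unknown resident_id: ",
         paste(sort(unique(unknown)), collapse = ", "), call. = FALSE)
  }
  keep <- events$admission_date >= window$start &
    events$admission_date < window$end
  if (acute_only) keep <- keep & events$acute
  keep <- keep & classify_events(events, code_list)
  counts <- table(factor(events$resident_id[keep],
                         levels = residents$resident_id))
  data.frame(resident_id = residents$resident_id,
             facility_id = residents$facility_id,
             pah_count = as.integer(counts),
             stringsAsFactors = FALSE)
}
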