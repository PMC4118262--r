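#' Ranking values for the four selection methods
#'
#' Per-facility values underlying each ranking method:
#' * Method 1 (`method1_values`): observed events per resident (or per bed
#'   with `denominator = "beds"`), ignoring survival and turnover.
#' * Method 2 (`method2_values`): observed events per person-year at risk,
#'   using exact or approximate exposure as carried by the aggregates.
#' * Method 3 (`method3_values`): model-predicted expected counts — a
#'   case-mix-adjusted predictive risk score from
#'   [predict_facility_counts()].
#' * Method 4 (`method4_values`): the change in ranks, observed (Method 2)
#'   minus predicted (Method 3); a large positive change marks a facility
#'   observed well above what its case-mix predicts.
#' * `residual_values`: observed minus predicted counts (`type = "raw"`), or
#'   Pearson residuals `(obs - pred)/sqrt(pred + pred^2/k)`.
#'
#' Facilities with a zero denominator are flagged with `NA` and excluded
#' from ranking (but kept in reports).
#'
#' @param aggregates a [facility_aggregates][aggregate_facilities] table.
#' @param denominator for Method 1: `"residents"` (default) or `"beds"`.
#' @return A numeric vector, one value per facility row (named by
#'   `facility_id` where the input carries it).
#' @name ranking_values
NULL

#' @rdname ranking_values
#' @export
method1_values <- function(aggregates, denominator = c("residents", "beds")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "residents") aggregates$n_residents else aggregates$n_beds
  flag_zero_denominator(aggregates$pah_count / den, aggregates$facility_id,
                        den, "method1")
}

#' @rdname ranking_values
#' @export
method2_values <- function(aggregates) {
  flag_zero_denominator(aggregates$pah_count / aggregates$person_years,
                        aggregates$facility_id, aggregates$person_years,
                        "method2")
}

flag_zero_denominator <- function(v, ids, den, what) {
  bad <- !is.finite(v) | den <= 0
  if (any(bad)) {
    warning(sprintf("%s: zero denominator for facility %s; excluded from ranking",
                    what, paste(ids[bad], collapse = ", ")), call. = FALSE)
    v[bad] <- NA_real_
  }
  names(v) <- ids
  v
}

#' @rdname ranking_values
#' @param model an [nbmm] fit (Method 3 / residuals).
#' @export
method3_values <- function(model, aggregates) {
  predict_facility_counts(model, aggregates)
}

#' @rdname ranking_values
#' @param rank2,rank3 integer rank vectors from [rank_values()] over the same
#'   facilities (names must agree as sets).
#' @export
method4_values <- function(rank2, rank3) {
  if (!setequal(names(rank2), names(rank3)) ||
      length(rank2) != length(rank3)) {
    stop("method4: facility sets differ: ",
         paste(c(setdiff(names(rank2), names(rank3)),
                 setdiff(names(rank3), names(rank2))), collapse = ", "),
         call. = FALSE)
  }
  rank2 - rank3[names(rank2)]
}

#' @rdname ranking_values
#' @param observed,predicted aligned per-facility observed and expected
#'   counts.
#' @param type `"raw"` or `"pearson"`.
#' @param k NB2 size parameter for the Pearson variance `pred + pred^2/k`;
#'   `Inf` gives the Poisson-scaled residual.
#' @export
residual_values <- function(observed, predicted, type = c("raw", "pearson"),
                            k = Inf) {
  type <- match.arg(type)
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must be aligned", call. = FALSE)
  }
  if (any(predicted < 0)) stop("negative predicted count", call. = FALSE)
  r <- observed - predicted
  if (type == "pearson") {
    r <- r / sqrt(predicted + predicted^2 / k)
  }
  r
}

#' Rank facilities by a value (1 = lowest use)
#'
#' Ascending ranks with a deterministic tie-break so the result is always a
#' strict permutation of `1..n`: ties are resolved by facility id order
#' (stable, documented in the rank table). A rank of one signifies the
#' lowest PAH use; rank `n` the highest.
#'
#' @param values named numeric vector (names = facility ids). `NA` values
#'   (flagged facilities) are returned as `NA` ranks and skipped; remaining
#'   ranks are a permutation of `1..(number of non-flagged)`. Values are
#'   compared at 12 significant digits, so ratios that are equal up to
#'   floating-point rounding (e.g. the same rate computed through different
#'   denominators) tie and fall to the id tie-break.
#' @param ids facility ids (defaults to `names(values)`).
#' @return Integer vector of ranks, named by facility id.
#' @export
rank_values <- function(values, ids = names(values)) {
  if (is.null(ids)) stop("rank_values: facility ids required", call. = FALSE)
  if (any(is.nan(values) | is.infinite(values))) {
    stop("rank_values: non-finite value for facility ",
         paste(ids[is.nan(values) | is.infinite(values)], collapse = ", "),
         call. = FALSE)
  }
  ok <- !is.na(values)
  r <- rep(NA_integer_, length(values))
  ord <- order(signif(values[ok], 12), ids[ok])
  r[which(ok)[ord]] <- seq_len(sum(ok))
  names(r) <- ids
  r
}

#' Assemble the facility rank table
#'
#' Computes values and ranks for Methods 1-4 and the residual variant and
#' returns them as one table, one row per facility. Methods 3, 4 and the
#' residual require a fitted model; without one only Methods 1-2 are
#' computed.
#'
#' @param aggregates a [facility_aggregates][aggregate_facilities] table.
#' @param model optional [nbmm] fit.
#' @param method1_denominator `"residents"` or `"beds"`.
#' @param residual_type `"raw"` or `"pearson"`.
#' @param method4_absolute rank Method 4 by absolute rather than signed rank
#'   change (default signed: positive change = more use than predicted).
#' @return A data frame of class `pah_rank_table` with columns
#'   `facility_id`, `stratum`, `value_method1` ... `value_residual`,
#'   `rank_method1` ... `rank_residual`, and a `tie_break` attribute
#'   documenting the tie rule.
#' @export
rank_facilities <- function(aggregates, model = NULL,
                            method1_denominator = c("residents", "beds"),
                            residual_type = c("raw", "pearson"),
                            method4_absolute = FALSE) {
  method1_denominator <- match.arg(method1_denominator)
  residual_type <- match.arg(residual_type)
  out <- data.frame(facility_id = aggregates$facility_id,
                    stratum = aggregates$stratum %||%
                      rep(NA_character_, nrow(aggregates)),
                    stringsAsFactors = FALSE)
  v1 <- method1_values(aggregates, method1_denominator)
  v2 <- method2_values(aggregates)
  out$value_method1 <- unname(v1)
  out$rank_method1 <- unname(rank_values(v1))
  out$value_method2 <- unname(v2)
  r2 <- rank_values(v2)
  out$rank_method2 <- unname(r2)
  if (!is.null(model)) {
    v3 <- method3_values(model, aggregates)
    r3 <- rank_values(v3)
    out$value_method3 <- unname(v3)
    out$rank_method3 <- unname(r3)
    chg <- method4_values(r2, r3)
    out$value_method4 <- unname(chg)
    out$rank_method4 <- unname(rank_values(if (method4_absolute) abs(chg) else chg,
                                           ids = names(chg)))
    res <- residual_values(aggregates$pah_count, unname(v3),
                           type = residual_type, k = model$k)
    names(res) <- aggregates$facility_id
    out$value_residual <- unname(res)
    out$rank_residual <- unname(rank_values(res))
  }
  attr(out, "tie_break") <- "stable ascending by (value, facility_id)"
  attr(out, "method1_denominator") <- method1_denominator
  attr(out, "residual_type") <- residual_type
  class(out) <- c("pah_rank_table", "data.frame")
  out
}

rank_methods <- function(rank_table) {
  sub("^rank_", "", grep("^rank_", names(rank_table), value = TRUE))
}

#' @export
print.pah_rank_table <- function(x, ...) {
  cat(sprintf("Facility rank table: %d facilities; methods: %s\n",
              nrow(x), paste(rank_methods(x), collapse = ", ")))
  cat(sprintf("  tie break: %s\n", attr(x, "tie_break")))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Select the top-ranked facilities
#'
#' Returns the `n` facilities with the highest use by the chosen method —
#' the largest rank numbers, since rank 1 is the lowest use. With `strata`,
#' selection is performed within each stratum (e.g. 12 facilities per
#' district health board), re-ranking facilities inside the stratum.
#'
#' @param rank_table a [pah_rank_table][rank_facilities].
#' @param method one of the computed methods (e.g. `"method2"`).
#' @param n how many facilities to select (per stratum when stratified).
#' @param strata if `TRUE`, select within each stratum of the table.
#' @return A data frame `facility_id`, `stratum`, `value`, `rank` (and
#'   `stratum_rank` when stratified), highest use first.
#' @export
select_top <- function(rank_table, method, n, strata = FALSE) {
  stopifnot(n >= 1)
  if (!method %in% rank_methods(rank_table)) {
    stop(sprintf("method '%s' not computed; available: %s", method,
                 paste(rank_methods(rank_table), collapse = ", ")),
         call. = FALSE)
  }
  val <- rank_table[[paste0("value_", method)]]
  rk <- rank_table[[paste0("rank_", method)]]
  base <- data.frame(facility_id = rank_table$facility_id,
                     stratum = rank_table$stratum,
                     value = val, rank = rk, stringsAsFactors = FALSE)
  base <- base[!is.na(base$rank), , drop = FALSE]
  pick <- function(df) {
    df <- df[order(-df$rank), , drop = FALSE]
    if (n > nrow(df)) {
      warning(sprintf("requested %d facilities but only %d available%s",
                      n, nrow(df),
                      if (strata) sprintf(" in stratum %s", df$stratum[1]) else ""),
              call. = FALSE)
    }
    utils::head(df, n)
  }
  if (strata) {
    out <- do.call(rbind, lapply(split(base, base$stratum), function(df) {
      df$stratum_rank <- unname(rank_values(stats::setNames(df$value, df$facility_id)))
      pick(df)
    }))
    rownames(out) <- NULL
    out
  } else {
    out <- pick(base)
    rownames(out) <- NULL
    out
  }
}

#' Compare two ranking methods
#'
#' Summarises the agreement between two computed methods: size of the top-`n`
#' overlap, Spearman correlation of the full rankings, and per-facility rank
#' shifts.
#'
#' @param rank_table a [pah_rank_table][rank_facilities].
#' @param method_a,method_b computed method names.
#' @param top_n size of the "top" sets compared (default 10).
#' @return A list of class `pah_method_comparison`: `overlap` (count),
#'   `top_a`, `top_b` (facility ids), `spearman`, and `shifts` (data frame
#'   `facility_id`, `rank_a`, `rank_b`, `shift`).
#' @export
compare_methods <- function(rank_table, method_a, method_b, top_n = 10) {
  for (m in c(method_a, method_b)) {
    if (!m %in% rank_methods(rank_table)) {
      stop(sprintf("method '%s' not computed", m), call. = FALSE)
    }
  }
  ra <- rank_table[[paste0("rank_", method_a)]]
  rb <- rank_table[[paste0("rank_", method_b)]]
  ok <- !is.na(ra) & !is.na(rb)
  ids <- rank_table$facility_id
  top_a <- ids[ok][order(-ra[ok])][seq_len(min(top_n, sum(ok)))]
  top_b <- ids[ok][order(-rb[ok])][seq_len(min(top_n, sum(ok)))]
  structure(list(method_a = method_a, method_b = method_b, top_n = top_n,
                 overlap = length(intersect(top_a, top_b)),
                 top_a = top_a, top_b = top_b,
                 spearman = stats::cor(ra[ok], rb[ok], method = "spearman"),
                 shifts = data.frame(facility_id = ids[ok],
                                     rank_a = ra[ok], rank_b = rb[ok],
                                     shift = ra[ok] - rb[ok],
                                     stringsAsFactors = FALSE)),
            class = "pah_method_comparison")
}

#' @export
print.pah_method_comparison <- function(x, ...) {
  cat(sprintf("Rank comparison %s vs %s: top-%d overlap %d, Spearman %.3f\n",
              x$method_a, x$method_b, x$top_n, x$overlap, x$spearman))
  invisible(x)
}

#' Write a rank report (tab-separated)
#'
#' One row per facility with all computed values and ranks, sorted by the
#' chosen method's rank — the tabular analogue of a rank-comparison bar
#' chart. Deterministic formatting: identical inputs give byte-identical
#' files.
#'
#' @param rank_table a [pah_rank_table][rank_facilities].
#' @param path output TSV path.
#' @param sort_by method whose rank orders the rows (default `"method2"`).
#' @return `path`, invisibly.
#' @export
write_rank_report <- function(rank_table, path, sort_by = "method2") {
  if (!sort_by %in% rank_methods(rank_table)) {
    stop(sprintf("unknown sort method '%s'; available: %s", sort_by,
                 paste(rank_methods(rank_table), collapse = ", ")),
         call. = FALSE)
  }
  df <- as.data.frame(rank_table)
  df <- df[order(df[[paste0("rank_", sort_by)]], df$facility_id), , drop = FALSE]
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- formatC(df[[nm]], format = "g", digits = 10)
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
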