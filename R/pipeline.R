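#' Build and validate a pipeline configuration
#'
#' The configuration drives [run_pipeline()] and the command-line interface.
#' It is validated as a whole before any stage runs; unknown keys are
#' rejected so typos fail loudly.
#'
#' @param window list with `start` and `end` (ISO-8601).
#' @param paths list with either `facilities`, `residents`, `events` (input
#'   CSVs) or nothing (when `simulate` is given), plus `out_dir`.
#' @param simulate optional: a preset name (see [scenario_presets()]) or a
#'   list of [simulation_scenario()] arguments; when present the cohort is
#'   generated rather than read.
#' @param filters list: `exclude_care_levels`, `min_residents`,
#'   `strata_include`, `whole_facility` (see [cohort_filter()]).
#' @param classification list: `code_list` (path; `NULL` = bundled default),
#'   `acute_only`, `max_position`.
#' @param exposure list: `mode` (`"exact"` or `"approximate"`).
#' @param model list: `covariates` (default: the four core predictors),
#'   `offset_mode`, `quadrature_points`, `alpha`, `backward_elimination`.
#' @param ranking list: `methods` sort order for the report (`sort_by`),
#'   `top_n`, `stratified`, `residual_type`, `method1_denominator`,
#'   `select_method`.
#' @param seed integer seed for any simulated input.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(window, paths,
                            simulate = NULL,
                            filters = list(),
                            classification = list(),
                            exposure = list(),
                            model = list(),
                            ranking = list(),
                            seed = 1L) {
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra)) {
      stop(sprintf("unknown config key(s) in %s: %s", where,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
  }
  check_keys(window, c("start", "end"), "window")
  check_keys(paths, c("facilities", "residents", "events", "out_dir"), "paths")
  check_keys(filters, c("exclude_care_levels", "min_residents",
                        "strata_include", "whole_facility"), "filters")
  check_keys(classification, c("code_list", "acute_only", "max_position"),
             "classification")
  check_keys(exposure, c("mode"), "exposure")
  check_keys(model, c("covariates", "offset_mode", "quadrature_points",
                      "alpha", "backward_elimination", "unit"), "model")
  check_keys(ranking, c("sort_by", "top_n", "stratified", "residual_type",
                        "method1_denominator", "select_method",
                        "method4_absolute"), "ranking")
  if (is.null(paths$out_dir)) stop("paths$out_dir is required", call. = FALSE)
  win <- follow_up_window(window$start, window$end)
  cfg <- list(
    window = win,
    paths = paths,
    simulate = simulate,
    filter = cohort_filter(
      exclude_care_levels = filters$exclude_care_levels %||% character(),
      min_residents = filters$min_residents %||% 0L,
      strata_include = if (!is.null(filters$strata_include))
        as.character(unlist(filters$strata_include)),
      whole_facility = filters$whole_facility %||% TRUE),
    classification = list(
      code_list = classification$code_list,
      acute_only = classification$acute_only %||% TRUE,
      max_position = classification$max_position %||% 3L),
    exposure = list(mode = match.arg(exposure$mode %||% "exact",
                                     c("exact", "approximate"))),
    model = list(
      covariates = as.character(unlist(model$covariates %||% CORE_COVARIATES)),
      offset_mode = match.arg(model$offset_mode %||% "log_person_time",
                              c("log_person_time", "none")),
      quadrature_points = model$quadrature_points %||% 15L,
      alpha = model$alpha %||% 0.05,
      backward_elimination = model$backward_elimination %||% FALSE,
      unit = match.arg(model$unit %||% "resident", c("resident", "facility"))),
    ranking = list(
      sort_by = ranking$sort_by %||% "method2",
      top_n = ranking$top_n %||% 10L,
      stratified = ranking$stratified %||% FALSE,
      residual_type = match.arg(ranking$residual_type %||% "raw",
                                c("raw", "pearson")),
      method1_denominator = match.arg(ranking$method1_denominator %||% "residents",
                                      c("residents", "beds")),
      select_method = ranking$select_method %||% "method4",
      method4_absolute = ranking$method4_absolute %||% FALSE),
    seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("window", "paths", "simulate", "filters", "classification",
               "exposure", "model", "ranking", "seed")
  extra <- setdiff(names(raw), allowed)
  if (length(extra)) {
    stop("unknown top-level config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw[intersect(allowed, names(raw))])
}

#' Run the full facility-selection pipeline
#'
#' Orchestrates simulate/read -> filter -> classify -> aggregate -> fit ->
#' rank -> select -> report over the documented file formats. Writes into
#' `config$paths$out_dir`: `aggregates.csv`, `model.json`, `ranks.tsv`,
#' `selection.tsv` and `comparison.tsv`. The pipeline is a pure function of
#' (inputs, config, seed): identical reruns produce byte-identical outputs.
#'
#' @param config a [pipeline_config()] (or path to a YAML config).
#' @return Invisibly, a list with the in-memory stage results: `cohort`,
#'   `aggregates`, `model`, `elimination`, `rank_table`, `selection`,
#'   `comparisons`, and `files` (the written paths).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$paths$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cohort <- stage("input", {
    if (!is.null(config$simulate)) {
      sc <- if (is.character(config$simulate)) {
        scenario_presets(config$simulate, seed = config$seed)
      } else {
        args <- config$simulate
        args$seed <- config$seed
        args$window <- config$window
        do.call(simulation_scenario, args)
      }
      simulate_cohort(sc)
    } else {
      read_cohort(config$paths$facilities, config$paths$residents,
                  config$paths$events)
    }
  })
  cohort <- stage("filter", apply_filter(cohort, config$filter))
  code_list <- stage("code_list", load_code_list(
    config$classification$code_list %||% default_code_list_path(),
    max_diagnosis_position = config$classification$max_position))
  counts <- stage("classify", count_pah_events(
    cohort$events, cohort$residents, code_list, config$window,
    acute_only = config$classification$acute_only))
  aggregates <- stage("aggregate", aggregate_facilities(
    cohort, counts, config$window, mode = config$exposure$mode))

  model_data <- stage("model_frame", {
    if (config$model$unit == "resident") {
      df <- cohort$residents
      df$pah_count <- counts$pah_count[match(df$resident_id, counts$resident_id)]
      df$person_time <- person_time(df, config$window)
      df
    } else {
      df <- as.data.frame(aggregates)
      df$person_time <- df$person_years
      df
    }
  })
  elim <- NULL
  model <- stage("fit", {
    if (isTRUE(config$model$backward_elimination)) {
      elim <<- backward_eliminate(
        model_data, covariates = config$model$covariates,
        alpha = config$model$alpha,
        offset_mode = config$model$offset_mode,
        quadrature_points = config$model$quadrature_points)
      elim$model
    } else {
      nbmm_fit(model_data, covariates = config$model$covariates,
               offset_mode = config$model$offset_mode,
               quadrature_points = config$model$quadrature_points)
    }
  })
  rank_table <- stage("rank", rank_facilities(
    aggregates, model,
    method1_denominator = config$ranking$method1_denominator,
    residual_type = config$ranking$residual_type,
    method4_absolute = config$ranking$method4_absolute))
  selection <- stage("select", select_top(
    rank_table, method = config$ranking$select_method,
    n = config$ranking$top_n, strata = config$ranking$stratified))
  comparisons <- stage("compare", {
    pairs <- list(c("method1", "method2"), c("method2", "method3"),
                  c("method3", "method4"))
    lapply(pairs, function(p) {
      compare_methods(rank_table, p[1], p[2], top_n = config$ranking$top_n)
    })
  })

  files <- stage("report", {
    agg_path <- file.path(out_dir, "aggregates.csv")
    agg_out <- as.data.frame(aggregates)
    num <- vapply(agg_out, is.double, logical(1))
    agg_out[num] <- lapply(agg_out[num], formatC, format = "g", digits = 10)
    utils::write.csv(agg_out, agg_path, row.names = FALSE, quote = FALSE)
    model_path <- file.path(out_dir, "model.json")
    write_model_json(model, model_path, trace = elim$trace)
    ranks_path <- file.path(out_dir, "ranks.tsv")
    write_rank_report(rank_table, ranks_path, sort_by = config$ranking$sort_by)
    sel_path <- file.path(out_dir, "selection.tsv")
    utils::write.table(selection, sel_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cmp_path <- file.path(out_dir, "comparison.tsv")
    cmp <- do.call(rbind, lapply(comparisons, function(x) {
      data.frame(method_a = x$method_a, method_b = x$method_b,
                 top_n = x$top_n, overlap = x$overlap,
                 spearman = formatC(x$spearman, format = "g", digits = 10))
    }))
    utils::write.table(cmp, cmp_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    c(aggregates = agg_path, model = model_path, ranks = ranks_path,
      selection = sel_path, comparison = cmp_path)
  })
  pah_log("pipeline", out_dir = out_dir, facilities = nrow(aggregates),
          pah_total = sum(aggregates$pah_count))
  invisible(list(cohort = cohort, aggregates = aggregates, model = model,
                 elimination = elim, rank_table = rank_table,
                 selection = selection, comparisons = comparisons,
                 files = files))
}
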