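#' @keywords internal
"_PACKAGE"

# Stage-tagged key=value logging. Silenced via options(pahrank.verbose = FALSE).
pah_log <- function(stage, ...) {
  if (!isTRUE(getOption("pahrank.verbose", TRUE))) return(invisible(NULL))
  kv <- list(...)
  msg <- if (length(kv)) {
    paste(paste0(names(kv), "=", vapply(kv, function(x) paste(x, collapse = ","),
                                        character(1))), collapse = " ")
  } else ""
  message(sprintf("[%s] stage=%s %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, msg))
  invisible(NULL)
}

DAYS_PER_YEAR <- 365.25

# ISO-8601 date parsing with an informative error naming the offending values.
parse_iso_date <- function(x, what) {
  x <- as.character(x)
  blank <- is.na(x) | !nzchar(trimws(x))
  out <- rep(as.Date(NA), length(x))
  if (any(!blank)) {
    parsed <- as.Date(x[!blank], format = "%Y-%m-%d")
    if (anyNA(parsed)) {
      bad <- unique(x[!blank][is.na(parsed)])
      stop(sprintf("unparseable ISO-8601 date(s) in %s: %s", what,
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    }
    out[!blank] <- parsed
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed derivation so per-table RNG streams stay independent
# of each other when scenario dimensions change. Kept below 2^31.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 48271 + offset * 10007) %% 2147483647)
}
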