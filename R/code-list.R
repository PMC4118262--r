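#' Load a PAH condition code list
#'
#' A PAH (potentially avoidable hospitalisation) code list maps condition
#' labels to diagnosis-code prefixes. A hospital event is classified PAH when
#' any of its first `max_diagnosis_position` diagnosis codes starts with any
#' prefix; matching is case-insensitive and ignores dots, so prefix `J18`
#' covers `J18.0`-`J18.9`.
#'
#' @param path CSV file with columns `condition_label` and `code_prefix`
#'   (extra columns are ignored). Defaults to the code list bundled with the
#'   package, which maps each condition in the default PAH definition (COPD,
#'   bronchitis, pneumonia, congestive heart failure, dehydration, urinary
#'   tract infection, anaemia, cellulitis, leg ulcers, collapse or syncope,
#'   constipation, influenza, fall-related fractures and injuries) to ICD-10
#'   prefixes chosen by the package authors — a documented stand-in, not an
#'   official definition; studies should supply their own list.
#' @param max_diagnosis_position deepest diagnosis position considered
#'   (default 3: primary plus the next two).
#' @return An object of class `pah_code_list` with elements `entries`
#'   (data frame: `condition_label`, `code_prefix`, `prefix_norm`) and
#'   `max_diagnosis_position`.
#' @export
load_code_list <- function(path = default_code_list_path(),
                           max_diagnosis_position = 3L) {
  df <- read_table_checked(path, "code list", c("condition_label", "code_prefix"))
  if (nrow(df) == 0) {
    stop("code list is empty: a PAH definition must contain at least one entry",
         call. = FALSE)
  }
  df <- df[, c("condition_label", "code_prefix")]
  bad <- !grepl("^[A-Za-z0-9.]+$", df$code_prefix)
  if (any(bad)) {
    stop("invalid code_prefix (must be alphanumeric with optional dot): ",
         paste(unique(df$code_prefix[bad]), collapse = ", "), call. = FALSE)
  }
  df$prefix_norm <- normalize_code(df$code_prefix)
  dup <- duplicated(df$prefix_norm)
  if (any(dup)) {
    warning(sprintf("code list: %d duplicate prefix(es) collapsed (%s)",
                    sum(dup), paste(unique(df$code_prefix[dup]), collapse = ", ")),
            call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  stopifnot(max_diagnosis_position >= 1)
  structure(list(entries = df,
                 max_diagnosis_position = as.integer(max_diagnosis_position)),
            class = "pah_code_list")
}

#' Path of the bundled default PAH code list
#' @return File path of the CSV shipped in `inst/extdata`.
#' @export
default_code_list_path <- function() {
  system.file("extdata", "pah_codes.csv", package = "pahrank", mustWork = TRUE)
}

# Codes compared upper-case with dots stripped; stored verbatim for reporting.
normalize_code <- function(x) gsub(".", "", toupper(trimws(x)), fixed = TRUE)

#' @export
print.pah_code_list <- function(x, ...) {
  cat(sprintf("PAH code list: %d prefixes, %d conditions, first %d diagnoses considered\n",
              nrow(x$entries), length(unique(x$entries$condition_label)),
              x$max_diagnosis_position))
  invisible(x)
}
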