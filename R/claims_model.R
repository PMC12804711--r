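#' Prefix code matching with ICD wildcard semantics
#'
#' Tests whether each code begins with any prefix in the group, after
#' removing dot separators from both sides. `"C83.38"` matches prefix
#' `"C83.3"`; so does `"C8338"`; `"C83.40"` does not.
#'
#' @param code Character vector of codes.
#' @param prefix_set Character vector of prefixes (a code-prefix group).
#' @return Logical vector, one element per code.
#' @export
code_matches <- function(code, prefix_set) {
  if (!length(code)) return(logical(0))
  if (!length(prefix_set)) return(rep(FALSE, length(code)))
  norm <- function(x) toupper(gsub(".", "", x, fixed = TRUE))
  code_n <- norm(code)
  pref_n <- norm(prefix_set)
  out <- rep(FALSE, length(code_n))
  for (p in pref_n) out <- out | startsWith(code_n, p)
  out
}

empty_table <- function(spec) {
  out <- lapply(spec, function(cls) {
    switch(cls,
      character = character(0),
      Date = as.Date(character(0)),
      integer = integer(0),
      numeric = numeric(0)
    )
  })
  as.data.frame(out, stringsAsFactors = FALSE)
}

bundle_schema <- list(
  enrollment = list(patient_id = "character", start_date = "Date", end_date = "Date"),
  medical = list(patient_id = "character", service_date = "Date",
                 setting = "character", diagnosis_codes = "character",
                 procedure_codes = "character"),
  pharmacy = list(patient_id = "character", fill_date = "Date",
                  drug_code = "character", days_supply = "integer"),
  death = list(patient_id = "character", death_date = "Date"),
  patients = list(patient_id = "character", birth_year = "integer", sex = "character")
)

coerce_table <- function(df, spec, name) {
  missing_cols <- setdiff(names(spec), names(df))
  if (length(missing_cols)) {
    cl_stop(sprintf("table '%s' is missing column(s): %s",
                    name, paste(missing_cols, collapse = ", ")),
            "cl_load_error")
  }
  df <- df[, names(spec), drop = FALSE]
  for (col in names(spec)) {
    cls <- spec[[col]]
    v <- df[[col]]
    df[[col]] <- switch(cls,
      character = {
        v <- as.character(v)
        v[is.na(v)] <- ""
        v
      },
      Date = {
        d <- tryCatch(as_date(v), error = function(e) NULL)
        if (is.null(d) || anyNA(d)) {
          bad <- if (is.null(d)) 1L else which(is.na(d))[1]
          cl_stop(sprintf("table '%s', row %d, column '%s': unparseable date",
                          name, bad, col), "cl_load_error")
        }
        d
      },
      integer = {
        iv <- suppressWarnings(as.integer(v))
        if (anyNA(iv)) {
          cl_stop(sprintf("table '%s', row %d, column '%s': not an integer",
                          name, which(is.na(iv))[1], col), "cl_load_error")
        }
        iv
      },
      numeric = as.numeric(v)
    )
  }
  rownames(df) <- NULL
  df
}

#' Normalize enrollment spans
#'
#' Sorts spans within patient and merges overlapping or near-adjacent spans
#' (separated by at most `allowable_gap_days`) into single continuous-coverage
#' intervals. Idempotent and independent of input row order.
#'
#' @param enrollment Data frame with `patient_id`, `start_date`, `end_date`.
#' @param allowable_gap_days Maximum administrative gap still treated as
#'   continuous (default 1 day, i.e. abutting spans merge).
#' @return The merged enrollment table.
#' @export
normalize_enrollment <- function(enrollment, allowable_gap_days = 1L) {
  if (any(enrollment$start_date > enrollment$end_date)) {
    cl_stop("enrollment span with start_date after end_date", "cl_validation_error")
  }
  if (!nrow(enrollment)) return(enrollment)
  dt <- data.table::as.data.table(enrollment)
  data.table::setorder(dt, patient_id, start_date, end_date)
  merged <- dt[, {
    s <- as.integer(start_date); e <- as.integer(end_date)
    ks <- integer(0); ke <- integer(0)
    cs <- s[1]; ce <- e[1]
    if (length(s) > 1) {
      for (i in 2:length(s)) {
        if (s[i] <= ce + allowable_gap_days + 1L) {
          ce <- max(ce, e[i])
        } else {
          ks <- c(ks, cs); ke <- c(ke, ce)
          cs <- s[i]; ce <- e[i]
        }
      }
    }
    ks <- c(ks, cs); ke <- c(ke, ce)
    list(start_date = as.Date(ks, origin = "1970-01-01"),
         end_date = as.Date(ke, origin = "1970-01-01"))
  }, by = patient_id]
  out <- as.data.frame(merged)
  rownames(out) <- NULL
  out
}

#' Assemble and validate a claims bundle
#'
#' The canonical in-memory claims database slice: enrollment spans, medical
#' claims (diagnosis + procedure codes, inpatient/outpatient setting),
#' pharmacy claims, death records, and patient demographics. Dates are
#' `Date`s; multi-code fields are semicolon-packed strings with position 1 the
#' primary diagnosis. Enrollment is normalized on construction.
#'
#' @param enrollment,medical,pharmacy,death,patients The five tables (missing
#'   tables default to empty).
#' @param config A [study_config()]; supplies `allowable_gap_days`.
#' @return An object of class `cl_bundle`.
#' @export
claims_bundle <- function(enrollment = NULL, medical = NULL, pharmacy = NULL,
                          death = NULL, patients = NULL,
                          config = study_config()) {
  tabs <- list(enrollment = enrollment, medical = medical,
               pharmacy = pharmacy, death = death, patients = patients)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) tabs[[nm]] <- empty_table(bundle_schema[[nm]])
    tabs[[nm]] <- coerce_table(as.data.frame(tabs[[nm]]), bundle_schema[[nm]], nm)
  }
  if (any(tabs$pharmacy$days_supply < 0)) {
    bad <- which(tabs$pharmacy$days_supply < 0)[1]
    cl_stop(sprintf("table 'pharmacy', row %d, column 'days_supply': negative value", bad),
            "cl_load_error")
  }
  empty_claim <- tabs$medical$diagnosis_codes == "" & tabs$medical$procedure_codes == ""
  if (any(empty_claim)) {
    cl_stop(sprintf("table 'medical', row %d: claim carries neither diagnosis nor procedure codes",
                    which(empty_claim)[1]), "cl_load_error")
  }
  if (anyDuplicated(tabs$death$patient_id)) {
    cl_stop("table 'death': more than one death record for a patient",
            "cl_validation_error")
  }
  if (anyDuplicated(tabs$patients$patient_id)) {
    cl_stop("table 'patients': duplicated patient_id", "cl_validation_error")
  }
  tabs$enrollment <- normalize_enrollment(tabs$enrollment, config$allowable_gap_days)
  structure(tabs, class = "cl_bundle")
}

#' @export
print.cl_bundle <- function(x, ...) {
  cat("<claims bundle>\n")
  cat(sprintf("  patients:   %d\n", length(unique(c(
    x$enrollment$patient_id, x$medical$patient_id, x$pharmacy$patient_id)))))
  for (nm in names(x)) cat(sprintf("  %-10s %d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Load a claims bundle from delimited files
#'
#' Reads the five bundle tables from CSV (headered, ISO-8601 dates) and
#' validates them. File names are `<table>.csv` under `dir`, or explicit
#' paths via `paths`.
#'
#' @param dir Directory containing `enrollment.csv`, `medical.csv`,
#'   `pharmacy.csv`, `death.csv`, `patients.csv` (missing files allowed for
#'   `death`/`patients`).
#' @param paths Optional named list/character vector of explicit file paths
#'   overriding `dir`.
#' @param config A [study_config()].
#' @return A `cl_bundle`.
#' @export
load_bundle <- function(dir = NULL, paths = NULL, config = study_config()) {
  tabs <- list()
  for (nm in names(bundle_schema)) {
    p <- if (!is.null(paths) && !is.null(paths[[nm]])) paths[[nm]]
         else if (!is.null(dir)) file.path(dir, paste0(nm, ".csv"))
         else NULL
    if (is.null(p) || !file.exists(p)) {
      if (nm %in% c("death", "patients")) next
      cl_stop(sprintf("required table file not found: %s", p %||% nm), "cl_load_error")
    }
    tabs[[nm]] <- read.csv(p, colClasses = "character", check.names = FALSE)
  }
  claims_bundle(tabs$enrollment, tabs$medical, tabs$pharmacy,
                tabs$death, tabs$patients, config = config)
}

#' Write a claims bundle to CSV files
#'
#' Inverse of [load_bundle()]: writes each table as `<table>.csv` under `dir`
#' with ISO-8601 dates. Loading the written files reproduces the bundle
#' exactly.
#'
#' @param bundle A `cl_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle)) {
    df <- bundle[[nm]]
    for (col in names(df)) if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]])
    write.csv(df, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}
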