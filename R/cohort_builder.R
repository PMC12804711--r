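#' First observed DLBCL diagnosis per patient
#'
#' The earliest medical-claim service date carrying a DLBCL code (C83.3x by
#' default) in any diagnosis position. Patients without a matching code are
#' absent from the result.
#'
#' @param bundle A `cl_bundle`.
#' @param codes A [code_sets()].
#' @return A data.frame with `patient_id` and `diagnosis_date`.
#' @export
first_dlbcl_diagnosis <- function(bundle, codes) {
  md <- bundle$medical
  if (!nrow(md)) {
    return(data.frame(patient_id = character(0),
                      diagnosis_date = as.Date(character(0))))
  }
  dx <- split_codes(md$diagnosis_codes)
  has <- vapply(dx, function(v) any(code_matches(v, codes$dlbcl_icd10_prefix)),
                logical(1))
  md <- md[has, ]
  if (!nrow(md)) {
    return(data.frame(patient_id = character(0),
                      diagnosis_date = as.Date(character(0))))
  }
  agg <- aggregate(md$service_date, by = list(patient_id = md$patient_id), FUN = min)
  data.frame(patient_id = agg$patient_id, diagnosis_date = agg$x,
             stringsAsFactors = FALSE)
}

#' Confirm a DLBCL diagnosis at an index date
#'
#' Confirmation requires, on or before the index date, either (1) one
#' inpatient claim with a DLBCL code in the primary (first) diagnosis
#' position, or (2) two outpatient claims with a DLBCL code in any position
#' whose service dates are at least 30 days apart.
#'
#' @param bundle A `cl_bundle`.
#' @param patient_id Patient identifier.
#' @param index_date Index date of the line under evaluation.
#' @param codes A [code_sets()].
#' @param min_outpatient_gap_days Required spacing of the two outpatient
#'   encounters (default 30).
#' @return `TRUE` or `FALSE`.
#' @export
confirm_dlbcl <- function(bundle, patient_id, index_date, codes,
                          min_outpatient_gap_days = 30L) {
  md <- bundle$medical
  md <- md[md$patient_id == patient_id & md$service_date <= as_date(index_date), ]
  if (!nrow(md)) return(FALSE)
  dx <- split_codes(md$diagnosis_codes)
  primary <- vapply(dx, function(v) length(v) > 0 &&
                      code_matches(v[1], codes$dlbcl_icd10_prefix), logical(1))
  anypos <- vapply(dx, function(v) any(code_matches(v, codes$dlbcl_icd10_prefix)),
                   logical(1))
  if (any(primary & md$setting == "inpatient")) return(TRUE)
  out_dates <- md$service_date[anypos & md$setting == "outpatient"]
  if (length(out_dates) >= 2 &&
      as.integer(max(out_dates) - min(out_dates)) >= min_outpatient_gap_days) {
    return(TRUE)
  }
  FALSE
}

# Enrollment span (post-merge) covering a date, or NULL.
covering_span <- function(bundle, patient_id, date) {
  en <- bundle$enrollment
  en <- en[en$patient_id == patient_id &
             en$start_date <= date & en$end_date >= date, ]
  if (!nrow(en)) return(NULL)
  en[1, ]
}

#' Evaluate study eligibility for one line of therapy
#'
#' Applies every inclusion/exclusion rule at the line's index date, without
#' short-circuiting, so the returned reason list is complete (attrition
#' tables need every failed check). Rules: confirmed DLBCL diagnosis;
#' continuous enrollment >= 365 days before through >= 29 days after the
#' index date; age >= 18 at index (by birth year); no clinical-trial code in
#' the 183 days before or on the index date; no other-malignancy code in the
#' 365 days strictly before the index date; index date inside the study
#' window. Under `subgroup_mode = "lot_number"` (the 1L/2L/3L and named
#' LOT-number treatment subgroups) two further checks apply: continuous
#' enrollment from >= 183 days before the first observed diagnosis through
#' the index date (washout), and no legacy ICD-9 200.7x code at any time
#' before the diagnosis date. Under `subgroup_mode = "treatment_only"` (CAR T
#' and post-CAR T subgroups) those two checks are skipped.
#'
#' @param bundle A `cl_bundle`.
#' @param lot One row of a line table (list or single-row data.frame with
#'   `patient_id`, `lot_number`, `index_date`).
#' @param config A [study_config()].
#' @param codes A [code_sets()].
#' @param subgroup_mode `"lot_number"` or `"treatment_only"`.
#' @param diagnosis_date First observed DLBCL diagnosis for the patient
#'   (computed from the bundle when `NULL`).
#' @return A one-row data.frame: `patient_id`, `lot_number`, `eligible`,
#'   `reasons` (semicolon-joined reason codes, empty when eligible),
#'   `index_date`, `follow_up_end`, `follow_up_end_cause`.
#' @export
evaluate_lot_eligibility <- function(bundle, lot, config = study_config(),
                                     codes = code_sets(),
                                     subgroup_mode = c("lot_number", "treatment_only"),
                                     diagnosis_date = NULL) {
  subgroup_mode <- match.arg(subgroup_mode)
  if (is.null(lot$index_date) || is.na(lot$index_date)) {
    cl_stop("line has no index date", "cl_contract_error")
  }
  pid <- lot$patient_id
  idx <- as_date(lot$index_date)
  if (is.null(diagnosis_date)) {
    dg <- first_dlbcl_diagnosis(bundle, codes)
    diagnosis_date <- dg$diagnosis_date[dg$patient_id == pid][1]
  }
  reasons <- character(0)

  if (!confirm_dlbcl(bundle, pid, idx, codes)) {
    reasons <- c(reasons, "diagnosis_confirmation")
  }

  span <- covering_span(bundle, pid, idx)
  if (is.null(span) ||
      as.integer(idx - span$start_date) < config$pre_index_enrollment_days) {
    reasons <- c(reasons, "pre_index_enrollment")
  }
  if (is.null(span) ||
      as.integer(span$end_date - idx) < config$post_index_enrollment_days) {
    reasons <- c(reasons, "post_index_enrollment")
  }

  pt <- bundle$patients[bundle$patients$patient_id == pid, ]
  age <- if (nrow(pt)) as.integer(format(idx, "%Y")) - pt$birth_year[1] else NA_integer_
  if (is.na(age) || age < config$min_age_years) {
    reasons <- c(reasons, "age")
  }

  md <- bundle$medical[bundle$medical$patient_id == pid, ]
  all_codes_by_claim <- function(df) {
    Map(c, split_codes(df$diagnosis_codes), split_codes(df$procedure_codes))
  }
  in_window <- function(df, from, to) df[df$service_date >= from & df$service_date <= to, ]

  trial_md <- in_window(md, idx - config$trial_lookback_days, idx)
  if (nrow(trial_md) &&
      any(vapply(all_codes_by_claim(trial_md),
                 function(v) any(code_matches(v, codes$clinical_trial_codes)),
                 logical(1)))) {
    reasons <- c(reasons, "clinical_trial")
  }

  malig_md <- in_window(md, idx - config$malignancy_lookback_days, idx - 1L)
  if (nrow(malig_md) &&
      any(vapply(split_codes(malig_md$diagnosis_codes),
                 function(v) any(code_matches(v, codes$other_malignancy_codes)),
                 logical(1)))) {
    reasons <- c(reasons, "other_malignancy")
  }

  if (subgroup_mode == "lot_number") {
    if (is.na(diagnosis_date) || is.null(span) ||
        as.integer(diagnosis_date - span$start_date) < config$washout_days ||
        span$start_date > diagnosis_date) {
      reasons <- c(reasons, "washout")
    }
    if (!is.na(diagnosis_date) && nrow(md)) {
      pre_dx <- md[md$service_date < diagnosis_date, ]
      if (nrow(pre_dx) &&
          any(vapply(split_codes(pre_dx$diagnosis_codes),
                     function(v) any(code_matches(v, codes$legacy_icd9_prefix)),
                     logical(1)))) {
        reasons <- c(reasons, "legacy_icd9")
      }
    }
  }

  if (idx < config$study_start || idx > config$study_end) {
    reasons <- c(reasons, "outside_study_window")
  }

  death <- bundle$death$death_date[bundle$death$patient_id == pid]
  cand <- c(
    death = if (length(death)) as.integer(death[1]) else NA_integer_,
    disenrollment = if (!is.null(span)) as.integer(span$end_date) else NA_integer_,
    study_end = as.integer(config$study_end)
  )
  cause <- names(cand)[which.min(cand)]
  fu_end <- as.Date(min(cand, na.rm = TRUE), origin = "1970-01-01")

  data.frame(
    patient_id = pid,
    lot_number = as.integer(lot$lot_number),
    eligible = !length(reasons),
    reasons = paste(reasons, collapse = ";"),
    index_date = idx,
    follow_up_end = fu_end,
    follow_up_end_cause = cause,
    stringsAsFactors = FALSE
  )
}

#' Evaluate eligibility for every derived line in a cohort
#'
#' @param bundle A `cl_bundle`.
#' @param lots Line table from [derive_all_lots()].
#' @param config,codes,subgroup_mode Passed to [evaluate_lot_eligibility()].
#' @return A data.frame with one eligibility row per (patient, line).
#' @export
build_cohort <- function(bundle, lots, config = study_config(),
                         codes = code_sets(),
                         subgroup_mode = "lot_number") {
  dg <- first_dlbcl_diagnosis(bundle, codes)
  dg_map <- setNames(as.integer(dg$diagnosis_date), dg$patient_id)
  # Pre-split each table by patient so evaluation is linear in cohort size.
  sl <- lapply(bundle[names(bundle_schema)], function(df) {
    split(df, factor(df$patient_id, levels = unique(lots$patient_id)))
  })
  mini_for <- function(pid) {
    b <- lapply(names(bundle_schema), function(nm) {
      x <- sl[[nm]][[pid]]
      if (is.null(x)) empty_table(bundle_schema[[nm]]) else x
    })
    names(b) <- names(bundle_schema)
    structure(b, class = "cl_bundle")
  }
  out <- vector("list", nrow(lots))
  minis <- list()
  for (i in seq_len(nrow(lots))) {
    pid <- lots$patient_id[i]
    if (is.null(minis[[pid]])) minis[[pid]] <- mini_for(pid)
    dd <- dg_map[pid]
    dd <- if (!is.na(dd)) as.Date(dd, origin = "1970-01-01") else as.Date(NA)
    out[[i]] <- evaluate_lot_eligibility(
      minis[[pid]], lots[i, ], config, codes,
      subgroup_mode = subgroup_mode, diagnosis_date = dd
    )
  }
  if (!length(out)) {
    return(data.frame(patient_id = character(0), lot_number = integer(0),
                      eligible = logical(0), reasons = character(0),
                      index_date = as.Date(character(0)),
                      follow_up_end = as.Date(character(0)),
                      follow_up_end_cause = character(0)))
  }
  as.data.frame(data.table::rbindlist(out))
}

#' Attrition summary
#'
#' Counts, per exclusion reason, how many lines failed that check (a line can
#' contribute to several reasons because checks are not short-circuited).
#'
#' @param eligibility Result of [build_cohort()].
#' @return A data.frame with `reason` and `n`.
#' @export
attrition_summary <- function(eligibility) {
  rs <- unlist(strsplit(eligibility$reasons[eligibility$reasons != ""], ";",
                        fixed = TRUE))
  if (!length(rs)) return(data.frame(reason = character(0), n = integer(0)))
  tab <- sort(table(rs), decreasing = TRUE)
  data.frame(reason = names(tab), n = as.integer(tab), stringsAsFactors = FALSE)
}
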