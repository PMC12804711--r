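#' Boundary fixture cohort for eligibility and LOT rules
#'
#' Builds one synthetic patient per boundary condition of the study rules,
#' each labeled with its expected outcome: 364 vs 365 days of pre-index
#' enrollment; 28 vs 29 days of post-index enrollment; outpatient
#' confirmation encounters 29 vs 30 days apart; a clinical-trial code at
#' exactly 183 vs 184 days before index; an other-malignancy code at exactly
#' 365 vs 366 days before index; age 17 vs 18 at index; enrollment starting
#' 182 vs 183 days before diagnosis (washout); a legacy ICD-9 200.7x code
#' before diagnosis; plus the LOT-engine boundaries (combination partner on
#' day 30 vs 31, regimen restart after a 90- vs 91-day gap).
#'
#' @param config A [study_config()].
#' @param codes A [code_sets()].
#' @param dict A drug dictionary.
#' @return A list with `bundle` and `truth`; `truth$eligibility` has one row
#'   per patient (`eligible`, `reason` under LOT-number subgroup rules) and
#'   `truth$lots` the expected line structure (`n_lots`, per-line core drug
#'   sets).
#' @export
make_eligibility_edge_cases <- function(config = study_config(),
                                        codes = code_sets(),
                                        dict = default_drug_dictionary()) {
  diag <- as.Date("2018-03-01")
  rit <- codes_for_drug(dict, "rituximab")
  ben <- codes_for_drug(dict, "bendamustine")
  gem <- codes_for_drug(dict, "gemcitabine")
  dlbcl_code <- paste0(codes$dlbcl_icd10_prefix, "0")

  enr <- list(); med <- list(); pha <- list(); pat <- list()
  elig <- list(); lots <- list()

  add <- function(id, index_offset = 14L, enroll_start = diag - 400L,
                  enroll_end_offset = 200L, birth_year = 1948L,
                  confirm = "inpatient", outpt_gap = 30L,
                  extra_med = NULL, drug_schedule = NULL,
                  eligible = TRUE, reason = "",
                  expected_cores = NULL) {
    idx <- diag + index_offset
    enr[[id]] <<- data.frame(patient_id = id, start_date = enroll_start,
                             end_date = idx + enroll_end_offset)
    pat[[id]] <<- data.frame(patient_id = id, birth_year = birth_year,
                             sex = "F")
    med[[id]] <<- if (confirm == "inpatient") {
      data.frame(patient_id = id, service_date = diag, setting = "inpatient",
                 diagnosis_codes = dlbcl_code, procedure_codes = "")
    } else {
      data.frame(patient_id = id, service_date = c(diag, diag + outpt_gap),
                 setting = "outpatient", diagnosis_codes = dlbcl_code,
                 procedure_codes = "")
    }
    if (!is.null(extra_med)) {
      extra_med$patient_id <- id
      med[[paste0(id, "_x")]] <<- extra_med
    }
    if (is.null(drug_schedule)) {
      drug_schedule <- data.frame(code = rit, offset = index_offset)
    }
    pha[[id]] <<- data.frame(patient_id = id,
                             fill_date = diag + drug_schedule$offset,
                             drug_code = drug_schedule$code,
                             days_supply = 0L)
    elig[[id]] <<- data.frame(patient_id = id, lot_number = 1L,
                              eligible = eligible, reason = reason,
                              stringsAsFactors = FALSE)
    if (is.null(expected_cores)) {
      nm <- dict$drug_name[match(drug_schedule$code[1], dict$drug_code)]
      expected_cores <- nm
    }
    lots[[id]] <<- data.frame(patient_id = id,
                              lot_number = seq_along(expected_cores),
                              core_drugs = expected_cores,
                              stringsAsFactors = FALSE)
  }

  idx14 <- 14L # default index offset from diagnosis

  add("edge_pre_364", enroll_start = diag + idx14 - 364L,
      eligible = FALSE, reason = "pre_index_enrollment")
  add("edge_pre_365", enroll_start = diag + idx14 - 365L)
  add("edge_post_28", enroll_end_offset = 28L,
      eligible = FALSE, reason = "post_index_enrollment")
  add("edge_post_29", enroll_end_offset = 29L)
  add("edge_outpt_29", index_offset = 35L, confirm = "outpatient",
      outpt_gap = 29L, eligible = FALSE, reason = "diagnosis_confirmation")
  add("edge_outpt_30", index_offset = 35L, confirm = "outpatient",
      outpt_gap = 30L)
  add("edge_trial_183",
      extra_med = data.frame(patient_id = NA,
                             service_date = diag + idx14 - config$trial_lookback_days,
                             setting = "outpatient", diagnosis_codes = "",
                             procedure_codes = codes$clinical_trial_codes[1]),
      eligible = FALSE, reason = "clinical_trial")
  add("edge_trial_184",
      extra_med = data.frame(patient_id = NA,
                             service_date = diag + idx14 - config$trial_lookback_days - 1L,
                             setting = "outpatient", diagnosis_codes = "",
                             procedure_codes = codes$clinical_trial_codes[1]))
  add("edge_malig_365",
      extra_med = data.frame(patient_id = NA,
                             service_date = diag + idx14 - config$malignancy_lookback_days,
                             setting = "outpatient",
                             diagnosis_codes = paste0(codes$other_malignancy_codes[1], "0"),
                             procedure_codes = ""),
      eligible = FALSE, reason = "other_malignancy")
  add("edge_malig_366",
      extra_med = data.frame(patient_id = NA,
                             service_date = diag + idx14 - config$malignancy_lookback_days - 1L,
                             setting = "outpatient",
                             diagnosis_codes = paste0(codes$other_malignancy_codes[1], "0"),
                             procedure_codes = ""))
  add("edge_age_17", birth_year = 2001L, eligible = FALSE, reason = "age")
  add("edge_age_18", birth_year = 2000L)
  add("edge_washout_182", index_offset = 200L, enroll_start = diag - 182L,
      eligible = FALSE, reason = "washout")
  add("edge_washout_183", index_offset = 200L, enroll_start = diag - 183L)
  add("edge_icd9_prior",
      extra_med = data.frame(patient_id = NA, service_date = diag - 30L,
                             setting = "outpatient",
                             diagnosis_codes = paste0(codes$legacy_icd9_prefix, "1"),
                             procedure_codes = ""),
      eligible = FALSE, reason = "legacy_icd9")
  add("edge_baseline")

  add("edge_combo_30",
      drug_schedule = data.frame(code = c(ben, gem), offset = idx14 + c(0L, 30L)),
      expected_cores = "bendamustine;gemcitabine")
  add("edge_combo_31",
      drug_schedule = data.frame(code = c(ben, gem), offset = idx14 + c(0L, 31L)),
      expected_cores = c("bendamustine", "gemcitabine"))
  add("edge_restart_90",
      drug_schedule = data.frame(code = c(ben, ben), offset = idx14 + c(0L, 90L)),
      expected_cores = "bendamustine")
  add("edge_restart_91",
      drug_schedule = data.frame(code = c(ben, ben), offset = idx14 + c(0L, 91L)),
      expected_cores = c("bendamustine", "bendamustine"))

  bind <- function(x) as.data.frame(data.table::rbindlist(x))
  bundle <- claims_bundle(enrollment = bind(enr), medical = bind(med),
                          pharmacy = bind(pha), patients = bind(pat),
                          config = config)
  truth <- list(eligibility = bind(elig), lots = bind(lots))
  list(bundle = bundle, truth = truth)
}
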