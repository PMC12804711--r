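#' Study configuration
#'
#' All numeric thresholds used by the line-of-therapy (LOT) algorithm, the
#' eligibility rules, and the outcome definitions, with defaults matching the
#' published study design for diffuse large B-cell lymphoma (DLBCL) claims
#' analyses: a 30-day combination window, advancement on a new therapy more
#' than 30 days after line start, a more-than-90-day discontinuation/restart
#' gap, 365 days of pre-index and 29 days of post-index continuous enrollment,
#' a 6-month (183-day) clinical-trial lookback and washout, a 12-month
#' (365-day) other-malignancy lookback, and small-cell masking below 5.
#'
#' @param study_start,study_end Calendar bounds of the study period.
#' @param combination_window_days Days after line start during which newly
#'   initiated drugs join the line as combination partners (inclusive).
#' @param advancement_threshold_days A new DLBCL-directed drug first observed
#'   strictly more than this many days after line start advances the LOT.
#' @param restart_gap_days Re-initiation of a current-line drug after all the
#'   line's exposures have lapsed for strictly more than this many days starts
#'   a new line.
#' @param pre_index_enrollment_days,post_index_enrollment_days Continuous
#'   enrollment required before (>= 365 days) and after (>= 29 days) the index
#'   date.
#' @param washout_days Continuous enrollment required before the first observed
#'   DLBCL diagnosis (LOT-number subgroups only).
#' @param trial_lookback_days Clinical-trial code exclusion window before or on
#'   the index date.
#' @param malignancy_lookback_days Other-malignancy exclusion window, strictly
#'   before the index date.
#' @param min_age_years Minimum age at the index date.
#' @param allowable_gap_days Administrative gap between enrollment spans that
#'   is still treated as continuous coverage (spans separated by at most this
#'   many days are merged).
#' @param bridging_end_offset_days Bridging window ends this many days before
#'   the CAR T infusion.
#' @param bridging_fallback_window_days Width of the pre-infusion bridging
#'   window used when no apheresis claim exists.
#' @param salvage_window_days Drugs that would otherwise advance the line but
#'   start within this many days before a stem cell transplant are salvage and
#'   attributed to the transplant line.
#' @param maintenance_drug_names Drugs eligible for maintenance attribution.
#' @param mask_threshold Patient counts in `[1, mask_threshold)` are masked in
#'   every rendered artifact.
#' @param most_common_fraction Minimum frequency (fraction of the denominator)
#'   for a regimen/class to be reported as "most common".
#' @param failure_horizons_months Horizons for treatment failure rates.
#' @param month_length_days Days per month used for all day-to-month
#'   conversions (30.4375 = 365.25 / 12).
#' @return An object of class `cl_config` (a validated list).
#' @export
study_config <- function(study_start = as.Date("2015-10-01"),
                         study_end = as.Date("2024-06-30"),
                         combination_window_days = 30L,
                         advancement_threshold_days = 30L,
                         restart_gap_days = 90L,
                         pre_index_enrollment_days = 365L,
                         post_index_enrollment_days = 29L,
                         washout_days = 183L,
                         trial_lookback_days = 183L,
                         malignancy_lookback_days = 365L,
                         min_age_years = 18L,
                         allowable_gap_days = 1L,
                         bridging_end_offset_days = 7L,
                         bridging_fallback_window_days = 60L,
                         salvage_window_days = 90L,
                         maintenance_drug_names = c("rituximab", "lenalidomide"),
                         mask_threshold = 5L,
                         most_common_fraction = 0.05,
                         failure_horizons_months = c(12, 24),
                         month_length_days = 30.4375) {
  cfg <- list(
    study_start = as_date(study_start),
    study_end = as_date(study_end),
    combination_window_days = as.integer(combination_window_days),
    advancement_threshold_days = as.integer(advancement_threshold_days),
    restart_gap_days = as.integer(restart_gap_days),
    pre_index_enrollment_days = as.integer(pre_index_enrollment_days),
    post_index_enrollment_days = as.integer(post_index_enrollment_days),
    washout_days = as.integer(washout_days),
    trial_lookback_days = as.integer(trial_lookback_days),
    malignancy_lookback_days = as.integer(malignancy_lookback_days),
    min_age_years = as.integer(min_age_years),
    allowable_gap_days = as.integer(allowable_gap_days),
    bridging_end_offset_days = as.integer(bridging_end_offset_days),
    bridging_fallback_window_days = as.integer(bridging_fallback_window_days),
    salvage_window_days = as.integer(salvage_window_days),
    maintenance_drug_names = as.character(maintenance_drug_names),
    mask_threshold = as.integer(mask_threshold),
    most_common_fraction = as.numeric(most_common_fraction),
    failure_horizons_months = as.numeric(failure_horizons_months),
    month_length_days = as.numeric(month_length_days)
  )
  windows <- c(
    "combination_window_days", "advancement_threshold_days", "restart_gap_days",
    "pre_index_enrollment_days", "post_index_enrollment_days", "washout_days",
    "trial_lookback_days", "malignancy_lookback_days",
    "bridging_end_offset_days", "bridging_fallback_window_days",
    "salvage_window_days", "month_length_days"
  )
  for (w in windows) {
    if (cfg[[w]] <= 0) cl_stop(sprintf("config field '%s' must be positive", w), "cl_config_error")
  }
  if (cfg$study_start >= cfg$study_end) {
    cl_stop("study_start must precede study_end", "cl_config_error")
  }
  structure(cfg, class = "cl_config")
}

#' Diagnosis/procedure code sets
#'
#' Code-prefix groups that drive cohort identification and modality detection.
#' Matching is prefix-based after dot-stripping, so `"C83.3"` matches
#' `"C83.35"` and `"C8335"` alike (the ICD "x" wildcard convention).
#'
#' @param dlbcl_icd10_prefix ICD-10-CM prefix identifying DLBCL (C83.3x).
#' @param legacy_icd9_prefix ICD-9-CM legacy DLBCL prefix (200.7x), used to
#'   exclude potentially prevalent pre-ICD-10 cases.
#' @param sct_procedure_codes,cart_procedure_codes,apheresis_codes Procedure
#'   code groups for stem cell transplant, CAR T infusion, and apheresis.
#' @param clinical_trial_codes Codes flagging clinical-trial participation.
#' @param other_malignancy_codes Diagnosis prefixes for other NHL / non-NHL
#'   hematologic malignancies.
#' @param comorbidity_code_map Named list of diagnosis-code prefix groups used
#'   for descriptive comorbidity flags.
#' @return An object of class `cl_code_sets`.
#' @export
code_sets <- function(dlbcl_icd10_prefix = "C83.3",
                      legacy_icd9_prefix = "200.7",
                      sct_procedure_codes = c("SCT01", "SCT02"),
                      cart_procedure_codes = c("CART1", "CART2"),
                      apheresis_codes = c("APH01"),
                      clinical_trial_codes = c("TRIAL1"),
                      other_malignancy_codes = c("C82", "C85.1", "C91"),
                      comorbidity_code_map = list(
                        hypertension = c("I10"),
                        anemia = c("D64"),
                        infection = c("A41", "J18")
                      )) {
  cs <- list(
    dlbcl_icd10_prefix = as.character(dlbcl_icd10_prefix),
    legacy_icd9_prefix = as.character(legacy_icd9_prefix),
    sct_procedure_codes = as.character(sct_procedure_codes),
    cart_procedure_codes = as.character(cart_procedure_codes),
    apheresis_codes = as.character(apheresis_codes),
    clinical_trial_codes = as.character(clinical_trial_codes),
    other_malignancy_codes = as.character(other_malignancy_codes),
    comorbidity_code_map = lapply(comorbidity_code_map, as.character)
  )
  if (!nzchar(cs$dlbcl_icd10_prefix) || !nzchar(cs$legacy_icd9_prefix)) {
    cl_stop("diagnosis prefixes must be non-empty", "cl_config_error")
  }
  modality <- c(cs$sct_procedure_codes, cs$cart_procedure_codes, cs$apheresis_codes)
  if (anyDuplicated(modality)) {
    cl_stop("SCT, CAR T and apheresis procedure code groups must be disjoint",
            "cl_config_error")
  }
  structure(cs, class = "cl_code_sets")
}

#' Drug dictionary
#'
#' Maps claim drug codes to canonical drug names and reporting classes.
#' Multiple codes (e.g. biosimilars) may map to one canonical name; every
#' name has exactly one class. Corticosteroids are never considered during
#' LOT derivation or regimen classification; drugs with
#' `dlbcl_directed = FALSE` are ignored by the LOT engine entirely.
#'
#' @param codes,names,classes,directed Parallel vectors defining the mapping.
#'   `classes` must be one of `chemotherapy`, `monoclonal_antibody`,
#'   `antibody_drug_conjugate`, `bispecific_antibody`, `targeted_other`,
#'   `corticosteroid`, `cart_product`.
#' @return A `data.frame` of class `cl_drug_dictionary` with columns
#'   `drug_code`, `drug_name`, `drug_class`, `dlbcl_directed`.
#' @export
drug_dictionary <- function(codes, names, classes, directed = TRUE) {
  valid_classes <- c("chemotherapy", "monoclonal_antibody",
                     "antibody_drug_conjugate", "bispecific_antibody",
                     "targeted_other", "corticosteroid", "cart_product")
  d <- data.frame(
    drug_code = as.character(codes),
    drug_name = as.character(names),
    drug_class = as.character(classes),
    dlbcl_directed = rep_len(as.logical(directed), length(codes)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(d$drug_code)) {
    cl_stop("every drug_code must map to exactly one drug_name", "cl_config_error")
  }
  bad <- !d$drug_class %in% valid_classes
  if (any(bad)) {
    cl_stop(sprintf("unknown drug_class: %s",
                    paste(unique(d$drug_class[bad]), collapse = ", ")),
            "cl_config_error")
  }
  by_name <- unique(d[, c("drug_name", "drug_class")])
  if (anyDuplicated(by_name$drug_name)) {
    cl_stop("a drug_name is mapped to more than one drug_class", "cl_config_error")
  }
  class(d) <- c("cl_drug_dictionary", "data.frame")
  d
}

#' Default drug dictionary for DLBCL-directed agents
#'
#' Synthetic claim codes for the agents that appear in contemporary DLBCL
#' regimens (R-CHOP components, pola + R-CHP, bendamustine combinations,
#' platinum salvage chemotherapy, tafasitamab, bispecific antibodies,
#' CAR T products, targeted oral agents, corticosteroids) plus one
#' non-oncology drug used to exercise the `dlbcl_directed = FALSE` path.
#'
#' @return A `cl_drug_dictionary`.
#' @export
default_drug_dictionary <- function() {
  rows <- list(
    c("RX-RIT", "rituximab", "monoclonal_antibody", TRUE),
    c("RX-RITB", "rituximab", "monoclonal_antibody", TRUE), # biosimilar code
    c("RX-CYC", "cyclophosphamide", "chemotherapy", TRUE),
    c("RX-DOX", "doxorubicin", "chemotherapy", TRUE),
    c("RX-VIN", "vincristine", "chemotherapy", TRUE),
    c("RX-PRE", "prednisone", "corticosteroid", TRUE),
    c("RX-DEX", "dexamethasone", "corticosteroid", TRUE),
    c("RX-BEN", "bendamustine", "chemotherapy", TRUE),
    c("RX-GEM", "gemcitabine", "chemotherapy", TRUE),
    c("RX-OXA", "oxaliplatin", "chemotherapy", TRUE),
    c("RX-CIS", "cisplatin", "chemotherapy", TRUE),
    c("RX-CAR", "carboplatin", "chemotherapy", TRUE),
    c("RX-CYT", "cytarabine", "chemotherapy", TRUE),
    c("RX-ETO", "etoposide", "chemotherapy", TRUE),
    c("RX-MTX", "methotrexate", "chemotherapy", TRUE),
    c("RX-POL", "polatuzumab vedotin", "antibody_drug_conjugate", TRUE),
    c("RX-LON", "loncastuximab tesirine", "antibody_drug_conjugate", TRUE),
    c("RX-TAF", "tafasitamab", "monoclonal_antibody", TRUE),
    c("RX-EPC", "epcoritamab", "bispecific_antibody", TRUE),
    c("RX-GLO", "glofitamab", "bispecific_antibody", TRUE),
    c("RX-LEN", "lenalidomide", "targeted_other", TRUE),
    c("RX-IBR", "ibrutinib", "targeted_other", TRUE),
    c("RX-VEN", "venetoclax", "targeted_other", TRUE),
    c("RX-SEL", "selinexor", "targeted_other", TRUE),
    c("RX-AXI", "axicabtagene ciloleucel", "cart_product", TRUE),
    c("RX-LIS", "lisocabtagene maraleucel", "cart_product", TRUE),
    c("RX-TIS", "tisagenlecleucel", "cart_product", TRUE),
    c("RX-STA", "atorvastatin", "targeted_other", FALSE)
  )
  m <- do.call(rbind, rows)
  drug_dictionary(m[, 1], m[, 2], m[, 3], as.logical(m[, 4]))
}

dict_lookup <- function(dict, codes) {
  i <- match(codes, dict$drug_code)
  data.frame(
    drug_code = codes,
    drug_name = dict$drug_name[i],
    drug_class = dict$drug_class[i],
    dlbcl_directed = dict$dlbcl_directed[i],
    known = !is.na(i),
    stringsAsFactors = FALSE
  )
}

codes_for_drug <- function(dict, name) {
  out <- dict$drug_code[dict$drug_name == name]
  if (!length(out)) {
    cl_stop(sprintf("drug name '%s' not present in dictionary", name),
            "cl_config_error")
  }
  out[1]
}

#' Write / read a configuration document
#'
#' Serializes a [study_config()], [code_sets()] and drug dictionary to one
#' YAML document and back, so a study's thresholds travel with its outputs.
#'
#' @param config A `cl_config`.
#' @param codes A `cl_code_sets`.
#' @param dict A `cl_drug_dictionary`.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   `list(config, code_sets, dictionary)`.
#' @export
write_config <- function(config, codes, dict, path) {
  doc <- list(
    study = lapply(unclass(config), function(x) {
      if (inherits(x, "Date")) format(x) else x
    }),
    code_sets = unclass(codes),
    drug_dictionary = as.list(as.data.frame(dict))
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  st <- doc$study
  st$study_start <- as.Date(st$study_start)
  st$study_end <- as.Date(st$study_end)
  cfg <- do.call(study_config, st)
  cs <- do.call(code_sets, doc$code_sets)
  dd <- doc$drug_dictionary
  dict <- drug_dictionary(dd$drug_code, dd$drug_name, dd$drug_class, dd$dlbcl_directed)
  list(config = cfg, code_sets = cs, dictionary = dict)
}
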