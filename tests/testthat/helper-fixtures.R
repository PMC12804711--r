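# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk.

DAY0 <- as.Date("2019-01-01")

# Event-stream builder for derive_lots(): each argument is a day offset from
# DAY0. drugs: named list name -> vector of offsets (refills allowed);
# supply: days supply applied to every fill of that drug.
mk_events <- function(drugs = list(), sct = integer(0), cart = integer(0),
                      apheresis = integer(0), supply = 0L,
                      dict = default_drug_dictionary()) {
  rows <- list()
  for (j in seq_along(drugs)) { # positional: duplicate names allowed
    nm <- names(drugs)[j]
    cls <- dict$drug_class[match(nm, dict$drug_name)]
    rows[[length(rows) + 1]] <- data.frame(
      patient_id = "T1", event_date = DAY0 + drugs[[j]],
      kind = "drug_fill", drug_name = nm,
      drug_class = ifelse(is.na(cls), "unknown", cls),
      dlbcl_directed = !is.na(cls) &&
        dict$dlbcl_directed[match(nm, dict$drug_name)],
      exposure_end = DAY0 + drugs[[j]] + supply,
      stringsAsFactors = FALSE)
  }
  mod <- function(off, kind) {
    if (!length(off)) return(NULL)
    data.frame(patient_id = "T1", event_date = DAY0 + off, kind = kind,
               drug_name = NA_character_, drug_class = NA_character_,
               dlbcl_directed = FALSE, exposure_end = DAY0 + off,
               stringsAsFactors = FALSE)
  }
  rows$sct <- mod(sct, "sct")
  rows$cart <- mod(cart, "cart_infusion")
  rows$aph <- mod(apheresis, "apheresis")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(therapy_events(claims_bundle(), code_sets(), dict))
  }
  as.data.frame(data.table::rbindlist(rows))
}

# Day offsets (from DAY0) of each line's start in a derived history.
lot_offsets <- function(history) as.integer(history$lots$start_date - DAY0)

# A minimal single-patient bundle for cohort tests.
mk_bundle <- function(enroll_start = DAY0 - 400, enroll_end = DAY0 + 400,
                      diagnosis_offset = 0, drug_offsets = 14,
                      drug = "rituximab", inpatient = TRUE,
                      birth_year = 1950L, death_offset = NULL,
                      extra_medical = NULL,
                      dict = default_drug_dictionary()) {
  diag <- DAY0 + diagnosis_offset
  med <- data.frame(patient_id = "T1", service_date = diag,
                    setting = if (inpatient) "inpatient" else "outpatient",
                    diagnosis_codes = "C83.30", procedure_codes = "")
  if (!is.null(extra_medical)) med <- rbind(med, extra_medical)
  pha <- data.frame(patient_id = "T1", fill_date = DAY0 + drug_offsets,
                    drug_code = dict$drug_code[match(drug, dict$drug_name)],
                    days_supply = 0L)
  death <- if (!is.null(death_offset)) {
    data.frame(patient_id = "T1", death_date = DAY0 + death_offset)
  } else NULL
  claims_bundle(
    enrollment = data.frame(patient_id = "T1", start_date = enroll_start,
                            end_date = enroll_end),
    medical = med, pharmacy = pha, death = death,
    patients = data.frame(patient_id = "T1", birth_year = birth_year,
                          sex = "F")
  )
}

# Canonical line signature used when comparing two LOT derivations.
lot_signature <- function(lots) {
  if (!nrow(lots)) return("")
  paste(sprintf("%d|%s|%s|%s|%s|%d%d",
                lots$lot_number, format(lots$start_date),
                format(lots$index_date), lots$core_drugs, lots$all_drugs,
                lots$contains_sct, lots$contains_cart),
        collapse = " ;; ")
}
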