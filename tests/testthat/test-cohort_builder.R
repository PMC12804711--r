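cs <- code_sets()
cfg <- study_config()

test_that("first DLBCL diagnosis is the earliest matching claim in any position", {
  med <- data.frame(
    patient_id = c("A", "A", "B", "C", "C"),
    service_date = as.Date(c("2018-05-01", "2018-03-01", "2019-01-01",
                             "2020-02-02", "2020-02-02")),
    setting = c("outpatient", "outpatient", "inpatient", "inpatient",
                "outpatient"),
    diagnosis_codes = c("C83.35", "I10;C83.35", "C85.1", "C83.30", "C83.30"),
    procedure_codes = ""
  )
  b <- claims_bundle(medical = med)
  dg <- first_dlbcl_diagnosis(b, cs)
  expect_equal(dg$diagnosis_date[dg$patient_id == "A"], as.Date("2018-03-01"))
  expect_false("B" %in% dg$patient_id) # C85.1 does not match C83.3x
  expect_equal(dg$diagnosis_date[dg$patient_id == "C"], as.Date("2020-02-02"))
})

test_that("diagnosis confirmation follows the inpatient-primary / outpatient-pair rule", {
  mk <- function(dates, settings, dx) {
    claims_bundle(medical = data.frame(patient_id = "A", service_date = dates,
                                       setting = settings,
                                       diagnosis_codes = dx,
                                       procedure_codes = ""))
  }
  idx <- as.Date("2019-06-01")
  # one inpatient primary, five days before index
  expect_true(confirm_dlbcl(mk(idx - 5, "inpatient", "C83.31"), "A", idx, cs))
  # primary position required for the inpatient path
  expect_false(confirm_dlbcl(mk(idx - 5, "inpatient", "I10;C83.30"), "A", idx, cs))
  # two outpatient encounters 30 vs 29 days apart
  expect_true(confirm_dlbcl(mk(idx - c(40, 10), c("outpatient", "outpatient"),
                               "C83.30"), "A", idx, cs))
  expect_false(confirm_dlbcl(mk(idx - c(39, 10), c("outpatient", "outpatient"),
                                "C83.30"), "A", idx, cs))
  # outpatient DLBCL may sit in any diagnosis position
  expect_true(confirm_dlbcl(mk(idx - c(40, 10), c("outpatient", "outpatient"),
                               "I10;C83.30"), "A", idx, cs))
  # claims after the index date do not count
  expect_false(confirm_dlbcl(mk(idx + c(1, 40), c("outpatient", "outpatient"),
                                "C83.30"), "A", idx, cs))
})

test_that("eligibility reasons are exhaustive and subgroup-mode aware", {
  ec <- make_eligibility_edge_cases()
  d <- derive_all_lots(ec$bundle, cs, default_drug_dictionary())
  lot1 <- d$lots[d$lots$lot_number == 1, ]
  el <- build_cohort(ec$bundle, lot1, cfg, cs, subgroup_mode = "lot_number")
  m <- merge(ec$truth$eligibility, el, by = "patient_id")
  expect_equal(m$eligible.y, m$eligible.x)
  for (i in seq_len(nrow(m))) {
    if (m$reason[i] != "") {
      expect_true(grepl(m$reason[i], m$reasons[i], fixed = TRUE),
                  info = m$patient_id[i])
    } else {
      expect_equal(m$reasons[i], "", info = m$patient_id[i])
    }
  }
  # the legacy ICD-9 and washout checks are skipped for treatment-only subgroups
  icd9_lot <- lot1[lot1$patient_id == "edge_icd9_prior", ]
  el_t <- build_cohort(ec$bundle, icd9_lot, cfg, cs,
                       subgroup_mode = "treatment_only")
  expect_true(el_t$eligible)
  # a clinical-trial code 150 days before index excludes in both modes
  b150 <- mk_bundle(extra_medical = data.frame(
    patient_id = "T1", service_date = DAY0 + 14 - 150, setting = "outpatient",
    diagnosis_codes = "", procedure_codes = cs$clinical_trial_codes[1]))
  d150 <- derive_all_lots(b150, cs, default_drug_dictionary())
  el150 <- build_cohort(b150, d150$lots, cfg, cs, subgroup_mode = "treatment_only")
  expect_false(el150$eligible)
  expect_match(el150$reasons, "clinical_trial")
})

test_that("follow-up ends at the earliest of death, disenrollment, study end", {
  # death inside enrollment
  b <- mk_bundle(death_offset = 100, enroll_end = DAY0 + 400)
  d <- derive_all_lots(b, cs, default_drug_dictionary())
  el <- build_cohort(b, d$lots, cfg, cs)
  expect_equal(el$follow_up_end_cause, "death")
  expect_equal(el$follow_up_end, DAY0 + 100)
  expect_equal(b$death$death_date[b$death$patient_id == el$patient_id],
               el$follow_up_end)
  # no death: disenrollment before study end
  b2 <- mk_bundle(enroll_end = DAY0 + 200)
  el2 <- build_cohort(b2, derive_all_lots(b2, cs, default_drug_dictionary())$lots,
                      cfg, cs)
  expect_equal(el2$follow_up_end_cause, "disenrollment")
  expect_equal(el2$follow_up_end, DAY0 + 200)
  # enrollment past study end: administrative censoring at study end
  b3 <- mk_bundle(enroll_end = as.Date("2030-01-01"))
  el3 <- build_cohort(b3, derive_all_lots(b3, cs, default_drug_dictionary())$lots,
                      cfg, cs)
  expect_equal(el3$follow_up_end_cause, "study_end")
  expect_equal(el3$follow_up_end, cfg$study_end)
})

test_that("extending enrollment never turns an eligible line ineligible", {
  ec <- make_eligibility_edge_cases()
  d <- derive_all_lots(ec$bundle, cs, default_drug_dictionary())
  lot1 <- d$lots[d$lots$lot_number == 1, ]
  el <- build_cohort(ec$bundle, lot1, cfg, cs)
  wider <- ec$bundle
  wider$enrollment$start_date <- wider$enrollment$start_date - 500L
  wider$enrollment$end_date <- wider$enrollment$end_date + 500L
  el_w <- build_cohort(wider, lot1, cfg, cs)
  m <- merge(el, el_w, by = "patient_id")
  expect_true(all(!m$eligible.x | m$eligible.y))
})

test_that("a line without an index date is a contract error", {
  b <- mk_bundle()
  expect_error(
    evaluate_lot_eligibility(b, list(patient_id = "T1", lot_number = 1,
                                     index_date = NA), cfg, cs),
    class = "cl_contract_error"
  )
})
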