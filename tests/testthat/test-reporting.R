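cfg <- study_config()
cs <- code_sets()
dict <- default_drug_dictionary()

test_that("the rendering chokepoint masks counts in [1, 5)", {
  expect_equal(render_count(c(0, 1, 2, 4, 5, 12)),
               c("0", "<5", "<5", "<5", "5", "12"))
  expect_equal(render_count(3, mask_threshold = 3), "3")
  expect_equal(render_count(2, token = "(masked)"), "(masked)")
})

test_that("therapy distribution tabulates by start year within line number", {
  lots <- data.frame(
    patient_id = sprintf("P%02d", 1:13),
    lot_number = c(rep(1L, 10), rep(2L, 3)),
    start_date = as.Date(c(rep("2020-03-01", 10), rep("2020-06-01", 3))),
    regimen = factor(c(rep("rchop", 6), rep("chemoimmunotherapy", 4),
                       rep("chemotherapy", 3)), levels = regimen_levels())
  )
  tab <- therapy_distribution_by_year(lots, cfg)
  r <- tab[tab$lot_number == 1 & tab$regimen == "rchop", ]
  expect_equal(r$n, 6)
  expect_equal(r$percent, 60)
  expect_equal(r$display, "6")
  small <- tab[tab$lot_number == 2, ]
  expect_equal(small$display, "<5") # 3 patients masked
  expect_equal(small$percent, 100)
  # percentages sum to 100 within each (year, line) stratum
  sums <- aggregate(percent ~ year + lot_number, tab, sum)
  expect_true(all(abs(sums$percent - 100) < 0.2))
  # a line starting after the study end is excluded
  lots2 <- rbind(lots, data.frame(patient_id = "P99", lot_number = 1L,
                                  start_date = as.Date("2024-07-15"),
                                  regimen = factor("rchop",
                                                   levels = regimen_levels())))
  expect_equal(nrow(therapy_distribution_by_year(lots2, cfg)),
               nrow(tab))
})

test_that("characteristics table computes degenerate and boundary summaries", {
  diag <- as.Date("2019-01-01")
  idx <- diag + 39 # 39 / 30.4375 = 1.28 months, reported 1.3
  pts <- sprintf("C%02d", 1:6)
  bundle <- claims_bundle(
    enrollment = data.frame(patient_id = pts, start_date = diag - 600,
                            end_date = idx + 600),
    medical = rbind(
      data.frame(patient_id = pts, service_date = diag, setting = "inpatient",
                 diagnosis_codes = "C83.30", procedure_codes = ""),
      # hypertension inside the 12-month window for one patient,
      # 13 months pre-index (outside) for another
      data.frame(patient_id = c("C01", "C02"),
                 service_date = c(idx - 100, idx - 396),
                 setting = "outpatient", diagnosis_codes = "I10",
                 procedure_codes = "")
    ),
    pharmacy = data.frame(patient_id = pts, fill_date = idx,
                          drug_code = "RX-RIT", days_supply = 0L),
    patients = data.frame(patient_id = pts, birth_year = 1949L, sex = "F")
  )
  el <- data.frame(patient_id = pts, lot_number = 1L, eligible = TRUE,
                   reasons = "", index_date = idx,
                   follow_up_end = idx + 200,
                   follow_up_end_cause = "disenrollment",
                   stringsAsFactors = FALSE)
  tab <- characteristics_table(el, bundle, cs, cfg)
  g <- function(var, stat) tab$value[tab$variable == var & tab$statistic == stat]
  expect_equal(g("age", "mean"), 70)
  expect_equal(g("age", "sd"), 0)
  expect_equal(g("age_category", "70-74"), 100)
  expect_equal(g("months_from_diagnosis_to_index", "median"), 1.3)
  expect_equal(g("comorbidity", "hypertension"), round(100 / 6, 1))
  # small cells masked in the display column
  htn <- tab[tab$variable == "comorbidity" & tab$statistic == "hypertension", ]
  expect_equal(htn$display, "<5")
})

test_that("the peri-CAR T report applies denominators and enrollment restrictions", {
  sim <- simulation_config(n_patients = 260, seed = 14)
  out <- simulate_cohort(sim)
  res <- run_pipeline(out$bundle)
  pc <- res$reports$peri_cart
  sm <- setNames(pc$summary$value, pc$summary$measure)
  expect_gt(sm["cart_patients"], 0)
  expect_lte(sm["post_cart_patients"], sm["cart_patients"])
  expect_lte(sm["apheresis_patients"], sm["cart_patients"])
  expect_equal(sm[["apheresis_to_infusion_median_days"]],
               median(pc$apheresis_days$days))
  # bridging percentages use the apheresis denominator
  if (nrow(pc$bridging_regimens)) {
    expect_equal(pc$bridging_regimens$percent,
                 round(100 * pc$bridging_regimens$n / sm[["apheresis_patients"]], 1))
  }
  # distinct post-CAR T regimen count is a set cardinality
  expect_gte(sm[["post_cart_distinct_regimens"]], 1)
  expect_lte(sm[["post_cart_distinct_regimens"]], sm[["post_cart_patients"]])
})

test_that("a patient disenrolling within 29 days of the next line is excluded post-CAR T", {
  # hand-built: one CAR T patient whose enrollment ends 20 days after the
  # next line starts, one fully enrolled
  mk_one <- function(pid, enroll_end_offset) {
    diag <- DAY0
    list(
      enrollment = data.frame(patient_id = pid, start_date = diag - 400,
                              end_date = DAY0 + 300 + enroll_end_offset),
      medical = data.frame(patient_id = pid, service_date = diag,
                           setting = "inpatient", diagnosis_codes = "C83.30",
                           procedure_codes = ""),
      pharmacy = data.frame(
        patient_id = pid,
        fill_date = c(DAY0 + 14, DAY0 + 233, DAY0 + 300),
        drug_code = c("RX-RIT", "RX-AXI", "RX-LON"),
        days_supply = 0L),
      patients = data.frame(patient_id = pid, birth_year = 1950L, sex = "M")
    )
  }
  a <- mk_one("A", 20 - 29) # ends 20 days after next-line start
  b <- mk_one("B", 200)
  bundle <- claims_bundle(
    enrollment = rbind(a$enrollment, b$enrollment),
    medical = rbind(a$medical, b$medical),
    pharmacy = rbind(a$pharmacy, b$pharmacy),
    patients = rbind(a$patients, b$patients)
  )
  d <- derive_all_lots(bundle, cs, dict)
  lots <- classify_lots(d$lots, dict)
  pc <- peri_cart_report(lots, d$events, bundle, dict, cfg)
  sm <- setNames(pc$summary$value, pc$summary$measure)
  expect_equal(unname(sm["cart_patients"]), 2)
  expect_equal(unname(sm["post_cart_patients"]), 1)
})

test_that("no emitted artifact contains an unmasked small count", {
  sim <- simulation_config(n_patients = 120, seed = 33)
  out <- simulate_cohort(sim)
  res <- run_pipeline(out$bundle)
  dir <- withr::local_tempdir()
  files <- write_report_tables(res$reports, dir)
  expect_gt(length(files), 3)
  for (f in list.files(dir, full.names = TRUE)) {
    df <- read.csv(f, colClasses = "character")
    for (col in grep("display", names(df), value = TRUE)) {
      expect_false(any(df[[col]] %in% c("1", "2", "3", "4")), info = f)
    }
    # raw count columns are not written at all
    expect_false("n" %in% names(df), info = f)
  }
})
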