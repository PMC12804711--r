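cfg <- study_config()

test_that("drugs initiated within 30 days of line start form one combination", {
  h <- derive_lots(mk_events(drugs = list(
    rituximab = 0, cyclophosphamide = 14, doxorubicin = 14, vincristine = 14
  )), DAY0, cfg)
  expect_equal(nrow(h$lots), 1)
  expect_equal(h$lots$core_drugs,
               "cyclophosphamide;doxorubicin;rituximab;vincristine")
  expect_equal(h$lots$end_trigger, "none")

  # inclusive boundary: day 30 joins, day 31 advances
  h30 <- derive_lots(mk_events(drugs = list(bendamustine = 0, gemcitabine = 30)),
                     DAY0, cfg)
  expect_equal(nrow(h30$lots), 1)
  h31 <- derive_lots(mk_events(drugs = list(bendamustine = 0, gemcitabine = 31)),
                     DAY0, cfg)
  expect_equal(nrow(h31$lots), 2)
  expect_equal(lot_offsets(h31), c(0L, 31L))
  expect_equal(h31$lots$end_trigger, c("new_therapy", "none"))
})

test_that("a new therapy past 30 days advances the line", {
  h <- derive_lots(mk_events(drugs = list(
    rituximab = 0, cyclophosphamide = 0, doxorubicin = 0, vincristine = 0,
    gemcitabine = 200
  )), DAY0, cfg)
  expect_equal(nrow(h$lots), 2)
  expect_equal(lot_offsets(h), c(0L, 200L))
  expect_equal(h$lots$end_trigger[1], "new_therapy")
  expect_equal(h$lots$core_drugs[2], "gemcitabine")
})

test_that("restart after a >90 day gap starts a new line, measured from exposure end", {
  # two cycles with 21-day supply: last exposure ends day 79 + 21 = 100
  sched <- list(rituximab = c(0, 79), cyclophosphamide = c(0, 79),
                doxorubicin = c(0, 79), vincristine = c(0, 79))
  base <- mk_events(drugs = sched, supply = 21L)
  reinit <- mk_events(drugs = list(cyclophosphamide = 191, doxorubicin = 191,
                                   rituximab = 191, vincristine = 191))
  h2 <- derive_lots(rbind(base, reinit), DAY0, cfg) # gap 91 > 90
  expect_equal(nrow(h2$lots), 2)
  expect_equal(h2$lots$end_trigger[1], "restart_gap")
  expect_equal(h2$lots$core_drugs[1], h2$lots$core_drugs[2])

  reinit90 <- mk_events(drugs = list(cyclophosphamide = 190, doxorubicin = 190,
                                     rituximab = 190, vincristine = 190))
  h1 <- derive_lots(rbind(base, reinit90), DAY0, cfg) # gap 90, not > 90
  expect_equal(nrow(h1$lots), 1)
})

test_that("SCT advances the line and salvage therapy joins the transplant line", {
  # 1L R-CHOP; salvage platinum 45 days before SCT
  ev <- rbind(
    mk_events(drugs = list(rituximab = 0, cyclophosphamide = 0,
                           doxorubicin = 0, vincristine = 0)),
    mk_events(drugs = list(cisplatin = 160, cytarabine = 160), sct = 205)
  )
  h <- derive_lots(ev, DAY0, cfg)
  expect_equal(nrow(h$lots), 2)
  expect_true(h$lots$contains_sct[2])
  expect_equal(as.integer(h$lots$start_date[2] - DAY0), 160L)
  expect_equal(as.integer(h$lots$index_date[2] - DAY0), 205L)
  expect_true(h$lots$has_salvage[2])
  expect_equal(h$lots$all_drugs[2], "cisplatin;cytarabine")
  expect_equal(h$lots$end_trigger[1], "sct_observed")

  # combination 120 days before SCT is outside the salvage window:
  # it forms its own line and SCT advances again
  ev2 <- rbind(
    mk_events(drugs = list(rituximab = 0, cyclophosphamide = 0,
                           doxorubicin = 0, vincristine = 0)),
    mk_events(drugs = list(cisplatin = 160, cytarabine = 160), sct = 280)
  )
  h2 <- derive_lots(ev2, DAY0, cfg)
  expect_equal(nrow(h2$lots), 3)
  expect_false(h2$lots$has_salvage[3])
  expect_true(h2$lots$contains_sct[3])

  # a drug after the SCT date is never salvage
  ev3 <- rbind(
    mk_events(drugs = list(rituximab = 0)),
    mk_events(drugs = list(gemcitabine = 170), sct = 160)
  )
  h3 <- derive_lots(ev3, DAY0, cfg)
  ann <- h3$events$annotation[h3$events$drug_name %in% "gemcitabine"]
  expect_false(any(ann == "salvage"))
})

test_that("same-day SCT dominates a drug event", {
  ev <- rbind(
    mk_events(drugs = list(rituximab = 0)),
    mk_events(drugs = list(cisplatin = 45), sct = 45)
  )
  h <- derive_lots(ev, DAY0, cfg)
  expect_equal(nrow(h$lots), 2)
  expect_true(h$lots$contains_sct[2])
  expect_equal(as.integer(h$lots$index_date[2] - DAY0), 45L)
  expect_true("cisplatin" %in% strsplit(h$lots$all_drugs[2], ";")[[1]])
})

test_that("bridging therapy is attributed to the CAR T line and does not advance", {
  # 1L R-CHOP; apheresis day 200; bridging pola+R day 220; infusion day 233
  ev <- rbind(
    mk_events(drugs = list(rituximab = 0, cyclophosphamide = 0,
                           doxorubicin = 0, vincristine = 0)),
    mk_events(drugs = list(`polatuzumab vedotin` = 220, rituximab = 220),
              cart = 233, apheresis = 200)
  )
  h <- derive_lots(ev, DAY0, cfg)
  expect_equal(nrow(h$lots), 2)
  expect_true(h$lots$contains_cart[2])
  expect_true(h$lots$has_bridging[2])
  expect_equal(as.integer(h$lots$start_date[2] - DAY0), 220L)
  expect_equal(as.integer(h$lots$index_date[2] - DAY0), 233L)
  expect_equal(h$lots$all_drugs[2], "polatuzumab vedotin;rituximab")
  expect_equal(h$lots$end_trigger[1], "cart_observed")

  # a drug 6 days before infusion is outside the bridging window
  ev6 <- rbind(
    mk_events(drugs = list(rituximab = 0, cyclophosphamide = 0,
                           doxorubicin = 0, vincristine = 0)),
    mk_events(drugs = list(`polatuzumab vedotin` = 227), cart = 233,
              apheresis = 200)
  )
  h6 <- derive_lots(ev6, DAY0, cfg)
  ann <- h6$events$annotation[h6$events$drug_name %in% "polatuzumab vedotin"]
  expect_false(any(ann == "bridging"))

  # no apheresis claim: 60-day fallback window before infusion - 7
  evf <- rbind(
    mk_events(drugs = list(rituximab = 0, cyclophosphamide = 0,
                           doxorubicin = 0, vincristine = 0)),
    mk_events(drugs = list(`polatuzumab vedotin` = 183), cart = 233)
  )
  hf <- derive_lots(evf, DAY0, cfg)
  expect_true(hf$lots$has_bridging[nrow(hf$lots)])
})

test_that("standalone exemption detectors pin their window boundaries", {
  ev <- mk_events(drugs = list(`polatuzumab vedotin` = c(20, 26, 27, 33)))
  br <- detect_bridging(ev, DAY0 + 33, apheresis_date = DAY0, config = cfg)
  expect_equal(as.integer(ev$event_date[br] - DAY0), c(20L, 26L))
  # apheresis after infusion falls back with a warning
  expect_warning(
    brf <- detect_bridging(ev, DAY0 + 33, apheresis_date = DAY0 + 40, config = cfg),
    "fallback"
  )
  expect_equal(as.integer(ev$event_date[brf] - DAY0), c(20L, 26L))

  ev2 <- mk_events(drugs = list(cisplatin = c(9, 10, 100, 101)))
  sv <- detect_salvage(ev2, DAY0 + 100, cfg)
  expect_equal(as.integer(ev2$event_date[sv] - DAY0), c(10L, 100L))
})

test_that("maintenance monotherapy does not advance the line", {
  base <- list(rituximab = 0, cyclophosphamide = 0, doxorubicin = 0,
               vincristine = 0)
  h <- derive_lots(mk_events(drugs = c(base, list(rituximab = 120))), DAY0, cfg)
  expect_equal(nrow(h$lots), 1)
  expect_true(h$lots$has_maintenance)
  expect_equal(sum(h$events$annotation == "maintenance", na.rm = TRUE), 1)

  # paired with a new drug the next day it is not maintenance; advancement
  h2 <- derive_lots(mk_events(drugs = c(base, list(rituximab = 120,
                                                   gemcitabine = 121))),
                    DAY0, cfg)
  expect_equal(nrow(h2$lots), 2)
  expect_false(h2$lots$has_maintenance[1])
  expect_true(as.integer(h2$lots$start_date[2] - DAY0) %in% c(120L, 121L))
  expect_true("gemcitabine" %in% strsplit(h2$lots$core_drugs[2], ";")[[1]])

  # a maintenance-list drug after a line not containing it advances
  h3 <- derive_lots(mk_events(drugs = list(bendamustine = 0, gemcitabine = 0,
                                           lenalidomide = 120)), DAY0, cfg)
  expect_equal(nrow(h3$lots), 2)

  # a drug outside the maintenance list advances even as monotherapy refill
  h4 <- derive_lots(mk_events(drugs = c(base, list(gemcitabine = 120))),
                    DAY0, cfg)
  expect_equal(nrow(h4$lots), 2)

  expect_equal(sum(detect_maintenance(
    mk_events(drugs = c(base, list(rituximab = 120))),
    list(core_drugs = "cyclophosphamide;doxorubicin;rituximab;vincristine",
         start_date = DAY0), cfg)), 1)
})

test_that("corticosteroids and unknown or non-directed drugs never join a line", {
  base <- list(rituximab = 0, cyclophosphamide = 0, doxorubicin = 0,
               vincristine = 0)
  h <- derive_lots(mk_events(drugs = c(base, list(prednisone = c(0, 200)))),
                   DAY0, cfg)
  expect_equal(nrow(h$lots), 1)
  expect_false(grepl("prednisone", h$lots$core_drugs))
  expect_true(all(h$events$annotation[h$events$drug_name %in% "prednisone"] ==
                    "excluded_corticosteroid"))

  h2 <- derive_lots(mk_events(drugs = c(base, list(atorvastatin = 200))),
                    DAY0, cfg)
  expect_equal(nrow(h2$lots), 1)
})

test_that("events before the diagnosis date are excluded with a warning", {
  ev <- mk_events(drugs = list(rituximab = c(-30, 10)))
  expect_warning(h <- derive_lots(ev, DAY0, cfg), "before the DLBCL diagnosis")
  expect_equal(nrow(h$lots), 1)
  expect_equal(as.integer(h$lots$start_date - DAY0), 10L)
  expect_equal(sum(h$events$annotation == "pre_diagnosis", na.rm = TRUE), 1)
})

test_that("event order never changes the derivation (permutation stability)", {
  set.seed(99)
  scenarios <- list(
    mk_events(drugs = list(rituximab = c(0, 21), cyclophosphamide = c(1, 22),
                           gemcitabine = 200)),
    rbind(mk_events(drugs = list(rituximab = 0, bendamustine = 0)),
          mk_events(drugs = list(cisplatin = 160), sct = 200)),
    rbind(mk_events(drugs = list(rituximab = 0)),
          mk_events(drugs = list(`polatuzumab vedotin` = 210), cart = 233,
                    apheresis = 200))
  )
  for (ev in scenarios) {
    ref <- lot_signature(derive_lots(ev, DAY0, cfg)$lots)
    for (k in 1:8) {
      sh <- ev[sample(nrow(ev)), ]
      expect_equal(lot_signature(derive_lots(sh, DAY0, cfg)$lots), ref)
    }
  }
})

test_that("every DLBCL-directed event lands in exactly one line's ledger", {
  sim <- simulation_config(n_patients = 60, seed = 21)
  out <- simulate_cohort(sim)
  d <- derive_all_lots(out$bundle, code_sets(), default_drug_dictionary())
  ev <- d$events
  directed <- ev$dlbcl_directed &
    ev$kind %in% c("drug_fill", "drug_administration") &
    ev$drug_class != "corticosteroid"
  expect_true(all(!is.na(ev$lot_number[directed])))
  expect_true(all(!is.na(ev$annotation[directed])))
  # and the lot it points to exists for that patient
  key_ev <- unique(paste(ev$patient_id[directed], ev$lot_number[directed]))
  key_lot <- paste(d$lots$patient_id, d$lots$lot_number)
  expect_true(all(key_ev %in% key_lot))
})
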