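#' Run the full study pipeline on a claims bundle
#'
#' Chains the whole analysis: derive lines of therapy, classify regimens,
#' evaluate eligibility, build OS and TTNT survival records per line-number
#' group, fit Kaplan-Meier curves with median/CI and fixed-horizon failure
#' rates, and produce the descriptive reports (therapy distribution by year,
#' baseline characteristics, peri-CAR T tables) with small-cell masking.
#'
#' @param bundle A `cl_bundle`.
#' @param config A [study_config()].
#' @param codes A [code_sets()].
#' @param dict A drug dictionary.
#' @param max_lot Highest line number to summarize as its own group.
#' @return A list: `lots` (labeled line table), `events`, `eligibility`,
#'   `attrition`, `outcomes` (per line group: `os`/`ttnt` medians with CI
#'   and failure rates), `reports`.
#' @export
run_pipeline <- function(bundle, config = study_config(), codes = code_sets(),
                         dict = default_drug_dictionary(), max_lot = 3L) {
  derived <- derive_all_lots(bundle, codes, dict, config)
  lots <- classify_lots(derived$lots, dict)
  eligibility <- build_cohort(bundle, lots, config, codes,
                              subgroup_mode = "lot_number")

  outcomes <- list()
  for (lot in seq_len(max_lot)) {
    el <- eligibility[eligibility$lot_number == lot, , drop = FALSE]
    if (!any(el$eligible)) next
    os_rec <- build_survival_records(lots, el, bundle, "os", config)
    tt_rec <- build_survival_records(lots, el, bundle, "ttnt", config)
    os_fit <- km_fit(os_rec)
    tt_fit <- km_fit(tt_rec)
    fr <- lapply(config$failure_horizons_months, function(h) {
      failure_rate(tt_fit, h, config)
    })
    outcomes[[paste0("lot", lot)]] <- list(
      n = sum(el$eligible),
      os_median = km_median_ci(os_fit, config),
      ttnt_median = km_median_ci(tt_fit, config),
      failure_rates = as.data.frame(data.table::rbindlist(fr)),
      os_fit = os_fit, ttnt_fit = tt_fit
    )
  }

  reports <- list(
    therapy_by_year = therapy_distribution_by_year(lots, config),
    characteristics = characteristics_table(eligibility, bundle, codes, config),
    peri_cart = peri_cart_report(lots, derived$events, bundle, dict, config)
  )

  list(lots = lots, events = derived$events, eligibility = eligibility,
       attrition = attrition_summary(eligibility),
       outcomes = outcomes, reports = reports)
}
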