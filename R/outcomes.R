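#' Build survival records for OS or TTNT
#'
#' One record per eligible (patient, line). Overall survival (OS) runs from
#' the line's index date to death (event) or to the end of follow-up
#' (censored at disenrollment or study end). Time to next treatment or death
#' (TTNT) is the composite endpoint: event at the earlier of the next line's
#' start date or death; censored at the end of follow-up otherwise.
#'
#' @param lots Line table (all derived lines, so next-line starts are
#'   visible even when the next line itself fails eligibility).
#' @param eligibility Result of [build_cohort()]; only eligible rows yield
#'   records.
#' @param bundle A `cl_bundle` (death dates).
#' @param endpoint `"os"` or `"ttnt"`.
#' @param config A [study_config()].
#' @return A data.frame with `patient_id`, `lot_number`, `duration_days`,
#'   `event`, `event_type` (`death`, `next_lot`, `censor`), `censor_cause`.
#' @export
build_survival_records <- function(lots, eligibility, bundle,
                                   endpoint = c("os", "ttnt"),
                                   config = study_config()) {
  endpoint <- match.arg(endpoint)
  el <- eligibility[eligibility$eligible, , drop = FALSE]
  if (!nrow(el)) {
    return(data.frame(patient_id = character(0), lot_number = integer(0),
                      duration_days = integer(0), event = logical(0),
                      event_type = character(0), censor_cause = character(0)))
  }
  death <- as.integer(bundle$death$death_date)[
    match(el$patient_id, bundle$death$patient_id)]
  nxt <- as.integer(lots$start_date)[
    match(paste(el$patient_id, el$lot_number + 1L),
          paste(lots$patient_id, lots$lot_number))]
  idx <- as.integer(el$index_date)
  fu_end <- as.integer(el$follow_up_end)
  if (any(!is.na(nxt) & nxt < idx)) {
    cl_stop("next line starts before the current index date", "cl_contract_error")
  }
  if (endpoint == "os") {
    ev <- !is.na(death) & death <= fu_end
    dur <- ifelse(ev, death - idx, fu_end - idx)
    et <- ifelse(ev, "death", "censor")
  } else {
    ev_date <- pmin(nxt, death, na.rm = TRUE)
    ev <- !is.na(ev_date) & ev_date <= fu_end
    dur <- ifelse(ev, ev_date - idx, fu_end - idx)
    et <- ifelse(ev, ifelse(!is.na(nxt) & !is.na(ev_date) & nxt == ev_date,
                            "next_lot", "death"),
                 "censor")
  }
  data.frame(
    patient_id = el$patient_id, lot_number = el$lot_number,
    duration_days = as.integer(dur), event = ev, event_type = et,
    censor_cause = ifelse(ev, NA_character_, el$follow_up_end_cause),
    stringsAsFactors = FALSE
  )
}

#' Product-limit (Kaplan-Meier) fit
#'
#' Fits the product-limit estimator to survival records, grouping same-day
#' ties, with censored observations at an event time leaving the risk set
#' after that time (events precede censorings). Pointwise confidence
#' intervals use the complementary log-log transform, which also drives the
#' Brookmeyer-Crowley-style median interval of [km_median_ci()].
#'
#' @param records Data frame with `duration_days` and logical `event` (e.g.
#'   from [build_survival_records()]).
#' @param level Confidence level (default 0.95).
#' @return An object of class `cl_km` with `time` (distinct event times),
#'   `n_risk`, `n_event`, `surv`, `greenwood_var`, `n`, and the underlying
#'   `survival::survfit` fit.
#' @export
km_fit <- function(records, level = 0.95) {
  if (!nrow(records)) cl_stop("no survival records", "cl_contract_error")
  if (any(records$duration_days < 0)) {
    cl_stop("negative durations", "cl_contract_error")
  }
  fit <- survival::survfit(
    survival::Surv(records$duration_days, records$event) ~ 1,
    conf.type = "log-log", conf.int = level
  )
  ev <- fit$n.event > 0
  structure(list(
    time = fit$time[ev],
    n_risk = fit$n.risk[ev],
    n_event = fit$n.event[ev],
    surv = fit$surv[ev],
    greenwood_var = (fit$std.err[ev] * fit$surv[ev])^2,
    n = fit$n,
    level = level,
    fit = fit
  ), class = "cl_km")
}

#' @export
print.cl_km <- function(x, ...) {
  cat(sprintf("<Kaplan-Meier fit> n = %d, %d event time(s)\n",
              x$n, length(x$time)))
  invisible(x)
}

# Survival (and its CI) at a single time point; extends flat beyond the
# last observed time.
km_surv_at <- function(curve, t) {
  s <- summary(curve$fit, times = t, extend = TRUE)
  list(surv = s$surv, lower = s$lower, upper = s$upper,
       n_risk = s$n.risk)
}

#' Median survival with confidence interval
#'
#' The median is the smallest time with S(t) <= 0.5; its interval inverts
#' the complementary log-log pointwise bands (Brookmeyer-Crowley style).
#' Medians or bounds the curve never reaches are returned as `NA` with
#' `not_reached` flags, never as numeric infinities.
#'
#' @param curve A `cl_km` fit.
#' @param config A [study_config()]; supplies the day-to-month conversion.
#' @param units `"months"` (default) or `"days"`.
#' @return A one-row data.frame: `median`, `ci_low`, `ci_high`,
#'   `median_not_reached`, `ci_high_not_reached`, `n`.
#' @export
km_median_ci <- function(curve, config = study_config(), units = c("months", "days")) {
  units <- match.arg(units)
  q <- quantile(curve$fit, probs = 0.5, conf.int = TRUE)
  med <- unname(q$quantile[1])
  lo <- unname(q$lower[1])
  hi <- unname(q$upper[1])
  conv <- if (units == "months") 1 / config$month_length_days else 1
  data.frame(
    median = if (is.na(med)) NA_real_ else med * conv,
    ci_low = if (is.na(lo)) NA_real_ else lo * conv,
    ci_high = if (is.na(hi)) NA_real_ else hi * conv,
    median_not_reached = is.na(med),
    ci_high_not_reached = is.na(hi),
    n = curve$n
  )
}

#' Fixed-horizon treatment failure rate
#'
#' The percentage of patients who initiated a next line or died within the
#' horizon: `100 * (1 - S(h))` on a TTNT curve, with the confidence interval
#' from the complementary log-log band of S(h). When the horizon lies beyond
#' the last observed time while subjects remain at risk, the rate at the
#' last estimable time is returned with a warning.
#'
#' @param curve A `cl_km` fit of TTNT records.
#' @param horizon_months Horizon in months (> 0).
#' @param config A [study_config()].
#' @return A one-row data.frame: `horizon_months`, `rate`, `ci_low`,
#'   `ci_high` (percent), `n_at_risk_at_horizon`.
#' @export
failure_rate <- function(curve, horizon_months, config = study_config()) {
  if (horizon_months <= 0) cl_stop("horizon must be positive", "cl_contract_error")
  h <- horizon_months * config$month_length_days
  last_t <- max(curve$fit$time)
  if (h > last_t && min(curve$fit$n.risk[curve$fit$time == last_t]) > 0) {
    warning(sprintf("horizon %.0f months beyond last observed time; reporting rate at the last estimable time",
                    horizon_months), call. = FALSE)
    h <- last_t
  }
  s <- km_surv_at(curve, h)
  no_events <- !length(curve$time) || min(curve$time) > h
  data.frame(
    horizon_months = horizon_months,
    rate = 100 * (1 - s$surv),
    ci_low = if (no_events) 0 else 100 * (1 - s$upper),
    ci_high = 100 * (1 - s$lower),
    n_at_risk_at_horizon = s$n_risk
  )
}
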