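# Synthetic claims generation with known ground truth.
#
# The generator plans each patient's treatment trajectory from a template
# (an intended sequence of lines with drugs, modality events and exempt
# therapy segments), realizes it against the patient's simulated death /
# enrollment horizon, and then emits exactly the claims that would produce
# that trajectory. Ground truth is computed from the *realized* schedule, so
# truth and claims stay consistent under truncation at death or data cutoff.

draw1 <- function(x) {
  if (length(x) == 1) return(as.integer(x))
  as.integer(x[1] + floor(runif(1) * (x[2] - x[1] + 1)))
}

#' Template line specification
#'
#' One planned line inside a [trajectory_template()]. `gap` is the start
#' offset in days: from diagnosis for the first line, from the prior line's
#' index date otherwise; a scalar is fixed, a length-2 vector is uniform,
#' and `NULL` means survival-driven (an exponential progression time derived
#' from the configured TTNT and OS medians). Modality lines: `sct = TRUE`
#' places salvage `drugs` at the line start and the transplant
#' `sct_offset` days later; `cart = TRUE` places an apheresis claim at the
#' line start, `bridge_drugs` shortly after it, and the infusion
#' `apheresis_lead` days after apheresis (default 33 days, the typical
#' apheresis-to-infusion interval).
#'
#' @param drugs Drug names (combination partners, or salvage drugs for an
#'   SCT line). May be `character(0)` for a bare modality line.
#' @param gap Start offset spec (see above).
#' @param stagger_max Later combination drugs start `U{0..stagger_max}` days
#'   after the first (0 = simultaneous).
#' @param cycles,cycle_length_days Number of repeat fills per drug and their
#'   spacing.
#' @param days_supply Days supply per fill.
#' @param sct,sct_offset Transplant line and its offset from line start.
#' @param cart,cart_product,apheresis_lead,bridge_drugs,bridge_offset CAR T
#'   line: product name (`"unspecified"` emits a brandless infusion
#'   procedure code), apheresis-to-infusion lead, bridging drugs and their
#'   offset from apheresis.
#' @param maint_drug,maint_offset,maint_n,maint_interval Optional
#'   maintenance segment after the line.
#' @param restart_gap Optional: re-initiate the same drug set this many days
#'   after the line's last exposure ends (a value > 90 produces a new line).
#' @return A list of class `cl_template_line`.
#' @export
template_line <- function(drugs, gap, stagger_max = 0, cycles = 1L,
                          cycle_length_days = 21L, days_supply = 0L,
                          sct = FALSE, sct_offset = 45,
                          cart = FALSE, cart_product = "unspecified",
                          apheresis_lead = 33, bridge_drugs = NULL,
                          bridge_offset = 5,
                          maint_drug = NULL, maint_offset = 150,
                          maint_n = 4L, maint_interval = 60L,
                          restart_gap = NULL) {
  structure(list(drugs = drugs, gap = gap, stagger_max = stagger_max,
                 cycles = as.integer(cycles),
                 cycle_length_days = as.integer(cycle_length_days),
                 days_supply = as.integer(days_supply),
                 sct = sct, sct_offset = sct_offset,
                 cart = cart, cart_product = cart_product,
                 apheresis_lead = apheresis_lead,
                 bridge_drugs = bridge_drugs, bridge_offset = bridge_offset,
                 maint_drug = maint_drug, maint_offset = maint_offset,
                 maint_n = as.integer(maint_n),
                 maint_interval = as.integer(maint_interval),
                 restart_gap = restart_gap),
            class = "cl_template_line")
}

#' Trajectory template
#'
#' A named, ordered plan of treatment lines used by [simulate_cohort()].
#'
#' @param name Template name.
#' @param lines List of [template_line()]s.
#' @param confirm_mode `"inpatient"` (one inpatient claim with primary DLBCL
#'   code at diagnosis) or `"outpatient"` (two outpatient claims 30 days
#'   apart starting at diagnosis); both diagnosis-confirmation paths are
#'   exercised across the default templates.
#' @return A list of class `cl_template`.
#' @export
trajectory_template <- function(name, lines, confirm_mode = "inpatient") {
  structure(list(name = name, lines = lines, confirm_mode = confirm_mode),
            class = "cl_template")
}

rchop_drugs <- c("rituximab", "cyclophosphamide", "doxorubicin",
                 "vincristine", "prednisone")

#' Default trajectory templates
#'
#' A mixture emulating contemporary DLBCL practice: R-CHOP-based first-line
#' therapy for most patients (with survival-driven progression to
#' gemcitabine/oxaliplatin-based and pola-based later lines), rituximab
#' maintenance, platinum salvage followed by autologous SCT, CAR T with
#' pola + rituximab bridging, and an R-CHOP discontinuation/restart pattern.
#'
#' @param stochastic When `FALSE`, every offset/stagger distribution
#'   collapses to a fixed value (zero-variance templates, used for exact
#'   ground-truth recovery checks); survival times remain stochastic.
#' @return Named list of templates with a `weights` attribute.
#' @export
default_templates <- function(stochastic = TRUE) {
  rng <- function(fixed, range) if (stochastic) range else fixed
  tpl <- list(
    rchop = trajectory_template("rchop", list(
      template_line(rchop_drugs, gap = rng(14, c(7, 28)),
                    stagger_max = if (stochastic) 5 else 0,
                    cycles = 6),
      template_line(c("gemcitabine", "oxaliplatin", "rituximab"), gap = NULL,
                    cycles = 4, cycle_length_days = 14),
      template_line(c("polatuzumab vedotin", "bendamustine", "rituximab"),
                    gap = NULL, cycles = 4)
    )),
    rchop_outpt = trajectory_template("rchop_outpt", list(
      template_line(rchop_drugs, gap = rng(40, c(35, 60)), cycles = 6),
      template_line(c("gemcitabine", "oxaliplatin", "rituximab"), gap = NULL,
                    cycles = 4, cycle_length_days = 14)
    ), confirm_mode = "outpatient"),
    rchop_maint = trajectory_template("rchop_maint", list(
      template_line(rchop_drugs, gap = rng(14, c(7, 28)), cycles = 6,
                    maint_drug = "rituximab",
                    maint_offset = rng(150, c(130, 200)),
                    maint_n = 4, maint_interval = 60)
    )),
    salvage_sct = trajectory_template("salvage_sct", list(
      template_line(rchop_drugs, gap = rng(14, c(7, 28)), cycles = 6),
      template_line(c("cisplatin", "cytarabine"), gap = rng(180, c(150, 250)),
                    sct = TRUE, sct_offset = rng(45, c(35, 60))),
      template_line("glofitamab", gap = NULL)
    )),
    cart_bridging = trajectory_template("cart_bridging", list(
      template_line(rchop_drugs, gap = rng(14, c(7, 28)), cycles = 6),
      template_line(character(0), gap = rng(200, c(160, 300)), cart = TRUE,
                    cart_product = "axicabtagene ciloleucel",
                    apheresis_lead = rng(33, c(26, 40)),
                    bridge_drugs = c("polatuzumab vedotin", "rituximab"),
                    bridge_offset = rng(5, c(2, 18))),
      template_line("loncastuximab tesirine", gap = NULL)
    )),
    rchop_restart = trajectory_template("rchop_restart", list(
      template_line(rchop_drugs, gap = rng(14, c(7, 28)), cycles = 1,
                    restart_gap = rng(95, c(92, 130)))
    ))
  )
  attr(tpl, "weights") <- c(rchop = 0.5, rchop_outpt = 0.15, rchop_maint = 0.1,
                            salvage_sct = 0.1, cart_bridging = 0.1,
                            rchop_restart = 0.05)
  tpl
}

#' Simulation configuration
#'
#' @param n_patients Cohort size.
#' @param seed Master seed (mandatory). Each patient gets an independent RNG
#'   stream derived from it, so enlarging the cohort never perturbs earlier
#'   patients.
#' @param templates Named list of [trajectory_template()]s.
#' @param weights Template mixture weights (default: the templates'
#'   `weights` attribute); must sum to 1.
#' @param os_median_months Median overall survival from the first-line index
#'   date (exponential; default 58.1 months, a typical first-line claims
#'   cohort value).
#' @param ttnt_median_months Median time to next treatment or death
#'   (exponential composite; default 36.1 months). Must be below the OS
#'   median; the progression hazard is the difference of the two exponential
#'   rates, so the composite endpoint is exponential with the stated median
#'   and progression never outlives death by construction.
#' @param churn_monthly_hazard Hazard of disenrollment per month after the
#'   first index date (default 0.01, roughly 11% annual turnover).
#' @param death_recording_prob Probability a true death appears in the death
#'   table (default 1; lower values emulate incomplete mortality capture).
#' @param diagnosis_window Calendar window for diagnosis dates.
#' @param birth_year_offset_range Age at diagnosis range (years).
#' @param comorbidity_prob Probability of emitting a pre-index hypertension
#'   claim (exercises comorbidity flags).
#' @param pre_enrollment_range Days of enrollment before diagnosis.
#' @return A list of class `cl_sim_config`.
#' @export
simulation_config <- function(n_patients = 500L, seed,
                              templates = default_templates(),
                              weights = NULL,
                              os_median_months = 58.1,
                              ttnt_median_months = 36.1,
                              churn_monthly_hazard = 0.01,
                              death_recording_prob = 1,
                              diagnosis_window = as.Date(c("2016-01-01", "2021-06-30")),
                              birth_year_offset_range = c(40, 80),
                              comorbidity_prob = 0.3,
                              pre_enrollment_range = c(400, 900)) {
  if (missing(seed)) cl_stop("a seed is mandatory", "cl_config_error")
  weights <- weights %||% attr(templates, "weights")
  if (is.null(weights)) weights <- setNames(rep(1 / length(templates), length(templates)),
                                            names(templates))
  if (abs(sum(weights) - 1) > 1e-8) {
    cl_stop("template weights must sum to 1", "cl_config_error")
  }
  if (os_median_months <= 0 || ttnt_median_months <= 0) {
    cl_stop("survival medians must be positive", "cl_config_error")
  }
  if (ttnt_median_months >= os_median_months) {
    cl_stop("ttnt_median_months must be below os_median_months", "cl_config_error")
  }
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    templates = templates, weights = weights,
    os_median_months = os_median_months,
    ttnt_median_months = ttnt_median_months,
    churn_monthly_hazard = churn_monthly_hazard,
    death_recording_prob = death_recording_prob,
    diagnosis_window = as_date(diagnosis_window),
    birth_year_offset_range = birth_year_offset_range,
    comorbidity_prob = comorbidity_prob,
    pre_enrollment_range = pre_enrollment_range
  ), class = "cl_sim_config")
}

# Plan one patient's full event schedule (no truncation yet).
# Returns a list of "planned lines", each with meta + an event data.frame
# (date, type in drug/sct/cart/apheresis, drug, annotation).
plan_trajectory <- function(tpl, diag, sim, config) {
  rate_d <- log(2) / (sim$os_median_months * config$month_length_days)
  rate_t <- log(2) / (sim$ttnt_median_months * config$month_length_days)
  rate_p <- rate_t - rate_d

  planned <- list()
  prev_index <- NULL
  prev_start <- NULL
  for (L in tpl$lines) {
    if (is.null(prev_index)) {
      start0 <- diag + draw1(L$gap)
    } else if (is.null(L$gap)) {
      p_days <- max(1L, as.integer(round(rexp(1, rate_p))))
      min_gap <- max(1L, 31L - as.integer(prev_index - prev_start))
      start0 <- prev_index + max(p_days, min_gap)
    } else {
      start0 <- prev_index + draw1(L$gap)
    }
    # Therapy on the prior line stops at progression: drop its planned
    # fills on/after the new line's start so lines never interleave.
    if (length(planned)) {
      k <- length(planned)
      planned[[k]]$events <- planned[[k]]$events[planned[[k]]$events$date < start0, , drop = FALSE]
    }
    e_date <- integer(0); e_type <- character(0)
    e_drug <- character(0); e_ann <- character(0)
    push <- function(date, type, drug, ann) {
      e_date <<- c(e_date, as.integer(date))
      e_type <<- c(e_type, rep_len(type, length(date)))
      e_drug <<- c(e_drug, rep_len(drug, length(date)))
      e_ann <<- c(e_ann, rep_len(ann, length(date)))
    }
    if (L$cart) {
      push(start0, "apheresis", NA_character_, "apheresis")
      lead <- draw1(L$apheresis_lead)
      infusion <- start0 + lead
      for (d in L$bridge_drugs %||% character(0)) {
        push(start0 + draw1(L$bridge_offset), "drug", d, "bridging")
      }
      push(infusion, "cart", L$cart_product, "modality")
      index <- infusion
      modality_date <- infusion
    } else if (L$sct) {
      sct_date <- start0 + draw1(L$sct_offset)
      for (d in L$drugs) {
        push(start0 + draw1(c(0, L$stagger_max)), "drug", d, "salvage")
      }
      push(sct_date, "sct", NA_character_, "modality")
      index <- sct_date
      modality_date <- sct_date
    } else {
      first_dates <- c(start0, start0 + vapply(seq_along(L$drugs)[-1],
                                               function(i) draw1(c(0, L$stagger_max)),
                                               integer(1)))
      for (j in seq_along(L$drugs)) {
        cyc_dates <- first_dates[j] + (seq_len(L$cycles) - 1L) * L$cycle_length_days
        push(cyc_dates, "drug", L$drugs[j],
             c("core", rep("continuation", L$cycles - 1L)))
      }
      index <- start0
      modality_date <- as.Date(NA)
    }
    if (!is.null(L$maint_drug)) {
      m0 <- start0 + draw1(L$maint_offset)
      push(m0 + (seq_len(L$maint_n) - 1L) * L$maint_interval,
           "drug", L$maint_drug, "maintenance")
    }
    evdf <- data.frame(date = as.Date(e_date, origin = "1970-01-01"),
                       type = e_type, drug = e_drug, annotation = e_ann,
                       stringsAsFactors = FALSE)
    planned[[length(planned) + 1]] <- list(
      start = min(evdf$date), index = index, sct = isTRUE(L$sct),
      cart = isTRUE(L$cart),
      cart_product = if (isTRUE(L$cart)) L$cart_product else NA_character_,
      modality_date = modality_date, days_supply = L$days_supply,
      events = evdf)

    if (!is.null(L$restart_gap)) {
      last_exp <- max(evdf$date[evdf$type == "drug"]) + L$days_supply
      r0 <- last_exp + draw1(L$restart_gap)
      rev <- data.frame(date = rep(r0, length(L$drugs)), type = "drug",
                        drug = L$drugs, annotation = "core",
                        stringsAsFactors = FALSE)
      planned[[length(planned) + 1]] <- list(
        start = r0, index = r0, sct = FALSE, cart = FALSE,
        cart_product = NA_character_, modality_date = as.Date(NA),
        days_supply = L$days_supply, events = rev)
      prev_index <- r0; prev_start <- r0
    } else {
      prev_index <- index
      # apheresis is not a therapy event and does not open the line
      prev_start <- min(evdf$date[evdf$type != "apheresis"])
    }
  }
  planned
}

#' Simulate a claims cohort with ground truth
#'
#' Generates a seedable synthetic claims bundle plus the ground truth that
#' produced it: per-patient diagnosis date, realized lines of therapy (with
#' bridging/salvage/maintenance attribution), true death date, and expected
#' eligibility. Claims are emitted only up to the patient's data horizon
#' (death or study end, and never beyond disenrollment), and modality lines
#' are emitted atomically, so the bundle and the truth always agree. The
#' same seed reproduces the output exactly.
#'
#' @param sim A [simulation_config()].
#' @param codes A [code_sets()].
#' @param dict A drug dictionary; every template drug must resolve in it.
#' @param config A [study_config()].
#' @return A list with `bundle` (a `cl_bundle`) and `truth` (list of
#'   `patients`, `lots`, `eligibility` data.frames).
#' @export
simulate_cohort <- function(sim, codes = code_sets(),
                            dict = default_drug_dictionary(),
                            config = study_config()) {
  all_drugs <- unique(unlist(lapply(sim$templates, function(t) {
    unlist(lapply(t$lines, function(L) c(L$drugs, L$bridge_drugs, L$maint_drug)))
  })))
  unresolved <- setdiff(all_drugs, dict$drug_name)
  if (length(unresolved)) {
    cl_stop(sprintf("template drug(s) not in dictionary: %s",
                    paste(unresolved, collapse = ", ")), "cl_config_error")
  }

  # Flat accumulators (one entry per emitted row), bound into tables once
  # at the end; drug codes are resolved through a name -> code map.
  per_pat <- vector("list", sim$n_patients)
  P <- NULL # per-patient chunk store; flattened once at the end
  put <- function(field, value) {
    cur <- P[[field]]
    P[[field]] <<- if (is.null(cur)) list(value) else c(cur, list(value))
  }
  code_of <- setNames(dict$drug_code[match(unique(dict$drug_name), dict$drug_name)],
                      unique(dict$drug_name))
  diag_span <- as.integer(sim$diagnosis_window[2] - sim$diagnosis_window[1])
  rate_d <- log(2) / (sim$os_median_months * config$month_length_days)
  churn_daily <- sim$churn_monthly_hazard / config$month_length_days
  dlbcl_code <- paste0(codes$dlbcl_icd10_prefix, "0")

  for (i in seq_len(sim$n_patients)) {
    set.seed((sim$seed %% 100000L) * 20011L + i)
    P <- list()
    pid <- sprintf("P%05d", i)
    diag <- sim$diagnosis_window[1] + draw1(c(0, diag_span))
    tname <- names(sim$templates)[
      sample.int(length(sim$templates), 1, prob = sim$weights[names(sim$templates)])]
    tpl <- sim$templates[[tname]]
    birth_year <- as.integer(format(diag, "%Y")) - draw1(sim$birth_year_offset_range)
    sex <- c("M", "F")[draw1(c(1, 2))]

    planned <- plan_trajectory(tpl, diag, sim, config)
    index1 <- planned[[1]]$index
    death <- index1 + as.integer(round(rexp(1, rate_d)))
    disenroll <- if (churn_daily > 0) {
      index1 + as.integer(round(rexp(1, churn_daily)))
    } else {
      config$study_end + 1L
    }
    enroll_start <- diag - draw1(sim$pre_enrollment_range)
    enroll_end <- min(disenroll, config$study_end)
    death_recorded <- runif(1) <= sim$death_recording_prob
    has_comorb <- runif(1) <= sim$comorbidity_prob
    cutoff <- min(death, enroll_end)

    # Realize: truncate at the data horizon; modality lines are kept only
    # when the modality event itself is reachable.
    realized <- list()
    for (pl in planned) {
      if (pl$start > cutoff) next
      if ((pl$sct || pl$cart) && pl$modality_date > cutoff) next
      pl$events <- pl$events[pl$events$date <= cutoff, , drop = FALSE]
      if (!nrow(pl$events)) next
      realized[[length(realized) + 1]] <- pl
    }
    if (!length(realized)) next

    # Claims emission: confirmation (and optional comorbidity) claims.
    if (tpl$confirm_mode == "inpatient") {
      put("md_pid", pid); put("md_date", as.integer(diag))
      put("md_set", "inpatient"); put("md_dx", dlbcl_code); put("md_pr", "")
    } else {
      put("md_pid", c(pid, pid))
      put("md_date", as.integer(c(diag, diag + 30L)))
      put("md_set", c("outpatient", "outpatient"))
      put("md_dx", c(dlbcl_code, dlbcl_code)); put("md_pr", c("", ""))
    }
    if (has_comorb) {
      put("md_pid", pid); put("md_date", as.integer(diag - 30L))
      put("md_set", "outpatient")
      put("md_dx", codes$comorbidity_code_map[[1]][1]); put("md_pr", "")
    }

    for (k in seq_along(realized)) {
      pl <- realized[[k]]
      evdf <- pl$events
      dr <- evdf[evdf$type == "drug", , drop = FALSE]
      if (nrow(dr)) {
        put("ph_pid", rep(pid, nrow(dr)))
        put("ph_date", as.integer(dr$date))
        put("ph_code", unname(code_of[dr$drug]))
        put("ph_sup", rep(pl$days_supply, nrow(dr)))
      }
      proc <- character(0); pdates <- integer(0)
      if (any(evdf$type == "apheresis")) {
        proc <- c(proc, codes$apheresis_codes[1])
        pdates <- c(pdates, as.integer(evdf$date[evdf$type == "apheresis"][1]))
      }
      if (any(evdf$type == "sct")) {
        proc <- c(proc, codes$sct_procedure_codes[1])
        pdates <- c(pdates, as.integer(evdf$date[evdf$type == "sct"][1]))
      }
      if (any(evdf$type == "cart")) {
        cdate <- evdf$date[evdf$type == "cart"][1]
        if (pl$cart_product == "unspecified") {
          proc <- c(proc, codes$cart_procedure_codes[1])
          pdates <- c(pdates, as.integer(cdate))
        } else {
          put("ph_pid", pid); put("ph_date", as.integer(cdate))
          put("ph_code", unname(code_of[pl$cart_product])); put("ph_sup", 0L)
        }
      }
      if (length(proc)) {
        put("md_pid", rep(pid, length(proc))); put("md_date", pdates)
        put("md_set", rep("outpatient", length(proc)))
        put("md_dx", rep(dlbcl_code, length(proc))); put("md_pr", proc)
      }

      # Ground-truth line, from the realized events.
      dcls <- dict$drug_class[match(dr$drug, dict$drug_name)]
      noncort <- dr[dcls != "corticosteroid", , drop = FALSE]
      # Apheresis is a collection procedure, not a therapy: it does not
      # open the line.
      start <- min(evdf$date[evdf$type != "apheresis"])
      core <- sort(unique(noncort$drug[noncort$annotation %in% c("core", "continuation") &
                                         noncort$date <= start + config$combination_window_days]))
      put("lt_pid", pid); put("lt_num", k)
      put("lt_start", as.integer(start)); put("lt_index", as.integer(pl$index))
      put("lt_core", paste(core, collapse = ";"))
      put("lt_all", paste(sort(unique(noncort$drug)), collapse = ";"))
      put("lt_sct", pl$sct); put("lt_cart", pl$cart)
      put("lt_prod", if (pl$cart && pl$cart_product != "unspecified") pl$cart_product else NA_character_)
      put("lt_br", any(noncort$annotation == "bridging"))
      put("lt_sv", any(noncort$annotation == "salvage"))
      put("lt_mt", any(noncort$annotation == "maintenance"))

      # Ground-truth eligibility (LOT-number subgroup rules).
      conf_ready <- if (tpl$confirm_mode == "inpatient") diag else diag + 30L
      idx <- pl$index
      reasons <- character(0)
      if (conf_ready > idx) reasons <- c(reasons, "diagnosis_confirmation")
      if (as.integer(idx - enroll_start) < config$pre_index_enrollment_days)
        reasons <- c(reasons, "pre_index_enrollment")
      if (as.integer(enroll_end - idx) < config$post_index_enrollment_days)
        reasons <- c(reasons, "post_index_enrollment")
      if (as.integer(format(idx, "%Y")) - birth_year < config$min_age_years)
        reasons <- c(reasons, "age")
      if (as.integer(diag - enroll_start) < config$washout_days)
        reasons <- c(reasons, "washout")
      if (idx < config$study_start || idx > config$study_end)
        reasons <- c(reasons, "outside_study_window")
      put("el_pid", pid); put("el_num", k)
      put("el_ok", !length(reasons))
      put("el_rs", paste(reasons, collapse = ";"))
    }

    put("en_pid", pid); put("en_start", as.integer(enroll_start))
    put("en_end", as.integer(enroll_end))
    put("pt_pid", pid); put("pt_by", birth_year); put("pt_sex", sex)
    if (death <= config$study_end && death_recorded) {
      put("dt_pid", pid); put("dt_date", as.integer(death))
    }
    put("tp_pid", pid); put("tp_tpl", tname)
    put("tp_diag", as.integer(diag)); put("tp_death", as.integer(death))
    put("tp_rec", death <= config$study_end && death_recorded)
    put("tp_es", as.integer(enroll_start)); put("tp_ee", as.integer(enroll_end))
    put("tp_by", birth_year); put("tp_sex", sex)
    per_pat[[i]] <- P
  }

  gv <- function(field, as = c("chr", "int", "date", "lgl")) {
    as <- match.arg(as)
    x <- unlist(lapply(per_pat, function(p) p[[field]]), use.names = FALSE)
    switch(as,
      chr = as.character(x %||% character(0)),
      int = as.integer(x %||% integer(0)),
      lgl = as.logical(x %||% logical(0)),
      date = as.Date(as.integer(x %||% integer(0)), origin = "1970-01-01"))
  }
  bundle <- claims_bundle(
    enrollment = data.frame(patient_id = gv("en_pid"),
                            start_date = gv("en_start", "date"),
                            end_date = gv("en_end", "date")),
    medical = data.frame(patient_id = gv("md_pid"),
                         service_date = gv("md_date", "date"),
                         setting = gv("md_set"), diagnosis_codes = gv("md_dx"),
                         procedure_codes = gv("md_pr")),
    pharmacy = data.frame(patient_id = gv("ph_pid"),
                          fill_date = gv("ph_date", "date"),
                          drug_code = gv("ph_code"),
                          days_supply = gv("ph_sup", "int")),
    death = data.frame(patient_id = gv("dt_pid"),
                       death_date = gv("dt_date", "date")),
    patients = data.frame(patient_id = gv("pt_pid"),
                          birth_year = gv("pt_by", "int"),
                          sex = gv("pt_sex")),
    config = config
  )
  truth <- list(
    patients = data.frame(patient_id = gv("tp_pid"), template = gv("tp_tpl"),
                          diagnosis_date = gv("tp_diag", "date"),
                          death_date = gv("tp_death", "date"),
                          death_recorded = gv("tp_rec", "lgl"),
                          enroll_start = gv("tp_es", "date"),
                          enroll_end = gv("tp_ee", "date"),
                          birth_year = gv("tp_by", "int"), sex = gv("tp_sex"),
                          stringsAsFactors = FALSE),
    lots = data.frame(patient_id = gv("lt_pid"), lot_number = gv("lt_num", "int"),
                      start_date = gv("lt_start", "date"),
                      index_date = gv("lt_index", "date"),
                      core_drugs = gv("lt_core"), all_drugs = gv("lt_all"),
                      contains_sct = gv("lt_sct", "lgl"),
                      contains_cart = gv("lt_cart", "lgl"),
                      cart_product = gv("lt_prod"),
                      has_bridging = gv("lt_br", "lgl"),
                      has_salvage = gv("lt_sv", "lgl"),
                      has_maintenance = gv("lt_mt", "lgl"),
                      stringsAsFactors = FALSE),
    eligibility = data.frame(patient_id = gv("el_pid"),
                             lot_number = gv("el_num", "int"),
                             eligible = gv("el_ok", "lgl"),
                             reasons = gv("el_rs"), stringsAsFactors = FALSE)
  )
  list(bundle = bundle, truth = truth)
}
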