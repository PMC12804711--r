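#' Extract dated therapy events from a claims bundle
#'
#' Builds the event stream the LOT engine consumes: pharmacy fills become
#' drug exposures running from `fill_date` to `fill_date + days_supply`;
#' medical-claim procedure codes matching the SCT, CAR T or apheresis code
#' sets become modality events; procedure codes found in the drug dictionary
#' become same-day drug administrations. Pharmacy claims for CAR T products
#' (drug class `cart_product`) are treated as CAR T infusion events, carrying
#' the product name for brand reporting.
#'
#' @param bundle A `cl_bundle`.
#' @param codes A [code_sets()].
#' @param dict A drug dictionary.
#' @return A data.frame with columns `patient_id`, `event_date`, `kind`
#'   (`drug_fill`, `drug_administration`, `sct`, `cart_infusion`,
#'   `apheresis`), `drug_name`, `drug_class`, `dlbcl_directed`,
#'   `exposure_end`. Unknown drug codes are retained with
#'   `drug_name = "unknown"` and `dlbcl_directed = FALSE`.
#' @export
therapy_events <- function(bundle, codes, dict) {
  rows <- list()

  ph <- bundle$pharmacy
  if (nrow(ph)) {
    lk <- dict_lookup(dict, ph$drug_code)
    is_cart <- lk$known & lk$drug_class == "cart_product"
    rows$fills <- data.frame(
      patient_id = ph$patient_id,
      event_date = ph$fill_date,
      kind = ifelse(is_cart, "cart_infusion", "drug_fill"),
      drug_name = ifelse(lk$known, lk$drug_name, "unknown"),
      drug_class = ifelse(lk$known, lk$drug_class, "unknown"),
      dlbcl_directed = lk$known & lk$dlbcl_directed,
      exposure_end = ph$fill_date + ifelse(is_cart, 0L, ph$days_supply),
      stringsAsFactors = FALSE
    )
    if (any(!lk$known)) {
      warning(sprintf("%d pharmacy claim(s) carry drug codes absent from the dictionary; excluded from LOT derivation",
                      sum(!lk$known)), call. = FALSE)
    }
  }

  md <- bundle$medical
  if (nrow(md)) {
    pcodes <- split_codes(md$procedure_codes)
    n_per <- lengths(pcodes)
    if (any(n_per > 0)) {
      flat <- data.frame(
        patient_id = rep(md$patient_id, n_per),
        event_date = rep(md$service_date, n_per),
        code = unlist(pcodes),
        stringsAsFactors = FALSE
      )
      kind <- rep(NA_character_, nrow(flat))
      kind[code_matches(flat$code, codes$sct_procedure_codes)] <- "sct"
      kind[code_matches(flat$code, codes$cart_procedure_codes)] <- "cart_infusion"
      kind[code_matches(flat$code, codes$apheresis_codes)] <- "apheresis"
      lk <- dict_lookup(dict, flat$code)
      is_drug <- is.na(kind) & lk$known
      keep <- !is.na(kind) | is_drug
      if (any(keep)) {
        rows$procs <- data.frame(
          patient_id = flat$patient_id[keep],
          event_date = flat$event_date[keep],
          kind = ifelse(is.na(kind[keep]), "drug_administration", kind[keep]),
          drug_name = ifelse(is_drug[keep], lk$drug_name[keep], NA_character_),
          drug_class = ifelse(is_drug[keep], lk$drug_class[keep], NA_character_),
          dlbcl_directed = ifelse(is_drug[keep], lk$dlbcl_directed[keep], FALSE),
          exposure_end = flat$event_date[keep],
          stringsAsFactors = FALSE
        )
      }
    }
  }

  if (!length(rows)) {
    return(data.frame(patient_id = character(0),
                      event_date = as.Date(character(0)),
                      kind = character(0), drug_name = character(0),
                      drug_class = character(0), dlbcl_directed = logical(0),
                      exposure_end = as.Date(character(0)),
                      stringsAsFactors = FALSE))
  }
  ev <- as.data.frame(data.table::rbindlist(rows))
  kind_rank <- match(ev$kind, c("sct", "cart_infusion", "apheresis",
                                "drug_fill", "drug_administration"))
  ev <- ev[order(ev$patient_id, ev$event_date, kind_rank, ev$drug_name), ]
  rownames(ev) <- NULL
  ev
}

# Bridging window for one CAR T infusion: [apheresis, infusion - 7] when an
# apheresis claim precedes the infusion; otherwise a fixed-width fallback
# window ending 7 days before infusion.
bridging_window <- function(cart_date, apheresis_dates, config) {
  end <- cart_date - config$bridging_end_offset_days
  aph <- apheresis_dates[apheresis_dates <= cart_date]
  if (length(aph)) {
    start <- max(aph)
  } else {
    if (length(apheresis_dates)) {
      warning("apheresis claim dated after CAR T infusion; using fallback bridging window",
              call. = FALSE)
    }
    start <- cart_date - config$bridging_fallback_window_days
  }
  c(start = start, end = end)
}

#' Identify bridging-exempt drug events around a CAR T infusion
#'
#' Drug events dated within `[apheresis, infusion - 7]` days are bridging
#' therapy: attributed to the CAR T line and never advancing the LOT. With no
#' apheresis claim the window is `[infusion - 60, infusion - 7]` (fallback
#' width configurable).
#'
#' @param events Therapy-event data.frame (one patient).
#' @param cart_infusion_date CAR T infusion date.
#' @param apheresis_date Apheresis date or `NULL`.
#' @param config A [study_config()].
#' @return Logical vector marking bridging-exempt rows of `events`.
#' @export
detect_bridging <- function(events, cart_infusion_date, apheresis_date = NULL,
                            config = study_config()) {
  w <- bridging_window(cart_infusion_date,
                       if (is.null(apheresis_date)) as.Date(character(0)) else as_date(apheresis_date),
                       config)
  is_drug <- events$kind %in% c("drug_fill", "drug_administration")
  is_drug & events$event_date >= w["start"] & events$event_date <= w["end"]
}

#' Identify salvage-window drug events before a stem cell transplant
#'
#' Drug events initiated within `salvage_window_days` before (or on) the SCT
#' date. Inside [derive_lots()] the exemption is applied only to events that
#' would otherwise advance the line; events already inside the current line's
#' combination window simply remain in that line.
#'
#' @param events Therapy-event data.frame (one patient).
#' @param sct_date SCT date.
#' @param config A [study_config()].
#' @return Logical vector marking salvage-window rows of `events`.
#' @export
detect_salvage <- function(events, sct_date, config = study_config()) {
  sct_date <- as_date(sct_date)
  is_drug <- events$kind %in% c("drug_fill", "drug_administration")
  is_drug & events$event_date <= sct_date &
    events$event_date >= sct_date - config$salvage_window_days
}

#' Identify maintenance-exempt drug events after a line
#'
#' A drug event is maintenance when its drug is on the configured maintenance
#' list (default rituximab, lenalidomide), the line it follows is multi-agent
#' and contains that drug, and no other DLBCL-directed non-corticosteroid
#' drug is initiated within the combination window after it. Maintenance
#' never advances the LOT.
#'
#' @param events Therapy-event data.frame (one patient).
#' @param current_lot A list with at least `core_drugs` (character vector)
#'   and `start_date`.
#' @param config A [study_config()].
#' @return Logical vector marking maintenance-exempt rows of `events`.
#' @export
detect_maintenance <- function(events, current_lot, config = study_config()) {
  core <- current_lot$core_drugs
  if (is.character(core) && length(core) == 1 && grepl(";", core)) {
    core <- strsplit(core, ";", fixed = TRUE)[[1]]
  }
  is_drug <- events$kind %in% c("drug_fill", "drug_administration")
  directed <- is_drug & events$dlbcl_directed & events$drug_class != "corticosteroid"
  out <- rep(FALSE, nrow(events))
  if (length(core) < 2) return(out)
  for (i in which(directed)) {
    d <- events$drug_name[i]
    if (!d %in% config$maintenance_drug_names || !d %in% core) next
    win_end <- events$event_date[i] + config$combination_window_days
    other <- directed & events$drug_name != d &
      events$event_date >= events$event_date[i] & events$event_date <= win_end
    if (!any(other)) out[i] <- TRUE
  }
  out
}

new_line <- function(number, start, index, sct = FALSE, cart = FALSE) {
  list(number = number, start = start, index = index,
       sct = sct, cart = cart,
       drugs = character(0),     # working drug set (core + exempt attributions)
       core = character(0),      # drugs initiated within the combination window
       last_exposure = NA_integer_,
       end_trigger = "none")
}

#' Derive lines of therapy for one patient
#'
#' Implements the claims LOT algorithm: the first line starts with the first
#' DLBCL-directed therapy after diagnosis and absorbs every therapy initiated
#' within 30 days (inclusive) of line start as a combination partner. A line
#' advances at the earliest of (a) a DLBCL-directed drug not in the current
#' line's drug set first observed strictly more than 30 days after line
#' start, (b) a stem cell transplant, (c) a CAR T infusion, or (d)
#' re-initiation of a current-line drug after every exposure in the line has
#' lapsed for strictly more than 90 days (regimen restart). Maintenance
#' therapy, salvage therapy within 90 days before SCT, and bridging therapy
#' between apheresis and 7 days before CAR T infusion are attributed to their
#' line (same line / transplant line / CAR T line) and never advance the LOT.
#' SCT and CAR T lines take the transplant or infusion date as index date.
#' Corticosteroids and non-DLBCL-directed drugs never join or advance a line.
#' Radiotherapy is assumed excluded upstream.
#'
#' @param events Therapy-event data.frame for a single patient (see
#'   [therapy_events()]).
#' @param diagnosis_date First observed DLBCL diagnosis date; events dated
#'   before it are excluded with a warning.
#' @param config A [study_config()].
#' @return A list of class `cl_lot_history` with `patient_id`,
#'   `diagnosis_date`, `lots` (one row per line: `lot_number`, `start_date`,
#'   `index_date`, `core_drugs`, `all_drugs`, `contains_sct`,
#'   `contains_cart`, `cart_product`, `has_bridging`, `has_salvage`,
#'   `has_maintenance`, `end_trigger`) and `events` (the input with
#'   `lot_number` and `annotation` columns).
#' @export
derive_lots <- function(events, diagnosis_date, config = study_config()) {
  diagnosis_date <- as_date(diagnosis_date)
  pid <- if (nrow(events)) events$patient_id[1] else NA_character_
  n <- nrow(events)
  lot_of <- rep(NA_integer_, n)
  annot <- rep(NA_character_, n)

  kind_rank <- match(events$kind, c("sct", "cart_infusion", "apheresis",
                                    "drug_fill", "drug_administration"))
  ord <- order(events$event_date, kind_rank, events$drug_name)
  events <- events[ord, ]

  # Hot path works on plain integer days and character vectors.
  ed <- as.integer(events$event_date)
  xd <- as.integer(events$exposure_end)
  kv <- events$kind
  dv <- events$drug_name

  is_drug <- kv %in% c("drug_fill", "drug_administration")
  usable <- events$dlbcl_directed & is_drug &
    events$drug_class != "corticosteroid"
  annot[is_drug & events$drug_class == "corticosteroid"] <- "excluded_corticosteroid"
  annot[is_drug & !events$dlbcl_directed &
          (is.na(events$drug_class) | events$drug_class != "corticosteroid")] <- "excluded_not_directed"

  pre <- ed < as.integer(diagnosis_date)
  if (any(pre & (usable | !is_drug))) {
    warning(sprintf("patient %s: %d therapy event(s) before the DLBCL diagnosis date excluded",
                    pid, sum(pre & (usable | !is_drug))), call. = FALSE)
  }
  annot[pre] <- "pre_diagnosis"

  live <- !pre
  aph_dates <- ed[live & kv == "apheresis"]
  cart_dates <- sort(unique(ed[live & kv == "cart_infusion"]))
  sct_dates <- sort(unique(ed[live & kv == "sct"]))

  # Bridging target per event: the earliest infusion whose window contains it.
  windows <- lapply(cart_dates, bridging_window, apheresis_dates = aph_dates,
                    config = config)
  bridge_for <- function(d) {
    for (k in seq_along(cart_dates)) {
      w <- windows[[k]]
      if (d >= w["start"] && d <= w["end"]) return(cart_dates[k])
    }
    NA_integer_
  }
  ev_bridge <- rep(NA_integer_, n)
  for (i in which(live & usable)) ev_bridge[i] <- bridge_for(ed[i])

  # Lookahead for the maintenance rule: is a *different* DLBCL-directed,
  # non-exempt drug initiated within the combination window after event i?
  other_drug_in_window <- function(i) {
    d0 <- ed[i]
    any(live & usable & is.na(ev_bridge) & dv != dv[i] &
          ed >= d0 & ed <= d0 + config$combination_window_days)
  }

  lines <- list()
  cur <- NULL
  pending_bridge <- list()   # keyed by infusion date
  pending_salvage <- list()  # keyed by sct date

  close_line <- function(trigger) {
    cur$end_trigger <<- trigger
    lines[[length(lines) + 1]] <<- cur
    cur <<- NULL
  }
  add_exposure <- function(i, line) {
    e <- xd[i]
    if (is.na(line$last_exposure) || e > line$last_exposure) line$last_exposure <- e
    line
  }

  attach_pool <- function(pool_key, pool, line, tag) {
    evs <- pool[[pool_key]]
    if (is.null(evs)) return(line)
    for (i in evs) {
      lot_of[i] <<- line$number
      annot[i] <<- tag
      line$drugs <- union(line$drugs, dv[i])
      if (line$start > ed[i]) line$start <- ed[i]
      line <- add_exposure(i, line)
    }
    line
  }

  for (i in seq_len(n)) {
    if (!live[i]) next
    k <- kv[i]
    d <- ed[i]

    if (k == "sct") {
      if (!is.null(cur)) close_line("sct_observed")
      ln <- new_line(length(lines) + 1L, d, d, sct = TRUE)
      ln <- attach_pool(as.character(d), pending_salvage, ln, "salvage")
      pending_salvage[[as.character(d)]] <- NULL
      lot_of[i] <- ln$number; annot[i] <- "modality"
      cur <- ln
      next
    }
    if (k == "cart_infusion") {
      if (!is.null(cur)) close_line("cart_observed")
      ln <- new_line(length(lines) + 1L, d, d, cart = TRUE)
      ln$cart_product <- dv[i]
      ln <- attach_pool(as.character(d), pending_bridge, ln, "bridging")
      pending_bridge[[as.character(d)]] <- NULL
      lot_of[i] <- ln$number; annot[i] <- "modality"
      cur <- ln
      next
    }
    if (k == "apheresis") {
      annot[i] <- "apheresis"
      next
    }
    if (!usable[i]) next

    # Bridging exemption takes precedence over everything else.
    if (!is.na(ev_bridge[i])) {
      key <- as.character(ev_bridge[i])
      pending_bridge[[key]] <- c(pending_bridge[[key]], i)
      next
    }

    drug <- dv[i]
    if (is.null(cur)) {
      cur <- new_line(length(lines) + 1L, d, d)
      cur$drugs <- drug; cur$core <- drug
      cur <- add_exposure(i, cur)
      lot_of[i] <- cur$number; annot[i] <- "core"
      next
    }

    offset <- d - cur$start
    if (offset <= config$combination_window_days) {
      cur$drugs <- union(cur$drugs, drug)
      cur$core <- union(cur$core, drug)
      cur <- add_exposure(i, cur)
      lot_of[i] <- cur$number; annot[i] <- "core"
      next
    }

    if (drug %in% cur$drugs) {
      # Re-exposure to a current-line drug: maintenance, restart, or
      # plain continuation.
      is_maint <- drug %in% config$maintenance_drug_names &&
        drug %in% cur$core && length(cur$core) >= 2 &&
        !other_drug_in_window(i)
      if (is_maint) {
        cur <- add_exposure(i, cur)
        lot_of[i] <- cur$number; annot[i] <- "maintenance"
        next
      }
      gap <- d - cur$last_exposure
      if (!is.na(gap) && gap > config$restart_gap_days) {
        s_next <- sct_dates[sct_dates > d & sct_dates - d <= config$salvage_window_days]
        if (length(s_next)) {
          # A restart that would advance, inside the salvage window: the
          # re-initiated therapy belongs to the upcoming transplant line.
          key <- as.character(s_next[1])
          pending_salvage[[key]] <- c(pending_salvage[[key]], i)
          next
        }
        close_line("restart_gap")
        cur <- new_line(length(lines) + 1L, d, d)
        cur$drugs <- drug; cur$core <- drug
        cur <- add_exposure(i, cur)
        lot_of[i] <- cur$number; annot[i] <- "core"
      } else {
        cur <- add_exposure(i, cur)
        lot_of[i] <- cur$number; annot[i] <- "continuation"
      }
      next
    }

    # New drug beyond the combination window: advancement candidate.
    if (offset > config$advancement_threshold_days) {
      s_next <- sct_dates[sct_dates > d & sct_dates - d <= config$salvage_window_days]
      if (length(s_next)) {
        key <- as.character(s_next[1])
        pending_salvage[[key]] <- c(pending_salvage[[key]], i)
        next
      }
      close_line("new_therapy")
      cur <- new_line(length(lines) + 1L, d, d)
      cur$drugs <- drug; cur$core <- drug
      cur <- add_exposure(i, cur)
      lot_of[i] <- cur$number; annot[i] <- "core"
    } else {
      # Degenerate config (advancement threshold > combination window):
      # attribute to the current line without advancing.
      cur$drugs <- union(cur$drugs, drug)
      cur <- add_exposure(i, cur)
      lot_of[i] <- cur$number; annot[i] <- "core"
    }
  }
  if (!is.null(cur)) close_line("none")

  # Apheresis events annotate into the CAR T line when one exists.
  cart_line_nums <- vapply(lines, function(l) if (isTRUE(l$cart)) l$number else NA_integer_, integer(1))
  if (any(!is.na(cart_line_nums))) {
    first_cart <- min(cart_line_nums, na.rm = TRUE)
    lot_of[live & kv == "apheresis" & is.na(lot_of)] <- first_cart
  }

  pack <- function(v) paste(sort(unique(v)), collapse = ";")
  lots <- if (length(lines)) {
    data.frame(
      patient_id = pid,
      lot_number = vapply(lines, `[[`, integer(1), "number"),
      start_date = as.Date(vapply(lines, function(l) as.integer(l$start), integer(1)),
                           origin = "1970-01-01"),
      index_date = as.Date(vapply(lines, function(l) as.integer(l$index), integer(1)),
                           origin = "1970-01-01"),
      core_drugs = vapply(lines, function(l) pack(l$core), character(1)),
      all_drugs = vapply(lines, function(l) pack(l$drugs), character(1)),
      contains_sct = vapply(lines, function(l) isTRUE(l$sct), logical(1)),
      contains_cart = vapply(lines, function(l) isTRUE(l$cart), logical(1)),
      cart_product = vapply(lines, function(l) {
        p <- l$cart_product %||% NA_character_
        if (is.null(p) || is.na(p)) NA_character_ else p
      }, character(1)),
      has_bridging = vapply(lines, function(l) {
        any(annot == "bridging" & lot_of == l$number, na.rm = TRUE)
      }, logical(1)),
      has_salvage = vapply(lines, function(l) {
        any(annot == "salvage" & lot_of == l$number, na.rm = TRUE)
      }, logical(1)),
      has_maintenance = vapply(lines, function(l) {
        any(annot == "maintenance" & lot_of == l$number, na.rm = TRUE)
      }, logical(1)),
      end_trigger = vapply(lines, `[[`, character(1), "end_trigger"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(patient_id = character(0), lot_number = integer(0),
               start_date = as.Date(character(0)), index_date = as.Date(character(0)),
               core_drugs = character(0), all_drugs = character(0),
               contains_sct = logical(0), contains_cart = logical(0),
               cart_product = character(0), has_bridging = logical(0),
               has_salvage = logical(0), has_maintenance = logical(0),
               end_trigger = character(0), stringsAsFactors = FALSE)
  }

  events$lot_number <- lot_of
  events$annotation <- annot
  structure(list(patient_id = pid, diagnosis_date = diagnosis_date,
                 lots = lots, events = events),
            class = "cl_lot_history")
}

#' @export
print.cl_lot_history <- function(x, ...) {
  cat(sprintf("<LOT history> patient %s, diagnosed %s, %d line(s)\n",
              x$patient_id, format(x$diagnosis_date), nrow(x$lots)))
  if (nrow(x$lots)) print(x$lots[, c("lot_number", "start_date", "index_date",
                                     "core_drugs", "contains_sct",
                                     "contains_cart", "end_trigger")])
  invisible(x)
}

#' Derive lines of therapy for every diagnosed patient in a bundle
#'
#' Convenience wrapper: finds each patient's first DLBCL diagnosis, extracts
#' therapy events, and runs [derive_lots()] per patient.
#'
#' @param bundle A `cl_bundle`.
#' @param codes A [code_sets()].
#' @param dict A drug dictionary.
#' @param config A [study_config()].
#' @return A list with `lots` (row-bound line table over all patients) and
#'   `events` (annotated event ledger), plus `diagnosis` (per-patient first
#'   diagnosis dates).
#' @export
derive_all_lots <- function(bundle, codes, dict, config = study_config()) {
  diag <- first_dlbcl_diagnosis(bundle, codes)
  ev <- therapy_events(bundle, codes, dict)
  lots_acc <- list()
  ev_acc <- list()
  ev_split <- split(ev, ev$patient_id)
  for (pid in names(ev_split)) {
    dd <- diag$diagnosis_date[diag$patient_id == pid]
    if (!length(dd) || is.na(dd)) next
    h <- derive_lots(ev_split[[pid]], dd, config)
    lots_acc[[pid]] <- h$lots
    ev_acc[[pid]] <- h$events
  }
  lots <- if (length(lots_acc)) as.data.frame(data.table::rbindlist(lots_acc))
          else derive_lots(ev[0, ], as.Date("2000-01-01"), config)$lots
  events <- if (length(ev_acc)) as.data.frame(data.table::rbindlist(ev_acc)) else ev
  list(lots = lots, events = events, diagnosis = diag)
}
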