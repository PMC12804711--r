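# Independent brute-force reference for the LOT rules, written directly from
# the algorithm's verbal statement as a flat chronological simulation, and an
# exhaustive enumerator of small event configurations around the 30- and
# 90-day boundaries. Kept deliberately separate from the package internals:
# it recomputes every window inline and carries its own state layout.

# ev: data.frame with columns day (integer), kind ("drug","sct","cart","aph"),
# drug (character, NA for modalities), expend (integer exposure end day).
# Returns a data.frame: start, index, core, all (sorted ";"-joined), sct, cart.
oracle_derive <- function(ev, comb = 30, adv = 30, restart = 90, salv = 90,
                          b_end = 7, b_fb = 60,
                          maint = c("rituximab", "lenalidomide")) {
  rk <- c(sct = 1, cart = 2, aph = 3, drug = 4)
  ev <- ev[order(ev$day, rk[ev$kind], ev$drug), , drop = FALSE]
  n <- nrow(ev)
  carts <- sort(unique(ev$day[ev$kind == "cart"]))
  aphs <- sort(unique(ev$day[ev$kind == "aph"]))
  scts <- sort(unique(ev$day[ev$kind == "sct"]))

  # Which CAR T infusion (if any) claims drug event at day d as bridging?
  bridge_of <- function(d) {
    for (cc in carts) {
      lo <- if (any(aphs <= cc)) max(aphs[aphs <= cc]) else cc - b_fb
      if (d >= lo && d <= cc - b_end) return(cc)
    }
    NA_real_
  }
  is_drug <- ev$kind == "drug"
  ebr <- rep(NA_real_, n)
  for (i in which(is_drug)) ebr[i] <- bridge_of(ev$day[i])

  # Lookahead used by the maintenance rule: another (non-bridging) drug with
  # a different name starting within the combination window after day d.
  other_in_window <- function(i) {
    any(is_drug & is.na(ebr) & ev$drug != ev$drug[i] &
          ev$day >= ev$day[i] & ev$day <= ev$day[i] + comb)
  }

  out <- list()
  st <- NULL # start, index, drugs, core, lastexp, sct, cart
  hold_b <- list() # infusion day -> row indices
  hold_s <- list() # sct day -> row indices
  flush <- function() { out[[length(out) + 1]] <<- st; st <<- NULL }
  absorb <- function(idx_set) {
    for (j in idx_set) {
      st$drugs <<- union(st$drugs, ev$drug[j])
      st$start <<- min(st$start, ev$day[j])
      st$lastexp <<- max(st$lastexp, ev$expend[j])
    }
  }

  for (i in seq_len(n)) {
    d <- ev$day[i]
    if (ev$kind[i] == "aph") next
    if (ev$kind[i] == "sct") {
      if (!is.null(st)) flush()
      st <- list(start = d, index = d, drugs = character(0),
                 core = character(0), lastexp = -Inf, sct = TRUE, cart = FALSE)
      absorb(hold_s[[as.character(d)]])
      hold_s[[as.character(d)]] <- NULL
      next
    }
    if (ev$kind[i] == "cart") {
      if (!is.null(st)) flush()
      st <- list(start = d, index = d, drugs = character(0),
                 core = character(0), lastexp = -Inf, sct = FALSE, cart = TRUE)
      absorb(hold_b[[as.character(d)]])
      hold_b[[as.character(d)]] <- NULL
      next
    }
    # drug event
    if (!is.na(ebr[i])) { # bridging: belongs to the infusion's line
      k <- as.character(ebr[i])
      hold_b[[k]] <- c(hold_b[[k]], i)
      next
    }
    if (is.null(st)) {
      st <- list(start = d, index = d, drugs = ev$drug[i], core = ev$drug[i],
                 lastexp = ev$expend[i], sct = FALSE, cart = FALSE)
      next
    }
    if (d - st$start <= comb) { # combination window, inclusive
      st$drugs <- union(st$drugs, ev$drug[i])
      st$core <- union(st$core, ev$drug[i])
      st$lastexp <- max(st$lastexp, ev$expend[i])
      next
    }
    if (ev$drug[i] %in% st$drugs) {
      maintenance <- ev$drug[i] %in% maint && ev$drug[i] %in% st$core &&
        length(st$core) >= 2 && !other_in_window(i)
      if (maintenance) {
        st$lastexp <- max(st$lastexp, ev$expend[i])
        next
      }
      if (d - st$lastexp > restart) {
        ups <- scts[scts > d & scts - d <= salv]
        if (length(ups)) {
          k <- as.character(ups[1])
          hold_s[[k]] <- c(hold_s[[k]], i)
          next
        }
        flush()
        st <- list(start = d, index = d, drugs = ev$drug[i], core = ev$drug[i],
                   lastexp = ev$expend[i], sct = FALSE, cart = FALSE)
      } else {
        st$lastexp <- max(st$lastexp, ev$expend[i])
      }
      next
    }
    # a new therapy, past the advancement threshold
    if (d - st$start > adv) {
      ups <- scts[scts > d & scts - d <= salv]
      if (length(ups)) { # salvage: goes with the upcoming transplant
        k <- as.character(ups[1])
        hold_s[[k]] <- c(hold_s[[k]], i)
        next
      }
      flush()
      st <- list(start = d, index = d, drugs = ev$drug[i], core = ev$drug[i],
                 lastexp = ev$expend[i], sct = FALSE, cart = FALSE)
    } else {
      st$drugs <- union(st$drugs, ev$drug[i])
      st$lastexp <- max(st$lastexp, ev$expend[i])
    }
  }
  if (!is.null(st)) flush()

  if (!length(out)) {
    return(data.frame(start = integer(0), index = integer(0),
                      core = character(0), all = character(0),
                      sct = logical(0), cart = logical(0)))
  }
  data.frame(
    start = vapply(out, function(l) as.integer(l$start), integer(1)),
    index = vapply(out, function(l) as.integer(l$index), integer(1)),
    core = vapply(out, function(l) paste(sort(unique(l$core)), collapse = ";"),
                  character(1)),
    all = vapply(out, function(l) paste(sort(unique(l$drugs)), collapse = ";"),
                 character(1)),
    sct = vapply(out, function(l) l$sct, logical(1)),
    cart = vapply(out, function(l) l$cart, logical(1)),
    stringsAsFactors = FALSE
  )
}

oracle_signature <- function(orc) {
  if (!nrow(orc)) return("")
  paste(sprintf("%d|%d|%s|%s|%d%d", orc$start, orc$index, orc$core, orc$all,
                orc$sct, orc$cart), collapse = " ;; ")
}

# Engine output expressed in the oracle's signature (day offsets from DAY0).
engine_signature <- function(history) {
  lt <- history$lots
  if (!nrow(lt)) return("")
  paste(sprintf("%d|%d|%s|%s|%d%d",
                as.integer(lt$start_date - DAY0),
                as.integer(lt$index_date - DAY0),
                lt$core_drugs, lt$all_drugs,
                lt$contains_sct, lt$contains_cart), collapse = " ;; ")
}

# All multisets of size 0..n_max over (drug, day) options, with optional
# SCT / CAR T / apheresis placements. Returns a list of oracle-style event
# data.frames.
enumerate_event_sets <- function(days = c(0L, 29L, 30L, 31L, 90L, 91L, 120L, 185L),
                                 drugs = c("gemcitabine", "rituximab"),
                                 n_max = 4L,
                                 sct_days = c(NA, 45L, 91L),
                                 cart_days = c(NA, 100L),
                                 aph_days = c(NA, 67L)) {
  opts <- expand.grid(drug = drugs, day = days, stringsAsFactors = FALSE)
  n_opts <- nrow(opts)
  combos <- list(integer(0))
  grow <- function(sets) {
    res <- list()
    for (s in sets) {
      lo <- if (length(s)) s[length(s)] else 1L
      for (j in lo:n_opts) res[[length(res) + 1]] <- c(s, j)
    }
    res
  }
  cur <- list(integer(0))
  for (sz in seq_len(n_max)) {
    cur <- grow(cur)
    combos <- c(combos, cur)
  }
  cases <- list()
  for (cmb in combos) {
    base <- if (length(cmb)) {
      data.frame(day = opts$day[cmb], kind = "drug", drug = opts$drug[cmb],
                 expend = opts$day[cmb], stringsAsFactors = FALSE)
    } else {
      data.frame(day = integer(0), kind = character(0), drug = character(0),
                 expend = integer(0), stringsAsFactors = FALSE)
    }
    for (sd in sct_days) for (cd in cart_days) {
      aph_opts <- if (is.na(cd)) NA else aph_days
      for (ad in aph_opts) {
        extra <- list()
        if (!is.na(sd)) extra$s <- data.frame(day = sd, kind = "sct",
                                              drug = NA_character_, expend = sd)
        if (!is.na(cd)) extra$c <- data.frame(day = cd, kind = "cart",
                                              drug = NA_character_, expend = cd)
        if (!is.na(cd) && !is.na(ad)) {
          extra$a <- data.frame(day = ad, kind = "aph",
                                drug = NA_character_, expend = ad)
        }
        case <- rbind(base, do.call(rbind, extra))
        if (is.null(case) || !nrow(case)) next
        cases[[length(cases) + 1]] <- case
      }
    }
  }
  cases
}

# Convert an oracle-style case into the engine's therapy-event table.
case_to_events <- function(case, dict = default_drug_dictionary()) {
  cls <- dict$drug_class[match(case$drug, dict$drug_name)]
  kind_map <- c(drug = "drug_fill", sct = "sct", cart = "cart_infusion",
                aph = "apheresis")
  data.frame(
    patient_id = "E1",
    event_date = DAY0 + case$day,
    kind = unname(kind_map[case$kind]),
    drug_name = case$drug,
    drug_class = cls,
    dlbcl_directed = !is.na(cls),
    exposure_end = DAY0 + case$expend,
    stringsAsFactors = FALSE
  )
}
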