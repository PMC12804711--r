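#' Render patient counts with small-cell masking
#'
#' The single rendering chokepoint for every artifact the package emits:
#' counts in `[1, mask_threshold)` are replaced by the mask token; zero is
#' rendered as `"0"`. Percentages are computed on raw counts before masking
#' (masking affects display only).
#'
#' @param n Integer vector of raw counts.
#' @param mask_threshold Masking threshold (default 5).
#' @param token Mask token (default `"<5"`).
#' @return Character vector of display values.
#' @export
render_count <- function(n, mask_threshold = 5L, token = "<5") {
  ifelse(n >= 1 & n < mask_threshold, token, as.character(n))
}

#' Therapy distribution by calendar year
#'
#' Tabulates regimen categories by the calendar year of line start, within
#' line number. A patient contributes once per line (no deduplication across
#' line numbers). Lines starting outside the study window are excluded;
#' the final partial study year is included as-is. Percentages are within
#' each (year, line number) stratum.
#'
#' @param labeled_lots Line table with a `regimen` column ([classify_lots()]).
#' @param config A [study_config()].
#' @return Data frame with `year`, `lot_number`, `regimen`, `n`, `display`,
#'   `percent`.
#' @export
therapy_distribution_by_year <- function(labeled_lots, config = study_config()) {
  lt <- labeled_lots[labeled_lots$start_date >= config$study_start &
                       labeled_lots$start_date <= config$study_end, , drop = FALSE]
  if (!nrow(lt)) {
    return(data.frame(year = integer(0), lot_number = integer(0),
                      regimen = character(0), n = integer(0),
                      display = character(0), percent = numeric(0)))
  }
  lt$year <- as.integer(format(lt$start_date, "%Y"))
  agg <- aggregate(list(n = rep(1L, nrow(lt))),
                   by = list(year = lt$year, lot_number = lt$lot_number,
                             regimen = as.character(lt$regimen)),
                   FUN = sum)
  denom <- aggregate(list(total = agg$n),
                     by = list(year = agg$year, lot_number = agg$lot_number),
                     FUN = sum)
  agg <- merge(agg, denom, by = c("year", "lot_number"))
  agg$percent <- round(100 * agg$n / agg$total, 1)
  agg$display <- render_count(agg$n, config$mask_threshold)
  agg <- agg[order(agg$year, agg$lot_number, -agg$n, agg$regimen),
             c("year", "lot_number", "regimen", "n", "display", "percent")]
  rownames(agg) <- NULL
  agg
}

fmt1 <- function(x) round(x, 1)

#' Baseline characteristics table
#'
#' Demographic and clinical summaries per line-number group among eligible
#' lines: age at index (mean, SD, median, and the <65 / 65-69 / 70-74 / >=75
#' bins), sex, configurable comorbidity flags over the 365-day pre-index
#' window, time from first observed diagnosis to index (months), and
#' follow-up time (months). All counts pass through the masking chokepoint.
#'
#' @param eligibility Result of [build_cohort()].
#' @param bundle A `cl_bundle`.
#' @param codes A [code_sets()] (supplies `comorbidity_code_map`).
#' @param config A [study_config()].
#' @return Long data frame: `lot_number`, `variable`, `statistic`, `value`,
#'   `display`.
#' @export
characteristics_table <- function(eligibility, bundle, codes = code_sets(),
                                  config = study_config()) {
  el <- eligibility[eligibility$eligible, , drop = FALSE]
  dg <- first_dlbcl_diagnosis(bundle, codes)
  med_split <- split(bundle$medical, bundle$medical$patient_id)
  rows <- list()
  put <- function(lot, var, stat, value, count = NA_integer_) {
    rows[[length(rows) + 1]] <<- data.frame(
      lot_number = lot, variable = var, statistic = stat,
      value = value,
      display = if (!is.na(count)) render_count(count, config$mask_threshold)
                else as.character(value),
      stringsAsFactors = FALSE)
  }
  for (lot in sort(unique(el$lot_number))) {
    g <- el[el$lot_number == lot, ]
    n <- nrow(g)
    put(lot, "n", "count", n, n)
    by <- bundle$patients$birth_year[match(g$patient_id, bundle$patients$patient_id)]
    age <- as.integer(format(g$index_date, "%Y")) - by
    put(lot, "age", "mean", fmt1(mean(age)))
    put(lot, "age", "sd", fmt1(sd(age)))
    put(lot, "age", "median", fmt1(median(age)))
    bins <- cut(age, c(-Inf, 64, 69, 74, Inf),
                labels = c("<65", "65-69", "70-74", ">=75"))
    for (b in levels(bins)) {
      nb <- sum(bins == b)
      put(lot, "age_category", b, fmt1(100 * nb / n), nb)
    }
    sex <- bundle$patients$sex[match(g$patient_id, bundle$patients$patient_id)]
    for (s in c("M", "F")) {
      ns <- sum(sex == s, na.rm = TRUE)
      put(lot, "sex", s, fmt1(100 * ns / n), ns)
    }
    for (cm in names(codes$comorbidity_code_map)) {
      prefixes <- codes$comorbidity_code_map[[cm]]
      flag <- vapply(seq_len(n), function(i) {
        md <- med_split[[g$patient_id[i]]]
        if (is.null(md)) return(FALSE)
        md <- md[md$service_date >= g$index_date[i] - 365L &
                   md$service_date <= g$index_date[i], ]
        nrow(md) > 0 && any(vapply(split_codes(md$diagnosis_codes),
                                   function(v) any(code_matches(v, prefixes)),
                                   logical(1)))
      }, logical(1))
      put(lot, "comorbidity", cm, fmt1(100 * sum(flag) / n), sum(flag))
    }
    dxd <- dg$diagnosis_date[match(g$patient_id, dg$patient_id)]
    t_dx <- as.numeric(g$index_date - dxd) / config$month_length_days
    put(lot, "months_from_diagnosis_to_index", "mean", fmt1(mean(t_dx, na.rm = TRUE)))
    put(lot, "months_from_diagnosis_to_index", "median", fmt1(median(t_dx, na.rm = TRUE)))
    fu <- as.numeric(g$follow_up_end - g$index_date) / config$month_length_days
    put(lot, "followup_months", "mean", fmt1(mean(fu)))
    put(lot, "followup_months", "median", fmt1(median(fu)))
  }
  out <- as.data.frame(data.table::rbindlist(rows))
  out
}

#' Bridging and post-CAR T treatment report
#'
#' Summarizes the peri-CAR T experience: apheresis-to-infusion interval
#' statistics among patients with an apheresis claim; bridging regimen and
#' drug-class frequencies (denominator: patients with an apheresis claim,
#' both filtered to >= 5% via [most_common()]); and the next line after
#' CAR T, restricted to patients with continuous enrollment from the CAR T
#' index through at least 29 days after the next line's start, with the
#' distinct-regimen count. Corticosteroids are excluded throughout.
#'
#' @param labeled_lots Line table with `regimen` ([classify_lots()]).
#' @param events Annotated event ledger from [derive_all_lots()].
#' @param bundle A `cl_bundle`.
#' @param dict A drug dictionary.
#' @param config A [study_config()].
#' @return A list of data frames: `summary`, `apheresis_days`,
#'   `bridging_regimens`, `bridging_classes`, `post_cart_regimens`,
#'   `post_cart_classes`.
#' @export
peri_cart_report <- function(labeled_lots, events, bundle,
                             dict = default_drug_dictionary(),
                             config = study_config()) {
  cart <- labeled_lots[labeled_lots$contains_cart, , drop = FALSE]
  n_cart <- length(unique(cart$patient_id))
  aph_events <- events[events$kind == "apheresis", , drop = FALSE]
  aph_split <- split(aph_events$event_date, aph_events$patient_id)
  br_events <- events[!is.na(events$annotation) &
                        events$annotation == "bridging" &
                        events$drug_class != "corticosteroid", , drop = FALSE]
  br_split <- split(br_events, br_events$patient_id)

  # Apheresis-to-infusion interval per CAR T line.
  aph_days <- rep(NA_real_, nrow(cart))
  for (i in seq_len(nrow(cart))) {
    aph <- aph_split[[cart$patient_id[i]]]
    aph <- aph[aph <= cart$index_date[i]]
    if (length(aph)) aph_days[i] <- as.numeric(cart$index_date[i] - max(aph))
  }
  has_aph <- !is.na(aph_days)
  n_aph <- sum(has_aph)

  # Bridging drugs per CAR T line (corticosteroids excluded).
  bridge_sets <- lapply(seq_len(nrow(cart)), function(i) {
    pe <- br_split[[cart$patient_id[i]]]
    if (is.null(pe)) return(character(0))
    unique(pe$drug_name[pe$lot_number == cart$lot_number[i]])
  })
  bridged <- lengths(bridge_sets) > 0
  regimen_key <- vapply(bridge_sets, function(d) paste(sort(d), collapse = " + "),
                        character(1))
  br_counts <- table(regimen_key[bridged & has_aph])
  br_reg <- if (n_aph > 0 && length(br_counts)) {
    most_common(setNames(as.integer(br_counts), names(br_counts)),
                n_aph, config$most_common_fraction)
  } else data.frame(label = character(0), n = integer(0), percent = numeric(0))
  cls_list <- lapply(bridge_sets[bridged & has_aph], drug_class_profile, dict = dict)
  cls_counts <- table(unlist(cls_list))
  br_cls <- if (n_aph > 0 && length(cls_counts)) {
    most_common(setNames(as.integer(cls_counts), names(cls_counts)),
                n_aph, config$most_common_fraction)
  } else data.frame(label = character(0), n = integer(0), percent = numeric(0))

  # Post-CAR T next line, with the continuous-enrollment restriction.
  post <- list()
  for (i in seq_len(nrow(cart))) {
    nxt <- labeled_lots[labeled_lots$patient_id == cart$patient_id[i] &
                          labeled_lots$lot_number == cart$lot_number[i] + 1L, ]
    if (!nrow(nxt)) next
    span <- covering_span(bundle, cart$patient_id[i], cart$index_date[i])
    if (is.null(span) ||
        span$end_date < nxt$start_date[1] + config$post_index_enrollment_days) next
    post[[length(post) + 1]] <- nxt[1, ]
  }
  post <- if (length(post)) as.data.frame(data.table::rbindlist(post)) else NULL
  n_post <- if (is.null(post)) 0L else nrow(post)
  post_counts <- if (n_post) table(as.character(post$regimen)) else integer(0)
  post_reg <- if (n_post && length(post_counts)) {
    most_common(setNames(as.integer(post_counts), names(post_counts)),
                n_post, config$most_common_fraction)
  } else data.frame(label = character(0), n = integer(0), percent = numeric(0))
  post_cls_counts <- if (n_post) {
    table(unlist(lapply(strsplit(post$core_drugs, ";", fixed = TRUE),
                        drug_class_profile, dict = dict)))
  } else integer(0)
  post_cls <- if (n_post && length(post_cls_counts)) {
    most_common(setNames(as.integer(post_cls_counts), names(post_cls_counts)),
                n_post, config$most_common_fraction)
  } else data.frame(label = character(0), n = integer(0), percent = numeric(0))

  mask <- function(df) {
    if (nrow(df)) df$display <- render_count(df$n, config$mask_threshold)
    else df$display <- character(0)
    df
  }
  summary <- data.frame(
    measure = c("cart_patients", "apheresis_patients", "bridged_patients",
                "post_cart_patients", "post_cart_distinct_regimens",
                "apheresis_to_infusion_mean_days",
                "apheresis_to_infusion_median_days"),
    value = c(n_cart, n_aph, sum(bridged & has_aph), n_post,
              if (n_post) length(unique(as.character(post$regimen))) else 0L,
              fmt1(mean(aph_days[has_aph])), fmt1(median(aph_days[has_aph]))),
    stringsAsFactors = FALSE)
  summary$display <- c(render_count(summary$value[1:5], config$mask_threshold),
                       as.character(summary$value[6:7]))
  list(summary = summary,
       apheresis_days = data.frame(days = aph_days[has_aph]),
       bridging_regimens = mask(br_reg),
       bridging_classes = mask(br_cls),
       post_cart_regimens = mask(post_reg),
       post_cart_classes = mask(post_cls))
}

#' Write report tables with masking enforced
#'
#' Writes each report data frame as CSV under `dir`, dropping raw count
#' columns so that every emitted count passes through the masking
#' chokepoint (the `display` column).
#'
#' @param reports Named list of data frames (nested lists are flattened with
#'   dotted names).
#' @param dir Output directory.
#' @return Character vector of files written, invisibly.
#' @export
write_report_tables <- function(reports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- list()
  flatten <- function(x, prefix = "") {
    for (nm in names(x)) {
      key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
      if (is.data.frame(x[[nm]])) flat[[key]] <<- x[[nm]]
      else if (is.list(x[[nm]])) flatten(x[[nm]], key)
    }
  }
  flatten(reports)
  files <- character(0)
  for (nm in names(flat)) {
    df <- flat[[nm]]
    drop <- intersect(c("n", "raw_count", "value"), names(df))
    if ("display" %in% names(df)) df <- df[, setdiff(names(df), drop), drop = FALSE]
    for (col in names(df)) if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]])
    f <- file.path(dir, paste0(nm, ".csv"))
    write.csv(df, f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
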