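#' Regimen hierarchy levels
#'
#' The 12 regimen categories in hierarchy order. Classification scans this
#' order and returns the first match, so earlier categories dominate (a
#' regimen containing pola + R-CHP components is `pola_rchp` even though it
#' also satisfies the R-CHOP pattern).
#'
#' @return Character vector of the 12 labels in precedence order.
#' @export
regimen_levels <- function() {
  c("cart", "sct", "pola_rchp", "pola_other", "rchop", "tafa_other",
    "r_mono", "chemotherapy", "r_squared", "other_targeted",
    "immunotherapy", "chemoimmunotherapy")
}

# Ordered rule list; each rule sees the non-corticosteroid drug name set,
# their classes, and the modality flags. First TRUE wins.
regimen_rules <- function() {
  list(
    cart = function(d, cls, sct, cart) cart,
    sct = function(d, cls, sct, cart) sct,
    pola_rchp = function(d, cls, sct, cart) {
      all(c("polatuzumab vedotin", "rituximab", "cyclophosphamide",
            "doxorubicin") %in% d)
    },
    pola_other = function(d, cls, sct, cart) "polatuzumab vedotin" %in% d,
    rchop = function(d, cls, sct, cart) {
      all(c("rituximab", "cyclophosphamide", "doxorubicin", "vincristine") %in% d)
    },
    tafa_other = function(d, cls, sct, cart) "tafasitamab" %in% d,
    r_mono = function(d, cls, sct, cart) identical(d, "rituximab"),
    chemotherapy = function(d, cls, sct, cart) {
      length(d) > 0 && all(cls == "chemotherapy")
    },
    r_squared = function(d, cls, sct, cart) {
      all(c("rituximab", "lenalidomide") %in% d)
    },
    other_targeted = function(d, cls, sct, cart) {
      any(c("lenalidomide", "ibrutinib", "venetoclax", "selinexor") %in% d)
    },
    immunotherapy = function(d, cls, sct, cart) !any(cls == "chemotherapy"),
    chemoimmunotherapy = function(d, cls, sct, cart) TRUE
  )
}

#' Classify a line of therapy into the 12-category regimen hierarchy
#'
#' First-match classification in hierarchy order: (1) CAR T; (2) SCT;
#' (3) pola + R-CHP (at least pola, rituximab, cyclophosphamide,
#' doxorubicin); (4) pola +/- other; (5) R-CHOP (at least rituximab,
#' cyclophosphamide, doxorubicin, vincristine); (6) tafa +/- other;
#' (7) rituximab monotherapy; (8) chemotherapy (all drugs chemotherapy
#' class); (9) R-squared (at least rituximab and lenalidomide); (10) other
#' targeted (contains lenalidomide, ibrutinib, venetoclax, or selinexor);
#' (11) immunotherapy (contains no chemotherapy-class drug);
#' (12) chemoimmunotherapy (everything else). Corticosteroids are removed
#' before any rule is evaluated.
#'
#' @param lot A line: list or one-row data.frame with `core_drugs`
#'   (character vector or semicolon-packed string), `contains_sct`,
#'   `contains_cart`.
#' @param dict A drug dictionary (supplies drug classes).
#' @return A single label, a factor level of [regimen_levels()].
#' @export
classify_regimen <- function(lot, dict) {
  drugs <- lot$core_drugs
  if (is.character(drugs) && length(drugs) == 1) {
    drugs <- strsplit(drugs, ";", fixed = TRUE)[[1]]
  }
  drugs <- sort(unique(drugs[nzchar(drugs)]))
  cls <- dict$drug_class[match(drugs, dict$drug_name)]
  cls[is.na(cls)] <- "unknown"
  keep <- cls != "corticosteroid"
  drugs <- drugs[keep]
  cls <- cls[keep]
  sct <- isTRUE(lot$contains_sct)
  cart <- isTRUE(lot$contains_cart)
  if (!length(drugs) && !sct && !cart) {
    cl_stop("cannot classify a line with no drugs and no modality",
            "cl_classification_error")
  }
  rules <- regimen_rules()
  for (nm in names(rules)) {
    if (isTRUE(rules[[nm]](drugs, cls, sct, cart))) {
      return(factor(nm, levels = regimen_levels()))
    }
  }
  factor("chemoimmunotherapy", levels = regimen_levels()) # unreachable
}

#' Classify every line in a line table
#'
#' @param lots Line table from [derive_all_lots()].
#' @param dict A drug dictionary.
#' @return `lots` with a `regimen` factor column appended.
#' @export
classify_lots <- function(lots, dict) {
  lots$regimen <- factor(
    vapply(seq_len(nrow(lots)),
           function(i) as.character(classify_regimen(lots[i, ], dict)),
           character(1)),
    levels = regimen_levels()
  )
  lots
}

#' Reporting drug-class profile of a drug set
#'
#' Maps a regimen's drugs to the reporting classes used in the bridging and
#' post-CAR T tables (monoclonal antibody, chemotherapy, antibody-drug
#' conjugate, bispecific antibody, other targeted, CAR T product). Each class
#' appears at most once per input set (a patient counts once per class);
#' corticosteroids are excluded; unknown drugs are reported under `unknown`
#' with a warning.
#'
#' @param drugs Character vector of drug names (or semicolon-packed string).
#' @param dict A drug dictionary.
#' @return Character vector of distinct reporting classes, sorted.
#' @export
drug_class_profile <- function(drugs, dict) {
  if (is.character(drugs) && length(drugs) == 1 && grepl(";", drugs)) {
    drugs <- strsplit(drugs, ";", fixed = TRUE)[[1]]
  }
  drugs <- unique(drugs[nzchar(drugs)])
  if (!length(drugs)) return(character(0))
  cls <- dict$drug_class[match(drugs, dict$drug_name)]
  if (anyNA(cls)) {
    warning(sprintf("unknown drug(s): %s",
                    paste(drugs[is.na(cls)], collapse = ", ")), call. = FALSE)
    cls[is.na(cls)] <- "unknown"
  }
  sort(unique(cls[cls != "corticosteroid"]))
}

#' Filter labeled counts to the "most common" items
#'
#' Keeps labels whose frequency is at least `threshold_fraction` of the
#' denominator (>= 5% by default, inclusive), sorted by descending count and
#' then label; ties are stable.
#'
#' @param counts Named integer vector (label -> count).
#' @param denominator Positive count base.
#' @param threshold_fraction Minimum fraction, inclusive (default 0.05).
#' @return Data frame with `label`, `n`, `percent`, filtered and sorted.
#' @export
most_common <- function(counts, denominator, threshold_fraction = 0.05) {
  if (denominator <= 0) cl_stop("denominator must be positive", "cl_contract_error")
  if (!length(counts)) {
    return(data.frame(label = character(0), n = integer(0), percent = numeric(0)))
  }
  keep <- counts / denominator >= threshold_fraction
  counts <- counts[keep]
  ord <- order(-counts, names(counts))
  data.frame(label = names(counts)[ord],
             n = as.integer(counts[ord]),
             percent = round(100 * as.numeric(counts[ord]) / denominator, 1),
             stringsAsFactors = FALSE)
}

#' CAR T brand for reporting
#'
#' Resolves a CAR T line's product to one of the four reporting bins:
#' the three named products or `"unspecified"` (infusion coded without an
#' identifiable product).
#'
#' @param cart_product Product drug name or `NA`.
#' @return One of `"axicabtagene ciloleucel"`, `"lisocabtagene maraleucel"`,
#'   `"tisagenlecleucel"`, `"unspecified"`.
#' @export
cart_brand <- function(cart_product) {
  known <- c("axicabtagene ciloleucel", "lisocabtagene maraleucel",
             "tisagenlecleucel")
  ifelse(!is.na(cart_product) & cart_product %in% known,
         cart_product, "unspecified")
}
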