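dict <- default_drug_dictionary()

lab <- function(drugs, sct = FALSE, cart = FALSE) {
  as.character(classify_regimen(list(core_drugs = drugs, contains_sct = sct,
                                     contains_cart = cart), dict))
}

test_that("hierarchy traces match the 12-group definitions", {
  expect_equal(lab(c("polatuzumab vedotin", "rituximab", "cyclophosphamide",
                     "doxorubicin", "prednisone")), "pola_rchp")
  # earlier category wins even when a later pattern also matches
  expect_equal(lab(c("rituximab", "cyclophosphamide", "doxorubicin",
                     "vincristine", "polatuzumab vedotin")), "pola_rchp")
  expect_equal(lab(c("polatuzumab vedotin", "bendamustine", "rituximab")),
               "pola_other")
  expect_equal(lab(c("rituximab", "cyclophosphamide", "doxorubicin",
                     "vincristine")), "rchop")
  expect_equal(lab(c("tafasitamab", "lenalidomide")), "tafa_other")
  expect_equal(lab("rituximab"), "r_mono")
  expect_equal(lab(c("gemcitabine", "oxaliplatin")), "chemotherapy")
  expect_equal(lab(c("rituximab", "lenalidomide")), "r_squared")
  expect_equal(lab("ibrutinib"), "other_targeted")
  expect_equal(lab("epcoritamab"), "immunotherapy")
  expect_equal(lab(c("rituximab", "bendamustine")), "chemoimmunotherapy")
  # modality flags outrank any drug pattern
  expect_equal(lab(c("rituximab", "cyclophosphamide"), sct = TRUE), "sct")
  expect_equal(lab(character(0), cart = TRUE), "cart")
  expect_equal(lab(c("polatuzumab vedotin", "rituximab"), cart = TRUE), "cart")
  expect_error(classify_regimen(list(core_drugs = character(0),
                                     contains_sct = FALSE,
                                     contains_cart = FALSE), dict),
               class = "cl_classification_error")
})

# Independent restatement of the hierarchy used to cross-check first-match
# behavior during fuzzing.
independent_matches <- function(drugs, sct, cart) {
  cls <- dict$drug_class[match(drugs, dict$drug_name)]
  keep <- !is.na(cls) & cls != "corticosteroid"
  drugs <- drugs[keep]; cls <- cls[keep]
  has <- function(...) all(c(...) %in% drugs)
  c(cart = cart,
    sct = sct,
    pola_rchp = has("polatuzumab vedotin", "rituximab", "cyclophosphamide",
                    "doxorubicin"),
    pola_other = has("polatuzumab vedotin"),
    rchop = has("rituximab", "cyclophosphamide", "doxorubicin", "vincristine"),
    tafa_other = has("tafasitamab"),
    r_mono = length(drugs) == 1 && drugs == "rituximab",
    chemotherapy = length(drugs) > 0 && all(cls == "chemotherapy"),
    r_squared = has("rituximab", "lenalidomide"),
    other_targeted = any(c("lenalidomide", "ibrutinib", "venetoclax",
                           "selinexor") %in% drugs),
    immunotherapy = !any(cls == "chemotherapy"),
    chemoimmunotherapy = TRUE)
}

test_that("fuzzing: exactly one label, first-match order, corticosteroid invariance", {
  set.seed(404)
  pool <- dict$drug_name[dict$dlbcl_directed & dict$drug_class != "cart_product"]
  steroids <- dict$drug_name[dict$drug_class == "corticosteroid"]
  non_ster <- setdiff(pool, steroids)
  for (k in 1:2000) {
    drugs <- sample(non_ster, sample(1:5, 1))
    sct <- runif(1) < 0.1
    cart <- runif(1) < 0.1
    got <- lab(drugs, sct, cart)
    expect_true(got %in% regimen_levels())
    m <- independent_matches(drugs, sct, cart)
    expect_equal(got, names(m)[which(m)[1]])
    # corticosteroids never change the label
    expect_equal(lab(c(drugs, sample(steroids, 1)), sct, cart), got)
  }
})

test_that("adding a drug never demotes a superset-rule label", {
  set.seed(505)
  superset <- c("cart", "sct", "pola_rchp", "pola_other", "rchop",
                "tafa_other", "r_squared", "other_targeted")
  pool <- dict$drug_name[dict$dlbcl_directed &
                           !dict$drug_class %in% c("cart_product",
                                                   "corticosteroid")]
  n_checked <- 0
  for (k in 1:500) {
    drugs <- sample(pool, sample(1:4, 1))
    l1 <- lab(drugs)
    if (!l1 %in% superset) next
    l2 <- lab(union(drugs, sample(pool, 1)))
    if (!l2 %in% superset) next
    expect_lte(match(l2, regimen_levels()), match(l1, regimen_levels()))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 50)
})

test_that("drug class profiles count each class once and drop corticosteroids", {
  expect_equal(drug_class_profile(c("polatuzumab vedotin", "rituximab"), dict),
               c("antibody_drug_conjugate", "monoclonal_antibody"))
  expect_equal(drug_class_profile("ibrutinib", dict), "targeted_other")
  expect_equal(drug_class_profile(c("rituximab", "prednisone"), dict),
               "monoclonal_antibody")
  expect_equal(drug_class_profile(character(0), dict), character(0))
  expect_warning(p <- drug_class_profile("notadrug", dict), "unknown")
  expect_equal(p, "unknown")
})

test_that("most_common applies the inclusive >=5% threshold with stable ordering", {
  out <- most_common(c(A = 13, B = 4), 100, 0.05)
  expect_equal(out$label, "A")
  expect_equal(out$percent, 13)
  out5 <- most_common(c(A = 5), 100, 0.05)
  expect_equal(out5$label, "A") # exactly 5% is included
  expect_equal(nrow(most_common(integer(0), 100, 0.05)), 0)
  # descending count, label breaks ties
  tied <- most_common(c(B = 7, A = 7, C = 9), 50, 0.05)
  expect_equal(tied$label, c("C", "A", "B"))
  expect_error(most_common(c(A = 1), 0), class = "cl_contract_error")
})

test_that("CAR T brands resolve to the four reporting bins", {
  expect_equal(cart_brand(c("axicabtagene ciloleucel", NA, "something")),
               c("axicabtagene ciloleucel", "unspecified", "unspecified"))
})
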