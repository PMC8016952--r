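# Curation: activity classification, TI concatenation, PI decoy sampling.

rec <- function(...) {
  rows <- list(...)
  data.frame(compound_id = "c1",
             assay_type = vapply(rows, `[[`, character(1), 1),
             value = as.numeric(vapply(rows, `[[`, character(1), 2)),
             units = vapply(rows, `[[`, character(1), 3),
             stringsAsFactors = FALSE)
}

test_that("classify_activity takes the minimum standardised concentration", {
  expect_identical(classify_activity(rec(c("IC50", "5", "uM"),
                                         c("Kd", "50", "uM"))), "active")
  # the 10 uM threshold is inclusive
  expect_identical(classify_activity(rec(c("EC50", "10", "uM"))), "active")
  expect_identical(classify_activity(rec(c("IC50", "10.1", "uM"))), "inactive")
  # nanomolar records are standardised before comparison
  expect_identical(classify_activity(rec(c("Kd", "9000", "nM"))), "active")
  expect_identical(classify_activity(rec(c("Kd", "90000", "nM"))), "inactive")
})

test_that("percent-inhibition records use the separate configurable rule", {
  expect_identical(classify_activity(rec(c("InhibitionPct", "62", "percent"))),
                   "active")
  expect_identical(classify_activity(rec(c("InhibitionPct", "35", "percent"))),
                   "inactive")
  expect_identical(
    classify_activity(rec(c("InhibitionPct", "35", "percent")),
                      inhibition_threshold = 30), "active")
  # inactive by concentration but active by inhibition -> active
  expect_identical(classify_activity(rec(c("IC50", "40", "uM"),
                                         c("InhibitionPct", "80", "percent"))),
                   "active")
})

test_that("classify_activity flags unusable input and empty records", {
  expect_identical(classify_activity(rec(c("IC50", "5", "uM"))[0, ]),
                   NA_character_)
  expect_error(classify_activity(rec(c("IC50", "50", "percent"))),
               "not convertible")
  expect_error(classify_activity(rbind(rec(c("IC50", "5", "uM")),
                                       data.frame(compound_id = "c2",
                                                  assay_type = "IC50",
                                                  value = 1, units = "uM"))),
               "one compound_id")
})

test_that("classify_activity is monotone in concentration", {
  ppilbvs:::with_seed(5, {
    for (i in 1:50) {
      v <- stats::runif(3, 0.1, 100)
      base <- rec(c("IC50", v[1], "uM"), c("EC50", v[2], "uM"),
                  c("Kd", v[3], "uM"))
      before <- classify_activity(base)
      lowered <- base
      j <- sample(3, 1)
      lowered$value[j] <- lowered$value[j] * stats::runif(1)
      after <- classify_activity(lowered)
      if (before == "active") expect_identical(after, "active")
    }
  })
})

test_that("build_ti_dataset concatenates and rejects class overlap", {
  act <- tiny_compounds(c("CCO", "CCN", "CCC(=O)O"), "a")
  ina <- tiny_compounds(c("CCCl", "CCBr"), "i")
  ti <- build_ti_dataset(act, ina)
  expect_equal(nrow(ti), 5)
  expect_setequal(unique(ti$label_basis), "true_measured")
  expect_equal(sum(ti$label == "active"), 3)

  # same structure in both classes (different SMILES writing) is rejected
  ina_bad <- tiny_compounds(c("OCC", "CCBr"), "i")
  expect_error(build_ti_dataset(act, ina_bad), "both classes")
  expect_error(build_ti_dataset(act, ina[0, ]), "non-empty")
})

test_that("build_pi_dataset balances actives with seeded vendor decoys", {
  u <- small_universe()
  pi <- build_pi_dataset(u$actives, u$vendor_pool, seed = 11)
  expect_equal(sum(pi$label == "active"), nrow(u$actives))
  expect_equal(sum(pi$label == "inactive"), nrow(u$actives))
  expect_setequal(pi$label_basis[pi$label == "inactive"], "putative")
  expect_false(any(duplicated(pi$canonical_key)))

  # determinism under the same seed; a different seed changes the draw
  pi2 <- build_pi_dataset(u$actives, u$vendor_pool, seed = 11)
  expect_identical(pi, pi2)
  pi3 <- build_pi_dataset(u$actives, u$vendor_pool, seed = 12)
  expect_false(identical(pi$compound_id, pi3$compound_id))
})

test_that("vendor compounds identical to an active are never sampled", {
  act <- tiny_compounds(c("CCO", "CC(=O)O"), "a")
  # vendor pool: one disguised copy of an active plus exactly one other
  ven <- tiny_compounds(c("OCC", "CCCl", "CCBr"), "v", source = "vendor")
  for (s in 1:10) {
    pi <- build_pi_dataset(act, ven, seed = s)
    decoys <- pi[pi$label_basis == "putative", ]
    expect_false(any(decoys$canonical_key %in% act$canonical_key))
  }
  # pool too small once the duplicate is excluded
  expect_error(build_pi_dataset(act, ven[1:2, ], seed = 1), "insufficient")
})

test_that("molecular-weight cap filters actives before balancing", {
  u <- small_universe()
  mw <- featurize_set(u$actives$smiles, u$actives$compound_id)$props$mw
  cap <- stats::median(mw)
  pi <- build_pi_dataset(u$actives, u$vendor_pool, mw_cap = cap, seed = 2)
  expect_equal(nrow(pi), 2 * sum(mw < cap))
})
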