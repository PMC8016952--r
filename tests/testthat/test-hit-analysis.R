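# Hit analysis: inhibition formula, hit calling with counter triage,
# per-arm rates, extrapolation, substructure and novelty statistics.

hit_fixture <- function() {
  as_assay_results(system.file("extdata", "keap1_hit_table.csv",
                               package = "ppilbvs"))
}

test_that("TR-FRET inhibition formula hits its anchors and is linear", {
  expect_equal(trfret_inhibition(10000, 10000, 1000), 0)
  expect_equal(trfret_inhibition(1000, 10000, 1000), 100)
  expect_equal(trfret_inhibition(5500, 10000, 1000), 50)  # midpoint
  # below-baseline signal exceeds 100 under noise, above-baseline goes < 0
  expect_gt(trfret_inhibition(500, 10000, 1000), 100)
  expect_lt(trfret_inhibition(11000, 10000, 1000), 0)
  expect_error(trfret_inhibition(1, 5, 5), "equal")
})

test_that("NI tokens parse as provenance-preserving zeros", {
  res <- hit_fixture()
  expect_equal(nrow(res), 16)
  expect_true(res$counter_ni[res$compound_id == "hit02"])
  expect_equal(res$counter_inhibition_pct[res$compound_id == "hit02"], 0)
  expect_false(res$counter_ni[res$compound_id == "hit01"])
  expect_error(as_assay_results(data.frame(compound_id = "x",
                                           primary_inhibition_pct = "oops",
                                           counter_inhibition_pct = "NI")),
               "non-numeric")
})

test_that("hit calling applies the strict primary and counter thresholds", {
  flags <- call_hits(hit_fixture())
  # strongest compound: clear primary hit but a non-specific inhibitor
  h1 <- flags[flags$compound_id == "hit01", ]
  expect_true(h1$primary_hit)
  expect_false(h1$specific_hit)
  # weakest listed compound: 15.2 > 15 with NI counter -> specific
  h16 <- flags[flags$compound_id == "hit16", ]
  expect_true(h16$primary_hit)
  expect_true(h16$specific_hit)
  expect_equal(sum(flags$primary_hit), 16)
  expect_equal(sum(flags$specific_hit), 15)

  # boundary: exactly at the threshold is not a hit
  bd <- call_hits(data.frame(compound_id = "b",
                             primary_inhibition_pct = 15.0, primary_ni = FALSE,
                             counter_inhibition_pct = 0, counter_ni = TRUE))
  expect_false(bd$primary_hit)
  # specific hits are a subset of primary hits
  expect_true(all(!flags$specific_hit | flags$primary_hit))
})

test_that("arm hit rates include the overlap arm in both model denominators", {
  sel <- structure(data.frame(
    compound_id = sprintf("c%02d", 1:20),
    arm = rep(c("overlap", "pi_only", "ti_only", "random"), each = 5),
    stringsAsFactors = FALSE
  ), class = c("lbvs_selection", "data.frame"))
  flags <- data.frame(
    compound_id = sprintf("c%02d", 1:20),
    primary_hit = rep(FALSE, 20), specific_hit = rep(FALSE, 20)
  )
  flags$primary_hit[c(1, 6, 16)] <- TRUE          # overlap, pi_only, random
  flags$specific_hit[c(1, 16)] <- TRUE
  rates <- arm_hit_rates(flags, sel)
  expect_equal(rates$n, c(10, 10, 5))
  # the overlap hit counts for both models
  expect_equal(rates$primary_hits, c(2, 1, 1))
  expect_equal(rates$primary_rate, c(0.2, 0.1, 0.2))
  expect_equal(rates$specific_hits, c(1, 1, 1))

  # a flagged compound without an arm is an error
  orphan <- rbind(flags, data.frame(compound_id = "zz", primary_hit = TRUE,
                                    specific_hit = FALSE))
  expect_error(arm_hit_rates(orphan, sel), "without a selection arm")

  # empty arm -> undefined rate
  sel_no_rand <- structure(sel[sel$arm != "random", ],
                           class = c("lbvs_selection", "data.frame"))
  r2 <- arm_hit_rates(flags[1:15, ], sel_no_rand)
  expect_true(is.na(r2$primary_rate[r2$arm == "random"]))

  # all compounds hitting gives 100% everywhere
  flags$primary_hit <- TRUE; flags$specific_hit <- TRUE
  r3 <- arm_hit_rates(flags, sel)
  expect_equal(r3$primary_rate, c(1, 1, 1))
})

test_that("overlap hits count once in the union and twice across model arms", {
  sel <- structure(data.frame(
    compound_id = sprintf("c%02d", 1:16),
    arm = rep(c("overlap", "pi_only", "ti_only", "random"), each = 4),
    stringsAsFactors = FALSE
  ), class = c("lbvs_selection", "data.frame"))
  ppilbvs:::with_seed(13, {
    for (i in 1:20) {
      hit <- stats::runif(16) < 0.4
      flags <- data.frame(compound_id = sel$compound_id,
                          primary_hit = hit, specific_hit = hit)
      r <- arm_hit_rates(flags, sel)
      arm <- sel$arm
      # union accounting: every hit appears exactly once over the arms
      expect_equal(sum(hit), sum(hit[arm == "overlap"]) +
                     sum(hit[arm == "pi_only"]) + sum(hit[arm == "ti_only"]) +
                     sum(hit[arm == "random"]))
      # overlap hits appear in both model numerators
      expect_equal(sum(r$primary_hits[r$arm %in% c("pi", "ti")]) +
                     r$primary_hits[r$arm == "random"],
                   sum(hit) + sum(hit[arm == "overlap"]))
    }
  })
})

test_that("specific planted hits are recovered at low noise and strong effect", {
  u <- generate_universe(universe_config(
    n_known_actives = 15, n_known_inactives = 15, n_vendor_pool = 60,
    n_library = 200, base_hit_rate = 0.3, enrichment_factor = 1,
    similarity_cap_library_to_actives = 1, assay_noise_sd = 2,
    nonspecific_fraction = 0.2, hit_effect_mean = 80, hit_effect_sd = 5,
    seed = 404))
  ids <- u$library$compound_id
  flags <- call_hits(simulate_assay(u, ids))
  planted_specific <- u$latent_hit_labels[ids] & !u$nonspecific[ids]
  recovered <- flags$specific_hit & planted_specific
  expect_gt(sum(planted_specific), 20)     # the check has something to find
  expect_gte(sum(recovered) / sum(planted_specific), 0.9)
})

test_that("extrapolation arithmetic and its monotonicity", {
  # nothing untested collapses to the observed rate
  e0 <- extrapolate_hit_rate(10, 500, 500, 0.25)
  expect_equal(e0$possible_hits, 10)
  expect_equal(e0$possible_hit_rate, 10 / 500)
  # zero reference rate adds nothing
  expect_equal(extrapolate_hit_rate(7, 100, 900, 0)$possible_hits, 7)
  # monotone increasing in the reference rate
  rates <- seq(0, 1, by = 0.1)
  vals <- vapply(rates, function(r)
    extrapolate_hit_rate(16, 620, 2684, r)$possible_hits, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(extrapolate_hit_rate(1, 100, 50, 0.1), "n_assayed")
})

test_that("substructure hit rate counts SMARTS matches among tested", {
  tested <- tiny_compounds(
    c("CC(=O)Nc1ccccc1C(=O)N1CCC(C(=O)O)CC1",   # has the amide-piperidine acid
      "COc1ccccc1C(=O)N1CCC(C(=O)O)CC1",        # has it
      "c1ccccc1",                               # does not
      "CCNC(=O)C1CCN(C(=O)c2ccccc2)CC1"),       # amide in place of the acid
    "t", source = "library")
  flags <- data.frame(compound_id = tested$compound_id,
                      primary_hit = c(TRUE, FALSE, TRUE, FALSE),
                      specific_hit = c(TRUE, FALSE, FALSE, FALSE))
  blk <- substructure_hit_rate("C(=O)N1CCC(CC1)C(=O)O", tested, flags)
  expect_equal(blk$n_tested_with_pattern, 2)
  expect_equal(blk$n_hits_with_pattern, 1)
  expect_equal(blk$rate, 0.5)

  # nothing matches -> undefined rate, not an error
  none <- substructure_hit_rate("[Se]", tested, flags)
  expect_equal(none$n_tested_with_pattern, 0)
  expect_true(is.na(none$rate))

  # the full structure of one hit matches itself only
  self <- substructure_hit_rate("c1ccccc1", tested[3, , drop = FALSE],
                                flags[3, , drop = FALSE])
  expect_equal(self$rate, 1.0)
})

test_that("novelty table reports nearest-known similarity per hit", {
  known <- tiny_compounds(c("CC(=O)Oc1ccccc1C(=O)O", "CN1CCC(O)CC1"), "k")
  hits <- tiny_compounds(c("CC(=O)Oc1ccccc1C(=O)O", "CCCCCCCCC"), "h",
                         source = "library")
  nv <- novelty_table(hits, known)
  expect_equal(nv$nearest_similarity[1], 1.0)    # identical to a known
  expect_lt(nv$nearest_similarity[2], 0.3)
  expect_identical(nv$nearest_known_id[1], "k01")
  expect_error(novelty_table(hits, known[0, ]), "empty")
})
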