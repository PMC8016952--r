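# The synthetic universe: determinism, structural invariants, planted
# statistics and the simulated TR-FRET assay.

test_that("the same seed reproduces the universe byte-for-byte", {
  cfg <- universe_config(n_known_actives = 12, n_known_inactives = 12,
                         n_vendor_pool = 40, n_library = 80,
                         similarity_cap_library_to_actives = 1, seed = 1)
  u1 <- generate_universe(cfg)
  u2 <- generate_universe(cfg)
  for (set in c("actives", "true_inactives", "vendor_pool", "library")) {
    expect_identical(u1[[set]]$smiles, u2[[set]]$smiles)
  }
  expect_identical(u1$latent_hit_labels, u2$latent_hit_labels)
  expect_identical(u1$library$available, u2$library$available)
  # a different seed gives a different universe
  u3 <- generate_universe(universe_config(
    n_known_actives = 12, n_known_inactives = 12, n_vendor_pool = 40,
    n_library = 80, similarity_cap_library_to_actives = 1, seed = 2))
  expect_false(identical(u1$library$smiles, u3$library$smiles))
})

test_that("compound sets are pairwise disjoint by canonical structure", {
  u <- small_universe()
  keys <- c(u$actives$canonical_key, u$true_inactives$canonical_key,
            u$vendor_pool$canonical_key, u$library$canonical_key)
  expect_false(any(duplicated(keys)))
})

test_that("every library compound respects the similarity cap to actives", {
  u <- small_universe()
  nn <- nearest_neighbor_similarity(universe_features(u, "library"),
                                    universe_features(u, "actives"))
  expect_lte(max(nn$similarity),
             u$config$similarity_cap_library_to_actives)
})

test_that("library molecular weights fall mainly in the 450-650 window", {
  u <- small_universe()
  mw <- universe_features(u, "library")$props$mw
  expect_gt(mean(mw >= 450 & mw <= 650), 0.6)
})

test_that("availability counts round to the nearest integer, ties up", {
  u <- nullhit_universe()   # 21.3% of 1,000
  expect_equal(sum(u$library$available), 213)
  # half-way fraction rounds up
  u2 <- generate_universe(universe_config(
    n_known_actives = 8, n_known_inactives = 8, n_vendor_pool = 20,
    n_library = 2, availability_fraction = 0.25,
    similarity_cap_library_to_actives = 1, seed = 3))
  expect_equal(sum(u2$library$available), 1)
})

test_that("latent hit fraction matches the binomial expectation at scale", {
  u <- generate_universe(universe_config(
    n_known_actives = 15, n_known_inactives = 15, n_vendor_pool = 60,
    n_library = 10000, base_hit_rate = 0.01, enrichment_factor = 1,
    similarity_cap_library_to_actives = 1, seed = 17))
  phat <- mean(u$latent_hit_labels[u$library$compound_id])
  half <- stats::qnorm(0.995) * sqrt(0.01 * 0.99 / 10000)
  expect_lt(abs(phat - 0.01), half)
})

test_that("an overdrawn template space fails with a named shortfall", {
  expect_error(generate_universe(universe_config(
    n_known_actives = 600, n_known_inactives = 10, n_vendor_pool = 20,
    n_library = 10, similarity_cap_library_to_actives = 1, seed = 1)),
    "template pool too small")
})

test_that("noise-free assay hits the anchor values exactly", {
  u <- cleanhit_universe()   # effect 100, no noise, no nonspecific hits
  lib_ids <- u$library$compound_id
  res <- simulate_assay(u, lib_ids)
  latent <- u$latent_hit_labels[lib_ids]
  expect_true(all(res$primary_inhibition_pct[!latent] == 0))
  expect_true(all(res$primary_inhibition_pct[latent] == 100))
  expect_true(all(res$counter_inhibition_pct == 0))
  # repeated simulation of the same universe is identical
  expect_identical(res, simulate_assay(u, lib_ids))
  expect_error(simulate_assay(u, "nope"), "unknown compound")
})

test_that("assay noise has the configured Gaussian tail", {
  u <- nullhit_universe()    # no latent hits, noise sd = 5
  res <- simulate_assay(u, u$library$compound_id)
  # ~2.5% of non-hits should exceed 1.96 sd = 9.8% inhibition
  frac <- mean(res$primary_inhibition_pct > 9.8)
  half <- stats::qnorm(0.995) * sqrt(0.025 * 0.975 / nrow(res))
  expect_lt(abs(frac - 0.025), half)
})

test_that("a written universe reloads into an equivalent object", {
  u <- small_universe()
  dir <- withr::local_tempdir()
  write_universe(u, dir)
  u2 <- read_universe(dir, u$config)
  for (set in c("actives", "true_inactives", "vendor_pool", "library")) {
    expect_equal(u2[[set]], u[[set]])
  }
  expect_equal(u2$latent_hit_labels, u$latent_hit_labels)
  expect_equal(u2$latent_effect, u$latent_effect)
  expect_equal(u2$scaffold_family, u$scaffold_family)
  # SDF artifact holds one block per compound
  n_blocks <- sum(grepl("^\\$\\$\\$\\$", readLines(file.path(dir, "compounds.sdf"))))
  expect_equal(n_blocks, nrow(u$actives) + nrow(u$true_inactives) +
                 nrow(u$vendor_pool) + nrow(u$library))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(universe_config(base_hit_rate = 1.2), "fractions")
  expect_error(universe_config(enrichment_factor = 0.5), "enrichment_factor")
  expect_error(universe_config(n_library = 0), "positive")
  expect_error(universe_config(assay_noise_sd = -1), "non-negative")
})
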