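# Shared fixtures, built once per test run and memoised. Universes are kept
# deliberately small; their feature caches are shared across tests.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# a small full universe with the similarity cap active
small_universe <- function() {
  memo("small_universe", function() {
    generate_universe(universe_config(
      n_known_actives = 40, n_known_inactives = 40,
      n_vendor_pool = 200, n_library = 400,
      availability_fraction = 0.213, base_hit_rate = 0.05,
      enrichment_factor = 6, seed = 101
    ))
  })
}

# 1,000-compound library with no planted hits and no similarity cap
# (cheap to build); exercises availability rounding and assay noise tails
nullhit_universe <- function() {
  memo("nullhit_universe", function() {
    generate_universe(universe_config(
      n_known_actives = 15, n_known_inactives = 15,
      n_vendor_pool = 60, n_library = 1000,
      availability_fraction = 0.213, base_hit_rate = 0,
      similarity_cap_library_to_actives = 1,
      assay_noise_sd = 5, seed = 202
    ))
  })
}

# universe with strong, noise-free planted effects for exact assay checks
cleanhit_universe <- function() {
  memo("cleanhit_universe", function() {
    generate_universe(universe_config(
      n_known_actives = 15, n_known_inactives = 15,
      n_vendor_pool = 60, n_library = 80,
      availability_fraction = 0.5, base_hit_rate = 0.5,
      similarity_cap_library_to_actives = 1,
      assay_noise_sd = 0, nonspecific_fraction = 0,
      hit_effect_mean = 100, hit_effect_sd = 0, seed = 303
    ))
  })
}

# synthetic feature sets that bypass the chemistry layer entirely: two
# classes with (optionally) disjoint characteristic bits
fake_features <- function(n, ids = sprintf("f%03d", seq_len(n)),
                          bit_pool = 1:400, n_bits = 30, seed = 1,
                          signature = NULL) {
  ppilbvs:::with_seed(seed, {
    bits <- lapply(seq_len(n), function(i) {
      b <- sample(bit_pool, n_bits)
      if (!is.null(signature)) b <- c(b, signature)
      sort(unique(as.integer(b)))
    })
    names(bits) <- ids
    props <- data.frame(
      mw = stats::runif(n, 200, 600), alogp = stats::runif(n, -1, 5),
      n_hba = sample(0:8, n, replace = TRUE),
      n_hbd = sample(0:4, n, replace = TRUE),
      n_rotatable = sample(0:10, n, replace = TRUE),
      row.names = ids
    )
    structure(list(ids = ids, smiles = rep("", n), props = props, bits = bits),
              class = "lbvs_features")
  })
}

# a balanced labelled set with separable synthetic features
fake_labeled_set <- function(n_per_class = 52, separable = TRUE, seed = 1) {
  ids_a <- sprintf("a%03d", seq_len(n_per_class))
  ids_i <- sprintf("i%03d", seq_len(n_per_class))
  fa <- fake_features(n_per_class, ids_a, bit_pool = 1:400, seed = seed,
                      signature = if (separable) 900:905 else NULL)
  fi <- fake_features(n_per_class, ids_i, bit_pool = if (separable) 401:800 else 1:400,
                      seed = seed + 1)
  labeled <- data.frame(
    compound_id = c(ids_a, ids_i),
    smiles = "",
    label = rep(c("active", "inactive"), each = n_per_class),
    label_basis = "true_measured",
    stringsAsFactors = FALSE
  )
  list(labeled = labeled, features = combine_features(list(fa, fi),
                                                      labeled$compound_id))
}

# plain compound tables for curation tests (tiny molecules, fast)
tiny_compounds <- function(smiles, prefix = "c", source = "known_db") {
  compound_table(smiles, sprintf("%s%02d", prefix, seq_along(smiles)),
                 source = source)
}
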