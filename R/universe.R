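# Synthetic compound universe: a mock chemical world with the statistical
# structure the screening study assumes -- a small pharmacophore-rich active
# set, true inactives sharing the active chemotypes, a plain vendor pool for
# putative-inactive sampling, and a large screening library structurally
# dissimilar to the actives in which latent hits are planted, enriched in
# scaffold families that share functional-class features with the actives.

# Substituent pools. PHARM carries the hydrogen-bonding / acidic groups the
# actives are built from; PLAIN is alkyl/ether/halogen decoration.
# Substituent ring closures use digit 9 so they never collide with the
# scaffolds' ring numbering (scaffolds use 1-4).
PHARM_SUBS <- c("F", "Cl", "O", "OC", "N", "C(=O)O", "C(=O)N", "S(=O)(=O)N",
                "S(=O)(=O)C", "C(=O)OC", "NC(=O)C", "C#N", "CO", "OCC(=O)O",
                "C(=O)NC")
# the acidic/H-bonding substituents that separate measured actives from the
# measured inactives sharing their chemotypes: actives carry at least one,
# true inactives none (the class signal a trained model can recover)
ACID_SUBS <- c("C(=O)O", "OCC(=O)O", "S(=O)(=O)N")
PLAIN_SUBS <- c("C", "CC", "CCC", "C(C)C", "C(C)(C)C", "CCCC", "OC", "OCC",
                "OC(C)C", "F", "Cl", "Br", "C9CCCCC9", "CC=C", "OCCC")

# 20 scaffold templates. A* families build the known actives and true
# inactives (sulfonamide/carboxylate chemotypes of reported Keap1/Nrf2
# inhibitors); V* families are small plain vendor compounds; L* families are
# the PPI-library-sized molecules (MW mainly 450-650). L1-L3 are the
# "feature-correlated" families: distinct scaffolds from the actives but
# sharing the ortho-substituted aromatic amide with a carboxylated
# piperidine motif and the pharmacophoric substituent pool.
SCAFFOLDS <- list(
  A1 = list(set = "active", pool = "pharm",
            tpl = "O=S(=O)(Nc1ccc2ccccc2c1NS(=O)(=O)c1ccc(<R1>)cc1)c1ccc(<R2>)cc1"),
  A2 = list(set = "active", pool = "pharm",
            tpl = "O=C(O)c1ccc(N(Cc2ccc(<R1>)cc2)S(=O)(=O)c2ccc(<R2>)cc2)cc1"),
  A3 = list(set = "active", pool = "pharm",
            tpl = "O=C(Nc1ccc(<R1>)cc1)c1cc(<R2>)ccc1OCC(=O)O"),
  A4 = list(set = "active", pool = "pharm",
            tpl = "O=C(N1CCN(Cc2ccc(<R1>)cc2)CC1)c1ccc(<R2>)cc1C(=O)O"),
  A5 = list(set = "active", pool = "pharm",
            tpl = "O=S(=O)(Nc1nc(-c2ccc(<R1>)cc2)cs1)c1ccc(<R2>)cc1"),
  V1 = list(set = "vendor", pool = "plain",
            tpl = "CC(C)Oc1ccc(<R1>)cc1<R2>"),
  V2 = list(set = "vendor", pool = "plain",
            tpl = "Cn1cc(<R1>)c2cc(<R2>)ccc21"),
  V3 = list(set = "vendor", pool = "plain",
            tpl = "CCN(CC)C(=O)c1ccc(<R1>)cc1<R2>"),
  V4 = list(set = "vendor", pool = "plain",
            tpl = "Cc1noc(C)c1-c1ccc(<R1>)cc1<R2>"),
  V5 = list(set = "vendor", pool = "plain",
            tpl = "C1COc2cc(<R1>)c(<R2>)cc2O1"),
  V6 = list(set = "vendor", pool = "plain",
            tpl = "CC(C)(C)c1ccc(CN2CCCC2)c(<R1>)c1<R2>"),
  V7 = list(set = "vendor", pool = "plain",
            tpl = "COc1cc(<R1>)cc(<R2>)c1CN1CCOCC1"),
  L1 = list(set = "library", pool = "pharm", correlated = TRUE,
            tpl = "O=C(Nc1ccc2cc(<R3>)ccc2c1)c1cc(<R1>)ccc1NC(=O)c1ccc(<R2>)cc1C(=O)N1CCC(C(=O)O)CC1"),
  L2 = list(set = "library", pool = "pharm", correlated = TRUE,
            tpl = "O=C(O)C1CCN(C(=O)c2cc(<R1>)ccc2NC(=O)c2cc(<R2>)c(<R3>)cc2Cc2ccccc2)CC1"),
  L3 = list(set = "library", pool = "pharm", correlated = TRUE,
            tpl = "O=C(O)C1CCN(C(=O)c2ccc(S(=O)(=O)N(C)c3ccc(<R2>)c(<R3>)c3)cc2NC(=O)Cc2ccc(<R1>)cc2)CC1"),
  L4 = list(set = "library", pool = "plain",
            tpl = "CC(C)(C)c1ccc(C(=O)N2CCN(c3ccc(<R1>)c(<R2>)c3)CC2)cc1-c1ccc(<R3>)cc1"),
  L5 = list(set = "library", pool = "plain",
            tpl = "O=C(NCc1ccc(<R1>)cc1)c1ccc(N2CCC(Cc3ccc(<R2>)cc3)CC2)c(<R3>)c1"),
  L6 = list(set = "library", pool = "plain",
            tpl = "Cn1cc(-c2ccc(CN3CCC(c4ccc(<R1>)cc4)CC3)c(<R2>)c2)c2cc(<R3>)ccc21"),
  L7 = list(set = "library", pool = "plain",
            tpl = "CC(C)Cc1ccc(-c2nc(-c3ccc(<R1>)c(<R2>)c3)no2)cc1OCc1ccc(<R3>)cc1C"),
  L8 = list(set = "library", pool = "plain",
            tpl = "COc1ccc(-c2ccc(N3CCN(Cc4ccc(<R1>)cc4<R2>)CC3)cc2CC(C)C)c(<R3>)c1")
)

TRFRET_T0 <- 10000   # 0%-inhibition anchor signal (arbitrary units)
TRFRET_T100 <- 1000  # 100%-inhibition anchor signal

#' Configuration of the synthetic compound universe
#'
#' Defaults mirror the modelled screening study: 108 known actives and 106
#' true inactives, a 12,593-compound screening library with 21.3% of entries
#' available for assay, a 1% base hit rate enriched sixfold in the
#' feature-correlated scaffold families (the ratio of the reported model-arm
#' to random-arm hit rates), a 0.32 cap on library-to-active Tanimoto
#' similarity, and assay noise of 5 percentage points. `hit_effect_mean` /
#' `hit_effect_sd` set the true inhibition of planted hits (percent),
#' spanning the weak-to-strong hit range the modelled assay reported.
#'
#' @param n_known_actives,n_known_inactives,n_vendor_pool,n_library counts.
#' @param availability_fraction fraction of library compounds available.
#' @param base_hit_rate latent hit probability of uncorrelated library
#'   compounds.
#' @param enrichment_factor multiplier (>= 1) on the hit probability in
#'   feature-correlated scaffold families (probability capped at 1).
#' @param similarity_cap_library_to_actives Tanimoto bound in \[0,1\];
#'   every library compound stays at or below this similarity to its
#'   nearest active (a cap of 1 disables the constraint).
#' @param assay_noise_sd Gaussian assay noise, percentage points.
#' @param nonspecific_fraction fraction of latent hits that also inhibit
#'   the counter assay.
#' @param hit_effect_mean,hit_effect_sd true inhibition of latent hits (%).
#' @param seed integer seed; the same seed reproduces the universe exactly.
#' @return validated config object of class `lbvs_universe_config`.
#' @export
universe_config <- function(n_known_actives = 108, n_known_inactives = 106,
                            n_vendor_pool = 2000, n_library = 12593,
                            availability_fraction = 0.213,
                            base_hit_rate = 0.01, enrichment_factor = 6,
                            similarity_cap_library_to_actives = 0.32,
                            assay_noise_sd = 5, nonspecific_fraction = 0.0625,
                            hit_effect_mean = 40, hit_effect_sd = 20,
                            seed = 1) {
  cfg <- list(n_known_actives = n_known_actives,
              n_known_inactives = n_known_inactives,
              n_vendor_pool = n_vendor_pool, n_library = n_library,
              availability_fraction = availability_fraction,
              base_hit_rate = base_hit_rate,
              enrichment_factor = enrichment_factor,
              similarity_cap_library_to_actives = similarity_cap_library_to_actives,
              assay_noise_sd = assay_noise_sd,
              nonspecific_fraction = nonspecific_fraction,
              hit_effect_mean = hit_effect_mean, hit_effect_sd = hit_effect_sd,
              seed = seed)
  counts <- cfg[c("n_known_actives", "n_known_inactives", "n_vendor_pool",
                  "n_library")]
  if (any(unlist(counts) <= 0)) stop("all counts must be positive")
  fracs <- cfg[c("availability_fraction", "base_hit_rate",
                 "similarity_cap_library_to_actives", "nonspecific_fraction")]
  if (any(unlist(fracs) < 0 | unlist(fracs) > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  if (enrichment_factor < 1) stop("enrichment_factor must be >= 1")
  if (assay_noise_sd < 0 || hit_effect_sd < 0) stop("sd must be non-negative")
  structure(cfg, class = "lbvs_universe_config")
}

#' @noRd
fill_template <- function(tpl, subs) {
  for (k in seq_along(subs)) {
    tpl <- sub(paste0("<R", k, ">"), subs[k], tpl, fixed = TRUE)
  }
  tpl
}

#' @noRd
template_points <- function(tpl) {
  sum(vapply(1:3, function(k) grepl(paste0("<R", k, ">"), tpl, fixed = TRUE),
             logical(1)))
}

# decode a combo index (1-based) into substituent choices
#' @noRd
combo_subs <- function(idx, pool, points) {
  idx <- idx - 1
  subs <- character(points)
  for (k in seq_len(points)) {
    subs[k] <- pool[(idx %% length(pool)) + 1]
    idx <- idx %/% length(pool)
  }
  subs
}

# fingerprint bits only (no properties); used for the similarity cap
#' @noRd
fingerprint_set <- function(smiles, ids) {
  sdf <- parse_molecules(smiles, ids)
  bits <- lapply(seq_along(smiles), function(i) mol_fingerprint(mol_graph(sdf[[i]])))
  names(bits) <- ids
  bits
}

#' Generate a synthetic compound universe
#'
#' Molecules are enumerated from the internal scaffold-template grammar
#' (20 scaffolds x 15 substituents, 2-3 substitution points), so that
#' within-family structural similarity is high and across-family similarity
#' is low. The four compound sets are pairwise disjoint by canonical
#' structure; every library compound is kept at or below the configured
#' Tanimoto similarity to its nearest active (violating draws are replaced;
#' an exhausted template space is an explicit error naming the shortfall).
#' Latent hit labels are drawn per library compound with probability
#' `base_hit_rate`, multiplied by `enrichment_factor` in the
#' feature-correlated families and capped at 1; a `nonspecific_fraction`
#' of latent hits is flagged as counter-assay inhibitors.
#'
#' @param config an [universe_config()].
#' @return object of class `lbvs_universe`: list with compound tables
#'   `actives`, `true_inactives`, `vendor_pool`, `library`, plus
#'   `latent_hit_labels`, `scaffold_family`, `nonspecific`, `latent_effect`
#'   (all keyed by compound id), `correlated_families` and `config`.
#' @export
generate_universe <- function(config = universe_config()) {
  stopifnot(inherits(config, "lbvs_universe_config"))
  with_seed(config$seed, .generate_universe(config))
}

.generate_universe <- function(config) {
  sets <- vapply(SCAFFOLDS, `[[`, character(1), "set")
  fam_names <- split(names(SCAFFOLDS), sets)
  pool_of <- function(fam) {
    if (SCAFFOLDS[[fam]]$pool == "pharm") PHARM_SUBS else PLAIN_SUBS
  }
  capacity <- vapply(names(SCAFFOLDS), function(fam) {
    length(pool_of(fam))^template_points(SCAFFOLDS[[fam]]$tpl)
  }, numeric(1))
  used <- lapply(capacity, function(cap) integer(0))   # combo indices drawn

  draw_family <- function(fam, k, combo_ok = NULL) {
    remaining <- setdiff(seq_len(capacity[[fam]]), used[[fam]])
    pool <- pool_of(fam)
    pts <- template_points(SCAFFOLDS[[fam]]$tpl)
    if (!is.null(combo_ok)) {
      keep <- vapply(remaining, function(i) combo_ok(combo_subs(i, pool, pts)),
                     logical(1))
      remaining <- remaining[keep]
    }
    if (length(remaining) < k) {
      stop("template pool too small: scaffold family ", fam, " short by ",
           k - length(remaining), " structure(s)")
    }
    idx <- if (length(remaining) == 1) remaining else sample(remaining, k)
    used[[fam]] <<- c(used[[fam]], idx)
    vapply(idx, function(i) {
      fill_template(SCAFFOLDS[[fam]]$tpl, combo_subs(i, pool, pts))
    }, character(1))
  }

  alloc <- function(n, fams) {
    base <- n %/% length(fams)
    extra <- n %% length(fams)
    stats::setNames(base + (seq_along(fams) <= extra), fams)
  }

  seen_keys <- character(0)
  # draw `n` structurally new molecules for one set, replacing canonical
  # duplicates; `accept` optionally rejects candidates (similarity cap),
  # `combo_ok` constrains the substituent tuples drawn
  draw_set <- function(n, fams, prefix, accept = NULL, combo_ok = NULL) {
    counts <- alloc(n, fams)
    out_smiles <- character(0); out_keys <- character(0); out_fam <- character(0)
    pending <- counts
    for (round in 1:25) {
      if (sum(pending) == 0) break
      cand_smi <- character(0); cand_fam <- character(0)
      for (fam in fams[pending[fams] > 0]) {
        s <- draw_family(fam, pending[[fam]], combo_ok = combo_ok)
        cand_smi <- c(cand_smi, s)
        cand_fam <- c(cand_fam, rep(fam, length(s)))
      }
      keys <- canonical_smiles(cand_smi, paste0("t", seq_along(cand_smi)))
      ok <- !(keys %in% c(seen_keys, out_keys)) & !duplicated(keys)
      if (!is.null(accept) && any(ok)) {
        ok[ok] <- accept(cand_smi[ok])
      }
      out_smiles <- c(out_smiles, cand_smi[ok])
      out_keys <- c(out_keys, keys[ok])
      out_fam <- c(out_fam, cand_fam[ok])
      got <- table(factor(cand_fam[ok], levels = fams))
      pending <- pending - as.integer(got[fams])
    }
    if (sum(pending) > 0) {
      stop("template pool too small: could not draw ", sum(pending),
           " more structure(s) for families ",
           paste(fams[pending[fams] > 0], collapse = ", "))
    }
    seen_keys <<- c(seen_keys, out_keys)
    ids <- sprintf("%s%05d", prefix, seq_len(n))
    list(table = data.frame(compound_id = ids, smiles = out_smiles,
                            canonical_key = out_keys,
                            source = if (prefix == "LIB") "library" else
                              if (prefix == "VEN") "vendor" else "known_db",
                            available = NA, stringsAsFactors = FALSE),
         family = stats::setNames(out_fam, ids))
  }

  # actives and true inactives share the A-scaffold chemotypes; actives
  # carry at least one acidic substituent, true inactives none
  has_acid <- function(subs) any(subs %in% ACID_SUBS)
  act <- draw_set(config$n_known_actives, fam_names$active, "ACT",
                  combo_ok = has_acid)
  ina <- draw_set(config$n_known_inactives, fam_names$active, "INA",
                  combo_ok = function(subs) !has_acid(subs))
  ven <- draw_set(config$n_vendor_pool, fam_names$vendor, "VEN")

  cap <- config$similarity_cap_library_to_actives
  accept <- NULL
  bit_store <- new.env(parent = emptyenv())   # keep fingerprints for reuse
  if (cap < 1) {
    active_bits <- fingerprint_set(act$table$smiles, act$table$compound_id)
    for (i in seq_along(active_bits)) {
      assign(act$table$smiles[i], active_bits[[i]], envir = bit_store)
    }
    accept <- function(smiles) {
      bits <- fingerprint_set(smiles, paste0("q", seq_along(smiles)))
      ok <- nearest_neighbor_similarity(bits, active_bits)$similarity <= cap
      for (i in which(ok)) assign(smiles[i], bits[[i]], envir = bit_store)
      ok
    }
  }
  lib <- draw_set(config$n_library, fam_names$library, "LIB", accept = accept)

  # availability: nearest-integer count, ties up, assigned at random
  n_avail <- floor(config$availability_fraction * config$n_library + 0.5)
  lib$table$available <- FALSE
  lib$table$available[sample.int(config$n_library, n_avail)] <- TRUE

  corr_fams <- names(SCAFFOLDS)[vapply(SCAFFOLDS, function(s)
    isTRUE(s$correlated), logical(1))]
  p_hit <- pmin(1, config$base_hit_rate *
                  ifelse(lib$family %in% corr_fams, config$enrichment_factor, 1))
  lib_hit <- stats::runif(config$n_library) < p_hit
  latent <- c(stats::setNames(rep(TRUE, nrow(act$table)), act$table$compound_id),
              stats::setNames(rep(FALSE, nrow(ina$table)), ina$table$compound_id),
              stats::setNames(rep(FALSE, nrow(ven$table)), ven$table$compound_id),
              stats::setNames(lib_hit, lib$table$compound_id))
  effect <- stats::setNames(rep(0, length(latent)), names(latent))
  hits <- names(latent)[latent]
  effect[hits] <- pmin(100, pmax(0, stats::rnorm(length(hits),
                                                 config$hit_effect_mean,
                                                 config$hit_effect_sd)))
  nonspec <- stats::setNames(rep(FALSE, length(latent)), names(latent))
  nonspec[hits] <- stats::runif(length(hits)) < config$nonspecific_fraction

  structure(list(
    actives = act$table, true_inactives = ina$table,
    vendor_pool = ven$table, library = lib$table,
    latent_hit_labels = latent,
    scaffold_family = c(act$family, ina$family, ven$family, lib$family),
    nonspecific = nonspec, latent_effect = effect,
    correlated_families = corr_fams,
    config = config,
    cache = local({
      e <- new.env(parent = emptyenv())
      e$bit_store <- bit_store
      e
    })
  ), class = "lbvs_universe")
}

#' @export
print.lbvs_universe <- function(x, ...) {
  cat("Synthetic screening universe (seed ", x$config$seed, ")\n", sep = "")
  cat("  actives:", nrow(x$actives),
      " true inactives:", nrow(x$true_inactives),
      " vendor pool:", nrow(x$vendor_pool),
      " library:", nrow(x$library), "\n")
  cat("  available library compounds:", sum(x$library$available),
      " latent hits:", sum(x$latent_hit_labels[x$library$compound_id]), "\n")
  invisible(x)
}

#' Features of a universe compound set, computed once and cached
#'
#' @param universe an `lbvs_universe`.
#' @param set one of `"actives"`, `"true_inactives"`, `"vendor_pool"`,
#'   `"library"`.
#' @return an `lbvs_features` object.
#' @export
universe_features <- function(universe,
                              set = c("actives", "true_inactives",
                                      "vendor_pool", "library")) {
  set <- match.arg(set)
  key <- paste0("feat_", set)
  if (is.null(universe$cache[[key]])) {
    tab <- universe[[set]]
    store <- universe$cache$bit_store
    known <- lapply(tab$smiles, function(s) {
      if (!is.null(store) && exists(s, envir = store, inherits = FALSE)) {
        get(s, envir = store, inherits = FALSE)
      } else NULL
    })
    universe$cache[[key]] <- featurize_set(tab$smiles, tab$compound_id,
                                           bits = known)
  }
  universe$cache[[key]]
}

#' Simulate the TR-FRET primary and counter assay
#'
#' For each compound a raw TR-FRET signal is generated between the 0%- and
#' 100%-inhibition anchors (10,000 and 1,000 arbitrary units): latent hits
#' sit at their planted effect toward the 100% anchor, non-hits at the 0%
#' anchor. Gaussian noise of `assay_noise_sd` percentage points (expressed
#' on the signal scale) is added, and signals are converted back through
#' [trfret_inhibition()]. Latent hits flagged as nonspecific inhibit the
#' counter assay with the same effect; all other counter signals are at the
#' 0% anchor.
#'
#' @param universe an `lbvs_universe`.
#' @param compound_ids ids to assay (must exist in the universe).
#' @param config config whose `assay_noise_sd` and `seed` drive the
#'   simulation (default: the universe's own).
#' @return assay-results data frame (see [as_assay_results()]).
#' @export
simulate_assay <- function(universe, compound_ids, config = universe$config) {
  unknown <- setdiff(compound_ids, names(universe$latent_hit_labels))
  if (length(unknown)) {
    stop("unknown compound id(s): ", paste(unknown, collapse = ", "))
  }
  n <- length(compound_ids)
  span <- TRFRET_T0 - TRFRET_T100
  effect <- universe$latent_effect[compound_ids]
  counter_effect <- ifelse(universe$nonspecific[compound_ids], effect, 0)
  noise_sig <- config$assay_noise_sd / 100 * span
  with_seed(config$seed + 104729L, {
    t_primary <- TRFRET_T100 + (1 - effect / 100) * span +
      stats::rnorm(n, 0, noise_sig)
    t_counter <- TRFRET_T100 + (1 - counter_effect / 100) * span +
      stats::rnorm(n, 0, noise_sig)
    data.frame(
      compound_id = compound_ids,
      primary_inhibition_pct = trfret_inhibition(t_primary, TRFRET_T0, TRFRET_T100),
      primary_ni = FALSE,
      counter_inhibition_pct = trfret_inhibition(t_counter, TRFRET_T0, TRFRET_T100),
      counter_ni = FALSE,
      stringsAsFactors = FALSE
    )
  })
}

#' Write a universe to disk as plain-text artifacts
#'
#' Writes `compounds.smi` (SMILES + id), `compounds.sdf`, and
#' `compounds_meta.csv` (id, source, available, scaffold_family,
#' latent_hit) covering all four compound sets.
#'
#' @param universe an `lbvs_universe`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_universe <- function(universe, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  all_tab <- rbind(universe$actives, universe$true_inactives,
                   universe$vendor_pool, universe$library)
  smi_path <- file.path(dir, "compounds.smi")
  writeLines(paste(all_tab$smiles, all_tab$compound_id), smi_path)
  sdf_path <- file.path(dir, "compounds.sdf")
  sdf <- parse_molecules(all_tab$smiles, all_tab$compound_id)
  ChemmineR::write.SDF(sdf, file = sdf_path, cid = TRUE)
  # OpenBabel stamps a creation time into the SDF program line; blank it so
  # re-running a configuration reproduces the artifact byte-identically
  lines <- readLines(sdf_path)
  lines[grepl("^ OpenBabel", lines)] <- " OpenBabel                    2D"
  writeLines(lines, sdf_path)
  meta_path <- file.path(dir, "compounds_meta.csv")
  ids <- all_tab$compound_id
  meta <- data.frame(
    compound_id = ids,
    source = all_tab$source,
    available = all_tab$available,
    scaffold_family = universe$scaffold_family[ids],
    latent_hit = universe$latent_hit_labels[ids],
    canonical_key = all_tab$canonical_key,
    latent_effect = universe$latent_effect[ids],
    nonspecific = universe$nonspecific[ids],
    set = rep(c("actives", "true_inactives", "vendor_pool", "library"),
              c(nrow(universe$actives), nrow(universe$true_inactives),
                nrow(universe$vendor_pool), nrow(universe$library))),
    stringsAsFactors = FALSE
  )
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(c(smi_path, sdf_path, meta_path))
}

#' Reload a written universe
#'
#' Reconstructs an `lbvs_universe` from the artifacts of [write_universe()].
#'
#' @param dir directory holding `compounds.smi` and `compounds_meta.csv`.
#' @param config the [universe_config()] the universe was generated with.
#' @return an `lbvs_universe`.
#' @export
read_universe <- function(dir, config) {
  # not read.table: SMILES may contain '#' (triple bonds) and quotes
  lines <- readLines(file.path(dir, "compounds.smi"))
  parts <- strsplit(lines, " ", fixed = TRUE)
  stopifnot(all(lengths(parts) == 2))
  smi <- data.frame(smiles = vapply(parts, `[`, character(1), 1),
                    compound_id = vapply(parts, `[`, character(1), 2),
                    stringsAsFactors = FALSE)
  meta <- utils::read.csv(file.path(dir, "compounds_meta.csv"),
                          stringsAsFactors = FALSE)
  stopifnot(identical(smi$compound_id, meta$compound_id))
  tab_of <- function(set) {
    idx <- meta$set == set
    data.frame(compound_id = meta$compound_id[idx], smiles = smi$smiles[idx],
               canonical_key = meta$canonical_key[idx],
               source = meta$source[idx], available = meta$available[idx],
               stringsAsFactors = FALSE)
  }
  structure(list(
    actives = tab_of("actives"), true_inactives = tab_of("true_inactives"),
    vendor_pool = tab_of("vendor_pool"), library = tab_of("library"),
    latent_hit_labels = stats::setNames(meta$latent_hit, meta$compound_id),
    scaffold_family = stats::setNames(meta$scaffold_family, meta$compound_id),
    nonspecific = stats::setNames(meta$nonspecific, meta$compound_id),
    latent_effect = stats::setNames(meta$latent_effect, meta$compound_id),
    correlated_families = names(SCAFFOLDS)[vapply(SCAFFOLDS, function(s)
      isTRUE(s$correlated), logical(1))],
    config = config,
    cache = new.env(parent = emptyenv())
  ), class = "lbvs_universe")
}

#' Write assay results, preserving "NI" provenance
#'
#' @param results assay-results data frame.
#' @param path CSV path.
#' @return invisibly, `path`.
#' @export
write_assay_results <- function(results, path) {
  fmt <- function(value, ni) ifelse(ni, "NI", format(round(value, 6), trim = TRUE,
                                                     scientific = FALSE))
  out <- data.frame(
    compound_id = results$compound_id,
    primary_inhibition_pct = fmt(results$primary_inhibition_pct, results$primary_ni),
    counter_inhibition_pct = fmt(results$counter_inhibition_pct, results$counter_ni),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
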