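# End-to-end pipeline: generate -> curate -> crossval -> screen -> select
# -> assay -> analyze, with YAML configuration, per-stage artifacts and a
# reproducible JSON manifest.

#' Default pipeline configuration
#'
#' A demonstration-scale configuration of the whole study: a 1,000-compound
#' screening library (availability 21.3%), 54 + 54 known actives/inactives,
#' a 400-compound vendor pool, top-350 selection per model with an
#' 80-compound random arm, and the assay thresholds of the modelled
#' campaign. All sizes can be overridden through a YAML file with the same
#' structure (see [read_pipeline_config()]).
#'
#' @param seed global seed (propagated to every stage).
#' @return nested configuration list of class `lbvs_pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    universe = list(
      n_known_actives = 54, n_known_inactives = 54,
      n_vendor_pool = 400, n_library = 1000,
      availability_fraction = 0.213,
      base_hit_rate = 0.01, enrichment_factor = 6,
      similarity_cap_library_to_actives = 0.32,
      assay_noise_sd = 5, nonspecific_fraction = 0.0625,
      hit_effect_mean = 40, hit_effect_sd = 20
    ),
    curation = list(activity_threshold_um = 10, inhibition_threshold_pct = 50,
                    mw_cap = 1200),
    fingerprint = list(radius = 3),
    model = list(n_trees = 1000, k_folds = 5, threshold = 0.5),
    selection = list(top_n = 350, n_random = 80),
    assay = list(primary_threshold = 15, counter_threshold = 15,
                 substructure_smarts = "C(=O)N1CCC(CC1)C(=O)O")
  ), class = "lbvs_pipeline_config")
}

#' Read and validate a pipeline configuration from YAML
#'
#' Unknown keys are rejected; keys missing from the file keep their
#' defaults.
#'
#' @param path YAML file path.
#' @param seed seed used when the file does not set one.
#' @return an `lbvs_pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = 1) {
  user <- yaml::read_yaml(path)
  def <- unclass(default_pipeline_config(seed))
  merge_block <- function(defblock, userblock, where) {
    if (is.null(userblock)) return(defblock)
    unknown <- setdiff(names(userblock), names(defblock))
    if (length(unknown)) {
      stop("unknown configuration key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
    }
    utils::modifyList(defblock, userblock)
  }
  unknown_top <- setdiff(names(user), names(def))
  if (length(unknown_top)) {
    stop("unknown configuration block(s): ", paste(unknown_top, collapse = ", "))
  }
  out <- def
  for (block in setdiff(names(def), "seed")) {
    out[[block]] <- merge_block(def[[block]], user[[block]], block)
  }
  if (!is.null(user$seed)) out$seed <- user$seed
  structure(out, class = "lbvs_pipeline_config")
}

#' @noRd
config_universe <- function(config) {
  do.call(universe_config, c(config$universe, list(seed = config$seed)))
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the whole screening study
#'
#' Executes all stages in order, persisting every intermediate artifact in
#' `out_dir`: the synthetic universe (`compounds.smi`, `compounds.sdf`,
#' `compounds_meta.csv`), labelled training sets (`labeled_ti.csv`,
#' `labeled_pi.csv`), cross-validation report (`cv_report.json/.csv`),
#' library ranks (`ranks.csv`), the selection (`selection.csv`), assay
#' results (`assay_results.csv`), the hit report (`hit_report.json`,
#' `hit_table.csv`) and a manifest (`manifest.json`) with the config, seeds,
#' per-stage record counts, headline statistics, and the MD5 of every
#' artifact. Re-running with the same configuration reproduces all
#' artifacts byte-identically.
#'
#' @param config an `lbvs_pipeline_config`.
#' @param out_dir writable output directory.
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         quiet = FALSE) {
  stopifnot(inherits(config, "lbvs_pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message("[ppilbvs] ", ...)
  manifest <- list(config = unclass(config), seed = config$seed, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    say(stage, ": ", paste(names(list(...)), unlist(list(...)),
                           sep = "=", collapse = ", "))
  }

  ucfg <- config_universe(config)
  universe <- generate_universe(ucfg)
  write_universe(universe, out_dir)
  note("generate", n_actives = nrow(universe$actives),
       n_true_inactives = nrow(universe$true_inactives),
       n_vendor = nrow(universe$vendor_pool),
       n_library = nrow(universe$library),
       n_available = sum(universe$library$available),
       n_latent_hits = sum(universe$latent_hit_labels[universe$library$compound_id]))

  st <- list(universe = universe)
  st <- stage_curate(st, config, out_dir)
  note("curate", n_ti = nrow(st$ti_set), n_pi = nrow(st$pi_set))
  st <- stage_crossval(st, config, out_dir)
  note("crossval",
       ti_aucroc = round(st$cv$ti$mean[["aucroc"]], 4),
       pi_aucroc = round(st$cv$pi$mean[["aucroc"]], 4))
  st <- stage_screen(st, config, out_dir)
  note("screen", n_ranked = nrow(st$ranks))
  st <- stage_select(st, config, out_dir)
  note("select", n_selected = nrow(st$selection),
       n_overlap = sum(st$selection$arm == "overlap"),
       n_pi_only = sum(st$selection$arm == "pi_only"),
       n_ti_only = sum(st$selection$arm == "ti_only"),
       n_random = sum(st$selection$arm == "random"))
  st <- stage_assay(st, config, out_dir)
  note("assay", n_assayed = nrow(st$assay))
  st <- stage_analyze(st, config, out_dir)
  note("analyze", n_primary_hits = st$report$n_primary_hits,
       n_specific_hits = st$report$n_specific_hits)

  manifest$headline <- st$report[c("n_primary_hits", "n_specific_hits",
                                   "arm_rates", "extrapolation",
                                   "availability")]
  artifacts <- c("compounds.smi", "compounds.sdf", "compounds_meta.csv",
                 "labeled_ti.csv", "labeled_pi.csv", "cv_report.json",
                 "cv_report.csv", "ranks.csv", "selection.csv",
                 "assay_results.csv", "hit_report.json", "hit_table.csv")
  md5 <- tools::md5sum(file.path(out_dir, artifacts))
  manifest$artifacts <- stats::setNames(as.list(unname(md5)), artifacts)
  write_json_artifact(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

# ---- individual stages (each reads what it needs from the state and
# writes its artifact; the CLI reloads state from disk between stages) ----

#' @noRd
stage_curate <- function(st, config, out_dir) {
  u <- st$universe
  st$ti_set <- build_ti_dataset(u$actives, u$true_inactives)
  st$pi_set <- build_pi_dataset(u$actives, u$vendor_pool,
                                mw_cap = config$curation$mw_cap,
                                seed = config$seed + 1)
  write_labeled <- function(labeled, path) {
    utils::write.csv(labeled[, c("compound_id", "smiles", "label", "label_basis")],
                     path, row.names = FALSE)
  }
  write_labeled(st$ti_set, file.path(out_dir, "labeled_ti.csv"))
  write_labeled(st$pi_set, file.path(out_dir, "labeled_pi.csv"))
  st
}

#' @noRd
training_features <- function(st, labeled) {
  sets <- c("actives", "true_inactives", "vendor_pool")
  combine_features(lapply(sets, function(s) universe_features(st$universe, s)),
                   labeled$compound_id)
}

#' @noRd
stage_crossval <- function(st, config, out_dir) {
  mcfg <- config$model
  st$cv <- list(
    ti = stratified_cv(st$ti_set, "TI", k = mcfg$k_folds, n_trees = mcfg$n_trees,
                       seed = config$seed + 2, threshold = mcfg$threshold,
                       features = training_features(st, st$ti_set)),
    pi = stratified_cv(st$pi_set, "PI", k = mcfg$k_folds, n_trees = mcfg$n_trees,
                       seed = config$seed + 3, threshold = mcfg$threshold,
                       features = training_features(st, st$pi_set))
  )
  per_fold <- rbind(cbind(model = "ti", st$cv$ti$per_fold),
                    cbind(model = "pi", st$cv$pi$per_fold))
  utils::write.csv(per_fold, file.path(out_dir, "cv_report.csv"), row.names = FALSE)
  write_json_artifact(list(ti = list(per_fold = st$cv$ti$per_fold,
                                     mean = as.list(st$cv$ti$mean)),
                           pi = list(per_fold = st$cv$pi$per_fold,
                                     mean = as.list(st$cv$pi$mean))),
                      file.path(out_dir, "cv_report.json"))
  st
}

#' @noRd
stage_screen <- function(st, config, out_dir) {
  mcfg <- config$model
  st$model_ti <- train_activity_model(st$ti_set, "TI", n_trees = mcfg$n_trees,
                                      seed = config$seed + 4,
                                      features = training_features(st, st$ti_set))
  st$model_pi <- train_activity_model(st$pi_set, "PI", n_trees = mcfg$n_trees,
                                      seed = config$seed + 5,
                                      features = training_features(st, st$pi_set))
  lib_feat <- universe_features(st$universe, "library")
  st$ranks <- rank_library(st$model_ti, st$model_pi, st$universe$library,
                           features = lib_feat)
  out <- st$ranks
  out$score_ti <- round(out$score_ti, 6)
  out$score_pi <- round(out$score_pi, 6)
  utils::write.csv(out, file.path(out_dir, "ranks.csv"), row.names = FALSE)
  st
}

#' @noRd
stage_select <- function(st, config, out_dir) {
  st$selection <- select_candidates(st$ranks, st$universe$library,
                                    top_n = config$selection$top_n,
                                    n_random = config$selection$n_random,
                                    seed = config$seed + 6)
  utils::write.csv(as.data.frame(st$selection), file.path(out_dir, "selection.csv"),
                   row.names = FALSE)
  st
}

#' @noRd
stage_assay <- function(st, config, out_dir) {
  st$assay <- simulate_assay(st$universe, st$selection$compound_id)
  write_assay_results(st$assay, file.path(out_dir, "assay_results.csv"))
  st
}

#' @noRd
stage_analyze <- function(st, config, out_dir) {
  acfg <- config$assay
  flags <- call_hits(st$assay, primary_threshold = acfg$primary_threshold,
                     counter_threshold = acfg$counter_threshold)
  rates <- arm_hit_rates(flags, st$selection)
  u <- st$universe
  n_available <- sum(u$library$available)
  rand_rate <- rates$primary_rate[rates$arm == "random"]
  extrap <- extrapolate_hit_rate(sum(flags$primary_hit), nrow(flags),
                                 n_available,
                                 if (is.na(rand_rate)) 0 else rand_rate,
                                 nrow(u$library))
  hits <- u$library[u$library$compound_id %in%
                      flags$compound_id[flags$primary_hit], , drop = FALSE]
  novelty <- if (nrow(hits) > 0) novelty_table(hits, u$actives) else NULL
  tested_tab <- u$library[match(flags$compound_id, u$library$compound_id), ,
                          drop = FALSE]
  substr_block <- substructure_hit_rate(acfg$substructure_smarts, tested_tab, flags)
  bias <- availability_bias_check(st$ranks, u$library, config$selection$top_n)

  # recovery of planted hits among the assayed compounds
  latent <- u$latent_hit_labels[flags$compound_id]
  nonspec <- u$nonspecific[flags$compound_id]
  st$report <- list(
    n_assayed = nrow(flags),
    n_primary_hits = sum(flags$primary_hit),
    n_specific_hits = sum(flags$specific_hit),
    arm_rates = rates,
    extrapolation = extrap,
    substructure = substr_block,
    availability = list(n_available = n_available,
                        fraction = n_available / nrow(u$library),
                        bias = bias),
    latent_truth = list(
      n_latent_assayed = sum(latent),
      n_latent_specific_assayed = sum(latent & !nonspec),
      recovered_specific = sum(flags$specific_hit & latent & !nonspec)
    )
  )
  write_json_artifact(st$report, file.path(out_dir, "hit_report.json"))

  rk <- st$ranks[match(flags$compound_id, st$ranks$compound_id), ]
  hit_tab <- data.frame(
    compound_id = flags$compound_id,
    primary_inhibition_pct = round(flags$primary_inhibition_pct, 1),
    counter_inhibition_pct = round(flags$counter_inhibition_pct, 1),
    rank_ti = rk$rank_ti, rank_pi = rk$rank_pi,
    arm = st$selection$arm[match(flags$compound_id, st$selection$compound_id)],
    primary_hit = flags$primary_hit,
    specific_hit = flags$specific_hit,
    stringsAsFactors = FALSE
  )
  if (!is.null(novelty)) {
    m <- match(hit_tab$compound_id, novelty$compound_id)
    hit_tab$nearest_known_similarity <- round(novelty$nearest_similarity[m], 3)
  } else {
    hit_tab$nearest_known_similarity <- NA_real_
  }
  hit_tab <- hit_tab[order(-hit_tab$primary_inhibition_pct), ]
  utils::write.csv(hit_tab, file.path(out_dir, "hit_table.csv"), row.names = FALSE)
  st
}
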