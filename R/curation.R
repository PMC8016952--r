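# Curation: turn raw compound/activity tables into labelled training sets,
# including the putative-inactive (decoy) negative-sampling strategy.

CONC_TYPES <- c("IC50", "EC50", "Kd", "AC50")
ASSAY_TYPES <- c(CONC_TYPES, "InhibitionPct")

#' Build a compound table
#'
#' Normalises a set of structures into the compound-record table used across
#' the pipeline, attaching a canonical structure key (canonical SMILES of the
#' charge-normalised largest fragment) that is stable under atom reordering.
#'
#' @param smiles character vector of SMILES.
#' @param compound_id identifiers (default names or cmp1..n).
#' @param source one of `"known_db"`, `"vendor"`, `"library"`.
#' @param available logical availability flags (default `NA`).
#' @return data frame with columns compound_id, smiles, canonical_key,
#'   source, available.
#' @export
compound_table <- function(smiles, compound_id = names(smiles),
                           source = "known_db", available = NA) {
  if (is.null(compound_id)) compound_id <- paste0("cmp", seq_along(smiles))
  stopifnot(!anyDuplicated(compound_id))
  source <- match.arg(source, c("known_db", "vendor", "library"))
  lf <- vapply(as.character(smiles), largest_fragment, character(1), USE.NAMES = FALSE)
  data.frame(
    compound_id = as.character(compound_id),
    smiles = as.character(smiles),
    canonical_key = canonical_smiles(lf, compound_id),
    source = source,
    available = rep_len(available, length(smiles)),
    stringsAsFactors = FALSE
  )
}

.to_um <- function(value, units) {
  switch(units,
         nM = value / 1000,
         uM = value,
         stop("unit '", units, "' is not convertible to micromolar"))
}

#' Classify a compound's activity from its assay records
#'
#' Concentration-type records (IC50, EC50, Kd, AC50) are standardised to
#' micromolar and the minimum across records is compared against the
#' activity threshold: minimum <= threshold (inclusive) is active, otherwise
#' inactive. Percent-inhibition records are handled by a separate
#' configurable rule: inhibition >= `inhibition_threshold` at the recorded
#' concentration counts as active. A compound with any record classifying as
#' active is active; with usable records but none active it is inactive;
#' with no usable record the result is `NA`.
#'
#' @param records data frame with columns compound_id, assay_type
#'   (IC50/EC50/Kd/AC50/InhibitionPct), value, units (nM/uM/percent); all
#'   rows must share one compound_id.
#' @param threshold_um activity threshold in micromolar (default 10, i.e.
#'   <= 10 uM is active).
#' @param inhibition_threshold percent-inhibition cutoff for
#'   InhibitionPct records (default 50).
#' @return `"active"`, `"inactive"`, or `NA` when no usable record exists.
#' @export
classify_activity <- function(records, threshold_um = 10,
                              inhibition_threshold = 50) {
  stopifnot(is.data.frame(records),
            all(c("compound_id", "assay_type", "value", "units") %in% names(records)))
  if (nrow(records) == 0) return(NA_character_)
  if (length(unique(records$compound_id)) != 1) {
    stop("all records must share one compound_id")
  }
  bad_type <- setdiff(records$assay_type, ASSAY_TYPES)
  if (length(bad_type)) stop("unknown assay_type: ", paste(bad_type, collapse = ", "))

  conc <- records[records$assay_type %in% CONC_TYPES, , drop = FALSE]
  inh <- records[records$assay_type == "InhibitionPct", , drop = FALSE]
  usable <- FALSE
  if (nrow(conc) > 0) {
    if (any(conc$units == "percent")) {
      off <- which(conc$units == "percent")[1]
      stop("record ", off, " (", conc$assay_type[off],
           ") has percent units; not convertible to micromolar")
    }
    if (any(conc$value <= 0)) stop("concentration values must be positive")
    um <- mapply(.to_um, conc$value, conc$units)
    usable <- TRUE
    if (min(um) <= threshold_um) return("active")
  }
  if (nrow(inh) > 0) {
    if (any(inh$units != "percent")) {
      stop("InhibitionPct records must have percent units")
    }
    usable <- TRUE
    if (any(inh$value >= inhibition_threshold)) return("active")
  }
  if (usable) "inactive" else NA_character_
}

.check_class_overlap <- function(actives, inactives, context) {
  both <- intersect(actives$canonical_key, inactives$canonical_key)
  if (length(both)) {
    stop(context, ": structure(s) present in both classes: ",
         paste(both, collapse = ", "))
  }
}

.as_labeled <- function(compounds, label, label_basis) {
  data.frame(
    compound_id = compounds$compound_id,
    smiles = compounds$smiles,
    canonical_key = compounds$canonical_key,
    label = label,
    label_basis = label_basis,
    stringsAsFactors = FALSE
  )
}

#' Build the true-inactive (TI) training set
#'
#' Concatenates measured actives and measured ("true") inactives into one
#' labelled set. Compounds whose canonical structure appears in both classes
#' are rejected.
#'
#' @param actives,inactives compound tables ([compound_table()]), already
#'   structurally deduplicated within each class.
#' @return labelled data frame with columns compound_id, smiles,
#'   canonical_key, label, label_basis.
#' @export
build_ti_dataset <- function(actives, inactives) {
  stopifnot(is.data.frame(actives), is.data.frame(inactives))
  if (nrow(actives) == 0 || nrow(inactives) == 0) {
    stop("both actives and inactives must be non-empty")
  }
  if (anyDuplicated(actives$canonical_key) || anyDuplicated(inactives$canonical_key)) {
    stop("input classes must be structurally deduplicated")
  }
  .check_class_overlap(actives, inactives, "build_ti_dataset")
  rbind(.as_labeled(actives, "active", "true_measured"),
        .as_labeled(inactives, "inactive", "true_measured"))
}

#' Build the putative-inactive (PI) training set
#'
#' Actives are filtered to molecular weight below `mw_cap`; an equal number
#' of vendor compounds is then sampled uniformly at random (seeded) as
#' putative inactives, after excluding any vendor compound whose canonical
#' structure matches an active. The result is balanced 1:1.
#'
#' @param actives compound table of measured actives.
#' @param vendor_pool compound table of untested vendor compounds.
#' @param mw_cap molecular-weight cap for actives in Daltons (default 1200).
#' @param seed integer seed for the vendor draw.
#' @return labelled data frame as in [build_ti_dataset()]; putative
#'   inactives carry `label_basis = "putative"`.
#' @export
build_pi_dataset <- function(actives, vendor_pool, mw_cap = 1200, seed = 1) {
  stopifnot(is.data.frame(actives), is.data.frame(vendor_pool))
  if (nrow(actives) == 0) stop("actives must be non-empty")
  if (anyDuplicated(actives$canonical_key)) {
    stop("actives must be structurally deduplicated")
  }
  mw <- featurize_set(actives$smiles, actives$compound_id)$props$mw
  keep <- actives[mw < mw_cap, , drop = FALSE]
  if (nrow(keep) == 0) stop("no active below the molecular-weight cap")
  eligible <- vendor_pool[!(vendor_pool$canonical_key %in% keep$canonical_key), ,
                          drop = FALSE]
  eligible <- eligible[!duplicated(eligible$canonical_key), , drop = FALSE]
  if (nrow(eligible) < nrow(keep)) {
    stop("insufficient eligible vendor compounds: need ", nrow(keep),
         ", have ", nrow(eligible))
  }
  eligible <- eligible[order(eligible$compound_id), , drop = FALSE]
  idx <- with_seed(seed, sample.int(nrow(eligible), nrow(keep)))
  decoys <- eligible[idx, , drop = FALSE]
  rbind(.as_labeled(keep, "active", "true_measured"),
        .as_labeled(decoys, "inactive", "putative"))
}

# run code under a local RNG state so package functions never disturb the
# caller's random stream
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
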