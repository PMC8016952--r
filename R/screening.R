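# Library scoring, ranking, and assay-candidate selection with an
# availability filter and a random comparator arm.

#' Score and rank a screening library with both models
#'
#' Every library compound is scored by the two models and assigned dense
#' 1-based ranks per model (1 = highest score). Ties are broken by
#' ascending compound_id so ranking is deterministic and independent of
#' input order. Compounds whose structure fails to parse are excluded with
#' a warning, not an error.
#'
#' @param model_ti,model_pi trained `lbvs_rf` models (see
#'   [train_activity_model()]).
#' @param library compound table of the screening library.
#' @param features optional pre-computed [featurize_set()] for the library.
#' @return data frame with columns compound_id, score_ti, score_pi,
#'   rank_ti, rank_pi.
#' @export
rank_library <- function(model_ti, model_pi, library, features = NULL) {
  stopifnot(inherits(model_ti, "lbvs_rf"), inherits(model_pi, "lbvs_rf"),
            is.data.frame(library), nrow(library) > 0)
  if (is.null(features)) {
    keep <- vapply(seq_len(nrow(library)), function(i) {
      ok <- tryCatch({
        canonical_smiles(library$smiles[i], library$compound_id[i])
        TRUE
      }, error = function(e) FALSE)
      ok
    }, logical(1))
    if (!all(keep)) {
      warning("excluded ", sum(!keep), " unparseable structure(s): ",
              paste(library$compound_id[!keep], collapse = ", "))
      library <- library[keep, , drop = FALSE]
    }
    features <- featurize_set(library$smiles, library$compound_id)
  }
  score_ti <- predict(model_ti, features)
  score_pi <- predict(model_pi, features)
  id <- library$compound_id
  rk <- function(score) {
    ord <- order(-score, id)
    r <- integer(length(score)); r[ord] <- seq_along(score)
    r
  }
  data.frame(compound_id = id,
             score_ti = unname(score_ti), score_pi = unname(score_pi),
             rank_ti = rk(score_ti), rank_pi = rk(score_pi),
             stringsAsFactors = FALSE)
}

#' Select assay candidates from ranked compounds
#'
#' Model arms are the available compounds ranked in the top `top_n` by the
#' respective model (ranks are computed over the full library before the
#' availability filter), partitioned into overlap / pi_only / ti_only. The
#' random comparator arm draws `n_random` compounds uniformly (seeded) from
#' the available compounds outside all model arms.
#'
#' @param ranks output of [rank_library()].
#' @param library compound table with the `available` flag.
#' @param top_n rank cutoff per model (default 1000).
#' @param n_random size of the random arm.
#' @param seed integer seed for the random arm.
#' @return object of class `lbvs_selection`: data frame with columns
#'   compound_id and arm (overlap / pi_only / ti_only / random), with the
#'   `top_n` used stored as an attribute.
#' @export
select_candidates <- function(ranks, library, top_n = 1000, n_random = 0,
                              seed = 1) {
  stopifnot(is.data.frame(ranks), top_n <= nrow(ranks), n_random >= 0)
  avail_ids <- library$compound_id[isTRUE_vec(library$available)]
  in_ti <- ranks$compound_id[ranks$rank_ti <= top_n]
  in_pi <- ranks$compound_id[ranks$rank_pi <= top_n]
  ti_sel <- intersect(in_ti, avail_ids)
  pi_sel <- intersect(in_pi, avail_ids)
  overlap <- intersect(ti_sel, pi_sel)
  pi_only <- setdiff(pi_sel, overlap)
  ti_only <- setdiff(ti_sel, overlap)
  pool <- setdiff(avail_ids, c(overlap, pi_only, ti_only))
  if (n_random > length(pool)) {
    stop("n_random = ", n_random, " exceeds the remaining available pool (",
         length(pool), ")")
  }
  rand <- if (n_random > 0) {
    pool <- sort(pool)
    pool[with_seed(seed, sample.int(length(pool), n_random))]
  } else character(0)
  sel <- data.frame(
    compound_id = c(overlap, pi_only, ti_only, rand),
    arm = rep(c("overlap", "pi_only", "ti_only", "random"),
              c(length(overlap), length(pi_only), length(ti_only), length(rand))),
    stringsAsFactors = FALSE
  )
  structure(sel, top_n = top_n, class = c("lbvs_selection", "data.frame"))
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Availability bias of the high-ranked selection
#'
#' Reports, per model, the fraction of the top `top_n` ranked compounds
#' that are available, next to the library-wide availability fraction and
#' their ratio. Fractions near the global value indicate that the
#' available subset is unbiased with respect to the model scores.
#'
#' @inheritParams select_candidates
#' @return data frame with rows ti/pi and columns top_fraction,
#'   global_fraction, ratio.
#' @export
availability_bias_check <- function(ranks, library, top_n = 1000) {
  stopifnot(is.data.frame(ranks), top_n <= nrow(ranks))
  avail <- stats::setNames(isTRUE_vec(library$available), library$compound_id)
  global <- mean(avail)
  frac <- function(rank_col) {
    ids <- ranks$compound_id[ranks[[rank_col]] <= top_n]
    mean(avail[ids])
  }
  out <- data.frame(
    model = c("ti", "pi"),
    top_fraction = c(frac("rank_ti"), frac("rank_pi")),
    global_fraction = global,
    stringsAsFactors = FALSE
  )
  out$ratio <- out$top_fraction / out$global_fraction
  out
}
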