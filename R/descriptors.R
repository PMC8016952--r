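#' Extract the largest covalently connected fragment of a SMILES
#'
#' Multi-component structures (salts, mixtures) are reduced to the component
#' with the most heavy atoms before any descriptor calculation. Ties are
#' broken by higher molecular weight, then by the lexicographically smaller
#' canonical SMILES, so the choice is deterministic. Single-fragment input is
#' returned unchanged.
#'
#' @param structure a single SMILES string.
#' @return the SMILES of the largest fragment, as written in the input.
#' @examples
#' \dontrun{
#' largest_fragment("CCO.[Na+]")   # "CCO"
#' }
#' @export
largest_fragment <- function(structure) {
  stopifnot(is.character(structure), length(structure) == 1)
  frags <- strsplit(structure, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 0) stop("empty structure")
  if (length(frags) == 1) return(structure)
  canonical_smiles(frags)   # validates every fragment, errors name offenders
  heavy <- vapply(frags, smiles_heavy_atoms, numeric(1), USE.NAMES = FALSE)
  cand <- which(heavy == max(heavy))
  if (length(cand) > 1) {
    mw <- vapply(cand, function(i) graph_mw(fragment_graph(frags[i])), numeric(1))
    cand <- cand[mw == max(mw)]
    if (length(cand) > 1) {
      can <- canonical_smiles(frags[cand])
      cand <- cand[order(can)][1]
    }
  }
  frags[cand[1]]
}

# graph of a single-fragment SMILES, with the single-atom fallback
#' @noRd
fragment_graph <- function(smiles) {
  info <- single_atom_info(smiles)
  if (!is.null(info)) return(graph_from_single_atom(info))
  mol_graph(parse_molecules(smiles, "x")[[1]])
}

#' Compute descriptors for a set of structures
#'
#' For each structure the largest fragment is taken and five molecular
#' properties (molecular weight, an atom-contribution logP, number of
#' hydrogen-bond acceptors, donors, and rotatable bonds) plus a
#' functional-class circular fingerprint are computed. The fingerprint is a
#' radius-3 (diameter-6) iterative neighbourhood hash over pharmacophoric
#' atom roles (H-donor, H-acceptor, positively/negatively ionizable,
#' aromatic, halogen) with sparse, unfolded integer identifiers; it is the
#' package's analogue of the FCFP_6 fingerprint, and the donor/acceptor
#' property counts use the same atom roles as the fingerprint for
#' consistency. Molecular weight and logP come from OpenBabel.
#'
#' @param smiles character vector of SMILES.
#' @param ids optional compound identifiers (defaults to names or cmp1..n).
#' @param radius fingerprint radius (default 3).
#' @param bits optional list of already-computed fingerprint bit vectors
#'   (entries may be `NULL`); missing ones are computed.
#' @return an object of class `lbvs_features`: a list with `ids`, `smiles`,
#'   `props` (data frame with columns mw, alogp, n_hba, n_hbd, n_rotatable)
#'   and `bits` (list of sorted integer fingerprint-bit identifiers).
#' @export
featurize_set <- function(smiles, ids = names(smiles), radius = 3L,
                          bits = NULL) {
  stopifnot(length(smiles) > 0)
  if (is.null(ids)) ids <- paste0("cmp", seq_along(smiles))
  lf <- vapply(as.character(smiles), largest_fragment, character(1), USE.NAMES = FALSE)
  single <- lapply(lf, single_atom_info)
  is_single <- !vapply(single, is.null, logical(1))
  graphs <- vector("list", length(lf))
  mw <- alogp <- numeric(length(lf))
  if (any(is_single)) {
    graphs[is_single] <- lapply(single[is_single], graph_from_single_atom)
    mw[is_single] <- vapply(graphs[is_single], graph_mw, numeric(1))
    alogp[is_single] <- 0   # atom-contribution logP is meaningless for bare atoms
  }
  if (any(!is_single)) {
    sdf <- parse_molecules(lf[!is_single], ids[!is_single])
    graphs[!is_single] <- lapply(seq_len(sum(!is_single)), function(i) mol_graph(sdf[[i]]))
    pr <- ChemmineR::propOB(sdf)
    mw[!is_single] <- pr$MW
    alogp[!is_single] <- pr$logP
  }
  props <- data.frame(
    mw = mw,
    alogp = alogp,
    n_hba = vapply(graphs, function(g) sum(bitwAnd(g$classes, 2L) > 0), numeric(1)),
    n_hbd = vapply(graphs, function(g) sum(bitwAnd(g$classes, 1L) > 0), numeric(1)),
    n_rotatable = vapply(graphs, function(g) as.numeric(graph_rotatable(g)), numeric(1)),
    row.names = ids
  )
  if (is.null(bits)) bits <- vector("list", length(lf))
  stopifnot(length(bits) == length(lf))
  todo <- vapply(bits, is.null, logical(1))
  bits[todo] <- lapply(graphs[todo], mol_fingerprint, radius = as.integer(radius))
  names(bits) <- ids
  structure(list(ids = ids, smiles = as.character(smiles), props = props,
                 bits = bits),
            class = "lbvs_features")
}

#' Compute the feature vector of a single structure
#'
#' @inheritParams featurize_set
#' @param structure a single SMILES string.
#' @return a list with elements `mw`, `alogp`, `n_hba`, `n_hbd`,
#'   `n_rotatable` and `fp_bits` (sorted integer identifiers).
#' @export
featurize <- function(structure, radius = 3L) {
  fs <- featurize_set(structure, ids = "x", radius = radius)
  c(as.list(fs$props["x", ]), list(fp_bits = fs$bits[["x"]]))
}

#' Combine feature sets and align them to a set of compound ids
#'
#' Stacks `lbvs_features` objects and reorders the result to `ids`; every id
#' must be present in exactly one input.
#'
#' @param feature_sets list of `lbvs_features` objects.
#' @param ids compound ids selecting and ordering the output.
#' @return an `lbvs_features` object aligned to `ids`.
#' @export
combine_features <- function(feature_sets, ids) {
  all_ids <- unlist(lapply(feature_sets, `[[`, "ids"), use.names = FALSE)
  if (anyDuplicated(all_ids)) stop("duplicate compound ids across feature sets")
  missing <- setdiff(ids, all_ids)
  if (length(missing)) {
    stop("ids not present in any feature set: ", paste(missing, collapse = ", "))
  }
  smiles <- unlist(lapply(feature_sets, `[[`, "smiles"), use.names = FALSE)
  props <- do.call(rbind, lapply(feature_sets, `[[`, "props"))
  bits <- do.call(c, lapply(feature_sets, `[[`, "bits"))
  ord <- match(ids, all_ids)
  structure(list(ids = all_ids[ord], smiles = smiles[ord],
                 props = props[ord, , drop = FALSE], bits = bits[ord]),
            class = "lbvs_features")
}

#' @export
print.lbvs_features <- function(x, ...) {
  cat("Feature set:", length(x$ids), "compounds,",
      length(unique(unlist(x$bits))), "distinct fingerprint bits\n")
  invisible(x)
}

.bits_of <- function(x) {
  if (is.list(x) && !is.null(x$fp_bits)) x <- x$fp_bits
  if (!is.numeric(x)) stop("expected a fingerprint bit vector or featurize() output")
  x
}

#' Tanimoto similarity of two fingerprints
#'
#' The Tanimoto coefficient |A intersect B| / |A union B| over fingerprint
#' bit sets (the five scalar properties are never part of the similarity).
#'
#' @param a,b fingerprint bit vectors, or outputs of [featurize()].
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- .bits_of(a); b <- .bits_of(b)
  if (length(a) == 0 || length(b) == 0) stop("empty fingerprint bit set")
  ni <- length(intersect(a, b))
  ni / (length(a) + length(b) - ni)
}

.bits_list <- function(x) {
  if (inherits(x, "lbvs_features")) return(x$bits)
  if (is.list(x)) return(lapply(x, .bits_of))
  stop("expected an lbvs_features object or a list of bit vectors")
}

#' Nearest-neighbour similarity against a reference set
#'
#' For each query fingerprint, the maximum Tanimoto similarity over the
#' reference set and the index of the closest reference compound (ties go to
#' the lowest index). Computed with sparse bit-incidence matrices so large
#' query/reference sets stay fast.
#'
#' @param query_set,reference_set `lbvs_features` objects or lists of bit
#'   vectors.
#' @return data frame with columns `similarity` and `ref_index`.
#' @export
nearest_neighbor_similarity <- function(query_set, reference_set) {
  qb <- .bits_list(query_set); rb <- .bits_list(reference_set)
  if (length(qb) == 0 || length(rb) == 0) stop("empty query or reference set")
  sizes_q <- lengths(qb); sizes_r <- lengths(rb)
  if (any(sizes_q == 0) || any(sizes_r == 0)) stop("empty fingerprint bit set")
  univ <- sort(unique(c(unlist(qb, use.names = FALSE), unlist(rb, use.names = FALSE))))
  Q <- Matrix::sparseMatrix(
    i = match(unlist(qb, use.names = FALSE), univ),
    j = rep(seq_along(qb), sizes_q), x = 1,
    dims = c(length(univ), length(qb)))
  R <- Matrix::sparseMatrix(
    i = match(unlist(rb, use.names = FALSE), univ),
    j = rep(seq_along(rb), sizes_r), x = 1,
    dims = c(length(univ), length(rb)))
  inter <- as.matrix(Matrix::crossprod(Q, R))             # |A n B|
  uni <- outer(sizes_q, sizes_r, `+`) - inter             # |A u B|
  sim <- inter / uni
  idx <- apply(sim, 1, which.max)
  data.frame(similarity = sim[cbind(seq_along(qb), idx)], ref_index = idx)
}

#' Freeze a feature space from a training set
#'
#' The model feature space is the five property names plus every distinct
#' fingerprint bit observed in the training set, in sorted order. It is
#' built from training data only and frozen; bits never seen in training are
#' dropped at projection time.
#'
#' @param training an `lbvs_features` object for the training compounds.
#' @return an object of class `lbvs_feature_space`.
#' @export
build_feature_space <- function(training) {
  stopifnot(inherits(training, "lbvs_features"), length(training$ids) > 0)
  structure(list(
    properties = c("mw", "alogp", "n_hba", "n_hbd", "n_rotatable"),
    bits = sort(unique(unlist(training$bits, use.names = FALSE)))
  ), class = "lbvs_feature_space")
}

#' @export
print.lbvs_feature_space <- function(x, ...) {
  cat("Feature space: 5 properties +", length(x$bits), "fingerprint bits =",
      5 + length(x$bits), "features\n")
  invisible(x)
}

#' Number of features in a feature space
#' @param space an `lbvs_feature_space`.
#' @return integer feature count (5 + number of bits).
#' @export
feature_space_size <- function(space) {
  stopifnot(inherits(space, "lbvs_feature_space"))
  length(space$properties) + length(space$bits)
}

#' Project feature vectors into a frozen feature space
#'
#' @param space an `lbvs_feature_space`.
#' @param features an `lbvs_features` object.
#' @return numeric matrix, one row per compound, columns = properties then
#'   bit indicator columns (0/1).
#' @export
project_features <- function(space, features) {
  stopifnot(inherits(space, "lbvs_feature_space"), inherits(features, "lbvs_features"))
  n <- length(features$ids)
  bitmat <- matrix(0, n, length(space$bits))
  for (i in seq_len(n)) {
    bitmat[i, ] <- as.numeric(space$bits %in% features$bits[[i]])
  }
  m <- cbind(as.matrix(features$props[, space$properties, drop = FALSE]), bitmat)
  colnames(m) <- c(space$properties, paste0("fcfp_", space$bits))
  rownames(m) <- features$ids
  m
}
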