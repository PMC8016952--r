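# Internal chemistry layer: SMILES parsing, canonicalisation and perception
# of the atom-level features the functional-class fingerprint needs.
# Parsing, canonical SMILES and molecular properties are delegated to
# OpenBabel through ChemmineR/ChemmineOB; everything downstream works on a
# plain R graph representation extracted from the kekulised SDF blocks.

MODP <- 2147483647   # 2^31 - 1; all hash arithmetic stays < 2^53 in doubles
HASHP <- 1009

hmix <- function(h, x) (h * HASHP + x) %% MODP

ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.086, P = 30.974, S = 32.065,
  Cl = 35.453, K = 39.098, Ca = 40.078, Se = 78.971, Br = 79.904, I = 126.904
)

# default valences used to infer implicit hydrogen counts on the kekulised
# heavy-atom graph; elements not listed get no implicit hydrogens
DEFAULT_VALENCE <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1, Se = 2
)

HALOGENS <- c("F", "Cl", "Br", "I")

# count heavy (non-hydrogen) atoms by lexing SMILES atom tokens; bracket
# atoms count unless they are bare hydrogens
#' @noRd
smiles_heavy_atoms <- function(smiles) {
  brackets <- regmatches(smiles, gregexpr("\\[[^]]*\\]", smiles))[[1]]
  rest <- gsub("\\[[^]]*\\]", "", smiles)
  organic <- regmatches(rest, gregexpr("Cl|Br|[BCNOPSFI]|[bcnops]", rest))[[1]]
  n_br <- sum(!grepl("^\\[[0-9]*H[0-9]*[+-]?[0-9]*\\]$", brackets))
  n_br + length(organic)
}

# parse a SMILES that is one single heavy atom (e.g. "O", "[Na+]", "[NH4+]");
# returns element, implicit/explicit H count and charge, or NULL if the
# SMILES is not a single atom
#' @noRd
single_atom_info <- function(smiles) {
  if (smiles_heavy_atoms(smiles) != 1) return(NULL)
  m <- regmatches(smiles, regexec(
    "^\\[([A-Z][a-z]?|[cnops])(H([0-9]?))?(([+-])([0-9]?)|(\\+\\+)|(--))?\\]$", smiles))[[1]]
  if (length(m) > 0) {
    elem <- m[2]
    nH <- if (nzchar(m[3])) {
      if (nzchar(m[4])) as.integer(m[4]) else 1L
    } else 0L
    charge <- 0L
    if (nzchar(m[5])) {
      if (m[5] %in% c("++", "--")) {
        charge <- if (m[5] == "++") 2L else -2L
      } else {
        mag <- if (nzchar(m[7])) as.integer(m[7]) else 1L
        charge <- if (m[6] == "+") mag else -mag
      }
    }
    return(list(elem = toupper(substr(elem, 1, 1)) %+% substring(elem, 2),
                nH = nH, charge = charge))
  }
  if (grepl("^(Cl|Br|[BCNOPSFI])$", smiles)) {
    dv <- DEFAULT_VALENCE[smiles]
    return(list(elem = smiles, nH = as.integer(if (is.na(dv)) 0 else dv), charge = 0L))
  }
  NULL
}

`%+%` <- function(a, b) paste0(a, b)

# graph stand-in for a single-atom molecule (ChemmineR's SDF reader rejects
# zero-bond molecules, so these never go through it)
#' @noRd
graph_from_single_atom <- function(info) {
  elem <- info$elem
  nH <- info$nH
  donor <- elem %in% c("N", "O") && nH >= 1
  acceptor <- elem %in% c("N", "O")
  pos_ion <- elem == "N"
  halogen <- elem %in% HALOGENS
  classes <- 1L * donor + 2L * acceptor + 4L * pos_ion + 32L * halogen
  list(elem = elem, n = 1L,
       bonds = matrix(integer(0), 0, 3, dimnames = list(NULL, c("i", "j", "order"))),
       adj = list(NULL), nH = nH, arom = FALSE, in_ring = FALSE,
       ring_bond = logical(0), heavy_deg = 0L, dbl_to_O = FALSE,
       acyl_N = FALSE, classes = classes)
}

#' @noRd
parse_molecules <- function(smiles, ids = names(smiles)) {
  if (is.null(ids)) ids <- paste0("cmp", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  smiles <- as.character(smiles)
  names(smiles) <- ids
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL
  )
  bad_individually <- function() {
    ids[vapply(smiles, function(s) {
      r <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(s, "x"))),
                    error = function(e) e)
      inherits(r, "error") || !all(suppressWarnings(ChemmineR::validSDF(r)))
    }, logical(1))]
  }
  if (is.null(sdf)) {
    stop("unparseable SMILES for compound(s): ", paste(bad_individually(), collapse = ", "))
  }
  ChemmineR::cid(sdf) <- ids
  ok <- suppressWarnings(ChemmineR::validSDF(sdf))
  if (!all(ok)) {
    stop("unparseable SMILES for compound(s): ", paste(ids[!ok], collapse = ", "))
  }
  sdf
}

#' @noRd
canonical_smiles <- function(smiles, ids = NULL) {
  if (length(smiles) == 0) return(character(0))
  if (is.null(ids)) ids <- paste0("c", seq_along(smiles))
  conv <- function(s, id) {
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", source = paste0(paste(s, id), collapse = "\n")),
      error = function(e) "")
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines[nzchar(lines)]
  }
  lines <- conv(smiles, ids)
  if (length(lines) != length(smiles)) {
    # OpenBabel aborts batch conversion on a bad line: find the offenders
    bad <- ids[vapply(seq_along(smiles),
                      function(i) length(conv(smiles[i], ids[i])) != 1, logical(1))]
    stop("unparseable SMILES for compound(s): ", paste(bad, collapse = ", "))
  }
  vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1L)
}

# Extract a plain graph from one SDF molecule: elements, bond matrix,
# implicit H counts, aromaticity and pharmacophoric atom classes.
#' @noRd
mol_graph <- function(sdfmol) {
  ab <- ChemmineR::atomblock(sdfmol)
  elem <- sub("_[0-9]+$", "", rownames(ab))
  n <- length(elem)
  bb <- ChemmineR::bondblock(sdfmol)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = as.integer(length(bb) > 0), byrow = TRUE)
  bonds <- if (nrow(bb) > 0) {
    cbind(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]), order = as.integer(bb[, 3]))
  } else {
    matrix(integer(0), 0, 3, dimnames = list(NULL, c("i", "j", "order")))
  }

  arom <- logical(n)
  arom_bond <- logical(nrow(bonds))
  in_ring <- logical(n)
  ring_bond <- logical(nrow(bonds))
  rg <- ChemmineR::rings(sdfmol, type = "all", arom = TRUE)
  bond_key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  if (!is.null(rg$RINGS) && length(rg$RINGS) > 0) {
    for (k in seq_along(rg$RINGS)) {
      ring_idx <- as.integer(sub("^[A-Za-z]+_", "", rg$RINGS[[k]]))
      in_ring[ring_idx] <- TRUE
      pairs <- cbind(ring_idx, c(ring_idx[-1], ring_idx[1]))
      keys <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
      hit <- bond_key %in% keys
      ring_bond <- ring_bond | hit
      if (isTRUE(rg$AROMATIC[[k]])) {
        arom[ring_idx] <- TRUE
        arom_bond <- arom_bond | hit
      }
    }
  }

  val_sum <- numeric(n)
  heavy_deg <- integer(n)
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      val_sum[bonds[r, 1]] <- val_sum[bonds[r, 1]] + bonds[r, 3]
      val_sum[bonds[r, 2]] <- val_sum[bonds[r, 2]] + bonds[r, 3]
      heavy_deg[bonds[r, 1]] <- heavy_deg[bonds[r, 1]] + 1L
      heavy_deg[bonds[r, 2]] <- heavy_deg[bonds[r, 2]] + 1L
    }
  }
  dv <- DEFAULT_VALENCE[elem]
  dv[is.na(dv)] <- 0
  nH <- pmax(0, dv - val_sum)

  # adjacency with bond orders (aromatic bonds normalised to a common type so
  # the fingerprint is invariant to the kekulisation OpenBabel happens to pick)
  adj <- vector("list", n)
  horder <- ifelse(arom_bond, 4L, bonds[, 3])
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      adj[[i]] <- rbind(adj[[i]], c(j, horder[r]))
      adj[[j]] <- rbind(adj[[j]], c(i, horder[r]))
    }
  }

  # pharmacophoric atom classes (functional-class fingerprint roles)
  dbl_to_O <- logical(n)  # atom has a double bond to an oxygen
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      if (bonds[r, 3] == 2L) {
        if (elem[bonds[r, 2]] == "O") dbl_to_O[bonds[r, 1]] <- TRUE
        if (elem[bonds[r, 1]] == "O") dbl_to_O[bonds[r, 2]] <- TRUE
      }
    }
  }
  acyl_N <- logical(n)     # N bonded to a C/S/P carrying a double-bonded O
  neg_ion <- logical(n)    # acidic O-H: hydroxyl on an atom that also bears =O
  for (a in seq_len(n)) {
    nb <- adj[[a]]
    if (is.null(nb)) next
    if (elem[a] == "N" && any(dbl_to_O[nb[, 1]] & elem[nb[, 1]] %in% c("C", "S", "P"))) {
      acyl_N[a] <- TRUE
    }
    if (elem[a] == "O" && nH[a] >= 1 && any(dbl_to_O[nb[, 1]])) neg_ion[a] <- TRUE
  }
  all_single <- vapply(seq_len(n), function(a) {
    nb <- adj[[a]]
    is.null(nb) || all(nb[, 2] == 1L)
  }, logical(1))

  donor <- elem %in% c("N", "O") & nH >= 1
  acceptor <- elem == "O" | (elem == "N" & !(arom & nH >= 1) & !acyl_N)
  pos_ion <- elem == "N" & !arom & all_single & !acyl_N
  halogen <- elem %in% HALOGENS

  classes <- 1L * donor + 2L * acceptor + 4L * pos_ion + 8L * neg_ion +
    16L * arom + 32L * halogen

  list(elem = elem, n = n, bonds = bonds, adj = adj, nH = nH, arom = arom,
       in_ring = in_ring, ring_bond = ring_bond, heavy_deg = heavy_deg,
       dbl_to_O = dbl_to_O, acyl_N = acyl_N, classes = classes)
}

# exact monoisotopic-free molecular weight from the heavy-atom graph
#' @noRd
graph_mw <- function(g) {
  m <- ATOMIC_MASS[g$elem]
  m[is.na(m)] <- 0
  sum(m) + sum(g$nH) * ATOMIC_MASS[["H"]]
}

# rotatable bonds: acyclic single bonds between two non-terminal heavy atoms,
# amide C-N bonds excluded
#' @noRd
graph_rotatable <- function(g) {
  if (nrow(g$bonds) == 0) return(0L)
  rot <- 0L
  for (r in seq_len(nrow(g$bonds))) {
    i <- g$bonds[r, 1]; j <- g$bonds[r, 2]
    if (g$bonds[r, 3] != 1L || g$ring_bond[r]) next
    if (g$heavy_deg[i] < 2L || g$heavy_deg[j] < 2L) next
    amide <- (g$elem[i] == "N" && g$elem[j] == "C" && g$dbl_to_O[j]) ||
      (g$elem[j] == "N" && g$elem[i] == "C" && g$dbl_to_O[i])
    if (!amide) rot <- rot + 1L
  }
  rot
}

# Functional-class circular fingerprint: iterative neighbourhood hashing of
# the pharmacophoric atom classes out to the given radius (radius 3 is the
# diameter-6 analogue). Identifiers are sparse hashed integers; the set of
# distinct identifiers over all atoms and radii is returned.
#' @noRd
mol_fingerprint <- function(g, radius = 3L) {
  codes <- as.numeric(g$classes)
  bits <- codes
  if (g$n > 0 && radius > 0) {
    for (r in seq_len(radius)) {
      newc <- numeric(g$n)
      for (a in seq_len(g$n)) {
        h <- hmix(hmix(7, r), codes[a])
        nb <- g$adj[[a]]
        if (!is.null(nb)) {
          pairs <- cbind(nb[, 2], codes[nb[, 1]])
          ord <- order(pairs[, 1], pairs[, 2])
          for (k in ord) h <- hmix(hmix(h, pairs[k, 1]), pairs[k, 2])
        }
        newc[a] <- h
      }
      codes <- newc
      bits <- c(bits, codes)
    }
  }
  sort(unique(as.integer(bits)))
}
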