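# Descriptor layer: largest fragment, properties, the functional-class
# circular fingerprint, Tanimoto and nearest-neighbour search.

test_that("largest_fragment keeps the component with most heavy atoms", {
  expect_identical(largest_fragment("CCO.[Na+]"), "CCO")
  expect_identical(largest_fragment("CCO"), "CCO")            # identity
  expect_identical(largest_fragment("[Na+].CC(=O)O"), "CC(=O)O")
  expect_error(largest_fragment("C1CC.CC"), "unparseable")
})

test_that("largest_fragment ties break by weight then canonical SMILES", {
  # equal heavy atoms, different mass: CCS (62.1 Da) beats CCO (46.1 Da)
  expect_identical(largest_fragment("CCO.CCS"), "CCS")
  expect_identical(largest_fragment("CCS.CCO"), "CCS")
  # equal heavy atoms and equal weight: lexicographically smaller canonical
  # SMILES, independent of input order
  pick1 <- largest_fragment("CCN.CNC")
  pick2 <- largest_fragment("CNC.CCN")
  expect_identical(sort(c(pick1, pick2))[1], pick1)
  expect_identical(pick1, pick2)
})

test_that("featurize matches simple physical expectations", {
  benzene <- featurize("c1ccccc1")
  expect_equal(benzene$n_hbd, 0)
  expect_equal(benzene$n_hba, 0)
  expect_equal(benzene$n_rotatable, 0)
  expect_gt(length(benzene$fp_bits), 0)

  water <- featurize("O")
  expect_equal(water$mw, 18.02, tolerance = 0.1 / 18.02)

  # atom-contribution logP orders hydrophobic above hydrophilic molecules
  expect_gt(featurize("CCCCCCCC")$alogp, featurize("OCC(O)CO")$alogp)

  # a salt is reduced to its largest fragment before properties
  expect_equal(featurize("CCO.[Na+]")$mw, featurize("CCO")$mw)
})

test_that("featurization is invariant to SMILES atom ordering", {
  mols <- c("CC(=O)Nc1ccc(Cl)cc1C(=O)N1CCC(C(=O)O)CC1",
            "O=S(=O)(N)c1ccc2ccccc2c1", "CCOC(=O)c1ccco1",
            "c1ccc(-c2ccccc2)cc1", "CN1CCN(C(=O)c2cccnc2)CC1")
  for (smi in mols) {
    ref <- featurize(smi)
    # re-express the molecule from randomly rewritten SMILES: convert to
    # SDF, permute atom order, convert back
    sdf <- ppilbvs:::parse_molecules(smi, "x")
    for (rep in 1:20) {
      alt <- ppilbvs:::with_seed(rep, {
        ab <- ChemmineR::atomblock(sdf[[1]])
        perm <- sample(nrow(ab))
        inv <- order(perm)
        bb <- ChemmineR::bondblock(sdf[[1]])
        bb[, 1] <- inv[bb[, 1]]; bb[, 2] <- inv[bb[, 2]]
        s2 <- sdf
        ChemmineR::atomblock(s2) <- list(x = ab[perm, , drop = FALSE])
        ChemmineR::bondblock(s2) <- list(x = bb)
        ChemmineOB::convertFormat("SDF", "SMI",
                                  paste(ChemmineR::sdf2str(s2[[1]]),
                                        collapse = "\n"))
      })
      alt <- sub("\t.*", "", strsplit(alt, "\n")[[1]][1])
      alt_fp <- featurize(alt)
      expect_identical(alt_fp$fp_bits, ref$fp_bits)
      expect_equal(alt_fp$n_hba, ref$n_hba)
      expect_equal(alt_fp$n_hbd, ref$n_hbd)
    }
  }
})

test_that("tanimoto implements set arithmetic and its invariants", {
  expect_equal(tanimoto(c(1L, 2L, 5L), c(1L, 2L, 5L)), 1.0)
  expect_equal(tanimoto(c(1L, 2L), c(3L, 4L)), 0.0)
  # |intersection| = 3, |a| = 5, |b| = 6 -> 3/8
  expect_equal(tanimoto(1:5, c(1L, 2L, 3L, 7L, 8L, 9L)), 0.375)
  expect_error(tanimoto(integer(0), 1:3), "empty")

  brute <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  ppilbvs:::with_seed(42, {
    for (i in 1:200) {
      a <- sample(1:50, sample(1:20, 1))
      b <- sample(1:50, sample(1:20, 1))
      s <- tanimoto(a, b)
      expect_equal(s, brute(a, b))
      expect_equal(s, tanimoto(b, a))     # symmetry
      expect_gte(s, 0); expect_lte(s, 1)  # range
    }
  })
})

test_that("nearest-neighbour search equals brute force on random sets", {
  ppilbvs:::with_seed(7, {
    q <- lapply(1:20, function(i) sort(sample(1:80, sample(5:25, 1))))
    r <- lapply(1:20, function(i) sort(sample(1:80, sample(5:25, 1))))
    got <- nearest_neighbor_similarity(q, r)
    for (i in seq_along(q)) {
      sims <- vapply(r, function(b) tanimoto(q[[i]], b), numeric(1))
      expect_equal(got$similarity[i], max(sims))
      expect_equal(got$ref_index[i], which.max(sims))  # ties: lowest index
    }
  })
  # a query present in the reference scores exactly 1
  one <- nearest_neighbor_similarity(list(c(1L, 5L)), list(c(9L), c(1L, 5L)))
  expect_equal(one$similarity, 1.0)
  expect_equal(one$ref_index, 2L)
  expect_error(nearest_neighbor_similarity(list(1:3), list()), "empty")
})

test_that("feature space is frozen from training data and sized exactly", {
  tr <- fake_features(10, n_bits = 20, seed = 3)
  sp <- build_feature_space(tr)
  n_distinct <- length(unique(unlist(tr$bits)))
  expect_equal(feature_space_size(sp), 5 + n_distinct)

  m <- project_features(sp, tr)
  expect_equal(dim(m), c(10, 5 + n_distinct))
  # a training compound reproduces its own bits
  for (i in 1:10) {
    on <- sp$bits[m[i, -(1:5)] == 1]
    expect_identical(on, tr$bits[[i]])
  }
  # unseen bits are dropped at projection
  te <- fake_features(3, ids = c("t1", "t2", "t3"), bit_pool = 10000:10100,
                      seed = 4)
  expect_true(all(project_features(sp, te)[, -(1:5)] == 0))
})
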