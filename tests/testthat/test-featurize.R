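# Physicochemical profile, descriptors, fingerprints, QED, diversity stats.

test_that("physicochemical profile matches hand-derivable values", {
  p <- physchem_profile(c("c1ccccc1", "O", "CCO"))
  expect_equal(p$tpsa[1], 0)
  expect_equal(p$mw[2], 18.015, tolerance = 1e-3)
  expect_equal(p$hbd[3], 1L)
  expect_equal(p$hba[3], 1L)
  expect_equal(p$nrot[3], 0L)
  expect_true(all(is.finite(as.matrix(p))))
})

test_that("logP and TPSA reproduce the published atom-contribution values", {
  ref <- qed_reference()
  expect_equal(crippen_logp(ref$smiles), ref$ALOGP, tolerance = 1e-6)
  expect_equal(tpsa(ref$smiles), ref$PSA, tolerance = 1e-6)
  expect_equal(mol_weight(ref$smiles), ref$MW, tolerance = 1e-2)
})

test_that("descriptor vector has the pinned length, is finite and deterministic", {
  smis <- c("CC(=O)Oc1ccccc1C(=O)O", "CCO")
  m1 <- descriptor_matrix(smis)
  expect_equal(dim(m1), c(2L, 200L))
  expect_equal(colnames(m1), descriptor_names())
  expect_true(all(is.finite(m1)))
  expect_identical(m1, descriptor_matrix(smis))
})

test_that("descriptor z-scaler gives mean 0 / sd 1 on its training set", {
  x <- generate_endpoint_dataset(50, effect = 1, seed = 3)
  m <- as.matrix(x[-1])
  sc <- fit_descriptor_scaler(m)
  z <- apply_descriptor_scaler(m, sc)
  expect_equal(unname(colMeans(z)), rep(0, 200), tolerance = 1e-10)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 200), tolerance = 1e-10)
  # zero-variance features map to 0
  m2 <- cbind(m[, -1, drop = FALSE], const = 5)
  z2 <- apply_descriptor_scaler(m2, fit_descriptor_scaler(m2))
  expect_true(all(z2[, "const"] == 0))
})

test_that("fingerprints have the contracted lengths and are deterministic", {
  smis <- c("CCO", "CC(=O)Oc1ccccc1C(=O)O")
  widths <- c(MACCS = 166L, Morgan = 2048L, AtomPairs = 2048L,
              RDKFingerprint = 2048L, TopoTorsion = 2048L)
  for (k in names(widths)) {
    fp <- fingerprint(smis, k)
    expect_equal(ncol(fp), widths[[k]], info = k)
    expect_true(all(fp %in% c(0L, 1L)), info = k)
    expect_identical(fp, fingerprint(smis, k), info = k)
    expect_gt(sum(fp), 0)
  }
  expect_error(fingerprint("CCO", "nope"))
})

test_that("tanimoto matrix matches a brute-force bit-set oracle", {
  smis <- c("CCO", "c1ccccc1", "CC(=O)O", "CCN", "CCCCO")
  ts <- tanimoto_stats(smis)
  fp <- fingerprint(smis, "MACCS")
  # oracle: explicit set arithmetic per pair
  for (i in 1:4) for (j in (i + 1):5) {
    a <- which(fp[i, ] == 1); b <- which(fp[j, ] == 1)
    expect_equal(ts$matrix[i, j],
                 length(intersect(a, b)) / length(union(a, b)))
  }
  expect_equal(diag(ts$matrix), rep(1, 5))
  expect_equal(ts$matrix, t(ts$matrix))
  expect_equal(ts$mean_similarity,
               mean(ts$matrix[upper.tri(ts$matrix)]))
  expect_equal(tanimoto_stats(c("CCO", "CCO"))$mean_similarity, 1)
  expect_error(tanimoto_stats("CCO"), "two")
})

test_that("Murcko scaffolds match independently derived frameworks", {
  # expected scaffolds cross-checked against a reference implementation
  cases <- list(
    c("Cc1ccccc1", "c1ccccc1"),                   # toluene -> benzene
    c("CC(=O)Oc1ccccc1C(=O)O", "c1ccccc1"),       # aspirin
    c("O=C(c1ccccc1)c1ccccc1", "O=C(c1ccccc1)c1ccccc1"),  # benzophenone
    c("COc1ccc2cc(C(C)C(=O)O)ccc2c1", "c1ccc2ccccc2c1"),  # naproxen
    c("CN1c2ccc(Cl)cc2C(=Nc3ccccc3)CC1=O",
      "O=C1CC(=Nc2ccccc2)c2ccccc2N1"),            # diazepam
    c("CC(C)NCC(O)COc1cccc2ccccc12", "c1ccc2ccccc2c1")    # propranolol
  )
  for (cs in cases) {
    expect_equal(murcko_scaffold(cs[1]), canonical_smiles(cs[2]),
                 info = cs[1])
  }
  expect_equal(murcko_scaffold("CCO"), "")
})

test_that("Murcko summary partitions the molecule set", {
  std <- test_fixtures_std()
  s <- murcko_summary(std$canonical_smiles)
  expect_equal(s$n_molecules, nrow(std))
  expect_equal(sum(s$scaffold_counts) + s$acyclic_count, s$n_molecules)
  expect_lte(s$n_scaffolds, s$n_molecules)
  s2 <- murcko_summary(c("Cc1ccccc1", "c1ccccc1", "CCO"))
  expect_equal(s2$n_scaffolds, 1L)
  expect_equal(s2$acyclic_count, 1L)
  expect_equal(unname(s2$scaffold_counts), 2L)
})

test_that("QED agrees with the independent reference implementation", {
  ref <- qed_reference()
  props <- qed_properties(ref$smiles)
  expect_equal(props$HBA, ref$HBA)
  expect_equal(props$HBD, ref$HBD)
  expect_equal(props$ROTB, ref$ROTB)
  expect_equal(props$AROM, ref$AROM)
  expect_equal(props$ALERTS, ref$ALERTS)
  q <- qed_score(ref$smiles, properties = props)
  expect_lt(max(abs(q - ref$qed)), 1e-3)
  expect_true(all(q > 0 & q < 1))
  # extreme chain: desirability collapse
  expect_lt(qed_score("CCCCCCCCCCCCCCCCCCCCCCCCCCCCCC"), 0.3)
  expect_equal(qed_score("CC(=O)Oc1ccccc1C(=O)O"), 0.55, tolerance = 0.01)
})

test_that("featurizers are pure functions of the canonical SMILES", {
  # equivalent SMILES spellings give identical features
  a <- "c1ccccc1CCO"; b <- "OCCc1ccccc1"
  expect_identical(descriptor_matrix(a), descriptor_matrix(b))
  expect_identical(fingerprint(a, "Morgan"), fingerprint(b, "Morgan"))
  expect_equal(qed_score(a), qed_score(b))
})
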