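# Standardization, deduplication and dataset assembly.

test_that("standardize handles clean, salted and rejected inputs", {
  res <- standardize_smiles(c("CCO", "CCO.Cl", "[Na+].[Cl-]",
                              "C1CC", "c1ccccc1.NCCCC"))
  expect_equal(res$status, c("accepted", "accepted", "rejected",
                             "rejected", "rejected"))
  expect_equal(res$canonical_smiles[1], "CCO")
  expect_equal(res$canonical_smiles[2], "CCO")
  expect_equal(res$applied_fixes[2], "salt_stripped")
  expect_equal(res$reason[3], "inorganic")
  expect_equal(res$reason[4], "unparseable")
  expect_equal(res$reason[5], "mixture")
})

test_that("charge neutralization converts salts to parent acids/bases", {
  res <- standardize_smiles(c("CC(=O)[O-].[Na+]", "C[NH3+].[Cl-]"))
  expect_equal(res$status, rep("accepted", 2))
  expect_equal(res$canonical_smiles[1], canonical_smiles("CC(=O)O"))
  expect_equal(res$canonical_smiles[2], canonical_smiles("CN"))
  expect_true(all(grepl("salt_stripped", res$applied_fixes)))
  expect_true(all(grepl("neutralized", res$applied_fixes)))
})

test_that("standardization is idempotent on the fixture panel", {
  std <- test_fixtures_std()
  again <- standardize_smiles(std$canonical_smiles)
  expect_equal(again$canonical_smiles, std$canonical_smiles)
  expect_true(all(again$applied_fixes == ""))
})

test_that("deduplication keeps first occurrences and resolves cross-class conflicts", {
  res <- standardize_smiles(c("CCO", "CCO", "OCC", "CCN"),
                            label = c(0, 0, 1, 0))
  expect_message(out <- deduplicate_molecules(res), "cross-class")
  expect_equal(nrow(out), 2L)
  # ethanol written two ways is one structure; the drug label wins
  expect_equal(out$label[out$canonical_smiles == "CCO"], 1)
  # idempotent, never increases length
  expect_equal(deduplicate_molecules(out), out)
  expect_lte(nrow(deduplicate_molecules(out)), nrow(out))
})

test_that("dataset assembly is balanced, seeded and replicate-distinct", {
  pos <- data.frame(canonical_smiles = paste0("P", 1:50))
  neg <- data.frame(canonical_smiles = paste0("N", 1:500))
  d1 <- assemble_dataset(pos, neg, 50, replicate_id = 0, seed = 7)
  expect_equal(nrow(d1), 100L)
  expect_equal(sum(d1$label == 1), 50L)
  expect_equal(sum(d1$label == 0), 50L)
  d1b <- assemble_dataset(pos, neg, 50, replicate_id = 0, seed = 7)
  expect_identical(d1, d1b)
  subsets <- lapply(0:2, function(r) {
    sort(assemble_dataset(pos, neg, 50, replicate_id = r,
                          seed = 7)$canonical_smiles[51:100])
  })
  expect_false(identical(subsets[[1]], subsets[[2]]))
  expect_false(identical(subsets[[1]], subsets[[3]]))
  expect_false(identical(subsets[[2]], subsets[[3]]))
  expect_error(assemble_dataset(pos, neg, 501), "exceeds")
})
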