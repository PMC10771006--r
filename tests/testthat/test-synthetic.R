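# Synthetic fixture generators: determinism, calibration, monotonicity.

test_that("profile generator is fully determined by its seed", {
  cfg <- profile_generator_config(n_per_class = 100, admet_effect = 1,
                                  pc_effect = 0.5, seed = 21)
  g1 <- generate_profiles(cfg)
  g2 <- generate_profiles(cfg)
  expect_identical(g1, g2)
  g3 <- generate_profiles(profile_generator_config(
    n_per_class = 100, admet_effect = 1, pc_effect = 0.5, seed = 22))
  expect_false(identical(g1$pc, g3$pc))
  expect_equal(dim(g1$pc), c(200L, 6L))
  expect_equal(dim(g1$admet), c(200L, 20L))
  expect_true(all(g1$admet >= 0 & g1$admet <= 1))
  expect_equal(sum(g1$label), 100L)
})

test_that("generated ADMET coordinates converge to their latent targets", {
  # oracle: E[plogis(Z)], Z ~ N(mu, sd) by numeric integration
  target <- function(mu, sd) {
    stats::integrate(function(z) plogis(z) * dnorm(z, mu, sd),
                     mu - 10 * sd, mu + 10 * sd)$value
  }
  cfg <- profile_generator_config(n_per_class = 5000, admet_effect = 2,
                                  seed = 31)
  g <- generate_profiles(cfg)
  mu_drug <- target(1, 1)
  mu_non <- target(-1, 1)
  for (j in c(1, 10, 20)) {
    m1 <- mean(g$admet[g$label == 1, j])
    se1 <- sd(g$admet[g$label == 1, j]) / sqrt(5000)
    expect_lt(abs(m1 - mu_drug), 3 * se1)
    m0 <- mean(g$admet[g$label == 0, j])
    se0 <- sd(g$admet[g$label == 0, j]) / sqrt(5000)
    expect_lt(abs(m0 - mu_non), 3 * se0)
  }
})

test_that("downstream CV AUC is monotone in the generative effect size", {
  aucs <- vapply(c(0, 0.5, 1, 2), function(eff) {
    mean(vapply(1:3, function(s) {
      g <- generate_profiles(profile_generator_config(
        n_per_class = 150, admet_effect = eff, seed = 40 + s))
      cv <- cv_dbpp(g$pc, g$admet, g$label, algo = "logistic", k = 3,
                    seed = s)
      cv$mean[["auc"]]
    }, numeric(1)))
  }, numeric(1))
  # allow small simulation error on a short ladder
  expect_true(all(diff(aucs) > -0.03))
  expect_gt(aucs[4], aucs[1] + 0.2)
})

test_that("endpoint dataset generator is balanced, seeded and shaped", {
  d <- generate_endpoint_dataset(600, effect = 3, seed = 1)
  expect_equal(dim(d), c(600L, 201L))
  expect_equal(sum(d$label), 300L)
  expect_identical(d, generate_endpoint_dataset(600, effect = 3, seed = 1))
  expect_equal(names(d)[-1], descriptor_names())
})

test_that("fixture molecules all pass standardization and QED contracts", {
  fx <- fixture_molecules()
  expect_equal(nrow(fx), 40L)
  expect_equal(sum(fx$class == "drug"), 20L)
  std <- test_fixtures_std()
  expect_true(all(std$status == "accepted"))
  expect_equal(std$canonical_smiles[std$name == "aspirin"],
               canonical_smiles("CC(=O)Oc1ccccc1C(=O)O"))
  q <- qed_score(std$canonical_smiles)
  expect_true(all(q > 0 & q < 1))
  fp <- fingerprint(std$canonical_smiles, "MACCS")
  expect_equal(nrow(fp), 40L)
})
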