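# Eq.-style gamma weighting, profile construction and the DBPP classifier.

unit_scaler <- function() fit_pc_scaler(rbind(rep(0, 6), rep(1, 6)))

test_that("gamma weighting follows the hybrid profile formula", {
  sc <- unit_scaler()
  pc1 <- matrix(1, 1, 6); ad1 <- matrix(1, 1, 20)
  # gamma = 0.5: both blocks at unit weight
  expect_equal(unname(build_profile(pc1, ad1, 0.5, sc)[1, ]), rep(1, 26))
  # gamma = 1: physicochemical block zeroed, ADMET doubled
  p1 <- build_profile(pc1, ad1, 1, sc)
  expect_equal(unname(p1[1, 1:6]), rep(0, 6))
  expect_equal(unname(p1[1, 7:26]), rep(2, 20))
  # gamma = 0: ADMET zeroed, physicochemical doubled
  p0 <- build_profile(pc1, ad1, 0, sc)
  expect_equal(unname(p0[1, 1:6]), rep(2, 6))
  expect_equal(unname(p0[1, 7:26]), rep(0, 20))
  # gamma = 0.6 (the default optimum): factors 0.8 and 1.2
  p6 <- build_profile(pc1, ad1, 0.6, sc)
  expect_equal(unname(p6[1, 1:6]), rep(0.8, 6))
  expect_equal(unname(p6[1, 7:26]), rep(1.2, 20))
  expect_error(build_profile(pc1, ad1, 1.2, sc), "gamma")
})

test_that("block norms are linear in gamma and cross at 0.5", {
  sc <- unit_scaler()
  set.seed(1)
  pc <- matrix(runif(6), 1); ad <- matrix(runif(20), 1)
  gs <- c(0, 0.25, 0.5, 0.75, 1)
  norms <- t(vapply(gs, function(g) {
    pr <- build_profile(pc, ad, g, sc)
    c(pc = sqrt(sum(pr[1, 1:6]^2)), admet = sqrt(sum(pr[1, 7:26]^2)))
  }, numeric(2)))
  base_pc <- sqrt(sum(pc^2)); base_ad <- sqrt(sum(ad^2))
  expect_equal(norms[, "pc"], (2 - 2 * gs) * base_pc)
  expect_equal(norms[, "admet"], 2 * gs * base_ad)
  expect_equal(unname(norms[3, "pc"] / base_pc),
               unname(norms[3, "admet"] / base_ad))
})

test_that("physicochemical min-max scaling clips out-of-range queries", {
  tr <- matrix(runif(60, 10, 20), 10, 6)
  sc <- fit_pc_scaler(tr)
  z <- apply_pc_scaler(tr, sc)
  expect_true(all(z >= 0 & z <= 1))
  q <- apply_pc_scaler(matrix(c(0, 100, 15, 15, 15, 15), 1), sc)
  expect_equal(q[1, 1], 0)
  expect_equal(q[1, 2], 1)
})

test_that("block rescaling is absorbed by an unpenalized linear model", {
  # scaling a feature block by c > 0 and dividing the matching weights by c
  # leaves the linear score unchanged; checked with an explicit glm fit
  set.seed(4)
  cfg <- profile_generator_config(n_per_class = 150, admet_effect = 1,
                                  seed = 4)
  g <- generate_profiles(cfg)
  sc <- fit_pc_scaler(g$pc)
  x1 <- build_profile(g$pc, g$admet, 0.5, sc)
  x2 <- build_profile(g$pc, g$admet, 0.8, sc)   # blocks scaled 0.4 / 1.6
  df1 <- data.frame(y = g$label, x1)
  fit1 <- suppressWarnings(glm(y ~ ., data = df1, family = binomial()))
  co <- coef(fit1)
  # manually rescale the weights by the inverse block factors
  co2 <- co
  co2[2:7] <- co[2:7] * (2 - 2 * 0.5) / (2 - 2 * 0.8)
  co2[8:27] <- co[8:27] * (2 * 0.5) / (2 * 0.8)
  eta1 <- co[1] + as.numeric(x1 %*% co[-1])
  eta2 <- co2[1] + as.numeric(x2 %*% co2[-1])
  expect_equal(eta1, eta2, tolerance = 1e-10)
})

test_that("training separates synthetic classes and is deterministic", {
  cfg <- profile_generator_config(n_per_class = 500, admet_effect = 2,
                                  seed = 3)
  g <- generate_profiles(cfg)
  m1 <- train_dbpp(g$pc, g$admet, g$label, seed = 3)
  m2 <- train_dbpp(g$pc, g$admet, g$label, seed = 3)
  s1 <- dbpp_score(m1, pc = g$pc, admet = g$admet)
  s2 <- dbpp_score(m2, pc = g$pc, admet = g$admet)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_gt(mean(s1[g$label == 1]), mean(s1[g$label == 0]))
  expect_error(train_dbpp(g$pc, g$admet, rep(1, nrow(g$pc))), "class")
})

test_that("grid search is recorded and reproducible", {
  cfg <- profile_generator_config(n_per_class = 100, admet_effect = 2,
                                  seed = 5)
  g <- generate_profiles(cfg)
  grid <- data.frame(C = c(0.1, 1, 10))
  m1 <- train_dbpp(g$pc, g$admet, g$label, algo = "logistic", seed = 5,
                   grid = grid)
  m2 <- train_dbpp(g$pc, g$admet, g$label, algo = "logistic", seed = 5,
                   grid = grid)
  expect_equal(m1$grid_record, m2$grid_record)
  expect_equal(nrow(m1$grid_record), 3L)
  expect_identical(m1$classifier$params, m2$classifier$params)
})

test_that("druggability call uses a strict threshold", {
  expect_equal(classify_druggable(c(0.80, 0.50, 0.736)),
               c(TRUE, FALSE, FALSE))
  expect_equal(classify_druggable(0.737, threshold = 0.736), TRUE)
  expect_error(classify_druggable(1.2))
})

test_that("model artifacts round-trip with manifest", {
  cfg <- profile_generator_config(n_per_class = 80, admet_effect = 2,
                                  seed = 6)
  g <- generate_profiles(cfg)
  m <- train_dbpp(g$pc, g$admet, g$label, algo = "logistic", seed = 6)
  path <- tempfile(fileext = ".rds")
  save_dbpp_model(m, path)
  expect_true(file.exists(paste0(path, ".manifest.json")))
  man <- jsonlite::read_json(paste0(path, ".manifest.json"))
  expect_equal(man$gamma, 0.6)
  expect_equal(man$threshold, 0.736)
  m2 <- load_dbpp_model(path)
  expect_equal(dbpp_score(m2, pc = g$pc, admet = g$admet),
               dbpp_score(m, pc = g$pc, admet = g$admet))
})
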