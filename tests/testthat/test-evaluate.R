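# Metrics, AUC, cross-validation, score distributions, PU analysis,
# attributions.

test_that("confusion metrics match direct arithmetic on random counts", {
  m <- confusion_metrics(tp = 90, tn = 80, fp = 20, fn = 10)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$recall, 0.90)
  expect_equal(m$specificity, 0.80)
  expect_equal(m$precision, 90 / 110, tolerance = 1e-12)
  set.seed(1)
  for (i in 1:50) {
    cts <- rpois(4, 20)
    if (sum(cts) == 0) cts[1] <- 1
    m <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(m$accuracy, (cts[1] + cts[2]) / sum(cts))
    if (cts[1] + cts[4] > 0) expect_equal(m$recall, cts[1] / (cts[1] + cts[4]))
    if (cts[2] + cts[3] > 0) expect_equal(m$specificity, cts[2] / (cts[2] + cts[3]))
    if (cts[1] + cts[3] > 0) expect_equal(m$precision, cts[1] / (cts[1] + cts[3]))
    # identity: accuracy decomposes over class prevalences
    P <- cts[1] + cts[4]; N <- cts[2] + cts[3]
    if (P >= 1 && N >= 1) {
      expect_equal(m$accuracy, (m$recall * P + m$specificity * N) / (P + N))
    }
  }
})

test_that("undefined metrics are marked, not silently zero", {
  m <- confusion_metrics(tp = 0, tn = 10, fp = 0, fn = 5)
  expect_true(is.na(m$precision))
  m2 <- confusion_metrics(tp = 50, tn = 50, fp = 0, fn = 0)
  expect_equal(unlist(m2[c("accuracy", "recall", "specificity",
                           "precision", "f1")]),
               c(accuracy = 1, recall = 1, specificity = 1,
                 precision = 1, f1 = 1))
  expect_error(confusion_metrics(0, 0, 0, 0), "zero")
})

brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

test_that("roc_auc equals exhaustive pair counting incl. ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0)
  set.seed(7)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0.1, 0.5, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(roc_auc(scores, labels), brute_auc(scores, labels))
  }
  expect_error(roc_auc(c(1, 2), c(1, 1)), "class")
})

test_that("roc_auc is invariant under strictly increasing transforms", {
  set.seed(8)
  scores <- runif(50); labels <- rbinom(50, 1, 0.5)
  labels[1:2] <- c(0, 1)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(qlogis(scores), labels), a)
  expect_equal(roc_auc(scores^3 + 2 * scores, labels), a)
})

test_that("k-fold partitions are stratified, disjoint and seeded", {
  y <- rep(c(0, 1), each = 100)
  cv <- kfold_cv(y, function(tr, te) runif(length(te)), k = 10, seed = 2)
  folds <- cv$folds
  expect_equal(sort(unique(folds)), 1:10)
  expect_equal(as.integer(table(folds)), rep(20L, 10))
  for (f in 1:10) expect_equal(sum(y[folds == f]), 10)  # stratification
  cv2 <- kfold_cv(y, function(tr, te) runif(length(te)), k = 10, seed = 2)
  expect_identical(cv$folds, cv2$folds)
  expect_error(kfold_cv(c(0, rep(1, 20)), function(tr, te) 1, k = 5),
               "at least k")
})

test_that("leave-one-out agrees with an explicit loop oracle", {
  set.seed(3)
  x <- matrix(rnorm(20), 10, 2)
  y <- rep(c(0, 1), 5)
  trainer <- function(tr) {
    suppressWarnings(glm.fit(cbind(1, x[tr, , drop = FALSE]), y[tr],
                             family = binomial()))$coefficients
  }
  fit_score <- function(tr, te) {
    co <- trainer(tr)
    plogis(cbind(1, x[te, , drop = FALSE]) %*% co)[, 1]
  }
  loo <- kfold_cv(y, fit_score, k = 10, seed = 9)  # k = n
  expect_equal(nrow(loo$per_fold), 10L)
  accs <- vapply(1:10, function(f) {
    te <- which(loo$folds == f)
    mean((fit_score(which(loo$folds != f), te) > 0.5) == y[te])
  }, numeric(1))
  expect_equal(loo$per_fold$accuracy, accs)
  cv <- kfold_cv(y, fit_score, k = 5, seed = 9)
  # oracle: recompute each fold by hand from the same assignment
  for (f in 1:5) {
    te <- which(cv$folds == f); tr <- which(cv$folds != f)
    co <- trainer(tr)
    sc <- plogis(cbind(1, x[te, , drop = FALSE]) %*% co)[, 1]
    acc <- mean((sc > 0.5) == y[te])
    expect_equal(cv$per_fold$accuracy[f], acc)
  }
  expect_equal(cv$mean[["accuracy"]], mean(cv$per_fold$accuracy))
  expect_equal(cv$sd[["accuracy"]], sd(cv$per_fold$accuracy))
})

test_that("score distribution report matches arithmetic and U statistics", {
  sets <- list(a = c(0.9, 0.8, 0.7), b = c(0.1, 0.2, 0.3, 0.15))
  rep1 <- score_distributions(sets)
  expect_equal(rep1$summary$mean, c(mean(sets$a), mean(sets$b)))
  expect_equal(rep1$summary$n, c(3L, 4L))
  # disjoint ranges: U equals n1 * n2
  expect_equal(rep1$pairwise$U, 12)
  same <- score_distributions(list(x = 1:20 / 21, y = 1:20 / 21))
  expect_gt(same$pairwise$p_value, 0.9)
})

test_that("external validation on the training set matches self-evaluation", {
  cfg <- profile_generator_config(n_per_class = 150, admet_effect = 2,
                                  seed = 10)
  g <- generate_profiles(cfg)
  m <- train_dbpp(g$pc, g$admet, g$label, algo = "logistic", seed = 10)
  tab <- external_validate(m, list(train = list(pc = g$pc, admet = g$admet,
                                                label = g$label)))
  sc <- dbpp_score(m, pc = g$pc, admet = g$admet)
  expect_equal(tab$auc, roc_auc(sc, g$label))
  expect_equal(tab$n, 300L)
  # a shifted external set degrades but stays well-formed
  g2 <- generate_profiles(profile_generator_config(
    n_per_class = 150, admet_effect = 0.3, seed = 11))
  tab2 <- external_validate(m, list(shifted = list(
    pc = g2$pc, admet = g2$admet, label = g2$label)))
  expect_lt(tab2$auc, tab$auc)
  expect_true(all(is.finite(c(tab2$accuracy, tab2$auc))))
})

test_that("PU spy analysis is seeded and reproducible", {
  set.seed(1)
  pos <- matrix(rnorm(200 * 5, 1), 200, 5)
  unl <- matrix(rnorm(200 * 5, 1), 200, 5)
  r1 <- pu_noise_analysis(pos, unl, spy_fraction = 0.5, seed = 5, n_rep = 2)
  r2 <- pu_noise_analysis(pos, unl, spy_fraction = 0.5, seed = 5, n_rep = 2)
  expect_identical(r1, r2)
  expect_length(r1$per_replicate, 2L)
})

test_that("tree attributions satisfy local accuracy and agree with the booster", {
  set.seed(2)
  x <- matrix(rnorm(300 * 8), 300, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- as.numeric(x[, 1] + x[, 2] > 0)
  clf <- fit_classifier(x, y, "gbt", seed = 2)
  sh <- shap_attributions(clf, x[1:50, ])
  expect_lt(max(abs(rowSums(sh$attributions) + sh$base - sh$margin)), 1e-6)
  # cross-check against the booster's own attribution engine
  pc <- predict(clf$model, xgboost::xgb.DMatrix(x[1:50, ], nthread = 1),
                predcontrib = TRUE)
  expect_lt(max(abs(sh$attributions - pc[, 1:8])), 1e-4)
  expect_lt(max(abs(sh$margin - predict_margin(clf, x[1:50, ]))), 1e-4)
})

test_that("linear attribution ranking equals |weight x sd| and constants get zero", {
  set.seed(3)
  x <- matrix(rnorm(400 * 6), 400, 6, dimnames = list(NULL, paste0("f", 1:6)))
  x <- sweep(x, 2, c(3, 1, 0.5, 2, 1, 0.2), "*")
  x[, 6] <- 1  # constant feature
  y <- rbinom(400, 1, plogis(0.8 * x[, 1] - 0.5 * x[, 2] + 0.1 * x[, 3]))
  clf <- fit_classifier(x, y, "logistic", params = list(C = 100), seed = 3)
  sh <- shap_attributions(clf, x)
  expect_lt(max(abs(rowSums(sh$attributions) + sh$base - sh$margin)), 1e-8)
  expect_true(all(sh$attributions[, 6] == 0))
  beta <- as.numeric(coef(clf$model, s = clf$lambda))[-1]
  oracle_rank <- order(abs(beta) * apply(x, 2, sd), decreasing = TRUE)
  got_rank <- match(names(sh$importance), colnames(x))
  expect_equal(got_rank[1:3], oracle_rank[1:3])
})
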