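# Unified binary-classifier interface over the three model families used
# for drug-likeness models: regularized logistic regression (glmnet), RBF
# support-vector machines (e1071) and gradient-boosted trees (xgboost).
# All fits are seeded and single-threaded so that scoring runs are
# bit-reproducible.

.default_grids <- list(
  gbt = expand.grid(max_depth = c(3L, 5L, 7L, 0L),
                    max_leaves = c(15L, 31L, 63L)),
  logistic = data.frame(C = c(0.01, 0.1, 1, 10, 100)),
  svm = data.frame(C = c(0.01, 0.1, 1, 10, 100))
)

#' Fit a binary classifier
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y 0/1 labels.
#' @param algo `"gbt"` (gradient-boosted trees), `"logistic"` or `"svm"`.
#' @param params named list/row of hyperparameters (`max_depth`/`max_leaves`
#'   for gbt, `C` for the linear/kernel families); defaults are used when
#'   omitted.
#' @param seed integer seed.
#' @return object of class `dbpp_classifier`.
#' @export
fit_classifier <- function(x, y, algo = c("gbt", "logistic", "svm"),
                           params = NULL, seed = 1L) {
  algo <- match.arg(algo)
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  stopifnot(nrow(x) == length(y))
  model <- switch(algo,
    gbt = {
      md <- if (!is.null(params$max_depth)) as.integer(params$max_depth) else 5L
      ml <- if (!is.null(params$max_leaves)) as.integer(params$max_leaves) else 31L
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 0.1,
                      max_depth = md, max_leaves = ml,
                      grow_policy = "lossguide", tree_method = "hist",
                      nthread = 1, seed = as.integer(seed)),
        data = dtrain, nrounds = 100L, verbose = 0)
    },
    logistic = {
      C <- if (!is.null(params$C)) params$C else 1
      lam <- 1 / (max(C, 1e-8) * nrow(x))
      glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                     lambda = sort(unique(c(lam * c(10, 1), 0)),
                                   decreasing = TRUE),
                     standardize = FALSE)
    },
    svm = {
      C <- if (!is.null(params$C)) params$C else 1
      .with_seed(seed,
        e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                   cost = C, probability = TRUE, scale = FALSE))
    })
  structure(list(algo = algo, model = model, params = params,
                 seed = as.integer(seed),
                 n_features = ncol(x),
                 feature_names = colnames(x),
                 feature_means = colMeans(x),
                 lambda = if (algo == "logistic") {
                   1 / (max(if (!is.null(params$C)) params$C else 1, 1e-8) * nrow(x))
                 } else NULL),
            class = "dbpp_classifier")
}

#' Predicted probability of the positive class
#'
#' @param clf a `dbpp_classifier`.
#' @param x feature matrix.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(clf, x) {
  stopifnot(inherits(clf, "dbpp_classifier"))
  x <- as.matrix(x)
  switch(clf$algo,
    gbt = as.numeric(stats::predict(clf$model,
                                    xgboost::xgb.DMatrix(x, nthread = 1))),
    logistic = as.numeric(stats::predict(clf$model, newx = x,
                                         s = clf$lambda, type = "response")),
    svm = {
      pr <- attr(stats::predict(clf$model, x, probability = TRUE),
                 "probabilities")
      as.numeric(pr[, "1"])
    })
}

#' Margin (pre-link) output of a classifier
#'
#' Log-odds for the probabilistic families, decision value for the SVM;
#' Shapley attributions reconstruct this quantity.
#'
#' @inheritParams predict_prob
#' @return numeric vector.
#' @export
predict_margin <- function(clf, x) {
  stopifnot(inherits(clf, "dbpp_classifier"))
  x <- as.matrix(x)
  switch(clf$algo,
    gbt = as.numeric(stats::predict(clf$model,
                                    xgboost::xgb.DMatrix(x, nthread = 1),
                                    outputmargin = TRUE)),
    logistic = as.numeric(stats::predict(clf$model, newx = x,
                                         s = clf$lambda, type = "link")),
    svm = as.numeric(attr(stats::predict(clf$model, x,
                                         decision.values = TRUE),
                          "decision.values")))
}

.stratified_folds <- function(y, k, seed) {
  if (k == length(y)) {  # leave-one-out: stratification is vacuous
    return(.with_seed(seed, sample(seq_along(y))))
  }
  if (min(table(y)) < k) stop("each class needs at least k members")
  .with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Grid search over classifier hyperparameters
#'
#' Seeded stratified k-fold cross-validated AUC over the pinned grid;
#' deterministic for a fixed seed (ties broken toward the first grid row).
#'
#' @param x feature matrix.
#' @param y 0/1 labels.
#' @param algo classifier family.
#' @param grid data.frame of candidate hyperparameters; defaults to the
#'   pinned family grid.
#' @param k inner folds.
#' @param seed integer seed.
#' @return list with `best` (row of `grid`), `record` (grid + mean CV AUC)
#'   and `seed`.
#' @export
grid_search <- function(x, y, algo = "gbt", grid = NULL, k = 5L, seed = 1L) {
  if (is.null(grid)) grid <- .default_grids[[algo]]
  x <- as.matrix(x); y <- as.numeric(y)
  fold <- .stratified_folds(y, k, seed)
  scores <- vapply(seq_len(nrow(grid)), function(gi) {
    aucs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      clf <- fit_classifier(x[tr, , drop = FALSE], y[tr], algo,
                            params = as.list(grid[gi, , drop = FALSE]),
                            seed = seed)
      roc_auc(predict_prob(clf, x[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  best <- which.max(scores)
  record <- cbind(grid, cv_auc = scores)
  list(best = as.list(grid[best, , drop = FALSE]), record = record,
       seed = as.integer(seed))
}

# ---- Shapley attributions --------------------------------------------------

#' Per-sample Shapley feature attributions
#'
#' Exact tree-path Shapley attributions (double precision, compiled path
#' algorithm) for gradient-boosted trees, closed-form linear attributions
#' (`weight * (x - training mean)`) for the logistic family.  Local
#' accuracy holds: attribution row sums plus the base value equal the
#' model margin (returned as `margin`).
#'
#' @param clf a `dbpp_classifier` (gbt or logistic).
#' @param x feature matrix.
#' @return list with `attributions` (n x p matrix), `base` (scalar expected
#'   margin), `margin` (per-sample margin the attributions reconstruct) and
#'   `importance` (mean |attribution| per feature, decreasing).
#' @export
shap_attributions <- function(clf, x) {
  stopifnot(inherits(clf, "dbpp_classifier"))
  x <- as.matrix(x)
  if (clf$algo == "gbt") {
    ts <- .treeshap_gbt(clf, x)
    attr_mat <- ts$attributions
    base <- ts$base
    margin <- ts$margin
  } else if (clf$algo == "logistic") {
    beta <- as.numeric(stats::coef(clf$model, s = clf$lambda))
    b0 <- beta[1L]; w <- beta[-1L]
    mu <- clf$feature_means
    attr_mat <- sweep(x, 2L, mu, "-") %*% diag(w, length(w))
    colnames(attr_mat) <- clf$feature_names
    base <- b0 + sum(w * mu)
    margin <- predict_margin(clf, x)
  } else {
    stop("attributions are available for tree and linear models only")
  }
  imp <- sort(colMeans(abs(attr_mat)), decreasing = TRUE)
  list(attributions = attr_mat, base = base, margin = margin,
       importance = imp)
}
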