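# Profile-level evaluation wrappers: cross-validated DBPP training, the
# gamma sweep, external-set validation and Shapley endpoint attribution.

#' Cross-validate a DBPP model on property profiles
#'
#' Ten-fold (by default) stratified cross-validation; the physicochemical
#' scaler and any grid search are re-fitted inside every training fold.
#'
#' @inheritParams train_dbpp
#' @param k number of folds.
#' @return [kfold_cv()] result: per-fold metrics plus mean and sd.
#' @export
cv_dbpp <- function(pc, admet, labels, algo = "gbt", gamma = 0.6, k = 10L,
                    seed = 1L, grid = NULL) {
  pc <- as.matrix(pc); admet <- as.matrix(admet)
  labels <- as.numeric(labels)
  kfold_cv(labels, function(tr, te) {
    m <- train_dbpp(pc[tr, , drop = FALSE], admet[tr, , drop = FALSE],
                    labels[tr], algo = algo, gamma = gamma, seed = seed,
                    grid = grid)
    dbpp_score(m, pc = pc[te, , drop = FALSE],
               admet = admet[te, , drop = FALSE])
  }, k = k, seed = seed)
}

#' Sweep the hybrid weighting parameter gamma
#'
#' Cross-validated AUC and F1 for each candidate gamma; the selected value
#' maximizes the unweighted mean of AUC and F1, with exact ties broken
#' toward 0.5 (the most balanced weighting).
#'
#' @inheritParams cv_dbpp
#' @param gammas numeric grid of candidate gammas in `[0, 1]`.
#' @return list with `results` (data.frame: gamma, auc, f1, score) and
#'   `selected` (the chosen gamma).
#' @export
gamma_sweep <- function(pc, admet, labels, gammas = seq(0, 1, by = 0.1),
                        algo = "gbt", k = 10L, seed = 1L, grid = NULL) {
  if (!length(gammas) || any(gammas < 0 | gammas > 1)) {
    stop("gamma grid must be non-empty with values in [0, 1]")
  }
  rows <- lapply(gammas, function(g) {
    cv <- cv_dbpp(pc, admet, labels, algo = algo, gamma = g, k = k,
                  seed = seed, grid = grid)
    data.frame(gamma = g, auc = cv$mean[["auc"]], f1 = cv$mean[["f1"]])
  })
  res <- do.call(rbind, rows)
  res$score <- (res$auc + res$f1) / 2
  best <- max(res$score)
  cand <- which(res$score == best)
  selected <- res$gamma[cand[which.min(abs(res$gamma[cand] - 0.5))]]
  list(results = res, selected = selected)
}

#' Validate a fitted DBPP model on external sets
#'
#' Applies the model without any refitting and reports one metrics row per
#' set.
#'
#' @param model a `dbpp_model`.
#' @param sets named list; each element either a list with `pc`, `admet`,
#'   `label`, or a data.frame with `canonical_smiles` and `label` (scored
#'   through the stored panel).
#' @param threshold score cut-off for the confusion metrics (default 0.5,
#'   the trained classifier's decision point).
#' @return data.frame with one row per set: n, accuracy, recall,
#'   specificity, precision, f1, auc.
#' @export
external_validate <- function(model, sets, threshold = 0.5) {
  stopifnot(inherits(model, "dbpp_model"), is.list(sets),
            !is.null(names(sets)))
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    if (is.data.frame(s)) {
      scores <- dbpp_score(model, s$canonical_smiles)
      lab <- as.numeric(s$label)
    } else {
      scores <- dbpp_score(model, pc = s$pc, admet = s$admet)
      lab <- as.numeric(s$label)
    }
    m <- .metrics_from_scores(scores, lab, threshold)
    data.frame(set = nm, n = length(lab), accuracy = m$accuracy,
               recall = m$recall, specificity = m$specificity,
               precision = m$precision, f1 = m$f1, auc = m$auc)
  })
  do.call(rbind, rows)
}

#' Shapley attribution of profile coordinates
#'
#' Per-sample signed attributions over the 26 profile coordinates and the
#' mean-|attribution| importance ranking (exact tree-path attributions for
#' the gbt family, closed-form linear attributions for the logistic
#' family).  Local accuracy: attribution row sums plus the base value
#' reconstruct the model margin.
#'
#' @param model a `dbpp_model`.
#' @param pc,admet raw profile matrices of the samples to explain.
#' @return list with `attributions` (n x 26), `base`, `importance`
#'   (data.frame: feature, mean_abs_attribution, decreasing).
#' @export
endpoint_attribution <- function(model, pc, admet) {
  stopifnot(inherits(model, "dbpp_model"))
  x <- build_profile(pc, admet, model$gamma, model$pc_scaler)
  sh <- shap_attributions(model$classifier, x)
  colnames(sh$attributions) <- colnames(x)
  imp <- sort(colMeans(abs(sh$attributions)), decreasing = TRUE)
  list(attributions = sh$attributions, base = sh$base, margin = sh$margin,
       importance = data.frame(feature = names(imp),
                               mean_abs_attribution = unname(imp)))
}
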