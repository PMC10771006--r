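# Evaluation machinery: confusion-matrix metrics, rank-based ROC AUC,
# stratified k-fold cross-validation, the gamma sweep selecting the hybrid
# weighting, external-set validation, score-distribution reports with
# Mann-Whitney comparisons, and positive-unlabeled spy analysis.

#' Confusion-count metrics
#'
#' Accuracy, recall (sensitivity), specificity, precision and F1 from the
#' four confusion counts.  Metrics with a zero denominator are reported as
#' `NA` (undefined), never silently 0.
#'
#' @param tp,tn,fp,fn non-negative integer counts (at least one positive
#'   total).
#' @return object of class `eval_metrics`: list with the five metrics and
#'   the counts.
#' @export
#' @examples
#' confusion_metrics(tp = 90, tn = 80, fp = 20, fn = 10)
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  stopifnot(all(counts >= 0))
  total <- sum(counts)
  if (total < 1) stop("all confusion counts are zero")
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- sdiv(tp, tp + fp)
  recall <- sdiv(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(list(
    accuracy = (tp + tn) / total,
    recall = recall,
    specificity = sdiv(tn, tn + fp),
    precision = precision,
    f1 = f1,
    counts = counts
  ), class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  v <- unlist(x[c("accuracy", "recall", "specificity", "precision", "f1")])
  cat("eval_metrics:", paste(names(v), sprintf("%.4f", v), collapse = "  "),
      "\n  counts:", paste(names(x$counts), x$counts, collapse = "  "), "\n")
  invisible(x)
}

.metrics_from_scores <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores > threshold)
  m <- confusion_metrics(tp = sum(pred == 1 & labels == 1),
                         tn = sum(pred == 0 & labels == 0),
                         fp = sum(pred == 1 & labels == 0),
                         fn = sum(pred == 0 & labels == 1))
  m$auc <- if (length(unique(labels)) == 2L) roc_auc(scores, labels) else
    NA_real_  # degenerate fold (e.g. leave-one-out)
  m
}

#' ROC AUC by rank statistics
#'
#' Equals the Mann-Whitney U statistic divided by (n+ * n-), with tied
#' scores counted half; invariant under strictly increasing transforms of
#' the scores.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 labels (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Stratified k-fold cross-validation
#'
#' Builds seeded stratified folds and evaluates a user-supplied training
#' recipe per fold; all preprocessing must happen inside the recipe so that
#' nothing is fitted on held-out data.
#'
#' @param labels 0/1 labels of the full dataset.
#' @param fit_score function(train_idx, test_idx) returning held-out scores
#'   for `test_idx` (it receives row indices and must fit on the training
#'   rows only).
#' @param k number of folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param threshold score cut-off for the confusion metrics.
#' @return list with `per_fold` (data.frame of per-fold metrics), `mean`
#'   and `sd` rows, and `folds` (the fold assignment).
#' @export
kfold_cv <- function(labels, fit_score, k = 10L, seed = 1L, threshold = 0.5) {
  labels <- as.numeric(labels)
  fold <- .stratified_folds(labels, k, seed)
  rows <- lapply(seq_len(k), function(f) {
    te <- which(fold == f); tr <- which(fold != f)
    scores <- fit_score(tr, te)
    m <- .metrics_from_scores(scores, labels[te], threshold)
    data.frame(fold = f, accuracy = m$accuracy, recall = m$recall,
               specificity = m$specificity, precision = m$precision,
               f1 = m$f1, auc = m$auc)
  })
  per_fold <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_fold), "fold")
  list(per_fold = per_fold,
       mean = colMeans(per_fold[metric_cols], na.rm = TRUE),
       sd = apply(per_fold[metric_cols], 2L, stats::sd, na.rm = TRUE),
       folds = fold)
}

#' Score-distribution report with Mann-Whitney comparisons
#'
#' Per-set summaries of drug-likeness scores plus all pairwise two-sided
#' Mann-Whitney U tests (the shape of the screening-assessment tables).
#'
#' @param score_sets named list of numeric score vectors.
#' @return list with `summary` (data.frame: set, n, mean, quartiles) and
#'   `pairwise` (data.frame: set1, set2, U statistic, p value); the input
#'   vectors are kept under `scores` for plotting.
#' @export
score_distributions <- function(score_sets) {
  stopifnot(is.list(score_sets), length(score_sets) >= 1L,
            !is.null(names(score_sets)))
  summ <- do.call(rbind, lapply(names(score_sets), function(nm) {
    s <- score_sets[[nm]]
    q <- stats::quantile(s, c(0.25, 0.5, 0.75))
    data.frame(set = nm, n = length(s), mean = mean(s),
               q25 = q[[1]], median = q[[2]], q75 = q[[3]])
  }))
  pairs <- NULL
  nms <- names(score_sets)
  if (length(nms) >= 2L) {
    cmb <- utils::combn(nms, 2L)
    pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      a <- score_sets[[cmb[1L, j]]]; b <- score_sets[[cmb[2L, j]]]
      wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                correct = TRUE))
      data.frame(set1 = cmb[1L, j], set2 = cmb[2L, j],
                 U = unname(wt$statistic), p_value = wt$p.value)
    }))
  }
  list(summary = summ, pairwise = pairs, scores = score_sets)
}

#' Positive-unlabeled spy analysis
#'
#' Two-step spy technique: a fraction of the positives is hidden among the
#' unlabeled set, a positive-vs-unlabeled classifier is trained, the
#' reliability threshold is set at a lower quantile of the spy scores, and
#' the fraction of unlabeled samples scoring above it -- the likely-positive
#' fraction -- is reported, averaged over replicates.
#'
#' @param positives feature matrix of labeled positives.
#' @param unlabeled feature matrix of unlabeled samples.
#' @param spy_fraction fraction of positives hidden as spies (0 < f < 1).
#' @param seed integer seed.
#' @param n_rep replicates to average over.
#' @param spy_quantile quantile of spy scores used as the reliability
#'   threshold (default 0.05).
#' @param algo classifier family for the spy model.
#' @return list with `likely_positive_fraction` (mean over replicates) and
#'   `per_replicate`.
#' @export
pu_noise_analysis <- function(positives, unlabeled, spy_fraction = 0.15,
                              seed = 1L, n_rep = 5L, spy_quantile = 0.05,
                              algo = "logistic") {
  positives <- as.matrix(positives); unlabeled <- as.matrix(unlabeled)
  stopifnot(nrow(positives) > 1L, nrow(unlabeled) > 1L,
            spy_fraction > 0, spy_fraction < 1)
  fr <- vapply(seq_len(n_rep), function(r) {
    rs <- as.integer(seed) + r - 1L
    n_spy <- max(1L, round(spy_fraction * nrow(positives)))
    spy_idx <- .with_seed(rs, sample.int(nrow(positives), n_spy))
    x <- rbind(positives[-spy_idx, , drop = FALSE],
               unlabeled, positives[spy_idx, , drop = FALSE])
    y <- c(rep(1, nrow(positives) - n_spy),
           rep(0, nrow(unlabeled) + n_spy))
    clf <- fit_classifier(x, y, algo, seed = rs)
    sc <- predict_prob(clf, x)
    spy_scores <- sc[seq.int(length(sc) - n_spy + 1L, length(sc))]
    thr <- stats::quantile(spy_scores, spy_quantile, names = FALSE)
    unl_scores <- sc[seq.int(nrow(positives) - n_spy + 1L,
                             length.out = nrow(unlabeled))]
    mean(unl_scores >= thr)
  }, numeric(1))
  list(likely_positive_fraction = mean(fr), per_replicate = fr)
}
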