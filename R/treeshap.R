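# R-side glue for the exact tree Shapley attribution: parses a fitted
# gradient-boosted ensemble into flat arrays and calls the compiled path
# algorithm.

.xgb_tree_list <- function(clf) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = clf$model))
  fnames <- clf$feature_names
  lapply(split(dt, dt$Tree), function(td) {
    td <- td[order(td$Node), , drop = FALSE]
    id2idx <- stats::setNames(seq_len(nrow(td)) - 1L, td$ID)
    is_leaf <- td$Feature == "Leaf"
    feature <- rep(-1L, nrow(td))
    if (!is.null(fnames)) {
      feature[!is_leaf] <- match(td$Feature[!is_leaf], fnames) - 1L
    }
    if (anyNA(feature[!is_leaf])) {
      feature[!is_leaf] <- as.integer(sub("^f", "", td$Feature[!is_leaf]))
    }
    list(
      feature = feature,
      threshold = ifelse(is_leaf, 0, suppressWarnings(as.numeric(td$Split))),
      yes = ifelse(is_leaf, -1L, as.integer(id2idx[td$Yes])),
      no = ifelse(is_leaf, -1L, as.integer(id2idx[td$No])),
      value = ifelse(is_leaf, td$Gain, 0),
      cover = td$Cover
    )
  })
}

.xgb_base_margin <- function(clf) {
  cfg <- xgboost::xgb.config(clf$model)
  p <- as.numeric(cfg$learner$learner_model_param$base_score)
  stats::qlogis(p)
}

.treeshap_gbt <- function(clf, x) {
  x <- as.matrix(x)
  res <- .treeshap_cpp(x, .xgb_tree_list(clf))
  offset <- .xgb_base_margin(clf)
  colnames(res$phi) <- clf$feature_names
  list(attributions = res$phi,
       base = res$base + offset,
       margin = as.numeric(res$margin_raw) + offset)
}
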