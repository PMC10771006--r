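# Batch prediction tables: one row per input molecule, accepted rows carry
# the DBPP score, druggability call, QED and the full 26-value profile;
# rejected rows keep their rejection reason and are never dropped.

#' Score a batch of molecules into a prediction table
#'
#' @param model a `dbpp_model` with a stored ADMET panel.
#' @param smiles character vector of input SMILES (raw; standardization is
#'   applied and rejected inputs are reported per row).
#' @param ids optional input identifiers (defaults to `mol<i>`).
#' @param threshold druggability cut-off; defaults to the model's stored
#'   threshold.
#' @return data.frame with columns `input_id`, `smiles_in`,
#'   `canonical_smiles`, `status`, `reason`, `dbpp_score`, `druggable`,
#'   `qed`, the 6 scaled physicochemical values (`pc_*`) and the 20 ADMET
#'   probabilities, in input order.
#' @export
predict_table <- function(model, smiles, ids = NULL, threshold = NULL) {
  stopifnot(inherits(model, "dbpp_model"))
  if (is.null(model$panel)) stop("model carries no ADMET panel")
  if (is.null(threshold)) threshold <- model$threshold
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  std <- standardize_smiles(smiles)
  n <- nrow(std)
  panel_names <- names(model$panel)
  base <- data.frame(
    input_id = ids, smiles_in = smiles,
    canonical_smiles = std$canonical_smiles,
    status = std$status, reason = std$reason,
    dbpp_score = NA_real_, druggable = NA,
    qed = NA_real_, stringsAsFactors = FALSE
  )
  prof_cols <- matrix(NA_real_, n, 26L)
  colnames(prof_cols) <- c(paste0("pc_", c("mw", "logp", "tpsa", "hba",
                                           "hbd", "nrot")), panel_names)
  acc <- which(std$status == "accepted")
  if (length(acc)) {
    can <- std$canonical_smiles[acc]
    pc <- as.matrix(physchem_profile(can))
    admet <- predict_panel(model$panel, can)
    base$dbpp_score[acc] <- dbpp_score(model, pc = pc, admet = admet)
    base$druggable[acc] <- classify_druggable(base$dbpp_score[acc], threshold)
    base$qed[acc] <- qed_score(can)
    prof_cols[acc, 1:6] <- apply_pc_scaler(pc, model$pc_scaler)
    prof_cols[acc, 7:26] <- admet
  }
  cbind(base, as.data.frame(prof_cols))
}

#' Write a prediction table as CSV
#'
#' @param table result of [predict_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_prediction_csv <- function(table, path) {
  df <- table
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) ifelse(is.na(v), NA, sprintf("%.6g", v)))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Property-profile plot of one molecule
#'
#' Bar chart of the 26 profile values (scaled physicochemical block and
#' ADMET probabilities) backing the visual optimization guidance of the
#' prediction tool.
#'
#' @param row one row of a [predict_table()] result (accepted molecule).
#' @return a ggplot object.
#' @export
profile_plot <- function(row) {
  stopifnot(is.data.frame(row), nrow(row) == 1L,
            row$status == "accepted")
  drop_cols <- c("input_id", "smiles_in", "canonical_smiles", "status",
                 "reason", "dbpp_score", "druggable", "qed")
  vals <- unlist(row[setdiff(names(row), drop_cols)])
  df <- data.frame(
    feature = factor(names(vals), levels = names(vals)),
    value = as.numeric(vals),
    block = rep(c("physicochemical (scaled)", "ADMET probability"),
                c(6L, length(vals) - 6L))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = feature, y = value, fill = block)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      title = paste0(row$input_id, "  (DBPP score ",
                     sprintf("%.3f", row$dbpp_score), ")"),
      x = NULL, y = "profile value", fill = NULL) +
    ggplot2::theme_minimal()
}
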