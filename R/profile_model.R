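# The hybrid property-profile representation and the drug-likeness model.
# A molecule is the concatenation of a min-max-scaled 6-value
# physicochemical block weighted by (2 - 2*gamma) and a 20-value ADMET
# probability block weighted by 2*gamma; a binary classifier trained on
# these 26 values emits the drug-likeness (DBPP) score, thresholded at
# 0.736 for the druggability call.

#' Fit the physicochemical min-max scaler
#'
#' Training-range min-max scaling maps each of the six physicochemical
#' values to `[0, 1]`, making the block commensurate with the ADMET
#' probabilities before the gamma weighting; queries outside the training
#' range are clipped.
#'
#' @param pc numeric matrix (n x 6) of training physicochemical profiles.
#' @return object of class `pc_scaler`.
#' @export
fit_pc_scaler <- function(pc) {
  pc <- as.matrix(pc)
  stopifnot(ncol(pc) == 6L)
  structure(list(min = apply(pc, 2L, min), max = apply(pc, 2L, max)),
            class = "pc_scaler")
}

#' Apply a fitted physicochemical scaler
#'
#' @param pc matrix (n x 6) of raw physicochemical values.
#' @param scaler a `pc_scaler`.
#' @return matrix of the same shape with values clipped to `[0, 1]`.
#' @export
apply_pc_scaler <- function(pc, scaler) {
  stopifnot(inherits(scaler, "pc_scaler"))
  pc <- as.matrix(pc)
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1
  out <- sweep(sweep(pc, 2L, scaler$min, "-"), 2L, rng, "/")
  pmin(pmax(out, 0), 1)
}

#' Build gamma-weighted property profiles
#'
#' `Profile = Concat((2 - 2*gamma) * PC_scaled, 2*gamma * ADMET)`: at
#' `gamma = 0.5` both blocks carry unit weight, `gamma = 1` keeps only the
#' ADMET block, `gamma = 0` only the physicochemical block.
#'
#' @param pc matrix (n x 6) of raw physicochemical values.
#' @param admet matrix (n x 20) of ADMET probabilities in `[0, 1]`.
#' @param gamma weighting parameter in `[0, 1]`.
#' @param pc_scaler fitted [fit_pc_scaler()] (training ranges only).
#' @return numeric matrix (n x 26): 6 weighted physicochemical values then
#'   20 weighted ADMET values.
#' @export
build_profile <- function(pc, admet, gamma, pc_scaler) {
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  pc <- as.matrix(pc); admet <- as.matrix(admet)
  stopifnot(ncol(pc) == 6L, ncol(admet) == 20L, nrow(pc) == nrow(admet))
  pcs <- apply_pc_scaler(pc, pc_scaler)
  out <- cbind((2 - 2 * gamma) * pcs, 2 * gamma * admet)
  colnames(out) <- c(paste0("pc_", c("mw", "logp", "tpsa", "hba", "hbd",
                                     "nrot")),
                     if (!is.null(colnames(admet))) colnames(admet) else
                       paste0("admet_", seq_len(20L)))
  out
}

#' Train a drug-likeness (DBPP) model on property profiles
#'
#' Fits the physicochemical scaler on the training rows, builds the
#' gamma-weighted 26-value profiles and trains the chosen classifier
#' family, optionally selecting hyperparameters by seeded grid search.
#'
#' @param pc matrix (n x 6) of raw physicochemical values.
#' @param admet matrix (n x 20) of ADMET probabilities.
#' @param labels 0/1 vector (1 = drug).
#' @param algo classifier family (`"gbt"`, `"logistic"`, `"svm"`).
#' @param gamma hybrid weighting (default 0.6, the selected optimum).
#' @param seed integer seed.
#' @param grid `NULL` for family defaults, `TRUE` for the pinned default
#'   grid, or a data.frame of candidates.
#' @param threshold druggability cut-off stored with the model (default
#'   0.736, the mean score of the approved-drug reference set in the
#'   original calibration).
#' @param panel optional `admet_panel` stored for molecule-level scoring.
#' @return object of class `dbpp_model`.
#' @export
train_dbpp <- function(pc, admet, labels, algo = "gbt", gamma = 0.6,
                       seed = 1L, grid = NULL, threshold = 0.736,
                       panel = NULL) {
  pc <- as.matrix(pc); admet <- as.matrix(admet)
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) stop("training labels contain one class")
  pc_scaler <- fit_pc_scaler(pc)
  x <- build_profile(pc, admet, gamma, pc_scaler)
  params <- NULL; gs <- NULL
  if (isTRUE(grid)) grid <- .default_grids[[algo]]
  if (is.data.frame(grid)) {
    gs <- grid_search(x, labels, algo, grid, k = 5L, seed = seed)
    params <- gs$best
  }
  clf <- fit_classifier(x, labels, algo, params = params, seed = seed)
  structure(list(classifier = clf, algo = algo, gamma = gamma,
                 pc_scaler = pc_scaler, threshold = threshold,
                 grid_record = gs$record, seed = as.integer(seed),
                 panel_hash = if (!is.null(panel)) panel_manifest(panel)$hash,
                 panel = panel),
            class = "dbpp_model")
}

#' @export
print.dbpp_model <- function(x, ...) {
  cat("<dbpp_model> algo:", x$algo, " gamma:", x$gamma,
      " threshold:", x$threshold,
      if (!is.null(x$panel_hash)) paste(" panel:", x$panel_hash), "\n")
  invisible(x)
}

#' Train a DBPP model from standardized molecules
#'
#' Molecule-level wrapper: computes physicochemical profiles and panel
#' predictions for a labeled dataset, then calls [train_dbpp()]; the panel
#' is stored in the model for later scoring.
#'
#' @param dataset data.frame with `canonical_smiles` and `label` (from
#'   [assemble_dataset()]).
#' @param panel fitted `admet_panel`.
#' @inheritParams train_dbpp
#' @return a `dbpp_model`.
#' @export
train_dbpp_molecules <- function(dataset, panel, algo = "gbt", gamma = 0.6,
                                 seed = 1L, grid = NULL, threshold = 0.736) {
  stopifnot(is.data.frame(dataset),
            all(c("canonical_smiles", "label") %in% names(dataset)))
  pc <- as.matrix(physchem_profile(dataset$canonical_smiles))
  admet <- predict_panel(panel, dataset$canonical_smiles)
  train_dbpp(pc, admet, dataset$label, algo = algo, gamma = gamma,
             seed = seed, grid = grid, threshold = threshold, panel = panel)
}

#' DBPP drug-likeness score
#'
#' Probability of the drug class under the fitted profile classifier.
#' Accepts either SMILES (the stored panel is used to compute the ADMET
#' block) or pre-computed `pc`/`admet` matrices.
#'
#' @param model a `dbpp_model`.
#' @param smiles character vector of accepted SMILES (requires a stored
#'   panel), or `NULL` when `pc`/`admet` are given.
#' @param pc,admet optional raw profile matrices (n x 6, n x 20).
#' @return numeric vector of scores in `[0, 1]`.
#' @export
dbpp_score <- function(model, smiles = NULL, pc = NULL, admet = NULL) {
  stopifnot(inherits(model, "dbpp_model"))
  if (!is.null(smiles)) {
    if (is.null(model$panel)) {
      stop("model carries no ADMET panel; supply pc/admet matrices")
    }
    can <- canonical_smiles(smiles)
    if (anyNA(can)) stop("unparseable SMILES: ",
                         paste(smiles[is.na(can)], collapse = ", "))
    pc <- as.matrix(physchem_profile(can))
    admet <- predict_panel(model$panel, can)
  }
  x <- build_profile(pc, admet, model$gamma, model$pc_scaler)
  predict_prob(model$classifier, x)
}

#' Druggability call
#'
#' A compound is recommended as druggable when its score is strictly
#' greater than the threshold.
#'
#' @param score numeric score(s) in `[0, 1]`.
#' @param threshold cut-off (default 0.736).
#' @return logical vector.
#' @export
#' @examples
#' classify_druggable(c(0.80, 0.50, 0.736))  # TRUE FALSE FALSE
classify_druggable <- function(score, threshold = 0.736) {
  stopifnot(all(score >= 0 & score <= 1))
  score > threshold
}

#' Re-derive the druggability threshold from a reference drug set
#'
#' Mirrors how the published cut-off was obtained: the mean score of an
#' approved-drug reference collection.
#'
#' @param model a `dbpp_model` with a stored panel.
#' @param smiles reference drug SMILES.
#' @return numeric threshold.
#' @export
derive_threshold <- function(model, smiles) {
  mean(dbpp_score(model, smiles))
}

#' Save / load a DBPP model artifact
#'
#' The artifact is an RDS file accompanied by a JSON manifest recording
#' algorithm, gamma, threshold, physicochemical ranges, panel hash, seed
#' and the grid-search record.
#'
#' @param model a `dbpp_model`.
#' @param path artifact path (`.rds`); the manifest is written next to it.
#' @return `path`, invisibly.
#' @export
save_dbpp_model <- function(model, path) {
  stopifnot(inherits(model, "dbpp_model"))
  saveRDS(model, path)
  manifest <- list(
    algo = model$algo, gamma = model$gamma, threshold = model$threshold,
    pc_min = as.list(model$pc_scaler$min), pc_max = as.list(model$pc_scaler$max),
    panel_hash = model$panel_hash, seed = model$seed,
    grid_record = model$grid_record)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_dbpp_model
#' @export
load_dbpp_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "dbpp_model"))
  model
}
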