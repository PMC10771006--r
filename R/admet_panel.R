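# The 20-endpoint ADMET prediction panel: an ordered registry of binary
# classifiers, each mapping the 200-descriptor representation of a molecule
# to a probability.  The default registry fixes the endpoints named in the
# method's description; slots whose exact identity is not public are
# explicit placeholders that users replace through a panel configuration
# file.

.default_endpoints <- data.frame(
  name = c("HIA", "Caco-2",
           "OralBioavailability",
           "Clearance", "CYP3A4-inh", "CYP2D6-inh",
           "RenalExcretion",
           "OATP1B1-inh", "OATP1B3-inh", "Pgp-inh", "BCRP-inh",
           "BSEP-inh", "MATE1-inh",
           "MitochondrialMembranePotential", "Hepatotoxicity",
           "Mutagenicity", "OralAcuteToxicity", "Genotoxicity",
           "Carcinogenicity", "RespiratoryToxicity"),
  category = c("absorption", "absorption",
               "bioavailability",
               "metabolism/clearance", "metabolism/clearance",
               "metabolism/clearance",
               "excretion",
               rep("distribution/transporter", 6L),
               rep("toxicity", 7L)),
  positive_meaning = c(
    "well absorbed", "permeable", "orally bioavailable",
    "high clearance", "inhibitor", "inhibitor", "readily excreted",
    "inhibitor", "inhibitor", "inhibitor", "inhibitor", "inhibitor",
    "inhibitor",
    "disrupts membrane potential", "hepatotoxic", "mutagenic",
    "acutely toxic", "genotoxic", "carcinogenic", "respiratory toxicant"),
  placeholder = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
                  FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                  FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

#' Default 20-endpoint ADMET panel specification
#'
#' Ordered registry of the endpoint models behind the ADMET half of the
#' property profile: absorption (HIA, Caco-2), oral bioavailability,
#' metabolism/clearance, excretion, six transporter-inhibition endpoints
#' (OATP1B1, OATP1B3 and four placeholder slots) and seven toxicity
#' endpoints.  Slots marked `placeholder = TRUE` stand for endpoints whose
#' published identity is not fixed here; replace them via
#' [read_panel_config()].
#'
#' @param min_records minimum training records required per endpoint.
#' @param target_accuracy accuracy level below which training warns.
#' @return data.frame of 20 endpoint specifications (in panel order) with
#'   columns `name`, `category`, `positive_meaning`, `placeholder`,
#'   `min_records`, `target_accuracy`.
#' @export
#' @examples
#' nrow(default_panel())  # 20
default_panel <- function(min_records = 500L, target_accuracy = 0.8) {
  out <- .default_endpoints
  out$min_records <- as.integer(min_records)
  out$target_accuracy <- target_accuracy
  out
}

#' Read a panel configuration file
#'
#' YAML list of ordered endpoints, each with `name`, `category` and
#' optionally `positive_meaning`, `min_records`, `target_accuracy`,
#' `training_data` (path of a labeled table).
#'
#' @param path YAML file path.
#' @return data.frame shaped like [default_panel()], plus a
#'   `training_data` column when given.
#' @export
read_panel_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  eps <- cfg$endpoints
  if (is.null(eps)) stop("panel config needs an 'endpoints' list")
  rows <- lapply(eps, function(e) {
    if (is.null(e$name) || is.null(e$category)) {
      stop("each endpoint needs 'name' and 'category'")
    }
    data.frame(name = e$name, category = e$category,
               positive_meaning = e$positive_meaning %||% "",
               placeholder = isTRUE(e$placeholder),
               min_records = as.integer(e$min_records %||% 500L),
               target_accuracy = as.numeric(e$target_accuracy %||% 0.8),
               training_data = e$training_data %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$name)) stop("endpoint names must be unique")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train one ADMET endpoint model
#'
#' Fits a binary classifier for an endpoint on the z-scored 200-descriptor
#' representation, with a seeded stratified 80/20 held-out split for the
#' recorded metrics.  Warns (does not fail) when held-out accuracy is below
#' the endpoint's target accuracy.
#'
#' @param spec one row of a panel specification ([default_panel()]).
#' @param data either a data.frame with a `smiles` column plus `label`, or
#'   a data.frame/matrix of numeric features plus `label` (the layout
#'   written by [generate_endpoint_dataset()]).
#' @param algo classifier family (default gradient-boosted trees).
#' @param seed integer seed.
#' @param permissive allow fewer than `spec$min_records` rows (for toy
#'   fixtures).
#' @param grid optional hyperparameter grid for [grid_search()]; `NULL`
#'   fits the family defaults directly.
#' @return object of class `endpoint_model`.
#' @export
train_endpoint <- function(spec, data, algo = "gbt", seed = 1L,
                           permissive = FALSE, grid = NULL) {
  stopifnot(is.data.frame(data), "label" %in% names(data))
  n <- nrow(data)
  if (!permissive && n < spec$min_records) {
    stop("endpoint '", spec$name, "': ", n, " records < min_records (",
         spec$min_records, "); pass permissive = TRUE for toy data")
  }
  y <- as.numeric(data$label)
  if (length(unique(y)) < 2L) stop("endpoint training data has one class")
  if ("smiles" %in% names(data)) {
    x <- descriptor_matrix(data$smiles)
  } else {
    x <- as.matrix(data[setdiff(names(data), "label")])
  }
  stopifnot(ncol(x) == 200L)
  hold_idx <- .with_seed(seed, unlist(lapply(unique(y), function(cls) {
    rows <- which(y == cls)
    sample(rows, floor(0.2 * length(rows)))
  })))
  hold <- seq_along(y) %in% hold_idx
  if (!any(hold)) hold[seq_len(max(1L, n %/% 5L))] <- TRUE
  scaler <- fit_descriptor_scaler(x[!hold, , drop = FALSE])
  xtr <- apply_descriptor_scaler(x[!hold, , drop = FALSE], scaler)
  xte <- apply_descriptor_scaler(x[hold, , drop = FALSE], scaler)
  params <- NULL
  gs <- NULL
  if (!is.null(grid)) {
    gs <- grid_search(xtr, y[!hold], algo, grid, k = 3L, seed = seed)
    params <- gs$best
  }
  clf <- fit_classifier(xtr, y[!hold], algo, params = params, seed = seed)
  sc <- predict_prob(clf, xte)
  metrics <- .metrics_from_scores(sc, y[hold])
  if (!is.na(metrics$accuracy) && metrics$accuracy < spec$target_accuracy) {
    warning("endpoint '", spec$name, "': held-out accuracy ",
            sprintf("%.3f", metrics$accuracy), " below target ",
            spec$target_accuracy)
  }
  # refit on all data with the selected hyperparameters
  scaler_all <- fit_descriptor_scaler(x)
  clf_all <- fit_classifier(apply_descriptor_scaler(x, scaler_all), y,
                            algo, params = params, seed = seed)
  structure(list(spec = as.list(spec), classifier = clf_all,
                 scaler = scaler_all, metrics = metrics,
                 grid_record = gs$record, seed = as.integer(seed)),
            class = "endpoint_model")
}

#' Train a full panel on synthetic endpoint data
#'
#' Convenience constructor for tests and demonstrations: every endpoint of
#' the panel registry gets its own seeded synthetic training set.
#'
#' @param specs panel specification data.frame (default [default_panel()]).
#' @param n rows per endpoint training set.
#' @param effect class separation passed to [generate_endpoint_dataset()].
#' @param seed integer seed (endpoint i uses `seed + i`).
#' @param algo classifier family.
#' @return object of class `admet_panel`: ordered list of `endpoint_model`s.
#' @export
train_synthetic_panel <- function(specs = default_panel(), n = 600L,
                                  effect = 3, seed = 1L, algo = "gbt") {
  models <- lapply(seq_len(nrow(specs)), function(i) {
    dat <- generate_endpoint_dataset(n, effect, seed = seed + i)
    suppressWarnings(train_endpoint(specs[i, ], dat, algo = algo,
                                    seed = seed + i, permissive = n < 500L))
  })
  names(models) <- specs$name
  structure(models, class = "admet_panel")
}

#' Panel manifest and content hash
#'
#' @param panel an `admet_panel`.
#' @return list with `endpoints` (name, category, held-out accuracy/AUC per
#'   endpoint) and `hash` (content fingerprint of the panel).
#' @export
panel_manifest <- function(panel) {
  stopifnot(inherits(panel, "admet_panel"))
  eps <- do.call(rbind, lapply(panel, function(m) {
    data.frame(name = m$spec$name, category = m$spec$category,
               algo = m$classifier$algo, seed = m$seed,
               accuracy = m$metrics$accuracy, auc = m$metrics$auc)
  }))
  key <- paste(eps$name, eps$algo, eps$seed,
               sprintf("%.6f", eps$accuracy), collapse = "|")
  h <- .fnv1a(key)
  list(endpoints = eps,
       hash = paste0(sprintf("%04x", as.integer(h %/% 65536)),
                     sprintf("%04x", as.integer(h %% 65536))))
}

#' Predict the 20-value ADMET profile of molecules
#'
#' @param panel an `admet_panel` (all endpoints fitted).
#' @param smiles character vector of accepted SMILES, or a pre-computed
#'   200-descriptor matrix.
#' @return matrix (n x panel size) of probabilities in `[0, 1]`, columns in
#'   panel order.
#' @export
predict_panel <- function(panel, smiles) {
  stopifnot(inherits(panel, "admet_panel"), length(panel) >= 1L)
  x <- if (is.character(smiles)) descriptor_matrix(smiles) else as.matrix(smiles)
  out <- vapply(panel, function(m) {
    if (!inherits(m, "endpoint_model")) stop("panel contains an unfitted slot")
    predict_prob(m$classifier, apply_descriptor_scaler(x, m$scaler))
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) out <- matrix(out, nrow = 1L,
                                   dimnames = list(NULL, names(panel)))
  out
}
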