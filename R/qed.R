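# Weighted quantitative estimate of drug-likeness (QED): geometric mean of
# asymmetric double-sigmoid desirability functions over eight properties
# (MW, logP, HBA, HBD, PSA, rotatable bonds, aromatic rings, structural
# alerts).  Used as the baseline drug-likeness score throughout.

.ads <- function(x, p) {
  num <- p[["A"]] +
    p[["B"]] / (1 + exp(-(x - p[["C"]] + p[["D"]] / 2) / p[["E"]])) *
      (1 - 1 / (1 + exp(-(x - p[["C"]] - p[["D"]] / 2) / p[["F"]])))
  num / p[["DMAX"]]
}

#' QED component properties
#'
#' The eight molecular properties entering the weighted QED score.
#' Structural alerts are counted as the number of alert patterns present
#' (each catalogue entry contributes at most once).
#'
#' @param smiles character vector of accepted SMILES.
#' @return data.frame with columns `MW`, `ALOGP`, `HBA`, `HBD`, `PSA`,
#'   `ROTB`, `AROM`, `ALERTS`.
#' @export
qed_properties <- function(smiles) {
  can <- canonical_smiles(smiles)
  if (anyNA(can)) stop("unparseable SMILES: ",
                       paste(smiles[is.na(can)], collapse = ", "))
  sdf <- .sdfset_of(can)
  alerts <- numeric(length(can))
  for (p in .qed_alert_smarts) {
    if (grepl(".", p, fixed = TRUE)) {
      # dot-separated component pattern (repeated fragment): present when
      # the fragment occurs at least as many times as it is repeated
      comp <- strsplit(p, ".", fixed = TRUE)[[1]]
      hit <- rep(TRUE, length(can))
      for (cc in unique(comp)) {
        need <- sum(comp == cc)
        hit <- hit & (.smarts_count(sdf, cc) >= need)
      }
      alerts <- alerts + as.numeric(hit)
    } else {
      alerts <- alerts + as.numeric(.smarts_count(sdf, p) > 0)
    }
  }
  data.frame(
    MW = mol_weight(can),
    ALOGP = crippen_logp(can),
    HBA = as.integer(.hba_counts(sdf)),
    HBD = as.integer(.smarts_count(sdf, .hbd_smarts)),
    PSA = tpsa(can),
    ROTB = as.integer(.smarts_count(sdf, .rotb_smarts)),
    AROM = n_aromatic_rings(can),
    ALERTS = as.integer(alerts)
  )
}

#' Weighted QED drug-likeness score
#'
#' @param smiles character vector of accepted SMILES.
#' @param properties optional pre-computed result of [qed_properties()].
#' @return numeric vector of QED scores, strictly inside (0, 1).
#' @export
#' @examples
#' qed_score("CC(=O)Oc1ccccc1C(=O)O")  # aspirin, about 0.55
qed_score <- function(smiles, properties = NULL) {
  props <- if (is.null(properties)) qed_properties(smiles) else properties
  w <- .qed_weights
  vapply(seq_len(nrow(props)), function(i) {
    d <- vapply(names(w), function(nm) {
      .ads(props[[nm]][i], .qed_ads[[nm]])
    }, numeric(1))
    exp(sum(w * log(pmax(d, .Machine$double.xmin))) / sum(w))
  }, numeric(1))
}
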