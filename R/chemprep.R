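# Data preparation: the three-step standardization used throughout the
# package (salts -> parent acid/base, removal of mixtures and inorganics,
# canonicalization + deduplication) and balanced dataset assembly with
# seeded down-sampling of the negative class.

# counterions and common solvates stripped from multi-fragment records;
# stored as written, canonicalized once per session
.salt_fragments <- c(
  # mineral acids / halides
  "Cl", "Br", "I", "F", "[Cl-]", "[Br-]", "[I-]", "[F-]",
  "O", "[OH-]", "N", "[NH4+]",
  "O[N+](=O)[O-]", "[O-][N+](=O)[O-]",
  "OS(=O)(=O)O", "[O-]S(=O)(=O)O", "[O-]S(=O)(=O)[O-]", "OS(=O)O",
  "OP(=O)(O)O", "[O-]P(=O)(O)O", "[O-]P(=O)([O-])[O-]", "B(O)(O)O",
  # metal / simple cations
  "[Li+]", "[Na+]", "[K+]", "[Rb+]", "[Cs+]", "[Ca+2]", "[Mg+2]",
  "[Zn+2]", "[Ba+2]", "[Al+3]", "[Fe+2]", "[Fe+3]", "[Cu+2]", "[Mn+2]",
  "[Ca++]", "[Mg++]", "[Zn++]",
  # organic acids / conjugate bases
  "CC(=O)O", "CC(=O)[O-]", "C(=O)O", "[O-]C=O",
  "OC(=O)C(F)(F)F", "[O-]C(=O)C(F)(F)F",
  "CS(=O)(=O)O", "CS(=O)(=O)[O-]",
  "Cc1ccc(cc1)S(=O)(=O)O", "Cc1ccc(cc1)S(=O)(=O)[O-]",
  "OC(=O)C(=O)O", "[O-]C(=O)C(=O)[O-]",
  "OC(=O)C=CC(=O)O", "OC(=O)/C=C\\C(=O)O", "OC(=O)/C=C/C(=O)O",
  "OC(C(O)C(=O)O)C(=O)O", "OC(=O)CC(O)(CC(=O)O)C(=O)O",
  "OC(=O)CCC(=O)O", "OC(=O)CC(=O)O", "OC(CC(=O)O)C(=O)O",
  "OCC(O)C(O)C(O)C(O)C(=O)O",
  "OC(=O)c1ccccc1C(=O)O",
  "OS(=O)(=O)c1ccccc1", "[O-]S(=O)(=O)c1ccccc1",
  "OC(=O)CS", "C(=O)(O)O", "[O-]C(=O)[O-]", "OC(=O)[O-]",
  # common solvates
  "CO", "CCO", "CC(C)O", "CC(C)=O", "C1CCOC1", "CS(C)=O", "CC#N"
)

.salt_set <- function() {
  hit <- .cache_get("saltset")
  if (!is.null(hit)) return(hit)
  cs <- canonical_smiles(.salt_fragments)
  .cache_set("saltset", unique(cs[!is.na(cs)]))
}

.split_fragments <- function(can) strsplit(can, ".", fixed = TRUE)[[1]]

.has_carbon <- function(smiles) {
  g <- mol_graph(smiles)
  !is.null(g) && any(g$atoms$elem == "C")
}

.standardize_one <- function(smi) {
  rej <- function(reason) {
    list(canonical_smiles = NA_character_, status = "rejected",
         reason = reason, applied_fixes = "")
  }
  if (is.na(smi) || !nzchar(trimws(smi))) return(rej("unparseable"))
  can <- canonical_smiles(smi)
  if (is.na(can)) return(rej("unparseable"))

  fixes <- character(0)
  frags <- .split_fragments(can)
  if (length(frags) > 1L) {
    fc <- canonical_smiles(frags)
    keep <- !(fc %in% .salt_set())
    if (!any(keep)) {
      # every fragment is a listed counterion/solvate: keep the largest
      sizes <- vapply(frags, function(f) {
        g <- mol_graph(f)
        if (is.null(g)) 0L else g$n_heavy
      }, integer(1))
      keep <- seq_along(frags) == which.max(sizes)
    }
    if (sum(keep) > 1L) return(rej("mixture"))
    if (sum(!keep) > 0L) fixes <- c(fixes, "salt_stripped")
    can <- canonical_smiles(frags[keep])
    if (is.na(can)) return(rej("unparseable"))
  }

  if (!.has_carbon(can)) return(rej("inorganic"))

  neut <- ob_convert(can, "CAN", neutralize = TRUE)
  if (!is.na(neut)) {
    neut <- sub("[\t\n].*$", "", trimws(neut))
    neut <- canonical_smiles(neut)
    if (!is.na(neut) && !identical(neut, can)) {
      fixes <- c(fixes, "neutralized")
      can <- neut
    }
  }

  list(canonical_smiles = can, status = "accepted", reason = "",
       applied_fixes = paste(fixes, collapse = ";"))
}

#' Standardize SMILES records
#'
#' Applies the three preparation steps used for all data entering the models:
#' (1) counterions and solvates of multi-fragment records are stripped and
#' remaining protonation states neutralized to the parent acid/base,
#' (2) mixtures (several organic fragments) and inorganics (no carbon atom)
#' are rejected, (3) the surviving structure is written as the package's
#' canonical SMILES.  Rejected inputs are reported row-by-row, never dropped.
#'
#' @param smiles character vector of input SMILES.
#' @param label optional numeric/integer vector (1 = drug, 0 = non-drug).
#' @param source optional character vector naming the originating set.
#' @return data.frame with columns `smiles_in`, `canonical_smiles`, `status`
#'   (`"accepted"`/`"rejected"`), `reason` (`unparseable`, `mixture`,
#'   `inorganic` or empty), `applied_fixes` (`;`-separated tags from
#'   `salt_stripped`, `neutralized`), `label`, `source`.
#' @export
#' @examples
#' standardize_smiles(c("CCO", "CCO.Cl", "[Na+].[Cl-]"))
standardize_smiles <- function(smiles, label = NULL, source = NULL) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  if (is.null(label)) label <- rep(NA_real_, n)
  if (is.null(source)) source <- rep(NA_character_, n)
  stopifnot(length(label) == n, length(source) == n)
  res <- lapply(smiles, .standardize_one)
  data.frame(
    smiles_in = smiles,
    canonical_smiles = vapply(res, `[[`, character(1), "canonical_smiles"),
    status = vapply(res, `[[`, character(1), "status"),
    reason = vapply(res, `[[`, character(1), "reason"),
    applied_fixes = vapply(res, `[[`, character(1), "applied_fixes"),
    label = as.numeric(label),
    source = as.character(source),
    stringsAsFactors = FALSE
  )
}

#' Remove duplicate structures
#'
#' Keeps the first occurrence of every canonical SMILES, preserving row
#' order.  When the same structure carries both a drug and a non-drug label,
#' the drug record wins (curated positives outrank sampled negatives); the
#' number of such cross-class conflicts is reported via a message.
#'
#' @param records data.frame as returned by [standardize_smiles()] (only
#'   accepted rows are considered; rejected rows are dropped with a message).
#' @return the deduplicated data.frame.
#' @export
deduplicate_molecules <- function(records) {
  stopifnot(is.data.frame(records), "canonical_smiles" %in% names(records))
  if ("status" %in% names(records)) {
    n_rej <- sum(records$status != "accepted")
    if (n_rej > 0L) {
      message(n_rej, " rejected record(s) dropped before deduplication")
      records <- records[records$status == "accepted", , drop = FALSE]
    }
  }
  if (!nrow(records)) return(records)
  cs <- records$canonical_smiles
  keep <- !duplicated(cs)
  if ("label" %in% names(records) && !all(is.na(records$label))) {
    # cross-class duplicates: promote the first drug-labelled record
    lab <- records$label
    conflicts <- 0L
    for (s in unique(cs[keep])) {
      rows <- which(cs == s)
      labs <- unique(stats::na.omit(lab[rows]))
      if (length(labs) > 1L) {
        conflicts <- conflicts + 1L
        chosen <- rows[which(lab[rows] == 1)[1L]]
        keep[rows] <- FALSE
        keep[chosen] <- TRUE
      }
    }
    if (conflicts > 0L) {
      message(conflicts, " cross-class duplicate(s) resolved in favour of the drug label")
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Assemble a balanced labeled training dataset
#'
#' Keeps all positives and samples `n_negative` negatives without
#' replacement.  The sampling stream is seeded with `seed XOR replicate_id`,
#' so replicates drawn with the same `seed` but different `replicate_id`
#' give distinct, individually reproducible negative subsets (supporting
#' parallel down-sampling replicates of the training design).
#'
#' @param positives,negatives data.frames with a `canonical_smiles` column
#'   (standardized and deduplicated).
#' @param n_negative number of negatives to sample; must not exceed the
#'   available negatives.
#' @param replicate_id non-negative integer tag of the down-sampling run.
#' @param seed integer seed.
#' @return data.frame with `canonical_smiles` and `label` (1/0), positives
#'   first; attributes `replicate_id` and `seed` record provenance.
#' @export
assemble_dataset <- function(positives, negatives, n_negative,
                             replicate_id = 0L, seed = 1L) {
  stopifnot(is.data.frame(positives), is.data.frame(negatives),
            "canonical_smiles" %in% names(positives),
            "canonical_smiles" %in% names(negatives),
            replicate_id >= 0L)
  if (n_negative > nrow(negatives)) {
    stop("n_negative (", n_negative, ") exceeds available negatives (",
         nrow(negatives), ")")
  }
  idx <- .with_seed(bitwXor(as.integer(seed), as.integer(replicate_id)),
                    sample.int(nrow(negatives), n_negative))
  out <- data.frame(
    canonical_smiles = c(positives$canonical_smiles,
                         negatives$canonical_smiles[idx]),
    label = c(rep(1, nrow(positives)), rep(0, n_negative)),
    stringsAsFactors = FALSE
  )
  attr(out, "replicate_id") <- as.integer(replicate_id)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Read molecules from SMI or CSV files
#'
#' SMI files carry one SMILES per line with an optional whitespace-separated
#' identifier; CSV files need a `smiles` column and may carry `label` and
#' `source` columns.
#'
#' @param path file path; format inferred from the extension (`.smi`/`.txt`
#'   vs `.csv`).
#' @return data.frame with columns `smiles` and, when present, `id`,
#'   `label`, `source`.
#' @export
read_molecules <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"smiles" %in% names(df)) stop("CSV input needs a 'smiles' column")
    return(df)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  data.frame(
    smiles = vapply(parts, `[`, character(1), 1L),
    id = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
                character(1)),
    stringsAsFactors = FALSE
  )
}
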