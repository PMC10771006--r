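# The five fingerprint kinds used for representation experiments and
# dataset-diversity statistics: MACCS structural keys (166 bits) and four
# 2048-bit hashed fingerprints (Morgan/ECFP4, atom pairs, a path-based
# fingerprint, topological torsions).

.fp_kinds <- c("MACCS", "Morgan", "AtomPairs", "RDKFingerprint", "TopoTorsion")

.fpset_matrix <- function(fpset) {
  # rows = molecules; avoids relying on the S4 as.matrix method being attached
  n <- length(fpset)
  first <- methods::slot(fpset[[1]], "fp")
  out <- matrix(0L, n, length(first))
  for (i in seq_len(n)) out[i, ] <- as.integer(methods::slot(fpset[[i]], "fp"))
  out
}

# 32-bit FNV-1a over a string; arithmetic kept exact inside doubles
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- .bitxor32(h, b)
    h <- .mulmod32(h, prime)
  }
  h
}

.bitxor32 <- function(a, b) {
  # xor of two non-negative doubles < 2^32
  hi_a <- a %/% 2^16; lo_a <- a %% 2^16
  hi_b <- b %/% 2^16; lo_b <- b %% 2^16
  bitwXor(as.integer(hi_a), as.integer(hi_b)) * 2^16 +
    bitwXor(as.integer(lo_a), as.integer(lo_b))
}

.mulmod32 <- function(a, b) {
  lo <- a %% 2^16
  hi <- a %/% 2^16
  (((hi * b) %% 2^16) * 2^16 + lo * b) %% 2^32
}

.hash_bits <- function(labels, nbits) {
  if (!length(labels)) return(integer(0))
  unique(vapply(labels, function(s) as.integer(.fnv1a(s) %% nbits) + 1L,
                integer(1), USE.NAMES = FALSE))
}

# enumerate simple paths (no repeated atom) of 1..max_len bonds; returns
# canonical string labels combining element/aromaticity and bond orders
.path_labels <- function(g, min_len = 1L, max_len = 7L) {
  b <- g$bonds
  if (is.null(b) || !nrow(b)) return(character(0))
  at <- g$atoms
  atom_lab <- paste0(at$elem, ifelse(at$arom, "a", ""))
  nb <- lapply(seq_len(g$n_heavy), function(v) {
    rows <- which(b$i == v | b$j == v)
    data.frame(to = ifelse(b$i[rows] == v, b$j[rows], b$i[rows]),
               lab = ifelse(b$arom[rows], "~", as.character(b$order[rows])))
  })
  out <- character(0)
  walk <- function(path, labels, visited) {
    depth <- length(path) - 1L
    if (depth >= min_len) {
      fwd <- paste(labels, collapse = "")
      # canonical direction: lexicographic min of the two readings
      rev_atoms <- rev(atom_lab[path])
      rev_bonds <- rev(labels[seq(2, length(labels), by = 2)])
      bwd <- paste(c(rbind(rev_atoms[-length(rev_atoms)], rev_bonds),
                     rev_atoms[length(rev_atoms)]), collapse = "")
      out[[length(out) + 1L]] <<- if (fwd <= bwd) fwd else bwd
    }
    if (depth == max_len) return()
    v <- path[length(path)]
    cand <- nb[[v]]
    for (k in seq_len(nrow(cand))) {
      w <- cand$to[k]
      if (!visited[w]) {
        visited[w] <- TRUE
        walk(c(path, w), c(labels, cand$lab[k], atom_lab[w]), visited)
        visited[w] <- FALSE
      }
    }
  }
  for (v in seq_len(g$n_heavy)) {
    visited <- logical(g$n_heavy)
    visited[v] <- TRUE
    walk(v, atom_lab[v], visited)
  }
  unique(out)
}

.torsion_labels <- function(g) {
  b <- g$bonds
  if (is.null(b) || !nrow(b)) return(character(0))
  at <- g$atoms
  tlab <- paste0(at$elem, ifelse(at$arom, "a", ""), at$degree)
  nb <- lapply(seq_len(g$n_heavy), function(v) {
    c(b$j[b$i == v], b$i[b$j == v])
  })
  out <- character(0)
  for (k in seq_len(nrow(b))) {
    v2 <- b$i[k]; v3 <- b$j[k]
    for (v1 in setdiff(nb[[v2]], v3)) {
      for (v4 in setdiff(nb[[v3]], c(v2, v1))) {
        fwd <- paste(tlab[c(v1, v2, v3, v4)], collapse = "-")
        bwd <- paste(tlab[c(v4, v3, v2, v1)], collapse = "-")
        out[[length(out) + 1L]] <- if (fwd <= bwd) fwd else bwd
      }
    }
  }
  unique(out)
}

#' Molecular fingerprints
#'
#' Computes one of the five supported fingerprint kinds for a batch of
#' molecules.  `MACCS` is the 166-key structural fingerprint; `Morgan` is a
#' radius-2 circular fingerprint folded to 2048 bits; `AtomPairs`,
#' `RDKFingerprint` (bond paths of 1-7 bonds) and `TopoTorsion` (4-atom
#' linear torsions) are hashed into 2048 bits.
#'
#' @param smiles character vector of accepted SMILES.
#' @param kind one of `"MACCS"`, `"Morgan"`, `"AtomPairs"`,
#'   `"RDKFingerprint"`, `"TopoTorsion"`.
#' @return binary 0/1 matrix, one row per molecule; 166 columns for MACCS,
#'   2048 otherwise.
#' @export
#' @examples
#' dim(fingerprint("CCO", "MACCS"))
fingerprint <- function(smiles, kind = "MACCS") {
  kind <- match.arg(kind, .fp_kinds)
  can <- canonical_smiles(smiles)
  if (anyNA(can)) stop("unparseable SMILES: ",
                       paste(smiles[is.na(can)], collapse = ", "))
  n <- length(can)
  if (kind == "MACCS") {
    m <- .fpset_matrix(ChemmineR::fingerprintOB(.sdfset_of(can), "MACCS"))
    out <- m[, seq_len(166L), drop = FALSE]
  } else if (kind == "Morgan") {
    m <- .fpset_matrix(ChemmineR::fingerprintOB(.sdfset_of(can), "ECFP4"))
    stopifnot(ncol(m) %% 2048L == 0L)
    out <- matrix(0L, n, 2048L)
    for (blk in seq_len(ncol(m) / 2048L)) {
      out <- pmax(out, m[, (blk - 1L) * 2048L + seq_len(2048L), drop = FALSE])
    }
  } else if (kind == "AtomPairs") {
    apset <- ChemmineR::sdf2ap(.sdfset_of(can))
    codes <- ChemmineR::ap(apset)
    if (n == 1L && !is.list(codes)) codes <- list(codes)
    out <- matrix(0L, n, 2048L)
    for (i in seq_len(n)) {
      out[i, unique(as.integer(as.numeric(codes[[i]]) %% 2048)) + 1L] <- 1L
    }
  } else {
    out <- matrix(0L, n, 2048L)
    for (i in seq_len(n)) {
      g <- mol_graph(can[i])
      labs <- if (kind == "RDKFingerprint") .path_labels(g) else .torsion_labels(g)
      out[i, .hash_bits(labs, 2048L)] <- 1L
    }
  }
  storage.mode(out) <- "integer"
  rownames(out) <- NULL
  out
}

#' Pairwise Tanimoto similarity statistics
#'
#' Tanimoto index |A intersect B| / |A union B| over fingerprint bit sets,
#' with the dataset mean taken over the off-diagonal upper triangle.
#'
#' @param smiles character vector of at least two accepted SMILES.
#' @param kind fingerprint kind (default MACCS, the convention for
#'   dataset-diversity reporting).
#' @return list with `matrix` (symmetric, unit diagonal) and
#'   `mean_similarity`.
#' @export
tanimoto_stats <- function(smiles, kind = "MACCS") {
  if (length(smiles) < 2L) stop("need at least two molecules")
  fp <- fingerprint(smiles, kind)
  inter <- fp %*% t(fp)
  ones <- rowSums(fp)
  uni <- outer(ones, ones, "+") - inter
  sim <- ifelse(uni == 0, 1, inter / uni)  # two empty sets: identical
  diag(sim) <- 1
  list(matrix = sim,
       mean_similarity = mean(sim[upper.tri(sim)]))
}
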