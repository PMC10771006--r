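# Murcko framework analysis: ring systems plus connecting linkers after
# side-chain removal.  Scaffold identity is the canonical SMILES of the
# framework subgraph (terminal atoms double- or triple-bonded to the
# framework are retained, e.g. the ketone oxygen of benzophenone).

# elements that may be written bare in SMILES (organic subset)
.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

.write_smiles <- function(g, keep) {
  # serialize the induced subgraph on `keep` (atom indices of g) as SMILES;
  # hydrogens implicit except where needed for aromatic N / charged atoms
  at <- g$atoms
  b <- g$bonds
  sub <- sort(keep)
  idx <- match(sub, sub)
  n <- length(sub)
  brows <- which(b$i %in% sub & b$j %in% sub)
  bi <- match(b$i[brows], sub); bj <- match(b$j[brows], sub)
  bord <- b$order[brows]; barom <- b$arom[brows]
  adj <- lapply(seq_len(n), function(v) {
    k <- which(bi == v | bj == v)
    data.frame(k = k, to = ifelse(bi[k] == v, bj[k], bi[k]))
  })

  atom_token <- function(v) {
    orig <- sub[v]
    el <- at$elem[orig]
    ar <- at$arom[orig]
    sym <- if (ar && el %in% c("B", "C", "N", "O", "P", "S", "Se", "As")) {
      tolower(el)
    } else el
    chg <- at$charge[orig]
    needs_h <- FALSE
    nh <- at$nh[orig]
    if (ar && el == "N") {
      # pyrrole-type nitrogen keeps its hydrogen in the framework
      total_conn <- at$degree[orig] + at$nh[orig]
      if (total_conn >= 3L) { needs_h <- TRUE; nh <- 1L }
    }
    if (chg != 0L || !(el %in% .organic_subset) || needs_h) {
      hs <- if (needs_h) "H" else if (chg != 0L && nh > 0L) {
        if (nh == 1L) "H" else paste0("H", nh)
      } else ""
      cs <- if (chg > 0L) {
        if (chg == 1L) "+" else paste0("+", chg)
      } else if (chg < 0L) {
        if (chg == -1L) "-" else as.character(chg)
      } else ""
      paste0("[", sym, hs, cs, "]")
    } else sym
  }

  bond_token <- function(k, from, to) {
    if (barom[k]) return("")
    if (bord[k] == 2L) return("=")
    if (bord[k] == 3L) return("#")
    # explicit single bond between two aromatic atoms (e.g. biphenyl)
    if (at$arom[sub[from]] && at$arom[sub[to]]) return("-")
    ""
  }

  # pass 1: DFS forest; classify bonds as tree or ring-closure edges and
  # assign closure digits up front
  visited <- logical(n)
  used_bond <- logical(length(brows))
  tree_children <- vector("list", n)  # per atom: data.frame(k, to)
  closure_tok <- vector("list", n)    # per atom: closure strings in order
  roots <- integer(0)
  digit_next <- 0L
  for (start in seq_len(n)) {
    if (visited[start]) next
    roots <- c(roots, start)
    stack <- list(start)
    visited[start] <- TRUE
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      cand <- adj[[v]]
      for (r in seq_len(nrow(cand))) {
        k <- cand$k[r]; w <- cand$to[r]
        if (used_bond[k]) next
        used_bond[k] <- TRUE
        if (visited[w]) {
          digit_next <- digit_next + 1L
          dig <- if (digit_next < 10L) as.character(digit_next) else {
            paste0("%", digit_next)
          }
          bt <- bond_token(k, v, w)
          closure_tok[[v]] <- c(closure_tok[[v]], paste0(bt, dig))
          closure_tok[[w]] <- c(closure_tok[[w]], paste0(bt, dig))
        } else {
          visited[w] <- TRUE
          tree_children[[v]] <- rbind(tree_children[[v]],
                                      data.frame(k = k, to = w))
          stack[[length(stack) + 1L]] <- v
          stack[[length(stack) + 1L]] <- w
          break
        }
      }
    }
  }

  # pass 2: emit SMILES along the DFS tree, closures known in advance
  emit <- function(v) {
    tok <- paste0(atom_token(v), paste(closure_tok[[v]], collapse = ""))
    ch <- tree_children[[v]]
    if (is.null(ch) || !nrow(ch)) return(tok)
    parts <- vapply(seq_len(nrow(ch)), function(r) {
      paste0(bond_token(ch$k[r], v, ch$to[r]), emit(ch$to[r]))
    }, character(1))
    if (length(parts) > 1L) {
      paste0(tok, paste0("(", parts[-length(parts)], ")", collapse = ""),
             parts[length(parts)])
    } else paste0(tok, parts)
  }
  paste(vapply(roots, emit, character(1)), collapse = ".")
}

.murcko_scaffold_one <- function(smi) {
  g <- mol_graph(smi)
  if (is.null(g)) return(NA_character_)
  b <- g$bonds
  if (is.null(b) || !any(b$ring)) return("")  # acyclic: empty framework
  # iteratively prune terminal atoms (side chains)
  keep <- rep(TRUE, g$n_heavy)
  repeat {
    deg <- integer(g$n_heavy)
    rows <- which(keep[b$i] & keep[b$j])
    for (k in rows) {
      deg[b$i[k]] <- deg[b$i[k]] + 1L
      deg[b$j[k]] <- deg[b$j[k]] + 1L
    }
    drop <- which(keep & deg <= 1L & !g$atoms$ring)
    if (!length(drop)) break
    keep[drop] <- FALSE
  }
  # retain terminal atoms multiply-bonded to the framework (C=O, C=N, ...)
  extra <- unique(unlist(lapply(which(!keep), function(v) {
    rows <- which((b$i == v & keep[b$j]) | (b$j == v & keep[b$i]))
    if (length(rows) && any(b$order[rows] >= 2L & !b$arom[rows])) v else NULL
  })))
  keep[extra] <- TRUE
  raw <- .write_smiles(g, which(keep))
  canonical_smiles(raw)
}

#' Murcko scaffold of each molecule
#'
#' @param smiles character vector of accepted SMILES.
#' @return character vector of canonical scaffold SMILES; `""` for acyclic
#'   molecules (no ring system).
#' @export
#' @examples
#' murcko_scaffold(c("Cc1ccccc1", "CCO"))  # benzene scaffold; acyclic
murcko_scaffold <- function(smiles) {
  vapply(smiles, .murcko_scaffold_one, character(1), USE.NAMES = FALSE)
}

#' Murcko scaffold summary of a molecule set
#'
#' Counts distinct ring-system frameworks, the molecules-per-scaffold
#' distribution and the most frequent scaffolds (the "molecular cloud"
#' table); acyclic molecules are tallied separately.
#'
#' @param smiles character vector of accepted SMILES.
#' @param top_k how many of the most frequent scaffolds to report.
#' @return list with `n_molecules`, `n_scaffolds`, `acyclic_count`,
#'   `scaffold_counts` (named integer vector, scaffold SMILES -> count,
#'   decreasing), `molecules_per_scaffold` (table of scaffold sizes) and
#'   `top_scaffolds`.
#' @export
murcko_summary <- function(smiles, top_k = 150L) {
  sc <- murcko_scaffold(smiles)
  if (anyNA(sc)) stop("unparseable SMILES in input")
  acyclic <- sum(sc == "")
  sc <- sc[sc != ""]
  counts <- sort(table(sc), decreasing = TRUE)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(
    n_molecules = length(smiles),
    n_scaffolds = length(counts),
    acyclic_count = as.integer(acyclic),
    scaffold_counts = counts,
    molecules_per_scaffold = table(counts),
    top_scaffolds = utils::head(counts, top_k)
  )
}
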