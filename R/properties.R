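# Native physicochemical property calculators: Wildman-Crippen logP
# (atom-contribution method over the published SMARTS typing table) and
# Ertl's topological polar surface area.  Both are computed from the
# package's own molecular graph / SMARTS layer so that their values match
# the canonical implementations used by the QED publication.

.sdfset_h <- function(smiles) {
  # SDFset with explicit hydrogens (needed for hydrogen atom typing)
  blocks <- vapply(smiles, function(s) {
    txt <- ob_convert(s, "SDF", add_h = TRUE)
    if (is.na(txt)) stop("cannot render SDF for: ", s)
    txt
  }, character(1))
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(paste0(blocks, collapse = ""), tf)
  sdf <- ChemmineR::read.SDFset(tf)
  ChemmineR::cid(sdf) <- paste0("mol", seq_along(smiles))
  sdf
}

.crippen_family <- function(type) {
  # anchor-element family; priority chains only need to run within a family
  if (grepl("^C[0-9S]", type)) return("C")
  if (grepl("^H[0-9S]", type)) return("H")
  if (grepl("^N", type)) return("N")
  if (grepl("^O", type)) return("O")
  if (type %in% c("F", "Cl", "Br", "I", "Hal", "Me1", "Me2")) return("X")
  if (type == "P") return("P")
  if (grepl("^S[0-9]", type)) return("S")
  stop("unknown Crippen type: ", type)
}

.crippen_table <- function() {
  hit <- .cache_get("crippen")
  if (!is.null(hit)) return(hit)
  path <- .pkg_extdata("crippen_logp.tsv")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$family <- vapply(tab$type, .crippen_family, character(1))
  # first-match-wins typing: each pattern is anchored on its first atom and
  # negates every earlier pattern of the same family via recursive SMARTS
  chain <- character(nrow(tab))
  for (fam in unique(tab$family)) {
    rows <- which(tab$family == fam)
    for (k in seq_along(rows)) {
      i <- rows[k]
      negs <- if (k > 1L) {
        paste0(";!$(", tab$smarts[rows[seq_len(k - 1L)]], ")", collapse = "")
      } else ""
      chain[i] <- paste0("[$(", tab$smarts[i], ")", negs, "]")
    }
  }
  tab$anchored <- chain
  .cache_set("crippen", tab)
}

#' Wildman-Crippen logP
#'
#' Octanol-water partition coefficient estimated by the published
#' atom-contribution method: every atom (hydrogens included) is assigned the
#' first matching SMARTS type of the contribution table and the typed
#' contributions are summed.
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector of logP estimates.
#' @export
#' @examples
#' crippen_logp("CC(=O)Oc1ccccc1C(=O)O")  # aspirin, about 1.31
crippen_logp <- function(smiles) {
  can <- canonical_smiles(smiles)
  if (anyNA(can)) stop("unparseable SMILES: ",
                       paste(smiles[is.na(can)], collapse = ", "))
  key <- paste0("logp\r", can)
  cached <- vapply(key, function(k) {
    v <- .cache_get(k); if (is.null(v)) NA_real_ else v
  }, numeric(1), USE.NAMES = FALSE)
  todo <- which(is.na(cached))
  if (length(todo)) {
    tab <- .crippen_table()
    sdf <- .sdfset_h(can[todo])
    acc <- numeric(length(todo))
    for (i in seq_len(nrow(tab))) {
      counts <- .smarts_count(sdf, tab$anchored[i])
      acc <- acc + counts * tab$logp[i]
    }
    for (k in seq_along(todo)) .cache_set(key[todo[k]], acc[k])
    cached[todo] <- acc
  }
  cached
}

# ---- Ertl TPSA -------------------------------------------------------------

.atom_env <- function(g) {
  # per heavy atom: single/double/triple bonds to heavy neighbours
  # (aromatic bonds counted separately, kekulized orders ignored for them)
  n <- g$n_heavy
  s <- integer(n); d <- integer(n); t <- integer(n); a <- integer(n)
  b <- g$bonds
  if (!is.null(b) && nrow(b)) {
    for (k in seq_len(nrow(b))) {
      i <- b$i[k]; j <- b$j[k]
      if (b$arom[k]) { a[i] <- a[i] + 1L; a[j] <- a[j] + 1L }
      else if (b$order[k] == 1L) { s[i] <- s[i] + 1L; s[j] <- s[j] + 1L }
      else if (b$order[k] == 2L) { d[i] <- d[i] + 1L; d[j] <- d[j] + 1L }
      else if (b$order[k] == 3L) { t[i] <- t[i] + 1L; t[j] <- t[j] + 1L }
    }
  }
  data.frame(s = s, d = d, t = t, a = a)
}

.tpsa_contrib_n <- function(ar, chg, s, d, t, a, nh, ring3) {
  if (ar && a >= 2L) {
    if (chg == 0L) {
      if (nh == 0L && s == 0L && d == 0L && a == 2L) return(12.89)
      if (nh == 0L && a == 3L) return(4.41)
      if (nh == 0L && s == 1L && a == 2L) return(4.93)
      if (nh == 0L && d == 1L && a == 2L) return(8.39)
      if (nh == 1L && a == 2L) return(15.79)
    } else if (chg == 1L) {
      if (nh == 0L && a == 3L) return(4.10)
      if (nh == 0L && s == 1L && a == 2L) return(3.88)
      if (nh == 1L && a == 2L) return(14.14)
    }
  } else if (chg == 0L) {
    if (nh == 0L && s == 3L && d == 0L && t == 0L) {
      return(if (ring3) 3.01 else 3.24)
    }
    if (nh == 0L && s == 1L && d == 1L && t == 0L) return(12.36)
    if (nh == 0L && s == 0L && d == 0L && t == 1L) return(23.79)
    if (nh == 0L && s == 1L && d == 2L && t == 0L) return(11.68)
    if (nh == 0L && s == 0L && d == 1L && t == 1L) return(13.60)
    if (nh == 1L && s == 2L && d == 0L && t == 0L) {
      return(if (ring3) 21.94 else 12.03)
    }
    if (nh == 1L && s == 0L && d == 1L && t == 0L) return(23.85)
    if (nh == 2L && s == 1L && d == 0L && t == 0L) return(26.02)
  } else if (chg == 1L) {
    if (nh == 0L && s == 4L && d == 0L && t == 0L) return(0.00)
    if (nh == 0L && s == 2L && d == 1L && t == 0L) return(3.01)
    if (nh == 0L && s == 1L && d == 0L && t == 1L) return(4.36)
    if (nh == 1L && s == 3L && d == 0L && t == 0L) return(4.44)
    if (nh == 1L && s == 1L && d == 1L && t == 0L) return(13.97)
    if (nh == 2L && s == 2L && d == 0L && t == 0L) return(16.61)
    if (nh == 2L && s == 0L && d == 1L && t == 0L) return(25.59)
    if (nh == 3L && s == 1L && d == 0L && t == 0L) return(27.64)
  }
  max(0, 30.5 - (s + d + t + a + nh) * 8.2 + nh * 1.5)
}

.tpsa_contrib_o <- function(ar, chg, s, d, t, a, nh, ring3) {
  if (ar && a >= 2L) return(13.14)
  if (chg == 0L) {
    if (nh == 0L && s == 2L && d == 0L) return(if (ring3) 12.53 else 9.23)
    if (nh == 0L && s == 0L && d == 1L) return(17.07)
    if (nh == 1L && s == 1L && d == 0L) return(20.23)
  } else if (chg == -1L) {
    if (nh == 0L && s == 1L && d == 0L) return(23.06)
  }
  max(0, 28.5 - (s + d + t + a + nh) * 8.6 + nh * 1.5)
}

.tpsa_contrib_sp <- function(elem, ar, chg, s, d, t, a, nh) {
  if (elem == "S") {
    if (ar && a >= 2L) return(if (d == 1L) 21.70 else 28.24)
    if (nh == 1L && s == 1L && d == 0L) return(38.80)
    if (nh == 0L && s == 2L && d == 0L) return(25.30)
    if (nh == 0L && s == 0L && d == 1L) return(32.09)
    if (nh == 0L && s == 2L && d == 1L) return(19.21)
    if (nh == 0L && s == 2L && d == 2L) return(8.38)
    return(0)
  }
  # phosphorus
  if (nh == 0L && s == 3L && d == 0L) return(13.59)
  if (nh == 0L && s == 1L && d == 1L) return(34.14)
  if (nh == 0L && s == 3L && d == 1L) return(9.81)
  if (nh == 1L && s == 2L && d == 1L) return(23.47)
  0
}

#' Topological polar surface area (Ertl)
#'
#' Sums the published fragment contributions of nitrogen and oxygen
#' environments (and optionally sulfur/phosphorus).  The default
#' `include_sp = FALSE` matches the N/O-only convention used by the QED
#' desirability functions.
#'
#' @param smiles character vector of SMILES.
#' @param include_sp also add sulfur and phosphorus contributions.
#' @return numeric vector of TPSA values in square Angstroms.
#' @export
#' @examples
#' tpsa("c1ccccc1")           # benzene: 0
#' tpsa("CC(=O)Oc1ccccc1C(=O)O")  # aspirin: 63.6
tpsa <- function(smiles, include_sp = FALSE) {
  vapply(smiles, function(smi) {
    g <- mol_graph(smi)
    if (is.null(g)) stop("unparseable SMILES: ", smi)
    env <- .atom_env(g)
    at <- g$atoms
    total <- 0
    for (v in seq_len(g$n_heavy)) {
      el <- at$elem[v]
      if (el == "N") {
        total <- total + .tpsa_contrib_n(at$arom[v], at$charge[v], env$s[v],
                                         env$d[v], env$t[v], env$a[v],
                                         at$nh[v], at$ring3[v])
      } else if (el == "O") {
        total <- total + .tpsa_contrib_o(at$arom[v], at$charge[v], env$s[v],
                                         env$d[v], env$t[v], env$a[v],
                                         at$nh[v], at$ring3[v])
      } else if (include_sp && el %in% c("S", "P")) {
        total <- total + .tpsa_contrib_sp(el, at$arom[v], at$charge[v],
                                          env$s[v], env$d[v], env$t[v],
                                          env$a[v], at$nh[v])
      }
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Number of aromatic rings
#'
#' Counted as the cycle rank of the aromatic-bond subgraph (naphthalene 2,
#' biphenyl 2, benzene 1).
#'
#' @param smiles character vector of SMILES.
#' @return integer vector.
#' @export
n_aromatic_rings <- function(smiles) {
  vapply(smiles, function(smi) {
    g <- mol_graph(smi)
    if (is.null(g)) stop("unparseable SMILES: ", smi)
    b <- g$bonds
    if (is.null(b) || !any(b$arom)) return(0L)
    ab <- b[b$arom, , drop = FALSE]
    verts <- sort(unique(c(ab$i, ab$j)))
    el <- cbind(match(ab$i, verts), match(ab$j, verts))
    gr <- igraph::graph_from_edgelist(el, directed = FALSE)
    as.integer(nrow(ab) - length(verts) + igraph::components(gr)$no)
  }, integer(1), USE.NAMES = FALSE)
}

#' Molecular weight
#'
#' Average molecular weight from standard atomic weights, hydrogens included.
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector in g/mol.
#' @export
mol_weight <- function(smiles) {
  vapply(smiles, function(smi) {
    g <- mol_graph(smi)
    if (is.null(g)) stop("unparseable SMILES: ", smi)
    .mol_weight(g)
  }, numeric(1), USE.NAMES = FALSE)
}

# SMARTS definitions shared by the physicochemical profile and QED:
# Lipinski-family donor count and the strict rotatable-bond definition
# (terminal, triple-bond, trihalomethyl, t-butyl and amide-type bonds
# excluded).
.hbd_smarts <- "[$([N;!H0;v3,v4&+1]),$([O,S;H1;+0]),n&H1&+0]"
.rotb_smarts <- paste0(
  "[!$(*#*)&!D1&!$(C(F)(F)F)&!$(C(Cl)(Cl)Cl)&!$(C(Br)(Br)Br)",
  "&!$(C([CH3])([CH3])[CH3])",
  "&!$([CD3](=[N,O,S])-!@[#7,O,S!D1])&!$([#7,O,S!D1]-!@[CD3]=[N,O,S])",
  "&!$([CD3](=[N+])-!@[#7!D1])&!$([#7!D1]-!@[CD3]=[N+])]-!@",
  "[!$(*#*)&!D1&!$(C(F)(F)F)&!$(C(Cl)(Cl)Cl)&!$(C(Br)(Br)Br)",
  "&!$(C([CH3])([CH3])[CH3])]")

.hba_counts <- function(sdf) {
  counts <- numeric(length(sdf))
  for (p in .qed_acceptor_smarts) counts <- counts + .smarts_count(sdf, p)
  counts
}

#' Six-value physicochemical profile
#'
#' Molecular weight, Wildman-Crippen logP, topological polar surface area,
#' hydrogen-bond acceptor and donor counts, and rotatable-bond count -- the
#' physicochemical half of the 26-value property profile.
#'
#' @param smiles character vector of accepted (standardized) SMILES.
#' @return data.frame with columns `mw`, `logp`, `tpsa`, `hba`, `hbd`,
#'   `nrot`, one row per molecule.
#' @export
#' @examples
#' physchem_profile(c("CCO", "c1ccccc1"))
physchem_profile <- function(smiles) {
  can <- canonical_smiles(smiles)
  if (anyNA(can)) stop("unparseable SMILES: ",
                       paste(smiles[is.na(can)], collapse = ", "))
  sdf <- .sdfset_of(can)
  out <- data.frame(
    mw = mol_weight(can),
    logp = crippen_logp(can),
    tpsa = tpsa(can),
    hba = as.integer(.hba_counts(sdf)),
    hbd = as.integer(.smarts_count(sdf, .hbd_smarts)),
    nrot = as.integer(.smarts_count(sdf, .rotb_smarts))
  )
  rownames(out) <- NULL
  out
}
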