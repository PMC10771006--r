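# Low-level bridge to Open Babel (via ChemmineOB) plus a light molecular
# graph representation parsed from SDF/MOL2 output.  All chemistry in the
# package flows through these helpers so that one canonicalization dialect
# (Open Babel "can") defines molecular identity everywhere.

# per-session caches: conversions are pure functions of the input string
.dbppr_cache <- new.env(parent = emptyenv())

.pkg_extdata <- function(...) {
  p <- system.file("extdata", ..., package = "dbppr")
  if (nzchar(p)) p else file.path("inst", "extdata", ...)
}

.cache_get <- function(key) {
  if (exists(key, envir = .dbppr_cache, inherits = FALSE)) {
    get(key, envir = .dbppr_cache, inherits = FALSE)
  } else NULL
}

.cache_set <- function(key, value) {
  assign(key, value, envir = .dbppr_cache)
  value
}

.ob_options <- function(add_h = FALSE, neutralize = FALSE) {
  nm <- character(0)
  if (neutralize) nm <- c(nm, "neutralize")
  if (add_h) nm <- c(nm, "h")
  if (!length(nm)) return(NULL)
  data.frame(names = nm, args = rep("", length(nm)))
}

#' Convert a single SMILES string to another chemical format
#'
#' Thin wrapper around [ChemmineOB::convertFormat()] that returns `NA` when
#' Open Babel cannot parse the input instead of raising an error.
#'
#' @param smiles single SMILES string.
#' @param to output format name understood by Open Babel (e.g. `"CAN"`,
#'   `"SDF"`, `"MOL2"`, `"INCHI"`).
#' @param add_h add explicit hydrogens before writing.
#' @param neutralize apply Open Babel's charge-neutralization operation.
#' @return character scalar with the converted record, or `NA_character_`.
#' @keywords internal
ob_convert <- function(smiles, to, add_h = FALSE, neutralize = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  key <- paste0("conv\r", to, "\r", add_h, "\r", neutralize, "\r", smiles)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  opts <- .ob_options(add_h = add_h, neutralize = neutralize)
  out <- tryCatch({
    if (is.null(opts)) {
      ChemmineOB::convertFormat("SMI", to, source = smiles)
    } else {
      ChemmineOB::convertFormat("SMI", to, source = smiles, options = opts)
    }
  }, error = function(e) NA_character_)
  if (is.na(out) || !nzchar(trimws(out))) out <- NA_character_
  .cache_set(key, out)
}

#' Canonical SMILES via Open Babel
#'
#' The package-wide canonicalization routine: molecular identity (duplicate
#' detection, scaffold identity, caching) is defined as equality of the
#' strings returned here.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES; `NA` where parsing failed.
#' @export
#' @examples
#' canonical_smiles(c("OCC", "CCO"))  # both ethanol
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- ob_convert(trimws(s), "CAN")
    if (is.na(out)) return(NA_character_)
    # Open Babel appends the title after a tab and a trailing newline
    sub("[\t\n].*$", "", trimws(out))
  }, character(1), USE.NAMES = FALSE)
}

# ---- SDF / MOL2 parsing ----------------------------------------------------

.parse_sdf_block <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) return(NULL)
  counts <- lines[4L]
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || natoms < 1L) return(NULL)
  atom_lines <- lines[5L:(4L + natoms)]
  elem <- trimws(substr(atom_lines, 32L, 34L))
  bonds <- NULL
  if (!is.na(nbonds) && nbonds > 0L) {
    bond_lines <- lines[(5L + natoms):(4L + natoms + nbonds)]
    bonds <- data.frame(
      i = as.integer(substr(bond_lines, 1L, 3L)),
      j = as.integer(substr(bond_lines, 4L, 6L)),
      order = as.integer(substr(bond_lines, 7L, 9L))
    )
  }
  charge <- integer(natoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    n <- f[1L]
    for (k in seq_len(n)) {
      charge[f[2L * k]] <- f[2L * k + 1L]
    }
  }
  list(elem = elem, charge = charge, bonds = bonds)
}

.parse_mol2_block <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  ai <- grep("^@<TRIPOS>ATOM", lines)[1L]
  bi <- grep("^@<TRIPOS>BOND", lines)[1L]
  if (is.na(ai) || is.na(bi)) return(NULL)
  atom_lines <- lines[(ai + 1L):(bi - 1L)]
  # other sections (e.g. UNITY_ATOM_ATTR) may sit between ATOM and BOND
  sec <- grep("^@", atom_lines)
  if (length(sec)) atom_lines <- atom_lines[seq_len(sec[1L] - 1L)]
  afields <- strsplit(trimws(atom_lines), "\\s+")
  atype <- vapply(afields, `[`, character(1), 6L)
  tail_lines <- lines[(bi + 1L):length(lines)]
  tail_lines <- tail_lines[grepl("^\\s*\\d", tail_lines)]
  btype <- NULL
  if (length(tail_lines)) {
    bfields <- strsplit(trimws(tail_lines), "\\s+")
    btype <- data.frame(
      i = as.integer(vapply(bfields, `[`, character(1), 2L)),
      j = as.integer(vapply(bfields, `[`, character(1), 3L)),
      type = vapply(bfields, `[`, character(1), 4L)
    )
  }
  list(atype = atype, bonds = btype)
}

#' Molecular graph of a standardized molecule
#'
#' Parses Open Babel's SDF (elements, formal charges, kekulized bond orders)
#' and MOL2 (aromaticity flags) renderings of one SMILES into a heavy-atom
#' graph with per-atom hydrogen counts.  The result feeds the native
#' featurizers (TPSA, logP atom typing, path/torsion fingerprints, Murcko
#' scaffolds, ring statistics).
#'
#' @param smiles single SMILES string (need not be canonical).
#' @return a list of class `mol_graph` with components `atoms` (data.frame:
#'   `elem`, `charge`, `nh`, `arom`, `ring`, `ring3`, `degree`), `bonds`
#'   (data.frame: `i`, `j`, `order`, `arom`, `ring` over heavy atoms),
#'   `n_heavy`, `n_h`, and the canonical SMILES as `smiles`; or `NULL` when
#'   the molecule cannot be parsed.
#' @export
mol_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  can <- canonical_smiles(smiles)
  if (is.na(can)) return(NULL)
  key <- paste0("graph\r", can)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)

  sdf_txt <- ob_convert(can, "SDF", add_h = TRUE)
  mol2_txt <- ob_convert(can, "MOL2", add_h = TRUE)
  if (is.na(sdf_txt) || is.na(mol2_txt)) return(NULL)
  sdf <- .parse_sdf_block(sdf_txt)
  m2 <- .parse_mol2_block(mol2_txt)
  if (is.null(sdf) || is.null(m2)) return(NULL)
  n_all <- length(sdf$elem)
  if (length(m2$atype) != n_all) {
    stop("internal: SDF/MOL2 atom count mismatch for ", can)
  }

  heavy <- which(sdf$elem != "H")
  idx_map <- integer(n_all)
  idx_map[heavy] <- seq_along(heavy)
  elem <- sdf$elem[heavy]
  charge <- sdf$charge[heavy]

  # aromatic flags from MOL2 bond records
  arom_bond_of <- logical(n_all)
  b_all <- sdf$bonds
  arom_flag_all <- logical(if (is.null(b_all)) 0L else nrow(b_all))
  if (!is.null(m2$bonds) && nrow(m2$bonds)) {
    ar <- m2$bonds[m2$bonds$type == "ar", , drop = FALSE]
    if (nrow(ar)) {
      arom_bond_of[unique(c(ar$i, ar$j))] <- TRUE
      if (!is.null(b_all)) {
        keys_ar <- paste(pmin(ar$i, ar$j), pmax(ar$i, ar$j))
        keys_b <- paste(pmin(b_all$i, b_all$j), pmax(b_all$i, b_all$j))
        arom_flag_all <- keys_b %in% keys_ar
      }
    }
  }

  nh <- integer(length(heavy))
  bonds <- NULL
  if (!is.null(b_all) && nrow(b_all)) {
    is_h_i <- sdf$elem[b_all$i] == "H"
    is_h_j <- sdf$elem[b_all$j] == "H"
    hb <- b_all[xor(is_h_i, is_h_j), , drop = FALSE]
    if (nrow(hb)) {
      heavy_end <- ifelse(sdf$elem[hb$i] == "H", hb$j, hb$i)
      tab <- table(idx_map[heavy_end])
      nh[as.integer(names(tab))] <- as.integer(tab)
    }
    keep <- !is_h_i & !is_h_j
    if (any(keep)) {
      bonds <- data.frame(
        i = idx_map[b_all$i[keep]],
        j = idx_map[b_all$j[keep]],
        order = b_all$order[keep],
        arom = arom_flag_all[keep]
      )
    }
  }

  degree <- integer(length(heavy))
  ring_bond <- logical(if (is.null(bonds)) 0L else nrow(bonds))
  ring_atom <- logical(length(heavy))
  ring3 <- logical(length(heavy))
  if (!is.null(bonds) && nrow(bonds)) {
    tab <- table(factor(c(bonds$i, bonds$j), levels = seq_along(heavy)))
    degree <- as.integer(tab)
    g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j), directed = FALSE)
    if (igraph::vcount(g) < length(heavy)) {
      g <- igraph::add_vertices(g, length(heavy) - igraph::vcount(g))
    }
    br <- igraph::bridges(g)
    ring_bond <- !(seq_len(nrow(bonds)) %in% as.integer(br))
    ring_atom[unique(c(bonds$i[ring_bond], bonds$j[ring_bond]))] <- TRUE
    # 3-membered ring membership: atom with two mutually bonded neighbours
    adj <- lapply(seq_along(heavy), function(v) {
      c(bonds$j[bonds$i == v], bonds$i[bonds$j == v])
    })
    bonded <- function(a, b) any((bonds$i == a & bonds$j == b) |
                                   (bonds$i == b & bonds$j == a))
    for (v in which(ring_atom)) {
      nb <- adj[[v]]
      if (length(nb) >= 2L) {
        pr <- utils::combn(nb, 2L)
        for (k in seq_len(ncol(pr))) {
          if (bonded(pr[1L, k], pr[2L, k])) { ring3[v] <- TRUE; break }
        }
      }
    }
    bonds$ring <- ring_bond
  }

  arom_atom <- arom_bond_of[heavy]

  out <- structure(list(
    atoms = data.frame(elem = elem, charge = charge, nh = nh,
                       arom = arom_atom, ring = ring_atom, ring3 = ring3,
                       degree = degree, stringsAsFactors = FALSE),
    bonds = bonds,
    n_heavy = length(heavy),
    n_h = n_all - length(heavy),
    smiles = can
  ), class = "mol_graph")
  .cache_set(key, out)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$smiles, ": ", x$n_heavy, " heavy atoms, ",
      if (is.null(x$bonds)) 0L else nrow(x$bonds), " bonds, ",
      x$n_h, " H\n", sep = "")
  invisible(x)
}

# ---- SDFset helpers (for Open Babel fingerprints / SMARTS) -----------------

.sdfset_of <- function(smiles) {
  # ChemmineR SDFset for a character vector of canonical SMILES.  Molecules
  # without heavy-atom bonds (water, monoatomic ions) get explicit
  # hydrogens so that their connection table is non-empty.
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  blocks <- vapply(smiles, function(s) {
    g <- mol_graph(s)
    bondless <- is.null(g) || is.null(g$bonds) || nrow(g$bonds) == 0L
    txt <- ob_convert(s, "SDF", add_h = bondless)
    if (is.na(txt)) stop("cannot render SDF for: ", s)
    txt
  }, character(1))
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(paste0(blocks, collapse = ""), tf)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(tf))
  ChemmineR::cid(sdf) <- paste0("mol", seq_along(smiles))
  sdf
}

.smarts_count <- function(sdfset, pattern) {
  # number of unique matches per molecule; errors surface as an R error
  as.numeric(ChemmineR::smartsSearchOB(sdfset, pattern, uniqueMatches = TRUE))
}

# standard atomic weights for mass computation
.atomic_weights <- c(
  H = 1.008, He = 4.003, Li = 6.941, Be = 9.012, B = 10.812, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.18, Na = 22.99, Mg = 24.305,
  Al = 26.982, Si = 28.086, P = 30.974, S = 32.067, Cl = 35.453, Ar = 39.948,
  K = 39.098, Ca = 40.078, Ti = 47.867, Cr = 51.996, Mn = 54.938,
  Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.39,
  Ga = 69.723, Ge = 72.61, As = 74.922, Se = 78.96, Br = 79.904, Kr = 83.8,
  Rb = 85.468, Sr = 87.62, Mo = 95.94, Ru = 101.07, Pd = 106.42,
  Ag = 107.868, Cd = 112.412, In = 114.818, Sn = 118.711, Sb = 121.76,
  Te = 127.6, I = 126.904, Xe = 131.29, Cs = 132.905, Ba = 137.328,
  W = 183.84, Pt = 195.078, Au = 196.967, Hg = 200.59, Tl = 204.383,
  Pb = 207.2, Bi = 208.98
)

.mol_weight <- function(g) {
  w <- .atomic_weights[g$atoms$elem]
  if (anyNA(w)) {
    stop("unknown element(s): ",
         paste(unique(g$atoms$elem[is.na(w)]), collapse = ", "))
  }
  sum(w) + g$n_h * .atomic_weights[["H"]]
}
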