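# The 200-descriptor molecular representation.  The membership and order of
# the vector are pinned by a packaged manifest (constitutional counts,
# physicochemical values, topological indices and 128 functional-group
# SMARTS counts) so that vector positions are stable.  A z-score scaler
# fitted on training data provides the normalized variant.

.descriptor_base_names <- c(
  # physicochemical block
  "mw", "heavy_mw", "logp", "mr", "tpsa", "tpsa_sp", "hba", "hbd", "nrot",
  "qed",
  # constitutional counts
  "n_heavy", "n_atoms", "n_h", "n_bonds", "n_ring_bonds", "n_rings",
  "n_arom_rings", "n_arom_atoms", "n_ring_atoms", "frac_ring_atoms",
  "n_hetero", "frac_hetero", "n_halogen", "n_pos_charge", "n_neg_charge",
  "net_charge", "abs_charge", "n_terminal_atoms", "max_degree",
  "mean_degree",
  # element counts
  "count_B", "count_C", "count_N", "count_O", "count_F", "count_Si",
  "count_P", "count_S", "count_Cl", "count_Br", "count_I", "count_other",
  # hybridization-like counts
  "c_sp3", "c_sp2", "c_sp", "c_arom", "frac_csp3", "n_arom_n", "n_arom_o",
  "n_arom_s", "o_carbonyl", "o_ether_like", "deg3_atoms", "deg4_atoms",
  # topological indices
  "wiener", "mean_distance", "diameter", "radius", "petitjean",
  "eccentric_connectivity", "mean_eccentricity", "randic", "chi0",
  "zagreb1", "zagreb2", "kappa1", "kappa2", "kappa3", "graph_density",
  "complexity_deg", "n_bridge_bonds", "frac_rotatable"
)

.fragment_table <- function() {
  hit <- .cache_get("fragtab")
  if (!is.null(hit)) return(hit)
  tab <- utils::read.delim(.pkg_extdata("fragment_smarts.tsv"),
                           stringsAsFactors = FALSE)
  .cache_set("fragtab", tab)
}

#' Names of the 200 pinned descriptors
#'
#' @return character vector of length 200 giving the descriptor manifest in
#'   vector order.
#' @export
descriptor_names <- function() {
  nm <- c(.descriptor_base_names, .fragment_table()$name)
  stopifnot(length(nm) == 200L)
  nm
}

.crippen_mr <- function(smiles) {
  tab <- .crippen_table()
  tab$mr[is.na(tab$mr)] <- 0
  sdf <- .sdfset_h(smiles)
  acc <- numeric(length(smiles))
  for (i in seq_len(nrow(tab))) {
    acc <- acc + .smarts_count(sdf, tab$anchored[i]) * tab$mr[i]
  }
  acc
}

.topo_block <- function(g) {
  n <- g$n_heavy
  b <- g$bonds
  nb <- if (is.null(b)) 0L else nrow(b)
  deg <- g$atoms$degree
  zero <- stats::setNames(numeric(18), .descriptor_base_names[55:72])
  if (n < 2L || nb == 0L) {
    zero["kappa1"] <- n
    return(zero)
  }
  el <- cbind(b$i, b$j)
  gr <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(gr) < n) gr <- igraph::add_vertices(gr, n - igraph::vcount(gr))
  D <- igraph::distances(gr)
  finite <- is.finite(D)
  D[!finite] <- 0
  wiener <- sum(D) / 2
  npairs <- (sum(finite) - n) / 2
  mean_dist <- if (npairs > 0) sum(D) / 2 / npairs else 0
  ecc <- apply(D, 1L, max)
  diam <- max(ecc); rad <- min(ecc)
  petitjean <- if (rad > 0) (diam - rad) / rad else 0
  ecc_conn <- sum(ecc * deg)
  randic <- sum(1 / sqrt(deg[b$i] * deg[b$j]))
  chi0 <- sum(1 / sqrt(pmax(deg, 1)))
  zag1 <- sum(deg^2)
  zag2 <- sum(deg[b$i] * deg[b$j])
  p2 <- sum(vapply(seq_len(n), function(v) choose(deg[v], 2), numeric(1)))
  # Kier shape indices (simple variants)
  kappa1 <- if (nb > 0) n * (n - 1)^2 / nb^2 else n
  kappa2 <- if (p2 > 0 && n >= 3L) (n - 1) * (n - 2)^2 / p2^2 else 0
  p3 <- sum(vapply(seq_len(nb), function(k) {
    (deg[b$i[k]] - 1) * (deg[b$j[k]] - 1)
  }, numeric(1))) - 3 * .count_triangles(b, n)
  kappa3 <- if (p3 > 0 && n >= 4L) {
    if (n %% 2L == 1L) (n - 1) * (n - 3)^2 / p3^2 else (n - 3) * (n - 2)^2 / p3^2
  } else 0
  dens <- nb / (n * (n - 1) / 2)
  cplx <- sum(ifelse(deg > 0, deg * log2(deg), 0))
  nbridge <- sum(!b$ring)
  c(wiener = wiener, mean_distance = mean_dist, diameter = diam,
    radius = rad, petitjean = petitjean, eccentric_connectivity = ecc_conn,
    mean_eccentricity = mean(ecc), randic = randic, chi0 = chi0,
    zagreb1 = zag1, zagreb2 = zag2, kappa1 = kappa1, kappa2 = kappa2,
    kappa3 = kappa3, graph_density = dens, complexity_deg = cplx,
    n_bridge_bonds = nbridge, frac_rotatable = 0)  # filled by caller
}

.count_triangles <- function(b, n) {
  if (is.null(b) || nrow(b) < 3L) return(0L)
  adj <- matrix(FALSE, n, n)
  adj[cbind(b$i, b$j)] <- TRUE
  adj[cbind(b$j, b$i)] <- TRUE
  tri <- 0L
  for (k in seq_len(nrow(b))) {
    tri <- tri + sum(adj[b$i[k], ] & adj[b$j[k], ])
  }
  tri %/% 3L
}

#' Compute the pinned 200-descriptor vector
#'
#' @param smiles character vector of accepted SMILES.
#' @param scaler optional scaler from [fit_descriptor_scaler()]; when given,
#'   each descriptor is z-scored with training means/sds and zero-variance
#'   descriptors map to 0.
#' @return numeric matrix, one row per molecule, 200 named columns in
#'   manifest order; all values finite.
#' @export
descriptor_matrix <- function(smiles, scaler = NULL) {
  can <- canonical_smiles(smiles)
  if (anyNA(can)) stop("unparseable SMILES: ",
                       paste(smiles[is.na(can)], collapse = ", "))
  nmol <- length(can)
  nm <- descriptor_names()
  out <- matrix(NA_real_, nmol, 200L, dimnames = list(NULL, nm))

  pc <- physchem_profile(can)
  qed <- qed_score(can)
  out[, "mw"] <- pc$mw
  out[, "logp"] <- pc$logp
  out[, "mr"] <- .crippen_mr(can)
  out[, "tpsa"] <- pc$tpsa
  out[, "tpsa_sp"] <- tpsa(can, include_sp = TRUE)
  out[, "hba"] <- pc$hba
  out[, "hbd"] <- pc$hbd
  out[, "nrot"] <- pc$nrot
  out[, "qed"] <- qed

  halogens <- c("F", "Cl", "Br", "I")
  tracked <- c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I")
  for (i in seq_len(nmol)) {
    g <- mol_graph(can[i])
    at <- g$atoms
    b <- g$bonds
    nb <- if (is.null(b)) 0L else nrow(b)
    out[i, "heavy_mw"] <- .mol_weight(g) - g$n_h * .atomic_weights[["H"]]
    out[i, "n_heavy"] <- g$n_heavy
    out[i, "n_atoms"] <- g$n_heavy + g$n_h
    out[i, "n_h"] <- g$n_h
    out[i, "n_bonds"] <- nb
    out[i, "n_ring_bonds"] <- if (nb) sum(b$ring) else 0
    comp <- if (nb) {
      gr <- igraph::graph_from_edgelist(cbind(b$i, b$j), directed = FALSE)
      if (igraph::vcount(gr) < g$n_heavy) {
        gr <- igraph::add_vertices(gr, g$n_heavy - igraph::vcount(gr))
      }
      igraph::components(gr)$no
    } else g$n_heavy
    out[i, "n_rings"] <- nb - g$n_heavy + comp
    out[i, "n_arom_rings"] <- n_aromatic_rings(can[i])
    out[i, "n_arom_atoms"] <- sum(at$arom)
    out[i, "n_ring_atoms"] <- sum(at$ring)
    out[i, "frac_ring_atoms"] <- mean(at$ring)
    out[i, "n_hetero"] <- sum(!at$elem %in% c("C", "H"))
    out[i, "frac_hetero"] <- mean(!at$elem %in% c("C", "H"))
    out[i, "n_halogen"] <- sum(at$elem %in% halogens)
    out[i, "n_pos_charge"] <- sum(at$charge > 0)
    out[i, "n_neg_charge"] <- sum(at$charge < 0)
    out[i, "net_charge"] <- sum(at$charge)
    out[i, "abs_charge"] <- sum(abs(at$charge))
    out[i, "n_terminal_atoms"] <- sum(at$degree == 1L)
    out[i, "max_degree"] <- max(at$degree)
    out[i, "mean_degree"] <- mean(at$degree)
    for (el in tracked) out[i, paste0("count_", el)] <- sum(at$elem == el)
    out[i, "count_other"] <- sum(!at$elem %in% c(tracked, "H"))

    env <- .atom_env(g)
    isC <- at$elem == "C"
    out[i, "c_arom"] <- sum(isC & at$arom)
    out[i, "c_sp"] <- sum(isC & !at$arom & (env$t >= 1L | env$d >= 2L))
    out[i, "c_sp2"] <- sum(isC & !at$arom & env$d == 1L & env$t == 0L)
    out[i, "c_sp3"] <- sum(isC & !at$arom & env$d == 0L & env$t == 0L)
    out[i, "frac_csp3"] <- if (sum(isC)) out[i, "c_sp3"] / sum(isC) else 0
    out[i, "n_arom_n"] <- sum(at$elem == "N" & at$arom)
    out[i, "n_arom_o"] <- sum(at$elem == "O" & at$arom)
    out[i, "n_arom_s"] <- sum(at$elem == "S" & at$arom)
    out[i, "o_carbonyl"] <- sum(at$elem == "O" & env$d == 1L)
    out[i, "o_ether_like"] <- sum(at$elem == "O" & env$s == 2L & at$nh == 0L)
    out[i, "deg3_atoms"] <- sum(at$degree == 3L)
    out[i, "deg4_atoms"] <- sum(at$degree >= 4L)

    topo <- .topo_block(g)
    topo["frac_rotatable"] <- if (nb) pc$nrot[i] / nb else 0
    out[i, names(topo)] <- topo
  }

  frag <- .fragment_table()
  sdf <- .sdfset_of(can)
  for (k in seq_len(nrow(frag))) {
    out[, frag$name[k]] <- .smarts_count(sdf, frag$smarts[k])
  }

  stopifnot(all(is.finite(out)))
  if (!is.null(scaler)) out <- apply_descriptor_scaler(out, scaler)
  out
}

#' Fit a z-score scaler on a training descriptor matrix
#'
#' @param x descriptor matrix from [descriptor_matrix()] (training rows
#'   only: the scaler must never see validation data).
#' @return object of class `descriptor_scaler` with per-column means and
#'   standard deviations.
#' @export
fit_descriptor_scaler <- function(x) {
  structure(list(mean = colMeans(x), sd = apply(x, 2L, stats::sd)),
            class = "descriptor_scaler")
}

#' Apply a fitted z-score scaler
#'
#' Columns with zero training variance are mapped to 0.
#'
#' @param x descriptor matrix.
#' @param scaler result of [fit_descriptor_scaler()].
#' @return scaled matrix of the same shape.
#' @export
apply_descriptor_scaler <- function(x, scaler) {
  stopifnot(inherits(scaler, "descriptor_scaler"))
  out <- sweep(x, 2L, scaler$mean, "-")
  sd <- scaler$sd
  sd[!is.finite(sd) | sd == 0] <- Inf  # zero-variance -> 0 after division
  sweep(out, 2L, sd, "/")
}
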