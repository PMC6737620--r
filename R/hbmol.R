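# Molecular graph container used throughout the package.  Kekulized by
# construction: bond orders are the integers 1, 2, 3 (aromatic type 4 is
# resolved on read, see kekulize()).

#' Standard atomic weights for the organic subset handled here
#' @keywords internal
.atomic_masses <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.086, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Br = 79.904, I = 126.904
)

#' Atomic numbers for the same subset
#' @keywords internal
.atomic_numbers <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Si = 14,
  P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Br = 35, I = 53
)

#' Pauling electronegativities (pseudo-charge rule in the fixture generator)
#' @keywords internal
.electronegativity <- c(
  H = 2.20, B = 2.04, C = 2.55, N = 3.04, O = 3.44, F = 3.98, Na = 0.93,
  Mg = 1.31, Si = 1.90, P = 2.19, S = 2.58, Cl = 3.16, K = 0.82,
  Ca = 1.00, Br = 2.96, I = 2.66
)

# default valences used to resolve implicit hydrogens
.default_valence <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

#' Construct a molecule record
#'
#' The container every stage of the pipeline operates on: a kekulized
#' molecular graph with optional Cartesian coordinates, per-atom partial
#' charges and an ordered string-keyed property map.  Atom indices are
#' 1-based and coincide with V2000 SDF atom numbering.
#'
#' @param elements character vector of element symbols.
#' @param bonds integer matrix with columns `from`, `to`, `order`
#'   (orders must be 1, 2 or 3), or NULL for an atom-only record.
#' @param charges formal charges, integer vector (default all 0).
#' @param coords numeric n x 3 matrix of coordinates in Angstrom, or NULL.
#' @param atom_charges per-atom partial charges (dimensionless e), or NULL.
#' @param props named list/character vector of SDF property tags.
#' @param name molecule name (SDF title line).
#' @return an object of class `hbmol`.
#' @export
hbmol <- function(elements, bonds = NULL, charges = NULL, coords = NULL,
                  atom_charges = NULL, props = list(), name = "") {
  n <- length(elements)
  if (n == 0L) stop("a molecule needs at least one atom")
  elements <- as.character(elements)
  unknown <- setdiff(unique(elements), names(.atomic_masses))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (is.null(charges)) charges <- integer(n)
  if (length(charges) != n) stop("charges length must equal atom count")
  if (is.null(bonds)) {
    bonds <- matrix(integer(0), ncol = 3,
                    dimnames = list(NULL, c("from", "to", "order")))
  } else {
    bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 3,
                    dimnames = list(NULL, c("from", "to", "order")))
    if (nrow(bonds)) {
      idx <- c(bonds[, 1], bonds[, 2])
      if (any(idx < 1L) || any(idx > n))
        stop("bond refers to atom index out of range")
      if (!all(bonds[, 3] %in% 1:3))
        stop("bond orders must be 1, 2 or 3 (kekulized graph)")
    }
  }
  if (!is.null(coords)) {
    coords <- matrix(as.numeric(coords), ncol = 3)
    if (nrow(coords) != n) stop("coords must have one row per atom")
  }
  if (!is.null(atom_charges)) {
    atom_charges <- as.numeric(atom_charges)
    if (length(atom_charges) != n)
      stop("atom_charges length must equal atom count")
  }
  props <- as.list(props)
  if (length(props) && is.null(names(props)))
    stop("props must be named")
  structure(list(elements = elements, charges = as.integer(charges),
                 bonds = bonds, coords = coords,
                 atom_charges = atom_charges, props = props,
                 name = as.character(name)),
            class = "hbmol")
}

#' @export
print.hbmol <- function(x, ...) {
  nh <- sum(x$elements == "H")
  cat(sprintf("<hbmol> %s: %d atoms (%d heavy), %d bonds",
              if (nzchar(x$name)) x$name else "(unnamed)",
              n_atoms(x), n_atoms(x) - nh, nrow(x$bonds)))
  if (!is.null(x$coords)) cat(", 3D")
  if (!is.null(x$atom_charges)) cat(", partial charges")
  if (length(x$props)) cat(sprintf(", %d props", length(x$props)))
  cat("\n")
  invisible(x)
}

#' Number of atoms in a record
#' @param mol an `hbmol`.
#' @export
n_atoms <- function(mol) length(mol$elements)

#' Adjacency list of a molecule
#' @return list: for each atom, data.frame of neighbor index + bond order.
#' @keywords internal
adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- list(nbr = integer(0), order = integer(0))
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b[k, 1]; j <- b[k, 2]; o <- b[k, 3]
    adj[[i]]$nbr <- c(adj[[i]]$nbr, j); adj[[i]]$order <- c(adj[[i]]$order, o)
    adj[[j]]$nbr <- c(adj[[j]]$nbr, i); adj[[j]]$order <- c(adj[[j]]$order, o)
  }
  adj
}

#' Neighbor indices of one atom
#' @keywords internal
neighbors_of <- function(mol, i) {
  b <- mol$bonds
  c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
}

#' Graph (topological) distances from a center atom by BFS
#'
#' @param mol an `hbmol`.
#' @param center 1-based atom index.
#' @return integer vector of bond-count distances; `Inf` (stored as NA)
#'   for atoms disconnected from the center.
#' @export
graph_distances <- function(mol, center) {
  n <- n_atoms(mol)
  stopifnot(center >= 1L, center <= n)
  adj <- adjacency(mol)
  d <- rep(NA_integer_, n)
  d[center] <- 0L
  frontier <- center
  k <- 0L
  while (length(frontier)) {
    k <- k + 1L
    nxt <- integer(0)
    for (i in frontier) {
      for (j in adj[[i]]$nbr) if (is.na(d[j])) { d[j] <- k; nxt <- c(nxt, j) }
    }
    frontier <- unique(nxt)
  }
  d
}

#' Sum of bond orders at each atom
#' @keywords internal
bond_order_sums <- function(mol) {
  s <- numeric(n_atoms(mol))
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    s[b[k, 1]] <- s[b[k, 1]] + b[k, 3]
    s[b[k, 2]] <- s[b[k, 2]] + b[k, 3]
  }
  s
}

#' Implicit hydrogen counts under the standard valence model
#'
#' Hydrogens implied by default valences minus bonded order, adjusted for
#' formal charge (N+ 4, O- 1, etc.).  Explicit H atoms count as ordinary
#' neighbors, so a fully explicit molecule returns all zeros.
#'
#' @param mol an `hbmol`.
#' @export
implicit_h_counts <- function(mol) {
  bos <- bond_order_sums(mol)
  n <- n_atoms(mol)
  out <- integer(n)
  for (i in seq_len(n)) {
    el <- mol$elements[i]
    v <- .default_valence[el]
    if (is.na(v)) { out[i] <- 0L; next }
    q <- mol$charges[i]
    adj_v <- v
    if (el %in% c("N", "P")) adj_v <- v + q
    if (el %in% c("O", "S")) adj_v <- v + q
    if (el == "C" && q != 0) adj_v <- v - abs(q)
    out[i] <- max(0L, as.integer(round(adj_v - bos[i])))
  }
  out
}

#' Materialize implicit hydrogens as explicit atoms
#'
#' Appends one H atom per implicit hydrogen, bonded with order 1.  If the
#' molecule carries coordinates, hydrogens are placed 1.09 Angstrom from
#' their parent in a deterministic direction; if it carries partial
#' charges, new hydrogens get charge 0.
#'
#' @param mol an `hbmol`.
#' @return an `hbmol` with no implicit hydrogens left.
#' @export
add_hydrogens <- function(mol) {
  hc <- implicit_h_counts(mol)
  if (!any(hc > 0L)) return(mol)
  elements <- mol$elements
  charges <- mol$charges
  bonds <- mol$bonds
  coords <- mol$coords
  ach <- mol$atom_charges
  n <- length(elements)
  for (i in which(hc > 0L)) {
    for (k in seq_len(hc[i])) {
      n <- n + 1L
      elements <- c(elements, "H")
      charges <- c(charges, 0L)
      bonds <- rbind(bonds, c(i, n, 1L))
      if (!is.null(coords)) {
        # deterministic placement fanned around the parent
        ang <- 2.399963 * (n + k)   # golden-angle spacing
        dir <- c(cos(ang), sin(ang), cos(ang * 0.5) * 0.5)
        dir <- dir / sqrt(sum(dir^2))
        coords <- rbind(coords, coords[i, ] + 1.09 * dir)
      }
      if (!is.null(ach)) ach <- c(ach, 0)
    }
  }
  hbmol(elements, bonds, charges, coords, ach, mol$props, mol$name)
}

#' Molecular weight (implicit hydrogens included)
#' @param mol an `hbmol`.
#' @export
mol_weight <- function(mol) {
  sum(.atomic_masses[mol$elements]) +
    sum(implicit_h_counts(mol)) * .atomic_masses[["H"]]
}

#' igraph view of the heavy+H molecular graph
#' @keywords internal
as_igraph <- function(mol) {
  igraph::graph_from_edgelist(
    matrix(mol$bonds[, 1:2], ncol = 2), directed = FALSE) |>
    (\(g) if (igraph::vcount(g) < n_atoms(mol))
       igraph::add_vertices(g, n_atoms(mol) - igraph::vcount(g)) else g)()
}

#' Indices of atoms that are part of some ring
#' @param mol an `hbmol`.
#' @export
ring_atoms <- function(mol) {
  if (!nrow(mol$bonds)) return(integer(0))
  g <- as_igraph(mol)
  br <- igraph::bridges(g)
  keep <- setdiff(seq_len(nrow(mol$bonds)), as.integer(br))
  sort(unique(c(mol$bonds[keep, 1], mol$bonds[keep, 2])))
}

#' Fused ring systems of a molecule
#'
#' A ring system is a connected component of the subgraph induced by ring
#' bonds (bonds lying on at least one cycle); fused and spiro-free
#' bridged rings sharing a bond end up in the same system.
#'
#' @param mol an `hbmol`.
#' @return list of integer vectors of atom indices, one per system.
#' @export
ring_systems <- function(mol) {
  if (!nrow(mol$bonds)) return(list())
  g <- as_igraph(mol)
  br <- as.integer(igraph::bridges(g))
  ring_edges <- setdiff(seq_len(nrow(mol$bonds)), br)
  if (!length(ring_edges)) return(list())
  sub <- igraph::subgraph_from_edges(g, ring_edges, delete.vertices = FALSE)
  comp <- igraph::components(sub)
  deg <- igraph::degree(sub)
  out <- list()
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid & deg > 0)
    if (length(members) >= 3) out[[length(out) + 1L]] <- sort(members)
  }
  out
}

#' Number of rings (SSSR count via cyclomatic number per component)
#' @param mol an `hbmol`.
#' @export
ring_count <- function(mol) {
  g <- as_igraph(mol)
  comp <- igraph::components(g)
  nrow(mol$bonds) - n_atoms(mol) + comp$no
}

#' Net formal charge of a molecule
#' @param mol an `hbmol`.
#' @export
net_charge <- function(mol) sum(mol$charges)

#' Explicit hydrogen neighbors of an atom
#' @keywords internal
h_neighbors <- function(mol, i) {
  nb <- neighbors_of(mol, i)
  nb[mol$elements[nb] == "H"]
}

#' Heavy-atom neighbors of an atom
#' @keywords internal
heavy_neighbors <- function(mol, i) {
  nb <- neighbors_of(mol, i)
  nb[mol$elements[nb] != "H"]
}
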