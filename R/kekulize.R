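# Resolution of aromatic-typed (order 4) SDF bonds into alternating
# single/double bonds.  Heterocycles are the reason this package insists
# on kekulized graphs: aromaticity perception differs between toolkits,
# explicit bond orders do not.

#' Kekulize a molecular graph with aromatic-typed bonds
#'
#' Bonds of order 4 are resolved to single/double by perfect matching on
#' the aromatic subgraph.  An aromatic atom "needs" exactly one double
#' bond when it is a carbon (without an exocyclic double bond already) or
#' a pyridine-type nitrogen (two connections, no hydrogen, neutral);
#' pyrrole-type N, O and S contribute a lone pair and take only single
#' bonds.  Backtracking search over the needy atoms yields a valid
#' alternation or fails.
#'
#' @param elements,bonds,charges as in [hbmol()] but with bond order 4
#'   allowed; `h_counts` gives explicit+implicit hydrogen counts per atom
#'   (used to classify N).
#' @return bonds matrix with all orders in 1..3, or NULL when no valid
#'   kekule structure exists.
#' @keywords internal
kekulize_bonds <- function(elements, bonds, charges, h_counts) {
  arom <- which(bonds[, 3] == 4L)
  if (!length(arom)) return(bonds)
  arom_atoms <- sort(unique(c(bonds[arom, 1], bonds[arom, 2])))
  degree <- table(factor(c(bonds[, 1], bonds[, 2]),
                         levels = seq_along(elements)))
  # does this aromatic atom require one double bond?
  needs <- logical(length(elements))
  for (a in arom_atoms) {
    el <- elements[a]
    q <- charges[a]
    exo_double <- any(bonds[, 3] %in% c(2L, 3L) &
                        (bonds[, 1] == a | bonds[, 2] == a))
    needs[a] <- if (exo_double) FALSE
    else if (el == "C") q == 0
    else if (el == "N") (q == 0 && h_counts[a] == 0 && degree[a] == 2) ||
      (q == 1 && h_counts[a] == 0 && degree[a] == 3)
    else FALSE
  }
  # perfect matching of 'needy' atoms along aromatic bonds, backtracking
  edges <- bonds[arom, , drop = FALSE]
  matched <- logical(length(elements))
  assign_order <- integer(length(arom))  # 0 unset, 1 single, 2 double
  needy <- arom_atoms[needs[arom_atoms]]

  edge_idx_of <- lapply(seq_along(elements), function(a)
    which(edges[, 1] == a | edges[, 2] == a))

  solve <- function(pos) {
    while (pos <= length(needy) && matched[needy[pos]]) pos <- pos + 1L
    if (pos > length(needy)) return(TRUE)
    a <- needy[pos]
    for (e in edge_idx_of[[a]]) {
      if (assign_order[e] != 0L) next
      b <- if (edges[e, 1] == a) edges[e, 2] else edges[e, 1]
      if (!needs[b] || matched[b]) next
      assign_order[e] <<- 2L
      matched[a] <<- TRUE; matched[b] <<- TRUE
      if (solve(pos + 1L)) return(TRUE)
      assign_order[e] <<- 0L
      matched[a] <<- FALSE; matched[b] <<- FALSE
    }
    FALSE
  }
  if (!solve(1L)) return(NULL)
  new_orders <- ifelse(assign_order == 2L, 2L, 1L)
  bonds[arom, 3] <- new_orders
  bonds
}
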