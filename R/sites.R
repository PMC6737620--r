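# Perception of hydrogen-bond acceptor and donor sites on kekulized
# molecular graphs.
#
# Acceptors: every oxygen; every nitrogen unless it has a covalent bond
# (any order) to an oxygen -- which excludes nitro-N, N-oxide-N and
# nitroso-N while keeping both nitro oxygens as acceptors.
# Donors: R-OH, R-NH2, R1-NH-R2 (secondary amines, heterocyclic and
# amide N-H), R-SH, and terminal alkyne C-H.  The R requirement means
# the heavy atom must have at least one heavy-atom neighbor, so bare
# water/ammonia are not annotated.

#' Construct a site annotation
#' @param atom_index 1-based index of the heavy atom.
#' @param role "HBA" or "HBD".
#' @param site_kind one of O_acceptor, N_acceptor, OH_donor, NH2_donor,
#'   NH_donor, SH_donor, alkyne_CH_donor.
#' @param donated_h_index for donors, 1-based index of the donated
#'   hydrogen (lowest-index attached H).
#' @export
site_annotation <- function(atom_index, role, site_kind,
                            donated_h_index = NA_integer_) {
  structure(list(atom_index = as.integer(atom_index), role = role,
                 site_kind = site_kind,
                 donated_h_index = as.integer(donated_h_index)),
            class = "hb_site")
}

#' @export
print.hb_site <- function(x, ...) {
  cat(sprintf("<hb_site> %s %s at atom %d%s\n", x$role, x$site_kind,
              x$atom_index,
              if (!is.na(x$donated_h_index))
                sprintf(" (H at %d)", x$donated_h_index) else ""))
  invisible(x)
}

#' Find hydrogen-bond acceptor sites
#'
#' Every oxygen and every nitrogen not bonded to an oxygen (any bond
#' order) is annotated, in atom-index order.
#'
#' @param mol an [hbmol()] (kekulized).
#' @return list of site annotations (possibly empty).
#' @export
find_acceptor_sites <- function(mol) {
  out <- list()
  for (i in seq_len(n_atoms(mol))) {
    el <- mol$elements[i]
    if (el == "O") {
      out[[length(out) + 1L]] <- site_annotation(i, "HBA", "O_acceptor")
    } else if (el == "N") {
      nb <- neighbors_of(mol, i)
      if (!any(mol$elements[nb] == "O"))
        out[[length(out) + 1L]] <- site_annotation(i, "HBA", "N_acceptor")
    }
  }
  out
}

#' Find hydrogen-bond donor sites
#'
#' One annotation per matching heavy atom; the donated hydrogen is the
#' lowest-index attached H.  Hydrogens must be explicit on candidate
#' heavy atoms (see [add_hydrogens()]); an implicit-H candidate raises an
#' error rather than guessing an index.
#'
#' @param mol an [hbmol()] (kekulized).
#' @return list of site annotations (possibly empty).
#' @export
find_donor_sites <- function(mol) {
  out <- list()
  impl <- implicit_h_counts(mol)
  adj <- adjacency(mol)
  for (i in seq_len(n_atoms(mol))) {
    el <- mol$elements[i]
    if (!el %in% c("O", "N", "S", "C")) next
    hs <- h_neighbors(mol, i)
    heavies <- heavy_neighbors(mol, i)
    if (el %in% c("O", "N", "S") && impl[i] > 0L)
      stop(sprintf(
        "atom %d (%s) has implicit hydrogens; call add_hydrogens() before donor perception",
        i, el))
    if (!length(hs) || !length(heavies)) next
    kind <- NULL
    if (el == "O" && length(heavies) == 1L) kind <- "OH_donor"
    else if (el == "N") kind <- if (length(hs) >= 2L) "NH2_donor" else "NH_donor"
    else if (el == "S" && length(heavies) == 1L) kind <- "SH_donor"
    else if (el == "C") {
      # terminal alkyne: sp carbon in a triple bond whose partner bears R
      ords <- adj[[i]]$order
      trip <- adj[[i]]$nbr[ords == 3L]
      if (length(trip) == 1L && mol$elements[trip] == "C" &&
          length(hs) == 1L &&
          length(heavy_neighbors(mol, trip)) >= 2L)
        kind <- "alkyne_CH_donor"
    }
    if (!is.null(kind))
      out[[length(out) + 1L]] <- site_annotation(i, "HBD", kind, min(hs))
  }
  out
}

#' Find sites of one or both roles
#' @param mol an [hbmol()].
#' @param role "HBA", "HBD" or "both".
#' @export
find_sites <- function(mol, role = c("both", "HBA", "HBD")) {
  role <- match.arg(role)
  switch(role,
         HBA = find_acceptor_sites(mol),
         HBD = find_donor_sites(mol),
         both = c(find_acceptor_sites(mol), find_donor_sites(mol)))
}

#' Tabulate sites over a list of molecules
#' @param mols list of [hbmol()] records.
#' @param role "HBA", "HBD" or "both".
#' @return data.frame: record ordinal, atom index, role, site_kind,
#'   donated H index.
#' @export
sites_table <- function(mols, role = "both") {
  rows <- list()
  for (m in seq_along(mols)) {
    for (s in find_sites(mols[[m]], role)) {
      rows[[length(rows) + 1L]] <- data.frame(
        record = m, atom_index = s$atom_index, role = s$role,
        site_kind = s$site_kind, donated_h_index = s$donated_h_index)
    }
  }
  if (!length(rows))
    return(data.frame(record = integer(0), atom_index = integer(0),
                      role = character(0), site_kind = character(0),
                      donated_h_index = integer(0)))
  do.call(rbind, rows)
}
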