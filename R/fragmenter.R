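# Extraction of hydrogen-bonding fragments by topological shells around
# a perceived site, followed by element/ring/weight/site-count
# filtering, canonical-SMILES deduplication, class assignment and
# fingerprint-based diversity selection.
#
# Three topology cases, decided in priority order ring > ring+sidechain
# > chain:
#   ring           -- the site atom lies in a ring: its whole fused ring
#                     system plus side-chain atoms within 4 bonds.
#   ring_sidechain -- a ring atom occurs within 3 bonds of the site: the
#                     complete fused ring system(s) of those atoms plus
#                     everything within 4 bonds.
#   chain          -- no ring atom within 3 bonds: everything within 4
#                     bonds; ring atoms appearing exactly in the 4th
#                     shell are element-substituted by an sp3 carbon cap
#                     so shell occupancy is preserved without importing
#                     ring context.
# Open valences left by severed bonds are capped with hydrogens (one per
# severed bond order unit).

#' Fragment filter configuration
#'
#' @param allowed_elements organic element whitelist.
#' @param max_rings maximum ring count (cyclomatic), kept iff <=.
#' @param max_mw molecular weight bound in Dalton, kept iff strictly
#'   below.
#' @param max_sites maximum number of sites of the fragment's role, kept
#'   iff <=.
#' @param mw_correction "none" (plain MW) or "halogen_corrected"
#'   (subtract mass - 35.45 for each Br/I, so heavy halogens weigh like
#'   chlorine).
#' @export
fragment_filter_config <- function(
    allowed_elements = c("H", "C", "N", "O", "F", "Cl", "S", "Br", "I"),
    max_rings = 3, max_mw = 300, max_sites = 4,
    mw_correction = c("none", "halogen_corrected")) {
  stopifnot(max_rings > 0, max_mw > 0, max_sites > 0)
  structure(list(allowed_elements = allowed_elements,
                 max_rings = max_rings, max_mw = max_mw,
                 max_sites = max_sites,
                 mw_correction = match.arg(mw_correction)),
            class = "fragment_filter_config")
}

#' Extract the hydrogen-bonding fragment around a site
#'
#' @param mol an [hbmol()] with explicit hydrogens.
#' @param site a site annotation from [find_sites()].
#' @param parent_id identifier recorded as provenance (default the
#'   molecule name or its ordinal attribute).
#' @return an object of class `hb_fragment`: `$mol`, `$site` (indices
#'   remapped to the fragment), `$topo_case`, `$canonical_key`,
#'   `$parent_ids`, `$incidence`, `$class_label` (filled by
#'   [assign_class()]).
#' @export
extract_fragment <- function(mol, site, parent_id = NULL) {
  stopifnot(inherits(mol, "hbmol"), inherits(site, "hb_site"))
  center <- site$atom_index
  if (center < 1L || center > n_atoms(mol))
    stop("site atom index out of range")
  if (n_atoms(mol) > 1L && !length(neighbors_of(mol, center)))
    stop("site atom is disconnected from the molecule")
  d <- graph_distances(mol, center)
  ratoms <- ring_atoms(mol)
  rsys <- ring_systems(mol)
  in_ring <- center %in% ratoms
  near_ring <- intersect(which(!is.na(d) & d >= 1L & d <= 3L), ratoms)
  substitute_c <- integer(0)
  if (in_ring) {
    topo_case <- "ring"
    sys <- unlist(rsys[vapply(rsys, function(s) center %in% s, logical(1))])
    keep <- union(which(!is.na(d) & d <= 4L), sys)
  } else if (length(near_ring)) {
    topo_case <- "ring_sidechain"
    sys <- unlist(rsys[vapply(rsys, function(s)
      any(near_ring %in% s), logical(1))])
    keep <- union(which(!is.na(d) & d <= 4L), sys)
  } else {
    topo_case <- "chain"
    keep <- which(!is.na(d) & d <= 4L)
    substitute_c <- intersect(which(!is.na(d) & d == 4L), ratoms)
  }
  keep <- sort(keep)
  remap <- match(seq_len(n_atoms(mol)), keep)
  elements <- mol$elements[keep]
  charges <- mol$charges[keep]
  if (length(substitute_c)) {
    sel <- remap[substitute_c]
    elements[sel] <- "C"
    charges[sel] <- 0L
  }
  coords <- if (!is.null(mol$coords)) mol$coords[keep, , drop = FALSE]
  ach <- if (!is.null(mol$atom_charges)) mol$atom_charges[keep]
  b <- mol$bonds
  inside <- !is.na(remap[b[, 1]]) & !is.na(remap[b[, 2]])
  bonds <- cbind(remap[b[inside, 1]], remap[b[inside, 2]],
                 b[inside, 3, drop = TRUE])
  bonds <- matrix(as.integer(bonds), ncol = 3)
  # cap severed bonds with hydrogens (one per order unit)
  nfrag <- length(keep)
  sever <- which(xor(is.na(remap[b[, 1]]), is.na(remap[b[, 2]])))
  for (k in sever) {
    inside_atom <- if (is.na(remap[b[k, 1]])) b[k, 2] else b[k, 1]
    outside_atom <- if (is.na(remap[b[k, 1]])) b[k, 1] else b[k, 2]
    ia <- remap[inside_atom]
    for (rep_h in seq_len(b[k, 3])) {
      nfrag <- nfrag + 1L
      elements <- c(elements, "H")
      charges <- c(charges, 0L)
      bonds <- rbind(bonds, c(ia, nfrag, 1L))
      if (!is.null(coords)) {
        dir <- mol$coords[outside_atom, ] - mol$coords[inside_atom, ]
        nrm <- sqrt(sum(dir^2))
        if (nrm < 1e-8) dir <- c(1, 0, 0) else dir <- dir / nrm
        coords <- rbind(coords,
                        mol$coords[inside_atom, ] + 1.09 * dir +
                          (rep_h - 1) * 0.05)
      }
      if (!is.null(ach)) ach <- c(ach, 0)
    }
  }
  fmol <- hbmol(elements, bonds, charges, coords, ach,
                props = list(), name = mol$name)
  fsite <- site_annotation(remap[center], site$role, site$site_kind,
                           if (!is.na(site$donated_h_index))
                             remap[site$donated_h_index]
                           else NA_integer_)
  if (is.na(fsite$atom_index)) stop("site atom lost during extraction")
  if (is.null(parent_id)) {
    parent_id <- if (nzchar(mol$name)) mol$name
    else if (!is.null(attr(mol, "ordinal")))
      as.character(attr(mol, "ordinal")) else "parent"
  }
  structure(list(mol = fmol, site = fsite, topo_case = topo_case,
                 canonical_key = mol_to_smiles(fmol),
                 parent_ids = as.character(parent_id), incidence = 1L,
                 class_label = NA_character_),
            class = "hb_fragment")
}

#' @export
print.hb_fragment <- function(x, ...) {
  cat(sprintf("<hb_fragment> %s %s (%s) key=%s incidence=%d\n",
              x$site$role, x$site$site_kind, x$topo_case,
              x$canonical_key, x$incidence))
  invisible(x)
}

#' Extract all fragments for one role over a molecule list
#' @param mols list of [hbmol()] with explicit hydrogens.
#' @param role "HBA" or "HBD".
#' @return list of `hb_fragment`.
#' @export
extract_fragments <- function(mols, role = c("HBA", "HBD")) {
  role <- match.arg(role)
  out <- list()
  for (m in seq_along(mols)) {
    mol <- mols[[m]]
    pid <- if (nzchar(mol$name)) mol$name else as.character(m)
    for (s in find_sites(mol, role))
      out[[length(out) + 1L]] <- extract_fragment(mol, s, pid)
  }
  out
}

# corrected molecular weight for the filter
.fragment_mw <- function(mol, mw_correction) {
  mw <- mol_weight(mol)
  if (mw_correction == "halogen_corrected") {
    heavy_hal <- mol$elements %in% c("Br", "I")
    mw <- mw - sum(.atomic_masses[mol$elements[heavy_hal]] - 35.45)
  }
  unname(mw)
}

#' Filter fragments by the organic-subset rules
#'
#' A fragment is kept iff all its elements are allowed, its ring count
#' is at most `max_rings`, its (possibly halogen-corrected) molecular
#' weight is strictly below `max_mw`, its number of sites of `role` is
#' at most `max_sites`, and its net formal charge is zero.  Each
#' rejection reports the first failing rule.
#'
#' @param frags list of `hb_fragment`.
#' @param cfg a [fragment_filter_config()].
#' @param role "HBA" or "HBD".
#' @return list with `kept` (fragments) and `rejected` (data.frame:
#'   index, canonical key, reason in {element, rings, mw, sites,
#'   charge}).
#' @export
filter_fragments <- function(frags, cfg = fragment_filter_config(),
                             role = c("HBA", "HBD")) {
  role <- match.arg(role)
  kept <- list()
  rej <- list()
  for (i in seq_along(frags)) {
    f <- frags[[i]]
    reason <- NULL
    if (!all(f$mol$elements %in% cfg$allowed_elements)) reason <- "element"
    else if (ring_count(f$mol) > cfg$max_rings) reason <- "rings"
    else if (.fragment_mw(f$mol, cfg$mw_correction) >= cfg$max_mw)
      reason <- "mw"
    else if (length(find_sites(f$mol, role)) > cfg$max_sites)
      reason <- "sites"
    else if (net_charge(f$mol) != 0L) reason <- "charge"
    if (is.null(reason)) kept[[length(kept) + 1L]] <- f
    else rej[[length(rej) + 1L]] <- data.frame(
      index = i, canonical_key = f$canonical_key, reason = reason)
  }
  rejected <- if (length(rej)) do.call(rbind, rej)
  else data.frame(index = integer(0), canonical_key = character(0),
                  reason = character(0))
  list(kept = kept, rejected = rejected)
}

#' Deduplicate fragments by canonical key
#'
#' Merges fragments with identical canonical SMILES: incidences add,
#' parent identifiers concatenate; output sorted by descending incidence
#' then key.  Idempotent.
#'
#' @param frags list of `hb_fragment`.
#' @export
dedup_fragments <- function(frags) {
  if (!length(frags)) return(frags)
  keys <- vapply(frags, function(f) f$canonical_key, character(1))
  groups <- split(seq_along(frags), keys)
  merged <- lapply(groups, function(idx) {
    f <- frags[[idx[1]]]
    f$incidence <- sum(vapply(frags[idx], function(g)
      g$incidence, integer(1)))
    f$parent_ids <- unname(unlist(lapply(frags[idx],
                                         function(g) g$parent_ids)))
    f
  })
  inc <- vapply(merged, function(f) f$incidence, integer(1))
  unname(merged[order(-inc, names(groups))])
}

#' Assign the element x topology class label
#'
#' Acceptor classes combine the site element (O, N) with the topology
#' case; donor classes use element classes O, N, S, Csp (terminal
#' alkyne).
#'
#' @param frag an `hb_fragment`.
#' @return the fragment with `class_label` set (e.g. "O-chain",
#'   "N-ring", "Csp-chain").
#' @export
assign_class <- function(frag) {
  el <- frag$mol$elements[frag$site$atom_index]
  lab <- if (frag$site$role == "HBA") {
    if (!el %in% c("O", "N"))
      stop("unexpected acceptor element: ", el)
    el
  } else {
    if (!el %in% c("O", "N", "S", "C"))
      stop("unexpected donor element: ", el)
    if (el == "C") "Csp" else el
  }
  frag$class_label <- paste0(lab, "-", frag$topo_case)
  frag
}

#' MACCS structural-key fingerprints of fragments
#'
#' 166-bit MDL public keys computed by OpenBabel (returned zero-padded
#' to 256 columns).
#'
#' @param frags list of `hb_fragment` (or `hbmol`).
#' @return binary matrix, one row per fragment.
#' @export
maccs_fingerprints <- function(frags) {
  mols <- lapply(frags, function(f) if (inherits(f, "hb_fragment")) f$mol
                 else f)
  txt <- paste(vapply(mols, function(m)
    paste(c(.mol_to_block(m), "$$$$"), collapse = "\n"), character(1)),
    collapse = "\n")
  obm <- ChemmineOB::forEachMol("SDF", paste0(txt, "\n"), identity)
  fp <- ChemmineOB::fingerprint_OB(obm, "MACCS")
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
  if (nrow(fp) != length(mols))
    stop("fingerprint generation lost molecules")
  fp
}

#' Tanimoto distance matrix of binary fingerprints
#' @param fp binary matrix (rows = molecules).
#' @return symmetric distance matrix, 1 - Tanimoto similarity.
#' @export
tanimoto_dist <- function(fp) {
  fp <- as.matrix(fp)
  ab <- fp %*% t(fp)
  n1 <- rowSums(fp)
  tot <- outer(n1, n1, "+") - ab
  sim <- ifelse(tot == 0, 1, ab / pmax(tot, 1e-300))
  d <- 1 - sim
  diag(d) <- 0
  d
}

# maximum-dissimilarity seeding + nearest-seed assignment + medoid
# refinement on a distance matrix; deterministic given RNG state
.cluster_maxdiss <- function(d, k) {
  n <- nrow(d)
  k <- min(k, n)
  seeds <- sample.int(n, 1)
  while (length(seeds) < k) {
    mind <- apply(d[, seeds, drop = FALSE], 1, min)
    mind[seeds] <- -1
    seeds <- c(seeds, which.max(mind))
  }
  assign <- apply(d[, seeds, drop = FALSE], 1, which.min)
  for (it in 1:25) {
    medoids <- vapply(seq_len(k), function(c) {
      members <- which(assign == c)
      if (!length(members)) return(seeds[c])
      members[which.min(rowSums(d[members, members, drop = FALSE]))]
    }, integer(1))
    new_assign <- apply(d[, medoids, drop = FALSE], 1, which.min)
    if (all(new_assign == assign)) break
    assign <- new_assign
    seeds <- medoids
  }
  assign
}

#' Diversity selection of fragments by clustering
#'
#' Per class (or over the whole set): MACCS fingerprints, Tanimoto
#' distance, `max(1, floor(N / k_divisor))` clusters grown by
#' maximum-dissimilarity seeding with medoid refinement; from each
#' cluster the `keep_central` most central members (minimum summed
#' intra-cluster distance) are kept, never more than `cluster_cap`.
#' Deterministic under `seed`.
#'
#' @param frags list of `hb_fragment` with class labels (see
#'   [assign_class()]) when `per_class = TRUE`.
#' @param per_class cluster within each class label (default TRUE).
#' @param k_divisor cluster-count divisor (default 25).
#' @param keep_central members kept per cluster (default 3).
#' @param cluster_cap hard per-cluster cap (default 30).
#' @param seed RNG seed.
#' @return list of selected `hb_fragment`.
#' @export
select_diverse <- function(frags, per_class = TRUE, k_divisor = 25,
                           keep_central = 3, cluster_cap = 30, seed = 1) {
  if (!length(frags)) return(frags)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  labels <- if (per_class) {
    lv <- vapply(frags, function(f) f$class_label, character(1))
    if (anyNA(lv)) stop("fragments must carry class labels; see assign_class()")
    lv
  } else rep("all", length(frags))
  out <- list()
  for (lab in sort(unique(labels))) {
    idx <- which(labels == lab)
    if (!length(idx)) { message("class ", lab, " empty; skipped"); next }
    sub <- frags[idx]
    if (length(sub) == 1L) { out <- c(out, sub); next }
    fp <- maccs_fingerprints(sub)
    d <- tanimoto_dist(fp)
    k <- max(1L, floor(length(sub) / k_divisor))
    assign <- .cluster_maxdiss(d, k)
    for (c in sort(unique(assign))) {
      members <- which(assign == c)
      central <- members[order(rowSums(d[members, members,
                                         drop = FALSE]))]
      take <- utils::head(central, min(keep_central, cluster_cap))
      out <- c(out, sub[take])
    }
  }
  out
}

#' Write fragments to an SDF with provenance tags
#'
#' Tags: CANONICAL_KEY, TOPO_CASE, CLASS, INCIDENCE, SITE_IDX (1-based),
#' ROLE, PARENT_IDS.
#'
#' @param frags list of `hb_fragment`.
#' @param path output SDF.
#' @export
write_fragments <- function(frags, path) {
  recs <- lapply(frags, function(f) {
    m <- f$mol
    m$props <- c(m$props, list(
      CANONICAL_KEY = f$canonical_key, TOPO_CASE = f$topo_case,
      CLASS = as.character(f$class_label),
      INCIDENCE = as.character(f$incidence),
      SITE_IDX = as.character(f$site$atom_index), ROLE = f$site$role,
      PARENT_IDS = paste(f$parent_ids, collapse = " ")))
    m
  })
  write_sdf(recs, path)
}
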