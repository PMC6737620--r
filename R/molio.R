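# V2000 SDF reading/writing in the dialect used by the strength
# databases: per-record property tags carry site indices, free energies,
# complex geometry metadata and optional per-atom partial charges.

#' Default property-tag dictionary
#'
#' Maps the package's field names onto SDF tag names.  The supplementary
#' databases of different provenance spell their tags differently; pass a
#' modified copy (JSON-loadable) to the readers to adapt.  Readers fail
#' loudly, listing the tags actually present, when a required tag is
#' missing.
#'
#' @return named list of tag names.
#' @export
default_tag_dict <- function() {
  list(
    atom_charges     = "ATOM_CHARGES",
    role             = "ROLE",
    site_index       = "SITE_IDX",
    dg               = "DG_KJMOL",
    dg_qc            = "DG_QC_KJMOL",
    xh_distance      = "XH_DISTANCE",
    lowest_freq      = "LOWEST_FREQ",
    converged        = "CONVERGED",
    functional_class = "FUNCTIONAL_CLASS",
    e_highdft        = c("E_HIGHDFT_COMPLEX", "E_HIGHDFT_MOLECULE",
                         "E_HIGHDFT_REFERENCE"),
    g_rrho           = c("G_RRHO_COMPLEX", "G_RRHO_MOLECULE",
                         "G_RRHO_REFERENCE"),
    dg_solv          = c("DG_SOLV_COMPLEX", "DG_SOLV_MOLECULE",
                         "DG_SOLV_REFERENCE")
  )
}

#' Load a tag dictionary from JSON
#' @param path JSON file mapping field names to tag names.
#' @export
read_tag_dict <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- default_tag_dict()
  for (k in names(d)) out[[k]] <- d[[k]]
  out
}

.legacy_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                    `5` = -1L, `6` = -2L, `7` = -3L)

# parse one molblock + data block into an hbmol (or condition)
.parse_record <- function(lines, ordinal, require_kekulized, tag_dict) {
  if (length(lines) < 4L)
    stop(sprintf("record %d: truncated molblock", ordinal))
  name <- trimws(lines[1])
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds))
    stop(sprintf("record %d: malformed counts line '%s'", ordinal, counts))
  if (length(lines) < 4L + natoms + nbonds)
    stop(sprintf("record %d: molblock shorter than counts line claims",
                 ordinal))
  atom_lines <- lines[4L + seq_len(natoms)]
  elements <- character(natoms)
  coords <- matrix(0, natoms, 3)
  charges <- integer(natoms)
  for (i in seq_len(natoms)) {
    ln <- atom_lines[i]
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 1, 10),
                                         substr(ln, 11, 20),
                                         substr(ln, 21, 30))))
    sym <- trimws(substr(ln, 32, 34))
    if (any(is.na(xyz)) || !nzchar(sym))
      stop(sprintf("record %d: malformed atom line %d", ordinal, i))
    coords[i, ] <- xyz
    elements[i] <- sym
    cc <- suppressWarnings(as.integer(substr(ln, 37, 39)))
    if (!is.na(cc) && as.character(cc) %in% names(.legacy_charge))
      charges[i] <- .legacy_charge[[as.character(cc)]]
  }
  bonds <- matrix(integer(0), 0, 3)
  if (nbonds > 0) {
    bl <- lines[4L + natoms + seq_len(nbonds)]
    bonds <- matrix(0L, nbonds, 3)
    for (i in seq_len(nbonds)) {
      ln <- bl[i]
      v <- suppressWarnings(as.integer(c(substr(ln, 1, 3), substr(ln, 4, 6),
                                         substr(ln, 7, 9))))
      if (any(is.na(v)))
        stop(sprintf("record %d: malformed bond line %d", ordinal, i))
      bonds[i, ] <- v
    }
  }
  rest <- lines[-seq_len(4L + natoms + nbonds)]
  chg_lines <- grep("^M  CHG", rest, value = TRUE)
  if (length(chg_lines)) {
    charges[] <- 0L
    for (ln in chg_lines) {
      f <- strsplit(trimws(sub("^M  CHG\\s+\\d+", "", ln)), "\\s+")[[1]]
      f <- as.integer(f)
      for (k in seq_len(length(f) / 2))
        charges[f[2 * k - 1]] <- f[2 * k]
    }
  }
  # property block
  mend <- grep("^M  END", rest)
  props <- list()
  if (length(mend)) {
    dat <- rest[-seq_len(mend[1])]
    i <- 1L
    while (i <= length(dat)) {
      m <- regmatches(dat[i], regexec("^>.*<([^>]+)>", dat[i]))[[1]]
      if (length(m) == 2L) {
        tag <- m[2]
        vals <- character(0)
        i <- i + 1L
        while (i <= length(dat) && nzchar(trimws(dat[i]))) {
          vals <- c(vals, dat[i]); i <- i + 1L
        }
        props[[tag]] <- paste(vals, collapse = "\n")
      }
      i <- i + 1L
    }
  }
  # kekulize aromatic-typed bonds
  if (nrow(bonds) && any(bonds[, 3] == 4L)) {
    h_exp <- vapply(seq_len(natoms), function(a)
      sum(elements[c(bonds[bonds[, 1] == a, 2],
                     bonds[bonds[, 2] == a, 1])] == "H"), integer(1))
    kb <- kekulize_bonds(elements, bonds, charges, h_exp)
    if (is.null(kb)) {
      if (require_kekulized)
        return(structure(list(ordinal = ordinal,
                              reason = "kekulization failed",
                              name = name),
                         class = "hbmol_reject"))
      warning(sprintf("record %d (%s): kekulization failed; aromatic bonds kept as order 4",
                      ordinal, name))
    } else bonds <- kb
  }
  if (nrow(bonds) && any(!bonds[, 3] %in% 1:4))
    stop(sprintf("record %d: unsupported bond order", ordinal))
  atom_charges <- NULL
  act <- tag_dict$atom_charges
  if (!is.null(act) && act %in% names(props)) {
    atom_charges <- suppressWarnings(
      as.numeric(strsplit(trimws(props[[act]]), "\\s+")[[1]]))
    if (length(atom_charges) != natoms || anyNA(atom_charges))
      stop(sprintf("record %d: %s tag does not hold %d numeric values",
                   ordinal, act, natoms))
  }
  mol <- hbmol(elements, bonds, charges, coords, atom_charges, props, name)
  attr(mol, "ordinal") <- ordinal
  mol
}

#' Read a V2000 SDF file
#'
#' One record per molblock, in file order.  Aromatic-typed bonds (order
#' 4) are kekulized on read; records for which no kekule structure exists
#' are quarantined, not silently dropped: they are returned in the
#' `rejects` attribute (ordinal, name, reason) and optionally written to
#' a rejects file.
#'
#' @param path SDF file.
#' @param require_kekulized quarantine records that cannot be kekulized
#'   (default TRUE); with FALSE they are kept with order-4 bonds and a
#'   warning.
#' @param tag_dict tag dictionary, see [default_tag_dict()].
#' @param rejects_path optional path; quarantined record ordinals/reasons
#'   are written there as tab-separated text.
#' @return list of [hbmol()] records with attribute `rejects`
#'   (data.frame of ordinal, name, reason).
#' @export
read_sdf <- function(path, require_kekulized = TRUE,
                     tag_dict = default_tag_dict(), rejects_path = NULL) {
  lines <- readLines(path, warn = FALSE)
  parse_sdf_lines(lines, require_kekulized, tag_dict, rejects_path)
}

#' @keywords internal
parse_sdf_lines <- function(lines, require_kekulized = TRUE,
                            tag_dict = default_tag_dict(),
                            rejects_path = NULL) {
  recs <- list()
  rejects <- data.frame(ordinal = integer(0), name = character(0),
                        reason = character(0))
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    out <- recs; attr(out, "rejects") <- rejects; return(out)
  }
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) ends <- length(lines)  # tolerate missing terminator
  start <- 1L
  ordinal <- 0L
  for (e in ends) {
    chunk <- lines[start:min(e - 1L, length(lines))]
    start <- e + 1L
    if (!length(chunk) || all(!nzchar(trimws(chunk)))) next
    ordinal <- ordinal + 1L
    rec <- .parse_record(chunk, ordinal, require_kekulized, tag_dict)
    if (inherits(rec, "hbmol_reject")) {
      rejects <- rbind(rejects, data.frame(ordinal = rec$ordinal,
                                           name = rec$name,
                                           reason = rec$reason))
    } else recs[[length(recs) + 1L]] <- rec
  }
  if (!is.null(rejects_path))
    utils::write.table(rejects, rejects_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  attr(recs, "rejects") <- rejects
  recs
}

# fixed-width molblock of one record (no timestamp: byte-determinism)
.mol_to_block <- function(mol) {
  n <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  co <- if (is.null(mol$coords)) matrix(0, n, 3) else mol$coords
  out <- c(mol$name, "  hbstrength", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (i in seq_len(n))
    out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          co[i, 1], co[i, 2], co[i, 3], mol$elements[i]))
  for (k in seq_len(nb))
    out <- c(out, sprintf("%3d%3d%3d  0  0  0  0",
                          mol$bonds[k, 1], mol$bonds[k, 2], mol$bonds[k, 3]))
  chg <- which(mol$charges != 0L)
  while (length(chg)) {
    take <- chg[seq_len(min(8, length(chg)))]
    chg <- chg[-seq_len(min(8, length(chg)))]
    out <- c(out, paste0("M  CHG", sprintf("%3d", length(take)),
                         paste0(sprintf("%4d%4d", take, mol$charges[take]),
                                collapse = "")))
  }
  c(out, "M  END")
}

#' Write records to a V2000 SDF file
#'
#' Round-trips through [read_sdf()] preserve atoms, bonds, integer bond
#' orders, formal charges and all property-tag values.  Per-atom partial
#' charges, when present, are serialized to the `atom_charges` tag of the
#' dictionary as whitespace-separated decimals with 6 digits.
#'
#' @param records list of [hbmol()] (a single record is accepted).
#' @param path output file.
#' @param tag_dict tag dictionary naming the partial-charge tag.
#' @export
write_sdf <- function(records, path, tag_dict = default_tag_dict()) {
  if (inherits(records, "hbmol")) records <- list(records)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (mol in records) {
    lines <- .mol_to_block(mol)
    props <- mol$props
    if (!is.null(mol$atom_charges))
      props[[tag_dict$atom_charges]] <-
        paste(sprintf("%.6f", mol$atom_charges), collapse = " ")
    for (tag in names(props))
      lines <- c(lines, sprintf(">  <%s>", tag),
                 strsplit(as.character(props[[tag]]), "\n")[[1]], "")
    writeLines(c(lines, "$$$$"), con)
  }
  invisible(NULL)
}

#' Convert SMILES to molecule records
#'
#' Uses OpenBabel for SMILES interpretation; the resulting molblock is
#' kekulized (OpenBabel writes alternating single/double bonds).
#'
#' @param smiles character vector of SMILES strings.
#' @param names optional molecule names.
#' @param explicit_h materialize implicit hydrogens (default TRUE; site
#'   perception of donors and descriptor generation need explicit H).
#' @return list of [hbmol()] records.
#' @export
smiles_to_mol <- function(smiles, names = NULL, explicit_h = TRUE) {
  stopifnot(length(smiles) >= 1)
  txt <- ChemmineOB::convertFormat("SMI", "SDF",
                                   paste0(paste(smiles, collapse = "\n"), "\n"))
  recs <- parse_sdf_lines(strsplit(txt, "\n", fixed = TRUE)[[1]])
  if (length(recs) != length(smiles))
    stop("SMILES conversion lost records (", length(recs), " of ",
         length(smiles), " survived)")
  for (i in seq_along(recs)) {
    if (!is.null(names)) recs[[i]]$name <- names[i]
    if (explicit_h) recs[[i]] <- add_hydrogens(recs[[i]])
  }
  recs
}

#' Read a SMILES file (one molecule per line, optional name column)
#' @param path file with `SMILES [name]` per line.
#' @param explicit_h see [smiles_to_mol()].
#' @export
read_smiles <- function(path, explicit_h = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  parts <- strsplit(trimws(lines), "\\s+")
  smi <- vapply(parts, `[`, "", 1)
  nm <- vapply(parts, function(p) if (length(p) > 1)
    paste(p[-1], collapse = " ") else "", "")
  smiles_to_mol(smi, names = nm, explicit_h = explicit_h)
}

#' Canonical SMILES of a record (dedup key backend)
#' @param mol an `hbmol`.
#' @return canonical SMILES string.
#' @export
mol_to_smiles <- function(mol) {
  block <- paste(c(.mol_to_block(mol), "$$$$"), collapse = "\n")
  out <- ChemmineOB::convertFormat("SDF", "CAN", paste0(block, "\n"))
  smi <- strsplit(trimws(out), "\\s+")[[1]][1]
  if (is.na(smi) || !nzchar(smi)) stop("canonical SMILES generation failed")
  smi
}

.unit_factor <- function(units) {
  switch(match.arg(units, c("kj", "hartree", "kcal")),
         kj = 1, hartree = 2625.4996, kcal = 4.184)
}

.num_tag <- function(props, tag, ordinal, n_sites) {
  if (is.null(tag) || !tag %in% names(props)) return(rep(NA_real_, n_sites))
  v <- suppressWarnings(as.numeric(strsplit(trimws(props[[tag]]),
                                            "\\s+")[[1]]))
  if (anyNA(v))
    stop(sprintf("record %d: non-numeric value in tag <%s>", ordinal, tag))
  if (length(v) == 1L) rep(v, n_sites)
  else if (length(v) == n_sites) v
  else stop(sprintf("record %d: tag <%s> holds %d values for %d sites",
                    ordinal, tag, length(v), n_sites))
}

#' Read per-site strength entries from a database SDF
#'
#' Emits one entry per (record, annotated site).  Site atoms come from
#' the 1-based `site_index` tag; per-site numeric tags may hold one value
#' per site (whitespace-separated) or a single value recycled.  Missing
#' optional fields are NA, never silently zero.  Energy triples, when
#' present, are composed into the solution-phase reaction free energy and
#' checked against any stored value to 1e-6.
#'
#' @param path SDF file.
#' @param role "HBA" or "HBD"; if the file carries a role tag it must
#'   agree.
#' @param tag_dict tag dictionary, see [default_tag_dict()].
#' @param units unit of the energy tags: "kj" (default), "hartree",
#'   "kcal"; converted to kJ/mol on read.
#' @return list of `hb_entry` objects; see [entries_table()].
#' @export
read_strength_entries <- function(path, role = c("HBA", "HBD"),
                                  tag_dict = default_tag_dict(),
                                  units = "kj") {
  role <- match.arg(role)
  fac <- .unit_factor(units)
  recs <- read_sdf(path, tag_dict = tag_dict)
  entries <- list()
  for (mol in recs) {
    ordinal <- attr(mol, "ordinal")
    props <- mol$props
    rt <- tag_dict$role
    if (!is.null(rt) && rt %in% names(props)) {
      found <- toupper(trimws(props[[rt]]))
      if (found != role)
        stop(sprintf("record %d: role tag is %s but %s was requested",
                     ordinal, found, role))
    }
    st <- tag_dict$site_index
    if (is.null(st) || !st %in% names(props))
      stop(sprintf(
        "record %d: required site-index tag <%s> missing; tags present: %s",
        ordinal, if (is.null(st)) "?" else st,
        paste(names(props), collapse = ", ")))
    sites <- suppressWarnings(
      as.integer(strsplit(trimws(props[[st]]), "\\s+")[[1]]))
    if (anyNA(sites) || any(sites < 1L) || any(sites > n_atoms(mol)))
      stop(sprintf("record %d: invalid site indices in tag <%s>",
                   ordinal, st))
    ns <- length(sites)
    dgt <- tag_dict$dg
    if (is.null(dgt) || !dgt %in% names(props))
      stop(sprintf(
        "record %d: required free-energy tag <%s> missing; tags present: %s",
        ordinal, if (is.null(dgt)) "?" else dgt,
        paste(names(props), collapse = ", ")))
    dg <- .num_tag(props, dgt, ordinal, ns) * fac
    dg_qc <- .num_tag(props, tag_dict$dg_qc, ordinal, ns) * fac
    xh <- .num_tag(props, tag_dict$xh_distance, ordinal, ns)
    lf <- .num_tag(props, tag_dict$lowest_freq, ordinal, ns)
    conv <- if (!is.null(tag_dict$converged) &&
                tag_dict$converged %in% names(props)) {
      v <- toupper(strsplit(trimws(props[[tag_dict$converged]]),
                            "\\s+")[[1]])
      v <- v %in% c("1", "TRUE", "T", "YES")
      if (length(v) == 1L) rep(v, ns) else v
    } else rep(NA, ns)
    fc <- if (!is.null(tag_dict$functional_class) &&
              tag_dict$functional_class %in% names(props)) {
      v <- strsplit(trimws(props[[tag_dict$functional_class]]), "\\s+")[[1]]
      if (length(v) == 1L) rep(v, ns) else v
    } else rep(NA_character_, ns)
    triple <- function(tags) {
      if (is.null(tags) || !all(tags %in% names(props))) return(NULL)
      v <- vapply(tags, function(t) .num_tag(props, t, ordinal, ns),
                  numeric(ns))
      if (ns == 1L) v <- matrix(v, 1)
      v * fac
    }
    eh <- triple(tag_dict$e_highdft)
    gr <- triple(tag_dict$g_rrho)
    ds <- triple(tag_dict$dg_solv)
    for (k in seq_len(ns)) {
      tr <- function(m) if (is.null(m)) NULL else
        stats::setNames(m[k, ], c("complex", "molecule", "reference"))
      ent <- structure(list(
        fragment = mol, site_atom = sites[k], role = role,
        e_highdft = tr(eh), g_rrho = tr(gr), dg_solv = tr(ds),
        dg_qc = dg_qc[k], dg_calibrated = dg[k],
        xh_distance = xh[k], lowest_freq = lf[k], converged = conv[k],
        functional_class = fc[k], ordinal = ordinal), class = "hb_entry")
      if (!is.null(ent$e_highdft) && !is.null(ent$g_rrho) &&
          !is.null(ent$dg_solv)) {
        comp <- compose_dg(energy_breakdown(ent$e_highdft, ent$g_rrho,
                                            ent$dg_solv))
        if (is.na(ent$dg_qc)) ent$dg_qc <- comp
        else if (abs(comp - ent$dg_qc) > 1e-6)
          stop(sprintf(
            "record %d site %d: stored dg_qc %.6f disagrees with composed value %.6f",
            ordinal, sites[k], ent$dg_qc, comp))
      }
      entries[[length(entries) + 1L]] <- ent
    }
  }
  entries
}

#' @export
print.hb_entry <- function(x, ...) {
  cat(sprintf("<hb_entry> %s site at atom %d (%s): dG = %.2f kJ/mol\n",
              x$role, x$site_atom, x$fragment$elements[x$site_atom],
              if (is.na(x$dg_calibrated)) NaN else x$dg_calibrated))
  invisible(x)
}

#' Flatten strength entries to a data frame
#'
#' @param entries list of `hb_entry` from [read_strength_entries()] or
#'   the fixture generator.
#' @return data.frame with one row per entry: ordinal, site_atom, site
#'   element, role, dg_calibrated, dg_qc, xh_distance, lowest_freq,
#'   converged, functional_class.
#' @export
entries_table <- function(entries) {
  data.frame(
    ordinal = vapply(entries, function(e) e$ordinal, integer(1)),
    site_atom = vapply(entries, function(e) e$site_atom, integer(1)),
    element = vapply(entries, function(e)
      e$fragment$elements[e$site_atom], character(1)),
    role = vapply(entries, function(e) e$role, character(1)),
    dg_calibrated = vapply(entries, function(e)
      as.numeric(e$dg_calibrated), numeric(1)),
    dg_qc = vapply(entries, function(e) as.numeric(e$dg_qc), numeric(1)),
    xh_distance = vapply(entries, function(e)
      as.numeric(e$xh_distance), numeric(1)),
    lowest_freq = vapply(entries, function(e)
      as.numeric(e$lowest_freq), numeric(1)),
    converged = vapply(entries, function(e) as.logical(e$converged),
                       logical(1)),
    functional_class = vapply(entries, function(e)
      as.character(e$functional_class), character(1)),
    stringsAsFactors = FALSE)
}
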