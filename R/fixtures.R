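# Synthetic fixtures: toy molecules with deterministic pseudo-charges
# and stand-in 3D geometries, plus synthetic strength data whose
# statistical structure mirrors the calibration regime (a linear map
# from composed free energies to the experimental scale with Gaussian
# residuals of ~2.6 kJ/mol, and a distance-energy coupling of moderate
# Pearson correlation).  Nothing here is physically realistic; the
# point is full coverage of every code path without quantum chemistry.

#' Fixture generator configuration
#'
#' @param n_molecules molecules to emit.
#' @param seed RNG seed (the generator is deterministic given the
#'   config).
#' @param target_model c(slope, intercept, noise sd): the linear map
#'   from latent composed free energies to "experimental" targets.
#'   Defaults to the acceptor calibration regime (0.56, -20.12, 2.6
#'   kJ/mol).
#' @param families functional families to emit.
#' @param rho target Pearson correlation between hydrogen-bond distance
#'   and target free energy (default 0.5).
#' @export
fixture_config <- function(n_molecules = 50, seed = 1,
                           target_model = c(slope = 0.56,
                                            intercept = -20.12,
                                            noise_sd = 2.6),
                           families = c("alcohols", "amines", "ethers",
                                        "carbonyls", "n_heterocycles",
                                        "thiols", "alkynes"),
                           rho = 0.5) {
  stopifnot(n_molecules >= 1, target_model[3] >= 0, abs(rho) <= 1)
  families <- match.arg(families, several.ok = TRUE)
  structure(list(n_molecules = as.integer(n_molecules),
                 seed = as.integer(seed),
                 target_model = stats::setNames(
                   as.numeric(target_model),
                   c("slope", "intercept", "noise_sd")),
                 families = families, rho = rho),
            class = "fixture_config")
}

.family_templates <- list(
  alcohols = c("CO", "CCO", "CCCO", "CC(C)O", "OCc1ccccc1", "CC(C)CO"),
  amines = c("CN", "CCN", "CNC", "CCNC", "NCc1ccccc1", "CCNCC"),
  ethers = c("COC", "CCOC", "CCOCC", "C1CCOC1", "COCc1ccccc1"),
  carbonyls = c("CC=O", "CC(=O)C", "CCC(=O)C", "CC(=O)O", "CC(=O)N",
                "CCC(=O)O"),
  n_heterocycles = c("c1ccncc1", "Cc1ccncc1", "c1cc[nH]c1",
                     "Cc1ccc[nH]1", "c1cnc[nH]1", "c1cc[nH]n1"),
  thiols = c("CS", "CCS", "CCCS", "CC(C)S"),
  alkynes = c("CC#C", "CCC#C", "CCCC#C", "CC(C)C#C")
)

#' Electronegativity-difference pseudo-charges
#'
#' charge(atom) = sum over bonds of kappa * (chi_neighbor - chi_self)
#' with kappa = 0.1 and Pauling electronegativities.  Antisymmetric per
#' bond, so charges sum to zero per molecule.  A stand-in for
#' semi-empirical CM5 charges in tests; not a physical charge model.
#'
#' @param mol an [hbmol()].
#' @param kappa coupling constant (default 0.1).
#' @return numeric charge vector.
#' @export
pseudo_charges <- function(mol, kappa = 0.1) {
  chi <- .electronegativity[mol$elements]
  q <- numeric(n_atoms(mol))
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b[k, 1]; j <- b[k, 2]
    q[i] <- q[i] + kappa * (chi[j] - chi[i])
    q[j] <- q[j] + kappa * (chi[i] - chi[j])
  }
  unname(q)
}

#' Deterministic stand-in 3D embedding
#'
#' Places atoms by BFS from atom 1: each atom sits at an idealized bond
#' length from its parent in a seeded pseudo-random direction, with
#' clash-avoidance retries.  Deterministic given the seed; nothing more
#' than a geometry carrier for the spatial descriptors.
#'
#' @param mol an [hbmol()].
#' @param seed RNG seed.
#' @return the molecule with `coords` set.
#' @export
embed_coords <- function(mol, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  co <- matrix(NA_real_, n, 3)
  rand_dir <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  for (root in seq_len(n)) {
    if (!is.na(co[root, 1])) next
    co[root, ] <- stats::runif(3, -0.1, 0.1) +
      c(8 * sum(is.na(co[, 1]) == FALSE), 0, 0)
    queue <- root
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      for (j in adj[[i]]$nbr) {
        if (!is.na(co[j, 1])) next
        len <- if (mol$elements[i] == "H" || mol$elements[j] == "H")
          1.09 else 1.5
        for (try in 1:25) {
          pos <- co[i, ] + len * rand_dir()
          placed <- which(!is.na(co[, 1]))
          dmin <- min(sqrt(rowSums(
            (co[placed, , drop = FALSE] -
               matrix(pos, length(placed), 3, byrow = TRUE))^2)))
          if (dmin > 0.8 * 1.09) break
        }
        co[j, ] <- pos
        queue <- c(queue, j)
      }
    }
  }
  mol$coords <- co
  mol
}

#' Generate toy molecules covering all site kinds
#'
#' Enumerates small molecules from a template grammar (family templates
#' grown by alkyl prefixes), with explicit hydrogens, pseudo-charges
#' and a deterministic stand-in 3D embedding.  Same config, same bytes.
#'
#' @param cfg a [fixture_config()].
#' @return list of [hbmol()] records (FAMILY property set).
#' @export
make_toy_molecules <- function(cfg = fixture_config()) {
  fams <- rep(cfg$families, length.out = cfg$n_molecules)
  counters <- stats::setNames(integer(length(cfg$families)),
                              cfg$families)
  smiles <- character(cfg$n_molecules)
  for (i in seq_len(cfg$n_molecules)) {
    f <- fams[i]
    tpl <- .family_templates[[f]]
    k <- counters[[f]]
    counters[[f]] <- k + 1L
    base <- tpl[(k %% length(tpl)) + 1L]
    grow <- k %/% length(tpl)
    smiles[i] <- paste0(strrep("C", grow), base)
  }
  mols <- smiles_to_mol(smiles,
                        names = sprintf("fix_%03d", seq_len(cfg$n_molecules)))
  for (i in seq_along(mols)) {
    mols[[i]]$atom_charges <- pseudo_charges(mols[[i]])
    mols[[i]] <- embed_coords(mols[[i]], seed = cfg$seed + i)
    mols[[i]]$props$FAMILY <- fams[i]
    attr(mols[[i]], "ordinal") <- i
  }
  mols
}

#' Synthetic calibration pairs
#'
#' Composed free energies drawn Uniform(-60, 10) kJ/mol with targets
#' from the configured linear model plus Gaussian noise -- the
#' statistical shape of the quantum-chemistry-to-experiment
#' calibration.
#'
#' @param n pairs.
#' @param slope,intercept,noise_sd linear model (defaults: acceptor
#'   regime).
#' @param seed RNG seed.
#' @return data.frame with columns dg_qc, dg_exp.
#' @export
make_calibration_pairs <- function(n = 425, slope = 0.56,
                                   intercept = -20.12, noise_sd = 2.6,
                                   seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  dg_qc <- stats::runif(n, -60, 10)
  dg_exp <- slope * dg_qc + intercept + stats::rnorm(n, 0, noise_sd)
  data.frame(dg_qc = dg_qc, dg_exp = dg_exp)
}

#' Synthetic strength data over toy molecules
#'
#' For every perceivable site: a latent composed free energy Uniform
#' (-60, 10); an "experimental" target from the configured linear model
#' plus noise; an energy-component breakdown that composes exactly to
#' the latent value; a hydrogen-bond distance coupled to the target via
#' a Gaussian copula (normal-scores coupling) at Pearson `rho`; benign
#' convergence metadata.  Sites whose descriptors are inapplicable in
#' strict mode are skipped with a message (the realistic loss mode).
#'
#' @param mols toy molecules from [make_toy_molecules()].
#' @param specs descriptor spec list for the X matrix (default CS +
#'   sorted_shell at K = 2 so small fixtures stay applicable).
#' @param cfg a [fixture_config()].
#' @param role "HBA", "HBD" or "both".
#' @return list: `X` (descriptor matrix), `y` (targets, kJ/mol),
#'   `entries` (list of `hb_entry`), `sites` (data.frame), `dg_qc`
#'   (latent composed energies).
#' @export
make_synthetic_strength_data <- function(mols,
                                         specs = list(
                                           descriptor_spec("CS",
                                                           n_shells = 2),
                                           descriptor_spec("sorted_shell",
                                                           n_shells = 2)),
                                         cfg = fixture_config(),
                                         role = c("both", "HBA", "HBD")) {
  role <- match.arg(role)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  site_rows <- list()
  vecs <- list()
  for (m in seq_along(mols)) {
    for (s in find_sites(mols[[m]], role)) {
      dv <- tryCatch(combine_blocks(mols[[m]], s$atom_index, specs),
                     error = function(e) {
                       if (grepl("inapplicable", conditionMessage(e))) {
                         message(sprintf(
                           "molecule %d site %d: descriptors inapplicable; skipped",
                           m, s$atom_index))
                         NULL
                       } else stop(e)
                     })
      if (is.null(dv)) next
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        molecule = m, atom_index = s$atom_index, role = s$role,
        site_kind = s$site_kind)
      vecs[[length(vecs) + 1L]] <- dv$values
    }
  }
  if (!length(vecs)) stop("no applicable sites in the fixture set")
  X <- do.call(rbind, vecs)
  sites <- do.call(rbind, site_rows)
  ns <- nrow(sites)
  tm <- cfg$target_model
  dg_qc <- stats::runif(ns, -60, 10)
  y <- tm[["slope"]] * dg_qc + tm[["intercept"]] +
    stats::rnorm(ns, 0, tm[["noise_sd"]])
  # Gaussian copula: normal scores of y, correlated latent, normal
  # marginal for the distance.  The coupling coefficient compensates
  # the normal-scores attenuation (cor(z_y, y) < 1 for non-normal y)
  # so the population Pearson correlation of (xh, y) is rho itself.
  z_y <- stats::qnorm((rank(y, ties.method = "first") - 0.5) / ns)
  a <- max(-1, min(1, cfg$rho / stats::cor(z_y, y)))
  z_x <- a * z_y + sqrt(1 - a^2) * stats::rnorm(ns)
  xh <- pmax(2.1 + 0.2 * z_x, 0.8)
  entries <- vector("list", ns)
  for (i in seq_len(ns)) {
    p1 <- 0.6 * dg_qc[i]
    p2 <- 0.25 * dg_qc[i]
    p3 <- dg_qc[i] - p1 - p2
    base <- stats::rnorm(6, -1000, 50)
    eh <- c(complex = base[1] + base[2] + p1, molecule = base[1],
            reference = base[2])
    gr <- c(complex = base[3] + base[4] + p2, molecule = base[3],
            reference = base[4])
    ds <- c(complex = base[5] + base[6] + p3, molecule = base[5],
            reference = base[6])
    mol <- mols[[sites$molecule[i]]]
    entries[[i]] <- structure(list(
      fragment = mol, site_atom = sites$atom_index[i],
      role = sites$role[i], e_highdft = eh, g_rrho = gr, dg_solv = ds,
      dg_qc = dg_qc[i], dg_calibrated = y[i], xh_distance = xh[i],
      lowest_freq = stats::runif(1, -45, 0), converged = TRUE,
      functional_class = as.character(mol$props$FAMILY),
      ordinal = sites$molecule[i]), class = "hb_entry")
  }
  list(X = X, y = y, entries = entries, sites = sites, dg_qc = dg_qc)
}

#' Serialize strength entries to a database SDF
#'
#' One record per entry, tags per [default_tag_dict()]; round-trips
#' through [read_strength_entries()].
#'
#' @param entries list of `hb_entry`.
#' @param path output SDF.
#' @param tag_dict tag dictionary.
#' @export
write_strength_entries <- function(entries, path,
                                   tag_dict = default_tag_dict()) {
  fmt <- function(x) sprintf("%.8f", x)
  recs <- lapply(entries, function(e) {
    m <- e$fragment
    pr <- list()
    pr[[tag_dict$role]] <- e$role
    pr[[tag_dict$site_index]] <- as.character(e$site_atom)
    pr[[tag_dict$dg]] <- fmt(e$dg_calibrated)
    if (!is.na(e$dg_qc)) pr[[tag_dict$dg_qc]] <- fmt(e$dg_qc)
    if (!is.na(e$xh_distance))
      pr[[tag_dict$xh_distance]] <- fmt(e$xh_distance)
    if (!is.na(e$lowest_freq))
      pr[[tag_dict$lowest_freq]] <- fmt(e$lowest_freq)
    if (!is.na(e$converged))
      pr[[tag_dict$converged]] <- if (e$converged) "1" else "0"
    if (!is.na(e$functional_class))
      pr[[tag_dict$functional_class]] <- e$functional_class
    triple_tags <- list(e_highdft = e$e_highdft, g_rrho = e$g_rrho,
                        dg_solv = e$dg_solv)
    for (nm in names(triple_tags)) {
      v <- triple_tags[[nm]]
      if (is.null(v)) next
      tags <- tag_dict[[nm]]
      for (k in 1:3) pr[[tags[k]]] <- fmt(v[[k]])
    }
    m$props <- pr
    m
  })
  write_sdf(recs, path, tag_dict)
}
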