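# Radial atomic reactivity descriptors for a designated HBA/HBD site
# atom.  Six families, all centered on the site:
#
#   CS           mean partial charge per topological shell
#   sorted_shell per-shell charges ordered by substituent priority
#                (CIP-style), truncated/zero-padded to W slots
#   MS           summed atomic masses per shell
#   GACF         topological charge autocorrelation: sum over shell k of
#                q_center * q_j
#   CRDF         spatial charge radial distribution:
#                g(r) = sum_j q_j exp(-beta (r - d_cj)^2)
#   CACF         spatial charge autocorrelation of q_center * q_j
#                products, split into positive and negative parts
#
# All atoms participate, including hydrogens.  Topological families need
# partial charges only; spatial families also need 3D coordinates.
# Empty shells make the averaging families inapplicable in strict mode
# (division by zero), which is how sites drop out of training sets.

#' Descriptor specification
#'
#' @param family one of "CS", "sorted_shell", "MS", "GACF", "CRDF",
#'   "CACF".
#' @param n_shells K, number of topological shells (default 4: the
#'   fragment radius).
#' @param shell_width W, slots per shell for sorted_shell (default 4).
#' @param r_min,r_max,r_step spatial grid in Angstrom (default 1.0 to
#'   8.0 by 0.5, spanning the 4-shell fragment radius).
#' @param beta Gaussian smoothing exponent in 1/Angstrom^2 (default 4).
#' @param charge_source name of the SDF tag holding the charges
#'   (informational; the record's `atom_charges` are used, falling back
#'   to topology-derived pseudo-charges with a warning).
#' @param empty_shell "strict" (default: empty shell makes CS/
#'   sorted-averaging inapplicable) or "zero_fill".
#' @export
descriptor_spec <- function(family = c("CS", "sorted_shell", "MS", "GACF",
                                       "CRDF", "CACF"),
                            n_shells = 4, shell_width = 4, r_min = 1.0,
                            r_max = 8.0, r_step = 0.5, beta = 4,
                            charge_source = "ATOM_CHARGES",
                            empty_shell = c("strict", "zero_fill")) {
  family <- match.arg(family)
  stopifnot(n_shells >= 1, shell_width >= 1, r_min < r_max, r_step > 0,
            beta > 0)
  structure(list(family = family, n_shells = as.integer(n_shells),
                 shell_width = as.integer(shell_width), r_min = r_min,
                 r_max = r_max, r_step = r_step, beta = beta,
                 charge_source = charge_source,
                 empty_shell = match.arg(empty_shell)),
            class = "descriptor_spec")
}

#' Length of the block a spec generates (independent of the molecule)
#' @param spec a [descriptor_spec()].
#' @export
spec_length <- function(spec) {
  grid <- .r_grid(spec)
  as.numeric(switch(spec$family,
         CS = spec$n_shells,
         MS = spec$n_shells,
         GACF = spec$n_shells,
         sorted_shell = spec$n_shells * spec$shell_width,
         CRDF = length(grid),
         CACF = 2L * length(grid)))
}

.r_grid <- function(spec) {
  npts <- ceiling((spec$r_max - spec$r_min) / spec$r_step) + 1
  spec$r_min + spec$r_step * (seq_len(npts) - 1)
}

#' Topological shells around a center atom
#'
#' Shell k holds the atoms at graph distance exactly k from the center,
#' hydrogens included; shells beyond the eccentricity are empty.
#'
#' @param mol an [hbmol()].
#' @param center 1-based atom index.
#' @param K number of shells.
#' @return list of K integer vectors.
#' @export
topological_shells <- function(mol, center, K) {
  d <- graph_distances(mol, center)
  lapply(seq_len(K), function(k) which(!is.na(d) & d == k))
}

# charges with pseudo-charge fallback
.charges_for <- function(mol) {
  if (!is.null(mol$atom_charges)) return(mol$atom_charges)
  warning("no partial charges on record; falling back to ",
          "electronegativity-based pseudo-charges", call. = FALSE)
  pseudo_charges(mol)
}

.inapplicable <- function(spec, what) {
  stop(sprintf(
    "descriptor %s inapplicable: %s (strict empty-shell mode)",
    spec$family, what), call. = FALSE)
}

#' Charge-shell descriptor (mean charge per shell)
#' @param mol an [hbmol()] carrying partial charges.
#' @param center site atom index.
#' @param spec a [descriptor_spec()].
#' @return numeric vector of length K.
#' @export
charge_shell <- function(mol, center, spec = descriptor_spec("CS")) {
  q <- .charges_for(mol)
  shells <- topological_shells(mol, center, spec$n_shells)
  vapply(seq_along(shells), function(k) {
    s <- shells[[k]]
    if (!length(s)) {
      if (spec$empty_shell == "strict")
        .inapplicable(spec, sprintf("no shell %d around atom %d", k, center))
      return(0)
    }
    mean(q[s])
  }, numeric(1))
}

# substituent priority key: descending atomic number, then mass, then
# recursively compared neighbor environments (depth-limited), then
# charge, then input index -- a deterministic CIP-style ordering
.priority_keys <- function(mol, depth = 3) {
  z <- .atomic_numbers[mol$elements]
  adj <- adjacency(mol)
  key <- sprintf("%03d", z)
  for (d in seq_len(depth)) {
    key <- vapply(seq_along(key), function(i) {
      nb <- sort(key[adj[[i]]$nbr], decreasing = TRUE)
      paste(c(key[i], nb), collapse = "|")
    }, character(1))
  }
  key
}

#' Sorted-shell descriptor (per-shell charges in priority order)
#'
#' Within each shell, individual atom charges are ordered by descending
#' substituent priority (atomic number, mass, recursive neighbor
#' comparison; ties broken by descending charge then input index) and
#' truncated/zero-padded to W slots.
#'
#' @inheritParams charge_shell
#' @return numeric vector of length K * W.
#' @export
sorted_shell <- function(mol, center, spec = descriptor_spec("sorted_shell")) {
  q <- .charges_for(mol)
  shells <- topological_shells(mol, center, spec$n_shells)
  keys <- .priority_keys(mol)
  unlist(lapply(shells, function(s) {
    vals <- numeric(spec$shell_width)
    if (length(s)) {
      ord <- s[order(keys[s], -q[s], s, decreasing = c(TRUE, FALSE, FALSE),
                     method = "radix")]
      take <- utils::head(q[ord], spec$shell_width)
      vals[seq_along(take)] <- take
    }
    vals
  }))
}

#' Mass-shell descriptor (summed atomic masses per shell)
#' @inheritParams charge_shell
#' @return numeric vector of length K; empty shells contribute 0.
#' @export
mass_shell <- function(mol, center, spec = descriptor_spec("MS")) {
  shells <- topological_shells(mol, center, spec$n_shells)
  vapply(shells, function(s)
    if (length(s)) sum(.atomic_masses[mol$elements[s]]) else 0,
    numeric(1))
}

#' Topological charge autocorrelation (GACF)
#' @inheritParams charge_shell
#' @return numeric vector of length K: sum over shell k of
#'   q_center * q_j; empty shells contribute 0.
#' @export
topo_cacf <- function(mol, center, spec = descriptor_spec("GACF")) {
  q <- .charges_for(mol)
  shells <- topological_shells(mol, center, spec$n_shells)
  vapply(shells, function(s)
    if (length(s)) sum(q[center] * q[s]) else 0, numeric(1))
}

.center_distances <- function(mol, center) {
  if (is.null(mol$coords))
    stop("spatial descriptors need 3D coordinates", call. = FALSE)
  co <- mol$coords
  sqrt(rowSums((co - matrix(co[center, ], nrow(co), 3, byrow = TRUE))^2))
}

#' Spatial charge radial distribution function (CRDF)
#'
#' g(r_m) = sum over atoms j != center of q_j exp(-beta (r_m - d_cj)^2)
#' on the inclusive grid r_min..r_max.
#'
#' @inheritParams charge_shell
#' @return numeric vector over the grid.
#' @export
spatial_rdf <- function(mol, center, spec = descriptor_spec("CRDF")) {
  q <- .charges_for(mol)
  dd <- .center_distances(mol, center)
  grid <- .r_grid(spec)
  others <- setdiff(seq_len(n_atoms(mol)), center)
  vapply(grid, function(r)
    sum(q[others] * exp(-spec$beta * (r - dd[others])^2)), numeric(1))
}

#' Spatial charge autocorrelation function (CACF)
#'
#' Products p_j = q_center * q_j are smoothed onto the CRDF grid;
#' positive products populate the first half of the block, negative
#' products the second half.
#'
#' @inheritParams charge_shell
#' @return numeric vector of length 2 * gridlen, [positive | negative].
#' @export
spatial_cacf <- function(mol, center, spec = descriptor_spec("CACF")) {
  q <- .charges_for(mol)
  dd <- .center_distances(mol, center)
  grid <- .r_grid(spec)
  others <- setdiff(seq_len(n_atoms(mol)), center)
  p <- q[center] * q[others]
  gpart <- function(sel) vapply(grid, function(r)
    sum(p[sel] * exp(-spec$beta * (r - dd[others][sel])^2)), numeric(1))
  c(gpart(p > 0), gpart(p < 0))
}

.family_fun <- list(CS = charge_shell, sorted_shell = sorted_shell,
                    MS = mass_shell, GACF = topo_cacf,
                    CRDF = spatial_rdf, CACF = spatial_cacf)

# tiny polynomial hash for spec digests (keeps the package dependency-free)
.spec_digest <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Compute one descriptor block
#' @inheritParams charge_shell
#' @export
descriptor_block <- function(mol, center, spec) {
  .family_fun[[spec$family]](mol, center, spec)
}

#' Concatenate descriptor blocks into a combinatorial descriptor
#'
#' Blocks are concatenated in spec order with a recorded layout.  Any
#' strict-mode inapplicability propagates, marking the whole site
#' descriptor-inapplicable (such sites are dropped from training).
#'
#' @param mol an [hbmol()].
#' @param center site atom index.
#' @param specs ordered list of [descriptor_spec()].
#' @return object of class `descriptor_vector`: `$values`,
#'   `$block_layout` (family, offset, length), `$spec_hash`.
#' @export
combine_blocks <- function(mol, center, specs) {
  if (!length(specs)) stop("empty descriptor spec list")
  if (inherits(specs, "descriptor_spec")) specs <- list(specs)
  values <- numeric(0)
  layout <- list()
  off <- 0L
  for (spec in specs) {
    block <- descriptor_block(mol, center, spec)
    layout[[length(layout) + 1L]] <- data.frame(
      family = spec$family, offset = off, length = length(block))
    values <- c(values, block)
    off <- off + length(block)
  }
  structure(list(values = values, block_layout = do.call(rbind, layout),
                 spec_hash = .spec_digest(lapply(specs, unclass))),
            class = "descriptor_vector")
}

#' @export
print.descriptor_vector <- function(x, ...) {
  cat(sprintf("<descriptor_vector> length %d (%s) hash %s\n",
              length(x$values),
              paste(sprintf("%s:%d", x$block_layout$family,
                            x$block_layout$length), collapse = " + "),
              x$spec_hash))
  invisible(x)
}

#' Descriptor matrix over many (molecule, site) pairs
#'
#' Strict-mode inapplicable sites get NA rows and are flagged; callers
#' drop them from training (the standard loss mode for sites whose
#' environment has fewer shells than K).
#'
#' @param mols list of [hbmol()].
#' @param centers integer vector of site atom indices, one per molecule
#'   entry.
#' @param specs ordered list of [descriptor_spec()].
#' @return list: `X` numeric matrix (rows = sites), `applicable` logical
#'   vector, `layout` block layout.
#' @export
descriptor_matrix <- function(mols, centers, specs) {
  stopifnot(length(mols) == length(centers))
  if (inherits(specs, "descriptor_spec")) specs <- list(specs)
  p <- sum(vapply(specs, spec_length, numeric(1)))
  X <- matrix(NA_real_, length(mols), p)
  applicable <- logical(length(mols))
  layout <- NULL
  for (i in seq_along(mols)) {
    dv <- tryCatch(combine_blocks(mols[[i]], centers[i], specs),
                   error = function(e)
                     if (grepl("inapplicable", conditionMessage(e))) NULL
                   else stop(e))
    if (!is.null(dv)) {
      X[i, ] <- dv$values
      applicable[i] <- TRUE
      layout <- dv$block_layout
    }
  }
  list(X = X, applicable = applicable, layout = layout)
}

#' Read descriptor specs from a JSON config
#' @param path JSON array of spec objects (fields as in
#'   [descriptor_spec()]).
#' @export
read_descriptor_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(cfg, function(d) do.call(descriptor_spec, d))
}
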