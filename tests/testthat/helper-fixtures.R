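# Shared builders and independent oracles for the test suite.

# three-carbon chain with the spec charges used across descriptor tests
toy_chain <- function(q = c(0.2, -0.1, 0.3), elements = c("C", "C", "C")) {
  hbmol(elements, rbind(c(1, 2, 1), c(2, 3, 1)), atom_charges = q)
}

# random tree-shaped molecule (valid graph, arbitrary charges/coords);
# independent of any chemistry toolkit
random_tree_mol <- function(n = 8, seed = 1, elements = c("C", "N", "O", "H"),
                            coords = TRUE) {
  set.seed(seed)
  el <- sample(elements, n, replace = TRUE)
  el[1] <- "C"
  bonds <- NULL
  for (i in seq_len(n)[-1]) bonds <- rbind(bonds, c(sample(i - 1, 1), i, 1L))
  hbmol(el, bonds,
        coords = if (coords) matrix(stats::rnorm(3 * n, sd = 2), n, 3),
        atom_charges = round(stats::runif(n, -0.5, 0.5), 3))
}

# apply an atom permutation consistently: atom i moves to position perm[i]
permute_mol <- function(mol, perm) {
  inv <- order(perm)
  b <- mol$bonds
  nb <- cbind(perm[b[, 1]], perm[b[, 2]], b[, 3])
  hbmol(mol$elements[inv], nb, mol$charges[inv],
        if (!is.null(mol$coords)) mol$coords[inv, , drop = FALSE],
        if (!is.null(mol$atom_charges)) mol$atom_charges[inv],
        mol$props, mol$name)
}

# brute-force BFS shell oracle (independent of graph_distances)
oracle_shells <- function(mol, center, K) {
  n <- n_atoms(mol)
  adj <- lapply(seq_len(n), function(i) {
    b <- mol$bonds
    c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
  })
  dist <- rep(Inf, n)
  dist[center] <- 0
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[k, 1]; j <- mol$bonds[k, 2]
      if (dist[i] + 1 < dist[j]) { dist[j] <- dist[i] + 1; changed <- TRUE }
      if (dist[j] + 1 < dist[i]) { dist[i] <- dist[j] + 1; changed <- TRUE }
    }
    if (!changed) break
  }
  lapply(seq_len(K), function(k) which(dist == k))
}

# direct-summation oracles for the descriptor families
oracle_cs <- function(mol, center, K) {
  sh <- oracle_shells(mol, center, K)
  vapply(sh, function(s) if (length(s)) mean(mol$atom_charges[s])
         else NA_real_, numeric(1))
}
oracle_ms <- function(mol, center, K) {
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)
  sh <- oracle_shells(mol, center, K)
  vapply(sh, function(s) sum(masses[mol$elements[s]]), numeric(1))
}
oracle_gacf <- function(mol, center, K) {
  sh <- oracle_shells(mol, center, K)
  q <- mol$atom_charges
  vapply(sh, function(s) sum(q[center] * q[s]), numeric(1))
}
oracle_rdf <- function(mol, center, grid, beta) {
  q <- mol$atom_charges
  co <- mol$coords
  out <- numeric(length(grid))
  for (m in seq_along(grid)) {
    acc <- 0
    for (j in seq_len(n_atoms(mol))) {
      if (j == center) next
      d <- sqrt(sum((co[center, ] - co[j, ])^2))
      acc <- acc + q[j] * exp(-beta * (grid[m] - d)^2)
    }
    out[m] <- acc
  }
  out
}
oracle_cacf <- function(mol, center, grid, beta) {
  q <- mol$atom_charges
  co <- mol$coords
  pos <- numeric(length(grid)); neg <- numeric(length(grid))
  for (m in seq_along(grid)) {
    for (j in seq_len(n_atoms(mol))) {
      if (j == center) next
      d <- sqrt(sum((co[center, ] - co[j, ])^2))
      p <- q[center] * q[j]
      w <- exp(-beta * (grid[m] - d)^2)
      if (p > 0) pos[m] <- pos[m] + p * w
      if (p < 0) neg[m] <- neg[m] + p * w
    }
  }
  c(pos, neg)
}

# random rigid motion for invariance checks
rigid_transform <- function(co, seed = 1) {
  set.seed(seed)
  A <- matrix(stats::rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  t(Q %*% t(co)) + matrix(stats::rnorm(3, sd = 5), nrow(co), 3,
                          byrow = TRUE)
}
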