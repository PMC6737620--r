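# Radial atomic descriptor families against direct-summation oracles,
# plus the invariances the descriptor contract promises.

test_that("topological shells match a brute-force BFS oracle", {
  # linear chain A-B-C
  m <- toy_chain()
  expect_identical(topological_shells(m, 1, 2), list(2L, 3L))
  # benzene ring atom: two ring neighbors + its hydrogen in shell 1
  benz <- smiles_to_mol("c1ccccc1")[[1]]
  ring_c <- which(benz$elements == "C")[1]
  sh1 <- topological_shells(benz, ring_c, 1)[[1]]
  expect_length(sh1, 3)
  expect_setequal(benz$elements[sh1], c("C", "C", "H"))
  # trailing empty shells beyond the eccentricity
  sh <- topological_shells(m, 1, 5)
  expect_identical(lengths(sh), c(1L, 1L, 0L, 0L, 0L))
  # random trees against the oracle
  for (i in 1:10) {
    rm <- random_tree_mol(n = 10, seed = 300 + i)
    ctr <- sample(10, 1)
    expect_identical(lapply(topological_shells(rm, ctr, 5), as.integer),
                     lapply(oracle_shells(rm, ctr, 5), as.integer))
  }
})

test_that("charge shell averages per shell and fails strictly on empty shells", {
  m <- toy_chain()
  expect_equal(charge_shell(m, 1, descriptor_spec("CS", n_shells = 2)),
               c(-0.1, 0.3))
  expect_error(charge_shell(m, 1, descriptor_spec("CS", n_shells = 3)),
               "inapplicable")
  zf <- descriptor_spec("CS", n_shells = 3, empty_shell = "zero_fill")
  expect_equal(charge_shell(m, 1, zf), c(-0.1, 0.3, 0))
  # two-atom shell averages
  star <- hbmol(c("C", "C", "C"), rbind(c(1, 2, 1), c(1, 3, 1)),
                atom_charges = c(0, 0.1, -0.3))
  expect_equal(charge_shell(star, 1, descriptor_spec("CS", n_shells = 1)),
               -0.1)
})

test_that("sorted shell orders by substituent priority with zero padding", {
  # single-atom shell pads with zeros
  m <- toy_chain(q = c(0, -0.1, 0))
  ss <- sorted_shell(m, 1, descriptor_spec("sorted_shell", n_shells = 1,
                                           shell_width = 2))
  expect_equal(ss, c(-0.1, 0))
  # O outranks H in the same shell
  m2 <- hbmol(c("C", "O", "H"), rbind(c(1, 2, 1), c(1, 3, 1)),
              atom_charges = c(0, -0.4, 0.1))
  ss2 <- sorted_shell(m2, 1, descriptor_spec("sorted_shell", n_shells = 1,
                                             shell_width = 2))
  expect_equal(ss2, c(-0.4, 0.1))
  # invariance to atom-order permutation
  for (i in 1:10) {
    rm <- random_tree_mol(n = 9, seed = 400 + i)
    set.seed(500 + i)
    perm <- sample(9)
    pm <- permute_mol(rm, perm)
    spec <- descriptor_spec("sorted_shell", n_shells = 3, shell_width = 3)
    expect_equal(sorted_shell(rm, 1, spec),
                 sorted_shell(pm, perm[1], spec))
  }
})

test_that("mass shell sums standard atomic weights", {
  m <- hbmol(c("N", "C", "O"), rbind(c(1, 2, 1), c(2, 3, 2)),
             atom_charges = c(0, 0, 0))
  expect_equal(mass_shell(m, 1, descriptor_spec("MS", n_shells = 2)),
               c(12.011, 15.999))
  # {C, O} shell sums to 28.010
  star <- hbmol(c("N", "C", "O"), rbind(c(1, 2, 1), c(1, 3, 1)))
  expect_equal(mass_shell(star, 1, descriptor_spec("MS", n_shells = 2)),
               c(28.010, 0))
  # methane center: 4 hydrogens
  methane <- smiles_to_mol("C")[[1]]
  ctr <- which(methane$elements == "C")
  expect_equal(mass_shell(methane, ctr, descriptor_spec("MS", n_shells = 1)),
               4 * 1.008)
})

test_that("topological autocorrelation follows the closed form", {
  m <- toy_chain()
  expect_equal(topo_cacf(m, 1, descriptor_spec("GACF", n_shells = 2)),
               c(0.2 * -0.1, 0.2 * 0.3))
  # equal charges: element k = q^2 * |shell k|
  eq <- random_tree_mol(n = 8, seed = 600)
  eq$atom_charges <- rep(0.2, 8)
  sh <- topological_shells(eq, 1, 3)
  expect_equal(topo_cacf(eq, 1, descriptor_spec("GACF", n_shells = 3)),
               0.04 * lengths(sh))
  # random trees against the oracle
  for (i in 1:10) {
    rm <- random_tree_mol(n = 10, seed = 700 + i)
    expect_equal(topo_cacf(rm, 2, descriptor_spec("GACF", n_shells = 4)),
                 oracle_gacf(rm, 2, 4))
  }
})

test_that("spatial RDF and CACF equal direct summation to 1e-12", {
  spec <- descriptor_spec("CRDF", r_min = 0.5, r_max = 2.5, r_step = 0.5,
                          beta = 4)
  grid <- seq(0.5, 2.5, by = 0.5)
  # single neighbor at 1.0 A with q = -0.1: grid point r = 1.0 recovers it
  two <- hbmol(c("C", "C"), rbind(c(1, 2, 1)),
               coords = rbind(c(0, 0, 0), c(1, 0, 0)),
               atom_charges = c(0.3, -0.1))
  g <- spatial_rdf(two, 1, spec)
  expect_equal(g[2], -0.1, tolerance = 1e-3)
  # all charges zero: zero block
  two0 <- two; two0$atom_charges <- c(0, 0)
  expect_equal(spatial_rdf(two0, 1, spec), rep(0, 5))
  # CACF sign split
  cspec <- descriptor_spec("CACF", r_min = 0.5, r_max = 2.5, r_step = 0.5,
                           beta = 4)
  two$atom_charges <- c(0.2, -0.1)
  cc <- spatial_cacf(two, 1, cspec)
  expect_equal(cc[1:5], rep(0, 5))          # no positive products
  expect_equal(cc[5 + 2], -0.02, tolerance = 1e-3)
  twoz <- two; twoz$atom_charges <- c(0, -0.1)
  expect_equal(spatial_cacf(twoz, 1, cspec), rep(0, 10))
  # random geometries against the brute-force oracles
  for (i in 1:50) {
    rm <- random_tree_mol(n = sample(4:9, 1), seed = 800 + i)
    expect_equal(spatial_rdf(rm, 1, spec), oracle_rdf(rm, 1, grid, 4),
                 tolerance = 1e-12)
    expect_equal(spatial_cacf(rm, 1, cspec), oracle_cacf(rm, 1, grid, 4),
                 tolerance = 1e-12)
    expect_equal(charge_shell(rm, 1, descriptor_spec(
      "CS", n_shells = 2, empty_shell = "zero_fill")),
      ifelse(is.na(oracle_cs(rm, 1, 2)), 0, oracle_cs(rm, 1, 2)))
    expect_equal(mass_shell(rm, 1, descriptor_spec("MS", n_shells = 3)),
                 oracle_ms(rm, 1, 3))
  }
})

test_that("blocks are invariant to permutation and rigid motion", {
  specs_topo <- list(descriptor_spec("CS", n_shells = 2),
                     descriptor_spec("GACF", n_shells = 2),
                     descriptor_spec("MS", n_shells = 2),
                     descriptor_spec("sorted_shell", n_shells = 2))
  specs_spatial <- list(descriptor_spec("CRDF"), descriptor_spec("CACF"))
  for (i in 1:10) {
    rm <- random_tree_mol(n = 8, seed = 900 + i)
    set.seed(950 + i)
    perm <- sample(8)
    pm <- permute_mol(rm, perm)
    for (spec in c(specs_topo, specs_spatial))
      expect_equal(descriptor_block(rm, 1, spec),
                   descriptor_block(pm, perm[1], spec))
    rt <- rm
    rt$coords <- rigid_transform(rm$coords, seed = i)
    for (spec in specs_spatial)
      expect_equal(descriptor_block(rm, 1, spec),
                   descriptor_block(rt, 1, spec), tolerance = 1e-9)
    for (spec in specs_topo)   # topological blocks ignore coordinates
      expect_identical(descriptor_block(rm, 1, spec),
                       descriptor_block(rt, 1, spec))
  }
})

test_that("sharp smoothing recovers the charge at an exact grid distance", {
  two <- hbmol(c("C", "N"), rbind(c(1, 2, 1)),
               coords = rbind(c(0, 0, 0), c(2, 0, 0)),
               atom_charges = c(0.3, -0.25))
  spec <- descriptor_spec("CRDF", r_min = 1, r_max = 3, r_step = 1,
                          beta = 1e6)
  g <- spatial_rdf(two, 1, spec)
  expect_equal(g, c(0, -0.25, 0), tolerance = 1e-6)
})

test_that("combinatorial descriptors concatenate with a reconstructable layout", {
  m <- toy_chain()
  dv <- combine_blocks(m, 1, list(descriptor_spec("CS", n_shells = 2),
                                  descriptor_spec("MS", n_shells = 2)))
  expect_equal(dv$values, c(-0.1, 0.3, 12.011, 12.011))
  expect_equal(dv$block_layout$length, c(2, 2))
  # slicing by layout reproduces each block
  for (r in seq_len(nrow(dv$block_layout))) {
    off <- dv$block_layout$offset[r]
    len <- dv$block_layout$length[r]
    expect_equal(dv$values[(off + 1):(off + len)],
                 descriptor_block(m, 1, descriptor_spec(
                   dv$block_layout$family[r], n_shells = 2)))
  }
  expect_error(combine_blocks(m, 1, list()), "empty")
  # dimensionality depends only on the specs, not the molecule
  specs <- list(descriptor_spec("CS", n_shells = 2),
                descriptor_spec("CRDF"))
  m2 <- random_tree_mol(n = 11, seed = 77)
  expect_equal(length(combine_blocks(m2, 1, specs)$values),
               sum(vapply(specs, spec_length, numeric(1))))
  # strict-mode failure propagates through combine
  expect_error(combine_blocks(m, 1, list(descriptor_spec("CS",
                                                         n_shells = 4))),
               "inapplicable")
})

test_that("descriptor matrices flag inapplicable sites instead of fabricating rows", {
  short <- toy_chain()
  long <- random_tree_mol(n = 9, seed = 55)
  dm <- descriptor_matrix(list(short, long), c(1, 1),
                          list(descriptor_spec("CS", n_shells = 4)))
  expect_false(dm$applicable[1])
  expect_true(all(is.na(dm$X[1, ])))
})
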