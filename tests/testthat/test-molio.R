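# SDF dialect reading/writing and the strength-entry loader.

test_that("a minimal SDF parses into the expected graph", {
  acetone <- smiles_to_mol("CC(=O)C", explicit_h = FALSE)[[1]]
  tmp <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(acetone, tmp)
  recs <- read_sdf(tmp)
  expect_length(recs, 1)
  m <- recs[[1]]
  expect_equal(sum(m$elements != "H"), 4)
  expect_equal(sum(m$bonds[, 3] == 2), 1)
  expect_equal(sort(unique(m$bonds[, 3])), c(1, 2))
})

test_that("an empty file yields an empty record list", {
  tmp <- withr::local_tempfile(fileext = ".sdf")
  writeLines(character(0), tmp)
  recs <- read_sdf(tmp)
  expect_length(recs, 0)
  expect_equal(nrow(attr(recs, "rejects")), 0)
})

test_that("round trips preserve graphs, charges and props on randomized molecules", {
  set.seed(42)
  mols <- lapply(1:100, function(i) {
    m <- random_tree_mol(n = sample(3:12, 1), seed = i)
    m$charges[sample(n_atoms(m), 1)] <- sample(c(-1L, 0L, 1L), 1)
    m$props <- list(TAG_A = sprintf("value_%d", i),
                    TAG_B = paste(round(stats::runif(3), 4), collapse = " "))
    m$name <- sprintf("rand_%03d", i)
    m
  })
  tmp <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(mols, tmp)
  back <- read_sdf(tmp)
  expect_length(back, 100)
  for (i in seq_along(mols)) {
    expect_identical(back[[i]]$elements, mols[[i]]$elements)
    expect_identical(back[[i]]$bonds, mols[[i]]$bonds)
    expect_identical(back[[i]]$charges, mols[[i]]$charges)
    expect_identical(back[[i]]$props$TAG_A, mols[[i]]$props$TAG_A)
    expect_identical(back[[i]]$props$TAG_B, mols[[i]]$props$TAG_B)
    expect_equal(back[[i]]$atom_charges, mols[[i]]$atom_charges,
                 tolerance = 1e-6)
    expect_identical(back[[i]]$name, mols[[i]]$name)
  }
})

test_that("partial charges serialize at 6 decimals and recover exactly", {
  m <- random_tree_mol(n = 6, seed = 7)
  m$atom_charges <- c(0.123456789, -0.5, 0.000001, 1.25, -0.333333333, 0)
  tmp <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(m, tmp)
  txt <- readLines(tmp)
  tagline <- grep("ATOM_CHARGES", txt)
  expect_length(tagline, 1)
  vals <- strsplit(txt[tagline + 1], " ")[[1]]
  expect_true(all(grepl("^-?\\d+\\.\\d{6}$", vals)))
  back <- read_sdf(tmp)[[1]]
  expect_equal(back$atom_charges, round(m$atom_charges, 6))
})

test_that("records without props terminate with $$$$ and re-read cleanly", {
  m <- hbmol(c("C", "O"), rbind(c(1, 2, 1)))
  tmp <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(m, tmp)
  txt <- readLines(tmp)
  expect_identical(txt[length(txt)], "$$$$")
  expect_length(read_sdf(tmp), 1)
})

test_that("malformed molblocks raise errors naming the record ordinal", {
  good <- random_tree_mol(5, seed = 1)
  tmp <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(list(good, good), tmp)
  txt <- readLines(tmp)
  # corrupt the counts line of the second record
  ends <- grep("^\\$\\$\\$\\$", txt)
  txt[ends[1] + 4] <- "garbage"
  writeLines(txt, tmp)
  expect_error(read_sdf(tmp), "record 2")
})

test_that("aromatic-typed input is kekulized on read; impossible rings are quarantined", {
  # pyridine with order-4 bonds, plus a cyclopentadienyl-like ring that
  # admits no kekule structure (5 aromatic carbons, odd matching)
  block <- function(n, elems, bonds, name) {
    c(name, "  test", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bonds)),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              seq_len(n), 0, 0, elems),
      sprintf("%3d%3d%3d  0  0  0  0", bonds[, 1], bonds[, 2], bonds[, 3]),
      "M  END", "$$$$")
  }
  ringbonds <- function(n) cbind(seq_len(n), c(2:n, 1), 4L)
  lines <- c(block(6, c("N", rep("C", 5)), ringbonds(6), "pyridine"),
             block(5, rep("C", 5), ringbonds(5), "c5ring"))
  tmp <- withr::local_tempfile(fileext = ".sdf")
  writeLines(lines, tmp)
  recs <- read_sdf(tmp)
  expect_length(recs, 1)
  expect_setequal(unique(recs[[1]]$bonds[, 3]), c(1L, 2L))
  expect_equal(sum(recs[[1]]$bonds[, 3] == 2), 3)  # alternating sextet
  rej <- attr(recs, "rejects")
  expect_equal(rej$ordinal, 2)
  expect_match(rej$reason, "kekulization")
})

test_that("strength entries load with per-site targets and absent fields stay NA", {
  m1 <- random_tree_mol(5, seed = 11)
  m2 <- random_tree_mol(6, seed = 12)
  m1$props <- list(ROLE = "HBA", SITE_IDX = "2", DG_KJMOL = "-10.0")
  m2$props <- list(ROLE = "HBA", SITE_IDX = "3", DG_KJMOL = "-5.0",
                   XH_DISTANCE = "2.1")
  tmp <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(list(m1, m2), tmp)
  ents <- read_strength_entries(tmp, "HBA")
  expect_length(ents, 2)
  expect_equal(vapply(ents, function(e) e$dg_calibrated, numeric(1)),
               c(-10, -5))
  expect_true(is.na(ents[[1]]$xh_distance))
  expect_equal(ents[[2]]$xh_distance, 2.1)
  # entry without distance is summarizable but excluded from correlations
  expect_equal(database_summary(ents)$table$n_xh, 1)
  expect_error(distance_energy_correlation(ents), "at least 3")
})

test_that("role mismatches and non-numeric energies fail loudly", {
  m <- random_tree_mol(5, seed = 2)
  m$props <- list(ROLE = "HBD", SITE_IDX = "1", DG_KJMOL = "-1.0")
  tmp <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(m, tmp)
  expect_error(read_strength_entries(tmp, "HBA"), "role tag is HBD")
  m$props$ROLE <- "HBA"
  m$props$DG_KJMOL <- "not_a_number"
  write_sdf(m, tmp)
  expect_error(read_strength_entries(tmp, "HBA"), "non-numeric")
  m$props$DG_KJMOL <- NULL
  write_sdf(m, tmp)
  expect_error(read_strength_entries(tmp, "HBA"), "tags present")
})

test_that("energy units convert on read and triples compose consistently", {
  m <- random_tree_mol(4, seed = 3)
  m$props <- list(ROLE = "HBA", SITE_IDX = "1", DG_KJMOL = "-10.0",
                  E_HIGHDFT_COMPLEX = "-30", E_HIGHDFT_MOLECULE = "-15",
                  E_HIGHDFT_REFERENCE = "-10",
                  G_RRHO_COMPLEX = "42", G_RRHO_MOLECULE = "1",
                  G_RRHO_REFERENCE = "1",
                  DG_SOLV_COMPLEX = "3", DG_SOLV_MOLECULE = "1",
                  DG_SOLV_REFERENCE = "2")
  tmp <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(m, tmp)
  e <- read_strength_entries(tmp, "HBA")[[1]]
  expect_equal(e$dg_qc, (-30 + 15 + 10) + (42 - 2) + (3 - 3))  # 35
  # a stored dg_qc that disagrees with the composition is an error
  m$props$DG_QC_KJMOL <- "34.9"
  write_sdf(m, tmp)
  expect_error(read_strength_entries(tmp, "HBA"), "disagrees")
  # kcal conversion scales everything
  m$props$DG_QC_KJMOL <- NULL
  write_sdf(m, tmp)
  e2 <- read_strength_entries(tmp, "HBA", units = "kcal")[[1]]
  expect_equal(e2$dg_qc, 35 * 4.184)
})

test_that("SMILES files read with names and internal indexing round-trips 1-based SDF", {
  tmp <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "c1ccncc1 pyridine"), tmp)
  mols <- read_smiles(tmp)
  expect_length(mols, 2)
  expect_identical(mols[[1]]$name, "ethanol")
  # site index survives an SDF round trip unchanged (1-based both sides)
  s <- find_acceptor_sites(mols[[2]])[[1]]
  mols[[2]]$props$SITE_IDX <- as.character(s$atom_index)
  out <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(mols[[2]], out)
  back <- read_sdf(out)[[1]]
  idx <- as.integer(back$props$SITE_IDX)
  expect_identical(back$elements[idx], "N")
})
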