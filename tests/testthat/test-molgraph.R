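# Featurization checked against an RDKit reference (rdkit 2024.09.2)
# whose per-atom/per-bond values for these molecules were computed
# independently and frozen here.

test_that("atom feature vector has the documented 42-slot layout", {
  g <- quiet_parse("C")
  v <- g$atom_features[1, ]
  expect_length(v, 42L)
  # methane: C (slot 2 of 16), degree 0, sp3 (slot 3 of 5), implicit
  # valence 4, no radicals, no charge, not aromatic
  expect_equal(which(v[1:16] == 1), 2L)
  expect_equal(which(v[17:27] == 1), 1L)
  expect_equal(which(v[28:32] == 1), 3L)
  expect_equal(which(v[33:39] == 1), 5L)
  expect_equal(unname(v[40:42]), c(0, 0, 0))
})

test_that("bond feature vector has the documented 6-slot layout", {
  g <- quiet_parse("CC")
  expect_equal(g$n_directed_bonds, 2L)
  expect_equal(unname(g$bond_features[1, ]), c(1, 0, 0, 0, 0, 0))
  b <- quiet_parse("c1ccccc1")$bond_features
  expect_true(all(b[, 4] == 1))  # aromatic slot
  expect_true(all(b[, 5] == 1))  # conjugated
  expect_true(all(b[, 6] == 1))  # ring
})

test_that("parsing matches frozen RDKit reference values", {
  g <- quiet_parse("c1ccccc1")
  expect_equal(g$n_atoms, 6L)
  expect_equal(g$n_directed_bonds, 12L)
  expect_true(all(g$atoms$degree == 2))
  expect_true(all(g$atoms$hybridization == "sp2"))
  expect_true(all(g$atoms$implicit_valence == 1))
  expect_true(all(g$atoms$aromatic == 1))

  g <- quiet_parse("CC(C)C")
  expect_equal(g$atoms$degree, c(1, 3, 1, 1))
  expect_true(all(g$atoms$hybridization == "sp3"))
  expect_equal(g$atoms$implicit_valence, c(3, 1, 3, 3))

  g <- quiet_parse("C=C")
  expect_true(all(g$atoms$hybridization == "sp2"))
  expect_equal(g$bonds$bondtype, "double")
  expect_equal(g$bonds$conjugated, 0L)

  g <- quiet_parse("CC(=O)N")  # acetamide: conjugated amide, sp2 N
  expect_equal(g$atoms$hybridization, c("sp3", "sp2", "sp2", "sp2"))
  expect_equal(g$atoms$implicit_valence, c(3, 0, 0, 2))
  expect_equal(g$bonds$conjugated, c(0L, 1L, 1L))

  g <- quiet_parse("CS(=O)(=O)C")  # sulfone: hypervalent S stays sp3
  expect_equal(g$atoms$hybridization[2], "sp3")
  expect_true(all(g$bonds$conjugated == 0L))

  g <- quiet_parse("C#N")
  expect_equal(g$atoms$hybridization, c("sp", "sp"))
  expect_equal(g$atoms$implicit_valence, c(1, 0))

  g <- quiet_parse("C=C=C")  # allene: sp center, conjugated per RDKit
  expect_equal(g$atoms$hybridization, c("sp2", "sp", "sp2"))
  expect_equal(g$bonds$conjugated, c(1L, 1L))

  g <- quiet_parse("CC(=O)Oc1ccccc1C")  # cresyl acetate
  expect_equal(g$atoms$degree,
               c(1, 3, 1, 2, 3, 2, 2, 2, 2, 3, 1))
  expect_equal(g$atoms$aromatic,
               c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L, 1L, 0L))
  ester <- g$bonds$bondtype[g$bonds$i == 2 | g$bonds$j == 2]
  expect_setequal(ester, c("single", "double", "single"))
})

test_that("charges, radicals and the meta element slot", {
  g <- quiet_parse("[Na+]")
  expect_equal(g$n_atoms, 1L)
  expect_equal(which(g$atom_features[1, 1:16] == 1), 16L)  # meta slot
  expect_equal(g$atoms$formal_charge, 1L)

  g <- quiet_parse("[CH3]")
  expect_equal(g$atoms$radical_electrons, 1L)
  expect_equal(g$atoms$implicit_valence, 3L)
})

test_that("salt stripping keeps the largest fragment", {
  g <- quiet_parse("[Na+].[O-]C(=O)C")
  expect_equal(g$n_atoms, 4L)
  expect_equal(g$atoms$formal_charge, c(-1L, 0L, 0L, 0L))
  expect_equal(g$atoms$aromatic, rep(0L, 4))  # acyclic resonance != aromatic
  expect_equal(g$bonds$conjugated, c(1L, 1L, 0L))
})

test_that("molecular graph invariants hold across a fixture panel", {
  panel <- c("C", "CC", "c1ccccc1", "CC(=O)N", "CC(=O)Oc1ccccc1C",
             "C1CCCCC1", "C=CC=C", "c1ccoc1", "CCCl")
  for (s in panel) {
    g <- quiet_parse(s)
    m <- g$n_directed_bonds
    expect_true(m %% 2 == 0)
    if (m > 0) {
      expect_equal(g$reverse_index[g$reverse_index], seq_len(m))
      expect_equal(g$src, g$dst[g$reverse_index])
      expect_true(all(g$src >= 1 & g$src <= g$n_atoms))
    }
    # each directed bond is counted once at its target atom's degree
    expect_equal(sum(g$atoms$degree), m)
    # exactly-one-hot blocks
    expect_true(all(rowSums(g$atom_features[, 1:16, drop = FALSE]) == 1))
    expect_true(all(rowSums(g$atom_features[, 17:27, drop = FALSE]) == 1))
    expect_true(all(rowSums(g$atom_features[, 33:39, drop = FALSE]) == 1))
    expect_true(all(rowSums(g$atom_features[, 28:32, drop = FALSE]) <= 1))
    if (m > 0)
      expect_true(all(rowSums(g$bond_features[, 1:4, drop = FALSE]) == 1))
    # determinism: re-parsing yields byte-identical features
    g2 <- quiet_parse(s)
    expect_identical(g$atom_features, g2$atom_features)
    expect_identical(g$bond_features, g2$bond_features)
  }
})

test_that("degenerate and invalid inputs error cleanly", {
  expect_error(parse_smiles("notasmiles(("), "invalid SMILES")
  expect_error(parse_smiles(""), "non-empty")
  expect_error(parse_smiles(c("C", "CC")), "single")
})

test_that("drug and DDI tables round-trip and validate", {
  drugs <- data.frame(id = c("a", "b", "c"),
                      smiles = c("CC", "CCO", "c1ccccc1"))
  for (ext in c("csv", "tsv")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_drug_table(drugs, f)
    expect_equal(read_drug_table(f), drugs)
  }
  tuples <- data.frame(drug_x = c("a", "b"), drug_y = c("b", "c"),
                       type = c(0L, 1L), label = c(1L, 1L))
  f <- tempfile(fileext = ".csv")
  write_ddi_table(tuples, f)
  expect_equal(read_ddi_table(f, drugs), tuples)

  dup <- rbind(drugs, drugs[1, ])
  fd <- tempfile(fileext = ".csv")
  write_drug_table(dup, fd)
  expect_error(read_drug_table(fd), "duplicate drug id")

  bad <- data.frame(drug_x = "a", drug_y = "zz", type = 0L)
  fb <- tempfile(fileext = ".csv")
  write_ddi_table(bad, fb)
  expect_error(read_ddi_table(fb, drugs), "zz")

  sparse <- data.frame(drug_x = c("a", "b"), drug_y = c("b", "c"),
                       type = c(0L, 3L))
  fs <- tempfile(fileext = ".csv")
  write_ddi_table(sparse, fs)
  expect_message(out <- read_ddi_table(fs, drugs), "relabeled")
  expect_equal(out$type, c(0L, 1L))
  expect_equal(attr(out, "relation_map")$original, c(0L, 3L))
})
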