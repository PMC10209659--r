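test_that("parse_structure handles single atoms, multi-component records and formulas", {
  methane <- parse_structure("C")
  expect_equal(methane$atoms, "C")
  expect_equal(nrow(methane$bonds), 0L)
  expect_equal(methane$formula, "CH4")
  expect_equal(methane$n_components, 1L)

  mix <- parse_structure("CCO.CCN")
  expect_equal(mix$n_components, 2L)

  hba <- parse_structure("NC(=O)c1cccc(O)c1")
  expect_equal(length(hba$atoms), 10L)
  expect_equal(nrow(hba$bonds), 10L)
  expect_equal(hba$formula, "C7H7NO2")
  expect_equal(hba$mol_weight, 137.14, tolerance = 1e-3)

  expect_error(parse_structure("C1CC("), "cannot parse")
})

test_that("bond indices are in range and formulas count hydrogens", {
  pairs <- cached_pairs(20)
  for (p in pairs) {
    st <- p$structure
    n <- length(st$atoms)
    if (nrow(st$bonds)) {
      expect_true(all(st$bonds$a != st$bonds$b))
      expect_true(all(c(st$bonds$a, st$bonds$b) %in% seq_len(n)))
    }
    counts <- parse_formula(st$formula)
    n_h <- if ("H" %in% names(counts)) counts[["H"]] else 0L
    expect_equal(unname(n_h), st$n_hydrogens)
    expect_gte(st$n_components, 1L)
  }
})

test_that("element filter accepts GC-MS elements and rejects others", {
  expect_true(has_allowed_elements(parse_structure("CCO")))
  expect_true(has_allowed_elements(parse_structure("c1ccccc1Cl")))
  expect_false(has_allowed_elements(parse_structure("CC(=O)O[Na]")))
  expect_false(has_allowed_elements(parse_structure("CC[Si](C)(C)O[Al](C)C")))
})

test_that("to_graph produces consistent adjacency, incidence and feature matrices", {
  g <- to_graph(parse_structure("NC(=O)c1cccc(O)c1"))
  expect_equal(g$n_nodes, 10L)
  expect_equal(g$n_edges, 10L)
  expect_true(all(rowSums(g$node_features) == 1L))
  expect_true(all(rowSums(g$incidence) == 2L))
  expect_identical(g$adjacency, t(g$adjacency))
  expect_true(all(diag(g$adjacency) == 0L))
  expect_true(all(rowSums(g$edge_features[, 1:4, drop = FALSE]) == 1L))

  benz <- to_graph(parse_structure("c1ccccc1"))
  expect_equal(benz$n_nodes, 6L)
  expect_equal(benz$n_edges, 6L)
  expect_true(all(benz$edge_features[, "aromatic"] == 1L))
  expect_true(all(benz$edge_features[, "ring"] == 1L))

  methane <- to_graph(parse_structure("C"))
  expect_equal(methane$n_nodes, 1L)
  expect_equal(methane$n_edges, 0L)
  expect_identical(methane$adjacency, matrix(0L, 1L, 1L))

  expect_error(to_graph(parse_structure("CCO.CCN")), "components")
  expect_error(to_graph(parse_structure("CC(=O)O[Na]")), "disallowed")
})

test_that("edge feature rows distinguish bond orders and ring membership", {
  hba <- to_graph(parse_structure("NC(=O)c1cccc(O)c1"))
  expect_equal(unname(single_bond_feature_row(hba, 1)), c(1, 0, 0, 0, 0))
  benz <- to_graph(parse_structure("c1ccccc1"))
  expect_equal(unname(single_bond_feature_row(benz, 1)), c(0, 0, 0, 1, 1))
  ethene <- to_graph(parse_structure("C=C"))
  expect_equal(unname(single_bond_feature_row(ethene, 1)), c(0, 1, 0, 0, 0))
  ethyne <- to_graph(parse_structure("C#C"))
  expect_equal(unname(single_bond_feature_row(ethyne, 1)), c(0, 0, 1, 0, 0))
  cyclohexane <- to_graph(parse_structure("C1CCCCC1"))
  expect_equal(unname(single_bond_feature_row(cyclohexane, 1)), c(1, 0, 0, 0, 1))
  expect_error(single_bond_feature_row(benz, 7), "out of range")
  expect_error(single_bond_feature_row(benz, 0), "out of range")
})

test_that("stereochemistry collapses and explicit hydrogens do not add nodes", {
  cis <- to_graph(parse_structure("F/C=C\\F"))
  trans <- to_graph(parse_structure("F/C=C/F"))
  plain <- to_graph(parse_structure("FC=CF"))
  for (field in c("adjacency", "incidence", "node_features", "edge_features")) {
    expect_identical(cis[[field]], trans[[field]])
    expect_identical(cis[[field]], plain[[field]])
  }

  chiral_r <- parse_structure("C[C@H](N)C(=O)O")
  chiral_s <- parse_structure("C[C@@H](N)C(=O)O")
  expect_identical(chiral_r$bonds, chiral_s$bonds)

  bare <- parse_structure("CCO")
  explicit <- parse_structure("C([H])([H])([H])C([H])([H])O[H]")
  expect_equal(length(explicit$atoms), length(bare$atoms))
  expect_equal(nrow(explicit$bonds), nrow(bare$bonds))
  expect_equal(explicit$formula, bare$formula)
})

test_that("isotopic labels are stripped before featurization", {
  lab <- parse_structure("[13C]CO")
  ref <- parse_structure("CCO")
  expect_identical(lab$atoms, ref$atoms)
  expect_equal(lab$formula, ref$formula)
  expect_equal(lab$mol_weight, ref$mol_weight)
})

test_that("atom reindexing permutes the graph consistently (100 permutations x 20 molecules)", {
  pairs <- cached_pairs(20)
  set.seed(202)
  for (p in pairs) {
    g0 <- p$graph
    n <- g0$n_nodes
    for (rep in seq_len(5L)) {
      perm <- sample(n)
      gp <- to_graph(permute_structure(p$structure, perm))
      expect_identical(gp$adjacency, g0$adjacency[perm, perm, drop = FALSE])
      expect_identical(gp$node_features, g0$node_features[perm, , drop = FALSE])
      expect_identical(gp$edge_features, g0$edge_features)
      expect_true(igraph::isomorphic(
        igraph::graph_from_adjacency_matrix(gp$adjacency, mode = "undirected"),
        igraph::graph_from_adjacency_matrix(g0$adjacency, mode = "undirected")))
    }
  }
})

test_that("incidence and adjacency agree: t(B) B - D reproduces A", {
  for (p in cached_pairs(20)) {
    g <- p$graph
    if (!g$n_edges) next
    btb <- t(g$incidence) %*% g$incidence
    degree <- rowSums(g$adjacency)
    expect_equal(btb - diag(degree, nrow = g$n_nodes),
                 g$adjacency, ignore_attr = TRUE)
  }
})

test_that("SDF records parse with input-order atom numbering", {
  st <- parse_structure(hba_sdf(), format = "sdf")
  expect_equal(st$atoms, c("N", "O", "C", "C", "C", "C", "C", "C", "C", "O"))
  expect_equal(st$formula, "C7H7NO2")
  expect_equal(st$bonds$a[1], 1L)
  expect_equal(st$bonds$b[1], 3L)
  expect_equal(st$bonds$order[1], "single")
})

test_that("SMILES and SDF files round through the readers", {
  smi_path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO\tethanol", "c1ccccc1\tbenzene", "CCN"), smi_path)
  tab <- read_smiles_file(smi_path)
  expect_equal(tab$id, c("ethanol", "benzene", "mol0003"))
  expect_equal(tab$smiles[2], "c1ccccc1")

  sdf_path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(hba_sdf(), hba_sdf()), sdf_path)
  recs <- read_sdf_records(sdf_path)
  expect_length(recs, 2L)
  expect_equal(parse_structure(recs[[2]], format = "sdf")$formula, "C7H7NO2")
})
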