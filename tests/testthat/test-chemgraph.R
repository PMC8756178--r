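test_that("standardization strips salts, neutralizes and is idempotent", {
  s <- standardize_structure("CC(=O)[O-].[Na+]")
  expect_identical(as.character(s), as.character(standardize_structure("CC(=O)O")))
  expect_false(attr(s, "flagged"))

  # order of salt fragments does not matter
  s2 <- standardize_structure("[Na+].CC(=O)[O-]")
  expect_identical(as.character(s), as.character(s2))

  # fixed point
  expect_identical(as.character(standardize_structure(as.character(s))),
                   as.character(s))

  # benzene is already standard
  b <- standardize_structure("c1ccccc1")
  expect_identical(as.character(standardize_structure(as.character(b))),
                   as.character(b))

  # quaternary N cannot be neutralized: charge kept, record flagged
  q <- standardize_structure("C[N+](C)(C)C")
  expect_true(attr(q, "flagged"))
  expect_match(as.character(q), "N\\+", all = FALSE)

  # zwitterion collapses to the neutral form
  z <- standardize_structure("C(C(=O)[O-])[NH3+]")
  expect_identical(as.character(z),
                   as.character(standardize_structure("NCC(=O)O")))

  expect_error(standardize_structure("not_a_smiles((("), "unparseable")
  expect_error(standardize_structure(""), "empty")
})

test_that("standardization is idempotent across the fixture set", {
  fx <- fixture_molecules()
  for (i in seq_len(nrow(fx))) {
    s1 <- as.character(standardize_structure(fx$smiles[i]))
    expect_identical(as.character(standardize_structure(s1)), s1,
                     label = fx$name[i])
  }
})

test_that("build_graph produces correct skeleton, hydrogens and features", {
  g <- build_graph("CCO")
  expect_equal(g$n, 3L)
  expect_equal(nrow(g$bonds), 2L)
  expect_equal(g$h_count, c(3L, 2L, 1L))

  g1 <- build_graph("C")
  expect_equal(g1$n, 1L)
  expect_equal(nrow(g1$bonds), 0L)
  expect_equal(g1$h_count, 4L)

  gb <- build_graph("c1ccccc1")
  expect_equal(gb$n, 6L)
  expect_equal(nrow(gb$bonds), 6L)
  expect_true(all(gb$bond_type == "aromatic"))
  expect_true(all(gb$aromatic))
  expect_true(all(gb$in_ring))
  expect_true(all(gb$hybridization == "sp2"))

  # explicit-H input collapses to the same graph
  expect_equal(build_graph("[OH2]")$h_count, build_graph("O")$h_count)

  # constant feature dimensions across molecules
  cfg <- default_feature_config()
  expect_length(cfg$atom_schema, 8L)
  expect_length(cfg$bond_schema, 4L)
  for (smi in c("CCO", "c1ccccc1", "CS(N)(=O)=O")) {
    g <- build_graph(smi, cfg)
    expect_equal(ncol(g$atom_features), cfg$atom_dim)
    expect_equal(ncol(g$bond_features), cfg$bond_dim)
  }

  expect_error(build_graph("[H][H]"), "heavy")
})

test_that("site enumeration matches the frozen per-atom rule oracle", {
  fx <- fixture_molecules()
  for (i in seq_len(nrow(fx))) {
    g <- build_graph(as.character(standardize_structure(fx$smiles[i])))
    expect_equal(g$n, fx$n_heavy[i], label = fx$name[i])
    P <- enumerate_acidic_sites(g)
    Q <- enumerate_basic_sites(g)
    expect_identical(sort(g$element[P]), split_elements(fx$acidic_elements[i]),
                     label = paste(fx$name[i], "acidic"))
    expect_identical(sort(g$element[Q]), split_elements(fx$basic_elements[i]),
                     label = paste(fx$name[i], "basic"))
    # brute-force re-application of the textual rules on the graph
    expect_identical(P, which(g$element != "C" & g$h_count >= 1L))
    expect_identical(Q, which(g$element == "N" & g$formal_charge <= 0L))
    ann <- annotate_sites(g)
    expect_identical(ann$acidic_sites, P)
    expect_identical(ann$basic_sites, Q)
  }
})

test_that("atom reindexing yields an isomorphic graph with mapped sites", {
  # same molecules written from different starting atoms
  pairs <- list(
    c("CC(=O)O", "OC(C)=O"),
    c("Oc1ccccc1", "c1ccc(O)cc1"),
    c("NCC(N)CN", "C(N)C(CN)N")
  )
  for (p in pairs) {
    g1 <- build_graph(as.character(standardize_structure(p[1])))
    g2 <- build_graph(as.character(standardize_structure(p[2])))
    expect_equal(g1$n, g2$n)
    expect_identical(sort(g1$element), sort(g2$element))
    expect_identical(sort(g1$element[enumerate_acidic_sites(g1)]),
                     sort(g2$element[enumerate_acidic_sites(g2)]))
    expect_identical(sort(g1$element[enumerate_basic_sites(g1)]),
                     sort(g2$element[enumerate_basic_sites(g2)]))
    # canonicalization makes the two graphs identical, not just isomorphic
    expect_identical(g1$smiles, g2$smiles)
  }
})

test_that("record readers round-trip ids, structures and labels", {
  tmp <- withr::local_tempdir()
  smi_path <- file.path(tmp, "mols.smi")
  writeLines(c("CC(=O)O acetic", "c1ccncc1 pyridine"), smi_path)
  r <- read_smiles_file(smi_path)
  expect_equal(r$record_id, c("acetic", "pyridine"))

  csv_path <- file.path(tmp, "mols.csv")
  write.csv(data.frame(id = c("a", "b"), smiles = c("CC(=O)O", "CCN"),
                       pka_acidic = c(4.76, NA), pka_basic = c(NA, 10.7)),
            csv_path, row.names = FALSE)
  rc <- read_molecule_csv(csv_path)
  expect_equal(rc$acidic_label, c(4.76, NA))
  expect_equal(rc$basic_label, c(NA, 10.7))

  rc <- standardize_records(rc)
  expect_false(anyNA(rc$standardized_smiles))
  st <- site_table(rc, mode = "both")
  expect_true(all(c("record_id", "mode", "atom_index", "element", "rule")
                  %in% names(st)))
  expect_setequal(st$element[st$record_id == "a"], "O")
  expect_true(any(st$mode[st$record_id == "b"] == "basic"))
})
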