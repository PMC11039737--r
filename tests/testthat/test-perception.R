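# A hand-built planar benzene with explicit hydrogens, used so perception
# tests do not depend on the SMILES embedder.
hand_benzene <- function() {
  ang <- (0:5) * pi / 3
  cxy <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  hxy <- cbind(2.5 * cos(ang), 2.5 * sin(ang), 0)
  atoms <- data.frame(element = c(rep("C", 6), rep("H", 6)))
  bonds <- data.frame(a1 = c(1:6, 1:6),
                      a2 = c(2:6, 1, 7:12),
                      order = c(rep(c(2L, 1L), 3), rep(1L, 6)))
  molecule3d("benzene", atoms, bonds, rbind(cxy, hxy))
}

test_that("default rules cover all five kinds and the documented patterns", {
  rules <- default_rules()
  expect_setequal(unique(rules$kind), FEATURE_KINDS)
  # cyclopropyl-bearing pattern is hydrophobic; carboxyl oxygens are ML
  expect_true("Hyd" %in% rules$kind[rules$pattern == "aliphatic_carbocycle"])
  expect_true("ML" %in% rules$kind[rules$pattern == "carboxyl_o"])
  expect_error(write_perception_rules(
    data.frame(kind = "Zzz", pattern = "aromatic_ring", placement = "atom"),
    tempfile()), "unknown feature kind")
})

test_that("benzene perceives as a single aromatic centroid", {
  fs <- perceive(hand_benzene())
  expect_length(fs$features, 1L)
  expect_true("Aro" %in% fs$features[[1]]$kinds)
  expect_equal(fs$features[[1]]$xyz, c(0, 0, 0), tolerance = 1e-8)
  expect_true(all(fs$features[[1]]$atoms %in% 1:6))
})

test_that("methanol merges donor and acceptor at the oxygen; ethane is one hydrophobe", {
  mols <- smiles_to_mol3d(c(methanol = "CO", ethane = "CC"))
  fs_meoh <- perceive(mols$methanol)
  expect_length(fs_meoh$features, 1L)
  expect_setequal(fs_meoh$features[[1]]$kinds, c("Acc", "Don"))
  o_idx <- which(mols$methanol$atoms$element == "O")
  expect_equal(fs_meoh$features[[1]]$xyz,
               as.numeric(mols$methanol$conformers[[1]][o_idx, ]),
               tolerance = 1e-8)

  fs_eth <- perceive(mols$ethane)
  expect_length(fs_eth$features, 1L)
  expect_identical(fs_eth$features[[1]]$kinds, "Hyd")
  c_idx <- which(mols$ethane$atoms$element == "C")
  expect_equal(fs_eth$features[[1]]$xyz,
               colMeans(mols$ethane$conformers[[1]][c_idx, ]),
               tolerance = 1e-8)
})

test_that("perception is equivariant under rigid motion of the conformer", {
  mol <- hand_benzene()
  fs0 <- perceive(mol)
  set.seed(5)
  R <- test_rotation(); t_ <- stats::rnorm(3, 0, 10)
  mol$conformers[[1]] <- sweep(mol$conformers[[1]] %*% t(R), 2, t_, `+`)
  fs1 <- perceive(mol)
  expect_length(fs1$features, length(fs0$features))
  for (i in seq_along(fs0$features)) {
    expect_identical(fs1$features[[i]]$kinds, fs0$features[[i]]$kinds)
    expect_equal(fs1$features[[i]]$xyz,
                 as.vector(R %*% fs0$features[[i]]$xyz) + t_,
                 tolerance = 1e-6)
  }
})

test_that("no two perceived features lie within the merge radius", {
  mols <- smiles_to_mol3d(c(asp = "CC(=O)Oc1ccccc1C(=O)O",  # aspirin
                            ser = "NC(CO)C(=O)O"))
  for (mol in mols) {
    fs <- perceive(mol)
    pos <- t(vapply(fs$features, `[[`, numeric(3), "xyz"))
    if (nrow(pos) >= 2) {
      dmin <- min(stats::dist(pos))
      expect_gt(dmin, 0.5)
    }
    for (f in fs$features)
      expect_true(all(f$atoms >= 1 & f$atoms <= nrow(mol$atoms)))
  }
})

test_that("aspirin's carboxyl oxygens carry the metal-ligator kind", {
  mol <- smiles_to_mol3d(c(asp = "CC(=O)Oc1ccccc1C(=O)O"))[[1]]
  fs <- perceive(mol)
  kinds <- lapply(fs$features, `[[`, "kinds")
  expect_true(any(vapply(kinds, function(k) all(c("ML", "Acc") %in% k), logical(1))))
  expect_true(any(vapply(kinds, function(k) "Aro" %in% k, logical(1))))
})

test_that("the ten fixture drugs parse, embed deterministically and perceive", {
  drugs <- fixture_drugs()
  expect_length(drugs, 10L)
  expect_named(drugs, c("Trovafloxacin", "Vilazodone", "Pitavastatin",
                        "Dasabuvir", "Ranolazine", "Acetophenazine",
                        "Dasatinib", "Gefitinib", "Apixaban", "Nefazodone"))
  for (mol in drugs) {
    expect_s3_class(mol, "molecule3d")
    expect_gte(length(mol$conformers), 1L)
  }
  # the statin hit presents aromatic, donor and acceptor features
  pit <- perceive(drugs$Pitavastatin)
  all_kinds <- unique(unlist(lapply(pit$features, `[[`, "kinds")))
  expect_true(all(c("Aro", "Don", "Acc") %in% all_kinds))

  # re-embedding is stable at the connectivity level (the 3D cleanup is
  # stochastic, but everything asserted about the fixtures is graph-based)
  again <- smiles_to_mol3d(phorescreen:::DRUG_SMILES["Pitavastatin"])[[1]]
  expect_identical(again$atoms, drugs$Pitavastatin$atoms)
  expect_identical(again$bonds, drugs$Pitavastatin$bonds)
  kind_multiset <- function(m) sort(vapply(perceive(m)$features, function(f)
    paste(f$kinds, collapse = ","), character(1)))
  expect_identical(kind_multiset(again), kind_multiset(drugs$Pitavastatin))
  # and the cached fixtures are stable within a session
  expect_identical(fixture_drugs()$Pitavastatin$conformers,
                   drugs$Pitavastatin$conformers)
})

test_that("perception rules survive a JSON round trip", {
  rules <- default_rules()
  path <- withr::local_tempfile(fileext = ".json")
  write_perception_rules(rules, path)
  expect_equal(read_perception_rules(path), rules)
})
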