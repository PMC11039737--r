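model <- builtin_dual_model()

test_that("enumeration equals brute force on random small instances", {
  set.seed(17)
  for (rep in 1:12) {
    np <- sample(0:8, 1)
    feats <- lapply(seq_len(np), function(i) {
      list(kinds = sample(FEATURE_KINDS, sample(1:2, 1)),
           xyz = stats::rnorm(3, 0, 3), atoms = integer())
    })
    fs <- feature_set(paste0("rand", rep), 1L, feats)
    got <- enumerate_correspondences(fs, model)
    want <- brute_force_correspondences(fs, model)
    expect_setequal(vapply(got, corr_key, character(1)),
                    vapply(want, corr_key, character(1)))
  }
  # and on near-model geometry where matches actually exist
  for (rep in 1:6) {
    fs <- exact_feature_set(model)
    fs$features <- lapply(fs$features, function(f) {
      f$xyz <- f$xyz + stats::rnorm(3, 0, 0.3); f
    })
    got <- enumerate_correspondences(fs, model)
    want <- brute_force_correspondences(fs, model)
    expect_setequal(vapply(got, corr_key, character(1)),
                    vapply(want, corr_key, character(1)))
    expect_gte(length(got), 1L)
  }
})

test_that("exact synthetic actives score 5/5 with zero RMSD", {
  fs <- exact_feature_set(model)
  res <- best_match(fs, model)
  expect_identical(res$fitting, "5/5")
  expect_lt(res$rmsd, 1e-8)
  expect_identical(unname(res$correspondence[c("F1", "F5")]), c(1L, 5L))
})

test_that("dropping the non-essential feature gives 4/5; dropping an essential kills the match", {
  fs <- exact_feature_set(model)
  fs4 <- feature_set("noF4", 1L, fs$features[-4])
  expect_identical(best_match(fs4, model)$fitting, "4/5")

  for (drop in c(1L, 2L, 3L, 5L)) {
    fs_e <- feature_set(paste0("noF", drop), 1L, fs$features[-drop])
    expect_null(best_match(fs_e, model))
    expect_length(brute_force_correspondences(fs_e, model), 0L)
  }
  expect_length(enumerate_correspondences(feature_set("empty", 1L, list()),
                                          model), 0L)
})

test_that("match decisions are invariant under proper rigid motion", {
  set.seed(31)
  base <- exact_feature_set(model)
  base$features <- lapply(base$features, function(f) {
    f$xyz <- f$xyz + stats::rnorm(3, 0, 0.15); f
  })
  ref <- best_match(base, model)
  for (rep in 1:5) {
    moved <- rigidly_move(base, test_rotation(), stats::rnorm(3, 0, 8))
    res <- best_match(moved, model)
    expect_identical(res$fitting, ref$fitting)
    expect_equal(res$rmsd, ref$rmsd, tolerance = 1e-6)
  }
})

test_that("shrinking radii never creates a match", {
  set.seed(41)
  scales <- c(1.5, 1.0, 0.7, 0.4, 0.2)
  for (rep in 1:6) {
    fs <- exact_feature_set(model)
    fs$features <- lapply(fs$features, function(f) {
      f$xyz <- f$xyz + stats::rnorm(3, 0, 0.25); f
    })
    n_prev <- Inf
    for (s in scales) {
      res <- best_match(fs, model, match_params(radius_scale = s))
      n <- if (is.null(res)) 0L else res$n_matched
      expect_lte(n, n_prev)
      n_prev <- n
    }
  }
})

test_that("accepted residuals always sit inside the scaled radii", {
  set.seed(43)
  radii <- feature_radii(model)
  for (rep in 1:10) {
    fs <- exact_feature_set(model)
    fs$features <- lapply(fs$features, function(f) {
      f$xyz <- f$xyz + stats::rnorm(3, 0, 0.3); f
    })
    res <- best_match(fs, model)
    if (!is.null(res))
      expect_true(all(res$residuals <= radii[names(res$residuals)] + 1e-9))
  }
})

test_that("screening orders hits first and tolerates bad records", {
  set.seed(53)
  actives <- lapply(1:3, function(i)
    synth_active(model, generator_params(jitter_sd = 0, dropout_prob = 0),
                 id = paste0("act", i)))
  decoys <- lapply(1:2, function(i)
    synth_decoy(model, generator_params(), id = paste0("dec", i),
                mode = "type_scramble"))
  tab <- screen_features(c(actives, decoys), model)
  expect_equal(sum(tab$hit), 3L)
  expect_equal(sum(!tab$hit), 2L)
  expect_lt(max(which(tab$hit)), min(which(!tab$hit)))

  empty <- screen_features(list(), model)
  expect_equal(nrow(empty), 0L)

  # TSV round trip preserves the table
  path <- withr::local_tempfile(fileext = ".tsv")
  write_screening_tsv(tab, path, provenance = c(tool = "phorescreen test"))
  back <- read_screening_tsv(path)
  expect_equal(back$molecule_id, tab$molecule_id)
  expect_equal(back$hit, tab$hit)
})

test_that("a multi-conformer molecule is matched on its best conformer", {
  good <- exact_feature_set(model)
  good$conformer <- 2L
  bad <- feature_set("exact", 1L, lapply(good$features, function(f) {
    f$xyz <- f$xyz * 3; f
  }))
  res <- best_match(list(bad, good), model)
  expect_identical(res$conformer, 2L)
  expect_identical(res$fitting, "5/5")
})
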