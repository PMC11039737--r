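model <- builtin_dual_model()

test_that("consensus of identical copies reproduces the feature set", {
  fs <- exact_feature_set(model)
  ens <- lapply(1:12, function(i) { fs$molecule_id <- paste0("lig", i); fs })
  cm <- consensus_model(ens)
  df <- as.data.frame(cm)
  expect_equal(nrow(df), 5L)
  expect_true(all(as.data.frame(cm)$essential))
  expect_equal(attr(cm, "support"), stats::setNames(rep(1, 5), df$id))
  centers_in <- t(vapply(fs$features, `[[`, numeric(3), "xyz"))
  centers_out <- as.matrix(df[, c("x", "y", "z")])
  for (i in seq_len(5))
    expect_true(any(apply(centers_in, 1, function(p)
      isTRUE(all.equal(p, unname(centers_out[i, ]), tolerance = 1e-12)))))
  expect_equal(cm$min_match, 5L)
})

test_that("features below the support threshold are excluded", {
  fs <- exact_feature_set(model)
  # an extra satellite feature present in only 5 of 12 ligands (41.7% < 50%)
  ens <- lapply(1:12, function(i) {
    feats <- fs$features
    if (i <= 5)
      feats[[length(feats) + 1L]] <- list(kinds = "Don", xyz = c(8, 8, 8),
                                          atoms = integer())
    feature_set(paste0("lig", i), 1L, feats)
  })
  cm <- consensus_model(ens)
  expect_equal(nrow(as.data.frame(cm)), 5L)
  expect_true(all(abs(as.data.frame(cm)$x) < 5))  # satellite at x=8 excluded

  # raising the threshold never adds a feature
  n_at <- function(th) nrow(as.data.frame(
    consensus_model(ens, consensus_params(threshold = th,
                                          essential_threshold = max(th, 0.9)))))
  counts <- vapply(c(0.3, 0.5, 0.8), n_at, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("an ensemble with no majority feature raises an empty-model error", {
  ens <- lapply(1:4, function(i)
    feature_set(paste0("lig", i), 1L,
                list(list(kinds = "Aro", xyz = c(10 * i, 0, 0),
                          atoms = integer()))))
  expect_error(consensus_model(ens), "support threshold")
})

test_that("jittered copies of the built-in model are recovered within tolerance", {
  set.seed(7)
  ens <- jittered_ensemble(model, n = 12L, sd = 0.2, n_drop = 5L)
  cm <- consensus_model(ens)
  df <- as.data.frame(cm)
  sup <- attr(cm, "support")
  expect_equal(nrow(df), 5L)
  true_centers <- feature_centers(model)
  # each consensus center lies within the clustering tolerance of a distinct
  # true center, and within 0.3 A of it (jitter averages out)
  assigned <- apply(as.matrix(df[, c("x", "y", "z")]), 1, function(p) {
    d <- sqrt(rowSums((true_centers - matrix(p, 5, 3, byrow = TRUE))^2))
    which.min(d)
  })
  expect_setequal(assigned, 1:5)
  for (i in seq_len(5)) {
    d <- sqrt(sum((as.numeric(df[i, c("x", "y", "z")]) -
                     true_centers[assigned[i], ])^2))
    expect_lt(d, 0.3)
  }
  # the F4 cluster has the lowest support and is the only non-essential
  f4_row <- which(assigned == 4)
  expect_equal(unname(sup[f4_row]), min(sup))
  expect_false(df$essential[f4_row])
  expect_equal(cm$min_match, 4L)
  # the result is a valid, serializable model
  path <- withr::local_tempfile(fileext = ".json")
  write_pharmacophore(cm, path)
  expect_equal(as.data.frame(read_pharmacophore(path)), df)
})
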