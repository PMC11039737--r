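test_that("the six statistics follow their defining ratios", {
  m <- metrics_from_counts(confusion_counts(tp = 10, fn = 10, fp = 5, tn = 45))
  expect_equal(unname(m$percent["sensitivity"]), 50.00, tolerance = 1e-10)
  expect_equal(unname(m$percent["specificity"]), 90.00, tolerance = 1e-10)
  expect_equal(unname(m$percent["fpr"]), 10.00, tolerance = 1e-10)
  expect_equal(round(unname(m$percent["accuracy"]), 2), 78.57)
  expect_equal(round(unname(m$percent["ppv"]), 2), 66.67)
  expect_equal(round(unname(m$percent["npv"]), 2), 81.82)

  perfect <- metrics_from_counts(confusion_counts(20, 0, 0, 30))
  expect_equal(unname(perfect$percent["fpr"]), 0)
  expect_true(all(perfect$percent[names(perfect$percent) != "fpr"] == 100))
})

test_that("algebraic identities hold on random counts", {
  set.seed(2)
  for (rep in 1:25) {
    c_ <- confusion_counts(sample(0:50, 1), sample(0:50, 1),
                           sample(0:50, 1), sample(0:50, 1))
    if (c_$n_actives == 0 || c_$n_decoys == 0) next
    m <- metrics_from_counts(c_)
    expect_equal(unname(m$percent["specificity"] + m$percent["fpr"]), 100)
    expect_equal(unname(m$percent["accuracy"]),
                 unname((m$percent["sensitivity"] * c_$n_actives +
                           m$percent["specificity"] * c_$n_decoys) /
                          (c_$n_actives + c_$n_decoys)))
    ok <- !is.na(m$percent)
    expect_true(all(m$percent[ok] >= 0 & m$percent[ok] <= 100))
  }
})

test_that("zero denominators mark only the affected statistics undefined", {
  # internal validation style: actives only, no decoys, all hit
  m <- metrics_from_counts(confusion_counts(tp = 12, fn = 0, fp = 0, tn = 0))
  expect_equal(unname(m$percent["sensitivity"]), 100)
  expect_true(is.na(m$percent["specificity"]))
  expect_true(is.na(m$percent["fpr"]))
  expect_false(is.na(m$percent["accuracy"]))
  expect_true(is.na(m$percent["npv"]))

  empty <- metrics_from_counts(confusion_counts(0, 0, 0, 0))
  expect_true(all(is.na(empty$percent)))
})

test_that("screen tallies agree with an independent per-molecule recount", {
  model <- builtin_dual_model()
  bench <- make_benchmark(model, generator_params(n_actives = 12,
                                                  n_decoys = 15, seed = 1))
  tab <- screen_features(bench$feature_sets, model)
  counts <- counts_from_screen(bench$labels, tab)

  # oracle: recount by re-matching each molecule independently
  tp <- fn <- fp <- tn <- 0L
  for (i in seq_len(nrow(bench$labels))) {
    id <- bench$labels$molecule_id[i]
    hit <- !is.null(best_match(bench$feature_sets[[id]], model))
    if (bench$labels$label[i] == "active") {
      if (hit) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (hit) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  expect_equal(counts$tp, tp)
  expect_equal(counts$fn, fn)
  expect_equal(counts$fp, fp)
  expect_equal(counts$tn, tn)
})

test_that("unlabeled molecules are reported by id", {
  tab <- data.frame(molecule_id = c("a", "mystery"), hit = c(TRUE, FALSE),
                    n_matched = c(5L, 0L), fitting = c("5/5", "0/5"),
                    rmsd_A = c(0.1, NA), conformer = c(1L, NA),
                    error = FALSE)
  labels <- data.frame(molecule_id = "a", label = "active")
  expect_error(counts_from_screen(labels, tab), "mystery")
})
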