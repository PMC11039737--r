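test_that("the built-in dual-inhibitor model carries the published geometry", {
  m <- builtin_dual_model()
  df <- as.data.frame(m)
  expect_identical(df$id, c("F1", "F2", "F3", "F4", "F5"))
  expect_identical(df$expr, c("Aro|Hyd", "Aro|Hyd", "Aro|Hyd",
                              "ML|Acc|Don", "ML&(Acc|Don)"))
  expect_equal(df$radius, c(1.5, 1.5, 0.7, 1.3, 0.4))
  expect_identical(df$essential, c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(m$min_match, 4L)
  expect_equal(unlist(df[5, c("x", "y", "z")], use.names = FALSE),
               c(-0.9913, -2.8787, 0.6632))
})

test_that("inter-feature distances and angles match the published values", {
  m <- builtin_dual_model()
  expect_equal(round(feature_distance(m, "F1", "F3"), 2), 4.85)
  expect_equal(round(feature_distance(m, "F3", "F5"), 2), 1.04)
  expect_equal(feature_distance(m, "F2", "F2"), 0)
  expect_equal(round(feature_angle(m, "F1", "F3", "F4"), 1), 44.8)
  expect_equal(round(feature_angle(m, "F3", "F1", "F5"), 1), 124.5)

  # symmetry and triangle inequality over all feature triples
  ids <- c("F1", "F2", "F3", "F4", "F5")
  for (a in ids) for (b in ids)
    expect_equal(feature_distance(m, a, b), feature_distance(m, b, a))
  for (tri in utils::combn(ids, 3, simplify = FALSE)) {
    d12 <- feature_distance(m, tri[1], tri[2])
    d13 <- feature_distance(m, tri[1], tri[3])
    d23 <- feature_distance(m, tri[2], tri[3])
    expect_lte(d12, d13 + d23 + 1e-12)
  }
})

test_that("angle convention: apex at the named feature, collinear gives 0", {
  synth <- pharmacophore(data.frame(
    id = c("A", "B", "C"), expr = "Aro",
    x = c(0, 1, 2), y = 0, z = 0, radius = 1,
    essential = FALSE), min_match = 1L)
  expect_equal(feature_angle(synth, "A", "B", "C"), 0)
  expect_equal(feature_angle(synth, "B", "A", "C"), 180)
  expect_error(feature_angle(synth, "A", "A", "B"), "distinct")
  degenerate <- pharmacophore(data.frame(
    id = c("A", "B", "C"), expr = "Aro",
    x = c(0, 0, 1), y = 0, z = 0, radius = 1,
    essential = FALSE), min_match = 1L)
  expect_error(feature_angle(degenerate, "A", "B", "C"), "degenerate")
})

test_that("geometry_report emits the ten published relations", {
  rep_ <- geometry_report(builtin_dual_model())
  expect_equal(nrow(rep_), 10L)
  get_d <- function(a, b) rep_$value[rep_$kind == "distance" & rep_$a == a & rep_$b == b]
  get_a <- function(ap) rep_$value[rep_$kind == "angle" & rep_$apex == ap]
  expect_equal(get_d("F2", "F4"), 4.13, tolerance = 0.01 / 4.13)
  expect_equal(get_a("F4"), 124.4, tolerance = 0.1 / 124.4)
  expect_equal(get_a("F5"), 64.7, tolerance = 0.1 / 64.7)

  # a two-feature model yields one distance and no angles
  two <- pharmacophore(data.frame(id = c("A", "B"), expr = "Aro",
                                  x = c(0, 3), y = 0, z = 0, radius = 1,
                                  essential = FALSE), min_match = 1L)
  rep2 <- geometry_report(two)
  expect_identical(rep2$kind, "distance")
  expect_equal(rep2$value, 3)
})

test_that("model JSON IO round-trips and validates", {
  m <- builtin_dual_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_pharmacophore(m, path)
  m2 <- read_pharmacophore(path)
  expect_equal(as.data.frame(m2), as.data.frame(m))
  expect_equal(m2$min_match, m$min_match)

  # invariant violations are rejected with informative messages
  obj <- jsonlite::read_json(path)
  obj$features[[1]]$radius <- -1
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, bad, auto_unbox = TRUE, digits = NA)
  expect_error(read_pharmacophore(bad), "radius")

  obj2 <- jsonlite::read_json(path)
  obj2$features[[2]]$essential <- NULL
  defaulted <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj2, defaulted, auto_unbox = TRUE, digits = NA)
  expect_warning(m3 <- read_pharmacophore(defaulted), "essential")
  expect_true(as.data.frame(m3)$essential[2])
})

test_that("model invariants are enforced at construction", {
  feats <- data.frame(id = c("A", "A"), expr = "Aro", x = 0, y = 0, z = 0,
                      radius = 1, essential = FALSE)
  expect_error(pharmacophore(feats, min_match = 1L), "duplicate")
  feats2 <- data.frame(id = c("A", "B"), expr = "Aro", x = 0:1, y = 0, z = 0,
                       radius = 1, essential = TRUE)
  expect_error(pharmacophore(feats2, min_match = 1L), "essential")
  expect_error(pharmacophore(feats2, min_match = 5L), "min_match")
})
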