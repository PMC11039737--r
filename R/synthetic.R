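#' Synthetic benchmark generator parameters
#'
#' Defaults mirror the validation design the package emulates: 56 actives
#' and 207 decoys, actives jittered with isotropic Gaussian noise of sd
#' 0.2 \enc{Å}{A} and dropping the non-essential feature with probability
#' 0.3; decoys drawn round-robin from the three failure modes with a
#' geometry inflation factor of 3.
#'
#' @param n_actives,n_decoys set sizes.
#' @param jitter_sd isotropic Gaussian positional noise on actives
#'   (\enc{Å}{A}, per coordinate).
#' @param dropout_prob probability that an active omits a non-essential
#'   feature.
#' @param decoy_mode \code{"type_scramble"} (correct geometry, polar and
#'   apolar kinds swapped so the aromatic/hydrophobic essentials cannot all
#'   be satisfied), \code{"geometry_inflate"} (correct kinds, all pairwise
#'   distances scaled by \code{inflate_factor}), \code{"feature_deficit"}
#'   (two essential features deleted) or \code{"mixed"} (round-robin over
#'   the three).
#' @param inflate_factor distance scale factor for geometry-inflated
#'   decoys (> 1; \eqn{\ge} 2 guarantees failure against the built-in
#'   radii).
#' @param kind_mode \code{"minimal"}: each active feature carries a random
#'   minimal kind set satisfying its expression; \code{"full"}: it carries
#'   every kind the expression mentions (appropriate for consensus
#'   ensembles).
#' @param seed integer seed recorded in the benchmark provenance.
#' @return An object of class \code{generator_params}.
#' @export
generator_params <- function(n_actives = 56L, n_decoys = 207L, jitter_sd = 0.2,
                             dropout_prob = 0.3, decoy_mode = "mixed",
                             inflate_factor = 3, kind_mode = "minimal",
                             seed = 1L) {
  decoy_mode <- match.arg(decoy_mode, c("mixed", "type_scramble",
                                        "geometry_inflate", "feature_deficit"))
  kind_mode <- match.arg(kind_mode, c("minimal", "full"))
  stopifnot(n_actives >= 0, n_decoys >= 0, jitter_sd >= 0,
            dropout_prob >= 0, dropout_prob <= 1, inflate_factor > 1)
  structure(list(n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys),
                 jitter_sd = jitter_sd, dropout_prob = dropout_prob,
                 decoy_mode = decoy_mode, inflate_factor = inflate_factor,
                 kind_mode = kind_mode, seed = as.integer(seed)),
            class = "generator_params")
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

apply_random_rigid_motion <- function(features) {
  R <- random_rotation()
  t_ <- stats::rnorm(3, 0, 5)
  lapply(features, function(f) {
    f$xyz <- as.vector(R %*% f$xyz) + t_
    f
  })
}

sample_kinds_for <- function(expr, kind_mode) {
  if (kind_mode == "full") return(expr_leaves(expr))
  sets <- minimal_satisfying_sets(expr)
  sets[[sample.int(length(sets), 1L)]]
}

#' Generate a synthetic active-like feature set
#'
#' One point per model feature at the feature center plus isotropic
#' Gaussian jitter, carrying kinds that satisfy the feature's expression;
#' each non-essential feature is omitted with probability
#' \code{dropout_prob}; the whole set receives a random rigid motion.
#' Uses the current RNG state (seed at the benchmark level, see
#' \code{\link{make_benchmark}}).
#'
#' @param model a \code{\link{pharmacophore}}.
#' @param params a \code{\link{generator_params}}.
#' @param id molecule identifier for the generated set.
#' @return A \code{\link{feature_set}}.
#' @export
synth_active <- function(model, params = generator_params(), id = "active") {
  feats <- list()
  for (f in model$features) {
    if (!f$essential && stats::runif(1) < params$dropout_prob) next
    feats[[length(feats) + 1L]] <- list(
      kinds = sample_kinds_for(f$expr, params$kind_mode),
      xyz = f$center + stats::rnorm(3, 0, params$jitter_sd),
      atoms = integer())
  }
  feature_set(id, 1L, apply_random_rigid_motion(feats))
}

#' Generate a synthetic decoy-like feature set
#'
#' Each mode guarantees no valid correspondence of size \code{min_match}
#' including all essential features (for \code{geometry_inflate}, when
#' \code{inflate_factor} \eqn{\ge} 2 against the built-in radii):
#' \code{type_scramble} keeps the (jittered) geometry but swaps polar and
#' apolar kinds, so at most one point can serve the aromatic/hydrophobic
#' essentials; \code{geometry_inflate} keeps kinds but scales all pairwise
#' distances about the centroid; \code{feature_deficit} deletes two
#' essential features.
#'
#' @inheritParams synth_active
#' @param mode one of \code{"type_scramble"}, \code{"geometry_inflate"},
#'   \code{"feature_deficit"}.
#' @return A \code{\link{feature_set}}.
#' @export
synth_decoy <- function(model, params = generator_params(), id = "decoy",
                        mode = c("type_scramble", "geometry_inflate",
                                 "feature_deficit")) {
  mode <- match.arg(mode)
  feats <- list()
  apolar <- c("Aro", "Hyd")
  for (f in model$features) {
    xyz <- f$center + stats::rnorm(3, 0, params$jitter_sd)
    kinds <- switch(
      mode,
      type_scramble = {
        leaves <- expr_leaves(f$expr)
        if (any(leaves %in% apolar)) sample(c("Acc", "Don"), 1L)
        else sample(apolar, 1L)
      },
      sample_kinds_for(f$expr, params$kind_mode))
    feats[[length(feats) + 1L]] <- list(kinds = kinds, xyz = xyz,
                                        atoms = integer())
  }
  if (mode == "geometry_inflate") {
    pos <- t(vapply(feats, `[[`, numeric(3), "xyz"))
    centroid <- colMeans(pos)
    for (i in seq_along(feats))
      feats[[i]]$xyz <- centroid + params$inflate_factor * (feats[[i]]$xyz - centroid)
  }
  if (mode == "feature_deficit") {
    ess <- which(vapply(model$features, `[[`, logical(1), "essential"))
    drop <- sample(ess, min(2L, length(ess)))
    feats <- feats[-drop]
  }
  feature_set(id, 1L, apply_random_rigid_motion(feats))
}

#' Generate a labeled synthetic actives/decoys benchmark
#'
#' Seeds the RNG from \code{params$seed}, generates \code{n_actives}
#' active-like and \code{n_decoys} decoy-like feature sets and records the
#' full generation provenance; regeneration from the same parameters is
#' bit-identical.
#'
#' @param model a \code{\link{pharmacophore}}.
#' @param params a \code{\link{generator_params}}.
#' @return An object of class \code{synthetic_benchmark}: list with
#'   \code{feature_sets} (named list), \code{labels} (data.frame
#'   \code{molecule_id}, \code{label}) and \code{params}.
#' @export
make_benchmark <- function(model, params = generator_params()) {
  validate_pharmacophore(model)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)

  modes <- c("type_scramble", "geometry_inflate", "feature_deficit")
  fsets <- list()
  labels <- list()
  for (i in seq_len(params$n_actives)) {
    id <- sprintf("active_%03d", i)
    fsets[[id]] <- synth_active(model, params, id)
    labels[[id]] <- "active"
  }
  for (i in seq_len(params$n_decoys)) {
    id <- sprintf("decoy_%03d", i)
    mode <- if (params$decoy_mode == "mixed")
      modes[((i - 1L) %% 3L) + 1L] else params$decoy_mode
    fsets[[id]] <- synth_decoy(model, params, id, mode)
    labels[[id]] <- "decoy"
  }
  structure(list(
    feature_sets = fsets,
    labels = data.frame(molecule_id = names(labels),
                        label = unname(unlist(labels)),
                        stringsAsFactors = FALSE),
    params = params), class = "synthetic_benchmark")
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat(sprintf("<synthetic_benchmark> %d actives + %d decoys (seed %d, jitter %.2f A, dropout %.2f, decoys %s)\n",
              x$params$n_actives, x$params$n_decoys, x$params$seed,
              x$params$jitter_sd, x$params$dropout_prob, x$params$decoy_mode))
  invisible(x)
}

#' Write / read feature sets as JSON lines
#'
#' One JSON object per line: \code{\{molecule_id, conformer, features:
#' [\{kinds, xyz, atoms\}]\}}.
#'
#' @param fsets list of \code{\link{feature_set}} objects.
#' @param path file path.
#' @export
write_feature_sets <- function(fsets, path) {
  lines <- vapply(fsets, function(fs) {
    jsonlite::toJSON(list(molecule_id = fs$molecule_id,
                          conformer = fs$conformer,
                          features = lapply(fs$features, function(f)
                            list(kinds = as.list(f$kinds),
                                 xyz = f$xyz,
                                 atoms = as.list(f$atoms)))),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_feature_sets
#' @export
read_feature_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    feature_set(obj$molecule_id, obj$conformer,
                lapply(obj$features, function(f)
                  list(kinds = unlist(f$kinds),
                       xyz = as.numeric(unlist(f$xyz)),
                       atoms = as.integer(unlist(f$atoms)))))
  })
}
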