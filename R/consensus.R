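#' Consensus model parameters
#'
#' @param threshold fraction of ligands a consensus feature must appear in
#'   (strictly more than \code{threshold * M} distinct ligands).
#' @param tolerance clustering radius in \enc{Å}{A} (complete linkage: a
#'   feature joins a cluster only when within \code{tolerance} of every
#'   member).
#' @param essential_threshold support fraction at or above which a feature
#'   is flagged essential.
#' @param radius_floor minimum feature radius (\enc{Å}{A}) assigned to a
#'   consensus feature; prevents zero-radius features from degenerate
#'   clusters.
#' @return An object of class \code{consensus_params}.
#' @export
consensus_params <- function(threshold = 0.5, tolerance = 1.15,
                             essential_threshold = 0.9, radius_floor = 0.4) {
  stopifnot(threshold > 0, threshold <= 1, tolerance > 0,
            essential_threshold >= threshold, radius_floor >= 0)
  structure(list(threshold = threshold, tolerance = tolerance,
                 essential_threshold = essential_threshold,
                 radius_floor = radius_floor),
            class = "consensus_params")
}

#' Derive a consensus pharmacophore from an aligned ligand ensemble
#'
#' All perceived features of all ligands (assumed to share one coordinate
#' frame) are clustered greedily with complete linkage in deterministic
#' order (ligand index, then feature index); a candidate joins the first
#' cluster whose every member lies within \code{tolerance} and whose
#' running kind-intersection it overlaps. Clusters supported by strictly
#' more than \code{threshold * M} distinct ligands become model features:
#' center = mean position, expression = OR over the kind-intersection,
#' radius = max(largest deviation from center, \code{radius_floor}),
#' essential iff support \eqn{\ge} \code{essential_threshold * M}. The
#' model's \code{min_match} is the number of essential features (at least
#' 1).
#'
#' @param ensemble a list of at least two \code{\link{feature_set}} objects
#'   in a common frame.
#' @param params a \code{\link{consensus_params}}.
#' @param name name for the resulting model.
#' @return A \code{\link{pharmacophore}}; feature ids are \code{F1},
#'   \code{F2}, ... in order of decreasing support (first-seen order breaks
#'   ties). The support fractions are attached as attribute
#'   \code{"support"}.
#' @export
consensus_model <- function(ensemble, params = consensus_params(),
                            name = "consensus") {
  stopifnot(is.list(ensemble), length(ensemble) >= 2L,
            all(vapply(ensemble, inherits, logical(1), "feature_set")))
  M <- length(ensemble)

  clusters <- list()  # each: members (positions), kinds, ligands
  for (li in seq_along(ensemble)) {
    for (f in ensemble[[li]]$features) {
      placed <- FALSE
      for (ci in seq_along(clusters)) {
        cl <- clusters[[ci]]
        if (!length(intersect(cl$kinds, f$kinds))) next
        dists <- sqrt(colSums((t(cl$pos) - f$xyz)^2))
        if (all(dists <= params$tolerance)) {
          cl$pos <- rbind(cl$pos, f$xyz)
          cl$kinds <- intersect(cl$kinds, f$kinds)
          cl$ligands <- c(cl$ligands, li)
          clusters[[ci]] <- cl
          placed <- TRUE
          break
        }
      }
      if (!placed)
        clusters[[length(clusters) + 1L]] <-
          list(pos = matrix(f$xyz, 1L, 3L), kinds = f$kinds, ligands = li)
    }
  }

  support <- vapply(clusters, function(cl) length(unique(cl$ligands)), integer(1))
  keep <- which(support > params$threshold * M)
  if (!length(keep))
    stop("consensus failed: no feature cluster exceeds the ", params$threshold * 100,
         "% support threshold", call. = FALSE)
  keep <- keep[order(-support[keep], keep)]

  rows <- lapply(seq_along(keep), function(k) {
    cl <- clusters[[keep[k]]]
    center <- colMeans(cl$pos)
    devs <- sqrt(colSums((t(cl$pos) - center)^2))
    kinds <- FEATURE_KINDS[FEATURE_KINDS %in% cl$kinds]
    data.frame(id = paste0("F", k),
               expr = paste(kinds, collapse = "|"),
               x = center[1], y = center[2], z = center[3],
               radius = max(max(devs), params$radius_floor),
               essential = support[keep[k]] >= params$essential_threshold * M,
               stringsAsFactors = FALSE)
  })
  feats <- do.call(rbind, rows)
  model <- pharmacophore(feats, min_match = max(1L, sum(feats$essential)),
                         name = name)
  attr(model, "support") <- stats::setNames(support[keep] / M, feats$id)
  model
}
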