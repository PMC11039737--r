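#' Matching parameters
#'
#' @param min_match minimum number of model features a hit must satisfy;
#'   defaults to the model's own \code{min_match} when \code{NULL}.
#' @param radius_scale dimensionless multiplier applied to every feature
#'   tolerance radius.
#' @param pair_slack extra slack (\enc{Å}{A}) allowed in the pairwise
#'   distance pruning of candidate correspondences.
#' @param max_correspondences safety cap on the number of enumerated
#'   correspondences per conformer.
#' @return An object of class \code{match_params}.
#' @export
match_params <- function(min_match = NULL, radius_scale = 1.0, pair_slack = 1.0,
                         max_correspondences = 20000L) {
  stopifnot(is.null(min_match) || min_match >= 1L,
            radius_scale > 0, pair_slack >= 0)
  structure(list(min_match = min_match, radius_scale = radius_scale,
                 pair_slack = pair_slack,
                 max_correspondences = as.integer(max_correspondences)),
            class = "match_params")
}

## Type-compatibility matrix: model features x perceived features.
compat_matrix <- function(fs, model) {
  nm <- length(model$features); np <- length(fs$features)
  C <- matrix(FALSE, nm, np)
  for (i in seq_len(nm))
    for (j in seq_len(np))
      C[i, j] <- expr_satisfied(model$features[[i]]$expr, fs$features[[j]]$kinds)
  C
}

#' Enumerate candidate correspondences
#'
#' Finds every injective, type-compatible map from model features to
#' perceived features of size at least \code{min_match} that includes every
#' essential feature and survives pairwise-distance pruning: for each mapped
#' pair of model features (i, j), the perceived inter-feature distance may
#' deviate from the model inter-center distance by at most
#' \code{radius_scale * (r_i + r_j) + pair_slack}. Larger correspondences
#' are returned first.
#'
#' @param fs a \code{\link{feature_set}}.
#' @param model a \code{\link{pharmacophore}}.
#' @param params a \code{\link{match_params}}.
#' @return A list of named integer vectors (model feature id ->
#'   perceived-feature index).
#' @export
enumerate_correspondences <- function(fs, model, params = match_params()) {
  validate_pharmacophore(model)
  nm <- length(model$features)
  np <- length(fs$features)
  min_match <- if (is.null(params$min_match)) model$min_match else
    as.integer(params$min_match)
  essential <- vapply(model$features, `[[`, logical(1), "essential")
  if (np == 0L) return(list())

  C <- compat_matrix(fs, model)
  centers <- feature_centers(model)
  radii <- feature_radii(model)
  pos <- fs_positions(fs)
  dmodel <- as.matrix(stats::dist(centers))
  dperc <- as.matrix(stats::dist(pos))
  ## tolerated |d_perceived - d_model| per model feature pair
  dtol <- outer(radii, radii, `+`) * params$radius_scale + params$pair_slack

  results <- list()
  assign_vec <- rep(NA_integer_, nm)
  used <- rep(FALSE, np)
  capped <- FALSE

  recurse <- function(i, n_assigned) {
    if (capped) return()
    if (i > nm) {
      if (n_assigned >= min_match) {
        results[[length(results) + 1L]] <<- assign_vec
        if (length(results) >= params$max_correspondences) capped <<- TRUE
      }
      return()
    }
    remaining <- nm - i + 1L
    ## try each compatible unused perceived feature
    for (j in which(C[i, ] & !used)) {
      ok <- TRUE
      for (k in seq_len(i - 1L)) {
        if (!is.na(assign_vec[k]) &&
            abs(dperc[assign_vec[k], j] - dmodel[k, i]) > dtol[k, i]) {
          ok <- FALSE; break
        }
      }
      if (ok) {
        assign_vec[i] <<- j; used[j] <<- TRUE
        recurse(i + 1L, n_assigned + 1L)
        assign_vec[i] <<- NA_integer_; used[j] <<- FALSE
      }
    }
    ## or skip a non-essential feature if min_match stays reachable
    if (!essential[i] && n_assigned + remaining - 1L >= min_match)
      recurse(i + 1L, n_assigned)
  }
  recurse(1L, 0L)
  if (capped)
    warning("correspondence enumeration capped at ", params$max_correspondences,
            call. = FALSE)

  ids <- vapply(model$features, `[[`, character(1), "id")
  out <- lapply(results, function(v) {
    keep <- !is.na(v)
    stats::setNames(v[keep], ids[keep])
  })
  sizes <- vapply(out, length, integer(1))
  out[order(-sizes)]
}

#' Best pharmacophore match of a molecule
#'
#' Searches all conformers and all surviving correspondences; a
#' correspondence is accepted when a proper rigid transform places every
#' matched perceived feature inside \code{radius_scale} times its model
#' feature's tolerance radius (least-squares superposition, refined by a
#' tolerance-weighted fit and a minimax polish when the plain fit narrowly
#' fails). Among accepted correspondences the one with the highest number
#' of matched features wins, ties broken by lowest RMSD, then lowest
#' conformer index.
#'
#' @param fsets a \code{\link{feature_set}} or a list of them (one per
#'   conformer of the same molecule).
#' @param model a \code{\link{pharmacophore}}.
#' @param params a \code{\link{match_params}}.
#' @return An object of class \code{match_result}, or \code{NULL} when the
#'   molecule does not fit the model.
#' @export
best_match <- function(fsets, model, params = match_params()) {
  if (inherits(fsets, "feature_set")) fsets <- list(fsets)
  centers <- feature_centers(model)
  radii <- feature_radii(model)
  best <- NULL
  for (fs in fsets) {
    corrs <- enumerate_correspondences(fs, model, params)
    if (!length(corrs)) next
    pos <- fs_positions(fs)
    sizes <- vapply(corrs, length, integer(1))
    for (s in sort(unique(sizes), decreasing = TRUE)) {
      if (!is.null(best) && best$n_matched > s) break
      for (corr in corrs[sizes == s]) {
        fit <- fit_within_radii(pos[corr, , drop = FALSE],
                                centers[names(corr), , drop = FALSE],
                                params$radius_scale * radii[names(corr)])
        if (!fit$accepted) next
        cand <- structure(list(
          molecule_id = fs$molecule_id,
          conformer = fs$conformer,
          correspondence = corr,
          n_matched = s,
          fitting = sprintf("%d/%d", s, length(model$features)),
          residuals = stats::setNames(fit$residuals, names(corr)),
          rmsd = fit$rmsd,
          rotation = fit$rotation,
          translation = fit$translation), class = "match_result")
        stopifnot(all(cand$residuals <=
                        params$radius_scale * radii[names(corr)] + 1e-9))
        if (is.null(best) ||
            cand$n_matched > best$n_matched ||
            (cand$n_matched == best$n_matched && cand$rmsd < best$rmsd - 1e-12))
          best <- cand
      }
      if (!is.null(best) && best$n_matched == s) break  # smaller sizes can't win here
    }
  }
  best
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %s: fitting %s, RMSD %.3f A (conformer %d)\n",
              x$molecule_id, x$fitting, x$rmsd, x$conformer))
  cat("  matched:", paste(sprintf("%s->%d (%.2f A)", names(x$correspondence),
                                  x$correspondence, x$residuals),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Screen a collection of feature sets
#'
#' @param fsets a list whose elements are either single
#'   \code{\link{feature_set}} objects or lists of conformer feature sets of
#'   one molecule.
#' @param model a \code{\link{pharmacophore}}.
#' @param params a \code{\link{match_params}}.
#' @return A screening table: data.frame with columns \code{molecule_id},
#'   \code{hit}, \code{n_matched}, \code{fitting}, \code{rmsd_A},
#'   \code{conformer}, \code{error}, ordered by (hit desc, n_matched desc,
#'   RMSD asc, id).
#' @export
screen_features <- function(fsets, model, params = match_params()) {
  rows <- lapply(fsets, function(fs) {
    id <- if (inherits(fs, "feature_set")) fs$molecule_id else fs[[1L]]$molecule_id
    tryCatch({
      m <- best_match(fs, model, params)
      if (is.null(m)) {
        data.frame(molecule_id = id, hit = FALSE, n_matched = 0L,
                   fitting = sprintf("0/%d", length(model$features)),
                   rmsd_A = NA_real_, conformer = NA_integer_, error = FALSE,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(molecule_id = id, hit = TRUE, n_matched = m$n_matched,
                   fitting = m$fitting, rmsd_A = m$rmsd,
                   conformer = m$conformer, error = FALSE,
                   stringsAsFactors = FALSE)
      }
    }, error = function(e) {
      data.frame(molecule_id = id, hit = FALSE, n_matched = 0L,
                 fitting = NA_character_, rmsd_A = NA_real_,
                 conformer = NA_integer_, error = TRUE,
                 stringsAsFactors = FALSE)
    })
  })
  if (!length(rows)) {
    return(data.frame(molecule_id = character(), hit = logical(),
                      n_matched = integer(), fitting = character(),
                      rmsd_A = numeric(), conformer = integer(),
                      error = logical(), stringsAsFactors = FALSE))
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tab[order(-tab$hit, -tab$n_matched, tab$rmsd_A, tab$molecule_id,
            na.last = TRUE), , drop = FALSE]
}

#' Screen a molecule library against a pharmacophore model
#'
#' Perceives features on every conformer of every molecule and reports the
#' best match per molecule. Unparseable records are flagged in the
#' \code{error} column and screening continues.
#'
#' @param library a list of \code{\link{molecule3d}} objects (e.g. from
#'   \code{\link{read_sdf}}).
#' @param model a \code{\link{pharmacophore}}.
#' @param params a \code{\link{match_params}}.
#' @param rules perception rules (see \code{\link{default_rules}}).
#' @return A screening table (see \code{\link{screen_features}}).
#' @export
screen_library <- function(library, model, params = match_params(),
                           rules = default_rules()) {
  fsets <- lapply(library, function(mol) {
    if (inherits(mol, "molecule3d_error"))
      return(structure(list(molecule_id = mol$id), class = "perception_failure"))
    tryCatch(lapply(seq_along(mol$conformers), function(k)
      perceive(mol, k, rules)),
      error = function(e) structure(list(molecule_id = mol$id),
                                    class = "perception_failure"))
  })
  ok <- !vapply(fsets, inherits, logical(1), "perception_failure")
  tab <- screen_features(fsets[ok], model, params)
  if (any(!ok)) {
    bad_ids <- vapply(fsets[!ok], `[[`, character(1), "molecule_id")
    err_rows <- data.frame(molecule_id = bad_ids, hit = FALSE, n_matched = 0L,
                           fitting = NA_character_, rmsd_A = NA_real_,
                           conformer = NA_integer_, error = TRUE,
                           stringsAsFactors = FALSE)
    tab <- rbind(tab, err_rows)
  }
  tab
}

#' Write / read a screening table as TSV
#'
#' @param table a screening table.
#' @param path output path.
#' @param provenance optional named character vector written as
#'   \code{# key: value} header lines.
#' @export
write_screening_tsv <- function(table, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_screening_tsv
#' @export
read_screening_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
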