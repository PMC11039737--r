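#' Construct a pharmacophore model
#'
#' A pharmacophore model is an ordered set of typed features, each with a 3D
#' centroid (\enc{Å}{Angstrom}), a spherical tolerance radius and an
#' essential flag, plus a partial-match threshold \code{min_match}: a hit
#' must satisfy at least \code{min_match} features \emph{and} every
#' essential feature.
#'
#' @param features a data.frame with columns \code{id} (unique labels),
#'   \code{expr} (feature-type expression strings, see
#'   \code{\link{parse_type_expr}}), \code{x}, \code{y}, \code{z}
#'   (\enc{Å}{A}), \code{radius} (\enc{Å}{A}, > 0) and \code{essential}
#'   (logical).
#' @param min_match integer, number of features a hit must satisfy.
#' @param name optional model name.
#' @return An object of class \code{pharmacophore}.
#' @seealso \code{\link{builtin_dual_model}}, \code{\link{geometry_report}}
#' @export
pharmacophore <- function(features, min_match = nrow(features), name = "pharmacophore") {
  stopifnot(is.data.frame(features))
  needed <- c("id", "expr", "x", "y", "z", "radius", "essential")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols))
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  feats <- lapply(seq_len(nrow(features)), function(i) {
    row <- features[i, ]
    list(id = as.character(row$id),
         expr = parse_type_expr(as.character(row$expr)),
         center = c(row$x, row$y, row$z),
         radius = as.numeric(row$radius),
         essential = isTRUE(as.logical(row$essential)))
  })
  model <- structure(list(name = name, min_match = as.integer(min_match),
                          features = feats),
                     class = "pharmacophore")
  validate_pharmacophore(model)
  model
}

validate_pharmacophore <- function(model) {
  problems <- character()
  ids <- vapply(model$features, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    problems <- c(problems, paste0("duplicate feature ids: ",
                                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  for (f in model$features) {
    if (!is.numeric(f$radius) || length(f$radius) != 1L || is.na(f$radius) || f$radius <= 0)
      problems <- c(problems, paste0(f$id, ": radius must be a positive number"))
    if (length(f$center) != 3L || !all(is.finite(f$center)))
      problems <- c(problems, paste0(f$id, ": center must be a finite 3-vector"))
  }
  n <- length(model$features)
  n_ess <- sum(vapply(model$features, `[[`, logical(1), "essential"))
  if (is.na(model$min_match) || model$min_match < 1L || model$min_match > n)
    problems <- c(problems, sprintf("min_match must be in [1, %d]", n))
  else if (n_ess > model$min_match)
    problems <- c(problems, sprintf("essential feature count (%d) exceeds min_match (%d)",
                                    n_ess, model$min_match))
  if (length(problems))
    stop("invalid pharmacophore model:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  invisible(model)
}

#' The built-in dual hIDO1/hTDO2 inhibitor pharmacophore model
#'
#' Five features derived from a consensus over aligned dual
#' tryptophan-dioxygenase inhibitors: three aromatic/hydrophobic centers
#' (F1, F2, F3), one H-bond donor/acceptor or metal-ligator point (F4,
#' non-essential) and one tight metal-ligator point that is also an H-bond
#' partner (F5, radius 0.4 \enc{Å}{A}, pointing at the heme iron). A hit
#' must match at least four features including every essential one
#' (F1, F2, F3, F5), i.e. only F4 may be dropped.
#'
#' @return A \code{\link{pharmacophore}} object with 5 features and
#'   \code{min_match = 4}.
#' @examples
#' m <- builtin_dual_model()
#' feature_distance(m, "F1", "F3")
#' @export
builtin_dual_model <- function() {
  pharmacophore(
    data.frame(
      id = c("F1", "F2", "F3", "F4", "F5"),
      expr = c("Aro|Hyd", "Aro|Hyd", "Aro|Hyd", "ML|Acc|Don", "ML&(Acc|Don)"),
      x = c(0.6502, -4.1278, -0.6952, -0.6360, -0.9913),
      y = c(2.0583, -0.8281, -2.0007, 1.2624, -2.8787),
      z = c(2.4823, -1.5894, 0.1855, -0.8650, 0.6632),
      radius = c(1.5, 1.5, 0.7, 1.3, 0.4),
      essential = c(TRUE, TRUE, TRUE, FALSE, TRUE),
      stringsAsFactors = FALSE
    ),
    min_match = 4L,
    name = "dual-IDO1/TDO2"
  )
}

feature_index <- function(model, id) {
  ids <- vapply(model$features, `[[`, character(1), "id")
  i <- match(id, ids)
  if (is.na(i)) stop("unknown feature id: ", id, call. = FALSE)
  i
}

feature_centers <- function(model) {
  m <- t(vapply(model$features, `[[`, numeric(3), "center"))
  rownames(m) <- vapply(model$features, `[[`, character(1), "id")
  colnames(m) <- c("x", "y", "z")
  m
}

feature_radii <- function(model) {
  r <- vapply(model$features, `[[`, numeric(1), "radius")
  names(r) <- vapply(model$features, `[[`, character(1), "id")
  r
}

#' Distance between two feature centroids
#'
#' @param model a \code{\link{pharmacophore}}.
#' @param a,b feature ids.
#' @return Euclidean distance in \enc{Å}{A}.
#' @export
feature_distance <- function(model, a, b) {
  ca <- model$features[[feature_index(model, a)]]$center
  cb <- model$features[[feature_index(model, b)]]$center
  sqrt(sum((ca - cb)^2))
}

#' Angle at a feature centroid
#'
#' The angle at \code{apex} between the direction vectors towards features
#' \code{a} and \code{b}, in degrees within [0, 180].
#'
#' @param model a \code{\link{pharmacophore}}.
#' @param apex,a,b three distinct feature ids.
#' @return Angle in degrees.
#' @export
feature_angle <- function(model, apex, a, b) {
  if (length(unique(c(apex, a, b))) != 3L)
    stop("apex, a and b must be three distinct feature ids", call. = FALSE)
  p0 <- model$features[[feature_index(model, apex)]]$center
  u <- model$features[[feature_index(model, a)]]$center - p0
  v <- model$features[[feature_index(model, b)]]$center - p0
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12)
    stop("degenerate geometry: coincident feature centers", call. = FALSE)
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Inter-feature geometry report
#'
#' Computes the canonical set of inter-feature relations describing a model
#' in 3D: for the built-in dual model these are the five distances
#' F1--F3, F1--F4, F2--F4, F2--F5, F3--F5 and the five apex angles
#' F3--F1--F4, F4--F2--F5, F1--F3--F5, F1--F4--F2 and F2--F5--F3. For other
#' models, all pairwise distances and, for models with at least 3 features,
#' the angle at each feature between its two nearest neighbours.
#'
#' @param model a \code{\link{pharmacophore}}.
#' @return A data.frame with columns \code{kind} ("distance"/"angle"),
#'   \code{apex} (NA for distances), \code{a}, \code{b} and \code{value}
#'   (\enc{Å}{A} or degrees, full precision).
#' @export
geometry_report <- function(model) {
  validate_pharmacophore(model)
  ids <- vapply(model$features, `[[`, character(1), "id")
  if (identical(ids, c("F1", "F2", "F3", "F4", "F5"))) {
    dist_pairs <- list(c("F1","F3"), c("F1","F4"), c("F2","F4"), c("F2","F5"), c("F3","F5"))
    angle_triples <- list(c("F1","F3","F4"), c("F2","F4","F5"), c("F3","F1","F5"),
                          c("F4","F1","F2"), c("F5","F2","F3"))
  } else {
    dist_pairs <- if (length(ids) >= 2) utils::combn(ids, 2, simplify = FALSE) else list()
    angle_triples <- list()
    if (length(ids) >= 3) {
      cm <- feature_centers(model)
      for (ap in ids) {
        others <- setdiff(ids, ap)
        d <- vapply(others, function(o) sqrt(sum((cm[ap, ] - cm[o, ])^2)), numeric(1))
        nb <- others[order(d)][1:2]
        angle_triples[[length(angle_triples) + 1L]] <- c(ap, nb)
      }
    }
  }
  rows <- list()
  for (p in dist_pairs)
    rows[[length(rows) + 1L]] <- data.frame(kind = "distance", apex = NA_character_,
                                            a = p[1], b = p[2],
                                            value = feature_distance(model, p[1], p[2]),
                                            stringsAsFactors = FALSE)
  for (tr in angle_triples)
    rows[[length(rows) + 1L]] <- data.frame(kind = "angle", apex = tr[1],
                                            a = tr[2], b = tr[3],
                                            value = feature_angle(model, tr[1], tr[2], tr[3]),
                                            stringsAsFactors = FALSE)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.pharmacophore <- function(x, ...) {
  cat(sprintf("Pharmacophore model '%s': %d features, min_match = %d\n",
              x$name, length(x$features), x$min_match))
  df <- as.data.frame(x)
  df$radius <- sprintf("%.2f", df$radius)
  df[c("x", "y", "z")] <- lapply(df[c("x", "y", "z")], function(v) sprintf("%.4f", v))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.pharmacophore <- function(x, ...) {
  data.frame(
    id = vapply(x$features, `[[`, character(1), "id"),
    expr = vapply(x$features, function(f) format(f$expr), character(1)),
    x = vapply(x$features, function(f) f$center[1], numeric(1)),
    y = vapply(x$features, function(f) f$center[2], numeric(1)),
    z = vapply(x$features, function(f) f$center[3], numeric(1)),
    radius = vapply(x$features, `[[`, numeric(1), "radius"),
    essential = vapply(x$features, `[[`, logical(1), "essential"),
    stringsAsFactors = FALSE
  )
}

#' Read / write a pharmacophore model file
#'
#' Models are stored as JSON with top-level keys \code{format_version} (1),
#' \code{name}, \code{min_match} and \code{features}, the latter a list of
#' \code{\{id, expr, center, radius, essential\}} records. A feature record
#' without an \code{essential} field defaults to essential with a warning.
#'
#' @param path file path.
#' @return \code{read_pharmacophore} returns a \code{\link{pharmacophore}};
#'   \code{write_pharmacophore} returns \code{path} invisibly.
#' @export
read_pharmacophore <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  problems <- character()
  for (key in c("min_match", "features"))
    if (is.null(obj[[key]])) problems <- c(problems, paste0("missing key: ", key))
  if (length(problems))
    stop("invalid model file:\n  - ", paste(problems, collapse = "\n  - "), call. = FALSE)
  rows <- lapply(seq_along(obj$features), function(i) {
    f <- obj$features[[i]]
    for (key in c("id", "expr", "center", "radius"))
      if (is.null(f[[key]]))
        problems <<- c(problems, sprintf("feature %d: missing key %s", i, key))
    if (length(problems)) return(NULL)
    ess <- f$essential
    if (is.null(ess)) {
      warning(sprintf("feature %s: no 'essential' field; defaulting to TRUE", f$id),
              call. = FALSE)
      ess <- TRUE
    }
    data.frame(id = f$id, expr = f$expr,
               x = f$center[[1]], y = f$center[[2]], z = f$center[[3]],
               radius = f$radius, essential = ess, stringsAsFactors = FALSE)
  })
  if (length(problems))
    stop("invalid model file:\n  - ", paste(problems, collapse = "\n  - "), call. = FALSE)
  pharmacophore(do.call(rbind, rows), min_match = obj$min_match,
                name = if (is.null(obj$name)) "pharmacophore" else obj$name)
}

#' @rdname read_pharmacophore
#' @param model a \code{\link{pharmacophore}}.
#' @export
write_pharmacophore <- function(model, path) {
  validate_pharmacophore(model)
  obj <- list(
    format_version = 1L,
    name = model$name,
    min_match = model$min_match,
    features = lapply(model$features, function(f)
      list(id = f$id, expr = format(f$expr), center = f$center,
           radius = f$radius, essential = f$essential))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
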