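#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rigid transform (rotation with determinant +1 plus
#' translation) minimizing the (optionally weighted) sum of squared
#' distances between transformed source points and target points.
#' Reflections are never returned: pharmacophore geometry is chiral.
#'
#' @param source n-by-3 matrix of moving points (e.g. perceived features).
#' @param target n-by-3 matrix of reference points (e.g. model centers).
#' @param weights optional positive weights, one per pair.
#' @return A list with \code{rotation} (3x3), \code{translation} (length 3),
#'   \code{transformed} (n-by-3), \code{residuals} (per-pair distances,
#'   \enc{Å}{A}) and \code{rmsd} (unweighted root-mean-square residual).
#' @examples
#' m <- feature_centers(builtin_dual_model())
#' superpose(m, m)$rmsd  # 0
#' @export
superpose <- function(source, target, weights = NULL) {
  source <- as.matrix(source); target <- as.matrix(target)
  n <- nrow(source)
  if (n < 1L || nrow(target) != n)
    stop("superpose needs at least one pair and equal point counts", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  w <- weights / sum(weights)

  cs <- colSums(source * w)
  ct <- colSums(target * w)
  S <- sweep(source, 2, cs)
  T_ <- sweep(target, 2, ct)
  H <- t(S * w) %*% T_
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- ct - as.vector(R %*% cs)
  transformed <- sweep(source %*% t(R), 2, trans, `+`)
  res <- sqrt(rowSums((transformed - target)^2))
  list(rotation = R, translation = trans, transformed = transformed,
       residuals = res, rmsd = sqrt(mean(res^2)))
}

## Rodrigues rotation from an axis-angle vector.
rotation_from_axis_angle <- function(w) {
  theta <- sqrt(sum(w^2))
  if (theta < 1e-12) return(diag(3))
  k <- w / theta
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

## Tolerance-sphere feasibility: is there a proper rigid transform placing
## every source point within its tolerance radius of its target point?
## Certificates tried in order: unweighted least squares, tolerance-weighted
## least squares (w = 1/r^2), then a minimax polish of max(residual/radius)
## started from the weighted fit. Returns the accepting transform (or the
## best transform found, with accepted = FALSE).
fit_within_radii <- function(source, target, radii, polish_maxit = 400L) {
  stopifnot(length(radii) == nrow(source))
  fit <- superpose(source, target)
  if (all(fit$residuals <= radii + 1e-9))
    return(c(fit, list(accepted = TRUE)))
  fit_w <- superpose(source, target, weights = 1 / radii^2)
  if (all(fit_w$residuals <= radii + 1e-9))
    return(c(fit_w, list(accepted = TRUE)))
  if (max(fit_w$residuals / radii) > 4)  # hopeless; skip the polish
    return(c(fit_w, list(accepted = FALSE)))

  base <- fit_w$transformed
  objective <- function(par) {
    R <- rotation_from_axis_angle(par[1:3])
    moved <- sweep(base %*% t(R), 2, par[4:6], `+`)
    max(sqrt(rowSums((moved - target)^2)) / radii)
  }
  opt <- stats::optim(rep(0, 6), objective,
                      control = list(maxit = polish_maxit, reltol = 1e-10))
  Rc <- rotation_from_axis_angle(opt$par[1:3])
  R <- Rc %*% fit_w$rotation
  trans <- as.vector(Rc %*% fit_w$translation) + opt$par[4:6]
  transformed <- sweep(source %*% t(R), 2, trans, `+`)
  res <- sqrt(rowSums((transformed - target)^2))
  list(rotation = R, translation = trans, transformed = transformed,
       residuals = res, rmsd = sqrt(mean(res^2)),
       accepted = all(res <= radii + 1e-9))
}
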