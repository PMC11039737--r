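# Independent oracles used to cross-check the package's core algorithms.
# These deliberately use naive exhaustive or numeric-optimization approaches
# and share no code with the implementation paths they verify.

# All k-permutations of the integers in `pool`.
k_permutations <- function(pool, k) {
  if (k == 0L) return(list(integer()))
  out <- list()
  for (i in seq_along(pool)) {
    for (rest in k_permutations(pool[-i], k - 1L))
      out[[length(out) + 1L]] <- c(pool[i], rest)
  }
  out
}

# Naive enumeration of every injective, type-compatible, essential-complete,
# pairwise-pruned correspondence of size >= min_match.
brute_force_correspondences <- function(fs, model, params = match_params()) {
  nm <- length(model$features)
  np <- length(fs$features)
  min_match <- if (is.null(params$min_match)) model$min_match else params$min_match
  ids <- vapply(model$features, `[[`, character(1), "id")
  essential <- vapply(model$features, `[[`, logical(1), "essential")
  centers <- feature_centers(model)
  radii <- feature_radii(model)
  pos <- if (np) t(vapply(fs$features, `[[`, numeric(3), "xyz")) else matrix(0, 0, 3)

  out <- list()
  if (np == 0L) return(out)
  for (size in seq(from = min_match, to = min(nm, np))) {
    for (subset in utils::combn(nm, size, simplify = FALSE)) {
      if (!all(which(essential) %in% subset)) next
      for (perm in k_permutations(seq_len(np), size)) {
        ok <- TRUE
        for (a in seq_len(size)) {
          i <- subset[a]; j <- perm[a]
          if (!expr_satisfied(model$features[[i]]$expr, fs$features[[j]]$kinds)) {
            ok <- FALSE; break
          }
        }
        if (!ok) next
        for (a in seq_len(size - 1L)) {
          for (b in seq((a + 1L), size)) {
            dm <- sqrt(sum((centers[subset[a], ] - centers[subset[b], ])^2))
            dp <- sqrt(sum((pos[perm[a], ] - pos[perm[b], ])^2))
            tol <- params$radius_scale * (radii[subset[a]] + radii[subset[b]]) +
              params$pair_slack
            if (abs(dp - dm) > tol) { ok <- FALSE; break }
          }
          if (!ok) break
        }
        if (ok)
          out[[length(out) + 1L]] <- stats::setNames(perm, ids[subset])
      }
    }
  }
  out
}

corr_key <- function(corr) {
  o <- order(names(corr))
  paste(names(corr)[o], corr[o], sep = "=", collapse = ";")
}

# Numeric-minimization RMSD oracle: direct optimization of the sum of
# squared distances over axis-angle rotation + translation, multi-start.
rmsd_oracle <- function(source, target) {
  obj <- function(par) {
    theta <- sqrt(sum(par[1:3]^2))
    R <- if (theta < 1e-12) diag(3) else {
      k <- par[1:3] / theta
      K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
                  3, 3, byrow = TRUE)
      diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
    }
    moved <- sweep(source %*% t(R), 2, par[4:6], `+`)
    sum((moved - target)^2)
  }
  best <- Inf
  set.seed(99)
  for (start in 1:8) {
    par0 <- c(stats::runif(3, -pi, pi), colMeans(target) - colMeans(source))
    opt <- stats::optim(par0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, opt$value)
  }
  sqrt(best / nrow(source))
}

# A feature set sitting exactly on the model's centers with compatible
# minimal kinds, in model feature order.
exact_feature_set <- function(model, id = "exact",
                              kinds = list(c("Aro"), c("Hyd"), c("Aro"),
                                           c("Acc"), c("ML", "Don"))) {
  feats <- lapply(seq_along(model$features), function(i)
    list(kinds = kinds[[i]], xyz = model$features[[i]]$center,
         atoms = integer()))
  feature_set(id, 1L, feats)
}

# Random rotation matrix (det +1) from the test RNG.
test_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

rigidly_move <- function(fs, R, t_) {
  fs$features <- lapply(fs$features, function(f) {
    f$xyz <- as.vector(R %*% f$xyz) + t_
    f
  })
  fs
}

# Aligned ensemble of jittered copies of the built-in model's feature sets,
# with the non-essential F4 dropped in `n_drop` of the `n` ligands.
jittered_ensemble <- function(model, n = 12L, sd = 0.2, n_drop = 5L) {
  dropped <- sample(rep(c(TRUE, FALSE), c(n_drop, n - n_drop)))
  lapply(seq_len(n), function(i) {
    feats <- list()
    for (f in model$features) {
      if (!f$essential && dropped[i]) next
      feats[[length(feats) + 1L]] <- list(
        kinds = phorescreen:::expr_leaves(f$expr),
        xyz = f$center + stats::rnorm(3, 0, sd),
        atoms = integer())
    }
    feature_set(paste0("ligand_", i), 1L, feats)
  })
}
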