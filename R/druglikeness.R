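#' Compute a drug-likeness descriptor profile
#'
#' Descriptors are computed from 2D connectivity and are deterministic:
#' molecular weight from atomic masses; H-bond donors as the count of O-H
#' and N-H hydrogens and acceptors as the count of N and O atoms (the
#' conventions of the rule of five); rotatable bonds as acyclic single
#' bonds between two non-terminal heavy atoms, amide C-N bonds excluded;
#' logP (atom-contribution estimate) and topological polar surface area
#' from Open Babel.
#'
#' @param mol a \code{\link{molecule3d}}.
#' @return A one-row data.frame of class \code{descriptor_profile} with
#'   columns \code{molecule_id}, \code{mw}, \code{logp}, \code{hbd},
#'   \code{hba}, \code{rotb}, \code{tpsa}.
#' @export
compute_profile <- function(mol) {
  if (inherits(mol, "molecule3d_error"))
    stop("cannot compute descriptors: ", mol$error, call. = FALSE)
  stopifnot(inherits(mol, "molecule3d"))
  el <- mol$atoms$element
  unknown <- setdiff(unique(el), names(ATOMIC_MASSES))
  if (length(unknown))
    stop("no atomic mass for element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  mw <- sum(ATOMIC_MASSES[el])

  hbd <- sum(vapply(which(el %in% c("N", "O")), function(a)
    length(h_neighbours(mol, a)), integer(1)))
  hba <- sum(el %in% c("N", "O"))

  rotb <- 0L
  ring_atoms <- unique(unlist(mol$rings))
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      if (mol$bonds$order[k] != 1L) next
      if (el[i] == "H" || el[j] == "H") next
      if (i %in% ring_atoms && j %in% ring_atoms &&
          any(vapply(mol$rings, function(r) all(c(i, j) %in% r), logical(1)))) next
      if (length(heavy_neighbours(mol, i)) < 2L ||
          length(heavy_neighbours(mol, j)) < 2L) next
      if (is_amide_bond(mol, i, j)) next
      rotb <- rotb + 1L
    }
  }

  sdf_lines <- strsplit(mol3d_to_sdf_text(mol), "\n", fixed = TRUE)[[1L]]
  sdfset <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(sdf_lines))
  ob <- ChemmineR::propOB(sdfset)
  profile <- data.frame(molecule_id = mol$id, mw = mw,
                        logp = as.numeric(ob[["logP"]]),
                        hbd = hbd, hba = hba, rotb = rotb,
                        tpsa = as.numeric(ob[["TPSA"]]),
                        stringsAsFactors = FALSE)
  class(profile) <- c("descriptor_profile", class(profile))
  profile
}

is_amide_bond <- function(mol, i, j) {
  el <- mol$atoms$element
  pair_is <- function(c_at, n_at) {
    el[c_at] == "C" && el[n_at] == "N" &&
      any(vapply(heavy_neighbours(mol, c_at), function(o)
        el[o] == "O" && bond_order_between(mol, c_at, o) == 2L, logical(1)))
  }
  pair_is(i, j) || pair_is(j, i)
}

#' Lipinski rule-of-five filter
#'
#' Violations are counted against MW \eqn{\le} 500 g/mol, logP \eqn{\le} 5,
#' H-bond donors \eqn{\le} 5 and acceptors \eqn{\le} 10; following the
#' original formulation, a compound passes with at most
#' \code{max_violations} (default 1) violations.
#'
#' @param profile a profile from \code{\link{compute_profile}} (or any list
#'   with \code{mw}, \code{logp}, \code{hbd}, \code{hba}).
#' @param max_violations violations tolerated while still passing.
#' @return A list with \code{pass} (logical) and \code{violations}
#'   (character vector).
#' @export
lipinski_pass <- function(profile, max_violations = 1L) {
  v <- character()
  if (profile$mw > 500) v <- c(v, sprintf("MW %.1f > 500", profile$mw))
  if (profile$logp > 5) v <- c(v, sprintf("logP %.2f > 5", profile$logp))
  if (profile$hbd > 5) v <- c(v, sprintf("HBD %d > 5", profile$hbd))
  if (profile$hba > 10) v <- c(v, sprintf("HBA %d > 10", profile$hba))
  list(pass = length(v) <= max_violations, violations = v)
}

#' Veber oral-bioavailability filter
#'
#' Passes iff rotatable bonds \eqn{\le} 10 and TPSA \eqn{\le} 140
#' \enc{Å}{A}\eqn{^2} (inclusive thresholds).
#'
#' @param profile a profile from \code{\link{compute_profile}}.
#' @return A list with \code{pass} and \code{violations}.
#' @export
veber_pass <- function(profile) {
  v <- character()
  if (profile$rotb > 10) v <- c(v, sprintf("rotatable bonds %d > 10", profile$rotb))
  if (profile$tpsa > 140) v <- c(v, sprintf("TPSA %.1f > 140", profile$tpsa))
  list(pass = length(v) == 0L, violations = v)
}

#' Drug-likeness filtration table
#'
#' Applies \code{\link{lipinski_pass}} and \code{\link{veber_pass}} to a
#' library; a molecule passes the combined filter iff it passes both rules.
#'
#' @param library list of \code{\link{molecule3d}} objects.
#' @param max_violations Lipinski violations tolerated.
#' @return data.frame with columns \code{molecule_id}, \code{mw},
#'   \code{logp}, \code{hbd}, \code{hba}, \code{rotb}, \code{tpsa},
#'   \code{lipinski}, \code{veber}, \code{pass}.
#' @export
druglikeness_table <- function(library, max_violations = 1L) {
  rows <- lapply(library, function(mol) {
    p <- compute_profile(mol)
    lp <- lipinski_pass(p, max_violations)
    vb <- veber_pass(p)
    cbind(as.data.frame(p), data.frame(lipinski = lp$pass, veber = vb$pass,
                                       pass = lp$pass && vb$pass))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
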