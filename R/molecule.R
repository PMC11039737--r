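## Molecule container and structure I/O.
##
## A molecule3d is a light graph-plus-conformers container filled from SDF
## (via ChemmineR) or from SMILES embedded to 3D with Open Babel (via
## ChemmineOB). Rings and a Kekule-based aromaticity assignment are computed
## once at construction; perception rules consume them.

ATOMIC_MASSES <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                   F = 18.998, Na = 22.990, Mg = 24.305, Si = 28.085,
                   P = 30.974, S = 32.06, Cl = 35.45, K = 39.098,
                   Ca = 40.078, Br = 79.904, I = 126.904)

HALOGENS <- c("F", "Cl", "Br", "I")

#' Construct a molecule with one or more 3D conformers
#'
#' @param id molecule identifier.
#' @param atoms data.frame with column \code{element} (and optionally
#'   \code{charge}, defaulting to 0).
#' @param bonds data.frame with columns \code{a1}, \code{a2} (1-based atom
#'   indices) and \code{order} (1, 2 or 3; Kekule convention).
#' @param conformers a single n-by-3 coordinate matrix (\enc{Å}{A}) or a
#'   list of them, one row per atom.
#' @param sdf_text optional raw SDF block kept for descriptor computation.
#' @return An object of class \code{molecule3d}.
#' @export
molecule3d <- function(id, atoms, bonds, conformers, sdf_text = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.matrix(conformers)) conformers <- list(conformers)
  for (cc in conformers) {
    if (!is.matrix(cc) || nrow(cc) != nrow(atoms) || ncol(cc) != 3L)
      stop("each conformer must be an n_atoms-by-3 coordinate matrix", call. = FALSE)
  }
  if (nrow(bonds) > 0L) {
    stopifnot(all(bonds$a1 >= 1L & bonds$a1 <= nrow(atoms)),
              all(bonds$a2 >= 1L & bonds$a2 <= nrow(atoms)))
  }
  mol <- structure(list(id = as.character(id), atoms = atoms, bonds = bonds,
                        conformers = conformers, sdf_text = sdf_text),
                   class = "molecule3d")
  mol$adj <- build_adjacency(mol)
  mol$rings <- find_rings(mol)
  mol$aromatic_rings <- mol$rings[vapply(mol$rings, ring_is_aromatic,
                                         logical(1), mol = mol)]
  mol
}

#' @export
print.molecule3d <- function(x, ...) {
  heavy <- sum(x$atoms$element != "H")
  cat(sprintf("<molecule3d> %s: %d atoms (%d heavy), %d bonds, %d conformer(s), %d ring(s)\n",
              x$id, nrow(x$atoms), heavy, nrow(x$bonds), length(x$conformers),
              length(x$rings)))
  invisible(x)
}

build_adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

bond_order_between <- function(mol, i, j) {
  hit <- (mol$bonds$a1 == i & mol$bonds$a2 == j) | (mol$bonds$a1 == j & mol$bonds$a2 == i)
  if (!any(hit)) return(0L)
  mol$bonds$order[which(hit)[1L]]
}

## Smallest ring through each bond (BFS on the graph minus that bond),
## deduplicated by atom set; rings up to size 8 kept.
find_rings <- function(mol, max_size = 8L) {
  if (nrow(mol$bonds) == 0L) return(list())
  rings <- list()
  seen <- character()
  for (k in seq_len(nrow(mol$bonds))) {
    u <- mol$bonds$a1[k]; v <- mol$bonds$a2[k]
    path <- bfs_path(mol$adj, u, v, skip_edge = c(u, v), max_len = max_size - 1L)
    if (is.null(path)) next
    ring <- path  # path runs u..v; closing bond u-v completes the cycle
    key <- paste(sort(ring), collapse = "-")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- ring
    }
  }
  rings
}

bfs_path <- function(adj, from, to, skip_edge, max_len) {
  n <- length(adj)
  prev <- rep(NA_integer_, n)
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    if (cur == to) break
    if (dist[cur] >= max_len) next
    for (nb in adj[[cur]]) {
      if ((cur == skip_edge[1L] && nb == skip_edge[2L]) ||
          (cur == skip_edge[2L] && nb == skip_edge[1L])) next
      if (is.na(dist[nb])) {
        dist[nb] <- dist[cur] + 1L
        prev[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  if (is.na(dist[to])) return(NULL)
  path <- to
  while (path[1L] != from) path <- c(prev[path[1L]], path)
  path
}

## Hueckel-style aromaticity on Kekule structures: every ring atom must be
## sp2-capable and the pi-electron count must be 4n+2. An atom with an
## in-ring double bond contributes 1, one with only an exocyclic double bond
## contributes 0, a ring N/O/S without a double bond contributes its lone
## pair (2); a carbon without any double bond disqualifies the ring.
ring_is_aromatic <- function(mol, ring) {
  if (!(length(ring) %in% c(5L, 6L))) return(FALSE)
  pi_e <- 0L
  for (a in ring) {
    el <- mol$atoms$element[a]
    nbs <- mol$adj[[a]]
    dbl <- nbs[vapply(nbs, function(b) bond_order_between(mol, a, b) == 2L, logical(1))]
    if (length(dbl) && any(dbl %in% ring)) {
      pi_e <- pi_e + 1L
    } else if (length(dbl)) {
      pi_e <- pi_e + 0L
    } else if (el %in% c("N", "O", "S")) {
      pi_e <- pi_e + 2L
    } else {
      return(FALSE)
    }
  }
  (pi_e - 2L) %% 4L == 0L
}

atom_in_aromatic_ring <- function(mol, a) {
  any(vapply(mol$aromatic_rings, function(r) a %in% r, logical(1)))
}

h_neighbours <- function(mol, a) {
  nbs <- mol$adj[[a]]
  nbs[mol$atoms$element[nbs] == "H"]
}

heavy_neighbours <- function(mol, a) {
  nbs <- mol$adj[[a]]
  nbs[mol$atoms$element[nbs] != "H"]
}

## ---- SDF / SMILES I/O ----------------------------------------------------

chemmine_to_mol3d <- function(sdf, id = NULL, sdf_text = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_\\d+$", "", rownames(ab))
  atoms <- data.frame(element = elements, charge = 0L, stringsAsFactors = FALSE)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) {
    data.frame(a1 = integer(), a2 = integer(), order = integer())
  } else {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  if (is.null(id)) {
    id <- tryCatch(ChemmineR::sdfid(sdf), error = function(e) NULL)
    if (is.null(id) || !nzchar(id)) id <- "molecule"
  }
  molecule3d(id, atoms, bonds, coords, sdf_text = sdf_text)
}

split_sdf_blocks <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) return(list(paste(lines, collapse = "\n")))
  starts <- c(1L, head(ends, -1L) + 1L)
  mapply(function(s, e) paste(lines[s:e], collapse = "\n"), starts, ends,
         SIMPLIFY = FALSE)
}

#' Read molecules from an SDF (V2000) file
#'
#' Coordinates are used as written. When a record carries no explicit
#' hydrogens they are added with Open Babel (heavy-atom coordinates are
#' preserved), because donor perception requires explicit H.
#'
#' @param path SDF file path.
#' @param add_h add explicit hydrogens to records lacking them.
#' @return A list of \code{\link{molecule3d}} objects.
#' @export
read_sdf <- function(path, add_h = TRUE) {
  if (!file.exists(path)) stop("SDF file not found: ", path, call. = FALSE)
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  sdf_to_mols(text, add_h = add_h)
}

sdf_to_mols <- function(text, add_h = TRUE) {
  if (!grepl("\n$", text)) text <- paste0(text, "\n")
  if (add_h) {
    has_h <- grepl(" H  ", text, fixed = TRUE) || grepl(" H$", text)
    if (!has_h)
      text <- ChemmineOB::convertFormat(
        "SDF", "SDF", text, options = data.frame(names = "h", args = ""))
  }
  blocks <- split_sdf_blocks(text)
  sdfset <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(strsplit(text, "\n")[[1L]]))
  out <- vector("list", length(sdfset))
  for (i in seq_along(sdfset)) {
    block <- if (i <= length(blocks)) blocks[[i]] else NULL
    out[[i]] <- tryCatch(
      chemmine_to_mol3d(sdfset[[i]], sdf_text = block),
      error = function(e) structure(list(id = paste0("record_", i),
                                         error = conditionMessage(e)),
                                    class = "molecule3d_error"))
  }
  out
}

#' Embed SMILES into 3D molecules
#'
#' Uses Open Babel's \code{gen3D} builder (rule-based 3D generation
#' followed by force-field cleanup) and adds explicit hydrogens. One
#' conversion is run per molecule so records never influence each other;
#' note the force-field cleanup is stochastic, so coordinates (not
#' connectivity) can differ between runs. Conformational ensembles should
#' be supplied as multi-record SDF files sharing one molecule id; all
#' graph-level results (perception kinds, descriptors) are deterministic.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids molecule identifiers (defaults to names of \code{smiles} or
#'   \code{mol1}, \code{mol2}, ...).
#' @return A list of \code{\link{molecule3d}} objects.
#' @export
smiles_to_mol3d <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- names(smiles)
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  ## one conversion per molecule: the builder is deterministic per input,
  ## but shares state across records within one call
  mols <- lapply(seq_along(smiles), function(i) {
    text <- tryCatch(
      ChemmineOB::convertFormat(
        "SMI", "SDF", paste0(smiles[[i]], "\t", ids[[i]], "\n"),
        options = data.frame(names = c("gen3D", "h"), args = c("", ""))),
      error = function(e) "")
    if (!nzchar(text))
      return(structure(list(id = ids[[i]], error = "SMILES conversion failed"),
                       class = "molecule3d_error"))
    mol <- sdf_to_mols(text, add_h = FALSE)[[1L]]
    if (!inherits(mol, "molecule3d_error")) mol$id <- ids[[i]]
    mol
  })
  names(mols) <- ids[seq_along(mols)]
  mols
}

#' Read molecules from a SMILES file
#'
#' One record per line: a SMILES string optionally followed by whitespace
#' and an identifier.
#'
#' @param path file path.
#' @return A list of \code{\link{molecule3d}} objects (3D embedded).
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) stop("SMILES file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  smiles <- vapply(parts, `[[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i)
    if (length(parts[[i]]) > 1L) parts[[i]][2L] else paste0("mol", i), character(1))
  smiles_to_mol3d(smiles, ids)
}

## Minimal V2000 writer used to hand molecules to Open Babel for descriptor
## computation when no source SDF block is available.
mol3d_to_sdf_text <- function(mol, conformer = 1L) {
  if (!is.null(mol$sdf_text)) return(mol$sdf_text)
  xyz <- mol$conformers[[conformer]]
  na <- nrow(mol$atoms); nb <- nrow(mol$bonds)
  lines <- c(mol$id, "  phorescreen", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  for (i in seq_len(na))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              xyz[i, 1], xyz[i, 2], xyz[i, 3], mol$atoms$element[i]))
  for (k in seq_len(nb))
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              mol$bonds$a1[k], mol$bonds$a2[k], mol$bonds$order[k]))
  paste(c(lines, "M  END", "$$$$"), collapse = "\n")
}

## Apply a rigid motion to all conformers (used by tests and the generator).
transform_conformer <- function(xyz, rotation, translation) {
  sweep(xyz %*% t(rotation), 2, translation, `+`)
}
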