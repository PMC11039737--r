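## Rule-based pharmacophoric feature perception.
##
## Each rule is a named structural predicate over the molecular graph plus a
## placement ("atom" or "centroid"). The default registry approximates the
## conventional typing scheme: aromatic ring centroids (Aro), apolar carbon
## chains / aliphatic carbocycles / halogens (Hyd), N-H and O-H (Don),
## lone-pair N and O (Acc), and metal-coordinating atoms - carboxyl oxygens,
## azine nitrogens, thiol sulfur, phenolic oxygen (ML).

## Each predicate returns a list of integer vectors (atom index groups);
## the placed position is the single atom or the group centroid.
perception_registry <- function() {
  list(
    aromatic_ring = function(mol) mol$aromatic_rings,
    aliphatic_carbocycle = function(mol) {
      Filter(function(r) all(mol$atoms$element[r] == "C"),
             mol$rings[!vapply(mol$rings, ring_is_aromatic, logical(1), mol = mol)])
    },
    apolar_chain = function(mol) {
      apolar <- which(vapply(seq_len(nrow(mol$atoms)), function(a) {
        mol$atoms$element[a] == "C" &&
          !atom_in_aromatic_ring(mol, a) &&
          all(mol$atoms$element[mol$adj[[a]]] %in% c("C", "H", HALOGENS))
      }, logical(1)))
      comps <- connected_components(mol$adj, apolar)
      Filter(function(g) length(g) >= 2L, comps)
    },
    halogen_on_carbon = function(mol) {
      idx <- which(mol$atoms$element %in% HALOGENS &
                     vapply(seq_len(nrow(mol$atoms)), function(a)
                       any(mol$atoms$element[mol$adj[[a]]] == "C"), logical(1)))
      lapply(idx, identity)
    },
    nh_oh_donor = function(mol) {
      idx <- which(mol$atoms$element %in% c("N", "O") &
                     vapply(seq_len(nrow(mol$atoms)), function(a)
                       length(h_neighbours(mol, a)) > 0L, logical(1)))
      lapply(idx, identity)
    },
    acceptor_o = function(mol) {
      lapply(which(mol$atoms$element == "O"), identity)
    },
    acceptor_n = function(mol) {
      idx <- which(vapply(seq_len(nrow(mol$atoms)), function(a) {
        if (mol$atoms$element[a] != "N") return(FALSE)
        if (length(mol$adj[[a]]) >= 4L) return(FALSE)          # quaternary
        if (is_amide_n(mol, a)) return(FALSE)                  # amide N
        if (atom_in_aromatic_ring(mol, a) &&
            length(h_neighbours(mol, a)) > 0L) return(FALSE)   # pyrrole-type
        TRUE
      }, logical(1)))
      lapply(idx, identity)
    },
    carboxyl_o = function(mol) {
      out <- list()
      for (c_at in which(mol$atoms$element == "C")) {
        os <- heavy_neighbours(mol, c_at)
        os <- os[mol$atoms$element[os] == "O"]
        if (length(os) < 2L) next
        dbl <- os[vapply(os, function(o) bond_order_between(mol, c_at, o) == 2L,
                         logical(1))]
        if (length(dbl) >= 1L) out <- c(out, lapply(os, identity))
      }
      out
    },
    azine_n = function(mol) {
      idx <- which(vapply(seq_len(nrow(mol$atoms)), function(a) {
        mol$atoms$element[a] == "N" &&
          atom_in_aromatic_ring(mol, a) &&
          length(h_neighbours(mol, a)) == 0L &&
          length(mol$adj[[a]]) <= 2L
      }, logical(1)))
      lapply(idx, identity)
    },
    thiol_s = function(mol) {
      idx <- which(mol$atoms$element == "S" &
                     vapply(seq_len(nrow(mol$atoms)), function(a)
                       length(h_neighbours(mol, a)) > 0L, logical(1)))
      lapply(idx, identity)
    },
    phenol_o = function(mol) {
      idx <- which(vapply(seq_len(nrow(mol$atoms)), function(a) {
        mol$atoms$element[a] == "O" &&
          length(h_neighbours(mol, a)) > 0L &&
          any(vapply(heavy_neighbours(mol, a), function(b)
            atom_in_aromatic_ring(mol, b), logical(1)))
      }, logical(1)))
      lapply(idx, identity)
    }
  )
}

is_amide_n <- function(mol, a) {
  any(vapply(heavy_neighbours(mol, a), function(c_at) {
    mol$atoms$element[c_at] == "C" &&
      any(vapply(heavy_neighbours(mol, c_at), function(o)
        mol$atoms$element[o] == "O" && bond_order_between(mol, c_at, o) == 2L,
        logical(1)))
  }, logical(1)))
}

connected_components <- function(adj, subset) {
  subset <- as.integer(subset)
  comps <- list()
  remaining <- subset
  while (length(remaining)) {
    seed <- remaining[1L]
    comp <- seed
    frontier <- seed
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(a)
        intersect(adj[[a]], remaining))))
      nxt <- setdiff(nxt, comp)
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps
}

#' Default feature-perception rules
#'
#' Returns the default rule table mapping structural patterns to feature
#' kinds: aromatic rings (\code{Aro}, ring centroid); aliphatic
#' carbocycles including cyclopropyl, halogens on carbon and chains of two
#' or more apolar carbons (\code{Hyd}); N-H and O-H (\code{Don});
#' lone-pair N (excluding amide and pyrrole-type N) and O (\code{Acc});
#' carboxyl oxygens, pyridine/imidazole-type ring N, thiol S and phenolic O
#' (\code{ML}). Patterns are names into the package's predicate registry;
#' the table can be subset or reordered and serialized with
#' \code{\link{write_perception_rules}}.
#'
#' @return A data.frame with columns \code{kind}, \code{pattern},
#'   \code{placement}.
#' @export
default_rules <- function() {
  data.frame(
    kind = c("Aro", "Hyd", "Hyd", "Hyd", "Don", "Acc", "Acc",
             "ML", "ML", "ML", "ML"),
    pattern = c("aromatic_ring", "aliphatic_carbocycle", "apolar_chain",
                "halogen_on_carbon", "nh_oh_donor", "acceptor_o", "acceptor_n",
                "carboxyl_o", "azine_n", "thiol_s", "phenol_o"),
    placement = c("centroid", "centroid", "centroid", "atom", "atom", "atom",
                  "atom", "atom", "atom", "atom", "atom"),
    stringsAsFactors = FALSE
  )
}

validate_rules <- function(rules) {
  stopifnot(is.data.frame(rules),
            all(c("kind", "pattern", "placement") %in% names(rules)))
  registry <- perception_registry()
  bad_kind <- setdiff(rules$kind, FEATURE_KINDS)
  if (length(bad_kind))
    stop("unknown feature kind(s) in rules: ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  bad_pat <- setdiff(rules$pattern, names(registry))
  if (length(bad_pat))
    stop("unknown pattern(s) in rules: ", paste(bad_pat, collapse = ", "),
         call. = FALSE)
  missing_kind <- setdiff(FEATURE_KINDS, rules$kind)
  if (length(missing_kind))
    warning("rules define no pattern for kind(s): ",
            paste(missing_kind, collapse = ", "), call. = FALSE)
  invisible(rules)
}

#' Read / write perception rules as JSON
#'
#' @param path file path.
#' @param rules a rules data.frame (see \code{\link{default_rules}}).
#' @export
read_perception_rules <- function(path) {
  rules <- jsonlite::fromJSON(path)
  validate_rules(rules)
  rules
}

#' @rdname read_perception_rules
#' @export
write_perception_rules <- function(rules, path) {
  validate_rules(rules)
  jsonlite::write_json(rules, path, pretty = TRUE)
  invisible(path)
}

#' Construct a feature set
#'
#' A feature set is the perceived pharmacophoric fingerprint of one
#' conformer of one molecule: a list of features, each with a set of kinds
#' (composite when co-located), a 3D position and its source atoms.
#'
#' @param molecule_id molecule identifier.
#' @param conformer conformer index.
#' @param features list of \code{list(kinds =, xyz =, atoms =)} entries.
#' @return An object of class \code{feature_set}.
#' @export
feature_set <- function(molecule_id, conformer = 1L, features = list()) {
  for (f in features) {
    stopifnot(length(f$kinds) >= 1L, all(f$kinds %in% FEATURE_KINDS),
              length(f$xyz) == 3L, all(is.finite(f$xyz)))
  }
  structure(list(molecule_id = as.character(molecule_id),
                 conformer = as.integer(conformer), features = features),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s (conformer %d): %d feature(s)\n",
              x$molecule_id, x$conformer, length(x$features)))
  for (f in x$features)
    cat(sprintf("  %-12s (%8.3f, %8.3f, %8.3f)\n",
                paste(f$kinds, collapse = ","), f$xyz[1], f$xyz[2], f$xyz[3]))
  invisible(x)
}

fs_positions <- function(fs) {
  if (!length(fs$features)) return(matrix(numeric(), 0L, 3L))
  t(vapply(fs$features, `[[`, numeric(3), "xyz"))
}

#' Perceive pharmacophoric features of a conformer
#'
#' Applies the perception rules to the molecular graph and places one
#' feature per match. Matches of any kind lying within 0.5 \enc{Å}{A} of
#' each other are merged into a single composite feature carrying the union
#' of kinds (e.g. a carboxyl oxygen is both \code{Acc} and \code{ML}, a
#' hydroxyl oxygen both \code{Don} and \code{Acc}); the merge radius sits
#' below the smallest model tolerance so that merging never conflates
#' distinct model features.
#'
#' @param mol a \code{\link{molecule3d}}.
#' @param conformer conformer index.
#' @param rules a rules data.frame; defaults to \code{\link{default_rules}}.
#' @param merge_radius co-location merge radius in \enc{Å}{A}.
#' @return A \code{\link{feature_set}}.
#' @export
perceive <- function(mol, conformer = 1L, rules = default_rules(),
                     merge_radius = 0.5) {
  if (inherits(mol, "molecule3d_error"))
    stop("cannot perceive features: ", mol$error, call. = FALSE)
  stopifnot(inherits(mol, "molecule3d"))
  if (conformer < 1L || conformer > length(mol$conformers))
    stop("no such conformer: ", conformer, call. = FALSE)
  validate_rules(rules)
  registry <- perception_registry()
  xyz <- mol$conformers[[conformer]]

  raw <- list()
  for (r in seq_len(nrow(rules))) {
    matches <- registry[[rules$pattern[r]]](mol)
    for (grp in matches) {
      pos <- if (rules$placement[r] == "centroid" && length(grp) > 1L)
        colMeans(xyz[grp, , drop = FALSE]) else as.numeric(xyz[grp[1L], ])
      raw[[length(raw) + 1L]] <- list(kinds = rules$kind[r], xyz = pos,
                                      atoms = as.integer(grp))
    }
  }

  ## single-linkage merge of co-located placements
  merged <- list()
  for (f in raw) {
    hit <- 0L
    for (i in seq_along(merged)) {
      if (sqrt(sum((merged[[i]]$xyz - f$xyz)^2)) <= merge_radius) { hit <- i; break }
    }
    if (hit > 0L) {
      g <- merged[[hit]]
      members <- g$n_members + 1L
      merged[[hit]] <- list(
        kinds = sort(unique(c(g$kinds, f$kinds))),
        xyz = (g$xyz * g$n_members + f$xyz) / members,
        atoms = sort(unique(c(g$atoms, f$atoms))),
        n_members = members)
    } else {
      merged[[length(merged) + 1L]] <-
        c(f[c("kinds", "xyz", "atoms")], list(n_members = 1L))
    }
  }
  merged <- lapply(merged, function(f) f[c("kinds", "xyz", "atoms")])
  feature_set(mol$id, conformer, merged)
}

## Fixture drug SMILES (top screening hits; used for qualitative
## perception and drug-likeness tests). Embedded to 3D on first use and
## cached for the session.
DRUG_SMILES <- c(
  Trovafloxacin  = "OC(=O)c1cn(-c2ccc(F)cc2F)c2nc(N3CC4C(N)C4C3)c(F)cc2c1=O",
  Vilazodone     = "N#Cc1ccc2[nH]cc(CCCCN3CCN(c4ccc5cc(C(N)=O)oc5c4)CC3)c2c1",
  Pitavastatin   = "OC(=O)C[C@H](O)C[C@H](O)/C=C/c1c(C2CC2)c2ccccc2nc1-c1ccc(F)cc1",
  Dasabuvir      = "CC(C)(C)c1cc(-c2ccc3cc(N4C=CC(=O)NC4=O)ccc3c2)cc(OC)c1NS(C)(=O)=O",
  Ranolazine     = "COc1ccccc1OCC(O)CN1CCN(CC(=O)Nc2c(C)cccc2C)CC1",
  Acetophenazine = "CC(=O)c1ccc2Sc3ccccc3N(CCCN3CCN(CCO)CC3)c2c1",
  Dasatinib      = "Cc1cccc(Cl)c1NC(=O)c1cnc(Nc2cc(N3CCN(CCO)CC3)nc(C)n2)s1",
  Gefitinib      = "COc1cc2ncnc(Nc3ccc(F)c(Cl)c3)c2cc1OCCCN1CCOCC1",
  Apixaban       = "COc1ccc(-n2nc(C(N)=O)c3c2C(=O)N(c2ccc(N4CCCCC4=O)cc2)CC3)cc1",
  Nefazodone     = "CCc1nn(CCCN2CCN(c3cccc(Cl)c3)CC2)c(=O)n1CCOc1ccccc1"
)

.phore_cache <- new.env(parent = emptyenv())

#' Reference drug molecules
#'
#' The ten named drugs retained by the screening analysis (Trovafloxacin,
#' Vilazodone, Pitavastatin, Dasabuvir, Ranolazine, Acetophenazine,
#' Dasatinib, Gefitinib, Apixaban, Nefazodone), built from packaged SMILES
#' and embedded to 3D with the deterministic Open Babel builder. Used for
#' qualitative perception and drug-likeness checks.
#'
#' @return A named list of 10 \code{\link{molecule3d}} objects.
#' @export
fixture_drugs <- function() {
  if (is.null(.phore_cache$drugs)) {
    mols <- smiles_to_mol3d(DRUG_SMILES, names(DRUG_SMILES))
    names(mols) <- names(DRUG_SMILES)
    .phore_cache$drugs <- mols
  }
  .phore_cache$drugs
}
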