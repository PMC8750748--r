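# SMILES -> featurized molecular graphs.
#
# Molecules are parsed with OpenBabel (via ChemmineOB/ChemmineR); featurization
# turns the perceived structure into fixed-length per-atom and per-bond feature
# vectors whose layout is frozen in a `feature_config`. Hydrogens are implicit:
# they appear as an atom-level count, never as graph nodes.

# standard valences used only for molecules OpenBabel emits without bonds
# (single heavy atom), where ChemmineR::bonds() cannot be consulted
.default_valence <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

.sdf_charge_codes <- c(0, 3, 2, 1, 0, -1, -2, -3) # V2000 old-style codes 0..7

# Parse one SMILES into elements, formal charges, bonds and ring perception.
# Returns a plain list; errors name the offending string.
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stopf("`smiles` must be a single non-empty string")
  }
  smiles <- trimws(smiles)
  txt <- try(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles, "\tmol\n")
    )),
    silent = TRUE
  )
  if (inherits(txt, "try-error") || !nzchar(txt)) {
    stopf("failed to parse SMILES '%s'", smiles)
  }
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) stopf("failed to parse SMILES '%s'", smiles)
  counts <- lines[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || n_atoms < 1L) {
    stopf("failed to parse SMILES '%s' (no heavy atoms)", smiles)
  }

  if (n_bonds >= 1L) {
    sdf <- suppressWarnings(ChemmineR::read.SDFset(lines))[[1]]
    binfo <- ChemmineR::bonds(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- as.character(binfo$atom)
    charge <- as.numeric(binfo$charge)
    order_sum <- as.numeric(binfo$Nbondcount) # sum of incident bond orders
    base_valence <- as.numeric(binfo$Nbondrule)
    bonds <- cbind(
      from = pmin(bb[, 1], bb[, 2]),
      to = pmax(bb[, 1], bb[, 2]),
      order = bb[, 3]
    )
    storage.mode(bonds) <- "integer"
    ring_info <- suppressWarnings(
      ChemmineR::rings(sdf, upper = 8, type = "all", arom = TRUE)
    )
  } else {
    atom_lines <- lines[5:(4 + n_atoms)]
    fields <- strsplit(trimws(atom_lines), "\\s+")
    elements <- vapply(fields, function(f) f[[4]], character(1))
    code <- vapply(fields, function(f) suppressWarnings(as.integer(f[[5]])),
                   integer(1))
    code[is.na(code) | code < 0L | code > 7L] <- 0L
    charge <- .sdf_charge_codes[code + 1L]
    chg_lines <- grep("^M  CHG", lines, value = TRUE)
    for (cl in chg_lines) {
      tok <- as.integer(strsplit(trimws(sub("^M  CHG\\s*\\d*", "", cl)),
                                 "\\s+")[[1]])
      if (length(tok) >= 2L) {
        pairs <- matrix(tok, ncol = 2, byrow = TRUE)
        charge[pairs[, 1]] <- pairs[, 2]
      }
    }
    order_sum <- rep(0, n_atoms)
    base_valence <- unname(.default_valence[elements])
    base_valence[is.na(base_valence)] <- 0
    bonds <- matrix(integer(0), nrow = 0, ncol = 3,
                    dimnames = list(NULL, c("from", "to", "order")))
    ring_info <- NULL
  }

  n_bonds <- nrow(bonds)
  degree <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n_atoms)
  h_count <- pmax(0, round(base_valence + charge - order_sum))

  # ring perception: membership via bridge edges, sizes/aromaticity via the
  # perceived ring set (sizes up to 8; anything beyond sets the "larger" flag)
  atom_aromatic <- rep(FALSE, n_atoms)
  bond_aromatic <- rep(FALSE, n_bonds)
  ring_size_sets <- vector("list", n_atoms)
  bond_in_ring <- rep(FALSE, n_bonds)
  if (n_bonds > 0L) {
    g <- igraph::make_empty_graph(n = n_atoms, directed = FALSE)
    g <- igraph::add_edges(g, t(bonds[, 1:2, drop = FALSE]))
    bridge_ids <- as.integer(igraph::bridges(g))
    bond_in_ring <- !(seq_len(n_bonds) %in% bridge_ids)
  }
  atom_in_ring <- rep(FALSE, n_atoms)
  if (any(bond_in_ring)) {
    ring_bonds <- bonds[bond_in_ring, , drop = FALSE]
    atom_in_ring[unique(c(ring_bonds[, 1], ring_bonds[, 2]))] <- TRUE
  }
  if (!is.null(ring_info) && length(ring_info$RINGS)) {
    arom <- ring_info$AROMATIC
    for (ri in seq_along(ring_info$RINGS)) {
      members <- as.integer(sub(".*_", "", ring_info$RINGS[[ri]]))
      k <- length(members)
      for (a in members) {
        ring_size_sets[[a]] <- union(ring_size_sets[[a]], k)
      }
      if (isTRUE(arom[[ri]])) {
        atom_aromatic[members] <- TRUE
        pair_from <- members
        pair_to <- c(members[-1], members[1])
        for (b in seq_len(n_bonds)) {
          hit <- (bonds[b, 1] %in% members) && (bonds[b, 2] %in% members) &&
            any((pair_from == bonds[b, 1] & pair_to == bonds[b, 2]) |
                  (pair_from == bonds[b, 2] & pair_to == bonds[b, 1]))
          if (hit) bond_aromatic[b] <- TRUE
        }
      }
    }
  }

  # hybridization from incident bond orders (aromatic counts as sp2)
  n_double <- rep(0L, n_atoms)
  has_triple <- rep(FALSE, n_atoms)
  if (n_bonds > 0L) {
    for (b in seq_len(n_bonds)) {
      if (bonds[b, 3] == 2L) {
        n_double[bonds[b, 1]] <- n_double[bonds[b, 1]] + 1L
        n_double[bonds[b, 2]] <- n_double[bonds[b, 2]] + 1L
      } else if (bonds[b, 3] == 3L) {
        has_triple[bonds[b, 1]] <- TRUE
        has_triple[bonds[b, 2]] <- TRUE
      }
    }
  }
  hybrid <- ifelse(has_triple | n_double >= 2L, "sp",
                   ifelse(n_double >= 1L | atom_aromatic, "sp2", "sp3"))

  list(
    smiles = smiles,
    n_atoms = n_atoms,
    elements = elements,
    charge = charge,
    degree = degree,
    h_count = as.numeric(h_count),
    valence = order_sum + h_count,
    hybridization = hybrid,
    aromatic_atom = atom_aromatic,
    in_ring_atom = atom_in_ring,
    ring_sizes = ring_size_sets,
    bonds = bonds,
    bond_aromatic = bond_aromatic,
    bond_in_ring = bond_in_ring
  )
}

#' Create a frozen feature configuration for molecular graphs
#'
#' Fixes the vocabularies that define the per-atom feature length `p` and
#' per-bond feature length `q`. The atom-type vocabulary is either supplied
#' explicitly or collected from the elements observed in a set of SMILES
#' (typically the training data); an out-of-vocabulary fallback slot is always
#' present, so unseen elements at prediction time map to the fallback rather
#' than erroring. Freezing the vocabularies at creation guarantees that every
#' graph produced under one config has identical feature dimensions.
#'
#' @param smiles Optional character vector of SMILES whose observed elements
#'   define the atom-type vocabulary (sorted, duplicates removed).
#' @param elements Optional explicit character vector of element symbols.
#'   When both `smiles` and `elements` are `NULL`, a default organic-chemistry
#'   set is used.
#' @param ring_sizes Integer ring sizes that receive individual membership
#'   flags; membership in any larger ring sets a separate "larger" flag.
#' @return An object of class `feature_config` with derived lengths `p`
#'   (atom features) and `q` (bond features).
#' @examples
#' cfg <- feature_config(smiles = c("CCO", "c1ccccc1"))
#' cfg$p
#' cfg$q
#' @export
feature_config <- function(smiles = NULL, elements = NULL, ring_sizes = 3:8) {
  if (is.null(elements)) {
    if (!is.null(smiles)) {
      elements <- sort(unique(unlist(
        lapply(unique(smiles), function(s) parse_smiles(s)$elements)
      )))
    } else {
      elements <- c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I")
    }
  }
  if (length(elements) < 1L) stopf("element vocabulary must be non-empty")
  ring_sizes <- sort(unique(as.integer(ring_sizes)))
  cfg <- list(
    elements = as.character(elements),
    degree_levels = 0:5,
    hybridization = c("sp", "sp2", "sp3", "other"),
    numh_levels = 0:4,
    chirality = c("none", "cw", "ccw"),
    ring_sizes = ring_sizes,
    bond_types = c("single", "double", "triple", "aromatic"),
    stereo = c("none", "Z", "E")
  )
  cfg$p <- length(cfg$elements) + 1L + # element one-hot + fallback
    1L +                               # formal charge
    length(cfg$degree_levels) +
    length(cfg$hybridization) +
    length(cfg$numh_levels) +
    1L +                               # valence
    length(cfg$chirality) +
    4L +                               # donor, acceptor, aromatic, in-ring
    length(cfg$ring_sizes) + 1L        # ring-size flags + "larger"
  cfg$q <- length(cfg$bond_types) + length(cfg$stereo) + 2L
  structure(cfg, class = "feature_config")
}

#' @export
print.feature_config <- function(x, ...) {
  cat("<feature_config>\n")
  cat("  elements:", paste(x$elements, collapse = " "), "+ fallback\n")
  cat("  atom feature length p:", x$p, "\n")
  cat("  bond feature length q:", x$q, "\n")
  invisible(x)
}

one_hot <- function(value, vocab, fallback = FALSE) {
  v <- numeric(length(vocab) + as.integer(fallback))
  idx <- match(value, vocab)
  if (is.na(idx)) {
    if (fallback) v[length(v)] <- 1 else v[length(vocab)] <- 1
  } else {
    v[idx] <- 1
  }
  v
}

#' Convert a SMILES string to a featurized molecular graph
#'
#' Parses the molecule, perceives rings and aromaticity, and encodes one
#' feature vector per heavy atom (atom type, formal charge, degree,
#' hybridization, implicit hydrogen count, valence, chirality, donor/acceptor
#' flags, aromaticity, ring membership and ring-size flags) plus one feature
#' vector per bond (bond type, stereochemistry, ring membership, conjugation).
#' Hydrogens are implicit. Elements outside the configured vocabulary map to
#' the fallback category.
#'
#' @param smiles A single SMILES string.
#' @param config A [feature_config()].
#' @return An object of class `molecular_graph`: a list with `n` (atom count),
#'   `node_features` (`n x p` matrix), `edge_index` (`E x 2` matrix of
#'   unordered atom index pairs, `from < to`), `edge_features` (`E x q`
#'   matrix) and the source `smiles`.
#' @examples
#' cfg <- feature_config()
#' g <- featurize_molecule("c1ccccc1", cfg)
#' g$n
#' nrow(g$edge_index)
#' @export
featurize_molecule <- function(smiles, config) {
  stopifnot(inherits(config, "feature_config"))
  m <- parse_smiles(smiles)
  n <- m$n_atoms

  node_features <- matrix(0, nrow = n, ncol = config$p)
  for (j in seq_len(n)) {
    donor <- as.numeric(m$elements[j] %in% c("N", "O") && m$h_count[j] >= 1)
    acceptor <- as.numeric(m$elements[j] %in% c("N", "O") && m$charge[j] <= 0)
    sizes <- m$ring_sizes[[j]]
    node_features[j, ] <- c(
      one_hot(m$elements[j], config$elements, fallback = TRUE),
      m$charge[j],
      one_hot(min(m$degree[j], max(config$degree_levels)),
              config$degree_levels),
      one_hot(m$hybridization[j], config$hybridization),
      one_hot(min(m$h_count[j], max(config$numh_levels)), config$numh_levels),
      m$valence[j],
      one_hot("none", config$chirality),
      donor,
      acceptor,
      as.numeric(m$aromatic_atom[j]),
      as.numeric(m$in_ring_atom[j]),
      as.numeric(config$ring_sizes %in% sizes),
      as.numeric(m$in_ring_atom[j] && length(sizes) == 0L)
    )
  }

  n_bonds <- nrow(m$bonds)
  edge_features <- matrix(0, nrow = n_bonds, ncol = config$q)
  if (n_bonds > 0L) {
    for (b in seq_len(n_bonds)) {
      btype <- if (m$bond_aromatic[b]) {
        "aromatic"
      } else {
        c("single", "double", "triple")[m$bonds[b, 3]]
      }
      sp2ish <- m$hybridization[m$bonds[b, 1:2]] %in% c("sp", "sp2")
      conjugated <- as.numeric(m$bond_aromatic[b] || all(sp2ish))
      edge_features[b, ] <- c(
        one_hot(btype, config$bond_types),
        one_hot("none", config$stereo),
        as.numeric(m$bond_in_ring[b]),
        conjugated
      )
    }
  }

  structure(
    list(
      n = n,
      node_features = node_features,
      edge_index = m$bonds[, 1:2, drop = FALSE],
      edge_features = edge_features,
      smiles = m$smiles
    ),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %s: %d atoms, %d bonds (p=%d, q=%d)\n",
              x$smiles, x$n, nrow(x$edge_index),
              ncol(x$node_features), ncol(x$edge_features)))
  invisible(x)
}

#' Assemble a reaction record from SMILES
#'
#' A reaction is a set of `m >= 1` reactant graphs, one product graph and an
#' optional measured yield in percent. The order of the reactants carries no
#' meaning downstream: the model representation sums over them.
#'
#' @param reactant_smiles Character vector of reactant SMILES (length `m >= 1`).
#' @param product_smiles A single product SMILES.
#' @param yield_percent Optional measured yield in `[0, 100]`.
#' @param config A [feature_config()].
#' @return An object of class `reaction_record` with elements `reactants`
#'   (list of `molecular_graph`), `product`, `yield_percent` and `m`.
#' @examples
#' cfg <- feature_config()
#' r <- featurize_reaction(c("CCO", "c1ccccc1"), "CC", 50, cfg)
#' r$m
#' @export
featurize_reaction <- function(reactant_smiles, product_smiles,
                               yield_percent = NULL, config) {
  if (length(reactant_smiles) < 1L) {
    stopf("a reaction needs at least one reactant")
  }
  if (length(product_smiles) != 1L) {
    stopf("a reaction has exactly one product")
  }
  if (!is.null(yield_percent) && !is.na(yield_percent)) {
    assert_scalar_number(yield_percent, "yield_percent", 0, 100)
  } else {
    yield_percent <- NULL
  }
  structure(
    list(
      reactants = lapply(reactant_smiles, featurize_molecule, config = config),
      product = featurize_molecule(product_smiles, config),
      yield_percent = yield_percent,
      m = length(reactant_smiles)
    ),
    class = "reaction_record"
  )
}

#' @export
print.reaction_record <- function(x, ...) {
  cat(sprintf("<reaction_record> m=%d reactants -> %s%s\n", x$m,
              x$product$smiles,
              if (is.null(x$yield_percent)) "" else
                sprintf(" (yield %.1f%%)", x$yield_percent)))
  invisible(x)
}

# Featurize each unique SMILES once; returns a named list of molecular_graph.
featurize_unique <- function(smiles, config) {
  smiles <- unique(smiles[!is.na(smiles) & nzchar(smiles)])
  graphs <- lapply(smiles, featurize_molecule, config = config)
  names(graphs) <- smiles
  graphs
}
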