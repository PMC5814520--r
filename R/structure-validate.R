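# Cross-link validation against a crystal structure: C-alpha coordinates
# from PDB, Euclidean residue-pair distances, the 30 A cross-linker limit,
# a random-pair distance baseline, and decoy-based FDR.

#' Load C-alpha coordinates from a PDB file
#'
#' Reads ATOM records via bio3d and keeps one C-alpha per residue of the
#' requested chain. Alternate locations are resolved by highest occupancy,
#' ties by first appearance. Residues without a C-alpha record are simply
#' absent from the model (their pairs cannot be distance-checked).
#'
#' @param pdb_file Path to a PDB file.
#' @param chain Chain identifier (default `"A"`).
#' @return Object of class `structure_model`: data.frame with `resno`,
#'   `x`, `y`, `z`; chain id as attribute `chain`.
#' @export
load_ca_coords <- function(pdb_file, chain = "A") {
  pdb <- bio3d::read.pdb(pdb_file, verbose = FALSE, rm.alt = FALSE)
  atoms <- pdb$atom
  chains <- unique(atoms$chain)
  if (!chain %in% chains) {
    stop("chain '", chain, "' not found; available chains: ",
         paste(chains, collapse = ", "))
  }
  ca <- atoms[atoms$chain == chain & atoms$elety == "CA" &
                atoms$type == "ATOM", , drop = FALSE]
  if (!nrow(ca)) stop("no C-alpha atoms in chain ", chain)
  # altloc: highest occupancy first, then file order
  ca <- ca[order(ca$resno, -ca$o), ]
  ca <- ca[!duplicated(ca$resno), ]
  coords <- data.frame(resno = ca$resno, x = ca$x, y = ca$y, z = ca$z)
  if (any(!is.finite(as.matrix(coords[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in ", pdb_file)
  }
  structure(coords, class = c("structure_model", "data.frame"),
            chain = chain)
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: chain %s, %d C-alpha residues (%d-%d)\n",
              attr(x, "chain"), nrow(x), min(x$resno), max(x$resno)))
  invisible(x)
}

#' C-alpha to C-alpha distance
#'
#' Euclidean distance between the C-alpha atoms of residues `i` and `j`;
#' `NA` when either residue is not resolved in the model. Vectorized over
#' `i`/`j`.
#'
#' @param model A [load_ca_coords()] model.
#' @param i,j Residue numbers.
#' @return Distance(s) in Angstrom, `NA` where unresolved.
#' @export
ca_distance <- function(model, i, j) {
  ai <- match(i, model$resno)
  aj <- match(j, model$resno)
  dx <- model$x[ai] - model$x[aj]
  dy <- model$y[ai] - model$y[aj]
  dz <- model$z[ai] - model$z[aj]
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Distance filter on cross-linked residue pairs
#'
#' Removes pairs whose measured C-alpha distance is at or beyond the
#' cross-linker's theoretical limit (30 A for BS3) and all decoy matches.
#' Pairs with an unresolved residue cannot be falsified and are retained
#' (flagged `NA` in the distance column).
#'
#' @param pairs data.frame with columns `i`, `j` (residue numbers, protein
#'   numbering) and optionally `is_decoy`.
#' @param model A [load_ca_coords()] model.
#' @param threshold Distance limit in Angstrom (default 30; removal at
#'   `distance >= threshold`).
#' @param offset Numbering offset added to `i`/`j` to translate sequence
#'   numbering into structure numbering (default 0).
#' @return List with data.frames `retained` and `removed`, each carrying a
#'   `ca_distance` column.
#' @export
distance_filter <- function(pairs, model, threshold = 30, offset = 0) {
  if (is.null(pairs$is_decoy)) pairs$is_decoy <- FALSE
  pairs$ca_distance <- ca_distance(model, pairs$i + offset, pairs$j + offset)
  too_far <- !is.na(pairs$ca_distance) & pairs$ca_distance >= threshold
  drop <- too_far | pairs$is_decoy
  list(retained = pairs[!drop, , drop = FALSE],
       removed = pairs[drop, , drop = FALSE])
}

#' Linkable residue positions of a protein sequence
#'
#' Positions the cross-linker can react with: lysine, serine, threonine,
#' tyrosine side chains and the protein N-terminus (position 1).
#'
#' @param sequence Protein residue string.
#' @return Sorted integer positions.
#' @export
linkable_residues <- function(sequence) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  sort(unique(c(1L, which(aa %in% c("K", "S", "T", "Y")))))
}

#' Random cross-linkable distance distribution
#'
#' Baseline for judging observed cross-link distances: distances of
#' uniformly drawn unordered pairs of linkable residues (without
#' replacement within a draw, with replacement across draws).
#'
#' @param model A [load_ca_coords()] model.
#' @param linkable Integer residue numbers eligible for linking; defaults
#'   to every resolved residue.
#' @param n_samples Number of random pairs.
#' @param seed RNG seed (reproducible draws).
#' @return Numeric vector of distances in Angstrom.
#' @export
random_distance_distribution <- function(model, linkable = model$resno,
                                         n_samples = 10000L, seed = 1L) {
  linkable <- intersect(linkable, model$resno)
  if (length(linkable) < 2L) stop("need >= 2 linkable resolved residues")
  set.seed(seed)
  i <- integer(n_samples); j <- integer(n_samples)
  for (s in seq_len(n_samples)) {
    pick <- sample(linkable, 2L)
    i[s] <- pick[1L]; j[s] <- pick[2L]
  }
  ca_distance(model, i, j)
}

#' Decoy-based FDR
#'
#' Fraction of matches hitting the reversed-sequence decoy database,
#' reported as a percentage of all matches, with the raw counts attached.
#'
#' @param is_decoy Logical vector of decoy flags (one per match or unique
#'   residue pair).
#' @return Numeric percentage with attributes `n_decoy` and `n_total`.
#' @export
decoy_fdr <- function(is_decoy) {
  if (!length(is_decoy)) stop("decoy FDR undefined for an empty match list")
  pct <- 100 * sum(is_decoy) / length(is_decoy)
  structure(pct, n_decoy = sum(is_decoy), n_total = length(is_decoy))
}
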