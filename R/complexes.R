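#' Protein-ligand complex graphs
#'
#' A complex graph merges the bonded graphs of a protein (pocket) and a
#' ligand -- protein atoms first, ligand indices offset -- and adds typed
#' nonbonded edges between every intermolecular atom pair closer than a
#' cutoff (default 5 Angstrom). Bonded edges keep the bond-distance basis;
#' nonbonded edges carry the nonbonded basis \{r^-1, r^-12, r^-6\} through
#' an edge-type-specific projection. 2-hop and 3-hop chains are built over
#' the bonded graph only: angle and torsion terms are defined along bonded
#' chains.
#'
#' @name complexes
NULL

#' Intermolecular close-contact pairs
#'
#' All index pairs (a, b) with `||pos_A[a] - pos_B[b]|| < cutoff` (strict
#' inequality).
#'
#' @param pos_a,pos_b coordinate matrices `n x 3` (same frame, Angstrom).
#' @param cutoff contact cutoff in Angstrom (default 5).
#' @return two-column integer matrix of (a, b) pairs.
#' @export
intermolecular_pairs <- function(pos_a, pos_b, cutoff = 5) {
  stopifnot(cutoff > 0)
  if (nrow(pos_a) == 0 || nrow(pos_b) == 0)
    return(matrix(integer(0), 0, 2))
  d2 <- outer(rowSums(pos_a^2), rowSums(pos_b^2), "+") -
    2 * pos_a %*% t(pos_b)
  hits <- which(d2 < cutoff^2, arr.ind = TRUE)
  dimnames(hits) <- NULL
  hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
}

#' Merge a protein and a ligand into a complex graph
#'
#' @param protein,ligand `ffinet_molecule` records with positions in the
#'   same coordinate frame.
#' @param cutoff nonbonded contact cutoff in Angstrom.
#' @param affinity optional binding-affinity label (pK scale).
#' @param pocket_radius if not NULL, protein atoms farther than this from
#'   every ligand atom are pruned before merging (bonds re-indexed).
#' @return object of class `ffinet_complex` with fields `record` (merged
#'   molecule), `n_protein`, `n_ligand`, `nonbonded_pairs` (directed,
#'   global indices), `edge_type` markers, and `affinity`.
#' @export
merge_complex <- function(protein, ligand, cutoff = 5, affinity = NULL,
                          pocket_radius = NULL) {
  if (protein$n_atoms == 0 || ligand$n_atoms == 0)
    stop_config("protein and ligand must both have atoms")
  if (!is.null(pocket_radius))
    protein <- prune_to_pocket(protein, ligand, pocket_radius)
  np <- protein$n_atoms
  nl <- ligand$n_atoms
  bonds <- rbind(protein$bonds, ligand$bonds + np)
  inter <- intermolecular_pairs(protein$positions, ligand$positions, cutoff)
  # directed, both orientations, ligand indices offset
  nb <- if (nrow(inter)) {
    fwd <- cbind(inter[, 1], inter[, 2] + np)
    rbind(fwd, fwd[, 2:1, drop = FALSE])
  } else matrix(integer(0), 0, 2)
  merged <- structure(list(
    mol_id = paste0(protein$mol_id, "::", ligand$mol_id),
    smiles = NULL,
    n_atoms = np + nl,
    symbols = c(protein$symbols, ligand$symbols),
    atom_features = rbind(protein$atom_features, ligand$atom_features),
    positions = rbind(protein$positions, ligand$positions),
    bonds = bonds,
    bond_orders = c(protein$bond_orders %||% rep(1L, nrow(protein$bonds)),
                    ligand$bond_orders %||% rep(1L, nrow(ligand$bonds))),
    labels = affinity,
    label_mask = if (is.null(affinity)) NULL else !is.na(affinity),
    feature_version = protein$feature_version
  ), class = "ffinet_molecule")
  structure(list(record = merged, n_protein = np, n_ligand = nl,
                 nonbonded_pairs = nb, cutoff = cutoff,
                 affinity = affinity),
            class = "ffinet_complex")
}

#' @noRd
prune_to_pocket <- function(protein, ligand, radius) {
  d2 <- outer(rowSums(protein$positions^2), rowSums(ligand$positions^2), "+") -
    2 * protein$positions %*% t(ligand$positions)
  keep <- which(apply(d2, 1, min) < radius^2)
  if (!length(keep)) stop_config("pocket pruning removed every protein atom")
  remap <- match(seq_len(protein$n_atoms), keep)
  b <- protein$bonds
  keep_b <- !is.na(remap[b[, 1]]) & !is.na(remap[b[, 2]])
  protein$bonds <- matrix(remap[b[keep_b, , drop = FALSE]], ncol = 2)
  protein$bond_orders <- (protein$bond_orders %||% rep(1L, nrow(b)))[keep_b]
  protein$atom_features <- protein$atom_features[keep, , drop = FALSE]
  protein$positions <- protein$positions[keep, , drop = FALSE]
  protein$symbols <- protein$symbols[keep]
  protein$n_atoms <- length(keep)
  protein
}

#' @export
print.ffinet_complex <- function(x, ...) {
  cat(sprintf("<ffinet_complex> %d protein + %d ligand atoms, %d nonbonded edges (< %.1f A)\n",
              x$n_protein, x$n_ligand, nrow(x$nonbonded_pairs), x$cutoff))
  invisible(x)
}

# prepared network input for a complex: nonbonded edges join hop 1 with the
# nonbonded basis in a separate block; hop 2/3 stay bonded-only
#' @noRd
prepare_complex <- function(cx, config) {
  rec <- cx$record
  index <- build_khop_index(rec$bonds, rec$n_atoms,
                            dedupe_hops = config$dedupe_hops)
  basis <- assemble_basis(rec, index)
  nb <- cx$nonbonded_pairs
  hop1 <- rbind(index$hop1, nb)
  m1 <- rbind(basis$m1, matrix(0, nrow(nb), 2))
  m1_nb <- rbind(matrix(0, nrow(index$hop1), NONBONDED_NCOL),
                 if (nrow(nb)) nonbonded_basis(path_distances(rec$positions, nb))
                 else matrix(numeric(0), 0, NONBONDED_NCOL))
  list(x = rec$atom_features, n_atoms = rec$n_atoms,
       paths = list(hop1, index$hop2, index$hop3),
       basis = list(m1, basis$m2, basis$m3),
       basis1_nb = m1_nb,
       labels = cx$affinity, label_mask = if (is.null(cx$affinity)) NULL
       else !is.na(cx$affinity),
       mol_id = rec$mol_id)
}

# standardization statistics for complex inputs: bonded hop-1 rows and
# nonbonded hop-1 rows are scaled separately
#' @noRd
complex_basis_stats <- function(inputs) {
  col_stats <- function(m) {
    if (is.null(m) || nrow(m) == 0)
      return(NULL)
    s <- unname(apply(m, 2, stats::sd))
    list(mean = unname(colMeans(m)), sd = ifelse(s < 1e-8, 1, s))
  }
  stack <- function(getter) do.call(rbind, lapply(inputs, getter))
  m1_all <- stack(function(gi) {
    keep <- rowSums(abs(gi$basis[[1]])) > 0
    gi$basis[[1]][keep, , drop = FALSE]
  })
  nb_all <- stack(function(gi) {
    if (is.null(gi$basis1_nb)) return(NULL)
    keep <- rowSums(abs(gi$basis1_nb)) > 0
    gi$basis1_nb[keep, , drop = FALSE]
  })
  default <- function(st, nc) st %||% list(mean = rep(0, nc), sd = rep(1, nc))
  structure(list(
    m1 = default(col_stats(m1_all), 2L),
    m2 = default(col_stats(stack(function(gi) gi$basis[[2]])), 5L),
    m3 = default(col_stats(stack(function(gi) gi$basis[[3]])), 9L),
    m1_nb = default(col_stats(nb_all), NONBONDED_NCOL)
  ), class = "ffinet_basis_stats")
}

#' Read a PDBBind-style affinity index file
#'
#' Expects whitespace-delimited rows of at least (complex id, affinity);
#' lines starting with `#` are skipped.
#'
#' @param path index file path.
#' @return data.frame with columns `id` and `affinity` (pK scale).
#' @export
read_pdbbind_index <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  data.frame(id = vapply(parts, `[[`, character(1), 1),
             affinity = as.numeric(vapply(parts, `[[`, character(1), 2)),
             stringsAsFactors = FALSE)
}

#' Load one complex from a PDBBind-style directory
#'
#' Expects `<dir>/<id>/<id>_ligand.sdf` (or `.mol2`) and
#' `<dir>/<id>/<id>_pocket.pdb`.
#'
#' @param dir dataset root directory.
#' @param id complex identifier.
#' @param affinity label to attach.
#' @param cutoff,pocket_radius forwarded to [merge_complex()].
#' @return an `ffinet_complex`.
#' @export
load_pdbbind_complex <- function(dir, id, affinity = NULL, cutoff = 5,
                                 pocket_radius = NULL) {
  base <- file.path(dir, id)
  lig_path <- Filter(file.exists,
                     file.path(base, paste0(id, c("_ligand.sdf", "_ligand.mol2"))))
  if (!length(lig_path)) stop_config("no ligand file found for ", id)
  ligand <- read_structure_file(lig_path[[1]], mol_id = paste0(id, "_ligand"))
  pocket <- read_structure_file(file.path(base, paste0(id, "_pocket.pdb")),
                                format = "pdb", mol_id = paste0(id, "_pocket"))
  merge_complex(pocket, ligand, cutoff = cutoff, affinity = affinity,
                pocket_radius = pocket_radius)
}
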