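#' Molecule records
#'
#' The central container is the `ffinet_molecule`: heavy atoms only
#' (hydrogens are folded into the per-atom H-count feature), with a fixed
#' 38-column feature matrix, 3D positions in Angstrom, the undirected bond
#' list, and an optional label vector with missing-value mask.
#'
#' Atom features encode eight families: atomic number, formal charge,
#' chirality tag, number of bonded hydrogens, hybridization (each one-hot
#' with an "other" bucket), aromaticity flag, atomic mass / 100, and
#' hydrogen-bond donor/acceptor flags.
#'
#' @name molio
NULL

# fixed feature layout; must agree with the vocabularies in
# inst/python/ffinet_rdkit.py (version ffinet-features-1)
FFINET_FEATURE_VERSION <- "ffinet-features-1"
FFINET_FEATURE_WIDTHS <- c(atomic_num = 12L, formal_charge = 6L,
                           chirality = 4L, num_h = 6L, hybridization = 6L,
                           aromatic = 1L, mass = 1L, hbond = 2L)

#' Number of atom-feature columns
#' @return integer, the fixed feature width F.
#' @export
ffinet_n_features <- function() sum(FFINET_FEATURE_WIDTHS)

#' @noRd
new_molecule_record <- function(rec, mol_id = NULL, smiles = NULL,
                                labels = NULL) {
  feats <- do.call(rbind, lapply(rec$features, unlist))
  bonds_raw <- do.call(rbind, lapply(rec$bonds, unlist))
  if (is.null(bonds_raw)) bonds_raw <- matrix(integer(0), 0, 3)
  positions <- do.call(rbind, lapply(rec$positions, unlist))
  if (is.null(positions)) positions <- matrix(numeric(0), 0, 3)
  out <- structure(list(
    mol_id = mol_id %||% (rec$canonical_smiles %||% "mol"),
    smiles = smiles %||% rec$canonical_smiles,
    n_atoms = as.integer(rec$n_atoms),
    symbols = vapply(rec$symbols, identity, character(1)),
    atom_features = feats,
    positions = positions,
    bonds = matrix(as.integer(bonds_raw[, 1:2]), ncol = 2),
    bond_orders = as.integer(bonds_raw[, 3]),
    labels = labels,
    label_mask = if (is.null(labels)) NULL else !is.na(labels),
    feature_version = rec$feature_version %||% FFINET_FEATURE_VERSION
  ), class = "ffinet_molecule")
  validate_molecule_record(out)
}

#' @noRd
validate_molecule_record <- function(x) {
  stopifnot(is.matrix(x$atom_features), nrow(x$atom_features) == x$n_atoms)
  if (nrow(x$positions) > 0) {
    stopifnot(nrow(x$positions) == x$n_atoms, all(is.finite(x$positions)))
  }
  normalize_bonds(x$bonds, x$n_atoms)  # errors on bad bonds
  x
}

#' @export
print.ffinet_molecule <- function(x, ...) {
  cat(sprintf("<ffinet_molecule> %s: %d heavy atoms, %d bonds%s\n",
              x$mol_id, x$n_atoms, nrow(x$bonds),
              if (nrow(x$positions)) ", 3D" else ""))
  invisible(x)
}

#' Read a SMILES + labels table
#'
#' Reads a delimited text file with a header row, one molecule per row.
#' Empty label cells become missing-mask entries; rows whose SMILES RDKit
#' cannot parse are skipped with a warning naming the row.
#'
#' @param path file path to a CSV/TSV table.
#' @param smiles_column name of the SMILES column.
#' @param label_columns character vector of label column names.
#' @param sep field separator (default `,`).
#' @param validate check SMILES parseability through the RDKit bridge and
#'   drop unparseable rows (default TRUE).
#' @return a data.frame with column `smiles` and one numeric column per
#'   label (NA where the cell was empty).
#' @export
read_smiles_table <- function(path, smiles_column = "smiles",
                              label_columns = NULL, sep = ",",
                              validate = TRUE) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "\"")
  if (!smiles_column %in% names(df))
    stop_config("smiles column '", smiles_column, "' not present in ", path)
  missing_labels <- setdiff(label_columns, names(df))
  if (length(missing_labels))
    stop_config("label column(s) not present: ",
                paste(missing_labels, collapse = ", "))
  out <- data.frame(smiles = as.character(df[[smiles_column]]),
                    stringsAsFactors = FALSE)
  for (lc in label_columns) {
    v <- df[[lc]]
    v[v == ""] <- NA
    out[[lc]] <- suppressWarnings(as.numeric(v))
  }
  if (validate) {
    resp <- rdkit_call("validate", list(smiles = as.list(out$smiles)))
    ok <- vapply(resp$ok, isTRUE, logical(1))
    if (any(!ok)) {
      warning(sprintf("skipped %d unparseable SMILES row(s): %s",
                      sum(!ok), paste(which(!ok), collapse = ", ")),
              call. = FALSE)
      out <- out[ok, , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  out
}

#' Embed a 3D conformer for a SMILES string
#'
#' Generates a single conformer with the ETKDG distance-geometry method,
#' seeded for reproducibility: the same (smiles, seed) pair always yields
#' bitwise-identical positions. On embedding failure the generator retries
#' once with random-coordinate initialization; if that also fails an error
#' is raised (batch callers drop the record and log the reason).
#'
#' @param smiles a SMILES string.
#' @param seed integer random seed for the conformer generator.
#' @param mol_id optional identifier.
#' @return an `ffinet_molecule` with positions.
#' @export
embed_conformer <- function(smiles, seed = 0L, mol_id = NULL) {
  stopifnot(length(smiles) == 1)
  resp <- rdkit_call("molecules",
                     list(items = list(list(smiles = smiles,
                                            seed = as.integer(seed),
                                            embed = TRUE))))
  rec <- resp$results[[1]]
  if (!isTRUE(rec$ok)) stop_config(rec$error)
  new_molecule_record(rec, mol_id = mol_id, smiles = smiles)
}

#' Embed conformers for many SMILES in one bridge call
#'
#' @param smiles character vector.
#' @param seeds integer vector recycled to `length(smiles)`.
#' @param labels optional numeric matrix/vector of labels, one row per
#'   SMILES; attached to the records.
#' @param on_error "drop" (default; failed records removed with a warning)
#'   or "error".
#' @return list of `ffinet_molecule`.
#' @export
embed_conformers <- function(smiles, seeds = 0L, labels = NULL,
                             on_error = c("drop", "error")) {
  on_error <- match.arg(on_error)
  seeds <- rep_len(as.integer(seeds), length(smiles))
  if (!is.null(labels)) labels <- as.matrix(labels)
  items <- lapply(seq_along(smiles), function(i)
    list(smiles = smiles[i], seed = seeds[i], embed = TRUE))
  resp <- rdkit_call("molecules", list(items = items))
  records <- vector("list", length(smiles))
  failed <- character(0)
  for (i in seq_along(smiles)) {
    rec <- resp$results[[i]]
    if (isTRUE(rec$ok)) {
      lab <- if (!is.null(labels)) labels[i, ] else NULL
      records[[i]] <- new_molecule_record(rec, mol_id = paste0("mol", i),
                                          smiles = smiles[i], labels = lab)
    } else {
      failed <- c(failed, sprintf("row %d (%s): %s", i, smiles[i], rec$error))
    }
  }
  if (length(failed)) {
    msg <- paste("dropped", length(failed), "record(s):",
                 paste(failed, collapse = "; "))
    if (on_error == "error") stop_config(msg)
    warning(msg, call. = FALSE)
  }
  Filter(Negate(is.null), records)
}

#' Atom feature matrix for a molecule
#'
#' @param x an `ffinet_molecule`, or a SMILES string (featurized through
#'   the bridge without conformer generation).
#' @return numeric matrix `n_atoms x 38`.
#' @export
featurize_atoms <- function(x) {
  if (inherits(x, "ffinet_molecule")) return(x$atom_features)
  stopifnot(is.character(x), length(x) == 1)
  resp <- rdkit_call("molecules",
                     list(items = list(list(smiles = x, embed = FALSE))))
  rec <- resp$results[[1]]
  if (!isTRUE(rec$ok)) stop_config(rec$error)
  do.call(rbind, lapply(rec$features, unlist))
}

#' Read a structure file with coordinates
#'
#' Positions are taken from the file; no conformer generation. Bonds come
#' from the file's connectivity; for PDB files without CONECT records they
#' are perceived from interatomic distances (with a warning).
#'
#' @param path path to the structure file.
#' @param format one of "sdf", "pdb", "mol2"; inferred from the file
#'   extension when missing.
#' @param mol_id optional identifier.
#' @return an `ffinet_molecule`.
#' @export
read_structure_file <- function(path, format = NULL, mol_id = NULL) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("sdf", "pdb", "mol2"))
    stop_config("unsupported structure format: ", format)
  rec <- rdkit_call("read_structure", list(path = normalizePath(path),
                                           format = format))
  if (format == "pdb" && !isTRUE(rec$had_conect))
    warning("PDB file has no CONECT records; bonds perceived from distances",
            call. = FALSE)
  new_molecule_record(rec, mol_id = mol_id %||% basename(path))
}

#' Write a molecule as a V2000 SDF file
#'
#' A native R writer (independent of the RDKit reader, so the SDF round
#' trip crosses two implementations).
#'
#' @param record an `ffinet_molecule` with positions.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(record, path) {
  stopifnot(inherits(record, "ffinet_molecule"), nrow(record$positions) > 0)
  n <- record$n_atoms
  nb <- nrow(record$bonds)
  lines <- c(record$mol_id, "  ffinet", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              record$positions[i, 1], record$positions[i, 2],
                              record$positions[i, 3], record$symbols[i]))
  }
  orders <- record$bond_orders %||% rep(1L, nb)
  for (b in seq_len(nb)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0",
                              record$bonds[b, 1], record$bonds[b, 2], orders[b]))
  }
  lines <- c(lines, "M  END", "$$$$")
  writeLines(lines, path)
  invisible(path)
}
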