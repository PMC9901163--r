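# Hand-built molecule records (no chemistry toolkit needed) and a cache of
# bridge-derived fixtures shared across test files.

make_record <- function(positions, bonds, features = NULL, labels = NULL,
                        symbols = NULL, mol_id = "fixture", feat_seed = 1L) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(features))
    features <- ffinet:::with_seed(feat_seed,
                                   matrix(stats::rnorm(n * ffinet_n_features()),
                                          n, ffinet_n_features()))
  if (is.null(bonds) || length(bonds) == 0) bonds <- matrix(integer(0), 0, 2)
  bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 2)
  structure(list(mol_id = mol_id, smiles = NULL, n_atoms = as.integer(n),
                 symbols = symbols %||% rep("C", n),
                 atom_features = features, positions = positions,
                 bonds = bonds, bond_orders = rep(1L, nrow(bonds)),
                 labels = labels,
                 label_mask = if (is.null(labels)) NULL else !is.na(labels),
                 feature_version = "test"),
            class = "ffinet_molecule")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a staggered butane-like chain with nondegenerate dihedral
chain4_record <- function(labels = NULL) {
  make_record(rbind(c(0, 1, 0), c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1, 1)),
              rbind(c(1, 2), c(2, 3), c(3, 4)), labels = labels)
}

random_conformation <- function(n, seed) {
  # random positions with a minimum separation, avoiding degenerate geometry
  ffinet:::with_seed(seed, {
    repeat {
      pos <- matrix(stats::runif(n * 3, -4, 4), n, 3)
      d <- as.matrix(stats::dist(pos))
      if (min(d[upper.tri(d)]) > 0.9) break
    }
    pos
  })
}

random_connected_graph <- function(n, seed) {
  ffinet:::with_seed(seed, {
    bonds <- cbind(2:n, vapply(2:n, function(v) sample(v - 1L, 1), integer(1)))
    extra <- utils::combn(n, 2)
    is_tree <- apply(extra, 2, function(e)
      any(bonds[, 1] == e[2] & bonds[, 2] == e[1] |
            bonds[, 1] == e[1] & bonds[, 2] == e[2]))
    pool <- extra[, !is_tree, drop = FALSE]
    n_extra <- if (ncol(pool)) sample(0:min(3, ncol(pool)), 1) else 0L
    if (n_extra > 0) {
      pick <- sample(ncol(pool), n_extra)
      bonds <- rbind(bonds, t(pool[, pick, drop = FALSE]))
    }
    matrix(as.integer(bonds), ncol = 2)
  })
}

path_set <- function(m) {
  if (nrow(m) == 0) return(character(0))
  sort(apply(m, 1, paste, collapse = "-"))
}

random_rotation <- function(seed) {
  ffinet:::with_seed(seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

tiny_config <- function(hidden_dim = 8L, n_heads = 2L, n_layers = 2L,
                        dropout = 0, seed = 7L, ...) {
  ffinet_config(hidden_dim = hidden_dim, n_heads = n_heads,
                n_layers = n_layers, dropout = dropout, seed = seed, ...)
}

# bridge-derived fixtures, computed once per test run
.fixture_env <- new.env(parent = emptyenv())

fixture_molecules <- function() {
  if (is.null(.fixture_env$mols)) {
    smiles <- c(ethane = "CC", ethanol = "CCO", propane = "CCC",
                butane = "CCCC", benzene = "c1ccccc1",
                cyclohexane = "C1CCCCC1", toluene = "Cc1ccccc1")
    .fixture_env$mols <- embed_conformers(unname(smiles),
                                          seeds = 100L + seq_along(smiles))
    names(.fixture_env$mols) <- names(smiles)
  }
  .fixture_env$mols
}

fixture_dataset <- function() {
  if (is.null(.fixture_env$ds))
    .fixture_env$ds <- make_dataset(60, seed = 3, noise_sd = 0.05)
  .fixture_env$ds
}
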