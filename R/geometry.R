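#' Internal coordinates along indexed paths
#'
#' Distances, valence angles and signed dihedrals for the atom tuples of a
#' k-hop index, plus their expansion into the force-field embedding bases.
#' All distances are in Angstrom, angles and dihedrals in radians.
#'
#' @name geometry
NULL

#' Euclidean distances for atom pairs
#'
#' @param positions numeric matrix `n x 3` of coordinates (Angstrom).
#' @param pairs integer matrix with columns (i, j).
#' @return numeric vector of distances, one per row of `pairs`.
#' @export
path_distances <- function(positions, pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0) return(numeric(0))
  d <- positions[pairs[, 1], , drop = FALSE] - positions[pairs[, 2], , drop = FALSE]
  r <- sqrt(rowSums(d * d))
  if (any(r < 1e-6)) {
    bad <- which(r < 1e-6)[1]
    stop_config(sprintf("degenerate geometry: atoms %d and %d are coincident",
                        pairs[bad, 1], pairs[bad, 2]))
  }
  r
}

#' Valence angles at the middle atom of three-atom chains
#'
#' The angle at vertex m between rays m->i and m->j, via the arc-cosine of
#' the clamped normalized dot product; always in [0, pi].
#'
#' @param positions numeric matrix `n x 3`.
#' @param triples integer matrix with columns (i, m, j).
#' @return numeric vector of angles in radians.
#' @export
path_angles <- function(positions, triples) {
  triples <- as.matrix(triples)
  if (nrow(triples) == 0) return(numeric(0))
  u <- positions[triples[, 1], , drop = FALSE] - positions[triples[, 2], , drop = FALSE]
  v <- positions[triples[, 3], , drop = FALSE] - positions[triples[, 2], , drop = FALSE]
  nu <- sqrt(rowSums(u * u)); nv <- sqrt(rowSums(v * v))
  if (any(nu < 1e-6) || any(nv < 1e-6))
    stop_config("degenerate geometry: zero-length ray in angle computation")
  acos(clamp(rowSums(u * v) / (nu * nv), -1, 1))
}

#' Signed dihedral angles of four-atom chains
#'
#' The dihedral between plane (i, a, b) and plane (a, b, j) about the central
#' a-b bond, with the right-handed two-argument arctangent convention:
#' phi = atan2((n1 x n2) . b_hat, n1 . n2) where n1 = b1 x b2, n2 = b2 x b3
#' and b1, b2, b3 are the successive chain displacement vectors. The result
#' lies in (-pi, pi], is unchanged by reversing the chain, and changes sign
#' under reflection. A chain with a collinear triple has no defined dihedral:
#' those entries are returned as 0 with a warning.
#'
#' @param positions numeric matrix `n x 3`.
#' @param quads integer matrix with columns (i, a, b, j).
#' @return numeric vector of signed dihedrals in radians.
#' @export
path_dihedrals <- function(positions, quads) {
  quads <- as.matrix(quads)
  if (nrow(quads) == 0) return(numeric(0))
  b1 <- positions[quads[, 2], , drop = FALSE] - positions[quads[, 1], , drop = FALSE]
  b2 <- positions[quads[, 3], , drop = FALSE] - positions[quads[, 2], , drop = FALSE]
  b3 <- positions[quads[, 4], , drop = FALSE] - positions[quads[, 3], , drop = FALSE]
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  b2n <- sqrt(rowSums(b2 * b2))
  if (any(b2n < 1e-6))
    stop_config("degenerate geometry: zero-length central bond in dihedral")
  collinear <- sqrt(rowSums(n1 * n1)) < 1e-8 | sqrt(rowSums(n2 * n2)) < 1e-8
  y <- rowSums(row_cross(n1, n2) * (b2 / b2n))
  x <- rowSums(n1 * n2)
  phi <- atan2(y, x)
  if (any(collinear)) {
    warning(sprintf("%d dihedral(s) undefined (collinear triple); set to 0",
                    sum(collinear)), call. = FALSE)
    phi[collinear] <- 0
  }
  phi
}

#' @noRd
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Force-field embedding bases
#'
#' Elementary expansions of internal coordinates, extracted from the
#' functional form of the OPLS potential energy terms: the harmonic bond
#' term yields \{r, r^2\}, the harmonic angle term \{theta, theta^2\}, the
#' three-fold torsion series \{cos phi, cos 2phi, cos 3phi, sin phi,
#' sin 2phi, sin 3phi\}, and the Coulomb + Lennard-Jones nonbonded term
#' \{r^-1, r^-12, r^-6\}. Only the functional forms are used; no force-field
#' parameters enter the model.
#'
#' Distances feeding inverse powers are clamped below at `clamp_min`
#' (default 0.8 Angstrom, under any physical heavy-atom separation) so that
#' r^-12 cannot blow up on distorted conformers.
#'
#' @param r distances (Angstrom); `theta` angles and `phi` dihedrals in
#'   radians. Vectors of any length.
#' @param clamp_min lower distance clamp for inverse powers.
#' @return a matrix with one row per input value and the listed columns.
#' @examples
#' torsion_basis(0)            # (1, 1, 1, 0, 0, 0)
#' nonbonded_basis(2)          # (0.5, 2^-12, 2^-6)
#' @export
bonded_basis <- function(r) {
  cbind(r = r, r2 = r^2)
}

#' @rdname bonded_basis
#' @param theta valence angles in radians.
#' @export
angle_basis <- function(theta) {
  cbind(theta = theta, theta2 = theta^2)
}

#' @rdname bonded_basis
#' @param phi signed dihedrals in radians.
#' @export
torsion_basis <- function(phi) {
  cbind(cos1 = cos(phi), cos2 = cos(2 * phi), cos3 = cos(3 * phi),
        sin1 = sin(phi), sin2 = sin(2 * phi), sin3 = sin(3 * phi))
}

#' @rdname bonded_basis
#' @export
nonbonded_basis <- function(r, clamp_min = 0.8) {
  rc <- pmax(r, clamp_min)
  cbind(rinv = 1 / rc, rinv12 = rc^-12, rinv6 = rc^-6)
}

#' Assemble the per-path spatial basis of a molecule
#'
#' Rows align 1:1 with the hop lists of `index`: `m1` holds the bonded basis
#' of each 1-hop pair (2 columns); `m2` the angle basis of each three-atom
#' chain concatenated with the nonbonded basis of its end-pair i...j distance
#' (5 columns); `m3` the torsion basis of each four-atom chain concatenated
#' with the nonbonded basis of its end-pair distance (9 columns).
#'
#' @param record an `ffinet_molecule` (or any list with a `positions` matrix).
#' @param index an `ffinet_khop` built from the record's bonds.
#' @param clamp_min distance clamp for inverse powers.
#' @return an object of class `ffinet_basis`: list of matrices `m1`, `m2`,
#'   `m3`.
#' @export
assemble_basis <- function(record, index, clamp_min = 0.8) {
  pos <- record$positions
  m1 <- if (nrow(index$hop1)) bonded_basis(path_distances(pos, index$hop1))
        else matrix(numeric(0), 0, 2)
  if (nrow(index$hop2)) {
    theta <- path_angles(pos, index$hop2)
    r_end <- path_distances(pos, index$hop2[, c(1, 3), drop = FALSE])
    m2 <- cbind(angle_basis(theta), nonbonded_basis(r_end, clamp_min))
  } else m2 <- matrix(numeric(0), 0, 5)
  if (nrow(index$hop3)) {
    phi <- path_dihedrals(pos, index$hop3)
    r_end <- path_distances(pos, index$hop3[, c(1, 4), drop = FALSE])
    m3 <- cbind(torsion_basis(phi), nonbonded_basis(r_end, clamp_min))
  } else m3 <- matrix(numeric(0), 0, 9)
  structure(list(m1 = m1, m2 = m2, m3 = m3), class = "ffinet_basis")
}

#' Per-column standardization statistics for spatial bases
#'
#' The basis columns live on very different scales (r^2 of order tens,
#' r^-12 of order 1e-4), so each column is z-scored with statistics frozen
#' from the training split before entering the network.
#'
#' @param bases list of `ffinet_basis` objects (the training split).
#' @return list with per-hop `mean` and `sd` vectors (class
#'   `ffinet_basis_stats`).
#' @export
basis_stats <- function(bases) {
  out <- lapply(c("m1", "m2", "m3"), function(nm) {
    stacked <- do.call(rbind, lapply(bases, `[[`, nm))
    if (is.null(stacked) || nrow(stacked) == 0) {
      nc <- c(m1 = 2L, m2 = 5L, m3 = 9L)[[nm]]
      list(mean = rep(0, nc), sd = rep(1, nc))
    } else {
      s <- unname(apply(stacked, 2, stats::sd))
      list(mean = unname(colMeans(stacked)), sd = ifelse(s < 1e-8, 1, s))
    }
  })
  names(out) <- c("m1", "m2", "m3")
  structure(out, class = "ffinet_basis_stats")
}

#' @rdname basis_stats
#' @param basis an `ffinet_basis` to standardize.
#' @param stats statistics from [basis_stats()]; NULL leaves the basis as-is.
#' @export
standardize_basis <- function(basis, stats) {
  if (is.null(stats)) return(basis)
  for (nm in c("m1", "m2", "m3")) {
    m <- basis[[nm]]
    if (nrow(m)) {
      basis[[nm]] <- sweep(sweep(m, 2, stats[[nm]]$mean), 2, stats[[nm]]$sd, "/")
    }
  }
  basis
}
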