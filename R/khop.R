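#' k-hop path indexes over the bonded graph
#'
#' A molecule's receptive field is fixed at three hops: a 1-hop path is a
#' bonded pair, a 2-hop path a three-atom bonded chain (carrying a valence
#' angle), a 3-hop path a four-atom bonded chain (carrying a dihedral).
#' All paths are directed -- column 1 is the target atom i, the last column
#' the source atom j -- and simple (all atoms distinct). Every path appears
#' together with its reversal, so `hop1` has exactly twice as many rows as
#' there are bonds.
#'
#' Membership is by path length, not shortest-path distance: in a ring a
#' bonded neighbour is also the endpoint of a 2-hop path and both entries
#' are kept, each carrying its own geometry, unless `dedupe_hops = TRUE`
#' restricts hop k to atom pairs at shortest-path distance exactly k.
#'
#' @param bonds integer matrix with two columns of 1-based atom indices (one
#'   row per undirected bond), or a zero-row matrix / NULL for no bonds.
#' @param n_atoms number of atoms in the molecule.
#' @param dedupe_hops if TRUE, drop hop-k paths whose endpoints are closer
#'   than k along the graph.
#' @return an object of class `ffinet_khop`: a list with integer matrices
#'   `hop1` (m x 2), `hop2` (m x 3), `hop3` (m x 4), rows in lexicographic
#'   order.
#' @examples
#' idx <- build_khop_index(rbind(c(1, 2), c(2, 3)), 3)  # propane skeleton
#' nrow(idx$hop2)  # 2 directed angle chains
#' @export
build_khop_index <- function(bonds, n_atoms, dedupe_hops = FALSE) {
  bonds <- normalize_bonds(bonds, n_atoms)
  adj <- vector("list", n_atoms)
  for (v in seq_len(n_atoms)) adj[[v]] <- integer(0)
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
    adj <- lapply(adj, sort)
  }

  hop1 <- vector("list", n_atoms)
  for (i in seq_len(n_atoms)) {
    if (length(adj[[i]]))
      hop1[[i]] <- cbind(i, adj[[i]])
  }
  hop1 <- rbind_paths(hop1, 2L)

  hop2 <- list()
  if (nrow(hop1) > 0) {
    hop2 <- lapply(seq_len(nrow(hop1)), function(r) {
      i <- hop1[r, 1]; m <- hop1[r, 2]
      js <- setdiff(adj[[m]], i)
      if (length(js)) cbind(i, m, js) else NULL
    })
  }
  hop2 <- rbind_paths(hop2, 3L)

  hop3 <- list()
  if (nrow(hop2) > 0) {
    hop3 <- lapply(seq_len(nrow(hop2)), function(r) {
      i <- hop2[r, 1]; m <- hop2[r, 2]; j <- hop2[r, 3]
      ls <- setdiff(adj[[j]], c(i, m, j))
      if (length(ls)) cbind(i, m, j, ls) else NULL
    })
  }
  hop3 <- rbind_paths(hop3, 4L)

  if (dedupe_hops && n_atoms > 0) {
    dist <- bfs_distances(adj, n_atoms)
    keep2 <- dist[cbind(hop2[, 1], hop2[, 3])] == 2L
    keep3 <- dist[cbind(hop3[, 1], hop3[, 4])] == 3L
    hop2 <- hop2[keep2, , drop = FALSE]
    hop3 <- hop3[keep3, , drop = FALSE]
  }

  structure(list(hop1 = hop1, hop2 = hop2, hop3 = hop3,
                 n_atoms = as.integer(n_atoms),
                 dedupe_hops = isTRUE(dedupe_hops)),
            class = "ffinet_khop")
}

#' @noRd
rbind_paths <- function(chunks, width) {
  chunks <- Filter(Negate(is.null), chunks)
  if (!length(chunks)) {
    m <- matrix(integer(0), nrow = 0, ncol = width)
  } else {
    m <- do.call(rbind, chunks)
    storage.mode(m) <- "integer"
  }
  dimnames(m) <- NULL
  m
}

#' @noRd
normalize_bonds <- function(bonds, n_atoms) {
  if (is.null(bonds) || length(bonds) == 0)
    return(matrix(integer(0), 0, 2))
  bonds <- as.matrix(bonds)[, 1:2, drop = FALSE]
  storage.mode(bonds) <- "integer"
  if (any(bonds < 1L) || any(bonds > n_atoms))
    stop_config("bond indices must lie in [1, n_atoms]")
  if (any(bonds[, 1] == bonds[, 2]))
    stop_config("self-bonds are not allowed")
  key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  if (anyDuplicated(key))
    stop_config("duplicate bonds are not allowed")
  bonds
}

#' @noRd
bfs_distances <- function(adj, n) {
  d <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- adj[[v]][is.na(dist[adj[[v]]])]
        dist[nb] <- dist[v] + 1L
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    d[s, ] <- dist
  }
  d
}

#' Exhaustive simple-path enumeration (test oracle)
#'
#' Depth-first enumeration of all directed simple paths of length exactly
#' `k`, written independently of [build_khop_index()] so the two can be
#' cross-checked. Intended for small graphs only.
#'
#' @param bonds two-column bond matrix (1-based).
#' @param k path length, one of 1, 2, 3.
#' @param n_atoms number of atoms; inferred from `bonds` if missing.
#' @return integer matrix with `k + 1` columns, one row per directed path.
#' @export
enumerate_paths_oracle <- function(bonds, k, n_atoms = NULL) {
  if (!k %in% 1:3) stop_config("k must be 1, 2 or 3")
  if (is.null(bonds) || length(bonds) == 0)
    return(matrix(integer(0), 0, k + 1L))
  bonds <- as.matrix(bonds)[, 1:2, drop = FALSE]
  n <- n_atoms %||% max(bonds)
  neighbours <- function(v)
    sort(unique(c(bonds[bonds[, 1] == v, 2], bonds[bonds[, 2] == v, 1])))
  out <- list()
  extend <- function(path) {
    if (length(path) == k + 1L) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (nb in neighbours(path[length(path)]))
      if (!nb %in% path) extend(c(path, nb))
  }
  for (s in seq_len(n)) extend(s)
  if (!length(out)) return(matrix(integer(0), 0, k + 1L))
  m <- do.call(rbind, out)
  storage.mode(m) <- "integer"
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}
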