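# Forward pass of the network. The architecture per layer, per hop k:
#
#   e_p  = a_k' LeakyReLU( (sum_{r in p} W_r h'_r) * (W_k m_k[p]) )
#   alpha = softmax of e over all hop-k paths sharing the target atom
#   o_k[i] = sum_p alpha_p (W_src h'_{source(p)})
#
# with h'_r the node embedding multiplied elementwise by the hop positional
# encoding, W_r indexed by the node's position along the path, and all of it
# computed per head on hidden_dim/n_heads column slices. Axial attention then
# mixes the hop outputs per node, followed by dropout, a residual connection
# and layer normalization. Readout is a gated weighted sum concatenated with
# max pooling, followed by a two-layer MLP.

#' @noRd
prepare_molecule <- function(record, config, clamp_min = 0.8) {
  index <- build_khop_index(record$bonds, record$n_atoms,
                            dedupe_hops = config$dedupe_hops)
  basis <- assemble_basis(record, index, clamp_min = clamp_min)
  list(x = record$atom_features, n_atoms = record$n_atoms,
       paths = list(index$hop1, index$hop2, index$hop3),
       basis = list(basis$m1, basis$m2, basis$m3),
       basis1_nb = NULL,
       labels = record$labels, label_mask = record$label_mask,
       mol_id = record$mol_id)
}

#' Assemble a mini-batch as one disjoint graph
#'
#' Concatenates prepared molecule inputs with offset atom indices; grouped
#' softmax and per-graph pooling make disjoint molecules batch exactly.
#'
#' @param inputs list of prepared inputs (see [prepare_molecule]).
#' @param stats basis standardization statistics or NULL.
#' @param config an `ffinet_config`.
#' @return a batch list consumed by the forward/backward passes.
#' @keywords internal
assemble_batch <- function(inputs, stats = NULL, config) {
  n_per <- vapply(inputs, `[[`, integer(1), "n_atoms")
  offsets <- c(0L, cumsum(n_per))[seq_along(inputs)]
  n <- sum(n_per)
  x <- do.call(rbind, lapply(inputs, `[[`, "x"))
  graph_id <- rep(seq_along(inputs), n_per)

  paths <- vector("list", 3L)
  basis <- vector("list", 3L)
  for (k in 1:3) {
    pk <- lapply(seq_along(inputs), function(g) {
      p <- inputs[[g]]$paths[[k]]
      if (nrow(p)) p + offsets[g] else p
    })
    paths[[k]] <- do.call(rbind, pk)
    basis[[k]] <- do.call(rbind, lapply(inputs, function(gi) gi$basis[[k]]))
  }
  basis1_nb <- NULL
  if (any(!vapply(inputs, function(gi) is.null(gi$basis1_nb), logical(1)))) {
    basis1_nb <- do.call(rbind, lapply(inputs, function(gi)
      gi$basis1_nb %||% matrix(0, nrow(gi$paths[[1]]), NONBONDED_NCOL)))
  }
  nb_rows <- if (!is.null(basis1_nb)) rowSums(abs(basis1_nb)) > 0 else NULL
  if (!is.null(stats)) {
    sb <- standardize_basis(structure(list(m1 = basis[[1]], m2 = basis[[2]],
                                           m3 = basis[[3]]),
                                      class = "ffinet_basis"), stats)
    basis <- list(sb$m1, sb$m2, sb$m3)
    if (!is.null(basis1_nb)) {
      # bonded-basis columns of nonbonded rows (and vice versa) must stay 0
      basis[[1]][nb_rows, ] <- 0
      if (!is.null(stats$m1_nb) && any(nb_rows)) {
        scaled <- sweep(sweep(basis1_nb[nb_rows, , drop = FALSE], 2,
                              stats$m1_nb$mean), 2, stats$m1_nb$sd, "/")
        basis1_nb[nb_rows, ] <- scaled
      }
    }
  }

  groups <- vector("list", 3L)
  has <- matrix(FALSE, n, 3L)
  for (k in 1:3) {
    g <- paths[[k]][, 1]
    ug <- sort(unique(g))
    groups[[k]] <- list(g = g, ug = ug, gidx = match(g, ug))
    has[ug, k] <- TRUE
  }

  labels <- do.call(rbind, lapply(inputs, function(gi)
    matrix(gi$labels %||% NA_real_, nrow = 1)))
  mask <- !is.na(labels)

  list(x = x, n_atoms = n, graph_id = graph_id, n_graphs = length(inputs),
       graph_atoms = split(seq_len(n), graph_id),
       paths = paths, basis = basis, basis1_nb = basis1_nb,
       groups = groups, has = has, labels = labels, label_mask = mask)
}

# single-hop attention; returns output plus everything backward needs
#' @noRd
hop_forward <- function(h, k, paths, mk, mk_nb, grp, hp, config) {
  d <- config$hidden_dim; nh <- config$n_heads
  cols <- head_cols(d, nh)
  n <- nrow(h)
  np <- nrow(paths)
  pe <- positional_encoding(k, d)
  if (np == 0) {
    return(list(O = matrix(0, n, d), empty = TRUE, pe = pe))
  }
  hpm <- sweep(h, 2, pe, "*")

  Z <- matrix(0, np, d)
  for (r in seq_len(k + 1L))
    Z <- Z + bd_mm(hpm[paths[, r], , drop = FALSE], hp$Wr[[r]], cols, cols)
  M <- matrix(0, np, d)
  for (t in seq_len(nh)) M[, cols[[t]]] <- mk %*% hp$Wk[, , t]
  if (!is.null(mk_nb) && !is.null(hp$Wk_nb)) {
    for (t in seq_len(nh))
      M[, cols[[t]]] <- M[, cols[[t]]] + mk_nb %*% hp$Wk_nb[, , t]
  }
  U <- Z * M
  D <- (U > 0) + config$leaky_slope * (U <= 0)
  L <- U * D
  escore <- matrix(0, np, nh)
  for (t in seq_len(nh)) escore[, t] <- L[, cols[[t]], drop = FALSE] %*% hp$a[, t]
  alpha <- softmax_grouped(escore, grp$gidx, length(grp$ug))
  V <- bd_mm(hpm[paths[, k + 1L], , drop = FALSE], hp$Wsrc, cols, cols)
  alpha_exp <- alpha[, rep(seq_len(nh), each = d %/% nh), drop = FALSE]
  o_raw <- matrix(0, n, d)
  o_raw[grp$ug, ] <- rowsum_padded(V * alpha_exp, grp$gidx, length(grp$ug))
  O <- o_raw %*% hp$WO
  list(O = O, o_raw = o_raw, Z = Z, M = M, D = D, alpha = alpha, V = V,
       escore = escore, pe = pe, empty = FALSE)
}

# one attention layer: k-hop attention, axial combination, dropout,
# residual, layer norm
#' @noRd
layer_forward <- function(h, lp, batch, config, training = FALSE) {
  d <- config$hidden_dim
  K <- config$use_hops
  n <- nrow(h)
  hop_caches <- list()
  O_list <- list()
  for (k in K) {
    hc <- hop_forward(h, k, batch$paths[[k]], batch$basis[[k]],
                      if (k == 1L) batch$basis1_nb else NULL,
                      batch$groups[[k]], lp$hops[[as.character(k)]], config)
    hop_caches[[as.character(k)]] <- hc
    O_list[[as.character(k)]] <- hc$O
  }
  nK <- length(K)
  hasK <- batch$has[, K, drop = FALSE]
  if (config$use_axial) {
    S <- matrix(0, n, nK)
    for (ki in seq_len(nK))
      S[, ki] <- rowSums(h * O_list[[ki]]) / sqrt(d)
    expS <- exp(clamp(S, -80, 80))
    expS[!hasK] <- 0
    denom <- rowSums(expS)
    beta <- expS / ifelse(denom > 0, denom, 1)
    h_mid <- matrix(0, n, d)
    for (ki in seq_len(nK)) h_mid <- h_mid + beta[, ki] * O_list[[ki]]
  } else {
    beta <- NULL
    h_mid <- Reduce(`+`, O_list)
  }
  if (training && config$dropout > 0) {
    keep <- 1 - config$dropout
    dmask <- matrix(stats::rbinom(n * d, 1, keep) / keep, n, d)
    h_drop <- h_mid * dmask
  } else {
    dmask <- NULL
    h_drop <- h_mid
  }
  res <- h + h_drop
  mu <- rowMeans(res)
  xc <- res - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + 1e-6)
  xhat <- xc * inv
  h_out <- sweep(xhat, 2, lp$ln_g, "*")
  h_out <- sweep(h_out, 2, lp$ln_b, "+")
  list(h = h_out,
       cache = list(h_in = h, hops = hop_caches, O_list = O_list,
                    beta = beta, hasK = hasK, dmask = dmask,
                    xhat = xhat, inv = inv))
}

#' @noRd
nn_forward <- function(params, config, batch, training = FALSE,
                       record_attention = FALSE) {
  d <- config$hidden_dim
  n <- batch$n_atoms
  h <- batch$x %*% params$emb$W +
    matrix(params$emb$b, n, d, byrow = TRUE)
  layers_cache <- vector("list", config$n_layers)
  attn <- if (record_attention) list(layers = vector("list", config$n_layers))

  for (l in seq_len(config$n_layers)) {
    lf <- layer_forward(h, params$layers[[l]], batch, config, training)
    layers_cache[[l]] <- lf$cache
    if (record_attention) {
      attn$layers[[l]] <- list(
        alpha = lapply(lf$cache$hops, function(hc)
          if (isTRUE(hc$empty)) NULL else hc$alpha),
        beta = lf$cache$beta, hops = config$use_hops)
    }
    h <- lf$h
  }

  # readout: gated weighted sum + max pooling, concatenated
  g_score <- as.numeric(h %*% params$readout$w) + params$readout$b
  g <- sigmoid(g_score)
  sumvec <- rowsum_padded(h * g, batch$graph_id, batch$n_graphs)
  maxvec <- matrix(0, batch$n_graphs, d)
  argmax <- matrix(0L, batch$n_graphs, d)
  for (gi in seq_len(batch$n_graphs)) {
    idx <- batch$graph_atoms[[gi]]
    sub <- h[idx, , drop = FALSE]
    am <- max.col(t(sub), ties.method = "first")
    argmax[gi, ] <- idx[am]
    maxvec[gi, ] <- sub[cbind(am, seq_len(d))]
  }
  Gv <- cbind(sumvec, maxvec)
  A1 <- Gv %*% params$mlp$W1 +
    matrix(params$mlp$b1, batch$n_graphs, d, byrow = TRUE)
  R1 <- A1 * (A1 > 0)
  out <- R1 %*% params$mlp$W2 +
    matrix(params$mlp$b2, batch$n_graphs, config$n_tasks, byrow = TRUE)

  if (record_attention) {
    attn$gate <- g
    attn$h_final <- h
    attn$paths <- batch$paths
  }
  list(out = out,
       cache = list(layers = layers_cache, hN = h, g = g, g_score = g_score,
                    sumvec = sumvec, maxvec = maxvec, argmax = argmax,
                    Gv = Gv, A1 = A1, R1 = R1),
       attn = attn)
}

# task losses with gradients; labels may carry NA handled via mask
#' @noRd
loss_and_grad <- function(out, labels, mask, task) {
  y <- labels
  y[!mask] <- 0
  m <- mask * 1
  n_eff <- max(sum(m), 1)
  if (task == "regression") {
    diff <- (out - y) * m
    list(loss = sum(diff^2) / n_eff, dout = 2 * diff / n_eff)
  } else {
    # numerically stable BCE-with-logits, masked per task
    x <- out
    l_elem <- pmax(x, 0) - x * y + log1p(exp(-abs(x)))
    p <- sigmoid(x)
    list(loss = sum(l_elem * m) / n_eff, dout = (p - y) * m / n_eff)
  }
}
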