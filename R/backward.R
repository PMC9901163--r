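# Reverse-mode gradients, mirroring forward.R exactly. Verified against
# central finite differences in the test suite (test-model.R).

#' @noRd
hop_backward <- function(dO, h_in, k, paths, mk, mk_nb, grp, hp, hc, config) {
  d <- config$hidden_dim; nh <- config$n_heads; dh <- d %/% nh
  cols <- head_cols(d, nh)
  np <- nrow(paths)
  nug <- length(grp$ug)
  pe <- hc$pe
  hpm <- sweep(h_in, 2, pe, "*")

  g <- list(Wr = lapply(seq_len(k + 1L), function(r) array(0, c(dh, dh, nh))),
            Wsrc = array(0, c(dh, dh, nh)),
            Wk = array(0, dim(hp$Wk)),
            a = matrix(0, dh, nh),
            WO = matrix(0, d, d))
  if (!is.null(hp$Wk_nb)) g$Wk_nb <- array(0, dim(hp$Wk_nb))

  g$WO <- t(hc$o_raw) %*% dO
  do_raw <- dO %*% t(hp$WO)
  dAV <- do_raw[paths[, 1], , drop = FALSE]
  alpha_exp <- hc$alpha[, rep(seq_len(nh), each = dh), drop = FALSE]
  dV <- dAV * alpha_exp
  dalpha <- matrix(0, np, nh)
  dae <- dAV * hc$V
  for (t in seq_len(nh)) dalpha[, t] <- rowSums(dae[, cols[[t]], drop = FALSE])

  srep <- rowsum_padded(hc$alpha * dalpha, grp$gidx, nug)[grp$gidx, , drop = FALSE]
  descore <- hc$alpha * (dalpha - srep)

  U <- hc$Z * hc$M
  L <- U * hc$D
  dL <- matrix(0, np, d)
  for (t in seq_len(nh)) {
    dL[, cols[[t]]] <- outer(descore[, t], hp$a[, t])
    g$a[, t] <- crossprod(L[, cols[[t]], drop = FALSE], descore[, t])
  }
  dU <- dL * hc$D
  dZ <- dU * hc$M
  dM <- dU * hc$Z
  for (t in seq_len(nh)) {
    g$Wk[, , t] <- crossprod(mk, dM[, cols[[t]], drop = FALSE])
    if (!is.null(hp$Wk_nb))
      g$Wk_nb[, , t] <- crossprod(mk_nb, dM[, cols[[t]], drop = FALSE])
  }

  dhpm <- matrix(0, nrow(h_in), d)
  add_scatter <- function(dG, rows) {
    acc <- rowsum(dG, rows)
    at <- as.integer(rownames(acc))
    dhpm[at, ] <<- dhpm[at, , drop = FALSE] + acc
  }
  # value path (source node)
  G_last <- hpm[paths[, k + 1L], , drop = FALSE]
  dG_last <- matrix(0, np, d)
  for (t in seq_len(nh)) {
    g$Wsrc[, , t] <- crossprod(G_last[, cols[[t]], drop = FALSE],
                               dV[, cols[[t]], drop = FALSE])
    dG_last[, cols[[t]]] <- dV[, cols[[t]], drop = FALSE] %*% t(hp$Wsrc[, , t])
  }
  add_scatter(dG_last, paths[, k + 1L])
  # score path (every node along the path)
  for (r in seq_len(k + 1L)) {
    G_r <- hpm[paths[, r], , drop = FALSE]
    dG_r <- matrix(0, np, d)
    for (t in seq_len(nh)) {
      g$Wr[[r]][, , t] <- crossprod(G_r[, cols[[t]], drop = FALSE],
                                    dZ[, cols[[t]], drop = FALSE])
      dG_r[, cols[[t]]] <- dZ[, cols[[t]], drop = FALSE] %*% t(hp$Wr[[r]][, , t])
    }
    add_scatter(dG_r, paths[, r])
  }
  dh <- sweep(dhpm, 2, pe, "*")
  list(grads = g, dh = dh)
}

#' @noRd
nn_backward <- function(params, config, batch, cache, dout) {
  d <- config$hidden_dim
  K <- config$use_hops
  n <- batch$n_atoms
  grads <- rapply(params, function(x) x * 0, how = "replace")

  # MLP head
  grads$mlp$W2 <- crossprod(cache$R1, dout)
  grads$mlp$b2 <- colSums(dout)
  dR1 <- dout %*% t(params$mlp$W2)
  dA1 <- dR1 * (cache$A1 > 0)
  grads$mlp$W1 <- crossprod(cache$Gv, dA1)
  grads$mlp$b1 <- colSums(dA1)
  dGv <- dA1 %*% t(params$mlp$W1)
  dsum <- dGv[, seq_len(d), drop = FALSE]
  dmax <- dGv[, d + seq_len(d), drop = FALSE]

  # readout
  hN <- cache$hN
  dh <- matrix(0, n, d)
  dweighted <- dsum[batch$graph_id, , drop = FALSE]
  dh <- dh + dweighted * cache$g
  dg <- rowSums(dweighted * hN)
  dgs <- dg * cache$g * (1 - cache$g)
  grads$readout$w <- as.numeric(crossprod(hN, dgs))
  grads$readout$b <- sum(dgs)
  dh <- dh + outer(dgs, params$readout$w)
  idx <- cbind(as.vector(cache$argmax),
               rep(seq_len(d), each = batch$n_graphs))
  dh[idx] <- dh[idx] + as.vector(dmax)

  # layers, reversed
  for (l in rev(seq_len(config$n_layers))) {
    lc <- cache$layers[[l]]
    lp <- params$layers[[l]]
    dy <- dh
    grads$layers[[l]]$ln_g <- colSums(dy * lc$xhat)
    grads$layers[[l]]$ln_b <- colSums(dy)
    dxhat <- sweep(dy, 2, lp$ln_g, "*")
    dres <- lc$inv * (dxhat - rowMeans(dxhat) -
                        lc$xhat * rowMeans(dxhat * lc$xhat))
    dh <- dres                      # residual branch
    dh_drop <- dres
    dh_mid <- if (is.null(lc$dmask)) dh_drop else dh_drop * lc$dmask

    nK <- length(K)
    dO <- vector("list", nK)
    if (config$use_axial) {
      dbeta <- matrix(0, n, nK)
      for (ki in seq_len(nK)) {
        dO[[ki]] <- dh_mid * lc$beta[, ki]
        dbeta[, ki] <- rowSums(dh_mid * lc$O_list[[ki]])
      }
      sum_term <- rowSums(lc$beta * dbeta)
      dS <- lc$beta * (dbeta - sum_term)
      for (ki in seq_len(nK)) {
        dh <- dh + dS[, ki] * lc$O_list[[ki]] / sqrt(d)
        dO[[ki]] <- dO[[ki]] + dS[, ki] * lc$h_in / sqrt(d)
      }
    } else {
      for (ki in seq_len(nK)) dO[[ki]] <- dh_mid
    }

    for (ki in seq_len(nK)) {
      k <- K[ki]
      hc <- lc$hops[[as.character(k)]]
      if (isTRUE(hc$empty)) next
      hb <- hop_backward(dO[[ki]], lc$h_in, k, batch$paths[[k]],
                         batch$basis[[k]],
                         if (k == 1L) batch$basis1_nb else NULL,
                         batch$groups[[k]],
                         lp$hops[[as.character(k)]], hc, config)
      grads$layers[[l]]$hops[[as.character(k)]] <- hb$grads
      dh <- dh + hb$dh
    }
  }

  grads$emb$W <- crossprod(batch$x, dh)
  grads$emb$b <- colSums(dh)
  grads
}
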