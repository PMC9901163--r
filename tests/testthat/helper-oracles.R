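pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Independent dense-loop implementation of the k-hop attention score
# (plain per-path, per-head scalar loops with a conventional max-shifted
# softmax), used to cross-check the vectorized implementation.

eq2_oracle <- function(h, paths, mk, hp, config, k) {
  d <- config$hidden_dim; nh <- config$n_heads; dh <- d / nh
  n <- nrow(h); np <- nrow(paths)
  pe <- positional_encoding(k, d)
  hp_full <- h * matrix(pe, n, d, byrow = TRUE)
  alpha <- matrix(0, np, nh)
  o_raw <- matrix(0, n, d)
  scores <- matrix(0, np, nh)
  for (t in seq_len(nh)) {
    cols <- ((t - 1) * dh + 1):(t * dh)
    for (p in seq_len(np)) {
      z <- rep(0, dh)
      for (r in seq_len(k + 1)) {
        x <- hp_full[paths[p, r], cols]
        z <- z + as.numeric(x %*% hp$Wr[[r]][, , t])
      }
      mm <- as.numeric(mk[p, ] %*% hp$Wk[, , t])
      u <- z * mm
      l <- ifelse(u > 0, u, config$leaky_slope * u)
      scores[p, t] <- sum(l * hp$a[, t])
    }
    for (i in unique(paths[, 1])) {
      sel <- which(paths[, 1] == i)
      e <- scores[sel, t]
      w <- exp(e - max(e))
      alpha[sel, t] <- w / sum(w)
    }
    for (p in seq_len(np)) {
      i <- paths[p, 1]; j <- paths[p, k + 1]
      v <- as.numeric(hp_full[j, cols] %*% hp$Wsrc[, , t])
      o_raw[i, cols] <- o_raw[i, cols] + alpha[p, t] * v
    }
  }
  list(scores = scores, alpha = alpha, output = o_raw %*% hp$WO)
}
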