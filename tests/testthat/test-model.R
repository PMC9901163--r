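test_that("positional encoding matches its closed form and separates hops", {
  expect_equal(positional_encoding(1, 8)[1], sin(1))
  expect_equal(positional_encoding(2, 4), c(sin(2), cos(2), sin(2 / 100),
                                            cos(2 / 100)))
  pes <- sapply(1:3, positional_encoding, dim = 16)
  expect_gt(min(dist(t(pes))), 0.1)  # pairwise distinct
})

test_that("k-hop attention normalizes per target and handles singletons exactly", {
  cfg <- tiny_config()
  m <- ffinet_model(cfg)
  hp <- m$params$layers[[1]]$hops[["2"]]
  rec <- chain4_record()
  idx <- build_khop_index(rec$bonds, rec$n_atoms)
  basis <- assemble_basis(rec, idx)
  h <- ffinet:::with_seed(3, matrix(stats::rnorm(4 * cfg$hidden_dim), 4))
  att <- khop_attention(h, idx$hop2, basis$m2, hp, cfg, hop = 2)
  # atom 1 has exactly one 2-hop path (1-2-3): alpha = 1
  expect_equal(unname(att$weights[idx$hop2[, 1] == 1, ]),
               rep(1, cfg$n_heads))
  # normalization per target node per head
  for (i in unique(idx$hop2[, 1]))
    expect_equal(unname(colSums(att$weights[idx$hop2[, 1] == i, , drop = FALSE])),
                 rep(1, cfg$n_heads), tolerance = 1e-6)
  # singleton output equals W_O-mixed source projection exactly
  pe <- positional_encoding(2, cfg$hidden_dim)
  dh <- cfg$hidden_dim / cfg$n_heads
  src <- h[3, ] * pe
  v <- unlist(lapply(seq_len(cfg$n_heads), function(t)
    as.numeric(src[((t - 1) * dh + 1):(t * dh)] %*% hp$Wsrc[, , t])))
  expect_equal(att$output[1, ], as.numeric(v %*% hp$WO), tolerance = 1e-12)
  expect_error(khop_attention(h, idx$hop2, basis$m2[-1, ], hp, cfg, hop = 2),
               "misaligned")
})

test_that("vectorized attention equals the dense-loop oracle", {
  for (case in 1:4) {
    n <- c(5, 7, 8, 10)[case]
    bonds <- random_connected_graph(n, seed = 900 + case)
    rec <- make_record(random_conformation(n, 910 + case), bonds,
                       feat_seed = case)
    cfg <- ffinet_config(hidden_dim = 12, n_heads = 3, n_layers = 1,
                         dropout = 0, seed = 20 + case)
    model <- ffinet_model(cfg)
    idx <- build_khop_index(bonds, n)
    basis <- assemble_basis(rec, idx)
    h <- ffinet:::with_seed(case, matrix(stats::rnorm(n * 12), n))
    for (k in 1:3) {
      paths <- list(idx$hop1, idx$hop2, idx$hop3)[[k]]
      if (nrow(paths) == 0) next
      mk <- list(basis$m1, basis$m2, basis$m3)[[k]]
      hp <- model$params$layers[[1]]$hops[[as.character(k)]]
      got <- khop_attention(h, paths, mk, hp, cfg, hop = k)
      ref <- eq2_oracle(h, paths, mk, hp, cfg, k)
      expect_equal(got$scores, ref$scores, tolerance = 1e-6)
      expect_equal(got$weights, ref$alpha, tolerance = 1e-6)
      expect_equal(got$output, ref$output, tolerance = 1e-6)
    }
  }
})

test_that("axial combination obeys its identities", {
  n <- 5; d <- 8
  h <- ffinet:::with_seed(1, matrix(stats::rnorm(n * d), n))
  u <- ffinet:::with_seed(2, matrix(stats::rnorm(n * d), n))
  v <- ffinet:::with_seed(3, matrix(stats::rnorm(n * d), n))
  w <- ffinet:::with_seed(4, matrix(stats::rnorm(n * d), n))
  # single hop: output is that hop regardless of scores
  ax1 <- axial_combine(h, list(u))
  expect_equal(ax1$h_out, u)
  expect_equal(unname(ax1$beta[, 1]), rep(1, n))
  # identical hop outputs: equal weights, unchanged output
  ax2 <- axial_combine(h, list(u, u, u))
  expect_equal(ax2$h_out, u, tolerance = 1e-12)
  expect_equal(unname(ax2$beta), matrix(1 / 3, n, 3), tolerance = 1e-12)
  # no-axial ablation: exact summation
  ax3 <- axial_combine(h, list(u, v, w), use_axial = FALSE)
  expect_identical(ax3$h_out, u + v + w)
  expect_null(ax3$beta)
  # weights normalize; masking removes a hop from the softmax
  ax4 <- axial_combine(h, list(u, v, w))
  expect_equal(unname(rowSums(ax4$beta)), rep(1, n), tolerance = 1e-12)
  has <- cbind(TRUE, FALSE, TRUE)[rep(1, n), , drop = FALSE]
  ax5 <- axial_combine(h, list(u, v, w), has = has)
  expect_equal(unname(ax5$beta[, 2]), rep(0, n))
})

test_that("a layer is deterministic, reduces to LayerNorm without paths, and is equivariant", {
  cfg <- tiny_config()
  model <- ffinet_model(cfg)
  lp <- model$params$layers[[1]]
  rec <- chain4_record()
  idx <- build_khop_index(rec$bonds, rec$n_atoms)
  basis <- assemble_basis(rec, idx)
  h <- ffinet:::with_seed(11, matrix(stats::rnorm(4 * 8), 4))
  out1 <- ffinet_layer(h, idx, basis, lp, cfg)
  out2 <- ffinet_layer(h, idx, basis, lp, cfg)
  expect_identical(out1, out2)

  # no bonds -> every hop empty -> residual path only: LayerNorm(h)
  idx0 <- build_khop_index(NULL, 4)
  basis0 <- assemble_basis(make_record(rec$positions, NULL), idx0)
  out0 <- ffinet_layer(h, idx0, basis0, lp, cfg)
  mu <- rowMeans(h); xc <- h - mu
  ln <- xc / sqrt(rowMeans(xc^2) + 1e-6)
  expect_equal(out0, sweep(sweep(ln, 2, lp$ln_g, "*"), 2, lp$ln_b, "+"),
               tolerance = 1e-12)

  # permuting atoms permutes the layer output identically
  perm <- c(3, 1, 4, 2)
  bonds_p <- matrix(match(rec$bonds, perm), ncol = 2)
  idx_p <- build_khop_index(bonds_p, 4)
  rec_p <- make_record(rec$positions[perm, ], bonds_p)
  basis_p <- assemble_basis(rec_p, idx_p)
  out_p <- ffinet_layer(h[perm, ], idx_p, basis_p, lp, cfg)
  expect_equal(out_p, out1[perm, ], tolerance = 1e-10)
})

test_that("readout and head obey their contracts", {
  cfg <- tiny_config()
  model <- ffinet_model(cfg)
  rp <- model$params$readout
  h1 <- matrix(ffinet:::with_seed(1, stats::rnorm(8)), 1)
  r1 <- readout(h1, rp)
  g1 <- attr(r1, "gate")
  expect_equal(as.numeric(r1), c(g1 * h1[1, ], h1[1, ]))
  # duplicated identical atoms: max half unchanged
  r2 <- readout(rbind(h1, h1), rp)
  expect_equal(as.numeric(r2)[9:16], as.numeric(r1)[9:16])
  # permutation invariance
  h4 <- ffinet:::with_seed(2, matrix(stats::rnorm(4 * 8), 4))
  expect_equal(as.numeric(readout(h4, rp)),
               as.numeric(readout(h4[c(3, 1, 4, 2), ], rp)))
  expect_error(readout(h4[0, , drop = FALSE], rp), "empty")

  # zero-weight MLP returns its bias
  mlp0 <- list(W1 = matrix(0, 16, 8), b1 = rep(0, 8),
               W2 = matrix(0, 8, 2), b2 = c(1.5, -2))
  expect_equal(as.numeric(predict_head(as.numeric(r1), mlp0)), c(1.5, -2))
  # shape contracts
  expect_equal(dim(predict_head(rbind(as.numeric(r1), as.numeric(r2)),
                                model$params$mlp)), c(2L, 1L))
  cfg12 <- tiny_config(task = "classification", n_tasks = 12)
  m12 <- ffinet_model(cfg12)
  rec <- chain4_record()
  expect_equal(dim(predict(m12, rec, type = "link")), c(1L, 12L))
})

test_that("predictions are invariant to rigid motions and atom permutations", {
  mols <- lapply(1:20, function(i) {
    n <- 4 + (i %% 5)
    make_record(random_conformation(n, 7000 + i),
                random_connected_graph(n, 7100 + i), feat_seed = i)
  })
  cfg <- ffinet_config(hidden_dim = 16, n_heads = 4, n_layers = 2,
                       dropout = 0, seed = 3)
  model <- ffinet_model(cfg)
  for (i in seq_along(mols)) {
    rec <- mols[[i]]
    p0 <- predict(model, rec, type = "link")
    rot <- random_rotation(8000 + i)
    shift <- ffinet:::with_seed(8200 + i, stats::rnorm(3, sd = 5))
    rec_r <- rec
    rec_r$positions <- sweep(rec$positions %*% rot, 2, shift, "+")
    expect_equal(predict(model, rec_r, type = "link"), p0,
                 tolerance = 1e-4)
    perm <- ffinet:::with_seed(8400 + i, sample(rec$n_atoms))
    rec_p <- rec
    rec_p$positions <- rec$positions[order(perm), ]
    rec_p$atom_features <- rec$atom_features[order(perm), , drop = FALSE]
    rec_p$bonds <- matrix(match(rec$bonds, order(perm)), ncol = 2)
    expect_equal(predict(model, rec_p, type = "link"), p0,
                 tolerance = 1e-5)
  }
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_config()
  model <- ffinet_model(cfg)
  recs <- list(make_record(random_conformation(5, 31),
                           rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(2, 5)),
                           labels = 0.4, feat_seed = 31),
               chain4_record(labels = -0.7))
  prep <- ffinet:::prepare_inputs(recs, cfg)
  batch <- ffinet:::assemble_batch(prep, NULL, cfg)
  params <- model$params
  theta <- flatten_params(params)
  loss_at <- function(th) {
    p <- unflatten_params(th, params)
    fw <- ffinet:::nn_forward(p, cfg, batch)
    ffinet:::loss_and_grad(fw$out, batch$labels, batch$label_mask,
                           cfg$task)$loss
  }
  fw <- ffinet:::nn_forward(params, cfg, batch)
  lg <- ffinet:::loss_and_grad(fw$out, batch$labels, batch$label_mask,
                               cfg$task)
  g <- flatten_params(ffinet:::nn_backward(params, cfg, batch, fw$cache,
                                           lg$dout))
  idx <- ffinet:::with_seed(1, sample(length(theta), 120))
  eps <- 1e-4
  num <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps; up <- loss_at(tp)
    tp[i] <- theta[i] - eps; (up - loss_at(tp)) / (2 * eps)
  }, numeric(1))
  denom <- pmax(abs(num) + abs(g[idx]), 1e-6)
  expect_lt(max(abs(num - g[idx]) / denom), 1e-3)
})

test_that("gradients are finite everywhere and flow to every parameter block", {
  cfg <- ffinet_config(hidden_dim = 8, n_heads = 2, n_layers = 2,
                       dropout = 0, seed = 9)
  model <- ffinet_model(cfg)
  recs <- list(make_record(random_conformation(6, 61),
                           random_connected_graph(6, 62),
                           labels = 1.1, feat_seed = 61),
               make_record(random_conformation(5, 63),
                           random_connected_graph(5, 64),
                           labels = -0.2, feat_seed = 63))
  prep <- ffinet:::prepare_inputs(recs, cfg)
  batch <- ffinet:::assemble_batch(prep, NULL, cfg)
  fw <- ffinet:::nn_forward(model$params, cfg, batch)
  lg <- ffinet:::loss_and_grad(fw$out, batch$labels, batch$label_mask,
                               cfg$task)
  grads <- ffinet:::nn_backward(model$params, cfg, batch, fw$cache, lg$dout)
  expect_true(all(is.finite(flatten_params(grads))))
  check_block <- function(x, path) {
    if (is.list(x)) {
      for (nm in names(x) %||% seq_along(x))
        check_block(x[[nm]], c(path, nm))
    } else {
      expect_gt(sum(abs(x)), 0, label = paste(path, collapse = "/"))
    }
  }
  check_block(grads, "grads")
})

test_that("ablation switches change the computed function", {
  rec <- chain4_record()
  p_full <- predict(ffinet_model(ffinet_config(hidden_dim = 16, n_heads = 2,
                                               n_layers = 2, dropout = 0,
                                               seed = 5)),
                    rec, type = "link")
  p_1hop <- predict(ffinet_model(ffinet_config(hidden_dim = 16, n_heads = 2,
                                               n_layers = 2, dropout = 0,
                                               use_hops = 1, seed = 5)),
                    rec, type = "link")
  expect_gt(abs(p_full - p_1hop), 1e-8)
})
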