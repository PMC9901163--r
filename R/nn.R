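#' Model configuration
#'
#' @param hidden_dim embedding width (must be divisible by `n_heads`).
#' @param n_heads number of attention heads; each head works on a
#'   `hidden_dim / n_heads` slice with its own score parameters.
#' @param n_layers number of stacked attention layers N.
#' @param dropout dropout probability applied to the combined hop output
#'   before the residual connection (training only).
#' @param leaky_slope negative slope of the LeakyReLU inside the attention
#'   score (GATv2 convention).
#' @param use_hops subset of c(1, 2, 3): which hop channels exist. The
#'   restricted variants are the 1-hop / 2-hop ablations.
#' @param use_axial if FALSE, hop outputs are summed instead of combined by
#'   axial attention (the no-axial ablation).
#' @param task "regression" or "classification".
#' @param n_tasks number of prediction targets.
#' @param dedupe_hops restrict hop k to shortest-path distance k (see
#'   [build_khop_index()]).
#' @param complex_mode reserve an extra basis projection for nonbonded
#'   intermolecular 1-hop edges (protein-ligand complex graphs).
#' @param seed integer seed for parameter initialization.
#' @return an object of class `ffinet_config`.
#' @export
ffinet_config <- function(hidden_dim = 64L, n_heads = 4L, n_layers = 3L,
                          dropout = 0.1, leaky_slope = 0.2,
                          use_hops = c(1L, 2L, 3L), use_axial = TRUE,
                          task = c("regression", "classification"),
                          n_tasks = 1L, dedupe_hops = FALSE,
                          complex_mode = FALSE, seed = 1L) {
  task <- match.arg(task)
  use_hops <- sort(unique(as.integer(use_hops)))
  if (!length(use_hops) || !all(use_hops %in% 1:3))
    stop_config("use_hops must be a nonempty subset of {1, 2, 3}")
  if (hidden_dim %% n_heads != 0)
    stop_config("hidden_dim must be divisible by n_heads")
  if (dropout < 0 || dropout >= 1) stop_config("dropout must be in [0, 1)")
  structure(list(hidden_dim = as.integer(hidden_dim),
                 n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers),
                 dropout = dropout, leaky_slope = leaky_slope,
                 use_hops = use_hops, use_axial = isTRUE(use_axial),
                 task = task, n_tasks = as.integer(n_tasks),
                 dedupe_hops = isTRUE(dedupe_hops),
                 complex_mode = isTRUE(complex_mode),
                 seed = as.integer(seed)),
            class = "ffinet_config")
}

# basis widths per hop (bonded; angle+nonbonded; torsion+nonbonded)
BASIS_NCOL <- c(2L, 5L, 9L)
NONBONDED_NCOL <- 3L

#' @noRd
xavier <- function(nin, nout, dims = c(nin, nout)) {
  s <- sqrt(6 / (nin + nout))
  array(stats::runif(prod(dims), -s, s), dim = dims)
}

#' Initialize FFiNet parameters
#'
#' Xavier-uniform initialization, deterministic per `config$seed`.
#'
#' @param config an `ffinet_config`.
#' @param n_features atom-feature width F.
#' @return nested parameter list.
#' @export
ffinet_init_params <- function(config, n_features = ffinet_n_features()) {
  d <- config$hidden_dim; nh <- config$n_heads; dh <- d %/% nh
  with_seed(config$seed, {
    layers <- lapply(seq_len(config$n_layers), function(l) {
      hops <- lapply(config$use_hops, function(k) {
        hp <- list(
          Wr = lapply(seq_len(k + 1L), function(r)
            xavier(dh, dh, c(dh, dh, nh))),
          Wsrc = xavier(dh, dh, c(dh, dh, nh)),
          Wk = xavier(BASIS_NCOL[k], dh, c(BASIS_NCOL[k], dh, nh)),
          a = xavier(dh, 1, c(dh, nh)),
          WO = xavier(d, d)
        )
        if (k == 1L && config$complex_mode)
          hp$Wk_nb <- xavier(NONBONDED_NCOL, dh, c(NONBONDED_NCOL, dh, nh))
        hp
      })
      names(hops) <- as.character(config$use_hops)
      list(hops = hops, ln_g = rep(1, d), ln_b = rep(0, d))
    })
    list(emb = list(W = xavier(n_features, d), b = rep(0, d)),
         layers = layers,
         readout = list(w = as.numeric(xavier(d, 1)), b = 0),
         mlp = list(W1 = xavier(2 * d, d), b1 = rep(0, d),
                    W2 = xavier(d, config$n_tasks), b2 = rep(0, config$n_tasks)))
  })
}

#' Flatten / restore a nested parameter list
#'
#' Used by the optimizer and the finite-difference gradient checks; the
#' traversal order is deterministic.
#' @param params nested list of numeric arrays.
#' @return numeric vector.
#' @export
flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

#' @rdname flatten_params
#' @param vec numeric vector from [flatten_params()].
#' @param skeleton a parameter list with the target shapes.
#' @export
unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  rebuild <- function(x) {
    if (is.list(x)) return(lapply(x, rebuild))
    n <- length(x)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  out <- rebuild(skeleton)
  stopifnot(pos == length(vec))
  out
}

#' Sinusoidal hop positional encoding
#'
#' The transformer sinusoid evaluated at position k (the hop distance):
#' entry 2t+1 is sin(k / 10000^(2t/dim)), entry 2t+2 is cos of the same
#' argument (1-based entries). It is multiplied elementwise into the node
#' embeddings entering hop-k attention so the score can distinguish hops.
#'
#' @param k hop index (1, 2, or 3).
#' @param dim encoding width (the hidden dimension).
#' @return numeric vector of length `dim`.
#' @examples
#' positional_encoding(2, 4)  # sin(2), cos(2), sin(2/100), cos(2/100)
#' @export
positional_encoding <- function(k, dim) {
  stopifnot(k %in% 1:3, dim >= 1)
  j <- seq_len(dim) - 1L              # 0-based entry index
  t <- j %/% 2L
  arg <- k / 10000^(2 * t / dim)
  ifelse(j %% 2L == 0L, sin(arg), cos(arg))
}

#' @noRd
head_cols <- function(d, nh) {
  dh <- d %/% nh
  lapply(seq_len(nh), function(t) ((t - 1L) * dh + 1L):(t * dh))
}

# block-diagonal matmul: X (n x d) against per-head weights W3 (dh_in x
# dh_out x nh), input/output columns partitioned into head blocks
#' @noRd
bd_mm <- function(X, W3, cols_in, cols_out) {
  n <- nrow(X)
  nh <- dim(W3)[3]
  out <- matrix(0, n, dim(W3)[2] * nh)
  for (t in seq_len(nh))
    out[, cols_out[[t]]] <- X[, cols_in[[t]], drop = FALSE] %*% W3[, , t]
  out
}

# grouped softmax over rows of a matrix, groups given by `gidx` (match of
# each row's group into the sorted unique groups); columns independent.
# Scores are clamped to +-80, which cannot change a softmax materially but
# guarantees exp() never overflows.
#' @noRd
softmax_grouped <- function(e, gidx, n_groups) {
  ee <- exp(clamp(e, -80, 80))
  denom <- rowsum_padded(ee, gidx, n_groups)
  ee / denom[gidx, , drop = FALSE]
}

# rowsum onto exactly n_groups rows (gidx values must be in 1..n_groups)
#' @noRd
rowsum_padded <- function(x, gidx, n_groups) {
  out <- matrix(0, n_groups, ncol(x))
  acc <- rowsum(x, gidx)
  out[as.integer(rownames(acc)), ] <- acc
  out
}
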