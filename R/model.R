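#' Construct an FFiNet model
#'
#' Creates the model object holding the configuration, initialized
#' parameters, and (once fitted) the frozen basis/label standardization
#' statistics.
#'
#' @param config an [ffinet_config()].
#' @param n_features atom-feature width (default: the packaged featurizer's
#'   width).
#' @return object of class `ffinet_model`.
#' @export
ffinet_model <- function(config = ffinet_config(),
                         n_features = ffinet_n_features()) {
  structure(list(config = config,
                 params = ffinet_init_params(config, n_features),
                 n_features = as.integer(n_features),
                 basis_stats = NULL, label_stats = NULL,
                 trained = FALSE),
            class = "ffinet_model")
}

#' @export
print.ffinet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<ffinet_model> %s, hidden %d, %d heads, %d layers, ",
                     "hops {%s}%s%s, %s\n"),
              if (x$trained) "trained" else "untrained",
              cfg$hidden_dim, cfg$n_heads, cfg$n_layers,
              paste(cfg$use_hops, collapse = ","),
              if (cfg$use_axial) "" else ", no-axial",
              if (cfg$complex_mode) ", complex-mode" else "",
              cfg$task))
  invisible(x)
}

#' @noRd
prepare_inputs <- function(records, config) {
  if (inherits(records, "ffinet_molecule")) records <- list(records)
  lapply(records, function(r) {
    if (inherits(r, "ffinet_complex")) prepare_complex(r, config)
    else prepare_molecule(r, config)
  })
}

#' Run the model on molecules
#'
#' @param object an `ffinet_model`.
#' @param newdata an `ffinet_molecule`/`ffinet_complex` or a list of them.
#' @param type "response" (regression values on the label scale /
#'   classification probabilities) or "link" (raw network outputs).
#' @param batch_size forward-pass chunk size.
#' @param ... unused.
#' @return numeric matrix `n_molecules x n_tasks`.
#' @export
predict.ffinet_model <- function(object, newdata, type = c("response", "link"),
                                 batch_size = 256L, ...) {
  type <- match.arg(type)
  inputs <- prepare_inputs(newdata, object$config)
  chunks <- split(seq_along(inputs),
                  ceiling(seq_along(inputs) / batch_size))
  out <- do.call(rbind, lapply(chunks, function(ix) {
    batch <- assemble_batch(inputs[ix], object$basis_stats, object$config)
    nn_forward(object$params, object$config, batch)$out
  }))
  rownames(out) <- NULL
  if (type == "response") {
    if (object$config$task == "classification") out <- sigmoid(out)
    else if (!is.null(object$label_stats))
      out <- out * object$label_stats$sd + object$label_stats$mean
  }
  out
}

#' Full forward pass on one molecule with attention capture
#'
#' @param model an `ffinet_model`.
#' @param record an `ffinet_molecule` or `ffinet_complex`.
#' @return list with `prediction` (response scale) and `attention`, the
#'   per-layer attention record: path-level k-hop weights `alpha` (one
#'   column per head), per-node axial weights `beta`, the readout gate, and
#'   the final node embeddings.
#' @export
ffinet_forward <- function(model, record) {
  inputs <- prepare_inputs(record, model$config)
  batch <- assemble_batch(inputs, model$basis_stats, model$config)
  fw <- nn_forward(model$params, model$config, batch, record_attention = TRUE)
  pred <- fw$out
  if (model$config$task == "classification") pred <- sigmoid(pred)
  else if (!is.null(model$label_stats))
    pred <- pred * model$label_stats$sd + model$label_stats$mean
  list(prediction = as.numeric(pred), attention = fw$attn)
}

#' k-hop attention as a standalone operation
#'
#' Computes scores, normalized weights, and the hop output for one hop
#' channel with given parameters -- the elementary message-passing step of
#' the network, exposed for inspection and oracle testing.
#'
#' @param h node embedding matrix `n x hidden_dim`.
#' @param paths hop-k path matrix (`k + 1` columns, target first).
#' @param m_k basis rows aligned with `paths`.
#' @param hop_params one hop's parameter list (e.g.
#'   `model$params$layers[[1]]$hops[["2"]]`).
#' @param config the model's `ffinet_config`.
#' @param hop the hop number k.
#' @return list with `scores` (paths x heads), `weights` (softmax-normalized
#'   per target node, per head), `output` (`n x hidden_dim`).
#' @export
khop_attention <- function(h, paths, m_k, hop_params, config, hop) {
  paths <- as.matrix(paths)
  if (nrow(paths) && ncol(paths) != hop + 1L)
    stop_config("paths must have hop + 1 columns")
  if (nrow(paths) != nrow(m_k))
    stop_config("paths and basis rows are misaligned")
  g <- paths[, 1]
  ug <- sort(unique(g))
  grp <- list(g = g, ug = ug, gidx = match(g, ug))
  hc <- hop_forward(h, hop, paths, m_k, NULL, grp, hop_params, config)
  list(scores = hc$escore, weights = hc$alpha, output = hc$O)
}

#' Axial combination of hop outputs
#'
#' Per node, the axial score of hop k is the scaled dot product of the
#' node's input embedding with its hop-k output; a softmax over the
#' available hops yields weights beta, and the node update is the
#' beta-weighted sum. With `use_axial = FALSE` the hop outputs are summed
#' unweighted (the no-axial ablation).
#'
#' @param h_in input node embeddings `n x d`.
#' @param o_list list of hop output matrices (same shape as `h_in`).
#' @param use_axial logical.
#' @param has optional `n x length(o_list)` logical availability mask; hops
#'   with no path to a node are excluded from its softmax.
#' @return list with `h_out` and `beta` (NULL when `use_axial = FALSE`).
#' @export
axial_combine <- function(h_in, o_list, use_axial = TRUE, has = NULL) {
  nK <- length(o_list)
  n <- nrow(h_in); d <- ncol(h_in)
  if (!use_axial)
    return(list(h_out = Reduce(`+`, o_list), beta = NULL))
  if (is.null(has)) has <- matrix(TRUE, n, nK)
  S <- matrix(0, n, nK)
  for (ki in seq_len(nK)) S[, ki] <- rowSums(h_in * o_list[[ki]]) / sqrt(d)
  expS <- exp(clamp(S, -80, 80))
  expS[!has] <- 0
  denom <- rowSums(expS)
  beta <- expS / ifelse(denom > 0, denom, 1)
  h_out <- matrix(0, n, d)
  for (ki in seq_len(nK)) h_out <- h_out + beta[, ki] * o_list[[ki]]
  list(h_out = h_out, beta = beta)
}

#' One FFiNet layer in evaluation mode
#'
#' @param h node embeddings `n x hidden_dim`.
#' @param index `ffinet_khop` of the molecule.
#' @param basis `ffinet_basis` aligned with `index` (standardize first if
#'   the parameters were trained on standardized bases).
#' @param layer_params one layer's parameters
#'   (`model$params$layers[[l]]`).
#' @param config the model's `ffinet_config`.
#' @return updated embedding matrix `n x hidden_dim`.
#' @export
ffinet_layer <- function(h, index, basis, layer_params, config) {
  n <- nrow(h)
  paths <- list(index$hop1, index$hop2, index$hop3)
  bas <- list(basis$m1, basis$m2, basis$m3)
  groups <- vector("list", 3L)
  has <- matrix(FALSE, n, 3L)
  for (k in 1:3) {
    g <- paths[[k]][, 1]
    ug <- sort(unique(g))
    groups[[k]] <- list(g = g, ug = ug, gidx = match(g, ug))
    has[ug, k] <- TRUE
  }
  batch <- list(paths = paths, basis = bas, basis1_nb = NULL,
                groups = groups, has = has)
  layer_forward(h, layer_params, batch, config, training = FALSE)$h
}

#' Graph readout
#'
#' Concatenation of a gated weighted sum (gate `g_i = sigmoid(w'h_i + b)`,
#' the atom-contribution signal) and per-dimension max pooling.
#'
#' @param h final node embeddings `n x d`.
#' @param readout_params list with `w` (length d) and scalar `b`.
#' @return numeric vector of length `2 d`, with the gates in attribute
#'   `"gate"`.
#' @export
readout <- function(h, readout_params) {
  if (nrow(h) == 0) stop_config("readout of an empty graph")
  g <- sigmoid(as.numeric(h %*% readout_params$w) + readout_params$b)
  out <- c(colSums(h * g), apply(h, 2, max))
  attr(out, "gate") <- g
  out
}

#' Prediction head
#'
#' Two-layer MLP mapping the graph vector to task outputs: raw values for
#' regression, per-task logits for classification.
#'
#' @param graph_vec numeric vector (length `2 d`) or matrix with one row
#'   per graph.
#' @param mlp_params list with `W1`, `b1`, `W2`, `b2`.
#' @return numeric matrix `n_graphs x n_tasks`.
#' @export
predict_head <- function(graph_vec, mlp_params) {
  G <- if (is.matrix(graph_vec)) graph_vec else matrix(graph_vec, nrow = 1)
  A1 <- sweep(G %*% mlp_params$W1, 2, mlp_params$b1, "+")
  R1 <- A1 * (A1 > 0)
  sweep(R1 %*% mlp_params$W2, 2, mlp_params$b2, "+")
}
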