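# Interpretation extractors: which atoms and which paths the trained model
# attends to.

#' Per-atom contribution weights
#'
#' The readout gate of each atom, normalized to sum to one for display;
#' because the gated weighted sum feeds the prediction head, the gate is
#' the model's atom-importance signal.
#'
#' @param model an `ffinet_model`.
#' @param record an `ffinet_molecule` or `ffinet_complex`.
#' @return numeric vector of length `n_atoms` summing to 1.
#' @export
atom_contributions <- function(model, record) {
  fw <- ffinet_forward(model, record)
  g <- fw$attention$gate
  g / sum(g)
}

#' Total attention weights toward one target atom
#'
#' Multiplies a node's axial weight for hop k with the path-level k-hop
#' attention weights of the chosen head: the total weight of path p at hop
#' k is beta_k[target] * alpha_p. Per head, the totals over all hops and
#' paths of a target atom sum to 1 (when every hop has at least one path).
#'
#' @param model an `ffinet_model`.
#' @param record the molecule.
#' @param target_atom 1-based atom index.
#' @param layer layer to inspect (default: last).
#' @param head attention head (default 1).
#' @return data.frame with columns `hop`, `source`, `path` (dash-joined
#'   atom indices), `alpha`, `beta`, `total`.
#' @export
attention_map <- function(model, record, target_atom,
                          layer = model$config$n_layers, head = 1L) {
  fw <- ffinet_forward(model, record)
  at <- fw$attention
  la <- at$layers[[layer]]
  rows <- list()
  for (k in model$config$use_hops) {
    alpha <- la$alpha[[as.character(k)]]
    if (is.null(alpha)) next
    paths <- at$paths[[k]]
    sel <- which(paths[, 1] == target_atom)
    if (!length(sel)) next
    beta_k <- if (is.null(la$beta)) 1 / length(model$config$use_hops)
              else la$beta[target_atom, match(k, model$config$use_hops)]
    rows[[length(rows) + 1L]] <- data.frame(
      hop = k,
      source = paths[sel, k + 1L],
      path = apply(paths[sel, , drop = FALSE], 1, paste, collapse = "-"),
      alpha = alpha[sel, head],
      beta = beta_k,
      total = beta_k * alpha[sel, head])
  }
  if (!length(rows))
    return(data.frame(hop = integer(0), source = integer(0),
                      path = character(0), alpha = numeric(0),
                      beta = numeric(0), total = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Atom-pair similarity of final-layer embeddings
#'
#' Pearson correlation between the final-layer state vectors of every atom
#' pair; after training, blocks of high similarity tend to align with
#' functional groups.
#'
#' @param model an `ffinet_model`.
#' @param record the molecule.
#' @return symmetric `n_atoms x n_atoms` matrix with unit diagonal.
#' @export
node_similarity <- function(model, record) {
  fw <- ffinet_forward(model, record)
  h <- fw$attention$h_final
  sim <- suppressWarnings(stats::cor(t(h)))
  sim[!is.finite(sim)] <- 0
  diag(sim) <- 1
  clamp(sim, -1, 1)
}
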