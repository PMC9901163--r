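#' Training configuration
#'
#' @param batch_size molecules per mini-batch (default 128).
#' @param lr Adam learning rate.
#' @param max_epochs hard epoch cap.
#' @param patience early-stopping patience: training stops after this many
#'   epochs without validation improvement and the best-epoch parameters
#'   are restored.
#' @param lr_decay multiplicative learning-rate decay applied on plateau.
#' @param lr_patience epochs without improvement before a decay step.
#' @param grad_clip global gradient-norm clip (0 disables).
#' @param monitor validation quantity to monitor ("val_loss").
#' @param seed seed controlling data order, dropout and initialization
#'   during the fit.
#' @param verbose print per-epoch progress.
#' @return an `ffinet_train_config` list.
#' @export
ffinet_train_config <- function(batch_size = 128L, lr = 1e-3,
                                max_epochs = 300L, patience = 30L,
                                lr_decay = 0.5, lr_patience = 10L,
                                grad_clip = 5, monitor = "val_loss",
                                seed = 1L, verbose = FALSE) {
  stopifnot(batch_size >= 1)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr_decay = lr_decay,
                 lr_patience = as.integer(lr_patience), grad_clip = grad_clip,
                 monitor = monitor, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "ffinet_train_config")
}

#' Random train/validation/test split
#'
#' Largest-remainder rounding of the requested ratios (default 8:1:1);
#' disjoint, exhaustive, reproducible per seed.
#'
#' @param n number of items.
#' @param ratios length-3 positive vector summing to 1.
#' @param seed integer seed.
#' @return list with integer index vectors `train`, `val`, `test`.
#' @export
random_split <- function(n, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (n < 3) stop_config("need at least 3 items to split")
  stopifnot(length(ratios) == 3, all(ratios > 0),
            abs(sum(ratios) - 1) < 1e-8)
  raw <- n * ratios
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(sizes[1])]),
       val = sort(perm[sizes[1] + seq_len(sizes[2])]),
       test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]))
}

#' Fit an FFiNet model
#'
#' Mini-batch Adam with early stopping on the validation loss. All
#' randomness (initialization, data order, dropout) is driven by
#' `train_config$seed`, so identical calls produce identical histories.
#' For regression the labels are z-scored on the training split (inverted
#' at prediction time); the spatial-basis standardization statistics are
#' likewise frozen from the training split.
#'
#' @param model an `ffinet_model` (its parameters are re-initialized with
#'   the training seed).
#' @param records list of labelled `ffinet_molecule`/`ffinet_complex`.
#' @param split list with `train` and `val` (and optionally `test`) index
#'   vectors; default: a seeded 8:1:1 random split.
#' @param train_config an [ffinet_train_config()].
#' @return list with the fitted `model` (best-validation parameters), a
#'   per-epoch `history` data.frame, and the `split` used.
#' @export
fit_ffinet <- function(model, records, split = NULL,
                       train_config = ffinet_train_config()) {
  tc <- train_config
  config <- model$config
  split <- split %||% random_split(length(records), seed = tc$seed)
  stopifnot(length(split$train) > 0, length(split$val) > 0)

  inputs <- prepare_inputs(records, config)
  is_complex <- any(vapply(inputs, function(gi) !is.null(gi$basis1_nb),
                           logical(1)))
  train_in <- inputs[split$train]
  stats <- if (is_complex) complex_basis_stats(train_in) else {
    basis_stats(lapply(train_in, function(gi)
      structure(list(m1 = gi$basis[[1]], m2 = gi$basis[[2]],
                     m3 = gi$basis[[3]]), class = "ffinet_basis")))
  }
  model$basis_stats <- stats

  if (config$task == "regression") {
    ytr <- unlist(lapply(train_in, `[[`, "labels"))
    mu <- mean(ytr, na.rm = TRUE)
    sg <- stats::sd(ytr, na.rm = TRUE)
    if (!is.finite(sg) || sg < 1e-8) sg <- 1
    model$label_stats <- list(mean = mu, sd = sg)
    inputs <- lapply(inputs, function(gi) {
      gi$labels <- (gi$labels - mu) / sg
      gi
    })
  }

  val_batch <- assemble_batch(inputs[split$val], stats, config)

  # fresh parameters under the fit seed
  config$seed <- tc$seed
  params <- ffinet_init_params(config, model$n_features)
  theta <- flatten_params(params)
  m_adam <- v_adam <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  lr <- tc$lr

  best_val <- Inf
  best_theta <- theta
  best_epoch <- 0L
  bad_epochs <- 0L
  bad_lr <- 0L
  history <- list()
  n_train <- length(split$train)

  with_seed(tc$seed + 1L, {
    for (epoch in seq_len(tc$max_epochs)) {
      ord <- sample(split$train)
      chunks <- split(ord, ceiling(seq_along(ord) / tc$batch_size))
      epoch_loss <- 0
      for (ix in chunks) {
        batch <- assemble_batch(inputs[ix], stats, config)
        fw <- nn_forward(params, config, batch, training = TRUE)
        lg <- loss_and_grad(fw$out, batch$labels, batch$label_mask,
                            config$task)
        if (!is.finite(lg$loss))
          stop_config("non-finite training loss at epoch ", epoch,
                      "; try a lower learning rate or check input geometry")
        grads <- nn_backward(params, config, batch, fw$cache, lg$dout)
        gvec <- flatten_params(grads)
        if (tc$grad_clip > 0) {
          gn <- sqrt(sum(gvec^2))
          if (gn > tc$grad_clip) gvec <- gvec * (tc$grad_clip / gn)
        }
        step <- step + 1L
        m_adam <- b1 * m_adam + (1 - b1) * gvec
        v_adam <- b2 * v_adam + (1 - b2) * gvec^2
        mhat <- m_adam / (1 - b1^step)
        vhat <- v_adam / (1 - b2^step)
        theta <- theta - lr * mhat / (sqrt(vhat) + eps)
        params <- unflatten_params(theta, params)
        epoch_loss <- epoch_loss + lg$loss * length(ix)
      }
      epoch_loss <- epoch_loss / n_train

      vf <- nn_forward(params, config, val_batch)
      val_loss <- loss_and_grad(vf$out, val_batch$labels,
                                val_batch$label_mask, config$task)$loss
      improved <- val_loss < best_val - 1e-9
      if (improved) {
        best_val <- val_loss
        best_theta <- theta
        best_epoch <- epoch
        bad_epochs <- 0L
        bad_lr <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        bad_lr <- bad_lr + 1L
        if (bad_lr >= tc$lr_patience) {
          lr <- lr * tc$lr_decay
          bad_lr <- 0L
        }
      }
      history[[epoch]] <- data.frame(epoch = epoch, train_loss = epoch_loss,
                                     val_loss = val_loss, lr = lr,
                                     best_val = best_val)
      if (tc$verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  best %.4f  lr %.2g",
                        epoch, epoch_loss, val_loss, best_val, lr))
      if (bad_epochs > tc$patience) break
    }
  })

  model$params <- unflatten_params(best_theta, params)
  model$config <- config
  model$trained <- TRUE
  model$best_epoch <- best_epoch
  list(model = model, history = do.call(rbind, history), split = split)
}
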