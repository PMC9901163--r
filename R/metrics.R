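#' Evaluation metrics
#'
#' The regression metrics are RMSE, MAE, the Pearson correlation R, and the
#' residual standard deviation SD about the least-squares line of labels on
#' predictions (the Pafnucy convention): with (a, b) from OLS of y on
#' y-hat, SD = sqrt( sum((y - (a + b y-hat))^2) / (N - 1) ). SD and R are
#' invariant under affine transforms of the predictions. Classification is
#' scored by ROC-AUC, macro-averaged over tasks using only unmasked labels.
#'
#' @param y numeric vector of labels.
#' @param yhat numeric vector of predictions.
#' @return scalar metric value.
#' @name metrics
NULL

#' @rdname metrics
#' @export
metric_rmse <- function(y, yhat) sqrt(mean((y - yhat)^2))

#' @rdname metrics
#' @export
metric_mae <- function(y, yhat) mean(abs(y - yhat))

#' @rdname metrics
#' @export
metric_pearson <- function(y, yhat) {
  if (length(y) < 2) return(NA_real_)
  sy <- stats::sd(y); sh <- stats::sd(yhat)
  if (!is.finite(sy) || !is.finite(sh) || sy < 1e-12 || sh < 1e-12)
    return(NA_real_)
  stats::cor(y, yhat)
}

#' @rdname metrics
#' @export
metric_sd <- function(y, yhat) {
  n <- length(y)
  if (n < 2) return(NA_real_)
  vx <- sum((yhat - mean(yhat))^2)
  b <- if (vx < 1e-12) 0 else sum((yhat - mean(yhat)) * (y - mean(y))) / vx
  a <- mean(y) - b * mean(yhat)
  sqrt(sum((y - (a + b * yhat))^2) / (n - 1))
}

#' @rdname metrics
#' @param score numeric vector of classification scores (higher = more
#'   positive).
#' @export
metric_roc_auc <- function(y, score) {
  y <- as.integer(y > 0.5)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro ROC-AUC over masked tasks
#'
#' @param labels,scores matrices `n x n_tasks`.
#' @param mask logical matrix of observed labels.
#' @return mean AUC over tasks with both classes present; single-class
#'   tasks are skipped with a warning.
#' @export
metric_roc_auc_masked <- function(labels, scores, mask = !is.na(labels)) {
  aucs <- vapply(seq_len(ncol(labels)), function(j) {
    m <- mask[, j]
    if (!any(m)) return(NA_real_)
    metric_roc_auc(labels[m, j], scores[m, j])
  }, numeric(1))
  if (anyNA(aucs))
    warning(sprintf("%d task(s) skipped for ROC-AUC (single class)",
                    sum(is.na(aucs))), call. = FALSE)
  mean(aucs, na.rm = TRUE)
}

#' Evaluate a model on labelled molecules
#'
#' @param model a fitted `ffinet_model`.
#' @param records list of labelled `ffinet_molecule`/`ffinet_complex`.
#' @param labels optional label matrix overriding the records' labels.
#' @return a `ffinet_metrics` list: rmse, mae, pearson_r, sd for
#'   regression; roc_auc additionally for classification.
#' @export
evaluate_ffinet <- function(model, records, labels = NULL) {
  if (is.null(labels)) {
    labels <- do.call(rbind, lapply(records, function(r) {
      lab <- if (inherits(r, "ffinet_complex")) r$affinity else r$labels
      matrix(lab %||% NA_real_, nrow = 1)
    }))
  }
  labels <- as.matrix(labels)
  mask <- !is.na(labels)
  if (model$config$task == "classification") {
    scores <- predict(model, records, type = "response")
    ym <- labels[mask]; sm <- scores[mask]
    out <- list(roc_auc = metric_roc_auc_masked(labels, scores, mask),
                rmse = metric_rmse(ym, sm), mae = metric_mae(ym, sm),
                pearson_r = metric_pearson(ym, sm), sd = metric_sd(ym, sm))
  } else {
    yhat <- predict(model, records, type = "response")
    ym <- labels[mask]; sm <- yhat[mask]
    out <- list(rmse = metric_rmse(ym, sm), mae = metric_mae(ym, sm),
                pearson_r = metric_pearson(ym, sm), sd = metric_sd(ym, sm))
  }
  structure(out, class = "ffinet_metrics")
}

#' @export
print.ffinet_metrics <- function(x, ...) {
  vals <- unlist(x)
  cat(paste(sprintf("%s = %.4f", names(vals), vals), collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate metrics over repeated runs
#'
#' @param run_fn function(seed) returning a named numeric vector (or
#'   `ffinet_metrics`) for one independent run.
#' @param n_runs number of repeats (default 3, matching the convention of
#'   reporting mean and standard deviation over three seeded runs).
#' @param seeds explicit seeds (default `seq_len(n_runs)`).
#' @return data.frame with one row per metric: mean and sd over runs.
#' @export
run_repeats <- function(run_fn, n_runs = 3L, seeds = NULL) {
  seeds <- seeds %||% seq_len(n_runs)
  if (length(seeds) == 1)
    warning("single run: standard deviation reported as 0", call. = FALSE)
  rows <- lapply(seeds, function(s) unlist(run_fn(s)))
  m <- do.call(rbind, rows)
  data.frame(metric = colnames(m),
             mean = colMeans(m),
             sd = if (nrow(m) > 1) apply(m, 2, stats::sd) else rep(0, ncol(m)),
             row.names = NULL)
}
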