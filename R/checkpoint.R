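#' Save / load model checkpoints
#'
#' Checkpoints are plain JSON: the flat parameter vector at full double
#' precision, the model configuration, the frozen basis/label
#' standardization statistics, and a format version.
#'
#' @param model an `ffinet_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(
    format = "ffinet-checkpoint-1",
    config = unclass(model$config),
    n_features = model$n_features,
    params = flatten_params(model$params),
    basis_stats = if (!is.null(model$basis_stats)) unclass(model$basis_stats),
    label_stats = model$label_stats,
    trained = model$trained
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "ffinet-checkpoint-1"))
    stop_config("unrecognized checkpoint format: ", p$format %||% "<none>")
  cfg <- do.call(ffinet_config, p$config[setdiff(names(p$config), NULL)])
  model <- ffinet_model(cfg, n_features = p$n_features)
  model$params <- unflatten_params(as.numeric(p$params), model$params)
  if (!is.null(p$basis_stats)) {
    bs <- lapply(p$basis_stats, function(s)
      list(mean = as.numeric(s$mean), sd = as.numeric(s$sd)))
    model$basis_stats <- structure(bs, class = "ffinet_basis_stats")
  }
  if (!is.null(p$label_stats))
    model$label_stats <- list(mean = p$label_stats$mean, sd = p$label_stats$sd)
  model$trained <- isTRUE(p$trained)
  model
}
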