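#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded helpers do not disturb
#' the caller's random stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
ffinet_log <- function(...) {
  if (isTRUE(getOption("ffinet.verbose", FALSE))) message(...)
}

stop_config <- function(...) stop(..., call. = FALSE)

#' Sigmoid and ReLU-family primitives used across the network
#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-clamp(x, -60, 60)))

leaky_relu <- function(x, slope) x * ((x > 0) + slope * (x <= 0))
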