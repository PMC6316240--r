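#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a named random substream seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seed from a single master
#' seed combined with a stage label, so that stages are decoupled (changing the
#' number of draws in one stage does not shift another) while the whole
#' campaign remains reproducible from one integer.
#'
#' @param seed master integer seed
#' @param name character stage label (e.g. `"measure_run_07"`)
#' @return an integer seed below 2^31
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(seed) * 2654435761 + h) %% 2147483647)
}

stop_domain <- function(arg, msg) {
  stop(sprintf("invalid argument `%s`: %s", arg, msg), call. = FALSE)
}

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop_domain(nm, "must be a positive finite number")
    }
  }
  invisible(TRUE)
}
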