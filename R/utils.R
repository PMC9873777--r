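# internal helpers shared across modules

#' Round half away from zero
#'
#' Base `round()` rounds half to even; agronomic targets quoted to whole
#' degree-days use the conventional "half up" rule (346.5 -> 347).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  trunc(abs(x) * m + 0.5) / m * sign(x)
}

# stop() with a condition class so callers can distinguish input errors
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "sorghumsim_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar", name), "input_error")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
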