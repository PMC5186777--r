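#' Model parameters for the false-belief network
#'
#' Bundles the four probabilities that fully parameterise the theory-of-mind
#' (ToM) network:
#'
#' * `pi_B` — the degree to which the child attributes *different* beliefs to
#'   others (the gate on the theory-based strategy).
#' * `pi_V` — the degree to which the child correctly identifies the other's
#'   visual access (knowledge state).
#' * `delta` — the small probability of failing to maintain one's own updated
#'   belief (memory/attention slip).
#' * `epsilon` — the attributed chance that the other expects something other
#'   than the default contents of the container.
#'
#' Values exactly 0 or 1 are legal (the limiting cases of a perfect or fully
#' defaulting reasoner use them); anything outside `[0, 1]`, `NA`, or `NaN` is
#' rejected with an error naming the offending field.
#'
#' @param pi_B,pi_V,delta,epsilon Probabilities in `[0, 1]`.
#'
#' @return An object of class `tom_params`: a named list with the four fields.
#' @examples
#' p <- tom_params(pi_B = 0.8, pi_V = 0.7, delta = 0.05, epsilon = 0.02)
#' predict_false_belief(p)
#' @export
tom_params <- function(pi_B, pi_V, delta, epsilon) {
  check_prob(pi_B, "pi_B")
  check_prob(pi_V, "pi_V")
  check_prob(delta, "delta")
  check_prob(epsilon, "epsilon")
  structure(
    list(pi_B = as.numeric(pi_B), pi_V = as.numeric(pi_V),
         delta = as.numeric(delta), epsilon = as.numeric(epsilon)),
    class = "tom_params"
  )
}

# scalar probability validator; NaN/NA are invalid, 0 and 1 are legal
check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    rlang::abort(
      sprintf("`%s` must be a single probability in [0, 1] (got %s).",
              field, deparse(x)),
      class = "tom_params_error",
      field = field
    )
  }
  invisible(x)
}

as_tom_params <- function(x) {
  if (inherits(x, "tom_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    if (all(c("pi_B", "pi_V", "delta", "epsilon") %in% names(x))) {
      return(tom_params(x$pi_B, x$pi_V, x$delta, x$epsilon))
    }
  }
  rlang::abort("Cannot coerce to `tom_params`; need fields pi_B, pi_V, delta, epsilon.",
               class = "tom_params_error")
}

#' @export
print.tom_params <- function(x, ...) {
  cat("<tom_params>\n")
  cat(sprintf("  pi_B    = %.4f  (attributing different beliefs)\n", x$pi_B))
  cat(sprintf("  pi_V    = %.4f  (identifying others' visual access)\n", x$pi_V))
  cat(sprintf("  delta   = %.4f  (own-belief maintenance failure)\n", x$delta))
  cat(sprintf("  epsilon = %.4f  (attributed non-default expectation)\n", x$epsilon))
  invisible(x)
}

#' @export
as.data.frame.tom_params <- function(x, ...) {
  as.data.frame(tibble::as_tibble(unclass(x)))
}
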