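#' Build the conditional probability tables of the ToM network
#'
#' The network has five nodes: the world state `W` (fixed), the child's own
#' visual access `V_S` (observed, always 1: the child saw the true contents),
#' the child's own belief `B_S`, the other's visual access `V_O`, and the
#' other's belief `B_O`. Belief variables code 1 for the true belief (the
#' actual contents) and 0 for the false belief (the default contents); visual
#' access codes 1 for "contents observed". The joint factorises as
#' `P(B_O | V_O, B_S, W) P(V_O | V_S) P(B_S | V_S, W) P(V_S) P(W)`.
#'
#' The child-to-other CPT is a mixture gated by `pi_B`:
#' `P(B_O | V_O, B_S, W) = pi_B * P(B_O | V_O, W) + (1 - pi_B) * P(B_O | B_S)`,
#' where the theory component uses the internal model of the other
#' (`P(B_O = 0 | V_O = 1, W) = delta`, `P(B_O = 0 | V_O = 0, W) = 1 - epsilon`)
#' and the simulation component copies the child's own belief state
#' deterministically.
#'
#' All `P(x = 1 | ...)` entries are stored explicitly rather than derived as
#' complements; normalisation of every table is an invariant checked by the
#' test suite.
#'
#' @param params A [tom_params()] object.
#'
#' @return An object of class `tom_cpts`: a list with
#'   * `p_bs` — `P(B_S | V_S = 1, W)`, named vector over `B_S` in `{0, 1}`;
#'   * `p_vo` — `P(V_O | V_S = 1)`, named vector over `V_O`;
#'   * `p_bo` — `P(B_O | V_O, B_S, W)`, a 2 x 2 x 2 array with dimensions
#'     `b_o`, `v_o`, `b_s`;
#'   * `params` — the parameters used.
#' @examples
#' cpts <- build_cpts(tom_params(0.5, 0.7, 0.1, 0.2))
#' cpts$p_bo["0", "0", "1"] # 0.5 * 0.8 + 0.5 * 0 = 0.40
#' @export
build_cpts <- function(params) {
  params <- as_tom_params(params)
  lv <- c("0", "1")

  p_bs <- c(`0` = params$delta, `1` = 1 - params$delta)
  p_vo <- c(`0` = params$pi_V, `1` = 1 - params$pi_V)

  # theory component P(B_O | V_O, W): rows b_o, cols v_o
  theory <- matrix(
    c(1 - params$epsilon, params$epsilon,   # v_o = 0: other kept the default
      params$delta,       1 - params$delta),# v_o = 1: other saw the contents
    nrow = 2, dimnames = list(b_o = lv, v_o = lv)
  )

  p_bo <- array(NA_real_, dim = c(2, 2, 2),
                dimnames = list(b_o = lv, v_o = lv, b_s = lv))
  for (b_o in 0:1) {
    for (v_o in 0:1) {
      for (b_s in 0:1) {
        copy <- as.numeric(b_o == b_s)
        p_bo[b_o + 1L, v_o + 1L, b_s + 1L] <-
          params$pi_B * theory[b_o + 1L, v_o + 1L] + (1 - params$pi_B) * copy
      }
    }
  }

  structure(list(p_bs = p_bs, p_vo = p_vo, p_bo = p_bo, params = params),
            class = "tom_cpts")
}

#' @export
print.tom_cpts <- function(x, ...) {
  cat("<tom_cpts>  P(B_S | V_S = 1, W):\n")
  print(x$p_bs)
  cat("P(V_O | V_S = 1):\n")
  print(x$p_vo)
  cat("P(B_O | V_O, B_S, W) [b_o, v_o, b_s]:\n")
  print(x$p_bo)
  invisible(x)
}

check_binary <- function(x, field) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || !all(x %in% c(0, 1))) {
    rlang::abort(sprintf("`%s` must contain only 0 or 1.", field),
                 class = "tom_state_error", field = field)
  }
  invisible(x)
}

#' Joint probability of a latent assignment given the evidence
#'
#' Evaluates `P(b_o | v_o, b_s, W) * P(v_o | V_S = 1) * P(b_s | V_S = 1, W)`
#' for one or more assignments of the latent variables, with `V_S = 1` as hard
#' evidence and the world state `W` a fixed constant (both contribute factor 1).
#' Vectorised over the three state arguments.
#'
#' @param params A [tom_params()] object.
#' @param v_o,b_s,b_o Binary (0/1) vectors of equal length: the other's visual
#'   access, the child's own belief, and the other's belief.
#'
#' @return A numeric vector of probabilities; over the 8 possible assignments
#'   these sum to 1.
#' @examples
#' p <- tom_params(0.8, 0.7, 0.05, 0.02)
#' joint_probability(p, v_o = 0, b_s = 1, b_o = 0) # 0.7 * 0.95 * 0.784
#' @export
joint_probability <- function(params, v_o, b_s, b_o) {
  cpts <- build_cpts(params)
  check_binary(v_o, "v_o")
  check_binary(b_s, "b_s")
  check_binary(b_o, "b_o")
  n <- max(length(v_o), length(b_s), length(b_o))
  v_o <- rep_len(v_o, n); b_s <- rep_len(b_s, n); b_o <- rep_len(b_o, n)
  unname(cpts$p_bo[cbind(b_o + 1L, v_o + 1L, b_s + 1L)] *
           cpts$p_vo[v_o + 1L] * cpts$p_bs[b_s + 1L])
}

#' Enumerate the joint distribution over the latent variables
#'
#' @param params A [tom_params()] object.
#' @return A tibble with one row per assignment of `(v_o, b_s, b_o)` (8 rows),
#'   a constant `v_s = 1` evidence column, and the joint `prob`.
#' @export
enumerate_joint <- function(params) {
  states <- tidyr::expand_grid(v_o = 0:1, b_s = 0:1, b_o = 0:1)
  dplyr::mutate(states,
                v_s = 1L,
                prob = joint_probability(params, .data$v_o, .data$b_s, .data$b_o),
                .before = 1L)[, c("v_s", "v_o", "b_s", "b_o", "prob")]
}

#' Predict the probability of a correct false-belief response
#'
#' Computes `P(B_O = 0 | V_S = 1, W)` — the probability that the child
#' attributes the false (default-contents) belief to the naive other — either
#' by the closed form `pi_B * pi_V * (1 - epsilon) + (1 - pi_B * pi_V) * delta`
#' or by explicit marginalisation over the four latent assignments of
#' `(V_O, B_S)`. The two routes agree to machine precision; the enumeration
#' path exists as an independent check on the algebra.
#'
#' @param params A [tom_params()] object.
#' @param method `"closed_form"` (default) or `"enumeration"`.
#' @return A single probability.
#' @examples
#' p <- tom_params(0.8, 0.7, 0.05, 0.02)
#' predict_false_belief(p)                        # 0.5708
#' predict_false_belief(p, method = "enumeration")
#' @export
predict_false_belief <- function(params, method = c("closed_form", "enumeration")) {
  params <- as_tom_params(params)
  method <- match.arg(method)
  if (method == "closed_form") {
    q <- params$pi_B * params$pi_V
    return(q * (1 - params$epsilon) + (1 - q) * params$delta)
  }
  cpts <- build_cpts(params)
  total <- 0
  for (v_o in 0:1) {
    for (b_s in 0:1) {
      total <- total +
        cpts$p_bo["0", as.character(v_o), as.character(b_s)] *
        cpts$p_vo[[as.character(v_o)]] * cpts$p_bs[[as.character(b_s)]]
    }
  }
  total
}

#' Decompose the false-belief prediction into strategy contributions
#'
#' Splits `P(B_O = 0 | V_S = 1, W)` into the theory-based term
#' `pi_B * (pi_V * (1 - epsilon) + (1 - pi_V) * delta)` — the child runs the
#' internal model of the other, fed by the estimate of the other's visual
#' access — and the simulation-based term `(1 - pi_B) * delta` — the child
#' simulates their own belief update and projects it onto the other. The two
#' terms sum exactly to [predict_false_belief()].
#'
#' @param params A [tom_params()] object.
#' @return A one-row tibble with columns `theory`, `simulation`, `total`.
#' @examples
#' strategy_decomposition(tom_params(0.8, 0.7, 0.05, 0.02)) # 0.5608 + 0.01
#' @export
strategy_decomposition <- function(params) {
  params <- as_tom_params(params)
  theory <- params$pi_B *
    (params$pi_V * (1 - params$epsilon) + (1 - params$pi_V) * params$delta)
  simulation <- (1 - params$pi_B) * params$delta
  tibble::tibble(theory = theory, simulation = simulation,
                 total = theory + simulation)
}

#' Product approximation of the false-belief probability
#'
#' For small noise parameters the false-belief probability is closely
#' approximated by the product `pi_B * pi_V`: the model's multiplicative
#' prediction that false-belief performance is the product of diverse-beliefs
#' and knowledge-access performance. The approximation error is a signed
#' combination `(1 - pi_B * pi_V) * delta - pi_B * pi_V * epsilon`, so its
#' magnitude never exceeds `max(delta, epsilon)`.
#'
#' @param pi_B,pi_V Probabilities in `[0, 1]` (vectorised, recycled).
#' @return `pi_B * pi_V`.
#' @examples
#' approximate_false_belief(0.8, 0.7) # 0.56; exact value at small noise 0.5708
#' @export
approximate_false_belief <- function(pi_B, pi_V) {
  for (v in pi_B) check_prob(v, "pi_B")
  for (v in pi_V) check_prob(v, "pi_V")
  pi_B * pi_V
}
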