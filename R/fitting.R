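#' Study counts for one group of children
#'
#' Correct/total counts on the three ToM-scale tasks used by the model:
#' diverse beliefs (DB, maps to `pi_B`), knowledge access (KA, maps to
#' `pi_V`), and the unexpected-contents false-belief task (FB, maps to the
#' model prediction `pi_FB`).
#'
#' @param label Group label.
#' @param k_DB,n_DB,k_KA,n_KA,k_FB,n_FB Correct/total counts per task;
#'   `0 <= k <= n`, `n >= 1`.
#' @return A one-row tibble of class `tom_study`.
#' @examples
#' tom_study("preschoolers", 40, 50, 35, 50, 28, 50)
#' @export
tom_study <- function(label, k_DB, n_DB, k_KA, n_KA, k_FB, n_FB) {
  for (nm in c("n_DB", "n_KA", "n_FB")) check_count(get(nm), nm)
  for (task in c("DB", "KA", "FB")) {
    k <- get(paste0("k_", task)); n <- get(paste0("n_", task))
    if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != floor(k) ||
        k < 0 || k > n) {
      rlang::abort(
        sprintf("`k_%s` must be an integer in [0, n_%s = %d].", task, task, n),
        class = "tom_data_error", field = paste0("k_", task)
      )
    }
  }
  out <- tibble::tibble(label = as.character(label),
                        k_DB = as.integer(k_DB), n_DB = as.integer(n_DB),
                        k_KA = as.integer(k_KA), n_KA = as.integer(n_KA),
                        k_FB = as.integer(k_FB), n_FB = as.integer(n_FB))
  class(out) <- c("tom_study", class(out))
  out
}

as_tom_study <- function(x) {
  if (inherits(x, "tom_study")) {
    if (nrow(x) != 1L) {
      rlang::abort("Expected exactly one study row.", class = "tom_data_error")
    }
    return(x)
  }
  x <- tibble::as_tibble(x)
  tom_study(if ("label" %in% names(x)) x$label else "study",
            x$k_DB, x$n_DB, x$k_KA, x$n_KA, x$k_FB, x$n_FB)
}

#' Beta prior configuration for the four model parameters
#'
#' Independent beta priors. The defaults place asymmetric `Beta(1, 19)` priors
#' on the two noise parameters `delta` and `epsilon` — mode 0, mean 0.05 —
#' making small values more likely than large ones, and flat `Beta(1, 1)`
#' priors on `pi_B` and `pi_V`. All shapes must be strictly positive.
#'
#' @param a_delta,b_delta,a_epsilon,b_epsilon Beta shapes for `delta`, `epsilon`.
#' @param a_pi_B,b_pi_B,a_pi_V,b_pi_V Beta shapes for `pi_B`, `pi_V`.
#' @return An object of class `tom_priors`.
#' @examples
#' tom_priors()                      # defaults
#' tom_priors(b_delta = 9, b_epsilon = 9)  # weaker shrinkage of the noise terms
#' @export
tom_priors <- function(a_delta = 1, b_delta = 19,
                       a_epsilon = 1, b_epsilon = 19,
                       a_pi_B = 1, b_pi_B = 1,
                       a_pi_V = 1, b_pi_V = 1) {
  shapes <- list(a_delta = a_delta, b_delta = b_delta,
                 a_epsilon = a_epsilon, b_epsilon = b_epsilon,
                 a_pi_B = a_pi_B, b_pi_B = b_pi_B,
                 a_pi_V = a_pi_V, b_pi_V = b_pi_V)
  for (nm in names(shapes)) {
    v <- shapes[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || !is.finite(v) || v <= 0) {
      rlang::abort(sprintf("Beta shape `%s` must be strictly positive.", nm),
                   class = "tom_prior_error", field = nm)
    }
  }
  structure(lapply(shapes, as.numeric), class = "tom_priors")
}

#' @export
print.tom_priors <- function(x, ...) {
  cat("<tom_priors>\n")
  cat(sprintf("  pi_B    ~ Beta(%g, %g)\n", x$a_pi_B, x$b_pi_B))
  cat(sprintf("  pi_V    ~ Beta(%g, %g)\n", x$a_pi_V, x$b_pi_V))
  cat(sprintf("  delta   ~ Beta(%g, %g)\n", x$a_delta, x$b_delta))
  cat(sprintf("  epsilon ~ Beta(%g, %g)\n", x$a_epsilon, x$b_epsilon))
  invisible(x)
}

#' Binomial log-likelihood of study counts under the model
#'
#' Per-child task successes are independent Bernoulli trials, so the group
#' counts are binomial: `k_DB ~ Binom(n_DB, pi_B)`, `k_KA ~ Binom(n_KA,
#' pi_V)`, and `k_FB ~ Binom(n_FB, pi_FB)` with `pi_FB` always the full
#' closed-form prediction (never the product approximation). Binomial
#' coefficients are included. A success probability of exactly 0 with `k > 0`
#' (or 1 with `k < n`) yields `-Inf`, a legal likelihood value distinct from a
#' validation error.
#'
#' @param data A [tom_study()] row (or coercible data frame).
#' @param params A [tom_params()] object.
#' @return The log-likelihood (may be `-Inf`).
#' @examples
#' d <- tom_study("g", 40, 50, 35, 50, 28, 50)
#' log_likelihood(d, tom_params(0.8, 0.7, 0.05, 0.02))
#' @export
log_likelihood <- function(data, params) {
  data <- as_tom_study(data)
  params <- as_tom_params(params)
  p <- c(params$pi_B, params$pi_V, predict_false_belief(params))
  sum(stats::dbinom(c(data$k_DB, data$k_KA, data$k_FB),
                    c(data$n_DB, data$n_KA, data$n_FB),
                    p, log = TRUE))
}

#' Log prior density of the model parameters
#'
#' Sum of four beta log-densities (normalising constants included). Returns
#' `-Inf` at boundary values where a beta density vanishes.
#'
#' @param params A [tom_params()] object.
#' @param priors A [tom_priors()] object.
#' @return The log prior density (may be `-Inf`).
#' @export
log_prior <- function(params, priors = tom_priors()) {
  params <- as_tom_params(params)
  stopifnot(inherits(priors, "tom_priors"))
  stats::dbeta(params$pi_B, priors$a_pi_B, priors$b_pi_B, log = TRUE) +
    stats::dbeta(params$pi_V, priors$a_pi_V, priors$b_pi_V, log = TRUE) +
    stats::dbeta(params$delta, priors$a_delta, priors$b_delta, log = TRUE) +
    stats::dbeta(params$epsilon, priors$a_epsilon, priors$b_epsilon, log = TRUE)
}

#' Unnormalised log posterior of the model parameters
#'
#' @inheritParams log_likelihood
#' @inheritParams log_prior
#' @return `log_likelihood(data, params) + log_prior(params, priors)`.
#' @export
log_posterior <- function(data, params, priors = tom_priors()) {
  log_likelihood(data, params) + log_prior(params, priors)
}

#' Optimiser settings for MAP estimation
#'
#' @param restarts Number of multistart points (>= 1). Starts are a fixed
#'   low-discrepancy (Halton) set plus an empirical plug-in point, so fitting
#'   is deterministic.
#' @param reltol Relative convergence tolerance on the objective.
#' @param maxit Maximum iterations per restart.
#' @return An object of class `tom_control`.
#' @export
fit_control <- function(restarts = 10L, reltol = 1e-8, maxit = 500L) {
  check_count(restarts, "restarts")
  check_count(maxit, "maxit")
  if (!is.numeric(reltol) || length(reltol) != 1L || is.na(reltol) || reltol <= 0) {
    rlang::abort("`reltol` must be a positive number.",
                 class = "tom_validation_error", field = "reltol")
  }
  structure(list(restarts = as.integer(restarts), reltol = reltol,
                 maxit = as.integer(maxit)), class = "tom_control")
}

# Halton low-discrepancy sequence in [0,1]^d — fixed multistart point set.
halton <- function(n, dim = 4L, bases = c(2L, 3L, 5L, 7L)) {
  vdc <- function(i, base) {
    x <- 0; f <- 1 / base
    while (i > 0) {
      x <- x + f * (i %% base)
      i <- i %/% base
      f <- f / base
    }
    x
  }
  sapply(bases[seq_len(dim)], function(b) vapply(seq_len(n), vdc, 0, base = b))
}

# starting points on the probability scale: plug-in first, then Halton points
map_start_points <- function(data, restarts) {
  clip <- function(p) pmin(pmax(p, 0.02), 0.98)
  plug_in <- c(clip(data$k_DB / data$n_DB), clip(data$k_KA / data$n_KA),
               0.05, 0.05)
  n_extra <- restarts - 1L
  pts <- matrix(plug_in, nrow = 1L)
  if (n_extra > 0L) {
    h <- matrix(halton(n_extra), nrow = n_extra)
    # pi_B, pi_V spread over (0.02, 0.98); noise terms over a plausible (0, 0.3)
    extra <- cbind(0.02 + 0.96 * h[, 1L], 0.02 + 0.96 * h[, 2L],
                   0.005 + 0.29 * h[, 3L], 0.005 + 0.29 * h[, 4L])
    pts <- rbind(pts, extra)
  }
  colnames(pts) <- c("pi_B", "pi_V", "delta", "epsilon")
  pts
}

params_from_vec <- function(p) tom_params(p[1L], p[2L], p[3L], p[4L])

# Fast objective/gradient pair for the optimiser, on the logit scale.
# Algebraically identical to -log_posterior(); the equality is asserted by a
# property test. Probabilities are clamped away from 0/1 so the logit-scale
# gradient (chain factor p(1-p)) stays finite when a restart wanders far out.
make_neg_log_post <- function(data, priors) {
  k <- c(data$k_DB, data$k_KA, data$k_FB)
  n <- c(data$n_DB, data$n_KA, data$n_FB)
  a <- c(priors$a_pi_B, priors$a_pi_V, priors$a_delta, priors$a_epsilon)
  b <- c(priors$b_pi_B, priors$b_pi_V, priors$b_delta, priors$b_epsilon)
  clamp <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  fb <- function(p) p[1L] * p[2L] * (1 - p[4L]) + (1 - p[1L] * p[2L]) * p[3L]

  fn <- function(theta) {
    p <- clamp(stats::plogis(theta))
    q <- fb(p)
    v <- sum(stats::dbinom(k, n, c(p[1L], p[2L], q), log = TRUE)) +
      sum(stats::dbeta(p, a, b, log = TRUE))
    if (!is.finite(v)) return(1e12)
    -v
  }
  gr <- function(theta) {
    p <- clamp(stats::plogis(theta))
    q <- clamp(fb(p))
    slope <- 1 - p[4L] - p[3L]                      # d(pi_FB)/d(pi_B pi_V)
    dq <- c(p[2L] * slope, p[1L] * slope, 1 - p[1L] * p[2L], -p[1L] * p[2L])
    g_binom <- c(k[1L] / p[1L] - (n[1L] - k[1L]) / (1 - p[1L]),
                 k[2L] / p[2L] - (n[2L] - k[2L]) / (1 - p[2L]),
                 0, 0)
    g_fb <- (k[3L] / q - (n[3L] - k[3L]) / (1 - q)) * dq
    g_prior <- (a - 1) / p - (b - 1) / (1 - p)
    -(g_binom + g_fb + g_prior) * p * (1 - p)
  }
  list(fn = fn, gr = gr)
}

#' Maximum a posteriori fit of the four model parameters
#'
#' Maximises the log posterior over `(0, 1)^4` by bounded multistart local
#' optimisation on the logit transform of each parameter (BFGS on the
#' unconstrained scale), returning the best terminal point across restarts.
#' The start set is fixed, so the fit is fully deterministic. Estimates
#' within `1e-4` of 0 or 1 are flagged as boundary solutions in
#' `boundary_flags`.
#'
#' @param data A [tom_study()] row (or coercible data frame).
#' @param priors A [tom_priors()] object.
#' @param control A [fit_control()] object.
#' @return An object of class `tom_fit` with elements `map_params`
#'   ([tom_params()]), `log_posterior`, `fitted` (named `pi_B`, `pi_V`,
#'   `pi_FB` — the last always via [predict_false_belief()]), `observed`
#'   (the `k/n` triple), `n_restarts_converged`, `restarts` (per-restart
#'   diagnostics tibble), `boundary_flags`, `method = "optimizer"`, plus the
#'   `data` and `priors` used. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' d <- simulate_study_counts(tom_params(0.8, 0.7, 0.02, 0.02),
#'                            n_per_task = 500, seed = 7)
#' fit <- fit_map(d)
#' tidy(fit)
#' @export
fit_map <- function(data, priors = tom_priors(), control = fit_control()) {
  data <- as_tom_study(data)
  stopifnot(inherits(priors, "tom_priors"), inherits(control, "tom_control"))

  obj <- make_neg_log_post(data, priors)

  starts <- map_start_points(data, control$restarts)
  runs <- purrr::map(seq_len(nrow(starts)), function(i) {
    theta0 <- stats::qlogis(starts[i, ])
    res <- tryCatch(
      stats::optim(theta0, obj$fn, obj$gr, method = "BFGS",
                   control = list(maxit = control$maxit,
                                  reltol = control$reltol)),
      error = function(e) NULL
    )
    if (is.null(res)) {
      return(tibble::tibble(restart = i, value = NA_real_, converged = FALSE,
                            par = list(NULL)))
    }
    tibble::tibble(restart = i, value = -res$value,
                   converged = res$convergence == 0L,
                   par = list(stats::plogis(res$par)))
  })
  runs <- dplyr::bind_rows(runs)
  ok <- !is.na(runs$value)
  if (!any(ok)) {
    rlang::abort("All optimisation restarts failed.",
                 class = "tom_fit_error", diagnostics = runs)
  }
  best <- which.max(runs$value)
  map_vec <- runs$par[[best]]
  map_params <- params_from_vec(map_vec)
  new_tom_fit(map_params, data, priors,
              log_post = runs$value[best],
              method = "optimizer",
              n_restarts_converged = sum(runs$converged, na.rm = TRUE),
              restarts = runs[, c("restart", "value", "converged")])
}

new_tom_fit <- function(map_params, data, priors, log_post, method,
                        n_restarts_converged, restarts) {
  fitted <- c(pi_B = map_params$pi_B, pi_V = map_params$pi_V,
              pi_FB = predict_false_belief(map_params))
  observed <- c(DB = data$k_DB / data$n_DB, KA = data$k_KA / data$n_KA,
                FB = data$k_FB / data$n_FB)
  eps_b <- 1e-4
  flags <- vapply(map_params[c("pi_B", "pi_V", "delta", "epsilon")],
                  function(v) v < eps_b || v > 1 - eps_b, logical(1L))
  structure(
    list(map_params = map_params, log_posterior = log_post, fitted = fitted,
         observed = observed, n_restarts_converged = n_restarts_converged,
         restarts = restarts, boundary_flags = flags, method = method,
         data = data, priors = priors),
    class = "tom_fit"
  )
}

#' @export
print.tom_fit <- function(x, ...) {
  cat(sprintf("<tom_fit>  MAP estimates for group '%s' (%s)\n",
              x$data$label, x$method))
  print(x$map_params)
  cat(sprintf("  pi_FB (closed form) = %.4f\n", x$fitted[["pi_FB"]]))
  cat(sprintf("  log posterior = %.4f\n", x$log_posterior))
  if (any(x$boundary_flags)) {
    cat("  boundary solution in:",
        paste(names(x$boundary_flags)[x$boundary_flags], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Default grid for the grid-search MAP oracle
#'
#' @param pi_step Grid step for `pi_B` and `pi_V` over `[0, 1]`.
#' @param noise_step Grid step for `delta` and `epsilon`.
#' @param noise_max Upper end of the noise grids (the priors concentrate the
#'   noise terms near 0, so a restricted grid keeps the search exhaustive
#'   where mass lives).
#' @return A named list of four grid vectors (`pi_B`, `pi_V`, `delta`,
#'   `epsilon`), which can also be built by hand and passed to
#'   [fit_map_grid()].
#' @export
grid_resolution <- function(pi_step = 0.01, noise_step = 0.005,
                            noise_max = 0.25) {
  list(pi_B = seq(0, 1, by = pi_step), pi_V = seq(0, 1, by = pi_step),
       delta = seq(0, noise_max, by = noise_step),
       epsilon = seq(0, noise_max, by = noise_step))
}

#' Exhaustive grid-search MAP estimate (optimiser oracle)
#'
#' Evaluates the log posterior at every point of a four-dimensional grid and
#' returns the argmax. Exists as an independent check on [fit_map()]: the two
#' must agree within one grid step per coordinate. Ties are broken towards
#' the smallest `(delta, epsilon, pi_B, pi_V)` in lexicographic order.
#'
#' @inheritParams fit_map
#' @param resolution A list of four grid vectors as built by
#'   [grid_resolution()] (each may be a single point).
#' @return A `tom_fit` object with `method = "grid"`.
#' @export
fit_map_grid <- function(data, priors = tom_priors(),
                         resolution = grid_resolution()) {
  data <- as_tom_study(data)
  stopifnot(inherits(priors, "tom_priors"))
  g <- resolution
  for (nm in c("pi_B", "pi_V", "delta", "epsilon")) {
    if (is.null(g[[nm]]) || !is.numeric(g[[nm]]) || length(g[[nm]]) == 0L ||
        anyNA(g[[nm]])) {
      rlang::abort(sprintf("Empty or invalid grid for `%s`.", nm),
                   class = "tom_validation_error", field = nm)
    }
    g[[nm]] <- sort(unique(g[[nm]]))
  }

  # separable pieces: binomial + prior terms in pi_B and pi_V alone
  ll_b <- stats::dbinom(data$k_DB, data$n_DB, g$pi_B, log = TRUE) +
    stats::dbeta(g$pi_B, priors$a_pi_B, priors$b_pi_B, log = TRUE)
  ll_v <- stats::dbinom(data$k_KA, data$n_KA, g$pi_V, log = TRUE) +
    stats::dbeta(g$pi_V, priors$a_pi_V, priors$b_pi_V, log = TRUE)
  # base[i_V, j_B]: column-major scan then finds, among ties, the smallest
  # pi_B first and pi_V second — matching the documented lexicographic order
  base <- outer(ll_v, ll_b, "+")
  prod_pi <- outer(g$pi_V, g$pi_B)

  lp_d <- stats::dbeta(g$delta, priors$a_delta, priors$b_delta, log = TRUE)
  lp_e <- stats::dbeta(g$epsilon, priors$a_epsilon, priors$b_epsilon, log = TRUE)

  best_val <- -Inf
  best <- NULL
  for (id in seq_along(g$delta)) {
    d <- g$delta[id]
    for (ie in seq_along(g$epsilon)) {
      e <- g$epsilon[ie]
      pi_fb <- prod_pi * (1 - e) + (1 - prod_pi) * d
      total <- base + stats::dbinom(data$k_FB, data$n_FB, pi_fb, log = TRUE) +
        lp_d[id] + lp_e[ie]
      m <- max(total)
      # strict > keeps the earliest (smallest delta, then epsilon) among ties
      if (is.null(best) || m > best_val) {
        idx <- which.max(total)  # first occurrence: smallest pi_B, then pi_V
        ij <- arrayInd(idx, dim(total))
        best_val <- m
        best <- c(pi_B = g$pi_B[ij[2L]], pi_V = g$pi_V[ij[1L]],
                  delta = d, epsilon = e)
      }
    }
  }
  map_params <- params_from_vec(best)
  new_tom_fit(map_params, data, priors, log_post = best_val, method = "grid",
              n_restarts_converged = NA_integer_,
              restarts = tibble::tibble(restart = integer(), value = numeric(),
                                        converged = logical()))
}

#' Observed versus fitted proportions for one fit
#'
#' The tabular analogue of a grouped observed-vs-fitted bar chart: one row per
#' task with the observed proportion correct `k/n`, the fitted value
#' (`pi_B`, `pi_V`, or the closed-form `pi_FB`), and the absolute difference.
#'
#' @param fit A [fit_map()] or [fit_map_grid()] result.
#' @return A three-row tibble with columns `task`, `observed`, `fitted`,
#'   `abs_diff`.
#' @export
predicted_vs_observed <- function(fit) {
  stopifnot(inherits(fit, "tom_fit"))
  tibble::tibble(
    task = c("DB", "KA", "FB"),
    observed = unname(fit$observed[c("DB", "KA", "FB")]),
    fitted = unname(fit$fitted[c("pi_B", "pi_V", "pi_FB")]),
    abs_diff = abs(observed - fitted)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_map
#' @param x A `tom_fit` object.
#' @param ... Unused.
#' @method tidy tom_fit
#' @export
tidy.tom_fit <- function(x, ...) {
  tibble::tibble(
    term = c("pi_B", "pi_V", "delta", "epsilon"),
    estimate = unlist(x$map_params[c("pi_B", "pi_V", "delta", "epsilon")],
                      use.names = FALSE),
    boundary = unname(x$boundary_flags)
  )
}

#' @rdname fit_map
#' @method glance tom_fit
#' @export
glance.tom_fit <- function(x, ...) {
  tibble::tibble(
    log_posterior = x$log_posterior,
    pi_FB = x$fitted[["pi_FB"]],
    n_restarts_converged = x$n_restarts_converged,
    method = x$method
  )
}
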