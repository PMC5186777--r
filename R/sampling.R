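#' Forward (ancestral) sampling of the ToM network
#'
#' Draws joint samples of the latent variables by sampling each node after its
#' parents under the fixed evidence `V_S = 1`: the child's own belief `B_S`
#' from `P(B_S | V_S = 1, W)`, the other's visual access `V_O` from
#' `P(V_O | V_S = 1)`, then the other's belief `B_O` from the mixture CPT.
#' Identical `(params, n, seed)` give byte-identical output; the caller's RNG
#' state is left untouched.
#'
#' @param params A [tom_params()] object.
#' @param n Number of samples (positive integer).
#' @param seed Integer seed.
#' @return A tibble with `n` rows and integer columns `v_s` (all 1), `v_o`,
#'   `b_s`, `b_o`.
#' @examples
#' draws <- sample_network(tom_params(0.8, 0.7, 0.05, 0.02), n = 1000, seed = 1)
#' mean(draws$b_o == 0) # near predict_false_belief(...) = 0.5708
#' @export
sample_network <- function(params, n, seed) {
  params <- as_tom_params(params)
  check_count(n, "n")
  check_seed(seed)
  cpts <- build_cpts(params)
  withr::with_seed(seed, {
    b_s <- stats::rbinom(n, 1L, 1 - params$delta)  # P(B_S = 1) = 1 - delta
    v_o <- stats::rbinom(n, 1L, 1 - params$pi_V)   # P(V_O = 1) = 1 - pi_V
    p_bo1 <- cpts$p_bo[cbind(2L, v_o + 1L, b_s + 1L)]
    b_o <- stats::rbinom(n, 1L, p_bo1)
    tibble::tibble(v_s = 1L, v_o = as.integer(v_o),
                   b_s = as.integer(b_s), b_o = as.integer(b_o))
  })
}

#' Simulate ToM-scale study counts for one cohort
#'
#' Emulates a cohort of children assessed on three theory-of-mind scale tasks,
#' treating each child's per-task response as an independent Bernoulli trial:
#' diverse beliefs (DB) with success probability `pi_B`, knowledge access (KA)
#' with `pi_V`, and the unexpected-contents false-belief task (FB) with the
#' model prediction `pi_FB` from [predict_false_belief()]. Per-task draws use
#' sub-streams split from the seed, so adding a task never perturbs earlier
#' draws.
#'
#' @param params A [tom_params()] object (the cohort's true abilities).
#' @param n_per_task Number of children per task (positive integer).
#' @param seed Integer seed.
#' @param label Cohort label carried into the result.
#' @return A `tom_study` tibble (one row): `label`, `k_DB`, `n_DB`, `k_KA`,
#'   `n_KA`, `k_FB`, `n_FB`.
#' @examples
#' simulate_study_counts(tom_params(0.8, 0.7, 0.05, 0.02),
#'                       n_per_task = 50, seed = 1)
#' @export
simulate_study_counts <- function(params, n_per_task, seed, label = "simulated") {
  params <- as_tom_params(params)
  check_count(n_per_task, "n_per_task")
  check_seed(seed)
  pi_fb <- predict_false_belief(params)
  sub <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 3L))
  k <- c(
    withr::with_seed(sub[1L], stats::rbinom(1L, n_per_task, params$pi_B)),
    withr::with_seed(sub[2L], stats::rbinom(1L, n_per_task, params$pi_V)),
    withr::with_seed(sub[3L], stats::rbinom(1L, n_per_task, pi_fb))
  )
  tom_study(label = label,
            k_DB = k[1L], n_DB = n_per_task,
            k_KA = k[2L], n_KA = n_per_task,
            k_FB = k[3L], n_FB = n_per_task)
}

#' Simulate a multi-group study table
#'
#' Generates a long-format study table (one row per group x task) from a data
#' frame of true parameters, one cohort per row, via
#' [simulate_study_counts()]. Per-group sub-seeds are split from `seed`, so a
#' group's counts do not depend on how many groups follow it.
#'
#' @param truth A data frame with columns `group_id`, `pi_B`, `pi_V`, `delta`,
#'   `epsilon`, and optionally `study_id` (default `"synthetic"`) and
#'   `n_per_task` (overrides the argument).
#' @param n_per_task Children per task for every group without its own column.
#' @param seed Integer seed.
#' @return A `tom_study_table` tibble with columns `study_id`, `group_id`,
#'   `task` (DB/KA/FB), `n_correct`, `n_total`.
#' @examples
#' truth <- tibble::tibble(group_id = c("g1", "g2"),
#'                         pi_B = c(0.9, 0.5), pi_V = c(0.8, 0.6),
#'                         delta = 0.02, epsilon = 0.02)
#' simulate_study_table(truth, n_per_task = 60, seed = 1)
#' @export
simulate_study_table <- function(truth, n_per_task, seed) {
  truth <- tibble::as_tibble(truth)
  needed <- c("group_id", "pi_B", "pi_V", "delta", "epsilon")
  missing <- setdiff(needed, names(truth))
  if (length(missing)) {
    rlang::abort(paste0("`truth` is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "tom_schema_error")
  }
  check_seed(seed)
  if (!"study_id" %in% names(truth)) truth$study_id <- "synthetic"
  if (!"n_per_task" %in% names(truth)) truth$n_per_task <- n_per_task
  sub <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, nrow(truth)))
  rows <- purrr::pmap(
    list(truth$study_id, truth$group_id, truth$pi_B, truth$pi_V,
         truth$delta, truth$epsilon, truth$n_per_task, sub),
    function(study_id, group_id, pi_B, pi_V, delta, epsilon, n, s) {
      cohort <- simulate_study_counts(tom_params(pi_B, pi_V, delta, epsilon),
                                      n_per_task = n, seed = s,
                                      label = group_id)
      tibble::tibble(study_id = study_id, group_id = group_id,
                     task = c("DB", "KA", "FB"),
                     n_correct = c(cohort$k_DB, cohort$k_KA, cohort$k_FB),
                     n_total = c(cohort$n_DB, cohort$n_KA, cohort$n_FB))
    }
  )
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tom_study_table", class(out))
  out
}

check_count <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    rlang::abort(sprintf("`%s` must be a positive integer.", field),
                 class = "tom_validation_error", field = field)
  }
  invisible(x)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != floor(seed)) {
    rlang::abort("`seed` must be a single integer.",
                 class = "tom_validation_error", field = "seed")
  }
  invisible(seed)
}
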