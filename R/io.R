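#' Read a long-format study table from CSV
#'
#' Expects a comma-separated UTF-8 file with the exact header
#' `study_id,group_id,task,n_correct,n_total` and one row per group x task.
#' Tasks are `DB` (diverse beliefs), `KA` (knowledge access), `FB`
#' (unexpected-contents false belief). A group is fittable only when all three
#' tasks are present.
#'
#' Validation is strict and errors carry distinct classes: malformed CSV or a
#' wrong header raises `tom_parse_error`; unknown task labels, duplicate
#' group/task rows, or non-integer counts raise `tom_schema_error`; `n_correct
#' > n_total` or `n_total < 1` raise `tom_integrity_error`. Messages name the
#' offending data rows.
#'
#' @param path Path to a CSV file.
#' @return A `tom_study_table` tibble with columns `study_id`, `group_id`,
#'   `task`, `n_correct`, `n_total`, preserving file order.
#' @examples
#' path <- system.file("extdata", "tom_scale_synthetic.csv", package = "tomnet")
#' read_study_table(path)
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path), class = "tom_parse_error")
  }
  header <- readLines(path, n = 1L)
  expected <- "study_id,group_id,task,n_correct,n_total"
  if (!identical(trimws(header), expected)) {
    rlang::abort(
      sprintf("Header must be exactly '%s' (got '%s').", expected, header),
      class = "tom_parse_error"
    )
  }
  tbl <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(
      study_id = readr::col_character(),
      group_id = readr::col_character(),
      task = readr::col_character(),
      n_correct = readr::col_double(),
      n_total = readr::col_double()
    ), progress = FALSE),
    error = function(e) {
      rlang::abort(paste0("Malformed CSV: ", conditionMessage(e)),
                   class = "tom_parse_error")
    }
  )
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0L) {
    rlang::abort(
      sprintf("Malformed CSV: %d parsing problem(s), first at row %d.",
              nrow(probs), probs$row[1L]),
      class = "tom_parse_error"
    )
  }
  validate_study_table(tbl)
}

validate_study_table <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  row_id <- seq_len(nrow(tbl))

  bad_task <- row_id[!tbl$task %in% c("DB", "KA", "FB")]
  if (length(bad_task)) {
    rlang::abort(
      sprintf("Unknown task label(s) in row(s): %s (must be DB, KA, or FB).",
              paste(bad_task, collapse = ", ")),
      class = "tom_schema_error", rows = bad_task
    )
  }
  not_int <- function(x) is.na(x) | x != floor(x)
  bad_count <- row_id[not_int(tbl$n_correct) | not_int(tbl$n_total) |
                        tbl$n_correct < 0]
  if (length(bad_count)) {
    rlang::abort(
      sprintf("Counts must be non-negative integers; bad row(s): %s.",
              paste(bad_count, collapse = ", ")),
      class = "tom_schema_error", rows = bad_count
    )
  }
  dup <- duplicated(tbl[, c("study_id", "group_id", "task")])
  if (any(dup)) {
    rlang::abort(
      sprintf("Duplicate task row(s) for a group: row(s) %s.",
              paste(row_id[dup], collapse = ", ")),
      class = "tom_schema_error", rows = row_id[dup]
    )
  }
  bad_n <- row_id[tbl$n_total < 1 | tbl$n_correct > tbl$n_total]
  if (length(bad_n)) {
    rlang::abort(
      sprintf("n_correct > n_total or n_total < 1 in row(s): %s.",
              paste(bad_n, collapse = ", ")),
      class = "tom_integrity_error", rows = bad_n
    )
  }
  tbl$n_correct <- as.integer(tbl$n_correct)
  tbl$n_total <- as.integer(tbl$n_total)
  if (!inherits(tbl, "tom_study_table")) {
    class(tbl) <- c("tom_study_table", class(tbl))
  }
  tbl
}

#' Write a study table to CSV
#'
#' Inverse of [read_study_table()]: writes the canonical comma-separated,
#' header-first dialect, so read/write round-trips reproduce the file up to
#' whitespace normalisation.
#'
#' @param table A `tom_study_table` (or compatible data frame).
#' @param path Output path.
#' @return `table`, invisibly.
#' @export
write_study_table <- function(table, path) {
  table <- validate_study_table(table)
  readr::write_csv(table[, c("study_id", "group_id", "task",
                             "n_correct", "n_total")], path, progress = FALSE)
  invisible(table)
}

#' Split a study table into per-group study rows
#'
#' @param table A `tom_study_table`.
#' @return A tibble with one row per (study_id, group_id): a `fittable` flag
#'   (all three tasks present) and a list-column `study` of [tom_study()] rows
#'   (`NULL` where unfittable), preserving file order.
#' @export
study_groups <- function(table) {
  table <- validate_study_table(table)
  key <- paste(table$study_id, table$group_id, sep = "\r")
  groups <- unique(key)
  purrr::map(groups, function(k) {
    rows <- table[key == k, ]
    fittable <- all(c("DB", "KA", "FB") %in% rows$task)
    study <- NULL
    if (fittable) {
      g <- function(task, col) rows[[col]][rows$task == task]
      study <- tom_study(
        label = paste(rows$study_id[1L], rows$group_id[1L], sep = ":"),
        k_DB = g("DB", "n_correct"), n_DB = g("DB", "n_total"),
        k_KA = g("KA", "n_correct"), n_KA = g("KA", "n_total"),
        k_FB = g("FB", "n_correct"), n_FB = g("FB", "n_total")
      )
    }
    tibble::tibble(study_id = rows$study_id[1L], group_id = rows$group_id[1L],
                   fittable = fittable, study = list(study))
  }) |> dplyr::bind_rows()
}

#' Fit the model to every group of a study table
#'
#' Runs [fit_map()] independently on each fittable group (no hierarchical
#' pooling), mirroring per-study aggregated fits. Unfittable groups (missing
#' tasks) are skipped with a warning, never a crash; an empty fittable set is
#' an error of class `tom_run_error`.
#'
#' @param table A `tom_study_table` (see [read_study_table()]).
#' @param priors A [tom_priors()] object.
#' @param control A [fit_control()] object.
#' @return An object of class `tom_report`: `fits` (named list of `tom_fit`),
#'   `comparison` (per group x task observed/fitted tibble), `correlation`
#'   (overall observed-vs-fitted linear correlation across all groups and
#'   tasks), `skipped` (labels of unfittable groups), plus the `priors` and
#'   `control` used. Supports `tidy()`, `glance()` and `autoplot()`.
#' @examples
#' truth <- tibble::tibble(group_id = c("3y", "5y"),
#'                         pi_B = c(0.55, 0.9), pi_V = c(0.5, 0.85),
#'                         delta = 0.02, epsilon = 0.02)
#' tbl <- simulate_study_table(truth, n_per_task = 80, seed = 11)
#' rep <- fit_study_table(tbl)
#' rep$correlation
#' @export
fit_study_table <- function(table, priors = tom_priors(),
                            control = fit_control()) {
  groups <- study_groups(table)
  skipped <- character()
  fits <- list()
  for (i in seq_len(nrow(groups))) {
    label <- paste(groups$study_id[i], groups$group_id[i], sep = ":")
    if (!groups$fittable[i]) {
      rlang::warn(sprintf("Group '%s' lacks one of DB/KA/FB; skipped.", label))
      skipped <- c(skipped, label)
      next
    }
    fits[[label]] <- fit_map(groups$study[[i]], priors = priors,
                             control = control)
  }
  if (length(fits) == 0L) {
    rlang::abort("No fittable group in the study table.",
                 class = "tom_run_error")
  }
  comparison <- purrr::imap(fits, function(f, label) {
    dplyr::mutate(predicted_vs_observed(f), group = label, .before = 1L)
  }) |> dplyr::bind_rows()
  correlation <- stats::cor(comparison$observed, comparison$fitted)
  structure(
    list(fits = fits, comparison = comparison, correlation = correlation,
         skipped = skipped, priors = priors, control = control),
    class = "tom_report"
  )
}

#' @export
print.tom_report <- function(x, ...) {
  cat(sprintf("<tom_report>  %d group fit(s), %d skipped\n",
              length(x$fits), length(x$skipped)))
  cat(sprintf("  observed-vs-fitted correlation: %.4f\n", x$correlation))
  print(x$comparison)
  invisible(x)
}

#' @rdname fit_study_table
#' @param x A `tom_report` object.
#' @param ... Unused.
#' @method tidy tom_report
#' @export
tidy.tom_report <- function(x, ...) {
  purrr::imap(x$fits, function(f, label) {
    dplyr::mutate(tidy(f), group = label, .before = 1L)
  }) |> dplyr::bind_rows()
}

#' @rdname fit_study_table
#' @method glance tom_report
#' @export
glance.tom_report <- function(x, ...) {
  tibble::tibble(
    n_groups = length(x$fits),
    n_skipped = length(x$skipped),
    correlation = x$correlation,
    max_abs_diff = max(x$comparison$abs_diff)
  )
}

# deterministic JSON for a single fit; field names fixed by the interchange
# contract: pi_B, pi_V, delta, epsilon, log_posterior, fitted, observed,
# method, boundary_flags
fit_to_json_list <- function(fit) {
  list(
    pi_B = fit$map_params$pi_B,
    pi_V = fit$map_params$pi_V,
    delta = fit$map_params$delta,
    epsilon = fit$map_params$epsilon,
    log_posterior = fit$log_posterior,
    fitted = as.list(fit$fitted),
    observed = as.list(fit$observed),
    method = fit$method,
    boundary_flags = as.list(fit$boundary_flags)
  )
}

#' Serialise a fit or report to JSON
#'
#' @param x A `tom_fit` or `tom_report`.
#' @param path Optional file path; when given, the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_json <- function(x, path = NULL) {
  payload <- if (inherits(x, "tom_fit")) {
    fit_to_json_list(x)
  } else if (inherits(x, "tom_report")) {
    list(groups = purrr::map(x$fits, fit_to_json_list),
         correlation = x$correlation,
         skipped = x$skipped)
  } else {
    rlang::abort("`x` must be a tom_fit or tom_report.",
                 class = "tom_validation_error")
  }
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Run configuration: priors, optimiser settings, seed
#'
#' A serialisable bundle of everything a `fit` run depends on, so that runs
#' are reproducible from a single JSON file. Round-trips losslessly through
#' [write_run_config()] / [read_run_config()].
#'
#' @param priors A [tom_priors()] object.
#' @param control A [fit_control()] object.
#' @param seed Integer seed governing all randomness of a run.
#' @return An object of class `tom_config`.
#' @export
run_config <- function(priors = tom_priors(), control = fit_control(),
                       seed = 1L) {
  stopifnot(inherits(priors, "tom_priors"), inherits(control, "tom_control"))
  check_seed(seed)
  structure(list(priors = priors, control = control, seed = as.integer(seed)),
            class = "tom_config")
}

#' @rdname run_config
#' @param config A `tom_config` object.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "tom_config"))
  payload <- list(priors = unclass(config$priors),
                  control = unclass(config$control),
                  seed = config$seed)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(config)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Config file not found: %s", path),
                 class = "tom_parse_error")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  priors <- do.call(tom_priors, as.list(raw$priors))
  control <- do.call(fit_control, as.list(raw$control))
  run_config(priors = priors, control = control, seed = raw$seed)
}
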