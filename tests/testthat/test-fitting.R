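test_that("study rows validate their counts", {
  expect_s3_class(tom_study("g", 0, 1, 1, 1, 1, 1), "tom_study")
  expect_error(tom_study("g", 5, 4, 1, 1, 1, 1), class = "tom_data_error")
  expect_error(tom_study("g", -1, 4, 1, 1, 1, 1), class = "tom_data_error")
  expect_error(tom_study("g", 1, 0, 1, 1, 1, 1), class = "tom_validation_error")
  expect_error(tom_study("g", 0.5, 4, 1, 1, 1, 1), class = "tom_data_error")
})

test_that("prior configuration validates shapes and defaults are mode-zero on the noise terms", {
  pr <- tom_priors()
  expect_equal(pr$a_delta, 1)
  expect_gt(pr$b_delta, pr$a_delta)  # asymmetric, small values favoured
  expect_gt(pr$b_epsilon, pr$a_epsilon)
  expect_error(tom_priors(a_delta = 0), class = "tom_prior_error")
  expect_error(tom_priors(b_pi_V = -3), class = "tom_prior_error")
  expect_error(tom_priors(b_delta = Inf), class = "tom_prior_error")
})

test_that("log-likelihood matches hand and brute-force factorial oracles", {
  # all probabilities 1 and k = n: every binomial term is log(1) = 0
  d_all <- tom_study("g", 50, 50, 50, 50, 50, 50)
  expect_equal(log_likelihood(d_all, tom_params(1, 1, 0, 0)), 0)
  # single Bernoulli trial on DB, certain successes elsewhere
  # (delta = 1 lifts pi_FB to exactly 1 despite pi_B = 0.5)
  d_one <- tom_study("g", 1, 1, 3, 3, 3, 3)
  expect_equal(log_likelihood(d_one, tom_params(0.5, 1, 1, 0)), log(0.5))
  # general counts against an independent log-factorial evaluation
  d <- tom_study("g", 40, 50, 35, 50, 28, 50)
  p <- ref_params()
  oracle <- log_binom_oracle(40L, 50L, 0.8) +
    log_binom_oracle(35L, 50L, 0.7) +
    log_binom_oracle(28L, 50L, predict_false_belief(p))
  expect_equal(log_likelihood(d, p), oracle, tolerance = 1e-10)
  # zero probability with successes observed is -Inf, not an error
  expect_identical(log_likelihood(d, tom_params(0, 0.5, 0, 0)), -Inf)
  # zero probability with zero successes contributes exactly 0 (0*log 0 := 0)
  expect_identical(log_likelihood(tom_study("g", 0, 5, 5, 5, 5, 5),
                                  tom_params(0, 1, 1, 0)), 0)
})

test_that("log-prior matches the beta density formula", {
  p_interior <- tom_params(0.3, 0.6, 0.05, 0.1)
  expect_equal(log_prior(p_interior, tom_priors(b_delta = 1, b_epsilon = 1)), 0)
  pr <- tom_priors()
  expect_equal(log_prior(tom_params(0.5, 0.5, 0, 0.5), pr) -
                 log_prior(tom_params(0.5, 0.5, 0.5, 0.5), pr) +
                 log(19 * 0.5^18), log(19), tolerance = 1e-10)
  # direct density: Beta(1, 19) at 0.05 is 19 * 0.95^18
  expect_equal(stats::dbeta(0.05, 1, 19, log = TRUE), log(19 * 0.95^18))
  one_delta <- tom_priors(b_pi_B = 1, b_pi_V = 1, b_epsilon = 1)
  expect_equal(log_prior(tom_params(0.5, 0.5, 0.05, 0.5), one_delta),
               log(19 * 0.95^18), tolerance = 1e-12)
  expect_equal(log_prior(tom_params(0.5, 0.5, 0, 0.5), one_delta), log(19))
  # boundary where the density vanishes
  expect_identical(log_prior(tom_params(0.5, 0.5, 1, 0.5), one_delta), -Inf)
})

test_that("log-posterior is likelihood plus prior and -Inf dominates", {
  d <- tom_study("g", 40, 50, 35, 50, 28, 50)
  p <- ref_params()
  flat <- tom_priors(b_delta = 1, b_epsilon = 1)
  expect_equal(log_posterior(d, p, flat), log_likelihood(d, p))
  expect_equal(log_posterior(d, p), log_likelihood(d, p) + log_prior(p))
  expect_identical(log_posterior(d, tom_params(0, 0.5, 0, 0)), -Inf)
  # finite on the open hypercube whenever 0 < k < n on all tasks
  quads <- random_quadruples(50, seed = 5)
  interior <- quads * 0.98 + 0.01
  for (i in seq_len(nrow(interior))) {
    expect_true(is.finite(
      log_posterior(d, tomnet:::params_from_vec(interior[i, ]))))
  }
})

test_that("the internal optimiser objective equals the public posterior", {
  d <- tom_study("g", 33, 60, 41, 60, 20, 60)
  pr <- tom_priors(b_delta = 9, a_pi_B = 2, b_pi_B = 3)
  obj <- tomnet:::make_neg_log_post(d, pr)
  quads <- random_quadruples(25, seed = 31) * 0.9 + 0.05
  for (i in seq_len(nrow(quads))) {
    theta <- stats::qlogis(quads[i, ])
    expect_equal(obj$fn(theta),
                 -log_posterior(d, tomnet:::params_from_vec(quads[i, ]), pr),
                 tolerance = 1e-9)
    numeric_grad <- vapply(1:4, function(j) {
      h <- 1e-6
      tp <- theta; tm <- theta
      tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
      (obj$fn(tp) - obj$fn(tm)) / (2 * h)
    }, numeric(1))
    expect_equal(obj$gr(theta), numeric_grad, tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
})

test_that("MAP fitting recovers ceiling data and simulated truth", {
  d_ceiling <- tom_study("g", 100, 100, 100, 100, 100, 100)
  f <- fit_map(d_ceiling)
  expect_gt(f$map_params$pi_B, 0.98)
  expect_gt(f$map_params$pi_V, 0.98)
  expect_lt(f$map_params$delta, 0.02)
  expect_lt(f$map_params$epsilon, 0.02)

  truth <- tom_params(0.8, 0.7, 0.02, 0.02)
  d <- simulate_study_counts(truth, 10000, seed = 1)
  f2 <- fit_map(d)
  expect_lt(abs(f2$map_params$pi_B - 0.8), 0.02)
  expect_lt(abs(f2$map_params$pi_V - 0.7), 0.02)
  # fitted pi_FB is the closed form of the MAP point (same code path)
  expect_identical(f2$fitted[["pi_FB"]], predict_false_belief(f2$map_params))
  # the MAP beats the empirical plug-in candidate
  plug_in <- tom_params(min(max(d$k_DB / d$n_DB, 0.01), 0.99),
                        min(max(d$k_KA / d$n_KA, 0.01), 0.99), 0.01, 0.01)
  expect_gte(f2$log_posterior, log_posterior(d, plug_in))
  # and every restart's terminal value
  expect_true(all(f2$log_posterior >= f2$restarts$value - 1e-9))
})

test_that("fitting is deterministic and tidiers expose the estimates", {
  d <- tom_study("g", 40, 50, 35, 50, 28, 50)
  f1 <- fit_map(d)
  f2 <- fit_map(d)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$log_posterior, f2$log_posterior)
  td <- tidy(f1)
  expect_identical(td$term, c("pi_B", "pi_V", "delta", "epsilon"))
  expect_true(all(td$estimate >= 0 & td$estimate <= 1))
  gl <- glance(f1)
  expect_identical(gl$method, "optimizer")
  expect_identical(gl$n_restarts_converged, f1$n_restarts_converged)
})

test_that("the grid oracle returns single-point grids and breaks ties lexicographically", {
  d <- tom_study("g", 40, 50, 35, 50, 28, 50)
  point <- list(pi_B = 0.8, pi_V = 0.7, delta = 0.05, epsilon = 0.02)
  g <- fit_map_grid(d, resolution = point)
  expect_equal(unclass(g$map_params)[c("pi_B", "pi_V", "delta", "epsilon")],
               point)
  expect_equal(g$log_posterior,
               log_posterior(d, tomnet:::params_from_vec(unlist(point))))
  expect_identical(g$method, "grid")
  expect_error(fit_map_grid(d, resolution = list(pi_B = numeric(), pi_V = 1,
                                                 delta = 0, epsilon = 0)),
               class = "tom_validation_error")
  # engineered four-way tie: with pi_V = 0 the FB probability is exactly
  # delta, so Binom(1; 2, p) ties delta in {0.4, 0.6} and pi_B in {0.3, 0.7}
  flat <- tom_priors(b_delta = 1, b_epsilon = 1, b_pi_B = 1, b_pi_V = 1)
  d1 <- tom_study("g", 1, 2, 0, 2, 1, 2)
  res <- list(pi_B = c(0.3, 0.7), pi_V = 0,
              delta = c(0.4, 0.6), epsilon = 0.3)
  g2 <- fit_map_grid(d1, priors = flat, resolution = res)
  expect_equal(g2$map_params$delta, 0.4)  # smallest delta wins
  expect_equal(g2$map_params$pi_B, 0.3)   # then smallest pi_B
})

test_that("optimizer and grid oracle agree within one grid step", {
  truth <- tom_params(0.75, 0.6, 0.03, 0.02)
  for (s in 1:5) {
    d <- simulate_study_counts(truth, 400, seed = s)
    f <- fit_map(d)
    g <- fit_map_grid(d)
    expect_lt(abs(f$map_params$pi_B - g$map_params$pi_B), 0.01 + 1e-9)
    expect_lt(abs(f$map_params$pi_V - g$map_params$pi_V), 0.01 + 1e-9)
    expect_lt(abs(f$map_params$delta - g$map_params$delta), 0.005 + 1e-9)
    expect_lt(abs(f$map_params$epsilon - g$map_params$epsilon), 0.005 + 1e-9)
  }
})

test_that("swapping DB and KA counts swaps the two ability estimates", {
  d <- tom_study("g", 45, 60, 30, 60, 20, 60)
  d_swapped <- tom_study("g", 30, 60, 45, 60, 20, 60)
  g <- fit_map_grid(d)
  g_swapped <- fit_map_grid(d_swapped)
  expect_equal(g$map_params$pi_B, g_swapped$map_params$pi_V)
  expect_equal(g$map_params$pi_V, g_swapped$map_params$pi_B)
  expect_equal(g$map_params$delta, g_swapped$map_params$delta)
  f <- fit_map(d)
  f_swapped <- fit_map(d_swapped)
  expect_equal(f$map_params$pi_B, f_swapped$map_params$pi_V, tolerance = 1e-4)
  expect_equal(f$map_params$pi_V, f_swapped$map_params$pi_B, tolerance = 1e-4)
})

test_that("fits with small noise estimates respect the multiplicative relation", {
  truth <- tom_params(0.85, 0.75, 0.02, 0.02)
  for (s in 1:5) {
    f <- fit_map(simulate_study_counts(truth, 1000, seed = s + 100))
    if (max(f$map_params$delta, f$map_params$epsilon) < 0.05) {
      expect_lte(abs(f$fitted[["pi_FB"]] -
                       f$map_params$pi_B * f$map_params$pi_V),
                 max(f$map_params$delta, f$map_params$epsilon) + 1e-12)
    }
  }
})

test_that("predicted versus observed tables are well formed and accurate on consistent data", {
  # counts built to satisfy the multiplicative relation exactly at n = 1000
  d <- tom_study("g", 800, 1000, 700, 1000, 560, 1000)
  f <- fit_map(d)
  tab <- predicted_vs_observed(f)
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$task, c("DB", "KA", "FB"))
  expect_true(all(tab$observed >= 0 & tab$observed <= 1))
  expect_true(all(tab$fitted >= 0 & tab$fitted <= 1))
  expect_lte(max(tab$abs_diff), 0.02)
  expect_identical(tab, predicted_vs_observed(f))
})
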