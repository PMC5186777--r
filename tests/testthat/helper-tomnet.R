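# shared test utilities

# n uniform parameter quadruples in [0,1]^4, reproducible
random_quadruples <- function(n, seed = 424242) {
  withr::with_seed(seed, matrix(
    stats::runif(4L * n), ncol = 4L,
    dimnames = list(NULL, c("pi_B", "pi_V", "delta", "epsilon"))
  ))
}

ref_params <- function() tom_params(0.8, 0.7, 0.05, 0.02)

# brute-force binomial log-pmf via explicit log-factorial summation,
# independent of dbinom
log_binom_oracle <- function(k, n, p) {
  lfact <- function(m) if (m == 0L) 0 else sum(log(seq_len(m)))
  log_coef <- lfact(n) - lfact(k) - lfact(n - k)
  term <- function(count, prob) {
    if (count == 0L) 0 else count * log(prob)
  }
  log_coef + term(k, p) + term(n - k, 1 - p)
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
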