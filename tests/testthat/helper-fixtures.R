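# Shared fixtures, built in code.

# small session with a handful of cells from every class
small_session <- function(n_trials = 40, seed = 7L, error_rate = 0.2,
                          error_degradation = 0) {
  cells <- make_cells(n_mixed = 4, n_pure_sample = 2, n_pure_test = 2,
                      n_choice = 2, n_movement = 2,
                      error_degradation = error_degradation,
                      seed = seed + 1L)
  simulate_session(n_trials = n_trials, cells = cells,
                   error_rate = error_rate, seed = seed)
}

# hand-built encoding fit over a design's columns: named coefficients,
# everything else zero
toy_fit <- function(design, beta0 = 0, coefs = c()) {
  beta <- stats::setNames(numeric(ncol(design$X)), colnames(design$X))
  beta[names(coefs)] <- coefs
  structure(list(beta0 = beta0, beta = beta, lambda_min = NA, lambda_1se = NA,
                 cv = NULL, alpha = 0.95, converged = TRUE,
                 groups = design$groups, y_mean = 1, n_obs = nrow(design$X),
                 include_interactions = design$include_interactions),
            class = "encode_fit")
}

# random sparse fits for oracle-equivalence checks
random_fits <- function(design, n_cells, seed = 1L, n_active = 6) {
  set.seed(seed)
  lapply(seq_len(n_cells), function(i) {
    cols <- sample(colnames(design$X), n_active)
    toy_fit(design, beta0 = stats::rnorm(1, -1, 0.3),
            coefs = stats::setNames(stats::rnorm(n_active, 0, 0.7), cols))
  })
}

# brute-force population logLR by direct enumeration over the 8 conditions
enumerate_population_loglr <- function(fits, design, rows, cells, variable,
                                       Pc, Pe) {
  cond <- task_conditions()
  vapply(rows, function(rw) {
    lik <- numeric(8)
    for (k in 1:8) {
      l <- 1
      for (cl in cells) {
        mu <- conditional_rate(fits[[cl]], design, rw,
                               cond$S[k], cond$T[k], cond$C[k])
        r <- design$y[rw, cl]
        l <- l * stats::dpois(r, mu)
      }
      lik[k] <- l
    }
    v <- switch(variable, sample = cond$S, test = cond$T, xor = cond$xor)
    w <- ifelse(cond$correct, Pc / 2, Pe / 2)
    log(sum(lik[v == +1] * w[v == +1])) -
      log(sum(lik[v == -1] * w[v == -1]))
  }, 0)
}
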