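test_that("conditional rates match direct dot-product evaluation", {
  ses <- small_session(n_trials = 10, seed = 41)
  d <- build_design_matrix(ses, include_interactions = TRUE)
  # intercept-only: mu = 2 under every hypothesis
  f0 <- toy_fit(d, beta0 = log(2))
  expect_equal(conditional_rate(f0, d, 1:5, +1, -1, +1), rep(2, 5))
  # hand-built fit: brute-force eta over a few columns
  coefs <- c(O_13 = 0.5, S_13 = 0.4, ST_14 = -0.3, roll_7 = 0.2)
  f <- toy_fit(d, beta0 = -0.5, coefs = coefs)
  rows <- 3:7
  Xr <- as.matrix(d$X[rows, names(coefs)])
  tr <- ses$trials[match(d$trial[rows], ses$trials$trial), ]
  # observed design columns carry the trial's signs; rescale to hypothesis
  f_x13 <- Xr[, "O_13"]
  f_x14 <- position_basis(d$position[rows], basis_centers()$position[14])
  for (hyp in list(c(1, 1, 1), c(-1, 1, -1), c(1, -1, -1))) {
    eta <- -0.5 + 0.5 * f_x13 + 0.4 * hyp[1] * f_x13 +
      (-0.3) * hyp[1] * hyp[2] * f_x14 + 0.2 * Xr[, "roll_7"]
    expect_equal(conditional_rate(f, d, rows, hyp[1], hyp[2], hyp[3]),
                 exp(eta))
  }
  # flipping S flips only S-carrying contributions
  mu_p <- conditional_rate(f, d, rows, +1, +1, +1)
  mu_m <- conditional_rate(f, d, rows, -1, +1, +1)
  expect_equal(log(mu_p) - log(mu_m),
               2 * (0.4 * f_x13 + (-0.3) * f_x14))
})

test_that("cells without task loadings have exactly zero information", {
  ses <- small_session(n_trials = 10, seed = 42)
  d <- build_design_matrix(ses, include_interactions = TRUE)
  f <- toy_fit(d, beta0 = 0.1, coefs = c(O_12 = 0.7, pitch_5 = 0.3))
  y <- d$y[, 1]
  for (v in c("sample", "test", "xor")) {
    lr <- cell_loglr(f, d, 1:50, y, v, Pc = 0.8, Pe = 0.2, ses$trials)
    expect_true(all(lr == 0))
  }
})

test_that("logLR reduces to the closed-form Poisson ratio without marginalization spread", {
  # both retained conditions per side share mu: mu+ = 2, mu- = 1, r = 2
  ll <- matrix(NA_real_, 1, 8)
  cond <- mixedsel:::task_conditions()
  r <- 2
  for (k in 1:8) {
    mu <- if (cond$S[k] == +1) 2 else 1
    ll[1, k] <- r * log(mu) - mu
  }
  lr <- mixedsel:::loglr_from_loglik(ll, "sample", Pc = 1, Pe = 0)
  expect_equal(lr, 2 * log(2) - 1)
  expect_equal(lr, 0.3862944, tolerance = 1e-6)
})

test_that("sign-adjusted information is positive for the encoded variable only", {
  cells <- make_cells(n_mixed = 0, n_pure_sample = 2, n_pure_test = 0,
                      n_choice = 0, n_movement = 0, seed = 43)
  ses <- simulate_session(n_trials = 120, cells = cells, error_rate = 0.1,
                          seed = 44)
  d <- build_design_matrix(ses, include_interactions = TRUE)
  fold <- condition_folds(ses$trials, 5, seed = 45)
  train_tr <- ses$trials$trial[fold != 1]
  rows_tr <- which(d$trial %in% train_tr & d$frame %% 3 == 0)
  trials_tr <- ses$trials[ses$trials$trial %in% train_tr, ]
  fits <- lapply(1:2, function(j)
    fit_encoding_glm(d, d$y[, j], trials = trials_tr, rows = rows_tr,
                     nlambda = 20, lambda_min_ratio = 0.05, seed = 46))
  w <- segment_windows(ses)
  w <- w[!(w$trial %in% train_tr), ]
  info <- session_information(fits, d, w, ses$trials)
  wa <- window_average(info, windows = "test_early")
  expect_gt(mean(wa$I_sample), 0.05)
  expect_lt(abs(mean(wa$I_test)), 0.05)
  bs <- bootstrap_stat(wa$I_sample, n_boot = 2000, seed = 47)
  expect_lt(bs$p, 0.05)
})

test_that("window averaging preserves constants and separates outcomes", {
  df <- expand.grid(cell = 1, trial = 1:4, frame = 1:3)
  df$window <- "test_early"
  df$correct <- df$trial <= 2
  df$sample <- 0.3
  df$test <- ifelse(df$correct, 0.2, -0.2)
  df$xor <- 0
  wa <- window_average(df)
  expect_equal(wa$I_sample, 0.3)
  expect_equal(wa$I_test, 0)
  wo <- window_average(df, by_outcome = TRUE)
  expect_equal(wo$I_test[wo$correct], 0.2)
  expect_equal(wo$I_test[!wo$correct], -0.2)
})

test_that("logLR values are clamped, never infinite", {
  ses <- small_session(n_trials = 10, seed = 48)
  d <- build_design_matrix(ses, include_interactions = TRUE)
  f <- toy_fit(d, beta0 = 5, coefs = c(S_13 = 30))  # explosive rates
  y <- d$y[, 1]
  lr <- cell_loglr(f, d, seq_len(200), y, "sample", 0.9, 0.1, ses$trials)
  expect_true(all(is.finite(lr)))
  expect_true(all(abs(lr) <= 50))
})
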