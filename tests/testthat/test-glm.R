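test_that("degenerate responses fall back to the Poisson null model", {
  ses <- small_session(n_trials = 12, seed = 31)
  d <- build_design_matrix(ses)
  f0 <- fit_encoding_glm(d, rep(0, nrow(d$X)), trials = ses$trials, seed = 1)
  expect_false(f0$converged)
  expect_true(all(f0$beta == 0))
  # intercept-only MLE: beta0 = log(mean y) in the fallback
  y <- rep(2, nrow(d$X))
  fc <- fit_encoding_glm(d, y, trials = ses$trials, seed = 1)
  expect_equal(fc$beta0, log(2), tolerance = 1e-3)
  expect_true(all(fc$beta == 0))
  expect_false(fc$converged)  # flat response: solver flags, never raises
})

test_that("known sparse coefficients are recovered at lambda_min", {
  ses <- small_session(n_trials = 80, seed = 32)
  d <- build_design_matrix(ses)
  set.seed(33)
  support <- c("S_13", "S_14", "T_13")
  beta_true <- stats::setNames(c(1.2, 0.8, -1.0), support)
  eta <- -1 + as.numeric(d$X[, support] %*% beta_true)
  y <- stats::rpois(length(eta), exp(eta))
  fit <- fit_encoding_glm(d, y, trials = ses$trials, seed = 34)
  expect_true(fit$converged)
  est <- fit$beta_min[support]
  expect_true(all(sign(est) == sign(beta_true)))
  # oracle: unpenalized Poisson fit on the true support
  Xs <- as.matrix(d$X[, support])
  oracle <- stats::glm(y ~ Xs, family = stats::poisson())
  rmse_oracle <- sqrt(mean((stats::coef(oracle)[-1] - beta_true)^2))
  rmse_fit <- sqrt(mean((est - beta_true)^2))
  expect_lt(rmse_fit, 2 * rmse_oracle + 0.05)
  # lambda_1se is never below lambda_min
  expect_gte(fit$lambda_1se, fit$lambda_min)
})

test_that("FDE matches hand-evaluated Poisson deviance arithmetic", {
  y <- c(2, 0); mu <- c(1.5, 0.5); mu0 <- 1
  ll <- function(y, m) sum(ifelse(y == 0, 0, y * log(m)) - m)
  expected <- (ll(y, mu) - ll(y, rep(mu0, 2))) /
    (ll(y, y) - ll(y, rep(mu0, 2)))
  expect_equal(fraction_deviance_explained(mu, y = y, null_rate = mu0),
               expected)
  expect_equal(expected, 0.5849625, tolerance = 1e-6)
})

test_that("FDE hits its analytic limits and flags constant responses", {
  y <- c(3, 0, 1, 2)
  expect_equal(fraction_deviance_explained(y, y = y, null_rate = mean(y)), 1)
  expect_equal(fraction_deviance_explained(rep(mean(y), 4), y = y,
                                           null_rate = mean(y)), 0)
  expect_warning(
    out <- fraction_deviance_explained(c(1, 1), y = c(1, 1), null_rate = 1),
    class = "mixedsel_degenerate")
  expect_true(is.na(out))
})

test_that("held-out FDE separates task-tuned from movement-only cells", {
  cells <- make_cells(n_mixed = 2, n_pure_sample = 2, n_pure_test = 0,
                      n_choice = 0, n_movement = 2, seed = 35)
  ses <- simulate_session(n_trials = 60, cells = cells, error_rate = 0.1,
                          seed = 36)
  d <- build_design_matrix(ses)
  dm <- mixedsel:::subset_design(d, c("roll", "pitch", "yaw"))
  fold <- condition_folds(ses$trials, 5, seed = 37)
  train_tr <- ses$trials$trial[fold != 1]
  rows_tr <- which(d$trial %in% train_tr & d$frame %% 3 == 0)
  rows_te <- which(!(d$trial %in% train_tr) & d$frame %% 3 == 0)
  trials_tr <- ses$trials[ses$trials$trial %in% train_tr, ]
  fde_f <- fde_m <- rep(NA_real_, 6)
  for (j in 1:6) {
    ff <- fit_encoding_glm(d, d$y[, j], trials = trials_tr, rows = rows_tr,
                           nlambda = 20, lambda_min_ratio = 0.05, seed = 38)
    fm <- fit_encoding_glm(dm, d$y[, j], trials = trials_tr, rows = rows_tr,
                           nlambda = 20, lambda_min_ratio = 0.05, seed = 38)
    fde_f[j] <- fraction_deviance_explained(ff, d, d$y[, j], rows = rows_te)
    fde_m[j] <- fraction_deviance_explained(fm, dm, d$y[, j], rows = rows_te)
  }
  names(fde_f) <- names(fde_m) <- as.character(1:6)
  cmp <- compare_full_vs_movement(fde_f, fde_m)
  task <- cmp$cell %in% c("1", "2", "3", "4")
  expect_gt(mean(cmp$delta_fde[task]), 0.05)
  expect_lt(abs(mean(cmp$delta_fde[!task])), 0.1)
})

test_that("fold assignment is stratified by condition", {
  tr <- generate_trials(160, error_rate = 0.25, seed = 39)
  fold <- condition_folds(tr, 5, seed = 40)
  cond <- interaction(tr$S, tr$T, tr$C, drop = TRUE)
  tab <- table(cond, fold)
  expect_true(all(apply(tab, 1, function(r) diff(range(r)) <= 1)))
})
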