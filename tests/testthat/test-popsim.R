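test_that("unit population templates cover the trial types as designed", {
  mx <- unit_population("mixed")
  expect_equal(nrow(mx), 4)
  expect_equal(colSums(mx[, paste0("m", 1:4)]), rep(1, 4),
               ignore_attr = TRUE)  # each type preferred by exactly one cell
  pu <- unit_population("pure")
  expect_equal(colSums(pu[, paste0("m", 1:4)]), rep(2, 4),
               ignore_attr = TRUE)  # each type preferred by one cue cell each
  expect_equal(nrow(unit_population("mixed", 3)), 12)
  expect_equal(as.vector(table(unit_population("mixed", 3)$pref)),
               rep(3, 4))
})

test_that("the copula preserves Poisson marginals and correlation structure", {
  tmpl <- unit_population("mixed", 2)
  sim <- simulate_correlated_poisson(tmpl, 2, 1, rho_noise = 0.1,
                                     n_trials = 10000, seed = 81)
  # marginal means within 3 sigma of their lambda
  for (j in c(1, 5)) {
    lam <- sim$lambda[j, sim$type]
    se <- sqrt(mean(lam) / length(lam))
    expect_lt(abs(mean(sim$counts[, j]) - mean(lam)), 3 * se)
  }
  # chi-square goodness of fit of one cell's counts within one trial type
  rows <- sim$type == 1
  obs <- tabulate(sim$counts[rows, 1] + 1, 8)
  expp <- stats::dpois(0:6, sim$lambda[1, 1])
  expp <- c(expp, 1 - sum(expp)) * sum(obs)
  pval <- stats::chisq.test(obs, p = expp / sum(expp))$p.value
  expect_gt(pval, 0.01)
  # within-type count correlation: positive but attenuated below the
  # latent rho for same-selectivity pairs; near zero otherwise
  cc_same <- stats::cor(sim$counts[rows, 1], sim$counts[rows, 5])
  cc_diff <- stats::cor(sim$counts[rows, 1], sim$counts[rows, 2])
  expect_gt(cc_same, 0.02)
  expect_lt(cc_same, 0.1 + 3 / sqrt(sum(rows)))
  expect_lt(abs(cc_diff), 3 / sqrt(sum(rows)))
  # rho = 0: no within-type correlation anywhere
  sim0 <- simulate_correlated_poisson(tmpl, 2, 1, rho_noise = 0,
                                      n_trials = 5000, seed = 82)
  r0 <- sim0$type == 1
  expect_lt(abs(stats::cor(sim0$counts[r0, 1], sim0$counts[r0, 5])),
            3 / sqrt(sum(r0)))
  expect_identical(sim$counts,
                   simulate_correlated_poisson(tmpl, 2, 1, 0.1, 10000,
                                               seed = 81)$counts)
})

test_that("decoding hits its analytic limits", {
  tmpl <- unit_population("mixed", 2)
  # no rate contrast: chance accuracy (allowed as a degenerate probe)
  sim_flat <- simulate_correlated_poisson(tmpl, 2, 2 - 1e-12, 0,
                                          n_trials = 4000, seed = 83)
  acc <- decode_sim_population(sim_flat, "xor", seed = 84)$accuracy
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 4000))
  # separable limit: silent off preferred type, strong preferred rate
  sim_sep <- simulate_correlated_poisson(tmpl, 12, 0, 0, n_trials = 2000,
                                         seed = 85)
  expect_gt(decode_sim_population(sim_sep, "xor", seed = 86)$accuracy, 0.999)
})

test_that("mixed and pure populations order as the theory predicts", {
  grid <- data.frame(lambda_pref = 2, lambda_unpref = 1, n_sets = 2,
                     rho_noise = 0.1)
  res <- popsim_sweep(grid, n_trials = 1000, n_reps = 40, seed = 87)
  g <- function(mode, v, col) res[res$mode == mode & res$variable == v, col]
  # XOR: mixed beats pure; single cues: pure beats mixed
  expect_gt(g("mixed", "xor", "accuracy") - g("pure", "xor", "accuracy"),
            3 * sqrt(g("mixed", "xor", "accuracy_se")^2 +
                       g("pure", "xor", "accuracy_se")^2))
  expect_gt(g("pure", "sample", "accuracy") -
              g("mixed", "sample", "accuracy"),
            3 * sqrt(g("pure", "sample", "accuracy_se")^2 +
                       g("mixed", "sample", "accuracy_se")^2))
  # energy efficiency: more XOR bits per spike in the mixed population
  expect_gt(g("mixed", "xor", "bits_per_spike"),
            g("pure", "xor", "bits_per_spike"))
  # pure-population XOR accuracy follows p^2 + (1-p)^2
  p <- g("pure", "sample", "accuracy")
  expect_lt(abs(g("pure", "xor", "accuracy") - predicted_xor_accuracy(p)),
            3 * g("pure", "xor", "accuracy_se") + 0.01)
  # determinism of the sweep
  res2 <- popsim_sweep(grid, n_trials = 1000, n_reps = 40, seed = 87)
  expect_identical(res, res2)
})

test_that("predicted XOR accuracy and bits-per-spike arithmetic", {
  expect_equal(predicted_xor_accuracy(0.5), 0.5)
  expect_equal(predicted_xor_accuracy(1), 1)
  expect_equal(predicted_xor_accuracy(0.8), 0.68)
  expect_error(predicted_xor_accuracy(1.2), "\\[0, 1\\]")
  expect_equal(info_per_spike(1, 10), 0.1)
  expect_equal(info_per_spike(0.5, 6) / 2, info_per_spike(0.5, 12))
  expect_error(info_per_spike(1, 0), "positive")
  lam <- unit_population("mixed", 2)
  sim <- simulate_correlated_poisson(lam, 2, 1, 0, 100, seed = 88)
  expect_equal(expected_spikes(sim$lambda), 8 * (2 + 3 * 1) / 4)
})

test_that("invalid simulation configs are rejected", {
  tmpl <- unit_population("pure")
  expect_error(simulate_correlated_poisson(tmpl, 1, 2), "lambda_pref")
  expect_error(simulate_correlated_poisson(tmpl, 2, 1, rho_noise = 1),
               "rho_noise")
})
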