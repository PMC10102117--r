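test_that("population logLR equals the single-cell logLR for one cell", {
  ses <- small_session(n_trials = 12, seed = 61)
  d <- build_design_matrix(ses, include_interactions = TRUE)
  fits <- random_fits(d, 3, seed = 62)
  rows <- seq(5, 120, by = 7)
  pop <- population_loglr(fits, d, rows, cells = 2, variable = "xor",
                          Pc = 0.8, Pe = 0.2)
  single <- cell_loglr(fits[[2]], d, rows, d$y[, 2], "xor", 0.8, 0.2,
                       ses$trials, adjust_sign = FALSE)
  expect_equal(pop, single)
})

test_that("with full conditioning the population logLR is the sum of cell logLRs", {
  ses <- small_session(n_trials = 12, seed = 63)
  d <- build_design_matrix(ses, include_interactions = TRUE)
  # cells driven by S only: under Pe = 0 and the sample variable, both
  # retained conditions per side share mu, so no marginalization spread
  fits <- lapply(c(0.6, -0.4), function(b)
    toy_fit(d, beta0 = -0.3, coefs = c(O_13 = 0.3, S_13 = b)))
  rows <- 1:80
  pop <- population_loglr(fits, d, rows, cells = 1:2, variable = "sample",
                          Pc = 1, Pe = 0)
  s1 <- cell_loglr(fits[[1]], d, rows, d$y[, 1], "sample", 1, 0,
                   ses$trials, adjust_sign = FALSE)
  s2 <- cell_loglr(fits[[2]], d, rows, d$y[, 2], "sample", 1, 0,
                   ses$trials, adjust_sign = FALSE)
  expect_equal(pop, s1 + s2, tolerance = 1e-12)
})

test_that("population logLR matches exhaustive enumeration over all 8 conditions", {
  ses <- small_session(n_trials = 20, seed = 64)
  d <- build_design_matrix(ses, include_interactions = TRUE)
  fits <- random_fits(d, 4, seed = 65)
  rows <- seq(3, 150, by = 11)
  for (v in c("sample", "test", "xor")) {
    pop <- population_loglr(fits, d, rows, cells = 1:4, variable = v,
                            Pc = 0.75, Pe = 0.25)
    oracle <- enumerate_population_loglr(fits, d, rows, 1:4, v, 0.75, 0.25)
    expect_equal(pop, oracle, tolerance = 1e-10)
  }
})

test_that("zero logLR decodes to a fair seeded coin", {
  expect_equal(decode_identity(c(0.5, -0.3)), c(1, -1))
  dec <- decode_identity(rep(0, 4000), seed = 66)
  expect_lt(abs(mean(dec == 1) - 0.5), 3 * sqrt(0.25 / 4000))
  expect_identical(dec, decode_identity(rep(0, 4000), seed = 66))
})

test_that("confusion mutual information matches direct evaluation", {
  expect_equal(confusion_mutual_information(matrix(c(50, 0, 0, 50), 2)), 1)
  expect_equal(confusion_mutual_information(matrix(c(25, 25, 25, 25), 2)), 0)
  mi <- confusion_mutual_information(matrix(c(45, 5, 5, 45), 2))
  expect_equal(mi, 1 - (-0.9 * log2(0.9) - 0.1 * log2(0.1)),
               tolerance = 1e-12)
  expect_equal(mi, 0.531004, tolerance = 1e-6)
  # invariant to joint relabeling
  truth <- c(rep(1, 30), rep(-1, 30)); dec <- rev(truth)
  expect_equal(confusion_mutual_information(truth, dec),
               confusion_mutual_information(-truth, -dec))
  expect_warning(confusion_mutual_information(rep(1, 10), rep(1, 10)),
                 "single-class")
})

test_that("signal and noise correlations behave on constructed populations", {
  tr <- generate_trials(400, error_rate = 0, seed = 67)
  type <- trial_type_of(tr$S, tr$T)
  set.seed(68)
  tuning <- c(4, 1, 1, 1)
  # cell 2 = cell 1 reshuffled within type: identical type means by
  # construction, independent trial-to-trial noise
  c1 <- stats::rpois(400, tuning[type])
  c2 <- c1
  for (k in 1:4) c2[type == k] <- sample(c1[type == k])
  act <- cbind(c1, c2, stats::rpois(400, 2))
  sc <- signal_noise_correlations(act, tr)
  expect_equal(sc$signal[1, 2], 1, tolerance = 1e-12)
  expect_lt(abs(sc$noise[1, 2]), 3 / sqrt(400))
  expect_equal(diag(sc$noise), rep(1, 3), ignore_attr = TRUE)
  # shared latent gain induces positive noise correlation
  gain <- stats::rexp(400)
  act2 <- cbind(stats::rpois(400, 2 * gain), stats::rpois(400, 2 * gain))
  sc2 <- signal_noise_correlations(act2, tr)
  expect_gt(sc2$noise[1, 2], 0.2)
})

test_that("within-condition shuffling preserves condition means exactly", {
  tr <- generate_trials(200, error_rate = 0.25, seed = 69)
  set.seed(70)
  act <- matrix(stats::rpois(200 * 4, 3), 200, 4)
  sh <- shuffle_within_condition(act, tr, seed = 71)
  cond <- interaction(tr$S, tr$T, tr$C, drop = TRUE)
  for (j in 1:4)
    expect_equal(tapply(sh[, j], cond, mean), tapply(act[, j], cond, mean))
  expect_identical(sh, shuffle_within_condition(act, tr, seed = 71))
  # destroys noise correlations between correlated cells
  gain <- stats::rexp(200)
  act2 <- cbind(stats::rpois(200, 3 * gain), stats::rpois(200, 3 * gain))
  sh2 <- shuffle_within_condition(act2, tr, seed = 72)
  resid_of <- function(a) {
    type <- trial_type_of(tr$S, tr$T)
    r <- a
    for (k in 1:4) r[type == k, ] <- sweep(a[type == k, , drop = FALSE], 2,
                                           colMeans(a[type == k, , drop = FALSE]))
    r
  }
  expect_lt(abs(stats::cor(resid_of(sh2))[1, 2]), 3 / sqrt(200))
})

test_that("subsampling variance vanishes at full population size", {
  metric <- function(cells) sum(cells)
  out <- subsample_population(metric, 1:20, n = 20, reps = 10, seed = 73)
  expect_equal(stats::sd(out$values), 0)
  one <- subsample_population(metric, 1:20, n = 5, reps = 1, seed = 74)
  expect_equal(length(one$values), 1)
  expect_error(subsample_population(metric, 1:20, n = 30), "exceeds")
})

test_that("bootstrap se matches the closed-form se of a mean", {
  set.seed(75)
  x <- stats::rnorm(400, 1, 2)
  bs <- bootstrap_stat(x, n_boot = 3000, seed = 76)
  expect_lt(abs(bs$se - 2 / sqrt(400)) / (2 / sqrt(400)), 0.10)
  expect_lt(bs$p, 0.05)  # mean 1 is far from the null of 0
  # identical groups: difference statistic has p near 1
  d <- data.frame(a = x, b = x)
  bs0 <- bootstrap_stat(d, statistic = function(z) mean(z$a - z$b),
                        n_boot = 500, seed = 77)
  expect_gt(bs0$p, 0.5)
  expect_equal(bonferroni_threshold(0.05, 6), 0.05 / 6)
  expect_equal(bonferroni_threshold(0.05, 6), 0.0083333, tolerance = 1e-5)
})

test_that("weighted performance averages follow trial counts", {
  expect_equal(weighted_performance(c(10, 10), c(0.8, 0.6))$p, 0.7)
  expect_equal(weighted_performance(c(10, 30), c(1.0, 0.5))$p, 0.625)
  expect_equal(weighted_performance(c(40, 0), c(0.9, 0.1))$p, 0.9)
  wp <- weighted_performance(c(10, 30), c(0.9, 0.7),
                             p_control = c(0.95, 0.9))
  expect_equal(wp$delta, 0.25 * (0.9 - 0.95) + 0.75 * (0.7 - 0.9))
})
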