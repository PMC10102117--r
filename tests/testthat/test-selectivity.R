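test_that("polar decomposition matches atan2 arithmetic", {
  pd <- polar_decompose(0.03, 0.03)
  expect_equal(pd$r, sqrt(2 * 0.03^2))
  expect_equal(pd$r, 0.0424264, tolerance = 1e-6)
  expect_equal(pd$theta_deg, 45)
  expect_equal(polar_decompose(0.05, 0)$theta_deg, 0)
  expect_equal(polar_decompose(-0.02, 0.02)$theta_deg, 135)
  expect_true(is.na(polar_decompose(0.005, 0.005)$theta_deg))
})

test_that("selectivity classes follow the angle and noise rules", {
  prof <- data.frame(
    I_sample = c(0.05, 0.03, 0.005, 0.004, -0.02, 0.05),
    I_test   = c(0.004, 0.03, 0.005, 0.05, 0.02, -0.03),
    I_xor    = c(0.005, 0.05, 0, 0.002, 0.05, 0.05))
  out <- classify_selectivity(prof, epsilon = 0.01, chance_xor_level = 0.01)
  # near-axis cell snapped to theta = 0, pure sample (XOR below chance)
  expect_equal(out$theta_deg[1], 0)
  expect_equal(out$class[1], "pure_sample")
  # 45 degrees with XOR above chance: mixed
  expect_equal(out$class[2], "mixed")
  # below the noise level: unbinned but kept in the denominator
  expect_equal(out$class[3], "noise")
  expect_true(is.na(out$bin[3]))
  # snapped to theta = 90, pure test
  expect_equal(out$theta_deg[4], 90)
  expect_equal(out$class[4], "pure_test")
  # quadrant cells: wrong-identity encoding
  expect_equal(out$class[5], "incorrect_sample")
  expect_equal(out$class[6], "incorrect_test")
  expect_equal(out$bin[5], "theta>90")
  expect_equal(out$bin[6], "theta<0")
})

test_that("axis cells with XOR above chance are not called pure", {
  prof <- data.frame(I_sample = 0.05, I_test = 0.001, I_xor = 0.04)
  out <- classify_selectivity(prof, epsilon = 0.01, chance_xor_level = 0.01)
  expect_equal(out$theta_deg, 0)
  expect_equal(out$class, "other")
})

test_that("normalized activity sums to one and finds preferences", {
  tr <- generate_trials(80, error_rate = 0, seed = 51)
  type <- trial_type_of(tr$S, tr$T)
  # cell 1 fires only on B/BW (type 1); cell 2 uniform
  act <- cbind(as.numeric(type == 1), rep(0.5, 80))
  na <- normalized_activity(act, tr)
  expect_equal(unlist(na[1, paste0("q", 1:4)]), c(1, 0, 0, 0),
               ignore_attr = TRUE)
  expect_equal(na$pref_type[1], 1)
  expect_equal(unlist(na[2, paste0("q", 1:4)]), rep(0.25, 4),
               ignore_attr = TRUE)
  expect_equal(rowSums(na[, paste0("q", 1:4)]), c(1, 1), ignore_attr = TRUE)
  # cross-validated preference on split halves still sums to one
  nacv <- normalized_activity(act + 0.01, tr, cross_validate = TRUE,
                              seed = 52)
  expect_equal(rowSums(nacv[, paste0("q", 1:4)]), c(1, 1),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("nonlinearity index hits its landmarks and rejects bad input", {
  expect_equal(nonlinearity_index(c(1, 0, 0, 0)), 1)
  expect_equal(nonlinearity_index(c(0.5, 0, 0, 0.5)), 1)   # choice pair
  expect_equal(nonlinearity_index(c(0.4, 0.1, 0.4, 0.1)), 0)
  expect_equal(nonlinearity_index(c(0.5, 0.25, 0.15, 0.10)), 0.2)
  expect_error(nonlinearity_index(c(2, 0, 0, 0)), "normalized")
  # scale invariance via normalization
  raw <- c(8, 4, 2, 2)
  expect_equal(nonlinearity_index(raw / sum(raw)),
               nonlinearity_index(10 * raw / sum(10 * raw)))
})

test_that("chance NI follows the folded-Gaussian oracle and 1/sqrt(n) scaling", {
  lam <- 4
  ni_means <- vapply(c(50, 200), function(n_per_type) {
    n <- 4 * n_per_type
    tr <- generate_trials(n, error_rate = 0, seed = 53)
    set.seed(54)
    act <- matrix(stats::rpois(n * 3, lam), n, 3)
    ch <- shuffle_chance_ni(act, tr, n_shuffles = 400, seed = 55)
    mean(ch$per_cell$mean)
  }, 0)
  oracle <- function(n_per_type) sqrt(2 / pi) / (2 * sqrt(lam * n_per_type))
  expect_lt(abs(ni_means[1] - oracle(50)) / oracle(50), 0.15)
  expect_lt(abs(ni_means[2] - oracle(200)) / oracle(200), 0.15)
  expect_lt(abs(ni_means[1] / ni_means[2] - 2), 0.3)
})

test_that("deterministic equal activity gives exactly zero chance NI", {
  tr <- generate_trials(40, error_rate = 0, seed = 56)
  act <- matrix(1, 40, 2)
  ch <- shuffle_chance_ni(act, tr, n_shuffles = 100, seed = 57)
  expect_true(all(ch$values == 0))
  ch2 <- shuffle_chance_ni(act, tr, n_shuffles = 100, seed = 57)
  expect_identical(ch$values, ch2$values)
})

test_that("conditioned XOR comparison bins at multiples of the bin width", {
  set.seed(58)
  n <- 400
  ti <- data.frame(sample_info = stats::runif(n, 0, 0.05),
                   correct = stats::runif(n) < 0.7)
  ti$xor_info <- ifelse(ti$correct, 0.04, 0.005) + stats::rnorm(n, 0, 0.01)
  out <- compare_xor_by_sample_info(ti, bin_width = 0.01, n_boot = 500,
                                    seed = 59)
  expect_true(all(abs(out$bin_lo / 0.01 - round(out$bin_lo / 0.01)) < 1e-9))
  expect_true(all(out$diff > 0))
  expect_true(any(out$p < 0.05))
  # null process: no bin strongly significant at this seed
  ti$xor_info <- stats::rnorm(n, 0.02, 0.01)
  out0 <- compare_xor_by_sample_info(ti, bin_width = 0.01, n_boot = 500,
                                     seed = 60)
  expect_gt(min(out0$p), 0.01)
})
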