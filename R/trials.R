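#' Generate a trial table for the delayed match-to-sample task
#'
#' Draws independent sample and test cues for each trial, sets the choice to
#' the rewarded direction (the XOR of the two cues) with probability
#' `1 - error_rate`, and draws segment lengths on the 400 cm T-stem: the test
#' segment is fixed at 160 cm, the delay segment is uniform on
#' `delay_range_cm`, and the sample segment takes the remainder.
#'
#' @param n_trials Number of trials (>= 1).
#' @param error_rate Probability that the choice is the unrewarded direction.
#' @param delay_range_cm Length-2 numeric interval within \[20, 100\] cm.
#' @param seed Integer seed; the table is reproducible given the seed.
#' @return A `trial_table` data frame with columns `trial`, `S`, `T`, `C`,
#'   `xor`, `correct`, `sample_len_cm`, `delay_len_cm`, `test_len_cm`.
#' @export
#' @examples
#' tr <- generate_trials(8, error_rate = 0, seed = 1)
#' all(tr$C == tr$S * tr$T)
generate_trials <- function(n_trials, error_rate = 0.1,
                            delay_range_cm = c(20, 100), seed = 1L) {
  if (!is.numeric(n_trials) || n_trials < 1)
    stop("n_trials must be >= 1")
  check_prob(error_rate, "error_rate")
  if (length(delay_range_cm) != 2 || delay_range_cm[1] > delay_range_cm[2] ||
      delay_range_cm[1] < 20 || delay_range_cm[2] > 100)
    stop("delay_range_cm must be an interval within [20, 100]")
  n_trials <- as.integer(n_trials)

  set.seed(seed)
  S <- sample(c(-1, 1), n_trials, replace = TRUE)
  T_ <- sample(c(-1, 1), n_trials, replace = TRUE)
  correct <- stats::runif(n_trials) >= error_rate
  C <- ifelse(correct, S * T_, -S * T_)
  delay <- stats::runif(n_trials, delay_range_cm[1], delay_range_cm[2])
  test <- rep(160, n_trials)
  smp <- 400 - delay - test

  out <- data.frame(
    trial = seq_len(n_trials), S = S, T = T_, C = C, xor = S * T_,
    correct = correct,
    sample_len_cm = smp, delay_len_cm = delay, test_len_cm = test
  )
  class(out) <- c("trial_table", "data.frame")
  attr(out, "error_rate") <- error_rate
  attr(out, "seed") <- seed
  out
}

#' @export
#' @method print trial_table
print.trial_table <- function(x, ...) {
  cat(sprintf("Trial table: %d trials, %.1f%% correct\n",
              nrow(x), 100 * mean(x$correct)))
  cat("Trial-type counts:\n")
  print(table(trial_types()$label[trial_type_of(x$S, x$T)]))
  invisible(x)
}
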