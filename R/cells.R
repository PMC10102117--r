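#' Build a ground-truth cell roster
#'
#' Creates a roster of simulated cells spanning the selectivity classes seen
#' in posterior-cortex imaging during the task: cells preferring one sample
#' cue (`pure_sample`), one test cue (`pure_test`), exactly one of the four
#' trial types (`mixed`, i.e. nonlinear mixed selectivity), one choice
#' direction (`choice`), movement-tuned cells with no task preference
#' (`movement_only`), and optional `silent` cells. Task cells are
#' position-tuned with a raised-cosine envelope; by default their tuning
#' centers tile the test segment, where memory and visual information mix.
#' Movement cells are tuned to the z-scored pitch (forward) velocity instead
#' of position.
#'
#' `error_degradation` in \[0, 1\] scales down the selectivity contrast of
#' `mixed` cells on error trials (1 removes it entirely), emulating the loss
#' of single-trial-type selectivity when the animal chooses incorrectly.
#'
#' @param n_mixed,n_pure_sample,n_pure_test,n_choice,n_movement,n_silent
#'   Cell counts per class.
#' @param rate_pref,rate_unpref Event probability per frame at the tuning
#'   peak on preferred / unpreferred trials (`rate_pref >= rate_unpref`).
#' @param width_cm Full width of the positional raised-cosine envelope.
#' @param center_range_cm Range over which task-cell tuning centers are
#'   spread; the default places them around test-cue onset (240 cm), where
#'   memory and visual information mix and the analysis windows sit.
#' @param error_degradation Factor in \[0, 1\] applied to mixed-cell
#'   selectivity on error trials.
#' @param seed Integer seed (randomizes center jitter and preferences).
#' @return A `cell_roster` data frame.
#' @export
make_cells <- function(n_mixed = 16, n_pure_sample = 12, n_pure_test = 12,
                       n_choice = 8, n_movement = 12, n_silent = 0,
                       rate_pref = 0.5, rate_unpref = 0.05,
                       width_cm = 80, center_range_cm = c(240, 300),
                       error_degradation = 0, seed = 1L) {
  if (rate_pref < rate_unpref || rate_unpref < 0)
    stop("need rate_pref >= rate_unpref >= 0")
  if (rate_pref > 1)
    stop("rate_pref is a per-frame event probability and must be <= 1")
  check_prob(error_degradation, "error_degradation")
  set.seed(seed)

  mk <- function(n, cls) {
    if (n == 0) return(NULL)
    data.frame(class = rep(cls, n),
               pref_S = NA_real_, pref_T = NA_real_, pref_C = NA_real_)
  }
  roster <- rbind(mk(n_mixed, "mixed"), mk(n_pure_sample, "pure_sample"),
                  mk(n_pure_test, "pure_test"), mk(n_choice, "choice"),
                  mk(n_movement, "movement_only"), mk(n_silent, "silent"))
  if (is.null(roster)) stop("roster is empty")
  tt <- trial_types()
  for (i in seq_len(nrow(roster))) {
    cls <- roster$class[i]
    if (cls == "mixed") {
      k <- ((i - 1) %% 4) + 1  # cycle through the four trial types
      roster$pref_S[i] <- tt$S[k]; roster$pref_T[i] <- tt$T[k]
    } else if (cls == "pure_sample") {
      roster$pref_S[i] <- c(-1, 1)[((i - 1) %% 2) + 1]
    } else if (cls == "pure_test") {
      roster$pref_T[i] <- c(-1, 1)[((i - 1) %% 2) + 1]
    } else if (cls == "choice") {
      roster$pref_C[i] <- c(-1, 1)[((i - 1) %% 2) + 1]
    }
  }
  n <- nrow(roster)
  task <- roster$class %in% c("mixed", "pure_sample", "pure_test", "choice")
  x0 <- rep(NA_real_, n)
  x0[task] <- stats::runif(sum(task), center_range_cm[1], center_range_cm[2])
  roster$cell <- seq_len(n)
  roster$x0_cm <- x0
  roster$width_cm <- ifelse(task, width_cm, NA_real_)
  # movement cells: tuning center on z-scored pitch velocity
  roster$z0 <- ifelse(roster$class == "movement_only",
                      stats::runif(n, -1, 1), NA_real_)
  roster$rate_pref <- ifelse(roster$class == "silent", 0, rate_pref)
  roster$rate_unpref <- ifelse(roster$class == "silent", 0,
                               ifelse(roster$class == "movement_only",
                                      rate_pref, rate_unpref))
  roster$error_degradation <- ifelse(roster$class == "mixed",
                                     error_degradation, 0)
  roster <- roster[, c("cell", "class", "pref_S", "pref_T", "pref_C",
                       "x0_cm", "width_cm", "z0", "rate_pref",
                       "rate_unpref", "error_degradation")]
  class(roster) <- c("cell_roster", "data.frame")
  roster
}

# raised-cosine envelope used by the generator (width = full support)
raised_cosine_env <- function(x, center, width) {
  d <- x - center
  ifelse(!is.na(d) & abs(d) < width / 2,
         0.5 * (1 + cos(2 * pi * d / width)), 0)
}

#' Generate binarized event trains for a session
#'
#' Forward model for per-frame event probabilities: a positional (or, for
#' movement cells, velocity) raised-cosine envelope multiplied by
#' `rate_pref` on trials matching the cell's preference and `rate_unpref`
#' otherwise. Mixed cells prefer exactly one (sample, test) combination; on
#' error trials their rate contrast about the midpoint is multiplied by
#' `1 - error_degradation`. Events are independent Bernoulli draws per frame
#' given the rates, so trains are binary as in thresholded deconvolved
#' calcium signals. Inter-trial-interval frames are silent.
#'
#' @param session A `dms_session` from [generate_trajectory()].
#' @param cells A `cell_roster` from [make_cells()].
#' @param seed Integer seed.
#' @return The session with an `events` matrix (frames x cells) and the
#'   roster attached.
#' @export
generate_activity <- function(session, cells, seed = 1L) {
  stopifnot(inherits(session, "dms_session"), inherits(cells, "cell_roster"))
  fr <- session$frames
  trials <- session$trials
  task <- cells$class %in% c("mixed", "pure_sample", "pure_test", "choice")
  if (any(task & (is.na(cells$x0_cm) | cells$x0_cm < 0 |
                  cells$x0_cm > 400 + session$arm_len_cm)))
    stop("tuning centers must lie within the maze span")
  set.seed(seed)

  tr_row <- match(fr$trial, trials$trial)
  n_f <- nrow(fr); n_c <- nrow(cells)
  events <- matrix(0L, n_f, n_c)
  for (j in seq_len(n_c)) {
    cl <- cells[j, ]
    p <- numeric(n_f)
    if (cl$class == "silent") {
      # stays zero
    } else if (cl$class == "movement_only") {
      env <- raised_cosine_env(fr$pitch, cl$z0, 2)
      p <- env * cl$rate_pref
      p[fr$segment == "iti"] <- 0
    } else {
      env <- raised_cosine_env(fr$position, cl$x0_cm, cl$width_cm)
      match_trial <- switch(cl$class,
        mixed       = trials$S == cl$pref_S & trials$T == cl$pref_T,
        pure_sample = trials$S == cl$pref_S,
        pure_test   = trials$T == cl$pref_T,
        choice      = trials$C == cl$pref_C
      )
      r_hi <- cl$rate_pref; r_lo <- cl$rate_unpref
      rate <- ifelse(match_trial[tr_row], r_hi, r_lo)
      if (cl$class == "mixed" && cl$error_degradation > 0) {
        mid <- (r_hi + r_lo) / 2
        shrink <- 1 - cl$error_degradation
        err <- !trials$correct[tr_row]
        err[is.na(err)] <- FALSE  # inter-trial frames
        rate[err] <- mid + shrink * (rate[err] - mid)
      }
      rate[is.na(rate)] <- 0
      p <- env * rate
    }
    if (any(p > 1 + 1e-12))
      stop(sprintf("cell %d: event probability exceeds 1", cl$cell))
    events[, j] <- stats::rbinom(n_f, 1L, pmin(p, 1))
  }
  colnames(events) <- cells$cell
  session$events <- events
  session$cells <- cells
  session
}

#' Simulate a complete synthetic session
#'
#' Convenience wrapper chaining [generate_trials()], [generate_trajectory()]
#' and [generate_activity()] with sub-seeds derived from `seed`.
#'
#' @param n_trials Number of trials.
#' @param cells A `cell_roster`; default roster of 60 cells.
#' @param error_rate Behavioral error probability.
#' @param delay_range_cm Delay-segment length interval (cm).
#' @param speed_mean_cm_s,speed_sd_cm_s Forward-speed distribution.
#' @param delay_cue_velocity_shift Cue-dependent delay running shift.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [generate_trajectory()].
#' @return A `dms_session` with events.
#' @export
simulate_session <- function(n_trials = 250, cells = make_cells(),
                             error_rate = 0.2, delay_range_cm = c(20, 100),
                             speed_mean_cm_s = 50, speed_sd_cm_s = 10,
                             delay_cue_velocity_shift = 0, seed = 1L, ...) {
  trials <- generate_trials(n_trials, error_rate, delay_range_cm,
                            seed = seed)
  session <- generate_trajectory(trials, speed_mean_cm_s, speed_sd_cm_s,
                                 delay_cue_velocity_shift, seed = seed + 1L,
                                 ...)
  generate_activity(session, cells, seed = seed + 2L)
}
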