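#' Generate maze trajectories and treadmill velocities for a trial table
#'
#' Simulates frame-resolved (30 Hz by default) forward progress along the
#' T-stem and arm for each trial, plus three treadmill velocity components
#' (roll, pitch, yaw). Pitch carries the forward running speed; roll and yaw
#' are unit-variance noise. When `delay_cue_velocity_shift` is nonzero, the
#' roll velocity acquires a mean shift of `S * delay_cue_velocity_shift`
#' during the delay segment only, emulating sessions in which the running
#' pattern during the delay depends on the remembered sample cue (a
#' "running mnemonic" confound). Velocities are z-scored over the session.
#'
#' The position axis is a single scalar: cumulative path length, 0 cm at the
#' maze start through 400 cm at the T-intersection and continuing along the
#' chosen arm. Forward speed is truncated below at 1 cm/s so position is
#' non-decreasing within a trial.
#'
#' @param trials A `trial_table` from [generate_trials()].
#' @param speed_mean_cm_s,speed_sd_cm_s Mean and s.d. of per-frame forward
#'   speed (cm/s); mean must be positive.
#' @param delay_cue_velocity_shift Roll-velocity mean shift (in raw s.d.
#'   units) applied during the delay with sign given by the sample cue.
#' @param frame_period Seconds per imaging frame (default 1/30).
#' @param arm_len_cm Path length simulated beyond the T-intersection.
#' @param iti_s Inter-trial interval in seconds (emitted, excluded from
#'   analyses).
#' @param seed Integer seed.
#' @return A `dms_session` list with elements `frames` (data frame: `frame`,
#'   `trial`, `position`, `segment`, `roll`, `pitch`, `yaw`, `speed_cm_s`),
#'   `trials` (input table with per-segment start/end frame columns added),
#'   `frame_period`, and empty `events`/`cells` slots.
#' @export
generate_trajectory <- function(trials, speed_mean_cm_s = 50,
                                speed_sd_cm_s = 10,
                                delay_cue_velocity_shift = 0,
                                frame_period = 1 / 30,
                                arm_len_cm = 60, iti_s = 1, seed = 1L) {
  stopifnot(inherits(trials, "trial_table"))
  if (speed_mean_cm_s <= 0) stop("speed_mean_cm_s must be positive")
  set.seed(seed)

  n_iti <- max(0L, as.integer(round(iti_s / frame_period)))
  seg_levels <- c("sample", "delay", "test", "arm", "iti")
  per_trial <- vector("list", nrow(trials))
  bounds <- matrix(NA_integer_, nrow(trials), 8)
  frame0 <- 0L
  for (k in seq_len(nrow(trials))) {
    tr <- trials[k, ]
    total <- 400 + arm_len_cm
    # generous upper bound on frames needed, then truncate at arm end
    n_max <- ceiling(total / (1 * frame_period)) + 10L
    speed <- pmax(stats::rnorm(n_max, speed_mean_cm_s, speed_sd_cm_s), 1)
    pos <- cumsum(speed * frame_period)
    n <- which(pos >= total)[1]
    if (is.na(n)) n <- n_max
    speed <- speed[seq_len(n)]
    pos <- pos[seq_len(n)]
    seg <- cut(pos,
               breaks = c(-Inf, tr$sample_len_cm,
                          tr$sample_len_cm + tr$delay_len_cm, 400, Inf),
               labels = c("sample", "delay", "test", "arm"))
    seg <- factor(as.character(seg), levels = seg_levels)
    roll <- stats::rnorm(n) +
      ifelse(seg == "delay", tr$S * delay_cue_velocity_shift, 0)
    yaw <- stats::rnorm(n)
    df <- data.frame(trial = tr$trial, position = pos,
                     segment = seg, roll = roll, pitch = speed,
                     yaw = yaw, speed_cm_s = speed)
    if (n_iti > 0) {
      iti <- data.frame(trial = NA_integer_, position = NA_real_,
                        segment = factor("iti", levels = seg_levels),
                        roll = stats::rnorm(n_iti),
                        pitch = pmax(stats::rnorm(n_iti, 5, 5), 0),
                        yaw = stats::rnorm(n_iti),
                        speed_cm_s = 0)
      df <- rbind(df, iti)
    }
    per_trial[[k]] <- df
    seg_idx <- as.integer(seg)
    for (s in 1:4) {
      w <- which(seg_idx == s)
      if (length(w)) bounds[k, c(2 * s - 1, 2 * s)] <- frame0 + range(w)
    }
    frame0 <- frame0 + nrow(df)
  }
  frames <- do.call(rbind, per_trial)
  frames$frame <- seq_len(nrow(frames))
  frames <- frames[, c("frame", "trial", "position", "segment",
                       "roll", "pitch", "yaw", "speed_cm_s")]
  # z-score velocities over the whole session
  for (v in c("roll", "pitch", "yaw")) {
    frames[[v]] <- as.numeric(scale(frames[[v]]))
  }
  colnames(bounds) <- as.vector(t(outer(c("sample", "delay", "test", "arm"),
                                        c("_start", "_end"), paste0)))
  trials <- cbind(trials, as.data.frame(bounds))
  class(trials) <- c("trial_table", "data.frame")

  structure(list(frames = frames, trials = trials,
                 frame_period = frame_period, arm_len_cm = arm_len_cm,
                 events = NULL, cells = NULL),
            class = "dms_session")
}

#' @export
#' @method print dms_session
print.dms_session <- function(x, ...) {
  cat(sprintf("DMS session: %d trials, %d frames at %.1f Hz",
              nrow(x$trials), nrow(x$frames), 1 / x$frame_period))
  if (!is.null(x$events))
    cat(sprintf(", %d cells (%.3f events/frame)",
                ncol(x$events), mean(x$events)))
  cat("\n")
  invisible(x)
}
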