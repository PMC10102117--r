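# Raised-cosine basis expansion and design-matrix construction for the
# Poisson encoding model.

#' Signed positional raised-cosine basis
#'
#' One cycle of a raised cosine with a 40 cm width centered on `x_c`,
#' multiplied by the identity `V` of a binary task variable:
#' `V * 0.5 * (1 + cos(2*pi*(x - x_c)/40))` for `|x - x_c| < 20`, 0 outside.
#'
#' @param x Position (cm along the maze path).
#' @param x_c Basis center (cm).
#' @param V Task-variable sign (+1/-1); use +1 for the offset subset.
#' @return Predictor value(s).
#' @export
#' @examples
#' position_basis(100, 100)        # 1 at the peak
#' position_basis(110, 100, -1)    # -0.5 halfway to the edge
position_basis <- function(x, x_c, V = 1) {
  V * raised_cosine_env(x, x_c, 40)
}

#' Velocity raised-cosine basis
#'
#' One cycle of a raised cosine with width 1 in z-scored velocity:
#' `0.5 * (1 + cos(2*pi*(z - z_c)))` for `|z - z_c| < 0.5`, 0 outside.
#' `z` is clipped to \[-3, 3\] before evaluation.
#'
#' @param z Z-scored velocity.
#' @param z_c Basis center.
#' @return Predictor value(s).
#' @export
velocity_basis <- function(z, z_c) {
  z <- pmin(pmax(z, -3), 3)
  raised_cosine_env(z, z_c, 1)
}

#' Default basis centers
#'
#' 31 position centers at 0, 20, ..., 600 cm (20 cm spacing, half-width
#' overlap, covering the stem and arm path) and 13 velocity centers from -3
#' to 3 in steps of 0.5.
#' @return List with `position` and `velocity` center vectors.
#' @export
basis_centers <- function() {
  list(position = seq(0, 600, by = 20), velocity = seq(-3, 3, by = 0.5))
}

#' Windowed event counts
#'
#' The modelled response at frame i is the event count summed over the 10
#' neighboring frames \[i-5, i+4\] (about 350 ms at 30 Hz), computed per cell.
#'
#' @param events Frames x cells binary matrix.
#' @param before,after Frames before/after included in the window.
#' @return Integer matrix of the same shape.
#' @export
windowed_counts <- function(events, before = 5, after = 4) {
  events <- as.matrix(events)
  n <- nrow(events)
  cs <- apply(events, 2, cumsum)
  cs <- rbind(0, cs)
  lo <- pmax(seq_len(n) - before, 1)
  hi <- pmin(seq_len(n) + after, n)
  out <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  dimnames(out) <- dimnames(events)
  out
}

#' Build the encoding-model design matrix
#'
#' Constructs the predictor matrix over all trial frames (sample through
#' arm; inter-trial frames are excluded). Task predictors comprise the
#' offset (O), sample cue (S), test cue (T) and choice (C) subsets — plus
#' the S*T, T*C, S*C and S*T*C interaction subsets when
#' `include_interactions` is `TRUE` — each expanded over 31 positional
#' raised-cosine bases whose peak sign follows the trial's variable
#' identity. Movement predictors are 13 velocity bases for each of the
#' roll, pitch and yaw z-scored velocities, independent of position.
#' Column counts: 31*4 + 39 = 163, or 31*8 + 39 = 287 with interactions.
#'
#' @param session A `dms_session`.
#' @param include_interactions Include the four interaction subsets.
#' @return A `design_matrix` list: sparse `X`, per-column `groups`, frame
#'   metadata (`frame`, `trial`, `segment`, `position`), the windowed
#'   response matrix `y` (frames x cells) when events are present, and the
#'   basis centers.
#' @export
build_design_matrix <- function(session, include_interactions = FALSE) {
  stopifnot(inherits(session, "dms_session"))
  fr <- session$frames
  keep <- which(fr$segment != "iti" & !is.na(fr$trial))
  dropped <- nrow(fr) - length(keep) -
    sum(fr$segment == "iti", na.rm = TRUE)
  if (dropped > 0)
    message(sprintf("build_design_matrix: %d non-ITI frames without a trial excluded",
                    dropped))
  fr <- fr[keep, ]
  ctr <- basis_centers()

  F_pos <- outer(fr$position, ctr$position,
                 function(x, c) position_basis(x, c))
  G <- do.call(cbind, lapply(c("roll", "pitch", "yaw"), function(v) {
    m <- outer(fr[[v]], ctr$velocity, velocity_basis)
    colnames(m) <- paste0(v, "_", seq_along(ctr$velocity))
    m
  }))

  trials <- session$trials
  tr <- trials[match(fr$trial, trials$trial), ]
  groups <- c("O", "S", "T", "C")
  signs <- list(O = rep(1, nrow(fr)), S = tr$S, T = tr$T, C = tr$C)
  if (include_interactions) {
    groups <- c(groups, "ST", "TC", "SC", "STC")
    signs$ST <- tr$S * tr$T; signs$TC <- tr$T * tr$C
    signs$SC <- tr$S * tr$C; signs$STC <- tr$S * tr$T * tr$C
  }
  task_blocks <- lapply(groups, function(g) {
    m <- F_pos * signs[[g]]
    colnames(m) <- paste0(g, "_", seq_along(ctr$position))
    m
  })
  X <- Matrix::Matrix(cbind(do.call(cbind, task_blocks), G), sparse = TRUE)
  col_groups <- c(rep(groups, each = length(ctr$position)),
                  rep(c("roll", "pitch", "yaw"),
                      each = length(ctr$velocity)))

  y <- NULL
  if (!is.null(session$events)) {
    yw <- windowed_counts(session$events)
    y <- yw[keep, , drop = FALSE]
  }
  structure(list(X = X, groups = col_groups, frame = fr$frame,
                 trial = fr$trial, segment = fr$segment,
                 position = fr$position, y = y,
                 include_interactions = include_interactions,
                 pos_centers = ctr$position, vel_centers = ctr$velocity),
            class = "design_matrix")
}

#' @export
#' @method print design_matrix
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d frames x %d predictors (%s model)\n",
              nrow(x$X), ncol(x$X),
              if (x$include_interactions) "full, 8 task subsets"
              else "4 task subsets"))
  invisible(x)
}

#' Analysis-window frames
#'
#' Returns the frames used for information summaries: the last 1 s of the
#' sample segment, the last 0.35 s of the delay segment (10 frames at
#' 30 Hz), and the first 1 s of the test segment, per trial. Trials with a
#' segment shorter than the window contribute the frames they have.
#'
#' @param session A `dms_session`.
#' @param windows_s Named numeric vector of window durations in seconds.
#' @return Data frame with `frame`, `trial`, `window`.
#' @export
segment_windows <- function(session,
                            windows_s = c(sample_late = 1,
                                          delay_late = 0.35,
                                          test_early = 1)) {
  fp <- session$frame_period
  nfr <- function(s) max(1L, as.integer(s / fp))  # truncate toward shorter
  fr <- session$frames
  out <- list()
  for (k in seq_len(nrow(session$trials))) {
    t_id <- session$trials$trial[k]
    idx <- which(fr$trial == t_id & !is.na(fr$trial))
    seg <- fr$segment[idx]
    take <- function(which_seg, n, from_start) {
      w <- idx[seg == which_seg]
      if (!length(w)) return(integer(0))
      if (from_start) utils::head(w, n) else utils::tail(w, n)
    }
    out[[k]] <- rbind(
      data.frame(frame = take("sample", nfr(windows_s[["sample_late"]]), FALSE),
                 trial = t_id, window = "sample_late"),
      data.frame(frame = take("delay", nfr(windows_s[["delay_late"]]), FALSE),
                 trial = t_id, window = "delay_late"),
      data.frame(frame = take("test", nfr(windows_s[["test_early"]]), TRUE),
                 trial = t_id, window = "test_early")
    )
  }
  do.call(rbind, out)
}
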