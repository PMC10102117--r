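# Task structure shared across the package.
#
# Binary task variables are coded as signs: sample cue S (+1 white, -1 black),
# test cue T (+1 BW, -1 WB), choice C (+1 right, -1 left). The reward
# direction is the XOR combination S*T, which equals C on correct trials.

#' Trial-type table
#'
#' The four trial types of the delayed match-to-sample task, in the canonical
#' order used throughout the package (and by [nonlinearity_index()]):
#' B/BW, B/WB, W/BW, W/WB, where the first letter is the sample cue (black or
#' white) and the second pair is the test cue configuration.
#'
#' @return A data frame with columns `type` (1:4), `label`, `S`, `T`, and
#'   `xor` (= S*T, the rewarded choice direction).
#' @export
#' @examples
#' trial_types()
trial_types <- function() {
  data.frame(
    type  = 1:4,
    label = c("B/BW", "B/WB", "W/BW", "W/WB"),
    S     = c(-1, -1, +1, +1),
    T     = c(+1, -1, +1, -1),
    xor   = c(-1, +1, +1, -1)
  )
}

#' Map sample/test cue signs to a trial-type index
#'
#' @param S,T sign vectors in {-1, +1}.
#' @return Integer vector of trial types 1:4 in the order of [trial_types()].
#' @export
trial_type_of <- function(S, T) {
  tt <- trial_types()
  idx <- match(paste(S, T), paste(tt$S, tt$T))
  if (anyNA(idx)) stop("S and T must be -1 or +1")
  idx
}

# The eight (S, T, C) conditions used for marginalized likelihoods.
# Row order is fixed so that condition log-likelihood matrices line up
# across cells and with the enumeration oracle in the tests.
task_conditions <- function() {
  g <- expand.grid(C = c(-1, 1), T = c(-1, 1), S = c(-1, 1))
  data.frame(S = g$S, T = g$T, C = g$C, xor = g$S * g$T,
             correct = (g$C == g$S * g$T))
}

# Marginalization weights on the 8 conditions for one side (identity = +1 or
# -1) of a task variable. Each retained condition receives Pc/2 when the
# choice matches the reward direction and Pe/2 otherwise; conditions with the
# opposite identity of `variable` get weight 0.
condition_weights <- function(variable = c("sample", "test", "xor"),
                              identity, Pc, Pe) {
  variable <- match.arg(variable)
  stopifnot(identity %in% c(-1, 1))
  if (abs(Pc + Pe - 1) > 1e-8) stop("Pc and Pe must sum to 1")
  cond <- task_conditions()
  v <- switch(variable, sample = cond$S, test = cond$T, xor = cond$xor)
  w <- ifelse(cond$correct, Pc / 2, Pe / 2)
  w[v != identity] <- 0
  w
}

# Observed identity of a task variable on each trial (for sign adjustment).
observed_identity <- function(trials, variable = c("sample", "test", "xor")) {
  variable <- match.arg(variable)
  switch(variable,
    sample = trials$S,
    test   = trials$T,
    xor    = trials$S * trials$T
  )
}

check_prob <- function(p, what) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stop(sprintf("%s must be a probability in [0, 1]", what))
  invisible(p)
}
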