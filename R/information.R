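# Single-trial log-likelihood-ratio information from the encoding model.
#
# The likelihood of observed activity under each hypothesized identity of a
# task variable is a mixture of Poisson likelihoods over the 8 (S, T, C)
# conditions, conditioned on the observed movement and position predictors
# and weighted Pc/2 (choice matches the reward direction) or Pe/2
# (mismatch). Mixtures are evaluated with log-sum-exp; the resulting logLR
# is in natural-log units and clamped to +/- 50.

LOGLR_CLAMP <- 50

logsumexp <- function(m) {
  # rowwise log-sum-exp of a matrix with possible -Inf entries
  mx <- apply(m, 1, max)
  bad <- !is.finite(mx)
  out <- mx + log(rowSums(exp(m - ifelse(bad, 0, mx))))
  out[bad] <- -Inf
  out
}

# Per-frame linear-predictor pieces of one cell's fit, for hypothesis
# evaluation: base = beta0 + offset-group + movement contribution; one
# positional loading per signed task group.
fit_loadings <- function(fit, design, rows) {
  grp <- fit$groups
  F_pos <- design$X[rows, grp == "O", drop = FALSE]
  mov_cols <- grp %in% c("roll", "pitch", "yaw")
  base <- fit$beta0 +
    as.numeric(F_pos %*% fit$beta[grp == "O"]) +
    as.numeric(design$X[rows, mov_cols, drop = FALSE] %*% fit$beta[mov_cols])
  task_groups <- c("S", "T", "C",
                   if (fit$include_interactions) c("ST", "TC", "SC", "STC"))
  loads <- lapply(task_groups, function(g)
    as.numeric(F_pos %*% fit$beta[grp == g]))
  names(loads) <- task_groups
  list(base = base, loads = loads)
}

# Log mean-rate per frame under each of the 8 conditions: n x 8 matrix.
condition_log_mu <- function(fit, design, rows) {
  ld <- fit_loadings(fit, design, rows)
  cond <- task_conditions()
  sign_of <- function(g, k) switch(g,
    S = cond$S[k], T = cond$T[k], C = cond$C[k],
    ST = cond$S[k] * cond$T[k], TC = cond$T[k] * cond$C[k],
    SC = cond$S[k] * cond$C[k], STC = cond$S[k] * cond$T[k] * cond$C[k])
  out <- matrix(0, length(rows), nrow(cond))
  for (k in seq_len(nrow(cond))) {
    eta <- ld$base
    for (g in names(ld$loads)) eta <- eta + sign_of(g, k) * ld$loads[[g]]
    out[, k] <- eta
  }
  out
}

#' Expected count under a hypothesized task condition
#'
#' Evaluates the fitted model's mean count with the task-variable predictor
#' columns set by the hypothesized identities (S, T, C) and the position and
#' movement predictors set by their observed values at the given frames.
#'
#' @param fit A converged `encode_fit`.
#' @param design A `design_matrix`.
#' @param rows Design rows (frames) to evaluate.
#' @param S,T,C Hypothesized signs.
#' @return Vector of expected counts, one per row.
#' @export
conditional_rate <- function(fit, design, rows, S, T, C) {
  stopifnot(S %in% c(-1, 1), T %in% c(-1, 1), C %in% c(-1, 1))
  cond <- task_conditions()
  k <- which(cond$S == S & cond$T == T & cond$C == C)
  mu <- exp(condition_log_mu(fit, design, rows)[, k])
  if (any(!is.finite(mu)))
    stop("non-finite conditional rate; check fit coefficients")
  mu
}

# Condition log-likelihoods for one cell: n x 8 matrix of
# r * log(mu) - mu (lgamma(r+1) omitted; it cancels in every ratio).
condition_loglik <- function(fit, design, rows, y) {
  lmu <- condition_log_mu(fit, design, rows)
  r <- y[rows]
  r * lmu - exp(lmu)
}

# Core logLR from an n x 8 condition log-likelihood matrix.
loglr_from_loglik <- function(ll, variable, Pc, Pe) {
  w_pos <- condition_weights(variable, +1, Pc, Pe)
  w_neg <- condition_weights(variable, -1, Pc, Pe)
  lw_pos <- ifelse(w_pos > 0, log(w_pos), -Inf)
  lw_neg <- ifelse(w_neg > 0, log(w_neg), -Inf)
  num <- logsumexp(sweep(ll, 2, lw_pos, "+"))
  den <- logsumexp(sweep(ll, 2, lw_neg, "+"))
  pmin(pmax(num - den, -LOGLR_CLAMP), LOGLR_CLAMP)
}

#' Single-cell log-likelihood-ratio information
#'
#' Computes the per-frame logLR between the two identities of a task
#' variable from a cell's fitted encoding model, marginalizing over the
#' remaining task variables with outcome proportions `Pc`/`Pe` and
#' conditioning on observed movement. With `adjust_sign = TRUE` the logLR
#' is multiplied by the identity observed on the trial, so a positive value
#' means the activity correctly encodes the variable.
#'
#' @param fit A converged `encode_fit`.
#' @param design A `design_matrix`.
#' @param rows Design rows (frames) to evaluate.
#' @param y Windowed-count response vector for the cell (full design length).
#' @param variable `"sample"`, `"test"`, or `"xor"`.
#' @param Pc,Pe Proportions of correct and error trials (sum to 1).
#' @param trials Trial table (for the observed identity).
#' @param adjust_sign Sign-adjust by the observed identity.
#' @return Numeric vector of logLR values (natural log), one per row.
#' @export
cell_loglr <- function(fit, design, rows, y, variable, Pc, Pe, trials,
                       adjust_sign = TRUE) {
  ll <- condition_loglik(fit, design, rows, y)
  out <- loglr_from_loglik(ll, variable, Pc, Pe)
  if (adjust_sign) {
    obs <- observed_identity(trials, variable)
    out <- out * obs[match(design$trial[rows], trials$trial)]
  }
  out
}

#' Per-frame information table for a set of cells
#'
#' Evaluates sign-adjusted sample, test and XOR logLR for every cell at the
#' analysis-window frames, and returns both the long table and the per-cell
#' condition log-likelihood array reused by the population decoder.
#' Non-converged fits are skipped.
#'
#' @param fits List of `encode_fit` objects indexed by cell.
#' @param design A `design_matrix` whose `y` holds per-cell responses.
#' @param windows Data frame from [segment_windows()] (or a subset).
#' @param trials Trial table.
#' @param Pc,Pe Outcome proportions; default estimated from `trials`.
#' @param cells Cells to include (default: all converged fits).
#' @return A `session_info` list: `info` (long data frame: cell, frame,
#'   trial, window, correct, sample, test, xor), `loglik` (frames x 8 x
#'   cells array), `rows`, `frame_meta`, `Pc`, `Pe`.
#' @export
session_information <- function(fits, design, windows, trials,
                                Pc = NULL, Pe = NULL, cells = NULL) {
  if (is.null(Pc)) Pc <- mean(trials$correct)
  if (is.null(Pe)) Pe <- 1 - Pc
  if (is.null(cells))
    cells <- which(vapply(fits, function(f) isTRUE(f$converged), TRUE))
  rows <- match(windows$frame, design$frame)
  if (anyNA(rows)) stop("windows contain frames outside the design")
  n <- length(rows)
  ll_arr <- array(NA_real_, c(n, 8, length(cells)),
                  dimnames = list(NULL, NULL, cells))
  info <- vector("list", length(cells))
  tr_idx <- match(design$trial[rows], trials$trial)
  meta <- data.frame(frame = windows$frame, trial = windows$trial,
                     window = windows$window,
                     correct = trials$correct[tr_idx])
  for (j in seq_along(cells)) {
    cl <- cells[j]
    ll <- condition_loglik(fits[[cl]], design, rows, design$y[, cl])
    ll_arr[, , j] <- ll
    obs_s <- trials$S[tr_idx]; obs_t <- trials$T[tr_idx]
    info[[j]] <- data.frame(
      cell = cl, meta,
      sample = loglr_from_loglik(ll, "sample", Pc, Pe) * obs_s,
      test   = loglr_from_loglik(ll, "test", Pc, Pe) * obs_t,
      xor    = loglr_from_loglik(ll, "xor", Pc, Pe) * (obs_s * obs_t)
    )
  }
  structure(list(info = do.call(rbind, info), loglik = ll_arr,
                 cells = cells, rows = rows, frame_meta = meta,
                 Pc = Pc, Pe = Pe),
            class = "session_info")
}

#' Window-averaged information per cell
#'
#' Averages sign-adjusted logLR over the frames of each analysis window
#' within a trial, then across trials, per cell (optionally split by trial
#' outcome).
#'
#' @param info A `session_info` object or its long `info` data frame.
#' @param by_outcome Split averages by correct/error.
#' @param windows Subset of window names to keep (default all).
#' @return Data frame with `cell`, `window`, (optionally `correct`,)
#'   `I_sample`, `I_test`, `I_xor`, `n_trials`.
#' @export
window_average <- function(info, by_outcome = FALSE, windows = NULL) {
  df <- if (inherits(info, "session_info")) info$info else info
  if (!is.null(windows)) df <- df[df$window %in% windows, ]
  keys <- c("cell", "window", if (by_outcome) "correct", "trial")
  per_trial <- stats::aggregate(df[, c("sample", "test", "xor")],
                                df[, keys, drop = FALSE], mean)
  keys2 <- setdiff(keys, "trial")
  out <- stats::aggregate(per_trial[, c("sample", "test", "xor")],
                          per_trial[, keys2, drop = FALSE], mean)
  cnt <- stats::aggregate(list(n_trials = per_trial$trial),
                          per_trial[, keys2, drop = FALSE], length)
  out <- merge(out, cnt, by = keys2)
  names(out)[match(c("sample", "test", "xor"), names(out))] <-
    c("I_sample", "I_test", "I_xor")
  out
}
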