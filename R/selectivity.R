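# Selectivity classification in information polar coordinates, normalized
# trial-type activity, and the nonlinearity index.

#' Polar decomposition of cue information
#'
#' Converts per-cell sample and test cue information to a magnitude
#' `r = sqrt(I_sample^2 + I_test^2)` and an angle
#' `theta = atan2(I_test, I_sample)` in degrees. The angle is undefined
#' (NA) when `r < epsilon` — such cells carry only noise-level information.
#'
#' @param I_sample,I_test Window-averaged sign-adjusted logLR values.
#' @param epsilon Noise level below which the angle is undefined.
#' @return Data frame with `r` and `theta_deg`.
#' @export
#' @examples
#' polar_decompose(0.03, 0.03)  # r ~ 0.042, theta = 45
polar_decompose <- function(I_sample, I_test, epsilon = 0.01) {
  r <- sqrt(I_sample^2 + I_test^2)
  theta <- atan2(I_test, I_sample) * 180 / pi
  theta[r < epsilon] <- NA_real_
  data.frame(r = r, theta_deg = theta)
}

#' Classify cue selectivity of cells
#'
#' Implements the polar-angle classification of cue information. Cells with
#' magnitude `r < epsilon` are labelled `noise`: they are not assigned an
#' angle or bin but stay in the denominator of bin fractions. Cells whose
#' test (sample) information is below `epsilon` while the other component is
#' positive are snapped onto the axis, `theta = 0` (`theta = 90`): the axis
#' bins hold cells on the axes and those within noise-level deviation of
#' them. Angles are then assigned to seven bins
#' (`theta < 0`, `0`, `(0, 30)`, `[30, 60)`, `[60, 90)`, `90`,
#' `theta > 90`). Classes: `mixed` for `15 <= theta < 75`; `pure_sample` /
#' `pure_test` for axis cells whose XOR information magnitude is below
#' `chance_xor_level`; `incorrect_sample` (`theta > 90`) and
#' `incorrect_test` (`theta < 0`) for cells encoding the wrong identity;
#' remaining cells are `other`.
#'
#' @param profile Data frame with `I_sample`, `I_test`, `I_xor` per cell
#'   (e.g., one window of [window_average()]).
#' @param epsilon Noise level (logLR units).
#' @param chance_xor_level Chance-level XOR information magnitude; defaults
#'   to `epsilon`. See [estimate_chance_level()].
#' @return The input with `r`, `theta_deg`, `bin`, `class` columns added.
#' @export
classify_selectivity <- function(profile, epsilon = 0.01,
                                 chance_xor_level = epsilon) {
  stopifnot(all(c("I_sample", "I_test", "I_xor") %in% names(profile)))
  Is <- profile$I_sample; It <- profile$I_test; Ix <- profile$I_xor
  r <- sqrt(Is^2 + It^2)
  theta <- atan2(It, Is) * 180 / pi
  snap0 <- abs(It) < epsilon & Is > 0
  snap90 <- abs(Is) < epsilon & It > 0
  theta[snap0] <- 0
  theta[snap90] <- 90
  noise <- r < epsilon
  theta[noise] <- NA_real_

  bin <- rep(NA_character_, length(r))
  bin[!noise & theta < 0] <- "theta<0"
  bin[!noise & theta == 0] <- "theta=0"
  bin[!noise & theta > 0 & theta < 30] <- "(0,30)"
  bin[!noise & theta >= 30 & theta < 60] <- "[30,60)"
  bin[!noise & theta >= 60 & theta < 90] <- "[60,90)"
  bin[!noise & theta == 90] <- "theta=90"
  bin[!noise & theta > 90] <- "theta>90"

  cls <- rep("other", length(r))
  cls[noise] <- "noise"
  mixed <- !noise & theta >= 15 & theta < 75
  cls[mixed] <- "mixed"
  cls[!noise & theta == 0 & abs(Ix) < chance_xor_level] <- "pure_sample"
  cls[!noise & theta == 90 & abs(Ix) < chance_xor_level] <- "pure_test"
  cls[!noise & theta > 90] <- "incorrect_sample"
  cls[!noise & theta < 0] <- "incorrect_test"

  profile$r <- r
  profile$theta_deg <- theta
  profile$bin <- bin
  profile$class <- cls
  profile
}

#' Estimate the chance information level
#'
#' One standard deviation of the test cue information averaged over the late
#' sample-segment window — before the test cue exists, any apparent test
#' cue information is noise, so its spread estimates the chance level.
#'
#' @param info A `session_info` object.
#' @return Scalar chance level (logLR units).
#' @export
estimate_chance_level <- function(info) {
  wa <- window_average(info, windows = "sample_late")
  stats::sd(wa$I_test)
}

#' Normalized activity across the four trial types
#'
#' For each cell, mean activity on correct trials is computed per trial type
#' (order B/BW, B/WB, W/BW, W/WB) and normalized to sum to one with
#' `k = 1 / sum`. The trial type with the highest activity defines the
#' preferred sample and test cues. With `cross_validate = TRUE` the
#' preference is determined on one half of the trials and the reported
#' quadruple computed on the held-out half. With `outcome = "error"` the
#' error-trial means are reported scaled by the correct-trial `k` (and
#' sorted by the correct-trial preference downstream).
#'
#' @param activity Trials x cells matrix of per-trial activity (e.g., mean
#'   events per frame in the early test window).
#' @param trials Trial table matching the rows.
#' @param cross_validate Split-half preference determination.
#' @param outcome `"correct"` or `"error"`.
#' @param seed Seed for the split-half partition.
#' @return Data frame per cell: `q1..q4` (trial-type order), `k`,
#'   `pref_type`, and `sorted_pp, sorted_pu, sorted_up, sorted_uu` (both
#'   cues preferred, sample-only, test-only, neither). Cells with all-zero
#'   activity get NA with a warning.
#' @export
normalized_activity <- function(activity, trials, cross_validate = FALSE,
                                outcome = c("correct", "error"), seed = 1L) {
  outcome <- match.arg(outcome)
  activity <- as.matrix(activity)
  stopifnot(nrow(activity) == nrow(trials))
  type <- trial_type_of(trials$S, trials$T)
  cor_rows <- which(trials$correct)
  if (any(tabulate(type[cor_rows], 4) == 0))
    stop("need at least one correct trial of each trial type")
  set.seed(seed)

  type_means <- function(rows, w) {
    vapply(1:4, function(k) {
      rr <- rows[type[rows] == k & w[rows]]
      if (!length(rr)) return(NA_real_)
      mean(activity[rr, j])
    }, 0)
  }
  n_cells <- ncol(activity)
  out <- data.frame(cell = if (!is.null(colnames(activity)))
    colnames(activity) else seq_len(n_cells))
  qm <- matrix(NA_real_, n_cells, 4)
  pref <- integer(n_cells); kk <- numeric(n_cells)
  keep_all <- rep(TRUE, nrow(trials))
  for (j in seq_len(n_cells)) {
    if (cross_validate) {
      half <- rep(FALSE, nrow(trials))
      for (k in 1:4) {
        rows_k <- intersect(cor_rows, which(type == k))
        half[sample(rows_k, ceiling(length(rows_k) / 2))] <- TRUE
      }
      m_pref <- type_means(cor_rows, half)
      m_eval <- type_means(cor_rows, !half)
    } else {
      m_pref <- m_eval <- type_means(cor_rows, keep_all)
    }
    if (all(m_eval == 0) || anyNA(m_eval)) {
      warning(sprintf("cell %s: all-zero or undefined activity", out$cell[j]))
      next
    }
    k_norm <- 1 / sum(m_eval)
    if (outcome == "error") {
      err_rows <- which(!trials$correct)
      m_eval <- type_means(err_rows, keep_all)
      # scaled by the correct-trial normalization factor
    }
    qm[j, ] <- k_norm * m_eval
    pref[j] <- which.max(m_pref)
    kk[j] <- k_norm
  }
  colnames(qm) <- paste0("q", 1:4)
  out <- cbind(out, qm)
  out$k <- kk
  out$pref_type <- pref

  tt <- trial_types()
  sorted <- t(vapply(seq_len(n_cells), function(j) {
    if (is.na(qm[j, 1])) return(rep(NA_real_, 4))
    ps <- tt$S[pref[j]]; pt <- tt$T[pref[j]]
    idx <- c(which(tt$S == ps & tt$T == pt),   # both preferred
             which(tt$S == ps & tt$T != pt),   # sample preferred only
             which(tt$S != ps & tt$T == pt),   # test preferred only
             which(tt$S != ps & tt$T != pt))   # neither
    qm[j, idx]
  }, numeric(4)))
  colnames(sorted) <- c("sorted_pp", "sorted_pu", "sorted_up", "sorted_uu")
  cbind(out, sorted)
}

#' Nonlinearity index of trial-type tuning
#'
#' `NI = |(k r_B/BW - k r_B/WB) - (k r_W/BW - k r_W/WB)|` on the normalized
#' activity quadruple (trial-type order B/BW, B/WB, W/BW, W/WB, sum 1).
#' Additive (linear) mixing of sample and test tuning gives 0; activity
#' confined to a single trial type — or to the two trial types of one
#' choice direction — gives 1.
#'
#' @param quad Numeric vector of length 4, or a matrix with 4 columns
#'   (`q1..q4`), each row summing to 1.
#' @return NI value(s) in \[0, 1\].
#' @export
#' @examples
#' nonlinearity_index(c(1, 0, 0, 0))           # 1
#' nonlinearity_index(c(0.4, 0.1, 0.4, 0.1))   # 0
nonlinearity_index <- function(quad) {
  m <- if (is.null(dim(quad))) matrix(quad, 1) else as.matrix(quad)
  if (ncol(m) != 4) stop("quad must have 4 components")
  if (any(abs(rowSums(m) - 1) > 1e-6, na.rm = TRUE))
    stop("quadruple must be normalized to sum to 1")
  ni <- abs((m[, 1] - m[, 2]) - (m[, 3] - m[, 4]))
  if (is.null(dim(quad))) ni[1] else ni
}

#' Chance-level nonlinearity index by trial shuffling
#'
#' Permutes trial-type labels across correct trials and recomputes the
#' nonlinearity index per shuffle and cell. Because NI is an absolute
#' value, finite-trial noise alone produces a positive chance level that
#' shrinks as trials per type grow.
#'
#' @param activity Trials x cells matrix.
#' @param trials Trial table.
#' @param n_shuffles Number of permutations (>= 100 recommended).
#' @param seed Integer seed.
#' @return List: `per_cell` data frame (`cell`, `mean`, `sd`), and the
#'   `shuffles` x cells matrix of NI values.
#' @export
shuffle_chance_ni <- function(activity, trials, n_shuffles = 1000,
                              seed = 1L) {
  activity <- as.matrix(activity)
  set.seed(seed)
  cor_rows <- which(trials$correct)
  type <- trial_type_of(trials$S, trials$T)[cor_rows]
  act <- activity[cor_rows, , drop = FALSE]
  ni_of <- function(ty) {
    m <- vapply(1:4, function(k)
      colMeans(act[ty == k, , drop = FALSE]), numeric(ncol(act)))
    m <- m / rowSums(m)  # per-cell normalization
    abs((m[, 1] - m[, 2]) - (m[, 3] - m[, 4]))
  }
  res <- vapply(seq_len(n_shuffles), function(s) ni_of(sample(type)),
                numeric(ncol(act)))
  res <- t(res)
  per_cell <- data.frame(cell = seq_len(ncol(act)),
                         mean = colMeans(res),
                         sd = apply(res, 2, stats::sd))
  list(per_cell = per_cell, values = res)
}

#' XOR information on correct versus error trials, conditioned on sample
#' cue information
#'
#' Bins trials by their preexisting sample cue information (session mean
#' across cells over the late delay window; bin edges at multiples of
#' `bin_width`), then compares mean XOR information between correct and
#' error trials within each populated bin with a bootstrap difference test.
#'
#' @param trial_info Data frame with one row per trial: `sample_info`,
#'   `xor_info`, `correct`.
#' @param bin_width Bin size in logLR units.
#' @param n_boot Bootstrap resamples per bin.
#' @param seed Integer seed.
#' @return Data frame per populated bin: `bin_lo`, `n_correct`, `n_error`,
#'   `mean_correct`, `mean_error`, `diff`, `p`. Bins lacking either outcome
#'   are omitted with a message.
#' @export
compare_xor_by_sample_info <- function(trial_info, bin_width = 0.01,
                                       n_boot = 2000, seed = 1L) {
  stopifnot(all(c("sample_info", "xor_info", "correct") %in%
                  names(trial_info)))
  set.seed(seed)
  b <- floor(trial_info$sample_info / bin_width)
  out <- list()
  skipped <- 0L
  for (bv in sort(unique(b))) {
    rows <- trial_info[b == bv, ]
    xc <- rows$xor_info[rows$correct]
    xe <- rows$xor_info[!rows$correct]
    if (!length(xc) || !length(xe)) { skipped <- skipped + 1L; next }
    bs <- bootstrap_stat(
      rows[, c("xor_info", "correct")],
      statistic = function(d) mean(d$xor_info[d$correct]) -
        mean(d$xor_info[!d$correct]),
      n_boot = n_boot, seed = seed + bv)
    out[[length(out) + 1]] <- data.frame(
      bin_lo = bv * bin_width, n_correct = length(xc), n_error = length(xe),
      mean_correct = mean(xc), mean_error = mean(xe),
      diff = mean(xc) - mean(xe), p = bs$p)
  }
  if (skipped > 0)
    message(sprintf("compare_xor_by_sample_info: %d bins lacking one outcome omitted", skipped))
  do.call(rbind, out)
}
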