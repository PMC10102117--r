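# Population likelihood decoding under conditional independence, and
# correlation / shuffling utilities.

#' Population log-likelihood-ratio information
#'
#' Under conditionally independent noise across simultaneously recorded
#' cells, the population likelihood of each (S, T, C) condition is the
#' product of single-cell Poisson likelihoods; the population logLR then
#' marginalizes over conditions exactly as in the single-cell case. With one
#' cell this reduces to [cell_loglr()]; with `Pe = 0` and a single retained
#' condition per side it is the sum of per-cell logLRs.
#'
#' @param fits List of `encode_fit` objects indexed by cell.
#' @param design A `design_matrix` with per-cell responses in `design$y`.
#' @param rows Design rows (frames) to evaluate.
#' @param cells Cell indices forming the population.
#' @param variable `"sample"`, `"test"`, or `"xor"`.
#' @param Pc,Pe Outcome proportions.
#' @param trials Trial table (needed when `adjust_sign = TRUE`).
#' @param adjust_sign Multiply by the observed identity per trial.
#' @return Per-frame population logLR vector.
#' @export
population_loglr <- function(fits, design, rows, cells, variable, Pc, Pe,
                             trials = NULL, adjust_sign = FALSE) {
  if (!length(cells)) stop("empty cell set")
  if (!all(cells <= length(fits)) ||
      any(vapply(fits[cells], is.null, TRUE)))
    stop("fits missing for some requested cells")
  ll <- 0
  for (cl in cells)
    ll <- ll + condition_loglik(fits[[cl]], design, rows, design$y[, cl])
  out <- loglr_from_loglik(ll, variable, Pc, Pe)
  if (adjust_sign) {
    if (is.null(trials)) stop("trials required for sign adjustment")
    obs <- observed_identity(trials, variable)
    out <- out * obs[match(design$trial[rows], trials$trial)]
  }
  out
}

#' Decode a binary identity from a logLR
#'
#' The decoded identity is the sign of the logLR; exact zeros are broken by
#' a seeded fair coin.
#'
#' @param loglr Numeric vector.
#' @param seed Integer seed for tie-breaking.
#' @return Vector of -1/+1.
#' @export
decode_identity <- function(loglr, seed = 1L) {
  out <- sign(loglr)
  z <- which(out == 0)
  if (length(z)) {
    set.seed(seed)
    out[z] <- sample(c(-1, 1), length(z), replace = TRUE)
  }
  out
}

#' Mutual information of a binary decoding confusion matrix
#'
#' Plug-in mutual information (base 2) between true and decoded identities;
#' 1 bit for a perfect balanced decode, 0 under independence.
#'
#' @param true_ids,decoded_ids Vectors of -1/+1 (or a 2x2 count matrix as
#'   the single first argument).
#' @return Mutual information in bits.
#' @export
confusion_mutual_information <- function(true_ids, decoded_ids = NULL) {
  if (is.matrix(true_ids) && is.null(decoded_ids)) {
    cm <- true_ids
  } else {
    if (length(unique(true_ids)) < 2)
      warning("single-class truth: mutual information is 0")
    cm <- table(factor(true_ids, c(-1, 1)), factor(decoded_ids, c(-1, 1)))
  }
  p <- cm / sum(cm)
  px <- rowSums(p); py <- colSums(p)
  terms <- p * log2(p / outer(px, py))
  sum(terms[p > 0])
}

#' Likelihood decoding of a task variable from a population
#'
#' Per trial, averages the frame-wise population logLR over the early test
#' window, decodes the identity from its sign (seeded coin on ties), and
#' summarizes accuracy as confusion-matrix mutual information, optionally
#' split by trial outcome.
#'
#' @param info A `session_info` object (holds the per-cell condition
#'   log-likelihoods at the analysis windows).
#' @param trials Trial table.
#' @param cells Cell indices (must be a subset of `info$cells`).
#' @param variable Task variable to decode.
#' @param window Analysis window to average over.
#' @param outcome_split Also report correct/error splits.
#' @param seed Tie-breaking seed.
#' @return A `population_decode` list: `per_trial` data frame (`trial`,
#'   `loglr`, `decoded`, `true`, `correct`), `confusion`, `mi`, and (when
#'   split) `mi_correct`, `mi_error`.
#' @export
decode_population <- function(info, trials, cells = info$cells,
                              variable = "xor", window = "test_early",
                              outcome_split = TRUE, seed = 1L) {
  stopifnot(inherits(info, "session_info"))
  j <- match(cells, info$cells)
  if (anyNA(j)) stop("requested cells without stored log-likelihoods")
  keep <- info$frame_meta$window == window
  ll <- 0
  for (idx in j) ll <- ll + info$loglik[keep, , idx]
  loglr <- loglr_from_loglik(ll, variable, info$Pc, info$Pe)
  tr <- info$frame_meta$trial[keep]
  per_trial <- stats::aggregate(list(loglr = loglr), list(trial = tr), mean)
  per_trial$decoded <- decode_identity(per_trial$loglr, seed)
  m <- match(per_trial$trial, trials$trial)
  per_trial$true <- observed_identity(trials, variable)[m]
  per_trial$correct <- trials$correct[m]
  out <- list(per_trial = per_trial,
              confusion = table(factor(per_trial$true, c(-1, 1)),
                                factor(per_trial$decoded, c(-1, 1))),
              mi = confusion_mutual_information(per_trial$true,
                                               per_trial$decoded),
              variable = variable, n_cells = length(cells))
  if (outcome_split) {
    for (oc in c(TRUE, FALSE)) {
      pt <- per_trial[per_trial$correct == oc, ]
      nm <- if (oc) "mi_correct" else "mi_error"
      out[[nm]] <- if (nrow(pt) >= 2 && length(unique(pt$true)) == 2)
        confusion_mutual_information(pt$true, pt$decoded) else NA_real_
    }
  }
  class(out) <- "population_decode"
  out
}

#' @export
#' @method print population_decode
print.population_decode <- function(x, ...) {
  cat(sprintf("Population decode of %s: %d cells, %d trials, MI = %.3f bits\n",
              x$variable, x$n_cells, nrow(x$per_trial), x$mi))
  if (!is.null(x$mi_correct))
    cat(sprintf("  correct trials: %.3f bits; error trials: %.3f bits\n",
                x$mi_correct, x$mi_error))
  invisible(x)
}

#' Decode from selectivity-defined sub-populations
#'
#' Builds the mixed (`class == "mixed"`), pure (`pure_sample` or
#' `pure_test`) and combined partitions from a classified selectivity
#' profile and decodes the task variable from each.
#'
#' @param info A `session_info`.
#' @param trials Trial table.
#' @param profile Output of [classify_selectivity()] with a `cell` column.
#' @param variable Task variable to decode (default `"xor"`).
#' @param window Averaging window.
#' @param seed Tie-breaking seed.
#' @return Named list of `population_decode` objects (`mixed`, `pure`,
#'   `combined`); empty partitions are `NULL` with a message.
#' @export
decode_partitioned_populations <- function(info, trials, profile,
                                           variable = "xor",
                                           window = "test_early",
                                           seed = 1L) {
  parts <- list(
    mixed = profile$cell[profile$class == "mixed"],
    pure = profile$cell[profile$class %in% c("pure_sample", "pure_test")])
  parts$combined <- c(parts$mixed, parts$pure)
  out <- list()
  for (nm in names(parts)) {
    cl <- intersect(parts[[nm]], info$cells)
    if (!length(cl)) {
      message(sprintf("partition '%s' is empty; skipped", nm))
      out[nm] <- list(NULL)
      next
    }
    out[[nm]] <- decode_population(info, trials, cl, variable, window,
                                   seed = seed)
  }
  out
}

#' Signal and noise correlations
#'
#' Signal correlation: Pearson correlation of the two cells' mean activity
#' across the four trial types. Noise correlation: Pearson correlation of
#' residual activity (observed minus own trial-type mean) pooled across all
#' trials of all trial types. Pairs involving a zero-variance cell are NA.
#'
#' @param activity Trials x cells matrix.
#' @param trials Trial table matching the rows.
#' @return List with `signal` and `noise` correlation matrices.
#' @export
signal_noise_correlations <- function(activity, trials) {
  activity <- as.matrix(activity)
  type <- trial_type_of(trials$S, trials$T)
  if (any(tabulate(type, 4) < 2)) stop("need >= 2 trials per trial type")
  means <- vapply(1:4, function(k)
    colMeans(activity[type == k, , drop = FALSE]), numeric(ncol(activity)))
  signal <- suppressWarnings(stats::cor(t(means)))
  resid <- activity
  for (k in 1:4)
    resid[type == k, ] <- sweep(activity[type == k, , drop = FALSE], 2,
                                means[, k])
  noise <- suppressWarnings(stats::cor(resid))
  list(signal = signal, noise = noise)
}

#' Shuffle trials within task conditions
#'
#' Independently for each cell, permutes trial rows within each of the 8
#' conditions (sample cue x test cue x choice). Per-condition mean activity
#' is preserved exactly; trial-to-trial (noise) correlations between cells
#' are destroyed in expectation.
#'
#' @param activity Trials x cells matrix.
#' @param trials Trial table.
#' @param seed Integer seed.
#' @return Shuffled matrix of the same shape.
#' @export
shuffle_within_condition <- function(activity, trials, seed = 1L) {
  activity <- as.matrix(activity)
  set.seed(seed)
  cond <- interaction(trials$S, trials$T, trials$C, drop = TRUE)
  out <- activity
  for (g in levels(cond)) {
    rows <- which(cond == g)
    for (j in seq_len(ncol(activity)))
      out[rows, j] <- activity[sample(rows), j]
  }
  out
}

#' Decoding metric over random cell subsamples
#'
#' @param metric_fun Function taking a vector of cell indices and returning
#'   a scalar metric (e.g., MI from [decode_population()]).
#' @param cells Available cell indices.
#' @param n Subsample size (must not exceed the population).
#' @param reps Number of subsamples.
#' @param seed Integer seed.
#' @return List with `mean`, `se`, and the per-subsample `values`.
#' @export
subsample_population <- function(metric_fun, cells, n = 100, reps = 100,
                                 seed = 1L) {
  if (n > length(cells)) stop("subsample size exceeds population size")
  set.seed(seed)
  vals <- vapply(seq_len(reps),
                 function(i) metric_fun(sample(cells, n)), 0)
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(reps), values = vals)
}
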