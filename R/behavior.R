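# Behavioral statistics: choice bias indices, decoding task variables from
# running patterns, and choice-attribution regression.

#' Choice bias indices
#'
#' From the per-trial-type performance quadruple `P_X/Y` (fraction correct
#' on trials with sample cue X and test cue Y), computes three indices in
#' \[0, 1\]: the color bias (preference for black or white arms), the
#' direction bias (preference for right or left turns), and the direction
#' bias conditioned on the sample cue (different turn preferences for
#' different remembered cues, the running-mnemonic signature).
#'
#' @param q Named numeric vector or list with elements `P_B_BW`, `P_B_WB`,
#'   `P_W_BW`, `P_W_WB`, or a `trial_table` (performance computed per type).
#' @return Named vector `c(color_bias, direction_bias,
#'   conditional_direction_bias)`; an index with a zero denominator is NA
#'   with a warning.
#' @export
#' @examples
#' bias_indices(c(P_B_BW = 1, P_B_WB = 1, P_W_BW = 0, P_W_WB = 0))
bias_indices <- function(q) {
  if (inherits(q, "trial_table")) {
    type <- trial_type_of(q$S, q$T)
    perf <- vapply(1:4, function(k) mean(q$correct[type == k]), 0)
    q <- stats::setNames(perf, c("P_B_BW", "P_B_WB", "P_W_BW", "P_W_WB"))
  }
  q <- unlist(q)[c("P_B_BW", "P_B_WB", "P_W_BW", "P_W_WB")]
  if (anyNA(q)) stop("q must supply all four trial-type performances")
  bbw <- q[["P_B_BW"]]; bwb <- q[["P_B_WB"]]
  wbw <- q[["P_W_BW"]]; wwb <- q[["P_W_WB"]]
  ratio <- function(num, den) {
    if (den == 0) { warning("zero denominator in a bias index"); NA_real_ }
    else abs(num) / den
  }
  color <- ratio((bbw + bwb) - (wbw + wwb), bbw + bwb + wbw + wwb)
  direction <- ratio((bwb + wbw) - (bbw + wwb), bwb + wbw + bbw + wwb)
  cond <- mean(c(ratio(bwb - bbw, bwb + bbw), ratio(wbw - wwb, wbw + wwb)))
  c(color_bias = color, direction_bias = direction,
    conditional_direction_bias = cond)
}

# subsample the majority class to balance binary labels (seeded upstream)
balance_classes <- function(labels) {
  pos <- which(labels == +1); neg <- which(labels == -1)
  n <- min(length(pos), length(neg))
  sort(c(sample(pos, n), sample(neg, n)))
}

#' Decode a binary task variable from trial features
#'
#' Cross-validated L2-regularized logistic decoding: the logit of the class
#' probability is fitted as a weighted sum of the features (e.g., mean
#' z-scored velocities over a 0.35 s window) on 80% of trials and evaluated
#' on the held-out 20%, cycling through `n_splits` splits. Class imbalance
#' is handled by subsampling the majority class in each training set. A
#' zero logit on a test trial is decoded by a seeded fair coin.
#'
#' @param features Trials x features matrix.
#' @param labels Vector of -1/+1 per trial.
#' @param n_splits Train/test splits to cycle through.
#' @param seed Integer seed.
#' @return List: `accuracy` (overall fraction of test trials decoded
#'   correctly), `per_split` accuracies, `n_used`.
#' @export
decode_binary_from_features <- function(features, labels, n_splits = 5,
                                        seed = 1L) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels), all(labels %in% c(-1, 1)))
  if (ncol(features) == 1)  # the solver wants >= 2 columns
    features <- cbind(features, 0)
  set.seed(seed)
  fold <- integer(length(labels))
  for (s in c(-1, 1)) {
    idx <- sample(which(labels == s))
    fold[idx] <- rep_len(sample(n_splits), length(idx))
  }
  correct <- logical(0); per_split <- numeric(0)
  for (f in seq_len(n_splits)) {
    train <- which(fold != f); test <- which(fold == f)
    if (length(unique(labels[train])) < 2 ||
        length(unique(labels[test])) < 1) {
      message(sprintf("split %d skipped: a class is absent", f))
      next
    }
    train <- train[balance_classes(labels[train])]
    yb <- (labels[train] + 1) / 2
    cvfit <- tryCatch(
      glmnet::cv.glmnet(features[train, , drop = FALSE], yb,
                        family = "binomial", alpha = 0, nfolds = 10,
                        standardize = FALSE),
      error = function(e) NULL)
    if (is.null(cvfit)) { message(sprintf("split %d skipped: fit failed", f)); next }
    logit <- as.numeric(stats::predict(cvfit, features[test, , drop = FALSE],
                                       s = "lambda.1se", type = "link"))
    dec <- decode_identity(logit, seed + f)
    ok <- dec == labels[test]
    correct <- c(correct, ok)
    per_split <- c(per_split, mean(ok))
  }
  if (!length(correct)) stop("no usable splits")
  list(accuracy = mean(correct), per_split = per_split,
       n_used = length(correct))
}

#' Attribute choices to the presented versus running-decoded sample cue
#'
#' Logistic regression of the probability of choosing the white arm on the
#' presented sample cue `S` and the cue decoded from the delay running
#' pattern `S_hat` (both coded +1 white / -1 black):
#' `logit P(white) = b0 + b1*S + b2*S_hat`. An equal number of white- and
#' black-chosen trials is sampled; L2 regularization with 10-fold
#' cross-validation. A dominant `b1` means choices follow the cue itself; a
#' dominant `b2` means they follow the running mnemonic.
#'
#' @param S Presented sample cue per trial (-1/+1).
#' @param S_hat Running-decoded sample cue per trial (-1/+1).
#' @param choice_white Logical (or -1/+1 choice-color code) per trial.
#' @param seed Integer seed.
#' @return Named coefficient vector `c(b0, b1, b2)`.
#' @export
choice_attribution_regression <- function(S, S_hat, choice_white,
                                          seed = 1L) {
  if (is.logical(choice_white)) choice_white <- ifelse(choice_white, 1, -1)
  stopifnot(length(S) == length(S_hat), length(S) == length(choice_white))
  if (length(unique(choice_white)) < 2)
    stop("choices are constant; attribution undefined")
  set.seed(seed)
  keep <- balance_classes(choice_white)
  X <- cbind(S = S[keep], S_hat = S_hat[keep])
  y <- (choice_white[keep] + 1) / 2
  cvfit <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 0,
                             nfolds = 10, standardize = FALSE)
  co <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
  stats::setNames(co, c("b0", "b1", "b2"))
}
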