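# Elastic-net Poisson encoding model, fitted per cell.

#' Condition-stratified fold assignment
#'
#' Assigns trials to `k` folds so that each fold has (as near as possible)
#' an equal number of trials from each of the 8 conditions defined by the
#' combination of sample cue, test cue and choice.
#'
#' @param trials A `trial_table`.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per trial (in trial-table order).
#' @export
condition_folds <- function(trials, k = 5, seed = 1L) {
  set.seed(seed)
  cond <- interaction(trials$S, trials$T, trials$C, drop = TRUE)
  fold <- integer(nrow(trials))
  for (g in levels(cond)) {
    idx <- sample(which(cond == g))
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  fold
}

#' Fit the elastic-net Poisson encoding model for one cell
#'
#' Fits event counts (10-frame windowed sums) against the design matrix by
#' penalized Poisson regression with mixing parameter `alpha = 0.95`
#' (L1-like), choosing the penalty by 10-fold cross-validation stratified by
#' task condition. Both the deviance-minimizing `lambda_min` and the
#' one-standard-error `lambda_1se` (the most regularized model whose mean CV
#' deviance is within one s.e. of the minimum) are recorded; reported
#' coefficients are taken at `lambda_1se` from the path fit on the full
#' training data. The intercept is never penalized, and basis columns are
#' not standardized (they are already bounded). A solver failure or an
#' all-zero response yields `converged = FALSE` with an intercept-only
#' fallback rather than an error, so such cells can be excluded downstream.
#'
#' @param design A `design_matrix`.
#' @param y Response vector (windowed counts) aligned with `design` rows, or
#'   a cell index into `design$y`.
#' @param trials Trial table used for fold stratification (required unless
#'   `foldid` is given).
#' @param rows Optional row subset (e.g., training frames); default all.
#' @param foldid Optional explicit fold id per (subset) row.
#' @param alpha Elastic-net mixing parameter.
#' @param n_folds CV folds.
#' @param nlambda,lambda_min_ratio Penalty path: log-spaced values from the
#'   smallest lambda that zeroes all penalized coefficients down to
#'   `lambda_min_ratio` times it.
#' @param balance_trials If `TRUE`, each frame's loss is weighted by the
#'   inverse number of trials sharing its (trial type x outcome) group,
#'   compensating for the excess of correct trials. Off by default.
#' @param seed Integer seed for fold assignment.
#' @return An `encode_fit` object.
#' @export
fit_encoding_glm <- function(design, y, trials = NULL, rows = NULL,
                             foldid = NULL, alpha = 0.95, n_folds = 10,
                             nlambda = 50, lambda_min_ratio = 1e-4,
                             balance_trials = FALSE, seed = 1L) {
  stopifnot(inherits(design, "design_matrix"))
  if (length(y) == 1 && !is.null(design$y)) y <- design$y[, y]
  if (is.null(rows)) rows <- seq_len(nrow(design$X))
  X <- design$X[rows, , drop = FALSE]
  yy <- y[rows]
  tr_of_row <- design$trial[rows]

  if (is.null(foldid)) {
    if (is.null(trials)) stop("supply trials or foldid")
    f_tr <- condition_folds(trials, n_folds, seed)
    foldid <- f_tr[match(tr_of_row, trials$trial)]
  }
  weights <- rep(1, length(yy))
  if (balance_trials) {
    if (is.null(trials)) stop("balance_trials requires trials")
    grp <- interaction(trials$S, trials$T, trials$correct, drop = TRUE)
    n_grp <- table(grp)
    w_tr <- 1 / as.numeric(n_grp[grp])
    weights <- w_tr[match(tr_of_row, trials$trial)]
    weights <- weights / mean(weights)
  }

  null_fit <- function(conv) {
    mu0 <- mean(yy)
    structure(list(beta0 = if (mu0 > 0) log(mu0) else -50,
                   beta = stats::setNames(numeric(ncol(X)), colnames(X)),
                   lambda_min = NA_real_, lambda_1se = NA_real_,
                   cv = NULL, alpha = alpha, converged = conv,
                   groups = design$groups, y_mean = mu0,
                   n_obs = length(yy),
                   include_interactions = design$include_interactions),
              class = "encode_fit")
  }
  if (all(yy == 0)) return(null_fit(FALSE))

  solver_ok <- TRUE
  cv <- tryCatch(
    withCallingHandlers(
      glmnet::cv.glmnet(X, yy, family = "poisson", alpha = alpha,
                        foldid = foldid, nlambda = nlambda,
                        lambda.min.ratio = lambda_min_ratio,
                        standardize = FALSE, weights = weights),
      warning = function(w) {
        if (grepl("onvergence|empty model", conditionMessage(w)))
          solver_ok <<- FALSE
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(cv)) return(null_fit(FALSE))

  co <- as.numeric(stats::coef(cv, s = "lambda.1se"))
  co_min <- as.numeric(stats::coef(cv, s = "lambda.min"))
  structure(list(beta0 = co[1],
                 beta = stats::setNames(co[-1], colnames(X)),
                 beta0_min = co_min[1],
                 beta_min = stats::setNames(co_min[-1], colnames(X)),
                 lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
                 cv = data.frame(lambda = cv$lambda, mean_dev = cv$cvm,
                                 sd_dev = cv$cvsd),
                 alpha = alpha, converged = solver_ok,
                 groups = design$groups, y_mean = mean(yy),
                 n_obs = length(yy),
                 include_interactions = design$include_interactions),
            class = "encode_fit")
}

#' @export
#' @method print encode_fit
print.encode_fit <- function(x, ...) {
  cat(sprintf("Poisson encoding fit (alpha = %.2f): %d obs, %d predictors\n",
              x$alpha, x$n_obs, length(x$beta)))
  if (x$converged) {
    cat(sprintf("  lambda_min = %.4g, lambda_1se = %.4g, %d nonzero coefficients\n",
                x$lambda_min, x$lambda_1se, sum(x$beta != 0)))
  } else {
    cat("  did not converge; intercept-only fallback\n")
  }
  invisible(x)
}

#' @export
coef.encode_fit <- function(object, ...) {
  c("(Intercept)" = object$beta0, object$beta)
}

#' @export
#' @method summary encode_fit
summary.encode_fit <- function(object, ...) {
  nz <- object$beta[object$beta != 0]
  grp <- table(object$groups[object$beta != 0])
  out <- list(converged = object$converged, n_nonzero = length(nz),
              by_group = grp, lambda_1se = object$lambda_1se,
              mean_rate = object$y_mean)
  class(out) <- "summary.encode_fit"
  out
}

#' @export
#' @method print summary.encode_fit
print.summary.encode_fit <- function(x, ...) {
  cat(sprintf("converged: %s; %d nonzero coefficients (lambda_1se = %.4g)\n",
              x$converged, x$n_nonzero, x$lambda_1se))
  if (length(x$by_group)) print(x$by_group)
  invisible(x)
}

#' Predicted mean counts from an encoding fit
#'
#' @param object An `encode_fit`.
#' @param design A `design_matrix` (columns must match the fit).
#' @param rows Optional row subset.
#' @param type `"response"` for expected counts, `"link"` for the linear
#'   predictor.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.encode_fit <- function(object, design, rows = NULL,
                               type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- design$X
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  eta <- object$beta0 + as.numeric(X %*% object$beta)
  if (type == "link") eta else exp(eta)
}

#' @export
simulate.encode_fit <- function(object, nsim = 1, seed = NULL, design,
                                rows = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict.encode_fit(object, design, rows)
  out <- replicate(nsim, stats::rpois(length(mu), mu))
  as.data.frame(out)
}

#' @export
plot.encode_fit <- function(x, ...) {
  if (is.null(x$cv)) {
    warning("no cross-validation curve to plot")
    return(invisible(x))
  }
  with(x$cv, {
    plot(log(lambda), mean_dev, type = "b", pch = 16, cex = 0.6,
         xlab = expression(log(lambda)), ylab = "mean CV deviance", ...)
    graphics::arrows(log(lambda), mean_dev - sd_dev, log(lambda),
                     mean_dev + sd_dev, length = 0.02, angle = 90, code = 3,
                     col = "grey60")
  })
  graphics::abline(v = log(c(x$lambda_min, x$lambda_1se)), lty = c(2, 3))
  invisible(x)
}

# Poisson log-likelihood without the lgamma(y+1) term (which cancels in all
# ratios used here); 0*log(0) treated as 0.
poisson_ll <- function(y, mu) {
  lmu <- ifelse(mu > 0, log(mu), -Inf)
  term <- ifelse(y == 0, 0, y * lmu)
  sum(term - mu)
}

#' Fraction of deviance explained on held-out data
#'
#' `FDE = (L_GLM - L_null) / (L_sat - L_null)`, where the null model
#' predicts the training-mean rate everywhere and the saturated model
#' predicts the observed counts exactly. `FDE = 1` matches the saturated
#' model, `FDE = 0` is no better than the null.
#'
#' @param fit An `encode_fit`, or a numeric vector of predicted means `mu`.
#' @param design A `design_matrix` (when `fit` is an `encode_fit`).
#' @param y Observed test counts.
#' @param rows Test rows of the design (when `fit` is an `encode_fit`).
#' @param null_rate Null-model rate; defaults to the fit's training mean.
#' @return FDE value, or `NA` with a `"mixedsel_degenerate"` warning when
#'   the response is constant (saturated and null models coincide).
#' @export
fraction_deviance_explained <- function(fit, design = NULL, y, rows = NULL,
                                        null_rate = NULL) {
  if (inherits(fit, "encode_fit")) {
    mu <- predict(fit, design, rows)
    if (is.null(null_rate)) null_rate <- fit$y_mean
    if (!is.null(rows)) y <- y[rows]
  } else {
    mu <- fit
    if (is.null(null_rate)) stop("null_rate required when fit is a vector")
  }
  if (length(mu) != length(y)) stop("length mismatch between mu and y")
  l_sat <- poisson_ll(y, y)
  l_null <- poisson_ll(y, rep(null_rate, length(y)))
  l_glm <- poisson_ll(y, mu)
  if (abs(l_sat - l_null) < 1e-12) {
    warning(structure(class = c("mixedsel_degenerate", "warning", "condition"),
                      list(message = "constant response: FDE undefined",
                           call = sys.call())))
    return(NA_real_)
  }
  (l_glm - l_null) / (l_sat - l_null)
}

#' Compare full-model and movement-only fits per cell
#'
#' @param fde_full,fde_movement Named numeric vectors of per-cell FDE from
#'   the full (task + movement) and movement-only models on identical
#'   train/test splits.
#' @param run_mean_window Width of the running-mean window applied to the
#'   FDE difference after sorting cells by full-model FDE.
#' @return Data frame sorted by full-model FDE with `delta_fde` and its
#'   running mean; cells present in only one input are dropped with a
#'   message.
#' @export
compare_full_vs_movement <- function(fde_full, fde_movement,
                                     run_mean_window = 9) {
  common <- intersect(names(fde_full), names(fde_movement))
  drop_n <- length(union(names(fde_full), names(fde_movement))) -
    length(common)
  if (drop_n > 0)
    message(sprintf("compare_full_vs_movement: %d cells present in only one fit set excluded", drop_n))
  out <- data.frame(cell = common,
                    fde_full = fde_full[common],
                    fde_movement = fde_movement[common])
  out$delta_fde <- out$fde_full - out$fde_movement
  out <- out[order(out$fde_full), ]
  k <- min(run_mean_window, nrow(out))
  if (k %% 2 == 0) k <- k - 1
  out$delta_run_mean <- as.numeric(stats::filter(out$delta_fde,
                                                 rep(1 / k, k), sides = 2))
  rownames(out) <- NULL
  out
}
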