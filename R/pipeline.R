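# End-to-end analysis pipeline on a synthetic (or loaded) session:
# simulate -> fit encoding models -> information -> classify -> decode.

# design restricted to a subset of column groups (e.g., movement-only model)
subset_design <- function(design, groups) {
  keep <- design$groups %in% groups
  out <- design
  out$X <- design$X[, keep, drop = FALSE]
  out$groups <- design$groups[keep]
  out
}

#' Default pipeline configuration
#'
#' @param ... Overrides of the defaults.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_trials = 250L, error_rate = 0.2, delay_range_cm = c(20, 100),
    speed_mean_cm_s = 50, speed_sd_cm_s = 10, delay_cue_velocity_shift = 0,
    cells = NULL,                 # cell_roster; default make_cells(...)
    error_degradation = 0.9,      # mixed-cell selectivity loss on errors
    include_interactions = TRUE,
    n_splits = 5L, n_folds = 10L, alpha = 0.95, nlambda = 30L,
    lambda_min_ratio = 0.05,
    fit_thin = 5L,                # fit on every fit_thin-th trial frame
    balance_trials = FALSE,
    epsilon = 0.01, chance_xor_level = 0.01,
    movement_model = TRUE,
    n_boot = 2000L,
    verbose = TRUE
  )
  utils::modifyList(cfg, list(...))
}

#' Run the full analysis pipeline
#'
#' Simulates a session (unless one is supplied), fits per-cell elastic-net
#' Poisson encoding models on `n_splits` condition-stratified train/test
#' splits (cycling so every trial is evaluated held-out exactly once),
#' computes sign-adjusted logLR information at the analysis windows,
#' classifies selectivity in information polar coordinates, computes
#' normalized activity and nonlinearity indices, and decodes the reward
#' direction (XOR) from the mixed, pure and combined sub-populations with
#' correct/error outcome splits and a bootstrap test on the difference of
#' the correct-minus-error MI gaps.
#'
#' @param config From [pipeline_config()].
#' @param session Optional pre-built `dms_session` (must contain events).
#' @return A `pipeline_report` list.
#' @export
run_pipeline <- function(config = pipeline_config(), session = NULL) {
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  t0 <- Sys.time()
  if (is.null(session)) {
    cells <- config$cells
    if (is.null(cells))
      cells <- make_cells(error_degradation = config$error_degradation,
                          seed = config$seed + 100L)
    say("stage simulate: %d trials, %d cells", config$n_trials, nrow(cells))
    session <- simulate_session(
      n_trials = config$n_trials, cells = cells,
      error_rate = config$error_rate,
      delay_range_cm = config$delay_range_cm,
      speed_mean_cm_s = config$speed_mean_cm_s,
      speed_sd_cm_s = config$speed_sd_cm_s,
      delay_cue_velocity_shift = config$delay_cue_velocity_shift,
      seed = config$seed)
  }
  if (is.null(session$events)) stop("stage simulate: session has no events")
  trials <- session$trials
  n_cells <- ncol(session$events)

  say("stage design: building predictors")
  design <- build_design_matrix(session, config$include_interactions)
  design_mov <- subset_design(design, c("roll", "pitch", "yaw"))
  windows <- segment_windows(session)
  fit_rows_all <- which(design$frame %% config$fit_thin == 0L)

  split_of <- condition_folds(trials, config$n_splits,
                              seed = config$seed + 11L)
  fits_by_split <- vector("list", config$n_splits)
  info_by_split <- vector("list", config$n_splits)
  fde_full <- matrix(NA_real_, n_cells, config$n_splits)
  fde_mov <- matrix(NA_real_, n_cells, config$n_splits)
  Pc <- mean(trials$correct)

  for (s in seq_len(config$n_splits)) {
    say("stage fit: split %d/%d", s, config$n_splits)
    train_tr <- trials$trial[split_of != s]
    test_tr <- trials$trial[split_of == s]
    rows_tr <- fit_rows_all[design$trial[fit_rows_all] %in% train_tr]
    rows_te <- fit_rows_all[design$trial[fit_rows_all] %in% test_tr]
    trials_tr <- trials[trials$trial %in% train_tr, ]
    fits <- vector("list", n_cells)
    for (j in seq_len(n_cells)) {
      fits[[j]] <- fit_encoding_glm(
        design, design$y[, j], trials = trials_tr, rows = rows_tr,
        alpha = config$alpha, n_folds = config$n_folds,
        nlambda = config$nlambda,
        lambda_min_ratio = config$lambda_min_ratio,
        balance_trials = config$balance_trials,
        seed = config$seed + 1000L * s + j)
      if (fits[[j]]$converged)
        fde_full[j, s] <- suppressWarnings(fraction_deviance_explained(
          fits[[j]], design, design$y[, j], rows = rows_te))
      if (config$movement_model) {
        fm <- fit_encoding_glm(
          design_mov, design$y[, j], trials = trials_tr, rows = rows_tr,
          alpha = config$alpha, n_folds = config$n_folds,
          nlambda = config$nlambda,
          lambda_min_ratio = config$lambda_min_ratio,
          seed = config$seed + 2000L * s + j)
        if (fm$converged)
          fde_mov[j, s] <- suppressWarnings(fraction_deviance_explained(
            fm, design_mov, design$y[, j], rows = rows_te))
      }
    }
    fits_by_split[[s]] <- fits
    win_s <- windows[windows$trial %in% test_tr, ]
    keep_cells <- which(vapply(fits, function(f) f$converged, TRUE))
    info_by_split[[s]] <- session_information(fits, design, win_s, trials,
                                              Pc, 1 - Pc,
                                              cells = keep_cells)
  }

  say("stage info: combining splits")
  cells_ok <- Reduce(intersect, lapply(info_by_split, function(x) x$cells))
  info <- combine_session_info(info_by_split, cells_ok, Pc)

  say("stage classify")
  wa <- window_average(info, by_outcome = TRUE, windows = "test_early")
  prof <- wa[wa$correct & wa$window == "test_early",
             c("cell", "I_sample", "I_test", "I_xor")]
  prof <- classify_selectivity(prof, config$epsilon,
                               config$chance_xor_level)
  gt <- if (!is.null(session$cells)) session$cells$class else NULL
  agreement <- NULL
  if (!is.null(gt)) {
    m <- match(prof$cell, seq_along(gt))
    recover <- c(mixed = "mixed", pure_sample = "pure_sample",
                 pure_test = "pure_test")
    tab <- table(truth = gt[m], assigned = prof$class)
    agr <- vapply(names(recover), function(cl) {
      rows <- which(gt[m] == cl)
      if (!length(rows)) return(NA_real_)
      mean(prof$class[rows] == recover[[cl]])
    }, 0)
    agreement <- list(table = tab, by_class = agr)
  }

  say("stage activity summaries")
  act <- window_activity(session, windows, "test_early")
  na_corr <- normalized_activity(act, trials)
  ni <- nonlinearity_index(as.matrix(
    na_corr[stats::complete.cases(na_corr[, paste0("q", 1:4)]),
            paste0("q", 1:4)]))
  chance <- shuffle_chance_ni(act, trials, n_shuffles = 200,
                              seed = config$seed + 5L)

  say("stage decode")
  dec <- decode_partitioned_populations(info, trials, prof,
                                        seed = config$seed + 6L)
  gap <- function(d) if (is.null(d)) NA_real_ else d$mi_correct - d$mi_error
  gap_test <- NULL
  if (!is.null(dec$mixed) && !is.null(dec$pure))
    gap_test <- mi_gap_bootstrap(dec$mixed, dec$pure,
                                 n_boot = config$n_boot,
                                 seed = config$seed + 7L)

  report <- list(
    config = config,
    n_trials = nrow(trials), n_cells = n_cells,
    n_converged = length(cells_ok),
    fde = data.frame(cell = seq_len(n_cells),
                     fde_full = rowMeans(fde_full, na.rm = TRUE),
                     fde_movement = rowMeans(fde_mov, na.rm = TRUE)),
    profile = prof,
    agreement = agreement,
    class_fractions = table(prof$class) / nrow(prof),
    normalized_activity = na_corr,
    ni_mean = mean(ni), chance_ni_mean = mean(chance$per_cell$mean),
    decode = dec,
    mi = data.frame(
      partition = names(dec),
      mi = vapply(dec, function(d) if (is.null(d)) NA_real_ else d$mi, 0),
      mi_correct = vapply(dec, function(d) if (is.null(d)) NA_real_
                          else d$mi_correct, 0),
      mi_error = vapply(dec, function(d) if (is.null(d)) NA_real_
                        else d$mi_error, 0)),
    mi_gap = c(mixed = gap(dec$mixed), pure = gap(dec$pure),
               combined = gap(dec$combined)),
    gap_test = gap_test,
    info = info,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  class(report) <- "pipeline_report"
  say("pipeline done in %.1f s", report$elapsed_s)
  report
}

# concatenate per-split session_info objects over a common cell set
combine_session_info <- function(parts, cells, Pc) {
  info <- do.call(rbind, lapply(parts, function(x)
    x$info[x$info$cell %in% cells, ]))
  meta <- do.call(rbind, lapply(parts, function(x) x$frame_meta))
  ll <- do.call(abind_rows, lapply(parts, function(x)
    x$loglik[, , match(cells, x$cells), drop = FALSE]))
  structure(list(info = info, loglik = ll, cells = cells,
                 rows = unlist(lapply(parts, function(x) x$rows)),
                 frame_meta = meta, Pc = Pc, Pe = 1 - Pc),
            class = "session_info")
}

abind_rows <- function(...) {
  arrs <- list(...)
  n <- sum(vapply(arrs, nrow, 0L))
  out <- array(NA_real_, c(n, dim(arrs[[1]])[2], dim(arrs[[1]])[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(nrow(a)), , ] <- a
    at <- at + nrow(a)
  }
  out
}

#' Per-trial mean event rate in an analysis window
#'
#' @param session A `dms_session` with events.
#' @param windows From [segment_windows()].
#' @param window Window name.
#' @return Trials x cells matrix of mean events per frame.
#' @export
window_activity <- function(session, windows, window = "test_early") {
  w <- windows[windows$window == window, ]
  n_tr <- nrow(session$trials)
  out <- matrix(NA_real_, n_tr, ncol(session$events))
  for (k in seq_len(n_tr)) {
    fr <- w$frame[w$trial == session$trials$trial[k]]
    if (length(fr))
      out[k, ] <- colMeans(session$events[fr, , drop = FALSE])
  }
  out
}

# bootstrap test: (correct - error) MI gap of the mixed partition minus the
# pure partition's, resampling trials
mi_gap_bootstrap <- function(dec_mixed, dec_pure, n_boot = 2000,
                             seed = 1L) {
  d <- merge(dec_mixed$per_trial[, c("trial", "true", "correct", "decoded")],
             dec_pure$per_trial[, c("trial", "decoded")],
             by = "trial", suffixes = c("_mixed", "_pure"))
  mi_of <- function(dd, col, oc) {
    dd <- dd[dd$correct == oc, ]
    if (nrow(dd) < 2 || length(unique(dd$true)) < 2) return(NA_real_)
    suppressWarnings(confusion_mutual_information(dd$true, dd[[col]]))
  }
  stat <- function(dd) {
    (mi_of(dd, "decoded_mixed", TRUE) - mi_of(dd, "decoded_mixed", FALSE)) -
      (mi_of(dd, "decoded_pure", TRUE) - mi_of(dd, "decoded_pure", FALSE))
  }
  bootstrap_stat(d, statistic = stat, n_boot = n_boot, seed = seed)
}

#' @export
#' @method print pipeline_report
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %d trials, %d cells (%d converged), %.1f s\n",
              x$n_trials, x$n_cells, x$n_converged, x$elapsed_s))
  cat("Class fractions:\n"); print(round(x$class_fractions, 3))
  if (!is.null(x$agreement)) {
    cat("Ground-truth recovery:\n")
    print(round(x$agreement$by_class, 3))
  }
  cat("Population XOR MI (bits):\n")
  print(transform(x$mi, mi = round(mi, 3), mi_correct = round(mi_correct, 3),
                  mi_error = round(mi_error, 3)), row.names = FALSE)
  if (!is.null(x$gap_test))
    cat(sprintf("MI gap difference (mixed - pure): %.3f (p = %.4g)\n",
                x$gap_test$estimate, x$gap_test$p))
  invisible(x)
}
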