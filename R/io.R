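# Session persistence: a versioned plain-text directory layout (CSV tables
# plus a JSON manifest), diffable and dependency-free.

SESSION_FORMAT_VERSION <- "1.0"

#' Write a session to a directory
#'
#' Lays out `manifest.json` (format version, frame period, dimensions),
#' `trials.csv`, `frames.csv`, and — when present — `cells.csv` and a
#' sparse `events.csv` (frame, cell pairs of the 1-entries).
#'
#' @param session A `dms_session`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "dms_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format = "mixedsel-session",
                   version = SESSION_FORMAT_VERSION,
                   frame_period = session$frame_period,
                   arm_len_cm = session$arm_len_cm,
                   n_trials = nrow(session$trials),
                   n_frames = nrow(session$frames),
                   n_cells = if (is.null(session$events)) 0L
                             else ncol(session$events))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(session$trials),
                   file.path(path, "trials.csv"), row.names = FALSE)
  utils::write.csv(session$frames, file.path(path, "frames.csv"),
                   row.names = FALSE)
  if (!is.null(session$cells))
    utils::write.csv(as.data.frame(session$cells),
                     file.path(path, "cells.csv"), row.names = FALSE)
  if (!is.null(session$events)) {
    idx <- which(session$events == 1L, arr.ind = TRUE)
    utils::write.csv(data.frame(frame = idx[, 1], cell = idx[, 2]),
                     file.path(path, "events.csv"), row.names = FALSE)
  }
  invisible(path)
}

format_error <- function(msg) {
  stop(structure(class = c("mixedsel_format_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Read a session directory
#'
#' Validates the manifest (format tag and version) and required tables,
#' raising a `mixedsel_format_error` naming the missing piece rather than
#' crashing on malformed input.
#'
#' @param path Directory written by [write_session()].
#' @return A `dms_session`.
#' @export
read_session <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) format_error("missing manifest.json")
  manifest <- tryCatch(jsonlite::read_json(mf),
                       error = function(e) format_error("unreadable manifest.json"))
  if (!identical(manifest$format, "mixedsel-session"))
    format_error("manifest.json: not a mixedsel session")
  if (!identical(manifest$version, SESSION_FORMAT_VERSION))
    format_error(sprintf("unsupported session format version '%s'",
                         manifest$version))
  for (f in c("trials.csv", "frames.csv"))
    if (!file.exists(file.path(path, f)))
      format_error(paste("missing", f))
  trials <- utils::read.csv(file.path(path, "trials.csv"))
  trials$correct <- as.logical(trials$correct)
  class(trials) <- c("trial_table", "data.frame")
  frames <- utils::read.csv(file.path(path, "frames.csv"))
  frames$segment <- factor(frames$segment,
                           levels = c("sample", "delay", "test", "arm", "iti"))
  events <- NULL; cells <- NULL
  if (manifest$n_cells > 0) {
    ef <- file.path(path, "events.csv")
    if (!file.exists(ef)) format_error("missing events.csv")
    ev <- utils::read.csv(ef)
    events <- matrix(0L, manifest$n_frames, manifest$n_cells)
    events[cbind(ev$frame, ev$cell)] <- 1L
    colnames(events) <- seq_len(manifest$n_cells)
    cf <- file.path(path, "cells.csv")
    if (file.exists(cf)) {
      cells <- utils::read.csv(cf)
      class(cells) <- c("cell_roster", "data.frame")
    }
  }
  structure(list(frames = frames, trials = trials,
                 frame_period = manifest$frame_period,
                 arm_len_cm = manifest$arm_len_cm,
                 events = events, cells = cells),
            class = "dms_session")
}
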