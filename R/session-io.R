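#' Construct a session bundle
#'
#' A session bundle holds one neuron's recording session: trial epochs,
#' pole locations and outcomes, touch events, spike times, and the 1-kHz
#' whisker-angle trace with its fur mask. All times are in milliseconds
#' from trial start; whisker samples are 0-based (sample i covers
#' millisecond i); pole locations are in mm with 0 the most posterior
#' presented position; angles are in degrees.
#'
#' @param session_id character scalar.
#' @param trials tibble: `trial_id`, `duration_ms`, `pole_location_mm`,
#'   `pole_onset_ms`, `sampling_period_ms`, `answer_period_ms`, `licked`,
#'   `outcome` (hit/miss/false_alarm/correct_rejection/none), `tracked`.
#' @param touches tibble: `trial_id`, `onset_ms`, `offset_ms`,
#'   `angle_at_touch`, `max_curvature_change`, `direction`.
#' @param spikes tibble: `trial_id`, `time_ms`.
#' @param whisker tibble: `trial_id`, `sample_ms`, `angle`, `masked`.
#' @param neuron_depth microns from pia.
#' @param condition `"naive"` or `"trained"`.
#' @param sampling_rate Hz; fixed at 1000 (video tracked at 1,000 fps).
#' @param validate run [validate_session_bundle()] (default `TRUE`).
#' @return object of class `session_bundle`.
#' @export
session_bundle <- function(session_id, trials, touches, spikes, whisker,
                           neuron_depth = NA_real_,
                           condition = c("naive", "trained"),
                           sampling_rate = 1000, validate = TRUE) {
  condition <- match.arg(condition)
  b <- structure(
    list(
      meta = list(
        session_id = as.character(session_id),
        neuron_depth = as.numeric(neuron_depth),
        condition = condition,
        sampling_rate = as.numeric(sampling_rate)
      ),
      trials = as_tibble(trials),
      touches = as_tibble(touches),
      spikes = as_tibble(spikes),
      whisker = as_tibble(whisker)
    ),
    class = "session_bundle"
  )
  if (validate) validate_session_bundle(b)
  b
}

#' Validate a session bundle's invariants
#'
#' Checks: sampling rate is 1000 Hz; every spike lies within its trial's
#' duration; the whisker series length per trial equals the trial duration
#' in ms; touches are disjoint, ordered and within the trial; pole
#' locations lie within the presented range; touch offsets follow onsets
#' and touch angles are finite. Errors name the offending trial and field.
#'
#' @param b a `session_bundle`.
#' @param pole_range presented pole range in mm.
#' @return `b`, invisibly, if valid.
#' @export
validate_session_bundle <- function(b, pole_range = c(0, 10)) {
  stopifnot(inherits(b, "session_bundle"))
  if (!identical(as.numeric(b$meta$sampling_rate), 1000)) {
    abort("validation error: sampling_rate must be 1000 Hz.")
  }
  tr <- b$trials
  need <- c("trial_id", "duration_ms", "pole_location_mm", "pole_onset_ms",
            "licked", "outcome", "tracked")
  miss <- setdiff(need, names(tr))
  if (length(miss)) abort(paste0("format error: trials missing column(s) ",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(tr$trial_id)) abort("validation error: duplicate trial_id.")
  bad <- tr$trial_id[tr$pole_location_mm < pole_range[1] |
                       tr$pole_location_mm > pole_range[2]]
  if (length(bad)) {
    abort(sprintf("validation error: trial %d field pole_location_mm outside [%g, %g].",
                  bad[1], pole_range[1], pole_range[2]))
  }
  dur <- setNames(tr$duration_ms, tr$trial_id)
  sp <- b$spikes
  if (nrow(sp)) {
    bad <- sp$time_ms < 0 | sp$time_ms > dur[as.character(sp$trial_id)]
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("validation error: trial %d field time_ms: spike at %g ms outside trial duration.",
                    sp$trial_id[i], sp$time_ms[i]))
    }
  }
  w <- b$whisker
  if (nrow(w)) {
    len <- table(factor(w$trial_id, levels = tr$trial_id))
    bad <- which(as.integer(len) != tr$duration_ms & as.integer(len) != 0L)
    if (length(bad)) {
      abort(sprintf("validation error: trial %d field angle: whisker series length %d != duration %d ms.",
                    tr$trial_id[bad[1]], as.integer(len)[bad[1]],
                    tr$duration_ms[bad[1]]))
    }
  }
  to <- b$touches
  if (nrow(to)) {
    if (any(to$offset_ms <= to$onset_ms)) {
      i <- which(to$offset_ms <= to$onset_ms)[1]
      abort(sprintf("validation error: trial %d field offset_ms: touch offset <= onset.",
                    to$trial_id[i]))
    }
    if (any(!is.finite(to$angle_at_touch))) {
      i <- which(!is.finite(to$angle_at_touch))[1]
      abort(sprintf("validation error: trial %d field angle_at_touch not finite.",
                    to$trial_id[i]))
    }
    for (tid in unique(to$trial_id)) {
      tt <- to[to$trial_id == tid, ]
      if (is.unsorted(tt$onset_ms, strictly = TRUE) ||
          any(tt$onset_ms[-1] < tt$offset_ms[-nrow(tt)])) {
        abort(sprintf("validation error: trial %d field onset_ms: touches overlap or are unordered.", tid))
      }
      if (any(tt$offset_ms > dur[as.character(tid)])) {
        abort(sprintf("validation error: trial %d field offset_ms: touch extends past trial end.", tid))
      }
    }
  }
  invisible(b)
}

#' @exportS3Method base::print
print.session_bundle <- function(x, ...) {
  cat(sprintf(
    "<session_bundle %s: %d trials, %d touches, %d spikes, %s, depth %s um>\n",
    x$meta$session_id, nrow(x$trials), nrow(x$touches), nrow(x$spikes),
    x$meta$condition, format(x$meta$neuron_depth)
  ))
  invisible(x)
}

#' Write a session bundle to a directory of plain CSV tables
#'
#' One directory per session: `metadata.txt` (key-value), `trials.csv`,
#' `touches.csv`, `spikes.csv`, `whisker.csv`. The layout is inspectable,
#' language-agnostic and diff-able; [read_session()] inverts it. Continuous
#' values are stored at fixed decimal precision (times to 1 microsecond,
#' angles and locations to 1e-6, curvature to 1e-9) so that
#' write/read/write is byte-stable.
#'
#' @param bundle a valid `session_bundle`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(bundle, path) {
  validate_session_bundle(bundle)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort(sprintf("cannot create directory '%s'", path))
  meta <- bundle$meta
  writeLines(
    sprintf("%s: %s", names(meta), vapply(meta, format, character(1))),
    file.path(path, "metadata.txt")
  )
  rnd <- function(df, cols, digits) {
    for (nm in intersect(cols, names(df))) df[[nm]] <- round(df[[nm]], digits)
    df
  }
  trials <- rnd(bundle$trials, "pole_location_mm", 6)
  touches <- rnd(rnd(bundle$touches, c("onset_ms", "offset_ms"), 3),
                 "angle_at_touch", 6)
  touches <- rnd(touches, "max_curvature_change", 9)
  spikes <- rnd(bundle$spikes, "time_ms", 3)
  whisker <- rnd(bundle$whisker, "angle", 6)
  readr::write_csv(trials, file.path(path, "trials.csv"), progress = FALSE)
  readr::write_csv(touches, file.path(path, "touches.csv"), progress = FALSE)
  readr::write_csv(spikes, file.path(path, "spikes.csv"), progress = FALSE)
  readr::write_csv(whisker, file.path(path, "whisker.csv"), progress = FALSE)
  invisible(path)
}

#' Read a session bundle from disk
#'
#' @param path directory written by [write_session()].
#' @param validate check invariants after reading.
#' @return a `session_bundle`.
#' @export
read_session <- function(path, validate = TRUE) {
  files <- c("metadata.txt", "trials.csv", "touches.csv", "spikes.csv",
             "whisker.csv")
  missing <- files[!file.exists(file.path(path, files))]
  if (length(missing)) {
    abort(sprintf("format error: '%s' is missing %s.", path,
                  paste(missing, collapse = ", ")))
  }
  kv <- readLines(file.path(path, "metadata.txt"))
  kv <- strsplit(kv, ": ", fixed = TRUE)
  meta <- setNames(vapply(kv, function(p) paste(p[-1], collapse = ": "),
                          character(1)),
                   vapply(kv, `[[`, character(1), 1))
  rd <- function(f, types) {
    readr::read_csv(file.path(path, f), col_types = types, progress = FALSE)
  }
  trials <- rd("trials.csv", readr::cols(
    trial_id = "i", duration_ms = "i", pole_location_mm = "d",
    pole_onset_ms = "d", sampling_period_ms = "d", answer_period_ms = "d",
    licked = "l", outcome = "c", tracked = "l"
  ))
  touches <- rd("touches.csv", readr::cols(
    trial_id = "i", onset_ms = "d", offset_ms = "d", angle_at_touch = "d",
    max_curvature_change = "d", direction = "c"
  ))
  spikes <- rd("spikes.csv", readr::cols(trial_id = "i", time_ms = "d"))
  whisker <- rd("whisker.csv", readr::cols(
    trial_id = "i", sample_ms = "i", angle = "d", masked = "l"
  ))
  session_bundle(
    session_id = meta[["session_id"]],
    trials = trials, touches = touches, spikes = spikes, whisker = whisker,
    neuron_depth = as.numeric(meta[["neuron_depth"]]),
    condition = meta[["condition"]],
    sampling_rate = as.numeric(meta[["sampling_rate"]]),
    validate = validate
  )
}
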