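# Pick/place event detection, the anticipation scheme, and assembly of the
# instant-wise (FFNN) case table and delay-embedded (TDNN) datasets.

#' Detect the pick and place instants of a normalized trial
#'
#' The pick (PK) instant is the minimum of the hand-sensor Y coordinate in
#' the part of the record prior to the transport (normalized indices 0..50);
#' the place (PL) instant is the minimum in the part subsequent to it
#' (51..100). The transmitter Y axis points from the shelf towards the
#' subject, so the hand is nearest the shelf at the minima. Ties take the
#' earliest index.
#'
#' @param trial A \code{normalized_trial} with hand-position channels.
#' @return A list with 0-based \code{pk} and \code{pl} indices on the
#'   101-point grid (\code{pk < pl}).
#' @export
detect_pick_place <- function(trial) {
  y <- trial$hand_pos[, "y"]
  if (diff(range(y)) < 0.1)
    stop("hand Y coordinate is flat: cannot detect pick/place", call. = FALSE)
  pk <- which.min(y[1:51]) - 1L
  pl <- 51L + which.min(y[52:101]) - 1L
  list(pk = as.integer(pk), pl = as.integer(pl))
}

#' Attach detected events to every trial of a study
#'
#' @param trials A \code{normalized_study}.
#' @return The same list with \code{pk} and \code{pl} set on each trial.
#' @export
detect_events <- function(trials) {
  out <- lapply(trials, function(x) {
    ev <- detect_pick_place(x)
    x$pk <- ev$pk
    x$pl <- ev$pl
    x
  })
  attributes(out) <- attributes(trials)
  out
}

#' Convert a time anticipation to normalized grid steps
#'
#' @param anticipation Anticipation in seconds (non-negative).
#' @param step_duration Duration of one normalized step (s); with ~5 s trials
#'   on the 101-point grid one step is about 0.05 s.
#' @return Integer number of steps, \code{round(anticipation/step_duration)}.
#' @examples
#' anticipation_to_steps(0.5)   # 10
#' anticipation_to_steps(0.75)  # 15
#' @export
anticipation_to_steps <- function(anticipation, step_duration = 0.05) {
  if (anticipation < 0) stop("anticipation must be non-negative", call. = FALSE)
  as.integer(round(anticipation / step_duration))
}

#' Assemble the instant-wise case table for the feed-forward network
#'
#' Two rows per trial: one for the pick and one for the place instant. The
#' inputs are the five elbow/shoulder angles sampled \code{anticipation_steps}
#' before the event; the targets are the three wrist angles at the event
#' itself. Optional one-hot extensions append the transported object (1
#' column), the subject (one column per subject) and the task (PK vs PL, 1
#' column) to the inputs.
#'
#' @param trials A \code{normalized_study} with events detected (see
#'   [detect_events()]); angles are normally subject-centered first.
#' @param anticipation_steps Integer anticipation in grid steps.
#' @param extensions Character subset of \code{c("object", "subject", "task")}.
#' @return A data.frame of inputs (prefix \code{in_}), targets (prefix
#'   \code{tgt_}) and metadata columns (\code{subject}, \code{object},
#'   \code{origin}, \code{destination}, \code{repetition}, \code{event}).
#'   Trials whose PK index precedes the anticipation are skipped with a
#'   warning.
#' @export
assemble_ffnn_cases <- function(trials, anticipation_steps,
                                extensions = character()) {
  stopifnot(all(extensions %in% c("object", "subject", "task")))
  subjects <- sort(unique(vapply(trials, function(x) x$meta$subject, character(1))))
  objects <- sort(unique(vapply(trials, function(x) x$meta$object, character(1))))
  rows <- list()
  skipped <- 0
  for (tr in trials) {
    if (is.null(tr$pk) || is.null(tr$pl))
      stop("events not detected; run detect_events() first", call. = FALSE)
    if (tr$pk < anticipation_steps) {
      skipped <- skipped + 1
      next
    }
    for (event in c("PK", "PL")) {
      ev_idx <- if (event == "PK") tr$pk else tr$pl
      inp <- tr$angles[ev_idx - anticipation_steps + 1, INPUT_CHANNELS]
      tgt <- tr$angles[ev_idx + 1, TARGET_CHANNELS]
      ext <- numeric(0)
      if ("object" %in% extensions)
        ext <- c(ext, setNames(as.numeric(tr$meta$object == objects[2]), "ext_object"))
      if ("subject" %in% extensions)
        ext <- c(ext, setNames(as.numeric(tr$meta$subject == subjects),
                               paste0("ext_subject_", subjects)))
      if ("task" %in% extensions)
        ext <- c(ext, setNames(as.numeric(event == "PL"), "ext_task"))
      rows[[length(rows) + 1]] <- data.frame(
        t(setNames(inp, paste0("in_", INPUT_CHANNELS))),
        t(ext),
        t(setNames(tgt, paste0("tgt_", TARGET_CHANNELS))),
        subject = tr$meta$subject, object = tr$meta$object,
        origin = tr$meta$origin, destination = tr$meta$destination,
        repetition = tr$meta$repetition, event = event,
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0)
    warning(sprintf("%d trial(s) skipped: PK earlier than the anticipation", skipped))
  do.call(rbind, rows)
}

case_input_cols <- function(cases) grep("^(in|ext)_", names(cases), value = TRUE)
case_target_cols <- function(cases) grep("^tgt_", names(cases), value = TRUE)

#' Split a case table into training and test sets
#'
#' Seeded random selection of \code{test_fraction} of the rows; with
#' \code{stratify = "object"} the test rows are balanced across the two
#' objects (half and half, within one row).
#'
#' @param cases Case table from [assemble_ffnn_cases()].
#' @param test_fraction Fraction of rows held out for testing.
#' @param stratify \code{"none"} or \code{"object"}.
#' @param seed Seed for the selection.
#' @return A list with integer row indices \code{train} and \code{test}
#'   (disjoint, exhaustive).
#' @export
split_cases <- function(cases, test_fraction = 0.15,
                        stratify = c("none", "object"), seed = 1) {
  stratify <- match.arg(stratify)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  n <- nrow(cases)
  with_seed(seed, {
    if (stratify == "none") {
      test <- sort(sample(n, round(test_fraction * n)))
    } else {
      objs <- unique(cases$object)
      n_test <- round(test_fraction * n)
      per <- c(floor(n_test / length(objs)), ceiling(n_test / length(objs)))
      test <- integer(0)
      for (k in seq_along(objs)) {
        idx <- which(cases$object == objs[k])
        take <- if (k <= n_test %% length(objs)) per[2] else per[1]
        test <- c(test, sample(idx, min(take, length(idx))))
      }
      test <- sort(test)
    }
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Parse a delay-window specification string
#'
#' \code{"a:b"} denotes the inclusive integer delays a..b (in normalized
#' steps) applied to the input channels: \code{"1:10"} is the previous ten
#' instants (about 0.5 s), \code{"11:12"} two instants anticipated a further
#' 0.5 s before the prediction instant.
#'
#' @param spec String \code{"a:b"} or an integer vector of delays.
#' @return Strictly increasing positive integer delays.
#' @export
parse_delay_spec <- function(spec) {
  if (is.character(spec)) {
    ab <- as.integer(strsplit(spec, ":", fixed = TRUE)[[1]])
    if (length(ab) != 2 || anyNA(ab)) stop("malformed delay spec", call. = FALSE)
    spec <- seq(ab[1], ab[2])
  }
  spec <- as.integer(spec)
  if (any(spec <= 0) || is.unsorted(spec, strictly = TRUE))
    stop("delays must be strictly positive and strictly increasing", call. = FALSE)
  spec
}

#' Delay-embed a concatenated series for time-delay prediction
#'
#' For every valid instant t, the input row is the concatenation of the five
#' elbow/shoulder channels at t - d for each delay d (features ordered delay
#' by delay); the targets are the wrist angles at t. Only the first
#' max(delay) samples of the whole concatenation are masked out — trial
#' boundaries are not, since the Tukey taper already removes the jumps there.
#'
#' @param concat Concatenation from [taper_concatenate()].
#' @param delays Delay specification (string or integer vector, see
#'   [parse_delay_spec()]).
#' @param input_channels,target_channels Channel names embedded as inputs and
#'   predicted as targets.
#' @return A list with \code{x} (rows x (|channels| |delays|) feature
#'   matrix), \code{y} (rows x targets matrix) and \code{t_index} (the
#'   1-based instants of the concatenation each row predicts).
#' @export
embed_delays <- function(concat, delays,
                         input_channels = INPUT_CHANNELS,
                         target_channels = TARGET_CHANNELS) {
  delays <- parse_delay_spec(delays)
  a <- concat$angles
  n <- nrow(a)
  maxd <- max(delays)
  if (n <= maxd) stop("series shorter than the maximum delay", call. = FALSE)
  valid <- seq(maxd + 1, n)
  blocks <- lapply(delays, function(d) a[valid - d, input_channels, drop = FALSE])
  x <- do.call(cbind, blocks)
  colnames(x) <- unlist(lapply(delays, function(d)
    paste0("in_", input_channels, "_d", d)))
  y <- a[valid, target_channels, drop = FALSE]
  colnames(y) <- paste0("tgt_", target_channels)
  list(x = x, y = y, t_index = valid)
}
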