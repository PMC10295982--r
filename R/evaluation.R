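# Metrics and the experiment harness: error/correlation tables for the
# instant-wise (FFNN) predictor, the time-delay (TDNN) predictor and the
# linear baseline, averaged over training sessions.

#' Mean absolute error (degrees)
#' @param actual,predicted Numeric vectors or matrices of equal shape.
#' @return Mean of |actual - predicted|.
#' @export
mae <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("length mismatch between actual and predicted", call. = FALSE)
  mean(abs(actual - predicted))
}

#' Root-mean-square error (degrees)
#' @inheritParams mae
#' @return sqrt(mean((actual - predicted)^2)).
#' @export
rmse <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("length mismatch between actual and predicted", call. = FALSE)
  sqrt(mean((actual - predicted)^2))
}

#' Correlation between actual and predicted angles
#'
#' Pearson correlation; \code{"pooled"} concatenates all target channels into
#' one pair of vectors (the single-number summary used for the multi-output
#' instant-wise predictor), \code{"per_angle_mean"} averages the per-channel
#' correlations (the mean correlation coefficient reported for per-angle
#' time-delay networks).
#'
#' @inheritParams mae
#' @param mode \code{"pooled"} or \code{"per_angle_mean"}.
#' @return A correlation coefficient in [-1, 1].
#' @export
correlation <- function(actual, predicted, mode = c("pooled", "per_angle_mean")) {
  mode <- match.arg(mode)
  a <- as.matrix(actual); p <- as.matrix(predicted)
  if (!all(dim(a) == dim(p))) stop("shape mismatch", call. = FALSE)
  if (nrow(a) < 2) stop("need at least 2 samples", call. = FALSE)
  if (mode == "pooled") {
    if (sd(as.vector(a)) == 0 || sd(as.vector(p)) == 0)
      stop("zero variance: correlation undefined", call. = FALSE)
    return(cor(as.vector(a), as.vector(p)))
  }
  ccs <- vapply(seq_len(ncol(a)), function(k) {
    if (sd(a[, k]) == 0 || sd(p[, k]) == 0)
      stop("zero variance: correlation undefined", call. = FALSE)
    cor(a[, k], p[, k])
  }, numeric(1))
  mean(ccs)
}

restrict_trials <- function(trials, object = NULL, subject = NULL) {
  keep <- vapply(trials, function(x) {
    (is.null(object) || x$meta$object %in% object) &&
      (is.null(subject) || x$meta$subject %in% subject)
  }, logical(1))
  out <- trials[keep]
  attributes(out) <- c(attributes(out),
                       attributes(trials)[setdiff(names(attributes(trials)), "names")])
  class(out) <- class(trials)
  out
}

#' Run the instant-wise (FFNN) prediction experiment
#'
#' For each (anticipation, neurons) grid cell: centers angles by subject,
#' assembles the two-cases-per-trial table, and over \code{sessions}
#' training sessions (distinct derived seeds) splits 15\% of cases for
#' testing, fits a 3-output network and scores it. Reported errors are
#' per-angle test MAE in degrees (identical on the centered and un-centered
#' scales); the correlation is pooled over the three outputs on the centered
#' scale.
#'
#' @param trials A \code{normalized_study} (uncentered; events are detected
#'   if missing).
#' @param neurons Vector of hidden-layer widths.
#' @param anticipation_s Vector of anticipations (s) between input instant
#'   and predicted event.
#' @param extensions One-hot input extensions, subset of
#'   \code{c("object", "subject", "task")}.
#' @param trainer Training algorithm (see [arm_net()]).
#' @param sessions Training sessions averaged per cell.
#' @param seed Master seed.
#' @param test_fraction Held-out fraction of cases.
#' @param restrict_object,restrict_subject Optional restriction of the study
#'   to one object or subject before training (reported in the grid label).
#' @param max_epochs Epoch cap per session.
#' @param step_duration Normalized step duration (s).
#' @return An object of class \code{eval_report}: \code{report} (one row per
#'   grid cell with mean +/- SD over sessions) and \code{session_cc} (cell x
#'   session matrix of correlation coefficients).
#' @export
run_ffnn_experiment <- function(trials, neurons = c(10, 15),
                                anticipation_s = 0.5,
                                extensions = character(),
                                trainer = "bayes-lm", sessions = 5, seed = 1,
                                test_fraction = 0.15,
                                restrict_object = NULL, restrict_subject = NULL,
                                max_epochs = 120, step_duration = 0.05) {
  if (!length(neurons) || !length(anticipation_s))
    stop("empty experiment grid", call. = FALSE)
  trials <- restrict_trials(trials, restrict_object, restrict_subject)
  if (is.null(trials[[1]]$pk)) trials <- detect_events(trials)
  centered <- center_by_subject(trials)$trials
  grid <- expand.grid(neurons = neurons, anticipation_s = anticipation_s,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  cc_mat <- matrix(NA_real_, nrow(grid), sessions)
  for (g in seq_len(nrow(grid))) {
    steps <- anticipation_to_steps(grid$anticipation_s[g], step_duration)
    cases <- assemble_ffnn_cases(centered, steps, extensions)
    xin <- as.matrix(cases[, case_input_cols(cases)])
    yt <- as.matrix(cases[, case_target_cols(cases)])
    maes <- matrix(NA_real_, sessions, 3)
    ccs <- numeric(sessions)
    for (s in seq_len(sessions)) {
      sseed <- derive_seed(seed, g * 1000 + s)
      sp <- split_cases(cases, test_fraction, stratify = "none", seed = sseed)
      fit <- arm_net(xin[sp$train, , drop = FALSE], yt[sp$train, , drop = FALSE],
                     hidden = grid$neurons[g], trainer = trainer,
                     max_epochs = max_epochs, seed = sseed)
      pred <- predict(fit, xin[sp$test, , drop = FALSE])
      act <- yt[sp$test, , drop = FALSE]
      maes[s, ] <- vapply(1:3, function(k) mae(act[, k], pred[, k]), numeric(1))
      ccs[s] <- correlation(act, pred, "pooled")
    }
    cc_mat[g, ] <- ccs
    rows[[g]] <- data.frame(
      anticipation_s = grid$anticipation_s[g], neurons = grid$neurons[g],
      extensions = paste(extensions, collapse = "+"),
      restricted = paste(c(restrict_object, restrict_subject), collapse = "+"),
      fe_err = mean(maes[, 1]), aa_err = mean(maes[, 2]), ps_err = mean(maes[, 3]),
      cc = mean(ccs), cc_sd = sd(ccs), sessions = sessions)
  }
  structure(list(report = do.call(rbind, rows), session_cc = cc_mat,
                 kind = "ffnn"), class = "eval_report")
}

# Trial-level stratified split: test_fraction of the trials, balanced across
# objects (half cylinder, half sphere when both are present).
split_trials_stratified <- function(trials, test_fraction, seed) {
  objs <- vapply(trials, function(x) x$meta$object, character(1))
  uo <- sort(unique(objs))
  n_test <- max(1, round(test_fraction * length(trials)))
  with_seed(seed, {
    test <- integer(0)
    per <- floor(n_test / length(uo))
    extra <- n_test %% length(uo)
    for (k in seq_along(uo)) {
      idx <- which(objs == uo[k])
      take <- per + as.integer(k <= extra)
      test <- c(test, sample(idx, min(take, length(idx))))
    }
    list(train = setdiff(seq_along(trials), test), test = sort(test))
  })
}

#' Run the time-delay (TDNN) prediction experiment
#'
#' For each (delay specification, neurons) grid cell and session: splits 15\%
#' of the trials for testing (stratified by object), Tukey-tapers and
#' concatenates the training and test groups separately, delay-embeds the
#' five input channels, and fits one network per wrist angle on the training
#' concatenation (training rows thinned by \code{stride} — the normalized
#' series are heavily oversampled). Scores per-angle test RMSE (degrees) and
#' the mean per-angle correlation.
#'
#' @inheritParams run_ffnn_experiment
#' @param delays List of delay specifications (strings like \code{"1:10"} or
#'   integer vectors).
#' @param stride Training-row thinning stride on the concatenated series.
#' @param taper_len Tukey ramp length (samples).
#' @return An \code{eval_report} (per-angle RMSE columns; \code{cc} is the
#'   mean per-angle correlation).
#' @export
run_tdnn_experiment <- function(trials, neurons = c(10, 15), delays = list("1:10"),
                                trainer = "bayes-lm", sessions = 5, seed = 1,
                                test_fraction = 0.15,
                                restrict_object = NULL, restrict_subject = NULL,
                                max_epochs = 40, stride = 2, taper_len = 5) {
  if (!length(neurons) || !length(delays))
    stop("empty experiment grid", call. = FALSE)
  trials <- restrict_trials(trials, restrict_object, restrict_subject)
  centered <- center_by_subject(trials)$trials
  if (!is.list(delays)) delays <- as.list(delays)
  grid <- expand.grid(neurons = neurons, delay = seq_along(delays),
                      KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  cc_mat <- matrix(NA_real_, nrow(grid), sessions)
  for (g in seq_len(nrow(grid))) {
    dl <- parse_delay_spec(delays[[grid$delay[g]]])
    label <- if (is.character(delays[[grid$delay[g]]]))
      delays[[grid$delay[g]]] else paste(range(dl), collapse = ":")
    errs <- matrix(NA_real_, sessions, 3)
    ccs <- numeric(sessions)
    for (s in seq_len(sessions)) {
      sseed <- derive_seed(seed, g * 1000 + s)
      sp <- split_trials_stratified(centered, test_fraction, sseed)
      ctr <- taper_concatenate(centered[sp$train], taper_len,
                               seed = derive_seed(sseed, 1))
      cte <- taper_concatenate(centered[sp$test], taper_len,
                               seed = derive_seed(sseed, 2))
      etr <- embed_delays(ctr, dl)
      ete <- embed_delays(cte, dl)
      keep <- seq(1, nrow(etr$x), by = stride)
      for (k in 1:3) {
        fit <- arm_net(etr$x[keep, , drop = FALSE],
                       etr$y[keep, k, drop = FALSE],
                       hidden = grid$neurons[g], trainer = trainer,
                       max_epochs = max_epochs, seed = derive_seed(sseed, 10 + k))
        pred <- predict(fit, ete$x)[, 1]
        errs[s, k] <- rmse(ete$y[, k], pred)
        ccs[s] <- ccs[s] + cor(ete$y[, k], pred) / 3
      }
    }
    cc_mat[g, ] <- ccs
    rows[[g]] <- data.frame(
      delay = label, neurons = grid$neurons[g],
      restricted = paste(c(restrict_object, restrict_subject), collapse = "+"),
      fe_err = mean(errs[, 1]), aa_err = mean(errs[, 2]), ps_err = mean(errs[, 3]),
      cc = mean(ccs), cc_sd = sd(ccs), sessions = sessions)
  }
  structure(list(report = do.call(rbind, rows), session_cc = cc_mat,
                 kind = "tdnn"), class = "eval_report")
}

#' Run the linear-regression baseline
#'
#' Stacks every normalized instant of every trial into one matrix and fits
#' the per-angle linear models on the whole dataset.
#'
#' @param trials A \code{normalized_study}.
#' @return An \code{eval_report} whose \code{report} has one row per target
#'   angle (MAE and per-angle correlation), with the fitted [fit_linear()]
#'   model attached.
#' @export
run_linear_baseline <- function(trials) {
  stacked <- stack_study_angles(trials)
  fit <- fit_linear(stacked)
  structure(list(report = fit$diagnostics, model = fit, kind = "linear"),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation report (%s)\n", x$kind))
  print(x$report, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run the whole pipeline on a configuration
#'
#' Generates the synthetic study, preprocesses it, detects pick/place events
#' and produces the instant-wise, time-delay and linear evaluation reports —
#' the single-command equivalent of running every stage in order. With
#' \code{out_dir} set, the resolved configuration and the report tables are
#' written there.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for report CSVs, the study
#'   manifest and the resolved configuration.
#' @return A list with the study, normalized trials and the three
#'   \code{eval_report}s.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  design <- do.call(study_design, config$design)
  study <- generate_study(design, seed = config$seeds$study)
  norm <- preprocess_study(study, cutoff = config$preprocess$cutoff_hz,
                           zero_phase = config$preprocess$zero_phase)
  norm <- detect_events(norm)
  ffnn <- run_ffnn_experiment(norm, neurons = config$model$neurons,
                              anticipation_s = config$events$anticipation_s,
                              trainer = config$model$trainer,
                              sessions = config$model$sessions,
                              seed = config$seeds$experiment,
                              max_epochs = config$model$ffnn_epochs)
  tdnn <- run_tdnn_experiment(norm, neurons = config$model$neurons,
                              delays = config$model$delays,
                              trainer = config$model$trainer,
                              sessions = config$model$sessions,
                              seed = config$seeds$experiment,
                              max_epochs = config$model$tdnn_epochs,
                              stride = config$model$stride)
  linear <- run_linear_baseline(norm)
  out <- list(study = study, normalized = norm,
              ffnn = ffnn, tdnn = tdnn, linear = linear, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
    write.csv(ffnn$report, file.path(out_dir, "ffnn_report.csv"), row.names = FALSE)
    write.csv(tdnn$report, file.path(out_dir, "tdnn_report.csv"), row.names = FALSE)
    write.csv(linear$report, file.path(out_dir, "linear_report.csv"), row.names = FALSE)
  }
  out
}
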