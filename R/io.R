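# Configuration and plain-text interchange formats. The tracker record is a
# plain pose table, so CSV + JSON sidecars are used throughout.

#' Default pipeline configuration
#'
#' Nested configuration for the full pipeline: study design, preprocessing,
#' event/anticipation settings, model grid and seeds. Unknown keys are
#' rejected when read from file.
#'
#' @param ... Named overrides of the top-level blocks (\code{design},
#'   \code{preprocess}, \code{events}, \code{model}, \code{seeds}); each a
#'   list merged over the defaults.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    design = list(n_subjects = 5, objects = c("cylinder", "sphere"),
                  slots = c("UL", "UR", "DL", "DR"), n_repetitions = 3,
                  rate_hz = 60, duration_s = 5,
                  noise_pos_cm = 0.1, noise_angle_deg = 0.5, jitter_frac = 0.1),
    preprocess = list(cutoff_hz = 5, zero_phase = TRUE, taper_len = 5),
    events = list(anticipation_s = 0.5),
    model = list(neurons = 15, delays = list("1:10"), trainer = "bayes-lm",
                 sessions = 5, test_fraction = 0.15,
                 ffnn_epochs = 120, tdnn_epochs = 40, stride = 2),
    seeds = list(study = 1, experiment = 1))
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (blk in names(overrides)) {
    bad <- setdiff(names(overrides[[blk]]), names(cfg[[blk]]))
    if (length(bad)) stop("unknown config key(s) in ", blk, ": ",
                          paste(bad, collapse = ", "), call. = FALSE)
    cfg[[blk]][names(overrides[[blk]])] <- overrides[[blk]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the configuration blocks;
#'   unknown blocks or keys are rejected.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Write a trial to CSV with a JSON metadata sidecar
#'
#' Long-format pose table with columns
#' \code{t,sensor,x,y,z,azimuth,elevation,roll}; the metadata (subject,
#' object, origin, destination, repetition, seed) goes to \code{<path>.json}.
#'
#' @param trial A \code{trial_record}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  tabs <- lapply(SENSOR_NAMES, function(s) {
    data.frame(t = trial$t, sensor = s,
               x = trial$sensors[[s]]$pos[, 1],
               y = trial$sensors[[s]]$pos[, 2],
               z = trial$sensors[[s]]$pos[, 3],
               azimuth = trial$sensors[[s]]$orient[, 1],
               elevation = trial$sensors[[s]]$orient[, 2],
               roll = trial$sensors[[s]]$orient[, 3])
  })
  write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  meta <- c(trial$meta, list(seed = trial$seed))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a trial written by [write_trial_csv()]
#'
#' @param path CSV path (the \code{<path>.json} sidecar must exist).
#' @return A \code{trial_record} (without synthetic ground truth).
#' @export
read_trial_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sensors <- list()
  for (s in unique(tab$sensor)) {
    sub <- tab[tab$sensor == s, ]
    sensors[[s]] <- list(pos = as.matrix(sub[, c("x", "y", "z")]),
                         orient = as.matrix(sub[, c("azimuth", "elevation", "roll")]))
  }
  structure(list(meta = meta[setdiff(names(meta), "seed")],
                 t = tab$t[tab$sensor == unique(tab$sensor)[1]],
                 sensors = sensors, truth = NULL,
                 seed = meta$seed),
            class = "trial_record")
}

#' Write the ground-truth angle series of a synthetic trial
#'
#' Columns \code{t}, the nine canonical angles and indicator columns
#' \code{is_grasp}, \code{is_release} marking the true event samples.
#'
#' @param trial A synthetic \code{trial_record}.
#' @param path Output CSV path.
#' @export
write_ground_truth_csv <- function(trial, path) {
  if (is.null(trial$truth)) stop("trial carries no ground truth", call. = FALSE)
  n <- length(trial$t)
  tab <- data.frame(t = trial$t, trial$truth$q,
                    is_grasp = as.integer(seq_len(n) == trial$truth$grasp_idx),
                    is_release = as.integer(seq_len(n) == trial$truth$release_idx))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a study to a directory with a JSON manifest
#'
#' One trial CSV (+ JSON sidecar) per trial plus \code{manifest.json} listing
#' the files and echoing the design.
#'
#' @param study A \code{wrist_study}.
#' @param dir Output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(study))
  for (i in seq_along(study)) {
    m <- study[[i]]$meta
    files[i] <- sprintf("trial_%s_%s_%s-%s_r%d.csv", m$subject, m$object,
                        m$origin, m$destination, m$repetition)
    write_trial_csv(study[[i]], file.path(dir, files[i]))
  }
  jsonlite::write_json(list(files = files,
                            design = unclass(attr(study, "design")),
                            seed = attr(study, "seed")),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Write a normalized angle series to CSV
#'
#' Columns \code{tau}, the nine canonical angles and the hand position, with
#' a provenance header comment.
#'
#' @param trial A \code{normalized_trial}.
#' @param path Output CSV path.
#' @export
write_normalized_csv <- function(trial, path) {
  tab <- data.frame(tau = sprintf("%.2f", trial$tau), trial$angles,
                    hand_x = trial$hand_pos[, 1], hand_y = trial$hand_pos[, 2],
                    hand_z = trial$hand_pos[, 3])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# normalized trial; centered=%s", trial$centered), con)
  write.csv(tab, con, row.names = FALSE)
  invisible(path)
}
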