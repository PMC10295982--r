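# Plain-text persistence for angle series, case tables and fitted networks.

#' Write a joint-angle series to CSV
#'
#' Columns \code{t} and the nine canonical angle channels, with a provenance
#' header comment.
#'
#' @param series A \code{joint_angles} object.
#' @param path Output CSV path.
#' @export
write_angles_csv <- function(series, path) {
  tab <- data.frame(t = series$t, series$angles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# joint angles; provenance=%s", series$provenance), con)
  write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Write a case table and its train/test split
#'
#' The case table goes to CSV with its named input, target and metadata
#' columns; the split (with its seed) to a JSON manifest, so a training run
#' can be reconstructed exactly.
#'
#' @param cases Case table from [assemble_ffnn_cases()].
#' @param path Output CSV path.
#' @param split Optional split from [split_cases()].
#' @param seed The seed the split was drawn with (recorded in the manifest).
#' @export
write_cases_csv <- function(cases, path, split = NULL, seed = NULL) {
  write.csv(cases, path, row.names = FALSE)
  if (!is.null(split))
    jsonlite::write_json(list(seed = seed, train = split$train,
                              test = split$test),
                         paste0(path, ".split.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Serialize a fitted network to JSON
#'
#' Stores the layer widths, scalers, weights, regularization state
#' (\eqn{\alpha}, \eqn{\beta}, \eqn{\gamma}), trainer and seed as nested
#' JSON arrays; the per-epoch training log goes to a companion CSV
#' (\code{<path>.log.csv}) with columns \code{epoch,train_mse} and, when
#' logged, \code{test_mse}.
#'
#' @param model An [arm_net()] fit.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_arm_net <- function(model, path) {
  stopifnot(inherits(model, "arm_net"))
  obj <- list(widths = c(model$n_in, model$hidden, model$n_out),
              trainer = model$trainer, activation = model$activation,
              seed = model$seed,
              alpha = model$alpha, beta = model$beta, gamma = model$gamma,
              scaler_in = model$scaler_in, scaler_out = model$scaler_out,
              params = model$params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(model$log) && nrow(model$log)) {
    cols <- intersect(c("epoch", "train_mse", "test_mse"), names(model$log))
    write.csv(model$log[, cols], paste0(path, ".log.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Restore a network serialized by [write_arm_net()]
#'
#' @param path JSON path.
#' @return An \code{arm_net} usable with [predict()] (the training log is not
#'   restored).
#' @export
read_arm_net <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) if (is.list(p)) do.call(rbind, p) else p)
  for (nm in intersect(c("W1", "W2"), names(params)))
    params[[nm]] <- as.matrix(params[[nm]])
  structure(list(params = params,
                 scaler_in = lapply(obj$scaler_in, as.numeric),
                 scaler_out = lapply(obj$scaler_out, as.numeric),
                 n_in = obj$widths[1], hidden = obj$widths[2],
                 n_out = obj$widths[3],
                 trainer = obj$trainer, activation = obj$activation,
                 alpha = obj$alpha, beta = obj$beta, gamma = obj$gamma,
                 log = NULL, seed = obj$seed),
            class = "arm_net")
}
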