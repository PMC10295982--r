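# Per-angle linear regression baseline on the vertically stacked angle
# matrix: every row is one instant of one experiment.

#' Fit per-angle linear models of the wrist on the proximal joints
#'
#' Ordinary least squares of each target wrist angle (wrist F/E, wrist A/A,
#' forearm P/S) on the five elbow/shoulder angles plus intercept. When the
#' predictors are rank deficient the fit is flagged and the minimum-norm
#' solution (singular-value pseudoinverse) is used.
#'
#' @param angles Stacked angle matrix or data.frame containing the canonical
#'   angle columns (degrees); typically all 101-point samples of all trials
#'   stacked with [stack_study_angles()].
#' @return An object of class \code{wrist_lm}: a 6 x 3 coefficient matrix
#'   (intercept + 5 slopes per target) and per-target fit diagnostics (MAE,
#'   Pearson correlation).
#' @export
fit_linear <- function(angles) {
  angles <- as.matrix(as.data.frame(angles)[, ANGLE_NAMES[ANGLE_NAMES %in% colnames(as.data.frame(angles))], drop = FALSE])
  need <- c(INPUT_CHANNELS, TARGET_CHANNELS)
  if (!all(need %in% colnames(angles)))
    stop("angle matrix must contain the five predictor and three target channels",
         call. = FALSE)
  if (nrow(angles) < 6) stop("need at least 6 rows to fit", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, angles[, INPUT_CHANNELS, drop = FALSE])
  Y <- angles[, TARGET_CHANNELS, drop = FALSE]
  qr_fit <- lm.fit(X, Y)
  rank_deficient <- qr_fit$rank < ncol(X)
  if (rank_deficient) {
    sv <- svd(X)
    keep <- sv$d > max(sv$d) * 1e-10
    coefs <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], Y)) / sv$d[keep])
  } else {
    coefs <- qr_fit$coefficients
  }
  rownames(coefs) <- colnames(X)
  colnames(coefs) <- TARGET_CHANNELS
  pred <- X %*% coefs
  diag_tab <- data.frame(
    target = TARGET_CHANNELS,
    mae = vapply(seq_len(3), function(k) mean(abs(Y[, k] - pred[, k])), numeric(1)),
    cc = vapply(seq_len(3), function(k) cor(Y[, k], pred[, k]), numeric(1)))
  structure(list(coefficients = coefs, diagnostics = diag_tab,
                 rank_deficient = rank_deficient, n = nrow(X)),
            class = "wrist_lm")
}

#' @export
coef.wrist_lm <- function(object, ...) object$coefficients

#' @export
predict.wrist_lm <- function(object, newdata, ...) {
  newdata <- as.matrix(as.data.frame(newdata))
  X <- cbind(1, newdata[, INPUT_CHANNELS, drop = FALSE])
  out <- X %*% object$coefficients
  colnames(out) <- TARGET_CHANNELS
  out
}

#' @export
print.wrist_lm <- function(x, ...) {
  cat(sprintf("Per-angle linear wrist models (n = %d instants%s)\n", x$n,
              if (x$rank_deficient) ", rank-deficient predictors" else ""))
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' Stack the angle samples of a study into one matrix
#'
#' Vertically stacks the 101-point angle series of every trial, one row per
#' instant, for whole-dataset fits.
#'
#' @param trials A \code{normalized_study}.
#' @return A matrix with the 9 canonical angle columns plus an attached
#'   \code{subject} attribute (one entry per row).
#' @export
stack_study_angles <- function(trials) {
  out <- do.call(rbind, lapply(trials, function(x) x$angles))
  attr(out, "subject") <- rep(vapply(trials, function(x) x$meta$subject,
                                     character(1)), each = 101)
  out
}
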