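# Joint-angle extraction from raw sensor pose records.

#' Extract the nine inter-segment joint angles from a trial
#'
#' For every sample, rebuilds each sensor's rotation matrix from its recorded
#' Euler angles (matrices are invariant to the +/-180 degree wrapping),
#' removes the known sensor mounting frames, forms the relative rotation of
#' each sensor pair — forearm->hand (wrist), arm->forearm (elbow + forearm
#' P/S), trunk->arm (shoulder) — and decomposes it in the ordered
#' FE -> AA -> PS convention. The nine output channels are unwrapped to
#' continuous series.
#'
#' @param trial A \code{trial_record}.
#' @param model The [arm_model()] carrying the mounting frames (defaults to
#'   the generator's default model).
#' @return An object of class \code{joint_angles}: time base \code{t},
#'   \code{angles} (n x 9 matrix, degrees, unwrapped), \code{hand_pos}
#'   (n x 3 cm, the recorded hand-sensor position), metadata, provenance and
#'   the fraction of gimbal-flagged samples (a warning is raised above 1\%).
#' @export
extract_joint_angles <- function(trial, model = arm_model()) {
  stopifnot(inherits(trial, "trial_record"))
  missing <- setdiff(SENSOR_NAMES, names(trial$sensors))
  if (length(missing))
    stop("trial is missing sensor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  seg_rot <- function(sensor) {
    o <- trial$sensors[[sensor]]$orient
    Rs <- rot_zyx_arr(o[, 1], o[, 2], o[, 3])
    rot_mul_arr(Rs, t(model$mounts[[sensor]]$rot))  # remove mounting frame
  }
  R_hand <- seg_rot("hand"); R_fore <- seg_rot("forearm")
  R_arm <- seg_rot("arm");   R_trunk <- seg_rot("trunk")

  joint <- function(Rp, Rd) rot_to_zyx_arr(rot_mul_arr(rot_t_arr(Rp), Rd))
  wr <- joint(R_fore, R_hand)
  el <- joint(R_arm, R_fore)
  sh <- joint(R_trunk, R_arm)

  angles <- cbind(wr[, 1:3, drop = FALSE], el[, 1:3, drop = FALSE],
                  sh[, 1:3, drop = FALSE])
  colnames(angles) <- ANGLE_NAMES
  angles <- apply(angles, 2, unwrap_series)
  if (is.null(dim(angles))) angles <- matrix(angles, nrow = 1,
                                             dimnames = list(NULL, ANGLE_NAMES))
  gimbal_frac <- mean(c(wr[, 4], el[, 4], sh[, 4]))
  if (gimbal_frac > 0.01)
    warning(sprintf("%.1f%% of samples are gimbal-flagged", 100 * gimbal_frac))
  structure(list(t = trial$t, angles = angles,
                 hand_pos = trial$sensors$hand$pos,
                 meta = trial$meta, provenance = "raw",
                 gimbal_frac = gimbal_frac,
                 truth = trial$truth),
            class = "joint_angles")
}

#' @export
print.joint_angles <- function(x, ...) {
  cat(sprintf("Joint-angle series (%s): %d samples x 9 angles\n",
              x$provenance, nrow(x$angles)))
  invisible(x)
}
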