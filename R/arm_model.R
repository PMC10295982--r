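# Kinematic arm model and posture keyframes for the synthetic generator.
#
# Frames. The transmitter sits on top of the shelf: x points to the subject's
# right, y towards the subject (away from the shelf), z towards the ground.
# All segment frames coincide at the anatomical position with a common base
# frame whose x-axis is distal (towards the ground for a hanging arm), y-axis
# points forward (towards the shelf, i.e. -y of the transmitter) and z-axis
# towards the subject's right. Joint rotations are FE about z, AA about y,
# PS about x of the proximal frame, so positive shoulder FE swings the arm
# forward and the hand y-coordinate decreases as the hand approaches the
# shelf.

# Base segment orientation in the transmitter frame (columns = segment axes).
BASE_ROT <- matrix(c(0, 0, 1,
                     0, -1, 0,
                     1, 0, 0), nrow = 3, byrow = FALSE)

SLOT_NAMES <- c("UL", "UR", "DL", "DR")
PHASE_NAMES <- c("anatomical", "grasp", "release")

#' Posture keyframes for the pick-and-place protocol
#'
#' Authored joint-angle keyframes (degrees, 9 angles) indexed by shelf slot,
#' object and phase. Grasp postures differ by slot (upper slots demand more
#' shoulder flexion and wrist abduction, left slots cross-body adduction and
#' wrist extension) and by object: the cylinder is approached from the side
#' with a pronated forearm, the sphere from above with a more supinated
#' forearm, larger elbow flexion and a distinct wrist F/E pattern. The
#' release posture at a slot is the grasp posture with a small placement
#' offset. The anatomical keyframe keeps a slight natural shoulder/elbow
#' flexion.
#'
#' @param objects Character vector of object names.
#' @return A 4-dimensional array [slot, object, phase, angle] in degrees.
#' @export
default_keyframes <- function(objects = c("cylinder", "sphere")) {
  kf <- array(0, dim = c(4, length(objects), 3, 9),
              dimnames = list(SLOT_NAMES, objects, PHASE_NAMES, ANGLE_NAMES))
  anat <- c(wrist_FE = 0, wrist_AA = 0, wrist_PS_res = 0,
            elbow_FE = 8, elbow_AA = 0, forearm_PS = 0,
            shoulder_FE = 5, shoulder_AA = 0, shoulder_PS = 0)
  for (obj in objects) for (slot in SLOT_NAMES) {
    upper <- slot %in% c("UL", "UR")
    left  <- slot %in% c("UL", "DL")
    # Total (shoulder + elbow) flexion stays below ~90 deg at every shelf
    # posture, so forward reach is monotone in the flexion angles and the
    # hand-depth minimum of a trial falls exactly at the grasp/release
    # postures, as in the protocol.
    g <- anat * 0
    g["shoulder_FE"] <- (if (upper) 60 else 38) - (if (left) 5 else 0)
    g["shoulder_AA"] <- if (left) 25 else -5
    g["shoulder_PS"] <- if (left) 10 else 0
    g["elbow_FE"]    <- (if (upper) 18 else 42) - (if (left) 4 else 0)
    g["elbow_AA"]    <- if (upper) 5 else 0
    g["wrist_FE"]    <- if (left) -14 else 10
    g["wrist_AA"]    <- if (upper) 9 else -8
    if (obj == "cylinder") {
      g["forearm_PS"] <- -70
      g["wrist_FE"] <- g["wrist_FE"] + 4
    } else {
      g["forearm_PS"] <- 45
      g["wrist_FE"] <- g["wrist_FE"] - 8
      g["wrist_AA"] <- g["wrist_AA"] + 3
      g["elbow_FE"] <- g["elbow_FE"] + 2
      g["elbow_AA"] <- g["elbow_AA"] + 4
    }
    r <- g
    r["wrist_FE"] <- r["wrist_FE"] + 2
    r["shoulder_FE"] <- r["shoulder_FE"] + 1
    kf[slot, obj, "anatomical", ] <- anat
    kf[slot, obj, "grasp", ] <- g
    kf[slot, obj, "release", ] <- r
  }
  kf
}

default_mounts <- function() {
  # Fixed sensor mounting frames (rotation + offset, cm) relative to the
  # carrying segment; x-axes stay approximately distal (hand/forearm/arm) or
  # ground-directed (trunk), with modest tilts so mount removal is exercised.
  list(
    hand    = list(rot = euler_to_matrix(4, -6, 15),  offset = c(4, -1.5, 0.5)),
    forearm = list(rot = euler_to_matrix(-5, 3, -20), offset = c(10, -2, 1)),
    arm     = list(rot = euler_to_matrix(6, 4, 25),   offset = c(15, -2, 2)),
    trunk   = list(rot = euler_to_matrix(-3, 5, 10),  offset = c(5, -4, 0))
  )
}

#' Kinematic arm model for the synthetic generator
#'
#' Defines the rigid-body chain trunk -> shoulder -> elbow -> wrist, the
#' sensor mounting frames, the posture keyframes of the pick-and-place
#' protocol and the per-subject keyframe perturbation scale.
#'
#' @param lengths Named segment lengths in cm: \code{upper_arm},
#'   \code{forearm}, \code{hand}.
#' @param trunk_origin Position (cm, transmitter frame) of the trunk segment
#'   origin on the upper back.
#' @param shoulder_offset Offset (cm, segment frame) from the trunk origin to
#'   the right shoulder centre.
#' @param mounts Per-sensor mounting frames: list of \code{rot} (3x3) and
#'   \code{offset} (cm, segment frame) for hand, forearm, arm and trunk.
#' @param keyframes Keyframe array as produced by [default_keyframes()].
#' @param carry_offset Joint-space retraction (degrees, named) added to the
#'   midpoint of grasp and release to form the transport via posture, pulling
#'   the object away from the shelf between pick and place.
#' @param perturb_scale Standard deviation (degrees) of the per-subject
#'   keyframe perturbations.
#' @return An object of class \code{arm_model}.
#' @export
arm_model <- function(lengths = c(upper_arm = 30, forearm = 26, hand = 9),
                      trunk_origin = c(50, 62, 20),
                      shoulder_offset = c(2, 6, 18),
                      mounts = default_mounts(),
                      keyframes = default_keyframes(),
                      carry_offset = c(elbow_FE = -15, shoulder_FE = -30),
                      perturb_scale = 3) {
  if (any(lengths <= 0)) stop("segment lengths must be positive", call. = FALSE)
  if (perturb_scale < 0) stop("perturb_scale must be non-negative", call. = FALSE)
  stopifnot(all(SENSOR_NAMES %in% names(mounts)))
  validate_keyframes(keyframes)
  structure(list(lengths = lengths, trunk_origin = trunk_origin,
                 shoulder_offset = shoulder_offset, mounts = mounts,
                 keyframes = keyframes, carry_offset = carry_offset,
                 perturb_scale = perturb_scale),
            class = "arm_model")
}

validate_keyframes <- function(kf) {
  stopifnot(length(dim(kf)) == 4, dim(kf)[4] == 9)
  fe <- kf[, , , "wrist_FE"]; aa <- kf[, , , "wrist_AA"]
  ps <- kf[, , , "forearm_PS"]
  if (any(abs(fe) > 70)) stop("wrist F/E keyframe outside +/-70 deg", call. = FALSE)
  if (any(abs(aa) > 40)) stop("wrist A/A keyframe outside +/-40 deg", call. = FALSE)
  if (any(ps < -90 | ps > 90)) stop("forearm P/S keyframe outside [-90, 90] deg", call. = FALSE)
  for (obj in dimnames(kf)[[2]]) {
    g <- kf[, obj, "grasp", , drop = TRUE]
    if (anyDuplicated(round(g, 6)))
      stop("grasp keyframes for distinct slots must be distinct", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.arm_model <- function(x, ...) {
  cat("Arm model: segments",
      paste(sprintf("%s=%g cm", names(x$lengths), x$lengths), collapse = ", "),
      "\n  keyframes:", paste(dim(x$keyframes)[1:3], collapse = " x "),
      "(slot x object x phase); subject perturbation sd",
      x$perturb_scale, "deg\n")
  invisible(x)
}

#' Study design for the pick-and-place protocol
#'
#' Describes the factorial design of the object-transport study: subjects,
#' SHAP objects, shelf slots, repetitions, the raw sampling rate and trial
#' duration, and the measurement noise model.
#'
#' @param n_subjects Number of subjects.
#' @param objects Objects transported (power-cylinder and sphere grips).
#' @param slots Shelf slot labels.
#' @param n_repetitions Consecutive repetitions of each transport.
#' @param rate_hz Raw sampling rate of the pose records (Hz).
#' @param duration_s Nominal trial duration (s); trials start and end at the
#'   anatomical position.
#' @param noise_pos_cm,noise_angle_deg I.i.d. Gaussian measurement noise
#'   standard deviations on sensor positions (cm) and orientation angles
#'   (degrees).
#' @param jitter_frac Repetition-to-repetition multiplicative timing jitter:
#'   each movement segment duration is scaled by \code{1 + U(-j, +j)}.
#' @return An object of class \code{study_design}.
#' @export
study_design <- function(n_subjects = 5,
                         objects = c("cylinder", "sphere"),
                         slots = c("UL", "UR", "DL", "DR"),
                         n_repetitions = 3,
                         rate_hz = 60, duration_s = 5,
                         noise_pos_cm = 0.1, noise_angle_deg = 0.5,
                         jitter_frac = 0.1) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (n_repetitions < 1) stop("n_repetitions must be >= 1", call. = FALSE)
  if (rate_hz * duration_s < 101)
    stop("sampling rate x duration must give at least 101 samples", call. = FALSE)
  if (noise_pos_cm < 0 || noise_angle_deg < 0)
    stop("noise standard deviations must be non-negative", call. = FALSE)
  if (jitter_frac < 0 || jitter_frac >= 1)
    stop("jitter_frac must be in [0, 1)", call. = FALSE)
  structure(list(n_subjects = n_subjects, objects = objects, slots = slots,
                 n_repetitions = n_repetitions, rate_hz = rate_hz,
                 duration_s = duration_s, noise_pos_cm = noise_pos_cm,
                 noise_angle_deg = noise_angle_deg, jitter_frac = jitter_frac),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  nt <- x$n_subjects * length(x$objects) *
    nrow(enumerate_transports(x$slots)) * x$n_repetitions
  cat(sprintf(paste0("Pick-and-place study design: %d subject(s) x %d object(s)",
                     " x %d transports x %d repetition(s) = %d trials\n"),
              x$n_subjects, length(x$objects),
              nrow(enumerate_transports(x$slots)), x$n_repetitions, nt))
  invisible(x)
}

#' Enumerate ordered transports between shelf slots
#'
#' All ordered (origin, destination) pairs of distinct slots, in
#' lexicographic order: the 12 transports of the four-slot shelf.
#'
#' @param slots Character vector of at least two distinct slot labels.
#' @return A data.frame with columns \code{origin} and \code{destination}.
#' @examples
#' nrow(enumerate_transports(c("UL", "UR", "DL", "DR")))  # 12
#' @export
enumerate_transports <- function(slots) {
  slots <- unique(as.character(slots))
  if (length(slots) < 2)
    stop("need at least 2 distinct slots to enumerate transports", call. = FALSE)
  s <- sort(slots)
  g <- expand.grid(destination = s, origin = s,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[g$origin != g$destination, c("origin", "destination")]
  g <- g[order(g$origin, g$destination), ]
  rownames(g) <- NULL
  g
}
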