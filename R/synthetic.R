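# Synthetic motion-capture generator: joint-space trajectories through the
# protocol keyframes, forward kinematics to sensor poses, measurement noise.

#' Minimum-jerk interpolation between two postures
#'
#' Quintic minimum-jerk profile
#' \eqn{q(t) = q_s + (q_e - q_s)(10\tau^3 - 15\tau^4 + 6\tau^5)},
#' \eqn{\tau = t / T}: the standard smooth model of natural reaching, with
#' zero velocity and acceleration at both endpoints.
#'
#' @param q_start,q_end Numeric angle vectors (degrees).
#' @param duration Segment duration T (s), positive.
#' @param t Time (s), scalar or vector in \code{[0, duration]}.
#' @return If \code{t} is scalar, an angle vector; otherwise a matrix with
#'   one row per time.
#' @export
minimum_jerk_path <- function(q_start, q_end, duration, t) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (any(t < -1e-12 | t > duration + 1e-12))
    stop("t outside [0, duration]", call. = FALSE)
  tau <- pmin(pmax(t / duration, 0), 1)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  out <- outer(s, q_end - q_start) + rep(q_start, each = length(s))
  colnames(out) <- names(q_start)
  if (length(t) == 1) drop(out) else out
}

#' Forward kinematics of the sensor-equipped arm
#'
#' Composes the rigid chain trunk -> shoulder -> elbow -> wrist with the same
#' ordered FE -> AA -> PS joint rotation convention used by
#' [decompose_joint()], applies the sensor mounting frames, and returns the
#' pose of the four sensors in the transmitter frame.
#'
#' @param model An [arm_model()].
#' @param q Joint angles (degrees): vector of 9 or an n x 9 matrix in the
#'   canonical angle order.
#' @return A list with per-sensor poses (\code{pos}: n x 3 cm,
#'   \code{rot}: 3 x 3 x n) and a \code{joints} element with the shoulder,
#'   elbow and wrist centre trajectories.
#' @export
forward_kinematics <- function(model, q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  stopifnot(ncol(q) == 9)
  n <- nrow(q)
  R_sh  <- rot_mul_arr(BASE_ROT, rot_zyx_arr(q[, 7], q[, 8], q[, 9]))
  R_fo  <- rot_mul_arr(R_sh,  rot_zyx_arr(q[, 4], q[, 5], q[, 6]))
  R_ha  <- rot_mul_arr(R_fo,  rot_zyx_arr(q[, 1], q[, 2], q[, 3]))

  p_sh <- matrix(rep(model$trunk_origin + as.vector(BASE_ROT %*% model$shoulder_offset),
                     each = n), n, 3)
  xcol <- function(R) t(matrix(R[, 1, ], nrow = 3))      # n x 3 segment x-axes
  p_el <- p_sh + model$lengths[["upper_arm"]] * xcol(R_sh)
  p_wr <- p_el + model$lengths[["forearm"]] * xcol(R_fo)

  sensor_pose <- function(R_seg, p_org, mount) {
    off <- mount$offset
    pos <- p_org + t(matrix(R_seg[, 1, ], 3)) * off[1] +
      t(matrix(R_seg[, 2, ], 3)) * off[2] + t(matrix(R_seg[, 3, ], 3)) * off[3]
    list(pos = pos, rot = rot_mul_arr(R_seg, mount$rot))
  }
  R_tr <- array(BASE_ROT, c(3, 3, n))
  p_tr <- matrix(rep(model$trunk_origin, each = n), n, 3)
  list(hand    = sensor_pose(R_ha, p_wr, model$mounts$hand),
       forearm = sensor_pose(R_fo, p_el, model$mounts$forearm),
       arm     = sensor_pose(R_sh, p_sh, model$mounts$arm),
       trunk   = sensor_pose(R_tr, p_tr, model$mounts$trunk),
       joints  = list(shoulder = p_sh, elbow = p_el, wrist = p_wr))
}

# Keyframes for one trial, with optional per-subject perturbation (a
# [slot, object, phase, angle] array of additive degree offsets; the
# anatomical phase is never perturbed).
trial_keyframes <- function(model, meta, perturb = NULL) {
  kf <- model$keyframes
  pget <- function(slot, phase) {
    base <- kf[slot, meta$object, phase, ]
    if (!is.null(perturb) && phase != "anatomical")
      base <- base + perturb[slot, meta$object, phase, ]
    base
  }
  anat <- kf[meta$origin, meta$object, "anatomical", ]
  grasp <- pget(meta$origin, "grasp")
  release <- pget(meta$destination, "release")
  carry <- (grasp + release) / 2
  co <- model$carry_offset
  carry[names(co)] <- carry[names(co)] + co
  list(anatomical = anat, grasp = grasp, carry = carry, release = release)
}

#' Generate one synthetic pick-and-place trial
#'
#' Builds the joint-space trajectory anatomical -> grasp(origin) ->
#' carry -> release(destination) -> anatomical from minimum-jerk segments
#' with per-repetition jittered segment durations (the carry via posture is
#' the retracted midpoint of grasp and release, reproducing the arc the hand
#' describes away from the shelf), converts it to sensor poses by forward
#' kinematics, and adds i.i.d. Gaussian noise to positions and to the wrapped
#' orientation angles. Ground-truth joint angles and the true grasp/release
#' instants are attached.
#'
#' @param model An [arm_model()].
#' @param design A [study_design()].
#' @param meta List with \code{subject}, \code{object}, \code{origin},
#'   \code{destination}, \code{repetition}.
#' @param seed Integer seed; the trial is fully reproducible from it.
#' @param perturb Optional per-subject keyframe perturbation array.
#' @return An object of class \code{trial_record}: metadata, time base,
#'   per-sensor pose series (orientations wrapped to [-180, 180) degrees) and
#'   a \code{truth} element with the noise-free joint angles, the grasp and
#'   release sample indices on the raw time base (1-based) and on the
#'   normalized 0..100 grid.
#' @export
generate_trial <- function(model, design, meta, seed = 1, perturb = NULL) {
  stopifnot(inherits(model, "arm_model"), inherits(design, "study_design"))
  if (identical(meta$origin, meta$destination))
    stop("origin and destination must differ", call. = FALSE)
  if (!all(c(meta$origin, meta$destination) %in% design$slots))
    stop("transport slots not in design", call. = FALSE)
  with_seed(seed, {
    kfs <- trial_keyframes(model, meta, perturb)
    frac <- c(reach = 0.31, carry_in = 0.19, carry_out = 0.19, back = 0.31)
    dur <- design$duration_s * frac *
      (1 + runif(4, -design$jitter_frac, design$jitter_frac))
    total <- sum(dur)
    t <- seq(0, total, by = 1 / design$rate_hz)
    qa <- rbind(kfs$anatomical, kfs$grasp, kfs$carry, kfs$release)
    qb <- rbind(kfs$grasp, kfs$carry, kfs$release, kfs$anatomical)
    starts <- c(0, cumsum(dur))[1:4]
    seg <- pmin(findInterval(t, c(0, cumsum(dur)), rightmost.closed = TRUE), 4)
    q <- matrix(0, length(t), 9, dimnames = list(NULL, ANGLE_NAMES))
    for (s in 1:4) {
      idx <- which(seg == s)
      if (!length(idx)) next
      q[idx, ] <- minimum_jerk_path(qa[s, ], qb[s, ], dur[s], t[idx] - starts[s])
    }
    fk <- forward_kinematics(model, q)
    sensors <- list()
    for (s in SENSOR_NAMES) {
      pos <- fk[[s]]$pos +
        matrix(rnorm(3 * length(t), sd = design$noise_pos_cm), ncol = 3)
      eul <- rot_to_zyx_arr(fk[[s]]$rot)[, 1:3, drop = FALSE]
      eul <- wrap_deg(eul +
        matrix(rnorm(3 * length(t), sd = design$noise_angle_deg), ncol = 3))
      colnames(eul) <- c("azimuth", "elevation", "roll")
      sensors[[s]] <- list(pos = pos, orient = eul)
    }
    grasp_t <- dur[1]; release_t <- sum(dur[1:3])
    structure(list(
      meta = meta, t = t, sensors = sensors,
      truth = list(q = q,
                   grasp_idx = which.min(abs(t - grasp_t)),
                   release_idx = which.min(abs(t - release_t)),
                   grasp_tau_idx = as.integer(round(100 * grasp_t / total)),
                   release_tau_idx = as.integer(round(100 * release_t / total)),
                   grasp_t = grasp_t, release_t = release_t,
                   durations = dur, keyframes = kfs),
      seed = seed), class = "trial_record")
  })
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("Pick-and-place trial: subject %s, %s, %s -> %s, repetition %d (%d samples)\n",
              x$meta$subject, x$meta$object, x$meta$origin, x$meta$destination,
              x$meta$repetition, length(x$t)))
  invisible(x)
}

#' Generate a full synthetic study
#'
#' One trial per (subject, object, transport, repetition) of the design.
#' Per-subject keyframe perturbations (additive, sd \code{perturb_scale}
#' degrees on every grasp/release keyframe angle) are drawn once per subject,
#' emulating sensor-placement and style differences between subjects.
#'
#' @param design A [study_design()].
#' @param seed Master seed; the whole study is reproducible from it.
#' @param model An [arm_model()].
#' @return A list of \code{trial_record} objects of class \code{wrist_study},
#'   with the design, model and perturbation draws attached as attributes.
#' @examples
#' study <- generate_study(study_design(n_subjects = 1, n_repetitions = 1),
#'                         seed = 7)
#' length(study)  # 1 x 2 x 12 x 1 = 24
#' @export
generate_study <- function(design = study_design(), seed = 1,
                           model = arm_model()) {
  transports <- enumerate_transports(design$slots)
  nobj <- length(design$objects)
  perturb <- with_seed(derive_seed(seed, 0), {
    p <- array(0, c(design$n_subjects, dim(model$keyframes)),
               dimnames = c(list(NULL), dimnames(model$keyframes)))
    for (sub in seq_len(design$n_subjects)) {
      draw <- array(rnorm(length(model$keyframes), sd = model$perturb_scale),
                    dim(model$keyframes), dimnames = dimnames(model$keyframes))
      draw[, , "anatomical", ] <- 0
      p[sub, , , , ] <- draw
    }
    p
  })
  trials <- list()
  i <- 0
  for (sub in seq_len(design$n_subjects)) {
    psub <- array(perturb[sub, , , , ], dim(model$keyframes),
                  dimnames = dimnames(model$keyframes))
    for (obj in design$objects) for (tr in seq_len(nrow(transports))) {
      for (rep in seq_len(design$n_repetitions)) {
        i <- i + 1
        meta <- list(subject = sprintf("S%02d", sub), object = obj,
                     origin = transports$origin[tr],
                     destination = transports$destination[tr],
                     repetition = rep)
        trials[[i]] <- generate_trial(model, design, meta,
                                      seed = derive_seed(seed, i),
                                      perturb = psub)
      }
    }
  }
  structure(trials, class = "wrist_study", design = design, model = model,
            perturbations = perturb, seed = seed)
}

#' @export
print.wrist_study <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf("Synthetic pick-and-place study: %d trials (%d subjects, %d objects, %d repetitions)\n",
              length(x), d$n_subjects, length(d$objects), d$n_repetitions))
  invisible(x)
}
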