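# Rotation algebra for tracker-style pose records.
#
# Orientations are intrinsic Z-Y'-X'' Euler triples (azimuth, elevation, roll)
# in degrees, the convention of electromagnetic trackers; joint rotations use
# the same algebra with the anatomical reading flexion/extension about z,
# abduction/adduction about y and pronation/supination about the distal long
# axis x, so that axial rotation is the final rotation.

DEG <- pi / 180

# Vectorised builders: angles (deg, length n) -> 3 x 3 x n array.
rot_zyx_arr <- function(az, el, roll) {
  a <- az * DEG; e <- el * DEG; r <- roll * DEG
  ca <- cos(a); sa <- sin(a); ce <- cos(e); se <- sin(e)
  cr <- cos(r); sr <- sin(r)
  n <- length(a)
  R <- array(0, c(3, 3, n))
  R[1, 1, ] <- ca * ce
  R[1, 2, ] <- ca * se * sr - sa * cr
  R[1, 3, ] <- ca * se * cr + sa * sr
  R[2, 1, ] <- sa * ce
  R[2, 2, ] <- sa * se * sr + ca * cr
  R[2, 3, ] <- sa * se * cr - ca * sr
  R[3, 1, ] <- -se
  R[3, 2, ] <- ce * sr
  R[3, 3, ] <- ce * cr
  R
}

# Array multiply: (3x3xn) x (3x3xn | 3x3) -> 3x3xn, elementwise over slices.
rot_mul_arr <- function(A, B) {
  if (length(dim(A)) == 2) A <- array(A, c(3, 3, if (length(dim(B)) == 3) dim(B)[3] else 1))
  n <- dim(A)[3]
  fixedB <- length(dim(B)) == 2
  R <- array(0, c(3, 3, n))
  for (i in 1:3) for (j in 1:3) {
    acc <- 0
    for (k in 1:3) {
      b <- if (fixedB) B[k, j] else B[k, j, ]
      acc <- acc + A[i, k, ] * b
    }
    R[i, j, ] <- acc
  }
  R
}

rot_t_arr <- function(A) aperm(A, c(2, 1, 3))

# Inverse of rot_zyx_arr: returns n x 3 matrix (az, el, roll in deg) plus a
# gimbal flag per sample. At |elevation| = 90 deg the outer angles are
# coupled; the free part is assigned to azimuth and roll is reported as 0.
rot_to_zyx_arr <- function(R, tol = 1e-6) {
  cel <- sqrt(R[3, 2, ]^2 + R[3, 3, ]^2)  # |cos(elevation)|
  gimbal <- cel < tol
  el <- atan2(-R[3, 1, ], cel)
  az <- atan2(R[2, 1, ], R[1, 1, ])
  roll <- atan2(R[3, 2, ], R[3, 3, ])
  if (any(gimbal)) {
    up <- gimbal & (R[3, 1, ] < 0)    # elevation = +90
    dn <- gimbal & (R[3, 1, ] >= 0)   # elevation = -90
    az[up] <- atan2(R[2, 3, up], R[2, 2, up])
    az[dn] <- atan2(-R[1, 2, dn], R[2, 2, dn])
    roll[gimbal] <- 0
  }
  cbind(azimuth = az / DEG, elevation = el / DEG, roll = roll / DEG,
        gimbal = as.numeric(gimbal))
}

check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || !all(dim(R) == c(3, 3)))
    stop("rotation must be a 3x3 matrix", call. = FALSE)
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("matrix is not orthonormal within tolerance ", tol, call. = FALSE)
  if (abs(det(R) - 1) > tol)
    stop("matrix is not a proper rotation (det != +1)", call. = FALSE)
  invisible(TRUE)
}

#' Rotation matrix from tracker Euler angles
#'
#' Builds the intrinsic Z-Y'-X'' rotation \eqn{R = R_z(az) R_y(el) R_x(roll)}
#' used by electromagnetic trackers to report sensor orientation.
#'
#' @param azimuth,elevation,roll Angles in degrees.
#' @return A 3x3 right-handed rotation matrix.
#' @examples
#' euler_to_matrix(90, 0, 0) %*% c(1, 0, 0)  # maps unit-x to unit-y
#' @export
euler_to_matrix <- function(azimuth, elevation, roll) {
  matrix(rot_zyx_arr(azimuth, elevation, roll)[, , 1], 3, 3)
}

#' Relative rotation across a joint
#'
#' Expresses the distal segment frame in the proximal segment frame:
#' \eqn{R = P^T D}.
#'
#' @param proximal,distal 3x3 rotation matrices (orthonormal within 1e-6).
#' @return A 3x3 rotation matrix.
#' @export
relative_rotation <- function(proximal, distal) {
  check_rotation(proximal)
  check_rotation(distal)
  crossprod(proximal, distal)
}

#' Ordered anatomical decomposition of a joint rotation
#'
#' Factors a relative joint rotation as flexion/extension (about z), then
#' abduction/adduction (about y), then pronation/supination (about the distal
#' long axis x): \eqn{R = R_{FE}(\alpha) R_{AA}(\beta) R_{PS}(\gamma)}, with
#' \eqn{\beta \in [-90, 90]} degrees. At gimbal lock (\eqn{|\cos\beta|} below
#' \code{tol}) the outer angles are coupled; the free part is reported in FE,
#' PS is set to 0 and the \code{gimbal} flag raised.
#'
#' @param R A 3x3 rotation matrix.
#' @param tol Gimbal detection tolerance on \eqn{|\cos\beta|}.
#' @return A list with elements \code{FE}, \code{AA}, \code{PS} (degrees) and
#'   logical \code{gimbal}.
#' @export
decompose_joint <- function(R, tol = 1e-6) {
  check_rotation(R, tol = 1e-6)
  z <- rot_to_zyx_arr(array(R, c(3, 3, 1)), tol = tol)
  list(FE = unname(z[1, "azimuth"]), AA = unname(z[1, "elevation"]),
       PS = unname(z[1, "roll"]), gimbal = z[1, "gimbal"] > 0)
}

#' Unwrap a wrapped angle series
#'
#' Removes the artificial jumps of angle channels recorded in
#' [-180, +180] degrees by adding multiples of 360 so that no consecutive
#' difference exceeds 180 degrees in magnitude. The first sample is unchanged.
#'
#' @param wrapped Numeric vector, or matrix treated column-wise (degrees).
#' @return Continuous series of the same shape.
#' @examples
#' unwrap_series(c(179, -179))  # 179, 181
#' @export
unwrap_series <- function(wrapped) {
  if (is.matrix(wrapped)) return(apply(wrapped, 2, unwrap_series))
  if (length(wrapped) < 2) return(wrapped)
  d <- diff(wrapped)
  adj <- d - 360 * round(d / 360)
  c(wrapped[1], wrapped[1] + cumsum(adj))
}

# Wrap degrees into [-180, 180).
wrap_deg <- function(x) ((x + 180) %% 360) - 180
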