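test_that("tracker Euler angles build the expected rotation matrices", {
  expect_equal(euler_to_matrix(0, 0, 0), diag(3), tolerance = 1e-12)
  # a 90 deg azimuth maps unit-x to unit-y
  expect_equal(as.vector(euler_to_matrix(90, 0, 0) %*% c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  # composition about a single axis adds angles
  set.seed(4)
  for (i in 1:100) {
    a <- runif(1, -90, 90); b <- runif(1, -90, 90)
    expect_equal(euler_to_matrix(a, 0, 0) %*% euler_to_matrix(b, 0, 0),
                 euler_to_matrix(a + b, 0, 0), tolerance = 1e-12)
  }
})

test_that("relative rotation expresses the distal frame in the proximal one", {
  R <- euler_to_matrix(25, -40, 60)
  expect_equal(relative_rotation(R, R), diag(3), tolerance = 1e-12)
  expect_equal(relative_rotation(diag(3), R), R)
  set.seed(7)
  for (i in 1:25) {
    A <- random_rotation(); B <- random_rotation()
    expect_equal(relative_rotation(A, A %*% B), B, tolerance = 1e-10)
  }
  expect_error(relative_rotation(diag(3) * 1.01, R), "orthonormal")
})

test_that("ordered FE-AA-PS decomposition inverts composition off gimbal", {
  d0 <- decompose_joint(diag(3))
  expect_equal(c(d0$FE, d0$AA, d0$PS), c(0, 0, 0))
  expect_false(d0$gimbal)

  d <- decompose_joint(euler_to_matrix(30, 20, 10))
  expect_equal(c(d$FE, d$AA, d$PS), c(30, 20, 10), tolerance = 1e-9)

  # property: compose-then-decompose identity on gimbal-safe triples
  tr <- random_safe_triples(2000, seed = 12)
  R <- wristcast:::rot_zyx_arr(tr[, 1], tr[, 2], tr[, 3])
  back <- wristcast:::rot_to_zyx_arr(R)
  expect_lt(max(abs(back[, 1:3] - tr)), 1e-9)
  expect_true(all(back[, 4] == 0))

  # gimbal lock at AA = 90 deg is flagged, not thrown
  dg <- decompose_joint(euler_to_matrix(10, 90, 0))
  expect_true(dg$gimbal)
})

test_that("unwrapping removes recording-range jumps and is invertible", {
  expect_equal(unwrap_series(c(179, -179)), c(179, 181))
  expect_equal(unwrap_series(rep(42, 10)), rep(42, 10))
  set.seed(3)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    s <- runif(1, -170, 170) + cumsum(c(0, runif(n - 1, -179, 179)))
    w <- wristcast:::wrap_deg(s)
    u <- unwrap_series(w)
    # unwrap recovers the continuous series up to the wrap of its first sample
    expect_equal(u - u[1], s - s[1], tolerance = 1e-12)
    expect_equal(wristcast:::wrap_deg(u), w, tolerance = 1e-12)
  }
})

test_that("joint-angle extraction inverts the forward kinematics exactly", {
  model <- arm_model()
  set.seed(5)
  q <- cbind(runif(400, -60, 60), runif(400, -35, 35), runif(400, -20, 20),
             runif(400, 0, 80), runif(400, -30, 30), runif(400, -85, 85),
             runif(400, -70, 80), runif(400, -50, 50), runif(400, -40, 40))
  colnames(q) <- wristcast:::ANGLE_NAMES
  tr <- trial_from_q(q, model)
  ja <- extract_joint_angles(tr, model)
  # unwrapped output can differ by whole turns on strongly rotated channels
  err <- wristcast:::wrap_deg(ja$angles - q)
  expect_lt(max(abs(err)), 1e-9)
})

test_that("a trial at anatomical rest extracts constant zero angles", {
  model <- arm_model()
  q <- matrix(0, 50, 9, dimnames = list(NULL, wristcast:::ANGLE_NAMES))
  ja <- extract_joint_angles(trial_from_q(q, model), model)
  expect_lt(max(abs(ja$angles)), 1e-9)
})

test_that("a fixed elbow offset shifts only the elbow channel", {
  model <- arm_model()
  set.seed(8)
  q <- cbind(runif(60, -20, 20), runif(60, -15, 15), 0,
             runif(60, 10, 60), runif(60, -10, 10), runif(60, -60, 60),
             runif(60, 0, 60), runif(60, -30, 30), runif(60, -20, 20))
  colnames(q) <- wristcast:::ANGLE_NAMES
  q2 <- q
  q2[, "elbow_FE"] <- q2[, "elbow_FE"] + 10
  a1 <- extract_joint_angles(trial_from_q(q, model), model)$angles
  a2 <- extract_joint_angles(trial_from_q(q2, model), model)$angles
  expect_equal(a2[, "elbow_FE"] - a1[, "elbow_FE"], rep(10, 60),
               tolerance = 1e-9, ignore_attr = TRUE)
  sh <- c("shoulder_FE", "shoulder_AA", "shoulder_PS")
  expect_lt(max(abs(a2[, sh] - a1[, sh])), 1e-6)
})

test_that("extraction is equivariant to a global rigid motion", {
  model <- arm_model()
  tr <- generate_trial(model, tiny_design(),
                       list(subject = "S01", object = "cylinder",
                            origin = "UL", destination = "DR", repetition = 1),
                       seed = 9)
  G <- euler_to_matrix(33, -21, 58)
  g <- c(10, -40, 25)
  tr2 <- tr
  for (s in names(tr$sensors)) {
    o <- tr$sensors[[s]]$orient
    R <- wristcast:::rot_mul_arr(array(G, c(3, 3, nrow(o))),
                                 wristcast:::rot_zyx_arr(o[, 1], o[, 2], o[, 3]))
    eul <- wristcast:::wrap_deg(wristcast:::rot_to_zyx_arr(R)[, 1:3])
    colnames(eul) <- colnames(o)
    tr2$sensors[[s]]$orient <- eul
    tr2$sensors[[s]]$pos <- t(G %*% t(tr$sensors[[s]]$pos) + g)
  }
  a1 <- extract_joint_angles(tr, model)$angles
  a2 <- extract_joint_angles(tr2, model)$angles
  expect_lt(max(abs(wristcast:::wrap_deg(a2 - a1))), 1e-9)
})

test_that("extraction error stays bounded under measurement noise", {
  model <- arm_model()
  design <- study_design(n_subjects = 1, n_repetitions = 1,
                         noise_pos_cm = 0.1, noise_angle_deg = 0.5,
                         jitter_frac = 0)
  meta <- list(subject = "S01", object = "sphere", origin = "DL",
               destination = "UR", repetition = 1)
  tr <- generate_trial(model, design, meta, seed = 31)
  ja <- extract_joint_angles(tr, model)
  err <- wristcast:::wrap_deg(ja$angles - tr$truth$q)
  per_channel_rms <- sqrt(colMeans(err^2))
  expect_true(all(per_channel_rms < 1.5))
})
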