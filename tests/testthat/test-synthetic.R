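test_that("transport enumeration gives every ordered pair of distinct slots", {
  tp <- enumerate_transports(c("UL", "UR", "DL", "DR"))
  expect_equal(nrow(tp), 12)
  expect_true(all(tp$origin != tp$destination))
  expect_equal(nrow(unique(tp)), 12)
  expect_equal(enumerate_transports(c("UL", "UR")),
               data.frame(origin = c("UL", "UR"), destination = c("UR", "UL")))
  expect_error(enumerate_transports("UL"), "at least 2")
})

test_that("minimum-jerk interpolation has the right boundary behaviour", {
  qs <- c(0, 10, -5); qe <- c(30, -10, 5)
  expect_equal(minimum_jerk_path(qs, qe, 2, 0), qs, ignore_attr = TRUE)
  expect_equal(minimum_jerk_path(qs, qe, 2, 2), qe, ignore_attr = TRUE)
  expect_equal(minimum_jerk_path(qs, qe, 2, 1), (qs + qe) / 2, ignore_attr = TRUE)
  # endpoint velocities vanish (finite differences on the closed form)
  h <- 1e-5
  v0 <- (minimum_jerk_path(qs, qe, 2, h) - qs) / h
  v1 <- (qe - minimum_jerk_path(qs, qe, 2, 2 - h)) / h
  expect_lt(max(abs(c(v0, v1))), 1e-6)
  expect_error(minimum_jerk_path(qs, qe, 2, 2.5), "outside")
  expect_error(minimum_jerk_path(qs, qe, -1, 0), "positive")
})

test_that("forward kinematics respects the reference posture and rigid lengths", {
  model <- arm_model()
  fk0 <- forward_kinematics(model, rep(0, 9))
  # at the anatomical posture every segment x-axis points towards the ground
  expect_equal(as.vector(fk0$joints$elbow - fk0$joints$shoulder),
               c(0, 0, model$lengths[["upper_arm"]]), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:20) {
    q <- runif(9, -45, 45)
    fk <- forward_kinematics(model, q)
    expect_equal(sqrt(sum((fk$joints$elbow - fk$joints$shoulder)^2)),
                 unname(model$lengths[["upper_arm"]]), tolerance = 1e-10)
    expect_equal(sqrt(sum((fk$joints$wrist - fk$joints$elbow)^2)),
                 unname(model$lengths[["forearm"]]), tolerance = 1e-10)
  }
})

test_that("trial generation is reproducible and hits its keyframes", {
  model <- arm_model()
  meta <- list(subject = "S01", object = "cylinder", origin = "UL",
               destination = "DR", repetition = 1)
  t1 <- generate_trial(model, tiny_design(), meta, seed = 13)
  t2 <- generate_trial(model, tiny_design(), meta, seed = 13)
  expect_identical(t1, t2)
  noisy <- tiny_design(noise_pos_cm = 0.1, jitter_frac = 0.1)
  n1 <- generate_trial(model, noisy, meta, seed = 13)
  n3 <- generate_trial(model, noisy, meta, seed = 14)
  expect_false(identical(n1$sensors$hand$pos, n3$sensors$hand$pos))

  # noise-free, jitter-free: wrist angles at the true grasp instant equal the
  # grasp keyframe
  g <- t1$truth$keyframes$grasp
  expect_equal(t1$truth$q[t1$truth$grasp_idx, ], g, tolerance = 1e-9)
  ja <- extract_joint_angles(t1, model)
  expect_equal(ja$angles[t1$truth$grasp_idx, ], g, tolerance = 1e-6)

  expect_error(generate_trial(model, tiny_design(),
                              list(subject = "S01", object = "cylinder",
                                   origin = "UL", destination = "UL",
                                   repetition = 1), seed = 1),
               "differ")
})

test_that("study generation matches the factorial design", {
  d <- study_design(n_subjects = 1, objects = "cylinder")
  st <- generate_study(d, seed = 3)
  expect_length(st, 1 * 1 * 12 * 3)
  expect_identical(generate_study(d, seed = 3), st)

  d2 <- study_design(n_subjects = 2, objects = c("cylinder", "sphere"),
                     n_repetitions = 1, slots = c("UL", "DR"))
  st2 <- generate_study(d2, seed = 3)
  expect_length(st2, 2 * 2 * 2 * 1)
  metas <- unique(t(sapply(st2, function(x) unlist(x$meta[1:4]))))
  expect_equal(nrow(metas), length(st2))
})

test_that("subject keyframe perturbations have the declared scale", {
  model <- arm_model()
  st <- generate_study(study_design(n_subjects = 3, n_repetitions = 1), seed = 5,
                       model = model)
  p <- attr(st, "perturbations")
  live <- p[, , , c("grasp", "release"), ]
  expect_gt(sqrt(mean(live^2)), model$perturb_scale * 0.5)
  expect_lt(sqrt(mean(live^2)), model$perturb_scale * 1.5)
  # distinct subjects get distinct draws
  expect_false(identical(p[1, , , , ], p[2, , , , ]))
  # the anatomical phase is never perturbed
  expect_true(all(p[, , , "anatomical", ] == 0))
})

test_that("every trial starts and ends near the anatomical posture", {
  st <- generate_study(study_design(n_subjects = 1, n_repetitions = 1), seed = 6)
  anat <- arm_model()$keyframes["UL", "cylinder", "anatomical", ]
  for (tr in st) {
    expect_lt(max(abs(tr$truth$q[1, ] - anat)), 2)
    expect_lt(max(abs(tr$truth$q[nrow(tr$truth$q), ] - anat)), 2)
  }
})

test_that("simulated wrist ranges order as P/S > F/E > A/A", {
  st <- generate_study(study_design(n_subjects = 1), seed = 8)
  norm <- preprocess_study(st)
  rng <- sapply(c("wrist_FE", "wrist_AA", "forearm_PS"), function(ch)
    mean(vapply(norm, function(x) diff(range(x$angles[, ch])), numeric(1))))
  expect_gt(rng[["forearm_PS"]], rng[["wrist_FE"]])
  expect_gt(rng[["wrist_FE"]], rng[["wrist_AA"]])
})
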