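# Shared fixtures and independent oracles, built in code at test time.

# Random gimbal-safe Euler triples: middle angle well away from +/-90 deg.
random_safe_triples <- function(n, seed = 1) {
  set.seed(seed)
  cbind(az = runif(n, -179, 179), el = runif(n, -80, 80),
        roll = runif(n, -179, 179))
}

random_rotation <- function() {
  tr <- random_safe_triples(1, seed = sample.int(1e6, 1))
  euler_to_matrix(tr[1], tr[2], tr[3])
}

# Brute-force DTW: enumerate every monotone path over the step set
# {(1,1),(1,0),(0,1)} by recursion and take the minimum cumulative cost.
# Exponential — only usable for tiny series; that is the point.
dtw_bruteforce <- function(ref, qry) {
  if (is.null(dim(ref))) ref <- matrix(ref, ncol = 1)
  if (is.null(dim(qry))) qry <- matrix(qry, ncol = 1)
  n <- nrow(ref); m <- nrow(qry)
  d <- function(i, j) sqrt(sum((ref[i, ] - qry[j, ])^2))
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(d(1, 1))
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    best + d(i, j)
  }
  rec(n, m)
}

# A small noise-free study design used across tests.
tiny_design <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 1, objects = "cylinder", slots = c("UL", "DR"),
         n_repetitions = 1, noise_pos_cm = 0, noise_angle_deg = 0,
         jitter_frac = 0),
    list(...))
  do.call(study_design, args)
}

# Build a trial_record directly from a joint-angle matrix (no noise), using
# the model's forward kinematics — used to probe extraction in isolation.
trial_from_q <- function(q, model = arm_model(), rate = 60) {
  n <- nrow(q)
  fk <- forward_kinematics(model, q)
  sensors <- list()
  for (s in c("hand", "forearm", "arm", "trunk")) {
    eul <- wristcast:::rot_to_zyx_arr(fk[[s]]$rot)[, 1:3, drop = FALSE]
    colnames(eul) <- c("azimuth", "elevation", "roll")
    sensors[[s]] <- list(pos = fk[[s]]$pos, orient = wristcast:::wrap_deg(eul))
  }
  structure(list(meta = list(subject = "S01", object = "cylinder",
                             origin = "UL", destination = "DR", repetition = 1),
                 t = seq(0, by = 1 / rate, length.out = n),
                 sensors = sensors, truth = list(q = q)),
            class = "trial_record")
}

# Lazily cached default-scale study shared by the acceptance tests (one
# generation + preprocessing for the whole suite).
.fixture_env <- new.env()

default_norm_study <- function() {
  if (is.null(.fixture_env$norm)) {
    study <- generate_study(study_design(), seed = 11)
    .fixture_env$study <- study
    .fixture_env$norm <- detect_events(preprocess_study(study))
  }
  .fixture_env$norm
}

default_raw_study <- function() {
  default_norm_study()
  .fixture_env$study
}

# Small preprocessed noisy study for harness smoke tests.
small_norm_study <- function() {
  if (is.null(.fixture_env$small)) {
    d <- study_design(n_subjects = 2, n_repetitions = 2, slots = c("UL", "DR", "UR"))
    .fixture_env$small <- detect_events(preprocess_study(generate_study(d, seed = 21)))
  }
  .fixture_env$small
}
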