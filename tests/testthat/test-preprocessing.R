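test_that("dtw solves the alignment problem optimally", {
  r <- dtw(c(0, 1, 2), c(0, 1, 2))
  expect_equal(r$cost, 0)
  expect_equal(r$path, cbind(i = 1:3, j = 1:3), ignore_attr = TRUE)

  r2 <- dtw(c(0, 1, 2), c(0, 1, 1, 2))
  expect_equal(r2$cost, 0)
  expect_equal(nrow(r2$path), 4)  # one vertical step absorbs the repeat

  expect_error(dtw(numeric(0), 1:3), "non-empty")
  expect_error(dtw(cbind(1:3, 1:3), 1:3), "channel")

  # self-alignment of a reversed series is not degenerate
  s <- sin(seq(0, 3, length.out = 20))
  expect_gt(dtw(s, rev(s))$cost, 0)
})

test_that("dtw equals the exhaustive-path oracle on all small sizes", {
  set.seed(10)
  for (n in 1:7) for (m in 1:7) {
    for (rep in 1:2) {
      ref <- round(runif(n, 0, 5), 2)
      qry <- round(runif(m, 0, 5), 2)
      expect_equal(dtw(ref, qry)$cost, dtw_bruteforce(ref, qry))
    }
  }
})

test_that("dtw cost is symmetric with a transposed path", {
  set.seed(11)
  for (i in 1:100) {
    a <- runif(sample(3:12, 1)); b <- runif(sample(3:12, 1))
    ra <- dtw(a, b); rb <- dtw(b, a)
    expect_equal(ra$cost, rb$cost)
    expect_equal(ra$path[, c(2, 1)], rb$path, ignore_attr = TRUE)
  }
})

test_that("repetition synchronization aligns time-dilated repetitions", {
  st <- generate_study(tiny_design(n_repetitions = 3), seed = 2)
  series <- lapply(st[1:3], extract_joint_angles)
  out <- synchronize_repetitions(series)
  for (k in 1:3) expect_equal(out[[k]]$angles, series[[1]]$angles * 0 +
                                out[[k]]$angles)  # shapes match reference
  expect_equal(nrow(out[[2]]$angles), nrow(series[[1]]$angles))

  # three identical repetitions pass through unchanged
  same <- synchronize_repetitions(list(series[[1]], series[[1]], series[[1]]))
  expect_equal(same[[2]]$angles, series[[1]]$angles)
  expect_equal(same[[3]]$hand_pos, series[[1]]$hand_pos)

  # a 20% time-dilated copy re-aligns: post-alignment RMS shrinks
  ref <- series[[1]]
  n <- nrow(ref$angles)
  idx <- seq(1, n, length.out = round(1.2 * n))
  dil <- ref
  dil$angles <- apply(ref$angles, 2, function(col) approx(seq_len(n), col, idx)$y)
  dil$hand_pos <- apply(ref$hand_pos, 2, function(col) approx(seq_len(n), col, idx)$y)
  dil$t <- seq(0, by = diff(ref$t)[1], length.out = nrow(dil$angles))
  dil$meta$repetition <- 2
  dil$truth <- NULL
  pre_rms <- sqrt(mean((dil$angles[seq_len(n), ] - ref$angles)^2))
  al <- synchronize_repetitions(list(ref, dil))
  post_rms <- sqrt(mean((al[[2]]$angles - ref$angles)^2))
  expect_lt(post_rms, pre_rms)

  expect_warning(synchronize_repetitions(series[1]), "fewer than 2")
})

test_that("the low-pass filter honours the Butterworth contract", {
  rate <- 100; cutoff <- 5
  # unit DC gain
  const <- rep(3.7, 400)
  expect_equal(butterworth_lowpass(const, cutoff, rate), const, tolerance = 1e-9)
  # single-pass gain at the cutoff is 1/sqrt(2)
  t <- seq(0, 60, by = 1 / rate)
  x <- sin(2 * pi * cutoff * t)
  y1 <- butterworth_lowpass(x, cutoff, rate, zero_phase = FALSE)
  core <- seq(1000, length(x) - 1000)
  gain1 <- sqrt(mean(y1[core]^2) / mean(x[core]^2))
  expect_lt(abs(gain1 - 1 / sqrt(2)), 0.01)
  # zero-phase gain at the cutoff is 0.5 and the output is unshifted
  y2 <- butterworth_lowpass(x, cutoff, rate, zero_phase = TRUE)
  gain2 <- sqrt(mean(y2[core]^2) / mean(x[core]^2))
  expect_lt(abs(gain2 - 0.5), 0.01)
  lag <- which.max(ccf(y2[core], x[core], lag.max = 5, plot = FALSE)$acf) - 6
  expect_lt(abs(lag), 1)
  expect_error(butterworth_lowpass(x, 60, rate), "cutoff")
})

test_that("time normalization resamples onto exactly 101 points", {
  set.seed(12)
  x <- cumsum(rnorm(307))
  y <- resample_normalized(x)
  expect_length(y, 101)
  expect_identical(y[1], x[1])
  expect_identical(y[101], x[307])
  # linear interpolation is exact on a line
  ramp <- seq(-3, 8, length.out = 240)
  expect_equal(resample_normalized(ramp), seq(-3, 8, length.out = 101),
               tolerance = 1e-12)
  expect_error(resample_normalized(1), "at least 2")
})

test_that("per-subject centering is exact, idempotent and invertible", {
  norm <- small_norm_study()
  cen <- center_by_subject(norm)
  subs <- vapply(cen$trials, function(x) x$meta$subject, character(1))
  for (s in unique(subs)) {
    stacked <- do.call(rbind, lapply(cen$trials[subs == s], function(x) x$angles))
    expect_lt(max(abs(colMeans(stacked))), 1e-9)
  }
  twice <- center_by_subject(cen$trials)
  expect_equal(twice$trials[[1]]$angles, cen$trials[[1]]$angles)
  back <- uncenter_by_subject(cen$trials, cen$offsets)
  expect_equal(back[[3]]$angles, norm[[3]]$angles, tolerance = 1e-12)
})

test_that("tapered concatenation preserves the central samples", {
  norm <- small_norm_study()
  cc <- taper_concatenate(norm[1:2], taper_len = 5)
  expect_equal(nrow(cc$angles), 202)
  expect_equal(cc$boundaries, c(0, 101))
  expect_equal(cc$angles[1, ], norm[[1]]$angles[1, ] * 0, ignore_attr = TRUE)
  expect_equal(cc$angles[101, ], norm[[1]]$angles[101, ] * 0, ignore_attr = TRUE)
  expect_equal(cc$angles[6:96, ], norm[[1]]$angles[6:96, ])
  expect_error(taper_concatenate(norm[1:2], taper_len = 50), "below 50")
  # seeded order is recorded and reproducible
  c1 <- taper_concatenate(norm, seed = 5)
  c2 <- taper_concatenate(norm, seed = 5)
  expect_identical(c1$order, c2$order)
  expect_false(identical(c1$order, seq_along(norm)))
})

test_that("preprocessing a noise-free study perturbs ground truth very little", {
  st <- generate_study(tiny_design(n_repetitions = 1), seed = 4)
  norm <- preprocess_study(st)
  for (k in seq_along(st)) {
    q101 <- resample_normalized(st[[k]]$truth$q)
    err <- norm[[k]]$angles - q101
    expect_lt(sqrt(mean(err^2)), 0.5)
  }
})
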