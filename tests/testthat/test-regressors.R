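test_that("network initialization is seeded Nguyen-Widrow", {
  p1 <- init_network(5, 10, 3, seed = 7)
  p2 <- init_network(5, 10, 3, seed = 7)
  expect_identical(p1, p2)
  expect_false(identical(p1, init_network(5, 10, 3, seed = 8)))
  # hidden rows sit at the Nguyen-Widrow scale 0.7 h^(1/n_in)
  scale <- 0.7 * 10^(1 / 5)
  expect_equal(sqrt(rowSums(p1$W1^2)), rep(scale, 10), tolerance = 1e-12)
  expect_true(all(abs(p1$b1) <= scale + 1e-12))
})

test_that("the forward pass reduces to the output bias with zero weights", {
  p <- init_network(4, 6, 2, seed = 1)
  p$W1[] <- 0; p$b1[] <- 0; p$W2[] <- 0; p$b2 <- c(1.5, -2)
  out <- wristcast:::net_forward(p, matrix(rnorm(40), 10, 4))$ys
  expect_equal(out, matrix(rep(c(1.5, -2), each = 10), 10, 2))
  expect_true(all(abs(tanh(matrix(rnorm(40), 10, 4) %*% t(init_network(4, 6, 2, 1)$W1))) < 1))
})

test_that("the scaled forward pass linearizes for small signals", {
  set.seed(3)
  x <- matrix(rnorm(600), 200, 3)
  p <- init_network(3, 4, 2, seed = 5)
  eps <- 1e-4
  p$b1[] <- 0  # small-signal regime through the origin, where tanh ~ identity
  full <- wristcast:::net_forward(p, x * eps)$ys
  lin <- sweep((x * eps) %*% t(p$W1) %*% t(p$W2), 2, p$b2, "+")
  expect_equal(full, lin, tolerance = 1e-6)
  # scaling round trip
  sc <- wristcast:::fit_scaler(x)
  expect_equal(wristcast:::invert_scaler(wristcast:::apply_scaler(x, sc), sc), x,
               tolerance = 1e-12)
})

test_that("Bayesian-regularized training converges to the ridge fixed point", {
  set.seed(1)
  n <- 200; p <- 4
  X <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  Y <- scale(matrix(X %*% c(1, -2, 0.5, 0) + rnorm(n, sd = 0.5)), scale = FALSE)
  fit <- arm_net(X, Y, hidden = 0, trainer = "bayes-lm", scale = FALSE,
                 max_epochs = 300, seed = 2)
  ridge <- solve(crossprod(X) + diag(fit$alpha / fit$beta, p), crossprod(X, Y))
  expect_lt(max(abs(as.vector(coef(fit)$W2) - as.vector(ridge))), 1e-6)
  nw <- length(wristcast:::pack_params(coef(fit)))
  expect_true(all(fit$log$gamma >= 0 & fit$log$gamma <= nw))
})

test_that("the regularized loss never increases between accepted steps", {
  set.seed(6)
  X <- matrix(runif(300, -1, 1), 100, 3)
  Y <- cbind(sin(2 * X[, 1]) + X[, 2]^2)
  fit <- arm_net(X, Y, hidden = 6, trainer = "bayes-lm", max_epochs = 60, seed = 3)
  expect_true(all(fit$log$f_after <= fit$log$f_before))
  nw <- length(wristcast:::pack_params(coef(fit)))
  expect_true(all(fit$log$gamma >= 0 & fit$log$gamma <= nw))
})

test_that("a constant target collapses to the bias with tiny gamma", {
  set.seed(7)
  X <- matrix(rnorm(150), 50, 3)
  Y <- matrix(4.2, 50, 1)
  fit <- arm_net(X, Y, hidden = 4, trainer = "bayes-lm", max_epochs = 100, seed = 1)
  expect_equal(as.vector(predict(fit, X)), rep(4.2, 50), tolerance = 1e-6)
  expect_lt(fit$gamma, 2)
})

test_that("teacher networks are recovered from noise-free data", {
  set.seed(3)
  teach <- init_network(3, 5, 1, seed = 9)
  Xt <- matrix(runif(1500, -1, 1), 500, 3)
  Yt <- wristcast:::net_forward(teach, Xt)$ys
  Xs <- matrix(runif(600, -1, 1), 200, 3)
  Ys <- wristcast:::net_forward(teach, Xs)$ys
  fit <- arm_net(Xt, Yt, hidden = 5, trainer = "bayes-lm", max_epochs = 400,
                 seed = 4)
  # scaled test MSE: targets were scaled to [-1,1] during fitting
  half <- diff(range(Yt)) / 2
  expect_lt(mean((predict(fit, Xs) - Ys)^2) / half^2, 1e-4)
})

test_that("plain Levenberg-Marquardt matches least squares on linear data", {
  set.seed(8)
  X <- matrix(rnorm(240), 80, 3)
  B <- c(2, -1, 0.5)
  Y <- cbind(X %*% B + 3)
  fit <- arm_net(X, Y, hidden = 0, trainer = "lm", activation = "identity",
                 scale = FALSE, max_epochs = 200, seed = 5, val_fraction = 0.2)
  ols <- lm.fit(cbind(1, X), Y)$coefficients
  expect_equal(as.vector(coef(fit)$W2), unname(ols[2:4]), tolerance = 1e-6)
  expect_equal(as.vector(coef(fit)$b2), unname(ols[1]), tolerance = 1e-6)
  expect_true(all(diff(fit$log$train_mse) < 1e-12))
})

test_that("scaled conjugate gradient minimizes and tracks the LM solution", {
  # quadratic bowl: linear net on well-conditioned linear data
  set.seed(9)
  X <- matrix(rnorm(300), 100, 3)
  Y <- cbind(X %*% c(1, 2, -1))
  fit <- arm_net(X, Y, hidden = 0, trainer = "scg", activation = "identity",
                 scale = FALSE, max_epochs = 3000, seed = 6, val_fraction = 0)
  g <- wristcast:::net_gradient(coef(fit), X, Y)$grad
  expect_lt(sqrt(sum(g^2)), 1e-4)
  # noisy teacher: final losses of scg and lm agree within 10%
  teach <- init_network(3, 4, 1, seed = 2)
  Xt <- matrix(runif(1200, -1, 1), 400, 3)
  Yt <- wristcast:::net_forward(teach, Xt)$ys + rnorm(400, sd = 0.1)
  f_lm <- arm_net(Xt, Yt, hidden = 4, trainer = "lm", max_epochs = 300, seed = 3,
                  val_fraction = 0)
  f_sc <- arm_net(Xt, Yt, hidden = 4, trainer = "scg", max_epochs = 8000, seed = 3,
                  val_fraction = 0)
  m_lm <- mean((predict(f_lm, Xt) - Yt)^2)
  m_sc <- mean((predict(f_sc, Xt) - Yt)^2)
  expect_lt(abs(m_sc - m_lm) / m_lm, 0.1)
  # determinism
  f_sc2 <- arm_net(Xt, Yt, hidden = 4, trainer = "scg", max_epochs = 8000, seed = 3,
                   val_fraction = 0)
  expect_identical(coef(f_sc), coef(f_sc2))
})

test_that("time-delay prediction recovers a teacher and keeps lengths", {
  norm <- small_norm_study()
  cen <- center_by_subject(norm)$trials
  cc <- taper_concatenate(cen, taper_len = 5, seed = 1)
  emb <- embed_delays(cc, "1:2")
  teach <- init_network(10, 3, 1, seed = 11)
  ytrue <- wristcast:::net_forward(teach, emb$x / 100)$ys
  fit <- arm_net(emb$x / 100, ytrue, hidden = 3, trainer = "bayes-lm",
                 max_epochs = 150, seed = 2, scale = FALSE)
  expect_lt(mean((predict(fit, emb$x / 100) - ytrue)^2), 1e-4)

  models <- lapply(1:3, function(k)
    arm_net(emb$x, emb$y[, k, drop = FALSE], hidden = 2, trainer = "bayes-lm",
            max_epochs = 10, seed = k))
  pred <- predict_tdnn(models, cc, "1:2")
  expect_equal(nrow(pred), nrow(cc$angles))
  expect_true(all(is.na(pred[1:2, ])))
  expect_false(anyNA(pred[-(1:2), ]))
  expect_error(predict_tdnn(models, cc, "1:10"), "delay specification")
})

test_that("the linear baseline matches the normal equations", {
  norm <- small_norm_study()
  stacked <- stack_study_angles(norm)
  fit <- fit_linear(stacked)
  X <- cbind(1, stacked[, wristcast:::INPUT_CHANNELS])
  for (k in 1:3) {
    beta <- solve(crossprod(X), crossprod(X, stacked[, wristcast:::TARGET_CHANNELS[k]]))
    expect_equal(unname(coef(fit)[, k]), as.vector(beta), tolerance = 1e-9)
  }
  # permutation invariance
  fit2 <- fit_linear(stacked[sample(nrow(stacked)), ])
  expect_equal(coef(fit), coef(fit2), tolerance = 1e-9)

  # exactly linear targets give a perfect fit
  lin <- stacked
  lin[, "wrist_FE"] <- 2 * lin[, "elbow_FE"] - lin[, "shoulder_AA"] + 5
  lin[, "wrist_AA"] <- lin[, "shoulder_FE"] * 0.5
  lin[, "forearm_PS"] <- lin[, "elbow_AA"] - 3
  pf <- fit_linear(lin)
  expect_true(all(pf$diagnostics$mae < 1e-9))
  expect_true(all(abs(pf$diagnostics$cc - 1) < 1e-9))
})
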