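# Shallow feed-forward network with Bayesian-regularized Levenberg-Marquardt
# training, plus plain Levenberg-Marquardt and scaled-conjugate-gradient
# alternatives. The network is hyperbolic-tangent hidden + linear output with
# min-max [-1, 1] scaling of inputs and targets, the toolbox-style default
# for shallow regression networks.
#
# Loss bookkeeping: E_D = sum of squared scaled errors, E_W = 0.5 * sum of
# squared weights. The Levenberg-Marquardt step solves
#   (beta J'J + (alpha + mu) I) dw = -(beta J'e + alpha w),
# whose fixed point for a linear net is the ridge solution
# w = (X'X + (alpha/beta) I)^-1 X'y. The objective that this step descends,
# and that acceptance is tested against, is F = beta E_D + 2 alpha E_W.
# After each accepted step the evidence framework re-estimates the effective
# number of parameters gamma = sum beta l_i / (beta l_i + alpha) over the
# eigenvalues l_i of J'J (so 0 <= gamma <= N_w always), then
# alpha <- gamma / (2 E_W), beta <- (M - gamma) / (2 E_D).

# ---- parameter packing ------------------------------------------------------

init_params <- function(n_in, hidden, n_out, seed = 1) {
  with_seed(seed, {
    if (hidden == 0) {
      list(W2 = matrix(runif(n_out * n_in, -0.5, 0.5), n_out, n_in),
           b2 = runif(n_out, -0.5, 0.5))
    } else {
      # Nguyen-Widrow: random unit directions scaled to partition the input
      # hypercube, biases spread across [-scale, scale].
      scale <- 0.7 * hidden^(1 / n_in)
      W1 <- matrix(runif(hidden * n_in, -1, 1), hidden, n_in)
      W1 <- W1 / sqrt(rowSums(W1^2)) * scale
      b1 <- scale * seq(-1, 1, length.out = hidden) * sign(W1[, 1])
      list(W1 = W1, b1 = b1,
           W2 = matrix(runif(n_out * hidden, -0.5, 0.5), n_out, hidden),
           b2 = runif(n_out, -0.5, 0.5))
    }
  })
}

#' Initialize a shallow network
#'
#' Seeded Nguyen-Widrow-style initialization: hidden weight rows are random
#' directions scaled by \eqn{0.7 h^{1/n_{in}}} with biases spread over the
#' input hypercube, so the hidden units partition the input range.
#'
#' @param n_in,hidden,n_out Layer widths (\code{hidden = 0} gives a direct
#'   affine map, used for linear-regime checks).
#' @param seed Seed; identical seeds give identical weights.
#' @return A list of weight matrices \code{W1}, \code{b1}, \code{W2},
#'   \code{b2}.
#' @export
init_network <- function(n_in, hidden, n_out, seed = 1) {
  stopifnot(n_in >= 1, n_out >= 1, hidden >= 0)
  init_params(n_in, hidden, n_out, seed)
}

pack_params <- function(p) unlist(p, use.names = FALSE)

unpack_params <- function(w, n_in, hidden, n_out) {
  if (hidden == 0) {
    list(W2 = matrix(w[seq_len(n_out * n_in)], n_out, n_in),
         b2 = w[n_out * n_in + seq_len(n_out)])
  } else {
    i <- 0
    W1 <- matrix(w[i + seq_len(hidden * n_in)], hidden, n_in); i <- i + hidden * n_in
    b1 <- w[i + seq_len(hidden)]; i <- i + hidden
    W2 <- matrix(w[i + seq_len(n_out * hidden)], n_out, hidden); i <- i + n_out * hidden
    b2 <- w[i + seq_len(n_out)]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
}

# ---- scaling ----------------------------------------------------------------

fit_scaler <- function(x) {
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  half <- (hi - lo) / 2
  half[half == 0] <- 1
  list(center = (hi + lo) / 2, half = half)
}
apply_scaler <- function(x, s) sweep(sweep(x, 2, s$center), 2, s$half, "/")
invert_scaler <- function(x, s) sweep(sweep(x, 2, s$half, "*"), 2, s$center, "+")

# ---- forward pass and Jacobian ---------------------------------------------

net_forward <- function(p, xs, activation = "tanh") {
  if (is.null(p$W1)) {
    h <- NULL
    ys <- xs %*% t(p$W2) + rep(p$b2, each = nrow(xs))
  } else {
    a <- xs %*% t(p$W1) + rep(p$b1, each = nrow(xs))
    h <- if (activation == "tanh") tanh(a) else a
    ys <- h %*% t(p$W2) + rep(p$b2, each = nrow(xs))
  }
  list(h = h, ys = ys)
}

# Jacobian of the stacked scaled outputs (column-stacked by output) with
# respect to the packed parameter vector, by exact backpropagation.
net_jacobian <- function(p, xs, h, activation = "tanh") {
  n <- nrow(xs)
  if (is.null(p$W1)) {
    n_out <- nrow(p$W2); n_in <- ncol(p$W2)
    J <- matrix(0, n * n_out, n_out * n_in + n_out)
    for (k in seq_len(n_out)) {
      rows <- (k - 1) * n + seq_len(n)
      for (i in seq_len(n_in)) J[rows, (i - 1) * n_out + k] <- xs[, i]
      J[rows, n_out * n_in + k] <- 1
    }
    return(J)
  }
  hidden <- ncol(h); n_in <- ncol(xs); n_out <- nrow(p$W2)
  dh <- if (activation == "tanh") 1 - h^2 else matrix(1, n, hidden)
  nw <- hidden * n_in + hidden + n_out * hidden + n_out
  J <- matrix(0, n * n_out, nw)
  for (k in seq_len(n_out)) {
    rows <- (k - 1) * n + seq_len(n)
    dk <- dh * rep(p$W2[k, ], each = n)               # n x hidden
    for (i in seq_len(n_in))                           # W1 block, column-major
      J[rows, (i - 1) * hidden + seq_len(hidden)] <- dk * xs[, i]
    J[rows, hidden * n_in + seq_len(hidden)] <- dk     # b1
    off <- hidden * n_in + hidden
    for (j in seq_len(hidden))                         # W2 block, column-major
      J[rows, off + (j - 1) * n_out + k] <- h[, j]
    J[rows, off + n_out * hidden + k] <- 1             # b2
  }
  J
}

# ---- trainers ---------------------------------------------------------------

lm_solve <- function(A, g) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  backsolve(ch, forwardsolve(t(ch), g))
}

train_bayes_lm <- function(p, xs, ys, max_epochs, tol = 1e-9,
                           bayes = TRUE, activation = "tanh",
                           xs_val = NULL, ys_val = NULL, patience = 6,
                           xs_test = NULL, ys_test = NULL) {
  dims <- list(n_in = ncol(xs), hidden = if (is.null(p$W1)) 0 else nrow(p$W1),
               n_out = length(p$b2))
  w <- pack_params(p)
  nw <- length(w)
  m <- nrow(xs) * dims$n_out
  alpha <- if (bayes) 0.01 else 0
  beta <- 1
  mu <- 0.005
  log <- list()
  best_val <- Inf; best_w <- w; wait <- 0
  gamma <- nw
  f_prev <- NA
  for (epoch in seq_len(max_epochs)) {
    p <- unpack_params(w, dims$n_in, dims$hidden, dims$n_out)
    fw <- net_forward(p, xs, activation)
    e <- as.vector(fw$ys - ys)
    ed <- sum(e^2); ew <- 0.5 * sum(w^2)
    f <- beta * ed + 2 * alpha * ew
    J <- net_jacobian(p, xs, fw$h, activation)
    JtJ <- crossprod(J)
    g <- beta * crossprod(J, e)[, 1] + alpha * w
    accepted <- FALSE
    while (mu <= 1e10) {
      step <- lm_solve(beta * JtJ + diag(alpha + mu, nw), -g)
      if (!is.null(step)) {
        w_new <- w + step
        p_new <- unpack_params(w_new, dims$n_in, dims$hidden, dims$n_out)
        e_new <- as.vector(net_forward(p_new, xs, activation)$ys - ys)
        if (all(is.finite(e_new))) {
          f_new <- beta * sum(e_new^2) + alpha * sum(w_new^2)
          if (f_new < f) {
            w <- w_new
            mu <- max(mu / 10, 1e-10)
            accepted <- TRUE
            break
          }
        }
      }
      mu <- mu * 10
    }
    if (!accepted) break  # mu overflow: no further descent possible
    p <- unpack_params(w, dims$n_in, dims$hidden, dims$n_out)
    e <- as.vector(net_forward(p, xs, activation)$ys - ys)
    ed <- sum(e^2); ew <- 0.5 * sum(w^2)
    if (bayes) {
      # gamma = sum beta*l/(beta*l + alpha) = N_w - alpha tr((beta J'J + alpha I)^-1)
      ch <- tryCatch(chol(beta * JtJ + diag(alpha, nw)), error = function(e) NULL)
      if (!is.null(ch)) {
        gamma <- nw - alpha * sum(diag(chol2inv(ch)))
      } else {
        lam <- eigen(JtJ, symmetric = TRUE, only.values = TRUE)$values
        lam[lam < 0] <- 0
        gamma <- sum(beta * lam / (beta * lam + alpha))
      }
      gamma <- min(max(gamma, 0), nw)
      alpha <- gamma / (2 * max(ew, 1e-12))
      beta <- (m - gamma) / (2 * max(ed, 1e-12))
    }
    f_now <- beta * ed + 2 * alpha * ew
    ent <- list(epoch = epoch, train_mse = ed / m, f_before = f, f_after = f_new,
                alpha = alpha, beta = beta, gamma = gamma, mu = mu)
    if (!is.null(xs_val)) {
      ev <- as.vector(net_forward(p, xs_val, activation)$ys - ys_val)
      ent$val_mse <- mean(ev^2)
      if (ent$val_mse < best_val - 1e-12) {
        best_val <- ent$val_mse; best_w <- w; wait <- 0
      } else wait <- wait + 1
    }
    if (!is.null(xs_test)) {
      et <- as.vector(net_forward(p, xs_test, activation)$ys - ys_test)
      ent$test_mse <- mean(et^2)
    }
    log[[epoch]] <- ent
    if (!is.null(xs_val) && wait >= patience) break
    if (!is.na(f_prev) && abs(f_prev - f_now) / max(f_now, 1e-300) < tol) break
    f_prev <- f_now
  }
  if (!is.null(xs_val)) w <- best_w
  list(params = unpack_params(w, dims$n_in, dims$hidden, dims$n_out),
       alpha = alpha, beta = beta, gamma = gamma,
       log = do.call(rbind, lapply(log, function(l)
         as.data.frame(l[!vapply(l, is.null, logical(1))]))))
}

net_gradient <- function(p, xs, ys, activation = "tanh") {
  fw <- net_forward(p, xs, activation)
  E <- fw$ys - ys
  if (is.null(p$W1)) {
    g <- list(W2 = 2 * crossprod(E, xs), b2 = 2 * colSums(E))
    return(list(grad = pack_params(g), ed = sum(E^2)))
  }
  dH <- (E %*% p$W2) * (if (activation == "tanh") 1 - fw$h^2 else 1)
  g <- list(W1 = 2 * crossprod(dH, xs), b1 = 2 * colSums(dH),
            W2 = 2 * crossprod(E, fw$h), b2 = 2 * colSums(E))
  list(grad = pack_params(g), ed = sum(E^2))
}

# Moller's scaled conjugate gradient on the sum-of-squares loss.
train_scg <- function(p, xs, ys, max_epochs, tol = 1e-9, activation = "tanh",
                      xs_val = NULL, ys_val = NULL, patience = 6,
                      xs_test = NULL, ys_test = NULL) {
  dims <- list(n_in = ncol(xs), hidden = if (is.null(p$W1)) 0 else nrow(p$W1),
               n_out = length(p$b2))
  ed_of <- function(w) {
    pp <- unpack_params(w, dims$n_in, dims$hidden, dims$n_out)
    sum((net_forward(pp, xs, activation)$ys - ys)^2)
  }
  grad_of <- function(w) {
    pp <- unpack_params(w, dims$n_in, dims$hidden, dims$n_out)
    net_gradient(pp, xs, ys, activation)$grad
  }
  w <- pack_params(p)
  nw <- length(w)
  sigma0 <- 5e-5; lambda <- 5e-7; lambda_bar <- 0
  r <- -grad_of(w); d <- r
  success <- TRUE
  f <- ed_of(w)
  delta <- 0
  log <- list()
  best_val <- Inf; best_w <- w; wait <- 0
  m <- nrow(xs) * dims$n_out
  for (epoch in seq_len(max_epochs)) {
    if (success) {
      nd2 <- sum(d^2)
      if (nd2 < 1e-300) break
      sigma <- sigma0 / sqrt(nd2)
      s <- (-grad_of(w + sigma * d) - r) / sigma
      delta <- sum(d * s)
    }
    delta_reg <- delta + (lambda - lambda_bar) * sum(d^2)
    if (delta_reg <= 0) {
      lambda_bar <- 2 * (lambda - delta_reg / sum(d^2))
      delta_reg <- -delta + lambda * sum(d^2)
      lambda <- lambda_bar
    }
    mu_step <- sum(d * r)
    step_a <- mu_step / delta_reg
    w_new <- w + step_a * d
    f_new <- ed_of(w_new)
    comp <- 2 * delta_reg * (f - f_new) / mu_step^2
    if (is.finite(comp) && comp >= 0) {
      w <- w_new
      f_old <- f; f <- f_new
      r_new <- -grad_of(w)
      lambda_bar <- 0; success <- TRUE
      if (epoch %% nw == 0) d <- r_new
      else {
        beta_cg <- (sum(r_new^2) - sum(r_new * r)) / mu_step
        d <- r_new + beta_cg * d
      }
      r <- r_new
      if (comp >= 0.75) lambda <- lambda / 4
      ent <- list(epoch = epoch, train_mse = f / m)
      if (!is.null(xs_val)) {
        pp <- unpack_params(w, dims$n_in, dims$hidden, dims$n_out)
        ev <- as.vector(net_forward(pp, xs_val, activation)$ys - ys_val)
        ent$val_mse <- mean(ev^2)
        if (ent$val_mse < best_val - 1e-12) {
          best_val <- ent$val_mse; best_w <- w; wait <- 0
        } else wait <- wait + 1
      }
      if (!is.null(xs_test)) {
        pp <- unpack_params(w, dims$n_in, dims$hidden, dims$n_out)
        et <- as.vector(net_forward(pp, xs_test, activation)$ys - ys_test)
        ent$test_mse <- mean(et^2)
      }
      log[[length(log) + 1]] <- ent
      if (!is.null(xs_val) && wait >= patience) break
      if (abs(f_old - f) / max(f, 1e-300) < tol && sqrt(sum(r^2)) < 1e-6) break
    } else {
      lambda_bar <- lambda; success <- FALSE
    }
    if (comp < 0.25 || !is.finite(comp)) lambda <- lambda + delta_reg * (1 - comp) / sum(d^2)
    if (!is.finite(lambda) || lambda > 1e15) break
  }
  if (!is.null(xs_val)) w <- best_w
  list(params = unpack_params(w, dims$n_in, dims$hidden, dims$n_out),
       alpha = 0, beta = 1, gamma = NA_real_,
       log = do.call(rbind, lapply(log, function(l)
         as.data.frame(l[!vapply(l, is.null, logical(1))]))))
}

# ---- the user-facing model --------------------------------------------------

#' Fit a shallow wrist-prediction network
#'
#' Fits a single-hidden-layer network (hyperbolic-tangent hidden units,
#' linear output, min-max scaling of inputs and targets to [-1, 1]) mapping
#' elbow/shoulder angles to wrist angles.
#'
#' Trainers: \code{"bayes-lm"} (default) is Bayesian-regularized
#' Levenberg-Marquardt — LM steps on the regularized loss
#' \eqn{F = \beta E_D + \alpha \|w\|^2}, with \eqn{\alpha, \beta}
#' re-estimated each epoch from the evidence framework through the effective
#' number of parameters \eqn{\gamma}; no validation set is used, the
#' regularization replacing early stopping. \code{"lm"} is plain
#' Levenberg-Marquardt and \code{"scg"} scaled conjugate gradient, both with
#' early stopping on a validation subset carved from the training rows.
#'
#' @param x,y Numeric input and target matrices (rows = cases, degrees).
#' @param hidden Hidden-layer width (5-20 typical; 0 gives a direct affine
#'   map).
#' @param trainer One of \code{"bayes-lm"}, \code{"lm"}, \code{"scg"}.
#' @param activation Hidden activation (\code{"identity"} is available for
#'   linear-regime analysis).
#' @param scale Fit min-max scalers on the training data (frozen before
#'   training). Disable only for controlled numerical experiments.
#' @param max_epochs Epoch cap.
#' @param seed Seed for initialization and the validation split.
#' @param x_test,y_test Optional held-out data logged per epoch
#'   (train/test loss curves).
#' @param val_fraction,patience Early-stopping parameters for the
#'   non-Bayesian trainers.
#' @param tol Relative loss-change convergence tolerance.
#' @return An object of class \code{arm_net} with weight matrices, scalers,
#'   regularization state (\code{alpha}, \code{beta}, \code{gamma}) and the
#'   per-epoch training log.
#' @examples
#' x <- matrix(rnorm(200), 100, 2)
#' y <- cbind(tanh(x[, 1]) + 0.5 * x[, 2])
#' fit <- arm_net(x, y, hidden = 4, seed = 1, max_epochs = 50)
#' mean((predict(fit, x) - y)^2)
#' @export
arm_net <- function(x, y, hidden = 10,
                    trainer = c("bayes-lm", "lm", "scg"),
                    activation = c("tanh", "identity"),
                    scale = TRUE, max_epochs = 1000, seed = 1,
                    x_test = NULL, y_test = NULL,
                    val_fraction = 0.15, patience = 6, tol = 1e-9) {
  trainer <- match.arg(trainer)
  activation <- match.arg(activation)
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), nrow(x) >= 2)
  sc_in <- if (scale) fit_scaler(x) else list(center = rep(0, ncol(x)), half = rep(1, ncol(x)))
  sc_out <- if (scale) fit_scaler(y) else list(center = rep(0, ncol(y)), half = rep(1, ncol(y)))
  xs <- apply_scaler(x, sc_in); ys <- apply_scaler(y, sc_out)
  xs_test <- if (!is.null(x_test)) apply_scaler(as.matrix(x_test), sc_in)
  ys_test <- if (!is.null(y_test)) apply_scaler(as.matrix(y_test), sc_out)
  p0 <- init_params(ncol(x), hidden, ncol(y), seed)
  use_val <- trainer %in% c("lm", "scg") && val_fraction > 0
  if (use_val) {
    idx <- with_seed(derive_seed(seed, 97L),
                     sample(nrow(xs), max(1, round(val_fraction * nrow(xs)))))
    xs_val <- xs[idx, , drop = FALSE]; ys_val <- ys[idx, , drop = FALSE]
    xs_tr <- xs[-idx, , drop = FALSE]; ys_tr <- ys[-idx, , drop = FALSE]
  } else {
    xs_val <- NULL; ys_val <- NULL; xs_tr <- xs; ys_tr <- ys
  }
  fit <- switch(trainer,
    "bayes-lm" = train_bayes_lm(p0, xs_tr, ys_tr, max_epochs, tol,
                                bayes = TRUE, activation = activation,
                                xs_test = xs_test, ys_test = ys_test),
    "lm" = train_bayes_lm(p0, xs_tr, ys_tr, max_epochs, tol, bayes = FALSE,
                          activation = activation,
                          xs_val = xs_val, ys_val = ys_val, patience = patience,
                          xs_test = xs_test, ys_test = ys_test),
    "scg" = train_scg(p0, xs_tr, ys_tr, max_epochs, tol, activation = activation,
                      xs_val = xs_val, ys_val = ys_val, patience = patience,
                      xs_test = xs_test, ys_test = ys_test))
  structure(list(params = fit$params, scaler_in = sc_in, scaler_out = sc_out,
                 hidden = hidden, n_in = ncol(x), n_out = ncol(y),
                 trainer = trainer, activation = activation,
                 alpha = fit$alpha, beta = fit$beta, gamma = fit$gamma,
                 log = fit$log, seed = seed,
                 call = match.call()),
            class = "arm_net")
}

#' @export
predict.arm_net <- function(object, newdata, ...) {
  xs <- apply_scaler(as.matrix(newdata), object$scaler_in)
  if (ncol(xs) != object$n_in) stop("input width mismatch", call. = FALSE)
  invert_scaler(net_forward(object$params, xs, object$activation)$ys,
                object$scaler_out)
}

#' @export
print.arm_net <- function(x, ...) {
  cat(sprintf("Shallow network %d-%d-%d (%s, trainer %s)\n",
              x$n_in, x$hidden, x$n_out, x$activation, x$trainer))
  if (x$trainer == "bayes-lm")
    cat(sprintf("  alpha = %.4g, beta = %.4g, effective parameters gamma = %.1f / %d\n",
                x$alpha, x$beta, x$gamma, length(pack_params(x$params))))
  if (!is.null(x$log) && nrow(x$log))
    cat(sprintf("  %d epochs, final train MSE (scaled) = %.3g\n",
                nrow(x$log), x$log$train_mse[nrow(x$log)]))
  invisible(x)
}

#' @export
summary.arm_net <- function(object, ...) {
  out <- list(widths = c(object$n_in, object$hidden, object$n_out),
              trainer = object$trainer,
              n_weights = length(pack_params(object$params)),
              alpha = object$alpha, beta = object$beta, gamma = object$gamma,
              epochs = if (is.null(object$log)) 0 else nrow(object$log),
              final_train_mse = if (is.null(object$log) || !nrow(object$log))
                NA_real_ else object$log$train_mse[nrow(object$log)])
  class(out) <- "summary.arm_net"
  out
}

#' @export
print.summary.arm_net <- function(x, ...) {
  cat(sprintf("arm_net %d-%d-%d, trainer %s, %d weights, %d epochs\n",
              x$widths[1], x$widths[2], x$widths[3], x$trainer, x$n_weights,
              x$epochs))
  cat(sprintf("  final scaled train MSE %.3g; alpha %.3g beta %.3g gamma %.1f\n",
              x$final_train_mse, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' @export
coef.arm_net <- function(object, ...) object$params

#' @export
residuals.arm_net <- function(object, x, y, ...) {
  as.matrix(y) - predict(object, x)
}

#' Plot the training log of a network
#'
#' Scaled train (and, when logged, test) mean squared error against epoch on
#' a log scale — the loss-curve diagnostic of the training process.
#'
#' @param x An \code{arm_net}.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.arm_net <- function(x, ...) {
  if (is.null(x$log) || !nrow(x$log)) {
    warning("no training log to plot")
    return(invisible(x))
  }
  cols <- intersect(c("train_mse", "test_mse"), names(x$log))
  graphics::matplot(x$log$epoch, as.matrix(x$log[, cols, drop = FALSE]),
                    type = "l", lty = 1, log = "y",
                    xlab = "epoch", ylab = "MSE (scaled)", ...)
  graphics::legend("topright", legend = cols, lty = 1,
                   col = seq_along(cols), bty = "n")
  invisible(x)
}

#' Predict wrist-angle series with per-angle time-delay networks
#'
#' Applies the delay embedding and one network per wrist angle to a
#' concatenated input series. The first max(delay) samples of the
#' concatenation cannot be predicted and are returned as \code{NA}.
#'
#' @param models List of three \code{arm_net} fits (wrist F/E, wrist A/A,
#'   forearm P/S), trained on the same delay specification.
#' @param concat Concatenation from [taper_concatenate()].
#' @param delays Delay specification used at training time.
#' @return A matrix with one row per concatenation sample and one column per
#'   target angle; leading masked samples are \code{NA}.
#' @export
predict_tdnn <- function(models, concat, delays) {
  delays <- parse_delay_spec(delays)
  emb <- embed_delays(concat, delays)
  exp_in <- length(delays) * length(INPUT_CHANNELS)
  out <- matrix(NA_real_, nrow(concat$angles), length(models),
                dimnames = list(NULL, paste0("pred_", TARGET_CHANNELS)))
  for (k in seq_along(models)) {
    if (models[[k]]$n_in != exp_in)
      stop("model input width does not match the delay specification",
           call. = FALSE)
    out[emb$t_index, k] <- predict(models[[k]], emb$x)[, 1]
  }
  out
}
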