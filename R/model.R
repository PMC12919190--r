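#' Configuration for the dual-branch ordinal severity model
#'
#' The model scores a clip from two inputs: the task-specific kinematic
#' signal, resampled to a fixed length and processed by a temporal
#' convolutional branch (1D convolutions with batch normalization, ReLU
#' and max pooling, then global average pooling), and the handcrafted
#' kinematic feature vector processed by a small multilayer perceptron.
#' The concatenated embeddings feed a rank-consistent cumulative-logit
#' (CORAL-style) head: a single learned score plus `K - 1` ordered bias
#' thresholds, so the cumulative probabilities P(severity > k) are
#' non-increasing by construction.
#'
#' Training minimizes a disagreement-aware loss: a Huber loss of the
#' predicted mean severity against the rater-panel mean, plus
#' `lambda` times the predicted distribution's variance, which pushes the
#' model to be confident exactly where raters agree.
#'
#' @param num_classes Number of ordinal severity levels K (default 5,
#'   scores 0-4).
#' @param input_length Fixed signal length T after resampling (default
#'   256).
#' @param cnn_blocks List of `c(channels, kernel, pool)` triples for the
#'   convolutional branch.
#' @param mlp_widths Hidden-layer widths of the feature branch.
#' @param lambda Weight of the predictive-variance penalty (>= 0).
#' @param huber_delta Huber transition point (> 0, default 1).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 32).
#' @param epochs Training epochs (default 100).
#' @param seed RNG seed controlling initialization and batch shuffling.
#' @returns A `model_config` list.
#' @export
model_config <- function(num_classes = 5L, input_length = 256L,
                         cnn_blocks = list(
                           c(16L, 7L, 2L), c(32L, 5L, 2L), c(64L, 3L, 2L)
                         ),
                         mlp_widths = c(32L, 16L),
                         lambda = 0.1, huber_delta = 1,
                         lr = 1e-3, batch_size = 32L, epochs = 100L,
                         seed = 1L) {
  if (num_classes < 2L) {
    rlang::abort("num_classes must be >= 2", class = "kinscore_config_error")
  }
  if (input_length < 8L) {
    rlang::abort("input_length must be >= 8", class = "kinscore_config_error")
  }
  if (lambda < 0) {
    rlang::abort("lambda must be >= 0", class = "kinscore_config_error")
  }
  if (huber_delta <= 0) {
    rlang::abort("huber_delta must be > 0", class = "kinscore_config_error")
  }
  structure(
    list(
      num_classes = as.integer(num_classes),
      input_length = as.integer(input_length),
      cnn_blocks = cnn_blocks, mlp_widths = as.integer(mlp_widths),
      lambda = lambda, huber_delta = huber_delta,
      lr = lr, batch_size = as.integer(batch_size),
      epochs = as.integer(epochs), seed = as.integer(seed)
    ),
    class = "model_config"
  )
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

#' Build an untrained dual-branch ordinal model
#'
#' Initializes all parameters (He-scaled Gaussians) under the config seed.
#' The forward pass maps a `(batch, T)` signal matrix and a
#' `(batch, n_features)` feature matrix to `K - 1` cumulative logits per
#' sample.
#'
#' @param config A [model_config()].
#' @param n_features Length of the handcrafted feature vector (>= 1).
#' @returns A `kin_model` object (untrained).
#' @export
build_model <- function(config, n_features) {
  stopifnot(inherits(config, "model_config"))
  if (n_features < 1L) {
    rlang::abort("n_features must be >= 1", class = "kinscore_config_error")
  }
  set.seed(config$seed)
  K <- config$num_classes
  params <- list()
  state <- list()
  c_in <- 1L
  for (i in seq_along(config$cnn_blocks)) {
    blk <- config$cnn_blocks[[i]]
    c_out <- blk[1L]
    k <- blk[2L]
    if (k %% 2L == 0L) {
      rlang::abort("conv kernel sizes must be odd",
        class = "kinscore_config_error"
      )
    }
    params[[paste0("conv", i, "_W")]] <- he_init(c_in * k, c_out, c_in * k)
    params[[paste0("conv", i, "_b")]] <- rep(0, c_out)
    params[[paste0("bn", i, "_gamma")]] <- rep(1, c_out)
    params[[paste0("bn", i, "_beta")]] <- rep(0, c_out)
    state[[paste0("bn", i, "_mean")]] <- rep(0, c_out)
    state[[paste0("bn", i, "_var")]] <- rep(1, c_out)
    c_in <- c_out
  }
  d_in <- n_features
  for (i in seq_along(config$mlp_widths)) {
    d_out <- config$mlp_widths[i]
    params[[paste0("fc", i, "_W")]] <- he_init(d_in, d_out, d_in)
    params[[paste0("fc", i, "_b")]] <- rep(0, d_out)
    d_in <- d_out
  }
  embed_dim <- c_in + d_in
  params$head_w <- he_init(embed_dim, 1L, embed_dim)
  # ordered thresholds: b_1 = theta_1, b_k = b_{k-1} - exp(theta_k)
  params$head_theta <- c((K - 2) / 2, rep(0, K - 2L))

  structure(
    list(
      config = config, n_features = as.integer(n_features),
      params = params, state = state,
      signal_center = 0, signal_scale = 1,
      feature_center = rep(0, n_features),
      feature_scale = rep(1, n_features),
      trained = FALSE, history = NULL
    ),
    class = "kin_model"
  )
}

#' @export
print.kin_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1L)))
  cat(sprintf(
    "<dual-branch ordinal model: K = %d, T = %d, %d features, %d parameters, %s>\n",
    x$config$num_classes, x$config$input_length, x$n_features, n_par,
    if (x$trained) "trained" else "untrained"
  ))
  invisible(x)
}

head_biases <- function(theta) {
  if (length(theta) == 1L) {
    return(theta)
  }
  theta[1L] - cumsum(c(0, exp(theta[-1L])))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- layer forward/backward primitives (B x C x L arrays) ----------------

im2col <- function(X, k) {
  B <- dim(X)[1L]
  C <- dim(X)[2L]
  L <- dim(X)[3L]
  pad <- (k - 1L) %/% 2L
  Xp <- array(0, c(B, C, L + 2L * pad))
  Xp[, , pad + seq_len(L)] <- X
  cols <- matrix(0, B * L, C * k)
  col <- 0L
  for (ch in seq_len(C)) {
    for (j in seq_len(k)) {
      col <- col + 1L
      cols[, col] <- as.vector(Xp[, ch, j:(j + L - 1L)])
    }
  }
  cols
}

col2im <- function(dcols, B, C, L, k) {
  pad <- (k - 1L) %/% 2L
  dXp <- array(0, c(B, C, L + 2L * pad))
  col <- 0L
  for (ch in seq_len(C)) {
    for (j in seq_len(k)) {
      col <- col + 1L
      dXp[, ch, j:(j + L - 1L)] <-
        dXp[, ch, j:(j + L - 1L)] + matrix(dcols[, col], B, L)
    }
  }
  dXp[, , pad + seq_len(L), drop = FALSE]
}

conv_forward <- function(X, W, b, k) {
  B <- dim(X)[1L]
  L <- dim(X)[3L]
  cols <- im2col(X, k)
  out <- sweep(cols %*% W, 2L, b, "+")
  Y <- aperm(array(out, c(B, L, ncol(W))), c(1L, 3L, 2L))
  list(Y = Y, cols = cols)
}

conv_backward <- function(dY, cache, W, k, in_dim) {
  B <- in_dim[1L]
  C <- in_dim[2L]
  L <- in_dim[3L]
  dout <- matrix(aperm(dY, c(1L, 3L, 2L)), B * L, dim(dY)[2L])
  dW <- crossprod(cache$cols, dout)
  db <- colSums(dout)
  dcols <- dout %*% t(W)
  dX <- col2im(dcols, B, C, L, k)
  list(dX = dX, dW = dW, db = db)
}

bn_forward <- function(X, gamma, beta, run_mean, run_var, training,
                       eps = 1e-5, momentum = 0.1) {
  B <- dim(X)[1L]
  C <- dim(X)[2L]
  L <- dim(X)[3L]
  if (training) {
    mu <- apply(X, 2L, mean)
    vr <- apply(X, 2L, function(m) mean((m - mean(m))^2))
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * vr
  } else {
    mu <- run_mean
    vr <- run_var
  }
  ivar <- 1 / sqrt(vr + eps)
  xhat <- sweep(sweep(X, 2L, mu), 2L, ivar, "*")
  Y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(
    Y = Y, xhat = xhat, ivar = ivar,
    run_mean = run_mean, run_var = run_var, m = B * L
  )
}

bn_backward <- function(dY, cache, gamma) {
  m <- cache$m
  dgamma <- apply(dY * cache$xhat, 2L, sum)
  dbeta <- apply(dY, 2L, sum)
  dxhat <- sweep(dY, 2L, gamma, "*")
  sum_dx <- apply(dxhat, 2L, sum)
  sum_dxx <- apply(dxhat * cache$xhat, 2L, sum)
  t1 <- sweep(m * dxhat, 2L, sum_dx)
  t2 <- sweep(cache$xhat, 2L, sum_dxx, "*")
  dX <- sweep(t1 - t2, 2L, cache$ivar / m, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

pool_forward <- function(X) {
  B <- dim(X)[1L]
  C <- dim(X)[2L]
  L <- dim(X)[3L]
  Lo <- L %/% 2L
  a <- X[, , 2L * seq_len(Lo) - 1L, drop = FALSE]
  b <- X[, , 2L * seq_len(Lo), drop = FALSE]
  take_a <- a >= b
  Y <- ifelse(take_a, a, b)
  list(Y = Y, take_a = take_a, L = L)
}

pool_backward <- function(dY, cache) {
  B <- dim(dY)[1L]
  C <- dim(dY)[2L]
  Lo <- dim(dY)[3L]
  dX <- array(0, c(B, C, cache$L))
  dX[, , 2L * seq_len(Lo) - 1L] <- dY * cache$take_a
  dX[, , 2L * seq_len(Lo)] <- dY * !cache$take_a
  dX
}

# ---- full forward pass ---------------------------------------------------

model_forward <- function(model, X_sig, X_feat, training = FALSE) {
  cfg <- model$config
  p <- model$params
  st <- model$state
  B <- nrow(X_sig)
  caches <- list()
  A <- array(X_sig, c(B, 1L, ncol(X_sig)))
  for (i in seq_along(cfg$cnn_blocks)) {
    blk <- cfg$cnn_blocks[[i]]
    k <- blk[2L]
    caches[[paste0("in_dim", i)]] <- dim(A)
    cv <- conv_forward(A, p[[paste0("conv", i, "_W")]], p[[paste0("conv", i, "_b")]], k)
    caches[[paste0("conv", i)]] <- cv
    bn <- bn_forward(
      cv$Y, p[[paste0("bn", i, "_gamma")]], p[[paste0("bn", i, "_beta")]],
      st[[paste0("bn", i, "_mean")]], st[[paste0("bn", i, "_var")]],
      training
    )
    caches[[paste0("bn", i)]] <- bn
    if (training) {
      st[[paste0("bn", i, "_mean")]] <- bn$run_mean
      st[[paste0("bn", i, "_var")]] <- bn$run_var
    }
    R <- pmax(bn$Y, 0)
    caches[[paste0("relu", i)]] <- bn$Y > 0
    pl <- pool_forward(R)
    caches[[paste0("pool", i)]] <- pl
    A <- pl$Y
  }
  Lf <- dim(A)[3L]
  h_cnn <- apply(A, c(1L, 2L), mean) # global average pool: B x C
  caches$gap_L <- Lf
  caches$gap_dim <- dim(A)

  H <- X_feat
  for (i in seq_along(cfg$mlp_widths)) {
    Z <- sweep(H %*% p[[paste0("fc", i, "_W")]], 2L, p[[paste0("fc", i, "_b")]], "+")
    caches[[paste0("fc_in", i)]] <- H
    caches[[paste0("fc_mask", i)]] <- Z > 0
    H <- pmax(Z, 0)
  }
  h <- cbind(h_cnn, H)
  caches$h <- h
  s <- as.numeric(h %*% p$head_w)
  biases <- head_biases(p$head_theta)
  Z <- outer(s, biases, "+")
  Cmat <- sigmoid(Z)
  list(cum = Cmat, score = s, caches = caches, state = st)
}

# ---- loss and gradients --------------------------------------------------

huber_value <- function(e, delta) {
  ifelse(abs(e) <= delta, 0.5 * e^2, delta * (abs(e) - 0.5 * delta))
}

huber_grad <- function(e, delta) {
  ifelse(abs(e) <= delta, e, delta * sign(e))
}

#' Disagreement-aware loss
#'
#' The training objective: a Huber loss of the predicted mean severity
#' against the rater-panel mean, plus `lambda` times the predicted
#' distribution's variance. With `lambda = 0` it reduces to the plain
#' Huber term; with a perfect mean prediction the loss is exactly
#' `lambda * sigma2_hat`.
#'
#' @param mu_hat Predicted mean severities.
#' @param sigma2_hat Predicted distribution variances (>= 0).
#' @param target_mean Rater-panel mean ratings.
#' @param lambda Variance-penalty weight (>= 0).
#' @param delta Huber transition point (> 0).
#' @returns Per-sample loss values (same length as `mu_hat`).
#' @export
disagreement_loss <- function(mu_hat, sigma2_hat, target_mean,
                              lambda = 0.1, delta = 1) {
  if (lambda < 0) {
    rlang::abort("lambda must be >= 0", class = "kinscore_domain_error")
  }
  if (delta <= 0) {
    rlang::abort("delta must be > 0", class = "kinscore_domain_error")
  }
  huber_value(mu_hat - target_mean, delta) + lambda * sigma2_hat
}

# gradient of the mean disagreement loss w.r.t. every parameter
model_backward <- function(model, fwd, target, lambda, delta) {
  cfg <- model$config
  p <- model$params
  K <- cfg$num_classes
  Cmat <- fwd$cum
  B <- nrow(Cmat)
  w2 <- 2 * (0:(K - 2L)) + 1
  mu <- rowSums(Cmat)
  e <- mu - target
  hg <- huber_grad(e, delta)
  # dL/dc_k = huber' + lambda * ((2k+1) - 2 mu), averaged over the batch
  dC <- (matrix(hg, B, K - 1L) +
    lambda * (matrix(w2, B, K - 1L, byrow = TRUE) - 2 * mu)) / B
  dZ <- dC * Cmat * (1 - Cmat)
  ds <- rowSums(dZ)
  db <- colSums(dZ)

  grads <- list()
  theta <- p$head_theta
  dtheta <- numeric(length(theta))
  dtheta[1L] <- sum(db)
  if (length(theta) > 1L) {
    for (j in 2:length(theta)) {
      dtheta[j] <- -exp(theta[j]) * sum(db[j:length(db)])
    }
  }
  grads$head_theta <- dtheta
  h <- fwd$caches$h
  grads$head_w <- crossprod(h, matrix(ds, ncol = 1L))
  dh <- matrix(ds, ncol = 1L) %*% t(p$head_w)

  n_cnn_out <- ncol(h) - cfg$mlp_widths[length(cfg$mlp_widths)]
  d_cnn <- dh[, seq_len(n_cnn_out), drop = FALSE]
  d_mlp <- dh[, -seq_len(n_cnn_out), drop = FALSE]

  for (i in rev(seq_along(cfg$mlp_widths))) {
    d_mlp <- d_mlp * fwd$caches[[paste0("fc_mask", i)]]
    grads[[paste0("fc", i, "_W")]] <-
      crossprod(fwd$caches[[paste0("fc_in", i)]], d_mlp)
    grads[[paste0("fc", i, "_b")]] <- colSums(d_mlp)
    d_mlp <- d_mlp %*% t(p[[paste0("fc", i, "_W")]])
  }

  gd <- fwd$caches$gap_dim
  dA <- array(0, gd)
  for (l in seq_len(gd[3L])) dA[, , l] <- d_cnn / fwd$caches$gap_L
  for (i in rev(seq_along(cfg$cnn_blocks))) {
    blk <- cfg$cnn_blocks[[i]]
    k <- blk[2L]
    dR <- pool_backward(dA, fwd$caches[[paste0("pool", i)]])
    dBN <- dR * fwd$caches[[paste0("relu", i)]]
    bnb <- bn_backward(
      dBN, fwd$caches[[paste0("bn", i)]],
      p[[paste0("bn", i, "_gamma")]]
    )
    grads[[paste0("bn", i, "_gamma")]] <- bnb$dgamma
    grads[[paste0("bn", i, "_beta")]] <- bnb$dbeta
    cvb <- conv_backward(
      bnb$dX, fwd$caches[[paste0("conv", i)]],
      p[[paste0("conv", i, "_W")]], k,
      fwd$caches[[paste0("in_dim", i)]]
    )
    grads[[paste0("conv", i, "_W")]] <- cvb$dW
    grads[[paste0("conv", i, "_b")]] <- cvb$db
    dA <- cvb$dX
  }
  grads
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- g * 0
      opt$v[[nm]] <- g * 0
    }
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

# ---- data preparation ----------------------------------------------------

prepare_inputs <- function(model, data, fit_scaling = FALSE) {
  cfg <- model$config
  sig_list <- data$signal
  X <- t(vapply(sig_list, function(s) {
    v <- if (inherits(s, "kin_signal")) resample_signal(s, cfg$input_length) else as.numeric(s)
    if (length(v) != cfg$input_length) {
      v <- stats::approx(seq_along(v), v, n = cfg$input_length)$y
    }
    v
  }, numeric(cfg$input_length)))
  feat_cols <- intersect(feature_names(), names(data))
  Fm <- as.matrix(data[, feat_cols])
  if (fit_scaling) {
    model$signal_center <- mean(X, na.rm = TRUE)
    model$signal_scale <- max(stats::sd(as.numeric(X), na.rm = TRUE), 1e-8)
    model$feature_center <- apply(Fm, 2L, mean, na.rm = TRUE)
    fs <- apply(Fm, 2L, stats::sd, na.rm = TRUE)
    fs[!is.finite(fs) | fs < 1e-8] <- 1
    model$feature_scale <- fs
    model$feature_center[!is.finite(model$feature_center)] <- 0
  }
  X <- (X - model$signal_center) / model$signal_scale
  X[!is.finite(X)] <- 0
  Fm <- sweep(sweep(Fm, 2L, model$feature_center), 2L, model$feature_scale, "/")
  Fm[!is.finite(Fm)] <- 0 # unavailable cycle features enter at the mean
  list(X = X, F = Fm, model = model)
}

#' Train the dual-branch ordinal model
#'
#' Minimizes the mean [disagreement_loss()] with Adam over minibatches;
#' the regression target of each clip is its rater-panel mean. Signals
#' are resampled to the configured length and standardized, and features
#' are standardized, using training-set statistics stored in the model.
#' Deterministic given the config seed.
#'
#' @param data A tibble with a `signal` list-column ([kin_signal()] or
#'   fixed-length numeric vectors), the [feature_names()] columns, and a
#'   `target_mean` column (panel mean ratings).
#' @param config A [model_config()].
#' @returns A trained `kin_model` whose `history` tibble records the
#'   per-epoch mean training loss. Supports [generics::tidy()] /
#'   [generics::glance()] and [stats::predict()].
#' @export
train_model <- function(data, config = model_config()) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    rlang::abort("training data must be a non-empty data frame",
      class = "kinscore_empty_input_error"
    )
  }
  stopifnot("signal" %in% names(data), "target_mean" %in% names(data))
  feat_cols <- intersect(feature_names(), names(data))
  model <- build_model(config, n_features = length(feat_cols))
  prep <- prepare_inputs(model, data, fit_scaling = TRUE)
  model <- prep$model
  X <- prep$X
  Fm <- prep$F
  target <- as.numeric(data$target_mean)
  n <- nrow(X)
  opt <- list(t = 0L, m = list(), v = list())
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    n_batches <- 0L
    for (b0 in seq(1L, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      fwd <- model_forward(model, X[idx, , drop = FALSE],
        Fm[idx, , drop = FALSE],
        training = TRUE
      )
      model$state <- fwd$state
      mu <- rowSums(fwd$cum)
      w2 <- 2 * (0:(config$num_classes - 2L)) + 1
      sigma2 <- as.numeric(fwd$cum %*% w2) - mu^2
      loss <- mean(disagreement_loss(
        mu, sigma2, target[idx],
        lambda = config$lambda, delta = config$huber_delta
      ))
      if (!is.finite(loss)) {
        rlang::abort("training diverged: non-finite loss",
          class = "kinscore_divergence_error"
        )
      }
      grads <- model_backward(model, fwd, target[idx],
        lambda = config$lambda, delta = config$huber_delta
      )
      step <- adam_step(model$params, grads, opt, lr = config$lr)
      model$params <- step$params
      opt <- step$opt
      ep_loss <- ep_loss + loss
      n_batches <- n_batches + 1L
    }
    history[ep] <- ep_loss / n_batches
  }
  model$trained <- TRUE
  model$history <- tibble::tibble(epoch = seq_len(config$epochs), loss = history)
  model
}

#' Expand cumulative ordinal probabilities to a class distribution
#'
#' Converts the `K - 1` cumulative probabilities P(severity > k) into the
#' K-class distribution, its mean and its variance. Inputs that are not
#' non-increasing are monotonized by a running maximum from the right
#' (with a message), which guarantees a valid simplex.
#'
#' @param cumulative Numeric vector of `K - 1` values in `[0, 1]`.
#' @returns A list: `class_probs` (length K, sums to 1), `mu` (in
#'   `[0, K-1]`), `sigma2` (>= 0), and the monotonized `cumulative`.
#' @export
expand_distribution <- function(cumulative) {
  cumulative <- as.numeric(cumulative)
  if (anyNA(cumulative) || any(cumulative < 0 | cumulative > 1)) {
    rlang::abort("cumulative probabilities must lie in [0, 1]",
      class = "kinscore_domain_error"
    )
  }
  mono <- rev(cummax(rev(cumulative)))
  if (any(mono != cumulative)) {
    rlang::inform("cumulative probabilities were not non-increasing; monotonized")
    cumulative <- mono
  }
  K <- length(cumulative) + 1L
  probs <- c(1 - cumulative[1L], -diff(cumulative), cumulative[K - 1L])
  k <- 0:(K - 1L)
  mu <- sum(k * probs)
  sigma2 <- sum(probs * (k - mu)^2)
  list(class_probs = probs, mu = mu, sigma2 = max(sigma2, 0), cumulative = cumulative)
}

#' Predict severity distributions for new clips
#'
#' Runs the trained model in inference mode (batch-norm running
#' statistics; deterministic) and expands the cumulative logits into a
#' class distribution per clip.
#'
#' @param object A trained `kin_model`.
#' @param newdata A tibble like the `data` argument of [train_model()]
#'   (the `target_mean` column is not required).
#' @param ... Unused.
#' @returns A tibble with one row per clip: `mu_hat`, `sigma2_hat`,
#'   `pred_class`, and list-columns `cumulative`, `class_probs`.
#' @export
predict.kin_model <- function(object, newdata, ...) {
  if (!object$trained) {
    rlang::warn("predicting with an untrained model")
  }
  prep <- prepare_inputs(object, newdata, fit_scaling = FALSE)
  fwd <- model_forward(object, prep$X, prep$F, training = FALSE)
  rows <- purrr::map(seq_len(nrow(prep$X)), function(i) {
    ex <- expand_distribution(fwd$cum[i, ])
    tibble::tibble(
      mu_hat = ex$mu, sigma2_hat = ex$sigma2,
      pred_class = which.max(ex$class_probs) - 1L,
      cumulative = list(ex$cumulative), class_probs = list(ex$class_probs)
    )
  })
  dplyr::bind_rows(rows)
}

#' @exportS3Method generics::tidy
tidy.kin_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(0), loss = numeric(0)))
  }
  x$history
}

#' @exportS3Method generics::glance
glance.kin_model <- function(x, ...) {
  tibble::tibble(
    trained = x$trained,
    epochs = x$config$epochs,
    final_loss = if (is.null(x$history)) NA_real_ else utils::tail(x$history$loss, 1L),
    n_parameters = sum(vapply(x$params, length, integer(1L))),
    lambda = x$config$lambda
  )
}

#' @exportS3Method generics::tidy
tidy.kin_regression <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "complexity"),
    estimate = c(x$intercept, x$slope),
    p.value = c(NA_real_, x$p_value)
  )
}

#' @exportS3Method generics::glance
glance.kin_regression <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, p.value = x$p_value, nobs = x$n
  )
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing JSON archive holding the config,
#' the feature/signal standardization constants, and all weights, so a
#' model can be restored in a fresh session without binary files.
#'
#' @param model A `kin_model`.
#' @param path Output path (JSON).
#' @returns `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` the restored `kin_model`.
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(
    config = unclass(model$config),
    n_features = model$n_features,
    params = purrr::map(model$params, function(p) {
      list(dim = dim(p) %||% length(p), data = as.numeric(p))
    }),
    state = model$state,
    signal_center = model$signal_center, signal_scale = model$signal_scale,
    feature_center = model$feature_center, feature_scale = model$feature_scale,
    trained = model$trained,
    history = if (is.null(model$history)) NULL else as.list(model$history)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg_raw <- payload$config
  cfg <- model_config(
    num_classes = cfg_raw$num_classes, input_length = cfg_raw$input_length,
    cnn_blocks = purrr::map(
      if (is.list(cfg_raw$cnn_blocks)) cfg_raw$cnn_blocks else
        apply(cfg_raw$cnn_blocks, 1, identity, simplify = FALSE),
      as.integer
    ),
    mlp_widths = as.integer(cfg_raw$mlp_widths),
    lambda = cfg_raw$lambda, huber_delta = cfg_raw$huber_delta,
    lr = cfg_raw$lr, batch_size = cfg_raw$batch_size,
    epochs = cfg_raw$epochs, seed = cfg_raw$seed
  )
  model <- build_model(cfg, n_features = payload$n_features)
  model$params <- purrr::map(payload$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1L], p$dim[2L]) else p$data
  })
  model$state <- payload$state
  model$signal_center <- payload$signal_center
  model$signal_scale <- payload$signal_scale
  model$feature_center <- payload$feature_center
  model$feature_scale <- payload$feature_scale
  model$trained <- payload$trained
  if (!is.null(payload$history)) {
    model$history <- tibble::as_tibble(payload$history)
  }
  model
}
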