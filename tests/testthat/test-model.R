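small_config <- function(epochs = 5L, seed = 7L, ...) {
  model_config(
    input_length = 32L,
    cnn_blocks = list(c(4L, 3L, 2L), c(8L, 3L, 2L)),
    mlp_widths = c(8L, 4L),
    epochs = epochs, batch_size = 8L, seed = seed, ...
  )
}

rand_inputs <- function(model, B, seed = 1) {
  set.seed(seed)
  list(
    X = matrix(rnorm(B * model$config$input_length), B),
    F = matrix(rnorm(B * model$n_features), B)
  )
}

test_that("the forward pass emits K-1 cumulative logits with CORAL monotonicity", {
  model <- build_model(small_config(num_classes = 5L), n_features = 12L)
  inp <- rand_inputs(model, 6L)
  fwd <- kinscore:::model_forward(model, inp$X, inp$F)
  expect_equal(dim(fwd$cum), c(6L, 4L)) # K - 1 = 4 outputs per sample
  # rank consistency by construction, for every sample
  for (i in seq_len(6L)) {
    expect_true(all(diff(fwd$cum[i, ]) <= 1e-12))
  }
})

test_that("different seeds change the initialization but not the shapes", {
  m1 <- build_model(small_config(seed = 1L), 12L)
  m2 <- build_model(small_config(seed = 2L), 12L)
  expect_identical(
    lapply(m1$params, dim), lapply(m2$params, dim)
  )
  expect_false(isTRUE(all.equal(m1$params$head_w, m2$params$head_w)))
})

test_that("expand_distribution matches the explicit expectation oracle", {
  ex <- expand_distribution(c(0.9, 0.5, 0.2, 0.05))
  expect_equal(ex$class_probs, c(0.1, 0.4, 0.3, 0.15, 0.05))
  # oracle: expectation over the expanded distribution, computed directly
  expect_equal(ex$mu, sum((0:4) * c(0.1, 0.4, 0.3, 0.15, 0.05)))
  expect_equal(ex$mu, 1.65)
  expect_equal(sum(ex$class_probs), 1, tolerance = 1e-12)

  top <- expand_distribution(c(1, 1, 1, 1))
  expect_equal(top$class_probs, c(0, 0, 0, 0, 1))
  expect_equal(top$mu, 4)
  expect_equal(top$sigma2, 0)

  bottom <- expand_distribution(c(0, 0, 0, 0))
  expect_equal(bottom$mu, 0)
  expect_equal(bottom$sigma2, 0)

  expect_error(expand_distribution(c(0.5, 1.2)), class = "kinscore_domain_error")
  expect_message(out <- expand_distribution(c(0.2, 0.6, 0.1)), "monotonized")
  expect_true(all(diff(out$cumulative) <= 0))
})

test_that("expanding then re-accumulating is the identity on valid input", {
  cum <- c(0.95, 0.7, 0.3, 0.1)
  ex <- expand_distribution(cum)
  # P(y > k) = sum of class probabilities above k
  reacc <- rev(cumsum(rev(ex$class_probs)))[-1L]
  expect_equal(unname(reacc), cum, tolerance = 1e-12)
})

test_that("the disagreement loss obeys its closed-form identities", {
  expect_equal(disagreement_loss(2, 0, 2, lambda = 1), 0)
  expect_equal(disagreement_loss(2.5, 0, 2, lambda = 0, delta = 1), 0.125)
  expect_equal(disagreement_loss(2, 0.3, 2, lambda = 1), 0.3)
  # linear (not quadratic) tail beyond delta
  expect_equal(disagreement_loss(5, 0, 2, lambda = 0, delta = 1), 1 * (3 - 0.5))
  # lambda = 0 reduces to the Huber term element-by-element
  mu <- c(0.2, 1.7, 3.9)
  t <- c(1, 2, 2)
  s2 <- c(0.5, 0.1, 0.9)
  expect_equal(
    disagreement_loss(mu, s2, t, lambda = 0),
    disagreement_loss(mu, 0 * s2, t, lambda = 1)
  )
  expect_error(disagreement_loss(1, 0, 1, lambda = -1), class = "kinscore_domain_error")
})

test_that("analytic gradients agree with numerical differentiation", {
  cfg <- model_config(
    input_length = 16L, cnn_blocks = list(c(3L, 3L, 2L)),
    mlp_widths = c(4L), seed = 3L
  )
  model <- build_model(cfg, n_features = 5L)
  inp <- rand_inputs(model, 4L, seed = 5)
  target <- c(0.5, 2, 3.3, 1)

  loss_at <- function(model) {
    fwd <- kinscore:::model_forward(model, inp$X, inp$F, training = TRUE)
    mu <- rowSums(fwd$cum)
    w2 <- 2 * (0:3) + 1
    s2 <- as.numeric(fwd$cum %*% w2) - mu^2
    mean(disagreement_loss(mu, s2, target, lambda = 0.1, delta = 1))
  }
  fwd <- kinscore:::model_forward(model, inp$X, inp$F, training = TRUE)
  grads <- kinscore:::model_backward(model, fwd, target, lambda = 0.1, delta = 1)

  eps <- 1e-5
  for (nm in c("conv1_W", "bn1_gamma", "fc1_W", "head_w", "head_theta")) {
    p <- model$params[[nm]]
    idx <- sample(length(p), min(4L, length(p)))
    for (i in idx) {
      mp <- model
      mp$params[[nm]][i] <- p[i] + eps
      mm <- model
      mm$params[[nm]][i] <- p[i] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(as.numeric(grads[[nm]][i]), num, tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic under a fixed seed and reduces the loss", {
  data <- direct_training_data(24L, seed = 11)
  cfg <- small_config()
  m1 <- train_model(data, cfg)
  m2 <- train_model(data, cfg)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(m1$params, m2$params)

  data50 <- direct_training_data(50L, seed = 12)
  m <- train_model(data50, small_config(epochs = 30L))
  expect_lt(utils::tail(m$history$loss, 1L), m$history$loss[1L])
})

test_that("predictions stay in the distribution's support and are deterministic", {
  data <- direct_training_data(24L, seed = 13)
  model <- train_model(data, small_config())
  p1 <- predict(model, data)
  p2 <- predict(model, data)
  expect_identical(p1, p2)
  expect_true(all(p1$mu_hat >= 0 & p1$mu_hat <= 4))
  expect_true(all(p1$sigma2_hat >= 0 & p1$sigma2_hat <= 4))
  # CORAL monotonicity for every emitted prediction
  expect_true(all(vapply(
    p1$cumulative, function(cm) all(diff(cm) <= 1e-12), logical(1L)
  )))
})

test_that("the model recovers the severity ordering on held-out synthetic data", {
  tr <- direct_training_data(80L, seed = 14)
  te <- direct_training_data(30L, seed = 15)
  model <- train_model(tr, small_config(epochs = 40L))
  p <- predict(model, te)
  expect_gt(
    mean(p$mu_hat[te$severity == 4]), mean(p$mu_hat[te$severity == 0])
  )
  expect_gt(cor(te$severity, p$mu_hat, method = "spearman"), 0.6)
})

test_that("checkpoints round-trip the model through JSON", {
  data <- direct_training_data(16L, seed = 16)
  model <- train_model(data, small_config(epochs = 3L))
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_equal(predict(back, data), predict(model, data), tolerance = 1e-10)
})

test_that("tidy and glance expose the training history and fit summary", {
  data <- direct_training_data(16L, seed = 17)
  model <- train_model(data, small_config(epochs = 4L))
  td <- tidy(model)
  expect_identical(names(td), c("epoch", "loss"))
  expect_equal(nrow(td), 4L)
  gl <- glance(model)
  expect_true(gl$trained)
  expect_equal(gl$final_loss, utils::tail(td$loss, 1L))
})
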