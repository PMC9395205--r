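test_that("initialization is seeded, shaped, and He-scaled", {
  m1 <- skinnet_init(seed = 7)
  m2 <- skinnet_init(seed = 7)
  expect_identical(m1, m2)
  expect_false(identical(m1, skinnet_init(seed = 8)))

  dims <- lapply(m1$weights, dim)
  expect_equal(dims, list(c(10L, 64L), c(64L, 32L), c(32L, 16L),
                          c(16L, 2L)))
  expect_true(all(vapply(m1$biases, function(b) all(b == 0), logical(1))))

  v <- var(as.vector(m1$weights[[1]]))
  expect_lt(abs(v - 2 / 10) / (2 / 10), 0.2)
  expect_equal(m1$l2, c(0.001, 0.002, 0.001, 0))
})

test_that("forward pass gives symmetric softmax for zero weights", {
  m <- skinnet_init(n_inputs = 3, hidden = c(4, 3, 2), seed = 1)
  m$weights <- lapply(m$weights, function(w) w * 0)
  p <- skinnet_forward(m, matrix(rnorm(15), 5, 3))$probs
  expect_equal(p, matrix(0.5, 5, 2))

  m2 <- skinnet_init(seed = 3)
  p2 <- skinnet_forward(m2, matrix(rnorm(40), 4, 10))$probs
  expect_equal(rowSums(p2), rep(1, 4), tolerance = 1e-9)
})

test_that("a hand-computed forward pass matches", {
  # 2 inputs -> 1 hidden ReLU unit -> 2-way softmax, all weights set by hand
  m <- skinnet_init(n_inputs = 2, hidden = 1, l2 = 0, dropout_rate = 0,
                    seed = 1)
  m$weights[[1]] <- matrix(c(0.5, -1), 2, 1)
  m$biases[[1]] <- 0.2
  m$weights[[2]] <- matrix(c(1.5, -0.5), 1, 2)
  m$biases[[2]] <- c(0.1, -0.1)
  x <- matrix(c(2, 0.5), 1, 2)
  h <- max(0, 2 * 0.5 + 0.5 * (-1) + 0.2)        # 0.7
  z <- c(h * 1.5 + 0.1, h * (-0.5) - 0.1)
  expect_equal(skinnet_forward(m, x)$probs[1, ],
               exp(z) / sum(exp(z)), tolerance = 1e-12)
})

test_that("the loss is cross-entropy plus the L2 penalty", {
  m <- skinnet_init(n_inputs = 4, hidden = c(3, 3, 3), seed = 5)
  zero <- m
  zero$weights <- lapply(zero$weights, function(w) w * 0)
  y <- factor(c("benign", "malignant", "benign"))
  p <- skinnet_forward(zero, matrix(rnorm(12), 3, 4))$probs
  expect_equal(skinnet_loss(p, y, zero), log(2), tolerance = 1e-12)

  perfect <- matrix(c(1, 0, 0, 1, 1, 0), 3, 2, byrow = TRUE)
  reg <- sum(vapply(seq_along(m$weights), function(l) {
    m$l2[l] * sum(m$weights[[l]]^2)
  }, numeric(1)))
  expect_equal(skinnet_loss(perfect, y, m), reg, tolerance = 1e-9)
})

test_that("optimizer first steps match their one-step algebra", {
  th <- c(1, -2, 0.5)
  g <- c(0.3, -0.1, 0)
  lr <- 0.01

  sg <- optimizer_step(optimizer_init("sgd", list(th)), list(th), list(g), lr)
  expect_equal(sg$params[[1]], th - lr * g)

  ax <- optimizer_step(optimizer_init("adamax", list(th)), list(th),
                       list(g), lr)
  expect_equal(ax$params[[1]], th - lr * sign(g), tolerance = 1e-6)

  ad <- optimizer_step(optimizer_init("adam", list(th)), list(th),
                       list(g), lr)
  expect_equal(ad$params[[1]][1:2], (th - lr * sign(g))[1:2],
               tolerance = 1e-5)
  expect_equal(ad$params[[1]][3], th[3])  # zero gradient leaves it in place
})

test_that("every optimizer collapses a quadratic to below 1e-3 of start", {
  for (opt in c("sgd", "rmsprop", "adam", "adamax", "nadam")) {
    th <- list(1)
    st <- optimizer_init(opt, th)
    for (i in 1:500) {
      upd <- optimizer_step(st, th, list(2 * th[[1]]), 0.006)
      th <- upd$params; st <- upd$state
    }
    expect_lt(th[[1]]^2, 1e-3, label = paste0(opt, " final loss"))
  }
})

test_that("backpropagation matches central finite differences", {
  worst <- 0
  for (s in 1:3) {
    set.seed(s)
    m <- skinnet_init(n_inputs = 4, hidden = c(5, 4, 3), dropout_rate = 0,
                      seed = s)
    # nonzero biases keep every pre-activation away from the ReLU kink,
    # where central differences are undefined
    m$biases <- lapply(m$biases, function(b) rnorm(length(b), sd = 0.3))
    x <- matrix(rnorm(8 * 4), 8, 4)
    y <- factor(sample(c("benign", "malignant"), 8, replace = TRUE))
    fw <- skinnet_forward(m, x, training = TRUE)
    got <- lesionpipe:::skinnet_backward(m, fw$cache, y)
    num <- fd_gradients(m, x, y)
    for (l in seq_along(got$weights)) {
      denom <- pmax(abs(num$weights[[l]]), 1e-4)
      worst <- max(worst, max(abs(got$weights[[l]] - num$weights[[l]]) /
                                denom))
      denomb <- pmax(abs(num$biases[[l]]), 1e-4)
      worst <- max(worst, max(abs(got$biases[[l]] - num$biases[[l]]) /
                                denomb))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("training separates two Gaussian clusters with every optimizer", {
  spec <- feature_table_spec(n_per_class = 200,
                             class_means = list(rep(0.25, 20),
                                                rep(0.75, 20)),
                             covariance = diag(20) * 0.01, seed = 6)
  tab <- generate_feature_table(spec)[c(lesion_feature_names()[1:10],
                                        "prediction")]
  for (opt in c("sgd", "rmsprop", "adam", "adamax", "nadam")) {
    cfg <- train_config(optimizer = opt, learning_rate = 0.006,
                        epochs = 100, seed = 11)
    fit <- skinnet_train(skinnet_init(seed = 11), tab, cfg)
    expect_gte(fit$history$val_acc[100], 0.95,
               label = paste0(opt, " validation accuracy"))
  }
})

test_that("full-batch SGD at a tiny rate decreases the loss monotonically", {
  spec <- feature_table_spec(n_per_class = 60,
                             class_means = list(rep(0.3, 20), rep(0.7, 20)),
                             covariance = diag(20) * 0.04, seed = 4)
  tab <- generate_feature_table(spec)[c(lesion_feature_names()[1:10],
                                        "prediction")]
  cfg <- train_config(optimizer = "sgd", learning_rate = 1e-4, epochs = 60,
                      batch_size = 120, val_fraction = 0, seed = 2)
  m <- skinnet_init(dropout_rate = 0, seed = 2)
  fit <- skinnet_train(m, tab, cfg)
  expect_lte(sum(diff(fit$history$train_loss) > 0), 2)
})

test_that("training is bit-reproducible for a fixed seed", {
  spec <- feature_table_spec(n_per_class = 40, seed = 9)
  tab <- generate_feature_table(spec)[c(lesion_feature_names()[1:10],
                                        "prediction")]
  cfg <- train_config(optimizer = "adamax", learning_rate = 0.006,
                      epochs = 5, seed = 3)
  f1 <- skinnet_train(skinnet_init(seed = 3), tab, cfg)
  f2 <- skinnet_train(skinnet_init(seed = 3), tab, cfg)
  expect_identical(f1$model$weights, f2$model$weights)
  expect_identical(f1$history, f2$history)

  pred <- skinnet_predict(f1$model, tab)
  expect_equal(dim(pred$probs), c(80L, 2L))
  expect_true(all(pred$class %in% c("benign", "malignant")))
})
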