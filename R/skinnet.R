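# A compact dense two-class network (default hidden widths 64/32/16, ReLU
# hidden activations, two-unit softmax output) with per-layer L2 weight
# penalties and dropout, trained by mini-batch gradient descent under one of
# five hand-rolled optimizers. All array math is plain R; gradients are exact
# backpropagation (verified against finite differences in the test suite).

relu <- function(z) { z[z < 0] <- 0; z }

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Initialize the dense lesion classifier
#'
#' Weights are drawn from scaled symmetric normals (He initialization,
#' `sd = sqrt(2 / fan_in)`, suited to ReLU layers), biases start at zero.
#' The default L2 coefficients (0.001, 0.002, 0.001) apply to the three hidden
#' layers; the output layer is unpenalized.
#'
#' @param n_inputs Number of input features (default 10).
#' @param hidden Hidden layer widths (default `c(64, 32, 16)`).
#' @param l2 L2 penalty per layer, recycled/padded to one value per weight
#'   matrix (hidden layers then output).
#' @param dropout_rate Dropout probability for hidden activations during
#'   training (default 0.2).
#' @param seed Integer RNG seed; the same seed gives identical weights.
#' @return An object of class `skinnet_model`.
#' @export
skinnet_init <- function(n_inputs = 10, hidden = c(64, 32, 16),
                         l2 = c(0.001, 0.002, 0.001), dropout_rate = 0.2,
                         seed = 1L) {
  sizes <- c(n_inputs, hidden, 2L)
  n_layers <- length(sizes) - 1L
  l2 <- c(l2, rep(0, n_layers))[seq_len(n_layers)]
  if (any(l2 < 0)) stop("l2 coefficients must be >= 0", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    weights <- vector("list", n_layers)
    biases <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      fan_in <- sizes[l]
      weights[[l]] <- matrix(rnorm(fan_in * sizes[l + 1],
                                   sd = sqrt(2 / fan_in)),
                             fan_in, sizes[l + 1])
      biases[[l]] <- numeric(sizes[l + 1])
    }
    structure(list(weights = weights, biases = biases, sizes = sizes,
                   l2 = l2, dropout_rate = dropout_rate,
                   classes = c("benign", "malignant")),
              class = "skinnet_model")
  })
}

#' Forward pass of the classifier
#'
#' ReLU hidden layers, two-unit softmax output; each probability row sums to
#' one. Dropout (inverted scaling) is applied to hidden activations only when
#' `training = TRUE`, using the current RNG stream.
#'
#' @param model A [skinnet_init()] model.
#' @param x Numeric matrix of inputs (rows = samples).
#' @param training Apply dropout (default `FALSE`).
#' @return A list with `probs` (n x 2 matrix) and `cache` (intermediate
#'   activations for backpropagation).
#' @export
skinnet_forward <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "skinnet_model"))
  x <- as.matrix(x)
  n_layers <- length(model$weights)
  a <- list(x)
  zs <- vector("list", n_layers)
  masks <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    z <- a[[l]] %*% model$weights[[l]] +
      matrix(model$biases[[l]], nrow(x), length(model$biases[[l]]),
             byrow = TRUE)
    zs[[l]] <- z
    if (l < n_layers) {
      h <- relu(z)
      if (training && model$dropout_rate > 0) {
        keep <- 1 - model$dropout_rate
        m <- matrix(runif(length(h)) < keep, nrow(h), ncol(h)) / keep
        h <- h * m
        masks[[l]] <- m
      }
      a[[l + 1]] <- h
    } else {
      a[[l + 1]] <- softmax_rows(z)
    }
  }
  list(probs = a[[n_layers + 1]],
       cache = list(a = a, z = zs, masks = masks))
}

# encode labels (factor/character/0-1) as an indicator matrix over
# model$classes
label_onehot <- function(model, y) {
  if (is.numeric(y)) {
    idx <- as.integer(y) + 1L
  } else {
    idx <- match(as.character(y), model$classes)
    if (anyNA(idx)) stop("labels must be among: ",
                         paste(model$classes, collapse = ", "), call. = FALSE)
  }
  out <- matrix(0, length(idx), 2)
  out[cbind(seq_along(idx), idx)] <- 1
  out
}

#' Training loss: cross-entropy plus L2 penalty
#'
#' Mean categorical cross-entropy of the predicted probabilities plus
#' `sum_l l2_l * ||W_l||^2` over the weight matrices.
#'
#' @param probs n x 2 probability matrix from [skinnet_forward()].
#' @param y Labels (factor/character over the model classes, or 0/1).
#' @param model The model (for the L2 coefficients and weights).
#' @return Scalar loss.
#' @export
skinnet_loss <- function(probs, y, model) {
  yh <- label_onehot(model, y)
  ce <- -mean(log(pmax(rowSums(probs * yh), 1e-300)))
  reg <- sum(vapply(seq_along(model$weights), function(l) {
    model$l2[l] * sum(model$weights[[l]]^2)
  }, numeric(1)))
  ce + reg
}

# exact gradients of skinnet_loss via backpropagation, reusing the forward
# cache (dropout masks included)
skinnet_backward <- function(model, cache, y) {
  n_layers <- length(model$weights)
  a <- cache$a; zs <- cache$z; masks <- cache$masks
  n <- nrow(a[[1]])
  yh <- label_onehot(model, y)
  dz <- (a[[n_layers + 1]] - yh) / n
  gw <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  for (l in rev(seq_len(n_layers))) {
    gw[[l]] <- crossprod(a[[l]], dz) + 2 * model$l2[l] * model$weights[[l]]
    gb[[l]] <- colSums(dz)
    if (l > 1) {
      da <- dz %*% t(model$weights[[l]])
      if (!is.null(masks[[l - 1]])) da <- da * masks[[l - 1]]
      dz <- da * (zs[[l - 1]] > 0)
    }
  }
  list(weights = gw, biases = gb)
}

#' Create an optimizer state
#'
#' Supports the five standard first-order update rules: plain stochastic
#' gradient descent (`sgd`), RMSprop, Adam, Adamax (the infinity-norm Adam
#' variant), and Nadam (Adam with a Nesterov momentum term). Moment
#' accumulators are shaped like the parameters and start at zero.
#'
#' @param name One of `"sgd"`, `"rmsprop"`, `"adam"`, `"adamax"`, `"nadam"`.
#' @param params List of numeric arrays (the trainable parameters).
#' @param beta1,beta2 Exponential decay rates for the first/second moments
#'   (defaults 0.9 and 0.999; `beta2` doubles as RMSprop's decay 0.9).
#' @param epsilon Numerical stabilizer (default 1e-8).
#' @return An object of class `optimizer_state`.
#' @export
optimizer_init <- function(name = c("sgd", "rmsprop", "adam", "adamax",
                                    "nadam"),
                           params, beta1 = 0.9, beta2 = 0.999,
                           epsilon = 1e-8) {
  name <- match.arg(name)
  zeros <- lapply(params, function(p) p * 0)  # accumulators shaped like p
  structure(list(name = name, t = 0L, m = zeros, v = zeros, u = zeros,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon),
            class = "optimizer_state")
}

#' Apply one optimizer update
#'
#' Standard published update rules; see [optimizer_init()] for the supported
#' optimizers and hyperparameters.
#'
#' @param state An [optimizer_init()] state.
#' @param params List of parameter arrays.
#' @param grads List of gradient arrays, same shapes.
#' @param learning_rate Positive step size.
#' @return A list with updated `params` and `state`.
#' @export
optimizer_step <- function(state, params, grads, learning_rate) {
  stopifnot(inherits(state, "optimizer_state"))
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2; eps <- state$epsilon
  t <- state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    params[[i]] <- switch(
      state$name,
      sgd = params[[i]] - learning_rate * g,
      rmsprop = {
        state$v[[i]] <- 0.9 * state$v[[i]] + 0.1 * g^2
        params[[i]] - learning_rate * g / (sqrt(state$v[[i]]) + eps)
      },
      adam = {
        state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * g
        state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * g^2
        mhat <- state$m[[i]] / (1 - b1^t)
        vhat <- state$v[[i]] / (1 - b2^t)
        params[[i]] - learning_rate * mhat / (sqrt(vhat) + eps)
      },
      adamax = {
        state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * g
        state$u[[i]] <- pmax(b2 * state$u[[i]], abs(g))
        params[[i]] - learning_rate * state$m[[i]] /
          ((1 - b1^t) * (state$u[[i]] + eps))
      },
      nadam = {
        state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * g
        state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * g^2
        mhat <- state$m[[i]] / (1 - b1^t)
        vhat <- state$v[[i]] / (1 - b2^t)
        params[[i]] - learning_rate * (b1 * mhat + (1 - b1) * g / (1 - b1^t)) /
          (sqrt(vhat) + eps)
      })
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' @param optimizer One of the five supported optimizers.
#' @param learning_rate Positive step size (the evaluation grid uses 0.001 and
#'   0.006).
#' @param epochs Number of passes over the training data (default 150).
#' @param batch_size Mini-batch size (default 32).
#' @param val_fraction Fraction of the training rows held out for per-epoch
#'   validation (default 0.1).
#' @param seed Integer RNG seed controlling shuffling, dropout, and the
#'   validation split.
#' @return An object of class `train_config`.
#' @export
train_config <- function(optimizer = "adamax", learning_rate = 0.006,
                         epochs = 150, batch_size = 32, val_fraction = 0.1,
                         seed = 1L) {
  optimizer <- match.arg(optimizer,
                         c("sgd", "rmsprop", "adam", "adamax", "nadam"))
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

# flatten model parameters to a list and back (weights then biases)
model_params <- function(model) c(model$weights, model$biases)
set_model_params <- function(model, params) {
  k <- length(model$weights)
  model$weights <- params[seq_len(k)]
  model$biases <- params[k + seq_len(k)]
  model
}

#' Train the classifier
#'
#' Mini-batch training with a stratified validation holdout and per-epoch
#' train/validation loss and accuracy history. Fully deterministic for a fixed
#' config seed. Aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param model A [skinnet_init()] model.
#' @param table Data frame of scaled input columns plus a label column.
#' @param config A [train_config()].
#' @param label_col Name of the label column (default `"prediction"`).
#' @return A list with the trained `model` and the `history` data frame.
#' @export
skinnet_train <- function(model, table, config = train_config(),
                          label_col = "prediction") {
  stopifnot(inherits(model, "skinnet_model"),
            inherits(config, "train_config"))
  y_all <- table[[label_col]]
  if (is.null(y_all)) stop("label column `", label_col, "` not found",
                           call. = FALSE)
  x_all <- as.matrix(table[setdiff(names(table), label_col)])
  if (ncol(x_all) != model$sizes[1]) {
    stop("model expects ", model$sizes[1], " input columns, got ",
         ncol(x_all), call. = FALSE)
  }
  classes <- sort(unique(as.character(y_all)))
  if (length(classes) > 2) stop("binary classification only", call. = FALSE)
  model$classes <- if (length(classes) == 2) classes else model$classes

  with_seed(config$seed, {
    # stratified validation holdout
    val_idx <- integer(0)
    if (config$val_fraction > 0) {
      for (cl in classes) {
        rows <- which(as.character(y_all) == cl)
        n_val <- floor(length(rows) * config$val_fraction)
        if (n_val > 0) val_idx <- c(val_idx, sample(rows, n_val))
      }
    }
    tr_idx <- setdiff(seq_len(nrow(x_all)), val_idx)
    xt <- x_all[tr_idx, , drop = FALSE]; yt <- y_all[tr_idx]
    xv <- x_all[val_idx, , drop = FALSE]; yv <- y_all[val_idx]

    state <- optimizer_init(config$optimizer, model_params(model))
    history <- vector("list", config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(nrow(xt))
      for (start in seq(1, nrow(xt), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, nrow(xt))]
        fw <- skinnet_forward(model, xt[idx, , drop = FALSE],
                              training = TRUE)
        gr <- skinnet_backward(model, fw$cache, yt[idx])
        upd <- optimizer_step(state, model_params(model),
                              c(gr$weights, gr$biases),
                              config$learning_rate)
        model <- set_model_params(model, upd$params)
        state <- upd$state
      }
      ft <- skinnet_forward(model, xt)
      tl <- skinnet_loss(ft$probs, yt, model)
      ta <- mean(model$classes[max.col(ft$probs)] == as.character(yt))
      if (!is.finite(tl)) {
        stop("non-finite training loss at epoch ", ep,
             " (optimizer ", config$optimizer, ", lr ",
             config$learning_rate, ")", call. = FALSE)
      }
      if (length(val_idx) > 0) {
        fv <- skinnet_forward(model, xv)
        vl <- skinnet_loss(fv$probs, yv, model)
        va <- mean(model$classes[max.col(fv$probs)] == as.character(yv))
      } else {
        vl <- NA_real_; va <- NA_real_
      }
      history[[ep]] <- data.frame(epoch = ep, train_loss = tl,
                                  train_acc = ta, val_loss = vl,
                                  val_acc = va)
    }
    list(model = model, history = do.call(rbind, history))
  })
}

#' Predict class probabilities and labels
#'
#' @param model A trained [skinnet_init()] model.
#' @param table Data frame or matrix of input features (a label column, if
#'   present, is ignored).
#' @param label_col Label column name to drop (default `"prediction"`).
#' @return A list with `probs` (n x 2 matrix, columns named by class) and
#'   `class` (character vector of argmax labels).
#' @export
skinnet_predict <- function(model, table, label_col = "prediction") {
  if (is.data.frame(table)) {
    table <- table[setdiff(names(table), label_col)]
  }
  probs <- skinnet_forward(model, as.matrix(table))$probs
  colnames(probs) <- model$classes
  list(probs = probs, class = model$classes[max.col(probs)])
}
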