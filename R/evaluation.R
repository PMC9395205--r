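# Class balancing, stratified splitting, and the nine-metric evaluation report
# (accuracy, sensitivity, specificity, FPR, FNR, FDR, MSE, RMSE, log-loss, all
# as percentages) produced per optimizer x learning-rate combination.

#' Near-miss class balancing by random elimination
#'
#' Randomly removes rows from the majority class until both classes have the
#' minority count; minority rows are all retained. (This follows the
#' random-elimination description of the balancing step; a distance-based
#' variant in the style of NearMiss-1, keeping the majority rows closest in
#' feature space to the minority class, is available via `variant`.)
#'
#' @param table Data frame with a two-class label column.
#' @param seed Integer RNG seed.
#' @param label_col Label column name (default `"prediction"`).
#' @param variant `"random"` (default) or `"distance"`.
#' @return The balanced data frame (row order preserved).
#' @export
near_miss_balance <- function(table, seed = 1L, label_col = "prediction",
                              variant = c("random", "distance")) {
  variant <- match.arg(variant)
  y <- as.character(table[[label_col]])
  counts <- table(y)
  if (length(counts) != 2) {
    stop("exactly two classes are required for balancing", call. = FALSE)
  }
  minority <- names(counts)[which.min(counts)]
  majority <- names(counts)[which.max(counts)]
  if (counts[minority] == counts[majority]) return(table)
  maj_rows <- which(y == majority)
  n_keep <- as.integer(counts[minority])
  keep <- if (variant == "random") {
    with_seed(seed, sample(maj_rows, n_keep))
  } else {
    num <- vapply(table, is.numeric, logical(1))
    x <- as.matrix(table[num])
    min_x <- x[y == minority, , drop = FALSE]
    # mean distance to the 3 nearest minority rows, NearMiss-1 style
    d <- vapply(maj_rows, function(i) {
      dd <- sqrt(colSums((t(min_x) - x[i, ])^2))
      mean(sort(dd)[seq_len(min(3, length(dd)))])
    }, numeric(1))
    maj_rows[order(d)[seq_len(n_keep)]]
  }
  out <- table[sort(c(which(y == minority), keep)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified train/validation/test split
#'
#' Per class, `floor(train_frac * n)` rows go to the training pool, the rest
#' to the test set; `floor(val_frac_of_train * n_train)` of the training pool
#' is then held out for validation. The three index sets are disjoint and
#' exhaust the rows.
#'
#' @param table Data frame with a label column.
#' @param train_frac Training fraction per class (default 0.8).
#' @param val_frac_of_train Fraction of the training pool used for validation
#'   (default 0.1).
#' @param seed Integer RNG seed.
#' @param label_col Label column name (default `"prediction"`).
#' @return A list of integer row indices `train`, `validation`, `test`, plus
#'   the `seed`.
#' @export
split_dataset <- function(table, train_frac = 0.8, val_frac_of_train = 0.1,
                          seed = 1L, label_col = "prediction") {
  y <- as.character(table[[label_col]])
  with_seed(seed, {
    train <- integer(0); val <- integer(0); test <- integer(0)
    for (cl in sort(unique(y))) {
      rows <- which(y == cl)
      n_train <- floor(length(rows) * train_frac)
      tr <- sort(sample(rows, n_train))
      te <- setdiff(rows, tr)
      n_val <- floor(length(tr) * val_frac_of_train)
      va <- if (n_val > 0) sort(sample(tr, n_val)) else integer(0)
      train <- c(train, setdiff(tr, va))
      val <- c(val, va)
      test <- c(test, te)
    }
    list(train = sort(train), validation = sort(val), test = sort(test),
         seed = seed)
  })
}

#' Confusion-matrix rates as percentages
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, the
#' false-positive, false-negative, and false-discovery rates, accuracy,
#' MSE (the misclassified fraction of hard 0/1 predictions, so that
#' MSE = 100 - accuracy), and `RMSE = 100 * sqrt(MSE / 100)`, all scaled to
#' percent. Zero-denominator rates are reported as 0 with a warning. The
#' complements `SEN + FNR = 100` and `SPE + FPR = 100` hold exactly.
#'
#' @param truth,predicted Label vectors of equal length.
#' @param positive_class The class counted as positive.
#' @return Named numeric vector: `t_acc`, `sensitivity`, `specificity`,
#'   `fpr`, `fnr`, `fdr`, `mse`, `rmse`.
#' @export
confusion_metrics <- function(truth, predicted, positive_class) {
  if (length(truth) == 0) stop("empty input", call. = FALSE)
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` lengths differ", call. = FALSE)
  }
  truth <- as.character(truth); predicted <- as.character(predicted)
  pos_t <- truth == positive_class
  pos_p <- predicted == positive_class
  tp <- sum(pos_t & pos_p); fn <- sum(pos_t & !pos_p)
  fp <- sum(!pos_t & pos_p); tn <- sum(!pos_t & !pos_p)
  rate <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; reporting 0", call. = FALSE)
      return(0)
    }
    100 * num / den
  }
  sen <- rate(tp, tp + fn, "sensitivity")
  spe <- rate(tn, tn + fp, "specificity")
  fpr <- if (tn + fp == 0) 0 else 100 - spe
  fnr <- if (tp + fn == 0) 0 else 100 - sen
  fdr <- rate(fp, fp + tp, "FDR")
  acc <- 100 * (tp + tn) / length(truth)
  mse <- 100 - acc
  c(t_acc = acc, sensitivity = sen, specificity = spe, fpr = fpr, fnr = fnr,
    fdr = fdr, mse = mse, rmse = 100 * sqrt(mse / 100))
}

#' Logarithmic loss as a percentage
#'
#' Mean negative log of the probability assigned to the true class, with
#' probabilities clipped to `[epsilon, 1 - epsilon]`, scaled by 100. For hard
#' 0/1 predictions each error contributes `-log(epsilon)` nats, so the loss
#' equals `error_fraction * (-log(epsilon)) * 100`.
#'
#' @param truth Label vector.
#' @param probs n x k probability matrix with columns named by class, or a
#'   vector of probabilities of the true class.
#' @param epsilon Clipping bound (default 1e-15).
#' @return Log-loss percentage.
#' @export
log_loss <- function(truth, probs, epsilon = 1e-15) {
  truth <- as.character(truth)
  p_true <- if (is.matrix(probs)) {
    if (is.null(colnames(probs))) {
      stop("probability matrix must have class column names", call. = FALSE)
    }
    probs[cbind(seq_along(truth), match(truth, colnames(probs)))]
  } else {
    probs
  }
  p_true <- pmin(pmax(p_true, epsilon), 1 - epsilon)
  100 * mean(-log(p_true))
}

#' Evaluate the classifier across the optimizer grid
#'
#' Trains one model per optimizer x learning-rate combination on the training
#' rows, evaluates on the test rows, and emits one report row per combination
#' with the column layout `Optimizer, LR, CT, V_Loss, V_Acc, T_Acc, SEN, SPE,
#' FPR, FNR, FDR, MSE, RMSE, LL` (CT is wall-clock training time in seconds,
#' informational only).
#'
#' @param table Feature table (scaled inputs + label column).
#' @param split A [split_dataset()] result.
#' @param positive_class Class counted as positive (default `"benign"`).
#' @param optimizers Optimizers to run (default all five).
#' @param learning_rates Learning rates to run (default `c(0.001, 0.006)`).
#' @param epochs,batch_size,seed Training settings passed to
#'   [train_config()].
#' @param label_col Label column name.
#' @return A data frame with one row per combination.
#' @export
evaluate_run <- function(table, split, positive_class = "benign",
                         optimizers = c("rmsprop", "adam", "sgd", "adamax",
                                        "nadam"),
                         learning_rates = c(0.001, 0.006),
                         epochs = 150, batch_size = 32, seed = 1L,
                         label_col = "prediction") {
  train_tab <- table[c(split$train, split$validation), , drop = FALSE]
  test_tab <- table[split$test, , drop = FALSE]
  n_inputs <- sum(vapply(table, is.numeric, logical(1))) -
    (!is.null(table[[label_col]]) && is.numeric(table[[label_col]]))
  rows <- list()
  for (opt in optimizers) {
    for (lr in learning_rates) {
      cfg <- train_config(optimizer = opt, learning_rate = lr,
                          epochs = epochs, batch_size = batch_size,
                          seed = seed)
      model <- skinnet_init(n_inputs = n_inputs, seed = seed)
      t0 <- proc.time()[["elapsed"]]
      fit <- skinnet_train(model, train_tab, cfg, label_col = label_col)
      ct <- proc.time()[["elapsed"]] - t0
      last <- fit$history[nrow(fit$history), ]
      pred <- skinnet_predict(fit$model, test_tab, label_col = label_col)
      cm <- confusion_metrics(test_tab[[label_col]], pred$class,
                              positive_class)
      ll <- log_loss(test_tab[[label_col]], pred$probs)
      rows[[length(rows) + 1]] <- data.frame(
        Optimizer = opt, LR = lr, CT = ct,
        V_Loss = 100 * last$val_loss, V_Acc = 100 * last$val_acc,
        T_Acc = cm[["t_acc"]], SEN = cm[["sensitivity"]],
        SPE = cm[["specificity"]], FPR = cm[["fpr"]], FNR = cm[["fnr"]],
        FDR = cm[["fdr"]], MSE = cm[["mse"]], RMSE = cm[["rmse"]], LL = ll)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
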