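# label convention, asserted in one place: the positive class is
# artifact-free, artifactual records are the negative class
label_to_y <- function(label) {
  if (any(label == "UNLABELED")) stop("cannot train/evaluate on UNLABELED records")
  as.numeric(label == "ARTIFACT_FREE")
}

#' Training configuration for the 1D CNN
#'
#' Defaults follow the usual protocol for this fixture: Glorot-uniform
#' initialized convolutions with 80-tap kernels, binary cross-entropy loss,
#' Adam at learning rate 1e-4, 50 epochs, and selection of the epoch with the
#' best validation accuracy (ties broken by the earliest epoch).
#'
#' @param kernel_size Convolution kernel length used when a model is built
#'   from this config.
#' @param learning_rate Adam step size.
#' @param epochs Number of training epochs (>= 1).
#' @param batch_size Minibatch size.
#' @param seed Seed for shuffling and any derived randomness.
#' @return A list of class `train_config`.
#' @export
train_config <- function(kernel_size = 80, learning_rate = 1e-4, epochs = 50,
                         batch_size = 16, seed = 1) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  structure(list(kernel_size = kernel_size, learning_rate = learning_rate,
                 epochs = epochs, batch_size = batch_size, seed = seed,
                 init = "glorot_uniform", loss = "binary_cross_entropy",
                 optimizer = "adam", selection = "best_val_accuracy"),
            class = "train_config")
}

#' Train the CNN with Adam on binary cross-entropy
#'
#' Runs minibatch Adam for `config$epochs` epochs, computes validation
#' accuracy (threshold 0.5) after every epoch, and returns the parameters
#' from the epoch with the highest validation accuracy (earliest epoch on
#' ties). The per-epoch history is attached to the returned model.
#'
#' @param model A `cnn1d` from [build_cnn1d()].
#' @param train,val Label-diverse [ppg_dataset()]s.
#' @param config A [train_config()].
#' @return The trained `cnn1d`, with a `history` data.frame
#'   (`epoch`, `train_loss`, `val_accuracy`).
#' @export
train_cnn1d <- function(model, train, val, config = train_config()) {
  ytr <- label_to_y(train$label)
  yva <- label_to_y(val$label)
  if (length(unique(ytr)) < 2L) stop("training set must contain both classes")
  if (length(ytr) == 0 || length(yva) == 0) stop("empty training or validation set")
  template <- model$params
  theta <- params_flatten(template)
  m_adam <- v_adam <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  best <- list(acc = -Inf, theta = theta, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_accuracy = numeric())
  orders <- with_seed(config$seed,
                      lapply(seq_len(config$epochs),
                             function(e) sample(length(ytr))))
  for (epoch in seq_len(config$epochs)) {
    ord <- orders[[epoch]]
    epoch_loss <- 0
    for (start in seq(1, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      gsum <- NULL
      for (i in idx) {
        fw <- cnn_forward(model, train$x[i, ], cache = TRUE)
        pr <- min(max(fw$prob, 1e-12), 1 - 1e-12)
        epoch_loss <- epoch_loss - (ytr[i] * log(pr) + (1 - ytr[i]) * log(1 - pr))
        g <- params_flatten(cnn_backward_params(model, fw, fw$prob - ytr[i]))
        gsum <- if (is.null(gsum)) g else gsum + g
      }
      gbar <- gsum / length(idx)
      step <- step + 1L
      m_adam <- b1 * m_adam + (1 - b1) * gbar
      v_adam <- b2 * v_adam + (1 - b2) * gbar^2
      mhat <- m_adam / (1 - b1^step)
      vhat <- v_adam / (1 - b2^step)
      theta <- theta - config$learning_rate * mhat / (sqrt(vhat) + eps)
      model$params <- params_unflatten(theta, template)
    }
    pv <- predict(model, val)
    acc <- mean((pv >= 0.5) == (yva == 1))
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = epoch_loss / length(ytr),
                                   val_accuracy = acc))
    if (acc > best$acc) best <- list(acc = acc, theta = theta, epoch = epoch)
  }
  model$params <- params_unflatten(best$theta, template)
  model$history <- hist
  model$best_epoch <- best$epoch
  model
}

#' Evaluate a classifier on a labeled test set
#'
#' Binarizes the predicted artifact-free probability at `threshold` and
#' reports sensitivity (recall of artifact-free records), specificity
#' (recall of artifactual records), accuracy, and negative predictive value
#' (precision on the artifactual/negative side). A rate whose denominator is
#' zero is reported as `NA` (undefined), never as 0.
#'
#' @param model A `cnn1d` (or any object with a [predict()] method returning
#'   artifact-free probabilities).
#' @param test A label-diverse [ppg_dataset()].
#' @param threshold Probability cutoff (default 0.5).
#' @return An object of class `performance_report`.
#' @export
evaluate_model <- function(model, test, threshold = 0.5) {
  y <- label_to_y(test$label)
  p <- predict(model, test)
  pred <- as.numeric(p >= threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(sensitivity = rate(tp, tp + fn),
                 specificity = rate(tn, tn + fp),
                 accuracy = rate(tp + tn, tp + tn + fp + fn),
                 npv = rate(tn, tn + fn),
                 threshold = threshold,
                 confusion = c(tp = tp, fn = fn, tn = tn, fp = fp)),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report at threshold %.2f>\n", x$threshold))
  cat(sprintf("  sensitivity %.4f | specificity %.4f | accuracy %.4f | NPV %.4f\n",
              x$sensitivity, x$specificity, x$accuracy, x$npv))
  cat(sprintf("  confusion: TP=%d FN=%d TN=%d FP=%d (positive = artifact-free)\n",
              x$confusion["tp"], x$confusion["fn"], x$confusion["tn"],
              x$confusion["fp"]))
  invisible(x)
}

#' Split a dataset into train/validation parts, stratified by label
#'
#' @param dataset A [ppg_dataset()].
#' @param val_fraction Fraction of each class held out for validation.
#' @param seed Integer seed.
#' @return List with `train` and `val` datasets.
#' @export
split_dataset <- function(dataset, val_fraction = 0.2, seed = 1) {
  idx_val <- with_seed(seed, {
    unlist(lapply(unique(dataset$label), function(l) {
      ii <- which(dataset$label == l)
      ii[sample.int(length(ii), max(1L, round(length(ii) * val_fraction)))]
    }))
  })
  list(train = dataset[setdiff(seq_len(length(dataset)), idx_val)],
       val = dataset[sort(idx_val)])
}
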