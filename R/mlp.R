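#' Configuration of the age-prediction multilayer perceptron
#'
#' Defaults are the standard recipe for capacity-based age prediction: four
#' ReLU hidden layers (256, 512, 512, 256 units), 10% dropout between hidden
#' layers, Adam with learning rate 5e-4, batch size 64, 100 epochs, the
#' epoch checkpoint with the lowest validation loss, an 80/10/10
#' train/validation/test split per fold, 10 folds, and min-max feature
#' scaling fit on the training set only. Loss is mean absolute error for
#' regression (linear output) and binary cross-entropy for classification
#' (sigmoid output).
#'
#' @param hidden_sizes integer vector of hidden-layer widths
#' @param dropout_rate dropout probability in \[0, 1)
#' @param task `"regression"` or `"classification"`
#' @param learning_rate Adam step size
#' @param batch_size minibatch size
#' @param epochs training epochs
#' @param n_folds cross-validation folds
#' @param split train/validation/test fractions (must sum to 1)
#' @param seed integer seed
#' @export
predictor_config <- function(hidden_sizes = c(256, 512, 512, 256),
                             dropout_rate = 0.10,
                             task = c("regression", "classification"),
                             learning_rate = 5e-4, batch_size = 64,
                             epochs = 100, n_folds = 10,
                             split = c(0.8, 0.1, 0.1), seed = 1L) {
  task <- match.arg(task)
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout_rate must be in [0, 1)")
  if (abs(sum(split) - 1) > 1e-8) stopf("split fractions must sum to 1")
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 dropout_rate = dropout_rate, task = task,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 n_folds = as.integer(n_folds),
                 split = split, seed = as.integer(seed)),
            class = "predictor_config")
}

#' Age-stratified train/validation/test split
#'
#' Orders subjects by age, partitions the ordering into as many contiguous
#' strata as there are test subjects, and draws one test subject per stratum
#' (then the same for validation from the remainder), so all three sets have
#' similar age distributions. Deterministic given `(seed, fold)`.
#'
#' @param age numeric vector of ages
#' @param config a [predictor_config()]
#' @param fold fold index, 1-based
#' @return list of index vectors `train`, `validation`, `test` (disjoint,
#'   exhaustive). Test size is `round(split[3] * n)`, validation
#'   `round(split[2] * n)`.
#' @export
stratified_split <- function(age, config, fold = 1) {
  n <- length(age)
  if (n < 10) stopf("need at least 10 subjects to split")
  n_test <- round(config$split[3] * n)
  n_val <- round(config$split[2] * n)
  with_seed(substream_seed(config$seed, "split", fold), {
    pick_stratified <- function(pool, k) {
      ord <- pool[order(age[pool], runif(length(pool)))]
      strata <- split(ord, cut(seq_along(ord), k, labels = FALSE))
      vapply(strata, function(s) s[sample.int(length(s), 1)], numeric(1))
    }
    test <- sort(pick_stratified(seq_len(n), n_test))
    rest <- setdiff(seq_len(n), test)
    val <- sort(pick_stratified(rest, n_val))
    train <- setdiff(rest, val)
    list(train = train, validation = val, test = as.integer(test))
  })
}

# ---- minimal MLP with Adam, ReLU hidden units and inverted dropout ----

mlp_init <- function(n_in, hidden, n_out, seed) {
  sizes <- c(n_in, hidden, n_out)
  with_seed(seed, {
    lapply(seq_len(length(sizes) - 1), function(l) {
      fan_in <- sizes[l]
      list(W = matrix(rnorm(sizes[l] * sizes[l + 1], 0,
                            sqrt(2 / fan_in)),
                      sizes[l], sizes[l + 1]),
           b = rep(0, sizes[l + 1]))
    })
  })
}

mlp_forward <- function(layers, X, dropout = 0, training = FALSE) {
  L <- length(layers)
  acts <- vector("list", L + 1)
  masks <- vector("list", L)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    if (l < L) {
      z <- pmax(z, 0)
      if (training && dropout > 0) {
        m <- matrix(runif(length(z)) >= dropout, nrow(z), ncol(z)) /
          (1 - dropout)
        z <- z * m
        masks[[l]] <- m
      }
    }
    acts[[l + 1]] <- z
  }
  list(acts = acts, masks = masks)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

mlp_loss <- function(pred, y, task) {
  if (task == "regression") {
    mean(abs(pred - y))
  } else {
    p <- pmin(pmax(sigmoid(pred), 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
}

# gradient of the loss w.r.t. the linear output
output_grad <- function(pred, y, task) {
  n <- length(y)
  if (task == "regression") sign(pred - y) / n else (sigmoid(pred) - y) / n
}

mlp_backward <- function(layers, fwd, y, task, dropout) {
  L <- length(layers)
  acts <- fwd$acts
  grads <- vector("list", L)
  delta <- matrix(output_grad(drop(acts[[L + 1]]), y, task), ncol = 1)
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1) {
      delta <- delta %*% t(layers[[l]]$W)
      delta <- delta * (acts[[l]] > 0)
      # inverted-dropout mask carries the 1/(1-p) rescaling
      if (!is.null(fwd$masks[[l - 1]])) delta <- delta * fwd$masks[[l - 1]]
    }
  }
  grads
}

adam_update <- function(layers, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    for (nm in c("W", "b")) {
      g <- grads[[l]][[nm]]
      state[[l]][[nm]]$m <- beta1 * state[[l]][[nm]]$m + (1 - beta1) * g
      state[[l]][[nm]]$v <- beta2 * state[[l]][[nm]]$v + (1 - beta2) * g^2
      mhat <- state[[l]][[nm]]$m / (1 - beta1^t)
      vhat <- state[[l]][[nm]]$v / (1 - beta2^t)
      layers[[l]][[nm]] <- layers[[l]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, state = state)
}

#' Fit min-max feature scaling on training data
#' @param X training feature matrix
#' @return list of per-column `min` and `range`
#' @export
fit_minmax <- function(X) {
  mins <- apply(X, 2, min)
  rng <- apply(X, 2, max) - mins
  rng[rng == 0] <- 1
  list(min = mins, range = rng)
}

#' Apply min-max scaling fitted with [fit_minmax()]
#' @param X feature matrix
#' @param scaling result of [fit_minmax()]
#' @export
apply_minmax <- function(X, scaling) {
  sweep(sweep(X, 2, scaling$min, "-"), 2, scaling$range, "/")
}

#' Train the multilayer perceptron
#'
#' Minibatch Adam on mean absolute error (regression) or binary
#' cross-entropy (classification), with inverted dropout between hidden
#' layers. After every epoch the validation loss is evaluated without
#' dropout; the returned model is the checkpoint with the lowest validation
#' loss.
#'
#' @param X_train,y_train training features (already scaled to \[0, 1\]) and
#'   targets (class targets coded 0/1)
#' @param X_val,y_val validation set used for checkpoint selection
#' @param config a [predictor_config()]
#' @param seed seed for initialization and batch shuffling (defaults to
#'   `config$seed`)
#' @return list of class `mlp_model`: `layers`, `task`, `history`
#'   (per-epoch train/validation loss), `best_epoch`
#' @export
train_predictor <- function(X_train, y_train, X_val, y_val, config,
                            seed = NULL) {
  if (anyNA(X_train) || anyNA(y_train)) stopf("missing values in training data")
  if (is.null(seed)) seed <- config$seed
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  n_out <- 1L
  layers <- mlp_init(ncol(X_train), config$hidden_sizes, n_out,
                     substream_seed(seed, "init"))
  state <- lapply(layers, function(l) {
    list(W = list(m = 0 * l$W, v = 0 * l$W),
         b = list(m = 0 * l$b, v = 0 * l$b))
  })
  n <- nrow(X_train)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  step <- 0
  with_seed(substream_seed(seed, "batches"), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (bi in batches) {
        fwd <- mlp_forward(layers, X_train[bi, , drop = FALSE],
                           config$dropout_rate, training = TRUE)
        grads <- mlp_backward(layers, fwd, y_train[bi], config$task,
                              config$dropout_rate)
        step <- step + 1
        upd <- adam_update(layers, grads, state, config$learning_rate, step)
        layers <- upd$layers; state <- upd$state
      }
      tr_pred <- drop(mlp_forward(layers, X_train)$acts[[length(layers) + 1]])
      va_pred <- drop(mlp_forward(layers, X_val)$acts[[length(layers) + 1]])
      tr_loss <- mlp_loss(tr_pred, y_train, config$task)
      va_loss <- mlp_loss(va_pred, y_val, config$task)
      if (!is.finite(tr_loss)) {
        stopf("divergent training loss at epoch %d (seed %d)", epoch, seed)
      }
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = tr_loss,
                                           val_loss = va_loss))
      if (va_loss < best$loss) {
        best <- list(loss = va_loss, layers = layers, epoch = epoch)
      }
    }
  })
  structure(list(layers = best$layers, task = config$task,
                 history = history, best_epoch = best$epoch,
                 best_val_loss = best$loss),
            class = "mlp_model")
}

#' Predict with a trained MLP
#'
#' @param object an `mlp_model`
#' @param newdata scaled feature matrix
#' @param ... unused
#' @return regression: numeric predictions; classification: probabilities
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  out <- drop(mlp_forward(object$layers,
                          as.matrix(newdata))$acts[[length(object$layers) + 1]])
  if (object$task == "classification") sigmoid(out) else out
}

#' Evaluate a trained predictor on held-out data
#'
#' Regression: Pearson correlation between true and predicted values (0 with
#' a `degenerate` flag if predictions are constant) and mean absolute error.
#' Classification: ROC AUC and the confusion matrix at threshold 0.5,
#' normalized by true-class row.
#'
#' @param model an `mlp_model`
#' @param X_test scaled test features
#' @param y_test test targets (0/1 for classification)
#' @return list of metrics
#' @export
evaluate_predictor <- function(model, X_test, y_test) {
  pred <- predict(model, X_test)
  if (model$task == "regression") {
    degenerate <- sd(pred) == 0
    list(r = if (degenerate) 0 else cor(pred, y_test),
         mae = mean(abs(pred - y_test)),
         degenerate = degenerate)
  } else {
    if (length(unique(y_test)) < 2) {
      stopf("single-class test set: ROC AUC undefined")
    }
    roc <- pROC::roc(y_test, pred, quiet = TRUE, direction = "<")
    cls <- as.integer(pred >= 0.5)
    cm <- table(factor(y_test, levels = c(0, 1)),
                factor(cls, levels = c(0, 1)))
    cm_norm <- sweep(cm, 1, pmax(rowSums(cm), 1), "/")
    list(auc = as.numeric(pROC::auc(roc)),
         confusion = cm_norm,
         accuracy_by_class = diag(cm_norm))
  }
}

#' Cross-validated prediction of age (or age group) from capacity features
#'
#' Per fold: an age-stratified 80/10/10 split, min-max scaling fit on the
#' training set only, MLP training with validation-loss checkpointing, and
#' evaluation on the untouched test slice. Regression targets are scaled to
#' \[0, 1\] with the training set's range and predictions mapped back.
#'
#' @param features numeric feature matrix (rows = subjects)
#' @param targets ages (regression) or 0/1 classes (classification)
#' @param config a [predictor_config()]
#' @return list: `per_fold` (metric list per fold), `summary` (mean and sd
#'   of the headline metric), `predictions` (per-fold data.frames)
#' @export
cross_validate_predictor <- function(features, targets, config) {
  features <- as.matrix(features)
  metric_name <- if (config$task == "regression") "r" else "auc"
  per_fold <- vector("list", config$n_folds)
  predictions <- vector("list", config$n_folds)
  strat_var <- targets  # for classification, stratifies on the class label
  for (fold in seq_len(config$n_folds)) {
    sp <- stratified_split(strat_var, config, fold)
    scaling <- fit_minmax(features[sp$train, , drop = FALSE])
    Xtr <- apply_minmax(features[sp$train, , drop = FALSE], scaling)
    Xva <- apply_minmax(features[sp$validation, , drop = FALSE], scaling)
    Xte <- apply_minmax(features[sp$test, , drop = FALSE], scaling)
    ytr <- targets[sp$train]; yva <- targets[sp$validation]
    yte <- targets[sp$test]
    if (config$task == "regression") {
      yr <- range(ytr)
      sc <- function(y) (y - yr[1]) / (yr[2] - yr[1])
      unsc <- function(y) y * (yr[2] - yr[1]) + yr[1]
      model <- train_predictor(Xtr, sc(ytr), Xva, sc(yva), config,
                               seed = substream_seed(config$seed, "fold", fold))
      pred <- unsc(predict(model, Xte))
      degenerate <- sd(pred) == 0
      per_fold[[fold]] <- list(r = if (degenerate) 0 else cor(pred, yte),
                               mae = mean(abs(pred - yte)),
                               degenerate = degenerate,
                               best_epoch = model$best_epoch)
      predictions[[fold]] <- data.frame(fold = fold, true = yte, pred = pred)
    } else {
      model <- train_predictor(Xtr, ytr, Xva, yva, config,
                               seed = substream_seed(config$seed, "fold", fold))
      ev <- evaluate_predictor(model, Xte, yte)
      ev$best_epoch <- model$best_epoch
      per_fold[[fold]] <- ev
      predictions[[fold]] <- data.frame(fold = fold, true = yte,
                                        pred = predict(model, Xte))
    }
  }
  vals <- vapply(per_fold, `[[`, numeric(1), metric_name)
  list(per_fold = per_fold,
       summary = c(mean = mean(vals), sd = sd(vals)),
       metric = metric_name,
       predictions = do.call(rbind, predictions))
}
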