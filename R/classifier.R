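#' Classifier configuration
#'
#' A feed-forward softmax network: dense hidden layers with rectifier
#' activations and inverted dropout, cross-entropy loss, mini-batch Adam,
#' and early stopping on a held-back slice of the training data. The
#' defaults (two hidden layers of 128 and 64 units) are the smallest stack
#' that comfortably separates the study's 68 classes; everything is
#' overridable.
#'
#' @param hidden Integer vector of hidden-layer sizes.
#' @param dropout Dropout rate in `[0, 1)` applied to hidden activations
#'   during training.
#' @param l2 L2 weight-decay coefficient on the weights (not biases);
#'   together with dropout this is what keeps the network from memorising
#'   the per-copy noise of augmented data.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param epochs Epoch budget.
#' @param patience Early-stop patience (epochs without validation
#'   improvement).
#' @param val_fraction Fraction of the training data held back for early
#'   stopping (0 disables early stopping).
#' @param folds Folds for [kfold_evaluate()] (default 6).
#' @param seed Integer seed; training is deterministic given the seed.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(hidden = c(128L, 64L), dropout = 0.2,
                              l2 = 1e-3,
                              learning_rate = 3e-3, batch_size = 256L,
                              epochs = 100L, patience = 10L,
                              val_fraction = 0.1, folds = 6L, seed = 1L) {
  stopifnot(all(hidden >= 1L), dropout >= 0, dropout < 1, folds >= 2L,
            learning_rate > 0, batch_size >= 1L, epochs >= 1L, l2 >= 0)
  structure(list(hidden = as.integer(hidden), dropout = dropout, l2 = l2,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 val_fraction = val_fraction, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

relu <- function(z) z * (z > 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

init_net <- function(sizes) {
  # He-normal initialisation
  lapply(seq_len(length(sizes) - 1L), function(l)
    list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                 sd = sqrt(2 / sizes[l])),
                    sizes[l], sizes[l + 1L]),
         b = numeric(sizes[l + 1L])))
}

forward_net <- function(net, x, dropout = 0, training = FALSE) {
  acts <- vector("list", length(net))
  masks <- vector("list", length(net))
  a <- x
  for (l in seq_along(net)) {
    z <- sweep(a %*% net[[l]]$W, 2L, net[[l]]$b, "+")
    if (l < length(net)) {
      a <- relu(z)
      if (training && dropout > 0) {
        m <- matrix(stats::runif(length(a)) >= dropout, nrow(a)) / (1 - dropout)
        a <- a * m
        masks[[l]] <- m
      }
    } else a <- softmax_rows(z)
    acts[[l]] <- a
  }
  list(acts = acts, masks = masks)
}

#' Train the feed-forward classifier
#'
#' @param x Numeric matrix, samples x features (finite values).
#' @param y Factor of class labels; every level must be present.
#' @param config A [classifier_config()].
#' @return An object of class `mlp_classifier`.
#' @export
train_classifier <- function(x, y, config = classifier_config()) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite inputs", call. = FALSE)
  y <- as.factor(y)
  if (any(table(y) == 0L))
    stop("class absent from training set: ",
         paste(levels(y)[table(y) == 0L], collapse = ", "), call. = FALSE)
  classes <- levels(y)
  yi <- as.integer(y)
  n <- nrow(x); k <- length(classes)
  sizes <- c(ncol(x), config$hidden, k)

  withr::with_seed(config$seed, {
    # held-back validation slice for early stopping
    val <- integer(0)
    if (config$val_fraction > 0 && n >= 20L) {
      val <- unlist(lapply(split(seq_len(n), yi), function(ix)
        if (length(ix) >= 2L)
          sample(ix, max(1L, floor(config$val_fraction * length(ix))))))
      if (length(val) < 2L || length(val) >= n - 1L) val <- integer(0)
    }
    tr <- setdiff(seq_len(n), val)
    xt <- x[tr, , drop = FALSE]; yt <- yi[tr]
    net <- init_net(sizes)
    mom <- lapply(net, function(l) list(mW = 0 * l$W, vW = 0 * l$W,
                                        mb = 0 * l$b, vb = 0 * l$b))
    b1 <- 0.9; b2 <- 0.999; epsad <- 1e-8; step <- 0L
    best <- list(loss = Inf, net = net, epoch = 0L)
    wait <- 0L
    L <- length(net)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(tr))
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        xb <- xt[bi, , drop = FALSE]
        fw <- forward_net(net, xb, config$dropout, training = TRUE)
        m <- length(bi)
        onehot <- matrix(0, m, k); onehot[cbind(seq_len(m), yt[bi])] <- 1
        delta <- (fw$acts[[L]] - onehot) / m
        step <- step + 1L
        for (l in rev(seq_len(L))) {
          a_prev <- if (l == 1L) xb else fw$acts[[l - 1L]]
          gW <- crossprod(a_prev, delta) + config$l2 * net[[l]]$W
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- tcrossprod(delta, net[[l]]$W)
            if (!is.null(fw$masks[[l - 1L]])) delta <- delta * fw$masks[[l - 1L]]
            delta <- delta * (fw$acts[[l - 1L]] > 0)
          }
          mo <- mom[[l]]
          mo$mW <- b1 * mo$mW + (1 - b1) * gW
          mo$vW <- b2 * mo$vW + (1 - b2) * gW^2
          mo$mb <- b1 * mo$mb + (1 - b1) * gb
          mo$vb <- b2 * mo$vb + (1 - b2) * gb^2
          mom[[l]] <- mo
          corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
          net[[l]]$W <- net[[l]]$W - config$learning_rate *
            (mo$mW / corr1) / (sqrt(mo$vW / corr2) + epsad)
          net[[l]]$b <- net[[l]]$b - config$learning_rate *
            (mo$mb / corr1) / (sqrt(mo$vb / corr2) + epsad)
        }
      }
      # monitor: validation loss if available, else training loss
      mon_idx <- if (length(val)) val else tr
      probs <- forward_net(net, x[mon_idx, , drop = FALSE])$acts[[L]]
      loss <- -mean(log(pmax(probs[cbind(seq_along(mon_idx), yi[mon_idx])],
                             1e-12)))
      if (loss < best$loss - 1e-6) {
        best <- list(loss = loss, net = net, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (config$patience > 0L && wait >= config$patience) break
      }
    }
  })
  structure(list(net = best$net, classes = classes, config = config,
                 monitor_loss = best$loss, epochs_run = best$epoch,
                 n_features = ncol(x)),
            class = "mlp_classifier")
}

#' @export
predict.mlp_classifier <- function(object, newdata,
                                   type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  probs <- forward_net(object$net, newdata)$acts[[length(object$net)]]
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs, ties.method = "first")],
         levels = object$classes)
}

#' Confusion matrix over a known class set
#'
#' Entry `(i, j)` counts samples of true class `i` predicted as class `j`;
#' `sum(diag(.)) / sum(.)` is the accuracy.
#'
#' @param true,predicted Equal-length label vectors.
#' @param levels The known class set (default: levels of `true`).
#' @return A square count matrix (true x predicted).
#' @export
confusion_matrix <- function(true, predicted, levels = NULL) {
  if (is.null(levels)) levels <- base::levels(as.factor(true))
  if (length(true) != length(predicted))
    stop("label sequences differ in length", call. = FALSE)
  if (!all(c(as.character(true), as.character(predicted)) %in% levels))
    stop("unknown label", call. = FALSE)
  t <- factor(as.character(true), levels = levels)
  p <- factor(as.character(predicted), levels = levels)
  unclass(table(true = t, predicted = p))
}

#' k-fold cross-validated evaluation of the classifier
#'
#' Splits the samples into `config$folds` class-stratified folds; each fold
#' is held out once, the classifier is trained on the remainder, and
#' accuracy is computed on the held-out fold only. Reports per-fold
#' accuracies (percent), their mean, and the confusion matrix pooled over
#' folds. The 68-class task needs augmented-scale data so that every class
#' appears in every training partition.
#'
#' @param matrix A `feature_matrix`.
#' @param config A [classifier_config()].
#' @param feature_set `"combined"`, `"sugars"` or `"organics"`.
#' @return A `classifier_report` with `fold_accuracies`, `mean_accuracy`
#'   (percent) and `confusion`.
#' @export
kfold_evaluate <- function(matrix, config = classifier_config(),
                           feature_set = c("combined", "sugars", "organics")) {
  feature_set <- match.arg(feature_set)
  fm <- select_features(matrix, feature_set)
  y <- factor(fm$labels)
  n <- nrow(fm$values)
  stopifnot(config$folds >= 2L)
  if (min(table(y)) < config$folds)
    stop("stratification impossible: a class has fewer samples than folds",
         call. = FALSE)
  fold_of <- withr::with_seed(config$seed, {
    f <- integer(n)
    for (ix in split(seq_len(n), y))
      f[ix] <- sample(rep_len(seq_len(config$folds), length(ix)))
    f
  })
  acc <- numeric(config$folds)
  confusion <- matrix(0L, nlevels(y), nlevels(y),
                      dimnames = list(true = levels(y),
                                      predicted = levels(y)))
  for (f in seq_len(config$folds)) {
    te <- fold_of == f
    cfg <- config; cfg$seed <- config$seed + f
    model <- train_classifier(fm$values[!te, , drop = FALSE], y[!te], cfg)
    pred <- predict(model, fm$values[te, , drop = FALSE])
    confusion <- confusion + confusion_matrix(y[te], pred, levels(y))
    acc[f] <- 100 * mean(pred == y[te])
  }
  structure(list(feature_set = feature_set, fold_accuracies = acc,
                 mean_accuracy = mean(acc), confusion = confusion,
                 folds = config$folds),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("classifier_report (%s): mean accuracy %.2f%% over %d folds\n",
              x$feature_set, x$mean_accuracy, x$folds))
  cat("fold accuracies:", paste(sprintf("%.2f", x$fold_accuracies),
                                collapse = ", "), "\n")
  invisible(x)
}
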