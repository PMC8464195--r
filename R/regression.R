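#' Predictor matrix for a sugar target
#'
#' Regression of a sugar uses all other features: the remaining three
#' sugars (unless `include_other_sugars = FALSE`) and every organic
#' feature. The target column itself is always excluded.
#'
#' @param matrix A `feature_matrix`.
#' @param target One of `"fructose"`, `"glucose"`, `"maltose"`, `"sucrose"`.
#' @param include_other_sugars Keep the three non-target sugar columns.
#' @return List with `x` (predictor matrix) and `y` (target vector).
#' @export
regression_design <- function(matrix, target, include_other_sugars = TRUE) {
  stopifnot(inherits(matrix, "feature_matrix"),
            target %in% sugar_names())
  is_target <- matrix$meta$kind == "sugar" & matrix$meta$name == target
  drop <- is_target
  if (!include_other_sugars) drop <- drop | matrix$meta$kind == "sugar"
  list(x = matrix$values[, !drop, drop = FALSE],
       y = as.numeric(matrix$values[, which(is_target)]))
}

# --- latent-variable fits -------------------------------------------------

# One-response NIPALS partial least squares on centred data. Returns
# weights/loadings so that coefficients for any 1..ncomp can be formed.
pls1_fit <- function(x, y, ncomp) {
  x <- as.matrix(x)
  xm <- colMeans(x); ym <- mean(y)
  e <- sweep(x, 2L, xm); f <- y - ym
  p <- ncol(x)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(e, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { W <- W[, seq_len(a - 1L), drop = FALSE]
                      P <- P[, seq_len(a - 1L), drop = FALSE]
                      q <- q[seq_len(a - 1L)]; break }
    w <- w / nw
    t <- drop(e %*% w); tt <- sum(t^2)
    pl <- drop(crossprod(e, t)) / tt
    qa <- sum(f * t) / tt
    e <- e - tcrossprod(t, pl)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pl; q[a] <- qa
  }
  structure(list(method = "PLS", W = W, P = P, q = q,
                 x_mean = xm, y_mean = ym, ncomp = length(q)),
            class = "latent_fit")
}

# Principal component regression: y regressed on leading PC scores.
pcr_fit <- function(x, y, ncomp) {
  x <- as.matrix(x)
  xm <- colMeans(x); ym <- mean(y)
  xc <- sweep(x, 2L, xm)
  sv <- svd(xc, nu = 0, nv = min(ncomp, min(dim(xc))))
  V <- sv$v
  scores <- xc %*% V
  b <- drop(crossprod(scores, y - ym)) / colSums(scores^2)
  b[!is.finite(b)] <- 0
  structure(list(method = "PCR", V = V, b = b,
                 x_mean = xm, y_mean = ym, ncomp = ncol(V)),
            class = "latent_fit")
}

fit_latent <- function(x, y, method, ncomp) {
  switch(method, PLS = pls1_fit(x, y, ncomp), PCR = pcr_fit(x, y, ncomp),
         stop("unknown method: ", method, call. = FALSE))
}

# Regression coefficients (and intercept) using the first `a` components.
latent_coef <- function(fit, a = fit$ncomp) {
  a <- min(a, fit$ncomp)
  if (a == 0L) return(list(beta = NULL, intercept = fit$y_mean))
  beta <- if (fit$method == "PLS") {
    W <- fit$W[, seq_len(a), drop = FALSE]
    P <- fit$P[, seq_len(a), drop = FALSE]
    drop(W %*% solve(crossprod(P, W), fit$q[seq_len(a)]))
  } else {
    drop(fit$V[, seq_len(a), drop = FALSE] %*% fit$b[seq_len(a)])
  }
  list(beta = beta, intercept = fit$y_mean - sum(fit$x_mean * beta))
}

#' @export
predict.latent_fit <- function(object, newdata, ncomp = object$ncomp, ...) {
  co <- latent_coef(object, ncomp)
  if (is.null(co$beta)) return(rep(co$intercept, nrow(newdata)))
  drop(as.matrix(newdata) %*% co$beta) + co$intercept
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

#' Cross-validated error curve over component counts
#'
#' For each candidate component count, fits the model on `folds - 1` folds
#' and pools the squared out-of-fold residuals; RMSECV is the root of the
#' pooled mean. Fold assignment is a deterministic shuffle under `seed`
#' with sizes as equal as possible. Centring is learned on the training
#' folds only.
#'
#' @param x Predictor matrix. @param y Target vector (non-degenerate).
#' @param method `"PLS"` or `"PCR"`.
#' @param max_components Largest candidate count.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @return Numeric vector `rmsecv[c]`, `c = 1..max_components`.
#' @export
rmsecv_curve <- function(x, y, method = c("PLS", "PCR"), max_components,
                         folds = 10L, seed = 1L) {
  method <- match.arg(method)
  x <- as.matrix(x); n <- nrow(x)
  stopifnot(length(y) == n, folds >= 2L, folds <= n)
  if (stats::var(y) == 0) stop("degenerate target: zero variance", call. = FALSE)
  min_train <- n - ceiling(n / folds)
  if (max_components > min(min_train - 1L, ncol(x)))
    stop("max_components too large for the fold sizes", call. = FALSE)
  fold_of <- withr::with_seed(seed, sample(rep_len(seq_len(folds), n)))
  sse <- numeric(max_components)
  for (f in seq_len(folds)) {
    te <- fold_of == f
    fit <- fit_latent(x[!te, , drop = FALSE], y[!te], method, max_components)
    for (a in seq_len(max_components)) {
      pr <- predict(fit, x[te, , drop = FALSE], ncomp = a)
      sse[a] <- sse[a] + sum((y[te] - pr)^2)
    }
  }
  sqrt(sse / n)
}

#' @rdname rmsecv_curve
#' @param curve An RMSECV curve.
#' @return `select_components()`: the argmin, ties to fewer components.
#' @export
select_components <- function(curve) {
  which(curve <= min(curve) + 1e-12)[1L]
}

#' Fit on a train split and evaluate on the held-out split
#'
#' Splits samples into train/test (stratified over class labels when every
#' class has enough members, otherwise a simple random split), fits the
#' latent-variable regression on the training split only (centring learned
#' there), and reports the training RMSE, the prediction RMSEP and R^2 on
#' the held-out split.
#'
#' @inheritParams rmsecv_curve
#' @param n_components Number of latent components.
#' @param train_fraction Fraction of samples used for training.
#' @param labels Optional class labels used for stratification.
#' @return A `regression_report`.
#' @export
fit_evaluate <- function(x, y, method = c("PLS", "PCR"), n_components,
                         train_fraction = 0.7, seed = 1L, labels = NULL) {
  method <- match.arg(method)
  x <- as.matrix(x); n <- nrow(x)
  stopifnot(train_fraction > 0, train_fraction < 1)
  tr <- withr::with_seed(seed, {
    if (!is.null(labels) && min(table(labels)) >= 2L) {
      unlist(lapply(split(seq_len(n), labels), function(ix)
        sample(ix, max(1L, round(train_fraction * length(ix))))))
    } else sample.int(n, round(train_fraction * n))
  })
  te <- setdiff(seq_len(n), tr)
  if (length(te) < 2L) stop("test partition smaller than 2", call. = FALSE)
  fit <- fit_latent(x[tr, , drop = FALSE], y[tr], method, n_components)
  pred_tr <- predict(fit, x[tr, , drop = FALSE])
  pred_te <- predict(fit, x[te, , drop = FALSE])
  r2 <- 1 - sum((y[te] - pred_te)^2) / sum((y[te] - mean(y[te]))^2)
  structure(list(method = method, n_components = fit$ncomp,
                 rmse = rmse(y[tr], pred_tr),
                 rmsep = rmse(y[te], pred_te),
                 r2 = r2,
                 split = list(train_fraction = train_fraction, seed = seed,
                              n_train = length(tr), n_test = length(te),
                              train_idx = sort(tr), test_idx = te),
                 fit = fit),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("%s (%d components): RMSE %.4g, RMSEP %.4g, R^2 %.4f [train %d / test %d]\n",
              x$method, x$n_components, x$rmse, x$rmsep, x$r2,
              x$split$n_train, x$split$n_test))
  invisible(x)
}

#' Compare PCR and PLS on the same target
#'
#' Runs [rmsecv_curve()] for both methods with identical folds and reports
#' each method's minimising component count and RMSECV minimum. PCR
#' typically needs more components than PLS for the same error.
#'
#' @inheritParams rmsecv_curve
#' @return List with per-method `curve`, `n_components` and `rmsecv_min`.
#' @export
compare_methods <- function(x, y, max_components, folds = 10L, seed = 1L) {
  out <- lapply(c(PLS = "PLS", PCR = "PCR"), function(m) {
    curve <- rmsecv_curve(x, y, m, max_components, folds, seed)
    list(curve = curve, n_components = select_components(curve),
         rmsecv_min = min(curve))
  })
  out
}
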