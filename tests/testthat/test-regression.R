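make_latent_data <- function(n = 30, p = 8, seed = 1) {
  set.seed(seed)
  t <- rnorm(n)
  loadings <- rnorm(p)
  list(x = outer(t, loadings), y = 2 * t + 1)
}

test_that("RMSECV selects one component on noiseless single-factor data, for both methods", {
  d <- make_latent_data()
  for (m in c("PLS", "PCR")) {
    curve <- rmsecv_curve(d$x, d$y, m, max_components = 4L, folds = 5L,
                          seed = 2L)
    expect_equal(select_components(curve), 1L)
    expect_lt(curve[1], 1e-8)
  }
  cmp <- compare_methods(d$x, d$y, max_components = 4L, folds = 5L, seed = 2L)
  expect_equal(cmp$PLS$n_components, 1L)
  expect_equal(cmp$PCR$n_components, 1L)
})

test_that("degenerate targets and oversized component requests are rejected", {
  d <- make_latent_data()
  expect_error(rmsecv_curve(d$x, rep(1, 30), "PLS", 2L), "degenerate")
  expect_error(rmsecv_curve(d$x, d$y, "PLS", 40L), "too large")
})

test_that("argmin tie-breaking prefers fewer components", {
  expect_equal(select_components(c(0.5, 0.2, 0.2, 0.3)), 2L)
  expect_equal(select_components(c(0.2, 0.2)), 1L)
})

test_that("exact linear relations are fit perfectly given enough components", {
  set.seed(3)
  x <- matrix(rnorm(40 * 5), 40, 5)
  beta <- c(1, -2, 0.5, 3, -1)
  y <- drop(x %*% beta) + 4
  for (m in c("PLS", "PCR")) {
    rep <- fit_evaluate(x, y, m, n_components = 5L, seed = 7L)
    expect_equal(rep$r2, 1, tolerance = 1e-8)
    expect_lt(rep$rmsep, 1e-6)
  }
})

test_that("PLS with full rank components reproduces ordinary least squares", {
  set.seed(4)
  x <- matrix(rnorm(20 * 5), 20, 5)
  y <- rnorm(20)
  fit <- hptlcauth:::pls1_fit(x, y, 5L)
  co <- hptlcauth:::latent_coef(fit)
  ols <- lm(y ~ x)
  expect_equal(unname(co$beta), unname(coef(ols)[-1]), tolerance = 1e-6)
  expect_equal(co$intercept, unname(coef(ols)[1]), tolerance = 1e-6)
})

test_that("our PLS predictions agree with an independent implementation", {
  set.seed(8)
  x <- matrix(rnorm(25 * 6), 25, 6,
              dimnames = list(NULL, sprintf("v%d", 1:6)))
  y <- drop(x %*% rnorm(6)) + rnorm(25, 0, 0.2)
  fit <- hptlcauth:::pls1_fit(x, y, 3L)
  ours <- predict(fit, x, ncomp = 3L)
  mo <- mixOmics::pls(x, y, ncomp = 3L, scale = FALSE, mode = "regression")
  theirs <- drop(predict(mo, x)$predict[, 1, 3])
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("targets independent of the predictors give non-positive expected test R^2", {
  set.seed(5)
  r2s <- replicate(100, {
    x <- matrix(rnorm(30 * 3), 30, 3)
    y <- rnorm(30)
    fit_evaluate(x, y, "PLS", 2L, seed = sample.int(1e6, 1))$r2
  })
  expect_lt(mean(r2s), 0.05)
})

test_that("a direction of low variance but high relevance makes PCR need more components than PLS", {
  # exactly orthogonal predictors with variance ordering opposed to
  # relevance: the response lives on the smallest-variance column, which
  # PCR (variance-greedy) reaches last while PLS (covariance-greedy)
  # reaches early; compared as components needed to attain a common error
  for (seed in c(2L, 6L, 9L)) {
    set.seed(seed)
    n <- 60
    q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
    x <- q %*% diag(c(2, 1.5, 1)) * sqrt(n)
    y <- x[, 3] + rnorm(n, 0, 0.3)
    cmp <- compare_methods(x, y, max_components = 3L, folds = 5L, seed = seed)
    target <- 1.1 * max(cmp$PLS$rmsecv_min, cmp$PCR$rmsecv_min)
    needed <- function(curve) which(curve <= target)[1]
    expect_gt(needed(cmp$PCR$curve), needed(cmp$PLS$curve))
  }
})

test_that("preprocessing is learned on the training partition only", {
  set.seed(10)
  x <- matrix(rnorm(40 * 4, mean = 5), 40, 4)
  y <- drop(x %*% c(1, 2, -1, 0.5)) + rnorm(40, 0, 0.5)
  rep <- fit_evaluate(x, y, "PLS", 2L, seed = 11L)
  tr <- rep$split$train_idx
  # centring parameters equal train-only means, not full-data means
  expect_equal(rep$fit$x_mean, colMeans(x[tr, , drop = FALSE]),
               ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(rep$fit$x_mean, colMeans(x),
                                check.attributes = FALSE)))
  # and test predictions derive from that train-only fit
  manual <- predict(rep$fit, x[-tr, , drop = FALSE])
  expect_equal(hptlcauth:::rmse(y[-tr], manual), rep$rmsep, tolerance = 1e-12)
})

test_that("the design for a sugar target excludes that sugar but keeps the rest", {
  fm <- study_features_std()
  d <- regression_design(fm, "glucose")
  expect_equal(ncol(d$x), ncol(fm$values) - 1L)
  expect_false("glucose" %in% colnames(d$x))
  expect_true(all(c("fructose", "maltose", "sucrose") %in% colnames(d$x)))
  d2 <- regression_design(fm, "glucose", include_other_sugars = FALSE)
  expect_equal(ncol(d2$x), ncol(fm$values) - 4L)
  expect_equal(d$y, unname(fm$values[, "glucose"]))
})
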