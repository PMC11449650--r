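# Oracle-backed tests of the six calibration families. Synthetic feature
# matrices are built in code with known structure; ordinary least squares
# (computed directly) serves as the reference for the full-rank and
# small-lambda limits.

ols_predict <- function(X, Y, Xnew) {
  fit <- qr.coef(qr(cbind(1, X)), Y)
  cbind(1, Xnew) %*% fit
}

make_linear_data <- function(n = 60, p = 20, seed = 11, noise = 0) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    X <- matrix(rnorm(n * p), n, p)
    B <- matrix(rnorm(p * 3), p, 3) * 50
    Y <- X %*% B + matrix(rnorm(n * 3, sd = noise), n, 3)
    Y <- sweep(Y, 2, apply(Y, 2, min))          # keep labels >= 0
    list(X = X, Y = Y)
  })
}

test_that("PCR keeps the cumulative-variance component count and matches OLS
           at full rank", {
  d <- make_linear_data()
  # component count equals the brute-force count from singular values
  Xc <- sweep(d$X, 2, colMeans(d$X))
  sv <- svd(Xc, nu = 0)$d
  k_oracle <- which(cumsum(sv^2) / sum(sv^2) >= 0.99)[1]
  m <- fit_pcr(d, variance_target = 0.99)
  expect_identical(m$n_components, k_oracle)
  # all components: identical to OLS predictions
  m_full <- fit_pcr(d, n_components = 20)
  expect_equal(predict_shallow(m_full, d$X), ols_predict(d$X, d$Y, d$X),
               tolerance = 1e-6, ignore_attr = TRUE)
  # rank-1 features keep exactly one component
  X1 <- outer(rnorm(30), rnorm(5))
  m1 <- fit_pcr(list(X = X1, Y = matrix(1:90, 30, 3)), variance_target = 0.99)
  expect_identical(m1$n_components, 1L)
  expect_error(fit_pcr(d, variance_target = 1.5), "variance_target")
})

test_that("PLSR matches OLS at full rank and finds single-direction structure", {
  d <- make_linear_data(n = 50, p = 15)
  m <- fit_plsr(d, n_components = 15)
  expect_equal(predict_shallow(m, d$X), ols_predict(d$X, d$Y, d$X),
               tolerance = 1e-6, ignore_attr = TRUE)
  # one latent direction drives all labels -> 1 component suffices
  set.seed(2)
  t_lat <- rnorm(80)
  X <- outer(t_lat, rnorm(12)) + matrix(rnorm(80 * 12, sd = 1e-3), 80, 12)
  Y <- cbind(100 + 50 * t_lat, 200 + 30 * t_lat, 10 + 5 * t_lat)
  tr <- 1:60; te <- 61:80
  m1 <- fit_plsr(list(X = X[tr, ], Y = Y[tr, ]), n_components = 1)
  rmse <- sqrt(colMeans((predict_shallow(m1, X[te, ]) - Y[te, ])^2))
  rng <- apply(Y, 2, function(y) diff(range(y)))
  expect_true(all(rmse < 0.01 * rng))
  # record order does not change the model (loadings up to sign)
  perm <- sample(nrow(d$X))
  mp <- fit_plsr(list(X = d$X[perm, ], Y = d$Y[perm, ]), n_components = 5)
  m5 <- fit_plsr(d, n_components = 5)
  expect_equal(abs(mp$fit$W), abs(m5$fit$W), tolerance = 1e-8)
  expect_error(fit_plsr(d, n_components = 51), "rank")
})

test_that("PLSR agrees with an independent PLS implementation", {
  d <- make_linear_data(n = 40, p = 10, noise = 20)
  colnames(d$X) <- paste0("px", 1:10)
  m <- fit_plsr(d, n_components = 4)
  ref <- mixOmics::pls(d$X, d$Y, ncomp = 4, mode = "regression",
                       scale = FALSE)
  pred_ref <- predict(ref, d$X)$predict[, , 4]
  expect_equal(unname(predict_shallow(m, d$X)), unname(pred_ref),
               tolerance = 1e-6)
})

test_that("penalized families follow the 1-SE rule on principal-component
           scores", {
  d <- make_linear_data(n = 80, p = 30, noise = 40)
  for (fam in c("lasso", "ridge", "enet")) {
    m <- fit_penalized(d, fam, n_pcs = 100, folds = 20, seed = 5)
    expect_identical(m$n_components, min(100L, 30L))
    for (cv in m$cv_curves) {
      expect_gte(cv$lambda_sel, cv$lambda_min)      # 1-SE picks larger lambda
      i_min <- which.min(cv$cvm)
      i_sel <- which(cv$lambda == cv$lambda_sel)
      expect_lte(cv$cvm[i_sel], cv$cvm[i_min] + cv$cvsd[i_min])
    }
    m2 <- fit_penalized(d, fam, n_pcs = 100, folds = 20, seed = 5)
    expect_identical(m$cv_curves$da$lambda_sel, m2$cv_curves$da$lambda_sel)
  }
  expect_error(fit_penalized(d, "lasso", folds = 99), "folds")
})

test_that("ridge at vanishing lambda reproduces OLS on the scores", {
  d <- make_linear_data(n = 100, p = 8, noise = 5)
  m <- fit_penalized(d, "ridge", n_pcs = 8, folds = 5, seed = 3,
                     lambda_grid = c(1e-4, 1e-5, 1e-6, 1e-7, 1e-8))
  pred <- predict_shallow(m, d$X)
  expect_equal(pred, ols_predict(d$X, d$Y, d$X), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("SVR logs exactly the budgeted candidate evaluations and recovers
           a linear signal", {
  d <- make_linear_data(n = 70, p = 6, seed = 21)
  tr <- 1:50; te <- 51:70
  m <- fit_svr(list(X = d$X[tr, ], Y = d$Y[tr, ]), folds = 5, budget = 30,
               seed = 4)
  for (a in c("da", "ne", "ht5")) {
    expect_identical(nrow(m$search[[a]]), 30L)
    expect_true(all(is.finite(m$search[[a]]$cv_mse)))
  }
  pred <- predict_shallow(m, d$X[te, ])
  rng <- apply(d$Y, 2, function(y) diff(range(y)))
  rmse <- sqrt(colMeans((pred - d$Y[te, ])^2))
  expect_true(all(rmse < 0.05 * rng))
  expect_error(fit_svr(d, budget = 0), "budget")
})

test_that("every family predicts three outputs, even for an all-zero label
           column", {
  set.seed(9)
  X <- matrix(rnorm(40 * 12), 40, 12)
  Y <- cbind(da = 100 + 40 * X[, 1], ne = 0, ht5 = 50 + 10 * X[, 2])
  for (fam in c("svr", "pcr", "plsr", "lasso", "ridge", "enet")) {
    m <- fit_shallow(list(X = X, Y = Y), fam, seed = 2)
    p <- predict_shallow(m, X[1:5, ])
    expect_equal(dim(p), c(5, 3))
    expect_true(all(abs(p[, "ne"]) < 25))   # near-zero for the absent analyte
  }
})

test_that("huge ridge shrinkage predicts the training label means", {
  d <- make_linear_data(n = 50, p = 10, noise = 10)
  m <- fit_penalized(d, "ridge", n_pcs = 10, folds = 5, seed = 1,
                     lambda_grid = c(1e9, 1e8))
  pred <- predict_shallow(m, d$X)
  mu <- colMeans(d$Y)
  expect_equal(pred, matrix(mu, 50, 3, byrow = TRUE), tolerance = 1e-2,
               ignore_attr = TRUE)
})
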