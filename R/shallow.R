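# Six shallow calibration baselines. Every family consumes flattened
# voltammogram heatmaps and predicts all three analytes (DA, NE, 5-HT)
# whether or not an analyte was present in training solutions.

shallow_xy <- function(train) {
  if (inherits(train, "vg_dataset")) to_feature_matrix(train)
  else if (is.list(train) && !is.null(train$X) && !is.null(train$Y)) {
    stopifnot(is.matrix(train$X), nrow(train$X) == nrow(train$Y),
              ncol(train$Y) == 3)
    train
  } else stop("train must be a vg_dataset or a list(X, Y)")
}

new_shallow_model <- function(family, fit, p, extra = list()) {
  structure(c(list(family = family, fit = fit, n_features = p), extra),
            class = c(paste0("shallow_", family), "shallow_model"))
}

analyte_names <- c("da", "ne", "ht5")

# epsilon-SVR can legitimately end up with zero support vectors (every
# residual inside the epsilon tube, e.g. constant labels or a huge epsilon
# candidate); fall back to the constant mean predictor in that case.
svm_fit_safe <- function(X, y, cost, epsilon, gamma) {
  if (stats::sd(y) == 0) return(list(constant = y[1]))
  f <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                  cost = cost, epsilon = epsilon, gamma = gamma,
                  scale = FALSE, fitted = FALSE)
  if (f$tot.nSV == 0) return(list(constant = mean(y)))
  f
}

svm_predict_safe <- function(f, X) {
  if (!is.null(f$constant)) rep(f$constant, nrow(X))
  else as.numeric(stats::predict(f, X))
}

# centered PCA helper: thin SVD of the centered feature matrix
centered_pca <- function(X) {
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc, nu = 0)
  tol <- max(dim(Xc)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  list(center = center, rotation = sv$v, d = sv$d, rank = rank)
}

#' Fit support vector regression with seeded random hyperparameter search
#'
#' One epsilon-SVR (radial-basis kernel, libsvm's dual quadratic-programming
#' solver) per analyte. The box constraint, epsilon, and kernel scale are
#' tuned by log-uniform random search — exactly `budget` candidate
#' evaluations per analyte, each scored by `folds`-fold cross-validated MSE
#' on the training set — and the best candidate is refit on the full
#' training set. Search ranges: box constraint `[1e-2, 1e3]`, epsilon
#' `[1e-2, 1e2]` nM, kernel scale `[1e-1, 1e2]` (the RBF kernel is
#' `exp(-||x - x'||^2 / scale^2)`).
#'
#' @param train a `vg_dataset` or `list(X, Y)`.
#' @param folds cross-validation folds for the search (default 5).
#' @param budget number of candidate evaluations (default 30).
#' @param seed integer seed for candidate draws and fold assignment.
#' @return a `shallow_model`; `$search` holds the per-analyte candidate log
#'   (`budget` rows each: box, epsilon, kernel_scale, cv_mse).
#' @export
fit_svr <- function(train, folds = 5, budget = 30, seed = 1) {
  if (budget < 1) stop("fit_svr: budget must be >= 1")
  xy <- shallow_xy(train)
  X <- xy$X; Y <- xy$Y
  n <- nrow(X)
  res <- with_local_seed(derive_seed(seed, "svr"), {
    cand <- data.frame(
      box = exp(stats::runif(budget, log(1e-2), log(1e3))),
      epsilon = exp(stats::runif(budget, log(1e-2), log(1e2))),
      kernel_scale = exp(stats::runif(budget, log(1e-1), log(1e2))))
    foldid <- sample(rep_len(seq_len(folds), n))
    fits <- list(); search <- list()
    for (a in seq_len(3)) {
      y <- Y[, a]
      cv_mse <- vapply(seq_len(budget), function(i) {
        errs <- vapply(seq_len(folds), function(f) {
          tr <- foldid != f
          m <- svm_fit_safe(X[tr, , drop = FALSE], y[tr],
                            cost = cand$box[i], epsilon = cand$epsilon[i],
                            gamma = 1 / cand$kernel_scale[i]^2)
          mean((svm_predict_safe(m, X[!tr, , drop = FALSE]) - y[!tr])^2)
        }, numeric(1))
        mean(errs)
      }, numeric(1))
      best <- which.min(cv_mse)
      fits[[a]] <- svm_fit_safe(X, y, cost = cand$box[best],
                                epsilon = cand$epsilon[best],
                                gamma = 1 / cand$kernel_scale[best]^2)
      search[[a]] <- cbind(cand, cv_mse = cv_mse)
    }
    list(fits = fits, search = stats::setNames(search, analyte_names))
  })
  new_shallow_model("svr", res$fits, ncol(X), list(search = res$search))
}

#' Fit principal components regression
#'
#' Centers the features, projects onto the leading principal components —
#' the smallest number whose cumulative explained variance reaches
#' `variance_target` (or an explicit `n_components`) — and regresses the
#' three labels on the scores by ordinary least squares.
#'
#' @param train a `vg_dataset` or `list(X, Y)` with >= 2 records.
#' @param variance_target cumulative explained-variance threshold in (0, 1].
#' @param n_components optional explicit component count (overrides the
#'   variance rule).
#' @return a `shallow_model` with `$n_components` the count retained.
#' @export
fit_pcr <- function(train, variance_target = 0.99, n_components = NULL) {
  xy <- shallow_xy(train)
  X <- xy$X; Y <- xy$Y
  if (nrow(X) < 2) stop("fit_pcr: need >= 2 records")
  if (!(variance_target > 0 && variance_target <= 1))
    stop("fit_pcr: variance_target must be in (0, 1]")
  pca <- centered_pca(X)
  if (is.null(n_components)) {
    cumvar <- cumsum(pca$d^2) / sum(pca$d^2)
    n_components <- which(cumvar >= variance_target)[1]
  }
  if (n_components > pca$rank)
    stop("fit_pcr: n_components exceeds feature rank ", pca$rank)
  rot <- pca$rotation[, seq_len(n_components), drop = FALSE]
  S <- sweep(X, 2, pca$center) %*% rot
  coef <- qr.coef(qr(cbind(1, S)), Y)
  new_shallow_model("pcr", list(center = pca$center, rotation = rot,
                                coef = coef),
                    ncol(X), list(n_components = n_components))
}

#' Fit partial least squares regression (PLS2, NIPALS)
#'
#' Multi-output PLS with `n_components` latent variables, fit by the NIPALS
#' algorithm on centered features and labels.
#'
#' @param train a `vg_dataset` or `list(X, Y)`.
#' @param n_components latent variables (default 7); must not exceed the
#'   rank of the centered feature matrix.
#' @return a `shallow_model` holding the coefficient matrix, loadings and
#'   weights.
#' @export
fit_plsr <- function(train, n_components = 7) {
  xy <- shallow_xy(train)
  X <- xy$X; Y <- xy$Y
  center <- colMeans(X); y_center <- colMeans(Y)
  Xc <- sweep(X, 2, center); Yc <- sweep(Y, 2, y_center)
  # rank via the (small) Gram matrix side
  g <- if (nrow(Xc) <= ncol(Xc)) tcrossprod(Xc) else crossprod(Xc)
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  rank <- sum(ev > max(ev) * max(dim(Xc)) * .Machine$double.eps)
  if (n_components > rank)
    stop("fit_plsr: n_components (", n_components,
         ") exceeds rank of centered features (", rank, ")")
  p <- ncol(X); q <- ncol(Y)
  W <- matrix(0, p, n_components); P <- matrix(0, p, n_components)
  Q <- matrix(0, q, n_components)
  Xd <- Xc; Yd <- Yc
  for (a in seq_len(n_components)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    t_old <- rep(Inf, nrow(Xd))
    for (it in seq_len(500)) {
      w <- crossprod(Xd, u); w <- w / sqrt(sum(w^2))
      t_sc <- Xd %*% w
      q_a <- crossprod(Yd, t_sc) / sum(t_sc^2)
      u <- Yd %*% q_a / sum(q_a^2)
      if (sqrt(sum((t_sc - t_old)^2)) < 1e-12 * sqrt(sum(t_sc^2))) break
      t_old <- t_sc
    }
    p_a <- crossprod(Xd, t_sc) / sum(t_sc^2)
    Xd <- Xd - t_sc %*% t(p_a)
    Yd <- Yd - t_sc %*% t(q_a)
    W[, a] <- w; P[, a] <- p_a; Q[, a] <- q_a
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  new_shallow_model("plsr", list(center = center, y_center = y_center,
                                 B = B, W = W, P = P, Q = Q),
                    ncol(X), list(n_components = n_components))
}

#' Fit lasso, ridge, or elastic-net regression on principal-component scores
#'
#' Projects the training features onto their first `min(n_pcs, rank)`
#' principal components, then fits one penalized linear model per analyte
#' with `folds`-fold cross-validation over a descending 100-point lambda
#' grid (log-spaced over four decades below the lasso-style `lambda_max`).
#' The selected lambda is the largest whose mean CV MSE is within one
#' standard error of the minimum (the 1-SE rule); the model is refit at that
#' lambda on all training data. The elastic-net mixing parameter is fixed at
#' 0.5.
#'
#' @param train a `vg_dataset` or `list(X, Y)`.
#' @param penalty `"lasso"`, `"ridge"`, or `"enet"`.
#' @param n_pcs principal components retained (default 100, capped at rank).
#' @param folds CV folds (default 20); must not exceed the record count.
#' @param seed integer seed for fold assignment.
#' @param lambda_grid optional explicit descending lambda grid (overrides the
#'   automatic path).
#' @return a `shallow_model`; `$cv_curves` holds one CV curve per analyte
#'   (lambda, mean CV MSE, SE, selected and minimizing lambda).
#' @export
fit_penalized <- function(train, penalty = c("lasso", "ridge", "enet"),
                          n_pcs = 100, folds = 20, seed = 1,
                          lambda_grid = NULL) {
  penalty <- match.arg(penalty)
  xy <- shallow_xy(train)
  X <- xy$X; Y <- xy$Y
  n <- nrow(X)
  if (folds > n) stop("fit_penalized: folds (", folds,
                      ") exceeds record count (", n, ")")
  alpha <- switch(penalty, lasso = 1, ridge = 0, enet = 0.5)
  pca <- centered_pca(X)
  k <- min(n_pcs, pca$rank)
  rot <- pca$rotation[, seq_len(k), drop = FALSE]
  S <- sweep(X, 2, pca$center) %*% rot
  foldid <- with_local_seed(derive_seed(seed, paste0("penalized:", penalty)),
                            sample(rep_len(seq_len(folds), n)))
  fits <- list(); curves <- list()
  for (a in seq_len(3)) {
    y <- Y[, a]
    if (stats::sd(y) == 0) {           # glmnet rejects constant responses
      fits[[a]] <- list(constant = y[1])
      curves[[a]] <- list(lambda = NA_real_, cvm = 0, cvsd = 0,
                          folds = folds, lambda_min = NA_real_,
                          lambda_sel = NA_real_)
      next
    }
    grid <- lambda_grid
    if (is.null(grid)) {
      lmax <- max(abs(crossprod(S, y - mean(y)))) / (n * max(alpha, 1e-3))
      if (!is.finite(lmax) || lmax <= 0) lmax <- 1  # constant label column
      grid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 100))
    }
    cv <- glmnet::cv.glmnet(S, y, alpha = alpha, lambda = grid,
                            foldid = foldid, standardize = FALSE)
    i_min <- which.min(cv$cvm)
    ok <- cv$cvm <= cv$cvm[i_min] + cv$cvsd[i_min]
    lambda_sel <- max(cv$lambda[ok])      # largest lambda within 1 SE
    fits[[a]] <- list(glmnet = cv$glmnet.fit, lambda = lambda_sel)
    curves[[a]] <- list(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
                        folds = folds, lambda_min = cv$lambda[i_min],
                        lambda_sel = lambda_sel)
  }
  new_shallow_model(penalty,
                    list(center = pca$center, rotation = rot, models = fits),
                    ncol(X),
                    list(n_components = as.integer(k),
                         cv_curves = stats::setNames(curves, analyte_names)))
}

#' Dispatch a shallow model fit by family name
#' @param train a `vg_dataset` or `list(X, Y)`.
#' @param family one of `"svr"`, `"pcr"`, `"plsr"`, `"lasso"`, `"ridge"`,
#'   `"enet"`.
#' @param seed integer seed for seeded families.
#' @param ... passed on to the family's fitting function.
#' @return a `shallow_model`.
#' @export
fit_shallow <- function(train, family = c("svr", "pcr", "plsr", "lasso",
                                          "ridge", "enet"), seed = 1, ...) {
  family <- match.arg(family)
  switch(family,
         svr = fit_svr(train, seed = seed, ...),
         pcr = fit_pcr(train, ...),
         plsr = fit_plsr(train, ...),
         fit_penalized(train, penalty = family, seed = seed, ...))
}

#' Predict concentrations from a shallow model
#'
#' Applies the fitted preprocessing (centering/loadings) and the per-analyte
#' predictors. Predictions are unconstrained: negative values are allowed,
#' matching unclamped linear/kernel regressors.
#'
#' @param m a `shallow_model`.
#' @param X matrix of flattened heatmaps (or a `vg_dataset`).
#' @return matrix `nrow(X) x 3`, columns (da, ne, ht5), in nM.
#' @export
predict_shallow <- function(m, X) {
  stopifnot(inherits(m, "shallow_model"))
  if (inherits(X, "vg_dataset")) X <- to_feature_matrix(X)$X
  if (ncol(X) != m$n_features)
    stop("predict_shallow: expected ", m$n_features, " features, got ",
         ncol(X))
  out <- switch(m$family,
    svr = vapply(m$fit, function(f) svm_predict_safe(f, X),
                 numeric(nrow(X))),
    pcr = {
      S <- sweep(X, 2, m$fit$center) %*% m$fit$rotation
      cbind(1, S) %*% m$fit$coef
    },
    plsr = sweep(sweep(X, 2, m$fit$center) %*% m$fit$B, 2, m$fit$y_center,
                 FUN = "+"),
    { # penalized families
      S <- sweep(X, 2, m$fit$center) %*% m$fit$rotation
      vapply(m$fit$models, function(f) {
        if (!is.null(f$constant)) rep(f$constant, nrow(S))
        else as.numeric(stats::predict(f$glmnet, S, s = f$lambda,
                                       exact = FALSE))
      }, numeric(nrow(X)))
    })
  out <- matrix(out, nrow = nrow(X), ncol = 3)
  colnames(out) <- analyte_names
  out
}
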