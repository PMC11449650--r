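test_that("per-analyte RMSE matches a naive loop oracle", {
  set.seed(14)
  pred <- matrix(runif(300, 0, 500), 100, 3)
  truth <- matrix(runif(300, 0, 500), 100, 3)
  r <- rmse_per_analyte(pred, truth)
  oracle <- numeric(3)
  for (a in 1:3) {
    s <- 0
    for (i in 1:100) s <- s + (pred[i, a] - truth[i, a])^2
    oracle[a] <- sqrt(s / 100)
  }
  expect_equal(unname(r), oracle, tolerance = 1e-12)
  # exactness and permutation invariance
  expect_equal(unname(rmse_per_analyte(truth, truth)), c(0, 0, 0))
  perm <- sample(100)
  expect_equal(rmse_per_analyte(pred[perm, ], truth[perm, ]), r)
  # worked residual example: residuals (3, 4) -> sqrt(12.5)
  p2 <- matrix(0, 2, 3); t2 <- matrix(0, 2, 3)
  p2[, 1] <- c(3, 4)
  expect_equal(unname(rmse_per_analyte(p2, t2))[1], sqrt(12.5))
  expect_error(rmse_per_analyte(matrix(0, 0, 3), matrix(0, 0, 3)), "empty")
})

test_that("one-way ANOVA and Levene match hand-computed sums of squares", {
  g <- list(a = c(1, 2, 3, 2), b = c(4, 5, 6, 5), c = c(2, 2, 3, 3))
  res <- compare_errors(g, "one_way", variance_test = TRUE)
  # brute-force fixed-effects oracle
  all_v <- unlist(g)
  grand <- mean(all_v)
  ss_between <- sum(vapply(g, function(x) length(x) * (mean(x) - grand)^2,
                           numeric(1)))
  ss_within <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  F_oracle <- (ss_between / 2) / (ss_within / 9)
  p_oracle <- stats::pf(F_oracle, 2, 9, lower.tail = FALSE)
  expect_equal(res$anova$F, F_oracle, tolerance = 1e-10)
  expect_equal(res$anova$p, p_oracle, tolerance = 1e-10)
  # Levene (median-centered) oracle
  adev <- lapply(g, function(x) abs(x - stats::median(x)))
  alld <- unlist(adev); grd <- mean(alld)
  ssb <- sum(vapply(adev, function(x) length(x) * (mean(x) - grd)^2,
                    numeric(1)))
  ssw <- sum(vapply(adev, function(x) sum((x - mean(x))^2), numeric(1)))
  expect_equal(res$levene$statistic, (ssb / 2) / (ssw / 9), tolerance = 1e-10)
  # identical groups: F = 0, p = 1; Levene statistic 0
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  res0 <- compare_errors(same, "one_way", variance_test = TRUE)
  expect_equal(res0$anova$F, 0)
  expect_equal(res0$anova$p, 1)
  expect_equal(res0$levene$statistic, 0)
  expect_error(compare_errors(list(a = 1:3), "one_way"), "groups")
  expect_error(compare_errors(list(a = 1, b = 1:3), "one_way"), ">= 2 values")
})

test_that("two-way ANOVA reports model and analyte effects on absolute
           errors", {
  set.seed(3)
  df <- expand.grid(model = c("m1", "m2", "m3"),
                    analyte = c("da", "ne", "ht5"), rep = 1:6)
  df$error <- rnorm(nrow(df)) + (df$model == "m1") * 2
  res <- compare_errors(df[, c("error", "model", "analyte")], "two_way")
  expect_setequal(res$anova$term, c("model", "analyte", "model:analyte"))
  expect_true(all(is.finite(res$anova$F)))
  # oracle: same F values from lm/anova on |error|
  df$abs_err <- abs(df$error)
  ref <- stats::anova(stats::lm(abs_err ~ model * analyte, data = df))
  expect_equal(res$anova$F, ref[["F value"]][1:3], tolerance = 1e-10)
})

test_that("the validation mixture set contains the eight three-analyte
           solutions", {
  m <- validation_mixtures()
  expect_equal(dim(m), c(8, 3))
  expect_equal(unname(m[1, ]), c(100, 250, 500))
  expect_true(all(m > 0))           # every mixture contains all three
  expect_equal(anyDuplicated(m), 0)
})
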