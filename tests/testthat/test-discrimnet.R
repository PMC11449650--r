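# Network mechanics: architecture validation, gradient correctness against
# finite differences, weight transfer and predictor assembly identities,
# and the training-schedule contract. Training runs here are tiny smoke
# probes on 8 x 16 heatmaps.

test_that("architecture invariants are enforced at build time", {
  a <- tiny_arch()
  expect_lt(prod(a$latent_shape[1:2]), prod(a$input_shape))
  expect_identical(utils::tail(a$head_units, 1), 3L)
  # shape arithmetic that cannot return to the input is rejected
  expect_error(arch_config(input_shape = c(30, 64)), "divisible")
  expect_error(arch_config(head_units = c(16, 2)), "width must be 3")
  expect_error(arch_config(enc_filters = c(8, 16), dec_filters = c(8)),
               "mirror")
})

test_that("analytic gradients match finite differences through every layer
           type", {
  arch <- arch_config(input_shape = c(8, 16), enc_filters = c(3, 4),
                      dec_filters = c(3, 2), head_units = c(5, 3),
                      dropout = 0, depth_multiplier = 2)
  w <- tonicnet:::init_weights(arch, seed = 7, with_head = TRUE)
  set.seed(42)
  X <- array(runif(8 * 16 * 4), dim = c(8, 16, 4))
  Y <- matrix(runif(12), 4, 3)
  lg <- tonicnet:::dn_lossgrad_cpp(w, unclass(arch), X, Y, TRUE, TRUE, 1, 1)
  eps <- 1e-5
  for (nm in c("enc0_dw", "enc0_pw", "enc1_gamma", "enc1_beta", "head0_W",
               "head1_b", "dec0_W", "dec1_b", "out_W")) {
    set.seed(nchar(nm))
    for (i in sample(length(w[[nm]]), min(3, length(w[[nm]])))) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      fd <- (tonicnet:::dn_lossgrad_cpp(wp, unclass(arch), X, Y, TRUE, TRUE,
                                        1, 1)$loss -
             tonicnet:::dn_lossgrad_cpp(wm, unclass(arch), X, Y, TRUE, TRUE,
                                        1, 1)$loss) / (2 * eps)
      an <- lg$grads[[nm]][i]
      # tolerance allows for ReLU/max-pool kink crossings under the
      # finite-difference step; a wrong gradient shows errors of order 1
      expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-2)
    }
  }
})

test_that("phase-1 training respects the epoch cap and reduces the loss on
           an overfit probe", {
  train <- tiny_norm_dataset()
  sub <- tonicnet:::dataset_subset(train, 1:40)
  net <- build_autoencoder(tiny_arch(), TRUE, seed = 3)
  t <- training_config(max_epochs = 12, batch_size = 8, initial_lr = 3e-3,
                       seed = 5)
  ph <- train_phase1(net, sub, t)
  h <- ph$history
  expect_lte(nrow(h), 12)
  expect_lt(utils::tail(h$train_total, 1), h$train_total[1])
  expect_identical(ph$weights$phase, 1L)
  expect_s3_class(ph$weights$norm_map, "norm_map")
  # unnormalized input is rejected (cross-entropy needs [0, 1] pixels)
  raw <- suppressWarnings(
    prepare_invitro_dataset(seed = 77, n_electrodes = 1,
                            scans_per_solution = 1, spec = short_spec()))
  expect_error(train_phase1(net, raw, t), "normalized")
})

test_that("the recorded learning-rate sequence follows reduce-on-plateau
           with early stopping", {
  train <- tiny_norm_dataset()
  net <- build_autoencoder(tiny_arch(), TRUE, seed = 11)
  t <- training_config(max_epochs = 20, batch_size = 8, initial_lr = 1e-2,
                       lr_patience = 2, stop_patience = 8, seed = 13)
  h <- train_phase1(net, train, t)$history
  # independent replay of the schedule from the recorded validation losses
  lr <- t$initial_lr; best <- Inf; wait <- 0; stop_wait <- 0
  expected_lr <- numeric(0)
  for (v in h$val_total) {
    expected_lr <- c(expected_lr, lr)
    if (v < best - 1e-12) { best <- v; wait <- 0; stop_wait <- 0 }
    else {
      wait <- wait + 1; stop_wait <- stop_wait + 1
      if (wait >= t$lr_patience) { lr <- max(lr / t$lr_factor, t$lr_min); wait <- 0 }
      if (stop_wait >= t$stop_patience) break
    }
  }
  expect_equal(h$lr, expected_lr)
  expect_lte(nrow(h), 20)
  # learning rate never falls below the floor
  expect_true(all(h$lr >= t$lr_min))
})

test_that("weight transfer is bitwise, idempotent, and head-free for
           phase 2", {
  train <- tiny_norm_dataset()
  arch <- tiny_arch()
  net <- build_autoencoder(arch, TRUE, seed = 3)
  ph1 <- train_phase1(net, train,
                      training_config(max_epochs = 3, batch_size = 8,
                                      seed = 5))
  net2 <- build_autoencoder(arch, FALSE, seed = 4)
  expect_false(any(startsWith(names(net2$weights), "head")))
  tr1 <- transfer_weights(ph1$weights, net2)
  for (nm in names(tr1$weights))
    expect_identical(tr1$weights[[nm]], ph1$weights$weights[[nm]])
  tr2 <- transfer_weights(ph1$weights, tr1)
  expect_identical(tr2$weights, tr1$weights)
  # shape mismatch names the offending layer
  bad <- ph1$weights
  bad$weights$enc0_pw <- matrix(0, 5, 5)
  expect_error(transfer_weights(bad, net2), "enc0_pw")
})

test_that("phase 2 trains reconstruction only and is a no-op at zero
           epochs", {
  train <- tiny_norm_dataset()
  arch <- tiny_arch()
  ph1 <- train_phase1(build_autoencoder(arch, TRUE, seed = 3), train,
                      training_config(max_epochs = 3, batch_size = 8,
                                      seed = 5))
  vivo <- suppressWarnings(
    prepare_invivo_corpus(seed = 21, n_electrodes = 2,
                          minutes_per_session = 3, spec = short_spec()))
  vivo_n <- normalize_dataset(vivo, ph1$weights$norm_map)
  net2 <- transfer_weights(ph1$weights,
                           build_autoencoder(arch, FALSE, seed = 4))
  # zero-epoch limit: output weights equal the transferred weights
  ph0 <- train_phase2(net2, vivo_n, training_config(max_epochs = 0,
                                                    batch_size = 8))
  expect_identical(ph0$weights$weights, net2$weights)
  ph2 <- train_phase2(net2, vivo_n,
                      training_config(max_epochs = 6, batch_size = 8,
                                      seed = 9))
  expect_false("val_reg" %in% names(ph2$history))
  expect_false("train_reg" %in% names(ph2$history))
  expect_lte(utils::tail(ph2$history$val_rec, 1), ph2$history$val_rec[1])
  # a labeled (non-latent) dataset triggers the labels-ignored notice
  expect_message(train_phase2(net2, train,
                              training_config(max_epochs = 1,
                                              batch_size = 8)),
                 "ignored")
})

test_that("the assembled predictor takes encoder weights from phase 2 and
           head weights from phase 1", {
  train <- tiny_norm_dataset()
  arch <- tiny_arch()
  ph1 <- train_phase1(build_autoencoder(arch, TRUE, seed = 3), train,
                      training_config(max_epochs = 3, batch_size = 8,
                                      seed = 5))
  vivo <- normalize_dataset(
    suppressWarnings(prepare_invivo_corpus(seed = 21, n_electrodes = 2,
                                           minutes_per_session = 3,
                                           spec = short_spec())),
    ph1$weights$norm_map)
  net2 <- transfer_weights(ph1$weights,
                           build_autoencoder(arch, FALSE, seed = 4))
  ph2 <- train_phase2(net2, vivo, training_config(max_epochs = 4,
                                                  batch_size = 8, seed = 9))
  pred <- build_predictor(ph1$weights, ph2$weights)
  for (nm in names(pred$weights)) {
    if (startsWith(nm, "enc"))
      expect_identical(pred$weights[[nm]], ph2$weights$weights[[nm]])
    if (startsWith(nm, "head"))
      expect_identical(pred$weights[[nm]], ph1$weights$weights[[nm]])
  }
  expect_false(any(startsWith(names(pred$weights), "dec")))
  expect_error(build_predictor(ph2$weights, ph1$weights), "phase")

  # prediction contract: stored normalization, 3 non-negative columns,
  # deterministic inference
  hold <- suppressWarnings(
    prepare_invivo_corpus(seed = 55, n_electrodes = 1,
                          minutes_per_session = 2, spec = short_spec()))
  p1 <- predict_discrimnet(pred, hold)
  p2 <- predict_discrimnet(pred, hold)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(length(hold), 3))
  expect_true(all(p1 >= 0))
  expect_identical(colnames(p1), c("da", "ne", "ht5"))
})
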