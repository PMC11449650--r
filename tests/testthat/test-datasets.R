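test_that("within-electrode splitting reproduces the 80/20 record counts", {
  hms <- fake_heatmaps(11350, electrode_ids = rep(paste0("e", 1:12),
                                                  length.out = 11350))
  d <- as_dataset(hms)
  sp <- split_dataset(d, split_spec("within", train_fraction = 0.8, seed = 1))
  expect_length(sp$train, 9080)
  expect_length(sp$test, 2270)
})

test_that("splits partition the records exactly and are seed-reproducible", {
  hms <- fake_heatmaps(101, electrode_ids = rep(paste0("e", 1:5),
                                                length.out = 101))
  d <- as_dataset(hms)
  for (mode in c("within", "across")) {
    s <- split_spec(mode, held_out_electrodes = 2, seed = 7)
    sp <- split_dataset(d, s)
    got <- sort(c(vapply(sp$train$heatmaps, function(h) h$grid[1, 1],
                         numeric(1)),
                  vapply(sp$test$heatmaps, function(h) h$grid[1, 1],
                         numeric(1))))
    expect_equal(got, as.numeric(seq_len(101)))   # union = input, no overlap
    sp2 <- split_dataset(d, s)
    expect_identical(sp$train$electrode_ids, sp2$train$electrode_ids)
    expect_identical(sp$test$labels, sp2$test$labels)
  }
  # across mode: electrode sets disjoint
  sp <- split_dataset(d, split_spec("across", held_out_electrodes = 2,
                                    seed = 3))
  expect_length(intersect(unique(sp$train$electrode_ids),
                          unique(sp$test$electrode_ids)), 0)
  # too few electrodes
  d2 <- as_dataset(fake_heatmaps(10, electrode_ids = rep(c("a", "b"), 5)))
  expect_error(split_dataset(d2, split_spec("across",
                                            held_out_electrodes = 2)),
               "electrodes")
})

test_that("feature matrices flatten heatmaps row-major with fixed label order", {
  spec <- tiny_spec()
  v <- voltammogram(seq_len(32), "e1", spec, label = conc_triple(10, 20, 30))
  d <- as_dataset(list(reshape_heatmap(v)))
  xy <- to_feature_matrix(d)
  expect_equal(dim(xy$X), c(1, 32))
  expect_equal(xy$X[1, ], as.numeric(1:32))
  expect_identical(colnames(xy$Y), c("da", "ne", "ht5"))
  expect_equal(xy$Y[1, ], c(da = 10, ne = 20, ht5 = 30))
  expect_false(any(d$labels < 0))
})

test_that("datasets reject mixed shapes and normalization states", {
  spec <- tiny_spec()
  h1 <- reshape_heatmap(voltammogram(seq_len(32), "e1", spec))
  h2 <- h1; h2$grid <- h2$grid[, 1:4]
  expect_error(as_dataset(list(h1, h2)), "mixed grid shapes")
  h3 <- normalize_heatmap(h1, structure(list(lo = 0, hi = 40),
                                        class = "norm_map"))
  expect_error(as_dataset(list(h1, h3)), "normalization")
})
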