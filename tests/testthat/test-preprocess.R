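test_that("background subtraction removes the capacitive current to within
           the residual bound on every electrode of a seeded population", {
  spec <- waveform_spec()
  blank <- solution_spec()
  for (el in sample_electrodes(10, "in_vitro", seed = 31)) {
    el$noise_sd <- 0
    v <- simulate_voltammogram(blank, el, spec, seed = 1)
    res <- subtract_background(v)
    bg <- background_current(el, spec, blank)
    expect_lt(max(abs(res$trace)), 1e-3 * max(abs(bg)))
    expect_length(res$trace, length(v$trace))
  }
})

test_that("background subtraction ignores signal confined to early samples", {
  # a perturbation supported outside the fitted tail must not change the
  # fitted background: residuals shift by exactly that perturbation
  spec <- waveform_spec()
  el <- ref_electrode(noise_sd = 0)
  v <- simulate_voltammogram(solution_spec(), el, spec, seed = 1)
  hl <- spec$samples_per_step / (2 * spec$cycles_per_step)   # 16
  within <- rep(seq_len(hl), times = trace_length(spec) / hl)
  f <- ifelse(within <= 4, 5.0, 0)     # early-sample bump, zero on the tail
  v_f <- v; v_f$trace <- v$trace + f
  r0 <- subtract_background(v)
  r1 <- subtract_background(v_f)
  expect_equal(r1$trace - f, r0$trace, tolerance = 1e-9)
})

test_that("degenerate background fits fall back to the tail median with a
           warning", {
  spec <- tiny_spec()
  v <- voltammogram(rep(0, trace_length(spec)), "e1", spec)
  expect_warning(res <- subtract_background(v), "degenerate")
  expect_equal(res$trace, rep(0, trace_length(spec)))
})

test_that("temporal averaging is a moving mean over consecutive scans", {
  spec <- tiny_spec()
  mk <- function(x, id = "e1") voltammogram(rep(x, trace_length(spec)), id, spec)
  scans <- list(mk(1), mk(3), mk(5))
  expect_identical(temporal_average(scans, 1), scans)
  out <- temporal_average(scans, 2)
  expect_length(out, 2)
  expect_equal(out[[1]]$trace, rep(2, trace_length(spec)))
  expect_equal(out[[2]]$trace, rep(4, trace_length(spec)))
  expect_error(temporal_average(list(mk(1), mk(1, "e2")), 2), "electrode")
})

test_that("heatmap reshape is the row-major inverse of the trace", {
  spec <- tiny_spec()
  v <- voltammogram(seq_len(32), "e1", spec, label = conc_triple(1, 2, 3))
  h <- reshape_heatmap(v)
  expect_equal(dim(h$grid), c(4, 8))
  expect_equal(h$grid[1, ], 1:8)
  expect_equal(h$grid[3, 2], 18)
  expect_equal(flatten_heatmap(h), as.numeric(1:32))
  bad <- v; bad$trace <- bad$trace[-1]
  expect_error(reshape_heatmap(bad), "32")
})

test_that("normalization is a reference-set affine map with clipping", {
  spec <- tiny_spec()
  h1 <- reshape_heatmap(voltammogram(seq(0, 10, length.out = 32), "e1", spec))
  h2 <- reshape_heatmap(voltammogram(seq(-2, 5, length.out = 32), "e1", spec))
  m <- fit_normalization(list(h1, h2))
  # brute-force oracle over the concatenated grids
  allv <- c(h1$grid, h2$grid)
  expect_equal(m$lo, min(allv))
  expect_equal(m$hi, max(allv))
  expect_identical(fit_normalization(list(h2, h1)), m)
  n1 <- normalize_heatmap(h1, m)
  expect_true(n1$normalized)
  expect_true(all(n1$grid >= 0 & n1$grid <= 1))
  # pointwise map and clipping
  m0 <- structure(list(lo = 0, hi = 10), class = "norm_map")
  g <- normalize_heatmap(reshape_heatmap(
    voltammogram(c(5, 12, rep(0, 30)), "e1", spec)), m0)$grid
  expect_equal(g[1, 1], 0.5)
  expect_equal(g[1, 2], 1.0)
  # monotone non-decreasing in the input
  x <- sort(runif(32, -5, 15))
  gx <- normalize_heatmap(reshape_heatmap(voltammogram(x, "e", spec)), m0)$grid
  expect_true(all(diff(as.vector(t(gx))) >= 0))
  expect_error(fit_normalization(list()), "empty")
  h_const <- reshape_heatmap(voltammogram(rep(1, 32), "e1", spec))
  expect_error(fit_normalization(list(h_const)), "degenerate")
})
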