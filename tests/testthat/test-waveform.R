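test_that("waveform has the staircase + square-wave structure", {
  spec <- tiny_spec()
  E <- build_waveform(spec)
  expect_length(E, 4 * 8)
  # within any step the mean over one full square-wave cycle is the baseline
  base <- spec$e_min + (0:3) * (spec$e_max - spec$e_min) / 3
  M <- matrix(E, nrow = 8)
  cyc <- M[1:4, ]                      # one full cycle (2 samples per half)
  expect_equal(colMeans(cyc), base, tolerance = 1e-12)
  # square wave symmetric around baseline
  expect_equal(M[1, ] - base, rep(spec$sw_amplitude, 4))
  expect_equal(M[3, ] - base, rep(-spec$sw_amplitude, 4))
  # full trace length identity at the default desk scale
  expect_length(build_waveform(waveform_spec()), 64 * 32)
})

test_that("waveform validation names the violated invariant", {
  expect_error(waveform_spec(n_steps = 1), "n_steps")
  expect_error(waveform_spec(samples_per_step = 10, cycles_per_step = 3),
               "divisible")
  expect_error(waveform_spec(e_min = 0.5, e_max = 0.1), "e_min")
})

test_that("acquisition-scale geometry and scan period match the instrument", {
  fs <- full_scale_waveform()
  expect_identical(trace_length(fs), 128L * 45000L)
  expect_equal(scan_period(fs), 10)
})
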