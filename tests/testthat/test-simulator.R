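test_that("faradaic response is zero without analytes and superposes linearly", {
  spec <- short_spec()
  el <- ref_electrode()
  expect_equal(faradaic_current(solution_spec(), el, spec),
               rep(0, trace_length(spec)))
  f_da <- faradaic_current(solution_spec(conc_triple(100, 0, 0)), el, spec)
  f_ne <- faradaic_current(solution_spec(conc_triple(0, 250, 0)), el, spec)
  f_mix <- faradaic_current(solution_spec(conc_triple(100, 250, 0)), el, spec)
  expect_equal(f_mix, f_da + f_ne, tolerance = 1e-9)
  # linearity in concentration: doubling DA doubles its contribution
  f_da2 <- faradaic_current(solution_spec(conc_triple(200, 0, 0)), el, spec)
  expect_equal(f_da2, 2 * f_da, tolerance = 1e-12)
})

test_that("background current matches the closed-form superposition of
           transition tails", {
  spec <- tiny_spec()
  el <- ref_electrode()
  sol <- solution_spec()
  bg <- background_current(el, spec, sol)
  # brute-force oracle: every transition contributes scale*dE*exp(-t'/tau)
  E <- build_waveform(spec)
  dE <- c(E[1] - spec$e_min, diff(E))
  dt <- scan_period(spec) / trace_length(spec)
  oracle <- numeric(length(E))
  for (j in seq_along(E)) {
    if (dE[j] == 0) next
    idx <- j:length(E)
    oracle[idx] <- oracle[idx] +
      el$background_scale * dE[j] * exp(-(idx - j) * dt / el$rc_tau)
  }
  expect_equal(bg, oracle, tolerance = 1e-10)
  # exponential decay within a half-cycle: last sample smaller than first
  hl <- trace_length(spec) / (2 * spec$cycles_per_step * spec$n_steps)
  M <- matrix(bg, nrow = hl)
  expect_true(all(abs(M[hl, ]) < abs(M[1, ])))
  # doubling the square-wave amplitude doubles the background at samples
  # whose contributions are all square-wave transitions (sample 3: initial
  # +A tail and the fresh -2A transition, both proportional to amplitude)
  spec2 <- tiny_spec(); spec2$sw_amplitude <- 2 * spec$sw_amplitude
  bg2 <- background_current(el, spec2, sol)
  expect_equal(bg2[3], 2 * bg[3], tolerance = 1e-12)
})

test_that("simulated voltammograms are seeded and reproducible", {
  spec <- short_spec()
  el <- ref_electrode(noise_sd = 0.05)
  sol <- solution_spec(conc_triple(100, 250, 500))
  v1 <- simulate_voltammogram(sol, el, spec, seed = 7)
  v2 <- simulate_voltammogram(sol, el, spec, seed = 7)
  v3 <- simulate_voltammogram(sol, el, spec, seed = 8)
  expect_identical(v1$trace, v2$trace)
  expect_false(identical(v1$trace, v3$trace))
  # noise-free trace equals faradaic + background exactly
  el0 <- ref_electrode(noise_sd = 0)
  v0 <- simulate_voltammogram(sol, el0, spec, seed = 1)
  expect_equal(v0$trace,
               faradaic_current(sol, el0, spec) +
                 background_current(el0, spec, sol))
  # a 5-HT-containing mixture adds exactly the 5-HT response
  va <- simulate_voltammogram(solution_spec(conc_triple(100, 250, 0)),
                              el0, spec, seed = 1)
  diff_tr <- v0$trace - va$trace
  expect_equal(diff_tr,
               faradaic_current(solution_spec(conc_triple(0, 0, 500)),
                                el0, spec),
               tolerance = 1e-9)
  expect_gt(max(abs(diff_tr)), 0)
})

test_that("electrode populations are seeded, domain-tagged, and disjoint", {
  vitro <- sample_electrodes(12, "in_vitro", seed = 3)
  expect_length(vitro, 12)
  expect_true(all(vapply(vitro, function(e) e$biofouling, numeric(1)) == 1))
  ids <- vapply(vitro, function(e) e$electrode_id, character(1))
  expect_false(anyDuplicated(ids) > 0)
  vitro2 <- sample_electrodes(12, "in_vitro", seed = 3)
  expect_identical(vitro, vitro2)
  vivo <- sample_electrodes(4, "in_vivo", seed = 3)
  expect_length(intersect(ids, vapply(vivo, function(e) e$electrode_id,
                                      character(1))), 0)
  expect_true(all(vapply(vivo, function(e) e$biofouling, numeric(1)) < 1))
})

test_that("DA and NE traces are mutually confusable while 5-HT is distinct", {
  spec <- waveform_spec()
  el <- ref_electrode()
  shape <- function(conc) {
    x <- faradaic_current(solution_spec(conc), el, spec)
    (x - min(x)) / (max(x) - min(x))
  }
  cos_dist <- function(a, b) 1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  s_da <- shape(conc_triple(500, 0, 0))
  s_ne <- shape(conc_triple(0, 500, 0))
  s_ht <- shape(conc_triple(0, 0, 100))
  expect_lt(cos_dist(s_da, s_ne), cos_dist(s_da, s_ht))
})

test_that("drug timecourses encode the expected pharmacology", {
  sc <- pharm_scenario("cocaine")
  t_grid <- seq(0, 60, by = 1 / 6)
  tc <- pharm_timecourse(sc, t_grid)
  # at administration time the concentration is exactly baseline
  expect_equal(tc[t_grid == sc$t_admin, ], unclass(sc$baseline),
               ignore_attr = TRUE)
  rise <- sweep(tc, 2, unclass(sc$baseline))
  expect_gt(max(rise[, "da"]), max(rise[, "ht5"]))
  expect_gt(max(rise[, "ht5"]), 0)
  expect_equal(max(abs(rise[, "ne"])), 0)
  # none scenario is constant baseline
  tc0 <- pharm_timecourse(pharm_scenario("none"), t_grid)
  expect_true(all(tc0 == rep(unclass(sc$baseline), each = length(t_grid))))
  # invalid drug scenario is rejected
  expect_error(pharm_scenario("cocaine", delta_peak = conc_triple(10, 0, 50)),
               "DA > 5-HT")
  expect_error(pharm_scenario("cocaine", delta_peak = conc_triple(100, 5, 50)),
               "NE")
})

test_that("in-vivo sessions have one scan per period with latent labels", {
  spec <- short_spec()
  el <- sample_electrodes(1, "in_vivo", seed = 5)[[1]]
  sc <- pharm_scenario("cocaine", session_length = 50)
  scans <- simulate_session(sc, el, spec, seed = 2)
  expect_length(scans, 50 * 60 * spec$scan_repetition_rate)  # 300 at 0.1 Hz
  expect_true(all(vapply(scans, function(s) s$electrode_id, character(1)) ==
                    el$electrode_id))
  expect_true(all(vapply(scans, function(s) s$latent, logical(1))))
  pre <- Filter(function(s) s$t / 60 < sc$t_admin, scans)
  labs <- unique(t(vapply(pre, function(s) unclass(s$label), numeric(3))))
  expect_equal(nrow(labs), 1)
  expect_equal(as.numeric(labs), as.numeric(sc$baseline))
})
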