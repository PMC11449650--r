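# Small shared fixtures. Everything is generated in code at test time.

tiny_spec <- function() {
  waveform_spec(n_steps = 4, samples_per_step = 8, cycles_per_step = 2)
}

# desk-scale spec but shorter trace, for preprocessing tests
short_spec <- function() {
  waveform_spec(n_steps = 8, samples_per_step = 16, cycles_per_step = 2)
}

ref_electrode <- function(noise_sd = 0, domain = "in_vitro", ...) {
  electrode_profile(electrode_id = "ref", noise_sd = noise_sd,
                    domain = domain, ...)
}

# lightweight labeled heatmaps without running the simulator (for split /
# dataset mechanics on large N)
fake_heatmaps <- function(n, electrode_ids = rep("e1", n), value = NULL) {
  lapply(seq_len(n), function(i) {
    structure(list(grid = matrix(if (is.null(value)) i else value, 1, 2),
                   electrode_id = electrode_ids[i],
                   label = conc_triple(i %% 7, 0, 1), latent = FALSE,
                   t = 0, normalized = FALSE),
              class = "vg_heatmap")
  })
}

# memoised small simulated dataset shared by slower tests
local_sim_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(
        prepare_invitro_dataset(seed = 404, n_electrodes = 2,
                                scans_per_solution = 1,
                                spec = short_spec()))
    cache
  }
})

# tiny network fixtures shared by the network and acceptance tests
tiny_arch <- function(...) {
  arch_config(input_shape = c(8, 16), enc_filters = c(4, 6),
              dec_filters = c(4, 4), head_units = c(8, 3),
              depth_multiplier = 2, ...)
}

tiny_norm_dataset <- function(n_electrodes = 2, scans = 2, seed = 77) {
  # the toy 8 x 16 geometry leaves few tail samples per half-cycle, so
  # degenerate-fit fallbacks (a warned, handled condition) are routine here
  d <- suppressWarnings(
    prepare_invitro_dataset(seed = seed, n_electrodes = n_electrodes,
                            scans_per_solution = scans,
                            spec = short_spec()))
  normalize_dataset(d, fit_normalization(d$heatmaps))
}

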