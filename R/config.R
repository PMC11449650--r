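# Structured run configuration: one YAML file drives simulation,
# preprocessing, splitting, model fitting and training.

default_run_config <- function() {
  list(
    seed = 1L,
    simulator = list(
      n_electrodes = 6L, domain = "in_vitro", scans_per_solution = 3L,
      n_steps = 64L, samples_per_step = 32L, cycles_per_step = 2L,
      e_min = -0.1, e_max = 0.9, sw_amplitude = 0.1,
      scan_repetition_rate = 0.1, full_scale = FALSE),
    preprocess = list(fit_fraction = 0.25, window = 1L),
    split = list(mode = "within", train_fraction = 0.8,
                 held_out_electrodes = 1L),
    model = list(family = "svr", n_components = 7L, n_pcs = 100L,
                 svr_folds = 5L, svr_budget = 30L, penalized_folds = 20L),
    training = list(initial_lr = 3e-3, lr_patience = 3L, lr_factor = 10,
                    lr_min = 1e-6, max_epochs = 50L, stop_patience = 20L,
                    batch_size = 8L, val_fraction = 0.15,
                    loss_weights = c(1, 1)),
    scenario = list(drug = "cocaine", t_admin = 27, session_length = 60))
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(base))
      stop("unknown config key: ", paste0(path, nm))
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("config key ", paste0(path, nm), " must be a section")
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste0(path, nm, "."))
    } else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read a run configuration
#'
#' Loads a YAML run configuration, merges it over the documented defaults,
#' and rejects unknown keys. `NULL` returns the defaults.
#'
#' @param path YAML file path, or `NULL`.
#' @return a validated `run_config` list with sections `simulator`,
#'   `preprocess`, `split`, `model`, `training`, `scenario` and a global
#'   `seed`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  structure(cfg, class = "run_config")
}

config_waveform <- function(cfg) {
  s <- cfg$simulator
  if (isTRUE(s$full_scale)) return(full_scale_waveform())
  waveform_spec(e_min = s$e_min, e_max = s$e_max, n_steps = s$n_steps,
                samples_per_step = s$samples_per_step,
                sw_amplitude = s$sw_amplitude,
                cycles_per_step = s$cycles_per_step,
                scan_repetition_rate = s$scan_repetition_rate)
}

config_hash <- function(cfg) {
  txt <- yaml::as.yaml(unclass(cfg))
  codes <- utf8ToInt(txt)
  h <- 5381
  for (c in codes) h <- (h * 33 + c) %% 2^31
  sprintf("%08x", h)
}
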