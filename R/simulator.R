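#' @useDynLib tonicnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run expr with a private RNG stream so generators are pure functions of
# (arguments, seed) and never disturb the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a global seed
#'
#' Single global seeds are expanded into independent per-stage streams by
#' hashing the stage name into an offset: `(seed * 2654435761 + sum of the
#' stage name's character codes) mod (2^31 - 1)`. Documented so runs are
#' reproducible across sessions.
#'
#' @param seed integer global seed.
#' @param stage character stage tag, e.g. `"simulate"`, `"split"`.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage))
  as.integer((as.numeric(seed) %% 65536 * 2654435761 + h) %% (2^31 - 1))
}

# Analytes --------------------------------------------------------------------

#' Analyte response models
#'
#' Redox peak parameters for the three monoamines. Dopamine (DA) and
#' norepinephrine (NE) are structurally similar catechols and oxidize at
#' nearly identical potentials (12 mV apart here, far less than the 50 mV
#' peak width), which is what makes their voltammograms nearly
#' indistinguishable; serotonin (5-HT) oxidizes at a clearly separated
#' potential. Reduction peaks sit 80 mV cathodic of the oxidation peaks.
#'
#' @param name one of `"DA"`, `"NE"`, `"5HT"`.
#' @return An `analyte_model` list with fields `name`, `e_ox`, `e_red`,
#'   `peak_width`, `sensitivity_ref` (nA/nM), `adsorption_tau` (s),
#'   `asymmetry`.
#' @export
analyte_model <- function(name = c("DA", "NE", "5HT")) {
  name <- match.arg(name)
  p <- switch(name,
    DA  = list(e_ox = 0.650, peak_width = 0.05, sensitivity_ref = 0.020,
               adsorption_tau = 0.10, asymmetry = 0.5),
    NE  = list(e_ox = 0.662, peak_width = 0.05, sensitivity_ref = 0.018,
               adsorption_tau = 0.10, asymmetry = 0.5),
    `5HT` = list(e_ox = 0.580, peak_width = 0.05, sensitivity_ref = 0.024,
               adsorption_tau = 0.08, asymmetry = 1.0))
  structure(c(list(name = name), p, list(e_red = p$e_ox - 0.08)),
            class = "analyte_model")
}

analyte_panel <- function() {
  list(da = analyte_model("DA"), ne = analyte_model("NE"),
       ht5 = analyte_model("5HT"))
}

# Concentrations and solutions ------------------------------------------------

#' Concentration triple (DA, NE, 5-HT)
#'
#' @param da,ne,ht5 concentrations in nM; all must be >= 0.
#' @return a named numeric vector of class `conc_triple`, order fixed as
#'   (DA, NE, 5-HT).
#' @export
conc_triple <- function(da = 0, ne = 0, ht5 = 0) {
  x <- c(da = as.numeric(da), ne = as.numeric(ne), ht5 = as.numeric(ht5))
  if (any(!is.finite(x)) || any(x < 0))
    stop("conc_triple: concentrations must be finite and >= 0")
  structure(x, class = "conc_triple")
}

#' Solution specification
#'
#' An in-vitro (or emulated in-vivo) solution: the three monoamine
#' concentrations plus an optional interferent panel. Interferents carry no
#' Faradaic signature in M-CSWV voltammograms; they only perturb the
#' capacitive background slightly (see [background_current()]).
#'
#' @param conc a [conc_triple()] (nM).
#' @param adenosine,ascorbic_acid,hva,dopac,uric_acid interferent
#'   concentrations in uM.
#' @param delta_ph pH change relative to physiological buffer (pH units).
#' @return a `solution_spec` list.
#' @export
solution_spec <- function(conc = conc_triple(), adenosine = 0,
                          ascorbic_acid = 0, hva = 0, dopac = 0,
                          uric_acid = 0, delta_ph = 0) {
  if (!inherits(conc, "conc_triple")) conc <- do.call(conc_triple, as.list(conc))
  inter <- c(adenosine = adenosine, ascorbic_acid = ascorbic_acid, hva = hva,
             dopac = dopac, uric_acid = uric_acid, delta_ph = delta_ph)
  if (any(!is.finite(inter))) stop("solution_spec: non-finite interferent value")
  structure(list(conc = conc, interferents = inter), class = "solution_spec")
}

#' The standard interferent selectivity panel
#'
#' Physiological interferent challenges used for selectivity validation:
#' adenosine 1 uM, ascorbic acid 200 uM, HVA 20 uM, DOPAC 20 uM, uric acid
#' 100 uM, and a pH change of -0.2.
#'
#' @return named list of interferent argument lists for [solution_spec()].
#' @export
interferent_panel <- function() {
  list(adenosine     = list(adenosine = 1),
       ascorbic_acid = list(ascorbic_acid = 200),
       hva           = list(hva = 20),
       dopac         = list(dopac = 20),
       uric_acid     = list(uric_acid = 100),
       delta_ph      = list(delta_ph = -0.2))
}

# Electrodes ------------------------------------------------------------------

#' Electrode response profile
#'
#' Per-electrode response parameters capturing the surface-to-surface
#' variability of carbon-fiber microelectrodes: a multiplicative sensitivity
#' gain, an additive redox peak potential shift, the capacitive background's
#' RC decay constant and amplitude, the current noise level, and (for in-vivo
#' electrodes) a biofouling attenuation factor in (0, 1].
#'
#' @param electrode_id unique id string.
#' @param gain multiplicative sensitivity factor (> 0).
#' @param peak_shift additive potential offset (V).
#' @param rc_tau background decay time constant (s, > 0); the default is
#'   chosen comparable to the square-wave pulse length so the charging
#'   current decays smoothly across each half-cycle.
#' @param background_scale capacitive amplitude factor (nA per V of step).
#' @param noise_sd Gaussian current noise sd (nA, >= 0).
#' @param biofouling sensitivity attenuation in (0, 1]; 1 = pristine.
#' @param domain `"in_vitro"` or `"in_vivo"`.
#' @return an `electrode_profile` list.
#' @export
electrode_profile <- function(electrode_id = "ref", gain = 1, peak_shift = 0,
                              rc_tau = 0.035, background_scale = 300,
                              noise_sd = 0.05, biofouling = 1,
                              domain = c("in_vitro", "in_vivo")) {
  domain <- match.arg(domain)
  if (gain <= 0) stop("electrode_profile: gain must be > 0")
  if (rc_tau <= 0) stop("electrode_profile: rc_tau must be > 0")
  if (noise_sd < 0) stop("electrode_profile: noise_sd must be >= 0")
  if (biofouling <= 0 || biofouling > 1)
    stop("electrode_profile: biofouling must be in (0, 1]")
  structure(list(electrode_id = electrode_id, gain = gain,
                 peak_shift = peak_shift, rc_tau = rc_tau,
                 background_scale = background_scale, noise_sd = noise_sd,
                 biofouling = biofouling, domain = domain),
            class = "electrode_profile")
}

#' Draw a population of electrode profiles
#'
#' Gains are log-normal (sdlog 0.3), peak shifts normal (sd 5 mV), RC decay
#' constants log-normal around the reference 35 ms (sdlog 0.25), and noise
#' is a fixed fraction of the reference 500 nM DA signal. The spreads are
#' wide enough that a model trained on one electrode population transfers
#' only imperfectly to unseen electrodes — the regime that motivates
#' across-electrode evaluation. In-vivo electrodes
#' additionally carry a shifted (x1.3) background amplitude and a biofouling
#' attenuation drawn uniformly from [0.8, 0.95] — mild, reflecting coated
#' carbon-fiber electrodes whose surface treatment suppresses fouling;
#' in-vitro electrodes have biofouling fixed at 1.
#'
#' @param n number of electrodes (>= 1).
#' @param domain `"in_vitro"` or `"in_vivo"`.
#' @param seed integer seed; the population is a pure function of
#'   `(n, domain, seed)`.
#' @return list of [electrode_profile()] objects with unique, domain-tagged
#'   ids.
#' @export
sample_electrodes <- function(n, domain = c("in_vitro", "in_vivo"), seed = 1) {
  domain <- match.arg(domain)
  stopifnot(n >= 1)
  with_local_seed(derive_seed(seed, paste0("electrodes:", domain)), {
    tag <- if (domain == "in_vitro") "vitro" else "vivo"
    lapply(seq_len(n), function(i) {
      electrode_profile(
        electrode_id = sprintf("%s_%02d", tag, i),
        gain = stats::rlnorm(1, 0, 0.3),
        peak_shift = stats::rnorm(1, 0, 0.005),
        rc_tau = stats::rlnorm(1, log(0.035), 0.25),
        background_scale = (if (domain == "in_vivo") 1.3 else 1) *
          stats::rlnorm(1, log(300), 0.2),
        noise_sd = 0.05,
        biofouling = if (domain == "in_vivo") stats::runif(1, 0.8, 0.95) else 1,
        domain = domain)
    })
  })
}

# Currents --------------------------------------------------------------------

# skewed Gaussian peak shape, unit height scale
skew_peak <- function(x, width, asymmetry) {
  2 * exp(-x^2 / (2 * width^2)) * stats::pnorm(asymmetry * x / width)
}

#' Noise-free Faradaic current of a solution at an electrode
#'
#' Linear-in-concentration forward model: each analyte contributes
#' `gain * biofouling * sensitivity_ref * conc` times a skewed-Gaussian peak
#' in the applied potential, centered at its oxidation peak on anodic
#' half-cycles and (negated) at its reduction peak on cathodic half-cycles,
#' shifted by the electrode's `peak_shift`. Amplitudes decay within each
#' square-wave half-cycle (pulse relaxation, so the late-half-cycle tail used
#' for background fitting is essentially analyte-free) and grow within each
#' staircase step with the analyte's adsorption time constant. Interferents
#' contribute no Faradaic current.
#'
#' @param solution a [solution_spec()].
#' @param electrode an [electrode_profile()].
#' @param spec a [waveform_spec()].
#' @return numeric current vector (nA), length `trace_length(spec)`.
#' @export
faradaic_current <- function(solution, electrode, spec) {
  validate_waveform_spec(spec)
  if (!inherits(solution, "solution_spec")) stop("solution must be a solution_spec")
  conc <- solution$conc
  if (any(conc < 0)) stop("faradaic_current: negative concentration")
  E <- build_waveform(spec)
  dt <- sample_dt(spec)
  sgn <- half_cycle_sign(spec)
  t_hc <- within_half_cycle_index(spec) * dt
  t_step <- within_step_index(spec) * dt
  hc_dur <- half_cycle_length(spec) * dt
  pulse_tau <- hc_dur / 9     # Faradaic pulse decays within the early samples
  pulse <- exp(-t_hc / pulse_tau)
  panel <- analyte_panel()
  out <- numeric(length(E))
  for (key in names(panel)) {
    c_nM <- unname(conc[[key]])
    if (c_nM == 0) next
    a <- panel[[key]]
    amp <- electrode$gain * electrode$biofouling * a$sensitivity_ref * c_nM
    grow <- 1 - 0.3 * exp(-t_step / a$adsorption_tau)
    ox <- (sgn > 0) * skew_peak(E - a$e_ox - electrode$peak_shift,
                                a$peak_width, a$asymmetry)
    red <- (sgn < 0) * skew_peak(E - a$e_red - electrode$peak_shift,
                                 a$peak_width, a$asymmetry)
    out <- out + amp * (ox - red) * pulse * grow
  }
  out
}

#' Non-Faradaic (capacitive) background current
#'
#' Every potential transition of magnitude `dE` injects a charging current
#' `background_scale * dE * exp(-t' / rc_tau)` where `t'` is time since the
#' transition; contributions from successive transitions superpose.
#' Interferent concentrations and pH shifts apply small (<= 5% at panel
#' levels) multiplicative perturbations to `background_scale`; in-vivo
#' electrodes add a slow linear drift of 1% of `background_scale` over the
#' scan. The first sample's transition is taken from the step-0 baseline
#' (`e_min`) to the first applied potential.
#'
#' @inheritParams faradaic_current
#' @return numeric current vector (nA).
#' @export
background_current <- function(electrode, spec, solution = solution_spec()) {
  validate_waveform_spec(spec)
  E <- build_waveform(spec)
  dE <- c(E[1] - spec$e_min, diff(E))
  dt <- sample_dt(spec)
  rho <- exp(-dt / electrode$rc_tau)
  inter <- solution$interferents
  scale_eff <- electrode$background_scale *
    (1 + 0.010 * inter[["adenosine"]] + 0.0001 * inter[["ascorbic_acid"]] +
       0.0005 * inter[["hva"]] + 0.0005 * inter[["dopac"]] +
       0.0001 * inter[["uric_acid"]] - 0.05 * inter[["delta_ph"]])
  bg <- stats::filter(scale_eff * dE, rho, method = "recursive")
  bg <- as.numeric(bg)
  if (electrode$domain == "in_vivo") {
    tt <- seq_along(E) * dt / scan_period(spec)
    bg <- bg + 0.01 * electrode$background_scale * tt
  }
  bg
}

# Voltammograms ---------------------------------------------------------------

#' Construct a voltammogram record
#' @param trace numeric current vector (nA), length `trace_length(waveform)`.
#' @param electrode_id electrode id string.
#' @param waveform the generating [waveform_spec()].
#' @param t acquisition time (s).
#' @param label optional [conc_triple()] ground truth.
#' @param latent logical; `TRUE` when the label is a held-back latent truth
#'   (in-vivo records) unavailable to training.
#' @return a `voltammogram` object.
#' @export
voltammogram <- function(trace, electrode_id, waveform, t = 0, label = NULL,
                         latent = FALSE) {
  if (length(trace) != trace_length(waveform))
    stop("voltammogram: trace length ", length(trace), " != n_steps * samples_per_step = ",
         trace_length(waveform))
  structure(list(trace = as.numeric(trace), electrode_id = electrode_id,
                 waveform = waveform, t = t, label = label, latent = latent),
            class = "voltammogram")
}

#' Simulate one M-CSWV voltammogram
#'
#' Trace = Faradaic current + capacitive background + white Gaussian noise
#' with sd `electrode$noise_sd`, generated from `seed`. Identical inputs and
#' seed reproduce the identical trace.
#'
#' @inheritParams faradaic_current
#' @param seed integer seed for the noise draw.
#' @param t acquisition time stamp (s).
#' @param latent mark the stored label as latent (evaluation-only).
#' @return a [voltammogram()] carrying the solution's concentrations as label.
#' @export
simulate_voltammogram <- function(solution, electrode, spec, seed = 1, t = 0,
                                  latent = FALSE) {
  clean <- faradaic_current(solution, electrode, spec) +
    background_current(electrode, spec, solution)
  noise <- if (electrode$noise_sd > 0) {
    with_local_seed(seed, stats::rnorm(length(clean), 0, electrode$noise_sd))
  } else 0
  voltammogram(clean + noise, electrode$electrode_id, spec, t = t,
               label = solution$conc, latent = latent)
}

# Pharmacology ----------------------------------------------------------------

#' Drug administration scenario
#'
#' Tonic concentration timecourse around an i.v. drug administration at
#' `t_admin` minutes. The response is a rise-and-decay transient
#' `delta_peak * (1 - exp(-(t - t_admin)/rise_tau)) * exp(-(t - t_admin)/decay_tau)`
#' added to a constant baseline. Cocaine and oxycodone scenarios must raise
#' DA more than 5-HT and leave NE unchanged (their nucleus-accumbens
#' pharmacology); defaults encode an NAc-like baseline of (DA 100, NE 5,
#' 5-HT 60) nM.
#'
#' @param drug `"cocaine"`, `"oxycodone"`, or `"none"`.
#' @param t_admin administration time (min).
#' @param baseline baseline [conc_triple()] (nM).
#' @param delta_peak peak rise per analyte (nM); `NULL` picks the drug
#'   default (cocaine: DA +150, NE 0, 5-HT +60; oxycodone: DA +100, NE 0,
#'   5-HT +50; none: all 0).
#' @param rise_tau,decay_tau transient time constants (min).
#' @param session_length recording length (min).
#' @return a `pharm_scenario` object.
#' @export
pharm_scenario <- function(drug = c("cocaine", "oxycodone", "none"),
                           t_admin = 27,
                           baseline = conc_triple(100, 5, 60),
                           delta_peak = NULL, rise_tau = 5, decay_tau = 40,
                           session_length = 60) {
  drug <- match.arg(drug)
  if (is.null(delta_peak))
    delta_peak <- switch(drug,
      cocaine = conc_triple(150, 0, 60),
      oxycodone = conc_triple(100, 0, 50),
      none = conc_triple(0, 0, 0))
  if (!inherits(delta_peak, "conc_triple"))
    delta_peak <- do.call(conc_triple, as.list(delta_peak))
  if (drug != "none") {
    if (!(delta_peak[["da"]] > delta_peak[["ht5"]] && delta_peak[["ht5"]] > 0))
      stop("pharm_scenario: drug scenarios require delta_peak DA > 5-HT > 0")
    if (delta_peak[["ne"]] != 0)
      stop("pharm_scenario: drug scenarios require delta_peak NE = 0")
  }
  if (rise_tau <= 0 || decay_tau <= 0)
    stop("pharm_scenario: time constants must be > 0")
  structure(list(drug = drug, t_admin = t_admin, baseline = baseline,
                 delta_peak = delta_peak, rise_tau = rise_tau,
                 decay_tau = decay_tau, session_length = session_length),
            class = "pharm_scenario")
}

#' Concentration timecourse of a drug scenario
#'
#' @param scenario a [pharm_scenario()].
#' @param t_grid increasing vector of times (min).
#' @return matrix `length(t_grid) x 3` (columns da, ne, ht5) of tonic
#'   concentrations (nM).
#' @export
pharm_timecourse <- function(scenario, t_grid) {
  if (is.unsorted(t_grid, strictly = FALSE)) stop("t_grid must be increasing")
  dtm <- pmax(t_grid - scenario$t_admin, 0)
  factor <- ifelse(t_grid < scenario$t_admin, 0,
                   (1 - exp(-dtm / scenario$rise_tau)) *
                     exp(-dtm / scenario$decay_tau))
  base <- matrix(unclass(scenario$baseline), nrow = length(t_grid), ncol = 3,
                 byrow = TRUE)
  delta <- outer(factor, unclass(scenario$delta_peak))
  out <- base + delta
  colnames(out) <- c("da", "ne", "ht5")
  out
}

#' Simulate a full in-vivo recording session
#'
#' One voltammogram per scan period (`1 / scan_repetition_rate` seconds, 10 s
#' at the default rate) along the scenario's timecourse. The true
#' concentrations are stored on each record but flagged latent: they emulate
#' an unlabeled in-vivo recording and are available only to evaluation code,
#' never to training.
#'
#' @param scenario a [pharm_scenario()].
#' @param electrode an [electrode_profile()] (typically in-vivo domain).
#' @param spec a [waveform_spec()].
#' @param seed integer seed.
#' @return list of [voltammogram()] records with latent labels.
#' @export
simulate_session <- function(scenario, electrode, spec, seed = 1) {
  period_min <- scan_period(spec) / 60
  t_scans <- seq(0, scenario$session_length - period_min, by = period_min)
  concs <- pharm_timecourse(scenario, t_scans)
  lapply(seq_along(t_scans), function(i) {
    sol <- solution_spec(conc_triple(concs[i, 1], concs[i, 2], concs[i, 3]))
    simulate_voltammogram(sol, electrode, spec,
                          seed = derive_seed(seed, paste0("session:", i)),
                          t = t_scans[i] * 60, latent = TRUE)
  })
}

# Training solution grid ------------------------------------------------------

#' Default in-vitro training solution grid
#'
#' Single-monoamine solutions at four concentrations each plus two-monoamine
#' mixtures over a 3-level grid, and a blank — the kind of one- and
#' two-analyte calibration set used to train concentration models. Three-
#' analyte mixtures are deliberately excluded (they are reserved for
#' validation).
#'
#' @return list of [solution_spec()] objects.
#' @export
training_solutions <- function() {
  singles <- c(100, 250, 500, 1000)
  sols <- list(solution_spec(conc_triple(0, 0, 0)))
  for (v in singles) {
    sols <- c(sols, list(solution_spec(conc_triple(v, 0, 0)),
                         solution_spec(conc_triple(0, v, 0)),
                         solution_spec(conc_triple(0, 0, v))))
  }
  pairs <- expand.grid(a = c(250, 500), b = c(250, 500))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$a[i]; b <- pairs$b[i]
    sols <- c(sols, list(solution_spec(conc_triple(a, b, 0)),
                         solution_spec(conc_triple(a, 0, b)),
                         solution_spec(conc_triple(0, a, b))))
  }
  sols
}

#' Simulate a labeled in-vitro calibration dataset
#'
#' For each electrode and each solution, records `scans_per_solution`
#' voltammograms with independent noise seeds.
#'
#' @param electrodes list of [electrode_profile()]s.
#' @param solutions list of [solution_spec()]s (default [training_solutions()]).
#' @param spec a [waveform_spec()].
#' @param scans_per_solution scans recorded per (electrode, solution).
#' @param seed integer seed.
#' @return list of labeled [voltammogram()]s.
#' @export
simulate_invitro_dataset <- function(electrodes,
                                     solutions = training_solutions(),
                                     spec = waveform_spec(),
                                     scans_per_solution = 3, seed = 1) {
  out <- list()
  idx <- 0L
  for (e in electrodes) {
    for (s in seq_along(solutions)) {
      for (r in seq_len(scans_per_solution)) {
        idx <- idx + 1L
        out[[idx]] <- simulate_voltammogram(
          solutions[[s]], e, spec,
          seed = derive_seed(seed, paste0(e$electrode_id, ":", s, ":", r)),
          t = (r - 1) * scan_period(spec))
      }
    }
  }
  out
}
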