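#' M-CSWV waveform specification
#'
#' Describes a multiple cyclic square-wave voltammetry (M-CSWV) excitation
#' waveform: a symmetric square wave superimposed on a staircase sweep. One
#' scan visits `n_steps` staircase levels between `e_min` and `e_max`; at each
#' level the applied potential alternates between level + `sw_amplitude` and
#' level - `sw_amplitude` for `cycles_per_step` full square-wave cycles,
#' sampled `samples_per_step` times.
#'
#' The desk-scale default (64 steps x 32 samples) keeps a full pipeline run
#' interactive while sampling the potential axis finely enough (~16 mV per
#' step) to resolve the ~12 mV dopamine/norepinephrine oxidation peak
#' separation; the acquisition-scale geometry of 128 steps x 45,000 samples
#' is available through [full_scale_waveform()].
#'
#' @param e_min,e_max staircase sweep limits (V); `e_min < e_max`.
#' @param n_steps number of staircase levels (>= 2).
#' @param samples_per_step current samples recorded per staircase level; must
#'   be divisible by `2 * cycles_per_step` so each square-wave half-cycle has
#'   an integral number of samples.
#' @param sw_amplitude square-wave half-amplitude (V).
#' @param cycles_per_step full square-wave cycles per staircase level.
#' @param sweep `"forward"` (forward-only staircase) or `"forward-reverse"`.
#' @param scan_repetition_rate scan rate (Hz); one scan lasts
#'   `1 / scan_repetition_rate` seconds (10 s at the default 0.1 Hz).
#' @return An object of class `waveform_spec`.
#' @export
waveform_spec <- function(e_min = -0.1, e_max = 0.9, n_steps = 64,
                          samples_per_step = 32, sw_amplitude = 0.1,
                          cycles_per_step = 2,
                          sweep = c("forward", "forward-reverse"),
                          scan_repetition_rate = 0.1) {
  sweep <- match.arg(sweep)
  spec <- structure(
    list(e_min = e_min, e_max = e_max, n_steps = as.integer(n_steps),
         samples_per_step = as.integer(samples_per_step),
         sw_amplitude = sw_amplitude,
         cycles_per_step = as.integer(cycles_per_step), sweep = sweep,
         scan_repetition_rate = scan_repetition_rate),
    class = "waveform_spec")
  validate_waveform_spec(spec)
  spec
}

#' Acquisition-scale waveform geometry
#'
#' The full 128-step x 45,000-sample scan geometry used by the hardware
#' acquisition system, at the standard 0.1 Hz repetition rate.
#'
#' @param ... overrides passed to [waveform_spec()].
#' @return A `waveform_spec`.
#' @export
full_scale_waveform <- function(...) {
  args <- utils::modifyList(
    list(n_steps = 128, samples_per_step = 45000, cycles_per_step = 5),
    list(...))
  do.call(waveform_spec, args)
}

validate_waveform_spec <- function(spec) {
  if (!inherits(spec, "waveform_spec")) stop("not a waveform_spec")
  if (spec$n_steps < 2L)
    stop("invalid waveform_spec: n_steps must be >= 2 (got ", spec$n_steps, ")")
  if (spec$samples_per_step %% (2L * spec$cycles_per_step) != 0L)
    stop("invalid waveform_spec: samples_per_step (", spec$samples_per_step,
         ") must be divisible by 2 * cycles_per_step (",
         2L * spec$cycles_per_step, ")")
  if (!(spec$e_min < spec$e_max))
    stop("invalid waveform_spec: e_min must be < e_max")
  if (spec$sw_amplitude <= 0)
    stop("invalid waveform_spec: sw_amplitude must be > 0")
  if (spec$scan_repetition_rate <= 0)
    stop("invalid waveform_spec: scan_repetition_rate must be > 0")
  invisible(spec)
}

#' Total samples in one scan
#' @param spec a `waveform_spec`.
#' @return `n_steps * samples_per_step`.
#' @export
trace_length <- function(spec) spec$n_steps * spec$samples_per_step

#' Scan duration and sample interval
#' @param spec a `waveform_spec`.
#' @return duration of one scan in seconds.
#' @export
scan_period <- function(spec) 1 / spec$scan_repetition_rate

sample_dt <- function(spec) scan_period(spec) / trace_length(spec)

#' Build the applied-potential sequence of one scan
#'
#' Within staircase level `k` (0-based) the baseline potential is
#' `e_min + k * (e_max - e_min) / (n_steps - 1)` for a forward sweep, and the
#' square wave alternates `+sw_amplitude` (anodic half-cycle) then
#' `-sw_amplitude` (cathodic half-cycle).
#'
#' @param spec a `waveform_spec`.
#' @return numeric vector of applied potentials (V), length
#'   `trace_length(spec)`.
#' @export
build_waveform <- function(spec) {
  validate_waveform_spec(spec)
  k <- seq_len(spec$n_steps) - 1L
  base <- spec$e_min + k * (spec$e_max - spec$e_min) / (spec$n_steps - 1L)
  if (spec$sweep == "forward-reverse") {
    half <- ceiling(spec$n_steps / 2)
    up <- spec$e_min + (seq_len(half) - 1L) * (spec$e_max - spec$e_min) / (half - 1L)
    base <- c(up, rev(up))[seq_len(spec$n_steps)]
  }
  half_len <- spec$samples_per_step %/% (2L * spec$cycles_per_step)
  # +A for anodic half-cycles, -A for cathodic, repeated cycles_per_step times
  sq <- rep(rep(c(spec$sw_amplitude, -spec$sw_amplitude), each = half_len),
            times = spec$cycles_per_step)
  as.vector(vapply(base, function(b) b + sq, numeric(spec$samples_per_step)))
}

# index helpers shared by the simulator and preprocessing ---------------------

half_cycle_length <- function(spec)
  spec$samples_per_step %/% (2L * spec$cycles_per_step)

n_half_cycles <- function(spec)
  2L * spec$cycles_per_step * spec$n_steps

# 0-based sample index within the current half-cycle, for every sample
within_half_cycle_index <- function(spec) {
  rep.int(seq_len(half_cycle_length(spec)) - 1L,
          n_half_cycles(spec))
}

# +1 on anodic (positive square phase) samples, -1 on cathodic
half_cycle_sign <- function(spec) {
  hl <- half_cycle_length(spec)
  rep.int(rep(c(1, -1), each = hl), spec$cycles_per_step * spec$n_steps)
}

# 0-based sample index within the current staircase step
within_step_index <- function(spec) {
  rep.int(seq_len(spec$samples_per_step) - 1L, spec$n_steps)
}
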