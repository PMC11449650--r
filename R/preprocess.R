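#' Dynamic background subtraction
#'
#' Removes the non-Faradaic (capacitive) charging current from a raw
#' voltammogram. Within each square-wave half-cycle the background is an
#' exponential relaxation `a * exp(-t'/tau)` (a superposition of same-tau
#' transition tails is again a single exponential), while the Faradaic pulse
#' has decayed to near zero by the late samples. The decay is therefore
#' estimated from the last `fit_fraction` of each half-cycle's samples: the
#' per-sample decay ratio by a least-squares one-lag regression
#' (`sum(y[k+1] y[k]) / sum(y[k]^2)`, exact for a noise-free geometric
#' sequence of either sign) and the amplitude `a` by least squares given the
#' ratio.
#' The extrapolated exponential is subtracted over the whole half-cycle.
#'
#' Half-cycles whose fit is degenerate (non-finite parameters or a ratio
#' outside (0, 1)) fall back to subtracting the tail median, with a warning.
#'
#' @param v a [voltammogram()].
#' @param fit_fraction fraction (0, 1) of each half-cycle's trailing samples
#'   used for the fit; default 0.25.
#' @return a [voltammogram()] with the background removed.
#' @export
subtract_background <- function(v, fit_fraction = 0.25) {
  stopifnot(inherits(v, "voltammogram"))
  if (!(fit_fraction > 0 && fit_fraction < 1))
    stop("fit_fraction must be in (0, 1)")
  spec <- v$waveform
  hl <- half_cycle_length(spec)
  nhc <- n_half_cycles(spec)
  m <- max(2L, ceiling(fit_fraction * hl))
  Y <- matrix(v$trace, nrow = hl, ncol = nhc)          # column = one half-cycle
  tail_rows <- (hl - m + 1L):hl
  Tl <- Y[tail_rows, , drop = FALSE]
  y1 <- Tl[-m, , drop = FALSE]
  y2 <- Tl[-1L, , drop = FALSE]
  denom <- colSums(y1^2)
  r <- colSums(y1 * y2) / denom
  # amplitude at half-cycle start: y[k] = a * r^k, k 0-based
  k_tail <- tail_rows - 1L
  bad <- !is.finite(r) | r <= 0 | r >= 1
  r_safe <- ifelse(bad, 0.5, r)
  Rk <- outer(k_tail, seq_len(nhc), function(k, j) r_safe[j]^k)
  a <- colSums(Tl * Rk) / colSums(Rk^2)
  bad <- bad | !is.finite(a)
  if (any(bad))
    warning(sum(bad), " half-cycle background fit(s) degenerate; ",
            "subtracting tail median instead")
  k_all <- seq_len(hl) - 1L
  fit <- vapply(seq_len(nhc), function(j) {
    if (bad[j]) rep(stats::median(Tl[, j]), hl) else a[j] * r_safe[j]^k_all
  }, numeric(hl))
  out <- v
  out$trace <- as.vector(Y - fit)
  out
}

#' Moving temporal average of consecutive scans
#'
#' @param scans list of [voltammogram()]s from one electrode and waveform,
#'   in acquisition order.
#' @param window number of consecutive scans averaged (>= 1); output count is
#'   `length(scans) - window + 1`.
#' @return list of averaged [voltammogram()]s (label/time taken from the last
#'   scan of each window).
#' @export
temporal_average <- function(scans, window = 1) {
  stopifnot(window >= 1, length(scans) >= window)
  ids <- vapply(scans, function(s) s$electrode_id, character(1))
  if (length(unique(ids)) != 1L)
    stop("temporal_average: scans come from multiple electrodes: ",
         paste(unique(ids), collapse = ", "))
  if (window == 1) return(scans)
  traces <- vapply(scans, function(s) s$trace, numeric(length(scans[[1]]$trace)))
  n_out <- length(scans) - window + 1L
  lapply(seq_len(n_out), function(i) {
    out <- scans[[i + window - 1L]]
    out$trace <- rowMeans(traces[, i:(i + window - 1L), drop = FALSE])
    out
  })
}

#' Reshape a voltammogram into its 2D heatmap
#'
#' Row r (staircase step), column c (within-step sample) holds trace sample
#' `(r - 1) * samples_per_step + c` — the row-major reshape, so flattening
#' the grid row by row recovers the trace exactly.
#'
#' @param v a [voltammogram()].
#' @return a `heatmap` object: list with `grid` (n_steps x samples_per_step
#'   matrix), `electrode_id`, `label`, `latent`, `t`, `normalized` flag.
#' @export
reshape_heatmap <- function(v) {
  stopifnot(inherits(v, "voltammogram"))
  spec <- v$waveform
  if (length(v$trace) != trace_length(spec))
    stop("reshape_heatmap: trace length ", length(v$trace),
         " does not match expected ", trace_length(spec))
  grid <- matrix(v$trace, nrow = spec$n_steps,
                 ncol = spec$samples_per_step, byrow = TRUE)
  structure(list(grid = grid, electrode_id = v$electrode_id, label = v$label,
                 latent = isTRUE(v$latent), t = v$t, normalized = FALSE),
            class = "vg_heatmap")
}

#' Flatten a heatmap row-major (inverse of [reshape_heatmap()])
#' @param h a `vg_heatmap`.
#' @return numeric vector.
#' @export
flatten_heatmap <- function(h) as.vector(t(h$grid))

#' Fit a global [0, 1] normalization map
#'
#' A single affine map with `lo` = global minimum and `hi` = global maximum
#' over a stated reference set (normally the training split). The same map is
#' reused on validation, test and in-vivo data: concentration information
#' lives in absolute current amplitude, so per-image min-max scaling would
#' erase the regression target.
#'
#' @param reference non-empty list of `vg_heatmap`s.
#' @return a `norm_map` with fields `lo`, `hi`.
#' @export
fit_normalization <- function(reference) {
  if (length(reference) == 0) stop("fit_normalization: empty reference set")
  lo <- min(vapply(reference, function(h) min(h$grid), numeric(1)))
  hi <- max(vapply(reference, function(h) max(h$grid), numeric(1)))
  if (hi == lo)
    stop("fit_normalization: degenerate reference set (hi == lo)")
  structure(list(lo = lo, hi = hi), class = "norm_map")
}

#' Normalize a heatmap into [0, 1]
#'
#' Applies `clip((value - lo) / (hi - lo), 0, 1)` and sets the `normalized`
#' flag. Monotone non-decreasing in the input.
#'
#' @param h a `vg_heatmap`.
#' @param m a `norm_map` from [fit_normalization()].
#' @return the normalized `vg_heatmap`.
#' @export
normalize_heatmap <- function(h, m) {
  stopifnot(inherits(m, "norm_map"))
  h$grid <- pmin(pmax((h$grid - m$lo) / (m$hi - m$lo), 0), 1)
  h$normalized <- TRUE
  h
}

#' Preprocess raw voltammograms into heatmaps
#'
#' Background subtraction, optional temporal averaging (per electrode, in
#' order), and reshaping. Normalization is fit separately (on the training
#' split only) via [fit_normalization()].
#'
#' @param scans list of [voltammogram()]s.
#' @param fit_fraction passed to [subtract_background()].
#' @param window temporal averaging window (1 = none), applied per electrode.
#' @return list of unnormalized `vg_heatmap`s.
#' @export
preprocess_scans <- function(scans, fit_fraction = 0.25, window = 1) {
  sub <- lapply(scans, subtract_background, fit_fraction = fit_fraction)
  if (window > 1) {
    ids <- vapply(sub, function(s) s$electrode_id, character(1))
    sub <- unlist(lapply(unique(ids), function(id)
      temporal_average(sub[ids == id], window)), recursive = FALSE)
  }
  lapply(sub, reshape_heatmap)
}
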