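# Deterministic synthetic traces with known ground-truth features, for
# unit-testing the analysis layer without running the simulator.

#' Build a synthetic voltage trace
#'
#' Piecewise waveform: a flat baseline, optional square "stimulus" context,
#' triangular spikes at prescribed times with prescribed peaks, an optional
#' sag during a hyperpolarizing step, and an optional raised shelf
#' (plateau) after stimulus offset.
#'
#' @param spike_times Spike onset times, ms.
#' @param peaks Spike peak voltages, mV (recycled).
#' @param baseline Resting potential, mV.
#' @param spike_width Total triangle width, ms.
#' @param onset_ms,dur_ms Nominal stimulus window (carried into the trace
#'   metadata so detectors can window on it).
#' @param step_mV Baseline displacement during the stimulus window, mV.
#' @param sag Optional list `list(depth, tau)`: an initial extra
#'   displacement of `depth` mV relaxing with time constant `tau` during
#'   the step.
#' @param plateau Optional list `list(level, duration)`: shelf at `level`
#'   mV above baseline for `duration` ms after offset, then back to
#'   baseline.
#' @param dt Sample interval, ms.
#' @param tstop Total duration, ms.
#' @return A `pg_trace`-compatible object.
#' @export
make_synthetic_trace <- function(spike_times = numeric(0), peaks = 20,
                                 baseline = -70, spike_width = 2,
                                 onset_ms = 100, dur_ms = 600, step_mV = 0,
                                 sag = NULL, plateau = NULL, dt = 0.05,
                                 tstop = onset_ms + dur_ms + 400) {
  t <- seq(0, tstop, by = dt)
  v <- rep(baseline, length(t))
  offset <- onset_ms + dur_ms
  instep <- t >= onset_ms & t < offset
  v[instep] <- baseline + step_mV
  if (!is.null(sag)) {
    ts <- t[instep] - onset_ms
    v[instep] <- v[instep] - sag$depth * exp(-ts / sag$tau)
  }
  if (!is.null(plateau)) {
    shelf <- t >= offset & t < offset + plateau$duration
    v[shelf] <- baseline + plateau$level
  }
  peaks <- rep_len(peaks, length(spike_times))
  for (k in seq_along(spike_times)) {
    s <- spike_times[k]
    tri <- abs(t - (s + spike_width / 2)) <= spike_width / 2
    frac <- 1 - abs(t[tri] - (s + spike_width / 2)) / (spike_width / 2)
    v[tri] <- pmax(v[tri], v[tri] + (peaks[k] - v[tri]) * frac)
  }
  proto <- stimulus_protocol(if (step_mV >= 0) 1 else -1, dur_ms = dur_ms,
                             onset_ms = onset_ms,
                             post_ms = tstop - offset)
  structure(list(time = t, v = matrix(v, ncol = 1,
                                      dimnames = list(NULL, "soma_1")),
                 ca = rep(2.4e-4, length(t)), g = NULL, v_rest = baseline,
                 meta = list(label = "synthetic", protocol = proto,
                             noise = NULL, dt = dt, record_every = 1L,
                             record_comp = "soma")),
            class = "pg_trace")
}
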