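# Trace analysis: spike detection, accommodation, sag/rebound, LTS and
# plateau detection, input resistance, and phenotype classification.
#
# The classifier thresholds are declared operationalizations (the source
# phenotypes are defined by visual correspondence to recordings); they live
# in analysis_options() and the preset regression suite pins them.

#' Analysis thresholds
#'
#' @param spike_threshold Spike detection threshold, mV.
#' @param refractory Minimum spike separation, ms.
#' @param accommodation_cut Last-ISI/first-ISI ratio separating
#'   non-accommodating (<=) from accommodating (>) trains.
#' @param lts_amp Minimum LTS envelope amplitude above baseline, mV.
#' @param lts_min_ms Minimum LTS envelope width, ms.
#' @param plateau_level Minimum post-offset elevation above rest, mV.
#' @param plateau_min_ms Minimum post-offset persistence, ms.
#' @param cv_cut ISI coefficient-of-variation bound for "irregular".
#' @param rebound_window_ms Window after stimulus offset searched for
#'   rebound spikes, ms.
#' @return Named list of thresholds.
#' @export
analysis_options <- function(spike_threshold = -20, refractory = 2,
                             accommodation_cut = 1.3, lts_amp = 10,
                             lts_min_ms = 20, plateau_level = 20,
                             plateau_min_ms = 100, cv_cut = 0.5,
                             rebound_window_ms = 400) {
  as.list(environment())
}

.trace_tv <- function(trace) {
  if (inherits(trace, "pg_trace")) list(t = trace$time, v = soma_v(trace))
  else if (is.list(trace) && all(c("time", "v") %in% names(trace)))
    list(t = trace$time, v = if (is.matrix(trace$v)) trace$v[, 1] else trace$v)
  else stop("expected a pg_trace or a list with time and v", call. = FALSE)
}

#' Detect action potentials
#'
#' Upward threshold crossings separated by at least the refractory period.
#'
#' @param trace A `pg_trace` (somatic voltage is used) or a list with
#'   `time`/`v`.
#' @param threshold Crossing threshold, mV.
#' @param refractory Minimum separation, ms.
#' @param window Optional `c(t0, t1)` restricting the search, ms.
#' @return Numeric vector of crossing times, ms.
#' @export
detect_spikes <- function(trace, threshold = -20, refractory = 2,
                          window = NULL) {
  tv <- .trace_tv(trace)
  t <- tv$t; v <- tv$v
  if (is.unsorted(t, strictly = TRUE)) stop("time grid must be increasing")
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; v <- v[keep]
  }
  if (length(v) < 2) return(numeric(0))
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  times <- t[up]
  if (length(times) > 1) {
    keep <- c(TRUE, diff(times) >= refractory)
    # enforce refractory sequentially
    out <- times[1]
    for (x in times[-1]) if (x - out[length(out)] >= refractory) out <- c(out, x)
    times <- out
  }
  times
}

# peak voltage following each spike onset (up to the next onset or +10 ms)
.spike_peaks <- function(t, v, spike_times, horizon = 10) {
  vapply(seq_along(spike_times), function(k) {
    t0 <- spike_times[k]
    t1 <- if (k < length(spike_times)) spike_times[k + 1] else t0 + horizon
    max(v[t >= t0 & t <= min(t1, t0 + horizon)])
  }, numeric(1))
}

#' Detect a low-threshold calcium spike
#'
#' The LTS is identified on a pharmacological companion trace simulated
#' with the fast sodium conductance at zero (so fast spikes cannot mask the
#' envelope): present iff the companion shows a depolarizing envelope
#' exceeding `lts_amp` above the pre-window baseline for at least
#' `lts_min_ms`.
#'
#' @param trace The intact trace (used for protocol checking; may be `NULL`).
#' @param na_blocked Companion `pg_trace` with identical protocol and
#'   `Na = 0`.
#' @param window `c(t0, t1)` search window, ms (e.g. the depolarizing step,
#'   or the post-offset window for anode-break responses).
#' @param baseline_window Window used for the baseline, ms; defaults to the
#'   100 ms before `window[1]` clipped to the trace.
#' @param opts [analysis_options()].
#' @return List: `present`, `amplitude` (mV), `duration` (ms).
#' @export
detect_lts <- function(trace, na_blocked, window, baseline_window = NULL,
                       opts = analysis_options()) {
  if (!is.null(trace) && inherits(trace, "pg_trace") &&
      inherits(na_blocked, "pg_trace")) {
    p1 <- trace$meta$protocol$segments
    p2 <- na_blocked$meta$protocol$segments
    if (!isTRUE(all.equal(p1, p2)))
      stop("intact and Na-blocked traces must share the same protocol",
           call. = FALSE)
  }
  tv <- .trace_tv(na_blocked)
  t <- tv$t; v <- tv$v
  if (is.null(baseline_window))
    baseline_window <- c(max(min(t), window[1] - 100), window[1])
  base <- mean(v[t >= baseline_window[1] & t < baseline_window[2]])
  keep <- t >= window[1] & t <= window[2]
  tw <- t[keep]; vw <- v[keep]
  above <- vw >= base + opts$lts_amp
  if (!any(above)) return(list(present = FALSE, amplitude = max(vw) - base,
                               duration = 0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  durs <- ifelse(r$values, tw[ends] - tw[starts], 0)
  dur <- max(durs)
  list(present = dur >= opts$lts_min_ms, amplitude = max(vw) - base,
       duration = dur)
}

#' Detect a persistent plateau potential
#'
#' Present iff the membrane potential remains more than `plateau_level`
#' above rest for more than `plateau_min_ms` after stimulus offset.
#' Duration is measured from offset to half-repolarization (the first
#' post-offset crossing of the midpoint between the plateau level and
#' rest); censored at the end of the trace.
#'
#' @param trace A `pg_trace` (or time/v list).
#' @param offset_ms Stimulus offset time, ms; defaults to the last segment
#'   offset of the trace's protocol.
#' @param rest Resting potential, mV; defaults to the mean voltage over the
#'   100 ms before stimulus onset.
#' @param opts [analysis_options()].
#' @return List: `present`, `duration` (ms), `level` (mV), `censored`.
#' @export
detect_plateau <- function(trace, offset_ms = NULL, rest = NULL,
                           opts = analysis_options()) {
  tv <- .trace_tv(trace)
  t <- tv$t; v <- tv$v
  if (is.null(offset_ms)) {
    seg <- trace$meta$protocol$segments
    offset_ms <- max(seg$onset_ms + seg$dur_ms)
  }
  if (is.null(rest)) {
    seg_on <- if (inherits(trace, "pg_trace"))
      min(trace$meta$protocol$segments$onset_ms) else offset_ms
    rest <- mean(v[t >= max(0, seg_on - 100) & t < seg_on])
  }
  post <- t > offset_ms
  tp <- t[post]; vp <- v[post]
  if (length(tp) < 2) return(list(present = FALSE, duration = 0,
                                  level = NA_real_, censored = FALSE))
  # plateau reference level: median over a short window past the offset,
  # robust to spikes riding on the plateau
  ref_win <- tp <= offset_ms + 60 & tp >= offset_ms + 10
  level <- stats::median(vp[ref_win])
  above <- vp >= rest + opts$plateau_level
  # persistence from the offset (allow 10 ms of slack for the falling edge
  # of a final spike)
  lead <- tp <= offset_ms + 10
  first_below <- which(!above & !lead)
  dur_above <- if (length(first_below)) tp[first_below[1]] - offset_ms
               else max(tp) - offset_ms
  present <- is.finite(level) && (level >= rest + opts$plateau_level) &&
    dur_above > opts$plateau_min_ms
  half <- rest + (level - rest) / 2
  below_half <- which(vp < half & !lead)
  censored <- !length(below_half)
  duration <- if (censored) max(tp) - offset_ms else tp[below_half[1]] - offset_ms
  list(present = isTRUE(present), duration = duration, level = level,
       censored = censored)
}

#' Measure somatic input resistance
#'
#' Steady-state voltage deflection per injected current from a small, long
#' somatic step on the settled cell.
#'
#' @param cell A `pg_cell`.
#' @param amp_pA Step amplitude, pA (default -1).
#' @param dur_ms Step duration, ms (default 2000).
#' @param dt Integrator step, ms.
#' @return Input resistance, MOhm.
#' @export
measure_input_resistance <- function(cell, amp_pA = -1, dur_ms = 2000,
                                     dt = 0.025) {
  proto <- stimulus_protocol(amp_pA, dur_ms = dur_ms, onset_ms = 50,
                             post_ms = 10)
  tr <- run_current_clamp(cell, proto, noise = NULL, dt = dt,
                          record_every = max(1L, round(1 / dt)))
  t <- tr$time; v <- soma_v(tr)
  base <- mean(v[t < 50])
  vss <- mean(v[t >= 50 + dur_ms - 100 & t < 50 + dur_ms])
  1000 * (vss - base) / amp_pA   # mV / pA -> MOhm
}

#' Response features of a depolarizing/hyperpolarizing trace pair member
#'
#' @param trace A `pg_trace`.
#' @param na_blocked Optional Na = 0 companion for LTS detection.
#' @param polarity `"depol"` or `"hyperpol"` (selects the analysis windows).
#' @param opts [analysis_options()].
#' @return List of features: spike times/count/peaks, accommodation ratio,
#'   ISI CV, sag ratio, rebound spike count, LTS and plateau records.
#' @export
response_features <- function(trace, na_blocked = NULL, polarity = "depol",
                              opts = analysis_options()) {
  stopifnot(inherits(trace, "pg_trace"), polarity %in% c("depol", "hyperpol"))
  seg <- trace$meta$protocol$segments
  onset <- seg$onset_ms[1]; offset <- seg$onset_ms[1] + seg$dur_ms[1]
  t <- trace$time; v <- soma_v(trace)
  rest <- mean(v[t >= max(0, onset - 100) & t < onset])

  if (polarity == "depol") {
    sp <- detect_spikes(trace, opts$spike_threshold, opts$refractory,
                        window = c(onset, offset))
    lts_window <- c(onset, offset)
  } else {
    sp <- detect_spikes(trace, opts$spike_threshold, opts$refractory,
                        window = c(offset, offset + opts$rebound_window_ms))
    lts_window <- c(offset, offset + opts$rebound_window_ms)
  }
  peaks <- .spike_peaks(t, v, sp)
  isi <- diff(sp)
  acc <- if (length(sp) >= 3) isi[length(isi)] / isi[1] else NA_real_
  cv <- if (length(isi) >= 2) stats::sd(isi) / mean(isi) else NA_real_

  # sag during a hyperpolarizing step
  sag <- NA_real_
  if (polarity == "hyperpol") {
    instep <- t >= onset & t <= offset
    vmin <- min(v[instep])
    vss <- mean(v[t >= offset - 0.1 * seg$dur_ms[1] & t <= offset])
    sag <- if (rest - vmin > 1e-6) (vss - vmin) / (rest - vmin) else 0
  }

  lts <- if (!is.null(na_blocked))
    detect_lts(trace, na_blocked, lts_window,
               baseline_window = c(max(0, onset - 100), onset), opts = opts)
  else list(present = NA, amplitude = NA_real_, duration = NA_real_)
  plateau <- detect_plateau(trace, offset_ms = offset, rest = rest,
                            opts = opts)

  list(polarity = polarity, rest = rest, spike_times = sp,
       spike_count = length(sp), peaks = peaks,
       decrementing = length(peaks) >= 2 && all(diff(peaks) < 0),
       accommodation_ratio = acc, isi_cv = cv, sag_ratio = sag,
       rebound_spike_count = if (polarity == "hyperpol") length(sp) else NA,
       lts = lts, plateau = plateau)
}

#' Classify a depolarization/hyperpolarization response pair
#'
#' Decision rules (defaults in [analysis_options()]):
#' plateau -> `"plateau"`; LTS with <= 1 spike -> `"LTS-single-AP"`; LTS
#' with >= 2 decrementing spikes -> `"LTS-burst"`; with noise on, >= 3
#' spikes and ISI CV above the cut -> `"irregular"` (never returned for
#' noiseless traces); >= 3 spikes -> `"non-accommodating"` or
#' `"accommodating"` by the last/first ISI ratio; exactly 1 spike ->
#' `"single-spike"`; 2 spikes (train too short to judge) ->
#' `"accommodating"`; none -> `"silent"`.
#'
#' @param depol,hyperpol Feature lists from [response_features()] for the
#'   two members of the pair (same parameter set).
#' @param noise_enabled Whether the depolarizing trace carried the noise
#'   source.
#' @param opts [analysis_options()].
#' @return Phenotype label (character).
#' @export
classify_response <- function(depol, hyperpol = NULL, noise_enabled = FALSE,
                              opts = analysis_options()) {
  if (isTRUE(depol$plateau$present)) return("plateau")
  if (isTRUE(depol$lts$present)) {
    if (depol$spike_count <= 1) return("LTS-single-AP")
    if (depol$spike_count >= 2 && isTRUE(depol$decrementing))
      return("LTS-burst")
  }
  if (noise_enabled && depol$spike_count >= 3 &&
      is.finite(depol$isi_cv) && depol$isi_cv > opts$cv_cut)
    return("irregular")
  if (depol$spike_count >= 3) {
    if (depol$accommodation_ratio <= opts$accommodation_cut)
      return("non-accommodating")
    return("accommodating")
  }
  if (depol$spike_count == 1) return("single-spike")
  if (depol$spike_count == 2) return("accommodating")
  "silent"
}

#' Simulate and classify one parameter set under a protocol pair
#'
#' Runs the depolarizing and hyperpolarizing protocols (same parameter
#' set), plus Na-blocked companions for LTS detection, extracts features
#' and applies [classify_response()].
#'
#' @param params A `pg_params`.
#' @param protocol A `pg_protocol_pair` (see [load_preset()]).
#' @param dt Integrator step, ms.
#' @param noise_seed Seed for the noise source when the parameter set
#'   enables noise.
#' @param opts [analysis_options()].
#' @param config Cell configuration.
#' @param keep_traces Also return the four traces.
#' @return List: `label`, `depol`, `hyperpol` feature lists (and `traces`
#'   when requested).
#' @export
classify_phenotype <- function(params, protocol, dt = 0.01, noise_seed = 1L,
                               opts = analysis_options(),
                               config = cell_config(), keep_traces = FALSE) {
  stopifnot(inherits(protocol, "pg_protocol_pair"))
  cell <- build_cell(params, config)
  cell0 <- build_cell(apply_pharmacology(params, c(Na = 0)), config)
  noise <- if (isTRUE(params$noise)) noise_source(seed = noise_seed)
  pd <- stimulus_protocol(protocol$depol$amp_pA, protocol$depol$dur_ms,
                          onset_ms = 100, post_ms = protocol$post_ms)
  ph <- stimulus_protocol(protocol$hyperpol$amp_pA, protocol$hyperpol$dur_ms,
                          onset_ms = 100, post_ms = protocol$post_ms)
  tr_d <- run_current_clamp(cell, pd, noise = noise, dt = dt)
  tr_h <- run_current_clamp(cell, ph, noise = noise, dt = dt)
  bl_d <- run_current_clamp(cell0, pd, noise = noise, dt = dt)
  bl_h <- run_current_clamp(cell0, ph, noise = noise, dt = dt)
  fd <- response_features(tr_d, bl_d, "depol", opts)
  fh <- response_features(tr_h, bl_h, "hyperpol", opts)
  out <- list(label = classify_response(fd, fh, isTRUE(params$noise), opts),
              depol = fd, hyperpol = fh)
  if (keep_traces) out$traces <- list(depol = tr_d, hyperpol = tr_h,
                                      depol_na0 = bl_d, hyperpol_na0 = bl_h)
  out
}

#' Run the full preset regression
#'
#' Simulates every published preset under its printed protocol pair and
#' compares the classified label with the published response type.
#'
#' @param keys Preset keys (default all nine).
#' @param dt Integrator step, ms.
#' @param noise_seed Seed for noise-enabled presets.
#' @param opts [analysis_options()].
#' @return data.frame: key, expected and observed label, pass flag, spike
#'   counts and rebound counts.
#' @export
classify_all <- function(keys = preset_keys(), dt = 0.01, noise_seed = 1L,
                         opts = analysis_options()) {
  rows <- lapply(keys, function(k) {
    pre <- load_preset(k)
    res <- classify_phenotype(pre$params, pre$protocol, dt = dt,
                              noise_seed = noise_seed, opts = opts)
    data.frame(key = k, expected = pre$label, observed = res$label,
               pass = identical(res$label, pre$label),
               depol_spikes = res$depol$spike_count,
               rebound_spikes = res$hyperpol$rebound_spike_count,
               sag_ratio = round(res$hyperpol$sag_ratio, 3),
               depol_lts = isTRUE(res$depol$lts$present),
               hyperpol_lts = isTRUE(res$hyperpol$lts$present),
               depol_plateau = isTRUE(res$depol$plateau$present),
               hyperpol_plateau = isTRUE(res$hyperpol$plateau$present),
               isi_cv = round(res$depol$isi_cv, 3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
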