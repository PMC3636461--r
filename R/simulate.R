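# Current-clamp simulation: stimulus protocols, the colored current-noise
# source, and the front end to the compiled Crank-Nicolson integrator.

#' Somatic current-clamp protocol
#'
#' One or more non-overlapping square current steps injected into the soma.
#'
#' @param amp_pA Step amplitude(s), pA (positive = depolarizing).
#' @param dur_ms Step duration(s), ms.
#' @param onset_ms Step onset(s) relative to the start of the recorded
#'   (post-settle) window, ms.
#' @param post_ms Recording continues this long after the last step offset.
#' @return Object of class `pg_protocol`.
#' @export
stimulus_protocol <- function(amp_pA, dur_ms = 600, onset_ms = 100,
                              post_ms = 400) {
  n <- max(length(amp_pA), length(dur_ms), length(onset_ms))
  seg <- data.frame(amp_pA = rep_len(as.numeric(amp_pA), n),
                    onset_ms = rep_len(as.numeric(onset_ms), n),
                    dur_ms = rep_len(as.numeric(dur_ms), n))
  stopifnot(all(is.finite(seg$amp_pA)), all(seg$dur_ms > 0),
            all(seg$onset_ms >= 0))
  o <- order(seg$onset_ms)
  seg <- seg[o, , drop = FALSE]
  if (n > 1 && any(seg$onset_ms[-1] < (seg$onset_ms + seg$dur_ms)[-n]))
    stop("stimulus segments must not overlap", call. = FALSE)
  structure(list(segments = seg,
                 tstop = max(seg$onset_ms + seg$dur_ms) + post_ms),
            class = "pg_protocol")
}

#' Colored current-noise source
#'
#' Gaussian white noise (SD 50 fA = 0.05 pA, band-limited by its 8 kHz
#' sampling rate to 0-4 kHz) colored by convolution with a single
#' exponential kernel (tau = 5 ms).  The white source's SD is specified
#' before coloring; the colored series' SD is whatever the convolution
#' yields.
#'
#' @param sd_pA White-noise standard deviation, pA.
#' @param tau_ms Coloring time constant, ms.
#' @param dt_ms Sampling interval, ms (must be <= 0.125 to represent the
#'   4 kHz bandwidth).
#' @param seed Integer RNG seed (reproducibility); `NULL` uses the current
#'   RNG state.
#' @return Object of class `pg_noise`.
#' @export
noise_source <- function(sd_pA = 0.05, tau_ms = 5, dt_ms = 0.125,
                         seed = NULL) {
  stopifnot(sd_pA >= 0, tau_ms > 0, dt_ms > 0)
  structure(list(sd_pA = sd_pA, tau_ms = tau_ms, dt_ms = dt_ms, seed = seed),
            class = "pg_noise")
}

#' Generate the colored noise current series
#'
#' Draws the zero-mean Gaussian white sequence with the stated SD and
#' convolves it with the causal exponential kernel `exp(-t/tau)`
#' (discretely, `y_n = sum_k w_(n-k) exp(-k dt / tau)`, evaluated as the
#' equivalent first-order recursive filter).  Deterministic under a fixed
#' seed.
#'
#' @param n_steps Number of samples.
#' @param dt Sampling interval, ms (<= 0.125).
#' @param noise A [noise_source()].
#' @param white Return the pre-coloring white series instead.
#' @return Numeric current series, pA.
#' @export
generate_colored_noise <- function(n_steps, dt = NULL, noise = noise_source(),
                                   white = FALSE) {
  if (is.null(dt)) dt <- noise$dt_ms
  if (dt > 0.125 + 1e-12)
    stop("dt must be <= 0.125 ms to represent the 0-4 kHz bandwidth",
         call. = FALSE)
  if (!is.null(noise$seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(noise$seed)
  }
  w <- stats::rnorm(n_steps, mean = 0, sd = noise$sd_pA)
  if (white) return(w)
  as.numeric(stats::filter(w, exp(-dt / noise$tau_ms), method = "recursive"))
}

.comp_index <- function(cell, compartment) {
  if (is.numeric(compartment)) return(as.integer(compartment))
  i <- which(cell$comp$section == compartment)
  if (!length(i)) stop("no compartment in section '", compartment, "'",
                       call. = FALSE)
  i[(length(i) + 1L) %/% 2L]  # middle compartment of the section
}

#' Run a current-clamp simulation
#'
#' Integrates the coupled compartmental voltage/gating/calcium system.  The
#' cell is first settled to its resting fixed point with no stimulus (the
#' settle phase is discarded), then the protocol is applied with current
#' injected into the soma.  Voltage is recorded in every compartment;
#' perimembrane calcium and per-channel conductance densities are recorded
#' in one chosen compartment.
#'
#' The integrator is a fixed-step, second-order implicit scheme:
#' Crank-Nicolson for the voltages (Hines-ordered tree solve for the axial
#' coupling) with staggered exponential-Euler gating updates.
#'
#' @param cell A [build_cell()] result.
#' @param protocol A [stimulus_protocol()].
#' @param noise A [noise_source()], or `NULL`.  Defaults to the standard
#'   source when the parameter set has `noise = TRUE`.
#' @param dt Time step, ms (default 0.01).
#' @param settle_ms Settle duration before the recorded window (default
#'   2000 ms; extended automatically until `|dV/dt| < settle_tol` at every
#'   compartment, up to `settle_max_ms`).
#' @param settle_tol Settle criterion, mV/ms.
#' @param settle_max_ms Cap on the settle phase.
#' @param record_every Record every this-many steps (default 5, i.e.
#'   0.05 ms at the default dt).
#' @param record_comp Section name (or compartment index) for calcium and
#'   conductance recording (default `"soma"`).
#' @param record_channels Channel names whose conductance time series
#'   `g(t) = Gmax m(t)^a h(t)^b` to record, or `NULL`.
#' @param v_init Initial voltage, mV (default: the leak reversal).
#' @return Object of class `pg_trace`: list with `time` (ms), `v` (matrix,
#'   mV, one column per compartment), `ca` (mM), `g` (matrix, S/cm2),
#'   `v_rest` (post-settle somatic potential) and `meta`.
#' @export
run_current_clamp <- function(cell, protocol, noise = NULL, dt = 0.01,
                              settle_ms = 2000, settle_tol = 1e-6,
                              settle_max_ms = 10000, record_every = 5L,
                              record_comp = "soma", record_channels = NULL,
                              v_init = NULL) {
  stopifnot(inherits(cell, "pg_cell"), inherits(protocol, "pg_protocol"),
            dt > 0)
  if (is.null(noise) && isTRUE(cell$params$noise)) noise <- noise_source()
  if (is.null(v_init)) v_init <- cell$eleak[1]

  rcomp <- .comp_index(cell, record_comp)
  rch <- integer(0)
  if (!is.null(record_channels)) {
    rch <- vapply(record_channels, .channel_index, integer(1)) - 1L
    # structurally absent channels cannot be recorded
    for (nm in record_channels) {
      cn <- channel_name(nm)
      sec <- cell$comp$section[rcomp]
      if (cn == "CaT" && cell$params$cat_scope == "soma" && sec != "soma")
        stop("channel CaT is not expressed in section '", sec, "'",
             call. = FALSE)
    }
  }

  noise_vec <- numeric(0)
  noise_dt <- 0.125
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "pg_noise"))
    noise_dt <- noise$dt_ms
    n_noise <- ceiling(protocol$tstop / noise_dt) + 1L
    noise_vec <- generate_colored_noise(n_noise, noise_dt, noise)
  }

  model <- list(
    area = cell$comp$area_cm2,
    parent = cell$comp$parent - 1L,   # 0-based, root -1
    gax = cell$comp$gax_S,
    cm = cell$cm, gleak = cell$gleak, eleak = cell$eleak, gnic = cell$gnic,
    gbar = cell$gbar,
    ena = cell$config$reversals_mV$Na, ek = cell$config$reversals_mV$K,
    eh = cell$config$reversals_mV$H, ecan = cell$config$reversals_mV$CAN,
    enic = cell$config$nicotinic$e_mV,
    cao = cell$config$calcium$external_mM,
    tempK = cell$config$calcium$temperature_C + 273.15,
    cabasal = cell$config$calcium$basal_mM,
    catau = cell$config$calcium$tau_decay_ms,
    cadepth = cell$config$calcium$shell_depth_um,
    inj = 0L)

  stim <- as.matrix(protocol$segments[, c("amp_pA", "onset_ms", "dur_ms")])
  out <- cpp_simulate(model, stim, protocol$tstop, dt, settle_ms, settle_tol,
                      settle_max_ms, noise_vec, noise_dt,
                      as.integer(record_every), rcomp - 1L, rch, v_init)
  colnames(out$v) <- paste0(cell$comp$section, "_", cell$comp$seg)
  if (length(rch)) colnames(out$g) <- vapply(record_channels, channel_name,
                                             character(1))
  structure(list(
    time = out$time, v = out$v, ca = out$ca,
    g = if (length(rch)) out$g else NULL,
    v_rest = out$v_rest,
    meta = list(label = cell$params$label, protocol = protocol,
                noise = noise, dt = dt, record_every = record_every,
                record_comp = cell$comp$section[rcomp],
                settle_ms = out$settle_ms, settle_dvmax = out$settle_dvmax)),
    class = "pg_trace")
}

#' Somatic voltage of a trace
#' @param trace A `pg_trace`.
#' @return Numeric vector, mV.
#' @export
soma_v <- function(trace) {
  stopifnot(inherits(trace, "pg_trace"))
  trace$v[, "soma_1"]
}

#' @export
print.pg_trace <- function(x, ...) {
  cat("PG current-clamp trace (", x$meta$label, ")\n", sep = "")
  cat("  ", length(x$time), " samples over ", max(x$time), " ms (dt ",
      x$meta$dt, " ms, recorded every ", x$meta$record_every, " steps)\n",
      sep = "")
  seg <- x$meta$protocol$segments
  cat("  stimulus:", paste(sprintf("%g pA @ %g-%g ms", seg$amp_pA,
                                   seg$onset_ms, seg$onset_ms + seg$dur_ms),
                           collapse = "; "), "\n")
  cat("  resting potential:", round(x$v_rest, 2), "mV; somatic range [",
      round(min(soma_v(x)), 1), ",", round(max(soma_v(x)), 1), "] mV\n")
  invisible(x)
}

#' @export
as.data.frame.pg_trace <- function(x, ...) {
  df <- data.frame(time_ms = x$time, v_soma_mV = soma_v(x),
                   ca_mM = x$ca)
  if (!is.null(x$g)) {
    g <- as.data.frame(x$g)
    names(g) <- paste0("g_", names(g), "_S_cm2")
    df <- cbind(df, g)
  }
  df
}

#' @export
plot.pg_trace <- function(x, ...) {
  plot(x$time, soma_v(x), type = "l", xlab = "time (ms)",
       ylab = "somatic V (mV)", main = x$meta$label, ...)
  seg <- x$meta$protocol$segments
  graphics::abline(v = c(seg$onset_ms, seg$onset_ms + seg$dur_ms),
                   lty = 3, col = "grey50")
  invisible(x)
}

#' Write a trace as delimited text
#'
#' One header line with column names and units, tab-separated values.
#' Optionally writes a YAML metadata sidecar capturing the resolved
#' configuration.
#'
#' @param trace A `pg_trace`.
#' @param file Output path.
#' @param sidecar Write `<file>.meta.yaml`.
#' @return `file`, invisibly.
#' @export
write_trace <- function(trace, file, sidecar = FALSE) {
  utils::write.table(as.data.frame(trace), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- trace$meta
    meta$protocol <- list(segments = as.list(meta$protocol$segments),
                          tstop = meta$protocol$tstop)
    meta$noise <- if (!is.null(meta$noise)) unclass(meta$noise)
    yaml::write_yaml(meta, paste0(file, ".meta.yaml"))
  }
  invisible(file)
}

#' Record channel conductance time courses
#'
#' Convenience wrapper around [run_current_clamp()] that records
#' `g(t) = Gmax m(t)^a h(t)^b` for the requested channels in a named
#' compartment (e.g. the primary dendrite during an LTS).
#'
#' @param cell A `pg_cell`.
#' @param protocol A `pg_protocol`.
#' @param channels Channel names.
#' @param compartment Section name (default `"dend1"`).
#' @param ... Passed to [run_current_clamp()].
#' @return A `pg_trace` with the `g` matrix filled.
#' @export
record_conductances <- function(cell, protocol, channels,
                                compartment = "dend1", ...) {
  run_current_clamp(cell, protocol, record_comp = compartment,
                    record_channels = channels, ...)
}
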