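# Channel kinetics layer: the eight gated membrane mechanisms plus the two
# ohmic ones (leak, nicotinic).  Steady states and time constants are
# evaluated in compiled code (single source shared with the integrator);
# this file provides the user-facing surface and the channel catalogue.

# canonical gated-channel order; must match the enum in src/pgcell.cpp
.CHANNELS <- c("Na", "K", "KA", "KCa", "H", "CaL", "CaT", "CAN")
.OHMIC <- c("leak", "nic")

.CH_A <- c(Na = 3L, K = 4L, KA = 1L, KCa = 2L, H = 1L, CaL = 2L, CaT = 2L, CAN = 2L)
.CH_B <- c(Na = 1L, K = 0L, KA = 1L, KCa = 0L, H = 0L, CaL = 1L, CaT = 1L, CAN = 0L)
.CH_PHIM <- c(Na = 0.24, K = 0.24, KA = 0.46, KCa = 1.12, H = 0.35,
              CaL = 1.00, CaT = 0.85, CAN = 1.12)
.CH_PHIH <- c(Na = 0.24, K = 0, KA = 0.46, KCa = 0, H = 0,
              CaL = 1.00, CaT = 0.90, CAN = 0)
# channels whose gating reads the perimembrane calcium concentration
.CA_GATED <- c("KCa", "CaL", "CAN")

#' Canonical channel name
#'
#' Accepts the field's parenthesised spellings (`"K(A)"`, `"K(Ca)"`,
#' `"Ca(L)"`, `"Ca(T)"`) as well as the compact forms used internally.
#'
#' @param name Character channel identifier.
#' @param ohmic_ok Also accept `"leak"` and `"nic"`.
#' @return The canonical name (one of `Na, K, KA, KCa, H, CaL, CaT, CAN`,
#'   plus `leak`/`nic` when `ohmic_ok`).
#' @export
channel_name <- function(name, ohmic_ok = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- gsub("[()_ ]", "", name)
  map <- c(na = "Na", k = "K", ka = "KA", kca = "KCa", h = "H", ih = "H",
           cal = "CaL", cat = "CaT", can = "CAN", ican = "CAN",
           leak = "leak", nic = "nic", nicotinic = "nic")
  out <- unname(map[tolower(key)])
  if (is.na(out) || (!ohmic_ok && out %in% .OHMIC))
    stop("unknown channel: '", name, "'", call. = FALSE)
  out
}

.channel_index <- function(name) {
  match(channel_name(name), .CHANNELS)
}

#' Channel catalogue
#'
#' One row per gated mechanism: gating orders, temperature coefficients,
#' kinetics kind per gate and reversal-potential rule.  The same records are
#' shipped as a structured config in `inst/extdata/channels.yaml` so the
#' kinetic scheme is data-inspectable.
#'
#' @return A data.frame with columns `channel, a, b, phi_m, phi_h,
#'   kinetics_m, kinetics_h, reversal, permeant_ion`.
#' @export
channel_catalog <- function() {
  path <- system.file("extdata", "channels.yaml", package = "pgcell")
  raw <- yaml::read_yaml(path)
  do.call(rbind, lapply(raw$channels, function(ch) {
    data.frame(channel = ch$name, a = as.integer(ch$a), b = as.integer(ch$b),
               phi_m = as.numeric(ch$phi_m), phi_h = as.numeric(ch$phi_h),
               kinetics_m = ch$kinetics_m, kinetics_h = ch$kinetics_h,
               reversal = ch$reversal, permeant_ion = ch$permeant_ion,
               stringsAsFactors = FALSE)
  }))
}

.check_ca <- function(channel, ca) {
  if (channel %in% .CA_GATED && is.null(ca))
    stop("channel ", channel,
         " is calcium-gated: a perimembrane calcium value (mM) is required",
         call. = FALSE)
  if (is.null(ca)) ca <- 0 else {
    if (any(!is.finite(ca)) || any(ca < 0))
      stop("calcium concentration must be finite and >= 0", call. = FALSE)
  }
  ca
}

#' Steady-state activation curves and time constants
#'
#' Evaluates a channel's steady states (`m_inf`, `h_inf`) and time constants
#' (`tau_m`, `tau_h`, ms) at the given membrane potential and, for
#' calcium-gated channels, perimembrane calcium concentration.  For
#' alpha/beta-form channels `m_inf = alpha/(alpha+beta)` and
#' `tau = 1/(alpha+beta)`; removable singularities in the rate functions are
#' evaluated by their analytic limits.  The temperature coefficient Phi is
#' *not* applied here; it enters the state-update equation
#' (see [gating_derivative()]).
#'
#' @param channel Channel name (see [channel_name()]).
#' @param v Membrane potential, mV (vectorised).
#' @param ca Perimembrane calcium, mM; required for `KCa`, `CAN` and `CaL`.
#' @return List with numeric vectors `m_inf`, `tau_m`, `h_inf`, `tau_h`
#'   (`NA` for gates the channel does not have; `tau_h` is `NA` for the
#'   instantaneous Ca(L) inactivation gate).
#' @export
gating_curves <- function(channel, v, ca = NULL) {
  idx <- .channel_index(channel)
  ca <- .check_ca(.CHANNELS[idx], ca)
  stopifnot(all(is.finite(v)))
  if (length(ca) != 1L && length(ca) != length(v))
    stop("ca must be scalar or the same length as v", call. = FALSE)
  cpp_gating_curves(idx - 1L, as.numeric(v), as.numeric(ca))
}

#' Hodgkin-Huxley channel current density
#'
#' `I = Gmax * m^a * h^b * (V - E)`, positive outward, in mA/cm2.  The ohmic
#' channels (`leak`, `nic`) carry no gates (`m^0 h^0 = 1`).
#'
#' @param channel Channel name, including `"leak"` and `"nic"`.
#' @param v Membrane potential, mV.
#' @param e Reversal potential, mV.
#' @param gmax Maximal conductance density, S/cm2 (>= 0).
#' @param m,h Gating state in `[0, 1]`; ignored for ohmic channels.
#' @return Current density, mA/cm2.
#' @export
channel_current <- function(channel, v, e, gmax, m = 1, h = 1) {
  nm <- channel_name(channel, ohmic_ok = TRUE)
  stopifnot(all(gmax >= 0))
  if (nm %in% .OHMIC) return(gmax * (v - e))
  if (any(m < 0 | m > 1) || any(h < 0 | h > 1))
    stop("gating state components must lie in [0, 1]", call. = FALSE)
  gmax * m^.CH_A[[nm]] * h^.CH_B[[nm]] * (v - e)
}

#' Gating-state time derivatives
#'
#' `dm/dt = Phi_m (m_inf - m)/tau_m` and `dh/dt = Phi_h (h_inf - h)/tau_h`
#' (per ms).  Instantaneous gates (the Ca(L) inactivation, set algebraically
#' each step) return derivative zero.
#'
#' @inheritParams gating_curves
#' @param m,h Current gating state.
#' @return List with `dm` and `dh` (per ms; `dh` is `NA` for channels with
#'   no inactivation gate, `0` for instantaneous ones).
#' @export
gating_derivative <- function(channel, m, h = NULL, v, ca = NULL) {
  nm <- channel_name(channel)
  cv <- gating_curves(nm, v, ca)
  dm <- .CH_PHIM[[nm]] * (cv$m_inf - m) / cv$tau_m
  dh <- NA_real_
  if (.CH_B[[nm]] > 0) {
    if (nm == "CaL") {
      dh <- rep(0, length(v))  # instantaneous, set algebraically
    } else {
      if (is.null(h)) stop("channel ", nm, " has an inactivation gate: h required")
      dh <- .CH_PHIH[[nm]] * (cv$h_inf - h) / cv$tau_h
    }
  }
  list(dm = dm, dh = dh)
}

#' Instantaneous (algebraic) gates
#'
#' The Ca(L) inactivation gate tracks perimembrane calcium instantaneously:
#' `h = 1.245 / (1.245 + [Ca]_i)`.
#'
#' @param channel Channel name; only `"CaL"` has an instantaneous gate.
#' @param ca Perimembrane calcium, mM (>= 0).
#' @return Gate value in `(0, 1]`.
#' @export
instantaneous_gates <- function(channel, ca) {
  nm <- channel_name(channel)
  if (nm != "CaL")
    stop("channel ", nm, " has no instantaneous gate", call. = FALSE)
  stopifnot(all(ca >= 0))
  1.245 / (1.245 + ca)
}

#' Write gating-curve tables for plotting or validation
#'
#' Dumps `(V, m_inf, tau_m, h_inf, tau_h)` over a voltage grid as
#' tab-delimited text, one file per channel.
#'
#' @param channel Channel name.
#' @param file Output path.
#' @param v Voltage grid, mV.
#' @param ca Calcium value for calcium-gated channels, mM.
#' @return The output path, invisibly.
#' @export
dump_gating_curves <- function(channel, file, v = seq(-120, 60, by = 0.5),
                               ca = 2.4e-4) {
  cv <- gating_curves(channel, v, ca)
  df <- data.frame(v_mV = v, m_inf = cv$m_inf, tau_m_ms = cv$tau_m,
                   h_inf = cv$h_inf, tau_h_ms = cv$tau_h)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
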