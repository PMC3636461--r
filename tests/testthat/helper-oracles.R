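# Independent transcriptions of the published rate equations, written
# directly from the kinetics table.  These act as an oracle for the compiled
# kinetics core; they deliberately use plain formulas (no shared code).

or_na_alpha_m <- function(v) {
  ifelse(abs(v + 39) < 1e-12, 0.32 * 4,
         0.32 * (v + 39) / (1 - exp(-(v + 39) / 4)))
}
or_na_beta_m <- function(v) {
  ifelse(abs(v + 12) < 1e-12, 0.28 * 5,
         -0.28 * (v + 12) / (1 - exp((v + 12) / 5)))
}
or_na_alpha_h <- function(v) 0.128 * exp(-(v + 35) / 18)
or_na_beta_h <- function(v) 4 / (1 + exp(-(v + 12) / 5))
or_k_alpha_m <- function(v) {
  ifelse(abs(v + 37) < 1e-12, 0.032 * 5,
         0.032 * (v + 37) / (1 - exp(-(v + 37) / 5)))
}
or_k_beta_m <- function(v) 0.5 * exp(-(v + 42) / 40)
or_ka <- function(v) {
  am <- exp(-0.118 * (v + 33.6)); bm <- exp(-0.071 * (v + 33.6))
  ah <- exp(0.157 * (v + 83))
  list(m_inf = 1 / (1 + am), tau_m = 50 * bm / (1 + am),
       h_inf = 1 / (1 + ah), tau_h = 12.5 * ah / (1 + ah))
}
or_h <- function(v) {
  list(m_inf = 1 / (1 + exp((v + 80) / 10)),
       tau_m = 1176.5 * exp((v + 65) / 23.5) / (1 + exp((v + 65) / 11.8)))
}
or_cat <- function(v) {
  list(m_inf = 1 / (1 + exp(-(v + 49) / 7.4)),
       tau_m = 3 + 1 / (exp((v + 24) / 10) + exp(-(v + 99) / 15)),
       h_inf = 1 / (1 + exp((v + 77) / 5)),
       tau_h = 85 + 1 / (exp((v + 45) / 4) + exp(-(v + 404) / 50)))
}
or_cal_m <- function(v) list(m_inf = 1 / (1 + exp(-(v + 30) / 6)), tau_m = 20)
or_kca <- function(ca) {
  list(m_inf = ca^2 / (6.25e-4 + ca^2),
       tau_m = pmax(0.021 / (6.25e-4 + ca^2), 0.1))
}
or_can <- function(ca) {
  list(m_inf = ca^2 / (1e-4 + ca^2),
       tau_m = pmax(1 / (2e-3 + 20 * ca^2), 0.1))
}

# fixed-step RK4 for a scalar gating ODE dx/dt = phi*(xinf - x)/tau
rk4_gate <- function(x0, xinf, tau, phi, t_end, dt = tau / phi / 200) {
  f <- function(x) phi * (xinf - x) / tau
  x <- x0
  n <- ceiling(t_end / dt)
  dt <- t_end / n
  for (i in seq_len(n)) {
    k1 <- f(x); k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2); k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}
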