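# Current-clamp integration and the colored noise source.

test_that("passive cell shows linear exponential charging to I*R_in", {
  cell <- build_cell(parameter_set(label = "passive"))
  proto <- stimulus_protocol(-1, dur_ms = 1500, onset_ms = 50, post_ms = 50)
  tr <- run_current_clamp(cell, proto, dt = 0.025,
                          settle_ms = 500, settle_max_ms = 1000)
  t <- tr$time; v <- soma_v(tr)
  base <- mean(v[t < 50])
  vss <- mean(v[t > 1400 & t < 1550])
  expect_equal(vss - base, -1e-3 * 775, tolerance = 0.01)  # -0.775 mV
  # monotone charging, no overshoot in the passive response
  seg <- v[t > 50 & t < 300]
  expect_true(all(diff(seg) <= 1e-9))
  # linearity: response scales with amplitude and is sign-symmetric
  tr2 <- run_current_clamp(cell, stimulus_protocol(0.5, 1500, 50, 50),
                           dt = 0.025, settle_ms = 500, settle_max_ms = 1000)
  v2 <- soma_v(tr2)
  vss2 <- mean(v2[t > 1400 & t < 1550]) - mean(v2[t < 50])
  expect_equal(vss2 / (vss - base), -0.5, tolerance = 0.01)
})

test_that("zero stimulus leaves every preset at its resting fixed point", {
  quiet <- stimulus_protocol(0, dur_ms = 300, onset_ms = 0, post_ms = 0)
  cell <- build_cell(load_preset("fig2C")$params)
  tr <- run_current_clamp(cell, quiet, dt = 0.01)
  expect_length(detect_spikes(tr), 0)
  expect_lt(max(abs(soma_v(tr) - tr$v_rest)), 1e-2)
  expect_lt(tr$meta$settle_dvmax, 1e-6)
  # uniform initial V on the passive cell: exact fixed point
  pc <- build_cell(parameter_set())
  tp <- run_current_clamp(pc, quiet, dt = 0.01, settle_ms = 500,
                          settle_max_ms = 500)
  expect_lt(tp$meta$settle_dvmax, 1e-9)
  expect_lt(max(abs(soma_v(tp) - tp$v_rest)), 1e-9)
})

test_that("white noise source has the stated statistics and determinism", {
  ns <- noise_source(seed = 42)
  w <- generate_colored_noise(1e6, 0.125, ns, white = TRUE)
  expect_equal(sd(w), 0.05, tolerance = 3 / sqrt(2 * 1e6) )
  expect_lt(abs(mean(w)), 3 * 0.05 / sqrt(1e6))
  expect_identical(w, generate_colored_noise(1e6, 0.125, ns, white = TRUE))
  w2 <- generate_colored_noise(1e6, 0.125, noise_source(seed = 43),
                               white = TRUE)
  expect_false(identical(w, w2))
  expect_error(generate_colored_noise(10, dt = 0.5), "0.125")
})

test_that("colored noise decays with the 5 ms kernel time constant", {
  ns <- noise_source(seed = 7)
  y <- generate_colored_noise(4e5, 0.125, ns)
  ac <- stats::acf(y, lag.max = 40, plot = FALSE)$acf[, 1, 1]
  lags <- (0:40) * 0.125
  fit <- stats::lm(log(ac) ~ lags)  # all lags <= 5 ms stay positive
  tau_hat <- -1 / coef(fit)[["lags"]]
  expect_equal(tau_hat, 5, tolerance = 0.1)
  # coloring is a pure convolution: linear in the white input
  w <- generate_colored_noise(1000, 0.125, ns, white = TRUE)
  a <- exp(-0.125 / 5)
  y2 <- as.numeric(stats::filter(w, a, method = "recursive"))
  expect_equal(generate_colored_noise(1000, 0.125, ns), y2, tolerance = 1e-12)
})

test_that("noisy simulations are reproducible under a fixed seed", {
  pre <- load_preset("fig2D")
  cell <- build_cell(pre$params)
  proto <- stimulus_protocol(7.5, dur_ms = 100, onset_ms = 20, post_ms = 20)
  t1 <- run_current_clamp(cell, proto, noise = noise_source(seed = 11),
                          dt = 0.02, settle_ms = 500, settle_max_ms = 500)
  t2 <- run_current_clamp(cell, proto, noise = noise_source(seed = 11),
                          dt = 0.02, settle_ms = 500, settle_max_ms = 500)
  expect_identical(t1$v, t2$v)
  t3 <- run_current_clamp(cell, proto, noise = noise_source(seed = 12),
                          dt = 0.02, settle_ms = 500, settle_max_ms = 500)
  expect_false(identical(t1$v, t3$v))
})

test_that("recorded conductances stay within gating bounds", {
  pre <- load_preset("fig3A")
  cell <- build_cell(pre$params)
  proto <- stimulus_protocol(10, dur_ms = 300, onset_ms = 50, post_ms = 50)
  tr <- record_conductances(cell, proto, channels = c("CaT", "KA", "CAN"),
                            compartment = "dend1", dt = 0.02)
  expect_true(all(tr$g[, "CaT"] >= 0 & tr$g[, "CaT"] <= 0.005))
  expect_true(all(tr$g[, "KA"] >= 0 & tr$g[, "KA"] <= 0.1))
  # zero-Gmax channel records an identically zero series
  expect_true(all(tr$g[, "CAN"] == 0))
  # structurally absent channel cannot be recorded
  p <- pre$params; p$cat_scope <- "soma"
  expect_error(record_conductances(build_cell(p), proto, channels = "CaT",
                                   compartment = "dend1"),
               "not expressed")
})

test_that("traces serialize as delimited text with unit-bearing headers", {
  cell <- build_cell(parameter_set())
  tr <- run_current_clamp(cell, stimulus_protocol(1, 50, 10, 10), dt = 0.05,
                          settle_ms = 200, settle_max_ms = 200)
  f <- tempfile(fileext = ".tsv")
  write_trace(tr, f, sidecar = TRUE)
  df <- read.delim(f)
  expect_true(all(c("time_ms", "v_soma_mV", "ca_mM") %in% names(df)))
  expect_equal(nrow(df), length(tr$time))
  expect_true(file.exists(paste0(f, ".meta.yaml")))
  meta <- yaml::read_yaml(paste0(f, ".meta.yaml"))
  expect_equal(meta$dt, 0.05)
  unlink(c(f, paste0(f, ".meta.yaml")))
})

test_that("enabling the nicotinic conductance recruits extra spiking", {
  pre <- load_preset("fig2B")
  proto <- stimulus_protocol(22, dur_ms = 600, onset_ms = 100, post_ms = 100)
  base <- run_current_clamp(build_cell(pre$params), proto, dt = 0.02)
  nic <- run_current_clamp(build_cell(set_nicotinic(pre$params, TRUE, 0.005)),
                           proto, dt = 0.02)
  n0 <- length(detect_spikes(base, window = c(100, 700)))
  n1 <- length(detect_spikes(nic, window = c(100, 700)))
  expect_gt(n1, 2 * n0)
  # uniform whole-cell expression at matched total conductance acts alike
  uni <- run_current_clamp(
    build_cell(set_nicotinic(pre$params, TRUE, 0.005, scope = "all")),
    proto, dt = 0.02)
  nu <- length(detect_spikes(uni, window = c(100, 700)))
  expect_lt(abs(nu - n1), 3)
})

test_that("compartmental integrator matches an independent stiff ODE solve", {
  # lumped isopotential version of the fig3B cell (the cell is electrically
  # compact), integrated by deSolve::lsoda at tight tolerance
  pre <- load_preset("fig3B"); gm <- pre$params$gmax
  cfg <- cell_config()
  cell <- build_cell(pre$params, cfg)
  area <- sum(cell$comp$area_cm2)
  gl <- cfg$passive$g_leak_S_cm2
  rhs <- function(t, y, p) {
    v <- y[1]; ca <- y[10]; g <- y[2:9]
    na <- gating_curves("Na", v); k <- gating_curves("K", v)
    ka <- gating_curves("KA", v); ct <- gating_curves("CaT", v, ca)
    hh <- gating_curves("H", v)
    eca <- calcium_reversal(ca)
    itot <- gm[["Na"]] * g[1]^3 * g[2] * (v - 50) +
      gm[["K"]] * g[3]^4 * (v + 85) +
      gm[["KA"]] * g[4] * g[5] * (v + 85) +
      gm[["CaT"]] * g[6]^2 * g[7] * (v - eca) +
      gm[["H"]] * g[8] * v + gl * (v + 70)
    iinj <- if (t >= 50 && t < 250) 10e-9 / area else 0
    dg <- c(0.24 * (na$m_inf - g[1]) / na$tau_m,
            0.24 * (na$h_inf - g[2]) / na$tau_h,
            0.24 * (k$m_inf - g[3]) / k$tau_m,
            0.46 * (ka$m_inf - g[4]) / ka$tau_m,
            0.46 * (ka$h_inf - g[5]) / ka$tau_h,
            0.85 * (ct$m_inf - g[6]) / ct$tau_m,
            0.90 * (ct$h_inf - g[7]) / ct$tau_h,
            0.35 * (hh$m_inf - g[8]) / hh$tau_m)
    icat <- gm[["CaT"]] * g[6]^2 * g[7] * (v - eca)
    dca <- max(0, -1e4 * icat / (2 * 96485.33212 * 0.1)) - (ca - 2.4e-4) / 5
    list(c(1000 * (-itot + iinj) / 1.2, dg, dca))
  }
  g0 <- c(gating_curves("Na", -69)$m_inf, gating_curves("Na", -69)$h_inf,
          gating_curves("K", -69)$m_inf,
          gating_curves("KA", -69)$m_inf, gating_curves("KA", -69)$h_inf,
          gating_curves("CaT", -69, 2.4e-4)$m_inf,
          gating_curves("CaT", -69, 2.4e-4)$h_inf,
          gating_curves("H", -69)$m_inf)
  settle <- deSolve::ode(c(-69, g0, 2.4e-4), c(0, 3000),
                         function(t, y, p) rhs(-1, y, p), NULL,
                         method = "lsoda", rtol = 1e-9, atol = 1e-9)
  y0 <- as.numeric(settle[nrow(settle), -1])
  ref <- deSolve::ode(y0, seq(0, 400, 0.5), rhs, NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-9)
  tr <- run_current_clamp(cell, stimulus_protocol(10, 200, 50, 150),
                          dt = 0.01, settle_ms = 3000)
  mine <- soma_v(tr)[match(seq(0, 400, 0.5), tr$time)]
  expect_lt(abs(tr$v_rest - y0[1]), 0.05)
  expect_lt(max(abs(mine - ref[, 2])), 0.2)
})
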