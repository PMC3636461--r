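# Channel kinetics: published half-activation identities, removable
# singularities, bounds, monotonicity and the gating fixed point.

test_that("printed half-activation identities hold", {
  expect_equal(gating_curves("H", -80)$m_inf, 0.5)
  ct <- gating_curves("CaT", c(-49, -77))
  expect_equal(ct$m_inf[1], 0.5)
  expect_equal(ct$h_inf[2], 0.5)
  expect_equal(gating_curves("KCa", 0, ca = 0.025)$m_inf, 0.5)
  expect_equal(gating_curves("CAN", -60, ca = 0.01)$m_inf, 0.5)
  expect_equal(gating_curves("CaL", -30, ca = 0)$m_inf, 0.5)
  expect_equal(gating_curves("CaL", 0, ca = 0)$tau_m, 20)
  # calcium-independence of voltage gates
  expect_equal(gating_curves("KCa", -120, ca = 0.025)$m_inf,
               gating_curves("KCa", +60, ca = 0.025)$m_inf)
})

test_that("compiled kinetics agree with independently transcribed rates", {
  v <- seq(-120, 60, by = 0.25)
  na <- gating_curves("Na", v)
  am <- or_na_alpha_m(v); bm <- or_na_beta_m(v)
  expect_equal(na$m_inf, am / (am + bm), tolerance = 1e-12)
  expect_equal(na$tau_m, 1 / (am + bm), tolerance = 1e-12)
  ah <- or_na_alpha_h(v); bh <- or_na_beta_h(v)
  expect_equal(na$h_inf, ah / (ah + bh), tolerance = 1e-12)
  k <- gating_curves("K", v)
  akm <- or_k_alpha_m(v); bkm <- or_k_beta_m(v)
  expect_equal(k$m_inf, akm / (akm + bkm), tolerance = 1e-12)
  ka <- gating_curves("KA", v); o <- or_ka(v)
  expect_equal(ka$m_inf, o$m_inf, tolerance = 1e-12)
  expect_equal(ka$tau_m, o$tau_m, tolerance = 1e-12)
  expect_equal(ka$h_inf, o$h_inf, tolerance = 1e-12)
  expect_equal(ka$tau_h, o$tau_h, tolerance = 1e-12)
  h <- gating_curves("H", v); o <- or_h(v)
  expect_equal(h$m_inf, o$m_inf, tolerance = 1e-12)
  expect_equal(h$tau_m, o$tau_m, tolerance = 1e-12)
  ct <- gating_curves("CaT", v); o <- or_cat(v)
  expect_equal(ct$m_inf, o$m_inf, tolerance = 1e-12)
  expect_equal(ct$tau_m, o$tau_m, tolerance = 1e-12)
  expect_equal(ct$h_inf, o$h_inf, tolerance = 1e-12)
  expect_equal(ct$tau_h, o$tau_h, tolerance = 1e-12)
  ca <- 10^seq(-5, 0.5, by = 0.05)
  kca <- gating_curves("KCa", rep(-60, length(ca)), ca); o <- or_kca(ca)
  expect_equal(kca$m_inf, o$m_inf, tolerance = 1e-12)
  expect_equal(kca$tau_m, o$tau_m, tolerance = 1e-12)
  can <- gating_curves("CAN", rep(-60, length(ca)), ca); o <- or_can(ca)
  expect_equal(can$m_inf, o$m_inf, tolerance = 1e-12)
  expect_equal(can$tau_m, o$tau_m, tolerance = 1e-12)
})

test_that("removable singularities are evaluated by their analytic limits", {
  # Na alpha_m at V = -39: limit 0.32 * 4 = 1.28 /ms
  na <- gating_curves("Na", -39)
  expect_lt(abs(na$m_inf / na$tau_m - 1.28), 1e-9)
  # Na beta_m at V = -12: limit 0.28 * 5 = 1.4 /ms
  na <- gating_curves("Na", -12)
  expect_lt(abs((1 - na$m_inf) / na$tau_m - 1.4), 1e-9)
  # K alpha_m at V = -37: limit 0.032 * 5 = 0.16 /ms
  k <- gating_curves("K", -37)
  expect_lt(abs(k$m_inf / k$tau_m - 0.16), 1e-9)
  # within +/- 1 mV of the singularity the direct formula applies exactly
  for (dv in c(-1, -0.5, 0.5, 1)) {
    na <- gating_curves("Na", -39 + dv)
    expect_lt(abs(na$m_inf / na$tau_m - or_na_alpha_m(-39 + dv)), 1e-12)
  }
})

test_that("curves are bounded and time constants strictly positive", {
  v <- seq(-120, 60, by = 0.5)
  for (ch in c("Na", "K", "KA", "KCa", "H", "CaL", "CaT", "CAN")) {
    for (ca in c(0, 2.4e-4, 0.01, 1, 10)) {
      cv <- gating_curves(ch, v, ca)
      expect_true(all(cv$m_inf >= 0 & cv$m_inf <= 1), label = ch)
      expect_true(all(cv$tau_m > 0), label = ch)
      hin <- cv$h_inf[!is.na(cv$h_inf)]
      expect_true(all(hin >= 0 & hin <= 1), label = ch)
      th <- cv$tau_h[!is.na(cv$tau_h)]
      expect_true(all(th > 0), label = ch)
    }
  }
})

test_that("activation/inactivation curves are monotone", {
  v <- seq(-120, 60, by = 0.5)
  for (ch in c("Na", "K", "KA", "CaL", "CaT"))
    expect_true(all(diff(gating_curves(ch, v, 1e-4)$m_inf) >= 0), label = ch)
  expect_true(all(diff(gating_curves("H", v)$m_inf) <= 0))
  for (ch in c("Na", "KA", "CaT"))
    expect_true(all(diff(gating_curves(ch, v, 1e-4)$h_inf) <= 0), label = ch)
  ca <- 10^seq(-5, 0, by = 0.05)
  expect_true(all(diff(gating_curves("KCa", rep(-60, length(ca)), ca)$m_inf) >= 0))
  expect_true(all(diff(gating_curves("CAN", rep(-60, length(ca)), ca)$m_inf) >= 0))
  expect_true(all(diff(instantaneous_gates("CaL", ca)) <= 0))
})

test_that("channel_current implements the Hodgkin-Huxley product", {
  expect_equal(channel_current("K", v = -85, e = -75, gmax = 0.01, m = 1), -0.1)
  expect_equal(channel_current("Na", v = 13, e = 13, gmax = 0.5, m = 0.4, h = 0.7), 0)
  expect_equal(channel_current("CaT", v = -20, e = 100, gmax = 0, m = 1, h = 1), 0)
  # gating orders: Na uses m^3 h, K uses m^4
  expect_equal(channel_current("Na", v = 0, e = 50, gmax = 0.02, m = 0.5, h = 0.5),
               0.02 * 0.5^3 * 0.5 * (-50))
  expect_equal(channel_current("K", v = 0, e = -85, gmax = 0.01, m = 0.5),
               0.01 * 0.5^4 * 85)
  # ohmic channels carry no gates
  expect_equal(channel_current("leak", v = -60, e = -70, gmax = 2e-4),
               2e-4 * 10)
  expect_equal(channel_current("nic", v = 3.2, e = 3.2, gmax = 0.005), 0)
  expect_error(channel_current("K", v = 0, e = -85, gmax = 0.01, m = 1.2),
               "\\[0, 1\\]")
})

test_that("gating derivatives vanish at the fixed point and follow Phi-scaled rates", {
  cv <- gating_curves("H", -80)
  expect_equal(gating_derivative("H", m = cv$m_inf, v = -80)$dm, 0)
  # H at m = 0, V = -80: dm/dt = 0.35 * (0.5 - 0) / tau_m(-80)
  d <- gating_derivative("H", m = 0, v = -80)
  expect_equal(d$dm, 0.35 * 0.5 / or_h(-80)$tau_m, tolerance = 1e-12)
  # instantaneous Ca(L) inactivation has zero ODE derivative
  expect_equal(gating_derivative("CaL", m = 0.2, v = -30, ca = 0.1)$dh, 0)
})

test_that("gating ODE converges to the steady state within 10 tau/Phi", {
  cases <- list(list(ch = "H", v = -80, phi = 0.35),
                list(ch = "Na", v = -50, phi = 0.24),
                list(ch = "CaT", v = -65, phi = 0.85))
  for (cs in cases) {
    cv <- gating_curves(cs$ch, cs$v, 2.4e-4)
    x <- rk4_gate(cv$m_inf + 0.02, cv$m_inf, cv$tau_m, cs$phi,
                  t_end = 10 * cv$tau_m / cs$phi)
    expect_lt(abs(x - cv$m_inf), 1e-6, label = cs$ch)
  }
})

test_that("instantaneous Ca(L) gate follows the printed saturation", {
  expect_equal(instantaneous_gates("CaL", 0), 1)
  expect_equal(instantaneous_gates("CaL", 1.245), 0.5)
  expect_lt(instantaneous_gates("CaL", 1e6), 1e-5)
  expect_error(instantaneous_gates("Na", 0.1), "no instantaneous gate")
})

test_that("calcium-gated channels demand a calcium value", {
  expect_error(gating_curves("KCa", -60), "calcium")
  expect_error(gating_curves("CAN", -60), "calcium")
  expect_error(gating_curves("CaL", -60), "calcium")
  expect_silent(gating_curves("Na", -60))
  expect_error(gating_curves("KCa", -60, ca = -1))
})

test_that("channel catalogue records the published orders and Phi values", {
  cat <- channel_catalog()
  rows <- split(cat, cat$channel)
  expect_equal(rows$Na$a, 3L);  expect_equal(rows$Na$b, 1L)
  expect_equal(rows$K$a, 4L);   expect_equal(rows$K$b, 0L)
  expect_equal(rows$KA$a, 1L);  expect_equal(rows$KA$b, 1L)
  expect_equal(rows$KCa$a, 2L); expect_equal(rows$H$a, 1L)
  expect_equal(rows$CaL$a, 2L); expect_equal(rows$CaL$b, 1L)
  expect_equal(rows$CaT$a, 2L); expect_equal(rows$CaT$b, 1L)
  expect_equal(rows$CAN$a, 2L)
  expect_equal(rows$Na$phi_m, 0.24); expect_equal(rows$K$phi_m, 0.24)
  expect_equal(rows$KA$phi_m, 0.46); expect_equal(rows$KCa$phi_m, 1.12)
  expect_equal(rows$H$phi_m, 0.35);  expect_equal(rows$CaL$phi_m, 1)
  expect_equal(rows$CaT$phi_m, 0.85); expect_equal(rows$CaT$phi_h, 0.90)
  expect_equal(rows$CAN$phi_m, 1.12)
})

test_that("gating curve dumps are readable delimited text", {
  f <- tempfile(fileext = ".tsv")
  dump_gating_curves("CaT", f, v = seq(-100, 0, by = 1), ca = 2.4e-4)
  df <- read.delim(f)
  expect_named(df, c("v_mV", "m_inf", "tau_m_ms", "h_inf", "tau_h_ms"))
  expect_equal(nrow(df), 101)
  unlink(f)
})
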