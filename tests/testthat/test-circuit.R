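p <- circuit_params(c_cl = 10e-12, g_cl = 1e-6)

test_that("the cleft-entering current is the capacitive plus ionic current", {
  flat <- cleft_ts(rep(-0.07, 200), dt = 1e-5, unit = "V")
  expect_lt(max(abs(cleft_entering_current(flat, p)$value)), 1e-18)
  # sine oracle: c_pre V0 w cos(wt)
  w <- 2 * pi * 500
  t <- seq(0, 10e-3, by = 1e-5)
  sine <- cleft_ts(0.05 * sin(w * t), time = t, unit = "V")
  got <- cleft_entering_current(sine, p)$value
  want <- p$c_pre * 0.05 * w * cos(w * t)
  inner <- 50:950
  expect_lt(max(abs(got - want)[inner]), 0.01 * max(abs(want)))
  # a pure ionic current passes through
  ica <- fix_ca(dt = 1e-5)
  flat2 <- cleft_ts(rep(-0.07, nrow(ica)), time = ica$time, unit = "V")
  expect_equal(cleft_entering_current(flat2, p, list(ica))$value, ica$value)
})

test_that("closed-form cleft potentials match both dissipation regimes", {
  # resistive: pointwise division
  const <- cleft_ts(rep(1e-9, 100), dt = 1e-5, unit = "A")
  expect_equal(predict_cleft_potential(const, p, "resistive")$value,
               rep(1e-3, 100))
  # capacitive: rectangular 10 pA x 1 ms over 20 pF ramps to 0.5 mV
  t <- seq(0, 2e-3, by = 1e-5)
  rect <- cleft_ts(ifelse(t > 0 & t <= 1e-3, 10e-12, 0), time = t, unit = "A")
  vc <- predict_cleft_potential(rect, p, "capacitive")
  expect_rel(max(vc$value), 0.5e-3, 0.02)
  expect_equal(vc$value[1], 0)
  # resistive Gaussian trough: -2 nA / 1 uS = -2 mV
  ica <- fix_ca()
  expect_rel(min(predict_cleft_potential(ica, p, "resistive")$value), -2e-3, 1e-6)
})

test_that("the full first-order cleft ODE bridges the two regimes", {
  ap <- make_action_potential(ap_shape(), dt = 5e-6)
  i_enter <- cleft_entering_current(ap, p)
  res <- predict_cleft_potential(i_enter, p, "resistive")$value
  cap <- predict_cleft_potential(i_enter, p, "capacitive")$value
  env_hi <- pmax(abs(res), abs(cap))
  for (scale in c(1e-2, 1, 1e2)) {
    pp <- circuit_params(c_cl = 10e-12, g_cl = 1e-6 * scale)
    full <- predict_cleft_potential(i_enter, pp, "full")$value
    res_s <- predict_cleft_potential(i_enter, pp, "resistive")$value
    cap_s <- predict_cleft_potential(i_enter, pp, "capacitive")$value
    expect_lte(max(abs(full)), 1.05 * max(pmax(abs(res_s), abs(cap_s))))
  }
  # limits: converges to the resistive form at high g_cl ...
  hi <- circuit_params(c_cl = 10e-12, g_cl = 1e-4)
  full_hi <- predict_cleft_potential(i_enter, hi, "full")$value
  res_hi <- predict_cleft_potential(i_enter, hi, "resistive")$value
  expect_lt(max(abs(full_hi - res_hi)), 0.02 * max(abs(res_hi)))
  # ... and to the capacitive form at low g_cl
  lo <- circuit_params(c_cl = 10e-12, g_cl = 1e-10)
  full_lo <- predict_cleft_potential(i_enter, lo, "full")$value
  cap_lo <- predict_cleft_potential(i_enter, lo, "capacitive")$value
  expect_lt(max(abs(full_lo - cap_lo)), 0.02 * max(abs(cap_lo)))
})

test_that("the VC prespike follows the regime-specific closed forms", {
  flat <- cleft_ts(rep(-0.08, 300), dt = 1e-5, unit = "V")
  expect_lt(max(abs(predict_vc_prespike(flat, p, "capacitive")$value)), 1e-18)
  expect_lt(max(abs(predict_vc_prespike(flat, p, "resistive")$value)), 1e-15)
  # resistive sine amplitude: g tau^2 V0 w^2
  w <- 2 * pi * 1000
  t <- seq(0, 5e-3, by = 2e-6)
  sine <- cleft_ts(0.05 * sin(w * t), time = t, unit = "V")
  got <- predict_vc_prespike(sine, p, "resistive")$value
  inner <- 500:2000
  expect_rel(max(abs(got[inner])), 1e-6 * (10e-6)^2 * 0.05 * w^2, 0.01)
  # capacitive prespike with c_syn = c_pre is exactly half of i_enter, inverted
  ap <- make_action_potential(ap_shape(), dt = 5e-6)
  i_enter <- cleft_entering_current(ap, p)
  expect_equal(predict_vc_prespike(ap, p, "capacitive")$value,
               -0.5 * i_enter$value)
  # linearity: doubling the AP amplitude doubles the resistive prespike
  ap2 <- make_action_potential(ap_shape(amplitude = 240e-3), dt = 5e-6)
  expect_equal(predict_vc_prespike(ap2, p, "resistive")$value,
               2 * predict_vc_prespike(ap, p, "resistive")$value,
               tolerance = 1e-9)
})

test_that("both forms of the resistive prespike agree and charge balances", {
  ap <- make_action_potential(ap_shape(), dt = 5e-6)
  i_enter <- cleft_entering_current(ap, p)
  a <- -tau_cl(p) * prespike:::ts_derivative(i_enter)$value
  b <- predict_vc_prespike(ap, p, "resistive")$value
  expect_lt(max(abs(a - b)), 1e-3 * max(abs(b)))
  # integral of the prespike over a full AP returning to rest is ~0
  expect_lt(abs(sum(b) * ts_dt(ap)), 1e-4 * max(abs(b)) * ts_fwhm(ap))
})

test_that("the calcium prespike inverts or differentiates the calcium current", {
  ica <- fix_ca(amplitude = -2e-9, tau_ca = 0.25e-3)
  expect_equal(predict_calcium_prespike(ica, p, "capacitive")$value, -ica$value)
  res <- predict_calcium_prespike(ica, p, "resistive")
  # Gaussian-derivative closed form: peaks of +/- tau_cl/tau_ca e^-0.5 |amp|
  # at t_peak -/+ tau_ca
  want_pk <- 10e-6 / 0.25e-3 * exp(-0.5) * 2e-9
  expect_rel(max(res$value), want_pk, 1e-3)
  expect_rel(min(res$value), -want_pk, 1e-3)
  expect_rel(res$time[which.max(res$value)], 2e-3 - 0.25e-3, 0.005)
  expect_rel(res$time[which.min(res$value)], 2e-3 + 0.25e-3, 0.005)
  zero <- cleft_ts(rep(0, 100), dt = 1e-5, unit = "A")
  expect_true(all(predict_calcium_prespike(zero, p, "resistive")$value == 0))
})

test_that("the current-clamp prespike is an RC response about rest", {
  z <- cleft_ts(rep(0, 400), dt = 1e-5, unit = "A")
  expect_equal(cc_prespike_from_current(z, p)$value, rep(p$v_rest, 400))
  # step oracle: exponential approach to I/g_post above rest
  step <- cleft_ts(rep(-0.5e-9, 4000), dt = 1e-5, unit = "A")
  got <- cc_prespike_from_current(step, p)
  tau <- p$c_post / p$g_post
  want <- p$v_rest + 0.5e-9 / p$g_post * (1 - exp(-(step$time) / tau))
  expect_lt(max(abs(got$value - want)), 1e-6 * max(abs(want - p$v_rest)))
  # biphasic current in -> biphasic voltage deflection, positive first
  ap <- make_action_potential(ap_shape(), dt = 5e-6)
  i_rec <- predict_vc_prespike(ap, p, "resistive")
  cc <- cc_prespike_from_current(i_rec, p)
  dev <- cc$value - p$v_rest
  expect_gt(max(dev), 0)
  expect_lt(min(dev), 0)
  expect_lt(which.max(dev), which.min(dev))
  expect_error(cc_prespike_from_current(z, circuit_params(g_post = 0)), "g_post")
})
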