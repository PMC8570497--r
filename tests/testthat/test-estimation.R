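p <- circuit_params(c_cl = 10e-12, g_cl = 1e-6) # tau_cl = 10 us

test_that("the local-quadratic derivative matches analytic oracles", {
  t <- seq(0, 1e-2, by = 1e-5)
  ramp <- cleft_ts(3 * t, time = t, unit = "V")
  d1 <- differentiate(ramp, 1)
  expect_lt(max(abs(d1$value - 3)), 1e-9)
  # sine second derivative at 50 samples per period (5-sample window: the
  # attenuation of a quadratic window grows with its length)
  w <- 2 * pi / (50 * 1e-5)
  sine <- cleft_ts(sin(w * t), time = t, unit = "V")
  d2 <- differentiate(sine, 2, window = 5)
  inner <- 30:(length(t) - 30)
  expect_lt(max(abs(d2$value + w^2 * sin(w * t))[inner]), 0.01 * w^2)
  # smoothing monotonicity: a larger window gives lower noise variance
  set.seed(1)
  noise <- cleft_ts(stats::rnorm(2000), dt = 1e-5, unit = "V")
  v_small <- stats::var(differentiate(noise, 1, 7)$value)
  v_large <- stats::var(differentiate(noise, 1, 21)$value)
  expect_lt(v_large, v_small)
  expect_error(differentiate(ramp, 1, window = 3), "too small")
})

test_that("prespike features capture the biphasic peaks and their delay", {
  ap <- make_action_potential(ap_shape(), dt = 2e-5)
  ps <- predict_vc_prespike(ap, p, "resistive")
  f <- extract_prespike_features(ps)
  expect_lt(f$neg_peak, 0)
  expect_gt(f$pos_peak, 0)
  expect_lt(f$t_neg, f$t_pos)
  # the delay equals the peak-to-peak delay of the inverted second derivative
  d2 <- differentiate(ap, 2)
  md2 <- cleft_ts(-d2$value, time = d2$time, unit = "A")
  f2 <- extract_prespike_features(md2)
  # the smoothed-derivative route broadens the lobes slightly relative to the
  # spline route inside predict_vc_prespike
  expect_rel(f$peak_delay, f2$peak_delay, 0.06)
  expect_error(extract_prespike_features(cleft_ts(rep(0, 100), dt = 1e-5, unit = "A")),
               "no prespike")
})

test_that("peak amplitudes at SNR 10 are unbiased to within 5% (Monte Carlo)", {
  ap <- make_action_potential(ap_shape(), dt = 2e-5)
  ps <- predict_vc_prespike(ap, p, "resistive")
  f0 <- extract_prespike_features(ps)
  sd0 <- max(abs(ps$value)) / 10
  set.seed(123)
  est <- purrr::map(1:100, function(i) {
    noisy <- cleft_ts(ps$value + stats::rnorm(nrow(ps), 0, sd0),
                      time = ps$time, unit = "A")
    extract_prespike_features(noisy, smooth_window = 7)
  }) |> dplyr::bind_rows()
  expect_rel(median(est$neg_peak), f0$neg_peak, 0.05)
  expect_rel(median(est$pos_peak), f0$pos_peak, 0.05)
})

test_that("noiseless resistive trains regress perfectly on the second derivative", {
  pr <- fix_protocol(n = 8, decay = 0.94, broad = 1.04)
  v_pre <- make_ap_train(ap_shape(), pr, dt = 2e-5)
  i_post <- predict_vc_prespike(v_pre, p, "resistive")
  fits <- fit_derivative_models(v_pre, i_post, pr$interval)
  expect_rel(fits$ap2$pearson_r, -1, 1e-4)
  expect_lt(fits$ap2$deviation_at_origin, 1e-2 * max(abs(i_post$value)))
  gt2 <- p$c_pre * p$c_syn / p$g_cl
  # the smoothed derivative attenuates the narrow second-derivative lobes,
  # so the recovered slope magnitude is a few percent low
  expect_rel(fits$ap2$slope, -gt2, 0.10)
  # the mismatched first-derivative model fits worse
  expect_lt(abs(fits$ap1$pearson_r), abs(fits$ap2$pearson_r))
  expect_gt(fits$ap1$deviation_at_origin, fits$ap2$deviation_at_origin)
})

test_that("capacitive-regime trains prefer the first derivative (converse)", {
  pr <- fix_protocol(n = 8, decay = 0.94, broad = 1.04)
  v_pre <- make_ap_train(ap_shape(), pr, dt = 2e-5)
  i_post <- predict_vc_prespike(v_pre, p, "capacitive")
  fits <- fit_derivative_models(v_pre, i_post, pr$interval)
  expect_gt(abs(fits$ap1$pearson_r), abs(fits$ap2$pearson_r))
  expect_lt(fits$ap1$deviation_at_origin, fits$ap2$deviation_at_origin)
})

test_that("a single AP yields an under-determined perfect fit", {
  ps <- tibble::tibble(neg_peak = -1e-10, pos_peak = 2e-10)
  dv <- tibble::tibble(pos_peak = 3e6, neg_peak = -5e6)
  fit <- regress_prespike_vs_derivative(ps, dv)
  expect_true(fit$underdetermined)
  expect_equal(abs(fit$pearson_r), 1)
  expect_error(
    regress_prespike_vs_derivative(ps, tibble::tibble(pos_peak = 1, neg_peak = 1)),
    "degenerate")
})

test_that("model comparison reduces to the textbook paired t-test", {
  mk <- function(r, dev) structure(list(pearson_r = r, deviation_at_origin = dev),
                                   class = "derivative_fit")
  f1 <- list(mk(-0.95, 120e-12), mk(-0.93, 100e-12), mk(-0.94, 140e-12))
  f2 <- list(mk(-0.98, 20e-12), mk(-0.99, 15e-12), mk(-0.97, 30e-12))
  cmp <- compare_derivative_models(f1, f2)
  # closed-form oracle via stats::t.test on the same numbers
  tt_r <- stats::t.test(c(-0.95, -0.93, -0.94), c(-0.98, -0.99, -0.97),
                        paired = TRUE)
  row_r <- dplyr::filter(cmp, metric == "pearson_r")
  expect_rel(row_r$t, unname(tt_r$statistic), 1e-9)
  expect_rel(row_r$p, tt_r$p.value, 1e-9)
  expect_equal(row_r$df, 2)
  # identical lists: t = 0, p = 1
  same <- compare_derivative_models(f1, f1)
  expect_true(all(same$t == 0) && all(same$p == 1))
  expect_error(compare_derivative_models(f1, f2[1:2]), "equal")
})

test_that("P/5 subtraction isolates exactly the calcium prespike", {
  rs <- fix_recording(noise_sd = 0)
  delta <- isolate_calcium_prespike(rs$active_sweeps, rs$passive_sweeps,
                                    rs$protocol$interval, skip = 2, use = 8)
  i_ca_ep <- fold_epochs(rs$i_ca_true, rs$protocol$interval, 2, 8)
  want <- predict_calcium_prespike(i_ca_ep, rs$truth[c("c_pre", "c_syn", "c_post",
                                                       "g_pre", "g_syn", "g_post",
                                                       "g_cl", "v_rest")] |>
                                     (\(x) do.call(circuit_params, x))(),
                                   "resistive")
  expect_lt(max(abs(delta$value - want$value)), 1e-6 * max(abs(want$value)))
  # without calcium the subtraction leaves nothing
  rs0 <- synthesize_p5_recording(protocol = fix_protocol(n = 6),
                                 ca_amplitude = 0, noise_sd = 0, seed = 2)
  d0 <- isolate_calcium_prespike(rs0$active_sweeps, rs0$passive_sweeps,
                                 rs0$protocol$interval, 1, 5)
  expect_lt(max(abs(d0$value)), 1e-20)
})

test_that("epoch averaging reduces noise as the square root of the count", {
  set.seed(5)
  pr <- fix_protocol(n = 27)
  noise <- cleft_ts(stats::rnorm(27 * 500 + 1), dt = 2e-5, unit = "A")
  one <- fold_epochs(noise, pr$interval, skip = 0, use = 1)
  many <- fold_epochs(noise, pr$interval, skip = 2, use = 25)
  expect_rel(sd(one$value) / sd(many$value), 5, 0.15)
  expect_error(fold_epochs(noise, pr$interval, skip = 20, use = 25), "epochs")
  expect_error(fold_epochs(noise, 1.00037e-3, 0, 1), "misaligned")
})

test_that("the peak-ratio estimator inverts the Gaussian forward model", {
  i_ca <- fix_ca(amplitude = -2e-9, tau_ca = 0.25e-3, dt = 2e-5)
  delta <- predict_calcium_prespike(i_ca, p, "resistive")
  est <- estimate_tau_cl_peak_ratio(delta, i_ca, cleft_fraction = 1)
  expect_rel(est$tau_cl, 10e-6, 0.02)
  expect_rel(est$tau_ca, 0.25e-3, 0.02)
  # assuming only 2/3 of the current is in the cleft scales tau_cl by 1.5
  est23 <- estimate_tau_cl_peak_ratio(delta, i_ca, cleft_fraction = 2 / 3)
  expect_rel(est23$tau_cl / est$tau_cl, 1.5, 1e-9)
  flat <- cleft_ts(rep(0, nrow(i_ca)), time = i_ca$time, unit = "A")
  expect_error(estimate_tau_cl_peak_ratio(flat, i_ca), "undetectable")
})

test_that("the slope estimator recovers tau_cl and imposed time shifts", {
  i_ca <- fix_ca(amplitude = -2e-9, tau_ca = 0.25e-3, dt = 5e-6)
  delta <- predict_calcium_prespike(i_ca, p, "resistive")
  est <- estimate_tau_cl_slope(delta, i_ca)
  expect_rel(est$tau_cl, 10e-6, 0.01)
  expect_lt(abs(est$lag), 5e-6)
  expect_gt(est$r, 0.999)
  # shift the calcium prespike by +60 us: the lag search must find it
  k <- 12L # 60 us at 5 us sampling
  shifted <- cleft_ts(c(rep(0, k), delta$value[1:(nrow(delta) - k)]),
                      time = delta$time, unit = "A")
  est2 <- estimate_tau_cl_slope(shifted, i_ca)
  expect_lt(abs(est2$lag - 60e-6), 2e-5)
  expect_rel(est2$tau_cl, 10e-6, 0.02)
  # pure noise carries no usable relation
  set.seed(9)
  noise <- cleft_ts(stats::rnorm(nrow(i_ca), 0, 1e-12), time = i_ca$time, unit = "A")
  expect_warning(out <- estimate_tau_cl_slope(noise, i_ca), "weak relation")
  expect_lt(out$r, 0.5)
  flat <- cleft_ts(rep(0, nrow(i_ca)), time = i_ca$time, unit = "A")
  expect_error(estimate_tau_cl_slope(flat, i_ca), "flat")
})

test_that("cleft parameters derive algebraically from slope and tau_cl", {
  d <- derive_cleft_parameters(0.1e-15, 10e-6, nm(30))
  expect_rel(d$g_cl, 1e-6, 1e-12)
  expect_rel(d$c_cl, 10e-12, 1e-12)
  expect_rel(to_ohm_cm(derive_cleft_parameters(0.1e-15, 10e-6, nm(30))$R_ex),
             75.4, 0.01)
  # doubling tau_cl at fixed slope quarters g_cl and halves c_cl
  d2 <- derive_cleft_parameters(0.1e-15, 20e-6, nm(30))
  expect_rel(d2$g_cl / d$g_cl, 0.25, 1e-12)
  expect_rel(d2$c_cl / d$c_cl, 0.5, 1e-12)
  expect_error(derive_cleft_parameters(0.1e-15, 0), "tau_cl")
})

test_that("the full pipeline recovers the generator's cleft parameters", {
  rs <- fix_recording(noise_sd = 0, params = fix_params(g_cl = 1e-6))
  est <- analyze_recording_set(rs, cleft_fraction = 1, skip = 2L, use = 8L)
  expect_rel(est$tau_cl_slope, 10e-6, 0.02)
  expect_rel(est$tau_cl_peak_ratio, 10e-6, 0.05)
  expect_rel(est$g_cl, 1e-6, 0.15)
  expect_rel(est$c_cl, 10e-12, 0.15)
  gl <- glance(est)
  expect_equal(gl$tau_cl_truth, 10e-6)
  td <- tidy(est)
  expect_true(all(c("tau_cl_slope", "g_cl", "R_ex_given_h") %in% td$term))
})
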