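test_that("identical seeds give identical recording sets", {
  a <- fix_recording(noise_sd = 20e-12, seed = 7, n = 4L)
  b <- fix_recording(noise_sd = 20e-12, seed = 7, n = 4L)
  expect_identical(a, b)
  c <- fix_recording(noise_sd = 20e-12, seed = 8, n = 4L)
  expect_false(identical(a$active_sweeps[[1]]$value, c$active_sweeps[[1]]$value))
})

test_that("passive sweeps are exact 1/5-scale responses (P/5 construction)", {
  rs <- fix_recording(noise_sd = 0, n = 4L)
  # summing five noiseless passive sweeps reproduces the capacitive part of
  # the active sweep; the difference is exactly the calcium prespike
  five_passive <- 5 * rs$passive_sweeps[[1]]$value
  params <- fix_params()
  cap <- predict_vc_prespike(rs$v_pre, params, "resistive")$value
  expect_lt(max(abs(five_passive - cap)), 1e-9 * max(abs(cap)))
  delta <- rs$active_sweeps[[1]]$value - five_passive
  want <- predict_calcium_prespike(rs$i_ca_true, params, "resistive")$value
  expect_lt(max(abs(delta - want)), 1e-9 * max(abs(want)))
})

test_that("capacitive-scenario sweeps follow the half-current rule", {
  rs <- fix_recording(scenario = "capacitive", noise_sd = 0, n = 4L)
  params <- fix_params()
  i_enter <- cleft_entering_current(rs$v_pre, params)
  want <- -0.5 * i_enter$value - rs$i_ca_true$value
  expect_lt(max(abs(rs$active_sweeps[[1]]$value - want)), 1e-12 * max(abs(want)))
})

test_that("the full-ODE scenario approaches the resistive forms for tau_cl << AP", {
  # the full cleft equation low-passes the resistive prespike with time
  # constant 2 tau_cl; convergence needs tau_cl well below the AP timescale
  err <- purrr::map_dbl(c(1e-6, 10e-6), function(g) {
    p <- fix_params(g_cl = g)
    a <- fix_recording(scenario = "full_ode", noise_sd = 0, n = 4L, params = p)
    b <- fix_recording(scenario = "resistive", noise_sd = 0, n = 4L, params = p)
    max(abs(a$active_sweeps[[1]]$value - b$active_sweeps[[1]]$value)) /
      max(abs(b$active_sweeps[[1]]$value))
  })
  expect_lt(err[2], 0.05) # tau_cl = 1 us vs ~100 us prespike lobes
  expect_lt(err[2], err[1]) # and the error shrinks with tau_cl
})

test_that("doubling the AP amplitude doubles the resistive prespike (linearity)", {
  r1 <- synthesize_p5_recording(shape = ap_shape(amplitude = 120e-3),
                                protocol = fix_protocol(n = 3), noise_sd = 0)
  r2 <- synthesize_p5_recording(shape = ap_shape(amplitude = 240e-3),
                                protocol = fix_protocol(n = 3), noise_sd = 0,
                                ca_amplitude = 0)
  r1b <- synthesize_p5_recording(shape = ap_shape(amplitude = 120e-3),
                                 protocol = fix_protocol(n = 3), noise_sd = 0,
                                 ca_amplitude = 0)
  expect_equal(r2$passive_sweeps[[1]]$value, 2 * r1b$passive_sweeps[[1]]$value,
               tolerance = 1e-9)
  expect_equal(r2$active_sweeps[[1]]$value, 2 * r1b$active_sweeps[[1]]$value,
               tolerance = 1e-9)
})

test_that("an EPSC contaminant appears in active sweeps only, after the calcium peak", {
  epsc <- list(amplitude = -1e-9, delay = 0.3e-3)
  rs <- fix_recording(noise_sd = 0, n = 4L, epsc = epsc)
  rs0 <- fix_recording(noise_sd = 0, n = 4L)
  expect_equal(rs$passive_sweeps[[1]]$value, rs0$passive_sweeps[[1]]$value)
  d <- rs$active_sweeps[[1]]$value - rs0$active_sweeps[[1]]$value
  expect_lt(min(d), -0.9e-9) # inward transient present
  # within the first stimulus epoch the EPSC trails the calcium trough
  ep1 <- rs$v_pre$time < 10e-3
  t_ca1 <- rs$i_ca_true$time[ep1][which.min(rs$i_ca_true$value[ep1])]
  expect_gt(rs$v_pre$time[ep1][which.min(d[ep1])], t_ca1)
})

test_that("recording sets round-trip through a directory of text files", {
  dir <- withr::local_tempdir()
  rs <- fix_recording(noise_sd = 15e-12, seed = 3, n = 3L)
  write_recording_set(rs, dir)
  expect_true(file.exists(file.path(dir, "metadata.json")))
  back <- read_recording_set(dir)
  expect_equal(back$v_pre$value, rs$v_pre$value, tolerance = 1e-12)
  expect_equal(back$active_sweeps[[1]]$value, rs$active_sweeps[[1]]$value,
               tolerance = 1e-12)
  expect_equal(length(back$passive_sweeps), length(rs$passive_sweeps))
  expect_equal(back$truth$tau_cl, rs$truth$tau_cl, tolerance = 1e-12)
  expect_equal(back$protocol$interval, rs$protocol$interval)
  expect_equal(back$seed, rs$seed)
})

test_that("unknown scenarios are rejected", {
  v <- make_ap_train(ap_shape(), fix_protocol(n = 2), dt = 2e-5)
  i <- prespike:::make_calcium_train(fix_protocol(n = 2), ap_shape(), dt = 2e-5)
  expect_error(synthesize_paired_recording(v, i, fix_params(), scenario = "weird"))
})
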