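# Forward-modelled paired recordings with known ground truth, emulating the
# paired voltage-clamp protocol: an APW command train, a pharmacologically
# isolated presynaptic calcium current, the P/5 passive protocol, additive
# Gaussian recording noise, and optionally an EPSC contaminant.

#' Synthesize a paired pre/postsynaptic recording with known ground truth
#'
#' Forward-models the postsynaptic voltage-clamp current evoked by a
#' presynaptic waveform plus calcium current under one of three scenarios:
#' * `"resistive"`: `i_rec = -g_cl tau_cl^2 v_pre'' - tau_cl i_ca'`
#'   (the resistive-dissipation closed forms);
#' * `"capacitive"`: `i_rec = -0.5 c_pre v_pre' - i_ca`;
#' * `"full_ode"`: the first-order lumped cleft equation
#'   `(c_pre + c_syn) dv_cl/dt + g_cl v_cl = c_pre v_pre' + i_ca` solved
#'   exactly, with `i_rec = -c_syn dv_cl/dt` (postsynaptic side clamped).
#'
#' Each passive sweep is the response to `v_pre` scaled by exactly 1/5 about
#' rest, with no calcium current (a fifth-sized command does not open the
#' calcium channels), so that summing five passive sweeps reproduces the
#' capacitive part of the active sweep — the P/5 protocol. Gaussian noise of
#' `noise_sd` is added independently to every sweep; a fixed seed makes the
#' output reproducible.
#'
#' @param v_pre presynaptic command waveform (`cleft_ts`, volts).
#' @param i_ca presynaptic calcium current (`cleft_ts`, amperes, inward
#'   negative), aligned with `v_pre`.
#' @param params ground-truth [circuit_params()].
#' @param scenario `"resistive"`, `"capacitive"` or `"full_ode"`.
#' @param noise_sd standard deviation of the additive current noise (A).
#' @param n_active,n_passive number of active / passive sweeps.
#' @param epsc optional EPSC contaminant descriptor, a list with `amplitude`
#'   (A, negative), `delay` (s after each calcium-current trough),
#'   `tau_rise` and `tau_decay` (s); the EPSC is a difference of
#'   exponentials added to active sweeps only.
#' @param seed integer RNG seed.
#' @param protocol optional [train_protocol()] recorded in the metadata so
#'   downstream epoch folding knows the stimulus interval.
#' @return an object of class `recording_set`: a list with `v_pre`,
#'   `i_ca_true`, `active_sweeps`, `passive_sweeps`, `truth` (the parameters
#'   plus scenario and `tau_cl`), `protocol` and `seed`.
#' @export
synthesize_paired_recording <- function(v_pre, i_ca, params,
                                        scenario = c("resistive", "capacitive", "full_ode"),
                                        noise_sd = 10e-12, n_active = 1L,
                                        n_passive = 5L, epsc = NULL, seed = 1L,
                                        protocol = NULL) {
  scenario <- match.arg(scenario)
  check_aligned(v_pre, i_ca)
  set.seed(seed)
  clean <- prespike_forward(v_pre, i_ca, params, scenario)
  epsc_part <- if (!is.null(epsc)) epsc_train(i_ca, epsc) else 0
  n <- nrow(v_pre)
  noisy <- function(base) ts_like(i_ca, base + stats::rnorm(n, 0, noise_sd), unit = "A")
  active <- purrr::map(seq_len(n_active), ~ noisy(clean$active + epsc_part))
  passive <- purrr::map(seq_len(n_passive), ~ noisy(clean$passive))
  truth <- params
  structure(list(v_pre = v_pre, i_ca_true = i_ca,
                 active_sweeps = active, passive_sweeps = passive,
                 truth = c(unclass(params),
                           list(tau_cl = tau_cl(params), scenario = scenario)),
                 protocol = protocol, seed = as.integer(seed)),
            class = "recording_set")
}

# noiseless active and single-passive responses per scenario
prespike_forward <- function(v_pre, i_ca, params, scenario) {
  v5 <- ts_like(v_pre, v_pre$value[1] + (v_pre$value - v_pre$value[1]) / 5, unit = "V")
  switch(scenario,
    resistive = list(
      active = predict_vc_prespike(v_pre, params, "resistive")$value +
        predict_calcium_prespike(i_ca, params, "resistive")$value,
      passive = predict_vc_prespike(v5, params, "resistive")$value),
    capacitive = list(
      active = predict_vc_prespike(v_pre, params, "capacitive")$value +
        predict_calcium_prespike(i_ca, params, "capacitive")$value,
      passive = predict_vc_prespike(v5, params, "capacitive")$value),
    full_ode = {
      run <- function(v, ion) {
        i_enter <- cleft_entering_current(v, params, ion)
        v_cl <- predict_cleft_potential(i_enter, params, "full")
        -params$c_syn * ts_derivative(v_cl)$value
      }
      list(active = run(v_pre, list(i_ca)), passive = run(v5, NULL))
    }
  )
}

# difference-of-exponentials EPSC after each calcium-current trough
epsc_train <- function(i_ca, epsc) {
  amp <- epsc$amplitude %||% -2e-9
  delay <- epsc$delay %||% 0.2e-3
  tr <- epsc$tau_rise %||% 0.2e-3
  td <- epsc$tau_decay %||% 1e-3
  v <- i_ca$value
  thr <- 0.5 * min(v)
  mins <- which(diff(sign(diff(v))) > 0) + 1L
  mins <- mins[v[mins] < thr]
  # merge plateau/adjacent detections: keep troughs at least 1 ms apart
  if (length(mins) > 1L) {
    gap <- round(1e-3 / ts_dt(i_ca))
    mins <- mins[c(TRUE, diff(mins) > gap)]
  }
  out <- rep(0, length(v))
  t <- i_ca$time
  for (m in mins) {
    s <- t - (t[m] + delay)
    w <- ifelse(s > 0, exp(-s / td) - exp(-s / tr), 0)
    out <- out + w / max(w) * amp
  }
  out
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf("<recording_set: %s scenario, %d active + %d passive sweeps, %d samples, tau_cl(truth) = %.3g us, seed %d>\n",
              x$truth$scenario, length(x$active_sweeps), length(x$passive_sweeps),
              nrow(x$v_pre), x$truth$tau_cl * 1e6, x$seed))
  invisible(x)
}

#' Synthesize a full P/5 train experiment
#'
#' Convenience wrapper that builds the complete study protocol: a train of
#' APW commands (default 45 identical waveforms at 100 Hz), a Gaussian
#' calcium-current pulse per stimulus during AP repolarisation, and the
#' paired active/passive (P/5) sweeps from [synthesize_paired_recording()].
#'
#' @param shape [ap_shape()] of the first APW.
#' @param protocol [train_protocol()].
#' @param params ground-truth [circuit_params()].
#' @param ca_amplitude,tau_ca calcium-current peak (A, negative) and Gaussian
#'   width (s).
#' @param dt sample interval (s); default 20 us, the recording-grade rate.
#' @inheritParams synthesize_paired_recording
#' @return a `recording_set` (with the protocol recorded for epoch folding).
#' @export
synthesize_p5_recording <- function(shape = ap_shape(), protocol = train_protocol(),
                                    params = circuit_params(),
                                    ca_amplitude = -1.9e-9, tau_ca = 0.217e-3,
                                    scenario = "resistive", noise_sd = 10e-12,
                                    n_active = 1L, n_passive = 5L, epsc = NULL,
                                    seed = 1L, dt = 20e-6) {
  v_pre <- make_ap_train(shape, protocol, dt = dt)
  i_ca <- make_calcium_train(protocol, shape, amplitude = ca_amplitude,
                             tau_ca = tau_ca, dt = dt)
  synthesize_paired_recording(v_pre, i_ca, params, scenario = scenario,
                              noise_sd = noise_sd, n_active = n_active,
                              n_passive = n_passive, epsc = epsc, seed = seed,
                              protocol = protocol)
}

#' Write / read a recording set as a directory of tabular text files
#'
#' Writes one tab-separated file per signal (time in ms, potentials in mV,
#' currents in nA) plus a `metadata.json` carrying units, the sample
#' interval, the ground-truth circuit parameters, the protocol and the seed,
#' so a written set can be re-read (or re-generated) bit-identically.
#'
#' @param rs a `recording_set`.
#' @param dir output directory (created if needed).
#' @return `write_recording_set()`: `dir`, invisibly;
#'   `read_recording_set()`: a `recording_set`.
#' @export
write_recording_set <- function(rs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_timeseries(rs$v_pre, file.path(dir, "v_pre.tsv"), name = "v_pre")
  write_timeseries(rs$i_ca_true, file.path(dir, "i_ca.tsv"), name = "i_ca")
  for (i in seq_along(rs$active_sweeps)) {
    write_timeseries(rs$active_sweeps[[i]],
                     file.path(dir, sprintf("active_%02d.tsv", i)), name = "i_post")
  }
  for (i in seq_along(rs$passive_sweeps)) {
    write_timeseries(rs$passive_sweeps[[i]],
                     file.path(dir, sprintf("passive_%02d.tsv", i)), name = "i_post")
  }
  meta <- list(
    dt_s = ts_dt(rs$v_pre), seed = rs$seed,
    units = list(time = "ms", v_pre = "mV", i_ca = "nA", i_post = "nA"),
    truth = rs$truth[!purrr::map_lgl(rs$truth, is.null)],
    protocol = if (!is.null(rs$protocol)) unclass(rs$protocol),
    n_active = length(rs$active_sweeps), n_passive = length(rs$passive_sweeps))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_recording_set
#' @export
read_recording_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE)
  rd <- function(f) read_timeseries(file.path(dir, f))
  active <- purrr::map(sprintf("active_%02d.tsv", seq_len(meta$n_active)), rd)
  passive <- purrr::map(sprintf("passive_%02d.tsv", seq_len(meta$n_passive)), rd)
  truth <- as.list(meta$truth)
  protocol <- if (!is.null(meta$protocol)) {
    do.call(train_protocol, as.list(meta$protocol))
  }
  structure(list(v_pre = rd("v_pre.tsv"), i_ca_true = rd("i_ca.tsv"),
                 active_sweeps = active, passive_sweeps = passive,
                 truth = truth, protocol = protocol,
                 seed = as.integer(meta$seed)),
            class = "recording_set")
}
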