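#' Parametric action-potential surrogate
#'
#' Describes a smooth surrogate for a presynaptic action-potential waveform
#' (APW) as the product of two logistic ramps with independent rise and decay
#' time constants, rescaled to a requested amplitude and full width at half
#' maximum. The true calyceal AP template is not public; this surrogate
#' matches its qualitative shape (fast rise, slower decay, smooth throughout)
#' and is twice differentiable, which matters because the resistive-regime
#' prespike is proportional to the second derivative of the AP.
#'
#' @param v_rest resting potential (V). Default -80 mV, the juvenile calyx
#'   resting potential used in the simulations.
#' @param amplitude peak depolarisation above rest (V). Default 120 mV.
#' @param fwhm full width at half maximum (s). Default 0.5 ms, the juvenile
#'   calyceal AP half-width; the mature AP is about 0.2 ms.
#' @param t_peak time of the peak (s).
#' @param asymmetry ratio of rise to decay time constants (dimensionless,
#'   < 1 means the rise is faster). Default 0.5.
#' @return an object of class `ap_shape`.
#' @examples
#' ap_shape(fwhm = 0.2e-3)
#' @export
ap_shape <- function(v_rest = -80e-3, amplitude = 120e-3, fwhm = 0.5e-3,
                     t_peak = 2 * fwhm, asymmetry = 0.5) {
  if (amplitude < 0) abort("amplitude must be >= 0 (depolarisation above rest)")
  if (fwhm <= 0) abort("fwhm must be positive")
  if (asymmetry <= 0) abort("asymmetry must be positive")
  structure(list(v_rest = v_rest, amplitude = amplitude, fwhm = fwhm,
                 t_peak = t_peak, asymmetry = asymmetry),
            class = "ap_shape")
}

# Base (unscaled) logistic-product pulse and its calibration.
# f(s) = plogis(s / tau_r) * plogis((delta - s) / 1), tau_r = asymmetry,
# evaluated in dimensionless time s; the peak value and FWHM of this base
# shape are found numerically once and cached per asymmetry.
ap_base <- function(asymmetry) {
  delta <- 2.5
  f <- function(s) stats::plogis(s / asymmetry) * stats::plogis(delta - s)
  s_pk <- stats::optimize(f, c(-5, delta + 5), maximum = TRUE)$maximum
  v_pk <- f(s_pk)
  half <- v_pk / 2
  s_lo <- stats::uniroot(function(s) f(s) - half, c(s_pk - 50, s_pk))$root
  s_hi <- stats::uniroot(function(s) f(s) - half, c(s_pk, s_pk + 50))$root
  list(f = f, s_pk = s_pk, v_pk = v_pk, fwhm = s_hi - s_lo)
}

# Evaluate one AP pulse (relative to rest) at times t, for a given shape,
# with amplitude and FWHM scaled exactly by construction.
ap_pulse <- function(t, shape) {
  if (shape$amplitude == 0) return(rep(0, length(t)))
  base <- ap_base(shape$asymmetry)
  k <- shape$fwhm / base$fwhm          # time scale factor
  s <- (t - shape$t_peak) / k + base$s_pk
  shape$amplitude * base$f(s) / base$v_pk
}

#' Generate a single surrogate action potential
#'
#' Samples the logistic-product AP surrogate on a uniform time base. The
#' waveform starts and ends at the resting potential, its measured FWHM
#' equals the requested one (the shape is calibrated numerically and then
#' rescaled in time, which preserves the width exactly), and time-rescaling
#' the same shape rescales all derivatives by the inverse power of the
#' scale factor.
#'
#' @param shape an [ap_shape()].
#' @param dt sample interval (s). Default 5 us (200 kHz), fine enough to
#'   resolve cleft time constants of ~10 us in forward models.
#' @param duration total duration (s); must exceed `t_peak + 5 * fwhm` so the
#'   waveform returns to rest.
#' @return a `cleft_ts` in volts.
#' @examples
#' ap <- make_action_potential(ap_shape(fwhm = 0.2e-3), dt = 5e-6)
#' ts_fwhm(ap) # 0.2 ms
#' @export
make_action_potential <- function(shape, dt = 5e-6,
                                  duration = shape$t_peak + 6 * shape$fwhm) {
  stopifnot(inherits(shape, "ap_shape"))
  min_dur <- shape$t_peak + 5 * shape$fwhm
  if (duration <= min_dur) {
    abort(sprintf("duration %.3g s too short for this pulse: need > %.3g s (t_peak + 5 fwhm)",
                  duration, min_dur))
  }
  if (shape$t_peak < 1.5 * shape$fwhm) {
    abort(sprintf("t_peak %.3g s too early: need >= %.3g s (1.5 fwhm) for the rise to start at rest",
                  shape$t_peak, 1.5 * shape$fwhm))
  }
  t <- seq(0, duration, by = dt)
  cleft_ts(shape$v_rest + ap_pulse(t, shape), time = t, unit = "V")
}

#' Train protocol for action-potential waveforms
#'
#' @param n_stimuli number of APs in the train (>= 1).
#' @param interval inter-stimulus interval (s). Default 10 ms (100 Hz), the
#'   stimulation rate of the paired-recording protocol.
#' @param amplitude_decay per-stimulus multiplicative amplitude factor; during
#'   natural 100 Hz trains the presynaptic AP becomes smaller. 1 = identical
#'   APWs as in the voltage-clamp command protocol.
#' @param broadening per-stimulus multiplicative FWHM factor; the AP also
#'   becomes slower during a train. 1 = identical APWs.
#' @return an object of class `train_protocol`.
#' @export
train_protocol <- function(n_stimuli = 45, interval = 10e-3,
                           amplitude_decay = 1, broadening = 1) {
  if (n_stimuli < 1) abort("n_stimuli must be >= 1")
  if (interval <= 0) abort("interval must be positive")
  structure(list(n_stimuli = as.integer(n_stimuli), interval = interval,
                 amplitude_decay = amplitude_decay, broadening = broadening),
            class = "train_protocol")
}

#' Generate a train of surrogate action potentials
#'
#' The k-th pulse (k = 0, 1, ...) has amplitude `amplitude * amplitude_decay^k`
#' and FWHM `fwhm * broadening^k`; pulse k peaks at `t_peak + k * interval`.
#' The total duration is `n_stimuli * interval`.
#'
#' @param shape an [ap_shape()] describing the first AP.
#' @param protocol a [train_protocol()].
#' @param dt sample interval (s).
#' @return a `cleft_ts` in volts.
#' @export
make_ap_train <- function(shape, protocol, dt = 5e-6) {
  stopifnot(inherits(shape, "ap_shape"), inherits(protocol, "train_protocol"))
  n <- protocol$n_stimuli
  fwhm_max <- shape$fwhm * protocol$broadening^(n - 1)
  if (protocol$interval <= 3 * fwhm_max) {
    abort(sprintf("pulses overlap: interval %.3g s must exceed 3x the widest FWHM (%.3g s)",
                  protocol$interval, fwhm_max))
  }
  if (shape$t_peak + 5 * fwhm_max >= protocol$interval) {
    abort("t_peak + 5 * (widest) fwhm must fit within one interval")
  }
  t <- seq(0, n * protocol$interval, by = dt)
  v <- rep(0, length(t))
  for (k in seq_len(n) - 1L) {
    pk <- list(v_rest = 0,
               amplitude = shape$amplitude * protocol$amplitude_decay^k,
               fwhm = shape$fwhm * protocol$broadening^k,
               t_peak = shape$t_peak + k * protocol$interval,
               asymmetry = shape$asymmetry)
    class(pk) <- "ap_shape"
    v <- v + ap_pulse(t, pk)
  }
  cleft_ts(shape$v_rest + v, time = t, unit = "V")
}

#' Generate a Gaussian presynaptic calcium current
#'
#' The presynaptic calcium current evoked by an APW is well approximated by a
#' Gaussian pulse during AP repolarisation:
#' `i(t) = amplitude * exp(-(t - t_peak)^2 / (2 * tau_ca^2))`.
#' Its FWHM is `2 * sqrt(2 * log(2)) * tau_ca`; the recorded juvenile calyceal
#' current has a peak of about -1.9 nA and a FWHM of about 0.51 ms
#' (tau_ca ~ 0.217 ms).
#'
#' @param amplitude peak current (A); inward currents are negative, so this
#'   must be <= 0.
#' @param t_peak time of the peak (s).
#' @param tau_ca Gaussian width parameter (s); must exceed `3 * dt` to be
#'   resolvable.
#' @param dt sample interval (s).
#' @param duration total duration (s).
#' @return a `cleft_ts` in amperes.
#' @export
make_calcium_current <- function(amplitude = -1.9e-9, t_peak = 1.5e-3,
                                 tau_ca = 0.217e-3, dt = 5e-6,
                                 duration = t_peak + 6 * tau_ca) {
  if (amplitude > 0) abort("amplitude must be <= 0 (inward current convention)")
  if (tau_ca <= 0) abort("tau_ca must be positive")
  if (tau_ca < 3 * dt) {
    abort(sprintf("tau_ca = %.3g s is unresolvable at dt = %.3g s (need tau_ca >= 3 dt)",
                  tau_ca, dt))
  }
  t <- seq(0, duration, by = dt)
  cleft_ts(amplitude * exp(-(t - t_peak)^2 / (2 * tau_ca^2)), time = t, unit = "A")
}

# Gaussian calcium-current train matching an AP train: one pulse per stimulus,
# peaking `ca_offset` after each AP peak, amplitude following the train decay.
make_calcium_train <- function(protocol, shape, amplitude = -1.9e-9,
                               tau_ca = 0.217e-3, ca_offset = 0.7 * shape$fwhm,
                               dt = 5e-6) {
  t <- seq(0, protocol$n_stimuli * protocol$interval, by = dt)
  i <- rep(0, length(t))
  for (k in seq_len(protocol$n_stimuli) - 1L) {
    tp <- shape$t_peak + ca_offset + k * protocol$interval
    i <- i + amplitude * protocol$amplitude_decay^k *
      exp(-(t - tp)^2 / (2 * tau_ca^2))
  }
  cleft_ts(i, time = t, unit = "A")
}
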