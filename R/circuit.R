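#' Lumped circuit parameters of the synapse
#'
#' Capacitances and conductances of the prespike-generating circuit: the
#' terminal's release face (`c_pre`, `g_pre`), the synaptic cleft with its
#' leak to the interstitial space (`g_cl`), and the postsynaptic cell, of
#' which `c_syn`/`g_syn` face the cleft and the remainder is
#' `c_nsyn = c_post - c_syn`, `g_nsyn = g_post - g_syn`. For a giant
#' calyx-type synapse the pre- and postsynaptic capacitances facing the cleft
#' are close to equal, and both are referred to as the cleft capacitance
#' `c_cl`; the cleft time constant is `tau_cl = c_cl / g_cl`.
#'
#' Defaults describe the juvenile calyx of Held: `c_cl` = 10 pF,
#' `g_cl` = 1 uS (so `tau_cl` = 10 us), postsynaptic resting conductance
#' 4 nS, and a postsynaptic rest of -70 mV. `g_cl = Inf` encodes a
#' zero-resistance cleft (no cleft potential).
#'
#' @param c_cl cleft-facing capacitance (F); sets `c_pre` and `c_syn` unless
#'   these are given explicitly.
#' @param g_cl cleft leak conductance (S); may be `Inf`.
#' @param c_pre,c_syn pre- and postsynaptic cleft-facing capacitances (F).
#' @param c_post total postsynaptic capacitance (F).
#' @param g_pre,g_syn,g_post leak conductances (S) of the release face, the
#'   cleft-facing postsynaptic membrane, and the whole postsynaptic cell.
#' @param v_rest postsynaptic resting potential (V).
#' @return an object of class `circuit_params`.
#' @examples
#' p <- circuit_params(c_cl = 10e-12, g_cl = 0.67e-6)
#' tau_cl(p) # ~ 15 us
#' @export
circuit_params <- function(c_cl = 10e-12, g_cl = 1e-6,
                           c_pre = c_cl, c_syn = c_cl, c_post = 25e-12,
                           g_pre = 5e-9, g_syn = 2e-9, g_post = 4e-9,
                           v_rest = -70e-3) {
  if (any(c(c_pre, c_syn, c_post) <= 0)) abort("all capacitances must be positive")
  if (g_cl <= 0) abort("g_cl must be positive (use Inf for a zero-resistance cleft)")
  if (c_post <= c_syn / 2) abort("c_post must exceed c_syn / 2")
  structure(list(c_pre = c_pre, c_syn = c_syn, c_post = c_post,
                 g_pre = g_pre, g_syn = g_syn, g_post = g_post,
                 g_cl = g_cl, v_rest = v_rest),
            class = "circuit_params")
}

#' @rdname circuit_params
#' @param params a `circuit_params` object.
#' @export
tau_cl <- function(params) cleft_capacitance(params) / params$g_cl

#' @rdname circuit_params
#' @export
cleft_capacitance <- function(params) (params$c_pre + params$c_syn) / 2

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf(paste0("<circuit_params: c_pre %.3g pF, c_syn %.3g pF, c_post %.3g pF,\n",
                     "  g_cl %.3g uS, g_post %.3g nS, v_rest %.1f mV, tau_cl %.3g us>\n"),
              x$c_pre * 1e12, x$c_syn * 1e12, x$c_post * 1e12,
              x$g_cl * 1e6, x$g_post * 1e9, x$v_rest * 1e3, tau_cl(x) * 1e6))
  invisible(x)
}

# spline-based derivative of a cleft_ts (exact time base preserved)
ts_derivative <- function(x, order = 1) {
  f <- splinefun(x$time, x$value, method = "natural")
  ts_like(x, f(x$time, deriv = order), unit = paste0(ts_unit(x), "/s^", order))
}

# cumulative trapezoidal integral, zero at t0
ts_cumtrapz <- function(x) {
  dt <- diff(x$time)
  inc <- dt * (head(x$value, -1) + tail(x$value, -1)) / 2
  c(0, cumsum(inc))
}

#' Current entering the synaptic cleft
#'
#' The cleft-entering current is the presynaptic capacitive current plus the
#' currents through the cleft-facing voltage-gated channels:
#' `i_enter(t) = c_pre * dv_pre/dt + sum(ionic currents)`.
#'
#' @param v_pre presynaptic potential, a `cleft_ts` in volts.
#' @param params a [circuit_params()].
#' @param ionic_currents optional list of `cleft_ts` currents (A) on the same
#'   time base (inward currents negative).
#' @return a `cleft_ts` in amperes.
#' @export
cleft_entering_current <- function(v_pre, params, ionic_currents = NULL) {
  if (ts_unit(v_pre) != "V") abort("v_pre must be a potential (unit 'V')")
  i <- params$c_pre * ts_derivative(v_pre)$value
  for (ion in ionic_currents %||% list()) {
    if (ts_unit(ion) != "A") abort("ionic currents must have unit 'A'")
    check_aligned(v_pre, ion)
    i <- i + ion$value
  }
  ts_like(v_pre, i, unit = "A")
}

#' Cleft potential predicted from the entering current
#'
#' Closed-form predictions for the two dissipation regimes, plus the full
#' first-order solution of the lumped cleft equation:
#' * `"capacitive"` (high cleft resistance; currents leave over the
#'   membranes' capacitance): `v_cl = (c_pre + c_syn)^-1 * integral(i_enter)`,
#'   with the integration constant chosen so `v_cl = 0` at the start.
#' * `"resistive"` (highly conductive cleft): `v_cl = i_enter / g_cl`.
#' * `"full"`: integrates
#'   `(c_pre + c_syn) dv_cl/dt + g_cl v_cl = i_enter` with an exponential
#'   integrator (exact for piecewise-linear input); this bridges the two
#'   regimes and converges to each as `g_cl` goes to 0 or infinity.
#'
#' The postsynaptic side is assumed voltage-clamped here, so the non-cleft
#' postsynaptic parameters do not enter.
#'
#' @param i_enter cleft-entering current, a `cleft_ts` in amperes.
#' @param params a [circuit_params()].
#' @param scenario `"capacitive"`, `"resistive"` or `"full"`.
#' @return a `cleft_ts` in volts (relative to the interstitial space).
#' @export
predict_cleft_potential <- function(i_enter, params,
                                    scenario = c("capacitive", "resistive", "full")) {
  scenario <- match.arg(scenario)
  v <- switch(scenario,
    capacitive = ts_cumtrapz(i_enter) / (params$c_pre + params$c_syn),
    resistive = i_enter$value / params$g_cl,
    full = solve_rc(i_enter$value, ts_dt(i_enter),
                    cap = params$c_pre + params$c_syn, g = params$g_cl)
  )
  ts_like(i_enter, v, unit = "V")
}

# exponential integrator for cap * dv/dt + g * v = u(t), v(0) = v0,
# exact for piecewise-linear u; for g = Inf returns u/g = 0.
solve_rc <- function(u, dt, cap, g, v0 = 0) {
  n <- length(u)
  if (!is.finite(g)) return(rep(0, n))
  tau <- cap / g
  e <- exp(-dt / tau)
  # response to u linear on [0, dt]: v1 = v0*e + (u0/g)*(1-e) + (du/g)*(1 - tau/dt*(1-e))
  f1 <- (1 - e)
  f2 <- 1 - (tau / dt) * (1 - e)
  v <- numeric(n)
  v[1] <- v0
  du <- diff(u)
  for (i in seq_len(n - 1)) {
    v[i + 1] <- v[i] * e + (u[i] / g) * f1 + (du[i] / g) * f2
  }
  v
}

#' Voltage-clamp prespike predicted from the presynaptic AP
#'
#' The prespike current a postsynaptic voltage-clamp amplifier records for a
#' purely capacitive cleft-entering current:
#' * capacitive regime: `i_rec = -c_syn / (c_pre + c_syn) * i_enter`, which is
#'   `-0.5 * i_enter` for the symmetric calyx-type synapse — the prespike
#'   resembles the inverted first derivative of the AP;
#' * resistive regime: `i_rec = -g_cl * tau_cl^2 * d2v_pre/dt2` — the prespike
#'   resembles the inverted second derivative of the AP.
#'
#' The first peak is negative for a rising AP in both regimes.
#'
#' @param v_pre presynaptic potential, a `cleft_ts` in volts.
#' @param params a [circuit_params()].
#' @param scenario `"capacitive"` or `"resistive"`.
#' @return a `cleft_ts` in amperes.
#' @export
predict_vc_prespike <- function(v_pre, params,
                                scenario = c("capacitive", "resistive")) {
  scenario <- match.arg(scenario)
  i <- switch(scenario,
    capacitive = {
      i_enter <- cleft_entering_current(v_pre, params)
      -params$c_syn / (params$c_pre + params$c_syn) * i_enter$value
    },
    resistive = {
      gt2 <- params$c_syn * params$c_pre / params$g_cl # = g_cl tau_cl^2 (symmetric)
      -gt2 * ts_derivative(v_pre, 2)$value
    }
  )
  ts_like(v_pre, i, unit = "A")
}

#' Calcium prespike predicted from the presynaptic calcium current
#'
#' The component of the prespike generated by the cleft-facing calcium
#' current: `-i_ca` in the capacitive regime (an inverted calcium current) and
#' `-tau_cl * di_ca/dt` in the resistive regime (an inverted, scaled first
#' derivative). For an inward Gaussian calcium current the resistive-regime
#' calcium prespike is biphasic, positive first, with a positive peak of
#' `tau_cl / tau_ca * exp(-0.5)` times the calcium-current amplitude.
#'
#' @param i_ca presynaptic calcium current, a `cleft_ts` in amperes (inward
#'   negative).
#' @param params a [circuit_params()].
#' @param scenario `"capacitive"` or `"resistive"`.
#' @return a `cleft_ts` in amperes.
#' @export
predict_calcium_prespike <- function(i_ca, params,
                                     scenario = c("capacitive", "resistive")) {
  scenario <- match.arg(scenario)
  i <- switch(scenario,
    capacitive = -i_ca$value,
    resistive = -tau_cl(params) * ts_derivative(i_ca)$value
  )
  ts_like(i_ca, i, unit = "A")
}

#' Current-clamp prespike from the recorded cleft current
#'
#' In current clamp the prespike current charges the postsynaptic membrane:
#' `c_post dv_post/dt + g_post (v_post - v_rest) = -i_rec`, a first-order
#' low-pass of `-i_rec` with time constant `c_post / g_post` and gain
#' `1 / g_post` about the resting potential.
#'
#' @param i_rec recorded voltage-clamp prespike, a `cleft_ts` in amperes.
#' @param params a [circuit_params()].
#' @return a `cleft_ts` in volts (absolute, baseline `v_rest`).
#' @export
cc_prespike_from_current <- function(i_rec, params) {
  if (params$g_post <= 0) abort("g_post must be positive for the current-clamp response")
  dv <- solve_rc(-i_rec$value, ts_dt(i_rec), cap = params$c_post, g = params$g_post)
  ts_like(i_rec, params$v_rest + dv, unit = "V")
}
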