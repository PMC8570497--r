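# Markov-state models of the presynaptic voltage-gated conductances.
#
# Rates follow k = a * exp(b * v) with v the potential sensed by the channel
# (the presynaptic membrane potential minus the cleft potential, in mV) and
# a in 1/ms, b in 1/mV. The built-in rate constants are the published set for
# the calyceal sodium, high- and low-threshold potassium, and calcium
# conductances; stoichiometric multipliers of the activation schemes (2a, 3b,
# ...) are folded into the per-transition `a` values.

# per-channel rate parameters: a (1/ms), b (1/mV)
.rate_tables <- list(
  na5 = list(alpha = c(48.9, 1 / 128.4), beta = c(1.46, -1 / 8.9),
             gamma = c(392.8, 1 / 36.0), delta = c(0.73, -1 / 15.5),
             epsilon = c(7.8, 1 / 35.9), theta = c(0.01, -1 / 18)),
  k6_ht = list(alpha = c(1.097, 1 / 57.404), beta = c(0.794, -1 / 79.264),
               gamma = c(33.750, 0), delta = c(74.360, 0)),
  k6_lt = list(alpha = c(1.204, 1 / 37.574), beta = c(0.360, -1 / 230),
               gamma = c(245.488, 0), delta = c(132.566, 0)),
  ca2 = list(alpha = c(1.78, 1 / 23.3), beta = c(0.14, -1 / 15))
)

# default conductance densities (nS/um^2) and reversal potentials (V)
.channel_defaults <- list(
  na5   = list(density = 0.2,  v_rev =  50e-3),
  k6_ht = list(density = 0.08, v_rev = -90e-3),
  k6_lt = list(density = 0.24, v_rev = -90e-3),
  ca2   = list(density = 0.04, v_rev =  40e-3)
)

# build the transition table (from, to, a, b) for a kind from named rates;
# multipliers of the linear activation chains are folded into `a`.
channel_transitions <- function(kind, rates) {
  tr <- function(from, to, rate, mult = 1) {
    tibble::tibble(from = from, to = to, a = mult * rate[1], b = rate[2])
  }
  switch(kind,
    na5 = dplyr::bind_rows(
      tr("C1", "C2", rates$alpha, 2), tr("C2", "C1", rates$beta),
      tr("C2", "C3", rates$alpha),    tr("C3", "C2", rates$beta, 2),
      tr("C3", "O",  rates$gamma),    tr("O",  "C3", rates$delta),
      tr("O",  "I",  rates$theta),    tr("I",  "O",  rates$epsilon)),
    k6_ht = ,
    k6_lt = dplyr::bind_rows(
      tr("C1", "C2", rates$alpha, 4), tr("C2", "C1", rates$beta),
      tr("C2", "C3", rates$alpha, 3), tr("C3", "C2", rates$beta, 2),
      tr("C3", "C4", rates$alpha, 2), tr("C4", "C3", rates$beta, 3),
      tr("C4", "C5", rates$alpha),    tr("C5", "C4", rates$beta, 4),
      tr("C5", "O",  rates$gamma),    tr("O",  "C5", rates$delta)),
    ca2 = dplyr::bind_rows(
      tr("C", "O", rates$alpha), tr("O", "C", rates$beta)),
    abort(sprintf("unknown channel kind '%s'", kind))
  )
}

channel_states <- function(kind) {
  switch(kind,
    na5 = c("C1", "C2", "C3", "O", "I"),
    k6_ht = ,
    k6_lt = c("C1", "C2", "C3", "C4", "C5", "O"),
    ca2 = c("C", "O"),
    abort(sprintf("unknown channel kind '%s'", kind)))
}

#' Voltage-gated channel specification
#'
#' Builds a Markov-state channel model. Available kinds: `"na5"` (sodium,
#' five states C1-C2-C3-O-I), `"k6_ht"` and `"k6_lt"` (high- and low-threshold
#' potassium, six states C1..C5-O) and `"ca2"` (calcium, two states C-O with
#' the open probability squared). Rate constants and default densities are the
#' published calyx of Held set; both can be overridden.
#'
#' @param kind one of `"na5"`, `"k6_ht"`, `"k6_lt"`, `"ca2"`.
#' @param density conductance density in nS/um^2. Defaults: Na 0.2,
#'   K(HT) 0.08, K(LT) 0.24, Ca 0.04.
#' @param area_um2 cleft-facing membrane area in um^2 (default 1000).
#' @param v_rev reversal potential (V). Defaults: Na +50 mV, K -90 mV,
#'   Ca +40 mV.
#' @param transitions optional replacement transition table with columns
#'   `from`, `to`, `a` (1/ms), `b` (1/mV); states must match the kind.
#' @return an object of class `channel_spec` with elements `kind`, `states`,
#'   `transitions`, `g_max` (S) and `v_rev` (V).
#' @examples
#' ca <- channel_spec("ca2", density = 2.8)
#' ca$g_max # 2.8 uS over 1000 um^2
#' @export
channel_spec <- function(kind = c("na5", "k6_ht", "k6_lt", "ca2"),
                         density = NULL, area_um2 = 1000, v_rev = NULL,
                         transitions = NULL) {
  kind <- match.arg(kind)
  def <- .channel_defaults[[kind]]
  density <- density %||% def$density
  v_rev <- v_rev %||% def$v_rev
  states <- channel_states(kind)
  tr <- transitions %||% channel_transitions(kind, .rate_tables[[kind]])
  if (!all(c(tr$from, tr$to) %in% states)) {
    abort("transition table references states not in this channel kind")
  }
  if (any(tr$a < 0)) abort("all rate amplitudes `a` must be >= 0")
  structure(list(kind = kind, states = states, transitions = tr,
                 g_max = density * area_um2 * 1e-9, v_rev = v_rev),
            class = "channel_spec")
}

#' Exponential voltage dependence of a transition rate
#'
#' `k = a * exp(b * v)`, the rate law used by all channel transitions; `v` is
#' the potential sensed by the channel in mV (for cleft-facing channels, the
#' presynaptic potential minus the cleft potential). The exponent argument is
#' clamped to +/- 50 for numerical safety far outside the physiological range.
#'
#' @param a rate amplitude (1/ms).
#' @param b voltage sensitivity (1/mV); 0 gives a voltage-independent rate.
#' @param v potential (mV).
#' @return rate in 1/ms.
#' @examples
#' transition_rate(48.9, 1 / 128.4, 0) # 48.9
#' @export
transition_rate <- function(a, b, v) {
  a * exp(pmin(pmax(b * v, -50), 50))
}

# generator matrix Q (1/ms) at potential v (mV): Q[i, j] = rate state i -> j,
# diagonal = -rowSums, so d p / dt = t(Q) %*% p conserves sum(p) exactly.
rate_matrix <- function(spec, v) {
  n <- length(spec$states)
  Q <- matrix(0, n, n, dimnames = list(spec$states, spec$states))
  k <- transition_rate(spec$transitions$a, spec$transitions$b, v)
  for (i in seq_along(k)) {
    Q[spec$transitions$from[i], spec$transitions$to[i]] <-
      Q[spec$transitions$from[i], spec$transitions$to[i]] + k[i]
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

check_state <- function(spec, state) {
  if (length(state) != length(spec$states)) {
    abort(sprintf("state vector length %d does not match the %d states of '%s'",
                  length(state), length(spec$states), spec$kind))
  }
  invisible(TRUE)
}

#' Master-equation occupancy derivative
#'
#' Rate of change of the state occupancies of a Markov channel at a given
#' sensed potential. The components sum to zero exactly (probability
#' conservation).
#'
#' @param spec a [channel_spec()].
#' @param state numeric vector of occupancies (one per state).
#' @param v sensed potential (mV).
#' @return named numeric vector of d(occupancy)/dt in 1/ms.
#' @export
occupancy_derivative <- function(spec, state, v) {
  check_state(spec, state)
  drop(crossprod(rate_matrix(spec, v), state))
}

#' Open probability of a channel
#'
#' The O-state occupancy; for the two-state calcium channel the open
#' probability is the O occupancy squared.
#'
#' @inheritParams occupancy_derivative
#' @return open probability in \[0, 1\].
#' @export
open_probability <- function(spec, state) {
  check_state(spec, state)
  o <- state[[match("O", spec$states)]]
  if (spec$kind == "ca2") o^2 else o
}

#' Steady-state occupancy of a channel
#'
#' Solves the null space of the generator matrix at a fixed potential,
#' normalised to sum to one. Used to initialise simulations at rest.
#'
#' @inheritParams occupancy_derivative
#' @return named numeric vector of stationary occupancies.
#' @examples
#' steady_state_occupancy(channel_spec("na5"), -80) # C1-dominant at rest
#' @export
steady_state_occupancy <- function(spec, v) {
  Q <- rate_matrix(spec, v)
  n <- nrow(Q)
  M <- t(Q)
  M[n, ] <- 1            # replace one balance equation by the normalisation
  b <- c(rep(0, n - 1), 1)
  p <- tryCatch(solve(M, b), error = function(e) {
    abort(sprintf("degenerate generator for '%s' at v = %g mV: %s",
                  spec$kind, v, conditionMessage(e)))
  })
  resid <- max(abs(crossprod(Q, p)))
  if (resid > 1e-8 || any(p < -1e-10)) {
    abort(sprintf("generator for '%s' at v = %g mV is reducible or ill-conditioned (residual %.2g)",
                  spec$kind, v, resid))
  }
  setNames(pmax(p, 0) / sum(pmax(p, 0)), spec$states)
}

#' Read channel specifications from a YAML config file
#'
#' Each entry names a `kind` and may override `density` (nS/um^2), `area_um2`,
#' `v_rev` (V) and `transitions` (list of `from`, `to`, `a`, `b`). Setting a
#' density to 0 removes a conductance, enabling scenario toggles such as
#' "no sodium at the release face" or "calcium only".
#'
#' @param path path to a YAML file with a top-level `channels` list.
#' @return a list of [channel_spec()] objects.
#' @export
read_channel_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading channel configs requires the 'yaml' package")
  }
  cfg <- yaml::read_yaml(path)
  purrr::map(cfg$channels, function(ch) {
    tr <- if (!is.null(ch$transitions)) {
      dplyr::bind_rows(purrr::map(ch$transitions, tibble::as_tibble))
    }
    channel_spec(kind = ch$kind, density = ch$density,
                 area_um2 = ch$area_um2 %||% 1000,
                 v_rev = ch$v_rev, transitions = tr)
  })
}
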