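# broom-style tidiers for the package's fitted objects.

#' Tidy a derivative-resemblance fit
#'
#' @param x a `derivative_fit` from [regress_prespike_vs_derivative()].
#' @param ... unused.
#' @return a tibble with one row per regression term.
#' @export
tidy.derivative_fit <- function(x, ...) {
  generics::tidy(x$model)
}

#' @rdname tidy.derivative_fit
#' @return `glance()`: a one-row tibble with `slope`, `intercept`,
#'   `pearson_r`, `deviation_at_origin`, `n_points`, `underdetermined`.
#' @export
glance.derivative_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 pearson_r = x$pearson_r,
                 deviation_at_origin = x$deviation_at_origin,
                 n_points = x$n_points, underdetermined = x$underdetermined)
}

#' Tidy a cleft-parameter estimate
#'
#' @param x a `cleft_estimate` from [analyze_recording_set()].
#' @param ... unused.
#' @return `tidy()`: a long tibble (term, estimate, unit) in the
#'   conventional units of the field (us, fA s^2/V, uS, pF, Ohm cm);
#'   `glance()`: a one-row tibble in SI units, with the ground-truth
#'   `tau_cl` and `g_cl` when the recording is synthetic.
#' @export
tidy.cleft_estimate <- function(x, ...) {
  tibble::tribble(
    ~term, ~estimate, ~unit,
    "tau_cl_peak_ratio", x$tau_cl_peak_ratio * 1e6, "us",
    "tau_cl_slope", x$tau_cl_slope * 1e6, "us",
    "tau_ca", x$tau_ca * 1e3, "ms",
    "lag_at_max_r", x$lag_at_max_r * 1e6, "us",
    "slope_gcl_tau2", x$slope_gcl_tau2 * 1e15, "fA s^2/V",
    "g_cl", x$g_cl * 1e6, "uS",
    "c_cl", x$c_cl * 1e12, "pF",
    "R_ex_given_h", to_ohm_cm(x$R_ex_given_h), "Ohm cm")
}

#' @rdname tidy.cleft_estimate
#' @export
glance.cleft_estimate <- function(x, ...) {
  tibble::tibble(tau_cl_peak_ratio = x$tau_cl_peak_ratio,
                 tau_cl_slope = x$tau_cl_slope, tau_ca = x$tau_ca,
                 lag_at_max_r = x$lag_at_max_r, r_slope_fit = x$r_slope_fit,
                 slope_gcl_tau2 = x$slope_gcl_tau2,
                 g_cl = x$g_cl, c_cl = x$c_cl, R_ex_given_h = x$R_ex_given_h,
                 cleft_fraction = x$cleft_fraction,
                 tau_cl_truth = x$truth$tau_cl %||% NA_real_,
                 g_cl_truth = x$truth$g_cl %||% NA_real_)
}

#' Tidy a synapse simulation
#'
#' @param x a `synapse_sim` from [simulate_synapse()].
#' @param ... unused.
#' @return `tidy()`: the simulation data in long format (time, signal,
#'   value); `glance()`: one-row summary (cleft-potential extrema, peak
#'   recorded current, solver step count).
#' @export
tidy.synapse_sim <- function(x, ...) {
  tidyr::pivot_longer(x$data, -"time", names_to = "signal")
}

#' @rdname tidy.synapse_sim
#' @export
glance.synapse_sim <- function(x, ...) {
  tibble::tibble(vcl_max = max(x$data$v_cl), vcl_min = min(x$data$v_cl),
                 i_rec_min = min(x$data$i_rec), i_rec_max = max(x$data$i_rec),
                 steps = x$diagnostics$steps %||% NA_integer_)
}
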