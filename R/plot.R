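# Quick-look ggplot2 figures for the package's result objects.

#' Plot a synapse simulation
#'
#' Facetted traces of the cleft potential, the sensed potential
#' `v_pre - v_cl`, the recorded prespike current and the per-channel
#' currents, on a millisecond time axis.
#'
#' @param object a `synapse_sim`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.synapse_sim <- function(object, ...) {
  long <- tidy.synapse_sim(object) |>
    dplyr::mutate(value = ifelse(startsWith(.data$signal, "i_"),
                                 .data$value * 1e9, .data$value * 1e3),
                  unit = ifelse(startsWith(.data$signal, "i_"), "nA", "mV"),
                  signal = paste0(.data$signal, " (", .data$unit, ")"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time * 1e3, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~signal, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic recording set
#'
#' Shows the command waveform, the calcium current, the averaged active
#' sweep and the averaged passive sweep upscaled by 5 (the P/5 pair whose
#' difference is the calcium prespike).
#'
#' @param object a `recording_set`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.recording_set <- function(object, ...) {
  avg <- function(sweeps) purrr::reduce(purrr::map(sweeps, "value"), `+`) / length(sweeps)
  long <- dplyr::bind_rows(
    tibble::tibble(time = object$v_pre$time, value = object$v_pre$value * 1e3,
                   signal = "v_pre (mV)"),
    tibble::tibble(time = object$i_ca_true$time,
                   value = object$i_ca_true$value * 1e9, signal = "i_ca (nA)"),
    tibble::tibble(time = object$v_pre$time,
                   value = avg(object$active_sweeps) * 1e9,
                   signal = "active i_post (nA)"),
    tibble::tibble(time = object$v_pre$time,
                   value = 5 * avg(object$passive_sweeps) * 1e9,
                   signal = "5 x passive i_post (nA)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time * 1e3, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~signal, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cleft-potential profiles for a set of synapse radii
#'
#' Spatial profile of the cleft potential against the relative distance from
#' the centre, one curve per radius, at a fixed rate of change of the
#' presynaptic potential.
#'
#' @param radii synapse radii (m).
#' @param dvdt rate of change of the presynaptic potential (V/s).
#' @param h cleft height (m).
#' @param R_ex extracellular resistivity (Ohm m).
#' @param C_m specific capacitance (F/m^2).
#' @param shape `"disc"` or `"sheet"`.
#' @return a ggplot object.
#' @export
plot_cleft_profiles <- function(radii = um(c(2, 5, 10, 20)), dvdt = 500,
                                h = nm(30), R_ex = ohm_cm(100),
                                C_m = uF_per_cm2(1), shape = "disc") {
  long <- purrr::map(radii, function(r) {
    g <- synapse_geometry(shape, r = r, h = h, R_ex = R_ex, C_m = C_m,
                          area = if (shape == "sheet") 1 else NULL)
    prof <- cleft_potential_profile(g, dvdt, seq(0, r, length.out = 101))
    tibble::tibble(rel_x = prof$x / r, v_cl_mv = prof$v_cl * 1e3,
                   radius_um = r * 1e6)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(long, ggplot2::aes(.data$rel_x, .data$v_cl_mv,
                                     colour = factor(.data$radius_um))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from centre (fraction of r)",
                  y = "cleft potential (mV)", colour = "radius (um)") +
    ggplot2::theme_minimal()
}
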