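#' Simulate the synapse with voltage-gated channels and cleft feedback
#'
#' Integrates the coupled lumped-circuit equations
#' \deqn{c_{post} dv_{post}/dt = c_{cl} dv_{cl}/dt - g_{post}(v_{post}-v_{rest})}
#' \deqn{2 c_{cl} dv_{cl}/dt = c_{cl}(dv_{pre}/dt + dv_{post}/dt) - g_{cl} v_{cl}
#'   + \sum g_{max} p_{open} (v_{pre} - v_{cl} - v_{rev})}
#' together with the master equations of each Markov channel, whose rates are
#' evaluated at the transmembrane potential sensed in the cleft,
#' `v_pre - v_cl`. The two derivative equations reference each other and are
#' solved by exact algebraic elimination at every step (they are linear in
#' the derivatives). Occupancies are integrated as raw states and only
#' renormalised for reporting, so probability conservation is a genuine
#' accuracy check on the integration.
#'
#' `v_pre` and its derivative are supplied to the adaptive integrator by
#' cubic-spline interpolation of the input series. With `g_cl = Inf` (a
#' zero-resistance cleft) the cleft potential is identically zero and the
#' channels sense `v_pre` directly.
#'
#' @param v_pre presynaptic potential, a `cleft_ts` in volts, densely sampled
#'   (5 us or finer recommended).
#' @param specs list of [channel_spec()] objects (may be empty).
#' @param params a [circuit_params()]; `c_pre` and `c_syn` must be equal (the
#'   symmetric calyx-type cleft this model describes).
#' @param atol,rtol absolute and relative error tolerances of the adaptive
#'   integrator, applied to potentials (V) and occupancies.
#' @param method integration method passed to [deSolve::ode()]. The default
#'   `"lsoda"` switches automatically to a stiff solver: the closed-state
#'   transition rates of the sodium scheme reach ~1e7/s near rest, which
#'   stalls explicit embedded Runge-Kutta pairs (`"ode45"` remains available
#'   and gives the same trajectories, much more slowly).
#' @return an object of class `synapse_sim`: a list with `data` (a tibble
#'   with columns `time`, `v_cl`, `v_post`, `i_rec`, `v_eff` and one current
#'   column `i_<kind>` per channel), `params`, `specs` and `diagnostics`
#'   (integrator step counts). `i_rec` is the current a postsynaptic
#'   voltage-clamp amplifier would record, `-c_cl dv_cl/dt` (negative first
#'   peak for a rising AP); `v_eff = v_pre - v_cl` is the potential sensed by
#'   cleft-facing channels.
#' @export
simulate_synapse <- function(v_pre, specs, params, atol = 1e-9, rtol = 1e-8,
                             method = "lsoda") {
  if (abs(params$c_pre - params$c_syn) > 1e-9 * params$c_pre) {
    abort("simulate_synapse assumes a symmetric cleft: c_pre must equal c_syn")
  }
  c_cl <- cleft_capacitance(params)
  denom <- 2 * c_cl - c_cl^2 / params$c_post
  if (abs(denom) < 1e-30) abort("singular derivative system: c_post too close to c_cl / 2")
  zero_res <- !is.finite(params$g_cl)

  vf <- splinefun(v_pre$time, v_pre$value, method = "natural")
  kinds <- purrr::map_chr(specs, "kind")
  if (anyDuplicated(kinds)) kinds <- make.unique(kinds, sep = "_")
  cur_names <- if (length(kinds)) paste0("i_", kinds) else character(0)
  nst <- purrr::map_int(specs, ~ length(.x$states))
  off <- 2L + c(0L, cumsum(head(nst, -1)))[seq_along(specs)] # offsets after (v_cl, v_post)

  y0 <- c(0, params$v_rest,
          unlist(purrr::map(specs, ~ steady_state_occupancy(.x, (vf(ts_t0(v_pre)) - 0) * 1e3))))
  names(y0) <- c("v_cl", "v_post",
                 unlist(purrr::map2(kinds, specs,
                                    ~ paste(.x, .y$states, sep = "."))))

  rhs <- function(t, y, parms) {
    y <- unname(y)
    v_cl <- if (zero_res) 0 else y[1]
    v_post <- y[2]
    vp <- vf(t)
    dvp <- vf(t, deriv = 1)
    v_mv <- (vp - v_cl) * 1e3
    i_ion_tot <- 0
    i_ch <- numeric(length(specs))
    docc <- vector("list", length(specs))
    for (j in seq_along(specs)) {
      s <- specs[[j]]
      occ <- y[off[j] + seq_len(nst[j])]
      i_ch[j] <- s$g_max * open_probability(s, occ) * (vp - v_cl - s$v_rev)
      i_ion_tot <- i_ion_tot + i_ch[j]
      docc[[j]] <- 1e3 * occupancy_derivative(s, occ, v_mv) # 1/ms -> 1/s
    }
    if (zero_res) {
      dv_cl <- 0
    } else {
      dv_cl <- (c_cl * dvp - (c_cl * params$g_post / params$c_post) * (v_post - params$v_rest) -
                  params$g_cl * v_cl + i_ion_tot) / denom
    }
    dv_post <- (c_cl * dv_cl - params$g_post * (v_post - params$v_rest)) / params$c_post
    list(c(dv_cl, dv_post, unlist(docc)),
         c(i_rec = -c_cl * dv_cl, setNames(i_ch, cur_names)))
  }

  out <- deSolve::ode(y = y0, times = v_pre$time, func = rhs, parms = NULL,
                      method = method, atol = atol, rtol = rtol)
  istate <- attr(out, "istate")
  df <- tibble::as_tibble(as.data.frame(out))
  data <- tibble::tibble(
    time = df$time,
    v_cl = if (zero_res) 0 * df$time else df$v_cl,
    v_post = df$v_post,
    i_rec = df$i_rec,
    v_eff = vf(df$time) - (if (zero_res) 0 else df$v_cl)
  )
  for (nm in cur_names) data[[nm]] <- df[[nm]]
  # renormalised occupancy bookkeeping for the conservation diagnostic
  occ_sums <- purrr::map(seq_along(specs), function(j) {
    rowSums(as.matrix(df[, 3L + off[j] - 2L + seq_len(nst[j]), drop = FALSE]))
  })
  structure(list(data = data, params = params, specs = specs,
                 occupancies = df[, 3L + seq_len(sum(nst)), drop = FALSE],
                 occupancy_sums = setNames(occ_sums, kinds),
                 diagnostics = list(steps = if (!is.null(istate)) unname(istate[3]),
                                    rhs_evals = if (!is.null(istate)) unname(istate[4]))),
            class = "synapse_sim")
}

#' @export
print.synapse_sim <- function(x, ...) {
  cat(sprintf("<synapse_sim: %d samples, %d channel(s) [%s], v_cl range [%.2f, %.2f] mV>\n",
              nrow(x$data), length(x$specs),
              paste(purrr::map_chr(x$specs, "kind"), collapse = ", "),
              min(x$data$v_cl) * 1e3, max(x$data$v_cl) * 1e3))
  invisible(x)
}

# peak (most negative) of an inward current with parabolic refinement
inward_peak <- function(time, i) {
  idx <- which.min(i)
  pk <- parabolic_peak(time, i, idx)
  list(t = pk[1], value = pk[2])
}

# onset time: first crossing of `frac` of the (negative) peak amplitude
inward_onset <- function(time, i, frac = 0.1) {
  thr <- frac * min(i)
  idx <- which(i <= thr)[1]
  if (is.na(idx) || idx == 1L) return(NA_real_)
  approx(i[(idx - 1):idx], time[(idx - 1):idx], xout = thr)$y
}

#' Calibrate a calcium conductance density to a target peak current
#'
#' With a zero-resistance cleft there is no feedback of the cleft potential on
#' gating, so the peak calcium current is exactly proportional to the
#' conductance density; one simulation therefore suffices to rescale a
#' starting density to the target peak (the published simulations used a
#' 2 nA peak at 0 MOhm cleft leak resistance).
#'
#' @param v_pre presynaptic potential (`cleft_ts`, volts).
#' @param target_peak target peak current in A (positive magnitude).
#' @param density0 starting density (nS/um^2).
#' @param area_um2 cleft-facing area (um^2).
#' @param params a [circuit_params()] (only the postsynaptic side is used).
#' @return the calibrated density in nS/um^2.
#' @export
calibrate_ca_density <- function(v_pre, target_peak = 2e-9, density0 = 1,
                                 area_um2 = 1000, params = circuit_params()) {
  p0 <- circuit_params(c_cl = cleft_capacitance(params), g_cl = Inf,
                       c_post = params$c_post, g_post = params$g_post,
                       v_rest = params$v_rest)
  sim <- simulate_synapse(v_pre, list(channel_spec("ca2", density = density0,
                                                   area_um2 = area_um2)), p0)
  density0 * target_peak / abs(min(sim$data$i_ca2))
}

#' Simulate an AP-by-cleft-resistance scenario grid
#'
#' Runs the calcium-only ODE model for each combination of AP waveform and
#' cleft leak resistance, and summarises the cleft potential and the calcium
#' current per cell, including the shift of the calcium current relative to
#' the zero-resistance run of the same AP. This reproduces the published
#' slow-AP/fast-AP comparison across leak resistances.
#'
#' @param aps named list of `cleft_ts` presynaptic waveforms.
#' @param resistance_mohm cleft leak resistances in MOhm; 0 means a
#'   zero-resistance cleft (`g_cl = Inf`). A zero-resistance run is always
#'   added as the reference if absent.
#' @param ca_density named numeric vector (same names as `aps`) of calcium
#'   conductance densities in nS/um^2, or a single number.
#' @param area_um2 cleft-facing area (um^2).
#' @param params a [circuit_params()]; its `g_cl` is overridden per cell.
#' @param onset_frac fraction of the peak defining calcium-current onset.
#' @return a tibble with one row per (ap, resistance): `vcl_max_mv`,
#'   `vcl_min_mv`, `ica_peak_na`, `ica_peak_t_ms`, `peak_shift_us`,
#'   `onset_shift_us`, `peak_reduction_pct` (all shifts and reductions
#'   relative to the same AP at zero resistance).
#' @export
simulate_ap_grid <- function(aps, resistance_mohm = c(0, 1, 5),
                             ca_density = 0.2, area_um2 = 1000,
                             params = circuit_params(c_cl = 10e-12),
                             onset_frac = 0.1) {
  if (length(ca_density) == 1L) {
    ca_density <- setNames(rep(ca_density, length(aps)), names(aps))
  }
  res <- sort(unique(c(0, resistance_mohm)))
  rows <- purrr::map(names(aps), function(nm) {
    ref <- NULL
    purrr::map(res, function(r) {
      g <- if (r == 0) Inf else 1 / (r * 1e6)
      p <- circuit_params(c_cl = cleft_capacitance(params), g_cl = g,
                          c_post = params$c_post, g_post = params$g_post,
                          v_rest = params$v_rest)
      sim <- simulate_synapse(aps[[nm]],
                              list(channel_spec("ca2", density = ca_density[[nm]],
                                                area_um2 = area_um2)), p)
      pk <- inward_peak(sim$data$time, sim$data$i_ca2)
      on <- inward_onset(sim$data$time, sim$data$i_ca2, onset_frac)
      if (r == 0) ref <<- list(pk = pk, on = on)
      tibble::tibble(
        ap = nm, resistance_mohm = r,
        vcl_max_mv = max(sim$data$v_cl) * 1e3,
        vcl_min_mv = min(sim$data$v_cl) * 1e3,
        ica_peak_na = pk$value * 1e9,
        ica_peak_t_ms = pk$t * 1e3,
        peak_shift_us = (pk$t - ref$pk$t) * 1e6,
        onset_shift_us = (on - ref$on) * 1e6,
        peak_reduction_pct = 100 * (1 - abs(pk$value) / abs(ref$pk$value))
      )
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows) |>
    dplyr::filter(.data$resistance_mohm %in% resistance_mohm)
}
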