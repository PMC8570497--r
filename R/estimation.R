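# The prespike analysis pipeline: smoothed differentiation, peak extraction,
# derivative-resemblance regression and model comparison, P/5 isolation of
# the calcium prespike, the two cleft-time-constant estimators, and the
# derivation of g_cl, c_cl and R_ex.

#' Smoothed derivative of a time series
#'
#' Local-polynomial (Savitzky-Golay, quadratic) derivative estimate. Raw
#' finite differences amplify recording noise unacceptably at 50-200 kHz
#' sampling; fitting a quadratic over a short moving window gives a derivative
#' estimate whose noise decreases with window length. Endpoints are handled by
#' one-sided fits over the first/last window.
#'
#' @param x a `cleft_ts`.
#' @param order derivative order, 1 or 2.
#' @param window odd window length in samples (> order + 1); default 7.
#' @return a `cleft_ts` on the same time base (unit tagged `/s^order`).
#' @export
differentiate <- function(x, order = 1L, window = 7L) {
  if (!order %in% c(1L, 2L)) abort("order must be 1 or 2")
  if (window %% 2 == 0) window <- window + 1L
  if (window <= order + 1L || window < 5L) {
    abort(sprintf("window %d too small for a quadratic fit of derivative order %d", window, order))
  }
  if (nrow(x) <= window) abort("series shorter than the smoothing window")
  d <- signal::sgolayfilt(x$value, p = 2, n = window, m = order, ts = ts_dt(x))
  ts_like(x, d, unit = paste0(ts_unit(x), "/s^", order))
}

# local extrema indices of v: minima and maxima (interior)
local_extrema <- function(v) {
  d <- diff(sign(diff(v)))
  list(minima = which(d > 0) + 1L, maxima = which(d < 0) + 1L)
}

# robust per-sample noise scale (sd of the first difference / sqrt(2))
noise_scale <- function(v) stats::mad(diff(v)) / sqrt(2)

# find the first qualifying peak of the given sign, then the subsequent peak
# of the opposite sign; returns rows (value, t) refined parabolically
biphasic_peaks <- function(time, v, first = c("min", "max"), noise_k = 4) {
  first <- match.arg(first)
  ex <- local_extrema(v)
  base <- stats::median(v)
  # prominence threshold: noise-scaled, with a floor at a quarter of the
  # dominant deflection so shallow wiggles never pre-empt the true peaks
  thr <- max(noise_k * noise_scale(v), 0.25 * max(abs(v - base)))
  sel <- function(idx, sign) idx[sign * (v[idx] - base) > thr]
  sgn1 <- if (first == "min") -1 else +1
  i1s <- if (first == "min") sel(ex$minima, -1) else sel(ex$maxima, +1)
  if (length(i1s) == 0L) abort("no prespike detected: no qualifying first peak")
  i2s <- if (first == "min") sel(ex$maxima, +1) else sel(ex$minima, -1)
  # first peak: the largest qualifying extremum preceding the first
  # opposite-sign peak (noise shoulders on the leading lobe are absorbed)
  lead <- if (length(i2s) > 0L) i1s[i1s < i2s[1]] else integer(0)
  if (length(lead) == 0L) lead <- i1s
  i1 <- lead[which.max(sgn1 * v[lead])]
  i2s <- i2s[i2s > i1]
  if (length(i2s) == 0L) abort("no prespike detected: no qualifying second peak")
  # second peak: the largest opposite extremum following the first peak
  i2 <- i2s[which.max(-sgn1 * v[i2s])]
  p1 <- parabolic_peak(time, v, i1)
  p2 <- parabolic_peak(time, v, i2)
  list(first = list(t = p1[1], value = p1[2]),
       second = list(t = p2[1], value = p2[2]))
}

#' Extract the biphasic peaks of a voltage-clamp prespike
#'
#' Finds the first negative peak and the subsequent positive peak of the
#' prespike (the capacitive prespike of a rising-then-falling AP is negative
#' first), above a noise-scaled prominence threshold, with parabolically
#' interpolated peak times and amplitudes.
#'
#' @param i_post postsynaptic current, a `cleft_ts` in amperes.
#' @param window optional `c(t_min, t_max)` (s) restricting the search.
#' @param noise_k prominence threshold in units of the per-sample noise scale.
#' @param smooth_window odd Savitzky-Golay pre-smoothing window in samples
#'   (1 = none); a short window (5-7) stabilises peak picking on noisy
#'   single sweeps at the cost of a small attenuation of narrow lobes.
#' @return a one-row tibble: `neg_peak`, `t_neg`, `pos_peak`, `t_pos`,
#'   `peak_delay` (s).
#' @export
extract_prespike_features <- function(i_post, window = NULL, noise_k = 4,
                                      smooth_window = 1) {
  t <- i_post$time; v <- i_post$value
  if (smooth_window > 1) v <- signal::sgolayfilt(v, p = 2, n = smooth_window, m = 0)
  if (!is.null(window)) {
    if (window[1] < t[1] - 1e-12 || window[2] > t[length(t)] + 1e-12) {
      abort("window must lie within the series")
    }
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; v <- v[keep]
  }
  pk <- biphasic_peaks(t, v, first = "min", noise_k = noise_k)
  tibble::tibble(neg_peak = pk$first$value, t_neg = pk$first$t,
                 pos_peak = pk$second$value, t_pos = pk$second$t,
                 peak_delay = pk$second$t - pk$first$t)
}

# features of a derivative trace: first positive then negative peak
extract_derivative_features <- function(dx, window = NULL, noise_k = 4) {
  t <- dx$time; v <- dx$value
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; v <- v[keep]
  }
  pk <- biphasic_peaks(t, v, first = "max", noise_k = noise_k)
  tibble::tibble(pos_peak = pk$first$value, t_pos = pk$first$t,
                 neg_peak = pk$second$value, t_neg = pk$second$t)
}

#' Regress prespike peak amplitudes on AP-derivative peak amplitudes
#'
#' Ordinary least squares of the prespike peak amplitudes on the
#' corresponding peaks of the first or second derivative of the presynaptic
#' AP, using both peaks of every AP in a train as separate points: the first
#' negative prespike peak is paired with the first positive derivative peak
#' and the positive prespike peak with the negative derivative peak. Under
#' the resistive dissipation scenario the prespike is
#' `-g_cl tau_cl^2 v_pre''`, so against the second derivative the regression
#' is linear through the origin with slope `-g_cl tau_cl^2`; the intercept
#' magnitude ("deviation at origin") and Pearson's r measure how well a
#' candidate derivative explains the prespike.
#'
#' @param prespike_features tibble with one row per AP (`neg_peak`,
#'   `pos_peak`), from [extract_prespike_features()].
#' @param derivative_features tibble with one row per AP (`pos_peak`,
#'   `neg_peak`) of the AP derivative.
#' @return an object of class `derivative_fit`: slope, intercept,
#'   `pearson_r`, `deviation_at_origin` (A), `n_points`, and an
#'   `underdetermined` flag when only one AP (2 points) is available.
#' @export
regress_prespike_vs_derivative <- function(prespike_features, derivative_features) {
  if (nrow(prespike_features) != nrow(derivative_features)) {
    abort("feature tables must have one row per AP each")
  }
  y <- c(rbind(prespike_features$neg_peak, prespike_features$pos_peak))
  x <- c(rbind(derivative_features$pos_peak, derivative_features$neg_peak))
  if (stats::sd(x) == 0) abort("degenerate regressor: derivative peaks have zero variance")
  fit <- lm(y ~ x)
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 pearson_r = cor(x, y),
                 deviation_at_origin = abs(unname(coef(fit)[1])),
                 n_points = length(y), underdetermined = length(y) <= 2,
                 model = fit),
            class = "derivative_fit")
}

#' @export
print.derivative_fit <- function(x, ...) {
  cat(sprintf("<derivative_fit: slope %.3g, r %.4f, |deviation at origin| %.3g A, n %d%s>\n",
              x$slope, x$pearson_r, x$deviation_at_origin, x$n_points,
              if (x$underdetermined) " (under-determined)" else ""))
  invisible(x)
}

#' Per-AP derivative-resemblance fits for a recorded train
#'
#' Splits a presynaptic AP train and the postsynaptic current into stimulus
#' epochs, extracts the biphasic peaks of the prespike and of the first and
#' second AP derivatives per epoch, and regresses the prespike peaks on each
#' derivative's peaks.
#'
#' @param v_pre presynaptic train (`cleft_ts`, volts).
#' @param i_post postsynaptic current (`cleft_ts`, amperes), aligned.
#' @param interval stimulus interval (s).
#' @param smooth_window derivative smoothing window (samples).
#' @param noise_k peak prominence threshold (noise units).
#' @return list with elements `ap1` and `ap2` (the two [regress_prespike_vs_derivative()]
#'   fits) and `features` (per-epoch peak table). Epochs in which a peak
#'   cannot be detected are dropped with a warning.
#' @export
fit_derivative_models <- function(v_pre, i_post, interval,
                                  smooth_window = 7, noise_k = 4) {
  check_aligned(v_pre, i_post)
  d1 <- differentiate(v_pre, 1, smooth_window)
  d2 <- differentiate(v_pre, 2, smooth_window)
  dt <- ts_dt(v_pre)
  n_ep <- floor((nrow(v_pre) - 1) / round(interval / dt))
  rows <- purrr::map(seq_len(n_ep) - 1L, function(k) {
    w <- c(k * interval, (k + 1) * interval)
    tryCatch({
      ps <- extract_prespike_features(i_post, w, noise_k)
      f1 <- extract_derivative_features(d1, w, noise_k)
      f2 <- extract_derivative_features(d2, w, noise_k)
      tibble::tibble(epoch = k + 1L,
                     ps_neg = ps$neg_peak, ps_pos = ps$pos_peak,
                     d1_pos = f1$pos_peak, d1_neg = f1$neg_peak,
                     d2_pos = f2$pos_peak, d2_neg = f2$neg_peak)
    }, error = function(e) NULL)
  })
  dropped <- sum(purrr::map_lgl(rows, is.null))
  if (dropped > 0) warn(sprintf("%d epoch(s) dropped: peaks not detectable", dropped))
  feat <- dplyr::bind_rows(rows)
  if (nrow(feat) < 2) abort("need at least 2 usable APs for the regressions")
  ps <- tibble::tibble(neg_peak = feat$ps_neg, pos_peak = feat$ps_pos)
  list(ap1 = regress_prespike_vs_derivative(
         ps, tibble::tibble(pos_peak = feat$d1_pos, neg_peak = feat$d1_neg)),
       ap2 = regress_prespike_vs_derivative(
         ps, tibble::tibble(pos_peak = feat$d2_pos, neg_peak = feat$d2_neg)),
       features = feat)
}

# textbook paired t-test (closed form), tolerating a zero-variance difference
paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  s <- sd(d)
  if (s == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    t <- mean(d) / (s / sqrt(n))
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df = n - 1)
  list(t = t, df = n - 1, p = p)
}

#' Compare first- and second-derivative prespike models across trains
#'
#' Given one [regress_prespike_vs_derivative()] fit per train for each
#' candidate derivative, summarises Pearson's r and the deviation at origin
#' (mean +/- SD per model) and tests both contrasts with two-sided paired
#' t-tests (df = n - 1).
#'
#' @param fits_ap1,fits_ap2 lists of `derivative_fit` objects, one per train,
#'   in matching order.
#' @return a tibble with one row per metric (`pearson_r`,
#'   `deviation_at_origin`): per-model means and SDs, the paired t statistic,
#'   degrees of freedom and two-sided p value.
#' @export
compare_derivative_models <- function(fits_ap1, fits_ap2) {
  if (length(fits_ap1) != length(fits_ap2)) abort("need equal train counts")
  if (length(fits_ap1) < 2) abort("need at least 2 trains for a paired comparison")
  metric <- function(fits, what) purrr::map_dbl(fits, what)
  rows <- purrr::map(c("pearson_r", "deviation_at_origin"), function(what) {
    x1 <- metric(fits_ap1, what); x2 <- metric(fits_ap2, what)
    tt <- paired_t(x1, x2)
    tibble::tibble(metric = what,
                   ap1_mean = mean(x1), ap1_sd = sd(x1),
                   ap2_mean = mean(x2), ap2_sd = sd(x2),
                   t = tt$t, df = tt$df, p = tt$p)
  })
  dplyr::bind_rows(rows)
}

#' Fold a train recording into averaged stimulus epochs
#'
#' Cuts a uniformly sampled train into epochs of one stimulus interval,
#' skips the first `skip` epochs (which may be contaminated by large EPSCs in
#' real recordings) and averages the next `use`.
#'
#' @param x a `cleft_ts` covering the whole train.
#' @param interval stimulus interval (s); must be an integer number of
#'   samples.
#' @param skip,use epochs to skip / to average. The historical protocol
#'   skipped the first 20 of a 45-stimulus train and averaged the next 25.
#' @return a `cleft_ts` of one epoch (time starting at 0).
#' @export
fold_epochs <- function(x, interval, skip = 20L, use = 25L) {
  dt <- ts_dt(x)
  m <- interval / dt
  if (abs(m - round(m)) > 1e-6) {
    abort("misaligned epochs: interval is not an integer number of samples")
  }
  m <- as.integer(round(m))
  n_ep <- floor((nrow(x) - 1L) / m)
  if (n_ep < skip + use) {
    abort(sprintf("need %d epochs (skip %d + use %d) but the sweep holds %d",
                  skip + use, skip, use, n_ep))
  }
  idx <- function(k) (k * m) + seq_len(m) # epoch k (0-based), m samples
  acc <- rep(0, m)
  for (k in seq(skip, skip + use - 1L)) acc <- acc + x$value[idx(k)]
  cleft_ts(acc / use, dt = dt, t0 = 0, unit = ts_unit(x))
}

#' Isolate the calcium prespike by P/5 subtraction
#'
#' Averages the active sweeps and the passive (1/5-scale) sweeps, folds both
#' into averaged stimulus epochs, and subtracts five times the passive epoch
#' from the active epoch:
#' `delta_i_post = mean(active) - 5 * mean(passive)`. The passive command is
#' too small to open calcium channels, so the difference removes the
#' capacitive prespike and leaves the calcium prespike (plus noise reduced by
#' the epoch averaging).
#'
#' @param active_sweeps,passive_sweeps lists of aligned `cleft_ts` currents.
#' @param interval stimulus interval (s); `NULL` treats each sweep as one
#'   epoch.
#' @param skip,use epoch protocol, see [fold_epochs()].
#' @return a `cleft_ts` of one averaged epoch, in amperes.
#' @export
isolate_calcium_prespike <- function(active_sweeps, passive_sweeps,
                                     interval = NULL, skip = 20L, use = 25L) {
  do.call(check_aligned, c(active_sweeps, passive_sweeps))
  avg <- function(sweeps) {
    v <- purrr::reduce(purrr::map(sweeps, "value"), `+`) / length(sweeps)
    ts_like(sweeps[[1]], v, unit = "A")
  }
  a <- avg(active_sweeps)
  p <- avg(passive_sweeps)
  delta <- ts_like(a, a$value - 5 * p$value, unit = "A")
  if (is.null(interval)) delta else fold_epochs(delta, interval, skip, use)
}

#' Cleft time constant from the calcium-prespike peak ratio
#'
#' For a Gaussian calcium current of width `tau_ca`, the resistive-regime
#' calcium prespike `-tau_cl di_ca/dt` is biphasic with peaks at
#' `+/- tau_ca` around the current peak (so the peak-to-peak delay is about
#' `2 tau_ca`) and a positive peak of `tau_cl / tau_ca * exp(-0.5)` times the
#' calcium-current amplitude. Inverting that percentage gives
#' `tau_cl = ratio * tau_ca * exp(0.5)`. If only a fraction of the measured
#' calcium current flows in the cleft, the cleft current is smaller and the
#' estimate scales inversely with that fraction (2/3 is the anatomically
#' motivated default; 1 gives the lower bound).
#'
#' @param delta_i_post isolated calcium prespike (`cleft_ts`, amperes).
#' @param i_ca presynaptic calcium current of one epoch (`cleft_ts`,
#'   amperes, inward negative).
#' @param cleft_fraction fraction of the calcium current arising from the
#'   cleft-facing membrane, in (0, 1].
#' @param noise_k peak prominence threshold (noise units).
#' @return a one-row tibble: `tau_cl` (s), `tau_ca` (s), `peak_ratio`.
#' @export
estimate_tau_cl_peak_ratio <- function(delta_i_post, i_ca, cleft_fraction = 2 / 3,
                                       noise_k = 4) {
  if (cleft_fraction <= 0 || cleft_fraction > 1) {
    abort("cleft_fraction must be in (0, 1]")
  }
  pk <- tryCatch(
    biphasic_peaks(delta_i_post$time, delta_i_post$value, first = "max",
                   noise_k = noise_k),
    error = function(e) abort(paste0("calcium prespike peaks undetectable: ",
                                     conditionMessage(e))))
  tau_ca <- (pk$second$t - pk$first$t) / 2
  i_pk <- abs(min(i_ca$value)) * cleft_fraction
  if (i_pk == 0) abort("calcium current is zero")
  ratio <- pk$first$value / i_pk
  tibble::tibble(tau_cl = ratio * tau_ca * exp(0.5), tau_ca = tau_ca,
                 peak_ratio = ratio)
}

#' Cleft time constant from the slope against the current derivative
#'
#' Regresses the isolated calcium prespike on the inverted first derivative
#' of the calcium current, `-di_ca/dt`, allowing a slight time shift between
#' the two: a grid of integer-sample lags within `+/- max_lag` is searched
#' for maximal Pearson correlation (with parabolic refinement of the
#' reported lag), and the OLS slope at the best integer lag is the cleft
#' time constant.
#'
#' @param delta_i_post isolated calcium prespike (`cleft_ts`, amperes).
#' @param i_ca calcium current of one epoch (`cleft_ts`, amperes).
#' @param max_lag lag search half-range (s), at least one sample.
#' @param smooth_window derivative smoothing window (samples).
#' @return a one-row tibble: `tau_cl` (s, the slope), `lag` (s), `r`. A
#'   warning flags fits with `r < 0.5` (no usable relation).
#' @export
estimate_tau_cl_slope <- function(delta_i_post, i_ca, max_lag = 200e-6,
                                  smooth_window = 7) {
  dt <- ts_dt(delta_i_post)
  if (max_lag < dt) abort("max_lag must be at least one sample interval")
  x_full <- -differentiate(i_ca, 1, smooth_window)$value
  y_full <- delta_i_post$value
  n <- length(y_full)
  if (length(x_full) < n) abort("i_ca must cover the calcium-prespike epoch")
  x_full <- x_full[seq_len(n)]
  if (sd(x_full) == 0 || sd(y_full) == 0) abort("flat input: nothing to regress")
  lags <- seq(-floor(max_lag / dt), floor(max_lag / dt))
  rs <- purrr::map_dbl(lags, function(L) {
    # delay the derivative by L samples: compare y[t] with x[t - L]
    if (L >= 0) {
      yy <- y_full[(1 + L):n]; xx <- x_full[1:(n - L)]
    } else {
      yy <- y_full[1:(n + L)]; xx <- x_full[(1 - L):n]
    }
    if (sd(xx) == 0) return(NA_real_)
    cor(xx, yy)
  })
  ib <- which.max(rs)
  ref <- parabolic_peak(lags * dt, rs, ib)
  L <- lags[ib]
  if (L >= 0) {
    yy <- y_full[(1 + L):n]; xx <- x_full[1:(n - L)]
  } else {
    yy <- y_full[1:(n + L)]; xx <- x_full[(1 - L):n]
  }
  slope <- unname(coef(lm(yy ~ xx))[2])
  if (rs[ib] < 0.5) {
    warn(sprintf("weak relation between calcium prespike and -di_ca/dt (r = %.2f)", rs[ib]))
  }
  tibble::tibble(tau_cl = slope, lag = ref[1], r = rs[ib])
}

#' Derive cleft conductance, capacitance and resistivity
#'
#' From the regression of the capacitive prespike on the second AP
#' derivative (`slope = g_cl tau_cl^2`) and an independent cleft time
#' constant: `g_cl = |slope| / tau_cl^2`, `c_cl = g_cl tau_cl`, and, via the
#' disc-cleft relation, `R_ex = 8 pi h / g_cl`.
#'
#' @param slope_gcl_tau2 regression slope (A s^2 / V); the sign is ignored.
#' @param tau_cl cleft time constant (s).
#' @param h cleft height (m).
#' @return a one-row tibble: `g_cl` (S), `c_cl` (F), `R_ex` (Ohm m).
#' @examples
#' derive_cleft_parameters(0.1e-15, 10e-6, nm(30))
#' @export
derive_cleft_parameters <- function(slope_gcl_tau2, tau_cl, h = nm(30)) {
  if (tau_cl <= 0) abort("tau_cl must be positive")
  g_cl <- abs(slope_gcl_tau2) / tau_cl^2
  tibble::tibble(g_cl = g_cl, c_cl = g_cl * tau_cl,
                 R_ex = resistivity_from_conductance(g_cl, h))
}

#' Full estimation pipeline for a recording set
#'
#' Runs the whole analysis the package implements on a `recording_set`:
#' P/5 isolation of the calcium prespike (epoch-folded with the recorded
#' protocol), both cleft-time-constant estimators, the capacitive-prespike
#' slope `g_cl tau_cl^2` (obtained by regressing the passive prespike,
#' upscaled by 5, on the second derivative of the command waveform across
#' time samples), and the derived `g_cl`, `c_cl` and `R_ex`.
#'
#' @param rs a `recording_set` (with a protocol for epoch folding).
#' @param cleft_fraction fraction of the calcium current from the cleft.
#' @param h cleft height (m) for the resistivity estimate.
#' @param skip,use epoch-averaging protocol.
#' @param smooth_window derivative smoothing window (samples).
#' @param max_lag lag search half-range (s) for the slope estimator.
#' @return an object of class `cleft_estimate` with the estimates, fit
#'   diagnostics and (for synthetic data) the ground truth; see [tidy()] and
#'   [glance()] methods.
#' @export
analyze_recording_set <- function(rs, cleft_fraction = 2 / 3, h = nm(30),
                                  skip = 20L, use = 25L, smooth_window = 7,
                                  max_lag = 200e-6) {
  if (is.null(rs$protocol)) abort("recording set carries no train protocol")
  interval <- rs$protocol$interval
  if (skip + use > rs$protocol$n_stimuli) {
    skip <- 0L
    use <- rs$protocol$n_stimuli
  }
  delta <- isolate_calcium_prespike(rs$active_sweeps, rs$passive_sweeps,
                                    interval, skip, use)
  i_ca_ep <- fold_epochs(rs$i_ca_true, interval, skip, use)
  est_pr <- estimate_tau_cl_peak_ratio(delta, i_ca_ep, cleft_fraction)
  est_sl <- estimate_tau_cl_slope(delta, i_ca_ep, max_lag, smooth_window)
  # capacitive prespike (5x the averaged passive epoch) vs command second
  # derivative, regressed across time samples: slope = -g_cl tau_cl^2
  avg_passive <- purrr::reduce(purrr::map(rs$passive_sweeps, "value"), `+`) /
    length(rs$passive_sweeps)
  cap_prespike <- fold_epochs(ts_like(rs$v_pre, 5 * avg_passive, unit = "A"),
                              interval, skip, use)
  v_ep <- fold_epochs(rs$v_pre, interval, skip, use)
  d2v <- differentiate(v_ep, 2, smooth_window)
  cap_fit <- lm(cap_prespike$value ~ d2v$value)
  slope_gcl_tau2 <- unname(coef(cap_fit)[2])
  derived <- derive_cleft_parameters(slope_gcl_tau2, est_sl$tau_cl, h)
  structure(list(tau_cl_peak_ratio = est_pr$tau_cl,
                 tau_cl_slope = est_sl$tau_cl,
                 tau_ca = est_pr$tau_ca,
                 lag_at_max_r = est_sl$lag, r_slope_fit = est_sl$r,
                 slope_gcl_tau2 = slope_gcl_tau2,
                 g_cl = derived$g_cl, c_cl = derived$c_cl,
                 R_ex_given_h = derived$R_ex, h = h,
                 cleft_fraction = cleft_fraction,
                 delta_i_post = delta, i_ca_epoch = i_ca_ep,
                 truth = rs$truth),
            class = "cleft_estimate")
}

#' @export
print.cleft_estimate <- function(x, ...) {
  cat(sprintf(paste0("<cleft_estimate: tau_cl %.3g us (peak ratio) / %.3g us (slope, r = %.3f),\n",
                     "  g_cl %.3g uS, c_cl %.3g pF, R_ex %.3g Ohm cm (h = %g nm, cleft fraction %.2g)>\n"),
              x$tau_cl_peak_ratio * 1e6, x$tau_cl_slope * 1e6, x$r_slope_fit,
              x$g_cl * 1e6, x$c_cl * 1e12, to_ohm_cm(x$R_ex_given_h),
              x$h * 1e9, x$cleft_fraction))
  invisible(x)
}
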