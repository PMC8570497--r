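# Analytic cleft-geometry relations.
#
# All functions work in SI units (m, Ohm m, F/m^2, S, A, V). The field mixes
# unit systems (Ohm cm, um, nm, uF/cm^2, nS), and silent conversion slips of
# 10^2-10^4 are the dominant implementation risk, so explicit converters are
# provided for the interface.

#' Unit converters to SI
#'
#' Convenience converters from the conventional units of synaptic biophysics
#' to SI: `ohm_cm()` (extracellular resistivity, Ohm cm to Ohm m), `um()` and
#' `nm()` (lengths to m), `um2()` (areas to m^2), `uF_per_cm2()` (specific
#' capacitance to F/m^2), and their inverses `to_ohm_cm()`, `to_nS()`,
#' `to_pA()`.
#'
#' @param x numeric value in the conventional unit.
#' @return the value in SI units (or, for the `to_*` functions, in the
#'   conventional unit).
#' @examples
#' ohm_cm(75)       # 0.75 Ohm m
#' uF_per_cm2(1)    # 0.01 F/m^2
#' @export
ohm_cm <- function(x) x / 100

#' @rdname ohm_cm
#' @export
um <- function(x) x * 1e-6

#' @rdname ohm_cm
#' @export
nm <- function(x) x * 1e-9

#' @rdname ohm_cm
#' @export
um2 <- function(x) x * 1e-12

#' @rdname ohm_cm
#' @export
uF_per_cm2 <- function(x) x * 0.01

#' @rdname ohm_cm
#' @export
to_ohm_cm <- function(x) x * 100

#' @rdname ohm_cm
#' @export
to_nS <- function(x) x * 1e9

#' @rdname ohm_cm
#' @export
to_pA <- function(x) x * 1e12

#' Synapse cleft geometry
#'
#' Geometry of the cleft of a radially-symmetric (`"disc"`) or finger-like
#' (`"sheet"`) synapse. For a disc, `r` is the radius; for a sheet, `r` is
#' the half-width of the finger. Either `r` or `area` may be given for a
#' disc (they are checked for consistency to 1% when both are present).
#'
#' @param shape `"disc"` or `"sheet"`.
#' @param r radius or half-width (m).
#' @param h cleft height (m); typically 10-30 nm.
#' @param R_ex extracellular resistivity (Ohm m); ~0.75 Ohm m (75 Ohm cm) in
#'   the cleft.
#' @param C_m specific membrane capacitance (F/m^2); default 0.01
#'   (1 uF/cm^2).
#' @param area total apposition area (m^2); for a disc, `pi r^2`.
#' @return an object of class `synapse_geometry`.
#' @examples
#' synapse_geometry("disc", area = um2(1000), h = nm(30), R_ex = ohm_cm(75))
#' @export
synapse_geometry <- function(shape = c("disc", "sheet"), r = NULL, h = nm(30),
                             R_ex = ohm_cm(75), C_m = uF_per_cm2(1),
                             area = NULL) {
  shape <- match.arg(shape)
  if (is.null(r) && is.null(area)) abort("give `r` or (for a disc) `area`")
  if (shape == "disc") {
    if (is.null(r)) r <- sqrt(area / pi)
    if (is.null(area)) area <- pi * r^2
    if (abs(area - pi * r^2) > 0.01 * area) {
      abort("disc `area` and `r` disagree by more than 1% (area should be pi r^2)")
    }
  }
  if (any(c(r, h, R_ex, C_m) <= 0)) abort("all geometry parameters must be positive")
  structure(list(shape = shape, r = r, h = h, R_ex = R_ex, C_m = C_m,
                 area = area), class = "synapse_geometry")
}

#' Spatial profile of the cleft potential
#'
#' For a homogeneously distributed capacitive current density
#' `C_m dv_pre/dt`, cleft currents flow outward and the cleft potential at a
#' distance `x` from the centre is
#' `v(x) = (r^2 - x^2) R_ex C_m / (4 h) dv_pre/dt` for a disc and
#' `v(x) = (r^2 - x^2) R_ex C_m / (2 h) dv_pre/dt` for a sheet (the escape
#' route of a sheet is more restricted, so its gradient is steeper). The
#' potential vanishes at the rim and grows with the square of the size, and
#' the radial field grows linearly from the centre.
#'
#' @param geom a [synapse_geometry()].
#' @param dvdt rate of change of the presynaptic potential (V/s).
#' @param x positions relative to the centre (m); must satisfy `|x| <= r`.
#' @return a tibble with columns `x` and `v_cl` (V).
#' @export
cleft_potential_profile <- function(geom, dvdt, x = seq(0, geom$r, length.out = 101)) {
  if (any(abs(x) > geom$r * (1 + 1e-12))) {
    abort("positions |x| must not exceed the synapse radius/half-width r")
  }
  denom <- if (geom$shape == "disc") 4 else 2
  v <- (geom$r^2 - x^2) * geom$R_ex * geom$C_m / (denom * geom$h) * dvdt
  tibble::tibble(x = x, v_cl = v)
}

#' Voltage-clamp prespike of a disc synapse
#'
#' The postsynaptic capacitive current collected over the whole disc:
#' `i_post = pi r^4 R_ex C_m^2 / (8 h) d2v_pre/dt2`. The prespike grows with
#' the fourth power of the radius, which is why intracellularly recorded
#' prespikes are only seen at giant synapses. The result is identical to the
#' lumped form `g_cl tau_cl^2 d2v/dt2` with `g_cl = 8 pi h / R_ex` and
#' `c_cl = C_m pi r^2`.
#'
#' @param geom a disc [synapse_geometry()].
#' @param d2vdt2 second derivative of the presynaptic potential (V/s^2).
#' @return prespike current (A).
#' @export
vc_prespike_disc <- function(geom, d2vdt2) {
  if (geom$shape != "disc") {
    abort("vc_prespike_disc needs a disc geometry; use sheet_prespike/fenestration_ratios for sheets")
  }
  pi * geom$r^4 * geom$R_ex * geom$C_m^2 / (8 * geom$h) * d2vdt2
}

#' Voltage-clamp prespike of a sheet-like (finger) synapse
#'
#' Integrates the postsynaptic capacitive current density
#' `C_m dv_cl/dt` over a sheet of half-width `r` and total apposition area
#' `area` (total finger length `area / (2 r)`), giving
#' `i_post = area r^2 R_ex C_m^2 / (3 h) d2v_pre/dt2`.
#'
#' @param geom a sheet [synapse_geometry()] with `area` set.
#' @param d2vdt2 second derivative of the presynaptic potential (V/s^2).
#' @return prespike current (A).
#' @export
sheet_prespike <- function(geom, d2vdt2) {
  if (geom$shape != "sheet") abort("sheet_prespike needs a sheet geometry")
  if (is.null(geom$area)) abort("sheet_prespike needs the total apposition `area`")
  geom$area * geom$r^2 * geom$R_ex * geom$C_m^2 / (3 * geom$h) * d2vdt2
}

#' Cleft conductance of a disc synapse, and its inverse
#'
#' For a radially-symmetric cleft the leak conductance is
#' `g_cl = 8 pi h / R_ex`: independent of the radius, because the escape
#' perimeter grows exactly as fast as the current-generating area.
#' `resistivity_from_conductance()` inverts the relation to estimate the
#' intra-cleft resistivity from a measured `g_cl` (1 uS at h = 30 nm gives
#' about 75 Ohm cm).
#'
#' @param h cleft height (m).
#' @param R_ex extracellular resistivity (Ohm m).
#' @param g_cl cleft conductance (S).
#' @return conductance in S, or resistivity in Ohm m.
#' @examples
#' to_nS(cleft_conductance_disc(nm(30), ohm_cm(75)))      # ~1000 nS
#' to_ohm_cm(resistivity_from_conductance(1e-6, nm(30)))  # ~75 Ohm cm
#' @export
cleft_conductance_disc <- function(h, R_ex) {
  if (h <= 0 || R_ex <= 0) abort("h and R_ex must be positive")
  8 * pi * h / R_ex
}

#' @rdname cleft_conductance_disc
#' @export
resistivity_from_conductance <- function(g_cl, h) {
  if (h <= 0 || g_cl <= 0) abort("h and g_cl must be positive")
  8 * pi * h / g_cl
}

#' Effect of fenestration on cleft potential and prespike
#'
#' Developmental fenestration turns a cup-shaped (disc) terminal into fingers
#' over the same total contact area. Comparing a sheet-like finger of width
#' `finger_width` against the disc of area `total_area` under identical
#' `h`, `R_ex`, `C_m` and presynaptic waveform gives a centre-potential ratio
#' `2 r_f^2 / r_c^2` and a prespike ratio `(8/3) r_f^2 / r_c^2`
#' (`r_f = finger_width / 2`, `r_c = sqrt(total_area / pi)`). For a 4 um
#' finger versus a 1000 um^2 disc these are ~2.5% and ~3.3%: fenestration
#' almost abolishes cleft potentials.
#'
#' @param finger_width width of a finger (m).
#' @param total_area conserved total contact area (m^2).
#' @param h cleft height (m); cancels in both ratios but is kept for the
#'   underlying absolute quantities.
#' @return a tibble with `potential_ratio`, `prespike_ratio` (dimensionless
#'   fractions) and a `degenerate` flag set when the finger is as wide as the
#'   disc (single-sheet limit, where the ratios approach 2 and 8/3).
#' @examples
#' fenestration_ratios(um(4), um2(1000))
#' @export
fenestration_ratios <- function(finger_width, total_area, h = nm(30)) {
  if (finger_width <= 0 || total_area <= 0 || h <= 0) {
    abort("finger_width, total_area and h must be positive")
  }
  r_c <- sqrt(total_area / pi)
  r_f <- finger_width / 2
  degenerate <- finger_width >= 2 * r_c
  # ratios computed from the underlying absolute quantities so the sheet
  # integral, not a memorised constant, carries the result
  disc <- synapse_geometry("disc", r = r_c, h = h, area = total_area)
  sheet <- synapse_geometry("sheet", r = r_f, h = h, area = total_area)
  dvdt <- 1; d2 <- 1
  potential_ratio <- cleft_potential_profile(sheet, dvdt, 0)$v_cl /
    cleft_potential_profile(disc, dvdt, 0)$v_cl
  prespike_ratio <- sheet_prespike(sheet, d2) / vc_prespike_disc(disc, d2)
  if (degenerate) {
    warn("finger as wide as the equivalent disc: degenerate single-sheet limit")
  }
  tibble::tibble(potential_ratio = potential_ratio,
                 prespike_ratio = prespike_ratio,
                 degenerate = degenerate)
}

#' Membrane susceptance of an apposition area
#'
#' `2 pi f C_m A`, the capacitive admittance magnitude at frequency `f`; at
#' 1 kHz over 1000 um^2 with 1 uF/cm^2 this is ~63 nS, far larger than the
#' ~4 nS postsynaptic resting conductance — capacitive currents dominate the
#' ephaptic coupling.
#'
#' @param f frequency (Hz).
#' @param C_m specific membrane capacitance (F/m^2).
#' @param area membrane area (m^2).
#' @return susceptance (S).
#' @examples
#' to_nS(membrane_susceptance(1000, uF_per_cm2(1), um2(1000))) # ~63 nS
#' @export
membrane_susceptance <- function(f, C_m = uF_per_cm2(1), area = um2(1000)) {
  if (f < 0 || C_m <= 0 || area <= 0) abort("f must be >= 0; C_m and area positive")
  2 * pi * f * C_m * area
}
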