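# Closed-form biophysical relations used throughout the package.
# Sign convention everywhere: membrane voltage is the cis-side potential
# with the trans chamber held at ground, so equilibrium potentials are
# E = (RT/zF) * ln(c_trans / c_cis).

#' Physical constants
#'
#' Gas constant `R` (J mol^-1 K^-1), Faraday constant `F` (C mol^-1) and the
#' elementary charge `e` (C). Fixed values; exposed read-only so tests and
#' downstream code share a single source.
#'
#' @format A named list with elements `R`, `F_`, `e`.
#' @export
phys_constants <- list(
  R  = 8.314,
  F_ = 96485,
  e  = 1.602177e-19
)

#' Ion species descriptor
#'
#' @param name Short label, e.g. `"K"`, `"Cl"`, `"Ca"`.
#' @param z Signed integer valence; must be non-zero.
#' @return An object of class `ion_species`.
#' @examples
#' ion_species("Ca", +2)
#' @export
ion_species <- function(name, z) {
  z <- as.integer(z)
  if (length(z) != 1L || is.na(z) || z == 0L) {
    err_domain("ion valence z must be a non-zero integer")
  }
  structure(list(name = as.character(name), z = z), class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion> %s (z = %+d)\n", x$name, x$z))
  invisible(x)
}

#' Solution pair for a bilayer experiment
#'
#' Per-ion concentrations (mM) on the cis and trans sides plus the bath
#' temperature. Concentrations are treated as activities (no activity
#' coefficients are applied).
#'
#' @param cis,trans Named numeric vectors of concentrations in mM, names are
#'   ion labels. All declared concentrations must be positive.
#' @param temperature_C Bath temperature in degrees Celsius.
#' @return An object of class `solution_pair`.
#' @export
solution_pair <- function(cis, trans, temperature_C = 22) {
  if (any(cis <= 0) || any(trans <= 0)) {
    err_domain("all declared ion concentrations must be > 0 mM")
  }
  if (temperature_C <= -273.15) err_domain("temperature below absolute zero")
  structure(list(cis = cis, trans = trans, temperature_C = temperature_C),
            class = "solution_pair")
}

#' Thermal voltage RT/F
#'
#' @param temperature_C Temperature in degrees Celsius (> -273.15).
#' @return RT/F in millivolts (about 25.4 mV at 22 degrees C).
#' @examples
#' thermal_voltage(22) # 25.43 mV
#' @export
thermal_voltage <- function(temperature_C) {
  if (any(temperature_C <= -273.15)) {
    err_domain("temperature must be above absolute zero (-273.15 C)")
  }
  1000 * phys_constants$R * (temperature_C + 273.15) / phys_constants$F_
}

#' Nernst equilibrium potential
#'
#' Voltage at which an ion species is at electrochemical equilibrium across
#' the membrane, under the cis-minus-trans voltage convention:
#' `E = (rt_over_f / z) * ln(c_trans / c_cis)`.
#'
#' @param ion An [ion_species()], or a signed integer valence.
#' @param c_cis,c_trans Concentrations in mM (> 0).
#' @param rt_over_f Thermal voltage RT/F in mV; see [thermal_voltage()].
#' @return Equilibrium potential in mV.
#' @examples
#' nernst_potential(ion_species("K", 1), 510, 210, thermal_voltage(25))
#' @export
nernst_potential <- function(ion, c_cis, c_trans,
                             rt_over_f = thermal_voltage(22)) {
  z <- if (inherits(ion, "ion_species")) ion$z else as.integer(ion)
  if (z == 0L) err_domain("valence must be non-zero")
  if (any(c_cis <= 0) || any(c_trans <= 0)) {
    err_domain("concentrations must be > 0 mM")
  }
  (rt_over_f / z) * log(c_trans / c_cis)
}

#' Fatt-Ginsborg bi-ionic permeability ratio
#'
#' Divalent/monovalent permeability ratio for a bi-ionic condition with
#' Ca2+ on one side and K+ on the other:
#' `P_Ca/P_K = ([K]/(4 [Ca])) * exp(x) * (exp(x) + 1)` with
#' `x = e_rev / rt_over_f`. The ratio is 1/2 at `e_rev = 0` for equimolar
#' solutions and is strictly increasing in `e_rev`.
#'
#' @param e_rev Reversal potential in mV (on the Ca-side-positive convention
#'   of the bi-ionic measurement).
#' @param k_conc,ca_conc K+ and Ca2+ concentrations in mM (> 0).
#' @param rt_over_f Thermal voltage in mV.
#' @return Dimensionless permeability ratio (> 0).
#' @examples
#' fatt_ginsborg_ratio(-1.42, 210, 210, 25.4) # about 0.46
#' @export
fatt_ginsborg_ratio <- function(e_rev, k_conc, ca_conc,
                                rt_over_f = thermal_voltage(22)) {
  if (any(k_conc <= 0) || any(ca_conc <= 0)) {
    err_domain("concentrations must be > 0 mM")
  }
  x <- e_rev / rt_over_f
  (k_conc / (4 * ca_conc)) * exp(x) * (exp(x) + 1)
}

#' Reversal potential giving a target Fatt-Ginsborg ratio
#'
#' Inverse of [fatt_ginsborg_ratio()], solved in closed form through the
#' quadratic in `y = exp(e_rev / rt_over_f)`:
#' `y^2 + y - 4 * ratio * ca / k = 0`.
#'
#' @param ratio Target permeability ratio (> 0).
#' @inheritParams fatt_ginsborg_ratio
#' @return Reversal potential in mV; exact inverse to better than 1e-9
#'   relative tolerance.
#' @export
erev_for_fg_ratio <- function(ratio, k_conc, ca_conc,
                              rt_over_f = thermal_voltage(22)) {
  if (any(ratio <= 0)) err_domain("ratio must be > 0")
  if (any(k_conc <= 0) || any(ca_conc <= 0)) {
    err_domain("concentrations must be > 0 mM")
  }
  c0 <- 4 * ratio * ca_conc / k_conc
  y <- (-1 + sqrt(1 + 4 * c0)) / 2
  rt_over_f * log(y)
}

#' Anion/cation permeability ratio from a KCl reversal potential
#'
#' Two-ion Goldman-Hodgkin-Katz voltage equation for a KCl gradient
#' ([Cl-] = [K+] on each side), solved for `r = P_Cl / P_K`:
#' `e_rev = rt_over_f * ln((K_trans + r * K_cis) / (K_cis + r * K_trans))`.
#' The solution is `r = 0` when `e_rev` equals the K+ Nernst potential and
#' `r = 1` when `e_rev = 0`; `e_rev` outside the interval bounded by the two
#' Nernst potentials has no non-negative solution.
#'
#' @param e_rev Measured (junction-corrected) reversal potential, mV.
#' @param k_cis,k_trans KCl concentrations in mM on cis and trans sides.
#' @param rt_over_f Thermal voltage in mV.
#' @return Non-negative permeability ratio P_Cl/P_K.
#' @examples
#' pcl_pk_from_erev(-14.5, 510, 210, 25.4) # about 0.20
#' @export
pcl_pk_from_erev <- function(e_rev, k_cis, k_trans,
                             rt_over_f = thermal_voltage(22)) {
  if (any(k_cis <= 0) || any(k_trans <= 0)) {
    err_domain("concentrations must be > 0 mM")
  }
  e_k  <- rt_over_f * log(k_trans / k_cis)
  e_cl <- -e_k
  lo <- min(e_k, e_cl); hi <- max(e_k, e_cl)
  if (e_rev < lo || e_rev > hi) {
    err_domain(sprintf(
      "e_rev = %.3g mV lies outside the Nernst interval [%.3g, %.3g] mV; no non-negative P_Cl/P_K solves the GHK equation",
      e_rev, lo, hi
    ))
  }
  q <- exp(e_rev / rt_over_f)
  # q = (K_t + r K_c) / (K_c + r K_t)  =>  r = (K_t - q K_c) / (q K_t - K_c)
  r <- (k_trans - q * k_cis) / (q * k_trans - k_cis)
  # endpoints are exact by construction; guard tiny negative round-off
  max(r, 0)
}

#' Ohmic open-channel current
#'
#' Linear single-channel current `i = G * (V - E_rev)`, with the unit
#' bookkeeping pS x mV = 1e-3 pA.
#'
#' @param conductance_pS Single-channel conductance in pS (>= 0).
#' @param voltage_mV Membrane voltage in mV (cis relative to grounded trans).
#' @param e_rev_mV Reversal potential in mV.
#' @return Current in pA.
#' @examples
#' ohmic_open_current(18.4, 80, 0) # 1.472 pA
#' @export
ohmic_open_current <- function(conductance_pS, voltage_mV, e_rev_mV = 0) {
  if (any(conductance_pS < 0)) err_domain("conductance must be >= 0")
  conductance_pS * (voltage_mV - e_rev_mV) * 1e-3
}
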