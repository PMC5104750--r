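# Gas constant in L atm mol^-1 K^-1 and STP molar volume (ideal gas, 0 degC, 1 atm)
.R_L_ATM <- 0.082057366
.VM_STP_L <- 22.413969

#' Gas solubility models
#'
#' A `solubility_model` stores the coefficients of the standard
#' Bunsen-coefficient fit in temperature and salinity,
#' \deqn{\ln \beta = A_1 + A_2 (100/T) + A_3 \ln(T/100) +
#'       S \left[B_1 + B_2 (T/100) + B_3 (T/100)^2\right],}
#' with \eqn{T} in kelvin and \eqn{S} the practical salinity. `ch4_solubility()`
#' returns the methane model with the coefficient set in routine use for
#' headspace back-calculation of dissolved CH4 in fresh and marine waters.
#'
#' An ideal-gas fallback with a user-supplied Henry constant can be built by
#' passing `henry_M_per_atm`; such a model ignores the A/B coefficients and
#' evaluates \eqn{\beta = H \cdot V_m} (dimensionless) at all T, S.
#'
#' @param name label of the model.
#' @param a,b numeric coefficient vectors of length 3 (temperature block and
#'   salinity block).
#' @param t_range validity range of the fit in degrees Celsius.
#' @param henry_M_per_atm optional Henry constant (mol L-1 atm-1) for a
#'   constant-solubility fallback model.
#' @return An object of class `solubility_model`.
#' @examples
#' ch4_solubility()
#' @export
solubility_model <- function(name, a = NULL, b = NULL,
                             t_range = c(-2, 30), henry_M_per_atm = NULL) {
  if (is.null(henry_M_per_atm)) {
    stopifnot(length(a) == 3L, length(b) == 3L)
  } else {
    stopifnot(is.numeric(henry_M_per_atm), henry_M_per_atm > 0)
  }
  structure(list(name = name, a = a, b = b, t_range = t_range,
                 henry_M_per_atm = henry_M_per_atm),
            class = "solubility_model")
}

#' @rdname solubility_model
#' @export
ch4_solubility <- function() {
  solubility_model(
    name = "CH4 Bunsen fit v1",
    a = c(-68.8862, 101.4956, 28.7314),
    b = c(-0.076146, 0.043970, -0.0068672),
    t_range = c(-2, 30)
  )
}

#' @export
print.solubility_model <- function(x, ...) {
  cat(sprintf("<solubility_model> %s (valid %g to %g degC)\n",
              x$name, x$t_range[1], x$t_range[2]))
  invisible(x)
}

#' Bunsen solubility coefficient
#'
#' Evaluates the dimensionless Bunsen coefficient (volume of gas at STP
#' absorbed per volume of water at 1 atm gas partial pressure) of a
#' [solubility_model()] at a given temperature and salinity. Solubility
#' decreases with warming and with salting-out, and the function errors (or
#' warns, per `on_extrapolation`) outside the fit's validity range.
#'
#' @param model a [solubility_model()].
#' @param temperature_C water temperature in degrees Celsius.
#' @param salinity practical salinity (permil); 0 for fresh water.
#' @param on_extrapolation `"error"` (default) or `"warn"` when T lies outside
#'   the model's validity range.
#' @return Dimensionless Bunsen coefficient (> 0).
#' @examples
#' bunsen_coefficient(ch4_solubility(), 6, 0)
#' @export
bunsen_coefficient <- function(model, temperature_C, salinity = 0,
                               on_extrapolation = c("error", "warn")) {
  on_extrapolation <- match.arg(on_extrapolation)
  stopifnot(inherits(model, "solubility_model"))
  if (any(salinity < 0)) stop("salinity must be non-negative", call. = FALSE)
  out_of_range <- temperature_C < model$t_range[1] | temperature_C > model$t_range[2]
  if (any(out_of_range)) {
    msg <- sprintf("temperature outside solubility-fit validity range [%g, %g] degC",
                   model$t_range[1], model$t_range[2])
    if (on_extrapolation == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  if (!is.null(model$henry_M_per_atm))
    return(rep_len(model$henry_M_per_atm * .VM_STP_L, length(temperature_C)))
  tk <- temperature_C + 273.15
  lnb <- model$a[1] + model$a[2] * (100 / tk) + model$a[3] * log(tk / 100) +
    salinity * (model$b[1] + model$b[2] * (tk / 100) + model$b[3] * (tk / 100)^2)
  exp(lnb)
}

#' Back-calculate dissolved methane from a headspace equilibration
#'
#' For a serum bottle in which an initially gas-free (N2) headspace of volume
#' `v_gas_mL` was equilibrated with `v_water_mL` of sample, and in which the
#' headspace CH4 mole fraction `x_ch4` was then measured, returns the original
#' dissolved concentration before the headspace was introduced:
#' \deqn{C_0 = \frac{n_{gas} + n_{aq}}{V_{water}},\qquad
#'       n_{gas} = \frac{x P V_{gas}}{R T},\qquad
#'       n_{aq} = \frac{\beta\, x P}{V_m} V_{water}.}
#'
#' @param x_ch4 measured headspace CH4 mole fraction (0 to 1); vectorised.
#' @param v_water_mL volume of the water phase (mL).
#' @param v_gas_mL volume of the headspace (mL).
#' @param model a [solubility_model()]; default [ch4_solubility()].
#' @param temperature_C equilibration temperature (degC); default 20 (lab).
#' @param salinity practical salinity; default 0 (fresh water).
#' @param pressure_atm total pressure (atm); default 1.
#' @return Original dissolved CH4 concentration in micromolar (umol L-1).
#' @examples
#' headspace_to_dissolved(0.01, v_water_mL = 100, v_gas_mL = 20)
#' @export
headspace_to_dissolved <- function(x_ch4, v_water_mL = 100, v_gas_mL = 20,
                                   model = ch4_solubility(),
                                   temperature_C = 20, salinity = 0,
                                   pressure_atm = 1) {
  if (v_water_mL <= 0 || v_gas_mL <= 0)
    stop("phase volumes must be positive", call. = FALSE)
  if (any(!is.finite(x_ch4)) || any(x_ch4 < 0) || any(x_ch4 > 1))
    stop("x_ch4 must lie in [0, 1]", call. = FALSE)
  beta <- bunsen_coefficient(model, temperature_C, salinity)
  tk <- temperature_C + 273.15
  p <- x_ch4 * pressure_atm                         # atm partial pressure
  n_gas <- p * (v_gas_mL / 1000) / (.R_L_ATM * tk)  # mol in headspace
  n_aq <- beta * p / .VM_STP_L * (v_water_mL / 1000) # mol still dissolved
  (n_gas + n_aq) / (v_water_mL / 1000) * 1e6        # umol per L
}

#' Partition a dissolved gas pool into headspace and water phases
#'
#' Forward model complementing [headspace_to_dissolved()]: given the original
#' dissolved concentration, returns the equilibrium headspace mole fraction.
#' Used for mass-closure checks and synthetic data.
#'
#' @param c0_uM original dissolved concentration (umol L-1).
#' @inheritParams headspace_to_dissolved
#' @return Equilibrium headspace mole fraction.
#' @export
dissolved_to_headspace <- function(c0_uM, v_water_mL = 100, v_gas_mL = 20,
                                   model = ch4_solubility(),
                                   temperature_C = 20, salinity = 0,
                                   pressure_atm = 1) {
  if (v_water_mL <= 0 || v_gas_mL <= 0)
    stop("phase volumes must be positive", call. = FALSE)
  beta <- bunsen_coefficient(model, temperature_C, salinity)
  tk <- temperature_C + 273.15
  n_total <- c0_uM * 1e-6 * (v_water_mL / 1000)     # mol
  # n_total = x P [Vg/(RT) + beta Vw / Vm]  =>  solve for x
  denom <- pressure_atm *
    ((v_gas_mL / 1000) / (.R_L_ATM * tk) + beta * (v_water_mL / 1000) / .VM_STP_L)
  n_total / denom
}

#' Atmospheric-equilibrium dissolved gas concentration
#'
#' Henry-law equilibrium concentration of a gas in water exposed to an
#' atmosphere with mole fraction `x_atm`, in nanomolar. Equals the
#' infinite-headspace limit of the bottle partitioning model.
#'
#' @param x_atm atmospheric mole fraction of the gas (e.g. ~1.9e-6 for CH4).
#' @inheritParams headspace_to_dissolved
#' @return Dissolved concentration in nanomolar (nmol L-1).
#' @examples
#' atmospheric_equilibrium(1.9e-6, temperature_C = 6)
#' @export
atmospheric_equilibrium <- function(x_atm, model = ch4_solubility(),
                                    temperature_C = 20, salinity = 0,
                                    pressure_atm = 1) {
  if (any(x_atm < 0)) stop("x_atm must be non-negative", call. = FALSE)
  beta <- bunsen_coefficient(model, temperature_C, salinity)
  beta * x_atm * pressure_atm / .VM_STP_L * 1e9     # nmol per L
}
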