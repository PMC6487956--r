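#' Canopy-profile multiplier of mesophyll conductance
#'
#' gm declines with depth in the canopy in parallel with photosynthetic
#' capacity (leaf nitrogen), as \code{exp(-kn * L)} where \code{L} is the
#' cumulative leaf area index above the leaf.
#'
#' @param cumulative_lai Cumulative LAI above the leaf (m2 m-2, >= 0).
#' @param kn Nitrogen extinction coefficient (default 0.11).
#' @return Dimensionless multiplier in (0, 1].
#' @export
f_canopy <- function(cumulative_lai, kn = 0.11) {
  if (any(cumulative_lai < 0)) stop("cumulative_lai must be non-negative")
  exp(-kn * cumulative_lai)
}

#' Temperature multiplier of mesophyll conductance
#'
#' Peaked (modified) Arrhenius response normalized to 1 at the reference
#' temperature, with an optimum near 35.5 degC for the default parameters:
#' \deqn{f_2(T_l) = \exp\!\left(\frac{H_a (T_l - T_{ref})}{T_{ref} R T_l}\right)
#'   \frac{1 + \exp\!\left(\frac{T_{ref}\Delta S - H_d}{T_{ref} R}\right)}
#'        {1 + \exp\!\left(\frac{T_l \Delta S - H_d}{T_l R}\right)}}
#'
#' @param Tl Leaf temperature (K). Accepts vectors.
#' @param p A \code{\link{gm_temp_params}} object.
#' @return Dimensionless multiplier; exactly 1 at \code{p$Tref}.
#' @export
f_temperature <- function(Tl, p = gm_temp_params()) {
  if (any(Tl <= 250) || any(Tl >= 330))
    stop("leaf temperature outside the supported range (250, 330) K")
  exp(p$Ha * (Tl - p$Tref) / (p$Tref * .Rgas * Tl)) *
    (1 + exp((p$Tref * p$dS - p$Hd) / (p$Tref * .Rgas))) /
    (1 + exp((Tl * p$dS - p$Hd) / (Tl * .Rgas)))
}

#' Soil-moisture multiplier
#'
#' Piecewise power response: no stress above the critical moisture, total
#' stress at or below the wilting point, and \code{beta^q} in between with
#' \code{beta = (theta - theta_wilt) / (theta_crit - theta_wilt)}. The same
#' form is applied to gm, gs and leaf biochemistry but with different
#' exponents (\code{qm}, \code{qs}, \code{qb}).
#'
#' @param theta Soil moisture (m).
#' @param soil A \code{\link{soil_params}} object.
#' @param q Sensitivity exponent (> 0).
#' @return Multiplier in [0, 1].
#' @export
f_soil <- function(theta, soil = soil_params(), q = 0.75) {
  stopifnot(q > 0)
  if (soil$theta_crit <= soil$theta_wilt)
    stop("theta_crit must exceed theta_wilt")
  beta <- pmin(1, pmax(0, (theta - soil$theta_wilt) /
                            (soil$theta_crit - soil$theta_wilt)))
  beta^q
}

#' Soil water stress level
#'
#' The relative plant-available water \code{beta} in [0, 1] underlying
#' \code{\link{f_soil}}; exposed because experiment filters ("unstressed"
#' periods) are defined on beta rather than on a particular exponent.
#'
#' @inheritParams f_soil
#' @export
soil_beta <- function(theta, soil = soil_params()) {
  pmin(1, pmax(0, (theta - soil$theta_wilt) /
                    (soil$theta_crit - soil$theta_wilt)))
}

#' Intercellular-CO2 multiplier
#'
#' Empirical response with an abrupt rise at low Ci, a maximum near
#' 100 umol/mol, and an exponential decline thereafter:
#' \code{f4 = fmin + 1.5 * (1 - exp(-Ci/38)) * exp(-Ci/460)}. It tends to
#' \code{fmin} at both limits and passes close to 1 at the standardization
#' point Ci = 260 umol/mol.
#'
#' @param Ci Intercellular CO2 mole fraction (umol/mol, >= 0).
#' @param fmin Minimum relative gm (default 0.15).
#' @return Dimensionless multiplier.
#' @export
f_ci <- function(Ci, fmin = 0.15) {
  if (any(Ci < 0)) stop("Ci must be non-negative")
  fmin + 1.5 * (1 - exp(-Ci / 38)) * exp(-Ci / 460)
}

#' Light multiplier
#'
#' Saturating response \code{f5 = 1 - (1 - fmin) * exp(-0.003 * Qa)}: equal to
#' \code{fmin} in darkness, about 0.8 at 500 umol m-2 s-1 and close to 1 at
#' 1500 umol m-2 s-1.
#'
#' @param Qa Absorbed PPFD (umol m-2 s-1, >= 0).
#' @param fmin Minimum relative gm (default 0.15).
#' @return Dimensionless multiplier in [fmin, 1).
#' @export
f_light <- function(Qa, fmin = 0.15) {
  if (any(Qa < 0)) stop("Qa must be non-negative")
  1 - (1 - fmin) * exp(-0.003 * Qa)
}

#' Effective mesophyll conductance
#'
#' Multiplicative gm model: the unstressed PFT maximum at 25 degC is scaled by
#' the canopy-profile, temperature, soil-moisture and (depending on the model
#' version) Ci and light multipliers, and clamped from below at
#' \code{fmin * gm_max25}:
#' \deqn{g_m = \max(g_{m,min},\; g_{m,max25}\, f_1 f_2 f_3 f_4 f_5)}
#' The clamp applies to the final product, not to individual factors.
#'
#' @param pft A \code{\link{pft_params}} object.
#' @param env An \code{\link{env_state}} object.
#' @param cumulative_lai Cumulative LAI above the leaf.
#' @param version A \code{\link{model_version}} (explicit versions only).
#' @param soil A \code{\link{soil_params}} object.
#' @param gm_temp A \code{\link{gm_temp_params}} object.
#' @param Ci Intercellular CO2 used for the f4 factor when the version enables
#'   it (defaults to \code{env$Ca * 0.7} as a pre-iteration stand-in; the leaf
#'   solver passes its current iterate).
#' @return List of class \code{gm_factors}: \code{f1} ... \code{f5}, the
#'   unclamped product, and the clamped conductance \code{gm} (mol m-2 s-1).
#' @export
gm_effective <- function(pft, env, cumulative_lai = 0,
                         version = model_version("Exp"),
                         soil = soil_params(), gm_temp = gm_temp_params(),
                         Ci = env$Ca * 0.7) {
  if (is.character(version)) version <- model_version(version)
  if (version$name == "Imp")
    stop("gm is not modeled explicitly in the 'Imp' version")
  f1 <- f_canopy(cumulative_lai, pft$kn)
  f2 <- f_temperature(env$Tl + 273.15, gm_temp)
  f3 <- f_soil(env$theta, soil, pft$qm)
  f4 <- if (version$use_ci_response) f_ci(Ci, pft$fmin) else 1
  f5 <- if (version$use_light_response) f_light(env$Qa, pft$fmin) else 1
  raw <- pft$gm_max25 * f1 * f2 * f3 * f4 * f5
  gm <- max(pft$fmin * pft$gm_max25, raw)
  structure(list(f1 = f1, f2 = f2, f3 = f3, f4 = f4, f5 = f5,
                 raw = raw, gm = gm), class = "gm_factors")
}
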