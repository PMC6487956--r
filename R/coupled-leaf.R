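#' Instantaneous leaf environment
#'
#' @param Tl Leaf temperature (degC).
#' @param Qa Absorbed PPFD (umol m-2 s-1).
#' @param Ca Atmospheric CO2 mole fraction (umol/mol).
#' @param D Vapor pressure deficit (kPa); floored at 0.05.
#' @param theta Soil moisture (m); defaults to field capacity (no stress).
#' @return Object of class \code{env_state}.
#' @export
env_state <- function(Tl = 25, Qa = 1500, Ca = 400, D = 1, theta = 0.3) {
  stopifnot(Ca > 0, Qa >= 0)
  structure(list(Tl = Tl, Qa = Qa, Ca = Ca, D = max(D, 0.05), theta = theta),
            class = "env_state")
}

#' Medlyn stomatal conductance
#'
#' Unified optimal stomatal model: \code{gs = g0 + 1.6 * (1 + g1/sqrt(D)) *
#' An / Ca} for positive net assimilation, and the residual conductance
#' \code{g0} otherwise. \code{gs} is on the water-vapor basis; the CO2 supply
#' uses \code{gs / 1.6}.
#'
#' @param An Net assimilation (umol m-2 s-1).
#' @param Ca Atmospheric CO2 (umol/mol).
#' @param D Vapor pressure deficit (kPa).
#' @param g0 Residual conductance (mol m-2 s-1).
#' @param g1 Stomatal slope (kPa^0.5).
#' @return Stomatal conductance to water vapor (mol m-2 s-1). Note the 1e-6
#'   flux-to-mole-fraction conversion cancels because An and Ca are both in
#'   micro-units.
#' @export
medlyn_gs <- function(An, Ca, D, g0 = 0.005, g1 = 4) {
  stopifnot(Ca > 0)
  D <- pmax(D, 0.05)
  ifelse(An > 0, g0 + 1.6 * (1 + g1 / sqrt(D)) * An / Ca, g0)
}

# biochemistry at leaf temperature for one leaf, with soil stress beta^qb
# applied to the capacities. Capacities are held at their 25 degC values
# (all calibrated quantities in this package are defined at 25 degC; a
# temperature scaling can be supplied via `tscale`).
.leaf_biochem_at <- function(pft, env, scale_n = 1, beta = 1,
                             kin, saturating_light = FALSE,
                             alpha = 0.3, theta_curv = 0.7, tscale = 1) {
  s <- scale_n * beta^pft$qb * tscale
  Rl <- pft$Rl_frac * pft$Vcmax25 * scale_n
  if (pft$pathway == "C3") {
    J <- if (saturating_light) s * pft$Jmax25 else
      electron_transport(env$Qa, s * pft$Jmax25, alpha, theta_curv)
    leaf_biochem(Vcmax = s * pft$Vcmax25, J = J, Rl = Rl, kinetics = kin)
  } else {
    J <- if (is.finite(pft$Jmax25) && !saturating_light)
      electron_transport(env$Qa, s * pft$Jmax25, alpha, theta_curv)
    else if (is.finite(pft$Jmax25)) s * pft$Jmax25 else NA_real_
    leaf_biochem(Vcmax = s * pft$Vcmax25, J = if (is.na(J)) Inf else J,
                 Vpmax = s * pft$Vpmax25, Rl = Rl, kinetics = kin)
  }
}

#' Converged leaf gas exchange
#'
#' Couples the gm model, C3/C4 biochemistry and Medlyn stomatal conductance.
#' A damped fixed-point iteration updates Ci: gm is evaluated (refreshing its
#' Ci factor from the current iterate when the model version enables it), net
#' assimilation is solved at that Ci through the finite-gm quadratic,
#' stomatal conductance follows from the Medlyn equation, and the CO2 supply
#' equation \code{Ci = Ca - 1.6 An / gs} closes the loop. If the damped
#' iteration (factor 0.5) has not converged to |dCi| < 1e-4 umol/mol after 50
#' steps, a bracketed root search on Ci takes over.
#'
#' Under the implicit version gm is infinite and Ci-based parameters and
#' kinetics are used throughout.
#'
#' @param env An \code{\link{env_state}}.
#' @param pft A \code{\link{pft_params}}; capacities must be on the basis the
#'   version expects (Ci-based for \code{Imp}, Cc-based for explicit runs, see
#'   \code{\link{adjust_pft}}).
#' @param version A \code{\link{model_version}} or name.
#' @param cumulative_lai Cumulative LAI above the leaf (canopy profile factor).
#' @param soil A \code{\link{soil_params}}.
#' @param kinetics_file Optional alternative kinetics parameter file.
#' @param gm_override Fix gm at a given value (mol m-2 s-1), bypassing the gm
#'   model (used by sensitivity sweeps); \code{NULL} for the model value.
#' @return Object of class \code{leaf_solution}: \code{An}, \code{gs},
#'   \code{gm}, \code{Ci}, \code{Cx}, \code{limitation}, \code{iterations},
#'   \code{residual} and the gm factor diagnostics.
#' @export
solve_leaf <- function(env, pft, version = model_version("Exp"),
                       cumulative_lai = 0, soil = soil_params(),
                       kinetics_file = NULL, gm_override = NULL) {
  if (is.character(version)) version <- model_version(version)
  res <- resolve_kinetics(version, file = kinetics_file)
  kin <- res$kinetics
  gmt <- res$gm_temp
  beta <- soil_beta(env$theta, soil)
  scale_n <- f_canopy(cumulative_lai, pft$kn)
  b <- .leaf_biochem_at(pft, env, scale_n, beta, kin)

  # dark / zero-light short circuit: no iteration needed
  if (env$Qa <= 0 && pft$pathway == "C3") {
    An <- -b$Rl
    gs <- pft$g0
    Ci <- env$Ca - 1.6 * An / gs
    return(structure(list(An = An, gs = gs, gm = NA_real_, Ci = Ci, Cx = Ci,
                          limitation = "rubp", iterations = 0L, residual = 0,
                          factors = NULL, beta = beta), class = "leaf_solution"))
  }

  gs_stress <- beta^pft$qs
  gm_at <- function(Ci) {
    if (!is.null(gm_override)) {
      return(list(gm = gm_override, f1 = NA, f2 = NA, f3 = NA, f4 = NA, f5 = NA))
    }
    if (version$name == "Imp") {
      list(gm = Inf, f1 = NA, f2 = NA, f3 = NA, f4 = NA, f5 = NA)
    } else {
      gm_effective(pft, env, cumulative_lai, version, soil, gmt, Ci = Ci)
    }
  }
  step <- function(Ci) {
    fac <- gm_at(Ci)
    sol <- solve_an_at_ci(Ci, fac$gm, b, pft$pathway)
    gs <- pft$g0 + gs_stress *
      (medlyn_gs(sol$An, env$Ca, env$D, 0, pft$g1))
    gs <- max(gs, pft$g0)
    Ci_new <- env$Ca - 1.6 * sol$An / gs
    list(Ci_new = Ci_new, sol = sol, gs = gs, fac = fac)
  }

  Ci <- 0.7 * env$Ca
  damp <- 0.5
  it <- 0L
  converged <- FALSE
  st <- NULL
  while (it < 50L) {
    it <- it + 1L
    st <- step(Ci)
    dCi <- st$Ci_new - Ci
    if (abs(dCi) < 1e-4) { converged <- TRUE; break }
    Ci <- Ci + damp * dCi
    Ci <- max(Ci, 1e-3)
  }
  if (!converged) {
    # bracketed fallback on the fixed-point residual
    g <- function(ci) step(ci)$Ci_new - ci
    lo <- max(b$kinetics$GammaStar25, 1e-3)
    hi <- env$Ca * 3
    root <- tryCatch(stats::uniroot(g, c(lo, hi), tol = 1e-6),
                     error = function(e) NULL)
    if (is.null(root))
      stop(sprintf("leaf solver failed to converge (last dCi = %.3g)",
                   st$Ci_new - Ci))
    Ci <- root$root
    st <- step(Ci)
    it <- it + as.integer(root$iter)
    converged <- TRUE
  } else {
    Ci <- st$Ci_new
    st <- step(Ci)
  }
  residual <- abs(st$Ci_new - Ci) * st$gs / 1.6
  structure(list(An = st$sol$An, gs = st$gs, gm = st$fac$gm, Ci = Ci,
                 Cx = st$sol$Cx, limitation = st$sol$limitation,
                 iterations = it, residual = residual,
                 factors = st$fac, beta = beta),
            class = "leaf_solution")
}

#' Relative CO2 response
#'
#' Percent change of a flux or conductance between an ambient and an elevated
#' CO2 run: \code{(x_elevated - x_ambient) / x_ambient * 100}.
#'
#' @param x_ambient,x_elevated The quantity under ambient and elevated CO2.
#' @return Percent change.
#' @export
co2_response <- function(x_ambient, x_elevated) {
  if (any(x_ambient == 0)) stop("CO2 response undefined for zero ambient value")
  (x_elevated - x_ambient) / x_ambient * 100
}

#' CO2 sensitivity of an An-Ci curve over paired Ci windows
#'
#' Compares mean net assimilation over the ambient-CO2 operating range of Ci
#' (240-320 umol/mol, i.e. 0.6-0.8 of Ca = 400) with the mean over the
#' elevated range (360-480, i.e. 0.6-0.8 of Ca = 600), as a percent change.
#' Means are uniform over an evenly spaced Ci grid obtained by linear
#' interpolation of the curve.
#'
#' @param curve A data frame with columns \code{ci} and \code{an} spanning at
#'   least 240-480 umol/mol (see \code{\link{simulate_anci}}).
#' @param ambient_range,elevated_range Ci windows (umol/mol).
#' @param n Number of interpolation points per window.
#' @return Percent change of mean An between the two windows.
#' @export
delta_an_ci_ranges <- function(curve, ambient_range = c(240, 320),
                               elevated_range = c(360, 480), n = 81) {
  if (min(curve$ci) > ambient_range[1] || max(curve$ci) < elevated_range[2])
    stop("curve does not span the required Ci range")
  mean_win <- function(r) {
    grid <- seq(r[1], r[2], length.out = n)
    mean(stats::approx(curve$ci, curve$an, xout = grid)$y)
  }
  co2_response(mean_win(ambient_range), mean_win(elevated_range))
}
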