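#' Leaf biochemical state
#'
#' Bundles the capacities and kinetic constants needed to evaluate net
#' assimilation at a given CO2 concentration at the carboxylation site.
#'
#' @param Vcmax Carboxylation capacity at leaf temperature (umol m-2 s-1).
#' @param J Realized electron transport rate (umol m-2 s-1); \code{Inf} for a
#'   purely enzyme-limited (saturating light) evaluation, \code{NA} if the
#'   RuBP-regeneration branch is not represented (some C4 setups).
#' @param Vpmax PEP carboxylation capacity (umol m-2 s-1; C4 only).
#' @param Rl Day respiration (umol m-2 s-1).
#' @param kinetics A \code{rubisco_kinetics} object (see
#'   \code{\link{resolve_kinetics}}).
#' @param Kp PEP carboxylase Michaelis constant for CO2 (umol/mol; C4).
#' @return Object of class \code{leaf_biochem}.
#' @export
leaf_biochem <- function(Vcmax, J = Inf, Vpmax = NA_real_, Rl = 0,
                         kinetics = resolve_kinetics("Exp")$kinetics,
                         Kp = 80) {
  stopifnot(Vcmax >= 0, Rl >= 0)
  structure(list(Vcmax = Vcmax, J = J, Vpmax = Vpmax, Rl = Rl,
                 kinetics = kinetics, Kp = Kp), class = "leaf_biochem")
}

#' Realized electron transport rate
#'
#' Smaller root of the non-rectangular hyperbola
#' \code{theta * J^2 - (alpha*Qa + Jmax) * J + alpha*Qa*Jmax = 0}.
#'
#' @param Qa Absorbed PPFD (umol m-2 s-1).
#' @param Jmax Maximum electron transport rate (umol m-2 s-1).
#' @param alpha Quantum yield of electron transport (mol e- / mol photons).
#' @param theta_curv Curvature parameter in (0, 1].
#' @return J (umol m-2 s-1); 0 in darkness, approaching \code{Jmax} at
#'   saturating light.
#' @export
electron_transport <- function(Qa, Jmax, alpha = 0.3, theta_curv = 0.7) {
  if (any(Qa < 0)) stop("Qa must be non-negative")
  if (theta_curv <= 0 || theta_curv > 1)
    stop("theta_curv must lie in (0, 1]")
  b <- alpha * Qa + Jmax
  (b - sqrt(b^2 - 4 * theta_curv * alpha * Qa * Jmax)) / (2 * theta_curv)
}

.rate_bundle <- function(Ac, Aj, Ap = NA_real_) {
  rates <- c(rubisco = Ac, rubp = Aj, pep = Ap)
  ok <- !is.na(rates)
  An <- min(rates[ok])
  # tie or joint minimum resolves to rubisco first (declaration order)
  lim <- names(rates[ok])[which.min(rates[ok])]
  list(Ac = Ac, Aj = Aj, Ap = Ap, An = An, limitation = lim)
}

#' C3 net assimilation at a known carboxylation-site CO2
#'
#' Farquhar-type two-state model: the Rubisco-limited rate
#' \code{Vcmax * (Cx - GammaStar) / (Cx + Kc * (1 + O/Ko))} and the
#' RuBP-regeneration-limited rate \code{J * (Cx - GammaStar) / (4*Cx +
#' 8*GammaStar)}, each minus day respiration; net assimilation is their
#' minimum. The O2 mole fraction is fixed at 210 mmol/mol.
#'
#' @param Cx CO2 mole fraction at the carboxylation site (umol/mol): Ci under
#'   the implicit treatment of gm, Cc under the explicit one.
#' @param b A \code{\link{leaf_biochem}} object.
#' @return List with \code{Ac}, \code{Aj}, \code{An} (umol m-2 s-1) and
#'   \code{limitation} (\code{"rubisco"} or \code{"rubp"}).
#' @export
c3_rates <- function(Cx, b) {
  if (any(Cx < 0)) stop("Cx must be non-negative")
  k <- b$kinetics
  Km <- k$Kc25 * (1 + .O2 / k$Ko25)
  Ac <- b$Vcmax * (Cx - k$GammaStar25) / (Cx + Km) - b$Rl
  Aj <- if (is.infinite(b$J)) rep(Inf, length(Cx)) else
    b$J * (Cx - k$GammaStar25) / (4 * Cx + 8 * k$GammaStar25) - b$Rl
  if (length(Cx) > 1L) {
    An <- pmin(Ac, Aj)
    lim <- ifelse(Ac <= Aj, "rubisco", "rubp")
    list(Ac = Ac, Aj = Aj, An = An, limitation = lim)
  } else .rate_bundle(Ac, if (is.infinite(b$J) && is.infinite(Aj)) NA_real_ else Aj)
}

#' C4 net assimilation at a known mesophyll-cytosol CO2
#'
#' Reduced von Caemmerer-Furbank enzyme-limited model: the PEP-limited initial
#' slope \code{Cm * Vpmax / (Cm + Kp)}, the CO2-saturated Rubisco rate
#' \code{Vcmax}, and (when J is finite) a light-limited rate \code{J/6}, each
#' minus day respiration. Bundle-sheath leakage is neglected; gm here spans
#' only the intercellular-airspace-to-cytosol segment.
#'
#' @param Cm Mesophyll cytosol CO2 mole fraction (umol/mol).
#' @param b A \code{\link{leaf_biochem}} object with \code{Vpmax} set.
#' @return List with \code{Ac}, \code{Aj}, \code{Ap}, \code{An}
#'   (umol m-2 s-1) and \code{limitation}.
#' @export
c4_rates <- function(Cm, b) {
  if (any(Cm < 0)) stop("Cm must be non-negative")
  if (!is.finite(b$Vpmax)) stop("C4 rates require Vpmax")
  Ap <- Cm * b$Vpmax / (Cm + b$Kp) - b$Rl
  Ac <- b$Vcmax - b$Rl
  Aj <- if (is.infinite(b$J) || is.na(b$J)) NA_real_ else b$J / 6 - b$Rl
  if (length(Cm) > 1L) {
    An <- pmin(Ap, Ac, if (is.na(Aj)) Inf else Aj)
    lim <- ifelse(Ac <= An + 1e-12 & Ac <= Ap, "rubisco",
                  ifelse(Ap <= An + 1e-12, "pep", "rubp"))
    list(Ac = Ac, Aj = Aj, Ap = Ap, An = An, limitation = lim)
  } else .rate_bundle(Ac, Aj, Ap)
}

# Solve An for one hyperbolic limitation state with finite gm:
#   An = a * (Cx - gamma) / (Cx + bcoef) - Rl,  Cx = Ci - An/gm
# Quadratic in An (Ethier & Livingston form); returns the root with
# Cx in [0, Ci], or NA if none.
.solve_state_quad <- function(Ci, gm, a, bcoef, gamma, Rl) {
  if (is.infinite(gm)) {
    An <- a * (Ci - gamma) / (Ci + bcoef) - Rl
    return(list(An = An, Cx = Ci))
  }
  # substitute Cx = Ci - An/gm into (An+Rl)(Cx+bcoef) = a(Cx-gamma):
  #   (1/gm) An^2 - (Ci + bcoef + (a-Rl)/gm) An + a(Ci-gamma) - Rl(Ci+bcoef) = 0
  qa <- 1 / gm
  qb <- -(Ci + bcoef + (a - Rl) / gm)
  qc <- a * (Ci - gamma) - Rl * (Ci + bcoef)
  disc <- qb^2 - 4 * qa * qc
  if (disc < 0) return(list(An = NA_real_, Cx = NA_real_))
  # the smaller root is physical; the larger lies beyond the Cx = -bcoef pole.
  # Cx may exceed Ci only when An < 0 (CO2 diffusing out below compensation).
  for (An in sort(c((-qb - sqrt(disc)) / (2 * qa),
                    (-qb + sqrt(disc)) / (2 * qa)))) {
    Cx <- Ci - An / gm
    if (Cx >= -1e-9 && (Cx <= Ci + 1e-9 || An < 0))
      return(list(An = An, Cx = max(0, Cx)))
  }
  list(An = NA_real_, Cx = NA_real_)
}

#' Net assimilation at a given intercellular CO2 with finite gm
#'
#' Substitutes Fick's first law \code{Cx = Ci - An/gm} into each limitation
#' state's rate equation and solves the resulting quadratic, keeping per state
#' the root with \code{Cx} in \code{[0, Ci]}; net assimilation is the minimum
#' over states. With \code{gm = Inf} this reduces exactly to evaluating
#' \code{\link{c3_rates}} / \code{\link{c4_rates}} at \code{Ci}.
#'
#' @param Ci Intercellular CO2 (umol/mol).
#' @param gm Mesophyll conductance (mol m-2 s-1); \code{Inf} for the implicit
#'   (infinite-conductance) treatment.
#' @param b A \code{\link{leaf_biochem}} object.
#' @param pathway \code{"C3"} or \code{"C4"}.
#' @return List with \code{An} (umol m-2 s-1), \code{Cx} (umol/mol, the
#'   carboxylation-site CO2 consistent with \code{An}) and \code{limitation}.
#' @export
solve_an_at_ci <- function(Ci, gm, b, pathway = c("C3", "C4")) {
  pathway <- match.arg(pathway)
  stopifnot(Ci >= 0, gm > 0)
  k <- b$kinetics
  if (pathway == "C3") {
    states <- list(
      rubisco = .solve_state_quad(Ci, gm, b$Vcmax,
                                  k$Kc25 * (1 + .O2 / k$Ko25),
                                  k$GammaStar25, b$Rl))
    if (is.finite(b$J))
      states$rubp <- .solve_state_quad(Ci, gm, b$J / 4, 2 * k$GammaStar25,
                                       k$GammaStar25, b$Rl)
  } else {
    states <- list(
      pep = .solve_state_quad(Ci, gm, b$Vpmax, b$Kp, 0, b$Rl),
      rubisco = list(An = b$Vcmax - b$Rl,
                     Cx = if (is.infinite(gm)) Ci
                          else max(0, Ci - (b$Vcmax - b$Rl) / gm)))
    if (is.finite(b$J) && !is.na(b$J))
      states$rubp <- list(An = b$J / 6 - b$Rl,
                          Cx = max(0, Ci - (b$J / 6 - b$Rl) / gm))
  }
  an <- vapply(states, function(s) s$An, numeric(1))
  if (all(is.na(an)))
    stop(sprintf("no admissible root with Cx in [0, Ci] (Ci=%.3g, gm=%.3g)",
                 Ci, gm))
  # prefer rubisco on ties, per declaration order of `states`
  ord <- order(an, na.last = TRUE)
  best <- ord[1]
  nm <- names(states)[best]
  # canonical tie-break: rubisco first
  ties <- which(abs(an - an[best]) < 1e-12)
  if (length(ties) > 1 && "rubisco" %in% names(states)[ties]) nm <- "rubisco"
  list(An = an[[nm]], Cx = states[[nm]]$Cx, limitation = nm)
}
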