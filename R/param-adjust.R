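#' Simulate an An-Ci demand curve at reference conditions
#'
#' Step 1 of the apparent-to-true parameter adjustment: a PFT-specific An-Ci
#' curve is generated with the implicit (infinite gm, Ci-based) photosynthesis
#' routine under unstressed conditions, saturating light and 25 degC.
#'
#' @param Vcmax25_ci,Jmax25_ci Apparent (Ci-based) capacities (umol m-2 s-1).
#' @param Rl Day respiration (umol m-2 s-1), held fixed throughout the
#'   adjustment.
#' @param kinetics Ci-based \code{rubisco_kinetics}.
#' @param grid Ci grid (umol/mol); default 40-1500 in 5 umol/mol steps.
#' @return Data frame of class \code{an_ci_curve} with columns \code{ci},
#'   \code{an}, \code{cx} (equal to \code{ci} here) and \code{limitation}.
#' @export
simulate_anci <- function(Vcmax25_ci, Jmax25_ci, Rl,
                          kinetics = resolve_kinetics("Imp")$kinetics,
                          grid = seq(40, 1500, by = 5)) {
  if (kinetics$basis != "Ci")
    stop("the demand curve must be simulated with Ci-based kinetics")
  if (min(grid) < 0 || max(grid) > 2000)
    stop("Ci grid must lie within [0, 2000] umol/mol")
  b <- leaf_biochem(Vcmax = Vcmax25_ci, J = Jmax25_ci, Rl = Rl,
                    kinetics = kinetics)
  r <- c3_rates(grid, b)
  structure(data.frame(ci = grid, an = r$An, cx = grid,
                       limitation = r$limitation),
            class = c("an_ci_curve", "data.frame"))
}

#' Convert an An-Ci curve to an An-Cc curve via Fick's first law
#'
#' Step 2 of the adjustment: \code{Cc = Ci - An/gm} per point. gm is either
#' constant at \code{gm_max25}, or, when the model version carries a Ci
#' response, varies along the curve as \code{gm_max25 * f4(Ci) / f4(260)}
#' (the published gm maxima are standardized to Ci = 260 umol/mol, so the Ci
#' factor is applied as a ratio).
#'
#' @param curve An \code{an_ci_curve} from \code{\link{simulate_anci}}.
#' @param gm_max25 Mesophyll conductance (mol m-2 s-1); \code{Inf} leaves the
#'   curve unchanged.
#' @param use_ci_response Apply the Ci response of gm along the curve?
#' @param fmin Minimum relative gm for the f4 factor.
#' @param ci_norm Standardization Ci of the gm values (umol/mol).
#' @return The curve with \code{cx} replaced by Cc and an extra \code{gm}
#'   column.
#' @export
to_cc_curve <- function(curve, gm_max25, use_ci_response = FALSE,
                        fmin = 0.15, ci_norm = 260) {
  stopifnot(gm_max25 > 0)
  gm <- if (use_ci_response)
    gm_max25 * f_ci(curve$ci, fmin) / f_ci(ci_norm, fmin)
  else rep(gm_max25, nrow(curve))
  cc <- curve$ci - curve$an / gm
  bad <- which(cc < 0)
  if (length(bad))
    stop(sprintf("negative Cc at Ci = %g umol/mol: gm too small for this curve",
                 curve$ci[bad[1]]))
  out <- curve
  out$cx <- cc
  out$gm <- gm
  out
}

#' Refit Vcmax25 and Jmax25 on the Cc basis
#'
#' Step 3 of the adjustment: simultaneous least-squares fit of the two-state
#' C3 model, with Cc-based Rubisco kinetics, to the An-Cc curve from step 2.
#' Residuals are equally weighted; day respiration is held at its input value;
#' the optimizer is bounded Levenberg-Marquardt initialized at the Ci-based
#' values.
#'
#' @param cc_curve Curve from \code{\link{to_cc_curve}}.
#' @param kinetics Cc-based \code{rubisco_kinetics}.
#' @param init Named vector or list with the Ci-based starting values
#'   \code{Vcmax25} and \code{Jmax25}.
#' @param Rl Day respiration (umol m-2 s-1), fixed.
#' @return List of class \code{adjustment_result}: \code{Vcmax25_cc},
#'   \code{Jmax25_cc}, \code{ratio_cc} (Jmax/Vcmax), \code{rmse}
#'   (umol m-2 s-1) and the Ci grid used.
#' @export
fit_cc_params <- function(cc_curve, kinetics, init, Rl) {
  if (kinetics$basis != "Cc")
    stop("refitting requires Cc-based kinetics")
  v0 <- init[["Vcmax25"]]; j0 <- init[["Jmax25"]]
  stopifnot(v0 > 0, j0 > 0)
  resid_fn <- function(p) {
    b <- leaf_biochem(Vcmax = p[1], J = p[2], Rl = Rl, kinetics = kinetics)
    c3_rates(cc_curve$cx, b)$An - cc_curve$an
  }
  fit <- minpack.lm::nls.lm(par = c(v0, j0), fn = resid_fn,
                            lower = c(1e-6, 1e-6), upper = c(10 * v0, 10 * j0),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info == 0 || fit$info == 9)
    stop("nonlinear refit failed to converge: ", fit$message)
  p <- fit$par
  if (any(p <= 0)) stop("refit produced non-positive parameter estimates")
  structure(list(Vcmax25_cc = p[1], Jmax25_cc = p[2],
                 ratio_cc = p[2] / p[1],
                 rmse = sqrt(mean(fit$fvec^2)),
                 ci_grid = cc_curve$ci), class = "adjustment_result")
}

#' Three-step C3 parameter adjustment
#'
#' Convenience wrapper running \code{\link{simulate_anci}},
#' \code{\link{to_cc_curve}} and \code{\link{fit_cc_params}} with a shared
#' configuration: simulate the apparent An-Ci curve at 25 degC and saturating
#' light, convert it to the Cc basis with the PFT's gm, and refit the
#' capacities with true (Cc-based) kinetics.
#'
#' @param Vcmax25_ci,Jmax25_ci Apparent capacities (umol m-2 s-1).
#' @param gm_max25 Mesophyll conductance (mol m-2 s-1).
#' @param Rl Day respiration (umol m-2 s-1); default \code{0.011 * Vcmax25_ci}.
#' @param use_ci_response Carry the Ci response of gm along the curve
#'   (ExpC/ExpCL-style adjustment)?
#' @param fmin Minimum relative gm.
#' @param grid Ci grid for step 1.
#' @param kinetics_file Optional alternative kinetics parameter file.
#' @return An \code{adjustment_result} (see \code{\link{fit_cc_params}}).
#' @examples
#' adjust_c3(40, 76, gm_max25 = 0.1, Rl = 0.44)
#' @export
adjust_c3 <- function(Vcmax25_ci, Jmax25_ci, gm_max25,
                      Rl = 0.011 * Vcmax25_ci, use_ci_response = FALSE,
                      fmin = 0.15, grid = seq(40, 1500, by = 5),
                      kinetics_file = NULL) {
  kin_ci <- resolve_kinetics("Imp", file = kinetics_file)$kinetics
  kin_cc <- resolve_kinetics("Exp", file = kinetics_file)$kinetics
  curve <- simulate_anci(Vcmax25_ci, Jmax25_ci, Rl, kin_ci, grid)
  cc <- to_cc_curve(curve, gm_max25, use_ci_response, fmin)
  fit_cc_params(cc, kin_cc, init = c(Vcmax25 = Vcmax25_ci,
                                     Jmax25 = Jmax25_ci), Rl = Rl)
}

#' C4 parameter adjustment (Vpmax on the Cm basis)
#'
#' In the reduced von Caemmerer-Furbank model the only parameter affected by
#' the explicit treatment of gm is the maximum PEP carboxylation rate, which
#' governs the initial (low-Ci) slope of the An-Ci curve. The apparent curve
#' is simulated over a low-Ci grid with \code{An = min(Ci Vpmax / (Ci + Kp),
#' Vcmax) - Rl}, converted to the mesophyll-cytosol basis via
#' \code{Cm = Ci - An/gm}, and Vpmax is refitted by least squares with the
#' other branches unchanged (they are independent of the site CO2 and need no
#' adjustment).
#'
#' @param Vpmax25_ci Apparent PEP carboxylation capacity (umol m-2 s-1).
#' @param gm_max25 Mesophyll conductance (mol m-2 s-1).
#' @param Kp PEP carboxylase Michaelis constant (umol/mol).
#' @param Rl Day respiration (umol m-2 s-1).
#' @param Vcmax25 CO2-saturated Rubisco capacity; defaults to
#'   \code{Vpmax25_ci / 2}, the standard ratio between the two capacities in
#'   the C4 model.
#' @param grid Ci grid covering the PEP-limited branch (umol/mol).
#' @return List of class \code{adjustment_result} with \code{Vpmax25_cm},
#'   \code{rmse} and the grid.
#' @examples
#' adjust_c4(60, gm_max25 = 0.739)
#' @export
adjust_c4 <- function(Vpmax25_ci, gm_max25, Kp = 80, Rl = 0,
                      Vcmax25 = Vpmax25_ci / 2,
                      grid = seq(20, 150, by = 5)) {
  stopifnot(Vpmax25_ci > 0, gm_max25 > 0)
  an <- pmin(Vpmax25_ci * grid / (grid + Kp), Vcmax25) - Rl
  cm <- grid - an / gm_max25
  if (any(cm < 0))
    stop("negative Cm: gm too small for the PEP-limited branch")
  resid_fn <- function(p)
    (pmin(p[1] * cm / (cm + Kp), Vcmax25) - Rl) - an
  fit <- minpack.lm::nls.lm(par = Vpmax25_ci, fn = resid_fn,
                            lower = 1e-6, upper = 50 * Vpmax25_ci)
  if (fit$info == 0 || fit$info == 9)
    stop("C4 refit failed to converge: ", fit$message)
  structure(list(Vpmax25_cm = fit$par[1],
                 rmse = sqrt(mean(fit$fvec^2)),
                 ci_grid = grid), class = "adjustment_result")
}

#' Adjust a whole PFT registry from the Ci to the Cc basis
#'
#' Applies \code{\link{adjust_c3}} / \code{\link{adjust_c4}} to every entry of
#' a registry and returns a table in the layout of a published parameter
#' table: apparent values, adjusted values and their ratio.
#'
#' @param registry Named list of \code{pft_params} (see
#'   \code{\link{load_pft_registry}}).
#' @param use_ci_response Adjust for the ExpC-style gm (uses the
#'   Ci-260-standardized gm column of the registry when present).
#' @param ... Passed on to the adjustment functions.
#' @return Data frame with one row per PFT.
#' @export
adjust_pft_table <- function(registry, use_ci_response = FALSE, ...) {
  rows <- lapply(registry, function(p) {
    gm <- if (use_ci_response && !is.null(p$gm_max25_ci260))
      p$gm_max25_ci260 else p$gm_max25
    if (p$pathway == "C3") {
      a <- adjust_c3(p$Vcmax25, p$Jmax25, gm,
                     Rl = p$Rl_frac * p$Vcmax25,
                     use_ci_response = use_ci_response, fmin = p$fmin, ...)
      data.frame(pft = p$pft, pathway = "C3", gm_max25 = gm,
                 Vcmax25_Ci = p$Vcmax25, Jmax25_Ci = p$Jmax25,
                 Vcmax25_Cc = a$Vcmax25_cc, Jmax25_Cc = a$Jmax25_cc,
                 ratio_Cc = a$ratio_cc, Vpmax25_Cm = NA_real_, rmse = a$rmse)
    } else {
      a <- adjust_c4(p$Vpmax25, gm, ...)
      data.frame(pft = p$pft, pathway = "C4", gm_max25 = gm,
                 Vcmax25_Ci = p$Vcmax25, Jmax25_Ci = NA_real_,
                 Vcmax25_Cc = NA_real_, Jmax25_Cc = NA_real_,
                 ratio_Cc = NA_real_, Vpmax25_Cm = a$Vpmax25_cm, rmse = a$rmse)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Adjust one PFT's parameters for use in an explicit-gm run
#'
#' Returns a copy of the PFT parameters with capacities replaced by their
#' Cc/Cm-based refits (and the basis tag updated), suitable for passing to
#' \code{\link{solve_leaf}} or the canopy simulators under an explicit model
#' version.
#'
#' @param pft A \code{pft_params} with Ci-based capacities.
#' @param version Model version the parameters are adjusted for (determines
#'   whether the Ci response of gm enters the adjustment).
#' @param gm_max25 Override the gm used in the adjustment and stored on the
#'   returned object (used by sensitivity sweeps).
#' @param ... Passed to the adjustment functions.
#' @return A \code{pft_params} on the Cc basis.
#' @export
adjust_pft <- function(pft, version = model_version("Exp"),
                       gm_max25 = NULL, ...) {
  if (is.character(version)) version <- model_version(version)
  if (pft$basis == "Cc") return(pft)
  gm <- if (!is.null(gm_max25)) gm_max25 else pft$gm_max25
  out <- pft
  if (pft$pathway == "C3") {
    a <- adjust_c3(pft$Vcmax25, pft$Jmax25, gm,
                   Rl = pft$Rl_frac * pft$Vcmax25,
                   use_ci_response = version$use_ci_response,
                   fmin = pft$fmin, ...)
    # keep absolute Rl unchanged: re-express as a fraction of the new Vcmax25
    out$Rl_frac <- pft$Rl_frac * pft$Vcmax25 / a$Vcmax25_cc
    out$Vcmax25 <- a$Vcmax25_cc
    out$Jmax25 <- a$Jmax25_cc
  } else {
    a <- adjust_c4(pft$Vpmax25, gm, ...)
    out$Vpmax25 <- a$Vpmax25_cm
  }
  out$gm_max25 <- gm
  out$basis <- "Cc"
  out
}
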