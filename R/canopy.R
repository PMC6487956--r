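#' Vertical canopy profile with sun/shade partitioning
#'
#' Splits the canopy into equal-LAI layers; photosynthetic capacity and
#' gm share the nitrogen extinction profile \code{exp(-kn * L)} evaluated at
#' layer midpoints, and the sunlit fraction follows beam extinction
#' \code{exp(-kb * L)} with \code{kb = 0.5 / cos(zenith)}.
#'
#' @param lai_total Total canopy leaf area index (> 0).
#' @param n_layers Number of layers (default 9).
#' @param kn Nitrogen extinction coefficient.
#' @param solar_zenith Solar zenith angle (degrees); at or beyond 90 the
#'   canopy is entirely shaded.
#' @return List of class \code{canopy_profile}: \code{layer_lai},
#'   \code{cum_lai_mid}, \code{scale_n}, \code{sunlit_frac}.
#' @export
build_profile <- function(lai_total, n_layers = 9, kn = 0.11,
                          solar_zenith = 30) {
  stopifnot(lai_total > 0, n_layers >= 1)
  layer_lai <- rep(lai_total / n_layers, n_layers)
  cum_mid <- (seq_len(n_layers) - 0.5) * lai_total / n_layers
  scale_n <- exp(-kn * cum_mid)
  if (solar_zenith >= 90) {
    sunlit <- rep(0, n_layers)
    kb <- Inf
  } else {
    kb <- 0.5 / cos(solar_zenith * pi / 180)
    sunlit <- exp(-kb * cum_mid)
  }
  structure(list(lai_total = lai_total, n_layers = n_layers,
                 layer_lai = layer_lai, cum_lai_mid = cum_mid,
                 scale_n = scale_n, sunlit_frac = sunlit, kb = kb, kn = kn),
            class = "canopy_profile")
}

# absorbed PPFD on sunlit and shaded leaves at cumulative LAI L for
# above-canopy PPFD Q0 with diffuse fraction fd; simplified attenuation with
# a fixed diffuse extinction coefficient.
.layer_light <- function(Q0, L, kb, fd = 0.3, kd = 0.5) {
  q_shade <- fd * Q0 * exp(-kd * L)
  q_sun <- if (is.infinite(kb)) q_shade else q_shade + (1 - fd) * Q0 * kb
  list(sun = q_sun, shade = q_shade)
}

#' Canopy-integrated assimilation and conductance
#'
#' Solves leaf gas exchange for the sunlit and shaded fraction of every layer
#' (direct plus diffuse vs diffuse-only light) and integrates over the LAI:
#' \code{An_canopy = sum(layer_lai * (fsun * An_sun + (1-fsun) * An_shade))},
#' likewise for the conductance.
#'
#' @param profile A \code{\link{build_profile}} object.
#' @param env Above-canopy \code{\link{env_state}} (its \code{Qa} is the
#'   incident PPFD).
#' @param pft A \code{\link{pft_params}} on the basis matching the version.
#' @param version Model version.
#' @param diffuse_frac Diffuse fraction of incident PPFD.
#' @param soil A \code{\link{soil_params}}.
#' @param gm_override Optional fixed gm (see \code{\link{solve_leaf}}).
#' @return List with \code{An_canopy} (umol m-2 ground s-1), \code{Gc}
#'   (mol m-2 ground s-1, water basis), and the LAI-weighted fraction of
#'   positive assimilation in each limitation state.
#' @export
canopy_flux <- function(profile, env, pft, version = model_version("Exp"),
                        diffuse_frac = 0.3, soil = soil_params(),
                        gm_override = NULL) {
  if (is.character(version)) version <- model_version(version)
  an_tot <- 0; gc_tot <- 0
  lim_w <- c(rubisco = 0, rubp = 0, pep = 0)
  for (i in seq_len(profile$n_layers)) {
    L <- profile$cum_lai_mid[i]
    light <- .layer_light(env$Qa, L, profile$kb, diffuse_frac)
    fs <- profile$sunlit_frac[i]
    for (part in c("sun", "shade")) {
      w <- profile$layer_lai[i] * if (part == "sun") fs else 1 - fs
      if (w <= 0) next
      env_l <- env_state(Tl = env$Tl, Qa = light[[part]], Ca = env$Ca,
                         D = env$D, theta = env$theta)
      sol <- solve_leaf(env_l, pft, version, cumulative_lai = L, soil = soil,
                        gm_override = gm_override)
      an_tot <- an_tot + w * sol$An
      gc_tot <- gc_tot + w * sol$gs
      if (sol$An > 0)
        lim_w[sol$limitation] <- lim_w[sol$limitation] + w * sol$An
    }
  }
  lim_frac <- if (sum(lim_w) > 0) lim_w / sum(lim_w) else lim_w
  list(An_canopy = an_tot, Gc = gc_tot, limitation_fractions = lim_frac)
}

#' Synthetic diurnal forcing generator
#'
#' Produces a half-hourly forcing series with sinusoidal PPFD and temperature
#' (temperature lagging solar noon by two hours), VPD derived from temperature
#' at fixed relative humidity anchored to the requested VPD at the daily
#' temperature maximum, optional linear soil dry-down, and small seeded
#' Gaussian perturbations on temperature and light.
#'
#' @param seed Integer RNG seed; the series is reproducible for a given seed
#'   and parameter set.
#' @param days Number of days.
#' @param Tmean Daily mean air (= leaf) temperature (degC).
#' @param Tamp Diurnal temperature range (degC).
#' @param Qmax Clear-sky maximum incident PPFD (umol m-2 s-1).
#' @param D_at_Tmax VPD at the daily temperature maximum (kPa).
#' @param Ca Atmospheric CO2 (umol/mol).
#' @param theta_start,theta_end Soil moisture at the start and end of the
#'   series (m); equal values give constant moisture.
#' @param dt Time step (hours).
#' @param sd_T,sd_Q Standard deviations of the Gaussian perturbations.
#' @return Data frame of class \code{forcing_series} with columns \code{time}
#'   (hours), \code{Tl}, \code{Qa}, \code{Ca}, \code{D}, \code{theta}.
#' @export
generate_forcing <- function(seed = 1, days = 2, Tmean = 20, Tamp = 8,
                             Qmax = 1800, D_at_Tmax = 1.5, Ca = 400,
                             theta_start = 0.3, theta_end = theta_start,
                             dt = 0.5, sd_T = 0.3, sd_Q = 30) {
  stopifnot(days >= 1, Qmax >= 0, Tamp >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  t <- seq(0, days * 24 - dt, by = dt)
  hod <- t %% 24
  q <- Qmax * pmax(0, sin(pi * (hod - 6) / 12))
  Tl <- Tmean + Tamp / 2 * sin(pi * (hod - 8) / 12)
  q <- pmax(0, q + stats::rnorm(length(t), 0, sd_Q) * (q > 0))
  Tl <- Tl + stats::rnorm(length(t), 0, sd_T)
  esat <- function(Tc) 0.6108 * exp(17.27 * Tc / (Tc + 237.3))
  Tmax <- Tmean + Tamp / 2
  rh <- max(0.05, 1 - D_at_Tmax / esat(Tmax))
  D <- pmax(0.05, esat(Tl) * (1 - rh))
  theta <- seq(theta_start, theta_end, length.out = length(t))
  structure(data.frame(time = t, Tl = Tl, Qa = q, Ca = Ca, D = D,
                       theta = theta),
            class = c("forcing_series", "data.frame"),
            seed = seed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# run a canopy series at one CO2 level; returns per-step An_canopy/Gc
.run_series <- function(forcing, pft, version, lai, dCO2 = 0,
                        n_layers = 9, soil = soil_params(),
                        solar_zenith = 30, gm_override = NULL) {
  profile <- build_profile(lai, n_layers, pft$kn, solar_zenith)
  n <- nrow(forcing)
  an <- numeric(n); gc <- numeric(n)
  lim <- matrix(0, n, 3, dimnames = list(NULL, c("rubisco", "rubp", "pep")))
  for (i in seq_len(n)) {
    env <- env_state(Tl = forcing$Tl[i], Qa = forcing$Qa[i],
                     Ca = forcing$Ca[i] + dCO2, D = forcing$D[i],
                     theta = forcing$theta[i])
    fl <- canopy_flux(profile, env, pft, version, soil = soil,
                      gm_override = gm_override)
    an[i] <- fl$An_canopy
    gc[i] <- fl$Gc
    lim[i, ] <- fl$limitation_fractions[colnames(lim)]
  }
  list(an = an, gc = gc, lim = lim)
}

#' Paired ambient/elevated-CO2 canopy experiment
#'
#' Runs the canopy model twice over the same forcing, differing only in
#' atmospheric CO2 (elevated = ambient + \code{dCO2}), and reports the
#' relative CO2 responses of time-integrated canopy assimilation, daytime-mean
#' canopy conductance, and intrinsic water-use efficiency, plus the
#' ambient-run limitation-state fractions. Daytime is defined as incident
#' PPFD above 200 umol m-2 s-1.
#'
#' @param forcing A \code{\link{generate_forcing}} data frame (or any data
#'   frame with the same columns).
#' @param pft A \code{pft_params}; adjusted to the Cc basis internally for
#'   explicit versions (via \code{\link{adjust_pft}}) if still Ci-based.
#' @param version Model version.
#' @param lai Canopy LAI.
#' @param dCO2 CO2 enrichment (umol/mol).
#' @param n_layers Canopy layers.
#' @param soil A \code{soil_params}.
#' @param solar_zenith Representative solar zenith angle (degrees).
#' @param gm_override Optional fixed gm passed to the leaf solver.
#' @return List of class \code{experiment_result} with the responses
#'   (percent), limitation fractions and the two run series.
#' @export
run_paired_co2 <- function(forcing, pft, version = model_version("Exp"),
                           lai = 3, dCO2 = 200, n_layers = 9,
                           soil = soil_params(), solar_zenith = 30,
                           gm_override = NULL) {
  if (is.character(version)) version <- model_version(version)
  if (version$name != "Imp" && pft$basis == "Ci" && is.null(gm_override))
    pft <- adjust_pft(pft, version)
  amb <- .run_series(forcing, pft, version, lai, 0, n_layers, soil,
                     solar_zenith, gm_override)
  ele <- .run_series(forcing, pft, version, lai, dCO2, n_layers, soil,
                     solar_zenith, gm_override)
  day <- forcing$Qa > 200
  an_a <- sum(amb$an); an_e <- sum(ele$an)
  gc_a <- mean(amb$gc[day]); gc_e <- mean(ele$gc[day])
  iwue_a <- an_a / gc_a; iwue_e <- an_e / gc_e
  w <- pmax(amb$an, 0)
  lim_frac <- colSums(amb$lim * w) / sum(w)
  structure(list(
    co2_response_an = co2_response(an_a, an_e),
    co2_response_gc = co2_response(gc_a, gc_e),
    co2_response_iwue = co2_response(iwue_a, iwue_e),
    limitation_fractions = lim_frac,
    ambient = amb, elevated = ele, daytime = day
  ), class = "experiment_result")
}

#' Sensitivity of the CO2 response to the magnitude of gm
#'
#' For each gm value, the photosynthetic capacities are re-adjusted to the Cc
#' basis with that gm and the paired ambient/elevated-CO2 experiment is rerun;
#' the implicit model run is included as the non-limiting reference.
#'
#' @param forcing Forcing series.
#' @param pft A \code{pft_params} with Ci-based capacities.
#' @param versions Character vector of explicit version names to sweep.
#' @param gm_values Decreasing vector of gm_max25 values (mol m-2 s-1).
#' @param ... Passed to \code{\link{run_paired_co2}}.
#' @return Data frame with one row per (version, gm): CO2 responses and the
#'   Rubisco-limited fraction.
#' @export
gm_sweep <- function(forcing, pft, versions = "Exp",
                     gm_values = c(10000, 0.3, 0.075), ...) {
  stopifnot(all(diff(gm_values) < 0))
  rows <- list()
  imp <- run_paired_co2(forcing, pft, model_version("Imp"), ...)
  rows[[1]] <- data.frame(version = "Imp", gm_max25 = Inf,
                          co2_response_an = imp$co2_response_an,
                          co2_response_gc = imp$co2_response_gc,
                          rubisco_fraction = imp$limitation_fractions[["rubisco"]])
  for (v in versions) {
    for (gm in gm_values) {
      adj <- adjust_pft(pft, model_version(v), gm_max25 = gm)
      res <- run_paired_co2(forcing, adj, model_version(v), ...)
      rows[[length(rows) + 1L]] <- data.frame(
        version = v, gm_max25 = gm,
        co2_response_an = res$co2_response_an,
        co2_response_gc = res$co2_response_gc,
        rubisco_fraction = res$limitation_fractions[["rubisco"]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
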