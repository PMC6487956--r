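# universal gas constant (J mol-1 K-1)
.Rgas <- 8.314
# reference temperature (K)
.Tref <- 298.15
# O2 mole fraction (mmol/mol), fixed package-wide
.O2 <- 210

#' Model version switches
#'
#' The package distinguishes one implicit and four explicit treatments of
#' mesophyll conductance. \code{Imp} assumes infinite gm and uses Ci-based
#' Rubisco kinetics and photosynthetic capacities; the explicit versions use
#' Cc-based parameters and differ only in whether gm responds to intercellular
#' CO2 (\code{ExpC}, \code{ExpCL}) and/or light (\code{ExpL}, \code{ExpCL}).
#' Temperature, soil-moisture and canopy-profile responses of gm are active in
#' all explicit versions.
#'
#' @param name One of \code{"Imp"}, \code{"Exp"}, \code{"ExpC"}, \code{"ExpL"},
#'   \code{"ExpCL"}.
#' @return An object of class \code{gm_version} with elements \code{name},
#'   \code{use_ci_response}, \code{use_light_response} and \code{kinetics_basis}
#'   (\code{"Ci"} or \code{"Cc"}).
#' @examples
#' model_version("ExpC")$use_ci_response
#' @export
model_version <- function(name = c("Imp", "Exp", "ExpC", "ExpL", "ExpCL")) {
  name <- match.arg(name)
  structure(list(
    name               = name,
    use_ci_response    = name %in% c("ExpC", "ExpCL"),
    use_light_response = name %in% c("ExpL", "ExpCL"),
    kinetics_basis     = if (name == "Imp") "Ci" else "Cc"
  ), class = "gm_version")
}

#' @export
print.gm_version <- function(x, ...) {
  cat(sprintf("<gm_version> %s (kinetics: %s-based; Ci response: %s; light response: %s)\n",
              x$name, x$kinetics_basis, x$use_ci_response, x$use_light_response))
  invisible(x)
}

.kinetics_file_default <- function() {
  system.file("extdata", "kinetics_params.csv", package = "gmphoto", mustWork = TRUE)
}

#' Rubisco kinetics and gm temperature parameters
#'
#' Returns the Rubisco kinetic constants (Kc, Ko, GammaStar at 25 degC and
#' their Arrhenius activation energies) consistent with the kinetics basis of a
#' model version, plus, for the explicit versions, the peaked-Arrhenius
#' parameters of the gm temperature response. The two constant sets are kept
#' strictly separate: apparent (Ci-based) kinetics for the implicit model,
#' true (Cc-based) kinetics for all explicit versions.
#'
#' Values are read from an editable parameter file
#' (\code{inst/extdata/kinetics_params.csv}) so they can be swapped against
#' other published sets without touching code.
#'
#' @param version A \code{gm_version}, or a version name.
#' @param file Optional path to an alternative parameter file with the same
#'   layout as the shipped one.
#' @return A list with \code{kinetics} (class \code{rubisco_kinetics}: Kc25
#'   (umol/mol), Ko25 (mmol/mol), GammaStar25 (umol/mol), Ea_Kc, Ea_Ko,
#'   Ea_GammaStar (J/mol), basis) and \code{gm_temp} (class \code{gm_temp_params}:
#'   Ha, Hd (J/mol), dS (J mol-1 K-1), Tref (K); \code{NULL} for \code{Imp}).
#' @export
resolve_kinetics <- function(version, file = NULL) {
  if (is.character(version)) version <- model_version(version)
  stopifnot(inherits(version, "gm_version"))
  if (is.null(file)) file <- .kinetics_file_default()
  key <- paste0(version$kinetics_basis, "|", normalizePath(file))
  hit <- .kin_cache[[key]]
  if (!is.null(hit)) return(hit)
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  basis <- version$kinetics_basis
  row <- tab[tab$set == paste0("rubisco_", basis), ]
  if (nrow(row) != 1L) stop("kinetics file lacks a unique 'rubisco_", basis, "' row")
  kin <- structure(list(
    Kc25 = row$Kc25, Ko25 = row$Ko25, GammaStar25 = row$GammaStar25,
    Ea_Kc = row$Ea_Kc, Ea_Ko = row$Ea_Ko, Ea_GammaStar = row$Ea_GammaStar,
    basis = basis
  ), class = "rubisco_kinetics")
  validate_kinetics(kin)
  gmt <- NULL
  if (basis == "Cc") {
    trow <- tab[tab$set == "gm_temperature", ]
    if (nrow(trow) != 1L) stop("kinetics file lacks a 'gm_temperature' row")
    gmt <- gm_temp_params(Ha = trow$Ha, Hd = trow$Hd, dS = trow$dS)
  }
  out <- list(kinetics = kin, gm_temp = gmt)
  .kin_cache[[key]] <- out
  out
}

# per-session cache of parsed kinetics files (keyed on basis and path)
.kin_cache <- new.env(parent = emptyenv())

validate_kinetics <- function(k) {
  num <- unlist(k[c("Kc25", "Ko25", "GammaStar25", "Ea_Kc", "Ea_Ko", "Ea_GammaStar")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("Rubisco kinetic constants must be strictly positive and finite")
  invisible(k)
}

#' Peaked-Arrhenius parameters of the gm temperature response
#'
#' @param Ha Activation energy (J/mol).
#' @param Hd Deactivation energy (J/mol); must exceed \code{Ha}.
#' @param dS Entropy term (J mol-1 K-1).
#' @param Tref Reference temperature (K).
#' @return An object of class \code{gm_temp_params}. The implied temperature
#'   optimum \code{Topt = Hd / (dS - R * log(Ha / (Hd - Ha)))} is stored as an
#'   attribute and must lie between 25 and 45 degC.
#' @export
gm_temp_params <- function(Ha = 49600, Hd = 437400, dS = 1400, Tref = .Tref) {
  stopifnot(Ha > 0, Hd > Ha, dS > 0)
  topt <- Hd / (dS - .Rgas * log(Ha / (Hd - Ha)))
  if (topt <= 298.15 || topt >= 318.15)
    stop(sprintf("implied gm temperature optimum %.1f K outside (25, 45) degC", topt))
  structure(list(Ha = Ha, Hd = Hd, dS = dS, Tref = Tref, Topt = topt),
            class = "gm_temp_params")
}

#' Soil moisture stress thresholds
#'
#' Wilting point and critical moisture are fixed fractions of field capacity;
#' stress is total below the former and absent above the latter.
#'
#' @param theta_fc Field capacity (m).
#' @param wilt_frac,crit_frac Fractions of field capacity defining the wilting
#'   point and the onset of stress.
#' @return List of class \code{soil_params} with \code{theta_wilt} and
#'   \code{theta_crit} resolved in metres.
#' @export
soil_params <- function(theta_fc = 0.3, wilt_frac = 0.32, crit_frac = 0.70) {
  stopifnot(theta_fc > 0, wilt_frac > 0, wilt_frac < crit_frac, crit_frac <= 1)
  structure(list(theta_fc = theta_fc,
                 theta_wilt = wilt_frac * theta_fc,
                 theta_crit = crit_frac * theta_fc),
            class = "soil_params")
}

.pft_codes <- c("DNF", "TDF", "ENF", "DSH", "EBF", "TRF",
                "DBF", "C3G", "RSH", "C3C", "C4G", "C4C")

#' Per-PFT physiological parameters
#'
#' Constructor with validation and defaults for one plant functional type.
#' Capacities are tagged with the basis on which they were estimated
#' (\code{"Ci"} for apparent values assuming infinite gm, \code{"Cc"} after
#' adjustment).
#'
#' @param pft One of the twelve PFT codes (\code{DNF}, \code{TDF}, \code{ENF},
#'   \code{DSH}, \code{EBF}, \code{TRF}, \code{DBF}, \code{C3G}, \code{RSH},
#'   \code{C3C}, \code{C4G}, \code{C4C}).
#' @param pathway \code{"C3"} or \code{"C4"}.
#' @param gm_max25 Unstressed mesophyll conductance at 25 degC (mol m-2 s-1).
#' @param Vcmax25 Maximum carboxylation rate at 25 degC (umol m-2 s-1).
#' @param Jmax25 Maximum electron transport rate (umol m-2 s-1; C3).
#' @param Vpmax25 Maximum PEP carboxylation rate (umol m-2 s-1; C4).
#' @param basis Basis tag of the capacities, \code{"Ci"} or \code{"Cc"}.
#' @param g1 Medlyn stomatal slope (kPa^0.5).
#' @param g0 Residual stomatal conductance (mol m-2 s-1).
#' @param fmin Minimum relative gm (dimensionless).
#' @param kn Canopy nitrogen extinction coefficient.
#' @param qm,qs,qb Soil-stress exponents for gm, gs and biochemistry.
#' @param Rl_frac Leaf day respiration as a fraction of Vcmax25.
#' @return Object of class \code{pft_params}.
#' @export
pft_params <- function(pft, pathway = c("C3", "C4"), gm_max25,
                       Vcmax25, Jmax25 = NA_real_, Vpmax25 = NA_real_,
                       basis = "Ci", g1 = 4, g0 = 0.005, fmin = 0.15,
                       kn = 0.11, qm = 0.75, qs = 0.50, qb = 0.25,
                       Rl_frac = 0.011) {
  pathway <- match.arg(pathway)
  if (!pft %in% .pft_codes) stop("unknown PFT code: ", pft)
  if (!is.finite(gm_max25) || gm_max25 <= 0)
    stop("gm_max25 must be positive (PFT ", pft, ")")
  stopifnot(fmin > 0, fmin < 1, qm >= qs, qs >= qb, g0 >= 0)
  if (pathway == "C3" && !is.finite(Jmax25))
    stop("C3 PFT ", pft, " requires Jmax25")
  if (pathway == "C4" && !is.finite(Vpmax25))
    stop("C4 PFT ", pft, " requires Vpmax25")
  structure(list(pft = pft, pathway = pathway, gm_max25 = gm_max25,
                 Vcmax25 = Vcmax25, Jmax25 = Jmax25, Vpmax25 = Vpmax25,
                 basis = basis, g1 = g1, g0 = g0, fmin = fmin, kn = kn,
                 qm = qm, qs = qs, qb = qb, Rl_frac = Rl_frac),
            class = "pft_params")
}

#' Load a PFT parameter registry
#'
#' Reads a CSV with one row per plant functional type (columns \code{pft},
#' \code{pathway}, \code{gm_max25}, \code{Vcmax25_Ci}, and optionally
#' \code{Jmax25_Ci}, \code{Vpmax25_Ci}, \code{g1}, \code{g0}, \code{fmin},
#' \code{kn}, \code{qm}, \code{qs}, \code{qb}, \code{Rl_frac},
#' \code{gm_max25_ci260}) and returns a named list of validated
#' \code{pft_params}. Omitted optional columns fall back to package defaults.
#'
#' The shipped registry (\code{inst/extdata/pft_registry.csv}) carries the
#' published PFT medians of gm_max25 and the Ci-based capacities; its g1
#' column and the C4G row are indicative defaults, not literature medians.
#'
#' @param source Path to the CSV; defaults to the shipped registry.
#' @return Named list of \code{pft_params}, one per row.
#' @export
load_pft_registry <- function(source = NULL) {
  if (is.null(source))
    source <- system.file("extdata", "pft_registry.csv", package = "gmphoto",
                          mustWork = TRUE)
  tab <- utils::read.csv(source, stringsAsFactors = FALSE)
  required <- c("pft", "pathway", "gm_max25", "Vcmax25_Ci")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("PFT registry is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  opt <- function(col, default) {
    if (col %in% names(tab)) ifelse(is.na(tab[[col]]), default, tab[[col]])
    else rep(default, nrow(tab))
  }
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    out[[i]] <- pft_params(
      pft = tab$pft[i], pathway = tab$pathway[i],
      gm_max25 = tab$gm_max25[i],
      Vcmax25 = tab$Vcmax25_Ci[i],
      Jmax25 = opt("Jmax25_Ci", NA_real_)[i],
      Vpmax25 = opt("Vpmax25_Ci", NA_real_)[i],
      basis = "Ci",
      g1 = opt("g1", 4)[i], g0 = opt("g0", 0.005)[i],
      fmin = opt("fmin", 0.15)[i], kn = opt("kn", 0.11)[i],
      qm = opt("qm", 0.75)[i], qs = opt("qs", 0.50)[i], qb = opt("qb", 0.25)[i],
      Rl_frac = opt("Rl_frac", 0.011)[i])
    if ("gm_max25_ci260" %in% names(tab) && is.finite(tab$gm_max25_ci260[i]))
      out[[i]]$gm_max25_ci260 <- tab$gm_max25_ci260[i]
  }
  names(out) <- tab$pft
  out
}

#' Write a PFT registry back to CSV
#'
#' Inverse of \code{\link{load_pft_registry}}; full numeric precision is
#' preserved so that a write/read round trip reproduces the parameter values
#' exactly.
#'
#' @param registry Named list of \code{pft_params}.
#' @param path Output CSV path.
#' @export
write_pft_registry <- function(registry, path) {
  rows <- lapply(registry, function(p) {
    data.frame(pft = p$pft, pathway = p$pathway, gm_max25 = p$gm_max25,
               Vcmax25_Ci = p$Vcmax25, Jmax25_Ci = p$Jmax25,
               Vpmax25_Ci = p$Vpmax25, g1 = p$g1, g0 = p$g0, fmin = p$fmin,
               kn = p$kn, qm = p$qm, qs = p$qs, qb = p$qb,
               Rl_frac = p$Rl_frac,
               gm_max25_ci260 = if (is.null(p$gm_max25_ci260)) NA_real_
                                else p$gm_max25_ci260)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(format(tab, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
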