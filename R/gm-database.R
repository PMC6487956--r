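#' Read a gm measurement table
#'
#' One row per leaf-level mesophyll-conductance measurement with columns
#' \code{species}, \code{pft}, \code{gm_meas} (mol m-2 s-1), \code{t_meas}
#' (degC) and optionally \code{qa_meas} (umol m-2 s-1), \code{ci_meas}
#' (umol/mol) and \code{method}.
#'
#' @param path CSV path.
#' @return Validated data frame of class \code{gm_records}.
#' @export
read_gm_records <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "pft", "gm_meas", "t_meas")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("gm record table missing column(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(tab$gm_meas)) || any(tab$gm_meas <= 0))
    stop("gm_meas must be positive")
  if (any(tab$t_meas < 0 | tab$t_meas > 45))
    stop("t_meas outside [0, 45] degC")
  if (!"qa_meas" %in% names(tab)) tab$qa_meas <- NA_real_
  if (!"ci_meas" %in% names(tab)) tab$ci_meas <- NA_real_
  structure(tab, class = c("gm_records", "data.frame"))
}

#' Standardize gm measurements to reference conditions
#'
#' Converts measured gm to the unstressed 25 degC maximum used by the model:
#' each value is divided by the temperature factor at the measurement
#' temperature, and additionally by the light factor ratio
#' \code{f5(qa_meas)/f5(qa_ref)} when the model version carries a light
#' response, and the Ci factor ratio \code{f4(ci_meas)/f4(ci_ref)} when it
#' carries a Ci response. Records lacking a field needed by an enabled
#' correction are dropped with a warning, never imputed.
#'
#' @param records A \code{gm_records} data frame.
#' @param version Model version controlling which corrections apply.
#' @param ci_ref Reference Ci (umol/mol).
#' @param qa_ref Reference PPFD (umol m-2 s-1).
#' @param fmin Minimum relative gm.
#' @param gm_temp A \code{\link{gm_temp_params}}.
#' @return The records with an added \code{gm_max25} column; dropped rows are
#'   excluded.
#' @export
standardize_records <- function(records, version = model_version("Exp"),
                                ci_ref = 260, qa_ref = 1500, fmin = 0.15,
                                gm_temp = gm_temp_params()) {
  if (is.character(version)) version <- model_version(version)
  g <- records$gm_meas / f_temperature(records$t_meas + 273.15, gm_temp)
  keep <- rep(TRUE, nrow(records))
  if (version$use_light_response) {
    ok <- is.finite(records$qa_meas)
    keep <- keep & ok
    g[ok] <- g[ok] / (f_light(records$qa_meas[ok], fmin) / f_light(qa_ref, fmin))
  }
  if (version$use_ci_response) {
    ok <- is.finite(records$ci_meas)
    keep <- keep & ok
    g[ok] <- g[ok] / (f_ci(records$ci_meas[ok], fmin) / f_ci(ci_ref, fmin))
  }
  if (any(!keep))
    warning(sum(!keep), " record(s) dropped: missing fields required by the ",
            version$name, " standardization")
  out <- records[keep, , drop = FALSE]
  out$gm_max25 <- g[keep]
  out
}

#' Aggregate standardized gm values to PFT-level statistics
#'
#' Median, mean and a bootstrap standard error of the median per PFT.
#'
#' @param records Data frame with \code{pft} and \code{gm_max25} columns (see
#'   \code{\link{standardize_records}}).
#' @param boot_n Number of bootstrap resamples for the SEM of the median.
#' @param seed RNG seed for the bootstrap.
#' @return Data frame with columns \code{pft}, \code{n}, \code{median},
#'   \code{mean}, \code{sem_median}.
#' @export
aggregate_pft <- function(records, boot_n = 10000, seed = 1) {
  if (!nrow(records)) stop("no records to aggregate")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  groups <- split(records$gm_max25, records$pft)
  rows <- lapply(names(groups), function(p) {
    x <- groups[[p]]
    sem <- if (length(x) > 1) {
      boots <- vapply(seq_len(boot_n),
                      function(i) stats::median(sample(x, replace = TRUE)),
                      numeric(1))
      stats::sd(boots)
    } else 0
    data.frame(pft = p, n = length(x), median = stats::median(x),
               mean = mean(x), sem_median = sem)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic gm measurement table
#'
#' Stands in for a literature compilation: per-PFT lognormal draws centered on
#' the registry medians with a spread typical of published gm compilations
#' (geometric SD about 1.6), measurement temperatures uniform in 20-30 degC,
#' and light/Ci metadata present for a configurable fraction of records.
#' Clearly synthetic; used by tests and examples only.
#'
#' @param registry PFT registry supplying the per-PFT medians.
#' @param n_per_pft Records per PFT.
#' @param seed RNG seed.
#' @param meta_frac Fraction of records carrying qa/ci metadata.
#' @return A \code{gm_records} data frame.
#' @export
simulate_gm_records <- function(registry = load_pft_registry(),
                                n_per_pft = 20, seed = 1, meta_frac = 0.7) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- lapply(registry, function(p) {
    g <- stats::rlnorm(n_per_pft, log(p$gm_max25), log(1.6))
    t <- stats::runif(n_per_pft, 20, 30)
    has_meta <- stats::runif(n_per_pft) < meta_frac
    data.frame(species = paste0(tolower(p$pft), "_sp",
                                seq_len(n_per_pft)),
               pft = p$pft, gm_meas = g * f_temperature(t + 273.15),
               t_meas = t,
               qa_meas = ifelse(has_meta,
                                stats::runif(n_per_pft, 800, 1800), NA),
               ci_meas = ifelse(has_meta,
                                stats::runif(n_per_pft, 200, 320), NA),
               method = "synthetic")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("gm_records", "data.frame"))
}
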