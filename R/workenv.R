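#' Facility exposure profile
#'
#' A facility profile states how workplace dose is distributed over photon
#' energy bands and over exposure geometries. Each fraction map must sum to
#' one. Presets for nuclear power plants (NPP: 0/10/90% over the 0-100,
#' 100-300 and 300-3000 keV bands; 50% AP / 50% ISO) and mixed-activities
#' facilities (MA: 0/20/80%; 50/50) are available via [facility_profiles()].
#'
#' @param name Profile label.
#' @param energy_fractions Named numeric vector over
#'   `band_0_100`, `band_100_300`, `band_300_3000`.
#' @param geometry_fractions Named numeric vector over `AP`, `ISO`, `ROT`.
#' @return Object of class `facility_profile`.
#' @export
facility_profile <- function(name, energy_fractions, geometry_fractions) {
  check_fractions <- function(x, what, keys) {
    if (!all(keys %in% names(x)))
      stop(what, " must be named over: ", paste(keys, collapse = ", "))
    x <- x[keys]
    if (any(x < 0) || any(x > 1))
      stop(what, " must lie in [0, 1]")
    if (abs(sum(x) - 1) > 1e-9)
      stop(what, " must sum to 1 (got ", sum(x), ")")
    x
  }
  structure(
    list(name = name,
         energy_fractions = check_fractions(
           energy_fractions, "'energy_fractions'",
           c("band_0_100", "band_100_300", "band_300_3000")),
         geometry_fractions = check_fractions(
           geometry_fractions, "'geometry_fractions'",
           c("AP", "ISO", "ROT"))),
    class = "facility_profile")
}

#' Preset facility profiles
#'
#' @return Named list of [facility_profile()] objects `NPP` and `MA`.
#' @export
facility_profiles <- function() {
  list(
    NPP = facility_profile(
      "NPP",
      c(band_0_100 = 0, band_100_300 = 0.10, band_300_3000 = 0.90),
      c(AP = 0.50, ISO = 0.50, ROT = 0)),
    MA = facility_profile(
      "MA",
      c(band_0_100 = 0, band_100_300 = 0.20, band_300_3000 = 0.80),
      c(AP = 0.50, ISO = 0.50, ROT = 0)))
}

#' Default energy-band composition
#'
#' The 100-300 keV band is represented by the responses at 119 and 207 keV
#' mixed 25:75; the 300-3000 keV band by the single point at 662 keV.
#'
#' @return Named list of named weight vectors keyed by energy (keV).
#' @export
default_band_mixes <- function() {
  list(band_100_300 = c(`119` = 0.25, `207` = 0.75),
       band_300_3000 = c(`662` = 1))
}

#' Mean response of an energy band
#'
#' Combines single-energy responses into a band response with the band's
#' component weights, either arithmetically (`sum w_e * B_e`) or on the log
#' scale (`exp(sum w_e * log B_e)`, a weighted geometric mean).
#'
#' @param components Named weight vector keyed by energy in keV, summing
#'   to 1.
#' @param responses Named list (keyed by energy) of [response_value()]
#'   objects, or a named numeric vector of mean responses.
#' @param method `"log_scale"` or `"arithmetic"`.
#' @return A [response_value()]; `sd_log` is propagated as
#'   `sqrt(sum((w_e * sd_e)^2))` when component spreads are available.
#' @export
band_response <- function(components, responses,
                          method = c("log_scale", "arithmetic")) {
  method <- match.arg(method)
  if (abs(sum(components) - 1) > 1e-9)
    stop("band component weights must sum to 1")
  keys <- names(components)
  missing_e <- setdiff(keys, names(responses))
  if (length(missing_e))
    stop("missing response at energy: ", paste(missing_e, collapse = ", "))
  if (is.list(responses) && !is.data.frame(responses)) {
    b <- vapply(responses[keys], function(r) r$mean_B, numeric(1))
    s <- vapply(responses[keys], function(r) r$sd_log, numeric(1))
  } else {
    b <- responses[keys]
    s <- rep(NA_real_, length(keys))
  }
  mean_B <- if (method == "arithmetic") sum(components * b)
            else exp(sum(components * log(b)))
  sd_log <- if (anyNA(s)) NA_real_ else sqrt(sum((components * s)^2))
  response_value(mean_B, sd_log, NA_integer_)
}

#' Working-environment conversion factor for a facility profile
#'
#' Combines per-(energy, geometry) responses into the mean conversion factor
#' a dosemeter shows in a working environment, by doubly weighting over the
#' profile's energy bands (via the band mixes) and geometries. With the
#' default `method = "log_scale"` every weighted average is taken on the log
#' scale (weighted geometric mean), consistent with the lognormal treatment
#' of response uncertainty; `"arithmetic"` averages on the natural scale and
#' is reported for sensitivity. By the AM-GM inequality the log-scale result
#' never exceeds the arithmetic one.
#'
#' The uncertainty factor is propagated from the per-cell log-scale SDs
#' assuming independent cells: `sd_workenv = sqrt(sum((w_cell * sd_cell)^2))`
#' with `w_cell` the product of geometry, band and within-band weights, and
#' `K = exp(1.96 * sd_workenv)`.
#'
#' @param profile A [facility_profile()].
#' @param responses Nested named list: `responses[[geometry]][[energy]]` is a
#'   [response_value()] (geometries `AP`, `ISO`, `ROT` as needed; energies
#'   `"119"`, `"207"`, `"662"`).
#' @param band_mixes Band composition, default [default_band_mixes()].
#' @param method `"log_scale"` (default) or `"arithmetic"`.
#' @return List of class `workenv_result`: `facility`, `method`,
#'   `B_workenv`, `sd_log`, `K_workenv`.
#' @examples
#' tab <- phantom_response_table()
#' resp <- responses_by_cell(tab[tab$dosemeter_type == "EPD", ])
#' facility_response(facility_profiles()$NPP, resp)  # B close to 1
#' @export
facility_response <- function(profile, responses,
                              band_mixes = default_band_mixes(),
                              method = c("log_scale", "arithmetic")) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "facility_profile"))
  band_for <- c(band_0_100 = "band_0_100", band_100_300 = "band_100_300",
                band_300_3000 = "band_300_3000")
  # flatten to cell weights: geometry x band x component energy
  cells <- list()
  for (geom in names(profile$geometry_fractions)) {
    gw <- profile$geometry_fractions[[geom]]
    if (gw == 0) next
    for (band in names(profile$energy_fractions)) {
      bw <- profile$energy_fractions[[band]]
      if (bw == 0) next
      mix <- band_mixes[[band]]
      if (is.null(mix))
        stop("no band mix defined for nonzero-weight band '", band, "'")
      for (en in names(mix)) {
        rv <- responses[[geom]][[en]]
        if (is.null(rv))
          stop("no response available for cell (", en, " keV, ", geom,
               ") required with nonzero weight")
        cells[[length(cells) + 1L]] <- list(
          w = gw * bw * mix[[en]], b = rv$mean_B, s = rv$sd_log)
      }
    }
  }
  w <- vapply(cells, `[[`, numeric(1), "w")
  b <- vapply(cells, `[[`, numeric(1), "b")
  s <- vapply(cells, `[[`, numeric(1), "s")
  B <- if (method == "arithmetic") sum(w * b) else exp(sum(w * log(b)))
  sd_log <- if (anyNA(s)) NA_real_ else sqrt(sum((w * s)^2))
  structure(
    list(facility = profile$name, method = method, B_workenv = B,
         sd_log = sd_log, K_workenv = uncertainty_K(sd_log)),
    class = "workenv_result")
}

#' @export
print.workenv_result <- function(x, ...) {
  cat(sprintf("%s (%s): B = %.4f mSv/mGy, K = %s\n",
              x$facility, x$method, x$B_workenv,
              if (is.na(x$K_workenv)) "NA" else sprintf("%.3f", x$K_workenv)))
  invisible(x)
}

#' Restructure a responses table into per-cell response values
#'
#' Turns a long responses data frame (one dosemeter type) into the nested
#' `responses[[geometry]][[energy]]` list [facility_response()] consumes.
#'
#' @param responses Data frame with columns `geometry`, `mean_energy_keV`,
#'   `mean_B`, and optionally `sd_log` (or `K`, from which `sd_log` is
#'   recovered as `log(K)/1.96`).
#' @return Nested named list of [response_value()] objects.
#' @export
responses_by_cell <- function(responses) {
  stopifnot(all(c("geometry", "mean_energy_keV", "mean_B") %in%
                  names(responses)))
  sd_log <- if ("sd_log" %in% names(responses)) responses$sd_log
            else if ("K" %in% names(responses)) log(responses$K) / 1.96
            else rep(NA_real_, nrow(responses))
  out <- list()
  for (i in seq_len(nrow(responses))) {
    geom <- as.character(responses$geometry[i])
    en <- as.character(responses$mean_energy_keV[i])
    out[[geom]][[en]] <- response_value(responses$mean_B[i], sd_log[i])
  }
  out
}

#' Working-environment factors for every dosemeter type and facility
#'
#' Convenience wrapper producing the table of working-environment conversion
#' factors: one row per (dosemeter type, facility, method).
#'
#' @param responses Data frame with columns `dosemeter_type`, `geometry`,
#'   `mean_energy_keV`, `mean_B` and `sd_log` or `K` (AP and ISO rows are
#'   used). Defaults to the bundled phantom response table.
#' @param profiles List of [facility_profile()]s, default
#'   [facility_profiles()].
#' @param method Aggregation method(s) to report.
#' @param band_mixes Band composition, default [default_band_mixes()].
#' @return Data frame: `dosemeter_type`, `facility`, `method`, `B_workenv`,
#'   `K_workenv`.
#' @export
workenv_table <- function(responses = phantom_response_table(),
                          profiles = facility_profiles(),
                          method = "log_scale",
                          band_mixes = default_band_mixes()) {
  rows <- list()
  for (ty in unique(responses$dosemeter_type)) {
    cellmap <- responses_by_cell(responses[responses$dosemeter_type == ty, ])
    for (pr in profiles) for (m in method) {
      res <- facility_response(pr, cellmap, band_mixes, m)
      rows[[length(rows) + 1L]] <- data.frame(
        dosemeter_type = ty, facility = res$facility, method = m,
        B_workenv = res$B_workenv, K_workenv = res$K_workenv)
    }
  }
  do.call(rbind, rows)
}
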