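#' Estimate dosemeter responses from an experiment's runs and readings
#'
#' Runs the full estimation chain on raw data: calibration factors from the
#' calibration exposure (per dosemeter for the EPD, per lot for the passive
#' GB and LB badges), per-dosemeter responses for every phantom run,
#' per-run mean responses with lognormal uncertainty, and the synthesized
#' isotropic row per (type, energy) from the per-dosemeter rotational
#' responses.
#'
#' Readings of zero (below the detection limit) carry no response
#' information and are excluded with a warning.
#'
#' @param runs Run design data frame, as [irradiation_design()] or
#'   [read_runs()]; must contain one `purpose = "calibration"` row.
#' @param readings Long readings data frame: `run_id`, `dosemeter_type`,
#'   `dosemeter_id`, `reading_mSv`.
#' @param coefficients Conversion-coefficient table, default
#'   [default_coefficients()].
#' @param weight_mode Band-weight mode for the isotropic synthesis
#'   (`"exact"` for analysis, `"printed"` to mirror published tables).
#' @param cf_scope Named character vector giving the calibration scope per
#'   dosemeter type.
#' @return List with `cf` (calibration factors), `responses` (one row per
#'   run and type plus ISO rows: `dosemeter_type`, `mean_energy_keV`,
#'   `geometry`, `zenith_angle_deg`, `mean_B`, `sd_log`, `K`, `n`) and
#'   `per_dosemeter` (individual calibrated responses).
#' @export
estimate_responses <- function(runs, readings,
                               coefficients = default_coefficients(),
                               weight_mode = c("exact", "printed"),
                               cf_scope = c(EPD = "per_dosemeter",
                                            GB = "per_lot",
                                            LB = "per_lot")) {
  weight_mode <- match.arg(weight_mode)
  if (!"reference_kerma_mGy" %in% names(runs))
    runs$reference_kerma_mGy <-
      reference_air_kerma(runs$dose_rate_mGy_h, runs$duration_s)
  cal_runs <- runs[runs$purpose == "calibration", ]
  if (nrow(cal_runs) == 0L)
    stop("no calibration run (purpose = 'calibration') in 'runs'")
  cal <- cal_runs[1L, ]
  cal_coeff <- lookup_coefficient(coefficients, cal$mean_energy_keV,
                                  cal$geometry)
  cal_hp10 <- air_kerma_to_hp10(cal$reference_kerma_mGy, cal_coeff)

  zero <- !is.na(readings$reading_mSv) & readings$reading_mSv == 0
  if (any(zero)) {
    warning(sum(zero), " zero reading(s) (below detection limit) excluded")
    readings <- readings[!zero, ]
  }

  types <- intersect(names(cf_scope), unique(readings$dosemeter_type))
  cf_rows <- list(); resp_rows <- list(); ind_rows <- list()
  for (ty in types) {
    cal_rd <- readings[readings$run_id == cal$run_id &
                         readings$dosemeter_type == ty, ]
    if (nrow(cal_rd) == 0L)
      stop("no calibration readings for dosemeter type ", ty)
    scope <- cf_scope[[ty]]
    if (scope == "per_dosemeter") {
      cfv <- calibration_factor(cal_rd$reading_mSv, cal_hp10,
                                "per_dosemeter", cal_rd$dosemeter_id)
      cf_rows[[ty]] <- data.frame(dosemeter_type = ty, scope = scope,
                                  dosemeter_id = names(cfv), cf = cfv)
      cf_of <- function(id) cfv[[id]]
    } else {
      cfv <- calibration_factor(cal_rd$reading_mSv, cal_hp10, "per_lot")
      cf_rows[[ty]] <- data.frame(dosemeter_type = ty, scope = scope,
                                  dosemeter_id = NA_character_, cf = cfv)
      cf_of <- function(id) cfv
    }
    phantom <- runs[runs$purpose == "phantom", ]
    for (i in seq_len(nrow(phantom))) {
      run <- phantom[i, ]
      rd <- readings[readings$run_id == run$run_id &
                       readings$dosemeter_type == ty, ]
      if (nrow(rd) == 0L) next
      cf_i <- vapply(rd$dosemeter_id, cf_of, numeric(1))
      resp <- single_response(rd$reading_mSv, cf_i,
                              run$reference_kerma_mGy)
      agg <- aggregate_response(resp)
      resp_rows[[length(resp_rows) + 1L]] <- data.frame(
        dosemeter_type = ty, mean_energy_keV = run$mean_energy_keV,
        geometry = run$geometry, zenith_angle_deg = run$zenith_angle_deg,
        mean_B = agg$mean_B, sd_log = agg$sd_log, K = agg$K, n = agg$n)
      ind_rows[[length(ind_rows) + 1L]] <- data.frame(
        run_id = run$run_id, dosemeter_type = ty,
        dosemeter_id = rd$dosemeter_id,
        mean_energy_keV = run$mean_energy_keV, geometry = run$geometry,
        zenith_angle_deg = run$zenith_angle_deg, response = resp)
    }
  }
  responses <- do.call(rbind, resp_rows)
  per_dosemeter <- do.call(rbind, ind_rows)

  # isotropic synthesis per (type, energy), per dosemeter across angles
  iso_rows <- list()
  rot <- per_dosemeter[per_dosemeter$geometry == "ROT", ]
  for (ty in unique(rot$dosemeter_type)) {
    for (en in unique(rot$mean_energy_keV[rot$dosemeter_type == ty])) {
      sub <- rot[rot$dosemeter_type == ty & rot$mean_energy_keV == en, ]
      angles <- sort(unique(sub$zenith_angle_deg))
      needed <- default_band_set()$representative_angle
      if (!all(needed %in% angles)) {
        warning("isotropic synthesis skipped for (", ty, ", ", en,
                " keV): missing zenith angle(s) ",
                paste(setdiff(needed, angles), collapse = ", "))
        next
      }
      ids <- unique(sub$dosemeter_id)
      m <- matrix(NA_real_, length(ids), length(needed),
                  dimnames = list(ids, as.character(needed)))
      for (j in seq_len(nrow(sub)))
        m[sub$dosemeter_id[j], as.character(sub$zenith_angle_deg[j])] <-
          sub$response[j]
      if (anyNA(m)) {
        warning("isotropic synthesis skipped for (", ty, ", ", en,
                " keV): incomplete per-dosemeter angle coverage")
        next
      }
      agg <- iso_from_matrix(m, weight_mode)
      iso_rows[[length(iso_rows) + 1L]] <- data.frame(
        dosemeter_type = ty, mean_energy_keV = en, geometry = "ISO",
        zenith_angle_deg = NA_real_, mean_B = agg$mean_B,
        sd_log = agg$sd_log, K = agg$K, n = agg$n)
    }
  }
  if (length(iso_rows))
    responses <- rbind(responses, do.call(rbind, iso_rows))
  rownames(responses) <- NULL
  list(cf = do.call(rbind, c(cf_rows, list(make.row.names = FALSE))),
       responses = responses, per_dosemeter = per_dosemeter)
}

#' Run the full computation chain and write its artifact set
#'
#' Orchestrates calibration, response estimation, isotropic synthesis,
#' working-environment factors and the plain-text report, writing
#' `cf.csv`, `responses.csv`, `workenv.csv`, `report.txt` and a
#' `provenance.json` sidecar (package version, flags and MD5 digests of the
#' written artifacts) under `out_dir`. Outputs are a pure function of the
#' inputs and flags.
#'
#' @param runs Run design data frame or path to a runs CSV.
#' @param readings Readings data frame or path to a readings CSV.
#' @param coefficients Coefficient table or path to a CSV.
#' @param profiles Named list of [facility_profile()]s or path to a
#'   profiles JSON; default [facility_profiles()].
#' @param out_dir Output directory, created if needed.
#' @param weight_mode Isotropic band-weight mode (`"exact"`/`"printed"`).
#' @param method Working-environment aggregation (`"log_scale"`/
#'   `"arithmetic"`).
#' @return Invisibly, a list with `cf`, `responses`, `workenv`, `report`
#'   and `provenance`.
#' @export
run_pipeline <- function(runs, readings,
                         coefficients = default_coefficients(),
                         profiles = facility_profiles(),
                         out_dir = NULL,
                         weight_mode = c("exact", "printed"),
                         method = "log_scale") {
  weight_mode <- match.arg(weight_mode)
  if (is.character(runs)) runs <- read_runs(runs)
  else runs <- validate_runs(runs)
  if (is.character(readings)) readings <- read_readings(readings)
  if (is.character(coefficients)) coefficients <- read_coefficients(coefficients)
  if (is.character(profiles)) profiles <- read_profiles(profiles)

  fit <- estimate_responses(runs, readings, coefficients, weight_mode)
  wenv <- workenv_table(fit$responses, profiles, method)
  report <- render_report(fit$responses, wenv)
  prov <- list(package = "doseresp",
               version = as.character(utils::packageVersion("doseresp")),
               weight_mode = weight_mode, method = method,
               n_runs = nrow(runs), n_readings = nrow(readings))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fit$cf, file.path(out_dir, "cf.csv"),
                     row.names = FALSE)
    utils::write.csv(fit$responses, file.path(out_dir, "responses.csv"),
                     row.names = FALSE)
    utils::write.csv(wenv, file.path(out_dir, "workenv.csv"),
                     row.names = FALSE)
    writeLines(report, file.path(out_dir, "report.txt"))
    prov$artifact_md5 <- as.list(tools::md5sum(
      file.path(out_dir, c("cf.csv", "responses.csv", "workenv.csv",
                           "report.txt"))))
    names(prov$artifact_md5) <- basename(names(prov$artifact_md5))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(cf = fit$cf, responses = fit$responses, workenv = wenv,
                 report = report, provenance = prov))
}
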