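# Bundled reference tables: the irradiation design, the measured phantom
# response table and the conversion-coefficient fixture. These are the
# experiment's published summary data; raw readings are not public, which is
# why the synthetic generator exists.

#' Irradiation design of the phantom response experiment
#'
#' One row per irradiation run: the slab-phantom calibration exposure
#' (Cs-137, AP) plus, for each of the three beam qualities (N-150 at
#' 119 keV, N-250 at 207 keV, Cs-137 at 662 keV), one AP run at 3.38 m and
#' five rotational runs (zenith angles 30-150 degrees) at 3.5 m. Rotation
#' period is 45 s per turn; the rotational runs use an integer number of
#' rotations. The `reference_kerma_mGy` column is computed as
#' rate x duration / 3600.
#'
#' Note the N-250 rotational rows print 11 rotations with a 445 s duration
#' although 11 turns at 45 s would last 495 s; the reference kerma is
#' consistent with 445 s, and [validate_runs()] surfaces the mismatch as a
#' warning rather than resolving it.
#'
#' @return Data frame with columns `run_id`, `source_quality`,
#'   `mean_energy_keV`, `geometry` (`AP`/`ROT`), `zenith_angle_deg` (`NA`
#'   for AP), `dose_rate_mGy_h`, `duration_s`, `n_rotations`,
#'   `reference_distance_m`, `purpose` (`calibration`/`phantom`),
#'   `reference_kerma_mGy`.
#' @export
irradiation_design <- function() {
  sources <- data.frame(
    source_quality = c("N-150", "N-250", "Cs-137"),
    mean_energy_keV = c(119, 207, 662),
    ap_rate = c(27.6, 7.88, 11.3), ap_dur = c(315, 990, 720),
    rot_rate = c(25.7, 7.33, 10.5), rot_dur = c(180, 445, 360),
    n_rot = c(4, 11, 8))
  rows <- list(data.frame(
    run_id = "CAL_Cs137_AP", source_quality = "Cs-137",
    mean_energy_keV = 662, geometry = "AP", zenith_angle_deg = NA_real_,
    dose_rate_mGy_h = 10.5, duration_s = 720, n_rotations = NA_real_,
    reference_distance_m = 3.5, purpose = "calibration"))
  for (i in seq_len(nrow(sources))) {
    s <- sources[i, ]
    tag <- gsub("-", "", s$source_quality)
    rows[[length(rows) + 1L]] <- data.frame(
      run_id = paste0(tag, "_AP"), source_quality = s$source_quality,
      mean_energy_keV = s$mean_energy_keV, geometry = "AP",
      zenith_angle_deg = NA_real_, dose_rate_mGy_h = s$ap_rate,
      duration_s = s$ap_dur, n_rotations = NA_real_,
      reference_distance_m = 3.38, purpose = "phantom")
    for (ang in c(30, 60, 90, 120, 150))
      rows[[length(rows) + 1L]] <- data.frame(
        run_id = sprintf("%s_ROT%03d", tag, ang),
        source_quality = s$source_quality,
        mean_energy_keV = s$mean_energy_keV, geometry = "ROT",
        zenith_angle_deg = ang, dose_rate_mGy_h = s$rot_rate,
        duration_s = s$rot_dur, n_rotations = s$n_rot,
        reference_distance_m = 3.5, purpose = "phantom")
  }
  design <- do.call(rbind, rows)
  design$reference_kerma_mGy <-
    reference_air_kerma(design$dose_rate_mGy_h, design$duration_s)
  design
}

#' Measured mean responses on the anthropomorphic phantom
#'
#' The published summary of the irradiation experiment: mean dosemeter
#' response B (mSv per mGy air kerma) and multiplicative uncertainty factor
#' K for each dosemeter type (EPD, GB, LB), beam quality (119, 207,
#' 662 keV) and exposure geometry (AP, rotational at five zenith angles,
#' and the synthesized isotropic row).
#'
#' @param include_iso Keep the synthesized ISO rows (default `TRUE`).
#' @return Data frame with columns `dosemeter_type`, `geometry`
#'   (`AP`/`ROT`/`ISO`), `zenith_angle_deg`, `mean_energy_keV`, `mean_B`,
#'   `K`.
#' @export
phantom_response_table <- function(include_iso = TRUE) {
  geoms <- c("AP", "ROT30", "ROT60", "ROT90", "ROT120", "ROT150", "ISO")
  tab <- list(
    EPD = list(
      B = rbind(c(1.38, 1.35, 1.20), c(0.84, 0.99, 0.87),
                c(0.83, 0.97, 0.86), c(0.83, 0.97, 0.87),
                c(0.78, 0.92, 0.83), c(0.51, 0.69, 0.64),
                c(0.77, 0.92, 0.82)),
      K = rbind(c(1.010, 1.008, 1.000), c(1.021, 1.008, 1.031),
                c(1.021, 1.027, 1.008), c(1.011, 1.015, 1.014),
                c(1.018, 1.029, 1.015), c(1.039, 1.041, 1.022),
                c(1.009, 1.011, 1.008))),
    GB = list(
      B = rbind(c(1.47, 1.30, 1.21), c(0.65, 0.84, 0.87),
                c(0.80, 0.89, 0.87), c(0.83, 0.92, 0.88),
                c(0.82, 0.90, 0.89), c(0.80, 0.79, 0.79),
                c(0.79, 0.88, 0.86)),
      K = rbind(c(1.046, 1.035, 1.021), c(1.056, 1.059, 1.072),
                c(1.014, 1.037, 1.036), c(1.040, 1.017, 1.015),
                c(1.059, 1.021, 1.009), c(1.058, 1.023, 1.020),
                c(1.020, 1.014, 1.014))),
    LB = list(
      B = rbind(c(1.98, 1.55, 1.19), c(1.15, 1.01, 0.90),
                c(1.14, 1.03, 0.88), c(1.17, 1.08, 0.96),
                c(1.16, 1.07, 0.87), c(1.09, 0.90, 0.80),
                c(1.14, 1.03, 0.89)),
      K = rbind(c(1.049, 1.062, 1.079), c(1.055, 1.065, 1.097),
                c(1.127, 1.064, 1.066), c(1.046, 1.017, 1.060),
                c(1.042, 1.083, 1.034), c(1.128, 1.021, 1.094),
                c(1.037, 1.025, 1.029))))
  energies <- c(119, 207, 662)
  rows <- list()
  for (ty in names(tab)) for (g in seq_along(geoms)) for (e in 1:3) {
    geom_label <- geoms[g]
    rows[[length(rows) + 1L]] <- data.frame(
      dosemeter_type = ty,
      geometry = if (grepl("^ROT", geom_label)) "ROT" else geom_label,
      zenith_angle_deg = if (grepl("^ROT", geom_label))
        as.numeric(sub("ROT", "", geom_label)) else NA_real_,
      mean_energy_keV = energies[e],
      mean_B = tab[[ty]]$B[g, e], K = tab[[ty]]$K[g, e])
  }
  out <- do.call(rbind, rows)
  if (!include_iso) out <- out[out$geometry != "ISO", ]
  rownames(out) <- NULL
  out
}

#' Bundled Hp(10)-per-air-kerma conversion coefficients
#'
#' Only values used by the computation chain are bundled; no interpolation
#' of full coefficient tables is performed. The slab-calibration coefficient
#' is 1.21 mSv per mGy at 662 keV, AP incidence.
#'
#' @return Data frame with columns `energy_keV`, `geometry`,
#'   `coefficient_mSv_per_mGy`.
#' @export
default_coefficients <- function() {
  data.frame(energy_keV = 662, geometry = "AP",
             coefficient_mSv_per_mGy = 1.21)
}

#' Look up a conversion coefficient
#'
#' @param coefficients Coefficient table, as [default_coefficients()].
#' @param energy_keV Photon energy in keV; energies within `tol_keV` match.
#' @param geometry Geometry/angle label.
#' @param tol_keV Energy matching tolerance in keV (default 2, so the
#'   118/119 and 207/208 keV mean-energy variants of the same beam quality
#'   are treated as identical).
#' @return The coefficient in mSv per mGy.
#' @export
lookup_coefficient <- function(coefficients, energy_keV, geometry,
                               tol_keV = 2) {
  hit <- abs(coefficients$energy_keV - energy_keV) <= tol_keV &
    coefficients$geometry == geometry
  if (!any(hit))
    stop("no conversion coefficient for (", energy_keV, " keV, ",
         geometry, ")")
  cc <- coefficients$coefficient_mSv_per_mGy[hit]
  if (length(unique(cc)) > 1L)
    stop("ambiguous coefficient match for (", energy_keV, " keV, ",
         geometry, ")")
  cc[1L]
}
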