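#' Reference air kerma delivered by an irradiation run
#'
#' The reference air kerma of a run is the product of the air-kerma dose rate
#' at the reference distance and the irradiation time, converted from hours to
#' seconds. The value is returned at full precision; display tables round it
#' to two decimals with [round_display()].
#'
#' @param dose_rate Air-kerma dose rate at the reference position, mGy per
#'   hour. Must be positive.
#' @param duration Irradiation time in seconds. Must be positive.
#' @return Reference air kerma in mGy (unrounded). Vectorised over both
#'   arguments.
#' @examples
#' reference_air_kerma(10.5, 720)   # 2.10 mGy, the slab calibration exposure
#' reference_air_kerma(27.6, 315)   # 2.415 mGy
#' @seealso [air_kerma_to_hp10()], [calibration_factor()]
#' @export
reference_air_kerma <- function(dose_rate, duration) {
  if (any(!is.finite(dose_rate)) || any(dose_rate <= 0))
    stop("'dose_rate' must be positive (mGy per hour)")
  if (any(!is.finite(duration)) || any(duration <= 0))
    stop("'duration' must be positive (seconds)")
  dose_rate * duration / 3600
}

#' Convert air kerma to personal dose equivalent Hp(10)
#'
#' Multiplies an air kerma by a conversion coefficient c = Hp(10) per air
#' kerma (mSv/mGy) for the relevant photon energy and incidence geometry.
#' Under the standard calibration condition (662 keV, AP incidence on the
#' slab phantom) the coefficient is 1.21 mSv per mGy.
#'
#' @param kerma Air kerma in mGy, non-negative.
#' @param coefficient Conversion coefficient in mSv per mGy, positive.
#' @return Hp(10) in mSv.
#' @examples
#' air_kerma_to_hp10(2.10, 1.21)  # 2.541 mSv, reported as 2.54
#' @export
air_kerma_to_hp10 <- function(kerma, coefficient) {
  if (any(!is.finite(kerma)) || any(kerma < 0))
    stop("'kerma' must be non-negative (mGy)")
  if (any(!is.finite(coefficient)) || any(coefficient <= 0))
    stop("'coefficient' must be positive (mSv per mGy)")
  kerma * coefficient
}

#' Calibration factors from a slab-phantom calibration exposure
#'
#' The calibration factor (mSv/mSv) corrects individual sensitivity
#' differences between dosemeters. It is the inverse ratio of reading to the
#' reference Hp(10) of the calibration exposure: `reference_hp10 / reading`.
#'
#' Active dosemeters (EPD) are calibrated individually, one factor per
#' dosemeter (`scope = "per_dosemeter"`). Passive badges (GB, LB), whose
#' element quality is uniform within a lot, receive one factor per lot,
#' computed from the mean reading of the calibration samples
#' (`scope = "per_lot"`).
#'
#' @param readings Numeric vector of calibration readings in mSv, all
#'   positive. A zeroed dosemeter cannot be calibrated.
#' @param reference_hp10 Delivered reference Hp(10) in mSv, positive.
#' @param scope `"per_dosemeter"` (one factor per reading) or `"per_lot"`
#'   (a single factor from the mean reading).
#' @param dosemeter_id Optional identifiers naming the per-dosemeter factors.
#' @return Numeric vector of calibration factors: length of `readings` for
#'   `per_dosemeter`, length one for `per_lot`.
#' @examples
#' calibration_factor(c(2.50, 2.58), 2.54, scope = "per_lot")        # 1.0
#' calibration_factor(c(2.50, 2.58), 2.54, scope = "per_dosemeter")
#' @export
calibration_factor <- function(readings, reference_hp10,
                               scope = c("per_lot", "per_dosemeter"),
                               dosemeter_id = NULL) {
  scope <- match.arg(scope)
  if (length(readings) == 0L)
    stop("'readings' must be non-empty")
  if (any(!is.finite(readings)) || any(readings <= 0))
    stop("all 'readings' must be positive: a zeroed dosemeter cannot be calibrated")
  if (!is.finite(reference_hp10) || reference_hp10 <= 0)
    stop("'reference_hp10' must be positive (mSv)")
  if (scope == "per_lot") {
    reference_hp10 / mean(readings)
  } else {
    cf <- reference_hp10 / readings
    if (!is.null(dosemeter_id)) {
      if (length(dosemeter_id) != length(readings))
        stop("'dosemeter_id' must match 'readings' in length")
      names(cf) <- dosemeter_id
    }
    cf
  }
}

#' Round for display tables
#'
#' Dose tables print mGy and mSv quantities at two decimals. Rounding is
#' round-half-to-even (the IEC 60559 behaviour of [base::round()]), which is
#' platform-stable.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_display <- function(x, digits = 2) round(x, digits)
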