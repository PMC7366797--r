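#' Convert a response per Hp(10) to a response per air kerma
#'
#' Historical dosemeter responses are often expressed as assessed Hp(10) per
#' delivered Hp(10) (mSv/mSv). Since
#' `[Readings/air kerma] / [Hp(10)/air kerma] = [Readings/Hp(10)]`,
#' multiplying by the conversion coefficient c = Hp(10) per air kerma for the
#' matching energy and geometry yields the response per air kerma (mSv/mGy).
#'
#' @param response_per_hp10 Response in mSv per mSv, positive.
#' @param coefficient Conversion coefficient in mSv per mGy, positive.
#' @return Response in mSv per mGy. Vectorised.
#' @examples
#' per_hp10_to_per_kerma(0.90, 1.21)  # 1.089
#' @export
per_hp10_to_per_kerma <- function(response_per_hp10, coefficient) {
  if (any(!is.finite(response_per_hp10)) || any(response_per_hp10 <= 0))
    stop("'response_per_hp10' must be positive")
  if (any(!is.finite(coefficient)) || any(coefficient <= 0))
    stop("'coefficient' must be positive")
  response_per_hp10 * coefficient
}

#' Mapping from historical Japanese dosemeter types to reference models
#'
#' Groups of reference dosemeter models whose unweighted average represents
#' each historical dosemeter type used in Japan: the old film badge
#' (FR-1, US-2, UK-2, UK-5), the multi-element film badge (UK-9, US-8,
#' FR-6) and the thermoluminescence dosemeter (US-22 alone).
#'
#' @return Named list of character vectors of model codes.
#' @export
legacy_group_map <- function() {
  list(old_FB = c("FR-1", "US-2", "UK-2", "UK-5"),
       multi_element_FB = c("UK-9", "US-8", "FR-6"),
       TLD = "US-22")
}

#' Group-average legacy response at one energy and geometry
#'
#' Unweighted arithmetic mean of the member models' responses at the
#' requested condition. Energies within `tol_keV` of the request are treated
#' as matching (beam qualities quoted at 118 vs 119 keV or 207 vs 208 keV
#' are the same quality).
#'
#' @param members Character vector of model codes (one group from
#'   [legacy_group_map()]).
#' @param responses Data frame with columns `model_code`, `energy_keV`,
#'   `geometry` and a response column (`response_per_kerma`, or any single
#'   column named by `value_col`).
#' @param energy_keV,geometry Requested condition.
#' @param value_col Name of the response column (default
#'   `"response_per_kerma"`).
#' @param tol_keV Energy matching tolerance, keV.
#' @return The group mean response.
#' @export
group_average <- function(members, responses, energy_keV, geometry,
                          value_col = "response_per_kerma", tol_keV = 2) {
  stopifnot(all(c("model_code", "energy_keV", "geometry") %in%
                  names(responses)))
  if (!value_col %in% names(responses))
    stop("no column '", value_col, "' in 'responses'")
  vals <- vapply(members, function(m) {
    hit <- responses$model_code == m &
      abs(responses$energy_keV - energy_keV) <= tol_keV &
      responses$geometry == geometry
    if (!any(hit))
      stop("no response for model ", m, " at (", energy_keV, " keV, ",
           geometry, ")")
    v <- responses[[value_col]][hit]
    if (length(v) > 1L)
      stop("multiple responses for model ", m, " at (", energy_keV,
           " keV, ", geometry, ")")
    v
  }, numeric(1))
  mean(vals)
}
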