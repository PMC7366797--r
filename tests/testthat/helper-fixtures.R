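# Shared fixtures built in code.

# Published mean rotational responses keyed by zenith angle, per type and
# energy, for isotropic-synthesis checks.
rot_means <- function(type, energy) {
  tab <- phantom_response_table(include_iso = FALSE)
  sub <- tab[tab$dosemeter_type == type & tab$geometry == "ROT" &
               tab$mean_energy_keV == energy, ]
  stats::setNames(sub$mean_B, as.character(sub$zenith_angle_deg))
}

# Published isotropic-row mean for comparison.
iso_mean <- function(type, energy) {
  tab <- phantom_response_table()
  tab$mean_B[tab$dosemeter_type == type & tab$geometry == "ISO" &
               tab$mean_energy_keV == energy]
}

# Brute-force solid-angle band weight: numerical quadrature of sin(t)/2.
quad_band_weight <- function(lo, hi) {
  stats::integrate(function(t) sin(t) / 2, lo * pi / 180, hi * pi / 180,
                   rel.tol = 1e-12)$value
}

# A tiny two-run design (calibration + one phantom run) for fast IO and
# pipeline tests.
tiny_design <- function() {
  d <- irradiation_design()
  d[d$run_id %in% c("CAL_Cs137_AP", "Cs137_AP"), ]
}
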