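test_that("band weight closed form matches numerical quadrature", {
  cases <- rbind(c(0, 45), c(45, 75), c(75, 105), c(105, 135),
                 c(135, 180), c(0, 180), c(45, 75), c(10, 20), c(88, 92))
  for (i in seq_len(nrow(cases))) {
    lo <- cases[i, 1]; hi <- cases[i, 2]
    expect_equal(band_weight(lo, hi), quad_band_weight(lo, hi),
                 tolerance = 1e-9)
  }
  expect_equal(round(band_weight(0, 45), 3), 0.146)
  expect_equal(round(band_weight(75, 105), 3), 0.259)
  expect_equal(band_weight(0, 180), 1)
  expect_equal(band_weight(45, 75), quad_band_weight(45, 75),
               tolerance = 1e-9)
  expect_error(band_weight(45, 45), "theta")
  expect_error(band_weight(-5, 45), "theta")
  expect_error(band_weight(90, 200), "theta")
})

test_that("default band set partitions the sphere symmetrically", {
  b <- default_band_set()
  expect_equal(sum(b$weight), 1, tolerance = 1e-12)
  expect_equal(b$theta_lo, c(0, 45, 75, 105, 135))
  expect_equal(b$theta_hi, c(45, 75, 105, 135, 180))
  # symmetric pairs about 90 degrees
  expect_equal(b$weight[1], b$weight[5])
  expect_equal(b$weight[2], b$weight[4])
  expect_equal(round(b$weight, 3), c(0.146, 0.224, 0.259, 0.224, 0.146))
  expect_equal(unname(printed_band_weights()),
               c(0.146, 0.224, 0.259, 0.224, 0.146))
})

test_that("isotropic synthesis reproduces every published ISO cell", {
  for (ty in c("EPD", "GB", "LB")) for (en in c(119, 207, 662)) {
    got <- iso_response(rot_means(ty, en), weight_mode = "printed")
    expect_lt(abs(round(got$mean_B, 2) - iso_mean(ty, en)) , 0.011,
              label = sprintf("|ISO %s %d - table|", ty, en))
  }
  # the rounding-boundary cell: printed weights give the published 0.82
  epd662 <- iso_response(rot_means("EPD", 662), weight_mode = "printed")
  expect_equal(round(epd662$mean_B, 2), 0.82)
  expect_equal(epd662$mean_B,
               sum(c(0.146, 0.224, 0.259, 0.224, 0.146) *
                     c(0.87, 0.86, 0.87, 0.83, 0.64)))
  expect_equal(iso_response(rot_means("EPD", 662), "exact")$mean_B,
               0.8251, tolerance = 1e-4)
})

test_that("isotropic synthesis is a weighted mean with sane bounds", {
  b <- c(`30` = 1, `60` = 1, `90` = 1, `120` = 1, `150` = 1) * 0.9
  expect_equal(iso_response(b, weight_mode = "exact")$mean_B, 0.9)
  set.seed(5)
  for (i in 1:20) {
    b <- stats::setNames(runif(5, 0.5, 1.5),
                         c("30", "60", "90", "120", "150"))
    got <- iso_response(b, weight_mode = "exact")$mean_B
    expect_gte(got, min(b)); expect_lte(got, max(b))
  }
  # angle-symmetric responses are invariant to reversing the band order
  b <- c(`30` = 0.7, `60` = 0.9, `90` = 1.1, `120` = 0.9, `150` = 0.7)
  rev_bands <- default_band_set()[5:1, ]
  expect_equal(iso_response(b, "exact")$mean_B,
               iso_response(b, "exact", bands = rev_bands)$mean_B)
  expect_error(iso_response(b[-2]), "60")
})

test_that("per-angle uncertainties propagate to the synthesized K", {
  tab <- phantom_response_table(include_iso = FALSE)
  sub <- tab[tab$dosemeter_type == "EPD" & tab$geometry == "ROT" &
               tab$mean_energy_keV == 662, ]
  sd_log <- stats::setNames(log(sub$K) / 1.96,
                            as.character(sub$zenith_angle_deg))
  got <- iso_response(rot_means("EPD", 662), "printed", sd_log = sd_log)
  # reproduces the published ISO-row K for this cell
  expect_equal(round(got$K, 3), 1.008)
})

test_that("per-dosemeter synthesis aggregates across positions", {
  m <- rbind(c(0.86, 0.85, 0.86, 0.82, 0.63),
             c(0.87, 0.86, 0.87, 0.83, 0.64),
             c(0.88, 0.87, 0.88, 0.84, 0.65),
             c(0.87, 0.86, 0.87, 0.83, 0.64))
  colnames(m) <- c("30", "60", "90", "120", "150")
  got <- iso_from_matrix(m, "printed")
  per <- as.numeric(m %*% printed_band_weights())
  expect_equal(got$mean_B, mean(per))
  expect_equal(got$n, 4L)
  expect_equal(got$K, exp(1.96 * sd(log(per))))
  expect_error(iso_from_matrix(m[, -1]), "30")
})
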