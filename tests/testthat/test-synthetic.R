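test_that("single readings follow the noise-and-rounding model", {
  set.seed(1)
  expect_equal(generate_reading(0.82, 1.05, 0, 0.01), 0.86)  # 0.861 rounds
  expect_equal(generate_reading(0.82, 1.05, 0, 0), 0.82 * 1.05)
  # generator's own log-scale SD is the requested one
  set.seed(2)
  r <- generate_reading(1.0, 2.0, 2.0, 0, n = 10000)
  expect_equal(sd(log(r)), 0.02, tolerance = 0.05)
  expect_error(generate_reading(-1, 1), "true_B")
})

test_that("the generated experiment has the designed shape and is seeded", {
  cfg <- generator_config(seed = 123)
  ds <- generate_experiment(cfg)
  # 1 calibration + 3 energies x 6 geometries of phantom runs
  expect_equal(nrow(ds$runs), 19L)
  # every (run, type) has 4 readings
  expect_equal(nrow(ds$readings), 19L * 3L * 4L)
  counts <- table(ds$readings$run_id, ds$readings$dosemeter_type)
  expect_true(all(counts == 4L))
  # readings are positive multiples of the display unit
  expect_true(all(ds$readings$reading_mSv > 0))
  expect_equal(ds$readings$reading_mSv,
               round(ds$readings$reading_mSv / 0.01) * 0.01)
  # determinism: identical seeds give identical datasets
  ds2 <- generate_experiment(generator_config(seed = 123))
  expect_identical(ds$readings, ds2$readings)
  ds3 <- generate_experiment(generator_config(seed = 124))
  expect_false(identical(ds$readings, ds3$readings))
})

test_that("substream seeding keeps runs stable when the design grows", {
  cfg <- generator_config(seed = 9)
  ds_full <- generate_experiment(cfg)
  cfg_small <- cfg
  cfg_small$run_design <- cfg$run_design[1:5, ]
  ds_small <- generate_experiment(cfg_small)
  shared <- ds_small$readings
  full_shared <- ds_full$readings[
    ds_full$readings$run_id %in% cfg_small$run_design$run_id, ]
  rownames(shared) <- rownames(full_shared) <- NULL
  expect_identical(shared[order(shared$run_id, shared$dosemeter_type,
                                shared$dosemeter_id), ],
                   full_shared[order(full_shared$run_id,
                                     full_shared$dosemeter_type,
                                     full_shared$dosemeter_id), ])
})

test_that("uncovered design rows are rejected before generation", {
  cfg <- generator_config(seed = 1)
  cfg$true_response_table <-
    cfg$true_response_table[cfg$true_response_table$geometry != "AP", ]
  expect_error(generate_experiment(cfg), "does not cover")
})

test_that("with zero noise and no rounding the chain is the identity", {
  cfg <- generator_config(
    error_sd_pct = c(EPD = 0, GB = 0, LB = 0),
    rounding_unit = 0, seed = 5)
  ds <- generate_experiment(cfg)
  fit <- estimate_responses(ds$runs, ds$readings, weight_mode = "exact")
  got <- fit$responses[fit$responses$geometry != "ISO", ]
  truth <- cfg$true_response_table
  for (i in seq_len(nrow(got))) {
    hit <- truth$dosemeter_type == got$dosemeter_type[i] &
      truth$geometry == got$geometry[i] &
      truth$mean_energy_keV == got$mean_energy_keV[i] &
      (is.na(got$zenith_angle_deg[i]) & is.na(truth$zenith_angle_deg) |
         !is.na(got$zenith_angle_deg[i]) & !is.na(truth$zenith_angle_deg) &
         truth$zenith_angle_deg == got$zenith_angle_deg[i])
    expect_equal(got$mean_B[i], truth$true_B[hit], tolerance = 1e-9)
    expect_equal(got$K[i], 1, tolerance = 1e-9)
  }
  # the ISO rows equal the exact-weight synthesis of the true responses
  iso <- fit$responses[fit$responses$geometry == "ISO", ]
  w <- default_band_set()$weight
  for (i in seq_len(nrow(iso))) {
    tr <- truth[truth$dosemeter_type == iso$dosemeter_type[i] &
                  truth$geometry == "ROT" &
                  truth$mean_energy_keV == iso$mean_energy_keV[i], ]
    tr <- tr[order(tr$zenith_angle_deg), ]
    expect_equal(iso$mean_B[i], sum(w * tr$true_B), tolerance = 1e-9)
  }
})

test_that("rounding alone biases responses by at most half a display unit", {
  cfg <- generator_config(error_sd_pct = c(EPD = 0, GB = 0, LB = 0),
                          rounding_unit = 0.01, seed = 2)
  ds <- generate_experiment(cfg)
  fit <- estimate_responses(ds$runs, ds$readings, weight_mode = "exact")
  got <- fit$responses[fit$responses$geometry != "ISO", ]
  runs <- ds$runs
  for (i in seq_len(nrow(got))) {
    run_kerma <- runs$reference_kerma_mGy[
      runs$purpose == "phantom" &
        runs$mean_energy_keV == got$mean_energy_keV[i] &
        runs$geometry == got$geometry[i] &
        (is.na(got$zenith_angle_deg[i]) & is.na(runs$zenith_angle_deg) |
           !is.na(got$zenith_angle_deg[i]) & !is.na(runs$zenith_angle_deg) &
           runs$zenith_angle_deg == got$zenith_angle_deg[i])][1]
    truth <- cfg$true_response_table
    hit <- truth$dosemeter_type == got$dosemeter_type[i] &
      truth$geometry == got$geometry[i] &
      truth$mean_energy_keV == got$mean_energy_keV[i] &
      (is.na(got$zenith_angle_deg[i]) & is.na(truth$zenith_angle_deg) |
         !is.na(got$zenith_angle_deg[i]) & !is.na(truth$zenith_angle_deg) &
         truth$zenith_angle_deg == got$zenith_angle_deg[i])
    # calibration rounding can shift the factor slightly too; allow one unit
    expect_lt(abs(got$mean_B[i] - truth$true_B[hit]),
              0.01 / run_kerma + 0.005)
  }
})

test_that("a small recovery study is unbiased and recovers the error SDs", {
  cfg <- generator_config(seed = 31)
  rs <- recovery_study(cfg, n_replicates = 8)
  expect_equal(rs$n_replicates, 8)
  # bias of estimated responses is small at these noise levels
  expect_lt(max(abs(rs$bias)), 0.05)
  # per-type pooled deviation SDs sit near the generating 1.1/2.0/3.5 %
  expect_equal(unname(rs$deviation_sd_summary[c("EPD", "GB", "LB")]),
               c(1.1, 2.0, 3.5), tolerance = 0.25)
  # K-interval coverage near the nominal 95%
  expect_true(all(rs$k_coverage > 0.85 & rs$k_coverage < 1))
})
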