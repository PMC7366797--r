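# Synthetic irradiation experiment. Raw per-dosemeter readings from the
# phantom experiment are not public; this generator emulates the experiment's
# statistical structure (design, multiplicative lognormal reading error,
# display rounding) so the whole computation chain can be exercised and
# validated by parameter recovery.

#' True response table used by the synthetic generator
#'
#' The measured mean responses (AP and rotational rows of
#' [phantom_response_table()]) serve as the generator's ground truth, plus a
#' `calibration` row per dosemeter type: under the standard slab condition
#' every dosemeter type reads 1.21 mSv per mGy (the Hp(10)-per-air-kerma
#' coefficient), i.e. unit response in Hp(10) terms.
#'
#' @return Data frame: `dosemeter_type`, `geometry`, `zenith_angle_deg`,
#'   `mean_energy_keV`, `true_B`.
#' @export
default_true_response_table <- function() {
  tab <- phantom_response_table(include_iso = FALSE)
  truth <- tab[, c("dosemeter_type", "geometry", "zenith_angle_deg",
                   "mean_energy_keV")]
  truth$true_B <- tab$mean_B
  cal <- data.frame(dosemeter_type = c("EPD", "GB", "LB"),
                    geometry = "CAL", zenith_angle_deg = NA_real_,
                    mean_energy_keV = 662, true_B = 1.21)
  rbind(truth, cal)
}

#' Configuration of the synthetic experiment generator
#'
#' Defaults reproduce the study conditions: the full irradiation design
#' (calibration exposure plus 3 energies x 6 geometries), four dosemeters
#' per run, per-type multiplicative reading error (SD 1.1% for the EPD,
#' 2.0% for the GB, 3.5% for the LB) and readings rounded to the 0.01 mSv
#' minimum display unit.
#'
#' @param true_response_table Ground-truth responses, as
#'   [default_true_response_table()].
#' @param error_sd_pct Named vector of per-type reading-error SDs in
#'   percent.
#' @param rounding_unit Display resolution in mSv; 0 disables rounding.
#' @param n_dosemeters_per_run Dosemeters irradiated simultaneously per run.
#' @param seed Master seed; per-run substreams are derived from it by a
#'   stable hash of run id and type, so adding runs does not perturb
#'   existing ones.
#' @param run_design Irradiation design, as [irradiation_design()].
#' @return List of class `generator_config`.
#' @export
generator_config <- function(true_response_table = default_true_response_table(),
                             error_sd_pct = c(EPD = 1.1, GB = 2.0, LB = 3.5),
                             rounding_unit = 0.01,
                             n_dosemeters_per_run = 4L,
                             seed = 1L,
                             run_design = irradiation_design()) {
  if (any(error_sd_pct < 0)) stop("'error_sd_pct' must be non-negative")
  if (rounding_unit < 0) stop("'rounding_unit' must be non-negative")
  if (n_dosemeters_per_run < 1L) stop("'n_dosemeters_per_run' must be >= 1")
  structure(
    list(true_response_table = true_response_table,
         error_sd_pct = error_sd_pct, rounding_unit = rounding_unit,
         n_dosemeters_per_run = as.integer(n_dosemeters_per_run),
         seed = as.integer(seed), run_design = run_design),
    class = "generator_config")
}

#' Generate synthetic dosemeter readings for one run
#'
#' A reading is the true response times the delivered air kerma, perturbed
#' by multiplicative lognormal noise (`exp(e)`, `e ~ N(0, sd)` with `sd` the
#' error SD as a fraction), then rounded to the display unit. The
#' multiplicative model matches the lognormal treatment of response
#' uncertainty and keeps readings positive by construction; at SDs of a few
#' percent it is numerically indistinguishable from additive noise.
#'
#' Uses the current RNG state; seed upstream (see [generate_experiment()]).
#'
#' @param true_B True response, mSv per mGy, positive.
#' @param reference_kerma Delivered air kerma, mGy, positive.
#' @param error_sd_pct Reading-error SD in percent.
#' @param rounding_unit Display unit in mSv (0 = no rounding).
#' @param n Number of readings to draw.
#' @return Numeric vector of `n` readings in mSv.
#' @export
generate_reading <- function(true_B, reference_kerma, error_sd_pct = 0,
                             rounding_unit = 0.01, n = 1L) {
  if (!is.finite(true_B) || true_B <= 0)
    stop("'true_B' must be positive")
  if (!is.finite(reference_kerma) || reference_kerma <= 0)
    stop("'reference_kerma' must be positive")
  x <- true_B * reference_kerma *
    exp(stats::rnorm(n, 0, error_sd_pct / 100))
  if (rounding_unit > 0) x <- round(x / rounding_unit) * rounding_unit
  x
}

# Stable 31-bit string hash for per-run RNG substreams.
stable_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Generate a full synthetic irradiation experiment
#'
#' Produces one reading set per (run, dosemeter type): the calibration
#' exposure and every phantom run of the design, each with
#' `n_dosemeters_per_run` simultaneous readings. Deterministic given the
#' config seed; each (run, type) pair draws from its own substream so the
#' dataset is invariant to run order.
#'
#' @param config A [generator_config()].
#' @return List of class `synthetic_dataset`: `runs` (the design),
#'   `readings` (data frame `run_id`, `dosemeter_type`, `dosemeter_id`,
#'   `reading_mSv`) and `truth` (the config).
#' @export
generate_experiment <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  design <- config$run_design
  truth <- config$true_response_table
  types <- names(config$error_sd_pct)
  # coverage check before any drawing
  for (i in seq_len(nrow(design))) for (ty in types) {
    if (is.na(true_b_for(truth, ty, design[i, ])))
      stop("true_response_table does not cover (", ty, ", run ",
           design$run_id[i], ")")
  }
  rows <- vector("list", nrow(design) * length(types))
  k <- 0L
  for (i in seq_len(nrow(design))) {
    run <- design[i, ]
    for (ty in types) {
      b <- true_b_for(truth, ty, run)
      sub_seed <- (config$seed + stable_hash(paste(run$run_id, ty))) %%
        2147483647
      set.seed(sub_seed)
      r <- generate_reading(b, run$reference_kerma_mGy,
                            config$error_sd_pct[[ty]],
                            config$rounding_unit,
                            config$n_dosemeters_per_run)
      k <- k + 1L
      rows[[k]] <- data.frame(
        run_id = run$run_id, dosemeter_type = ty,
        dosemeter_id = sprintf("%s_%d", ty,
                               seq_len(config$n_dosemeters_per_run)),
        reading_mSv = r)
    }
  }
  structure(list(runs = design, readings = do.call(rbind, rows),
                 truth = config),
            class = "synthetic_dataset")
}

# True response for a dosemeter type under one design row. Calibration runs
# match the type's CAL entry; phantom runs match on (energy, geometry,
# zenith angle). Returns NA when uncovered.
true_b_for <- function(truth, type, run) {
  if (identical(run$purpose, "calibration")) {
    hit <- truth$dosemeter_type == type & truth$geometry == "CAL"
  } else {
    hit <- truth$dosemeter_type == type &
      truth$geometry == run$geometry &
      truth$mean_energy_keV == run$mean_energy_keV &
      (is.na(run$zenith_angle_deg) & is.na(truth$zenith_angle_deg) |
         !is.na(run$zenith_angle_deg) & !is.na(truth$zenith_angle_deg) &
         truth$zenith_angle_deg == run$zenith_angle_deg)
  }
  if (!any(hit)) NA_real_ else truth$true_B[which(hit)[1L]]
}

#' Parameter-recovery study over replicated synthetic experiments
#'
#' Replicates the synthetic experiment, runs the full estimation chain on
#' each replicate and summarises how well the generator's parameters are
#' recovered: bias and spread of the estimated responses, the pooled
#' deviation-rate SD per dosemeter type against the generating error SD,
#' and the empirical coverage of the K uncertainty interval.
#'
#' Coverage is measured against the generator's known truth (a quantity
#' available only in simulation): the fraction of individual per-dosemeter
#' responses lying within `[B_true / K, B_true * K]`, where `K` is built
#' from the SD of log responses pooled over all replicates of a cell. By
#' construction of `K = exp(1.96 * SD)` this should be close to 95%.
#'
#' @param config A [generator_config()]; replicate `r` uses seed
#'   `config$seed + r`.
#' @param n_replicates Number of replicated experiments.
#' @return List with `estimates` (per replicate x cell estimated `mean_B`
#'   with truth), `bias` (mean estimate minus truth per cell),
#'   `deviation_sd` (per replicate x type pooled deviation-rate SD, %),
#'   `deviation_sd_summary` (mean per type), `k_coverage` (per type) and
#'   `n_replicates`.
#' @export
recovery_study <- function(config = generator_config(), n_replicates = 10L) {
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1")
  est <- list(); dev <- list(); logresp <- list()
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- (config$seed + r) %% 2147483647
    ds <- generate_experiment(cfg)
    fit <- estimate_responses(ds$runs, ds$readings)
    resp <- fit$responses[fit$responses$geometry != "ISO", ]
    resp$replicate <- r
    resp$true_B <- mapply(function(ty, g, a, e) {
      tr <- config$true_response_table
      hit <- tr$dosemeter_type == ty & tr$geometry == g &
        tr$mean_energy_keV == e &
        (is.na(a) & is.na(tr$zenith_angle_deg) |
           !is.na(a) & !is.na(tr$zenith_angle_deg) &
           tr$zenith_angle_deg == a)
      if (any(hit)) tr$true_B[which(hit)[1L]] else NA_real_
    }, resp$dosemeter_type, resp$geometry, resp$zenith_angle_deg,
       resp$mean_energy_keV)
    est[[r]] <- resp
    dev[[r]] <- deviation_rate_by_type(
      ds$readings[ds$readings$run_id %in%
                    ds$runs$run_id[ds$runs$purpose == "phantom"], ])
    # individual log deviations from truth, for K coverage
    ind <- fit$per_dosemeter
    ind <- ind[ind$geometry != "ISO", ]
    ind$true_B <- mapply(function(ty, g, a, e) {
      tr <- config$true_response_table
      hit <- tr$dosemeter_type == ty & tr$geometry == g &
        tr$mean_energy_keV == e &
        (is.na(a) & is.na(tr$zenith_angle_deg) |
           !is.na(a) & !is.na(tr$zenith_angle_deg) &
           tr$zenith_angle_deg == a)
      if (any(hit)) tr$true_B[which(hit)[1L]] else NA_real_
    }, ind$dosemeter_type, ind$geometry, ind$zenith_angle_deg,
       ind$mean_energy_keV)
    logresp[[r]] <- ind
  }
  estimates <- do.call(rbind, est)
  ind_all <- do.call(rbind, logresp)
  ind_all$log_dev <- log(ind_all$response / ind_all$true_B)
  k_cov <- vapply(split(ind_all, ind_all$dosemeter_type), function(d) {
    pooled_sd <- stats::sd(d$log_dev)
    mean(abs(d$log_dev) <= 1.96 * pooled_sd)
  }, numeric(1))
  dev_mat <- do.call(rbind, dev)
  key <- paste(estimates$dosemeter_type, estimates$geometry,
               estimates$zenith_angle_deg, estimates$mean_energy_keV)
  bias <- tapply(estimates$mean_B - estimates$true_B, key, mean)
  list(estimates = estimates, bias = bias,
       deviation_sd = dev_mat,
       deviation_sd_summary = colMeans(dev_mat),
       k_coverage = k_cov, n_replicates = n_replicates)
}
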