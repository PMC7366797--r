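# Readers and writers for the package's CSV/JSON dialects. All dose columns
# carry explicit unit suffixes in headers; no unit inference is performed.

#' Validate a run design table
#'
#' Checks required columns, positivity of rates and durations, geometry and
#' zenith-angle labels and run-id uniqueness, with row-addressed error
#' messages. Photon energies outside the study design (119, 207, 662 keV)
#' are allowed but flagged with a warning, as is a rotation count
#' inconsistent with the duration at the 45 s rotation period (surfaced,
#' not resolved). Adds `reference_kerma_mGy` when absent.
#'
#' @param runs Data frame of runs.
#' @return The validated (and possibly augmented) data frame.
#' @export
validate_runs <- function(runs) {
  required <- c("run_id", "mean_energy_keV", "geometry",
                "zenith_angle_deg", "dose_rate_mGy_h", "duration_s")
  missing_cols <- setdiff(required, names(runs))
  if (length(missing_cols))
    stop("runs table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(runs) == 0L) stop("no runs")
  dup <- runs$run_id[duplicated(runs$run_id)]
  if (length(dup))
    stop("duplicated run_id: ", paste(unique(dup), collapse = ", "))
  for (i in seq_len(nrow(runs))) {
    r <- runs[i, ]
    if (!r$geometry %in% c("AP", "ROT"))
      stop("row ", i, " (", r$run_id, "): unknown geometry '",
           r$geometry, "'")
    if (!is.finite(r$dose_rate_mGy_h) || r$dose_rate_mGy_h <= 0)
      stop("row ", i, " (", r$run_id, "): dose_rate_mGy_h must be positive")
    if (!is.finite(r$duration_s) || r$duration_s <= 0)
      stop("row ", i, " (", r$run_id, "): duration_s must be positive")
    if (r$geometry == "ROT" &&
        (is.na(r$zenith_angle_deg) ||
           !r$zenith_angle_deg %in% c(30, 60, 90, 120, 150)))
      stop("row ", i, " (", r$run_id,
           "): ROT runs need zenith_angle_deg in {30, 60, 90, 120, 150}")
    if (!r$mean_energy_keV %in% c(119, 207, 662))
      warning("row ", i, " (", r$run_id, "): energy ", r$mean_energy_keV,
              " keV is outside the study design")
    if ("n_rotations" %in% names(runs) && !is.na(r$n_rotations) &&
        abs(r$n_rotations * 45 - r$duration_s) > 22.5)
      warning("row ", i, " (", r$run_id, "): n_rotations (",
              r$n_rotations, ") x 45 s rotation period = ",
              r$n_rotations * 45, " s is inconsistent with duration_s = ",
              r$duration_s, "; kerma is validated against duration only")
  }
  if (!"purpose" %in% names(runs)) runs$purpose <- "phantom"
  if (!"reference_kerma_mGy" %in% names(runs))
    runs$reference_kerma_mGy <-
      reference_air_kerma(runs$dose_rate_mGy_h, runs$duration_s)
  runs
}

#' Read a run design CSV
#'
#' Expected columns: `run_id`, `source_quality`, `mean_energy_keV`,
#' `geometry`, `zenith_angle_deg` (empty for AP), `dose_rate_mGy_h`,
#' `duration_s`, optionally `n_rotations`, `reference_distance_m`,
#' `purpose`.
#'
#' @param path CSV path.
#' @return Validated runs data frame (see [validate_runs()]).
#' @export
read_runs <- function(path) {
  runs <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_runs(runs)
}

#' Read a readings CSV
#'
#' Expected columns: `run_id`, `dosemeter_type`, `dosemeter_id`,
#' `reading_mSv`, optionally `phase` (`pre`/`post`/`single`). When pre/post
#' phases are present (cumulative active-dosemeter readings) they are
#' collapsed to increments per (run, type, dosemeter) via
#' [increment_readings()].
#'
#' @param path CSV path.
#' @return Data frame `run_id`, `dosemeter_type`, `dosemeter_id`,
#'   `reading_mSv`.
#' @export
read_readings <- function(path) {
  rd <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("run_id", "dosemeter_type", "dosemeter_id", "reading_mSv")
  missing_cols <- setdiff(required, names(rd))
  if (length(missing_cols))
    stop("readings table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  bad_type <- !rd$dosemeter_type %in% c("EPD", "GB", "LB")
  if (any(bad_type))
    stop("row(s) ", paste(which(bad_type), collapse = ", "),
         ": unknown dosemeter_type '",
         paste(unique(rd$dosemeter_type[bad_type]), collapse = "', '"), "'")
  neg <- is.na(rd$reading_mSv) | rd$reading_mSv < 0
  if (any(neg))
    stop("row(s) ", paste(which(neg), collapse = ", "),
         ": reading_mSv must be a non-negative dose")
  if ("phase" %in% names(rd) && any(rd$phase %in% c("pre", "post"))) {
    single <- rd[!rd$phase %in% c("pre", "post"),
                 c("run_id", "dosemeter_type", "dosemeter_id",
                   "reading_mSv")]
    cum <- rd[rd$phase %in% c("pre", "post"), ]
    key <- paste(cum$run_id, cum$dosemeter_type, cum$dosemeter_id)
    parts <- lapply(split(cum, key), function(d) {
      pre <- d$reading_mSv[d$phase == "pre"]
      post <- d$reading_mSv[d$phase == "post"]
      if (length(pre) != 1L || length(post) != 1L)
        stop("run ", d$run_id[1L], ", dosemeter ", d$dosemeter_id[1L],
             ": need exactly one pre and one post reading")
      data.frame(run_id = d$run_id[1L],
                 dosemeter_type = d$dosemeter_type[1L],
                 dosemeter_id = d$dosemeter_id[1L],
                 reading_mSv = increment_readings(pre, post))
    })
    rd <- rbind(single, do.call(rbind, parts))
    rownames(rd) <- NULL
  } else {
    rd <- rd[, required]
  }
  rd
}

#' Read a conversion-coefficient CSV
#'
#' Columns: `energy_keV`, `geometry`, `coefficient_mSv_per_mGy` (all
#' coefficients positive).
#'
#' @param path CSV path.
#' @return Coefficient data frame.
#' @export
read_coefficients <- function(path) {
  cc <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("energy_keV", "geometry", "coefficient_mSv_per_mGy")
  missing_cols <- setdiff(required, names(cc))
  if (length(missing_cols))
    stop("coefficient table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(!is.finite(cc$coefficient_mSv_per_mGy)) ||
      any(cc$coefficient_mSv_per_mGy <= 0))
    stop("all conversion coefficients must be positive")
  cc
}

#' Read facility profiles from JSON
#'
#' The JSON maps profile names to objects with `energy_fractions` and
#' `geometry_fractions` maps; each profile is validated by
#' [facility_profile()].
#'
#' @param path JSON path.
#' @return Named list of [facility_profile()]s.
#' @export
read_profiles <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(raw), function(nm)
    facility_profile(nm, unlist(raw[[nm]]$energy_fractions),
                     unlist(raw[[nm]]$geometry_fractions)))
  names(out) <- names(raw)
  out
}

#' Read a legacy group map from JSON
#'
#' @param path JSON path: object mapping group names to arrays of model
#'   codes. Groups must be disjoint and non-empty.
#' @return Named list of character vectors.
#' @export
read_groups <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- lapply(raw, as.character)
  if (any(lengths(groups) == 0L)) stop("empty group in group map")
  all_members <- unlist(groups)
  if (anyDuplicated(all_members))
    stop("groups must be disjoint; duplicated member(s): ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  groups
}

#' Read a zenith-band override from JSON
#'
#' The JSON is an array of objects with `representative_angle`, `theta_lo`,
#' `theta_hi`; solid-angle weights are recomputed from the limits. The band
#' set must partition 0-180 degrees.
#'
#' @param path JSON path.
#' @return Band set data frame as [default_band_set()].
#' @export
read_bands <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  b <- b[order(b$theta_lo), ]
  b$weight <- band_weight(b$theta_lo, b$theta_hi)
  if (abs(sum(b$weight) - 1) > 1e-12)
    stop("band set must partition 0-180 degrees (weights sum to ",
         sum(b$weight), ")")
  b
}

#' Render the plain-text response and working-environment report
#'
#' Mean responses are printed at two decimals and uncertainty factors at
#' three, one block per dosemeter type with the three energies as columns,
#' mirroring the shape of the published summary tables. Missing cells are
#' left blank and listed in a warning.
#'
#' @param responses Responses data frame (from [estimate_responses()] or
#'   [phantom_response_table()]).
#' @param workenv Optional working-environment table (from
#'   [workenv_table()]).
#' @param path Optional file to write the report to.
#' @return Character vector of report lines, invisibly.
#' @export
render_report <- function(responses, workenv = NULL, path = NULL) {
  energies <- sort(unique(responses$mean_energy_keV))
  geom_label <- function(g, a)
    ifelse(g == "ROT", sprintf("ROT (%d°)", a), g)
  lines <- c("Dosemeter response B (mSv/mGy) and uncertainty K", "")
  missing_cells <- character(0)
  hdr <- sprintf("%-12s %s   %s", "Geometry",
                 paste(sprintf("B@%dkeV", energies), collapse = "  "),
                 paste(sprintf("K@%dkeV", energies), collapse = "  "))
  for (ty in unique(responses$dosemeter_type)) {
    sub <- responses[responses$dosemeter_type == ty, ]
    lines <- c(lines, paste0("== ", ty, " =="), hdr)
    combos <- unique(sub[, c("geometry", "zenith_angle_deg")])
    ord <- order(match(combos$geometry, c("AP", "ROT", "ISO")),
                 combos$zenith_angle_deg)
    combos <- combos[ord, ]
    for (i in seq_len(nrow(combos))) {
      g <- combos$geometry[i]; a <- combos$zenith_angle_deg[i]
      bcell <- kcell <- character(length(energies))
      for (j in seq_along(energies)) {
        hit <- sub$geometry == g & sub$mean_energy_keV == energies[j] &
          (is.na(a) & is.na(sub$zenith_angle_deg) |
             !is.na(a) & !is.na(sub$zenith_angle_deg) &
             sub$zenith_angle_deg == a)
        if (any(hit)) {
          bcell[j] <- sprintf("%7.2f", sub$mean_B[which(hit)[1L]])
          kv <- sub$K[which(hit)[1L]]
          kcell[j] <- if (is.na(kv)) "     NA" else sprintf("%7.3f", kv)
        } else {
          bcell[j] <- kcell[j] <- "       "
          missing_cells <- c(missing_cells,
                             sprintf("%s/%s/%d keV", ty,
                                     geom_label(g, a), energies[j]))
        }
      }
      lines <- c(lines, sprintf("%-12s %s   %s", geom_label(g, a),
                                paste(bcell, collapse = "  "),
                                paste(kcell, collapse = "  ")))
    }
    lines <- c(lines, "")
  }
  if (!is.null(workenv) && nrow(workenv)) {
    lines <- c(lines, "Working-environment conversion factors", "",
               sprintf("%-6s %-10s %-12s %8s %8s", "Type", "Facility",
                       "Method", "B", "K"))
    for (i in seq_len(nrow(workenv)))
      lines <- c(lines, sprintf("%-6s %-10s %-12s %8.2f %8s",
                                workenv$dosemeter_type[i],
                                workenv$facility[i], workenv$method[i],
                                workenv$B_workenv[i],
                                if (is.na(workenv$K_workenv[i])) "NA"
                                else sprintf("%.3f", workenv$K_workenv[i])))
  }
  if (length(missing_cells))
    warning("missing cells rendered blank: ",
            paste(missing_cells, collapse = "; "))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
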