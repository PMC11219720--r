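#' Read and validate an impedance table
#'
#' @param path CSV with columns \code{subject_id}, \code{t_min},
#'   \code{segment}, \code{frequency_khz}, \code{z_ohm}.
#' @return Validated data frame.
#' @export
read_impedance_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("impedance file not found: %s", path), "hemobia_io")
  }
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) abort(
                   sprintf("cannot read %s: %s", path, conditionMessage(e)),
                   "hemobia_io"))
  if (nrow(df) == 0) abort("impedance file is empty", "hemobia_io")
  required <- c("subject_id", "t_min", "segment", "frequency_khz", "z_ohm")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste("missing columns:", paste(missing, collapse = ", ")),
          "hemobia_io")
  }
  bad_seg <- which(!df$segment %in% SEGMENTS)
  if (length(bad_seg) > 0) {
    abort(sprintf("unknown segment '%s' at row(s) %s",
                  df$segment[bad_seg[1]],
                  paste(utils::head(bad_seg, 5), collapse = ", ")),
          "hemobia_io")
  }
  bad_freq <- which(!df$frequency_khz %in% FREQUENCIES_KHZ)
  if (length(bad_freq) > 0) {
    abort(sprintf("unknown frequency %s kHz at row(s) %s",
                  df$frequency_khz[bad_freq[1]],
                  paste(utils::head(bad_freq, 5), collapse = ", ")),
          "hemobia_io")
  }
  bad_z <- which(!is.finite(df$z_ohm) | df$z_ohm <= 0)
  if (length(bad_z) > 0) {
    abort(sprintf("non-positive impedance at row(s) %s",
                  paste(utils::head(bad_z, 5), collapse = ", ")),
          "hemobia_io")
  }
  key <- paste(df$subject_id, df$t_min, df$segment, df$frequency_khz)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate (subject, t, segment, frequency) at row(s) %s",
                  paste(utils::head(which(duplicated(key)), 5),
                        collapse = ", ")),
          "hemobia_io")
  }
  df
}

#' Write an impedance table
#'
#' @param impedance Impedance data frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_impedance_table <- function(impedance, path) {
  utils::write.csv(
    impedance[c("subject_id", "t_min", "segment", "frequency_khz", "z_ohm")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a vitals table
#'
#' Empty fields are missing readings (undetectable arterial waveform), never
#' sentinel numbers.
#'
#' @param path CSV with columns \code{subject_id}, \code{t_min}, \code{pr},
#'   \code{map}, \code{sv}, \code{svv}.
#' @return Data frame with \code{NA} for missing readings.
#' @export
read_vitals_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("vitals file not found: %s", path), "hemobia_io")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  required <- c("subject_id", "t_min", "pr", "map", "sv", "svv")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste("missing columns:", paste(missing, collapse = ", ")),
          "hemobia_io")
  }
  df
}

#' Write a vitals table
#'
#' @param vitals Vitals data frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_vitals_table <- function(vitals, path) {
  utils::write.csv(vitals[c("subject_id", "t_min", "pr", "map", "sv", "svv")],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run configuration
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Integer RNG seed.
#' @param groups Groups to simulate/analyse.
#' @param n_subjects Subjects per group.
#' @param noise_cv Impedance noise CV.
#' @param segment Analysis segment (default "torso"; the limbs are measured
#'   but not analysed).
#' @param low_freq_khz,high_freq_khz The analysis frequency pair; must be
#'   distinct members of the measured set with low < high.
#' @param spline_degree Interpolating spline degree.
#' @param curvature_threshold Threshold for the curved/linear label.
#' @param curvature_window Trajectory window for curvature ("resus" default).
#' @param alpha Significance level for endpoint comparisons.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(out_dir, seed = 1, groups = GROUPS, n_subjects = 5,
                       noise_cv = 0.005, segment = "torso",
                       low_freq_khz = 5, high_freq_khz = 1000,
                       spline_degree = 3, curvature_threshold = 2.5e-4,
                       curvature_window = "resus", alpha = 0.05) {
  if (!low_freq_khz %in% FREQUENCIES_KHZ ||
      !high_freq_khz %in% FREQUENCIES_KHZ ||
      low_freq_khz >= high_freq_khz) {
    abort("analysis frequencies must be measured frequencies with low < high",
          "hemobia_bad_config")
  }
  structure(list(out_dir = out_dir, seed = seed, groups = groups,
                 n_subjects = n_subjects, noise_cv = noise_cv,
                 segment = segment, low_freq_khz = low_freq_khz,
                 high_freq_khz = high_freq_khz,
                 spline_degree = spline_degree,
                 curvature_threshold = curvature_threshold,
                 curvature_window = curvature_window, alpha = alpha),
            class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' @param path Config file.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, obj)
}

#' Run the full simulate-and-analyse pipeline
#'
#' Simulates each configured group, then runs the analysis chain:
#' standardization, group median/IQR curves at the two analysis frequencies,
#' the impedance/impedance-ratio trajectory with curvature classification,
#' 1 MHz recovery-time detection, endpoint extraction and pointwise
#' comparisons. Writes per-group \code{impedance.csv}/\code{vitals.csv}/
#' \code{truth.csv}, combined \code{group_curves.csv},
#' \code{trajectory.csv}, \code{recovery.json}, \code{curvature.json},
#' \code{endpoints.csv}, \code{comparisons.csv}, \code{report.json}, and a
#' \code{manifest.json} with the configuration, seed, package version and
#' md5 hashes of every output (identical config + seed reproduce identical
#' hashes).
#'
#' @param config A \code{\link{run_config}} (or path to one).
#' @param params_template Simulator template parameters.
#' @return Invisibly, a list with the per-group analysis objects and the
#'   manifest.
#' @export
run_pipeline <- function(config, params_template = subject_params()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  curves_rows <- traj_rows <- endp_rows <- comp_rows <- list()
  recovery <- curvature <- report <- list()
  results <- list()

  for (gi in seq_along(config$groups)) {
    g <- config$groups[[gi]]
    ds <- generate_dataset(n_subjects = config$n_subjects, group = g,
                           params_template = params_template,
                           noise_cv = config$noise_cv,
                           seed = config$seed + gi - 1)
    gdir <- file.path(config$out_dir, g)
    dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
    write_impedance_table(ds$impedance, file.path(gdir, "impedance.csv"))
    write_vitals_table(ds$vitals, file.path(gdir, "vitals.csv"))
    utils::write.csv(ds$truth, file.path(gdir, "truth.csv"),
                     row.names = FALSE, quote = FALSE)

    for (f in c(config$low_freq_khz, config$high_freq_khz)) {
      cv <- impedance_group_curve(ds$impedance, segment = config$segment,
                                  frequency_khz = f)
      curves_rows[[length(curves_rows) + 1]] <- data.frame(
        group = g, frequency_khz = f, t_min = cv$t, median = cv$median,
        p25 = cv$p25, p75 = cv$p75)
      if (f == config$high_freq_khz) curve_high <- cv
    }

    traj <- impedance_trajectory(ds$impedance, segment = config$segment,
                                 low_khz = config$low_freq_khz,
                                 high_khz = config$high_freq_khz,
                                 window = config$curvature_window)
    traj_rows[[length(traj_rows) + 1]] <- data.frame(
      group = g, t_min = traj$t, x = traj$x, y = traj$y, phase = traj$phase)
    curv <- curvature_statistic(traj, threshold = config$curvature_threshold)
    curvature[[g]] <- curv

    rec <- recovery_time(curve_high, infusion_start = 60)
    recovery[[g]] <- if (is.na(rec)) NULL else rec

    ep <- extract_endpoints(ds$vitals, ds$protocol, recovery_minute = rec)
    endp_rows[[length(endp_rows) + 1]] <- data.frame(group = g,
                                                     as.data.frame(ep))
    rep_g <- endpoint_comparison_report(ep, alpha = config$alpha)
    comp_rows[[length(comp_rows) + 1]] <- data.frame(
      group = g, rep_g$comparisons)

    sv_resus1_end <- mean(ep$value[ep$variable == "SV" &
                                     ep$timepoint == "start_resus2"],
                          na.rm = TRUE)
    sv_recovery <- if (!is.na(rec)) {
      mean(ep$value[ep$variable == "SV" & ep$timepoint == "recovery_1M"],
           na.rm = TRUE)
    } else NA_real_
    resp <- if (is.finite(sv_resus1_end) && is.finite(sv_recovery)) {
      delta_sv_responsiveness(sv_resus1_end, sv_recovery)
    } else list(delta_pct = NA_real_, responsive = NA)
    report[[g]] <- list(restored = as.list(rep_g$restored),
                        recovery_min = if (is.na(rec)) NULL else rec,
                        curvature = curv,
                        delta_sv = resp)
    results[[g]] <- list(dataset = ds, trajectory = traj, curvature = curv,
                         recovery = rec, endpoints = ep, report = rep_g)
  }

  paths <- c(
    group_curves = file.path(config$out_dir, "group_curves.csv"),
    trajectory = file.path(config$out_dir, "trajectory.csv"),
    endpoints = file.path(config$out_dir, "endpoints.csv"),
    comparisons = file.path(config$out_dir, "comparisons.csv"),
    recovery = file.path(config$out_dir, "recovery.json"),
    curvature = file.path(config$out_dir, "curvature.json"),
    report = file.path(config$out_dir, "report.json"))
  utils::write.csv(do.call(rbind, curves_rows), paths[["group_curves"]],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, traj_rows), paths[["trajectory"]],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, endp_rows), paths[["endpoints"]],
                   row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(do.call(rbind, comp_rows), paths[["comparisons"]],
                   row.names = FALSE, quote = FALSE, na = "")
  jsonlite::write_json(recovery, paths[["recovery"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  jsonlite::write_json(curvature, paths[["curvature"]], auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, null = "null")

  all_outputs <- c(paths, vapply(config$groups, function(g) {
    file.path(config$out_dir, g, c("impedance.csv", "vitals.csv", "truth.csv"))
  }, character(3)))
  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    package = "hemobia",
    version = as.character(utils::packageVersion("hemobia")),
    outputs = as.list(tools::md5sum(unname(unlist(all_outputs)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(results = results, manifest = manifest, config = config))
}
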