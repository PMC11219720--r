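#' Standard three-phase hemorrhage-resuscitation protocol
#'
#' Builds the experimental protocol used throughout the package: a 180-min
#' experiment in three 60-min phases. Phase 1 is a controlled hemorrhage of
#' 1 L (100 ml withdrawn every 6 min, ten times); phases 2 and 3 each deliver
#' 1 L of resuscitation fluid as a continuous infusion, with a per-group
#' composition:
#'
#' \itemize{
#'   \item \code{crystalloid}: 1 L balanced crystalloid per phase (2 L total).
#'   \item \code{crystalloid_dextrose}: 0.5 L balanced crystalloid +
#'     0.5 L 5\% dextrose water per phase.
#'   \item \code{crystalloid_albumin}: 0.8 L balanced crystalloid +
#'     200 ml 20\% albumin per phase.
#' }
#'
#' Bioimpedance is measured every \code{bia_interval} minutes (baseline at
#' t = 0 included) and vital signs every \code{vitals_interval} minutes.
#'
#' Crystalloid and dextrose are infused continuously over each 60-min phase.
#' Concentrated (20\%) albumin is modelled as a rapid piggyback infusion
#' over the first \code{albumin_bolus_min} minutes of each resuscitation
#' phase, the usual way a 200-ml colloid dose is given; set
#' \code{albumin_bolus_min = 60} for a continuous co-infusion.
#'
#' @param group One of \code{"crystalloid"}, \code{"crystalloid_dextrose"},
#'   \code{"crystalloid_albumin"}.
#' @param bia_interval Minutes between impedance measurements; must divide 180.
#' @param vitals_interval Minutes between vital-sign readings; must divide 180.
#' @param baseline_replicates Number of baseline impedance replicates taken
#'   before the experiment to confirm a stable baseline.
#' @param albumin_bolus_min Minutes over which each phase's albumin dose is
#'   delivered, starting at the phase boundary.
#' @return An object of class \code{bia_protocol}: a list with elements
#'   \code{group}, \code{phase_bounds}, \code{bleed_events} (data frame of
#'   \code{time}/\code{volume}), \code{phases} (list of phase descriptors with
#'   fluid compositions), \code{bia_interval}, \code{vitals_interval},
#'   \code{baseline_replicates}.
#' @examples
#' p <- standard_protocol("crystalloid_albumin")
#' cumulative_infused(p, 180)
#' @export
standard_protocol <- function(group = GROUPS,
                              bia_interval = 3,
                              vitals_interval = 1,
                              baseline_replicates = 3,
                              albumin_bolus_min = 10) {
  if (length(group) != 1 || !group %in% GROUPS) {
    abort(sprintf("unknown group '%s'; must be one of %s",
                  paste(group, collapse = ","), paste(GROUPS, collapse = ", ")),
          "hemobia_unknown_group")
  }
  if (bia_interval <= 0 || 180 %% bia_interval != 0) {
    abort("bia_interval must be a positive divisor of 180 minutes",
          "hemobia_bad_interval")
  }
  if (vitals_interval <= 0 || 180 %% vitals_interval != 0) {
    abort("vitals_interval must be a positive divisor of 180 minutes",
          "hemobia_bad_interval")
  }

  per_phase <- switch(group,
    crystalloid          = c(balanced_crystalloid = 1000),
    crystalloid_dextrose = c(balanced_crystalloid = 500, dextrose5 = 500),
    crystalloid_albumin  = c(balanced_crystalloid = 800, albumin20 = 200))

  phases <- list(
    list(name = "hemorrhage", start_min = 0, end_min = 60, fluids = numeric(0)),
    list(name = "resus1", start_min = 60, end_min = 120, fluids = per_phase),
    list(name = "resus2", start_min = 120, end_min = 180, fluids = per_phase))

  protocol <- structure(list(
    group = group,
    phase_bounds = c(0, 60, 120, 180),
    bleed_events = data.frame(time = seq(6, 60, by = 6), volume = 100),
    phases = phases,
    bia_interval = bia_interval,
    vitals_interval = vitals_interval,
    baseline_replicates = baseline_replicates,
    albumin_bolus_min = albumin_bolus_min
  ), class = "bia_protocol")
  validate_protocol(protocol)
  protocol
}

validate_protocol <- function(protocol) {
  stopifnot(inherits(protocol, "bia_protocol"))
  if (any(protocol$bleed_events$volume <= 0)) {
    abort("bleed volumes must be positive", "hemobia_bad_protocol")
  }
  if (sum(protocol$bleed_events$volume) != 1000) {
    abort("total bleed volume must be 1000 ml", "hemobia_bad_protocol")
  }
  resus_total <- sum(vapply(protocol$phases, function(ph) sum(ph$fluids), 0))
  if (resus_total != 2000) {
    abort("total resuscitation volume must be 2000 ml", "hemobia_bad_protocol")
  }
  invisible(protocol)
}

#' @export
print.bia_protocol <- function(x, ...) {
  cat("Hemorrhage-resuscitation protocol (", x$group, ")\n", sep = "")
  cat("  phases: hemorrhage [0,60), resus1 [60,120), resus2 [120,180] min\n")
  cat("  bleed:  ", nrow(x$bleed_events), " events x ",
      x$bleed_events$volume[1], " ml\n", sep = "")
  for (ph in x$phases[-1]) {
    cat("  ", ph$name, ": ",
        paste(sprintf("%s %g ml", names(ph$fluids), ph$fluids), collapse = " + "),
        "\n", sep = "")
  }
  cat("  BIA every ", x$bia_interval, " min; vitals every ",
      x$vitals_interval, " min\n", sep = "")
  invisible(x)
}

#' Impedance measurement schedule
#'
#' Times (minutes) at which impedance is measured: the baseline at 0 and one
#' measurement every \code{bia_interval} minutes through minute 180. The
#' default 3-min interval yields 61 timepoints.
#'
#' @param protocol A \code{bia_protocol}.
#' @return Ascending numeric vector of measurement times in minutes.
#' @export
measurement_schedule <- function(protocol) {
  validate_protocol(protocol)
  seq(0, 180, by = protocol$bia_interval)
}

#' Vital-sign measurement schedule
#'
#' @param protocol A \code{bia_protocol}.
#' @return Ascending numeric vector of vitals reading times in minutes.
#' @export
vitals_schedule <- function(protocol) {
  validate_protocol(protocol)
  seq(0, 180, by = protocol$vitals_interval)
}

check_time_range <- function(t) {
  if (any(!is.finite(t)) || any(t < 0) || any(t > 180)) {
    abort("time must lie within [0, 180] minutes", "hemobia_time_range")
  }
}

#' Cumulative bled volume
#'
#' Total blood withdrawn by time \code{t}, as a right-continuous step
#' function over the bleed events (an event at time e counts for t >= e).
#'
#' @param protocol A \code{bia_protocol}.
#' @param t Time(s) in minutes, within [0, 180].
#' @return Cumulative bled volume in ml (vectorized over \code{t}).
#' @export
cumulative_bled_volume <- function(protocol, t) {
  validate_protocol(protocol)
  check_time_range(t)
  ev <- protocol$bleed_events
  vapply(t, function(ti) sum(ev$volume[ev$time <= ti]), 0)
}

#' Cumulative infused volume per fluid
#'
#' Volume of each fluid delivered by time \code{t}, assuming each phase's
#' fluids are infused simultaneously at constant rate over the 60-min phase.
#' All zero for t <= 60 (the hemorrhage phase).
#'
#' @param protocol A \code{bia_protocol}.
#' @param t Time in minutes, within [0, 180] (scalar).
#' @return Named numeric vector of per-fluid cumulative volumes (ml); fluids
#'   absent from the protocol are omitted.
#' @export
cumulative_infused <- function(protocol, t) {
  validate_protocol(protocol)
  if (length(t) != 1) abort("t must be a scalar", "hemobia_time_range")
  check_time_range(t)
  totals <- numeric(0)
  for (ph in protocol$phases) {
    for (k in names(ph$fluids)) {
      win <- fluid_window(protocol, ph, k)
      frac <- min(max(t - win[1], 0) / (win[2] - win[1]), 1)
      totals[k] <- (if (k %in% names(totals)) totals[k] else 0) +
        ph$fluids[[k]] * frac
    }
  }
  totals
}

# delivery window [start, end] of one fluid within a phase
fluid_window <- function(protocol, ph, fluid) {
  if (fluid == "albumin20") {
    bm <- protocol$albumin_bolus_min %||% (ph$end_min - ph$start_min)
    c(ph$start_min, ph$start_min + bm)
  } else {
    c(ph$start_min, ph$end_min)
  }
}

#' Per-fluid infusion rates at a time
#'
#' @param protocol A \code{bia_protocol}.
#' @param t Time in minutes. Phases are half-open: [60,120), [120,180);
#'   t = 180 has zero rates.
#' @return Named numeric vector of infusion rates (ml/min), possibly empty.
#' @keywords internal
infusion_rates_at <- function(protocol, t) {
  rates <- numeric(0)
  for (ph in protocol$phases) {
    for (k in names(ph$fluids)) {
      win <- fluid_window(protocol, ph, k)
      if (t >= win[1] && t < win[2]) {
        rates[k] <- (if (k %in% names(rates)) rates[k] else 0) +
          ph$fluids[[k]] / (win[2] - win[1])
      }
    }
  }
  rates
}

#' Serialize a protocol to JSON or YAML
#'
#' @param protocol A \code{bia_protocol}.
#' @param path Output file; format inferred from extension (.json/.yaml/.yml)
#'   unless \code{format} is given.
#' @param format "json" or "yaml".
#' @return \code{path}, invisibly.
#' @export
write_protocol <- function(protocol, path, format = NULL) {
  validate_protocol(protocol)
  format <- format %||% if (grepl("\\.ya?ml$", path)) "yaml" else "json"
  obj <- list(
    group = protocol$group,
    bleed_events = lapply(seq_len(nrow(protocol$bleed_events)), function(i) {
      list(time = protocol$bleed_events$time[i],
           volume = protocol$bleed_events$volume[i])
    }),
    phases = lapply(protocol$phases, function(ph) {
      list(name = ph$name, start_min = ph$start_min, end_min = ph$end_min,
           fluids = lapply(seq_along(ph$fluids), function(j) {
             list(kind = names(ph$fluids)[j], volume_ml = unname(ph$fluids[j]))
           }))
    }),
    bia_interval_min = protocol$bia_interval,
    vitals_interval_min = protocol$vitals_interval,
    baseline_replicates = protocol$baseline_replicates,
    albumin_bolus_min = protocol$albumin_bolus_min
  )
  if (format == "yaml") {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a protocol from JSON or YAML
#'
#' @param path File written by \code{\link{write_protocol}} (or hand-authored
#'   with the same keys).
#' @return A \code{bia_protocol}.
#' @export
read_protocol <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path)
  }
  bleed <- do.call(rbind, lapply(obj$bleed_events, function(e) {
    data.frame(time = e$time, volume = e$volume)
  }))
  phases <- lapply(obj$phases, function(ph) {
    fl <- vapply(ph$fluids, function(f) f$volume_ml, 0)
    names(fl) <- vapply(ph$fluids, function(f) f$kind, "")
    list(name = ph$name, start_min = ph$start_min, end_min = ph$end_min,
         fluids = fl)
  })
  protocol <- structure(list(
    group = obj$group,
    phase_bounds = c(0, 60, 120, 180),
    bleed_events = bleed,
    phases = phases,
    bia_interval = obj$bia_interval_min,
    vitals_interval = obj$vitals_interval_min,
    baseline_replicates = obj$baseline_replicates %||% 3,
    albumin_bolus_min = obj$albumin_bolus_min %||% 10
  ), class = "bia_protocol")
  validate_protocol(protocol)
  protocol
}

#' Phase label for a time
#'
#' @param t Time(s) in minutes.
#' @return Character vector: "hemorrhage" for [0,60), "resus1" for [60,120),
#'   "resus2" for [120,180].
#' @export
phase_of <- function(t) {
  check_time_range(t)
  ifelse(t < 60, "hemorrhage", ifelse(t < 120, "resus1", "resus2"))
}
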