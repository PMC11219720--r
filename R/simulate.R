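#' Subject parameter set for the fluid-kinetics simulator
#'
#' Bundles the physiological constants used by \code{\link{simulate_compartments}},
#' \code{\link{cole_impedance}} and \code{\link{hemodynamics_from_volume}}.
#' Baseline body-water partitions follow the standard rule of thumb: total
#' body water (TBW) = \code{tbw_fraction} x weight, of which
#' \code{icw_fraction_of_tbw} is intracellular (ICW) and the rest
#' extracellular (ECW); blood volume = \code{blood_volume_per_kg} x weight,
#' split into plasma water (x (1 - hematocrit)) and red-cell volume.
#'
#' @param weight Body weight (kg).
#' @param hematocrit Hematocrit as a fraction of blood volume.
#' @param blood_volume_per_kg Estimated blood volume (ml/kg); 65 is the
#'   midpoint of the 58-74 ml/kg range commonly quoted for swine.
#' @param tbw_fraction TBW as a fraction of body weight.
#' @param icw_fraction_of_tbw ICW as a fraction of TBW (2/3 by the usual
#'   distribution rule; the same rule that routes metabolized free water
#'   1/3 to ECW and 2/3 to ICW).
#' @param segment_fractions Named fractions (summing to 1) of body water in
#'   each of the five segments; the torso dominates because it holds most of
#'   the blood reserve.
#' @param cole Cole dispersion parameters: \code{k_e}, \code{k_i}
#'   (ohm-litre volume-to-resistance constants for ECW and ICW),
#'   \code{f_c} (characteristic frequency, kHz), \code{alpha} (0, 1].
#' @param refill_rate Transcapillary refill rate constant (1/min): first-order
#'   relaxation of plasma water toward its oncotic target (baseline plasma
#'   plus any albumin-held expansion volume), fed from (or drained to) the
#'   interstitium.
#' @param equil_rate Crystalloid equilibration rate constant (1/min): relaxes
#'   the free (non-albumin-held) plasma share of the ECW excess toward a 1:3
#'   plasma:interstitial split.
#' @param glucose_half_life Half-life (min) of the unmetabolized dextrose
#'   water pool; on metabolism the freed water redistributes 1/3 ECW, 2/3 ICW.
#' @param glucose_osmotic_shift ml of intracellular water drawn osmotically
#'   into the extracellular space per ml of unmetabolized dextrose water
#'   (hyperglycemia raises extracellular tonicity; the shift reverses as
#'   glucose is metabolized).
#' @param glucose_osmotic_rate First-order rate (1/min) at which the osmotic
#'   shift relaxes toward its glucose-determined target.
#' @param albumin_expansion_factor Plasma volume expansion per ml of 20\%
#'   albumin infused (dimensionless); 4 sits inside the 300-500\% expansion
#'   quoted for concentrated albumin. Intravascular albumin holds
#'   (factor - 1) x its solution-equivalent volume of extra plasma water,
#'   recruited from the interstitium; the held volume decays as albumin
#'   leaks out of the vasculature.
#' @param albumin_leak_rate Rate constant (1/min) for leak of intravascular
#'   albumin to the interstitium (endothelial dysfunction in shock).
#' @param icw_pull_coefficient ml of intracellular water drawn into the
#'   interstitium per ml-equivalent of leaked 20\% albumin solution (the
#'   persistent interstitial-oncotic component).
#' @param icw_osmotic_per_g ml of intracellular water reversibly drawn
#'   towards the extracellular space per gram of intravascular albumin
#'   (hyperoncotic recruitment); released again as the albumin leaks away.
#' @param icw_osmotic_rate First-order rate (1/min) at which the reversible
#'   oncotic shift is recruited when intravascular albumin rises.
#' @param icw_osmotic_release_rate First-order rate (1/min) at which
#'   recruited water re-enters the cells once the intravascular albumin
#'   level falls; much slower than recruitment, since re-equilibration runs
#'   against the residual oncotic gradient.
#' @param hemo_baseline Named list of baseline vitals: \code{PR0} (bpm),
#'   \code{MAP0} (mmHg), \code{SV0} (ml/beat), \code{SVV0} (\%).
#' @param hemo_shape Exponent of the saturating volume-response map
#'   \code{g(phi) = 2 phi^m / (1 + phi^m)} linking relative blood volume
#'   \code{phi} to SV and MAP.
#' @param svv_sensitivity Percentage-point rise in SVV per unit fall in
#'   \code{g(phi)}.
#' @param map_detect_floor MAP (mmHg) below which the arterial waveform is
#'   undetectable and MAP/SV/SVV are recorded as missing.
#' @param noise_cv Coefficient of variation of multiplicative impedance
#'   measurement noise.
#' @return A list of class \code{subject_params}.
#' @export
subject_params <- function(weight = 37.7,
                           hematocrit = 0.33,
                           blood_volume_per_kg = 65,
                           tbw_fraction = 0.6,
                           icw_fraction_of_tbw = 2 / 3,
                           segment_fractions = c(right_arm = 0.125,
                                                 left_arm = 0.125,
                                                 torso = 0.5,
                                                 right_leg = 0.125,
                                                 left_leg = 0.125),
                           cole = list(k_e = 250, k_i = 380,
                                       f_c = 50, alpha = 0.7),
                           refill_rate = 0.15,
                           equil_rate = 0.03,
                           glucose_half_life = 20,
                           glucose_osmotic_shift = 1.5,
                           glucose_osmotic_rate = 0.1,
                           albumin_expansion_factor = 4,
                           albumin_leak_rate = 0.03,
                           icw_pull_coefficient = 1,
                           icw_osmotic_per_g = 20,
                           icw_osmotic_rate = 0.08,
                           icw_osmotic_release_rate = 0.012,
                           hemo_baseline = list(PR0 = 95, MAP0 = 55,
                                                SV0 = 75, SVV0 = 12),
                           hemo_shape = 5,
                           svv_sensitivity = 20,
                           map_detect_floor = 25,
                           noise_cv = 0.005) {
  p <- list(weight = weight, hematocrit = hematocrit,
            blood_volume_per_kg = blood_volume_per_kg,
            tbw_fraction = tbw_fraction,
            icw_fraction_of_tbw = icw_fraction_of_tbw,
            segment_fractions = segment_fractions, cole = cole,
            refill_rate = refill_rate, equil_rate = equil_rate,
            glucose_half_life = glucose_half_life,
            glucose_osmotic_shift = glucose_osmotic_shift,
            glucose_osmotic_rate = glucose_osmotic_rate,
            albumin_expansion_factor = albumin_expansion_factor,
            albumin_leak_rate = albumin_leak_rate,
            icw_pull_coefficient = icw_pull_coefficient,
            icw_osmotic_per_g = icw_osmotic_per_g,
            icw_osmotic_rate = icw_osmotic_rate,
            icw_osmotic_release_rate = icw_osmotic_release_rate,
            hemo_baseline = hemo_baseline, hemo_shape = hemo_shape,
            svv_sensitivity = svv_sensitivity,
            map_detect_floor = map_detect_floor, noise_cv = noise_cv)
  class(p) <- "subject_params"
  validate_subject_params(p)
  p
}

validate_subject_params <- function(p) {
  fr <- c(p$hematocrit, p$tbw_fraction, p$icw_fraction_of_tbw,
          p$segment_fractions)
  if (any(fr <= 0) || any(fr >= 1)) {
    abort("all fractions must lie in (0, 1)", "hemobia_bad_params")
  }
  if (abs(sum(p$segment_fractions) - 1) > 1e-9) {
    abort("segment_fractions must sum to 1", "hemobia_bad_params")
  }
  if (!setequal(names(p$segment_fractions), SEGMENTS)) {
    abort("segment_fractions must name the five body segments",
          "hemobia_bad_params")
  }
  if (p$cole$alpha <= 0 || p$cole$alpha > 1) {
    abort("Cole alpha must lie in (0, 1]", "hemobia_bad_params")
  }
  if (p$weight <= 0) abort("weight must be positive", "hemobia_bad_params")
  invisible(p)
}

#' Compartment routing of an infused or metabolized fluid volume
#'
#' Returns the plasma/interstitial/intracellular increments produced by a
#' fluid volume once it has reached its distribution space:
#' \itemize{
#'   \item \code{balanced_crystalloid}: confined to extracellular water,
#'     entering the plasma (subsequent plasma-interstitial equilibration is a
#'     kinetic process, see \code{\link{simulate_compartments}});
#'   \item \code{dextrose5} (metabolized free water): distributed across all
#'     body water, 1/3 to ECW (split 1:3 plasma:interstitial) and 2/3 to ICW;
#'   \item \code{albumin20}: the fluid volume stays in the plasma;
#'   \item \code{whole_blood} (withdrawal accounting): plasma water fraction
#'     (1 - hematocrit) and red-cell water fraction (hematocrit, charged to
#'     intracellular water).
#' }
#'
#' @param fluid_kind One of \code{"balanced_crystalloid"}, \code{"dextrose5"},
#'   \code{"albumin20"}, \code{"whole_blood"}.
#' @param volume Volume in ml (>= 0).
#' @param hematocrit Used only for \code{whole_blood}.
#' @return Named numeric vector \code{c(plasma=, interstitial=, intracellular=)}
#'   in ml.
#' @examples
#' distribute_fluid("dextrose5", 1000) # 2/3 of the free water to ICW
#' @export
distribute_fluid <- function(fluid_kind, volume, hematocrit = 0.33) {
  fluid_kind <- match.arg(fluid_kind, FLUID_KINDS)
  if (!is.finite(volume) || volume < 0) {
    abort("volume must be non-negative", "hemobia_bad_volume")
  }
  switch(fluid_kind,
    balanced_crystalloid = c(plasma = volume, interstitial = 0,
                             intracellular = 0),
    dextrose5 = c(plasma = volume / 3 * 0.25,
                  interstitial = volume / 3 * 0.75,
                  intracellular = volume * 2 / 3),
    albumin20 = c(plasma = volume, interstitial = 0, intracellular = 0),
    whole_blood = c(plasma = volume * (1 - hematocrit), interstitial = 0,
                    intracellular = volume * hematocrit))
}

baseline_state <- function(params) {
  w <- params$weight
  tbw <- params$tbw_fraction * w * 1000
  icw <- params$icw_fraction_of_tbw * tbw
  ecw <- tbw - icw
  bv <- params$blood_volume_per_kg * w
  plasma <- bv * (1 - params$hematocrit)
  if (plasma >= ecw) {
    abort("baseline plasma exceeds extracellular water; check parameters",
          "hemobia_bad_params")
  }
  list(tbw = tbw, icw = icw, ecw = ecw, blood = bv, plasma = plasma,
       interstitial = ecw - plasma, rbc = bv * params$hematocrit)
}

#' Simulate compartment fluid kinetics over the protocol
#'
#' Explicit Euler time-stepping of a three-pool body-water model (plasma,
#' interstitial, intracellular water) driven by the protocol's bleed events
#' and infusion schedule. Per step:
#' \enumerate{
#'   \item infusions enter the plasma (dextrose water is additionally tagged
#'     in an unmetabolized pool; albumin mass enters an intravascular pool);
#'   \item the dextrose pool decays with half-life
#'     \code{glucose_half_life}; freed water redistributes per
#'     \code{\link{distribute_fluid}} (net: 2/3 of the freed water moves
#'     plasma to intracellular); while unmetabolized, the glucose raises
#'     extracellular tonicity and osmotically shifts intracellular water
#'     into the interstitium (\code{glucose_osmotic_shift} ml per ml of
#'     pool, relaxed at \code{glucose_osmotic_rate}); the shift reverses as
#'     the pool is metabolized, so a fully metabolized bolus still nets
#'     2/3 of its water intracellular;
#'   \item transcapillary refill relaxes plasma water toward its oncotic
#'     target -- baseline plasma plus the albumin-held expansion volume
#'     (\code{albumin_expansion_factor} - 1) x the solution-equivalent of
#'     retained intravascular albumin -- at \code{refill_rate}, exchanging
#'     with the interstitium (this realizes the up-to-(factor - 1)x
#'     interstitial-to-plasma recruitment first-order);
#'   \item crystalloid equilibration relaxes the free (non-albumin-held)
#'     plasma share of the ECW excess toward a 1:3 plasma:interstitial split
#'     at \code{equil_rate};
#'   \item intravascular albumin leaks to the interstitium at
#'     \code{albumin_leak_rate}; each ml-equivalent of leaked 20\% albumin
#'     draws \code{icw_pull_coefficient} ml of intracellular water into the
#'     interstitium;
#'   \item bleed events remove blood instantaneously at their event times:
#'     plasma water x (1 - hematocrit) and red-cell water x hematocrit
#'     (charged to intracellular water).
#' }
#' Total body water obeys \code{d(TBW) = infused - bled} exactly (urine output
#' is out of scope).
#'
#' @param params A \code{\link{subject_params}}.
#' @param protocol A \code{\link{standard_protocol}}.
#' @param dt Time step in minutes; must divide the bleed-event times and
#'   phase boundaries.
#' @return Data frame of class \code{compartment_sim} with one row per grid
#'   time: \code{t}, \code{plasma}, \code{interstitial}, \code{intracellular},
#'   \code{circulating_blood}, \code{glucose_pool}, \code{osmotic_shift},
#'   \code{oncotic_shift} (ml), \code{alb_iv}, \code{alb_is} (albumin g),
#'   \code{infused_water}, \code{bled_water} (cumulative ml). The baseline
#'   volumes and parameters are kept as attributes \code{baseline} and
#'   \code{params}.
#' @export
simulate_compartments <- function(params, protocol, dt = 0.5) {
  validate_subject_params(params)
  validate_protocol(protocol)
  if (!is.finite(dt) || dt <= 0) {
    abort("dt must be positive", "hemobia_bad_dt")
  }
  event_times <- c(protocol$bleed_events$time, protocol$phase_bounds)
  if (any(abs(event_times / dt - round(event_times / dt)) > 1e-9)) {
    abort("dt must divide all event times", "hemobia_bad_dt")
  }

  b <- baseline_state(params)
  lambda <- log(2) / params$glucose_half_life
  hct <- params$hematocrit
  exf <- params$albumin_expansion_factor

  n <- round(180 / dt) + 1
  t_grid <- seq(0, 180, by = dt)
  out <- matrix(0, n, 11)
  colnames(out) <- c("plasma", "interstitial", "intracellular",
                     "circulating_blood", "glucose_pool", "osmotic_shift",
                     "oncotic_shift", "alb_iv", "alb_is",
                     "infused_water", "bled_water")

  P <- b$plasma; I <- b$interstitial; C <- b$icw; rbc <- b$rbc
  G <- 0; S <- 0; Wa <- 0; AlbIV <- 0; AlbIS <- 0
  infused <- 0; bled <- 0

  out[1, ] <- c(P, I, C, rbc + P, G, S, Wa, AlbIV, AlbIS, infused, bled)

  for (k in 2:n) {
    t0 <- t_grid[k - 1]
    # (1) continuous infusion over [t0, t0 + dt)
    rates <- infusion_rates_at(protocol, t0)
    for (fl in names(rates)) {
      v <- rates[[fl]] * dt
      P <- P + v
      infused <- infused + v
      if (fl == "dextrose5") G <- G + v
      if (fl == "albumin20") AlbIV <- AlbIV + v * 0.2  # 20% w/v -> grams
    }
    # (2) glucose metabolism: freed water 2/3 plasma -> intracellular
    m <- lambda * G * dt
    G <- G - m
    C <- C + (2 / 3) * m
    P <- P - (2 / 3) * m
    # (2b) osmotic intracellular -> interstitial shift tracking the pool
    f_os <- params$glucose_osmotic_rate *
      (params$glucose_osmotic_shift * G - S) * dt
    C <- C - f_os; I <- I + f_os; S <- S + f_os
    # albumin-held expansion volume (ml) recruited beyond baseline plasma
    v_onc <- (exf - 1) * AlbIV / 0.2
    # (3) transcapillary refill toward the oncotic plasma target
    f_r <- params$refill_rate * (b$plasma + v_onc - P) * dt
    P <- P + f_r; I <- I - f_r
    # (4) crystalloid equilibration toward 1:3 plasma:interstitial excess
    #     of the free (non-albumin-held) water
    eP <- P - b$plasma - v_onc; eI <- I - b$interstitial
    f_eq <- params$equil_rate * (eP - 0.25 * (eP + eI)) * dt
    P <- P - f_eq; I <- I + f_eq
    # (5) albumin leak; leaked albumin draws intracellular water
    leak <- params$albumin_leak_rate * AlbIV * dt
    AlbIV <- AlbIV - leak; AlbIS <- AlbIS + leak
    w_pull <- params$icw_pull_coefficient * (leak / 0.2)
    C <- C - w_pull; I <- I + w_pull
    # (5b) reversible oncotic intracellular shift tracking intravascular
    #      albumin; recruited fast, released slowly as albumin leaks away
    gap <- params$icw_osmotic_per_g * AlbIV - Wa
    k_oc <- if (gap >= 0) params$icw_osmotic_rate
            else params$icw_osmotic_release_rate
    f_oc <- k_oc * gap * dt
    C <- C - f_oc; I <- I + f_oc; Wa <- Wa + f_oc
    # (6) instantaneous bleed events at the step's end time
    tk <- t_grid[k]
    hit <- abs(protocol$bleed_events$time - tk) < 1e-9
    if (any(hit)) {
      v <- sum(protocol$bleed_events$volume[hit])
      P <- P - v * (1 - hct)
      C <- C - v * hct
      rbc <- rbc - v * hct
      bled <- bled + v
    }
    if (min(P, I, C, G, AlbIV, rbc) < -1e-9) {
      abort(sprintf(
        "compartment volume went negative at t = %g min (P=%.1f I=%.1f C=%.1f)",
        tk, P, I, C), "hemobia_negative_volume")
    }
    out[k, ] <- c(P, I, C, rbc + P, G, S, Wa, AlbIV, AlbIS, infused, bled)
  }

  df <- data.frame(t = t_grid, out)
  attr(df, "baseline") <- b
  attr(df, "params") <- params
  class(df) <- c("compartment_sim", "data.frame")
  df
}

#' Segment water volumes from a compartment state
#'
#' @param state One row of a \code{compartment_sim} (or a list with
#'   \code{plasma}, \code{interstitial}, \code{intracellular}).
#' @param params The \code{subject_params}.
#' @param segment Segment name.
#' @return List with \code{ecw} and \code{icw} in ml for the segment.
#' @export
segment_water <- function(state, params, segment) {
  segment <- match.arg(segment, SEGMENTS)
  fr <- params$segment_fractions[[segment]]
  list(ecw = fr * (state$plasma + state$interstitial),
       icw = fr * state$intracellular)
}

cole_magnitude <- function(r0, rinf, f_c, alpha, freq) {
  z <- rinf + (r0 - rinf) / (1 + (1i * freq / f_c)^alpha)
  Mod(z)
}

#' Cole-model impedance magnitude of a body segment
#'
#' Maps segment water volumes to impedance through a Cole dispersion:
#' the zero-frequency resistance is \code{R0 = k_e / ECW} (litres) and the
#' infinite-frequency resistance the parallel combination
#' \code{R0 Ri / (R0 + Ri)} with \code{Ri = k_i / ICW}, so that low-frequency
#' current is confined to extracellular water while high-frequency current
#' also samples the intracellular path. The magnitude is strictly decreasing
#' in frequency and in each water volume.
#'
#' @param state One row of a \code{compartment_sim}.
#' @param params A \code{subject_params}.
#' @param segment Segment name.
#' @param frequency Frequency in kHz (vectorized).
#' @return Impedance magnitude(s) in ohms.
#' @export
cole_impedance <- function(state, params, segment, frequency) {
  sw <- segment_water(state, params, segment)
  if (sw$ecw <= 0 || sw$icw <= 0) {
    abort("segment water volumes must be positive", "hemobia_bad_volume")
  }
  r0 <- params$cole$k_e / (sw$ecw / 1000)
  ri <- params$cole$k_i / (sw$icw / 1000)
  rinf <- r0 * ri / (r0 + ri)
  cole_magnitude(r0, rinf, params$cole$f_c, params$cole$alpha, frequency)
}

#' Hemodynamics from circulating blood volume
#'
#' With \code{phi} the circulating blood volume relative to baseline, a
#' saturating response \code{g(phi) = 2 phi^m / (1 + phi^m)} (so
#' \code{g(1) = 1}) drives the vitals: \code{SV = SV0 g}, \code{MAP = MAP0 g},
#' \code{PR = PR0 (2 - g)}, \code{SVV = SVV0 + s (1 - g)}. A MAP below
#' \code{map_detect_floor} means the arterial waveform is lost and MAP, SV
#' and SVV are returned missing.
#'
#' @param state One row of a \code{compartment_sim}.
#' @param params A \code{subject_params}.
#' @return List \code{(t, PR, MAP, SV, SVV)}; MAP/SV/SVV are \code{NA} when
#'   MAP falls below the detection floor.
#' @export
hemodynamics_from_volume <- function(state, params) {
  b <- baseline_state(params)
  phi <- state$circulating_blood / b$blood
  g <- 2 * phi^params$hemo_shape / (1 + phi^params$hemo_shape)
  h <- params$hemo_baseline
  map <- h$MAP0 * g
  rec <- list(t = state$t,
              PR = h$PR0 * (2 - g),
              MAP = map,
              SV = h$SV0 * g,
              SVV = h$SVV0 + params$svv_sensitivity * (1 - g))
  if (map < params$map_detect_floor) {
    rec$MAP <- NA_real_; rec$SV <- NA_real_; rec$SVV <- NA_real_
  }
  rec
}

truncnorm1 <- function(mean, sd, lower, upper) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
}

#' Generate a synthetic cohort dataset
#'
#' Samples per-subject weights and hemodynamic baselines around the template,
#' simulates compartment kinetics, and emits measured impedance and vitals
#' tables at the protocol schedules, plus the ground-truth compartment
#' trajectories. Impedance noise is multiplicative Gaussian with coefficient
#' of variation \code{noise_cv}; vitals noise is additive Gaussian with the
#' per-variable standard deviations in \code{vitals_noise}. A single RNG
#' stream is seeded once per dataset, so a fixed seed reproduces the tables
#' exactly.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param group Protocol group (see \code{\link{standard_protocol}}).
#' @param params_template A \code{\link{subject_params}} around which
#'   subjects are sampled.
#' @param protocol Optional protocol; defaults to the group's standard one.
#' @param noise_cv Impedance noise CV; 0 for noise-free output.
#' @param vitals_noise Named additive noise SDs for PR (bpm), MAP (mmHg),
#'   SV (ml), SVV (\%); scaled to 0 when \code{noise_cv = 0}.
#' @param subject_sd Named SDs for between-subject sampling of weight and
#'   hemodynamic baselines.
#' @param seed Integer RNG seed.
#' @param dt Simulation time step (min).
#' @return List with data frames \code{impedance} (subject_id, t_min, segment,
#'   frequency_khz, z_ohm), \code{vitals} (subject_id, t_min, pr, map, sv,
#'   svv), \code{truth} (per-step compartment volumes), and \code{subjects}
#'   (sampled parameters).
#' @export
generate_dataset <- function(n_subjects = 5, group = GROUPS,
                             params_template = subject_params(),
                             protocol = NULL,
                             noise_cv = params_template$noise_cv,
                             vitals_noise = c(PR = 2, MAP = 1.5,
                                              SV = 1.5, SVV = 0.8),
                             subject_sd = c(weight = 3.2, MAP0 = 2.5,
                                            SV0 = 4, PR0 = 6, SVV0 = 1),
                             seed = 1, dt = 0.5) {
  if (n_subjects < 1) abort("n_subjects must be >= 1", "hemobia_bad_params")
  group <- match.arg(group)
  protocol <- protocol %||% standard_protocol(group)
  if (noise_cv == 0) vitals_noise[] <- 0
  set.seed(seed)

  sched <- measurement_schedule(protocol)
  vsched <- vitals_schedule(protocol)
  imp_list <- vit_list <- truth_list <- list()
  subj_rows <- list()

  for (s in seq_len(n_subjects)) {
    p <- params_template
    p$weight <- truncnorm1(37.7, subject_sd[["weight"]], 34.2, 41.5)
    p$hemo_baseline <- list(
      PR0 = stats::rnorm(1, params_template$hemo_baseline$PR0,
                         subject_sd[["PR0"]]),
      MAP0 = stats::rnorm(1, params_template$hemo_baseline$MAP0,
                          subject_sd[["MAP0"]]),
      SV0 = stats::rnorm(1, params_template$hemo_baseline$SV0,
                         subject_sd[["SV0"]]),
      SVV0 = stats::rnorm(1, params_template$hemo_baseline$SVV0,
                          subject_sd[["SVV0"]]))
    sim <- simulate_compartments(p, protocol, dt = dt)
    sid <- sprintf("%s_%02d", group, s)

    rows <- sim[match(sched, sim$t), ]
    grid <- expand.grid(t_min = sched, segment = SEGMENTS,
                        frequency_khz = FREQUENCIES_KHZ,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    z <- numeric(nrow(grid))
    for (seg in SEGMENTS) {
      sel <- grid$segment == seg
      idx <- match(grid$t_min[sel], sched)
      fr <- p$segment_fractions[[seg]]
      ecw <- fr * (rows$plasma[idx] + rows$interstitial[idx]) / 1000
      icw <- fr * rows$intracellular[idx] / 1000
      r0 <- p$cole$k_e / ecw
      ri <- p$cole$k_i / icw
      rinf <- r0 * ri / (r0 + ri)
      z[sel] <- cole_magnitude(r0, rinf, p$cole$f_c, p$cole$alpha,
                               grid$frequency_khz[sel])
    }
    if (noise_cv > 0) {
      z <- z * (1 + stats::rnorm(length(z), 0, noise_cv))
    }
    imp_list[[s]] <- data.frame(subject_id = sid, grid, z_ohm = z)

    vrows <- sim[match(vsched, sim$t), ]
    hb <- p$hemo_baseline
    phi <- vrows$circulating_blood / baseline_state(p)$blood
    g <- 2 * phi^p$hemo_shape / (1 + phi^p$hemo_shape)
    pr <- hb$PR0 * (2 - g) + stats::rnorm(length(g), 0, vitals_noise[["PR"]])
    map <- hb$MAP0 * g + stats::rnorm(length(g), 0, vitals_noise[["MAP"]])
    sv <- hb$SV0 * g + stats::rnorm(length(g), 0, vitals_noise[["SV"]])
    svv <- hb$SVV0 + p$svv_sensitivity * (1 - g) +
      stats::rnorm(length(g), 0, vitals_noise[["SVV"]])
    lost <- map < p$map_detect_floor
    map[lost] <- NA_real_; sv[lost] <- NA_real_; svv[lost] <- NA_real_
    vit_list[[s]] <- data.frame(subject_id = sid, t_min = vsched,
                                pr = pr, map = map, sv = sv, svv = svv)

    tr <- data.frame(subject_id = sid, t_min = sim$t,
                     plasma = sim$plasma, interstitial = sim$interstitial,
                     intracellular = sim$intracellular,
                     circulating_blood = sim$circulating_blood)
    truth_list[[s]] <- tr
    subj_rows[[s]] <- data.frame(subject_id = sid, weight = p$weight,
                                 PR0 = hb$PR0, MAP0 = hb$MAP0,
                                 SV0 = hb$SV0, SVV0 = hb$SVV0)
  }

  list(impedance = do.call(rbind, imp_list),
       vitals = do.call(rbind, vit_list),
       truth = do.call(rbind, truth_list),
       subjects = do.call(rbind, subj_rows),
       group = group, protocol = protocol)
}
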