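#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the simulated study: cohort size and phenotype
#' distributions, respirometry chamber constants and phase cadence, and the
#' telemetry/movement settings. Defaults emulate the study design the package
#' targets: ~23 perch of 54.2 +/- 15.3 g and 16.4 +/- 1.4 cm fork length,
#' 22 h intermittent-flow respirometry traces at 16 C with a chase-elicited
#' maximum, and 19 days of 30 s burst-interval positions in a ~1 ha lake with
#' 0.2 m positional noise and two-state (active/inactive) switching movement.
#'
#' @param n_fish number of fish in the cohort.
#' @param seed master RNG seed; all generators are pure functions of
#'   (config, seed).
#' @param burst_interval transmitter burst interval in seconds.
#' @param position_noise_sd per-axis positional error SD in metres.
#' @param lake_boundary two-column matrix of polygon vertices (metres); must be
#'   a simple polygon. Default is a 100 x 100 m square (1 ha).
#' @param trace_duration respirometry trace length in hours.
#' @param sample_period oxygen sampling period in seconds; must divide both
#'   phase durations.
#' @param n_days_track days of telemetry positions to simulate.
#' @param flush_duration,measure_duration respirometry phase lengths (seconds).
#' @param chamber_volume respirometer volume in litres.
#' @param beta oxygen solubility (mg O2 l^-1 kPa^-1).
#' @param o2_saturation air-saturated oxygen partial pressure (kPa).
#' @param sensor_noise_sd Gaussian sensor noise SD on the O2 channel (kPa).
#' @param blank_slope background (microbial) respiration slope added to every
#'   measure phase (kPa h^-1); recorded as ground truth.
#' @param diel_amplitude relative amplitude of the sinusoidal diel modulation
#'   of spontaneous-activity excursions (0 disables).
#' @param excursion_frac median spontaneous-activity excursion as a fraction
#'   of the fish's standard metabolic rate.
#' @param excursion_sdlog log-SD of the lognormal excursions.
#' @param mass_mean,mass_sd cohort body-mass distribution (g).
#' @param fl_mean,fl_sd cohort fork-length distribution (cm).
#' @param fr_mean,fr_sd cohort fineness-ratio distribution (unitless).
#' @param smr_mean,smr_sd,mmr_mean,mmr_sd cohort standard and maximal
#'   metabolic-rate distributions (mg O2 kg^-1 h^-1).
#' @param mass_scaling_exponent exponent of mass-specific metabolic rate on
#'   body mass (whole-animal exponent minus one; default -0.2).
#' @param length_sdlog lognormal scatter of fork length about the allometric
#'   mass-length curve.
#' @param halflife_mean,halflife_sd post-chase recovery half-life (hours).
#' @param prob_become_active,prob_become_inactive per-step switching
#'   probabilities of the two-state behaviour chain.
#' @param speed_mean,speed_sd cohort distribution of mean active swimming
#'   speed (m s^-1).
#' @param step_shape gamma shape of active-state step lengths.
#' @param turn_sd SD (radians) of the wrapped-normal turning angles of the
#'   active-state correlated random walk.
#' @param dropout_prob independent probability that an emitted fix is lost.
#' @param release_time absolute timestamp (seconds) of release into the lake.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_fish = 23L, seed = 1L,
                       burst_interval = 30, position_noise_sd = 0.2,
                       lake_boundary = NULL,
                       trace_duration = 22, sample_period = 5,
                       n_days_track = 19,
                       flush_duration = 300, measure_duration = 600,
                       chamber_volume = 0.54, beta = 0.4755,
                       o2_saturation = 21.0, sensor_noise_sd = 0.02,
                       blank_slope = 0.3,
                       diel_amplitude = 0.5, excursion_frac = 0.1,
                       excursion_sdlog = 1.0,
                       mass_mean = 54.2, mass_sd = 15.3,
                       fl_mean = 16.4, fl_sd = 1.4,
                       fr_mean = 5.9, fr_sd = 0.3,
                       smr_mean = 79.0, smr_sd = 9.9,
                       mmr_mean = 392.8, mmr_sd = 61.1,
                       mass_scaling_exponent = -0.2,
                       length_sdlog = 0.03,
                       halflife_mean = 1.0, halflife_sd = 0.2,
                       prob_become_active = 0.02,
                       prob_become_inactive = 0.10,
                       speed_mean = 0.25, speed_sd = 0.05,
                       step_shape = 2, turn_sd = 0.6,
                       dropout_prob = 0.05,
                       release_time = 0) {
  if (is.null(lake_boundary)) {
    lake_boundary <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  }
  lake_boundary <- as.matrix(lake_boundary)
  cfg <- list(
    n_fish = as.integer(n_fish), seed = as.integer(seed),
    burst_interval = burst_interval, position_noise_sd = position_noise_sd,
    lake_boundary = lake_boundary,
    trace_duration = trace_duration, sample_period = sample_period,
    n_days_track = n_days_track,
    flush_duration = flush_duration, measure_duration = measure_duration,
    chamber_volume = chamber_volume, beta = beta,
    o2_saturation = o2_saturation, sensor_noise_sd = sensor_noise_sd,
    blank_slope = blank_slope,
    diel_amplitude = diel_amplitude, excursion_frac = excursion_frac,
    excursion_sdlog = excursion_sdlog,
    mass_mean = mass_mean, mass_sd = mass_sd,
    fl_mean = fl_mean, fl_sd = fl_sd,
    fr_mean = fr_mean, fr_sd = fr_sd,
    smr_mean = smr_mean, smr_sd = smr_sd,
    mmr_mean = mmr_mean, mmr_sd = mmr_sd,
    mass_scaling_exponent = mass_scaling_exponent,
    length_sdlog = length_sdlog,
    halflife_mean = halflife_mean, halflife_sd = halflife_sd,
    prob_become_active = prob_become_active,
    prob_become_inactive = prob_become_inactive,
    speed_mean = speed_mean, speed_sd = speed_sd,
    step_shape = step_shape, turn_sd = turn_sd,
    dropout_prob = dropout_prob,
    release_time = release_time
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_fish < 1L) stop("n_fish must be >= 1", call. = FALSE)
  if (cfg$burst_interval <= 0) stop("burst_interval must be > 0", call. = FALSE)
  if (cfg$trace_duration <= 0) stop("trace_duration must be > 0", call. = FALSE)
  if (!is.matrix(cfg$lake_boundary) || ncol(cfg$lake_boundary) != 2 ||
      nrow(cfg$lake_boundary) < 3) {
    stop("lake_boundary must be an n x 2 matrix with n >= 3", call. = FALSE)
  }
  if (polygon_self_intersects(cfg$lake_boundary)) {
    stop("lake_boundary must be a simple (non-self-intersecting) polygon",
         call. = FALSE)
  }
  invisible(cfg)
}

# Check non-adjacent edge pairs for proper crossings.
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- function(i) rbind(poly[i, ], poly[if (i == n) 1 else i + 1, ])
  cross2 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next  # adjacent through closure
      s1 <- seg(i); s2 <- seg(j)
      d1 <- cross2(s1[1, ], s1[2, ], s2[1, ])
      d2 <- cross2(s1[1, ], s1[2, ], s2[2, ])
      d3 <- cross2(s2[1, ], s2[2, ], s1[1, ])
      d4 <- cross2(s2[1, ], s2[2, ], s1[2, ])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Generate a cohort of fish with known phenotypes
#'
#' Draws body mass from a truncated normal, couples fork length to mass
#' allometrically (mass proportional to length cubed, with lognormal scatter)
#' so that log10-log10 mass corrections downstream see realistic structure,
#' derives body depth from a truncated-normal fineness ratio, and draws true
#' standard and maximal metabolic rates on the log scale with a configurable
#' mass-scaling exponent. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` with one row per fish: `fish_id`, `fish_idx`,
#'   `body_mass` (g), `fork_length` (cm), `body_depth` (cm), `true_smr`,
#'   `true_mmr` (mg O2 kg^-1 h^-1), `recovery_halflife` (h),
#'   `activity_propensity` (per-step probability of switching to the active
#'   state), `mean_active_speed` (m s^-1).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  n <- config$n_fish
  with_seed(sub_seed(config$seed, 1L), {
    mass <- rnorm_trunc(n, config$mass_mean, config$mass_sd, lower = 1)
    # allometric length: FL = c * M^(1/3) * lognormal scatter, c set so the
    # configured mean mass maps to the configured mean fork length
    cc <- config$fl_mean / config$mass_mean^(1 / 3)
    fl <- cc * mass^(1 / 3) * rlnorm(n, 0, config$length_sdlog)
    fr <- rnorm_trunc(n, config$fr_mean, config$fr_sd, lower = 1.2)
    depth <- fl / fr
    lmass <- log10(mass / config$mass_mean)
    b <- config$mass_scaling_exponent
    smr <- 10^(log10(config$smr_mean) + b * lmass +
                 rnorm(n, 0, config$smr_sd / config$smr_mean / log(10)))
    mmr <- 10^(log10(config$mmr_mean) + b * lmass +
                 rnorm(n, 0, config$mmr_sd / config$mmr_mean / log(10)))
    bad <- which(mmr <= smr * 1.2)
    guard <- 0L
    while (length(bad) > 0L && guard < 100L) {
      mmr[bad] <- 10^(log10(config$mmr_mean) + b * lmass[bad] +
                        rnorm(length(bad), 0, config$mmr_sd / config$mmr_mean / log(10)))
      bad <- which(mmr <= smr * 1.2)
      guard <- guard + 1L
    }
    if (length(bad)) mmr[bad] <- smr[bad] * 2
    data.frame(
      fish_id = sprintf("F%02d", seq_len(n)),
      fish_idx = seq_len(n),
      body_mass = mass,
      fork_length = fl,
      body_depth = depth,
      true_smr = smr,
      true_mmr = mmr,
      recovery_halflife = rnorm_trunc(n, config$halflife_mean,
                                      config$halflife_sd, lower = 0.2),
      activity_propensity = rnorm_trunc(n, config$prob_become_active,
                                        config$prob_become_active / 4,
                                        lower = 1e-4, upper = 1),
      mean_active_speed = rnorm_trunc(n, config$speed_mean, config$speed_sd,
                                      lower = 0.05),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate an intermittent-flow respirometry trace
#'
#' Emits a raw oxygen partial-pressure series (kPa) with alternating measure
#' and flush phases. The underlying oxygen-uptake rate declines exponentially
#' from the fish's maximal rate (chase protocol ends at time zero) toward its
#' standard rate, with additive lognormal spontaneous-activity excursions
#' (optionally diel-modulated). Within each measure phase the O2 channel
#' declines linearly with the slope obtained by inverting the uptake equation
#' MO2 = K V beta / M for that cycle's true rate, plus the configured constant
#' background slope and Gaussian sensor noise; flush phases relax back to air
#' saturation. Per-cycle ground truth is stored in the `truth` element.
#'
#' @param phenotype one row of [generate_cohort()] output.
#' @param config a [sim_config()].
#' @return a `respirometry_trace` object (see [respirometry_trace()]) with an
#'   extra `truth` data.frame: per cycle, the midpoint time (h), true oxygen
#'   uptake (mg O2 kg^-1 h^-1) and true total slope (kPa h^-1).
#' @export
simulate_respirometry_trace <- function(phenotype, config) {
  stopifnot(inherits(config, "sim_config"))
  if ((config$measure_duration %% config$sample_period) != 0 ||
      (config$flush_duration %% config$sample_period) != 0) {
    stop("sample_period must divide both phase durations", call. = FALSE)
  }
  ph <- as.list(phenotype)
  mass_kg <- ph$body_mass / 1000
  v_eff <- config$chamber_volume - mass_kg  # density 1 g ml^-1
  if (v_eff <= 0) stop("fish displaces the whole chamber volume", call. = FALSE)

  cycle_len <- config$measure_duration + config$flush_duration
  n_cycles <- floor(config$trace_duration * 3600 / cycle_len)
  lambda <- log(2) / ph$recovery_halflife  # 1/h

  with_seed(sub_seed(config$seed, 100L + ph$fish_idx), {
    t0 <- (seq_len(n_cycles) - 1) * cycle_len / 3600  # measure start, hours
    t1 <- t0 + config$measure_duration / 3600
    # cycle-average of the recovery curve smr + (mmr-smr) exp(-lambda t)
    base <- ph$true_smr + (ph$true_mmr - ph$true_smr) *
      (exp(-lambda * t0) - exp(-lambda * t1)) / (lambda * (t1 - t0))
    tmid <- (t0 + t1) / 2
    diel <- 1 + config$diel_amplitude * sin(2 * pi * (tmid + 8) / 24)
    diel <- pmax(diel, 0)
    exc <- rlnorm(n_cycles, log(config$excursion_frac * ph$true_smr),
                  config$excursion_sdlog) * diel
    # exhausted fish ramp spontaneous activity back up as they recover
    exc <- exc * (1 - exp(-lambda * tmid))
    true_mo2 <- base + exc
    true_k <- true_mo2 * mass_kg / (v_eff * config$beta)  # kPa/h, fish only
    slope_total <- true_k + config$blank_slope

    dt <- config$sample_period / 3600  # hours
    n_meas <- config$measure_duration / config$sample_period
    n_flush <- config$flush_duration / config$sample_period
    times <- o2 <- numeric(0)
    phase <- character(0)
    sat <- config$o2_saturation
    for (k in seq_len(n_cycles)) {
      tm <- t0[k] + dt * (seq_len(n_meas) - 1)
      om <- sat - slope_total[k] * (tm - t0[k])
      tf <- t1[k] + dt * (seq_len(n_flush) - 1)
      # flush relaxes linearly back up to saturation
      o_end <- om[n_meas] - slope_total[k] * dt
      of <- pmin(sat, o_end + (sat - o_end) * seq_len(n_flush) / (n_flush * 0.6))
      times <- c(times, tm, tf)
      o2 <- c(o2, om, of)
      phase <- c(phase, rep("measure", n_meas), rep("flush", n_flush))
    }
    if (config$sensor_noise_sd > 0) {
      o2 <- o2 + rnorm(length(o2), 0, config$sensor_noise_sd)
    }
    tr <- respirometry_trace(
      fish_id = ph$fish_id,
      samples = data.frame(time_h = times, o2_kpa = o2, phase = phase,
                           stringsAsFactors = FALSE),
      chamber_volume = config$chamber_volume,
      body_mass = mass_kg,
      beta = config$beta,
      blank_slope = config$blank_slope
    )
    tr$truth <- data.frame(cycle = seq_len(n_cycles), t_mid = tmid,
                           true_mo2 = true_mo2, true_slope = slope_total)
    tr
  })
}

#' Simulate a telemetry track with hidden behavioural states
#'
#' A two-state (inactive/active) Markov chain at the burst-interval time step
#' drives a correlated random walk: inactive steps have zero true
#' displacement; active steps draw gamma step lengths (mean =
#' `mean_active_speed * burst_interval`) and wrapped-normal turning angles.
#' Proposed steps leaving the lake polygon are specularly reflected at the
#' crossed edge (with a stay-put fallback at corners). Isotropic Gaussian
#' noise is added to every emitted fix and fixes are dropped independently
#' with `config$dropout_prob` to emulate detection failure. True positions
#' and states are kept for validation.
#'
#' @param phenotype one row of [generate_cohort()] output.
#' @param config a [sim_config()].
#' @return a `data.frame` of emitted fixes: `fish_id`, `timestamp_s`, `x_m`,
#'   `y_m`, `true_state` (1 = inactive, 2 = active), `true_x`, `true_y`.
#'   The full (pre-dropout) series is attached as attribute `"truth"`.
#' @export
simulate_track <- function(phenotype, config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  ph <- as.list(phenotype)
  n_steps <- floor(config$n_days_track * 86400 / config$burst_interval)
  poly <- config$lake_boundary
  s <- ph$activity_propensity             # inactive -> active
  r <- config$prob_become_inactive        # active -> inactive
  shape <- config$step_shape
  scale <- ph$mean_active_speed * config$burst_interval / shape

  with_seed(sub_seed(config$seed, 5000L + ph$fish_idx), {
    state <- integer(n_steps + 1L)
    state[1] <- 1L
    u <- runif(n_steps)
    for (i in seq_len(n_steps)) {
      state[i + 1L] <- if (state[i] == 1L) {
        if (u[i] < s) 2L else 1L
      } else {
        if (u[i] < r) 1L else 2L
      }
    }
    centroid <- colMeans(poly)
    xs <- ys <- numeric(n_steps + 1L)
    xs[1] <- centroid[1]; ys[1] <- centroid[2]
    heading <- runif(1, 0, 2 * pi)
    active <- state[-1] == 2L
    lens <- numeric(n_steps)
    lens[active] <- rgamma(sum(active), shape = shape, scale = scale)
    turns <- rnorm(n_steps, 0, config$turn_sd)
    for (i in seq_len(n_steps)) {
      if (lens[i] == 0) {
        xs[i + 1L] <- xs[i]; ys[i + 1L] <- ys[i]
        next
      }
      heading <- heading + turns[i]
      px <- xs[i] + lens[i] * cos(heading)
      py <- ys[i] + lens[i] * sin(heading)
      if (!point_in_polygon(px, py, poly)) {
        ref <- reflect_step(xs[i], ys[i], px, py, poly)
        px <- ref[1]; py <- ref[2]
        if (!point_in_polygon(px, py, poly)) { px <- xs[i]; py <- ys[i] }
      }
      xs[i + 1L] <- px; ys[i + 1L] <- py
    }
    ts <- config$release_time + config$burst_interval * (0:n_steps)
    noise_x <- rnorm(n_steps + 1L, 0, config$position_noise_sd)
    noise_y <- rnorm(n_steps + 1L, 0, config$position_noise_sd)
    full <- data.frame(
      fish_id = ph$fish_id,
      timestamp_s = ts,
      x_m = xs + noise_x,
      y_m = ys + noise_y,
      true_state = state,
      true_x = xs,
      true_y = ys,
      stringsAsFactors = FALSE
    )
    keep <- runif(n_steps + 1L) >= config$dropout_prob
    out <- full[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "truth") <- full
    out
  })
}

# Specular reflection of the segment (x0,y0)->(px,py) at the first boundary
# edge it crosses.
reflect_step <- function(x0, y0, px, py, poly) {
  n <- nrow(poly)
  best_t <- Inf; best_edge <- NULL
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[j, 1]; by <- poly[j, 2]
    dx <- px - x0; dy <- py - y0
    ex <- bx - ax; ey <- by - ay
    den <- dx * ey - dy * ex
    if (abs(den) < 1e-12) next
    t <- ((ax - x0) * ey - (ay - y0) * ex) / den
    s <- ((ax - x0) * dy - (ay - y0) * dx) / den
    if (t > 1e-9 && t <= 1 && s >= 0 && s <= 1 && t < best_t) {
      best_t <- t; best_edge <- c(ex, ey)
    }
  }
  if (is.null(best_edge)) return(c(x0, y0))
  # reflect the overshoot across the edge direction
  ix <- x0 + best_t * (px - x0); iy <- y0 + best_t * (py - y0)
  vx <- px - ix; vy <- py - iy
  e <- best_edge / sqrt(sum(best_edge^2))
  dot <- vx * e[1] + vy * e[2]
  rx <- 2 * dot * e[1] - vx
  ry <- 2 * dot * e[2] - vy
  c(ix + rx, iy + ry)
}

#' Materialize a full synthetic cohort as CSV fixtures
#'
#' Writes `phenotypes.csv`, one `trace_<id>.csv` per fish (columns `time_s`,
#' `o2_kpa`, `phase`) and one `track_<id>.csv` per fish (columns `fish_id`,
#' `timestamp_s`, `x_m`, `y_m`, `true_state`) under `dir`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the cohort phenotype table.
#' @export
write_cohort <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config)
  write.csv(cohort, file.path(dir, "phenotypes.csv"), row.names = FALSE)
  for (i in seq_len(nrow(cohort))) {
    tr <- simulate_respirometry_trace(cohort[i, ], config)
    s <- tr$samples
    write.csv(
      data.frame(time_s = s$time_h * 3600, o2_kpa = s$o2_kpa, phase = s$phase),
      file.path(dir, sprintf("trace_%s.csv", cohort$fish_id[i])),
      row.names = FALSE
    )
    tk <- simulate_track(cohort[i, ], config)
    write.csv(
      tk[, c("fish_id", "timestamp_s", "x_m", "y_m", "true_state")],
      file.path(dir, sprintf("track_%s.csv", cohort$fish_id[i])),
      row.names = FALSE
    )
  }
  invisible(cohort)
}
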