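#' Simulation parameters for a synthetic actigraphy animal
#'
#' The generator models a latent activity drive `s(t)` in `[0, 1]`. Under an
#' LD schedule the drive relaxes exponentially towards 1 starting
#' `onset_latency` minutes after each lights-off (time constant `rise_time`)
#' and decays towards `light_suppression` at lights-on (time constant
#' `fall_time`); under DD the same dynamics follow a free-running subjective
#' night of period `tau` hours (half the cycle active). Expected counts per
#' bin are `baseline_rate + amplitude * s`; emitted counts are negative
#' binomial with the given `dispersion` (Poisson in the `Inf` limit; the
#' rounded mean in deterministic mode). Body temperature is the drive passed
#' through a first-order low-pass of time constant `temp_smooth`, scaled to
#' `temp_base + temp_amplitude * s_filtered` plus Gaussian noise.
#'
#' @param baseline_rate Expected counts per bin during rest (counts/bin).
#' @param amplitude Added expected counts per bin at full drive.
#' @param light_suppression Fraction of drive expressed during lights-on,
#'   in `[0, 1]` (masking strength; 0 = complete suppression).
#' @param onset_latency Minutes from lights-off to the start of the drive rise.
#' @param rise_time Minutes for the drive to reach `1 - exp(-1)` of full
#'   after the latency (exponential time constant).
#' @param fall_time Minutes of drive decay time constant at lights-on.
#' @param tau Free-running period in hours, used under DD; must lie in
#'   `[20, 28]`.
#' @param dispersion Negative binomial size parameter (`Inf` = Poisson).
#' @param temp_base Baseline body temperature, degrees C.
#' @param temp_amplitude Day-night temperature swing at full drive, degrees C.
#' @param temp_smooth Low-pass time constant (minutes) coupling the drive to
#'   temperature.
#' @param temp_noise_sd Gaussian temperature noise SD, degrees C.
#' @param deterministic If `TRUE`, all noise is disabled and the output is
#'   bit-identical for identical inputs irrespective of the seed.
#' @param waveform `"relaxation"` (rectified smoothed oscillator with a
#'   defined rising edge, the default) or `"cosine"` (pure sinusoid, for
#'   spectral tests).
#' @param ultradian_period_min Optional ultradian bout modulation: period in
#'   minutes of an on/off square modulation of the drive (0 = off, default).
#' @param ultradian_duty Fraction of the ultradian cycle spent "on".
#'
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(baseline_rate = 2, amplitude = 40,
                       light_suppression = 0.05,
                       onset_latency = 40, rise_time = 30, fall_time = 20,
                       tau = 23.7, dispersion = Inf,
                       temp_base = 36.2, temp_amplitude = 1.2,
                       temp_smooth = 45, temp_noise_sd = 0.1,
                       deterministic = FALSE,
                       waveform = c("relaxation", "cosine"),
                       ultradian_period_min = 0, ultradian_duty = 0.5) {
  waveform <- match.arg(waveform)
  stopifnot(baseline_rate >= 0, amplitude >= 0,
            light_suppression >= 0, light_suppression <= 1,
            onset_latency >= 0, rise_time > 0, fall_time > 0,
            tau >= 20, tau <= 28, dispersion > 0,
            temp_smooth > 0, temp_noise_sd >= 0,
            ultradian_period_min >= 0,
            ultradian_duty > 0, ultradian_duty <= 1)
  structure(as.list(environment()), class = "sim_params")
}

#' Genotype-like parameter presets
#'
#' Two presets mirroring the contrast the pipeline is designed to resolve:
#' `wt_like` with a free-running period of 23.7 h (the canonical laboratory
#' mouse value) and the default lights-off response, and `del_like` with a
#' period 5.3 min longer and a strictly faster lights-off response (shorter
#' `onset_latency` and `rise_time`), emulating a line hypersensitive to the
#' light-to-dark transition. All other numbers are shared implementation
#' defaults.
#'
#' @return Named list of two [sim_params()] objects, `wt_like` and `del_like`.
#' @export
genotype_presets <- function() {
  list(
    wt_like  = sim_params(),
    del_like = sim_params(onset_latency = 15, rise_time = 12,
                          tau = 23.7 + 5.3 / 60)
  )
}

# Event times (seconds) at which the drive target switches, over [t_lo, t_hi].
# Covers the LD portion (real light transitions) and the DD portion
# (subjective transitions free-running at period tau).
drive_events <- function(params, schedule, t_lo, t_hi) {
  dd0 <- schedule$dd_start_s
  ev_t <- numeric(0); ev_k <- character(0)
  ld_hi <- if (is.na(dd0)) t_hi else min(t_hi, dd0)
  if (ld_hi > t_lo) {
    cyc_s <- schedule$cycle_length * 3600
    for (b in list(c(0, 1), c(schedule$lights_off_zt, 2))) {
      t_first <- ((b[1] - schedule$anchor_zt) %% schedule$cycle_length) * 3600
      k0 <- ceiling((t_lo - t_first) / cyc_s); k1 <- floor((ld_hi - t_first) / cyc_s)
      if (k1 < k0) next
      tt <- t_first + (k0:k1) * cyc_s
      tt <- tt[tt >= t_lo & tt <= ld_hi]
      ev_t <- c(ev_t, tt)
      ev_k <- c(ev_k, rep(if (b[2] == 1) "on" else "off", length(tt)))
    }
  }
  if (!is.na(dd0) && t_hi > dd0) {
    tau_s <- params$tau * 3600
    c0 <- (schedule$anchor_zt + dd0 / 3600) %% 24  # circadian phase at DD start
    for (b in list(c(0, "on"), c(schedule$lights_off_zt, "off"))) {
      z <- as.numeric(b[1])
      t_first <- dd0 + ((z - c0) %% 24) / 24 * tau_s
      k0 <- ceiling((max(t_lo, dd0) - t_first) / tau_s)
      k1 <- floor((t_hi - t_first) / tau_s)
      if (k1 < k0) next
      tt <- t_first + (k0:k1) * tau_s
      tt <- tt[tt >= max(t_lo, dd0) & tt <= t_hi]
      ev_t <- c(ev_t, tt)
      ev_k <- c(ev_k, rep(b[2], length(tt)))
    }
  }
  o <- order(ev_t)
  list(time_s = ev_t[o], kind = ev_k[o])
}

# Subjective/zeitgeber phase in [0, 24): ZT before dd_start, free-running at
# period tau after.
circadian_phase <- function(t_s, params, schedule) {
  dd0 <- schedule$dd_start_s
  ph <- (schedule$anchor_zt + t_s / 3600) %% schedule$cycle_length
  if (!is.na(dd0)) {
    dd <- t_s >= dd0
    c0 <- (schedule$anchor_zt + dd0 / 3600) %% schedule$cycle_length
    ph[dd] <- (c0 + (t_s[dd] - dd0) / 3600 * 24 / params$tau) %% 24
  }
  ph
}

#' Evaluate the deterministic activity drive
#'
#' Computes the latent drive `s(t)` of the generator on a regular subgrid and
#' averaged per bin, with no noise. This is the expected-intensity path of
#' [simulate_animal()]: expected counts per bin are
#' `baseline_rate + amplitude * drive`.
#'
#' @inheritParams simulate_animal
#' @return List with `t_mid_s` (subgrid midpoints, seconds), `s` (drive on
#'   the subgrid), and `drive_bin` (per-bin mean drive).
#' @export
simulate_drive <- function(params, schedule, days, bin_seconds = 300L) {
  stopifnot(inherits(params, "sim_params"), inherits(schedule, "light_schedule"),
            days >= 1)
  total_s <- days * 86400
  if (total_s %% bin_seconds != 0)
    stop("days * 86400 must be divisible by bin_seconds", call. = FALSE)
  n_bins <- total_s %/% bin_seconds
  nsub <- max(1L, as.integer(bin_seconds) %/% 60L)
  dt <- bin_seconds / nsub
  t_mid <- (seq_len(n_bins * nsub) - 0.5) * dt

  if (params$waveform == "cosine") {
    ph <- circadian_phase(t_mid, params, schedule)
    s <- 0.5 + 0.5 * cos(2 * pi * (ph - 18) / 24)
  } else {
    # piecewise-constant target; exact first-order relaxation per segment
    cyc_s <- schedule$cycle_length * 3600
    ev <- drive_events(params, schedule, -params$tau * 3600 - cyc_s, total_s)
    sw_t <- ifelse(ev$kind == "off", ev$time_s + params$onset_latency * 60,
                   ev$time_s)
    sw_target <- ifelse(ev$kind == "off", 1, params$light_suppression)
    sw_tc <- ifelse(ev$kind == "off", params$rise_time, params$fall_time) * 60
    o <- order(sw_t)
    sw_t <- sw_t[o]; sw_target <- sw_target[o]; sw_tc <- sw_tc[o]
    # drop pre-history except the last switch before t = 0 (sets initial state)
    last_pre <- max(which(sw_t <= 0))
    keep <- last_pre:length(sw_t)
    seg_t <- sw_t[keep]; seg_target <- sw_target[keep]; seg_tc <- sw_tc[keep]
    seg_t[1] <- min(seg_t[1], 0)
    # segment-start values by exact stepping
    ns <- length(seg_t)
    s0 <- numeric(ns)
    s0[1] <- seg_target[1]  # steady state in the pre-history segment
    if (ns > 1) {
      for (i in 2:ns) {
        dur <- seg_t[i] - seg_t[i - 1]
        s0[i] <- seg_target[i - 1] +
          (s0[i - 1] - seg_target[i - 1]) * exp(-dur / seg_tc[i - 1])
      }
    }
    idx <- findInterval(t_mid, seg_t)
    s <- seg_target[idx] + (s0[idx] - seg_target[idx]) *
      exp(-(t_mid - seg_t[idx]) / seg_tc[idx])
  }
  if (params$ultradian_period_min > 0) {
    up_s <- params$ultradian_period_min * 60
    s <- s * as.numeric((t_mid %% up_s) / up_s < params$ultradian_duty)
  }
  drive_bin <- colMeans(matrix(s, nrow = nsub))
  list(t_mid_s = t_mid, s = s, drive_bin = drive_bin, nsub = nsub, dt = dt)
}

#' Simulate one animal's actigraphy record
#'
#' Generates a seeded activity-count and body-temperature series with the
#' statistical structure the downstream analyses assume: an entrained LD
#' rhythm with a lights-off response latency, or a free-running DD rhythm of
#' period `tau`; overdispersed count noise; and a temperature channel coupled
#' to the (smoothed) drive, not to the realised counts.
#'
#' @param params A [sim_params()] object.
#' @param schedule A [light_schedule()].
#' @param days Number of recording days (`days * 86400` must be divisible by
#'   `bin_seconds`).
#' @param seed Integer RNG seed (ignored when `params$deterministic`).
#' @param animal_id,group Labels stored in the record.
#' @param bin_seconds Bin width, seconds (default 300).
#' @return An [actigraphy_record()].
#' @examples
#' rec <- simulate_animal(sim_params(), light_schedule("LD"), days = 7, seed = 1)
#' mean(rec$activity)
#' @export
simulate_animal <- function(params, schedule, days, seed = 1L,
                            animal_id = "sim", group = "sim",
                            bin_seconds = 300L) {
  drv <- simulate_drive(params, schedule, days, bin_seconds)
  mu <- params$baseline_rate + params$amplitude * drv$drive_bin
  # low-pass the subgrid drive for the temperature channel
  a <- exp(-drv$dt / (params$temp_smooth * 60))
  sf <- as.numeric(stats::filter((1 - a) * drv$s, a, method = "recursive",
                                 init = drv$s[1]))
  sf_bin <- colMeans(matrix(sf, nrow = drv$nsub))
  n <- length(mu)
  if (params$deterministic) {
    counts <- round(mu)
    temp <- params$temp_base + params$temp_amplitude * sf_bin
  } else {
    old_rng <- save_rng_state()
    on.exit(restore_rng_state(old_rng), add = TRUE)
    set.seed(as.integer(seed))
    counts <- if (is.infinite(params$dispersion)) stats::rpois(n, mu)
              else stats::rnbinom(n, mu = mu, size = params$dispersion)
    temp <- params$temp_base + params$temp_amplitude * sf_bin +
      stats::rnorm(n, 0, params$temp_noise_sd)
  }
  actigraphy_record(animal_id, group, counts, temp,
                    bin_seconds = bin_seconds, schedule = schedule)
}

#' Simulate a cohort of animals
#'
#' Each animal receives an independent RNG substream derived from
#' `master_seed` and its (group, animal) indices, so the cohort is exactly
#' reproducible while animals are mutually independent.
#'
#' @param groups List of group specifications, each a list with elements
#'   `group` (unique label), `n` (number of animals) and `params`
#'   (a [sim_params()]).
#' @param schedule,days,bin_seconds Passed to [simulate_animal()].
#' @param master_seed Integer master seed.
#' @return List with `records` (list of [actigraphy_record()]s) and
#'   `manifest` (one data.frame row per record, in the same order).
#' @export
simulate_cohort <- function(groups, schedule, days, master_seed = 1L,
                            bin_seconds = 300L) {
  labels <- vapply(groups, function(g) g$group, character(1))
  if (anyDuplicated(labels)) stop("group labels must be unique", call. = FALSE)
  records <- list()
  rows <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    for (ai in seq_len(g$n)) {
      id <- sprintf("%s_%02d", g$group, ai)
      seed_a <- (master_seed + 100003 * gi + 1009 * ai) %% 2147483647
      rec <- simulate_animal(g$params, schedule, days, seed = seed_a,
                             animal_id = id, group = g$group,
                             bin_seconds = bin_seconds)
      records[[id]] <- rec
      rows[[id]] <- data.frame(
        animal_id = id, group = g$group, cycle = schedule$cycle,
        lights_off_zt = schedule$lights_off_zt,
        anchor_zt_at_start = schedule$anchor_zt,
        dd_start_s = schedule$dd_start_s, stringsAsFactors = FALSE)
    }
  }
  if (anyDuplicated(names(records)))
    stop("duplicate animal ids", call. = FALSE)
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  list(records = records, manifest = manifest)
}
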