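# Desk-scale simulator of heterogeneous multicenter 12-lead ECG-like data.
#
# Each record is a sum over beats of lead-projected Gaussian P-QRS-T
# templates at RR-jittered beat times, plus sinusoidal baseline wander and
# white noise, with per-site lead gains. Arrhythmia (label 1) is encoded as
# increased RR-interval variability plus probabilistic P-wave dropout - a
# caricature that gives detectors a learnable rhythm signal without any
# claim of clinical realism. Site-to-site heterogeneity covers cohort
# composition (age, sex, prevalence) and device/regional morphology shift
# (lead gains, wander, noise).

#' Site profile for the simulator
#'
#' @param n number of records
#' @param age_mean,age_sd age distribution in years (clipped to `[18, 100]`)
#' @param male_fraction proportion of male records
#' @param arrhythmia_prevalence proportion of label-1 records
#' @param lead_gain_shift multiplicative per-lead gain perturbation scale
#'   (0 = reference device)
#' @param wander_amp baseline-wander amplitude in mV
#' @param noise_sd white-noise standard deviation in mV
#' @param rr_cv_normal,rr_cv_arrhythmia coefficients of variation of RR
#'   intervals under labels 0 and 1 (`rr_cv_arrhythmia > rr_cv_normal`)
#' @param p_wave_dropout per-beat P-wave dropout probability under label 1
#' @param polarity fixed per-site sign/gain applied to the whole waveform
#'   (a device convention; -1 inverts every lead)
#' @param amplitude fixed per-site amplitude scale in mV per template unit
#' @return an object of class `site_profile`
#' @export
site_profile <- function(n, age_mean = 60, age_sd = 16, male_fraction = 0.45,
                         arrhythmia_prevalence = 0.5, lead_gain_shift = 0,
                         wander_amp = 0.05, noise_sd = 0.02,
                         rr_cv_normal = 0.02, rr_cv_arrhythmia = 0.25,
                         p_wave_dropout = 0.7, polarity = 1, amplitude = 1) {
  stopifnot(n >= 1, male_fraction >= 0, male_fraction <= 1,
            arrhythmia_prevalence >= 0, arrhythmia_prevalence <= 1,
            rr_cv_arrhythmia > rr_cv_normal, p_wave_dropout >= 0,
            p_wave_dropout <= 1, polarity != 0, amplitude > 0)
  structure(as.list(environment()), class = "site_profile")
}

#' Simulator configuration
#'
#' @param leads number of channels (default 12)
#' @param fs sampling frequency in Hz (default 500; desk-scale tests use 125)
#' @param duration record length in seconds (default 10; tests use about 2.5)
#' @param mean_rr mean RR interval in seconds (default 0.8)
#' @param seed base seed folded into every record's seed
#' @return an object of class `sim_config`
#' @export
sim_config <- function(leads = 12L, fs = 500, duration = 10, mean_rr = 0.8,
                       seed = 0L) {
  stopifnot((fs * duration) %% 1 == 0, leads >= 1)
  # fixed plausible lead projections for the P, QRS, and T waves: smooth
  # lead-dependent weights emulating the dipole projection onto 12 leads
  ang <- seq(0, pi, length.out = leads)
  proj <- list(p = 0.25 * sin(ang + 0.4) + 0.05,
               qrs = 1.0 * sin(ang + 0.9),
               t = 0.45 * sin(ang + 0.6) + 0.1)
  structure(list(leads = as.integer(leads), fs = fs, duration = duration,
                 samples = as.integer(fs * duration), mean_rr = mean_rr,
                 proj = proj, seed = as.integer(seed)),
            class = "sim_config")
}

# Gaussian bump helper: amplitude * exp(-(t-center)^2 / (2 width^2))
.bump <- function(t, center, width, amplitude) {
  amplitude * exp(-((t - center)^2) / (2 * width^2))
}

#' Simulate one ECG-like record
#'
#' @param profile a [site_profile()]
#' @param config a [sim_config()]
#' @param label 0 or 1; arrhythmia records draw RR intervals with
#'   `rr_cv_arrhythmia` and drop P waves with probability `p_wave_dropout`
#' @param seed integer seed; the full record is deterministic given it
#' @param record_id optional identifier
#' @return an [ecg_record()] (age and sex drawn from the profile)
#' @export
simulate_record <- function(profile, config, label, seed,
                            record_id = paste0("sim-", seed)) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed + config$seed, "record"))
  C <- config$leads; fs <- config$fs; L <- config$samples
  tgrid <- (seq_len(L) - 1) / fs
  rr_cv <- if (label == 1) profile$rr_cv_arrhythmia else profile$rr_cv_normal
  # beat times: cumulative RR intervals with multiplicative jitter
  n_beats <- ceiling(config$duration / config$mean_rr) + 3L
  rr <- config$mean_rr * pmax(0.3, 1 + rr_cv * stats::rnorm(n_beats))
  beats <- cumsum(c(0.3 * config$mean_rr, rr))
  beats <- beats[beats < config$duration + 0.5]
  base <- matrix(0, 1, L) # scalar morphology before lead projection
  pwave <- qrs <- twave <- numeric(L)
  for (b in beats) {
    has_p <- !(label == 1 && stats::runif(1) < profile$p_wave_dropout)
    if (has_p) pwave <- pwave + .bump(tgrid, b - 0.16, 0.025, 1)
    qrs <- qrs - .bump(tgrid, b - 0.025, 0.012, 0.25) +
      .bump(tgrid, b, 0.012, 1) - .bump(tgrid, b + 0.03, 0.015, 0.2)
    twave <- twave + .bump(tgrid, b + 0.25, 0.06, 1)
  }
  pr <- config$proj
  wave <- outer(pr$p, pwave) + outer(pr$qrs, qrs) + outer(pr$t, twave)
  # device / regional morphology shift: per-lead gains, wander, noise
  gains <- profile$polarity * profile$amplitude *
    (1 + profile$lead_gain_shift * stats::rnorm(C))
  wave <- wave * gains
  if (profile$wander_amp > 0) {
    ph <- stats::runif(C, 0, 2 * pi)
    f <- stats::runif(1, 0.15, 0.35)
    wander <- profile$wander_amp * sin(outer(ph, 2 * pi * f * tgrid, `+`))
    wave <- wave + wander
  }
  if (profile$noise_sd > 0)
    wave <- wave + matrix(stats::rnorm(C * L, 0, profile$noise_sd), C, L)
  age <- as.integer(round(min(100, max(18,
    stats::rnorm(1, profile$age_mean, profile$age_sd)))))
  sex <- if (stats::runif(1) < profile$male_fraction) "male" else "female"
  ecg_record(wave, fs, age, sex, label, record_id)
}

#' Simulate a full site dataset
#'
#' Labels are Bernoulli draws at the profile's arrhythmia prevalence; each
#' record is generated by [simulate_record()] with a seed derived from
#' `seed` and the record index.
#'
#' @param profile a [site_profile()]
#' @param config a [sim_config()]
#' @param seed integer seed
#' @param site_id site identifier
#' @return a [site_dataset()]
#' @export
simulate_site <- function(profile, config, seed = 0L, site_id = "sim") {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, paste0("site-", site_id)))
  labels <- as.integer(stats::runif(profile$n) < profile$arrhythmia_prevalence)
  rec_seeds <- sample.int(2^30, profile$n)
  records <- lapply(seq_len(profile$n), function(i) {
    r <- simulate_record(profile, config, labels[i], rec_seeds[i],
                         record_id = sprintf("%s-%05d", site_id, i))
    r$site_id <- site_id
    r
  })
  site_dataset(records, site_id)
}

#' Default multicenter scenarios
#'
#' Four site profiles emulating a heterogeneous multicenter study: pairwise
#' different sizes (so small-to-large and large-to-small orderings differ),
#' one low-prevalence outlier site, and distinct device/morphology shifts.
#' The `fourdb` scale uses the published four-database cohort statistics
#' (sizes 42299/21374/10197/6696, prevalences 0.8201/0.5612/0.8321/0.8775);
#' `tiny` keeps the same heterogeneity pattern at sizes that train in
#' minutes on one CPU; `small` is four times `tiny`.
#'
#' @param scale `"tiny"`, `"small"`, or `"fourdb"`
#' @param fs,duration sampling settings for the shared [sim_config()]
#'   (defaults depend on scale: 125 Hz / 2.5 s below full scale)
#' @return list with `profiles` (list of 4 [site_profile()]), `config`
#'   (shared [sim_config()]), and `site_ids`
#' @export
default_multicenter_scenario <- function(scale = c("tiny", "small", "fourdb"),
                                         fs = NULL, duration = NULL) {
  scale <- match.arg(scale)
  if (is.null(fs)) fs <- if (scale == "fourdb") 500 else 125
  if (is.null(duration)) duration <- if (scale == "fourdb") 10 else 2.504
  ns <- switch(scale,
               tiny = c(200L, 150L, 120L, 90L),
               small = c(800L, 600L, 480L, 360L),
               fourdb = c(42299L, 21374L, 10197L, 6696L))
  prev <- c(0.8201, 0.5612, 0.8321, 0.8775)
  ages <- list(c(60.79, 16.41), c(59.82, 16.42), c(60.54, 15.4),
               c(61.18, 17.9))
  male <- c(0.4361, 0.4750, 0.4631, 0.4618)
  # distinct device / morphology shifts per site
  gain_shift <- c(0.05, 0.30, 0.15, 0.45)
  wander <- c(0.03, 0.10, 0.06, 0.15)
  noise <- c(0.02, 0.06, 0.03, 0.08)
  profiles <- lapply(1:4, function(i) {
    site_profile(n = ns[i], age_mean = ages[[i]][1], age_sd = ages[[i]][2],
                 male_fraction = male[i], arrhythmia_prevalence = prev[i],
                 lead_gain_shift = gain_shift[i], wander_amp = wander[i],
                 noise_sd = noise[i])
  })
  list(profiles = profiles,
       config = sim_config(leads = 12L, fs = fs, duration = duration),
       site_ids = c("siteA", "siteB", "siteC", "siteD"))
}

#' Three-site scenario with strong inter-site domain shift
#'
#' A deliberately adversarial sequential setting for forgetting studies:
#' the sites share the label mechanism (RR irregularity + P-wave dropout)
#' but differ sharply in device conventions - the second site attenuates
#' amplitude under heavy noise and the last site inverts waveform polarity -
#' in addition to distinct prevalences and cohorts. Training sequentially
#' without regularization on these sites exhibits measurable catastrophic
#' forgetting of the first site, which continual regularization is meant to
#' suppress.
#'
#' @param scale `"tiny"` or `"small"`
#' @return list with `profiles`, `config`, `site_ids` (sizes pairwise
#'   distinct)
#' @export
strong_shift_scenario <- function(scale = c("tiny", "small")) {
  scale <- match.arg(scale)
  ns <- if (scale == "tiny") c(150L, 110L, 80L) else c(600L, 440L, 320L)
  profiles <- list(
    site_profile(n = ns[1], age_mean = 58, age_sd = 15, male_fraction = 0.45,
                 arrhythmia_prevalence = 0.55, lead_gain_shift = 0.05,
                 wander_amp = 0.03, noise_sd = 0.02),
    site_profile(n = ns[2], age_mean = 68, age_sd = 13, male_fraction = 0.40,
                 arrhythmia_prevalence = 0.70, lead_gain_shift = 0.30,
                 wander_amp = 0.15, noise_sd = 0.10, amplitude = 0.4),
    site_profile(n = ns[3], age_mean = 64, age_sd = 14, male_fraction = 0.55,
                 arrhythmia_prevalence = 0.80, lead_gain_shift = 0.20,
                 wander_amp = 0.10, noise_sd = 0.05, polarity = -1))
  list(profiles = profiles,
       config = sim_config(leads = 12L, fs = 125, duration = 2.504),
       site_ids = c("siteP", "siteQ", "siteR"))
}
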