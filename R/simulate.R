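#' Simulation configuration
#'
#' Defines the study conditions the simulator emulates: the finger-tapping
#' paradigm (20 blocks of 10 s, 10 per hand in random order, rests uniform
#' on 20-24 s), a 2-min walk with 20 s standing baseline, a 6-min resting
#' state, 25 Hz two-wavelength acquisition on the default 20-long + 2-short
#' probe, systemic physiological oscillations (cardiac 1.1 Hz, respiratory
#' 0.25 Hz, Mayer waves 0.1 Hz), a superficial component shared between
#' short and long channels, white measurement noise, sporadic motion
#' artifacts, and group-dependent evoked responses and interhemispheric
#' coupling.  Group defaults encode the qualitative disease contrast the
#' pipeline is designed to detect: the "pd" group has the dominant-hand
#' (right-tap, left-hemisphere) response reduced to 0.6x amplitude and
#' delayed by 2 s, the non-dominant response increased to 1.4x and delayed
#' by 2 s, and interhemispheric coupling reduced from 0.6 to 0.3.
#'
#' @param n_per_group subjects per group.
#' @param seed master seed; all per-subject randomness derives from it.
#' @param fs sampling frequency (Hz).
#' @param hrf_amplitude baseline contralateral evoked peak (uM*mm HbO).
#' @param hrf_params per-group, per-condition evoked parameters: named list
#'   `group$condition = c(amplitude, latency_shift, width_scale)`.
#' @param ipsi_fraction evoked amplitude fraction in the ipsilateral
#'   hemisphere.
#' @param hbr_ratio HbR evoked component as a fraction of HbO (negative,
#'   venous-weighted neurovascular coupling).
#' @param superficial_hbr_ratio HbR fraction of the superficial and
#'   systemic components; smaller in magnitude than the evoked ratio
#'   because scalp and systemic fluctuations are predominantly
#'   oxygenation-driven.
#' @param subject_amp_sd,subject_latency_sd between-subject variability of
#'   evoked amplitude (lognormal sd, unitless) and latency (s).
#' @param systemic named list: `cardiac_hz`, `resp_hz`, `mayer_hz` and
#'   `amps` (uM*mm, same order).
#' @param superficial_amp sd of the shared superficial component (uM*mm).
#' @param latent_amp sd of the band-limited resting-state latent signal
#'   (uM*mm).
#' @param white_noise_sd measurement noise sd (uM*mm).
#' @param artifact_rate motion artifacts per minute.
#' @param artifact_kinds subset of `c("spike", "shift")`.
#' @param amp_thresh_scale detection threshold scale the artifact
#'   magnitudes are drawn relative to (OD).
#' @param coupling per-group interhemispheric (`rho_inter`) and
#'   intrahemispheric (`rho_intra`) latent correlations.
#' @param walk_amplitude per-group left-hemisphere evoked amplitude during
#'   walking (uM*mm).
#' @param probe the acquisition probe.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 20, seed = 1, fs = 25,
                       hrf_amplitude = 0.5,
                       hrf_params = NULL,
                       ipsi_fraction = 0.25,
                       hbr_ratio = -1/3,
                       superficial_hbr_ratio = -0.1,
                       subject_amp_sd = 0.1, subject_latency_sd = 0.3,
                       systemic = list(cardiac_hz = 1.1, resp_hz = 0.25,
                                       mayer_hz = 0.1,
                                       amps = c(0.10, 0.05, 0.05)),
                       superficial_amp = 0.3, latent_amp = 0.5,
                       white_noise_sd = 0.05,
                       artifact_rate = 0.5,
                       artifact_kinds = c("spike", "shift"),
                       amp_thresh_scale = 0.5,
                       coupling = list(control = c(rho_inter = 0.6,
                                                   rho_intra = 0.5),
                                       pd = c(rho_inter = 0.3,
                                              rho_intra = 0.4)),
                       walk_amplitude = c(control = 0.3, pd = 0.3),
                       probe = default_probe()) {
  if (is.null(hrf_params)) {
    a <- hrf_amplitude
    hrf_params <- list(
      control = list(right_tap = c(amplitude = a, latency_shift = 0,
                                   width_scale = 1),
                     left_tap = c(amplitude = a, latency_shift = 0,
                                  width_scale = 1)),
      pd = list(right_tap = c(amplitude = 0.6 * a, latency_shift = 2,
                              width_scale = 1),
                left_tap = c(amplitude = 1.4 * a, latency_shift = 2,
                             width_scale = 1)))
  }
  stopifnot(fs > 2 * systemic$cardiac_hz, artifact_rate >= 0,
            all(abs(unlist(coupling)) <= 1))
  structure(list(n_per_group = n_per_group, seed = seed, fs = fs,
                 hrf_params = hrf_params, ipsi_fraction = ipsi_fraction,
                 hbr_ratio = hbr_ratio,
                 superficial_hbr_ratio = superficial_hbr_ratio,
                 subject_amp_sd = subject_amp_sd,
                 subject_latency_sd = subject_latency_sd,
                 systemic = systemic, superficial_amp = superficial_amp,
                 latent_amp = latent_amp, white_noise_sd = white_noise_sd,
                 artifact_rate = artifact_rate,
                 artifact_kinds = artifact_kinds,
                 amp_thresh_scale = amp_thresh_scale, coupling = coupling,
                 walk_amplitude = walk_amplitude, probe = probe),
            class = "sim_config")
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, ...) {
  codes <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in codes) s <- (s * 48271 + as.double(k) * 9973 + 1) %% 2147483647
  as.integer(s)
}

# canonical double-gamma normalizer: raw kernel peaks at t = 6 with value
# HRF_PEAK_RAW, computed once on a dense grid
hrf_raw <- function(t) {
  pos <- t > 0
  out <- numeric(length(t))
  tp <- t[pos]
  out[pos] <- tp^6 * exp(-tp) / gamma(7) - (1/6) * tp^16 * exp(-tp) / gamma(17)
  out
}
HRF_PEAK_RAW <- max(hrf_raw(seq(0, 30, by = 1e-3)))

#' Canonical hemodynamic response curve
#'
#' Difference-of-gammas (double-gamma) response: main lobe peaking at 6 s,
#' undershoot near 16 s with 1/6 relative depth, normalized so the
#' default-parameter maximum is exactly `amplitude`.  `latency_shift`
#' translates the curve (and hence the peak time) by exactly that amount;
#' `width_scale` stretches the time axis, moving the default peak to
#' `6 * width_scale + latency_shift`.  The response is causal: zero for
#' `t <= latency_shift`.
#'
#' @param t time (s), vectorized.
#' @param amplitude peak value (uM*mm).
#' @param latency_shift peak-time translation (s).
#' @param width_scale time-axis stretch (> 0).
#' @return numeric vector of responses.
#' @export
canonical_hrf <- function(t, amplitude = 1, latency_shift = 0,
                          width_scale = 1) {
  stopifnot(width_scale > 0)
  amplitude * hrf_raw((t - latency_shift) / width_scale) / HRF_PEAK_RAW
}

# spectral shaping of white noise: multiply column spectra by a magnitude
# response; circular filtering is exact for stationary noise input
fft_shape <- function(X, mag) {
  X <- as.matrix(X)
  Y <- Re(stats::mvfft(stats::mvfft(X) * mag, inverse = TRUE)) / nrow(X)
  Y
}

butter_magnitude <- function(n, fs, low, high, order) {
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                        # two-sided symmetry
  mag <- rep(1, n)
  if (!is.na(high)) mag <- mag / sqrt(1 + (f / high)^(2 * order))
  if (!is.na(low) && low > 0) {
    mag <- mag * ifelse(f == 0, 0, 1 / sqrt(1 + (low / pmax(f, 1e-12))^(2 * order)))
  }
  mag
}

# band/low-pass shaped Gaussian noise, generated at an FFT-friendly length
# and truncated; exact spectrum for stationary noise input
shaped_noise <- function(n, k, fs, low, high, order, X = NULL) {
  m <- stats::nextn(n, c(2, 3, 5))
  if (is.null(X)) X <- matrix(stats::rnorm(m * k), m, k)
  Y <- fft_shape(X, butter_magnitude(m, fs, low, high, order))
  Y[seq_len(n), , drop = FALSE]
}

# shared low-frequency superficial process: white noise shaped to a
# ~0.2 Hz low-pass spectrum, rescaled to unit sd
superficial_process <- function(n, fs) {
  y <- drop(shaped_noise(n, 1, fs, NA, 0.2, 2))
  y / stats::sd(y)
}

systemic_process <- function(t, systemic) {
  f <- c(systemic$cardiac_hz, systemic$resp_hz, systemic$mayer_hz)
  ph <- stats::runif(3, 0, 2 * pi)
  out <- numeric(length(t))
  for (k in 1:3) out <- out + systemic$amps[k] * sin(2 * pi * f[k] * t + ph[k])
  out
}

# assemble physiological + noise background shared by all paradigms;
# returns hbo/hbr matrices and the superficial series used
background_hemo <- function(n, t, cfg, nch, is_short) {
  sup <- superficial_process(n, cfg$fs) * cfg$superficial_amp
  syst <- systemic_process(t, cfg$systemic)
  sup_gain <- ifelse(is_short, stats::runif(nch, 0.8, 1.2),
                     stats::runif(nch, 0.5, 1.5))
  sys_gain <- stats::runif(nch, 0.8, 1.2)
  hbo <- outer(sup, sup_gain) + outer(syst, sys_gain) +
    matrix(stats::rnorm(n * nch, sd = cfg$white_noise_sd), n, nch)
  hbr <- cfg$superficial_hbr_ratio *
    (outer(sup, sup_gain) + outer(syst, sys_gain)) +
    matrix(stats::rnorm(n * nch, sd = cfg$white_noise_sd), n, nch)
  list(hbo = hbo, hbr = hbr, superficial = sup)
}

finish_session <- function(hbo, hbr, cfg, stim, subject, paradigm_code,
                           output, truth) {
  probe <- cfg$probe
  if (output == "hemoglobin") {
    rec <- hemo_series(hbo, hbr, cfg$fs, probe, stim)
    return(list(recording = rec, truth = truth))
  }
  intens <- chromo_to_intensity(hbo, hbr, probe, baseline_intensity = 1)
  rec <- nirs_recording(intens, cfg$fs, "intensity", probe, stim)
  art <- inject_motion_artifacts(rec, cfg,
                                 seed = derive_seed(cfg$seed, subject,
                                                    paradigm_code, 77))
  truth$artifact_log <- art$log
  list(recording = art$recording, truth = truth)
}

#' Simulate a finger-tapping task session
#'
#' Generates the 20-block left/right tapping schedule (order and
#' inter-stimulus rests from the seeded RNG), builds per-hemisphere evoked
#' HbO responses with contralateral dominance from the group's HRF
#' parameters (with per-subject amplitude and latency variability), adds
#' the shared superficial component, systemic sines, white noise, converts
#' to two-wavelength intensities through the forward optical model and
#' injects motion artifacts.  Fully deterministic given `(cfg, subject,
#' group)`.
#'
#' @param cfg a [sim_config()].
#' @param subject subject index (integer, used for seed derivation).
#' @param group "control" or "pd".
#' @param output "intensity" for the full forward model (with motion
#'   artifacts), or "hemoglobin" for the noiseless-optics chromophore
#'   series (no artifacts), useful when only the estimation layers are
#'   under study.
#' @return list with elements `recording` and `truth`; `truth` holds the
#'   true response curves on the (-2, 25) s window grid, true peak and
#'   time-to-peak per condition, the subject's evoked parameters and the
#'   artifact log.
#' @export
simulate_task_session <- function(cfg, subject, group = "control",
                                  output = c("intensity", "hemoglobin")) {
  output <- match.arg(output)
  if (!group %in% names(cfg$hrf_params)) stop("config error: unknown group")
  set.seed(derive_seed(cfg$seed, subject, 1))
  fs <- cfg$fs
  probe <- cfg$probe
  ch <- probe$channels

  conds <- sample(rep(c("left_tap", "right_tap"), 10))
  onsets <- numeric(20)
  onsets[1] <- 15
  for (k in 2:20) onsets[k] <- onsets[k - 1] + 10 + stats::runif(1, 20, 24)
  stim <- data.frame(condition = conds, onset = onsets, duration = 10,
                     accepted = TRUE)
  dur <- onsets[20] + 10 + 25
  n <- floor(dur * fs)
  t <- (seq_len(n) - 1) / fs

  # per-subject evoked parameters
  amp_jit <- exp(stats::rnorm(1, 0, cfg$subject_amp_sd))
  lat_jit <- stats::rnorm(1, 0, cfg$subject_latency_sd)
  pars <- lapply(cfg$hrf_params[[group]], function(p) {
    c(amplitude = unname(p["amplitude"]) * amp_jit,
      latency_shift = unname(p["latency_shift"]) + lat_jit,
      width_scale = unname(p["width_scale"]))
  })

  # evoked response per hemisphere (contralateral dominance)
  evoked <- list(left = numeric(n), right = numeric(n))
  for (e in seq_len(nrow(stim))) {
    p <- pars[[stim$condition[e]]]
    contra <- if (stim$condition[e] == "right_tap") "left" else "right"
    ipsi <- setdiff(c("left", "right"), contra)
    # response support: the kernel is negligible beyond ~30 s (scaled)
    hi <- stim$onset[e] + p["latency_shift"] + 32 * p["width_scale"]
    idx <- which(t >= stim$onset[e] & t <= hi)
    resp <- canonical_hrf(t[idx] - stim$onset[e], p["amplitude"],
                          p["latency_shift"], p["width_scale"])
    evoked[[contra]][idx] <- evoked[[contra]][idx] + resp
    evoked[[ipsi]][idx] <- evoked[[ipsi]][idx] + cfg$ipsi_fraction * resp
  }

  nch <- nrow(ch)
  bg <- background_hemo(n, t, cfg, nch, ch$is_short)
  hbo <- bg$hbo; hbr <- bg$hbr
  for (c in which(!ch$is_short)) {
    ev <- evoked[[ch$hemisphere[c]]]
    hbo[, c] <- hbo[, c] + ev
    hbr[, c] <- hbr[, c] + cfg$hbr_ratio * ev
  }

  grid <- seq(-2, 25, by = 1 / fs)
  truth <- list(subject = subject, group = group, params = pars,
                window_grid = grid)
  truth$hrf <- lapply(pars, function(p)
    canonical_hrf(grid, p["amplitude"], p["latency_shift"], p["width_scale"]))
  post <- grid >= 0
  truth$peak <- vapply(truth$hrf, function(h) h[post][which.max(abs(h[post]))],
                       0)
  truth$time_to_peak <- vapply(truth$hrf, function(h)
    grid[post][which.max(abs(h[post]))], 0)
  finish_session(hbo, hbr, cfg, stim, subject, 1, output, truth)
}

#' Simulate a walking session
#'
#' 20 s standing baseline followed by a single 2-min walking bout.  The
#' evoked response is confined to the left hemisphere (as observed for
#' overground walking in this protocol), with group-dependent amplitude.
#'
#' @inheritParams simulate_task_session
#' @export
simulate_walk_session <- function(cfg, subject, group = "control",
                                  output = c("intensity", "hemoglobin")) {
  output <- match.arg(output)
  set.seed(derive_seed(cfg$seed, subject, 2))
  fs <- cfg$fs
  ch <- cfg$probe$channels
  stim <- data.frame(condition = "walk", onset = 20, duration = 120,
                     accepted = TRUE)
  n <- floor((20 + 120 + 20) * fs)
  t <- (seq_len(n) - 1) / fs

  amp <- cfg$walk_amplitude[[group]] * exp(stats::rnorm(1, 0, cfg$subject_amp_sd))
  lat <- stats::rnorm(1, 0, cfg$subject_latency_sd)
  resp <- canonical_hrf(t - stim$onset, amp, lat, 1)

  nch <- nrow(ch)
  bg <- background_hemo(n, t, cfg, nch, ch$is_short)
  hbo <- bg$hbo; hbr <- bg$hbr
  for (c in which(!ch$is_short & ch$hemisphere == "left")) {
    hbo[, c] <- hbo[, c] + resp
    hbr[, c] <- hbr[, c] + cfg$hbr_ratio * resp
  }
  grid <- seq(-2, 25, by = 1 / fs)
  truth <- list(subject = subject, group = group,
                params = c(amplitude = amp, latency_shift = lat),
                window_grid = grid,
                hrf = list(walk = canonical_hrf(grid, amp, lat, 1)))
  finish_session(hbo, hbr, cfg, stim, subject, 2, output, truth)
}

#' Simulate a resting-state session
#'
#' 6-min eyes-closed recording.  A band-limited (0.009-0.08 Hz) latent
#' signal with the group's target channel-correlation structure is built by
#' applying a matrix square root (eigendecomposition, supporting
#' semidefinite targets) of the target matrix to white noise
#' (homolog pairs correlate at `rho_inter`, within-hemisphere pairs at
#' `rho_intra`, non-homolog cross-hemisphere pairs at
#' `rho_inter * rho_intra`); non-positive-definite targets are rejected.
#' Superficial, systemic and white-noise components are added as in the
#' task paradigm.
#'
#' @inheritParams simulate_task_session
#' @param duration recording length (s).
#' @export
simulate_resting_session <- function(cfg, subject, group = "control",
                                     output = c("intensity", "hemoglobin"),
                                     duration = 360) {
  output <- match.arg(output)
  set.seed(derive_seed(cfg$seed, subject, 3))
  fs <- cfg$fs
  probe <- cfg$probe
  ch <- probe$channels
  n <- floor(duration * fs)
  t <- (seq_len(n) - 1) / fs

  cp <- cfg$coupling[[group]]
  if (is.null(cp)) stop("config error: no coupling for group ", group)
  R <- resting_correlation_target(probe, cp["rho_inter"], cp["rho_intra"])
  eg <- eigen(R, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(eg$values))
    stop("config error: infeasible (non-positive-semidefinite) correlation structure")
  L <- diag(sqrt(pmax(eg$values, 0))) %*% t(eg$vectors)  # R = L'L

  long <- which(!ch$is_short)
  m <- stats::nextn(n, c(2, 3, 5))
  z <- matrix(stats::rnorm(m * length(long)), ncol = length(long))
  lat <- shaped_noise(n, length(long), fs, 0.009, 0.08, 3, X = z %*% L)
  lat <- sweep(lat, 2, apply(lat, 2, stats::sd), `/`) * cfg$latent_amp

  nch <- nrow(ch)
  bg <- background_hemo(n, t, cfg, nch, ch$is_short)
  hbo <- bg$hbo; hbr <- bg$hbr
  hbo[, long] <- hbo[, long] + lat
  hbr[, long] <- hbr[, long] + cfg$hbr_ratio * lat

  truth <- list(subject = subject, group = group,
                rho_inter = unname(cp["rho_inter"]),
                rho_intra = unname(cp["rho_intra"]),
                latent = lat)
  finish_session(hbo, hbr, cfg, stim = empty_schedule(), subject, 3, output,
                 truth)
}

# target correlation matrix of the long channels under the pair-factor
# model: guaranteed PSD whenever rho_inter, rho_intra lie in [0, 1]
resting_correlation_target <- function(probe, rho_inter, rho_intra) {
  ch <- probe$channels
  long <- ch[!ch$is_short, ]
  k <- nrow(long)
  R <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) R[i, j] <- 1
    else if (!is.na(long$homolog[i]) &&
             long$homolog[i] == long$channel_id[j]) R[i, j] <- rho_inter
    else if (long$hemisphere[i] == long$hemisphere[j]) R[i, j] <- rho_intra
    else R[i, j] <- rho_inter * rho_intra
  }
  R
}

#' Inject motion artifacts into a recording
#'
#' Adds transient optical-density excursions at Poisson-distributed times:
#' "spike" artifacts (half-cosine bumps, duration at most 1 s) and "shift"
#' artifacts (transient baseline steps holding 2-6 s).  Magnitudes are
#' drawn log-uniformly in 2-10 times `amp_thresh_scale`, giving detection
#' tests a controlled margin.  For intensity recordings the excursion is
#' applied multiplicatively (`I * 10^(-dOD)`), identically at both
#' wavelengths; for od recordings it is added.
#'
#' @param rec a `nirs_recording` of kind "intensity" or "od".
#' @param cfg a [sim_config()] (fields `artifact_rate`, `artifact_kinds`,
#'   `amp_thresh_scale`).
#' @param seed integer seed for this injection.
#' @return list with elements `recording` and `log` (data.frame: channel,
#'   onset, duration, kind, magnitude).
#' @export
inject_motion_artifacts <- function(rec, cfg, seed = cfg$seed) {
  if (!rec$kind %in% c("intensity", "od"))
    stop("inject_motion_artifacts expects an intensity or od recording")
  set.seed(seed)
  n <- dim(rec$data)[1]
  nch <- dim(rec$data)[2]
  dur_min <- n / rec$fs / 60
  n_art <- stats::rpois(1, cfg$artifact_rate * dur_min)
  log <- data.frame(channel = integer(), onset = numeric(),
                    duration = numeric(), kind = character(),
                    magnitude = numeric())
  if (n_art == 0) return(list(recording = rec, log = log))
  for (a in seq_len(n_art)) {
    chn <- sample(nch, 1)
    kind <- sample(cfg$artifact_kinds, 1)
    mag <- exp(stats::runif(1, log(2), log(10))) * cfg$amp_thresh_scale
    if (kind == "spike") {
      d <- stats::runif(1, 0.2, 0.8)
      onset <- stats::runif(1, 1, n / rec$fs - d - 1)
      i0 <- floor(onset * rec$fs) + 1
      len <- max(2L, round(d * rec$fs))
      shape <- mag * sin(pi * seq(0, 1, length.out = len))
    } else {
      d <- stats::runif(1, 2, 6)
      onset <- stats::runif(1, 1, n / rec$fs - d - 1)
      i0 <- floor(onset * rec$fs) + 1
      len <- max(2L, round(d * rec$fs))
      shape <- rep(mag, len)
    }
    idx <- i0:min(n, i0 + len - 1)
    shape <- shape[seq_along(idx)]
    sgn <- sample(c(-1, 1), 1)
    for (w in seq_len(dim(rec$data)[3])) {
      if (rec$kind == "intensity")
        rec$data[idx, chn, w] <- rec$data[idx, chn, w] * 10^(-sgn * shape)
      else rec$data[idx, chn, w] <- rec$data[idx, chn, w] + sgn * shape
    }
    log <- rbind(log, data.frame(channel = chn, onset = onset, duration = d,
                                 kind = kind, magnitude = mag))
  }
  list(recording = rec, log = log)
}

#' Simulate a synthetic clinical covariate table
#'
#' Draws demographics and disease scales with the cohort's published
#' group-level moments (ages near 70/66, MoCA 21.6 vs 26.2, UPDRS-III 37.4,
#' disease duration 8.2 y, FOGQ 2.7, LEDD 707.5 mg, HY 2-4, side of onset
#' 11 left / 9 right).  When per-subject evoked latencies are supplied, the
#' MoCA score is coupled monotonically (negatively) to the subject's
#' latency so that the clinical-correlation stage has a recoverable signal.
#'
#' @param cfg a [sim_config()].
#' @param latencies optional named numeric: per-PD-subject evoked latency
#'   shifts (s), names = subject ids.
#' @param coupling_slope MoCA points lost per second of latency delay.
#' @return data.frame in [read_clinical_table()] layout.
#' @export
simulate_clinical_table <- function(cfg, latencies = NULL,
                                    coupling_slope = 3) {
  set.seed(derive_seed(cfg$seed, 4))
  ng <- cfg$n_per_group
  mk <- function(group, ids) {
    pd <- group == "PD"
    moca <- stats::rnorm(ng, if (pd) 21.6 else 26.2, if (pd) 3.8 else 2.7)
    if (pd && !is.null(latencies)) {
      lat <- latencies[as.character(ids)]
      lat[is.na(lat)] <- mean(latencies)
      moca <- moca - coupling_slope * (lat - mean(lat))
    }
    data.frame(
      subject = ids, group = group,
      age = round(stats::rnorm(ng, if (pd) 69.9 else 65.6, 10)),
      sex = sample(c("m", "f"), ng, TRUE, prob = if (pd) c(0.6, 0.4) else c(0.45, 0.55)),
      education = pmax(0, round(stats::rnorm(ng, if (pd) 9.3 else 12.1, 4.5))),
      moca = pmin(30, pmax(0, round(moca))),
      updrs3 = if (pd) pmax(5, round(stats::rnorm(ng, 37.4, 18.6))) else NA,
      disease_duration = if (pd) pmax(0.5, round(stats::rnorm(ng, 8.2, 3.8), 1)) else NA,
      fogq = if (pd) pmin(15, pmax(0, round(stats::rnorm(ng, 2.7, 3)))) else NA,
      ledd = if (pd) pmax(50, round(stats::rnorm(ng, 707.5, 394.8))) else NA,
      hy = if (pd) sample(2:4, ng, TRUE, prob = c(0.4, 0.4, 0.2)) else NA,
      side_of_onset = if (pd) sample(c("left", "right"), ng, TRUE,
                                     prob = c(11, 9) / 20) else "none")
  }
  rbind(mk("control", seq_len(ng)), mk("PD", ng + seq_len(ng)))
}

#' Simulate a full two-group cohort
#'
#' @param cfg a [sim_config()].
#' @param paradigms subset of `c("task", "walk", "rest")`.
#' @param output "intensity" or "hemoglobin" (see
#'   [simulate_task_session()]).
#' @return list with `subjects` (per-subject list of recordings and ground
#'   truths, plus group), and `clinical` (synthetic clinical table, MoCA
#'   coupled to the PD subjects' evoked latencies).
#' @export
simulate_cohort <- function(cfg, paradigms = c("task", "walk", "rest"),
                            output = "intensity") {
  ng <- cfg$n_per_group
  groups <- rep(c("control", "pd"), each = ng)
  subjects <- vector("list", 2 * ng)
  for (s in seq_along(groups)) {
    entry <- list(subject = s, group = groups[s])
    if ("task" %in% paradigms)
      entry$task <- simulate_task_session(cfg, s, groups[s], output)
    if ("walk" %in% paradigms)
      entry$walk <- simulate_walk_session(cfg, s, groups[s], output)
    if ("rest" %in% paradigms)
      entry$rest <- simulate_resting_session(cfg, s, groups[s], output)
    subjects[[s]] <- entry
  }
  lat <- vapply(subjects[groups == "pd"], function(e) {
    if (!is.null(e$task)) unname(e$task$truth$params$right_tap["latency_shift"])
    else 0
  }, 0)
  names(lat) <- which(groups == "pd")
  clinical <- simulate_clinical_table(cfg, latencies = lat)
  list(subjects = subjects, clinical = clinical, config = cfg)
}
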