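test_that("channel pruning applies intensity, SNR and separation rules", {
  p <- default_probe()
  n <- 500
  set.seed(41)
  I <- array(1, c(n, 22, 2))
  rec <- nirs_recording(I, 25, "intensity", p)
  # constant intensity 1.0: sd -> 0, SNR -> Inf, separation 30 mm: kept
  r <- prune_channels(rec)
  expect_true(all(r$channel_mask))
  # mean below 1e-7: pruned
  I2 <- I; I2[, 3, ] <- 1e-9
  r2 <- prune_channels(nirs_recording(I2, 25, "intensity", p))
  expect_false(r2$channel_mask[3])
  expect_true(all(r2$channel_mask[-3]))
  # SNR below 2: pruned (alternating positive levels, mean/sd ~ 1.1)
  I3 <- I
  I3[, 4, 1] <- rep(c(0.2, 3.8), length.out = n)
  r3 <- prune_channels(nirs_recording(I3, 25, "intensity", p))
  expect_false(r3$channel_mask[4])
  # separation rule: shrink the allowed range to exclude shorts
  r4 <- prune_channels(rec, prune_params(sd_range = c(0.02, 0.45)))
  expect_false(any(r4$channel_mask[p$channels$is_short]))
  # all pruned is an error
  expect_error(prune_channels(rec, prune_params(sd_range = c(0.4, 0.45))),
               "all channels pruned")
})

test_that("od conversion has the closed form and scale invariance", {
  p <- make_probe(1)
  n <- 100
  I <- array(2, c(n, 4, 2))
  I[50, 1, 1] <- 1                       # half the reference at one sample
  rec <- nirs_recording(I, 25, "intensity", p)
  od <- intensity_to_od(rec, reference = 2)
  expect_equal(od$data[50, 1, 1], log10(2), tolerance = 1e-12)
  expect_equal(od$data[49, 1, 1], 0)
  # constant intensity gives all-zero od under the mean reference
  odm <- intensity_to_od(nirs_recording(array(5, c(n, 4, 2)), 25,
                                        "intensity", p))
  expect_true(all(odm$data == 0))
  # global scaling leaves mean-referenced od unchanged
  set.seed(42)
  I2 <- array(exp(rnorm(n * 4 * 2, sd = 0.05)), c(n, 4, 2))
  o1 <- intensity_to_od(nirs_recording(I2, 25, "intensity", p))
  o2 <- intensity_to_od(nirs_recording(I2 * 7, 25, "intensity", p))
  expect_equal(o1$data, o2$data, tolerance = 1e-12)
  # nonpositive sample on a kept channel is a domain error naming both
  I3 <- I; I3[10, 2, 1] <- -1
  rec3 <- nirs_recording(I, 25, "intensity", p)
  rec3$data <- I3
  expect_error(intensity_to_od(rec3), "channel 2.*sample 10")
})

test_that("motion detection flags steps and is monotone in the threshold", {
  p <- make_probe(1)
  rec <- noise_od_recording(n = 3000, probe = p, sd = 0.005, seed = 43)
  # clean low-amplitude sinusoid: fully clean mask
  t <- time_base(rec)
  rec$data[, 1, 1] <- 0.01 * sin(2 * pi * 0.3 * t)
  m <- detect_motion_by_channel(rec)
  expect_true(all(m))
  # injected 0.6 OD step (> 0.5): samples within 1 s flagged
  rec2 <- rec
  rec2$data[1500:3000, 2, 1] <- rec2$data[1500:3000, 2, 1] + 0.6
  m2 <- detect_motion_by_channel(rec2)
  expect_true(any(!m2[1475:1525, 2]))
  expect_true(all(m2[, 1]))            # other channels untouched
  # monotonicity: lower amp_thresh flags a superset
  m_lo <- detect_motion_by_channel(rec2, motion_params(amp_thresh = 0.1))
  expect_true(all(!m2 | m_lo | !m_lo))  # wherever m2 flags, m_lo flags
  expect_true(all((!m2[, 2]) <= (!m_lo[, 2])))
  expect_gte(sum(!m_lo), sum(!m2))
})

test_that("spline correction re-levels transient shifts and is identity on clean data", {
  p <- make_probe(1)
  rec <- noise_od_recording(n = 3000, probe = p, sd = 0.005, seed = 44)
  clean <- matrix(TRUE, 3000, 4)
  expect_identical(spline_correct(rec, clean)$data, rec$data)
  # transient baseline shift of 0.8 OD over samples 1200..1400
  shift <- 0.8
  rec2 <- rec
  rec2$data[1200:1400, 1, 1] <- rec2$data[1200:1400, 1, 1] + shift
  mask <- clean; mask[1180:1420, 1] <- FALSE
  fixed <- spline_correct(rec2, mask)
  pre <- mean(fixed$data[1000:1179, 1, 1])
  post <- mean(fixed$data[1421:1600, 1, 1])
  seg <- mean(fixed$data[1180:1420, 1, 1])
  expect_lt(abs(seg - mean(c(pre, post))), 0.1 * shift)
  # variance inside corrected segments does not increase
  expect_lte(var(fixed$data[1180:1420, 1, 1]), var(rec2$data[1180:1420, 1, 1]))
  # clean samples untouched
  expect_equal(fixed$data[1:1179, 1, 1], rec2$data[1:1179, 1, 1])
})

test_that("wavelet correction suppresses spikes and preserves length", {
  p <- make_probe(1)
  rec <- noise_od_recording(n = 3001, probe = p, sd = 0.005, seed = 45)
  spike <- 2 * sin(pi * seq(0, 1, length.out = 13))
  rec2 <- rec
  rec2$data[1500:1512, 1, 1] <- rec2$data[1500:1512, 1, 1] + spike
  out <- wavelet_correct(rec2)
  expect_equal(dim(out$data), dim(rec2$data))
  expect_lt(max(abs(out$data[1500:1512, 1, 1])), 0.5 * max(spike))
  # with fences wide enough to keep every coefficient the transform is lossless
  noop <- wavelet_correct(rec2, iqr_factor = 1e6)
  expect_lt(max(abs(noop$data - rec2$data)), 1e-10)
  # too-short records are skipped with a warning
  shortrec <- noise_od_recording(n = 15, probe = p, seed = 45)
  expect_warning(wavelet_correct(shortrec), "too short")
})

test_that("trial rejection uses exactly the (-2, 10) s window", {
  cfg <- tiny_cfg(seed = 46, artifact_rate = 0)
  s <- simulate_task_session(cfg, 1, "control", output = "intensity")
  rec <- intensity_to_od(prune_channels(s$recording))
  n <- dim(rec$data)[1]
  mask <- matrix(TRUE, n, 22)
  stim <- reject_trials(rec, mask)
  expect_true(all(stim$accepted))
  # artifact at onset+5 s on one kept channel rejects that trial only
  on1 <- rec$stim$onset[1]
  mask2 <- mask
  mask2[round((on1 + 5) * 25), 1] <- FALSE
  stim2 <- reject_trials(rec, mask2)
  expect_false(stim2$accepted[1])
  expect_true(all(stim2$accepted[-1]))
  # artifact at onset+15 s only: trial kept
  mask3 <- mask
  mask3[round((on1 + 15) * 25), 1] <- FALSE
  isi_ok <- rec$stim$onset[2] - on1 > 17   # ensure it is outside trial 2 too
  stim3 <- reject_trials(rec, mask3)
  expect_true(stim3$accepted[1])
})

test_that("band-pass filter meets gain and attenuation specs", {
  p <- make_probe(1)
  fs <- 25
  n <- 9000
  t <- (seq_len(n) - 1) / fs
  mk <- function(f) {
    rec <- noise_od_recording(n = n, probe = p, sd = 0, seed = 1)
    rec$data[, , ] <- 0
    rec$data[, 1, 1] <- sin(2 * pi * f * t)
    rec
  }
  gain <- function(rec, band) {
    out <- bandpass_filter(rec, band)
    max(abs(out$data[3000:6000, 1, 1]))
  }
  expect_gte(gain(mk(0.05), c(0.009, 0.08)), 0.9)    # FC band passes 0.05 Hz
  expect_lte(gain(mk(1.1), c(0.009, 0.08)), 0.1)     # cardiac rejected >20 dB
  expect_gte(gain(mk(0.1), c(0.01, 3)), 0.9)         # task band lower edge
  expect_gte(gain(mk(1), c(0.01, 3)), 0.9)           # task band upper edge
  z <- mk(0.05); z$data[, , ] <- 0
  expect_true(all(bandpass_filter(z, c(0.009, 0.08))$data == 0))
  expect_error(bandpass_filter(mk(0.05), c(0.01, 13)), "Nyquist")
})

test_that("stage functions refuse inputs of the wrong kind", {
  cfg <- tiny_cfg(seed = 47)
  s <- simulate_task_session(cfg, 1, "control", output = "intensity")
  expect_error(detect_motion_by_channel(s$recording), "od")
  expect_error(mbll(s$recording), "od")
  od <- intensity_to_od(s$recording)
  expect_error(prune_channels(od), "intensity")
  expect_error(intensity_to_od(od), "intensity")
})
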