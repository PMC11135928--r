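test_that("canonical response curve is causal, unit-peaked at 6 s, and translates", {
  tg <- seq(0, 30, by = 0.001)
  h <- canonical_hrf(tg)
  expect_equal(canonical_hrf(0), 0)
  expect_equal(canonical_hrf(-3), 0)
  expect_equal(max(h), 1, tolerance = 1e-9)
  expect_equal(tg[which.max(h)], 6, tolerance = 0.05)
  h2 <- canonical_hrf(tg, latency_shift = 2)
  expect_equal(tg[which.max(h2)], 8, tolerance = 0.05)
  # amplitude scales linearly, width stretches the peak time
  expect_equal(max(canonical_hrf(tg, amplitude = 0.5)), 0.5, tolerance = 1e-9)
  expect_equal(tg[which.max(canonical_hrf(tg, width_scale = 1.5))], 9,
               tolerance = 0.1)
  expect_error(canonical_hrf(1, width_scale = 0))
})

test_that("task schedule matches the block paradigm", {
  cfg <- tiny_cfg(seed = 31)
  s <- simulate_task_session(cfg, 1, "control", output = "hemoglobin")
  stim <- s$recording$stim
  expect_equal(nrow(stim), 20)
  expect_equal(sum(stim$condition == "left_tap"), 10)
  expect_equal(sum(stim$condition == "right_tap"), 10)
  expect_true(all(stim$duration == 10))
  isi <- diff(stim$onset) - 10
  expect_true(all(isi >= 20 & isi <= 24))
})

test_that("simulation is fully deterministic given (config, seed)", {
  cfg <- tiny_cfg(seed = 32)
  a <- simulate_task_session(cfg, 1, "pd", output = "intensity")
  b <- simulate_task_session(cfg, 1, "pd", output = "intensity")
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$artifact_log, b$truth$artifact_log)
  r1 <- simulate_resting_session(cfg, 2, "control")
  r2 <- simulate_resting_session(cfg, 2, "control")
  expect_identical(r1$recording$data, r2$recording$data)
  # different subjects differ
  c2 <- simulate_task_session(cfg, 2, "pd", output = "intensity")
  expect_false(identical(a$recording$data, c2$recording$data))
})

test_that("superficial component is shared between long and short channels", {
  cfg <- tiny_cfg(seed = 33, superficial_amp = 0.5, artifact_rate = 0,
                  hrf_params = list(control = list(
                    right_tap = c(amplitude = 0, latency_shift = 0, width_scale = 1),
                    left_tap = c(amplitude = 0, latency_shift = 0, width_scale = 1))))
  s <- simulate_task_session(cfg, 1, "control", output = "intensity")
  od <- intensity_to_od(s$recording)
  ch <- cfg$probe$channels
  shorts <- which(ch$is_short)
  longs <- which(!ch$is_short)
  r <- abs(cor(od$data[, shorts[1], 1], od$data[, longs, 1]))
  expect_true(mean(r > 0.5) > 0.9)
})

test_that("resting sessions have the configured duration and coupling", {
  cfg <- tiny_cfg(seed = 34)
  s <- simulate_resting_session(cfg, 1, "control", output = "hemoglobin")
  expect_equal(nrow(s$recording$hbo), 9000)   # 6 min at 25 Hz
  # empirical homolog correlation of the latent band-limited series
  hp <- homolog_pairs(cfg$probe)
  ch <- cfg$probe$channels
  long_row <- function(id) match(id, ch$channel_id[!ch$is_short])
  rs <- unlist(lapply(1:12, function(sub) {
    lat <- simulate_resting_session(cfg, sub, "control",
                                    output = "hemoglobin")$truth$latent
    mapply(function(l, r) cor(lat[, long_row(l)], lat[, long_row(r)]),
           hp$left_id, hp$right_id)
  }))
  expect_lt(abs(mean(rs) - 0.6), 0.05)
  # degenerate case: perfect coupling is representable
  cfg1 <- tiny_cfg(seed = 34,
                   coupling = list(control = c(rho_inter = 1, rho_intra = 0.5)))
  s1 <- simulate_resting_session(cfg1, 1, "control", output = "hemoglobin")
  lat <- s1$truth$latent
  expect_equal(cor(lat[, long_row(hp$left_id[1])],
                   lat[, long_row(hp$right_id[1])]), 1, tolerance = 1e-6)
  # infeasible structure rejected
  cfg2 <- tiny_cfg(seed = 34,
                   coupling = list(control = c(rho_inter = 0.9, rho_intra = -0.5)))
  expect_error(simulate_resting_session(cfg2, 1, "control"), "config error")
})

test_that("forward optical model inverts exactly through od and mbll", {
  p <- default_probe()
  set.seed(35)
  n <- 500
  hbo <- matrix(rnorm(n * 22, sd = 0.5), n, 22)
  hbr <- matrix(rnorm(n * 22, sd = 0.2), n, 22)
  I <- chromo_to_intensity(hbo, hbr, p, baseline_intensity = 2)
  rec <- nirs_recording(I, 25, "intensity", p)
  od <- intensity_to_od(rec, reference = 2)
  hm <- mbll(od)
  expect_lt(max(abs(hm$hbo - hbo)) / max(abs(hbo)), 1e-10)
  expect_lt(max(abs(hm$hbr - hbr)) / max(abs(hbr)), 1e-10)
  # zero concentration change gives constant baseline intensity
  I0 <- chromo_to_intensity(matrix(0, 5, 22), matrix(0, 5, 22), p, 3)
  expect_true(all(I0 == 3))
  expect_error(chromo_to_intensity(hbo, hbr, p, baseline_intensity = -1),
               "domain error")
  bad <- extinction_table()
  expect_error(extinction_matrix_check <- nirsmotor:::extinction_matrix(bad[1, ]),
               "two wavelengths")
})

test_that("motion artifact injection is seeded, logged, and above threshold", {
  cfg <- tiny_cfg(seed = 36, artifact_rate = 3)
  rec <- noise_od_recording(seed = 36)
  a <- inject_motion_artifacts(rec, cfg, seed = 99)
  b <- inject_motion_artifacts(rec, cfg, seed = 99)
  expect_identical(a$log, b$log)
  expect_true(nrow(a$log) > 0)
  expect_true(all(a$log$magnitude >= 2 * cfg$amp_thresh_scale - 1e-9))
  expect_true(all(a$log$magnitude <= 10 * cfg$amp_thresh_scale + 1e-9))
  expect_true(all(a$log$duration[a$log$kind == "spike"] <= 1))
  # every spike leaves a sample deviating > 0.5 OD from baseline
  spikes <- a$log[a$log$kind == "spike", ]
  for (i in seq_len(nrow(spikes))) {
    i0 <- floor(spikes$onset[i] * 25) + 1
    i1 <- min(dim(rec$data)[1], i0 + ceiling(spikes$duration[i] * 25))
    expect_gt(max(abs(a$recording$data[i0:i1, spikes$channel[i], 1])), 0.5)
  }
  # zero rate is the identity
  cfg0 <- tiny_cfg(seed = 36, artifact_rate = 0)
  z <- inject_motion_artifacts(rec, cfg0, seed = 1)
  expect_identical(z$recording$data, rec$data)
  expect_equal(nrow(z$log), 0)
})

test_that("injected group effects appear in the ground truth", {
  cfg <- sim_config(n_per_group = 8, seed = 37, subject_latency_sd = 0)
  tt <- function(g) sapply(1:8, function(s)
    simulate_task_session(cfg, s, g,
                          output = "hemoglobin")$truth$time_to_peak["right_tap"])
  d <- mean(tt("pd")) - mean(tt("control"))
  expect_equal(d, 2, tolerance = 0.1)  # configured latency shift
})
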