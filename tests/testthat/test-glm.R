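test_that("design matrix has the expected structure", {
  cfg <- tiny_cfg(seed = 51)
  s <- simulate_task_session(cfg, 1, "control", output = "hemoglobin")
  spec <- glm_spec()
  des <- build_design_matrix(s$recording$stim, spec, s$recording, "hbo")
  # 28 basis centers per condition over (-2, 25) at 1 s spacing
  expect_equal(sum(des$map$kind == "basis" & des$map$condition == "left_tap"), 28)
  expect_equal(sum(des$map$kind == "basis" & des$map$condition == "right_tap"), 28)
  # drift block has 4 columns (orders 0..3)
  expect_equal(sum(des$map$kind == "drift"), 4)
  expect_equal(ncol(des$X), 60)
  # dropping all trials of one condition drops its columns with a warning
  stim <- s$recording$stim
  stim$accepted[stim$condition == "left_tap"] <- FALSE
  expect_warning(des2 <- build_design_matrix(stim, spec, s$recording, "hbo"),
                 "left_tap")
  expect_false("left_tap" %in% des2$map$condition)
})

test_that("short-channel selection picks the most correlated short", {
  # duplicate one long channel's superficial part into short channel 1
  p <- make_probe(2)
  n <- 3000
  set.seed(52)
  sup <- as.numeric(arima.sim(list(ar = 0.99), n)) / 10
  hbo <- matrix(rnorm(n * 6, sd = 0.05), n, 6)
  hbo[, 1] <- hbo[, 1] + sup
  hbo[, 5] <- sup + rnorm(n, sd = 0.01)       # short 1 carries the confound
  hbo[, 6] <- rnorm(n, sd = 0.05)             # short 2 does not
  h <- hemo_series(hbo, -hbo / 3, 25, p)
  des <- build_design_matrix(data.frame(condition = "right_tap", onset = 10,
                                        duration = 10, accepted = TRUE),
                             glm_spec(), h, "hbo")
  expect_equal(des$ss_choice[1], 1)
})

test_that("OLS solution matches an independent normal-equations solve", {
  set.seed(53)
  n <- 200
  X <- cbind(1, matrix(rnorm(n * 5), n, 5))
  beta <- rnorm(6)
  y <- X %*% beta + rnorm(n, sd = 0.1)
  fit <- stats::lm.fit(X, y)$coefficients       # path used inside fit_glm
  oracle <- solve(t(X) %*% X, t(X) %*% y)       # brute-force normal equations
  expect_equal(unname(fit), drop(oracle), tolerance = 1e-10)
})

test_that("GLM recovers a noise-free band-limited response and absorbs constants", {
  cfg <- tiny_cfg(seed = 54, superficial_amp = 0, white_noise_sd = 1e-12,
                  systemic = list(cardiac_hz = 1.1, resp_hz = 0.25,
                                  mayer_hz = 0.1, amps = c(0, 0, 0)),
                  subject_amp_sd = 0, subject_latency_sd = 0,
                  artifact_rate = 0)
  s <- simulate_task_session(cfg, 1, "control", output = "hemoglobin")
  h <- s$recording
  ch <- h$probe$channels
  left1 <- which(ch$hemisphere == "left" & !ch$is_short)[1]
  est <- fit_glm(h, glm_spec(ss_regressor = "none"), chromophores = "hbo",
                 channels = left1)
  truth <- s$truth$hrf$right_tap
  rmse <- sqrt(mean((est$curves$hbo$right_tap[, left1] - truth)^2))
  expect_lt(rmse, 0.02 * max(abs(truth)))
  # adding a constant changes only the drift block
  h2 <- h
  h2$hbo <- h$hbo + 5
  est2 <- fit_glm(h2, glm_spec(ss_regressor = "none"), chromophores = "hbo",
                  channels = left1)
  expect_equal(est2$curves$hbo$right_tap[, left1],
               est$curves$hbo$right_tap[, left1], tolerance = 1e-8)
})

test_that("single-trial walking analysis requires one walk event and finds the effect", {
  cfg <- tiny_cfg(seed = 55)
  s <- simulate_walk_session(cfg, 1, "control", output = "hemoglobin")
  est <- single_trial_walk(s$recording, chromophores = "hbo")
  expect_equal(range(est$grid), c(-2, 25))    # 27 s span
  ft <- extract_features(est, 1)
  ch <- cfg$probe$channels
  left <- ft$channel %in% ch$channel_id[!ch$is_short & ch$hemisphere == "left"]
  expect_gt(mean(ft$mean[left]), mean(ft$mean[!left]))
  # zero or multiple walk events are paradigm errors
  bad <- s$recording
  bad$stim <- bad$stim[0, ]
  expect_error(single_trial_walk(bad), "paradigm error")
  bad2 <- s$recording
  bad2$stim <- rbind(bad2$stim, bad2$stim)
  expect_error(single_trial_walk(bad2), "paradigm error")
})

test_that("feature extraction matches closed forms", {
  p <- make_probe(1)
  fs <- 25
  grid <- seq(-2, 25, by = 1 / fs)
  # triangular curve: rise 0->1 over 0->5 s, decay back to 0 by 10 s
  tri <- approx(c(-2, 0, 5, 10, 25), c(0, 0, 1, 0, 0), xout = grid)$y
  est <- structure(list(grid = grid,
                        curves = list(hbo = list(right_tap = cbind(tri, tri, tri, tri))),
                        channels = 1L, probe = p),
                   class = "hrf_estimate")
  ft <- extract_features(est, 1)
  expect_equal(ft$peak, 1)
  expect_equal(ft$time_to_peak, 5)
  # least-squares slope of the 0->5 ramp is exactly 0.2
  expect_equal(ft$slope, 0.2, tolerance = 1e-10)
  # constant curve: mean c, auc 25c, degenerate peak convention for 0
  cst <- rep(0.4, length(grid))
  est$curves$hbo$right_tap <- cbind(cst, cst, cst, cst)
  ft2 <- extract_features(est, 1)
  expect_equal(ft2$mean, 0.4)
  expect_equal(ft2$auc, 10, tolerance = 1e-10)
  est$curves$hbo$right_tap <- matrix(0, length(grid), 4)
  ft3 <- extract_features(est, 1)
  expect_true(ft3$flat)
  expect_equal(c(ft3$peak, ft3$time_to_peak, ft3$slope), c(0, 0, 0))
  # HbR-style negative deflection keeps its sign
  est$curves$hbo$right_tap <- cbind(-tri, -tri, -tri, -tri)
  ft4 <- extract_features(est, 1)
  expect_equal(ft4$peak, -1)
  expect_equal(ft4$time_to_peak, 5)
})

test_that("hbt equals hbo + hbr exactly, including through the GLM", {
  cfg <- tiny_cfg(seed = 56)
  s <- simulate_task_session(cfg, 1, "control", output = "hemoglobin")
  h <- s$recording
  expect_identical(h$hbt, h$hbo + h$hbr)
  ch <- h$probe$channels
  left1 <- which(ch$hemisphere == "left" & !ch$is_short)[1]
  est <- fit_glm(h, glm_spec(ss_regressor = "none"),
                 chromophores = c("hbo", "hbr", "hbt"), channels = left1)
  expect_equal(est$curves$hbt$right_tap[, left1],
               est$curves$hbo$right_tap[, left1] +
                 est$curves$hbr$right_tap[, left1], tolerance = 1e-8)
})
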