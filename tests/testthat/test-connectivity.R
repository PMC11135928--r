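test_that("short-channel mean has the arithmetic-mean behavior", {
  s1 <- sin(seq(0, 10, by = 0.1))
  expect_equal(ssc_mean(cbind(s1, s1)), s1)
  expect_equal(ssc_mean(cbind(0 * s1, 2 * s1)), s1)
  expect_equal(ssc_mean(cbind(s1)), s1)    # n = 1 reduces to the series itself
})

test_that("tikhonov regression matches OLS at lambda 0 and the scalar closed form", {
  set.seed(61)
  n <- 500
  s <- rnorm(n)
  Y <- cbind(2 * s, s + rnorm(n), rnorm(n))
  reg0 <- tikhonov_regress(Y, s, lambda = 0)
  expect_equal(reg0$beta[1], 2, tolerance = 1e-10)
  # brute-force OLS oracle
  ols <- sapply(1:3, function(g) solve(sum(s^2), sum(s * Y[, g])))
  expect_equal(reg0$beta, ols, tolerance = 1e-10)
  # closed form under the published lambda policy
  for (rep in 1:20) {
    s2 <- rnorm(n)
    y2 <- rnorm(n)
    S <- sum(s2^2)
    regp <- tikhonov_regress(cbind(y2), s2, lambda = "policy")
    expect_equal(regp$lambda[1], 0.001 * S, tolerance = 1e-12)
    expect_equal(regp$beta[1], sum(s2 * y2) / (S + (0.001 * S)^2),
                 tolerance = 1e-12)
  }
  # shrinkage: |beta| decreases monotonically in lambda
  lams <- c(0, 1, 10, 100, 1000)
  bs <- sapply(lams, function(l) abs(tikhonov_regress(Y[, 1, drop = FALSE],
                                                      s, lambda = l)$beta))
  expect_true(all(diff(bs) <= 1e-12))
  expect_error(tikhonov_regress(Y, rep(1, n)), "zero-variance")
})

test_that("residualization removes the fitted superficial component", {
  set.seed(62)
  n <- 400
  s <- rnorm(n)
  Y <- cbind(3 * s + rnorm(n, sd = 0.1))
  reg <- tikhonov_regress(Y, s, lambda = 0)
  Yp <- residualize(Y, reg)
  # OLS orthogonality
  expect_lt(abs(sum(s * Yp)), 1e-8 * sqrt(sum(s^2) * sum(Y^2)))
  # beta = 0 is the identity
  reg0 <- reg; reg0$beta <- 0
  expect_equal(residualize(Y, reg0), Y)
  # Y = s at lambda 0 residualizes to ~0
  regs <- tikhonov_regress(cbind(s), s, lambda = 0)
  expect_lt(max(abs(residualize(cbind(s), regs))), 1e-10)
  expect_error(residualize(Y[1:10, , drop = FALSE], reg), "grid mismatch")
})

test_that("fisher z matches the printed formula and its symmetries", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisher_z(0.9), 1.47222, tolerance = 1e-5)
  r <- seq(-0.999, 0.999, by = 0.001)
  expect_equal(fisher_z(r), 0.5 * log((1 + r) / (1 - r)), tolerance = 1e-12)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  # clamping sentinel at |r| >= 1
  expect_equal(fisher_z(1), fisher_z(0.999999))
  expect_lt(fisher_z(1), Inf)
})

test_that("correlation matrices are symmetric with unit diagonal and honor masks", {
  set.seed(63)
  n <- 2000
  Y <- matrix(rnorm(n * 4), n, 4)
  Y[, 2] <- Y[, 1]
  res <- correlation_matrix(Y)
  expect_equal(res$r_matrix, t(res$r_matrix))
  expect_equal(diag(res$r_matrix), rep(1, 4))
  expect_equal(res$r_matrix[1, 2], 1)
  # white-noise null: off-diagonals are small at n = 9000
  Y2 <- matrix(rnorm(9000 * 6), 9000, 6)
  r2 <- correlation_matrix(Y2)$r_matrix
  off <- abs(r2[upper.tri(r2)])
  expect_gte(mean(off < 0.05), 0.90)
  # pruned channels give missing rows; sparse joint masks warn
  res3 <- correlation_matrix(Y, channel_mask = c(TRUE, TRUE, FALSE, TRUE))
  expect_true(all(is.na(res3$r_matrix[3, ])))
  clean <- matrix(TRUE, n, 4)
  clean[1:(n - 10), 4] <- FALSE
  w <- capture_warnings(res4 <- correlation_matrix(Y, clean = clean))
  expect_true(any(grepl("joint clean", w)))
  expect_true(is.na(res4$r_matrix[1, 4]))
  expect_false(is.na(res4$r_matrix[1, 2]))
})

test_that("hemispheric indices average the right pair sets", {
  p <- default_probe()
  nch <- nrow(p$channels)
  Z <- matrix(0, nch, nch)
  res <- list(z_matrix = Z)
  ix <- hemispheric_indices(res, p)
  expect_equal(ix$inter, 0)
  expect_equal(ix$intra_left, 0)
  expect_equal(unname(ix$n_pairs["intra_left"]), 45L)  # choose(10, 2)
  expect_equal(unname(ix$n_pairs["inter"]), 10L)
  # constant r = 0.9 everywhere
  R <- matrix(0.9, nch, nch); diag(R) <- 1
  res2 <- list(z_matrix = fisher_z(R))
  ix2 <- hemispheric_indices(res2, p)
  expect_equal(ix2$inter, 1.47222, tolerance = 1e-5)
  expect_equal(ix2$intra_right, 1.47222, tolerance = 1e-5)
  # clamped perfect correlation gives the finite sentinel
  R1 <- matrix(1, nch, nch)
  ix3 <- hemispheric_indices(list(z_matrix = fisher_z(R1)), p)
  expect_equal(ix3$inter, fisher_z(0.999999))
})

test_that("superficial-confound removal restores the latent homolog coupling", {
  # channels = latent + kappa * superficial, shorts = superficial
  set.seed(64)
  n <- 9000
  p <- make_probe(2)
  rho <- 0.5
  for (kappa in c(0.5, 2)) {
    lat <- matrix(rnorm(n * 2), n, 2) %*% chol(matrix(c(1, rho, rho, 1), 2))
    sup <- rnorm(n)
    hbo <- cbind(lat[, 1] + kappa * sup, rnorm(n),       # ch 1 (L) + ch 2
                 lat[, 2] + kappa * sup, rnorm(n),       # ch 3 (R, homolog of 1)
                 sup + rnorm(n, sd = 0.01), sup + rnorm(n, sd = 0.01))
    h <- hemo_series(hbo, -hbo / 3, 25, p)
    fc <- fc_analysis(h, chromophores = "hbo")
    r_post <- fc$hbo$r_matrix[1, 3]
    expect_lt(abs(r_post - rho), 0.05)
    fc0 <- fc_analysis(h, chromophores = "hbo", ssc = FALSE)
    expect_gt(fc0$hbo$r_matrix[1, 3], r_post)  # confound inflates coupling
  }
})
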