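#' GLM specification for HRF estimation
#'
#' The response window runs from 2 s before stimulus onset to 25 s
#' post-onset.  The temporal basis is a train of Gaussians about 1 s broad
#' (sd = `basis_sd`, full width at half maximum ~1.18 s) centered every
#' `spacing` seconds across the window; drift is modeled by Legendre
#' polynomials up to `drift_order`; the short-separation nuisance regressor
#' is, per long channel, the short-channel series with the largest absolute
#' Pearson correlation with that channel, computed on the chromophore being
#' fitted over clean samples only.
#'
#' @param window numeric pair (s) relative to onset.
#' @param basis_sd Gaussian sd (s).
#' @param spacing basis center spacing (s).
#' @param drift_order maximum drift polynomial order.
#' @param ss_regressor "max_correlation" or "none".
#' @export
glm_spec <- function(window = c(-2, 25), basis_sd = 0.5, spacing = 1,
                     drift_order = 3,
                     ss_regressor = c("max_correlation", "none")) {
  stopifnot(spacing > 0, basis_sd > 0, window[1] < window[2])
  list(window = window, basis_sd = basis_sd, spacing = spacing,
       drift_order = drift_order, ss_regressor = match.arg(ss_regressor))
}

basis_centers <- function(spec) {
  seq(spec$window[1], spec$window[2], by = spec$spacing)
}

# Legendre-style orthogonal drift polynomials over the record span
drift_block <- function(n, order) {
  u <- seq(-1, 1, length.out = n)
  out <- sapply(0:order, function(k) u^k)
  qr.Q(qr(out)) * sqrt(n)            # orthonormal columns, scaled O(1)
}

#' Build the GLM design matrix
#'
#' Columns: per modeled condition, one Gaussian-train regressor per basis
#' center (Gaussians placed at accepted onsets only); Legendre drift
#' polynomials of order 0..`drift_order`; optionally one short-channel
#' nuisance column per long channel, selected by largest absolute Pearson
#' correlation.  Conditions with no accepted trials are dropped with a
#' warning.
#'
#' @param stim stimulus schedule.
#' @param spec a [glm_spec()].
#' @param hemo a `hemo_series` (time base, masks, probe).
#' @param chromo chromophore the short-channel selection is computed on.
#' @return list: `X` (common columns), `map` (data.frame describing
#'   columns), `ss` (matrix of candidate short-channel series or NULL),
#'   `ss_choice` (per-channel index into `ss`), `conditions`.
#' @export
build_design_matrix <- function(stim, spec, hemo,
                                chromo = c("hbo", "hbr", "hbt")) {
  chromo <- match.arg(chromo)
  t <- time_base(hemo)
  n <- length(t)
  conds <- unique(stim$condition)
  keep <- vapply(conds, function(cc)
    any(stim$accepted[stim$condition == cc]), TRUE)
  if (any(!keep))
    warning("condition(s) without accepted trials dropped: ",
            paste(conds[!keep], collapse = ", "))
  conds <- conds[keep]
  if (!length(conds)) stop("no accepted trials in any condition")

  centers <- basis_centers(spec)
  nb <- length(centers)
  X <- matrix(0, n, nb * length(conds))
  col <- 0L
  for (cc in conds) {
    ons <- stim$onset[stim$condition == cc & stim$accepted]
    for (j in seq_len(nb)) {
      col <- col + 1L
      v <- numeric(n)
      for (o in ons) {
        mu <- o + centers[j]
        lo <- max(1L, floor((mu - 5 * spec$basis_sd) * hemo$fs))
        hi <- min(n, ceiling((mu + 5 * spec$basis_sd) * hemo$fs) + 1L)
        if (hi >= lo) {
          i <- lo:hi
          v[i] <- v[i] + exp(-(t[i] - mu)^2 / (2 * spec$basis_sd^2))
        }
      }
      X[, col] <- v
    }
  }
  map <- data.frame(kind = "basis",
                    condition = rep(conds, each = nb),
                    center = rep(centers, length(conds)))
  D <- drift_block(n, spec$drift_order)
  X <- cbind(X, D)
  map <- rbind(map, data.frame(kind = "drift", condition = NA,
                               center = 0:spec$drift_order))

  ss <- NULL; ss_choice <- NULL
  shorts <- which(hemo$probe$channels$is_short & hemo$channel_mask)
  if (spec$ss_regressor == "max_correlation") {
    if (!length(shorts)) {
      warning("no short channels survive pruning; SS regressor omitted")
    } else {
      ss <- chromophore(hemo, chromo)[, shorts, drop = FALSE]
      Y <- chromophore(hemo, chromo)
      clean <- hemo$motion_mask
      nch <- ncol(Y)
      ss_choice <- integer(nch)
      for (c in seq_len(nch)) {
        if (!hemo$channel_mask[c] || hemo$probe$channels$is_short[c]) next
        ok <- clean[, c] & rowSums(!clean[, shorts, drop = FALSE]) == 0
        if (sum(ok) < 30) ok <- rep(TRUE, nrow(Y))
        r <- abs(stats::cor(Y[ok, c], ss[ok, , drop = FALSE]))
        ss_choice[c] <- which.max(r)
      }
    }
  }
  list(X = X, map = map, ss = ss, ss_choice = ss_choice, conditions = conds)
}

#' Fit the GLM and reconstruct HRF curves
#'
#' Ordinary least squares per channel and chromophore.  The estimated HRF
#' for a condition is the Gaussian-basis block expanded onto the window
#' grid.  Rank-deficient designs have their aliased columns dropped with a
#' warning (their coefficients set to zero).
#'
#' @param hemo a `hemo_series`.
#' @param spec a [glm_spec()].
#' @param chromophores chromophores to fit.
#' @param channels channel indices to fit (default: kept long channels).
#' @return An object of class `hrf_estimate`: list with `curves`
#'   (`curves[[chromo]][[condition]]` = matrix `[grid x channel]`), `grid`,
#'   `betas`, `residual_variance`, `ss_used`, `spec`.
#' @export
fit_glm <- function(hemo, spec = glm_spec(),
                    chromophores = c("hbo", "hbr", "hbt"),
                    channels = NULL) {
  stopifnot(inherits(hemo, "hemo_series"))
  ch <- hemo$probe$channels
  if (is.null(channels))
    channels <- which(hemo$channel_mask & !ch$is_short)
  grid <- seq(spec$window[1], spec$window[2], by = 1 / hemo$fs)
  centers <- basis_centers(spec)
  B <- outer(grid, centers, function(a, b)
    exp(-(a - b)^2 / (2 * spec$basis_sd^2)))

  out <- list(grid = grid, spec = spec, curves = list(), betas = list(),
              residual_variance = list(), ss_used = list())
  for (chr in chromophores) {
    des <- build_design_matrix(hemo$stim, spec, hemo, chr)
    Y <- chromophore(hemo, chr)
    nb <- length(centers)
    curves <- lapply(des$conditions, function(cc)
      matrix(NA_real_, length(grid), ncol(Y)))
    names(curves) <- des$conditions
    betas <- matrix(NA_real_, ncol(des$X) + !is.null(des$ss), ncol(Y))
    rv <- rep(NA_real_, ncol(Y))
    ssu <- rep(NA_integer_, ncol(Y))
    for (c in channels) {
      X <- des$X
      if (!is.null(des$ss) && des$ss_choice[c] > 0) {
        X <- cbind(X, des$ss[, des$ss_choice[c]])
        ssu[c] <- des$ss_choice[c]
      }
      fit <- stats::lm.fit(X, Y[, c])
      beta <- fit$coefficients
      if (anyNA(beta)) {
        warning("rank-deficient design for channel ", ch$channel_id[c],
                ": dropped columns ", paste(which(is.na(beta)), collapse = ","))
        beta[is.na(beta)] <- 0
      }
      betas[seq_along(beta), c] <- beta
      rv[c] <- sum(fit$residuals^2) / max(1, length(fit$residuals) - fit$rank)
      for (k in seq_along(des$conditions)) {
        bi <- ((k - 1) * nb + 1):(k * nb)
        curves[[k]][, c] <- B %*% beta[bi]
      }
    }
    out$curves[[chr]] <- curves
    out$betas[[chr]] <- betas
    out$residual_variance[[chr]] <- rv
    out$ss_used[[chr]] <- ssu
  }
  out$channels <- channels
  out$probe <- hemo$probe
  class(out) <- "hrf_estimate"
  out
}

#' @export
print.hrf_estimate <- function(x, ...) {
  cat(sprintf("<hrf_estimate> %d channels, conditions: %s, window (%g, %g) s\n",
              length(x$channels),
              paste(names(x$curves[[1]]), collapse = ", "),
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' Single-trial GLM for the walking bout
#'
#' Applies the same Gaussian-basis GLM machinery to the one walking event,
#' over the (-2, 25) s window.
#'
#' @param hemo a `hemo_series` whose schedule contains exactly one "walk"
#'   event.
#' @param spec a [glm_spec()].
#' @inheritParams fit_glm
#' @return An `hrf_estimate`.
#' @export
single_trial_walk <- function(hemo, spec = glm_spec(),
                              chromophores = c("hbo", "hbr", "hbt"),
                              channels = NULL) {
  walks <- which(hemo$stim$condition == "walk")
  if (length(walks) != 1)
    stop("paradigm error: expected exactly one walk event, found ",
         length(walks))
  hemo$stim <- hemo$stim[walks, , drop = FALSE]
  fit_glm(hemo, spec, chromophores, channels)
}

#' Extract scalar HRF features
#'
#' Over the post-onset window `t` in `[0, 25]` s: `peak` is the signed
#' value at the extremum of largest magnitude (preserving the sign of
#' deactivations, e.g. for HbR), `time_to_peak` its time, `auc` the
#' trapezoidal integral, `mean` the time average, and `slope` the
#' least-squares line slope fitted from onset to the peak.  A flat curve
#' yields the degenerate convention peak = time_to_peak = slope = 0 with
#' `flat = TRUE`.
#'
#' @param est an `hrf_estimate`.
#' @param subject optional subject identifier carried into the table.
#' @return data.frame with one row per (condition, channel, chromophore)
#'   and columns `peak`, `time_to_peak`, `auc`, `mean`, `slope`, `flat`.
#' @export
extract_features <- function(est, subject = NA) {
  post <- est$grid >= 0
  tp <- est$grid[post]
  rows <- list()
  for (chr in names(est$curves)) {
    for (cc in names(est$curves[[chr]])) {
      M <- est$curves[[chr]][[cc]]
      for (c in est$channels) {
        y <- M[post, c]
        rows[[length(rows) + 1]] <- data.frame(
          subject = subject, condition = cc,
          channel = est$probe$channels$channel_id[c], chromophore = chr,
          curve_features(tp, y))
      }
    }
  }
  do.call(rbind, rows)
}

curve_features <- function(tp, y) {
  if (all(abs(y) < .Machine$double.eps * 100))
    return(data.frame(peak = 0, time_to_peak = 0,
                      auc = 0, mean = 0, slope = 0, flat = TRUE))
  i <- which.max(abs(y))
  peak <- y[i]
  ttp <- tp[i]
  auc <- sum(diff(tp) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  mn <- auc / (max(tp) - min(tp))
  rise <- tp <= ttp
  slope <- if (sum(rise) >= 2)
    stats::cov(tp[rise], y[rise]) / stats::var(tp[rise]) else 0
  data.frame(peak = peak, time_to_peak = ttp, auc = auc, mean = mn,
             slope = slope, flat = FALSE)
}
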