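#' Channel-pruning parameters
#'
#' Defaults follow the published quality-control settings: raw intensity
#' must average between 1e-7 and 1e7 a.u., the signal-to-noise ratio
#' (temporal mean / temporal sd of raw intensity) must reach 2 at both
#' wavelengths, and the source-detector separation must fall inside
#' `sd_range`, expressed in meters as in the Homer convention (the default
#' upper bound of 0.45 m imposes no effective limit on this probe).
#'
#' @param intensity_range numeric pair (a.u.).
#' @param snr_thresh positive scalar.
#' @param sd_range numeric pair (m).
#' @export
prune_params <- function(intensity_range = c(1e-7, 1e7), snr_thresh = 2,
                         sd_range = c(0, 0.45)) {
  stopifnot(intensity_range[1] < intensity_range[2], snr_thresh > 0)
  list(intensity_range = intensity_range, snr_thresh = snr_thresh,
       sd_range = sd_range)
}

#' Motion-detection parameters
#'
#' Defaults follow the published settings: a sliding window of `t_motion`
#' = 1 s flags motion when the within-window amplitude change exceeds
#' `amp_thresh` = 0.5 OD or the windowed standard deviation exceeds
#' `sd_thresh` = 15 times the channel's typical (median) windowed standard
#' deviation; `t_mask` = 1 s of data around the excursion is masked.
#'
#' @param t_motion,t_mask window and mask lengths (s).
#' @param amp_thresh amplitude threshold (OD).
#' @param sd_thresh fold-change threshold for the windowed sd.
#' @export
motion_params <- function(t_motion = 1, t_mask = 1, amp_thresh = 0.5,
                          sd_thresh = 15) {
  stopifnot(t_motion > 0, t_mask > 0, amp_thresh > 0, sd_thresh > 0)
  list(t_motion = t_motion, t_mask = t_mask, amp_thresh = amp_thresh,
       sd_thresh = sd_thresh)
}

#' Prune channels on intensity statistics
#'
#' Keeps a channel iff, at both wavelengths, its mean raw intensity lies in
#' `intensity_range` and its SNR (mean/sd) reaches `snr_thresh`, and its
#' source-detector separation lies inside `sd_range`.  The resulting mask is
#' stored on the returned recording.
#'
#' @param rec a `nirs_recording` of kind "intensity".
#' @param p parameters from [prune_params()].
#' @return The recording with `channel_mask` updated.
#' @export
prune_channels <- function(rec, p = prune_params()) {
  if (rec$kind != "intensity")
    stop("prune_channels operates on raw intensity recordings")
  nch <- dim(rec$data)[2]
  keep <- rep(TRUE, nch)
  for (c in seq_len(nch)) {
    sep_m <- rec$probe$channels$separation[c] / 1000
    if (sep_m < p$sd_range[1] || sep_m > p$sd_range[2]) { keep[c] <- FALSE; next }
    for (w in seq_len(dim(rec$data)[3])) {
      x <- rec$data[, c, w]
      m <- mean(x); s <- stats::sd(x)
      snr <- if (s == 0) Inf else m / s
      if (m < p$intensity_range[1] || m > p$intensity_range[2] ||
          snr < p$snr_thresh) keep[c] <- FALSE
    }
  }
  if (!any(keep)) stop("empty-data error: all channels pruned")
  rec$channel_mask <- keep
  rec
}

#' Convert intensity to optical-density changes
#'
#' `dOD(t) = -log10(I(t) / I_ref)` per channel and wavelength.  By default
#' `I_ref` is the temporal mean of each series (the convention of standard
#' fNIRS toolboxes); pass `reference` explicitly (scalar or
#' `[n_channels x n_wavelengths]` matrix) when the true baseline intensity
#' is known, e.g. for simulated data, which makes the conversion the exact
#' inverse of the forward optical model.
#'
#' @param rec a `nirs_recording` of kind "intensity".
#' @param reference "mean", a scalar, or a matrix of baseline intensities.
#' @return A `nirs_recording` of kind "od".
#' @export
intensity_to_od <- function(rec, reference = "mean") {
  if (rec$kind != "intensity")
    stop("intensity_to_od expects an intensity recording")
  d <- rec$data
  nch <- dim(d)[2]; nwl <- dim(d)[3]
  for (c in seq_len(nch)) {
    if (!rec$channel_mask[c]) next
    for (w in seq_len(nwl)) {
      x <- d[, c, w]
      if (any(x <= 0)) {
        bad <- which(x <= 0)[1]
        stop(sprintf("domain error: nonpositive intensity on kept channel %d (wavelength %d) at sample %d",
                     rec$probe$channels$channel_id[c], w, bad))
      }
      iref <- if (identical(reference, "mean")) mean(x)
              else if (is.matrix(reference)) reference[c, w]
              else as.numeric(reference)
      d[, c, w] <- -log10(x / iref)
    }
  }
  rec$data <- d
  rec$kind <- "od"
  rec
}

# rolling statistics over windows of w samples starting at 1..(n-w+1)
roll_maxmin <- function(x, w) {
  n <- length(x)
  shifts <- lapply(0:(w - 1), function(k) x[(1 + k):(n - w + 1 + k)])
  list(max = Reduce(pmax, shifts), min = Reduce(pmin, shifts))
}

roll_sd <- function(x, w) {
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  n <- length(x)
  i <- seq_len(n - w + 1)
  s1 <- cs[i + w] - cs[i]
  s2 <- cs2[i + w] - cs2[i]
  v <- pmax((s2 - s1^2 / w) / (w - 1), 0)
  sqrt(v)
}

#' Detect motion artifacts channel by channel
#'
#' Slides a `t_motion`-long window over each channel's OD series at each
#' wavelength.  A window triggers when its max-min signal change exceeds
#' `amp_thresh` or its standard deviation exceeds `sd_thresh` times the
#' channel's median windowed standard deviation.  Samples of triggered
#' windows, dilated by `t_mask / 2` seconds on each side, are marked as
#' artifact; a channel-sample is artifact if flagged at either wavelength.
#'
#' @param rec a `nirs_recording` of kind "od".
#' @param m parameters from [motion_params()].
#' @return logical matrix `[n x n_channels]`, `TRUE` = clean.
#' @export
detect_motion_by_channel <- function(rec, m = motion_params()) {
  if (rec$kind != "od")
    stop("detect_motion_by_channel expects an od recording")
  n <- dim(rec$data)[1]; nch <- dim(rec$data)[2]; nwl <- dim(rec$data)[3]
  w <- max(2L, round(m$t_motion * rec$fs))
  pad <- round(m$t_mask * rec$fs / 2)
  clean <- matrix(TRUE, n, nch)
  for (c in seq_len(nch)) {
    if (!rec$channel_mask[c]) next
    for (wl in seq_len(nwl)) {
      x <- rec$data[, c, wl]
      mm <- roll_maxmin(x, w)
      sds <- roll_sd(x, w)
      ref <- stats::median(sds)
      trig <- (mm$max - mm$min > m$amp_thresh) |
        (ref > 0 & sds > m$sd_thresh * ref)
      if (!any(trig)) next
      starts <- which(trig)
      lo <- pmax(1L, starts - pad)
      hi <- pmin(n, starts + w - 1L + pad)
      bad <- logical(n)
      for (k in seq_along(starts)) bad[lo[k]:hi[k]] <- TRUE
      clean[bad, c] <- FALSE
    }
  }
  clean
}

# contiguous runs of TRUE in a logical vector -> matrix of (start, end)
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Spline-based motion correction
#'
#' Within each artifact segment the signal is replaced by its residual
#' around a smoothing-spline fit, re-leveled so the segment mean matches
#' the mean of the adjacent clean data; clean segments are untouched.  The
#' smoothing parameter `p_smooth` follows the fidelity-vs-roughness
#' convention where `p -> 1` approaches interpolation; it is mapped to the
#' smoothing-spline penalty `lambda = (1 - p) / p`.  Segments touching the
#' record boundary are re-leveled to their single adjacent clean segment.
#'
#' @param rec a `nirs_recording` of kind "od".
#' @param mask logical `[n x n_channels]` motion mask, `TRUE` = clean.
#' @param p_smooth smoothing parameter in (0, 1).
#' @param neighborhood seconds of adjacent clean data used for re-leveling.
#' @return The corrected recording.
#' @export
spline_correct <- function(rec, mask, p_smooth = 0.99, neighborhood = 1) {
  if (rec$kind != "od") stop("spline_correct expects an od recording")
  stopifnot(p_smooth > 0, p_smooth < 1)
  lam <- (1 - p_smooth) / p_smooth
  n <- dim(rec$data)[1]
  nb <- max(1L, round(neighborhood * rec$fs))
  for (c in seq_len(dim(rec$data)[2])) {
    if (!rec$channel_mask[c]) next
    bad <- !mask[, c]
    if (!any(bad)) next
    segs <- runs_of(bad)
    for (wl in seq_len(dim(rec$data)[3])) {
      x <- rec$data[, c, wl]
      for (s in seq_len(nrow(segs))) {
        i0 <- segs[s, 1]; i1 <- segs[s, 2]
        idx <- i0:i1
        y <- x[idx]
        fit <- if (length(idx) >= 8) {
          stats::predict(stats::smooth.spline(idx, y, lambda = lam), idx)$y
        } else rep(mean(y), length(idx))
        resid <- y - fit
        pre <- if (i0 > 1) x[max(1, i0 - nb):(i0 - 1)] else NULL
        post <- if (i1 < n) x[(i1 + 1):min(n, i1 + nb)] else NULL
        level <- if (is.null(pre) && is.null(post)) mean(y)
                 else mean(c(mean(pre), mean(post)), na.rm = TRUE)
        x[idx] <- resid - mean(resid) + level
      }
      rec$data[, c, wl] <- x
    }
  }
  rec
}

#' Wavelet-based motion correction
#'
#' Per channel and wavelength: periodized Daubechies-5 discrete wavelet
#' decomposition down to `min(floor(log2(n)) - 4, 8)` levels; at each
#' detail level, coefficients outside the Tukey fences
#' `[Q1 - f*IQR, Q3 + f*IQR]` are set to zero; the series is reconstructed
#' at its original length.  Series with detail coefficients entirely inside
#' the fences are returned unchanged up to reconstruction round-off.
#'
#' @param rec a `nirs_recording` of kind "od".
#' @param iqr_factor the fence factor `f` (default 1.5).
#' @return The corrected recording.
#' @export
wavelet_correct <- function(rec, iqr_factor = 1.5) {
  if (rec$kind != "od") stop("wavelet_correct expects an od recording")
  n <- dim(rec$data)[1]
  depth <- min(floor(log2(n)) - 4, 8)
  if (depth < 1 || n < 2 * length(DB5_DEC_LO)) {
    warning("record too short for wavelet decomposition; skipped")
    return(rec)
  }
  for (c in seq_len(dim(rec$data)[2])) {
    if (!rec$channel_mask[c]) next
    for (wl in seq_len(dim(rec$data)[3])) {
      dec <- dwt_periodic(rec$data[, c, wl], depth)
      for (lev in seq_len(dec$depth)) {
        d <- dec$details[[lev]]
        q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
        iqr <- q[2] - q[1]
        out <- d < q[1] - iqr_factor * iqr | d > q[2] + iqr_factor * iqr
        d[out] <- 0
        dec$details[[lev]] <- d
      }
      rec$data[, c, wl] <- idwt_periodic(dec)
    }
  }
  rec
}

#' Reject trials contaminated by residual motion
#'
#' A trial is rejected iff any kept-channel sample inside
#' `[onset + window[1], onset + window[2]]` seconds is masked as artifact.
#'
#' @param rec a `nirs_recording` of kind "od".
#' @param mask logical motion mask, `TRUE` = clean.
#' @param window numeric pair (s) relative to onset; default `c(-2, 10)`.
#' @return The stimulus schedule with `accepted` updated.
#' @export
reject_trials <- function(rec, mask, window = c(-2, 10)) {
  stim <- rec$stim
  if (!nrow(stim)) return(stim)
  n <- dim(rec$data)[1]
  kept <- which(rec$channel_mask)
  for (e in seq_len(nrow(stim))) {
    i0 <- max(1L, floor((stim$onset[e] + window[1]) * rec$fs) + 1L)
    i1 <- min(n, ceiling((stim$onset[e] + window[2]) * rec$fs) + 1L)
    stim$accepted[e] <- all(mask[i0:i1, kept])
  }
  stim
}

# one ARMA pass (direct form) on every column of X, C-vectorized
arma_pass <- function(b, a, X) {
  k <- length(b) - 1
  Z <- rbind(matrix(0, k, ncol(X)), X)
  U <- stats::filter(Z, b, method = "convolution", sides = 1)
  U <- U[-seq_len(k), , drop = FALSE]
  as.matrix(stats::filter(U, -a[-1], method = "recursive"))
}

# forward-backward Butterworth on matrix columns with reflected end padding
zerophase_filter <- function(X, bf, npad_mult = 10) {
  X <- as.matrix(X)
  n <- nrow(X)
  b <- bf$b; a <- bf$a
  npad <- min(npad_mult * (length(a) - 1), n - 1)
  pre <- 2 * X[rep(1, npad), , drop = FALSE] - X[(npad + 1):2, , drop = FALSE]
  post <- 2 * X[rep(n, npad), , drop = FALSE] -
    X[(n - 1):(n - npad), , drop = FALSE]
  Y <- rbind(pre, X, post)
  Y <- arma_pass(b, a, Y)
  Y <- arma_pass(b, a, Y[nrow(Y):1, , drop = FALSE])
  Y <- Y[nrow(Y):1, , drop = FALSE]
  matrix(as.numeric(Y[(npad + 1):(npad + n), , drop = FALSE]), n)
}

butter_band <- function(band, fs, order) {
  if (band[1] == 0) signal::butter(order, band[2] / (fs / 2), type = "low")
  else signal::butter(order, band / (fs / 2), type = "pass")
}

#' Zero-phase band-pass filter
#'
#' Order-3 Butterworth applied forward and backward (with reflected end
#' padding), giving a zero-phase response with monotone passband and at
#' least 20 dB attenuation one octave outside the band edges.  The
#' published analysis bands are `c(0.01, 3)` Hz for task data and
#' `c(0.009, 0.08)` Hz for resting-state functional connectivity.
#'
#' @param rec a `nirs_recording` (od) or `hemo_series`.
#' @param band numeric pair `(low, high)` Hz with `0 <= low < high < fs/2`.
#' @param order filter order (default 3).
#' @return Object of the same class, filtered.
#' @export
bandpass_filter <- function(rec, band, order = 3) {
  fs <- rec$fs
  if (band[2] >= fs / 2)
    stop("parameter error: high cutoff must be below the Nyquist frequency")
  stopifnot(band[1] >= 0, band[1] < band[2])
  bf <- butter_band(band, fs, order)
  if (inherits(rec, "hemo_series")) {
    for (f in c("hbo", "hbr")) rec[[f]] <- zerophase_filter(rec[[f]], bf)
    rec$hbt <- rec$hbo + rec$hbr
  } else {
    for (w in seq_len(dim(rec$data)[3])) {
      kept <- which(rec$channel_mask)
      rec$data[, kept, w] <- zerophase_filter(rec$data[, kept, w, drop = FALSE],
                                              bf)
    }
  }
  rec
}

#' Standard preprocessing chains
#'
#' `preprocess_task()` runs the task/walk chain: prune, OD conversion,
#' motion detection, spline correction, wavelet correction, trial
#' rejection, 0.01-3 Hz band-pass, Beer-Lambert conversion.
#' `preprocess_rest()` runs the resting-state chain: prune, OD, motion
#' detection and correction, 0.009-0.08 Hz band-pass, Beer-Lambert.  The
#' motion mask carried on the result marks the samples excluded from
#' connectivity analysis.
#'
#' @param rec an intensity `nirs_recording`.
#' @param prune,motion parameter lists.
#' @param band analysis band (Hz).
#' @param spline,wavelet logical switches for the two correctors.
#' @param od_reference baseline-intensity reference for
#'   [intensity_to_od()].
#' @return A [hemo_series()].
#' @export
preprocess_task <- function(rec, prune = prune_params(),
                            motion = motion_params(), band = c(0.01, 3),
                            spline = TRUE, wavelet = TRUE,
                            od_reference = "mean") {
  rec <- prune_channels(rec, prune)
  rec <- intensity_to_od(rec, reference = od_reference)
  mask <- detect_motion_by_channel(rec, motion)
  if (spline) rec <- spline_correct(rec, mask)
  if (wavelet) rec <- wavelet_correct(rec)
  rec$stim <- reject_trials(rec, mask)
  rec$motion_mask <- mask
  rec <- bandpass_filter(rec, band)
  mbll(rec)
}

#' @rdname preprocess_task
#' @export
preprocess_rest <- function(rec, prune = prune_params(),
                            motion = motion_params(),
                            band = c(0.009, 0.08), spline = TRUE,
                            wavelet = TRUE, od_reference = "mean") {
  rec <- prune_channels(rec, prune)
  rec <- intensity_to_od(rec, reference = od_reference)
  mask <- detect_motion_by_channel(rec, motion)
  if (spline) rec <- spline_correct(rec, mask)
  if (wavelet) rec <- wavelet_correct(rec)
  rec$motion_mask <- mask
  rec <- bandpass_filter(rec, band)
  mbll(rec)
}
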