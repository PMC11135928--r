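#' Mean short-separation channel signal
#'
#' Pointwise average of the short-channel series,
#' `s(t) = (1/n) sum_i y_i(t)` (n = 2 on the default probe).
#'
#' @param short_series numeric matrix `[n x n_short]` (>= 1 column).
#' @return numeric vector.
#' @export
ssc_mean <- function(short_series) {
  short_series <- as.matrix(short_series)
  if (ncol(short_series) < 1)
    stop("no short channels available; disable SSC regression instead")
  rowMeans(short_series)
}

#' Tikhonov-regularized short-channel regression
#'
#' Per target channel `g`, the regression weight is
#' `beta_g = (s's + lambda^2)^-1 s'Y_g`, with the regularization parameter
#' chosen under the default policy as `lambda = 0.001 * max(diag(s's))`
#' (with a single mean short series, `s's` is scalar).  With `lambda = 0`
#' this is ordinary least squares.  Fitted over clean (motion-free) samples
#' only when a mask is given.
#'
#' @param Y numeric matrix `[n x n_channels]` of target series.
#' @param s numeric vector: the mean short-channel series.
#' @param lambda "policy" for the default rule, or a nonnegative numeric
#'   override.
#' @param clean optional logical `[n x n_channels]`; `beta_g` uses samples
#'   clean in channel `g` (the short series is assumed clean where used).
#' @return list of class `ssc_regression`: `beta` (per channel), `lambda`,
#'   `s`.
#' @export
tikhonov_regress <- function(Y, s, lambda = "policy", clean = NULL) {
  Y <- as.matrix(Y)
  stopifnot(length(s) == nrow(Y))
  if (stats::var(s) == 0) stop("zero-variance short-channel signal")
  nch <- ncol(Y)
  beta <- numeric(nch)
  lam_used <- numeric(nch)
  for (g in seq_len(nch)) {
    ok <- if (is.null(clean)) rep(TRUE, nrow(Y)) else clean[, g]
    ss <- sum(s[ok]^2)
    if (ss == 0) stop("zero-variance short-channel signal on clean samples")
    lam <- if (identical(lambda, "policy")) 0.001 * ss else as.numeric(lambda)
    beta[g] <- sum(s[ok] * Y[ok, g]) / (ss + lam^2)
    lam_used[g] <- lam
  }
  structure(list(beta = beta, lambda = lam_used, s = s),
            class = "ssc_regression")
}

#' Remove the superficial component
#'
#' `Y'(t) = Y(t) - s(t) beta_g`, applied on the full time grid.
#'
#' @param Y numeric matrix `[n x n_channels]`.
#' @param reg an `ssc_regression` fitted on the same grid.
#' @return numeric matrix of residual series.
#' @export
residualize <- function(Y, reg) {
  Y <- as.matrix(Y)
  if (length(reg$s) != nrow(Y))
    stop("grid mismatch between regression and data")
  Y - outer(reg$s, reg$beta)
}

#' Fisher z-transform of a correlation
#'
#' `z = 0.5 * log((1 + r) / (1 - r))`, strictly increasing and odd.
#' Correlations are clamped to +/- `r_max` first, so perfect correlations
#' map to the finite sentinel `fisher_z(r_max)`.
#'
#' @param r correlation(s) in `[-1, 1]`.
#' @param r_max clamping bound.
#' @return numeric z-score(s).
#' @export
fisher_z <- function(r, r_max = 0.999999) {
  r <- pmin(pmax(r, -r_max), r_max)
  0.5 * log((1 + r) / (1 - r))
}

#' Channel-wise correlation matrix over clean samples
#'
#' Pairwise Pearson correlations over samples jointly clean in both
#' channels; pruned channels and pairs with fewer than `min_samples` joint
#' clean samples yield missing entries (with a warning for the latter).
#'
#' @param Y numeric matrix `[n x n_channels]` of (residualized) series.
#' @param clean logical `[n x n_channels]`, `TRUE` = clean (default all).
#' @param channel_mask logical per channel (default all kept).
#' @param min_samples minimum joint clean samples per pair.
#' @return list of class `connectivity_result`: `r_matrix`, `z_matrix`,
#'   `n_clean_samples` (matrix of joint counts).
#' @export
correlation_matrix <- function(Y, clean = NULL, channel_mask = NULL,
                               min_samples = 30) {
  Y <- as.matrix(Y)
  nch <- ncol(Y)
  if (is.null(channel_mask)) channel_mask <- rep(TRUE, nch)
  R <- matrix(NA_real_, nch, nch)
  N <- matrix(0L, nch, nch)
  kept <- which(channel_mask)
  if (is.null(clean) || all(clean)) {
    R[kept, kept] <- stats::cor(Y[, kept, drop = FALSE])
    N[kept, kept] <- nrow(Y)
  } else {
    for (a in kept) for (b in kept[kept >= a]) {
      ok <- clean[, a] & clean[, b]
      N[a, b] <- N[b, a] <- sum(ok)
      if (sum(ok) < min_samples) {
        warning(sprintf("pair (%d, %d): only %d joint clean samples; entry left missing",
                        a, b, sum(ok)))
        next
      }
      R[a, b] <- R[b, a] <- stats::cor(Y[ok, a], Y[ok, b])
    }
  }
  diag(R)[channel_mask] <- 1
  structure(list(r_matrix = R, z_matrix = fisher_z(R),
                 n_clean_samples = N),
            class = "connectivity_result")
}

#' Inter- and intrahemispheric connectivity indices
#'
#' `inter` is the mean Fisher z over the homolog (contralateral mirror)
#' pairs; `intra_left` / `intra_right` are the means over all
#' within-hemisphere long-channel pairs (45 per side on the default
#' probe).  Missing entries are excluded, with the contributing pair count
#' reported; an index with no available pairs is `NA`.
#'
#' @param result a `connectivity_result` whose matrices are indexed by
#'   probe channel table rows.
#' @param probe the `nirs_probe`.
#' @return list: `inter`, `intra_left`, `intra_right`, and `n_pairs` (used
#'   pair counts).
#' @export
hemispheric_indices <- function(result, probe) {
  ch <- probe$channels
  Z <- result$z_matrix
  row_of <- function(id) match(id, ch$channel_id)
  hp <- homolog_pairs(probe)
  inter_z <- mapply(function(l, r) Z[row_of(l), row_of(r)],
                    hp$left_id, hp$right_id)
  intra <- function(hemi) {
    idx <- which(!ch$is_short & ch$hemisphere == hemi)
    if (length(idx) < 2) return(numeric(0))
    pr <- utils::combn(idx, 2)
    Z[cbind(pr[1, ], pr[2, ])]
  }
  il <- intra("left"); ir <- intra("right")
  mean_or_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  list(inter = mean_or_na(inter_z),
       intra_left = mean_or_na(il), intra_right = mean_or_na(ir),
       n_pairs = c(inter = sum(!is.na(inter_z)),
                   intra_left = sum(!is.na(il)),
                   intra_right = sum(!is.na(ir))))
}

#' Full functional-connectivity analysis of one session
#'
#' For each chromophore: averages the short channels, removes the
#' superficial component by Tikhonov-regularized regression (fitted on
#' motion-free samples), computes the channel-wise correlation matrix over
#' clean samples, Fisher-transforms it and derives the hemispheric
#' indices.
#'
#' @param hemo a `hemo_series` already filtered to the connectivity band.
#' @param chromophores chromophores to analyze.
#' @param lambda Tikhonov policy or numeric override.
#' @param ssc logical: apply short-channel regression (default TRUE; turned
#'   off automatically with a warning when no short channel survives).
#' @return named list per chromophore: `connectivity_result` with an extra
#'   `indices` element.
#' @export
fc_analysis <- function(hemo, chromophores = c("hbo", "hbr", "hbt"),
                        lambda = "policy", ssc = TRUE) {
  ch <- hemo$probe$channels
  shorts <- which(ch$is_short & hemo$channel_mask)
  long <- !ch$is_short
  out <- list()
  for (chr in chromophores) {
    M <- chromophore(hemo, chr)
    Yp <- M
    if (ssc) {
      if (!length(shorts)) {
        warning("no short channels survive pruning; SSC regression skipped")
      } else {
        s <- ssc_mean(M[, shorts, drop = FALSE])
        reg <- tikhonov_regress(M, s, lambda, clean = hemo$motion_mask)
        Yp <- residualize(M, reg)
      }
    }
    res <- correlation_matrix(Yp, clean = hemo$motion_mask,
                              channel_mask = hemo$channel_mask & long)
    res$indices <- hemispheric_indices(res, hemo$probe)
    out[[chr]] <- res
  }
  out
}
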