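#' Channel activation test (paired t on task vs baseline means)
#'
#' Per channel, a paired-sample t-test compares each subject's mean
#' hemoglobin change over the task window against the pre-task baseline
#' window; p-values are FDR-adjusted within the channel family.
#'
#' @param task_means,baseline_means numeric matrices
#'   `[subjects x channels]` of window means; rows are paired.
#' @param family_id label of the multiple-testing family.
#' @return data.frame: `channel`, `statistic`, `p`, `p_adjusted`, `n`,
#'   `effect_direction`, `family_id`.  Channels with fewer than 3 complete
#'   pairs get missing results.
#' @export
activation_test <- function(task_means, baseline_means,
                            family_id = "activation") {
  task_means <- as.matrix(task_means)
  baseline_means <- as.matrix(baseline_means)
  stopifnot(all(dim(task_means) == dim(baseline_means)))
  nch <- ncol(task_means)
  out <- data.frame(channel = seq_len(nch), statistic = NA_real_,
                    p = NA_real_, p_adjusted = NA_real_, n = 0L,
                    effect_direction = NA_real_, family_id = family_id)
  for (c in seq_len(nch)) {
    d <- task_means[, c] - baseline_means[, c]
    d <- d[!is.na(d)]
    out$n[c] <- length(d)
    if (length(d) < 3) next
    if (stats::sd(d) <= 10 * .Machine$double.eps * max(abs(d), 1)) {
      # degenerate separation: identical shift for all subjects
      out$statistic[c] <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      out$p[c] <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- stats::t.test(d)
      out$statistic[c] <- unname(tt$statistic)
      out$p[c] <- tt$p.value
    }
    out$effect_direction[c] <- sign(mean(d))
  }
  ok <- !is.na(out$p)
  out$p_adjusted[ok] <- fdr_adjust(out$p[ok], family_id = family_id)
  out
}

#' Shapiro-Wilk normality gate
#'
#' Routes the analysis to the nonparametric branch: a sample is declared
#' non-normal when the Shapiro-Wilk p-value falls below `alpha`.  Samples
#' outside the test's 3..5000 size range, or degenerate (constant)
#' samples, force the nonparametric branch.
#'
#' @param x numeric sample.
#' @param alpha gate level.
#' @return list: `verdict` ("normal"/"non_normal"), `p` (NA when the gate
#'   was skipped), `degenerate`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) >= 3 && stats::sd(x) == 0)
    return(list(verdict = "non_normal", p = NA_real_, degenerate = TRUE))
  if (length(x) < 3 || length(x) > 5000)
    return(list(verdict = "non_normal", p = NA_real_, degenerate = FALSE))
  p <- stats::shapiro.test(x)$p.value
  list(verdict = if (p < alpha) "non_normal" else "normal", p = p,
       degenerate = FALSE)
}

#' Two-group comparison (Wilcoxon-Mann-Whitney)
#'
#' Two-sided Mann-Whitney U: exact enumeration when the combined sample
#' size is at most 20 and there are no ties, tie-corrected normal
#' approximation otherwise.
#'
#' @param a,b numeric samples for the two groups.
#' @param family_id multiple-testing family label.
#' @return one-row data.frame: `statistic` (U for the first sample), `p`,
#'   `n1`, `n2`, `effect_direction` (sign of median(a) - median(b)),
#'   `family_id`.
#' @export
group_compare <- function(a, b, family_id = "group") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    return(data.frame(statistic = NA_real_, p = NA_real_,
                      n1 = length(a), n2 = length(b),
                      effect_direction = NA_real_, family_id = family_id))
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  data.frame(statistic = unname(wt$statistic), p = wt$p.value,
             n1 = length(a), n2 = length(b),
             effect_direction = sign(stats::median(a) - stats::median(b)),
             family_id = family_id)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1) within an explicitly
#' declared family.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param q nominal FDR level (recorded, not used in the adjustment).
#' @param family_id family label.
#' @return numeric adjusted p-values (empty input gives empty output).
#' @export
fdr_adjust <- function(p, q = 0.05, family_id = "family") {
  if (!length(p)) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Spearman correlations between HRF features and clinical variables
#'
#' For each (feature, clinical variable) combination: Spearman's rho over
#' PD subjects with non-missing values (pairwise deletion), two-sided
#' p-value, BH adjustment within the declared family.  Intended for
#' channels already gated on a significant group difference.
#'
#' @param features data.frame with a `subject` column and one column per
#'   feature.
#' @param clinical clinical table with `subject` and the variables in
#'   `clinical_vars`.
#' @param feature_cols,clinical_vars column names to correlate.
#' @param family_id family label (adjustment spans all combinations).
#' @param min_n records with fewer pairs are flagged `low_n`.
#' @return data.frame of correlation records.
#' @export
spearman_clinical <- function(features, clinical,
                              feature_cols = setdiff(names(features), "subject"),
                              clinical_vars = c("moca", "updrs3",
                                                "disease_duration", "fogq",
                                                "ledd", "hy"),
                              family_id = "clinical", min_n = 5) {
  m <- merge(features, clinical, by = "subject")
  out <- list()
  for (f in feature_cols) for (v in clinical_vars) {
    ok <- !is.na(m[[f]]) & !is.na(m[[v]])
    n <- sum(ok)
    if (n >= 3) {
      ct <- suppressWarnings(stats::cor.test(m[[f]][ok], m[[v]][ok],
                                             method = "spearman"))
      rho <- unname(ct$estimate); p <- ct$p.value
    } else { rho <- NA_real_; p <- NA_real_ }
    out[[length(out) + 1]] <- data.frame(feature = f, clinical = v,
                                         rho = rho, p = p, n = n,
                                         low_n = n < min_n,
                                         stratum = "all",
                                         family_id = family_id)
  }
  out <- do.call(rbind, out)
  out$p_adjusted <- NA_real_
  ok <- !is.na(out$p)
  out$p_adjusted[ok] <- fdr_adjust(out$p[ok], family_id = family_id)
  out
}

#' Rank-based (Spearman-flavored) partial correlation
#'
#' Rank-transforms all variables, residualizes the feature and clinical
#' ranks on the control ranks by least squares, and correlates the
#' residuals; the p-value uses the t approximation with `n - 2 - k`
#' degrees of freedom (k = number of controls).
#'
#' @param x,y numeric vectors.
#' @param controls numeric matrix or data.frame of control variables.
#' @return list: `rho`, `p`, `df`, `n`, `flagged` (degenerate control
#'   variance).
#' @export
partial_spearman <- function(x, y, controls) {
  controls <- as.matrix(controls)
  ok <- !is.na(x) & !is.na(y) & rowSums(is.na(controls)) == 0
  x <- x[ok]; y <- y[ok]; controls <- controls[ok, , drop = FALSE]
  n <- length(x); k <- ncol(controls)
  if (n < k + 3)
    return(list(rho = NA_real_, p = NA_real_, df = NA_integer_, n = n,
                flagged = TRUE))
  flagged <- any(apply(controls, 2, stats::var) == 0)
  rx <- rank(x); ry <- rank(y)
  rc <- apply(controls, 2, rank)
  Z <- cbind(1, rc)
  ex <- stats::lm.fit(Z, rx)$residuals
  ey <- stats::lm.fit(Z, ry)$residuals
  # residuals numerically zero mean the variable is a function of the controls
  if (stats::sd(ex) < 1e-10 * stats::sd(rx) ||
      stats::sd(ey) < 1e-10 * stats::sd(ry))
    return(list(rho = 0, p = 1, df = n - 2L - k, n = n, flagged = TRUE))
  rho <- stats::cor(ex, ey)
  df <- n - 2L - k
  tstat <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(rho = rho, p = p, df = df, n = n, flagged = flagged)
}

#' Stratified partial correlations between features and clinical variables
#'
#' Within each side-of-onset stratum, partial Spearman correlations
#' controlling for age and years of education.
#'
#' @inheritParams spearman_clinical
#' @param control_vars control variable columns in `clinical`.
#' @param strata_var stratification column (e.g. `side_of_onset`).
#' @return data.frame of correlation records with `stratum`, `df` and
#'   `partial_controls` columns.
#' @export
partial_spearman_clinical <- function(features, clinical,
                                      feature_cols = setdiff(names(features), "subject"),
                                      clinical_vars = c("moca", "updrs3",
                                                        "disease_duration",
                                                        "fogq", "ledd", "hy"),
                                      control_vars = c("age", "education"),
                                      strata_var = "side_of_onset",
                                      family_id = "clinical_partial") {
  m <- merge(features, clinical, by = "subject")
  strata <- unique(m[[strata_var]])
  strata <- strata[!is.na(strata) & strata != "none"]
  out <- list()
  for (s in strata) {
    ms <- m[m[[strata_var]] == s, ]
    for (f in feature_cols) for (v in clinical_vars) {
      r <- partial_spearman(ms[[f]], ms[[v]],
                            ms[, control_vars, drop = FALSE])
      out[[length(out) + 1]] <- data.frame(
        feature = f, clinical = v, rho = r$rho, p = r$p, n = r$n,
        df = if (is.na(r$df)) NA_integer_ else r$df,
        low_n = r$n < 5, flagged = r$flagged, stratum = s,
        partial_controls = paste(control_vars, collapse = "+"),
        family_id = family_id)
    }
  }
  out <- do.call(rbind, out)
  out$p_adjusted <- NA_real_
  ok <- !is.na(out$p)
  out$p_adjusted[ok] <- fdr_adjust(out$p[ok], family_id = family_id)
  out
}

#' Pearson chi-square test for a contingency table
#'
#' Uncorrected Pearson chi-square (1 df for a 2x2 table).  Tables with a
#' zero margin are undefined and flagged.
#'
#' @param tab matrix of nonnegative integer counts.
#' @return data.frame: `statistic`, `df`, `p`, `flagged`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(data.frame(statistic = NA_real_, df = NA_integer_, p = NA_real_,
                      flagged = TRUE))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  data.frame(statistic = unname(ct$statistic), df = unname(ct$parameter),
             p = ct$p.value, flagged = FALSE)
}
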