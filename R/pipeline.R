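#' Pipeline configuration
#'
#' Bundles every stage's parameters with the simulation config and master
#' seed.  Defaults equal the published processing parameters: pruning
#' (intensity 1e-7..1e7, SNR 2, separation range 0.45 m), motion detection
#' (1 s window, 0.5 OD amplitude, 15x sd, 1 s mask), task band 0.01-3 Hz,
#' connectivity band 0.009-0.08 Hz, GLM window (-2, 25) s with 1-s Gaussian
#' basis and drift order 3, Tikhonov lambda policy
#' `0.001 * max(diag(s's))`, alpha 0.05 and FDR q 0.05.
#'
#' @param sim a [sim_config()].
#' @param prune,motion stage parameter lists.
#' @param task_band,fc_band analysis bands (Hz).
#' @param glm a [glm_spec()].
#' @param lambda Tikhonov policy or numeric override.
#' @param alpha,q significance and FDR levels.
#' @param od_reference baseline reference for OD conversion.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), prune = prune_params(),
                            motion = motion_params(),
                            task_band = c(0.01, 3),
                            fc_band = c(0.009, 0.08),
                            glm = glm_spec(), lambda = "policy",
                            alpha = 0.05, q = 0.05,
                            od_reference = "mean") {
  structure(list(sim = sim, prune = prune, motion = motion,
                 task_band = task_band, fc_band = fc_band, glm = glm,
                 lambda = lambda, alpha = alpha, q = q,
                 od_reference = od_reference),
            class = "pipeline_config")
}

#' Generate the demonstration cohort on disk
#'
#' Simulates the default two-group cohort (disease-like group: +2 s evoked
#' latency, dominant-hand amplitude x0.6, non-dominant x1.4,
#' interhemispheric coupling 0.3 vs 0.6), writes one SNIRF file per
#' subject and paradigm plus a JSON ground-truth sidecar, a cohort
#' manifest TSV and the synthetic clinical table.
#'
#' @param dir output directory (created).
#' @param cfg a [pipeline_config()].
#' @param paradigms subset of `c("task", "walk", "rest")`.
#' @return the manifest data.frame (invisibly the directory layout is
#'   `dir/sub-XX_<paradigm>.snirf`).
#' @export
make_demo <- function(dir, cfg = pipeline_config(),
                      paradigms = c("task", "walk", "rest")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(cfg$sim, paradigms, output = "intensity")
  rows <- list()
  for (e in cohort$subjects) {
    for (p in intersect(paradigms, names(e))) {
      path <- file.path(dir, sprintf("sub-%02d_%s.snirf", e$subject, p))
      write_snirf(e[[p]]$recording, path)
      truth <- e[[p]]$truth
      truth$latent <- NULL                    # keep sidecars small
      jsonlite::write_json(truth, sub("\\.snirf$", "_truth.json", path),
                           auto_unbox = TRUE, digits = NA)
      rows[[length(rows) + 1]] <- data.frame(
        subject = e$subject, group = e$group, paradigm = p, path = path,
        seed = cfg$sim$seed)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  manifest
}

window_mean <- function(curve, grid, window) {
  i <- grid >= window[1] & grid <= window[2]
  mean(curve[i])
}

process_task_subject <- function(rec, cfg, conditions = NULL) {
  hemo <- preprocess_task(rec, cfg$prune, cfg$motion, cfg$task_band,
                          od_reference = cfg$od_reference)
  est <- if (identical(conditions, "walk")) single_trial_walk(hemo, cfg$glm)
         else fit_glm(hemo, cfg$glm)
  est
}

#' Run the full analysis pipeline over a cohort
#'
#' Executes, per subject: the task/walk preprocessing chain, GLM HRF
#' estimation and feature extraction; the resting-state chain and
#' connectivity analysis.  Then the group layer: channel activation maps
#' (paired t, task vs baseline window means, FDR per chromophore x
#' condition), Mann-Whitney group comparisons of every HRF feature (FDR
#' per chromophore x condition x feature) and of the Fisher-z connectivity
#' indices, and Spearman clinical correlations (with partial, stratified
#' variants) restricted to channels passing the group-difference gate.
#' Subjects whose processing fails are quarantined with a log entry and
#' the cohort run continues.
#'
#' @param cohort result of [simulate_cohort()], or a manifest data.frame
#'   (columns `subject`, `group`, `paradigm`, `path`) pointing at SNIRF
#'   files, with the clinical table passed separately.
#' @param cfg a [pipeline_config()].
#' @param clinical clinical table (defaults to the cohort's synthetic
#'   one).
#' @param output_dir optional; when given, tidy TSV results and a JSON
#'   provenance record are written there.
#' @return list of class `pipeline_result`: `features`, `activation`,
#'   `group_tests`, `fc_indices`, `fc_tests`, `clinical_cor`,
#'   `clinical_partial`, `quarantined`.
#' @export
run_pipeline <- function(cohort, cfg = pipeline_config(), clinical = NULL,
                         output_dir = NULL) {
  if (is.data.frame(cohort)) cohort <- load_manifest_cohort(cohort, cfg)
  if (is.null(clinical)) clinical <- cohort$clinical
  subjects <- cohort$subjects
  quarantined <- data.frame(subject = integer(), paradigm = character(),
                            error = character())
  feat_rows <- list(); act_rows <- list(); fc_rows <- list()

  for (e in subjects) {
    for (p in intersect(c("task", "walk", "rest"), names(e))) {
      if (!is.null(e[[p]]$error)) {
        quarantined <- rbind(quarantined,
                             data.frame(subject = e$subject, paradigm = p,
                                        error = e[[p]]$error))
        e[[p]] <- NULL
      }
    }
    for (p in intersect(c("task", "walk"), names(e))) {
      res <- tryCatch({
        est <- process_task_subject(e[[p]]$recording, cfg,
                                    conditions = if (p == "walk") "walk")
        ft <- extract_features(est, subject = e$subject)
        ft$group <- e$group
        feat_rows[[length(feat_rows) + 1]] <- ft
        for (chr in names(est$curves)) for (cc in names(est$curves[[chr]])) {
          M <- est$curves[[chr]][[cc]]
          for (c in est$channels) {
            act_rows[[length(act_rows) + 1]] <- data.frame(
              subject = e$subject, group = e$group, condition = cc,
              channel = est$probe$channels$channel_id[c], chromophore = chr,
              base_mean = window_mean(M[, c], est$grid, c(-2, 0)),
              task_mean = window_mean(M[, c], est$grid, c(0, 10)))
          }
        }
        NULL
      }, error = function(err) conditionMessage(err))
      if (!is.null(res))
        quarantined <- rbind(quarantined,
                             data.frame(subject = e$subject, paradigm = p,
                                        error = res))
    }
    if ("rest" %in% names(e)) {
      res <- tryCatch({
        rec <- e$rest$recording
        hemo <- if (inherits(rec, "hemo_series"))
          bandpass_filter(rec, cfg$fc_band)
        else preprocess_rest(rec, cfg$prune, cfg$motion, cfg$fc_band,
                             od_reference = cfg$od_reference)
        fc <- fc_analysis(hemo, lambda = cfg$lambda)
        for (chr in names(fc)) {
          ix <- fc[[chr]]$indices
          fc_rows[[length(fc_rows) + 1]] <- data.frame(
            subject = e$subject, group = e$group, chromophore = chr,
            inter = ix$inter, intra_left = ix$intra_left,
            intra_right = ix$intra_right)
        }
        NULL
      }, error = function(err) conditionMessage(err))
      if (!is.null(res))
        quarantined <- rbind(quarantined,
                             data.frame(subject = e$subject,
                                        paradigm = "rest", error = res))
    }
  }

  features <- if (length(feat_rows)) do.call(rbind, feat_rows) else NULL
  act <- if (length(act_rows)) do.call(rbind, act_rows) else NULL
  fc_indices <- if (length(fc_rows)) do.call(rbind, fc_rows) else NULL

  activation <- group_tests <- fc_tests <- clinical_cor <- clinical_partial <- NULL
  if (!is.null(act)) {
    activation <- do.call(rbind, lapply(
      split(act, list(act$chromophore, act$condition), drop = TRUE),
      function(d) {
        tm <- stats::reshape(d[, c("subject", "channel", "task_mean")],
                             idvar = "subject", timevar = "channel",
                             direction = "wide")
        bm <- stats::reshape(d[, c("subject", "channel", "base_mean")],
                             idvar = "subject", timevar = "channel",
                             direction = "wide")
        chans <- as.integer(sub(".*\\.", "", names(tm)[-1]))
        r <- activation_test(tm[, -1], bm[, -1],
                             family_id = paste0("activation:",
                                                d$chromophore[1], ":",
                                                d$condition[1]))
        r$channel <- chans
        r$chromophore <- d$chromophore[1]
        r$condition <- d$condition[1]
        r
      }))
    rownames(activation) <- NULL
  }
  if (!is.null(features)) {
    fnames <- c("peak", "time_to_peak", "auc", "mean", "slope")
    rows <- list()
    for (key in split(features,
                      list(features$condition, features$chromophore,
                           features$channel), drop = TRUE)) {
      for (f in fnames) {
        fam <- paste0("group:", key$condition[1], ":", key$chromophore[1],
                      ":", f)
        gc <- group_compare(key[[f]][key$group != "control"],
                            key[[f]][key$group == "control"],
                            family_id = fam)
        gc$condition <- key$condition[1]
        gc$chromophore <- key$chromophore[1]
        gc$channel <- key$channel[1]
        gc$feature <- f
        rows[[length(rows) + 1]] <- gc
      }
    }
    group_tests <- do.call(rbind, rows)
    group_tests$p_adjusted <- NA_real_
    for (fam in unique(group_tests$family_id)) {
      i <- which(group_tests$family_id == fam & !is.na(group_tests$p))
      group_tests$p_adjusted[i] <- fdr_adjust(group_tests$p[i],
                                              family_id = fam)
    }
  }
  if (!is.null(fc_indices)) {
    rows <- list()
    for (chr in unique(fc_indices$chromophore)) {
      d <- fc_indices[fc_indices$chromophore == chr, ]
      for (ix in c("inter", "intra_left", "intra_right")) {
        gc <- group_compare(d[[ix]][d$group != "control"],
                            d[[ix]][d$group == "control"],
                            family_id = paste0("fc:", chr))
        gc$chromophore <- chr
        gc$index <- ix
        rows[[length(rows) + 1]] <- gc
      }
    }
    fc_tests <- do.call(rbind, rows)
    fc_tests$p_adjusted <- NA_real_
    for (fam in unique(fc_tests$family_id)) {
      i <- which(fc_tests$family_id == fam & !is.na(fc_tests$p))
      fc_tests$p_adjusted[i] <- fdr_adjust(fc_tests$p[i], family_id = fam)
    }
  }
  if (!is.null(features) && !is.null(group_tests) && !is.null(clinical)) {
    gate <- group_tests[!is.na(group_tests$p_adjusted) &
                          group_tests$p_adjusted < cfg$alpha, ]
    if (nrow(gate)) {
      recs <- list(); precs <- list()
      for (i in seq_len(nrow(gate))) {
        sel <- features$condition == gate$condition[i] &
          features$chromophore == gate$chromophore[i] &
          features$channel == gate$channel[i] &
          features$group != "control"
        fdat <- features[sel, c("subject", gate$feature[i])]
        names(fdat)[2] <- paste(gate$condition[i], gate$chromophore[i],
                                gate$channel[i], gate$feature[i], sep = "_")
        recs[[i]] <- spearman_clinical(fdat, clinical,
                                       family_id = "clinical")
        precs[[i]] <- partial_spearman_clinical(fdat, clinical,
                                                family_id = "clinical_partial")
      }
      clinical_cor <- do.call(rbind, recs)
      clinical_partial <- do.call(rbind, precs)
      # one declared family across the gated set
      ok <- !is.na(clinical_cor$p)
      clinical_cor$p_adjusted[ok] <- fdr_adjust(clinical_cor$p[ok],
                                                family_id = "clinical")
      ok <- !is.na(clinical_partial$p)
      clinical_partial$p_adjusted[ok] <-
        fdr_adjust(clinical_partial$p[ok], family_id = "clinical_partial")
    }
  }

  out <- structure(list(features = features, activation = activation,
                        group_tests = group_tests, fc_indices = fc_indices,
                        fc_tests = fc_tests, clinical_cor = clinical_cor,
                        clinical_partial = clinical_partial,
                        quarantined = quarantined),
                   class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_results(out, cfg, output_dir)
  out
}

load_manifest_cohort <- function(manifest, cfg) {
  subjects <- list()
  for (s in unique(manifest$subject)) {
    rows <- manifest[manifest$subject == s, ]
    e <- list(subject = s, group = rows$group[1])
    for (i in seq_len(nrow(rows))) {
      e[[rows$paradigm[i]]] <- tryCatch(
        list(recording = read_snirf(rows$path[i], probe = cfg$sim$probe)),
        error = function(err) list(error = conditionMessage(err)))
    }
    subjects[[length(subjects) + 1]] <- e
  }
  clin_path <- file.path(dirname(manifest$path[1]), "clinical.tsv")
  clinical <- if (file.exists(clin_path)) read_clinical_table(clin_path)
  list(subjects = subjects, clinical = clinical)
}

write_pipeline_results <- function(out, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, name) if (!is.null(d))
    utils::write.table(format(d, digits = 15, trim = TRUE),
                       file.path(dir, name), sep = "\t", row.names = FALSE,
                       quote = FALSE)
  wt(out$features, "features.tsv")
  wt(out$activation, "activation.tsv")
  wt(out$group_tests, "group_tests.tsv")
  wt(out$fc_indices, "fc_indices.tsv")
  wt(out$fc_tests, "fc_tests.tsv")
  wt(out$clinical_cor, "clinical_correlations.tsv")
  wt(out$clinical_partial, "clinical_partial_correlations.tsv")
  prov <- list(package_version = as.character(utils::packageVersion("nirsmotor")),
               seed = cfg$sim$seed,
               config = utils::capture.output(utils::str(cfg, give.attr = FALSE)))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
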