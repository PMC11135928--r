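#' Multi-channel fNIRS recording
#'
#' Container for a single session.  `kind = "intensity"` and `kind = "od"`
#' recordings store a 3-d array `[n_samples x n_channels x n_wavelengths]`;
#' hemoglobin-kind series live in [hemo_series()].  Time is seconds from
#' recording start; sample `i` covers the half-open interval
#' `[(i-1)/fs, i/fs)`, and event onsets are expressed in seconds, not sample
#' indices.
#'
#' @param data numeric array `[n x n_channels x 2]`.
#' @param fs sampling frequency (Hz); the supported acquisition default is
#'   25 Hz.
#' @param kind "intensity" or "od".
#' @param probe a `nirs_probe`; channel dimension must follow
#'   `probe$channels` row order.
#' @param stim stimulus schedule: data.frame with columns `condition`
#'   ("left_tap", "right_tap" or "walk"), `onset` (s), `duration` (s),
#'   `accepted` (logical).  May have zero rows.
#' @param channel_mask logical per channel, `TRUE` = kept (default all).
#' @param motion_mask logical `[n x n_channels]`, `TRUE` = clean
#'   (default all).
#' @return An object of class `nirs_recording`.
#' @export
nirs_recording <- function(data, fs, kind = c("intensity", "od"), probe,
                           stim = empty_schedule(), channel_mask = NULL,
                           motion_mask = NULL) {
  kind <- match.arg(kind)
  stopifnot(fs > 0)
  data <- as.array(data)
  if (length(dim(data)) != 3)
    stop("data must be [n_samples x n_channels x n_wavelengths]")
  nch <- nrow(probe$channels)
  if (dim(data)[2] != nch)
    stop("data has ", dim(data)[2], " channels but probe defines ", nch)
  if (dim(data)[3] != length(probe$wavelengths))
    stop("data wavelength dimension does not match probe wavelengths")
  if (is.null(channel_mask)) channel_mask <- rep(TRUE, nch)
  if (is.null(motion_mask))
    motion_mask <- matrix(TRUE, dim(data)[1], nch)
  stopifnot(length(channel_mask) == nch,
            all(dim(motion_mask) == dim(data)[1:2]))
  stim <- validate_schedule(stim)
  if (kind == "intensity" && any(data[, channel_mask, , drop = FALSE] <= 0))
    stop("intensity data must be strictly positive on kept channels")
  structure(list(data = data, fs = fs, kind = kind, probe = probe,
                 stim = stim, channel_mask = channel_mask,
                 motion_mask = motion_mask),
            class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<nirs_recording:%s> %d samples x %d channels x %d wavelengths @ %g Hz (%.1f s), %d events\n",
              x$kind, d[1], d[2], d[3], x$fs, d[1] / x$fs, nrow(x$stim)))
  invisible(x)
}

#' @rdname nirs_recording
#' @export
empty_schedule <- function() {
  data.frame(condition = character(), onset = numeric(),
             duration = numeric(), accepted = logical())
}

validate_schedule <- function(stim) {
  need <- c("condition", "onset", "duration")
  if (!all(need %in% names(stim)))
    stop("stimulus schedule needs columns: ", paste(need, collapse = ", "))
  if (is.null(stim$accepted)) stim$accepted <- rep(TRUE, nrow(stim))
  if (is.unsorted(stim$onset)) stop("event onsets must be nondecreasing")
  stim
}

#' Time base of a recording
#' @param rec a `nirs_recording` or `hemo_series`.
#' @return numeric vector of sample times (s).
#' @export
time_base <- function(rec) {
  n <- if (inherits(rec, "hemo_series")) nrow(rec$hbo) else dim(rec$data)[1]
  (seq_len(n) - 1) / rec$fs
}

#' Hemoglobin concentration-change series
#'
#' Post-Beer-Lambert container: per-channel HbO/HbR/HbT concentration
#' changes in uM*mm.  `hbt` is maintained as the elementwise sum
#' `hbo + hbr`, exactly.
#'
#' @param hbo,hbr numeric matrices `[n x n_channels]` (uM*mm).
#' @param fs sampling frequency (Hz).
#' @param probe,stim,channel_mask,motion_mask carried over from the source
#'   recording.
#' @return An object of class `hemo_series`.
#' @export
hemo_series <- function(hbo, hbr, fs, probe, stim = empty_schedule(),
                        channel_mask = NULL, motion_mask = NULL) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  stopifnot(all(dim(hbo) == dim(hbr)), fs > 0)
  nch <- nrow(probe$channels)
  if (ncol(hbo) != nch) stop("channel count does not match probe")
  if (is.null(channel_mask)) channel_mask <- rep(TRUE, nch)
  if (is.null(motion_mask)) motion_mask <- matrix(TRUE, nrow(hbo), nch)
  structure(list(hbo = hbo, hbr = hbr, hbt = hbo + hbr, fs = fs,
                 probe = probe, stim = validate_schedule(stim),
                 channel_mask = channel_mask, motion_mask = motion_mask,
                 kind = "hemoglobin"),
            class = "hemo_series")
}

#' @export
print.hemo_series <- function(x, ...) {
  cat(sprintf("<hemo_series> %d samples x %d channels @ %g Hz, %d events\n",
              nrow(x$hbo), ncol(x$hbo), x$fs, nrow(x$stim)))
  invisible(x)
}

#' Select a chromophore matrix from a hemo_series
#' @param hemo a `hemo_series`.
#' @param chromophore "hbo", "hbr" or "hbt".
#' @return numeric matrix `[n x n_channels]`.
#' @export
chromophore <- function(hemo, chromophore = c("hbo", "hbr", "hbt")) {
  hemo[[match.arg(chromophore)]]
}

# ---- delimited-text fixture dialect -----------------------------------------
# One header row naming channels as S#D#_WL<nm> (intensity/od) or
# S#D#_HbO / S#D#_HbR (hemoglobin); first column "time_s".  Events in a
# sidecar "<path>_events.tsv".

channel_labels <- function(probe, wl = NULL) {
  ch <- probe$channels
  base <- sprintf("S%dD%d", ch$source, ch$detector)
  if (is.null(wl)) base else paste0(base, "_WL", wl)
}

#' Write a recording to the delimited-text fixture format
#'
#' Tab-separated, one row per sample, first column `time_s`, channels named
#' `S#D#_WL<nm>`.  Events go to `<path prefix>_events.tsv`.
#'
#' @param rec a `nirs_recording`.
#' @param path output file path (the events sidecar derives from it).
#' @export
write_recording_tsv <- function(rec, path) {
  mats <- lapply(seq_along(rec$probe$wavelengths), function(w)
    rec$data[, , w, drop = TRUE])
  labs <- unlist(lapply(rec$probe$wavelengths, function(wl)
    channel_labels(rec$probe, wl)))
  out <- data.frame(time_s = time_base(rec), do.call(cbind, mats),
                    check.names = FALSE)
  names(out) <- c("time_s", labs)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(rec$stim, events_path(path), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

events_path <- function(path) paste0(sub("\\.tsv$", "", path), "_events.tsv")

#' Read a recording from the delimited-text fixture format
#'
#' @param path file written by [write_recording_tsv()].
#' @param probe the probe the columns refer to.
#' @param kind "intensity" or "od".
#' @return A `nirs_recording`.
#' @export
read_recording_tsv <- function(path, probe, kind = "intensity") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  if (names(tab)[1] != "time_s") stop("first column must be time_s")
  t <- tab[[1]]
  fs <- 1 / stats::median(diff(t))
  nch <- nrow(probe$channels)
  data <- array(NA_real_, c(nrow(tab), nch, 2))
  for (w in 1:2) {
    labs <- channel_labels(probe, probe$wavelengths[w])
    miss <- setdiff(labs, names(tab))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
    data[, , w] <- as.matrix(tab[, labs])
  }
  stim <- if (file.exists(events_path(path))) {
    ev <- utils::read.table(events_path(path), sep = "\t", header = TRUE)
    if (!nrow(ev)) empty_schedule() else ev
  } else empty_schedule()
  nirs_recording(data, fs, kind, probe, stim)
}

#' Read / write a per-subject clinical covariate table
#'
#' Tab-separated, one row per subject.  Expected columns: `subject`, `group`
#' ("PD"/"control"), `age`, `sex`, `education`, `moca`, `updrs3`,
#' `disease_duration`, `fogq`, `ledd`, `hy`, `side_of_onset`
#' ("left"/"right"/"none").  Disease-specific fields may be missing (`NA`)
#' for controls; `moca` must lie in `[0, 30]` where present.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_clinical_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("subject", "group") %in% names(tab)))
    stop("clinical table needs at least subject and group columns")
  if ("moca" %in% names(tab) &&
      any(!is.na(tab$moca) & (tab$moca < 0 | tab$moca > 30)))
    stop("MoCA scores must lie in [0, 30]")
  tab
}

#' @rdname read_clinical_table
#' @param clinical data.frame as above.
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
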