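#' Write an intensity recording to a SNIRF (HDF5) file
#'
#' Writes the subset of the SNIRF container the pipeline needs: continuous
#' wave amplitudes (`dataType = 1`), the time vector, the measurement list,
#' probe geometry and per-condition stimulus blocks.  Trial acceptance is
#' encoded in the stimulus `amplitude` column (1 = accepted, 0 = rejected).
#'
#' @param rec a `nirs_recording` with `kind = "intensity"`.
#' @param path output path (overwritten if present).
#' @export
write_snirf <- function(rec, path) {
  if (!inherits(rec, "nirs_recording") || rec$kind != "intensity")
    stop("unsupported kind: write_snirf only writes intensity recordings")
  n <- dim(rec$data)[1]
  if (n == 0) stop("zero-length recording")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write("1.0", path, "formatVersion")
  rhdf5::h5createGroup(path, "nirs")
  rhdf5::h5createGroup(path, "nirs/data1")

  ch <- rec$probe$channels
  nwl <- length(rec$probe$wavelengths)
  # column k of dataTimeSeries = (channel row c, wavelength w), channel-major
  dts <- matrix(0, n, nrow(ch) * nwl)
  k <- 0L
  for (c in seq_len(nrow(ch))) for (w in seq_len(nwl)) {
    k <- k + 1L
    dts[, k] <- rec$data[, c, w]
    g <- sprintf("nirs/data1/measurementList%d", k)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(as.integer(ch$source[c]), path, paste0(g, "/sourceIndex"))
    rhdf5::h5write(as.integer(ch$detector[c]), path, paste0(g, "/detectorIndex"))
    rhdf5::h5write(as.integer(w), path, paste0(g, "/wavelengthIndex"))
    rhdf5::h5write(1L, path, paste0(g, "/dataType"))
  }
  rhdf5::h5write(dts, path, "nirs/data1/dataTimeSeries")
  rhdf5::h5write(time_base(rec), path, "nirs/data1/time")

  rhdf5::h5createGroup(path, "nirs/probe")
  rhdf5::h5write(rec$probe$wavelengths, path, "nirs/probe/wavelengths")
  rhdf5::h5write(rec$probe$sources, path, "nirs/probe/sourcePos3D")
  rhdf5::h5write(rec$probe$detectors, path, "nirs/probe/detectorPos3D")

  conds <- unique(rec$stim$condition)
  for (i in seq_along(conds)) {
    g <- sprintf("nirs/stim%d", i)
    ev <- rec$stim[rec$stim$condition == conds[i], ]
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(conds[i], path, paste0(g, "/name"))
    rhdf5::h5write(cbind(ev$onset, ev$duration, as.numeric(ev$accepted)),
                   path, paste0(g, "/data"))
  }
  invisible(path)
}

#' Read an intensity recording from a SNIRF (HDF5) file
#'
#' Channel order of the returned recording is deterministic: channels are
#' sorted by source index, then detector index, regardless of measurement
#' list order in the file.  If `probe` is supplied, its declared channel
#' table (and homolog pairing) is authoritative and the file's measurements
#' are matched to it; otherwise the probe is reconstructed from the file
#' geometry, hemispheres are assigned by the sign of the channel midpoint's
#' first coordinate, and homologs are inferred by mirror symmetry.
#'
#' @param path SNIRF file path.
#' @param probe optional `nirs_probe` declaring the channel table.
#' @param time_tol tolerated relative jitter of the sampling interval.
#' @return A `nirs_recording` of kind "intensity".
#' @export
read_snirf <- function(path, probe = NULL, time_tol = 1e-6) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  idx <- rhdf5::h5ls(path)
  root <- if (any(idx$group == "/" & idx$name == "nirs")) "nirs" else "nirs1"
  if (!any(idx$name == root))
    stop("format error: no nirs block in ", path)
  if (!any(idx$group == paste0("/", root) & idx$name == "probe"))
    stop("format error: file lacks a probe block")

  rd <- function(p) rhdf5::h5read(path, p)
  tvec <- as.numeric(rd(paste0(root, "/data1/time")))
  if (length(tvec) == 2 && tvec[2] < tvec[1])  # [start, step] form
    stop("format error: two-element time not supported")
  dt <- diff(tvec)
  if (length(dt) && (max(dt) - min(dt)) > time_tol * stats::median(dt))
    stop("format error: non-uniform sampling beyond tolerance")
  fs <- 1 / stats::median(dt)

  dts <- rd(paste0(root, "/data1/dataTimeSeries"))
  ml_names <- idx$name[grepl("^measurementList", idx$name) &
                         idx$group == paste0("/", root, "/data1")]
  ml_k <- sort(as.integer(sub("measurementList", "", ml_names)))
  ml <- do.call(rbind, lapply(ml_k, function(k) {
    g <- sprintf("%s/data1/measurementList%d", root, k)
    data.frame(col = k, source = as.integer(rd(paste0(g, "/sourceIndex"))),
               detector = as.integer(rd(paste0(g, "/detectorIndex"))),
               wl = as.integer(rd(paste0(g, "/wavelengthIndex"))))
  }))

  wavelengths <- as.numeric(rd(paste0(root, "/probe/wavelengths")))
  src <- as.matrix(rd(paste0(root, "/probe/sourcePos3D")))
  det <- as.matrix(rd(paste0(root, "/probe/detectorPos3D")))

  pairs <- unique(ml[, c("source", "detector")])
  pairs <- pairs[order(pairs$source, pairs$detector), , drop = FALSE]
  if (is.null(probe)) {
    sep <- sqrt(rowSums((src[pairs$source, , drop = FALSE] -
                           det[pairs$detector, , drop = FALSE])^2))
    mid <- (src[pairs$source, , drop = FALSE] +
              det[pairs$detector, , drop = FALSE]) / 2
    channels <- data.frame(channel_id = seq_len(nrow(pairs)),
                           source = pairs$source, detector = pairs$detector,
                           separation = sep,
                           hemisphere = ifelse(mid[, 1] < 0, "left", "right"),
                           is_short = sep < SHORT_SEPARATION_CUT,
                           homolog = NA_integer_)
    probe <- nirs_probe(src, det, channels, wavelengths)
    probe <- tryCatch(infer_homologs(probe), error = function(e) probe)
  }
  ch <- probe$channels
  n <- nrow(dts)
  data <- array(NA_real_, c(n, nrow(ch), length(wavelengths)))
  for (c in seq_len(nrow(ch))) for (w in seq_along(wavelengths)) {
    hit <- ml$col[ml$source == ch$source[c] & ml$detector == ch$detector[c] &
                    ml$wl == w]
    if (length(hit) != 1)
      stop("format error: no unique measurement for channel S", ch$source[c],
           "D", ch$detector[c], " wavelength ", w)
    data[, c, w] <- dts[, hit]
  }

  stim_names <- idx$name[grepl("^stim[0-9]+$", idx$name) &
                           idx$group == paste0("/", root)]
  stim <- empty_schedule()
  for (s in stim_names) {
    nm <- as.character(rd(sprintf("%s/%s/name", root, s)))
    d <- rd(sprintf("%s/%s/data", root, s))
    d <- matrix(as.numeric(d), ncol = 3)
    stim <- rbind(stim, data.frame(condition = nm, onset = d[, 1],
                                   duration = d[, 2],
                                   accepted = d[, 3] != 0))
  }
  stim <- stim[order(stim$onset), , drop = FALSE]
  rownames(stim) <- NULL
  nirs_recording(data, fs, "intensity", probe, stim)
}
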