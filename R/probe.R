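#' Probe layout for a bilateral motor-cortex montage
#'
#' A `nirs_probe` bundles optode coordinates with a channel table.  The
#' channel table is the authoritative description of the montage: which
#' source/detector pair forms each channel, its separation, hemisphere,
#' short/long status, and (for long channels) the identity of its
#' mirror-symmetric contralateral homolog.  Homolog pairing is declared, not
#' inferred: real-data users must supply their own table, while the bundled
#' default layout carries one by construction.
#'
#' @param sources numeric matrix `n_sources x 3` of optode positions (mm).
#' @param detectors numeric matrix `n_detectors x 3` of optode positions (mm).
#' @param channels data.frame with columns `channel_id`, `source`, `detector`,
#'   `separation`, `hemisphere` ("left"/"right"), `is_short`, `homolog`
#'   (`NA` for short channels).
#' @param wavelengths numeric pair of wavelengths (nm).
#' @return An object of class `nirs_probe`.
#' @export
nirs_probe <- function(sources, detectors, channels, wavelengths) {
  sources <- as.matrix(sources)
  detectors <- as.matrix(detectors)
  stopifnot(ncol(sources) == 3, ncol(detectors) == 3, length(wavelengths) == 2)
  need <- c("channel_id", "source", "detector", "separation", "hemisphere",
            "is_short", "homolog")
  if (!all(need %in% names(channels)))
    stop("channel table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(channels$channel_id))
    stop("duplicate channel_id in probe definition")
  if (any(channels$is_short & !is.na(channels$homolog)))
    stop("short channels must not declare a homolog")
  # homolog relation must be symmetric where declared
  for (i in which(!is.na(channels$homolog))) {
    j <- match(channels$homolog[i], channels$channel_id)
    if (is.na(j) || !identical(channels$homolog[j], channels$channel_id[i]))
      stop("homolog table is not symmetric at channel ", channels$channel_id[i])
  }
  structure(list(sources = sources, detectors = detectors,
                 channels = channels, wavelengths = as.numeric(wavelengths)),
            class = "nirs_probe")
}

#' @export
print.nirs_probe <- function(x, ...) {
  cat(sprintf("<nirs_probe> %d sources, %d detectors, %d long + %d short channels, wavelengths %s nm\n",
              nrow(x$sources), nrow(x$detectors),
              sum(!x$channels$is_short), sum(x$channels$is_short),
              paste(x$wavelengths, collapse = "/")))
  invisible(x)
}

# Separation below which a channel counts as short (mm).  The montage uses
# 30 mm long and 15 mm short pairs; 20 mm splits the two cleanly and absorbs
# placement jitter.
SHORT_SEPARATION_CUT <- 20

#' Construct a bilateral motor-strip probe
#'
#' Builds the montage used throughout the package: per hemisphere, a 2 x 4
#' checkerboard grid of 4 sources and 4 detectors with 30 mm spacing yields
#' exactly 10 source-detector pairs at 30 mm separation, plus one dedicated
#' short-channel source placed 15 mm from a detector.  The left hemisphere is
#' the mirror image of the right, which defines the homolog table: left
#' channel `i` pairs with right channel `i + n_long`.
#'
#' @param n_long_per_hemisphere number of long channels per hemisphere
#'   (1 to 10; the default 10 gives the full 20-long + 2-short montage with
#'   10 sources and 8 detectors).
#' @param wavelengths numeric pair (nm).
#' @return A `nirs_probe`.
#' @export
make_probe <- function(n_long_per_hemisphere = 10, wavelengths = c(757, 843)) {
  stopifnot(n_long_per_hemisphere >= 1, n_long_per_hemisphere <= 10)
  # right-hemisphere template, x lateral (mm), y anterior, z up (flat layout)
  sp <- 30
  src_r <- rbind(c(0, 0), c(2, 0), c(1, 1), c(3, 1)) * sp
  det_r <- rbind(c(1, 0), c(3, 0), c(0, 1), c(2, 1)) * sp
  # the 10 unit-spacing source-detector edges of the checkerboard
  edges <- rbind(c(1, 1), c(2, 1), c(2, 2),      # row y = 0
                 c(3, 3), c(3, 4), c(4, 4),      # row y = 30
                 c(1, 3), c(2, 4),               # verticals from sources
                 c(3, 1), c(4, 2))               # verticals from detectors
  edges <- edges[seq_len(n_long_per_hemisphere), , drop = FALSE]
  short_src_r <- c(0, 1.5) * sp                   # 15 mm above detector (0,30)
  short_det <- 3                                  # detector at (0,30)

  lateral <- 20                                   # offset from midline (mm)
  shift <- function(m, sgn) cbind(sgn * (m[, 1] + lateral), m[, 2], 0)
  nL <- n_long_per_hemisphere
  sources <- rbind(shift(src_r, -1), shift(matrix(short_src_r, 1), -1),
                   shift(src_r, +1), shift(matrix(short_src_r, 1), +1))
  detectors <- rbind(shift(det_r, -1), shift(det_r, +1))
  rownames(sources) <- NULL

  mk_side <- function(hemi) {
    s_off <- if (hemi == "left") 0L else 5L       # 5 sources per hemisphere
    d_off <- if (hemi == "left") 0L else 4L
    id0 <- if (hemi == "left") 0L else nL
    data.frame(channel_id = id0 + seq_len(nL),
               source = s_off + edges[, 1],
               detector = d_off + edges[, 2],
               hemisphere = hemi,
               is_short = FALSE,
               homolog = (if (hemi == "left") id0 + seq_len(nL) + nL
                          else id0 + seq_len(nL) - nL))
  }
  shorts <- data.frame(channel_id = 2L * nL + 1:2,
                       source = c(5L, 10L),
                       detector = c(short_det, short_det + 4L),
                       hemisphere = c("left", "right"),
                       is_short = TRUE,
                       homolog = NA_integer_)
  channels <- rbind(mk_side("left"), mk_side("right"), shorts)
  channels$separation <- sqrt(rowSums(
    (sources[channels$source, , drop = FALSE] -
       detectors[channels$detector, , drop = FALSE])^2))
  channels <- channels[, c("channel_id", "source", "detector", "separation",
                           "hemisphere", "is_short", "homolog")]
  rownames(channels) <- NULL
  nirs_probe(sources, detectors, channels, wavelengths)
}

#' Default probe: 10 sources, 8 detectors, 20 long + 2 short channels
#'
#' The acquisition montage the pipeline assumes by default: 20 long channels
#' (10 per hemisphere) at 30 mm separation over bilateral motor cortex, two
#' short-separation channels (15 mm, one per hemisphere) sensing superficial
#' hemodynamics, dual-wavelength LEDs at 757 and 843 nm.
#'
#' @return A `nirs_probe`.
#' @export
default_probe <- function() make_probe(10, c(757, 843))

#' Contralateral homolog pairs of a probe
#'
#' @param probe a `nirs_probe`.
#' @return data.frame with columns `left_id`, `right_id`, one row per homolog
#'   pair (10 for the default probe).
#' @export
homolog_pairs <- function(probe) {
  ch <- probe$channels
  long <- ch[!ch$is_short, ]
  if (any(is.na(long$homolog)))
    stop("probe-definition error: long channel(s) without homolog partner: ",
         paste(long$channel_id[is.na(long$homolog)], collapse = ", "))
  left <- long[long$hemisphere == "left", ]
  pairs <- data.frame(left_id = left$channel_id, right_id = left$homolog)
  # partner of a left channel must be a right channel
  rh <- long$hemisphere[match(pairs$right_id, long$channel_id)]
  if (any(rh != "right"))
    stop("probe-definition error: homolog of a left channel is not on the right")
  if (nrow(pairs) * 2L != nrow(long))
    stop("probe-definition error: homolog table does not cover all long channels")
  pairs
}

#' Infer homolog pairs from mirror symmetry
#'
#' Convenience for probes lacking a declared homolog table: pairs each left
#' long channel with the right long channel whose midpoint is closest to its
#' x-mirror image.  The declared table, when present, is authoritative.
#'
#' @param probe a `nirs_probe`.
#' @param tol maximum midpoint mismatch (mm) tolerated for a pair.
#' @return The probe with its `homolog` column filled in.
#' @export
infer_homologs <- function(probe, tol = 10) {
  ch <- probe$channels
  mid <- (probe$sources[ch$source, , drop = FALSE] +
            probe$detectors[ch$detector, , drop = FALSE]) / 2
  long <- which(!ch$is_short)
  left <- long[ch$hemisphere[long] == "left"]
  right <- long[ch$hemisphere[long] == "right"]
  ch$homolog <- NA_integer_
  for (i in left) {
    tgt <- mid[i, ] * c(-1, 1, 1)
    d <- sqrt(colSums((t(mid[right, , drop = FALSE]) - tgt)^2))
    j <- right[which.min(d)]
    if (min(d) > tol)
      stop("no mirror partner within ", tol, " mm for channel ", ch$channel_id[i])
    ch$homolog[i] <- ch$channel_id[j]
    ch$homolog[j] <- ch$channel_id[i]
  }
  probe$channels <- ch
  probe
}
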