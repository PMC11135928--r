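#' Hemoglobin extinction coefficients
#'
#' Specific extinction coefficients of oxy- and deoxyhemoglobin at the
#' probe's wavelengths, expressed as optical density per uM*mm of
#' concentration-pathlength so that `dOD = E %*% c(dHbO, dHbR)` with
#' concentrations in uM*mm.  Default values at 757 and 843 nm are
#' interpolated from the standard compiled hemoglobin absorption spectrum
#' used across the fNIRS field (the same table Homer and MNE ship);
#' override with measured coefficients if available.
#'
#' @param wavelengths numeric pair (nm); only the bundled 757/843 nm pair
#'   has built-in values.
#' @return data.frame with columns `wavelength`, `ext_hbo`, `ext_hbr`
#'   (OD per uM*mm).
#' @export
extinction_table <- function(wavelengths = c(757, 843)) {
  known <- data.frame(wavelength = c(757, 843),
                      ext_hbo = c(1.30810e-2, 2.38959e-2),
                      ext_hbr = c(3.59379e-2, 1.59386e-2))
  i <- match(wavelengths, known$wavelength)
  if (any(is.na(i)))
    stop("no bundled extinction coefficients for wavelengths ",
         paste(wavelengths[is.na(i)], collapse = ", "),
         " nm; supply a custom table")
  known[i, ]
}

extinction_matrix <- function(ext) {
  E <- as.matrix(ext[, c("ext_hbo", "ext_hbr")])
  if (nrow(E) != 2)
    stop("two chromophores need two wavelengths")
  if (kappa(E) >= 100)
    stop("configuration error: extinction matrix is ill-conditioned (kappa >= 100)")
  E
}

#' Modified Beer-Lambert law: optical density to hemoglobin
#'
#' Per channel and sample, solves the 2x2 linear system
#' `E %*% c(dHbO, dHbR) = dOD` where `E` holds the extinction coefficients
#' at the two wavelengths.  The partial pathlength factor defaults to 1 for
#' each wavelength, i.e. no pathlength scaling, so concentrations come out
#' in uM*mm.  HbT is the exact elementwise sum HbO + HbR.
#'
#' @param rec a `nirs_recording` of kind "od".
#' @param ext extinction table from [extinction_table()].
#' @param ppf partial pathlength factor per wavelength (default `c(1, 1)`).
#' @return A [hemo_series()].
#' @export
mbll <- function(rec, ext = extinction_table(rec$probe$wavelengths),
                 ppf = c(1, 1)) {
  if (!inherits(rec, "nirs_recording") || rec$kind != "od")
    stop("mbll expects an od-kind recording (run intensity_to_od first)")
  E <- extinction_matrix(ext) * ppf
  Einv <- solve(E)
  n <- dim(rec$data)[1]; nch <- dim(rec$data)[2]
  hbo <- matrix(NA_real_, n, nch)
  hbr <- matrix(NA_real_, n, nch)
  for (c in seq_len(nch)) {
    od <- rec$data[, c, ]                      # n x 2
    conc <- od %*% t(Einv)                     # n x 2: (hbo, hbr)
    hbo[, c] <- conc[, 1]
    hbr[, c] <- conc[, 2]
  }
  hemo_series(hbo, hbr, rec$fs, rec$probe, rec$stim,
              rec$channel_mask, rec$motion_mask)
}

#' Forward optical model: hemoglobin to two-wavelength intensity
#'
#' Exact inverse of [mbll()] composed with [intensity_to_od()]:
#' `I_w(t) = I0_w * 10^(-dOD_w(t))` with
#' `dOD_w = ext_hbo[w] * dHbO + ext_hbr[w] * dHbR` (ppf = 1).  Used by the
#' simulator to turn chromophore ground truth into raw intensities.
#'
#' @param hbo,hbr numeric matrices `[n x n_channels]` (uM*mm).
#' @param probe a `nirs_probe`.
#' @param baseline_intensity positive scalar or per-channel vector (a.u.).
#' @param ext extinction table.
#' @return array `[n x n_channels x 2]` of intensities.
#' @export
chromo_to_intensity <- function(hbo, hbr, probe, baseline_intensity = 1,
                                ext = extinction_table(probe$wavelengths)) {
  if (any(baseline_intensity <= 0))
    stop("domain error: baseline intensity must be positive")
  E <- extinction_matrix(ext)
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  n <- nrow(hbo); nch <- ncol(hbo)
  I0 <- rep_len(baseline_intensity, nch)
  out <- array(NA_real_, c(n, nch, 2))
  for (w in 1:2) {
    dod <- hbo * E[w, 1] + hbr * E[w, 2]
    out[, , w] <- sweep(10^(-dod), 2, I0, `*`)
  }
  out
}
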