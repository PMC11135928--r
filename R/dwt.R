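# Periodized orthogonal discrete wavelet transform (Daubechies-5).
#
# The decomposition/reconstruction filter bank below is the standard db5
# orthogonal wavelet (10 taps).  With periodic boundary handling the
# analysis operator is orthogonal, so synthesis is its transpose and
# reconstruction is exact to machine precision.

DB5_DEC_LO <- c(3.3357252854737712e-03, -1.2580751999081999e-02,
                -6.2414902127982744e-03, 7.7571493840045719e-02,
                -3.2244869584638375e-02, -2.4229488706638203e-01,
                1.3842814590132074e-01, 7.2430852843777294e-01,
                6.0382926979718965e-01, 1.6010239797419293e-01)
DB5_DEC_HI <- rev(DB5_DEC_LO) * (-1)^(seq_along(DB5_DEC_LO) - 1)

# one analysis step: x (even length) -> list(ca, cd), each length n/2
dwt_step <- function(x) {
  n <- length(x)
  L <- length(DB5_DEC_LO)
  idx <- outer(seq(1, n, by = 2), 0:(L - 1), `+`)  # (n/2) x L sliding starts
  idx <- (idx - 1) %% n + 1
  xm <- matrix(x[idx], nrow = n %/% 2)
  list(ca = drop(xm %*% DB5_DEC_LO), cd = drop(xm %*% DB5_DEC_HI))
}

# one synthesis step (transpose of the analysis operator)
idwt_step <- function(ca, cd) {
  n <- 2L * length(ca)
  L <- length(DB5_DEC_LO)
  x <- numeric(n)
  starts <- seq(1, n, by = 2)
  # positions are distinct for fixed k because decomposition stops while
  # n >= 2L, so plain indexed accumulation is safe
  for (k in seq_len(L)) {
    pos <- (starts + k - 2) %% n + 1
    x[pos] <- x[pos] + ca * DB5_DEC_LO[k] + cd * DB5_DEC_HI[k]
  }
  x
}

# multi-level periodized DWT; pads odd lengths by repeating the last sample
# and records padding so the inverse restores the original length
dwt_periodic <- function(x, depth) {
  details <- vector("list", depth)
  pads <- integer(depth)
  a <- x
  lev <- 0L
  while (lev < depth && length(a) >= 2L * length(DB5_DEC_LO)) {
    lev <- lev + 1L
    if (length(a) %% 2L == 1L) {
      a <- c(a, a[length(a)])
      pads[lev] <- 1L
    }
    st <- dwt_step(a)
    details[[lev]] <- st$cd
    a <- st$ca
  }
  list(approx = a, details = details[seq_len(lev)], pads = pads[seq_len(lev)],
       depth = lev)
}

idwt_periodic <- function(decomp) {
  a <- decomp$approx
  for (lev in rev(seq_len(decomp$depth))) {
    a <- idwt_step(a, decomp$details[[lev]])
    if (decomp$pads[lev]) a <- a[-length(a)]
  }
  a
}
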