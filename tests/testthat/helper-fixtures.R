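# shared fixtures: small probes and quick simulation configs

tiny_cfg <- function(seed = 1, ...) {
  sim_config(n_per_group = 2, seed = seed, ...)
}

# clean od recording of white noise on an arbitrary probe
noise_od_recording <- function(n = 2000, probe = default_probe(), sd = 0.01,
                               fs = 25, seed = 1) {
  set.seed(seed)
  nch <- nrow(probe$channels)
  rec <- nirs_recording(array(1, c(n, nch, 2)), fs, "intensity", probe)
  rec <- intensity_to_od(rec)
  rec$data <- array(rnorm(n * nch * 2, sd = sd), c(n, nch, 2))
  rec
}

# mann-whitney exact two-sided p by full enumeration (oracle)
mw_exact_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  pool <- c(a, b)
  u_of <- function(idx) {
    x <- pool[idx]; y <- pool[-idx]
    sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
  }
  obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(n, n1), 2, u_of)
  mu <- n1 * (n - n1) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}
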