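# shared fixtures built in code: small acquisitions keep the suite fast
# while preserving the structure of the full-size experiments

small_acq <- function(n_points = 256, spectral_width_hz = 614,
                      carrier_ppm = 4.7) {
  default_acq(n_points = n_points, spectral_width_hz = spectral_width_hz,
              carrier_ppm = carrier_ppm)
}

# one-component series with known truth, handy across files
one_comp_series <- function(shift_ppm = 4.5, t1_s = 0.1, t2star_s = 0.03,
                            amplitude = 1, noise_sigma = 0, seed = 42,
                            acq = small_acq(), tau_s = default_tau_s()) {
  make_fid_series(list(component(amplitude, shift_ppm, t2star_s, t1_s)),
                  tau_s, acq, noise_sigma, seed)
}

# amplitude-weighted centroid of a vector profile
wcentroid <- function(x, w) sum(x * w) / sum(w)

# seeded Gaussian noise without touching the suite's RNG stream further
with_seed_rnorm <- function(seed, n, sd) {
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}
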