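#' Signal component for the synthetic generator
#'
#' One resonance in the multi-component inversion-recovery signal model:
#' amplitude, chemical shift, apparent transverse decay time T2* (which sets
#' the linewidth of the Fourier-transformed peak), longitudinal relaxation
#' time T1, and the inversion efficiency `f` of the initial pi pulse.  The
#' recovery of row amplitude with delay tau follows `1 - 2 f exp(-tau/T1)`.
#'
#' For water in the motional-narrowing regime the transverse decay cannot
#' outlast the longitudinal recovery, so `t2star_s <= t1_s` is enforced.
#'
#' @param amplitude signal amplitude in arbitrary units, >= 0.
#' @param shift_ppm chemical shift of the resonance in ppm.
#' @param t2star_s apparent transverse decay time of the transient, seconds.
#' @param t1_s longitudinal relaxation time, seconds.
#' @param inv_eff inversion efficiency `f` in (0, 1]; 1 is an ideal pi pulse.
#' @return an object of class `component`.
#' @export
component <- function(amplitude, shift_ppm, t2star_s, t1_s, inv_eff = 1) {
  if (!is.numeric(amplitude) || amplitude < 0) stop_domain("amplitude must be >= 0")
  if (!is.numeric(t1_s) || t1_s <= 0) stop_domain("t1_s must be > 0")
  if (!is.numeric(t2star_s) || t2star_s <= 0) stop_domain("t2star_s must be > 0")
  if (t2star_s > t1_s)
    stop_domain("t2star_s must not exceed t1_s (T2* <= T1)")
  if (!is.numeric(inv_eff) || inv_eff <= 0 || inv_eff > 1)
    stop_domain("inv_eff must lie in (0, 1]")
  structure(list(amplitude = as.numeric(amplitude),
                 shift_ppm = as.numeric(shift_ppm),
                 t2star_s = as.numeric(t2star_s),
                 t1_s = as.numeric(t1_s),
                 inv_eff = as.numeric(inv_eff)), class = "component")
}

#' Default acquisition parameters
#'
#' Mirrors a routine deuterium inversion-recovery setup on a 400 MHz (proton)
#' instrument: 4096 complex points at 614 Hz spectral width, deuterium
#' carrier placed near the water resonance, with a companion proton TMS
#' frequency for referencing.
#'
#' @param n_points complex points per transient.
#' @param spectral_width_hz direct-dimension width in Hz.
#' @param proton_tms_hz absolute TMS proton frequency in Hz.
#' @param carrier_ppm carrier position on the referenced ppm axis.
#' @return an [acq_meta()].
#' @export
default_acq <- function(n_points = 4096, spectral_width_hz = 614,
                        proton_tms_hz = 400e6, carrier_ppm = 4.7) {
  f0 <- proton_tms_hz * gamma_ratio_2h_1h()
  acq_meta(carrier_hz = f0 * (1 + carrier_ppm * 1e-6),
           dwell_s = 1 / spectral_width_hz, n_points = n_points,
           nucleus_label = "2H", proton_tms_hz = proton_tms_hz)
}

#' Default recovery-delay list
#'
#' 16 delays log-spaced between 1 ms and 3 s, covering bulk-water T1
#' (~0.45 s) down to the shortest confined-water values.
#'
#' @param n number of delays.
#' @param min_s,max_s range in seconds.
#' @return numeric vector of delays, strictly increasing.
#' @export
default_tau_s <- function(n = 16, min_s = 1e-3, max_s = 3) {
  10^seq(log10(min_s), log10(max_s), length.out = n)
}

# absolute frequency offset (Hz) of a resonance at `ppm` from the carrier
ppm_to_offset_hz <- function(ppm, acq) {
  f0 <- zero_ppm_hz(acq, fallback = TRUE)
  f0 * (1 + ppm * 1e-6) - acq$carrier_hz
}

#' Simulate a multi-component inversion-recovery FID series
#'
#' Generates `data[i, k] = sum_j A_j (1 - 2 f_j exp(-tau_i / T1_j)) *
#' exp(2 pi i nu_j t_k - t_k / T2*_j)` plus circular complex Gaussian noise,
#' where `nu_j` is the offset of component `j` from the carrier implied by
#' its chemical shift and the referencing metadata in `acq`.  The signal is
#' linear in the component amplitudes, and identical seeds give bit-identical
#' output; the caller's RNG state is left untouched.
#'
#' @param components list of [component()] objects (nonempty).
#' @param tau_s strictly increasing recovery delays, seconds.
#' @param acq an [acq_meta()]; see [default_acq()].
#' @param noise_sigma standard deviation of the per-point complex Gaussian
#'   noise (applied independently to real and imaginary parts), >= 0.
#' @param seed integer seed for the noise; required (use any value for
#'   noiseless data, it is ignored when `noise_sigma = 0`).
#' @return a [fid_series()].
#' @export
make_fid_series <- function(components, tau_s, acq, noise_sigma, seed) {
  if (inherits(components, "component")) components <- list(components)
  if (!length(components)) stop_input("components must be nonempty")
  if (!all(vapply(components, inherits, logical(1), "component")))
    stop_input("components must be component() objects")
  if (!is.numeric(noise_sigma) || noise_sigma < 0)
    stop_domain("noise_sigma must be >= 0")
  tau_s <- as.numeric(tau_s)
  if (any(diff(tau_s) <= 0)) stop_domain("tau_s must be strictly increasing")
  t_k <- (seq_len(acq$n_points) - 1L) * acq$dwell_s
  data <- matrix(0 + 0i, nrow = length(tau_s), ncol = acq$n_points)
  for (cmp in components) {
    nu <- ppm_to_offset_hz(cmp$shift_ppm, acq)
    rec <- cmp$amplitude * (1 - 2 * cmp$inv_eff * exp(-tau_s / cmp$t1_s))
    fid <- exp((2i * pi * nu - 1 / cmp$t2star_s) * t_k)
    data <- data + outer(rec, fid)
  }
  if (noise_sigma > 0) {
    n <- length(data)
    noise <- with_local_seed(seed, {
      complex(real = stats::rnorm(n, sd = noise_sigma),
              imaginary = stats::rnorm(n, sd = noise_sigma))
    })
    data <- data + matrix(noise, nrow = nrow(data))
  }
  fid_series(data, tau_s, acq)
}

#' Trend parameters for a reverse-micelle water-loading series
#'
#' Phenomenological description of how the water resonance moves through
#' (chemical shift, T1) space as the water loading w0 grows: both the shift
#' and T1 rise steeply at low w0 and then saturate towards their bulk values.
#' The package models this with exponential saturation,
#' `x(w0) = x_confined + (x_bulk - x_confined) (1 - exp(-w0 / crossover_w0))`,
#' the simplest monotone family with a sharp rise followed by a gentle
#' approach to bulk.
#'
#' Defaults describe an AOT-like series: bulk D2O T1 of 0.45 s against a
#' strongly confined value of ~2 ms, a shift rising from 3.5 to 4.7 ppm, and
#' a crossover near w0 = 3.5 where the measured trends change slope.
#'
#' @param t1_bulk_s,t1_confined_s limiting T1 values, seconds
#'   (`t1_confined_s < t1_bulk_s`).
#' @param shift_bulk_ppm,shift_confined_ppm limiting chemical shifts.
#' @param crossover_w0 characteristic water loading of the saturation, > 0.
#' @param noise_sigma per-point noise amplitude passed to the FID generator.
#' @return an object of class `rm_trend_params`.
#' @export
rm_trend_params <- function(t1_bulk_s = 0.45, t1_confined_s = 0.002,
                            shift_bulk_ppm = 4.7, shift_confined_ppm = 3.5,
                            crossover_w0 = 3.5, noise_sigma = 0.01) {
  if (t1_confined_s >= t1_bulk_s) stop_domain("need t1_confined_s < t1_bulk_s")
  if (crossover_w0 <= 0) stop_domain("crossover_w0 must be > 0")
  if (noise_sigma < 0) stop_domain("noise_sigma must be >= 0")
  structure(list(t1_bulk_s = t1_bulk_s, t1_confined_s = t1_confined_s,
                 shift_bulk_ppm = shift_bulk_ppm,
                 shift_confined_ppm = shift_confined_ppm,
                 crossover_w0 = crossover_w0, noise_sigma = noise_sigma),
            class = "rm_trend_params")
}

#' Generating (shift, T1) values of a trend at given water loadings
#'
#' @param trend an [rm_trend_params()].
#' @param w0 water loading values, > 0.
#' @return data frame with columns `w0`, `shift_ppm`, `t1_s`.
#' @export
rm_trend_truth <- function(trend, w0) {
  if (!inherits(trend, "rm_trend_params")) stop_input("trend must be rm_trend_params")
  if (any(w0 <= 0)) stop_domain("w0 must be positive")
  s <- 1 - exp(-w0 / trend$crossover_w0)
  data.frame(
    w0 = w0,
    shift_ppm = trend$shift_confined_ppm +
      (trend$shift_bulk_ppm - trend$shift_confined_ppm) * s,
    t1_s = trend$t1_confined_s + (trend$t1_bulk_s - trend$t1_confined_s) * s
  )
}

#' Simulate a reverse-micelle water-loading series
#'
#' For each water loading, generates a one-component inversion-recovery FID
#' series whose (chemical shift, T1) follow the saturating trend of
#' [rm_trend_params()], together with a truth record carrying the generating
#' values.  T2* is tied to T1 (`min(0.3 T1, 0.1 s)`) so that small, strongly
#' confined pools also show the broader lines seen in practice.
#'
#' @param trend an [rm_trend_params()].
#' @param w0_list positive water loadings.
#' @param acq an [acq_meta()].
#' @param seed integer seed; each w0 uses a sub-seed derived from it.
#' @param tau_s recovery delays (defaults to [default_tau_s()]).
#' @return a list with one element per w0, each a list with elements
#'   `series` (a [fid_series()]) and `truth` (one-row data frame).
#' @export
make_rm_series <- function(trend, w0_list, acq = default_acq(), seed,
                           tau_s = default_tau_s()) {
  if (any(w0_list <= 0)) stop_domain("w0_list must be positive")
  truth <- rm_trend_truth(trend, w0_list)
  out <- vector("list", length(w0_list))
  for (i in seq_along(w0_list)) {
    tr <- truth[i, , drop = FALSE]
    cmp <- component(amplitude = 1, shift_ppm = tr$shift_ppm,
                     t2star_s = min(0.3 * tr$t1_s, 0.1), t1_s = tr$t1_s)
    out[[i]] <- list(
      series = make_fid_series(list(cmp), tau_s, acq, trend$noise_sigma,
                               seed = seed + i - 1L),
      truth = tr
    )
  }
  out
}

#' Simulate a T1-T2 relaxometry measurement
#'
#' Real-valued data matrix `M[i, k] = sum_j A_j (1 - 2 f_j exp(-tau1_i/T1_j))
#' exp(-tau2_k / T2_j)` plus Gaussian noise: an inversion-recovery kernel
#' along the first dimension and a pure decay along the second (stroboscopic
#' detection, no oscillating dimension).  The component field `t2star_s` is
#' used as the transverse relaxation time T2 here.
#'
#' @param components list of [component()] objects.
#' @param tau1_s,tau2_s strictly ascending delay lists for the two dimensions.
#' @param noise_sigma Gaussian noise standard deviation, >= 0.
#' @param seed integer seed for the noise.
#' @return numeric matrix `[length(tau1_s) x length(tau2_s)]`.
#' @export
make_t1t2_data <- function(components, tau1_s, tau2_s, noise_sigma, seed) {
  if (inherits(components, "component")) components <- list(components)
  if (!length(components)) stop_input("components must be nonempty")
  if (!is.numeric(noise_sigma) || noise_sigma < 0)
    stop_domain("noise_sigma must be >= 0")
  if (any(diff(tau1_s) <= 0) || any(diff(tau2_s) <= 0))
    stop_domain("delay lists must be strictly ascending")
  M <- matrix(0, nrow = length(tau1_s), ncol = length(tau2_s))
  for (cmp in components) {
    rec <- cmp$amplitude * (1 - 2 * cmp$inv_eff * exp(-tau1_s / cmp$t1_s))
    dec <- exp(-tau2_s / cmp$t2star_s)
    M <- M + outer(rec, dec)
  }
  if (noise_sigma > 0) {
    M <- M + with_local_seed(seed, matrix(stats::rnorm(length(M), sd = noise_sigma),
                                          nrow = nrow(M)))
  }
  M
}
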