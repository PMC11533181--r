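#' Acquisition metadata for a deuterium FID series
#'
#' Bundles the acquisition parameters needed to interpret a free induction
#' decay: carrier frequency, dwell time, number of complex points, and
#' (optionally) the absolute frequency of the TMS proton resonance from a
#' companion 1H spectrum, used for chemical-shift referencing.
#'
#' The spectral width is the reciprocal of the dwell time and is stored
#' redundantly for convenience.
#'
#' @param carrier_hz transmitter (carrier) frequency in Hz; must be positive.
#' @param dwell_s dwell time between complex points, in seconds.
#' @param n_points number of complex points per transient (>= 2).
#' @param nucleus_label text label for the observed nucleus, e.g. `"2H"`.
#' @param proton_tms_hz optional absolute frequency (Hz) of the TMS peak in a
#'   companion proton spectrum; enables gyromagnetic-ratio referencing.
#' @param temperature_k optional sample temperature in kelvin.
#' @return an object of class `acq_meta`.
#' @seealso [fid_series()], [reference_ppm()]
#' @export
acq_meta <- function(carrier_hz, dwell_s, n_points, nucleus_label = "2H",
                     proton_tms_hz = NULL, temperature_k = NULL) {
  if (!is.numeric(carrier_hz) || length(carrier_hz) != 1 || carrier_hz <= 0)
    stop_domain("carrier_hz must be a single positive number")
  if (!is.numeric(dwell_s) || length(dwell_s) != 1 || dwell_s <= 0)
    stop_domain("dwell_s must be a single positive number")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2)
    stop_domain("n_points must be an integer >= 2")
  if (!is.null(proton_tms_hz) &&
      (!is.numeric(proton_tms_hz) || proton_tms_hz <= 0))
    stop_domain("proton_tms_hz must be positive when supplied")
  structure(list(
    nucleus_label = as.character(nucleus_label),
    carrier_hz = as.numeric(carrier_hz),
    dwell_s = as.numeric(dwell_s),
    n_points = n_points,
    spectral_width_hz = 1 / as.numeric(dwell_s),
    proton_tms_hz = if (is.null(proton_tms_hz)) NULL else as.numeric(proton_tms_hz),
    temperature_k = if (is.null(temperature_k)) NULL else as.numeric(temperature_k)
  ), class = "acq_meta")
}

#' Inversion-recovery FID series
#'
#' A complex matrix of transients, one row per recovery delay, together with
#' the (strictly increasing, nonnegative) delay list and the acquisition
#' metadata.
#'
#' @param data complex matrix, `length(tau_s)` rows by `acq$n_points` columns.
#' @param tau_s recovery delays in seconds, strictly increasing, all >= 0.
#' @param acq an [acq_meta()] object.
#' @return an object of class `fid_series`.
#' @export
fid_series <- function(data, tau_s, acq) {
  if (!inherits(acq, "acq_meta")) stop_input("acq must be an acq_meta object")
  if (!is.matrix(data)) stop_format("data must be a matrix")
  if (!is.complex(data)) data <- matrix(as.complex(data), nrow = nrow(data))
  tau_s <- as.numeric(tau_s)
  if (length(tau_s) < 1 || any(tau_s < 0) || any(diff(tau_s) <= 0))
    stop_domain("tau_s must be strictly increasing and nonnegative")
  if (nrow(data) != length(tau_s))
    stop_format("row count (%d) does not equal number of recovery delays (%d)",
                nrow(data), length(tau_s))
  if (ncol(data) != acq$n_points)
    stop_format("column count (%d) does not equal acq$n_points (%d)",
                ncol(data), acq$n_points)
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    stop_format("FID data contain non-finite values")
  structure(list(data = data, tau_s = tau_s, acq = acq), class = "fid_series")
}

#' @export
print.fid_series <- function(x, ...) {
  cat(sprintf("<fid_series> %d recovery delays x %d complex points (%s, %.4g Hz width)\n",
              length(x$tau_s), x$acq$n_points, x$acq$nucleus_label,
              x$acq$spectral_width_hz))
  cat(sprintf("  tau: %.4g .. %.4g s\n", min(x$tau_s), max(x$tau_s)))
  invisible(x)
}

#' Phased real spectra on a referenced ppm axis
#'
#' Post-Fourier-transform representation of an inversion-recovery series: one
#' real (absorption-mode) spectrum per recovery delay, on a descending ppm
#' axis, with an estimate of the per-point noise amplitude.
#'
#' @param data real matrix, one row per recovery delay.
#' @param ppm_axis strictly monotonic ppm values (conventionally descending).
#' @param tau_s recovery delays, as in [fid_series()].
#' @param noise_sigma estimated per-point noise standard deviation (>= 0).
#' @param acq optional [acq_meta()] carried along for provenance.
#' @return an object of class `shift_series`.
#' @export
shift_series <- function(data, ppm_axis, tau_s, noise_sigma = 0, acq = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) stop_format("data must be a real matrix")
  ppm_axis <- as.numeric(ppm_axis)
  d <- diff(ppm_axis)
  if (length(ppm_axis) != ncol(data) || !(all(d > 0) || all(d < 0)))
    stop_domain("ppm_axis must be strictly monotonic and match ncol(data)")
  tau_s <- as.numeric(tau_s)
  if (nrow(data) != length(tau_s)) stop_format("row count must equal length(tau_s)")
  if (!is.numeric(noise_sigma) || noise_sigma < 0)
    stop_domain("noise_sigma must be >= 0")
  structure(list(data = data, ppm_axis = ppm_axis, tau_s = tau_s,
                 noise_sigma = as.numeric(noise_sigma), acq = acq),
            class = "shift_series")
}

#' @export
print.shift_series <- function(x, ...) {
  cat(sprintf("<shift_series> %d delays x %d frequency bins, ppm %.3f .. %.3f, sigma %.3g\n",
              nrow(x$data), ncol(x$data), x$ppm_axis[1],
              x$ppm_axis[length(x$ppm_axis)], x$noise_sigma))
  invisible(x)
}

#' Logarithmically spaced relaxation-time grid
#'
#' The discretization of a relaxation-time axis used by the inverse Laplace
#' transform: `n` values equally spaced in log10 between `min_s` and `max_s`.
#'
#' @param min_s,max_s grid bounds in seconds, `0 < min_s < max_s`.
#' @param n number of grid points (>= 2).
#' @return an object of class `relax_grid` with elements `values_s` and `n`.
#' @export
relax_grid <- function(min_s = 10^-3.5, max_s = 10, n = 100) {
  if (min_s <= 0 || max_s <= min_s) stop_domain("need 0 < min_s < max_s")
  n <- as.integer(n)
  if (n < 2) stop_domain("n must be >= 2")
  structure(list(values_s = 10^seq(log10(min_s), log10(max_s), length.out = n),
                 n = n), class = "relax_grid")
}

validate_relax_grid <- function(grid) {
  if (!inherits(grid, "relax_grid")) stop_input("expected a relax_grid")
  lg <- log10(grid$values_s)
  step <- diff(lg)
  if (any(step <= 0) || diff(range(step)) > 1e-9 * max(abs(step)))
    stop_domain("relax_grid values must be uniformly spaced in log10")
  invisible(grid)
}

#' 2D relaxation-shift correlation map
#'
#' Nonnegative amplitude over a (log-spaced T1 grid) x (ppm axis) plane: the
#' output of the per-channel inverse Laplace transform.  Rows index T1 grid
#' points, columns index frequency channels.
#'
#' @param amplitude nonnegative matrix `[n_T1 x n_freq]`.
#' @param t1_grid a [relax_grid()].
#' @param ppm_axis ppm values, one per column.
#' @param alpha_per_channel regularization parameter chosen per channel
#'   (`NA` for masked channels).
#' @param meta free-form provenance list.
#' @return an object of class `adrosys_map`.
#' @export
adrosys_map <- function(amplitude, t1_grid, ppm_axis, alpha_per_channel = NULL,
                        meta = list()) {
  validate_relax_grid(t1_grid)
  if (!is.matrix(amplitude) || nrow(amplitude) != t1_grid$n ||
      ncol(amplitude) != length(ppm_axis))
    stop_format("amplitude must be an [n_T1 x n_freq] matrix matching grid and axis")
  if (any(amplitude < 0)) stop_domain("map amplitudes must be nonnegative")
  structure(list(amplitude = amplitude, t1_grid = t1_grid,
                 ppm_axis = as.numeric(ppm_axis),
                 alpha_per_channel = alpha_per_channel, meta = meta),
            class = "adrosys_map")
}

#' @export
print.adrosys_map <- function(x, ...) {
  cat(sprintf("<adrosys_map> %d T1 points x %d channels; T1 %.3g .. %.3g s; total mass %.4g\n",
              x$t1_grid$n, length(x$ppm_axis), min(x$t1_grid$values_s),
              max(x$t1_grid$values_s), sum(x$amplitude)))
  invisible(x)
}

#' T1-T2 correlation map
#'
#' Nonnegative amplitude over two log-spaced relaxation grids, the result of a
#' 2D relaxation-relaxation inversion.  Rows index T1, columns index T2.
#'
#' @param amplitude nonnegative `[n_T1 x n_T2]` matrix.
#' @param t1_grid,t2_grid [relax_grid()] objects.
#' @return an object of class `t1t2_map`.
#' @export
t1t2_map <- function(amplitude, t1_grid, t2_grid) {
  validate_relax_grid(t1_grid); validate_relax_grid(t2_grid)
  if (!is.matrix(amplitude) || nrow(amplitude) != t1_grid$n ||
      ncol(amplitude) != t2_grid$n)
    stop_format("amplitude must be an [n_T1 x n_T2] matrix matching the grids")
  if (any(amplitude < 0)) stop_domain("map amplitudes must be nonnegative")
  structure(list(amplitude = amplitude, t1_grid = t1_grid, t2_grid = t2_grid),
            class = "t1t2_map")
}

#' Reverse-micelle sample record
#'
#' Identity and water loading of a reverse-micelle preparation, optionally
#' with the rotational correlation time determined from its T1.
#'
#' @param surfactant,dispersant text identifiers.
#' @param guest guest molecule identifier or `NA` for none.
#' @param w0 water loading (molar ratio of water to surfactant), > 0.
#' @param tau_c_ps rotational correlation time in picoseconds, > 0 or `NA`.
#' @return an object of class `rm_sample`.
#' @export
rm_sample <- function(surfactant, dispersant, guest = NA, w0, tau_c_ps = NA) {
  if (!is.numeric(w0) || w0 <= 0) stop_domain("w0 must be > 0")
  if (!is.na(tau_c_ps) && tau_c_ps <= 0) stop_domain("tau_c_ps must be > 0 when present")
  structure(list(surfactant = as.character(surfactant),
                 dispersant = as.character(dispersant),
                 guest = if (is.na(guest)) NA_character_ else as.character(guest),
                 w0 = as.numeric(w0), tau_c_ps = as.numeric(tau_c_ps)),
            class = "rm_sample")
}
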