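#' Gyromagnetic ratio of deuterium relative to the proton
#'
#' The constant used to transfer a 0-ppm reference measured on the proton
#' channel (TMS) to the deuterium axis: the deuterium frequency assigned
#' 0 ppm is `proton_tms_hz * gamma_ratio_2h_1h()`.
#'
#' @return the dimensionless ratio (0.15350609).
#' @export
gamma_ratio_2h_1h <- function() 0.15350609

# absolute deuterium frequency assigned 0 ppm; errors (or falls back to the
# carrier with a warning) when no proton reference is available
zero_ppm_hz <- function(acq, fallback = FALSE) {
  if (!is.null(acq$proton_tms_hz)) return(acq$proton_tms_hz * gamma_ratio_2h_1h())
  if (fallback) {
    warning("no proton_tms_hz in acquisition metadata; using the carrier as the 0 ppm reference",
            call. = FALSE)
    return(acq$carrier_hz)
  }
  stop_referencing(paste0(
    "acquisition metadata has no proton_tms_hz; acquire a companion proton ",
    "spectrum, or pass ref = \"carrier\" to fall back to carrier-as-reference"))
}

#' Referenced ppm axis for a processed spectrum
#'
#' Maps each direct-dimension frequency to ppm using the companion proton TMS
#' frequency: the deuterium frequency assigned 0 ppm is `proton_tms_hz`
#' scaled by the deuterium/proton gyromagnetic ratio, and
#' `ppm = 1e6 (f - f0) / f0`.  The axis is returned in descending order
#' (NMR display convention).
#'
#' @param acq an [acq_meta()] with `proton_tms_hz` set (unless
#'   `ref = "carrier"`).
#' @param n_freq number of frequency bins (after any zero filling); defaults
#'   to `acq$n_points`.
#' @param ref `"tms"` to require the proton reference, `"carrier"` to fall
#'   back to treating the carrier as 0 ppm (with a warning).
#' @return numeric vector of ppm values, strictly descending, bin-centred.
#' @export
reference_ppm <- function(acq, n_freq = acq$n_points, ref = c("tms", "carrier")) {
  ref <- match.arg(ref)
  f0 <- if (ref == "tms") zero_ppm_hz(acq) else zero_ppm_hz(acq, fallback = TRUE)
  offs <- fft_offsets_hz(n_freq, acq$dwell_s * acq$n_points / n_freq)
  f_abs <- acq$carrier_hz + offs
  ppm <- 1e6 * (f_abs - f0) / f0
  sort(ppm, decreasing = TRUE)
}

# offset frequencies (Hz) of the unshifted DFT bins for n points at dwell dw
fft_offsets_hz <- function(n, dw) {
  sw <- 1 / dw
  j <- 0:(n - 1)
  offs <- j / (n * dw)
  offs[offs >= sw / 2] <- offs[offs >= sw / 2] - sw
  offs
}

#' Zero- and first-order phase correction
#'
#' @param phi0 zero-order phase in radians.
#' @param phi1 first-order phase in radians across the full spectral width.
#' @return an object of class `phase_correction`.
#' @export
phase_correction <- function(phi0 = 0, phi1 = 0) {
  if (!is.finite(phi0) || !is.finite(phi1)) stop_domain("phases must be finite")
  structure(list(phi0 = phi0, phi1 = phi1), class = "phase_correction")
}

#' Automatic zero-order phasing
#'
#' Chooses the zero-order phase phi0 that minimizes the integral of negative
#' excursions of the real part of a (fully recovered, positive-signal)
#' spectrum, by coarse grid search refined with a local optimizer.  In an
#' inversion-recovery series this is applied to the longest-delay row and the
#' same correction is used for every row, preserving the sign structure of
#' partially recovered rows.
#'
#' @param last_row_spectrum complex spectrum vector (nonzero).
#' @return a [phase_correction()] with `phi1 = 0` and `phi0` in (-pi, pi].
#' @export
autophase <- function(last_row_spectrum) {
  v <- as.complex(last_row_spectrum)
  if (!length(v) || all(v == 0)) stop_input("autophase needs a nonzero spectrum")
  negcost <- function(phi) {
    re <- Re(v * exp(1i * phi))
    sum(pmin(re, 0)^2)
  }
  # on clean spectra the cost has a flat zero plateau around the optimum;
  # the amplitude-weighted mean phase pins the solution inside it and is
  # exactly equivariant under rotations of the input
  phi_w <- -Arg(sum(v * Mod(v)))
  refine <- function(phi) {
    stats::optimize(negcost, interval = phi + c(-1, 1) * (2 * pi / 180))
  }
  grid <- seq(0, 2 * pi, length.out = 361)[-361]
  costs <- vapply(grid, negcost, numeric(1))
  cand_g <- refine(grid[which.min(costs)])
  cand_w <- refine(phi_w)
  tol <- 1e-12 * sum(Mod(v)^2)^1  # plateau ties resolve to the weighted phase
  phi <- if (negcost(phi_w) <= min(cand_g$objective, cand_w$objective) + tol) {
    phi_w
  } else if (cand_w$objective <= cand_g$objective + tol) {
    cand_w$minimum
  } else {
    cand_g$minimum
  }
  # resolve the pi ambiguity of a symmetric cost: require positive net area
  if (sum(Re(v * exp(1i * phi))) < 0) phi <- phi + pi
  phi <- ((phi + pi) %% (2 * pi)) - pi
  if (phi <= -pi) phi <- phi + 2 * pi
  phase_correction(phi0 = phi, phi1 = 0)
}

apply_phase <- function(spec_rows, phase) {
  n <- ncol(spec_rows)
  ramp <- exp(1i * (phase$phi0 + phase$phi1 * (seq_len(n) - 1) / n))
  sweep(spec_rows, 2, ramp, `*`)
}

#' Estimate spectral noise from signal-free edges
#'
#' Robust per-point noise amplitude: 1.4826 times the median absolute
#' deviation of the real part over the outer fraction of the ppm axis on each
#' side (assumed signal-free), pooled over all rows.
#'
#' @param data real spectrum matrix (rows = recovery delays).
#' @param edge_frac fraction of the axis used on each side (default 0.1).
#' @return estimated noise standard deviation.
#' @export
estimate_noise <- function(data, edge_frac = 0.1) {
  n <- ncol(data)
  k <- max(1L, floor(edge_frac * n))
  edges <- c(data[, seq_len(k), drop = FALSE],
             data[, seq.int(n - k + 1L, n), drop = FALSE])
  stats::mad(edges, center = stats::median(edges))
}

#' Direct-dimension processing of an inversion-recovery series
#'
#' Standard NMR processing of each transient: exponential apodization
#' (`exp(-pi * line_broaden_hz * t)`), zero filling, discrete Fourier
#' transform (with the customary half-weighting of the first point), phase
#' rotation, and extraction of the real (absorption) part.  The frequency
#' axis is referenced to ppm via [reference_ppm()] and returned in descending
#' order; the per-point noise amplitude is estimated from the signal-free
#' edges of the axis.
#'
#' Processing is linear in the input for a fixed phase correction.
#'
#' @param series a [fid_series()].
#' @param line_broaden_hz exponential line broadening in Hz (>= 0; default 1).
#' @param zero_fill_factor 1, 2 or 4 (default 2).
#' @param phase a [phase_correction()], or `"auto"` to phase on the
#'   longest-delay row.
#' @param ref `"tms"` (require proton referencing) or `"carrier"` (fall back
#'   to carrier-as-reference with a warning).
#' @param noise_window_frac edge fraction used for the noise estimate.
#' @return a [shift_series()].
#' @export
process_direct <- function(series, line_broaden_hz = 1, zero_fill_factor = 2,
                           phase = "auto", ref = c("tms", "carrier"),
                           noise_window_frac = 0.1) {
  ref <- match.arg(ref)
  if (!inherits(series, "fid_series")) stop_input("series must be a fid_series")
  if (!length(series$tau_s) || !nrow(series$data))
    stop_input("empty series")
  if (!is.numeric(line_broaden_hz) || line_broaden_hz < 0)
    stop_domain("line_broaden_hz must be >= 0")
  if (!zero_fill_factor %in% c(1L, 2L, 4L))
    stop_domain("zero_fill_factor must be 1, 2 or 4")
  acq <- series$acq
  n <- acq$n_points
  nz <- n * as.integer(zero_fill_factor)
  t_k <- (seq_len(n) - 1L) * acq$dwell_s
  apod <- exp(-pi * line_broaden_hz * t_k)
  apod[1] <- apod[1] * 0.5   # first-point half weight: removes baseline offset
  rows <- sweep(series$data, 2, apod, `*`)
  if (nz > n) rows <- cbind(rows, matrix(0 + 0i, nrow(rows), nz - n))
  spec <- t(apply(rows, 1L, stats::fft))
  if (nrow(series$data) == 1L) spec <- matrix(spec, nrow = 1L)
  if (identical(phase, "auto")) {
    last <- spec[nrow(spec), ]
    phase <- if (all(last == 0)) phase_correction(0, 0) else autophase(last)
  }
  if (!inherits(phase, "phase_correction"))
    stop_input("phase must be \"auto\" or a phase_correction")
  spec <- apply_phase(spec, phase)
  # order columns by descending ppm
  offs <- fft_offsets_hz(nz, acq$dwell_s)
  f0 <- if (ref == "tms") zero_ppm_hz(acq) else zero_ppm_hz(acq, fallback = TRUE)
  ppm <- 1e6 * (acq$carrier_hz + offs - f0) / f0
  ord <- order(ppm, decreasing = TRUE)
  re <- Re(spec)[, ord, drop = FALSE]
  sigma_f <- estimate_noise(re, noise_window_frac)
  out <- shift_series(re, ppm[ord], series$tau_s, noise_sigma = sigma_f, acq = acq)
  out$phase <- phase
  out
}
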