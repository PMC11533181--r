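#' Relaxation kernel for the inverse Laplace transform
#'
#' Discretized kernel linking a distribution over relaxation times to the
#' measured delay series.  For inversion recovery the entries are
#' `1 - 2 f exp(-tau_i / T1_j)` (in `[1 - 2f, 1]`); for a pure decay they are
#' `exp(-tau_i / T2_j)` (in `(0, 1]`).
#'
#' @param tau_s delay list, seconds, strictly increasing.
#' @param grid a [relax_grid()] of candidate relaxation times.
#' @param kind `"inversion_recovery"` or `"decay"`.
#' @param inv_eff inversion efficiency `f` in (0, 1]; ignored for decay.
#' @return an object of class `relax_kernel` with elements `matrix`
#'   (`[n_delays x n_grid]`), `grid`, `tau_s`, `kind`, `inv_eff`.
#' @export
build_kernel <- function(tau_s, grid, kind = c("inversion_recovery", "decay"),
                         inv_eff = 1) {
  kind <- match.arg(kind)
  validate_relax_grid(grid)
  tau_s <- as.numeric(tau_s)
  if (any(diff(tau_s) <= 0)) stop_domain("tau_s must be strictly increasing")
  if (inv_eff <= 0 || inv_eff > 1) stop_domain("inv_eff must lie in (0, 1]")
  E <- exp(-outer(tau_s, 1 / grid$values_s))
  K <- if (kind == "inversion_recovery") 1 - 2 * inv_eff * E else E
  structure(list(matrix = K, grid = grid, tau_s = tau_s, kind = kind,
                 inv_eff = inv_eff), class = "relax_kernel")
}

#' Options for the BRD regularized inversion
#'
#' @param max_iter maximum fixed-point iterations on the regularization
#'   parameter alpha (>= 1).
#' @param alpha_tol relative tolerance for convergence of alpha.
#' @param alpha_init positive starting value for alpha.
#' @param compression_rank `"auto"` (retain singular values down to 1e-6 of
#'   the largest, capped at 16), a positive integer, or `FALSE` for no
#'   compression.
#' @return an object of class `brd_options`.
#' @export
brd_options <- function(max_iter = 50, alpha_tol = 1e-3, alpha_init = 1,
                        compression_rank = "auto") {
  if (max_iter < 1) stop_domain("max_iter must be >= 1")
  if (alpha_tol <= 0) stop_domain("alpha_tol must be > 0")
  if (alpha_init <= 0) stop_domain("alpha_init must be > 0")
  structure(list(max_iter = as.integer(max_iter), alpha_tol = alpha_tol,
                 alpha_init = alpha_init, compression_rank = compression_rank),
            class = "brd_options")
}

#' Truncated-SVD compression of a kernel and its data
#'
#' Computes the singular value decomposition `K = U S V'`, truncates to rank
#' `r`, and replaces the problem `K x ~ d` by the equivalent compressed
#' problem `(S_r V_r') x ~ U_r' d`.  The spectral norm of the discarded part
#' satisfies `||K - K_r||_2 <= sigma_{r+1}`, and because `U_r` has
#' orthonormal columns the per-point noise level of the projected data is
#' unchanged.
#'
#' @param kernel a [build_kernel()] result.
#' @param data optional vector (length `n_delays`) or matrix
#'   (`n_delays` rows) to project onto the retained left singular basis.
#' @param rank `"auto"`, a positive integer `<= min(dim)`, or `FALSE`
#'   (returns the inputs unchanged with full rank).
#' @return list with `kernel_matrix` (`[r x n_grid]`), `data` (projected),
#'   `singular_values` (all of them), `rank`, and `basis` (`U_r`).
#' @export
compress_kernel <- function(kernel, data = NULL, rank = "auto") {
  if (!inherits(kernel, "relax_kernel")) stop_input("kernel must be a relax_kernel")
  K <- kernel$matrix
  sv <- svd(K)
  full <- min(dim(K))
  r <- if (identical(rank, "auto")) {
    min(sum(sv$d / sv$d[1] >= 1e-6), 16L, full)
  } else if (identical(rank, FALSE)) {
    full
  } else {
    rank <- as.integer(rank)
    if (is.na(rank) || rank <= 0) stop_domain("rank must be a positive integer")
    if (rank > full) stop_domain("rank exceeds min(kernel dimensions)")
    rank
  }
  U <- sv$u[, seq_len(r), drop = FALSE]
  Kc <- diag(sv$d[seq_len(r)], r, r) %*% t(sv$v[, seq_len(r), drop = FALSE])
  dc <- if (is.null(data)) NULL else if (is.matrix(data)) {
    crossprod(U, data)
  } else {
    drop(crossprod(U, matrix(data, ncol = 1)))
  }
  list(kernel_matrix = Kc, data = dc, singular_values = sv$d, rank = r,
       basis = U)
}

# Tikhonov-regularized NNLS: min ||K x - d||^2 + alpha ||x||^2, x >= 0,
# via an active-set nonnegative least-squares solve on the stacked system.
nnls_tikhonov <- function(K, d, alpha) {
  ng <- ncol(K)
  C <- rbind(K, sqrt(alpha) * diag(ng))
  b <- c(d, rep(0, ng))
  pracma::lsqnonneg(C, b)$x
}

# BRD fixed point on alpha with Steffensen acceleration: the map
# alpha -> sigma sqrt(n0) / ||c(alpha)|| converges only sublinearly on its
# own, so each step uses two map applications plus an Aitken update.
brd_fixed_point <- function(K, d, sigma, n0, opts) {
  solve_x <- function(alpha) nnls_tikhonov(K, d, alpha)
  fmap <- function(alpha) {
    x <- solve_x(alpha)
    cn <- sqrt(sum(((d - drop(K %*% x)) / alpha)^2))
    if (cn == 0) Inf else sigma * sqrt(n0) / cn
  }
  alpha <- opts$alpha_init
  trace <- numeric(0)
  converged <- FALSE
  # when the data can be fit far below the stated noise level the fixed
  # point degenerates to alpha = 0 (pure NNLS); stop once alpha underflows
  floor_alpha <- 1e-13 * opts$alpha_init
  for (it in seq_len(opts$max_iter)) {
    a1 <- fmap(alpha)
    if (!is.finite(a1)) { converged <- TRUE; break }  # exact fit: alpha moot
    trace <- c(trace, a1)
    if (a1 < floor_alpha || abs(a1 - alpha) < opts$alpha_tol * alpha) {
      alpha <- a1; converged <- TRUE; break
    }
    a2 <- fmap(a1)
    if (!is.finite(a2)) { alpha <- a1; converged <- TRUE; break }
    trace <- c(trace, a2)
    if (a2 < floor_alpha || abs(a2 - a1) < opts$alpha_tol * a1) {
      alpha <- a2; converged <- TRUE; break
    }
    den <- a2 - 2 * a1 + alpha
    cand <- if (abs(den) > 0) alpha - (a1 - alpha)^2 / den else a2
    alpha <- if (is.finite(cand) && cand > 0) cand else a2
  }
  list(x = solve_x(alpha), alpha = alpha, trace = trace,
       converged = converged)
}

#' BRD regularized nonnegative inversion
#'
#' Solves `min ||K x - d||^2 + alpha ||x||^2` subject to `x >= 0`, choosing
#' the regularization parameter by the Butler-Reeds-Dawson fixed point: given
#' the dual vector `c = (d - K x) / alpha`, alpha is updated to
#' `noise_sigma * sqrt(n) / ||c||` and the nonnegative problem re-solved
#' until alpha changes by less than `alpha_tol` (relative) or `max_iter` is
#' reached.  At the fixed point the residual norm approximates
#' `sqrt(n) * noise_sigma` (the discrepancy principle).
#'
#' The kernel is optionally compressed by truncated SVD before solving; the
#' returned distribution always lives on the full grid.
#'
#' @param kernel a [build_kernel()] result.
#' @param data numeric vector, one value per kernel delay.
#' @param noise_sigma per-point noise standard deviation (> 0).
#' @param opts a [brd_options()].
#' @return list with `distribution` (nonnegative vector on the grid),
#'   `alpha`, and `diagnostics` (residual `chisq`, `alpha_trace`,
#'   `iterations`, `converged`, `rank`).
#' @export
brd_solve <- function(kernel, data, noise_sigma, opts = brd_options()) {
  if (!inherits(kernel, "relax_kernel")) stop_input("kernel must be a relax_kernel")
  data <- as.numeric(data)
  K0 <- kernel$matrix
  if (length(data) != nrow(K0))
    stop_input("data length (%d) must equal kernel delay count (%d)",
               length(data), nrow(K0))
  if (!is.numeric(noise_sigma) || noise_sigma <= 0)
    stop_domain("noise_sigma must be > 0")
  n0 <- length(data)
  ng <- ncol(K0)
  if (all(data == 0)) {
    return(list(distribution = rep(0, ng), alpha = opts$alpha_init,
                diagnostics = list(chisq = 0, alpha_trace = numeric(0),
                                   iterations = 0L, converged = TRUE,
                                   rank = NA_integer_)))
  }
  cmp <- compress_kernel(kernel, data, rank = opts$compression_rank)
  fp <- brd_fixed_point(cmp$kernel_matrix, cmp$data, noise_sigma, n0, opts)
  if (!fp$converged)
    warning("BRD alpha fixed point did not converge within max_iter", call. = FALSE)
  chisq <- sum((drop(K0 %*% fp$x) - data)^2)
  list(distribution = fp$x, alpha = fp$alpha,
       diagnostics = list(chisq = chisq, alpha_trace = fp$trace,
                          iterations = length(fp$trace),
                          converged = fp$converged, rank = cmp$rank))
}

#' Per-channel inverse Laplace transform of an inversion-recovery series
#'
#' The "1.5D" map builder: each retained frequency channel of the processed
#' spectrum supplies a recovery trace that is inverted independently with a
#' shared inversion-recovery kernel via [brd_solve()], producing a
#' nonnegative T1 distribution per channel.  Channels whose largest absolute
#' signal over the delays falls below `threshold_mult` times the noise level
#' are masked to exact zero columns (their alpha is recorded as `NA`).
#'
#' @param spec a [shift_series()] with at least 4 recovery delays.
#' @param grid T1 grid, a [relax_grid()].
#' @param opts a [brd_options()].
#' @param inv_eff inversion efficiency of the kernel (must match the
#'   acquisition; 1 for an ideal pi pulse).
#' @param threshold_mult channel retention threshold in noise-sigma units
#'   (default 5).
#' @param noise_sigma override for the noise level; defaults to
#'   `spec$noise_sigma`, with a small floor relative to the data for
#'   essentially noiseless input.
#' @param ppm_range optional `c(lo, hi)` window; channels outside are masked.
#' @return an [adrosys_map()].
#' @export
ilt_1p5d <- function(spec, grid = relax_grid(), opts = brd_options(),
                     inv_eff = 1, threshold_mult = 5, noise_sigma = NULL,
                     ppm_range = NULL) {
  if (!inherits(spec, "shift_series")) stop_input("spec must be a shift_series")
  if (length(spec$tau_s) < 4) stop_input("need at least 4 recovery delays")
  validate_relax_grid(grid)
  gv <- range(grid$values_s)
  tr <- range(spec$tau_s[spec$tau_s > 0])
  if (gv[1] < tr[1] / 10 || gv[2] > tr[2] * 10)
    warning("T1 grid extends beyond [min tau / 10, max tau * 10]; values out there are unconstrained by the delays",
            call. = FALSE)
  sigma <- if (is.null(noise_sigma)) spec$noise_sigma else noise_sigma
  sigma <- max(sigma, 1e-8 * max(abs(spec$data)), .Machine$double.eps)
  kernel <- build_kernel(spec$tau_s, grid, "inversion_recovery", inv_eff)
  cmp <- compress_kernel(kernel, spec$data, rank = opts$compression_rank)
  # per-channel solves reuse the shared compressed kernel
  sub_kernel <- kernel
  sub_kernel$matrix <- cmp$kernel_matrix
  sub_opts <- opts
  sub_opts$compression_rank <- FALSE
  nch <- ncol(spec$data)
  keep <- apply(abs(spec$data), 2, max) >= threshold_mult * sigma
  if (!is.null(ppm_range)) {
    keep <- keep & spec$ppm_axis >= min(ppm_range) & spec$ppm_axis <= max(ppm_range)
  }
  amp <- matrix(0, nrow = grid$n, ncol = nch)
  alphas <- rep(NA_real_, nch)
  n0 <- length(spec$tau_s)
  for (ch in which(keep)) {
    # projected trace for this channel; chisq inside brd_solve is computed
    # against the projected data, consistent at unchanged noise level
    res <- brd_solve_compressed(sub_kernel, cmp$data[, ch], sigma, n0, sub_opts)
    amp[, ch] <- res$distribution
    alphas[ch] <- res$alpha
  }
  adrosys_map(amp, grid, spec$ppm_axis, alpha_per_channel = alphas,
              meta = list(noise_sigma = sigma, threshold_mult = threshold_mult,
                          inv_eff = inv_eff, rank = cmp$rank,
                          n_delays = n0))
}

# brd_solve on an already-compressed kernel; n0 is the original data length
brd_solve_compressed <- function(kernel, data, noise_sigma, n0, opts) {
  K <- kernel$matrix
  if (all(data == 0)) {
    return(list(distribution = rep(0, ncol(K)), alpha = opts$alpha_init))
  }
  fp <- brd_fixed_point(K, data, noise_sigma, n0, opts)
  list(distribution = fp$x, alpha = fp$alpha)
}

#' 2D T1-T2 inversion
#'
#' Inverts a relaxation-relaxation data matrix with an inversion-recovery
#' kernel along the first dimension and a decay kernel along the second.
#' Both kernels are compressed by truncated SVD, the data are projected into
#' the compressed tensor space, and the separable problem
#' `vec(Mc) = (K2c kron K1c) vec(F)` is solved by BRD-regularized
#' nonnegative inversion.
#'
#' @param data numeric matrix `[length(tau1_s) x length(tau2_s)]`.
#' @param tau1_s,tau2_s delay lists of the two dimensions.
#' @param t1_grid,t2_grid [relax_grid()] objects for the two axes.
#' @param opts a [brd_options()].
#' @param inv_eff inversion efficiency of the recovery kernel.
#' @param noise_sigma per-point noise standard deviation (> 0; a small floor
#'   is applied for noiseless data).
#' @return a [t1t2_map()].
#' @export
ilt_2d_t1t2 <- function(data, tau1_s, tau2_s,
                        t1_grid = relax_grid(n = 40),
                        t2_grid = relax_grid(n = 40),
                        opts = brd_options(), inv_eff = 1, noise_sigma = 0) {
  if (!is.matrix(data) || nrow(data) != length(tau1_s) ||
      ncol(data) != length(tau2_s))
    stop_input("data dims must match the two delay lists")
  sigma <- max(noise_sigma, 1e-8 * max(abs(data)), .Machine$double.eps)
  if (all(data == 0))
    return(t1t2_map(matrix(0, t1_grid$n, t2_grid$n), t1_grid, t2_grid))
  k1 <- build_kernel(tau1_s, t1_grid, "inversion_recovery", inv_eff)
  k2 <- build_kernel(tau2_s, t2_grid, "decay")
  c1 <- compress_kernel(k1, rank = opts$compression_rank)
  c2 <- compress_kernel(k2, rank = opts$compression_rank)
  Mc <- crossprod(c1$basis, data %*% c2$basis)     # r1 x r2
  A <- kronecker(c2$kernel_matrix, c1$kernel_matrix)
  kern <- structure(list(matrix = A), class = "relax_kernel")
  res <- brd_solve_compressed(kern, as.vector(Mc), sigma,
                              n0 = length(data), opts = opts)
  F <- matrix(res$distribution, nrow = t1_grid$n, ncol = t2_grid$n)
  out <- t1t2_map(F, t1_grid, t2_grid)
  out$alpha <- res$alpha
  out
}
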