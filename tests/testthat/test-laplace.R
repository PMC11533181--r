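test_that("kernel entries follow the recovery and decay limits", {
  grid <- relax_grid(1e-3, 10, 25)
  tau <- c(0, 0.05 * log(2), 1, 500)
  kir <- build_kernel(tau, grid, "inversion_recovery", inv_eff = 1)
  expect_equal(kir$matrix[1, ], rep(-1, 25))           # tau = 0
  expect_equal(kir$matrix[4, ], rep(1, 25), tolerance = 1e-12)  # tau -> inf
  j <- which.min(abs(grid$values_s - 0.05))
  expect_equal(build_kernel(c(grid$values_s[j] * log(2)), grid,
                            "inversion_recovery")$matrix[1, j], 0,
               tolerance = 1e-12)
  kd <- build_kernel(tau[-1], grid, "decay")
  expect_true(all(kd$matrix >= 0 & kd$matrix <= 1))
  expect_true(all(kd$matrix[1, ] > 0))
  expect_equal(kd$matrix[3, 1], 0, tolerance = 1e-12)
  expect_error(build_kernel(tau, grid, inv_eff = 1.5),
               class = "adrosys_domain_error")
})

test_that("truncated SVD compression obeys the spectral-norm bound", {
  grid <- relax_grid(1e-3, 10, 60)
  k <- build_kernel(default_tau_s(16), grid, "inversion_recovery")
  sv <- svd(k$matrix)$d
  for (r in c(3, 6, 10)) {
    cmp <- compress_kernel(k, rank = r)
    # ||K - U_r Kc||_2 <= sigma_{r+1}
    resid <- k$matrix - cmp$basis %*% cmp$kernel_matrix
    expect_lte(svd(resid)$d[1], sv[r + 1] * (1 + 1e-8))
  }
  full <- compress_kernel(k, rank = 16)
  expect_lt(max(abs(k$matrix - full$basis %*% full$kernel_matrix)), 1e-10)
  auto <- compress_kernel(k, rank = "auto")
  expect_lte(auto$rank, 16L)
  expect_error(compress_kernel(k, rank = 0), class = "adrosys_domain_error")
})

test_that("BRD localizes a single on-grid relaxation time like dense NNLS", {
  grid <- relax_grid(1e-3, 10, 60)
  tau <- default_tau_s(16)
  k <- build_kernel(tau, grid, "inversion_recovery")
  node <- 30
  t1 <- grid$values_s[node]
  d <- 1 - 2 * exp(-tau / t1)

  expect_equal(brd_solve(k, rep(0, 16), 1e-3)$distribution, rep(0, 60))

  res <- brd_solve(k, d, noise_sigma = 1e-6)
  x <- res$distribution
  expect_true(all(x >= 0))
  near <- sum(x[(node - 1):(node + 1)]) / sum(x)
  expect_gte(near, 0.95)

  # oracle: dense nonnegative least squares on the full kernel
  xo <- pracma::lsqnonneg(k$matrix, d)$x
  expect_equal(which.max(xo), node)
  expect_equal(wcentroid(log10(grid$values_s), x),
               wcentroid(log10(grid$values_s), xo), tolerance = 0.05)
})

test_that("compressed and uncompressed BRD solutions agree on clean data", {
  grid <- relax_grid(1e-3, 10, 60)
  tau <- default_tau_s(16)
  k <- build_kernel(tau, grid, "inversion_recovery")
  d <- 0.7 * (1 - 2 * exp(-tau / 0.05)) + 0.3 * (1 - 2 * exp(-tau / 0.8))
  sigma <- 1e-4 * max(abs(d))
  xf <- brd_solve(k, d, sigma, brd_options(compression_rank = FALSE))
  xa <- brd_solve(k, d, sigma, brd_options(compression_rank = "auto"))
  # any rank at or above the numerical rank leaves the solution unchanged
  xr <- brd_solve(k, d, sigma, brd_options(compression_rank = xa$diagnostics$rank))
  rel <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
  expect_lt(rel(xa$distribution, xf$distribution), 1e-4)
  expect_lt(rel(xr$distribution, xf$distribution), 1e-4)
  expect_equal(xa$alpha, xf$alpha, tolerance = 1e-3)
})

test_that("BRD residual satisfies the discrepancy principle on noisy data", {
  grid <- relax_grid(1e-3, 10, 60)
  tau <- default_tau_s(16)
  k <- build_kernel(tau, grid, "inversion_recovery")
  sigma <- 0.01
  clean <- 1 - 2 * exp(-tau / 0.1)
  for (seed in 1:3) {
    d <- clean + with_seed_rnorm(seed, length(tau), sigma)
    res <- brd_solve(k, d, sigma)
    chisq <- res$diagnostics$chisq
    expect_gt(chisq, length(tau) * sigma^2 / 2)
    expect_lt(chisq, length(tau) * sigma^2 * 2)
    # fit beats the trivial constant model at this SNR
    expect_lt(chisq, sum((d - mean(d))^2))
  }
})

test_that("the BRD regularization parameter never falls as noise rises", {
  grid <- relax_grid(1e-3, 10, 50)
  tau <- default_tau_s(16)
  k <- build_kernel(tau, grid, "inversion_recovery")
  clean <- 1 - 2 * exp(-tau / 0.1)
  d <- clean + with_seed_rnorm(4, length(tau), 0.01)
  alphas <- vapply(c(0.005, 0.01, 0.02, 0.05, 0.1),
                   function(s) brd_solve(k, d, s)$alpha, numeric(1))
  expect_true(all(diff(alphas) >= 0))
})

test_that("the per-channel map recovers two components at their true positions", {
  acq <- small_acq(n_points = 512)
  tau <- default_tau_s(16)
  comps <- list(component(1.0, 2.0, 0.02, 0.03),
                component(1.0, 4.5, 0.05, 0.5))
  s <- make_fid_series(comps, tau, acq, noise_sigma = 0.01, seed = 21)
  spec <- process_direct(s, phase = "auto")
  grid <- relax_grid(10^-3.5, 10, 80)
  map <- ilt_1p5d(spec, grid = grid)
  expect_true(all(map$amplitude >= 0))

  peaks <- summarize_peaks(map, regions = list(c(1.0, 3.0), c(3.5, 5.5)))
  expect_identical(nrow(peaks), 2L)
  peaks <- peaks[order(peaks$shift_centroid_ppm), ]
  expect_equal(peaks$shift_centroid_ppm, c(2.0, 4.5), tolerance = 0.05)
  expect_equal(peaks$logt1_centroid, log10(c(0.03, 0.5)), tolerance = 0.15)

  # zero spectrum gives a zero map
  zspec <- shift_series(matrix(0, length(tau), 40),
                        seq(6, 2, length.out = 40), tau, noise_sigma = 0.01)
  zmap <- ilt_1p5d(zspec, grid = grid)
  expect_true(all(zmap$amplitude == 0))
})

test_that("channels are inverted independently (permutation contract)", {
  tau <- default_tau_s(12)
  grid <- relax_grid(1e-3, 5, 40)
  nch <- 6
  traces <- sapply(c(0.02, 0.05, 0.1, 0.2, 0.5, 1),
                   function(t1) 1 - 2 * exp(-tau / t1))
  ppm <- seq(6, 1, length.out = nch)
  sp <- shift_series(traces, ppm, tau, noise_sigma = 1e-3)
  map <- ilt_1p5d(sp, grid = grid, threshold_mult = 1)
  perm <- c(3, 1, 6, 2, 5, 4)
  # permuting channels permutes the spectrum columns; ppm must stay monotone,
  # so permute the traces while keeping the axis
  sp2 <- shift_series(traces[, perm], ppm, tau, noise_sigma = 1e-3)
  map2 <- ilt_1p5d(sp2, grid = grid, threshold_mult = 1)
  expect_equal(map2$amplitude, map$amplitude[, perm], tolerance = 1e-10)
})

test_that("2D T1-T2 inversion concentrates mass on the diagonal for T1 = T2", {
  tau1 <- default_tau_s(14)
  tau2 <- 10^seq(-3, 0.3, length.out = 14)
  cmp <- component(1, 4.7, 0.1, 0.1)   # T1 = T2 = 0.1 s
  M <- make_t1t2_data(list(cmp), tau1, tau2, noise_sigma = 1e-3, seed = 6)
  g <- relax_grid(1e-3, 3, 30)
  map <- ilt_2d_t1t2(M, tau1, tau2, g, g, noise_sigma = 1e-3)
  expect_true(all(map$amplitude >= 0))
  expect_gte(diagonality(map, 0.3), 0.9)

  zmap <- ilt_2d_t1t2(matrix(0, 14, 14), tau1, tau2, g, g)
  expect_true(all(zmap$amplitude == 0))
})

test_that("2D inversion preserves the amplitude ratio of separated components", {
  tau1 <- default_tau_s(14)
  tau2 <- 10^seq(-3.2, 0.3, length.out = 14)
  comps <- list(component(1.0, 4.7, 0.3, 0.3),
                component(0.4, 2.0, 0.004, 0.004))
  M <- make_t1t2_data(comps, tau1, tau2, noise_sigma = 5e-4, seed = 8)
  g1 <- relax_grid(10^-3.2, 3, 30)
  map <- ilt_2d_t1t2(M, tau1, tau2, g1, g1, noise_sigma = 5e-4)
  lt <- log10(map$t1_grid$values_s)
  split_at <- log10(0.03)
  slow <- sum(map$amplitude[lt > split_at, ])
  fast <- sum(map$amplitude[lt <= split_at, ])
  expect_equal(slow / fast, 2.5, tolerance = 0.1 * 2.5)
})
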