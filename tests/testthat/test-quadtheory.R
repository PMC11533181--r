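test_that("spectral density has the Lorentzian limits", {
  tc <- 7e-12
  expect_equal(spectral_density(0, tc), 2 * tc)
  # half height where 2 pi nu tau = 1
  nu_half <- 1 / (2 * pi * tc)
  expect_equal(spectral_density(nu_half, tc), tc)
  # narrowing: within 0.01% of 2 tau when 2 pi nu tau = 0.01
  nu_small <- 0.01 / (2 * pi * tc)
  expect_equal(spectral_density(nu_small, tc) / (2 * tc), 1, tolerance = 1e-4)
  expect_error(spectral_density(1e6, -1), class = "adrosys_domain_error")
})

test_that("R1 matches an independent arbitrary-precision evaluation", {
  ctx <- quad_context(chi_hz = 230e3, nu_d_hz = 61.4e6)
  # frozen value computed with a 30-digit symbolic evaluation of the full
  # spin-1 quadrupolar expression at tau_c = 10 ps
  expect_equal(r1_quad(1e-11, ctx), 7.83113481663983, tolerance = 1e-12)
  # narrowing closed form agrees within 0.1% at this tau_c
  expect_equal(r1_quad(1e-11, ctx, approx = "narrowing"), 7.83153109226441,
               tolerance = 1e-12)
  expect_equal(r1_quad(1e-11, ctx) / r1_quad(1e-11, ctx, "narrowing"), 1,
               tolerance = 1e-3)
  expect_equal(r1_quad(0, ctx), 0)
  # the full curve never exceeds the linear narrowing form
  taus <- 10^seq(-13, -6, length.out = 40)
  expect_true(all(r1_quad(taus, ctx) <= r1_quad(taus, ctx, "narrowing") + 1e-15))
})

test_that("R1 = R2 in the narrowing regime and R2 > R1 outside it", {
  ctx <- quad_context()
  expect_equal(r2_quad(1e-12, ctx) / r1_quad(1e-12, ctx), 1, tolerance = 1e-4)
  expect_equal(r2_quad(0, ctx), 0)
  # frozen symbolic values at tau_c = 1 us (far outside narrowing)
  expect_equal(r1_quad(1e-6, ctx), 2.1047880291132, tolerance = 1e-10)
  expect_equal(r2_quad(1e-6, ctx), 234948.826845506, tolerance = 1e-10)
  taus <- 10^seq(-13, -6, length.out = 40)
  expect_true(all(r2_quad(taus, ctx) >= r1_quad(taus, ctx) - 1e-15))
  # equality to 1e-4 deep in the narrowing regime, clear separation outside
  x <- 2 * pi * ctx$nu_d_hz * taus
  dev <- abs(r2_quad(taus, ctx) / r1_quad(taus, ctx) - 1)
  expect_true(all(dev[x <= 0.005] < 1e-4))
  expect_true(all(dev[x >= 0.05] > 1e-4))
})

test_that("correlation-time inversion round-trips and resolves both branches", {
  ctx <- quad_context()
  tc <- 8.1e-12
  t1 <- 1 / r1_quad(tc, ctx)
  expect_equal(as.numeric(tau_c_from_t1(t1, ctx)), tc, tolerance = 1e-9)
  # a T1 slightly above the curve minimum has two solutions, fast < slow
  tmin <- 1 / r1_quad(1.5962e-9, ctx)
  both <- tau_c_from_t1(tmin * 1.05, ctx, both = TRUE)
  expect_lt(both[1, "fast"], both[1, "slow"])
  expect_equal(unname(1 / r1_quad(both[1, "fast"], ctx)), tmin * 1.05,
               tolerance = 1e-6)
  expect_equal(unname(1 / r1_quad(both[1, "slow"], ctx)), tmin * 1.05,
               tolerance = 1e-6)
  # extremely long T1 lands deep in the narrowing branch
  long <- tau_c_from_t1(3.15e7, ctx)   # one year
  expect_lt(as.numeric(long), 1e-12)
  expect_true(attr(long, "narrowing"))
  # T1 below the attainable minimum is rejected with the minimum reported
  expect_error(tau_c_from_t1(1e-4, ctx), class = "adrosys_domain_error")
})

test_that("every tabulated correlation time survives the T1 round trip", {
  ctx <- quad_context()
  tbl <- table1_fixture()
  tau <- tbl$tau_c_ps * 1e-12
  t1 <- 1 / r1_quad(tau, ctx)
  back <- as.numeric(tau_c_from_t1(t1, ctx, branch = "fast"))
  expect_equal(back, tau, tolerance = 1e-9)
})

test_that("correlation-time combination rules behave as expected", {
  expect_equal(combine_tau_parallel(c(3e-12, 3e-12)), 1.5e-12)
  expect_equal(combine_tau_parallel(7e-12), 7e-12)
  # the shorter process dominates
  expect_equal(combine_tau_parallel(c(10e-12, 10e-9)), 9.99e-12,
               tolerance = 1e-5)
  expect_lte(combine_tau_parallel(c(2e-12, 5e-12, 9e-12)), 2e-12)

  expect_equal(exchange_average_tau(c(2e-12, 4e-12), c(0.5, 0.5)), 3e-12)
  expect_equal(exchange_average_tau(c(2e-12, 4e-12), c(0, 1)), 4e-12)
  x <- exchange_average_tau(c(1e-12, 5e-12, 9e-12), c(0.2, 0.5, 0.3))
  expect_gte(x, 1e-12); expect_lte(x, 9e-12)
  expect_error(exchange_average_tau(c(1e-12, 2e-12), c(0.5, 0.6)),
               class = "adrosys_domain_error")
  expect_warning(exchange_average_tau(c(1e-9, 2e-9), c(0.5, 0.5),
                                      ctx = quad_context()), "narrowing")
})

test_that("core-shell averaging reduces to the right geometric limits", {
  expect_equal(core_shell_average(2, core_shell(0, 1.5, 9)), 1.5)  # no shell
  expect_equal(core_shell_average(1, core_shell(2, 1.5, 9)), 9)    # all shell
  # r = 2t: shell occupies 7/8 of the volume
  expect_equal(core_shell_average(2, core_shell(1, 0, 1)), 7 / 8)
})

test_that("water-pool radius is linear in the water loading", {
  w0 <- c(1, 5, 12, 20, 60)
  r <- rm_radius(w0)
  expect_true(all(diff(r) > 0))
  expect_equal(rm_radius(7) - rm_radius(6), rm_radius(31) - rm_radius(30),
               tolerance = 1e-12)
  expect_equal(rm_radius(20) / rm_radius(5), (0.175 * 20 + 0.45) / (0.175 * 5 + 0.45))
  expect_lt(rm_radius(1), 1)    # sub-nanometre pools at w0 = 1
  expect_gt(rm_radius(60), 10)  # slightly over 10 nm at w0 = 60
})

test_that("aggregation number blends plateau, linear and quadratic regimes", {
  p <- micelle_params()
  expect_equal(aggregation_number(0.2, p), p$a, tolerance = 0.05)
  w0 <- seq(0.5, 60, by = 0.25)
  nb <- aggregation_number(w0, p)
  expect_true(all(diff(nb) >= 0))
  # linear regime around w0 ~ 8, quadratic by w0 ~ 40
  expect_equal(aggregation_number(8, p), p$m * 8 + p$b, tolerance = 0.05)
  expect_equal(aggregation_number(40, p), p$l * 40^2 + p$c, tolerance = 0.01)
})

test_that("aggregation-curve fitting recovers generating parameters", {
  p <- micelle_params()
  w0 <- c(0.5, 1, 2, 3, 5, 8, 12, 17, 23, 30, 40, 55)
  pts <- data.frame(w0 = w0, nbar = aggregation_number(w0, p))
  init <- micelle_params(a = 10, m = 5, b = 0, l = 0.5, c = -20, k = 0.2)
  fit <- fit_aggregation(pts, init)
  expect_equal(fit$params$a, p$a, tolerance = 1e-3)
  expect_equal(fit$params$m, p$m, tolerance = 1e-3)
  expect_lt(fit$residual_norm, 1e-4)

  noisy <- pts
  noisy$nbar <- noisy$nbar * (1 + with_seed_rnorm(13, nrow(pts), 0.02))
  fitn <- fit_aggregation(noisy, init)
  expect_equal(fitn$params$a, p$a, tolerance = 0.1 * p$a)
  expect_equal(fitn$params$m, p$m, tolerance = 0.1 * p$m)

  expect_error(fit_aggregation(pts[1:5, ]), class = "adrosys_input_error")
})

test_that("water-loading algebra matches the preparation bookkeeping", {
  # 115 uL D2O over 6.3 mmol and 0.317 mmol of AOT
  expect_equal(w0_equivalent(115e-6, 6.3e-3), 1, tolerance = 0.01)
  expect_equal(w0_equivalent(115e-6, 0.141 / surfactant_molar_masses()["AOT"]),
               20, tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(w0_equivalent(2 * 115e-6, 2 * 6.3e-3),
               w0_equivalent(115e-6, 6.3e-3))

  expect_equal(mix_equal_volumes(7.7, 7.7), 7.7)
  expect_equal(mix_equal_volumes(5.7, 20.3), 8.9, tolerance = 0.01)
  m <- mix_equal_volumes(3, 11)
  expect_gt(m, 3); expect_lt(m, 11)
  # the literal printed shorthand lacks the equal-volume factor of two
  expect_equal(mix_equal_volumes(5.7, 20.3, convention = "printed"),
               mix_equal_volumes(5.7, 20.3) / 2)
})

test_that("the two core-shell trajectory models curve in opposite directions", {
  cs_shift <- core_shell(0.4, x_core = 4.7, x_shell = 3.5)
  cs_relax <- core_shell(0.4, x_core = 0.45, x_shell = 0.01)
  w0 <- seq(1, 20, length.out = 40)
  trA <- core_shell_trajectory("average_R1", w0, cs_shift, cs_relax)
  trB <- core_shell_trajectory("interpolate_T1", w0, cs_shift, cs_relax)
  curv <- function(tr) {
    # second differences of log10(T1) against shift along the trajectory
    d1 <- diff(log10(tr$t1_s)) / diff(tr$shift_ppm)
    diff(d1)
  }
  cA <- curv(trA); cB <- curv(trB)
  expect_true(all(cA > 0))
  expect_true(all(cB < 0))

  # identical core and shell values give a flat trajectory
  flat <- core_shell_trajectory("average_R1", w0,
                                core_shell(0.4, 4.2, 4.2),
                                core_shell(0.4, 0.1, 0.1))
  expect_equal(diff(range(flat$shift_ppm)), 0, tolerance = 1e-12)
  expect_equal(diff(range(flat$t1_s)), 0, tolerance = 1e-9)

  # at large w0 the shell fraction vanishes and both models reach the core
  big <- core_shell_trajectory("interpolate_T1", c(500, 1000), cs_shift, cs_relax)
  expect_equal(big$t1_s[2], 0.45, tolerance = 1e-2)
  expect_equal(big$shift_ppm[2], 4.7, tolerance = 1e-2)
})

test_that("solvent molarities recompute from density and molar mass", {
  expect_equal(solvent_molarity("D2O"), 55.2, tolerance = 0.001)
  expect_equal(solvent_molarity("H2O"), 55.4, tolerance = 0.001)
})
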