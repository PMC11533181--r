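#' Quadrupolar relaxation context
#'
#' The two constants that fix the deuterium relaxation curves: the
#' quadrupolar coupling constant chi = e^2 q Q / h (230 kHz for D2O) and the
#' deuterium resonance frequency (61.4 MHz on a 400 MHz proton instrument).
#' The asymmetry of the electric field gradient is treated as absorbed into
#' chi.
#'
#' @param chi_hz quadrupolar coupling constant in Hz (> 0).
#' @param nu_d_hz deuterium resonance frequency in Hz (> 0).
#' @return an object of class `quad_context`.
#' @export
quad_context <- function(chi_hz = 230e3, nu_d_hz = 61.4e6) {
  if (chi_hz <= 0 || nu_d_hz <= 0) stop_domain("chi_hz and nu_d_hz must be > 0")
  structure(list(chi_hz = chi_hz, nu_d_hz = nu_d_hz), class = "quad_context")
}

#' Lorentzian spectral density
#'
#' `J(nu) = 2 tau_c / (1 + (2 pi nu tau_c)^2)`.  At zero frequency (and in
#' the extreme narrowing limit `2 pi nu tau_c << 1` at any frequency) this
#' equals `2 tau_c`.
#'
#' @param nu_hz evaluation frequency in Hz.
#' @param tau_c_s rotational correlation time in seconds (>= 0).
#' @return spectral density in seconds.
#' @export
spectral_density <- function(nu_hz, tau_c_s) {
  if (any(tau_c_s < 0)) stop_domain("tau_c_s must be >= 0")
  2 * tau_c_s / (1 + (2 * pi * nu_hz * tau_c_s)^2)
}

#' Longitudinal quadrupolar relaxation rate of deuterium
#'
#' Spin-1 quadrupolar R1:
#' `R1 = (3 pi^2 / 40) chi^2 [2 J(nu_D) + 4 * 2 J(2 nu_D)]`
#' with the Lorentzian [spectral_density()].  In the extreme narrowing limit
#' every spectral density equals `2 tau_c` and the expression collapses to
#' the linear form `R1 = (3 pi^2 / 2) chi^2 tau_c` (`approx = "narrowing"`).
#' Because `J(nu) <= 2 tau_c`, the full expression never exceeds the
#' narrowing form.
#'
#' @param tau_c_s rotational correlation time(s) in seconds (>= 0).
#' @param ctx a [quad_context()].
#' @param approx `"full"` (default) or `"narrowing"`.
#' @return relaxation rate(s) R1 in 1/s.
#' @export
r1_quad <- function(tau_c_s, ctx = quad_context(), approx = c("full", "narrowing")) {
  approx <- match.arg(approx)
  if (any(tau_c_s < 0)) stop_domain("tau_c_s must be >= 0")
  pref <- 3 * pi^2 / 40 * ctx$chi_hz^2
  if (approx == "narrowing") return(pref * 20 * tau_c_s)
  pref * (2 * spectral_density(ctx$nu_d_hz, tau_c_s) +
          8 * spectral_density(2 * ctx$nu_d_hz, tau_c_s))
}

#' Transverse quadrupolar relaxation rate of deuterium
#'
#' Spin-1 quadrupolar R2:
#' `R2 = (3 pi^2 / 40) chi^2 [3 J(0) + 5 J(nu_D) + 2 J(2 nu_D)]`.
#' In the extreme narrowing limit this equals [r1_quad()] exactly (R1 = R2);
#' outside it the `J(0)` term makes R2 strictly larger.
#'
#' @inheritParams r1_quad
#' @return relaxation rate(s) R2 in 1/s.
#' @export
r2_quad <- function(tau_c_s, ctx = quad_context(), approx = c("full", "narrowing")) {
  approx <- match.arg(approx)
  if (any(tau_c_s < 0)) stop_domain("tau_c_s must be >= 0")
  pref <- 3 * pi^2 / 40 * ctx$chi_hz^2
  if (approx == "narrowing") return(pref * 20 * tau_c_s)
  pref * (3 * spectral_density(0, tau_c_s) +
          5 * spectral_density(ctx$nu_d_hz, tau_c_s) +
          2 * spectral_density(2 * ctx$nu_d_hz, tau_c_s))
}

# correlation time at which R1 peaks (T1 minimum) for this context
tau_c_at_t1_minimum <- function(ctx) {
  opt <- stats::optimize(function(lt) -r1_quad(10^lt, ctx),
                         interval = c(-12, -6), tol = 1e-12)
  10^opt$minimum
}

#' Correlation time from a measured T1
#'
#' Numerically inverts the full [r1_quad()] curve.  R1(tau_c) rises linearly
#' in the motional-narrowing regime, peaks near `2 pi nu_D tau_c ~ 0.62`
#' (the T1 minimum), and falls again for slow motion, so a measured T1 above
#' the minimum corresponds to two correlation times; the fast
#' (motional-narrowing side) branch is the default.  The round trip
#' `tau_c_from_t1(1 / r1_quad(tau))` recovers `tau` to better than 1e-9
#' relative on the chosen branch.
#'
#' @param t1_s measured longitudinal relaxation time(s), seconds (> 0).
#' @param ctx a [quad_context()].
#' @param branch `"fast"` (default) or `"slow"`.
#' @param both if `TRUE`, return a two-column matrix with both branches.
#' @return correlation time(s) in seconds, with attribute `narrowing`
#'   (logical: `2 pi nu_D tau_c < 0.03`) when a single branch is requested.
#' @export
tau_c_from_t1 <- function(t1_s, ctx = quad_context(),
                          branch = c("fast", "slow"), both = FALSE) {
  branch <- match.arg(branch)
  if (any(t1_s <= 0)) stop_domain("t1_s must be > 0")
  tstar <- tau_c_at_t1_minimum(ctx)
  r1max <- r1_quad(tstar, ctx)
  one <- function(t1, br) {
    target <- 1 / t1
    if (target > r1max * (1 + 1e-12))
      stop_domain("T1 = %g s is below the attainable minimum %g s for this context",
                  t1, 1 / r1max)
    f <- function(lt) r1_quad(10^lt, ctx) - target
    iv <- if (br == "fast") c(-30, log10(tstar)) else c(log10(tstar), 0)
    if (br == "slow" && f(0) > 0)
      stop_domain("no slow-branch solution below tau_c = 1 s for T1 = %g s", t1)
    # the root can sit arbitrarily close to the curve maximum
    if (f(iv[1]) * f(iv[2]) > 0) return(tstar)
    10^stats::uniroot(f, iv, tol = 1e-13)$root
  }
  if (both) {
    res <- cbind(fast = vapply(t1_s, one, numeric(1), br = "fast"),
                 slow = vapply(t1_s, one, numeric(1), br = "slow"))
    return(res)
  }
  out <- vapply(t1_s, one, numeric(1), br = branch)
  attr(out, "narrowing") <- 2 * pi * ctx$nu_d_hz * out < 0.03
  out
}

#' Combine correlation times of simultaneous processes
#'
#' When several independent processes all decorrelate the molecular
#' orientation, the decay rates add: the total correlation time is
#' `(sum 1/tau_i)^-1`, dominated by the shortest process.
#'
#' @param tau_list positive correlation times, seconds.
#' @return combined correlation time; never exceeds `min(tau_list)`.
#' @export
combine_tau_parallel <- function(tau_list) {
  tau_list <- as.numeric(tau_list)
  if (!length(tau_list) || any(tau_list <= 0)) stop_domain("all tau must be > 0")
  1 / sum(1 / tau_list)
}

#' Fast-exchange average of correlation times
#'
#' For molecules exchanging between environments on a time scale longer than
#' tau_c but shorter than T1, the relaxation *rates* average, which (in the
#' motional-narrowing regime where R1 is linear in tau_c) corresponds to a
#' population-weighted average of the correlation times: `sum a_i tau_i`.
#'
#' @param tau_list positive correlation times, seconds.
#' @param weights fractional populations, nonnegative, summing to 1.
#' @param ctx optional [quad_context()]; if supplied, a warning is issued
#'   when any tau falls outside the narrowing regime where the averaging
#'   rule is exact.
#' @return weighted-average correlation time, between `min` and `max` input.
#' @export
exchange_average_tau <- function(tau_list, weights, ctx = NULL) {
  tau_list <- as.numeric(tau_list); weights <- as.numeric(weights)
  if (length(tau_list) != length(weights)) stop_input("lengths must match")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop_domain("weights must be nonnegative and sum to 1")
  if (any(tau_list <= 0)) stop_domain("all tau must be > 0")
  if (!is.null(ctx) && any(2 * pi * ctx$nu_d_hz * tau_list >= 0.03))
    warning("some correlation times fall outside the motional-narrowing regime; the population average of tau_c is only approximate there",
            call. = FALSE)
  sum(weights * tau_list)
}

#' Core-shell geometry
#'
#' @param shell_thickness_nm interfacial shell thickness `t` in nm (>= 0).
#' @param x_core,x_shell property values of core and shell water.
#' @return an object of class `core_shell`.
#' @export
core_shell <- function(shell_thickness_nm, x_core, x_shell) {
  if (shell_thickness_nm < 0) stop_domain("shell thickness must be >= 0")
  structure(list(shell_thickness_nm = shell_thickness_nm,
                 x_core = x_core, x_shell = x_shell), class = "core_shell")
}

#' Core-shell weighted average of a property
#'
#' For a spherical water pool of radius `r` with an interfacial shell of
#' thickness `t`, the shell volume fraction is `1 - ((r - t)/r)^3` (all
#' shell when `t >= r`), and any property that averages over the two
#' populations presents as
#' `x_avg = f_shell x_shell + (1 - f_shell) x_core`.
#'
#' @param r_nm water-pool radius in nm (> 0).
#' @param cs a [core_shell()].
#' @return the averaged property value.
#' @export
core_shell_average <- function(r_nm, cs) {
  if (any(r_nm <= 0)) stop_domain("r_nm must be > 0")
  f_shell <- ifelse(r_nm > cs$shell_thickness_nm,
                    1 - ((r_nm - cs$shell_thickness_nm) / r_nm)^3, 1)
  f_shell * cs$x_shell + (1 - f_shell) * cs$x_core
}

#' Water-pool radius from the water loading
#'
#' Linear approximation for AOT-style reverse micelles,
#' `r (nm) = slope * w0 + intercept`: the interior volume scales with the
#' water count (`r^3`) while the interfacial area scales with the
#' surfactant count (`r^2`), making the radius proportional to their ratio
#' w0.  Default coefficients span pools from under 1 nm at w0 = 1 to
#' slightly over 10 nm at w0 = 60.
#'
#' @param w0 water loading (> 0).
#' @param slope,intercept coefficients of the linear form (nm per unit w0,
#'   and nm).
#' @return radius in nm.
#' @export
rm_radius <- function(w0, slope = 0.175, intercept = 0.45) {
  if (any(w0 <= 0)) stop_domain("w0 must be > 0")
  slope * w0 + intercept
}

#' Aggregation-model parameters
#'
#' Parameters of the reverse-micelle aggregation-number curve fitted to
#' digitized osmometry / velocimetry / ultracentrifugation data sets:
#' a plateau `a` at small w0, a linear regime with slope `m` and intercept
#' `b`, a quadratic regime with curvature `l` and intercept `c`, and a
#' crossover-sharpness parameter `k`.
#'
#' @param a plateau aggregation number (> 0).
#' @param m slope of the linear regime, surfactants per unit w0 (> 0).
#' @param b intercept of the linear regime.
#' @param l curvature of the quadratic regime.
#' @param c intercept of the quadratic regime.
#' @param k crossover sharpness (> 0).
#' @return an object of class `micelle_params`.
#' @export
micelle_params <- function(a = 15.1, m = 7.15, b = 0.259, l = 0.673,
                           c = -37.1, k = 0.174) {
  if (a <= 0 || m <= 0 || k <= 0) stop_domain("a, m and k must be > 0")
  structure(list(a = a, m = m, b = b, l = l, c = c, k = k),
            class = "micelle_params")
}

#' Aggregation number of an AOT reverse micelle
#'
#' Blends the three regimes of the aggregation-number curve -- constant
#' (`a`), linear (`m w0 + b`) and quadratic (`l w0^2 + c`) -- with a smooth
#' maximum (log-sum-exp), the form suggested by an addition of equilibrium
#' terms whose free energies scale as polynomials of w0:
#'
#' `nbar(w0) = (1/k) log( exp(k a) + exp(k (m w0 + b)) + exp(k (l w0^2 + c)) )`
#'
#' Small `k` softens the crossovers; each regime dominates where its
#' polynomial is largest.  The curve is nondecreasing in w0 and approaches
#' `a` at small w0, the linear form at intermediate w0, and the quadratic at
#' large w0.
#'
#' @param w0 water loading (> 0); vectorized.
#' @param p a [micelle_params()].
#' @return mean aggregation number nbar.
#' @export
aggregation_number <- function(w0, p = micelle_params()) {
  if (any(w0 <= 0)) stop_domain("w0 must be > 0")
  vapply(w0, function(w) {
    terms <- p$k * c(p$a, p$m * w + p$b, p$l * w^2 + p$c)
    mx <- max(terms)
    (mx + log(sum(exp(terms - mx)))) / p$k
  }, numeric(1))
}

#' Fit the aggregation-number curve to (w0, nbar) data
#'
#' Nonlinear least squares on the [aggregation_number()] form, requiring at
#' least 8 points so that all three regimes are constrained.
#'
#' @param points data frame with columns `w0` and `nbar`.
#' @param init a [micelle_params()] with starting values.
#' @return list with `params` (a [micelle_params()]) and `residual_norm`.
#' @export
fit_aggregation <- function(points, init = micelle_params()) {
  if (!all(c("w0", "nbar") %in% names(points)))
    stop_input("points must have columns w0 and nbar")
  if (nrow(points) < 8)
    stop_input("need at least 8 points spanning the three regimes")
  fit <- minpack.lm::nlsLM(
    nbar ~ aggregation_number(w0, micelle_params(a, m, b, l, cc, k)),
    data = data.frame(w0 = points$w0, nbar = points$nbar),
    start = list(a = init$a, m = init$m, b = init$b, l = init$l,
                 cc = init$c, k = init$k),
    lower = c(a = 1e-6, m = 1e-6, b = -Inf, l = -Inf, cc = -Inf, k = 1e-4),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  list(params = micelle_params(cf[["a"]], cf[["m"]], cf[["b"]], cf[["l"]],
                               cf[["cc"]], cf[["k"]]),
       residual_norm = sqrt(sum(stats::residuals(fit)^2)))
}

#' Molarity of the neat solvent from density and molar mass
#'
#' Recomputes the water concentration constants used in the water-loading
#' definition from tabulated densities at 293 K: 55.2 M for D2O and 55.4 M
#' for H2O.
#'
#' @param solvent `"D2O"` or `"H2O"`.
#' @return molarity in mol/L.
#' @export
solvent_molarity <- function(solvent = c("D2O", "H2O")) {
  solvent <- match.arg(solvent)
  # densities in g/mL at 293 K; molar masses in g/mol
  if (solvent == "D2O") 1.1053 * 1000 / 20.0276 else 0.99821 * 1000 / 18.0153
}

#' Common surfactant molar masses
#'
#' @return named vector of molar masses in g/mol (AOT = sodium
#'   bis(2-ethylhexyl) sulfosuccinate; Igepal = Igepal CO-520 average;
#'   CTAB = cetrimonium bromide).
#' @export
surfactant_molar_masses <- function() {
  c(AOT = 444.56, Igepal = 441.0, CTAB = 364.45)
}

#' Water loading from preparation quantities
#'
#' The general (guest-tolerant) definition of w0: moles of water-equivalent
#' in the aqueous volume over moles of surfactant,
#' `w0 = molarity * V_solution / n_surfactant`, with 55.2 mol/L for pure
#' D2O.  With guest molecules present, the aqueous solution volume is used,
#' so equal w0 implies equal expected pool size regardless of guest.
#'
#' @param aqueous_volume_l volume of the aqueous (D2O or stock) solution, L.
#' @param n_surfactant_mol moles of surfactant.
#' @param molarity_mol_l water molarity (default pure D2O, 55.2).
#' @return the dimensionless water loading.
#' @export
w0_equivalent <- function(aqueous_volume_l, n_surfactant_mol,
                          molarity_mol_l = 55.2) {
  if (any(aqueous_volume_l <= 0) || any(n_surfactant_mol <= 0))
    stop_domain("volume and surfactant amount must be > 0")
  molarity_mol_l * aqueous_volume_l / n_surfactant_mol
}

#' Water loading after mixing equal volumes of two preparations
#'
#' Mixing equal volumes of two reverse-micelle solutions with the same water
#' concentration leaves the water concentration fixed while the surfactant
#' concentrations average, so the mixture's water loading is the harmonic
#' mean `w0 = 2 (1/w0_1 + 1/w0_2)^-1` (`convention = "bookkeeping"`,
#' default; it reproduces measured dilution chains).  The widely quoted
#' shorthand `(1/w0_1 + 1/w0_2)^-1` is also exposed
#' (`convention = "printed"`).
#'
#' @param w0_1,w0_2 water loadings of the two parents (> 0).
#' @param convention `"bookkeeping"` or `"printed"`.
#' @return water loading of the equal-volume mixture; for the bookkeeping
#'   convention it always lies between the two inputs.
#' @export
mix_equal_volumes <- function(w0_1, w0_2,
                              convention = c("bookkeeping", "printed")) {
  convention <- match.arg(convention)
  if (any(w0_1 <= 0) || any(w0_2 <= 0)) stop_domain("w0 values must be > 0")
  h <- 1 / (1 / w0_1 + 1 / w0_2)
  if (convention == "bookkeeping") 2 * h else h
}

#' Core-shell trajectory models in (shift, T1) space
#'
#' Predicts the path traced by the water signal across a water-loading
#' series under a two-population core-shell picture.  Per w0, the pool
#' radius comes from [rm_radius()] and the shell volume fraction from the
#' core-shell geometry; the chemical shift always averages linearly over
#' populations.  Two models for the relaxation coordinate:
#'
#' * `"average_R1"`: relaxation rates (equivalently correlation times)
#'   average -- `tau_avg = f tau_shell + (1 - f) tau_core`, converted to T1
#'   through the full [r1_quad()] curve.  This is the physically motivated
#'   fast-exchange rule.
#' * `"interpolate_T1"`: the relaxation times themselves mix linearly,
#'   `T1 = f T1_shell + (1 - f) T1_core`.
#'
#' The two models produce opposite curvature signs of log10(T1) against
#' shift, which is what makes them experimentally distinguishable.
#'
#' @param model `"average_R1"` or `"interpolate_T1"`.
#' @param w0_list positive ascending water loadings.
#' @param cs_shift a [core_shell()] whose `x_core` / `x_shell` are chemical
#'   shifts in ppm.
#' @param cs_relax a [core_shell()] whose `x_core` / `x_shell` are T1 values
#'   in seconds.
#' @param ctx a [quad_context()] (used by the `average_R1` model).
#' @param radius_fun function mapping w0 to pool radius in nm.
#' @return data frame with columns `w0`, `r_nm`, `f_shell`, `shift_ppm`,
#'   `t1_s`.
#' @export
core_shell_trajectory <- function(model = c("average_R1", "interpolate_T1"),
                                  w0_list, cs_shift, cs_relax,
                                  ctx = quad_context(),
                                  radius_fun = rm_radius) {
  model <- match.arg(model)
  if (any(w0_list <= 0) || any(diff(w0_list) <= 0))
    stop_domain("w0_list must be positive and ascending")
  r <- radius_fun(w0_list)
  t <- cs_relax$shell_thickness_nm
  f_shell <- ifelse(r > t, 1 - ((r - t) / r)^3, 1)
  shift <- core_shell_average(r, cs_shift)
  if (model == "interpolate_T1") {
    t1 <- f_shell * cs_relax$x_shell + (1 - f_shell) * cs_relax$x_core
  } else {
    tau_core <- tau_c_from_t1(cs_relax$x_core, ctx)
    tau_shell <- tau_c_from_t1(cs_relax$x_shell, ctx)
    tau_avg <- f_shell * as.numeric(tau_shell) + (1 - f_shell) * as.numeric(tau_core)
    t1 <- 1 / r1_quad(tau_avg, ctx)
  }
  data.frame(w0 = w0_list, r_nm = r, f_shell = f_shell,
             shift_ppm = shift, t1_s = t1)
}
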