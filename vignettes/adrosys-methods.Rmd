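---
title: "Methods: relaxation-ordered deuterium NMR of confined water"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relaxation-ordered deuterium NMR of confined water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrosys)
```

## The measurement and the signal model

Water confined to nanometre pockets — here modelled by reverse micelles
(RMs), surfactant-stabilized nanodroplets of D2O in an apolar dispersant —
rotates more slowly and hydrogen-bonds differently from bulk water.
Deuterium NMR reads both out at once: the longitudinal relaxation time T1
reports rotational mobility (through the quadrupolar mechanism), and the
chemical shift reports the average hydrogen-bonding environment.  The
ADROSYS experiment (Automated Deuterium Relaxation-Ordered SpectroscopY)
correlates the two in a 2D map: chemical shift along the direct dimension,
a *distribution* of T1 along the indirect one.

The raw data are inversion-recovery FID series.  The package's generative
model, which the synthetic-data module implements and the inversion engine
assumes, is

$$ d(\tau_i, t_k) \;=\; \sum_j A_j\,\bigl(1 - 2 f_j e^{-\tau_i/T_{1,j}}\bigr)\,
   e^{\,2\pi i \nu_j t_k - t_k / T^{*}_{2,j}} \;+\; \varepsilon, $$

with recovery delays $\tau_i$, acquisition times $t_k$, inversion
efficiency $f_j \in (0,1]$ (1 for an ideal $\pi$ pulse), offsets $\nu_j$
determined by each component's chemical shift, and circular complex
Gaussian noise $\varepsilon$.  The model is linear in the amplitudes; a
mandatory seed makes every simulated dataset bit-reproducible.

## Direct-dimension processing and referencing

`process_direct()` applies exponential apodization (default 1 Hz, a
conventional compromise between sensitivity and resolution — the method
itself does not prescribe one), zero filling (default ×2), FFT with the
customary half-weighting of the first point, and zero-order phasing.
Phasing minimizes the integral of negative excursions of the real part of
the longest-delay (fully recovered) row; because that cost is exactly zero
on a plateau of a few degrees for clean spectra, an amplitude-weighted
mean-phase estimator — exactly equivariant under rotations of the input —
pins the answer inside the plateau.  First-order phase defaults to zero:
short synthetic FIDs need none, and it is exposed for real data.

Deuterium spectra cannot be referenced against internal TMS directly, so
the ppm axis is transferred from a companion proton spectrum: the deuterium
frequency assigned 0 ppm is the TMS proton frequency times the
gyromagnetic-ratio constant 0.15350609, and
$\mathrm{ppm} = 10^6 (f - f_0)/f_0$.  Without a proton reference the
package raises a referencing error; a carrier-as-reference fallback is
available and warns.

The per-point noise level is estimated as 1.4826 × the median absolute
deviation of the real part over the outer 10% of the axis on each side
(assumed signal-free), pooled over rows.  This feeds both channel masking
and the regularization below.

## The inversion engine

Recovering a distribution of relaxation times from multiexponential data is
an ill-posed inverse Laplace transform.  Per frequency channel the model is
$d = K x + \varepsilon$ with kernel
$K_{ij} = 1 - 2 f e^{-\tau_i / T_{1,j}}$ on a log-spaced T1 grid (default
100 points, $10^{-3.5}$–$10^{1}$ s — wide enough for bulk D2O at 0.45 s and
for the millisecond T1 of strongly confined pools), and the estimate solves

$$ \min_{x \ge 0}\; \lVert K x - d \rVert^2 + \alpha \lVert x \rVert^2 . $$

The regularization parameter is chosen by the Butler–Reeds–Dawson (BRD)
rule: with the dual vector $c = (d - Kx)/\alpha$, iterate
$\alpha \leftarrow \sigma \sqrt{n} / \lVert c \rVert$ to its fixed point,
at which the residual approximates $\sigma\sqrt{n}$ (the discrepancy
principle).  Numerical choices: the nonnegative subproblem is solved by
active-set NNLS on the stacked Tikhonov system (the minimum-norm
nonnegative solution in degenerate cases); the plain fixed-point iteration
converges only sublinearly, so each step is Steffensen-accelerated (same
fixed point, two inner solves per step); convergence is declared when
$\alpha$ moves by less than `alpha_tol` (default 1e-3) relatively, with at
most 50 iterations; and when the data can be fit far below the stated
noise level the fixed point degenerates to $\alpha \to 0$ (pure NNLS),
detected by an underflow floor and treated as converged.

For efficiency the kernel is compressed first: a truncated SVD
$K \approx U_r S_r V_r^\top$ replaces the problem by the equivalent
$S_r V_r^\top x \approx U_r^\top d$.  The discarded spectral mass is at
most $\sigma_{r+1}$, and since $U_r$ is orthonormal the noise level is
unchanged.  The default rank keeps singular values down to $10^{-6}$ of
the largest, capped at 16 — inversion-recovery kernels with 16 delays have
numerical rank well below that cap.

The **1.5D map** applies this independently per retained frequency channel
(channels with peak signal below 5σ are exact zero columns; the
per-channel α is recorded).  Independence is the simplest reading of the
"1.5D" construction; smoothness coupling across ppm would be an extension.
The **2D T1–T2 mode** compresses an inversion-recovery kernel and a decay
kernel, projects the data matrix into the compressed tensor space and
solves the Kronecker-structured problem the same way.  Mass on the
T1 = T2 diagonal ([`diagonality()`]) is the fingerprint of motional
narrowing.

**Resolution honesty.** Two relaxation times within a factor of ~2 need
not resolve into separate peaks at these noise levels; the tests therefore
check amplitude-weighted *centroids* (to 0.05 ppm and 0.15 log10 units on
clean two-component data), never peak splitting.

## Quadrupolar relaxation and correlation times

For spin-1 deuterium the quadrupolar mechanism dominates.  With the
Lorentzian spectral density $J(\nu) = 2\tau_c / (1 + (2\pi\nu\tau_c)^2)$:

$$ R_1 = \tfrac{3\pi^2}{40}\chi^2\,[\,2J(\nu_D) + 8J(2\nu_D)\,], \qquad
   R_2 = \tfrac{3\pi^2}{40}\chi^2\,[\,3J(0) + 5J(\nu_D) + 2J(2\nu_D)\,], $$

with $\chi$ = 230 kHz for D2O and $\nu_D$ = 61.4 MHz by default (deuterium
on a 400 MHz-proton instrument); the field-gradient asymmetry is absorbed
into $\chi$.  In the extreme narrowing limit
($2\pi\nu_D\tau_c \ll 1$) every $J = 2\tau_c$ and both collapse to the
linear form $R_1 = R_2 = \tfrac{3\pi^2}{2}\chi^2\tau_c$; outside it
$R_2 > R_1$, and the full $R_1$ never exceeds the linear form (since
$J(\nu) \le 2\tau_c$).  `tau_c_from_t1()` inverts the full curve
numerically; because $R_1(\tau_c)$ peaks near
$2\pi\nu_D\tau_c \approx 0.62$ (the T1 minimum, ~1.73 ms here), a measured
T1 maps to a fast and a slow branch, with the fast (narrowing-side) branch
the default — appropriate for the overwhelming majority of RM samples.
The `narrowing` attribute flags $2\pi\nu_D\tau_c < 0.03$.

Multiple motions combine as parallel decays of the orientation correlation
function, $\tau_c^{-1} = \sum_i \tau_{c,i}^{-1}$ (the fastest process
dominates), while fast exchange between environments averages the rates —
equivalently, within the narrowing regime, the correlation times:
$\tau_c = \sum_i a_i \tau_{c,i}$.

## Reverse-micelle structural models

*Radius.* $r\,(\mathrm{nm}) = 0.175\,w_0 + 0.45$: interior volume tracks
the water count ($\propto r^3$), interfacial area the surfactant count
($\propto r^2$), so $r \propto w_0$; the coefficients place pools just
under 1 nm at $w_0 = 1$ and slightly over 10 nm at $w_0 = 60$.

*Aggregation number.* The curve compiled from osmometry (constant regime),
velocimetry and ultracentrifugation (linear, then quadratic regimes) is
blended as a log-sum-exp soft maximum,

$$ \bar n(w_0) = \tfrac{1}{k}\,\ln\!\bigl(e^{k a} + e^{k (m w_0 + b)}
   + e^{k (l w_0^2 + c)}\bigr), $$

with fitted constants $a = 15.1$, $m = 7.15$, $b = 0.259$, $l = 0.673$,
$c = -37.1$, $k = 0.174$.  The form realizes an addition of
equilibrium-like terms whose free energies scale as polynomials of $w_0$;
each regime dominates where its polynomial is largest, and $k$ sets the
crossover softness.  The significant figures of these digitization-derived
constants reproduce the curve rather than claim accuracy.  A caveat worth
recording: per-micelle solution masses computed from this curve at
$w_0 \approx 3$ sit at the crossover, where the curve has already left the
plateau; quoting plateau-based masses there understates the blended value
by roughly a quarter.

*Water-loading algebra.* $w_0 = 55.2\,\mathrm{M} \times V_\mathrm{aq} /
n_\mathrm{surf}$ (the "$w_0$-equivalent" definition, guest-tolerant); the
molarities 55.2 M (D2O) and 55.4 M (H2O) recompute from 293 K densities
and molar masses.  Mixing equal volumes of two preparations keeps the
water concentration fixed while surfactant concentrations average, giving
the harmonic-mean rule $w_0 = 2(1/w_{0,1} + 1/w_{0,2})^{-1}$; this
bookkeeping form reproduces measured dilution chains
(e.g. mix(5.7, 20.3) = 8.90), whereas the often-quoted shorthand without
the factor 2 does not — both are exposed, the bookkeeping form is the
default.

*Core–shell trajectories.* Treating the pool as a bulk-like core plus an
interfacial shell of thickness $t$, the shell volume fraction is
$f = 1 - ((r - t)/r)^3$ and any two-population property averages as
$x_\mathrm{avg} = f x_\mathrm{shell} + (1 - f) x_\mathrm{core}$.  Two
models for the relaxation coordinate: averaging *rates* (equivalently
$\tau_c$; the physically motivated fast-exchange rule) versus averaging
*times* (T1 directly).  Because shift is linear in $f$ in both, the
curvature of $\log_{10} T_1$ against shift has the sign of
$\partial^2_f(-\log \bar R_1) = (\Delta R_1)^2/\bar R_1^2 > 0$ for the
rate model and $\partial^2_f \log \bar T_1 = -(\Delta T_1)^2/\bar T_1^2 <
0$ for the time model — opposite for any parameter choice.  Strongly
confined AOT-style data curve like the time-averaging model, which is the
package's quantitative expression of why a plain rate-averaging core–shell
picture fails at low $w_0$.

## The synthetic water-loading series

`make_rm_series()` emulates how a $w_0$ series moves through the map: both
T1 and shift follow
$x(w_0) = x_\mathrm{conf} + (x_\mathrm{bulk} - x_\mathrm{conf})
(1 - e^{-w_0/w_0^\ast})$ — the simplest monotone family with the observed
sharp rise and gentle saturation; no published fit of this trend exists,
so the family is a modelling choice.  Defaults: bulk T1 0.45 s, confined
T1 2 ms, shifts 3.5 → 4.7 ppm, crossover $w_0^\ast = 3.5$ (the region
where measured trends change slope), $T_2^\ast = \min(0.3\,T_1, 0.1\,
\mathrm{s})$ so small pools also show broader lines, and noise set for
SNR ≈ 100 — chosen once to keep recovery tests stable, since no
quantitative SNR is published.  The generator reproduces the statistical
structure the analysis assumes (multi-exponential recovery, Lorentzian
lines, iid complex noise); it does *not* emulate phase cycling, pulse
imperfections beyond the scalar $f$, radiation damping, field drift,
baseline artifacts or temperature gradients — so green recovery tests
validate the processing and inversion chain, not robustness to every
instrumental pathology.

## Colormaps

`w0_colormap()` encodes water loading perceptually: all colors share one
lightness (L* = 45), sitting on a constant-chroma (55) arc from 30° to
330° in the CIE Lab (a*, b*) plane with arc position linear in $w_0$, so
equal steps in water loading are equal perceptual distances (ΔE).  The
published constraints fix the construction, not the constants; these
defaults are documented choices.

## Problem sizes, degenerate inputs, limitations

The test suite runs the full chain at reduced sizes — 256–512 direct
points (4096 nominal), 14–16 delays, grids of 30–80 points — which
preserves every structural property while keeping the suite fast; one
generator-contract test exercises the nominal 16 × 4096 size.  Degenerate
inputs are defined: zero data invert to zero maps; all-zero spectra cannot
be phased (input error); T1 below the attainable minimum of the relaxation
curve is a domain error reporting that minimum; empty ppm regions are
skipped with a warning; masked channels are exact zeros, not small values.

Known limitations: no uncertainty bands on distributions (single-point BRD
estimates); no maximum-entropy or Monte-Carlo alternatives; per-channel
independence means no cross-ppm smoothing; vendor binary formats are out
of scope (the documented CSV+JSON dialect plus an extension point); and
the theory layer deliberately uses one fixed $\chi$ although the
quadrupolar coupling varies slightly with hydrogen-bond geometry, so
extracted $\tau_c$ values are comparative rather than absolute.
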