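# adrosys

Processing and modelling toolkit for two-dimensional **relaxation-ordered
deuterium NMR spectroscopy** (ADROSYS) of confined water.

Water trapped in nanometre-scale pockets — reverse micelles, porous
materials, macromolecular cavities — rotates more slowly and hydrogen-bonds
differently from bulk water. Deuterium NMR captures both effects at once:
the longitudinal relaxation time T1 reads out rotational mobility through
the quadrupolar mechanism, while the chemical shift reads out the average
hydrogen-bonding environment. ADROSYS correlates the two in a 2D spectrum —
chemical shift along the direct dimension, a *distribution* of T1 along the
indirect one — so that a series of samples (e.g. reverse micelles of
increasing water loading w0) traces a diagnostic path through the
(shift, log T1) plane.

The package is aimed at NMR spectroscopists and biophysical chemists who
want to process inversion-recovery series into such maps, or to interpret
them with the standard quadrupolar-relaxation and reverse-micelle models.
It covers:

* **Data model and I/O** — a documented plain-text dataset dialect
  (`meta.json` + `data.csv`), plus a packaged table of rotational
  correlation times for 40 reverse-micelle samples across 7
  surfactant/dispersant/guest series (`table1_fixture()`).
* **Synthetic data** — multi-component inversion-recovery FID series,
  water-loading trend series with ground truth, and T1–T2 relaxometry data,
  all seeded and bit-reproducible (`make_fid_series()`, `make_rm_series()`,
  `make_t1t2_data()`).
* **Spectral processing** — apodization, zero-fill, FFT, automatic
  zero-order phasing, and chemical-shift referencing of the deuterium axis
  from a companion proton TMS frequency via the gyromagnetic ratio
  (`process_direct()`, `reference_ppm()`).
* **The inversion engine** — the regularized inverse Laplace transform:
  inversion-recovery/decay kernels, truncated-SVD basis compression,
  nonnegative Tikhonov inversion with Butler–Reeds–Dawson (BRD) selection
  of the regularization parameter from the noise level, a per-channel
  ("1.5D") map builder and a 2D T1–T2 solver (`brd_solve()`, `ilt_1p5d()`,
  `ilt_2d_t1t2()`).
* **Theory layer** — spin-1 quadrupolar R1/R2 with Lorentzian spectral
  densities, correlation-time extraction `tau_c_from_t1()`, fast-exchange
  averaging, core–shell averaging and trajectory models, water-pool radius,
  aggregation number, and water-loading algebra (`r1_quad()`,
  `aggregation_number()`, `w0_equivalent()`, `mix_equal_volumes()`).
* **Application layer** — peak summarization of maps, a T1–T2 diagonality
  metric, perceptually uniform (CIE Lab) water-loading colormaps, a
  one-call pipeline, and a thin command-line front end
  (`summarize_peaks()`, `diagonality()`, `w0_colormap()`,
  `run_pipeline()`; `inst/cli/adrosys.R`).

## The model at the core

Each frequency channel of the processed spectrum supplies a recovery trace
`d`, modelled as `d = K x + noise` with kernel
`K[i, j] = 1 − 2 f exp(−τ_i / T1_j)` over a log-spaced T1 grid. The
distribution solves

```
min over x ≥ 0 of  || K x − d ||² + α || x ||²
```

with α set by the BRD fixed point `α = σ √n / ||c||`, `c = (d − K x)/α`, so
that the residual matches the noise (discrepancy principle). Kernels are
compressed by truncated SVD before inversion. On the theory side, deuterium
relaxation follows the spin-1 quadrupolar expressions

```
R1 = (3π²/40) χ² [ 2 J(ν_D) + 8 J(2ν_D) ],    J(ν) = 2τc / (1 + (2πν τc)²)
R2 = (3π²/40) χ² [ 3 J(0) + 5 J(ν_D) + 2 J(2ν_D) ]
```

with χ = 230 kHz and ν_D = 61.4 MHz by default; in the extreme narrowing
limit both reduce to `R1 = R2 = (3π²/2) χ² τc`, which links T1 directly to
the rotational correlation time.

## Worked example

Simulate a reverse-micelle sample at w0 = 5.7, run the full pipeline, and
interpret the peak:

```r
library(adrosys)

acq   <- default_acq(n_points = 512)
trend <- rm_trend_params()                       # AOT-like w0 trend
sims  <- make_rm_series(trend, w0_list = c(1, 5.7, 20.3), acq = acq, seed = 7)
write_dataset(sims[[2]]$series, "demo/w0_5.7")

res <- run_pipeline("demo/w0_5.7", config = list(plot = FALSE))
res$peaks
#>   shift_centroid_ppm logt1_centroid width_ppm width_logt1  mass
#> 1              4.468        -0.4392    0.1053      0.1519 418.2

tc <- tau_c_from_t1(10^res$peaks$logt1_centroid[1])
as.numeric(tc) * 1e12                            # 3.51 ps, narrowing regime
```

The single peak sits at 4.468 ppm with a log10(T1) centroid of −0.439
(T1 ≈ 0.364 s), against generator truth of 4.465 ppm and T1 = 0.362 s — the
inversion recovers the generating values well within the map's resolution
(widths 0.105 ppm and 0.152 decades are the FWHM of the recovered peak).
Inverting the relaxation curve gives τc ≈ 3.5 ps: faster than strongly
confined water (hundreds to thousands of ps at w0 ≈ 1) but still slower
than bulk D2O, as expected for a mid-size pool. On the structural side,
`aggregation_number(5.7)` ≈ 41.1 surfactants per micelle, i.e. ≈ 234 water
molecules in the pool.

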