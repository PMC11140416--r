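# gletraj

Generalized-Langevin analysis and classification of 2-D cell trajectories.

## The problem

Motile micro-organisms can be told apart by *how they move*. For strongly
confined *Chlamydomonas reinhardtii*, two flagellar-beating phenotypes
("synchro": synchronous breaststroke; "wobbler": asynchronous paddling)
produce different trajectory statistics even though both look like noisy
persistent walks. `gletraj` implements a pipeline that classifies such
cells from the cell-center trajectory alone, for anyone who records
uniformly sampled 2-D tracks (time step of order milliseconds, speeds of
order 10–100 μm/s) and wants a physically interpretable feature set
instead of ad-hoc track statistics.

## The model

Each trajectory component is described by the generalized Langevin
equation (GLE)

    x''(t) = - ∫₀ᵗ Γ(t−t') x'(t') dt' + F_R(t),

with a Gaussian random force, ⟨F_R(0)F_R(t)⟩ = B Γ(t), B = ⟨v²⟩. The
effective memory kernel is parameterized as

    Γ(t) = 2a δ(t) + b e^(−t/τ) cos(Ωt),

a delta friction peak plus a damped oscillation at the flagellar beating
frequency. The package

* estimates VACF and MSD from trajectories (with localization-noise
  diagnostics),
* extracts Γ(t) by discrete Volterra inversion of the VACF,
* fits (a, b, τ, Ω) to the extracted kernel — or fits the discretized
  noisy forward model, which additionally estimates the localization-noise
  width σ_loc and removes finite-sampling bias,
* simulates trajectories with *exactly* known kernels via a Markovian
  embedding (two harmonically coupled degrees of freedom, exact
  discrete-time Gaussian propagation) — the built-in ground-truth factory,
* classifies cells by X-means clustering of the median-rescaled parameter
  vectors (a, b, τ, Ω, B), run once per pair of cells as initial centers
  and reduced to the modal partition.

## Worked example

Simulate one cell with a known kernel, fit it, and inspect the result:

```r
library(gletraj)

p  <- kernel_params(a = 5, b = 2000, tau = 0.5, omega = 120)  # 1/s, 1/s^2, s, 1/s
e  <- kernel_to_embedding(p, B = 1000)                        # B in um^2/s^2
tr <- simulate_embedding(e, n_steps = 1e5, dt = 0.002, seed = 55)

fit <- gle_fit(tr, smooth_window = 1)
fit
#> GLE fit ('kernel' route) for cell 'sim' (100001 positions, dt = 0.002 s)
#> Cell 'sim':
#>   a = 3.2551 1/s, b = 1909.6 1/s^2, tau = 0.39364 s, Omega = 120.61 1/s
#>   B = 997.24 um^2/s^2
```

b, Ω and B are recovered to a few percent. The printed `a` sits about a
third below the generating value 5/s: finite-step velocities smear the
delta peak of the kernel over the first two lags, an intrinsic property of
the direct extraction route (identical for every cell, so classification
is unaffected). The discretized-VACF route models the finite step and the
localization noise explicitly and recovers all six parameters:

```r
trn  <- add_localization_noise(tr, 0.02, seed = 7)
fit2 <- gle_fit(trn, method = "vacf", smooth_window = 1)
round(coef(fit2), 4)
#>         a         b       tau     omega         B sigma_loc 
#>    5.0703 1852.2381    0.4834  120.5357  996.8082    0.0201
```

`plot(fit)` draws MSD, VACF and extracted kernel with the model curves;
`predict(fit, "msd")` etc. evaluate the fitted forward model;
`simulate(fit)` generates new trajectories from the fitted parameters.

A full cohort round trip (simulate two populations, analyze, classify):

```r
dir <- tempfile()
run_simulate(demo_population_specs(n_cells = c(10, 10), seed = 1), dir)
rep <- run_analyze(dir, file.path(dir, "out"))
rep$clustering$k                 #> 2
rep$accuracy_vs_ground_truth     #> 1
```

A command-line wrapper with `analyze`, `simulate` and `demo` subcommands
is installed at `inst/cli/gletraj`.

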