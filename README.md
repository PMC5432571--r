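# glyrblock

Voltage-dependent open-channel block analysis for glycine-receptor (GlyR)
chloride channels, built around the pharmacology of the anionic blocker
niflumic acid (NFA).

GlyRs are pentameric Cys-loop channels whose pore is lined by five TM2
helices. An anionic open-channel blocker entering the pore from the outside
senses part of the transmembrane field, so its potency is voltage dependent.
glyrblock is for electrophysiologists and modellers who want to simulate,
fit and interpret that behaviour end to end:

* **Kinetic schemes** of agonist gating plus one- or two-site open-channel
  block, with analytic equilibrium solutions (the oracle for everything
  else).
* **A synthetic patch-clamp generator** (whole-cell voltage ramps, long
  drug-application sweeps, single-channel Gillespie simulation) with known
  ground truth, recording noise, cell variability and quality metadata.
* **Trace analysis**: percent inhibition, fraction-remaining-vs-voltage from
  ramp pairs, rectification indices, cell quality filtering.
* **Dose-response fitting**: Hill inhibition/activation fits, per-voltage
  IC50/nH tables, a stoichiometry heuristic.
* **Woodhull analysis**: the fractional electrical distance of the blocking
  site from IC50(V).
* **Single-channel analysis**: idealization, dwell-time mixtures, burst and
  flicker-block quantification, kon/koff estimation.
* **A Monte-Carlo energy-minimization module** that pulls the flexible NFA
  anion through pentameric TM2 pore models and maps interaction-energy
  profiles along the pore axis.

## The model in brief

Block equilibrium follows the Woodhull relation for a charged blocker at
fractional electrical distance δ from the external membrane surface,

    Kd(V) = Kd(0) · exp(−δ F V / R T),

dose-response curves follow the Hill equation

    I = Imax / (1 + ([B]/IC50)^nH),

and δ is estimated from the slope of log IC50 against membrane potential
(δ = −slope·RT/F, RT/F = 25.43 mV at 295.15 K). Fitted objects are tidy:
`tidy()`, `glance()` and `autoplot()` methods are provided throughout.

## Worked example

Simulate a cohort of four cells expressing a deep-site (alpha2-like)
receptor with a single blocking site, then recover the fractional electrical
distance through the full analysis chain:

```r
library(glyrblock)

res <- run_pipeline(list(
  subtype = "alpha2", n_sites = 1, n_cells = 4,
  conc_grid = c(3, 10, 30, 100, 300, 1000),          # uM NFA
  voltages = c(-80, -70, -50, -30, 30, 50, 70, 80),  # mV
  seed = 1
))
res$summary
#> # A tibble: 1 × 10
#>   subtype glycine_uM delta delta_sem n_cells delta_truth n_sites_truth
#>   <chr>        <dbl> <dbl>     <dbl>   <int>       <dbl>         <int>
#> 1 alpha2          30 0.667   0.00926       4        0.65             1
#>   n_sites_inferred mean_nH  seed
#>              <int>   <dbl> <dbl>
#> 1                1    1.01     1

res$per_cell
#> # A tibble: 4 × 5
#>   cell  delta delta_se IC50_0 n_voltages
#>   <chr> <dbl>    <dbl>  <dbl>      <int>
#> 1 cell1 0.688  0.00454   45.9          8
#> 2 cell2 0.663  0.00205   41.9          8
#> 3 cell3 0.644  0.00277   42.0          8
#> 4 cell4 0.673  0.00187   44.5          8
```

The generator's ground truth was δ = 0.65 with IC50(0) = 40 µM: with 5%
per-sweep amplitude noise the pipeline recovers δ = 0.667 ± 0.009 from
per-cell Woodhull fits, classifies the block as single-molecule
(mean nH ≈ 1.01), and the per-cell IC50(0) estimates sit a few percent
above the microscopic Kd(0), as expected from the resting/open balance of
the gating (see the methods vignette).

The closed-form two-point estimator works directly on published-style
numbers — an IC50 of 166 µM at −80 mV falling to 9 µM at +80 mV gives

```r
two_point_delta(166, -80, 9, 80)
#> [1] 0.4633391
fit_woodhull(tibble::tibble(voltage_mV = c(-80, 80), IC50 = c(166, 9)))
#> <woodhull_fit> delta = 0.4633, IC50(0) = 38.65 uM (2 voltages, loglinear)
```

i.e. a site ~46% into the field with a zero-voltage IC50 near 39 µM.

For the structural side, `build_nfa()` builds the energy-minimized NFA
anion, `build_pore("alpha1")` / `build_pore("alpha2")` build idealized
pentameric TM2 pores (differing only in the glycine/alanine ring at level
2′), and `pull_profile()` maps the MC-minimized interaction energy of the
ligand along the pore axis:

```r
lig  <- build_nfa()
pore <- build_pore("alpha2")
prof <- pull_profile(pore, lig, z_from = level_z(pore, 2),
                     z_to = level_z(pore, 6), step = 1,
                     stop_after = 25, seed = 1)
autoplot(prof)
```

## Documentation

The methods vignette (`vignettes/glyrblock-methods.Rmd`) documents the
kinetic model and its assumptions, the generator's noise model and what it
does and does not emulate, the fitting conventions, the pore-scanning force
field and search protocol, numerical choices, and known limitations.
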