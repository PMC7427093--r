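# ddstate

Oligomeric state and self-association kinetics of small proteins —
typically the ~10 kDa death domain (DD) of a single-pass receptor such
as the p75 neurotrophin receptor — inferred from solution-NMR
observables. The package is for structural biologists and NMR
spectroscopists who have measured rotational correlation times,
pulsed-field-gradient diffusion data, relaxation decay series, gel
densitometry time courses or chemical-shift tables and want the
downstream quantitative inference done reproducibly.

## What it computes

**The core inference** is the hydrodynamic chain. A rotational
correlation time τc or translational diffusion coefficient D maps to
the radius of the equivalent sphere,

    r_h = (3 k_B T τc / 4πη)^(1/3)          (Stokes–Einstein–Debye)
    r_h = k_B T / (6πη D)                   (Stokes–Einstein)

and the radius to an effective molecular weight of a compact globular
protein through a calibrated power law MW = 1.91 · r_h^2.85 (kDa, nm).
Comparing the predicted mass with the sequence mass calls the oligomer
number n (1 = monomer, 2 = dimer, ≥3 = higher-order).

Around that core:

* **TRACT relaxation analysis** — per-residue rotational correlation
  times from TROSY/anti-TROSY decay pairs via the dipole–CSA
  cross-correlation rate η_xy = (R_β − R_α)/2, inverted through the
  rigid-rotor spectral density; ensemble averages over a residue
  window and monomer/dimer difference estimates.
* **Pulsed-gradient diffusion** — Stejskal–Tanner fits
  I(g) = I₀ exp(−D(γgδ)²(Δ−δ/3)) and extrapolation of dilution series
  to the infinite-dilution coefficient D₀.
* **Kinetics** — first-order deamidation fits (rate and half-life) and
  closed-form irreversible second-order dimerization
  [M]t = [M]₀/(1+[M]₀kt) in mole-per-mole-lipid units, fed by gel
  densitometry; plus the membrane lipid-to-protein-ratio estimator
  LPR = N_lip/N_prot from cell geometry.
* **Chemical shifts** — generalized chemical-shift perturbations
  √(ΔδH² + (0.2 ΔδN)²) with threshold classification, secondary Cα
  shifts against a shipped random-coil table, and two-state population
  quantification by Lorentzian deconvolution of 1D projections.
* **Seeded synthetic-data generators** for every input type, so the
  entire pipeline is testable without instrument data.

All user-facing functions take data frames and return tibbles, fitted
objects support `tidy()`/`glance()` and `autoplot()`, and CSV/TSV,
Sparky-style peak-list and FASTA readers are included.

## Worked example

```r
library(ddstate)
library(dplyr)

tbl <- tibble::tibble(
  construct = c("rat DD", "cross-linked"),
  tau_c_ns  = c(6.0, 10.3),
  D_m2s     = c(154e-12, 123e-12))
oligomer_state(tbl, conditions(303.15), mw_monomer = 10.6) |>
  select(construct, rh_rot, mw_rot, mw_trans, n_oligomer, label)
#> # A tibble: 2 × 6
#>   construct    rh_rot mw_rot mw_trans n_oligomer label
#>   <chr>         <dbl>  <dbl>    <dbl>      <int> <chr>
#> 1 rat DD         1.96   13.0     10.3          1 monomer
#> 2 cross-linked   2.35   21.7     19.6          2 dimer
```

At 30 °C in water, a 6.0 ns correlation time corresponds to a 1.96 nm
sphere and ~13 kDa — the mass of one domain, so the construct is
monomeric; the 10.3 ns/123×10⁻¹² m² s⁻¹ pair predicts ~20–22 kDa,
twice the 10.6 kDa monomer, a dimer.

```r
lpr_ecoli()
#> # A tibble: 1 × 4
#>       n_lip n_prot   lpr lpr_1sf
#>       <dbl>  <dbl> <dbl>   <dbl>
#> 1 13333333. 69813.  191.     200
```

An induced E. coli membrane holds ~1.3×10⁷ lipids and ~7×10⁴ receptor
molecules per cell: a lipid-to-protein ratio of about 200:1.

```r
pk <- gen_deamidation_series(k_days = 0.1406, noise_sd = 0.02, seed = 1)
fit_first_order(population_course_to_kinetics(pk, 352, state = "asn"))
#> <dd_kinetic_fit> first-order: k = 0.1393 +/- 0.0009 per days, t1/2 = 4.98 days
```

A synthetic three-week peak-list course generated at
k = 0.1406 day⁻¹ (half-life ≈ 5 days) is recovered by the
peak-extraction + log-linear fitting pipeline to within 1 %.

See the vignette (`vignettes/death-domain-analyses.Rmd`) for the models,
their assumptions and the numerical choices.

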