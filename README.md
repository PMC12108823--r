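# dielspec

Tools for modelling the complex relative permittivity of lung tissue as a
function of ventilator tidal volume, in the 100 MHz–1 GHz band measured by
open-ended coaxial probes. The package is aimed at bioimpedance and
bioelectromagnetics researchers who need a runnable, testable version of
this analysis chain: forward dielectric relaxation models, a global fitter,
a synthetic measurement generator, and nonparametric group comparison at the
ISM frequencies (433 / 915 MHz).

## Models

Classical first-order Cole–Cole relaxation with static conduction:

    ε*(ω) = ε∞ + Δε / (1 + (jωτ)^(1−α)) + σs / (jωε0),   ω = 2πf

and an augmented ("improved") variant adding one purely real linear term
that captures the extra frequency dependence air content induces in
ventilated lung:

    ε*(ω) = ε∞ + Aω + Δε / (1 + (jωτ)^(1−α)) + σs / (jωε0)

with A of order −10⁻⁹ s/rad. Parameters are estimated by bounded simulated
annealing with Nelder–Mead polish, minimising the relative average fitting
error

    Err̄ = 100/N · Σᵢ √[ ((Re ε₁−Re ε₂)/Re ε₂)² + ((Im ε₁−Im ε₂)/Im ε₂)² ] %

and reporting R² separately for the real and loss components. A packaged
parameter table (six tidal volumes, 30–80 mL) drives a synthetic generator
with multiplicative Gaussian measurement noise, and tidal-volume groups are
compared with a tie-corrected Kruskal–Wallis test. See the methods vignette
(`vignettes/dielspec-methods.Rmd`) for assumptions, defaults and known
limitations.

## Worked example

```r
library(dielspec)
tab <- tidal_volume_table()                      # packaged parameter table
measured <- generate_spectrum(tab[["30"]], default_grid(),
                              noise_model(0.02, 0.02, 1, seed = 1))[[1]]
fit <- fit_improved(measured, fit_config(seed = 1))
fit
#> <improved fit: Err = 2.308%, R2(real) = 0.9794, R2(loss) = 0.9882>
#>   eps_inf = 1.5, delta_eps = 60.7, tau = 5.83 ps, alpha = 0, sigma_s = 0.01989 S/m
#>   a_coef = -3.686e-09 s/rad

ds <- generate_vt_dataset(noise = noise_model(0.02, 0.02, 3, seed = 1))
kruskal_wallis(extract_at_frequency(ds, 433e6, "conductivity"))
#> Kruskal-Wallis [conductivity @ 4.33e+08 Hz]: H = 16.11, df = 5, p = 0.006534
```

The fit reproduces the generating VT=30 mL condition up to the injected 2%
noise: the average fitting error (2.3%) is at the level the noise law
implies, σs and A are recovered closely, while ε∞ — which only offsets the
much larger dispersion term in-band — is weakly identified under noise (it
recovers to <1% relative on noiseless targets; see the acceptance suite).
The Kruskal–Wallis H of 16.11 on 5 degrees of freedom (p < 0.01) says the
six tidal-volume groups differ in conductivity at 433 MHz, the synthetic
analogue of the in vivo finding.

A command-line interface covers the same workflow
(`simulate`, `fit`, `metrics`, `compare`); see `?diel_cli`. Example:

```sh
Rscript -e 'dielspec::diel_cli()' simulate --vt all --noise-cv 0.02 --seed 1 --out runs/demo
Rscript -e 'dielspec::diel_cli()' compare --manifest runs/demo/manifest.json
```

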