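# dualprobe

Quantifying cell-surface receptor binding potential in fresh tissue from
dual-probe rinse kinetics.

## The problem

Topically applied receptor-targeted molecular probes (here, antibody-
conjugated SERS nanoparticles) accumulate in tissue for reasons that have
nothing to do with the receptor: uneven delivery, trapped unbound probe,
and reversible nonspecific binding. A spectrally distinct *untargeted*
(isotype-control) probe applied as an equimolar mixture experiences the
same nonspecific effects, so the pair can be used to isolate specific
binding. After a 10-minute stain, the tissue is rinsed repeatedly and the
concentration of both probes is measured before and after each rinse,
giving a pair of concentration-vs-rinse curves per sample.

`dualprobe` implements the kinetic analysis of those curves. Each probe is
modeled by a linear compartment system over free (`C_f`), specifically
bound (`C_b`) and nonspecifically bound (`C_ns`) probe:

    dC_f/dt  = -(F + k3 + k5) C_f + k4 C_b + k6 C_ns
    dC_b/dt  =  k3 C_f - k4 C_b          (targeted probe only)
    dC_ns/dt =  k5 C_f - k6 C_ns

where `F` (min^-1) is the first-order washout of free probe produced by
serial rinsing (active only during the rinse phase), `k3`/`k4` are the
specific association/dissociation rates, and `k5`/`k6` the nonspecific
ones. The quantity of interest is the **binding potential**

    BP = k3 / k4,

the equilibrium ratio of specifically bound to free probe, proportional to
available receptor concentration times affinity.

Three estimators are provided:

* **BP_Ratio** — `(targeted - untargeted) / untargeted` at the final
  rinse; model-free, but negatively biased when nonspecific binding is
  present.
* **BP_DPM** — two-step dual-probe model fit *without* a nonspecific
  compartment: the untargeted curve is fit with `A exp(-F t)` to estimate
  the rinse rate `F`, then the targeted curve is fit for `k3, k4`.
* **BP_DPM-NS** — the same two-step scheme with the nonspecific
  compartment: the untargeted curve estimates `F, k5, k6`, which are then
  fixed while the targeted curve is fit for `k3, k4`. Fits are separable
  non-negative least squares; amplitude coefficients are solved per
  candidate by a randomized column Kaczmarz solver with Tikhonov
  regularization (`kaczmarz_tikhonov_solve()`).

The package also contains the spectral front end (`dcls_unmix()`: direct
classical least squares demultiplexing of Raman-style fingerprint spectra
against a reference library, plus `calibrate()` to convert weights to pM
against a 150 pM stock), a Monte-Carlo study of estimator bias and
precision under nonspecific binding (`run_ns_sweep()`, `run_recovery()`),
an SPSS-style group comparison (`compare_groups()`: one-way ANOVA,
Levene-gated Bonferroni/Tamhane post-hoc), synthetic cohort generation
(`generate_cohort()`), CSV/JSON I/O and a small CLI
(`inst/cli/dualprobe.R`).

## Worked example

```r
library(dualprobe)

# a U251-like sample: BP = 1 with tissue-average nonspecific binding
rates <- rate_constants(F = 2, k3 = 0.1, k4 = 0.1, k5 = 0.16, k6 = 0.06)
m <- simulate_dual_probe(rates, acquisition_schedule(),
                         noise_percent = 0.48, seed = 1)

bp_ratio(m)$bp
#> [1] 0.1178758
fit_dual_probe(m, "dpmns")
#> BP fit [DPM-NS]: BP = 1.063 (residual 1.319 pM over 11 points)
#>   rates (min^-1): F = 2.091, k3 = 0.1074, k4 = 0.101, k5 = 0.1589, k6 = 0.05849
```

The ratio estimate (0.12) grossly underestimates the generating BP of 1
because most of the retained untargeted probe is nonspecifically bound;
the DPM-NS fit, which models that compartment, recovers 1.06. Group-level
analysis of a full synthetic cohort:

```r
cohort <- generate_cohort(simulation_config(seed = 7), as_table = FALSE)
bp <- vapply(cohort, function(m)
  fit_dual_probe(m, "dpmns", k4_fixed = 0.1)$bp, numeric(1))
groups <- split(bp, vapply(cohort, `[[`, "", "tissue_label"))
compare_groups(groups)
#> One-way ANOVA: F(2, 23) = 4325, P = 2.35e-30
#> Levene (center = mean): P = 8.63e-05 -> Tamhane post-hoc
```

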